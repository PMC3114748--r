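## Genome container: reference chromosome sequences (soft-masked with
## lowercase, as in repeat-masked references) plus a per-chromosome uniform
## recombination rate in cM/Mb.

#' Construct a genome object
#'
#' A genome is a set of named chromosome sequences over `{A,C,G,T}` in which
#' lowercase letters mark repeat-masked bases, together with a recombination
#' rate (cM/Mb, constant per chromosome) used by the meiosis simulator.
#'
#' @param sequences named character vector of chromosome sequences.
#' @param rate_cM_per_Mb numeric recombination rate(s), recycled per chromosome.
#' @return an object of class `ffg_genome`.
#' @export
ffg_genome <- function(sequences, rate_cM_per_Mb = 5) {
  if (length(sequences) == 0) stop_ffg("genome needs at least one chromosome")
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop_ffg("chromosome names must be present and unique")
  if (any(!nzchar(sequences))) stop_ffg("every chromosome sequence must be nonempty")
  rate <- rep_len(rate_cM_per_Mb, length(sequences))
  if (any(rate < 0)) stop_ffg("recombination rates must be >= 0")
  names(rate) <- names(sequences)
  ## unmasked (uppercase ACGT) length per chromosome, computed once:
  ## consumers like the EMS sampler need it on every call
  unmasked <- vapply(sequences, function(s)
    nchar(s) - nchar(gsub("[ACGT]", "", s)), numeric(1))
  structure(list(seq = sequences, rate = rate, unmasked = unmasked),
            class = "ffg_genome")
}

#' @export
print.ffg_genome <- function(x, ...) {
  len <- chrom_lengths(x)
  cat(sprintf("ffg_genome: %d chromosome(s), %s bp total\n",
              length(len), format(sum(len), big.mark = ",")))
  for (nm in names(len))
    cat(sprintf("  %s  %s bp  %.3g cM/Mb\n", nm, format(len[[nm]], big.mark = ","),
                x$rate[[nm]]))
  invisible(x)
}

#' @rdname ffg_genome
#' @param genome an `ffg_genome`.
#' @export
chrom_lengths <- function(genome) vapply(genome$seq, nchar, integer(1))

## genetic length of a chromosome in Morgans
map_length_morgans <- function(genome, chrom) {
  nchar(genome$seq[[chrom]]) / 1e6 * genome$rate[[chrom]] / 100
}

#' Reference base lookup
#'
#' @param genome an `ffg_genome`.
#' @param chrom chromosome name (scalar).
#' @param pos 1-based positions.
#' @param upper uppercase the result (ignore masking)?
#' @return character vector of bases.
#' @export
genome_base <- function(genome, chrom, pos, upper = TRUE) {
  s <- genome$seq[[chrom]]
  if (is.null(s)) stop_ffg("unknown chromosome '%s'", chrom)
  if (any(pos < 1 | pos > nchar(s))) stop_ffg("position outside chromosome '%s'", chrom)
  b <- substring(s, pos, pos)
  if (upper) toupper(b) else b
}

#' @rdname genome_base
#' @export
is_masked <- function(genome, chrom, pos) {
  b <- genome_base(genome, chrom, pos, upper = FALSE)
  b %in% c("a", "c", "g", "t", "n", "N")
}

#' Simulate a reference genome and ecotype SNP marker panel
#'
#' Emulates a repeat-masked reference plus the fixed polymorphisms that
#' distinguish the mutagenized ("reference") ecotype from the mapping ecotype;
#' those polymorphisms are the genetic markers the mapping step reads out.
#' Masked bases are drawn as random blocks (geometric lengths, mean 500 bp)
#' and never carry panel SNPs.
#'
#' @param n_chrom number of chromosomes.
#' @param lengths chromosome lengths in bp (recycled to `n_chrom`).
#' @param snp_density expected panel SNPs per unmasked bp.
#' @param masked_fraction fraction of each chromosome to soft-mask, in `[0,1)`.
#' @param rate_cM_per_Mb recombination rate, cM/Mb.
#' @param min_snps_per_chrom reject densities yielding fewer expected SNPs than
#'   this per chromosome (default `2 * 25`, two mapping bins).
#' @param seed RNG seed (all simulator entry points take one).
#' @return `list(genome = ffg_genome, snp_panel = data.table)` where the panel
#'   has columns `chrom, pos, ref, map_allele` (1-based, sorted, unique).
#' @export
simulate_genome <- function(n_chrom, lengths, snp_density, masked_fraction = 0,
                            rate_cM_per_Mb = 5, min_snps_per_chrom = 50L,
                            seed = NULL) {
  if (n_chrom < 1) stop_ffg("need at least one chromosome")
  if (snp_density <= 0) stop_ffg("snp_density must be > 0")
  if (masked_fraction < 0 || masked_fraction >= 1)
    stop_ffg("masked_fraction must be in [0, 1)")
  lengths <- rep_len(as.integer(lengths), n_chrom)
  if (any(lengths <= 0)) stop_ffg("chromosome lengths must be > 0")
  exp_snps <- lengths * (1 - masked_fraction) * snp_density
  if (any(exp_snps < min_snps_per_chrom))
    stop_ffg("snp_density %g yields < %d expected SNPs on a %d bp chromosome; mapping bins would be impossible",
             snp_density, min_snps_per_chrom, lengths[which.min(exp_snps)])
  set_seed_if(seed)
  seqs <- character(n_chrom)
  names(seqs) <- paste0("chr", seq_len(n_chrom))
  panel <- vector("list", n_chrom)
  for (i in seq_len(n_chrom)) {
    L <- lengths[i]
    chars <- sample(BASES, L, replace = TRUE)
    masked <- rep(FALSE, L)
    if (masked_fraction > 0) {
      target <- masked_fraction * L
      n_masked <- 0L
      while (n_masked < target) {
        w <- 1L + stats::rgeom(1L, 1 / 500)
        s <- sample.int(L, 1L)
        idx <- s:min(L, s + w - 1L)
        n_masked <- n_masked + sum(!masked[idx])
        masked[idx] <- TRUE
      }
    }
    chars[masked] <- tolower(chars[masked])
    unmasked_idx <- which(!masked)
    n_snp <- rbinom(1L, length(unmasked_idx), min(1, snp_density))
    pos <- sort(sample(unmasked_idx, n_snp))
    ref <- toupper(chars[pos])
    panel[[i]] <- data.table(chrom = names(seqs)[i], pos = pos, ref = ref,
                             map_allele = other_base(ref))
    seqs[i] <- paste(chars, collapse = "")
  }
  list(genome = ffg_genome(seqs, rate_cM_per_Mb),
       snp_panel = rbindlist(panel))
}

## ---- FASTA / panel I/O ----

#' Read and write soft-masked genome FASTA
#'
#' `BStringSet` is used so lowercase (repeat-masked) letters survive the
#' round trip; `Biostrings::DNAStringSet` would uppercase them.
#'
#' @param genome an `ffg_genome`.
#' @param path file path.
#' @param rate_cM_per_Mb rate to attach on read (FASTA carries none).
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(genome$seq), path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path, rate_cM_per_Mb = 5) {
  x <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  ffg_genome(setNames(as.character(x), nm), rate_cM_per_Mb)
}

#' SNP panel I/O
#'
#' TSV columns `chrom, pos1, ref, alt` (1-based), or a minimal VCF 4.2.
#' @param panel data.table with `chrom, pos, ref, map_allele`.
#' @param path file path.
#' @export
write_snp_panel_tsv <- function(panel, path) {
  out <- data.table(chrom = panel$chrom, pos1 = panel$pos,
                    ref = panel$ref, alt = panel$map_allele)
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_snp_panel_tsv
#' @export
read_snp_panel_tsv <- function(path) {
  x <- fread(path)
  data.table(chrom = x$chrom, pos = as.integer(x$pos1), ref = x$ref,
             map_allele = x$alt)
}

#' @rdname write_snp_panel_tsv
#' @export
write_snp_panel_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=ffg",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(panel))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", panel$chrom, panel$pos,
                       panel$ref, panel$map_allele), con)
  invisible(path)
}

## validate a panel against its genome (used by tests and file loaders)
validate_snp_panel <- function(panel, genome) {
  for (cn in unique(panel$chrom)) {
    p <- panel[chrom == cn]
    if (is.unsorted(p$pos, strictly = TRUE))
      stop_ffg("panel positions on %s are not sorted/unique", cn)
    if (!all(genome_base(genome, cn, p$pos) == p$ref))
      stop_ffg("panel ref alleles disagree with genome on %s", cn)
  }
  if (any(panel$ref == panel$map_allele))
    stop_ffg("panel has ref == map allele rows")
  invisible(TRUE)
}
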