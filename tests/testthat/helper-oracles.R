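## Independent oracles and fixture builders shared across the test files.
## These deliberately re-derive expected values by brute force, separately
## from the package's own code paths.

library(data.table)

## ---- brute-force four-rule SNP-calling oracle -----------------------------
## A plain re-implementation of: clonality cap; coverage >= 20; > 3 unique
## start sites per called allele (ref counts as called at >= 10% of reads);
## binomial-error variant quality > 10; variant allele on both strands.
oracle_call_status <- function(obs, ref_base, crit, prior = 1e-3) {
  obs <- as.data.frame(obs, stringsAsFactors = FALSE)
  obs <- obs[obs$base != "N", , drop = FALSE]
  if (nrow(obs) > 0) {
    key <- paste(obs$base, obs$read_start, obs$strand)
    keep <- logical(nrow(obs))
    for (k in unique(key)) {
      i <- which(key == k)
      i <- i[order(-obs$qual[i], i)]
      keep[utils::head(i, crit$max_identical_reads)] <- TRUE
    }
    obs <- obs[keep, , drop = FALSE]
  }
  cov <- nrow(obs)
  cnt <- table(factor(obs$base, levels = c("A", "C", "G", "T")))
  ref_n <- cnt[[ref_base]]
  nonref <- cnt[setdiff(names(cnt), ref_base)]
  alt <- if (sum(nonref) > 0) {
    o <- order(-as.integer(nonref), names(nonref))
    names(nonref)[o][1]
  } else NA_character_
  alt_n <- if (!is.na(alt)) cnt[[alt]] else 0L
  fails <- character(0)
  if (cov < crit$min_coverage) fails <- c(fails, "min_coverage")
  if (alt_n == 0)
    return(list(status = if (cov >= crit$min_coverage) "FULLY_REFERENCE" else "FAIL",
                reasons = if (cov < crit$min_coverage) "min_coverage" else character(0)))
  ustarts <- function(a) length(unique(obs$read_start[obs$base == a]))
  ref_called <- ref_n > 0 && ref_n >= 0.10 * cov
  if ((ref_called && ustarts(ref_base) < crit$min_unique_starts) ||
      ustarts(alt) < crit$min_unique_starts)
    fails <- c(fails, "unique_starts")
  p <- pbinom(alt_n - 1, cov, prior, lower.tail = FALSE)
  q <- min(-10 * log10(max(p, 1e-300)), 3000)
  if (q <= crit$min_variant_quality) fails <- c(fails, "variant_quality")
  if (crit$require_both_strands &&
      !(any(obs$base == alt & obs$strand == "+") &&
        any(obs$base == alt & obs$strand == "-")))
    fails <- c(fails, "both_strands")
  list(status = if (length(fails)) "FAIL" else "PASS", reasons = fails)
}

## random pileup column generator exercising every filter boundary
random_column <- function(n_max = 40) {
  n <- sample.int(n_max, 1)
  p_plus <- runif(1, 0.1, 0.9)
  data.table(
    base = sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
                  prob = c(0.35, 0.35, 0.12, 0.12, 0.06)),
    strand = sample(c("+", "-"), n, replace = TRUE,
                    prob = c(p_plus, 1 - p_plus)),
    read_start = sample.int(6L, n, replace = TRUE),
    qual = sample(5:40, n, replace = TRUE)
  )
}

## ---- gamete-enumeration oracle for expected_map_fraction ------------------
## Enumerates the four gamete classes at (causal, marker) with recombination
## fraction r, forms all 16 F2 gamete pairs, conditions on phenotype, and
## returns the expected mapping-allele fraction at the marker.
oracle_map_fraction <- function(pool, r) {
  ## gamete: causal in {m, M}, marker in {mut, map}
  g <- expand.grid(causal = c("m", "M"), marker = c("mut", "map"),
                   stringsAsFactors = FALSE)
  g$p <- ifelse((g$causal == "m") == (g$marker == "mut"), (1 - r) / 2, r / 2)
  num <- 0
  den <- 0
  for (i in 1:4) for (j in 1:4) {
    pr <- g$p[i] * g$p[j]
    is_mutant <- g$causal[i] == "m" && g$causal[j] == "m"
    in_pool <- if (pool == "mutant") is_mutant else !is_mutant
    if (in_pool) {
      num <- num + pr * (sum(c(g$marker[i], g$marker[j]) == "map") / 2)
      den <- den + pr
    }
  }
  num / den
}

## ---- full-translation effect oracle ---------------------------------------
## Applies the variant to the genome, re-splices and translates the entire
## CDS of the gene, and diffs the two proteins.
oracle_effect <- function(variant, gene, genome) {
  seqs <- genome$seq
  s <- seqs[[variant$chrom]]
  substring(s, variant$pos, variant$pos) <- variant$alt
  splice <- function(seqchar) {
    parts <- vapply(seq_len(nrow(gene$cds)), function(k)
      toupper(substring(seqchar, gene$cds$start[k], gene$cds$end[k])),
      character(1))
    cds <- paste(parts, collapse = "")
    if (gene$strand == "-")
      cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    cds
  }
  tr <- function(cds) {
    suppressWarnings(as.character(
      Biostrings::translate(Biostrings::DNAString(cds), no.init.codon = TRUE)))
  }
  p_ref <- tr(splice(seqs[[variant$chrom]]))
  p_alt <- tr(splice(s))
  d <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])
  if (length(d) == 0) {
    ## silent: find the codon containing the variant
    cds_pos <- cds_offset_of(gene, variant$pos)
    ci <- (cds_pos - 1) %/% 3 + 1
    aa <- sub("\\*", "X", substring(p_ref, ci, ci))
    return(list(effect = "silent", protein_label = paste0(aa, ci, aa)))
  }
  ci <- d[1]
  aa_ref <- sub("\\*", "X", substring(p_ref, ci, ci))
  aa_alt <- sub("\\*", "X", substring(p_alt, ci, ci))
  effect <- if (aa_alt == "X") "nonsense" else "missense"
  list(effect = effect, protein_label = paste0(aa_ref, ci, aa_alt))
}

cds_offset_of <- function(gene, pos) {
  before <- 0L
  for (k in seq_len(nrow(gene$cds))) {
    if (pos >= gene$cds$start[k] && pos <= gene$cds$end[k]) {
      before <- before + (pos - gene$cds$start[k])
      break
    }
    before <- before + (gene$cds$end[k] - gene$cds$start[k] + 1L)
  }
  cds_len <- sum(gene$cds$end - gene$cds$start + 1L)
  if (gene$strand == "+") before + 1L else cds_len - before
}

## ---- fixture builders ------------------------------------------------------

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

## random coding sequence of n_codons with no internal stop codons
random_cds_seq <- function(n_codons) {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste(sample(codons, n_codons, TRUE), collapse = "")
}

## small cross world reused by several files: returns genome, panel,
## mutations (causal mid-chromosome), f2 and pools
tiny_world <- function(len = 4e5, rate = 25, n_f2 = 400, pool_size = 80,
                       snp_density = 1e-3, seed = 42, causal_pos = NULL,
                       masked_fraction = 0) {
  gs <- simulate_genome(1, len, snp_density, masked_fraction, rate, seed = seed)
  mut <- apply_ems(gs$genome, gs$snp_panel, rate = 1e-5,
                   causal_pos = causal_pos %||% round(len / 2),
                   seed = seed + 1)
  f2 <- simulate_f2(gs$genome, gs$snp_panel, mut, n_f2, seed = seed + 2)
  pools <- build_pools(f2, pool_size, seed = seed + 3)
  list(genome = gs$genome, panel = gs$snp_panel, mutations = mut, f2 = f2,
       pools = pools)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
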