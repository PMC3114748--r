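## Pooled SNP discovery and genotyping.
##
## Discovery merges the mutant and wild-type pool pileups into a "virtual F1"
## (heterozygous at every ecotype polymorphism) and applies the strict filter
## set: minimum coverage 20, more than 3 unique read start sites per called
## allele, variant quality > 10, variant alleles seen on both strands, and a
## clonality cap of twice the number of pooled individuals on identical reads
## calling the same allele. Discovered positions are then genotyped in each
## pool separately, including the fully-reference check.

#' Strict SNP-calling filter criteria
#'
#' @param min_coverage minimum accepted reads at a position (default 20).
#' @param min_unique_starts minimum unique read start sites per called allele
#'   (default 4, i.e. "more than 3").
#' @param min_variant_quality phred threshold; variant calls must exceed it
#'   (default 10).
#' @param require_both_strands must variant alleles be seen on both strands?
#' @param max_identical_reads clonality cap: maximum identical reads (same
#'   allele, read start and strand) retained, conventionally twice the number
#'   of pooled individuals.
#' @param unique_start_uses_strand if `TRUE`, (start, strand) pairs define
#'   start-site uniqueness; default `FALSE` (start alone).
#' @return an object of class `ffg_criteria`.
#' @export
filter_criteria <- function(min_coverage = 20, min_unique_starts = 4,
                            min_variant_quality = 10,
                            require_both_strands = TRUE,
                            max_identical_reads = 400,
                            unique_start_uses_strand = FALSE) {
  stopifnot(min_coverage >= 0, min_unique_starts >= 0,
            min_variant_quality >= 0, max_identical_reads >= 1)
  structure(list(min_coverage = min_coverage,
                 min_unique_starts = min_unique_starts,
                 min_variant_quality = min_variant_quality,
                 require_both_strands = isTRUE(require_both_strands),
                 max_identical_reads = max_identical_reads,
                 unique_start_uses_strand = isTRUE(unique_start_uses_strand)),
            class = "ffg_criteria")
}

#' Permissive criteria for per-pool genotyping of discovered positions
#'
#' After discovery on the virtual F1, each pool is typed at the discovered
#' positions by ratio extraction (or the fully-reference check); at 6-10x
#' per-pool coverage the strict discovery thresholds would reject nearly
#' every site, so only the clonality cap is kept.
#'
#' @param pool_individuals number of individuals in the pool.
#' @export
pool_typing_criteria <- function(pool_individuals) {
  filter_criteria(min_coverage = 1, min_unique_starts = 0,
                  min_variant_quality = 0, require_both_strands = FALSE,
                  max_identical_reads = 2 * pool_individuals)
}

check_sorted <- function(pileup, what) {
  o <- order(pileup$chrom, pileup$pos)
  if (is.unsorted(o)) stop_ffg("%s pileup is not sorted by (chrom, pos); refusing to re-sort silently", what)
  invisible(TRUE)
}

#' Merge pool pileups into a virtual F1
#'
#' Position-wise concatenation of the two observation streams; counts add.
#' Inputs must already be sorted by `(chrom, pos)` — unsorted input is an
#' error, not a silent re-sort.
#'
#' @param mutant_pileup,wildtype_pileup `ffg_pileup` data.tables.
#' @return merged `ffg_pileup`, sorted.
#' @export
merge_virtual_f1 <- function(mutant_pileup, wildtype_pileup) {
  check_sorted(mutant_pileup, "mutant")
  check_sorted(wildtype_pileup, "wildtype")
  out <- rbind(as.data.table(mutant_pileup), as.data.table(wildtype_pileup))
  setorder(out, chrom, pos)
  setattr(out, "class", c("ffg_pileup", "data.table", "data.frame"))
  out[]
}

#' Suppress clonal reads
#'
#' Among observations sharing the identity key (allele, read start, strand) at
#' a position, at most `cap` are retained: highest base quality first, then
#' input order.
#'
#' @param observations data.table with at least `base, strand, read_start,
#'   qual` (and optionally `chrom, pos`).
#' @param cap maximum identical reads retained per identity key (>= 1).
#' @export
clonality_cap <- function(observations, cap) {
  if (cap < 1) stop_ffg("clonality cap must be >= 1")
  obs <- as.data.table(observations)
  if (nrow(obs) == 0) return(obs)
  obs[, .ord := .I]
  keycols <- intersect(c("chrom", "pos", "base", "read_start", "strand"),
                       names(obs))
  setorderv(obs, c(keycols, "qual", ".ord"), order = c(rep(1L, length(keycols)), -1L, 1L))
  obs[, .keep := seq_len(.N) <= cap, by = keycols]
  out <- obs[.keep == TRUE]
  setorder(out, .ord)
  out[, c(".ord", ".keep") := NULL]
  out[]
}

## phred-scaled probability that >= alt_n of cov reads are sequencing errors
variant_quality_score <- function(alt_n, cov, error_rate_prior) {
  p <- pbinom(alt_n - 1L, cov, error_rate_prior, lower.tail = FALSE)
  q <- ifelse(alt_n <= 0, 0, phred(pmax(p, 1e-300)))
  pmin(q, 3000)
}

## Vectorised genotyping engine. `alleles` optionally forces the alt allele
## per position (data.table chrom, pos, alt) as used when typing pools at
## positions discovered on the virtual F1.
genotype_pileup <- function(pileup, genome, criteria,
                            error_rate_prior = 1e-3, alleles = NULL) {
  obs <- as.data.table(pileup)[base != "N"]
  positions <- unique(as.data.table(pileup)[, .(chrom, pos)])
  if (nrow(positions) == 0) {
    return(data.table(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), ref_fwd = integer(), ref_rev = integer(),
                      ref_starts = integer(), alt_fwd = integer(),
                      alt_rev = integer(), alt_starts = integer(),
                      coverage = integer(), ref_reads = integer(),
                      alt_reads = integer(), nonref_fraction = numeric(),
                      variant_quality = numeric(), status = character(),
                      reasons = character(), ambiguous = logical()))
  }
  capped <- clonality_cap(obs, criteria$max_identical_reads)
  if (nrow(capped) == 0) {
    calls <- copy(positions)
    calls[, `:=`(ref = genome_base(genome, .BY$chrom, pos)), by = chrom]
    calls[, `:=`(alt = NA_character_, ref_fwd = 0L, ref_rev = 0L,
                 alt_fwd = 0L, alt_rev = 0L, ref_starts = 0L, alt_starts = 0L,
                 coverage = 0L, nonref_fraction = NA_real_,
                 variant_quality = 0, status = "FAIL",
                 reasons = "min_coverage", ambiguous = FALSE)]
    return(calls[])
  }
  if (criteria$unique_start_uses_strand) {
    capped[, .skey := paste0(read_start, strand)]
  } else {
    capped[, .skey := read_start]
  }
  per_allele <- capped[, .(
    n = .N,
    n_fwd = sum(strand == "+"),
    n_rev = sum(strand == "-"),
    ustarts = uniqueN(.skey)
  ), by = .(chrom, pos, base)]
  per_allele[, ref := genome_base(genome, .BY$chrom, pos), by = chrom]
  cov <- per_allele[, .(coverage = sum(n)), by = .(chrom, pos)]

  refrow <- per_allele[base == ref,
                       .(chrom, pos, ref_fwd = n_fwd, ref_rev = n_rev,
                         ref_starts = ustarts)]
  nonref <- per_allele[base != ref]
  empty_third <- data.table(chrom = character(), pos = integer(),
                            third_n = integer())
  if (!is.null(alleles)) {
    forced <- nonref[as.data.table(alleles)[, .(chrom, pos, base = alt)],
                     on = c("chrom", "pos", "base"), nomatch = NULL]
    altrow <- forced[, .(chrom, pos, alt = base, alt_fwd = n_fwd,
                         alt_rev = n_rev, alt_starts = ustarts)]
    others <- nonref[!altrow, on = c("chrom", "pos", base = "alt")]
    third <- if (nrow(others))
      others[, .(third_n = max(n)), by = .(chrom, pos)] else empty_third
    ## positions typed with a forced allele always know their alt
    calls_alt <- as.data.table(alleles)[, .(chrom, pos, forced_alt = alt)]
  } else {
    calls_alt <- NULL
    setorder(nonref, chrom, pos, -n, base)
    altrow <- nonref[, .SD[1L], by = .(chrom, pos)][
      , .(chrom, pos, alt = base, alt_fwd = n_fwd, alt_rev = n_rev,
          alt_starts = ustarts)]
    third <- if (nrow(nonref))
      nonref[, if (.N > 1L) .(third_n = n[2L]), by = .(chrom, pos)] else empty_third
    if (!nrow(third)) third <- empty_third
  }

  calls <- copy(positions)
  calls[, ref := genome_base(genome, .BY$chrom, pos), by = chrom]
  calls <- merge(calls, refrow, by = c("chrom", "pos"), all.x = TRUE)
  calls <- merge(calls, altrow, by = c("chrom", "pos"), all.x = TRUE)
  calls <- merge(calls, third, by = c("chrom", "pos"), all.x = TRUE)
  calls <- merge(calls, cov, by = c("chrom", "pos"), all.x = TRUE)
  if (!is.null(calls_alt)) {
    calls <- merge(calls, calls_alt, by = c("chrom", "pos"), all.x = TRUE)
    calls[is.na(alt) & !is.na(forced_alt), alt := forced_alt]
    calls[, forced_alt := NULL]
  }
  for (cn in c("ref_fwd", "ref_rev", "ref_starts", "alt_fwd", "alt_rev",
               "alt_starts", "third_n", "coverage"))
    set(calls, which(is.na(calls[[cn]])), cn, 0L)

  calls[, `:=`(ref_n = ref_fwd + ref_rev, alt_n = alt_fwd + alt_rev)]
  calls[, nonref_fraction := ifelse(ref_n + alt_n > 0,
                                    alt_n / (ref_n + alt_n), NA_real_)]
  calls[, variant_quality := variant_quality_score(alt_n, coverage, error_rate_prior)]
  calls[, ambiguous := third_n > 0.10 * coverage]

  ## the four filter rules. "Unique start sites per allele" applies to every
  ## called allele: the variant allele always, the reference allele only when
  ## it makes up >= 10% of accepted reads (a stray error read calling ref at
  ## a homozygous-variant site is not a called allele; 10% matches the
  ## third-allele ambiguity bound).
  fail_cov <- calls$coverage < criteria$min_coverage
  ref_called <- calls$ref_n >= 0.10 * calls$coverage & calls$ref_n > 0
  called_ref_bad <- ref_called & calls$ref_starts < criteria$min_unique_starts
  called_alt_bad <- calls$alt_n > 0 & calls$alt_starts < criteria$min_unique_starts
  fail_starts <- called_ref_bad | called_alt_bad
  fail_qual <- calls$alt_n > 0 & calls$variant_quality <= criteria$min_variant_quality
  fail_strand <- calls$alt_n > 0 & criteria$require_both_strands &
    !(calls$alt_fwd > 0 & calls$alt_rev > 0)

  reason <- paste0(ifelse(fail_cov, "min_coverage,", ""),
                   ifelse(fail_starts, "unique_starts,", ""),
                   ifelse(fail_qual, "variant_quality,", ""),
                   ifelse(fail_strand, "both_strands,", ""))
  reason <- sub(",$", "", reason)
  any_fail <- fail_cov | fail_starts | fail_qual | fail_strand
  calls[, status := fifelse(alt_n == 0L,
                            fifelse(fail_cov, "FAIL", "FULLY_REFERENCE"),
                            fifelse(any_fail, "FAIL", "PASS"))]
  calls[, reasons := fifelse(status == "FAIL",
                             fifelse(alt_n == 0L, "min_coverage", reason), "")]
  calls[, third_n := NULL]
  setnames(calls, c("ref_n", "alt_n"), c("ref_reads", "alt_reads"))
  setorder(calls, chrom, pos)
  calls[]
}

#' Call a SNP at a single pileup column
#'
#' Applies the clonality cap, then evaluates the four strict rules: coverage,
#' unique start sites per called allele, variant quality (phred-scaled
#' probability that the variant reads arise from sequencing error alone under
#' a binomial model), and both-strand support. `status` is `PASS` only when
#' all hold; `FAIL` carries the violated criteria; a site with adequate
#' coverage and zero variant reads is `FULLY_REFERENCE`.
#'
#' @param column data.frame of observations (`base, strand, read_start, qual`).
#' @param ref_base the reference base at the position.
#' @param criteria an `ffg_criteria`.
#' @param error_rate_prior binomial error prior for variant quality.
#' @param alt_allele optionally force the variant allele to count.
#' @return an `ffg_snp_call` list.
#' @export
call_snp <- function(column, ref_base, criteria, error_rate_prior = 1e-3,
                     alt_allele = NULL) {
  col <- as.data.table(column)
  if (nrow(col) == 0) {
    return(structure(list(chrom = NA_character_, pos = NA_integer_,
                          ref_allele = ref_base, alt_allele = NA_character_,
                          ref_reads = 0L, alt_reads = 0L, coverage = 0L,
                          nonref_fraction = NA_real_, variant_quality = 0,
                          status = "FAIL", reasons = "min_coverage",
                          ambiguous = FALSE),
                     class = "ffg_snp_call"))
  }
  orig_chrom <- if ("chrom" %in% names(col)) col$chrom[1] else "col"
  orig_pos <- if ("pos" %in% names(col)) col$pos[1] else 1L
  ## remap to a one-base genome stub so the engine path is the tested path
  col[, `:=`(chrom = "col", pos = 1L)]
  g <- ffg_genome(c(col = ref_base), 0)
  alleles <- if (!is.null(alt_allele))
    data.table(chrom = col$chrom[1], pos = col$pos[1], alt = alt_allele)
  call <- genotype_pileup(col, g, criteria, error_rate_prior, alleles = alleles)
  structure(list(chrom = orig_chrom, pos = orig_pos, ref_allele = call$ref,
                 alt_allele = call$alt,
                 ref_reads = call$ref_reads, alt_reads = call$alt_reads,
                 ref_fwd = call$ref_fwd, ref_rev = call$ref_rev,
                 alt_fwd = call$alt_fwd, alt_rev = call$alt_rev,
                 coverage = call$coverage,
                 nonref_fraction = call$nonref_fraction,
                 variant_quality = call$variant_quality,
                 status = call$status,
                 reasons = if (nzchar(call$reasons))
                   strsplit(call$reasons, ",")[[1]] else character(0),
                 ambiguous = call$ambiguous),
            class = "ffg_snp_call")
}

#' @export
print.ffg_snp_call <- function(x, ...) {
  cat(sprintf("ffg_snp_call %s:%s %s>%s  %d ref / %d alt (cov %d)  q=%.1f  %s%s\n",
              x$chrom, x$pos, x$ref_allele, x$alt_allele %||% ".",
              x$ref_reads, x$alt_reads, x$coverage, x$variant_quality,
              x$status,
              if (length(x$reasons)) paste0(" {", paste(x$reasons, collapse = ","), "}") else ""))
  invisible(x)
}

#' Discover variable positions on the virtual F1 and genotype each pool
#'
#' @param mutant_pileup,wildtype_pileup sorted `ffg_pileup`s.
#' @param genome an `ffg_genome`.
#' @param criteria strict discovery criteria; the clonality cap is doubled on
#'   the merged stream (the virtual F1 carries both pools' individuals).
#' @param pool_criteria criteria used when typing each pool at the discovered
#'   positions; defaults to [pool_typing_criteria()] with the cap taken from
#'   `criteria`.
#' @param error_rate_prior binomial error prior.
#' @return a list with `variable` (discovered positions with alleles),
#'   `mutant` / `wildtype` (per-pool call tables carrying `nonref_fraction`
#'   for binning) and `discovery` (the full virtual-F1 call table).
#' @export
discover_and_genotype <- function(mutant_pileup, wildtype_pileup, genome,
                                  criteria = filter_criteria(),
                                  pool_criteria = NULL,
                                  error_rate_prior = 1e-3) {
  virtual <- merge_virtual_f1(mutant_pileup, wildtype_pileup)
  disc_criteria <- criteria
  disc_criteria$max_identical_reads <- 2 * criteria$max_identical_reads
  discovery <- genotype_pileup(virtual, genome, disc_criteria, error_rate_prior)
  variable <- discovery[status == "PASS" & ambiguous == FALSE,
                        .(chrom, pos, ref, alt)]
  pool_criteria <- pool_criteria %||% {
    pc <- pool_typing_criteria(1)
    pc$max_identical_reads <- criteria$max_identical_reads
    pc
  }
  type_pool <- function(pp) {
    sub <- as.data.table(pp)[variable[, .(chrom, pos)], on = c("chrom", "pos"),
                             nomatch = NULL]
    if (nrow(sub) == 0)
      return(genotype_pileup(sub, genome, pool_criteria, error_rate_prior))
    genotype_pileup(sub, genome, pool_criteria, error_rate_prior,
                    alleles = variable)
  }
  list(variable = variable,
       mutant = type_pool(mutant_pileup),
       wildtype = type_pool(wildtype_pileup),
       discovery = discovery)
}

#' Write per-pool calls as TSV or minimal VCF 4.2
#'
#' @param calls call table from [discover_and_genotype()] / [genotype_pileup()].
#' @param path file path.
#' @param pool pool label recorded in the TSV.
#' @export
write_calls_tsv <- function(calls, path, pool = "pool") {
  out <- calls[, .(chrom, pos1 = pos, pool = pool, ref, alt,
                   ref_reads, alt_reads, nonref_fraction, coverage,
                   variant_quality, status, ambiguous, reasons)]
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
read_calls_tsv <- function(path) {
  x <- fread(path)
  data.table(chrom = as.character(x$chrom), pos = as.integer(x$pos1),
             ref = x$ref, alt = x$alt, ref_reads = as.integer(x$ref_reads),
             alt_reads = as.integer(x$alt_reads),
             nonref_fraction = as.numeric(x$nonref_fraction),
             coverage = as.integer(x$coverage),
             variant_quality = as.numeric(x$variant_quality),
             status = as.character(x$status),
             ambiguous = as.logical(x$ambiguous),
             reasons = as.character(x$reasons))
}

#' @rdname write_calls_tsv
#' @export
write_calls_vcf <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=ffg",
               "##INFO=<ID=NF,Number=1,Type=Float,Description=\"Non-reference fraction\">",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Accepted coverage\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls)) {
    filt <- ifelse(calls$status == "PASS", "PASS",
                   ifelse(calls$status == "FULLY_REFERENCE", "FullyReference",
                          gsub(",", ";", calls$reasons)))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%.1f\t%s\tNF=%.4f;DP=%d",
                       calls$chrom, calls$pos, calls$ref,
                       ifelse(is.na(calls$alt), ".", calls$alt),
                       calls$variant_quality, filt,
                       ifelse(is.na(calls$nonref_fraction), 0, calls$nonref_fraction),
                       calls$coverage), con)
  }
  invisible(path)
}
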