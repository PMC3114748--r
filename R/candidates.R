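## Candidate causal-mutation calling in the enriched interval.
##
## At ~1,000x-plus pooled coverage of the captured region, the causal
## mutation (and EMS mutations tightly linked to it) appears as a
## high-frequency novel non-reference allele; ecotype polymorphisms are
## filtered away using the known panel and the wild-type pool's variable
## positions. The >70% frequency bound is deliberately loose, absorbing
## sequencing noise and pool missorting.

#' Call candidate causal mutations in an enriched region
#'
#' A candidate is a PASS site under the strict criteria whose
#' `nonref_fraction` strictly exceeds `freq_threshold` and which is absent
#' from the known SNP panel and from the wild-type pool's variable positions.
#' Candidates are annotated against gene models when provided and flagged for
#' the EMS G/C -> A/T signature. A coverage report (fraction of surveyed
#' positions at or above `min_report_coverage`, plus uninspected intervals)
#' accompanies the calls; a zero-coverage region yields an empty candidate
#' list plus that report, not an error.
#'
#' @param pileup `ffg_pileup` restricted to (or intersected with) the region.
#' @param region `list(chrom, start, end)`, 1-based closed.
#' @param genome an `ffg_genome`.
#' @param criteria strict `ffg_criteria` (clonality cap = 2 x pool size).
#' @param freq_threshold candidate frequency bound, exclusive (default 0.70).
#' @param snp_panel known ecotype SNP panel (`NULL` if unavailable).
#' @param wildtype_calls wild-type pool call table; PASS positions whose
#'   wild-type `nonref_fraction` exceeds `wt_exclude_threshold` are treated
#'   as fixed ecotype-vs-reference differences and excluded. (Segregating
#'   variants linked to the causal locus run at ~1/3 in the wild-type pool
#'   and must survive this filter; fixed ecotype differences are near 100%
#'   in both pools.)
#' @param wt_exclude_threshold wild-type frequency above which a position is
#'   considered ecotype variation (default 0.70, matching the candidate
#'   bound; at light wild-type coverage a lower bound would self-exclude
#'   segregating causal variants by binomial noise).
#' @param gene_models list of `ffg_gene` (or `NULL` for effect "unannotated").
#' @param error_rate_prior binomial error prior.
#' @param min_report_coverage coverage bound for the report (default 20).
#' @param surveyed_positions optionally the positions sequencing targeted
#'   (`data.table(chrom, pos)`); defaults to every base of the region, which
#'   is correct for complete pileups and pessimistic for sparse ones.
#' @return `list(candidates = data.table, coverage = list(n_surveyed,
#'   n_ge_min, fraction_ge_min, uninspected))`.
#' @export
call_candidates <- function(pileup, region, genome, criteria,
                            freq_threshold = 0.70, snp_panel = NULL,
                            wildtype_calls = NULL, gene_models = NULL,
                            error_rate_prior = 1e-3,
                            min_report_coverage = 20,
                            surveyed_positions = NULL,
                            wt_exclude_threshold = 0.70) {
  lens <- chrom_lengths(genome)
  if (!region$chrom %in% names(lens) || region$start < 1 ||
      region$end > lens[[region$chrom]] || region$start > region$end)
    stop_ffg("region %s:%s-%s is not within the genome",
             region$chrom, region$start, region$end)
  sub <- as.data.table(pileup)[chrom == region$chrom & pos >= region$start &
                                 pos <= region$end]
  empty <- data.table(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), nonref_fraction = numeric(),
                      coverage = integer(), variant_quality = numeric(),
                      effect = character(), protein_label = character(),
                      is_gc_to_at = logical())
  surveyed <- if (is.null(surveyed_positions))
    data.table(chrom = region$chrom, pos = seq(region$start, region$end))
  else as.data.table(surveyed_positions)[chrom == region$chrom &
                                           pos >= region$start & pos <= region$end]
  if (nrow(sub) == 0) {
    return(list(candidates = empty,
                coverage = coverage_report(sub, surveyed, region,
                                           min_report_coverage)))
  }
  calls <- genotype_pileup(sub, genome, criteria, error_rate_prior)
  excl_key <- character(0)
  if (!is.null(snp_panel) && nrow(snp_panel))
    excl_key <- c(excl_key, paste(snp_panel$chrom, snp_panel$pos))
  if (!is.null(wildtype_calls) && nrow(wildtype_calls)) {
    wv <- as.data.table(wildtype_calls)[status == "PASS" &
                                          nonref_fraction > wt_exclude_threshold]
    excl_key <- c(excl_key, paste(wv$chrom, wv$pos))
  }
  cand <- calls[status == "PASS" & ambiguous == FALSE &
                  nonref_fraction > freq_threshold &
                  !paste(chrom, pos) %in% excl_key]
  if (nrow(cand)) {
    eff <- lapply(seq_len(nrow(cand)), function(i) {
      if (is.null(gene_models))
        list(effect = "unannotated", protein_label = "")
      else annotate_effect(cand[i, .(chrom, pos, ref, alt)], gene_models, genome)
    })
    cand[, effect := vapply(eff, `[[`, character(1), "effect")]
    cand[, protein_label := vapply(eff, `[[`, character(1), "protein_label")]
    cand[, is_gc_to_at := is_gc_to_at_pair(ref, alt)]
    cand <- cand[, .(chrom, pos, ref, alt, nonref_fraction, coverage,
                     variant_quality, effect, protein_label, is_gc_to_at)]
  } else cand <- empty
  list(candidates = cand,
       coverage = coverage_report(sub, surveyed, region, min_report_coverage))
}

coverage_report <- function(sub, surveyed, region, min_cov) {
  if (nrow(sub)) {
    depth <- sub[, .(cov = .N), by = .(chrom, pos)]
    surveyed <- merge(surveyed, depth, by = c("chrom", "pos"), all.x = TRUE)
    surveyed[is.na(cov), cov := 0L]
  } else {
    surveyed <- copy(surveyed)[, cov := 0L]
  }
  ok <- surveyed[cov >= min_cov]
  uninspected <- if (nrow(ok)) {
    covered <- IRanges::reduce(IRanges::IRanges(ok$pos, ok$pos))
    gaps <- IRanges::gaps(covered, start = region$start, end = region$end)
    data.table(start = IRanges::start(gaps), end = IRanges::end(gaps))
  } else data.table(start = region$start, end = region$end)
  list(n_surveyed = nrow(surveyed), n_ge_min = nrow(ok),
       fraction_ge_min = if (nrow(surveyed)) nrow(ok) / nrow(surveyed) else 0,
       uninspected = uninspected)
}

#' Which variants fall inside a genomic interval
#'
#' @param variants data.frame with `chrom, pos`.
#' @param chrom,start,end 1-based closed interval.
#' @return the subset of rows inside the interval.
#' @export
variants_in_region <- function(variants, chrom, start, end) {
  v <- as.data.table(variants)
  v[v$chrom == chrom & v$pos >= start & v$pos <= end]
}

#' Candidate output writers
#' @param candidates candidate table from [call_candidates()].
#' @param path file path.
#' @export
write_candidates_vcf <- function(candidates, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=ffg",
               "##INFO=<ID=NF,Number=1,Type=Float,Description=\"Non-reference fraction\">",
               "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Predicted effect\">",
               "##INFO=<ID=AAC,Number=1,Type=String,Description=\"Protein change\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(candidates))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%.1f\tPASS\tNF=%.4f;EFF=%s;AAC=%s",
                       candidates$chrom, candidates$pos, candidates$ref,
                       candidates$alt, candidates$variant_quality,
                       candidates$nonref_fraction, candidates$effect,
                       ifelse(nzchar(candidates$protein_label),
                              candidates$protein_label, ".")), con)
  invisible(path)
}

#' @rdname write_candidates_vcf
#' @export
write_candidates_tsv <- function(candidates, path) {
  fwrite(candidates[, .(chrom, pos1 = pos, ref, alt, nonref_fraction,
                        coverage, effect, protein_label, is_gc_to_at)],
         path, sep = "\t")
  invisible(path)
}

#' @rdname write_candidates_vcf
#' @param uninspected `data.table(start, end)` from the coverage report.
#' @param chrom chromosome of the region.
#' @export
write_uninspected_bed <- function(uninspected, chrom, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(uninspected))
    writeLines(sprintf("%s\t%d\t%d\tuninspected", chrom,
                       uninspected$start - 1L, uninspected$end), con)
  invisible(path)
}
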