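## End-to-end two-step orchestration: simulate (or load) -> discover and
## genotype -> binned mapping -> capture-interval selection and probe design
## -> enriched deep sequencing -> candidate mutations, with a truth
## comparison in simulate mode.

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 131 + k) %% 2147483647)
}

## hash of the scientific configuration; output paths deliberately excluded
## so identical experiments hash identically wherever they are written
config_hash <- function(config) {
  x <- unclass(config)
  rlang::hash(x[setdiff(names(x), "output")])
}

#' Run the two-step mapping pipeline
#'
#' In simulate mode: builds the genome and marker panel, applies EMS, selfs
#' the F1 to an F2, sorts and pools segregants, light-sequences both pools,
#' discovers SNPs on the virtual F1 and genotypes the pools, bins
#' mapping-allele fractions, detects the linked region, selects the capture
#' interval, designs tiling probes, deep-sequences the enriched mutant pool
#' and calls candidate mutations. All intermediates can be written to
#' `config$output$dir` in the declared text formats; outputs are byte-stable
#' for a fixed config.
#'
#' @param config an `ffg_config`.
#' @param genome,snp_panel optionally a pre-built genome and panel (shared
#'   across [multiplex()] runs); otherwise simulated from the config.
#' @return an `ffg_report`.
#' @export
run_pipeline <- function(config, genome = NULL, snp_panel = NULL) {
  stopifnot(inherits(config, "ffg_config"))
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_ffg("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  if (config$mode == "real-data")
    return(run_pipeline_real(config))

  gcfg <- config$genome
  if (is.null(genome)) {
    gs <- stage("simulate_genome", simulate_genome(
      gcfg$n_chrom, gcfg$lengths, gcfg$snp_density, gcfg$masked_fraction,
      gcfg$rate_cM_per_Mb, seed = derive_seed(seed, 1L)))
    genome <- gs$genome
    snp_panel <- gs$snp_panel
  }
  ecfg <- config$ems
  mutations <- stage("apply_ems", apply_ems(
    genome, snp_panel, ecfg$rate, ecfg$gc_to_at_bias,
    causal_pos = if (identical(ecfg$causal_pos, "random")) "random"
      else as.integer(ecfg$causal_pos),
    causal_chrom = if (nzchar(ecfg$causal_chrom)) ecfg$causal_chrom else NULL,
    seed = derive_seed(seed, 2L)))
  f2 <- stage("simulate_f2", simulate_f2(genome, snp_panel, mutations,
                                         config$cross$n_f2,
                                         seed = derive_seed(seed, 3L)))
  pools <- stage("build_pools", build_pools(f2, config$pools$pool_size,
                                            config$pools$missort_rate,
                                            seed = derive_seed(seed, 4L)))
  scfg <- config$sequencing
  vs <- variable_sites(f2)
  light_pos <- rbind(vs[, .(chrom, pos)],
                     sample_background_sites(genome, vs,
                                             scfg$background_sites,
                                             seed = derive_seed(seed, 5L)))
  setorder(light_pos, chrom, pos)
  light_pos <- unique(light_pos)
  mut_pileup <- stage("sequence_mutant", sequence_pool(
    pools$mutant, genome, light_pos, scfg$light_depth, scfg$error_rate,
    scfg$read_len, seed = derive_seed(seed, 6L)))
  wt_pileup <- stage("sequence_wildtype", sequence_pool(
    pools$wildtype, genome, light_pos, scfg$light_depth, scfg$error_rate,
    scfg$read_len, seed = derive_seed(seed, 7L)))
  fcfg <- config$filters
  criteria <- filter_criteria(fcfg$min_coverage, fcfg$min_unique_starts,
                              fcfg$min_variant_quality,
                              fcfg$require_both_strands,
                              max_identical_reads = 2 * config$pools$pool_size)
  dg <- stage("discover_and_genotype", discover_and_genotype(
    mut_pileup, wt_pileup, genome, criteria,
    error_rate_prior = scfg$error_rate))
  mcfg <- config$mapping
  aligned <- align_pool_calls(dg$mutant, dg$wildtype)
  mut_bins <- stage("bin_mutant", bin_frequencies(aligned$mutant, mcfg$bin_size))
  wt_bins <- stage("bin_wildtype", bin_frequencies(aligned$wildtype, mcfg$bin_size))
  regions <- stage("detect_linkage", detect_linkage(
    mut_bins, wt_bins, mcfg$dip_threshold, mcfg$wt_threshold, mcfg$min_run,
    mcfg$max_gap, mcfg$gap_fraction))
  capture <- select_capture_region(mut_bins, regions, mcfg$capture_low,
                                   mcfg$capture_pad, mcfg$max_gap)

  design <- NULL
  if (isTRUE(config$probes$enabled) && !is.null(capture)) {
    pcfg <- config$probes
    design <- stage("design_probes", design_probes(
      genome, capture, pcfg$slide, pcfg$window, pcfg$reverse_offset,
      pcfg$target_tm, pcfg$w_gc, pcfg$w_homopolymer))
    if (isTRUE(pcfg$uniqueness))
      design <- stage("uniqueness_filter", uniqueness_filter(design, genome))
  }

  enriched <- NULL
  cand <- list(candidates = NULL, coverage = NULL)
  if (!is.null(capture)) {
    surv <- sample_background_sites(genome, vs, scfg$survey_sites,
                                    region = capture,
                                    seed = derive_seed(seed, 8L))
    epos <- rbind(vs[chrom == capture$chrom & pos >= capture$start &
                       pos <= capture$end, .(chrom, pos)], surv)
    epos <- unique(epos)
    setorder(epos, chrom, pos)
    enriched <- stage("sequence_enriched", sequence_pool(
      pools$mutant, genome, epos, scfg$enriched_depth, scfg$error_rate,
      scfg$read_len, seed = derive_seed(seed, 9L)))
    cand <- stage("call_candidates", call_candidates(
      enriched, capture, genome, criteria,
      freq_threshold = config$candidates$freq_threshold,
      snp_panel = if (isTRUE(config$candidates$use_known_panel)) snp_panel,
      wildtype_calls = dg$wildtype,
      gene_models = NULL,
      error_rate_prior = scfg$error_rate,
      surveyed_positions = epos,
      wt_exclude_threshold = config$candidates$wt_exclude_threshold))
  }

  causal <- mutations[is_causal == TRUE]
  causal_in_region <- !is.null(capture) && causal$chrom == capture$chrom &&
    causal$pos >= capture$start && causal$pos <= capture$end
  cand_row <- if (!is.null(cand$candidates))
    cand$candidates[chrom == causal$chrom & pos == causal$pos] else NULL
  supported <- if (nrow(regions)) regions[supported == TRUE] else regions
  region_hit <- nrow(supported) > 0 &&
    any(supported$chrom == causal$chrom & supported$start <= causal$pos &
          supported$end >= causal$pos)
  truth <- list(
    causal_chrom = causal$chrom, causal_pos = causal$pos,
    n_supported_regions = if (nrow(regions)) sum(regions$supported) else 0L,
    causal_in_supported_region = region_hit,
    causal_in_capture = causal_in_region,
    causal_called_candidate = !is.null(cand_row) && nrow(cand_row) == 1,
    causal_nonref_fraction = if (!is.null(cand_row) && nrow(cand_row))
      cand_row$nonref_fraction else NA_real_,
    distance_from_capture_center = if (causal_in_region)
      abs(causal$pos - (capture$start + capture$end) / 2) else NA_real_)

  report <- structure(list(
    mode = "simulate",
    config = config,
    stages = list(
      n_panel_snps = nrow(snp_panel),
      n_mutations = nrow(mutations),
      n_f2 = f2$n,
      n_mutant_phenotype = sum(f2$phenotype == "mutant"),
      n_variable = nrow(dg$variable),
      n_bins = nrow(mut_bins),
      n_regions = nrow(regions),
      n_supported_regions = if (nrow(regions)) sum(regions$supported) else 0L,
      capture = capture,
      n_probes = if (!is.null(design)) nrow(design$probes) else 0L,
      n_candidates = if (!is.null(cand$candidates)) nrow(cand$candidates) else 0L,
      enriched_fraction_ge20 = if (!is.null(cand$coverage))
        cand$coverage$fraction_ge_min else NA_real_,
      ## on-target coverage is what the config states; the raw sequencing
      ## needed to reach it at the configured on-target read fraction
      enriched_raw_depth_equivalent = scfg$enriched_depth / scfg$on_target),
    truth = truth,
    tables = list(variable = dg$variable, mutant_calls = dg$mutant,
                  wildtype_calls = dg$wildtype, mutant_bins = mut_bins,
                  wildtype_bins = wt_bins, regions = regions,
                  candidates = cand$candidates, mutations = mutations,
                  snp_panel = snp_panel),
    design = design,
    config_hash = config_hash(config),
    version = as.character(utils::packageVersion("ffg"))),
    class = "ffg_report")
  if (nzchar(config$output$dir %||% ""))
    write_report_outputs(report, config$output$dir)
  report
}

## real-data mode: consume declared file formats, degrade gracefully
run_pipeline_real <- function(config) {
  inp <- config$inputs
  if (!nzchar(inp$genome_fasta)) stop_ffg("real-data mode requires inputs$genome_fasta")
  genome <- read_genome_fasta(inp$genome_fasta, config$genome$rate_cM_per_Mb)
  snp_panel <- if (nzchar(inp$snp_panel)) read_snp_panel_tsv(inp$snp_panel)
  gene_models <- if (nzchar(inp$gff)) read_gene_models(inp$gff)
  fcfg <- config$filters
  criteria <- filter_criteria(fcfg$min_coverage, fcfg$min_unique_starts,
                              fcfg$min_variant_quality,
                              fcfg$require_both_strands,
                              max_identical_reads = 2 * config$pools$pool_size)
  dg <- mut_bins <- wt_bins <- regions <- NULL
  if (nzchar(inp$mutant_pileup) && nzchar(inp$wildtype_pileup)) {
    dg <- discover_and_genotype(read_pileup(inp$mutant_pileup),
                                read_pileup(inp$wildtype_pileup),
                                genome, criteria,
                                error_rate_prior = config$sequencing$error_rate)
    mut_bins <- bin_frequencies(dg$mutant, config$mapping$bin_size)
    wt_bins <- bin_frequencies(dg$wildtype, config$mapping$bin_size)
    regions <- detect_linkage(mut_bins, wt_bins, config$mapping$dip_threshold,
                              config$mapping$wt_threshold, config$mapping$min_run)
  }
  cand <- NULL
  region <- if (nzchar(inp$region)) parse_region(inp$region)
  if (nzchar(inp$enriched_pileup) && !is.null(region)) {
    cand <- call_candidates(read_pileup(inp$enriched_pileup), region, genome,
                            criteria,
                            freq_threshold = config$candidates$freq_threshold,
                            snp_panel = snp_panel,
                            wildtype_calls = if (!is.null(dg)) dg$wildtype,
                            gene_models = gene_models,
                            error_rate_prior = config$sequencing$error_rate)
  }
  structure(list(mode = "real-data", config = config,
                 stages = list(
                   n_variable = if (!is.null(dg)) nrow(dg$variable) else 0L,
                   n_bins = if (!is.null(mut_bins)) nrow(mut_bins) else 0L,
                   n_regions = if (!is.null(regions)) nrow(regions) else 0L,
                   n_candidates = if (!is.null(cand)) nrow(cand$candidates) else 0L),
                 truth = NULL,
                 tables = list(variable = if (!is.null(dg)) dg$variable,
                               mutant_calls = if (!is.null(dg)) dg$mutant,
                               wildtype_calls = if (!is.null(dg)) dg$wildtype,
                               mutant_bins = mut_bins, wildtype_bins = wt_bins,
                               regions = regions,
                               candidates = if (!is.null(cand)) cand$candidates),
                 design = NULL,
                 config_hash = config_hash(config),
                 version = as.character(utils::packageVersion("ffg"))),
            class = "ffg_report")
}

#' Parse a `chr:start-end` region string
#' @param x region string, 1-based closed.
#' @export
parse_region <- function(x) {
  m <- regmatches(x, regexec("^(.+):([0-9,]+)[-_]([0-9,]+)$", x))[[1]]
  if (length(m) != 4) stop_ffg("cannot parse region '%s' (expected chr:start-end)", x)
  list(chrom = m[2], start = as.integer(gsub(",", "", m[3])),
       end = as.integer(gsub(",", "", m[4])))
}

## uniform sample of monomorphic unmasked sites (genome-wide or in a region)
sample_background_sites <- function(genome, vs, n, region = NULL, seed = NULL) {
  set_seed_if(seed)
  if (n <= 0) return(data.table(chrom = character(), pos = integer()))
  lens <- chrom_lengths(genome)
  out <- vector("list", 0)
  got <- 0L
  tries <- 0L
  key_var <- paste(vs$chrom, vs$pos)
  while (got < n && tries < 20L) {
    tries <- tries + 1L
    need <- (n - got) * 2L
    if (is.null(region)) {
      cn <- sample(names(lens), need, replace = TRUE, prob = lens / sum(lens))
      p <- floor(runif(need) * lens[cn]) + 1L
    } else {
      cn <- rep(region$chrom, need)
      p <- floor(runif(need) * (region$end - region$start + 1)) + region$start
    }
    cand <- unique(data.table(chrom = cn, pos = as.integer(p)))
    setorder(cand, chrom, pos)
    cand <- cand[!paste(chrom, pos) %in% key_var]
    if (nrow(cand)) {
      cand[, .masked := is_masked(genome, .BY$chrom, pos), by = chrom]
      cand <- cand[.masked == FALSE][, .masked := NULL]
    }
    if (nrow(cand)) {
      out[[length(out) + 1L]] <- cand
      got <- got + nrow(cand)
    }
  }
  if (!length(out)) return(data.table(chrom = character(), pos = integer()))
  res <- unique(rbindlist(out))
  res[seq_len(min(n, nrow(res)))]
}

#' @export
print.ffg_report <- function(x, ...) {
  cat(sprintf("ffg_report (%s mode)\n", x$mode))
  s <- x$stages
  for (nm in names(s)) {
    v <- s[[nm]]
    if (is.list(v)) v <- if (is.null(v)) "none" else
      sprintf("%s:%d-%d", v$chrom, v$start, v$end)
    cat(sprintf("  %-28s %s\n", nm, paste(format(v), collapse = " ")))
  }
  if (!is.null(x$truth)) {
    cat("  truth comparison:\n")
    for (nm in names(x$truth))
      cat(sprintf("    %-28s %s\n", nm, format(x$truth[[nm]])))
  }
  invisible(x)
}

write_report_outputs <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  write_config(report$config, fp("config.json"))
  tb <- report$tables
  if (!is.null(tb$snp_panel)) write_snp_panel_tsv(tb$snp_panel, fp("snp_panel.tsv"))
  if (!is.null(tb$mutations)) write_mutations_tsv(tb$mutations, fp("mutations.tsv"))
  if (!is.null(tb$mutant_calls)) {
    write_calls_tsv(tb$mutant_calls, fp("calls_mutant.tsv"), "mutant")
    write_calls_vcf(tb$mutant_calls, fp("calls_mutant.vcf"))
  }
  if (!is.null(tb$wildtype_calls)) {
    write_calls_tsv(tb$wildtype_calls, fp("calls_wildtype.tsv"), "wildtype")
    write_calls_vcf(tb$wildtype_calls, fp("calls_wildtype.vcf"))
  }
  if (!is.null(tb$mutant_bins)) write_bins_tsv(tb$mutant_bins, fp("bins_mutant.tsv"), "mutant")
  if (!is.null(tb$wildtype_bins)) write_bins_tsv(tb$wildtype_bins, fp("bins_wildtype.tsv"), "wildtype")
  if (!is.null(tb$regions)) write_regions_bed(tb$regions, fp("regions.bed"))
  if (!is.null(tb$candidates)) {
    write_candidates_tsv(tb$candidates, fp("candidates.tsv"))
    write_candidates_vcf(tb$candidates, fp("candidates.vcf"))
  }
  if (!is.null(report$design)) {
    write_probes_tsv(report$design, fp("probes.tsv"))
    write_probes_fasta(report$design, fp("probes.fasta"),
                       kept_only = !anyNA(report$design$probes$kept))
    write_probes_bed(report$design, fp("probes.bed"),
                     kept_only = !anyNA(report$design$probes$kept))
  }
  summary <- list(mode = report$mode, stages = report$stages,
                  truth = report$truth, config_hash = report$config_hash,
                  version = report$version)
  jsonlite::write_json(summary, fp("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(dir)
}

#' Run several mutants against a shared reference
#'
#' All configs must describe the same genome; the genome and marker panel are
#' simulated once and shared, then each mutant's cross, pools, sequencing and
#' mapping run independently (no cross-talk).
#'
#' @param configs list of `ffg_config`.
#' @return list of `ffg_report`s.
#' @export
multiplex <- function(configs) {
  if (length(configs) == 0) return(list())
  g0 <- configs[[1]]$genome
  for (cfg in configs)
    if (!identical(cfg$genome, g0))
      stop_ffg("multiplex configs disagree on the genome specification")
  gs <- simulate_genome(g0$n_chrom, g0$lengths, g0$snp_density,
                        g0$masked_fraction, g0$rate_cM_per_Mb,
                        seed = derive_seed(configs[[1]]$seed, 1L))
  lapply(configs, run_pipeline, genome = gs$genome, snp_panel = gs$snp_panel)
}
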