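## Run configuration: every simulator, filter, mapping, candidate and probe
## parameter plus all seeds, round-trippable to JSON.

#' Build a pipeline run configuration
#'
#' Defaults describe the reference experiment the simulator emulates: one
#' 10 Mb chromosome, ecotype SNPs at ~1/kb, EMS at 1/100 kb with the 0.85
#' G/C->A/T bias, an F2 of 800 plants pooled 200/200, light sequencing at
#' 10x and enriched sequencing of the capture interval at 1,600x with
#' per-base error 1e-3 and 50 bp reads. Empty strings mean "not set".
#'
#' @param ... named overrides of the nested defaults, e.g.
#'   `pools = list(pool_size = 100)` (partial lists are merged).
#' @param mode `"simulate"` or `"real-data"`.
#' @param seed master seed; every stochastic stage derives its own stream
#'   from it.
#' @return a nested list of class `ffg_config`.
#' @export
run_config <- function(..., mode = "simulate", seed = 1L) {
  defaults <- list(
    mode = mode,
    seed = as.integer(seed),
    genome = list(n_chrom = 1L, lengths = 1e7, snp_density = 1e-3,
                  masked_fraction = 0.05, rate_cM_per_Mb = 10),
    ems = list(rate = 1e-5, gc_to_at_bias = 0.85, causal_pos = "random",
               causal_chrom = ""),
    cross = list(n_f2 = 1000L),
    pools = list(pool_size = 200L, missort_rate = 0),
    sequencing = list(light_depth = 10, enriched_depth = 1600,
                      error_rate = 1e-3, read_len = 50L,
                      background_sites = 2000L, survey_sites = 2000L,
                      on_target = 0.87),
    filters = list(min_coverage = 20, min_unique_starts = 4,
                   min_variant_quality = 10, require_both_strands = TRUE),
    mapping = list(bin_size = 25L, dip_threshold = 0.25, wt_threshold = 0.55,
                   min_run = 2L, max_gap = 5L, gap_fraction = 0.35,
                   capture_low = 0.05,
                   capture_pad = 0L),
    candidates = list(freq_threshold = 0.70, wt_exclude_threshold = 0.70,
                      use_known_panel = FALSE),
    probes = list(enabled = TRUE, slide = 2L, window = 10L,
                  reverse_offset = 1L, uniqueness = FALSE, target_tm = 90,
                  w_gc = 20, w_homopolymer = 5),
    inputs = list(genome_fasta = "", mutant_pileup = "", wildtype_pileup = "",
                  enriched_pileup = "", snp_panel = "", gff = "",
                  region = ""),
    output = list(dir = "")
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop_ffg("unknown config section(s): %s", paste(bad, collapse = ", "))
  cfg <- defaults
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(defaults[[nm]]))
      utils::modifyList(defaults[[nm]], over[[nm]]) else over[[nm]]
  }
  structure(cfg, class = "ffg_config")
}

#' Config JSON round trip
#' @param config an `ffg_config`.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  cfg <- do.call(run_config, c(x[setdiff(names(x), c("mode", "seed"))],
                               list(mode = x$mode, seed = x$seed)))
  cfg
}
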