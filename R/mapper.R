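## Binned mapping-allele-frequency analysis.
##
## At a marker with recombination fraction r to the causal locus, the
## mapping-ecotype allele frequency tends to r in the mutant pool and to
## (2 - r) / 3 in the wild-type pool (2/3 at full linkage, 1/2 unlinked);
## binned raw-read ratios over consecutive runs of discovered SNPs trace
## those curves along the genome and the causal locus sits in the dip of the
## mutant-pool track.

#' Bin per-pool SNP calls into mapping-allele-fraction windows
#'
#' Reads are pooled across each bin's SNPs before the ratio is taken
#' (raw-read pooling); `method = "mean"` instead averages per-SNP fractions,
#' for comparison. Bins are consecutive, non-overlapping runs of genotyped
#' sites in position order, per chromosome; a trailing bin with fewer than
#' `bin_size / 2` SNPs is dropped.
#'
#' @param calls per-pool call table (from [discover_and_genotype()]); sites
#'   with status `PASS` or `FULLY_REFERENCE` and not flagged ambiguous enter
#'   bins.
#' @param bin_size SNPs per bin (default 25).
#' @param method `"pooled"` (raw-read pooling, default) or `"mean"`.
#' @return data.table `(chrom, bin_index, start, end, n_snps, ref_reads,
#'   map_reads, map_fraction)`.
#' @export
bin_frequencies <- function(calls, bin_size = 25, method = c("pooled", "mean")) {
  method <- match.arg(method)
  if (bin_size < 1) stop_ffg("bin_size must be >= 1")
  use <- as.data.table(calls)[status %in% c("PASS", "FULLY_REFERENCE") &
                                ambiguous == FALSE]
  if (nrow(use) == 0)
    return(data.table(chrom = character(), bin_index = integer(),
                      start = integer(), end = integer(), n_snps = integer(),
                      ref_reads = integer(), map_reads = integer(),
                      map_fraction = numeric()))
  setorder(use, chrom, pos)
  use[, bin_index := (seq_len(.N) - 1L) %/% as.integer(bin_size), by = chrom]
  bins <- use[, .(
    start = min(pos), end = max(pos), n_snps = .N,
    ref_reads = sum(ref_reads), map_reads = sum(alt_reads),
    map_fraction = if (method == "pooled")
      sum(alt_reads) / (sum(ref_reads) + sum(alt_reads))
    else mean(nonref_fraction[ref_reads + alt_reads > 0])
  ), by = .(chrom, bin_index)]
  bins <- bins[n_snps >= bin_size / 2]
  setorder(bins, chrom, bin_index)
  bins[]
}

#' Restrict two per-pool call tables to their common binnable site set
#'
#' A site enters bins only when both pools could genotype it (status `PASS`
#' or `FULLY_REFERENCE`, not ambiguous); aligning first guarantees the two
#' bin tracks cover the same SNP set, as [detect_linkage()] requires.
#'
#' @param mutant_calls,wildtype_calls per-pool call tables.
#' @return `list(mutant =, wildtype =)` subset to common sites, same order.
#' @export
align_pool_calls <- function(mutant_calls, wildtype_calls) {
  ok <- function(x) as.data.table(x)[status %in% c("PASS", "FULLY_REFERENCE") &
                                       ambiguous == FALSE]
  m <- ok(mutant_calls)
  w <- ok(wildtype_calls)
  common <- merge(m[, .(chrom, pos)], w[, .(chrom, pos)], by = c("chrom", "pos"))
  list(mutant = m[common, on = c("chrom", "pos")],
       wildtype = w[common, on = c("chrom", "pos")])
}

#' Expected mapping-allele frequency at a linked marker
#'
#' For a marker at recombination fraction `r` from the causal locus, the
#' expected mapping-ecotype allele frequency is `r` in the mutant pool (all
#' pooled individuals are homozygous causal) and `(2 - r) / 3` in the
#' wild-type pool (1/3 homozygous wild type, 2/3 heterozygous at `r = 0`).
#' Both equal 1/2 at `r = 0.5` (unlinked).
#'
#' @param pool `"mutant"` or `"wildtype"`.
#' @param r recombination fraction(s) in `[0, 0.5]`.
#' @return expected mapping-allele fraction(s).
#' @export
expected_map_fraction <- function(pool = c("mutant", "wildtype"), r) {
  pool <- match.arg(pool)
  if (any(is.na(r)) || any(r < 0 | r > 0.5))
    stop_ffg("recombination fraction must lie in [0, 0.5]")
  if (pool == "mutant") r else (2 - r) / 3
}

#' Haldane map function
#'
#' Converts genetic distance `d` (Morgans) to recombination fraction under
#' the no-interference crossover model used by the simulator.
#' @param d distance in Morgans.
#' @export
haldane_r <- function(d) (1 - exp(-2 * d)) / 2

#' Detect linked regions from mutant/wild-type bin tracks
#'
#' A region is a maximal run of at least `min_run` consecutive mutant-pool
#' bins with `map_fraction < dip_threshold`; it is "supported" when the
#' wild-type pool's mean `map_fraction` over the same bins exceeds
#' `wt_threshold`. Regions are ranked by their minimum bin fraction.
#'
#' @param mutant_bins,wildtype_bins bin tables from [bin_frequencies()],
#'   computed from the same SNP set (checked).
#' @param dip_threshold mutant-pool dip threshold (default 0.25).
#' @param wt_threshold wild-type support threshold (default 0.55).
#' @param min_run minimum dipping bins per region (default 2).
#' @param max_gap dip runs on the same chromosome separated by at most this
#'   many non-dipping bins are consolidated into one region (default 5).
#'   The allele-frequency gradient crosses `dip_threshold` gradually, so
#'   binomial noise flickers bins around the threshold in the transition
#'   zone.
#' @param gap_fraction a separating gap of any length is also bridged when
#'   every one of its bins stays below this fraction (default 0.35, midway
#'   between the dip threshold and the unlinked expectation). Flicker gaps
#'   in the transition zone run at 0.25-0.35; unlinked bins sit at ~0.5,
#'   many standard deviations above the bound, so genuinely distinct loci
#'   can never be joined.
#' @return data.table `(chrom, start, end, n_bins, min_bin_index,
#'   min_map_fraction, wt_support_fraction, supported)`; `n_bins` counts
#'   dipping bins.
#' @export
detect_linkage <- function(mutant_bins, wildtype_bins, dip_threshold = 0.25,
                           wt_threshold = 0.55, min_run = 2L, max_gap = 5L,
                           gap_fraction = 0.35) {
  mb <- as.data.table(mutant_bins)
  wb <- as.data.table(wildtype_bins)
  if (nrow(mb) != nrow(wb) ||
      !identical(mb[, .(chrom, bin_index, n_snps)], wb[, .(chrom, bin_index, n_snps)]))
    stop_ffg("mutant and wildtype bin lists do not cover the same SNP set")
  mb <- copy(mb)[, wt_fraction := wb$map_fraction]
  mb[, below := map_fraction < dip_threshold]
  mb[, run_id := merge_gap_runs(below, max_gap, map_fraction, gap_fraction),
     by = chrom]
  regions <- mb[run_id > 0L, {
    if (sum(below) >= min_run) .(
      start = min(start), end = max(end), n_bins = sum(below),
      min_bin_index = bin_index[which.min(map_fraction)],
      min_map_fraction = min(map_fraction),
      wt_support_fraction = mean(wt_fraction)
    )
  }, by = .(chrom, run_id)]
  if (nrow(regions) == 0)
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      n_bins = integer(), min_bin_index = integer(),
                      min_map_fraction = numeric(),
                      wt_support_fraction = numeric(), supported = logical()))
  regions[, run_id := NULL]
  regions[, supported := wt_support_fraction > wt_threshold]
  setorder(regions, min_map_fraction)
  regions[]
}

## Label gap-consolidated runs of TRUE: returns an integer id per element,
## 0 for elements outside any consolidated run. A separating FALSE-run is
## bridged (joining its flanking TRUE-runs under one id) when it is short
## (<= max_gap) or, if `frac` is supplied, when all of its values stay
## below `gap_fraction` - i.e. the gap is still clearly linked territory.
merge_gap_runs <- function(below, max_gap, frac = NULL, gap_fraction = Inf) {
  r <- rle(below)
  k <- length(r$lengths)
  keep_gap <- r$values == FALSE & r$lengths <= max_gap
  if (!is.null(frac) && is.finite(gap_fraction)) {
    run_id <- rep.int(seq_len(k), r$lengths)
    run_max <- vapply(split(frac, run_id), max, numeric(1))
    keep_gap <- keep_gap | (r$values == FALSE & run_max < gap_fraction)
  }
  ## a FALSE run bridges only if flanked by TRUE runs on both sides
  bridges <- keep_gap & c(FALSE, r$values[-k]) & c(r$values[-1], FALSE)
  grp <- integer(k)
  cur <- 0L
  for (i in seq_len(k)) {
    if (r$values[i]) {
      if (i >= 3 && bridges[i - 1] && grp[i - 2] > 0L) {
        grp[i] <- grp[i - 2]
        grp[i - 1] <- grp[i - 2]
      } else {
        cur <- cur + 1L
        grp[i] <- cur
      }
    }
  }
  rep.int(grp, r$lengths)
}

#' Select the capture interval from the mutant bin track
#'
#' Takes the contiguous run of bins with `map_fraction < low` containing the
#' minimum bin of the top-ranked supported region - the near-zero dip around
#' full linkage - as the interval to enrich and deep-sequence.
#'
#' @param mutant_bins mutant-pool bin table.
#' @param regions output of [detect_linkage()] (supported regions preferred).
#' @param low near-zero threshold (default 0.05).
#' @param pad bp added on each side (default 0).
#' @param max_gap bins above `low` tolerated inside the dip (default 5).
#' @return `list(chrom, start, end)` or `NULL` when no region exists.
#' @export
select_capture_region <- function(mutant_bins, regions, low = 0.05, pad = 0,
                                  max_gap = 5L) {
  if (nrow(regions) == 0) return(NULL)
  top <- if (any(regions$supported)) regions[supported == TRUE][1] else regions[1]
  mb <- as.data.table(mutant_bins)[chrom == top$chrom]
  setorder(mb, bin_index)
  ids <- merge_gap_runs(mb$map_fraction < low, max_gap)
  k <- which(mb$bin_index == top$min_bin_index)
  if (length(k) != 1 || ids[k] == 0L) {
    ## min bin not inside a near-zero run: fall back to the region span
    return(list(chrom = top$chrom, start = max(1L, as.integer(top$start - pad)),
                end = as.integer(top$end + pad)))
  }
  run <- which(ids == ids[k])
  list(chrom = top$chrom,
       start = max(1L, as.integer(min(mb$start[run]) - pad)),
       end = as.integer(max(mb$end[run]) + pad))
}

#' Minimal recombinant-flanked mapping interval of a mutant pool
#'
#' Across all causal-carrying gametes of a mutant pool, finds the nearest
#' crossover breakpoint on each side of the causal locus (the closest
#' positions where a pooled chromosome switches to mapping-ecotype origin)
#' and returns the genetic width of the interval they delimit. With `n`
#' pooled mutants the two flank distances are each approximately
#' Exp(2n) in Morgans, so the expected width is `1/n` Morgans, e.g. ~1 cM
#' for a pool of 100.
#'
#' @param pool a mutant `ffg_pool`.
#' @return interval width in cM.
#' @export
mapping_resolution <- function(pool) {
  f2 <- pool$f2
  cn <- f2$causal$chrom
  cp <- f2$causal$pos
  L <- chrom_lengths(f2$genome)[[cn]]
  gm <- f2$gametes[[cn]]
  g <- as.vector(rbind(2L * pool$idx - 1L, 2L * pool$idx))
  left <- right <- Inf
  for (gi in g) {
    br <- gm$breaks[[gi]]
    lb <- br[br < cp]
    rb <- br[br > cp]
    left <- min(left, if (length(lb)) cp - max(lb) else cp)
    right <- min(right, if (length(rb)) min(rb) - cp else L - cp)
  }
  (left + right) / 1e6 * f2$genome$rate[[cn]]
}

#' Sequencing-accuracy floor for single-allele detection
#'
#' In a pool of `n` individuals a single chromosome contributes allele
#' frequency `1 / (2n)`; the per-base accuracy at which sequencing error
#' equals that signal is `100 * (1 - 1/(2n))` percent - 99.9% for 500
#' pooled individuals, the point where single cross-over events drown in
#' background error.
#'
#' @param n_individuals pooled individuals.
#' @return accuracy in percent.
#' @export
error_floor_accuracy <- function(n_individuals) {
  stopifnot(n_individuals >= 1)
  100 * (1 - 1 / (2 * n_individuals))
}

#' Plot binned mapping-allele-fraction tracks
#'
#' Draws the mutant (black) and wild-type (blue) binned tracks along each
#' chromosome with the analytic guide lines at 0.5 and 2/3, shading any
#' detected regions - the diagnostic view from which linkage is read.
#'
#' @param mutant_bins,wildtype_bins bin tables from [bin_frequencies()].
#' @param regions optional region table from [detect_linkage()].
#' @param main plot title.
#' @return invisibly, `NULL`; draws on the active graphics device.
#' @export
plot_map_fractions <- function(mutant_bins, wildtype_bins = NULL,
                               regions = NULL, main = "mapping-allele fraction") {
  mb <- as.data.table(mutant_bins)
  chroms <- unique(mb$chrom)
  op <- graphics::par(mfrow = c(length(chroms), 1),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (cn in chroms) {
    m <- mb[chrom == cn]
    mid <- (m$start + m$end) / 2 / 1e6
    plot(mid, m$map_fraction, type = "l", col = "black", ylim = c(0, 1),
         xlab = sprintf("%s position (Mb)", cn), ylab = "map fraction",
         main = if (cn == chroms[1]) main else "")
    if (!is.null(regions)) {
      r <- as.data.table(regions)[chrom == cn]
      if (nrow(r))
        graphics::rect(r$start / 1e6, 0, r$end / 1e6, 1,
                       col = grDevices::adjustcolor("orange", 0.2),
                       border = NA)
    }
    graphics::lines(mid, m$map_fraction, col = "black")
    if (!is.null(wildtype_bins)) {
      w <- as.data.table(wildtype_bins)[chrom == cn]
      graphics::lines((w$start + w$end) / 2 / 1e6, w$map_fraction,
                      col = "blue")
    }
    graphics::abline(h = c(0.5, 2 / 3), lty = 3, col = "grey40")
  }
  invisible(NULL)
}

#' Bin table and region I/O
#' @param bins bin table; `pool` label column added on write.
#' @param path file path.
#' @param pool pool label.
#' @export
write_bins_tsv <- function(bins, path, pool = "pool") {
  out <- bins[, .(chrom, bin_index, start1 = start, end1 = end, n_snps,
                  ref_reads, map_reads, map_fraction, pool = pool)]
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_bins_tsv
#' @param regions region table from [detect_linkage()].
#' @export
write_regions_bed <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(regions))
    writeLines(sprintf("%s\t%d\t%d\tlinkage_region\t%d\t.",
                       regions$chrom, regions$start - 1L, regions$end,
                       as.integer(round(1000 * (1 - regions$min_map_fraction)))),
               con)
  invisible(path)
}
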