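## fabricate a per-pool call table with given per-site read counts
fake_calls <- function(pos, ref_reads, alt_reads, chrom = "chr1",
                       status = NULL) {
  n <- length(pos)
  data.table(chrom = chrom, pos = as.integer(pos), ref = "A", alt = "G",
             ref_reads = as.integer(ref_reads), alt_reads = as.integer(alt_reads),
             nonref_fraction = alt_reads / pmax(ref_reads + alt_reads, 1),
             coverage = as.integer(ref_reads + alt_reads),
             variant_quality = 100,
             status = status %||% ifelse(alt_reads > 0, "PASS", "FULLY_REFERENCE"),
             ambiguous = FALSE, reasons = "")
}

test_that("bin_frequencies pools raw reads over runs of 25 SNPs", {
  calls <- fake_calls(seq(100, by = 100, length.out = 100),
                      ref_reads = rep(6L, 100), alt_reads = rep(6L, 100))
  bins <- bin_frequencies(calls, 25)
  expect_equal(nrow(bins), 4L)
  expect_equal(bins$n_snps, rep(25L, 4))
  expect_equal(bins$map_fraction, rep(0.5, 4))
  expect_equal(bins$ref_reads, rep(150L, 4))
  ## 300/300 read totals give exactly 0.5
  one <- bin_frequencies(fake_calls(1:25, rep(12L, 25), rep(12L, 25)), 25)
  expect_equal(one$map_fraction, 0.5)
  ## raw-read pooling weights deep sites more than the per-SNP mean does
  uneven <- fake_calls(1:25, ref_reads = c(100L, rep(1L, 24)),
                       alt_reads = c(0L, rep(1L, 24)))
  pooled <- bin_frequencies(uneven, 25)$map_fraction
  bymean <- bin_frequencies(uneven, 25, method = "mean")$map_fraction
  expect_lt(pooled, bymean)
  expect_equal(pooled, 24 / 148)
  expect_equal(bymean, mean(c(0, rep(0.5, 24))))
})

test_that("trailing bins are dropped below half size and kept at half", {
  ## 60 SNPs, bin 25: trailing bin of 10 (< 12.5) dropped
  b1 <- bin_frequencies(fake_calls(1:60, rep(5L, 60), rep(5L, 60)), 25)
  expect_equal(nrow(b1), 2L)
  ## 63 SNPs: trailing bin of 13 (>= 12.5) kept
  b2 <- bin_frequencies(fake_calls(1:63, rep(5L, 63), rep(5L, 63)), 25)
  expect_equal(nrow(b2), 3L)
  expect_equal(b2$n_snps[3], 13L)
  ## FAIL and ambiguous sites never enter bins; zero calls -> empty
  mixed <- fake_calls(1:30, rep(5L, 30), rep(5L, 30))
  mixed$status[1:5] <- "FAIL"
  mixed$ambiguous[6] <- TRUE
  expect_equal(sum(bin_frequencies(mixed, 12)$n_snps), 24L)
  expect_equal(nrow(bin_frequencies(mixed[status == "FAIL"], 25)), 0L)
})

test_that("expected_map_fraction endpoints and oracle agreement", {
  expect_equal(expected_map_fraction("mutant", 0), 0)
  expect_equal(expected_map_fraction("wildtype", 0), 2 / 3)
  expect_equal(expected_map_fraction("mutant", 0.5), 0.5)
  expect_equal(expected_map_fraction("wildtype", 0.5), 0.5)
  expect_error(expected_map_fraction("mutant", -0.01))
  expect_error(expected_map_fraction("mutant", 0.51))
  expect_error(expected_map_fraction("mutant", NA))
  for (r in seq(0, 0.5, length.out = 21)) {
    expect_equal(expected_map_fraction("mutant", r),
                 oracle_map_fraction("mutant", r), tolerance = 1e-12)
    expect_equal(expected_map_fraction("wildtype", r),
                 oracle_map_fraction("wildtype", r), tolerance = 1e-12)
  }
})

test_that("detect_linkage finds supported dips and obeys the run rule", {
  mk_bins <- function(frac) {
    n <- length(frac)
    data.table(chrom = "chr1", bin_index = 0:(n - 1),
               start = as.integer(seq(1, by = 1000, length.out = n)),
               end = as.integer(seq(1000, by = 1000, length.out = n)),
               n_snps = 25L, ref_reads = 500L,
               map_reads = as.integer(round(frac * 500)),
               map_fraction = frac)
  }
  flat <- mk_bins(rep(0.5, 20))
  ## all ~0.5: no region
  expect_equal(nrow(detect_linkage(mk_bins(rep(0.5, 20)), flat)), 0L)
  ## single isolated low bin: run length < 2, no region
  one_low <- mk_bins(c(rep(0.5, 9), 0.05, rep(0.5, 10)))
  expect_equal(nrow(detect_linkage(one_low, flat)), 0L)
  ## a 3-bin dip with wild-type support
  dip <- mk_bins(c(rep(0.5, 8), 0.10, 0.02, 0.12, rep(0.5, 9)))
  wt <- mk_bins(c(rep(0.5, 8), 0.62, 0.66, 0.60, rep(0.5, 9)))
  reg <- detect_linkage(dip, wt)
  expect_equal(nrow(reg), 1L)
  expect_true(reg$supported)
  expect_equal(reg$n_bins, 3L)
  expect_equal(reg$min_map_fraction, 0.02)
  ## same dip without wild-type support is reported unsupported
  reg2 <- detect_linkage(dip, flat)
  expect_false(reg2$supported)
  ## dips separated by a small gap consolidate into one region
  gappy <- mk_bins(c(rep(0.5, 4), 0.1, 0.1, 0.4, 0.3, 0.1, 0.1, rep(0.5, 10)))
  reg3 <- detect_linkage(gappy, flat, max_gap = 2)
  expect_equal(nrow(reg3), 1L)
  expect_equal(reg3$n_bins, 4L)
  ## ... but not across a gap wider than max_gap
  reg4 <- detect_linkage(gappy, flat, max_gap = 1)
  expect_equal(nrow(reg4), 2L)
  ## mismatched bin lists are an error
  expect_error(detect_linkage(dip, flat[-1]), "same SNP set")
})

test_that("select_capture_region spans the near-zero dip around the minimum", {
  frac <- c(rep(0.5, 6), 0.2, 0.04, 0.01, 0.07, 0.003, 0.04, 0.2, rep(0.5, 7))
  mb <- data.table(chrom = "chr1", bin_index = 0:19,
                   start = as.integer(seq(1, by = 1000, length.out = 20)),
                   end = as.integer(seq(1000, by = 1000, length.out = 20)),
                   n_snps = 25L, ref_reads = 500L,
                   map_reads = as.integer(round(frac * 500)),
                   map_fraction = frac)
  wb <- copy(mb)[, map_fraction := ifelse(frac < 0.3, 0.63, 0.5)]
  reg <- detect_linkage(mb, wb)
  cap <- select_capture_region(mb, reg, low = 0.05, max_gap = 2)
  ## bins 7..11 are the consolidated < 0.05 run (bin 9 at 0.07 bridged)
  expect_equal(cap$chrom, "chr1")
  expect_equal(cap$start, mb$start[8])
  expect_equal(cap$end, mb$end[12])
})

test_that("bin-size smoothing: unlinked bin variance shrinks with bin size", {
  set.seed(5)
  n <- 2000
  depth <- 12L
  alt <- rbinom(n, depth, 0.5)
  calls <- fake_calls(seq_len(n) * 50, ref_reads = depth - alt, alt_reads = alt)
  v <- vapply(c(5, 10, 25, 50), function(bs)
    var(bin_frequencies(calls, bs)$map_fraction), numeric(1))
  expect_true(all(diff(v) < 0))
})

test_that("the causal bin ranks below every unlinked bin in the mutant pool", {
  gs <- simulate_genome(2, 2e5, 1e-3, rate_cM_per_Mb = 50, seed = 150)
  m <- apply_ems(gs$genome, gs$snp_panel, causal_pos = 1e5,
                 causal_chrom = "chr1", seed = 153)
  f2 <- simulate_f2(gs$genome, gs$snp_panel, m, 500, seed = 154)
  pools <- build_pools(f2, 100, seed = 155)
  vs <- ffg:::variable_sites(f2)
  mp <- sequence_pool(pools$mutant, gs$genome, vs[, .(chrom, pos)], 15,
                      error_rate = 0, seed = 151)
  wp <- sequence_pool(pools$wildtype, gs$genome, vs[, .(chrom, pos)], 15,
                      error_rate = 0, seed = 152)
  dg <- discover_and_genotype(mp, wp, gs$genome,
                              filter_criteria(max_identical_reads = 200))
  al <- align_pool_calls(dg$mutant, dg$wildtype)
  mb <- bin_frequencies(al$mutant, 25)
  causal_bin <- mb[chrom == "chr1" & start <= 1e5 & end >= 1e5]
  expect_equal(nrow(causal_bin), 1L)
  unlinked <- mb[chrom == "chr2"]
  expect_gt(nrow(unlinked), 2L)
  expect_true(all(causal_bin$map_fraction < unlinked$map_fraction))
  ## and the wild-type pool rises over the causal bin
  wbins <- bin_frequencies(al$wildtype, 25)
  wt_at_causal <- wbins[chrom == "chr1" &
                          bin_index == causal_bin$bin_index]$map_fraction
  expect_gt(wt_at_causal, 0.55)
})

test_that("downsampled coverage still ranks the true region first", {
  ## positions discovered at full depth, pools re-typed at ~1x: the binned
  ## track is noisier but the causal bin still carries the signal
  w <- tiny_world(len = 4e5, rate = 50, n_f2 = 500, pool_size = 100,
                  seed = 160)
  vs <- ffg:::variable_sites(w$f2)
  mp10 <- sequence_pool(w$pools$mutant, w$genome, vs[, .(chrom, pos)], 10,
                        seed = 161)
  wp10 <- sequence_pool(w$pools$wildtype, w$genome, vs[, .(chrom, pos)], 10,
                        seed = 162)
  dg <- discover_and_genotype(mp10, wp10, w$genome,
                              filter_criteria(max_identical_reads = 200))
  hits <- 0L
  for (k in 1:3) {
    mp1 <- sequence_pool(w$pools$mutant, w$genome, vs[, .(chrom, pos)], 1,
                         seed = 170 + k)
    wp1 <- sequence_pool(w$pools$wildtype, w$genome, vs[, .(chrom, pos)], 1,
                         seed = 180 + k)
    pc <- pool_typing_criteria(100)
    m1 <- ffg:::genotype_pileup(mp1, w$genome, pc, alleles = dg$variable)
    w1 <- ffg:::genotype_pileup(wp1, w$genome, pc, alleles = dg$variable)
    al <- align_pool_calls(m1, w1)
    mb <- bin_frequencies(al$mutant, 25)
    if (nrow(mb) > 2) {
      best <- mb[which.min(map_fraction)]
      hits <- hits + (abs((best$start + best$end) / 2 - w$f2$causal$pos) < 1e5)
    }
  }
  expect_gte(hits, 2L)
})

test_that("the diagnostic track plot renders", {
  frac <- c(rep(0.5, 8), 0.1, 0.05, 0.1, rep(0.5, 9))
  mb <- data.table(chrom = "chr1", bin_index = 0:19,
                   start = as.integer(seq(1, by = 1000, length.out = 20)),
                   end = as.integer(seq(1000, by = 1000, length.out = 20)),
                   n_snps = 25L, ref_reads = 500L,
                   map_reads = as.integer(round(frac * 500)),
                   map_fraction = frac)
  wb <- copy(mb)[, map_fraction := ifelse(frac < 0.3, 0.64, 0.5)]
  reg <- detect_linkage(mb, wb)
  pdf_file <- withr::local_tempfile(fileext = ".pdf")
  grDevices::pdf(pdf_file, width = 6, height = 3)
  expect_no_error(plot_map_fractions(mb, wb, reg))
  grDevices::dev.off()
  expect_gt(file.info(pdf_file)$size, 0)
})

test_that("mapping resolution scales as ~100/n cM and the error floor is exact", {
  expect_equal(error_floor_accuracy(500), 99.9)
  expect_equal(error_floor_accuracy(100), 99.5)
  ## wider pools give finer intervals (10 replicates each, loose ranking)
  gs <- simulate_genome(1, 4e6, 5e-5, rate_cM_per_Mb = 25, seed = 190)
  m <- apply_ems(gs$genome, gs$snp_panel, causal_pos = 2e6, seed = 191)
  res <- function(pool_size, seed) {
    f2 <- simulate_f2(gs$genome, gs$snp_panel, m, 6 * pool_size, seed = seed)
    pools <- build_pools(f2, pool_size, seed = seed + 1)
    mapping_resolution(pools$mutant)
  }
  r_small <- vapply(1:10, function(k) res(20, 200 + 7 * k), numeric(1))
  r_big <- vapply(1:10, function(k) res(80, 300 + 7 * k), numeric(1))
  expect_gt(mean(r_small), mean(r_big))
  ## mean ~ 100/n cM within broad simulation tolerance
  expect_lt(abs(mean(r_big) - 100 / 80), 0.8)
})
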