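## deep, well-behaved pileup column builder: alt_n variant reads among n
deep_col <- function(pos, n, alt_n, ref = "A", alt = "G", chrom = "chr1") {
  base <- c(rep(alt, alt_n), rep(ref, n - alt_n))
  data.table(chrom = chrom, pos = as.integer(pos), base = base,
             strand = rep(c("+", "-"), length.out = n),
             read_start = as.integer(pos - (seq_len(n) %% 40L)),
             qual = 30L)
}

test_that("the >70% bound is strict: 0.69 excluded, 0.71 included", {
  g <- ffg_genome(c(chr1 = paste(rep("A", 2000), collapse = "")), 5)
  pp <- rbind(deep_col(500, 100, 69), deep_col(1500, 100, 71))
  res <- call_candidates(pp, list(chrom = "chr1", start = 1, end = 2000), g,
                         filter_criteria(max_identical_reads = 400),
                         surveyed_positions = data.table(chrom = "chr1",
                                                         pos = c(500L, 1500L)))
  expect_equal(res$candidates$pos, 1500L)
  expect_equal(res$candidates$nonref_fraction, 0.71)
  expect_equal(res$candidates$effect, "unannotated")
})

test_that("panel SNPs and fixed ecotype variants are filtered, segregating ones kept", {
  g <- ffg_genome(c(chr1 = paste(rep("A", 4000), collapse = "")), 5)
  pp <- rbind(deep_col(500, 100, 95),    # known panel SNP
              deep_col(1500, 100, 95),   # fixed ecotype diff (wt ~ 95%)
              deep_col(2500, 100, 95),   # causal-like (wt ~ 33%)
              deep_col(3500, 100, 95))   # novel, wt fully reference
  panel <- data.table(chrom = "chr1", pos = 500L, ref = "A", map_allele = "G")
  wt_calls <- rbind(
    data.table(chrom = "chr1", pos = 1500L, status = "PASS", nonref_fraction = 0.96),
    data.table(chrom = "chr1", pos = 2500L, status = "PASS", nonref_fraction = 0.33),
    data.table(chrom = "chr1", pos = 3500L, status = "FULLY_REFERENCE",
               nonref_fraction = 0))
  res <- call_candidates(pp, list(chrom = "chr1", start = 1, end = 4000), g,
                         filter_criteria(max_identical_reads = 400),
                         snp_panel = panel, wildtype_calls = wt_calls,
                         surveyed_positions = unique(pp[, .(chrom, pos)]))
  expect_setequal(res$candidates$pos, c(2500L, 3500L))
})

test_that("zero-coverage regions report coverage, not an error", {
  g <- ffg_genome(c(chr1 = paste(rep("A", 1000), collapse = "")), 5)
  empty <- data.table(chrom = character(), pos = integer(), base = character(),
                      strand = character(), read_start = integer(),
                      qual = integer())
  res <- call_candidates(empty, list(chrom = "chr1", start = 1, end = 1000), g,
                         filter_criteria(max_identical_reads = 400))
  expect_equal(nrow(res$candidates), 0L)
  expect_equal(res$coverage$fraction_ge_min, 0)
  expect_equal(res$coverage$uninspected, data.table(start = 1L, end = 1000L))
  expect_error(call_candidates(empty, list(chrom = "chr1", start = 1,
                                           end = 2000), g,
                               filter_criteria(max_identical_reads = 4)),
               "not within")
})

test_that("coverage report counts surveyed bases at or above the bound", {
  g <- ffg_genome(c(chr1 = paste(rep("A", 100), collapse = "")), 5)
  pp <- rbind(deep_col(10, 25, 0), deep_col(20, 19, 0), deep_col(30, 30, 0))
  res <- call_candidates(pp, list(chrom = "chr1", start = 1, end = 100), g,
                         filter_criteria(max_identical_reads = 400))
  ## every region base surveyed; only pos 10 and 30 reach 20x
  expect_equal(res$coverage$n_surveyed, 100L)
  expect_equal(res$coverage$n_ge_min, 2L)
  expect_equal(res$coverage$fraction_ge_min, 0.02)
  expect_true(nrow(res$coverage$uninspected) >= 2)
})

test_that("enriched simulation recovers the causal and linked EMS mutations", {
  w <- tiny_world(len = 3e5, rate = 30, n_f2 = 500, pool_size = 100,
                  snp_density = 5e-4, seed = 301)
  ## force several linked background mutations
  vs <- ffg:::variable_sites(w$f2)
  region <- list(chrom = "chr1", start = 1L, end = 3e5L)
  epos <- vs[, .(chrom, pos)]
  ep <- sequence_pool(w$pools$mutant, w$genome, epos, depth = 400,
                      error_rate = 1e-3, seed = 302)
  wp <- sequence_pool(w$pools$wildtype, w$genome, epos, depth = 15,
                      error_rate = 1e-3, seed = 303)
  dg <- discover_and_genotype(ep, wp, w$genome,
                              filter_criteria(max_identical_reads = 200))
  res <- call_candidates(ep, region, w$genome,
                         filter_criteria(max_identical_reads = 200),
                         snp_panel = w$panel, wildtype_calls = dg$wildtype,
                         surveyed_positions = epos)
  causal <- w$mutations[is_causal == TRUE]
  expect_true(causal$pos %in% res$candidates$pos)
  expect_gt(res$candidates[pos == causal$pos]$nonref_fraction, 0.95)
  ## no panel SNP among candidates (mutant-pool map fraction is ~r << 0.7)
  expect_length(intersect(res$candidates$pos, w$panel$pos), 0)
  ## strongly linked mutations (within ~30 kb = 0.9 cM here) all recovered
  near <- w$mutations[abs(pos - causal$pos) < 3e4]
  expect_true(all(near$pos %in% res$candidates$pos))
})

test_that("missorted pools lower the causal fraction but stay above 70%", {
  w0 <- tiny_world(len = 1e5, n_f2 = 1100, pool_size = 200, seed = 310)
  pools <- build_pools(w0$f2, 200, missort_rate = 0.02, seed = 311)
  causal <- w0$mutations[is_causal == TRUE]
  sites <- data.table(chrom = causal$chrom, pos = causal$pos)
  pp <- sequence_pool(pools$mutant, w0$genome, sites, depth = 1500,
                      error_rate = 0, seed = 312)
  frac <- mean(pp$base == causal$alt)
  ## 4 swapped wild-type plants carry 4-8 non-causal haplotypes of 400:
  ## expectation ~ 1 - 4/200 x ~1.5 (mix of het/hom-wt swaps)
  expect_lt(frac, 1)
  expect_gt(frac, 0.95)
  gam <- as.vector(rbind(2L * pools$mutant$idx - 1L, 2L * pools$mutant$idx))
  truth <- mean(vapply(gam, function(g)
    gamete_origin(w0$f2, g, causal$chrom, causal$pos), logical(1)))
  expect_lt(abs(frac - truth), 3 * sqrt(0.03 / nrow(pp)))
})

toy_gene_world <- function(n_codons = 600, utr = 120, seed = 1) {
  set.seed(seed)
  cds_seq <- random_cds_seq(n_codons)
  left <- random_seq(500)
  right <- random_seq(500)
  seqchar <- paste0(left, random_seq(utr), cds_seq, random_seq(utr), right)
  cds_start <- 500 + utr + 1
  cds_end <- cds_start + 3 * n_codons - 1
  g <- ffg_genome(setNames(seqchar, "chr1"), 5)
  gene <- gene_model("G1", "chr1", "+",
                     exons = data.frame(start = 501, end = cds_end + utr),
                     cds = data.frame(start = cds_start, end = cds_end),
                     utr5 = data.frame(start = 501, end = cds_start - 1),
                     utr3 = data.frame(start = cds_end + 1, end = cds_end + utr))
  list(genome = g, gene = gene, cds_start = cds_start, cds_end = cds_end)
}

test_that("annotate_effect reproduces canonical coding labels", {
  tw <- toy_gene_world(n_codons = 600, seed = 11)
  g <- tw$genome
  gene <- tw$gene
  ## premature stop at codon 467: set codon to CAA (Q), mutate C->T -> TAA
  p467 <- tw$cds_start + 3 * 466
  s <- g$seq[["chr1"]]
  substring(s, p467, p467 + 2) <- "CAA"
  g$seq[["chr1"]] <- s
  eff <- annotate_effect(list(chrom = "chr1", pos = p467, ref = "C", alt = "T"),
                         list(gene), g)
  expect_equal(eff, list(effect = "nonsense", protein_label = "Q467X"))
  ## wobble position of codon 558: TCT -> TCC stays serine
  p558 <- tw$cds_start + 3 * 557
  substring(s, p558, p558 + 2) <- "TCT"
  g$seq[["chr1"]] <- s
  eff2 <- annotate_effect(list(chrom = "chr1", pos = p558 + 2, ref = "T",
                               alt = "C"), list(gene), g)
  expect_equal(eff2, list(effect = "silent", protein_label = "S558S"))
  ## missense A345T: GCT -> ACT
  p345 <- tw$cds_start + 3 * 344
  substring(s, p345, p345 + 2) <- "GCT"
  g$seq[["chr1"]] <- s
  eff3 <- annotate_effect(list(chrom = "chr1", pos = p345, ref = "G",
                               alt = "A"), list(gene), g)
  expect_equal(eff3, list(effect = "missense", protein_label = "A345T"))
  ## 100 bp past the stop, inside the annotated 3'UTR
  eff4 <- annotate_effect(list(chrom = "chr1", pos = tw$cds_end + 100,
                               ref = genome_base(g, "chr1", tw$cds_end + 100),
                               alt = "A"), list(gene), g)
  expect_equal(eff4$effect, "3'UTR")
  ## far outside any gene
  eff5 <- annotate_effect(list(chrom = "chr1", pos = 50,
                               ref = genome_base(g, "chr1", 50), alt = "A"),
                          list(gene), g)
  expect_equal(eff5$effect, "intergenic")
})

test_that("pseudogene flag dominates and intron placement works", {
  g <- ffg_genome(c(chr1 = random_seq(3000)), 5)
  pseudo <- gene_model("P1", "chr1", "+",
                       exons = data.frame(start = 100, end = 800),
                       pseudogene = TRUE)
  eff <- annotate_effect(list(chrom = "chr1", pos = 400,
                              ref = genome_base(g, "chr1", 400), alt = "A"),
                         list(pseudo), g)
  expect_equal(eff$effect, "pseudogene")
  ## two-exon gene: a variant between CDS chunks is intronic
  s <- g$seq[["chr1"]]
  substring(s, 1000, 1002) <- "ATG"
  substring(s, 2000, 2002) <- "TAA"
  g$seq[["chr1"]] <- s
  gene <- gene_model("G2", "chr1", "+",
                     exons = data.frame(start = c(1000, 2000),
                                        end = c(1002, 2002)),
                     cds = data.frame(start = c(1000, 2000),
                                      end = c(1002, 2002)))
  eff2 <- annotate_effect(list(chrom = "chr1", pos = 1500,
                               ref = genome_base(g, "chr1", 1500), alt = "A"),
                          list(gene), g)
  expect_equal(eff2$effect, "intron")
  ## CDS not divisible by 3 errors naming the model
  bad <- gene_model("G3", "chr1", "+", cds = data.frame(start = 100, end = 103))
  expect_error(annotate_effect(list(chrom = "chr1", pos = 101,
                                    ref = genome_base(g, "chr1", 101),
                                    alt = "A"), list(bad), g),
               "G3")
})

test_that("minus-strand annotation equals the reverse-complement construction", {
  set.seed(21)
  n_codons <- 200
  cds_seq <- random_cds_seq(n_codons)
  flank_l <- random_seq(300)
  flank_r <- random_seq(300)
  fwd_seq <- paste0(flank_l, cds_seq, flank_r)
  rev_seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd_seq)))
  g_fwd <- ffg_genome(c(chr1 = fwd_seq), 5)
  g_rev <- ffg_genome(c(chr1 = rev_seq), 5)
  L <- nchar(fwd_seq)
  cds_f <- data.frame(start = 301, end = 300 + 3 * n_codons)
  cds_r <- data.frame(start = L - (300 + 3 * n_codons) + 1, end = L - 301 + 1)
  gene_f <- gene_model("GF", "chr1", "+", cds = cds_f)
  gene_r <- gene_model("GR", "chr1", "-", cds = cds_r)
  for (k in 1:25) {
    off <- sample.int(3 * n_codons, 1)
    pos_f <- 300 + off
    ref_f <- genome_base(g_fwd, "chr1", pos_f)
    alt_f <- sample(setdiff(c("A", "C", "G", "T"), ref_f), 1)
    e_f <- annotate_effect(list(chrom = "chr1", pos = pos_f, ref = ref_f,
                                alt = alt_f), list(gene_f), g_fwd)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    e_r <- annotate_effect(list(chrom = "chr1", pos = L - pos_f + 1,
                                ref = comp[[ref_f]], alt = comp[[alt_f]]),
                           list(gene_r), g_rev)
    expect_identical(e_f, e_r)
    ## and both agree with the full-translation oracle
    want <- oracle_effect(list(chrom = "chr1", pos = pos_f, ref = ref_f,
                               alt = alt_f), gene_f, g_fwd)
    expect_identical(e_f, want)
  }
})

test_that("ems_spectrum classifies the printed candidate set and edge cases", {
  printed <- data.table(ref = c("T", "C", "C", "C", "C", "C"),
                        alt = c("A", "T", "T", "T", "T", "T"))
  expect_equal(ems_spectrum(printed), c(n_gc_to_at = 5L, n_other = 1L))
  expect_equal(ems_spectrum(printed[0]), c(n_gc_to_at = 0L, n_other = 0L))
  ## G->A counts, A->G does not
  expect_equal(ems_spectrum(data.table(ref = c("G", "A"), alt = c("A", "G"))),
               c(n_gc_to_at = 1L, n_other = 1L))
})

test_that("gene models survive a GFF3 round trip", {
  gff <- c("##gff-version 3",
           "chr1\ttoy\tgene\t501\t1400\t.\t+\t.\tID=G1",
           "chr1\ttoy\tmRNA\t501\t1400\t.\t+\t.\tID=G1.1;Parent=G1",
           "chr1\ttoy\texon\t501\t1400\t.\t+\t.\tID=G1.e1;Parent=G1.1",
           "chr1\ttoy\tfive_prime_UTR\t501\t620\t.\t+\t.\tID=G1.u5;Parent=G1.1",
           "chr1\ttoy\tCDS\t621\t1220\t.\t+\t0\tID=G1.c1;Parent=G1.1",
           "chr1\ttoy\tthree_prime_UTR\t1221\t1400\t.\t+\t.\tID=G1.u3;Parent=G1.1",
           "chr1\ttoy\tpseudogene\t2000\t2500\t.\t-\t.\tID=P1")
  tf <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff, tf)
  gm <- read_gene_models(tf)
  expect_length(gm, 2)
  g1 <- gm[[which(vapply(gm, `[[`, character(1), "id") == "G1")]]
  expect_equal(g1$strand, "+")
  expect_equal(g1$cds, data.table(start = 621L, end = 1220L))
  expect_equal(g1$utr3, data.table(start = 1221L, end = 1400L))
  p1 <- gm[[which(vapply(gm, `[[`, character(1), "id") == "P1")]]
  expect_true(p1$pseudogene)
})
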