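## EMS mutagenesis: Poisson-distributed point mutations on the unmasked
## genome with the alkylation-driven G/C -> A/T transition bias, one of which
## is flagged as the causal (phenotype-determining) mutation.

#' Simulate EMS-induced mutations
#'
#' Draws `N ~ Poisson(rate * unmasked length)` substitution positions on
#' unmasked, non-panel bases. EMS alkylates guanine, so a mutation hitting a
#' G becomes A (and C becomes T) with probability `gc_to_at_bias`; all other
#' cases substitute a uniform different base. Exactly one mutation is flagged
#' causal; if `N = 0` the causal mutation is still created, so the expected
#' total count is `rate * L` up to a negligible `P(N = 0)` correction and the
#' `rate -> 0` limit yields exactly the causal mutation.
#'
#' @param genome an `ffg_genome`.
#' @param snp_panel marker panel (`data.table`), used only to avoid placing
#'   mutations on panel positions.
#' @param rate mutations per unmasked bp (default 1/100,000).
#' @param gc_to_at_bias probability that a G/C site mutates to A/T (default 0.85).
#' @param causal_pos `"random"`, or a 1-based position (with `causal_chrom`)
#'   at which the causal mutation must sit.
#' @param causal_chrom chromosome of `causal_pos` (default first chromosome).
#' @param seed RNG seed.
#' @return `data.table(chrom, pos, ref, alt, is_causal)`, sorted by position.
#' @export
apply_ems <- function(genome, snp_panel, rate = 1e-5, gc_to_at_bias = 0.85,
                      causal_pos = "random", causal_chrom = NULL, seed = NULL) {
  if (rate <= 0) stop_ffg("rate must be > 0")
  if (gc_to_at_bias < 0 || gc_to_at_bias > 1)
    stop_ffg("gc_to_at_bias must be in [0, 1]")
  set_seed_if(seed)
  chroms <- names(genome$seq)
  lens <- chrom_lengths(genome)
  panel_key <- if (nrow(snp_panel)) paste(snp_panel$chrom, snp_panel$pos)
    else character(0)
  L <- sum(genome$unmasked) - length(panel_key)
  if (L <= 0) stop_ffg("genome has no eligible (unmasked, non-SNP) bases")

  fixed_causal <- !identical(causal_pos, "random")
  if (fixed_causal) {
    causal_chrom <- causal_chrom %||% chroms[1]
    causal_pos <- as.integer(causal_pos)
    if (is_masked(genome, causal_chrom, causal_pos))
      stop_ffg("causal_pos %d on %s is repeat-masked", causal_pos, causal_chrom)
    if (nrow(snp_panel[chrom == causal_chrom & pos == causal_pos]))
      stop_ffg("causal_pos %d on %s is occupied by a panel SNP", causal_pos, causal_chrom)
  }

  n_bg <- rpois(1L, rate * L)
  n_draw <- if (fixed_causal) max(n_bg - 1L, 0L) else max(n_bg, 1L)
  ## rejection-sample unmasked, non-panel, non-duplicate positions uniformly
  cum <- cumsum(as.numeric(lens))
  sel_chrom <- character(0)
  sel_pos <- integer(0)
  tries <- 0L
  while (length(sel_pos) < n_draw && tries < 50L) {
    tries <- tries + 1L
    need <- n_draw - length(sel_pos)
    g <- floor(runif(2L * need + 5L) * sum(lens)) + 1
    ci <- findInterval(g - 0.5, c(0, cum))
    cn <- chroms[ci]
    p <- as.integer(g - c(0, cum)[ci])
    key <- paste(cn, p)
    ok <- !duplicated(key) &
      !key %in% c(panel_key, paste(sel_chrom, sel_pos))
    cn <- cn[ok]
    p <- p[ok]
    if (length(p)) {
      keep <- logical(length(p))
      for (u in unique(cn)) {
        i <- cn == u
        keep[i] <- !is_masked(genome, u, p[i])
      }
      cn <- cn[keep]
      p <- p[keep]
    }
    take <- seq_len(min(need, length(p)))
    sel_chrom <- c(sel_chrom, cn[take])
    sel_pos <- c(sel_pos, p[take])
  }
  if (length(sel_pos) < n_draw)
    stop_ffg("could not place %d mutations on eligible bases", n_draw)
  mut <- data.table(chrom = sel_chrom, pos = sel_pos)
  if (fixed_causal) {
    mut <- rbind(mut, data.table(chrom = causal_chrom, pos = causal_pos))
    mut <- unique(mut)
    causal_key <- paste(causal_chrom, causal_pos)
  } else {
    causal_key <- paste(mut$chrom[1], mut$pos[1])
  }
  mut[, ref := genome_base(genome, .BY$chrom, pos), by = chrom]
  ## EMS spectrum
  alt <- character(nrow(mut))
  gc <- mut$ref %in% c("G", "C")
  to_at <- gc & (runif(nrow(mut)) < gc_to_at_bias)
  alt[to_at] <- ifelse(mut$ref[to_at] == "G", "A", "T")
  rest <- !to_at
  if (any(gc & rest)) {
    ## G -> C/T or C -> A/G uniformly (the non-transition outcomes)
    g2 <- which(gc & rest)
    alt[g2] <- ifelse(mut$ref[g2] == "G",
                      sample(c("C", "T"), length(g2), replace = TRUE),
                      sample(c("A", "G"), length(g2), replace = TRUE))
  }
  if (any(!gc)) alt[!gc] <- other_base(mut$ref[!gc])
  mut[, alt := alt]
  mut[, is_causal := paste(chrom, pos) == causal_key]
  setorder(mut, chrom, pos)
  stopifnot(sum(mut$is_causal) == 1L)
  mut[]
}

#' Mutation truth-set I/O (TSV)
#' @param mutations `data.table` as returned by [apply_ems()].
#' @param path file path.
#' @export
write_mutations_tsv <- function(mutations, path) {
  out <- copy(mutations)[, .(chrom, pos1 = pos, ref, alt, is_causal)]
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_mutations_tsv
#' @export
read_mutations_tsv <- function(path) {
  x <- fread(path)
  data.table(chrom = x$chrom, pos = as.integer(x$pos1), ref = x$ref,
             alt = x$alt, is_causal = as.logical(x$is_causal))
}
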