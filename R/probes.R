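## Dense 60-mer tiling capture probe design.
##
## A design window is anchored every `slide` bp; within each window the
## best-scoring eligible 60-mer (melting temperature near target, GC inside
## [0.35, 0.65], no long homopolymers, no masked or ambiguous base) is
## selected, with ties broken toward the earliest start. The reverse-strand
## design is run completely independently on the reverse complement with its
## first window offset. A seed-and-extend uniqueness scan discards probes
## with more than `max_hits` genomic loci above the identity bound.

PROBE_LEN <- 60L

## Tm via the GC-fraction formula: 81.5 + 0.41 * GC% - 675 / length.
probe_tm <- function(gc_fraction, len = PROBE_LEN) {
  81.5 + 0.41 * (100 * gc_fraction) - 675 / len
}

#' Score a candidate capture probe
#'
#' `score = -|tm - target_tm| - w_gc * dist(gc, [0.35, 0.65]) -
#' w_homopolymer * max(0, max_homopolymer - 5)`; a masked or non-ACGT base
#' makes the probe ineligible (`score = -Inf`).
#'
#' @param sequence length-60 character sequence (uppercase = unmasked).
#' @param target_tm target melting temperature, degrees C (default 90).
#' @param w_gc penalty weight per unit GC distance outside `[0.35, 0.65]`.
#' @param w_homopolymer penalty per homopolymer base beyond 5.
#' @return `list(score, tm, gc, max_homopolymer)`.
#' @export
probe_score <- function(sequence, target_tm = 90, w_gc = 20, w_homopolymer = 5) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (length(chars) != PROBE_LEN)
    stop_ffg("probe sequences must be %d bp", PROBE_LEN)
  if (!all(chars %in% BASES))
    return(list(score = -Inf, tm = NA_real_, gc = NA_real_,
                max_homopolymer = NA_integer_))
  gc <- mean(chars %in% c("G", "C"))
  tm <- probe_tm(gc)
  hp <- max(rle(chars)$lengths)
  gc_dist <- max(0, 0.35 - gc, gc - 0.65)
  score <- -abs(tm - target_tm) - w_gc * gc_dist * 100 -
    w_homopolymer * max(0, hp - 5)
  list(score = score, tm = tm, gc = gc, max_homopolymer = as.integer(hp))
}

## Vectorised scoring of every probe start in a character sequence.
## Returns a data.table(start, score, tm, gc, max_homopolymer) aligned with
## probe_score() exactly (tested); positions where the 60-mer would leave the
## sequence are absent.
score_all_starts <- function(seqchar, target_tm = 90, w_gc = 20,
                             w_homopolymer = 5) {
  chars <- strsplit(seqchar, "", fixed = TRUE)[[1]]
  n <- length(chars)
  w <- PROBE_LEN
  if (n < w) return(data.table(start = integer(), score = numeric(),
                               tm = numeric(), gc = numeric(),
                               max_homopolymer = integer()))
  n_start <- n - w + 1L
  bad <- cumsum(c(0L, as.integer(!chars %in% BASES)))
  n_bad <- bad[(1:n_start) + w] - bad[1:n_start]
  gcc <- cumsum(c(0L, as.integer(chars %in% c("G", "C", "g", "c"))))
  gc <- (gcc[(1:n_start) + w] - gcc[1:n_start]) / w
  ## run length ending at each position (h), then the exact in-window max
  ## homopolymer per start: max over offsets k of min(h[start + k], k + 1),
  ## which truncates runs crossing the left window boundary.
  rr <- rle(chars)
  h <- sequence(rr$lengths)
  H <- rep(1L, n_start)
  for (k in 0:(w - 1L)) {
    H <- pmax(H, pmin(h[(1:n_start) + k], k + 1L))
  }
  tm <- probe_tm(gc)
  gc_dist <- pmax(0, 0.35 - gc, gc - 0.65)
  score <- -abs(tm - target_tm) - w_gc * gc_dist * 100 -
    w_homopolymer * pmax(0, H - 5L)
  score[n_bad > 0L] <- -Inf
  data.table(start = 1:n_start, score = score, tm = tm, gc = gc,
             max_homopolymer = as.integer(H))
}

#' Design tiling capture probes for a region
#'
#' Windows of `window` candidate starts are anchored every `slide` bp along
#' the region; each emits its best-scoring eligible 60-mer (ties to the
#' earliest start; duplicate selections are collapsed). The reverse-strand
#' design repeats the procedure independently on the reverse complement with
#' the first window offset by `reverse_offset` (default `ceiling(slide / 2)`).
#' Probes containing any masked base are never emitted.
#'
#' @param genome an `ffg_genome`.
#' @param region `list(chrom, start, end)`.
#' @param slide window anchor interval in bp (default 2).
#' @param window candidate starts per window (default 10).
#' @param reverse_offset offset of the first reverse-strand window.
#' @param target_tm,w_gc,w_homopolymer scoring parameters (see
#'   [probe_score()]).
#' @return an `ffg_probe_design`: list with `region`, `params` and `probes`
#'   (data.table `chrom, start, end, strand, sequence, score, tm, gc,
#'   max_homopolymer, n_hits, kept`; `start` is the genomic start of the
#'   probe's footprint, 1-based).
#' @export
design_probes <- function(genome, region, slide = 2L, window = 10L,
                          reverse_offset = NULL, target_tm = 90, w_gc = 20,
                          w_homopolymer = 5) {
  if (slide < 1) stop_ffg("slide must be >= 1")
  reverse_offset <- reverse_offset %||% ceiling(slide / 2)
  lens <- chrom_lengths(genome)
  if (region$end > lens[[region$chrom]] || region$start < 1)
    stop_ffg("region outside genome")
  seqchar <- substring(genome$seq[[region$chrom]], region$start, region$end)
  n <- nchar(seqchar)
  empty <- data.table(chrom = character(), start = integer(), end = integer(),
                      strand = character(), sequence = character(),
                      score = numeric(), tm = numeric(), gc = numeric(),
                      max_homopolymer = integer(), n_hits = NA_integer_,
                      kept = NA)
  params <- list(slide = as.integer(slide), window = as.integer(window),
                 reverse_offset = as.integer(reverse_offset),
                 target_tm = target_tm, w_gc = w_gc,
                 w_homopolymer = w_homopolymer)
  if (n < PROBE_LEN) {
    warning(sprintf("region %s:%d-%d shorter than probe length; empty design",
                    region$chrom, region$start, region$end))
    return(structure(list(region = region, params = params, probes = empty),
                     class = "ffg_probe_design"))
  }
  pick <- function(sc, first_anchor) {
    n_start <- nrow(sc)
    anchors <- seq.int(first_anchor, n_start, by = slide)
    anchors <- anchors[anchors >= 1L]
    if (!length(anchors)) return(integer(0))
    best <- rep(NA_integer_, length(anchors))
    best_s <- rep(-Inf, length(anchors))
    for (j in 0:(window - 1L)) {
      cand <- anchors + j
      ok <- cand <= n_start
      s <- rep(-Inf, length(anchors))
      s[ok] <- sc$score[cand[ok]]
      upd <- s > best_s
      best[upd] <- cand[upd]
      best_s[upd] <- s[upd]
    }
    sel <- best[is.finite(best_s)]
    ## pin the boundary probes: the first and last eligible starts are the
    ## only 60-mers that can cover the region's edge bases, so a dense
    ## tiling must always emit them
    edges <- c(1L, n_start)
    sel <- c(sel, edges[is.finite(sc$score[edges])])
    sort(unique(sel))
  }
  ## reverse complement keeping masking: lowercase complements to lowercase
  rc_chars <- rev(strsplit(seqchar, "", fixed = TRUE)[[1]])
  comp <- c(A = "T", C = "G", G = "C", T = "A", a = "t", c = "g", g = "c",
            t = "a", N = "N", n = "n")
  rc_chars2 <- comp[rc_chars]
  rc_chars2[is.na(rc_chars2)] <- "N"
  rev_seq <- paste(rc_chars2, collapse = "")
  fwd_sc <- score_all_starts(seqchar, target_tm, w_gc, w_homopolymer)
  rev_sc <- score_all_starts(rev_seq, target_tm, w_gc, w_homopolymer)
  fwd_sel <- pick(fwd_sc, 1L)
  rev_sel <- pick(rev_sc, 1L + reverse_offset)

  mk <- function(sel, strand, seqc, sc_all) {
    if (!length(sel)) return(empty)
    sc <- sc_all[sel]
    seqs <- substring(seqc, sel, sel + PROBE_LEN - 1L)
    gstart <- if (strand == "+") region$start + sel - 1L
      else region$start + (n - (sel + PROBE_LEN - 1L))
    data.table(chrom = region$chrom, start = as.integer(gstart),
               end = as.integer(gstart + PROBE_LEN - 1L), strand = strand,
               sequence = toupper(seqs), score = sc$score, tm = sc$tm,
               gc = sc$gc, max_homopolymer = sc$max_homopolymer,
               n_hits = NA_integer_, kept = NA)
  }
  probes <- rbind(mk(fwd_sel, "+", seqchar, fwd_sc),
                  mk(rev_sel, "-", rev_seq, rev_sc))
  structure(list(region = region, params = params, probes = probes),
            class = "ffg_probe_design")
}

#' @export
print.ffg_probe_design <- function(x, ...) {
  p <- x$probes
  cat(sprintf("ffg_probe_design %s:%d-%d  %d forward / %d reverse probes%s\n",
              x$region$chrom, x$region$start, x$region$end,
              sum(p$strand == "+"), sum(p$strand == "-"),
              if (!anyNA(p$kept)) sprintf(" (%d kept)", sum(p$kept)) else ""))
  invisible(x)
}

#' Genome-uniqueness filter for designed probes
#'
#' Counts, for each probe, the genomic loci (both strands) at which an
#' ungapped full-length alignment of the probe exceeds `min_identity`, using
#' exact 12-mer seeding (three seeds per probe) and extension, a light
#' stand-in for a BLAST scan. The probe's own origin locus counts as a hit;
#' probes with more than `max_hits` hits are discarded (`kept = FALSE`).
#'
#' @param design an `ffg_probe_design`.
#' @param genome an `ffg_genome`.
#' @param max_hits maximum allowed hits (default 2).
#' @param min_identity identity bound, exclusive (default 0.60).
#' @param seed_len exact-match seed length (default 12).
#' @return the design with `n_hits` and `kept` filled in.
#' @export
uniqueness_filter <- function(design, genome, max_hits = 2, min_identity = 0.60,
                              seed_len = 12L) {
  probes <- design$probes
  if (nrow(probes) == 0) return(design)
  offs <- unique(c(1L, PROBE_LEN %/% 2L - seed_len %/% 2L + 1L,
                   PROBE_LEN - seed_len + 1L))
  pr_chars <- strsplit(probes$sequence, "", fixed = TRUE)
  hits_per_probe <- integer(nrow(probes))
  targets <- lapply(genome$seq, function(s) toupper(s))
  rc_targets <- lapply(targets, revcomp_chr)
  seeds <- unlist(lapply(offs, function(o)
    substring(probes$sequence, o, o + seed_len - 1L)))
  seed_probe <- rep(seq_len(nrow(probes)), times = length(offs))
  seed_off <- rep(offs, each = nrow(probes))
  valid <- !grepl("[^ACGT]", seeds)
  dict <- Biostrings::PDict(Biostrings::DNAStringSet(seeds[valid]))
  vidx <- which(valid)
  cand <- list()
  for (cn in names(targets)) {
    for (strand in c("+", "-")) {
      subj <- Biostrings::DNAString(if (strand == "+") targets[[cn]]
                                    else rc_targets[[cn]])
      m <- Biostrings::matchPDict(dict, subj)
      st <- Biostrings::startIndex(m)
      hit_rows <- which(lengths(st) > 0)
      if (!length(hit_rows)) next
      cand[[length(cand) + 1L]] <- rbindlist(lapply(hit_rows, function(k) {
        data.table(probe = seed_probe[vidx[k]],
                   chrom = cn, strand = strand,
                   locus = unlist(st[[k]]) - seed_off[vidx[k]] + 1L)
      }))
    }
  }
  if (length(cand)) {
    cand <- unique(rbindlist(cand))
    cand[, chrom_len := nchar(targets[[.BY$chrom]]), by = chrom]
    cand <- cand[locus >= 1L & locus + PROBE_LEN - 1L <= chrom_len]
    if (nrow(cand)) {
      ident <- vapply(seq_len(nrow(cand)), function(i) {
        tgt <- if (cand$strand[i] == "+") targets[[cand$chrom[i]]]
          else rc_targets[[cand$chrom[i]]]
        gseq <- substring(tgt, cand$locus[i], cand$locus[i] + PROBE_LEN - 1L)
        mean(pr_chars[[cand$probe[i]]] == strsplit(gseq, "", fixed = TRUE)[[1]])
      }, numeric(1))
      good <- cand[ident > min_identity]
      if (nrow(good)) {
        cnt <- good[, .N, by = probe]
        hits_per_probe[cnt$probe] <- cnt$N
      }
    }
  }
  probes <- copy(probes)
  probes[, n_hits := hits_per_probe]
  probes[, kept := n_hits <= max_hits]
  design$probes <- probes
  design
}

#' Probe design output writers
#' @param design an `ffg_probe_design`.
#' @param path file path.
#' @param kept_only write only kept probes (default TRUE when filtered).
#' @export
write_probes_fasta <- function(design, path, kept_only = !anyNA(design$probes$kept)) {
  p <- design$probes
  if (kept_only) p <- p[kept == TRUE]
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(p))
    writeLines(paste0(">", p$chrom, ":", p$start, "-", p$end, ":", p$strand,
                      "\n", p$sequence), con)
  invisible(path)
}

#' @rdname write_probes_fasta
#' @export
write_probes_bed <- function(design, path, kept_only = !anyNA(design$probes$kept)) {
  p <- design$probes
  if (kept_only) p <- p[kept == TRUE]
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(p))
    writeLines(sprintf("%s\t%d\t%d\tprobe\t0\t%s", p$chrom, p$start - 1L,
                       p$end, p$strand), con)
  invisible(path)
}

#' @rdname write_probes_fasta
#' @export
write_probes_tsv <- function(design, path) {
  fwrite(design$probes[, .(chrom, start1 = start, end1 = end, strand,
                           tm, gc, max_homopolymer, score, n_hits, kept)],
         path, sep = "\t")
  invisible(path)
}
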