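## F1 selfing -> F2 meiosis simulator.
##
## Each F2 individual is formed from two independent F1 gametes. An F1 is
## heterozygous MUT/MAP genome-wide (mutagenized ecotype x mapping ecotype),
## so a gamete is an alternating mosaic of the two parental origins determined
## by its crossover breakpoints. Crossovers per chromosome are Poisson with
## mean equal to the genetic length in Morgans, placed uniformly on the
## (uniform-rate) genetic map, without interference; the implied two-locus
## recombination fraction is Haldane's r = (1 - exp(-2d)) / 2.
##
## Internal layout ("ffg_f2"): per chromosome a list of 2n breakpoint vectors
## (gametes 2i-1 and 2i belong to individual i) plus a logical vector saying
## whether each gamete starts in MUT origin. This compact form is what the
## pooled-sequencing sampler and the resolution measurements read.

#' Simulate a selfed F2 population
#'
#' @param genome an `ffg_genome`.
#' @param snp_panel ecotype marker panel (carried along for allele queries).
#' @param mutations EMS mutation set from [apply_ems()]; exactly one row has
#'   `is_causal = TRUE`. All induced mutations ride on MUT-origin haplotype
#'   segments. The phenotype is recessive: mutant iff both haplotypes are
#'   MUT-origin at the causal position.
#' @param n_f2 number of F2 individuals (>= 1).
#' @param seed RNG seed.
#' @return an object of class `ffg_f2`.
#' @export
simulate_f2 <- function(genome, snp_panel, mutations, n_f2, seed = NULL) {
  if (n_f2 < 1) stop_ffg("n_f2 must be >= 1")
  if (sum(mutations$is_causal) != 1L)
    stop_ffg("mutation set must contain exactly one causal mutation")
  set_seed_if(seed)
  n_g <- 2L * n_f2
  chroms <- names(genome$seq)
  lens <- chrom_lengths(genome)
  gametes <- vector("list", length(chroms))
  names(gametes) <- chroms
  for (cn in chroms) {
    L_M <- map_length_morgans(genome, cn)
    k <- rpois(n_g, L_M)
    u <- runif(sum(k)) * lens[[cn]]
    breaks <- split(u, rep.int(seq_len(n_g), k))
    all_breaks <- rep(list(numeric(0)), n_g)
    if (length(breaks)) {
      idx <- as.integer(names(breaks))
      all_breaks[idx] <- lapply(breaks, sort)
    }
    gametes[[cn]] <- list(breaks = all_breaks,
                          start_mut = runif(n_g) < 0.5)
  }
  causal <- mutations[is_causal == TRUE]
  f2 <- structure(list(genome = genome, snp_panel = snp_panel,
                       mutations = mutations, n = as.integer(n_f2),
                       causal = list(chrom = causal$chrom, pos = causal$pos),
                       gametes = gametes),
                  class = "ffg_f2")
  co <- gamete_origin(f2, seq_len(n_g), causal$chrom, causal$pos)
  f2$phenotype <- ifelse(co[seq(1, n_g, 2)] & co[seq(2, n_g, 2)],
                         "mutant", "wildtype")
  f2
}

#' @export
print.ffg_f2 <- function(x, ...) {
  cat(sprintf("ffg_f2: %d individuals (%d mutant / %d wildtype), causal %s:%d\n",
              x$n, sum(x$phenotype == "mutant"), sum(x$phenotype == "wildtype"),
              x$causal$chrom, x$causal$pos))
  invisible(x)
}

#' Haplotype origin of gametes at one position
#'
#' @param f2 an `ffg_f2`.
#' @param g gamete indices (individual `i` owns gametes `2i-1`, `2i`).
#' @param chrom chromosome name.
#' @param pos single 1-based position.
#' @return logical vector, `TRUE` = MUT origin.
#' @export
gamete_origin <- function(f2, g, chrom, pos) {
  gm <- f2$gametes[[chrom]]
  vapply(g, function(gi) {
    nx <- sum(gm$breaks[[gi]] < pos) %% 2L
    xor(gm$start_mut[gi], nx == 1L)
  }, logical(1))
}

## origin of one gamete across many positions (vectorised over positions)
gamete_origin_at <- function(f2, gi, chrom, positions) {
  gm <- f2$gametes[[chrom]]
  nx <- findInterval(positions - 0.5, gm$breaks[[gi]]) %% 2L
  xor(gm$start_mut[gi], nx == 1L)
}

#' Materialize one F2 individual as haplotype segment mosaics
#'
#' @param f2 an `ffg_f2`.
#' @param i individual index.
#' @return a list with `haplotype_a`/`haplotype_b` (data.tables of
#'   `chrom, start, end, origin` tiling every chromosome), the induced
#'   `mutations` the individual carries (with dosage), and its `phenotype`.
#' @export
as_individual <- function(f2, i) {
  stopifnot(i >= 1, i <= f2$n)
  haps <- lapply(c(2L * i - 1L, 2L * i), function(gi) {
    rbindlist(lapply(names(f2$gametes), function(cn) {
      gm <- f2$gametes[[cn]]
      br <- floor(gm$breaks[[gi]])
      L <- chrom_lengths(f2$genome)[[cn]]
      bounds <- unique(c(0, br[br > 0 & br < L], L))
      first <- if (gm$start_mut[gi]) c("MUT", "MAP") else c("MAP", "MUT")
      org <- rep(first, length.out = length(bounds) - 1L)
      data.table(chrom = cn, start = as.integer(head(bounds, -1L) + 1L),
                 end = as.integer(tail(bounds, -1L)), origin = org)
    }))
  })
  mut_dose <- integer(nrow(f2$mutations))
  for (k in seq_len(nrow(f2$mutations))) {
    m <- f2$mutations[k]
    mut_dose[k] <- sum(gamete_origin(f2, c(2L * i - 1L, 2L * i), m$chrom, m$pos))
  }
  carried <- copy(f2$mutations)[, dosage := mut_dose][dosage > 0L]
  list(haplotype_a = haps[[1]], haplotype_b = haps[[2]],
       mutations = carried, phenotype = f2$phenotype[i])
}

## Allele matrix for a set of individuals at variable sites.
## Returns a character matrix [2 * length(idx) gametes x nrow(sites)], where
## sites has columns chrom, pos, ref, alt_map (allele carried by MAP origin)
## and alt_mut (allele carried by MUT origin). Panel SNPs: MUT -> ref,
## MAP -> map_allele. Induced mutations: MUT -> alt, MAP -> ref.
pool_allele_matrix <- function(f2, idx, sites) {
  g <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  n_g <- length(g)
  M <- matrix("", nrow = n_g, ncol = nrow(sites))
  for (cn in unique(sites$chrom)) {
    sc <- which(sites$chrom == cn)
    p <- sites$pos[sc]
    for (row in seq_len(n_g)) {
      mut_origin <- gamete_origin_at(f2, g[row], cn, p)
      M[row, sc] <- ifelse(mut_origin, sites$allele_mut[sc], sites$allele_map[sc])
    }
  }
  M
}

## Build the variable-site table (panel SNPs + induced mutations) with the
## allele carried by each parental origin.
variable_sites <- function(f2) {
  a <- data.table(chrom = f2$snp_panel$chrom, pos = f2$snp_panel$pos,
                  ref = f2$snp_panel$ref,
                  allele_mut = f2$snp_panel$ref,
                  allele_map = f2$snp_panel$map_allele)
  b <- data.table(chrom = f2$mutations$chrom, pos = f2$mutations$pos,
                  ref = f2$mutations$ref,
                  allele_mut = f2$mutations$alt,
                  allele_map = f2$mutations$ref)
  out <- rbind(a, b)
  setorder(out, chrom, pos)
  out
}
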