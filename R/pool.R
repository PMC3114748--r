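## Bulk-segregant pools and pooled sequencing at pileup level.

#' Build mutant and wild-type bulk-segregant pools
#'
#' Draws `pool_size` individuals of each phenotype without replacement.
#' `missort_rate` models phenotyping mistakes by swapping
#' `round(missort_rate * pool_size)` individuals between the two pools after
#' drawing, so a missorted mutant pool contains exactly that many wild-type
#' plants (and vice versa).
#'
#' @param f2 an `ffg_f2` population.
#' @param pool_size individuals per pool (default 200).
#' @param missort_rate fraction of each pool swapped across pools (default 0).
#' @param seed RNG seed.
#' @return `list(mutant =, wildtype =)` of `ffg_pool` objects.
#' @export
build_pools <- function(f2, pool_size = 200, missort_rate = 0, seed = NULL) {
  set_seed_if(seed)
  mut_idx <- which(f2$phenotype == "mutant")
  wt_idx <- which(f2$phenotype == "wildtype")
  for (lab in c("mutant", "wildtype")) {
    avail <- if (lab == "mutant") length(mut_idx) else length(wt_idx)
    if (avail < pool_size)
      stop_ffg("pool_size %d exceeds available %s individuals (%d; deficit %d)",
               pool_size, lab, avail, pool_size - avail)
  }
  m <- sample(mut_idx, pool_size)
  w <- sample(wt_idx, pool_size)
  n_swap <- round(missort_rate * pool_size)
  if (n_swap > 0) {
    mi <- sample.int(pool_size, n_swap)
    wi <- sample.int(pool_size, n_swap)
    tmp <- m[mi]
    m[mi] <- w[wi]
    w[wi] <- tmp
  }
  list(mutant = new_pool("mutant", f2, m),
       wildtype = new_pool("wildtype", f2, w))
}

new_pool <- function(label, f2, idx) {
  structure(list(label = label, f2 = f2, idx = as.integer(idx),
                 n = length(idx)),
            class = "ffg_pool")
}

#' @export
print.ffg_pool <- function(x, ...) {
  pure <- sum(x$f2$phenotype[x$idx] == x$label)
  cat(sprintf("ffg_pool '%s': %d individuals (%d with matching phenotype)\n",
              x$label, x$n, pure))
  invisible(x)
}

#' Simulate pooled sequencing as per-position pileup observations
#'
#' Per position, coverage is `Poisson(depth)`; each observation samples one of
#' the `2n` pool haplotypes uniformly with replacement, reads its allele, and
#' substitutes a uniform different base with probability `error_rate`. Strand
#' is Bernoulli(0.5), the read start uniform in `(pos - read_len, pos]`, and
#' the base quality is `round(phred(error_rate))` plus uniform jitter of
#' +-3 (quality only feeds the `> 10` filter downstream).
#'
#' Only sites that are actually polymorphic in the cross (panel SNPs and
#' induced mutations) need haplotype sampling; at every other position all
#' haplotypes read the reference base, so only sequencing errors can produce
#' non-reference observations there.
#'
#' @param pool an `ffg_pool`.
#' @param genome an `ffg_genome` (reference for monomorphic sites).
#' @param positions `"whole-genome"`, or a data.frame/data.table with columns
#'   `chrom, pos` naming the sites to emit.
#' @param depth mean fold coverage (> 0).
#' @param error_rate per-base substitution error in `[0, 0.25)`.
#' @param read_len read length in bp (default 50).
#' @param seed RNG seed.
#' @return an `ffg_pileup`: a data.table `(chrom, pos, base, strand,
#'   read_start, qual)` sorted by `(chrom, pos)`.
#' @export
sequence_pool <- function(pool, genome, positions = "whole-genome", depth,
                          error_rate = 1e-3, read_len = 50L, seed = NULL) {
  if (!inherits(pool, "ffg_pool")) stop_ffg("pool must be an ffg_pool")
  if (pool$n == 0) stop_ffg("cannot sequence an empty pool")
  if (depth <= 0) stop_ffg("depth must be > 0")
  if (error_rate < 0 || error_rate >= 0.25)
    stop_ffg("error_rate must be in [0, 0.25)")
  set_seed_if(seed)
  f2 <- pool$f2
  if (identical(positions, "whole-genome")) {
    lens <- chrom_lengths(genome)
    positions <- rbindlist(lapply(names(lens), function(cn)
      data.table(chrom = cn, pos = seq_len(lens[[cn]]))))
  } else {
    positions <- as.data.table(positions)[, .(chrom, pos = as.integer(pos))]
  }
  setorder(positions, chrom, pos)
  vs <- variable_sites(f2)
  key_var <- paste(vs$chrom, vs$pos)
  key_pos <- paste(positions$chrom, positions$pos)
  var_idx <- match(key_pos, key_var)  # NA -> monomorphic

  cov <- rpois(nrow(positions), depth)
  total <- sum(cov)
  pos_i <- rep.int(seq_len(nrow(positions)), cov)
  ## alleles
  base <- character(total)
  mono <- is.na(var_idx)[pos_i]
  if (any(mono)) {
    ## reference base per emitted observation at monomorphic sites
    mp <- positions[unique(pos_i[mono])]
    refs <- mp[, .(ref = genome_base(genome, .BY$chrom, pos)), by = chrom]$ref
    ref_by_row <- setNames(refs, paste(mp$chrom, mp$pos))
    base[mono] <- ref_by_row[paste(positions$chrom[pos_i[mono]],
                                   positions$pos[pos_i[mono]])]
  }
  if (any(!mono)) {
    vrows <- which(!mono)
    site <- var_idx[pos_i[vrows]]
    hap <- sample.int(2L * pool$n, length(vrows), replace = TRUE)
    ## group by sampled gamete: one findInterval pass per gamete
    allele <- character(length(vrows))
    gam <- as.vector(rbind(2L * pool$idx - 1L, 2L * pool$idx))
    by_h <- split(seq_along(vrows), hap)
    for (h in names(by_h)) {
      rows <- by_h[[h]]
      gi <- gam[as.integer(h)]
      srows <- site[rows]
      for (cn in unique(vs$chrom[srows])) {
        sel <- rows[vs$chrom[srows] == cn]
        p <- vs$pos[site[sel]]
        mut_origin <- gamete_origin_at(f2, gi, cn, p)
        allele[sel] <- ifelse(mut_origin, vs$allele_mut[site[sel]],
                              vs$allele_map[site[sel]])
      }
    }
    base[vrows] <- allele
  }
  ## sequencing errors
  err <- runif(total) < error_rate
  if (any(err)) base[err] <- other_base(base[err])
  q0 <- if (error_rate > 0) round(phred(error_rate)) else 40
  out <- data.table(
    chrom = positions$chrom[pos_i],
    pos = positions$pos[pos_i],
    base = base,
    strand = ifelse(runif(total) < 0.5, "+", "-"),
    read_start = positions$pos[pos_i] - sample.int(read_len, total, replace = TRUE) + 1L,
    qual = pmax(0L, q0 + sample(-3:3, total, replace = TRUE))
  )
  setorder(out, chrom, pos)
  setattr(out, "class", c("ffg_pileup", class(out)))
  out[]
}
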