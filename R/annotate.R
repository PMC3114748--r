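## Gene models and coding-effect prediction for single-base substitutions.

#' Construct a gene model
#'
#' Spans are 1-based closed `data.frame(start, end)` tables on the genome.
#' The CDS is the spliced coding sequence (must be divisible by 3); UTRs and
#' exons are optional. A `pseudogene` model annotates any overlapping variant
#' as `"pseudogene"` regardless of structure.
#'
#' @param id gene identifier.
#' @param chrom chromosome.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds,utr5,utr3 span tables (may be `NULL`).
#' @param pseudogene logical flag.
#' @export
gene_model <- function(id, chrom, strand, exons = NULL, cds = NULL,
                       utr5 = NULL, utr3 = NULL, pseudogene = FALSE) {
  stopifnot(strand %in% c("+", "-"))
  norm <- function(x) {
    if (is.null(x) || nrow(x) == 0) return(NULL)
    x <- as.data.table(x)[, .(start = as.integer(start), end = as.integer(end))]
    setorder(x, start)
    if (any(x$start > x$end)) stop_ffg("gene %s: span with start > end", id)
    if (nrow(x) > 1 && any(x$start[-1] <= x$end[-nrow(x)]))
      stop_ffg("gene %s: overlapping spans within a feature class", id)
    x
  }
  exons <- norm(exons); cds <- norm(cds); utr5 <- norm(utr5); utr3 <- norm(utr3)
  spans <- rbindlist(Filter(Negate(is.null), list(exons, cds, utr5, utr3)))
  if (is.null(spans) || nrow(spans) == 0) stop_ffg("gene %s has no features", id)
  structure(list(id = id, chrom = chrom, strand = strand,
                 start = min(spans$start), end = max(spans$end),
                 exons = exons, cds = cds, utr5 = utr5, utr3 = utr3,
                 pseudogene = isTRUE(pseudogene)),
            class = "ffg_gene")
}

#' Read gene models from GFF3
#'
#' Understands the conventional gene -> mRNA -> exon/CDS/UTR feature chain
#' plus top-level `pseudogene` features; the first transcript of each gene is
#' used.
#'
#' @param path GFF3 file.
#' @return list of `ffg_gene` objects.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  md <- as.data.table(GenomicRanges::as.data.frame(gr))
  md[, type := as.character(type)]
  md[, ID := as.character(ID %||% NA)]
  parent <- vapply(md$Parent %||% vector("list", nrow(md)), function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
  md[, parent := parent]
  genes <- md[type %in% c("gene", "pseudogene")]
  tx2gene <- md[type %in% c("mRNA", "transcript"), setNames(parent, ID)]
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i]
    tx <- md[parent == g$ID & type %in% c("mRNA", "transcript")]$ID
    owner <- c(g$ID, tx[1])
    feats <- md[parent %in% owner]
    spans <- function(ty) {
      f <- feats[type %in% ty, .(start, end)]
      if (nrow(f)) f else NULL
    }
    ## a featureless gene (e.g. a bare pseudogene line) is its own span
    own <- data.frame(start = g$start, end = g$end)
    out[[i]] <- gene_model(
      id = g$ID, chrom = as.character(g$seqnames), strand = as.character(g$strand),
      exons = spans("exon") %||% own,
      cds = spans("CDS"),
      utr5 = spans(c("five_prime_UTR", "5UTR")),
      utr3 = spans(c("three_prime_UTR", "3UTR")),
      pseudogene = g$type == "pseudogene"
    )
  }
  out
}

in_spans <- function(spans, pos) {
  !is.null(spans) && any(pos >= spans$start & pos <= spans$end)
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]

## spliced CDS sequence of a gene on its coding strand
spliced_cds <- function(gene, genome) {
  s <- genome$seq[[gene$chrom]]
  parts <- vapply(seq_len(nrow(gene$cds)), function(k)
    toupper(substring(s, gene$cds$start[k], gene$cds$end[k])), character(1))
  cds <- paste(parts, collapse = "")
  if (gene$strand == "-") cds <- revcomp_chr(cds)
  cds
}

#' Predict the coding effect of a substitution
#'
#' Locates the variant against the gene models (a pseudogene hit dominates;
#' then CDS, UTRs, intron, intergenic). For CDS variants the CDS is spliced,
#' the variant applied on the coding strand (reverse-complemented for `-`
#' strand genes), and the affected codon translated with the standard nuclear
#' code; the protein label is `refAA position altAA`, with `X` for a stop
#' (e.g. `Q467X` for a premature stop).
#'
#' @param variant list or one-row data.frame with `chrom, pos, ref, alt`.
#' @param gene_models list of `ffg_gene` objects.
#' @param genome an `ffg_genome`.
#' @return `list(effect =, protein_label =)` with `effect` one of
#'   `intergenic, intron, 5'UTR, 3'UTR, silent, missense, nonsense,
#'   pseudogene`.
#' @export
annotate_effect <- function(variant, gene_models, genome) {
  v <- as.list(as.data.frame(variant, stringsAsFactors = FALSE)[1, ])
  hits <- Filter(function(g) g$chrom == v$chrom && v$pos >= g$start &&
                   v$pos <= g$end, gene_models)
  if (length(hits) == 0) return(list(effect = "intergenic", protein_label = ""))
  if (any(vapply(hits, `[[`, logical(1), "pseudogene")))
    return(list(effect = "pseudogene", protein_label = ""))
  cds_hit <- Filter(function(g) in_spans(g$cds, v$pos), hits)
  if (length(cds_hit)) {
    g <- cds_hit[[1]]
    cds_len <- sum(g$cds$end - g$cds$start + 1L)
    if (cds_len %% 3L != 0L)
      stop_ffg("gene %s: CDS length %d is not divisible by 3", g$id, cds_len)
    cds <- spliced_cds(g, genome)
    ## offset of the variant within the spliced CDS, coding-strand orientation
    before <- 0L
    for (k in seq_len(nrow(g$cds))) {
      if (v$pos >= g$cds$start[k] && v$pos <= g$cds$end[k]) {
        before <- before + (v$pos - g$cds$start[k])
        break
      }
      before <- before + (g$cds$end[k] - g$cds$start[k] + 1L)
    }
    off <- if (g$strand == "+") before + 1L else cds_len - before
    ref_c <- if (g$strand == "+") toupper(v$ref) else comp_base(toupper(v$ref))
    alt_c <- if (g$strand == "+") toupper(v$alt) else comp_base(toupper(v$alt))
    if (substring(cds, off, off) != ref_c)
      stop_ffg("gene %s: reference allele mismatch at CDS offset %d", g$id, off)
    ci <- (off - 1L) %/% 3L + 1L
    codon <- substring(cds, 3L * (ci - 1L) + 1L, 3L * ci)
    wi <- off - 3L * (ci - 1L)
    alt_codon <- codon
    substring(alt_codon, wi, wi) <- alt_c
    code <- Biostrings::GENETIC_CODE
    aa_ref <- sub("\\*", "X", code[[codon]])
    aa_alt <- sub("\\*", "X", code[[alt_codon]])
    effect <- if (aa_ref == aa_alt) "silent"
      else if (aa_alt == "X") "nonsense" else "missense"
    return(list(effect = effect, protein_label = paste0(aa_ref, ci, aa_alt)))
  }
  for (g in hits) {
    if (in_spans(g$utr5, v$pos)) return(list(effect = "5'UTR", protein_label = ""))
    if (in_spans(g$utr3, v$pos)) return(list(effect = "3'UTR", protein_label = ""))
  }
  list(effect = "intron", protein_label = "")
}

#' EMS mutation spectrum
#'
#' Partitions variants into G/C -> A/T transitions (the canonical EMS
#' signature, i.e. `(G,A)` or `(C,T)` ref/alt pairs) and everything else.
#'
#' @param candidates data.frame with `ref` and `alt` columns.
#' @return named integer vector `c(n_gc_to_at =, n_other =)`.
#' @export
ems_spectrum <- function(candidates) {
  x <- as.data.table(candidates)
  if (nrow(x) == 0) return(c(n_gc_to_at = 0L, n_other = 0L))
  gcat <- (x$ref == "G" & x$alt == "A") | (x$ref == "C" & x$alt == "T")
  c(n_gc_to_at = sum(gcat), n_other = sum(!gcat))
}

is_gc_to_at_pair <- function(ref, alt) {
  (ref == "G" & alt == "A") | (ref == "C" & alt == "T")
}
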