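## ffpileup v1: the TSV dialect that carries per-position pooled sequencing
## observations between pipeline stages. First line is the format marker
## "#ffpileup v1", then a header row and columns
## chrom, pos1, base, strand, read_start1, qual (1-based coordinates).

#' Read/write the ffpileup v1 TSV format
#'
#' @param pileup an `ffg_pileup` data.table.
#' @param path file path.
#' @export
write_pileup <- function(pileup, path) {
  con <- file(path, "w")
  writeLines("#ffpileup v1", con)
  close(con)
  out <- data.table(chrom = pileup$chrom, pos1 = pileup$pos,
                    base = pileup$base, strand = pileup$strand,
                    read_start1 = pileup$read_start, qual = pileup$qual)
  fwrite(out, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_pileup
#' @export
read_pileup <- function(path) {
  marker <- readLines(path, n = 1L)
  if (!identical(marker, "#ffpileup v1"))
    stop_ffg("'%s' is not an ffpileup v1 file (marker line missing)", path)
  x <- fread(path, skip = 1L)
  out <- data.table(chrom = as.character(x$chrom), pos = as.integer(x$pos1),
                    base = as.character(x$base), strand = as.character(x$strand),
                    read_start = as.integer(x$read_start1),
                    qual = as.integer(x$qual))
  setattr(out, "class", c("ffg_pileup", class(out)))
  out[]
}
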