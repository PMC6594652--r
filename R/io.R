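#' Write reads to FASTQ
#'
#' Simulated reads carry no per-base quality model; a constant high quality
#' ("I", Q40) is written.
#'
#' @param reads named character vector of sequences.
#' @param path output FASTQ path.
#' @export
write_fastq <- function(reads, path) {
  if (is.null(names(reads)))
    names(reads) <- sprintf("read%06d", seq_along(reads))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(reads)) {
    lines <- rbind(paste0("@", names(reads)), as.character(reads),
                   "+", strrep("I", nchar(reads)))
    writeLines(as.vector(lines), con)
  }
  invisible(path)
}

#' Write a junction-call or unique-junction table to TSV
#'
#' Fixed, documented column order; header always present (an empty call
#' set yields a header-only file); a `# schema` comment records the
#' version.
#'
#' @param df data.frame of calls or unique junctions.
#' @param path output path.
#' @export
write_junction_table <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# lsrseq junction table, schema ", SCHEMA_VERSION), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a junction table written by [write_junction_table()]
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_junction_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Export motif occurrences or tract intervals as BED
#'
#' Intervals are 0-based half-open with the region id as chromosome; the
#' motif class (or tract sign) becomes the BED name and the strand encodes
#' stored (+) vs opposite (-) strand features.
#'
#' @param x motif data.frame ([scan_motifs()]) or an `lsr_g4track`.
#' @param path output BED path.
#' @export
write_bed <- function(x, path) {
  if (inherits(x, "lsr_g4track")) {
    df <- x$tracts
    if (!nrow(df)) {
      file.create(path); return(invisible(path))
    }
    gr <- GenomicRanges::GRanges(
      seqnames = x$region_id,
      ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
      strand = ifelse(df$sign > 0, "+", "-"))
    gr$name <- sprintf("G4_%s", ifelse(df$sign > 0, "stored", "opposite"))
    gr$score <- abs(df$peak_mean)
  } else {
    if (!nrow(x)) {
      file.create(path); return(invisible(path))
    }
    strand <- ifelse(x$motif_class %in% c("AID_RGYW", "APOBEC3_TC"),
                     "+", "-")
    gr <- GenomicRanges::GRanges(
      seqnames = x$region_id,
      ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
      strand = strand)
    gr$name <- x$motif_class
    gr$score <- 0L
  }
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write a versioned JSON report
#'
#' @param x list to serialise; a `schema_version` field is stamped in.
#' @param path output path.
#' @export
write_json_report <- function(x, path) {
  x$schema_version <- SCHEMA_VERSION
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
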