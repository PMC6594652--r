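JUNCTION_KEY <- c("donor_region", "donor_break", "acceptor_region",
                  "acceptor_break", "insertion_seq", "junction_type",
                  "intermediate_region")

#' Deduplicate junction calls into unique junctions
#'
#' Groups calls by the junction key (breakpoint coordinates, inserted
#' sequence, junction type and intermediate region) so that redundant
#' clonal reads -- including reads carrying sequencing errors away from the
#' junction -- collapse onto one unique junction.  Read counts are
#' conserved and the output order is deterministic (sorted key).
#'
#' @param calls data.frame of junction calls ([call_junctions()]`$calls`)
#'   or an `lsr_callset`.
#' @return data.frame of unique junctions: the key columns, `read_count`,
#'   and `structure`/`mh_len` carried from the calls.
#' @export
dedupe <- function(calls) {
  if (inherits(calls, "lsr_callset")) calls <- calls$calls
  if (!nrow(calls)) {
    out <- calls[, c(JUNCTION_KEY, "structure", "mh_len"), drop = FALSE]
    out$read_count <- integer(0)
    return(out)
  }
  key <- do.call(paste, c(calls[JUNCTION_KEY], sep = "\r"))
  o <- order(key, method = "radix")
  calls <- calls[o, , drop = FALSE]; key <- key[o]
  first <- !duplicated(key)
  out <- calls[first, c(JUNCTION_KEY, "structure", "mh_len"), drop = FALSE]
  out$read_count <- as.integer(table(key)[unique(key)])
  rownames(out) <- NULL
  out
}

#' Unique junctions per million reads
#'
#' @param unique_count number of unique junctions.
#' @param total_reads total reads entering the caller (>= 1).
#' @return `unique_count / total_reads * 1e6`.
#' @examples per_million(50, 2e6)  # 25
#' @export
per_million <- function(unique_count, total_reads) {
  stopifnot(total_reads >= 1)
  unique_count / total_reads * 1e6
}

#' Sample-level quantification
#'
#' @param uniques data.frame from [dedupe()].
#' @param total_reads denominator: all reads entering the caller
#'   (pre-filter), so that the read-out is junctions per million sequenced
#'   reads.
#' @param sample_id label.
#' @return list of class `lsr_sample_quant`: counts, `junctions_per_million`,
#'   per-acceptor breakdown and `complex_fraction`.
#' @export
sample_quant <- function(uniques, total_reads, sample_id = "sample") {
  n <- nrow(uniques)
  per_acc <- if (n) table(uniques$acceptor_region) else table(character(0))
  structure(list(
    sample_id = sample_id, total_reads = as.integer(total_reads),
    unique_junction_count = n,
    junctions_per_million = per_million(n, total_reads),
    per_acceptor = as.list(per_acc),
    complex_fraction = if (n) mean(uniques$junction_type == "complex") else NA_real_,
    supporting_reads = if (n) sum(uniques$read_count) else 0L),
    class = "lsr_sample_quant")
}

#' @export
print.lsr_sample_quant <- function(x, ...) {
  cat(sprintf(
    "<lsr_sample_quant> %s: %d unique junctions / %d reads = %.2f per million\n",
    x$sample_id, x$unique_junction_count, x$total_reads,
    x$junctions_per_million))
  invisible(x)
}

#' Merge unique-junction sets from several primer libraries
#'
#' Amplicons obtained with different reverse primers (hs3, hs1,2, hs4) are
#' pooled into one library: the union of unique junctions is taken, a key
#' present in several amplicons counts once with read counts summed, and
#' per-amplicon provenance is retained.
#'
#' @param unique_list named list of [dedupe()] outputs, one per amplicon.
#' @param total_reads total reads of the merged library.
#' @param sample_id label.
#' @return list with `uniques` (merged data.frame, extra column `amplicons`)
#'   and `quant` (an `lsr_sample_quant`).
#' @export
merge_primer_libraries <- function(unique_list, total_reads,
                                   sample_id = "sample") {
  stopifnot(is.list(unique_list), length(unique_list) >= 1L)
  if (is.null(names(unique_list)))
    names(unique_list) <- sprintf("amplicon%d", seq_along(unique_list))
  tagged <- do.call(rbind, lapply(names(unique_list), function(nm) {
    u <- unique_list[[nm]]
    if (nrow(u)) u$amplicon <- nm else u$amplicon <- character(0)
    u
  }))
  if (!nrow(tagged)) {
    merged <- tagged[, setdiff(names(tagged), "amplicon"), drop = FALSE]
    merged$amplicons <- character(0)
    return(list(uniques = merged,
                quant = sample_quant(merged, total_reads, sample_id)))
  }
  key <- do.call(paste, c(tagged[JUNCTION_KEY], sep = "\r"))
  o <- order(key, method = "radix")
  tagged <- tagged[o, , drop = FALSE]; key <- key[o]
  first <- !duplicated(key)
  merged <- tagged[first, c(JUNCTION_KEY, "structure", "mh_len"), drop = FALSE]
  merged$read_count <- as.integer(tapply(tagged$read_count, key, sum)[unique(key)])
  merged$amplicons <- as.character(tapply(tagged$amplicon, key, function(a)
    paste(sort(unique(a)), collapse = ","))[unique(key)])
  rownames(merged) <- NULL
  list(uniques = merged, quant = sample_quant(merged, total_reads, sample_id))
}

#' Dilution response of the per-million read-out
#'
#' Emulates a dilution series of junction-bearing DNA into junction-free
#' carrier DNA: at each fraction the accepted junction reads are thinned
#' binomially while the total read count (the per-million denominator)
#' stays constant.  Used as a property check that the read-out is
#' semi-quantitative (monotone non-increasing in expectation).
#'
#' @param calls junction calls of the undiluted sample (data.frame or
#'   `lsr_callset`).
#' @param total_reads constant total read count.
#' @param fractions dilution fractions in `[0, 1]`.
#' @param seed RNG seed.
#' @return data.frame with `fraction`, `junction_reads`, `unique_junctions`,
#'   `per_million`.
#' @export
dilution_response <- function(calls, total_reads,
                              fractions = c(1, 0.5, 0.25, 0.1, 0.05, 0),
                              seed = 1L) {
  if (inherits(calls, "lsr_callset")) calls <- calls$calls
  stopifnot(all(fractions >= 0 & fractions <= 1))
  set.seed(seed)
  rows <- lapply(fractions, function(f) {
    keep <- stats::runif(nrow(calls)) < f
    sub <- calls[keep, , drop = FALSE]
    u <- dedupe(sub)
    data.frame(fraction = f, junction_reads = nrow(sub),
               unique_junctions = nrow(u),
               per_million = per_million(nrow(u), total_reads))
  })
  do.call(rbind, rows)
}
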