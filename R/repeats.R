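#' Gapless dot-plot scan for direct and inverted repeats
#'
#' Reports maximal gapless diagonal matches of at least `window` bp at
#' identity `>= min_identity`, in direct orientation (`seq_a` vs `seq_b`)
#' and inverted orientation (`seq_a` vs the reverse complement of `seq_b`).
#' Overlapping qualifying windows on one diagonal are merged into a single
#' hit.  Self-comparison (`seq_b` missing or identical to `seq_a`) excludes
#' the trivial main diagonal and reports each repeat pair once.  Windows
#' containing N never qualify.
#'
#' The defaults (20 bp window, 90 % identity) are the classical dot-plot
#' settings used to delineate repetitive switch-like regions.
#'
#' @param seq_a,seq_b DNA strings; `seq_b` defaults to `seq_a`.
#' @param window minimum hit length in bp (>= 8).
#' @param min_identity minimum identity fraction within a window.
#' @return data.frame with 0-based half-open intervals `a_start`,`a_end`,
#'   `b_start`,`b_end` (on the input `seq_b` strand), `orientation`
#'   ("direct"/"inverted"), `identity`, `length`.
#' @export
scan_repeats <- function(seq_a, seq_b = NULL, window = 20L,
                         min_identity = 0.90) {
  seq_a <- toupper(seq_a); .check_dna(seq_a, "seq_a")
  self <- is.null(seq_b)
  if (!self) {
    seq_b <- toupper(seq_b); .check_dna(seq_b, "seq_b")
    self <- identical(seq_a, seq_b)
  }
  if (self) seq_b <- seq_a
  if (window < 8L) stop("window must be >= 8", call. = FALSE)
  lb <- nchar(seq_b)

  direct <- .diag_repeats(seq_a, seq_b, as.integer(window), min_identity,
                          exclude_main_diagonal = self)
  inv <- .diag_repeats(seq_a, reverse_complement(seq_b), as.integer(window),
                       min_identity, exclude_main_diagonal = FALSE)
  as_df <- function(m, orientation) {
    if (!nrow(m))
      return(data.frame(a_start = integer(0), a_end = integer(0),
                        b_start = integer(0), b_end = integer(0),
                        orientation = character(0), identity = numeric(0),
                        length = integer(0), stringsAsFactors = FALSE))
    b_start <- m[, "b_start"]; b_end <- m[, "b_end"]
    if (orientation == "inverted") {      # map back to input strand of seq_b
      tmp <- lb - b_end; b_end <- lb - b_start; b_start <- tmp
    }
    data.frame(a_start = m[, "a_start"], a_end = m[, "a_end"],
               b_start = b_start, b_end = b_end, orientation = orientation,
               identity = m[, "matches"] / m[, "length"],
               length = m[, "length"], stringsAsFactors = FALSE)
  }
  out <- rbind(as_df(direct, "direct"), as_df(inv, "inverted"))
  if (self && nrow(out)) {
    keep <- (out$orientation == "direct" & out$a_start < out$b_start) |
            (out$orientation == "inverted" & out$a_start <= out$b_start)
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out[order(out$orientation, out$a_start, out$b_start), , drop = FALSE]
}
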