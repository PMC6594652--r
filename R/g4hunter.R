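#' G4Hunter G-quadruplex propensity scores and tracts
#'
#' Run-based scoring: a G inside a maximal run of k consecutive G scores
#' `+min(k, 4)`, a C in a run of k C scores `-min(k, 4)`, A/T/N score 0.
#' The windowed score is the arithmetic mean over each sliding window;
#' tracts are maximal unions of overlapping windows whose `|mean|` reaches
#' the threshold, tagged by sign (+: G4 on the stored strand, -: G4 on the
#' opposite strand).
#'
#' Defaults (window 25, threshold 1.2) follow the published G4Hunter method.
#'
#' @param seq DNA string.
#' @param window sliding window size (>= 1, <= nchar(seq)).
#' @param threshold absolute windowed-mean threshold for calling a tract.
#' @param region_id id recorded in the output.
#' @return an object of class `lsr_g4track`: list with `scores` (per base),
#'   `window_means`, `window`, `threshold` and `tracts` (data.frame with
#'   0-based half-open `start`,`end`, `sign`, `peak_mean`).
#' @export
g4hunter_scores <- function(seq, window = 25L, threshold = 1.2,
                            region_id = "seq") {
  seq <- toupper(seq); .check_dna(seq)
  n <- nchar(seq)
  if (window < 1L || window > n)
    stop("window must be in [1, sequence length]", call. = FALSE)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  r <- rle(ch)
  val <- ifelse(r$values == "G", pmin(r$lengths, 4L),
                ifelse(r$values == "C", -pmin(r$lengths, 4L), 0L))
  scores <- rep.int(val, r$lengths)
  cs <- c(0, cumsum(scores))
  nw <- n - window + 1L
  means <- (cs[(window + 1L):(n + 1L)] - cs[1:nw]) / window
  qual <- which(abs(means) >= threshold)
  tracts <- data.frame(start = integer(0), end = integer(0),
                       sign = integer(0), peak_mean = numeric(0))
  if (length(qual)) {
    sgn <- sign(means[qual])
    cur_s <- qual[1] - 1L; cur_e <- qual[1] - 1L + window
    cur_sign <- sgn[1]; cur_peak <- means[qual[1]]
    flush <- function() {
      tracts <<- rbind(tracts, data.frame(start = cur_s, end = cur_e,
                                          sign = cur_sign,
                                          peak_mean = cur_peak))
    }
    for (i in seq_along(qual)[-1]) {
      s <- qual[i] - 1L
      if (s <= cur_e && sgn[i] == cur_sign) {
        cur_e <- s + window
        if (abs(means[qual[i]]) > abs(cur_peak)) cur_peak <- means[qual[i]]
      } else {
        flush()
        cur_s <- s; cur_e <- s + window
        cur_sign <- sgn[i]; cur_peak <- means[qual[i]]
      }
    }
    flush()
  }
  structure(list(region_id = region_id, scores = scores,
                 window_means = means, window = as.integer(window),
                 threshold = threshold, tracts = tracts),
            class = "lsr_g4track")
}

#' @export
print.lsr_g4track <- function(x, ...) {
  cat(sprintf("<lsr_g4track> %s: %d bases, window %d, threshold %.2f, %d tracts\n",
              x$region_id, length(x$scores), x$window, x$threshold,
              nrow(x$tracts)))
  invisible(x)
}
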