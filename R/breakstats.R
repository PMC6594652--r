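#' Distance from a break to the nearest feature occurrence
#'
#' A break is an inter-base position; the distance is 0 if the break lies
#' within (or on the boundary of) an occurrence interval, otherwise the gap
#' to the nearest interval edge.
#'
#' @param brk inter-base position (scalar or vector).
#' @param occurrences two-column matrix/data.frame of 0-based half-open
#'   intervals (columns start, end), non-empty.
#' @return integer distance(s) >= 0.
#' @export
distance_to_nearest <- function(brk, occurrences) {
  occ <- as.matrix(occurrences)[, 1:2, drop = FALSE]
  if (!nrow(occ))
    stop("occurrence list is empty: distance undefined", call. = FALSE)
  vapply(brk, function(b) {
    d <- pmax(0L, occ[, 1] - b, b - occ[, 2])
    as.integer(min(d))
  }, integer(1))
}

#' Exact expected distance under a uniform random break
#'
#' Enumerates every inter-base position of the interval (PCR-amplifiable
#' window) and averages [distance_to_nearest()] -- an exact null, not a
#' Monte Carlo estimate.
#'
#' @param occurrences feature intervals (see [distance_to_nearest()]).
#' @param interval 0-based half-open interval `[s, e)` of observable base
#'   positions; the enumerated inter-base break positions are `s..e`
#'   inclusive.
#' @return list with `expected_mean` and `profile` (named by position).
#' @export
expected_random_distance <- function(occurrences, interval) {
  stopifnot(length(interval) == 2L, interval[1] <= interval[2])
  pos <- seq.int(interval[1], interval[2])
  prof <- distance_to_nearest(pos, occurrences)
  names(prof) <- pos
  list(expected_mean = mean(prof), profile = prof)
}

#' Compare observed break distances with the random-break null
#'
#' Two-sided Mann-Whitney U test of the observed distances against the
#' exact per-position null profile, plus the difference of means
#' (observed - expected; negative when breaks sit closer to the feature
#' than expected by chance).
#'
#' @param observed integer vector of observed distances.
#' @param profile per-position null distances
#'   ([expected_random_distance()]`$profile`).
#' @return list with `statistic` (U), `p_value`, `mean_difference`,
#'   `observed_mean`, `expected_mean`.
#' @export
compare_observed_vs_null <- function(observed, profile) {
  stopifnot(length(observed) >= 1L, length(profile) >= 1L)
  wt <- suppressWarnings(stats::wilcox.test(observed, profile,
                                            alternative = "two.sided",
                                            exact = FALSE, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       mean_difference = mean(observed) - mean(profile),
       observed_mean = mean(observed), expected_mean = mean(profile))
}

#' Break-to-feature distance report for one region
#'
#' @param breaks observed inter-base break positions in the region.
#' @param occurrences feature intervals of one class (AID/APOBEC3/G4).
#' @param region an `lsr_region`; the null is restricted to its
#'   amplifiable interval (PCR cannot observe breaks beyond the primers).
#' @param feature_class label.
#' @return list of class `lsr_break_report`.
#' @export
break_distance_report <- function(breaks, occurrences, region,
                                  feature_class = "feature") {
  stopifnot(inherits(region, "lsr_region"))
  null <- expected_random_distance(occurrences, region$amplifiable_interval)
  obs <- distance_to_nearest(breaks, occurrences)
  cmp <- compare_observed_vs_null(obs, null$profile)
  structure(list(region_id = region$region_id, feature_class = feature_class,
                 observed_distances = obs, observed_mean = mean(obs),
                 expected_mean = null$expected_mean, profile = null$profile,
                 test_statistic = cmp$statistic, p_value = cmp$p_value,
                 mean_difference = cmp$mean_difference),
            class = "lsr_break_report")
}

#' @export
print.lsr_break_report <- function(x, ...) {
  cat(sprintf(
    "<lsr_break_report> %s / %s: observed mean %.2f vs expected %.2f (p = %.3g)\n",
    x$region_id, x$feature_class, x$observed_mean, x$expected_mean,
    x$p_value))
  invisible(x)
}

#' Summarise junction structures
#'
#' Counts and percentages of blunt / microhomology / insertion junctions,
#' mean microhomology length among microhomologous junctions and mean
#' insertion length among insertion junctions (NA when a subclass is
#' empty).
#'
#' @param uniques data.frame of unique junctions ([dedupe()]) or raw calls;
#'   must have `structure`, `mh_len`, `insertion_seq` columns
#'   (`insertion_seq` optional if no insertions).
#' @return list of class `lsr_structure_summary`.
#' @export
summarize_structures <- function(uniques) {
  if (inherits(uniques, "lsr_callset")) uniques <- uniques$calls
  n <- nrow(uniques)
  lv <- c("blunt", "microhomology", "insertion")
  counts <- table(factor(uniques$structure, levels = lv))
  mh <- uniques$mh_len[uniques$structure == "microhomology"]
  ins <- if ("insertion_seq" %in% names(uniques))
    nchar(uniques$insertion_seq[uniques$structure == "insertion"]) else integer(0)
  structure(list(
    n_junctions = n,
    counts = stats::setNames(as.integer(counts), lv),
    percentages = stats::setNames(
      if (n) 100 * as.numeric(counts) / n else rep(NA_real_, 3L), lv),
    mean_mh_len = if (length(mh)) mean(mh) else NA_real_,
    mean_insertion_len = if (length(ins)) mean(ins) else NA_real_),
    class = "lsr_structure_summary")
}

#' @export
print.lsr_structure_summary <- function(x, ...) {
  cat(sprintf(
    "<lsr_structure_summary> n=%d: blunt %.1f%%, microhomology %.1f%% (mean %.2f bp), insertion %.1f%% (mean %.2f bp)\n",
    x$n_junctions, x$percentages[["blunt"]],
    x$percentages[["microhomology"]], x$mean_mh_len,
    x$percentages[["insertion"]], x$mean_insertion_len))
  invisible(x)
}

#' Chi-square comparison of two structure distributions
#'
#' Pearson chi-square (no continuity correction) on the count table of the
#' two summaries.  Structure classes absent from both summaries are
#' dropped, so a full 3-class comparison has df = 2.  If any expected
#' count is below 1 a Fisher exact test is used instead and flagged.
#'
#' @param a,b `lsr_structure_summary` objects.
#' @return list with `chi2`, `df`, `p_value`, `method`.
#' @export
chi_square_structures <- function(a, b) {
  stopifnot(inherits(a, "lsr_structure_summary"),
            inherits(b, "lsr_structure_summary"))
  tab <- rbind(a$counts, b$counts)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2L)
    stop("need at least two structure classes with counts", call. = FALSE)
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_counts < 1)) {
    ft <- stats::fisher.test(tab)
    return(list(chi2 = NA_real_, df = NA_integer_, p_value = ft$p.value,
                method = "fisher"))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, method = "pearson")
}

#' Binned breakpoint maps
#'
#' Per-region histograms of break positions plus a 2D donor-by-acceptor
#' count matrix per acceptor region.  Counts are plain (log scaling, as
#' used for display, is left to rendering).
#'
#' @param uniques data.frame of unique junctions.
#' @param regions `lsr_region_set`.
#' @param bin_width bin width in bp (default 50).
#' @return list of class `lsr_breakpoint_map`: `donor` (counts data.frame),
#'   `acceptor` (named list of count data.frames), `matrix` (named list of
#'   donor x acceptor count matrices), `bin_width`.
#' @export
breakpoint_map <- function(uniques, regions, bin_width = 50L) {
  stopifnot(inherits(regions, "lsr_region_set"))
  bins_for <- function(len) seq.int(0L, len + bin_width, by = bin_width)
  hist1 <- function(pos, len) {
    br <- bins_for(len)
    cut_idx <- findInterval(pos, br, rightmost.closed = FALSE)
    counts <- tabulate(cut_idx, nbins = length(br) - 1L)
    data.frame(bin_start = br[-length(br)], bin_end = br[-1], count = counts)
  }
  donor_id <- names(regions)[vapply(regions, `[[`, character(1),
                                    "role") == "donor"][1]
  dlen <- nchar(regions[[donor_id]]$sequence)
  donor_hist <- hist1(uniques$donor_break[uniques$donor_region == donor_id],
                      dlen)
  acc_ids <- unique(uniques$acceptor_region)
  acc_hists <- lapply(acc_ids, function(id)
    hist1(uniques$acceptor_break[uniques$acceptor_region == id],
          nchar(regions[[id]]$sequence)))
  names(acc_hists) <- acc_ids
  mats <- lapply(acc_ids, function(id) {
    sub <- uniques[uniques$acceptor_region == id, , drop = FALSE]
    dbr <- bins_for(dlen); abr <- bins_for(nchar(regions[[id]]$sequence))
    di <- findInterval(sub$donor_break, dbr)
    ai <- findInterval(sub$acceptor_break, abr)
    m <- matrix(0L, length(dbr) - 1L, length(abr) - 1L,
                dimnames = list(dbr[-length(dbr)], abr[-length(abr)]))
    for (k in seq_len(nrow(sub))) m[di[k], ai[k]] <- m[di[k], ai[k]] + 1L
    m
  })
  names(mats) <- acc_ids
  structure(list(donor = donor_hist, acceptor = acc_hists, matrix = mats,
                 bin_width = as.integer(bin_width), donor_region = donor_id),
            class = "lsr_breakpoint_map")
}

#' @export
plot.lsr_breakpoint_map <- function(x, ...) {
  n <- 1L + length(x$acceptor)
  op <- graphics::par(mfrow = c(n, 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(x$donor$count, names.arg = x$donor$bin_start,
                    main = paste("donor:", x$donor_region),
                    ylab = "junctions", ...)
  for (id in names(x$acceptor))
    graphics::barplot(x$acceptor[[id]]$count,
                      names.arg = x$acceptor[[id]]$bin_start,
                      main = paste("acceptor:", id), ylab = "junctions", ...)
  invisible(x)
}
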