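test_that("distance_to_nearest follows the edge convention", {
  expect_identical(distance_to_nearest(5, matrix(c(2, 8), 1)), 0L)
  expect_identical(distance_to_nearest(0, matrix(c(10, 14), 1)), 10L)
  # break 9 vs [2,4) and [12,16): min(|9-4|, |12-9|) = 3
  occ <- rbind(c(2, 4), c(12, 16))
  expect_identical(distance_to_nearest(9, occ), 3L)
  # boundary positions count as inside
  expect_identical(distance_to_nearest(4, occ), 0L)
  expect_error(distance_to_nearest(1, occ[0, , drop = FALSE]), "empty")
})

test_that("expected_random_distance is an exact enumeration", {
  # documented example: breaks 0..4, occurrence [2,3) -> 2,1,0,0,1
  e <- expected_random_distance(matrix(c(2, 3), 1), c(0, 4))
  expect_equal(e$expected_mean, 0.8)
  expect_equal(unname(e$profile), c(2, 1, 0, 0, 1))

  # occurrences tiling the interval give 0
  tiles <- cbind(seq(0, 90, 10), seq(10, 100, 10))
  expect_equal(expected_random_distance(tiles, c(0, 100))$expected_mean, 0)

  # random configurations: equality with an independent per-position oracle
  set.seed(61)
  for (i in 1:20) {
    L <- sample(50:400, 1)
    k <- sample(1:8, 1)
    st <- sort(sample(0:(L - 5), k))
    occ <- cbind(st, st + sample(2:4, k, replace = TRUE))
    iv <- c(0, L)
    e <- expected_random_distance(occ, iv)
    oracle <- vapply(0:L, oracle_dist, numeric(1), occ = occ)
    expect_identical(as.numeric(e$profile), oracle)
    expect_identical(e$expected_mean, mean(oracle))
  }
})

test_that("Monte Carlo sampling agrees with the exact null within 3 SE", {
  set.seed(62)
  occ <- rbind(c(30, 34), c(120, 124), c(300, 304))
  e <- expected_random_distance(occ, c(0, 400))
  draws <- sample(0:400, 1e5, replace = TRUE)
  mc <- distance_to_nearest(draws, occ)
  se <- sd(mc) / sqrt(length(mc))
  expect_lt(abs(mean(mc) - e$expected_mean), 3 * se)
})

test_that("observed-vs-null comparison matches direction and the U oracle", {
  prof <- expected_random_distance(rbind(c(40, 44)), c(0, 100))$profile
  res0 <- compare_observed_vs_null(rep(0L, 20), prof)
  expect_lt(res0$mean_difference, 0)
  expect_lt(res0$p_value, 0.01)
  # observed equal to the full null profile: zero mean difference
  res1 <- compare_observed_vs_null(as.integer(prof), prof)
  expect_equal(res1$mean_difference, 0)

  # tiny case: U equals pair counting; p close to exact enumeration
  x <- c(1L, 3L, 9L); y <- c(2L, 5L, 6L, 11L, 14L)
  res <- compare_observed_vs_null(x, y)
  expect_equal(res$statistic, oracle_u_stat(x, y))
  expect_lt(abs(res$p_value - oracle_exact_p(x, y)), 0.15)
})

test_that("structure summaries and their chi-square comparison are exact", {
  mk <- function(st, mh = 0L, ins = "") {
    data.frame(structure = st, mh_len = mh, insertion_seq = ins,
               stringsAsFactors = FALSE)
  }
  all_blunt <- summarize_structures(do.call(rbind, replicate(10, mk("blunt"),
                                                             simplify = FALSE)))
  expect_equal(unname(all_blunt$percentages["blunt"]), 100)
  expect_true(is.na(all_blunt$mean_mh_len))
  expect_true(is.na(all_blunt$mean_insertion_len))

  mix <- rbind(do.call(rbind, replicate(2, mk("blunt"), simplify = FALSE)),
               do.call(rbind, replicate(5, mk("microhomology", mh = 3L),
                                        simplify = FALSE)),
               do.call(rbind, replicate(3, mk("insertion", ins = "ACGT"),
                                        simplify = FALSE)))
  s <- summarize_structures(mix)
  expect_equal(unname(s$percentages), c(20, 50, 30))
  expect_equal(sum(s$percentages), 100)
  expect_equal(s$mean_mh_len, 3)
  expect_equal(s$mean_insertion_len, 4)

  # identical distributions: chi2 exactly 0
  cs <- chi_square_structures(s, s)
  expect_equal(cs$chi2, 0)
  # frozen 2x2 case: [[10,20],[20,10]] -> chi2 = 20/3, df 1
  a <- summarize_structures(rbind(
    do.call(rbind, replicate(10, mk("blunt"), simplify = FALSE)),
    do.call(rbind, replicate(20, mk("microhomology", 2L), simplify = FALSE))))
  b <- summarize_structures(rbind(
    do.call(rbind, replicate(20, mk("blunt"), simplify = FALSE)),
    do.call(rbind, replicate(10, mk("microhomology", 2L), simplify = FALSE))))
  cs2 <- chi_square_structures(a, b)
  expect_equal(cs2$chi2, 20 / 3, tolerance = 1e-12)
  expect_identical(cs2$df, 1L)
})

test_that("breakpoint maps conserve totals", {
  u <- std_calls()
  uniques <- dedupe(u)
  bm <- breakpoint_map(uniques, std_regions(), bin_width = 50L)
  expect_identical(sum(bm$donor$count), nrow(uniques))
  expect_identical(sum(vapply(bm$acceptor, function(h) sum(h$count),
                              integer(1))),
                   nrow(uniques))
  for (id in names(bm$matrix))
    expect_identical(sum(bm$matrix[[id]]),
                     sum(uniques$acceptor_region == id))
  # single junction -> a single non-zero bin
  one <- uniques[1, ]
  bm1 <- breakpoint_map(one, std_regions())
  expect_identical(sum(bm1$donor$count > 0), 1L)
})
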