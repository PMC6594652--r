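mk_call <- function(read_id, db = 100L, ab = 50L, ins = "",
                    acc = "RR1_hs4", type = "direct", mid = NA_character_,
                    structure = "blunt", mh = 0L) {
  data.frame(read_id = read_id, donor_region = "Smu", donor_break = db,
             acceptor_region = acc, acceptor_break = ab,
             structure = structure, mh_len = mh, insertion_seq = ins,
             junction_type = type, intermediate_region = mid,
             stringsAsFactors = FALSE)
}

test_that("dedupe groups by the junction key and conserves counts", {
  calls <- rbind(mk_call("r1"), mk_call("r2"), mk_call("r3"))
  u <- dedupe(calls)
  expect_identical(nrow(u), 1L)
  expect_identical(u$read_count, 3L)

  # a differing insertion sequence is a different junction
  calls2 <- rbind(mk_call("r1", ins = "AA", structure = "insertion"),
                  mk_call("r2", ins = "AT", structure = "insertion"))
  expect_identical(nrow(dedupe(calls2)), 2L)

  # conservation on a full simulated sample
  cs <- std_calls()
  u3 <- dedupe(cs)
  expect_identical(sum(u3$read_count), nrow(cs$calls))
  key <- do.call(paste, u3[, c("donor_region", "donor_break",
                               "acceptor_region", "acceptor_break",
                               "insertion_seq", "junction_type",
                               "intermediate_region")])
  expect_false(anyDuplicated(key) > 0)
})

test_that("dedupe collapses clonal reads onto simulator truth junctions", {
  sim <- std_sim(); cs <- std_calls()
  u <- dedupe(cs)
  truth_keys <- unique(paste(sim$truth$donor_break, sim$truth$acceptor_region,
                             sim$truth$acceptor_break, sim$truth$insertion_seq))
  # essentially one unique junction per simulated truth junction
  expect_lt(abs(nrow(u) - length(truth_keys)), 0.05 * length(truth_keys))
})

test_that("per_million is exact arithmetic", {
  expect_identical(per_million(50, 2e6), 25.0)
  expect_identical(per_million(0, 123), 0.0)
  expect_identical(per_million(7, 350000), 20.0)
  expect_error(per_million(1, 0))
})

test_that("merging primer libraries takes the key union", {
  a <- dedupe(rbind(mk_call("r1", db = 1L), mk_call("r2", db = 2L),
                    mk_call("r3", db = 3L)))
  b <- dedupe(rbind(mk_call("r4", db = 4L), mk_call("r5", db = 5L),
                    mk_call("r6", db = 6L), mk_call("r7", db = 7L)))
  cc <- dedupe(rbind(mk_call("r8", db = 8L), mk_call("r9", db = 9L),
                     mk_call("r10", db = 10L), mk_call("r11", db = 11L),
                     mk_call("r12", db = 12L)))
  m <- merge_primer_libraries(list(hs3 = a, hs12 = b, hs4 = cc),
                              total_reads = 1e6)
  expect_identical(nrow(m$uniques), 12L)
  expect_identical(m$quant$unique_junction_count, 12L)

  # identical key in two amplicons counts once, read counts summed
  shared <- dedupe(rbind(mk_call("r1", db = 1L), mk_call("r2", db = 1L)))
  m2 <- merge_primer_libraries(list(hs3 = a, hs4 = shared), 1e6)
  expect_identical(nrow(m2$uniques), 3L)
  row <- m2$uniques[m2$uniques$donor_break == 1L, ]
  expect_identical(row$read_count, 3L)
  expect_identical(row$amplicons, "hs3,hs4")

  # seeded overlap case equals a brute-force set union
  set.seed(51)
  mk <- function(ids, dbs) dedupe(do.call(rbind, Map(mk_call, ids, dbs)))
  dbs1 <- sample(1:30, 12); dbs2 <- sample(1:30, 12)
  u1 <- mk(paste0("a", 1:12), dbs1); u2 <- mk(paste0("b", 1:12), dbs2)
  mm <- merge_primer_libraries(list(x = u1, y = u2), 1e6)
  expect_identical(nrow(mm$uniques), length(union(dbs1, dbs2)))
})

test_that("sample_quant computes the documented ratios", {
  u <- dedupe(rbind(mk_call("r1"), mk_call("r2", db = 7L),
                    mk_call("r3", db = 8L, type = "complex", mid = "Sg1")))
  q <- sample_quant(u, total_reads = 300000L)
  expect_identical(q$unique_junction_count, 3L)
  expect_equal(q$junctions_per_million, 10.0)
  expect_equal(q$complex_fraction, 1 / 3)
})

test_that("dilution response is exact at the endpoints and monotone in
           expectation", {
  calls <- std_calls()$calls
  d <- dilution_response(calls, total_reads = 1e6,
                         fractions = c(1, 0.5, 0), seed = 4)
  expect_identical(d$junction_reads[1], nrow(calls))
  expect_identical(d$junction_reads[3], 0L)
  expect_identical(d$per_million[3], 0.0)
  # means over seeded replicates are non-increasing across fractions
  fr <- c(1, 0.6, 0.3, 0.1, 0)
  mat <- sapply(1:10, function(s)
    dilution_response(calls, 1e6, fr, seed = s)$per_million)
  means <- rowMeans(mat)
  expect_true(all(diff(means) <= 1e-9))
})
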