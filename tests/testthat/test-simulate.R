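test_that("switch-like regions carry the advertised repeat architecture", {
  r <- make_switch_like_region(500L, "GAGCTGGGGT", seed = 3,
                               divergence = 0, flank = 0L)
  expect_identical(nchar(r$sequence), 500L)
  # one AGCT per 10-bp unit: at least 50 hotspot occurrences
  expect_gte(nrow(scan_aid_hotspots(r$sequence)), 50L)
  # identical seed, identical sequence; different seed differs
  r2 <- make_switch_like_region(500L, "GAGCTGGGGT", seed = 3,
                                divergence = 0, flank = 0L)
  expect_identical(r$sequence, r2$sequence)
  rdiv <- make_switch_like_region(500L, "GAGCTGGGGT", seed = 4,
                                  divergence = 0.1)
  expect_false(identical(r$sequence, rdiv$sequence))
  # the tandem array is seen by the repeat scanner at 20 bp / 90 %
  hits <- scan_repeats(rdiv$sequence)
  expect_gte(nrow(hits[hits$orientation == "direct", ]), 1L)
})

test_that("simulation is byte-identical under the seed contract", {
  regs <- std_regions()
  cfg <- sim_config(seed = 77, n_junctions = 15)
  s1 <- simulate_reads(cfg, regs)
  s2 <- simulate_reads(cfg, regs)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_reads(sim_config(seed = 78, n_junctions = 15), regs)
  expect_false(identical(s1$reads, s3$reads))
})

test_that("a blunt-only mix yields exclusively blunt truth records", {
  regs <- std_regions()
  cfg <- sim_config(seed = 5, n_junctions = 40, complex_fraction = 0,
                    structure_mix = c(blunt = 1, microhomology = 0,
                                      insertion = 0))
  sim <- simulate_reads(cfg, regs)
  expect_true(all(sim$truth$structure == "blunt"))
  expect_true(all(sim$truth$mh_len == 0L))
  expect_true(all(sim$truth$insertion_seq == ""))
})

test_that("error-free truth records are self-consistent with the read", {
  regs <- std_regions()
  sim <- std_sim()
  direct <- sim$truth[sim$truth$junction_type == "direct", ]
  set.seed(12)
  for (i in sample(nrow(direct), 40)) {
    tr <- direct[i, ]
    rd <- sim$reads[[tr$read_id]]
    don <- regs[[tr$donor_region]]$sequence
    acc <- regs[[tr$acceptor_region]]$sequence
    w <- 12L
    expected <- paste0(substr(don, tr$donor_break - w + 1L, tr$donor_break),
                       tr$insertion_seq,
                       substr(acc, tr$acceptor_break + tr$mh_len + 1L,
                              tr$acceptor_break + tr$mh_len + w))
    expect_true(grepl(expected, rd, fixed = TRUE),
                label = paste("truth window of", tr$read_id))
    # mh maximality: the shared flank extends on neither side
    if (tr$mh_len > 0L) {
      expect_identical(substr(don, tr$donor_break - tr$mh_len + 1L,
                              tr$donor_break),
                       substr(acc, tr$acceptor_break + 1L,
                              tr$acceptor_break + tr$mh_len))
      expect_false(substr(don, tr$donor_break + 1L, tr$donor_break + 1L) ==
                     substr(acc, tr$acceptor_break + tr$mh_len + 1L,
                            tr$acceptor_break + tr$mh_len + 1L))
    }
  }
})

test_that("clone sizes in the truth table match the emitted reads", {
  sim <- std_sim()
  expect_identical(nrow(sim$truth), sim$n_junction_reads)
  expect_identical(sort(unique(sim$truth$read_id)),
                   sort(intersect(names(sim$reads), sim$truth$read_id)))
  expect_identical(sim$n_reads, sim$n_junction_reads + sim$n_background)
})

test_that("dilution series thins junction reads at constant depth", {
  regs <- std_regions()
  cfg <- sim_config(seed = 9, n_junctions = 60)
  ser <- simulate_dilution_series(cfg, regs, fractions = c(1, 0.5, 0))
  n_total <- unique(vapply(ser, function(x) x$n_reads, integer(1)))
  expect_identical(length(n_total), 1L)
  expect_identical(nrow(ser[[3]]$truth), 0L)
  n1 <- nrow(ser[[1]]$truth); nh <- nrow(ser[[2]]$truth)
  # binomial CI for the halving
  expect_lt(abs(nh - 0.5 * n1), 4 * sqrt(n1 * 0.25))
})

test_that("primers are attached and trimmed end to end", {
  regs <- std_regions()
  pp <- primer_pair("CAGGGAACTGGGGTATCAAG", "GGACGCGGTTTGCTTTTAT")
  cfg <- sim_config(seed = 10, n_junctions = 20, primers = pp,
                    background_fraction = 0)
  sim <- simulate_reads(cfg, regs)
  expect_true(all(startsWith(unname(sim$reads), pp$forward_seq)))
  cs <- call_junctions(sim$reads, regs, primers = pp)
  expect_gte(recovery_ok(sim$truth, cs$calls), 0.9 * nrow(sim$truth))
})
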