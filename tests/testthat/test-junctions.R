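fixture_regions <- function(fx) {
  region_set(lsr_region("don", fx$donor, "donor"),
             lsr_region("acc", fx$acceptor, "acceptor"))
}

call_fixture <- function(fx) {
  regs <- fixture_regions(fx)
  segs <- align_read(fx$read, regs, read_id = "r")
  assemble_junction(segs, fx$read, regs, read_id = "r")
}

test_that("blunt, microhomology and insertion fixtures classify exactly", {
  fb <- make_junction_fixture("blunt", seed = 101)
  res <- call_fixture(fb)
  expect_null(res$reject)
  expect_identical(res$call$structure, "blunt")
  expect_identical(res$call$donor_break, fb$donor_break)
  expect_identical(res$call$acceptor_break, fb$acceptor_break)
  expect_identical(res$call$mh_len, 0L)

  fm <- make_junction_fixture("microhomology", mh_len = 4L, seed = 102)
  res <- call_fixture(fm)
  expect_identical(res$call$structure, "microhomology")
  expect_identical(res$call$mh_len, 4L)
  # canonical: donor break at the right edge, acceptor break at the left
  expect_identical(res$call$donor_break, fm$donor_break)
  expect_identical(res$call$acceptor_break, fm$acceptor_break)

  fi <- make_junction_fixture("insertion", insertion = "TTAAC", seed = 103)
  res <- call_fixture(fi)
  expect_identical(res$call$structure, "insertion")
  expect_identical(res$call$insertion_seq, "TTAAC")
  expect_identical(res$call$mh_len, 0L)
})

test_that("microhomology equals the brute-force maximal shared flank", {
  # oracle: try every split point of the read; the shared flank is the
  # longest stretch around the junction matching both references
  for (sd in 104:109) {
    m_req <- sample(1:8, 1)
    fx <- make_junction_fixture("microhomology", mh_len = m_req, seed = sd)
    res <- call_fixture(fx)
    d <- strsplit(fx$donor, "")[[1]]; a <- strsplit(fx$acceptor, "")[[1]]
    # brute force: longest m with donor[db-m..db) == acceptor[ab..ab+m)
    # that extends on neither side
    best <- 0L
    for (m in 1:20) {
      if (all(d[(fx$donor_break - m + 1L):fx$donor_break] ==
              a[(fx$acceptor_break + 1L):(fx$acceptor_break + m)])) best <- m
    }
    expect_identical(res$call$mh_len, best)
    expect_identical(res$call$mh_len, m_req)
  }
})

test_that("assembly enforces donor-5' / acceptor-3' deletional layout", {
  fx <- make_junction_fixture("blunt", seed = 110)
  regs <- fixture_regions(fx)

  # acceptor flank reverse-complemented: inversion junction -> rejected
  rd <- paste0(substr(fx$read, 1, 60),
               reverse_complement(substr(fx$read, 61, 120)))
  segs <- align_read(rd, regs, read_id = "r")
  res <- assemble_junction(segs, rd, regs, read_id = "r")
  expect_null(res$call)
  expect_identical(res$reject, "orientation_conflict")

  # donor-only read -> no_acceptor
  rd2 <- substr(fx$donor, 21, 140)
  res2 <- assemble_junction(align_read(rd2, regs, read_id = "r"), rd2, regs,
                            read_id = "r")
  expect_identical(res2$reject, "no_acceptor")

  # acceptor-only read -> no_donor
  rd3 <- substr(fx$acceptor, 121, 240)
  res3 <- assemble_junction(align_read(rd3, regs, read_id = "r"), rd3, regs,
                            read_id = "r")
  expect_identical(res3$reject, "no_donor")

  # whole read reverse-complemented is re-oriented, not rejected
  rd4 <- reverse_complement(fx$read)
  res4 <- assemble_junction(align_read(rd4, regs, read_id = "r"), rd4, regs,
                            read_id = "r")
  expect_null(res4$reject)
  expect_identical(res4$call$donor_break, fx$donor_break)
})

test_that("intermediate segments make junctions complex", {
  set.seed(44)
  don <- rand_dna(400); mid <- rand_dna(400); acc <- rand_dna(400)
  regs <- region_set(lsr_region("don", don, "donor"),
                     lsr_region("mid", mid, "intermediate"),
                     lsr_region("acc", acc, "acceptor"))
  rd <- paste0(substr(don, 101, 160), substr(mid, 151, 200),
               substr(acc, 201, 260))
  res <- assemble_junction(align_read(rd, regs, read_id = "r"), rd, regs,
                           read_id = "r")
  expect_null(res$reject)
  expect_identical(res$call$junction_type, "complex")
  expect_identical(res$call$intermediate_region, "mid")
  expect_identical(res$call$donor_region, "don")
  expect_identical(res$call$acceptor_region, "acc")
})

test_that("structure classes are mutually exclusive on every call", {
  calls <- std_calls()$calls
  expect_gt(nrow(calls), 500L)
  blunt <- calls$structure == "blunt"
  mh <- calls$structure == "microhomology"
  ins <- calls$structure == "insertion"
  expect_true(all(blunt | mh | ins))
  expect_true(all(calls$mh_len[blunt] == 0L & calls$insertion_seq[blunt] == ""))
  expect_true(all(calls$mh_len[mh] >= 1L & calls$insertion_seq[mh] == ""))
  expect_true(all(calls$mh_len[ins] == 0L & nchar(calls$insertion_seq[ins]) >= 1L))
  expect_true(all(calls$junction_type != "complex" |
                    !is.na(calls$intermediate_region)))
})

test_that("accepted calls reconstruct the read across the junction", {
  regs <- std_regions()
  calls <- std_calls()$calls
  calls <- calls[calls$junction_type == "direct", ]
  reads <- std_sim()$reads
  set.seed(8)
  for (i in sample(nrow(calls), 50)) {
    cl <- calls[i, ]
    rd <- reads[[cl$read_id]]
    don <- regs[[cl$donor_region]]$sequence
    acc <- regs[[cl$acceptor_region]]$sequence
    # window: 15 bp of donor flank + junction + 15 bp of acceptor flank
    w <- 15L
    expected <- paste0(substr(don, cl$donor_break - w + 1L, cl$donor_break),
                       cl$insertion_seq,
                       substr(acc, cl$acceptor_break + cl$mh_len + 1L,
                              cl$acceptor_break + cl$mh_len + w))
    expect_true(grepl(expected, rd, fixed = TRUE),
                label = paste("junction window of", cl$read_id))
  }
})

test_that("call_junctions handles empty and junction-free input", {
  regs <- std_regions()
  empty <- call_junctions(character(0), regs)
  expect_identical(empty$n_reads, 0L)
  expect_identical(nrow(empty$calls), 0L)
  set.seed(9)
  noise <- vapply(1:20, function(i) rand_dna(200), "")
  names(noise) <- paste0("n", 1:20)
  cs <- call_junctions(noise, regs)
  expect_identical(nrow(cs$calls), 0L)
  expect_identical(sum(cs$rejects$count), 20L)
})
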