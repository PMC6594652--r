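make_one_region_set <- function(seq, id = "R1") {
  region_set(lsr_region(id, seq, "donor"))
}

test_that("exact substrings map to their true placement", {
  set.seed(31)
  ref <- rand_dna(600)
  regs <- make_one_region_set(ref)
  read <- substr(ref, 101, 180)            # 0-based [100, 180)
  segs <- align_read(read, regs)
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$ref_start, 100L)
  expect_identical(segs$ref_end, 180L)
  expect_identical(segs$read_start, 0L)
  expect_identical(segs$read_end, 80L)
  expect_equal(segs$identity, 1.0)
  expect_identical(segs$orientation, "forward")
  # oracle: brute-force substring search finds the same unique placement
  expect_identical(as.integer(regexpr(read, ref, fixed = TRUE)) - 1L, 100L)
})

test_that("reverse-complement reads map with orientation reverse", {
  set.seed(32)
  ref <- rand_dna(600)
  regs <- make_one_region_set(ref)
  read <- reverse_complement(substr(ref, 101, 180))
  segs <- align_read(read, regs)
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$orientation, "reverse")
  expect_identical(segs$ref_start, 100L)
  expect_identical(segs$ref_end, 180L)
})

test_that("chimeric reads yield segments tiling the read", {
  set.seed(33)
  r1 <- rand_dna(500); r2 <- rand_dna(500)
  regs <- region_set(lsr_region("R1", r1, "donor"),
                     lsr_region("R2", r2, "acceptor"))
  read <- paste0(substr(r1, 1, 60), substr(r2, 41, 100))
  segs <- align_read(read, regs)
  expect_identical(nrow(segs), 2L)
  expect_identical(segs$region_id, c("R1", "R2"))
  # the two segments tile the read; chance matches may extend either one a
  # few bases across the junction
  expect_identical(segs$read_start[1], 0L)
  expect_identical(segs$read_end[2], 120L)
  expect_gte(segs$read_end[1], 60L); expect_lte(segs$read_end[1], 68L)
  expect_lte(segs$read_start[2], 60L); expect_gte(segs$read_start[2], 52L)
  # placements stay on the true diagonals
  expect_identical(segs$ref_end[1] - segs$read_end[1], 0L)
  expect_identical(segs$ref_start[2] - segs$read_start[2], -20L)
})

test_that("segment scores equal the Smith-Waterman oracle", {
  set.seed(34)
  for (i in 1:30) {
    n <- sample(40:300, 1); m <- sample(60:300, 1)
    a <- rand_dna(n); b <- rand_dna(m)
    if (i %% 2 == 0) {     # plant noisy homology in half the cases
      core <- substr(b, 11, 10 + min(50, m - 10))
      ch <- strsplit(core, "")[[1]]
      flip <- which(runif(length(ch)) < 0.05)
      for (k in flip) ch[k] <- sample(setdiff(c("A","C","G","T"), ch[k]), 1)
      a <- paste0(substr(a, 1, 20), paste(ch, collapse = ""))
    }
    got <- .sw_local(a, b, 2L, -3L, -5L, -2L)$score
    expect_identical(got, oracle_sw_score(a, b))
  }
})

test_that("short reads return an empty segment table", {
  regs <- make_one_region_set(rand_dna(100))
  expect_identical(nrow(align_read("ACGTACGT", regs)), 0L)
})

test_that("placement ties in perfect tandem repeats are flagged", {
  unit <- "GATCCGTAACGGTTACAGCTAATCG"     # 25 bp, no internal repetition
  ref <- strrep(unit, 12)
  regs <- make_one_region_set(ref)
  read <- strrep(unit, 2)
  segs <- align_read(read, regs)
  top <- segs[which.max(segs$score), ]
  expect_true(top$multi_mapped)
  expect_identical(top$ref_start %% 25L, 0L)  # smallest-offset convention
})

test_that("trim_primers removes terminal primer matches up to 2 mismatches", {
  pp <- primer_pair("CAGGGAACTGGGGTATCAAG", "GGACGCGGTTTGCTTTTAT")
  set.seed(36)
  core <- rand_dna(80)
  read <- paste0(pp$forward_seq, core, reverse_complement(pp$reverse_seq))
  tr <- trim_primers(read, pp)
  expect_identical(tr$seq, core)
  expect_true(tr$forward_found); expect_true(tr$reverse_found)

  # one mismatch in the forward primer is still trimmed (Hamming oracle)
  fwd_mm <- pp$forward_seq
  substr(fwd_mm, 5, 5) <- if (substr(fwd_mm, 5, 5) == "A") "C" else "A"
  expect_identical(sum(strsplit(fwd_mm, "")[[1]] !=
                         strsplit(pp$forward_seq, "")[[1]]), 1L)
  tr2 <- trim_primers(paste0(fwd_mm, core), pp)
  expect_identical(tr2$seq, core)
  expect_true(tr2$forward_found)

  # three mismatches are not trimmed
  fwd3 <- pp$forward_seq
  substr(fwd3, 1, 3) <- "TTT"
  tr3 <- trim_primers(paste0(fwd3, core), pp)
  expect_false(tr3$forward_found)

  # no primer: unchanged, flags FALSE
  tr4 <- trim_primers(core, pp)
  expect_identical(tr4$seq, core)
  expect_false(tr4$forward_found || tr4$reverse_found)
  # NULL primers are a no-op
  expect_identical(trim_primers(core, NULL)$seq, core)
})
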