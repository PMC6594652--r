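# Independent oracles and fixture builders.  Every oracle here is written
# against the definitions, not against the package implementation.

rand_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# -- motif oracle: explicit IUPAC set membership, position by position -----
oracle_aid_scan <- function(seq) {
  W <- c("A", "T"); R <- c("A", "G"); Y <- c("C", "T")
  ch <- strsplit(seq, "")[[1]]
  out <- NULL
  for (i in seq_len(max(0, length(ch) - 3L))) {
    q <- ch[i:(i + 3L)]
    if (q[1] %in% W && q[2] %in% R && q[3] == "C" && q[4] %in% Y)
      out <- rbind(out, data.frame(start = i - 1L, motif_class = "AID_WRCY"))
    if (q[1] %in% R && q[2] == "G" && q[3] %in% Y && q[4] %in% W)
      out <- rbind(out, data.frame(start = i - 1L, motif_class = "AID_RGYW"))
  }
  out
}

oracle_apobec_scan <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  out <- NULL
  for (i in seq_len(max(0, length(ch) - 1L))) {
    if (ch[i] == "T" && ch[i + 1] == "C")
      out <- rbind(out, data.frame(start = i - 1L, motif_class = "APOBEC3_TC"))
    if (ch[i] == "G" && ch[i + 1] == "A")
      out <- rbind(out, data.frame(start = i - 1L, motif_class = "APOBEC3_GA"))
  }
  out
}

# -- distance oracle -------------------------------------------------------
oracle_dist <- function(b, occ) {
  min(apply(occ, 1L, function(iv) max(0, iv[1] - b, b - iv[2])))
}

# -- Smith-Waterman oracle: Biostrings pairwiseAlignment with the same
#    scoring scheme (gap of length L costs 5 + 2L, matching the package's
#    gap_open = -5, gap_extend = -2) ---------------------------------------
oracle_sw_score <- function(a, b, match = 2, mismatch = -3,
                            gap_open = 5, gap_ext = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  as.integer(Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_ext, scoreOnly = TRUE))
}

# -- Mann-Whitney oracle: U statistic by pair counting, exact p by full
#    enumeration of group assignments (tiny n only) ------------------------
oracle_u_stat <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

oracle_exact_p <- function(x, y) {
  nx <- length(x); pooled <- c(x, y)
  u_obs <- oracle_u_stat(x, y)
  idx <- utils::combn(length(pooled), nx)
  mu <- nx * length(y) / 2
  us <- apply(idx, 2L, function(ii)
    oracle_u_stat(pooled[ii], pooled[-ii]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# -- junction fixture: donor/acceptor pair with a fully controlled join ----
# donor break fixed at 150, acceptor break at 100; flanks of 60 bp each.
make_junction_fixture <- function(structure = c("blunt", "microhomology",
                                                "insertion"),
                                  mh_len = 0L, insertion = "", seed = 1L) {
  structure <- match.arg(structure)
  set.seed(seed)
  d <- strsplit(rand_dna(300), "")[[1]]
  a <- strsplit(rand_dna(300), "")[[1]]
  db <- 150L; ab <- 100L
  pick_not <- function(...) sample(setdiff(c("A", "C", "G", "T"),
                                           c(...)), 1L)
  if (structure == "microhomology") {
    stopifnot(mh_len >= 1L)
    a[(ab + 1L):(ab + mh_len)] <- d[(db - mh_len + 1L):db]
    a[ab + mh_len + 1L] <- pick_not(d[db + 1L])      # no forward extension
    a[ab] <- pick_not(d[db - mh_len])                # no backward extension
    read <- paste(c(d[(db - 59L):db], a[(ab + mh_len + 1L):(ab + mh_len + 60L)]),
                  collapse = "")
  } else if (structure == "insertion") {
    stopifnot(nzchar(insertion))
    ins <- strsplit(insertion, "")[[1]]
    stopifnot(ins[1] != d[db + 1L] || length(unique(ins)) > 1L)
    a[ab + 1L] <- pick_not(d[db], ins[length(ins)])  # keep join unambiguous
    a[ab] <- pick_not(ins[length(ins)], d[db])
    d[db + 1L] <- pick_not(ins[1], a[ab + 1L])
    read <- paste(c(d[(db - 59L):db], ins, a[(ab + 1L):(ab + 60L)]),
                  collapse = "")
  } else {
    a[ab + 1L] <- pick_not(d[db + 1L])               # no shared flank
    a[ab] <- pick_not(d[db])
    read <- paste(c(d[(db - 59L):db], a[(ab + 1L):(ab + 60L)]), collapse = "")
  }
  list(read = read, donor = paste(d, collapse = ""),
       acceptor = paste(a, collapse = ""), donor_break = db,
       acceptor_break = ab)
}

# exact recovery of truth records by calls (all canonical fields)
recovery_ok <- function(truth, calls) {
  m <- merge(truth, calls, by = "read_id", suffixes = c(".t", ".c"))
  ok <- m$donor_break.t == m$donor_break.c &
    m$acceptor_region.t == m$acceptor_region.c &
    m$acceptor_break.t == m$acceptor_break.c &
    m$structure.t == m$structure.c & m$mh_len.t == m$mh_len.c &
    m$insertion_seq.t == m$insertion_seq.c &
    m$junction_type.t == m$junction_type.c
  sum(ok)
}
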