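REJECT_REASONS <- c("too_short", "no_donor", "no_acceptor",
                    "orientation_conflict", "chimera_ambiguous")

# Canonical split of a read into donor flank / junction / acceptor flank.
#
# All coordinates 0-based; `de`/`dr` anchor the donor segment (read end /
# ref end, exclusive), `as_`/`ar` anchor the acceptor segment (read start /
# ref start).  Each flank is first maximally extended by perfect matches
# toward the junction; a read overlap shared perfectly by both references
# is microhomology (assigned to both flanks, breaks at the outer edges:
# donor break at the rightmost donor-matching position, acceptor break at
# the leftmost acceptor-matching position); an empty overlap is blunt; read
# bases matching neither flank are an insertion.  An overlap containing a
# mismatch to either reference is shrunk to the maximal perfectly-shared
# core, any residue becoming insertion; mh_len > 0 and a non-empty
# insertion never co-occur.
.canonical_split <- function(read, donor, acceptor, de, dr, as_, ar) {
  rr <- .as_raw(read); Dr <- .as_raw(donor); Ar <- .as_raw(acceptor)
  L <- length(rr); Dl <- length(Dr); Al <- length(Ar)
  rawN <- charToRaw("N")
  eq <- function(a, b) a == b && a != rawN
  # maximal perfect forward extension of the donor flank
  e1 <- de
  while (e1 < L) {
    rp <- dr + (e1 - de)                  # donor ref position of read base e1
    if (rp >= Dl || !eq(rr[e1 + 1L], Dr[rp + 1L])) break
    e1 <- e1 + 1L
  }
  # maximal perfect backward extension of the acceptor flank
  s1 <- as_
  while (s1 > 0L) {
    rp <- ar + (s1 - as_) - 1L            # acceptor ref position of base s1-1
    if (rp < 0L || !eq(rr[s1], Ar[rp + 1L])) break
    s1 <- s1 - 1L
  }
  e1p <- e1; s1p <- s1
  if (e1 > s1) {
    # perfect run of donor matches backwards from e1, down to s1 at most
    b <- e1
    while (b > s1) {
      rp <- dr + (b - de) - 1L
      if (rp < 0L || !eq(rr[b], Dr[rp + 1L])) break
      b <- b - 1L
    }
    # perfect run of acceptor matches forward from s1, up to e1 at most
    f <- s1
    while (f < e1) {
      rp <- ar + (f - as_)
      if (rp >= Al || !eq(rr[f + 1L], Ar[rp + 1L])) break
      f <- f + 1L
    }
    e1p <- min(e1, f); s1p <- max(s1, b)
  }
  donor_break <- dr + (e1p - de)
  acceptor_break <- ar + (s1p - as_)
  if (e1p > s1p) {
    list(structure = "microhomology", mh_len = e1p - s1p, insertion_seq = "",
         donor_break = donor_break, acceptor_break = acceptor_break)
  } else if (e1p == s1p) {
    list(structure = "blunt", mh_len = 0L, insertion_seq = "",
         donor_break = donor_break, acceptor_break = acceptor_break)
  } else {
    list(structure = "insertion", mh_len = 0L,
         insertion_seq = substr(read, e1p + 1L, s1p),
         donor_break = donor_break, acceptor_break = acceptor_break)
  }
}

# walk a cigar string and return the aligned blocks with read/ref coords
.cigar_runs <- function(cigar, read_start, ref_start) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MID]", cigar))[[1]]
  dr <- ifelse(ops != "D", lens, 0L)
  ds <- ifelse(ops != "I", lens, 0L)
  re <- read_start + cumsum(dr)
  se <- ref_start + cumsum(ds)
  list(op = ops, len = lens,
       read_start = c(read_start, re[-length(re)]), read_end = re,
       ref_start = c(ref_start, se[-length(se)]), ref_end = se)
}

# junction-side anchor of a segment, robust to gapped over-extension past
# the junction: use the longest gapless block (equals the segment end for
# the usual gapless alignment; substitutions never split a block, only
# indel artifacts do)
.anchor_segment <- function(seg, side = c("end", "start")) {
  side <- match.arg(side)
  runs <- .cigar_runs(seg$cigar, seg$read_start, seg$ref_start)
  mi <- which(runs$op == "M")
  if (!length(mi)) {
    return(if (side == "end") c(seg$read_end, seg$ref_end)
           else c(seg$read_start, seg$ref_start))
  }
  best <- mi[runs$len[mi] == max(runs$len[mi])]
  i <- if (side == "end") best[length(best)] else best[1]
  if (side == "end") c(runs$read_end[i], runs$ref_end[i])
  else c(runs$read_start[i], runs$ref_start[i])
}

# per-position mismatch indicator of read positions `pos` (0-based) against
# a reference diagonal anchored at read position a_read <-> ref a_ref;
# out-of-range reference positions count as mismatches
.diag_mismatch <- function(rr, refr, pos, a_read, a_ref) {
  rp <- a_ref + (pos - a_read)
  bad <- rp < 0L | rp >= length(refr)
  out <- bad
  ok <- !bad
  out[ok] <- rr[pos[ok] + 1L] != refr[rp[ok] + 1L]
  out
}

# junction-side anchor retracted to the nearest run of >= k consecutive
# matches (guards against an aligner having extended a flank through a
# mismatch past the junction); diagonal taken from the longest gapless block
.run_anchor <- function(seg, read, ref, side, k = 10L) {
  base <- .anchor_segment(seg, side)
  rr <- .as_raw(read); refr <- .as_raw(ref)
  runs <- .cigar_runs(seg$cigar, seg$read_start, seg$ref_start)
  mi <- which(runs$op == "M")
  if (!length(mi)) return(base)
  i <- mi[which.max(runs$len[mi])]
  pos <- seq.int(runs$read_start[i], runs$read_end[i] - 1L)
  mis <- .diag_mismatch(rr, refr, pos, runs$read_start[i], runs$ref_start[i])
  r <- rle(!mis)
  ends <- cumsum(r$lengths)
  good <- which(r$values & r$lengths >= min(k, runs$len[i]))
  if (!length(good)) return(base)
  if (side == "end") {
    j <- good[length(good)]
    off <- ends[j]                       # run end, offset within block
  } else {
    j <- good[1]
    off <- ends[j] - r$lengths[j]        # run start
  }
  c(runs$read_start[i] + off, runs$ref_start[i] + off)
}

# extend an anchor along its diagonal, hopping isolated mismatches that are
# confirmed by >= `confirm` further matches (absorbs sequencing errors
# sitting between a trimmed segment end and the true junction)
.extend_anchor <- function(anchor, rr, refr, forward = TRUE, max_hops = 3L,
                           confirm = 4L) {
  p <- anchor[1]; q <- anchor[2]
  L <- length(rr); R <- length(refr)
  rawN <- charToRaw("N")
  hops <- 0L
  repeat {
    if (forward) {
      while (p < L && q < R && rr[p + 1L] == refr[q + 1L] &&
             rr[p + 1L] != rawN) { p <- p + 1L; q <- q + 1L }
      if (hops >= max_hops || p >= L || q >= R) break
      k <- 0L
      while (p + 1L + k < L && q + 1L + k < R && k < confirm &&
             rr[p + k + 2L] == refr[q + k + 2L]) k <- k + 1L
      if (k < confirm) break
      p <- p + 1L; q <- q + 1L; hops <- hops + 1L
    } else {
      while (p > 0L && q > 0L && rr[p] == refr[q] &&
             rr[p] != rawN) { p <- p - 1L; q <- q - 1L }
      if (hops >= max_hops || p <= 0L || q <= 0L) break
      k <- 0L
      while (p - 1L - k > 0L && q - 1L - k > 0L && k < confirm &&
             rr[p - 1L - k] == refr[q - 1L - k]) k <- k + 1L
      if (k < confirm) break
      p <- p - 1L; q <- q - 1L; hops <- hops + 1L
    }
  }
  c(p, q)
}

#' Classify the structure of a junction between two aligned segments
#'
#' Applies the canonical breakpoint convention: both flanks are maximally
#' extended by perfect matches toward the junction; a perfectly shared read
#' overlap is microhomology (breaks at the outer edges of the shared
#' stretch), no overlap is blunt, and unmatched intervening read bases are
#' an insertion.  Exactly one of `mh_len > 0` / non-empty `insertion_seq`
#' can hold.  When an aligner extended a flank through mismatches past the
#' junction, alternative retracted anchorings are evaluated and the split
#' that reconstructs the junction window most cheaply (2 per mismatching
#' base, 1 per inserted base) is kept.
#'
#' @param donor_seg,acceptor_seg one-row segment data.frames (as produced by
#'   [align_read()]) anchoring the donor (5') and acceptor (3') flanks on
#'   the same read orientation.
#' @param read the read sequence in the orientation the segments refer to.
#' @param donor_ref,acceptor_ref reference sequences of the two regions.
#' @return list with `structure`, `mh_len`, `insertion_seq`, `donor_break`,
#'   `acceptor_break` (inter-base, 0-based).
#' @export
classify_structure <- function(donor_seg, acceptor_seg, read,
                               donor_ref, acceptor_ref) {
  rr <- .as_raw(read); Dr <- .as_raw(donor_ref); Ar <- .as_raw(acceptor_ref)
  d_base <- .anchor_segment(donor_seg, "end")
  a_base <- .anchor_segment(acceptor_seg, "start")
  d_anchors <- unique(list(d_base,
                           .run_anchor(donor_seg, read, donor_ref, "end"),
                           .extend_anchor(d_base, rr, Dr, forward = TRUE)))
  a_anchors <- unique(list(a_base,
                           .run_anchor(acceptor_seg, read, acceptor_ref,
                                       "start"),
                           .extend_anchor(a_base, rr, Ar, forward = FALSE)))
  cands <- list(); splits <- list()
  for (da in d_anchors) for (aa in a_anchors) {
    cands[[length(cands) + 1L]] <- c(da, aa)
    splits[[length(splits) + 1L]] <-
      .canonical_split(read, donor_ref, acceptor_ref,
                       de = da[1], dr = da[2], as_ = aa[1], ar = aa[2])
  }
  if (length(splits) == 1L) return(splits[[1]])
  # several anchorings are possible when an aligner extended a flank
  # through mismatches across the junction; keep the split whose implied
  # reconstruction explains the junction window most cheaply (2 per
  # mismatching base, 1 per inserted base)
  L <- length(rr)
  e1p <- vapply(seq_along(splits), function(i)
    cands[[i]][1] + (splits[[i]]$donor_break - cands[[i]][2]), numeric(1))
  s1p <- vapply(seq_along(splits), function(i)
    cands[[i]][3] + (splits[[i]]$acceptor_break - cands[[i]][4]), numeric(1))
  w_lo <- max(0, min(s1p) - 30); w_hi <- min(L, max(e1p) + 30)
  cost <- vapply(seq_along(splits), function(i) {
    dpos <- if (e1p[i] > w_lo) seq.int(w_lo, e1p[i] - 1L) else integer(0)
    apos <- if (w_hi > s1p[i]) seq.int(s1p[i], w_hi - 1L) else integer(0)
    2 * sum(.diag_mismatch(rr, Dr, dpos, cands[[i]][1], cands[[i]][2])) +
      2 * sum(.diag_mismatch(rr, Ar, apos, cands[[i]][3], cands[[i]][4])) +
      nchar(splits[[i]]$insertion_seq)
  }, numeric(1))
  splits[[which.min(cost)]]
}

.empty_calls <- function() {
  data.frame(read_id = character(0), donor_region = character(0),
             donor_break = integer(0), acceptor_region = character(0),
             acceptor_break = integer(0), structure = character(0),
             mh_len = integer(0), insertion_seq = character(0),
             junction_type = character(0), intermediate_region = character(0),
             intermediate_start = integer(0), intermediate_end = integer(0),
             orientation_consistent = logical(0),
             ambiguous_acceptor = logical(0), multi_mapped = logical(0),
             donor_in_repeat = logical(0), acceptor_in_repeat = logical(0),
             stringsAsFactors = FALSE)
}

.in_intervals <- function(pos, iv) {
  if (is.null(iv)) return(NA)
  any(pos >= iv[, 1] & pos <= iv[, 2])
}

# flip a segment table onto the reverse-complemented read
.flip_segments <- function(segs, read_len) {
  rs <- read_len - segs$read_end
  segs$read_end <- read_len - segs$read_start
  segs$read_start <- rs
  segs$orientation <- ifelse(segs$orientation == "forward",
                             "reverse", "forward")
  segs
}

#' Assemble a junction call from the aligned segments of one read
#'
#' Requires one donor-role segment anchored toward the read 5' end and one
#' acceptor-role segment toward the 3' end in the same orientation
#' (deletional joins only; inverted acceptor segments are rejected as
#' `orientation_conflict`).  An intermediate-role segment (Sgamma/Salpha)
#' lying between them -- or substituting the acceptor flank -- makes the
#' junction `complex` (post-switch).  When several acceptor regions compete,
#' the highest score wins (ties: longer segment, then lexicographic region
#' id; surviving ties are flagged `ambiguous_acceptor`).
#'
#' @param segments data.frame from [align_read()] for a single read.
#' @param read the read sequence (original orientation).
#' @param regions the `lsr_region_set` used for alignment.
#' @param read_id id recorded in the call.
#' @return list with either `call` (one-row data.frame) and `reject = NULL`,
#'   or `call = NULL` and `reject` a reason code among
#'   `no_donor`, `no_acceptor`, `orientation_conflict`, `chimera_ambiguous`.
#' @export
assemble_junction <- function(segments, read, regions, read_id = "read") {
  roles <- vapply(regions, `[[`, character(1), "role")
  if (!nrow(segments)) return(list(call = NULL, reject = "no_donor"))
  seg_roles <- roles[segments$region_id]
  if (!any(seg_roles == "donor"))
    return(list(call = NULL, reject = "no_donor"))
  if (!any(seg_roles %in% c("acceptor", "intermediate")))
    return(list(call = NULL, reject = "no_acceptor"))

  # dominant orientation by total aligned score; re-orient the read so that
  # assembly always works donor-forward
  sc <- tapply(segments$score, segments$orientation, sum)
  dominant <- names(sc)[which.max(sc)]
  if (dominant == "reverse") {
    read <- reverse_complement(read)
    segments <- .flip_segments(segments, nchar(read))
  }
  fwd <- segments[segments$orientation == "forward", , drop = FALSE]
  f_roles <- roles[fwd$region_id]
  donors <- fwd[f_roles == "donor", , drop = FALSE]
  if (!nrow(donors)) return(list(call = NULL, reject = "orientation_conflict"))
  donor <- donors[which.max(donors$score), , drop = FALSE]

  downstream <- fwd[fwd$read_start > donor$read_start &
                    fwd$read_end > donor$read_end &
                    fwd$region_id != donor$region_id, , drop = FALSE]
  d_roles <- roles[downstream$region_id]
  acceptors <- downstream[d_roles == "acceptor", , drop = FALSE]
  intermediates <- downstream[d_roles == "intermediate", , drop = FALSE]
  if (!nrow(acceptors) && !nrow(intermediates)) {
    # acceptor-role alignments exist but not in a workable layout
    has_rev_acc <- any(roles[segments$region_id[
      segments$orientation != "forward"]] == "acceptor")
    return(list(call = NULL,
                reject = if (has_rev_acc) "orientation_conflict"
                         else "chimera_ambiguous"))
  }

  pick_best <- function(cand) {
    o <- order(-cand$score, -(cand$read_end - cand$read_start), cand$region_id)
    cand[o, , drop = FALSE]
  }
  ambiguous <- FALSE
  if (nrow(acceptors)) {
    acceptors <- pick_best(acceptors)
    acceptor <- acceptors[1L, , drop = FALSE]
    if (nrow(acceptors) > 1L) {
      a2 <- acceptors[2L, ]
      ambiguous <- a2$score == acceptor$score &&
        (a2$read_end - a2$read_start) ==
          (acceptor$read_end - acceptor$read_start)
    }
    # an intermediate segment lying between donor and acceptor => complex
    mids <- intermediates[intermediates$read_start >= donor$read_end - 10L &
                          intermediates$read_end <= acceptor$read_start + 10L, ,
                          drop = FALSE]
    mid <- if (nrow(mids)) pick_best(mids)[1L, , drop = FALSE] else NULL
  } else {
    # no acceptor flank on the read: the intermediate substitutes it
    acceptor <- pick_best(intermediates)[1L, , drop = FALSE]
    mid <- NULL
  }

  dref <- regions[[donor$region_id]]$sequence
  aref <- regions[[acceptor$region_id]]$sequence
  if (!is.null(mid)) {
    mref <- regions[[mid$region_id]]$sequence
    j1 <- classify_structure(donor, mid, read, dref, mref)
    j2 <- classify_structure(mid, acceptor, read, mref, aref)
    cls <- j1
    acceptor_break <- j2$acceptor_break
    jt <- "complex"
    int_region <- mid$region_id
    int_start <- j1$acceptor_break
    int_end <- j2$donor_break
  } else {
    cls <- classify_structure(donor, acceptor, read, dref, aref)
    acceptor_break <- cls$acceptor_break
    jt <- if (roles[[acceptor$region_id]] == "intermediate")
      "complex" else "direct"
    int_region <- if (jt == "complex") acceptor$region_id else NA_character_
    int_start <- NA_integer_; int_end <- NA_integer_
  }
  donor_reg <- regions[[donor$region_id]]
  acc_reg <- regions[[acceptor$region_id]]
  call <- data.frame(
    read_id = read_id, donor_region = donor$region_id,
    donor_break = cls$donor_break, acceptor_region = acceptor$region_id,
    acceptor_break = acceptor_break, structure = cls$structure,
    mh_len = cls$mh_len, insertion_seq = cls$insertion_seq,
    junction_type = jt, intermediate_region = int_region,
    intermediate_start = int_start, intermediate_end = int_end,
    orientation_consistent = all(fwd$orientation == "forward"),
    ambiguous_acceptor = ambiguous,
    multi_mapped = donor$multi_mapped || acceptor$multi_mapped,
    donor_in_repeat = .in_intervals(cls$donor_break, donor_reg$ls_intervals),
    acceptor_in_repeat = .in_intervals(acceptor_break, acc_reg$ls_intervals),
    stringsAsFactors = FALSE)
  list(call = call, reject = NULL)
}

#' Call junctions for a set of reads
#'
#' Pipeline driver: primer trimming, seed-and-extend alignment, junction
#' assembly and structure classification for every read.  Deterministic
#' given inputs and parameters.
#'
#' @param reads a named character vector of read sequences, a
#'   `Biostrings::DNAStringSet`, or a FASTQ/FASTA file path.
#' @param regions an `lsr_region_set` with exactly one donor region.
#' @param params [align_params()].
#' @param primers optional [primer_pair()] trimmed from read ends.
#' @param sample_id label carried into the result.
#' @return list of class `lsr_callset`: `calls` (data.frame, one row per
#'   accepted read), `rejects` (reason tally), `n_reads`, `sample_id`.
#' @export
call_junctions <- function(reads, regions, params = align_params(),
                           primers = NULL, sample_id = "sample") {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fmt <- if (grepl("\\.f(ast)?q$", reads, ignore.case = TRUE))
      "fastq" else "fasta"
    reads <- Biostrings::readDNAStringSet(reads, format = fmt)
  }
  if (methods::is(reads, "DNAStringSet")) {
    nm <- names(reads)
    reads <- as.character(reads)
    names(reads) <- nm
  }
  if (is.null(names(reads)) && length(reads))
    names(reads) <- sprintf("read%06d", seq_along(reads))
  stopifnot(inherits(regions, "lsr_region_set"))
  roles <- vapply(regions, `[[`, character(1), "role")
  if (sum(roles == "donor") != 1L)
    stop("region set must contain exactly one donor region", call. = FALSE)

  idx <- build_kmer_index(regions, params$seed_k)
  tally <- stats::setNames(integer(length(REJECT_REASONS)), REJECT_REASONS)
  calls <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    rid <- names(reads)[i]
    tr <- trim_primers(reads[[i]], primers)
    if (nchar(tr$seq) < 2L * params$min_seg_len) {
      tally[["too_short"]] <- tally[["too_short"]] + 1L
      next
    }
    segs <- align_read(tr$seq, regions, params, read_id = rid,
                       kmer_index = idx)
    res <- assemble_junction(segs, tr$seq, regions, read_id = rid)
    if (is.null(res$call)) {
      tally[[res$reject]] <- tally[[res$reject]] + 1L
    } else {
      calls[[i]] <- res$call
    }
  }
  calls <- do.call(rbind, c(list(.empty_calls()), calls[!vapply(calls, is.null,
                                                                logical(1))]))
  rownames(calls) <- NULL
  structure(list(calls = calls,
                 rejects = data.frame(reason = names(tally),
                                      count = as.integer(tally),
                                      stringsAsFactors = FALSE),
                 n_reads = length(reads), sample_id = sample_id),
            class = "lsr_callset")
}

#' @export
print.lsr_callset <- function(x, ...) {
  cat(sprintf("<lsr_callset> %s: %d reads, %d junction calls, %d rejected\n",
              x$sample_id, x$n_reads, nrow(x$calls), sum(x$rejects$count)))
  invisible(x)
}
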