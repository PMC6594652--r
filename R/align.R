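#' Alignment parameters
#'
#' Defaults follow BLAST-like nucleotide scoring; the 20 bp / 90 % segment
#' reporting floor echoes the classical dot-plot criterion used to define
#' repetitive switch-like DNA.  A gap of length L costs
#' `gap_open + L * gap_extend`.
#'
#' @param seed_k exact k-mer seed length used to pre-filter read/region pairs.
#' @param min_seg_len minimum reported segment length (bp).
#' @param min_identity minimum reported segment identity.
#' @param match,mismatch,gap_open,gap_extend alignment scores (penalties
#'   negative).
#' @param max_segments maximum segments reported per read/region/orientation.
#' @return a list of class `lsr_align_params`.
#' @export
align_params <- function(seed_k = 12L, min_seg_len = 20L, min_identity = 0.90,
                         match = 2L, mismatch = -3L, gap_open = -5L,
                         gap_extend = -2L, max_segments = 4L) {
  stopifnot(seed_k >= 4L, min_seg_len >= seed_k %/% 2L,
            min_identity > 0, min_identity <= 1,
            match > 0, mismatch < 0, gap_open <= 0, gap_extend < 0)
  structure(list(seed_k = as.integer(seed_k),
                 min_seg_len = as.integer(min_seg_len),
                 min_identity = min_identity, match = as.integer(match),
                 mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 max_segments = as.integer(max_segments)),
            class = "lsr_align_params")
}

.empty_segments <- function() {
  data.frame(read_id = character(0), read_start = integer(0),
             read_end = integer(0), region_id = character(0),
             ref_start = integer(0), ref_end = integer(0),
             orientation = character(0), score = integer(0),
             identity = numeric(0), matches = integer(0),
             mismatches = integer(0), insertions = integer(0),
             deletions = integer(0), cigar = character(0),
             multi_mapped = logical(0), stringsAsFactors = FALSE)
}

# maximal-scoring subarray (Kadane); returns c(start, end) 0-based
# half-open and the score, or NULL if all-negative
.max_subarray <- function(sc) {
  best <- -Inf; best_s <- 0L; best_e <- 0L
  cur <- 0; cur_s <- 0L
  for (k in seq_along(sc)) {
    if (cur <= 0) { cur <- sc[k]; cur_s <- k - 1L } else cur <- cur + sc[k]
    if (cur > best) { best <- cur; best_s <- cur_s; best_e <- k }
  }
  if (best <= 0) NULL else c(best_s, best_e, best)
}

# decompose one (possibly gapped) local alignment into gapless segments
# meeting the length/identity floor.  A chimeric read can make the single
# best local alignment bridge the junction through a low-identity stretch;
# block-wise extraction recovers the clean flank segments such a bridge
# would mask.  Extraction scores encode the identity floor (match +1,
# mismatch -t/(1-t)) so any stretch below threshold identity has negative
# drift and cannot be bridged.
.gapless_segments <- function(query, subject, al, params) {
  runs <- .cigar_runs(al$cigar, al$q_start, al$s_start)
  qr <- .as_raw(query); sr <- .as_raw(subject); rawN <- charToRaw("N")
  t <- params$min_identity
  penalty <- t / (1 - t + 1e-9)
  out <- list()
  for (i in which(runs$op == "M")) {
    qs <- runs$read_start[i]; ss <- runs$ref_start[i]; len <- runs$len[i]
    if (len < params$min_seg_len) next
    qa <- qr[(qs + 1L):(qs + len)]; sa <- sr[(ss + 1L):(ss + len)]
    is_match <- qa == sa & qa != rawN
    sc <- ifelse(is_match, 1, -penalty)
    for (k in 1:3) {
      ms <- .max_subarray(sc)
      if (is.null(ms)) break
      sl <- ms[2] - ms[1]
      idx <- (ms[1] + 1L):ms[2]
      matches <- sum(is_match[idx])
      identity <- matches / sl
      sc[idx] <- -Inf
      if (sl < params$min_seg_len || identity < params$min_identity) next
      # columns: read_start, read_end, ref_start, ref_end, score, matches,
      # mismatches, multi_mapped
      out[[length(out) + 1L]] <- c(
        qs + ms[1], qs + ms[2], ss + ms[1], ss + ms[2],
        params$match * matches + params$mismatch * (sl - matches),
        matches, sl - matches, as.integer(al$n_best > 1L))
    }
  }
  out
}

# recursively harvest non-overlapping local alignments of query vs subject;
# offset q_off (0-based) shifts reported query coordinates
.harvest_segments <- function(query, subject, params, q_off = 0L, depth = 0L) {
  if (nchar(query) < params$min_seg_len || depth >= params$max_segments)
    return(NULL)
  al <- .sw_local(query, subject, params$match, params$mismatch,
                  params$gap_open, params$gap_extend)
  if (al$score <= 0) return(NULL)
  if (al$q_end - al$q_start < params$min_seg_len %/% 2L) return(NULL)
  segs <- .gapless_segments(query, subject, al, params)
  segs <- lapply(segs, function(s) { s[1:2] <- s[1:2] + q_off; s })
  left <- if (al$q_start >= params$min_seg_len)
    .harvest_segments(substr(query, 1L, al$q_start), subject, params,
                      q_off, depth + 1L) else NULL
  right <- if (nchar(query) - al$q_end >= params$min_seg_len)
    .harvest_segments(substr(query, al$q_end + 1L, nchar(query)), subject,
                      params, q_off + al$q_end, depth + 1L) else NULL
  c(segs, left, right)
}

#' Align one read against a set of reference regions
#'
#' Exact k-mer seeding selects candidate region/orientation pairs; candidates
#' are aligned with affine-gap local alignment and all non-redundant segments
#' of at least `min_seg_len` bp and `min_identity` identity are reported, in
#' both read orientations.  Read coordinates always refer to the read as
#' given; `orientation == "reverse"` means the reverse complement of the read
#' matches the region forward strand.  When a placement ties in score across
#' reference offsets the smallest reference start is kept and the segment is
#' flagged `multi_mapped`.
#'
#' @param read DNA string.
#' @param regions an `lsr_region_set` (or list of `lsr_region`).
#' @param params an [align_params()] list.
#' @param read_id id copied into the output.
#' @param kmer_index optional precomputed region k-mer index from
#'   [build_kmer_index()] (speeds up repeated calls).
#' @return data.frame of aligned segments sorted by `read_start` (0-based
#'   half-open intervals).
#' @export
align_read <- function(read, regions, params = align_params(),
                       read_id = "read", kmer_index = NULL) {
  read <- toupper(read); .check_dna(read, "read")
  L <- nchar(read)
  if (L < params$min_seg_len) return(.empty_segments())
  if (is.null(kmer_index)) kmer_index <- build_kmer_index(regions, params$seed_k)
  rc <- reverse_complement(read)
  k <- params$seed_k
  qk <- list(forward = .kmer_set(read, k), reverse = .kmer_set(rc, k))
  rows <- list(); region_ids <- character(0); orients <- character(0)
  for (rid in names(regions)) {
    subject <- regions[[rid]]$sequence
    for (orient in c("forward", "reverse")) {
      if (!any(qk[[orient]] %in% kmer_index[[rid]])) next
      q <- if (orient == "forward") read else rc
      segs <- .harvest_segments(q, subject, params)
      if (!length(segs)) next
      if (orient == "reverse")          # map back to original read coordinates
        segs <- lapply(segs, function(s) {
          ns <- s; ns[1] <- L - s[2]; ns[2] <- L - s[1]; ns
        })
      rows <- c(rows, segs)
      region_ids <- c(region_ids, rep(rid, length(segs)))
      orients <- c(orients, rep(orient, length(segs)))
    }
  }
  if (!length(rows)) return(.empty_segments())
  m <- do.call(rbind, rows)
  len <- m[, 6] + m[, 7]
  segs <- data.frame(
    read_id = read_id, read_start = as.integer(m[, 1]),
    read_end = as.integer(m[, 2]), region_id = region_ids,
    ref_start = as.integer(m[, 3]), ref_end = as.integer(m[, 4]),
    orientation = orients, score = as.integer(m[, 5]),
    identity = m[, 6] / len, matches = as.integer(m[, 6]),
    mismatches = as.integer(m[, 7]), insertions = 0L, deletions = 0L,
    cigar = paste0(as.integer(len), "M"), multi_mapped = m[, 8] > 0,
    stringsAsFactors = FALSE)
  segs <- segs[order(segs$read_start, -segs$score, segs$region_id), ,
               drop = FALSE]
  rownames(segs) <- NULL
  segs
}

#' Precompute region k-mer sets for seeding
#'
#' @param regions an `lsr_region_set`.
#' @param k seed length.
#' @return named list of unique k-mer character vectors.
#' @export
build_kmer_index <- function(regions, k = 12L) {
  idx <- lapply(regions, function(r) .kmer_set(r$sequence, k))
  names(idx) <- names(regions)
  idx
}

#' Trim terminal primer matches from a read
#'
#' Removes a terminal match (up to `max_mismatch` substitutions) of the
#' forward primer or of the reverse complement of the reverse primer from
#' either read end, and records which primers were seen.
#'
#' @param read DNA string.
#' @param primers an [primer_pair()] object, or NULL (no-op).
#' @param max_mismatch maximum Hamming mismatches tolerated in a primer hit.
#' @return list with `seq` (trimmed read), `forward_found`, `reverse_found`.
#' @export
trim_primers <- function(read, primers, max_mismatch = 2L) {
  read <- toupper(read); .check_dna(read, "read")
  if (is.null(primers))
    return(list(seq = read, forward_found = FALSE, reverse_found = FALSE))
  stopifnot(inherits(primers, "lsr_primer_pair"))
  hamming_le <- function(a, b, k) {
    sum(charToRaw(a) != charToRaw(b)) <= k
  }
  fwd <- primers$forward_seq
  rev_rc <- reverse_complement(primers$reverse_seq)
  f_found <- r_found <- FALSE
  # forward primer at 5' end; reverse-complemented reverse primer at 3' end
  nf <- nchar(fwd); nr <- nchar(rev_rc); n <- nchar(read)
  if (n >= nf && hamming_le(substr(read, 1L, nf), fwd, max_mismatch)) {
    read <- substr(read, nf + 1L, n); f_found <- TRUE; n <- nchar(read)
  }
  if (n >= nr && hamming_le(substr(read, n - nr + 1L, n), rev_rc,
                            max_mismatch)) {
    read <- substr(read, 1L, n - nr); r_found <- TRUE
  }
  # reads sequenced from the other strand: reverse primer at 5' end,
  # reverse-complemented forward primer at 3' end
  n <- nchar(read)
  rev5 <- primers$reverse_seq; fwd_rc <- reverse_complement(fwd)
  if (!f_found && !r_found) {
    if (n >= nchar(rev5) &&
        hamming_le(substr(read, 1L, nchar(rev5)), rev5, max_mismatch)) {
      read <- substr(read, nchar(rev5) + 1L, n); r_found <- TRUE; n <- nchar(read)
    }
    if (n >= nchar(fwd_rc) &&
        hamming_le(substr(read, n - nchar(fwd_rc) + 1L, n), fwd_rc,
                   max_mismatch)) {
      read <- substr(read, 1L, n - nchar(fwd_rc)); f_found <- TRUE
    }
  }
  list(seq = read, forward_found = f_found, reverse_found = r_found)
}
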