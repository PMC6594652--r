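DNA_ALPHABET <- c("A", "C", "G", "T", "N")

.check_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single character string", call. = FALSE)
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad))
    stop(what, " contains non-DNA characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ""), call. = FALSE)
  invisible(seq)
}

#' Reverse complement of a DNA string
#'
#' Alphabet is restricted to A, C, G, T, N (N complements to N).
#'
#' @param seq single DNA string (uppercase).
#' @return the reverse complement as a character string.
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(seq) {
  .check_dna(seq)
  comp <- chartr("ACGTN", "TGCAN", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

# raw-vector view of a DNA string; single bytes compare fast
.as_raw <- function(seq) charToRaw(seq)

# set of k-mers of a sequence (character vector, unique)
.kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, seq_len(n - k + 1L), k:n))
}

# does `read` share at least one exact k-mer with precomputed region k-mer set
.shares_kmer <- function(read, kmers, k) {
  n <- nchar(read)
  if (n < k) return(FALSE)
  any(substring(read, seq_len(n - k + 1L), k:n) %in% kmers)
}

# deterministic child seed derivation, kept below 2^31
.child_seed <- function(seed, i) {
  (as.integer(seed) %% 1000003L) * 1009L + (as.integer(i) %% 1000L) * 7919L
}

# sample one element of a vector (immune to sample()'s scalar expansion)
.sample1 <- function(x) x[sample.int(length(x), 1L)]

.stopifnot_interval <- function(iv, len, what = "interval") {
  if (length(iv) != 2L || anyNA(iv) || iv[1] < 0 || iv[2] > len || iv[1] >= iv[2])
    stop(what, " must be a 0-based half-open interval within [0,", len, ")",
         call. = FALSE)
  invisible(iv)
}
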