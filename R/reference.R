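#' Reference region
#'
#' A named reference segment against which reads are aligned: the Smu donor,
#' an acceptor window (a downstream switch region or a 3'RR window around
#' hs3/hs1,2/hs4), or an intermediate switch region (Sgamma/Salpha) used to
#' type complex post-switch junctions.  All coordinates used throughout the
#' package are 0-based half-open; a "break" is an inter-base position in
#' `[0, nchar(sequence)]`.
#'
#' @param region_id short unique name.
#' @param sequence DNA string over A/C/G/T/N (lowercase accepted, stored
#'   uppercase).
#' @param role one of `"donor"`, `"acceptor"`, `"intermediate"`.
#' @param genomic_offset coordinate of sequence position 0 in an external
#'   assembly (0 if standalone).
#' @param locus_label free-text description (e.g. "3'RR2 hs4 window").
#' @param amplifiable_interval 0-based half-open interval of positions
#'   reachable by the primer pair; defaults to the whole sequence.
#' @param ls_intervals optional two-column matrix/data.frame of 0-based
#'   half-open intervals annotating repetitive (S or like-switch) stretches;
#'   used only to flag breaks as in/out of repeat.
#' @return an object of class `lsr_region`.
#' @export
lsr_region <- function(region_id, sequence,
                       role = c("donor", "acceptor", "intermediate"),
                       genomic_offset = 0L, locus_label = "",
                       amplifiable_interval = NULL, ls_intervals = NULL) {
  role <- match.arg(role)
  if (!is.character(region_id) || length(region_id) != 1L || !nzchar(region_id))
    stop("region_id must be a non-empty string", call. = FALSE)
  sequence <- toupper(sequence)
  .check_dna(sequence, paste0("sequence of region '", region_id, "'"))
  if (!nzchar(sequence))
    stop("region '", region_id, "' has an empty sequence", call. = FALSE)
  len <- nchar(sequence)
  if (is.null(amplifiable_interval)) amplifiable_interval <- c(0L, len)
  amplifiable_interval <- as.integer(amplifiable_interval)
  .stopifnot_interval(amplifiable_interval, len,
                      paste0("amplifiable_interval of '", region_id, "'"))
  if (!is.null(ls_intervals)) {
    ls_intervals <- as.matrix(ls_intervals)[, 1:2, drop = FALSE]
    storage.mode(ls_intervals) <- "integer"
    apply(ls_intervals, 1L, .stopifnot_interval, len = len,
          what = paste0("ls_interval of '", region_id, "'"))
  }
  structure(list(region_id = region_id, sequence = sequence, role = role,
                 genomic_offset = as.integer(genomic_offset),
                 locus_label = locus_label,
                 amplifiable_interval = amplifiable_interval,
                 ls_intervals = ls_intervals),
            class = "lsr_region")
}

#' @export
print.lsr_region <- function(x, ...) {
  cat(sprintf("<lsr_region> %s [%s] %d bp, amplifiable [%d,%d)%s\n",
              x$region_id, x$role, nchar(x$sequence),
              x$amplifiable_interval[1], x$amplifiable_interval[2],
              if (nzchar(x$locus_label)) paste0(" - ", x$locus_label) else ""))
  invisible(x)
}

#' Assemble a validated region set
#'
#' @param ... `lsr_region` objects (or a single list of them).
#' @param require_donor require exactly one donor-role region (the invariant
#'   for a junction-calling run); set `FALSE` for scan-only sets.
#' @return a named list of regions with class `lsr_region_set`.
#' @export
region_set <- function(..., require_donor = TRUE) {
  regs <- list(...)
  if (length(regs) == 1L && !inherits(regs[[1]], "lsr_region")) regs <- regs[[1]]
  if (!length(regs)) stop("no regions supplied", call. = FALSE)
  if (!all(vapply(regs, inherits, logical(1), "lsr_region")))
    stop("all elements must be lsr_region objects", call. = FALSE)
  ids <- vapply(regs, `[[`, character(1), "region_id")
  if (anyDuplicated(ids))
    stop("duplicate region ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  roles <- vapply(regs, `[[`, character(1), "role")
  if (require_donor && sum(roles == "donor") != 1L)
    stop("a region set for junction calling must contain exactly one donor ",
         "region (found ", sum(roles == "donor"), ")", call. = FALSE)
  names(regs) <- ids
  structure(regs, class = "lsr_region_set")
}

#' @export
print.lsr_region_set <- function(x, ...) {
  cat(sprintf("<lsr_region_set> %d regions\n", length(x)))
  for (r in x) print(r)
  invisible(x)
}

#' Load reference regions from FASTA plus a manifest
#'
#' The manifest (JSON file or equivalent list) maps each region id to its
#' role and optional `offset`, `interval` (0-based half-open amplifiable
#' interval), `label` and `ls_intervals`.  Every manifest id must be present
#' in the FASTA; sequences are uppercased and may contain N.
#'
#' @param fasta_path path to a FASTA file of reference segments.
#' @param manifest path to a JSON manifest, or a named list
#'   `list(region_id = list(role = ..., offset = ..., interval = ...), ...)`.
#' @param require_donor passed to [region_set()].
#' @return an `lsr_region_set`.
#' @export
load_regions <- function(fasta_path, manifest, require_donor = TRUE) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- names(seqs)
  ids <- sub("\\s.*$", "", ids)            # FASTA description after first word
  if (anyDuplicated(ids))
    stop("duplicate record ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(seqs) <- ids
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest)
  if (is.null(names(manifest)) || !all(nzchar(names(manifest))))
    stop("manifest must be a named mapping region_id -> spec", call. = FALSE)
  missing <- setdiff(names(manifest), ids)
  if (length(missing))
    stop("manifest names absent from FASTA: ",
         paste(missing, collapse = ", "), call. = FALSE)
  regs <- lapply(names(manifest), function(id) {
    sp <- manifest[[id]]
    lsr_region(region_id = id,
               sequence = as.character(seqs[[id]]),
               role = sp$role,
               genomic_offset = if (is.null(sp$offset)) 0L else sp$offset,
               locus_label = if (is.null(sp$label)) "" else sp$label,
               amplifiable_interval =
                 if (is.null(sp$interval)) NULL else unlist(sp$interval),
               ls_intervals =
                 if (is.null(sp$ls_intervals)) NULL
                 else do.call(rbind, lapply(sp$ls_intervals, unlist)))
  })
  region_set(regs, require_donor = require_donor)
}

#' Write a region set back to FASTA + JSON manifest
#'
#' Round-trips with [load_regions()].
#'
#' @param regions an `lsr_region_set`.
#' @param fasta_path,manifest_path output paths.
#' @export
write_regions <- function(regions, fasta_path, manifest_path) {
  stopifnot(inherits(regions, "lsr_region_set"))
  seqs <- Biostrings::DNAStringSet(vapply(regions, `[[`, character(1),
                                          "sequence"))
  names(seqs) <- names(regions)
  Biostrings::writeXStringSet(seqs, fasta_path)
  man <- lapply(regions, function(r) {
    sp <- list(role = r$role, offset = r$genomic_offset, label = r$locus_label,
               interval = r$amplifiable_interval)
    if (!is.null(r$ls_intervals))
      sp$ls_intervals <- lapply(seq_len(nrow(r$ls_intervals)),
                                function(i) r$ls_intervals[i, ])
    sp
  })
  jsonlite::write_json(man, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta_path, manifest_path))
}

#' Primer pair
#'
#' Both primers are stored as written 5'->3' on the strand each anneals to,
#' matching how primers appear in protocol tables.
#'
#' @param forward_seq,reverse_seq primer sequences (>= 15 nt).
#' @param forward_region,reverse_region region ids the primers sit in.
#' @param name free-text label.
#' @return an object of class `lsr_primer_pair`.
#' @export
primer_pair <- function(forward_seq, reverse_seq,
                        forward_region = NA_character_,
                        reverse_region = NA_character_, name = "") {
  forward_seq <- toupper(forward_seq); reverse_seq <- toupper(reverse_seq)
  .check_dna(forward_seq, "forward primer")
  .check_dna(reverse_seq, "reverse primer")
  if (nchar(forward_seq) < 15L || nchar(reverse_seq) < 15L)
    stop("primers must be at least 15 nt", call. = FALSE)
  structure(list(forward_seq = forward_seq, reverse_seq = reverse_seq,
                 forward_region = forward_region,
                 reverse_region = reverse_region, name = name),
            class = "lsr_primer_pair")
}
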