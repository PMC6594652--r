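MOTIF_CLASSES <- c("AID_WRCY", "AID_RGYW", "APOBEC3_TC", "APOBEC3_GA")

# overlapping regex scan; returns 0-based starts
.scan_pattern <- function(seq, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

.motif_df <- function(starts, width, motif_class, seq, region_id) {
  if (!length(starts))
    return(data.frame(region_id = character(0), start = integer(0),
                      end = integer(0), motif_class = character(0),
                      strand_spelling = character(0),
                      stringsAsFactors = FALSE))
  data.frame(region_id = region_id, start = starts, end = starts + width,
             motif_class = motif_class,
             strand_spelling = substring(seq, starts + 1L, starts + width),
             stringsAsFactors = FALSE)
}

#' Scan a sequence for AID hotspot motifs (WRCY / RGYW)
#'
#' Every 4-mer is tested against both IUPAC consensus spellings
#' (W = A/T, R = A/G, Y = C/T).  Overlapping occurrences are all reported
#' and a 4-mer matching both consensi (e.g. AGCT) yields one occurrence per
#' class.  N never matches.
#'
#' @param seq DNA string over A/C/G/T/N.
#' @param region_id id copied into the output (default "seq").
#' @return data.frame with columns region_id, start, end (0-based half-open),
#'   motif_class, strand_spelling.
#' @export
scan_aid_hotspots <- function(seq, region_id = "seq") {
  seq <- toupper(seq); .check_dna(seq)
  wrcy <- .scan_pattern(seq, "[AT][AG]C[CT]")
  rgyw <- .scan_pattern(seq, "[AG]G[CT][AT]")
  out <- rbind(.motif_df(wrcy, 4L, "AID_WRCY", seq, region_id),
               .motif_df(rgyw, 4L, "AID_RGYW", seq, region_id))
  out[order(out$start, out$motif_class), , drop = FALSE]
}

#' Scan a sequence for APOBEC3 target sites (TC / GA)
#'
#' TC marks a target on the stored strand; GA is the opposite-strand TC.
#'
#' @inheritParams scan_aid_hotspots
#' @return data.frame as in [scan_aid_hotspots()] (intervals of width 2).
#' @export
scan_apobec3 <- function(seq, region_id = "seq") {
  seq <- toupper(seq); .check_dna(seq)
  tc <- .scan_pattern(seq, "TC")
  ga <- .scan_pattern(seq, "GA")
  out <- rbind(.motif_df(tc, 2L, "APOBEC3_TC", seq, region_id),
               .motif_df(ga, 2L, "APOBEC3_GA", seq, region_id))
  out[order(out$start, out$motif_class), , drop = FALSE]
}

#' Scan a reference region for all motif classes
#'
#' @param region an `lsr_region`.
#' @return data.frame combining [scan_aid_hotspots()] and [scan_apobec3()].
#' @export
scan_motifs <- function(region) {
  stopifnot(inherits(region, "lsr_region"))
  out <- rbind(scan_aid_hotspots(region$sequence, region$region_id),
               scan_apobec3(region$sequence, region$region_id))
  out[order(out$start, out$motif_class), , drop = FALSE]
}

#' Per-region feature summary
#'
#' Motif counts and densities plus strand G-richness; descriptive output
#' mirroring feature-track summaries of switch-like regions.
#'
#' @param region an `lsr_region`.
#' @param motifs motif data.frame for this region (default: rescan).
#' @param g4track optional result of [g4hunter_scores()] for this region.
#' @return one-row data.frame: region_id, length, per-class counts and
#'   densities, g_richness_stored/g_richness_opposite, n_g4_tracts.
#' @export
region_feature_summary <- function(region, motifs = scan_motifs(region),
                                   g4track = NULL) {
  stopifnot(inherits(region, "lsr_region"))
  if (nrow(motifs) && !all(motifs$region_id == region$region_id))
    stop("motif annotations do not belong to region '",
         region$region_id, "'", call. = FALSE)
  len <- nchar(region$sequence)
  counts <- vapply(MOTIF_CLASSES,
                   function(cl) sum(motifs$motif_class == cl), integer(1))
  bases <- table(factor(strsplit(region$sequence, "")[[1]],
                        levels = DNA_ALPHABET))
  out <- data.frame(region_id = region$region_id, length = len,
                    stringsAsFactors = FALSE)
  for (cl in MOTIF_CLASSES) {
    out[[paste0("n_", cl)]] <- counts[[cl]]
    out[[paste0("density_", cl)]] <- counts[[cl]] / len
  }
  out$g_richness_stored <- as.numeric(bases[["G"]]) / len
  out$g_richness_opposite <- as.numeric(bases[["C"]]) / len
  out$n_g4_tracts <- if (is.null(g4track)) NA_integer_ else nrow(g4track$tracts)
  out
}
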