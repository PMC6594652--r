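#' Build a synthetic switch-like reference region
#'
#' Tandem copies of a motif-bearing repeat unit with seeded point
#' divergence between copies, flanked by random sequence.  The repetitive
#' core is annotated as an `ls_interval` so breaks can be flagged in/out of
#' repeat.  Defaults emulate like-switch DNA: a G-rich unit carrying an
#' AGCT AID hotspot, 0.5-2 kb of repeats.
#'
#' @param length total region length in bp.
#' @param repeat_unit repeat unit sequence (must contain at least one AID
#'   hotspot for motif-targeted simulations to make sense).
#' @param seed RNG seed; identical arguments give byte-identical regions.
#' @param divergence per-base substitution rate applied to the tandem
#'   array (inter-repeat divergence).
#' @param flank length of random flanking sequence on each side.
#' @param region_id,role,locus_label passed to [lsr_region()].
#' @return an `lsr_region`.
#' @export
make_switch_like_region <- function(length = 1000L,
                                    repeat_unit = "GAGCTGAGCTGGGGTAGCTGGGGT",
                                    seed = 1L, divergence = 0.10,
                                    flank = 50L, region_id = "Slike",
                                    role = "donor", locus_label = "") {
  repeat_unit <- toupper(repeat_unit); .check_dna(repeat_unit, "repeat_unit")
  stopifnot(length > 2L * flank + nchar(repeat_unit))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  core_len <- length - 2L * flank
  ncopy <- ceiling(core_len / nchar(repeat_unit))
  core <- substr(strrep(repeat_unit, ncopy), 1L, core_len)
  ch <- strsplit(core, "", fixed = TRUE)[[1]]
  mut <- which(stats::runif(core_len) < divergence)
  for (i in mut)
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
  seq <- paste0(rand_dna(flank), paste(ch, collapse = ""), rand_dna(flank))
  lsr_region(region_id, seq, role = role, locus_label = locus_label,
             ls_intervals = matrix(c(flank, flank + core_len), nrow = 1L))
}

# save/restore global RNG state so region builders are reproducible without
# clobbering an enclosing simulation's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Example synthetic locus for demos and tests
#'
#' A donor Smu-like region, two acceptor 3'RR-like windows and one
#' intermediate Sgamma-like region, all built with
#' [make_switch_like_region()] under seeds derived from `seed`.  Distinct
#' repeat units keep cross-region homology low while every region stays
#' repetitive and hotspot-bearing.
#'
#' @param seed master seed.
#' @param n_acceptors 1 or 2 acceptor windows.
#' @param intermediate include the Sgamma-like intermediate region.
#' @return an `lsr_region_set`.
#' @export
example_region_set <- function(seed = 42L, n_acceptors = 2L,
                               intermediate = TRUE) {
  regs <- list(
    make_switch_like_region(1500L, "GAGCTGAGCTGGGGTAGCTGGGGT",
                            seed = .child_seed(seed, 1L), divergence = 0.10,
                            region_id = "Smu", role = "donor",
                            locus_label = "Smu-like donor"))
  if (n_acceptors >= 1L)
    regs <- c(regs, list(make_switch_like_region(
      1000L, "GGGCTGGGCTAGCTTTGGGGCTCA", seed = .child_seed(seed, 2L),
      divergence = 0.10, region_id = "RR1_hs4", role = "acceptor",
      locus_label = "3'RR1-like hs4 window")))
  if (n_acceptors >= 2L)
    regs <- c(regs, list(make_switch_like_region(
      1000L, "GGAGCTGTGGGGTTCAGGGCTGTA", seed = .child_seed(seed, 3L),
      divergence = 0.10, region_id = "RR2_hs4", role = "acceptor",
      locus_label = "3'RR2-like hs4 window")))
  if (intermediate)
    regs <- c(regs, list(make_switch_like_region(
      800L, "GGGGTACCAGGGCTAGCTACTGGG", seed = .child_seed(seed, 4L),
      divergence = 0.10, region_id = "Sg1", role = "intermediate",
      locus_label = "Sgamma1-like intermediate")))
  region_set(regs)
}

#' Simulation configuration
#'
#' The stated world of the generator.  Structure-mix and length defaults
#' follow the reported composition of suicide-recombination junction sets:
#' few blunt joins, microhomology-dominated, mean microhomology 4.1 bp and
#' mean insertion 4.9 bp, ~14 % complex post-switch junctions; reads are
#' 200 bp single-end with a substitution-only error model.
#'
#' @param seed master RNG seed.
#' @param n_junctions number of distinct truth junctions.
#' @param structure_mix named fractions for blunt / microhomology /
#'   insertion (must sum to 1).
#' @param mh_mean,ins_mean means of the truncated-geometric microhomology /
#'   insertion length distributions (bp).
#' @param mh_max,ins_max truncation bounds.
#' @param complex_fraction fraction of junctions routed through an
#'   intermediate switch remnant (requires an intermediate region).
#' @param placement `"uniform"` or `"motif_targeted"` break placement.
#' @param sigma s.d. (bp) of targeted breaks around AID motif centres.
#' @param clone_mean mean clone size (reads per junction, geometric).
#' @param read_length read length in bp.
#' @param error_rate per-base substitution error rate.
#' @param background_fraction fraction of emitted reads that are
#'   junction-free background.
#' @param revcomp_fraction fraction of reads emitted reverse-complemented.
#' @param flank_min,flank_max donor-flank length range within a read (bp).
#' @param acceptor_weights optional named sampling weights per acceptor.
#' @param primers optional [primer_pair()] appended to read ends.
#' @return list of class `lsr_sim_config`.
#' @export
sim_config <- function(seed = 1L, n_junctions = 200L,
                       structure_mix = c(blunt = 0.08, microhomology = 0.70,
                                         insertion = 0.22),
                       mh_mean = 4.1, ins_mean = 4.9, mh_max = 15L,
                       ins_max = 20L, complex_fraction = 0.14,
                       placement = c("uniform", "motif_targeted"),
                       sigma = 10, clone_mean = 5, read_length = 200L,
                       error_rate = 0, background_fraction = 0.1,
                       revcomp_fraction = 0, flank_min = 40L,
                       flank_max = 120L, acceptor_weights = NULL,
                       primers = NULL) {
  placement <- match.arg(placement)
  structure_mix <- structure_mix[c("blunt", "microhomology", "insertion")]
  if (anyNA(structure_mix) || abs(sum(structure_mix) - 1) > 1e-8)
    stop("structure_mix must give blunt/microhomology/insertion summing to 1",
         call. = FALSE)
  stopifnot(mh_mean >= 1, ins_mean >= 1, clone_mean >= 1,
            read_length >= 2L * flank_min,
            flank_max + 2L * ins_max + 40L <= read_length,
            error_rate >= 0, error_rate < 1,
            background_fraction >= 0, background_fraction < 1,
            complex_fraction >= 0, complex_fraction <= 1)
  structure(as.list(environment()), class = "lsr_sim_config")
}

.rgeom1 <- function(n, mean, max) {
  pmin(max, 1L + stats::rgeom(n, prob = 1 / mean))
}

.random_base_swap <- function(ch) {
  vapply(ch, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
}

.apply_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  k <- stats::rbinom(1L, n, rate)
  if (!k) return(seq)
  pos <- sample.int(n, k)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ch[pos] <- .random_base_swap(ch[pos])
  paste(ch, collapse = "")
}

# break placement: uniform inter-base position within [lo, hi], or normal
# jitter around the centre of a randomly chosen AID motif, clamped
.draw_break <- function(region, lo, hi, placement, sigma, motif_starts) {
  if (placement == "motif_targeted" && length(motif_starts)) {
    centre <- sample(motif_starts, 1L) + 2L
    b <- round(centre + stats::rnorm(1L, 0, sigma))
    return(as.integer(min(max(b, lo), hi)))
  }
  as.integer(.sample1(seq.int(lo, hi)))
}

# locate acceptor positions where `kmer` occurs (0-based starts)
.kmer_hits <- function(seq, kmer, lo, hi) {
  if (!nzchar(kmer)) return(integer(0))
  m <- gregexpr(kmer, seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  h <- as.integer(m) - 1L
  h[h >= lo & h <= hi]
}

#' Simulate junction-bearing amplicon reads with a truth table
#'
#' Per junction: breakpoints are drawn according to the placement mode, a
#' read is built as donor flank + (microhomology / blunt / insertion join)
#' + acceptor flank (complex junctions insert an intermediate switch
#' remnant), replicated per a geometric clone-size draw, subjected to
#' substitution errors and shuffled with junction-free background reads.
#' The truth table records the canonical breakpoint convention (maximal
#' perfect extension, microhomology at outer edges) actually realised by
#' each read, so accidental homology at a drawn breakpoint is folded into
#' the truth rather than mislabelling it.  Deterministic under the seed.
#'
#' @param config an [sim_config()].
#' @param regions an `lsr_region_set` with one donor, >= 1 acceptor and
#'   (for complex junctions) an intermediate region.
#' @return list of class `lsr_simulation`: `reads` (named character
#'   vector), `truth` (data.frame, one row per junction-bearing read),
#'   `n_reads`, `n_junction_reads`, `n_background`, `config`.
#' @export
simulate_reads <- function(config, regions) {
  stopifnot(inherits(config, "lsr_sim_config"),
            inherits(regions, "lsr_region_set"))
  set.seed(config$seed)
  roles <- vapply(regions, `[[`, character(1), "role")
  donor <- regions[[names(roles)[roles == "donor"][1]]]
  acc_ids <- names(roles)[roles == "acceptor"]
  int_ids <- names(roles)[roles == "intermediate"]
  if (!length(acc_ids)) stop("need at least one acceptor region", call. = FALSE)
  w <- if (is.null(config$acceptor_weights)) rep(1, length(acc_ids)) else
    config$acceptor_weights[acc_ids]
  aid_starts <- lapply(regions, function(r)
    scan_aid_hotspots(r$sequence, r$region_id)$start)

  rl <- config$read_length
  d_lo <- donor$amplifiable_interval[1] + config$flank_max
  d_hi <- donor$amplifiable_interval[2]
  if (d_lo >= d_hi) stop("donor region too short for the flank range",
                         call. = FALSE)
  truth <- vector("list", config$n_junctions)
  clone_sizes <- .rgeom1(config$n_junctions, config$clone_mean, 50L)
  reads <- character(0); read_names <- character(0)

  for (j in seq_len(config$n_junctions)) {
    acc <- regions[[acc_ids[sample.int(length(acc_ids), 1L, prob = w)]]]
    is_complex <- length(int_ids) > 0 &&
      stats::runif(1L) < config$complex_fraction
    mid <- if (is_complex) regions[[.sample1(int_ids)]] else NULL
    f <- if (is_complex) sample(40:60, 1L) else
      sample(config$flank_min:config$flank_max, 1L)
    db <- .draw_break(donor, d_lo, d_hi, config$placement, config$sigma,
                      aid_starts[[donor$region_id]])
    f <- min(f, db)

    char_at <- function(seq, p) substring(seq, p + 1L, p + 1L)  # 0-based
    draw_join <- function(left_seq, left_break, right_reg) {
      # returns list(m, ins, ab) joining left_seq@left_break to right_reg;
      # maximality guards ensure the requested structure is also the
      # canonical one (blunt joins cannot extend into accidental homology,
      # insertions extend neither flank, microhomologies are maximal)
      structure_cl <- sample(names(config$structure_mix), 1L,
                             prob = config$structure_mix)
      rs <- right_reg$sequence
      a_lo <- max(1L, right_reg$amplifiable_interval[1])
      a_hi <- max(a_lo, right_reg$amplifiable_interval[2] - rl - 1L)
      if (structure_cl == "microhomology") {
        m <- .rgeom1(1L, config$mh_mean, config$mh_max)
        repeat {
          kmer <- substr(left_seq, left_break - m + 1L, left_break)
          hits <- .kmer_hits(rs, kmer, a_lo, a_hi)
          # maximality: the shared stretch must extend on neither side
          if (length(hits)) {
            keep <- char_at(left_seq, left_break) != char_at(rs, hits + m) &
              char_at(left_seq, left_break - m - 1L) != char_at(rs, hits - 1L)
            hits <- hits[keep]
          }
          if (length(hits)) {
            ab <- if (config$placement == "motif_targeted" &&
                      length(aid_starts[[right_reg$region_id]])) {
              tgt <- .draw_break(right_reg, a_lo, a_hi, config$placement,
                                 config$sigma,
                                 aid_starts[[right_reg$region_id]])
              hits[which.min(abs(hits - tgt))]
            } else .sample1(hits)
            return(list(m = m, ins = "", ab = as.integer(ab)))
          }
          if (m == 1L) { structure_cl <- "blunt"; break }
          m <- m - 1L
        }
      }
      ab <- .draw_break(right_reg, a_lo, a_hi, config$placement,
                        config$sigma, aid_starts[[right_reg$region_id]])
      if (structure_cl == "blunt") {
        for (try in 1:50) {
          if (char_at(left_seq, left_break) != char_at(rs, ab) &&
              char_at(left_seq, left_break - 1L) != char_at(rs, ab - 1L))
            break
          ab <- .draw_break(right_reg, a_lo, a_hi, config$placement,
                            config$sigma, aid_starts[[right_reg$region_id]])
        }
        return(list(m = 0L, ins = "", ab = ab))
      }
      li <- .rgeom1(1L, config$ins_mean, config$ins_max)
      ins <- sample(c("A", "C", "G", "T"), li, replace = TRUE)
      # the inserted bases must extend neither flank
      avoid1 <- c(char_at(left_seq, left_break), if (li == 1L)
        char_at(rs, ab - 1L))
      ins[1] <- sample(setdiff(c("A", "C", "G", "T"), avoid1), 1L)
      if (li > 1L)
        ins[li] <- sample(setdiff(c("A", "C", "G", "T"),
                                  char_at(rs, ab - 1L)), 1L)
      list(m = 0L, ins = paste(ins, collapse = ""), ab = ab)
    }

    dflank <- substr(donor$sequence, db - f + 1L, db)
    if (is_complex) {
      j1 <- draw_join(donor$sequence, db, mid)
      mid_len <- sample(40:60, 1L)
      mid_start_emit <- j1$ab + j1$m
      mid_end <- mid_start_emit + mid_len
      midpart <- substr(mid$sequence, mid_start_emit + 1L, mid_end)
      j2 <- draw_join(mid$sequence, mid_end, acc)
      acc_emit_start <- j2$ab + j2$m
      used <- f + nchar(j1$ins) + mid_len + nchar(j2$ins)
      alen <- rl - used
      accpart <- substr(acc$sequence, acc_emit_start + 1L,
                        acc_emit_start + alen)
      core <- paste0(dflank, j1$ins, midpart, j2$ins, accpart)
      # canonical truth for both sub-junctions
      c1 <- .canonical_split(core, donor$sequence, mid$sequence,
                             de = f, dr = db,
                             as_ = f + nchar(j1$ins), ar = mid_start_emit)
      base2 <- f + nchar(j1$ins) + mid_len
      c2 <- .canonical_split(core, mid$sequence, acc$sequence,
                             de = base2, dr = mid_end,
                             as_ = base2 + nchar(j2$ins), ar = acc_emit_start)
      rec <- data.frame(
        clone_id = j, donor_region = donor$region_id,
        donor_break = c1$donor_break, acceptor_region = acc$region_id,
        acceptor_break = c2$acceptor_break, structure = c1$structure,
        mh_len = c1$mh_len, insertion_seq = c1$insertion_seq,
        junction_type = "complex", intermediate_region = mid$region_id,
        intermediate_start = c1$acceptor_break,
        intermediate_end = c2$donor_break, stringsAsFactors = FALSE)
    } else {
      j1 <- draw_join(donor$sequence, db, acc)
      acc_emit_start <- j1$ab + j1$m
      alen <- rl - f - nchar(j1$ins)
      accpart <- substr(acc$sequence, acc_emit_start + 1L,
                        acc_emit_start + alen)
      core <- paste0(dflank, j1$ins, accpart)
      c1 <- .canonical_split(core, donor$sequence, acc$sequence,
                             de = f, dr = db,
                             as_ = f + nchar(j1$ins), ar = acc_emit_start)
      rec <- data.frame(
        clone_id = j, donor_region = donor$region_id,
        donor_break = c1$donor_break, acceptor_region = acc$region_id,
        acceptor_break = c1$acceptor_break, structure = c1$structure,
        mh_len = c1$mh_len, insertion_seq = c1$insertion_seq,
        junction_type = "direct", intermediate_region = NA_character_,
        intermediate_start = NA_integer_, intermediate_end = NA_integer_,
        stringsAsFactors = FALSE)
    }
    if (!is.null(config$primers))
      core <- paste0(config$primers$forward_seq, core,
                     reverse_complement(config$primers$reverse_seq))
    nrep <- clone_sizes[j]
    recs <- rec[rep(1L, nrep), , drop = FALSE]
    recs$read_id <- sprintf("j%04d_c%03d", j, seq_len(nrep))
    emitted <- vapply(seq_len(nrep), function(k) {
      s <- .apply_errors(core, config$error_rate)
      if (stats::runif(1L) < config$revcomp_fraction) s <- reverse_complement(s)
      s
    }, "")
    reads <- c(reads, emitted)
    read_names <- c(read_names, recs$read_id)
    truth[[j]] <- recs
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  n_junc <- length(reads)

  bf <- config$background_fraction
  n_bg <- if (bf > 0) as.integer(round(bf / (1 - bf) * n_junc)) else 0L
  if (n_bg > 0) {
    all_ids <- names(regions)
    bg <- vapply(seq_len(n_bg), function(k) {
      if (stats::runif(1L) < 0.5) {
        r <- regions[[.sample1(all_ids)]]
        len <- nchar(r$sequence)
        st <- sample.int(max(1L, len - rl), 1L)
        .apply_errors(substr(r$sequence, st, min(len, st + rl - 1L)),
                      config$error_rate)
      } else {
        paste(sample(c("A", "C", "G", "T"), rl, replace = TRUE),
              collapse = "")
      }
    }, "")
    reads <- c(reads, bg)
    read_names <- c(read_names, sprintf("bg%05d", seq_len(n_bg)))
  }
  ord <- sample.int(length(reads))
  reads <- reads[ord]; names(reads) <- read_names[ord]
  structure(list(reads = reads, truth = truth, n_reads = length(reads),
                 n_junction_reads = n_junc, n_background = n_bg,
                 config = config),
            class = "lsr_simulation")
}

#' @export
print.lsr_simulation <- function(x, ...) {
  cat(sprintf(
    "<lsr_simulation> %d reads (%d junction-bearing from %d junctions, %d background), seed %d\n",
    x$n_reads, x$n_junction_reads, length(unique(x$truth$clone_id)),
    x$n_background, x$config$seed))
  invisible(x)
}

#' Simulate a dilution series
#'
#' Junction-bearing reads are thinned binomially at each dilution fraction
#' while background reads top the library back up to a constant total, as
#' when positive DNA is diluted into junction-free carrier DNA.  Seeds are
#' derived deterministically from the master seed.
#'
#' @param config an [sim_config()]; its `seed` is the master seed.
#' @param regions an `lsr_region_set`.
#' @param fractions dilution fractions (1 = undiluted).
#' @return list of per-fraction elements, each with `fraction`, `reads`,
#'   `truth`, `n_reads`.
#' @export
simulate_dilution_series <- function(config, regions,
                                     fractions = c(1, 0.5, 0.25, 0.1, 0)) {
  stopifnot(all(fractions >= 0 & fractions <= 1))
  base <- simulate_reads(config, regions)
  is_junc <- names(base$reads) %in% base$truth$read_id
  junc_reads <- base$reads[is_junc]
  rl <- config$read_length
  lapply(seq_along(fractions), function(i) {
    f <- fractions[i]
    set.seed(.child_seed(config$seed, i))
    keep <- stats::runif(length(junc_reads)) < f
    kept <- junc_reads[keep]
    n_fill <- base$n_reads - base$n_background - length(kept)
    fill <- if (n_fill > 0) {
      v <- vapply(seq_len(n_fill), function(k)
        paste(sample(c("A", "C", "G", "T"), rl, replace = TRUE),
              collapse = ""), "")
      names(v) <- sprintf("fill%05d", seq_len(n_fill))
      v
    } else character(0)
    reads <- c(kept, base$reads[!is_junc], fill)
    reads <- reads[sample.int(length(reads))]
    list(fraction = f, reads = reads,
         truth = base$truth[base$truth$read_id %in% names(kept), ,
                            drop = FALSE],
         n_reads = length(reads))
  })
}

#' Write simulated reads to FASTQ (constant quality) and the truth table
#' to TSV
#'
#' @param sim an `lsr_simulation`.
#' @param fastq_path,truth_path output paths.
#' @export
write_simulation <- function(sim, fastq_path, truth_path) {
  stopifnot(inherits(sim, "lsr_simulation"))
  write_fastq(sim$reads, fastq_path)
  utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fastq_path, truth_path))
}
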