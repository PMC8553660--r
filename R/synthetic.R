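# Seeded synthetic promoter and upstream-region generator.
#
# Background bases are i.i.d. with strand-symmetric probabilities set by a
# single AT fraction — the minimal model consistent with using GC%/AT% as
# the compositional covariate. A degenerate TATA(-like) motif can be
# planted near -28 with positional jitter, and every planted position is
# recorded as ground truth.

#' Organism composition presets
#'
#' AT fractions of the three model archaea: whole 1000-nt TSS-centered
#' windows (`hvo` 0.338, `tko` 0.493, `sso` 0.655) and -80..+20 cores
#' (`hvo_core` 0.400, `tko_core` 0.568, `sso_core` 0.711), each with its
#' organism's TATA-region motif.
#'
#' @format Data.frame with columns `preset`, `at_fraction`, `length`,
#'   `motif`.
#' @export
ORGANISM_PRESETS <- data.frame(
  preset = c("hvo", "tko", "sso", "hvo_core", "tko_core", "sso_core"),
  at_fraction = c(0.338, 0.493, 0.655, 0.400, 0.568, 0.711),
  length = c(1000L, 1000L, 1000L, 100L, 100L, 100L),
  motif = c("SYTTWWAA", "VYTTWWAA", "KVRWAAAVYTTWWWW",
            "SYTTWWAA", "VYTTWWAA", "KVRWAAAVYTTWWWW"),
  stringsAsFactors = FALSE
)

#' Specify a synthetic sequence set
#'
#' @param n Number of sequences.
#' @param length Sequence length in nt (even; the TSS sits at `length/2`
#'   so a 1000-nt record spans -500..+500).
#' @param at_fraction Target AT fraction in `[0, 1]`;
#'   `P(A) = P(T) = at_fraction / 2`.
#' @param motif Optional IUPAC pattern planted in a subset of sequences.
#' @param motif_center TSS-relative label of the motif midpoint (default
#'   -28, the canonical TATA position).
#' @param jitter Maximum absolute positional jitter in nt (default 2);
#'   the planted midpoint is `motif_center` plus a uniform draw from
#'   `-jitter..jitter`.
#' @param motif_probability Probability that a sequence carries the motif
#'   (default 0.5).
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @param preset Optional preset name from [ORGANISM_PRESETS] filling
#'   `at_fraction`, `length` and `motif`.
#' @param tss_index 0-based offset of the +1 base; defaults to
#'   `length / 2` (TSS-centered, requiring even length). The `*_core`
#'   presets place it at 80 so records are -80..+20 cores.
#' @param elements Optional list of additional planted core-promoter
#'   elements (see [promoter_elements()]); each is a list with `pattern`
#'   (IUPAC), `center` (label of the pattern midpoint), `jitter` and
#'   `probability`. Elements are planted before the TATA motif, which wins
#'   any overlap.
#' @return A validated `generator_spec` list.
#' @export
generator_spec <- function(n, length = 1000L, at_fraction = 0.5,
                           motif = NULL, motif_center = -28L, jitter = 2L,
                           motif_probability = 0.5, seed = 1L,
                           preset = NULL, tss_index = NULL,
                           elements = NULL) {
  if (!is.null(preset)) {
    row <- ORGANISM_PRESETS[ORGANISM_PRESETS$preset == preset, ]
    if (nrow(row) != 1L) {
      stop("unknown preset '", preset, "'; see ORGANISM_PRESETS",
           call. = FALSE)
    }
    at_fraction <- row$at_fraction
    length <- row$length
    if (is.null(motif)) motif <- row$motif
    if (is.null(tss_index) && length == 100L) tss_index <- 80L
  }
  length <- as.integer(length)
  if (is.null(tss_index)) {
    if (length %% 2L != 0L) {
      stop("TSS-centered generation needs an even length (no integer ",
           "center under the no-zero convention)", call. = FALSE)
    }
    tss_index <- length %/% 2L
  }
  tss_index <- as.integer(tss_index)
  stopifnot(n >= 0, length >= 2L,
            tss_index >= 0L, tss_index < length,
            at_fraction >= 0, at_fraction <= 1,
            jitter >= 0L, motif_probability >= 0, motif_probability <= 1,
            motif_center != 0L)
  spec <- list(n = as.integer(n), length = length,
               at_fraction = at_fraction, motif = motif,
               motif_center = as.integer(motif_center),
               jitter = as.integer(jitter),
               motif_probability = motif_probability,
               seed = as.integer(seed),
               tss_index = tss_index,
               organism = preset %||% "synthetic",
               elements = elements)
  check_fit <- function(pattern, center, jit, what) {
    sets <- expand_iupac(pattern)  # validates alphabet
    w <- length(sets)
    c_off <- label_to_offset(center, spec$tss_index)
    lo <- c_off - (ceiling(w / 2) - 1L) - jit
    hi <- c_off - (ceiling(w / 2) - 1L) + jit + w - 1L
    if (lo < 0L || hi >= length) {
      stop(what, " does not fit inside the sequence at all jittered ",
           "placements (offsets ", lo, "..", hi, ")", call. = FALSE)
    }
  }
  if (!is.null(motif)) {
    check_fit(motif, spec$motif_center, spec$jitter, "motif")
  }
  for (el in elements) {
    stopifnot(is.list(el), !is.null(el$pattern), !is.null(el$center))
    check_fit(el$pattern, el$center, el$jitter %||% 0L,
              paste0("element ", el$pattern))
  }
  structure(spec, class = "generator_spec")
}

#' Standard archaeal core-promoter elements for the generator
#'
#' The three elements that flank the TATA box in archaeal core promoters:
#' the BRE (two adenines immediately 5' of the TATA region, around
#' -34/-33), the AT-rich PPE near -10 (TFE contact) and a
#' pyrimidine-purine initiator straddling the TSS. Passed as
#' `elements` to [generator_spec()] they give synthetic promoters the full
#' architecture that real TSS-aligned profiles show, rather than a TATA
#' bump alone.
#'
#' @param bre,ppe,inr IUPAC patterns for the three elements (set one to
#'   `NULL` to drop it).
#' @return A list of element descriptors for [generator_spec()].
#' @export
promoter_elements <- function(bre = "AA", ppe = "WWWW", inr = "YR") {
  els <- list()
  if (!is.null(bre)) {
    els$bre <- list(pattern = bre, center = -34L, jitter = 1L,
                    probability = 1)
  }
  if (!is.null(ppe)) {
    els$ppe <- list(pattern = ppe, center = -11L, jitter = 2L,
                    probability = 1)
  }
  if (!is.null(inr)) {
    els$inr <- list(pattern = inr, center = -1L, jitter = 0L,
                    probability = 1)
  }
  els
}

sample_background <- function(length, at_fraction) {
  paste(sample(c("A", "T", "C", "G"), length, replace = TRUE,
               prob = c(at_fraction / 2, at_fraction / 2,
                        (1 - at_fraction) / 2, (1 - at_fraction) / 2)),
        collapse = "")
}

sample_motif <- function(sets) {
  paste(vapply(sets, function(s) s[sample.int(length(s), 1L)], ""),
        collapse = "")
}

# Plant a concrete expansion of an IUPAC pattern (midpoint at `center`
# plus uniform jitter) into seq; returns seq plus the realized placement.
plant_pattern <- function(seq, sets, center, jitter, tss_index) {
  w <- length(sets)
  c_off <- label_to_offset(center, tss_index)
  j <- if (jitter > 0L) {
    sample.int(2L * jitter + 1L, 1L) - jitter - 1L
  } else {
    0L
  }
  start <- c_off - (ceiling(w / 2) - 1L) + j
  realized <- sample_motif(sets)
  substr(seq, start + 1L, start + w) <- realized
  list(sequence = seq, start_offset = start, motif_seq = realized)
}

# Plant the optional architecture elements, then (with probability
# motif_probability) the TATA motif; the motif overwrites any overlap.
plant_all <- function(seq, spec, motif_sets) {
  for (el in spec$elements) {
    if (stats::runif(1) <= (el$probability %||% 1)) {
      seq <- plant_pattern(seq, expand_iupac(el$pattern), el$center,
                           el$jitter %||% 0L, spec$tss_index)$sequence
    }
  }
  planted <- !is.null(motif_sets) && stats::runif(1) < spec$motif_probability
  if (planted) {
    p <- plant_pattern(seq, motif_sets, spec$motif_center, spec$jitter,
                       spec$tss_index)
    list(sequence = p$sequence, planted = TRUE,
         start_offset = p$start_offset, motif_seq = p$motif_seq)
  } else {
    list(sequence = seq, planted = FALSE, start_offset = NA_integer_,
         motif_seq = NA_character_)
  }
}

#' Generate a synthetic TSS-centered promoter set
#'
#' @param spec A [generator_spec()].
#' @return A list with `records` (list of [tss_sequence()]) and `truth`
#'   (data.frame: `id`, `has_motif`, `motif_start_offset`,
#'   `motif_start_label`, `motif_seq`).
#' @export
gen_promoters <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  sets <- if (!is.null(spec$motif)) expand_iupac(spec$motif)
  with_seed(spec$seed, {
    records <- vector("list", spec$n)
    truth <- data.frame(id = character(spec$n),
                        has_motif = logical(spec$n),
                        motif_start_offset = rep(NA_integer_, spec$n),
                        motif_start_label = rep(NA_integer_, spec$n),
                        motif_seq = rep(NA_character_, spec$n),
                        stringsAsFactors = FALSE)
    for (i in seq_len(spec$n)) {
      id <- sprintf("syn_%05d", i)
      seq <- sample_background(spec$length, spec$at_fraction)
      p <- plant_all(seq, spec, sets)
      if (p$planted) {
        truth$motif_start_offset[i] <- p$start_offset
        truth$motif_start_label[i] <- position_label(p$start_offset,
                                                     spec$tss_index)
        truth$motif_seq[i] <- p$motif_seq
      }
      truth$id[i] <- id
      truth$has_motif[i] <- p$planted
      records[[i]] <- tss_sequence(id, p$sequence, spec$tss_index,
                                   spec$organism)
    }
    list(records = records, truth = truth, spec = spec)
  })
}

#' Generate synthetic upstream regions (plain sequences)
#'
#' Emulates gene-upstream windows with, optionally, a promoter-like 100-nt
#' core (generated under the same composition/motif model) inserted so its
#' +20 edge coincides with the 3' end — the configuration in which real
#' upstream sets show promoter-like signal at the end of the region.
#'
#' @param spec A [generator_spec()] for the background (`length` >= 104).
#' @param insert_at_end Insert the promoter-like segment (default `TRUE`);
#'   `FALSE` gives pure background for null calibration.
#' @param insert_spec Optional [generator_spec()] for the inserted core
#'   (its `at_fraction`, `motif`, `motif_center`, `jitter` and
#'   `motif_probability` drive the insert). Defaults to `spec` itself, but
#'   real core promoters are more AT-rich than the surrounding upstream
#'   bulk, so passing a core preset here emulates that contrast.
#' @param core_upstream,core_downstream Geometry of the inserted core
#'   (default 80/20).
#' @return A list with `sequences` (named character vector) and `truth`
#'   (data.frame: `id`, `insert_start_offset`, `has_motif`).
#' @export
gen_upstream <- function(spec, insert_at_end = TRUE, insert_spec = NULL,
                         core_upstream = 80L, core_downstream = 20L) {
  stopifnot(inherits(spec, "generator_spec"))
  width <- core_upstream + core_downstream
  if (spec$length < width + 4L) {
    stop("upstream length must be at least ", width + 4L, " nt",
         call. = FALSE)
  }
  core_spec <- insert_spec %||% spec
  core_spec$length <- width
  core_spec$tss_index <- core_upstream
  sets <- if (!is.null(core_spec$motif)) expand_iupac(core_spec$motif)
  with_seed(spec$seed + 1L, {
    seqs <- character(spec$n)
    truth <- data.frame(id = sprintf("ups_%05d", seq_len(spec$n)),
                        insert_start_offset = rep(NA_integer_, spec$n),
                        has_motif = logical(spec$n),
                        stringsAsFactors = FALSE)
    for (i in seq_len(spec$n)) {
      seq <- sample_background(spec$length, spec$at_fraction)
      if (insert_at_end) {
        core <- sample_background(width, core_spec$at_fraction)
        p <- plant_all(core, core_spec, sets)
        start <- spec$length - width
        substr(seq, start + 1L, spec$length) <- p$sequence
        truth$insert_start_offset[i] <- start
        truth$has_motif[i] <- p$planted
      }
      seqs[i] <- seq
    }
    names(seqs) <- truth$id
    list(sequences = seqs, truth = truth, spec = spec)
  })
}
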