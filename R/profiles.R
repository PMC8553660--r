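# Per-position structural profiles on the TSS-relative axis.
#
# Dinucleotide features are anchored to the 5' base of each step, so a
# length-n record yields n-1 values; pentamer curvature is anchored to the
# center base, yielding n-4 values. Windows containing N give NA.

#' Encode a sequence into a per-position structural profile
#'
#' With a [step_table()], position `p` carries the table value of the 2-mer
#' starting at `p` (one-nucleotide sliding window over the `n - 1` steps).
#' With a [pentamer_table()], position `p` carries the curvature of the
#' 5-mer centered at `p` (positions 3..n-2 of the record). Any window
#' containing an ambiguous base encodes as `NA`.
#'
#' @param rec A [tss_sequence()].
#' @param table A `step_table` or `pentamer_table`.
#' @return A `profile` object: list with `id`, `feature`, `positions`
#'   (TSS-relative labels, strictly increasing, no zero) and `values`.
#' @export
encode_sequence <- function(rec, table) {
  n <- nchar(rec$sequence)
  labels <- sequence_labels(rec)
  if (inherits(table, "pentamer_table")) {
    if (n < 5L) stop("record '", rec$id, "' shorter than one pentamer",
                     call. = FALSE)
    kmers <- substring(rec$sequence, 1:(n - 4L), 5:n)
    values <- as.numeric(table)[match(kmers, names(table))]
    positions <- labels[3:(n - 2L)]
  } else if (inherits(table, "step_table")) {
    if (n < 2L) stop("record '", rec$id, "' shorter than one step",
                     call. = FALSE)
    kmers <- substring(rec$sequence, 1:(n - 1L), 2:n)
    values <- as.numeric(table)[match(kmers, names(table))]
    positions <- labels[seq_len(n - 1L)]
  } else {
    stop("table must be a step_table or pentamer_table", call. = FALSE)
  }
  new_profile(rec$id, attr(table, "feature"), positions, values)
}

new_profile <- function(id, feature, positions, values) {
  stopifnot(length(positions) == length(values),
            !is.unsorted(positions, strictly = TRUE), all(positions != 0L))
  structure(list(id = id, feature = feature,
                 positions = as.integer(positions),
                 values = as.numeric(values)),
            class = "profile")
}

#' @export
print.profile <- function(x, ...) {
  cat(sprintf("<profile> %s: %s over %d positions (%+d..%+d), %d missing\n",
              x$id, x$feature, length(x$positions), min(x$positions),
              max(x$positions), sum(is.na(x$values))))
  invisible(x)
}

#' Total duplex free energy of a sequence
#'
#' Sum of the nearest-neighbor stability contributions over all
#' dinucleotide steps (kcal/mol); equals the sum of the encoded stability
#' profile.
#'
#' @param rec A [tss_sequence()] (or plain DNA string) without `N`.
#' @param table Stability step table (packaged table by default).
#' @return Free energy in kcal/mol.
#' @export
total_free_energy <- function(rec, table = load_step_table("stability")) {
  if (is.character(rec)) rec <- tss_sequence("seq", rec, 0L)
  if (grepl("N", rec$sequence, fixed = TRUE)) {
    stop("record '", rec$id,
         "': ambiguous bases; total free energy undefined", call. = FALSE)
  }
  sum(encode_sequence(rec, table)$values)
}

#' Average profiles position-by-position across a set
#'
#' Profiles are aligned on their TSS-relative labels; the mean at each label
#' is taken over the non-missing contributions and the per-position count is
#' recorded, so edge effects and N-windows remain visible.
#'
#' @param profiles List of [encode_sequence()] outputs sharing one feature.
#' @return A `mean_profile`: list with `feature`, `positions`,
#'   `mean_values` (NA where no profile contributes) and `n_contributing`.
#' @export
mean_profile <- function(profiles) {
  if (length(profiles) == 0L) stop("no profiles to average", call. = FALSE)
  features <- unique(vapply(profiles, `[[`, "", "feature"))
  if (length(features) != 1L) {
    stop("profiles mix features: ", paste(features, collapse = ", "),
         call. = FALSE)
  }
  positions <- sort(unique(unlist(lapply(profiles, `[[`, "positions"))))
  sums <- numeric(length(positions))
  counts <- integer(length(positions))
  for (p in profiles) {
    idx <- match(p$positions, positions)
    ok <- !is.na(p$values)
    sums[idx[ok]] <- sums[idx[ok]] + p$values[ok]
    counts[idx[ok]] <- counts[idx[ok]] + 1L
  }
  structure(list(feature = features,
                 positions = positions,
                 mean_values = ifelse(counts > 0L, sums / pmax(counts, 1L),
                                      NA_real_),
                 n_contributing = counts),
            class = "mean_profile")
}

#' @export
print.mean_profile <- function(x, ...) {
  cat(sprintf(
    "<mean_profile> %s over %d positions (%+d..%+d), n up to %d\n",
    x$feature, length(x$positions), min(x$positions), max(x$positions),
    max(x$n_contributing)))
  invisible(x)
}

#' Encode a set of records and average per position
#'
#' Convenience wrapper: encode every record with `table` and return the
#' TSS-aligned [mean_profile()].
#'
#' @param records List of [tss_sequence()] objects.
#' @inheritParams encode_sequence
#' @export
encode_set <- function(records, table) {
  mean_profile(lapply(records, encode_sequence, table = table))
}

# Resolve feature names to lookup tables; `curvature` builds (once per call
# chain) the pentamer table from the packaged wedges unless overridden.
feature_tables <- function(features, pentamers = NULL) {
  stopifnot(length(features) >= 1L)
  lapply(stats::setNames(features, features), function(f) {
    if (f == "curvature") pentamers %||% build_pentamer_table()
    else load_step_table(f)
  })
}
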