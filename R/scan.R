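# Promoter-like reference profile and sliding-window structural scanning.
#
# The reference is the per-position mean of each structural feature over
# validated (or synthetic) core promoters. A candidate sequence is scanned
# by sliding a core-sized window and correlating its per-feature encoding
# with the reference; Pearson correlation makes features with different
# units combinable without scaling constants. Significance is judged
# against shuffled versions of the same sequence.

#' Build the promoter-like reference profile
#'
#' Per-feature mean across all sequences of all contributing sets, each
#' sequence weighted equally (the pooled-promoter convention); set
#' `per_set_weighting = TRUE` to average per-set means instead.
#'
#' @param sets A list of core-promoter sets (each a list of
#'   [tss_sequence()] objects), or a single such set; names label the
#'   provenance.
#' @param features Character vector over
#'   `{stability, enthalpy, bendability, curvature}`.
#' @param pentamers Optional [pentamer_table()] overriding the wedge-derived
#'   curvature lookup.
#' @param upstream,downstream Core window extent (defaults 80/20 nt).
#' @param per_set_weighting Weight each set, rather than each sequence,
#'   equally.
#' @return A `reference_profile`: per-feature [mean_profile()]s plus
#'   provenance.
#' @export
build_reference <- function(sets, features = c("stability", "enthalpy",
                                               "bendability", "curvature"),
                            pentamers = NULL, upstream = 80L,
                            downstream = 20L, per_set_weighting = FALSE) {
  if (length(features) == 0L) stop("empty feature list", call. = FALSE)
  if (length(sets) && inherits(sets[[1]], "tss_sequence")) sets <- list(sets)
  if (!length(sets) || !sum(lengths(sets))) {
    stop("no contributing sequences", call. = FALSE)
  }
  width <- upstream + downstream
  for (s in sets) for (rec in s) {
    if (nchar(rec$sequence) != width || rec$tss_index != upstream) {
      stop("record '", rec$id, "' is not a -", upstream, "..+", downstream,
           " core (length ", nchar(rec$sequence), ", TSS offset ",
           rec$tss_index, ")", call. = FALSE)
    }
  }
  tables <- feature_tables(features, pentamers)
  profiles <- lapply(tables, function(tab) {
    if (per_set_weighting) {
      per_set <- lapply(sets, encode_set, table = tab)
      pos <- per_set[[1]]$positions
      vals <- rowMeans(vapply(per_set, function(m) m$mean_values,
                              numeric(length(pos))))
      structure(list(feature = attr(tab, "feature"), positions = pos,
                     mean_values = vals,
                     n_contributing = rep(length(sets), length(pos))),
                class = "mean_profile")
    } else {
      encode_set(unlist(sets, recursive = FALSE), tab)
    }
  })
  structure(list(features = profiles,
                 provenance = names(sets) %||%
                   paste0("set", seq_along(sets)),
                 upstream = as.integer(upstream),
                 downstream = as.integer(downstream),
                 tables = tables),
            class = "reference_profile")
}

#' @export
print.reference_profile <- function(x, ...) {
  cat(sprintf(
    "<reference_profile> -%d..+%d core, features: %s; sets: %s\n",
    x$upstream, x$downstream, paste(names(x$features), collapse = ", "),
    paste(x$provenance, collapse = ", ")))
  invisible(x)
}

# Encode a plain sequence string into per-feature value vectors; value i of
# a vector sits at sequence offset anchor + i - 1 (anchor 0 for step
# features, 2 for the pentamer center).
encode_values <- function(seqstring, table) {
  n <- nchar(seqstring)
  if (inherits(table, "pentamer_table")) {
    kmers <- substring(seqstring, 1:(n - 4L), 5:n)
  } else {
    kmers <- substring(seqstring, 1:(n - 1L), 2:n)
  }
  as.numeric(table)[match(kmers, names(table))]
}

# Pearson correlation of a fixed reference vector against every length-len
# window of v (windows advance one position at a time). Fast closed form
# via rolling sums when both sides are complete; pairwise-complete loop
# otherwise. Windows with fewer than min_n usable pairs give NA.
sliding_correlation <- function(v, r, min_n = 50L) {
  len <- length(r)
  nx <- length(v) - len + 1L
  if (nx < 1L) stop("sequence shorter than the reference window",
                    call. = FALSE)
  if (!anyNA(v) && !anyNA(r)) {
    mr <- mean(r)
    ssr <- sum((r - mr)^2)
    cs1 <- cumsum(c(0, v))
    cs2 <- cumsum(c(0, v * v))
    s1 <- cs1[(len + 1L):(length(v) + 1L)] - cs1[seq_len(nx)]
    s2 <- cs2[(len + 1L):(length(v) + 1L)] - cs2[seq_len(nx)]
    sxr <- stats::filter(v, rev(r), sides = 1)[len:length(v)]
    den2 <- (s2 - s1^2 / len) * ssr
    out <- ifelse(den2 > 1e-12, (sxr - s1 * mr) / sqrt(pmax(den2, 1e-300)),
                  NA_real_)
    return(as.numeric(out))
  }
  vapply(seq_len(nx), function(s) {
    w <- v[s:(s + len - 1L)]
    ok <- !is.na(w) & !is.na(r)
    if (sum(ok) < min_n || stats::sd(w[ok]) == 0 || stats::sd(r[ok]) == 0) {
      return(NA_real_)
    }
    stats::cor(w[ok], r[ok])
  }, numeric(1))
}

# Per-offset combined similarity of every core-sized window of seqstring
# against the reference; returns matrix (offsets x features) plus the
# combined row means.
scan_scores <- function(seqstring, ref) {
  per_feature <- lapply(names(ref$features), function(f) {
    r <- ref$features[[f]]$mean_values
    v <- encode_values(seqstring, ref$tables[[f]])
    sliding_correlation(v, r)
  })
  mat <- do.call(cbind, per_feature)
  colnames(mat) <- names(ref$features)
  mat
}

#' Scan a sequence for promoter-like structural signal
#'
#' Slides a core-sized (default 100 nt) window along the sequence, encodes
#' each window with every reference feature and scores it by the Pearson
#' correlation with the reference profile; the combined score is the mean
#' of the feature correlations. The best window is compared against the
#' best scores of shuffled versions of the same sequence (its own
#' composition-matched null), yielding a z-score.
#'
#' @param sequence A plain DNA string or [tss_sequence()].
#' @param ref A [build_reference()] result.
#' @param null_draws Number of shuffled null sequences (default 100).
#' @param seed Integer seed for the null draws.
#' @param id Identifier carried into the result.
#' @details The null distribution of a best-of-all-windows score is
#'   extreme-value shaped, so a plain standard score against the null
#'   maxima is anticonservative in its right tail. As in common motif
#'   scanners, the null best scores are therefore summarized by a Gumbel
#'   fit (method of moments) and `z` is the normal quantile of the fitted
#'   tail probability of the observed best score: under the null `z` is
#'   approximately standard normal, including its tail. The uncalibrated
#'   standard score is kept as `z_raw`.
#' @return A `scan_hit`: list with `id`, `offset` (0-based start of the
#'   best window), `tss_offset` (implied TSS position), `score`,
#'   `feature_scores`, `z`, `z_raw`, `null_mean`, `null_sd`.
#' @export
scan_region <- function(sequence, ref, null_draws = 100L, seed = 1L,
                        id = "region") {
  if (inherits(sequence, "tss_sequence")) {
    id <- sequence$id
    sequence <- sequence$sequence
  }
  sequence <- toupper(sequence)
  width <- ref$upstream + ref$downstream
  if (nchar(sequence) < width + 4L) {
    stop("sequence '", id, "' shorter than ", width + 4L,
         " nt; cannot scan", call. = FALSE)
  }
  mat <- scan_scores(sequence, ref)
  combined <- rowMeans(mat, na.rm = TRUE)
  combined[!is.finite(combined)] <- NA_real_
  if (all(is.na(combined))) {
    stop("no scorable window in '", id, "'", call. = FALSE)
  }
  best <- which.max(combined)
  null_best <- if (null_draws > 0L) {
    chars <- strsplit(sequence, "")[[1]]
    vapply(seq_len(null_draws), function(d) {
      shuf <- with_seed(as.integer(seed) + d, paste(sample(chars),
                                                    collapse = ""))
      cmb <- rowMeans(scan_scores(shuf, ref), na.rm = TRUE)
      max(cmb[is.finite(cmb)], na.rm = TRUE)
    }, numeric(1))
  } else {
    numeric(0)
  }
  null_mean <- if (length(null_best)) mean(null_best) else NA_real_
  null_sd <- if (length(null_best) > 1L) stats::sd(null_best) else NA_real_
  z_raw <- z <- NA_real_
  if (!is.na(null_sd) && null_sd > 0) {
    z_raw <- (combined[best] - null_mean) / null_sd
    # Gumbel moment fit of the null maxima; z is the normal quantile of
    # the fitted upper-tail probability
    beta <- null_sd * sqrt(6) / pi
    mu <- null_mean - 0.5772156649 * beta
    p_upper <- -expm1(-exp(-(combined[best] - mu) / beta))
    p_upper <- min(max(p_upper, 1e-15), 1 - 1e-15)
    z <- stats::qnorm(p_upper, lower.tail = FALSE)
  }
  structure(list(id = id, offset = best - 1L,
                 tss_offset = best - 1L + ref$upstream,
                 score = combined[best],
                 feature_scores = mat[best, ],
                 z = z, z_raw = z_raw,
                 null_mean = null_mean, null_sd = null_sd),
            class = "scan_hit")
}

#' @export
print.scan_hit <- function(x, ...) {
  cat(sprintf(
    "<scan_hit> %s: best window at offset %d (TSS ~%d), score %.3f, z %.2f\n",
    x$id, x$offset, x$tss_offset, x$score,
    if (is.na(x$z)) NA_real_ else x$z))
  invisible(x)
}

#' Compare candidate mean profiles against the reference
#'
#' For each candidate set the per-position value distributions (reference
#' vs candidate, matched on the feature) are compared by the two-group
#' Kruskal-Wallis test, the rank analogue of the boxplot comparison of
#' pooled per-position values.
#'
#' @param ref A [build_reference()] result.
#' @param candidate_sets List of [mean_profile()]s (features must exist in
#'   the reference; coordinate ranges must match).
#' @return A list of `test_result`, one per candidate, in input order.
#' @export
compare_group_profiles <- function(ref, candidate_sets) {
  if (inherits(candidate_sets, "mean_profile")) {
    candidate_sets <- list(candidate_sets)
  }
  lapply(candidate_sets, function(cand) {
    rf <- ref$features[[cand$feature]]
    if (is.null(rf)) {
      stop("reference lacks feature '", cand$feature, "'", call. = FALSE)
    }
    if (!identical(rf$positions, cand$positions)) {
      stop("coordinate range mismatch between reference and candidate (",
           cand$feature, ")", call. = FALSE)
    }
    ok <- !is.na(rf$mean_values) & !is.na(cand$mean_values)
    kruskal_test(list(reference = rf$mean_values[ok],
                      candidate = cand$mean_values[ok]))
  })
}
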