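# BMHT-style intrinsic curvature: planar wedge-vector-sum model.
#
# Each dinucleotide step deflects the helical axis by its (roll, tilt) wedge
# vector; successive steps are rotated in the plane by the accumulated twist.
# Curvature of a window is the magnitude of the vector sum divided by the
# number of steps (degrees per step).

#' Rotate a wedge vector by the accumulated helical twist
#'
#' @param roll,tilt Wedge components in degrees.
#' @param cumulative_twist Sum of the twist angles of all preceding steps
#'   (degrees).
#' @return Numeric length-2 vector (planar deflection); its magnitude is
#'   `sqrt(roll^2 + tilt^2)` whatever the twist.
#' @export
step_deflection <- function(roll, tilt, cumulative_twist) {
  theta <- cumulative_twist * pi / 180
  c(roll * cos(theta) - tilt * sin(theta),
    roll * sin(theta) + tilt * cos(theta))
}

#' Intrinsic curvature of a DNA window
#'
#' Sums the twist-rotated wedge vectors of the `len - 1` steps of `kmer` and
#' normalizes by the step count, giving degrees per step. A constant offset
#' on the starting twist phase rotates the whole sum and leaves the
#' magnitude unchanged.
#'
#' @param kmer Character scalar over `{A,C,G,T}`, length >= 2.
#' @param wedges A [wedge_table()].
#' @param phase Starting twist phase in degrees (default 0).
#' @return Non-negative curvature in degrees per step; `NA` if the window
#'   contains an ambiguous base.
#' @export
window_curvature <- function(kmer, wedges, phase = 0) {
  kmer <- toupper(kmer)
  n <- nchar(kmer)
  stopifnot(n >= 2L)
  steps <- substring(kmer, 1:(n - 1L), 2:n)
  idx <- match(steps, rownames(wedges))
  if (anyNA(idx)) return(NA_real_)
  cum_twist <- c(0, cumsum(wedges$twist[idx]))[seq_len(n - 1L)] + phase
  v <- complex(real = wedges$roll[idx], imaginary = wedges$tilt[idx]) *
    exp(1i * cum_twist * pi / 180)
  Mod(sum(v)) / (n - 1L)
}

#' Build the 1024-entry pentamer curvature lookup
#'
#' Enumerates all 4^5 pentanucleotides and evaluates [window_curvature()]
#' on each, producing the lookup used by the profile encoder.
#'
#' @param wedges A [wedge_table()]; defaults to the packaged BMHT angles.
#' @return A `pentamer_table`: named numeric vector of length 1024 with a
#'   `provenance` attribute (`"computed-from-wedges"`).
#' @export
build_pentamer_table <- function(wedges = load_wedge_table()) {
  bases <- c("A", "C", "G", "T")
  pent <- do.call(paste0, rev(expand.grid(bases, bases, bases, bases, bases,
                                          stringsAsFactors = FALSE)))
  pent <- sort(pent)
  values <- vapply(pent, window_curvature, numeric(1), wedges = wedges)
  pentamer_table(values, provenance = "computed-from-wedges")
}

#' Construct and validate a pentamer curvature table
#'
#' @param values Named numeric vector: curvature (degrees per step) for all
#'   1024 pentamers over `{A,C,G,T}`.
#' @param provenance `"computed-from-wedges"` or `"user-supplied"`.
#' @return A validated `pentamer_table`.
#' @export
pentamer_table <- function(values, provenance = "user-supplied") {
  if (!is.numeric(values) || is.null(names(values))) {
    stop("pentamer table must be a named numeric vector", call. = FALSE)
  }
  if (length(values) != 1024L || anyDuplicated(names(values))) {
    stop("pentamer table must have exactly 1024 distinct 5-mers (got ",
         length(values), ")", call. = FALSE)
  }
  if (any(!grepl("^[ACGT]{5}$", names(values)))) {
    stop("pentamer table keys must be 5-mers over {A,C,G,T}", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("curvature values must be finite and non-negative", call. = FALSE)
  }
  values <- values[sort(names(values))]
  structure(values, feature = "curvature", units = "degrees/step",
            provenance = provenance,
            class = c("pentamer_table", "numeric"))
}

#' Read / write a pentamer curvature table (TSV: pentamer, curvature)
#'
#' Accepts precomputed lookup files (one 5-mer and one value per row), which
#' then override the wedge-derived table wherever a curvature encoding is
#' requested.
#'
#' @param path File path.
#' @rdname pentamer_table_io
#' @export
read_pentamer_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop("pentamer table file needs two columns (pentamer, curvature)",
         call. = FALSE)
  }
  pentamer_table(stats::setNames(as.numeric(df[[2L]]), toupper(df[[1L]])),
                 provenance = "user-supplied")
}

#' @param table A `pentamer_table`.
#' @rdname pentamer_table_io
#' @export
write_pentamer_table <- function(table, path) {
  utils::write.table(
    data.frame(pentamer = names(table), curvature = as.numeric(table)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
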