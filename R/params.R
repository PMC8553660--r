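# Packaged parameter tables (dinucleotide properties, BMHT wedge angles) and
# the IUPAC degenerate alphabet.

ALL_STEPS <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                             paste0))

#' IUPAC degenerate nucleotide alphabet
#'
#' Named list mapping each IUPAC code to the set of concrete bases it allows,
#' e.g. `W` = A/T, `S` = G/C, `V` = A/C/G.
#'
#' @format A named list of character vectors over `{A,C,G,T}`.
#' @export
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

step_complement <- function(step) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(step, ""), function(x) paste(rev(x), collapse = ""),
                ""))
}

#' Load a packaged dinucleotide property table
#'
#' Returns one of the three dinucleotide-step scales used by the encoders:
#' nearest-neighbor melting `enthalpy` (kcal/mol-bp), duplex `stability`
#' free energy (kcal/mol-bp), or protein-induced `bendability` (degrees).
#' Values are shipped verbatim in
#' `inst/extdata/dinucleotide_properties.tsv`; asymmetric complement pairs
#' present in the source scale are kept as-is (see [validate_step_table()]).
#'
#' @param feature_name One of `"enthalpy"`, `"stability"`, `"bendability"`.
#' @return A `step_table` object: a named numeric vector of length 16
#'   (names are the dinucleotide steps) with attributes `feature` and
#'   `units`.
#' @examples
#' load_step_table("bendability")[["TA"]]  # 6.74 degrees
#' @export
load_step_table <- function(feature_name) {
  features <- c(enthalpy = "kcal/mol-bp", stability = "kcal/mol-bp",
                bendability = "degrees")
  if (length(feature_name) != 1L || !feature_name %in% names(features)) {
    stop("unknown structural feature '", paste(feature_name, collapse = ","),
         "'; expected one of: ", paste(names(features), collapse = ", "),
         call. = FALSE)
  }
  path <- system.file("extdata", "dinucleotide_properties.tsv",
                      package = "promstruct", mustWork = TRUE)
  raw <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  values <- stats::setNames(raw[[feature_name]], raw$step)
  step_table(values, feature = feature_name,
             units = features[[feature_name]])
}

#' Construct and validate a dinucleotide step table
#'
#' @param values Named numeric vector: one value per dinucleotide step.
#' @param feature Feature label (`enthalpy`, `stability` or `bendability`).
#' @param units Unit string carried for display.
#' @param warn_asymmetry Warn when a step and its reverse complement carry
#'   different values (the packaged scales contain such pairs; they are
#'   reported but never altered).
#' @return A validated `step_table`.
#' @export
step_table <- function(values, feature, units,
                       warn_asymmetry = FALSE) {
  if (!is.numeric(values) || is.null(names(values))) {
    stop("step table values must be a named numeric vector", call. = FALSE)
  }
  if (anyDuplicated(names(values))) {
    stop("duplicate dinucleotide steps in table", call. = FALSE)
  }
  missing <- setdiff(ALL_STEPS, names(values))
  extra <- setdiff(names(values), ALL_STEPS)
  if (length(missing) || length(extra)) {
    stop("step table must cover exactly the 16 dinucleotides; missing: [",
         paste(missing, collapse = ","), "] unexpected: [",
         paste(extra, collapse = ","), "]", call. = FALSE)
  }
  values <- values[ALL_STEPS]
  if (any(!is.finite(values))) {
    stop("non-finite value in step table", call. = FALSE)
  }
  if (feature %in% c("enthalpy", "stability") && any(values >= 0)) {
    stop(feature, " values must be negative (free-energy release)",
         call. = FALSE)
  }
  if (feature == "bendability" && any(values <= 0)) {
    stop("bendability values must be positive angles", call. = FALSE)
  }
  if (warn_asymmetry) {
    comp <- step_complement(ALL_STEPS)
    bad <- ALL_STEPS[values[ALL_STEPS] != values[comp] & ALL_STEPS < comp]
    if (length(bad)) {
      warning("complement-asymmetric ", feature, " values for: ",
              paste(bad, "/", step_complement(bad), collapse = ", "),
              call. = FALSE)
    }
  }
  structure(values, feature = feature, units = units,
            class = c("step_table", "numeric"))
}

#' @export
print.step_table <- function(x, ...) {
  cat("Dinucleotide step table:", attr(x, "feature"),
      paste0("(", attr(x, "units"), ")\n"))
  print(unclass(structure(as.numeric(x), names = names(x))))
  invisible(x)
}

#' Write / read a step table as plain TSV
#'
#' Dot-decimal, header row `step<TAB>value`; reloading reproduces the values
#' bit-exactly.
#'
#' @param table A `step_table`.
#' @param path Output (or input) file path.
#' @rdname step_table_io
#' @export
write_step_table <- function(table, path) {
  df <- data.frame(step = names(table), value = as.numeric(table))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param feature,units Metadata for the reloaded table.
#' @rdname step_table_io
#' @export
read_step_table <- function(path, feature, units = "") {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("step", "value") %in% names(df))) {
    stop("step table file needs columns 'step' and 'value': ", path,
         call. = FALSE)
  }
  step_table(stats::setNames(df$value, df$step), feature = feature,
             units = units)
}

#' Load BMHT wedge angles (roll, tilt, twist per dinucleotide step)
#'
#' Without `source_path`, returns the packaged gel-mobility wedge table
#' (Bolshoy-style roll/tilt magnitudes with crystallographic twists). A
#' user-supplied table (TSV with columns `step`, `roll`, `tilt`, `twist`)
#' replaces it, so the curvature geometry can be driven by any parameter
#' set.
#'
#' @param source_path Optional path to a 16-row delimited table.
#' @return A `wedge_table`: data.frame with rownames the 16 steps and
#'   numeric columns `roll`, `tilt`, `twist` (degrees).
#' @export
load_wedge_table <- function(source_path = NULL) {
  path <- source_path %||% system.file("extdata", "bmht_wedge_angles.tsv",
                                       package = "promstruct", mustWork = TRUE)
  df <- tryCatch(
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("cannot read wedge table '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  needed <- c("step", "roll", "tilt", "twist")
  if (!all(needed %in% names(df))) {
    stop("wedge table must have columns step, roll, tilt, twist",
         call. = FALSE)
  }
  wedge_table(df$roll, df$tilt, df$twist, steps = df$step)
}

#' Construct and validate a wedge-angle table
#'
#' @param roll,tilt,twist Numeric vectors of per-step angles in degrees.
#' @param steps Dinucleotide step labels (all 16, no duplicates).
#' @return A validated `wedge_table`.
#' @export
wedge_table <- function(roll, tilt, twist, steps = ALL_STEPS) {
  if (anyDuplicated(steps)) {
    stop("duplicate dinucleotide steps in wedge table", call. = FALSE)
  }
  if (!setequal(steps, ALL_STEPS) || length(steps) != 16L) {
    stop("wedge table must cover exactly the 16 dinucleotide steps (got ",
         length(steps), ")", call. = FALSE)
  }
  if (!is.numeric(roll) || !is.numeric(tilt) || !is.numeric(twist)) {
    stop("non-numeric wedge angle column", call. = FALSE)
  }
  angles <- data.frame(roll = as.numeric(roll), tilt = as.numeric(tilt),
                       twist = as.numeric(twist), row.names = steps)
  if (any(!is.finite(as.matrix(angles)))) {
    stop("non-numeric or non-finite wedge angle", call. = FALSE)
  }
  if (any(angles$twist <= 0 | angles$twist > 60)) {
    stop("twist angles must lie in (0, 60] degrees", call. = FALSE)
  }
  angles <- angles[ALL_STEPS, ]
  class(angles) <- c("wedge_table", "data.frame")
  angles
}

#' Expand an IUPAC degenerate pattern into per-position base sets
#'
#' @param pattern Character scalar over the IUPAC alphabet, e.g.
#'   `"SYTTWWAA"`.
#' @return A list, one element per pattern position, each the character
#'   vector of allowed bases.
#' @examples
#' expand_iupac("W")   # list(c("A", "T"))
#' @export
expand_iupac <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_CODES))
  if (length(bad)) {
    stop("non-IUPAC character(s) in pattern: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  unname(IUPAC_CODES[chars])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
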