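# FASTA + metadata readers and the long-format profile TSV.
#
# All user-facing coordinates are TSS-relative labels (no zero); 0-based
# offsets stay internal.

#' Read TSS-anchored sequences from FASTA plus a metadata table
#'
#' The metadata TSV must have columns `id`, `tss_index` (0-based offset of
#' the +1 base) and optionally `organism`, and must cover every FASTA
#' record. With `centered = TRUE` no metadata is needed: every record is
#' asserted to be TSS-centered (even length, TSS at `length/2`).
#' Lowercase input is uppercased; `U` is mapped to `T` with a warning.
#'
#' @param fasta_path FASTA file path.
#' @param meta_path Metadata TSV path (ignored when `centered = TRUE`).
#' @param centered Assert TSS-centered records instead of reading metadata.
#' @return A list of [tss_sequence()] objects.
#' @export
read_fasta_with_meta <- function(fasta_path, meta_path = NULL,
                                 centered = FALSE) {
  raw <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(as.character(raw))
  if (any(grepl("U", seqs, fixed = TRUE))) {
    warning("RNA-style 'U' bases mapped to 'T'", call. = FALSE)
    seqs <- gsub("U", "T", seqs, fixed = TRUE)
  }
  if (centered) {
    tss <- vapply(seqs, function(s) {
      if (nchar(s) %% 2L != 0L) return(NA_integer_)
      nchar(s) %/% 2L
    }, integer(1))
    if (anyNA(tss)) {
      stop("centered records must have even length (no integer TSS under ",
           "the no-zero convention): ",
           paste(ids[is.na(tss)], collapse = ", "), call. = FALSE)
    }
    org <- rep("unknown", length(ids))
  } else {
    if (is.null(meta_path)) {
      stop("either a metadata table or centered = TRUE is required",
           call. = FALSE)
    }
    meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
    if (!all(c("id", "tss_index") %in% names(meta))) {
      stop("metadata must have columns 'id' and 'tss_index'", call. = FALSE)
    }
    idx <- match(ids, meta$id)
    if (anyNA(idx)) {
      stop("metadata missing record(s): ",
           paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    tss <- as.integer(meta$tss_index[idx])
    org <- if ("organism" %in% names(meta)) meta$organism[idx] else
      rep("unknown", length(ids))
  }
  mapply(tss_sequence, ids, seqs, tss, org,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write sequences as FASTA
#'
#' @param records List of [tss_sequence()]s or a named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  if (is.list(records)) {
    seqs <- vapply(records, `[[`, "", "sequence")
    names(seqs) <- vapply(records, `[[`, "", "id")
  } else {
    seqs <- records
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Write metadata (and truth labels) for a record set
#'
#' @param records List of [tss_sequence()]s.
#' @param path Output TSV path.
#' @param truth Optional truth data.frame merged in by `id`.
#' @export
write_meta <- function(records, path, truth = NULL) {
  meta <- data.frame(
    id = vapply(records, `[[`, "", "id"),
    tss_index = vapply(records, `[[`, integer(1), "tss_index"),
    organism = vapply(records, `[[`, "", "organism"),
    stringsAsFactors = FALSE)
  if (!is.null(truth)) meta <- merge(meta, truth, by = "id", sort = FALSE)
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write profiles as long-format TSV
#'
#' Columns `id`, `feature`, `position`, `value`, `n`; missing values are
#' serialized as `NA`; mean profiles carry id `MEAN`. The format
#' round-trips through [read_profiles()] bit-exactly for finite values.
#'
#' @param profiles A [encode_sequence()]/[mean_profile()] object or a list
#'   of them (a [build_reference()]'s `features` list also works).
#' @param path Output path.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, c("profile", "mean_profile"))) {
    profiles <- list(profiles)
  }
  if (inherits(profiles, "reference_profile")) profiles <- profiles$features
  rows <- lapply(profiles, function(p) {
    if (inherits(p, "mean_profile")) {
      data.frame(id = "MEAN", feature = p$feature, position = p$positions,
                 value = p$mean_values, n = p$n_contributing,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(id = p$id, feature = p$feature, position = p$positions,
                 value = p$values, n = 1L, stringsAsFactors = FALSE)
    }
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), feature = character(),
               position = integer(), value = numeric(), n = integer())
  # 17 significant digits so finite doubles round-trip bit-exactly
  df$value <- ifelse(is.na(df$value), NA,
                     formatC(df$value, digits = 17, format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read long-format profile TSV back into profile objects
#'
#' @param path Input path.
#' @return A list of `profile` / `mean_profile` objects (one per
#'   id-feature pair, in file order).
#' @export
read_profiles <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("id", "feature", "position", "value", "n")
  if (!all(needed %in% names(df))) {
    stop("profile file must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(df)) return(list())
  key <- paste(df$id, df$feature, sep = "\r")
  lapply(split(df, factor(key, levels = unique(key))), function(chunk) {
    chunk <- chunk[order(chunk$position), ]
    if (chunk$id[1] == "MEAN") {
      structure(list(feature = chunk$feature[1],
                     positions = as.integer(chunk$position),
                     mean_values = as.numeric(chunk$value),
                     n_contributing = as.integer(chunk$n)),
                class = "mean_profile")
    } else {
      new_profile(chunk$id[1], chunk$feature[1], chunk$position,
                  chunk$value)
    }
  })
}

#' Rebuild a reference profile from its long-format TSV
#'
#' @param path File written by [write_profiles()] from a reference.
#' @param pentamers Optional curvature lookup for later scans.
#' @param upstream,downstream Core geometry.
#' @return A `reference_profile`.
#' @export
read_reference <- function(path, pentamers = NULL, upstream = 80L,
                           downstream = 20L) {
  profs <- read_profiles(path)
  feats <- vapply(profs, `[[`, "", "feature")
  names(profs) <- feats
  structure(list(features = profs, provenance = basename(path),
                 upstream = as.integer(upstream),
                 downstream = as.integer(downstream),
                 tables = feature_tables(feats, pentamers)),
            class = "reference_profile")
}
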