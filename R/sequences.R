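# TSS-anchored sequence records and the TSS-relative coordinate convention.
#
# Coordinates have no position 0: the TSS base is +1 and the base before it
# is -1, so a 1000-nt TSS-centered record spans -500..+500 and the 100-nt
# core promoter spans -80..+20.

#' Create a TSS-anchored sequence record
#'
#' @param id Record identifier.
#' @param sequence DNA string; lowercased input is uppercased, characters
#'   must be in `{A,C,G,T,N}`.
#' @param tss_index 0-based index of the +1 (TSS) base within `sequence`.
#' @param organism Free-text organism label.
#' @return A `tss_sequence` object.
#' @export
tss_sequence <- function(id, sequence, tss_index, organism = "unknown") {
  sequence <- toupper(sequence)
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  if (grepl("[^ACGTN]", sequence)) {
    stop("record '", id, "': sequence contains characters outside {A,C,G,T,N}",
         call. = FALSE)
  }
  n <- nchar(sequence)
  tss_index <- as.integer(tss_index)
  if (is.na(tss_index) || tss_index < 0L || tss_index >= n) {
    stop("record '", id, "': tss_index ", tss_index,
         " outside sequence of length ", n, call. = FALSE)
  }
  structure(list(id = id, sequence = sequence, tss_index = tss_index,
                 organism = organism),
            class = "tss_sequence")
}

#' @export
print.tss_sequence <- function(x, ...) {
  n <- nchar(x$sequence)
  cat(sprintf("<tss_sequence> %s [%s] %d nt, TSS at offset %d (%+d..%+d)\n",
              x$id, x$organism, n, x$tss_index,
              position_label(0L, x$tss_index),
              position_label(n - 1L, x$tss_index)))
  invisible(x)
}

#' Map a 0-based sequence offset to its TSS-relative label
#'
#' Offsets before the TSS map to -1, -2, ... counting away from the TSS;
#' the TSS itself is +1 and label 0 never occurs.
#'
#' @param offset Integer vector of 0-based offsets.
#' @param tss_index 0-based offset of the TSS base.
#' @return Integer vector of labels.
#' @export
position_label <- function(offset, tss_index) {
  offset <- as.integer(offset)
  if (any(offset < 0L)) stop("negative sequence offset", call. = FALSE)
  ifelse(offset < tss_index, offset - tss_index, offset - tss_index + 1L)
}

#' Map a TSS-relative label back to a 0-based offset
#'
#' @param label Integer vector of nonzero labels.
#' @inheritParams position_label
#' @export
label_to_offset <- function(label, tss_index) {
  label <- as.integer(label)
  if (any(label == 0L)) stop("label 0 does not exist", call. = FALSE)
  ifelse(label < 0L, tss_index + label, tss_index + label - 1L)
}

#' TSS-relative labels of every base of a record
#'
#' @param rec A [tss_sequence()].
#' @return Integer vector of labels, one per base, never containing 0.
#' @export
sequence_labels <- function(rec) {
  position_label(seq_len(nchar(rec$sequence)) - 1L, rec$tss_index)
}

#' Extract the core promoter window (-80..+20)
#'
#' Returns the 100-base window spanning labels -80..-1,+1..+20 with the TSS
#' at offset 80 of the new record.
#'
#' @param rec A [tss_sequence()].
#' @param upstream,downstream Core window extent (defaults 80 and 20 nt).
#' @return A `tss_sequence` of length `upstream + downstream`.
#' @export
extract_core <- function(rec, upstream = 80L, downstream = 20L) {
  n <- nchar(rec$sequence)
  start <- rec$tss_index - upstream            # 0-based, inclusive
  end <- rec$tss_index + downstream - 1L
  if (start < 0L || end >= n) {
    stop("record '", rec$id, "': needs ", upstream, " nt upstream and ",
         downstream, " nt downstream of the TSS (has ", rec$tss_index,
         " and ", n - rec$tss_index, ")", call. = FALSE)
  }
  tss_sequence(rec$id, substr(rec$sequence, start + 1L, end + 1L),
               tss_index = upstream, organism = rec$organism)
}

#' Shuffle a sequence (mononucleotide permutation control)
#'
#' Uniformly random permutation of the bases; the base composition is
#' preserved exactly and the TSS anchor is kept, so the shuffled record is a
#' coordinate-compatible control for profile averaging.
#'
#' @param rec A [tss_sequence()].
#' @param seed Integer seed; the same seed reproduces the same permutation.
#' @param dinucleotide If `TRUE`, shuffle whole dinucleotide steps instead
#'   (approximate dinucleotide preservation for even-length sequences);
#'   mononucleotide shuffling is the default control.
#' @return A shuffled `tss_sequence`.
#' @export
shuffle_sequence <- function(rec, seed, dinucleotide = FALSE) {
  stopifnot(!missing(seed))
  chars <- strsplit(rec$sequence, "")[[1]]
  shuffled <- with_seed(seed, {
    if (dinucleotide && length(chars) >= 4L) {
      k <- length(chars) %/% 2L
      pairs <- paste0(chars[2L * seq_len(k) - 1L], chars[2L * seq_len(k)])
      rest <- if (length(chars) %% 2L) chars[length(chars)] else character()
      paste(c(sample(pairs), rest), collapse = "")
    } else {
      paste(sample(chars), collapse = "")
    }
  })
  tss_sequence(rec$id, shuffled, rec$tss_index, rec$organism)
}

#' GC content of a sequence, in percent
#'
#' `N` bases are excluded from both numerator and denominator.
#'
#' @param seq DNA string (or a [tss_sequence()]).
#' @return Percent GC in `[0, 100]`.
#' @export
gc_content <- function(seq) {
  if (inherits(seq, "tss_sequence")) seq <- seq$sequence
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  chars <- strsplit(toupper(seq), "")[[1]]
  counts <- table(factor(chars, levels = c("A", "C", "G", "T")))
  total <- sum(counts)
  if (total == 0L) {
    stop("sequence has no unambiguous bases; GC% undefined", call. = FALSE)
  }
  100 * (counts[["G"]] + counts[["C"]]) / total
}

#' AT content of a sequence, in percent
#'
#' @inheritParams gc_content
#' @export
at_content <- function(seq) 100 - gc_content(seq)

# Run code under a private RNG stream, leaving the caller's RNG untouched.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}
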