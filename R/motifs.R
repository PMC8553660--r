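# TATA-region motif matching and conserved/degenerated classification.
#
# The degenerate motifs are the organism-specific TATA(+BRE) consensuses
# reported for the three model archaea; matching is restricted to the
# TATA region upstream of the TSS and keeps at most one occurrence per
# sequence (the one closest to -28).

#' Organism TATA-region motifs
#'
#' The degenerate TATA consensuses of the three model archaea:
#' `SYTTWWAA` (*H. volcanii*), `VYTTWWAA` (*T. kodakarensis*) and the
#' combined BRE+TATA pattern `KVRWAAAVYTTWWWW` (*S. solfataricus*; the two
#' printed words are concatenated with no gap).
#' @format Named character vector.
#' @export
TATA_MOTIFS <- c(hvo = "SYTTWWAA", tko = "VYTTWWAA",
                 sso = "KVRWAAAVYTTWWWW")

#' Define a degenerate IUPAC motif with its search window
#'
#' @param pattern IUPAC pattern, 6-15 characters.
#' @param window Inclusive TSS-relative label range for the allowed motif
#'   *start* (default `c(-40, -20)`, covering the reported median TATA
#'   distances of ~30-35 bp upstream of the TSS).
#' @param gap Number of N spacers inserted after position `gap_after`
#'   (for two-part BRE+TATA motifs; default no gap).
#' @param gap_after Pattern position after which the spacer is inserted.
#' @return An `iupac_motif` object.
#' @export
iupac_motif <- function(pattern, window = c(-40L, -20L), gap = 0L,
                        gap_after = NULL) {
  pattern <- toupper(pattern)
  if (gap > 0L) {
    if (is.null(gap_after)) stop("gap requires gap_after", call. = FALSE)
    pattern <- paste0(substr(pattern, 1L, gap_after),
                      strrep("N", gap),
                      substr(pattern, gap_after + 1L, nchar(pattern)))
  }
  sets <- expand_iupac(pattern)  # validates the alphabet
  if (nchar(pattern) < 6L || nchar(pattern) > 15L) {
    stop("motif length must be 6-15 (got ", nchar(pattern), ")",
         call. = FALSE)
  }
  window <- as.integer(window)
  stopifnot(length(window) == 2L, window[1] <= window[2], all(window != 0L))
  structure(list(pattern = pattern, sets = sets, window = window),
            class = "iupac_motif")
}

#' Find the motif occurrence nearest the TATA position
#'
#' Scans every start position whose TSS-relative label lies in the motif's
#' search window; a start matches when each base of the record falls in the
#' corresponding IUPAC set (`N` in the sequence never matches). Among
#' matches, the one whose start label is closest to -28 wins; ties go to
#' the more upstream start, keeping at most one occurrence per sequence.
#'
#' @param rec A core-promoter [tss_sequence()].
#' @param motif An [iupac_motif()].
#' @param anchor Label the tie-break distance is measured from (default
#'   -28, the canonical archaeal TATA position).
#' @return A one-row data.frame (`id`, `match_label`, `match_seq`) or
#'   `NULL` when no start matches.
#' @export
match_motif <- function(rec, motif, anchor = -28L) {
  width <- nchar(motif$pattern)
  n <- nchar(rec$sequence)
  if (width > n) {
    stop("motif (", width, " nt) longer than record '", rec$id, "' (", n,
         " nt)", call. = FALSE)
  }
  labels <- motif$window[1]:motif$window[2]
  labels <- labels[labels != 0L]
  starts <- label_to_offset(labels, rec$tss_index)
  keep <- starts >= 0L & (starts + width - 1L) < n
  starts <- starts[keep]
  labels <- labels[keep]
  if (!length(starts)) return(NULL)
  chars <- strsplit(rec$sequence, "")[[1]]
  hit <- vapply(seq_along(starts), function(k) {
    s <- starts[k]
    all(vapply(seq_len(width),
               function(j) chars[s + j] %in% motif$sets[[j]], logical(1)))
  }, logical(1))
  if (!any(hit)) return(NULL)
  cand <- labels[hit]
  best <- cand[order(abs(cand - anchor), cand)][1L]
  off <- label_to_offset(best, rec$tss_index)
  data.frame(id = rec$id, match_label = best,
             match_seq = substr(rec$sequence, off + 1L, off + width),
             stringsAsFactors = FALSE)
}

#' Split a promoter set into conserved-TATA and degenerated-TATA groups
#'
#' Sequences with a motif occurrence in the search window go to the
#' conserved group (with the recorded match); all others are degenerated.
#' Per-sequence GC% is computed for the group comparison.
#'
#' @param records List of core-promoter [tss_sequence()] objects.
#' @param motif An [iupac_motif()] (or an IUPAC pattern string, taken with
#'   the default window).
#' @param anchor Passed to [match_motif()].
#' @return A `classified_set`: list with `conserved` (data.frame id,
#'   match_label, match_seq), `degenerated` (character ids) and `gc`
#'   (data.frame id, group, gc_percent).
#' @export
classify_promoters <- function(records, motif, anchor = -28L) {
  if (length(records) == 0L) stop("empty promoter set", call. = FALSE)
  if (is.character(motif)) motif <- iupac_motif(motif)
  matches <- lapply(records, match_motif, motif = motif, anchor = anchor)
  hit <- !vapply(matches, is.null, logical(1))
  conserved <- if (any(hit)) do.call(rbind, matches[hit]) else
    data.frame(id = character(), match_label = integer(),
               match_seq = character(), stringsAsFactors = FALSE)
  ids <- vapply(records, `[[`, "", "id")
  gc <- data.frame(
    id = ids,
    group = ifelse(hit, "conserved", "degenerated"),
    gc_percent = vapply(records, gc_content, numeric(1)),
    stringsAsFactors = FALSE)
  structure(list(conserved = conserved, degenerated = ids[!hit], gc = gc,
                 motif = motif),
            class = "classified_set")
}

#' @export
print.classified_set <- function(x, ...) {
  n <- nrow(x$gc)
  cat(sprintf(
    "<classified_set> %d sequences vs %s: %d conserved (%.1f%%), %d degenerated\n",
    n, x$motif$pattern, nrow(x$conserved), 100 * nrow(x$conserved) / n,
    length(x$degenerated)))
  invisible(x)
}

#' Summarize a classified set (group sizes and mean GC%)
#'
#' @param object A [classify_promoters()] result.
#' @param ... Unused.
#' @return Data.frame with one row per group: `group`, `n`, `percent`,
#'   `mean_gc`.
#' @export
summary.classified_set <- function(object, ...) {
  agg <- stats::aggregate(gc_percent ~ group, data = object$gc, FUN = mean)
  counts <- table(factor(object$gc$group,
                         levels = c("conserved", "degenerated")))
  data.frame(group = names(counts), n = as.integer(counts),
             percent = 100 * as.integer(counts) / nrow(object$gc),
             mean_gc = agg$gc_percent[match(names(counts), agg$group)],
             row.names = NULL, stringsAsFactors = FALSE)
}
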