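# Local pairwise alignment: user-facing wrappers around the Gotoh DP in src/.

#' Normalize a nucleotide sequence
#'
#' Uppercases, converts RNA `U` to `T`, and validates that every character is
#' one of `A`, `C`, `G`, `T`, `N`.
#'
#' @param seq a single character string.
#' @return The normalized sequence.
#' @export
normalize_sequence <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("sequence must be a single character string")
  s <- chartr("u", "t", seq)
  s <- toupper(s)
  s <- chartr("U", "T", s)
  bad <- gsub("[ACGTN]", "", s)
  if (nzchar(bad))
    stop(sprintf("invalid character(s) in sequence: '%s'",
                 paste(unique(strsplit(bad, "")[[1]]), collapse = "")))
  s
}

#' Optimal local alignment with affine gap penalties
#'
#' Gotoh dynamic programming over the two sequences, returning one optimal
#' local alignment. A gap of length `k` costs `gap_open + k * gap_extend`
#' (see [scoring_scheme()]). `N` scores as a mismatch against every base,
#' itself included, and is never counted as a match. If no positive-scoring
#' alignment exists the empty alignment (score 0, length 0) is returned.
#'
#' Ties are broken deterministically: among equally scoring end cells the one
#' with the smallest `(ref_end, query_end)` is used, and within the traceback
#' a residue pair is preferred over a gap in the reference row, which is
#' preferred over a gap in the query row.
#'
#' @param query,ref nucleotide strings (normalized with
#'   [normalize_sequence()] first).
#' @param scheme a [scoring_scheme()].
#' @return A `local_alignment` object: a list with `aligned_query`,
#'   `aligned_ref` (strings over `A,C,G,T,N,-`), integer `score`,
#'   half-open 0-based `query_span` and `ref_span`, and the column counts
#'   `n_match`, `n_mismatch`, `n_gap_columns`, `length`.
#' @examples
#' aln <- align_local("ACACGT", "ACGT")
#' aln$score      # 8: the gapless ACGT/ACGT suffix alignment
#' @export
align_local <- function(query, ref, scheme = scoring_scheme()) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  q <- normalize_sequence(query)
  r <- normalize_sequence(ref)
  if (!nzchar(q) || !nzchar(r)) stop("sequences must be non-empty")
  res <- .gotoh_local(q, r, scheme$match, scheme$mismatch,
                      scheme$gap_open, scheme$gap_extend)
  structure(list(
    aligned_query = res$aligned_query,
    aligned_ref   = res$aligned_ref,
    score         = res$score,
    query_span    = c(res$query_start, res$query_end),
    ref_span      = c(res$ref_start, res$ref_end),
    n_match       = res$n_match,
    n_mismatch    = res$n_mismatch,
    n_gap_columns = res$n_gap_columns,
    length        = res$length
  ), class = "local_alignment")
}

#' Build a local_alignment object from two aligned rows
#'
#' Derives the column counts and the affine-gap score from a pair of equal
#' length aligned strings. Useful for constructing worked examples and for
#' feeding [similarity_score()] with externally produced alignments.
#'
#' @param aligned_query,aligned_ref equal-length strings over `A,C,G,T,N,-`.
#' @param scheme a [scoring_scheme()] used to compute the score.
#' @param query_span,ref_span optional half-open 0-based spans in the
#'   original sequences; default to `[0, n_residues)`.
#' @return A `local_alignment` object.
#' @export
local_alignment <- function(aligned_query, aligned_ref,
                            scheme = scoring_scheme(),
                            query_span = NULL, ref_span = NULL) {
  qc <- strsplit(aligned_query, "")[[1]]
  rc <- strsplit(aligned_ref, "")[[1]]
  if (length(qc) != length(rc))
    stop("aligned rows must have equal length")
  if (any(qc == "-" & rc == "-"))
    stop("invalid alignment: column gapped in both rows")
  ok <- c("A", "C", "G", "T", "N", "-")
  if (!all(qc %in% ok) || !all(rc %in% ok))
    stop("aligned rows must be over the alphabet A,C,G,T,N,-")
  gap <- qc == "-" | rc == "-"
  mt  <- !gap & qc == rc & qc != "N"
  aln <- structure(list(
    aligned_query = aligned_query,
    aligned_ref   = aligned_ref,
    score         = NA_integer_,
    query_span    = query_span %||% c(0L, sum(qc != "-")),
    ref_span      = ref_span %||% c(0L, sum(rc != "-")),
    n_match       = sum(mt),
    n_mismatch    = sum(!gap & !mt),
    n_gap_columns = sum(gap),
    length        = length(qc)
  ), class = "local_alignment")
  aln$score <- score_alignment(aln, scheme)
  aln
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Re-score an alignment by scanning its columns
#'
#' Independent re-computation of an alignment's score: walks the columns,
#' charging match/mismatch for residue pairs and `gap_open + k * gap_extend`
#' for every maximal gap run of length `k`. Used as an internal consistency
#' check on [align_local()] output.
#'
#' @param aln a `local_alignment`.
#' @param scheme a [scoring_scheme()].
#' @return Integer score.
#' @export
score_alignment <- function(aln, scheme = scoring_scheme()) {
  stopifnot(inherits(aln, "local_alignment"), inherits(scheme, "scoring_scheme"))
  qc <- strsplit(aln$aligned_query, "")[[1]]
  rc <- strsplit(aln$aligned_ref, "")[[1]]
  if (length(qc) != length(rc)) stop("aligned rows differ in length")
  score <- 0L
  in_gap <- 0L # 0 none, 1 gap in query row, 2 gap in ref row
  for (k in seq_along(qc)) {
    a <- qc[k]; b <- rc[k]
    if (a == "-" && b == "-") stop("invalid alignment: column gapped in both rows")
    if (a == "-") {
      score <- score + scheme$gap_extend +
        if (in_gap == 1L) 0L else scheme$gap_open
      in_gap <- 1L
    } else if (b == "-") {
      score <- score + scheme$gap_extend +
        if (in_gap == 2L) 0L else scheme$gap_open
      in_gap <- 2L
    } else {
      score <- score + if (a == b && a != "N") scheme$match else scheme$mismatch
      in_gap <- 0L
    }
  }
  as.integer(score)
}

#' @export
print.local_alignment <- function(x, width = 60L, ...) {
  cat(sprintf(
    "<local_alignment> score %d, length %d (%d match / %d mismatch / %d gap)\n",
    x$score, x$length, x$n_match, x$n_mismatch, x$n_gap_columns))
  cat(sprintf("  query [%d,%d)  ref [%d,%d)\n",
              x$query_span[1], x$query_span[2],
              x$ref_span[1], x$ref_span[2]))
  if (x$length > 0L) cat(format_alignment(x, width = width), sep = "\n")
  invisible(x)
}

# Three-line text rendering (query / markers / ref), wrapped. Debug aid only.
format_alignment <- function(aln, width = 60L) {
  qc <- strsplit(aln$aligned_query, "")[[1]]
  rc <- strsplit(aln$aligned_ref, "")[[1]]
  mark <- ifelse(qc == "-" | rc == "-", " ",
                 ifelse(qc == rc & qc != "N", "|", "."))
  out <- character(0)
  for (s in seq(1L, length(qc), by = width)) {
    e <- min(s + width - 1L, length(qc))
    out <- c(out,
             paste0(qc[s:e], collapse = ""),
             paste0(mark[s:e], collapse = ""),
             paste0(rc[s:e], collapse = ""),
             "")
  }
  out[-length(out)]
}
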