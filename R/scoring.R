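#' Alignment scoring scheme
#'
#' The four parameters of the affine-gap local alignment: match and mismatch
#' scores plus gap opening and gap extension penalties. Defaults are the
#' BLAST-like values used throughout the package: +2 / -3 / -5 / -2. A gap of
#' length `k` costs `gap_open + k * gap_extend`, i.e. the first gapped
#' residue already pays both the opening and one extension charge.
#'
#' @param match positive integer score for an identical residue pair.
#' @param mismatch negative integer score for a differing residue pair.
#' @param gap_open negative integer, flat charge for opening a gap.
#' @param gap_extend negative integer, per-residue gap charge; must satisfy
#'   `gap_open <= gap_extend < 0`.
#' @return An object of class `scoring_scheme`.
#' @examples
#' scoring_scheme()
#' scoring_scheme(match = 1, mismatch = -1, gap_open = -2, gap_extend = -1)
#' @export
scoring_scheme <- function(match = 2L, mismatch = -3L,
                           gap_open = -5L, gap_extend = -2L) {
  vals <- c(match = match, mismatch = mismatch,
            gap_open = gap_open, gap_extend = gap_extend)
  if (any(vals != round(vals)))
    stop("scoring parameters must be integers")
  vals[] <- as.integer(vals)
  storage.mode(vals) <- "integer"
  if (vals[["match"]] <= 0L) stop("match score must be positive")
  if (vals[["mismatch"]] >= 0L) stop("mismatch score must be negative")
  if (!(vals[["gap_open"]] <= vals[["gap_extend"]] &&
        vals[["gap_extend"]] < 0L))
    stop("gap penalties must satisfy gap_open <= gap_extend < 0")
  structure(as.list(vals), class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf(
    "<scoring_scheme> match %+d, mismatch %+d, gap open %+d, gap extend %+d\n",
    x$match, x$mismatch, x$gap_open, x$gap_extend))
  cat("  gap of length k costs gap_open + k * gap_extend\n")
  invisible(x)
}
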