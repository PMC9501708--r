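# The analysis core: gap-aware similarity of an aligned pair, per-gene
# relative divergence between two lineages, length filtering, and threshold
# categorisation with summary counts.

#' Similarity of a local alignment
#'
#' `S = m / (L - g)`: the number of identically matching columns `m` divided
#' by the aligned length `L` minus the number of gap-containing columns `g`.
#' Equivalently, identity over the residue-pair columns, so `0 <= S <= 1`.
#' "Indels" are counted as gap *columns*, not gap events; per-event counting
#' could push the ratio above 1.
#'
#' @param aln a `local_alignment` (from [align_local()] or
#'   [local_alignment()]).
#' @return Similarity in `[0, 1]`.
#' @examples
#' similarity_score(align_local("ACGT", "ACGT")) # 1
#' @export
similarity_score <- function(aln) {
  stopifnot(inherits(aln, "local_alignment"))
  denom <- aln$length - aln$n_gap_columns
  if (aln$length == 0L || denom <= 0L)
    orthodiv_error("similarity undefined: alignment has no residue-pair columns",
                   "orthodiv_undefined_similarity")
  aln$n_match / denom
}

#' Genetic distance from a similarity
#'
#' `d = 1 - S`, the reporting scale for between-species divergence: the
#' difference of two distances equals minus the difference of the
#' similarities, so "rabbit closer to human" reads the same on either scale.
#'
#' @param S similarity in `[0, 1]`.
#' @return Distance in `[0, 1]`.
#' @export
genetic_distance <- function(S) {
  if (any(S < 0 | S > 1, na.rm = TRUE))
    orthodiv_error("similarity must lie in [0, 1]",
                   "orthodiv_precondition_error")
  1 - S
}

#' Per-gene similarity table from aligned pairs
#'
#' Helper assembling the long-format similarity table consumed by
#' [gene_comparisons()]: one row per gene x comparison species.
#'
#' @param gene_symbol,species character vectors.
#' @param aln list of `local_alignment` objects, parallel to the vectors.
#' @return A `data.frame` with columns `gene_symbol, species, similarity,
#'   aligned_length, n_gap_columns, n_match`.
#' @export
similarity_table <- function(gene_symbol, species, aln) {
  stopifnot(length(gene_symbol) == length(species),
            length(species) == length(aln))
  data.frame(
    gene_symbol = as.character(gene_symbol),
    species = as.character(species),
    similarity = vapply(aln, similarity_score, numeric(1)),
    aligned_length = vapply(aln, function(a) a$length, integer(1)),
    n_gap_columns = vapply(aln, function(a) a$n_gap_columns, integer(1)),
    n_match = vapply(aln, function(a) a$n_match, integer(1)),
    stringsAsFactors = FALSE)
}

#' Per-gene relative divergence between two comparison species
#'
#' For each gene with a similarity score against the reference for *both*
#' comparison species, computes `delta = S_first - S_second` (first and
#' second comparison species; in the motivating study, rabbit and mouse, so
#' positive `delta` means rabbit is closer to human). Genes missing either
#' species are dropped with a message. `min_aligned_length` is the smaller
#' of the two aligned lengths, the conservative per-gene aggregate used by
#' the length filter.
#'
#' @param sim a similarity table (see [similarity_table()]).
#' @param comparison_species character vector of length 2; order defines the
#'   sign of `delta`.
#' @return A `data.frame` with columns `gene_symbol, sim_first, sim_second,
#'   delta, min_aligned_length` (plus the species names as attributes).
#' @export
gene_comparisons <- function(sim,
                             comparison_species = c("Oryctolagus cuniculus",
                                                    "Mus musculus")) {
  stopifnot(length(comparison_species) == 2L)
  a <- sim[sim$species == comparison_species[1], , drop = FALSE]
  b <- sim[sim$species == comparison_species[2], , drop = FALSE]
  genes <- intersect(a$gene_symbol, b$gene_symbol)
  dropped <- setdiff(unique(sim$gene_symbol), genes)
  if (length(dropped))
    message(sprintf("dropping %d gene(s) without both comparison species: %s",
                    length(dropped),
                    paste(utils::head(dropped, 5), collapse = ", ")))
  ia <- match(genes, a$gene_symbol)
  ib <- match(genes, b$gene_symbol)
  out <- data.frame(
    gene_symbol = genes,
    sim_first = a$similarity[ia],
    sim_second = b$similarity[ib],
    delta = a$similarity[ia] - b$similarity[ib],
    min_aligned_length = pmin(a$aligned_length[ia], b$aligned_length[ib]),
    stringsAsFactors = FALSE)
  attr(out, "comparison_species") <- comparison_species
  out
}

#' Drop genes with short alignments
#'
#' Keeps genes whose minimum aligned length across the two comparisons is
#' *strictly greater* than `min_len` (default 150 bp), discarding partial or
#' chance matches: an alignment of exactly `min_len` columns is excluded.
#'
#' @param comparisons output of [gene_comparisons()].
#' @param min_len non-negative integer.
#' @return The filtered comparison table.
#' @export
filter_min_length <- function(comparisons, min_len = 150L) {
  if (min_len < 0) orthodiv_error("min_len must be >= 0",
                                  "orthodiv_precondition_error")
  keep <- comparisons$min_aligned_length > min_len
  out <- comparisons[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "comparison_species") <- attr(comparisons, "comparison_species")
  out
}

# Exact ties are representable (delta is a difference of rationals), but a
# tiny guard absorbs floating-point drift across platforms.
TIE_TOLERANCE <- 1e-12

#' Categorise genes by the sign of their relative divergence
#'
#' With threshold `t > 0`, genes with `|delta| < t` are excluded from the
#' summary; among the remainder, `delta > 0` counts the first comparison
#' species (rabbit, in the motivating study) as closer to the reference and
#' `delta < 0` the second (mouse). At `t = 0` every gene is kept and
#' `|delta| <= 1e-12` counts as an exact tie. Percentages are computed over
#' `n_total` and rounded half-up to integer percent; the raw fractions are
#' kept alongside.
#'
#' @param comparisons output of [gene_comparisons()] (possibly filtered).
#' @param threshold non-negative minimum `|delta|`; 0 means unthresholded.
#' @return A `category_summary` object; see [category_summary()].
#' @export
categorize <- function(comparisons, threshold = 0) {
  if (threshold < 0) orthodiv_error("threshold must be >= 0",
                                    "orthodiv_precondition_error")
  d <- comparisons$delta
  if (threshold > 0) {
    d <- d[abs(d) >= threshold]
    n_tie <- 0L
  } else {
    n_tie <- sum(abs(d) <= TIE_TOLERANCE)
  }
  n_first <- sum(d > TIE_TOLERANCE)
  n_second <- sum(d < -TIE_TOLERANCE)
  category_summary(n_rabbit_closer = n_first, n_mouse_closer = n_second,
                   n_tie = n_tie, threshold = threshold)
}

round_half_up <- function(x) floor(x + 0.5)

#' Category counts and percentages
#'
#' Summary layer over the three categories. The field names follow the
#' motivating study: `n_rabbit_closer` counts genes where the *first*
#' comparison species is closer to the reference, `n_mouse_closer` the
#' second. Percentages are over `n_total = n_rabbit_closer + n_mouse_closer
#' + n_tie`, rounded half-up to the nearest integer percent; the unrounded
#' fractions are reported as `frac_rabbit_closer` / `frac_mouse_closer`.
#'
#' @param n_rabbit_closer,n_mouse_closer,n_tie non-negative counts.
#' @param threshold the `|delta|` threshold the counts were computed under
#'   (0 = unthresholded).
#' @return A `category_summary` object (a list).
#' @examples
#' category_summary(2468, 320, 5, threshold = 0)$pct_rabbit_closer # 88
#' @export
category_summary <- function(n_rabbit_closer, n_mouse_closer, n_tie = 0L,
                             threshold = 0) {
  n_total <- n_rabbit_closer + n_mouse_closer + n_tie
  frac_r <- if (n_total > 0) n_rabbit_closer / n_total else NA_real_
  frac_m <- if (n_total > 0) n_mouse_closer / n_total else NA_real_
  structure(list(
    n_total = as.integer(n_total),
    n_rabbit_closer = as.integer(n_rabbit_closer),
    n_mouse_closer = as.integer(n_mouse_closer),
    n_tie = as.integer(n_tie),
    threshold = threshold,
    frac_rabbit_closer = frac_r,
    frac_mouse_closer = frac_m,
    pct_rabbit_closer = if (n_total > 0) round_half_up(100 * frac_r) else NA_real_,
    pct_mouse_closer = if (n_total > 0) round_half_up(100 * frac_m) else NA_real_
  ), class = "category_summary")
}

#' @export
print.category_summary <- function(x, ...) {
  cat(sprintf("<category_summary> threshold %g: %d genes\n",
              x$threshold, x$n_total))
  if (x$n_total > 0) {
    cat(sprintf("  first species closer:  %5d (%d%%, raw %.4f)\n",
                x$n_rabbit_closer, x$pct_rabbit_closer, x$frac_rabbit_closer))
    cat(sprintf("  second species closer: %5d (%d%%, raw %.4f)\n",
                x$n_mouse_closer, x$pct_mouse_closer, x$frac_mouse_closer))
    cat(sprintf("  exact ties:            %5d\n", x$n_tie))
  }
  invisible(x)
}

#' One summary row per threshold
#'
#' @param comparisons output of [gene_comparisons()] (possibly filtered).
#' @param thresholds non-negative numeric vector.
#' @return A `data.frame` with one row per threshold and all
#'   [category_summary()] fields.
#' @export
summarize_thresholds <- function(comparisons, thresholds = c(0, 0.05)) {
  do.call(rbind, lapply(thresholds, function(t) {
    s <- categorize(comparisons, t)
    data.frame(threshold = t, n_total = s$n_total,
               n_rabbit_closer = s$n_rabbit_closer,
               n_mouse_closer = s$n_mouse_closer, n_tie = s$n_tie,
               frac_rabbit_closer = s$frac_rabbit_closer,
               frac_mouse_closer = s$frac_mouse_closer,
               pct_rabbit_closer = s$pct_rabbit_closer,
               pct_mouse_closer = s$pct_mouse_closer)
  }))
}
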