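# Nucleotide and amino-acid p-distances with pairwise deletion, plus CDS
# translation. Consumes pre-aligned input; alignment construction lives in
# align_local() for the pairwise three-taxon workflow.

AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*", "-")

#' Translate a CDS with the standard genetic code
#'
#' Standard-code translation with the conventions used throughout the
#' package: a trailing stop codon is removed; a trailing incomplete codon is
#' dropped with a warning; any codon containing `N` translates to `X`
#' (even when all resolutions agree); an internal stop codon is an error
#' naming its codon position.
#'
#' @param cds nucleotide string, length >= 3.
#' @return Amino-acid string.
#' @examples
#' translate_cds("ATGAAATAA") # "MK"
#' @export
translate_cds <- function(cds) {
  s <- normalize_sequence(cds)
  if (nchar(s) < 3L)
    orthodiv_error("CDS shorter than one codon", "orthodiv_precondition_error")
  extra <- nchar(s) %% 3L
  if (extra) {
    warning(sprintf("dropping trailing incomplete codon (%d nt)", extra))
    s <- substr(s, 1L, nchar(s) - extra)
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(s),
                                           if.fuzzy.codon = "X"))
  # enforce the N rule regardless of resolvability
  codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
  aa_chars <- strsplit(aa, "")[[1]]
  aa_chars[grepl("N", codons, fixed = TRUE)] <- "X"
  n_aa <- length(aa_chars)
  if (aa_chars[n_aa] == "*") {
    aa_chars <- aa_chars[-n_aa]
    n_aa <- n_aa - 1L
  }
  stop_at <- which(aa_chars == "*")
  if (length(stop_at))
    orthodiv_error(sprintf("internal stop codon at codon %d", stop_at[1]),
                   "orthodiv_translation_error")
  paste(aa_chars, collapse = "")
}

#' An aligned set of sequences
#'
#' Validates a named character vector (or `labels` + `rows`) of equal-length
#' aligned rows over the nucleotide alphabet `A,C,G,T,N,-` or the amino-acid
#' alphabet plus `X` and `-`.
#'
#' @param rows character vector of aligned rows.
#' @param labels sequence labels; defaults to `names(rows)`.
#' @param mode `"nucleotide"` or `"amino_acid"`.
#' @return An `aligned_set` object.
#' @export
aligned_set <- function(rows, labels = names(rows),
                        mode = c("nucleotide", "amino_acid")) {
  mode <- match.arg(mode)
  force(labels) # before the transforms below drop names(rows)
  rows <- toupper(as.character(rows))
  if (length(rows) < 2L)
    orthodiv_error("an aligned set needs at least two rows",
                   "orthodiv_precondition_error")
  if (is.null(labels) || any(!nzchar(labels)) || anyDuplicated(labels))
    orthodiv_error("rows must carry unique non-empty labels",
                   "orthodiv_precondition_error")
  if (length(unique(nchar(rows))) != 1L)
    orthodiv_error("aligned rows must all have the same length",
                   "orthodiv_precondition_error")
  ok <- if (mode == "nucleotide") c("A", "C", "G", "T", "N", "-")
        else AA_ALPHABET
  for (k in seq_along(rows)) {
    bad <- setdiff(unique(strsplit(rows[k], "")[[1]]), ok)
    if (length(bad))
      orthodiv_error(sprintf("row '%s' has invalid character(s): %s",
                             labels[k], paste(bad, collapse = "")),
                     "orthodiv_parse_error")
  }
  structure(list(labels = as.character(labels), rows = unname(rows),
                 mode = mode), class = "aligned_set")
}

#' Read an aligned FASTA into an aligned_set
#'
#' @param path aligned FASTA (all records the same length).
#' @param mode `"nucleotide"` or `"amino_acid"`.
#' @return An `aligned_set`.
#' @export
read_aligned_fasta <- function(path, mode = c("nucleotide", "amino_acid")) {
  set <- Biostrings::readBStringSet(path)
  aligned_set(as.character(set), labels = names(set), mode = match.arg(mode))
}

ambiguity_symbol <- function(mode) if (mode == "nucleotide") "N" else "X"

#' p-distance of one aligned pair, with pairwise deletion
#'
#' The proportion of differing sites among the sites comparable in this
#' specific pair. Sites where either row carries a gap `-` — or, by default,
#' the ambiguity symbol (`N` for nucleotides, `X` for amino acids) — are
#' excluded before counting.
#'
#' @param row_a,row_b equal-length aligned rows.
#' @param mode `"nucleotide"` or `"amino_acid"`.
#' @param exclude_ambiguous treat ambiguity symbols as missing (default
#'   TRUE, matching the pairwise-deletion option of standard distance
#'   software); FALSE deletes gaps only.
#' @return A list with `distance` in `[0, 1]` and `n_compared`.
#' @examples
#' p_distance_pair("ACGT", "ACGA")$distance # 0.25
#' @export
p_distance_pair <- function(row_a, row_b,
                            mode = c("nucleotide", "amino_acid"),
                            exclude_ambiguous = TRUE) {
  mode <- match.arg(mode)
  a <- strsplit(toupper(row_a), "")[[1]]
  b <- strsplit(toupper(row_b), "")[[1]]
  if (length(a) != length(b))
    orthodiv_error("rows must have equal aligned length",
                   "orthodiv_precondition_error")
  drop <- a == "-" | b == "-"
  if (exclude_ambiguous) {
    amb <- ambiguity_symbol(mode)
    drop <- drop | a == amb | b == amb
  }
  a <- a[!drop]; b <- b[!drop]
  if (!length(a))
    orthodiv_error("no comparable sites after pairwise deletion",
                   "orthodiv_undefined_distance")
  list(distance = mean(a != b), n_compared = length(a))
}

#' Pairwise p-distance matrix with pairwise deletion
#'
#' Applies [p_distance_pair()] to every pair of rows. The result is
#' symmetric with a zero diagonal; `n_sites` records the per-pair number of
#' compared sites (pairwise deletion makes it pair-specific).
#'
#' @param aln an [aligned_set()].
#' @param exclude_ambiguous see [p_distance_pair()].
#' @return A `p_distance_matrix` object: list with `labels`, `values`
#'   (symmetric matrix), `n_sites` (integer matrix), `mode`.
#' @export
p_distance_matrix <- function(aln, exclude_ambiguous = TRUE) {
  stopifnot(inherits(aln, "aligned_set"))
  n <- length(aln$rows)
  values <- matrix(0, n, n, dimnames = list(aln$labels, aln$labels))
  n_sites <- matrix(nchar(aln$rows[1]), n, n,
                    dimnames = list(aln$labels, aln$labels))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    p <- tryCatch(
      p_distance_pair(aln$rows[i], aln$rows[j], mode = aln$mode,
                      exclude_ambiguous = exclude_ambiguous),
      orthodiv_undefined_distance = function(e) orthodiv_error(
        sprintf("pair (%s, %s): %s", aln$labels[i], aln$labels[j],
                conditionMessage(e)), "orthodiv_undefined_distance"))
    values[i, j] <- values[j, i] <- p$distance
    n_sites[i, j] <- n_sites[j, i] <- p$n_compared
  }
  diag(n_sites) <- NA_integer_
  structure(list(labels = aln$labels, values = values,
                 n_sites = n_sites, mode = aln$mode),
            class = "p_distance_matrix")
}

#' @export
print.p_distance_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("<p_distance_matrix> %s, %d sequences (pairwise deletion)\n",
              x$mode, length(x$labels)))
  print(round(x$values, digits))
  invisible(x)
}

#' Write a distance matrix (and its n_sites companion) as TSV
#'
#' @param dm a `p_distance_matrix`.
#' @param path output TSV for the distances; the per-pair compared-site
#'   counts go to `<path-sans-ext>_n_sites.tsv`.
#' @export
write_distance_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "p_distance_matrix"))
  write_square <- function(m, p) {
    df <- data.frame(label = rownames(m), m, check.names = FALSE)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_square(dm$values, path)
  write_square(dm$n_sites,
               paste0(tools::file_path_sans_ext(path), "_n_sites.tsv"))
  invisible(path)
}
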