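# Data model + I/O: one row per gene x species coding sequence, with
# provenance. Acquisition goes through a pluggable backend so the analysis
# never depends on network access.

orthodiv_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "orthodiv_error", "error")))
}

#' Construct a table of sequence records
#'
#' A `sequence_records` table holds one coding sequence per gene x species x
#' accession, with optional mRNA sequence and isoform label. CDS sequences
#' are normalized (uppercase, `U` to `T`) and must be non-empty over
#' `A,C,G,T,N`; `(gene_symbol, species, accession)` must be unique.
#'
#' @param gene_symbol,species,accession character vectors (recycled to a
#'   common length); species is a binomial name, accession a RefSeq-style or
#'   synthetic identifier.
#' @param isoform_label isoform tag such as `"X1"`, `"X2"`, or `""`.
#' @param mrna_seq mRNA sequence; may be empty (stored, unused downstream —
#'   the analysis aligns CDSs).
#' @param cds_seq coding sequence, required.
#' @return A `data.frame` of class `sequence_records`.
#' @export
sequence_records <- function(gene_symbol, species, accession,
                             isoform_label = "", mrna_seq = "", cds_seq) {
  if (length(gene_symbol) == 0L) {
    df <- data.frame(gene_symbol = character(0), species = character(0),
                     accession = character(0), isoform_label = character(0),
                     mrna_seq = character(0), cds_seq = character(0),
                     stringsAsFactors = FALSE)
    return(validate_sequence_records(df))
  }
  df <- data.frame(gene_symbol = as.character(gene_symbol),
                   species = as.character(species),
                   accession = as.character(accession),
                   isoform_label = as.character(isoform_label),
                   mrna_seq = as.character(mrna_seq),
                   cds_seq = as.character(cds_seq),
                   stringsAsFactors = FALSE)
  validate_sequence_records(df)
}

validate_sequence_records <- function(df) {
  need <- c("gene_symbol", "species", "accession", "isoform_label",
            "mrna_seq", "cds_seq")
  miss <- setdiff(need, names(df))
  if (length(miss))
    orthodiv_error(paste("missing record column(s):",
                         paste(miss, collapse = ", ")), "orthodiv_parse_error")
  df <- df[, need]
  if (nrow(df)) {
    if (any(!nzchar(df$gene_symbol)) || any(!nzchar(df$species)) ||
        any(!nzchar(df$accession)))
      orthodiv_error("gene_symbol, species and accession must be non-empty",
                     "orthodiv_parse_error")
    df$cds_seq <- vapply(df$cds_seq, function(s) {
      if (!nzchar(s))
        orthodiv_error("empty CDS sequence", "orthodiv_parse_error")
      normalize_sequence(s)
    }, character(1), USE.NAMES = FALSE)
    df$mrna_seq <- vapply(df$mrna_seq, function(s)
      if (nzchar(s)) normalize_sequence(s) else "",
      character(1), USE.NAMES = FALSE)
    key <- paste(df$gene_symbol, df$species, df$accession, sep = "\r")
    if (anyDuplicated(key))
      orthodiv_error(sprintf(
        "duplicate (gene, species, accession): %s",
        sub("\r.*", "", key[duplicated(key)][1])), "orthodiv_parse_error")
  }
  class(df) <- c("sequence_records", "data.frame")
  df
}

# FASTA header grammar used throughout: >GENE|Species binomial|ACCESSION|ISOFORM
record_headers <- function(records) {
  paste(records$gene_symbol, records$species, records$accession,
        records$isoform_label, sep = "|")
}

#' Read sequence records from FASTA
#'
#' Parses a multi-record FASTA whose headers follow the grammar
#' `>GENE|Species binomial|ACCESSION|ISOFORM`. Sequences are normalized on
#' load. Duplicate headers and empty sequence bodies are format errors that
#' name the offending header and its line number.
#'
#' @param path FASTA file path (CDS sequences; attach mRNA afterwards with
#'   [attach_mrna()]).
#' @return A `sequence_records` table.
#' @export
read_fasta_records <- function(path) {
  if (!file.exists(path))
    orthodiv_error(paste("cannot read FASTA:", path), "orthodiv_io_error")
  set <- Biostrings::readBStringSet(path)
  hdr <- names(set)
  header_line <- function(h) {
    ln <- which(startsWith(readLines(path), paste0(">", h)))
    if (length(ln)) ln[1] else NA_integer_
  }
  if (anyDuplicated(hdr)) {
    d <- hdr[duplicated(hdr)][1]
    orthodiv_error(sprintf("duplicate FASTA header '%s' (line %d)",
                           d, header_line(d)), "orthodiv_parse_error")
  }
  if (any(Biostrings::width(set) == 0L)) {
    d <- hdr[Biostrings::width(set) == 0L][1]
    orthodiv_error(sprintf("empty sequence body for header '%s' (line %d)",
                           d, header_line(d)), "orthodiv_parse_error")
  }
  parts <- regmatches(hdr, regexec("^([^|]+)\\|([^|]+)\\|([^|]+)\\|([^|]*)$",
                                   hdr))
  if (any(lengths(parts) != 5L)) {
    d <- hdr[lengths(parts) != 5L][1]
    orthodiv_error(sprintf(
      "header '%s' (line %d) does not follow GENE|Species|ACCESSION|ISOFORM",
      d, header_line(d)), "orthodiv_parse_error")
  }
  m <- do.call(rbind, parts)[, -1, drop = FALSE]
  sequence_records(gene_symbol = m[, 1], species = m[, 2],
                   accession = m[, 3], isoform_label = m[, 4],
                   mrna_seq = "", cds_seq = as.character(set))
}

#' Attach mRNA sequences from a FASTA to an existing record table
#'
#' Matches on the full `GENE|Species|ACCESSION|ISOFORM` header; records
#' without a matching mRNA keep an empty `mrna_seq`.
#'
#' @param records a `sequence_records` table.
#' @param path FASTA of mRNA sequences with the same header grammar.
#' @return The updated `sequence_records` table.
#' @export
attach_mrna <- function(records, path) {
  set <- Biostrings::readBStringSet(path)
  key <- record_headers(records)
  hit <- match(key, names(set))
  records$mrna_seq <- ifelse(is.na(hit), records$mrna_seq,
                             vapply(as.character(set)[hit], normalize_sequence,
                                    character(1), USE.NAMES = FALSE))
  validate_sequence_records(records)
}

#' Write sequence records to FASTA
#'
#' Writes the CDS (or mRNA) sequences with `GENE|Species|ACCESSION|ISOFORM`
#' headers, wrapped at 60 columns. Writing then reading is the identity on
#' all header fields and normalized sequences.
#'
#' @param records a `sequence_records` table.
#' @param path output path.
#' @param what which field to write (`"cds"` or `"mrna"`; records with an
#'   empty mRNA are skipped in mRNA mode).
#' @export
write_fasta_records <- function(records, path, what = c("cds", "mrna")) {
  what <- match.arg(what)
  records <- validate_sequence_records(records)
  seqs <- if (what == "cds") records$cds_seq else records$mrna_seq
  keep <- nzchar(seqs)
  set <- Biostrings::BStringSet(seqs[keep])
  names(set) <- record_headers(records)[keep]
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Manifest: the tabular inventory of a dataset.
# ---------------------------------------------------------------------------

manifest_columns <- c("gene_symbol", "species", "accession", "isoform_label",
                      "cds_length", "source")

#' Build a manifest from a record table
#'
#' @param records a `sequence_records` table.
#' @param source provenance label: `"fixture"`, `"live"` or `"simulated"`.
#' @return A `data.frame` with columns
#'   `gene_symbol, species, accession, isoform_label, cds_length, source`.
#' @export
manifest_from_records <- function(records,
                                  source = c("fixture", "live", "simulated")) {
  source <- match.arg(source)
  data.frame(gene_symbol = records$gene_symbol,
             species = records$species,
             accession = records$accession,
             isoform_label = records$isoform_label,
             cds_length = nchar(records$cds_seq),
             source = source,
             stringsAsFactors = FALSE)
}

#' Read / write a dataset manifest (TSV)
#'
#' The manifest is a tab-separated table with a fixed header row. Loading
#' validates the column set and that `cds_length` is integer; saving then
#' loading is the identity.
#'
#' @param path TSV path.
#' @return `load_manifest()` returns the manifest `data.frame`.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path))
    orthodiv_error(paste("cannot read manifest:", path), "orthodiv_io_error")
  df <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                   check.names = FALSE)
  miss <- setdiff(manifest_columns, names(df))
  if (length(miss))
    orthodiv_error(paste("manifest missing column(s):",
                         paste(miss, collapse = ", ")),
                   "orthodiv_parse_error")
  df <- df[, manifest_columns]
  len <- suppressWarnings(as.numeric(df$cds_length))
  if (any(is.na(len)) || any(len != round(len)) || any(len < 0))
    orthodiv_error("manifest cds_length must be a non-negative integer",
                   "orthodiv_parse_error")
  df$cds_length <- as.integer(len)
  df
}

#' @rdname load_manifest
#' @param manifest a manifest `data.frame`.
#' @export
save_manifest <- function(manifest, path) {
  miss <- setdiff(manifest_columns, names(manifest))
  if (length(miss))
    orthodiv_error(paste("manifest missing column(s):",
                         paste(miss, collapse = ", ")),
                   "orthodiv_parse_error")
  write.table(manifest[, manifest_columns], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check a manifest against its record table
#'
#' Errors unless every manifest row's `cds_length` equals the stored CDS
#' length of the matching record.
#'
#' @param manifest a manifest `data.frame`.
#' @param records the `sequence_records` it describes.
#' @export
validate_manifest <- function(manifest, records) {
  key_m <- paste(manifest$gene_symbol, manifest$species, manifest$accession)
  key_r <- paste(records$gene_symbol, records$species, records$accession)
  hit <- match(key_m, key_r)
  if (any(is.na(hit)))
    orthodiv_error(sprintf("manifest row without record: %s",
                           key_m[is.na(hit)][1]), "orthodiv_parse_error")
  actual <- nchar(records$cds_seq)[hit]
  bad <- which(manifest$cds_length != actual)
  if (length(bad))
    orthodiv_error(sprintf(
      "manifest cds_length %d != sequence length %d for %s",
      manifest$cds_length[bad[1]], actual[bad[1]], key_m[bad[1]]),
      "orthodiv_validation_error")
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Acquisition backends. The fixture backend is the one the analyses and
# tests use: a directory containing cds.fasta (+ optional mrna.fasta) and
# manifest.tsv, loaded once at construction, so acquisition is a pure
# function of the directory contents.
# ---------------------------------------------------------------------------

#' Offline acquisition backend over a fixture directory
#'
#' @param dir directory containing `cds.fasta`, `manifest.tsv` and optionally
#'   `mrna.fasta`.
#' @return A backend object usable with [fetch_gene_records()].
#' @export
fixture_backend <- function(dir) {
  if (!dir.exists(dir))
    orthodiv_error(paste("fixture directory not found:", dir),
                   "orthodiv_acquisition_error")
  records <- read_fasta_records(file.path(dir, "cds.fasta"))
  mrna <- file.path(dir, "mrna.fasta")
  if (file.exists(mrna)) records <- attach_mrna(records, mrna)
  manifest <- load_manifest(file.path(dir, "manifest.tsv"))
  validate_manifest(manifest, records)
  structure(list(dir = dir, records = records, manifest = manifest),
            class = c("fixture_backend", "acquisition_backend"))
}

#' Fetch all sequence records for one gene x species
#'
#' Returns every mRNA/CDS product the backend holds for the query, as a
#' (possibly zero-row) `sequence_records` table. An absent gene is not an
#' error. Mirrors the gene-search -> RefSeq -> record extraction workflow
#' used to assemble ortholog datasets from annotated genomes, with the
#' network replaced by a fixture for reproducibility.
#'
#' @param gene_symbol,species the query (both non-empty).
#' @param backend a backend from [fixture_backend()] or [live_backend()].
#' @return A `sequence_records` table.
#' @export
fetch_gene_records <- function(gene_symbol, species, backend) {
  if (!nzchar(gene_symbol) || !nzchar(species))
    orthodiv_error("gene_symbol and species must be non-empty",
                   "orthodiv_acquisition_error")
  UseMethod("fetch_gene_records", backend)
}

#' @export
fetch_gene_records.fixture_backend <- function(gene_symbol, species, backend) {
  r <- backend$records
  out <- r[r$gene_symbol == gene_symbol & r$species == species, ,
           drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sequence_records", "data.frame")
  out
}

#' @export
fetch_gene_records.default <- function(gene_symbol, species, backend) {
  orthodiv_error("not an acquisition backend", "orthodiv_acquisition_error")
}

#' Select the analysis product among a gene's isoforms
#'
#' When a gene x species has several mRNA/CDS products, the `"X1"` isoform is
#' used when present; otherwise the record with the longest CDS, with ties
#' broken by the lexicographically smallest accession. The choice is
#' invariant under permutation of the input rows.
#'
#' @param records a non-empty `sequence_records` table, all rows the same
#'   gene x species.
#' @return A single-row `sequence_records` table.
#' @export
select_product <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    orthodiv_error("select_product needs at least one record",
                   "orthodiv_precondition_error")
  if (length(unique(records$gene_symbol)) != 1L ||
      length(unique(records$species)) != 1L)
    orthodiv_error("records span more than one gene x species",
                   "orthodiv_precondition_error")
  ord <- order(records$isoform_label != "X1",       # X1 first
               -nchar(records$cds_seq),             # then longest CDS
               records$accession, method = "radix") # then smallest accession
  out <- records[ord[1L], , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sequence_records", "data.frame")
  out
}
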