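# Optional live acquisition backend against NCBI E-utilities. Experimental:
# requires network access and the xml2 package, and is deliberately not
# exercised by the test suite — all tested workflows use fixture_backend().

#' Live NCBI E-utilities acquisition backend (experimental)
#'
#' Thin adapter implementing the same contract as [fixture_backend()]:
#' gene-symbol search on the Gene database, gene report download, extraction
#' of RefSeq mRNA accessions, then per-accession retrieval of the mRNA and
#' CDS from Nuccore. Requires network access; intended for assembling real
#' datasets interactively, never for automated tests.
#'
#' @param base_url E-utilities base URL.
#' @param delay seconds to sleep between requests (NCBI rate etiquette).
#' @return A backend object usable with [fetch_gene_records()].
#' @export
live_backend <- function(base_url = "https://eutils.ncbi.nlm.nih.gov/entrez/eutils",
                         delay = 0.4) {
  if (!requireNamespace("xml2", quietly = TRUE))
    orthodiv_error("live_backend requires the xml2 package",
                   "orthodiv_acquisition_error")
  structure(list(base_url = base_url, delay = delay),
            class = c("live_backend", "acquisition_backend"))
}

eutils_get <- function(backend, endpoint, params) {
  url <- paste0(backend$base_url, "/", endpoint, "?",
                paste(names(params), vapply(params, utils::URLencode,
                                            character(1), reserved = TRUE),
                      sep = "=", collapse = "&"))
  Sys.sleep(backend$delay)
  tryCatch(paste(readLines(url, warn = FALSE), collapse = "\n"),
           error = function(e) orthodiv_error(
             sprintf("E-utilities request failed (%s): %s",
                     endpoint, conditionMessage(e)),
             "orthodiv_acquisition_error"))
}

#' @export
fetch_gene_records.live_backend <- function(gene_symbol, species, backend) {
  term <- sprintf('%s[Gene Name] AND "%s"[Organism]', gene_symbol, species)
  hits <- xml2::read_xml(eutils_get(backend, "esearch.fcgi",
                                    list(db = "gene", term = term,
                                         retmax = "20")))
  gene_ids <- xml2::xml_text(xml2::xml_find_all(hits, "//IdList/Id"))
  if (!length(gene_ids)) return(sequence_records(character(0), character(0),
                                                 character(0),
                                                 cds_seq = character(0)))
  out <- list()
  for (gid in gene_ids) {
    rep <- xml2::read_xml(eutils_get(backend, "efetch.fcgi",
                                     list(db = "gene", id = gid,
                                          retmode = "xml")))
    accs <- unique(xml2::xml_text(xml2::xml_find_all(
      rep, "//Gene-commentary[Gene-commentary_type[@value='mRNA']]/Gene-commentary_accession")))
    for (acc in accs) {
      gb <- xml2::read_xml(eutils_get(backend, "efetch.fcgi",
                                      list(db = "nuccore", id = acc,
                                           rettype = "gbc", retmode = "xml")))
      mrna <- xml2::xml_text(xml2::xml_find_first(gb, "//INSDSeq_sequence"))
      if (is.na(mrna) || !nzchar(mrna)) next
      feats <- xml2::xml_find_all(gb, "//INSDFeature[INSDFeature_key='CDS']")
      if (!length(feats)) next
      loc <- xml2::xml_text(xml2::xml_find_first(feats[[1]],
                                                 "INSDFeature_location"))
      rng <- regmatches(loc, regexec("(\\d+)\\.\\.(\\d+)", loc))[[1]]
      if (length(rng) != 3L) next
      from <- as.integer(rng[2]); to <- as.integer(rng[3])
      cds <- substr(mrna, from, to)
      iso <- regmatches(acc, regexpr("X\\d+$", acc))
      out[[length(out) + 1L]] <- sequence_records(
        gene_symbol = gene_symbol, species = species, accession = acc,
        isoform_label = if (length(iso)) iso else "",
        mrna_seq = mrna, cds_seq = cds)
    }
  }
  if (!length(out)) return(sequence_records(character(0), character(0),
                                            character(0),
                                            cds_seq = character(0)))
  validate_sequence_records(do.call(rbind, out))
}
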