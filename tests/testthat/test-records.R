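test_that("FASTA round-trip preserves headers and normalized sequences", {
  recs <- sequence_records(
    gene_symbol = c("CD4", "CD4", "IL2"),
    species = c("Oryctolagus cuniculus", "Oryctolagus cuniculus",
                "Homo sapiens"),
    accession = c("SYN-1", "SYN-2", "SYN-3"),
    isoform_label = c("X1", "X2", ""),
    cds_seq = c("atgaaacgu", "ATGCCC", "ATGNNNTTT"))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_records(recs, path)
  back <- read_fasta_records(path)
  expect_equal(as.data.frame(back), as.data.frame(recs))
  # normalization happened on construction: lowercase + U -> T
  expect_equal(recs$cds_seq[1], "ATGAAACGT")
})

test_that("malformed FASTA input is rejected with the offending header", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">G|Homo sapiens|A1|X1", "ATG",
               ">G|Homo sapiens|A1|X1", "ATG"), path)
  expect_error(read_fasta_records(path), "duplicate.*line",
               class = "orthodiv_parse_error")
  writeLines(c(">G|Homo sapiens|A1|X1", "ATG",
               ">H|Homo sapiens|A2|X1"), path)
  expect_error(read_fasta_records(path), "empty sequence.*H\\|Homo",
               class = "orthodiv_parse_error")
  writeLines(c(">broken header", "ATG"), path)
  expect_error(read_fasta_records(path), "GENE\\|Species",
               class = "orthodiv_parse_error")
})

test_that("record validation enforces alphabet, non-emptiness and key uniqueness", {
  expect_error(sequence_records("G", "Homo sapiens", "A1", cds_seq = "ATGQ"),
               "invalid character")
  expect_error(sequence_records("G", "Homo sapiens", "A1", cds_seq = ""),
               class = "orthodiv_parse_error")
  expect_error(sequence_records(c("G", "G"), "Homo sapiens", c("A1", "A1"),
                                cds_seq = c("ATG", "ATGCCC")),
               "duplicate", class = "orthodiv_parse_error")
})

test_that("manifest round-trips and validates lengths", {
  recs <- sequence_records(
    gene_symbol = sprintf("G%02d", 1:10), species = "Mus musculus",
    accession = sprintf("SYN-%02d", 1:10), isoform_label = "X1",
    cds_seq = vapply(1:10, function(i) strrep("ATG", i + 1), character(1)))
  man <- manifest_from_records(recs, source = "fixture")
  path <- withr::local_tempfile(fileext = ".tsv")
  save_manifest(man, path)
  expect_identical(load_manifest(path), man)
  expect_true(validate_manifest(man, recs))

  bad <- man
  bad$cds_length[3] <- bad$cds_length[3] + 1L
  expect_error(validate_manifest(bad, recs), "cds_length",
               class = "orthodiv_validation_error")

  writeLines(c("gene_symbol\tspecies", "G\tX"), path)
  expect_error(load_manifest(path), "missing column",
               class = "orthodiv_parse_error")
  writeLines(paste(c("gene_symbol", "species", "accession", "isoform_label",
                     "cds_length", "source"), collapse = "\t"), path)
  writeLines(c(readLines(path), "G\tS\tA\tX1\tabc\tfixture"), path)
  expect_error(load_manifest(path), "integer",
               class = "orthodiv_parse_error")
})

test_that("fixture backend returns every product for a query, empty for absent genes", {
  backend <- fixture_backend(worked_fixture_dir())
  recs <- fetch_gene_records("CD14", "Oryctolagus cuniculus", backend)
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$accession, "SYN-CD14-OC")
  expect_equal(nchar(recs$cds_seq), 180L)
  expect_equal(nrow(fetch_gene_records("NOSUCHGENE", "Mus musculus", backend)),
               0L)
  expect_error(fetch_gene_records("", "Mus musculus", backend),
               class = "orthodiv_acquisition_error")
})

test_that("acquisition round-trips a generated fixture (manifest lengths match)", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_genes = 6, length_min = 90, length_max = 150,
                           seed = 11)
  sim <- generate_dataset(cfg, dir)
  backend <- fixture_backend(dir)
  man <- backend$manifest
  expect_equal(nrow(man), 6L * 3L) # n_genes x n_species
  for (k in seq_len(nrow(man))) {
    r <- fetch_gene_records(man$gene_symbol[k], man$species[k], backend)
    expect_equal(nchar(r$cds_seq[r$accession == man$accession[k]]),
                 man$cds_length[k])
  }
  # pure function of the directory contents
  expect_identical(fixture_backend(dir)$records, backend$records)
})

test_that("select_product prefers X1, falls back to longest CDS then smallest accession", {
  mk <- function(acc, label, len) sequence_records(
    "G", "Homo sapiens", acc, isoform_label = label,
    cds_seq = strrep("A", len))
  x1  <- mk("B9", "X1", 300)
  x2  <- mk("A1", "X2", 450)
  x3  <- mk("C3", "X3", 300)
  sel <- select_product(rbind(x2, x1))
  expect_equal(sel$isoform_label, "X1")

  # no X1: longest CDS wins
  expect_equal(select_product(rbind(x3, x2))$accession, "A1")
  # tie on length: smallest accession
  expect_equal(select_product(rbind(x3, mk("A7", "X5", 300)))$accession, "A7")
  # singleton
  one <- mk("Z1", "", 90)
  expect_equal(select_product(one)$accession, "Z1")

  # permutation invariance
  pool <- rbind(x1, x2, x3)
  set.seed(5)
  for (i in 1:10) {
    perm <- pool[sample(nrow(pool)), ]
    expect_equal(select_product(perm)$accession, "B9")
  }
  expect_error(select_product(pool[0, ]),
               class = "orthodiv_precondition_error")
})
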