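test_that("CDS translation follows the standard code with the stated edge rules", {
  expect_equal(translate_cds("ATGAAATAA"), "MK")     # trailing stop trimmed
  expect_equal(translate_cds("ATGGCN"), "MX")        # N codon is always X
  expect_warning(aa <- translate_cds("ATGAAAGG"), "incomplete codon")
  expect_equal(aa, "MK")
  expect_error(translate_cds("ATGTAAAAA"), "codon 2",
               class = "orthodiv_translation_error")
  expect_error(translate_cds("AT"), class = "orthodiv_precondition_error")
})

test_that("translation matches a literal codon-table oracle on random ORFs", {
  set.seed(91)
  for (i in 1:50) {
    orf <- simulate_ancestor(3 * sample(5:60, 1))
    expect_equal(translate_cds(orf), translate_oracle(orf))
  }
  # including sequences with N codons
  expect_equal(translate_cds("ATGNNTCCGTAA"), translate_oracle("ATGNNTCCGTAA"))
})

test_that("pairwise p-distance excludes gaps and ambiguities pair-specifically", {
  p <- p_distance_pair("ACGT", "ACGA")
  expect_equal(p$distance, 0.25)
  expect_equal(p$n_compared, 4L)

  p <- p_distance_pair("AC-T", "ACGT")
  expect_equal(p$distance, 0.0)
  expect_equal(p$n_compared, 3L)

  p <- p_distance_pair("ANGT", "ACGT")
  expect_equal(p$distance, 0.0)
  expect_equal(p$n_compared, 3L)

  # gap-only deletion keeps the N site (and counts it as a difference)
  p <- p_distance_pair("ANGT", "ACGT", exclude_ambiguous = FALSE)
  expect_equal(p$n_compared, 4L)
  expect_equal(p$distance, 0.25)

  # amino-acid mode: X is the ambiguity symbol
  p <- p_distance_pair("MKX", "MRL", mode = "amino_acid")
  expect_equal(p$n_compared, 2L)
  expect_equal(p$distance, 0.5)

  expect_error(p_distance_pair("A-", "-A"),
               class = "orthodiv_undefined_distance")
  expect_error(p_distance_pair("ACG", "AC"),
               class = "orthodiv_precondition_error")
})

test_that("p-distance pair properties: symmetry, gapped-column insertion is a no-op", {
  set.seed(92)
  for (i in 1:50) {
    n <- sample(10:50, 1)
    a <- random_dna(n); b <- random_dna(n)
    pa <- p_distance_pair(a, b)
    pb <- p_distance_pair(b, a)
    expect_equal(pa$distance, pb$distance)
    expect_equal(pa$n_compared, pb$n_compared)
    # insert a column gapped in one row: excluded, so nothing changes
    k <- sample(n, 1)
    a2 <- paste0(substr(a, 1, k), "-", substr(a, k + 1, n))
    b2 <- paste0(substr(b, 1, k), "G", substr(b, k + 1, n))
    p2 <- p_distance_pair(a2, b2)
    expect_equal(p2$distance, pa$distance)
    expect_equal(p2$n_compared, pa$n_compared)
  }
})

test_that("distance matrix is symmetric with zero diagonal and hand-countable values", {
  aln <- aligned_set(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT"))
  expect_true(all(p_distance_matrix(aln)$values == 0))

  aln <- aligned_set(c(a = "AAAA", b = "AAAT", c = "TTTT"))
  dm <- p_distance_matrix(aln)
  expect_equal(dm$values["a", "b"], 0.25)
  expect_equal(dm$values["a", "c"], 1.0)
  expect_equal(dm$values["b", "c"], 0.75)
  expect_identical(dm$values, t(dm$values))
  expect_true(all(diag(dm$values) == 0))
})

test_that("nucleotide p-distance agrees with ape's raw pairwise-deletion distance", {
  skip_if_not_installed("ape")
  set.seed(93)
  rows <- c(h = random_dna(120), r = random_dna(120), m = random_dna(120))
  # punch a few shared gaps so pairwise deletion is exercised
  substr(rows["r"], 10, 12) <- "---"
  substr(rows["m"], 50, 52) <- "---"
  dm <- p_distance_matrix(aligned_set(rows))
  bin <- ape::as.DNAbin(lapply(rows, function(s) strsplit(tolower(s), "")[[1]]))
  ref <- as.matrix(ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE))
  expect_equal(dm$values[rownames(ref), colnames(ref)], ref,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("for gapless ambiguity-free pairs, p-distance equals 1 - similarity exactly", {
  set.seed(94)
  for (i in 1:25) {
    anc <- simulate_ancestor(3 * sample(40:80, 1))
    des <- evolve_sequence(anc, sub_prob = 0.1)$seq # no indels
    a <- align_local(des, anc)
    # full-length gapless alignment expected at this divergence
    expect_equal(a$n_gap_columns, 0L)
    p <- p_distance_pair(a$aligned_query, a$aligned_ref)
    expect_equal(p$distance, 1 - similarity_score(a), tolerance = 1e-12)
  }
})

test_that("mean p-distance matches the per-site substitution probability", {
  set.seed(95)
  q <- 0.1
  d <- replicate(100, {
    anc <- simulate_ancestor(999)
    des <- evolve_sequence(anc, sub_prob = q)$seq
    p_distance_pair(des, anc)$distance
  })
  se <- sqrt(q * (1 - q) / 999) / sqrt(100)
  expect_lt(abs(mean(d) - q), 3 * se)
})

test_that("distance matrix TSV round-trips through the report writer", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "aln.fasta")
  writeLines(c(">h", "ACGTACGT", ">r", "ACGTACGA", ">m", "AC-TACGA"), fa)
  out <- file.path(dir, "dist.tsv")
  dm <- pdist_report(fa, "nucleotide", out)
  expect_true(file.exists(out))
  expect_true(file.exists(file.path(dir, "dist_n_sites.tsv")))
  back <- read.delim(out, check.names = FALSE)
  expect_equal(back$h, unname(dm$values[, "h"]))
})
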