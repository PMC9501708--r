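test_that("ancestors are ORF-like: start codon, sense codons only, deterministic", {
  set.seed(21)
  s <- simulate_ancestor(9)
  expect_equal(nchar(s), 9L)
  expect_equal(substr(s, 1, 3), "ATG")
  expect_error(simulate_ancestor(10), class = "orthodiv_precondition_error")

  # stop-free property over many draws
  set.seed(22)
  for (i in 1:200) {
    s <- simulate_ancestor(3 * sample(2:80, 1))
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
  }

  set.seed(23); a <- simulate_ancestor(300)
  set.seed(23); b <- simulate_ancestor(300)
  expect_identical(a, b)
})

test_that("evolution respects the identity limit and binomial concentration", {
  set.seed(24)
  anc <- simulate_ancestor(300)
  ev <- evolve_sequence(anc, sub_prob = 0, indel_prob = 0)
  expect_identical(ev$seq, anc)
  expect_equal(ev$n_subs, 0L)

  expect_error(simulation_config(sub_prob_mouse = 1.0),
               class = "orthodiv_precondition_error")
  expect_error(evolve_sequence(anc, sub_prob = 0.9),
               class = "orthodiv_precondition_error")

  set.seed(25)
  long <- simulate_ancestor(10002)
  ev <- evolve_sequence(long, sub_prob = 0.1)
  frac <- ev$n_subs / nchar(long)
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / nchar(long)))
  # realized count consistent with a direct diff against the ancestor
  expect_equal(ev$n_subs,
               sum(strsplit(ev$seq, "")[[1]] != strsplit(long, "")[[1]]))
})

test_that("indels are codon-aligned, at most one per lineage, and recorded faithfully", {
  set.seed(26)
  n_indels <- 0L
  for (i in 1:50) {
    anc <- simulate_ancestor(300)
    ev <- evolve_sequence(anc, sub_prob = 0, indel_prob = 1,
                          indel_len_max = 9)
    expect_lte(nrow(ev$indels), 1L)
    if (nrow(ev$indels)) {
      n_indels <- n_indels + 1L
      expect_equal(ev$indels$position %% 3L, 1L)
      expect_equal(ev$indels$length %% 3L, 0L)
      expected_len <- nchar(anc) +
        ifelse(ev$indels$type == "insertion", 1, -1) * ev$indels$length
      expect_equal(nchar(ev$seq), expected_len)
      # descendant still translates (codon-aligned events, sense insertions)
      expect_no_error(translate_cds(ev$seq))
    }
  }
  expect_gt(n_indels, 40L) # indel_prob = 1 almost always realizes an event
})

test_that("generated datasets are byte-identical across runs for a fixed config", {
  cfg <- simulation_config(n_genes = 5, length_min = 120, length_max = 240,
                           indel_prob = 0.3, decoy_isoforms = TRUE, seed = 1)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_dataset(cfg, d1)
  generate_dataset(cfg, d2)
  for (f in c("cds.fasta", "manifest.tsv", "truth.tsv", "ancestors.fasta"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  # decoys: every third gene carries an X2 isoform of the reference species
  man <- load_manifest(file.path(d1, "manifest.tsv"))
  expect_equal(sum(man$isoform_label == "X2"), 1L) # genes 3 of 1..5
})

test_that("truth table substitution counts are recoverable by diffing against the ancestor", {
  cfg <- simulation_config(n_genes = 8, length_min = 300, length_max = 300,
                           indel_prob = 0, seed = 31)
  sim <- simulate_triplets(cfg)
  for (k in seq_len(nrow(sim$truth))) {
    row <- sim$truth[k, ]
    anc <- strsplit(sim$ancestors[[row$gene_symbol]], "")[[1]]
    des <- sim$records$cds_seq[sim$records$gene_symbol == row$gene_symbol &
                                 sim$records$species == row$species]
    expect_equal(sum(strsplit(des, "")[[1]] != anc), row$n_subs)
  }
})

test_that("swapping the two branch rates mirrors the category counts", {
  base <- simulation_config(n_genes = 120, length_min = 600, length_max = 600,
                            sub_prob_ref = 0.05, sub_prob_rabbit = 0.05,
                            sub_prob_mouse = 0.15, indel_prob = 0, seed = 33)
  swap <- simulation_config(n_genes = 120, length_min = 600, length_max = 600,
                            sub_prob_ref = 0.05, sub_prob_rabbit = 0.15,
                            sub_prob_mouse = 0.05, indel_prob = 0, seed = 34)
  frac_first <- function(cfg) {
    dir <- withr::local_tempdir(); out <- withr::local_tempdir()
    generate_dataset(cfg, dir)
    res <- run_pipeline(run_config(input_dir = dir, out_dir = out,
                                   make_plot = FALSE))
    s <- res$summary[res$summary$threshold == 0, ]
    s$frac_rabbit_closer
  }
  f1 <- suppressMessages(frac_first(base))
  f2 <- suppressMessages(frac_first(swap))
  # exchangeability up to Monte-Carlo noise (3 binomial SEs at n = 120)
  expect_lt(abs(f1 - (1 - f2)), 3 * sqrt(0.5 * 0.5 / 120) * 2)
})
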