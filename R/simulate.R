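# Branch-specific sequence-evolution simulator. Emulates ortholog triplets:
# an ancestral ORF evolved independently down a reference branch and two
# comparison branches ("rabbit", "mouse"), with per-branch substitution
# probabilities and optional codon-aligned indels. The scenario of interest
# is an accelerated second branch — the proposed mechanism behind unequal
# divergence of two lineages that split from the reference at the same time.

STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

SENSE_CODONS <- setdiff(all_codons(), STOP_CODONS)

#' Simulation configuration
#'
#' Parameters of the ortholog-triplet simulator. Defaults emulate the
#' rate-acceleration scenario: the second ("mouse") branch substitutes at
#' twice the per-site probability of the first ("rabbit") branch, with the
#' reference branch evolving at the first branch's rate. Substitution
#' probabilities are per site on `[0, 0.75)` (0.75 is the saturation limit
#' of a uniform 4-letter model); `indel_prob` is the per-gene, per-lineage
#' probability of one codon-aligned indel event.
#'
#' @param n_genes number of ortholog triplets.
#' @param length_min,length_max CDS length bounds, multiples of 3.
#' @param sub_prob_ref,sub_prob_rabbit,sub_prob_mouse per-site substitution
#'   probabilities of the reference, first and second comparison branches.
#' @param indel_prob per-gene probability of one indel per lineage.
#' @param indel_len_max maximum indel length, a multiple of 3 (>= 3).
#' @param decoy_isoforms also emit a truncated `"X2"` decoy isoform for the
#'   reference species of every third gene, to exercise isoform selection.
#' @param seed integer RNG seed; the whole dataset is a deterministic
#'   function of the configuration.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_genes = 100L,
                              length_min = 300L, length_max = 1500L,
                              sub_prob_ref = 0.08,
                              sub_prob_rabbit = 0.08,
                              sub_prob_mouse = 0.16,
                              indel_prob = 0.1,
                              indel_len_max = 9L,
                              decoy_isoforms = FALSE,
                              seed = 42L) {
  if (n_genes < 1L) orthodiv_error("n_genes must be >= 1",
                                   "orthodiv_precondition_error")
  if (length_min %% 3L || length_max %% 3L || length_min < 3L ||
      length_min > length_max)
    orthodiv_error("lengths must be multiples of 3 with length_min <= length_max",
                   "orthodiv_precondition_error")
  probs <- c(sub_prob_ref, sub_prob_rabbit, sub_prob_mouse)
  if (any(probs < 0 | probs >= 0.75))
    orthodiv_error("substitution probabilities must lie in [0, 0.75)",
                   "orthodiv_precondition_error")
  if (indel_prob < 0 || indel_prob >= 1)
    orthodiv_error("indel_prob must lie in [0, 1)",
                   "orthodiv_precondition_error")
  if (indel_len_max < 3L || indel_len_max %% 3L)
    orthodiv_error("indel_len_max must be a multiple of 3, >= 3",
                   "orthodiv_precondition_error")
  structure(list(n_genes = as.integer(n_genes),
                 length_min = as.integer(length_min),
                 length_max = as.integer(length_max),
                 sub_prob_ref = sub_prob_ref,
                 sub_prob_rabbit = sub_prob_rabbit,
                 sub_prob_mouse = sub_prob_mouse,
                 indel_prob = indel_prob,
                 indel_len_max = as.integer(indel_len_max),
                 decoy_isoforms = isTRUE(decoy_isoforms),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Draw an ancestral ORF-like coding sequence
#'
#' Starts with `ATG`; the remaining codons are sampled uniformly from the 61
#' sense codons, so the sequence contains no internal stop codon and
#' translates cleanly. Uses the current R RNG state.
#'
#' @param length total length in nt, a multiple of 3, >= 3.
#' @return A nucleotide string.
#' @export
simulate_ancestor <- function(length) {
  if (length < 3L || length %% 3L)
    orthodiv_error("ancestor length must be a positive multiple of 3",
                   "orthodiv_precondition_error")
  n_codons <- length %/% 3L
  body <- if (n_codons > 1L)
    sample(SENSE_CODONS, n_codons - 1L, replace = TRUE) else character(0)
  paste0("ATG", paste(body, collapse = ""))
}

BASES <- c("A", "C", "G", "T")

#' Evolve a sequence along one branch
#'
#' Each site is substituted independently with probability `sub_prob` to a
#' uniformly chosen *different* base. With probability `indel_prob` one
#' codon-aligned indel is applied: a deletion of whole codons (never the
#' initial ATG) or an insertion of random sense codons, of length
#' `3, 6, ..., indel_len_max` chosen uniformly. Draw order (one RNG stream):
#' substitution mask, substitution targets, indel occurrence, indel type,
#' indel length, indel position, insertion content.
#'
#' @param seq ancestor nucleotide string.
#' @param sub_prob per-site substitution probability in `[0, 0.75)`.
#' @param indel_prob per-call probability of one indel event.
#' @param indel_len_max maximum indel length (multiple of 3).
#' @return A list: `seq` (descendant), `n_subs` (realized substitution
#'   count), `indels` (data.frame of `position, length, type`, possibly
#'   empty; positions are 1-based in the pre-indel coordinate).
#' @export
evolve_sequence <- function(seq, sub_prob, indel_prob = 0,
                            indel_len_max = 9L) {
  if (sub_prob < 0 || sub_prob >= 0.75)
    orthodiv_error("sub_prob must lie in [0, 0.75)",
                   "orthodiv_precondition_error")
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  mask <- runif(n) < sub_prob
  n_subs <- sum(mask)
  if (n_subs) {
    # uniformly one of the three other bases per substituted site
    pick <- sample.int(3L, n_subs, replace = TRUE)
    for (k in seq_len(n_subs)) {
      i <- which(mask)[k]
      chars[i] <- setdiff(BASES, chars[i])[pick[k]]
    }
  }
  indels <- data.frame(position = integer(0), length = integer(0),
                       type = character(0), stringsAsFactors = FALSE)
  if (indel_prob > 0 && runif(1) < indel_prob) {
    type <- if (runif(1) < 0.5) "deletion" else "insertion"
    len <- 3L * sample.int(indel_len_max %/% 3L, 1L)
    n_codons <- n %/% 3L
    if (type == "deletion" && n_codons - 1L >= len %/% 3L) {
      # delete whole codons, never the initial one
      first <- 1L + sample.int(n_codons - len %/% 3L, 1L)
      pos <- (first - 1L) * 3L + 1L
      chars <- chars[-(pos:(pos + len - 1L))]
      indels <- rbind(indels, data.frame(position = pos, length = len,
                                         type = type))
    } else if (type == "insertion") {
      after_codon <- sample.int(n_codons, 1L)
      pos <- after_codon * 3L + 1L
      ins <- strsplit(paste(sample(SENSE_CODONS, len %/% 3L, replace = TRUE),
                            collapse = ""), "")[[1]]
      chars <- append(chars, ins, after = pos - 1L)
      indels <- rbind(indels, data.frame(position = pos, length = len,
                                         type = type))
    }
  }
  list(seq = paste(chars, collapse = ""), n_subs = n_subs, indels = indels)
}

SIM_SPECIES <- c(reference = "Homo sapiens",
                 rabbit = "Oryctolagus cuniculus",
                 mouse = "Mus musculus")

#' Simulate a set of ortholog triplets in memory
#'
#' For each gene an ancestral ORF is drawn and evolved independently down
#' the reference, "rabbit" and "mouse" branches (in that order, one RNG
#' stream seeded from the config). Species names follow the motivating
#' study; they are labels for the three branch roles.
#'
#' @param config a [simulation_config()].
#' @return A list: `records` (a `sequence_records` table), `truth` (per
#'   gene x lineage: `gene_symbol, lineage, species, n_subs, indels` with
#'   indels encoded `pos:len:type`), `ancestors` (named character vector),
#'   `config`.
#' @export
simulate_triplets <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  sub_probs <- c(config$sub_prob_ref, config$sub_prob_rabbit,
                 config$sub_prob_mouse)
  n_len <- (config$length_max - config$length_min) %/% 3L + 1L
  recs <- vector("list", config$n_genes * 4L)
  truth <- vector("list", config$n_genes * 3L)
  ancestors <- character(config$n_genes)
  width <- max(4L, nchar(as.character(config$n_genes)))
  for (g in seq_len(config$n_genes)) {
    gene <- sprintf("GENE%0*d", width, g)
    len <- config$length_min + 3L * (sample.int(n_len, 1L) - 1L)
    anc <- simulate_ancestor(len)
    ancestors[g] <- anc
    names(ancestors)[g] <- gene
    for (k in 1:3) {
      ev <- evolve_sequence(anc, sub_probs[k], config$indel_prob,
                            config$indel_len_max)
      sp <- SIM_SPECIES[[k]]
      acc <- sprintf("SIM-%s-%s", gene, c("HS", "OC", "MM")[k])
      recs[[(g - 1L) * 4L + k]] <- data.frame(
        gene_symbol = gene, species = sp, accession = acc,
        isoform_label = "X1", mrna_seq = "", cds_seq = ev$seq,
        stringsAsFactors = FALSE)
      truth[[(g - 1L) * 3L + k]] <- data.frame(
        gene_symbol = gene, lineage = names(SIM_SPECIES)[k], species = sp,
        n_subs = ev$n_subs,
        indels = if (nrow(ev$indels)) paste(
          sprintf("%d:%d:%s", ev$indels$position, ev$indels$length,
                  ev$indels$type), collapse = ";") else "",
        stringsAsFactors = FALSE)
    }
    if (config$decoy_isoforms && g %% 3L == 0L) {
      # deterministic truncated decoy (no RNG draws): first 60% of codons
      ref_seq <- recs[[(g - 1L) * 4L + 1L]]$cds_seq
      keep <- max(2L, floor(nchar(ref_seq) / 3L * 0.6)) * 3L
      recs[[(g - 1L) * 4L + 4L]] <- data.frame(
        gene_symbol = gene, species = SIM_SPECIES[["reference"]],
        accession = sprintf("SIM-%s-HS2", gene), isoform_label = "X2",
        mrna_seq = "", cds_seq = substr(ref_seq, 1L, keep),
        stringsAsFactors = FALSE)
    }
  }
  records <- validate_sequence_records(
    do.call(rbind, recs[!vapply(recs, is.null, logical(1))]))
  list(records = records, truth = do.call(rbind, truth),
       ancestors = ancestors, config = config)
}

#' Generate a simulated fixture dataset on disk
#'
#' Runs [simulate_triplets()] and writes a fixture directory consumable by
#' [fixture_backend()]: `cds.fasta`, `manifest.tsv`, the ground-truth table
#' `truth.tsv` and the ancestral sequences `ancestors.fasta`. Byte-identical
#' across runs for a fixed configuration.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the [simulate_triplets()] result.
#' @export
generate_dataset <- function(config, dir) {
  sim <- simulate_triplets(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta_records(sim$records, file.path(dir, "cds.fasta"))
  save_manifest(manifest_from_records(sim$records, source = "simulated"),
                file.path(dir, "manifest.tsv"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  anc <- Biostrings::BStringSet(sim$ancestors)
  Biostrings::writeXStringSet(anc, file.path(dir, "ancestors.fasta"),
                              width = 60L)
  invisible(sim)
}
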