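# End-to-end driver: load records through a backend, select one product per
# gene x species, align comparison species against the reference, compute
# similarities and relative divergences, filter, categorise per threshold,
# and write TSV/plot/JSON reports. Replaces interactive visualization with
# static, diffable outputs.

#' Run configuration
#'
#' @param input_dir fixture directory (see [fixture_backend()]).
#' @param out_dir output directory for reports.
#' @param reference_species reference species name.
#' @param comparison_species two species compared against the reference;
#'   order defines the sign of `delta`.
#' @param min_alignment_length strict lower bound on per-gene minimum
#'   aligned length (default 150 bp).
#' @param thresholds non-negative, sorted `|delta|` thresholds.
#' @param scoring a [scoring_scheme()].
#' @param seed integer seed (recorded in the run report; the analysis itself
#'   is deterministic).
#' @param make_plot write the delta histogram PNG (default TRUE).
#' @return A `run_config` object.
#' @export
run_config <- function(input_dir, out_dir,
                       reference_species = "Homo sapiens",
                       comparison_species = c("Oryctolagus cuniculus",
                                              "Mus musculus"),
                       min_alignment_length = 150L,
                       thresholds = c(0, 0.05),
                       scoring = scoring_scheme(),
                       seed = 42L,
                       make_plot = TRUE) {
  if (reference_species %in% comparison_species)
    orthodiv_error("reference species cannot be a comparison species",
                   "orthodiv_config_error")
  if (length(comparison_species) != 2L)
    orthodiv_error("exactly two comparison species are required",
                   "orthodiv_config_error")
  if (any(thresholds < 0) || is.unsorted(thresholds))
    orthodiv_error("thresholds must be non-negative and sorted",
                   "orthodiv_config_error")
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 reference_species = reference_species,
                 comparison_species = comparison_species,
                 min_alignment_length = as.integer(min_alignment_length),
                 thresholds = as.numeric(thresholds),
                 scoring = scoring, seed = as.integer(seed),
                 make_plot = isTRUE(make_plot)),
            class = "run_config")
}

#' Read a run configuration from a flat key=value file
#'
#' One `key = value` pair per line; `#` starts a comment. Recognised keys:
#' `input_dir, out_dir, reference_species, comparison_species` (two names
#' separated by a comma), `min_alignment_length, thresholds` (comma list),
#' `match, mismatch, gap_open, gap_extend, seed, make_plot`. Unknown keys
#' are errors, so a typo cannot silently fall back to a default.
#'
#' @param path config file path.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    orthodiv_error(paste("config file not found:", path),
                   "orthodiv_config_error")
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", lines))
  if (any(lengths(kv) != 3L))
    orthodiv_error(sprintf("malformed config line: '%s'",
                           lines[lengths(kv) != 3L][1]),
                   "orthodiv_config_error")
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- trimws(vapply(kv, `[`, character(1), 3L))
  known <- c("input_dir", "out_dir", "reference_species",
             "comparison_species", "min_alignment_length", "thresholds",
             "match", "mismatch", "gap_open", "gap_extend", "seed",
             "make_plot")
  bad <- setdiff(keys, known)
  if (length(bad))
    orthodiv_error(paste("unknown config key(s):", paste(bad, collapse = ", ")),
                   "orthodiv_config_error")
  if (anyDuplicated(keys))
    orthodiv_error(paste("duplicate config key:", keys[duplicated(keys)][1]),
                   "orthodiv_config_error")
  get <- function(k, default = NULL) if (k %in% keys) vals[keys == k] else default
  num <- function(k, default) {
    v <- get(k)
    if (is.null(v)) return(default)
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x)) orthodiv_error(sprintf("config key '%s' must be numeric", k),
                                 "orthodiv_config_error")
    x
  }
  split_list <- function(v) trimws(strsplit(v, ",")[[1]])
  if (is.null(get("input_dir")) || is.null(get("out_dir")))
    orthodiv_error("config must set input_dir and out_dir",
                   "orthodiv_config_error")
  run_config(
    input_dir = get("input_dir"), out_dir = get("out_dir"),
    reference_species = get("reference_species", "Homo sapiens"),
    comparison_species = if (!is.null(get("comparison_species")))
      split_list(get("comparison_species"))
      else c("Oryctolagus cuniculus", "Mus musculus"),
    min_alignment_length = num("min_alignment_length", 150),
    thresholds = if (!is.null(get("thresholds")))
      as.numeric(split_list(get("thresholds"))) else c(0, 0.05),
    scoring = scoring_scheme(match = num("match", 2),
                             mismatch = num("mismatch", -3),
                             gap_open = num("gap_open", -5),
                             gap_extend = num("gap_extend", -2)),
    seed = num("seed", 42),
    make_plot = !identical(get("make_plot", "true"), "false"))
}

# deterministic numeric formatting for TSV output
fmt_num <- function(x) sprintf("%.10g", x)

write_tsv_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full relative-divergence pipeline
#'
#' Loads the fixture dataset, selects one product per gene x species
#' ([select_product()]), locally aligns each comparison species' CDS against
#' the reference CDS, computes similarities and per-gene `delta`, applies
#' the strict length filter, and summarises categories at each threshold.
#' Writes `per_gene.tsv`, `summary.tsv`, `run_report.json` and (optionally)
#' `delta_histogram.png` into `out_dir`; all tabular output is
#' byte-deterministic for fixed inputs and configuration.
#'
#' @param config a [run_config()] (or path handled by [read_run_config()]).
#' @return Invisibly, a list with `similarity` (per gene x species table),
#'   `comparisons`, `filtered`, `summary` (one row per threshold) and
#'   `counts` (genes at each stage: loaded, aligned, filtered, plus per
#'   threshold).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  backend <- fixture_backend(config$input_dir)
  species <- c(config$reference_species, config$comparison_species)
  genes <- sort(unique(backend$records$gene_symbol))
  msg <- function(...) message(sprintf(...))
  msg("[orthodiv] loaded %d records over %d genes from %s",
      nrow(backend$records), length(genes), config$input_dir)

  sims <- list()
  n_aligned_genes <- 0L
  for (gene in genes) {
    prods <- lapply(species, function(sp) {
      r <- fetch_gene_records(gene, sp, backend)
      if (nrow(r) == 0L) NULL else select_product(r)
    })
    names(prods) <- species
    if (any(vapply(prods, is.null, logical(1)))) {
      msg("[orthodiv] gene %s incomplete (missing %s); dropped", gene,
          paste(species[vapply(prods, is.null, logical(1))], collapse = ", "))
      next
    }
    ref_cds <- prods[[config$reference_species]]$cds_seq
    ok <- TRUE
    for (sp in config$comparison_species) {
      aln <- align_local(prods[[sp]]$cds_seq, ref_cds, config$scoring)
      if (aln$length == 0L || aln$length == aln$n_gap_columns) {
        msg("[orthodiv] gene %s: empty alignment vs %s; dropped", gene, sp)
        ok <- FALSE
        break
      }
      sims[[paste(gene, sp)]] <- data.frame(
        gene_symbol = gene, species = sp,
        similarity = similarity_score(aln),
        aligned_length = aln$length, n_gap_columns = aln$n_gap_columns,
        n_match = aln$n_match, stringsAsFactors = FALSE)
    }
    if (ok) n_aligned_genes <- n_aligned_genes + 1L
  }
  if (!length(sims))
    orthodiv_error("no gene could be aligned for all species",
                   "orthodiv_data_error")
  sim <- do.call(rbind, sims)
  rownames(sim) <- NULL

  comparisons <- gene_comparisons(sim, config$comparison_species)
  filtered <- filter_min_length(comparisons, config$min_alignment_length)
  msg("[orthodiv] genes: loaded %d, aligned %d, length-filtered %d",
      length(genes), nrow(comparisons), nrow(filtered))
  summary_df <- summarize_thresholds(filtered, config$thresholds)
  for (k in seq_len(nrow(summary_df)))
    msg("[orthodiv] threshold %g: %d genes (%d / %d / %d tie)",
        summary_df$threshold[k], summary_df$n_total[k],
        summary_df$n_rabbit_closer[k], summary_df$n_mouse_closer[k],
        summary_df$n_tie[k])

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  per_gene <- merge(sim, filtered[, c("gene_symbol", "delta")],
                    by = "gene_symbol", all.x = FALSE)
  per_gene <- per_gene[order(per_gene$gene_symbol, per_gene$species), ]
  per_gene$category <- ifelse(abs(per_gene$delta) <= TIE_TOLERANCE, "tie",
                              ifelse(per_gene$delta > 0, "rabbit_closer",
                                     "mouse_closer"))
  out_pg <- per_gene
  out_pg$similarity <- fmt_num(out_pg$similarity)
  out_pg$delta <- fmt_num(out_pg$delta)
  write_tsv_atomic(out_pg, file.path(config$out_dir, "per_gene.tsv"))

  out_sum <- summary_df
  for (col in c("threshold", "frac_rabbit_closer", "frac_mouse_closer"))
    out_sum[[col]] <- fmt_num(out_sum[[col]])
  write_tsv_atomic(out_sum, file.path(config$out_dir, "summary.tsv"))

  counts <- list(loaded = length(genes), aligned = nrow(comparisons),
                 filtered = nrow(filtered))
  for (k in seq_len(nrow(summary_df)))
    counts[[sprintf("threshold_%g", summary_df$threshold[k])]] <-
      summary_df$n_total[k]

  report <- list(
    config = list(
      input_dir = config$input_dir, out_dir = config$out_dir,
      reference_species = config$reference_species,
      comparison_species = config$comparison_species,
      min_alignment_length = config$min_alignment_length,
      thresholds = config$thresholds,
      scoring = unclass(config$scoring), seed = config$seed),
    config_hash = config_hash(config),
    counts = counts,
    summary = summary_df,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (config$make_plot)
    try(plot_delta_histogram(filtered,
                             file.path(config$out_dir,
                                       "delta_histogram.png")),
        silent = TRUE)

  invisible(list(similarity = sim, comparisons = comparisons,
                 filtered = filtered, summary = summary_df,
                 counts = counts))
}

config_hash <- function(config) {
  flat <- paste(
    config$input_dir, config$reference_species,
    paste(config$comparison_species, collapse = ","),
    config$min_alignment_length,
    paste(fmt_num(config$thresholds), collapse = ","),
    paste(unlist(config$scoring), collapse = ","), config$seed,
    sep = "|")
  # small deterministic FNV-1a style hash; avoids a digest dependency
  h <- 2166136261 %% 2^28
  for (b in utf8ToInt(flat)) h <- (bitwXor(h, b) * 16777619) %% 2^28
  sprintf("%07x", h)
}

#' Histogram of per-gene relative divergence
#'
#' Static rendering of the distribution of `delta` = similarity(first
#' comparison species vs reference) minus similarity(second vs reference):
#' positive mass means the first species (rabbit, in the motivating study)
#' is the closer one, and the subtitle reports the category shares.
#'
#' @param comparisons output of [gene_comparisons()] (usually filtered).
#' @param path output PNG path.
#' @param binwidth histogram bin width on the delta scale.
#' @export
plot_delta_histogram <- function(comparisons, path, binwidth = 0.01) {
  s <- categorize(comparisons, 0)
  sp <- attr(comparisons, "comparison_species") %||%
    c("first species", "second species")
  p <- ggplot2::ggplot(comparisons, ggplot2::aes(x = delta)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "#2c7fb8",
                            colour = "grey30", linewidth = 0.1) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = expression(Delta ~ "similarity (first - second comparison species)"),
      y = "genes",
      title = "Relative divergence to the reference species",
      subtitle = sprintf("%s closer: %d (%d%%) | %s closer: %d (%d%%) | ties: %d",
                         sp[1], s$n_rabbit_closer, s$pct_rabbit_closer,
                         sp[2], s$n_mouse_closer, s$pct_mouse_closer,
                         s$n_tie)) +
    ggplot2::theme_minimal(base_size = 10)
  ggplot2::ggsave(path, p, width = 7, height = 4.5, dpi = 150)
  invisible(path)
}

#' Distance-matrix report over an aligned FASTA
#'
#' Reads a pre-aligned FASTA, computes the p-distance matrix with pairwise
#' deletion, and writes it (plus the per-pair compared-site counts) as TSV.
#'
#' @param fasta aligned FASTA path.
#' @param mode `"nucleotide"` or `"amino_acid"`.
#' @param out output TSV path.
#' @param exclude_ambiguous see [p_distance_pair()].
#' @return The `p_distance_matrix`, invisibly.
#' @export
pdist_report <- function(fasta, mode = c("nucleotide", "amino_acid"), out,
                         exclude_ambiguous = TRUE) {
  aln <- read_aligned_fasta(fasta, mode = match.arg(mode))
  dm <- p_distance_matrix(aln, exclude_ambiguous = exclude_ambiguous)
  write_distance_matrix(dm, out)
  invisible(dm)
}
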