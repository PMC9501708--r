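# Independent oracles used across the suite. Each deliberately avoids the
# package's own code path for the quantity it checks.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# --- exhaustive local-alignment score via the exponential enumerator -------
# (src/gotoh.cpp, enumerate_local_score: recursion over every substring pair
# and every column interleaving; independent of the Gotoh DP).
enum_score <- function(a, b, scheme = scoring_scheme()) {
  orthodiv:::.enumerate_local_score(a, b, scheme$match, scheme$mismatch,
                                    scheme$gap_open, scheme$gap_extend)
}

# --- Biostrings local alignment as an independent mature implementation ----
biostrings_score <- function(a, b, scheme = scoring_scheme()) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scheme$match, mismatch = scheme$mismatch, baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = mat,
    gapOpening = -scheme$gap_open, gapExtension = -scheme$gap_extend)
  as.integer(Biostrings::score(pa))
}

# --- literal 64-entry codon table (standard genetic code) ------------------
CODON_TABLE <- c(
  TTT="F", TTC="F", TTA="L", TTG="L", CTT="L", CTC="L", CTA="L", CTG="L",
  ATT="I", ATC="I", ATA="I", ATG="M", GTT="V", GTC="V", GTA="V", GTG="V",
  TCT="S", TCC="S", TCA="S", TCG="S", CCT="P", CCC="P", CCA="P", CCG="P",
  ACT="T", ACC="T", ACA="T", ACG="T", GCT="A", GCC="A", GCA="A", GCG="A",
  TAT="Y", TAC="Y", TAA="*", TAG="*", CAT="H", CAC="H", CAA="Q", CAG="Q",
  AAT="N", AAC="N", AAA="K", AAG="K", GAT="D", GAC="D", GAA="E", GAG="E",
  TGT="C", TGC="C", TGA="*", TGG="W", CGT="R", CGC="R", CGA="R", CGG="R",
  AGT="S", AGC="S", AGA="R", AGG="R", GGT="G", GGC="G", GGA="G", GGG="G")

translate_oracle <- function(cds) {
  n <- nchar(cds) - nchar(cds) %% 3
  codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  aa <- ifelse(grepl("N", codons), "X", unname(CODON_TABLE[codons]))
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

# --- column-scan similarity oracle -----------------------------------------
# identity fraction over residue-pair columns, computed directly from the
# aligned rows (never via the alignment's stored counts)
similarity_oracle <- function(aln) {
  q <- strsplit(aln$aligned_query, "")[[1]]
  r <- strsplit(aln$aligned_ref, "")[[1]]
  res <- q != "-" & r != "-"
  mean(q[res] == r[res] & q[res] != "N")
}

# --- tiny simulated fixture shared by several tests ------------------------
worked_fixture_dir <- function() {
  system.file("extdata", "worked_synthetic", package = "orthodiv")
}
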