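---
title: "orthodiv: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{orthodiv: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthodiv)
```

## The question and the statistic

Two lineages that split from a reference lineage at the same time need not
be equally distant from it today: substitution rates differ between
lineages, and rodents in particular are believed to have accumulated
substitutions faster than lagomorphs or primates. `orthodiv` quantifies
this per gene. For every orthologous gene, the coding sequence (CDS) of
each comparison species is locally aligned against the reference species'
CDS, and from the alignment (length $L$ columns, $m$ identical residue
pairs, $g$ gap-containing columns) we compute

$$S = \frac{m}{L - g}, \qquad d = 1 - S, \qquad
  \Delta = S_{\text{first}} - S_{\text{second}}.$$

$S$ is percent identity over the residue-pair columns, bounded by 1 by
construction; $\Delta > 0$ means the first comparison species (rabbit, in
the motivating application) is closer to the reference. The difference of
the two genetic distances equals $-\Delta$, so the categorisation reads the
same on either scale.

Counting $g$ as gap-containing *columns* rather than gap *events* is a
deliberate choice: with per-event counting the denominator could fall below
$m$ and push $S$ above 1. With column counting, $S$ is the standard
identity-over-aligned-residues statistic.

## Alignment model

Alignment is local (highest-scoring substring pair), under an affine gap
model with BLAST-like nucleotide scores: match $+2$, mismatch $-3$, gap
opening $-5$, gap extension $-2$. The gap-cost convention matters and is
easy to get silently wrong, so it is pinned and separately testable: a gap
of length $k$ costs $\mathrm{open} + k\cdot\mathrm{extend}$, i.e. the first
gapped residue pays $-7$ and each further one $-2$. `score_alignment()`
re-derives any alignment's score by a plain column scan and is checked
against the dynamic program on random inputs.

The implementation is a Gotoh three-state dynamic program in C++ (integer
arithmetic throughout, so scores are bit-exact across platforms). Ambiguous
bases (`N`) score as mismatches against everything, including `N`, and are
never counted in $m$ — ambiguity should not manufacture identity. Sequences
are normalized (uppercase, `U`→`T`) and restricted to `A,C,G,T,N` at load.

Co-optimal alignments exist, and different choices can change $S$ slightly.
One optimal alignment is returned under fixed tie-breaking: the end cell
with the smallest `(ref_end, query_end)` among maximal scores; within the
traceback, residue pair over gap-in-reference over gap-in-query; gap runs
are closed as early as possible. This makes every downstream number a pure
function of the inputs. Correctness is established two independent ways: an
explicitly exponential enumeration of *all* local alignments of short
random pairs (an oracle shipped in the package's compiled code, separate
from the DP), and Biostrings' `pairwiseAlignment()`, whose gap convention
matches the one above (verified on forced-gap cases in the test suite).

## Filtering, categorisation, reporting conventions

* **Length filter.** Genes whose *minimum* aligned length across the two
  comparisons is not strictly greater than 150 bp are dropped: short local
  matches arise by chance and carry little signal. The minimum is the
  conservative per-gene aggregate (an alternative would filter each
  alignment separately); an alignment of exactly 150 columns is excluded.
* **Threshold.** `categorize(comparisons, t)` keeps genes with
  $|\Delta| \ge t$ ("at least" semantics, so $|\Delta| = t$ is kept) and
  counts signs among the survivors. At $t = 0$, ties are genes with
  $|\Delta| \le 10^{-12}$: $\Delta$ is a difference of exact rationals, so
  true ties are representable, and the guard only absorbs floating-point
  drift.
* **Percentages** are reported over the kept total, rounded half-up to
  integer percent, with the unrounded fractions always carried alongside —
  rounding conventions differ between publications, and the raw fraction is
  the auditable number.

## p-distances

`p_distance_pair()` implements the proportion of differing sites among
comparable sites with *pairwise deletion*: sites gapped — or, by default,
ambiguous (`N` nucleotide, `X` amino acid) — in either member of a specific
pair are excluded for that pair only, so `n_sites` is pair-specific.
Treating ambiguity as missing matches the behaviour of the standard
distance software option the workflow mirrors; a flag restores gap-only
deletion. For gapless, ambiguity-free pairs the nucleotide p-distance
equals $1 - S$ exactly, which the tests assert as a cross-module identity.

Translation (`translate_cds()`) uses the standard genetic code via
Biostrings, with fixed edge rules: a trailing stop is trimmed; a trailing
incomplete codon is dropped with a warning; any codon containing `N`
becomes `X` even when all resolutions agree (conservative, and consistent
with excluding `X` under pairwise deletion); an internal stop is an error
naming the codon — silently translating through a pseudogene-like sequence
would corrupt distances downstream.

The module consumes pre-aligned FASTA. Multiple alignment itself is out of
scope: for three taxa the distance tables only need pairwise comparisons,
which the local aligner provides, and tree inference on three taxa is
topologically trivial, so no tree builder is included.

## Acquisition model and isoform choice

Record acquisition is backend-pluggable. The fixture backend (a directory
with `cds.fasta` + `manifest.tsv`) is loaded once at construction, making
acquisition a pure function of the directory contents; it is the only
backend used in tests and analyses. A live NCBI E-utilities adapter with
the same contract is included for interactive dataset assembly but is
experimental and never exercised automatically. mRNA sequences are carried
in the data model but unused by the analysis, which aligns CDSs.

When a gene×species has several products, the `"X1"` isoform is selected.
When no product is labelled `X1` the convention is undefined in the
workflow this package models, so the package makes its own deterministic
choice: the longest CDS, ties broken by smallest accession —
the most complete product, and permutation-invariant. The decoy-isoform
option of the simulator exists to keep this rule exercised.

## The simulator: what it emulates, and what it does not

`simulate_triplets()` draws, per gene, an ORF-like ancestor (starts `ATG`,
uniform sense codons, no internal stops) and evolves it independently down
three branches. Substitutions are site-independent and uniform over the
three alternative bases (Jukes–Cantor-like); each branch has its own
per-site probability, and at most one codon-aligned indel per gene per
lineage (deletion of whole codons or insertion of sense codons, length
uniform in $\{3, 6, \dots\}$). A single seeded RNG stream with documented
draw order makes the whole dataset byte-reproducible.

Default study conditions: the accelerated scenario uses substitution
probabilities 0.08 (reference and first branches) and 0.16 (second branch)
— a twofold rate acceleration at divergence levels comparable to
mammal-scale CDS divergence — on genes of 300–1500 nt (typical CDS
lengths), indel probability 0.1 per lineage, maximum indel 9 nt. The
recovery analyses use 500 genes of 900 nt, which gives binomial standard
errors near 2 percentage points on category fractions while keeping a full
Monte-Carlo run in minutes on one CPU.

The simulator is deliberately simpler than real ortholog evolution: no
selection, no rate heterogeneity across sites or domains, no
transition/transversion bias, no codon usage bias, no alternative splicing
beyond the deterministic decoy isoform, and substitutions may create
internal stop codons in a descendant (real purifying selection would remove
these; `translate_cds()` refuses them, which is why amino-acid distance
demonstrations use curated stop-free inputs). Passing recovery tests
therefore show that the *pipeline statistics* respond correctly to known
branch-rate asymmetry — not that the simulator reproduces real innate
immunity gene evolution. The published headline numbers from live database
snapshots are likewise not reproducible offline; the package instead
verifies the summary arithmetic on the published counts and the mechanism
on synthetic data.

## Numerical and degenerate-input conventions

* Integer DP; similarity and $\Delta$ are ratios of small integers.
* Empty or no-positive-score alignments return score 0 / length 0; the
  similarity of such an alignment is an error, and the pipeline drops the
  gene with a logged message rather than fabricating a value.
* A pair with zero comparable sites after pairwise deletion is an error
  naming the pair.
* An empty comparison set summarises to zero counts, not an error.
* TSV output formats numbers with `%.10g` so reruns are byte-identical.

## Known limitations

Local alignment of full CDSs can trim genuinely divergent termini, so $S$
describes the conserved alignable core; sequences whose orthology is
doubtful should be filtered upstream. The similarity statistic makes no
multiple-hit correction (it is a raw identity), so it compresses at high
divergence — within-Glires comparisons sit well inside its informative
range, but the machinery should not be read as a substitution-rate
estimator. The live backend depends on external database state and is
provided as-is.
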