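---
title: "Methods: how vqfam identifies, classifies and quantifies VQ-family evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how vqfam identifies, classifies and quantifies VQ-family evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vqfam)
```

vqfam is a toolkit for studying how a plant transcription-regulator family
defined by the short VQ motif (`FxxhVQxhTG`, with `x` any residue and `h`
hydrophobic) expands and diversifies. It covers the full chain of a
family-evolution study: find the family members in a proteome, decide how
each copy arose (tandem array, segmental duplication, mobile-element
capture, retrotransposition), measure the selective forces on duplicated
pairs (Ka/Ks), test for gene conversion between paralogs, count how many
family members the last common ancestor of two lineages must have carried,
and classify expression patterns. Because the real inputs of such a study
(genome releases, expression series) are large and external, the package
ships a synthetic-data generator that plants each of these signals with
recorded ground truth; every method is validated by round-trip recovery
against those plants, by independent brute-force oracles, and by
calibration of its error rates.

## Motif identification

The family is defined by a Pfam-style seed alignment of motif instances.
`build_profile()` converts the (gap-filtered) alignment columns into a
position-specific scoring matrix with log-odds scores

\[ s_j(a) = \log_2 \frac{(c_j(a) + \lambda\, q_a)/(n_j + \lambda)}{q_a}, \]

where $c_j(a)$ counts residue $a$ in column $j$, $q$ is the background
frequency vector (uniform by default) and $\lambda$ a pseudocount weight
(default 1). Columns with more than 50% gaps are dropped; the alignment
depth (119 seeds in the simulated stand-in, mirroring the Pfam VQ seed
set) keeps the variable motif positions near background so genuine
instances are not penalized for rare residues.

`scan_proteome()` slides the profile over every window of every protein.
Rather than an analytic E-value theory, significance is empirical: the
whole proteome is shuffled within proteins `n_shuffles` times (default
10), every decoy window is scored, and a window's E-value is the number of
decoy windows at or above its score divided by the number of shuffles —
the expected count of equally good hits in a random database of identical
size and composition. Hits at E ≤ 0.01 (the conventional cutoff) are
reported; overlapping windows in one gene are merged to the best one (ties
to the leftmost) and the best window per gene is flagged primary. The two
profile columns whose consensus reads V,Q define the motif core; hits
carrying V,H there are reported with `core_variant = "VH"`, matching the
VH-core family members known from monocots (the simulated seed set
therefore also contains 10% VH seeds). `regex_confirm()` grades each hit
`full` / `partial` / `none` against the canonical pattern, with the
hydrophobic class fixed to {A, V, L, I, M, F, W, C}. The pipeline accepts
a scan candidate into the family only when this confirmation finds at
least the core (`full` or `partial`), mirroring the usual two-step
search-then-confirm chain; with only 10 shuffles the empirical E-value
cannot resolve expectations below 0.1, so an unconfirmed random window
just above the decoy maximum would otherwise slip through roughly once
per ten proteomes.

## Duplication-mechanism classification

All coordinates are 0-based half-open internally; GFF3 is read and written
1-based inclusive and BED 0-based half-open, pinned by round-trip tests.
Strand is ignored for distances and overlaps.

*Tandem arrays.* Two family genes are tandem-linked when they lie on the
same chromosome, at most 10 array genes apart (ranks computed over the
complete annotation, not just the family), and within a species-class
distance: 100 kb for compact genomes (Arabidopsis, moss), 350 kb
otherwise, measured from the leftmost start to the rightmost end of the
two genes. Arrays are connected components of this relation; the
implementation is checked against an independent all-pairs union-find
oracle on random layouts.

*Segmental duplications.* A family pair is called segmental when at least
`min_anchors` (default 2) homologous gene pairs flank it collinearly
within ±50 kb of both members. The anchor table is an input (genome-wide
collinearity detection is out of scope); two flanking anchors are the
weakest defensible evidence and the threshold is configurable.

*Mobile elements.* A family gene overlapping an annotated MULE, hAT,
CACTA, LTR or helitron span by at least 1 bp is attributed to that
element; the largest overlap wins when several elements apply.

*Retrogenes.* A family gene with ≤ 1 intron whose best protein match among
≥ 2-intron family members reaches 70% global identity is called a
retrogene with that match as parent. The criteria for this class are not
standardized in the literature the package follows, so all three numbers
are explicit arguments.

## Ka/Ks and functional constraint

Protein pairs are aligned by Needleman–Wunsch (full-length rates) or
Smith–Waterman (`mode = "local"`) under BLOSUM62 with affine gap penalties
10/1, then back-translated onto their coding sequences codon-by-codon
(`backtranslate()` refuses any CDS that does not translate exactly to its
protein). `ng86()` implements Nei–Gojobori (1986) counting: each codon's
synonymous site count is the fraction of its nine single-nucleotide
neighbors that are synonymous (changes creating stop codons count as
nonsynonymous); sites are averaged over the two sequences; observed
differences are averaged over all minimal mutational pathways between each
codon pair, excluding pathways through stop codons; and both proportions
receive the Jukes–Cantor correction $K = -\tfrac34 \ln(1 - \tfrac43 p)$.
Proportions of 3/4 or more, or Ks = 0, yield NA sentinels rather than
numbers. The estimator is cross-checked against a from-scratch enumerator
at tolerance 1e-9.

The functional-constraint statistic is $c = 1 - K_a/K_s$ with a percentile
confidence interval from a codon-column bootstrap (1000 replicates by
default); a pair is flagged "under constraint" when the whole interval
lies above zero. This is a reconstruction from first principles — the
published C-value test this mirrors is not restated in the sources the
package follows — and the output labels it as such via the `estimator` and
constraint columns.

`batch_kaks()` applies the machinery to pair lists over either the
full-length proteins or only the motif windows of both genes
(`region = "motif_only"`), the comparison that shows motif-region
conservation: in constructs with an amino-acid-identical motif region and
near-neutral flanks, the motif-region ratio is below the full-length ratio
in ≥ 95% of cases.

Two numerical notes, measured with the package's own generator. First,
NG86's equal-weight pathway averaging misclassifies some differences in
codons hit more than once, so at a synonymous divergence of Ks ≈ 0.3 the
estimated Ka/Ks at true ω = 1 runs about 2% low (the bias vanishes as
Ks → 0 and grows with divergence); medians across ω ∈ {0.2, 1, 2} stay
well within ±20% of truth. Second, because stop-creating changes can never
fix, the codon-pair simulator inflates its nonsynonymous acceptance by the
ancestor's stop-neighbor site fraction (~4%) so that the realized
(Nd/N)/(Sd/S) — with sites counted exactly as NG86 counts them — equals
the requested ω in expectation.

## Gene conversion

`permutation_test()` implements a Sawyer-style fragment scan on an aligned
set of coding sequences (≥ 3, so conversion is detectable against the
group). Polymorphic sites are gap-free columns with at least two states.
For each sequence pair the statistic is the best-scoring contiguous run
over the pair's match/mismatch string at those sites — by default matches
score +1 and any mismatch breaks the run (the no-mismatch convention of
the classic tool; a finite penalty switches to Kadane scoring). The null
distribution permutes polymorphic-site columns jointly across all
sequences; with pure-match scoring a pair's best run after a permutation
depends only on where its mismatch sites land, which the C++ kernel
exploits to evaluate each permutation without rebuilding the alignment.
Per-pair P-values are $(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n)$;
global P-values apply Bonferroni over all ordered pairs, and events are
reported at global P ≤ 0.05. Calibration over 500 null data sets keeps the
family-wise false-positive rate within the binomial envelope of 0.05, and
a planted 200-polymorphic-site identical tract is recovered with global
P ≈ 0.003 at 10,000 permutations. The seed is a required argument: a
Monte-Carlo P-value without a recorded seed is not reproducible.

## Ancestral units

`count_ancestral_units()` decomposes a rooted, species-labeled gene tree
at a lineage bipartition into *minimal mixed clades*: nodes whose subtree
contains leaves from both sides of the split while no single child subtree
does. Each such clade witnesses one gene in the most recent common
ancestor, so the count is a parsimony lower bound — gene losses and
pseudogenes are not reconciled, and lineage-pure clades attached outside
mixed clades are not counted, which matches the known under-estimation of
MRCA content by this style of analysis. Multifurcating nodes are treated
as simultaneous radiations and may themselves be minimal mixed clades.
Unrooted trees are rejected rather than silently midpoint-rooted (rooting
changes the counts); `root_gene_tree()` makes the rooting step explicit.
On duplication-only simulated histories the counts are exact, and along
nested backbone splits they are non-decreasing.

## Expression rules

`classify_tissue()` implements the twofold preference rule: a gene is
detected in a tissue at mean abundance ≥ 1 FPKM (the "detectable signal"
threshold is not standardized, so it is an argument), *specific* when
detected only in the focal tissues, and *preferred* when the focal mean is
at least 2× the maximum over every remaining tissue — inclusively, pinned
by boundary tests at exactly 2. With ≥ 2 replicates per group the call
additionally requires a BH-adjusted two-sample t-test on log2 abundance
(P < 0.05) against the strongest remaining tissue; with single samples the
fold rule stands alone. `classify_treatment()` applies the same rule to
control/treated designs for up/down calls.

`coexpression_pairs()` calls a pair co-expressed when its Pearson
correlation reaches |r| ≥ 0.8 (inclusive) in at least 3 datasets with a
consistent sign; sign consistency is the package's reading of the
criterion and can be disabled. Correlations are computed on log2(x+1)
abundances by default — on the raw FPKM scale the log-normal nonlinearity
attenuates r, and perfectly anti-correlated genes cannot even reach
−0.8. Modules are connected components of the called-pair graph; heavier
weighted-network machinery (soft thresholding, topological overlap) is
deliberately out of scope because the operative pair criterion is the
correlation rule itself.

## The synthetic-data generator

`sim_config()` fixes the study conditions; the defaults are chosen once to
be realistic for a compact plant genome and strong-but-noisy expression
signals, and the same defaults drive the test suite and the acceptance
script:

* Genome: 2 chromosomes × 150 genes, geometric intergenic gaps with mean
  3 kb, gene lengths 120–300 codons. Planted: 3 tandem arrays of 3
  (intra-array gaps forced to 500 bp, so arrays sit far inside the
  distance threshold; all other family genes are kept > 10 ranks apart),
  2 segmental pairs with 3 collinear anchors each (a 60 kb "moat" gap
  isolates each anchor window so anchors support only their own pair),
  2 element-captured genes, 1 retrogene pair, 3 singletons; every family
  gene carries an intact planted motif.
* Codon pairs: 300 codons at target Ks 0.3, ω ∈ {0.2, 0.5, 1, 2}.
* Conversion alignments: 6 sequences, 10% divergence, 600 bp planted
  tracts (codon-aligned).
* Expression: 11 tissues × 3 replicates, log2-scale noise sd 0.25,
  planted fold 4 (detection uses the 2× rule, so the planted effect has a
  factor-2 margin plus a 1.5× guard), 5 co-expression datasets of 20
  samples with planted pairs sharing a unit-variance latent profile in 4
  of them.

What the generator does *not* emulate: introns only exist as annotation
(no sequence), there are no indels in codon evolution, no
transition/transversion bias, no gene loss in tree histories, no
between-sample library-size effects in expression. Passing the recovery
suite therefore demonstrates correctness of the rules and estimators under
their stated models, not robustness to every artifact of real data.

## Problem sizes and reproducibility

The validation suite uses 200 alignments of 300 codons for the NG86 oracle
check, 200 pairs per ω level for recovery, 100 constructs for the
motif-constraint property, 100 layouts of 500 genes for the tandem oracle,
500 null datasets (1000 permutations each) plus one 10,000-permutation
planted run for conversion, 100 recorded tree histories, and the default
expression design — sizes at which every stochastic check is stable
without being wasteful. All randomness flows through explicit seeds;
`make_fixture()` + `run_pipeline()` rerun byte-identically under a fixed
seed, and `scripts/acceptance.R` recomputes every headline number from
scratch for any seed.
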