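---
title: "prescan: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{prescan: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prescan)
```

# Scope

`prescan` implements a promoter-motif analysis pipeline for case/control
skin-transcriptome studies: a curated binding-site dictionary, PWM scans of
TSS-proximal sequence, enrichment of motifs among differentially expressed
genes (DEGs), risk-allele effects on motif matches, and decoy-oligo design.
This vignette records the models, the tunable parameters with their defaults
and rationale, and the places where the design was genuinely open.

# Motif dictionary

**Pseudocount.** Count matrices become probability matrices via
$(c_{bj} + \kappa/4)/(n_j + \kappa)$ with total pseudocount $\kappa = 0.80$
per column. The total follows an established recommendation for PWM
pseudocounts; splitting it equally across the four bases is our choice (any
split rule would do; the equal split keeps the conversion symmetric and is
what most motif toolkits implement).

**Trimming.** Flank columns are removed until two *consecutive* columns
exceed 0.25 bits of information content
($IC = 2 + \sum_b p_b \log_2 p_b$). Heavily gapped matrices where that rule
would leave nothing fall back to a single-column rule; anything still
narrower than 4 columns is discarded. Open point: whether the relaxed rule
should also apply when the strict rule leaves 1–3 columns (rather than
none). We apply it in both situations: a 1–3 column model is useless for
scanning either way, and the relaxed rule salvages a few usable matrices;
the applied rule is recorded on the returned object (`trim_rule`).

**IUPAC consensus for de-duplication.** The consensus letter of a column is
the degenerate code for $\{b : p_b \ge 0.25\}$. No published rule exists for
this step; the 0.25 cut is the uniform probability, so a base enters the
set exactly when it is at least as likely as under no preference, and the
rule is deterministic.

**Redundancy.** Same-width matrices with identical consensus strings lose
the lower-average-IC member unless the mean absolute PPM difference exceeds
0.05 (two genuinely different matrices can share a degenerate consensus).
Across widths, motifs at alignment distance below $10^{-14}$ — 1 minus the
best Pearson correlation over all ungapped offsets and both orientations,
minimum 4 overlapping columns — are grouped by single linkage and the
highest-IC member is kept. The ungapped-offset metric is a testable
stand-in for the cited Smith–Waterman/Pearson metric; at the $10^{-14}$
threshold it groups only numerically identical matrices, so the substitution
is immaterial in practice. Exact ties break by lexicographic motif id, which
makes curation order-insensitive up to tie groups.

# k-mer scores and clustering

The preference score of word $w$ (length $k \in \{3,4\}$) against a PPM of
width $m$ is
$\max_{i=1..m-k+1} \min(p_{w_1,i},\dots,p_{w_k,i+k-1})$, maximized over both
orientations; motifs narrower than the word score 0 (the min over $k$
probabilities is undefined past $m-k+1$, so the index range is read as start
positions). Profiles are reverse-complement symmetric by construction.

Clustering replaces the HOPACH algorithm (out of scope) with average-linkage
hierarchical clustering on correlation distance, choosing the number of
top-level groups in 2..10 by minimizing a median split silhouette: each
cluster is provisionally split in two and the median silhouette of its
members under that split measures how divisible it remains; clusters too
small to split (size < 3) contribute the worst value so fragmentation is
never rewarded. The test surface is qualitative — recovery of planted
families and their discriminative k-mers — not HOPACH internals. The
nearest-neighbor DNA-binding-domain enrichment uses Pearson correlation of
the k-mer profiles (the feature space is stated only implicitly alongside
the profiles, so profiles are assumed), the top 10% as neighbors
(ceiling rule, correlation ties broken by motif id), and one-sided Fisher
tests per superfamily/class.

# DEG calling

Per gene, the paired PP−PN log2 differences are tested against zero.
The source describes a "Wilcoxon rank sum test" of whether the median
difference differs from zero; the test that matches that description for
paired differences is the one-sample Wilcoxon *signed-rank* test, which is
what we fit. Gates: BH FDR < 0.05, median fold change > 1.50 (up) or
< 0.67 (down), and the per-dataset median FC on the same side of 1 in every
dataset. Genes with fewer than 80% complete pairs are skipped; constant
difference vectors get $p = 1$ by convention. QC metrics are Z-scored
within dataset and |Z| > 3.5 removes the sample and its patient's pair;
datasets with fewer than 3 samples cannot support a Z-score and are kept
with a warning. Label swaps are flagged only when *both* signature
directions invert (median up-signature difference < 0 **and** median
down-signature difference > 0).

# Promoter scanning

Windows span 5 kb upstream to 500 bp downstream of the TSS in gene
orientation, truncated at contig ends. Internally coordinates are 0-based
half-open; BED output follows BED conventions. Masked intervals (coding
sequence, assembly gaps) and N bases are excluded: a window containing any
such base is skipped entirely (window-level handling is unstated in the
source; skipping is the conservative choice and keeps the scanned-length
covariate honest). `nonmasked_length` therefore counts bases that are
neither masked nor N. Matches require $\psi/\psi_{max} \ge 0.80$ on either
strand; overlapping matches — including across strands — merge into one
interval, while merely adjacent matches stay separate ("overlapping" is the
stated merge rule). Promoter scans use the empirical base composition of
the scanned regions as background; all other scans (SNP windows, oligo
screens) use the uniform background, mirrored as a per-call option.
A numerical guard of $10^{-9}$ on the threshold comparison absorbs
floating-point noise in the window sums.

# Enrichment model

For each motif, a binomial generalized additive model
`DEG ~ log10(x1 + 1) + s(log10(x2), k = 5)` is fit over all scanned genes,
where `x1` is the merged match count and `x2` the non-masked scanned length.
The model is semiparametric without the smooth being assigned explicitly in
the source; since a Wald Z statistic is reported for the enrichment
covariate, `x1` must be parametric, so the smooth goes on `x2`. Basis
dimension 5 keeps the length adjustment flexible but cheap; smoothness is
chosen by GCV. `log10(x1 + 1)` guards zero counts (unstated in the source).
A motif is selected when BH FDR < 0.10 with Z > 0, separately for the
up-regulated, down-regulated and combined DEG sets. A main-effects model is
assumed (no smooth interaction). When the length covariate is (nearly)
constant the model degrades gracefully to plain logistic regression, and
constant match counts return Z = 0, p = 1 with a warning. Near complete
separation the Wald statistic is flagged; note that at extreme separation
the Wald Z can *shrink* (Hauck–Donner), which is why the monotonicity
property is asserted from a null baseline in the tests.

# Risk-allele effects

For a SNP and motif of width $m$, each allele is substituted at the SNP
base and the best $\psi$ over the $2m-1$-window neighborhood (every window
containing the SNP, both strands) is taken — the tightest reading of
"match scores calculated for each SNP"; a fixed wider window would let
SNP-independent matches dominate. The effect is
$(\psi_R - \psi_{NR})/\psi_{max}$, antisymmetric under allele swap.
Engendered: $\psi_R/\psi_{max} > 0.85$ and $\psi_{NR}/\psi_{max} < 0.75$;
disrupted: the mirror; thresholds are strict inequalities. The resampling
null draws panels of the observed size from a user-supplied sampler
(for the synthetic world: uniform promoter positions with random alternate
alleles — the source's sampling pool is unspecified) and reports
$(1 + \#\{t \ge obs\})/(1 + T)$ per tail. Candidate sites keep
engendered/disrupted combinations that are conserved (phastcons ≥ 0.50)
*or* recognized by a DEG-encoded protein, sorted by |effect|.

# Decoy design

All $n!\,2^n$ block orderings/orientations are enumerated without collapsing
palindromic duplicates (the published count of 384 for four blocks counts
them all); blocks concatenate with no spacer by default (a spacer option
exists). Screening reports motif *presence* (any window on either strand at
threshold 0.80), not match counts, matching how per-design tallies are
reported. Ranking sorts by mean enrichment Z over matched motifs; runs of
designs within 0.02 Z of each other count as tied — the window comes from
the published 1.71-vs-1.70 tie-break example — and re-order by fewer
matches (specificity), then lexicographic sequence, giving a deterministic
total order. Designs matching nothing rank last and are flagged.

# Synthetic world

The generators state a fixed world; they are not tuned to tests.

* **Expression** defaults mirror the study cohort: 16117 genes, 248
  patients in 9 datasets (split as evenly as possible — the cohort is not
  divisible by 9), 1027 up / 796 down planted DEGs, fold changes 2.0 / 0.5,
  within-patient SD 0.5 on the log2 scale, 9 QC-outlier samples from 9
  patients and 2 label-swapped patients. Outlier metrics are abstract
  numeric columns (the real array QC statistics are out of scope) forced to
  ±50; outliers within a dataset are spread over distinct metrics because
  two extremes in the same dataset × metric cell mask each other — the
  within-cell Z of duplicated extremes is bounded below 3.5 no matter how
  large the value.
* **Promoters** are i.i.d. background sequence at the empirical promoter
  composition (A 0.247, C 0.251, G 0.254, T 0.248) with Poisson-planted
  consensus instances at non-overlapping uniform positions and strands;
  DEG genes elevate the planting rate for the designated motifs (default
  rate ratio 2). A first-order Markov background was considered and left
  out: the pipeline's statistics depend on match counts and scanned length,
  not on local composition structure. Masks cover 10% of each promoter and
  avoid planted instances so recovery is measurable.
* **Motifs** come in families sharing a core word (defaults `GAAA` and
  `TGACT`, the two element families prominent in the up-regulated DEG
  analysis), with per-column IC drawn from 1.0–1.8 bits — typical of curated
  eukaryotic PWMs and high enough that single-base changes at the strongest
  column move a match across the 0.85/0.75 bands.
* **SNP panels** default to 572 loci (36 lead + 536 linked), an enhancer
  fraction of 53/572, 30% conserved loci, and planted fractions 10%
  disrupt / 5% engender / 85% neutral — the study does not state per-SNP
  planted fractions (they are unknowable), so these are chosen to give the
  classifier both signal and null mass.

A green synthetic test establishes that the statistics recover *planted*
structure in an i.i.d. world at the stated rates; it says nothing about
array normalization, probe effects, LD structure, repeat content or real
promoter composition, all of which are out of scope.

# Numerical and degenerate-input conventions

Uniform PPMs on uniform background give $\psi_{max} = 0$ and are flagged
degenerate (scanning them is an error; oligo screens skip them with a log).
Columns sum to 1 within $10^{-9}$; IC uses $0\log 0 = 0$. BH adjustment is
the closed-form step-up. All generators and the resampling null derive
per-trial seeds deterministically from a master seed and restore the
caller's RNG state.

# Known limitations

* The alignment distance is ungapped; true Smith–Waterman alignment could
  group gapped variants of a motif that we keep separate (harmless at the
  $10^{-14}$ threshold, relevant if a user raises it).
* The clustering criterion approximates the median-split-silhouette rule of
  the original partitioning algorithm; group counts on weakly structured
  data can differ from HOPACH's.
* Wald-based enrichment Z is unstable under complete separation (warned).
* The scan is O(genes × motifs × length) in plain R; it is comfortable at
  test scale (thousands of promoter-kb per second) but a compiled scanner
  would be the next step for genome-scale dictionaries.
* Printed-value arithmetic: a published disrupted/engendered proportion of
  1.79 corresponds to counts 130/73 = 1.7808; the package reports the count
  ratio and documents that the printed figure round-trips through rounded
  percentages.
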