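---
title: "Codon usage bias profiling with codonscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias profiling with codonscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonscope)
```

# The problem

Synonymous codons are not used interchangeably. In plant nuclear gene
families -- the motivating case is the polyphenol-oxidase (PPO) family of
the tea plant, a set of a few dozen paralogous coding sequences of roughly
1.8 kb with weak overall bias -- the balance of mutation pressure and
natural selection leaves quantitative fingerprints in codon usage.
`codonscope` computes the standard panel of codon-usage-bias (CUB)
statistics on a set of coding sequences (CDS), classifies codons, screens
candidate heterologous expression hosts, and runs the classical
mutation-versus-selection diagnostics. A seedable synthetic-CDS generator
with full ground-truth bookkeeping makes every stage testable without any
sequence download.

All statistics share one substrate: the `CodonCounts` object, a genes x 64
matrix of reading-frame-0 codon counts. Stop-codon columns are recorded
(they enter overall base composition) and excluded from every synonymous
statistic; codons containing ambiguous bases are skipped, never imputed.
Only the standard nuclear genetic code (translation table 1) is shipped:
all species this package was designed around are plants with nuclear
genes.

# Statistics and their conventions

## Composition panel

Per gene: overall A/T/G/C percentages over the full CDS including the stop
codon; GC1 and GC2 over sense codons; and the synonymous third-position
panel A3s/T3s/C3s/G3s/GC3s restricted to codons of amino acids with
degeneracy >= 2 (Met, Trp and stops excluded), so the four base fractions
sum to 100. Two conventions for AT3 coexist in the literature because the
two tools that popularised these panels differ: the default
(`convention = "caical"`) computes AT3 over third positions of *all* sense
codons, while `"codonw"` restricts it to the synonymous set like the other
"3s" metrics. Dataset summaries are unweighted per-gene means, not
length-weighted pools.

## Bias indices

* **ENC** (effective number of codons, 20-61). Wright's estimator: family
  homozygosity `F = (n*sum(p^2) - 1)/(n - 1)` averaged per degeneracy
  class, then `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, capped at 61.
  Edge handling follows the conventions of the classical CUB tool chain:
  families with `n <= 1` or non-positive `F` are dropped from their class
  average, and a missing three-fold class (Ile) is imputed as the mean of
  the two- and four-fold averages. Note that `F` carries an `O(1/n)`
  finite-sample term, so ENC is scale-invariant only in the large-count
  limit.
* **CAI** (codon adaptation index). Geometric mean of relative
  adaptiveness weights `w` over synonymous codons, excluding the
  single-codon families Met/Trp. Weights come from a reference usage table
  via `referenceWeights()` (`w = usage / max(usage)` within each family).
  The packaged default is derived from the synthetic E. coli-style table
  described below; CAI values are therefore meaningful *relative* to one
  another within a dataset, and users who need agreement with a specific
  published reference should supply that table via
  `readReferenceWeights()`. Zero weights are floored at 0.01 with a
  warning.
* **CBI** (codon bias index). `(Nopt - Nran)/(Ntot - Nran)` over
  degenerate families, with the optimal set taken from the reference
  weights (argmax per family, alphabetic tie-break) and `Nran` the count
  expected under uniform synonymous usage.
* **GRAVY / AROMA**. Mean Kyte-Doolittle hydropathy (one-decimal scale, as
  published) and aromatic-residue fraction of the encoded protein.

## RSCU, RFSC and codon classes

For codon `j` of amino acid `i` with count `X_ij` and degeneracy `n_i`:
`RSCU = X_ij / ((1/n_i) sum_j X_ij)` and `RFSC = X_ij / sum_j X_ij`.
Families with zero observations are reported missing, not zero.
Dataset-level tables pool codon counts across genes (concatenation), not
averages of per-gene tables. Thresholds: preferred RSCU > 1,
over-represented > 1.6, under-represented < 0.6. Two published
high-frequency rules are both implemented because they are genuinely
inequivalent and sources rarely say which they used: `rfsc60` (family
share > 60%, the default, matching the operational wording most studies
give) and `avg150` (share exceeding the family average by > 50%, which by
the identity `RSCU = RFSC * n_i` equals `RSCU > 1.5` exactly -- the test
suite checks that identity).

## Optimal codons

Genes are ranked by ENC; the lowest-ENC 10% is the high-bias
("high-expression") set and the highest-ENC 10% the low-bias set, each
pooled. Decile size is rounded half up with a floor of one gene (24 genes
gives 2 per extreme, 30 gives 3); ENC ties break by gene id so results are
deterministic. A codon is optimal when `dRSCU = RSCU_high - RSCU_low >=
0.08` with `RSCU_high > 1` and `RSCU_low < 1`.

## Mutation-selection diagnostics

* **ENC plot**: observed ENC against GC3s, with the mutation-only
  expectation `ENCexp = 2 + s + 29/(s^2 + (1-s)^2)`. A gene exactly on the
  curve is not counted "below".
* **PR2 plot**: `A3/(A3+T3)` against `G3/(G3+C3)` at third positions,
  computed over all sense codons by default (a fourfold-family-only mode
  is provided for comparability with part of the literature); (0.5, 0.5)
  is the parity equilibrium.
* **Neutrality regression**: OLS of GC12 on GC3s (both %); the slope times
  100 is read as the mutation-pressure percentage, the complement as
  selection. Pearson r accompanies the OLS slope, as is conventional for
  neutrality plots; Spearman rho is also reported for consistency with the
  rank-based correlation panels.
* **Correspondence analysis**: chi-square-metric CA of the genes x 59 RSCU
  matrix (single-codon families and stops dropped; the RSCU input rather
  than raw counts follows the convention of the CUB literature).
  Standardised residuals are decomposed by SVD; per-axis inertia
  percentages are invariant to the coordinate scaling, which is why they
  are the quantity the package reports prominently. Missing-family RSCU
  entries become 0 with a warning. Total inertia equals chi-square over
  the grand total; the test suite verifies this identity to 1e-10 and
  cross-checks eigenvalues against `vegan::cca`.

## Expression proxies and host screening

* **SCUO**: per degenerate family, the normalised entropy deficit
  `(Hmax - H)/Hmax`, weighted by the family's share of degenerate-family
  codons; 0 for uniform usage, 1 when each family uses a single codon.
* **MILC**: `sum_a M_a / L - C` with
  `M_a = 2 sum_c O_c ln(f_c / g_c)` (a per-family G statistic) and the
  length correction `C = sum_a(n_a - 1)/L - 0.5` over amino acids observed
  in the gene. The expected distribution `g` defaults to uniform within
  family, with the pooled dataset usage available via
  `expected = "dataset"`; the tool chain this mirrors does not document
  its choice, so both are exposed. Under the uniform expectation MILC is
  bounded below by `-C` with equality exactly at uniform usage, and for
  weakly biased genes it sits near 0.5 because the G statistic
  concentrates near its degrees of freedom.
* **Host screening**: gene usage scaled to per-1000 codons over the 61
  sense codons against a cusp-format host table; a codon is divergent when
  the gene/host ratio is <= 0.5 or >= 2 (boundaries inclusive).
  `rankHosts()` reports per-gene divergent counts as a min-max range per
  host, the form in which host suitability is conventionally quoted.

### The packaged host tables are synthetic

The six tables under `inst/extdata/hosts/` (E. coli, S. cerevisiae,
A. thaliana, N. tabacum, T. aestivum, Z. mays) are **synthetic emulations**
generated by a deterministic compositional model: uniform family weights,
a small set of species-typical codon multipliers, and a third-position GC
tilt solved to each species' characteristic GC3s (0.55, 0.38, 0.42, 0.41,
0.62, 0.63 respectively). The filenames, headers and the packaged
`MANIFEST.json` all say so. They reproduce the coarse structure that
drives host ranking -- GC3-rich monocots versus AT3-rich dicots and yeast
-- but not the fine per-codon frequencies of any database snapshot, and
the default CAI reference derived from the E. coli table inherits this
limitation. For production host screening or published-value comparisons,
drop genuine cusp tables in via `readCusp()`.

# The synthetic-CDS generator

`generateCDS()` samples genes codon-by-codon: the amino acid from a fixed
composition, the codon within its family from per-gene family weights that
are uniform, Dirichlet-sampled (concentration `alpha` tunes bias
strength), or degenerate (one codon per family -- the maximal-bias regime
where ENC = 20 and SCUO = 1 exactly). An optional tilt reweights
G/C-ending codons, solved numerically so the *expected* GC3s hits a
requested target; infeasible targets error. Everything is reproducible
from one seed (also embedded in the FASTA ids) and the truth record keeps
the sampled weights, codon probabilities and expected GC1/GC2/GC3s, so
tests can assert parameter recovery instead of mere smoke.

`emulateStudy()` reproduces the structure of the motivating corpus:
24 paralog-like genes of 600 sense codons derived from one simulated
ancestor by synonymous-only resampling (rate 0.025 per codon, keeping
pairwise identity >= 95% and the amino-acid profile fixed), plus 6
divergent out-groups spanning GC3s 0.46-0.58. The frozen parameters
(PPO-like amino-acid weights rich in Leu/Pro/Asp/Lys and poor in
Trp/Cys/Met, Dirichlet concentration 6, ancestor GC3s target 0.525) were
calibrated once so that dataset means land in the weak-bias plant regime:
across seeds, mean GC about 48-50%, GC3s about 52-54%, mean ENC about
56. Because paralog divergence is synonymous-only, GC12 is nearly constant
within the paralog set and the corpus yields a small neutrality slope by
construction -- the mutation-pressure share is low, as in the real gene
family the generator emulates.

What passing tests on this corpus do *not* show: real paralog families
carry nonsynonymous divergence, indels, alignment ambiguity and
correlated codon usage along the sequence, none of which the generator
produces. The generator isolates codon-level signal on purpose.

# Numerical choices and degenerate inputs

* Validation: `strict` rejects length not divisible by 3, internal stops
  and ambiguous bases; `lenient` truncates overhangs and leaves
  N-containing codons for the counter to skip, with warnings. A single
  trailing stop is always legitimate and is kept in the counts.
* Genes with no synonymous codons make the "3s" panel, SCUO and CAI
  undefined: these error rather than return a number.
* ENC returns NA (with a warning) for genes too short to form the class
  averages, and errors only when no gene can be scored. Family
  homozygosities indistinguishable from zero (below 1e-10) are dropped
  exactly like negative ones.
* CA treats singular values below `1e-10 * max(d)` as null axes; an
  identical-rows matrix therefore reports zero axes rather than noise.
* Spearman p-values are exact below 10 observations, t-approximate
  otherwise; constant columns yield NA, never a fabricated rho.
* Decile rounding, ENC tie-breaks and optimal-set tie-breaks are all
  deterministic (round half up; alphabetic ids).

# Problem sizes used by the shipped checks

The test suite runs entirely on generated data: toy hand-counted genes for
exact oracles; genes of 2,000-10,000 codons for limit regimes; 100
replicates of 20 genes x 700 codons for neutrality-slope recovery; 50
replicates of 30 genes x 500 codons for planted-optimal-codon recovery
(observed mean sensitivity about 0.95-0.98); and the 30-gene emulated
corpus for the end-to-end pipeline. `scripts/acceptance.R` regenerates
the emulated corpus from a command-line seed and recomputes the headline
quantities from scratch.

# Known limitations

* Reproducing published per-gene tables requires the original CDS; the
  package deliberately performs no network retrieval, and several
  published accessions are protein records whose underlying CDS choice the
  source studies do not document.
* CAI/CBI absolute values depend on the reference set; with the synthetic
  default they are comparable within a dataset but not across papers.
* Only translation table 1 is implemented (the table id is a forward
  compatibility hook, not a switch).
* The PR2 and composition panels follow frame 0 of the supplied CDS; no
  ORF scanning is attempted.
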