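---
title: "Methods: population-level analysis of tumor evolution direction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-level analysis of tumor evolution direction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorevol)
```

## The question and the data model

Breast tumors progress through pathological stages — normal epithelium,
ductal carcinoma in situ (DCIS), invasive ductal carcinoma (IDC), and
metastasis — yet most of the malignant phenotype is already present in situ.
`tumorevol` asks what the *additional* genetic alterations acquired in later
stages do: whether they push the tumor further in the direction set early
(forward evolution), whether they instead erase inherited changes that
oppose the late copy-number state (backward evolution), or whether they only
fine-tune pathways that were already running.

The package works entirely on population-level summaries, the kind of data
that public repositories provide:

* several independent case–control expression studies per stage contrast
  (log2 intensities, genes × samples);
* per-stage genome-wide copy-number alteration (CNA) frequency profiles —
  for each genomic interval, the fraction of tumors with a gain and with a
  loss (the representation used by population CNA databases);
* per-stage gene mutation frequencies;
* an undirected protein–protein interaction network with up/down expression
  labels on the nodes;
* signed pathway topologies (activation/inhibition edges);
* survival records with a per-subject risk score.

No per-sample segmentation, probe-level data or raw sequencing enters the
analysis.

## Stage summaries

**DEG meta-analysis.** Each contrast (DCIS vs normal = DEG1, IDC vs normal =
DEG2, IDC vs DCIS = DEG3, Met vs primary = DEG4) is tested per study with a
Welch two-sample *t*-test per gene on the log2 scale, BH-adjusted within the
study, and per-study p-values are combined across studies with Fisher's
method (`X = -2 Σ log p` against chi-square with `2k` df). A gene enters a
DEG list when its combined p falls below `alpha` (default 0.05). The emitted
direction is the sign of the unweighted mean log2 fold-change; genes with
discordant per-study signs are flagged but kept.

*Which p-values are combined* is a genuine fork. Combining the raw per-study
p-values keeps the null calibrated: with no signal, ~5% of genes pass at
`alpha = 0.05`, which is what the package's calibration suite verifies.
Combining the BH-adjusted values (as meta-analyses that start from
published per-study DEG tables effectively do) is strongly conservative
under the global null because adjusted p-values are stochastically much
larger than uniform. Both modes are exposed
(`run_deg_analysis(..., combine_on = c("raw", "adjusted"))`); raw is the
default for calibration, adjusted is the right choice when the downstream
question is set membership with strict error control (it is what the planted
common/disparate recovery checks use, since there a single false DEG1 entry
misclassifies a gene).

**Common and disparate genes.** DEG3 splits into *common* genes
(DEG1 ∩ DEG2 ∩ DEG3 — invasive-stage changes already present in situ) and
*disparate* genes (the rest of DEG3, acquired at invasion). The partition is
a disjoint cover of DEG3 by construction and is asserted on every run; the
overlap of the disparate set with DEG2 is reported separately because
published counts are compatible with either bookkeeping.

**CNA prototypes.** Genomic intervals whose gain or loss fraction strictly
exceeds `threshold` (default 0.10 — the canonical 10% population prevalence)
in a stage are aberrant; touching same-direction intervals merge with
length-weighted fractions. Overlaying the two stages classifies every
aberrant stretch, separately for gain and loss, into

| class | rule |
|---|---|
| `dcis_specific` | aberrant in DCIS only |
| `idc_specific` | aberrant in IDC only |
| `progressive` | both, IDC fraction − DCIS fraction > tolerance |
| `regressive` | both, DCIS fraction − IDC fraction > tolerance |
| `constant` | both, difference within tolerance |

`constancy_tolerance` defaults to 0.02 (2 percentage points); no numeric
band is published, so it is an exposed knob. The published description of
regressive prototypes reads, word for word, like the progressive one; this
package implements regressive as a frequency *decrease* on invasion, the
only reading that is distinct. Intervals where gain and loss both exceed
the threshold in one stage are labeled `complex` and excluded from every
direction-dependent test. Classification happens on an elementary grid and
merges back, so subdividing an interval never changes the classes.

**Densities.** Genes (with their DEG3 direction) are assigned to prototype
regions by ≥1 bp overlap, largest overlap winning ties, and counted per
(region, gene class, direction); `density = count / length in Mbp`. Rows
with zero counts are kept, and one `outside` block holds the same
quantities over the genome not covered by any prototype. SGA-enriched
stretches are maximal runs of gene midpoints with ≤ 5 Mb between neighbors
(midpoints because no anchor is published; the gap is the published 5 Mb).

## The directional tests

All three tests are matched-pair Wilcoxon signed-rank tests across
prototype regions, two-sided, `alpha = 0.05`, zero differences dropped.
The signed-rank p-value is exact for up to 25 informative pairs via a
shifted-convolution dynamic program over midranks — identical to
enumerating all `2^n` sign assignments, and valid under ties, which Poisson
gene counts produce constantly; beyond 25 pairs a tie-corrected normal
approximation takes over. A result "supports" its model only when the
median difference has the predicted sign *and* p < alpha.

* **Stage concordance** — per prototype, concordant density (up in gains,
  down in losses) vs discordant density; common genes against
  DCIS-aberrant prototypes, disparate genes against IDC-aberrant ones.
* **Forward evolution** — in IDC-specific and progressive prototypes,
  disparate concordant density vs common concordant density; forward
  predicts disparate > common.
* **Backward evolution** — same late prototypes, common genes in the
  direction *opposing* the CNA (down in gains, up in losses), against a
  reference density for the same class/direction. The reference is the
  genome-wide outside-of-CNA density by default; the published pairing
  lives in an unavailable appendix, so the constant-prototype density is
  offered as the alternative (`reference = "constant"`). Backward predicts
  inside < reference.

With fewer than two usable pairs a test returns p = 1 and an
`insufficient_pairs` flag rather than an error.

## Pathway perturbation

Signed topologies propagate expression change linearly: with
`M[t, s] = beta[t, s] / n_downstream(s)`, the perturbation factors solve
`PF = ΔE + M PF`, where `ΔE` carries the mean log2 fold-change of DE genes
and 0 for unchanged genes. `Acc = PF − ΔE`, and `tA = Σ Acc` summarizes net
activation (> 0) or inhibition (< 0). The solve is a dense linear system;
a cycle with unit gain makes `I − M` singular and raises an error naming
the pathway. Three p-values accompany `tA`: `pNDE` (upper-tail
hypergeometric over-representation of DE genes, universe = all genes on any
supplied pathway), `pPERT` (bootstrap: the observed fold-changes are
re-placed on random pathway positions, default 2000 draws, with `+1/(B+1)`
smoothing), and their Fisher combination `pG`, BH-adjusted across pathways;
significance gates on adjusted `pG` since the published account does not
say which of the three its threshold applied to.

**Fine-tuning** compares `|tA|` between an early gene set (common only) and
a late one (all of DEG3) over the pathways significant in both runs;
support requires a positive mean change at p < alpha. **Backward function**
re-enters the "reverted" genes — changes acquired in situ whose invasive
fold-change never reaches the DEG3 list — with their in situ fold-changes
and asks whether `|tA|` *drops* on pathways containing them. Both paired
comparisons pick their test by the published conditional: Student's paired
*t* when the differences pass a D'Agostino–Pearson normality check
(p > 0.05), otherwise the signed-rank test; below n = 8, where the
normality statistic is undefined, the signed-rank test is always used. The
K² omnibus test is implemented in-package (skewness and kurtosis z-scores
against chi-square df 2) and pinned in the tests against reference values.

## Networks, drivers, phylogeny

Hub homogeneity evaluates every node with ≥ `min_degree` (default 4)
connections and calls it homogeneous when ≥ 75% (inclusive) of its
direction-labeled neighbors share one direction; unlabeled neighbors leave
the denominator, and a hub left with fewer than `min_degree` labeled
neighbors is skipped. Two networks' homogeneous/heterogeneous counts meet
in a 2×2 test — chi-square without continuity correction when every
expected cell is ≥ 5, Fisher's exact test otherwise (the published
test-selection rule).

Driver detection per stage: add the stage's frequently mutated genes
(inclusive cutoffs 5% DCIS / 2.5% IDC / 5% Met) to its DEG symbols, induce
the interaction subnetwork on that list, keep hubs with degree ≥ 20, test
the hub set for pathway over-representation (hypergeometric, BH < 0.05),
and return the hubs sitting on at least one pathway that is both enriched
and significantly perturbed. Raising the degree cutoff can only shrink the
answer, which the suite checks.

Stages become taxa of a binary character matrix (1 = gene mutated in the
stage), an all-zero "normal" outgroup is prepended by default, and every
unrooted binary topology (≤ 8 taxa) is scored with an in-package Fitch
pass; all minimum-length trees are returned in a deterministic
(newick-sorted) order. The scoring is cross-checked in the tests against
exhaustive internal-labeling enumeration and against an independent
parsimony implementation.

## Classification and survival

The weighted-voting classifier uses signal-to-noise weights
`w = (μ₁ − μ₂)/(σ₁ + σ₂)` and votes `w (x − (μ₁ + μ₂)/2)`; a zero summed
vote deterministically yields class 1. k-NN uses k = 3, Euclidean distance
on per-gene z-scores, ties to the lower class label. Iterative feature
selection greedily grows a gene set by cross-validated AUC (candidates
ranked by signal-to-noise, a gene kept when it improves the AUC, at most 60
genes), removes the feature from the pool, and repeats for at most nine
rounds or until the AUC is ≤ 0.5 or flat — greedy forward selection is this
package's stand-in for an unpublished search procedure. AUC is the
rank-based Mann–Whitney statistic with half credit for ties; the
concordance index counts comparable survival pairs (earlier time is an
observed event) with half credit for risk ties; the hazard ratio comes from
a two-group Cox fit on a median split of the risk score (a deliberate,
simpler replacement for an interactive "maximize risk groups" splitter).

`signature_size_correlation` scores nested gene sets by a per-gene-weighted
risk sum and correlates set size with CI and HR, alongside a seeded
random-gene-set control of the same sizes. By default the weights are
univariate Cox coefficients fitted on the same records; this in-sample
weighting inflates the CI of larger sets even without any true signal, so
the function accepts externally derived weights, and the package's own
null check supplies fixed random weights.

## The synthetic cohort: what it emulates and what it does not

`generate_cohort()` plants known structure so that every stage of the
pipeline is testable offline:

* **Expression** is per-gene Gaussian on the log2 scale with a
  study-specific baseline shift (a batch surrogate), `noise_sd = 1`, and
  planted stage shifts: *common* genes move `d·lfc` in DCIS and `2 d·lfc`
  in IDC (changes strengthen on invasion), *disparate* genes move only in
  IDC, *dcis_only* genes move in DCIS and stay put (0.95×) afterwards —
  present in DEG1, absent from DEG3, available to the backward-functional
  analysis. Default effect size 1.5 log2 units, 3 studies, 20 samples per
  group: conditions under which planted common genes are recovered near
  completely, as the acceptance script measures.
* **CNA frequencies** are emitted *directly* from the prototype plan — the
  population-frequency representation — never re-estimated from per-sample
  segments, so planted fractions are exact.
* **Planted placement**: planted genes choose genomic slots with
  configurable weights — common genes concentrate in direction-matching
  DCIS-aberrant intervals, disparate genes in direction-matching late
  (IDC-acquired/progressing) intervals, and discordant placements inside
  planned intervals are down-weighted. The defaults therefore plant stage
  concordance, a forward-style disparate excess in late CNAs, and a
  backward-style depletion of opposing common genes, which is what the
  default `run_all()` summary reports as supported verdicts.
* **Density scenarios** (`generate_density_scenario()`) plant effects one
  level down, as Poisson gene counts at chosen per-Mbp rates per
  (class, concordance) cell over 20 prototype regions of 10 Mbp — the scale
  at which type-I error and power are measured.
* **Pathways, networks, mutations, survival**: all-activation cascades with
  planted DE genes upstream (so perturbation actually propagates), spoke
  networks with exact hub degrees and homogeneity fractions, mutation
  frequencies set directly, and exponential survival with hazard
  `∝ exp(risk)` plus uniform censoring, risk being a sum of many small
  Gaussian per-gene effects.

What the generator does **not** emulate: probe-level microarray artifacts,
correlated genes, per-sample copy-number segmentation, subclonal structure,
realistic mutational signatures, or non-proportional hazards. Passing tests
therefore demonstrate that the *procedures* are implemented correctly and
calibrated under their stated assumptions, not that real cohorts satisfy
those assumptions.

## Numerical choices and degenerate inputs

* All randomness flows from one integer master seed through a documented
  Lehmer-style splitter (`split_seed`), kept below 2^31; identical seeds
  give byte-identical outputs end to end.
* p = 0 is clamped to the smallest positive double before logs; genes with
  zero pooled standard error get p = 1.
* Signed-rank: zeros dropped; midrank ties handled exactly by the DP; the
  all-zero case warns and returns p = 1.
* Interval conventions are 0-based half-open everywhere; gene–region
  overlap needs ≥ 1 bp; straddling genes go to the largest overlap.
* A vote margin of exactly 0 is class 1; a k-NN tie is the lower label;
  parsimony ties return every minimum tree, newick-sorted.
* Under the null the backward test's paired differences are slightly
  skewed (Poisson counts against a near-constant outside reference), so
  its measured type-I error sits a point or two above the other tests';
  the calibration suite bounds all three within ±2 points of 5%.

## Problem sizes

The test suite and the acceptance script run at deliberately modest sizes
chosen to exercise every code path with stable statistics: cohorts of
250–600 genes on 5 chromosomes, 2–3 studies with 10–20 samples per group,
24 planted prototype intervals of 10 Mb, 12 pathways of 20 genes,
bootstrap sizes 200–2000, 200 replicates for calibration and 25–50 for
power, and survival components of 150–200 subjects. These sizes keep every
measured rate within its tolerance band while the whole pipeline remains a
desk-scale computation.

## Known limitations

* The backward-test reference is a documented stand-in; with the published
  appendix pairing unavailable, outside-of-CNA density (or constant-CNA
  density) defines "inherited" expectation.
* Reproducing the published prototype count (25) and common/disparate
  split (508/590) requires the original frequency export and supplementary
  DEG lists, which the package does not bundle; the pipeline reproduces
  its own planted counts exactly instead.
* The feature-selection search is greedy and seed-dependent in its
  cross-validation folds; it makes no optimality claim.
* `run_all()` resumes nothing mid-pipeline: a rerun recomputes all stages
  (they are cheap at these sizes); determinism makes the rerun
  byte-identical.
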