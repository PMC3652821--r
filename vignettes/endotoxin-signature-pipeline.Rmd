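---
title: "Deriving a cross-study inhaled-endotoxin gene signature: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving a cross-study inhaled-endotoxin gene signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endosig)
```

## The problem

Repeated low-dose inhalation of endotoxin (lipopolysaccharide, LPS) produces
obstructive lung disease in mice, and several laboratories have profiled the
pulmonary transcriptome of such models. The experiments differ in almost
everything incidental — endotoxin strain, mouse strain, exposure protocol,
and microarray platform — so genes reported by any single study mix real
endotoxin biology with lab- and platform-specific noise. The genes that
replicate *across* all studies are the interesting ones: `endosig`
implements the full chain that extracts such a conserved signature and asks,
quantitatively, whether it could have arisen by chance and whether it carries
biological signal in an independent multi-exposure experiment
(air / LPS / cigarette smoke / LPS+smoke).

The chain is: quantile normalization and probe-to-gene collapse per study;
permutation-based SAM differential expression per study; intersection of the
called gene sets over a common background universe, with exact 2-way and
3-way hypergeometric overlap tests; hypergeometric pathway enrichment with an
enrichment-map export; and consensus-clustering validation of the signature
against a random-signature null. Because the original probe-level array data
were never publicly deposited, a first-class synthetic-data module emulates
the study designs so that every stage is testable offline.

## Synthetic data: what it emulates, and what it does not

`generate_multistudy()` emulates the multi-study design: several independent
two-group studies (control vs. exposed), each on its own "platform" holding a
seeded random subset (default 70%) of a 2000-gene master universe, 1–3
probes per gene, and a planted shared differentially expressed signature
(default 100 genes) forced onto every platform. Forcing matters: real
platforms only partially overlap, and a planted signature that fell off one
platform could never be recovered, so feasibility is checked up front
(`signature_size` must not exceed either the per-study universe or the
expected n-study universe intersection). Planted effects are
`effect_size * noise_sd` on the log2 scale, half up / half down with
directions shared across studies, matching the mixed-direction character of
real exposure signatures. Each study additionally receives private DE genes
(default 150) disjoint from the signature, emulating lab-specific response.

Default conditions are chosen to resemble small murine exposure studies:
group sizes in the 4–8 range (default 6 per group), within-group noise 0.25
on the log2 scale (typical residual SD of RMA-summarized arrays), baseline
intensity 8.0, per-gene baseline spread 1.5, a small probe-level offset
(SD 0.3), and a standardized effect of 3 within-group SDs for planted genes.
About 10% of genes carry no Entrez ID so the symbol-fallback path of gene
harmonization is exercised.

What the generator does *not* model: array spatial artifacts, batch effects,
probe-level sequence biases, correlated gene modules, or heavy-tailed noise.
Passing tests on this generator therefore demonstrate that the pipeline's
logic and statistics are correct under clean Gaussian conditions — not that
any particular real data set satisfies those conditions.

`generate_multicondition()` builds the four-condition validation study
(default group sizes 6/5/6/5, i.e. 22 samples). Per-condition effects are
scalar magnitudes combined with *independent random sign patterns* over the
signature genes. This is deliberate: two conditions with equal magnitude
(e.g. LPS and LPS+smoke both at +2) still receive distinct expression
patterns and remain separable, mirroring how real exposures share genes but
differ in per-gene fold change. An explicit gene-by-condition effect matrix
can be supplied instead when a test needs exact control.

## Normalization and probe collapsing

`quantile_normalize()` (via `limma::normalizeQuantiles`, ties averaged)
forces every sample onto the common distribution of row means of the
column-sorted matrix. Within-column ranks are preserved; tied values receive
the mean of the reference values at their tied ranks. The pipeline's input
contract is *already background-adjusted* log2 intensities — platform-level
raw processing (CEL parsing, convolution background correction, median
polish) is upstream of this package's scope.

`collapse_probes()` maps probes to a harmonized gene key — Entrez ID when
present, otherwise the exact MGI symbol; Entrez is preferred because it is
unambiguous while symbols drift between annotation releases — and summarizes
multi-probe genes either by keeping the probe with the highest mean
intensity (`max_mean`, the default: deterministic and standard in signature
work) or by averaging (`mean`). Ties on mean intensity break to the
lexicographically smallest probe ID. Unmapped probes are dropped and
counted, never imputed.

One numerical subtlety: after quantile normalization a probe that ranks, say,
highest in every sample becomes exactly constant, and a constant gene has
pooled standard error 0. Downstream SAM treats a zero denominator as
"no evidence" (d = 0) rather than propagating NaN.

## SAM differential expression

Per gene, the relative difference is

$$d = \frac{\bar{x}_1 - \bar{x}_2}{s + s_0},$$

with $s$ the pooled standard error of the mean difference and $s_0$ a fudge
factor that stops low-variance genes from dominating. $s_0$ is selected from
the 21 percentiles (0, 5, …, 100) of the $s$ distribution by minimizing the
coefficient of variation of window-wise median absolute deviations of $d$
across 100 equal-count windows of $s$ — when the CV is flat, $d$ no longer
tracks variance. Ties break to the smallest candidate; a degenerate all-equal
$s$ returns $s_0 = 0$ with a warning.

The null is built by permuting group labels: all distinct assignments when
there are no more than `n_permutations` (default 200) of them, otherwise a
seeded sample of distinct assignments. Sorted permuted statistics give
expected order statistics $\bar{d}_{(i)}$; for a threshold $\delta$, the
upper cutoff is the smallest observed $d_{(i)}$ exceeding its expectation by
more than $\delta$ (symmetrically below), genes beyond the cutoffs are
called, and

$$\widehat{\mathrm{FDR}}(\delta) = \hat{\pi}_0 \cdot
\frac{\mathrm{median}_b \, \#\{d^{(b)} \text{ beyond cutoffs}\}}{\max(1, \#\text{called})}.$$

$\delta$ runs on a grid (step 0.05) from 0 to the largest observed
deviation, and the smallest $\delta$ whose estimated FDR is at or below the
target (default 5%) is selected; if none qualifies the called set is empty
and flagged. $\hat\pi_0 = 1$ by default (conservative); mode `"quantile"`
estimates it from the fraction of observed $d$ inside the interquartile band
of the permuted $d$, capped at 1. The conservative default is used because
the multi-study intersection that follows is itself a stringent filter, and
a per-study FDR overestimate only makes the intersection more conservative.

## Signature and overlap significance

Gene universes are harmonized per platform and intersected into the common
background; each study's called set is restricted to that background and the
signature is the k-way intersection. Under the null that each study's called
set is an independent uniform fixed-size subset of the background, the
2-way overlap is hypergeometric, and the 3-way overlap has the exact mixture
tail

$$P(X_3 \ge t) = \sum_m h(m; N, a, b) \, P\!\left(\mathrm{Hyper}(N, m, c) \ge t\right),$$

obtained by conditioning on the size $m$ of the first pairwise intersection:
given $|A \cap B| = m$, the third independent subset intersects it
hypergeometrically. The sum is evaluated in log space (log-sum-exp over
`dhyper`/`phyper` log terms) because real cross-study overlaps produce
p-values far below double-precision underflow in linear space; results are
reported both linear and as log10. Setting $c = N$ recovers the 2-way tail
exactly, a useful internal consistency check.

Pairwise tests default to the *per-pair* universe intersection as the
sampling frame (each pair of platforms defines its own background), with the
all-study common background available by flag; the published analyses are
ambiguous on this point and both variants are logged. The 3-way test always
uses the common background. Independence of the per-study called sets is an
idealization — shared true biology is exactly what the test is meant to
detect, but correlated *errors* (e.g. shared annotation problems) would also
shrink the p-value; the p-value should be read as evidence against "no
shared structure at all".

## Pathway enrichment and the enrichment map

`hypergeom_enrich()` tests each gene set of a user-supplied GMT collection
against a study's DE genes with the one-sided hypergeometric tail, using the
*platform universe of that study* as the sampling frame (not the common
background): each study's DE list was derived against its own universe.
Pathways are intersected with the universe before testing — an unrestricted
pathway size would count genes the platform can never report, diluting the
pathway and inflating the p-value. Benjamini–Hochberg q-values are reported
alongside; the retention rule for the map uses raw p ≤ 0.05 to reproduce
the thresholding convention of the original analyses, with q available for
modern use.

`merge_top_terms()` builds the enrichment map: the union of each study's top
20 terms, retained if significant in at least one study, with edges weighted
by Jaccard similarity of the universe-restricted gene sets and kept at
similarity ≥ 0.25 (the common enrichment-map convention; the edge rule is
not specified by the analyses this reproduces). Node and edge TSVs import
directly into network tools.

Because the exact hypergeometric test is discrete, it is conservative:
$P(p \le 0.05)$ under the null is strictly below 0.05 and depends on the
pathway size. The package's calibration test therefore centers its check on
the exact discrete null expectation (the largest achievable tail at or below
the threshold, averaged over pathways) rather than on the nominal 0.05.

## Consensus-clustering validation

Samples are clustered on the signature genes with average-linkage
agglomerative clustering at distance $1 - r$ (Pearson correlation between
sample profiles) — the dominant convention for expression heatmaps;
Euclidean/complete are available. Genes are mean-centered first, so the
clustering sees patterns, not absolute intensity. `k` defaults to the number
of exposure groups. A zero-variance sample profile makes correlation
undefined and is a named error, not a silent drop.

`consensus_cluster()` subsamples 80% of the signature genes 1000 times
(defaults), reclusters each time, and records (i) the consensus matrix —
the fraction of replicates in which each sample pair co-clusters — and (ii)
the replicate partition. Subsampling is over *features only*: every sample
pair appears in every replicate, so the consensus denominator is simply the
replicate count. "Accurate classification" is operationalized as exact
partition match with the exposure labels up to relabeling (adjusted Rand
index equal to 1) at k = number of groups; the headline
`signature_accuracy` is the fraction of replicates with an exact match.
Mean within-group and between-group consensus are reported alongside, since
published consensus summaries are sometimes quoted as mean pairwise
consensus rather than partition-match rates.

`random_signature_baseline()` repeats the whole procedure for 1000 random
gene sets of the same size drawn from the study universe (50 replicates
each by default, to keep 1000 × 1000 within desk scale). The comparison of
interest is directional: a signature that captures the exposure biology
should beat random sets when the group structure is confined to it, and
should *not* beat them when the structure is spread over all genes — both
directions are exercised in the test suite.

## Numerical and reproducibility choices

* All gene-identifier sorting and ordering uses radix (C-locale) collation,
  so outputs are byte-identical across locales.
* Every random stage takes an explicit seed and restores the caller's RNG
  state; pipeline stage seeds are the global seed plus fixed per-stage
  offsets, so adding a stage never perturbs earlier stages' randomness.
  Identical config + seed gives byte-identical output trees.
* Overlap tails are computed via `phyper`'s log-space tail; the 3-way
  mixture is a log-sum-exp, clipped at 0 to absorb round-off.
* Monte-Carlo cross-checks of the 3-way tail standardize deviations by the
  true-p binomial standard error, and calibration replicates are drawn from
  one continuous RNG stream (per-replicate reseeding with sequential seeds
  showed a small systematic bias in hit rates).
* Zero pooled standard error with $s_0 = 0$ yields $d = 0$ (no evidence)
  instead of NaN.
* Impossible overlaps ($t > \min$ set size) return p = 0 with a warning
  rather than an error, so reports on degenerate inputs still complete.

## Problem sizes in the shipped tests

The test-suite simulations run at desk scale chosen for statistical
resolution at interactive runtimes: 3 studies × 2000 master genes at 70%
universe coverage for signature recovery (10 seeds); 1000-gene single
studies for SAM null (20 seeds) and signal (10 seeds) calibration; a
2×10⁵-draw Monte-Carlo oracle for the 3-way tail; 50-replicate enrichment
null calibration on 50 pathways; and 5-seed paired consensus comparisons
with 200 random signatures × 25 replicates. The demonstration pipeline
configuration (`inst/extdata/demo_config.yaml`) uses 600 master genes and a
40-gene planted signature.

## Known limitations

* Two-class unpaired SAM only; no paired, multiclass, or survival variants,
  and no moderated-t alternative.
* The k-way exact overlap test is implemented for k ≤ 3; larger k would
  need nested mixtures (or Monte Carlo).
* Enrichment is the one-sided hypergeometric overrepresentation test on
  user-supplied GMT files; no GO-graph redundancy pruning and no rank-based
  (GSEA-style) statistics.
* The random-signature null draws uniformly from the universe; it does not
  match expression level or variance strata, so on real data a signature of
  highly variable genes enjoys an advantage a stratified null would remove.
* The synthetic generator's independence and Gaussianity mean calibration
  results transfer to real arrays only to the extent those assumptions hold.
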