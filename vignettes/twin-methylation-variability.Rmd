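---
title: "Methods: differential methylation and variability in discordant twin pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation and variability in discordant twin pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical models behind `twinvar`, the
design of its synthetic twin-cohort generator, and the numerical choices
that a user of the package should know about. It states no empirical
result beyond what the package's test suite and `scripts/acceptance.R`
themselves compute.

## Study design and data model

The package targets methylation BeadChip data (450K-style) from
monozygotic twin pairs discordant for a disease. Methylation at probe
$j$ in sample $i$ is a beta value $\beta_{ij} \in [0,1]$, the proportion
of methylated signal $\beta = M/(M + U + 100)$ with the platform's
conventional offset of 100. Modelling is done on the logit (M-value)
scale $m = \log_2\!\big(\beta/(1-\beta)\big)$, which stabilises the
variance; beta values are clipped into $[\varepsilon, 1-\varepsilon]$
with $\varepsilon = 10^{-6}$ before the transform so M values are always
finite.

## Probe quality control

`filter_probes()` removes probes that (i) fail a detection p-value of
0.01, (ii) map to chromosome X or Y, (iii) carry a SNP within two base
pairs of the interrogated CpG, (iv) are flagged cross-reactive, or
(v) have a bead count below 3 in at least 5% of samples. The detection
rule is ambiguous in common practice, so both readings are supported:
the default `"any"` removes a probe if any sample fails (the strictest
reading), `"fraction"` requires at least 5% of samples to fail.
Cross-reactive status is taken from a flag column or an external ID
list — published lists exist and recomputing cross-reactivity is out of
scope. Filtering is idempotent, and the QC report's per-reason counts
count a probe under every reason it triggers while the removal total
counts the union.

The optional `normalize_type_bias()` step addresses the two Infinium
probe chemistries, whose beta distributions differ systematically.
Per sample, the empirical quantile functions of type I and type II
probes are averaged and both types are quantile-mapped onto the average
using type-5 quantiles at plotting positions $(r - 0.5)/n$, which makes
data where the two types already share a distribution an exact fixed
point. The map is monotone, so within-type ranks are preserved. This is
deliberately a within-array, rank-preserving surrogate for
subset-quantile normalisation: full SWAN operates on raw intensities
stratified by probe-design CpG counts and is not reimplemented here.

## Covariate screening

`pca_covariate_screen()` performs PCA on row-centred M values in sample
space and tests each candidate factor (sex, age, smoking, cohort, chip,
position, estimated cell fractions) against each leading component —
one-way ANOVA for categorical factors, Pearson correlation tests for
continuous ones. Factors with $p < 0.05$ (unadjusted; no threshold is
standard, this is the package's choice) against any of the first four
components are proposed as model covariates. `mds_top_variable()`
embeds samples by classical MDS on the 1000 most variable probes and
scores a candidate grouping by mean silhouette width in the 2-D
embedding — a score near 0 means the grouping does not structure the
methylome (the basis for, e.g., deciding not to adjust for a treatment
variable).

## Differential methylation (DMP)

Per probe, `fit_dmp_model()` fits
$$\beta_{ij} = \mu + \tau\,\mathrm{status}_i + x_i^\top\gamma + a_{p(i)} + e_{ij},
\qquad a_p \sim N(0, \sigma_a^2),\; e \sim N(0, \sigma_e^2)$$
by REML with a sibling-pair random intercept, and reports the two-sided
p-value for $\tau$ with Satterthwaite degrees of freedom, followed by
Benjamini–Hochberg adjustment across probes. Tests run on beta values by
default (effect sizes are then directly interpretable as methylation
differences); the caller may transform to M values first.

Two implementation details matter:

- For the balanced no-covariate design (one case and one control per
  pair) the REML variance components have a closed form through the
  within-pair differences $d_p$ and pair sums $s_p$:
  $\hat\sigma_e^2 = \sum_p (d_p - \bar d)^2 / (2(n-1))$ and
  $\hat\sigma_a^2 = \max\{0, [\sum_p (s_p-\bar s)^2/(n-1) -
  2\hat\sigma_e^2]/4\}$. The variance ratio is plugged directly into the
  mixed-model machinery instead of being estimated by a numerical
  optimiser, whose ~$10^{-7}$ parameter noise would otherwise propagate
  into the reported p-values. In this case the disease-effect test is
  exactly the paired t-test, which the test suite verifies to $10^{-8}$.
- Covariates that never vary within a pair (age, sex, cohort for
  co-twins) carry no information about the within-pair disease contrast
  and are dropped with a message rather than left to produce
  near-aliased designs.

Fits that fail are refit by least squares with fixed pair intercepts and
flagged in the output. `ewas_power()` gives the power of the paired
design from the noncentral t distribution; the standard deviation of
within-pair differences is an explicit argument because no default could
be defended — published power panels for this design rest on empirical
variance estimates that are dataset-specific.

## Differential variability (DVP)

`ievora()` implements the two-stage differential-variability caller:

1. Per probe, a two-group Bartlett test of variance homogeneity; its
   p-values are BH-adjusted across **all** probes (never only a subset)
   and gated at $q < 0.001$.
2. A two-sided Welch t-test on group means over the retained probes,
   gated at $p < 0.05$ and used to rank the calls in ascending order.

The second stage is the "modification" of the plain Bartlett screen: the
Bartlett statistic is exquisitely sensitive to single outliers, and
requiring a nominally significant mean shift suppresses such calls while
ranking by the more robust t-statistic. No additional variance
regularisation is applied; sample variances are floored at $10^{-12}$
only to avoid infinities on constant probes. Each call is labelled with
its hypervariable group (strictly larger sample variance; ties, which
have probability zero in continuous data, resolve to "control") and its
mean trend (`hypo_in_case` when the case mean is below the control
mean). Ranking ties on the t-test p break by smaller Bartlett p, then
lexicographic probe ID, so output files are deterministic. Variability
is tested on beta values, matching how such signatures are visualised
and reported; the M scale can be used by transforming the input.

## Cell composition

`estimate_cell_fractions()` solves, per sample,
$\min_{w \ge 0} \lVert \beta_s - R\,w \rVert_2^2$ over a discriminating
probe subset of the reference panel $R$ (Lawson–Hanson NNLS via
`pracma::lsqnonneg`), then renormalises $w$ to sum to one. The
sum-to-one constraint is applied by renormalisation rather than inside
the solver — the standard practical compromise, which also makes the
estimate invariant to overall intensity scaling. Discriminating probes
are chosen per cell type by the standardised one-vs-rest mean gap
(default 100 per type); an F-statistic ranking would be a reasonable
alternative but the one-vs-rest gap directly mirrors how reference
panels are curated. Group differences in composition are tested by
Welch t-tests, with the convention $t = 0, p = 1$ when both groups are
constant and equal.

## Enrichment

`feature_enrichment()` assesses CpG-island-relation and gene-feature
composition of a probe signature against `n_draws` (default 1000)
uniform draws of equal size from the QC-passed background, reporting
both one-sided empirical p-values with the add-one correction
$(1 + \#\{\text{draws} \ge \text{obs}\})/(n + 1)$, which is never zero.

`probe_bias_gene_test()` corrects gene-set over-representation for
probe-number bias: genes with many probes are more likely to be touched
by any probe-level signature. Each gene's selection propensity is
estimated by isotonic regression of its selection indicator on its
probe count (floored at $10^{-6}$); a set's bias is summarised as
$\text{odds} = \bar w_{\text{in}}/\bar w_{\text{out}}$; and the
over-representation p-value is the upper tail of the Wallenius
noncentral hypergeometric distribution with those odds, computed by
numerical integration of its standard integral representation
(`rel.tol = 1e-10`). With constant probe counts the odds are exactly 1
and the test reduces to the central hypergeometric (`phyper` is used
directly when $|\text{odds} - 1| < 10^{-9}$). P-values are reported
without FDR adjustment across sets: gene sets overlap heavily and the
step-up procedure's independence assumptions do not hold — rankings, not
calibrated q-values, are the deliverable. With very small signatures the
isotonic propensity curve is poorly determined and the odds can be
extreme; results for signatures of a handful of genes should be read as
rankings only.

## Overlap and independent-cohort assessment

Gene-level overlap between two signatures uses the upper-tail
hypergeometric test over the gene universe represented on the QC-passed
array (the universe is the package's choice; no convention exists).
Probe-level overlap against an external signature uses permutation:
the target set is re-drawn uniformly from the background `n_perm`
(default 10,000) times while the external set stays fixed — the
published list is a constant of nature, not a random quantity — and
the empirical p uses the same add-one correction. Uniform redrawing is
the default; annotation-stratified redrawing (matching island
composition) is a documented option left to the caller via the
background argument. `variability_signature_assessment()` computes, per
signature probe, the variance and range (max − min) of beta in case
twins, control twins and an independent cohort, stratified by
hypervariable direction, with quartile aggregates — the qualitative
contract being that a case-hypervariable stratum shows its largest
variance and range in the case group.

## The synthetic twin-cohort generator

`generate_twin_cohort()` is the package's validation instrument, not a
fixture: a first-class, tested model of the study design. Its defaults
encode the cohort the package is built around — 79 discordant pairs, 86%
female pairs, ages $\sim N(54.2, 12.2^2)$ truncated to [18, 90], two
recruitment cohorts in a 62:17 ratio, six blood cell types with
granulocytes dominant, and co-twins always on the same chip.

The generative model, per probe:

- Baseline mean beta from a three-component mixture (low
  $\mathrm{Beta}(2,14)$, mid $\mathrm{Beta}(10,10)$, high
  $\mathrm{Beta}(14,2)$ with weights 0.35/0.20/0.45), mapped to the M
  scale.
- Total M-scale noise SD $\sigma_j = 0.25\,e^{N(0,0.2^2)}$. The 0.25
  centre is derived from typical within-pair beta-difference SDs of
  about 0.03 at intermediate methylation
  ($\sigma_M \approx \sigma_\beta / (\ln 2\,\bar\beta(1-\bar\beta))$);
  per-probe variance magnitudes are otherwise unreported for this
  design, so this is the package's documented choice.
- The pair effect takes a fraction $\rho$ (default 0.8) of that
  variance, giving intra-pair M correlation $\approx \rho$; chip batch
  offsets ($SD$ 0.1) and cell-mixture effects add technical and
  biological structure on top. Cell-mixing weights are Dirichlet with
  blood-like base proportions; a random 10% of probes respond to
  composition, and when a reference panel is supplied its marker probes
  become exact mixtures of the reference profiles so that deconvolution
  is coherent end-to-end.
- **DMP injection**: case betas shifted by `delta_beta` (default 0.05).
- **DVP injection**: the hypervariable group (cases with probability
  0.65, the direction split observed in real twin signatures) receives
  independent extra noise bringing its total per-probe variance to
  $v$ times the other group's (default $v = 4$), plus an M-scale mean
  trend of 0.9 total-SDs, towards hypomethylation with probability
  0.74. Both components are deliberate: real DVPs co-occur with
  directional mean trends of roughly this standardised size (top-ranked
  DVP t-test p-values around $5\times10^{-4}$ at $n = 79$ pairs imply
  standardised shifts near $0.9\sigma$), and a two-stage caller whose
  second gate is a mean test cannot, by construction, recover
  pure-variance effects.
- Effects are injected only at probes with baseline mean beta in
  [0.2, 0.8]: mean shifts need headroom, and methylation variability is
  only expressible away from the fully (un)methylated boundaries.
- Intensities are emitted as $U = (1-\beta)S$,
  $M = \beta(U + 100)/(1-\beta)$ with $S$ log-normal, so
  $\beta = M/(M+U+100)$ holds exactly; detection p-values are small
  except for a configurable failing-probe set, and bead counts are
  $3 + \mathrm{Poisson}(11)$ except for a configurable low-count set.

What the generator does **not** emulate: genotype effects on
methylation, spatial correlation along the genome (probes are
independent given their baseline), age/sex/smoking effects on
methylation itself (these appear only as sample-sheet covariates),
dye/background artefacts, and IDAT-level structure. Passing tests on
synthetic data therefore demonstrate the statistical machinery under the
declared model, not robustness to every artefact of real arrays.

## Numerical choices

- Beta clipping $\varepsilon = 10^{-6}$ for the M transform; generator
  betas clipped to $[10^{-4}, 1-10^{-4}]$ so intensities stay finite.
- Variance floor $10^{-12}$ in the Bartlett statistic.
- BH adjustment via `stats::p.adjust`; the test suite checks it against
  an independent brute-force step-up oracle.
- Wallenius tails by `stats::integrate` (`rel.tol = 1e-10`) summed over
  the upper tail; cross-checked against exhaustive biased-urn
  enumeration in the tests.
- All generator functions take explicit seeds, restore the caller's RNG
  state, and are byte-reproducible; the pipeline fans a single seed out
  to fixed per-stage offsets so stages can be reproduced in isolation.
- Table writers use 6 significant digits (3-digit scientific for p/q
  columns), making reruns byte-identical.

## Validation scale

The test suite and acceptance script exercise the pipeline at the
design's scale where the statistics demand it — 79 pairs × 20,000 probes
for the DVP null (20 seeds) and recovery (5 replicates averaged, since
single-run sensitivity is a stochastic quantity), 500 probes for the
mixed-model/paired-t agreement — and at toy scale for the exact
combinatorial oracles. These sizes are the package's validation design;
the generator itself scales to full-array dimensions.

## Known limitations

- The mixed model is fit probe-by-probe (~50 ms/probe); genome-scale DMP
  runs are batch jobs, not interactive calls. No moderation/shrinkage
  across probes is applied.
- The DVP caller tests marginal variance; it does not model covariates
  or batch inside the variance test. Structure that inflates variance
  differentially between groups will surface as DVPs.
- The probe-bias propensity curve is a simplification of curve-fitting
  approaches used by dedicated gene-set packages; with tiny signatures
  its odds estimates are unstable (see above).
- No region-level (DMR) detection: positions only.
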