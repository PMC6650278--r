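---
title: "Methods: longitudinal dysbiosis dynamics in multi-omic microbiome cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal dysbiosis dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dysbiome` implements a family of longitudinal analyses for gut microbiome
cohorts sampled repeatedly over months: an operational definition of
dysbiosis from Bray–Curtis dissimilarities, survival-style statistics for
dysbiotic episodes, detection of abrupt community shifts, models of temporal
divergence, repeated-measures-aware community statistics, cross-measurement
temporal matching, and residual association networks. Because the methods
are defined by procedures rather than closed-form estimands, the package
ships a synthetic cohort generator with known ground truth; every stage is
tested against that truth or against an independent oracle.

## The dysbiosis score and classification

A sample's dysbiosis score is its **median Bray–Curtis dissimilarity to a
reference set** of control samples,

$$ s_i \;=\; \operatorname{median}\{\, d_{BC}(x_i, x_r) : r \in R,\;
\text{subject}(r) \neq \text{subject}(i) \,\}, $$

where the reference set $R$ contains non-IBD samples collected strictly
after week 20 of each subject's own series (early control samples may still
reflect the gastrointestinal complaints that brought the subject to the
clinic). Excluding the query's own subject prevents a stably unusual
community from certifying itself as typical. Samples are classified
dysbiotic when their score strictly exceeds the 90th percentile
(type-7 linear interpolation, the R default) of the non-IBD score
distribution; by construction about 10% of control samples are flagged.
Both the week cutoff and the percentile are arguments
(`dysbiosis_classify(min_week = 20, percentile = 90)`); ties at the
threshold are non-dysbiotic, matching the "less than 10% probability"
reading.

## Episodes, intervals, and the censored exponential mean

Within each subject's classified series, a **duration** runs from the first
dysbiotic sample of an excursion to the next non-dysbiotic sample, and an
**interval** is the symmetric quantity for eubiotic runs between
excursions. Runs cut off by the end of a series are right-censored at the
last sample. Runs already in progress at the first sample are dropped by
default — their onset is unobserved, and for exponential sojourns
memorylessness makes dropping them unbiased; `include_initial = "censor"`
instead keeps them as censored spans, since published episode counts can be
read either way.

For exponential sojourns with right-censoring the maximum-likelihood mean
has the closed form

$$ \hat m \;=\; \frac{\sum_j \ell_j}{\#\{\text{uncensored}\}},
\qquad \operatorname{SE}(\hat m) = \frac{\hat m}{\sqrt{\#\{\text{uncensored}\}}}, $$

with censored spans contributing to the numerator only. The test suite
checks this against a numerical maximizer of the censored log-likelihood at
tolerance $10^{-6}$, and Kaplan–Meier curves (via the `survival` package)
summarize the same episode sets non-parametrically.

**Discretization.** Sampling every $\Delta$ weeks inflates grid-measured
sojourns: an isolated exponential episode with latent mean $m$, measured as
"week of next opposite-state sample minus week of first in-state sample",
has conditional expectation $\Delta / (1 - e^{-\Delta/m}) \approx m +
\Delta/2$, and short opposite-state sojourns that fall entirely between
sampling times merge adjacent runs, inflating further. The package reports
the grid-measured estimator faithfully and applies no debiasing — the
estimator is the field's, and the bias is a property of the design, not of
the code. At $\Delta = 2$ weeks this matters most for sojourn means near
the sampling resolution (e.g. a 4-week mean is overestimated by roughly a
third), which is why recovery checks on the sampled design carry a
sampling-interval allowance while checks on the continuous-time sojourns
(`$transitions`) hold at 5%.

## Microbiome shifts

A **shift** is a pair of consecutive samples from one subject whose
dissimilarity looks more like a between-person comparison than a
within-person one. For each time-gap window (bins centered on multiples of
the sampling interval, sparse bins pooled upward, at least 30 pairs per
window by default), Gaussian KDEs are fit to the windowed within-subject
dissimilarities of control subjects and to their pooled between-subject
dissimilarities, on a 512-point grid over $[0,1]$. The raw threshold is the
smallest dissimilarity **above the intra-density mode** at which the inter
density exceeds the intra density (linearly interpolated between grid
points); restricting the search to the upper tail avoids spurious low-end
crossings. The final curve is the running maximum over increasing gaps,
since a community naturally diverges from itself and the boundary must be
nondecreasing. Bandwidths use Sheather–Jones where the window has at least
20 points and the Silverman rule below that, recorded per window. A
consequence of the above-mode search worth knowing: if the two
distributions are fully inverted (within-subject dissimilarities above
between-subject ones) there is no upper-tail crossing and the threshold
saturates at 1 — the sanity check for inversion therefore evaluates
foreign pairs against a normally fitted curve rather than refitting on
inverted inputs.

For sparsely sampled measurement types without a clear upward divergence
trend (metabolite-like tables), `single_threshold_variant()` collapses the
construction to one pooled window.

Each call is attributed to the feature with the largest absolute abundance
change between the two samples (ties towards the lexicographically smaller
ID), and group shift rates divide call counts by observed consecutive-pair
time (52 weeks/year).

## Temporal divergence and repeated-measures statistics

Within-subject dissimilarity as a function of time gap is fit by least
squares to $d(\Delta t) = a\,\Delta t^b + c$ with a free intercept, using
derivative-free Nelder–Mead restarted from eight exponents in $[0.05, 1]$
(with $a, c$ from a conditional linear fit at each start) because the RSS
surface is multimodal in $b$; a flat candidate guarantees the nested
inequality $\mathrm{RSS}_{fit} \le \mathrm{RSS}_{flat}$. Note the
parameterization is weakly identified near $b \to 0$, where
$a\,\Delta t^b + c \to (a+c) + ab\,\ln \Delta t$: fits to
logarithmic-looking data may print large offsetting $a$ and $c$ while
describing a perfectly reasonable curve. Significance against a flat line,
and differences between disease groups (joint vs separate fits), use
F-tests on the residual sums of squares.

Community-level testing respects the repeated-measures design:

* `blocked_permanova()` computes the one-term distance-based decomposition
  $R^2 = \operatorname{tr}(HGH)/\operatorname{tr}(G)$ from the
  Gower-centered matrix $G$ and the centered hat matrix $H$, with pseudo-F
  degrees of freedom from the term rank. The null permutes **within
  subject** for time-varying variables, relabels whole subjects for
  subject-constant variables, or permutes freely; missing numeric
  covariates are mean-imputed. Each variable is tested as the sole model
  term, so its $R^2$ is the total variance explainable by that variable.
* `mantel_intra()` correlates two sample-by-sample dissimilarity matrices
  **only over within-subject pairs**, permuting sample labels independently
  within each subject block; `mantel_inter()` correlates subject-mean
  profiles with free subject permutations. Variance explained is the
  squared Mantel statistic.

All permutation p-values are $(1 + \#\{stat_{perm} \ge stat_{obs}\}) /
(1 + n_{perm})$; the default $n_{perm}$ is 999 (no published value exists,
so it is configurable and recorded in outputs). Size was verified by
simulation: at $\alpha = 0.05$ the within-subject PERMANOVA, the blocked
Mantel test, and the power-law F-test all reject within two points of
nominal over 500 null replicates.

## Cross-measurement temporal matching

Measurement types produced from the same stool protocol rarely cover
identical weeks. `match_samples()` implements a greedy matcher: find the
earliest window of width $w$ in which every type has a remaining sample
(window starts scanned over the sorted union of remaining weeks — any
feasible window slides left onto a sample week); take as target the week
where the most types have a sample exactly, ties earlier; per type select
the nearest in-window sample, ties earlier; then discard, per type,
everything up to the later of its selection and the target. Every sample
joins at most one matched set (asserted). One subtlety: the matched-set
count is *not* guaranteed monotone in $w$ — a wider window can consume two
samples of a type in one set where two narrower windows would have made two
sets — so completeness reports should be read as counts under each policy,
not as a nested hierarchy. Strict ($w=0$) counts did not exceed lenient
counts on any cohort we generated.

## Differential abundance, residualization, and the association network

Each feature is transformed (arcsine square root for relative abundances;
$\log(x+1)$ for intensity-like tables; plain log dropping non-finite values
for transcription ratios) and fit with a **random-intercept linear mixed
model** written for this package: the restricted likelihood is profiled
over the variance ratio $\theta = \sigma^2_{subject} / \sigma^2_{resid}$,
whose one-dimensional profile is searched by golden section on
$\log\theta \in [\log 10^{-8}, \log 10^{8}]$ (boundaries checked
explicitly); given $\theta$ the GLS coefficients and variances are closed
form through the block structure of $V = I + \theta ZZ^\top$. Wald z-tests
give per-coefficient p-values, adjusted per model term across features by
Benjamini–Hochberg. The design is intercept + diagnosis + dysbiosis nested
within diagnosis + antibiotic use + consent age + recruitment site, with
recruitment site as a **fixed** categorical covariate rather than a second
random effect — keeping the model to one variance component makes the
profiled REML exact and auditable (the fit is verified against a
1,000-point grid over $\theta$ and against `lme4` on matched designs), at
the cost of spending a few fixed-effect degrees of freedom on sites.

Two calibration facts shape how results should be read. First, the Wald
test is asymptotically exact when residuals are serially independent given
the subject intercept, and the suite verifies near-nominal behaviour in
that regime; under serially correlated residuals *and* a serially
correlated covariate — precisely the situation of a slowly varying
dysbiosis state measured every two weeks — the random-intercept model
underestimates uncertainty and the per-feature type-I error runs above
nominal (about twice nominal under this generator's default
autocorrelation). This inflation is a property of the random-intercept
formulation itself, which the package reproduces deliberately. Second, on
compositional data a large planted effect on some taxa mechanically moves
the relative abundances of *all* taxa, so "null" features in an
effect-spiked compositional simulation genuinely change; false-positive
calibration is therefore only meaningful on cohorts generated with zero
effect.

For the network, features are residualized with the same model (conditional
residuals $V^{-1}(y - X\hat\beta)$, exactly orthogonal to the fixed-effect
columns), adjusting for age, sex, diagnosis, antibiotic/immunosuppressant
use, surgery status, and — in the *adjusted* variant — dysbiosis, so that
surviving correlations reflect within-person covariation beyond disease
state. Subjects with fewer than four samples are dropped for longitudinal
types; baseline-only types use fixed-effects residuals. All-against-all
Spearman correlations between types (t-approximation p-values, BH within
each type pair, tier 0.05 — 0.25 for serology-like types) are ranked by p
(ties by $|\rho|$) and truncated to the top 300 per pair, optionally
restricted to edges touching dysbiosis-associated features; hubs have at
least 20 retained edges. The flat all-against-all testing replaces
hierarchical (tree-guided) association testing by design — with BH within
type pairs it is simpler, and its error control is directly testable.

## The synthetic cohort generator

The generator is first-class, tested code, and its defaults *are* the study
conditions used in the acceptance checks:

| parameter | default | rationale |
|---|---|---|
| subjects per group | 40 / 40 / 40 | cohort of ~120, year-long series |
| study length, sampling | 52 wk, every 2 wk | home-shipment stool protocol |
| sojourn means (dur/int) | CD 7.8/12.8, UC 4.1/17.2, nonIBD 4/36 wk | published Kaplan–Meier fits; non-IBD interval chosen so ~10% of control samples are dysbiotic-state |
| taxa; responsive | 100; 10 depleted + 10 enriched | obligate-anaerobe depletion / facultative-anaerobe enrichment motif |
| effect size | 3 (log scale, ~20-fold) | magnitude of hallmark taxon swings during activity |
| subject SD / temporal SD / AR | 1 / 0.35 / 0.5 | inter-individual variation dominant; within-subject divergence grows with gap |
| missingness | 0.1 per scheduled sample | realistic dropout |
| coupling strength | 0.7 | strong but imperfect cross-type concordance |
| detection limit | $10^{-4}$ relative abundance | zero inflation |

Subjects carry a continuous-time two-state semi-Markov process (alternating
exponential sojourns, initial state eubiotic) discretized by the state
holding at each sampling time; this matches the approximately exponential
published duration/interval distributions while producing exactly the grid
data the pipeline sees. Log-normal per-subject baselines plus AR(1)
temporal noise were chosen over a Dirichlet model to control subject-level
and temporal variance independently — the AR(1) supplies the
within-subject divergence trend that the power-law stage fits. Every
subject draws from an RNG substream named by subject ID and derived from
the master seed, so enlarging a cohort never perturbs existing subjects.
Whether non-IBD dysbiotic-state samples should arise from the same
excursion process as IBD is not settled; the generator exposes the sojourn
means per diagnosis rather than asserting either answer.

What the generator does **not** emulate: read-level sequencing noise,
taxon–taxon interaction structure, correlated subject baselines across
measurement types (cross-type coupling acts only through the dysbiosis
state, so inter-individual cross-type Mantel tests are null by
construction), diet, viromes, host expression, or serology beyond the
generic coupled type. Passing tests therefore demonstrate correctness of
the procedures under a controlled model, not performance on real
sequencing data.

## Problem sizes and numerical choices

Tests and the acceptance script run at desk scale by design: cohorts of
24–120 subjects (up to ~2,900 samples), 60–300 taxa, 199–999 permutations,
500-replicate calibration loops, and 20-replicate parameter-recovery runs —
sizes chosen so the full suite completes in minutes while keeping
Monte-Carlo error well inside the asserted tolerances. Numerical defaults:
golden-section tolerance $10^{-10}$ on $\log\theta$; Nelder–Mead
`reltol` $10^{-12}$ with 8 restarts; KDE grid 512 points; quantiles type 7;
Spearman ties by average ranks; odds ratios use the Haldane–Anscombe 0.5
correction only when a 2×2 margin is zero, with exact p from the
hypergeometric tail.

## Known limitations

* The dysbiosis classification is a marginal outlier rule; no temporal
  smoothing (e.g. HMMs) is applied, so single-sample blips count as
  episodes.
* Grid-measured sojourn statistics inherit the $+\Delta/2$-plus-merging
  bias described above; comparisons across designs with different sampling
  intervals should use the continuous-time process or equal grids.
* The mixed model has a single variance component; site effects are fixed,
  and serial correlation is not modeled (see the calibration notes above).
* Spearman p-values use the t approximation, adequate for the intended
  sample sizes (dozens of matched samples) but optimistic below ~10.
* Bray–Curtis is the only community metric; no phylogeny-aware metrics.
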