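---
title: "Modelling allele-specific accessibility loss during X inactivation"
author: "xcikinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling allele-specific accessibility loss during X inactivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xcikinetics)
```

## The measurement and the model

In hybrid mESC models of X inactivation, sequencing reads that overlap
strain-specific SNPs can be split by haplotype, and each regulatory
element's state on the inactive X is summarised by the allelic ratio
$AR = X_i / (X_i + X_a)$ — 0.5 when both alleles contribute equally,
falling toward 0 as the Xi copy is silenced. Over a multi-day Xist
induction time course, per-element trajectories are well described by a
three-parameter exponential decay

$$y(t) = y_f + y_0\, e^{-kt}$$

where $y$ is the allelic ratio, $t$ is time in days, $y_f$ is the final
(floor) ratio, $y_0 + y_f$ is the initial ratio, and $k \ge 0$ is the
decay rate per day. The floor is a free parameter because complete loss of
Xi accessibility at regulatory elements is rare — unlike nascent
transcription, where fixing $y_f = 0$ is the usual convention; that mode
is available as `fit_mode = "fixed_yf_zero"`.

The assumptions are worth stating plainly: a single exponential relaxation
towards a constant floor; time measured from induction with day 0 as an
uninduced biallelic baseline; replicate ratios exchangeable around the
curve; no lag phase and no non-monotonic behaviour. Elements that gain Xi
signal over time (e.g. the CTCF clusters at *Firre*/*Dxz4*-like loci) are
deliberately representable — $y_0$ may be negative — but they have no
halftime and are handled by the classification rules instead.

## Halftimes: two formula variants

The halftime is the time at which the fitted curve reaches a fraction
$F = 0.5$ of its initial value. Solving $y(t) = F(y_0 + y_f)$ gives

$$t_{1/2} = -\frac{1}{k}\,
  \ln\!\left(\frac{F\,(y_0 + y_f) - y_f}{y_0}\right)$$

which is the package default (`variant = "derived"`). The formula is
sometimes typeset with $(y_0 - y_f)$ in place of $(y_0 + y_f)$; that
variant is implemented verbatim as `variant = "printed"` rather than
silently corrected, because the two coincide exactly when $y_f = 0$
(both reduce to $\ln 2 / k$) and users comparing against existing result
tables may need either. For the worked values $y_0 = 0.4$, $y_f = 0.1$,
$k = 0.3$/day the derived variant gives $-\ln(0.375)/0.3 \approx 3.27$
days and the printed one $-\ln(0.125)/0.3 \approx 6.93$ days, so the
choice matters whenever the floor is substantial; the derived variant is
the one that satisfies "curve at $t_{1/2}$ equals half the initial value"
(asserted to $10^{-9}$ in the test suite).

A halftime is *not applicable* — reported `NA` — when $k \le 0$, when the
log argument is non-positive (the floor exceeds half the initial value),
or when the solution time is non-positive (gainers). Such elements are
never forced into a halftime; they fall through to the classification
rescue rule below.

## Fitting: numerical choices

`fit_decay()` minimises the residual sum of squares under box constraints
$k \ge 0$, $y_f \in [0, 1]$, $y_0 \in [-1, 1]$ using Levenberg–Marquardt
steps (`minpack.lm::nlsLM`, tolerance $10^{-8}$ on parameter and objective
change, at most 1000 iterations) from a multi-start grid
$k \in \{0.05, 0.2, 1, 5\}$ per day, with $y_f$ initialised at the
minimum observed ratio (floored at 0) and $y_0$ at the day-0 mean minus
that. An analytic flat candidate ($k = 0$, level $= \bar y$) is always
evaluated alongside, so constant trajectories return a degenerate
$k = 0$, RSS $= 0$ fit instead of an optimizer failure; ties in RSS
resolve to the flat candidate. The lowest-RSS candidate wins;
`converged = FALSE` marks features where every optimizer start failed and
only best-effort parameters are reported.

All replicate $(t, y)$ points are fitted with equal weight by default
(`fit_points = "replicates"`); a per-timepoint-means mode exists because
published trajectory figures average replicates, and the two options let
users match either convention. Fits require at least three distinct
timepoints including day 0 and refuse anything less.

Cohort-level fitting (`fit_decay_cohort()`) returns a `decay_cohort`
object with a per-feature parameter table and the underlying `decay_fit`
objects, which carry the usual `print`/`coef`/`predict`/`residuals`/
`summary`/`plot`/`simulate` methods.

## Filters, aggregation, classification

The standard allelic filters are implemented exactly as printed in the
field's methods: a feature is kept iff its allele-informative depth
$x_i + x_a$ reaches `min_allelic` (default 10, inclusive) in **strictly
more than** 80% of samples, and its day-0 ratio lies **strictly** inside
the biallelic window — (0.15, 0.85) for the `atac` preset, (0.2, 0.8) for
`chip`. Published methods print "at least 10" for ATAC but ">10" for
ChIP; rather than resolving that discrepancy we expose the comparator
(`min_allelic_strict`) and default both presets to the inclusive form.
The day-0 ratio uses pooled day-0 counts by default (more stable than a
mean of ratios at low depth); the alternative is available.

Per-timepoint ratios default to the mean of per-replicate ratios (matching
how trajectory figures average $n = 2$–3 replicates), with pooled counts
as the alternative; replicates with zero allelic fragments are excluded
from the mean.

Classification: elements with $t_{1/2}$ above the threshold (default 5.4
days) are *persistent*, at or below it *depleted*; elements without a
halftime are rescued into the persistent group when still biallelically
accessible at the final timepoint (ratio > 0.20), otherwise left
unclassified. The 5.4-day / 0.20 defaults follow the precise methods
values over the rounded 6-day / 0.25 figures sometimes quoted; both are
plain config keys (`kinetics.t_threshold_days`, `kinetics.biallelic_npc`).
A `median_split` mode sets the threshold at the median halftime to force
equal group sizes, which is how equal-sized persistent/depleted cohorts
are built in practice. The bookkeeping identity — classifiable =
halftimed + rescued, split into persistent + depleted — is reported by the
pipeline so users can audit their own cohort's counts.

## Interval semantics

Coordinates are 0-based half-open (BED convention) throughout; 1-based
inputs (featureCounts `Start`) are converted at the reader boundary.
Consensus regions are maximal runs of per-base coverage $\ge$
`min_support` across peak files (an any-overlap merge mode is exposed but
non-default), because per-base semantics is the natural reading of
"regions covered by peaks in at least two replicates" and is what the
brute-force oracle in the test suite checks. Support is counted over
*files*: a replicate whose non-overlapping peaks are split across two
files contributes identically. Length bounds (50 bp, 10 kb) are
inclusive. Blacklist subtraction removes whole peaks on any 1-bp overlap
— blacklisted signal marks a mapping artifact, not a region to trim.
Promoter calls use point-to-interval distance to a TSS within 500 bp
(distance 0 for containment; both the "extend the TSS" and
"edge-to-point" readings coincide for a symmetric window). Nearest-gene
ties break to the smaller TSS coordinate, then lexicographic gene id —
the bedtools-closest ambiguity made deterministic. Strand is ignored for
all distances.

## Enrichment and motif scanning

The persistent-vs-depleted contrast is delivered as a 2×2 Fisher exact
test of a property (motif occurrence, TF-binding flag) in the persistent
foreground against the depleted background, reporting the fold enrichment
of proportions and the sample odds ratio $ad/bc$ alongside the two-sided
p-value. This reproduces the fold-enrichment framing of
known-motif-enrichment tools without re-implementing their internal
background models, so exact numerical parity with e.g. HOMER is not
promised.

`pwm_scan()` scores every window of a sequence on both strands with the
log2-odds $\sum_j \log_2(p_{j,b_j}/q_{b_j})$ and returns hits above a
threshold in bits, defaulting to 80% of the maximal achievable score.
Windows containing `N` are skipped. This is a known-motif occurrence scan
in the FIMO style but thresholded in score rather than by a calibrated
p-value — the dynamic-programming score null is out of scope, and the
deviation is deliberate and documented. The JASPAR raw-count reader
converts counts to probabilities with a total pseudocount of 0.8 split by
the background distribution. The shipped example matrix
(`inst/extdata/yy1_like_synthetic.jaspar`) is a synthetic YY1-like motif
for examples and tests, not the real JASPAR entry.

## The synthetic-data generator

The generator exists so every downstream stage is testable with known
ground truth. Totals per feature and sample are negative-binomial
(variance $\mu + \phi\mu^2$; $\phi = 0$ gives Poisson); a fraction of
fragments is allele-informative (binomial thinning); Xi counts are
beta-binomial around the true curve $p(t) = y_f + y_0 e^{-kt}$ with
intra-class correlation $\rho$, which produces the replicate
overdispersion real allelic counts show. Cohort defaults
(`simulate_cohort_truth()`): lognormal decay rates centred at 0.2/day so
implied halftimes centre near 5 days and mostly span ~2–12 days — the
range over which accessibility loss is observable in a course reaching
day 9, matching published cohorts where halftimes cluster around the
5.4-day split and are computable for ~80–90% of elements; day-0 ratios
uniform in (0.42, 0.58) (a biallelic F1 baseline); floors uniform in
(0.02, 0.15); 30% YY1-target elements with rates halved; a small set of
gainers ($y_0 = -0.25$, rising to 0.75). The default time grid
{0, 1, 3, 5, 7, 9} days with 2 replicates per timepoint is loosely
modelled on real designs (3 replicates at day 0, 2 per later timepoint)
but is *not* a claim about any particular study's actual sampling days.
Degron experiments are simulated with independent per-allele
negative-binomial draws so that treated Xi means scale by the programmed
effect while Xa means are untouched.

What the generator does **not** emulate: reads, SNP density and
allele-assignment bias, mappability structure, copy-number or GC effects,
correlated noise between neighbouring elements, and escape
heterogeneity beyond a constant floor. Passing tests on this generator
therefore demonstrate that the estimator and bookkeeping are correct
under the stated noise model — not that any biological conclusion
transfers to a particular real dataset.

Fixed seeds give byte-identical output; `write_fixture_bundle()` emits
the full plain-text input set (per-replicate BED, featureCounts-style
count triple, design table, truth ledger).

## Validation problem sizes

The test suite validates: consensus construction against a per-base
brute-force oracle on 100+ random small instances (≤ 10 kb coordinates,
2–5 replicates); exact Wilcoxon p-values against full enumeration for all
$n + m \le 12$; Fisher p-values against hypergeometric enumeration for
tables with total ≤ 60; nearest-gene assignment against exhaustive
search; halftime identities to $10^{-9}$; and halftime recovery on a
500-feature beta-binomial cohort ($\rho = 0.01$, ~200 allelic
fragments/sample, 6 timepoints × 2 replicates), requiring median relative
error under 15% with rank correlation above 0.9. That recovery bound sits
essentially at the information limit of those noise conditions: restarting
the optimizer at the true parameters does not reduce the error, so the
bound certifies the estimator is efficient rather than merely adequate.
The degron workflow is required to recover a programmed 2-fold Xi effect
to within 0.05 log2 units at the cohort median, with the Xa median pinned
at 0.

## Known limitations

* Halftimes beyond the observation window are extrapolations; their
  relative error grows with $t_{1/2}$ and the persistent/depleted split
  should be read accordingly.
* No confidence intervals on halftimes, and no model comparison against
  alternative decay laws.
* Equal weighting of replicate points ignores depth differences between
  samples; at very low allelic depth the ratio noise is
  depth-dependent.
* The enrichment contrast inherits the usual caveats of 2×2 tests on
  classified features: classification uncertainty is not propagated.
* Differential-expression testing, peak calling, alignment and allele
  assignment are upstream of this package and out of scope.
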