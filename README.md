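# xcikinetics

Quantifying how fast regulatory elements on the inactive X chromosome (Xi)
lose chromatin accessibility — or transcription-factor binding — after Xist
induction, from allele-split sequencing counts.

## The problem

During X chromosome inactivation (XCI), Xist RNA silences genes on one X
chromosome over several days. In hybrid mouse embryonic stem cell models
with an inducible *Xist* allele, reads overlapping strain-specific SNPs can
be assigned to the inactive (Xi) or active (Xa) haplotype, so the state of
each ATAC-seq peak or ChIP-seq peak can be tracked allele-specifically
through a differentiation time course. The central quantity is the
**allelic ratio**

```
AR = Xi / (Xi + Xa)
```

which falls from ~0.5 (biallelic) toward 0 as an element is silenced on Xi.
This package takes per-replicate peak calls and allele-split count tables
(featureCounts-style, from an upstream alignment/SNPsplit/MACS2 stack) and
provides everything downstream:

* consensus regulatory-element sets from replicate peak calls (per-base
  support semantics, length filters, blacklist subtraction);
* allelic-ratio matrices with the standard allelic filters (minimum
  allele-informative fragments in >80% of samples; biallelic signal in
  uninduced cells);
* bounded exponential decay fits per element,

  `y(t) = y_f + y_0 * exp(-k t)`

  with *y* the allelic ratio, *y_f* the final (floor) ratio, *y_0 + y_f*
  the initial ratio, and *k* the decay rate per day. Accessibility-loss
  halftimes are derived as the time at which the curve reaches half its
  initial value,

  `t_1/2 = -(1/k) * ln( (F (y_0 + y_f) - y_f) / y_0 )`, `F = 0.5`;

* classification of elements as **persistent** (t½ above a threshold,
  default 5.4 days, or still biallelically accessible at the endpoint,
  AR > 0.20) versus **depleted**;
* annotation: promoter/distal calls around TSS, nearest-gene assignment
  (bedtools-closest semantics), TF-peak overlap flags, direct-target genes;
* comparison statistics (two-sided Wilcoxon rank-sum, paired t, Spearman),
  a Fisher-exact enrichment contrast of persistent vs depleted elements,
  and a JASPAR PWM scanner for known-motif occurrences;
* allele-separated log2 fold changes for degron (acute TF degradation)
  experiments, with the zero-count exclusion rule;
* a beta-binomial synthetic-data generator with known ground truth, so the
  whole pipeline is testable without any sequencing data.

## Worked example

Simulate a 200-element cohort over a 9-day induction time course, fit the
decay model, classify elements, and test whether simulated YY1-target
elements are enriched among persistent ones:

```r
library(xcikinetics)

truth <- simulate_cohort_truth(200, seed = 11)
sim   <- simulate_timecourse_counts(truth, sim_design(seed = 12))

filt     <- apply_allelic_filters(sim$counts, sim$design)   # atac defaults
counts_f <- subset_counts(sim$counts, features = filt$keep)
rt       <- ratio_timecourse(counts_f, sim$design)

cohort <- fit_decay_cohort(rt, fit_points = "replicates",
                           counts = counts_f, design = sim$design)
cohort
#> Decay-fit cohort: 200 features (free_yf, derived halftimes)
#>   fitted: 200; halftime defined: 177; no halftime: 23
#>   median t1/2 = 5.12 days

cohort$fits[["re_0001"]]
#> Exponential allelic-ratio decay fit [re_0001]
#>   y(t) = yf + y0 * exp(-k t)   (free_yf)
#>   y0 = 0.361, yf = 0.1262, k = 0.1521 /day
#>   t1/2 = 7.384 days, rss = 0.03479 over 12 points

cls <- classify_persistence(cohort, rt$ratio[, "9"])
table(cls$label)
#>   depleted persistent
#>         97        103
```

The fitted `y0`, `yf`, `k` are the decay parameters above; `t1/2 = 7.38`
days means this element is predicted to take ~7.4 days to lose half of its
initial Xi accessibility, so it lands in the persistent group (threshold
5.4 days). The 23 elements with no halftime either never decay by half or
gain Xi signal; those still biallelic at day 9 are rescued into the
persistent group. An enrichment contrast of the programmed YY1 targets:

```r
yy1   <- truth$feature_id[grepl("yy1_target", truth$labels)]
lab   <- cls$label[match(rownames(rt$ratio), cls$feature_id)]
bound <- rownames(rt$ratio) %in% yy1
fisher_enrichment(sum(bound & lab == "persistent"), sum(!bound & lab == "persistent"),
                  sum(bound & lab == "depleted"),   sum(!bound & lab == "depleted"),
                  label = "YY1")
#>   label  a  b  c  d fold_enrichment odds_ratio  p_two_sided infinite_fold
#> 1   YY1 48 55 12 85         3.76699   6.181818 9.688517e-08         FALSE
```

YY1-target elements are ~3.8-fold enriched among persistent elements in
this simulation — the generator programs slower decay at YY1 targets, and
the pipeline recovers it.

For file-based workflows, `run_pipeline(pipeline_config(...))` chains all
stages (consensus BED, filter report, ratio matrix, fits/halftimes/classes,
enrichment table, run log) from a YAML-loadable configuration; see
`?run_pipeline` and the methods vignette in `vignettes/`.

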