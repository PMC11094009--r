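## Ground-truth synthetic data: allele-resolved count time courses,
## replicate peak calls and annotations emulating an allele-specific
## ATAC/ChIP time course of Xist-mediated silencing. Totals are
## negative-binomial; allele-informative fragments are a binomial thinning
## of totals; Xi counts are beta-binomial around the true decay curve
## p(t) = yf + y0 * exp(-k t), giving replicate overdispersion via the
## intra-class correlation rho.

#' Feature-level simulation ground truth
#'
#' Validates and assembles the per-feature truth table driving the count
#' simulators. Invariants: `end > start`; `true_yf` and
#' `true_yf + true_y0` (the initial allelic ratio) in \[0, 1\] so the
#' expected ratio stays a valid ratio at every time.
#'
#' @param feature_id,chrom,start,end feature identity and location (0-based
#'   half-open).
#' @param true_y0,true_yf,true_k decay-model parameters (`true_k` per day,
#'   >= 0; negative `true_y0` encodes elements gaining Xi signal).
#' @param mean_total expected total fragments per sample (> 0).
#' @param dispersion negative-binomial overdispersion of totals (>= 0;
#'   0 = Poisson); variance = mu + dispersion * mu^2.
#' @param allelic_fraction fraction of fragments that are
#'   allele-informative, in (0, 1\].
#' @param rho beta-binomial intra-class correlation in \[0, 1).
#' @param labels character vector (per feature, comma-separated tags from
#'   yy1_target / ctcf_site / escapee / gainer).
#' @return data.frame of class `sim_truth`.
#' @export
sim_feature_truth <- function(feature_id, chrom, start, end, true_y0,
                              true_yf, true_k, mean_total = 500,
                              dispersion = 0.05, allelic_fraction = 0.5,
                              rho = 0.01, labels = "") {
  n <- length(feature_id)
  df <- data.frame(feature_id = as.character(feature_id),
                   chrom = as.character(chrom),
                   start = start, end = end,
                   true_y0 = true_y0, true_yf = true_yf, true_k = true_k,
                   mean_total = mean_total, dispersion = dispersion,
                   allelic_fraction = allelic_fraction, rho = rho,
                   labels = as.character(labels), stringsAsFactors = FALSE)
  if (any(df$end <= df$start)) stop("end must exceed start", call. = FALSE)
  if (any(df$true_k < 0)) stop("true_k must be >= 0", call. = FALSE)
  init <- df$true_y0 + df$true_yf
  bad <- which(init < -1e-12 | init > 1 + 1e-12 | df$true_yf < 0 |
                 df$true_yf > 1)
  if (length(bad) > 0) {
    stop(sprintf("expected allelic ratio leaves [0, 1] for feature '%s'",
                 df$feature_id[bad[1]]), call. = FALSE)
  }
  if (any(df$mean_total <= 0) || any(df$dispersion < 0) ||
      any(df$allelic_fraction <= 0) || any(df$allelic_fraction > 1) ||
      any(df$rho < 0) || any(df$rho >= 1)) {
    stop("invalid noise parameters", call. = FALSE)
  }
  class(df) <- c("sim_truth", "data.frame")
  df
}

#' Time-course simulation design
#'
#' @param timepoints days (must include day 0, the uninduced baseline).
#' @param replicates_per_timepoint replicate count (>= 1).
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @param xi_allele haplotype carrying inducible Xist (`"genome1"` or
#'   `"genome2"`).
#' @param condition,cell_line labels copied into the design table.
#' @return list of class `sim_design`.
#' @export
sim_design <- function(timepoints = c(0, 1, 3, 5, 7, 9),
                       replicates_per_timepoint = 2, seed = 1,
                       xi_allele = c("genome1", "genome2"),
                       condition = "dox", cell_line = "simDom") {
  xi_allele <- match.arg(xi_allele)
  if (!any(timepoints == 0)) {
    stop("design must include day 0 (uninduced baseline)", call. = FALSE)
  }
  if (any(timepoints < 0)) stop("timepoints must be >= 0", call. = FALSE)
  if (replicates_per_timepoint < 1) {
    stop("replicates_per_timepoint must be >= 1", call. = FALSE)
  }
  structure(list(timepoints = sort(unique(timepoints)),
                 replicates_per_timepoint = as.integer(replicates_per_timepoint),
                 seed = as.integer(seed), xi_allele = xi_allele,
                 condition = condition, cell_line = cell_line),
            class = "sim_design")
}

design_table <- function(design) {
  grid <- expand.grid(replicate = seq_len(design$replicates_per_timepoint),
                      day = design$timepoints)
  data.frame(sample_id = sprintf("%s_d%g_r%d", design$condition, grid$day,
                                 grid$replicate),
             day = grid$day, replicate = grid$replicate,
             condition = design$condition, cell_line = design$cell_line,
             xi_allele = design$xi_allele, stringsAsFactors = FALSE)
}

## negative binomial with var = mu + phi mu^2; phi = 0 -> Poisson (vectorized)
rnb <- function(n, mu, phi) {
  mu <- rep_len(mu, n); phi <- rep_len(phi, n)
  out <- integer(n)
  pois <- phi <= 0
  if (any(pois)) out[pois] <- rpois(sum(pois), mu[pois])
  if (any(!pois)) {
    out[!pois] <- rnbinom(sum(!pois), size = 1 / phi[!pois], mu = mu[!pois])
  }
  out
}

## beta-binomial(size, p, rho); rho = 0 -> binomial
rbetabinom <- function(n, size, p, rho) {
  out <- integer(n)
  deg <- p <= 0 | p >= 1 | rho <= 0
  if (any(deg)) {
    out[deg] <- rbinom(sum(deg), size[deg], p[deg])
  }
  if (any(!deg)) {
    a <- p * (1 - rho) / rho
    b <- (1 - p) * (1 - rho) / rho
    pp <- rbeta(sum(!deg), a[!deg], b[!deg])
    out[!deg] <- rbinom(sum(!deg), size[!deg], pp)
  }
  out
}

#' Simulate TSS, TF-peak, and blacklist annotations
#'
#' Places `n_genes` TSS at distinct positions on one chromosome, then
#' `n_tf_peaks` TF ChIP peaks of which exactly
#' `round(tss_overlap_frac * n_tf_peaks)` directly overlap a TSS (creating
#' "direct targets") and the rest avoid all TSS points, plus a small
#' blacklist. Deterministic under `seed`.
#'
#' @param n_genes number of genes (>= 1).
#' @param n_tf_peaks number of TF peaks (>= 0).
#' @param chrom_length chromosome length in bases.
#' @param seed RNG seed.
#' @param tss_overlap_frac fraction of TF peaks that overlap a TSS.
#' @param chrom chromosome name.
#' @param peak_width,n_blacklist geometry knobs.
#' @return list with `tss` (data.frame gene_id/chrom/tss/strand),
#'   `tf_peaks`, `blacklist` (interval data.frames).
#' @export
simulate_annotations <- function(n_genes, n_tf_peaks, chrom_length,
                                 seed = 1, tss_overlap_frac = 0.5,
                                 chrom = "chrXsim", peak_width = 200,
                                 n_blacklist = 3) {
  if (n_genes < 1 || n_tf_peaks < 0 || chrom_length < 10 * (n_genes + 1)) {
    stop("non-positive sizes or chromosome too short", call. = FALSE)
  }
  set.seed(seed)
  tss_pos <- sort(sample.int(chrom_length - 1, n_genes))
  tss <- data.frame(gene_id = sprintf("gene_%03d", seq_len(n_genes)),
                    chrom = chrom, tss = tss_pos,
                    strand = sample(c("+", "-"), n_genes, replace = TRUE),
                    stringsAsFactors = FALSE)
  tf_peaks <- empty_intervals()
  if (n_tf_peaks > 0) {
    n_over <- round(tss_overlap_frac * n_tf_peaks)
    starts <- integer(0)
    if (n_over > 0) {
      at <- sample(tss_pos, n_over, replace = FALSE)
      off <- sample.int(peak_width - 2, n_over, replace = TRUE)
      starts <- pmax(at - off, 0)
    }
    n_away <- n_tf_peaks - n_over
    away <- integer(0)
    while (length(away) < n_away) {
      cand <- sample.int(chrom_length - peak_width - 1, n_away * 2,
                         replace = TRUE)
      ok <- vapply(cand, function(s) {
        !any(tss_pos >= s & tss_pos < s + peak_width)
      }, logical(1))
      away <- unique(c(away, cand[ok]))
    }
    starts <- c(starts, away[seq_len(n_away)])
    tf_peaks <- genomic_intervals(chrom, starts, starts + peak_width,
                                  name = sprintf("tf_%03d", seq_along(starts)))
  }
  bl_start <- sample.int(chrom_length - 1000, n_blacklist)
  blacklist <- genomic_intervals(chrom, bl_start, bl_start + 500,
                                 name = sprintf("bl_%d", seq_len(n_blacklist)))
  list(tss = tss, tf_peaks = tf_peaks, blacklist = blacklist)
}

#' Simulate per-replicate peak calls around true intervals
#'
#' Each replicate retains each true interval with probability
#' `1 - dropout_rate`, with boundaries perturbed by integer-rounded
#' Gaussian jitter and clipped to width >= 1 bp and start >= 0.
#'
#' @param truth `sim_truth` table or interval data.frame.
#' @param n_replicates number of replicate peak files (>= 2).
#' @param jitter_sd boundary jitter standard deviation in bases (>= 0).
#' @param dropout_rate per-replicate peak dropout probability in \[0, 1).
#' @param seed RNG seed.
#' @return list of interval data.frames, one per replicate.
#' @export
simulate_replicate_peaks <- function(truth, n_replicates = 2, jitter_sd = 10,
                                     dropout_rate = 0.1, seed = 1) {
  if (n_replicates < 2) stop("n_replicates must be >= 2", call. = FALSE)
  if (jitter_sd < 0) stop("jitter_sd must be >= 0", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must lie in [0, 1)", call. = FALSE)
  }
  set.seed(seed)
  lapply(seq_len(n_replicates), function(r) {
    keep <- runif(nrow(truth)) >= dropout_rate
    tr <- truth[keep, , drop = FALSE]
    if (nrow(tr) == 0) return(empty_intervals())
    s <- tr$start + round(rnorm(nrow(tr), 0, jitter_sd))
    e <- tr$end + round(rnorm(nrow(tr), 0, jitter_sd))
    s <- pmax(s, 0)
    e <- pmax(e, s + 1)
    genomic_intervals(tr$chrom, s, e,
                      name = sprintf("%s_rep%d", tr$feature_id, r))
  })
}

#' Simulate an allele-resolved count time course
#'
#' For each feature x sample: total fragments are negative-binomial with
#' the feature's mean and overdispersion; `n = round(allelic_fraction *
#' total)` fragments are allele-informative; Xi counts are beta-binomial
#' with success probability `p(t) = true_yf + true_y0 * exp(-true_k * day)`
#' and intra-class correlation `rho`; Xa = n - Xi.
#'
#' @param truth `sim_truth` table.
#' @param design `sim_design` object.
#' @return list with `counts` (an [allelic_counts()] object) and `design`
#'   (the sample design table).
#' @export
simulate_timecourse_counts <- function(truth, design) {
  stopifnot(inherits(design, "sim_design"))
  if (nrow(truth) == 0) stop("truth must be non-empty", call. = FALSE)
  dt <- design_table(design)
  set.seed(design$seed)
  nf <- nrow(truth); ns <- nrow(dt)
  total <- xi <- xa <- matrix(0L, nf, ns,
                              dimnames = list(truth$feature_id, dt$sample_id))
  for (j in seq_len(ns)) {
    p <- decay_curve(dt$day[j], truth$true_y0, truth$true_yf, truth$true_k)
    bad <- which(p < -1e-9 | p > 1 + 1e-9)
    if (length(bad) > 0) {
      stop(sprintf("expected ratio outside [0, 1] at day %g for feature '%s'",
                   dt$day[j], truth$feature_id[bad[1]]), call. = FALSE)
    }
    p <- pmin(pmax(p, 0), 1)
    tot <- rnb(nf, truth$mean_total, truth$dispersion)
    n_all <- as.integer(round(truth$allelic_fraction * tot))
    xi_j <- rbetabinom(nf, n_all, p, truth$rho)
    total[, j] <- as.integer(tot)
    xi[, j] <- xi_j
    xa[, j] <- n_all - xi_j
  }
  features <- truth[, c("feature_id", "chrom", "start", "end")]
  counts <- allelic_counts(features, total, xi, xa,
                           xi_allele = design$xi_allele)
  list(counts = counts, design = dt)
}

#' Simulate a degron (control vs treated) experiment
#'
#' Control and treated allele counts are drawn independently per allele
#' (negative-binomial around the allele means implied by the decay curve);
#' in the treated arm the Xi mean of `yy1_target`-labelled features is
#' scaled by `target_effect` and of all other features by
#' `offtarget_effect`, while Xa means are untouched — emulating an acute
#' TF-degradation experiment where silencing deepens on Xi only.
#'
#' @param truth `sim_truth` table (targets tagged `yy1_target` in `labels`).
#' @param design `sim_design` object.
#' @param target_effect,offtarget_effect multiplicative Xi effects (> 0).
#' @return list with `control`, `treated` ([allelic_counts()] objects) and
#'   `design` (shared design table).
#' @export
simulate_degron_counts <- function(truth, design, target_effect = 0.5,
                                   offtarget_effect = 1) {
  stopifnot(inherits(design, "sim_design"))
  if (target_effect <= 0 || offtarget_effect <= 0) {
    stop("effect multipliers must be > 0", call. = FALSE)
  }
  dt <- design_table(design)
  set.seed(design$seed)
  is_target <- grepl("yy1_target", truth$labels)
  eff <- ifelse(is_target, target_effect, offtarget_effect)
  nf <- nrow(truth); ns <- nrow(dt)
  draw <- function(xi_mult) {
    total <- xi <- xa <- matrix(0L, nf, ns,
                                dimnames = list(truth$feature_id,
                                                dt$sample_id))
    for (j in seq_len(ns)) {
      p <- pmin(pmax(decay_curve(dt$day[j], truth$true_y0, truth$true_yf,
                                 truth$true_k), 0), 1)
      mu_all <- truth$allelic_fraction * truth$mean_total
      xi_j <- rnb(nf, mu_all * p * xi_mult, truth$dispersion)
      xa_j <- rnb(nf, mu_all * (1 - p), truth$dispersion)
      extra <- rnb(nf, (1 - truth$allelic_fraction) * truth$mean_total,
                   truth$dispersion)
      total[, j] <- xi_j + xa_j + extra
      xi[, j] <- xi_j
      xa[, j] <- xa_j
    }
    allelic_counts(truth[, c("feature_id", "chrom", "start", "end")],
                   total, xi, xa, xi_allele = design$xi_allele)
  }
  control <- draw(rep(1, nf))
  treated <- draw(eff)
  list(control = control, treated = treated, design = dt)
}

#' Generate a realistic cohort ground truth
#'
#' Draws a cohort of regulatory elements with log-uniform decay rates
#' (halftimes spanning roughly half a day to two weeks), biallelic initial
#' ratios, modest Xi floors, and a tagged subset of YY1 targets (slower
#' decay), CTCF sites and gainers (negative `true_y0`, increasing Xi
#' signal). Serves as default input for the simulators.
#'
#' @param n_features cohort size.
#' @param seed RNG seed.
#' @param mean_total,dispersion,allelic_fraction,rho noise parameters
#'   passed to [sim_feature_truth()].
#' @param frac_yy1,frac_gainer label fractions.
#' @param chrom,feature_width geometry.
#' @return `sim_truth` table.
#' @export
simulate_cohort_truth <- function(n_features = 200, seed = 1,
                                  mean_total = 500, dispersion = 0.05,
                                  allelic_fraction = 0.5, rho = 0.01,
                                  frac_yy1 = 0.3, frac_gainer = 0.03,
                                  chrom = "chrXsim", feature_width = 800) {
  set.seed(seed)
  ## evenly spaced along a ~150 Mb chromosome with jitter; never overlapping
  step <- floor((150e6 - 2 * feature_width) / n_features)
  step <- max(step, 2 * feature_width)
  start <- feature_width + step * (seq_len(n_features) - 1) +
    sample.int(max(step %/% 4, 2), n_features, replace = TRUE)
  ## decay rates: log-normal around 0.2/day so implied halftimes centre
  ## near 5 days and mostly span ~2-12 days, the range over which
  ## accessibility loss is observable in a time course reaching day 9;
  ## day-0 ratios sit tightly around 0.5 (biallelic F1 hybrid baseline)
  ## above a modest Xi floor (complete loss of accessibility is rare)
  k <- exp(rnorm(n_features, log(0.2), 0.45))
  init <- runif(n_features, 0.42, 0.58)
  yf <- runif(n_features, 0.02, 0.15)
  y0 <- init - yf
  labels <- rep("", n_features)
  yy1 <- sample.int(n_features, round(frac_yy1 * n_features))
  labels[yy1] <- "yy1_target"
  k[yy1] <- k[yy1] * 0.5             # targets decay slower
  gain <- sample(setdiff(seq_len(n_features), yy1),
                 max(1, round(frac_gainer * n_features)))
  labels[gain] <- paste0(labels[gain], "gainer")
  y0[gain] <- -0.25
  yf[gain] <- 0.75
  sim_feature_truth(sprintf("re_%04d", seq_len(n_features)), chrom,
                    start, start + feature_width, y0, yf, k,
                    mean_total = mean_total, dispersion = dispersion,
                    allelic_fraction = allelic_fraction, rho = rho,
                    labels = labels)
}
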