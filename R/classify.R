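## Persistent / depleted classification of regulatory elements, and the
## day0 -> dayN change in allelic ratio used to compare TF eviction rates.

#' Classify regulatory elements as persistent or depleted
#'
#' Elements with a defined accessibility-loss halftime above `t_threshold`
#' are persistent (`halftime_above`); at or below it, depleted
#' (`halftime_below`). Elements without a halftime (flat fits, gainers,
#' high floors) are rescued as persistent when they remain biallelically
#' accessible at the final timepoint (`npc_ratio > biallelic_npc`,
#' basis `biallelic_npc`), otherwise left unclassified
#' (`no_fit_dropped`). The default thresholds are 5.4 days and 0.20.
#' `mode = "median_split"` instead sets the halftime threshold to the
#' median halftime of classifiable features, forcing equal-sized groups.
#'
#' @param cohort `decay_cohort` object or its `$table` data.frame (needs
#'   `feature_id`, `t_half`).
#' @param npc_ratios named numeric vector of final-timepoint (NPC) allelic
#'   ratios per feature (mean of final-timepoint replicate ratios).
#' @param t_threshold halftime threshold in days.
#' @param biallelic_npc NPC allelic-ratio threshold for the rescue rule.
#' @param mode `"threshold"` (default) or `"median_split"`.
#' @return data.frame: `feature_id`, `label` (persistent/depleted/
#'   unclassified), `basis`, `t_half`, `npc_ratio`, plus the threshold used
#'   as attribute `t_threshold`.
#' @export
classify_persistence <- function(cohort, npc_ratios, t_threshold = 5.4,
                                 biallelic_npc = 0.20,
                                 mode = c("threshold", "median_split")) {
  mode <- match.arg(mode)
  tab <- if (inherits(cohort, "decay_cohort")) cohort$table else cohort
  t_half <- tab$t_half
  if (mode == "median_split") {
    t_threshold <- median(t_half, na.rm = TRUE)
  }
  npc <- unname(npc_ratios[match(tab$feature_id, names(npc_ratios))])

  label <- character(nrow(tab)); basis <- character(nrow(tab))
  has_t <- !is.na(t_half)
  label[has_t & t_half > t_threshold] <- "persistent"
  basis[has_t & t_half > t_threshold] <- "halftime_above"
  label[has_t & t_half <= t_threshold] <- "depleted"
  basis[has_t & t_half <= t_threshold] <- "halftime_below"
  rescue <- !has_t & !is.na(npc) & npc > biallelic_npc
  label[rescue] <- "persistent"; basis[rescue] <- "biallelic_npc"
  rest <- !has_t & !rescue
  label[rest] <- "unclassified"; basis[rest] <- "no_fit_dropped"

  out <- data.frame(feature_id = tab$feature_id, label = label,
                    basis = basis, t_half = t_half, npc_ratio = npc,
                    stringsAsFactors = FALSE)
  attr(out, "t_threshold") <- t_threshold
  out
}

#' Change in allelic ratio between two timepoints
#'
#' Per-feature delta `AR(t0) - AR(t1)` (a decrease in Xi signal is reported
#' as a positive delta) and the cohort median over defined deltas — the
#' statistic used to compare how fast different TFs are evicted from Xi
#' (e.g. day 0 to day 6 of Xist induction).
#'
#' @param ratios_t0,ratios_t1 named numeric vectors of allelic ratios at the
#'   two timepoints (matched by name when both are named).
#' @return list with `delta` (named per-feature vector) and `median`.
#' @export
delta_allelic_ratio <- function(ratios_t0, ratios_t1) {
  if (!is.null(names(ratios_t0)) && !is.null(names(ratios_t1))) {
    common <- intersect(names(ratios_t0), names(ratios_t1))
    ratios_t0 <- ratios_t0[common]; ratios_t1 <- ratios_t1[common]
  } else {
    stopifnot(length(ratios_t0) == length(ratios_t1))
  }
  delta <- ratios_t0 - ratios_t1
  list(delta = delta, median = median(delta, na.rm = TRUE))
}
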