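## Comparison statistics used throughout: two-sided Wilcoxon rank-sum,
## paired t, Spearman's rho, and the persistent-vs-depleted enrichment
## contrast as a Fisher exact test with fold enrichment. The hypothesis
## tests delegate to the corresponding base R routines; fold enrichment and
## the sample odds ratio are computed here.

#' Two-sided Wilcoxon rank-sum test
#'
#' Midranks for ties; exact enumeration when `n + m <= 20` and there are no
#' ties, otherwise the tie-corrected normal approximation with continuity
#' correction (the default unpaired comparison between two groups of genes
#' or regulatory elements).
#'
#' @param x,y non-empty numeric samples.
#' @param mode `"auto"` (exact when small and tie-free), `"exact"`, or
#'   `"normal_approx"`.
#' @return list with `statistic` (Mann-Whitney U for `x`) and `p` (two-sided).
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(mode,
                  auto = (length(x) + length(y) <= 20) && !has_ties,
                  exact = TRUE,
                  normal_approx = FALSE)
  if (exact && has_ties) {
    stop("exact mode is undefined in the presence of ties", call. = FALSE)
  }
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE,
                                     alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p = ht$p.value,
       exact = exact)
}

#' Two-sided paired t test
#'
#' Classical paired t on the differences, df = n - 1; used to compare the
#' same set of genes under two conditions. Refuses degenerate inputs whose
#' paired differences have zero variance.
#'
#' @param x,y equal-length numeric vectors (n >= 2).
#' @return list with `t`, `p`, `df`, `mean_difference`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop("paired samples must have equal length >= 2", call. = FALSE)
  }
  d <- x - y
  if (isTRUE(all.equal(var(d), 0)) || var(d) == 0) {
    stop("paired differences have zero variance; t statistic undefined",
         call. = FALSE)
  }
  ht <- t.test(x, y, paired = TRUE, alternative = "two.sided")
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_difference = mean(d))
}

#' Spearman's rank correlation
#'
#' Pearson correlation of midranks. Returns `NA` for constant input.
#'
#' @param x,y equal-length numeric vectors (n >= 3).
#' @return rho, or `NA_real_` when undefined.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need equal-length vectors of length >= 3", call. = FALSE)
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y, method = "spearman")
}

#' Fisher enrichment contrast between a foreground and a background set
#'
#' Tests whether a property (e.g. a motif occurrence or a TF-binding flag)
#' is enriched among foreground features (e.g. persistent REs) relative to
#' background features (e.g. depleted REs). `a`/`b` = foreground with /
#' without the property; `c`/`d` = background with / without. Two-sided
#' Fisher exact p (summation of hypergeometric tables no more probable than
#' the observed one), the fold enrichment of proportions
#' `(a/(a+b)) / (c/(c+d))`, and the sample odds ratio `ad/bc`.
#'
#' @param a,b,c,d non-negative counts of the 2x2 table.
#' @param label optional label carried through.
#' @return data.frame row: `label`, `a`, `b`, `c`, `d`, `fold_enrichment`,
#'   `odds_ratio`, `p_two_sided`. A zero background proportion gives
#'   infinite fold enrichment, flagged via the `infinite_fold` column.
#' @export
fisher_enrichment <- function(a, b, c, d, label = NA_character_) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("a, b, c, d must be non-negative integers", call. = FALSE)
  }
  if (a + b == 0 || c + d == 0) {
    stop("both foreground and background margins must be nonzero",
         call. = FALSE)
  }
  p <- fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE))$p.value
  fg <- a / (a + b); bg <- c / (c + d)
  fold <- if (bg == 0) Inf else fg / bg
  orat <- if (b * c == 0) Inf else (a * d) / (b * c)
  data.frame(label = label, a = a, b = b, c = c, d = d,
             fold_enrichment = fold, odds_ratio = orat, p_two_sided = p,
             infinite_fold = !is.finite(fold), stringsAsFactors = FALSE)
}
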