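## Bounded exponential decay model of Xi allelic-ratio loss:
##
##    y(t) = yf + y0 * exp(-k t)
##
## y  = allelic ratio at time t (days); yf = final allelic ratio;
## y0 + yf = initial allelic ratio; k = decay rate per day (>= 0).
## yf is a free parameter by default (complete loss of Xi accessibility is
## rare at regulatory elements); a fixed-yf-at-zero mode matches the
## convention used for nascent-transcription silencing fits.

decay_curve <- function(t, y0, yf, k) yf + y0 * exp(-k * t)

#' Fit the exponential allelic-ratio decay model
#'
#' Bounded nonlinear least squares for \eqn{y = y_f + y_0 e^{-kt}} with
#' \eqn{k \ge 0}, \eqn{y_f \in [0,1]}, \eqn{y_0 \in [-1,1]} (negative
#' \eqn{y_0} lets elements that gain Xi signal fit rather than error).
#' Levenberg-Marquardt steps (via \code{minpack.lm::nlsLM}) are run from a
#' multi-start grid over \eqn{k \in \{0.05, 0.2, 1, 5\}} per day with
#' \eqn{y_f} initialized at the minimum observed ratio and \eqn{y_0} at the
#' day-0 ratio minus that; an analytic flat candidate (\eqn{k = 0}) is
#' always evaluated so constant trajectories return a degenerate fit rather
#' than an optimizer failure. The best (lowest-RSS) candidate is returned;
#' `converged` is FALSE when every optimizer start failed to satisfy its
#' tolerance and only best-effort parameters are available.
#'
#' @param timepoints numeric vector of days (>= 3 distinct values including
#'   day 0 required).
#' @param ratios allelic ratios in \[0, 1\], same length; NA pairs dropped.
#' @param fit_mode `"free_yf"` (default) or `"fixed_yf_zero"`.
#' @param feature_id optional label carried into the result.
#' @param k_starts multi-start decay-rate grid (per day).
#' @param max_iter,tol optimizer iteration cap and tolerance on parameter
#'   change.
#' @return An object of class `decay_fit`: list with `y0`, `yf`, `k`, `rss`,
#'   `converged`, `fit_mode`, `t_half` (derived variant, NA when the curve
#'   never reaches half its initial value), `data` (points used), `n`.
#' @seealso [halftime()], [fit_decay_cohort()]
#' @export
fit_decay <- function(timepoints, ratios,
                      fit_mode = c("free_yf", "fixed_yf_zero"),
                      feature_id = NA_character_,
                      k_starts = c(0.05, 0.2, 1, 5),
                      max_iter = 1000, tol = 1e-8) {
  fit_mode <- match.arg(fit_mode)
  stopifnot(length(timepoints) == length(ratios))
  keep <- !is.na(timepoints) & !is.na(ratios)
  t <- as.numeric(timepoints[keep]); y <- as.numeric(ratios[keep])
  if (length(unique(t)) < 3 || !any(t == 0)) {
    stop("fit requires >= 3 distinct timepoints including day 0",
         call. = FALSE)
  }
  if (any(y < -1e-9) || any(y > 1 + 1e-9)) {
    stop("ratios must lie in [0, 1]", call. = FALSE)
  }

  y0_day0 <- mean(y[t == 0])
  yf_init <- max(min(y), 0)
  if (fit_mode == "fixed_yf_zero") yf_init <- 0

  rss_of <- function(p) sum((y - decay_curve(t, p[1], p[2], p[3]))^2)

  ## analytic flat candidate: k = 0, constant level = mean(y)
  flat <- list(y0 = 0, yf = min(max(mean(y), 0), 1), k = 0, ok = TRUE)
  flat$rss <- rss_of(c(flat$y0, flat$yf, flat$k))
  if (fit_mode == "fixed_yf_zero") {
    flat <- list(y0 = min(max(mean(y), -1), 1), yf = 0, k = 0, ok = TRUE)
    flat$rss <- rss_of(c(flat$y0, flat$yf, flat$k))
  }

  cands <- list(flat)
  for (k0 in k_starts) {
    y0_init <- min(max(y0_day0 - yf_init, -1), 1)
    fit <- tryCatch({
      if (fit_mode == "free_yf") {
        m <- minpack.lm::nlsLM(
          y ~ yf + y0 * exp(-k * t),
          start = list(y0 = y0_init, yf = yf_init, k = k0),
          lower = c(y0 = -1, yf = 0, k = 0), upper = c(y0 = 1, yf = 1, k = Inf),
          control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                               ptol = tol, ftol = tol))
        p <- coef(m)
        list(y0 = unname(p["y0"]), yf = unname(p["yf"]), k = unname(p["k"]),
             rss = sum(residuals(m)^2), ok = TRUE)
      } else {
        m <- minpack.lm::nlsLM(
          y ~ y0 * exp(-k * t),
          start = list(y0 = min(max(y0_day0, -1), 1), k = k0),
          lower = c(y0 = -1, k = 0), upper = c(y0 = 1, k = Inf),
          control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                               ptol = tol, ftol = tol))
        p <- coef(m)
        list(y0 = unname(p["y0"]), yf = 0, k = unname(p["k"]),
             rss = sum(residuals(m)^2), ok = TRUE)
      }
    }, error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) cands[[length(cands) + 1]] <- fit
  }

  best <- cands[[which.min(vapply(cands, `[[`, numeric(1), "rss"))]]
  converged <- length(cands) > 1 || best$rss <= tol
  out <- structure(
    list(feature_id = feature_id, y0 = best$y0, yf = best$yf, k = best$k,
         rss = best$rss, converged = converged, fit_mode = fit_mode,
         data = data.frame(t = t, ratio = y), n = length(y)),
    class = "decay_fit")
  out$t_half <- halftime(out)
  out
}

#' Accessibility-loss halftime from a decay fit
#'
#' Time at which the fitted curve reaches a fraction `F` of its initial
#' value. Two formula variants are provided. `derived` solves
#' \eqn{y_f + y_0 e^{-kt} = F (y_0 + y_f)} (initial value =
#' \eqn{y_0 + y_f}), giving
#' \eqn{t = -\frac{1}{k}\ln\frac{F(y_0+y_f) - y_f}{y_0}}. `printed`
#' evaluates the typeset form
#' \eqn{t = -\frac{1}{k}\ln\frac{F(y_0-y_f) - y_f}{y_0}} exactly as
#' published. The two coincide whenever \eqn{y_f = 0} (both reduce to
#' \eqn{\ln 2 / k} at F = 0.5). Not applicable (NA) when \eqn{k \le 0},
#' when the log argument is non-positive, or when the solution time is not
#' positive — i.e. for elements whose Xi signal never falls to half its
#' initial value (flat trajectories, gainers, high floors).
#'
#' @param fit `decay_fit` object (or a list with `y0`, `yf`, `k`).
#' @param F target fraction of the initial value (default 0.5).
#' @param variant `"derived"` (default) or `"printed"`.
#' @return halftime in days, or `NA_real_` when not applicable.
#' @export
halftime <- function(fit, F = 0.5, variant = c("derived", "printed")) {
  variant <- match.arg(variant)
  y0 <- fit$y0; yf <- fit$yf; k <- fit$k
  if (is.na(k) || k <= 0 || is.na(y0) || y0 == 0) return(NA_real_)
  num <- if (variant == "derived") F * (y0 + yf) - yf else F * (y0 - yf) - yf
  arg <- num / y0
  if (!is.finite(arg) || arg <= 0) return(NA_real_)
  t <- -log(arg) / k
  if (!is.finite(t) || t <= 0) return(NA_real_)
  t
}

#' @export
print.decay_fit <- function(x, digits = 4, ...) {
  cat("Exponential allelic-ratio decay fit")
  if (!is.na(x$feature_id)) cat(" [", x$feature_id, "]", sep = "")
  cat("\n  y(t) = yf + y0 * exp(-k t)   (", x$fit_mode, ")\n", sep = "")
  cat(sprintf("  y0 = %.*g, yf = %.*g, k = %.*g /day\n", digits, x$y0,
              digits, x$yf, digits, x$k))
  cat(sprintf("  t1/2 = %s days, rss = %.*g over %d points%s\n",
              if (is.na(x$t_half)) "n/a" else formatC(x$t_half, digits = digits),
              digits, x$rss, x$n,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) {
  c(y0 = object$y0, yf = object$yf, k = object$k)
}

#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$t
       else if (is.data.frame(newdata)) newdata$t else as.numeric(newdata)
  decay_curve(t, object$y0, object$yf, object$k)
}

#' @export
residuals.decay_fit <- function(object, ...) {
  object$data$ratio - predict(object)
}

#' @export
summary.decay_fit <- function(object, ...) {
  structure(list(fit = object,
                 initial = object$y0 + object$yf,
                 final = object$yf,
                 t_half_derived = halftime(object, variant = "derived"),
                 t_half_printed = halftime(object, variant = "printed")),
            class = "summary.decay_fit")
}

#' @export
print.summary.decay_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  initial ratio %.4g -> final %.4g; t1/2 derived = %s, printed = %s\n",
              x$initial, x$final,
              if (is.na(x$t_half_derived)) "n/a" else formatC(x$t_half_derived, digits = 4),
              if (is.na(x$t_half_printed)) "n/a" else formatC(x$t_half_printed, digits = 4)))
  invisible(x)
}

#' @export
plot.decay_fit <- function(x, xlab = "time (days)", ylab = "Xi allelic ratio",
                           main = x$feature_id, ...) {
  plot(x$data$t, x$data$ratio, xlab = xlab, ylab = ylab, main = main,
       ylim = c(0, 1), pch = 19, ...)
  tt <- seq(0, max(x$data$t), length.out = 200)
  graphics::lines(tt, predict(x, tt), col = "firebrick")
  if (!is.na(x$t_half)) graphics::abline(v = x$t_half, lty = 2, col = "grey40")
  invisible(x)
}

#' Simulate trajectories from a fitted decay model
#'
#' Draws `nsim` replicate trajectories at the fitted timepoints by adding
#' Gaussian noise with the residual standard deviation, truncated to
#' \[0, 1\].
#'
#' @param object `decay_fit` object.
#' @param nsim number of simulated trajectories.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @export
simulate.decay_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  sdr <- if (object$n > 3) sqrt(object$rss / (object$n - 3)) else 0
  out <- replicate(nsim, pmin(pmax(mu + rnorm(length(mu), 0, sdr), 0), 1))
  as.data.frame(out)
}

#' Fit the decay model to every feature of a ratio time course
#'
#' @param ratio_tc result of [ratio_timecourse()], or a features x days
#'   ratio matrix with day-valued column names.
#' @param fit_mode,halftime_variant,... passed to [fit_decay()] /
#'   [halftime()].
#' @param fit_points `"replicates"` fits all per-replicate (t, ratio) points
#'   when `counts`/`design` are supplied; `"means"` (default when a matrix
#'   is given) fits per-timepoint mean ratios.
#' @param counts,design optional `allelic_counts` + design to extract
#'   per-replicate points when `fit_points = "replicates"`.
#' @return An object of class `decay_cohort`: data.frame-backed table of
#'   per-feature parameters plus the list of `decay_fit` objects.
#' @export
fit_decay_cohort <- function(ratio_tc, fit_mode = "free_yf",
                             halftime_variant = "derived",
                             fit_points = c("replicates", "means"),
                             counts = NULL, design = NULL, ...) {
  fit_points <- match.arg(fit_points)
  if (is.list(ratio_tc) && !is.null(ratio_tc$ratio)) {
    mat <- ratio_tc$ratio; days <- ratio_tc$days
  } else {
    mat <- as.matrix(ratio_tc); days <- as.numeric(colnames(mat))
  }
  features <- rownames(mat)
  use_reps <- fit_points == "replicates" && !is.null(counts) && !is.null(design)
  if (fit_points == "replicates" && !use_reps) fit_points <- "means"
  if (use_reps) {
    design <- check_counts_design(counts, design)
    rep_ratio <- matrix(allelic_ratio(counts$xi, counts$xa),
                        nrow = nrow(counts$total),
                        dimnames = dimnames(counts$total))
    rep_days <- design$day
  }

  fits <- vector("list", length(features)); names(fits) <- features
  rows <- vector("list", length(features))
  for (i in seq_along(features)) {
    f <- features[i]
    if (use_reps) {
      t_i <- rep_days; y_i <- rep_ratio[f, ]
    } else {
      t_i <- days; y_i <- mat[i, ]
    }
    fit <- tryCatch(fit_decay(t_i, y_i, fit_mode = fit_mode,
                              feature_id = f, ...),
                    error = function(e) NULL)
    fits[[i]] <- fit
    rows[[i]] <- if (is.null(fit)) {
      data.frame(feature_id = f, y0 = NA_real_, yf = NA_real_, k = NA_real_,
                 rss = NA_real_, converged = FALSE, fittable = FALSE,
                 t_half = NA_real_, stringsAsFactors = FALSE)
    } else {
      data.frame(feature_id = f, y0 = fit$y0, yf = fit$yf, k = fit$k,
                 rss = fit$rss, converged = fit$converged, fittable = TRUE,
                 t_half = halftime(fit, variant = halftime_variant),
                 stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab, fits = fits, fit_mode = fit_mode,
                 halftime_variant = halftime_variant,
                 fit_points = fit_points, days = days),
            class = "decay_cohort")
}

#' @export
print.decay_cohort <- function(x, ...) {
  n <- nrow(x$table)
  n_fit <- sum(x$table$fittable)
  n_t <- sum(!is.na(x$table$t_half))
  cat(sprintf("Decay-fit cohort: %d features (%s, %s halftimes)\n", n,
              x$fit_mode, x$halftime_variant))
  cat(sprintf("  fitted: %d; halftime defined: %d; no halftime: %d\n",
              n_fit, n_t, n - n_t))
  if (n_t > 0) {
    cat(sprintf("  median t1/2 = %.3g days\n",
                median(x$table$t_half, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
coef.decay_cohort <- function(object, ...) {
  m <- as.matrix(object$table[, c("y0", "yf", "k")])
  rownames(m) <- object$table$feature_id
  m
}

#' @export
summary.decay_cohort <- function(object, ...) {
  t <- object$table$t_half
  structure(list(n = nrow(object$table),
                 n_halftime = sum(!is.na(t)),
                 t_half_quartiles = quantile(t, c(0.25, 0.5, 0.75),
                                             na.rm = TRUE, names = FALSE)),
            class = "summary.decay_cohort")
}

#' @export
print.summary.decay_cohort <- function(x, ...) {
  cat(sprintf("%d features, halftimes for %d; t1/2 quartiles %.3g / %.3g / %.3g days\n",
              x$n, x$n_halftime, x$t_half_quartiles[1], x$t_half_quartiles[2],
              x$t_half_quartiles[3]))
  invisible(x)
}

#' @export
plot.decay_cohort <- function(x, breaks = 30,
                              xlab = "accessibility-loss halftime (days)",
                              main = "halftime distribution", ...) {
  graphics::hist(x$table$t_half, breaks = breaks, xlab = xlab, main = main,
                 col = "grey80", ...)
  invisible(x)
}
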