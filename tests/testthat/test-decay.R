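days6 <- c(0, 1, 3, 5, 7, 9)

test_that("noiseless exponential data recover the generating parameters", {
  y <- 0.1 + 0.4 * exp(-0.3 * days6)
  fit <- fit_decay(days6, y)
  expect_equal(unname(coef(fit)), c(0.4, 0.1, 0.3), tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
  expect_true(fit$converged)

  # fixed-yf mode recovers a pure decay
  y2 <- 0.5 * exp(-0.7 * days6)
  fit2 <- fit_decay(days6, y2, fit_mode = "fixed_yf_zero")
  expect_equal(fit2$yf, 0)
  expect_equal(unname(coef(fit2))[c(1, 3)], c(0.5, 0.7), tolerance = 1e-6)
})

test_that("constant trajectories yield a flat k = 0 fit with zero rss", {
  fit <- fit_decay(days6, rep(0.5, 6))
  expect_equal(fit$k, 0)
  expect_equal(fit$rss, 0)
  expect_true(is.na(fit$t_half))
})

test_that("increasing (gainer) trajectories fit but yield no halftime", {
  y <- 0.8 - 0.3 * exp(-0.5 * days6)
  fit <- fit_decay(days6, y)
  expect_lt(fit$y0, 0)
  expect_true(is.na(fit$t_half))
})

test_that("fit refuses fewer than three usable points and missing day 0", {
  expect_error(fit_decay(c(0, 1), c(0.5, 0.4)), "3 distinct")
  expect_error(fit_decay(c(1, 3, 5), c(0.5, 0.4, 0.3)), "day 0")
  expect_error(fit_decay(c(0, NA, 3), c(0.5, 0.4, 0.3)), "3 distinct")
})

test_that("fitting is invariant to the order of the points", {
  set.seed(21)
  y <- 0.12 + 0.38 * exp(-0.4 * days6) + rnorm(6, 0, 0.02)
  y <- pmin(pmax(y, 0), 1)
  f1 <- fit_decay(days6, y)
  perm <- sample(6)
  f2 <- fit_decay(days6[perm], y[perm])
  expect_equal(coef(f1), coef(f2), tolerance = 1e-7)
})

test_that("multi-start least squares matches an independent bounded optimizer", {
  set.seed(33)
  for (i in 1:10) {
    truth <- c(y0 = runif(1, 0.2, 0.5), yf = runif(1, 0, 0.2),
               k = runif(1, 0.1, 1))
    y <- truth["yf"] + truth["y0"] * exp(-truth["k"] * days6) +
      rnorm(6, 0, 0.03)
    y <- pmin(pmax(y, 0), 1)
    fit <- fit_decay(days6, y)
    rss_fn <- function(p) sum((y - (p[2] + p[1] * exp(-p[3] * days6)))^2)
    oracle <- optim(unname(truth), rss_fn, method = "L-BFGS-B",
                    lower = c(-1, 0, 0), upper = c(1, 1, 50))
    expect_lte(fit$rss, oracle$value + 1e-6)
  }
})

test_that("halftime closed forms hold and variants coincide at yf = 0", {
  f <- list(y0 = 0.5, yf = 0, k = log(2))
  expect_equal(halftime(f, variant = "derived"), 1, tolerance = 1e-9)
  expect_equal(halftime(f, variant = "printed"), 1, tolerance = 1e-9)

  g <- list(y0 = 0.4, yf = 0.1, k = 0.3)
  expect_equal(halftime(g, variant = "derived"), -log(0.375) / 0.3,
               tolerance = 1e-12)
  expect_equal(halftime(g, variant = "printed"), -log(0.125) / 0.3,
               tolerance = 1e-12)

  # curve value at the derived halftime equals half the initial value
  set.seed(9)
  for (i in 1:50) {
    y0 <- runif(1, 0.05, 0.9); yf <- runif(1, 0, min(0.9, y0 * 0.9))
    k <- runif(1, 0.05, 2)
    th <- halftime(list(y0 = y0, yf = yf, k = k))
    if (is.na(th)) next
    expect_equal(yf + y0 * exp(-k * th), 0.5 * (y0 + yf), tolerance = 1e-9)
  }

  # floor above half the initial value: not applicable
  expect_true(is.na(halftime(list(y0 = 0.1, yf = 0.45, k = 0.5))))
  expect_true(is.na(halftime(list(y0 = 0.5, yf = 0.1, k = 0))))
})

test_that("decay_fit methods expose the fitted model coherently", {
  y <- 0.1 + 0.4 * exp(-0.3 * days6)
  fit <- fit_decay(days6, y, feature_id = "re_demo")
  expect_equal(predict(fit, c(0, 2)), 0.1 + 0.4 * exp(-0.3 * c(0, 2)),
               tolerance = 1e-6)
  expect_equal(sum(residuals(fit)^2), fit$rss, tolerance = 1e-12)
  expect_output(print(fit), "re_demo")
  s <- summary(fit)
  expect_equal(s$initial, fit$y0 + fit$yf)
  sim <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(6L, 3L))
  expect_true(all(sim >= 0 & sim <= 1))
})

test_that("cohort fitting returns per-feature parameters and halftimes", {
  mat <- rbind(re_a = 0.1 + 0.4 * exp(-0.3 * days6),
               re_b = 0.05 + 0.45 * exp(-0.9 * days6),
               re_c = rep(0.5, 6))
  colnames(mat) <- days6
  cohort <- fit_decay_cohort(mat)
  expect_s3_class(cohort, "decay_cohort")
  expect_equal(cohort$table$feature_id, c("re_a", "re_b", "re_c"))
  expect_equal(cohort$table$k[1:2], c(0.3, 0.9), tolerance = 1e-5)
  expect_true(is.na(cohort$table$t_half[3]))
  expect_equal(unname(coef(cohort)["re_a", "yf"]), 0.1, tolerance = 1e-5)
})
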