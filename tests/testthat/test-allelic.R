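test_that("allelic ratio is Xi over allele-informative total", {
  expect_equal(allelic_ratio(5, 15), 0.25)
  expect_equal(allelic_ratio(0, 10), 0)
  expect_true(is.na(allelic_ratio(0, 0)))
  expect_error(allelic_ratio(-1, 3), "non-negative")
})

test_that("complementary ratios sum to one when defined", {
  set.seed(3)
  xi <- rpois(50, 20); xa <- rpois(50, 20)
  ok <- xi + xa > 0
  expect_equal(allelic_ratio(xi, xa)[ok] + allelic_ratio(xa, xi)[ok],
               rep(1, sum(ok)))
})

test_that("allelic filters apply the strict >80% and strict ratio bounds", {
  # 4/5 samples meet the fragment rule: 0.8 is NOT > 0.8, so dropped
  cx <- make_counts(xi = matrix(c(6, 6, 4, 8, 10), 1),
                    xa = matrix(c(6, 5, 5, 7, 10), 1))
  res <- apply_allelic_filters(cx$counts, cx$design, min_allelic = 10,
                               min_sample_frac = 0.8)
  expect_equal(res$report$frac_samples_ok, 0.8)
  expect_length(res$keep, 0)
  expect_equal(res$report$dropped_by, "min_allelic_fragments")

  # day-0 pooled ratio exactly at the 0.85 bound: strict, dropped
  cx2 <- make_counts(xi = matrix(c(17, 17), 1), xa = matrix(c(3, 3), 1))
  res2 <- apply_allelic_filters(cx2$counts, cx2$design, min_allelic = 10,
                                min_sample_frac = 0.5)
  expect_equal(res2$report$day0_ratio, 0.85)
  expect_length(res2$keep, 0)
  expect_equal(res2$report$dropped_by, "day0_biallelic")

  # clean feature passes both rules
  cx3 <- make_counts(xi = matrix(c(10, 12), 1), xa = matrix(c(10, 12), 1))
  res3 <- apply_allelic_filters(cx3$counts, cx3$design)
  expect_equal(res3$keep, "f1")

  # no day-0 samples is an error
  cx4 <- make_counts(xi = matrix(c(10, 12), 1), xa = matrix(c(10, 12), 1),
                     days = c(1, 3))
  expect_error(apply_allelic_filters(cx4$counts, cx4$design), "day-0")
})

test_that("filters are monotone in their thresholds", {
  set.seed(11)
  nf <- 40
  cx <- make_counts(xi = matrix(rpois(nf * 6, 8), nf),
                    xa = matrix(rpois(nf * 6, 8), nf),
                    days = c(0, 0, 1, 1, 3, 3), reps = c(1, 2, 1, 2, 1, 2))
  strict <- apply_allelic_filters(cx$counts, cx$design, min_allelic = 12,
                                  ar0_low = 0.3, ar0_high = 0.7)
  loose <- apply_allelic_filters(cx$counts, cx$design, min_allelic = 8,
                                 ar0_low = 0.1, ar0_high = 0.9)
  expect_true(all(strict$keep %in% loose$keep))
})

test_that("ratio time course supports pooled and replicate-mean aggregation", {
  cx <- make_counts(xi = matrix(c(10, 20), 1), xa = matrix(c(30, 20), 1),
                    days = c(0, 0), reps = c(1, 2))
  pooled <- ratio_timecourse(cx$counts, cx$design, aggregation = "pooled")
  means <- ratio_timecourse(cx$counts, cx$design)
  expect_equal(pooled$ratio[1, "0"], 0.375)
  expect_equal(means$ratio[1, "0"], 0.375)  # (0.25 + 0.5) / 2

  cx2 <- make_counts(xi = matrix(c(10, 30), 1), xa = matrix(c(30, 10), 1),
                     days = c(0, 0), reps = c(1, 2))
  expect_equal(ratio_timecourse(cx2$counts, cx2$design)$ratio[1, "0"], 0.5)

  # a replicate with zero allelic counts is excluded from the mean
  cx3 <- make_counts(xi = matrix(c(10, 0), 1), xa = matrix(c(30, 0), 1),
                     days = c(0, 0), reps = c(1, 2))
  expect_equal(ratio_timecourse(cx3$counts, cx3$design)$ratio[1, "0"], 0.25)
})

test_that("FRiP is a guarded fraction", {
  expect_equal(frip(50, 200), 0.25)
  expect_equal(frip(0, 200), 0)
  expect_equal(frip(200, 200), 1)
  expect_error(frip(201, 200), "exceed")
})

test_that("library-size normalization equalizes totals to the mean size", {
  cx <- make_counts(xi = matrix(c(5, 10), 1), xa = matrix(c(5, 10), 1),
                    total = matrix(c(10, 20), 1))
  norm <- libsize_normalize(cx$counts)
  expect_equal(as.numeric(norm$total), c(15, 15))
  # equal sizes: identity
  cx2 <- make_counts(xi = matrix(c(5, 5), 1), xa = matrix(c(5, 5), 1))
  expect_equal(libsize_normalize(cx2$counts)$total, cx2$counts$total)
})

test_that("allele-separated fold changes obey the zero-count exclusion", {
  tr <- make_counts(xi = matrix(c(25, 25), 1), xa = matrix(c(50, 50), 1))$counts
  ct <- make_counts(xi = matrix(c(50, 50), 1), xa = matrix(c(50, 50), 1))$counts
  expect_equal(unname(allelic_log2fc(tr, ct, "Xi")), -1)
  expect_equal(unname(allelic_log2fc(tr, ct, "Xa")), 0)

  z <- make_counts(xi = matrix(c(0, 0), 1), xa = matrix(c(50, 50), 1))$counts
  expect_true(is.na(allelic_log2fc(tr, z, "Xi")))
  expect_true(is.na(allelic_log2fc(z, tr, "Xi")))

  # antisymmetry wherever defined
  set.seed(5)
  a <- make_counts(xi = matrix(rpois(20, 30), 10),
                   xa = matrix(rpois(20, 30), 10))$counts
  b <- make_counts(xi = matrix(rpois(20, 30), 10),
                   xa = matrix(rpois(20, 30), 10))$counts
  ab <- allelic_log2fc(a, b, "Xi"); ba <- allelic_log2fc(b, a, "Xi")
  ok <- !is.na(ab) & !is.na(ba)
  expect_equal(ab[ok], -ba[ok])
})

test_that("group summaries report medians over non-missing fold changes", {
  fc <- c(a = -1, b = 0, c = 1, d = NA)
  s <- summarize_fc_by_group(fc, list(g1 = c("a", "b", "c"),
                                      g2 = c("d"), g3 = character()))
  expect_equal(s$median[s$group == "g1"], 0)
  expect_equal(s$n[s$group == "g2"], 0)
  expect_true(is.na(s$median[s$group == "g3"]))
})
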