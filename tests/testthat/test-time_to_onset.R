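test_that("induction time is event date minus earliest therapy start", {
  asm <- make_assembled(primaryid = c("1", "2", "3"),
                        drugname = "HUMIRA",
                        pt = "Deep vein thrombosis",
                        start_dt = c("2010-01-01", "2010-06-01", "2012-01-01"),
                        event_dt = c("2010-01-11", "2010-05-01", "2012-01-01"))
  tto <- compute_tto(asm, "adalimumab", "Deep vein thrombosis")
  expect_equal(tto$tto_days[tto$primaryid == "1"], 10)
  # event before start and zero-day intervals are excluded with a reason
  expect_false(any(c("2", "3") %in% tto$primaryid))
  expect_equal(unname(attr(tto, "exclusions")["nonpositive"]), 2L)
})

test_that("implausibly long onsets fall to the cap", {
  asm <- make_assembled(primaryid = "1", drugname = "HUMIRA",
                        pt = "Thrombosis",
                        start_dt = "1990-01-01", event_dt = "2020-01-01")
  tto <- compute_tto(asm, "adalimumab", "Thrombosis", cap_days = 7300)
  expect_equal(nrow(tto), 0)
  expect_equal(unname(attr(tto, "exclusions")["over_cap"]), 1L)
})

test_that("quartile convention is type-7 linear interpolation", {
  s <- summarize_tto(c(1, 2, 3, 4))
  expect_equal(s$median, 2.5)
  expect_equal(s$q1, 1.75)
  expect_equal(s$q3, 3.25)
  s1 <- summarize_tto(42)
  expect_equal(c(s1$q1, s1$median, s1$q3), c(42, 42, 42))
  set.seed(15)
  for (i in 1:200) {
    x <- rweibull(sample(3:50, 1), 0.8, 300)
    s <- summarize_tto(x)
    expect_equal(c(s$q1, s$median, s$q3),
                 oracle_q7(x, c(0.25, 0.5, 0.75)), tolerance = 1e-12)
    expect_true(s$q1 <= s$median && s$median <= s$q3)
  }
})

test_that("recovered onsets reproduce the planted Weibull median", {
  pp <- data.frame(drug = "adalimumab", pt = "Deep vein thrombosis",
                   rho = 20, shape = 0.7, scale = 400)
  sc <- faers_scenario(n_reports = 20000, planted_pairs = pp,
                       duplicate_rate = 0)
  g <- generate_faers(sc, seed = 61)
  q <- structure(c(g$tables, list(quarter_label = "2020Q1",
                                  load_report = NULL)),
                 class = "faers_quarter")
  asm <- assemble_cases(q)
  asm$drugs$canonical <- normalize_drug(asm$drugs$drugname)
  tto <- compute_tto(asm, "adalimumab", "Deep vein thrombosis")
  med_true <- 400 * log(2)^(1 / 0.7)
  # bootstrap SE of the sample median
  set.seed(62)
  boot <- replicate(200, median(sample(tto$tto_days, replace = TRUE)))
  expect_lt(abs(median(tto$tto_days) - med_true), 4 * sd(boot) + 1)
})

test_that("identical groups give H = 0 and pairwise p = 1", {
  x <- rep(c(10, 20, 30, 40, 50), 2)
  rec <- data.frame(drug = rep(c("a", "b"), each = 5), tto_days = x)
  cmp <- group_comparisons(rec, nsim = 50)
  expect_equal(cmp$kw_H, 0)
  expect_equal(unname(cmp$pairwise["b", "a"]), 1)
})

test_that("Kruskal-Wallis H equals the brute-force rank formula", {
  set.seed(71)
  for (i in 1:30) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j) {
      round(rweibull(sample(5:20, 1), 0.8, 100))   # rounded -> ties
    })
    rec <- data.frame(drug = rep(letters[seq_len(k)], lengths(groups)),
                      tto_days = unlist(groups))
    cmp <- group_comparisons(rec, nsim = 10)
    expect_equal(cmp$kw_H, oracle_kw_h(groups), tolerance = 1e-10)
  }
})

test_that("KS normality test holds its size and sees skew", {
  # size: normal data at alpha = .05 rejects at roughly the nominal rate
  set.seed(81)
  seeds <- sample.int(1e6, 150)
  rej <- vapply(seeds, function(s) {
    set.seed(s)
    x <- rnorm(200, 500, 10)
    ks_normality(x, nsim = 300, seed = s + 1)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.005)
  expect_lte(mean(rej), 0.12)
  # power: a heavy right-skewed sample is rejected outright
  set.seed(82)
  y <- rlnorm(500, 5, 1)
  expect_lt(ks_normality(y, nsim = 2000)$p_value, 0.001)
  # statistic agrees with the Lilliefors statistic from nortest
  skip_if_not_installed("nortest")
  set.seed(83)
  z <- rweibull(300, 0.8, 200)
  expect_equal(ks_normality(z, nsim = 10)$statistic,
               unname(nortest::lillie.test(z)$statistic), tolerance = 1e-10)
})

test_that("zero-variance groups are flagged with a floor p-value", {
  r <- ks_normality(rep(5, 10), nsim = 10)
  expect_true(r$degenerate)
  expect_lte(r$p_value, .Machine$double.xmin)
})

test_that("Weibull MLE recovers the exponential special case", {
  set.seed(91)
  x <- rweibull(10000, shape = 1, scale = 100)
  f <- fit_weibull(x)
  expect_gt(f$shape, 0.97); expect_lt(f$shape, 1.03)
  expect_equal(f$scale, 100, tolerance = 0.05)
  expect_equal(classify_failure(f), "random")
})

test_that("Weibull MLE matches an independent fitter", {
  skip_if_not_installed("MASS")
  set.seed(92)
  for (i in 1:10) {
    x <- rweibull(500, runif(1, 0.5, 2.5), runif(1, 50, 800))
    f <- fit_weibull(x)
    m <- MASS::fitdistr(x, stats::dweibull,
                        start = list(shape = 1, scale = stats::median(x)),
                        lower = c(1e-3, 1e-3))
    expect_equal(f$shape, unname(m$estimate["shape"]), tolerance = 1e-4)
    expect_equal(f$scale, unname(m$estimate["scale"]), tolerance = 1e-4)
    # observed-information SEs agree on the original scale near the MLE
    expect_equal(f$shape_ci[2] - f$shape_ci[1],
                 2 * 1.96 * unname(m$sd["shape"]), tolerance = 0.05)
  }
})

test_that("Weibull CI coverage and bias behave over repeated samples", {
  set.seed(93)
  hits <- 0; bias <- numeric(100)
  for (i in 1:100) {
    x <- rweibull(1000, 0.7, 400)
    f <- fit_weibull(x)
    bias[i] <- f$shape - 0.7
    hits <- hits + (f$shape_ci[1] <= 0.7 && 0.7 <= f$shape_ci[2])
  }
  expect_lt(abs(mean(bias)), 0.01)
  expect_gte(hits, 90); expect_lte(hits, 99)
})

test_that("degenerate all-equal samples raise the error flag", {
  f <- fit_weibull(rep(100, 20))
  expect_true(f$degenerate)
  expect_false(f$converged)
  expect_true(is.na(f$shape))
})

test_that("failure-type classification follows the CI against 1", {
  expect_equal(classify_failure(c(0.65, 0.72)), "early")
  expect_equal(classify_failure(c(0.9, 1.1)), "random")
  expect_equal(classify_failure(c(1.1, 1.5)), "wear-out")
  # monotone: shifting the CI upward never moves wear-out toward early
  ranks <- c(early = 1, random = 2, `wear-out` = 3)
  set.seed(94)
  for (i in 1:50) {
    lo <- runif(1, 0.3, 1.4); hi <- lo + runif(1, 0.01, 0.6)
    shift <- runif(1, 0, 0.5)
    expect_gte(ranks[classify_failure(c(lo + shift, hi + shift))],
               ranks[classify_failure(c(lo, hi))])
  }
})
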