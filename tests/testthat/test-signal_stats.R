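test_that("ROR matches direct arithmetic and log-scale symmetry", {
  r <- ror(contingency_table(10, 90, 100, 9900))
  expect_equal(r$ror, 11)
  r1 <- ror(contingency_table(5, 5, 5, 5))
  expect_equal(r1$ror, 1)
  expect_equal(log(r1$hi), -log(r1$lo))          # CI symmetric about 1
  # all-zero table flagged undefined, not an exception
  expect_true(ror(contingency_table(0, 0, 0, 0))$undefined)
})

test_that("PRR and Yates chi-squared match stated arithmetic", {
  p <- prr_chi2(contingency_table(10, 90, 100, 9900))
  expect_equal(p$prr, 10)
  # independence table: Yates correction floors the statistic at 0
  expect_equal(prr_chi2(contingency_table(5, 5, 5, 5))$chi2, 0)
})

test_that("ROR/PRR/chi2 agree with independent oracles on random tables", {
  set.seed(404)
  for (i in 1:1000) {
    cells <- rpois(4, lambda = sample(c(2, 8, 40, 400), 4,
                                      replace = TRUE)) + 1
    a <- cells[1]; b <- cells[2]; c_ <- cells[3]; d <- cells[4]
    tab <- contingency_table(a, b, c_, d)
    want <- oracle_or_ci(a, b, c_, d)
    got <- ror(tab)
    expect_equal(got$ror, unname(want["or"]), tolerance = 1e-12)
    # own CI uses 1.96 rather than qnorm(0.975); equivalent to 4 digits
    expect_equal(got$lo, unname(want["lo"]), tolerance = 1e-4)
    expect_equal(got$hi, unname(want["hi"]), tolerance = 1e-4)
    want_chi <- suppressWarnings(
      stats::chisq.test(matrix(c(a, c_, b, d), 2), correct = TRUE)$statistic)
    expect_equal(prr_chi2(tab)$chi2, unname(want_chi), tolerance = 1e-9)
  }
})

test_that("information component matches its closed form", {
  b <- bcpnn_ic(contingency_table(10, 90, 100, 9900))
  e <- 100 * 110 / 10100
  expect_equal(b$expected, e)
  expect_equal(b$ic, log2(10.5 / (e + 0.5)))
  expect_equal(b$ic, 2.7240, tolerance = 1e-4)
  # observed equals expected at large counts: IC ~ 0
  big <- contingency_table(1000, 9000, 10000, 90000)
  expect_equal(bcpnn_ic(big)$ic, 0, tolerance = 0.01)
})

test_that("IC025 sits below IC for finite tables", {
  set.seed(7)
  for (i in 1:200) {
    cells <- rpois(4, 20) + 1
    b <- bcpnn_ic(contingency_table(cells[1], cells[2], cells[3], cells[4]))
    expect_lt(b$ic025, b$ic)
  }
})

test_that("MGPS prior fit recovers a planted two-component mixture", {
  set.seed(99)
  n_pairs <- 5000
  w_true <- 0.4
  lam <- ifelse(runif(n_pairs) < w_true,
                rgamma(n_pairs, 1, rate = 1),      # null-ish component
                rgamma(n_pairs, 3, rate = 0.6))    # signal component, mean 5
  e <- runif(n_pairs, 0.5, 20)
  n_obs <- rpois(n_pairs, lam * e)
  fit <- fit_mgps_prior(n_obs, e)
  expect_true(fit$converged)
  # raw gamma-mixture coordinates are weakly identified, so recovery is
  # judged on the induced prior law: its mean and upper-tail mass, which
  # drive the shrinkage, must match the planted mixture
  means <- c(fit$alpha1 / fit$beta1, fit$alpha2 / fit$beta2)
  mix_mean <- fit$w * means[1] + (1 - fit$w) * means[2]
  expect_equal(mix_mean, w_true * 1 + (1 - w_true) * 5, tolerance = 0.05)
  tail_mass <- function(w, a1, b1, a2, b2, x) {
    w * pgamma(x, a1, rate = b1, lower.tail = FALSE) +
      (1 - w) * pgamma(x, a2, rate = b2, lower.tail = FALSE)
  }
  for (x in c(1, 2, 4)) {
    expect_equal(tail_mass(fit$w, fit$alpha1, fit$beta1, fit$alpha2,
                           fit$beta2, x),
                 tail_mass(w_true, 1, 1, 3, 0.6, x), tolerance = 0.03)
  }
  # the two components still separate into a low and a high mean
  expect_lt(min(means), 1.5)
  expect_gt(max(means), 3.5)
})

test_that("single-component data drives the mixture weight to one side", {
  set.seed(17)
  n_pairs <- 3000
  lam <- rgamma(n_pairs, 2, rate = 2)
  e <- runif(n_pairs, 0.5, 20)
  fit <- fit_mgps_prior(rpois(n_pairs, lam * e), e)
  means <- c(fit$alpha1 / fit$beta1, fit$alpha2 / fit$beta2)
  close_components <- abs(diff(means)) < 0.25 * mean(means)
  expect_true(max(fit$w, 1 - fit$w) >= 0.95 || close_components)
})

test_that("optimizer never returns a worse point than its start", {
  set.seed(5)
  e <- runif(500, 0.5, 10)
  n_obs <- rpois(500, e)
  start <- c(0.2, 0.1, 2.0, 4.0, 1 / 3)
  fit <- fit_mgps_prior(n_obs, e, start = start)
  expect_gte(fit$loglik, faersignal:::.mgps_loglik(start, n_obs, e))
})

test_that("EBGM shrinks toward 1 and respects its quantile ordering", {
  set.seed(23)
  e <- runif(2000, 0.5, 10)
  n_obs <- rpois(2000, e)            # null universe
  prior <- fit_mgps_prior(n_obs, e)
  for (i in 1:50) {
    a <- rpois(1, 5) + 1
    tab <- contingency_table(a, 50, 40, 2000)
    eb <- ebgm(tab, prior)
    expect_lte(eb$ebgm05, eb$ebgm)
    e_i <- (tab$a + tab$b) * (tab$a + tab$c) / tab$n
    if (a / e_i > 1) {               # shrinkage toward the null
      expect_lte(abs(log(eb$ebgm)), abs(log(a / e_i)) + 1e-8)
    }
  }
  # prior concentrated at 1: EBGM pinned to 1 regardless of the table
  sharp <- structure(list(alpha1 = 5e4, beta1 = 5e4, alpha2 = 5e4,
                          beta2 = 5e4, w = 0.5), class = "mgps_prior")
  eb1 <- ebgm(contingency_table(50, 10, 5, 1000), sharp)
  expect_equal(eb1$ebgm, 1, tolerance = 0.01)
  expect_equal(eb1$ebgm05, 1, tolerance = 0.02)
})

test_that("positivity flags implement the four thresholds", {
  # table-driven: a, ror_lo, prr, chi2, ic025, ebgm05 -> expected flags
  f <- positivity_flags(a = 144, ror_lo = 8.57, prr = 10.39, chi2 = 885.18,
                        ic025 = 1.29, ebgm05 = 6.64)
  expect_true(f$ror_pos && f$prr_pos && f$ic_pos && f$ebgm_pos)
  expect_true(f$any_positive)
  # minimum-count rule beats a huge ROR
  f2 <- positivity_flags(a = 2, ror_lo = 50, prr = 100, chi2 = 30,
                         ic025 = -1, ebgm05 = 1)
  expect_false(f2$ror_pos); expect_false(f2$prr_pos)
  # strict inequality at the IC boundary
  expect_false(positivity_flags(3, 0.5, 1, 1, ic025 = 0, 1)$ic_pos)
  # EBGM05 threshold is >= 2
  expect_true(positivity_flags(3, 0.5, 1, 1, -1, ebgm05 = 2)$ebgm_pos)
})

test_that("statistics increase monotonically in a with margins fixed", {
  base <- c(b = 200, c = 100, d = 10000)
  prev <- NULL
  set.seed(3)
  e <- runif(500, 0.5, 10)
  prior <- fit_mgps_prior(rpois(500, e), e)
  for (a in c(5, 10, 20, 40)) {
    tab <- contingency_table(a, base["b"], base["c"], base["d"])
    cur <- c(ror(tab)$ror, prr_chi2(tab)$prr, bcpnn_ic(tab)$ic,
             ebgm(tab, prior)$ebgm)
    if (!is.null(prev)) expect_true(all(cur > prev))
    prev <- cur
  }
})

test_that("ROR converges to PRR when the target margin is tiny", {
  tab <- contingency_table(20, 30000, 40, 5e6)
  expect_equal(ror(tab)$ror / prr_chi2(tab)$prr, 1, tolerance = 0.01)
})

test_that("BH adjustment equals brute-force step-up, handles ties and m=1", {
  expect_equal(volcano_payload(data.frame(pt = "x", ror = 2,
                                          p_value = 0.031))$p_adj, 0.031)
  tied <- volcano_payload(data.frame(pt = letters[1:4], ror = 2,
                                     p_value = rep(0.02, 4)))
  expect_equal(tied$p_adj, rep(0.02, 4))
  set.seed(12)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    got <- volcano_payload(data.frame(pt = seq_along(p), ror = 1,
                                      p_value = p))
    want <- oracle_bh(p)
    expect_equal(got$p_adj[order(got$pt)], want, tolerance = 1e-12)
  }
})
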