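# The four disproportionality statistics and their positivity criteria.
#
# ROR   (a d)/(b c), Wald 95% CI on the log scale.
# PRR   [a/(a+b)] / [c/(c+d)], reported with the Pearson chi-squared
#       statistic (Yates-corrected by default).
# IC    BCPNN information component, log2 of the observed/expected
#       reporting ratio with a Gamma(a + 1/2, E + 1/2) posterior for the
#       rate ratio; IC025 is the 2.5% posterior quantile on the log2 scale.
# EBGM  multi-item gamma-Poisson shrinker: counts are Poisson(lambda E)
#       with a two-component gamma mixture prior on lambda fitted by
#       marginal maximum likelihood over the whole pair universe; EBGM is
#       the posterior geometric mean of lambda, EBGM05 its 5% quantile.
#
# Cells of zero get the Haldane-Anscombe 0.5 added to all four cells (only
# then), so rare pairs keep finite odds ratios and intervals.

.cc_cells <- function(tab, cc = 0.5) {
  cells <- c(tab$a, tab$b, tab$c, tab$d)
  if (min(cells) == 0 && cc > 0) cells <- cells + cc
  stats::setNames(as.list(cells), c("a", "b", "c", "d"))
}

#' Reporting odds ratio with 95% confidence interval
#'
#' @param tab A [contingency_table()].
#' @param cc Continuity constant added to every cell when any cell is zero.
#' @return List `ror`, `lo`, `hi`, `undefined` (all-zero table flag).
#' @export
ror <- function(tab, cc = 0.5) {
  if (tab$n == 0 || (tab$a + tab$b) == 0 && (tab$c + tab$d) == 0) {
    return(list(ror = NA_real_, lo = NA_real_, hi = NA_real_,
                undefined = TRUE))
  }
  z <- .cc_cells(tab, cc)
  if (min(unlist(z)) == 0) {
    return(list(ror = NA_real_, lo = NA_real_, hi = NA_real_,
                undefined = TRUE))
  }
  est <- (z$a * z$d) / (z$b * z$c)
  se <- sqrt(1 / z$a + 1 / z$b + 1 / z$c + 1 / z$d)
  list(ror = est, lo = exp(log(est) - 1.96 * se),
       hi = exp(log(est) + 1.96 * se), undefined = FALSE)
}

#' Proportional reporting ratio and Pearson chi-squared
#'
#' @param tab A [contingency_table()].
#' @param yates Apply the Yates continuity correction (default `TRUE`);
#'   the corrected statistic is floored at zero.
#' @param cc Continuity constant for the PRR when a margin cell is zero.
#' @return List `prr`, `chi2`, `undefined`.
#' @export
prr_chi2 <- function(tab, yates = TRUE, cc = 0.5) {
  z <- .cc_cells(tab, cc)
  undefined <- FALSE
  prr <- if ((z$a + z$b) > 0 && (z$c + z$d) > 0 && z$c > 0) {
    (z$a / (z$a + z$b)) / (z$c / (z$c + z$d))
  } else {
    undefined <- TRUE
    NA_real_
  }
  # chi-squared on the raw counts (the correction handles small cells)
  a <- tab$a; b <- tab$b; c_ <- tab$c; d <- tab$d; n <- tab$n
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  chi2 <- if (n > 0 && r1 > 0 && r2 > 0 && c1 > 0 && c2 > 0) {
    num <- abs(a * d - b * c_)
    if (yates) num <- max(num - n / 2, 0)
    n * num^2 / (r1 * r2 * c1 * c2)
  } else {
    NA_real_
  }
  list(prr = prr, chi2 = chi2, undefined = undefined)
}

#' BCPNN information component
#'
#' `IC = log2((a + 1/2) / (E + 1/2))` with `E = (a+b)(a+c)/n`; `IC025` is
#' the log2 of the 2.5% quantile of the Gamma(a + 1/2, rate = E + 1/2)
#' posterior of the rate ratio.
#'
#' @param tab A [contingency_table()].
#' @return List `ic`, `ic025`, `expected`.
#' @export
bcpnn_ic <- function(tab) {
  stopifnot(tab$n > 0)
  e <- (tab$a + tab$b) * (tab$a + tab$c) / tab$n
  ic <- log2((tab$a + 0.5) / (e + 0.5))
  lam025 <- stats::qgamma(0.025, shape = tab$a + 0.5, rate = e + 0.5)
  list(ic = ic, ic025 = log2(lam025), expected = e)
}

#' Fit the MGPS two-component gamma-Poisson prior
#'
#' Maximizes the marginal likelihood of the observed pair counts `N_i`
#' (negative-binomial mixture) over the prior hyperparameters
#' `(alpha1, beta1, alpha2, beta2, w)` by bounded quasi-Newton (L-BFGS-B)
#' from the conventional start `(0.2, 0.1, 2.0, 4.0, 1/3)`; on
#' non-convergence, five seeded random restarts are tried and the best
#' point returned with a warning flag.
#'
#' @param n_obs Observed counts per drug-event pair (the `a` cells).
#' @param e_expected Expected counts under row/column independence.
#' @param start Start vector `c(alpha1, beta1, alpha2, beta2, w)`.
#' @param seed Seed for the restart jitter.
#' @return List with the five hyperparameters, `loglik`, `converged`,
#'   `restarted`; class `mgps_prior`.
#' @export
fit_mgps_prior <- function(n_obs, e_expected,
                           start = c(0.2, 0.1, 2.0, 4.0, 1 / 3),
                           seed = 1L) {
  stopifnot(length(n_obs) == length(e_expected), all(e_expected > 0))
  if (length(n_obs) < 50) {
    warning("fewer than 50 pairs: MGPS hyperparameters may be unstable")
  }
  negll <- function(p) {
    ll <- .mgps_loglik(p, n_obs, e_expected)
    if (!is.finite(ll)) 1e10 else -ll
  }
  lower <- c(rep(1e-6, 4), 1e-4)
  upper <- c(rep(50, 4), 1 - 1e-4)
  run <- function(p0) {
    tryCatch(stats::optim(p0, negll, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(maxit = 500)),
             error = function(e) list(par = p0, value = negll(p0),
                                      convergence = 99L))
  }
  fit <- run(start)
  restarted <- FALSE
  if (fit$convergence != 0) {
    restarted <- TRUE
    old <- .seed_swap(seed)
    on.exit(.seed_restore(old), add = TRUE)
    cand <- list(fit)
    for (k in 1:5) {
      p0 <- pmin(pmax(start * stats::rlnorm(5, 0, 0.5), lower), upper)
      p0[5] <- stats::runif(1, 0.05, 0.95)
      cand[[k + 1]] <- run(p0)
    }
    fit <- cand[[which.min(vapply(cand, `[[`, numeric(1), "value"))]]
  }
  p <- fit$par
  structure(list(alpha1 = p[1], beta1 = p[2], alpha2 = p[3], beta2 = p[4],
                 w = p[5], loglik = -fit$value,
                 converged = fit$convergence == 0, restarted = restarted),
            class = "mgps_prior")
}

# marginal log-likelihood of counts under the NB mixture
.mgps_loglik <- function(p, n_obs, e) {
  f1 <- stats::dnbinom(n_obs, size = p[1], prob = p[2] / (p[2] + e),
                       log = TRUE)
  f2 <- stats::dnbinom(n_obs, size = p[3], prob = p[4] / (p[4] + e),
                       log = TRUE)
  m <- pmax(f1, f2)
  sum(m + log(p[5] * exp(f1 - m) + (1 - p[5]) * exp(f2 - m)))
}

.seed_swap <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  old
}
.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' EBGM and EBGM05 under a fitted MGPS prior
#'
#' The posterior of the reporting-rate ratio is the two-component gamma
#' mixture with updated shapes `alpha_j + N`, rates `beta_j + E` and
#' posterior component weight `Q_N`; EBGM is the posterior geometric mean
#' `2^E[log2 lambda]`, EBGM05 the 5% posterior quantile found by bisection
#' on the mixture CDF to 1e-10.
#'
#' @param tab A [contingency_table()] (or list with `a` and `expected`).
#' @param prior A fitted [fit_mgps_prior()].
#' @param e_expected Expected count; computed from the table when omitted.
#' @return List `ebgm`, `ebgm05`, `qn`.
#' @export
ebgm <- function(tab, prior, e_expected = NULL) {
  n_obs <- tab$a
  e <- if (!is.null(e_expected)) e_expected else
    (tab$a + tab$b) * (tab$a + tab$c) / tab$n
  stopifnot(e > 0)
  lf1 <- stats::dnbinom(n_obs, size = prior$alpha1,
                        prob = prior$beta1 / (prior$beta1 + e), log = TRUE)
  lf2 <- stats::dnbinom(n_obs, size = prior$alpha2,
                        prob = prior$beta2 / (prior$beta2 + e), log = TRUE)
  lw1 <- log(prior$w) + lf1
  lw2 <- log(1 - prior$w) + lf2
  qn <- 1 / (1 + exp(lw2 - lw1))
  s1 <- prior$alpha1 + n_obs; r1 <- prior$beta1 + e
  s2 <- prior$alpha2 + n_obs; r2 <- prior$beta2 + e
  elog <- qn * (digamma(s1) - log(r1)) + (1 - qn) * (digamma(s2) - log(r2))
  ebgm_val <- 2^(elog / log(2))
  cdf <- function(x) {
    qn * stats::pgamma(x, shape = s1, rate = r1) +
      (1 - qn) * stats::pgamma(x, shape = s2, rate = r2)
  }
  lo <- min(stats::qgamma(0.025, s1, rate = r1),
            stats::qgamma(0.025, s2, rate = r2))
  hi <- max(stats::qgamma(0.075, s1, rate = r1),
            stats::qgamma(0.075, s2, rate = r2))
  while (cdf(lo) > 0.05) lo <- lo / 2
  while (cdf(hi) < 0.05) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (cdf(mid) < 0.05) lo <- mid else hi <- mid
    if (hi - lo < 1e-10) break
  }
  list(ebgm = ebgm_val, ebgm05 = (lo + hi) / 2, qn = qn)
}

#' Positivity flags for the four methods
#'
#' ROR: `a >= 3` and CI lower bound > 1. PRR: `a >= 3`, `PRR >= 2`,
#' `chi2 >= 4`. IC: `IC025 > 0` (strict). EBGM: `EBGM05 >= 2`.
#' `any_positive` is the disjunction; a report meeting any one criterion
#' is treated as a signal.
#'
#' @param a Observed count.
#' @param ror_lo ROR CI lower bound.
#' @param prr,chi2 PRR and chi-squared.
#' @param ic025 IC 2.5% posterior bound.
#' @param ebgm05 EBGM 5% posterior quantile.
#' @return Logical list `ror_pos`, `prr_pos`, `ic_pos`, `ebgm_pos`,
#'   `any_positive`.
#' @export
positivity_flags <- function(a, ror_lo, prr, chi2, ic025, ebgm05) {
  ror_pos <- isTRUE(a >= 3 && is.finite(ror_lo) && ror_lo > 1)
  prr_pos <- isTRUE(a >= 3 && is.finite(prr) && prr >= 2 &&
                      is.finite(chi2) && chi2 >= 4)
  ic_pos <- isTRUE(is.finite(ic025) && ic025 > 0)
  ebgm_pos <- isTRUE(is.finite(ebgm05) && ebgm05 >= 2)
  list(ror_pos = ror_pos, prr_pos = prr_pos, ic_pos = ic_pos,
       ebgm_pos = ebgm_pos,
       any_positive = ror_pos || prr_pos || ic_pos || ebgm_pos)
}

#' All four statistics for one table
#'
#' Convenience wrapper: ROR/CI, PRR/chi2, IC/IC025, EBGM/EBGM05 (when a
#' prior is supplied), Fisher exact p, and positivity flags.
#'
#' @param tab A [contingency_table()].
#' @param prior Optional [fit_mgps_prior()]; EBGM columns are `NA` without.
#' @param yates,cc Passed to [prr_chi2()] / [ror()].
#' @return One-row data.frame (class keeps plain).
#' @export
signal_stats <- function(tab, prior = NULL, yates = TRUE, cc = 0.5) {
  r <- ror(tab, cc)
  p <- prr_chi2(tab, yates, cc)
  b <- bcpnn_ic(tab)
  eb <- if (!is.null(prior)) ebgm(tab, prior) else
    list(ebgm = NA_real_, ebgm05 = NA_real_)
  pv <- fisher_p(tab)
  fl <- positivity_flags(tab$a, r$lo, p$prr, p$chi2, b$ic025, eb$ebgm05)
  data.frame(a = tab$a, b = tab$b, c = tab$c, d = tab$d,
             expected = b$expected,
             ror = r$ror, ror_lo = r$lo, ror_hi = r$hi,
             prr = p$prr, chi2 = p$chi2,
             ic = b$ic, ic025 = b$ic025,
             ebgm = eb$ebgm, ebgm05 = eb$ebgm05,
             p_value = pv,
             ror_pos = fl$ror_pos, prr_pos = fl$prr_pos,
             ic_pos = fl$ic_pos, ebgm_pos = fl$ebgm_pos,
             any_positive = fl$any_positive)
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' @param tab A [contingency_table()].
#' @return p-value in [0, 1].
#' @export
fisher_p <- function(tab) {
  m <- matrix(c(tab$a, tab$c, tab$b, tab$d), 2, 2)
  if (sum(m) == 0) return(NA_real_)
  stats::fisher.test(round(m))$p.value
}

#' Volcano payload with FDR adjustment
#'
#' Benjamini-Hochberg adjustment of the per-PT Fisher p-values within one
#' drug's PT family; rows sorted by adjusted p.
#'
#' @param results Data.frame with columns `pt`, `ror`, `p_value`.
#' @param alpha Significance level used for the `significant` flag.
#' @return Data.frame `pt`, `log2_ror`, `p_value`, `p_adj`, `significant`.
#' @export
volcano_payload <- function(results, alpha = 0.05) {
  stopifnot(all(c("pt", "ror", "p_value") %in% names(results)))
  out <- data.frame(pt = results$pt,
                    log2_ror = log2(results$ror),
                    p_value = results$p_value,
                    p_adj = stats::p.adjust(results$p_value, method = "BH"))
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out[order(out$p_adj), , drop = FALSE]
}
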