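# Time-to-onset (induction time) analysis.
#
# The induction time of a report is the number of days from the earliest
# therapy start of its primary-suspect target drug to the event date.
# Onset distributions are summarized by type-7 quantiles, compared across
# drugs by Kruskal-Wallis / pairwise Wilcoxon after a Lilliefors-style
# normality check, and modelled by a two-parameter Weibull whose shape
# parameter classifies the hazard as early-failure (shape CI below 1),
# random (CI spans 1) or wear-out (CI above 1).

#' Compute induction times for one drug and event set
#'
#' Joins therapy starts to PS drug assignments on (primaryid, drug
#' sequence), takes the earliest start per report, and subtracts it from
#' the event date. Records with a missing date, a non-positive interval,
#' or an interval above `cap_days` are excluded and the exclusions counted
#' by reason.
#'
#' @param assembled A `faers_cases` list.
#' @param target_drug Canonical drug name.
#' @param event_set An `event_set` or character vector of PTs.
#' @param dict Drug dictionary.
#' @param cap_days Upper plausibility cap in days (default 7300 = 20 y).
#' @return Data.frame `primaryid`, `drug`, `tto_days`, with attribute
#'   `exclusions` (named counts).
#' @export
compute_tto <- function(assembled, target_drug, event_set,
                        dict = drug_dictionary(), cap_days = 7300) {
  ps <- assembled$drugs[assembled$drugs$role_cod == "PS", , drop = FALSE]
  canon <- if ("canonical" %in% names(ps)) ps$canonical else
    normalize_drug(ps$drugname, dict)
  ps <- ps[!is.na(canon) & canon %in% target_drug, , drop = FALSE]
  ev_ids <- unique(assembled$reactions$primaryid[
    .in_event_set(assembled$reactions$pt, event_set)])
  ps <- ps[ps$primaryid %in% ev_ids, , drop = FALSE]
  excl <- c(no_therapy_row = 0L, missing_start = 0L, missing_event = 0L,
            nonpositive = 0L, over_cap = 0L)
  empty <- data.frame(primaryid = character(), drug = character(),
                      tto_days = numeric(), stringsAsFactors = FALSE)
  if (!nrow(ps)) {
    attr(empty, "exclusions") <- excl
    return(empty)
  }
  ther <- assembled$therapy
  if (is.null(ther)) ther <- data.frame(primaryid = character(),
                                        dsg_drug_seq = integer(),
                                        start_dt = as.Date(character()))
  j <- merge(ps[c("primaryid", "drug_seq")],
             ther[c("primaryid", "dsg_drug_seq", "start_dt")],
             by.x = c("primaryid", "drug_seq"),
             by.y = c("primaryid", "dsg_drug_seq"), all.x = TRUE)
  # earliest therapy start per report for the target drug
  has_start <- !is.na(j$start_dt)
  excl["no_therapy_row"] <- length(unique(j$primaryid)) -
    length(unique(j$primaryid[has_start]))
  agg <- stats::aggregate(start_dt ~ primaryid, data = j[has_start, ],
                          FUN = min)
  ev <- assembled$cases[match(agg$primaryid, assembled$cases$primaryid),
                        "event_date"]
  miss_ev <- is.na(ev)
  excl["missing_event"] <- sum(miss_ev)
  tto <- as.numeric(ev - agg$start_dt)
  ok <- !miss_ev
  nonpos <- ok & tto <= 0
  excl["nonpositive"] <- sum(nonpos, na.rm = TRUE)
  over <- ok & !nonpos & tto > cap_days
  excl["over_cap"] <- sum(over, na.rm = TRUE)
  keep <- ok & !nonpos & !over
  label <- if (length(target_drug) == 1) target_drug else "class"
  out <- data.frame(primaryid = agg$primaryid[keep],
                    drug = rep(label, sum(keep, na.rm = TRUE)),
                    tto_days = tto[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}

#' Median and quartiles of induction times
#'
#' Type-7 (linear interpolation between closest ranks) quantiles, the
#' convention that yields fractional quartiles such as 129.75 on even
#' sample sizes.
#'
#' @param tto_days Numeric vector of onset times (n >= 1).
#' @return List `n`, `median`, `q1`, `q3`.
#' @export
summarize_tto <- function(tto_days) {
  tto_days <- tto_days[!is.na(tto_days)]
  if (!length(tto_days)) stop("no onset times to summarize")
  q <- stats::quantile(tto_days, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(n = length(tto_days), median = q[2], q1 = q[1], q3 = q[3])
}

#' Lilliefors-style normality test with Monte-Carlo p-value
#'
#' Kolmogorov-Smirnov distance of the sample against a normal with the
#' sample's own mean and SD; because the parameters are estimated, the
#' null distribution of the statistic is simulated (standard-normal
#' samples of the same size, re-estimated each time) rather than taken
#' from the classical KS tables.
#'
#' @param x Numeric sample (n >= 4).
#' @param nsim Monte-Carlo replicates.
#' @param seed RNG seed for the null simulation.
#' @return List `statistic`, `p_value`, `degenerate` (zero-variance flag).
#' @export
ks_normality <- function(x, nsim = 2000, seed = 20240101) {
  x <- x[!is.na(x)]
  n <- length(x)
  stopifnot(n >= 4)
  if (stats::sd(x) == 0) {
    return(list(statistic = NA_real_, p_value = .Machine$double.xmin,
                degenerate = TRUE))
  }
  dstat <- function(z) {
    z <- sort((z - mean(z)) / stats::sd(z))
    p <- stats::pnorm(z)
    i <- seq_len(length(z))
    max(i / length(z) - p, p - (i - 1) / length(z))
  }
  d_obs <- dstat(x)
  old <- .seed_swap(seed)
  on.exit(.seed_restore(old))
  d_null <- vapply(seq_len(nsim),
                   function(i) dstat(stats::rnorm(n)), numeric(1))
  list(statistic = d_obs,
       p_value = (1 + sum(d_null >= d_obs)) / (nsim + 1),
       degenerate = FALSE)
}

#' Normality and between-drug comparisons of onset times
#'
#' Per-drug Lilliefors normality p-values, Kruskal-Wallis H (with tie
#' correction) across the drug groups, and pairwise two-sided Wilcoxon
#' rank-sum tests with Bonferroni adjustment.
#'
#' @param records Data.frame with columns `drug` and `tto_days`.
#' @param nsim,seed Passed to [ks_normality()].
#' @return List `ks` (named p-values), `kw_H`, `kw_p`, `pairwise`
#'   (matrix of adjusted p-values).
#' @export
group_comparisons <- function(records, nsim = 2000, seed = 20240101) {
  stopifnot(all(c("drug", "tto_days") %in% names(records)))
  groups <- split(records$tto_days, records$drug)
  groups <- groups[vapply(groups, length, integer(1)) >= 3]
  if (length(groups) < 2) stop("need at least 2 drug groups with n >= 3")
  ks <- vapply(groups, function(g) {
    if (length(g) < 4) return(NA_real_)
    ks_normality(g, nsim = nsim, seed = seed)$p_value
  }, numeric(1))
  kw <- stats::kruskal.test(
    x = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), vapply(groups, length, integer(1)))))
  pw <- stats::pairwise.wilcox.test(
    x = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), vapply(groups, length, integer(1)))),
    p.adjust.method = "bonferroni", exact = FALSE)
  list(ks = ks, kw_H = unname(kw$statistic), kw_p = kw$p.value,
       pairwise = pw$p.value)
}

#' Two-parameter Weibull fit by maximum likelihood
#'
#' Newton iteration on the profile score for the shape parameter
#' (the scale has the closed form `(mean(x^shape))^(1/shape)` at any
#' shape); 95% confidence intervals come from the observed information on
#' the log-parameter scale. Non-convergence after `maxit` iterations falls
#' back to the method of moments with a flag; an all-equal sample is
#' degenerate and flagged.
#'
#' @param x Positive onset times, n >= 10.
#' @param maxit Newton iteration cap.
#' @return List `shape`, `scale`, `shape_ci`, `scale_ci`, `n`,
#'   `converged`, `degenerate`, `failure_type`; class `weibull_fit`.
#' @export
fit_weibull <- function(x, maxit = 200) {
  x <- x[!is.na(x)]
  stopifnot(length(x) >= 10, all(x > 0))
  n <- length(x)
  if (stats::sd(x) == 0) {
    return(structure(list(shape = NA_real_, scale = NA_real_,
                          shape_ci = c(NA_real_, NA_real_),
                          scale_ci = c(NA_real_, NA_real_), n = n,
                          converged = FALSE, degenerate = TRUE,
                          failure_type = NA_character_),
                     class = "weibull_fit"))
  }
  lx <- log(x)
  mlx <- mean(lx)
  # profile score g(k) = 1/k + mean(log x) - sum(x^k log x)/sum(x^k)
  score <- function(k) {
    w <- exp(k * (lx - max(lx)))            # stabilized x^k
    1 / k + mlx - sum(w * lx) / sum(w)
  }
  dscore <- function(k) {
    w <- exp(k * (lx - max(lx)))
    s <- sum(w); s1 <- sum(w * lx); s2 <- sum(w * lx^2)
    -1 / k^2 - (s2 * s - s1^2) / s^2
  }
  # moment start: shape ~ 1.2 / sd(log x) (Menon-type estimator)
  k <- max(1.2 / stats::sd(lx), 1e-3)
  converged <- FALSE
  for (i in seq_len(maxit)) {
    step <- score(k) / dscore(k)
    k_new <- k - step
    if (!is.finite(k_new) || k_new <= 0) k_new <- k / 2
    if (abs(k_new - k) < 1e-10 * max(1, k)) {
      k <- k_new
      converged <- TRUE
      break
    }
    k <- k_new
  }
  if (!converged) {
    # method-of-moments fallback: match CV of the Weibull
    cv <- stats::sd(x) / mean(x)
    f <- function(kk) sqrt(gamma(1 + 2 / kk) / gamma(1 + 1 / kk)^2 - 1) - cv
    k <- tryCatch(stats::uniroot(f, c(0.05, 50))$root, error = function(e) k)
  }
  scale <- mean(exp(k * (lx - max(lx))))^(1 / k) * exp(max(lx))
  ci <- .weibull_ci(x, k, scale)
  structure(list(shape = k, scale = scale,
                 shape_ci = ci$shape_ci, scale_ci = ci$scale_ci, n = n,
                 converged = converged, degenerate = FALSE,
                 failure_type = classify_failure(ci$shape_ci)),
            class = "weibull_fit")
}

# observed-information CIs on the log-parameter scale
.weibull_ci <- function(x, shape, scale) {
  ll <- function(p) {
    k <- exp(p[1]); s <- exp(p[2])
    sum(stats::dweibull(x, shape = k, scale = s, log = TRUE))
  }
  p_hat <- c(log(shape), log(scale))
  h <- matrix(0, 2, 2)
  eps <- 1e-4
  for (i in 1:2) for (j in 1:2) {
    e_i <- e_j <- c(0, 0); e_i[i] <- eps; e_j[j] <- eps
    h[i, j] <- (ll(p_hat + e_i + e_j) - ll(p_hat + e_i - e_j) -
                  ll(p_hat - e_i + e_j) + ll(p_hat - e_i - e_j)) /
      (4 * eps^2)
  }
  v <- tryCatch(solve(-h), error = function(e) matrix(NA_real_, 2, 2))
  se <- sqrt(pmax(diag(v), 0))
  list(shape_ci = exp(p_hat[1] + c(-1.96, 1.96) * se[1]),
       scale_ci = exp(p_hat[2] + c(-1.96, 1.96) * se[2]))
}

#' Classify the Weibull hazard by its shape CI
#'
#' Early failure when the CI upper bound is below 1 (hazard decreasing),
#' wear-out when the lower bound is above 1 (hazard increasing), random
#' otherwise.
#'
#' @param shape_ci Numeric length-2 CI for the shape parameter.
#' @return `"early"`, `"random"` or `"wear-out"`.
#' @export
classify_failure <- function(shape_ci) {
  if (inherits(shape_ci, "weibull_fit")) shape_ci <- shape_ci$shape_ci
  stopifnot(length(shape_ci) == 2)
  if (any(is.na(shape_ci))) return(NA_character_)
  if (shape_ci[2] < 1) "early"
  else if (shape_ci[1] > 1) "wear-out"
  else "random"
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf(
    "Weibull MLE (n = %d): shape %.3f (%.3f-%.3f), scale %.2f (%.2f-%.2f), %s\n",
    x$n, x$shape, x$shape_ci[1], x$shape_ci[2],
    x$scale, x$scale_ci[1], x$scale_ci[2],
    if (is.na(x$failure_type)) "degenerate" else
      paste0(x$failure_type, " failure")))
  invisible(x)
}
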