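# In-code fixtures: a hand-sized assembled universe and a tiny quarter on
# disk, built fresh per test so no binary fixtures are needed.

# assembled cases built directly (bypassing file IO) from parallel vectors
make_assembled <- function(primaryid, drugname, pt, sex = NULL, age = NULL,
                           role = "PS", start_dt = NULL, event_dt = NULL) {
  n <- length(primaryid)
  sex <- if (is.null(sex)) rep(NA_character_, n) else sex
  age <- if (is.null(age)) rep(NA_real_, n) else age
  cases <- data.frame(
    primaryid = primaryid, caseid = primaryid, caseversion = 1L,
    sex = sex, age_years = age, occp_cod = NA_character_,
    event_date = if (is.null(event_dt)) as.Date(rep(NA, n)) else
      as.Date(event_dt),
    stringsAsFactors = FALSE)
  drugs <- data.frame(primaryid = primaryid, drug_seq = 1L,
                      role_cod = role, drugname = drugname,
                      prod_ai = drugname, stringsAsFactors = FALSE)
  reactions <- data.frame(primaryid = primaryid, pt = pt,
                          stringsAsFactors = FALSE)
  therapy <- if (is.null(start_dt)) NULL else
    data.frame(primaryid = primaryid, dsg_drug_seq = 1L,
               start_dt = as.Date(start_dt), end_dt = as.Date(NA),
               start_imputed = FALSE, invalid = FALSE,
               stringsAsFactors = FALSE)
  structure(list(cases = cases, drugs = drugs, reactions = reactions,
                 therapy = therapy, log = list()),
            class = "faers_cases")
}

# write a minimal DEMO/DRUG/REAC trio and return the paths
write_tiny_quarter <- function(dir, demo_lines, drug_lines, reac_lines) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(demo = file.path(dir, "DEMO.txt"),
         drug = file.path(dir, "DRUG.txt"),
         reac = file.path(dir, "REAC.txt"))
  writeLines(demo_lines, p["demo"])
  writeLines(drug_lines, p["drug"])
  writeLines(reac_lines, p["reac"])
  p
}

# independent textbook odds-ratio oracle (kept separate from ror())
oracle_or_ci <- function(a, b, c, d) {
  or <- (a / c) / (b / d)
  se <- sqrt(sum(1 / c(a, b, c, d)))
  c(or = or,
    lo = exp(log(or) - stats::qnorm(0.975) * se),
    hi = exp(log(or) + stats::qnorm(0.975) * se))
}

# brute-force Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# brute-force Kruskal-Wallis H with tie correction
oracle_kw_h <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  n <- length(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * mean(ri)^2)) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# type-7 quantile by explicit linear interpolation
oracle_q7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[pmin(lo + 1, length(x))] - x[lo])
}
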