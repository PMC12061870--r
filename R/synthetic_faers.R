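# Synthetic FAERS-format data with planted ground truth.
#
# Each synthetic report draws one primary-suspect drug from a drug mix and
# one PT from a background pool; for planted (drug, PT) pairs the PT
# probability conditional on the drug is inflated by a reporting-rate
# ratio rho and renormalized over the remaining PTs.  Onset times for
# planted pairs are Weibull(shape, scale) days from therapy start (others
# uniform on 1-1000 d), so the downstream Weibull analysis has a known
# truth.  A configurable fraction of cases is re-emitted as a higher
# CASEVERSION with perturbed demographics, exercising deduplication.

#' Build a synthetic-scenario configuration
#'
#' @param n_reports Number of base reports (before duplicate versions).
#' @param drug_mix Named probability vector over PS drug names (must sum
#'   to 1); names may be canonical study drugs or background drugs.
#' @param pt_pool Named weight vector over background PTs (normalized).
#' @param planted_pairs Data.frame with columns `drug`, `pt`, `rho`
#'   (reporting-rate ratio), `shape`, `scale` (Weibull onset, days).
#' @param sex_mix Probabilities `c(F=, M=, missing=)`.
#' @param age_band_mix Probabilities over `c("<18","18-65",">65")`.
#' @param age_missing Probability an age is blanked after the draw.
#' @param duplicate_rate Fraction of cases re-emitted as a newer version.
#' @param multi_pt Extra-PT probability: with this probability a report
#'   carries a second background PT (used in ETL tests; default off keeps
#'   the expected 2x2 closed-form exact).
#' @return List of class `faers_scenario`.
#' @export
faers_scenario <- function(n_reports = 10000,
                           drug_mix = c(adalimumab = 0.25, infliximab = 0.15,
                                        etanercept = 0.20,
                                        `certolizumab pegol` = 0.05,
                                        golimumab = 0.05, backgroundine = 0.30),
                           pt_pool = NULL,
                           planted_pairs = NULL,
                           sex_mix = c(F = 0.60, M = 0.32, missing = 0.08),
                           age_band_mix = c(`<18` = 0.04, `18-65` = 0.80,
                                            `>65` = 0.16),
                           age_missing = 0.25,
                           duplicate_rate = 0.05,
                           multi_pt = 0) {
  if (is.null(pt_pool)) {
    pts <- c("Deep vein thrombosis", "Pulmonary thrombosis",
             "Postoperative thrombosis", "Cerebral thrombosis",
             "Thrombophlebitis", "Headache", "Nausea", "Arthralgia",
             "Injection site pain", "Pyrexia", "Rash", "Fatigue",
             "Infection", "Pneumonia", "Diarrhoea", "Dizziness",
             "Pruritus", "Cough", "Vomiting", "Abdominal pain")
    pt_pool <- stats::setNames(c(rep(0.02, 5), rep(0.9 / 15, 15)), pts)
  }
  pt_pool <- pt_pool / sum(pt_pool)
  stopifnot(abs(sum(drug_mix) - 1) < 1e-8,
            all(drug_mix >= 0), all(pt_pool >= 0),
            abs(sum(sex_mix) - 1) < 1e-8,
            abs(sum(age_band_mix) - 1) < 1e-8,
            duplicate_rate >= 0, duplicate_rate <= 1,
            age_missing >= 0, age_missing <= 1)
  if (!is.null(planted_pairs)) {
    stopifnot(all(c("drug", "pt", "rho", "shape", "scale") %in%
                    names(planted_pairs)),
              all(planted_pairs$rho > 0),
              all(planted_pairs$drug %in% names(drug_mix)),
              all(planted_pairs$pt %in% names(pt_pool)))
  }
  structure(list(n_reports = n_reports, drug_mix = drug_mix,
                 pt_pool = pt_pool, planted_pairs = planted_pairs,
                 sex_mix = sex_mix, age_band_mix = age_band_mix,
                 age_missing = age_missing, duplicate_rate = duplicate_rate,
                 multi_pt = multi_pt),
            class = "faers_scenario")
}

# per-drug PT distribution after planting: planted PTs get rho * base
# weight, the rest of the pool is scaled to keep the total at 1
.pt_probs_for_drug <- function(config, drug) {
  p <- config$pt_pool
  pp <- config$planted_pairs
  if (is.null(pp)) return(p)
  pp <- pp[pp$drug == drug, , drop = FALSE]
  if (!nrow(pp)) return(p)
  idx <- match(pp$pt, names(p))
  inflated <- p[idx] * pp$rho
  if (sum(inflated) >= 1) {
    stop("planted rate ratios push P(pt | ", drug, ") above 1: ",
         paste(pp$pt, collapse = ", "))
  }
  rest <- setdiff(seq_along(p), idx)
  p[rest] <- p[rest] * (1 - sum(inflated)) / sum(p[rest])
  p[idx] <- inflated
  p
}

#' Expected 2x2 table for a planted pair
#'
#' Closed-form expectation of (a, b, c, d) under the generative law, for
#' oracle comparisons against realized counts.
#'
#' @param config A [faers_scenario()].
#' @param drug,pt The pair.
#' @return A [contingency_table()] of expectations (non-integer).
#' @export
expected_table <- function(config, drug, pt) {
  n <- config$n_reports
  p_d <- config$drug_mix[drug]
  stopifnot(!is.na(p_d))
  a <- n * p_d * .pt_probs_for_drug(config, drug)[pt]
  b <- n * p_d - a
  others <- setdiff(names(config$drug_mix), drug)
  c_ <- sum(vapply(others, function(dd) {
    n * config$drug_mix[dd] * .pt_probs_for_drug(config, dd)[pt]
  }, numeric(1)))
  contingency_table(a, b, c_, n - a - b - c_)
}

#' Generate a synthetic FAERS universe
#'
#' Draws the reports, optionally writes them as one FAERS-dialect quarter,
#' and returns the in-memory tables plus the ground truth (planted
#' parameters, realized per-pair counts, duplicate bookkeeping).
#'
#' @param config A [faers_scenario()].
#' @param seed RNG seed; the same seed reproduces the same universe.
#' @param dir Optional directory: when given, the tables are also written
#'   with [write_quarter()].
#' @param quarter_label Label used for file naming when writing.
#' @return List `tables` (demo/drug/reac/ther/outc/rpsr/indi data.frames),
#'   `truth` (list), `paths` (when written).
#' @export
generate_faers <- function(config, seed = 1L, dir = NULL,
                           quarter_label = "2020Q1") {
  stopifnot(inherits(config, "faers_scenario"))
  old <- .seed_swap(as.integer(seed))
  on.exit(.seed_restore(old))
  n <- config$n_reports
  drugs_drawn <- sample(names(config$drug_mix), n, replace = TRUE,
                        prob = config$drug_mix)
  # PT draw per drug (vectorized by drug block)
  pt_drawn <- character(n)
  for (dd in unique(drugs_drawn)) {
    idx <- which(drugs_drawn == dd)
    p <- .pt_probs_for_drug(config, dd)
    pt_drawn[idx] <- sample(names(p), length(idx), replace = TRUE, prob = p)
  }
  # onset days: planted Weibull per pair, uniform otherwise
  onset <- ceiling(stats::runif(n, 0, 1000))
  pp <- config$planted_pairs
  if (!is.null(pp)) {
    for (i in seq_len(nrow(pp))) {
      idx <- which(drugs_drawn == pp$drug[i] & pt_drawn == pp$pt[i])
      if (length(idx)) {
        onset[idx] <- pmax(round(stats::rweibull(length(idx),
                                                 shape = pp$shape[i],
                                                 scale = pp$scale[i])), 1)
      }
    }
  }
  start <- as.Date("2004-01-01") +
    floor(stats::runif(n, 0, as.numeric(as.Date("2020-12-31") -
                                          as.Date("2004-01-01"))))
  event <- start + onset

  sex <- sample(c("F", "M", ""), n, replace = TRUE, prob = config$sex_mix)
  band <- sample(names(config$age_band_mix), n, replace = TRUE,
                 prob = config$age_band_mix)
  age <- numeric(n)
  age[band == "<18"] <- stats::runif(sum(band == "<18"), 1, 17.9)
  age[band == "18-65"] <- stats::runif(sum(band == "18-65"), 18, 65)
  age[band == ">65"] <- stats::runif(sum(band == ">65"), 65.1, 95)
  age <- as.character(round(age))
  age_cod <- rep("YR", n)
  blank_age <- stats::runif(n) < config$age_missing
  age[blank_age] <- ""
  age_cod[blank_age] <- ""
  occp <- sample(c("CN", "MD", "OT", "PH", "HP", ""), n, replace = TRUE,
                 prob = c(0.45, 0.25, 0.10, 0.05, 0.05, 0.10))

  caseid <- as.character(seq_len(n) + 10000000)
  primaryid <- paste0(caseid, "1")
  demo <- data.frame(
    primaryid = primaryid, caseid = caseid, caseversion = "1",
    event_dt = format(event, "%Y%m%d"),
    fda_dt = format(event + 14, "%Y%m%d"),
    age = age, age_cod = age_cod, sex = sex, occp_cod = occp,
    stringsAsFactors = FALSE)
  # free-text perturbation of drug names (case / whitespace only)
  name_style <- stats::runif(n)
  shown <- drugs_drawn
  shown[name_style < 0.3] <- toupper(shown[name_style < 0.3])
  shown[name_style > 0.8] <- paste0(" ", shown[name_style > 0.8], " ")
  drug <- data.frame(
    primaryid = primaryid, drug_seq = "1", role_cod = "PS",
    drugname = shown, prod_ai = drugs_drawn, stringsAsFactors = FALSE)
  reac <- data.frame(primaryid = primaryid, pt = pt_drawn,
                     stringsAsFactors = FALSE)
  if (config$multi_pt > 0) {
    extra <- which(stats::runif(n) < config$multi_pt)
    if (length(extra)) {
      reac <- rbind(reac, data.frame(
        primaryid = primaryid[extra],
        pt = sample(names(config$pt_pool), length(extra), replace = TRUE,
                    prob = config$pt_pool),
        stringsAsFactors = FALSE))
    }
  }
  ther <- data.frame(primaryid = primaryid, dsg_drug_seq = "1",
                     start_dt = format(start, "%Y%m%d"),
                     end_dt = format(event, "%Y%m%d"),
                     stringsAsFactors = FALSE)
  outc <- data.frame(primaryid = primaryid,
                     outc_cod = sample(c("HO", "OT", "DE", ""), n,
                                       replace = TRUE,
                                       prob = c(0.3, 0.5, 0.05, 0.15)),
                     stringsAsFactors = FALSE)
  rpsr <- data.frame(primaryid = primaryid, rpsr_cod = "FGN",
                     stringsAsFactors = FALSE)
  indi <- data.frame(primaryid = primaryid, indi_drug_seq = "1",
                     indi_pt = "Rheumatoid arthritis",
                     stringsAsFactors = FALSE)

  # duplicate versions: re-emit selected cases with caseversion 2 and
  # perturbed demographics; the version-1 primaryid becomes stale
  dup_idx <- which(stats::runif(n) < config$duplicate_rate)
  if (length(dup_idx)) {
    dup_demo <- demo[dup_idx, , drop = FALSE]
    dup_demo$caseversion <- "2"
    dup_demo$primaryid <- paste0(dup_demo$caseid, "2")
    dup_demo$fda_dt <- format(event[dup_idx] + 60, "%Y%m%d")
    dup_demo$occp_cod <- "MD"
    demo <- rbind(demo, dup_demo)
    dup_rows <- function(tab) {
      piece <- tab[dup_idx, , drop = FALSE]
      piece$primaryid <- paste0(caseid[dup_idx], "2")
      rbind(tab, piece)
    }
    drug <- dup_rows(drug); reac <- dup_rows(reac); ther <- dup_rows(ther)
    outc <- dup_rows(outc); rpsr <- dup_rows(rpsr); indi <- dup_rows(indi)
  }
  ord <- sample(nrow(demo))      # shuffle so dedup cannot rely on order
  demo <- demo[ord, , drop = FALSE]
  rownames(demo) <- NULL

  realized <- data.frame(drug = drugs_drawn, pt = pt_drawn,
                         stringsAsFactors = FALSE)
  truth <- list(
    planted_pairs = pp,
    n_reports = n,
    duplicate_caseids = caseid[dup_idx],
    duplicate_versions = length(dup_idx),
    surviving_primaryids = ifelse(seq_len(n) %in% dup_idx,
                                  paste0(caseid, "2"), paste0(caseid, "1")),
    realized_counts = .realized_counts(realized, pp))
  tables <- list(demo = demo, drug = drug, reac = reac, ther = ther,
                 outc = outc, rpsr = rpsr, indi = indi)
  paths <- NULL
  if (!is.null(dir)) {
    paths <- write_quarter(tables, dir, quarter_label)
    truth_path <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(truth[c("planted_pairs", "n_reports",
                                 "duplicate_versions")],
                         truth_path, auto_unbox = TRUE, digits = NA)
  }
  list(tables = tables, truth = truth, paths = paths)
}

# realized (a,b,c,d) per planted pair from the drawn assignments
.realized_counts <- function(realized, pp) {
  if (is.null(pp)) return(NULL)
  n <- nrow(realized)
  out <- lapply(seq_len(nrow(pp)), function(i) {
    is_d <- realized$drug == pp$drug[i]
    is_e <- realized$pt == pp$pt[i]
    list(drug = pp$drug[i], pt = pp$pt[i],
         a = sum(is_d & is_e), b = sum(is_d & !is_e),
         c = sum(!is_d & is_e), d = sum(!is_d & !is_e))
  })
  out
}

#' Read back a generated quarter as a `faers_quarter`
#'
#' Convenience wrapper pairing [generate_faers()] output paths with
#' [read_quarter()].
#'
#' @param paths Named paths as returned in `$paths`.
#' @param quarter_label Quarter tag.
#' @return A `faers_quarter`.
#' @export
read_generated <- function(paths, quarter_label = "2020Q1") {
  read_quarter(paths[setdiff(names(paths), "ground_truth")],
               quarter_label = quarter_label)
}

#' The default study scenario
#'
#' A synthetic universe emulating the statistical structure of the
#' TNF-alpha blocker thrombosis analysis: the five study drugs plus a
#' background comparator, one planted thrombosis pair per drug whose
#' reporting-rate ratio is set to its published reporting odds ratio and
#' whose onset times follow the published per-drug Weibull law
#' (see [reference_table()]).
#'
#' @param n_reports Number of base reports.
#' @param duplicate_rate Fraction of cases re-emitted as newer versions.
#' @return A [faers_scenario()].
#' @export
study_scenario <- function(n_reports = 30000, duplicate_rate = 0.05) {
  wb <- reference_table("weibull")
  sig <- reference_table("signals")
  pair_pt <- c(adalimumab = "Postoperative thrombosis",
               golimumab = "Thrombophlebitis",
               `certolizumab pegol` = "Deep vein thrombosis",
               etanercept = "Deep vein thrombosis",
               infliximab = "Thrombophlebitis")
  # published ROR for the drug's planted PT; the two deep-vein pairs take
  # the published postoperative deep-vein value for their drug
  ror_of <- function(drug, pt) {
    hit <- sig$ror[sig$drug == drug & sig$pt == pt]
    if (!length(hit)) {
      hit <- sig$ror[sig$drug == drug &
                       sig$pt == "Deep vein thrombosis postoperative"]
    }
    hit[1]
  }
  pp <- do.call(rbind, lapply(names(pair_pt), function(dd) {
    data.frame(drug = dd, pt = unname(pair_pt[dd]),
               rho = ror_of(dd, pair_pt[dd]),
               shape = wb$shape[wb$drug == dd],
               scale = wb$scale[wb$drug == dd],
               stringsAsFactors = FALSE)
  }))
  faers_scenario(n_reports = n_reports, planted_pairs = pp,
                 duplicate_rate = duplicate_rate)
}
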