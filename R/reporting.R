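# Descriptive tables, signal-table rendering and published reference data.
#
# Percentages in descriptive tables are rounded half-up to one decimal
# (two decimals for statistics), the convention of pharmacovigilance
# reporting tables.  The package ships the published thrombosis signal
# tables for the five TNF-alpha blockers (a published FAERS analysis) as
# plain-text reference data used by the consistency checks.

#' Round half-up
#'
#' `round()` in R rounds half to even; reporting tables round half up.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count, table-rounded
#'
#' @param count,total Counts.
#' @param digits Decimal places (default 1, the descriptive-table
#'   convention).
#' @return `count / total * 100` rounded half-up.
#' @export
pct <- function(count, total, digits = 1) {
  round_half_up(count / total * 100, digits)
}

#' Descriptive characteristics table
#'
#' Per-drug and all-drug counts and percentages of sex, age band and
#' reporter occupation, with a Missing row per block — the layout of a
#' clinical-characteristics table.
#'
#' @param assembled A `faers_cases` list.
#' @param drugs_of_interest Canonical drug names (columns of the table).
#' @param dict Drug dictionary.
#' @param edges Age band edges.
#' @return Long data.frame `drug`, `block`, `level`, `n`, `pct`.
#' @export
descriptive_table <- function(assembled, drugs_of_interest,
                              dict = drug_dictionary(), edges = c(18, 65)) {
  cases <- assembled$cases
  ps <- assembled$drugs[assembled$drugs$role_cod == "PS", , drop = FALSE]
  canon <- if ("canonical" %in% names(ps)) ps$canonical else
    normalize_drug(ps$drugname, dict)
  occ_labels <- c(CN = "Consumer", HP = "Health professional", LW = "Lawyer",
                  MD = "Physician", OT = "Other health-professional",
                  PH = "Pharmacist", RN = "Registered nurse")
  one_drug <- function(ids, label) {
    cc <- cases[cases$primaryid %in% ids, , drop = FALSE]
    tot <- nrow(cc)
    lvl <- function(block, level, nn) {
      data.frame(drug = label, block = block, level = level, n = nn,
                 pct = if (tot > 0) pct(nn, tot) else NA_real_,
                 stringsAsFactors = FALSE)
    }
    sex_rows <- rbind(
      lvl("sex", "Female", sum(cc$sex == "F", na.rm = TRUE)),
      lvl("sex", "Male", sum(cc$sex == "M", na.rm = TRUE)),
      lvl("sex", "Missing", sum(is.na(cc$sex))))
    a <- cc$age_years
    age_rows <- rbind(
      lvl("age", paste0("<", edges[1]), sum(!is.na(a) & a < edges[1])),
      lvl("age", paste0(edges[1], "-", edges[2]),
          sum(!is.na(a) & a >= edges[1] & a <= edges[2])),
      lvl("age", paste0(">", edges[2]), sum(!is.na(a) & a > edges[2])),
      lvl("age", "Missing", sum(is.na(a))))
    occ_rows <- do.call(rbind, c(
      lapply(names(occ_labels), function(k) {
        lvl("occupation", occ_labels[[k]],
            sum(cc$occp_cod == k, na.rm = TRUE))
      }),
      list(lvl("occupation", "Missing", sum(is.na(cc$occp_cod))))))
    rbind(lvl("total", "Reports", tot), sex_rows, age_rows, occ_rows)
  }
  per_drug <- lapply(drugs_of_interest, function(dd) {
    one_drug(unique(ps$primaryid[!is.na(canon) & canon == dd]), dd)
  })
  all_ids <- unique(ps$primaryid[!is.na(canon) &
                                   canon %in% drugs_of_interest])
  out <- do.call(rbind, c(per_drug, list(one_drug(all_ids, "ALL"))))
  rownames(out) <- NULL
  out
}

#' IC / EBGM print-consistency check
#'
#' The information component of a pair equals `log2` of its EBGM when the
#' empirical-Bayes shrinkage is weak; in a printed signal table the two
#' columns must therefore agree up to print rounding. The tolerance is the
#' half-ulp of the printed IC plus the half-ulp of the printed EBGM
#' propagated through `log2` (`0.5 * 10^-digits / (ebgm * ln 2)`).
#'
#' @param ebgm Printed EBGM values.
#' @param ic Printed IC values.
#' @param digits Decimals the table was printed to.
#' @return Logical vector: does `log2(ebgm)` reproduce `ic` within
#'   propagated print rounding?
#' @export
ic_ebgm_consistent <- function(ebgm, ic, digits = 2) {
  half <- 0.5 * 10^-digits
  tol <- half + half / (ebgm * log(2))
  abs(log2(ebgm) - ic) <= tol
}

#' Heatmap payload: shared positive-report PTs across drugs
#'
#' Returns the ROR matrix of exactly those PTs reported (a > 0) by every
#' drug in `drugs` (the intersection rule of a cross-drug signal heatmap).
#'
#' @param signals Data.frame with columns `drug`, `pt`, `a`, `ror`.
#' @param drugs Drugs that must all have reported the PT.
#' @return Matrix (drugs x PTs) of RORs.
#' @export
heatmap_payload <- function(signals, drugs) {
  sig <- signals[signals$drug %in% drugs & signals$a > 0, , drop = FALSE]
  shared <- Reduce(intersect, lapply(split(sig$pt, sig$drug)[drugs], unique))
  m <- matrix(NA_real_, length(drugs), length(shared),
              dimnames = list(drugs, shared))
  for (i in seq_len(nrow(sig))) {
    if (sig$pt[i] %in% shared) m[sig$drug[i], sig$pt[i]] <- sig$ror[i]
  }
  m
}

#' Published reference tables shipped with the package
#'
#' Plain-text copies of the printed results of a published FAERS
#' disproportionality analysis of thrombotic events under the five
#' TNF-alpha blockers: `"signals"` (the PT-level signal table: N, ROR/CI,
#' PRR/chi2, EBGM/EBGM05, IC/IC025 per drug), `"descriptives"` (the
#' clinical-characteristics counts), `"weibull"` (onset Weibull shape /
#' scale with CIs and failure type per drug). Used as inputs by the
#' consistency checks; they are published values, not package output.
#'
#' @param which One of `"signals"`, `"descriptives"`, `"weibull"`.
#' @return Data.frame.
#' @export
reference_table <- function(which = c("signals", "descriptives", "weibull")) {
  which <- match.arg(which)
  f <- c(signals = "reference_signals.tsv",
         descriptives = "reference_descriptives.tsv",
         weibull = "reference_weibull.tsv")[[which]]
  utils::read.delim(system.file("extdata", f, package = "faersignal"),
                    sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    quote = "")
}
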