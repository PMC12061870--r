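# 2x2 contingency construction for drug-event pairs.
#
# The disproportionality contrast is target drug vs. all other drugs in the
# loaded reporting universe (full-database comparator), with the report as
# the counting unit: a report sits in the "target drug" margin iff at least
# one of its primary-suspect (PS) drugs normalizes to the target, and in
# the "target event" margin iff at least one of its PTs is in the event
# set.  Strata restrict the universe to reports with known sex / age in
# the requested band before counting.

#' Define an analysis stratum
#'
#' @param sex `"F"`, `"M"` or `"ALL"`.
#' @param age_band `"<18"`, `"18-65"`, `">65"` or `"ALL"` (band edges per
#'   `edges`: `<18` is age < lower edge; the middle band is closed on both
#'   edges; `>65` is age > upper edge).
#' @param edges Numeric length-2 vector of band edges in years.
#' @return List with class `stratum`.
#' @export
stratum <- function(sex = "ALL", age_band = "ALL", edges = c(18, 65)) {
  sex <- toupper(sex)
  stopifnot(sex %in% c("F", "M", "ALL"),
            length(edges) == 2, edges[1] < edges[2])
  age_band <- sub("–", "-", age_band)   # en-dash tolerated
  bands <- c("<18", "18-65", ">65", "ALL")
  names(bands) <- c("lt", "mid", "gt", "ALL")
  band_key <- c("ALL" = "ALL",
                stats::setNames("lt", paste0("<", edges[1])),
                stats::setNames("mid", paste0(edges[1], "-", edges[2])),
                stats::setNames("gt", paste0(">", edges[2])))
  if (!age_band %in% names(band_key)) {
    stop("age_band must be one of ", paste(names(band_key), collapse = ", "))
  }
  structure(list(sex = sex, age_band = age_band,
                 band_key = unname(band_key[age_band]), edges = edges),
            class = "stratum")
}

# logical index of cases inside the stratum
.stratum_mask <- function(cases, st) {
  keep <- rep(TRUE, nrow(cases))
  if (st$sex != "ALL") keep <- keep & !is.na(cases$sex) & cases$sex == st$sex
  if (st$band_key != "ALL") {
    a <- cases$age_years
    keep <- keep & !is.na(a) & switch(st$band_key,
      lt  = a < st$edges[1],
      mid = a >= st$edges[1] & a <= st$edges[2],
      gt  = a > st$edges[2])
  }
  keep
}

# primaryids whose PS drug(s) normalize into `targets`
.drug_positive_ids <- function(drugs, targets, dict) {
  ps <- drugs[drugs$role_cod == "PS", , drop = FALSE]
  if (!nrow(ps) || !length(targets)) return(character(0))
  canon <- if ("canonical" %in% names(ps)) ps$canonical else
    normalize_drug(ps$drugname, dict)
  unique(ps$primaryid[!is.na(canon) & canon %in% targets])
}

#' Build the 2x2 table for one drug-event pair
#'
#' Counts reports in one stratum into the classic pharmacovigilance 2x2:
#' `a` = target drug & target event, `b` = target drug & other events,
#' `c` = other drugs & target event, `d` = neither. An empty stratum yields
#' a table of zeros, not an error.
#'
#' @param assembled A `faers_cases` list from [assemble_cases()].
#' @param target_drug Canonical drug name (or vector = drug class).
#' @param target_event An `event_set` or character vector of PTs.
#' @param strat A [stratum()]; default unstratified.
#' @param dict Drug dictionary used if `drugs` lacks a `canonical` column.
#' @param counting_unit `"report"` (default; one report, one count) or
#'   `"pair"` (each report-PT match counts once in the event margin).
#' @return List `a`,`b`,`c`,`d`,`n` with class `contingency_table`.
#' @export
count_table <- function(assembled, target_drug, target_event,
                        strat = stratum(), dict = drug_dictionary(),
                        counting_unit = c("report", "pair")) {
  counting_unit <- match.arg(counting_unit)
  cases <- assembled$cases
  keep_ids <- cases$primaryid[.stratum_mask(cases, strat)]
  drugs <- assembled$drugs[assembled$drugs$primaryid %in% keep_ids, ,
                           drop = FALSE]
  reac <- assembled$reactions[assembled$reactions$primaryid %in% keep_ids, ,
                              drop = FALSE]
  drug_pos <- .drug_positive_ids(drugs, target_drug, dict)
  if (counting_unit == "report") {
    ev_pos <- unique(reac$primaryid[.in_event_set(reac$pt, target_event)])
    univ <- keep_ids
    a <- sum(univ %in% drug_pos & univ %in% ev_pos)
    b <- sum(univ %in% drug_pos & !(univ %in% ev_pos))
    c_ <- sum(!(univ %in% drug_pos) & univ %in% ev_pos)
    d <- length(univ) - a - b - c_
  } else {
    # drug-event pair unit: each distinct (report, PT) row is one count
    is_ev <- .in_event_set(reac$pt, target_event)
    is_dr <- reac$primaryid %in% drug_pos
    a <- sum(is_dr & is_ev); b <- sum(is_dr & !is_ev)
    c_ <- sum(!is_dr & is_ev); d <- sum(!is_dr & !is_ev)
  }
  contingency_table(a, b, c_, d)
}

#' Construct a contingency table from counts
#'
#' @param a,b,c,d Nonnegative counts (target drug x target event layout).
#' @return Object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  structure(list(a = as.numeric(a), b = as.numeric(b),
                 c = as.numeric(c), d = as.numeric(d),
                 n = as.numeric(a + b + c + d)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("target drug", "other drugs"),
                              c("target event", "other events")))
  print(m)
  invisible(x)
}

#' 2x2 table for a drug class
#'
#' As [count_table()] with the drug margin defined by membership in a set
#' of canonical names (e.g. all five TNF-alpha blockers).
#'
#' @inheritParams count_table
#' @param drug_set Character vector of canonical names (may be empty,
#'   yielding `a = b = 0`).
#' @return A `contingency_table`.
#' @export
table_for_drug_class <- function(assembled, drug_set, target_event,
                                 strat = stratum(), dict = drug_dictionary()) {
  count_table(assembled, target_drug = drug_set, target_event = target_event,
              strat = strat, dict = dict)
}

#' All drug-event pair tables in a universe
#'
#' Enumerates every (PS canonical drug or raw PS drug name, PT) pair with
#' `a > 0` and returns their 2x2 counts — the pair universe over which the
#' empirical-Bayes prior is fitted.
#'
#' @param assembled A `faers_cases` list.
#' @param dict Drug dictionary; names that do not normalize are kept
#'   verbatim (folded) so the background universe is complete.
#' @return Data.frame drug/pt/a/b/c/d/n, one row per observed pair.
#' @export
pair_universe <- function(assembled, dict = drug_dictionary()) {
  ps <- assembled$drugs[assembled$drugs$role_cod == "PS", , drop = FALSE]
  canon <- if ("canonical" %in% names(ps)) ps$canonical else
    normalize_drug(ps$drugname, dict)
  canon[is.na(canon)] <- .fold_name(ps$drugname[is.na(canon)])
  ps_map <- unique(data.frame(primaryid = ps$primaryid, drug = canon,
                              stringsAsFactors = FALSE))
  reac <- assembled$reactions
  pairs <- merge(ps_map, reac, by = "primaryid")
  if (!nrow(pairs)) {
    return(data.frame(drug = character(), pt = character(), a = numeric(),
                      b = numeric(), c = numeric(), d = numeric(),
                      n = numeric()))
  }
  # report-level margins
  n_total <- length(unique(assembled$cases$primaryid))
  drug_margin <- table(unique(pairs[c("primaryid", "drug")])$drug)
  ev_margin <- tapply(pairs$primaryid, tolower(pairs$pt),
                      function(x) length(unique(x)))
  a_tab <- stats::aggregate(primaryid ~ drug + pt, data = pairs,
                            FUN = function(x) length(unique(x)))
  names(a_tab)[3] <- "a"
  a_tab$b <- as.numeric(drug_margin[a_tab$drug]) - a_tab$a
  a_tab$c <- as.numeric(ev_margin[tolower(a_tab$pt)]) - a_tab$a
  a_tab$d <- n_total - a_tab$a - a_tab$b - a_tab$c
  a_tab$n <- n_total
  a_tab[order(a_tab$drug, a_tab$pt), , drop = FALSE]
}
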