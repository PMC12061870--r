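# End-to-end orchestration: load -> dedup -> normalize -> count -> signal
# -> subgroup -> time-to-onset -> Weibull -> render, with a manifest that
# records how far the run got and every stage's row counts.

#' Per-PT signal table for one drug
#'
#' Runs the four disproportionality statistics for every PT in `pts`
#' against the full-database comparator, adds the BH-adjusted Fisher
#' p-value across the PT family, and the positivity flags.
#'
#' @param assembled A `faers_cases` list.
#' @param target_drug Canonical drug name.
#' @param pts Character vector of PTs to score.
#' @param strat A [stratum()].
#' @param prior Optional [fit_mgps_prior()] for the EBGM columns.
#' @param dict Drug dictionary.
#' @param yates,cc Statistical toggles.
#' @return Data.frame, one row per PT (drug, pt, stratum columns first).
#' @export
signal_table <- function(assembled, target_drug, pts, strat = stratum(),
                         prior = NULL, dict = drug_dictionary(),
                         yates = TRUE, cc = 0.5) {
  rows <- lapply(pts, function(p) {
    tab <- count_table(assembled, target_drug, p, strat = strat, dict = dict)
    cbind(data.frame(drug = target_drug, pt = p, sex = strat$sex,
                     age_band = strat$age_band, stringsAsFactors = FALSE),
          signal_stats(tab, prior = prior, yates = yates, cc = cc))
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order on a synthetic scenario or on FAERS-style
#' files, writing the table payloads (`table1.csv`, `signals.csv`,
#' `subgroup.csv`, `volcano.csv`, `heatmap.csv`, `tto.csv`,
#' `tto_summary.csv`, `weibull.csv`, `comparisons.json`) and a
#' `manifest.json` recording stage completion and row counts. A stage
#' failure stops the run but leaves earlier outputs in place, with the
#' failure point in the manifest.
#'
#' @param config List with elements:
#'   `scenario` (a [faers_scenario()]) or `paths` + `quarter_label`;
#'   `drugs` (canonical names to analyse); `event_stems` (substring stems
#'   for the event set) or `event_pts` (explicit); `strata` (list of
#'   [stratum()]); `out_dir`; `seed`; optional `yates`, `cc`, `alpha`,
#'   `edges`, `tto_cap`, `ks_nsim`.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(
    list(drugs = NULL, event_stems = "thrombo", event_pts = NULL,
         strata = list(stratum()), seed = 1L, yates = TRUE, cc = 0.5,
         alpha = 0.05, edges = c(18, 65), tto_cap = 7300, ks_nsim = 2000),
    config)
  stopifnot(!is.null(cfg$out_dir), cfg$alpha > 0, cfg$alpha < 1)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(status = "running", stages = list(), seed = cfg$seed)
  dict <- drug_dictionary()
  flush_manifest <- function() {
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      manifest$status <<- "failed"
      manifest$failed_stage <<- name
      manifest$error <<- conditionMessage(res)
      flush_manifest()
      stop("pipeline failed at stage ", sQuote(name), ": ",
           conditionMessage(res), call. = FALSE)
    }
    res
  }

  # load ------------------------------------------------------------------
  quarter <- stage("load", {
    if (!is.null(cfg$scenario)) {
      gen <- generate_faers(cfg$scenario, seed = cfg$seed)
      structure(c(gen$tables,
                  list(quarter_label = "synthetic", load_report = NULL)),
                class = "faers_quarter")
    } else {
      read_quarter(cfg$paths,
                   quarter_label = cfg$quarter_label %||% "0000Q1")
    }
  })
  manifest$stages$load <- list(demo_rows = nrow(quarter$demo))

  # dedup + assemble + normalize ------------------------------------------
  assembled <- stage("assemble", assemble_cases(quarter))
  assembled$drugs$canonical <- normalize_drug(assembled$drugs$drugname, dict)
  manifest$stages$assemble <- assembled$log
  if (is.null(cfg$drugs)) {
    cfg$drugs <- intersect(names(dict),
                           unique(stats::na.omit(assembled$drugs$canonical)))
  }

  # event set ---------------------------------------------------------------
  event_set <- stage("event_set", {
    if (!is.null(cfg$event_pts)) {
      build_event_set(mode = "explicit", pts = cfg$event_pts)
    } else {
      pts <- unique(assembled$reactions$pt)
      hit <- rep(FALSE, length(pts))
      for (s in cfg$event_stems) {
        hit <- hit | grepl(tolower(s), tolower(pts), fixed = TRUE)
      }
      if (!any(hit)) stop("no PT matches stems ",
                          paste(cfg$event_stems, collapse = ", "))
      structure(list(name = "event", pts = pts[hit]), class = "event_set")
    }
  })
  manifest$stages$event_set <- list(n_pts = length(event_set$pts))

  # descriptives ------------------------------------------------------------
  table1 <- stage("descriptives",
                  descriptive_table(assembled, cfg$drugs, dict = dict,
                                    edges = cfg$edges))
  utils::write.csv(table1, file.path(cfg$out_dir, "table1.csv"),
                   row.names = FALSE)
  manifest$stages$descriptives <- list(rows = nrow(table1))

  # MGPS prior over the whole pair universe ---------------------------------
  prior <- stage("mgps_prior", {
    univ <- pair_universe(assembled, dict = dict)
    e <- (univ$a + univ$b) * (univ$a + univ$c) / univ$n
    keep <- e > 0
    suppressWarnings(fit_mgps_prior(univ$a[keep], e[keep], seed = cfg$seed))
  })
  manifest$stages$mgps_prior <- prior[c("alpha1", "beta1", "alpha2",
                                        "beta2", "w", "converged")]

  # signals, overall and per stratum ----------------------------------------
  signals <- stage("signals", {
    do.call(rbind, lapply(cfg$strata, function(st) {
      do.call(rbind, lapply(cfg$drugs, function(dd) {
        signal_table(assembled, dd, event_set$pts, strat = st,
                     prior = prior, dict = dict,
                     yates = cfg$yates, cc = cfg$cc)
      }))
    }))
  })
  overall <- signals$sex == "ALL" & signals$age_band == "ALL"
  utils::write.csv(signals[overall, ], file.path(cfg$out_dir, "signals.csv"),
                   row.names = FALSE)
  utils::write.csv(signals[!overall, ],
                   file.path(cfg$out_dir, "subgroup.csv"), row.names = FALSE)
  manifest$stages$signals <- list(rows = nrow(signals))

  # volcano + heatmap payloads ----------------------------------------------
  stage("render", {
    vol <- do.call(rbind, lapply(cfg$drugs, function(dd) {
      part <- signals[overall & signals$drug == dd, ]
      if (!nrow(part)) return(NULL)
      cbind(drug = dd, volcano_payload(part, alpha = cfg$alpha))
    }))
    utils::write.csv(vol, file.path(cfg$out_dir, "volcano.csv"),
                     row.names = FALSE)
    hm <- heatmap_payload(signals[overall, ], cfg$drugs)
    utils::write.csv(as.data.frame(hm),
                     file.path(cfg$out_dir, "heatmap.csv"), row.names = TRUE)
    NULL
  })

  # time-to-onset ------------------------------------------------------------
  tto <- stage("tto", {
    do.call(rbind, lapply(cfg$drugs, function(dd) {
      compute_tto(assembled, dd, event_set, dict = dict,
                  cap_days = cfg$tto_cap)
    }))
  })
  utils::write.csv(tto, file.path(cfg$out_dir, "tto.csv"), row.names = FALSE)
  tto_sum <- do.call(rbind, lapply(split(tto$tto_days, tto$drug),
                                   function(x) as.data.frame(summarize_tto(x))))
  tto_sum <- cbind(drug = rownames(tto_sum), tto_sum)
  utils::write.csv(tto_sum, file.path(cfg$out_dir, "tto_summary.csv"),
                   row.names = FALSE)
  manifest$stages$tto <- list(records = nrow(tto),
                              exclusions = as.list(attr(tto, "exclusions")))

  # group comparisons + Weibull ----------------------------------------------
  stage("weibull", {
    enough <- names(which(table(tto$drug) >= 10))
    if (length(enough) >= 2) {
      cmp <- group_comparisons(tto[tto$drug %in% enough, ],
                               nsim = cfg$ks_nsim, seed = cfg$seed)
      jsonlite::write_json(
        list(ks_p = as.list(cmp$ks), kw_H = cmp$kw_H, kw_p = cmp$kw_p,
             pairwise = as.data.frame(cmp$pairwise)),
        file.path(cfg$out_dir, "comparisons.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    }
    wb <- do.call(rbind, lapply(enough, function(dd) {
      f <- fit_weibull(tto$tto_days[tto$drug == dd])
      data.frame(drug = dd, n = f$n, shape = f$shape,
                 shape_lo = f$shape_ci[1], shape_hi = f$shape_ci[2],
                 scale = f$scale, scale_lo = f$scale_ci[1],
                 scale_hi = f$scale_ci[2], type = f$failure_type,
                 converged = f$converged, stringsAsFactors = FALSE)
    }))
    utils::write.csv(wb, file.path(cfg$out_dir, "weibull.csv"),
                     row.names = FALSE)
    NULL
  })

  manifest$status <- "complete"
  flush_manifest()
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
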