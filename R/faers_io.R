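# Reading, writing and deduplicating FAERS-style quarterly ASCII extracts.
#
# The FAERS quarterly distribution ships one `$`-delimited ASCII table per
# dimension (DEMO, DRUG, REAC, OUTC, RPSR, THER, INDI), one header line,
# no quoting.  All tables are keyed by `primaryid`; a case (CASEID) may be
# re-submitted across quarters with an incremented CASEVERSION, so
# deduplication has to be global across the pooled quarters.

.faers_tables <- c("demo", "drug", "reac", "outc", "rpsr", "ther", "indi")
.faers_mandatory <- c("demo", "drug", "reac")

#' Read one FAERS-style quarter
#'
#' Reads the per-table ASCII files of one quarterly extract. Each file has a
#' single header line naming the columns (which must include the report
#' identifier `primaryid`) and `$`-separated fields. Rows whose field count
#' does not match the header are dropped and counted in the load report
#' rather than guessed at.
#'
#' @param paths Named list/character vector of file paths; names among
#'   `demo`, `drug`, `reac`, `outc`, `rpsr`, `ther`, `indi` (case
#'   insensitive). `demo`, `drug` and `reac` are mandatory.
#' @param quarter_label Quarter tag such as `"2004Q1"`.
#' @param delim Field delimiter, `"$"` for the FAERS dialect; `","` is
#'   accepted for CSV fixtures.
#' @return A `faers_quarter`: list with one data.frame per table (all
#'   columns character, names lower-cased), `quarter_label`, and
#'   `load_report` (per-table rows read / malformed counts).
#' @export
read_quarter <- function(paths, quarter_label = "0000Q1", delim = "$") {
  if (!grepl("^\\d{4}Q[1-4]$", quarter_label) && quarter_label != "0000Q1") {
    stop("quarter_label must look like 'YYYYQn': got ", quarter_label)
  }
  if (!delim %in% c("$", ",", "\t")) {
    stop("unknown delimiter ", sQuote(delim),
         ": the FAERS dialect is '$' ( ',' and tab accepted for fixtures)")
  }
  nm <- tolower(names(paths))
  if (is.null(nm) || any(!nzchar(nm))) stop("paths must be named by table")
  bad <- setdiff(nm, .faers_tables)
  if (length(bad)) stop("unknown table name(s): ", paste(bad, collapse = ", "))
  miss <- setdiff(.faers_mandatory, nm)
  if (length(miss)) {
    stop("missing mandatory table(s): ", paste(toupper(miss), collapse = ", "))
  }
  tables <- stats::setNames(vector("list", length(nm)), nm)
  report <- list()
  for (i in seq_along(nm)) {
    path <- paths[[i]]
    if (!file.exists(path)) stop("file not found for table ", nm[i], ": ", path)
    parsed <- .read_delim_table(path, delim)
    tables[[nm[i]]] <- parsed$table
    report[[nm[i]]] <- list(rows = nrow(parsed$table),
                            malformed = parsed$malformed)
  }
  for (tab in nm) {
    if (!"primaryid" %in% names(tables[[tab]])) {
      stop("table ", toupper(tab), " lacks a 'primaryid' column")
    }
  }
  structure(
    c(tables[intersect(.faers_tables, nm)],
      list(quarter_label = quarter_label, load_report = report)),
    class = "faers_quarter"
  )
}

# Line-level parser: FAERS files are unquoted, so a plain strsplit on the
# delimiter is the format's own definition.  UTF-8 with latin1 fallback.
.read_delim_table <- function(path, delim) {
  lines <- .read_lines_enc(path)
  if (!length(lines)) stop("empty file: ", path)
  split <- strsplit(lines, delim, fixed = TRUE)
  header <- tolower(trimws(split[[1]]))
  body <- split[-1]
  # trailing empty field is dropped by strsplit; pad rows one short whose
  # raw line ends in the delimiter
  nf <- lengths(body)
  ends <- endsWith(lines[-1], delim)
  body[nf == length(header) - 1L & ends] <-
    lapply(body[nf == length(header) - 1L & ends], function(x) c(x, ""))
  nf <- lengths(body)
  ok <- nf == length(header)
  body <- body[ok]
  tab <- as.data.frame(
    stats::setNames(
      lapply(seq_along(header), function(j) {
        vapply(body, function(r) r[[j]], character(1), USE.NAMES = FALSE)
      }),
      header),
    stringsAsFactors = FALSE, check.names = FALSE)
  list(table = tab, malformed = sum(!ok))
}

.read_lines_enc <- function(path) {
  lines <- tryCatch(readLines(path, encoding = "UTF-8", warn = FALSE),
                    error = function(e) NULL)
  if (is.null(lines) || any(!validUTF8(lines))) {
    lines <- readLines(path, encoding = "latin1", warn = FALSE)
    lines <- iconv(lines, from = "latin1", to = "UTF-8")
  }
  lines
}

#' Write tables as one FAERS-style quarter
#'
#' Inverse of [read_quarter()]: writes each table as a `$`-delimited ASCII
#' file named `<TABLE><suffix>.txt` under `dir`.
#'
#' @param tables Named list of data.frames (`demo`, `drug`, `reac`, ...).
#' @param dir Output directory (created if needed).
#' @param quarter_label Quarter tag, used in file names (e.g. `DRUG24Q1.txt`).
#' @param delim Field delimiter.
#' @return Named character vector of written file paths, invisibly.
#' @export
write_quarter <- function(tables, dir, quarter_label = "0000Q1", delim = "$") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  suffix <- paste0(substr(quarter_label, 3, 4), substr(quarter_label, 5, 6))
  nm <- tolower(names(tables))
  paths <- character(0)
  for (i in seq_along(nm)) {
    tab <- tables[[i]]
    path <- file.path(dir, paste0(toupper(nm[i]), suffix, ".txt"))
    lines <- c(paste(names(tab), collapse = delim),
               if (nrow(tab)) do.call(paste, c(lapply(tab, as.character),
                                               sep = delim)))
    writeLines(lines, path, useBytes = TRUE)
    paths[nm[i]] <- path
  }
  invisible(paths)
}

#' Deduplicate DEMO rows to one row per case
#'
#' FAERS cases are re-submitted as new versions; following the FDA
#' recommendation only the latest version of each CASEID is analysed.
#' Keeps, per `caseid`, the row with the highest `caseversion`; ties are
#' broken by latest receipt date (`fda_dt`, then `rept_dt`, when present),
#' then by largest `primaryid`. Non-numeric case versions are treated as
#' version 0 and logged.
#'
#' @param demo Data.frame of DEMO rows with `caseid` and `caseversion`.
#' @return The surviving rows, with attributes `removed` (count) and
#'   `removed_primaryids`.
#' @export
deduplicate <- function(demo) {
  stopifnot(all(c("caseid", "caseversion") %in% names(demo)))
  if (!nrow(demo)) {
    attr(demo, "removed") <- 0L
    attr(demo, "removed_primaryids") <- character(0)
    return(demo)
  }
  ver <- suppressWarnings(as.numeric(demo$caseversion))
  n_badver <- sum(is.na(ver))
  ver[is.na(ver)] <- 0
  date_col <- intersect(c("fda_dt", "rept_dt"), names(demo))
  rdate <- if (length(date_col)) {
    suppressWarnings(as.numeric(demo[[date_col[1]]]))
  } else {
    rep(0, nrow(demo))
  }
  rdate[is.na(rdate)] <- 0
  pid <- suppressWarnings(as.numeric(demo$primaryid))
  pid[is.na(pid)] <- 0
  ord <- order(demo$caseid, ver, rdate, pid)   # last per caseid wins
  demo_o <- demo[ord, , drop = FALSE]
  keep_last <- !duplicated(demo_o$caseid, fromLast = TRUE)
  out <- demo_o[keep_last, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- sum(!keep_last)
  attr(out, "removed_primaryids") <- demo_o$primaryid[!keep_last]
  attr(out, "nonnumeric_versions") <- n_badver
  out
}

# FAERS age_cod unit conversions to years.  The distribution codes a decade
# as DEC; unknown codes yield NA rather than a guess.
.age_to_years <- function(age, age_cod) {
  age_num <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(age_cod))
  factor <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.18,
              DY = 1 / 365.25, HR = 1 / 8766)
  f <- factor[cod]
  f[cod == "" & !is.na(age_num)] <- 1   # blank unit: FAERS convention is years
  out <- age_num * unname(f)
  out[!is.na(out) & (out < 0 | out > 130)] <- NA_real_
  out
}

# Partial FAERS dates are YYYY, YYYYMM or YYYYMMDD; midpoint imputation
# (July 1 / day 15) avoids directional bias in onset intervals.
#' Parse FAERS partial dates
#'
#' @param x Character vector of `YYYY`, `YYYYMM` or `YYYYMMDD` values.
#' @return `Date` vector; unparseable entries are `NA`, partial dates are
#'   imputed to mid-year / mid-month (attribute `imputed` marks which).
#' @export
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x)] <- ""
  imputed <- rep(FALSE, length(x))
  full <- ifelse(grepl("^\\d{8}$", x), x, NA_character_)
  ym <- grepl("^\\d{6}$", x)
  full[ym] <- paste0(x[ym], "15")
  y <- grepl("^\\d{4}$", x)
  full[y] <- paste0(x[y], "0701")
  imputed[ym | y] <- TRUE
  out <- as.Date(full, format = "%Y%m%d")
  imputed[is.na(out)] <- FALSE
  attr(out, "imputed") <- imputed
  out
}

#' Assemble deduplicated cases from one or more quarters
#'
#' Pools the quarters, deduplicates cases globally (CASEID versions span
#' quarters), restricts drug/reaction/therapy rows to the surviving
#' `primaryid`s, converts ages to years from FAERS unit codes, maps sex
#' values outside F/M to missing, and collapses duplicate (primaryid, PT)
#' reaction rows.
#'
#' @param quarters A `faers_quarter` or list of them.
#' @return List of data.frames `cases`, `drugs`, `reactions`, `therapy`
#'   plus a `log` of row counts (class `faers_cases`).
#' @export
assemble_cases <- function(quarters) {
  if (inherits(quarters, "faers_quarter")) quarters <- list(quarters)
  stopifnot(length(quarters) >= 1)
  pool <- function(tab) {
    pieces <- lapply(quarters, function(q) q[[tab]])
    pieces <- Filter(Negate(is.null), pieces)
    if (!length(pieces)) return(NULL)
    cols <- Reduce(union, lapply(pieces, names))
    pieces <- lapply(pieces, function(p) {
      for (cn in setdiff(cols, names(p))) p[[cn]] <- NA_character_
      p[cols]
    })
    do.call(rbind, pieces)
  }
  demo <- pool("demo")
  drug <- pool("drug")
  reac <- pool("reac")
  ther <- pool("ther")
  if (is.null(demo) || is.null(drug) || is.null(reac)) {
    stop("DEMO, DRUG and REAC are required to assemble cases")
  }
  n_demo_in <- nrow(demo)
  demo <- deduplicate(demo)
  keep <- demo$primaryid

  sex <- toupper(trimws(if ("sex" %in% names(demo)) demo$sex else
                        demo$gndr_cod))
  sex[!sex %in% c("F", "M")] <- NA_character_
  age_years <- if (all(c("age", "age_cod") %in% names(demo))) {
    .age_to_years(demo$age, demo$age_cod)
  } else {
    rep(NA_real_, nrow(demo))
  }
  event_date <- if ("event_dt" %in% names(demo)) {
    parse_faers_date(demo$event_dt)
  } else {
    as.Date(rep(NA, nrow(demo)))
  }
  occp <- if ("occp_cod" %in% names(demo)) {
    toupper(trimws(demo$occp_cod))
  } else {
    rep(NA_character_, nrow(demo))
  }
  occp[!occp %in% c("CN", "HP", "LW", "MD", "OT", "PH", "RN")] <- NA_character_

  cases <- data.frame(
    primaryid = demo$primaryid,
    caseid = demo$caseid,
    caseversion = suppressWarnings(as.integer(demo$caseversion)),
    sex = sex,
    age_years = age_years,
    occp_cod = occp,
    event_date = event_date,
    stringsAsFactors = FALSE)
  cases$caseversion[is.na(cases$caseversion)] <- 0L

  drugs <- drug[drug$primaryid %in% keep, , drop = FALSE]
  drugs$drug_seq <- suppressWarnings(as.integer(
    if ("drug_seq" %in% names(drugs)) drugs$drug_seq else drugs$dsg_drug_seq))
  drugs$role_cod <- toupper(trimws(drugs$role_cod))
  drugs <- drugs[drugs$role_cod %in% c("PS", "SS", "C", "I"), , drop = FALSE]
  drugs <- drugs[!duplicated(drugs[c("primaryid", "drug_seq")]), , drop = FALSE]
  rownames(drugs) <- NULL

  reac <- reac[reac$primaryid %in% keep, , drop = FALSE]
  reactions <- data.frame(primaryid = reac$primaryid,
                          pt = trimws(reac$pt), stringsAsFactors = FALSE)
  reactions <- reactions[nzchar(reactions$pt), , drop = FALSE]
  reactions <- reactions[!duplicated(
    data.frame(reactions$primaryid, tolower(reactions$pt))), , drop = FALSE]
  rownames(reactions) <- NULL

  therapy <- NULL
  if (!is.null(ther)) {
    ther <- ther[ther$primaryid %in% keep, , drop = FALSE]
    start <- parse_faers_date(ther$start_dt)
    end <- if ("end_dt" %in% names(ther)) parse_faers_date(ther$end_dt) else
      as.Date(rep(NA, nrow(ther)))
    therapy <- data.frame(
      primaryid = ther$primaryid,
      dsg_drug_seq = suppressWarnings(as.integer(ther$dsg_drug_seq)),
      start_dt = start,
      end_dt = end,
      start_imputed = attr(start, "imputed"),
      invalid = !is.na(start) & !is.na(end) & end < start,
      stringsAsFactors = FALSE)
    rownames(therapy) <- NULL
  }

  structure(list(
    cases = cases, drugs = drugs, reactions = reactions, therapy = therapy,
    log = list(demo_rows_in = n_demo_in,
               duplicates_removed = attr(demo, "removed"),
               cases_out = nrow(cases),
               nonnumeric_versions = attr(demo, "nonnumeric_versions"))),
    class = "faers_cases")
}
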