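# Drug-name normalization and a MedDRA-lite event hierarchy.
#
# Spontaneous reports carry free-text drug names (generic, trade,
# biosimilar-suffixed, arbitrary case and punctuation); analysis needs them
# collapsed onto canonical study drugs.  MedDRA itself is licensed, so the
# package ships a small "MedDRA-lite" table (pt, hlt, hlgt, soc) covering
# the preferred terms the analyses touch, and accepts a user-supplied full
# dictionary in the same 4-column format.

#' Default TNF-alpha blocker drug dictionary
#'
#' Canonical names and synonyms (generic, trade names, biosimilar stems)
#' for the five FDA-approved TNF-alpha blockers.
#'
#' @param path Optional YAML file (`canonical: [synonyms...]`) replacing the
#'   built-in dictionary.
#' @return Named list mapping canonical name to character vector of
#'   synonyms (class `drug_dictionary`).
#' @export
drug_dictionary <- function(path = NULL) {
  if (!is.null(path)) {
    raw <- yaml::read_yaml(path)
    dict <- lapply(raw, as.character)
  } else {
    dict <- list(
      adalimumab = c("humira", "adalimumab-atto", "adalimumab-adbm",
                     "adalimumab-adaz", "adalimumab-bwwd", "adalimumab-afzb",
                     "adalimumab-fkjp", "adalimumab-aqvh", "adalimumab-aacf",
                     "amjevita", "cyltezo", "hyrimoz", "hadlima", "abrilada",
                     "hulio", "yusimry", "idacio", "yuflyma"),
      infliximab = c("remicade", "infliximab-dyyb", "infliximab-abda",
                     "infliximab-qbtx", "infliximab-axxq", "inflectra",
                     "renflexis", "ixifi", "avsola"),
      etanercept = c("enbrel", "etanercept-szzs", "etanercept-ykro",
                     "erelzi", "eticovo"),
      `certolizumab pegol` = c("cimzia", "certolizumab"),
      golimumab = c("simponi", "simponi aria")
    )
  }
  syn <- unlist(dict, use.names = FALSE)
  if (anyDuplicated(tolower(syn))) {
    stop("drug dictionary synonym sets are not pairwise disjoint")
  }
  structure(dict, class = "drug_dictionary")
}

# Canonical string form used for matching: lower case, punctuation
# stripped, whitespace collapsed.
.fold_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[[:punct:]]+", " ", x)
  gsub("\\s+", " ", trimws(x))
}

#' Normalize a free-text drug name to a canonical study drug
#'
#' Matching is case-, whitespace- and punctuation-insensitive against the
#' canonical names and all synonyms; biosimilar suffixes listed in the
#' dictionary match by the same folding. Unmatched names return `NA`
#' (no match), vectorized.
#'
#' @param drugname Character vector of verbatim drug names.
#' @param dict A [drug_dictionary()].
#' @return Character vector of canonical names, `NA` where no match.
#' @export
normalize_drug <- function(drugname, dict = drug_dictionary()) {
  keys <- .fold_name(c(names(dict), unlist(dict, use.names = FALSE)))
  vals <- c(names(dict),
            rep(names(dict), times = lengths(dict)))
  lut <- stats::setNames(vals, keys)
  folded <- .fold_name(drugname)
  out <- unname(lut[folded])
  # biosimilar prefix rule: "<canonical>-xxxx" style names fold to
  # "<canonical> xxxx"; match on the leading canonical token(s)
  miss <- is.na(out) & nzchar(folded)
  if (any(miss)) {
    for (canon in names(dict)) {
      pref <- paste0("^", .fold_name(canon), " ")
      hit <- miss & grepl(pref, folded)
      out[hit] <- canon
      miss <- miss & !hit
    }
  }
  out
}

#' Load a MedDRA-lite hierarchy
#'
#' Reads a 4-column tab-separated table `pt`, `hlt`, `hlgt`, `soc` (one row
#' per preferred term). Lookup is case-insensitive; every PT maps to exactly
#' one SOC.
#'
#' @param path TSV path; default is the dictionary shipped with the package.
#' @return Data.frame with columns pt/hlt/hlgt/soc (class `meddra_lite`).
#' @export
read_meddra <- function(path = system.file("extdata", "meddra_lite.tsv",
                                           package = "faersignal")) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "")
  names(tab) <- tolower(names(tab))
  stopifnot(all(c("pt", "hlt", "hlgt", "soc") %in% names(tab)))
  if (anyDuplicated(tolower(tab$pt))) {
    stop("MedDRA-lite table maps a PT to more than one row")
  }
  structure(tab, class = c("meddra_lite", "data.frame"))
}

#' Look up hierarchy levels for preferred terms
#'
#' @param pt Character vector of PTs (case-insensitive).
#' @param meddra A [read_meddra()] table.
#' @return Data.frame pt/hlt/hlgt/soc, `NA` rows for unknown PTs.
#' @export
meddra_lookup <- function(pt, meddra = read_meddra()) {
  idx <- match(tolower(trimws(pt)), tolower(meddra$pt))
  out <- meddra[idx, c("pt", "hlt", "hlgt", "soc"), drop = FALSE]
  out$query <- pt
  rownames(out) <- NULL
  out
}

#' Build the thrombosis (or any) event PT set
#'
#' Two modes: `"substring"` collects every PT in the hierarchy whose name
#' contains one of the stem strings (case-insensitive; default stem
#' `"thrombo"` — embolism terms are not pulled in unless `"embol"` is added
#' to `stems`); `"explicit"` returns the supplied PT list verbatim.
#'
#' @param meddra A [read_meddra()] hierarchy (used by substring mode).
#' @param mode `"substring"` or `"explicit"`.
#' @param stems Character stems for substring mode.
#' @param pts Explicit PT list for explicit mode.
#' @param name Event-set label.
#' @return List with `name` and `pts` (class `event_set`).
#' @export
build_event_set <- function(meddra = read_meddra(),
                            mode = c("substring", "explicit"),
                            stems = "thrombo", pts = NULL,
                            name = "thrombosis") {
  mode <- match.arg(mode)
  if (mode == "substring") {
    hit <- rep(FALSE, nrow(meddra))
    for (s in stems) hit <- hit | grepl(tolower(s), tolower(meddra$pt),
                                        fixed = TRUE)
    set <- meddra$pt[hit]
  } else {
    set <- unique(as.character(pts))
  }
  if (!length(set)) {
    stop("event set ", sQuote(name), " is empty (mode = ", mode, ")")
  }
  structure(list(name = name, pts = set), class = "event_set")
}

# case-insensitive membership of PTs in an event set
.in_event_set <- function(pt, event_set) {
  if (inherits(event_set, "event_set")) event_set <- event_set$pts
  tolower(trimws(pt)) %in% tolower(trimws(event_set))
}
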