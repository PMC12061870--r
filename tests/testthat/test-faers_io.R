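test_that("read_quarter loads well-formed rows and drops malformed ones", {
  dir <- withr::local_tempdir()
  p <- write_tiny_quarter(
    dir,
    demo_lines = c("PRIMARYID$CASEID$CASEVERSION$SEX",
                   "1001$100$1$F", "1002$101$1$M", "1003$102$1$F"),
    drug_lines = c("PRIMARYID$DRUG_SEQ$ROLE_COD$DRUGNAME",
                   "1001$1$PS$HUMIRA",
                   "1002$1$PS",              # short row: dropped
                   "1003$1$PS$ENBREL"),
    reac_lines = c("PRIMARYID$PT", "1001$Deep vein thrombosis",
                   "1002$Headache", "1003$Nausea"))
  q <- read_quarter(p, quarter_label = "2019Q3")
  expect_s3_class(q, "faers_quarter")
  expect_equal(nrow(q$demo), 3)
  expect_equal(nrow(q$drug), 2)
  expect_equal(q$load_report$drug$malformed, 1)
  expect_equal(q$load_report$demo$malformed, 0)
  expect_named(q$demo, c("primaryid", "caseid", "caseversion", "sex"))
})

test_that("missing mandatory tables and unknown delimiters are fatal", {
  dir <- withr::local_tempdir()
  p <- write_tiny_quarter(dir, c("PRIMARYID$CASEID$CASEVERSION", "1$1$1"),
                          c("PRIMARYID$ROLE_COD", "1$PS"),
                          c("PRIMARYID$PT", "1$Headache"))
  expect_error(read_quarter(p[c("demo", "drug")]), "REAC")
  expect_error(read_quarter(p, delim = ";"), "delimiter")
  expect_error(read_quarter(p, quarter_label = "2019Q5"), "YYYYQn")
})

test_that("write_quarter then read_quarter is the identity on tables", {
  sc <- faers_scenario(n_reports = 300, duplicate_rate = 0.1)
  dir <- withr::local_tempdir()
  g <- generate_faers(sc, seed = 11, dir = dir, quarter_label = "2011Q2")
  q <- read_generated(g$paths, quarter_label = "2011Q2")
  for (tab in c("demo", "drug", "reac", "ther", "outc", "rpsr", "indi")) {
    got <- q[[tab]]
    want <- g$tables[[tab]]
    rownames(want) <- NULL
    expect_equal(got, want, label = tab)
    expect_equal(q$load_report[[tab]]$malformed, 0)
  }
})

test_that("deduplicate keeps the highest version with stated tie-breaks", {
  demo <- data.frame(
    primaryid = c("1001", "1002", "1003", "2001"),
    caseid = c("100", "100", "100", "200"),
    caseversion = c("1", "2", "3", "1"),
    stringsAsFactors = FALSE)
  out <- deduplicate(demo)
  expect_equal(sort(out$primaryid), c("1003", "2001"))
  expect_equal(attr(out, "removed"), 2)

  # ties on version broken by receipt date, then by largest primaryid
  demo2 <- data.frame(
    primaryid = c("11", "12", "13"),
    caseid = "9", caseversion = "2",
    fda_dt = c("20200105", "20200301", "20200301"),
    stringsAsFactors = FALSE)
  expect_equal(deduplicate(demo2)$primaryid, "13")

  # non-numeric version treated as version 0
  demo3 <- data.frame(primaryid = c("21", "22"), caseid = "5",
                      caseversion = c("x", "1"), stringsAsFactors = FALSE)
  out3 <- deduplicate(demo3)
  expect_equal(out3$primaryid, "22")
  expect_equal(attr(out3, "nonnumeric_versions"), 1)
})

test_that("deduplication is idempotent", {
  sc <- faers_scenario(n_reports = 500, duplicate_rate = 0.2)
  g <- generate_faers(sc, seed = 5)
  once <- deduplicate(g$tables$demo)
  twice <- deduplicate(once)
  attr(once, "removed") <- attr(twice, "removed") <- NULL
  attr(once, "removed_primaryids") <- attr(twice, "removed_primaryids") <- NULL
  attr(once, "nonnumeric_versions") <- NULL
  attr(twice, "nonnumeric_versions") <- NULL
  expect_identical(once[order(once$caseid), ], twice[order(twice$caseid), ])
})

test_that("assemble_cases filters superseded reports and converts units", {
  dir <- withr::local_tempdir()
  p <- write_tiny_quarter(
    dir,
    demo_lines = c("PRIMARYID$CASEID$CASEVERSION$SEX$AGE$AGE_COD",
                   "1001$100$1$F$730$DY",    # superseded by 1002
                   "1002$100$2$F$2$YR",
                   "2001$200$1$UNK$5$DEC",
                   "3001$300$1$M$6$MON"),
    drug_lines = c("PRIMARYID$DRUG_SEQ$ROLE_COD$DRUGNAME",
                   "1001$1$PS$HUMIRA", "1002$1$PS$HUMIRA",
                   "2001$1$PS$ENBREL", "3001$1$PS$REMICADE"),
    reac_lines = c("PRIMARYID$PT", "1001$Headache",
                   "1002$Deep vein thrombosis", "2001$Nausea",
                   "3001$Rash"))
  asm <- assemble_cases(read_quarter(p, quarter_label = "2015Q1"))
  expect_equal(nrow(asm$cases), 3)
  expect_false("1001" %in% asm$reactions$primaryid)   # referential filter
  ages <- setNames(asm$cases$age_years, asm$cases$primaryid)
  expect_equal(unname(ages["1002"]), 2)
  expect_equal(unname(ages["2001"]), 50)              # DEC = decades
  expect_equal(unname(ages["3001"]), 0.5)
  sexes <- setNames(asm$cases$sex, asm$cases$primaryid)
  expect_true(is.na(sexes["2001"]))                   # UNK -> missing
  # age 730 with unit days converts to 2 years
  expect_equal(faersignal:::.age_to_years("730", "DY"), 2, tolerance = 1e-3)
})

test_that("partial therapy dates impute to mid-year and mid-month", {
  d <- parse_faers_date(c("20100111", "201003", "2010", "bogus", ""))
  expect_equal(d[1], as.Date("2010-01-11"), ignore_attr = TRUE)
  expect_equal(d[2], as.Date("2010-03-15"), ignore_attr = TRUE)
  expect_equal(d[3], as.Date("2010-07-01"), ignore_attr = TRUE)
  expect_true(all(is.na(d[4:5])))
  expect_equal(attr(d, "imputed"), c(FALSE, TRUE, TRUE, FALSE, FALSE))
})
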