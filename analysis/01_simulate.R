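#!/usr/bin/env Rscript
# Step 1: generate the synthetic FAERS universe the analysis runs on.
#
# The scenario plants, for each of the five TNF-alpha blockers, one
# thrombosis preferred term whose reporting-rate ratio equals the
# published reporting odds ratio for that drug-event pair and whose
# onset times follow the published per-drug Weibull law, on top of a
# shared background of common adverse events.  Files are written in the
# FAERS quarterly ASCII dialect ($-delimited) so every later step
# exercises the real ingestion path.

suppressMessages(library(faersignal))

seed <- 20240401
out_dir <- "results/synthetic_faers"

sc <- study_scenario(n_reports = 30000, duplicate_rate = 0.05)
g <- generate_faers(sc, seed = seed, dir = out_dir, quarter_label = "2024Q1")

cat("Scenario: ", sc$n_reports, "base reports,",
    nrow(sc$planted_pairs), "planted drug-event pairs\n")
print(sc$planted_pairs, row.names = FALSE)
cat("\nWritten to", out_dir, ":\n")
cat(paste(" -", basename(g$paths)), sep = "\n")
cat("\nDuplicate case versions planted:", g$truth$duplicate_versions, "\n")
cat("Realized counts for the planted pairs (a = drug & event reports):\n")
for (rc in g$truth$realized_counts) {
  et <- expected_table(sc, rc$drug, rc$pt)
  cat(sprintf("  %-20s %-28s a=%4d (expected %6.1f)\n",
              rc$drug, rc$pt, rc$a, et$a))
}
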