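#!/usr/bin/env Rscript
# Step 2: ingest the FAERS-dialect files, deduplicate case versions, and
# assemble the normalized case tables used by every downstream step.

suppressMessages(library(faersignal))

in_dir <- "results/synthetic_faers"
out_dir <- "results/cases"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

files <- list.files(in_dir, pattern = "\\.txt$", full.names = TRUE)
paths <- setNames(files, tolower(sub("24Q1\\.txt$", "", basename(files))))
q <- read_quarter(paths, quarter_label = "2024Q1")

cat("Load report (rows read / malformed dropped):\n")
for (tab in names(q$load_report)) {
  cat(sprintf("  %-5s %6d / %d\n", tab, q$load_report[[tab]]$rows,
              q$load_report[[tab]]$malformed))
}

asm <- assemble_cases(q)
asm$drugs$canonical <- normalize_drug(asm$drugs$drugname)

cat("\nDeduplication:", asm$log$demo_rows_in, "DEMO rows ->",
    asm$log$cases_out, "cases (", asm$log$duplicates_removed,
    "superseded versions removed )\n")
canon <- asm$drugs$canonical[asm$drugs$role_cod == "PS"]
cat("PS reports by canonical drug:\n")
print(sort(table(canon, useNA = "ifany"), decreasing = TRUE))

write.csv(asm$cases, file.path(out_dir, "cases.csv"), row.names = FALSE)
write.csv(asm$drugs, file.path(out_dir, "drugs.csv"), row.names = FALSE)
write.csv(asm$reactions, file.path(out_dir, "reactions.csv"),
          row.names = FALSE)
write.csv(asm$therapy, file.path(out_dir, "therapy.csv"), row.names = FALSE)
cat("\nNormalized case tables written under", out_dir, "\n")
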