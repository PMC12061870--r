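#!/usr/bin/env Rscript
# Step 3: disproportionality analysis.  Builds the 2x2 tables for every
# thrombosis PT against the full-database comparator, computes
# ROR/PRR/IC/EBGM with positivity flags, the FDR-adjusted volcano payload,
# the cross-drug heatmap, and the sex/age subgroup tables.

suppressMessages(library(faersignal))

in_dir <- "results/synthetic_faers"
out_dir <- "results/signals"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

files <- list.files(in_dir, pattern = "\\.txt$", full.names = TRUE)
paths <- setNames(files, tolower(sub("24Q1\\.txt$", "", basename(files))))
asm <- assemble_cases(read_quarter(paths, quarter_label = "2024Q1"))
asm$drugs$canonical <- normalize_drug(asm$drugs$drugname)
drugs <- names(drug_dictionary())

# thrombosis event set: every observed PT carrying the stem
pts <- unique(asm$reactions$pt)
thromb <- pts[grepl("thrombo", tolower(pts))]
cat("Thrombosis PTs under study:", paste(thromb, collapse = ", "), "\n\n")

# empirical-Bayes prior fitted over the whole pair universe
univ <- pair_universe(asm)
e <- (univ$a + univ$b) * (univ$a + univ$c) / univ$n
prior <- suppressWarnings(fit_mgps_prior(univ$a[e > 0], e[e > 0], seed = 1))
cat(sprintf("MGPS prior over %d pairs: w=%.3f, (%.3f,%.3f) / (%.3f,%.3f)\n\n",
            nrow(univ), prior$w, prior$alpha1, prior$beta1,
            prior$alpha2, prior$beta2))

strata <- list(stratum(), stratum(sex = "F"), stratum(sex = "M"),
               stratum(age_band = "<18"), stratum(age_band = "18-65"),
               stratum(age_band = ">65"))
signals <- do.call(rbind, lapply(strata, function(st) {
  do.call(rbind, lapply(drugs, function(dd) {
    signal_table(asm, dd, thromb, strat = st, prior = prior)
  }))
}))
overall <- signals$sex == "ALL" & signals$age_band == "ALL"
write.csv(signals[overall, ], file.path(out_dir, "signals.csv"),
          row.names = FALSE)
write.csv(signals[!overall, ], file.path(out_dir, "subgroup.csv"),
          row.names = FALSE)

vol <- do.call(rbind, lapply(drugs, function(dd) {
  part <- signals[overall & signals$drug == dd, ]
  cbind(drug = dd, volcano_payload(part))
}))
write.csv(vol, file.path(out_dir, "volcano.csv"), row.names = FALSE)
hm <- heatmap_payload(signals[overall, ], drugs)
write.csv(as.data.frame(hm), file.path(out_dir, "heatmap.csv"))

pos <- signals[overall & signals$any_positive, ]
cat("Positive signals (any of the four methods), overall population:\n")
print(pos[, c("drug", "pt", "a", "ror", "ror_lo", "ror_hi", "prr",
              "chi2", "ebgm", "ebgm05", "ic", "ic025")],
      row.names = FALSE, digits = 3)
cat("\nSubgroup-only positives (not flagged in the overall population):\n")
sub_pos <- signals[!overall & signals$any_positive, ]
key <- paste(sub_pos$drug, sub_pos$pt)
print(sub_pos[!key %in% paste(pos$drug, pos$pt),
              c("drug", "pt", "sex", "age_band", "a", "ror")],
      row.names = FALSE, digits = 3)
cat("\nPayloads written under", out_dir, "\n")
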