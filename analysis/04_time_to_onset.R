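#!/usr/bin/env Rscript
# Step 4: time-to-onset analysis.  Induction times from therapy start to
# event for each drug's thrombosis reports, distribution summaries,
# normality / rank-based group comparisons, and the Weibull shape test
# classifying each drug's onset hazard.

suppressMessages(library(faersignal))

in_dir <- "results/synthetic_faers"
out_dir <- "results/tto"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

files <- list.files(in_dir, pattern = "\\.txt$", full.names = TRUE)
paths <- setNames(files, tolower(sub("24Q1\\.txt$", "", basename(files))))
asm <- assemble_cases(read_quarter(paths, quarter_label = "2024Q1"))
asm$drugs$canonical <- normalize_drug(asm$drugs$drugname)
drugs <- names(drug_dictionary())

pts <- unique(asm$reactions$pt)
thromb <- pts[grepl("thrombo", tolower(pts))]

tto <- do.call(rbind, lapply(drugs, function(dd) {
  compute_tto(asm, dd, thromb)
}))
write.csv(tto, file.path(out_dir, "tto.csv"), row.names = FALSE)

cat("Induction-time summaries (days):\n")
summ <- do.call(rbind, lapply(split(tto$tto_days, tto$drug), function(x) {
  as.data.frame(summarize_tto(x))
}))
summ <- cbind(drug = rownames(summ), summ)
print(summ, row.names = FALSE)
write.csv(summ, file.path(out_dir, "tto_summary.csv"), row.names = FALSE)

cmp <- group_comparisons(tto, nsim = 2000, seed = 20240401)
cat("\nNormality (Lilliefors KS, Monte-Carlo p) by drug:\n")
print(round(cmp$ks, 4))
cat(sprintf("\nKruskal-Wallis: H = %.3f, p = %.3g\n", cmp$kw_H, cmp$kw_p))
cat("Pairwise Wilcoxon (Bonferroni-adjusted p):\n")
print(round(cmp$pairwise, 4))
jsonlite::write_json(list(ks_p = as.list(cmp$ks), kw_H = cmp$kw_H,
                          kw_p = cmp$kw_p,
                          pairwise = as.data.frame(cmp$pairwise)),
                     file.path(out_dir, "comparisons.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE,
                     na = "null")

cat("\nWeibull shape test (planted truth: the published per-drug law):\n")
wb <- do.call(rbind, lapply(drugs, function(dd) {
  x <- tto$tto_days[tto$drug == dd]
  if (length(x) < 10) return(NULL)
  f <- fit_weibull(x)
  data.frame(drug = dd, n = f$n, shape = f$shape,
             shape_lo = f$shape_ci[1], shape_hi = f$shape_ci[2],
             scale = f$scale, scale_lo = f$scale_ci[1],
             scale_hi = f$scale_ci[2], type = f$failure_type)
}))
print(wb, row.names = FALSE, digits = 3)
write.csv(wb, file.path(out_dir, "weibull.csv"), row.names = FALSE)
cat("\nNote: per-drug onset samples mix the planted Weibull pair with\n")
cat("background thrombosis PTs (uniform onsets), so fitted shapes sit\n")
cat("between the planted value and 1; the planted pair alone is isolated\n")
cat("in weibull_planted.csv.\n")

pp <- study_scenario()$planted_pairs
wbp <- do.call(rbind, lapply(seq_len(nrow(pp)), function(i) {
  rec <- compute_tto(asm, pp$drug[i], pp$pt[i])
  if (nrow(rec) < 10) return(NULL)
  f <- fit_weibull(rec$tto_days)
  data.frame(drug = pp$drug[i], pt = pp$pt[i], n = f$n,
             shape = f$shape, shape_lo = f$shape_ci[1],
             shape_hi = f$shape_ci[2], planted_shape = pp$shape[i],
             scale = f$scale, planted_scale = pp$scale[i],
             type = f$failure_type)
}))
cat("\nPlanted pairs only:\n")
print(wbp, row.names = FALSE, digits = 3)
write.csv(wbp, file.path(out_dir, "weibull_planted.csv"), row.names = FALSE)
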