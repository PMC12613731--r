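#!/usr/bin/env Rscript
# Stage 3: out-of-sample calibration and centile scoring.
#
# For each simulated clinical study, estimates the study-specific offsets
# (dmu, dsigma, dnu per region) by maximum likelihood from that study's
# cognitively normal controls, then scores every subject in the study as an
# age-, sex- and eTIV-adjusted centile. Also writes one individual-level
# report for the most affected AD case, the package's analogue of a
# single-subject chart readout.

suppressPackageStartupMessages(library(regionchart))

model <- read_model_set("results/reference_model.json")
for (tag in c("AD", "bvFTD", "PPAPNFA")) {
  st <- read_cohort_csv(sprintf("results/study_%s_long.csv", tag),
                        sprintf("results/study_%s_meta.csv", tag))
  ctrl <- subset_cohort(st,
                        st$metadata$subject[st$metadata$diagnosis == "CN"])
  offs <- estimate_study_offsets(model, ctrl)
  write_study_offsets(offs, sprintf("results/offsets_%s.json", tag))
  cents <- score_centiles(model, offs, st)
  write.csv(cents, sprintf("results/centiles_%s.csv", tag),
            row.names = FALSE)
  message(sprintf("%s: calibrated on %d controls; scored %d subjects x %d regions",
                  tag, offs$n_controls, length(unique(cents$subject)),
                  length(unique(cents$region))))
}

cents <- read.csv("results/centiles_AD.csv")
meta <- read.csv("results/study_AD_meta.csv")
cases <- meta$subject[meta$diagnosis != "CN"]
sig <- intersect(ad_signature_regions(), unique(cents$region))
mean_sig <- tapply(cents$centile[cents$region %in% sig & cents$subject %in% cases],
                   cents$subject[cents$region %in% sig & cents$subject %in% cases],
                   mean)
worst <- names(which.min(mean_sig))
rep <- render_individual_report(cents, worst,
                                csv_path = "results/report_worst_case.csv",
                                text_path = "results/report_worst_case.txt")
message(sprintf("individual report for %s (mean signature centile %.1f): %d flagged regions",
                worst, min(mean_sig), sum(rep$table$flag %in% c("low", "very_low"))))
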