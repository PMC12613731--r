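#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study system.
#
# Builds (i) a four-batch lifespan reference population with known per-batch
# offsets and (ii) three clinical case/control studies (AD-like, bvFTD-like,
# PPA-PNFA-like) from the same generative truth, each on its own "scanner"
# with fresh study offsets. Writes everything under results/ as CSV; the
# ground truth's key parameters are saved as JSON for later comparison.

suppressPackageStartupMessages(library(regionchart))
dir.create("results", showWarnings = FALSE)

SEED <- 20260101L
truth <- generative_truth(SEED, n_batches = 4)

ref <- generate_reference_population(
  simulation_config(n_batches = 4, n_per_batch = 5000,
                    age_range = c(20, 95), seed = SEED + 1L),
  truth)$cohort
write_cohort_csv(ref, "results/reference_long.csv", "results/reference_meta.csv")
message(sprintf("reference: %d subjects across %d batches",
                n_subjects(ref), length(unique(ref$metadata$batch))))

studies <- list(
  AD = simulation_config(pattern = "AD", n_cases = 150, n_controls = 300,
                         age_range = c(55, 88), case_age_shift = 8,
                         study_label = "studyAD", seed = SEED + 2L),
  bvFTD = simulation_config(pattern = "bvFTD", n_cases = 100,
                            n_controls = 200, age_range = c(50, 85),
                            study_label = "studyFTD", seed = SEED + 3L),
  `PPA-PNFA` = simulation_config(pattern = "PPA-PNFA", n_cases = 80,
                                 n_controls = 160, age_range = c(50, 85),
                                 study_label = "studyPNFA", seed = SEED + 4L))
for (nm in names(studies)) {
  st <- generate_clinical_study(truth, studies[[nm]])
  tag <- gsub("[^A-Za-z]", "", nm)
  write_cohort_csv(st, sprintf("results/study_%s_long.csv", tag),
                   sprintf("results/study_%s_meta.csv", tag))
  message(sprintf("%s study: %d cases / %d controls", nm,
                  sum(st$metadata$diagnosis != "CN"),
                  sum(st$metadata$diagnosis == "CN")))
}

jsonlite::write_json(
  list(seed = SEED,
       patterns = truth$patterns,
       batch_offsets = truth$batch_offsets,
       mmse = truth$mmse, tau_slopes = truth$tau$slopes),
  "results/generative_truth.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
message("wrote results/generative_truth.json")
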