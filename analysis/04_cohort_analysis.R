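#!/usr/bin/env Rscript
# Stage 4: cohort-level statistics over the centile tables.
#
# Reproduces the analysis stack on the synthetic AD study: Euler-index QC
# filtering, Spearman correlations of regional centiles with MMSE (BH across
# regions) and with regional tau uptake, propensity matching of cases to
# controls on age and sex, per-ROI and combined logistic discrimination with
# a DeLong comparison of centile-based vs raw-value models, Youden
# cut-points, and repeated stratified cross-validation. Then contrasts the
# bvFTD-like and AD-like cohorts region by region.

suppressPackageStartupMessages({
  library(regionchart)
  library(dplyr)
  library(tidyr)
})

st <- read_cohort_csv("results/study_AD_long.csv", "results/study_AD_meta.csv")
cents <- as_tibble(read.csv("results/centiles_AD.csv"))
meta <- st$metadata
rois <- intersect(ad_signature_regions(), unique(cents$region))

## QC filter
qc <- euler_mad_filter(st)
message(sprintf("Euler QC: threshold %.1f, excluded %d of %d subjects",
                qc$threshold, nrow(qc$excluded), n_subjects(st)))
write.csv(qc$excluded, "results/qc_excluded.csv", row.names = FALSE)

## MMSE correlations (cases + controls), BH across the analysed regions
mmse <- spearman_fdr(cents, tibble(subject = meta$subject, value = meta$mmse),
                     regions = unique(cents$region))
write.csv(mmse, "results/mmse_spearman.csv", row.names = FALSE)
message(sprintf("MMSE: %d/%d regions BH-significant; top: %s (rho = %.2f)",
                sum(mmse$p_adj < 0.05), nrow(mmse), mmse$region[1],
                mmse$rho[1]))

## tau correlations (hippocampus excluded from the tau family by design)
tau <- spearman_fdr(cents, rename(st$tau, value = "suvr"),
                    regions = intersect(unique(st$tau$region),
                                        unique(cents$region)))
write.csv(tau, "results/tau_spearman.csv", row.names = FALSE)
message(sprintf("tau: rho range [%.2f, %.2f], %d BH-significant",
                min(tau$rho), max(tau$rho), sum(tau$p_adj < 0.05)))

## propensity matching, then discrimination on the matched sample
mres <- propensity_match(meta[meta$diagnosis != "CN",
                              c("subject", "age", "sex")],
                         meta[meta$diagnosis == "CN",
                              c("subject", "age", "sex")], seed = 11)
write.csv(mres$balance, "results/match_balance.csv", row.names = FALSE)
message(sprintf("matched %d pairs; age SMD %.2f -> %.2f",
                nrow(mres$pairs),
                mres$balance$age_smd[mres$balance$stage == "pre"],
                mres$balance$age_smd[mres$balance$stage == "post"]))
keep <- c(mres$pairs$case, mres$pairs$control)

wide_c <- pivot_wider(cents[c("subject", "region", "centile")],
                      names_from = region, values_from = centile) |>
  mutate(label = meta$diagnosis[match(subject, meta$subject)] != "CN") |>
  filter(subject %in% keep)
wide_r <- pivot_wider(
  st$measurements[st$measurements$region %in% rois,
                  c("subject", "region", "value")],
  names_from = region, values_from = value) |>
  mutate(label = meta$diagnosis[match(subject, meta$subject)] != "CN") |>
  filter(subject %in% keep)

disc_c <- discriminate(wide_c, rois)
disc_r <- discriminate(wide_r, rois, mode = "combined")
write.csv(disc_c$per_roi, "results/roi_auc.csv", row.names = FALSE)
message(sprintf("combined AUC: centiles %.3f vs raw %.3f",
                disc_c$combined$summary$auc, disc_r$combined$summary$auc))
stopifnot(identical(wide_c$subject, wide_r$subject))
dl <- delong_compare(disc_c$combined$probabilities,
                     disc_r$combined$probabilities, wide_c$label)
write.csv(dl, "results/delong_centile_vs_raw.csv", row.names = FALSE)
message(sprintf("DeLong: delta = %.3f, Z = %.2f, p = %.2g", dl$delta, dl$z,
                dl$p))

## Youden cut-points per ROI (cases expected at low centiles)
cuts <- bind_rows(lapply(rois, function(rg) {
  cp <- youden_cutpoint(wide_c[[rg]], wide_c$label)
  mutate(cp$optimal, region = rg, .before = 1)
}))
write.csv(cuts, "results/youden_cutpoints.csv", row.names = FALSE)
message(sprintf("optimal cut-points: median %.0fth centile (range %.0f-%.0f)",
                median(cuts$cutpoint), min(cuts$cutpoint),
                max(cuts$cutpoint)))

## repeated stratified cross-validation of the combined model
cv <- repeated_cv(wide_c, rois, k = 10, repeats = 10, seed = 12)
write.csv(cv$per_repeat, "results/cv_repeats.csv", row.names = FALSE)
message(sprintf("10x10 CV: mean AUC %.3f, sens %.2f, spec %.2f",
                cv$summary$mean_auc, cv$summary$mean_sensitivity,
                cv$summary$mean_specificity))

## bvFTD vs AD: which regions separate the two patterns?
cents_ftd <- as_tibble(read.csv("results/centiles_bvFTD.csv"))
meta_ftd <- read.csv("results/study_bvFTD_meta.csv")
bv_cases <- cents_ftd[cents_ftd$subject %in%
                        meta_ftd$subject[meta_ftd$diagnosis != "CN"], ]
ad_cases <- cents[cents$subject %in% meta$subject[meta$diagnosis != "CN"], ]
sep <- bind_rows(lapply(intersect(unique(bv_cases$region),
                                  unique(ad_cases$region)), function(rg) {
  x <- c(bv_cases$centile[bv_cases$region == rg],
         ad_cases$centile[ad_cases$region == rg])
  lab <- rep(c(TRUE, FALSE), c(sum(bv_cases$region == rg),
                               sum(ad_cases$region == rg)))
  tibble(region = rg, auc_directional = auc_score(x, lab),
         separation = abs(auc_score(x, lab) - 0.5))
})) |> arrange(desc(separation))
write.csv(sep, "results/bvftd_vs_ad_regions.csv", row.names = FALSE)
message("top bvFTD-vs-AD separators: ",
        paste(head(sep$region, 3), collapse = ", "))
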