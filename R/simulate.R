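# Seeded synthetic-data generator. The generative family equals the modelling
# family (generalized gamma on log/log/identity links over the same
# age/sex/eTIV basis), so parameter-recovery and calibration tests are
# well-posed; a lognormal toggle provides a misspecified generator for
# robustness checks.

.default_patterns <- function() {
  sig <- ad_signature_regions()
  vols <- c("lh_hippocampus", "rh_hippocampus", "lh_amygdala", "rh_amygdala")
  ad <- tibble::tibble(
    region = sig,
    shift = ifelse(sig %in% vols, -0.30, -0.10))
  frontal <- c("superiorfrontal", "caudalmiddlefrontal", "parsopercularis",
               "lateralorbitofrontal", "rostralmiddlefrontal", "parsorbitalis",
               "parstriangularis", "medialorbitofrontal")
  bv <- tibble::tibble(
    region = c(as.vector(outer(c("lh", "rh"), frontal, paste, sep = "_")),
               vols, "lh_middletemporal", "rh_middletemporal"),
    shift = c(rep(-0.15, 2L * length(frontal)), rep(-0.15, 4L),
              rep(-0.06, 2L)))
  sv_temporal <- c("temporalpole", "entorhinal", "fusiform",
                   "inferiortemporal", "middletemporal", "superiortemporal")
  sv <- tibble::tibble(
    region = c(paste0("lh_", sv_temporal), paste0("rh_", sv_temporal),
               "lh_hippocampus", "lh_amygdala",
               "rh_hippocampus", "rh_amygdala"),
    shift = c(rep(-0.18, length(sv_temporal)),
              rep(-0.08, length(sv_temporal)),
              -0.35, -0.35, -0.15, -0.15))
  pnfa <- tibble::tibble(
    region = c("lh_parstriangularis", "lh_precentral",
               "lh_caudalmiddlefrontal", "lh_parsopercularis"),
    shift = rep(-0.12, 4L))
  list(AD = ad, bvFTD = bv, `PPA-SV` = sv, `PPA-PNFA` = pnfa)
}

#' Ground-truth parameters for the synthetic generator
#'
#' Draws, deterministically from `seed`, per-region lifespan trajectory
#' coefficients for the location, scale and shape of the generative
#' generalized gamma distribution, per-batch study offsets, disease atrophy
#' patterns, and the linkage parameters tying cognition (MMSE) and regional
#' tau uptake to latent centiles.
#'
#' @param seed Master seed; fully determines the truth object.
#' @param n_batches Number of reference batches (site x software-version
#'   labels) for which true offsets are drawn.
#' @param family `"gg"` (default) or `"lognormal"` (misspecification toggle).
#' @param offset_sd_mu,offset_sd_sigma Standard deviations of the per-batch
#'   offsets drawn on the log-mu and log-sigma links (defaults 0.02 and 0.10;
#'   set to 0 for an offset-free reference, which makes study offsets
#'   identifiable against the true trajectory).
#' @return An object of class `generative_truth`.
#' @export
generative_truth <- function(seed = 1L, n_batches = 4L,
                             family = c("gg", "lognormal"),
                             offset_sd_mu = 0.02, offset_sd_sigma = 0.10) {
  family <- match.arg(family)
  cat <- region_catalog()
  r <- nrow(cat)
  withr_seed <- .local_seed(seed)
  on.exit(withr_seed(), add = TRUE)

  thick <- cat$metric == "thickness"
  base_level <- ifelse(thick, stats::runif(r, 2.2, 3.0),
                       ifelse(grepl("hippocampus", cat$region),
                              stats::runif(r, 3900, 4400),
                              stats::runif(r, 1500, 1900)))
  b_t2 <- ifelse(thick, stats::runif(r, -0.030, -0.015),
                 stats::runif(r, -0.060, -0.040))
  # peak ages: thickness in infancy, subcortical volume in adolescence
  t_peak <- ifelse(thick, stats::runif(r, 0.3, 0.8), stats::runif(r, 2.5, 2.9))
  traj <- tibble::tibble(
    region = cat$region, metric = cat$metric,
    b0 = log(base_level),
    b_sex = ifelse(thick, 0.015, 0.05),
    b_t = -2 * b_t2 * t_peak,
    b_t2 = b_t2,
    b_etiv = ifelse(thick, 0, stats::runif(r, 0.6, 0.9)),
    s0 = ifelse(thick, log(0.06), log(0.11)),
    s_t = stats::runif(r, 0.005, 0.02),
    nu = if (family == "gg") stats::runif(r, 0.5, 1.5) else rep(0, r))
  # correct b0 so that base_level is the median at the reference stratum
  # (age 70, female, mean eTIV): b0 is the log-median up to the gg median
  # factor, absorbed later by the model fit, so leave as drawn.

  batches <- sprintf("site%02d_fs%s", seq_len(n_batches),
                     rep(c("6.0", "7.1"), length.out = n_batches))
  offs <- tidyr::expand_grid(batch = batches, region = cat$region)
  offs$dmu <- stats::rnorm(nrow(offs), 0, 1) * offset_sd_mu
  offs$dsigma <- stats::rnorm(nrow(offs), 0, 1) * offset_sd_sigma
  offs$dnu <- 0

  tau_slope <- tibble::tibble(
    region = tau_regions(),
    slope = ifelse(tau_regions() %in%
                     c(temporal_regions(), "lh_amygdala", "rh_amygdala"),
                   -0.5, 0))

  structure(list(
    seed = seed, family = family, catalog = cat, trajectories = traj,
    offset_sd = c(mu = offset_sd_mu, sigma = offset_sd_sigma),
    batch_offsets = offs, patterns = .default_patterns(),
    mmse = list(intercept = stats::qlogis(0.85), slope = 2.5),
    tau = list(base = log(1.25), slopes = tau_slope, noise_sd = 0.2),
    euler = list(meanlog = log(40), sdlog = 0.4,
                 outlier_rate = 0.05, outlier_factor = 6),
    etiv = list(male = list(meanlog = log(1.55e6), sdlog = 0.065),
                female = list(meanlog = log(1.35e6), sdlog = 0.065)),
    basis = list(c_age = 0.75, etiv_center = log(1.45e6))),
    class = "generative_truth")
}

# restores the RNG state on exit so generators are self-contained
.local_seed <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  set.seed(seed)
  function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Simulation configuration
#'
#' @param n_batches Number of reference batches (>= 1).
#' @param n_per_batch Subjects per reference batch.
#' @param age_range Two ages in years within \[0, 100\]; subjects are sampled
#'   uniformly over the range.
#' @param female_prop Proportion of female subjects in \[0, 1\].
#' @param pattern Disease pattern for clinical studies: one of `"none"`,
#'   `"AD"`, `"bvFTD"`, `"PPA-SV"`, `"PPA-PNFA"`; must be `"none"` for
#'   reference populations.
#' @param n_cases,n_controls Clinical study group sizes (>= 0).
#' @param case_age_shift Years by which the case age range is shifted upward
#'   relative to controls (cases are sampled older, to exercise matching).
#' @param study_label Batch id given to a generated clinical study.
#' @param study_offsets Either `NULL` (drawn from the truth's offset prior) or
#'   a list `list(dmu =, dsigma =, dnu =)` applied uniformly to all regions.
#' @param pet_fraction Fraction of clinical-study subjects with tau PET.
#' @param seed Seed for the draw.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_batches = 1L, n_per_batch = 1000L,
                              age_range = c(6, 95), female_prop = 0.5,
                              pattern = "none", n_cases = 0L,
                              n_controls = 0L, case_age_shift = 8,
                              study_label = "study01",
                              study_offsets = NULL, pet_fraction = 0.9,
                              seed = 1L) {
  bad <- function(field, why) stop(sprintf("invalid config: %s %s", field, why),
                                   call. = FALSE)
  if (n_batches < 1L) bad("n_batches", "must be >= 1")
  if (n_per_batch < 1L) bad("n_per_batch", "must be >= 1")
  if (length(age_range) != 2L || any(age_range < 0) || any(age_range > 100) ||
      diff(age_range) <= 0)
    bad("age_range", "must be increasing and within [0, 100]")
  if (female_prop < 0 || female_prop > 1) bad("female_prop", "must be in [0, 1]")
  if (!pattern %in% c("none", "AD", "bvFTD", "PPA-SV", "PPA-PNFA"))
    bad("pattern", "is unknown")
  if (n_cases < 0L) bad("n_cases", "must be >= 0")
  if (n_controls < 0L) bad("n_controls", "must be >= 0")
  structure(list(n_batches = as.integer(n_batches),
                 n_per_batch = as.integer(n_per_batch),
                 age_range = as.numeric(age_range),
                 female_prop = female_prop, pattern = pattern,
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 case_age_shift = case_age_shift,
                 study_label = study_label, study_offsets = study_offsets,
                 pet_fraction = pet_fraction, seed = as.integer(seed)),
            class = "simulation_config")
}

# linear predictors for one region given subject covariates; offsets are
# (dmu, dsigma, dnu) vectors recycled over subjects
.truth_params <- function(truth, region, age, male, etiv,
                          dmu = 0, dsigma = 0, dnu = 0, shift = 0) {
  tr <- truth$trajectories[truth$trajectories$region == region, ]
  t <- log(age + truth$basis$c_age)
  lmu <- tr$b0 + tr$b_sex * male + tr$b_t * t + tr$b_t2 * t^2 + dmu + shift
  if (tr$metric == "volume")
    lmu <- lmu + tr$b_etiv * (log(etiv) - truth$basis$etiv_center)
  lsig <- tr$s0 + tr$s_t * t + dsigma
  list(mu = exp(lmu), sigma = exp(lsig), nu = tr$nu + dnu)
}

.draw_subjects <- function(truth, n, age_range, female_prop, batch) {
  age <- stats::runif(n, age_range[1], age_range[2])
  sex <- ifelse(stats::runif(n) < female_prop, "female", "male")
  et <- truth$etiv
  etiv <- ifelse(sex == "male",
                 stats::rlnorm(n, et$male$meanlog, et$male$sdlog),
                 stats::rlnorm(n, et$female$meanlog, et$female$sdlog))
  tibble::tibble(subject = NA_character_, batch = batch, age = age,
                 sex = sex, etiv = etiv)
}

.draw_measurements <- function(truth, meta, offsets_by_region, shifts) {
  # offsets_by_region: tibble(region, dmu, dsigma, dnu) per subject batch
  # shifts: named per-region log-mu shifts for cases (0-row for controls),
  # scaled per subject by meta$severity (0 for controls)
  cat <- truth$catalog
  male <- as.integer(meta$sex == "male")
  out <- vector("list", nrow(cat))
  for (k in seq_len(nrow(cat))) {
    rg <- cat$region[k]
    off <- offsets_by_region[offsets_by_region$region == rg, ]
    o <- meta_offsets(off, meta$batch)
    sh <- if (rg %in% names(shifts)) shifts[[rg]] else 0
    pr <- .truth_params(truth, rg, meta$age, male, meta$etiv,
                        o$dmu, o$dsigma, o$dnu, sh * meta$severity)
    val <- if (truth$family == "lognormal")
      stats::rlnorm(nrow(meta), log(pr$mu), pr$sigma)
    else rgg(nrow(meta), pr$mu, pr$sigma, pr$nu)
    out[[k]] <- tibble::tibble(subject = meta$subject, region = rg,
                               metric = cat$metric[k], value = val)
  }
  dplyr::bind_rows(out)
}

meta_offsets <- function(off, batch) {
  if (!nrow(off)) return(list(dmu = 0, dsigma = 0, dnu = 0))
  i <- match(batch, off$batch)
  list(dmu = ifelse(is.na(i), 0, off$dmu[i]),
       dsigma = ifelse(is.na(i), 0, off$dsigma[i]),
       dnu = ifelse(is.na(i), 0, off$dnu[i]))
}

#' Generate a reference population with retained ground truth
#'
#' Draws a multi-batch lifespan reference cohort from the generative model:
#' uniform ages over the configured range, Bernoulli sex, sex-dependent
#' lognormal eTIV, and one generalized-gamma draw per subject per region with
#' batch offsets applied on the mu and sigma links.
#'
#' @param config A [simulation_config()] with `pattern = "none"`.
#' @param truth Optional [generative_truth()]; created from `config$seed`
#'   (with `config$n_batches` batches) when missing.
#' @return List with elements `cohort` (a `cohort_table`) and `truth`.
#' @export
generate_reference_population <- function(config, truth = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$pattern != "none")
    stop("invalid config: pattern must be 'none' for a reference population",
         call. = FALSE)
  if (is.null(truth))
    truth <- generative_truth(config$seed, n_batches = config$n_batches)
  restore <- .local_seed(config$seed + 1L)
  on.exit(restore(), add = TRUE)

  batches <- unique(truth$batch_offsets$batch)[seq_len(config$n_batches)]
  meta <- dplyr::bind_rows(lapply(batches, function(b)
    .draw_subjects(truth, config$n_per_batch, config$age_range,
                   config$female_prop, b)))
  meta$subject <- sprintf("ref%06d", seq_len(nrow(meta)))
  meta$severity <- 0
  meas <- .draw_measurements(truth, meta, truth$batch_offsets, list())
  meta$severity <- NULL
  meta$diagnosis <- "CN"
  cohort <- cohort_table(meas, meta,
                         provenance = list(source = "synthetic-reference",
                                           seed = config$seed))
  list(cohort = cohort, truth = truth)
}

#' Generate a clinical case/control study
#'
#' Cases receive the configured pattern's region-specific downward shifts on
#' the log-mu scale and are sampled older than controls. MMSE is generated by
#' binomial thinning of a latent severity that increases with the mean
#' signature-region latent centile; regional tau uptake is generated with a
#' negative linkage to temporal/amygdala centiles for PET-available subjects;
#' the Euler index carries occasional large outliers. A fresh set of
#' study-level batch offsets is applied to every subject.
#'
#' @param truth A [generative_truth()].
#' @param config A [simulation_config()] with `pattern`, `n_cases`,
#'   `n_controls` set.
#' @return A `cohort_table`; its provenance records the true study offsets.
#' @export
generate_clinical_study <- function(truth, config) {
  stopifnot(inherits(truth, "generative_truth"),
            inherits(config, "simulation_config"))
  pat <- config$pattern
  if (!pat %in% c("none", names(truth$patterns)))
    stop(sprintf("unknown pattern '%s'", pat), call. = FALSE)
  if (config$n_cases + config$n_controls == 0L)
    stop("invalid config: n_cases + n_controls must be positive",
         call. = FALSE)
  restore <- .local_seed(config$seed + 2L)
  on.exit(restore(), add = TRUE)
  cat <- truth$catalog

  # study-level offsets: supplied uniform triple, or drawn from the prior
  if (is.null(config$study_offsets)) {
    study_off <- tibble::tibble(
      batch = config$study_label, region = cat$region,
      dmu = stats::rnorm(nrow(cat), 0, 1) * truth$offset_sd[["mu"]],
      dsigma = stats::rnorm(nrow(cat), 0, 1) * truth$offset_sd[["sigma"]],
      dnu = 0)
  } else {
    so <- config$study_offsets
    study_off <- tibble::tibble(
      batch = config$study_label, region = cat$region,
      dmu = so$dmu %||% 0, dsigma = so$dsigma %||% 0, dnu = so$dnu %||% 0)
  }

  ctrl <- if (config$n_controls > 0)
    .draw_subjects(truth, config$n_controls, config$age_range,
                   config$female_prop, config$study_label)
  case_range <- pmin(config$age_range + config$case_age_shift, 100)
  cases <- if (config$n_cases > 0)
    .draw_subjects(truth, config$n_cases, case_range,
                   config$female_prop, config$study_label)
  meta <- dplyr::bind_rows(ctrl, cases)
  meta$subject <- sprintf("sub%05d", seq_len(nrow(meta)))
  meta$is_case <- rep(c(0L, 1L), c(config$n_controls, config$n_cases))
  meta$diagnosis <- ifelse(meta$is_case == 1L,
                           if (pat == "none") "case" else pat, "CN")
  # disease severity varies across cases (mean 1, CV 0.5), scaling every
  # regional shift for that subject; controls are unaffected
  meta$severity <- meta$is_case * stats::rgamma(nrow(meta), 4, 4)

  shifts <- list()
  if (pat != "none" && config$n_cases > 0) {
    p <- truth$patterns[[pat]]
    shifts <- stats::setNames(as.list(p$shift), p$region)
  }
  meas <- .draw_measurements(truth, meta, study_off, shifts)

  # latent centiles wrt the study-offset-adjusted healthy distribution
  male <- as.integer(meta$sex == "male")
  centile_of <- function(region) {
    off <- study_off[study_off$region == region, ]
    pr <- .truth_params(truth, region, meta$age, male, meta$etiv,
                        off$dmu, off$dsigma, off$dnu)
    y <- meas$value[meas$region == region]
    if (truth$family == "lognormal") stats::plnorm(y, log(pr$mu), pr$sigma)
    else pgg(y, pr$mu, pr$sigma, pr$nu)
  }
  sig <- ad_signature_regions()
  sig_cent <- rowMeans(vapply(sig, centile_of, numeric(nrow(meta))))
  p_mmse <- stats::plogis(truth$mmse$intercept +
                            truth$mmse$slope * (sig_cent - 0.5))
  meta$mmse <- stats::rbinom(nrow(meta), 30L, p_mmse)

  base_euler <- round(stats::rlnorm(nrow(meta), truth$euler$meanlog,
                                    truth$euler$sdlog))
  outlier <- stats::runif(nrow(meta)) < truth$euler$outlier_rate
  meta$euler <- as.integer(ifelse(outlier,
                                  base_euler * truth$euler$outlier_factor,
                                  base_euler))

  pet <- stats::runif(nrow(meta)) < config$pet_fraction
  tau <- NULL
  if (any(pet)) {
    sl <- truth$tau$slopes
    tau <- dplyr::bind_rows(lapply(seq_len(nrow(sl)), function(k) {
      cent <- centile_of(sl$region[k])[pet]
      suvr <- exp(truth$tau$base + sl$slope[k] * (cent - 0.5) +
                    stats::rnorm(sum(pet), 0, truth$tau$noise_sd))
      tibble::tibble(subject = meta$subject[pet], region = sl$region[k],
                     suvr = suvr)
    }))
  }
  meta$is_case <- NULL
  meta$severity <- NULL
  cohort_table(meas, meta, tau = tau,
               provenance = list(source = "synthetic-study", pattern = pat,
                                 seed = config$seed,
                                 study_offsets = study_off))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
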