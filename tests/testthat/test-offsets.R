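new_study <- function(n_controls, seed, offsets = NULL, pattern = "none",
                      n_cases = 0) {
  scfg <- simulation_config(pattern = pattern, n_cases = n_cases,
                            n_controls = n_controls, age_range = c(50, 90),
                            study_offsets = offsets, seed = seed)
  generate_clinical_study(demo_truth(), scfg)
}

test_that("null studies recover offsets near zero", {
  ref <- demo_reference()
  st <- new_study(500, 71, offsets = list(dmu = 0, dsigma = 0, dnu = 0))
  offs <- estimate_study_offsets(ref$model, st)
  expect_true(all(offs$offsets$converged))
  # 3 x asymptotic SE of a location shift at n = 500 (sigma ~ 0.07-0.12)
  expect_lt(max(abs(offs$offsets$dmu)), 3 * 0.12 / sqrt(500) + 0.005)
  expect_lt(max(abs(offs$offsets$dsigma)), 3 * sqrt(1 / (2 * 500)) + 0.02)
  expect_false(offs$low_sample_warning)
})

test_that("injected offsets are recovered within the simulation-oracle SD", {
  ref <- demo_reference()
  inj <- list(dmu = 0.05, dsigma = -0.10, dnu = 0)
  est <- t(vapply(1:20, function(s) {
    st <- new_study(200, 700 + s, offsets = inj)
    o <- estimate_study_offsets(ref$model, st)
    r <- o$offsets[o$offsets$region == "lh_hippocampus", ]
    c(r$dmu, r$dsigma)
  }, numeric(2)))
  expect_lt(abs(mean(est[, 1]) - 0.05), sd(est[, 1]))
  expect_lt(abs(mean(est[, 2]) + 0.10), sd(est[, 2]))
})

test_that("control-count thresholds warn at 99 and error below the floor", {
  ref <- demo_reference()
  expect_warning(estimate_study_offsets(ref$model, new_study(99, 72)),
                 "unstable")
  expect_no_warning(estimate_study_offsets(ref$model, new_study(100, 73)))
  expect_error(estimate_study_offsets(ref$model, new_study(9, 74)),
               "hard floor")
})

test_that("calibration refuses mixed batches and non-normal controls", {
  ref <- demo_reference()
  st <- new_study(50, 75)
  st$metadata$batch[1] <- "other_site"
  expect_error(estimate_study_offsets(ref$model, st), "single batch")
  st2 <- new_study(120, 76, pattern = "AD", n_cases = 30)
  expect_error(estimate_study_offsets(ref$model, st2), "cognitively normal")
})

test_that("a value at the offset-adjusted median scores centile 50", {
  ref <- demo_reference()
  st <- new_study(150, 77)
  offs <- estimate_study_offsets(ref$model, st)
  m <- ref$model$models$lh_entorhinal
  o <- offs$offsets[offs$offsets$region == "lh_entorhinal", ]
  pr <- regionchart:::region_params(m, 64, "male", 1.5e6,
                                    o$dmu, o$dsigma, o$dnu)
  med <- qgg(0.5, pr$mu, pr$sigma, pr$nu)
  probe <- cohort_table(
    tibble::tibble(subject = "p1", region = "lh_entorhinal",
                   metric = "thickness", value = med),
    tibble::tibble(subject = "p1", batch = st$metadata$batch[1], age = 64,
                   sex = "male", etiv = 1.5e6))
  cent <- score_centiles(ref$model, offs, probe)
  expect_equal(cent$centile, 50, tolerance = 1e-8)
})

test_that("centiles match the percentile among simulated same-covariate peers", {
  set.seed(78)
  ref <- demo_reference()
  st <- new_study(150, 78)
  offs <- estimate_study_offsets(ref$model, st)
  m <- ref$model$models$lh_hippocampus
  o <- offs$offsets[offs$offsets$region == "lh_hippocampus", ]
  pr <- regionchart:::region_params(m, 71, "female", 1.42e6,
                                    o$dmu, o$dsigma, o$dnu)
  y <- qgg(0.37, pr$mu, pr$sigma, pr$nu)
  peers <- rgg(5e4, pr$mu, pr$sigma, pr$nu)
  probe <- cohort_table(
    tibble::tibble(subject = "p1", region = "lh_hippocampus",
                   metric = "volume", value = y),
    tibble::tibble(subject = "p1", batch = st$metadata$batch[1], age = 71,
                   sex = "female", etiv = 1.42e6))
  cent <- score_centiles(ref$model, offs, probe)$centile
  expect_lt(abs(cent - 100 * mean(peers <= y)), 0.7)
})

test_that("larger values give strictly larger centiles", {
  ref <- demo_reference()
  st <- new_study(150, 79)
  offs <- estimate_study_offsets(ref$model, st)
  two <- cohort_table(
    tibble::tibble(subject = c("a", "b"), region = "lh_hippocampus",
                   metric = "volume", value = c(3600, 4100)),
    tibble::tibble(subject = c("a", "b"), batch = st$metadata$batch[1],
                   age = 70, sex = "female", etiv = 1.45e6))
  cent <- score_centiles(ref$model, offs, two)
  expect_lt(cent$centile[cent$subject == "a"],
            cent$centile[cent$subject == "b"])
})

test_that("scoring is order-independent and bounded away from 0 and 100", {
  ref <- demo_reference()
  st <- new_study(120, 80)
  offs <- estimate_study_offsets(ref$model, st)
  a <- score_centiles(ref$model, offs, st)
  perm_ids <- rev(st$metadata$subject)
  st2 <- subset_cohort(st, perm_ids)
  st2$metadata <- st2$metadata[match(perm_ids, st2$metadata$subject), ]
  b <- score_centiles(ref$model, offs, st2)
  j <- match(paste(a$subject, a$region), paste(b$subject, b$region))
  expect_false(anyNA(j))
  expect_equal(a$centile, b$centile[j])
  expect_true(all(a$centile >= 0.01 & a$centile <= 99.99))
})

test_that("scoring with mismatched calibration is refused", {
  ref <- demo_reference()
  st <- new_study(120, 81)
  offs <- estimate_study_offsets(ref$model, st)
  st$metadata$batch <- "a_different_scanner"
  expect_error(score_centiles(ref$model, offs, st), "do not match")
  expect_error(score_centiles(ref$model, NULL, st), "calibrate")
})

test_that("held-out controls from a calibrated study have uniform centiles", {
  ref <- demo_reference()
  st <- new_study(2300, 82)
  ids <- st$metadata$subject
  cal <- subset_cohort(st, ids[1:300])
  held <- subset_cohort(st, ids[301:2300])
  offs <- estimate_study_offsets(ref$model, cal)
  cent <- score_centiles(ref$model, offs, held)
  x <- cent$centile[cent$region == "rh_middletemporal"]
  counts <- table(cut(x, seq(0, 100, 10)))
  # binomial 99% band at n = 2000, p = 0.1, widened for calibration noise
  band <- 2.576 * sqrt(2000 * 0.1 * 0.9)
  expect_true(all(abs(counts - 200) <= band + 20))
})

test_that("offset recovery RMSE does not increase with control count", {
  ref <- demo_reference()
  inj <- list(dmu = 0.05, dsigma = -0.10, dnu = 0)
  rmse <- vapply(c(25, 100), function(n) {
    err <- vapply(1:15, function(s) {
      st <- new_study(n, 900 + 37 * n + s, offsets = inj)
      o <- suppressWarnings(estimate_study_offsets(ref$model, st))
      o$offsets$dmu[o$offsets$region == "lh_hippocampus"] - 0.05
    }, numeric(1))
    sqrt(mean(err^2))
  }, numeric(1))
  expect_lte(rmse[2], rmse[1])
})
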