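test_that("analytic gradient matches central differences", {
  set.seed(51)
  n <- 60
  X_mu <- cbind(intercept = 1, sex_male = rbinom(n, 1, 0.5),
                age_p1 = rnorm(n))
  X_sigma <- cbind(intercept = 1, age_p1 = rnorm(n))
  X_nu <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  y <- rgg(n, 3, 0.2, 0.8)
  batch <- rep(c("a", "b", "c"), length.out = n)
  env <- new.env()
  env$X_mu <- X_mu; env$X_sigma <- X_sigma; env$X_nu <- X_nu
  env$logy <- log(y)
  env$pm <- 3L; env$ps <- 2L; env$pn <- 1L
  env$B <- 3L; env$batch_idx <- as.integer(factor(batch))
  env$tau2_mu <- 0.01; env$tau2_sigma <- 0.02
  nll <- regionchart:::.penalized_nll
  grd <- regionchart:::.penalized_grad
  for (i in 1:5) {
    par <- c(log(3) + rnorm(1, 0, 0.1), rnorm(2, 0, 0.05),
             log(0.2) + rnorm(1, 0, 0.1), rnorm(1, 0, 0.02),
             runif(1, -1.5, 1.5), rnorm(6, 0, 0.02))
    expect_equal(unname(grd(par, env)), num_grad(nll, par, env = env),
                 tolerance = 1e-4)
  }
})

test_that("intercept-only fit matches a brute-force grid-search MLE", {
  set.seed(52)
  y <- rgg(200, 3, 0.2, 0.8)
  basis <- list(X_mu = cbind(intercept = rep(1, 200)),
                X_sigma = cbind(intercept = rep(1, 200)),
                X_nu = cbind(intercept = rep(1, 200)))
  fit <- fit_region_model(y, basis)
  # derivative-free nested grid refinement around plausible ranges
  nll_of <- function(lmu, lsig, nu)
    -sum(dgg(y, exp(lmu), exp(lsig), nu, log = TRUE))
  ctr <- c(log(mean(y)), log(sd(y) / mean(y)), 1)
  width <- c(0.3, 0.5, 1.5)
  for (stage in 1:12) {  # slow shrink so the grid can follow the ridge
    gr <- lapply(1:3, function(k)
      seq(ctr[k] - width[k], ctr[k] + width[k], length.out = 13))
    vals <- expand.grid(lmu = gr[[1]], lsig = gr[[2]], nu = gr[[3]])
    nlls <- mapply(nll_of, vals$lmu, vals$lsig, vals$nu)
    ctr <- as.numeric(vals[which.min(nlls), ])
    width <- width / 2.5
  }
  expect_equal(unname(fit$beta_mu), ctr[1], tolerance = 1e-3)
  expect_equal(unname(fit$beta_sigma), ctr[2], tolerance = 1e-3)
  expect_equal(unname(fit$beta_nu), ctr[3], tolerance = 1e-3)
})

test_that("known coefficients are recovered within three asymptotic SEs", {
  set.seed(53)
  n <- 5000
  age <- runif(n, 5, 95)
  sex <- ifelse(runif(n) < 0.5, "female", "male")
  sp <- basis_spec("thickness", mu_powers = c(1, 2), sigma_powers = 1)
  X <- build_design_basis(age, sex, spec = sp)
  beta_mu <- c(1.05, 0.02, 0.03, -0.022)
  beta_sigma <- c(log(0.07), 0.01)
  nu <- 0.9
  y <- rgg(n, exp(drop(X$X_mu %*% beta_mu)),
           exp(drop(X$X_sigma %*% beta_sigma)), nu)
  fit <- fit_region_model(y, X, spec = sp, control = list(se = TRUE))
  est <- c(fit$beta_mu, fit$beta_sigma, fit$beta_nu)
  truth <- c(beta_mu, beta_sigma, nu)
  expect_true(fit$converged)
  expect_true(all(abs(est - truth) <= 3 * fit$se))
})

test_that("single-batch fits pin offsets at zero", {
  ref <- demo_reference()
  m <- ref$model$models$lh_hippocampus
  expect_equal(nrow(m$offsets), 0)
  expect_equal(m$tau2_mu, 0)
  expect_lt(m$tau2_sigma, 1e-4)
  expect_true(m$converged)
})

test_that("offset variance controls shrinkage between zero and per-batch MLEs", {
  set.seed(54)
  n_b <- 400
  batches <- rep(c("b1", "b2", "b3"), each = n_b)
  true_d <- c(b1 = -0.06, b2 = 0.01, b3 = 0.05)
  age <- runif(3 * n_b, 40, 90)
  sp <- basis_spec("thickness", mu_powers = 1)
  X <- build_design_basis(age, rep("female", 3 * n_b), spec = sp)
  lmu <- 1 + 0.01 * log(age + 0.75) + true_d[batches]
  y <- rgg(3 * n_b, exp(lmu), 0.07, 1)

  tiny <- fit_region_model(y, X, batch = batches, spec = sp,
                           control = list(fix_tau = list(tau2_mu = 1e-8,
                                                         tau2_sigma = 1e-8)))
  expect_lt(max(abs(tiny$offsets$dmu)), 1e-3)

  huge <- fit_region_model(y, X, batch = batches, spec = sp,
                           control = list(fix_tau = list(tau2_mu = 1e6,
                                                         tau2_sigma = 1e6)))
  # oracle: the same likelihood parameterized with batch dummy columns
  Xd <- X
  Xd$X_mu <- cbind(Xd$X_mu, b2 = as.integer(batches == "b2"),
                   b3 = as.integer(batches == "b3"))
  Xd$X_sigma <- cbind(Xd$X_sigma, b2 = as.integer(batches == "b2"),
                      b3 = as.integer(batches == "b3"))
  dummy <- fit_region_model(y, Xd, spec = sp)
  lmu_off <- unname(huge$beta_mu["intercept"]) + huge$offsets$dmu
  lmu_dum <- unname(dummy$beta_mu["intercept"]) +
    c(0, unname(dummy$beta_mu[c("b2", "b3")]))
  expect_equal(lmu_off, lmu_dum, tolerance = 1e-3)
})

test_that("the joint objective never decreases across fixed-point iterations", {
  set.seed(55)
  cfg <- simulation_config(n_batches = 3, n_per_batch = 400, seed = 56)
  coh <- generate_reference_population(cfg)$cohort
  m <- fit_reference_model(coh, regions = "lh_inferiorparietal", min_n = 100)
  tr <- m$models[[1]]$obj_trace
  expect_gte(length(tr), 2)
  expect_true(all(diff(tr) >= -1e-6))
})

test_that("fitted offsets recover true batch shifts with multiple batches", {
  truth <- generative_truth(57, n_batches = 3)
  cfg <- simulation_config(n_batches = 3, n_per_batch = 1200, seed = 57)
  coh <- generate_reference_population(cfg, truth)$cohort
  m <- fit_reference_model(coh, regions = "lh_fusiform", min_n = 100)
  fit_off <- m$models[[1]]$offsets
  true_off <- truth$batch_offsets[truth$batch_offsets$region == "lh_fusiform", ]
  j <- match(fit_off$batch, true_off$batch)
  # offsets identified relative to their mean; compare centred values
  expect_equal(unname(fit_off$dmu - mean(fit_off$dmu)),
               unname(true_off$dmu[j] - mean(true_off$dmu[j])),
               tolerance = 0.02)
})

test_that("eTIV changes the conditional location but not the centile", {
  ref <- demo_reference()
  m <- ref$model$models$lh_hippocampus
  p1 <- regionchart:::region_params(m, 70, "female", 1.3e6)
  p2 <- regionchart:::region_params(m, 70, "female", 1.6e6)
  expect_gt(p2$mu, p1$mu)
  y1 <- qgg(0.3, p1$mu, p1$sigma, p1$nu)
  y2 <- qgg(0.3, p2$mu, p2$sigma, p2$nu)
  expect_equal(pgg(y1, p1$mu, p1$sigma, p1$nu),
               pgg(y2, p2$mu, p2$sigma, p2$nu), tolerance = 1e-10)
})

test_that("fractional-polynomial selection is consistent and ties break smaller", {
  set.seed(58)
  # data generated from powers {0.5, 1}
  n <- 4000
  age <- runif(n, 20, 95)
  t <- log(age + 0.75)
  lmu <- 0.4 + 0.35 * sqrt(t) + 0.18 * t - 0.08 * t^2
  y <- rgg(n, exp(lmu), 0.07, 1)
  meta <- tibble::tibble(subject = sprintf("s%04d", 1:n), batch = "b1",
                         age = age, sex = "female", etiv = 1.4e6)
  meas <- tibble::tibble(subject = meta$subject, region = "lh_cuneus",
                         metric = "thickness", value = y)
  coh <- cohort_table(meas, meta)
  cands <- list(1, 2, c(0.5, 1), c(1, 2), c(0.5, 2))
  sel <- select_fp_powers(coh, "lh_cuneus", candidates = cands, min_n = 100)
  tab <- attr(sel, "bic_table")
  true_bic <- tab$bic[tab$powers == "1,2"]
  expect_lte(tab$bic[tab$selected], true_bic + 2)

  # single candidate returned unchanged
  one <- select_fp_powers(coh, "lh_cuneus", candidates = list(c(1, 2)),
                          min_n = 100)
  expect_equal(one$lh_cuneus$mu_powers, c(1, 2))

  # exact BIC tie -> fewer terms, then lexicographic
  rank <- regionchart:::.rank_fp_candidates(
    c(100, 100, 100), list(c(1, 2), 1, 2))
  expect_equal(rank[1], 2L)
  rank2 <- regionchart:::.rank_fp_candidates(c(50, 50), list(2, 1))
  expect_equal(rank2[1], 2L)
})

test_that("reference fitting enforces the minimum sample size", {
  coh <- demo_small_cohort()
  expect_error(fit_reference_model(coh, regions = "lh_cuneus"), "min_n")
})
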