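test_that("AUC equals the brute-force concordant-pair fraction", {
  set.seed(91)
  for (i in 1:10) {
    n <- sample(8:20, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    scores <- sample(1:6, n, replace = TRUE)  # forces ties
    expect_equal(auc_score(scores, labels), auc_brute(scores, labels))
  }
})

test_that("AUC equals the scaled Mann-Whitney U statistic", {
  set.seed(92)
  for (i in 1:10) {
    labels <- c(TRUE, FALSE, runif(30) < 0.4)
    scores <- rnorm(32)
    w <- wilcox.test(scores[labels], scores[!labels], exact = FALSE)
    expect_equal(auc_score(scores, labels),
                 unname(w$statistic) / (sum(labels) * sum(!labels)))
  }
})

test_that("Spearman correlations and BH correction behave as defined", {
  # perfect monotone association
  cent <- tibble::tibble(subject = sprintf("s%02d", 1:20),
                         region = "lh_entorhinal", centile = (1:20) * 4.7)
  out <- tibble::tibble(subject = cent$subject, value = cent$centile^3 + 2)
  res <- spearman_fdr(cent, out, regions = "lh_entorhinal")
  expect_equal(res$rho, 1)

  # BH step-up on the worked 4-p example
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  # monotone in raw p rank order
  set.seed(93)
  p <- runif(15)
  adj <- p.adjust(p, "BH")
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_true(all(adj >= p & adj <= 1))

  expect_error(spearman_fdr(cent, tibble::tibble(subject = cent$subject,
                                                 value = 5),
                            regions = "lh_entorhinal"), "constant")
  expect_error(spearman_fdr(cent[1:2, ], out[1:2, ],
                            regions = "lh_entorhinal"), "fewer than 3")
})

test_that("the tau analysis family excludes the hippocampus", {
  expect_equal(length(tau_regions()), 70)
  expect_false(any(grepl("hippocampus", tau_regions())))
  expect_true(all(c("lh_amygdala", "rh_amygdala") %in% tau_regions()))
  expect_equal(nrow(region_catalog()), 72)
})

test_that("propensity matching pairs nearest neighbours and reports balance", {
  cases <- tibble::tibble(subject = c("c1", "c2"), age = c(70, 80),
                          sex = c("female", "female"))
  controls <- tibble::tibble(subject = c("k1", "k2", "k3"),
                             age = c(69, 81, 50),
                             sex = c("female", "female", "female"))
  m <- propensity_match(cases, controls, seed = 1)
  pairs <- m$pairs[order(m$pairs$case), ]
  expect_equal(pairs$control[pairs$case == "c1"], "k1")
  expect_equal(pairs$control[pairs$case == "c2"], "k2")
  expect_equal(nrow(pairs), 2)
  expect_equal(length(m$unmatched_cases), 0)
})

test_that("identical covariates match perfectly with zero age SMD", {
  set.seed(94)
  cases <- tibble::tibble(subject = sprintf("c%02d", 1:20),
                          age = round(runif(20, 55, 85)),
                          sex = rep(c("female", "male"), 10))
  controls <- cases
  controls$subject <- sprintf("k%02d", 1:20)
  m <- propensity_match(cases, controls, seed = 2)
  expect_equal(nrow(m$pairs), 20)
  post <- m$balance[m$balance$stage == "post", ]
  expect_equal(post$age_smd, 0, tolerance = 1e-12)
  expect_equal(post$female_case, post$female_control)
})

test_that("matching reduces the age imbalance on overlapping cohorts", {
  set.seed(95)
  cases <- tibble::tibble(subject = sprintf("c%03d", 1:100),
                          age = runif(100, 63, 90),
                          sex = ifelse(runif(100) < 0.45, "female", "male"))
  controls <- tibble::tibble(subject = sprintf("k%03d", 1:400),
                             age = runif(400, 55, 85),
                             sex = ifelse(runif(400) < 0.6, "female", "male"))
  m <- propensity_match(cases, controls, seed = 3)
  expect_equal(nrow(m$pairs), 100)  # controls suffice: 1 control per case
  b <- m$balance
  expect_lte(abs(b$age_smd[b$stage == "post"]),
             abs(b$age_smd[b$stage == "pre"]))
  # fewer controls than cases -> partial matching with a warning
  expect_warning(m2 <- propensity_match(cases, controls[1:60, ], seed = 4),
                 "unmatched")
  expect_equal(nrow(m2$pairs), 60)
})

test_that("discrimination handles separation, constants and monotone maps", {
  feats <- tibble::tibble(subject = sprintf("s%02d", 1:16),
                          label = rep(c(TRUE, FALSE), each = 8),
                          roi_a = c(9:16, 1:8),     # perfect separation
                          roi_b = rep(1, 16))       # constant
  d <- discriminate(feats, c("roi_a", "roi_b"))
  expect_equal(d$per_roi$auc[d$per_roi$roi == "roi_a"], 1)
  expect_equal(d$per_roi$auc[d$per_roi$roi == "roi_b"], 0.5)
  # AUC invariant under a monotone transform of the feature
  feats2 <- feats
  feats2$roi_a <- exp(feats2$roi_a / 4)
  d2 <- discriminate(feats2, "roi_a", mode = "per-roi")
  expect_equal(d2$per_roi$auc, 1)
  expect_error(discriminate(feats[feats$label, ], "roi_a"), "both classes")
  # combined model fits all declared ROIs
  expect_equal(sort(names(d$combined$coefficients)),
               sort(c("(Intercept)", "roi_a", "roi_b")))
})

test_that("DeLong comparison is antisymmetric, null on self, and matches pROC", {
  set.seed(96)
  labels <- rep(c(TRUE, FALSE), each = 20)
  a <- rnorm(40) + labels * 1.2
  b <- 0.6 * a + rnorm(40, sd = 0.8)
  self <- delong_compare(a, a, labels)
  expect_equal(self$delta, 0)
  expect_equal(self$z, 0)
  expect_equal(self$p, 1)
  ab <- delong_compare(a, b, labels)
  ba <- delong_compare(b, a, labels)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$delta, -ba$delta)
  expect_error(delong_compare(a, b[1:10], labels), "paired")

  skip_if_not_installed("pROC")
  ra <- pROC::roc(labels, a, quiet = TRUE, direction = "<")
  rb <- pROC::roc(labels, b, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(ab$p, ref$p.value, tolerance = 1e-9)
  expect_equal(ab$z, unname(ref$statistic), tolerance = 1e-9)
})

test_that("Youden cut-point equals the exhaustive scan and breaks ties low", {
  # separable toy: any t in [20, 60) is perfect; lowest candidate returned
  cp <- youden_cutpoint(c(10, 20, 60, 70), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(cp$optimal$cutpoint, 20)
  expect_equal(cp$optimal$sensitivity, 1)
  expect_equal(cp$optimal$specificity, 1)

  set.seed(97)
  scores <- sample(seq(5, 95, 5), 6)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  cp6 <- youden_cutpoint(scores, labels)
  brute <- vapply(sort(unique(scores)), function(t)
    mean(scores[labels] <= t) + mean(scores[!labels] > t) - 1, numeric(1))
  expect_equal(cp6$optimal$youden_j, max(brute))
  expect_equal(cp6$optimal$cutpoint,
               sort(unique(scores))[which.max(brute)])

  # specificity is monotone non-increasing as the threshold rises
  g <- cp6$grid[order(cp6$grid$threshold), ]
  expect_true(all(diff(g$specificity) <= 1e-12))
  expect_error(youden_cutpoint(scores, rep(TRUE, 6)), "both classes")
})

test_that("repeated CV partitions subjects and is seed-deterministic", {
  set.seed(98)
  n <- 120
  feats <- tibble::tibble(subject = sprintf("s%03d", 1:n),
                          label = rep(c(TRUE, FALSE), each = n / 2),
                          f1 = rnorm(n) + rep(c(3.2, 0), each = n / 2),
                          f2 = rnorm(n))
  fold <- regionchart:::stratified_folds(feats$label, 10)
  expect_equal(sort(unique(fold)), 1:10)
  expect_true(max(table(fold)) - min(table(fold)) <= 1)
  by_class <- table(fold, feats$label)
  expect_true(all(apply(by_class, 2, function(x) max(x) - min(x)) <= 1))

  cv1 <- repeated_cv(feats, c("f1", "f2"), k = 10, repeats = 3, seed = 5)
  cv2 <- repeated_cv(feats, c("f1", "f2"), k = 10, repeats = 3, seed = 5)
  expect_identical(cv1$per_repeat, cv2$per_repeat)
  # well-separated features -> near-perfect cross-validated AUC
  expect_gt(cv1$summary$mean_auc, 0.95)
  expect_error(repeated_cv(feats[1:15, ], "f1", k = 10), "n >= 2k")

  # weaker signal: different seeds shuffle folds, results differ but agree
  # within simulation noise
  feats$f1 <- rnorm(n) + rep(c(1, 0), each = n / 2)
  cva <- repeated_cv(feats, c("f1", "f2"), k = 10, repeats = 3, seed = 5)
  cvb <- repeated_cv(feats, c("f1", "f2"), k = 10, repeats = 3, seed = 6)
  expect_false(identical(cva$per_repeat$auc, cvb$per_repeat$auc))
  expect_lt(abs(cva$summary$mean_auc - cvb$summary$mean_auc), 0.1)
})

test_that("the Euler MAD filter reproduces hand-computed exclusions", {
  toy <- tibble::tibble(subject = sprintf("s%d", 1:5),
                        euler = c(10, 12, 14, 16, 100))
  f <- euler_mad_filter(toy)
  expect_equal(f$median, 14)
  expect_equal(f$mad, 2)
  expect_equal(f$threshold, 18)
  expect_equal(f$excluded$subject, "s5")
  expect_equal(nrow(f$kept), 4)

  # degenerate: all equal -> MAD 0, inclusive rule keeps everyone
  same <- tibble::tibble(subject = sprintf("s%d", 1:4), euler = rep(7, 4))
  f2 <- euler_mad_filter(same)
  expect_equal(nrow(f2$excluded), 0)
  expect_equal(nrow(f2$kept), 4)
  # strict toggle drops everyone in the degenerate case
  f3 <- euler_mad_filter(same, strict = TRUE)
  expect_equal(nrow(f3$kept), 0)

  within <- tibble::tibble(subject = sprintf("s%d", 1:4),
                           euler = c(10, 11, 12, 13))
  expect_equal(nrow(euler_mad_filter(within)$excluded), 0)
  miss <- tibble::tibble(subject = c("a", "b"), euler = c(1, NA))
  expect_error(euler_mad_filter(miss), "b")
})
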