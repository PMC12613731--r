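# Shared fixtures, built lazily once per test run. All seeded.

.fixture_cache <- new.env()

memo_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# offset-free single-batch truth: study offsets identifiable against it
demo_truth <- function() {
  memo_fixture("truth", generative_truth(401, n_batches = 1,
                                         offset_sd_mu = 0,
                                         offset_sd_sigma = 0))
}

demo_regions <- c("lh_hippocampus", "lh_entorhinal", "rh_middletemporal")

demo_reference <- function() {
  memo_fixture("reference", {
    cfg <- simulation_config(n_batches = 1, n_per_batch = 6000,
                             age_range = c(45, 95), seed = 402)
    rp <- generate_reference_population(cfg, demo_truth())
    model <- fit_reference_model(rp$cohort, regions = demo_regions,
                                 min_n = 100)
    list(cohort = rp$cohort, model = model)
  })
}

# small cohort for io round-trips
demo_small_cohort <- function() {
  memo_fixture("small_cohort", {
    cfg <- simulation_config(n_batches = 1, n_per_batch = 3,
                             age_range = c(50, 80), seed = 403)
    generate_reference_population(cfg, demo_truth())$cohort
  })
}

# central-difference numeric gradient
num_grad <- function(f, x, eps = 1e-6, ...) {
  vapply(seq_along(x), function(i) {
    h <- numeric(length(x)); h[i] <- eps
    (f(x + h, ...) - f(x - h, ...)) / (2 * eps)
  }, numeric(1))
}

# brute-force AUC: concordant-pair fraction with ties counted 1/2
auc_brute <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}
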