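# Cohort-level analysis stack over centile tables: Spearman + BH, propensity
# matching, AUC/DeLong discrimination, Youden cut-points, repeated stratified
# CV, and Euler-index QC filtering. AUC and the DeLong variance are computed
# from midrank placements (tie-aware); base R supplies the standard tests.

#' Mann-Whitney AUC of a score against binary labels
#'
#' Tie-aware (midrank) probability that a random positive scores higher than
#' a random negative.
#'
#' @param scores Numeric scores.
#' @param labels Logical/0-1 labels (`TRUE` = positive).
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes required", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# midrank placements: for each positive, fraction of negatives it beats, and
# vice versa (DeLong's V10 / V01 components)
.placements <- function(scores, labels) {
  labels <- as.logical(labels)
  x <- scores[labels]; y <- scores[!labels]
  n1 <- length(x); n0 <- length(y)
  r_all <- rank(c(x, y))
  v10 <- (r_all[seq_len(n1)] - rank(x)) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - rank(y)) / n1
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Spearman correlations with Benjamini-Hochberg correction across regions
#'
#' Correlates each region's centile scores with a per-subject outcome using
#' midrank Spearman correlation, then applies BH step-up across exactly the
#' analysed regions.
#'
#' @param centiles A `centile_table` (long tibble with `subject`, `region`,
#'   `centile`).
#' @param outcome Tibble with columns `subject` and `value` (e.g. MMSE, or a
#'   regional tau value when `by_region` pairing is supplied via a `region`
#'   column).
#' @param regions Regions to analyse (defines the BH family size `m`).
#' @return Tibble of class rows: `region`, `rho`, `p`, `p_adj`, `n`, sorted
#'   by adjusted p.
#' @export
spearman_fdr <- function(centiles, outcome, regions = NULL) {
  outcome <- tibble::as_tibble(outcome)
  by_region <- "region" %in% names(outcome)
  if (is.null(regions)) regions <- unique(centiles$region)
  if (stats::sd(outcome$value, na.rm = TRUE) == 0)
    stop("outcome is constant; correlation undefined", call. = FALSE)
  rows <- lapply(regions, function(rg) {
    cc <- centiles[centiles$region == rg, c("subject", "centile")]
    oo <- if (by_region) outcome[outcome$region == rg,
                                 c("subject", "value")] else outcome
    j <- dplyr::inner_join(cc, oo, by = "subject")
    j <- j[stats::complete.cases(j[c("centile", "value")]), ]
    if (nrow(j) < 3L)
      stop(sprintf("fewer than 3 complete pairs for region %s", rg),
           call. = FALSE)
    ct <- suppressWarnings(stats::cor.test(j$centile, j$value,
                                           method = "spearman",
                                           exact = FALSE))
    tibble::tibble(region = rg, rho = unname(ct$estimate),
                   p = ct$p.value, n = nrow(j))
  })
  res <- dplyr::bind_rows(rows)
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res[order(res$p_adj, res$p, res$region), c("region", "rho", "p", "p_adj", "n")]
}

#' Nearest-neighbour propensity-score matching on age and sex
#'
#' Fits a logistic propensity model (case ~ age + sex), then greedily matches
#' each case (processed in descending propensity order) to the nearest unused
#' control on the linear propensity score, 1:1 without replacement. Balance
#' diagnostics before and after: standardized mean difference for age,
#' chi-squared test for sex, Mann-Whitney U test for age.
#'
#' @param cases,controls Tibbles with `subject`, `age`, `sex`.
#' @param seed Seed controlling tie-breaks among equidistant controls.
#' @return List of class `match_result`: `pairs` (tibble `case`, `control`,
#'   `distance`), `unmatched_cases`, and `balance` (pre/post diagnostics).
#' @export
propensity_match <- function(cases, controls, seed = 1L) {
  cases <- tibble::as_tibble(cases); controls <- tibble::as_tibble(controls)
  if (!nrow(cases) || !nrow(controls))
    stop("both groups must be non-empty", call. = FALSE)
  stacked <- dplyr::bind_rows(
    dplyr::mutate(cases, .case = 1L), dplyr::mutate(controls, .case = 0L))
  if (anyNA(stacked[c("age", "sex")]))
    stop("age and sex must be complete", call. = FALSE)
  stacked$.male <- as.integer(stacked$sex == "male")
  fit <- stats::glm(.case ~ age + .male,
                    family = stats::binomial(), data = stacked)
  lp <- stats::predict(fit, type = "link")
  lp_case <- lp[stacked$.case == 1L]; lp_ctrl <- lp[stacked$.case == 0L]

  restore <- .local_seed(seed)
  on.exit(restore(), add = TRUE)
  ctrl_order <- sample.int(length(lp_ctrl))  # seeded tie-break order
  available <- rep(TRUE, length(lp_ctrl))
  case_order <- order(lp_case, decreasing = TRUE)
  pairs <- vector("list", length(case_order))
  for (ci in case_order) {
    if (!any(available)) break
    cand <- which(available)
    d <- abs(lp_ctrl[cand] - lp_case[ci])
    best <- cand[ctrl_order[cand] == min(ctrl_order[cand][d == min(d)])]
    best <- best[which.min(abs(lp_ctrl[best] - lp_case[ci]))]
    available[best] <- FALSE
    pairs[[ci]] <- tibble::tibble(case = cases$subject[ci],
                                  control = controls$subject[best],
                                  distance = abs(lp_ctrl[best] - lp_case[ci]))
  }
  pairs <- dplyr::bind_rows(pairs)
  unmatched <- setdiff(cases$subject, pairs$case)
  if (length(unmatched))
    warning(sprintf("%d case(s) unmatched (controls exhausted)",
                    length(unmatched)), call. = FALSE)

  balance_of <- function(case_df, ctrl_df) {
    smd <- (mean(case_df$age) - mean(ctrl_df$age)) /
      sqrt((stats::var(case_df$age) + stats::var(ctrl_df$age)) / 2)
    sex_tab <- table(factor(c(case_df$sex, ctrl_df$sex),
                            levels = c("female", "male")),
                     rep(c("case", "control"),
                         c(nrow(case_df), nrow(ctrl_df))))
    chi_p <- if (any(rowSums(sex_tab) == 0)) 1 else
      suppressWarnings(stats::chisq.test(sex_tab)$p.value)
    mw_p <- suppressWarnings(
      stats::wilcox.test(case_df$age, ctrl_df$age)$p.value)
    tibble::tibble(age_smd = smd,
                   female_case = mean(case_df$sex == "female"),
                   female_control = mean(ctrl_df$sex == "female"),
                   sex_chisq_p = chi_p, age_mw_p = mw_p)
  }
  post_cases <- cases[match(pairs$case, cases$subject), ]
  post_ctrl <- controls[match(pairs$control, controls$subject), ]
  balance <- dplyr::bind_rows(
    dplyr::mutate(balance_of(cases, controls), stage = "pre"),
    dplyr::mutate(balance_of(post_cases, post_ctrl), stage = "post"))
  structure(list(pairs = pairs, unmatched_cases = unmatched,
                 balance = balance[c("stage", "age_smd", "female_case",
                                     "female_control", "sex_chisq_p",
                                     "age_mw_p")]),
            class = "match_result")
}

#' Per-ROI and combined logistic discrimination
#'
#' Fits a logistic regression per region of interest (and, in combined mode,
#' one model over all ROIs jointly), reporting the AUC of the fitted
#' probabilities with a DeLong confidence interval.
#'
#' @param features Tibble: one row per subject, columns `subject`, `label`
#'   (logical/0-1), plus one column per ROI.
#' @param roi_set Character vector of feature column names.
#' @param mode `"per-roi"`, `"combined"`, or `"both"`.
#' @return List of class `discrimination_result`: `per_roi` tibble
#'   (`roi`, `auc`, `ci_lo`, `ci_hi`, `converged`), `combined` (one-row tibble
#'   plus `coefficients` and training `loglik`).
#' @export
discriminate <- function(features, roi_set,
                         mode = c("both", "per-roi", "combined")) {
  mode <- match.arg(mode)
  features <- tibble::as_tibble(features)
  y <- as.integer(as.logical(features$label))
  if (length(unique(y)) != 2L)
    stop("both classes must be present", call. = FALSE)
  missing_roi <- setdiff(roi_set, names(features))
  if (length(missing_roi))
    stop("missing feature column(s): ", paste(missing_roi, collapse = ", "),
         call. = FALSE)
  auc_ci <- function(scores) {
    pl <- .placements(scores, y == 1L)
    v <- stats::var(pl$v10) / length(pl$v10) +
      stats::var(pl$v01) / length(pl$v01)
    se <- sqrt(v)
    c(auc = pl$auc, lo = max(0, pl$auc - 1.96 * se),
      hi = min(1, pl$auc + 1.96 * se))
  }
  per_roi <- NULL
  if (mode %in% c("both", "per-roi")) {
    per_roi <- dplyr::bind_rows(lapply(roi_set, function(r) {
      fit <- suppressWarnings(
        stats::glm(y ~ x, family = stats::binomial(),
                   data = data.frame(y = y, x = features[[r]])))
      a <- auc_ci(stats::fitted(fit))
      tibble::tibble(roi = r, auc = a[["auc"]], ci_lo = a[["lo"]],
                     ci_hi = a[["hi"]], converged = fit$converged)
    }))
  }
  combined <- NULL
  if (mode %in% c("both", "combined")) {
    X <- as.data.frame(features[roi_set])
    fit <- suppressWarnings(
      stats::glm(y ~ ., family = stats::binomial(),
                 data = cbind(y = y, X)))
    a <- auc_ci(stats::fitted(fit))
    combined <- list(
      summary = tibble::tibble(auc = a[["auc"]], ci_lo = a[["lo"]],
                               ci_hi = a[["hi"]], converged = fit$converged),
      coefficients = stats::coef(fit),
      loglik = as.numeric(stats::logLik(fit)),
      probabilities = stats::fitted(fit))
  }
  structure(list(roi_set = roi_set, per_roi = per_roi, combined = combined,
                 direction = "higher score = case"),
            class = "discrimination_result")
}

#' DeLong paired comparison of two AUCs
#'
#' Compares correlated AUCs computed from two score vectors on the same
#' subjects, using the paired DeLong variance from midrank placements.
#'
#' @param scores_a,scores_b Paired score vectors (same subjects, same order).
#' @param labels Binary labels.
#' @param conf_level Confidence level for the AUC-difference interval.
#' @return Tibble: `auc_a`, `auc_b`, `delta`, `z`, `p`, `ci_lo`, `ci_hi`.
#' @export
delong_compare <- function(scores_a, scores_b, labels, conf_level = 0.95) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("scores_a, scores_b and labels must be paired (equal length)",
         call. = FALSE)
  labels <- as.logical(labels)
  pa <- .placements(scores_a, labels)
  pb <- .placements(scores_b, labels)
  n1 <- length(pa$v10); n0 <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  delta <- pa$auc - pb$auc
  se <- sqrt(max(var_delta, 0))
  z <- if (se == 0) 0 else delta / se
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(auc_a = pa$auc, auc_b = pb$auc, delta = delta, z = z,
                 p = if (se == 0 && delta == 0) 1 else 2 * stats::pnorm(-abs(z)),
                 ci_lo = delta - q * se, ci_hi = delta + q * se)
}

#' Youden-index optimal centile cut-point
#'
#' Classifies subjects positive when their score falls at or below a
#' threshold (cases are expected at low centiles), scans all observed scores
#' as candidate thresholds, and returns the maximizer of Youden's J
#' (sensitivity + specificity - 1), breaking ties at the lowest threshold.
#' Sensitivity/specificity at a fixed grid of centile thresholds is also
#' reported.
#'
#' @param scores Centile scores.
#' @param labels Binary labels (`TRUE` = case).
#' @param grid Fixed thresholds to tabulate (default 1, 5, 10, ..., 50).
#' @return List of class `cutpoint_result`: `optimal` (one-row tibble
#'   `cutpoint`, `sensitivity`, `specificity`, `youden_j`) and `grid` tibble.
#' @export
youden_cutpoint <- function(scores, labels,
                            grid = c(1, 5, 10, 20, 30, 40, 50)) {
  labels <- as.logical(labels)
  if (length(unique(labels)) != 2L)
    stop("both classes must be present", call. = FALSE)
  sens_spec <- function(t) {
    pos <- scores <= t
    c(sens = mean(pos[labels]), spec = mean(!pos[!labels]))
  }
  cand <- sort(unique(scores))
  ss <- vapply(cand, sens_spec, numeric(2))
  j <- ss["sens", ] + ss["spec", ] - 1
  best <- which(j == max(j))[1]  # candidates sorted ascending: lowest t wins
  grid_ss <- vapply(grid, sens_spec, numeric(2))
  structure(list(
    optimal = tibble::tibble(cutpoint = cand[best],
                             sensitivity = unname(ss["sens", best]),
                             specificity = unname(ss["spec", best]),
                             youden_j = unname(j[best])),
    grid = tibble::tibble(threshold = grid,
                          sensitivity = unname(grid_ss["sens", ]),
                          specificity = unname(grid_ss["spec", ]))),
    class = "cutpoint_result")
}

# stratified fold assignment: shuffles within class, concatenates class
# blocks, and deals fold labels cyclically, so per-class counts and total
# fold sizes both differ by at most one
stratified_folds <- function(labels, k) {
  labels <- as.logical(labels)
  idx <- c(sample(which(labels)), sample(which(!labels)))
  folds <- rep(seq_len(k), length.out = length(idx))
  out <- integer(length(labels))
  out[idx] <- folds
  out
}

#' Repeated stratified k-fold cross-validation of a logistic model
#'
#' Refits the combined logistic model on each training fold, pools
#' out-of-fold probabilities within each repeat for the AUC, and reports
#' sensitivity/specificity at probability 0.5 averaged over repeats.
#'
#' @param features As in [discriminate()].
#' @param roi_set Feature columns for the combined model.
#' @param k Number of folds (default 10).
#' @param repeats Number of independent shuffles (default 10).
#' @param seed Seed; the result is fully deterministic given it.
#' @return List of class `cv_result`: `per_repeat` tibble (`repeat`, `auc`,
#'   `sensitivity`, `specificity`) and `summary` (means).
#' @export
repeated_cv <- function(features, roi_set, k = 10L, repeats = 10L,
                        seed = 1L) {
  features <- tibble::as_tibble(features)
  y <- as.integer(as.logical(features$label))
  n <- length(y)
  if (n < 2L * k) stop("need n >= 2k subjects", call. = FALSE)
  if (min(table(y)) < k)
    stop("each class needs at least k members for stratified folds",
         call. = FALSE)
  X <- as.data.frame(features[roi_set])
  restore <- .local_seed(seed)
  on.exit(restore(), add = TRUE)
  rows <- lapply(seq_len(repeats), function(r) {
    fold <- stratified_folds(y == 1L, k)
    prob <- rep(NA_real_, n)
    for (f in seq_len(k)) {
      tr <- fold != f
      if (length(unique(y[tr])) != 2L)
        stop("a training fold lost a class", call. = FALSE)
      fit <- suppressWarnings(
        stats::glm(y ~ ., family = stats::binomial(),
                   data = cbind(y = y[tr], X[tr, , drop = FALSE])))
      prob[!tr] <- stats::predict(fit, newdata = X[!tr, , drop = FALSE],
                                  type = "response")
    }
    pred <- prob >= 0.5
    tibble::tibble(rep = r, auc = auc_score(prob, y == 1L),
                   sensitivity = mean(pred[y == 1L]),
                   specificity = mean(!pred[y == 0L]))
  })
  per_repeat <- dplyr::bind_rows(rows)
  structure(list(
    k = k, repeats = repeats, seed = seed, per_repeat = per_repeat,
    summary = tibble::tibble(mean_auc = mean(per_repeat$auc),
                             mean_sensitivity = mean(per_repeat$sensitivity),
                             mean_specificity = mean(per_repeat$specificity))),
    class = "cv_result")
}

#' Euler-index quality-control filter
#'
#' Keeps subjects whose Euler index is at most the study median plus two
#' (unscaled) median absolute deviations. The boundary is inclusive so the
#' rule stays defined when the MAD is zero; set `strict = TRUE` for a strict
#' inequality.
#'
#' @param cohort A `cohort_table` (or tibble) with complete `euler` values.
#' @param n_mad Multiplier on the MAD (default 2).
#' @param strict Use `<` instead of `<=` at the boundary.
#' @return List: `kept` (filtered cohort, same class as input), `excluded`
#'   tibble (`subject`, `euler`), `median`, `mad`, `threshold`.
#' @export
euler_mad_filter <- function(cohort, n_mad = 2, strict = FALSE) {
  meta <- if (inherits(cohort, "cohort_table")) cohort$metadata
  else tibble::as_tibble(cohort)
  if (!"euler" %in% names(meta) || anyNA(meta$euler))
    stop("missing Euler values for subject(s): ",
         paste(meta$subject[if ("euler" %in% names(meta))
           is.na(meta$euler) else TRUE], collapse = ", "), call. = FALSE)
  med <- stats::median(meta$euler)
  mad_u <- stats::median(abs(meta$euler - med))  # unscaled MAD
  thr <- med + n_mad * mad_u
  keep <- if (strict) meta$euler < thr else meta$euler <= thr
  kept <- if (inherits(cohort, "cohort_table"))
    subset_cohort(cohort, meta$subject[keep]) else meta[keep, ]
  list(kept = kept,
       excluded = meta[!keep, c("subject", "euler")],
       median = med, mad = mad_u, threshold = thr)
}
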