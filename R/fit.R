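# Penalized maximum-likelihood fitting of the generalized-gamma normative
# model. Links: log for mu, log for sigma, identity for nu. Batch offsets on
# the mu and sigma links are penalized Gaussian (random-effect style), with
# the offset variances tau^2 updated by fixed-point iteration
# (tau^2 <- mean(delta^2)), which is coordinate ascent on the joint objective
#   sum log f - sum_b dmu_b^2/(2 tau_mu^2) - (B/2) log tau_mu^2  (same for
# sigma), so the monitored objective is non-decreasing across iterations.

# log-density terms and their gradients wrt the linear predictors
# (lmu = log mu, lsig = log sigma, nu itself). Vectorized over subjects.
.gg_ll_terms <- function(lmu, lsig, nu, logy) {
  u <- logy - lmu
  sigma2 <- exp(2 * lsig)
  n <- length(logy)
  logf <- glm_ <- gls <- gnu <- numeric(n)
  ln <- abs(nu) < .gg_nu_eps
  if (any(ln)) {
    i <- ln
    logf[i] <- -logy[i] - lsig[i] - 0.5 * log(2 * pi) - u[i]^2 / (2 * sigma2[i])
    glm_[i] <- u[i] / sigma2[i]
    gls[i] <- u[i]^2 / sigma2[i] - 1
    gnu[i] <- 0
  }
  if (any(!ln)) {
    i <- !ln
    th <- 1 / (sigma2[i] * nu[i]^2)
    z <- exp(nu[i] * u[i])
    br <- log(th) + 1 + nu[i] * u[i] - z - digamma(th)
    logf[i] <- log(abs(nu[i])) + th * log(th) + th * nu[i] * u[i] -
      th * z - lgamma(th) - logy[i]
    glm_[i] <- th * nu[i] * (z - 1)
    gls[i] <- -2 * th * br
    gnu[i] <- 1 / nu[i] + th * u[i] * (1 - z) - (2 * th / nu[i]) * br
  }
  list(logf = logf, glm = glm_, gls = gls, gnu = gnu)
}

# packed parameter vector: beta_mu, beta_sigma, beta_nu, dmu[B], dsigma[B]
.unpack <- function(par, pm, ps, pn, B) {
  list(bm = par[seq_len(pm)],
       bs = par[pm + seq_len(ps)],
       bn = par[pm + ps + seq_len(pn)],
       dm = if (B) par[pm + ps + pn + seq_len(B)] else numeric(0),
       ds = if (B) par[pm + ps + pn + B + seq_len(B)] else numeric(0))
}

.penalized_nll <- function(par, env) {
  p <- .unpack(par, env$pm, env$ps, env$pn, env$B)
  lmu <- drop(env$X_mu %*% p$bm)
  lsig <- drop(env$X_sigma %*% p$bs)
  nu <- drop(env$X_nu %*% p$bn)
  if (env$B) {
    lmu <- lmu + p$dm[env$batch_idx]
    lsig <- lsig + p$ds[env$batch_idx]
  }
  if (any(abs(nu) > 25) || any(abs(lsig) > 25) || any(abs(lmu) > 50))
    return(1e10)
  ll <- .gg_ll_terms(lmu, lsig, nu, env$logy)
  nll <- -sum(ll$logf)
  if (!is.finite(nll)) return(1e10)
  if (env$B)
    nll <- nll + sum(p$dm^2) / (2 * env$tau2_mu) +
      sum(p$ds^2) / (2 * env$tau2_sigma)
  nll
}

.penalized_grad <- function(par, env) {
  p <- .unpack(par, env$pm, env$ps, env$pn, env$B)
  lmu <- drop(env$X_mu %*% p$bm)
  lsig <- drop(env$X_sigma %*% p$bs)
  nu <- drop(env$X_nu %*% p$bn)
  if (env$B) {
    lmu <- lmu + p$dm[env$batch_idx]
    lsig <- lsig + p$ds[env$batch_idx]
  }
  ll <- .gg_ll_terms(lmu, lsig, nu, env$logy)
  g_bm <- -drop(crossprod(env$X_mu, ll$glm))
  g_bs <- -drop(crossprod(env$X_sigma, ll$gls))
  g_bn <- -drop(crossprod(env$X_nu, ll$gnu))
  g <- if (!env$B) c(g_bm, g_bs, g_bn) else {
    g_dm <- -rowsum_by(ll$glm, env$batch_idx, env$B) + p$dm / env$tau2_mu
    g_ds <- -rowsum_by(ll$gls, env$batch_idx, env$B) + p$ds / env$tau2_sigma
    c(g_bm, g_bs, g_bn, g_dm, g_ds)
  }
  g[!is.finite(g)] <- 0  # guard plateau (objective capped at 1e10)
  g
}

rowsum_by <- function(x, idx, B) {
  out <- numeric(B)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

.fit_control <- function(control = list()) {
  utils::modifyList(list(
    max_outer = 30L, maxit = 200L, reltol = 1e-10, outer_tol = 1e-6,
    tau_floor = 1e-8, tau_init = 0.01, starts = 3L, fix_tau = NULL,
    se = FALSE), control)
}

.start_values <- function(env) {
  fit <- stats::lm.fit(env$X_mu, env$logy)
  bm0 <- fit$coefficients
  bm0[is.na(bm0)] <- 0
  s0 <- max(stats::sd(fit$residuals), 1e-3)
  mk <- function(bm, lsig0, nu0) {
    c(bm, c(log(lsig0), numeric(env$ps - 1L)),
      c(nu0, numeric(env$pn - 1L)), numeric(2L * env$B))
  }
  list(mk(bm0, s0, 1),                                  # method of moments
       mk(bm0, s0, 0.1),                                # near-lognormal
       mk(bm0 + c(0.05, numeric(env$pm - 1L)), s0 * 1.5, 1.5))  # perturbed
}

#' Fit the normative model for a single region
#'
#' Maximizes the batch-penalized generalized-gamma log-likelihood by
#' quasi-Newton iteration with analytic gradients, multi-start (method of
#' moments, near-lognormal, perturbed; fixed order, best objective wins), and
#' fixed-point updates of the offset variances.
#'
#' @param y Positive measurements.
#' @param basis Design list from [build_design_basis()].
#' @param batch Optional batch factor/character (offsets pinned at 0 when
#'   absent or single-level).
#' @param spec The [basis_spec()] used to build `basis` (stored in the model).
#' @param region Region id label.
#' @param control List overriding fitting defaults: `max_outer`, `maxit`,
#'   `reltol` (inner relative tolerance), `outer_tol`, `tau_floor`,
#'   `tau_init`, `starts` (1-3), `fix_tau` (list `tau2_mu`, `tau2_sigma` to
#'   freeze the offset variances), `se` (compute asymptotic SEs).
#' @return An object of class `region_model`.
#' @export
fit_region_model <- function(y, basis, batch = NULL, spec = NULL,
                             region = NA_character_, control = list()) {
  ctl <- .fit_control(control)
  stopifnot(all(y > 0),
            nrow(basis$X_mu) == length(y),
            nrow(basis$X_sigma) == length(y),
            nrow(basis$X_nu) == length(y))
  env <- new.env(parent = emptyenv())
  env$X_mu <- basis$X_mu; env$X_sigma <- basis$X_sigma; env$X_nu <- basis$X_nu
  env$logy <- log(y)
  env$pm <- ncol(env$X_mu); env$ps <- ncol(env$X_sigma)
  env$pn <- ncol(env$X_nu)
  batches <- if (is.null(batch)) character(0) else levels(factor(batch))
  env$B <- if (length(batches) > 1L) length(batches) else 0L
  if (env$B) env$batch_idx <- as.integer(factor(batch))
  env$tau2_mu <- ctl$fix_tau$tau2_mu %||% ctl$tau_init
  env$tau2_sigma <- ctl$fix_tau$tau2_sigma %||% ctl$tau_init

  obj_trace <- numeric(0)
  joint_obj <- function(nll_pen) {
    j <- -nll_pen
    if (env$B && is.null(ctl$fix_tau))
      j <- j - (env$B / 2) * log(env$tau2_mu) -
        (env$B / 2) * log(env$tau2_sigma)
    j
  }

  starts <- .start_values(env)[seq_len(ctl$starts)]
  fits <- lapply(starts, function(s)
    stats::optim(s, .penalized_nll, .penalized_grad, env = env,
                 method = "BFGS",
                 control = list(maxit = ctl$maxit, reltol = ctl$reltol)))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  obj_trace <- joint_obj(best$value)
  converged <- best$convergence == 0L

  if (env$B && is.null(ctl$fix_tau)) {
    for (it in seq_len(ctl$max_outer)) {
      p <- .unpack(best$par, env$pm, env$ps, env$pn, env$B)
      env$tau2_mu <- max(mean(p$dm^2), ctl$tau_floor)
      env$tau2_sigma <- max(mean(p$ds^2), ctl$tau_floor)
      best <- stats::optim(best$par, .penalized_nll, .penalized_grad,
                           env = env, method = "BFGS",
                           control = list(maxit = ctl$maxit,
                                          reltol = ctl$reltol))
      obj_trace <- c(obj_trace, joint_obj(best$value))
      k <- length(obj_trace)
      if (abs(obj_trace[k] - obj_trace[k - 1L]) <
          ctl$outer_tol * (abs(obj_trace[k - 1L]) + 1)) break
    }
    converged <- best$convergence == 0L
  }

  p <- .unpack(best$par, env$pm, env$ps, env$pn, env$B)
  # unpenalized log-likelihood at the optimum
  lmu <- drop(env$X_mu %*% p$bm); lsig <- drop(env$X_sigma %*% p$bs)
  nuv <- drop(env$X_nu %*% p$bn)
  if (env$B) {
    lmu <- lmu + p$dm[env$batch_idx]; lsig <- lsig + p$ds[env$batch_idx]
  }
  loglik <- sum(.gg_ll_terms(lmu, lsig, nuv, env$logy)$logf)
  k <- env$pm + env$ps + env$pn
  se <- NULL
  if (isTRUE(ctl$se)) {
    H <- stats::optimHess(best$par, .penalized_nll, .penalized_grad, env = env)
    v <- tryCatch(diag(solve(H)), error = function(e) rep(NA_real_, length(best$par)))
    se <- sqrt(pmax(v, 0))[seq_len(k)]
  }
  structure(list(
    region = region,
    spec = spec,
    beta_mu = stats::setNames(p$bm, colnames(env$X_mu)),
    beta_sigma = stats::setNames(p$bs, colnames(env$X_sigma)),
    beta_nu = stats::setNames(p$bn, colnames(env$X_nu)),
    offsets = if (env$B)
      tibble::tibble(batch = batches, dmu = unname(p$dm),
                     dsigma = unname(p$ds))
    else tibble::tibble(batch = batches, dmu = numeric(0),
                        dsigma = numeric(0)),
    tau2_mu = if (env$B) env$tau2_mu else 0,
    tau2_sigma = if (env$B) env$tau2_sigma else 0,
    loglik = loglik,
    bic = -2 * loglik + k * log(length(y)),
    n = length(y), converged = converged,
    obj_trace = obj_trace, se = se), class = "region_model")
}

#' @export
print.region_model <- function(x, ...) {
  cat(sprintf("<region_model> %s: n=%d, loglik=%.2f, BIC=%.2f, %s\n",
              x$region, x$n, x$loglik, x$bic,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# evaluate a region model's (mu, sigma, nu) for given covariates and
# additive link offsets
region_params <- function(model, age, sex, etiv = NULL,
                          dmu = 0, dsigma = 0, dnu = 0) {
  X <- build_design_basis(age, sex, etiv, model$spec)
  list(mu = exp(drop(X$X_mu %*% model$beta_mu) + dmu),
       sigma = exp(drop(X$X_sigma %*% model$beta_sigma) + dsigma),
       nu = drop(X$X_nu %*% model$beta_nu) + dnu)
}

#' Fit the full reference model set
#'
#' Fits one independent normative model per region on the reference cohort.
#' Subjects missing any requested region are excluded from fitting.
#'
#' @param cohort A reference `cohort_table`.
#' @param specs `NULL` (defaults per metric), a single [basis_spec()], or a
#'   named list of specs keyed by region.
#' @param regions Regions to fit (default: all catalog regions present).
#' @param min_n Minimum subjects required per region (default 500).
#' @param control Passed to [fit_region_model()].
#' @return An object of class `reference_model_set`.
#' @export
fit_reference_model <- function(cohort, specs = NULL, regions = NULL,
                                min_n = 500L, control = list()) {
  stopifnot(inherits(cohort, "cohort_table"))
  cat72 <- region_catalog()
  if (is.null(regions)) regions <- intersect(cat72$region,
                                             unique(cohort$measurements$region))
  cat_fit <- cat72[cat72$region %in% regions, ]
  wide <- tidyr::pivot_wider(
    cohort$measurements[cohort$measurements$region %in% regions,
                        c("subject", "region", "value")],
    names_from = "region", values_from = "value")
  complete <- wide$subject[stats::complete.cases(wide)]
  if (length(complete) < nrow(wide))
    message(sprintf("%d subject(s) missing regions excluded from fitting",
                    nrow(wide) - length(complete)))
  meta <- cohort$metadata[match(complete, cohort$metadata$subject), ]
  wide <- wide[match(complete, wide$subject), ]
  if (nrow(meta) < min_n)
    stop(sprintf("only %d complete subjects; min_n = %d", nrow(meta), min_n),
         call. = FALSE)
  get_spec <- function(region, metric) {
    if (is.null(specs)) return(basis_spec(metric))
    if (inherits(specs, "basis_spec")) return(specs)
    specs[[region]] %||% basis_spec(metric)
  }
  models <- vector("list", nrow(cat_fit))
  names(models) <- cat_fit$region
  for (k in seq_len(nrow(cat_fit))) {
    rg <- cat_fit$region[k]
    sp <- get_spec(rg, cat_fit$metric[k])
    X <- build_design_basis(meta$age, meta$sex, meta$etiv, sp)
    models[[rg]] <- fit_region_model(wide[[rg]], X, batch = meta$batch,
                                     spec = sp, region = rg,
                                     control = control)
    if (!models[[rg]]$converged)
      warning(sprintf("region %s did not converge; excluded downstream", rg),
              call. = FALSE)
  }
  structure(list(
    catalog = cat_fit, models = models,
    batches = sort(unique(meta$batch)),
    provenance = list(
      data_hash = .string_md5(paste(signif(unlist(
        wide[-1]), 12), collapse = ",")),
      n = nrow(meta),
      software = as.character(utils::packageVersion("regionchart")),
      fit_date = format(Sys.Date()))), class = "reference_model_set")
}

#' @export
print.reference_model_set <- function(x, ...) {
  cat(sprintf("<reference_model_set> %d regions, %d batches, n=%d\n",
              length(x$models), length(x$batches), x$provenance$n))
  invisible(x)
}

# candidate ranking: BIC first (rounded to absorb float noise), then fewer
# terms, then lexicographic powers
.rank_fp_candidates <- function(bic, candidates) {
  lab <- vapply(candidates, function(p) paste(p, collapse = ","), "")
  order(round(bic, 6), lengths(candidates), lab)
}

#' Default fractional-polynomial candidate sets
#'
#' All degree-1 and degree-2 power sets over \{-1, 0, 0.5, 1, 2\} for the
#' location predictor.
#'
#' @return List of numeric power vectors.
#' @export
default_fp_candidates <- function() {
  base <- c(-1, 0, 0.5, 1, 2)
  c(lapply(base, identity),
    utils::combn(base, 2L, simplify = FALSE))
}

#' Select fractional-polynomial powers by BIC
#'
#' Fits each candidate power set for the location predictor of each region and
#' returns the BIC-minimizing [basis_spec()], breaking ties by fewer terms,
#' then lexicographically.
#'
#' @param cohort A reference `cohort_table`.
#' @param regions Regions to select for.
#' @param candidates List of candidate mu power vectors.
#' @param sigma_powers Scale-predictor powers held fixed across candidates.
#' @param min_n,control As in [fit_reference_model()].
#' @return Named list of `basis_spec` objects, with a `bic_table` attribute.
#' @export
select_fp_powers <- function(cohort, regions,
                             candidates = default_fp_candidates(),
                             sigma_powers = 1, min_n = 500L,
                             control = list()) {
  stopifnot(length(candidates) >= 1L)
  out <- list()
  rows <- list()
  cat72 <- region_catalog()
  for (rg in regions) {
    metric <- cat72$metric[cat72$region == rg]
    bics <- rep(NA_real_, length(candidates))
    for (j in seq_along(candidates)) {
      sp <- basis_spec(metric, mu_powers = candidates[[j]],
                       sigma_powers = sigma_powers)
      fit <- tryCatch(
        fit_reference_model(cohort, specs = sp, regions = rg,
                            min_n = min_n, control = control),
        error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(fit) && fit$models[[rg]]$converged)
        bics[j] <- fit$models[[rg]]$bic
    }
    if (all(is.na(bics)))
      stop(sprintf("no candidate converged for region %s", rg), call. = FALSE)
    ok <- which(!is.na(bics))
    rank <- .rank_fp_candidates(bics[ok], candidates[ok])
    pick <- ok[rank[1]]
    out[[rg]] <- basis_spec(metric, mu_powers = candidates[[pick]],
                            sigma_powers = sigma_powers)
    rows[[rg]] <- tibble::tibble(
      region = rg,
      powers = vapply(candidates, function(p) paste(p, collapse = ","), ""),
      bic = bics, selected = seq_along(candidates) == pick)
  }
  attr(out, "bic_table") <- dplyr::bind_rows(rows)
  out
}

.string_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(x, f)
  unname(tools::md5sum(f))
}
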