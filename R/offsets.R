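# Out-of-sample calibration: per-region maximum-likelihood estimation of
# study offsets (dmu, dsigma on the log links, dnu on the identity link) from
# cognitively normal controls, with the reference coefficients frozen and a
# mild ridge on dnu (small control samples cannot support a free skew shift).

.offset_nll <- function(d, base_lmu, base_lsig, base_nu, logy, ridge_nu) {
  lmu <- base_lmu + d[1]; lsig <- base_lsig + d[2]; nu <- base_nu + d[3]
  if (abs(d[1]) > 5 || abs(d[2]) > 5 || any(abs(nu) > 25)) return(1e10)
  v <- -sum(.gg_ll_terms(lmu, lsig, nu, logy)$logf) + ridge_nu * d[3]^2 / 2
  if (!is.finite(v)) 1e10 else v
}

.offset_grad <- function(d, base_lmu, base_lsig, base_nu, logy, ridge_nu) {
  ll <- .gg_ll_terms(base_lmu + d[1], base_lsig + d[2], base_nu + d[3], logy)
  g <- c(-sum(ll$glm), -sum(ll$gls), -sum(ll$gnu) + ridge_nu * d[3])
  g[!is.finite(g)] <- 0
  g
}

#' Estimate study-specific offsets from cognitively normal controls
#'
#' For each region, maximizes the generalized-gamma likelihood of the control
#' measurements over a single offset triple (dmu, dsigma, dnu) added to the
#' frozen reference linear predictors, starting from (0, 0, 0). Emits a
#' low-sample warning flag when fewer than `warn_n` controls are available
#' (stable calibration needs roughly 100 controls on one scanner) and errors
#' below the hard floor.
#'
#' @param model A `reference_model_set`.
#' @param controls A `cohort_table` of cognitively normal controls sharing one
#'   batch id.
#' @param ridge_nu Ridge weight on dnu (default 100; keeps the skew shift near
#'   zero unless the controls strongly demand otherwise).
#' @param min_n Hard floor on the number of controls (default 10).
#' @param warn_n Low-sample warning threshold (default 100).
#' @return An object of class `study_offsets`: per-region tibble of offsets
#'   with convergence flags, the study id, and `n_controls`.
#' @export
estimate_study_offsets <- function(model, controls, ridge_nu = 100,
                                   min_n = 10L, warn_n = 100L) {
  stopifnot(inherits(model, "reference_model_set"),
            inherits(controls, "cohort_table"))
  meta <- controls$metadata
  if (length(unique(meta$batch)) != 1L)
    stop("controls must share a single batch id", call. = FALSE)
  if ("diagnosis" %in% names(meta)) {
    dx <- meta$diagnosis[!is.na(meta$diagnosis)]
    if (!all(dx %in% c("CN", "control", "normal")))
      stop("controls must be cognitively normal", call. = FALSE)
  }
  n <- nrow(meta)
  if (n < min_n)
    stop(sprintf("only %d controls; hard floor is %d", n, min_n),
         call. = FALSE)
  low_n <- n < warn_n
  if (low_n)
    warning(sprintf(paste0("only %d controls (< %d); offset estimates may ",
                           "be unstable"), n, warn_n), call. = FALSE)

  meas <- controls$measurements
  rows <- vector("list", length(model$models))
  for (k in seq_along(model$models)) {
    m <- model$models[[k]]
    rg <- m$region
    idx <- meas$region == rg
    sub <- meas$subject[idx]
    mi <- match(sub, meta$subject)
    ok_flag <- FALSE
    d <- c(NA_real_, NA_real_, NA_real_)
    if (m$converged && sum(idx) >= min_n) {
      X <- build_design_basis(meta$age[mi], meta$sex[mi], meta$etiv[mi],
                              m$spec)
      base_lmu <- drop(X$X_mu %*% m$beta_mu)
      base_lsig <- drop(X$X_sigma %*% m$beta_sigma)
      base_nu <- drop(X$X_nu %*% m$beta_nu)
      opt <- stats::optim(c(0, 0, 0), .offset_nll, .offset_grad,
                          base_lmu = base_lmu, base_lsig = base_lsig,
                          base_nu = base_nu, logy = log(meas$value[idx]),
                          ridge_nu = ridge_nu, method = "BFGS",
                          control = list(maxit = 200, reltol = 1e-10))
      if (opt$convergence == 0L && all(is.finite(opt$par))) {
        d <- opt$par
        ok_flag <- TRUE
      }
    }
    rows[[k]] <- tibble::tibble(region = rg, dmu = d[1], dsigma = d[2],
                                dnu = d[3], converged = ok_flag)
  }
  offs <- dplyr::bind_rows(rows)
  if (any(!offs$converged))
    warning("offset estimation failed for region(s): ",
            paste(offs$region[!offs$converged], collapse = ", "),
            call. = FALSE)
  structure(list(study = unique(meta$batch), offsets = offs,
                 n_controls = n, low_sample_warning = low_n,
                 ridge_nu = ridge_nu), class = "study_offsets")
}

#' @export
print.study_offsets <- function(x, ...) {
  cat(sprintf("<study_offsets> study %s: %d regions, n_controls=%d%s\n",
              x$study, nrow(x$offsets), x$n_controls,
              if (x$low_sample_warning) " (low-sample warning)" else ""))
  invisible(x)
}

#' Convert measurements into centile scores
#'
#' Centile = 100 x the model CDF of the observed value given the subject's
#' age, sex (and eTIV for volumes), with study offsets applied on the link
#' scales. Scores are clamped to \[0.01, 99.99\]. With `offsets = NULL`,
#' subjects must belong to the reference batches and the model's own fitted
#' batch offsets are used.
#'
#' @param model A `reference_model_set`.
#' @param offsets A `study_offsets` object, or `NULL` for reference-batch
#'   subjects.
#' @param subjects A `cohort_table`.
#' @return A tibble (`centile_table`): one row per available subject-region
#'   with `subject`, `region`, `centile` and the covariates used. Regions
#'   whose offsets failed are reported `NA`, never silently dropped.
#' @export
score_centiles <- function(model, offsets = NULL, subjects) {
  stopifnot(inherits(model, "reference_model_set"),
            inherits(subjects, "cohort_table"))
  meta <- subjects$metadata
  if (is.null(offsets)) {
    bad <- setdiff(unique(meta$batch), model$batches)
    if (length(bad))
      stop("subjects from batch(es) not in the reference fit: ",
           paste(bad, collapse = ", "),
           "; calibrate with estimate_study_offsets() first", call. = FALSE)
  } else {
    stopifnot(inherits(offsets, "study_offsets"))
    bad <- setdiff(unique(meta$batch), offsets$study)
    if (length(bad))
      stop("subject batch(es) ", paste(bad, collapse = ", "),
           " do not match calibrated study ", offsets$study, call. = FALSE)
  }
  meas <- subjects$measurements
  out <- vector("list", length(model$models))
  for (k in seq_along(model$models)) {
    m <- model$models[[k]]
    rg <- m$region
    idx <- which(meas$region == rg)
    if (!length(idx)) next
    mi <- match(meas$subject[idx], meta$subject)
    if (is.null(offsets)) {
      oi <- match(meta$batch[mi], m$offsets$batch)
      dmu <- ifelse(is.na(oi), 0, m$offsets$dmu[oi])
      dsig <- ifelse(is.na(oi), 0, m$offsets$dsigma[oi])
      dnu <- 0
      usable <- m$converged
    } else {
      o <- offsets$offsets[offsets$offsets$region == rg, ]
      usable <- nrow(o) == 1L && o$converged && m$converged
      dmu <- if (usable) o$dmu else NA_real_
      dsig <- if (usable) o$dsigma else NA_real_
      dnu <- if (usable) o$dnu else NA_real_
    }
    cent <- rep(NA_real_, length(idx))
    if (usable) {
      pr <- region_params(m, meta$age[mi], meta$sex[mi], meta$etiv[mi],
                          dmu, dsig, dnu)
      cent <- 100 * pgg(meas$value[idx], pr$mu, pr$sigma, pr$nu)
      cent <- pmin(pmax(cent, 0.01), 99.99)
    }
    out[[k]] <- tibble::tibble(subject = meas$subject[idx], region = rg,
                               centile = cent, age = meta$age[mi],
                               sex = meta$sex[mi], etiv = meta$etiv[mi],
                               batch = meta$batch[mi])
  }
  res <- dplyr::bind_rows(out)
  attr(res, "model_hash") <- model$provenance$data_hash
  attr(res, "offsets_hash") <- if (!is.null(offsets))
    .string_md5(paste(signif(unlist(offsets$offsets[c("dmu", "dsigma",
                                                      "dnu")]), 12),
                      collapse = ",")) else "reference-batch"
  class(res) <- c("centile_table", class(res))
  res
}
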