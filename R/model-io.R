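# Versioned JSON serialization for fitted model sets and study offsets, with
# a checksum over the numeric payload so silent edits are caught on load.

.model_schema <- "regionchart-model/1"
.offsets_schema <- "regionchart-offsets/1"

# canonical checksum: md5 over the coefficients printed at 15 significant
# digits in a fixed order (full-precision JSON round-trips doubles exactly,
# so the checksum is reproducible after parse)
.model_checksum <- function(models) {
  num <- unlist(lapply(models, function(m)
    c(m$beta_mu, m$beta_sigma, m$beta_nu, m$tau2_mu, m$tau2_sigma,
      m$offsets$dmu, m$offsets$dsigma)))
  .string_md5(paste(sprintf("%.15g", num), collapse = ","))
}

.offsets_checksum <- function(offs) {
  num <- unlist(offs[c("dmu", "dsigma", "dnu")])
  .string_md5(paste(sprintf("%.15g", num[is.finite(num)]), collapse = ","))
}

.spec_to_list <- function(spec) {
  list(metric = spec$metric, mu_powers = spec$mu_powers,
       sigma_powers = spec$sigma_powers, nu_powers = spec$nu_powers,
       c_age = spec$c_age, etiv_center = spec$etiv_center)
}

.spec_from_list <- function(l) {
  basis_spec(l$metric, mu_powers = as.numeric(l$mu_powers),
             sigma_powers = as.numeric(l$sigma_powers),
             nu_powers = as.numeric(l$nu_powers),
             c_age = l$c_age, etiv_center = l$etiv_center)
}

#' Serialize / deserialize a fitted reference model set
#'
#' Writes a versioned JSON document with full-precision coefficients and a
#' payload checksum; reading verifies both the schema version and the
#' checksum, so truncated or hand-edited documents are rejected.
#'
#' @param model A `reference_model_set`.
#' @param path JSON file path.
#' @return `write_model_set` the path, invisibly; `read_model_set` the
#'   reconstructed `reference_model_set`.
#' @export
write_model_set <- function(model, path) {
  stopifnot(inherits(model, "reference_model_set"))
  doc <- list(
    schema = .model_schema,
    checksum = .model_checksum(model$models),
    batches = model$batches,
    catalog = model$catalog,
    provenance = model$provenance,
    models = lapply(model$models, function(m) list(
      region = m$region, spec = .spec_to_list(m$spec),
      beta_mu = as.list(m$beta_mu), beta_sigma = as.list(m$beta_sigma),
      beta_nu = as.list(m$beta_nu),
      offsets = m$offsets, tau2_mu = m$tau2_mu, tau2_sigma = m$tau2_sigma,
      loglik = m$loglik, bic = m$bic, n = m$n, converged = m$converged)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_set
#' @export
read_model_set <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  if (!identical(doc$schema, .model_schema))
    stop(sprintf("unknown model schema version '%s' (expected '%s')",
                 doc$schema %||% "<missing>", .model_schema), call. = FALSE)
  empty_offsets <- tibble::tibble(batch = character(0), dmu = numeric(0),
                                  dsigma = numeric(0))
  models <- lapply(doc$models, function(m) {
    offs <- tibble::as_tibble(m$offsets)
    if (!nrow(offs) || !ncol(offs)) offs <- empty_offsets
    structure(list(
      region = m$region, spec = .spec_from_list(m$spec),
      beta_mu = unlist(m$beta_mu), beta_sigma = unlist(m$beta_sigma),
      beta_nu = unlist(m$beta_nu),
      offsets = offs,
      tau2_mu = m$tau2_mu, tau2_sigma = m$tau2_sigma,
      loglik = m$loglik, bic = m$bic, n = m$n,
      converged = m$converged), class = "region_model")
  })
  if (!identical(.model_checksum(models), doc$checksum))
    stop("model checksum mismatch: document was edited or truncated",
         call. = FALSE)
  structure(list(catalog = tibble::as_tibble(doc$catalog), models = models,
                 batches = doc$batches,
                 provenance = doc$provenance), class = "reference_model_set")
}

#' Serialize / deserialize study offsets
#'
#' @param offsets A `study_offsets` object.
#' @param path JSON file path.
#' @return `write_study_offsets` the path, invisibly; `read_study_offsets`
#'   the reconstructed `study_offsets`.
#' @export
write_study_offsets <- function(offsets, path) {
  stopifnot(inherits(offsets, "study_offsets"))
  doc <- list(schema = .offsets_schema,
              checksum = .offsets_checksum(offsets$offsets),
              study = offsets$study, n_controls = offsets$n_controls,
              low_sample_warning = offsets$low_sample_warning,
              ridge_nu = offsets$ridge_nu, offsets = offsets$offsets)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_study_offsets
#' @export
read_study_offsets <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  if (!identical(doc$schema, .offsets_schema))
    stop(sprintf("unknown offsets schema version '%s' (expected '%s')",
                 doc$schema %||% "<missing>", .offsets_schema), call. = FALSE)
  offs <- tibble::as_tibble(doc$offsets)
  if (!identical(.offsets_checksum(offs), doc$checksum))
    stop("offsets checksum mismatch: document was edited or truncated",
         call. = FALSE)
  structure(list(study = doc$study, offsets = offs,
                 n_controls = doc$n_controls,
                 low_sample_warning = doc$low_sample_warning,
                 ridge_nu = doc$ridge_nu), class = "study_offsets")
}
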