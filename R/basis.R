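# Fractional-polynomial design bases over transformed age t = log(age + c),
# with a sex indicator, and a centred log-eTIV column for volume regions.

.fp_allowed <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' Construct a basis specification
#'
#' Defines the predictor basis for one region's normative model. Age enters
#' through `t = log(age + c_age)`; fractional-polynomial powers are drawn from
#' \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}, with power 0 meaning `log(t)`. The mu
#' predictor always carries an intercept and a sex indicator; volume regions
#' additionally carry a centred `log(eTIV)` column in the mu predictor.
#'
#' @param metric `"thickness"` or `"volume"`.
#' @param mu_powers Up to 3 distinct powers for the location predictor.
#' @param sigma_powers Up to 2 distinct powers for the scale predictor.
#' @param nu_powers Empty (constant shape) or 1 power.
#' @param c_age Age offset constant in years (> 0); default 0.75 so the
#'   transform is defined from birth.
#' @param etiv_center Centering constant for `log(eTIV)` (log mm^3).
#' @return An object of class `basis_spec`.
#' @export
basis_spec <- function(metric = c("thickness", "volume"),
                       mu_powers = c(1, 2), sigma_powers = 1,
                       nu_powers = numeric(0),
                       c_age = 0.75, etiv_center = log(1.45e6)) {
  metric <- match.arg(metric)
  check_powers <- function(p, max_n, what) {
    if (length(p) > max_n)
      stop(sprintf("at most %d %s powers allowed", max_n, what), call. = FALSE)
    if (anyDuplicated(p))
      stop(sprintf("duplicate %s powers", what), call. = FALSE)
    if (length(p) && !all(p %in% .fp_allowed))
      stop(sprintf("%s powers must come from {%s}", what,
                   paste(.fp_allowed, collapse = ", ")), call. = FALSE)
    as.numeric(sort(p))
  }
  if (!is.numeric(c_age) || length(c_age) != 1L || c_age <= 0)
    stop("c_age must be a single positive number", call. = FALSE)
  structure(list(
    metric = metric,
    mu_powers = check_powers(mu_powers, 3L, "mu"),
    sigma_powers = check_powers(sigma_powers, 2L, "sigma"),
    nu_powers = check_powers(nu_powers, 1L, "nu"),
    c_age = c_age,
    etiv = metric == "volume",
    etiv_center = etiv_center), class = "basis_spec")
}

fp_transform <- function(t, powers) {
  if (!length(powers)) return(matrix(numeric(0), nrow = length(t), ncol = 0))
  needs_pos <- any(powers < 1 | powers != round(powers))
  if (needs_pos && any(t <= 0))
    stop("fractional powers require log(age + c_age) > 0 ",
         "(i.e. age > 1 - c_age)", call. = FALSE)
  cols <- lapply(powers, function(p) if (p == 0) log(t) else t^p)
  m <- do.call(cbind, cols)
  colnames(m) <- paste0("age_p", powers)
  m
}

#' Build design bases for the three distribution parameters
#'
#' @param age Ages in years (>= 0).
#' @param sex Factor/character with levels `female`/`male`.
#' @param etiv Estimated total intracranial volume in mm^3 (required when the
#'   spec carries an eTIV term; may be `NULL` otherwise).
#' @param spec A [basis_spec()].
#' @return List with matrices `X_mu`, `X_sigma`, `X_nu` (each with an
#'   intercept column; `X_mu` also has the sex indicator and, for volumes,
#'   centred log eTIV).
#' @export
build_design_basis <- function(age, sex, etiv = NULL, spec) {
  stopifnot(inherits(spec, "basis_spec"))
  if (any(!is.finite(age)) || any(age + spec$c_age <= 0))
    stop("age + c_age must be positive and finite", call. = FALSE)
  sex <- as.character(sex)
  if (any(is.na(sex)) || !all(sex %in% c("female", "male")))
    stop("sex must be 'female' or 'male'", call. = FALSE)
  male <- as.integer(sex == "male")
  t <- log(age + spec$c_age)
  X_mu <- cbind(intercept = 1, sex_male = male,
                fp_transform(t, spec$mu_powers))
  if (spec$etiv) {
    if (is.null(etiv) || any(!is.finite(etiv)) || any(etiv <= 0))
      stop("positive eTIV values required for volume regions", call. = FALSE)
    X_mu <- cbind(X_mu, log_etiv_c = log(etiv) - spec$etiv_center)
  }
  X_sigma <- cbind(intercept = 1, fp_transform(t, spec$sigma_powers))
  X_nu <- cbind(intercept = 1, fp_transform(t, spec$nu_powers))
  list(X_mu = X_mu, X_sigma = X_sigma, X_nu = X_nu)
}
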