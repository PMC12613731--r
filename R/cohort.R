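# CohortTable: long measurement table + wide metadata table + optional
# per-region tau, with validated invariants.

#' Construct a cohort table
#'
#' @param measurements Tibble with columns `subject`, `region`, `metric`,
#'   `value` (one row per subject-region; regions from the 72-name catalog,
#'   values strictly positive, no duplicates).
#' @param metadata Tibble keyed by `subject` with `batch`, `age` (years,
#'   in \[0, 100\]), `sex` (`female`/`male`), `etiv` (mm^3, > 0) and optional
#'   `diagnosis`, `mmse` (integer 0-30), `euler` (integer).
#' @param tau Optional tibble `subject`, `region`, `suvr` (> 0).
#' @param provenance List recording where the cohort came from.
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(measurements, metadata, tau = NULL,
                         provenance = list()) {
  cat <- region_catalog()
  measurements <- tibble::as_tibble(measurements)
  metadata <- tibble::as_tibble(metadata)
  req <- c("subject", "region", "metric", "value")
  if (!all(req %in% names(measurements)))
    stop("measurements must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(metadata$subject))
    stop("duplicate subject ids in metadata", call. = FALSE)
  unknown <- setdiff(measurements$region, cat$region)
  if (length(unknown))
    stop("unknown regions: ", paste(utils::head(unknown, 5), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(measurements[c("subject", "region")]))
    stop("duplicate subject-region measurements", call. = FALSE)
  if (any(!is.finite(measurements$value)) || any(measurements$value <= 0))
    stop("measurement values must be finite and strictly positive",
         call. = FALSE)
  want <- cat$metric[match(measurements$region, cat$region)]
  if (any(want != measurements$metric))
    stop("metric does not match catalog for some regions", call. = FALSE)
  if (any(metadata$age < 0 | metadata$age > 100))
    stop("age outside [0, 100]", call. = FALSE)
  if (!all(metadata$sex %in% c("female", "male")))
    stop("sex must be 'female' or 'male'", call. = FALSE)
  if (any(metadata$etiv <= 0)) stop("eTIV must be positive", call. = FALSE)
  if ("mmse" %in% names(metadata)) {
    m <- metadata$mmse[!is.na(metadata$mmse)]
    if (any(m < 0 | m > 30 | m != round(m)))
      stop("MMSE must be an integer in [0, 30]", call. = FALSE)
  }
  orphan <- setdiff(measurements$subject, metadata$subject)
  if (length(orphan))
    stop("measurements for subjects missing from metadata: ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  structure(list(measurements = measurements, metadata = metadata,
                 tau = if (!is.null(tau)) tibble::as_tibble(tau),
                 provenance = provenance),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d subjects, %d measurement rows, %d regions\n",
              nrow(x$metadata), nrow(x$measurements),
              length(unique(x$measurements$region))))
  if (!is.null(x$tau)) cat(sprintf("  tau: %d rows\n", nrow(x$tau)))
  invisible(x)
}

#' Number of subjects in a cohort
#' @param cohort A `cohort_table`.
#' @return Integer count.
#' @export
n_subjects <- function(cohort) nrow(cohort$metadata)

#' Keep a subset of subjects
#' @param cohort A `cohort_table`.
#' @param subjects Character vector of subject ids.
#' @return A `cohort_table` restricted to `subjects`.
#' @export
subset_cohort <- function(cohort, subjects) {
  cohort_table(
    cohort$measurements[cohort$measurements$subject %in% subjects, ],
    cohort$metadata[cohort$metadata$subject %in% subjects, ],
    tau = if (!is.null(cohort$tau))
      cohort$tau[cohort$tau$subject %in% subjects, ],
    provenance = cohort$provenance)
}

#' Write / read a cohort as plain CSV
#'
#' The long measurement table and the wide metadata table are written as two
#' CSV files (tau, when present, as a third alongside the measurements).
#'
#' @param cohort A `cohort_table`.
#' @param measurements_path,metadata_path Output CSV paths.
#' @return `write_cohort_csv` the paths written, invisibly;
#'   `read_cohort_csv` a `cohort_table`.
#' @export
write_cohort_csv <- function(cohort, measurements_path, metadata_path) {
  utils::write.csv(cohort$measurements, measurements_path, row.names = FALSE)
  utils::write.csv(cohort$metadata, metadata_path, row.names = FALSE)
  paths <- c(measurements_path, metadata_path)
  if (!is.null(cohort$tau)) {
    tau_path <- sub("\\.csv$", "_tau.csv", measurements_path)
    utils::write.csv(cohort$tau, tau_path, row.names = FALSE)
    paths <- c(paths, tau_path)
  }
  invisible(paths)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(measurements_path, metadata_path) {
  meas <- utils::read.csv(measurements_path, stringsAsFactors = FALSE)
  meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  tau_path <- sub("\\.csv$", "_tau.csv", measurements_path)
  tau <- if (file.exists(tau_path))
    utils::read.csv(tau_path, stringsAsFactors = FALSE)
  cohort_table(meas, meta, tau = tau,
               provenance = list(source = measurements_path))
}
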