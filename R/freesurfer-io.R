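# Reader and fixture writer for the FreeSurfer stats text dialect:
# '#' comment lines, a '# ColHeaders ...' line naming the whitespace-delimited
# columns, and '# Measure ...' header lines (eTIV). Columns are located by
# header name, never by position.

.aparc_headers <- c("StructName", "NumVert", "SurfArea", "GrayVol", "ThickAvg",
                    "ThickStd", "MeanCurv", "GausCurv", "FoldInd", "CurvInd")
.aseg_headers <- c("Index", "SegId", "NVoxels", "Volume_mm3", "StructName",
                   "normMean", "normStdDev")

.parse_stats_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ch <- grep("^# ColHeaders", lines, value = TRUE)
  if (!length(ch))
    stop(sprintf("%s: no ColHeaders line", path), call. = FALSE)
  headers <- strsplit(sub("^# ColHeaders\\s+", "", ch[1]), "\\s+")[[1]]
  rows <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(rows))
    stop(sprintf("%s: no data rows", path), call. = FALSE)
  fields <- strsplit(trimws(rows), "\\s+")
  bad <- vapply(fields, length, 1L) != length(headers)
  if (any(bad))
    stop(sprintf("%s: malformed row(s)", path), call. = FALSE)
  df <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(df) <- headers
  df
}

.stats_measure <- function(path, name) {
  lines <- readLines(path, warn = FALSE)
  m <- grep(paste0("^# Measure ", name, ","), lines, value = TRUE)
  if (!length(m))
    stop(sprintf("%s: missing Measure line for %s", path, name), call. = FALSE)
  parts <- strsplit(m[1], ",")[[1]]
  val <- suppressWarnings(as.numeric(trimws(parts[length(parts) - 1L])))
  if (!is.finite(val))
    stop(sprintf("%s: unparseable %s value", path, name), call. = FALSE)
  val
}

.read_aparc <- function(path, hemi) {
  df <- .parse_stats_table(path)
  need <- c("StructName", "ThickAvg")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  extra <- setdiff(df$StructName, .dk_parcels)
  if (length(extra))
    message(sprintf("%s: ignoring unknown rows: %s", basename(path),
                    paste(extra, collapse = ", ")))
  missing <- setdiff(.dk_parcels, df$StructName)
  if (length(missing))
    stop(sprintf("%s: missing region row(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  df <- df[df$StructName %in% .dk_parcels, ]
  val <- as.numeric(df$ThickAvg)
  if (any(!is.finite(val)) || any(val <= 0))
    stop(sprintf("%s: non-positive ThickAvg for %s", path,
                 paste(df$StructName[!is.finite(val) | val <= 0],
                       collapse = ", ")), call. = FALSE)
  tibble::tibble(region = paste(hemi, df$StructName, sep = "_"),
                 metric = "thickness", value = val)
}

#' Read one subject's FreeSurfer-style stats files
#'
#' Parses left/right `aparc.stats` (68 `ThickAvg` thickness values) and
#' `aseg.stats` (hippocampus and amygdala `Volume_mm3` plus the
#' `EstimatedTotalIntraCranialVol` measure line) into a partial phenotype
#' record. Columns are located by name, so column order is irrelevant;
#' unknown extra rows are ignored with a notice.
#'
#' @param lh_aparc,rh_aparc,aseg File paths.
#' @return List with `measurements` (72-row tibble `region`, `metric`,
#'   `value`) and `etiv`.
#' @export
read_freesurfer_stats <- function(lh_aparc, rh_aparc, aseg) {
  for (p in c(lh_aparc, rh_aparc, aseg))
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
  cortical <- dplyr::bind_rows(.read_aparc(lh_aparc, "lh"),
                               .read_aparc(rh_aparc, "rh"))
  df <- .parse_stats_table(aseg)
  need <- c("StructName", "Volume_mm3")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: missing column(s) %s", aseg,
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  missing <- setdiff(unname(.aseg_names), df$StructName)
  if (length(missing))
    stop(sprintf("%s: missing region row(s): %s", aseg,
                 paste(missing, collapse = ", ")), call. = FALSE)
  i <- match(unname(.aseg_names), df$StructName)
  val <- as.numeric(df$Volume_mm3[i])
  if (any(!is.finite(val)) || any(val <= 0))
    stop(sprintf("%s: non-positive Volume_mm3 for %s", aseg,
                 paste(unname(.aseg_names)[!is.finite(val) | val <= 0],
                       collapse = ", ")), call. = FALSE)
  subcort <- tibble::tibble(region = names(.aseg_names), metric = "volume",
                            value = val)
  etiv <- .stats_measure(aseg, "EstimatedTotalIntraCranialVol")
  if (etiv <= 0)
    stop(sprintf("%s: non-positive eTIV", aseg), call. = FALSE)
  list(measurements = dplyr::bind_rows(cortical, subcort), etiv = etiv)
}

#' Write FreeSurfer-style stats fixtures for a cohort
#'
#' For each subject writes `lh.aparc.stats`, `rh.aparc.stats` (34
#' Desikan-Killiany rows each, ThickAvg populated) and `aseg.stats`
#' (hippocampus/amygdala rows plus the eTIV measure line) under
#' `directory/<subject>/`. Values round-trip through
#' [read_freesurfer_stats()] at the written precision.
#'
#' @param cohort A `cohort_table` with full 72-region coverage.
#' @param directory Output directory (created if needed).
#' @return Tibble manifest with columns `subject`, `lh_aparc`, `rh_aparc`,
#'   `aseg`.
#' @export
write_freesurfer_fixtures <- function(cohort, directory) {
  stopifnot(inherits(cohort, "cohort_table"))
  cat72 <- region_catalog()
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory))
    stop(sprintf("cannot create directory %s", directory), call. = FALSE)
  wide <- tidyr::pivot_wider(cohort$measurements[c("subject", "region", "value")],
                             names_from = "region", values_from = "value")
  miss <- setdiff(cat72$region, names(wide))
  if (length(miss) || anyNA(wide))
    stop("missing region value(s): ",
         paste(utils::head(c(miss,
           wide$subject[rowSums(is.na(wide)) > 0]), 5), collapse = ", "),
         call. = FALSE)
  manifest <- vector("list", nrow(wide))
  for (i in seq_len(nrow(wide))) {
    sub <- wide$subject[i]
    sdir <- file.path(directory, sub)
    dir.create(sdir, showWarnings = FALSE)
    meta <- cohort$metadata[cohort$metadata$subject == sub, ]
    paths <- c(lh_aparc = file.path(sdir, "lh.aparc.stats"),
               rh_aparc = file.path(sdir, "rh.aparc.stats"),
               aseg = file.path(sdir, "aseg.stats"))
    for (hemi in c("lh", "rh")) {
      vals <- unlist(wide[i, paste(hemi, .dk_parcels, sep = "_")])
      rows <- sprintf("%-26s %6d %8d %9d %7.4f %6.3f %8.3f %8.3f %5d %6.1f",
                      .dk_parcels, 1000L, 700L, 2000L, vals, 0.5,
                      0.1, 0.02, 10L, 1.0)
      writeLines(c(
        "# Table of FreeSurfer cortical parcellation anatomical statistics",
        sprintf("# subjectname %s", sub),
        sprintf("# hemi %s", hemi),
        paste("# ColHeaders", paste(.aparc_headers, collapse = " ")),
        rows), paths[[paste0(hemi, "_aparc")]])
    }
    aseg_regions <- names(.aseg_names)
    vals <- unlist(wide[i, aseg_regions])
    rows <- sprintf("%3d %4d %7d %10.1f %-24s %8.4f %8.4f",
                    seq_along(aseg_regions), c(17L, 53L, 18L, 54L),
                    round(vals), vals, unname(.aseg_names), 80, 8)
    writeLines(c(
      "# Title Segmentation Statistics",
      sprintf("# subjectname %s", sub),
      sprintf(paste0("# Measure EstimatedTotalIntraCranialVol, eTIV, ",
                     "Estimated Total Intracranial Volume, %.4f, mm^3"),
              meta$etiv),
      paste("# ColHeaders", paste(.aseg_headers, collapse = " ")),
      rows), paths[["aseg"]])
    manifest[[i]] <- tibble::tibble(subject = sub,
                                    lh_aparc = unname(paths["lh_aparc"]),
                                    rh_aparc = unname(paths["rh_aparc"]),
                                    aseg = unname(paths["aseg"]))
  }
  dplyr::bind_rows(manifest)
}

#' Assemble a cohort table from stats records and metadata
#'
#' Inner-joins parsed per-subject stats records with a metadata table keyed by
#' subject id; subjects present on one side only are dropped with a warning.
#'
#' @param records Named list (by subject id) of records from
#'   [read_freesurfer_stats()].
#' @param metadata Tibble keyed by `subject` with `batch`, `age`, `sex` and
#'   optional clinical fields (`diagnosis`, `mmse`, `euler`).
#' @return A `cohort_table`.
#' @export
assemble_cohort_table <- function(records, metadata) {
  metadata <- tibble::as_tibble(metadata)
  if (anyDuplicated(metadata$subject))
    stop("duplicate subject ids in metadata", call. = FALSE)
  if (is.null(names(records)) || anyDuplicated(names(records)))
    stop("records must be a uniquely named list keyed by subject id",
         call. = FALSE)
  common <- intersect(names(records), metadata$subject)
  orphan_meta <- setdiff(metadata$subject, names(records))
  orphan_rec <- setdiff(names(records), metadata$subject)
  if (length(orphan_meta))
    warning("metadata rows without stats records dropped: ",
            paste(orphan_meta, collapse = ", "), call. = FALSE)
  if (length(orphan_rec))
    warning("stats records without metadata dropped: ",
            paste(orphan_rec, collapse = ", "), call. = FALSE)
  if (!length(common)) stop("no subjects in common", call. = FALSE)
  meas <- dplyr::bind_rows(lapply(common, function(s)
    dplyr::mutate(records[[s]]$measurements, subject = s)))
  meta <- metadata[metadata$subject %in% common, ]
  meta$etiv <- vapply(meta$subject, function(s) records[[s]]$etiv, numeric(1))
  cohort_table(meas, meta, provenance = list(source = "freesurfer-stats"))
}
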