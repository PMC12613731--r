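# Individual-level reporting and the end-to-end pipeline orchestrator.

#' Render an individual centile report
#'
#' Arranges one subject's regional centiles by cortical lobe, flags regions
#' below configurable thresholds (default: flag below the 5th centile,
#' highlight below the 1st), and optionally writes machine-readable CSV and
#' human-readable text renderings. Catalog regions missing from the centile
#' table are listed as unavailable, never dropped.
#'
#' @param centiles A `centile_table`.
#' @param subject Subject id (must be present).
#' @param flag_below Flag threshold in centile points (default 5).
#' @param highlight_below Highlight threshold (default 1).
#' @param csv_path,text_path Optional output paths.
#' @return List of class `individual_report`: `subject`, `covariates`,
#'   `table` (tibble `lobe`, `region`, `centile`, `flag`).
#' @export
render_individual_report <- function(centiles, subject, flag_below = 5,
                                     highlight_below = 1,
                                     csv_path = NULL, text_path = NULL) {
  rows <- centiles[centiles$subject == subject, ]
  if (!nrow(rows))
    stop(sprintf("unknown subject '%s'", subject), call. = FALSE)
  cat72 <- region_catalog()
  tab <- dplyr::left_join(cat72[c("region", "lobe")],
                          rows[c("region", "centile")], by = "region")
  tab$flag <- dplyr::case_when(
    is.na(tab$centile) ~ "unavailable",
    tab$centile < highlight_below ~ "very_low",
    tab$centile < flag_below ~ "low",
    TRUE ~ "")
  lobe_order <- c("frontal", "temporal", "parietal", "occipital",
                  "cingulate", "insula", "subcortical")
  tab <- tab[order(match(tab$lobe, lobe_order), tab$region), ]
  cov <- rows[1, intersect(c("age", "sex", "batch"), names(rows))]
  rep_obj <- structure(list(subject = subject, covariates = cov,
                            flag_below = flag_below,
                            highlight_below = highlight_below,
                            table = tibble::as_tibble(tab),
                            model_hash = attr(centiles, "model_hash"),
                            offsets_hash = attr(centiles, "offsets_hash")),
                       class = "individual_report")
  if (!is.null(csv_path))
    utils::write.csv(rep_obj$table, csv_path, row.names = FALSE)
  if (!is.null(text_path))
    writeLines(utils::capture.output(print(rep_obj)), text_path)
  rep_obj
}

#' @export
print.individual_report <- function(x, ...) {
  cat(sprintf("Regional centile report - subject %s", x$subject))
  if (nrow(x$covariates))
    cat(sprintf(" (age %.1f, %s)", x$covariates$age, x$covariates$sex))
  cat("\n")
  cat(sprintf("flags: 'low' < %g, 'very_low' < %g centile\n\n",
              x$flag_below, x$highlight_below))
  for (lb in unique(x$table$lobe)) {
    cat(lb, "\n")
    sub <- x$table[x$table$lobe == lb, ]
    for (i in seq_len(nrow(sub)))
      cat(sprintf("  %-28s %8s  %s\n", sub$region[i],
                  ifelse(is.na(sub$centile[i]), "NA",
                         sprintf("%6.1f", sub$centile[i])), sub$flag[i]))
  }
  invisible(x)
}

.pipeline_stages <- c("simulate", "fit", "calibrate", "score", "analyze",
                      "report")

#' Default pipeline configuration
#'
#' Problem sizes are deliberately small so the demo pipeline completes in a
#' few minutes on one CPU.
#'
#' @param seed Master seed; every stage derives its seed from it.
#' @param stages Ordered subset of
#'   simulate, fit, calibrate, score, analyze, report.
#' @param n_reference Reference subjects per batch.
#' @param n_batches Reference batches.
#' @param n_cases,n_controls Clinical study sizes.
#' @param regions Regions fitted and analysed (default: the a-priori
#'   signature set).
#' @param pattern Disease pattern of the clinical study.
#' @return Named list understood by [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1L, stages = .pipeline_stages,
                            n_reference = 600L, n_batches = 2L,
                            n_cases = 80L, n_controls = 160L,
                            regions = ad_signature_regions(),
                            pattern = "AD") {
  list(seed = as.integer(seed), stages = stages, n_reference = n_reference,
       n_batches = n_batches, n_cases = n_cases, n_controls = n_controls,
       regions = regions, pattern = pattern)
}

.validate_pipeline_config <- function(config) {
  need <- c("seed", "stages", "n_reference", "n_batches", "n_cases",
            "n_controls", "regions", "pattern")
  missing <- setdiff(need, names(config))
  if (length(missing))
    stop("invalid pipeline config: missing field(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  st <- config$stages
  bad <- setdiff(st, .pipeline_stages)
  if (length(bad))
    stop("invalid pipeline config: unknown stage(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!identical(st, .pipeline_stages[.pipeline_stages %in% st]))
    stop("invalid pipeline config: stages out of order", call. = FALSE)
  deps <- list(fit = "simulate", calibrate = c("simulate", "fit"),
               score = c("simulate", "fit", "calibrate"),
               analyze = c("simulate", "fit", "calibrate", "score"),
               report = c("simulate", "fit", "calibrate", "score"))
  for (s in st) {
    miss <- setdiff(deps[[s]], st)
    if (length(miss))
      stop(sprintf("invalid pipeline config: stage '%s' requires %s",
                   s, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(config)
}

#' Run the end-to-end demo pipeline
#'
#' Executes the configured stages in order (simulate a reference population
#' and a clinical study, fit the reference models, calibrate the study,
#' score centiles, run the cohort analyses, render a report), writing every
#' artifact under `out_dir` along with a manifest of md5 hashes. Re-running
#' with an identical config reproduces identical artifacts.
#'
#' @param config List from [pipeline_config()] or a YAML file path.
#' @param out_dir Output directory.
#' @return Tibble manifest (`stage`, `file`, `md5`), invisibly written to
#'   `manifest.json` as well.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  base <- pipeline_config()
  config <- utils::modifyList(base[setdiff(names(base), names(config))],
                              config, keep.null = TRUE)
  .validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- .string_md5(paste(utils::capture.output(utils::str(config)),
                                collapse = "\n"))
  artifacts <- list()
  note <- function(stage, files) {
    artifacts[[length(artifacts) + 1L]] <<-
      tibble::tibble(stage = stage, file = basename(files),
                     md5 = unname(tools::md5sum(files)))
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }
  st <- config$stages

  ref <- study <- model <- offs <- cents <- NULL
  if ("simulate" %in% st) run_stage("simulate", function() {
    cfg <- simulation_config(n_batches = config$n_batches,
                             n_per_batch = config$n_reference,
                             age_range = c(45, 95), seed = config$seed)
    rp <- generate_reference_population(cfg)
    ref <<- rp$cohort
    scfg <- simulation_config(age_range = c(55, 85),
                              pattern = config$pattern,
                              n_cases = config$n_cases,
                              n_controls = config$n_controls,
                              seed = config$seed + 1000L)
    study <<- generate_clinical_study(rp$truth, scfg)
    p1 <- write_cohort_csv(ref, file.path(out_dir, "reference_long.csv"),
                           file.path(out_dir, "reference_meta.csv"))
    p2 <- write_cohort_csv(study, file.path(out_dir, "study_long.csv"),
                           file.path(out_dir, "study_meta.csv"))
    note("simulate", c(p1, p2))
  })
  if ("fit" %in% st) run_stage("fit", function() {
    model <<- fit_reference_model(ref, regions = config$regions,
                                  min_n = min(500L, n_subjects(ref)))
    f <- file.path(out_dir, "reference_model.json")
    write_model_set(model, f)
    note("fit", f)
  })
  if ("calibrate" %in% st) run_stage("calibrate", function() {
    ctrl_ids <- study$metadata$subject[study$metadata$diagnosis == "CN"]
    offs <<- suppressWarnings(
      estimate_study_offsets(model, subset_cohort(study, ctrl_ids)))
    f <- file.path(out_dir, "study_offsets.json")
    write_study_offsets(offs, f)
    note("calibrate", f)
  })
  if ("score" %in% st) run_stage("score", function() {
    cents <<- score_centiles(model, offs, study)
    f <- file.path(out_dir, "centiles.csv")
    utils::write.csv(cbind(config_hash = cfg_hash, as.data.frame(cents)),
                     f, row.names = FALSE)
    note("score", f)
  })
  if ("analyze" %in% st) run_stage("analyze", function() {
    meta <- study$metadata
    is_case <- meta$diagnosis != "CN"
    qc <- euler_mad_filter(study)
    utils::write.csv(qc$excluded, file.path(out_dir, "qc_excluded.csv"),
                     row.names = FALSE)
    cors <- spearman_fdr(
      cents, tibble::tibble(subject = meta$subject, value = meta$mmse),
      regions = intersect(config$regions, unique(cents$region)))
    utils::write.csv(cbind(config_hash = cfg_hash, as.data.frame(cors)),
                     file.path(out_dir, "mmse_spearman.csv"),
                     row.names = FALSE)
    wide <- tidyr::pivot_wider(cents[c("subject", "region", "centile")],
                               names_from = "region",
                               values_from = "centile")
    wide$label <- is_case[match(wide$subject, meta$subject)]
    rois <- intersect(config$regions, names(wide))
    disc <- discriminate(wide, rois)
    utils::write.csv(cbind(config_hash = cfg_hash,
                           as.data.frame(disc$per_roi)),
                     file.path(out_dir, "roi_auc.csv"), row.names = FALSE)
    utils::write.csv(cbind(config_hash = cfg_hash,
                           as.data.frame(disc$combined$summary)),
                     file.path(out_dir, "combined_auc.csv"),
                     row.names = FALSE)
    cp <- youden_cutpoint(wide[[rois[1]]], wide$label)
    utils::write.csv(cbind(config_hash = cfg_hash,
                           as.data.frame(cp$optimal)),
                     file.path(out_dir, "cutpoint.csv"), row.names = FALSE)
    note("analyze", file.path(out_dir, c("qc_excluded.csv",
                                         "mmse_spearman.csv", "roi_auc.csv",
                                         "combined_auc.csv",
                                         "cutpoint.csv")))
  })
  if ("report" %in% st) run_stage("report", function() {
    case_ids <- study$metadata$subject[study$metadata$diagnosis != "CN"]
    subj <- if (length(case_ids)) case_ids[1] else study$metadata$subject[1]
    render_individual_report(cents, subj,
                             csv_path = file.path(out_dir, "report.csv"),
                             text_path = file.path(out_dir, "report.txt"))
    note("report", file.path(out_dir, c("report.csv", "report.txt")))
  })

  manifest <- dplyr::bind_rows(artifacts)
  manifest_doc <- list(config_hash = cfg_hash, config = config,
                       files = manifest)
  jsonlite::write_json(manifest_doc, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
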