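# End-to-end orchestration: phantom cohort -> segmentation -> features ->
# stability selection -> survival models -> report. Stages communicate via
# files (NIfTI / CSV / JSON) so each stage is independently replaceable, and
# every output carries a provenance header with the config fingerprint.

#' Pipeline configuration
#'
#' Collects every tunable setting of a run with the study defaults:
#' 40% isocontour, 64 bins, 2.6 ml volume filter, 1000 stability runs with a
#' strict 0.5 frequency threshold, 10 CV folds.
#'
#' @param output_dir Output directory (created if needed).
#' @param n_subjects Number of synthetic subjects (default 40).
#' @param seg_fraction Isocontour fraction (default 0.40).
#' @param bins Quantization bins (default 64).
#' @param volume_threshold_ml Small-volume exclusion threshold (default 2.6).
#' @param stability_runs LASSO repetitions (default 1000).
#' @param stability_threshold Selection frequency threshold (default 0.5).
#' @param cv_folds Cross-validation folds (default 10).
#' @param n_boot Bootstrap replicates for the c-index comparison (default 2000).
#' @param grid_shape Phantom grid (default `c(32, 32, 24)`).
#' @param spacing_mm Voxel spacing (default `c(2.73, 2.73, 3.27)`).
#' @param sigma_range Range the per-subject border falloff is drawn from, mm
#'   (default `c(0.5, 4)`: sharp to Gaussian-like phenotypes).
#' @param radius_range Per-subject plateau radius range, mm.
#' @param peak_range Per-subject peak SUV range.
#' @param noise_sd Phantom noise SD (default 0.5).
#' @param log_hr Named list: log hazard ratio per 1-SD of each feature tying
#'   the survival times to the images (default `list(LILRE = -1.5)`).
#' @param censoring_rate Target censoring rate (default 0.3).
#' @param baseline_hazard Baseline hazard per month (default 0.02).
#' @param include_cht Include chemotherapy in the selection pool and final
#'   models (default TRUE).
#' @param seed Global seed; all stage seeds derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir,
                            n_subjects = 40,
                            seg_fraction = 0.40,
                            bins = 64,
                            volume_threshold_ml = 2.6,
                            stability_runs = 1000,
                            stability_threshold = 0.5,
                            cv_folds = 10,
                            n_boot = 2000,
                            grid_shape = c(32, 32, 24),
                            spacing_mm = c(2.73, 2.73, 3.27),
                            sigma_range = c(0.5, 4),
                            radius_range = c(10, 16),
                            peak_range = c(8, 16),
                            noise_sd = 0.5,
                            log_hr = list(LILRE = -1.5),
                            censoring_rate = 0.3,
                            baseline_hazard = 0.02,
                            include_cht = TRUE,
                            seed = 1) {
  stopifnot(
    n_subjects >= 4, seg_fraction > 0, seg_fraction < 1, bins >= 2,
    volume_threshold_ml >= 0, stability_runs >= 1,
    stability_threshold > 0, stability_threshold < 1,
    cv_folds >= 2, n_boot >= 1, noise_sd >= 0,
    censoring_rate >= 0, censoring_rate < 1, baseline_hazard > 0
  )
  cfg <- list(
    output_dir = output_dir, n_subjects = as.integer(n_subjects),
    seg_fraction = seg_fraction, bins = as.integer(bins),
    volume_threshold_ml = volume_threshold_ml,
    stability_runs = as.integer(stability_runs),
    stability_threshold = stability_threshold,
    cv_folds = as.integer(cv_folds), n_boot = as.integer(n_boot),
    grid_shape = as.integer(grid_shape), spacing_mm = as.double(spacing_mm),
    sigma_range = as.double(sigma_range),
    radius_range = as.double(radius_range),
    peak_range = as.double(peak_range), noise_sd = noise_sd,
    log_hr = as.list(log_hr), censoring_rate = censoring_rate,
    baseline_hazard = baseline_hazard, include_cht = isTRUE(include_cht),
    seed = as.integer(seed)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

# content hash over every setting except the output location
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$output_dir <- NULL
  fnv1a_hash(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA))
}

# CSV with a provenance comment header; read back with comment.char = "#".
write_csv_prov <- function(x, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# petrad %s config %s",
                     as.character(utils::packageVersion("petrad")), hash), con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

read_csv_prov <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

imaging_feature_names <- function() {
  c("SUVmean", "SUVmax", "skewness", "kurtosis", "SUV_peak", "SUL_peak",
    "GLCM_homogeneity", "GLCM_contrast", "run_percentage", "LILRE",
    "coarseness", "code_similarity", "LILZE")
}

#' Run the full synthetic radiomics survival pipeline
#'
#' Generates a phantom per subject, segments each with the fractional
#' isocontour, applies the small-volume filter, extracts the feature table,
#' generates a survival cohort whose hazard depends on the configured
#' features, runs stability selection over imaging and clinical variables,
#' fits the univariate and the two multivariate Cox models (clinical-only
#' and clinical + selected imaging features), compares their cross-validated
#' c-indexes by paired bootstrap and computes median-split Kaplan-Meier
#' curves for the headline feature. All intermediate artifacts are written
#' under `config$output_dir`; identical config + seed gives identical
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_run` list with all stage results and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  out <- config$output_dir
  vol_dir <- file.path(out, "volumes")
  mask_dir <- file.path(out, "masks")
  for (d in c(out, vol_dir, mask_dir)) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  writeLines(
    jsonlite::toJSON(c(unclass(config), list(config_hash = hash)),
                     auto_unbox = TRUE, pretty = TRUE, digits = NA),
    file.path(out, "config.json")
  )
  ids <- sprintf("S%03d", seq_len(config$n_subjects))

  # --- synth: one phantom per subject, border sharpness drawn per subject
  set.seed(derive_seed(config$seed, 1))
  sigma <- stats::runif(config$n_subjects, config$sigma_range[1],
                        config$sigma_range[2])
  radius <- stats::runif(config$n_subjects, config$radius_range[1],
                         config$radius_range[2])
  peak <- stats::runif(config$n_subjects, config$peak_range[1],
                       config$peak_range[2])
  vol_paths <- character(config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    spec <- phantom_spec(
      grid_shape = config$grid_shape, spacing_mm = config$spacing_mm,
      tumor_radius_mm = radius[i], peak_suv = peak[i],
      border_sigma_mm = sigma[i], noise_sd = config$noise_sd,
      seed = derive_seed(config$seed, 100 + i)
    )
    vol_paths[i] <- file.path(vol_dir, paste0(ids[i], ".nii.gz"))
    tryCatch(write_volume(generate_phantom(spec), vol_paths[i]),
             error = function(e) {
               stop(sprintf("stage synth failed for subject %s: %s",
                            ids[i], conditionMessage(e)), call. = FALSE)
             })
  }

  # --- segment + volume filter
  masks <- vector("list", config$n_subjects)
  names(masks) <- ids
  for (i in seq_len(config$n_subjects)) {
    masks[[i]] <- tryCatch({
      m <- segment_isocontour(read_volume(vol_paths[i]),
                              fraction = config$seg_fraction)
      write_volume(m, file.path(mask_dir, paste0(ids[i], "_mask.nii.gz")))
      m
    }, error = function(e) {
      stop(sprintf("stage segment failed for subject %s: %s",
                   ids[i], conditionMessage(e)), call. = FALSE)
    })
  }
  filt <- apply_volume_filter(masks, threshold_ml = config$volume_threshold_ml)
  write_csv_prov(filt$table, file.path(out, "volume_filter.csv"), hash)
  if (length(filt$retained) == 0) {
    stop(sprintf(
      "empty cohort: all %d subjects excluded by the %.3g ml volume filter",
      config$n_subjects, config$volume_threshold_ml), call. = FALSE)
  }

  # --- features (SUL peak filled in after the cohort provides anthropometrics)
  feats <- lapply(filt$retained, function(id) {
    tryCatch(
      extract_features(read_volume(file.path(vol_dir, paste0(id, ".nii.gz"))),
                       masks[[id]], B = config$bins),
      error = function(e) {
        stop(sprintf("stage features failed for subject %s: %s",
                     id, conditionMessage(e)), call. = FALSE)
      })
  })
  feat_cfg <- attr(feats[[1]], "config")
  features <- cbind(
    data.frame(subject_id = filt$retained, stringsAsFactors = FALSE),
    as.data.frame(do.call(rbind, feats))
  )
  writeLines(
    jsonlite::toJSON(c(feat_cfg, list(config_hash = hash)),
                     auto_unbox = TRUE, pretty = TRUE),
    file.path(out, "features_meta.json")
  )

  # --- cohort with image-linked hazard
  cspec <- cohort_spec(
    n_subjects = nrow(features), censoring_rate = config$censoring_rate,
    baseline_hazard = config$baseline_hazard,
    log_hr_per_feature = config$log_hr,
    seed = derive_seed(config$seed, 2)
  )
  cohort <- generate_cohort(cspec, features)
  cohort$SUL_peak <- sul_peak(cohort$SUV_peak, cohort$weight_kg,
                              cohort$height_cm, cohort$gender)
  features$SUL_peak <- cohort$SUL_peak
  write_csv_prov(features, file.path(out, "features.csv"), hash)
  write_csv_prov(cohort, file.path(out, "cohort.csv"), hash)

  # --- stability selection over imaging features + clinical variables
  pool <- imaging_feature_names()
  pool <- pool[vapply(pool, function(f) {
    v <- cohort[[f]]
    !any(is.na(v)) && stats::sd(v) > 0
  }, logical(1))]
  x <- as.matrix(cohort[pool])
  x <- cbind(x,
             age = cohort$age,
             stage = as.numeric(cohort$stage == "IV"))
  if (config$include_cht) x <- cbind(x, cht = as.numeric(cohort$cht == "yes"))
  stab <- stability_select(
    x, cohort$time_months, cohort$event,
    n_runs = config$stability_runs, threshold = config$stability_threshold,
    seed = derive_seed(config$seed, 3), nfolds = config$cv_folds
  )
  freq_tab <- data.frame(feature = names(stab$frequency),
                         count = as.integer(stab$counts),
                         frequency = as.numeric(stab$frequency),
                         selected = names(stab$frequency) %in% stab$selected,
                         stringsAsFactors = FALSE)
  write_csv_prov(freq_tab[order(-freq_tab$frequency), ],
                 file.path(out, "selection_frequencies.csv"), hash)
  writeLines(
    jsonlite::toJSON(list(
      selected = stab$selected, n_runs = stab$n_runs,
      threshold = stab$threshold, resample = stab$resample,
      seed = stab$seed, n_redraws = stab$n_redraws, config_hash = hash
    ), auto_unbox = TRUE, pretty = TRUE),
    file.path(out, "selection_summary.json")
  )

  # --- survival models
  clinical_covs <- c("gender", "age", "stage", "site_group",
                     if (config$include_cht) "cht")
  uni <- do.call(rbind, lapply(clinical_covs, function(cv) {
    f <- cox_fit(cohort, cv)
    cbind(covariate = cv, f$table)
  }))
  write_csv_prov(uni, file.path(out, "univariate_cox.csv"), hash)

  fit_clin <- cox_fit(cohort, clinical_covs)
  # age and stage are force-included alongside the selected imaging features
  selected_imaging <- intersect(stab$selected, pool)
  imaging_covs <- unique(c("age", "stage",
                           if (config$include_cht && "cht" %in% stab$selected) "cht",
                           selected_imaging))
  fit_img <- cox_fit(cohort, imaging_covs)
  write_csv_prov(fit_clin$table, file.path(out, "multivariate_clinical.csv"),
                 hash)
  write_csv_prov(fit_img$table,
                 file.path(out, "multivariate_clinical_imaging.csv"), hash)

  cv_clin <- crossvalidated_cindex(cohort, clinical_covs, k = config$cv_folds,
                                   seed = derive_seed(config$seed, 4))
  cv_img <- crossvalidated_cindex(cohort, imaging_covs, k = config$cv_folds,
                                  seed = derive_seed(config$seed, 5))
  cmp <- compare_cindex(cv_img$risk, cv_clin$risk, cohort$time_months,
                        cohort$event, n_boot = config$n_boot,
                        seed = derive_seed(config$seed, 6))

  km_feature <- if (length(selected_imaging)) selected_imaging[1] else
    names(config$log_hr)[1]
  km <- km_median_split(cohort, km_feature)
  km_tab <- rbind(
    data.frame(group = "low", time = km$low$time, surv = km$low$surv,
               n_risk = km$low$n_risk),
    data.frame(group = "high", time = km$high$time, surv = km$high$surv,
               n_risk = km$high$n_risk)
  )
  write_csv_prov(km_tab, file.path(out, "km_median_split.csv"), hash)

  run <- structure(
    list(
      config = config, config_hash = hash, ids = ids, filter = filt,
      features = features, cohort = cohort, stability = stab,
      univariate = uni, fit_clinical = fit_clin, fit_imaging = fit_img,
      cv_clinical = cv_clin, cv_imaging = cv_img, comparison = cmp,
      km_feature = km_feature, km = km, output_dir = out
    ),
    class = "pipeline_run"
  )
  report <- make_report(run)
  writeLines(report, file.path(out, "report.txt"))
  run
}

#' Human-readable run report
#'
#' A pure function of the run object: regenerating the report from the same
#' run yields identical text. Summarizes exclusions (with volumes), selection
#' frequencies, the model tables and the c-index comparison.
#'
#' @param run A `pipeline_run` from [run_pipeline()].
#' @return Character vector of report lines, invisibly printable.
#' @export
make_report <- function(run) {
  stopifnot(inherits(run, "pipeline_run"))
  fmt_tab <- function(df) {
    utils::capture.output(print(format(df, digits = 4), row.names = FALSE))
  }
  excl <- run$filter$table[!run$filter$table$retained, , drop = FALSE]
  lines <- c(
    "petrad pipeline report",
    sprintf("config hash: %s", run$config_hash),
    "",
    sprintf("subjects: %d generated, %d retained, %d excluded by the %.3g ml volume filter",
            length(run$ids), length(run$filter$retained), nrow(excl),
            run$config$volume_threshold_ml),
    if (nrow(excl)) c("excluded subjects:",
                      sprintf("  %s: %.3f ml", excl$id, excl$volume_ml)),
    "",
    sprintf("stability selection (%d runs, threshold > %.2f):",
            run$stability$n_runs, run$stability$threshold),
    sprintf("  %s: %.3f%s", names(run$stability$frequency),
            run$stability$frequency,
            ifelse(names(run$stability$frequency) %in% run$stability$selected,
                   "  [selected]", "")),
    if (!length(intersect(run$stability$selected, imaging_feature_names())))
      "  note: no imaging feature passed the selection threshold",
    "",
    "univariate Cox models:",
    fmt_tab(run$univariate),
    "",
    sprintf("multivariate clinical-only model (c-index %.3f, CV c-index %.3f):",
            run$fit_clinical$cindex, run$cv_clinical$cindex),
    fmt_tab(run$fit_clinical$table),
    "",
    sprintf("multivariate clinical+imaging model (c-index %.3f, CV c-index %.3f):",
            run$fit_imaging$cindex, run$cv_imaging$cindex),
    fmt_tab(run$fit_imaging$table),
    "",
    sprintf("paired-bootstrap c-index comparison: delta = %.4f (95%% CI %.4f to %.4f), p = %.4g",
            run$comparison$delta, run$comparison$ci[1], run$comparison$ci[2],
            run$comparison$p_value),
    "",
    sprintf("Kaplan-Meier median split on %s (median %.4g): log-rank chisq %.3f, p = %.4g (n = %d low / %d high)",
            run$km_feature, run$km$median, run$km$logrank_chisq,
            run$km$p_value, run$km$n_low, run$km$n_high)
  )
  unlist(lines)
}
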