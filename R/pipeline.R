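#' Full run configuration
#'
#' All pipeline constants in one place, with defaults fixed at the
#' protocol's stated values: 300-px clustering threshold, 10,000-cell
#' subsample, 15-px merge radius, 20-px match radius, 252-px patches.
#'
#' @param distance_threshold_px clustering agglomeration threshold.
#' @param subsample_max clustering subsample cap.
#' @param merge_radius_px cross-channel detection merge radius.
#' @param match_radius_px detection-evaluation match radius.
#' @param patch_px patch tiling side.
#' @param sigma_px Gaussian sigma of density labels.
#' @param min_probability local-maxima detection threshold.
#' @param min_group_frac minimum group fraction for cutoff feasibility.
#' @param cv_folds folds of the cutoff cross-validation.
#' @param seed master seed.
#' @return Named list.
#' @export
run_config <- function(distance_threshold_px = 300, subsample_max = 10000,
                       merge_radius_px = 15, match_radius_px = 20,
                       patch_px = 252, sigma_px = 3, min_probability = 0.5,
                       min_group_frac = 0.1, cv_folds = 3, seed = 1L) {
  list(distance_threshold_px = distance_threshold_px,
       subsample_max = as.integer(subsample_max),
       merge_radius_px = merge_radius_px,
       match_radius_px = match_radius_px,
       patch_px = as.integer(patch_px), sigma_px = sigma_px,
       min_probability = min_probability,
       min_group_frac = min_group_frac,
       cv_folds = as.integer(cv_folds), seed = as.integer(seed))
}

write_manifest <- function(out_dir, what, config, inputs = character(0)) {
  hashes <- vapply(inputs, function(p)
    if (file.exists(p)) as.character(tools::md5sum(p)) else NA_character_,
    character(1))
  jsonlite::write_json(
    list(command = what, config = config,
         inputs = as.list(hashes), timestamp = format(Sys.time(), tz = "UTC")),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
}

#' Score one or many slides from files
#'
#' Reads each cell table (and the matching region file, when given), scores
#' it under the chosen setting and writes `scores.csv` plus a manifest to
#' `out_dir`. Unscorable slides are reported and skipped; the run fails
#' only if every slide fails.
#'
#' @param cell_paths character vector of cell-table CSV paths.
#' @param region_paths optional GeoJSON paths aligned with `cell_paths`.
#' @param setting `"WITHOUT_DCIS"` or `"WITH_DCIS"`.
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return The scores data.frame, invisibly.
#' @export
run_score <- function(cell_paths, region_paths = NULL,
                      setting = c("WITHOUT_DCIS", "WITH_DCIS"),
                      config = run_config(), out_dir = ".") {
  setting <- match.arg(setting)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cc <- clustering_config(config$distance_threshold_px,
                          config$subsample_max, config$seed)
  scores <- list(); failed <- character(0)
  for (i in seq_along(cell_paths)) {
    res <- tryCatch({
      cells <- read_cells(cell_paths[i])
      regions <- if (!is.null(region_paths) && !is.na(region_paths[i]))
        read_regions(region_paths[i]) else NULL
      sc_setting <- if (is.null(regions)) "WITHOUT_DCIS" else setting
      score_slide(cells, regions = regions, setting = sc_setting,
                  config = cc)
    }, ki67cl_error = function(e) e)
    if (inherits(res, "ki67cl_error")) {
      warning(sprintf("slide %s unscorable: %s",
                      cell_paths[i], conditionMessage(res)), call. = FALSE)
      failed <- c(failed, cell_paths[i])
    } else scores[[length(scores) + 1L]] <- res
  }
  if (length(scores) == 0L)
    ki67cl_stop("all_failed", "no slide could be scored")
  df <- scores_to_df(scores)
  utils::write.csv(df, file.path(out_dir, "scores.csv"), row.names = FALSE)
  write_manifest(out_dir, "score", config,
                 c(cell_paths, region_paths[!is.na(region_paths)]))
  invisible(df)
}

#' Run the survival validation protocol from files
#'
#' Joins a slide-score table to a per-patient survival table on patient id,
#' then either stratifies at a fixed cutoff or runs the cross-validated
#' cutoff protocol. Results (KM curves, log-rank p, C-index, Cox table, CV
#' summary) are written as CSV/JSON to `out_dir`.
#'
#' @param scores_df data.frame with `slide_id` (treated as patient id) and a
#'   marker column, e.g. from [run_score()].
#' @param survival_df a [survival_table()] or raw data.frame with
#'   `patient_id`, `time`, `event` columns.
#' @param marker which score column to use (`"ki67cl"` or `"autoki67"`).
#' @param mode `"cv"` for cross-validated cutoff selection or `"fixed"` for
#'   a fixed cutoff.
#' @param cutoff fixed cutoff when `mode = "fixed"` (default 0.375, the
#'   published Ki67CL operating point).
#' @param covariates optional covariate columns for a multivariate Cox fit.
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return list with elements `records`, and `cv` ([cross_validate_marker()]
#'   output) or `stratification` ([stratify_at_cutoff()] output), plus
#'   `cox`.
#' @export
run_survival <- function(scores_df, survival_df, marker = "ki67cl",
                         mode = c("cv", "fixed"), cutoff = 0.375,
                         covariates = character(0),
                         config = run_config(), out_dir = ".") {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!marker %in% names(scores_df))
    ki67cl_stop("missing_column", "marker column '%s' absent from scores", marker)
  merged <- merge(survival_df,
                  scores_df[, c("slide_id", marker)],
                  by.x = "patient_id", by.y = "slide_id")
  n_drop <- nrow(survival_df) - nrow(merged)
  if (nrow(merged) == 0L)
    ki67cl_stop("empty_join", "no patients shared between scores and survival table")
  if (n_drop > 0)
    message(sprintf("%d survival record(s) had no matching slide score", n_drop))
  merged$marker <- merged[[marker]]
  records <- survival_table(merged)
  out <- list(records = records)
  if (mode == "cv") {
    out$cv <- cross_validate_marker(records, k = config$cv_folds,
                                    seed = config$seed,
                                    min_group_frac = config$min_group_frac)
    jsonlite::write_json(
      list(per_fold = out$cv$per_fold, combined_p = out$cv$combined_p,
           combined_c = as.list(out$cv$combined_c),
           chosen_cutoff = out$cv$chosen_cutoff),
      file.path(out_dir, "cv_summary.json"), auto_unbox = TRUE, digits = NA)
  } else {
    out$stratification <- stratify_at_cutoff(records, cutoff)
    utils::write.csv(out$stratification$km_curves$low,
                     file.path(out_dir, "km_low.csv"), row.names = FALSE)
    utils::write.csv(out$stratification$km_curves$high,
                     file.path(out_dir, "km_high.csv"), row.names = FALSE)
  }
  terms <- c("marker", covariates)
  out$cox <- tryCatch(
    cox_fit(records, terms,
            model_type = if (length(covariates)) "MULTIVARIATE" else "UNIVARIATE"),
    ki67cl_error = function(e) NULL)
  if (!is.null(out$cox))
    utils::write.csv(as.data.frame(out$cox), file.path(out_dir, "cox.csv"),
                     row.names = FALSE)
  write_manifest(out_dir, paste0("survival-", mode), config)
  out
}
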