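## End-to-end report assembly: the statistics that can be reproduced from
## the packaged reference tables alone (fixture mode), and the summaries of
## a simulated pipeline run (FEM couplings + staircase cohort).

#' Statistics derived from the packaged reference tables
#'
#' Recomputes, from the shipped fixture tables alone (no FEM run):
#' the Pearson regression of the five unilateral eye-specific montages'
#' mean thresholds on their eye-model current densities, the per-montage
#' eye-model minus brain-model density differences, and the one-tailed
#' Spearman correlations of the threshold medians with the eye and
#' occipital-cortex densities.
#'
#' @param fixtures a [load_fixtures()] result.
#' @return list: `eye_regression` (`stats_result`), `model_difference`
#'   (data.frame montage/difference in mA/m^2), `spearman_eye`,
#'   `spearman_oc_right` (`stats_result`s).
#' @export
fixture_statistics <- function(fixtures = load_fixtures()) {
  t1 <- fixtures$table1
  f4 <- fixtures$fig4
  mean_pt <- t1$mean_pt_uA[match(f4$montage, t1$montage)]
  reg <- pearson_regression(f4$eye_density_eye_model, mean_pt)
  md <- data.frame(
    montage = t1$montage,
    difference_mA_m2 = round(t1$eye_density_eye_model -
                               t1$eye_density_brain_model, 1))
  sp_eye <- spearman_cor(t1$eye_density_eye_model, t1$median_pt_uA,
                         sided = "less")
  t2 <- fixtures$table2
  sp_oc <- spearman_cor(t2$oc_right, t2$median_pt_uA, sided = "greater")
  list(eye_regression = reg, model_difference = md,
       spearman_eye = sp_eye, spearman_oc_right = sp_oc)
}

#' Assemble the pipeline report bundle
#'
#' Collects the stage outputs into one bundle mirroring the reference-table
#' structure (montage x {median PT, mean +/- SD PT, ROI densities}) plus the
#' statistical results, and optionally writes CSV/JSON files. Stages may be
#' omitted; requesting a summary whose stage is missing raises an error
#' naming the gap.
#'
#' @param fixtures optional [load_fixtures()] result.
#' @param roi_table optional [roi_summary_table()] result.
#' @param study optional [simulate_study()] result.
#' @param distances optional distance data.frame (`montage`, `eye_cm`,
#'   `oc_cm`).
#' @param out_dir optional output directory for CSV/JSON files.
#' @param seed seed recorded in the metadata.
#' @return list of class `phosfem_report`.
#' @export
build_report <- function(fixtures = NULL, roi_table = NULL, study = NULL,
                         distances = NULL, out_dir = NULL, seed = NULL) {
  report <- list()
  if (!is.null(fixtures)) report$fixture_stats <- fixture_statistics(fixtures)
  if (!is.null(study)) {
    pt <- study$pt
    report$pt_summary <- data.frame(
      montage = colnames(pt),
      median_pt_uA = apply(pt, 2, stats::median, na.rm = TRUE),
      mean_pt_uA = colMeans(pt, na.rm = TRUE),
      sd_pt_uA = apply(pt, 2, stats::sd, na.rm = TRUE),
      n_valid = colSums(!is.na(pt)))
  }
  if (!is.null(roi_table)) report$roi_table <- roi_table
  if (!is.null(roi_table) && !is.null(study)) {
    ## couple montage retinal density to the simulated medians
    ret <- roi_table[roi_table$roi == "retina_right", ]
    med <- report$pt_summary$median_pt_uA[
      match(ret$montage, report$pt_summary$montage)]
    keep <- !is.na(med)
    if (sum(keep) >= 3)
      report$density_vs_pt <- spearman_cor(ret$mean_mA_m2_per_mA[keep],
                                           med[keep], sided = "less")
  }
  if (!is.null(distances)) {
    if (is.null(study))
      stop("missing stage output: 'study' is needed for the distance analysis")
    pt_med <- setNames(report$pt_summary$median_pt_uA,
                       report$pt_summary$montage)
    report$distance_stats <- distance_analysis(distances, pt_med)
  }
  report$metadata <- list(package = "phosfem",
                          version = as.character(utils::packageVersion("phosfem")),
                          seed = seed, date = format(Sys.time(), "%Y-%m-%d"))
  class(report) <- "phosfem_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a report bundle to disk
#'
#' @param report a [build_report()] result.
#' @param out_dir directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(report$pt_summary)) wcsv(report$pt_summary, "pt_summary.csv")
  if (!is.null(report$roi_table)) wcsv(report$roi_table, "roi_summary.csv")
  if (!is.null(report$fixture_stats))
    wcsv(report$fixture_stats$model_difference, "model_difference.csv")
  stats_to_list <- function(x) {
    if (inherits(x, "stats_result")) unclass(x)
    else if (is.list(x)) lapply(x, stats_to_list)
    else x
  }
  jp <- file.path(out_dir, "stats.json")
  jsonlite::write_json(
    stats_to_list(report[setdiff(names(report),
                                 c("pt_summary", "roi_table"))]),
    jp, auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  paths <- c(paths, jp)
  invisible(paths)
}

#' @export
print.phosfem_report <- function(x, ...) {
  cat("phosfem_report with:",
      paste(setdiff(names(x), "metadata"), collapse = ", "), "\n")
  if (!is.null(x$fixture_stats)) {
    r2 <- x$fixture_stats$eye_regression$estimate["r2"]
    cat(sprintf("  eye-density regression: r2 = %.2f\n", r2))
  }
  if (!is.null(x$pt_summary)) {
    cat("  simulated median PTs (uA):\n")
    print(setNames(x$pt_summary$median_pt_uA, x$pt_summary$montage))
  }
  invisible(x)
}
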