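# Human-readable outputs: tidy CSV exports of the report tables and of the
# data layers behind the standard figures (no plotting dependency).

check_report <- function(report, fields) {
  stopifnot(inherits(report, "analysis_report"))
  for (f in fields) {
    if (is.null(report[[f]])) {
      stop("report is missing stage output '", f, "'", call. = FALSE)
    }
  }
  invisible(report)
}

#' Export figure-ready data layers from an analysis report
#'
#' Writes four tidy CSVs, pure functions of the report (an identical report
#' yields byte-identical files):
#'
#' * `gradient_scores.csv` — one row per specimen: projection of each
#'   individual shape onto the admixture regression vector (N rows).
#' * `distance_scatter.csv` — one row per group pair: Procrustes vs genomic
#'   distance, with flags for pairs closer than 20 percentage points and for
#'   pairs whose shape-change direction is not consistent with the
#'   mus-to-dom transition (C(G,2) rows).
#' * `group_variance_fa.csv` — one row per group: phenotypic variance (and
#'   its square root) plus mean fluctuating asymmetry (G rows).
#' * `bgpca_ordination.csv` — individuals and group means on the
#'   between-group PC axes (N + G rows).
#'
#' @param report An [run_full_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
export_figure_data <- function(report, dir) {
  check_report(report, c("gradient_results", "pairwise_table",
                         "distance_correlation", "direction_table",
                         "group_table", "grouping"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cov <- report$grouping$covariates
  reg <- report$gradient_results$regression

  grad <- data.frame(specimen_id = cov$specimen_id, group = cov$group,
                     pct_dom = cov$pct_dom,
                     sex = if ("sex" %in% names(cov)) cov$sex else NA,
                     projection_score = unname(reg$projection_scores))
  f1 <- file.path(dir, "gradient_scores.csv")
  utils::write.csv(grad, f1, row.names = FALSE)

  pw <- report$pairwise_table
  dirn <- report$direction_table
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  consistent <- dirn$consistent[match(key(pw$group_1, pw$group_2),
                                      key(dirn$group_low, dirn$group_high))]
  scatter <- data.frame(group_1 = pw$group_1, group_2 = pw$group_2,
                        procrustes_distance = pw$procrustes_distance,
                        genomic_distance = pw$genomic_distance,
                        genomic_lt20 = pw$genomic_distance < 20,
                        direction_consistent = consistent)
  f2 <- file.path(dir, "distance_scatter.csv")
  utils::write.csv(scatter, f2, row.names = FALSE)

  f3 <- file.path(dir, "group_variance_fa.csv")
  utils::write.csv(report$gradient_results$group_variance, f3, row.names = FALSE)

  bg <- report$gradient_results$bgpca
  m <- ncol(bg$axes)
  ord <- rbind(
    data.frame(kind = "group_mean", id = rownames(bg$group_scores),
               group = rownames(bg$group_scores),
               bg$group_scores, check.names = FALSE),
    data.frame(kind = "individual", id = cov$specimen_id,
               group = as.character(cov$group),
               bg$ind_scores, check.names = FALSE)
  )
  f4 <- file.path(dir, "bgpca_ordination.csv")
  utils::write.csv(ord, f4, row.names = FALSE)

  invisible(c(gradient_scores = f1, distance_scatter = f2,
              group_variance_fa = f3, bgpca_ordination = f4))
}

#' Write the report tables to CSV plus a JSON summary
#'
#' Writes the per-group summary table, the pairwise mean-shape comparison
#' table, the direction-comparison table, the size pairwise p-values, the
#' distance-correlation results, and a machine-readable `summary.json` of
#' the headline statistics.
#'
#' @param report An [run_full_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_report_tables <- function(report, dir) {
  check_report(report, c("group_table", "size_results", "extremes_comparison",
                         "gradient_results", "pairwise_table",
                         "distance_correlation", "direction_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    group_table = file.path(dir, "group_table.csv"),
    size_pairwise = file.path(dir, "size_pairwise_p.csv"),
    pairwise = file.path(dir, "pairwise_comparisons.csv"),
    direction = file.path(dir, "direction_comparisons.csv"),
    distance = file.path(dir, "distance_correlation.csv"),
    summary = file.path(dir, "summary.json")
  )
  utils::write.csv(report$group_table, paths[["group_table"]], row.names = FALSE)
  utils::write.csv(as.data.frame(report$size_results$pairwise$p_adjusted),
                   paths[["size_pairwise"]], row.names = TRUE)
  utils::write.csv(report$pairwise_table, paths[["pairwise"]], row.names = FALSE)
  utils::write.csv(report$direction_table, paths[["direction"]], row.names = FALSE)
  dc <- report$distance_correlation
  utils::write.csv(data.frame(
    set = c("all_pairs", "genomic_lt20"),
    r = c(dc$mantel$r, dc$subset_lt20$r),
    p = c(dc$mantel$p_perm, dc$subset_lt20$p_perm),
    n_pairs = c(sum(upper.tri(dc$procrustes_matrix)), dc$subset_lt20$n_pairs)
  ), paths[["distance"]], row.names = FALSE)

  ex <- report$extremes_comparison
  reg <- report$gradient_results$regression
  summary <- list(
    trait = report$trait,
    n_specimens = sum(report$group_table$n),
    n_groups = nrow(report$group_table),
    allometry_pct = report$allometry$pct_var_explained,
    regression = list(pct_var_explained = reg$pct_var_explained,
                      p_perm = reg$p_perm, n_perm = reg$n_perm),
    extremes = list(t2 = ex$hotelling$t2, df1 = ex$hotelling$df1,
                    df2 = ex$hotelling$df2, p = ex$hotelling$p_raw,
                    misclassification = ex$misclassification,
                    procrustes_distance = ex$procrustes_distance),
    mantel = list(r = dc$mantel$r, p = dc$mantel$p_perm),
    n_pairwise_significant = sum(report$pairwise_table$p_holm < 0.05),
    n_direction_consistent = sum(report$direction_table$consistent),
    n_pairs = nrow(report$pairwise_table),
    seed = report$seed
  )
  jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
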