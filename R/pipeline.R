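#' Run the full two-stage MET analysis
#'
#' Chains the stages on a plot-level dataset: stage-one model search
#' and BLUE extraction per trial, assembly of the weighted MET table,
#' FA order selection by AIC, principal-axis rotation, FAST summaries,
#' and — when an environment covariate table is supplied — contrast
#' selection, tolerance indices and the latent-covariate linkage.
#'
#' @param ds `famet_trials` plot dataset.
#' @param cfg `famet_config`.
#' @param env_covariates optional covariate table from
#'   [build_env_covariates()].
#' @param stage1_catalog optional restricted stage-one spec catalog.
#' @param out_dir optional directory; when given, every result table
#'   is also written as CSV.
#' @return list with `stage1`, `met`, `comparison`, `fit` (rotated),
#'   `correlations`, `clusters`, `variance`, `stability`, and (with
#'   covariates) `contrast`, `tolerance`, `linkage`.
#' @export
run_pipeline <- function(ds, cfg = analysis_config(),
                         env_covariates = NULL, stage1_catalog = NULL,
                         out_dir = NULL) {
  s1 <- run_stage1(ds, catalog = stage1_catalog)
  met <- build_met_table(s1$predictions)
  sel <- select_met_model(met, k_max = min(cfg$fa_k_max,
                                           length(met$environments) - 1))
  fit <- rotate_loadings(sel$fit)
  R <- genetic_correlations(fit)
  res <- list(stage1 = s1, met = met, comparison = sel$comparison,
              fit = fit,
              correlations = R,
              clusters = cluster_environments(R, min(4, nrow(R))),
              variance = variance_explained(fit),
              stability = rank_performance_stability(fast_tables(fit)))
  if (!is.null(env_covariates)) {
    res$contrast <- select_contrast_environments(env_covariates,
                                                 cfg$n_contrast_envs)
    res$tolerance <- tolerance_table(fit, res$contrast)
    res$linkage <- list(
      loadings = correlate_loadings_covariates(fit$Lambda,
                                               env_covariates),
      slopes = correlate_slopes_tolerance(fit$scores, res$tolerance))
  }
  if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir)
  res
}

.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) write.csv(x, file.path(out_dir, f),
                                row.names = FALSE)
  w(res$stage1$predictions, "stage1_predictions.csv")
  w(res$stage1$selection, "stage1_model_selection.csv")
  w(res$comparison, "fa_model_comparison.csv")
  ve <- res$variance
  w(data.frame(environment = rownames(res$fit$Lambda), res$fit$Lambda,
               psi = res$fit$Psi, cum_pct = ve$env_cum_pct),
    "fa_loadings.csv")
  w(data.frame(environment = rownames(res$correlations),
               res$correlations, cluster = res$clusters),
    "genetic_correlations.csv")
  w(res$stability, "stability.csv")
  if (!is.null(res$tolerance)) {
    w(res$tolerance, "tolerance.csv")
    w(data.frame(covariate = rownames(res$linkage$loadings),
                 res$linkage$loadings), "linkage_loadings.csv")
    w(data.frame(index = rownames(res$linkage$slopes),
                 res$linkage$slopes), "linkage_slopes.csv")
  }
  invisible(out_dir)
}

#' Performance-vs-stability scatter
#'
#' Predicted yield against Shukla's stability variance, the top and
#' bottom performers highlighted and a dashed line at the mean
#' stability.
#'
#' @param st labelled table from [rank_performance_stability()].
#' @return a ggplot object.
#' @export
plot_performance_stability <- function(st) {
  ggplot2::ggplot(st, ggplot2::aes(x = .data$predicted_yield,
                                   y = .data$shukla_var,
                                   colour = .data$label)) +
    ggplot2::geom_hline(yintercept = attr(st, "mean_stability"),
                        linetype = "dashed", colour = "blue") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_text(ggplot2::aes(label = .data$genotype),
                       vjust = -0.8, size = 2.8, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(top = "forestgreen",
                                            bottom = "red3",
                                            mid = "gold2")) +
    ggplot2::labs(x = "predicted yield (t/ha)",
                  y = "Shukla stability variance", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Latent-regression panel for one hybrid and factor
#'
#' @param lr data from [latent_regression()].
#' @return a ggplot object.
#' @export
plot_latent_regression <- function(lr) {
  ggplot2::ggplot(lr$points, ggplot2::aes(x = .data$loading,
                                          y = .data$blup)) +
    ggplot2::geom_abline(slope = lr$slope, intercept = 0,
                         colour = "red", linewidth = 0.8) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$environment),
                       vjust = -0.7, size = 2.6) +
    ggplot2::labs(title = sprintf("%s, factor %d (slope %.2f)",
                                  lr$hybrid, lr$factor, lr$slope),
                  x = sprintf("factor %d loading", lr$factor),
                  y = "genetic effect (BLUP, t/ha)") +
    ggplot2::theme_minimal()
}

#' Genetic-correlation heatmap with cluster labels
#'
#' @param R correlation matrix from [genetic_correlations()].
#' @param clusters labels from [cluster_environments()].
#' @return a ggplot object.
#' @export
plot_correlation_heatmap <- function(R, clusters = NULL) {
  ord <- hclust(as.dist(1 - R), method = "average")$order
  df <- expand.grid(e1 = rownames(R)[ord], e2 = colnames(R)[ord])
  df$r <- R[cbind(as.character(df$e1), as.character(df$e2))]
  ggplot2::ggplot(df, ggplot2::aes(.data$e1, .data$e2,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0.5,
                                  limits = c(min(R), 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "genetic r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Environment means against drought indices
#'
#' Dual view of average environment yield with seasonal VPD and scPDSI,
#' the sawtooth diagnostic relating yield level to drought status.
#'
#' @param cov covariate table with `environment`, `vpd_kpa`, `scpdsi`.
#' @param env_means named vector of environment mean yields (t/ha).
#' @return a ggplot object.
#' @export
plot_yield_vs_indices <- function(cov, env_means) {
  df <- cov[order(env_means[cov$environment]), ]
  df$environment <- factor(df$environment, levels = df$environment)
  df$yield <- env_means[as.character(df$environment)]
  long <- rbind(
    data.frame(environment = df$environment, what = "yield (t/ha)",
               value = df$yield),
    data.frame(environment = df$environment, what = "VPD (kPa)",
               value = df$vpd_kpa),
    data.frame(environment = df$environment, what = "scPDSI",
               value = df$scpdsi))
  ggplot2::ggplot(long, ggplot2::aes(.data$environment, .data$value,
                                     group = .data$what)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$what),
                        scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
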