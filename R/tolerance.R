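#' Select contrast (stress vs normal) environments
#'
#' Composite rank: mean of the rank by seasonal scPDSI ascending (most
#' negative = most stressed) and the rank by seasonal VPD descending
#' (highest atmospheric demand = most stressed). The `n` top composite
#' ranks are the stress set, the `n` bottom the normal set; ties are
#' broken by environment id. Environments missing either index are
#' excluded with a warning.
#'
#' @param cov environment covariate table from
#'   [build_env_covariates()] (needs `environment`, `scpdsi`,
#'   `vpd_kpa`).
#' @param n environments per set.
#' @return list with `stress_envs`, `normal_envs`, `ranking`
#'   diagnostics data.frame.
#' @export
select_contrast_environments <- function(cov, n = 3) {
  keep <- !is.na(cov$scpdsi) & !is.na(cov$vpd_kpa)
  if (any(!keep))
    warning("environment(s) without both indices excluded: ",
            paste(cov$environment[!keep], collapse = ", "))
  cov <- cov[keep, ]
  if (nrow(cov) < 2 * n) stop("need at least ", 2 * n, " environments")
  r_pdsi <- rank(cov$scpdsi, ties.method = "average")
  r_vpd <- rank(-cov$vpd_kpa, ties.method = "average")
  composite <- (r_pdsi + r_vpd) / 2
  if (anyDuplicated(composite))
    warning("ties in composite stress rank broken by environment id")
  ord <- order(composite, cov$environment)
  ranking <- data.frame(environment = cov$environment,
                        scpdsi = cov$scpdsi, vpd_kpa = cov$vpd_kpa,
                        composite_rank = composite)[ord, ]
  list(stress_envs = ranking$environment[seq_len(n)],
       normal_envs = rev(ranking$environment)[seq_len(n)],
       ranking = ranking)
}

#' Geometric mean productivity
#'
#' `GMP = sqrt(Yp * Ys)` over the normal-environment mean yield `Yp`
#' and the stress-environment mean `Ys`.
#'
#' @param Yp,Ys non-negative mean yields (t/ha).
#' @return GMP.
#' @export
gmp <- function(Yp, Ys) {
  if (any(Yp < 0 | Ys < 0)) stop("yields must be non-negative")
  sqrt(Yp * Ys)
}

#' Relative decrease in yield
#'
#' Default convention: `RDY = 100 * (Yp - Ys) / Yp`, the percent yield
#' decrease under stress; negative values mean a yield gain under
#' stress. An alternative ratio convention `Ys / Yp` is selectable.
#'
#' @param Yp positive non-stress mean yield.
#' @param Ys stress mean yield.
#' @param convention `"percent"` (default) or `"ratio"`.
#' @return RDY.
#' @export
rdy <- function(Yp, Ys, convention = c("percent", "ratio")) {
  convention <- match.arg(convention)
  if (any(Yp <= 0)) stop("Yp must be positive")
  if (convention == "percent") 100 * (Yp - Ys) / Yp else Ys / Yp
}

#' Per-hybrid drought-tolerance table
#'
#' `Yp`/`Ys` are means of the stage-two fitted yields
#' (`mu_j + u[i,j]`) over the selected normal and stress environments.
#'
#' @param fit `famet_fafit`.
#' @param contrast selection from [select_contrast_environments()].
#' @param convention RDY convention, see [rdy()].
#' @return data.frame with `hybrid`, `Yp`, `Ys`, `GMP`, `RDY`.
#' @export
tolerance_table <- function(fit, contrast, convention = "percent") {
  fitted <- sweep(fit$blups, 2, fit$mu, "+")
  Yp <- rowMeans(fitted[, contrast$normal_envs, drop = FALSE])
  Ys <- rowMeans(fitted[, contrast$stress_envs, drop = FALSE])
  data.frame(hybrid = rownames(fitted), Yp = Yp, Ys = Ys,
             GMP = gmp(Yp, Ys), RDY = rdy(Yp, Ys, convention),
             row.names = NULL)
}

#' Correlate rotated loadings with environmental covariates
#'
#' Pearson correlation of each factor's loading vector with each
#' covariate column across environments; zero-variance covariates are
#' reported as `NA`.
#'
#' @param Lambda rotated J x k loading matrix with environment
#'   rownames.
#' @param cov covariate table from [build_env_covariates()].
#' @param covariates covariate columns to use.
#' @return covariates x factors correlation matrix.
#' @export
correlate_loadings_covariates <- function(Lambda, cov,
    covariates = c("tmin_c", "tmax_c", "tavg_c", "rainfall_mm",
                   "rh_pct", "vpd_kpa", "scpdsi")) {
  if (nrow(Lambda) < 4) stop("need >= 4 environments")
  cov <- cov[match(rownames(Lambda), cov$environment), ]
  covariates <- intersect(covariates, names(cov))
  out <- matrix(NA_real_, length(covariates), ncol(Lambda),
                dimnames = list(covariates,
                                paste0("FA", seq_len(ncol(Lambda)))))
  for (cv in covariates) {
    x <- cov[[cv]]
    if (all(is.na(x)) || sd(x, na.rm = TRUE) == 0) next
    for (m in seq_len(ncol(Lambda)))
      out[cv, m] <- cor(x, Lambda[, m], use = "complete.obs")
  }
  out
}

#' Correlate latent-regression slopes with tolerance indices
#'
#' Pearson correlations of each factor's genotype scores (the latent
#' regression slopes `beta_m`) with GMP and RDY across hybrids;
#' constant indices or scores give `NA`.
#'
#' @param scores I x k genotype score matrix with hybrid rownames.
#' @param tol tolerance table from [tolerance_table()].
#' @return indices x factors correlation matrix.
#' @export
correlate_slopes_tolerance <- function(scores, tol) {
  if (nrow(scores) < 5) stop("need >= 5 hybrids")
  tol <- tol[match(rownames(scores), tol$hybrid), ]
  out <- matrix(NA_real_, 2, ncol(scores),
                dimnames = list(c("GMP", "RDY"),
                                paste0("beta", seq_len(ncol(scores)))))
  for (idx in c("GMP", "RDY")) {
    x <- tol[[idx]]
    if (sd(x) == 0) next
    for (m in seq_len(ncol(scores))) {
      if (sd(scores[, m]) == 0) next
      out[idx, m] <- cor(x, scores[, m])
    }
  }
  out
}
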