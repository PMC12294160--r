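#' Worked example: rotated FA(2) loadings from a published maize MET
#'
#' Rotated environmental factor loadings, and the per-environment
#' cumulative % of genetic variance explained, from a published
#' two-factor analysis of grain yield of 32 maize hybrids grown in 12
#' environments (6 Croatian locations x 2 years). Specific variances
#' are not printed in such tables; [example_fa2_fit()] reconstructs
#' them with [invert_env_cumpct()].
#'
#' @return data.frame with `location`, `year`, `fa1`, `fa2`,
#'   `cum_pct` and an `environment` key column.
#' @export
example_fa2_loadings <- function() {
  df <- read.csv(system.file("extdata", "fa2_loadings.csv",
                             package = "famet"))
  df$environment <- env_key(df$location, df$year)
  df
}

#' Worked example: FA model comparison statistics
#'
#' Variance-parameter counts and REML log-likelihoods of the FA(1)..
#' FA(5) fits from the same published maize MET analysis as
#' [example_fa2_loadings()]. AIC is recomputed with [fa_aic()].
#'
#' @return data.frame with `model`, `n_vc`, `logLik`, `AIC`.
#' @export
example_fa_comparison <- function() {
  df <- read.csv(system.file("extdata", "fa_model_comparison.csv",
                             package = "famet"))
  df$AIC <- fa_aic(df$logLik, df$n_vc)
  df
}

#' Reconstruct the worked-example FA(2) parameter set
#'
#' Builds a complete loading/specific-variance parameter set from the
#' printed loadings of [example_fa2_loadings()], inverting each
#' environment's cumulative-%-explained to recover its specific
#' variance. The result can be passed to [genetic_correlations()],
#' [variance_explained()] and [cluster_environments()].
#'
#' @return list with `Lambda` (12 x 2, rotated), `Psi` (length 12),
#'   environment names as dimnames.
#' @export
example_fa2_fit <- function() {
  df <- example_fa2_loadings()
  Lambda <- as.matrix(df[c("fa1", "fa2")])
  rownames(Lambda) <- df$environment
  Psi <- vapply(seq_len(nrow(df)), function(j)
    invert_env_cumpct(Lambda[j, ], df$cum_pct[j]), 0)
  names(Psi) <- df$environment
  list(Lambda = Lambda, Psi = Psi, k = 2L, rotated = TRUE)
}
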