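#' Shukla's stability variance from a two-way table
#'
#' For a complete genotype x environment table `x` with interaction
#' residuals `w[i,j] = x[i,j] - mean_i - mean_j + grand mean`:
#' `sigma2_i = I / ((I-2)(J-1)) * sum_j w[i,j]^2 -
#'             SS_GE / ((I-1)(I-2)(J-1))`.
#' The estimator can be slightly negative; values are clipped at zero
#' and flagged. Missing cells must be filled with model-based fitted
#' values before calling (see [fast_tables()]).
#'
#' @param x complete I x J numeric matrix, `I >= 3`, `J >= 2`.
#' @return data.frame with `genotype`, `shukla_var`, `clipped`.
#' @export
shukla_stability <- function(x) {
  I <- nrow(x); J <- ncol(x)
  if (I <= 2) stop("Shukla's variance needs I >= 3 genotypes")
  if (J < 2) stop("need J >= 2 environments")
  if (anyNA(x)) stop("table must be complete; fill missing cells first")
  w <- sweep(sweep(x, 1, rowMeans(x)), 2, colMeans(x)) + mean(x)
  ss_ge <- sum(w^2)
  s2 <- I / ((I - 2) * (J - 1)) * rowSums(w^2) -
    ss_ge / ((I - 1) * (I - 2) * (J - 1))
  clipped <- s2 < 0
  data.frame(genotype = rownames(x) %||% as.character(seq_len(I)),
             shukla_var = pmax(s2, 0), clipped = clipped,
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Performance-vs-stability table from an FA fit
#'
#' Predicted yield per hybrid is the mean over all environments of the
#' stage-two fitted values `mu_j + u[i,j]` (missing cells are thereby
#' filled model-based); stability is Shukla's variance on the same
#' fitted two-way table.
#'
#' @param fit `famet_fafit`.
#' @return data.frame with `genotype`, `predicted_yield`,
#'   `shukla_var`, `clipped`.
#' @export
fast_tables <- function(fit) {
  fitted <- sweep(fit$blups, 2, fit$mu, "+")
  st <- shukla_stability(fitted)
  st$predicted_yield <- rowMeans(fitted)
  st[c("genotype", "predicted_yield", "shukla_var", "clipped")]
}

#' Label top/bottom performers for the performance-stability plot
#'
#' Exactly `n_label` top-yielding hybrids are labelled `"top"`, the
#' `n_label` bottom-yielding `"bottom"`, the rest `"mid"`. Ties at a
#' boundary are resolved by hybrid id (with a warning). The mean
#' Shukla variance is attached as the average-stability reference.
#'
#' @param st stability table from [fast_tables()].
#' @param n_label labels per tail (default 5).
#' @return `st` with a `label` column and attribute
#'   `mean_stability`.
#' @export
rank_performance_stability <- function(st, n_label = 5) {
  I <- nrow(st)
  if (I < 2 * n_label) stop("need at least ", 2 * n_label, " hybrids")
  if (anyDuplicated(round(st$predicted_yield, 12)))
    warning("ties in predicted yield resolved by hybrid id")
  ord <- order(-st$predicted_yield, st$genotype)
  lab <- rep("mid", I)
  lab[ord[seq_len(n_label)]] <- "top"
  lab[ord[(I - n_label + 1):I]] <- "bottom"
  st$label <- lab
  attr(st, "mean_stability") <- mean(st$shukla_var)
  st
}

#' Latent-regression data for one hybrid and one factor
#'
#' For factor 1, points are `(lambda[j,1], mu-centered BLUP)` per
#' environment; for factor `m > 1` the contributions of factors
#' `1..m-1` are removed from the BLUPs first. The regression slope is
#' the hybrid's fitted factor score, by construction of the FA BLUP
#' decomposition `u[i,j] = sum_m f[i,m] lambda[j,m] + delta[i,j]`.
#'
#' @param fit rotated `famet_fafit`.
#' @param hybrid genotype id.
#' @param m factor index, `1 <= m <= k`.
#' @return list with `points` (data.frame `environment`, `loading`,
#'   `blup`), `slope`, `hybrid`, `factor`.
#' @export
latent_regression <- function(fit, hybrid, m = 1) {
  if (!hybrid %in% rownames(fit$scores)) stop("unknown hybrid: ", hybrid)
  stopifnot(m >= 1, m <= fit$k)
  u <- fit$blups[hybrid, ]
  if (m > 1) {
    lower <- seq_len(m - 1)
    u <- u - drop(fit$Lambda[, lower, drop = FALSE] %*%
                    fit$scores[hybrid, lower])
  }
  list(points = data.frame(environment = colnames(fit$blups),
                           loading = fit$Lambda[, m], blup = u,
                           row.names = NULL),
       slope = unname(fit$scores[hybrid, m]), hybrid = hybrid,
       factor = m)
}
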