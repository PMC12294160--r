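#' Candidate single-trial model specification
#'
#' A stage-one model always carries a genotype term; optional random
#' row and column effects and an optionally AR1-correlated residual in
#' either or both grid dimensions describe the spatial trend of a
#' row-column field trial.
#'
#' @param random_row,random_col logical, include an iid random effect
#'   for the grid dimension.
#' @param ar1_row,ar1_col logical, first-order autoregressive residual
#'   correlation along the dimension.
#' @param genotype `"random"` (model search) or `"fixed"` (BLUE refit).
#' @return object of class `famet_modelspec`.
#' @export
model_spec <- function(random_row = FALSE, random_col = FALSE,
                       ar1_row = FALSE, ar1_col = FALSE,
                       genotype = c("random", "fixed")) {
  genotype <- match.arg(genotype)
  structure(list(random_row = random_row, random_col = random_col,
                 ar1_row = ar1_row, ar1_col = ar1_col,
                 genotype = genotype),
            class = "famet_modelspec")
}

#' @export
format.famet_modelspec <- function(x, ...) {
  terms <- c("g", if (x$random_row) "row", if (x$random_col) "col")
  resid <- if (x$ar1_row && x$ar1_col) "ar1xar1"
           else if (x$ar1_row) "ar1(row)"
           else if (x$ar1_col) "ar1(col)" else "iid"
  sprintf("[%s | %s | genotype %s]",
          paste(terms, collapse = "+"), resid, x$genotype)
}

#' @export
print.famet_modelspec <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

# number of variance parameters of a spec (used for tie-breaking)
.n_varpar <- function(spec) {
  1L + (spec$genotype == "random") + spec$random_row + spec$random_col +
    spec$ar1_row + spec$ar1_col
}

#' Enumerate the candidate model catalog for a trial layout
#'
#' Full factorial of \{no row, random row\} x \{no col, random col\} x
#' \{iid, AR1(row), AR1(col), AR1xAR1\} residuals, with terms of a
#' degenerate dimension removed (random effect needs >= 2 levels, AR1
#' needs >= 3). The baseline model (genotype only, iid residual) is
#' always first.
#'
#' @param n_rows,n_cols grid dimensions of the trial.
#' @return list of `famet_modelspec`, deduplicated, baseline first.
#' @export
enumerate_candidate_models <- function(n_rows, n_cols) {
  stopifnot(n_rows >= 1, n_cols >= 1, n_rows * n_cols >= 2)
  row_opts <- if (n_rows >= 2) c(FALSE, TRUE) else FALSE
  col_opts <- if (n_cols >= 2) c(FALSE, TRUE) else FALSE
  ar1r_opts <- if (n_rows >= 3) c(FALSE, TRUE) else FALSE
  ar1c_opts <- if (n_cols >= 3) c(FALSE, TRUE) else FALSE
  grid <- expand.grid(ar1_col = ar1c_opts, ar1_row = ar1r_opts,
                      random_col = col_opts, random_row = row_opts)
  # baseline (all FALSE) sorts first by construction
  specs <- lapply(seq_len(nrow(grid)), function(i) {
    model_spec(random_row = grid$random_row[i],
               random_col = grid$random_col[i],
               ar1_row = grid$ar1_row[i], ar1_col = grid$ar1_col[i])
  })
  specs[!duplicated(vapply(specs, format, ""))]
}

# residual correlation matrix for plot coordinates; iid dimensions
# contribute an equality indicator (separable AR1 (x) I structure)
.resid_cor <- function(rows, cols, spec, rho_r = 0, rho_c = 0) {
  Mr <- if (spec$ar1_row) rho_r^abs(outer(rows, rows, "-"))
        else outer(rows, rows, "==") * 1
  Mc <- if (spec$ar1_col) rho_c^abs(outer(cols, cols, "-"))
        else outer(cols, cols, "==") * 1
  Mr * Mc
}

# scaled covariance H = sum(gamma_t Z_t Z_t') + R(rho); residual
# variance profiled out of the REML criterion
.stage1_H <- function(pars, dat, spec) {
  i <- 1
  H <- matrix(0, nrow(dat$X0), nrow(dat$X0))
  if (spec$genotype == "random") {
    H <- H + exp(pars[i]) * tcrossprod(dat$Zg); i <- i + 1
  }
  if (spec$random_row) { H <- H + exp(pars[i]) * tcrossprod(dat$Zr); i <- i + 1 }
  if (spec$random_col) { H <- H + exp(pars[i]) * tcrossprod(dat$Zc); i <- i + 1 }
  rho_r <- rho_c <- 0
  if (spec$ar1_row) { rho_r <- tanh(pars[i]); i <- i + 1 }
  if (spec$ar1_col) { rho_c <- tanh(pars[i]); i <- i + 1 }
  H + .resid_cor(dat$rows, dat$cols, spec, rho_r, rho_c)
}

# profiled REML log-likelihood (residual variance maximized out)
.stage1_loglik <- function(pars, dat, spec) {
  H <- .stage1_H(pars, dat, spec)
  X <- if (spec$genotype == "fixed") dat$Xg else dat$X0
  n <- nrow(H); p <- ncol(X)
  ch <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(ch)) return(-1e10)
  Hi_y <- backsolve(ch, forwardsolve(t(ch), dat$y))
  Hi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtHiX <- crossprod(X, Hi_X)
  chx <- tryCatch(chol(XtHiX), error = function(e) NULL)
  if (is.null(chx)) return(-1e10)
  XtHiy <- crossprod(X, Hi_y)
  b <- backsolve(chx, forwardsolve(t(chx), XtHiy))
  yPy <- sum(dat$y * Hi_y) - sum(XtHiy * b)
  if (yPy <= 0) return(-1e10)
  s2 <- yPy / (n - p)
  -0.5 * ((n - p) * (log(2 * pi) + log(s2) + 1) +
            2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))))
}

.stage1_start <- function(spec) {
  pars <- numeric(0)
  if (spec$genotype == "random") pars <- c(pars, 0)
  if (spec$random_row) pars <- c(pars, 0)
  if (spec$random_col) pars <- c(pars, 0)
  if (spec$ar1_row) pars <- c(pars, atanh(0.1))
  if (spec$ar1_col) pars <- c(pars, atanh(0.1))
  pars
}

.stage1_bounds <- function(spec) {
  nv <- (spec$genotype == "random") + spec$random_row + spec$random_col
  nr <- spec$ar1_row + spec$ar1_col
  list(lower = c(rep(-25, nv), rep(-5, nr)),
       upper = c(rep(12, nv), rep(5, nr)))
}

.stage1_prepare <- function(trial, spec) {
  trial <- trial[!is.na(trial$yield_t_ha), , drop = FALSE]
  if (nrow(trial) < 3) stop("too few plots with data")
  hyb <- factor(trial$hybrid)
  ind <- function(x) {             # indicator matrix, 1-level safe
    f <- factor(x)
    if (nlevels(f) < 2) matrix(1, length(x), 1)
    else stats::model.matrix(~ 0 + f)
  }
  list(y = trial$yield_t_ha,
       X0 = matrix(1, nrow(trial), 1),
       Xg = ind(trial$hybrid),
       Zg = ind(trial$hybrid),
       Zr = ind(trial$row),
       Zc = ind(trial$col),
       rows = trial$row, cols = trial$col,
       hybrids = levels(hyb))
}

#' Fit one single-trial mixed model by REML
#'
#' Maximizes the residual-variance-profiled REML log-likelihood of the
#' model described by `spec` on one trial's plot records. Variance
#' components estimated at the boundary (below `1e-8` of the total) are
#' reported as 0 and flagged. Per-genotype prediction error variances
#' are computed from the fitted covariance for random-genotype models.
#'
#' @param trial data.frame with columns `hybrid`, `row`, `col`,
#'   `yield_t_ha` (missing yields dropped).
#' @param spec `famet_modelspec`.
#' @param maxit maximal optimizer iterations.
#' @return object of class `famet_trialfit`: list with `spec`,
#'   `var_components` (named, includes `residual`), `rho` (AR1
#'   estimates), `logLik`, `H2`, `pev`, `sigma2_g`, `converged`,
#'   `boundary` flags.
#' @export
fit_reml <- function(trial, spec, maxit = 500) {
  dat <- .stage1_prepare(trial, spec)
  if (length(dat$hybrids) < 2) stop("need >= 2 genotypes with data")
  start <- .stage1_start(spec)
  if (length(start) == 0) {       # fixed-genotype iid model: closed form
    ll <- .stage1_loglik(numeric(0), dat, spec)
    return(.stage1_wrap(numeric(0), ll, TRUE, dat, spec))
  }
  b <- .stage1_bounds(spec)
  op <- tryCatch(
    optim(start, function(p) -.stage1_loglik(p, dat, spec),
          method = "L-BFGS-B", lower = b$lower, upper = b$upper,
          control = list(maxit = maxit, factr = 1e6)),
    error = function(e) NULL)
  if (is.null(op))
    return(.stage1_wrap(start, -Inf, FALSE, dat, spec))
  .stage1_wrap(op$par, -op$value, op$convergence == 0, dat, spec)
}

.stage1_wrap <- function(pars, logLik, converged, dat, spec) {
  H <- .stage1_H(pars, dat, spec)
  X <- if (spec$genotype == "fixed") dat$Xg else dat$X0
  n <- nrow(H); p <- ncol(X)
  Hi <- solve(H)
  XtHiX <- crossprod(X, Hi %*% X)
  XtHiXi <- solve(XtHiX)
  Pm <- Hi - Hi %*% X %*% XtHiXi %*% crossprod(X, Hi)
  s2e <- drop(crossprod(dat$y, Pm %*% dat$y)) / (n - p)
  i <- 1; vc <- c(); rho <- c()
  gam <- function() { v <- exp(pars[i]); i <<- i + 1; v }
  if (spec$genotype == "random") vc["genotype"] <- gam() * s2e
  if (spec$random_row) vc["row"] <- gam() * s2e
  if (spec$random_col) vc["col"] <- gam() * s2e
  if (spec$ar1_row) { rho["row"] <- tanh(pars[i]); i <- i + 1 }
  if (spec$ar1_col) { rho["col"] <- tanh(pars[i]); i <- i + 1 }
  vc["residual"] <- s2e
  boundary <- vc < pmax(1e-8 * sum(vc), 1e-12)
  vc[boundary] <- 0
  pev <- NULL; H2 <- NA_real_; s2g <- NA_real_
  if (spec$genotype == "random") {
    s2g <- vc[["genotype"]]
    # PEV = s2g I - s2g Zg' P Zg s2g, P in variance units = Pm / s2e
    ZPZ <- crossprod(dat$Zg, Pm %*% dat$Zg) / s2e
    pev <- pmax(s2g - s2g^2 * diag(ZPZ), 0)
    names(pev) <- dat$hybrids
    H2 <- generalized_heritability(list(pev = pev, sigma2_g = s2g))
  }
  structure(list(spec = spec, var_components = vc, rho = rho,
                 logLik = logLik, H2 = H2, pev = pev, sigma2_g = s2g,
                 converged = converged, boundary = boundary,
                 n_varpar = .n_varpar(spec)),
            class = "famet_trialfit")
}

#' @export
print.famet_trialfit <- function(x, ...) {
  cat(format(x$spec), sprintf(" logLik %.3f  H2 %.3f  %s\n", x$logLik,
      x$H2, if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Generalized heritability of a random-genotype fit
#'
#' Cullis-style criterion `H2 = 1 - mean(PEV) / (2 * sigma2_g)`,
#' clipped to `[0, 1]`; defined as 0 when the genetic variance is 0.
#'
#' @param fit `famet_trialfit` (or any list with `pev`, `sigma2_g`).
#' @return heritability in `[0, 1]`.
#' @export
generalized_heritability <- function(fit) {
  if (is.na(fit$sigma2_g) || fit$sigma2_g <= 0) return(0)
  min(max(1 - mean(fit$pev) / (2 * fit$sigma2_g), 0), 1)
}

#' Select the optimal single-trial model
#'
#' Fits every catalog spec by REML and returns the converged fit with
#' maximal generalized heritability; ties (within `1e-8`) are broken by
#' fewer variance parameters, then catalog order.
#'
#' @param trial plot data.frame (see [fit_reml()]).
#' @param catalog list of specs, default from
#'   [enumerate_candidate_models()] on the trial's grid.
#' @return list with `spec`, `fit`, and `fits` (all converged fits).
#' @export
select_optimal_model <- function(trial, catalog = NULL) {
  if (is.null(catalog))
    catalog <- enumerate_candidate_models(max(trial$row), max(trial$col))
  fits <- lapply(catalog, function(sp)
    tryCatch(fit_reml(trial, sp), error = function(e) NULL))
  keep <- vapply(fits, function(f) !is.null(f) && f$converged, TRUE)
  fits <- fits[keep]
  if (!length(fits))
    stop("no converged model for trial '",
         if (!is.null(trial$trial_id)) trial$trial_id[1] else "?", "'")
  H2 <- vapply(fits, function(f) f$H2, 0)
  np <- vapply(fits, function(f) f$n_varpar, 0L)
  best <- order(-round(H2 / 1e-8) * 1e-8, np, seq_along(fits))[1]
  list(spec = fits[[best]]$spec, fit = fits[[best]], fits = fits)
}

#' Un-shrunken genotype BLUEs from the selected model
#'
#' Refits the selected variance structure with genotype as a fixed
#' effect and returns generalized-least-squares genotype means and
#' standard errors. Non-genotype variance parameters are carried over
#' from the random-genotype fit: with as many genotype levels as plots
#' the fixed-genotype REML has no residual degrees of freedom of its
#' own, so re-estimation is not possible in general.
#'
#' @param trial plot data.frame.
#' @param fit the selected random-genotype `famet_trialfit`.
#' @return data.frame with `hybrid`, `blue`, `se`.
#' @export
predict_blues <- function(trial, fit) {
  dat <- .stage1_prepare(trial, fit$spec)
  all_h <- unique(trial$hybrid)
  if (length(setdiff(all_h, dat$hybrids)))
    warning("hybrid(s) without plots omitted: ",
            paste(setdiff(all_h, dat$hybrids), collapse = ", "))
  vc <- fit$var_components
  V <- vc[["residual"]] *
    .resid_cor(dat$rows, dat$cols, fit$spec,
                                  if (fit$spec$ar1_row) fit$rho[["row"]] else 0,
                                  if (fit$spec$ar1_col) fit$rho[["col"]] else 0)
  if (fit$spec$random_row) V <- V + vc[["row"]] * tcrossprod(dat$Zr)
  if (fit$spec$random_col) V <- V + vc[["col"]] * tcrossprod(dat$Zc)
  X <- dat$Xg
  Vi_X <- solve(V, X)
  XtViX <- crossprod(X, Vi_X)
  C <- solve(XtViX)
  beta <- drop(C %*% crossprod(Vi_X, dat$y))
  data.frame(hybrid = dat$hybrids, blue = beta,
             se = sqrt(diag(C)), row.names = NULL)
}

#' Run stage one over all trials of a dataset
#'
#' Per trial: model search by generalized heritability, then a
#' fixed-genotype refit for BLUEs and standard errors.
#'
#' @param ds `famet_trials` dataset.
#' @param catalog optional shared spec catalog (default per-trial
#'   enumeration).
#' @return list with `predictions` (hybrid, environment,
#'   maturity_group, blue, se) and `selection` (trial, spec, H2,
#'   logLik) data.frames.
#' @export
run_stage1 <- function(ds, catalog = NULL) {
  preds <- list(); sel <- list()
  for (tid in unique(ds$records$trial_id)) {
    trial <- ds$records[ds$records$trial_id == tid, ]
    ch <- select_optimal_model(trial, catalog)
    bl <- predict_blues(trial, ch$fit)
    bl$environment <- trial$environment[1]
    bl$maturity_group <- trial$maturity_group[1]
    preds[[tid]] <- bl
    sel[[tid]] <- data.frame(trial = tid, spec = format(ch$spec),
                             H2 = ch$fit$H2, logLik = ch$fit$logLik)
  }
  list(predictions = do.call(rbind, c(preds, make.row.names = FALSE)),
       selection = do.call(rbind, c(sel, make.row.names = FALSE)))
}
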