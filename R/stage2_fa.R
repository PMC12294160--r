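#' Assemble the genotype x environment table of weighted BLUEs
#'
#' Pools stage-one predictions from all maturity groups into one
#' rectangular genotype x environment table carrying the BLUE and its
#' standard error per cell. Missing cells are allowed; a genotype
#' observed in fewer than two environments is dropped with a warning;
#' a duplicated (hybrid, environment) cell is an error.
#'
#' @param predictions data.frame with `hybrid`, `environment`, `blue`,
#'   `se` (e.g. `run_stage1()$predictions`).
#' @param environments optional environment ids to retain as columns
#'   even when entirely unobserved (defaults to those present).
#' @return object of class `famet_met`: list with matrices `blue`,
#'   `se` (I x J) and `genotypes`, `environments`.
#' @export
build_met_table <- function(predictions, environments = NULL) {
  stopifnot(all(c("hybrid", "environment", "blue", "se") %in%
                  names(predictions)))
  key <- paste(predictions$hybrid, predictions$environment)
  if (anyDuplicated(key))
    stop("duplicate (hybrid, environment) cell: ", key[duplicated(key)][1])
  if (any(predictions$se <= 0, na.rm = TRUE))
    stop("standard errors must be positive")
  envs <- sort(unique(c(predictions$environment, environments)))
  if (length(envs) < 2) stop("need predictions for >= 2 environments")
  n_env <- tapply(predictions$environment, predictions$hybrid,
                  function(e) length(unique(e)))
  drop <- names(n_env)[n_env < 2]
  if (length(drop)) {
    warning("genotype(s) in < 2 environments dropped: ",
            paste(drop, collapse = ", "))
    predictions <- predictions[!predictions$hybrid %in% drop, ]
  }
  gen <- sort(unique(predictions$hybrid))
  B <- SE <- matrix(NA_real_, length(gen), length(envs),
                    dimnames = list(gen, envs))
  B[cbind(match(predictions$hybrid, gen),
          match(predictions$environment, envs))] <- predictions$blue
  SE[cbind(match(predictions$hybrid, gen),
           match(predictions$environment, envs))] <- predictions$se
  structure(list(blue = B, se = SE, genotypes = gen, environments = envs),
            class = "famet_met")
}

#' @export
print.famet_met <- function(x, ...) {
  cat(sprintf("MET table: %d genotypes x %d environments, %d filled cells\n",
              length(x$genotypes), length(x$environments),
              sum(!is.na(x$blue))))
  invisible(x)
}

#' Number of variance parameters of an FA(k) structure
#'
#' `J*(k+1) - k*(k-1)/2`: J*k loadings plus J specific variances minus
#' the k(k-1)/2 rotational (upper-triangle) constraints.
#'
#' @param J number of environments.
#' @param k factor order, `1 <= k < J`.
#' @return integer count.
#' @export
count_variance_parameters <- function(J, k) {
  stopifnot(k >= 1)
  if (k >= J) stop("factor order k must be smaller than J")
  as.integer(J * (k + 1) - k * (k - 1) / 2)
}

#' AIC from a REML log-likelihood and a variance-parameter count
#'
#' `AIC = -2 * logLik + 2 * n_vc`; only variance parameters are
#' counted, fixed environment means are not penalized.
#'
#' @param logLik REML log-likelihood.
#' @param n_vc number of variance parameters.
#' @return AIC value.
#' @export
fa_aic <- function(logLik, n_vc) -2 * logLik + 2 * n_vc

# group genotypes by identical (observed set, se vector) pattern so the
# per-genotype covariance factorization is shared
.fa_patterns <- function(met) {
  keys <- apply(met$se, 1, function(s)
    paste(ifelse(is.na(s), "na", sprintf("%.12g", s)), collapse = "|"))
  idx <- split(seq_along(keys), keys)
  lapply(idx, function(ii) {
    obs <- which(!is.na(met$se[ii[1], ]))
    list(rows = ii, obs = obs, se2 = met$se[ii[1], obs]^2)
  })
}

.fa_unpack <- function(theta, J, k) {
  Lambda <- matrix(0, J, k)
  Lambda[row(Lambda) >= col(Lambda)] <- theta[seq_len(J * k - k * (k - 1) / 2)]
  Psi <- exp(theta[(J * k - k * (k - 1) / 2 + 1):length(theta)])
  list(Lambda = Lambda, Psi = Psi)
}

# negative REML log-likelihood of the weighted FA(k) model; environment
# means are profiled out via the REML projection
.fa_negloglik <- function(theta, met, k, patterns) {
  J <- length(met$environments)
  pp <- .fa_unpack(theta, J, k)
  G <- tcrossprod(pp$Lambda) + diag(pp$Psi, J)
  A <- matrix(0, J, J)
  b <- numeric(J)
  q <- 0; logdet <- 0; n <- 0
  for (pt in patterns) {
    C <- G[pt$obs, pt$obs, drop = FALSE]
    diag(C) <- diag(C) + pt$se2
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Yg <- t(met$blue[pt$rows, pt$obs, drop = FALSE])   # obs x n_g
    U <- forwardsolve(t(ch), Yg)
    Ci <- chol2inv(ch)
    ng <- length(pt$rows)
    logdet <- logdet + ng * 2 * sum(log(diag(ch)))
    A[pt$obs, pt$obs] <- A[pt$obs, pt$obs] + ng * Ci
    b[pt$obs] <- b[pt$obs] + rowSums(Ci %*% Yg)
    q <- q + sum(U^2)
    n <- n + ng * length(pt$obs)
  }
  chA <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(chA)) return(1e10)
  v <- forwardsolve(t(chA), b)
  yPy <- q - sum(v^2)
  0.5 * ((n - J) * log(2 * pi) + logdet + 2 * sum(log(diag(chA))) + yPy)
}

# deterministic initialization from the eigendecomposition of the
# error-corrected sample covariance of the BLUEs
.fa_init <- function(met, k) {
  J <- length(met$environments)
  S <- stats::cov(met$blue, use = "pairwise.complete.obs")
  S[is.na(S)] <- 0
  diag(S) <- pmax(diag(S) - colMeans(met$se^2, na.rm = TRUE),
                  0.1 * diag(S))
  ee <- eigen(S, symmetric = TRUE)
  ev <- pmax(ee$values[seq_len(k)], 1e-4)
  L0 <- ee$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(ev), k)
  # rotate to the lower-triangular identified form (LQ decomposition)
  qq <- qr(t(L0))
  L <- t(qr.R(qq))[, seq_len(k), drop = FALSE]
  sgn <- sign(diag(L)[seq_len(k)]); sgn[sgn == 0] <- 1
  L <- L %*% diag(sgn, k)
  Psi0 <- pmax(diag(S) - rowSums(L^2), 0.05 * pmax(diag(S), 1e-3))
  c(L[row(L) >= col(L)], log(Psi0))
}

#' Fit a weighted factor-analytic MET model by REML
#'
#' Model: `blue[i,j] = mu_j + u[i,j] + e[i,j]` with genetic effects
#' `u[i,] ~ N(0, Lambda Lambda' + diag(Psi))` across environments and
#' measurement errors `e[i,j] ~ N(0, se[i,j]^2)` fixed from stage one.
#' Missing cells are handled by marginalizing each genotype over its
#' observed environments. Identification during fitting is by zeros in
#' the upper triangle of `Lambda`; use [rotate_loadings()] afterwards.
#' Specific variances may go to zero (Heywood cases); they are flagged.
#'
#' @param met `famet_met` table.
#' @param k factor order, `1 <= k < J`.
#' @param maxit maximal optimizer iterations.
#' @return object of class `famet_fafit`: `mu`, `Lambda`, `Psi`,
#'   `scores` (I x k), `blups` (I x J), `logLik`, `n_vc`, `AIC`, `k`,
#'   `converged`, `heywood`, `rotated`.
#' @export
fit_fa <- function(met, k, maxit = 2000) {
  J <- length(met$environments)
  if (k >= J) stop("factor order k must be smaller than J")
  patterns <- .fa_patterns(met)
  theta0 <- .fa_init(met, k)
  nl <- J * k - k * (k - 1) / 2
  lower <- c(rep(-Inf, nl), rep(-30, J))
  upper <- c(rep(Inf, nl), rep(12, J))
  op <- optim(theta0, .fa_negloglik, met = met, k = k,
              patterns = patterns, method = "L-BFGS-B",
              lower = lower, upper = upper,
              control = list(maxit = maxit, factr = 1e5))
  pp <- .fa_unpack(op$par, J, k)
  fit <- .fa_wrap(pp$Lambda, pp$Psi, met, -op$value,
                  converged = op$convergence == 0)
  fit
}

# assemble fit object: profile out mu, compute scores and BLUPs
.fa_wrap <- function(Lambda, Psi, met, logLik, converged = TRUE,
                     rotated = FALSE) {
  J <- length(met$environments); I <- length(met$genotypes)
  k <- ncol(Lambda)
  dimnames(Lambda) <- list(met$environments, NULL)
  names(Psi) <- met$environments
  G <- tcrossprod(Lambda) + diag(Psi, J)
  patterns <- .fa_patterns(met)
  A <- matrix(0, J, J); b <- numeric(J)
  for (pt in patterns) {
    C <- G[pt$obs, pt$obs, drop = FALSE]
    diag(C) <- diag(C) + pt$se2
    Ci <- solve(C)
    A[pt$obs, pt$obs] <- A[pt$obs, pt$obs] + length(pt$rows) * Ci
    b[pt$obs] <- b[pt$obs] +
      rowSums(Ci %*% t(met$blue[pt$rows, pt$obs, drop = FALSE]))
  }
  mu <- drop(solve(A, b))
  names(mu) <- met$environments
  FF <- matrix(0, I, k, dimnames = list(met$genotypes, NULL))
  U <- matrix(0, I, J, dimnames = list(met$genotypes, met$environments))
  delta <- matrix(0, I, J, dimnames = dimnames(U))
  for (pt in patterns) {
    C <- G[pt$obs, pt$obs, drop = FALSE]
    diag(C) <- diag(C) + pt$se2
    R <- t(met$blue[pt$rows, pt$obs, drop = FALSE]) - mu[pt$obs]
    CiR <- solve(C, R)                              # obs x n_g
    FF[pt$rows, ] <- t(crossprod(Lambda[pt$obs, , drop = FALSE], CiR))
    delta[pt$rows, pt$obs] <- t(Psi[pt$obs] * CiR)
  }
  U <- FF %*% t(Lambda) + delta
  structure(list(k = k, mu = mu,
                 Lambda = Lambda,
                 Psi = Psi,
                 scores = FF, delta = delta, blups = U,
                 logLik = logLik,
                 n_vc = count_variance_parameters(J, k),
                 AIC = fa_aic(logLik, count_variance_parameters(J, k)),
                 converged = converged,
                 heywood = Psi < 1e-6 * mean(diag(G)),
                 rotated = rotated, met = met),
            class = "famet_fafit")
}

#' @export
print.famet_fafit <- function(x, ...) {
  cat(sprintf("FA(%d) MET fit: %d genotypes x %d environments\n",
              x$k, nrow(x$scores), length(x$mu)))
  cat(sprintf("  logLik %.2f, %d variance parameters, AIC %.2f%s%s\n",
              x$logLik, x$n_vc, x$AIC,
              if (x$rotated) ", rotated" else "",
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Fit FA(1..k_max) and select the MET model by AIC
#'
#' @param met `famet_met` table.
#' @param k_max maximal factor order.
#' @return list with `fit` (minimal-AIC converged fit) and `comparison`
#'   data.frame (`k`, `n_vc`, `logLik`, `AIC`).
#' @export
select_met_model <- function(met, k_max = 5) {
  stopifnot(k_max >= 1)
  fits <- lapply(seq_len(k_max), function(k)
    tryCatch(fit_fa(met, k), error = function(e) NULL))
  comparison <- do.call(rbind, lapply(seq_len(k_max), function(k) {
    f <- fits[[k]]
    data.frame(k = k,
               n_vc = if (is.null(f)) NA else f$n_vc,
               logLik = if (is.null(f)) NA else f$logLik,
               AIC = if (is.null(f)) NA else f$AIC,
               converged = !is.null(f) && f$converged)
  }))
  ok <- which(comparison$converged)
  if (!length(ok)) stop("no converged FA fit")
  best <- ok[which.min(comparison$AIC[ok])]
  list(fit = fits[[best]], comparison = comparison)
}

#' Principal-axis rotation of a factor-analytic fit
#'
#' Orthogonal rotation that diagonalizes `Lambda' Lambda` with
#' non-increasing diagonal (SVD-based), with the sign convention that
#' each rotated column's loading sum is non-negative. Genotype scores
#' are co-rotated so every `scores %*% t(Lambda)` contribution — and
#' hence `Lambda Lambda'` and all BLUPs — is invariant.
#'
#' @param fit `famet_fafit`.
#' @return the fit with rotated `Lambda` and `scores`.
#' @export
rotate_loadings <- function(fit) {
  sv <- svd(fit$Lambda)
  Rot <- sv$v
  L <- fit$Lambda %*% Rot
  sgn <- ifelse(colSums(L) < 0, -1, 1)
  L <- sweep(L, 2, sgn, "*")
  Rot <- sweep(Rot, 2, sgn, "*")
  fit$Lambda <- L
  fit$scores <- fit$scores %*% Rot
  fit$rotated <- TRUE
  fit
}

#' Genetic correlations between environments
#'
#' `r[j,j'] = G[j,j'] / sqrt(G[j,j] G[j',j'])` with
#' `G = Lambda Lambda' + diag(Psi)`; identical before and after
#' rotation.
#'
#' @param fit `famet_fafit` (or any list with `Lambda` and `Psi`).
#' @return J x J correlation matrix, unit diagonal.
#' @export
genetic_correlations <- function(fit) {
  if (is.null(fit$Psi) || anyNA(fit$Psi)) stop("specific variances undefined")
  G <- tcrossprod(fit$Lambda) + diag(fit$Psi, nrow(fit$Lambda))
  dimnames(G) <- list(rownames(fit$Lambda), rownames(fit$Lambda))
  cov2cor(G)
}

#' Percentage of genetic variance explained by each factor
#'
#' Overall per factor:
#' `100 * sum_j lambda[j,m]^2 / sum_j (sum_m lambda[j,m]^2 + psi_j)`;
#' per environment (cumulative over factors):
#' `100 * sum_m lambda[j,m]^2 / (sum_m lambda[j,m]^2 + psi_j)`.
#' Meaningful on a rotated fit.
#'
#' @param fit `famet_fafit` (or list with `Lambda`, `Psi`).
#' @return list with `overall_pct` (per factor), `total_pct` (their
#'   sum) and `env_cum_pct` (per environment).
#' @export
variance_explained <- function(fit) {
  L2 <- fit$Lambda^2
  tot <- rowSums(L2) + fit$Psi
  if (sum(tot) <= 0) stop("all-zero genetic covariance")
  list(overall_pct = 100 * colSums(L2) / sum(tot),
       total_pct = 100 * sum(L2) / sum(tot),
       env_cum_pct = setNames(100 * rowSums(L2) / tot,
                              rownames(fit$Lambda)))
}

#' Recover a specific variance from a loading row and its cumulative %
#'
#' Inverts the per-environment cumulative-%-explained definition:
#' `psi = sum(lambda^2) * (100 - cum_pct) / cum_pct`. Used to
#' reconstruct complete FA parameter sets from published loading
#' tables that report only loadings and the cumulative % explained.
#'
#' @param lambda_row numeric loadings of one environment.
#' @param cum_pct cumulative % of genetic variance explained, in
#'   `(0, 100]`.
#' @return specific variance `psi >= 0`.
#' @export
invert_env_cumpct <- function(lambda_row, cum_pct) {
  if (any(cum_pct <= 0 | cum_pct > 100))
    stop("cum_pct must be in (0, 100]")
  sum(lambda_row^2) * (100 - cum_pct) / cum_pct
}

#' Cluster environments on genetic dissimilarity
#'
#' Agglomerative (average-linkage) clustering on `1 - r` cut at
#' `n_groups`.
#'
#' @param R genetic correlation matrix.
#' @param n_groups number of clusters, `1 <= n_groups <= J`.
#' @return named integer cluster labels.
#' @export
cluster_environments <- function(R, n_groups) {
  stopifnot(n_groups >= 1, n_groups <= nrow(R))
  hc <- hclust(as.dist(1 - R), method = "average")
  cutree(hc, k = n_groups)
}
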