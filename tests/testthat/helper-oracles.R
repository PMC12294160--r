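# Independent oracles: direct evaluations of the REML criterion and
# small brute-force utilities, kept free of the package's fitting code.

# generic REML log-likelihood of y ~ N(X beta, V)
reml_loglik_direct <- function(y, X, V) {
  n <- length(y); p <- ncol(X)
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi %*% X)
  P <- Vi - Vi %*% X %*% solve(XtViX, crossprod(X, Vi))
  as.numeric(-0.5 * ((n - p) * log(2 * pi) +
                       determinant(V)$modulus +
                       determinant(XtViX)$modulus +
                       crossprod(y, P %*% y)))
}

# direct maximization of the baseline (genotype + iid error) REML
# criterion on the natural variance scale
oracle_stage1_optimum <- function(trial) {
  hyb <- factor(trial$hybrid)
  Z <- model.matrix(~ 0 + hyb)
  X <- matrix(1, nrow(trial), 1)
  y <- trial$yield_t_ha
  nll <- function(lv) {
    V <- exp(lv[1]) * tcrossprod(Z) + exp(lv[2]) * diag(nrow(trial))
    -reml_loglik_direct(y, X, V)
  }
  best <- Inf
  for (s in list(c(0, 0), c(-2, 0), c(0, -2), c(1, 1))) {
    o <- nlminb(s, nll, lower = c(-15, -15), upper = c(8, 8))
    if (o$objective < best) best <- o$objective
  }
  -best
}

# direct maximization of the weighted FA(k=1) REML criterion on a
# complete MET table, stacked-covariance construction
oracle_fa1_optimum <- function(met) {
  I <- length(met$genotypes); J <- length(met$environments)
  y <- as.vector(t(met$blue))
  X <- kronecker(rep(1, I), diag(J))
  nll <- function(par) {
    lam <- par[1:J]; psi <- exp(par[(J + 1):(2 * J)])
    G <- tcrossprod(lam) + diag(psi, J)
    V <- matrix(0, I * J, I * J)
    for (i in seq_len(I)) {
      idx <- ((i - 1) * J + 1):(i * J)
      V[idx, idx] <- G + diag(met$se[i, ]^2, J)
    }
    val <- tryCatch(-reml_loglik_direct(y, X, V),
                    error = function(e) 1e10)
    if (!is.finite(val)) 1e10 else val
  }
  best <- Inf
  for (s in list(c(rep(0.5, J), rep(log(0.5), J)),
                 c(rep(1, J), rep(0, J)),
                 c(rep(0.2, J), rep(-1, J)))) {
    o <- nlminb(s, nll, lower = c(rep(-10, J), rep(-12, J)),
                upper = rep(8, 2 * J),
                control = list(iter.max = 2000, eval.max = 4000))
    if (o$objective < best) best <- o$objective
  }
  -best
}

# orthogonal Procrustes alignment error between loading matrices
procrustes_rmse <- function(A, B) {
  s <- svd(crossprod(A, B))
  sqrt(mean((A %*% (s$u %*% t(s$v)) - B)^2))
}
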