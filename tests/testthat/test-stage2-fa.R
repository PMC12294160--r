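test_that("the MET table pools predictions with missing cells and hard duplicate errors", {
  preds <- expand.grid(hybrid = sprintf("H%02d", 1:32),
                       environment = sprintf("L%d.2017", 1:12),
                       stringsAsFactors = FALSE)
  preds$blue <- rnorm(nrow(preds), 10)
  preds$se <- 0.3
  met <- build_met_table(preds)
  expect_equal(dim(met$blue), c(32, 12))
  expect_equal(sum(!is.na(met$blue)), 384)

  miss <- preds[!(preds$environment == "L3.2017"), ]
  met2 <- build_met_table(miss, environments = sprintf("L%d.2017", 1:12))
  expect_equal(sum(is.na(met2$blue[, "L3.2017"])), 32)
  expect_equal(dim(met2$blue), c(32, 12))

  expect_error(build_met_table(rbind(preds, preds[1, ])), "duplicate")

  two <- preds[preds$environment %in% c("L1.2017", "L2.2017") |
                 preds$hybrid != "H01", ]
  lone <- two[!(two$hybrid == "H01" & two$environment == "L2.2017"), ]
  expect_warning(met3 <- build_met_table(lone), "H01")
  expect_false("H01" %in% met3$genotypes)
})

test_that("variance-parameter counting follows the triangular identification rule", {
  expect_identical(count_variance_parameters(12, 1), 24L)
  expect_identical(count_variance_parameters(12, 2), 35L)
  expect_identical(count_variance_parameters(2, 1), 4L)
  expect_error(count_variance_parameters(4, 4), "smaller than J")
})

test_that("AIC counts only variance parameters", {
  expect_equal(fa_aic(-214.93, 24), 477.86)
  expect_equal(fa_aic(0, 0), 0)
  comp <- example_fa_comparison()
  expect_equal(comp$AIC[comp$model == "fa2"], 459.36, tolerance = 1e-8)
})

test_that("weighted FA REML matches direct optimization on a small instance", {
  tr <- make_truth(I = 30, J = 4, k = 1, link = NULL, seed = 31)
  met <- simulate_met_table(tr)
  fit <- fit_fa(met, 1)
  expect_true(fit$converged)
  expect_equal(fit$logLik, oracle_fa1_optimum(met), tolerance = 1e-4)
})

test_that("FA fitting recovers planted structure and handles nulls and missing cells", {
  tr <- make_truth(I = 200, J = 12, k = 2, seed = 101)
  fit <- rotate_loadings(fit_fa(simulate_met_table(tr), 2))
  expect_lt(procrustes_rmse(fit$Lambda, tr$Lambda), 0.15)

  # no genetic factor: the fitted structure carries no correlation
  # between environments (a rank-1 term can absorb one specific
  # variance without changing the likelihood, so the meaningful null
  # check is a near-diagonal genetic covariance)
  tr0 <- make_truth(I = 152, J = 8, k = 1, link = NULL, seed = 55)
  tr0$Lambda[] <- 0
  tr0$u <- tr0$scores %*% t(tr0$Lambda) + tr0$delta
  fit0 <- rotate_loadings(fit_fa(simulate_met_table(tr0), 1))
  R0 <- genetic_correlations(fit0)
  expect_lt(mean(abs(R0[upper.tri(R0)])), 0.05)

  # missing cells: per-genotype marginalization still converges
  tr <- make_truth(I = 60, J = 12, k = 2, seed = 66)
  met <- simulate_met_table(tr)
  drop <- cbind(sample(60, 40, TRUE), sample(12, 40, TRUE))
  met$blue[drop] <- NA; met$se[drop] <- NA
  fitm <- fit_fa(met, 2)
  expect_true(fitm$converged && is.finite(fitm$logLik))
  expect_true(all(is.finite(fitm$blups)))
})

test_that("model order selection is AIC-consistent and logLik is nested-monotone", {
  tr <- make_truth(I = 80, J = 10, k = 2, seed = 77)
  met <- simulate_met_table(tr)
  sel <- select_met_model(met, k_max = 3)
  expect_equal(nrow(sel$comparison), 3)
  lls <- sel$comparison$logLik
  expect_true(all(diff(lls) > -1e-6))
  expect_equal(sel$fit$AIC, min(sel$comparison$AIC))

  sel1 <- select_met_model(met, k_max = 1)
  expect_equal(sel1$fit$k, 1)
})

test_that("principal-axis rotation preserves the genetic covariance and fixes signs", {
  tr <- make_truth(I = 50, J = 12, k = 2, seed = 88)
  fit <- fit_fa(simulate_met_table(tr), 2)
  rot <- rotate_loadings(fit)
  expect_equal(tcrossprod(rot$Lambda), tcrossprod(fit$Lambda),
               tolerance = 1e-10)
  ltl <- crossprod(rot$Lambda)
  expect_lt(max(abs(ltl[upper.tri(ltl)])), 1e-10)
  expect_true(all(diff(diag(ltl)) <= 1e-10))
  expect_true(all(colSums(rot$Lambda) >= -1e-12))
  # scores co-rotate: fitted genetic effects invariant
  expect_equal(rot$scores %*% t(rot$Lambda),
               fit$scores %*% t(fit$Lambda), tolerance = 1e-10)

  # k = 1: rotation is at most a sign flip
  f1 <- fit_fa(simulate_met_table(make_truth(I = 40, J = 6, k = 1,
                                             link = NULL, seed = 3)), 1)
  r1 <- rotate_loadings(f1)
  expect_equal(abs(r1$Lambda), abs(f1$Lambda), tolerance = 1e-12)
})

test_that("genetic correlations are a valid correlation structure", {
  fit <- example_fa2_fit()
  R <- genetic_correlations(fit)
  expect_equal(diag(R), setNames(rep(1, 12), rownames(R)))
  expect_equal(R, t(R))
  expect_true(all(R >= -1 & R <= 1))
  expect_true(min(eigen(R, symmetric = TRUE)$values) > -1e-10)

  # psi = 0, one factor, same-sign loadings: perfect correlation
  R1 <- genetic_correlations(list(Lambda = matrix(c(1, 2, 3), 3),
                                  Psi = rep(0, 3)))
  expect_equal(unname(R1), matrix(1, 3, 3))
})

test_that("variance accounting identities and the cum-percent inversion hold", {
  L <- matrix(c(0.8, 0.6, 0.7, 0.3, -0.2, 0.4), 3)
  ve0 <- variance_explained(list(Lambda = L, Psi = rep(0, 3)))
  expect_equal(unname(ve0$env_cum_pct), rep(100, 3))

  lam <- c(0.9, 1.1, 0.5)
  ve50 <- variance_explained(list(Lambda = matrix(lam), Psi = lam^2))
  expect_equal(unname(ve50$overall_pct), 50)

  expect_equal(invert_env_cumpct(c(0.61, 0.34), 56.01), 0.38305,
               tolerance = 1e-4)
  expect_equal(invert_env_cumpct(c(1, 2), 100), 0)
  expect_error(invert_env_cumpct(c(1), 0), "cum_pct")

  # round trip through the per-environment accounting
  psi <- vapply(1:3, function(j) invert_env_cumpct(L[j, ], c(40, 70, 90)[j]), 0)
  ve <- variance_explained(list(Lambda = L, Psi = psi))
  expect_equal(unname(ve$env_cum_pct), c(40, 70, 90), tolerance = 1e-10)
})

test_that("environment clustering recovers block structure", {
  R <- rbind(cbind(matrix(1, 3, 3), matrix(0, 3, 3)),
             cbind(matrix(0, 3, 3), matrix(1, 3, 3)))
  dimnames(R) <- list(letters[1:6], letters[1:6])
  cl <- cluster_environments(R, 2)
  expect_length(unique(cl[1:3]), 1)
  expect_length(unique(cl[4:6]), 1)
  expect_false(cl[1] == cl[4])
  expect_length(unique(cluster_environments(R, 6)), 6)
})
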