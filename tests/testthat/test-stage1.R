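# helper: one simulated 8x4 row-column trial with AR1 plot error
sim_trial <- function(seed, rho_row = 0, sg = 1, se = 0.36) {
  set.seed(seed)
  hyb <- sprintf("g%d", 1:8)
  g <- rnorm(8, 0, sqrt(sg))
  lay <- sapply(1:4, function(cc) sample(hyb))
  ar1 <- function(n, rho) rho^abs(outer(1:n, 1:n, "-"))
  R <- kronecker(diag(4), ar1(8, rho_row))
  e <- drop(crossprod(chol(se * R), rnorm(32)))
  data.frame(hybrid = as.vector(lay), row = as.vector(row(lay)),
             col = as.vector(col(lay)),
             yield_t_ha = 10 + g[match(as.vector(lay), hyb)] + e)
}

test_that("the candidate catalog enumerates the factorial and trims degenerate dimensions", {
  cat84 <- enumerate_candidate_models(8, 4)
  expect_length(cat84, 16)          # 2 row x 2 col x 4 residual options
  expect_length(unique(vapply(cat84, format, "")), 16)
  base <- cat84[[1]]
  expect_false(base$random_row || base$random_col ||
                 base$ar1_row || base$ar1_col)

  cat1x <- enumerate_candidate_models(1, 32)
  expect_true(all(!vapply(cat1x, function(s) s$random_row, TRUE)))
  expect_true(all(!vapply(cat1x, function(s) s$ar1_row, TRUE)))
  # 2-level dimension admits a random effect but not an AR1 parameter
  cat2x <- enumerate_candidate_models(2, 16)
  expect_true(any(vapply(cat2x, function(s) s$random_row, TRUE)))
  expect_true(all(!vapply(cat2x, function(s) s$ar1_row, TRUE)))
})

test_that("REML recovers known variance components in replicated designs", {
  set.seed(42)
  est <- replicate(10, {
    g <- rnorm(200)
    tt <- data.frame(hybrid = rep(sprintf("g%03d", 1:200), 2),
                     row = rep(1:20, each = 20), col = rep(1:20, 20),
                     yield_t_ha = 10 + rep(g, 2) + rnorm(400))
    f <- fit_reml(tt, model_spec())
    c(f$var_components[["genotype"]], f$var_components[["residual"]])
  })
  expect_lt(abs(mean(est[1, ]) - 1), 0.2)
  expect_lt(abs(mean(est[2, ]) - 1), 0.2)
})

test_that("zero genetic variance collapses to the boundary with zero heritability", {
  tt <- data.frame(hybrid = sprintf("g%02d", 1:32), row = rep(1:8, 4),
                   col = rep(1:4, each = 8),
                   yield_t_ha = 10 + rnorm(32, 0, 0.01))
  tt$yield_t_ha <- ave(tt$yield_t_ha, FUN = mean)  # identical means
  f <- fit_reml(tt, model_spec())
  expect_equal(f$var_components[["genotype"]], 0)
  expect_equal(f$H2, 0)
})

test_that("profiled REML optimum matches direct maximization on a tiny trial", {
  set.seed(9)
  tiny <- data.frame(hybrid = rep(c("a", "b", "c"), 2),
                     row = 1:6, col = rep(1, 6),
                     yield_t_ha = 10 + rep(rnorm(3), 2) + rnorm(6, 0, 0.5))
  fit <- fit_reml(tiny, model_spec(random_col = FALSE))
  expect_equal(fit$logLik, oracle_stage1_optimum(tiny), tolerance = 1e-4)
})

test_that("generalized heritability obeys its defining identities", {
  expect_equal(generalized_heritability(list(pev = c(0, 0), sigma2_g = 2)), 1)
  expect_equal(generalized_heritability(list(pev = c(4, 4), sigma2_g = 2)), 0)
  expect_equal(generalized_heritability(list(pev = 1, sigma2_g = 0)), 0)
  # more replication -> higher H2
  h2_at <- function(reps) {
    set.seed(11)
    g <- rnorm(8)
    tt <- data.frame(hybrid = rep(sprintf("g%d", 1:8), reps),
                     row = rep(1:8, reps),
                     col = rep(seq_len(reps), each = 8),
                     yield_t_ha = 10 + rep(g, reps) + rnorm(8 * reps))
    fit_reml(tt, model_spec())$H2
  }
  h2 <- vapply(c(2, 4, 8), h2_at, 0)
  expect_true(all(diff(h2) > 0))
  expect_true(all(h2 >= 0 & h2 <= 1))
})

test_that("model search finds planted AR1 row correlation and respects tie-breaks", {
  hits <- 0
  for (r in 1:20) {
    sel <- select_optimal_model(sim_trial(1000 + r, rho_row = 0.6))
    if (sel$spec$ar1_row) hits <- hits + 1
  }
  expect_gte(hits, 14)              # >= 70% of 20 replicates

  # single-spec catalog returns that fit
  tt <- sim_trial(3)
  only <- select_optimal_model(tt, catalog = list(model_spec()))
  expect_identical(format(only$spec), format(model_spec()))

  # selected model is never worse than the nested baseline
  sel <- select_optimal_model(tt)
  base_ll <- fit_reml(tt, model_spec())$logLik
  if (sel$spec$genotype == "random")
    expect_gte(sel$fit$logLik, base_ll - 1e-6)
  expect_true(all(vapply(sel$fits, function(f)
    f$H2 >= 0 && f$H2 <= 1, TRUE)))
})

test_that("BLUEs are unshrunken GLS means with valid standard errors", {
  # unreplicated balanced iid trial: BLUE = plot value, SE = residual SD
  set.seed(21)
  tt <- data.frame(hybrid = sprintf("g%02d", 1:32), row = rep(1:8, 4),
                   col = rep(1:4, each = 8),
                   yield_t_ha = 10 + rnorm(32))
  fit <- fit_reml(tt, model_spec())
  bl <- predict_blues(tt, fit)
  expect_equal(nrow(bl), 32)
  expect_equal(bl$blue[match(tt$hybrid, bl$hybrid)], tt$yield_t_ha)
  expect_equal(bl$se,
               rep(sqrt(fit$var_components[["residual"]]), 32))

  # unbiasedness on replicated noisy trials
  set.seed(22)
  bias <- replicate(10, {
    g <- rnorm(8)
    tt <- sim_trial(sample.int(1e6, 1), sg = 0)
    tt$yield_t_ha <- tt$yield_t_ha + g[match(tt$hybrid, sprintf("g%d", 1:8))]
    fit <- fit_reml(tt, model_spec())
    bl <- predict_blues(tt, fit)
    mean(bl$blue - 10 - g[match(bl$hybrid, sprintf("g%d", 1:8))])
  })
  expect_lt(abs(mean(bias)), 0.15)

  # hybrid with no data is omitted with a warning
  tt2 <- tt[tt$hybrid != "g01", ]
  fit2 <- fit_reml(tt2, model_spec())
  expect_warning(bl2 <- predict_blues(rbind(tt2,
    transform(tt[1, ], yield_t_ha = NA)), fit2), "omitted")
  expect_equal(nrow(bl2), 31)
})
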