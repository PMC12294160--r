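#' Ground-truth parameter set for a simulated MET
#'
#' Draws a complete simulation truth mirroring the study design the
#' package targets: 32 hybrids in 4 maturity groups of 8, 12
#' environments (6 locations x 2 years), FA(k) genetic covariance
#' between environments, heterogeneous within-trial error variances
#' (max:min ratio at least 5 by construction) and an optional designed
#' correlation between one factor's loadings and an environmental
#' covariate.
#'
#' The first factor's loadings are positive (non-crossover
#' interaction) with mean about 0.85; the second factor flips sign
#' between years, the pattern under which a two-factor structure is
#' clearly identified.
#'
#' @param I number of hybrids (multiple of `n_groups`).
#' @param J number of environments (must be `n_locations * n_years`).
#' @param k true factor order (`k < J`).
#' @param link `NULL` or list with `factor` (index), `r` (designed
#'   Pearson correlation in `[-1, 1]`) linking that factor's loadings
#'   to the generated `covariate`.
#' @param seed integer root seed; all generators derive their streams
#'   from it.
#' @param n_groups maturity groups.
#' @return object of class `famet_truth`: list with `I`, `J`, `k`,
#'   `mu`, `Lambda`, `Psi`, `scores`, `delta`, `u` (total genetic
#'   effects), `covariate`, `groups`, `hybrids`, `environments`,
#'   `sigma2_trial` (per-trial error variances), `se_met`
#'   (per-environment stage-two cell standard errors), spatial
#'   parameters and `seed`.
#' @export
make_truth <- function(I = 32, J = 12, k = 2, link = list(factor = 1,
                       r = -0.8), seed = 1, n_groups = 4) {
  stopifnot(k < J, n_groups >= 1)
  if (!is.null(link) && abs(link$r) > 1) stop("designed |r| must be <= 1")
  set.seed(seed)
  locs <- c("BM", "KUT", "OSK", "RUG", "SAS", "TOV")
  n_years <- 2
  n_loc <- ceiling(J / n_years)
  locs <- rep(locs, length.out = n_loc)
  if (anyDuplicated(locs)) locs <- paste0("L", seq_len(n_loc))
  envs <- as.vector(outer(locs, 2017:(2016 + n_years), env_key))[seq_len(J)]
  years <- as.integer(sub(".*\\.", "", envs))
  mu <- runif(J, 8, 14.5)
  covariate <- runif(J, 1.0, 2.6)            # VPD-like seasonal demand
  Lambda <- matrix(0, J, k, dimnames = list(envs, NULL))
  raw1 <- rnorm(J)
  if (!is.null(link) && link$factor == 1) {
    resid <- residuals(lm(raw1 ~ covariate))
    w <- link$r * scale(covariate)[, 1] +
      sqrt(1 - link$r^2) * scale(resid)[, 1]
  } else w <- scale(raw1)[, 1]
  Lambda[, 1] <- pmax(0.85 + 0.25 * w, 0.05)
  if (k >= 2) {
    sgn <- ifelse(years == min(years), 1, -1)
    for (m in 2:k) {
      lm_raw <- if (m == 2) sgn * (0.45 + 0.1 * rnorm(J))
                else 0.25 * rnorm(J)
      # orthogonalize against earlier columns: the truth is expressed
      # in the principal-axis form the fitted model identifies
      prev <- Lambda[, seq_len(m - 1), drop = FALSE]
      Lambda[, m] <- lm_raw -
        prev %*% solve(crossprod(prev), crossprod(prev, lm_raw))
    }
  }
  cum_pct <- runif(J, 35, 85)
  Psi <- rowSums(Lambda^2) * (100 - cum_pct) / cum_pct
  hybrids <- sprintf("H%02d", seq_len(I))
  groups <- rep(MATURITY_GROUPS[seq_len(n_groups)],
                each = ceiling(I / n_groups))[seq_len(I)]
  scores <- matrix(rnorm(I * k), I, k, dimnames = list(hybrids, NULL))
  delta <- sweep(matrix(rnorm(I * J), I, J,
                        dimnames = list(hybrids, envs)),
                 2, sqrt(Psi), "*")
  u <- scores %*% t(Lambda) + delta
  n_trials <- J * n_groups
  s2 <- exp(runif(n_trials, log(0.1), log(0.8)))
  if (max(s2) / min(s2) < 5) {               # guarantee the >5 spread
    gm <- exp(mean(log(s2)))
    s2 <- gm * (s2 / gm)^(log(6) / log(max(s2) / min(s2)))
  }
  sigma2_trial <- matrix(s2, J, n_groups,
                         dimnames = list(envs, MATURITY_GROUPS[seq_len(n_groups)]))
  structure(list(I = I, J = J, k = k, mu = setNames(mu, envs),
                 Lambda = Lambda, Psi = setNames(Psi, envs),
                 scores = scores, delta = delta, u = u,
                 covariate = setNames(covariate, envs),
                 hybrids = hybrids, groups = setNames(groups, hybrids),
                 environments = envs,
                 sigma2_trial = sigma2_trial,
                 se_met = setNames(sqrt(rowMeans(sigma2_trial) / 4), envs),
                 sigma2_row = 0.05, sigma2_col = 0.05,
                 rho_row = 0.25, rho_col = 0.25,
                 seed = as.integer(seed)),
            class = "famet_truth")
}

#' @export
print.famet_truth <- function(x, ...) {
  cat(sprintf("simulation truth: %d hybrids x %d environments, FA(%d)\n",
              x$I, x$J, x$k))
  invisible(x)
}

#' Simulate plot-level trial data from a truth object
#'
#' Each (environment, maturity group) pair becomes one row-column
#' trial: the group's hybrids are laid out with `n_reps` replicates on
#' an `n_hybrids x n_reps` grid (randomized within columns), and plot
#' yield is `mu_j + u[i,j] + row + col + AR1xAR1 plot error` with the
#' trial's own error variance.
#'
#' @param truth `famet_truth`.
#' @param n_reps replicates per hybrid within a trial (default 4,
#'   giving 32-plot trials for groups of 8).
#' @return `famet_trials` dataset.
#' @export
simulate_met <- function(truth, n_reps = 4) {
  set.seed(truth$seed + 1L)
  per_group <- split(truth$hybrids, truth$groups)
  recs <- list()
  for (j in seq_len(truth$J)) {
    envid <- truth$environments[j]
    loc <- sub("\\..*", "", envid)
    yr <- as.integer(sub(".*\\.", "", envid))
    for (g in seq_along(per_group)) {
      hyb <- per_group[[g]]
      nr <- length(hyb); nc <- n_reps
      layout <- vapply(seq_len(nc), function(cc) sample(hyb), hyb)
      rows <- as.vector(row(layout)); cols <- as.vector(col(layout))
      ids <- as.vector(layout)
      s2e <- truth$sigma2_trial[j, g]
      ar1 <- function(n, rho) rho^abs(outer(seq_len(n), seq_len(n), "-"))
      e <- if (s2e < 1e-12) rep(0, nr * nc) else {
        R <- kronecker(ar1(nc, truth$rho_col), ar1(nr, truth$rho_row))
        drop(crossprod(chol(s2e * R), rnorm(nr * nc)))
      }
      re <- rnorm(nr, 0, sqrt(truth$sigma2_row))
      ce <- rnorm(nc, 0, sqrt(truth$sigma2_col))
      y <- truth$mu[j] + truth$u[ids, envid] + re[rows] + ce[cols] + e
      recs[[paste(envid, g)]] <- data.frame(
        location = loc, year = yr,
        maturity_group = names(per_group)[g],
        trial_id = paste(envid, names(per_group)[g], sep = "_"),
        row = rows, col = cols, hybrid = ids,
        yield_t_ha = pmax(as.numeric(y), 0))
    }
  }
  as_trial_dataset(do.call(rbind, c(recs, make.row.names = FALSE)))
}

#' Simulate a stage-two MET table directly from a truth object
#'
#' Bypasses the plot level: `blue[i,j] = mu_j + u[i,j] + e[i,j]` with
#' `e[i,j] ~ N(0, se_j^2)` using the truth's per-environment cell
#' standard errors. Convenient for exercising the factor-analytic
#' stage at known truth.
#'
#' @param truth `famet_truth`.
#' @return `famet_met` table.
#' @export
simulate_met_table <- function(truth) {
  set.seed(truth$seed + 2L)
  E <- sweep(matrix(rnorm(truth$I * truth$J), truth$I, truth$J), 2,
             truth$se_met, "*")
  B <- sweep(truth$u + E, 2, truth$mu, "+")
  dimnames(B) <- list(truth$hybrids, truth$environments)
  SE <- matrix(truth$se_met, truth$I, truth$J, byrow = TRUE,
               dimnames = dimnames(B))
  structure(list(blue = B, se = SE, genotypes = truth$hybrids,
                 environments = truth$environments),
            class = "famet_met")
}

#' Simulate station weather with controllable drought structure
#'
#' Generates an hourly May-September series for one location-year plus
#' a multi-decade monthly climatology (temperature, precipitation) for
#' Palmer-index calibration. A drought episode multiplies the affected
#' months' precipitation and depresses relative humidity (which raises
#' VPD).
#'
#' @param location location code.
#' @param year trial year.
#' @param seed integer seed.
#' @param drought `NULL` or list with `months` (calendar months
#'   affected), `precip_multiplier` (< 1 for drought),
#'   `rh_depression` (percentage points), `temp_anomaly_c`.
#' @param n_clim_years length of the climatology preceding and
#'   including `year`.
#' @return list with `hourly` (weather data.frame) and `climatology`
#'   (`year`, `month`, `temp_c`, `precip_mm`).
#' @export
simulate_weather <- function(location, year, seed = 1, drought = NULL,
                             n_clim_years = 40) {
  set.seed(seed)
  t_norm <- c(0.5, 2.5, 7.0, 12.0, 17.0, 20.5, 22.5, 22.0, 17.5,
              12.5, 6.5, 1.5)
  p_norm <- c(50, 45, 55, 65, 75, 85, 70, 75, 80, 75, 85, 65)
  yrs <- (year - n_clim_years + 1):year
  clim <- expand.grid(month = 1:12, year = yrs)[, 2:1]
  clim$temp_c <- t_norm[clim$month] + rnorm(nrow(clim), 0, 1.2)
  clim$precip_mm <- p_norm[clim$month] *
    rgamma(nrow(clim), shape = 6, rate = 6)
  if (!is.null(drought)) {
    hit <- clim$year == year & clim$month %in% drought$months
    clim$precip_mm[hit] <- clim$precip_mm[hit] *
      (drought$precip_multiplier %||% 0.3)
    clim$temp_c[hit] <- clim$temp_c[hit] + (drought$temp_anomaly_c %||% 1.5)
  }
  # hourly series for the vegetation period of the trial year
  days <- seq(as.Date(sprintf("%d-05-01", year)),
              as.Date(sprintf("%d-09-30", year)), by = "day")
  mo <- as.integer(format(days, "%m"))
  t_day <- clim$temp_c[match(paste(year, mo),
                             paste(clim$year, clim$month))] +
    rnorm(length(days), 0, 1.5)
  rh_base <- pmin(pmax(72 - 0.8 * (t_day - 17) +
                         rnorm(length(days), 0, 4), 25), 98)
  p_month <- clim$precip_mm[match(paste(year, mo),
                                  paste(clim$year, clim$month))]
  mdays <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  rain_today <- runif(length(days)) < 0.3
  p_day <- ifelse(rain_today, p_month / (0.3 * mdays[mo]), 0)
  if (!is.null(drought)) {
    hit <- mo %in% drought$months
    rh_base[hit] <- pmax(rh_base[hit] - (drought$rh_depression %||% 0), 5)
  }
  hours <- 0:23
  hourly <- data.frame(
    location = location,
    timestamp = rep(as.POSIXct(days, tz = "UTC"), each = 24) +
      rep(hours * 3600, length(days)),
    temp_c = rep(t_day, each = 24) +
      5 * cos(2 * pi * (rep(hours, length(days)) - 14) / 24),
    rh_pct = pmin(pmax(rep(rh_base, each = 24) -
      9 * cos(2 * pi * (rep(hours, length(days)) - 14) / 24) +
      rnorm(length(days) * 24, 0, 1.5), 3), 100),
    precip_mm = as.vector(vapply(seq_along(days), function(d) {
      w <- rep(0, 24)
      if (p_day[d] > 0) {
        hrs <- sample(24, 4)
        w[hrs] <- p_day[d] / 4
      }
      w
    }, numeric(24))))
  list(hourly = structure(hourly[c("timestamp", "temp_c", "rh_pct",
                                   "precip_mm")],
                          location = location, has_gaps = FALSE,
                          class = c("famet_weather", "data.frame")),
       climatology = clim)
}
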