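#' Palmer two-layer water balance
#'
#' Monthly bookkeeping of the Palmer soil moisture model: a surface
#' layer holding 25.4 mm (Palmer's one inch) and an underlying layer
#' holding `awc_mm - 25.4`. Evapotranspiration draws on precipitation
#' first, then on the surface layer, then proportionally on the
#' underlying layer; recharge fills the surface layer first; runoff
#' occurs only once both layers are full. Potential terms (PR, PRO,
#' PL) follow Palmer's definitions.
#'
#' @param P precipitation per period, mm (non-negative).
#' @param PET potential evapotranspiration per period, mm.
#' @param awc_mm available water capacity of the profile, > 25.4 mm.
#' @param start_full logical, start with a full profile (default) or
#'   empty.
#' @return data.frame per period with `P`, `PET`, `ET`, `R`
#'   (recharge), `RO` (runoff), `L` (loss), `PR`, `PRO`, `PL`, and
#'   end-of-period storages `Ss`, `Su`.
#' @export
palmer_water_balance <- function(P, PET, awc_mm, start_full = TRUE) {
  stopifnot(length(P) == length(PET), awc_mm > 25.4)
  if (any(P < 0)) stop("negative precipitation")
  ss_cap <- 25.4; su_cap <- awc_mm - 25.4
  ss <- if (start_full) ss_cap else 0
  su <- if (start_full) su_cap else 0
  n <- length(P)
  out <- matrix(0, n, 10,
                dimnames = list(NULL, c("ET", "R", "RO", "L", "PR",
                                        "PRO", "PL", "Ss", "Su", "dS")))
  for (t in seq_len(n)) {
    # potentials, from start-of-period storage
    pr <- awc_mm - (ss + su)
    pro <- ss + su
    pls <- min(PET[t], ss)
    plu <- min((PET[t] - pls) * su / awc_mm, su)
    pl <- pls + plu
    if (P[t] >= PET[t]) {
      et <- PET[t]
      surplus <- P[t] - PET[t]
      r_s <- min(surplus, ss_cap - ss)
      r_u <- min(surplus - r_s, su_cap - su)
      r <- r_s + r_u
      ro <- surplus - r
      ss <- ss + r_s; su <- su + r_u
      l <- 0
    } else {
      deficit <- PET[t] - P[t]
      ls <- min(ss, deficit)
      lu <- min((deficit - ls) * su / awc_mm, su)
      et <- P[t] + ls + lu
      ss <- ss - ls; su <- su - lu
      l <- ls + lu
      r <- 0; ro <- 0
    }
    out[t, ] <- c(et, r, ro, l, pr, pro, pl, ss, su,
                  r - l)      # storage change
  }
  data.frame(P = P, PET = PET, out)
}

#' CAFEC coefficients, moisture departures and Palmer Z-index
#'
#' Per calendar month over the calibration window, computes the CAFEC
#' ("climatically appropriate for existing conditions") ratio
#' coefficients `alpha = mean(ET)/mean(PET)`, `beta = mean(R)/mean(PR)`,
#' `gamma = mean(RO)/mean(PRO)`, `delta = mean(L)/mean(PL)` (0/0 ratios
#' fall back to 1 for alpha and 0 for the others, flagged), the CAFEC
#' precipitation `P_hat = alpha*PET + beta*PR + gamma*PRO - delta*PL`,
#' the moisture departure `d = P - P_hat`, Palmer's empirical climatic
#' characteristic `K` and the moisture anomaly `Z = d * K`.
#'
#' @param balance water-balance data.frame from
#'   [palmer_water_balance()].
#' @param year,month calendar year and month of each balance period.
#' @param calibration_window `(start, end)` years for the coefficient
#'   and `K` calibration.
#' @return list with `trace` (data.frame `year`, `month`, `d`, `K`,
#'   `Z`, `P_hat`), `coefficients` (12 x 4), `flags`.
#' @export
cafec_and_z <- function(balance, year, month,
                        calibration_window = range(year)) {
  stopifnot(nrow(balance) == length(year), length(year) == length(month))
  cal <- year >= calibration_window[1] & year <= calibration_window[2]
  if (sum(cal) < 120)
    warning("calibration window shorter than 10 years")
  ratio <- function(num, den, zero_val) {
    n <- mean(num); d <- mean(den)
    if (d <= 0) if (n <= 0) zero_val else 1 else min(max(n / d, 0), 1)
  }
  co <- t(vapply(1:12, function(m) {
    i <- cal & month == m
    c(alpha = ratio(balance$ET[i], balance$PET[i], 1),
      beta = ratio(balance$R[i], balance$PR[i], 0),
      gamma = ratio(balance$RO[i], balance$PRO[i], 0),
      delta = ratio(balance$L[i], balance$PL[i], 0))
  }, numeric(4)))
  # CAFEC precipitation; the loss term enters negatively, mirroring
  # the balance identity P = ET + R + RO - L
  p_hat <- co[month, "alpha"] * balance$PET + co[month, "beta"] * balance$PR +
    co[month, "gamma"] * balance$PRO - co[month, "delta"] * balance$PL
  d <- balance$P - p_hat
  # Palmer's climatic characteristic; the empirical constants are for
  # inches, so departures enter as d / 25.4
  din <- d / 25.4
  Kp <- vapply(1:12, function(m) {
    i <- cal & month == m
    Dbar <- mean(abs(din[i]))
    if (Dbar <= 0) return(0)
    Tm <- (mean(balance$PET[i]) + mean(balance$R[i]) + mean(balance$RO[i])) /
      (mean(balance$P[i]) + mean(balance$L[i]) + 1e-12)
    1.5 * log10((Tm + 2.8) / Dbar) + 0.5
  }, 0)
  DK <- sum(vapply(1:12, function(m)
    mean(abs(din[cal & month == m])) * Kp[m], 0))
  K <- if (DK > 0) 17.67 * Kp / DK else rep(0, 12)
  list(trace = data.frame(year = year, month = month, d = d,
                          K = K[month], Z = din * K[month], P_hat = p_hat),
       coefficients = co,
       flags = list(degenerate_K = DK <= 0))
}

# duration factors from linear fits of extreme accumulated Z against
# run length (dry: most negative sums, wet: most positive)
.duration_factors <- function(Z, lengths = c(3, 6, 9, 12, 18, 24, 36, 48)) {
  lengths <- lengths[lengths <= length(Z)]
  run_extreme <- function(L, dry) {
    cs <- c(0, cumsum(Z))
    sums <- cs[(L + 1):length(cs)] - cs[1:(length(cs) - L)]
    if (dry) min(sums) else max(sums)
  }
  fac <- function(dry) {
    y <- vapply(lengths, run_extreme, 0, dry = dry)
    fit <- coef(lm(y ~ lengths))
    b <- fit[[1]]; m <- fit[[2]]
    denom <- m + b
    c_target <- if (dry) -4 else 4
    if (abs(denom) < 1e-12) return(c(p = 0.897, q = 1 / 3))
    # clamp to the stable region; extreme-run regressions on short or
    # skewed records can otherwise give an explosive recursion
    c(p = min(max(1 - m / denom, 0.5), 0.99),
      q = min(max(c_target / denom, 0.05), 1.5))
  }
  list(dry = fac(TRUE), wet = fac(FALSE))
}

# Palmer X recursion with X1/X2/X3 spell bookkeeping and
# probability-of-ending backtracking
.palmer_x <- function(Z, dry, wet) {
  n <- length(Z)
  X <- numeric(n)
  x1 <- x2 <- x3 <- 0      # tentative wet, tentative dry, established
  V <- 0; Q <- 0
  pending <- integer(0)    # periods assigned provisionally
  x1h <- x2h <- numeric(n) # tentative-index histories for backtracking
  for (t in seq_len(n)) {
    z <- Z[t]
    x1 <- max(0, wet[["p"]] * x1 + wet[["q"]] * z)
    x2 <- min(0, dry[["p"]] * x2 + dry[["q"]] * z)
    x1h[t] <- x1; x2h[t] <- x2
    if (x3 == 0) {
      if (x1 >= 1) {                     # wet spell establishes
        x3 <- x1
        X[pending] <- x1h[pending]; pending <- integer(0)
        X[t] <- x3; x1 <- 0; x2 <- 0; V <- 0
      } else if (x2 <= -1) {             # dry spell establishes
        x3 <- x2
        X[pending] <- x2h[pending]; pending <- integer(0)
        X[t] <- x3; x1 <- 0; x2 <- 0; V <- 0
      } else {
        X[t] <- if (abs(x1) >= abs(x2)) x1 else x2
        pending <- c(pending, t)
      }
      next
    }
    fac <- if (x3 < 0) dry else wet
    x3new <- fac[["p"]] * x3 + fac[["q"]] * z
    # moisture needed to terminate the spell (bring X3 to the 0.5
    # band on the other side), and the Z that would just maintain 0.5
    if (x3 < 0) {
      Ze <- (0.5 - dry[["p"]] * x3) / dry[["q"]]
      U <- z - (-0.5) * (1 - dry[["p"]]) / dry[["q"]]
    } else {
      Ze <- (-0.5 - wet[["p"]] * x3) / wet[["q"]]
      U <- z - 0.5 * (1 - wet[["p"]]) / wet[["q"]]
      Ze <- -Ze; U <- -U                 # work with positive magnitudes
    }
    if (V <= 0) Q <- Ze           # fresh chance of the spell ending
    V <- max(V, 0) + U
    Pe <- if (V <= 0) 0 else min(100 * V / Q, 100)
    if (V <= 0) V <- 0
    if (Pe >= 100 || abs(x3new) < 0.5) {
      # spell over: provisional periods take the opposite tentative path
      X[pending] <- if (x3 < 0) x1h[pending] else x2h[pending]
      x3 <- 0; V <- 0
      X[t] <- if (abs(x1) >= abs(x2)) x1 else x2
      pending <- t
    } else {
      x3 <- x3new
      X[t] <- x3
      if (Pe > 0) pending <- c(pending, t) else pending <- integer(0)
    }
  }
  X
}

#' Self-calibrating Palmer Drought Severity Index
#'
#' Calibrates the Palmer recursion to the local climate record:
#' duration factors `p` and `q` are derived (separately for dry and
#' wet runs) from linear fits of extreme accumulated Z against run
#' length, replacing Palmer's fixed 0.897 and 1/3; the moisture
#' anomaly is then rescaled so that the 2nd percentile of the index
#' equals -4 and the 98th equals +4 on the calibration record. The
#' index recursion `X_t = p X_(t-1) + q Z_t` runs with Palmer's
#' X1/X2/X3 spell logic and probability-of-ending backtracking.
#'
#' @param Z monthly moisture anomaly series (from [cafec_and_z()]).
#' @param n_iter calibration passes (duration factors + percentile
#'   rescale), default 2.
#' @return object of class `famet_pdsi`: list with `X` (scPDSI), `Z`
#'   (rescaled anomaly), `duration` (dry/wet `p`, `q`), `scale`
#'   (dry/wet Z multipliers), `degenerate` flag.
#' @export
self_calibrate_scpdsi <- function(Z, n_iter = 2) {
  if (length(Z) < 120)
    warning("fewer than 10 years of Z; calibration may be unstable")
  if (all(abs(Z) < 1e-12)) {
    return(structure(list(X = rep(0, length(Z)), Z = Z,
                          duration = NULL, scale = c(dry = 1, wet = 1),
                          degenerate = TRUE), class = "famet_pdsi"))
  }
  Zs <- Z
  sc <- c(dry = 1, wet = 1)
  # duration factors are fixed after the first pass; the percentile
  # calibration then rescales the anomaly (equivalently K) so that the
  # 2nd/98th percentiles of the index sit at -4/+4
  dur <- .duration_factors(Zs)
  X <- .palmer_x(Zs, dur$dry, dur$wet)
  for (it in seq_len(n_iter)) {
    q02 <- quantile(X, 0.02, names = FALSE)
    q98 <- quantile(X, 0.98, names = FALSE)
    f_dry <- if (q02 < -1e-8) -4 / q02 else 1
    f_wet <- if (q98 > 1e-8) 4 / q98 else 1
    Zs <- ifelse(Zs < 0, Zs * f_dry, Zs * f_wet)
    sc <- sc * c(dry = f_dry, wet = f_wet)
    X <- .palmer_x(Zs, dur$dry, dur$wet)
  }
  structure(list(X = X, Z = Zs, duration = dur, scale = sc,
                 degenerate = FALSE), class = "famet_pdsi")
}

#' @export
print.famet_pdsi <- function(x, ...) {
  cat(sprintf("scPDSI trace: %d periods, range [%.2f, %.2f]%s\n",
              length(x$X), min(x$X), max(x$X),
              if (x$degenerate) " (degenerate climate)" else ""))
  invisible(x)
}

#' Palmer drought class of an scPDSI value
#'
#' Palmer's scale: within 0.49 of zero "near normal" (sign reported as
#' surplus/deficit side), 0.5-0.99 incipient, 1-1.99 slight, 2-2.99
#' moderate, 3-3.99 severe, beyond 4 extreme (dry or wet). The water
#' deficit flag is `value < -0.49`.
#'
#' @param x scPDSI value(s).
#' @return data.frame with `value`, `class`, `side`, `deficit`.
#' @export
classify_environment <- function(x) {
  stopifnot(all(is.finite(x)))
  sev <- cut(abs(x), c(-Inf, 0.495, 0.995, 1.995, 2.995, 3.995, Inf),
             labels = c("near normal", "incipient", "slight",
                        "moderate", "severe", "extreme"))
  side <- ifelse(x >= 0, "wet", "dry")
  cls <- ifelse(sev == "near normal", "near normal",
                paste(as.character(sev),
                      ifelse(x >= 0, "wet spell", "drought")))
  data.frame(value = x, class = cls,
             side = ifelse(x >= 0, "surplus", "deficit"),
             deficit = x < -0.49)
}

#' Monthly scPDSI from a temperature/precipitation climatology
#'
#' Chains PET (Thornthwaite), the Palmer water balance, CAFEC/Z
#' computation and self-calibration.
#'
#' @param climatology data.frame with `year`, `month`, `temp_c`,
#'   `precip_mm` (complete consecutive months).
#' @param latitude_deg station latitude.
#' @param awc_mm available water capacity, mm.
#' @param calibration_window years used for calibration (default all).
#' @return list with `trace` (year, month, PET, d, K, Z, X) and the
#'   `famet_pdsi` calibration object.
#' @export
compute_scpdsi <- function(climatology, latitude_deg = 45, awc_mm = 150,
                           calibration_window = range(climatology$year)) {
  cl <- climatology[order(climatology$year, climatology$month), ]
  pet <- thornthwaite_pet(cl$temp_c, cl$month, latitude_deg)
  bal <- palmer_water_balance(cl$precip_mm, pet, awc_mm)
  cz <- cafec_and_z(bal, cl$year, cl$month, calibration_window)
  pdsi <- self_calibrate_scpdsi(cz$trace$Z)
  list(trace = data.frame(year = cl$year, month = cl$month, PET = pet,
                          d = cz$trace$d, K = cz$trace$K,
                          Z = pdsi$Z, X = pdsi$X),
       calibration = pdsi)
}

#' Seasonal environment covariate table
#'
#' Per environment (location x year): seasonal means of daily minimum,
#' maximum and mean temperature, rainfall sum, mean relative humidity,
#' pointwise-mean VPD, and the seasonal mean scPDSI. An environment
#' covering less than 80% of the season's hours is flagged.
#'
#' @param weather_by_env named list (keys "LOC.YYYY") of hourly
#'   weather data.frames (`timestamp`, `temp_c`, `rh_pct`,
#'   `precip_mm`).
#' @param scpdsi named numeric vector of seasonal mean scPDSI per
#'   environment (optional, `NA` when absent).
#' @param cfg `famet_config` (vegetation months).
#' @return data.frame, one row per environment, columns `environment`,
#'   `tmin_c`, `tmax_c`, `tavg_c`, `rainfall_mm`, `rh_pct`, `vpd_kpa`,
#'   `scpdsi`, `coverage`, `flagged`.
#' @export
build_env_covariates <- function(weather_by_env, scpdsi = NULL,
                                 cfg = analysis_config()) {
  months <- cfg$vegetation_months
  rows <- lapply(names(weather_by_env), function(envid) {
    w <- weather_by_env[[envid]]
    mo <- as.integer(format(w$timestamp, "%m"))
    w <- w[mo %in% months, ]
    day <- format(w$timestamp, "%Y-%m-%d")
    tmin <- tapply(w$temp_c, day, min)
    tmax <- tapply(w$temp_c, day, max)
    tavg <- tapply(w$temp_c, day, mean)
    mdays <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
    expected <- sum(mdays[months]) * 24
    coverage <- nrow(w) / expected
    data.frame(environment = envid,
               tmin_c = mean(tmin), tmax_c = mean(tmax),
               tavg_c = mean(tavg),
               rainfall_mm = sum(w$precip_mm, na.rm = TRUE),
               rh_pct = mean(w$rh_pct, na.rm = TRUE),
               vpd_kpa = mean(vpd(w$temp_c, w$rh_pct), na.rm = TRUE),
               scpdsi = if (!is.null(scpdsi) && envid %in% names(scpdsi))
                 scpdsi[[envid]] else NA_real_,
               coverage = coverage,
               flagged = coverage < 0.8)
  })
  do.call(rbind, rows)
}
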