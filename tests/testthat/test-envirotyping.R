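test_that("saturation vapor pressure follows the Tetens curve", {
  expect_equal(saturation_vapor_pressure(0), 0.6108)
  # hand evaluation at 25 C: 0.6108 * exp(17.27*25/262.3)
  expect_equal(saturation_vapor_pressure(25),
               0.6108 * exp(17.27 * 25 / (25 + 237.3)))
  expect_equal(round(saturation_vapor_pressure(25), 2), 3.17)
  grid <- seq(-20, 45, by = 0.5)
  expect_true(all(diff(saturation_vapor_pressure(grid)) > 0))
  expect_error(saturation_vapor_pressure(80), "plausible range")
})

test_that("VPD is zero at saturation and monotone in temperature and humidity", {
  expect_equal(vpd(c(-5, 10, 30), 100), rep(0, 3))
  v25 <- vpd(25, 50)
  expect_equal(v25, saturation_vapor_pressure(25) / 2)
  expect_equal(vpd_class(v25), "below-threshold")   # 1.58 kPa < 1.7
  expect_equal(vpd_class(c(2.0, 2.7, 3.4)),
               c("sensitivity-band", "elevated", "severe"))
  tgrid <- seq(5, 40, 1)
  expect_true(all(diff(vpd(tgrid, 60)) > 0))
  rhgrid <- seq(0, 100, 5)
  expect_true(all(diff(vpd(25, rhgrid)) < 0))
  expect_error(vpd(25, 130), "humidity")
})

test_that("windowed VPD equals pointwise VPD under constant weather", {
  ts <- seq(as.POSIXct("2017-05-01", tz = "UTC"),
            as.POSIXct("2017-09-30 23:00", tz = "UTC"), by = "hour")
  s <- data.frame(timestamp = ts, temp_c = 22, rh_pct = 55,
                  precip_mm = 0)
  agg <- aggregate_vpd(s, "seasonal")
  expect_equal(agg$vpd_kpa, vpd(22, 55))
  expect_equal(agg$coverage, 1)
  mon <- aggregate_vpd(s, "monthly")
  expect_equal(nrow(mon), 5)
  dek <- aggregate_vpd(s, "10day")
  expect_equal(nrow(dek), 15)
})

test_that("Thornthwaite PET reproduces hand arithmetic and its limits", {
  expect_equal(thornthwaite_pet(rep(-3, 12), 1:12), rep(0, 12))
  # constant 20 C year, hand evaluation
  heat_i <- 12 * (20 / 5)^1.514
  a <- 6.75e-7 * heat_i^3 - 7.71e-5 * heat_i^2 + 1.792e-2 * heat_i +
    0.49239
  pet_raw <- 16 * (10 * 20 / heat_i)^a
  got <- thornthwaite_pet(rep(20, 12), 1:12, latitude_deg = 45)
  dl <- geosphere::daylength(45, c(15, 46, 74, 105, 135, 166, 196,
                                   227, 258, 288, 319, 349))
  nd <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  expect_equal(got, pet_raw * (dl / 12) * (nd / 30), tolerance = 1e-10)
  # monotone in temperature
  p1 <- thornthwaite_pet(c(rep(10, 11), 15), c(1:11, 7), 45)[12]
  p2 <- thornthwaite_pet(c(rep(10, 11), 25), c(1:11, 7), 45)[12]
  expect_gt(p2, p1)
})

test_that("the Palmer water balance conserves mass and orders layer depletion", {
  set.seed(8)
  P <- rgamma(240, 4, scale = 18)
  PET <- pmax(rnorm(240, 60, 25), 0)
  bal <- palmer_water_balance(P, PET, awc_mm = 150)
  expect_lt(max(abs(bal$P - bal$ET - bal$RO - bal$dS)), 1e-9)
  expect_true(all(bal$Ss >= 0 & bal$Ss <= 25.4))
  expect_true(all(bal$Su >= 0 & bal$Su <= 150 - 25.4))

  # equilibrium: P = PET with a full profile
  eq <- palmer_water_balance(rep(50, 24), rep(50, 24), 150)
  expect_true(all(eq$L == 0) && all(eq$dS == 0))

  # drydown: storage non-increasing, surface empties before underlying
  dd <- palmer_water_balance(rep(0, 24), rep(80, 24), 150)
  expect_true(all(diff(dd$Ss + dd$Su) <= 1e-12))
  first_ss_empty <- which(dd$Ss <= 1e-9)[1]
  expect_true(dd$Su[first_ss_empty] > 1)
  expect_error(palmer_water_balance(c(-1, 0), c(1, 1), 150),
               "negative precipitation")
})

test_that("CAFEC departures vanish at equilibrium and respond locally", {
  yrs <- rep(1:30, each = 12); mos <- rep(1:12, 30)
  P <- rep(50, 360); PET <- rep(50, 360)
  bal <- palmer_water_balance(P, PET, 150)
  cz <- cafec_and_z(bal, 1900 + yrs, mos)
  expect_equal(max(abs(cz$trace$d)), 0)
  expect_true(all(cz$coefficients[, "alpha"] >= 0 &
                    cz$coefficients[, "alpha"] <= 1))

  P2 <- P; P2[180] <- 100
  bal2 <- palmer_water_balance(P2, PET, 150)
  cz2 <- cafec_and_z(bal2, 1900 + yrs, mos)
  expect_gt(cz2$trace$d[180], 0)
  # other months of other years keep near-zero departures
  other <- setdiff(which(mos != mos[180]), 180)
  expect_lt(max(abs(cz2$trace$d[other])), 1e-9)
})

test_that("self-calibration pins the index tails near the 2 percent target", {
  sw <- simulate_weather("CAL", 2017, seed = 5, n_clim_years = 100)
  res <- compute_scpdsi(sw$climatology, latitude_deg = 45.5,
                        awc_mm = 150)
  frac_dry <- mean(res$trace$X <= -4)
  expect_gte(frac_dry, 0.005)
  expect_lte(frac_dry, 0.035)

  expect_true(all(self_calibrate_scpdsi(rep(0, 240))$X == 0))

  # a sustained dry decade registers at least moderate drought
  drought <- simulate_weather("CAL", 2017, seed = 5, n_clim_years = 100,
    drought = list(months = 4:9, precip_multiplier = 0.2,
                   rh_depression = 15))
  rd <- compute_scpdsi(drought$climatology, 45.5, 150)
  sel <- rd$trace$year == 2017 & rd$trace$month %in% 5:9
  expect_lt(min(rd$trace$X[sel]), -2)
})

test_that("Palmer classes and the water-deficit threshold are honoured", {
  cls <- classify_environment(c(-0.3, -2.5, 0.2, -4.4, 1.2))
  expect_equal(cls$class[1], "near normal")
  expect_false(cls$deficit[1])
  expect_equal(cls$class[2], "moderate drought")
  expect_true(cls$deficit[2])
  expect_equal(cls$side[3], "surplus")
  expect_false(cls$deficit[3])
  expect_equal(cls$class[4], "extreme drought")
  expect_equal(cls$class[5], "slight wet spell")
  expect_equal(classify_environment(-0.5)$deficit, TRUE)
})

test_that("environment covariates aggregate the season faithfully", {
  ts <- seq(as.POSIXct("2017-05-01", tz = "UTC"),
            as.POSIXct("2017-09-30 23:00", tz = "UTC"), by = "hour")
  const <- data.frame(timestamp = ts, temp_c = 20, rh_pct = 60,
                      precip_mm = 0.1)
  drier <- transform(const, rh_pct = 40)
  cov <- build_env_covariates(list(`A.2017` = const, `B.2017` = drier))
  expect_equal(cov$tmin_c, cov$tmax_c)
  expect_equal(cov$tavg_c, c(20, 20))
  expect_equal(cov$rainfall_mm, rep(0.1 * length(ts), 2))
  expect_false(any(cov$flagged))
  expect_gt(cov$vpd_kpa[2], cov$vpd_kpa[1])   # lower RH, higher VPD

  truncated <- const[1:1000, ]
  cov2 <- build_env_covariates(list(`C.2017` = truncated))
  expect_true(cov2$flagged)
})
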