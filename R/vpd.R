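#' Saturation vapor pressure (Tetens/Magnus form)
#'
#' `es = 0.6108 * exp(17.27 * T / (T + 237.3))` kPa.
#'
#' @param temp_c air temperature in degrees C, within (-50, 60).
#' @return saturation vapor pressure in kPa.
#' @export
saturation_vapor_pressure <- function(temp_c) {
  if (any(temp_c <= -50 | temp_c >= 60, na.rm = TRUE))
    stop("temperature outside plausible range (-50, 60) C")
  0.6108 * exp(17.27 * temp_c / (temp_c + 237.3))
}

#' Vapor pressure deficit
#'
#' `VPD = es(T) * (1 - RH/100)` in kPa: the atmospheric demand for
#' water. High seasonal values indicate water deficit; values in the
#' 1.7-2.5 kPa band are known to depress maize transpiration.
#'
#' @param temp_c air temperature, degrees C.
#' @param rh_pct relative humidity in `[0, 100]`.
#' @return VPD in kPa.
#' @export
vpd <- function(temp_c, rh_pct) {
  if (any(rh_pct < 0 | rh_pct > 100, na.rm = TRUE))
    stop("relative humidity outside [0,100]")
  saturation_vapor_pressure(temp_c) * (1 - rh_pct / 100)
}

#' Transpiration-sensitivity class of a VPD value
#'
#' Bands: below 1.7 kPa `"below-threshold"`, 1.7-2.5 kPa
#' `"sensitivity-band"` (transpiration of many maize hybrids is
#' affected), 2.5-3 kPa `"elevated"`, above 3 kPa `"severe"`.
#'
#' @param vpd_kpa VPD in kPa.
#' @return character class label(s).
#' @export
vpd_class <- function(vpd_kpa) {
  cut(vpd_kpa, c(-Inf, 1.7, 2.5, 3, Inf), right = FALSE,
      labels = c("below-threshold", "sensitivity-band", "elevated",
                 "severe")) |> as.character()
}

#' Aggregate pointwise VPD over time windows
#'
#' VPD is computed per record (not from window-mean temperature and
#' humidity, to respect the nonlinearity of `es`) and averaged over
#' 10-day, monthly or whole-season windows. Records with missing RH or
#' temperature are excluded from the mean and reported as reduced
#' coverage.
#'
#' @param series weather series (data.frame with `timestamp`, `temp_c`,
#'   `rh_pct`).
#' @param window `"10day"`, `"monthly"` or `"seasonal"`.
#' @param vegetation_months months kept for the `"seasonal"` window.
#' @return data.frame with `window`, `vpd_kpa`, `coverage`.
#' @export
aggregate_vpd <- function(series, window = c("monthly", "10day", "seasonal"),
                          vegetation_months = 5:9) {
  window <- match.arg(window)
  v <- vpd(series$temp_c, series$rh_pct)
  ts <- series$timestamp
  mo <- as.integer(format(ts, "%m"))
  key <- switch(window,
    monthly = format(ts, "%Y-%m"),
    "10day" = paste0(format(ts, "%Y-%m"), "-d",
                     pmin((as.integer(format(ts, "%d")) - 1) %/% 10 + 1, 3)),
    seasonal = ifelse(mo %in% vegetation_months, format(ts, "%Y"), NA))
  ok <- !is.na(key)
  out <- do.call(rbind, lapply(split(v[ok], key[ok]), function(x)
    data.frame(vpd_kpa = mean(x, na.rm = TRUE),
               coverage = mean(!is.na(x)))))
  data.frame(window = rownames(out), out, row.names = NULL)
}

#' Thornthwaite potential evapotranspiration
#'
#' Temperature-only monthly PET with day-length correction. The annual
#' heat index is taken from the record's mean temperature per calendar
#' month; months at or below 0 degrees C contribute zero PET. For mean
#' temperatures above 26.5 the standard high-temperature polynomial is
#' used. Day length at mid-month comes from solar geometry
#' (`geosphere::daylength`).
#'
#' @param temp_c monthly mean temperatures.
#' @param month calendar month (1-12) of each entry.
#' @param latitude_deg station latitude in degrees.
#' @return PET in mm per month, same length as `temp_c`.
#' @export
thornthwaite_pet <- function(temp_c, month, latitude_deg = 45) {
  stopifnot(length(temp_c) == length(month), all(month %in% 1:12))
  clim <- vapply(1:12, function(m) {
    x <- temp_c[month == m]
    if (length(x)) mean(x, na.rm = TRUE) else 0
  }, 0)
  heat_i <- sum(pmax(clim / 5, 0)^1.514)
  if (heat_i <= 0) return(rep(0, length(temp_c)))
  a <- 6.75e-7 * heat_i^3 - 7.71e-5 * heat_i^2 + 1.792e-2 * heat_i +
    0.49239
  mid_doy <- c(15, 46, 74, 105, 135, 166, 196, 227, 258, 288, 319, 349)
  ndays <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  dl <- geosphere::daylength(latitude_deg, mid_doy)
  corr <- (dl / 12) * (ndays / 30)
  pet <- ifelse(temp_c <= 0, 0,
         ifelse(temp_c < 26.5,
                16 * (10 * temp_c / heat_i)^a,
                -415.85 + 32.24 * temp_c - 0.43 * temp_c^2))
  pet * corr[month]
}
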