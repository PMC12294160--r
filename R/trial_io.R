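#' Maturity groups recognised in plot tables
#' @keywords internal
MATURITY_GROUPS <- c("FAO300", "FAO400", "FAO500", "FAO600")

#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline: the vegetation
#' period over which weather is aggregated, the soil available water
#' capacity used by the Palmer water balance, the climatology window
#' used to calibrate the scPDSI, the maximal factor order tried in the
#' MET stage and the number of contrast environments picked for the
#' tolerance indices.
#'
#' @param vegetation_months integer months defining the growing season
#'   (default May-September).
#' @param awc_mm available water capacity of the soil profile in mm;
#'   either a single value or a named vector per location. Must exceed
#'   25.4 mm (the Palmer surface layer).
#' @param calibration_window length-2 integer vector `(start, end)` of
#'   calendar years used to calibrate the Palmer index.
#' @param fa_k_max maximal factor-analytic order fitted in stage two.
#' @param n_contrast_envs number of stress and of normal environments
#'   selected for the tolerance indices.
#' @param rng_seed integer seed used by simulation helpers.
#' @param column_map optional named character vector remapping CSV
#'   column names (values = names in the file, names = canonical names).
#' @return An object of class `famet_config`.
#' @export
analysis_config <- function(vegetation_months = 5:9,
                            awc_mm = 150,
                            calibration_window = c(1989, 2018),
                            fa_k_max = 5,
                            n_contrast_envs = 3,
                            rng_seed = 1L,
                            column_map = NULL) {
  stopifnot(all(vegetation_months %in% 1:12),
            all(awc_mm > 25.4),
            length(calibration_window) == 2,
            calibration_window[1] <= calibration_window[2],
            fa_k_max >= 1, n_contrast_envs >= 1)
  structure(list(vegetation_months = as.integer(vegetation_months),
                 awc_mm = awc_mm,
                 calibration_window = as.integer(calibration_window),
                 fa_k_max = as.integer(fa_k_max),
                 n_contrast_envs = as.integer(n_contrast_envs),
                 rng_seed = as.integer(rng_seed),
                 column_map = column_map),
            class = "famet_config")
}

#' Environment key "LOC.YYYY"
#' @param location character location code.
#' @param year integer year.
#' @return character environment id.
#' @export
env_key <- function(location, year) paste(location, year, sep = ".")

.remap_columns <- function(df, column_map) {
  if (is.null(column_map)) return(df)
  for (canon in names(column_map)) {
    src <- column_map[[canon]]
    if (src %in% names(df)) names(df)[names(df) == src] <- canon
  }
  df
}

#' Read a plot-level trial table
#'
#' Reads a CSV of plot records (one row per plot) and assembles a
#' validated trial dataset. Missing yields (empty cells) are preserved
#' as `NA`, never imputed.
#'
#' @param path CSV file with columns `location`, `year`,
#'   `maturity_group`, `trial_id`, `row`, `col`, `hybrid`,
#'   `yield_t_ha`.
#' @param column_map optional column-name remapping, see
#'   [analysis_config()].
#' @return An object of class `famet_trials`: list with `records`
#'   (data.frame), `environments` (character "LOC.YYYY"), `groups`.
#' @export
read_plot_table <- function(path, column_map = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df <- .remap_columns(df, column_map)
  needed <- c("location", "year", "maturity_group", "trial_id",
              "row", "col", "hybrid", "yield_t_ha")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop("plot table is missing columns: ", paste(miss, collapse = ", "))
  df <- df[needed]
  df$year <- as.integer(df$year)
  df$row <- as.integer(df$row)
  df$col <- as.integer(df$col)
  df$yield_t_ha <- as.numeric(df$yield_t_ha)
  bad_grp <- !df$maturity_group %in% MATURITY_GROUPS
  if (any(bad_grp))
    stop("unknown maturity group(s) at rows ",
         paste(head(which(bad_grp), 5), collapse = ", "), ": ",
         paste(unique(df$maturity_group[bad_grp]), collapse = ", "))
  if (any(df$row < 1 | df$col < 1, na.rm = TRUE))
    stop("row and col must be positive integers")
  neg <- !is.na(df$yield_t_ha) & df$yield_t_ha < 0
  if (any(neg))
    stop("negative yields at rows ",
         paste(head(which(neg), 5), collapse = ", "))
  key <- paste(df$trial_id, df$row, df$col, sep = "|")
  dup <- duplicated(key)
  if (any(dup)) {
    d <- df[which(dup)[1], ]
    stop(sprintf("duplicated plot coordinate in trial '%s' at (row %d, col %d)",
                 d$trial_id, d$row, d$col))
  }
  as_trial_dataset(df)
}

#' Build a trial dataset from a plot data.frame
#' @param records data.frame of plot records.
#' @return `famet_trials` object.
#' @export
as_trial_dataset <- function(records) {
  records$environment <- env_key(records$location, records$year)
  structure(list(records = records,
                 environments = sort(unique(records$environment)),
                 groups = sort(unique(records$maturity_group))),
            class = "famet_trials")
}

#' @export
print.famet_trials <- function(x, ...) {
  cat(sprintf("MET plot data: %d records, %d trials, %d environments, %d hybrids\n",
              nrow(x$records), length(unique(x$records$trial_id)),
              length(x$environments), length(unique(x$records$hybrid))))
  invisible(x)
}

#' Write a trial dataset back to CSV
#' @param ds `famet_trials` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_plot_table <- function(ds, path) {
  cols <- c("location", "year", "maturity_group", "trial_id",
            "row", "col", "hybrid", "yield_t_ha")
  write.csv(ds$records[cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read station weather series
#'
#' One series per location, time-sorted. Gaps (non-uniform spacing) are
#' flagged on the series, never filled.
#'
#' @param path CSV with columns `location`, `timestamp`
#'   (`YYYY-MM-DD HH:MM:SS` or `YYYY-MM-DD`), `temp_c`, `rh_pct`,
#'   `precip_mm`.
#' @param column_map optional column remapping.
#' @return named list of `famet_weather` objects (data.frame plus
#'   `location`, `has_gaps` attributes).
#' @export
read_weather_table <- function(path, column_map = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df <- .remap_columns(df, column_map)
  needed <- c("location", "timestamp", "temp_c", "rh_pct", "precip_mm")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop("weather table is missing columns: ", paste(miss, collapse = ", "))
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC")
  if (anyNA(df$timestamp)) stop("unparseable timestamps present")
  bad_rh <- !is.na(df$rh_pct) & (df$rh_pct < 0 | df$rh_pct > 100)
  if (any(bad_rh))
    stop("relative humidity outside [0,100] at row(s) ",
         paste(head(which(bad_rh), 5), collapse = ", "))
  if (any(df$precip_mm < 0, na.rm = TRUE))
    stop("negative precipitation present")
  out <- lapply(split(df, df$location), function(s) {
    if (is.unsorted(s$timestamp, strictly = TRUE))
      stop("non-monotone timestamps for location ", s$location[1])
    dt <- diff(as.numeric(s$timestamp))
    structure(s[c("timestamp", "temp_c", "rh_pct", "precip_mm")],
              location = s$location[1],
              has_gaps = length(unique(dt)) > 1,
              class = c("famet_weather", "data.frame"))
  })
  out[sort(names(out))]
}

#' Write weather series to CSV
#' @param series list of weather series as from [read_weather_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_weather_table <- function(series, path) {
  rows <- do.call(rbind, lapply(series, function(s) {
    data.frame(location = attr(s, "location"),
               timestamp = format(s$timestamp, "%Y-%m-%d %H:%M:%S",
                                  tz = "UTC"),
               temp_c = s$temp_c, rh_pct = s$rh_pct,
               precip_mm = s$precip_mm)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Validate a trial dataset
#'
#' Counts trials per environment and maturity group, missing-plot
#' fractions and the connectivity of hybrids across environments.
#' An environment with no trials at all is a hard error; dropped trials
#' and disconnected hybrids are warnings.
#'
#' @param ds `famet_trials` object.
#' @param cfg `famet_config` (currently unused beyond presence checks).
#' @return list with `n_trials`, `n_missing_yield`, `trial_counts`
#'   (environment x group table), `missing_fraction`, `warnings`.
#' @export
validate_dataset <- function(ds, cfg = analysis_config()) {
  rec <- ds$records
  tab <- table(rec$environment[!duplicated(rec$trial_id)],
               rec$maturity_group[!duplicated(rec$trial_id)])
  if (any(rowSums(tab) == 0) || length(setdiff(ds$environments, rownames(tab))))
    stop("environment with zero trials present")
  warnings <- character()
  full <- length(ds$environments) * length(ds$groups)
  n_trials <- length(unique(rec$trial_id))
  if (n_trials < full)
    warnings <- c(warnings,
                  sprintf("expected %d trials (environments x groups), found %d",
                          full, n_trials))
  env_per_hyb <- tapply(rec$environment, rec$hybrid,
                        function(e) length(unique(e)))
  discon <- names(env_per_hyb)[env_per_hyb < 2]
  if (length(discon))
    warnings <- c(warnings,
                  paste("hybrid(s) observed in a single environment:",
                        paste(discon, collapse = ", ")))
  for (w in warnings) warning(w, call. = FALSE)
  list(n_trials = n_trials,
       n_missing_yield = sum(is.na(rec$yield_t_ha)),
       trial_counts = tab,
       missing_fraction = mean(is.na(rec$yield_t_ha)),
       warnings = warnings)
}
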