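.EC_COVARIATES <- c("PP", "DPT", "PET", "VPD", "TM", "TR", "APAR", "CPAR")
.EC_PHASES <- c("VE", "RE", "RI")

#' Saturation vapor pressure (Tetens)
#'
#' `es(T) = 0.61078 * exp(17.27 * T / (T + 237.3))` in kPa, for temperature
#' in degrees Celsius.
#'
#' @param temp_c Temperature in Celsius.
#' @return Saturation vapor pressure in kPa.
#' @export
svp_tetens <- function(temp_c) {
  0.61078 * exp(17.27 * temp_c / (temp_c + 237.3))
}

#' Extraterrestrial radiation
#'
#' Daily extraterrestrial radiation `Ra` (MJ m-2 d-1) from latitude and day
#' of year, using the standard FAO-56 solar geometry (inverse relative
#' Earth-Sun distance, solar declination, sunset hour angle).
#'
#' @param latitude Latitude in decimal degrees.
#' @param doy Day of year (1-366).
#' @return Ra in MJ m-2 d-1.
#' @export
extraterrestrial_radiation <- function(latitude, doy) {
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  x <- pmin(1, pmax(-1, -tan(phi) * tan(delta)))
  ws <- acos(x)
  (24 * 60 / pi) * 0.0820 * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
}

#' Derive temperature range, vapor pressure deficit and evapotranspiration
#'
#' Augments a daily weather table with three derived variables:
#' * `TR = TMAX - TMIN` (diurnal temperature range, degrees C);
#' * `VPD` (kPa): mean of the saturation vapor pressures at `TMIN` and
#'   `TMAX` minus the actual vapor pressure at the dew point `DPT`, Tetens
#'   formula throughout, floored at zero;
#' * `PET` (mm d-1): Hargreaves-Samani reference evapotranspiration
#'   `0.0023 * (TM + 17.8) * sqrt(TR) * Ra / lambda` with `Ra` the
#'   extraterrestrial radiation for the row's date and `lambda = 2.45`
#'   MJ kg-1, floored at zero.
#'
#' @param daily data.frame with columns `date` (Date or ISO string), `TMIN`,
#'   `TMAX`, `TM`, `DPT` (degrees C); other columns are passed through.
#' @param latitude Site latitude in decimal degrees, within \[-60, 60\].
#' @return The input with `TR`, `VPD`, `PET` columns added.
#' @export
derive_daily_variables <- function(daily, latitude) {
  stopifnot(is.data.frame(daily),
            all(c("date", "TMIN", "TMAX", "TM", "DPT") %in% names(daily)))
  if (latitude < -60 || latitude > 60) stop("latitude must be in [-60, 60]")
  if (any(daily$TMAX < daily$TMIN)) {
    stop("TMAX < TMIN on ", sum(daily$TMAX < daily$TMIN), " day(s)")
  }
  dates <- as.Date(daily$date)
  doy <- as.integer(strftime(dates, "%j"))
  daily$TR <- daily$TMAX - daily$TMIN
  daily$VPD <- pmax(0, (svp_tetens(daily$TMIN) + svp_tetens(daily$TMAX)) / 2 -
                      svp_tetens(daily$DPT))
  ra <- extraterrestrial_radiation(latitude, doy)
  daily$PET <- pmax(0, 0.0023 * (daily$TM + 17.8) * sqrt(daily$TR) * ra / 2.45)
  daily
}

#' Infer crop phenology windows for an environment
#'
#' Splits the field season into the three developmental phases used for
#' covariate aggregation: vegetative (transplanting to the earliest
#' flowering date in the trial), reproductive (earliest to latest flowering
#' date), and ripening (latest flowering to harvest). Flowering dates are
#' `seeding_date + days-to-flowering`, since flowering time is recorded from
#' seeding. A zero-length reproductive window (all lines flowering the same
#' day) is widened to one day with a warning.
#'
#' @param transplant_date Transplanting date (Date or ISO string).
#' @param harvest_date Harvest date.
#' @param seeding_date Seeding date (origin for `dtf`).
#' @param dtf Numeric vector of days-to-flowering values for the lines in
#'   the trial.
#' @return List with `vegetative`, `reproductive`, `ripening`, each
#'   `c(start, end)` Dates, plus `flowering_start`, `flowering_end`.
#'   Conventions: a day `d` is vegetative if `d < flowering_start`,
#'   reproductive if `flowering_start <= d <= flowering_end`, ripening if
#'   `d > flowering_end`.
#' @export
infer_phenology_windows <- function(transplant_date, harvest_date,
                                    seeding_date, dtf) {
  transplant <- as.Date(transplant_date)
  harvest <- as.Date(harvest_date)
  seeding <- as.Date(seeding_date)
  if (length(dtf) < 1L || any(!is.finite(dtf))) stop("invalid dtf values")
  fs <- seeding + round(min(dtf))
  fe <- seeding + round(max(dtf))
  if (fs == fe) {
    warning("all lines flower on the same day; reproductive window widened to 1 day")
    fe <- fs + 1L
  }
  if (!(transplant < fs && fs <= fe && fe < harvest)) {
    stop("phenology ordering violated: need transplant < earliest flowering ",
         "<= latest flowering < harvest (", transplant, ", ", fs, ", ", fe,
         ", ", harvest, ")")
  }
  list(vegetative = c(transplant, fs), reproductive = c(fs, fe),
       ripening = c(fe, harvest), flowering_start = fs, flowering_end = fe)
}

# Phase label per day under the window conventions documented above.
.phase_of_day <- function(dates, windows) {
  out <- rep(NA_character_, length(dates))
  out[dates >= windows$vegetative[1L] & dates < windows$flowering_start] <- "VE"
  out[dates >= windows$flowering_start & dates <= windows$flowering_end] <- "RE"
  out[dates > windows$flowering_end & dates <= windows$ripening[2L]] <- "RI"
  out
}

#' Aggregate daily weather into environmental covariates
#'
#' Averages each selected daily covariate within each phenology window
#' (vegetative, reproductive, ripening) and, optionally, over the whole
#' season, giving the environment's covariate x phase table. All covariates
#' are aggregated by the mean (including precipitation) because window
#' lengths differ between environments and the columns are standardized
#' afterwards.
#'
#' @param daily Daily weather table for one environment (with derived
#'   variables present if selected; see [derive_daily_variables()]).
#' @param windows Phenology windows from [infer_phenology_windows()].
#' @param covariates Covariate column names to aggregate (default the eight
#'   standard ones: PP, DPT, PET, VPD, TM, TR, APAR, CPAR).
#' @param whole_season Also emit `_WS` whole-season means.
#' @return A named numeric vector with elements `<covariate>_<phase>` for
#'   phases VE, RE, RI (and WS if requested).
#' @export
aggregate_ecs <- function(daily, windows, covariates = .EC_COVARIATES,
                          whole_season = FALSE) {
  stopifnot(is.data.frame(daily), all(covariates %in% names(daily)))
  dates <- as.Date(daily$date)
  phase <- .phase_of_day(dates, windows)
  if (any(is.na(phase[dates >= windows$vegetative[1L] &
                        dates <= windows$ripening[2L]]))) {
    stop("internal: day without phase inside the season")
  }
  phases <- .EC_PHASES
  out <- numeric(0)
  for (ph in phases) {
    idx <- which(phase == ph)
    if (length(idx) == 0L) stop("empty ", ph, " window in daily record")
    v <- vapply(covariates, function(cv) mean(daily[[cv]][idx]), numeric(1L))
    names(v) <- paste0(covariates, "_", ph)
    out <- c(out, v)
  }
  if (whole_season) {
    idx <- which(!is.na(phase))
    v <- vapply(covariates, function(cv) mean(daily[[cv]][idx]), numeric(1L))
    names(v) <- paste0(covariates, "_WS")
    out <- c(out, v)
  }
  out
}
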