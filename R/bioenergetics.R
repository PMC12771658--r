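# Bioenergetics: activity-specific multipliers of resting metabolic rate,
# allometric flight cost, thermoregulation below the lower critical
# temperature, and hourly/daily energy expenditure with diurnal and 24-h
# extrapolation modes.

#' Allometric flight multiplier
#'
#' Flight power `P = 52.6 * M^0.74` watts for a bird of mass `M` kg,
#' converted to kJ/h (x 3.6) and divided by the resting metabolic rate.
#' At the default mass of 0.70 kg and RMR 15.89 kJ/bird/h this evaluates
#' to 9.2 (1 dp), the conventional flight multiplier for a lesser
#' scaup-sized diving duck.
#'
#' @param mass_kg body mass (kg), > 0.
#' @param rmr resting metabolic rate (kJ/bird/h).
#' @param coef,expo allometric coefficients (watts at 1 kg, exponent).
#' @param w_to_kjh watts to kJ/h conversion (3.6 exactly).
#' @return the dimensionless flight multiplier (strictly increasing in
#'   mass).
#' @export
flight_multiplier <- function(mass_kg, rmr = 15.89, coef = 52.6,
                              expo = 0.74, w_to_kjh = 3.6) {
  if (any(!is.finite(mass_kg)) || any(mass_kg <= 0)) {
    stop_db("body mass must be positive")
  }
  coef * mass_kg^expo * w_to_kjh / rmr
}

#' Energetic model parameters
#'
#' All constants of the hourly/daily energy model: the resting metabolic
#' rate, activity-specific multipliers (feeding is the mean of diving and
#' swimming, resting the mean of loafing and sleeping, flight from the
#' allometric model at `mass_kg`), the lower critical temperature, the
#' thermoregulatory slope in L O2 per hour per degree C with its
#' oxygen-to-energy conversion, and body mass.
#'
#' The default mass of 0.70 kg is the value at which the allometric flight
#' multiplier reproduces the conventional 9.2; it is a back-solved
#' default, not a measured mass, and should be set from morphometrics when
#' available.
#'
#' @param mass_kg body mass (kg).
#' @param rmr resting metabolic rate (kJ/bird/h).
#' @param a_preening,a_diving,a_swimming,a_loafing,a_sleeping activity
#'   multipliers of RMR.
#' @param a_flight optional explicit flight multiplier; computed from
#'   `mass_kg` when `NULL`.
#' @param lct lower critical temperature (degrees C).
#' @param thermo_slope thermoregulatory oxygen demand
#'   (L O2 h^-1 degC^-1 below the LCT).
#' @param o2_to_kj energy equivalent of oxygen (kJ per L O2).
#' @param flight_coef,flight_exp allometric flight-power coefficients.
#' @return an `energy_params` list; `multipliers` holds the four class
#'   multipliers in canonical behavior order.
#' @export
energy_params <- function(mass_kg = 0.70, rmr = 15.89,
                          a_preening = 1.66, a_diving = 1.89,
                          a_swimming = 1.81, a_loafing = 1.10,
                          a_sleeping = 1.0, a_flight = NULL,
                          lct = 14.4, thermo_slope = 0.1392,
                          o2_to_kj = 20.1,
                          flight_coef = 52.6, flight_exp = 0.74) {
  vals <- c(mass_kg, rmr, a_preening, a_diving, a_swimming, a_loafing,
            a_sleeping, lct + 273.15, thermo_slope, o2_to_kj, flight_coef,
            flight_exp)
  if (any(!is.finite(vals)) || any(vals[-8] <= 0)) {
    stop_db("energy parameters must be positive and finite")
  }
  a_flight <- a_flight %||%
    flight_multiplier(mass_kg, rmr, flight_coef, flight_exp)
  mult <- c(feeding = (a_diving + a_swimming) / 2,
            flying = a_flight,
            preening = a_preening,
            resting = (a_loafing + a_sleeping) / 2)
  if (a_flight <= max(mult[-2])) {
    stop_db("flight must be the most expensive activity")
  }
  structure(
    list(mass_kg = mass_kg, rmr = rmr, multipliers = mult,
         a_diving = a_diving, a_swimming = a_swimming,
         a_loafing = a_loafing, a_sleeping = a_sleeping,
         lct = lct, thermo_slope = thermo_slope, o2_to_kj = o2_to_kj,
         flight_coef = flight_coef, flight_exp = flight_exp),
    class = "energy_params")
}

#' @export
print.energy_params <- function(x, ...) {
  cat("Energy model parameters\n")
  cat(sprintf("  RMR %.2f kJ/bird/h, mass %.2f kg\n", x$rmr, x$mass_kg))
  cat("  multipliers: ",
      paste(names(x$multipliers), round(x$multipliers, 2),
            sep = "=", collapse = ", "), "\n", sep = "")
  cat(sprintf("  LCT %.1f degC, thermo slope %.4f L O2/h/degC x %.1f kJ/L\n",
              x$lct, x$thermo_slope, x$o2_to_kj))
  invisible(x)
}

#' Thermoregulatory cost per hour
#'
#' Zero at or above the lower critical temperature; below it, the cost
#' rises linearly with the temperature deficit:
#' `C_T = slope * (LCT - T) * o2_to_kj` kJ/h, i.e. 0.1392 L O2/h/degC
#' x 20.1 kJ/L = 2.79792 kJ/h per degree of deficit at the defaults.
#' Continuous and piecewise linear in temperature.
#'
#' @param temp_c air temperature(s), degrees C.
#' @param params an [energy_params()].
#' @return thermoregulatory cost(s), kJ/h.
#' @export
thermo_cost <- function(temp_c, params = energy_params()) {
  if (any(!is.finite(temp_c))) stop_db("temperature must be finite")
  params$thermo_slope * pmax(0, params$lct - temp_c) * params$o2_to_kj
}

#' Hourly energy expenditure
#'
#' `HEE = RMR * sum_i(a_i * t_i) + C_T(temp)` kJ/bird/h, where `t_i` are
#' the behavior proportions for the hour (summing to 1) and `a_i` the
#' activity multipliers. The thermoregulatory cost enters once per hour,
#' not weighted by behavior. HEE is linear in the proportions: moving a
#' share `dt` of time from resting to flying raises HEE by exactly
#' `RMR * (a_flying - a_resting) * dt`.
#'
#' @param proportions named numeric vector over the behavior classes, or a
#'   matrix/data frame with one row per hour and one named column per
#'   class.
#' @param temp_c temperature (degrees C), scalar or one per row.
#' @param params an [energy_params()].
#' @return HEE in kJ/bird/h (vector when `proportions` is a matrix).
#' @export
hourly_energy <- function(proportions, temp_c, params = energy_params()) {
  m <- params$multipliers
  if (is.null(dim(proportions))) {
    proportions <- matrix(proportions, nrow = 1,
                          dimnames = list(NULL, names(proportions)))
  }
  proportions <- as.matrix(proportions[, names(m), drop = FALSE])
  if (any(proportions < 0)) stop_db("behavior proportions must be >= 0")
  tot <- rowSums(proportions)
  if (any(abs(tot - 1) > 1e-6)) {
    stop_db("behavior proportions must sum to 1 (got ",
            paste(round(tot[abs(tot - 1) > 1e-6], 4), collapse = ", "), ")")
  }
  as.numeric(params$rmr * (proportions %*% m) + thermo_cost(temp_c, params))
}

#' Daily energy expenditure
#'
#' Aggregates hourly energy expenditure into a daily value under one of
#' four modes: `sum24` sums exactly 24 hourly values; `diurnal_extrapolated`
#' multiplies the mean HEE by 24 (the scan-sampling extrapolation that
#' assumes diurnal behavior represents the whole day); `daylight_only`
#' multiplies by the number of daylight hours; `nocturnal_only` by
#' `24 - daylight_hours`.
#'
#' @param hee numeric HEE values (kJ/bird/h); for `sum24`, exactly the 24
#'   hours of one day (a missing hour is an error listing the gaps, pass
#'   `hours` to identify them).
#' @param mode aggregation mode.
#' @param daylight_hours required for the daylight/nocturnal modes.
#' @param hours optional integer hour-of-day labels used to report gaps in
#'   `sum24` mode.
#' @return DEE in kJ/bird/day.
#' @export
daily_energy <- function(hee, mode = c("sum24", "diurnal_extrapolated",
                                       "daylight_only", "nocturnal_only"),
                         daylight_hours = NULL, hours = NULL) {
  mode <- match.arg(mode)
  if (mode == "sum24") {
    if (length(hee) != 24) {
      gaps <- if (!is.null(hours)) {
        paste(setdiff(0:23, hours), collapse = ", ")
      } else paste(length(hee), "of 24 hours present")
      stop_db("sum24 requires 24 hourly values; missing: ", gaps)
    }
    return(sum(hee))
  }
  if (mode == "diurnal_extrapolated") return(mean(hee) * 24)
  if (is.null(daylight_hours)) {
    stop_db("daylight_hours required for mode ", mode)
  }
  if (mode == "daylight_only") mean(hee) * daylight_hours
  else mean(hee) * (24 - daylight_hours)
}

#' Pair records with the nearest hourly weather
#'
#' Nearest-timestamp join of behavior records onto an hourly weather table;
#' exact ties go to the earlier weather record, and records more than
#' `max_gap_h` hours from any weather row get `NA` temperature/wind and a
#' `weather_missing` flag.
#'
#' @param records data frame with `timestamp_utc`.
#' @param weather data frame `timestamp_utc, temp_c, wind_ms`, non-empty.
#' @param max_gap_h largest tolerated record-to-weather gap (hours).
#' @return `records` with `temp_c`, `wind_ms` and `weather_missing`
#'   columns appended.
#' @export
pair_weather <- function(records, weather, max_gap_h = 2) {
  if (!nrow(weather)) stop_db("weather table is empty")
  wt <- as_utc(weather$timestamp_utc)
  ord <- order(wt)
  wt <- wt[ord]; weather <- weather[ord, ]
  rt <- as_utc(records$timestamp_utc)
  pos <- findInterval(as.numeric(rt), as.numeric(wt))
  lo <- pmax(pos, 1L)
  hi <- pmin(pos + 1L, length(wt))
  d_lo <- abs(as.numeric(rt) - as.numeric(wt[lo]))
  d_hi <- abs(as.numeric(wt[hi]) - as.numeric(rt))
  nearest <- ifelse(d_lo <= d_hi, lo, hi)   # tie -> earlier record
  gap_h <- pmin(d_lo, d_hi) / 3600
  missing <- gap_h > max_gap_h
  records$temp_c <- ifelse(missing, NA_real_, weather$temp_c[nearest])
  records$wind_ms <- ifelse(missing, NA_real_, weather$wind_ms[nearest])
  records$weather_missing <- missing
  records
}

#' Hourly energy table from classified bursts
#'
#' Groups classified bursts into bird-hours, computes the behavior
#' proportions `t_i` for each hour, pairs each hour with the nearest
#' weather record, and evaluates [hourly_energy()]. Hours with missing
#' weather are dropped.
#'
#' @param bursts data frame `bird_id, timestamp_utc, behavior`.
#' @param weather hourly weather table.
#' @param params an [energy_params()].
#' @return data frame `bird_id, date, hour, n_bursts, temp_c, hee` plus
#'   one proportion column per behavior.
#' @export
hourly_energy_table <- function(bursts, weather, params = energy_params()) {
  ts <- as_utc(bursts$timestamp_utc)
  hour_start <- as.POSIXct(trunc(ts, "hours"), tz = "UTC")
  key <- paste(bursts$bird_id, format(hour_start, "%Y-%m-%d %H"))
  groups <- split(seq_len(nrow(bursts)), key)
  rows <- lapply(groups, function(i) {
    props <- as.numeric(table(factor(bursts$behavior[i], BEHAVIOR_CLASSES)))
    props <- props / length(i)
    data.frame(bird_id = bursts$bird_id[i][1],
               timestamp_utc = hour_start[i][1],
               n_bursts = length(i),
               t(setNames(props, paste0("p_", BEHAVIOR_CLASSES))))
  })
  he <- do.call(rbind, c(rows, make.row.names = FALSE))
  he <- pair_weather(he, weather)
  he <- he[!he$weather_missing, , drop = FALSE]
  pm <- as.matrix(he[paste0("p_", BEHAVIOR_CLASSES)])
  colnames(pm) <- BEHAVIOR_CLASSES
  he$hee <- hourly_energy(pm, he$temp_c, params)
  he$date <- as.Date(he$timestamp_utc, tz = "UTC")
  he$hour <- as.integer(format(he$timestamp_utc, "%H"))
  he
}
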