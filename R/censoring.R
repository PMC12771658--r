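# Post-release censoring: daily displacement from hourly GPS fixes,
# mean-shift change-point detection by binary segmentation, and removal of
# post-release days, short-lived birds and emigrants.

#' Great-circle distance in km
#'
#' Haversine distance on a sphere of radius 6371.0 km. Vectorized over
#' coordinate vectors.
#'
#' @param lat1,lon1,lat2,lon2 decimal degrees (WGS-84).
#' @return numeric distances (km).
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE) ||
      any(abs(c(lon1, lon2)) > 180, na.rm = TRUE)) {
    stop_db("invalid coordinates: |lat| <= 90 and |lon| <= 180 required")
  }
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}

#' Daily displacement series from hourly fixes
#'
#' Sums consecutive-fix great-circle distances, grouped by the UTC calendar
#' day on which each segment starts, indexed relative to release (the
#' bird's first fix): release day is day 0, the first full day is day 1.
#' Segments spanning a gap of more than `max_gap_h` hours contribute
#' nothing.
#'
#' @param gps data frame `bird_id, timestamp_utc, lat, lon` (one or more
#'   birds).
#' @param max_gap_h largest fix-to-fix gap (hours) still treated as a
#'   travelled segment.
#' @return data frame `bird_id, day, km`, one row per bird-day with any
#'   retained segment; a bird with fewer than two fixes yields no rows,
#'   with a warning.
#' @export
daily_displacement <- function(gps, max_gap_h = 3) {
  out <- lapply(split(gps, gps$bird_id), function(g) {
    g <- g[order(g$timestamp_utc), ]
    if (nrow(g) < 2) {
      warning("bird ", g$bird_id[1], ": fewer than 2 fixes; empty series",
              call. = FALSE)
      return(NULL)
    }
    ts <- as_utc(g$timestamp_utc)
    n <- nrow(g)
    gap_h <- as.numeric(difftime(ts[-1], ts[-n], units = "hours"))
    km <- haversine_km(g$lat[-n], g$lon[-n], g$lat[-1], g$lon[-1])
    keep <- gap_h <= max_gap_h
    release <- as.Date(ts[1], tz = "UTC")
    day <- as.integer(as.Date(ts[-n], tz = "UTC") - release)
    agg <- tapply(km[keep], day[keep], sum)
    if (!length(agg)) return(NULL)
    data.frame(bird_id = g$bird_id[1], day = as.integer(names(agg)),
               km = as.numeric(agg), row.names = NULL)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(NULL)
  do.call(rbind, c(out, make.row.names = FALSE))
}

cohens_d <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 + n2 < 3) return(NA_real_)
  # a singleton segment contributes zero df, not a missing variance
  ss <- function(v) if (length(v) < 2) 0 else (length(v) - 1) * var(v)
  sp2 <- (ss(a) + ss(b)) / (n1 + n2 - 2)
  if (!is.finite(sp2)) return(NA_real_)
  if (sp2 == 0) return(if (mean(a) == mean(b)) 0 else Inf)
  abs(mean(a) - mean(b)) / sqrt(sp2)
}

# Best single split of x[lo..hi] by residual sum of squares around segment
# means; returns the split index tau (last index of the left segment).
best_split <- function(x) {
  n <- length(x)
  if (n < 2) return(NULL)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  tot <- cs[n]
  sse <- vapply(1:(n - 1), function(t) {
    lm <- cs[t] / t
    rm <- (tot - cs[t]) / (n - t)
    (cs2[t] - t * lm^2) + (cs2[n] - cs2[t] - (n - t) * rm^2)
  }, numeric(1))
  which.min(sse)
}

#' Detect mean-shift change-points in a daily displacement series
#'
#' Binary segmentation on the mean: each segment is split at the point
#' minimizing the within-segment sum of squares, and a split is accepted
#' (and recursed into) only when the standardized mean difference between
#' the two resulting segments — Cohen's d with pooled SD — reaches
#' `min_effect`. Deterministic; a constant series yields no change-points.
#'
#' @param km numeric daily-displacement series (ordered by day).
#' @param max_cps maximum number of change-points to report.
#' @param min_effect smallest Cohen's d for a split to be reported.
#' @return data frame `tau, effect_size` where `tau` is the (1-based)
#'   index of the last day of the left segment, sorted by `tau`.
#' @export
detect_changepoints <- function(km, max_cps = 5L, min_effect = 0.5) {
  if (length(km) < 4) stop_db("series must have length >= 4")
  found <- data.frame(tau = integer(0), effect_size = numeric(0))
  queue <- list(c(1L, length(km)))
  while (length(queue) && nrow(found) < max_cps) {
    seg <- queue[[1]]; queue <- queue[-1]
    lo <- seg[1]; hi <- seg[2]
    if (hi - lo < 1) next
    t <- best_split(km[lo:hi])
    if (is.null(t)) next
    d <- cohens_d(km[lo:(lo + t - 1)], km[(lo + t):hi])
    if (!is.finite(d) || d < min_effect) next
    found <- rbind(found, data.frame(tau = lo + t - 1L, effect_size = d))
    queue <- c(queue, list(c(lo, lo + t - 1L)), list(c(lo + t, hi)))
  }
  found[order(found$tau), , drop = FALSE]
}

#' Censoring summary per bird
#'
#' Computes the daily displacement series per bird, detects change-points
#' over the first `window_days` days, and derives the censoring decision:
#' bursts through the last change-point day are censored (0 if none), and
#' a bird is excluded entirely if it survived 14 days or fewer (record
#' span) or, when a bounding box is supplied, if any fix leaves it.
#'
#' @param gps GPS data frame (all birds).
#' @param window_days number of post-release days scanned for
#'   change-points.
#' @param min_effect,max_cps passed to [detect_changepoints()].
#' @param min_survival_days a bird must survive strictly more than this
#'   many days to be included.
#' @param bbox optional numeric `c(lat_min, lat_max, lon_min, lon_max)`
#'   containment box (e.g. an approximate study-area polygon stand-in).
#' @return data frame `bird_id, release_date, last_day, changepoints,
#'   effect_sizes, censored_through, included` (change-points and effect
#'   sizes as comma-separated strings).
#' @export
censor_birds <- function(gps, window_days = 20L, min_effect = 0.5,
                         max_cps = 5L, min_survival_days = 14L,
                         bbox = NULL) {
  disp <- daily_displacement(gps)
  out <- lapply(split(gps, gps$bird_id), function(g) {
    id <- g$bird_id[1]
    release <- as.Date(min(as_utc(g$timestamp_utc)), tz = "UTC")
    last_day <- as.integer(max(as.Date(as_utc(g$timestamp_utc),
                                       tz = "UTC")) - release)
    d <- disp[disp$bird_id == id & disp$day >= 1 &
                disp$day <= window_days, ]
    cps <- if (nrow(d) >= 4) {
      detect_changepoints(d$km[order(d$day)], max_cps, min_effect)
    } else data.frame(tau = integer(0), effect_size = numeric(0))
    cp_days <- d$day[order(d$day)][cps$tau]
    inside <- is.null(bbox) ||
      all(g$lat >= bbox[1] & g$lat <= bbox[2] &
            g$lon >= bbox[3] & g$lon <= bbox[4])
    data.frame(
      bird_id = id, release_date = release, last_day = last_day,
      changepoints = paste(cp_days, collapse = ","),
      effect_sizes = paste(round(cps$effect_size, 3), collapse = ","),
      censored_through = if (length(cp_days)) max(cp_days) else 0L,
      included = last_day > min_survival_days && inside)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Apply censoring decisions to a burst table
#'
#' Removes bursts on days 1..censored_through for each bird and drops
#' excluded birds entirely. Every bird in the burst table must have a
#' censoring result.
#'
#' @param censor output of [censor_birds()].
#' @param bursts data frame with `bird_id` and `timestamp_utc`.
#' @return the filtered burst table.
#' @export
apply_censor <- function(censor, bursts) {
  i <- match(bursts$bird_id, censor$bird_id)
  if (anyNA(i)) {
    stop_db("no censoring result for bird(s): ",
            paste(unique(bursts$bird_id[is.na(i)]), collapse = ", "))
  }
  day <- as.integer(as.Date(as_utc(bursts$timestamp_utc), tz = "UTC") -
                      censor$release_date[i])
  keep <- censor$included[i] &
    !(day >= 1L & day <= censor$censored_through[i])
  bursts[keep, , drop = FALSE]
}
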