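# Per-burst feature battery: middle-3-s windowing, static/dynamic
# decomposition by centered running mean, descriptive statistics per axis,
# ODBA/VeDBA, Euler angles and axis correlations, plus a greedy 0.9
# correlation filter over the resulting feature table.

#' Extract the centered window of a burst
#'
#' Trims a burst to its middle `window_s` seconds (30 samples at 10 Hz for
#' a 3 s window) to isolate pure behaviors: transitions tend to occur at
#' burst edges. A 50-sample burst keeps 0-based samples 10--39; a burst
#' already at the window length is returned unchanged.
#'
#' @param burst an `acc_burst` (or any list with `x`, `y`, `z`, `hz`).
#' @param window_s window length in seconds.
#' @return the windowed `acc_burst`; timestamp/metadata fields preserved.
#' @export
middle_window <- function(burst, window_s = 3) {
  n <- length(burst$x)
  k <- as.integer(round(window_s * burst$hz))
  if (length(burst$y) != n || length(burst$z) != n) {
    stop_db("burst axes have unequal lengths")
  }
  if (n < k) {
    stop_db("burst ", burst$burst_id %||% "<unnamed>", " has ", n,
            " samples; ", k, " required for a ", window_s, " s window")
  }
  start <- (n - k) %/% 2L
  idx <- (start + 1L):(start + k)
  out <- burst
  out$x <- burst$x[idx]; out$y <- burst$y[idx]; out$z <- burst$z[idx]
  out
}

#' Static/dynamic decomposition of one axis
#'
#' Splits an acceleration series into a static (posture/gravity) component,
#' the centered running mean with shrinking windows at the edges, and a
#' dynamic (movement) component, the residual. The two always reconstruct
#' the input exactly: `static + dynamic == samples`.
#'
#' @param samples numeric vector (g).
#' @param window running-mean window in samples; the default 10 (1 s at
#'   10 Hz) separates posture from stroke/wingbeat frequencies.
#' @return list with numeric `static` and `dynamic` of the input length.
#' @export
static_dynamic <- function(samples, window = 10) {
  if (window < 1) stop_db("running-mean window must be >= 1")
  n <- length(samples)
  if (window > n) stop_db("running-mean window exceeds series length")
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window %/% 2L
  stat <- vapply(seq_len(n), function(i) {
    mean(samples[max(1L, i - half_lo):min(n, i + half_hi)])
  }, numeric(1))
  list(static = stat, dynamic = samples - stat)
}

# moment helpers; SD uses the n-1 denominator throughout
skew_ <- function(v) {
  s <- sd(v); if (!is.finite(s) || s == 0) return(NA_real_)
  mean((v - mean(v))^3) / s^3
}
kurt_ <- function(v) {
  s <- sd(v); if (!is.finite(s) || s == 0) return(NA_real_)
  mean((v - mean(v))^4) / s^4 - 3
}
icv_ <- function(v) {
  s <- sd(v); if (!is.finite(s) || s == 0) return(NA_real_)
  mean(v) / s
}
safe_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Compute the per-burst feature battery
#'
#' Computes 94 named features from one (windowed) burst: per-axis
#' descriptive statistics (mean, sd, quartiles, range, skewness, excess
#' kurtosis, RMS), the inverse coefficient of variation (`x_icv` etc.,
#' mean/SD of the raw axis), static summaries from the running-mean
#' decomposition (`static_y` is the absolute mean of the running-mean
#' series of y), dynamic-component statistics including zero-crossing
#' rates and jerk, pairwise axis correlations (raw and dynamic), the
#' acceleration-magnitude profile, ODBA and VeDBA intensity proxies, and
#' Euler posture angles (degrees) from the mean static vector:
#' `pitch = atan2(s_x, sqrt(s_y^2 + s_z^2))`,
#' `roll = atan2(s_y, sqrt(s_x^2 + s_z^2))`, `yaw = atan2(s_y, s_x)`.
#'
#' Zero-variance axes yield `NA` (never +/-Inf) for scale-free features
#' such as icv, skewness and correlations.
#'
#' @param burst an `acc_burst`, normally already passed through
#'   [middle_window()].
#' @param running_mean_window window (samples) for [static_dynamic()].
#' @return named numeric vector of features; names are stable across runs.
#' @export
compute_features <- function(burst, running_mean_window = 10) {
  axes <- list(x = burst$x, y = burst$y, z = burst$z)
  n <- length(axes$x)
  dec <- lapply(axes, static_dynamic,
                window = min(running_mean_window, n))
  out <- c()
  for (a in names(axes)) {
    v <- axes[[a]]
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    s <- dec[[a]]$static
    d <- dec[[a]]$dynamic
    zcr <- sum(diff(sign(d)) != 0) / (n - 1)
    dv <- diff(v)
    f <- c(mean(v), sd(v), min(v), max(v), max(v) - min(v),
           q[2], q[1], q[3], q[3] - q[1],
           skew_(v), kurt_(v), sqrt(mean(v^2)), icv_(v),
           abs(mean(s)), sd(s), max(s) - min(s),
           mean(d), sd(d), min(d), max(d), mean(abs(d)),
           sqrt(mean(d^2)), zcr,
           mean(abs(dv)), max(abs(dv)))
    names(f) <- c(
      paste0(a, c("_mean", "_sd", "_min", "_max", "_range",
                  "_median", "_q25", "_q75", "_iqr",
                  "_skew", "_kurt", "_rms", "_icv")),
      paste0("static_", a, c("", "_sd", "_range")),
      paste0("d", a, c("_mean", "_sd", "_min", "_max", "_absmean",
                       "_rms", "_zcr")),
      paste0("jerk_", a, c("_mean", "_max")))
    out <- c(out, f)
  }
  dx <- dec$x$dynamic; dy <- dec$y$dynamic; dz <- dec$z$dynamic
  mag <- sqrt(axes$x^2 + axes$y^2 + axes$z^2)
  odba_i <- abs(dx) + abs(dy) + abs(dz)
  vedba_i <- sqrt(dx^2 + dy^2 + dz^2)
  sx <- mean(dec$x$static); sy <- mean(dec$y$static); sz <- mean(dec$z$static)
  out <- c(out,
    cor_xy = safe_cor(axes$x, axes$y),
    cor_xz = safe_cor(axes$x, axes$z),
    cor_yz = safe_cor(axes$y, axes$z),
    dcor_xy = safe_cor(dx, dy),
    dcor_xz = safe_cor(dx, dz),
    dcor_yz = safe_cor(dy, dz),
    mag_mean = mean(mag), mag_sd = sd(mag), mag_min = min(mag),
    mag_max = max(mag), mag_range = max(mag) - min(mag),
    odba = mean(odba_i), odba_sd = sd(odba_i),
    vedba = mean(vedba_i), vedba_sd = sd(vedba_i), vedba_max = max(vedba_i),
    pitch = rad2deg(atan2(sx, sqrt(sy^2 + sz^2))),
    roll = rad2deg(atan2(sy, sqrt(sx^2 + sz^2))),
    yaw = rad2deg(atan2(sy, sx)))
  out
}

#' Feature table for many bursts
#'
#' Applies [middle_window()] then [compute_features()] to every burst of a
#' long-format ACC table (`burst_id, sample_idx, x_g, y_g, z_g`, samples
#' ordered by `sample_idx`).
#'
#' @param acc long-format ACC data frame.
#' @param window_s middle-window length (s); `NULL` skips windowing.
#' @param hz sampling rate.
#' @param running_mean_window passed to [compute_features()].
#' @return data frame: `burst_id` plus one column per feature.
#' @export
feature_table <- function(acc, window_s = 3, hz = 10,
                          running_mean_window = 10) {
  need <- c("burst_id", "sample_idx", "x_g", "y_g", "z_g")
  miss <- setdiff(need, names(acc))
  if (length(miss)) stop_db("acc table missing column(s): ",
                            paste(miss, collapse = ", "))
  ord <- order(acc$burst_id, acc$sample_idx)
  acc <- acc[ord, ]
  ids <- unique(acc$burst_id)
  idx <- split(seq_len(nrow(acc)), factor(acc$burst_id, levels = ids))
  xg <- acc$x_g; yg <- acc$y_g; zg <- acc$z_g
  rows <- lapply(idx, function(i) {
    b <- list(x = xg[i], y = yg[i], z = zg[i], hz = hz)
    if (!is.null(window_s)) b <- middle_window(b, window_s)
    compute_features(b, running_mean_window)
  })
  out <- as.data.frame(do.call(rbind, rows))
  cbind(data.frame(burst_id = ids), out, row.names = NULL)
}

#' Greedy correlation filter over a feature table
#'
#' Scans features in their given (canonical) order and drops any feature
#' whose absolute Pearson correlation with an already-retained feature
#' exceeds the threshold — the first-seen feature of a correlated pair is
#' kept, so the result is deterministic and idempotent. Constant or
#' all-missing columns are excluded before filtering and reported;
#' correlations use pairwise-complete observations.
#'
#' @param features data frame from [feature_table()] (non-numeric columns
#'   such as `burst_id` are ignored).
#' @param threshold absolute correlation above which a feature is dropped.
#' @return character vector of retained feature names, with attributes
#'   `dropped` (correlated-out names) and `excluded_constant`.
#' @export
correlation_filter <- function(features, threshold = 0.9) {
  num <- vapply(features, is.numeric, TRUE)
  m <- as.matrix(features[num])
  if (nrow(m) < 2) stop_db("correlation filter needs >= 2 rows")
  sds <- apply(m, 2, sd, na.rm = TRUE)
  const <- !is.finite(sds) | sds == 0
  excluded <- colnames(m)[const]
  m <- m[, !const, drop = FALSE]
  keep <- character(0)
  drop <- character(0)
  for (nm in colnames(m)) {
    if (!length(keep)) { keep <- nm; next }
    r <- suppressWarnings(
      abs(cor(m[, nm], m[, keep, drop = FALSE],
              use = "pairwise.complete.obs")))
    if (any(r > threshold, na.rm = TRUE)) drop <- c(drop, nm)
    else keep <- c(keep, nm)
  }
  structure(keep, dropped = drop, excluded_constant = excluded)
}
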