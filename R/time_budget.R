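# Time-activity budgets: daily completeness filtering, aggregation of
# classified bursts into per-period behavior proportions, and the two scan
# summary conventions (per-scan mean and pooled counts).

#' Keep only sufficiently complete bird-days
#'
#' A transmitter on a 10-min duty cycle should record 144 bursts per day;
#' bird-days with fewer than `min_frac` of the expected bursts are dropped
#' so partially recorded days do not distort budgets. 137/144 (0.9514) is
#' kept; 136/144 (0.9444) is dropped at the default 0.95.
#'
#' @param bursts data frame with `bird_id` and `timestamp_utc`.
#' @param expected_per_day expected bursts per bird-day (144 at a 10-min
#'   cadence).
#' @param min_frac minimum recorded/expected fraction.
#' @return the burst table restricted to retained bird-days.
#' @export
completeness_filter <- function(bursts, expected_per_day = 144L,
                                min_frac = 0.95) {
  if (expected_per_day <= 0) stop_db("expected_per_day must be positive")
  date <- as.Date(as_utc(bursts$timestamp_utc), tz = "UTC")
  key <- paste(bursts$bird_id, date)
  n <- table(key)
  keep_days <- names(n)[as.numeric(n) / expected_per_day >= min_frac]
  bursts[key %in% keep_days, , drop = FALSE]
}

budget_row <- function(beh, scope, classes = BEHAVIOR_CLASSES) {
  counts <- table(factor(beh, classes))
  n <- sum(counts)
  props <- if (n > 0) as.numeric(counts) / n else rep(NA_real_, length(classes))
  out <- data.frame(scope = scope, n_total = n)
  for (j in seq_along(classes)) {
    out[[paste0("n_", classes[j])]] <- as.numeric(counts[j])
    out[[paste0("p_", classes[j])]] <- props[j]
  }
  out
}

#' Aggregate behavior records into time budgets
#'
#' Counts and proportions per behavior at the requested scope: pooled over
#' everything, per solar period, or per bird (optionally crossed with
#' period). Proportions are counts/n_total and sum to 1 within each scope;
#' an empty scope carries `NA` proportions.
#'
#' @param records data frame with a `behavior` column and, as required by
#'   `scope`, `period` and/or `bird_id`.
#' @param scope one of `"pooled"`, `"period"`, `"bird"`, `"bird_period"`.
#' @param classes behavior class list fixing column order.
#' @return a `time_budget` data frame: one row per scope with `n_total`,
#'   `n_<behavior>` and `p_<behavior>` columns. For `scope = "period"` a
#'   pooled `"total"` row is appended.
#' @export
aggregate_budget <- function(records, scope = c("pooled", "period", "bird",
                                                "bird_period"),
                             classes = BEHAVIOR_CLASSES) {
  scope <- match.arg(scope)
  bad <- setdiff(unique(records$behavior), classes)
  if (length(bad)) stop_db("behavior(s) outside class list: ",
                           paste(bad, collapse = ", "))
  out <- switch(scope,
    pooled = budget_row(records$behavior, "total", classes),
    period = {
      per <- lapply(split(records, records$period), function(r) {
        budget_row(r$behavior, r$period[1], classes)
      })
      rbind(do.call(rbind, per), budget_row(records$behavior, "total", classes))
    },
    bird = do.call(rbind, lapply(split(records, records$bird_id), function(r) {
      budget_row(r$behavior, r$bird_id[1], classes)
    })),
    bird_period = do.call(rbind, lapply(
      split(records, list(records$bird_id, records$period), drop = TRUE),
      function(r) budget_row(r$behavior,
                             paste(r$bird_id[1], r$period[1]), classes)))
  )
  rownames(out) <- NULL
  structure(out, class = c("time_budget", "data.frame"))
}

#' Time budget directly from a count table
#'
#' Recomputes behavior proportions from per-period counts (e.g. a printed
#' contingency table), appending a pooled total row whose counts are the
#' column sums.
#'
#' @param counts numeric matrix, rows = periods (named), columns =
#'   behaviors (named by `classes`).
#' @param classes behavior class list.
#' @return a `time_budget` data frame as in [aggregate_budget()].
#' @export
budget_from_counts <- function(counts, classes = BEHAVIOR_CLASSES) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)) || !setequal(colnames(counts), classes)) {
    stop_db("counts must have one named column per behavior class")
  }
  counts <- counts[, classes, drop = FALSE]
  rows <- rbind(counts, total = colSums(counts))
  out <- do.call(rbind, lapply(rownames(rows), function(rn) {
    cnt <- rows[rn, ]
    r <- data.frame(scope = rn, n_total = sum(cnt))
    for (j in classes) {
      r[[paste0("n_", j)]] <- as.numeric(cnt[j])
      r[[paste0("p_", j)]] <- as.numeric(cnt[j]) / sum(cnt)
    }
    r
  }))
  rownames(out) <- NULL
  structure(out, class = c("time_budget", "data.frame"))
}

#' @export
print.time_budget <- function(x, digits = 3, ...) {
  cat("Time-activity budget\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Summarise instantaneous scan samples
#'
#' Returns both scan summary conventions, which differ whenever scan sizes
#' vary: the mean of per-scan proportion vectors (the mean +/- SE
#' reporting convention) and pooled counts over all observations (the
#' contingency-table convention).
#'
#' @param scans data frame with `scan_id` and `behavior`; scans with zero
#'   birds are skipped with a warning.
#' @param classes behavior class list.
#' @return list with `per_scan` (data frame of per-scan proportions),
#'   `mean_of_scans` (named proportions with `se` attribute), `pooled`
#'   (a `time_budget` row) and `n_total`.
#' @export
scan_budget <- function(scans, classes = BEHAVIOR_CLASSES) {
  groups <- split(scans$behavior, scans$scan_id)
  sizes <- lengths(groups)
  if (any(sizes == 0)) {
    warning(sum(sizes == 0), " scan(s) with zero birds skipped",
            call. = FALSE)
    groups <- groups[sizes > 0]
  }
  props <- t(vapply(groups, function(b) {
    as.numeric(table(factor(b, classes))) / length(b)
  }, numeric(length(classes))))
  colnames(props) <- classes
  per_scan <- data.frame(scan_id = names(groups),
                         n = lengths(groups), props, row.names = NULL)
  mos <- colMeans(props)
  attr(mos, "se") <- apply(props, 2, sd) / sqrt(nrow(props))
  list(per_scan = per_scan,
       mean_of_scans = mos,
       pooled = budget_row(scans$behavior, "pooled_scans", classes),
       n_total = length(scans$behavior))
}
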