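test_that("solar phases match reference behavior at canonical sites", {
  # equinox on the equator at the prime meridian: sunrise ~ 06:00 UTC
  eq <- solar_phases(as.Date("2023-03-20"), 0, 0)
  sunrise_min <- as.numeric(difftime(
    eq$sunrise, as.POSIXct("2023-03-20 06:00:00", tz = "UTC"),
    units = "mins"))
  expect_lt(abs(sunrise_min), 10)
  # solar noon at lon 0 is 12:00 UTC within the equation-of-time bound
  dates <- as.Date("2023-01-01") + seq(0, 360, by = 30)
  noon <- solar_phases(dates, 10, 0)$solar_noon
  offs <- abs(as.numeric(format(noon, "%H")) * 60 +
                as.numeric(format(noon, "%M")) - 720)
  expect_true(all(offs <= 17))
  # phase ordering holds across a full year at 39 degrees latitude
  yr <- solar_phases(as.Date("2023-01-01") + 0:364, 39, -76.2)
  expect_true(all(yr$dawn < yr$sunrise & yr$sunrise < yr$solar_noon &
                    yr$solar_noon < yr$sunset & yr$sunset < yr$dusk))
  expect_error(solar_phases(as.Date("2023-06-01"), 70, 0), "polar")
})

test_that("period assignment partitions time with a half-open day interval", {
  ph <- solar_phases(as.Date("2023-01-15"), 39, -76.2)
  expect_identical(assign_period(ph$solar_noon, 39, -76.2), "diurnal")
  midnight <- as.POSIXct("2023-01-15 05:00:00", tz = "UTC")  # local midnight
  expect_identical(assign_period(midnight, 39, -76.2), "nocturnal")
  expect_identical(assign_period(ph$sunrise, 39, -76.2), "diurnal")
  expect_identical(assign_period(ph$sunset, 39, -76.2), "nocturnal")
  ts <- seq(as.POSIXct("2023-01-15 00:00", tz = "UTC"), by = 600,
            length.out = 144)
  per <- assign_period(ts, 39, -76.2)
  expect_equal(sum(per == "diurnal") + sum(per == "nocturnal"), 144)
})

test_that("the completeness filter keeps bird-days at >= 95% of expected bursts", {
  mk <- function(n, date) data.frame(
    bird_id = "B1",
    timestamp_utc = as.POSIXct(paste(date, "00:00"), tz = "UTC") +
      600 * (seq_len(n) - 1))
  b <- rbind(mk(137, "2023-01-10"), mk(136, "2023-01-11"),
             mk(144, "2023-01-12"))
  kept <- completeness_filter(b, 144)
  days <- unique(as.Date(kept$timestamp_utc))
  expect_setequal(format(days), c("2023-01-10", "2023-01-12"))
  expect_error(completeness_filter(b, 0), "positive")
})

test_that("budgets recompute the published contingency percentages", {
  tb <- budget_from_counts(acc_counts_table())
  pct <- round(100 * as.matrix(tb[paste0("p_", BEHAVIOR_CLASSES)]), 1)
  expect_equal(pct[tb$scope == "diurnal", ], c(37.7, 3.0, 57.6, 1.7),
               ignore_attr = TRUE)
  expect_equal(pct[tb$scope == "nocturnal", ], c(21.9, 3.9, 71.1, 3.1),
               ignore_attr = TRUE)
  expect_equal(pct[tb$scope == "total", ], c(29.1, 3.5, 65.0, 2.5),
               ignore_attr = TRUE)
  expect_equal(tb$n_total, c(86781, 104405, 191186))
})

test_that("record-level aggregation matches counts and sums to one", {
  rec <- data.frame(
    behavior = c("feeding", "feeding", "flying", "preening", "resting",
                 "preening"),
    period = c("diurnal", "diurnal", "nocturnal", "diurnal", "nocturnal",
               "nocturnal"),
    bird_id = "B1")
  tb <- aggregate_budget(rec, "period")
  p <- as.matrix(tb[paste0("p_", BEHAVIOR_CLASSES)])
  expect_equal(rowSums(p), rep(1, 3), ignore_attr = TRUE)
  expect_equal(tb$n_total, c(3, 3, 6))
  # pooled counts are the sum over periods
  n <- as.matrix(tb[paste0("n_", BEHAVIOR_CLASSES)])
  expect_equal(n[3, ], n[1, ] + n[2, ])
  one <- aggregate_budget(data.frame(behavior = "feeding"), "pooled")
  expect_equal(as.numeric(one[paste0("p_", BEHAVIOR_CLASSES)]),
               c(1, 0, 0, 0))
  expect_error(aggregate_budget(data.frame(behavior = "moulting")),
               "outside class list")
})

test_that("scan budgets report both per-scan-mean and pooled conventions", {
  scans <- data.frame(scan_id = rep(1:2, each = 1),
                      behavior = c("feeding", "flying"))
  sb <- scan_budget(scans)
  expect_equal(unname(sb$mean_of_scans["feeding"]), 0.5)
  # a single scan: mean of scans equals pooled proportions
  one <- scan_budget(data.frame(scan_id = 1,
                                behavior = c("feeding", "feeding", "resting")))
  expect_equal(as.numeric(one$mean_of_scans),
               as.numeric(one$pooled[paste0("p_", BEHAVIOR_CLASSES)]))
  # pooled counts from the published diurnal scan row
  cnt <- scan_counts()
  big <- data.frame(scan_id = 1, behavior = rep(names(cnt), cnt))
  expect_equal(scan_budget(big)$n_total, 42713)
})
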