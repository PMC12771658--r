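test_that("haversine distances are correct, symmetric and validated", {
  expect_equal(haversine_km(39, -76, 39, -76), 0)
  # one degree of longitude on the equator: 2*pi*6371/360
  expect_equal(haversine_km(0, 0, 0, 1), 111.195, tolerance = 1e-4)
  set.seed(1)
  for (i in 1:10) {
    p <- runif(4, -60, 60)
    expect_equal(haversine_km(p[1], p[2], p[3], p[4]),
                 haversine_km(p[3], p[4], p[1], p[2]))
  }
  expect_error(haversine_km(91, 0, 0, 0), "invalid coordinates")
})

test_that("daily displacement sums consecutive segments by start day", {
  # two fixes one degree apart on the same day
  gps <- data.frame(
    bird_id = "B1",
    timestamp_utc = as.POSIXct(c("2023-01-10 10:00", "2023-01-10 11:00"),
                               tz = "UTC"),
    lat = c(0, 0), lon = c(0, 1))
  dd <- daily_displacement(gps)
  expect_equal(dd$km, 111.195, tolerance = 1e-4)
  expect_equal(dd$day, 0L)   # release day is day 0
  # stationary bird
  gps$lon <- c(1, 1)
  expect_true(all(daily_displacement(gps)$km == 0))
  # a > 3 h gap contributes no segment
  gps2 <- data.frame(
    bird_id = "B1",
    timestamp_utc = as.POSIXct(c("2023-01-10 10:00", "2023-01-10 14:30"),
                               tz = "UTC"),
    lat = c(0, 0), lon = c(0, 1))
  expect_null(daily_displacement(gps2))
  expect_warning(daily_displacement(gps[1, ]), "fewer than 2")
})

test_that("daily displacement exactly recovers the generator's path lengths", {
  cfg <- world_config(n_birds = 2, n_days = 6, seed = 21)
  gps <- generate_displacement_track(cfg, seed = 21)
  truth <- attr(gps, "daily_km")
  dd <- daily_displacement(gps)
  m <- merge(dd, truth, by = c("bird_id", "day"))
  expect_equal(nrow(m), nrow(truth))
  expect_equal(m$km.x, m$km.y, tolerance = 1e-10)
})

test_that("change-point detection recovers mean shifts and ignores constants", {
  expect_error(detect_changepoints(c(1, 2, 3)), "length >= 4")
  expect_equal(nrow(detect_changepoints(rep(5, 20))), 0)
  # single large shift: 230 (days 1-2) then 7 (days 3-20), sd 5
  hits <- 0
  for (s in 1:50) {
    set.seed(s)
    km <- pmax(0, c(rnorm(2, 230, 5), rnorm(18, 7, 5)))
    cp <- detect_changepoints(km)
    if (nrow(cp) && any(abs(cp$tau - 2) <= 1 & cp$effect_size > 2)) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / 50, 0.9)
})

test_that("the two-shift post-release scenario is recovered in >= 90% of seeds", {
  means <- c(229.3, 21.8, 13.9, 9.3, rep(7.2, 16))
  both <- 0
  for (s in 1:50) {
    set.seed(s)
    km <- pmax(0, rnorm(20, means, 0.15 * means))
    cp <- detect_changepoints(km, min_effect = 0.5)
    ok1 <- any(abs(cp$tau - 2) <= 1)
    ok2 <- any(abs(cp$tau - 4) <= 1)
    if (ok1 && ok2) both <- both + 1
  }
  expect_gte(both / 50, 0.9)
})

test_that("censoring drops early days, short records and emigrants", {
  km <- c(229.3, 21.8, 13.9, 9.3, rep(7.2, 16))
  gps <- straight_track(km)
  cen <- censor_birds(gps)
  expect_true(cen$included)
  expect_gte(cen$censored_through, 2)
  bursts <- data.frame(
    bird_id = "B01",
    timestamp_utc = as.POSIXct(paste(as.Date("2023-01-10") + 0:20, "06:00"),
                               tz = "UTC"))
  kept <- apply_censor(cen, bursts)
  day <- as.integer(as.Date(kept$timestamp_utc) - as.Date("2023-01-10"))
  expect_false(any(day >= 1 & day <= cen$censored_through))
  # explicit censored-through 4 removes days 1..4
  cen4 <- cen; cen4$censored_through <- 4L
  kept4 <- apply_censor(cen4, bursts)
  day4 <- as.integer(as.Date(kept4$timestamp_utc) - as.Date("2023-01-10"))
  expect_false(any(day4 >= 1 & day4 <= 4))
  # monotone: deeper censoring never adds bursts
  cen9 <- cen; cen9$censored_through <- 9L
  expect_true(all(apply_censor(cen9, bursts)$timestamp_utc %in%
                    kept4$timestamp_utc))
  # no change-points, long record: everything kept
  flat <- straight_track(rep(7, 20))
  cen_flat <- censor_birds(flat, min_effect = 3)
  expect_equal(cen_flat$censored_through, 0L)
  expect_equal(nrow(apply_censor(cen_flat, bursts)), nrow(bursts))
  # a 10-day record is excluded entirely (survival <= 14 days)
  short <- straight_track(rep(7, 10))
  cen_s <- censor_birds(short)
  expect_false(cen_s$included)
  expect_equal(nrow(apply_censor(cen_s, bursts)), 0)
  # unknown bird is an error
  expect_error(apply_censor(cen, data.frame(bird_id = "B99",
                                            timestamp_utc = Sys.time())),
               "B99")
})

test_that("a bounding box flags emigrant birds", {
  gps <- straight_track(rep(7, 16))
  box_in <- c(min(gps$lat) - 1, max(gps$lat) + 1,
              min(gps$lon) - 1, max(gps$lon) + 1)
  expect_true(censor_birds(gps, bbox = box_in)$included)
  box_out <- c(min(gps$lat), max(gps$lat) - 1e-9, -180, 180)
  expect_false(censor_birds(gps, bbox = box_out)$included)
})
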