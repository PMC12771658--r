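test_that("zero-noise resting burst is pure gravity with no dynamic component", {
  model <- signature_model(list(resting = list(noise_sd = 0)))
  b <- generate_acc_burst("resting", model, seed = 1)
  g <- model$resting$gravity
  expect_true(all(b$x == g[1]) && all(b$y == g[2]) && all(b$z == g[3]))
  f <- compute_features(middle_window(b))
  expect_identical(unname(f["odba"]), 0)
  expect_identical(unname(f["vedba"]), 0)
})

test_that("flying bursts carry far more dynamic body acceleration than resting", {
  model <- signature_model()
  odba_of <- function(beh, seed) {
    unname(compute_features(
      middle_window(generate_acc_burst(beh, model, seed = seed)))["odba"])
  }
  for (s in 1:5) expect_gt(odba_of("flying", s), odba_of("resting", s))
})

test_that("burst generation is deterministic given (behavior, model, seed)", {
  m <- signature_model()
  b1 <- generate_acc_burst("feeding", m, seed = 7)
  b2 <- generate_acc_burst("feeding", m, seed = 7)
  expect_identical(b1, b2)
  b3 <- generate_acc_burst("feeding", m, seed = 8)
  expect_false(identical(b1$x, b3$x))
})

test_that("unknown behaviors and invalid signatures are rejected", {
  expect_error(generate_acc_burst("moulting"), "unknown behavior")
  expect_error(signature_model(list(flying = list(freq = 6))), "Nyquist|frequency")
  expect_error(signature_model(list(flying = list(amp = -1))), ">= 0")
})

test_that("world generation yields one burst per cadence interval with valid schedules", {
  cfg <- world_config(n_birds = 1, n_days = 1, seed = 2)
  w <- generate_world(cfg)
  expect_equal(nrow(w$truth), 144)
  expect_equal(nrow(w$acc), 144 * 50)
  expect_setequal(unique(w$truth$period), c("diurnal", "nocturnal"))
  # scan table is a strict subset of diurnal truth within 200 m
  expect_true(all(w$scans$distance_m <= 200))
  key <- paste(w$scans$timestamp_utc, w$scans$behavior)
  tkey <- paste(w$truth$timestamp_utc[w$truth$period == "diurnal"],
                w$truth$behavior[w$truth$period == "diurnal"])
  expect_true(all(key %in% tkey))
})

test_that("a zero nocturnal-flight schedule produces no nocturnal flight", {
  cfg <- world_config(
    n_birds = 2, n_days = 2, seed = 3,
    p_nocturnal = c(feeding = 0.25, flying = 0, preening = 0.70,
                    resting = 0.05))
  w <- generate_world(cfg)
  noct <- w$truth[w$truth$period == "nocturnal", ]
  expect_gt(nrow(noct), 0)
  expect_false(any(noct$behavior == "flying"))
})

test_that("empirical behavior proportions converge to the configured schedule", {
  # 10 birds x 30 days at the published diurnal budget
  cfg <- world_config(n_birds = 10, n_days = 30, seed = 4)
  w <- generate_world(cfg, with_acc = FALSE)
  day <- w$truth[w$truth$period == "diurnal", ]
  p_hat <- as.numeric(table(factor(day$behavior, BEHAVIOR_CLASSES))) /
    nrow(day)
  expect_true(all(abs(p_hat - cfg$p_diurnal) <= 0.02))
  night <- w$truth[w$truth$period == "nocturnal", ]
  q_hat <- as.numeric(table(factor(night$behavior, BEHAVIOR_CLASSES))) /
    nrow(night)
  # within 3 binomial SEs of the configured nocturnal proportions
  se <- sqrt(cfg$p_nocturnal * (1 - cfg$p_nocturnal) / nrow(night))
  expect_true(all(abs(q_hat - cfg$p_nocturnal) <= pmax(3 * se, 0.005)))
})

test_that("world generation is reproducible bit-for-bit and rejects empty ranges", {
  cfg <- world_config(n_birds = 1, n_days = 1, seed = 11)
  expect_identical(generate_world(cfg), generate_world(cfg))
  expect_error(world_config(n_days = 0), "empty date range")
  expect_error(world_config(p_diurnal = c(feeding = 0.5, flying = 0.5,
                                          preening = 0.2, resting = -0.2)))
})

test_that("displacement tracks settle near the configured daily distance", {
  cfg <- world_config(n_birds = 1, n_days = 20, disp_cv = 0.05)
  gps <- generate_displacement_track(cfg, seed = 9)
  dd <- daily_displacement(gps)
  settled <- dd$km[dd$day >= 5 & dd$day <= 20]
  expect_lt(abs(mean(settled) - 7.2) / 7.2, 0.20)
})

test_that("expected daily displacement is monotone non-increasing over early days", {
  cfg <- world_config(n_birds = 1, n_days = 4)
  mat <- sapply(1:100, function(s) {
    dd <- daily_displacement(generate_displacement_track(cfg, seed = s))
    dd$km[match(1:4, dd$day)]
  })
  avg <- rowMeans(mat)
  expect_true(all(diff(avg) <= 0))
})

test_that("a zero-length track has zero displacement everywhere", {
  gps <- straight_track(rep(0, 4))
  expect_true(all(daily_displacement(gps)$km == 0))
})
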