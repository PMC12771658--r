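# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

burst_features <- function(bursts) {
  f1 <- compute_features(middle_window(bursts[[1]]))
  as.data.frame(t(vapply(bursts, function(b) {
    compute_features(middle_window(b))
  }, f1)))
}

# Labelled training features at n/class (default signatures), cached.
training_fixture <- function(n = 60, seed = 5) {
  key <- paste0("train_", n, "_", seed)
  if (is.null(.fixtures[[key]])) {
    tr <- generate_labeled_bursts(n, seed = seed)
    feats <- cbind(data.frame(burst_id = tr$labels$burst_id),
                   burst_features(tr$bursts), row.names = NULL)
    .fixtures[[key]] <- list(features = feats, labels = tr$labels,
                             retained = correlation_filter(feats))
  }
  .fixtures[[key]]
}

# A small fitted classifier on the cached training set.
classifier_fixture <- function(n = 60, seed = 5) {
  key <- paste0("model_", n, "_", seed)
  if (is.null(.fixtures[[key]])) {
    fx <- training_fixture(n, seed)
    sp <- stratified_split(fx$labels$behavior, 0.7, seed)
    m <- train_classifier(fx$features[sp$train, ],
                          fx$labels$behavior[sp$train],
                          retained = fx$retained, seed = seed)
    .fixtures[[key]] <- list(model = m, split = sp, fx = fx)
  }
  .fixtures[[key]]
}

# Published contingency-table counts used as printed-table inputs.
acc_counts_table <- function() {
  rbind(diurnal = c(feeding = 32715, flying = 2607,
                    preening = 50003, resting = 1456),
        nocturnal = c(feeding = 22838, flying = 4063,
                      preening = 74232, resting = 3272))
}

scan_counts <- function() {
  c(feeding = 10149, flying = 1676, preening = 867, resting = 30021)
}

# Hourly GPS fixture: one bird, explicit per-day path built from steps of
# known length starting at (39, -76).
straight_track <- function(daily_km, start_date = as.Date("2023-01-10")) {
  cfg <- world_config(n_birds = 1, start = start_date,
                      n_days = length(daily_km), disp_cv = 1e-9)
  generate_displacement_track(cfg, seed = 42, daily_km = daily_km)
}
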