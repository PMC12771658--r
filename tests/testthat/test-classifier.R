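test_that("purity filtering keeps bursts held for at least 3 of 5 seconds", {
  lab <- data.frame(burst_id = c("a", "b", "c"),
                    purity_seconds = c(3.0, 2.9, 5.0))
  kept <- purity_filter(lab)
  expect_identical(kept$burst_id, c("a", "c"))
  all5 <- data.frame(burst_id = letters[1:4], purity_seconds = rep(5, 4))
  expect_identical(purity_filter(all5), all5)
  expect_error(purity_filter(data.frame(x = 1)), "purity_seconds")
})

test_that("training selects three features and records per-class sizes", {
  cf <- classifier_fixture()
  m <- cf$model
  expect_length(m$features, 3)
  expect_identical(m$classes, BEHAVIOR_CLASSES)
  expect_true(all(m$features %in% as.character(cf$fx$retained)))
  # the dive-tank style fixture with unequal class sizes trains and
  # reports those counts in metadata
  sizes <- c(feeding = 319, flying = 103, preening = 169, resting = 282)
  tr <- generate_labeled_bursts(sizes, seed = 31)
  feats <- cbind(data.frame(burst_id = tr$labels$burst_id),
                 burst_features(tr$bursts), row.names = NULL)
  m2 <- train_classifier(feats, tr$labels$behavior, seed = 31,
                         nrounds = 50)
  expect_equal(unlist(m2$metadata$n_per_class)[names(sizes)], sizes)
})

test_that("degenerate training inputs are rejected", {
  fx <- training_fixture()
  one <- fx$labels$behavior == "resting"
  expect_error(train_classifier(fx$features[one, ],
                                fx$labels$behavior[one]), ">= 2")
  few <- c(which(fx$labels$behavior == "resting"),
           which(fx$labels$behavior == "flying")[1:5])
  expect_error(train_classifier(fx$features[few, ],
                                fx$labels$behavior[few]), ">= 10")
})

test_that("training is deterministic given the seed", {
  fx <- training_fixture()
  sp <- stratified_split(fx$labels$behavior, 0.7, 1)
  m1 <- train_classifier(fx$features[sp$train, ], fx$labels$behavior[sp$train],
                         retained = fx$retained, seed = 3, nrounds = 60)
  m2 <- train_classifier(fx$features[sp$train, ], fx$labels$behavior[sp$train],
                         retained = fx$retained, seed = 3, nrounds = 60)
  expect_identical(m1$features, m2$features)
  expect_identical(predict(m1, fx$features[sp$test, ]),
                   predict(m2, fx$features[sp$test, ]))
})

test_that("prediction honours its contract", {
  cf <- classifier_fixture()
  m <- cf$model; fx <- cf$fx; sp <- cf$split
  # training optimism: accuracy on training rows >= held-out accuracy
  acc_tr <- mean(predict(m, fx$features[sp$train, ]) ==
                   fx$labels$behavior[sp$train])
  acc_te <- mean(predict(m, fx$features[sp$test, ]) ==
                   fx$labels$behavior[sp$test])
  expect_gte(acc_tr, acc_te)
  # empty input, row-reordering stability, missing-feature error
  expect_identical(predict(m, fx$features[0, ]), character(0))
  ord <- rev(seq_len(nrow(fx$features)))
  expect_identical(predict(m, fx$features[ord, ]),
                   predict(m, fx$features)[ord])
  broken <- fx$features[setdiff(names(fx$features), m$features[1])]
  expect_error(predict(m, broken), m$features[1])
  # a noise-free resting burst is classified as resting
  quiet <- signature_model(list(resting = list(noise_sd = 0.001)))
  b <- generate_acc_burst("resting", quiet, seed = 12)
  f <- as.data.frame(t(compute_features(middle_window(b))))
  expect_identical(predict(m, f), "resting")
})

test_that("evaluation reproduces hand-computed confusion summaries", {
  ev <- evaluate_classifier(c("A", "A", "B", "B"), c("A", "B", "B", "B"),
                            classes = c("A", "B"))
  expect_equal(ev$accuracy, 0.75)
  expect_equal(ev$per_class$f1, c(2 / 3, 0.8))
  expect_equal(unname(rowSums(ev$confusion)), c(2, 2))
  expect_equal(unname(colSums(ev$confusion)), c(1, 3))
  expect_equal(ev$n, 4)
  # perfect predictions
  ev2 <- evaluate_classifier(BEHAVIOR_CLASSES, BEHAVIOR_CLASSES)
  expect_equal(ev2$accuracy, 1)
  expect_true(all(ev2$per_class$f1 == 1))
  # F1 = 2PR/(P+R): precision .5, recall 1 -> 2/3
  ev3 <- evaluate_classifier(c("A", "B"), c("A", "A"), classes = c("A", "B"))
  expect_equal(ev3$per_class$f1[1], 2 / 3)
  # zero-division -> F1 = 0 with flag; labels outside the class list error
  expect_equal(ev3$per_class$f1[2], 0)
  expect_true(ev3$per_class$zero_division[2])
  expect_error(evaluate_classifier("A", "C", classes = c("A", "B")),
               "outside class list")
  expect_error(evaluate_classifier(c("A", "A"), "A"), "equal length")
})

test_that("macro-F1 stays high across training seeds on default signatures", {
  fx <- training_fixture()
  f1s <- vapply(1:3, function(s) {
    sp <- stratified_split(fx$labels$behavior, 0.7, s)
    m <- train_classifier(fx$features[sp$train, ],
                          fx$labels$behavior[sp$train],
                          retained = fx$retained, seed = s, nrounds = 150)
    evaluate_classifier(fx$labels$behavior[sp$test],
                        predict(m, fx$features[sp$test, ]),
                        BEHAVIOR_CLASSES)$macro_f1
  }, numeric(1))
  expect_true(all(f1s >= 0.85))
  expect_lt(sd(f1s), 0.1)
})

test_that("wave surge on surface behaviors reduces resting recall", {
  cf <- classifier_fixture()
  surge <- signature_model(list(resting = list(surge_amp = 0.12),
                                swimming = list(surge_amp = 0.12)))
  eval_with <- function(model) {
    te <- generate_labeled_bursts(c(resting = 80, feeding = 80), model,
                                  seed = 77)
    feats <- cbind(data.frame(burst_id = te$labels$burst_id),
                   burst_features(te$bursts), row.names = NULL)
    ev <- evaluate_classifier(te$labels$behavior,
                              predict(cf$model, feats), BEHAVIOR_CLASSES)
    ev$per_class$recall[ev$per_class$class == "resting"]
  }
  expect_lt(eval_with(surge), eval_with(signature_model()))
})
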