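# Gradient-boosted decision-tree behavior classifier: purity filtering of
# labelled bursts, feature ranking by ensemble gain with top-3 refit,
# prediction, and confusion-matrix/F1 evaluation. Tree fitting delegates to
# xgboost; the module owns selection, the contract and the evaluation.

#' Filter labelled bursts by behavior purity
#'
#' Keeps only bursts whose labelled behavior was held for at least
#' `min_seconds` of the 5 s burst (boundary inclusive: a purity of exactly
#' 3 s is kept), discarding mixed-behavior bursts before training.
#'
#' @param labels data frame with a `purity_seconds` column.
#' @param min_seconds minimum purity duration (s).
#' @return the filtered data frame.
#' @export
purity_filter <- function(labels, min_seconds = 3) {
  if (!"purity_seconds" %in% names(labels)) {
    stop_db("labels must carry a purity_seconds column")
  }
  labels[labels$purity_seconds >= min_seconds, , drop = FALSE]
}

feature_matrix <- function(features, cols = NULL) {
  num <- vapply(features, is.numeric, TRUE)
  num["burst_id" == names(features)] <- FALSE
  m <- as.matrix(features[num])
  if (!is.null(cols)) {
    miss <- setdiff(cols, colnames(m))
    if (length(miss)) {
      stop_db("feature table is missing selected feature(s): ",
              paste(miss, collapse = ", "))
    }
    m <- m[, cols, drop = FALSE]
  }
  m
}

fit_booster <- function(x, y_int, n_class, nrounds, max_depth, eta, seed) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y_int, nthread = 1)
  with_seed(seed, xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = n_class,
                  max_depth = max_depth, eta = eta, nthread = 1,
                  seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0))
}

booster_accuracy <- function(bst, x, y_int, n_class) {
  p <- predict(bst, xgboost::xgb.DMatrix(x, nthread = 1))
  p <- matrix(p, ncol = n_class, byrow = !is.matrix(p))
  mean(max.col(p) - 1L == y_int)
}

#' Train the behavior classifier
#'
#' Fits a gradient-boosted decision-tree ensemble on all supplied features,
#' ranks features, and refits the final model on the top `n_select`
#' (default 3) features only. Ranking is by total ensemble gain
#' (`selection = "gain"`) or by greedy forward selection on training
#' accuracy (`selection = "forward"`).
#'
#' @param features data frame from [feature_table()]; apply
#'   [correlation_filter()] first and pass its result as `retained`.
#' @param labels behavior labels: a character/factor vector aligned with
#'   `features` rows, or a data frame with `burst_id` and `behavior`
#'   columns joined by `burst_id`.
#' @param retained optional character vector restricting candidate
#'   features (e.g. the output of [correlation_filter()]).
#' @param seed integer seed; training is deterministic given the seed.
#' @param n_select number of features in the final model.
#' @param nrounds,max_depth,eta boosting hyperparameters (500 trees of
#'   depth 3 at learning rate 0.1 by default).
#' @param selection feature-selection mode, `"gain"` or `"forward"`.
#' @return a `divebudget_classifier`: final booster, selected feature
#'   names, class list, full importance table, and training metadata
#'   (seed and per-class counts).
#' @export
train_classifier <- function(features, labels, retained = NULL, seed = 1L,
                             n_select = 3L, nrounds = 500L, max_depth = 3L,
                             eta = 0.1, selection = c("gain", "forward")) {
  selection <- match.arg(selection)
  if (is.data.frame(labels)) {
    i <- match(features$burst_id, labels$burst_id)
    if (anyNA(i)) stop_db("labels missing for some burst_ids")
    labels <- labels$behavior[i]
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(features)) {
    stop_db("labels length does not match feature rows")
  }
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop_db("training needs >= 2 behavior classes")
  counts <- table(labels)
  if (any(counts < 10)) {
    stop_db("each class needs >= 10 bursts; got: ",
            paste(names(counts), counts, sep = "=", collapse = ", "))
  }
  x <- feature_matrix(features, retained)
  y <- match(labels, classes) - 1L
  k <- length(classes)

  full <- fit_booster(x, y, k, nrounds, max_depth, eta, seed)
  imp <- xgboost::xgb.importance(model = full)
  imp <- as.data.frame(imp)
  n_select <- min(n_select, ncol(x))

  if (selection == "gain") {
    selected <- head(imp$Feature, n_select)
  } else {
    # greedy forward selection by training accuracy over gain-ranked
    # candidates (capped for tractability)
    cand <- head(imp$Feature, max(10L, n_select))
    selected <- character(0)
    for (step in seq_len(n_select)) {
      accs <- vapply(setdiff(cand, selected), function(f) {
        b <- fit_booster(x[, c(selected, f), drop = FALSE], y, k,
                         nrounds, max_depth, eta, seed)
        booster_accuracy(b, x[, c(selected, f), drop = FALSE], y, k)
      }, numeric(1))
      selected <- c(selected, names(which.max(accs)))
    }
  }

  final <- fit_booster(x[, selected, drop = FALSE], y, k,
                       nrounds, max_depth, eta, seed)
  structure(
    list(booster = final, features = selected, classes = classes,
         importance = imp,
         params = list(nrounds = nrounds, max_depth = max_depth, eta = eta,
                       selection = selection),
         metadata = list(seed = seed, n_per_class = as.list(counts))),
    class = "divebudget_classifier")
}

#' Predict behaviors for new bursts
#'
#' @param object a [train_classifier()] model.
#' @param newdata feature data frame containing the model's selected
#'   features (extra columns ignored; a missing selected feature is an
#'   error naming it).
#' @param type `"class"` for labels, `"prob"` for the class-probability
#'   matrix.
#' @param ... unused.
#' @return character vector of behavior labels (or a probability matrix);
#'   predictions are row-wise, hence stable under row reordering.
#' @export
predict.divebudget_classifier <- function(object, newdata,
                                          type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (nrow(newdata) == 0) {
    return(if (type == "class") character(0) else
      matrix(numeric(0), 0, length(object$classes),
             dimnames = list(NULL, object$classes)))
  }
  x <- feature_matrix(newdata, object$features)
  p <- predict(object$booster, xgboost::xgb.DMatrix(x, nthread = 1))
  p <- matrix(p, ncol = length(object$classes), byrow = !is.matrix(p))
  colnames(p) <- object$classes
  if (type == "prob") return(p)
  object$classes[max.col(p)]
}

#' @export
print.divebudget_classifier <- function(x, ...) {
  cat("Gradient-boosted behavior classifier\n")
  cat("  classes:  ", paste(x$classes, collapse = ", "), "\n")
  cat("  features: ", paste(x$features, collapse = ", "), "\n")
  cat("  trees:    ", x$params$nrounds, " (depth ", x$params$max_depth,
      ", eta ", x$params$eta, ")\n", sep = "")
  cat("  training n per class: ",
      paste(names(x$metadata$n_per_class),
            unlist(x$metadata$n_per_class), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Confusion matrix, accuracy and per-class precision/recall/F1
#'
#' @param truth,predicted equal-length behavior label vectors; any label
#'   outside `classes` is an error.
#' @param classes class list defining matrix order.
#' @return an `eval_report`: confusion matrix (true rows x predicted
#'   columns), overall accuracy (trace/total), per-class precision, recall
#'   and `F1 = 2PR/(P+R)`, with zero-division cases reported as `F1 = 0`
#'   and flagged. `macro_f1` averages F1 over classes.
#' @export
evaluate_classifier <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop_db("truth and predicted must have equal length")
  }
  classes <- classes %||% sort(unique(c(truth, predicted)))
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad)) stop_db("label(s) outside class list: ",
                           paste(bad, collapse = ", "))
  cm <- table(truth = factor(truth, classes),
              predicted = factor(predicted, classes))
  n <- sum(cm)
  acc <- sum(diag(cm)) / n
  prec <- diag(cm) / colSums(cm)
  rec <- diag(cm) / rowSums(cm)
  denom <- prec + rec
  zero_div <- !is.finite(prec) | !is.finite(rec) | denom == 0
  f1 <- ifelse(zero_div, 0, 2 * prec * rec / denom)
  structure(
    list(confusion = cm, accuracy = acc, n = n,
         per_class = data.frame(class = classes,
                                precision = as.numeric(prec),
                                recall = as.numeric(rec),
                                f1 = as.numeric(f1),
                                zero_division = as.logical(zero_div),
                                row.names = NULL),
         macro_f1 = mean(f1)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Behavior classification report (n = ", x$n, ")\n", sep = "")
  print(x$confusion)
  cat(sprintf("accuracy: %.3f   macro-F1: %.3f\n", x$accuracy, x$macro_f1))
  print(x$per_class, digits = 3)
  invisible(x)
}

#' Stratified train/test split indices
#'
#' @param labels class labels.
#' @param train_frac fraction per class assigned to training.
#' @param seed RNG seed.
#' @return list with integer `train` and `test` index vectors.
#' @export
stratified_split <- function(labels, train_frac = 0.7, seed = 1L) {
  with_seed(seed, {
    idx <- split(seq_along(labels), labels)
    train <- unlist(lapply(idx, function(i) {
      sample(i, max(1L, round(length(i) * train_frac)))
    }), use.names = FALSE)
    list(train = sort(train),
         test = sort(setdiff(seq_along(labels), train)))
  })
}
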