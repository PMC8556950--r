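#' Train/test split specification and splitter
#'
#' Randomly partitions a labelled spectra set; the default mirrors the study
#' design (75\% training, 25\% test). Stratified splitting draws
#' `round((1 - train_fraction) * n_class)` test spectra per class; the
#' unstratified mode draws `round((1 - train_fraction) * n)` overall, which
#' lets class totals drift as in the published split.
#'
#' @param set a labelled [raman_spectra] object.
#' @param train_fraction fraction used for training, in (0, 1).
#' @param stratified draw the test set per class (default) or overall.
#' @param seed integer seed; the split is a pure function of it.
#' @return list with `train` and `test` [raman_spectra] objects.
#' @export
split_train_test <- function(set, train_fraction = 0.75, stratified = TRUE,
                             seed = 1L) {
  stopifnot(inherits(set, "raman_spectra"),
            train_fraction > 0, train_fraction < 1)
  lab <- set$meta$label
  if (any(is.na(lab))) stop("split requires labelled spectra")
  n <- n_spectra(set)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (stratified) {
    test_idx <- integer(0)
    for (g in sort(unique(lab))) {
      idx <- which(lab == g)
      ntest <- round((1 - train_fraction) * length(idx))
      test_idx <- c(test_idx, sample(idx, ntest))
    }
  } else {
    test_idx <- sample.int(n, round((1 - train_fraction) * n))
  }
  test_idx <- sort(test_idx)
  train <- set[-test_idx]; test <- set[test_idx]
  for (g in unique(lab)) {
    if (!g %in% train$meta$label) stop("class ", g, " absent from training set")
    if (!g %in% test$meta$label) stop("class ", g, " absent from test set")
  }
  list(train = train, test = test)
}

#' Repeated k-fold cross-validation specification
#'
#' @param folds number of folds (>= 2); default 10.
#' @param repeats repetitions (>= 1); default 5.
#' @param seed integer seed for fold assignment.
#' @return object of class `cv_spec`.
#' @export
cv_spec <- function(folds = 10L, repeats = 5L, seed = 1L) {
  stopifnot(folds >= 2L, repeats >= 1L)
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 seed = as.integer(seed)), class = "cv_spec")
}

# stratified repeated k-fold assignment: list of held-out index vectors,
# one per repeat x fold, with attribute "repeat"
make_folds <- function(labels, cv) {
  n <- length(labels)
  if (cv$folds > min(table(labels))) stop("fold count exceeds smallest class size")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cv$seed)
  out <- list(); rep_id <- integer(0)
  for (r in seq_len(cv$repeats)) {
    assign_fold <- integer(n)
    for (g in unique(labels)) {
      idx <- sample(which(labels == g))
      assign_fold[idx] <- rep_len(seq_len(cv$folds), length(idx))
    }
    for (f in seq_len(cv$folds)) {
      out[[length(out) + 1L]] <- which(assign_fold == f)
      rep_id <- c(rep_id, r)
    }
  }
  attr(out, "repeat") <- rep_id
  out
}

#' Fit and tune the six base learners, with out-of-fold meta-features
#'
#' Each learner's hyperparameters are tuned by repeated stratified k-fold
#' cross-validation maximizing accuracy; at the selected values the same
#' folds are replayed to produce out-of-fold class-probability predictions
#' for every training spectrum (averaged over repeats), so no learner ever
#' scores a spectrum it was fitted on within a repeat. Finally each learner
#' is refitted on the full training set for later test-time prediction.
#'
#' @param x training matrix (spectra x channels) or [raman_spectra].
#' @param y training labels (taken from metadata when `x` is a set).
#' @param specs learner specs from [base_learner_specs()].
#' @param cv a [cv_spec()].
#' @param meta_mode `"prob"` (default) stacks class probabilities;
#'   `"label"` stacks one-hot hard predictions.
#' @return list with `learners` (per kind: `best`, `cv_accuracy`, `model`),
#'   `meta_features` (n x 6*nclass, columns `kind.class`), `class_order`,
#'   `cv`, `meta_mode`.
#' @export
fit_base_learners <- function(x, y = NULL, specs = base_learner_specs(),
                              cv = cv_spec(), meta_mode = c("prob", "label")) {
  meta_mode <- match.arg(meta_mode)
  if (inherits(x, "raman_spectra")) {
    if (is.null(y)) y <- x$meta$label
    x <- x$intensity
  }
  x <- as.matrix(x); y <- as.character(y)
  stopifnot(nrow(x) == length(y))
  class_order <- sort(unique(y))
  folds <- make_folds(y, cv)
  rep_id <- attr(folds, "repeat")
  fitted <- list(); meta_cols <- list()
  for (kind in names(specs)) {
    spec <- specs[[kind]]
    grid <- resolve_grid(spec, x)
    if (nrow(grid) > 1L) {
      acc <- if (!is.null(spec$cv_accuracy)) {
        spec$cv_accuracy(x, y, folds, grid, cv$seed)
      } else {
        a <- matrix(NA_real_, length(folds), nrow(grid))
        for (f in seq_along(folds)) {
          idx <- folds[[f]]
          for (g in seq_len(nrow(grid))) {
            m <- spec$fit(x[-idx, , drop = FALSE], y[-idx],
                          grid[g, , drop = FALSE], cv$seed + f)
            p <- spec$prob(m, x[idx, , drop = FALSE], class_order)
            a[f, g] <- mean(class_order[max.col(p, ties.method = "first")] == y[idx])
          }
        }
        colMeans(a)
      }
      best_i <- which.max(acc)
    } else {
      acc <- NA_real_; best_i <- 1L
    }
    best <- grid[best_i, , drop = FALSE]
    # out-of-fold probabilities at the tuned values, averaged over repeats
    prob_sum <- matrix(0, nrow(x), length(class_order),
                       dimnames = list(NULL, class_order))
    oof_acc <- numeric(length(folds))
    for (f in seq_along(folds)) {
      idx <- folds[[f]]
      m <- spec$fit(x[-idx, , drop = FALSE], y[-idx], best, cv$seed + f)
      p <- spec$prob(m, x[idx, , drop = FALSE], class_order)
      hard <- if (is.null(spec$predict_class))
        class_order[max.col(p, ties.method = "first")] else
        spec$predict_class(m, x[idx, , drop = FALSE])
      oof_acc[f] <- mean(hard == y[idx])
      prob_sum[idx, ] <- prob_sum[idx, ] + p
    }
    probs <- prob_sum / cv$repeats
    if (meta_mode == "label") {
      hard <- matrix(0, nrow(probs), ncol(probs), dimnames = dimnames(probs))
      hard[cbind(seq_len(nrow(probs)), max.col(probs, ties.method = "first"))] <- 1
      probs <- hard
    }
    colnames(probs) <- paste(kind, class_order, sep = ".")
    meta_cols[[kind]] <- probs
    final <- spec$fit(x, y, best, cv$seed)
    fitted[[kind]] <- list(kind = kind, best = best,
                           grid_accuracy = acc, cv_accuracy = mean(oof_acc),
                           model = final)
  }
  list(learners = fitted, meta_features = do.call(cbind, meta_cols),
       class_order = class_order, cv = cv, meta_mode = meta_mode)
}

# tune + fit the gradient-boosting meta-learner on meta-features
fit_gbm_meta <- function(meta, y, class_order, cv,
                         grid = expand.grid(nrounds = c(50L, 100L, 150L),
                                            max_depth = 1:3),
                         eta = 0.1) {
  yi <- match(y, class_order) - 1L
  nc <- length(class_order)
  params <- function(depth) list(objective = "multi:softprob", num_class = nc,
                                 max_depth = depth, eta = eta, nthread = 1L)
  folds <- make_folds(y, cv)
  acc <- matrix(NA_real_, length(folds), nrow(grid))
  if (nrow(grid) > 1L) {
    for (f in seq_along(folds)) {
      idx <- folds[[f]]
      dtr <- xgboost::xgb.DMatrix(meta[-idx, , drop = FALSE], label = yi[-idx])
      for (depth in unique(grid$max_depth)) {
        set.seed(cv$seed + f)
        m <- xgboost::xgb.train(params(depth), dtr, nrounds = max(grid$nrounds),
                                verbose = 0)
        for (g in which(grid$max_depth == depth)) {
          p <- stats::predict(m, meta[idx, , drop = FALSE],
                              iterationrange = c(1, grid$nrounds[g]))
          p <- matrix(as.numeric(p), ncol = nc, byrow = !is.matrix(p))
          acc[f, g] <- mean(class_order[max.col(p, ties.method = "first")] == y[idx])
        }
      }
    }
    best <- grid[which.max(colMeans(acc)), , drop = FALSE]
  } else best <- grid
  set.seed(cv$seed)
  model <- xgboost::xgb.train(params(best$max_depth),
                              xgboost::xgb.DMatrix(meta, label = yi),
                              nrounds = best$nrounds, verbose = 0)
  list(model = model, best = best, grid_accuracy = colMeans(acc), eta = eta)
}

#' Fit the two-layer stacked Raman classifier
#'
#' The headline model: six tuned base learners (KNN, PCA-LDA, PLS-DA, linear
#' SVM, RBF SVM, random forest) are cross-validated on the preprocessed
#' training spectra; their out-of-fold class-probability predictions form
#' the meta-feature matrix (6 learners x classes columns) on which a
#' gradient-boosting meta-learner is tuned and fitted. All randomness is
#' derived from `cv$seed`, so refitting with the same configuration
#' reproduces the model exactly.
#'
#' @param x training matrix (spectra x channels) or a labelled
#'   [raman_spectra] object (typically the output of [preprocess()]).
#' @param y training labels; defaults to the set's metadata labels.
#' @param specs base learner specs, see [base_learner_specs()].
#' @param cv a [cv_spec()] used for both layers.
#' @param meta_mode `"prob"` or `"label"` meta-features.
#' @param gbm_grid meta-learner grid (`nrounds` x `max_depth`), learning
#'   rate 0.1.
#' @return an object of class `raman_stack`.
#' @export
fit_stacked <- function(x, y = NULL, specs = base_learner_specs(),
                        cv = cv_spec(), meta_mode = c("prob", "label"),
                        gbm_grid = expand.grid(nrounds = c(50L, 100L, 150L),
                                               max_depth = 1:3)) {
  meta_mode <- match.arg(meta_mode)
  if (inherits(x, "raman_spectra")) {
    if (is.null(y)) y <- x$meta$label
    x <- x$intensity
  }
  y <- as.character(y)
  base <- fit_base_learners(x, y, specs = specs, cv = cv, meta_mode = meta_mode)
  meta <- fit_gbm_meta(base$meta_features, y, base$class_order, cv, grid = gbm_grid)
  structure(list(learners = base$learners, meta = meta,
                 class_order = base$class_order, cv = cv,
                 meta_mode = meta_mode, specs = lapply(specs, `[[`, "grid"),
                 spec_fns = specs,
                 n_channels = ncol(x), n_train = nrow(x),
                 meta_layout = colnames(base$meta_features),
                 meta_features = base$meta_features),
            class = "raman_stack")
}

#' @method print raman_stack
#' @export
print.raman_stack <- function(x, ...) {
  cat("raman_stack: two-layer stacked classifier\n")
  cat("  classes:", paste(x$class_order, collapse = ", "), "\n")
  cat("  trained on", x$n_train, "spectra x", x$n_channels, "channels\n")
  cat("  CV:", x$cv$folds, "folds x", x$cv$repeats, "repeats (seed", x$cv$seed, ")\n")
  cat("  base learner CV accuracy:\n")
  for (l in x$learners)
    cat(sprintf("    %-13s %5.1f%%  (%s)\n", l$kind, 100 * l$cv_accuracy,
                paste(names(l$best), unlist(l$best), sep = "=", collapse = ", ")))
  cat("  meta-learner: gradient boosting,",
      paste(names(x$meta$best), unlist(x$meta$best), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @method summary raman_stack
#' @export
summary.raman_stack <- function(object, ...) {
  df <- data.frame(
    learner = c(vapply(object$learners, `[[`, character(1), "kind"), "stacked (GBM)"),
    cv_accuracy_pct = round(100 * c(vapply(object$learners, `[[`, numeric(1), "cv_accuracy"),
                                    max(object$meta$grid_accuracy, na.rm = TRUE)), 1),
    row.names = NULL)
  class(df) <- c("summary.raman_stack", "data.frame")
  df
}

# base-learner probabilities on new data, assembled in meta-feature layout
stack_meta_row <- function(object, x) {
  cols <- lapply(object$learners, function(l) {
    spec_fns <- if (!is.null(object$spec_fns)) object$spec_fns[[l$kind]] else
      base_learner_specs()[[l$kind]]
    p <- spec_fns$prob(l$model, x, object$class_order)
    if (object$meta_mode == "label") {
      hard <- matrix(0, nrow(p), ncol(p), dimnames = dimnames(p))
      hard[cbind(seq_len(nrow(p)), max.col(p, ties.method = "first"))] <- 1
      p <- hard
    }
    colnames(p) <- paste(l$kind, object$class_order, sep = ".")
    p
  })
  do.call(cbind, cols)
}

#' Predict cell stages with a stacked model
#'
#' Base learners produce class probabilities for each spectrum, the
#' meta-learner combines them; ties are broken by the bundle's recorded
#' class order.
#'
#' @param object a fitted [fit_stacked()] model.
#' @param newdata matrix or [raman_spectra], preprocessed identically to the
#'   training data.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... unused.
#' @return label vector, or probability matrix for `type = "prob"`.
#' @export
predict.raman_stack <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "raman_spectra")) newdata <- newdata$intensity
  newdata <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1L) else as.matrix(newdata)
  if (ncol(newdata) != object$n_channels)
    stop("channel count ", ncol(newdata), " does not match the model (",
         object$n_channels, ")")
  meta <- stack_meta_row(object, newdata)
  p <- stats::predict(object$meta$model, meta)
  p <- matrix(as.numeric(p), ncol = length(object$class_order), byrow = !is.matrix(p))
  colnames(p) <- object$class_order
  if (type == "prob") p else object$class_order[max.col(p, ties.method = "first")]
}

#' Evaluate a fitted model on a labelled test set
#'
#' @param object a fitted model with a `predict` method returning labels.
#' @param test a labelled [raman_spectra] test set.
#' @param ... passed to methods.
#' @return an [evaluation_report()].
#' @export
evaluate <- function(object, test, ...) UseMethod("evaluate")

#' @export
evaluate.raman_stack <- function(object, test, ...) {
  stopifnot(inherits(test, "raman_spectra"))
  if (any(is.na(test$meta$label))) stop("test set must be fully labelled")
  pred <- stats::predict(object, test)
  evaluation_report(pred, test$meta$label, class_order = object$class_order,
                    provenance = list(
                      cv = unclass(object$cv), meta_mode = object$meta_mode,
                      n_train = object$n_train,
                      tuned = lapply(object$learners, function(l) as.list(l$best)),
                      gbm = as.list(object$meta$best)))
}
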