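# Base learner registry for the two-layer stacked classifier.
#
# Each learner exposes: fit(x, y, params, seed) -> model,
# prob(model, x) -> class-probability matrix, and optionally
# cv_accuracy(x, y, folds, grid, seed) overriding the generic grid loop
# (used by PLS-DA, where one fit yields predictions at every component
# count, and by the SVMs, which tune on hard labels without Platt scaling).
# Probability columns are always reordered to the fixed class order.

channel_colnames <- function(x) {
  colnames(x) <- paste0("w", seq_len(ncol(x)))
  x
}

softmax_rows <- function(s) {
  s <- s - apply(s, 1L, max)
  e <- exp(s)
  e / rowSums(e)
}

order_probs <- function(p, class_order) {
  missing <- setdiff(class_order, colnames(p))
  if (length(missing)) {
    add <- matrix(0, nrow(p), length(missing), dimnames = list(NULL, missing))
    p <- cbind(p, add)
  }
  p[, class_order, drop = FALSE]
}

learner_knn <- function(grid) {
  list(kind = "knn", grid = grid,
       fit = function(x, y, params, seed) caret::knn3(x, factor(y), k = params$k),
       prob = function(model, x, class_order)
         order_probs(stats::predict(model, x, type = "prob"), class_order))
}

learner_lda <- function(grid) {
  list(kind = "lda", grid = grid,
       fit = function(x, y, params, seed)
         fit_lda(x, y, pca_variance_target = params$variance_target),
       prob = function(model, x, class_order)
         order_probs(stats::predict(model, x, type = "prob"), class_order))
}

learner_pls_da <- function(grid) {
  list(kind = "pls_da", grid = grid,
       fit = function(x, y, params, seed)
         mixOmics::plsda(channel_colnames(x), factor(y), ncomp = params$ncomp),
       prob = function(model, x, class_order) {
         pr <- stats::predict(model, channel_colnames(x))$predict
         s <- pr[, , dim(pr)[3], drop = FALSE][, , 1, drop = TRUE]
         if (is.null(dim(s))) s <- matrix(s, nrow = 1L, dimnames = list(NULL, dimnames(pr)[[2]]))
         order_probs(softmax_rows(s), class_order)
       },
       # one fit per fold gives predictions at every ncomp
       cv_accuracy = function(x, y, folds, grid, seed) {
         ncmax <- max(grid$ncomp)
         acc <- matrix(NA_real_, length(folds), nrow(grid))
         for (f in seq_along(folds)) {
           idx <- folds[[f]]
           m <- mixOmics::plsda(channel_colnames(x[-idx, , drop = FALSE]),
                                factor(y[-idx]), ncomp = ncmax)
           pr <- stats::predict(m, channel_colnames(x[idx, , drop = FALSE]))$predict
           lev <- dimnames(pr)[[2]]
           for (g in seq_len(nrow(grid))) {
             s <- pr[, , grid$ncomp[g]]
             if (is.null(dim(s))) s <- matrix(s, nrow = 1L)
             pred <- lev[max.col(s, ties.method = "first")]
             acc[f, g] <- mean(pred == y[idx])
           }
         }
         colMeans(acc)
       })
}

learner_svm <- function(kind, grid, probability = c("softmax", "platt")) {
  kernel <- if (kind == "svm_linear") "linear" else "radial"
  probability <- match.arg(probability)
  platt <- probability == "platt"
  # channels are standardized with training statistics (an sd floor guards
  # near-constant channels); the cost grid assumes unit-variance inputs
  fit1 <- function(x, y, params, seed, want_prob) {
    ctr <- colMeans(x)
    scl <- sqrt(colMeans(sweep(x, 2L, ctr)^2))
    scl <- pmax(scl, 1e-12 * max(scl, 1))
    xs <- sweep(sweep(x, 2L, ctr), 2L, scl, `/`)
    set.seed(seed)   # Platt scaling uses internal CV
    gamma <- if (kernel == "radial") params$gamma else 1 / ncol(x)
    m <- e1071::svm(xs, factor(y), kernel = kernel, cost = params$cost,
                    gamma = gamma, probability = want_prob && platt,
                    scale = FALSE)
    list(svm = m, ctr = ctr, scl = scl)
  }
  std <- function(model, x) sweep(sweep(x, 2L, model$ctr), 2L, model$scl, `/`)
  # class scores from the pairwise decision values: each "A/B" margin counts
  # for A and against B; softmax maps the sums to probabilities. Avoids the
  # costly and small-sample-fragile Platt internal CV.
  dv_prob <- function(model, x, class_order) {
    pr <- stats::predict(model$svm, std(model, x), decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    s <- matrix(0, nrow(dv), length(class_order),
                dimnames = list(NULL, class_order))
    for (j in seq_len(ncol(dv))) {
      cls <- strsplit(colnames(dv)[j], "/", fixed = TRUE)[[1]]
      s[, cls[1]] <- s[, cls[1]] + dv[, j]
      s[, cls[2]] <- s[, cls[2]] - dv[, j]
    }
    softmax_rows(s)
  }
  list(kind = kind, grid = grid,
       fit = function(x, y, params, seed) fit1(x, y, params, seed, TRUE),
       prob = function(model, x, class_order) {
         if (platt) {
           p <- attr(stats::predict(model$svm, std(model, x), probability = TRUE),
                     "probabilities")
           order_probs(p, class_order)
         } else dv_prob(model, x, class_order)
       },
       # decision-value class prediction; Platt probabilities are unstable on
       # small separable folds, the margin rule is not
       predict_class = function(model, x)
         as.character(stats::predict(model$svm, std(model, x))),
       # tune on hard labels: skips the costly Platt-scaling fits
       cv_accuracy = function(x, y, folds, grid, seed) {
         acc <- matrix(NA_real_, length(folds), nrow(grid))
         for (f in seq_along(folds)) {
           idx <- folds[[f]]
           for (g in seq_len(nrow(grid))) {
             m <- fit1(x[-idx, , drop = FALSE], y[-idx], grid[g, , drop = FALSE],
                       seed + f, FALSE)
             pred <- as.character(stats::predict(m$svm, std(m, x[idx, , drop = FALSE])))
             acc[f, g] <- mean(pred == y[idx])
           }
         }
         colMeans(acc)
       })
}

learner_random_forest <- function(grid) {
  list(kind = "random_forest", grid = grid,
       fit = function(x, y, params, seed) {
         mtry <- if (params$mtry_rule == "sqrt") floor(sqrt(ncol(x))) else
           max(1L, floor(0.1 * ncol(x)))
         ranger::ranger(x = channel_colnames(x), y = factor(y),
                        num.trees = params$num_trees,
                        mtry = mtry, probability = TRUE, seed = seed,
                        num.threads = 1L)
       },
       prob = function(model, x, class_order)
         order_probs(stats::predict(model, channel_colnames(x),
                                    num.threads = 1L)$predictions, class_order))
}

#' Default base learner specifications
#'
#' The six first-layer learners of the stacked model with their default
#' hyperparameter grids: k-nearest neighbours (k in 3..11), PCA-LDA (99\%
#' variance), PLS-DA (2-20 components, one-hot response, argmax decision),
#' linear SVM (cost 0.01-10), RBF SVM (cost x gamma around the scale
#' heuristic 1 / (channels x mean variance)), and random forest (500 trees,
#' mtry sqrt or 10\% of channels). `reduced = TRUE` collapses every grid to a
#' single sensible point, for quick runs where tuning is not the question.
#'
#' @param reduced logical; use single-point grids.
#' @param svm_probability `"softmax"` (default) maps pairwise decision
#'   values to class probabilities; `"platt"` uses libsvm's internal
#'   cross-validated Platt scaling (slower, and noisy on small separable
#'   folds).
#' @return named list of learner specs (class `base_learner_specs`).
#' @export
base_learner_specs <- function(reduced = FALSE,
                               svm_probability = c("softmax", "platt")) {
  svm_probability <- match.arg(svm_probability)
  if (reduced) {
    specs <- list(
      knn = learner_knn(data.frame(k = 7L)),
      lda = learner_lda(data.frame(variance_target = 0.99)),
      pls_da = learner_pls_da(data.frame(ncomp = 10L)),
      svm_linear = learner_svm("svm_linear", data.frame(cost = 1),
                               svm_probability),
      svm_rbf = learner_svm("svm_rbf", data.frame(cost = 10, gamma = NA_real_),
                            svm_probability),
      random_forest = learner_random_forest(
        data.frame(num_trees = 500L, mtry_rule = "sqrt", stringsAsFactors = FALSE)))
  } else {
    specs <- list(
      knn = learner_knn(data.frame(k = c(3L, 5L, 7L, 9L, 11L))),
      lda = learner_lda(data.frame(variance_target = 0.99)),
      pls_da = learner_pls_da(data.frame(ncomp = 2:20)),
      svm_linear = learner_svm("svm_linear", data.frame(cost = c(0.01, 0.1, 1, 10)),
                               svm_probability),
      svm_rbf = learner_svm("svm_rbf",
        expand.grid(cost = c(0.1, 1, 10), gamma = NA_real_,
                    gamma_mult = c(0.1, 1, 10)), svm_probability),
      random_forest = learner_random_forest(
        expand.grid(num_trees = 500L, mtry_rule = c("sqrt", "frac10"),
                    stringsAsFactors = FALSE)))
  }
  class(specs) <- "base_learner_specs"
  specs
}

# resolve data-dependent grid entries (RBF gamma scale heuristic)
resolve_grid <- function(spec, x) {
  g <- spec$grid
  if (spec$kind == "svm_rbf") {
    gamma0 <- 1 / ncol(x)     # scale heuristic on standardized channels
    mult <- if ("gamma_mult" %in% names(g)) g$gamma_mult else 1
    g$gamma <- gamma0 * mult
    g$gamma_mult <- NULL
  }
  g
}
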