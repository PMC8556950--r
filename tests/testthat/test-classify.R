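make_labelled_set <- function(n_per_class = 8, seed = 1, dim = 30, sep = 8) {
  sep_d <- separable_classes(n_per_class, dim, sep, seed)
  raman_spectra(seq_len(dim) * 10 + 290, sep_d$x,
                data.frame(spectrum_id = sprintf("s%03d", seq_along(sep_d$y)),
                           label = sep_d$y))
}

test_that("train/test splitting follows the 75/25 rounding rules and the seed", {
  # unstratified split of 1850 spectra leaves round(0.25 * 1850) = 462 test
  set <- make_labelled_set(n_per_class = 10)
  lab <- rep(c("P1", "P4", "PHH"), times = c(624, 606, 620))
  big <- raman_spectra(c(400, 500), matrix(rnorm(2 * 1850), ncol = 2),
                       data.frame(spectrum_id = sprintf("s%04d", 1:1850),
                                  label = lab))
  sp <- split_train_test(big, stratified = FALSE, seed = 3)
  expect_equal(n_spectra(sp$test), 462L)
  expect_equal(n_spectra(sp$train), 1388L)
  expect_equal(sort(c(sp$train$meta$spectrum_id, sp$test$meta$spectrum_id)),
               big$meta$spectrum_id)
  # stratified: exactly 25% of each class
  even <- raman_spectra(c(400, 500), matrix(rnorm(2 * 1800), ncol = 2),
                        data.frame(spectrum_id = sprintf("e%04d", 1:1800),
                                   label = rep(c("P1", "P4", "PHH"), each = 600)))
  spe <- split_train_test(even, seed = 5)
  expect_equal(as.vector(table(spe$test$meta$label)), rep(150L, 3))
  # determinism
  spe2 <- split_train_test(even, seed = 5)
  expect_identical(spe$test$meta$spectrum_id, spe2$test$meta$spectrum_id)
  expect_error(split_train_test(set, train_fraction = 0.99), "absent")
})

test_that("out-of-fold meta-features have the contracted layout and are probabilities", {
  set <- make_labelled_set(n_per_class = 10, seed = 2)
  cv <- cv_spec(folds = 3, repeats = 2, seed = 2)
  base <- fit_base_learners(set, cv = cv, specs = base_learner_specs(reduced = TRUE))
  mf <- base$meta_features
  expect_equal(dim(mf), c(30L, 6L * 3L))
  expect_identical(base$class_order, c("A", "B", "C"))
  # per-learner probability rows sum to 1
  for (kind in names(base$learners)) {
    block <- mf[, paste(kind, base$class_order, sep = ".")]
    expect_equal(rowSums(block), rep(1, 30), tolerance = 1e-6, ignore_attr = TRUE)
  }
  expect_error(fit_base_learners(set, cv = cv_spec(folds = 20, seed = 1)),
               "fold count")
})

test_that("every base learner exceeds 95% CV accuracy on well-separated classes", {
  set <- make_labelled_set(n_per_class = 15, seed = 3, sep = 10)
  base <- fit_base_learners(set, cv = cv_spec(folds = 3, repeats = 1, seed = 3),
                            specs = base_learner_specs(reduced = TRUE))
  for (l in base$learners)
    expect_gt(l$cv_accuracy, 0.95, label = paste(l$kind, "cv accuracy"))
})

test_that("stacking does not fall below a perfect base learner", {
  set.seed(4)
  n <- 60
  y <- rep(c("A", "B", "C"), each = n / 3)
  # one perfect predictor block + two noise learners
  perfect <- matrix(0, n, 3, dimnames = list(NULL, c("A", "B", "C")))
  perfect[cbind(seq_len(n), match(y, c("A", "B", "C")))] <- 1
  noise <- matrix(runif(n * 3), n); noise <- noise / rowSums(noise)
  meta <- cbind(perfect, noise, noise)
  colnames(meta) <- paste(rep(c("knn", "lda", "pls_da"), each = 3),
                          c("A", "B", "C"), sep = ".")
  fitm <- ramanstage:::fit_gbm_meta(meta, y, c("A", "B", "C"),
                                    cv_spec(folds = 3, repeats = 1, seed = 4),
                                    grid = expand.grid(nrounds = 50L, max_depth = 2L))
  p <- predict(fitm$model, meta)
  p <- matrix(as.numeric(p), ncol = 3, byrow = !is.matrix(p))
  acc <- mean(c("A", "B", "C")[max.col(p)] == y)
  expect_gte(acc, 0.99)
})

test_that("the stacked model is deterministic and predicts single spectra", {
  set <- make_labelled_set(n_per_class = 10, seed = 5)
  cv <- cv_spec(folds = 3, repeats = 1, seed = 5)
  gg <- expand.grid(nrounds = 50L, max_depth = 1:2)
  m1 <- fit_stacked(set, cv = cv, specs = base_learner_specs(reduced = TRUE),
                    gbm_grid = gg)
  m2 <- fit_stacked(set, cv = cv, specs = base_learner_specs(reduced = TRUE),
                    gbm_grid = gg)
  expect_identical(m1$meta_features, m2$meta_features)
  expect_identical(lapply(m1$learners, `[[`, "best"),
                   lapply(m2$learners, `[[`, "best"))
  expect_identical(m1$meta$best, m2$meta$best)
  expect_identical(predict(m1, set), predict(m2, set))
  # training a perfectly separable problem predicts its training set exactly
  expect_equal(mean(predict(m1, set) == set$meta$label), 1)
  one <- predict(m1, set[3])
  expect_length(one, 1L)
  expect_identical(one, set$meta$label[3])
  expect_error(predict(m1, set$intensity[, 1:10]), "channel count")
})

test_that("confusion matrices follow the prediction-by-reference convention", {
  pred <- c("P1", "P1", "P4", "PHH"); ref <- c("P1", "P4", "P4", "PHH")
  m <- confusion(pred, ref)
  expect_equal(m["P1", "P4"], 1L)
  expect_equal(sum(m), 4L)
  expect_equal(sum(diag(m)), 3L)
  expect_error(confusion(character(0), character(0)), "empty")
  expect_error(confusion("A", "B", class_order = "A"), "outside")
  # published counts: column totals and grand total
  t2 <- make_table2_fixture()$confusion
  expect_equal(as.vector(colSums(t2)), c(156L, 151L, 155L))
  expect_equal(sum(t2), 462L)
})

test_that("sensitivity, specificity and accuracy reproduce hand-computed values", {
  m <- matrix(c(8L, 2L, 2L, 8L), 2, byrow = TRUE,
              dimnames = list(predicted = c("x", "y"), reference = c("x", "y")))
  expect_equal(sensitivity(m, "x"), 80.0)
  expect_equal(specificity(m, "x"), 80.0)
  expect_equal(overall_accuracy(m), 80.0)
  id <- diag(5L); dimnames(id) <- list(predicted = letters[1:5], reference = letters[1:5])
  for (k in letters[1:5]) {
    expect_equal(sensitivity(id, k), 100.0)
    expect_equal(specificity(id, k), 100.0)
  }
  expect_equal(overall_accuracy(matrix(1L, 3, 3,
    dimnames = list(predicted = 1:3, reference = 1:3))), 33.3)
  expect_error(overall_accuracy(matrix(0L, 2, 2)), "empty")
})

test_that("evaluation reports are internally consistent", {
  rep <- make_table2_fixture()
  m <- rep$confusion
  for (k in colnames(m)) {
    expect_equal(rep$sensitivity[[k]], sensitivity(m, k))
    expect_equal(rep$specificity[[k]], specificity(m, k))
  }
  expect_equal(rep$overall_accuracy, overall_accuracy(m))
  expect_equal(rep$n_test, sum(m))
  # single-class reference: sensitivity defined, specificity is not
  one <- confusion(c("A", "A"), c("A", "A"), class_order = "A")
  expect_equal(sensitivity(one, "A"), 100.0)
  expect_error(specificity(one, "A"), "negative")
})

test_that("sampling location does not sway the model when it carries no signal", {
  # center-only vs periphery-only training on data whose location flag is
  # pure metadata; test accuracies agree within 5 percentage points
  gen <- generate_dataset(synthetic_config(n_per_class = 60, seed = 29))
  clean <- preprocess(gen$spectra)
  sp <- split_train_test(clean, seed = 29)
  cv <- cv_spec(folds = 3, repeats = 1, seed = 29)
  gg <- expand.grid(nrounds = 50L, max_depth = 2L)
  accs <- vapply(c("center", "periphery"), function(loc) {
    sub <- sp$train[sp$train$meta$location == loc]
    m <- fit_stacked(sub, cv = cv, specs = base_learner_specs(reduced = TRUE),
                     gbm_grid = gg)
    mean(predict(m, sp$test) == sp$test$meta$label)
  }, numeric(1))
  expect_lt(abs(accs["center"] - accs["periphery"]), 0.05)
})
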