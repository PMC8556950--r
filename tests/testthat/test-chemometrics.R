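test_that("PCA recovers planar data and matches a brute-force eigendecomposition", {
  set.seed(2)
  # rank-2 data in 6-D
  basis <- qr.Q(qr(matrix(rnorm(12), 6, 2)))
  x <- matrix(rnorm(40), 20, 2) %*% t(basis)
  p <- fit_pca(x, k = 2)
  expect_equal(sum(p$explained), 1, tolerance = 1e-9)
  # reconstruction of rank-k data with k components
  sc <- project(p, x)
  rec <- sweep(sc %*% p$loadings, 2L, p$mean, `+`)
  expect_lt(max(abs(rec - x)), 1e-8)
  # eigenvalue oracle on a tiny 5 x 4 instance
  y <- matrix(rnorm(20), 5, 4)
  p2 <- fit_pca(y)
  ev <- sort(eigen(stats::cov(y), symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(p2$sdev^2, ev[seq_along(p2$sdev)], tolerance = 1e-9)
  expect_equal(sum(p2$all_explained), 1, tolerance = 1e-12)
  expect_error(fit_pca(y, k = 10), "exceeds")
})

test_that("PCA scores are centered and uncorrelated; loadings orthonormal", {
  set.seed(3)
  x <- matrix(rnorm(300), 30, 10)
  p <- fit_pca(x, k = 5)
  expect_equal(p$loadings %*% t(p$loadings), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  sc <- project(p, x)
  expect_lt(max(abs(colMeans(sc))), 1e-10)
  cv <- stats::cov(sc)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  # the model mean projects to the origin
  expect_lt(max(abs(project(p, p$mean))), 1e-10)
})

test_that("the two-class Fisher direction matches the closed-form oracle", {
  set.seed(5)
  # tiny 6-sample, 3-feature, 2-class instance
  x <- rbind(matrix(rnorm(9), 3, 3), sweep(matrix(rnorm(9), 3, 3), 2L, c(3, 1, -2), `+`))
  y <- rep(c("a", "b"), each = 3)
  m <- fit_lda(x, y, pca_variance_target = 1)
  # brute force: w = Sw^-1 (mu1 - mu2) in raw feature space
  mu1 <- colMeans(x[1:3, ]); mu2 <- colMeans(x[4:6, ])
  Sw <- crossprod(sweep(x[1:3, ], 2L, mu1)) + crossprod(sweep(x[4:6, ], 2L, mu2))
  w <- solve(Sw, mu1 - mu2)
  cosine <- abs(sum(w * m$directions[1, ])) /
    sqrt(sum(w^2) * sum(m$directions[1, ]^2))
  expect_gte(cosine, 0.999)
  expect_equal(nrow(m$directions), 1L)         # 2 classes -> 1 axis
})

test_that("LDA respects the axis bound and separates well-separated classes", {
  sep <- separable_classes(n_per_class = 50, dim = 10, sep = 10, seed = 6)
  m <- fit_lda(sep$x, sep$y)
  expect_lte(nrow(m$directions), 2L)           # 3 classes -> <= 2 axes
  expect_equal(sqrt(rowSums(m$directions^2)), rep(1, nrow(m$directions)),
               tolerance = 1e-9, ignore_attr = TRUE)
  # nearest class mean in LD space classifies the training data perfectly
  pred <- predict(m, sep$x, type = "class")
  expect_equal(mean(pred == sep$y), 1)
  # projecting the class means lands on the mean of projected scores
  sc <- project(m, sep$x)
  for (g in unique(sep$y)) {
    mu_g <- colMeans(sep$x[sep$y == g, ])
    expect_equal(drop(project(m, mu_g)), colMeans(sc[sep$y == g, , drop = FALSE]),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  expect_error(fit_lda(sep$x[1:3, ], c("a", "a", "b")), "at least 2 spectra")
  expect_error(project(m, sep$x[, 1:5]), "does not match")
})

test_that("top-loading extraction counts, sorts and ties deterministically", {
  sep <- separable_classes(n_per_class = 10, dim = 8, sep = 6, seed = 7)
  m <- fit_lda(sep$x, sep$y)
  wn <- seq(300, 1000, length.out = 8)
  expect_length(top_loading_wavenumbers(m, wn, 1, fraction = 1), 8L)
  expect_length(top_loading_wavenumbers(m, wn, 1, fraction = 0.25), 2L)
  top <- top_loading_wavenumbers(m, wn, 1, fraction = 0.5)
  w <- abs(m$directions[1, ])
  expect_equal(w[match(top, wn)], sort(w, decreasing = TRUE)[1:4],
               ignore_attr = TRUE)
  expect_error(top_loading_wavenumbers(m, wn, 1, fraction = 0), "fraction")
  expect_error(top_loading_wavenumbers(m, wn, 5), "no such")
  # ceiling rule at spectrum scale: 10% of 1501 channels = 151
  expect_equal(ceiling(0.10 * 1501), 151)
})

test_that("discriminant weight concentrates on the separating bands", {
  # classes differing only at the 1003 and 1440 bands
  x <- seq(300, 1800)
  sigma <- 15 / (2 * sqrt(2 * log(2)))
  base <- exp(-0.5 * ((x - 700) / sigma)^2)
  set.seed(8)
  mk <- function(a1003, a1440, n)
    t(replicate(n, base + a1003 * exp(-0.5 * ((x - 1003) / sigma)^2) +
                   a1440 * exp(-0.5 * ((x - 1440) / sigma)^2) +
                   rnorm(length(x), 0, 0.02)))
  mat <- rbind(mk(1, 0.3, 20), mk(0.3, 1, 20))
  y <- rep(c("hi1003", "hi1440"), each = 20)
  m <- fit_lda(mat, y)
  top <- top_loading_wavenumbers(m, x, 1, fraction = 0.10)
  expect_true(any(top >= 993 & top <= 1013))
  expect_true(any(top >= 1430 & top <= 1450))
})

test_that("projection-based class separation holds on synthetic spectra", {
  d <- small_dataset(n_per_class = 40, seed = 23)
  clean <- preprocess(d$spectra)
  # 5-fold cross-validated nearest-class-mean accuracy in LD space
  folds <- rep_len(1:5, n_spectra(clean))
  set.seed(23)
  folds <- sample(folds)
  acc <- vapply(1:5, function(f) {
    tr <- clean[folds != f]; te <- clean[folds == f]
    m <- fit_lda(tr)
    mean(predict(m, te, type = "class") == te$meta$label)
  }, numeric(1))
  expect_gt(mean(acc), 0.90)
})
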