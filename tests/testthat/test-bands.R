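test_that("the default band set matches the reported windows", {
  b <- default_bands()
  expect_equal(nrow(b), 13L)
  expect_equal(unlist(b[b$name == "840-860", c("lo", "hi")]), c(lo = 840, hi = 860))
  expect_equal(unlist(b[b$name == "1003", c("lo", "hi")]), c(lo = 993, hi = 1013))
  expect_equal(unlist(b[b$name == "831", c("lo", "hi")]), c(lo = 821, hi = 839))
  expect_true(all(b$lo < b$hi))
  # windows never overlap
  ord <- order(b$lo)
  expect_true(all(b$hi[ord][-13] <= b$lo[ord][-1]))
})

test_that("band integration matches closed forms and respects the axis", {
  x <- seq(300, 1800)
  const <- raman_spectra(x, rep(1, length(x)))
  expect_equal(integrate_band(const, 840, 860), 20, tolerance = 1e-12,
               ignore_attr = TRUE)
  # unit-area Gaussian at 1003, fwhm 15: the +/-10 window holds the
  # central normal mass 2*pnorm(10/sigma) - 1
  sigma <- 15 / (2 * sqrt(2 * log(2)))
  g <- raman_spectra(x, stats::dnorm(x, 1003, sigma))
  expect_equal(integrate_band(g, 993, 1013), 2 * stats::pnorm(10 / sigma) - 1,
               tolerance = 5e-3, ignore_attr = TRUE)
  expect_error(integrate_band(const, 200, 250), "outside")
})

test_that("band areas are additive over abutting windows and scale-equivariant", {
  d <- small_dataset(n_per_class = 2, seed = 8)
  set <- d$spectra
  ab <- integrate_band(set, 900, 950)
  bc <- integrate_band(set, 950, 1000)
  ac <- integrate_band(set, 900, 1000)
  expect_equal(ab + bc, ac, tolerance = 1e-9)
  doubled <- set; doubled$intensity <- doubled$intensity * 2
  expect_equal(integrate_band(doubled, 900, 1000), 2 * ac, tolerance = 1e-12)
})

test_that("band tables count groups correctly and flag unlabelled spectra", {
  d <- small_dataset(n_per_class = 4, seed = 9)
  clean <- preprocess(d$spectra)
  bt <- band_table(clean)
  expect_equal(dim(bt$medians), c(3L, 14L))           # group column + 13 bands
  expect_equal(nrow(bt$areas), 12L)
  part <- clean
  part$meta$label[1] <- NA
  expect_warning(bt2 <- band_table(part), "unlabelled")
  expect_equal(nrow(bt2$areas), 11L)
  # identical spectra give identical group medians
  same <- raman_spectra(clean$wavenumber,
                        clean$intensity[rep(1, 6), ],
                        data.frame(spectrum_id = sprintf("r%d", 1:6),
                                   label = rep(c("A", "B", "C"), each = 2)))
  bts <- band_table(same)
  expect_equal(bts$medians[["1003"]], rep(bts$medians[["1003"]][1], 3))
})

test_that("group comparison uses the pooled t-test with star annotation", {
  # identical groups: t = 0, p = 1, ns
  x <- seq(300, 1800)
  set <- raman_spectra(x, matrix(rep(stats::dnorm(x, 1003, 6), 4), 4, byrow = TRUE),
                       data.frame(spectrum_id = sprintf("s%d", 1:4),
                                  label = c("A", "A", "B", "B")))
  bt <- band_table(set)
  cmp <- compare_groups(bt, "A", "B")
  expect_equal(cmp$t, rep(0, 13))
  expect_equal(cmp$p, rep(1, 13))
  expect_equal(cmp$star, rep("ns", 13))
  expect_error(compare_groups(bt, "A", "Z"), "not present")
  # 5-sigma separated normals: essentially certain significance
  set.seed(4)
  a <- rnorm(50, 0); b <- rnorm(50, 5)
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_identical(star_annotation(tt$p.value), "****")
})

test_that("star annotation respects the published thresholds and boundaries", {
  expect_identical(star_annotation(c(0.03, 0.0005, 0.05, 0.2, 0.009, 5e-5)),
                   c("*", "***", "ns", "ns", "**", "****"))
})

test_that("synthetic group medians reproduce the encoded decreasing lipid trend", {
  d <- small_dataset(n_per_class = 15, seed = 19)
  clean <- preprocess(d$spectra)
  bt <- band_table(clean)
  med <- function(g, b) bt$medians[[b]][bt$medians$group == g]
  expect_gt(med("PHH", "1440"), med("P4", "1440"))
  expect_lt(med("PHH", "1003"), med("P4", "1003"))
})
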