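# Shared fixtures, generated in code and cached for the session.

# small labelled synthetic data set with defaults apart from size
small_dataset <- local({
  cache <- NULL
  function(n_per_class = 20, seed = 42, ...) {
    key <- paste(n_per_class, seed, ...)
    if (!is.null(cache) && identical(cache$key, key)) return(cache$value)
    value <- generate_dataset(synthetic_config(n_per_class = n_per_class,
                                               seed = seed, ...))
    cache <<- list(key = key, value = value)
    value
  }
})

# noise-free single-peak configuration for closed-form checks
single_peak_config <- function(amplitude = 2, center = 1003, fwhm = 15,
                               cv = 0) {
  prof <- structure(list(label = "X",
                         amplitudes = stats::setNames(amplitude, center),
                         amplitude_cv = cv), class = "class_profile")
  synthetic_config(n_per_class = 1, profiles = list(X = prof), fwhm = fwhm,
                   baseline_scale = 0, noise_sd = 0, spike_rate = 0, seed = 1)
}

# three well-separated spherical Gaussian classes in modest dimension,
# for classifier checks that do not need full spectra; class means lie on
# random directions (pairwise distance ~ sep noise s.d.)
separable_classes <- function(n_per_class = 20, dim = 10, sep = 10, seed = 1) {
  set.seed(seed)
  ang <- matrix(rnorm(3 * dim), 3)
  ang <- ang / sqrt(rowSums(ang^2))
  mu <- ang * sep / sqrt(2)
  x <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(n_per_class * dim), n_per_class), 2L, mu[k, ], `+`)))
  list(x = x, y = rep(c("A", "B", "C"), each = n_per_class))
}
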