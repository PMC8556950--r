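#' Preprocessing configuration
#'
#' Parameters of the fixed normalization chain applied to every spectrum:
#' resample -> despike -> baseline correction -> area normalization.
#'
#' Defaults: despiking by modified z-score of first differences with
#' threshold 8 and a 5-channel maximum artifact width (cosmic rays span 1-2
#' channels; genuine Raman bands are much wider); asymmetric least squares
#' (Whittaker) baseline with smoothness `lambda = 1e5`, asymmetry `p = 0.01`,
#' 10 reweighting passes; total trapezoid area normalized to 1 so band areas
#' read as dimensionless fractions of total scattering.
#'
#' @param despike_threshold modified z-score cutoff (> 0).
#' @param despike_window maximum width (channels) of a run flagged as a
#'   cosmic-ray artifact.
#' @param baseline_method `"als"` (asymmetric least squares, default) or
#'   `"poly"` (iterative polynomial fitting behind the same interface).
#' @param baseline_lambda ALS smoothness weight.
#' @param baseline_p ALS asymmetry weight, in (0, 1).
#' @param baseline_iters reweighting iterations (>= 1).
#' @param baseline_offset correct the downward noise offset of the raw
#'   asymmetric smoother (which tracks the lower noise envelope, roughly
#'   1.3 noise s.d. below the true background) by adding back the mean
#'   residual over non-peak channels. `TRUE` (default) gives an unbiased
#'   background estimate; `FALSE` keeps the classic lower-envelope
#'   behaviour.
#' @param poly_degree degree for `baseline_method = "poly"`.
#' @param target_axis optional `c(start, stop, step)` in cm^-1 to resample
#'   onto before anything else; `NULL` keeps the native axis.
#' @param normalization_area target trapezoid integral (> 0).
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(despike_threshold = 8, despike_window = 5L,
                              baseline_method = c("als", "poly"),
                              baseline_lambda = 1e5, baseline_p = 0.01,
                              baseline_iters = 10L, baseline_offset = TRUE,
                              poly_degree = 5L,
                              target_axis = NULL, normalization_area = 1) {
  baseline_method <- match.arg(baseline_method)
  stopifnot(despike_threshold > 0, despike_window >= 1,
            baseline_p > 0, baseline_p < 1, baseline_iters >= 1,
            normalization_area > 0)
  structure(list(despike_threshold = despike_threshold,
                 despike_window = as.integer(despike_window),
                 baseline_method = baseline_method,
                 baseline_lambda = baseline_lambda, baseline_p = baseline_p,
                 baseline_iters = as.integer(baseline_iters),
                 baseline_offset = isTRUE(baseline_offset),
                 poly_degree = as.integer(poly_degree),
                 target_axis = target_axis,
                 normalization_area = normalization_area),
            class = "preprocess_config")
}

#' Resample spectra onto a target axis
#'
#' Linear interpolation onto a new wavenumber grid; no extrapolation is ever
#' performed, so the target must lie inside the source range. Metadata are
#' preserved.
#'
#' @param set a [raman_spectra] object.
#' @param target_axis either a numeric axis vector or `c(start, stop, step)`.
#' @return a [raman_spectra] on the target axis.
#' @export
resample <- function(set, target_axis) {
  stopifnot(inherits(set, "raman_spectra"))
  ta <- if (length(target_axis) == 3L && target_axis[1] < target_axis[2] &&
            target_axis[3] > 0 && target_axis[3] < diff(range(target_axis[1:2])))
    seq(target_axis[1], target_axis[2], by = target_axis[3]) else as.numeric(target_axis)
  if (min(ta) < min(set$wavenumber) || max(ta) > max(set$wavenumber))
    stop("target axis [", min(ta), ", ", max(ta),
         "] extends beyond the spectrum range [", min(set$wavenumber), ", ",
         max(set$wavenumber), "]; extrapolation is not supported")
  out <- t(apply(set$intensity, 1L, function(y)
    stats::approx(set$wavenumber, y, xout = ta)$y))
  if (length(ta) == 1L) out <- matrix(out, ncol = 1L)
  raman_spectra(ta, out, set$meta)
}

# modified z-score despiking of a single intensity vector.
# Candidate channels touch a first-difference whose modified z-score exceeds
# the threshold; candidate runs wider than max_width are kept (real spectral
# features produce long runs on noiseless flanks), narrow runs are replaced
# by linear interpolation across the run from the nearest clean neighbours.
despike_vector <- function(y, threshold, max_width) {
  n <- length(y)
  if (n < 5L) stop("despiking needs at least 5 channels")
  d <- diff(y)
  med <- stats::median(d)
  s <- stats::mad(d, constant = 1)                           # raw MAD
  if (s <= 0) s <- mean(abs(d - med))
  if (s <= 0) return(list(y = y, positions = integer(0)))    # constant-slope input
  z <- 0.6745 * (d - med) / s                                # modified z-score
  hit <- abs(z) > threshold                                  # hit[i] ~ diff y[i]->y[i+1]
  cand <- logical(n)
  cand[which(hit)] <- TRUE
  cand[which(hit) + 1L] <- TRUE
  if (!any(cand)) return(list(y = y, positions = integer(0)))
  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  flagged <- integer(0)
  out <- y
  for (k in which(r$values)) {
    a <- starts[k]; b <- ends[k]
    if (b - a + 1L > max_width) next                         # too wide: a real band edge
    lo <- a - 1L; hi <- b + 1L
    if (lo < 1L && hi > n) stop("all channels flagged; cannot despike")
    # interpolate across the run from the nearest clean neighbours
    if (lo < 1L) {
      interp <- rep(y[hi], b - a + 1L)
    } else if (hi > n) {
      interp <- rep(y[lo], b - a + 1L)
    } else {
      interp <- y[lo] + (y[hi] - y[lo]) * (seq(a, b) - lo) / (hi - lo)
    }
    resid <- y[a:b] - interp
    big <- 0.6745 * abs(resid) / s > threshold / 2           # keep only true outliers
    if (!any(big)) next
    idx <- (a:b)[big]
    out[idx] <- interp[big]
    flagged <- c(flagged, idx)
  }
  list(y = out, positions = sort(flagged))
}

#' Remove cosmic-ray spikes
#'
#' Flags channels whose first-difference modified z-score exceeds the
#' threshold, restricts flags to runs no wider than `despike_window` channels
#' (cosmic rays are 1-2 channels; genuine bands are wider) and replaces them
#' by linear interpolation of the nearest unflagged neighbours. Idempotent on
#' its own output for a fixed configuration.
#'
#' @param set a [raman_spectra] object.
#' @param config a [preprocess_config()].
#' @return the despiked [raman_spectra]; per-spectrum spike counts are added
#'   to `meta$n_spikes` and the flagged wavenumbers are attached as
#'   `attr(, "spike_positions")` (a list).
#' @export
despike <- function(set, config = preprocess_config()) {
  stopifnot(inherits(set, "raman_spectra"))
  res <- lapply(seq_len(n_spectra(set)), function(i)
    despike_vector(set$intensity[i, ], config$despike_threshold, config$despike_window))
  out <- set
  out$intensity <- do.call(rbind, lapply(res, `[[`, "y"))
  rownames(out$intensity) <- set$meta$spectrum_id
  out$meta$n_spikes <- vapply(res, function(r) length(r$positions), integer(1))
  attr(out, "spike_positions") <- lapply(res, function(r) set$wavenumber[r$positions])
  out
}

# Whittaker smoother with asymmetric weights (ALS baseline).
als_baseline_vector <- function(y, lambda, p, iters, offset = TRUE) {
  n <- length(y)
  D <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                          diagonals = list(rep(1, n - 2L), rep(-2, n - 2L), rep(1, n - 2L)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(iters)) {
    W <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(W + DtD, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (all(w_new == w) && it > 1L) break
    w <- w_new
  }
  # under additive noise the asymmetric weights settle the smoother on the
  # lower noise envelope, a constant downward offset; optionally shift back
  # by the mean residual over baseline (non-peak) channels
  if (offset) {
    r <- y - z
    sig <- sqrt(mean(r[r < 0]^2))            # half-normal noise estimate
    if (is.finite(sig) && sig > 0) {
      base_chan <- abs(r) < 3 * sig
      if (any(base_chan)) z <- z + mean(r[base_chan])
    }
  }
  z
}

# iterative polynomial (modified polyfit) baseline
poly_baseline_vector <- function(y, x, degree, iters) {
  tt <- (x - min(x)) / diff(range(x))
  yy <- y
  for (it in seq_len(max(iters, 2L))) {
    fit <- stats::lm.fit(outer(tt, 0:degree, `^`), yy)$fitted.values
    yy <- pmin(yy, fit)
  }
  fit
}

#' Estimate and subtract the fluorescence baseline
#'
#' Baseline estimated by asymmetric least squares: a Whittaker smoother whose
#' weights are `p` above the current estimate and `1 - p` below it, iterated,
#' which drives the smooth curve under the peaks while following the broad
#' fluorescence background. `corrected + baseline` reconstructs the input
#' exactly. Negative corrected intensities are retained (not clipped) so
#' later band integration stays unbiased.
#'
#' @param set a [raman_spectra] object with finite intensities.
#' @param config a [preprocess_config()].
#' @return the corrected [raman_spectra], with the estimated baseline matrix
#'   attached as `attr(, "baseline")`.
#' @export
baseline_correct <- function(set, config = preprocess_config()) {
  stopifnot(inherits(set, "raman_spectra"))
  bl <- t(apply(set$intensity, 1L, function(y)
    if (config$baseline_method == "als")
      als_baseline_vector(y, config$baseline_lambda, config$baseline_p,
                          config$baseline_iters, config$baseline_offset)
    else
      poly_baseline_vector(y, set$wavenumber, config$poly_degree, config$baseline_iters)))
  out <- set
  out$intensity <- set$intensity - bl
  rownames(out$intensity) <- set$meta$spectrum_id
  attr(out, "baseline") <- bl
  out
}

#' Normalize each spectrum to a fixed total area
#'
#' Scales every spectrum so its trapezoid integral over the axis equals
#' `normalization_area` (default 1, the probability-density convention:
#' band areas then read as fractions of total scattering). Shape-preserving
#' and scale-invariant.
#'
#' @param set a [raman_spectra] object.
#' @param normalization_area target integral (> 0).
#' @return the normalized [raman_spectra].
#' @export
area_normalize <- function(set, normalization_area = 1) {
  stopifnot(inherits(set, "raman_spectra"), normalization_area > 0)
  areas <- apply(set$intensity, 1L, function(y) pracma::trapz(set$wavenumber, y))
  if (any(areas <= 0))
    stop("nonpositive total area for spectrum ",
         paste(set$meta$spectrum_id[areas <= 0][1]), "; cannot area-normalize")
  out <- set
  out$intensity <- set$intensity * (normalization_area / areas)
  rownames(out$intensity) <- set$meta$spectrum_id
  out
}

#' Run the full preprocessing chain
#'
#' Applies, in this fixed order: optional resampling onto
#' `config$target_axis`, cosmic-ray despiking, baseline correction, and area
#' normalization. Per-spectrum spike counts are recorded in `meta$n_spikes`;
#' the spike positions and baseline matrix of the intermediate stages are
#' carried through as attributes.
#'
#' @param set a non-empty [raman_spectra] object.
#' @param config a [preprocess_config()].
#' @return the preprocessed [raman_spectra].
#' @export
preprocess <- function(set, config = preprocess_config()) {
  stopifnot(inherits(set, "raman_spectra"))
  if (n_spectra(set) == 0L) stop("empty spectra set")
  if (!is.null(config$target_axis)) set <- resample(set, config$target_axis)
  ds <- despike(set, config)
  bc <- baseline_correct(ds, config)
  out <- area_normalize(bc, config$normalization_area)
  out$meta$n_spikes <- ds$meta$n_spikes
  attr(out, "spike_positions") <- attr(ds, "spike_positions")
  attr(out, "baseline") <- attr(bc, "baseline")
  out
}
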