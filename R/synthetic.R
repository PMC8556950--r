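#' Default hepatocyte class profiles
#'
#' Relative band amplitudes for the three cell stages (PHH, ProliHHs P1,
#' ProliHHs P4) at the 13 fingerprint bands used throughout the package.
#' The encoded trends are the directions reported for dedifferentiating
#' hepatocytes: polysaccharide (840-860), phospholipid (1080), collagen/
#' alpha-helix (1265), lipid (1300, 1440, 1744) and amide I (1658) bands
#' decrease monotonically PHH > P1 > P4; phenylalanine (1003),
#' hydroxyproline (1206) and amide III (1337) increase PHH < P1 < P4;
#' glycogen (480) and tyrosine (831) drop from PHH to both ProliHHs stages;
#' the tyrosine C-H bend (1172) is flat between PHH and P1 and elevated at
#' P4. The adjacent-class amplitude ratio for monotone bands is 1.35, a
#' generator choice (not a measurement) large enough for trend recovery at
#' n = 100 spectra/class under 5\% multiplicative noise.
#'
#' @param ratio amplitude ratio between adjacent classes on trending bands.
#' @param amplitude_cv coefficient of variation of the per-cell lognormal
#'   amplitude jitter applied by the generator.
#' @return named list of three `class_profile` objects (`PHH`, `P1`, `P4`),
#'   each with fields `label`, `amplitudes` (named by peak center),
#'   `amplitude_cv`.
#' @export
default_profiles <- function(ratio = 1.35, amplitude_cv = 0.10) {
  stopifnot(ratio > 0, amplitude_cv >= 0)
  # mid-stage (P1) relative amplitudes; rough relative strengths of the 13
  # bands in a fixed-cell fingerprint spectrum
  base <- c(`480` = 0.5, `831` = 0.6, `850` = 0.8, `1003` = 1.5, `1080` = 0.9,
            `1172` = 0.5, `1206` = 0.6, `1265` = 0.8, `1300` = 1.0,
            `1337` = 0.9, `1440` = 1.2, `1658` = 1.3, `1744` = 0.4)
  dec <- c("850", "1080", "1265", "1300", "1440", "1658", "1744") # PHH > P1 > P4
  inc <- c("1003", "1206", "1337")                                # PHH < P1 < P4
  phh_high <- c("480", "831")                                     # PHH > (P1 ~ P4)
  p4_high <- "1172"                                               # (PHH ~ P1) < P4
  amp <- list(PHH = base, P1 = base, P4 = base)
  amp$PHH[dec] <- base[dec] * ratio
  amp$P4[dec] <- base[dec] / ratio
  amp$PHH[inc] <- base[inc] / ratio
  amp$P4[inc] <- base[inc] * ratio
  amp$PHH[phh_high] <- base[phh_high] * ratio
  amp$P4[p4_high] <- base[p4_high] * ratio
  lapply(stats::setNames(names(amp), names(amp)), function(lb)
    structure(list(label = lb, amplitudes = amp[[lb]], amplitude_cv = amplitude_cv),
              class = "class_profile"))
}

#' Synthetic acquisition configuration
#'
#' Bundles every knob of the synthetic single-cell Raman generator. Defaults
#' emulate the hepatocyte study design: fingerprint axis 300-1800 cm^-1 at
#' 1 cm^-1 steps, roughly 600 spectra per class acquired as 20 cells x 3
#' batches with alternating center/periphery sampling, Gaussian peaks of
#' 15 cm^-1 FWHM on a smooth cubic fluorescence background, 5\% additive
#' noise, and sparse cosmic-ray spikes.
#'
#' @param axis_start,axis_stop,axis_step wavenumber axis (cm^-1).
#' @param n_per_class spectra per class; a single count recycled over
#'   profiles, or a vector named/ordered like `profiles`.
#' @param profiles list of class profiles, as from [default_profiles()].
#' @param fwhm Gaussian peak full width at half maximum (cm^-1).
#' @param baseline_order polynomial degree of the fluorescence background.
#' @param baseline_scale mean baseline height as a multiple of the tallest
#'   peak (dimensionless).
#' @param noise_sd additive Gaussian noise s.d. as a fraction of the tallest
#'   peak height.
#' @param spike_rate expected cosmic-ray spikes per spectrum (Poisson).
#' @param spike_amplitude_range spike height range, in multiples of the
#'   tallest peak height.
#' @param seed integer seed; the whole data set is a pure function of the
#'   configuration including this seed.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(axis_start = 300, axis_stop = 1800, axis_step = 1,
                             n_per_class = 600, profiles = default_profiles(),
                             fwhm = 15, baseline_order = 3, baseline_scale = 1,
                             noise_sd = 0.05, spike_rate = 0.3,
                             spike_amplitude_range = c(10, 100), seed = 1L) {
  stopifnot(axis_start < axis_stop, axis_step > 0, all(n_per_class >= 1),
            noise_sd >= 0, spike_rate >= 0, baseline_scale >= 0,
            fwhm > 0, length(spike_amplitude_range) == 2L)
  centers <- as.numeric(names(profiles[[1]]$amplitudes))
  for (p in profiles) {
    a <- p$amplitudes
    if (any(a <= 0)) stop("profile amplitudes must be positive")
    if (!identical(as.numeric(names(a)), centers))
      stop("all profiles must cover the same peak set")
  }
  if (any(centers < axis_start) || any(centers > axis_stop))
    stop("peak centers must lie inside the axis range")
  structure(list(axis_start = axis_start, axis_stop = axis_stop,
                 axis_step = axis_step, n_per_class = n_per_class,
                 profiles = profiles, fwhm = fwhm,
                 baseline_order = baseline_order,
                 baseline_scale = baseline_scale, noise_sd = noise_sd,
                 spike_rate = spike_rate,
                 spike_amplitude_range = as.numeric(spike_amplitude_range),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

sim_axis <- function(config) seq(config$axis_start, config$axis_stop, by = config$axis_step)

gauss_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# tallest noiseless peak height across a profile set (jitter excluded);
# the reference scale for baseline, noise and spikes
peak_height_scale <- function(config) {
  max(vapply(config$profiles, function(p) max(p$amplitudes), numeric(1)))
}

#' Generate one synthetic spectrum
#'
#' Builds intensity = sum of Gaussian peaks (per-cell lognormal amplitude
#' jitter) + nonnegative smooth polynomial baseline + additive Gaussian
#' noise + Poisson-count cosmic-ray spikes of 1-2 channels, and records every
#' component as ground truth. Uses the current RNG stream; seed it (or call
#' via [generate_dataset()]) for reproducibility.
#'
#' @param profile a `class_profile`.
#' @param config a [synthetic_config()].
#' @return list with `spectrum` (a one-row [raman_spectra]) and `truth`
#'   (list: `label`, `baseline`, `spike_positions` (axis values),
#'   `amplitudes`, `noise_free`).
#' @export
generate_spectrum <- function(profile, config) {
  x <- sim_axis(config)
  centers <- as.numeric(names(profile$amplitudes))
  if (any(centers < min(x)) || any(centers > max(x)))
    stop("peak centers must lie inside the axis")
  sigma <- gauss_sigma(config$fwhm)
  cv <- profile$amplitude_cv
  # lognormal jitter with unit median and cv ~ amplitude_cv
  sdlog <- sqrt(log(1 + cv^2))
  jitter <- if (cv > 0) stats::rlnorm(length(centers), -sdlog^2 / 2, sdlog) else rep(1, length(centers))
  amps <- profile$amplitudes * jitter
  peaks <- numeric(length(x))
  for (i in seq_along(centers))
    peaks <- peaks + amps[i] * exp(-0.5 * ((x - centers[i]) / sigma)^2)
  scale <- peak_height_scale(config)
  # smooth nonnegative polynomial background, mean height baseline_scale*scale
  baseline <- numeric(length(x))
  if (config$baseline_scale > 0) {
    tt <- (x - min(x)) / diff(range(x))
    co <- stats::rnorm(config$baseline_order + 1)
    b <- drop(outer(tt, 0:config$baseline_order, `^`) %*% co)
    b <- b - min(b)                       # nonnegative over the axis
    m <- mean(b)
    baseline <- if (m > 0) b * (config$baseline_scale * scale / m) else
      rep(config$baseline_scale * scale, length(x))
  }
  noise <- if (config$noise_sd > 0) stats::rnorm(length(x), 0, config$noise_sd * scale) else 0
  y <- peaks + baseline + noise
  nspikes <- stats::rpois(1, config$spike_rate)
  spike_idx <- integer(0)
  if (nspikes > 0) {
    starts <- sample.int(length(x) - 1L, nspikes)
    widths <- sample(1:2, nspikes, replace = TRUE)
    hts <- stats::runif(nspikes, config$spike_amplitude_range[1],
                        config$spike_amplitude_range[2]) * scale
    for (k in seq_len(nspikes)) {
      idx <- starts[k]:min(starts[k] + widths[k] - 1L, length(x))
      y[idx] <- y[idx] + hts[k]
      spike_idx <- union(spike_idx, idx)
    }
  }
  list(spectrum = raman_spectra(x, y,
         data.frame(spectrum_id = "s0001", label = profile$label)),
       truth = list(label = profile$label, baseline = baseline,
                    spike_positions = x[sort(spike_idx)],
                    amplitudes = amps, noise_free = peaks + baseline))
}

#' Generate a labelled synthetic data set
#'
#' Draws `n_per_class` spectra per profile, assigns cell/batch/location
#' metadata round-robin (3 batches, alternating center/periphery sampling,
#' mimicking 20 cells per batch over 3 replicate batches with paired
#' positions per cell) and shuffles spectrum order. Deterministic: the same
#' configuration (including its seed) yields bit-identical output.
#'
#' @param config a [synthetic_config()].
#' @return list with `spectra` (a [raman_spectra]) and `truth` (list:
#'   `baseline` matrix, `spike_positions` list, `amplitudes` matrix,
#'   `noise_free` matrix; rows aligned with `spectra`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  npc <- config$n_per_class
  if (length(npc) == 1L) npc <- rep(npc, length(config$profiles))
  if (length(npc) != length(config$profiles))
    stop("n_per_class must have length 1 or one entry per profile")
  x <- sim_axis(config)
  rows <- list(); truths <- list(); meta <- list()
  k <- 0L
  for (j in seq_along(config$profiles)) {
    prof <- config$profiles[[j]]
    for (i in seq_len(npc[j])) {
      k <- k + 1L
      g <- generate_spectrum(prof, config)
      rows[[k]] <- g$spectrum$intensity[1, ]
      truths[[k]] <- g$truth
      meta[[k]] <- data.frame(
        spectrum_id = sprintf("s%05d", k),
        cell_id = sprintf("%s_c%03d", prof$label, (i - 1L) %/% 2L + 1L),
        label = prof$label,
        batch = sprintf("b%d", (i - 1L) %% 3L + 1L),
        location = if (i %% 2L == 1L) "center" else "periphery",
        stringsAsFactors = FALSE)
    }
  }
  ord <- sample.int(k)
  intensity <- do.call(rbind, rows)[ord, , drop = FALSE]
  md <- do.call(rbind, meta)[ord, , drop = FALSE]
  rownames(md) <- NULL
  truths <- truths[ord]
  truth <- list(
    baseline = do.call(rbind, lapply(truths, `[[`, "baseline")),
    noise_free = do.call(rbind, lapply(truths, `[[`, "noise_free")),
    amplitudes = do.call(rbind, lapply(truths, `[[`, "amplitudes")),
    spike_positions = lapply(truths, `[[`, "spike_positions"),
    label = vapply(truths, `[[`, character(1), "label"))
  list(spectra = raman_spectra(x, intensity, md), truth = truth)
}

#' Write generator ground truth as JSON
#'
#' Serializes the per-spectrum ground truth of [generate_dataset()] —
#' labels, true band amplitudes, cosmic-spike positions and (optionally)
#' the true baseline vectors — for parameter-recovery analyses outside R.
#'
#' @param truth the `truth` element of a [generate_dataset()] result.
#' @param path output JSON path.
#' @param include_baseline include the full per-spectrum baseline matrix
#'   (large); the spike positions and amplitudes are always written.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path, include_baseline = TRUE) {
  obj <- list(label = truth$label,
              amplitudes = as.data.frame(truth$amplitudes),
              spike_positions = truth$spike_positions)
  if (include_baseline) obj$baseline <- truth$baseline
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
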