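#' Principal component analysis of a spectra matrix
#'
#' Centered singular value decomposition. Either a fixed number of
#' components `k` or a cumulative explained-variance target may be given;
#' with a target, the smallest `k` whose cumulative fraction reaches it is
#' retained. Each component is oriented so its largest-magnitude loading is
#' positive, making the decomposition deterministic.
#'
#' @param x numeric matrix (spectra x channels) or a [raman_spectra] object.
#' @param k number of components to retain.
#' @param variance_target cumulative explained-variance fraction in (0, 1\];
#'   ignored when `k` is given.
#' @return object of class `raman_pca`: list with `mean`, `loadings`
#'   (components x channels, orthonormal rows), `explained` (variance
#'   fractions), `sdev`, `k`.
#' @export
fit_pca <- function(x, k = NULL, variance_target = NULL) {
  if (inherits(x, "raman_spectra")) x <- x$intensity
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("PCA needs at least 2 spectra")
  kmax <- min(n - 1L, ncol(x))
  if (!is.null(k) && k > kmax) stop("k = ", k, " exceeds min(n - 1, channels) = ", kmax)
  mu <- colMeans(x)
  s <- svd(sweep(x, 2L, mu), nu = 0, nv = kmax)
  ev <- s$d[seq_len(kmax)]^2
  frac <- ev / sum(s$d^2)
  if (is.null(k)) {
    k <- if (is.null(variance_target)) kmax else {
      stopifnot(variance_target > 0, variance_target <= 1)
      which(cumsum(frac) >= variance_target - 1e-12)[1]
    }
  }
  load <- t(s$v[, seq_len(k), drop = FALSE])
  # deterministic sign: largest |loading| positive
  for (i in seq_len(k)) {
    j <- which.max(abs(load[i, ]))
    if (load[i, j] < 0) load[i, ] <- -load[i, ]
  }
  structure(list(mean = mu, loadings = load, explained = frac[seq_len(k)],
                 all_explained = frac, sdev = sqrt(ev / (n - 1L)), k = k),
            class = "raman_pca")
}

#' @method print raman_pca
#' @export
print.raman_pca <- function(x, ...) {
  cat("raman_pca: ", x$k, " components over ", length(x$mean), " channels; ",
      "cumulative explained variance ", round(100 * sum(x$explained), 2), "%\n", sep = "")
  invisible(x)
}

#' Fisher linear discriminant analysis after PCA reduction
#'
#' With ~1500 channels and a few hundred spectra per class the within-class
#' scatter matrix is singular in channel space, so the standard remedy is
#' applied: PCA reduction to a cumulative variance target, then Fisher LDA
#' in score space via the generalized eigenproblem of between-class against
#' within-class scatter. Discriminant directions are mapped back to channel
#' space, unit-normalized, and sign-fixed (largest |loading| positive). At
#' most `nclass - 1` axes are returned. If the within-class scatter is still
#' singular after PCA it is ridge-regularized and the epsilon recorded.
#'
#' @param x matrix (spectra x channels) or [raman_spectra]; if the latter and
#'   `labels` is missing, `meta$label` is used.
#' @param labels class label per spectrum (>= 2 classes, each >= 2 spectra).
#' @param pca_variance_target cumulative variance kept by the PCA step.
#' @return object of class `raman_lda`: list with `pca`, `directions` (axes x
#'   channels, unit rows), `scaling` (axes x PCA scores), `class_means`
#'   (class x axes, in LD space), `pooled_cov` (LD-space pooled covariance),
#'   `priors`, `labels` (class order), `ridge`.
#' @export
fit_lda <- function(x, labels = NULL, pca_variance_target = 0.99) {
  if (inherits(x, "raman_spectra")) {
    if (is.null(labels)) labels <- x$meta$label
    x <- x$intensity
  }
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (length(labels) != nrow(x)) stop("labels length must match spectra count")
  cls <- sort(unique(labels))
  if (length(cls) < 2L) stop("LDA needs at least 2 classes")
  cnt <- table(labels)
  if (any(cnt < 2L)) stop("every class needs at least 2 spectra")
  pca <- fit_pca(x, variance_target = pca_variance_target)
  sc <- project(pca, x)
  d <- ncol(sc)
  gm <- colMeans(sc)
  Sw <- matrix(0, d, d); Sb <- matrix(0, d, d)
  for (g in cls) {
    xg <- sc[labels == g, , drop = FALSE]
    mg <- colMeans(xg)
    Sw <- Sw + crossprod(sweep(xg, 2L, mg))
    Sb <- Sb + nrow(xg) * tcrossprod(mg - gm)
  }
  ridge <- 0
  ok <- tryCatch({solve(Sw); TRUE}, error = function(e) FALSE)
  if (!ok || kappa(Sw) > 1e12) {
    ridge <- 1e-8 * sum(diag(Sw)) / d
    Sw <- Sw + diag(ridge, d)
  }
  e <- eigen(solve(Sw, Sb))
  naxes <- min(length(cls) - 1L, d)
  W <- Re(e$vectors[, seq_len(naxes), drop = FALSE])     # PCA-score-space axes
  directions <- W
  chan_dir <- t(pca$loadings) %*% W                      # back to channel space
  for (i in seq_len(naxes)) {
    nrm <- sqrt(sum(chan_dir[, i]^2))
    chan_dir[, i] <- chan_dir[, i] / nrm
    W[, i] <- W[, i] / nrm
    j <- which.max(abs(chan_dir[, i]))
    if (chan_dir[j, i] < 0) { chan_dir[, i] <- -chan_dir[, i]; W[, i] <- -W[, i] }
  }
  ld <- sc %*% W
  cm <- do.call(rbind, lapply(cls, function(g) colMeans(ld[labels == g, , drop = FALSE])))
  rownames(cm) <- cls
  pooled <- matrix(0, naxes, naxes)
  for (g in cls) {
    zg <- ld[labels == g, , drop = FALSE]
    pooled <- pooled + crossprod(sweep(zg, 2L, colMeans(zg)))
  }
  pooled <- pooled / (nrow(x) - length(cls))
  structure(list(pca = pca, directions = t(chan_dir), scaling = W,
                 class_means = cm, pooled_cov = pooled,
                 priors = as.numeric(cnt[cls]) / length(labels),
                 labels = cls, ridge = ridge),
            class = "raman_lda")
}

#' @method print raman_lda
#' @export
print.raman_lda <- function(x, ...) {
  cat("raman_lda: ", nrow(x$directions), " discriminant axes over ",
      ncol(x$directions), " channels; classes: ",
      paste(x$labels, collapse = ", "), "\n", sep = "")
  cat("PCA pre-reduction: ", x$pca$k, " components\n", sep = "")
  if (x$ridge > 0) cat("within-class scatter ridge: ", format(x$ridge), "\n", sep = "")
  invisible(x)
}

#' Project spectra onto a fitted PCA or LDA model
#'
#' @param model a `raman_pca` or `raman_lda` object.
#' @param x matrix (spectra x channels) or [raman_spectra] with the model's
#'   channel count.
#' @return score matrix, one row per spectrum; columns `PC1..` or `LD1..`.
#' @export
project <- function(model, x) UseMethod("project")

#' @export
project.raman_pca <- function(model, x) {
  if (inherits(x, "raman_spectra")) x <- x$intensity
  x <- if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(x) != length(model$mean))
    stop("channel count ", ncol(x), " does not match model (", length(model$mean), ")")
  sc <- sweep(x, 2L, model$mean) %*% t(model$loadings)
  colnames(sc) <- paste0("PC", seq_len(ncol(sc)))
  sc
}

#' @export
project.raman_lda <- function(model, x) {
  sc <- project(model$pca, x) %*% model$scaling
  colnames(sc) <- paste0("LD", seq_len(ncol(sc)))
  sc
}

#' Posterior class probabilities / labels from an LDA model
#'
#' Gaussian posterior with shared (pooled) covariance in discriminant space
#' and training priors; `type = "class"` returns the maximum-posterior label.
#'
#' @param object a fitted `raman_lda`.
#' @param newdata matrix or [raman_spectra].
#' @param type `"prob"` or `"class"`.
#' @param ... unused.
#' @export
predict.raman_lda <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  z <- project(object, newdata)
  Sinv <- solve(object$pooled_cov)
  d2 <- vapply(seq_along(object$labels), function(k) {
    dk <- sweep(z, 2L, object$class_means[k, ])
    rowSums((dk %*% Sinv) * dk)
  }, numeric(nrow(z)))
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1L)
  lp <- sweep(-0.5 * d2, 2L, log(object$priors), `+`)
  lp <- lp - apply(lp, 1L, max)
  pr <- exp(lp) / rowSums(exp(lp))
  colnames(pr) <- object$labels
  if (type == "prob") pr else object$labels[max.col(pr, ties.method = "first")]
}

#' Wavenumbers with the largest discriminant loadings
#'
#' Returns the wavenumbers of the `ceiling(fraction * channels)` channels
#' with the largest absolute loading on the chosen discriminant axis, sorted
#' by descending magnitude; ties at the boundary are broken by the lower
#' wavenumber. This is the usual way to read which spectral features drive a
#' discriminant separation.
#'
#' @param model a fitted `raman_lda`.
#' @param wavenumber the channel axis the model was fitted on.
#' @param axis discriminant axis, e.g. 1 (LD1) or 2 (LD2).
#' @param fraction fraction of channels to return, in (0, 1].
#' @return numeric vector of wavenumbers.
#' @export
top_loading_wavenumbers <- function(model, wavenumber, axis = 1L, fraction = 0.10) {
  stopifnot(inherits(model, "raman_lda"))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (axis < 1L || axis > nrow(model$directions)) stop("no such discriminant axis")
  w <- abs(model$directions[axis, ])
  if (length(wavenumber) != length(w)) stop("wavenumber length mismatch")
  m <- ceiling(fraction * length(w))
  ord <- order(-w, wavenumber)
  wavenumber[ord[seq_len(m)]]
}
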