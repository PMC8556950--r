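#' Single-cell Raman spectra on a common wavenumber grid
#'
#' A `raman_spectra` object holds an aligned collection of spectra: one
#' ascending wavenumber axis (cm^-1), an intensity matrix with one row per
#' spectrum, and a metadata table aligned by row.
#'
#' @param wavenumber strictly ascending numeric vector of wavenumbers (cm^-1).
#' @param intensity numeric matrix, one row per spectrum, `length(wavenumber)`
#'   columns. A single spectrum may be given as a plain numeric vector.
#' @param meta data frame with one row per spectrum. Recognised columns:
#'   `spectrum_id`, `cell_id`, `label`, `batch`, `location` (one of
#'   `"center"`, `"periphery"`, `"unknown"`). Missing columns are filled with
#'   defaults; `label` may be `NA` for prediction-only sets.
#' @return an object of class `raman_spectra`.
#' @export
raman_spectra <- function(wavenumber, intensity, meta = NULL) {
  wavenumber <- as.numeric(wavenumber)
  if (is.null(dim(intensity))) intensity <- matrix(intensity, nrow = 1L)
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  if (length(wavenumber) < 2L) stop("need at least 2 wavenumber channels")
  if (any(diff(wavenumber) <= 0)) stop("wavenumber axis must be strictly ascending")
  if (ncol(intensity) != length(wavenumber))
    stop("intensity has ", ncol(intensity), " columns but axis has ",
         length(wavenumber), " channels")
  if (!all(is.finite(wavenumber)) || !all(is.finite(intensity)))
    stop("wavenumbers and intensities must all be finite")
  n <- nrow(intensity)
  if (is.null(meta)) meta <- data.frame(spectrum_id = sprintf("s%04d", seq_len(n)))
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(meta) != n) stop("metadata has ", nrow(meta), " rows for ", n, " spectra")
  if (is.null(meta$spectrum_id)) meta$spectrum_id <- sprintf("s%04d", seq_len(n))
  meta$spectrum_id <- as.character(meta$spectrum_id)
  if (anyDuplicated(meta$spectrum_id)) stop("duplicated spectrum_id in metadata")
  if (is.null(meta$cell_id)) meta$cell_id <- meta$spectrum_id
  if (is.null(meta$label)) meta$label <- NA_character_
  meta$label <- as.character(meta$label)
  if (is.null(meta$batch)) meta$batch <- NA_character_
  if (is.null(meta$location)) meta$location <- "unknown"
  bad <- setdiff(unique(meta$location), c("center", "periphery", "unknown"))
  if (length(bad)) stop("invalid location value(s): ", paste(bad, collapse = ", "))
  rownames(intensity) <- meta$spectrum_id
  colnames(intensity) <- NULL
  structure(list(wavenumber = wavenumber, intensity = intensity, meta = meta),
            class = "raman_spectra")
}

#' @method print raman_spectra
#' @export
print.raman_spectra <- function(x, ...) {
  cat("raman_spectra: ", nrow(x$intensity), " spectra x ",
      length(x$wavenumber), " channels (",
      format(min(x$wavenumber)), "-", format(max(x$wavenumber)), " cm^-1)\n", sep = "")
  if (any(!is.na(x$meta$label))) {
    tb <- table(x$meta$label, useNA = "ifany")
    cat("labels:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  } else cat("labels: none\n")
  invisible(x)
}

#' @export
`[.raman_spectra` <- function(x, i, ...) {
  raman_spectra(x$wavenumber, x$intensity[i, , drop = FALSE],
                x$meta[i, , drop = FALSE])
}

#' @method as.matrix raman_spectra
#' @export
as.matrix.raman_spectra <- function(x, ...) {
  m <- x$intensity
  colnames(m) <- as.character(x$wavenumber)
  m
}

#' Number of spectra in a set
#' @param x a [raman_spectra] object.
#' @return integer count of spectra.
#' @export
n_spectra <- function(x) nrow(x$intensity)

#' Plot mean spectra per class
#'
#' Draws the per-class average spectrum (base graphics), the usual first look
#' at a single-cell Raman data set.
#'
#' @param x a [raman_spectra] object.
#' @param ... passed to [graphics::matplot].
#' @export
plot.raman_spectra <- function(x, ...) {
  lab <- x$meta$label
  lab[is.na(lab)] <- "(unlabelled)"
  groups <- sort(unique(lab))
  avg <- vapply(groups, function(g) colMeans(x$intensity[lab == g, , drop = FALSE]),
                numeric(length(x$wavenumber)))
  graphics::matplot(x$wavenumber, avg, type = "l", lty = 1,
                    xlab = expression(paste("wavenumber (", cm^-1, ")")),
                    ylab = "intensity (a.u.)", ...)
  graphics::legend("topleft", legend = groups, lty = 1, col = seq_along(groups), bty = "n")
  invisible(x)
}

#' Read spectra from wide CSV
#'
#' The interchange format is a wide CSV whose first column, named
#' `wavenumber`, holds the common axis and whose remaining columns hold one
#' spectrum each (column name = spectrum id). A sibling metadata CSV keyed by
#' `spectrum_id` may be joined on read.
#'
#' @param path path to the wide spectra CSV.
#' @param metadata_path optional path to a metadata CSV with columns
#'   `spectrum_id` and any of `cell_id`, `label`, `batch`, `location`.
#' @return a [raman_spectra] object; spectrum order equals file column order.
#' @export
read_spectra_wide <- function(path, metadata_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L) stop("wide CSV needs a wavenumber column plus >= 1 spectrum column")
  if (names(df)[1] != "wavenumber") stop("first column must be named 'wavenumber'")
  wn <- as.numeric(df[[1]])
  if (any(diff(wn) <= 0)) stop("wavenumber column must be strictly ascending")
  ids <- names(df)[-1]
  if (anyDuplicated(ids)) stop("duplicated spectrum id in header")
  intensity <- t(as.matrix(df[, -1, drop = FALSE]))
  meta <- data.frame(spectrum_id = ids, stringsAsFactors = FALSE)
  if (!is.null(metadata_path)) {
    md <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
    if (is.null(md$spectrum_id)) stop("metadata CSV must have a spectrum_id column")
    missing <- setdiff(md$spectrum_id, ids)
    if (length(missing))
      stop("metadata ids absent from spectra file: ", paste(utils::head(missing, 5), collapse = ", "))
    meta <- merge(meta, md, by = "spectrum_id", all.x = TRUE, sort = FALSE)
    meta <- meta[match(ids, meta$spectrum_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  raman_spectra(wn, intensity, meta)
}

#' Write spectra to wide CSV
#'
#' Columns are emitted in sorted spectrum-id order so repeated writes of the
#' same set are byte-identical; values keep full double precision (15
#' significant digits).
#'
#' @param set a non-empty [raman_spectra] object.
#' @param path output CSV path.
#' @param metadata_path optional path for the sibling metadata CSV.
#' @return `path`, invisibly.
#' @export
write_spectra_wide <- function(set, path, metadata_path = NULL) {
  stopifnot(inherits(set, "raman_spectra"))
  if (n_spectra(set) == 0L) stop("cannot write an empty spectra set")
  ord <- order(set$meta$spectrum_id)
  m <- t(set$intensity[ord, , drop = FALSE])
  df <- data.frame(wavenumber = set$wavenumber, m, check.names = FALSE)
  names(df) <- c("wavenumber", set$meta$spectrum_id[ord])
  fmt <- function(v) formatC(v, digits = 15, format = "g")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  body <- do.call(paste, c(lapply(df, fmt), sep = ","))
  writeLines(body, con)
  if (!is.null(metadata_path))
    utils::write.csv(set$meta[ord, , drop = FALSE], metadata_path, row.names = FALSE)
  invisible(path)
}

#' Write a metadata table for a spectra set
#' @param set a [raman_spectra] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(set, path) {
  ord <- order(set$meta$spectrum_id)
  utils::write.csv(set$meta[ord, , drop = FALSE], path, row.names = FALSE)
  invisible(path)
}
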