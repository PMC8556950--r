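#' The 13 fingerprint bands used for hepatocyte staging
#'
#' Integration windows and biochemical assignments for the 13 Raman bands
#' that discriminate PHH from ProliHHs stages. Single-center bands get a
#' +/- 10 cm^-1 window (covers typical ~15 cm^-1 solid-phase linewidths); the
#' polysaccharide band is the interval 840-860 cm^-1 as reported; the
#' tyrosine 831 window is truncated to [821, 839] so it never double-counts
#' channels shared with its 840-860 neighbour.
#'
#' @param half_width half window width (cm^-1) for single-center bands.
#' @return data frame of class `band_definitions` with columns `name`, `lo`,
#'   `hi`, `assignment`.
#' @export
default_bands <- function(half_width = 10) {
  centers <- c(480, 831, NA, 1003, 1080, 1172, 1206, 1265, 1300, 1337, 1440, 1658, 1744)
  name <- c("480", "831", "840-860", "1003", "1080", "1172", "1206",
            "1265", "1300", "1337", "1440", "1658", "1744")
  assignment <- c("glycogen", "tyrosine", "polysaccharide structure",
                  "phenylalanine", "amide II, typical phospholipid",
                  "C-H in-plane bending mode of tyrosine",
                  "hydroxyproline, tyrosine", "alpha-helix, collagen, tryptophan",
                  "lipids", "amide III", "lipids", "amide I",
                  "carbonyl feature of lipid spectra")
  lo <- ifelse(is.na(centers), 840, centers - half_width)
  hi <- ifelse(is.na(centers), 860, centers + half_width)
  hi[name == "831"] <- min(839, 831 + half_width)   # avoid overlap with 840-860
  df <- data.frame(name = name, lo = lo, hi = hi, assignment = assignment,
                   stringsAsFactors = FALSE)
  class(df) <- c("band_definitions", "data.frame")
  df
}

#' Integrate one band of one or more spectra
#'
#' Trapezoid integral of intensity over the closed wavenumber window
#' `[lo, hi]`; when a window edge falls between channels the edge intensity
#' is linearly interpolated so the integral covers the window exactly.
#'
#' @param set a [raman_spectra] object.
#' @param lo,hi window bounds in cm^-1, inside the spectrum axis.
#' @return numeric vector of areas, one per spectrum.
#' @export
integrate_band <- function(set, lo, hi) {
  stopifnot(inherits(set, "raman_spectra"), lo < hi)
  x <- set$wavenumber
  if (lo < min(x) || hi > max(x))
    stop("band window [", lo, ", ", hi, "] lies outside the axis [",
         min(x), ", ", max(x), "]")
  inside <- x > lo & x < hi
  xs <- c(lo, x[inside], hi)
  apply(set$intensity, 1L, function(y) {
    ys <- c(stats::approx(x, y, xout = lo)$y, y[inside],
            stats::approx(x, y, xout = hi)$y)
    pracma::trapz(xs, ys)
  })
}

#' Per-spectrum band areas with group medians
#'
#' Integrates every band for every labelled spectrum and summarises per
#' (group, band) by the median, the headline statistic for semi-quantitative
#' band comparison. Unlabelled spectra are excluded with a warning.
#'
#' @param set a labelled, preprocessed [raman_spectra] object.
#' @param bands a band table as from [default_bands()].
#' @return an object of class `band_area_table`: list with `areas` (data
#'   frame spectrum x band), `medians` (data frame group x band), `bands`,
#'   `labels`.
#' @export
band_table <- function(set, bands = default_bands()) {
  stopifnot(inherits(set, "raman_spectra"))
  unlab <- is.na(set$meta$label)
  if (any(unlab)) {
    warning(sum(unlab), " unlabelled spectra excluded from band table")
    set <- set[!unlab]
  }
  if (n_spectra(set) == 0L) stop("no labelled spectra")
  areas <- vapply(seq_len(nrow(bands)),
                  function(i) integrate_band(set, bands$lo[i], bands$hi[i]),
                  numeric(n_spectra(set)))
  if (is.null(dim(areas))) areas <- matrix(areas, nrow = 1L)
  colnames(areas) <- bands$name
  groups <- sort(unique(set$meta$label))
  med <- t(vapply(groups, function(g)
    apply(areas[set$meta$label == g, , drop = FALSE], 2L, stats::median),
    numeric(nrow(bands))))
  structure(list(
    areas = data.frame(spectrum_id = set$meta$spectrum_id,
                       label = set$meta$label, areas, check.names = FALSE),
    medians = data.frame(group = groups, med, check.names = FALSE, row.names = NULL),
    bands = bands, labels = set$meta$label), class = "band_area_table")
}

#' @method print band_area_table
#' @export
print.band_area_table <- function(x, ...) {
  cat("band_area_table: ", nrow(x$areas), " spectra, ", nrow(x$bands),
      " bands, groups: ", paste(x$medians$group, collapse = ", "), "\n", sep = "")
  cat("group medians:\n")
  print(x$medians, digits = 3)
  invisible(x)
}

#' Significance stars for p-values
#'
#' The conventional annotation: `ns` for p >= 0.05, `*` p < 0.05, `**`
#' p < 0.01, `***` p < 0.001, `****` p < 0.0001.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return character vector of stars.
#' @export
star_annotation <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  as.character(cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
                   labels = c("****", "***", "**", "*", "ns"), right = FALSE))
}

#' Compare band areas between two groups
#'
#' Two-sided pooled-variance Student's t-test per band, with star
#' annotation; no multiple-testing correction is applied (each band is read
#' as its own univariate comparison).
#'
#' @param table a [band_table()] result.
#' @param groupA,groupB group labels present in the table, each with >= 2
#'   spectra.
#' @return data frame with columns `band`, `groupA`, `groupB`, `median_A`,
#'   `median_B`, `t`, `p`, `star`.
#' @export
compare_groups <- function(table, groupA, groupB) {
  stopifnot(inherits(table, "band_area_table"))
  lab <- table$areas$label
  for (g in c(groupA, groupB)) {
    if (!g %in% lab) stop("group not present: ", g)
    if (sum(lab == g) < 2L) stop("group ", g, " has fewer than 2 spectra")
  }
  bands <- table$bands$name
  rows <- lapply(bands, function(b) {
    a <- table$areas[[b]][lab == groupA]
    bb <- table$areas[[b]][lab == groupB]
    if (stats::sd(a) == 0 && stats::sd(bb) == 0 && isTRUE(all.equal(mean(a), mean(bb)))) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      tt <- stats::t.test(a, bb, var.equal = TRUE)
    }
    data.frame(band = b, groupA = groupA, groupB = groupB,
               median_A = stats::median(a), median_B = stats::median(bb),
               t = unname(tt$statistic), p = tt$p.value,
               star = star_annotation(tt$p.value), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' All pairwise group comparisons of a band table
#'
#' @param table a [band_table()] result.
#' @return row-bound [compare_groups()] output for every unordered group pair.
#' @export
compare_all_groups <- function(table) {
  g <- table$medians$group
  pairs <- utils::combn(g, 2L, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(p) compare_groups(table, p[1], p[2])))
}
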