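#' Prediction-by-reference confusion matrix
#'
#' Entry (i, j) counts spectra predicted as class i whose reference label is
#' class j: rows are model predictions, columns are reference labels.
#'
#' @param predicted,reference equal-length label vectors.
#' @param class_order character vector fixing row/column order; defaults to
#'   the sorted union of labels.
#' @return integer matrix with `predicted`/`reference` dimnames.
#' @export
confusion <- function(predicted, reference, class_order = NULL) {
  predicted <- as.character(predicted); reference <- as.character(reference)
  if (length(predicted) == 0L) stop("empty label vectors")
  if (length(predicted) != length(reference)) stop("label vectors differ in length")
  if (is.null(class_order)) class_order <- sort(unique(c(predicted, reference)))
  bad <- setdiff(unique(c(predicted, reference)), class_order)
  if (length(bad)) stop("label(s) outside class order: ", paste(bad, collapse = ", "))
  m <- table(factor(predicted, class_order), factor(reference, class_order))
  m <- matrix(as.integer(m), nrow = length(class_order),
              dimnames = list(predicted = class_order, reference = class_order))
  m
}

#' Per-class sensitivity
#'
#' `100 * correct / reference_total` for the class: the fraction of the
#' class's reference spectra that the model assigned to it, as a percent
#' rounded to one decimal.
#'
#' @param m confusion matrix in prediction-by-reference orientation.
#' @param class class name (a column of `m`).
#' @return percent, one decimal.
#' @export
sensitivity <- function(m, class) {
  tot <- sum(m[, class])
  if (tot == 0) stop("class ", class, " has no reference spectra")
  round(100 * m[class, class] / tot, 1)
}

#' Per-class specificity
#'
#' `100 * (negatives not predicted as the class) / negatives`, where
#' negatives are all spectra whose reference is any other class; percent to
#' one decimal.
#'
#' @inheritParams sensitivity
#' @export
specificity <- function(m, class) {
  neg <- sum(m[, colnames(m) != class])
  if (neg == 0) stop("no negative spectra for class ", class)
  fp <- sum(m[class, colnames(m) != class])
  round(100 * (neg - fp) / neg, 1)
}

#' Overall accuracy of a confusion matrix
#'
#' `100 * trace / total`, percent to one decimal.
#'
#' @param m confusion matrix.
#' @export
overall_accuracy <- function(m) {
  tot <- sum(m)
  if (tot == 0) stop("empty confusion matrix")
  round(100 * sum(diag(m)) / tot, 1)
}

#' Build an evaluation report from labels or a matrix
#'
#' @param predicted,reference label vectors (or pass `m` directly).
#' @param m optionally, a prediction-by-reference confusion matrix.
#' @param class_order optional class order.
#' @param provenance optional named list (seeds, specs) stored verbatim.
#' @return object of class `evaluation_report`: list with `confusion`,
#'   `sensitivity`, `specificity`, `overall_accuracy`, `n_test`,
#'   `class_order`, `provenance`.
#' @export
evaluation_report <- function(predicted = NULL, reference = NULL, m = NULL,
                              class_order = NULL, provenance = list()) {
  if (is.null(m)) m <- confusion(predicted, reference, class_order)
  cls <- colnames(m)
  sens <- vapply(cls, function(k) sensitivity(m, k), numeric(1))
  spec <- vapply(cls, function(k)
    tryCatch(specificity(m, k), error = function(e) NA_real_), numeric(1))
  structure(list(confusion = m, sensitivity = sens, specificity = spec,
                 overall_accuracy = overall_accuracy(m), n_test = sum(m),
                 class_order = cls, provenance = provenance),
            class = "evaluation_report")
}

#' @method print evaluation_report
#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report (n_test = ", x$n_test, ")\n", sep = "")
  cat("confusion (rows = prediction, cols = reference):\n")
  print(x$confusion)
  cat("sensitivity (%):", paste(names(x$sensitivity),
      format(x$sensitivity, nsmall = 1), sep = "=", collapse = ", "), "\n")
  cat("specificity (%):", paste(names(x$specificity),
      format(x$specificity, nsmall = 1), sep = "=", collapse = ", "), "\n")
  cat("overall accuracy (%):", format(x$overall_accuracy, nsmall = 1), "\n")
  invisible(x)
}

#' Write an evaluation report or band table to disk
#'
#' JSON keeps the full structure (confusion matrix with explicit predicted
#' row / reference column labels, metrics, provenance, software version);
#' CSV flattens to a per-class metric table (reports) or the long area table
#' (band tables).
#'
#' @param report an `evaluation_report` or `band_area_table`.
#' @param path output path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (inherits(report, "evaluation_report")) {
    if (is.null(report$confusion)) stop("report has no confusion matrix")
    if (format == "json") {
      obj <- list(
        type = "evaluation_report",
        version = as.character(utils::packageVersion("ramanstage")),
        class_order = report$class_order,
        confusion = list(
          orientation = "rows = model prediction, columns = reference",
          predicted = rownames(report$confusion),
          reference = colnames(report$confusion),
          counts = lapply(seq_len(nrow(report$confusion)), function(i)
            as.integer(report$confusion[i, ]))),
        sensitivity_pct = as.list(report$sensitivity),
        specificity_pct = as.list(report$specificity),
        overall_accuracy_pct = report$overall_accuracy,
        n_test = report$n_test,
        provenance = report$provenance)
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    } else {
      df <- data.frame(class = report$class_order,
                       sensitivity_pct = unname(report$sensitivity),
                       specificity_pct = unname(report$specificity),
                       overall_accuracy_pct = report$overall_accuracy,
                       n_test = report$n_test)
      utils::write.csv(df, path, row.names = FALSE)
    }
  } else if (inherits(report, "band_area_table")) {
    if (format == "json") {
      jsonlite::write_json(list(type = "band_area_table",
                                bands = report$bands, medians = report$medians,
                                areas = report$areas),
                           path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    } else {
      utils::write.csv(report$areas, path, row.names = FALSE)
    }
  } else stop("unsupported report type: ", paste(class(report), collapse = "/"))
  invisible(path)
}

#' Read back a JSON evaluation report
#'
#' @param path path written by [write_report()] with `format = "json"`.
#' @return an `evaluation_report`.
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "evaluation_report")) stop("not an evaluation report")
  cm <- obj$confusion$counts
  if (is.list(cm)) cm <- do.call(rbind, lapply(cm, as.integer))
  cm <- as.matrix(cm)
  if (ncol(cm) == 1L)
    cm <- matrix(as.integer(cm), nrow = length(obj$confusion$predicted), byrow = TRUE)
  storage.mode(cm) <- "integer"
  dimnames(cm) <- list(predicted = obj$confusion$predicted,
                       reference = obj$confusion$reference)
  evaluation_report(m = cm, provenance = as.list(obj$provenance))
}

#' Published stacked-model confusion matrix for the hepatocyte study
#'
#' The reference three-class test-set confusion matrix reported for the
#' stacked classifier on the real hepatocyte data (462 test spectra), used
#' by tests and documentation as a fixed known-answer fixture. Note: the
#' publication prints a PHH specificity of 81.2%, which is inconsistent with
#' its own printed counts (they give 91.2%); this report recomputes all
#' metrics from the counts.
#'
#' @return an `evaluation_report` built from the published counts.
#' @export
make_table2_fixture <- function() {
  m <- matrix(as.integer(c(118, 14, 16,
                           14, 134, 0,
                           24, 3, 139)), nrow = 3, byrow = TRUE,
              dimnames = list(predicted = c("P1", "P4", "PHH"),
                              reference = c("P1", "P4", "PHH")))
  evaluation_report(m = m, provenance = list(source = "published stacked-model test confusion matrix"))
}
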