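## ---------------------------------------------------------------------------
## Multi-label evaluation: per-class confusion counts, label-based metrics
## with micro/macro averaging, example-based metrics (Hamming loss, exact
## match ratio), dataset statistics (cardinality, label density), and
## Cohen's kappa. Undefined ratios (0/0) are reported as NA with a warning,
## never silently coerced to 0, because coercion biases macro-averages.
## ---------------------------------------------------------------------------

# Align prediction and reference label tables on id and class columns.
align_labels <- function(predictions, reference, classes = NULL) {
  stopifnot(is.data.frame(predictions), is.data.frame(reference),
            "id" %in% names(predictions), "id" %in% names(reference))
  if (nrow(predictions) == 0L || nrow(reference) == 0L) {
    stop("empty corpus: no reports to evaluate")
  }
  classes <- classes %||% intersect(setdiff(names(predictions), "id"),
                                    setdiff(names(reference), "id"))
  if (!length(classes)) stop("no shared class columns")
  missing_in_ref <- setdiff(predictions$id, reference$id)
  missing_in_pred <- setdiff(reference$id, predictions$id)
  if (length(missing_in_ref) || length(missing_in_pred)) {
    stop("report ids do not match; missing in reference: ",
         paste(utils::head(missing_in_ref, 10L), collapse = ", "),
         "; missing in predictions: ",
         paste(utils::head(missing_in_pred, 10L), collapse = ", "))
  }
  ord <- match(predictions$id, reference$id)
  p <- sapply(classes, function(cl) as.logical(predictions[[cl]]))
  r <- sapply(classes, function(cl) as.logical(reference[[cl]][ord]))
  if (is.null(dim(p))) p <- matrix(p, nrow = nrow(predictions))
  if (is.null(dim(r))) r <- matrix(r, nrow = nrow(predictions))
  colnames(p) <- colnames(r) <- classes
  list(pred = p, ref = r, classes = classes, ids = predictions$id)
}

#' Per-class confusion counts
#'
#' Standard 2x2 counts per class over aligned prediction and reference
#' label tables. For every class, `TP + FP + FN + TN` equals the number of
#' evaluated reports.
#'
#' @param predictions,reference data.frames with an `id` column plus one
#'   logical column per class. Row order need not match; ids must.
#' @param classes classes to evaluate (default: shared columns).
#' @return data.frame with columns `class`, `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(predictions, reference, classes = NULL) {
  al <- align_labels(predictions, reference, classes)
  out <- data.frame(class = al$classes,
                    TP = colSums(al$pred & al$ref),
                    FP = colSums(al$pred & !al$ref),
                    FN = colSums(!al$pred & al$ref),
                    TN = colSums(!al$pred & !al$ref),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

safe_div <- function(num, den, what) {
  out <- ifelse(den > 0, num / den, NA_real_)
  if (any(den == 0)) {
    warning(sprintf("%s undefined (0/0) for %d class(es); reported as NA",
                    what, sum(den == 0)), call. = FALSE)
  }
  out
}

#' Label-based metrics from confusion counts
#'
#' Computes precision (positive predictive value), sensitivity (recall,
#' true positive rate), specificity (true negative rate), F1 (harmonic mean
#' of precision and recall) and accuracy per class. Ratios with a zero
#' denominator are `NA` with a warning.
#'
#' @param counts data.frame from [confusion()] (columns `TP`, `FP`, `FN`,
#'   `TN`, optionally `class`).
#' @return data.frame of per-class metrics.
#' @export
label_metrics <- function(counts) {
  stopifnot(all(c("TP", "FP", "FN", "TN") %in% names(counts)))
  with(counts, {
    precision <- safe_div(TP, TP + FP, "precision")
    sensitivity <- safe_div(TP, TP + FN, "sensitivity")
    specificity <- safe_div(TN, TN + FP, "specificity")
    f1 <- ifelse(!is.na(precision) & !is.na(sensitivity) &
                   (precision + sensitivity) > 0,
                 2 * precision * sensitivity / (precision + sensitivity),
                 NA_real_)
    if (any(is.na(f1))) {
      warning("F1 undefined for some class(es); reported as NA", call. = FALSE)
    }
    accuracy <- (TP + TN) / (TP + FP + FN + TN)
    data.frame(class = if ("class" %in% names(counts)) counts$class else
                 seq_len(nrow(counts)),
               precision = precision, sensitivity = sensitivity,
               specificity = specificity, f1 = f1, accuracy = accuracy,
               stringsAsFactors = FALSE)
  })
}

#' Multi-label evaluation report
#'
#' Computes per-class metrics, micro-averages (from pooled confusion
#' counts), macro-averages (unweighted means of per-class values, excluding
#' undefined classes with a warning), Hamming loss (fraction of wrong
#' labels), exact match ratio (fraction of reports with every label
#' correct), and reference-set statistics: cardinality (mean labels per
#' report) and label density (cardinality / number of classes).
#'
#' @param predictions,reference data.frames with `id` plus logical class
#'   columns.
#' @param classes classes to evaluate; use a class group (e.g. the main
#'   classes without the BTA gradings) to reproduce grouped reporting.
#' @return An object of class `radex_metrics`.
#' @export
multilabel_metrics <- function(predictions, reference, classes = NULL) {
  al <- align_labels(predictions, reference, classes)
  n <- nrow(al$pred)
  counts <- confusion(predictions, reference, al$classes)
  per_class <- label_metrics(counts)

  pooled <- data.frame(TP = sum(counts$TP), FP = sum(counts$FP),
                       FN = sum(counts$FN), TN = sum(counts$TN))
  micro <- label_metrics(pooled)
  micro$class <- NULL

  macro <- lapply(per_class[c("precision", "sensitivity", "specificity",
                              "f1", "accuracy")], function(v) {
    if (anyNA(v)) {
      warning("macro-average excludes class(es) with undefined metrics",
              call. = FALSE)
    }
    mean(v, na.rm = TRUE)
  })

  wrong <- al$pred != al$ref
  hamming <- sum(wrong) / (n * length(al$classes))
  emr <- mean(rowSums(wrong) == 0L)
  cardinality <- mean(rowSums(al$ref))
  density <- cardinality / length(al$classes)

  structure(list(per_class = per_class, counts = counts,
                 micro = as.list(micro), macro = macro,
                 hamming_loss = hamming, exact_match_ratio = emr,
                 cardinality = cardinality, label_density = density,
                 n_reports = n, classes = al$classes),
            class = "radex_metrics")
}

#' @export
print.radex_metrics <- function(x, digits = 3, ...) {
  cat(sprintf("<multi-label metrics: %d report(s), %d class(es)>\n",
              x$n_reports, length(x$classes)))
  pc <- x$per_class
  pc[-1] <- lapply(pc[-1], round, digits)
  print(pc, row.names = FALSE)
  cat(sprintf("micro: precision %.3f, sensitivity %.3f, specificity %.3f, F1 %.3f\n",
              x$micro$precision, x$micro$sensitivity, x$micro$specificity,
              x$micro$f1))
  cat(sprintf("macro: precision %.3f, sensitivity %.3f, specificity %.3f, F1 %.3f\n",
              x$macro$precision, x$macro$sensitivity, x$macro$specificity,
              x$macro$f1))
  cat(sprintf("Hamming loss %.4f | exact match ratio %.3f | cardinality %.2f | label density %.2f\n",
              x$hamming_loss, x$exact_match_ratio, x$cardinality,
              x$label_density))
  invisible(x)
}

#' Cohen's kappa for binary label vectors
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' chance agreement `p_e` from the marginals. When `p_e = 1` (both raters
#' constant with the same label) kappa is undefined and reported as `NA`.
#'
#' @param labels_a,labels_b logical/0-1 vectors of equal length, or
#'   data.frames with `id` plus class columns (then kappa is computed per
#'   class and pooled over all labels).
#' @return For vectors, a single kappa value. For data.frames, a list with
#'   `per_class` (named numeric) and `pooled`.
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (is.data.frame(labels_a) && is.data.frame(labels_b)) {
    al <- align_labels(labels_a, labels_b)
    per_class <- vapply(seq_along(al$classes), function(j) {
      kappa_vec(al$pred[, j], al$ref[, j])
    }, numeric(1))
    names(per_class) <- al$classes
    return(list(per_class = per_class,
                pooled = kappa_vec(as.vector(al$pred), as.vector(al$ref))))
  }
  kappa_vec(labels_a, labels_b)
}

kappa_vec <- function(a, b) {
  a <- as.logical(a)
  b <- as.logical(b)
  if (length(a) != length(b)) stop("label vectors differ in length")
  if (!length(a)) stop("empty label vectors")
  n <- length(a)
  p_o <- mean(a == b)
  p_yes <- mean(a) * mean(b)
  p_no <- (1 - mean(a)) * (1 - mean(b))
  p_e <- p_yes + p_no
  if (p_e >= 1) {
    warning("kappa undefined: chance agreement is 1 (constant marginals)",
            call. = FALSE)
    return(NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}
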