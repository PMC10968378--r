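#' Three-class confusion matrix
#'
#' Counts are arranged with predicted classes in rows and actual classes in
#' columns, class order (108, 120, 144): `counts[p, a]` is the number of
#' patients predicted `p` whose reference call is `a`.
#'
#' @param actual,predicted integer vectors of hours in {108, 120, 144},
#'   equal length.
#' @return 3x3 integer matrix of class `confusion_matrix3`.
#' @export
confusion_matrix <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stop("actual and predicted must have equal length")
  if (!all(actual %in% CLASS_HOURS) || !all(predicted %in% CLASS_HOURS))
    stop("labels must be in {108, 120, 144}")
  lv <- as.character(CLASS_HOURS)
  counts <- table(factor(predicted, levels = lv), factor(actual, levels = lv))
  m <- matrix(as.integer(counts), 3, 3,
              dimnames = list(predicted = lv, actual = lv))
  class(m) <- c("confusion_matrix3", class(m))
  m
}

#' Build a confusion_matrix3 from explicit counts
#' @param counts 3x3 matrix, rows predicted, columns actual, order
#'   (108, 120, 144).
#' @export
as_confusion_matrix3 <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(3, 3)), all(counts >= 0),
            all(counts == round(counts)))
  m <- matrix(as.integer(counts), 3, 3,
              dimnames = list(predicted = as.character(CLASS_HOURS),
                              actual = as.character(CLASS_HOURS)))
  class(m) <- c("confusion_matrix3", class(m))
  m
}

ovr_counts <- function(cm, cls) {
  i <- match(as.character(cls), as.character(CLASS_HOURS))
  if (is.na(i)) stop("unknown class: ", cls)
  tp <- cm[i, i]
  fp <- sum(cm[i, ]) - tp   # predicted cls, actually other
  fn <- sum(cm[, i]) - tp   # actually cls, predicted other
  tn <- sum(cm) - tp - fp - fn
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' One-vs-rest metrics for a single class
#'
#' Collapses the other two classes into "rest" and computes sensitivity
#' TP/(TP+FN), specificity TN/(TN+FP), positive predictive value TP/(TP+FP),
#' and negative predictive value TN/(TN+FN). A metric whose denominator is 0
#' is returned as NA.
#'
#' @param cm a `confusion_matrix3`.
#' @param cls one of 108, 120, 144.
#' @return named numeric vector `sen, spe, ppv, npv` (proportions in
#'   \[0, 1\]).
#' @export
per_class_metrics <- function(cm, cls) {
  ct <- ovr_counts(cm, cls)
  safe_div <- function(a, b) if (b == 0) NA_real_ else unname(a / b)
  c(sen = safe_div(ct["tp"], ct["tp"] + ct["fn"]),
    spe = safe_div(ct["tn"], ct["tn"] + ct["fp"]),
    ppv = safe_div(ct["tp"], ct["tp"] + ct["fp"]),
    npv = safe_div(ct["tn"], ct["tn"] + ct["fn"]))
}

#' Macro-averaged metrics and overall accuracy
#'
#' Macro values are unweighted means over the three classes (classes with an
#' undefined metric are excluded with a warning); accuracy is
#' trace/total.
#'
#' @param cm a `confusion_matrix3`.
#' @return named numeric vector `sen, spe, ppv, npv, acc`.
#' @export
macro_metrics <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  per <- vapply(CLASS_HOURS, function(cls) per_class_metrics(cm, cls),
                numeric(4))
  if (anyNA(per))
    warning("undefined per-class metric(s) excluded from macro averages")
  out <- rowMeans(per, na.rm = TRUE)
  c(out, acc = sum(diag(cm)) / total)
}

#' Full evaluation report
#'
#' @param actual,predicted label vectors (hours).
#' @return list with `confusion` (matrix), `per_class` (data.frame) and
#'   `macro` (named vector); percentages formatted with
#'   [format_percent()].
#' @export
evaluate_predictions <- function(actual, predicted) {
  cm <- confusion_matrix(actual, predicted)
  per <- t(vapply(CLASS_HOURS, function(cls) per_class_metrics(cm, cls),
                  numeric(4)))
  per_df <- data.frame(class = CLASS_HOURS, per, row.names = NULL)
  list(confusion = cm, per_class = per_df, macro = macro_metrics(cm))
}

#' Format a proportion as a display percentage
#'
#' Rounds half away from zero at `digits` decimals (so 97.135 prints as
#' 97.14), the convention used for the reported metric tables.
#'
#' @param x proportion(s) in \[0, 1\].
#' @param digits decimals (default 2).
#' @return numeric percentage(s).
#' @export
format_percent <- function(x, digits = 2) {
  p <- x * 100
  f <- 10^digits
  sign(p) * floor(abs(p) * f + 0.5) / f
}

#' Concordance with a reference call, stratified by prior implantation
#' failures
#'
#' Restricts the paired calls to patients passing `pif_filter` and reports
#' the fraction on which classifier and reference agree. The display
#' percentage truncates toward zero at one decimal (12/19 reports as 63.1),
#' matching the convention of the reported concordance rates; the
#' full-precision `rate` is also returned.
#'
#' @param predicted,reference aligned label vectors.
#' @param n_pif aligned non-negative integer vector of previous implantation
#'   failures.
#' @param pif_filter predicate taking `n_pif`, e.g. `function(p) p >= 1`.
#' @return list `concordant`, `total`, `rate`, `percent` (NA rate on an empty
#'   subset).
#' @export
concordance_by_pif <- function(predicted, reference, n_pif,
                               pif_filter = function(p) p >= 0) {
  stopifnot(length(predicted) == length(reference),
            length(predicted) == length(n_pif))
  keep <- pif_filter(n_pif)
  total <- sum(keep)
  if (total == 0)
    return(list(concordant = 0L, total = 0L, rate = NA_real_,
                percent = NA_real_))
  conc <- sum(predicted[keep] == reference[keep])
  rate <- conc / total
  list(concordant = conc, total = total, rate = rate,
       percent = trunc(rate * 1000) / 10)
}
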