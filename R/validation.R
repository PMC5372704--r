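# Confusion-matrix validation of growth predictions against observations.

#' Build a confusion matrix from in-silico and in-vivo growth calls
#'
#' True positives are growth in both, true negatives no-growth in both,
#' false positives in-silico growth only, false negatives in-vivo growth
#' only.
#'
#' @param in_silico data frame of growth calls with columns \code{item} and
#'   \code{call} (\code{"growth"}/\code{"no_growth"}), as returned by the
#'   screen functions, or a named character vector of calls.
#' @param in_vivo named character vector (or data frame with \code{item} and
#'   \code{call}) of observed outcomes; every in-silico item needs a label.
#' @return List with \code{confusion} (class \code{confusion_matrix}: tp, tn,
#'   fp, fn) and \code{labels} (per-item table with a \code{result} column in
#'   TP/TN/FP/FN).
#' @export
classify_outcomes <- function(in_silico, in_vivo) {
  if (is.data.frame(in_silico))
    in_silico <- stats::setNames(in_silico$call, in_silico$item)
  if (is.data.frame(in_vivo))
    in_vivo <- stats::setNames(in_vivo$call, in_vivo$item)
  missing <- setdiff(names(in_silico), names(in_vivo))
  if (length(missing))
    stop("no in-vivo label for item(s): ", paste(missing, collapse = ", "))
  iv <- in_vivo[names(in_silico)]
  result <- ifelse(in_silico == "growth" & iv == "growth", "TP",
            ifelse(in_silico == "no_growth" & iv == "no_growth", "TN",
            ifelse(in_silico == "growth", "FP", "FN")))
  cm <- confusion_matrix(tp = sum(result == "TP"), tn = sum(result == "TN"),
                         fp = sum(result == "FP"), fn = sum(result == "FN"))
  list(confusion = cm,
       labels = data.frame(item = names(in_silico),
                           in_silico = unname(in_silico),
                           in_vivo = unname(iv),
                           result = unname(result),
                           stringsAsFactors = FALSE))
}

#' Confusion matrix
#' @param tp,tn,fp,fn nonnegative integer tallies.
#' @return An object of class \code{confusion_matrix}.
#' @export
confusion_matrix <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  structure(list(tp = as.integer(tp), tn = as.integer(tn),
                 fp = as.integer(fp), fn = as.integer(fn)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion_matrix: TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
              x$tp, x$tn, x$fp, x$fn, x$tp + x$tn + x$fp + x$fn))
  invisible(x)
}

#' Classifier performance metrics
#'
#' Computes sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision
#' TP/(TP+FP), negative predictive value TN/(TN+FN), accuracy
#' (TP+TN)/total, and the F-score (harmonic mean of precision and
#' sensitivity). A metric with a zero denominator is reported as \code{NaN},
#' never as 0.
#'
#' @param cm a \code{\link{confusion_matrix}}.
#' @return Named list of the six metrics, each in [0, 1] (or \code{NaN}).
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  div <- function(num, den) if (den == 0) NaN else num / den
  sens <- div(cm$tp, cm$tp + cm$fn)
  spec <- div(cm$tn, cm$tn + cm$fp)
  prec <- div(cm$tp, cm$tp + cm$fp)
  npv <- div(cm$tn, cm$tn + cm$fn)
  acc <- div(cm$tp + cm$tn, cm$tp + cm$tn + cm$fp + cm$fn)
  f <- if (is.nan(prec) || is.nan(sens) || (prec + sens) == 0) NaN else
    2 * prec * sens / (prec + sens)
  list(sensitivity = sens, specificity = spec, precision = prec,
       npv = npv, accuracy = acc, f_score = f)
}
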