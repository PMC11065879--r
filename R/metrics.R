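# Confusion-matrix accuracy metrics and mapped-vs-reported area agreement.

#' Build a binary confusion matrix
#'
#' @param truth,predicted class vectors (same length); `NA` predictions are
#'   dropped pairwise.
#' @param positive the positive class (default `"soybean"`).
#' @return An object of class `soy_confusion`: list with `TP`, `FP`, `FN`,
#'   `TN`.
#' @export
confusion_matrix <- function(truth, predicted, positive = "soybean") {
  ok <- !is.na(truth) & !is.na(predicted)
  truth <- truth[ok] == positive
  predicted <- predicted[ok] == positive
  structure(list(TP = sum(truth & predicted),
                 FP = sum(!truth & predicted),
                 FN = sum(truth & !predicted),
                 TN = sum(!truth & !predicted)),
            class = "soy_confusion")
}

#' @export
print.soy_confusion <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(truth = c("positive", "negative"),
                              predicted = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Accuracy metrics from a confusion matrix
#'
#' Producer's accuracy (recall, `TP/(TP+FN)`), user's accuracy (precision,
#' `TP/(TP+FP)`), F1, overall accuracy and Cohen's kappa, with soybean as
#' the positive class. Zero-denominator metrics are reported as `NA` and
#' listed in `undefined` rather than silently propagating `NaN`.
#'
#' Some mapping reports swap the producer's/user's denominators; set
#' `convention = "swapped"` to compute PA as `TP/(TP+FP)` and UA as
#' `TP/(TP+FN)`. The returned object records which convention was used.
#'
#' @param cm a `soy_confusion` (or list with `TP`, `FP`, `FN`, `TN`).
#' @param convention `"standard"` (PA = recall, UA = precision) or
#'   `"swapped"`.
#' @return List with `recall` (PA), `precision` (UA), `f1`, `oa`, `kappa`,
#'   `convention`, `undefined`.
#' @export
accuracy_metrics <- function(cm, convention = c("standard", "swapped")) {
  convention <- match.arg(convention)
  tp <- cm$TP; fp <- cm$FP; fn <- cm$FN; tn <- cm$TN
  total <- tp + fp + fn + tn
  if (total <= 0) stop("empty confusion matrix")
  undefined <- character(0)
  div <- function(num, den, what) {
    if (den == 0) {
      undefined <<- c(undefined, what)
      return(NA_real_)
    }
    num / den
  }
  recall <- div(tp, tp + fn, "recall")
  precision <- div(tp, tp + fp, "precision")
  if (convention == "swapped") {
    pa <- precision; ua <- recall
  } else {
    pa <- recall; ua <- precision
  }
  f1 <- if (is.na(pa) || is.na(ua) || pa + ua == 0) {
    undefined <- c(undefined, "f1"); NA_real_
  } else 2 * pa * ua / (pa + ua)
  oa <- (tp + tn) / total
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / total^2
  kappa <- if (pe == 1) {
    undefined <- c(undefined, "kappa"); NA_real_
  } else (oa - pe) / (1 - pe)
  list(recall = pa, precision = ua, f1 = f1, oa = oa, kappa = kappa,
       convention = convention, undefined = undefined)
}

#' Mapped-vs-reported area agreement
#'
#' Coefficient of determination (squared Pearson correlation), root mean
#' square error and mean absolute error between mapped and reported areas,
#' matched by unit name. Units follow the inputs.
#'
#' @param mapped,reported named numeric vectors sharing the same unit keys
#'   (n >= 2).
#' @return List with `r2`, `rmse`, `mae`, `n`, `undefined`.
#' @export
area_agreement <- function(mapped, reported) {
  if (is.null(names(mapped)) || is.null(names(reported)))
    stop("mapped and reported areas must be named by unit")
  if (!setequal(names(mapped), names(reported)))
    stop("unit keys differ between mapped and reported areas")
  reported <- reported[names(mapped)]
  if (length(mapped) < 2) stop("need at least 2 units")
  err <- mapped - reported
  undefined <- character(0)
  r2 <- if (stats::sd(mapped) == 0 || stats::sd(reported) == 0) {
    undefined <- c(undefined, "r2")
    NA_real_
  } else stats::cor(mapped, reported)^2
  list(r2 = r2, rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
       n = length(mapped), undefined = undefined)
}
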