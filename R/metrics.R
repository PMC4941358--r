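#' Confusion counts for a two-class prediction
#'
#' Tallies predictions in the confusion-count parameterization used
#' throughout the package: \code{Npos} and \code{Nneg} are the numbers of
#' true positives-class and negatives-class samples investigated;
#' \code{NminusPlus} the positives predicted negative (missed ACPs);
#' \code{NplusMinus} the negatives predicted positive (false alarms).
#'
#' @param truth Factor (or character) of true labels with positive level
#'   \code{"ACP"}.
#' @param predicted Parallel vector of predicted labels.
#' @return Named integer vector with elements \code{Npos}, \code{Nneg},
#'   \code{NminusPlus}, \code{NplusMinus}.
#' @export
confusionCounts <- function(truth, predicted) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted))
  pos <- truth == "ACP"
  c(Npos = sum(pos),
    Nneg = sum(!pos),
    NminusPlus = sum(pos & predicted != "ACP"),
    NplusMinus = sum(!pos & predicted == "ACP"))
}

#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' Computes the four standard quality metrics in their confusion-count form:
#' \deqn{Sn = 1 - N^{-}_{+}/N^{+}, \quad Sp = 1 - N^{+}_{-}/N^{-},}
#' \deqn{Acc = 1 - (N^{-}_{+} + N^{+}_{-})/(N^{+} + N^{-}),}
#' \deqn{MCC = \frac{1 - (N^{-}_{+}/N^{+} + N^{+}_{-}/N^{-})}
#'   {\sqrt{(1 + (N^{+}_{-} - N^{-}_{+})/N^{+})
#'          (1 + (N^{-}_{+} - N^{+}_{-})/N^{-})}}.}
#' This MCC is algebraically identical to the classical
#' \eqn{(TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' wherever both are defined. Degenerate cases (a factor under the square
#' root non-positive, or an absent class making Sn or Sp meaningless) are
#' reported as \code{NA} — an explicit undefined marker, never silently 0.
#'
#' @param counts Named vector as returned by \code{\link{confusionCounts}}.
#' @return Named numeric vector with elements \code{Sn}, \code{Sp},
#'   \code{Acc}, \code{MCC}, all in [0, 1] except MCC in [-1, 1].
#' @examples
#' computeMetrics(c(Npos = 138, Nneg = 206, NminusPlus = 14, NplusMinus = 3))
#' @export
computeMetrics <- function(counts) {
  np <- counts[["Npos"]]; nn <- counts[["Nneg"]]
  fn <- counts[["NminusPlus"]]; fp <- counts[["NplusMinus"]]
  if (fn > np || fp > nn || fn < 0 || fp < 0)
    stop("inconsistent confusion counts", call. = FALSE)
  sn <- if (np > 0) 1 - fn / np else NA_real_
  sp <- if (nn > 0) 1 - fp / nn else NA_real_
  acc <- if (np + nn > 0) 1 - (fn + fp) / (np + nn) else NA_real_
  mcc <- NA_real_
  if (np > 0 && nn > 0) {
    f1 <- 1 + (fp - fn) / np
    f2 <- 1 + (fn - fp) / nn
    if (f1 > 0 && f2 > 0)
      mcc <- (1 - (fn / np + fp / nn)) / sqrt(f1 * f2)
  }
  c(Sn = sn, Sp = sp, Acc = acc, MCC = mcc)
}

#' Format a metrics vector the way the reference tables print it
#'
#' Percentages with 2 decimals for Sn/Sp/Acc, MCC with 3 decimals.
#'
#' @param metrics Named vector from \code{\link{computeMetrics}}.
#' @return Single-row data.frame of formatted strings.
#' @export
formatMetrics <- function(metrics) {
  pct <- function(x) if (is.na(x)) "NA" else sprintf("%.2f", 100 * x)
  data.frame(Sn = pct(metrics[["Sn"]]), Sp = pct(metrics[["Sp"]]),
              Acc = pct(metrics[["Acc"]]),
              MCC = if (is.na(metrics[["MCC"]])) "undefined" else
                sprintf("%.3f", metrics[["MCC"]]),
              stringsAsFactors = FALSE)
}
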