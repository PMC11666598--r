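#' Within-cycle outlier detection by the 1.5 IQR rule
#'
#' Flags daily metric values lying strictly outside
#' \[Q1 - 1.5 IQR, Q3 + 1.5 IQR\] for one participant-cycle. Quartiles are
#' computed on the non-missing values by linear interpolation between order
#' statistics ([stats::quantile()] type 7). With fewer than `min_n`
#' non-missing values the quartiles are too unstable and no removal is
#' performed (infinite fences).
#'
#' @param values Numeric vector of daily values for one participant-cycle;
#'   may contain NA (missing wear days).
#' @param k Fence multiplier (default 1.5).
#' @param min_n Minimum non-missing values required to compute fences
#'   (default 4).
#' @return List with `keep` (logical vector, TRUE for non-missing values
#'   inside the fences) and `fences` (lower, upper).
#' @examples
#' remove_outliers_iqr(c(50, 51, 52, 53, 90))$keep
#' @export
remove_outliers_iqr <- function(values, k = 1.5, min_n = 4) {
  present <- !is.na(values)
  if (!any(present)) {
    warning("all values missing; nothing to keep", call. = FALSE)
    return(list(keep = present, fences = c(NA_real_, NA_real_)))
  }
  if (sum(present) < min_n) {
    return(list(keep = present, fences = c(-Inf, Inf)))
  }
  q <- quantile(values[present], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  fences <- c(q[1] - k * iqr, q[2] + k * iqr)
  keep <- present & values >= fences[1] & values <= fences[2]
  list(keep = keep, fences = fences)
}
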