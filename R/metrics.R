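# Colony-counting error metrics: mean absolute error and symmetric mean
# absolute percentage error between predicted and true per-dish (or
# per-patch) counts. sMAPE uses the symmetric denominator (p + t) / 2 and
# defines the 0/0 term as zero, so it lives in [0, 200] percent.

check_pairs <- function(predicted, actual) {
  if (length(predicted) == 0L || length(actual) == 0L) {
    stop("count vectors must be nonempty", call. = FALSE)
  }
  if (length(predicted) != length(actual)) {
    stop("predicted and actual counts must have equal length", call. = FALSE)
  }
  if (any(predicted < 0) || any(actual < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
}

#' Mean absolute counting error
#'
#' @param predicted,actual non-negative integer vectors, one entry per
#'   dish or patch.
#' @return mean of `|predicted - actual|`.
#' @export
count_mae <- function(predicted, actual) {
  check_pairs(predicted, actual)
  mean(abs(predicted - actual))
}

#' Symmetric mean absolute percentage counting error
#'
#' `100/n * sum |p - t| / ((p + t) / 2)`, with a term of 0 whenever
#' `p == t == 0`. Unlike MAE this weights errors by how populated the dish
#' is: missing 5 colonies of 10 hurts more than 5 of 100.
#'
#' @inheritParams count_mae
#' @return percentage in `[0, 200]`.
#' @export
count_smape <- function(predicted, actual) {
  check_pairs(predicted, actual)
  denom <- (predicted + actual) / 2
  term <- ifelse(denom == 0, 0, abs(predicted - actual) / denom)
  100 * mean(term)
}
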