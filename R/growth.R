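#' Population doubling time from a growth curve
#'
#' Fits ln(count) ~ time by least squares over the exponential window and
#' returns ln(2) / slope, in hours. By default all points are used; an
#' optional lag-phase trim drops leading points whose fold change over the
#' first observation stays below \code{lag_fold}.
#'
#' @param time_h observation times in hours, strictly increasing.
#' @param count cell counts (> 0), same length as \code{time_h}.
#' @param lag_fold if given (> 1), leading points with
#'   \code{count / count[1] < lag_fold} are dropped before fitting, keeping
#'   at least the last two points.
#' @return doubling time in hours, with the per-hour growth rate attached
#'   as attribute \code{"rate"}.
#' @examples
#' doubling_time(c(0, 24, 48), c(1000, 2000, 4000))  # 24
#' @export
doubling_time <- function(time_h, count, lag_fold = NULL) {
  if (length(time_h) != length(count)) {
    stop("`time_h` and `count` must have the same length", call. = FALSE)
  }
  if (length(time_h) < 2) {
    stop("need at least 2 growth points", call. = FALSE)
  }
  if (any(diff(time_h) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(count <= 0)) stop("counts must be positive", call. = FALSE)
  if (!is.null(lag_fold)) {
    stopifnot(lag_fold > 1)
    past_lag <- count / count[1] >= lag_fold
    first <- min(which(past_lag), length(time_h) - 1)
    keep <- seq(max(1, first - 1), length(time_h))  # include last lag point
    time_h <- time_h[keep]
    count <- count[keep]
  }
  fit <- stats::lm.fit(cbind(1, time_h), log(count))
  k <- fit$coefficients[[2]]
  if (!is.finite(k) || k <= 0) {
    stop("estimated growth rate is not positive: no exponential growth",
         call. = FALSE)
  }
  structure(log(2) / k, rate = k)
}
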