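#' Fit the median-effect dose-response law
#'
#' Fits the median-effect equation fa/fu = (D/Dm)^m to (dose, fraction
#' affected) data by ordinary least squares on the linearized (log-log)
#' median-effect plot: log10(fa/fu) = m*log10(D) - m*log10(Dm).
#'
#' Points with \code{fa <= 0} or \code{fa >= 1} carry no information on the
#' log-odds scale and are excluded with a warning (the classical practice of
#' excluding 0\% and 100\% effects). Alternatively \code{clamp = TRUE}
#' shrinks such points into \code{[eps, 1 - eps]} and keeps them.
#'
#' The base of the logarithm does not affect the estimates: slope and
#' intercept rescale together so that \code{m} and \code{Dm} are unchanged.
#'
#' @param dose numeric vector of doses (same concentration unit throughout,
#'   conventionally uM); must be strictly positive.
#' @param fa numeric vector of fractions affected, same length as
#'   \code{dose}; values in (0, 1) are usable.
#' @param clamp if \code{TRUE}, fa values outside (0, 1) are clamped to
#'   \code{[eps, 1 - eps]} instead of excluded. Default \code{FALSE}.
#' @param eps clamping margin, default \code{1e-4}.
#'
#' @return An object of class \code{"median_effect_fit"}: a list with
#'   \item{m}{slope of the median-effect plot (sigmoidicity); > 0 for
#'     cytotoxic agents.}
#'   \item{Dm}{median-effect dose, the dose giving fa = 0.5 (the model IC50),
#'     in the unit of \code{dose}.}
#'   \item{r}{Pearson correlation of the linearized points (linearity of the
#'     median-effect plot).}
#'   \item{n_points}{number of points used in the fit.}
#'   \item{n_excluded}{number of points excluded (fa outside (0,1)).}
#'
#' @examples
#' # exact law: m = 1, Dm = 5
#' fit <- fit_median_effect(c(5, 10, 20), c(0.5, 2/3, 0.8))
#' fit$Dm  # 5
#' @export
fit_median_effect <- function(dose, fa, clamp = FALSE, eps = 1e-4) {
  if (length(dose) != length(fa)) {
    stop("`dose` and `fa` must have the same length", call. = FALSE)
  }
  keep <- is.finite(dose) & is.finite(fa)
  dose <- dose[keep]
  fa <- fa[keep]
  if (any(dose <= 0)) {
    stop("all doses must be strictly positive", call. = FALSE)
  }
  if (clamp) {
    fa <- pmin(pmax(fa, eps), 1 - eps)
    usable <- rep(TRUE, length(fa))
  } else {
    usable <- fa > 0 & fa < 1
  }
  n_excluded <- sum(!usable)
  if (n_excluded > 0) {
    warning(sprintf(
      "%d point(s) with fa outside (0, 1) excluded from the median-effect fit",
      n_excluded
    ), call. = FALSE)
  }
  dose <- dose[usable]
  fa <- fa[usable]
  if (length(dose) < 2) {
    stop("need at least 2 usable points (0 < fa < 1) to fit", call. = FALSE)
  }
  if (length(unique(dose)) < 2) {
    stop("all doses identical: singular design, slope not estimable",
         call. = FALSE)
  }
  x <- log10(dose)
  y <- log10(fa / (1 - fa))
  ols <- stats::lm.fit(cbind(1, x), y)
  b0 <- ols$coefficients[[1]]
  m <- ols$coefficients[[2]]
  if (!is.finite(m) || abs(m) < sqrt(.Machine$double.eps)) {
    stop("slope m is zero within machine tolerance: non-identifiable fit",
         call. = FALSE)
  }
  r <- if (stats::sd(y) == 0) {
    # flat response over distinct doses: correlation undefined, report 0
    0
  } else {
    stats::cor(x, y)
  }
  structure(
    list(
      m = m,
      Dm = 10^(-b0 / m),
      r = r,
      n_points = length(dose),
      n_excluded = n_excluded
    ),
    class = "median_effect_fit"
  )
}

#' Construct a median-effect fit from known parameters
#'
#' Wraps known (m, Dm) values into a \code{median_effect_fit} object, e.g.
#' to evaluate doses at published parameter values without refitting.
#'
#' @param m slope of the median-effect plot; non-zero, positive for
#'   cytotoxic agents.
#' @param Dm median-effect dose (> 0), in the working concentration unit.
#' @param r linear correlation to record, default \code{NA}.
#' @return A \code{median_effect_fit} object.
#' @export
median_effect_fit <- function(m, Dm, r = NA_real_) {
  stopifnot(is.numeric(m), length(m) == 1L, is.finite(m), m != 0)
  stopifnot(is.numeric(Dm), length(Dm) == 1L, is.finite(Dm), Dm > 0)
  structure(
    list(m = m, Dm = Dm, r = r, n_points = 0L, n_excluded = 0L),
    class = "median_effect_fit"
  )
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat("Median-effect fit\n")
  cat(sprintf("  m  = %.5g\n", x$m))
  cat(sprintf("  Dm = %.5g (dose at fa = 0.5)\n", x$Dm))
  cat(sprintf("  r  = %s  (n = %d, excluded = %d)\n",
              ifelse(is.na(x$r), "NA", sprintf("%.4f", x$r)),
              x$n_points, x$n_excluded))
  invisible(x)
}

#' Dose producing a given effect level
#'
#' Inverts the median-effect law: Dx = Dm * (fa / fu)^(1/m), the dose of the
#' agent alone that produces fraction affected \code{fa}.
#'
#' @param fit a \code{median_effect_fit}.
#' @param fa effect level(s), each strictly inside (0, 1); fa = 0.5 returns
#'   \code{Dm} (the IC50), fa = 0.75 the IC75, and so on.
#' @return dose(s) in the unit the fit was made with.
#' @export
dose_for_effect <- function(fit, fa) {
  stopifnot(inherits(fit, "median_effect_fit"))
  if (any(!is.finite(fa)) || any(fa <= 0) || any(fa >= 1)) {
    stop("effect level fa must lie strictly inside (0, 1)", call. = FALSE)
  }
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Effect level at a given dose
#'
#' Evaluates the median-effect law: fa = 1 / (1 + (Dm/D)^m).
#'
#' @param fit a \code{median_effect_fit}.
#' @param dose dose(s) > 0 in the unit the fit was made with.
#' @return fraction(s) affected in (0, 1).
#' @export
effect_at_dose <- function(fit, dose) {
  stopifnot(inherits(fit, "median_effect_fit"))
  if (any(!is.finite(dose)) || any(dose <= 0)) {
    stop("dose must be strictly positive", call. = FALSE)
  }
  1 / (1 + (fit$Dm / dose)^fit$m)
}
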