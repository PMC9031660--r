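#' Relative viability from absorbance readings
#'
#' relative viability (\%) = mean(sample absorbance) / mean(control
#' absorbance) x 100. Replicates are aggregated by arithmetic mean before
#' normalization.
#'
#' @param sample_abs absorbance readings of treated wells (>= 0).
#' @param control_abs absorbance readings of untreated control wells.
#' @return relative viability in percent.
#' @export
relative_viability <- function(sample_abs, control_abs) {
  if (length(sample_abs) == 0 || length(control_abs) == 0) {
    stop("sample and control absorbances must be non-empty", call. = FALSE)
  }
  if (any(sample_abs < 0) || any(control_abs < 0)) {
    stop("absorbances must be non-negative", call. = FALSE)
  }
  ctrl <- mean(control_abs)
  if (ctrl <= 0) stop("control mean absorbance must be > 0", call. = FALSE)
  mean(sample_abs) / ctrl * 100
}

#' Fraction affected from relative viability
#'
#' fa = 1 - viability/100. Values above 100\% viability (possible under
#' absorbance noise) map to negative fa; such points are flagged and later
#' excluded by the median-effect fit rather than truncated.
#'
#' @param viability_percent relative viability in percent (>= 0).
#' @return fraction affected (may fall outside [0, 1] for noisy input).
#' @export
viability_to_fa <- function(viability_percent) {
  if (any(viability_percent < 0, na.rm = TRUE)) {
    stop("relative viability cannot be negative", call. = FALSE)
  }
  1 - viability_percent / 100
}

#' Dose-response table from plate records
#'
#' Converts tidy plate records for one drug (or one fixed-ratio mixture)
#' into a per-dose table of mean absorbance, relative viability and
#' fraction affected. Control wells are the rows with \code{dose_uM == 0}.
#'
#' @param records data.frame with columns \code{dose_uM} and \code{od}
#'   (one row per well; replicate and label columns are ignored). An
#'   optional \code{blank} column of blank readings is subtracted from
#'   \code{od} when \code{subtract_blank = TRUE}.
#' @param subtract_blank subtract a \code{blank} column before averaging;
#'   default \code{FALSE} (no blank correction).
#' @return data.frame with columns \code{dose_uM}, \code{viability_pct},
#'   \code{fa}, sorted by dose, controls excluded.
#' @export
fa_table <- function(records, subtract_blank = FALSE) {
  need <- c("dose_uM", "od")
  if (!all(need %in% names(records))) {
    stop("records need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  od <- records$od
  if (subtract_blank) {
    if (is.null(records$blank)) {
      stop("subtract_blank = TRUE but no `blank` column present",
           call. = FALSE)
    }
    od <- od - records$blank
  }
  is_ctrl <- records$dose_uM == 0
  if (!any(is_ctrl)) {
    stop("no control wells (dose_uM == 0) in plate records", call. = FALSE)
  }
  ctrl <- od[is_ctrl]
  doses <- sort(unique(records$dose_uM[!is_ctrl]))
  via <- vapply(doses, function(d) {
    relative_viability(od[records$dose_uM == d & !is_ctrl], ctrl)
  }, numeric(1))
  data.frame(dose_uM = doses,
             viability_pct = via,
             fa = viability_to_fa(via))
}

#' IC50 from a plate table
#'
#' Composes normalization, fraction-affected conversion and the
#' median-effect fit; the IC50 is the fitted median-effect dose Dm
#' (identically \code{dose_for_effect(fit, 0.5)}).
#'
#' @inheritParams fa_table
#' @param ... passed to [fit_median_effect()] (e.g. \code{clamp}).
#' @return the IC50 in uM, with the full \code{median_effect_fit} attached
#'   as attribute \code{"fit"}.
#' @export
ic50_from_table <- function(records, subtract_blank = FALSE, ...) {
  tab <- fa_table(records, subtract_blank = subtract_blank)
  fit <- fit_median_effect(tab$dose_uM, tab$fa, ...)
  ic50 <- dose_for_effect(fit, 0.5)
  # identical by construction; guards against regressions in either path
  stopifnot(isTRUE(all.equal(ic50, fit$Dm, tolerance = 1e-12)))
  structure(ic50, fit = fit)
}

#' Read a tidy plate CSV
#'
#' One row per well, columns \code{drug}, \code{dose_uM}, \code{replicate},
#' \code{od}; control wells have \code{dose_uM = 0}.
#'
#' @param path CSV file path.
#' @return data.frame of plate records.
#' @export
read_plate_csv <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug", "dose_uM", "od")
  miss <- setdiff(need, names(rec))
  if (length(miss) > 0) {
    stop("plate CSV ", path, " missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(rec$od)) || any(!is.finite(rec$dose_uM))) {
    bad <- which(!is.finite(rec$od) | !is.finite(rec$dose_uM))[1]
    stop("malformed plate CSV ", path, ": non-numeric value in row ", bad,
         call. = FALSE)
  }
  rec
}
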