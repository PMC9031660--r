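#' Define a constant-ratio drug combination
#'
#' A constant-ratio combination keeps the proportion of each component fixed
#' while total dose varies; the canonical design sets the ratio at the IC50
#' of each drug so that each contributes equally to the effect. Given basis
#' doses (e.g. single-agent IC50s) the ratio weights are
#' \code{w_i = basis_i / sum(basis)}.
#'
#' @param drug_names character vector of component names (2 or more;
#'   combinations of more than 3 drugs are accepted but the CI convention
#'   has only been validated against published 2- and 3-drug tables).
#' @param weights ratio fractions, one per drug, strictly positive and
#'   summing to 1. Supply either \code{weights} or \code{basis}.
#' @param basis per-drug reference doses (e.g. IC50s, uM) from which weights
#'   are derived; used when \code{weights} is missing.
#' @return A \code{combination_design} object.
#' @examples
#' combination_design(c("cisplatin", "paclitaxel"), basis = c(22, 0.38))
#' @export
combination_design <- function(drug_names, weights = NULL, basis = NULL) {
  drug_names <- as.character(drug_names)
  k <- length(drug_names)
  if (k < 2) stop("a combination needs at least 2 drugs", call. = FALSE)
  if (anyDuplicated(drug_names)) {
    stop("drug names must be unique", call. = FALSE)
  }
  if (is.null(weights)) {
    if (is.null(basis)) {
      stop("supply either `weights` or `basis` doses", call. = FALSE)
    }
    stopifnot(length(basis) == k, all(basis > 0))
    weights <- basis / sum(basis)
  } else {
    stopifnot(length(weights) == k)
    if (any(weights <= 0)) {
      stop("ratio weights must be strictly positive", call. = FALSE)
    }
    if (abs(sum(weights) - 1) > 1e-12) {
      stop("ratio weights must sum to 1 (within 1e-12)", call. = FALSE)
    }
  }
  structure(
    list(drug_names = drug_names,
         weights = stats::setNames(as.numeric(weights), drug_names),
         basis = if (is.null(basis)) NULL
                 else stats::setNames(as.numeric(basis), drug_names)),
    class = "combination_design"
  )
}

#' @export
print.combination_design <- function(x, ...) {
  cat("Constant-ratio combination:", paste(x$drug_names, collapse = " + "), "\n")
  cat("  weights:", paste(sprintf("%s=%.4g", x$drug_names, x$weights),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Component doses of a mixture at an effect level
#'
#' The mixture, fitted as a composite single agent on total dose, needs
#' total dose Dx_total to reach effect \code{fa}; under the constant-ratio
#' design each drug contributes \code{D_i = w_i * Dx_total}.
#'
#' @param design a \code{combination_design}.
#' @param combo_fit \code{median_effect_fit} of the mixture on total dose.
#' @param fa effect level in (0, 1).
#' @return named numeric vector of per-drug doses summing to Dx_total.
#' @export
component_doses <- function(design, combo_fit, fa) {
  stopifnot(inherits(design, "combination_design"))
  dx_total <- dose_for_effect(combo_fit, fa)
  design$weights * dx_total
}

#' Combination index from component doses
#'
#' The combination index at effect level fa is
#' \code{CI = sum_i D_i / Dx_i(fa)}, where D_i is the dose of drug i inside
#' the combination and Dx_i(fa) the dose of drug i alone producing the same
#' effect (the mutually-exclusive form, without a cross-product term).
#' CI < 1 indicates synergism, CI = 1 an additive effect, CI > 1 antagonism.
#'
#' @param component_doses named numeric vector of in-combination doses
#'   (uM), one per drug, all > 0.
#' @param single_fits named list of \code{median_effect_fit}s, one per drug
#'   in \code{component_doses} (matched by name when both are named).
#' @param fa effect level in (0, 1).
#' @return the combination index (scalar, > 0).
#' @seealso [ci_from_dri()] for the equivalent reciprocal-DRI form,
#'   [dose_reduction_index()].
#' @export
combination_index <- function(component_doses, single_fits, fa) {
  dri <- dose_reduction_index(component_doses, single_fits, fa)
  ci_from_dri(dri)
}

#' Per-drug dose-reduction index
#'
#' DRI_i = Dx_i(fa) / D_i: how many fold the dose of drug i may be reduced
#' in the combination, relative to its single-agent dose at the same effect
#' level. DRI > 1 means a dose reduction is achieved.
#'
#' @inheritParams combination_index
#' @return named numeric vector of DRIs, one per drug.
#' @export
dose_reduction_index <- function(component_doses, single_fits, fa) {
  fits <- match_fits(component_doses, single_fits)
  if (any(component_doses <= 0)) {
    stop("component doses must be strictly positive", call. = FALSE)
  }
  dx <- vapply(fits, dose_for_effect, numeric(1), fa = fa)
  dri <- dx / as.numeric(component_doses)
  stats::setNames(dri, names(component_doses))
}

#' Combination index from dose-reduction indices
#'
#' The algebraic identity \code{CI = sum_i 1 / DRI_i}: the reciprocal sum
#' of the per-drug dose-reduction indices at one effect level. This is the
#' form under which published CI/DRI tables are internally consistent.
#'
#' @param dri numeric vector of per-drug DRIs (all > 0), length = number of
#'   drugs in the combination.
#' @return the combination index.
#' @examples
#' ci_from_dri(c(51.06, 11.89))  # 0.104 after rounding to 3 decimals
#' @export
ci_from_dri <- function(dri) {
  if (any(!is.finite(dri)) || any(dri <= 0)) {
    stop("DRI values must be finite and strictly positive", call. = FALSE)
  }
  sum(1 / dri)
}

#' Reduced dose implied by a dose-reduction index
#'
#' @param reference_dose single-agent reference dose (uM), e.g. an IC50.
#' @param dri dose-reduction index (> 0).
#' @return \code{reference_dose / dri}.
#' @examples
#' reduced_dose(22, 51.06)  # cisplatin 22 uM reduced 51.06-fold -> ~0.43 uM
#' @export
reduced_dose <- function(reference_dose, dri) {
  if (any(!is.finite(dri)) || any(dri <= 0)) {
    stop("DRI must be strictly positive", call. = FALSE)
  }
  reference_dose / dri
}

#' Classify a combination index
#'
#' Strict thresholding at 1: CI < 1 synergism, CI = 1 additive, CI > 1
#' antagonism. An optional symmetric band around 1 classifies near-unity
#' values as "additive" (disabled by default, \code{band = 0}).
#'
#' @param ci combination index value(s), > 0.
#' @param band half-width of the additive band; \code{ci} within
#'   \code{[1 - band, 1 + band]} is called additive. Default 0 (strict).
#' @return character vector: "synergism", "additive" or "antagonism".
#' @export
classify_ci <- function(ci, band = 0) {
  if (any(!is.finite(ci)) || any(ci <= 0)) {
    stop("CI must be finite and strictly positive", call. = FALSE)
  }
  ifelse(ci < 1 - band, "synergism",
         ifelse(ci > 1 + band, "antagonism", "additive"))
}

#' Fa-CI curve of a constant-ratio combination
#'
#' Computes, for each effect level on a grid, the component doses, CI,
#' per-drug DRIs and the synergism classification, giving the table behind
#' an Fa-CI plot.
#'
#' @param design a \code{combination_design}.
#' @param combo_fit \code{median_effect_fit} of the mixture on total dose.
#' @param single_fits named list of per-drug \code{median_effect_fit}s
#'   covering every drug in \code{design}.
#' @param fa_grid effect levels, each in (0, 1); default the reporting
#'   levels 0.50, 0.75, 0.90 (IC50/IC75/IC90).
#' @return data.frame with one row per fa: columns \code{fa}, \code{ci},
#'   \code{classification}, \code{dose_<drug>} and \code{dri_<drug>}.
#'   Every row satisfies \code{ci == sum(1/dri)} by construction.
#' @export
fa_ci_curve <- function(design, combo_fit, single_fits,
                        fa_grid = c(0.50, 0.75, 0.90)) {
  stopifnot(inherits(design, "combination_design"))
  if (any(fa_grid <= 0) || any(fa_grid >= 1)) {
    stop("fa_grid values must lie strictly inside (0, 1)", call. = FALSE)
  }
  rows <- lapply(fa_grid, function(fa) {
    d <- component_doses(design, combo_fit, fa)
    dri <- dose_reduction_index(d, single_fits, fa)
    ci <- ci_from_dri(dri)
    out <- data.frame(fa = fa, ci = ci,
                      classification = classify_ci(ci),
                      stringsAsFactors = FALSE)
    for (nm in design$drug_names) out[[paste0("dose_", nm)]] <- d[[nm]]
    for (nm in design$drug_names) out[[paste0("dri_", nm)]] <- dri[[nm]]
    out
  })
  do.call(rbind, rows)
}

#' Pointwise CI at observed mixture data points
#'
#' Computes the combination index directly at each observed
#' (total dose, fraction affected) pair of a constant-ratio mixture,
#' without interpolating through a fitted composite curve:
#' \code{CI = D_total * sum_i(w_i / Dx_i(fa_obs))}. This is the estimate of
#' choice when the true CI varies with the effect level, since a single
#' median-effect line cannot represent an fa-dependent interaction.
#'
#' @param design a \code{combination_design}.
#' @param dose_total observed total mixture doses (uM, > 0).
#' @param fa_obs observed fractions affected, same length, each in (0, 1).
#' @param single_fits named list of per-drug \code{median_effect_fit}s.
#' @return data.frame with columns \code{dose_total}, \code{fa}, \code{ci},
#'   \code{classification}.
#' @export
ci_at_observations <- function(design, dose_total, fa_obs, single_fits) {
  stopifnot(inherits(design, "combination_design"),
            length(dose_total) == length(fa_obs))
  if (any(dose_total <= 0)) {
    stop("total doses must be strictly positive", call. = FALSE)
  }
  ci <- vapply(seq_along(fa_obs), function(i) {
    d <- design$weights * dose_total[i]
    combination_index(d, single_fits, fa_obs[i])
  }, numeric(1))
  data.frame(dose_total = dose_total, fa = fa_obs, ci = ci,
             classification = classify_ci(ci))
}

# Align a named list of single-drug fits with the component-dose vector;
# positional matching is accepted only when nothing is named.
match_fits <- function(component_doses, single_fits) {
  if (!is.list(single_fits) || inherits(single_fits, "median_effect_fit")) {
    stop("`single_fits` must be a list of median_effect_fit objects",
         call. = FALSE)
  }
  if (length(single_fits) != length(component_doses)) {
    stop("need exactly one single-drug fit per combination component",
         call. = FALSE)
  }
  nms <- names(component_doses)
  if (!is.null(nms) && !is.null(names(single_fits))) {
    missing <- setdiff(nms, names(single_fits))
    if (length(missing) > 0) {
      stop("no single-drug fit for component(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    single_fits <- single_fits[nms]
  }
  ok <- vapply(single_fits, inherits, logical(1), what = "median_effect_fit")
  if (!all(ok)) {
    stop("`single_fits` must contain median_effect_fit objects", call. = FALSE)
  }
  single_fits
}
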