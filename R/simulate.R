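# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Multiplicative log-normal noise with unit median; sd on the natural-log
# scale equals sdlog (plate-reader noise is scale-proportional).
lnoise <- function(n, sdlog) {
  if (sdlog == 0) rep(1, n) else stats::rlnorm(n, meanlog = 0, sdlog = sdlog)
}

#' Ground-truth parameters of a simulated drug
#'
#' @param name drug label.
#' @param m_true true median-effect slope (> 0).
#' @param dm_true true median-effect dose Dm (uM, > 0).
#' @param noise_sd multiplicative (log-normal) absorbance noise sigma;
#'   default 0.02, roughly the well-to-well spread of a careful MTT assay.
#' @return A \code{drug_truth} object.
#' @export
drug_truth <- function(name, m_true, dm_true, noise_sd = 0.02) {
  stopifnot(m_true > 0, dm_true > 0, noise_sd >= 0)
  structure(list(name = name, m_true = m_true, dm_true = dm_true,
                 noise_sd = noise_sd),
            class = "drug_truth")
}

#' Default dose grid bracketing the median-effect dose
#'
#' Log-spaced doses spanning \code{dm / span} to \code{dm * span},
#' mirroring the practice of dosing below and above the expected IC50. The
#' default 4-fold span keeps all wells inside the measurable effect range
#' (roughly 6-94\% inhibition for a slope of 2), where the linearized
#' median-effect fit is well conditioned.
#'
#' @param dm center dose (uM).
#' @param n number of doses, default 8.
#' @param span fold-range on each side of \code{dm}, default 4.
#' @return numeric dose vector.
#' @export
dose_grid <- function(dm, n = 8, span = 4) {
  10^seq(log10(dm / span), log10(dm * span), length.out = n)
}

#' Simulate an MTT plate for one drug
#'
#' Control wells read OD 1.0 x noise; a well treated at dose D reads
#' OD = (1 - fa_true(D)) x noise, where fa_true follows the median-effect
#' law of \code{truth} and noise is multiplicative log-normal with sigma =
#' \code{truth$noise_sd}. Deterministic given \code{seed}.
#'
#' @param truth a [drug_truth()].
#' @param doses treatment doses (uM, > 0); default [dose_grid()] around the
#'   true Dm.
#' @param replicates wells per dose (and control wells), default 3.
#' @param seed integer seed; \code{NULL} uses the current RNG stream.
#' @return data.frame of plate records: \code{drug}, \code{dose_uM},
#'   \code{replicate}, \code{od} (controls at \code{dose_uM = 0}).
#' @export
simulate_plate <- function(truth, doses = dose_grid(truth$dm_true),
                           replicates = 3, seed = NULL) {
  stopifnot(inherits(truth, "drug_truth"), all(doses > 0), replicates >= 1)
  fit <- median_effect_fit(truth$m_true, truth$dm_true)
  fa <- effect_at_dose(fit, doses)
  with_seed(seed, {
    dose_col <- c(rep(0, replicates), rep(doses, each = replicates))
    via <- c(rep(1, replicates), rep(1 - fa, each = replicates))
    od <- via * lnoise(length(via), truth$noise_sd)
    data.frame(drug = truth$name,
               dose_uM = dose_col,
               replicate = rep_len(seq_len(replicates), length(via)),
               od = od)
  })
}

#' Ground truth of a constant-ratio combination
#'
#' @param design a [combination_design()] over the simulated drugs.
#' @param ci_profile true combination index: either a single constant or a
#'   function of fa returning CI(fa) (> 0).
#' @return A \code{combo_truth} object.
#' @export
combo_truth <- function(design, ci_profile = 1) {
  stopifnot(inherits(design, "combination_design"))
  f <- if (is.function(ci_profile)) ci_profile else function(fa) {
    rep(ci_profile, length(fa))
  }
  structure(list(design = design, ci_profile = f), class = "combo_truth")
}

#' Simulate a constant-ratio combination plate
#'
#' Generates mixture wells by inverting the CI definition: at each effect
#' level fa on the grid the total mixture dose is set to
#' \code{D_total(fa) = CI_true(fa) / sum_i(w_i / Dx_i(fa))}, so that the
#' analytic CI of the generated series equals the requested profile. OD
#' noise is applied as in [simulate_plate()].
#'
#' @param drug_truths named list of [drug_truth()]s covering every drug in
#'   the design.
#' @param truth a [combo_truth()].
#' @param fa_grid effect levels at which mixture wells are placed; default
#'   9 levels from 0.1 to 0.9.
#' @param replicates wells per level, default 3.
#' @param noise_sd OD noise sigma for the mixture plate, default 0.02.
#' @param seed integer seed.
#' @param label plate label for the mixture, default the joined drug names.
#' @return data.frame of plate records on total dose (controls at 0).
#' @export
simulate_combination <- function(drug_truths, truth,
                                 fa_grid = seq(0.1, 0.9, by = 0.1),
                                 replicates = 3, noise_sd = 0.02,
                                 seed = NULL, label = NULL) {
  stopifnot(inherits(truth, "combo_truth"))
  design <- truth$design
  if (any(fa_grid <= 0) || any(fa_grid >= 1)) {
    stop("fa_grid values must lie strictly inside (0, 1)", call. = FALSE)
  }
  fits <- lapply(drug_truths, function(t) median_effect_fit(t$m_true, t$dm_true))
  names(fits) <- vapply(drug_truths, `[[`, character(1), "name")
  missing <- setdiff(design$drug_names, names(fits))
  if (length(missing) > 0) {
    stop("no drug_truth for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ci <- truth$ci_profile(fa_grid)
  stopifnot(all(ci > 0))
  d_total <- vapply(seq_along(fa_grid), function(i) {
    dx <- vapply(design$drug_names, function(nm) {
      dose_for_effect(fits[[nm]], fa_grid[i])
    }, numeric(1))
    ci[i] / sum(design$weights / dx)
  }, numeric(1))
  if (is.null(label)) label <- paste(design$drug_names, collapse = "+")
  with_seed(seed, {
    dose_col <- c(rep(0, replicates), rep(d_total, each = replicates))
    via <- c(rep(1, replicates), rep(1 - fa_grid, each = replicates))
    od <- via * lnoise(length(via), noise_sd)
    data.frame(drug = label,
               dose_uM = dose_col,
               replicate = rep_len(seq_len(replicates), length(via)),
               od = od)
  })
}

#' Simulate Annexin-V/PI flow-cytometry events
#'
#' Draws events from four bivariate log-normal clusters (viable, early
#' apoptotic, late apoptotic, necrotic) with multinomial population sizes.
#'
#' @param fractions length-4 vector of population fractions in the order
#'   viable, early, late, necrotic; must sum to 1.
#' @param n_events number of events, default 10000 (a typical acquisition).
#' @param centers 4x2 matrix of cluster centers (annexin, pi intensity);
#'   default puts negatives at 10 and positives at 1000 on each channel.
#' @param spread log10 standard deviation within clusters, default 0.15.
#' @param seed integer seed.
#' @return data.frame with columns \code{annexin}, \code{pi},
#'   \code{population} (the generating label).
#' @export
simulate_flow_events <- function(fractions, n_events = 10000,
                                 centers = NULL, spread = 0.15,
                                 seed = NULL) {
  stopifnot(length(fractions) == 4, all(fractions >= 0), n_events >= 1)
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("population fractions must sum to 1", call. = FALSE)
  }
  if (is.null(centers)) {
    centers <- rbind(viable = c(10, 10), early = c(1000, 10),
                     late = c(1000, 1000), necrotic = c(10, 1000))
  }
  stopifnot(nrow(centers) == 4, ncol(centers) == 2)
  labels <- c("viable", "early", "late", "necrotic")
  with_seed(seed, {
    pop <- sample(4, n_events, replace = TRUE, prob = fractions)
    ann <- 10^(log10(centers[pop, 1]) + stats::rnorm(n_events, 0, spread))
    pi <- 10^(log10(centers[pop, 2]) + stats::rnorm(n_events, 0, spread))
    data.frame(annexin = ann, pi = pi, population = labels[pop])
  })
}

#' Simulate a DNA-content histogram
#'
#' Draws DNA-stain intensities from normal peaks at 2N (G0/G1) and 4N
#' (G2/M) plus a uniform S-phase plateau between them.
#'
#' @param fractions length-3 vector of G0/G1, S, G2/M fractions summing
#'   to 1.
#' @param n_events number of events, default 10000.
#' @param g1_mean center of the 2N peak (intensity units), default 200;
#'   the 4N peak sits at twice this.
#' @param cv coefficient of variation of the peaks, default 0.04.
#' @param seed integer seed.
#' @return numeric vector of DNA intensities.
#' @export
simulate_dna_content <- function(fractions, n_events = 10000,
                                 g1_mean = 200, cv = 0.04, seed = NULL) {
  stopifnot(length(fractions) == 3, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("phase fractions must sum to 1", call. = FALSE)
  }
  with_seed(seed, {
    phase <- sample(3, n_events, replace = TRUE, prob = fractions)
    n1 <- sum(phase == 1); n2 <- sum(phase == 2); n3 <- sum(phase == 3)
    x <- numeric(n_events)
    x[phase == 1] <- stats::rnorm(n1, g1_mean, cv * g1_mean)
    x[phase == 2] <- stats::runif(n2, g1_mean * (1 + 3 * cv),
                                  2 * g1_mean * (1 - 3 * cv))
    x[phase == 3] <- stats::rnorm(n3, 2 * g1_mean, cv * 2 * g1_mean)
    x
  })
}

#' Simulate an exponential growth curve
#'
#' counts = n0 * 2^(t / td) x multiplicative log-normal noise;
#' deterministic given \code{seed}.
#'
#' @param n0 starting cell count (> 0).
#' @param td_hours true doubling time in hours (> 0).
#' @param times observation times in hours, strictly increasing.
#' @param noise_sd multiplicative noise sigma on counts, default 0.
#' @param seed integer seed.
#' @return data.frame with columns \code{time_h}, \code{count}.
#' @export
simulate_growth <- function(n0, td_hours, times = seq(0, 96, by = 24),
                            noise_sd = 0, seed = NULL) {
  stopifnot(n0 > 0, td_hours > 0, all(diff(times) > 0))
  with_seed(seed, {
    counts <- n0 * 2^(times / td_hours) * lnoise(length(times), noise_sd)
    data.frame(time_h = times, count = counts)
  })
}
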