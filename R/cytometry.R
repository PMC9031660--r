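#' Apoptosis quadrant classification of Annexin-V/PI events
#'
#' Assigns each event to one quadrant by strict comparison with the gate
#' thresholds: an intensity strictly greater than its threshold is
#' positive, equal-or-below is negative. Quadrants: viable (Annexin-V-/PI-),
#' early apoptotic (Annexin-V+/PI-), late apoptotic (Annexin-V+/PI+),
#' necrotic (Annexin-V-/PI+). Total apoptosis/necrosis combines the three
#' non-viable quadrants.
#'
#' @param events data.frame with numeric columns \code{annexin} and
#'   \code{pi} (per-event fluorescence intensities, >= 0). An optional
#'   logical \code{singlet} column restricts classification to
#'   scatter-gated single cells.
#' @param gate list or numeric vector with elements \code{annexin} and
#'   \code{pi}: the quadrant thresholds (> 0).
#' @return An \code{apoptosis_summary}: list with percentages
#'   \code{viable_pct}, \code{early_pct}, \code{late_pct},
#'   \code{necrotic_pct} (summing to 100),
#'   \code{total_apoptosis_necrosis_pct}, and \code{n_events}.
#' @export
quadrant_classify <- function(events, gate) {
  if (!all(c("annexin", "pi") %in% names(events))) {
    stop("events need columns `annexin` and `pi`", call. = FALSE)
  }
  if (!is.null(events$singlet)) events <- events[as.logical(events$singlet), ]
  n <- nrow(events)
  if (is.null(n) || n == 0) {
    stop("no events to classify", call. = FALSE)
  }
  gate <- as.list(gate)
  if (is.null(gate$annexin) || is.null(gate$pi) ||
      gate$annexin <= 0 || gate$pi <= 0) {
    stop("gate needs positive `annexin` and `pi` thresholds", call. = FALSE)
  }
  ann_pos <- events$annexin > gate$annexin
  pi_pos <- events$pi > gate$pi
  viable <- sum(!ann_pos & !pi_pos)
  early <- sum(ann_pos & !pi_pos)
  late <- sum(ann_pos & pi_pos)
  necrotic <- sum(!ann_pos & pi_pos)
  pct <- c(viable, early, late, necrotic) / n * 100
  structure(
    list(viable_pct = pct[1], early_pct = pct[2], late_pct = pct[3],
         necrotic_pct = pct[4],
         total_apoptosis_necrosis_pct = pct[2] + pct[3] + pct[4],
         n_events = n),
    class = "apoptosis_summary"
  )
}

#' @export
print.apoptosis_summary <- function(x, ...) {
  cat(sprintf("Apoptosis quadrants (n = %d events)\n", x$n_events))
  cat(sprintf("  viable (A-/PI-):   %6.2f%%\n", x$viable_pct))
  cat(sprintf("  early  (A+/PI-):   %6.2f%%\n", x$early_pct))
  cat(sprintf("  late   (A+/PI+):   %6.2f%%\n", x$late_pct))
  cat(sprintf("  necrotic (A-/PI+): %6.2f%%\n", x$necrotic_pct))
  cat(sprintf("  total apoptosis + necrosis: %.2f%%\n",
              x$total_apoptosis_necrosis_pct))
  invisible(x)
}

#' Suggest a gate threshold at the valley between two modes
#'
#' For a control sample whose negative and positive populations are both
#' present, places the threshold at the minimum of a kernel density
#' estimate (on log10 intensity) between the two largest modes.
#'
#' @param intensity event intensities (> 0).
#' @return suggested threshold on the original intensity scale.
#' @export
suggest_gate_threshold <- function(intensity) {
  intensity <- intensity[is.finite(intensity) & intensity > 0]
  if (length(intensity) < 10) {
    stop("need at least 10 positive intensities to locate a valley",
         call. = FALSE)
  }
  d <- stats::density(log10(intensity))
  y <- d$y
  # interior local maxima of the KDE
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  if (length(peaks) < 2) {
    stop("fewer than two modes found: supply the threshold explicitly",
         call. = FALSE)
  }
  top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
  valley <- top2[1] + which.min(y[top2[1]:top2[2]]) - 1
  10^d$x[valley]
}

#' Cell-cycle fractions from DNA-content intensities
#'
#' Partitions gated events into G0/G1 (inside \code{g1_window}), G2/M
#' (inside \code{g2_window}) and S phase (between the windows). Events
#' below the G1 window or above the G2 window are excluded as debris or
#' doublets and reported separately; phase percentages are taken over the
#' gated (non-debris) events only.
#'
#' @param dna_intensities per-event DNA-stain intensities.
#' @param g1_window numeric length-2, inclusive intensity bounds of the
#'   G0/G1 (2N) peak.
#' @param g2_window numeric length-2, inclusive bounds of the G2/M (4N)
#'   peak; must lie entirely above \code{g1_window} (it sits near twice the
#'   G1 center).
#' @return A \code{cell_cycle_fractions}: list with \code{g0g1_pct},
#'   \code{s_pct}, \code{g2m_pct} (summing to 100 over gated events),
#'   \code{debris_pct} (share of all events excluded) and counts.
#' @export
cell_cycle_fractions <- function(dna_intensities, g1_window, g2_window) {
  stopifnot(length(g1_window) == 2, length(g2_window) == 2)
  g1_window <- sort(g1_window)
  g2_window <- sort(g2_window)
  if (g2_window[1] <= g1_window[2]) {
    stop("g1_window and g2_window must be non-overlapping with G2 above G1",
         call. = FALSE)
  }
  x <- dna_intensities[is.finite(dna_intensities)]
  if (length(x) == 0) stop("no events", call. = FALSE)
  in_g1 <- x >= g1_window[1] & x <= g1_window[2]
  in_g2 <- x >= g2_window[1] & x <= g2_window[2]
  in_s <- x > g1_window[2] & x < g2_window[1]
  gated <- sum(in_g1) + sum(in_s) + sum(in_g2)
  if (gated == 0) {
    stop("no events inside the G1-G2 gating range", call. = FALSE)
  }
  structure(
    list(g0g1_pct = 100 * sum(in_g1) / gated,
         s_pct = 100 * sum(in_s) / gated,
         g2m_pct = 100 * sum(in_g2) / gated,
         debris_pct = 100 * (length(x) - gated) / length(x),
         n_gated = gated,
         n_total = length(x)),
    class = "cell_cycle_fractions"
  )
}

#' @export
print.cell_cycle_fractions <- function(x, ...) {
  cat(sprintf("Cell-cycle fractions (%d gated / %d events)\n",
              x$n_gated, x$n_total))
  cat(sprintf("  G0/G1: %6.2f%%\n  S:     %6.2f%%\n  G2/M:  %6.2f%%\n",
              x$g0g1_pct, x$s_pct, x$g2m_pct))
  cat(sprintf("  debris/doublets excluded: %.2f%%\n", x$debris_pct))
  invisible(x)
}
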