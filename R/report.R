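#' Read and validate a synergy-analysis configuration
#'
#' The configuration is a flat declarative YAML file:
#' \preformatted{
#' seed: 1
#' fa_levels: [0.5, 0.75, 0.9]
#' drugs:
#'   - name: cisplatin
#'     plate_csv: cisplatin.csv        # or simulate: {m: 2, dm: 22}
#' combinations:
#'   - name: Cis + Pac
#'     drugs: [cisplatin, paclitaxel]
#'     plate_csv: mixture.csv          # or simulate: {ci: 0.5}
#' }
#' Each drug supplies either a tidy plate CSV (see [read_plate_csv()]) or a
#' \code{simulate} block with true median-effect parameters. A combination
#' references declared drugs; its constant-ratio weights default to the
#' single-agent IC50 ratio and its mixture plate is either read from CSV or
#' simulated with a stated true CI.
#'
#' @param path YAML file path, or an already-parsed list.
#' @return validated configuration list.
#' @export
read_analysis_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(cfg$drugs) || length(cfg$drugs) == 0) {
    stop("config declares no drugs", call. = FALSE)
  }
  cfg$fa_levels <- if (is.null(cfg$fa_levels)) c(0.50, 0.75, 0.90)
                   else as.numeric(cfg$fa_levels)
  if (any(cfg$fa_levels <= 0) || any(cfg$fa_levels >= 1)) {
    stop("fa_levels must lie strictly inside (0, 1)", call. = FALSE)
  }
  drug_names <- vapply(cfg$drugs, `[[`, character(1), "name")
  if (anyDuplicated(drug_names)) {
    stop("duplicate drug declarations", call. = FALSE)
  }
  for (combo in cfg$combinations) {
    undeclared <- setdiff(unlist(combo$drugs), drug_names)
    if (length(undeclared) > 0) {
      stop("combination '", combo$name, "' references undeclared drug(s): ",
           paste(undeclared, collapse = ", "), call. = FALSE)
    }
  }
  cfg
}

#' Run the full synergy analysis
#'
#' For every declared drug, builds the dose-response table, fits the
#' median-effect law and reports the IC50; for every declared constant-ratio
#' combination, fits the mixture as a composite agent and reports CI,
#' per-drug DRI and the synergism classification at the configured effect
#' levels. Every CI row is audited against the reciprocal-DRI identity
#' before being reported. Deterministic given config + seed.
#'
#' @param config path to a YAML configuration or a configuration list (see
#'   [read_analysis_config()]).
#' @param out_dir if non-NULL, tidy CSV reports (\code{ic50_table.csv}, one
#'   \code{combo_*.csv} per combination) and a \code{warnings.txt} sidecar
#'   are written there.
#' @param base_dir directory against which relative \code{plate_csv} paths
#'   are resolved; defaults to the config file's directory (or "." for list
#'   input).
#' @return list with \code{ic50_table} (drug, m, Dm/IC50, r, n_points),
#'   \code{combo_tables} (named list of [fa_ci_curve()] data.frames with a
#'   leading \code{drug_combination} column), \code{fits}, and
#'   \code{warnings} (character log of excluded-point and other warnings).
#' @export
run_synergy_analysis <- function(config, out_dir = NULL, base_dir = NULL) {
  if (is.character(config) && is.null(base_dir)) base_dir <- dirname(config)
  if (is.null(base_dir)) base_dir <- "."
  cfg <- read_analysis_config(config)
  seed <- if (is.null(cfg$seed)) NULL else as.integer(cfg$seed)
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  fits <- list()
  ic50_rows <- list()
  for (i in seq_along(cfg$drugs)) {
    d <- cfg$drugs[[i]]
    rec <- drug_records(d, base_dir, seed, offset = i)
    tab <- NULL
    withCallingHandlers(
      {
        tab <- fa_table(rec)
        fits[[d$name]] <- fit_median_effect(tab$dose_uM, tab$fa)
      },
      warning = function(w) {
        note("drug %s: %s", d$name, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    f <- fits[[d$name]]
    note("drug %s: %d dose points fitted, %d excluded",
         d$name, f$n_points, f$n_excluded)
    ic50_rows[[i]] <- data.frame(drug = d$name, m = f$m, ic50_uM = f$Dm,
                                 r = f$r, n_points = f$n_points)
  }
  ic50_table <- do.call(rbind, ic50_rows)

  combo_tables <- list()
  for (j in seq_along(cfg$combinations)) {
    cb <- cfg$combinations[[j]]
    members <- unlist(cb$drugs)
    basis <- vapply(members, function(nm) fits[[nm]]$Dm, numeric(1))
    design <- if (is.null(cb$weights)) {
      combination_design(members, basis = basis)
    } else {
      combination_design(members, weights = as.numeric(unlist(cb$weights)))
    }
    rec <- combo_records(cb, design, cfg, base_dir, seed,
                         offset = length(cfg$drugs) + j)
    combo_fit <- NULL
    withCallingHandlers(
      {
        tab <- fa_table(rec)
        combo_fit <- fit_median_effect(tab$dose_uM, tab$fa)
      },
      warning = function(w) {
        note("combination %s: %s", cb$name, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    curve <- fa_ci_curve(design, combo_fit, fits[members],
                         fa_grid = cfg$fa_levels)
    audit_reciprocal_identity(curve, design$drug_names)
    combo_tables[[cb$name]] <- cbind(
      data.frame(drug_combination = cb$name), curve)
    note("combination %s: CI computed at %d effect level(s)",
         cb$name, length(cfg$fa_levels))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(round_report(ic50_table),
                     file.path(out_dir, "ic50_table.csv"), row.names = FALSE)
    for (nm in names(combo_tables)) {
      safe <- gsub("[^A-Za-z0-9]+", "_", nm)
      utils::write.csv(round_report(combo_tables[[nm]]),
                       file.path(out_dir, paste0("combo_", safe, ".csv")),
                       row.names = FALSE)
    }
    writeLines(log, file.path(out_dir, "warnings.txt"))
  }
  list(ic50_table = ic50_table, combo_tables = combo_tables,
       fits = fits, warnings = log)
}

# Every reported CI row must equal the reciprocal DRI sum to 1e-9.
audit_reciprocal_identity <- function(curve, drug_names) {
  dri_cols <- paste0("dri_", drug_names)
  recip <- rowSums(1 / as.matrix(curve[, dri_cols, drop = FALSE]))
  if (any(abs(curve$ci - recip) > 1e-9)) {
    stop("internal audit failed: CI row deviates from reciprocal-DRI sum",
         call. = FALSE)
  }
  invisible(TRUE)
}

# Report rounding convention: CI to 3 decimals, DRI to 2, doses to 4
# significant digits; full precision stays in the returned objects.
round_report <- function(df) {
  for (nm in names(df)) {
    if (nm == "ci") df[[nm]] <- round(df[[nm]], 3)
    else if (startsWith(nm, "dri_")) df[[nm]] <- round(df[[nm]], 2)
    else if (is.numeric(df[[nm]])) df[[nm]] <- signif(df[[nm]], 4)
  }
  df
}

drug_records <- function(d, base_dir, seed, offset) {
  if (!is.null(d$plate_csv)) {
    return(read_plate_csv(resolve_path(d$plate_csv, base_dir)))
  }
  if (is.null(d$simulate)) {
    stop("drug '", d$name, "' has neither plate_csv nor simulate block",
         call. = FALSE)
  }
  s <- d$simulate
  truth <- drug_truth(d$name, m_true = s$m, dm_true = s$dm,
                      noise_sd = if (is.null(s$noise_sd)) 0.02 else s$noise_sd)
  simulate_plate(truth, seed = derive_seed(seed, offset))
}

combo_records <- function(cb, design, cfg, base_dir, seed, offset) {
  if (!is.null(cb$plate_csv)) {
    return(read_plate_csv(resolve_path(cb$plate_csv, base_dir)))
  }
  if (is.null(cb$simulate)) {
    stop("combination '", cb$name,
         "' has neither plate_csv nor simulate block", call. = FALSE)
  }
  truths <- lapply(cfg$drugs[vapply(cfg$drugs, `[[`, character(1), "name")
                             %in% design$drug_names], function(d) {
    s <- d$simulate
    if (is.null(s)) {
      stop("simulated combination '", cb$name,
           "' needs simulate blocks for all member drugs", call. = FALSE)
    }
    drug_truth(d$name, s$m, s$dm,
               if (is.null(s$noise_sd)) 0.02 else s$noise_sd)
  })
  ci <- if (is.null(cb$simulate$ci)) 1 else cb$simulate$ci
  noise <- if (is.null(cb$simulate$noise_sd)) 0.02 else cb$simulate$noise_sd
  simulate_combination(truths, combo_truth(design, ci),
                       noise_sd = noise, seed = derive_seed(seed, offset),
                       label = cb$name)
}

resolve_path <- function(p, base_dir) {
  if (file.exists(p)) p else file.path(base_dir, p)
}

# Deterministic per-component sub-seed, kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483647)
}
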