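# Design rules and literature-device evaluation.
#
# The physics modules condense into a small set of design rules for a trap
# holding a tissue of diameter d: w = 2d (near-optimal settling, safe
# ejection), h = 0.9w (widest operating window), V_M >= 100 V_T (a day of
# unattended metabolism), L below the Damkohler limit, and w <= 1.4d when
# one sample per trap must be guaranteed. The FEM-derived admissible ranges
# around these optima are encoded as constants; the analytically computable
# rules are recomputed live.

# admissible ranges around the optimal design (dimensionless, in units of
# d or w); the settling and window ranges come from full hydrodynamic
# sweeps, the others from the analytical models
.design_rules <- list(
  settling_w_over_d = c(1.2, 6.7),   # settling time near minimum
  window_w_over_d = c(1.1, 3.3),     # ejection possible before damaging shear
  aspect_h_over_w = c(0.6, 1.1),     # trap depth keeping the window open
  single_sample_w_over_d = 1.4,      # at most one sample per trap below this
  vm_over_vt_min = 100               # >= 24 h of optimal metabolism
)

#' Recommend a trap design for a tissue
#'
#' Applies the package's design rules: trap width `w = 2d`, depth
#' `h = 0.9 w`, medium volume `V_M` the larger of `100 V_T` and what the
#' fitted replenishment law requires for the desired schedule, and channel
#' length capped at the Damkohler limit. Warnings flag tissues above the
#' anoxia diameter and traps below the minimum ejectable width.
#'
#' @param tissue a [tissue_sample].
#' @param schedule_h desired medium replenishment interval, hours.
#' @param medium a [medium_properties].
#' @param fit optional [sweep_and_fit_replenishment()] law used to convert
#'   the schedule into a required V_M/V_T; when `NULL` the zero-order law
#'   `t = tau * ratio` is used instead (slightly optimistic, since it
#'   ignores the head start of the tissue core).
#' @param metabolite finite-nutrient parameters for the schedule/channel
#'   calculations.
#' @param oxygen oxygen parameters for the anoxia check.
#' @param tau_max damaging shear-stress threshold, Pa.
#' @return an object of class `design_recommendation` with fields `w`, `h`,
#'   `V_M`, `L_max`, `single_sample_w` (all SI), the implied `ratio`
#'   V_M/V_T, and `warnings`.
#' @export
recommend_design <- function(tissue, schedule_h = 24,
                             medium = medium_properties(), fit = NULL,
                             metabolite = metabolite_preset(),
                             oxygen = metabolite_preset("typical", "oxygen"),
                             tau_max = 1.0) {
  .check_positive(schedule_h, "schedule_h")
  warnings <- character()
  d <- tissue$d
  d_max <- max_viable_diameter(oxygen, tissue$rho_cell)
  if (d > d_max)
    warnings <- c(warnings, sprintf(
      "anoxia: tissue diameter %.0f um exceeds the maximum viable diameter %.0f um; the core will be anoxic even with perfect perfusion",
      d * 1e6, d_max * 1e6))

  w <- 2 * d
  h <- 0.9 * w
  w_min <- minimum_trap_width(medium, tissue$rho_T / medium$rho_M, tau_max)
  if (w < w_min)
    warnings <- c(warnings, sprintf(
      "trap width %.1f um is below the minimum ejectable width %.1f um: tissues would not be extractable by applying flow",
      w * 1e6, w_min * 1e6))

  tau <- .uptake_timescale(metabolite, tissue$rho_cell)
  schedule_s <- schedule_h * 3600
  ratio_schedule <- if (is.null(fit)) schedule_s / tau
                    else (schedule_s - fit$b) / (fit$a * fit$tau)
  if (ratio_schedule < 0)
    stop("schedule shorter than the fitted intercept: no feasible medium volume",
         call. = FALSE)
  ratio <- max(.design_rules$vm_over_vt_min, ratio_schedule)
  V_M <- ratio * tissue$V_T
  L_max <- max_channel_length(metabolite, ratio, tissue$rho_cell)

  structure(list(w = w, h = h, V_M = V_M, ratio = ratio, L_max = L_max,
                 single_sample_w = .design_rules$single_sample_w_over_d * d,
                 d_max = d_max, w_min = w_min,
                 schedule_h = schedule_h, warnings = warnings),
            class = "design_recommendation")
}

#' Check a trap design against the design rules
#'
#' Evaluates each design rule for a (tissue, trap) pairing and reports
#' pass/fail with the violated bound. Required rules guard viability and
#' operability; advisory rows (single-sample bound) only inform.
#'
#' @param tissue a [tissue_sample].
#' @param trap a [trap_geometry].
#' @param medium a [medium_properties].
#' @param oxygen oxygen parameters for the anoxia rule.
#' @param tau_max damaging shear-stress threshold, Pa.
#' @return a `data.frame` with columns `rule`, `ok`, `required`, `detail`.
#' @export
check_design <- function(tissue, trap, medium = medium_properties(),
                         oxygen = metabolite_preset("typical", "oxygen"),
                         tau_max = 1.0) {
  d <- tissue$d; w <- trap$w; h <- trap$h
  r <- .design_rules
  d_max <- max_viable_diameter(oxygen, tissue$rho_cell)
  w_min <- minimum_trap_width(medium, tissue$rho_T / medium$rho_M, tau_max)
  rows <- list(
    list(rule = "anoxia_diameter", ok = d <= d_max, required = TRUE,
         detail = sprintf("d = %.0f um vs d_max = %.0f um", d * 1e6, d_max * 1e6)),
    list(rule = "settling_width", required = TRUE,
         ok = w > r$settling_w_over_d[1] * d & w < r$settling_w_over_d[2] * d,
         detail = sprintf("need %.1fd < w < %.1fd; w/d = %.2f",
                          r$settling_w_over_d[1], r$settling_w_over_d[2], w / d)),
    list(rule = "ejection_window_width", required = TRUE,
         ok = w > r$window_w_over_d[1] * d & w < r$window_w_over_d[2] * d,
         detail = sprintf("need %.1fd < w < %.1fd; w/d = %.2f",
                          r$window_w_over_d[1], r$window_w_over_d[2], w / d)),
    list(rule = "aspect_ratio", required = TRUE,
         ok = h > r$aspect_h_over_w[1] * w & h < r$aspect_h_over_w[2] * w,
         detail = sprintf("need %.1fw < h < %.1fw; h/w = %.2f",
                          r$aspect_h_over_w[1], r$aspect_h_over_w[2], h / w)),
    list(rule = "minimum_trap_width", required = TRUE,
         ok = w > w_min,
         detail = sprintf("w = %.1f um vs w_min = %.1f um", w * 1e6, w_min * 1e6)),
    list(rule = "medium_volume", required = TRUE,
         ok = trap$V_M >= r$vm_over_vt_min * tissue$V_T,
         detail = sprintf("V_M/V_T = %.1f; need >= %d",
                          trap$V_M / tissue$V_T, r$vm_over_vt_min)),
    list(rule = "single_sample", required = FALSE,
         ok = w <= r$single_sample_w_over_d * d,
         detail = sprintf("one sample per trap guaranteed only when w <= %.1fd; w/d = %.2f",
                          r$single_sample_w_over_d, w / d))
  )
  do.call(rbind, lapply(rows, function(x)
    data.frame(rule = x$rule, ok = x$ok, required = x$required,
               detail = x$detail)))
}

#' Density sensitivity of trap operation
#'
#' How settling time, minimum ejectable width and the critical flow rates
#' change with tissue mass density, for a reference 250 um tissue in a
#' 500 um cubic trap (d/w = 0.5). Shear damage is density-independent;
#' everything that moves the sample is not.
#'
#' @param densities tissue mass densities, kg/m^3. Defaults to 1.01, 1.1
#'   and 2 g/cm^3.
#' @param d tissue diameter, m.
#' @param medium a [medium_properties].
#' @param tau_max damaging shear-stress threshold, Pa.
#' @param rho_cell cellular density, cells/m^3.
#' @return a `data.frame` with raw and order-of-magnitude (1 significant
#'   figure) columns for each quantity.
#' @export
density_sensitivity_table <- function(densities = c(1010, 1100, 2000),
                                      d = 250e-6,
                                      medium = medium_properties(),
                                      tau_max = 1.0, rho_cell = 2.8e14) {
  if (any(densities <= medium$rho_M))
    stop("all densities must exceed the medium density", call. = FALSE)
  trap <- trap_geometry(w = 2 * d, h = 2 * d)
  rows <- lapply(densities, function(rho) {
    tis <- tissue_sample(d, rho_T = rho, rho_cell = rho_cell)
    data.frame(
      density_g_cm3 = rho / 1000,
      settling_time_s = settling_time(tis, trap, medium),
      min_width_um = minimum_trap_width(medium, rho / medium$rho_M, tau_max) * 1e6,
      ejection_flow_mL_min = critical_lift_flow(tis, trap, medium) * 6e7,
      shear_flow_mL_min = critical_shear_flow(trap, medium, tau_max) * 6e7)
  })
  out <- do.call(rbind, rows)
  for (col in c("settling_time_s", "min_width_um", "ejection_flow_mL_min",
                "shear_flow_mL_min"))
    out[[paste0(col, "_rounded")]] <- signif(out[[col]], 1)
  out
}

#' Published trap designs used for model validation
#'
#' Loads the packaged transcription of 13 published microfluidic sample
#' trap devices (single cells to 600 um spheroids): trapping mechanism,
#' sample diameter, medium-to-tissue volume ratio and the experimental
#' replenishment interval (`NA` when the device was perfused).
#'
#' @return a `data.frame`, one row per publication.
#' @export
literature_devices <- function() {
  path <- system.file("extdata", "table4_devices.csv", package = "mstdesign")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Evaluate a published device against the replenishment model
#'
#' Computes the modelled replenishment interval for a device's V_M/V_T and
#' classifies its experimental practice: `perfused` (continuous supply,
#' always sufficient), `replenished_within_model` (experimental interval at
#' or below the modelled one), `within_20pct` (experimental interval up to
#' 20% above the model: brief dips below k_M, no significant deprivation),
#' or `under_replenished` (longer than that: metabolism measurably
#' limited).
#'
#' @param device one row of [literature_devices()] (or any list with
#'   `vm_over_vt` and `t_exp_h`).
#' @param fit a [sweep_and_fit_replenishment()] law.
#' @return a list with `t_model_h` and `category`.
#' @export
evaluate_literature_device <- function(device, fit) {
  if (is.null(device$vm_over_vt) || is.na(device$vm_over_vt))
    stop("device is missing its V_M/V_T ratio", call. = FALSE)
  t_model_h <- replenishment_time(fit, device$vm_over_vt) / 3600
  t_exp <- device$t_exp_h
  category <-
    if (is.null(t_exp) || is.na(t_exp)) "perfused"
    else if (t_exp <= t_model_h) "replenished_within_model"
    else if (t_exp <= 1.2 * t_model_h) "within_20pct"
    else "under_replenished"
  list(t_model_h = t_model_h, category = category)
}

#' Evaluate the whole literature table
#'
#' @param devices a `data.frame` as returned by [literature_devices()].
#' @param fit a [sweep_and_fit_replenishment()] law.
#' @return `devices` with `t_model_h` and `category` columns appended.
#' @export
evaluate_literature_table <- function(devices = literature_devices(), fit) {
  res <- lapply(seq_len(nrow(devices)), function(i)
    evaluate_literature_device(devices[i, ], fit))
  devices$t_model_h <- vapply(res, `[[`, numeric(1), "t_model_h")
  devices$category <- vapply(res, `[[`, character(1), "category")
  devices
}

#' Maximum sample size for a replenishment schedule at fixed medium volume
#'
#' Inverts the fitted replenishment law: given a fixed medium volume `V_M`
#' and a desired interval, finds the V_M/V_T ratio delivering that interval
#' and hence the largest spheroid diameter `d = (6 V_M/(pi ratio))^(1/3)`
#' the device can sustain on that schedule.
#'
#' @param V_M fixed available medium volume per trap, m^3.
#' @param schedule_h desired replenishment interval, hours.
#' @param fit a [sweep_and_fit_replenishment()] law.
#' @return diameter, m.
#' @export
max_sample_size_for_schedule <- function(V_M, schedule_h, fit) {
  .check_positive(V_M, "V_M"); .check_positive(schedule_h, "schedule_h")
  stopifnot(inherits(fit, "replenishment_fit"))
  schedule_s <- schedule_h * 3600
  if (schedule_s <= fit$b)
    stop("schedule is shorter than the fitted intercept: no feasible sample size",
         call. = FALSE)
  ratio <- (schedule_s - fit$b) / (fit$a * fit$tau)
  (6 * V_M / (pi * ratio))^(1 / 3)
}

#' @export
print.design_recommendation <- function(x, ...) {
  cat("<design_recommendation>\n")
  cat(sprintf("  trap: w = %.4g um, h = %.4g um (single-sample variant: w <= %.4g um)\n",
              x$w * 1e6, x$h * 1e6, x$single_sample_w * 1e6))
  cat(sprintf("  medium: V_M = %.4g uL (V_M/V_T = %.4g) for a %.3g h schedule\n",
              x$V_M * 1e9, x$ratio, x$schedule_h))
  cat(sprintf("  channel: L <= %.4g mm (Damkohler limit)\n", x$L_max * 1e3))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
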