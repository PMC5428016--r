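# Sedimentation trapping and the critical-flow-rate operating window.
#
# A tissue settles into its trap under the net volume force
# F_V = (rho_T - rho_M) V_T g_eff. Confinement by the trap walls increases
# drag by the wall-correction factor K(d/w); applied channel flow can either
# eject the tissue (lift) or damage it (shear), and the two critical flow
# rates bound the safe operating window.

# upper validity limit of the wall-correction polynomial fit
.LAM_MAX <- 0.9

#' Unconfined Stokes settling velocity
#'
#' Terminal velocity of a sphere settling in an unbounded medium,
#' `v = (1/18) ((rho_T - rho_M)/eta) g_eff d^2`.
#'
#' @param tissue a [tissue_sample].
#' @param medium a [medium_properties].
#' @return velocity, m/s.
#' @export
stokes_settling_velocity <- function(tissue, medium = medium_properties()) {
  drho <- tissue$rho_T - medium$rho_M
  if (drho <= 0)
    stop("rho_T <= rho_M: the sample is neutrally buoyant or floats and never settles",
         call. = FALSE)
  (1 / 18) * (drho / medium$eta) * medium$g_eff * tissue$d^2
}

#' Wall-correction (drag) factor for confined settling
#'
#' The factor by which drag on a sphere settling along the axis of a
#' conduit of width `w` exceeds unbounded Stokes drag, as a function of the
#' confinement ratio `lam = d/w`:
#' `K = (1 - 0.76 lam^5) / (1 - 2.1 lam + 2.1 lam^3 - 1.7 lam^5 + 0.73 lam^6)`.
#' `K(0) = 1` and K increases steeply with confinement. The polynomial fit
#' is valid for `lam < 0.9`.
#'
#' @param lam confinement ratio d/w, in `[0, 0.9)`. Vectorized.
#' @return dimensionless drag factor `K >= 1`.
#' @export
wall_correction_factor <- function(lam) {
  if (any(lam < 0)) stop("confinement ratio d/w must be >= 0", call. = FALSE)
  if (any(lam >= .LAM_MAX))
    stop(sprintf("confinement ratio d/w = %g is outside the validity of the wall-correction fit (d/w < %g)",
                 max(lam), .LAM_MAX), call. = FALSE)
  (1 - 0.76 * lam^5) /
    (1 - 2.1 * lam + 2.1 * lam^3 - 1.7 * lam^5 + 0.73 * lam^6)
}

#' Confined settling velocity in a trap
#'
#' Stokes velocity divided by the wall-correction drag factor at the trap's
#' confinement ratio d/w. Bottom-wall retardation is neglected, so the
#' derived settling time is an upper bound on the true sedimentation time.
#'
#' @inheritParams stokes_settling_velocity
#' @param trap a [trap_geometry].
#' @return a list of class `settling_result` with `v_stokes`, `K`, `v_set`
#'   and `t_settle` (time to settle over the trap depth `h`), SI units.
#' @export
settling_velocity <- function(tissue, trap, medium = medium_properties()) {
  lam <- tissue$d / trap$w
  v_stokes <- stokes_settling_velocity(tissue, medium)
  K <- wall_correction_factor(lam)
  v_set <- v_stokes / K
  structure(list(v_stokes = v_stokes, K = K, lam = lam, v_set = v_set,
                 t_settle = trap$h / v_set),
            class = "settling_result")
}

#' Settling time over the trap depth
#'
#' @inheritParams settling_velocity
#' @return time `h / v_set`, s.
#' @export
settling_time <- function(tissue, trap, medium = medium_properties()) {
  settling_velocity(tissue, trap, medium)$t_settle
}

#' Confinement ratio minimizing settling time
#'
#' For a square trap with fixed `w = h` and varying tissue diameter, the
#' settling time is proportional to `K(lam)/lam^2` with `lam = d/w`: tiny
#' samples settle slowly for lack of weight, large ones for excess wall
#' drag. The minimizer is a pure number, independent of trap scale, density
#' contrast and viscosity. Found by a grid scan plus local refinement.
#'
#' @param lower,upper search bracket for `lam`, within `(0, 0.9)`.
#' @param grid_step resolution of the initial scan.
#' @return the minimizing confinement ratio (about 0.43, inside the 0.3-0.7
#'   range that keeps settling near-minimal).
#' @export
optimal_trap_ratio <- function(lower = 0.05, upper = .LAM_MAX - 1e-6,
                               grid_step = 1e-3) {
  if (lower <= 0 || upper >= .LAM_MAX || lower >= upper)
    stop("search bracket must lie inside (0, 0.9)", call. = FALSE)
  obj <- function(l) wall_correction_factor(l) / l^2
  grid <- seq(lower, upper, by = grid_step)
  i <- which.min(obj(grid))
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  stats::optimize(obj, c(lo, hi), tol = 1e-9)$minimum
}

#' Critical flow rate for damaging shear
#'
#' Channel flow rate at which the maximum shear stress on a trapped tissue
#' reaches the damage threshold `tau_max`:
#' `Q_shear = tau_max w^3 / (9.6 eta)`. The fitted constant 9.6 holds for a
#' cubic trap (`h = w`) holding a tissue with `d/w = 0.5`; a warning is
#' emitted when the trap is clearly outside that regime.
#'
#' @param trap a [trap_geometry].
#' @param medium a [medium_properties].
#' @param tau_max damaging shear-stress threshold, Pa (default 1 Pa, the
#'   physiological damage level).
#' @return flow rate, m^3/s.
#' @export
critical_shear_flow <- function(trap, medium = medium_properties(),
                                tau_max = 1.0) {
  .check_positive(tau_max, "tau_max")
  if (abs(trap$h / trap$w - 1) > 0.15)
    warning(sprintf(
      "Q_shear calibration assumes a cubic trap (h = w); here h/w = %.2f",
      trap$h / trap$w), call. = FALSE)
  tau_max * trap$w^3 / (9.6 * medium$eta)
}

#' Critical flow rate for tissue ejection (lift)
#'
#' Minimum channel flow rate at which hydrodynamic lift exceeds the net
#' weight of a non-adherent trapped tissue:
#' `Q_lift = sqrt(d) w^2 sqrt((4/3) g_eff (rho_T/rho_M - 1))`.
#' Partially adherent tissues require more flow, so this is the
#' conservative (lowest) ejection threshold.
#'
#' @param tissue a [tissue_sample].
#' @inheritParams critical_shear_flow
#' @return flow rate, m^3/s.
#' @export
critical_lift_flow <- function(tissue, trap, medium = medium_properties()) {
  ratio <- tissue$rho_T / medium$rho_M
  if (ratio <= 1)
    stop("rho_T <= rho_M: a buoyant sample has no lift threshold (it is never held down)",
         call. = FALSE)
  sqrt(tissue$d) * trap$w^2 * sqrt((4 / 3) * medium$g_eff * (ratio - 1))
}

#' Minimum trap width for safe ejection
#'
#' Below `w_min = 61 g_eff eta^2 (rho_T/rho_M - 1) / tau_max^2` the shear
#' damage threshold is reached at a lower flow rate than the ejection
#' threshold (Q_shear scales as w^3, Q_lift as w^2), so tissues in smaller
#' traps cannot be flushed out without damage. At `w = w_min`, with the
#' cubic-trap, `d = w/2` calibration, the two critical flows coincide.
#'
#' The conventional coefficient is 61; eliminating d between the two
#' critical-flow expressions gives exactly `9.6^2 * 2/3 = 61.44`, so with
#' `exact = TRUE` the returned width is the exact crossing of the two
#' curves (to machine precision) rather than the rounded convention.
#'
#' @param medium a [medium_properties].
#' @param rho_ratio tissue-to-medium density ratio `rho_T/rho_M` (> 1).
#' @param tau_max damaging shear-stress threshold, Pa.
#' @param exact use the unrounded crossing coefficient 61.44 instead of the
#'   conventional 61.
#' @return width, m.
#' @export
minimum_trap_width <- function(medium = medium_properties(),
                               rho_ratio = 1.02, tau_max = 1.0,
                               exact = FALSE) {
  .check_positive(tau_max, "tau_max")
  if (rho_ratio <= 1)
    stop("rho_ratio must exceed 1 for a settling sample", call. = FALSE)
  coefficient <- if (exact) 9.6^2 * 2 / 3 else 61
  coefficient * medium$g_eff * medium$eta^2 * (rho_ratio - 1) / tau_max^2
}

#' Operating window of a trap design
#'
#' Computes both critical flow rates and classifies the design: a safe
#' ejection window exists when `Q_lift < Q_shear` (tissues can be flushed
#' out before shear damage).
#'
#' @inheritParams critical_lift_flow
#' @param tau_max damaging shear-stress threshold, Pa.
#' @return an object of class `operating_window` with `Q_lift`, `Q_shear`
#'   (m^3/s) and `has_safe_ejection`.
#' @seealso [classify_flow()] for classifying an applied flow rate.
#' @export
operating_window <- function(tissue, trap, medium = medium_properties(),
                             tau_max = 1.0) {
  structure(list(Q_lift = critical_lift_flow(tissue, trap, medium),
                 Q_shear = critical_shear_flow(trap, medium, tau_max),
                 tau_max = tau_max),
            class = "operating_window") -> win
  win$has_safe_ejection <- win$Q_lift < win$Q_shear
  win
}

#' Classify an applied flow rate within an operating window
#'
#' Regimes: `trapped_safe` (below any threshold), `ejected_safe` (tissue is
#' flushed out before shear damage; only possible when the window exists)
#' and `damaging` (shear above `tau_max`). Values exactly on the shear
#' boundary are classified as damaging (conservative for the tissue).
#'
#' @param window an [operating_window()].
#' @param Q applied flow rate, m^3/s (or e.g. `"0.5 mL/min"`). Vectorized
#'   over numeric input.
#' @return character vector of regime labels.
#' @export
classify_flow <- function(window, Q) {
  stopifnot(inherits(window, "operating_window"))
  if (is.character(Q)) Q <- parse_quantity(Q, "flow", "Q")
  if (any(Q < 0)) stop("flow rate must be >= 0", call. = FALSE)
  if (window$has_safe_ejection) {
    ifelse(Q < window$Q_lift, "trapped_safe",
           ifelse(Q < window$Q_shear, "ejected_safe", "damaging"))
  } else {
    # shear damage occurs before ejection: no safe-ejection regime at all
    ifelse(Q < window$Q_shear, "trapped_safe", "damaging")
  }
}

#' @export
print.operating_window <- function(x, ...) {
  cat("<operating_window>\n")
  cat(sprintf("  Q_lift  %.4g m3/s (%.4g mL/min)\n",
              x$Q_lift, x$Q_lift * 6e7))
  cat(sprintf("  Q_shear %.4g m3/s (%.4g mL/min) at tau_max = %g Pa\n",
              x$Q_shear, x$Q_shear * 6e7, x$tau_max))
  cat(if (x$has_safe_ejection)
    "  safe ejection window exists (Q_lift < Q_shear)\n"
    else "  NO safe ejection: shear damage before lift\n")
  invisible(x)
}

#' @export
print.settling_result <- function(x, ...) {
  cat(sprintf("<settling_result: d/w = %.3g, K = %.4g, v_set = %.4g m/s, t_settle = %.4g s>\n",
              x$lam, x$K, x$v_set, x$t_settle))
  invisible(x)
}
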