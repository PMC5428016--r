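# Michaelis-Menten nutrient uptake and finite-nutrient depletion.
#
# Oxygen reaches the tissue continuously (through gas-permeable device
# walls); its supply limit is the anoxia diameter d_max. Finite nutrients
# (glucose) exist only in the loaded medium volume V_M and are consumed by
# the tissue with Michaelis-Menten kinetics; the time for the minimum
# concentration inside the tissue to fall to k_M sets the medium
# replenishment interval. The 3D trap-plus-channel problem is reduced to a
# concentric sphere-in-shell geometry with matched volumes, solved by a
# conservative finite-volume method of lines; a Damkohler-number check
# guards the reduction (valid only outside the diffusion-limited regime).

#' Michaelis-Menten volumetric uptake rate
#'
#' Saturating uptake kinetics `q(c) = q_max c / (c + k_M)` per cell, scaled
#' by the cellular density to a volumetric sink. At `c = k_M` uptake is
#' half-maximal, which is the threshold below which concentration limits
#' metabolism.
#'
#' @param c local concentration, mM. Vectorized.
#' @param metabolite a [metabolite_params].
#' @param rho_cell cellular density, cells/m^3.
#' @return volumetric uptake, mol/(m^3 s) (recall 1 mM = 1 mol/m^3).
#' @export
mm_uptake_rate <- function(c, metabolite, rho_cell = 2.8e14) {
  if (any(c < 0)) stop("concentration must be >= 0", call. = FALSE)
  metabolite$q_max * rho_cell * c / (c + metabolite$k_M)
}

#' Maximum viable (anoxia-limited) tissue diameter
#'
#' Largest spherical tissue whose core stays oxygenated when oxygen is
#' supplied from an effectively infinite surrounding medium:
#' `d_max = 2 sqrt( 3/(q_max rho_cell) * (1/(2 D_T c_sat_T) + 1/(D_M c_sat_M))^-1 )`.
#' With typical literature oxygen parameters this is about 0.5 mm, which
#' caps the sample sizes the trap models consider.
#'
#' @param oxygen a [metabolite_params] for oxygen (needs both saturation
#'   concentrations).
#' @param rho_cell cellular density, cells/m^3.
#' @return diameter, m.
#' @export
max_viable_diameter <- function(oxygen = metabolite_preset("typical", "oxygen"),
                                rho_cell = 2.8e14) {
  if (is.null(oxygen$c_sat_M) || is.null(oxygen$c_sat_T))
    stop("oxygen parameters must include c_sat_M and c_sat_T", call. = FALSE)
  resist <- 1 / (2 * oxygen$D_T * oxygen$c_sat_T) +
    1 / (oxygen$D_M * oxygen$c_sat_M)
  2 * sqrt(3 / (oxygen$q_max * rho_cell) / resist)
}

# characteristic zero-order uptake time c0/(q_max rho_cell), seconds
.uptake_timescale <- function(metabolite, rho_cell) {
  metabolite$c0 / (metabolite$q_max * rho_cell)
}

#' Depletion time for a well-mixed medium pool
#'
#' Ignores all gradients: the tissue and its medium share one uniform
#' concentration governed by
#' `dc/dt = -(V_T/(V_M + V_T)) q_max rho_cell c/(c + k_M)`, starting at c0.
#' The separable ODE has the exact implicit solution
#' `t(c) = ((c0 - c) + k_M log(c0/c)) (V_M + V_T)/(q_max rho_cell V_T)`,
#' evaluated at the metabolic threshold `c = k_M`. For `c0 >> k_M` this is
#' within a few percent of the zero-order estimate
#' `c0 (V_M + V_T)/(q_max rho_cell V_T)`.
#'
#' @param tissue a [tissue_sample].
#' @param V_M available medium volume, m^3.
#' @param metabolite a [metabolite_params] with `c0 > k_M`.
#' @return a list of class `depletion_result` with `t_threshold` (s), the
#'   zero-order estimate `t_zero_order`, and `method = "well_mixed"`.
#' @export
depletion_time_well_mixed <- function(tissue, V_M,
                                      metabolite = metabolite_preset()) {
  if (V_M < 0) stop("V_M must be >= 0", call. = FALSE)
  c0 <- metabolite$c0; kM <- metabolite$k_M
  pool_factor <- (V_M + tissue$V_T) / tissue$V_T
  qrho <- metabolite$q_max * tissue$rho_cell
  if (c0 <= kM) {
    warning("c0 <= k_M: metabolism is limited from the start (t = 0)",
            call. = FALSE)
    t_thr <- 0
  } else {
    t_thr <- ((c0 - kM) + kM * log(c0 / kM)) * pool_factor / qrho
  }
  structure(list(t_threshold = t_thr,
                 t_zero_order = c0 * pool_factor / qrho,
                 ratio = V_M / tissue$V_T,
                 method = "well_mixed"),
            class = "depletion_result")
}

# Build the sphere-in-shell finite-volume grid. Tissue: uniform cells up to
# R_T; shell: geometrically stretched cells from the interface (first cell
# matches the tissue spacing) out to R_out. The interface falls exactly on
# a face, so tissue and medium control volumes never mix materials.
.fv_grid <- function(R_T, R_out, n_tissue, n_shell) {
  if (n_tissue < 4 || n_shell < 4)
    stop("grid too coarse: need at least 4 cells per region", call. = FALSE)
  h0 <- R_T / n_tissue
  span <- R_out - R_T
  if (span < 2 * h0)
    stop("medium shell thinner than 2 tissue cells; increase V_M or coarsen the tissue grid",
         call. = FALSE)
  # growth factor g solving h0 (g^n - 1)/(g - 1) = span
  f <- function(g) h0 * (g^n_shell - 1) / (g - 1) - span
  g <- if (f(1 + 1e-9) >= 0) 1 + 1e-9 else stats::uniroot(f, c(1 + 1e-9, 10))$root
  faces <- c(seq(0, R_T, length.out = n_tissue + 1),
             R_T + h0 * cumsum(g^(0:(n_shell - 1))))
  faces[length(faces)] <- R_out
  n <- n_tissue + n_shell
  list(n = n, n_tissue = n_tissue, faces = faces,
       r = 0.5 * (faces[-1] + faces[-(n + 1)]),
       vol = 4 / 3 * pi * diff(faces^3),
       area = 4 * pi * faces[2:n]^2,          # interior faces
       half = 0.5 * diff(faces))              # cell half-widths
}

#' Depletion time by sphere-in-shell diffusion-reaction solving
#'
#' Solves the radially symmetric diffusion-reaction problem for a finite
#' nutrient: a tissue sphere of diameter `tissue$d` (diffusivity `D_T`,
#' Michaelis-Menten sink) centred in a concentric medium shell of volume
#' `V_M` (diffusivity `D_M`, no sink), with concentration and flux
#' continuity at the interface, a no-flux outer boundary (one trap's share
#' of medium exchanges nothing with its neighbours' shares), and a uniform
#' initial concentration `c0`. Discretized with a conservative finite-volume
#' method of lines (uniform cells in the tissue, geometrically stretched
#' cells in the shell starting at the tissue spacing) and integrated with a
#' stiff adaptive solver; the run stops by root-finding exactly when the
#' minimum concentration in the tissue reaches `k_M`.
#'
#' @inheritParams depletion_time_well_mixed
#' @param n_tissue,n_shell number of radial cells in each region.
#' @param rtol,atol integrator tolerances.
#' @return a list of class `depletion_result` with `t_threshold` (s), the
#'   final radial profile (`data.frame` with `radius_um`, `conc_mM`),
#'   `min_location` (radius of the concentration minimum, m),
#'   `mass_balance_error` (relative conservation drift) and the full
#'   time-radius concentration history (`times`, `r`, `conc` matrix).
#' @export
depletion_time_pde <- function(tissue, V_M, metabolite = metabolite_preset(),
                               n_tissue = 100, n_shell = 100,
                               rtol = 1e-8, atol = 1e-8) {
  .check_positive(V_M, "V_M")
  c0 <- metabolite$c0; kM <- metabolite$k_M
  if (c0 <= kM)
    stop("c0 <= k_M: no depletion problem to solve", call. = FALSE)
  R_T <- tissue$d / 2
  R_out <- (R_T^3 + 3 * V_M / (4 * pi))^(1 / 3)
  gr <- .fv_grid(R_T, R_out, n_tissue, n_shell)
  qrho <- metabolite$q_max * tissue$rho_cell
  tis <- seq_len(gr$n_tissue)
  Dcell <- c(rep(metabolite$D_T, gr$n_tissue),
             rep(metabolite$D_M, gr$n - gr$n_tissue))
  # distance-weighted harmonic-mean diffusivity at interior faces keeps the
  # flux continuous across the tissue/medium interface
  Dface <- (gr$half[-gr$n] + gr$half[-1]) /
    (gr$half[-gr$n] / Dcell[-gr$n] + gr$half[-1] / Dcell[-1])
  dr <- diff(gr$r)
  coef_face <- Dface * gr$area / dr     # mol/s per unit concentration jump

  rhs <- function(t, c, p) {
    flux <- -coef_face * diff(c)               # outward flux at interior faces
    dc <- -diff(c(0, flux, 0)) / gr$vol        # no-flux at r = 0 and R_out
    sink <- qrho * c[tis] / (c[tis] + kM)
    dc[tis] <- dc[tis] - sink
    list(dc, uptake_rate = sum(sink * gr$vol[tis]))
  }
  rootfun <- function(t, c, p) min(c[tis]) - kM

  # generous horizon: zero-order full-depletion time + margin
  horizon <- 1.3 * c0 * (V_M + tissue$V_T) / (qrho * tissue$V_T)
  times <- seq(0, horizon, length.out = 500)
  out <- deSolve::lsodar(y = rep(c0, gr$n), times = times, func = rhs,
                         parms = NULL, rootfunc = rootfun,
                         jactype = "bandint", bandup = 1, banddown = 1,
                         rtol = rtol, atol = atol)
  t_end <- unname(out[nrow(out), 1])
  istate <- attr(out, "istate")
  if (is.null(istate) || istate[1] < 0)
    stop("diffusion-reaction integration failed to converge; try finer tolerances",
         call. = FALSE)
  if (t_end >= horizon * 0.999)
    stop("threshold not reached within the integration horizon", call. = FALSE)

  conc <- out[, 1 + seq_len(gr$n), drop = FALSE]
  final <- conc[nrow(conc), ]
  # conservation audit: inventory + time-integrated uptake vs initial stock
  ts <- out[, 1]; up <- out[, "uptake_rate"]
  up_int <- sum(0.5 * (up[-1] + up[-length(up)]) * diff(ts))
  inv0 <- c0 * sum(gr$vol)
  mbe <- abs((sum(final * gr$vol) + up_int - inv0) / inv0)

  structure(list(t_threshold = t_end,
                 profile = data.frame(radius_um = gr$r * 1e6,
                                      conc_mM = as.numeric(final)),
                 min_location = gr$r[which.min(final[tis])],
                 mass_balance_error = mbe,
                 times = ts, r = gr$r, conc = conc,
                 ratio = V_M / tissue$V_T,
                 method = "pde"),
            class = "depletion_result")
}

#' @export
print.depletion_result <- function(x, ...) {
  cat(sprintf("<depletion_result (%s): t_threshold = %.4g h at V_M/V_T = %.4g>\n",
              x$method, x$t_threshold / 3600, x$ratio))
  if (!is.null(x$mass_balance_error))
    cat(sprintf("  mass balance drift %.2g\n", x$mass_balance_error))
  invisible(x)
}

#' Sweep medium volumes and fit the linear replenishment law
#'
#' Runs [depletion_time_pde()] over a range of medium-to-tissue volume
#' ratios and fits the replenishment law
#' `t = a (c0/(q_max rho_cell)) (V_M/V_T) + b` by least squares. The slope
#' `a` is slightly below 1 because the tissue core reaches `k_M` before the
#' pool as a whole is exhausted. Sweep points in the diffusion-limited
#' regime (Damkohler number >= 1, using the shell thickness as the
#' diffusion length) are excluded with a warning.
#'
#' @param tissue a [tissue_sample]; the default 375 um spheroid stresses
#'   depletion more than smaller samples.
#' @param metabolite a [metabolite_params] for the finite nutrient.
#' @param ratios vector of V_M/V_T ratios to sweep (default 12 log-spaced
#'   points over 10-1000).
#' @param ... passed to [depletion_time_pde()].
#' @return an object of class `replenishment_fit` with `a`, `b` (s),
#'   `r_squared`, the sweep `data.frame` and the uptake timescale `tau`
#'   (s) = c0/(q_max rho_cell).
#' @export
sweep_and_fit_replenishment <- function(tissue = tissue_sample(375e-6),
                                        metabolite = metabolite_preset(),
                                        ratios = exp(seq(log(10), log(1000),
                                                         length.out = 12)),
                                        ...) {
  if (length(ratios) < 3) stop("need at least 3 sweep points", call. = FALSE)
  tau <- .uptake_timescale(metabolite, tissue$rho_cell)
  R_T <- tissue$d / 2
  keep <- rep(TRUE, length(ratios))
  t_thr <- numeric(length(ratios))
  for (i in seq_along(ratios)) {
    V_M <- ratios[i] * tissue$V_T
    # diffusion length = shell thickness; uptake time = tau * ratio
    L_shell <- (R_T^3 + 3 * V_M / (4 * pi))^(1 / 3) - R_T
    Da0 <- (L_shell^2 / (8 * metabolite$D_M)) / (tau * ratios[i])
    if (Da0 >= 1) {
      warning(sprintf(
        "V_M/V_T = %.3g is diffusion-limited (Da0 = %.2g >= 1); excluded from the fit",
        ratios[i], Da0), call. = FALSE)
      keep[i] <- FALSE
      t_thr[i] <- NA_real_
      next
    }
    t_thr[i] <- depletion_time_pde(tissue, V_M, metabolite, ...)$t_threshold
  }
  if (sum(keep) < 3)
    stop("fewer than 3 sweep points outside the diffusion-limited regime",
         call. = FALSE)
  sweep <- data.frame(ratio = ratios, t_threshold_s = t_thr,
                      t_threshold_h = t_thr / 3600, included = keep)
  x <- tau * ratios[keep]
  fit <- stats::lm(t_thr[keep] ~ x)
  structure(list(a = unname(stats::coef(fit)[2]),
                 b = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 sweep = sweep, tau = tau,
                 tissue = tissue, metabolite = metabolite),
            class = "replenishment_fit")
}

#' Evaluate the fitted replenishment law
#'
#' Conservative medium replenishment interval
#' `t_rep = a (c0/(q_max rho_cell)) (V_M/V_T) + b` for a given volume ratio.
#'
#' @param fit a [sweep_and_fit_replenishment()] result.
#' @param ratio medium-to-tissue volume ratio V_M/V_T (> 0). Vectorized.
#' @return replenishment time, s.
#' @export
replenishment_time <- function(fit, ratio) {
  stopifnot(inherits(fit, "replenishment_fit"))
  if (any(ratio < 0)) stop("V_M/V_T ratio must be >= 0", call. = FALSE)
  rng <- range(fit$sweep$ratio[fit$sweep$included])
  if (any(ratio > 3 * rng[2] | (ratio > 0 & ratio < rng[1] / 3)))
    warning("evaluating the replenishment law well outside its fitted range",
            call. = FALSE)
  fit$a * fit$tau * ratio + fit$b
}

#' @export
print.replenishment_fit <- function(x, ...) {
  cat(sprintf("<replenishment_fit: t = a tau (V_M/V_T) + b>\n"))
  cat(sprintf("  a = %.4g, b = %.4g h, r^2 = %.6f, tau = %.4g s (%s)\n",
              x$a, x$b / 3600, x$r_squared, x$tau, x$metabolite$name))
  cat(sprintf("  fitted over V_M/V_T in [%.3g, %.3g] (%d points)\n",
              min(x$sweep$ratio[x$sweep$included]),
              max(x$sweep$ratio[x$sweep$included]),
              sum(x$sweep$included)))
  invisible(x)
}

#' Zero-order Damkohler number of the channel
#'
#' Ratio of the diffusion time across the inter-trap channel,
#' `t_diff = L^2/(8 D_M)`, to the total nutrient uptake time,
#' `t_up = c0 V_M / (q_max rho_cell V_T)`. The sphere-in-shell depletion
#' model and the linear replenishment law hold only for `Da0 < 1`
#' (uptake-limited, not diffusion-limited).
#'
#' @param L inter-trap channel length, m.
#' @param metabolite a [metabolite_params].
#' @param ratio medium-to-tissue volume ratio V_M/V_T.
#' @param rho_cell cellular density, cells/m^3.
#' @return dimensionless Da0.
#' @export
damkohler_number <- function(L, metabolite = metabolite_preset(),
                             ratio = 100, rho_cell = 2.8e14) {
  .check_positive(L, "L"); .check_positive(ratio, "ratio")
  t_diff <- L^2 / (8 * metabolite$D_M)
  t_up <- metabolite$c0 * ratio / (metabolite$q_max * rho_cell)
  t_diff / t_up
}

#' Maximum channel length outside the diffusion-limited regime
#'
#' Inverts the Damkohler criterion `Da0 = 1`:
#' `L_max = sqrt(8 c0 D_M (V_M/V_T) / (q_max rho_cell))`.
#'
#' @inheritParams damkohler_number
#' @return length, m.
#' @export
max_channel_length <- function(metabolite = metabolite_preset(),
                               ratio = 100, rho_cell = 2.8e14) {
  .check_positive(ratio, "ratio")
  sqrt(8 * metabolite$c0 * metabolite$D_M * ratio /
         (metabolite$q_max * rho_cell))
}
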