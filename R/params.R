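# Parameter containers and presets.
#
# Internal unit system: SI throughout, with concentrations carried in
# mol/m^3 (numerically equal to mM), cell densities in cells/m^3 and
# uptake rates in mol/(cell s). All constructors validate their inputs.

#' Transport and uptake parameters for one metabolite
#'
#' Bundles the Michaelis-Menten uptake kinetics and the diffusion/solubility
#' constants of a single nutrient (typically glucose or oxygen).
#'
#' @param name metabolite identifier, e.g. `"glucose"`.
#' @param q_max maximum cellular uptake rate, mol/(cell s).
#' @param k_M Michaelis-Menten (half-saturation) constant, mM.
#' @param D_M diffusion constant in the culture medium, m^2/s.
#' @param D_T diffusion constant in the tissue, m^2/s.
#' @param c_sat_M saturation concentration in the medium, mM.
#' @param c_sat_T saturation concentration in the tissue, mM.
#' @param c0 initial (reservoir) concentration, mM.
#' @return an object of class `metabolite_params`.
#' @export
metabolite_params <- function(name, q_max, k_M, D_M, D_T,
                              c_sat_M, c_sat_T, c0) {
  .check_positive(q_max, "q_max"); .check_positive(k_M, "k_M")
  .check_positive(D_M, "D_M"); .check_positive(D_T, "D_T")
  .check_positive(c_sat_M, "c_sat_M"); .check_positive(c_sat_T, "c_sat_T")
  .check_positive(c0, "c0")
  if (k_M >= c0)
    warning(sprintf(
      "k_M (%g mM) >= c0 (%g mM): the depletion problem is degenerate",
      k_M, c0), call. = FALSE)
  structure(list(name = as.character(name), q_max = q_max, k_M = k_M,
                 D_M = D_M, D_T = D_T, c_sat_M = c_sat_M, c_sat_T = c_sat_T,
                 c0 = c0),
            class = "metabolite_params")
}

#' Spherical tissue sample
#'
#' A spherical 3D tissue model (single cell, spheroid or micro-dissected
#' tissue) characterized by its diameter, mass density and cellular density.
#'
#' @param d diameter, m (or a string such as `"250 um"`).
#' @param rho_T volumetric mass density, kg/m^3 (or e.g. `"1.02 g/cm3"`).
#' @param rho_cell cellular density, cells/m^3 (or e.g. `"2.8e5 cells/uL"`).
#' @return an object of class `tissue_sample` with derived volume `V_T`.
#' @export
tissue_sample <- function(d, rho_T = 1020, rho_cell = 2.8e14) {
  d <- parse_quantity(d, "length", "d")
  rho_T <- parse_quantity(rho_T, "density", "rho_T")
  rho_cell <- parse_quantity(rho_cell, "cell_density", "rho_cell")
  .check_positive(d, "d"); .check_positive(rho_T, "rho_T")
  .check_positive(rho_cell, "rho_cell")
  structure(list(d = d, rho_T = rho_T, rho_cell = rho_cell,
                 V_T = tissue_volume(d)),
            class = "tissue_sample")
}

#' Culture medium properties
#'
#' @param rho_M medium density, kg/m^3.
#' @param eta dynamic viscosity, Pa s.
#' @param g_eff effective volume-force acceleration, m/s^2. Gravity by
#'   default; any other volume force (e.g. centrifugal) enters here.
#' @return an object of class `medium_properties`.
#' @export
medium_properties <- function(rho_M = 1000, eta = 1e-3, g_eff = 9.81) {
  rho_M <- parse_quantity(rho_M, "density", "rho_M")
  eta <- parse_quantity(eta, "viscosity", "eta")
  g_eff <- parse_quantity(g_eff, "acceleration", "g_eff")
  .check_positive(rho_M, "rho_M"); .check_positive(eta, "eta")
  if (!is.numeric(g_eff) || g_eff < 0) stop("'g_eff' must be >= 0", call. = FALSE)
  structure(list(rho_M = rho_M, eta = eta, g_eff = g_eff),
            class = "medium_properties")
}

#' Trap and channel geometry
#'
#' A square-cross-section trap (well) of width `w` and depth `h` adjacent to
#' a channel of cross-section `A`; `L` is the inter-trap channel length. The
#' available medium volume per trap `V_M` defaults to `A * L`.
#'
#' @param w trap width (square side), m.
#' @param h trap depth, m.
#' @param L inter-trap channel length, m.
#' @param A channel cross-section area, m^2 (default `w * h`).
#' @param V_M available medium volume per trap, m^3 (default `A * L`).
#' @return an object of class `trap_geometry`.
#' @export
trap_geometry <- function(w, h = w, L = 4 * w, A = NULL, V_M = NULL) {
  w <- parse_quantity(w, "length", "w")
  h <- parse_quantity(h, "length", "h")
  L <- parse_quantity(L, "length", "L")
  .check_positive(w, "w"); .check_positive(h, "h"); .check_positive(L, "L")
  if (is.null(A)) A <- w * h else A <- parse_quantity(A, "area", "A")
  .check_positive(A, "A")
  if (is.null(V_M)) V_M <- A * L else V_M <- parse_quantity(V_M, "volume", "V_M")
  .check_positive(V_M, "V_M")
  structure(list(w = w, h = h, L = L, A = A, V_M = V_M),
            class = "trap_geometry")
}

#' Sphere volume of a tissue of diameter d
#'
#' @param d diameter, m.
#' @return volume `pi * d^3 / 6`, m^3.
#' @export
tissue_volume <- function(d) {
  .check_positive(d, "d")
  pi * d^3 / 6
}

.load_presets <- function() {
  path <- system.file("extdata", "uptake_presets.json", package = "mstdesign")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Preset uptake/transport parameters for one metabolite
#'
#' Returns the literature parameter column (`minimum`, `maximum` or
#' `typical`) for glucose or oxygen, converted to internal SI units.
#' Typical values are for the EMT6/Ro cell line.
#'
#' @param preset one of `"typical"`, `"minimum"`, `"maximum"`.
#' @param metabolite one of `"glucose"`, `"oxygen"`.
#' @return a [metabolite_params] object.
#' @export
metabolite_preset <- function(preset = "typical", metabolite = "glucose") {
  preset <- match.arg(preset, c("typical", "minimum", "maximum"))
  metabolite <- match.arg(metabolite, c("glucose", "oxygen"))
  p <- .load_presets()[[metabolite]]
  pick <- function(x) if (is.list(x) || length(x) > 1) x[[preset]] else x
  if (metabolite == "glucose") {
    c0 <- pick(p$c0_mM)
    metabolite_params("glucose",
                      q_max = pick(p$q_max_mol_per_cell_s),
                      k_M = pick(p$k_M_mM),
                      D_M = pick(p$D_M_cm2_s) * 1e-4,
                      D_T = pick(p$D_T_cm2_s) * 1e-4,
                      # glucose does not partition: single aqueous phase
                      c_sat_M = c0, c_sat_T = c0, c0 = c0)
  } else {
    metabolite_params("oxygen",
                      q_max = pick(p$q_max_mol_per_cell_s),
                      k_M = pick(p$k_M_mM),
                      D_M = pick(p$D_M_cm2_s) * 1e-4,
                      D_T = pick(p$D_T_cm2_s) * 1e-4,
                      c_sat_M = pick(p$c_sat_M_mM),
                      c_sat_T = pick(p$c_sat_T_mM),
                      c0 = pick(p$c_sat_M_mM))
  }
}

#' Default parameter bundle
#'
#' Assembles a complete model parameter bundle from the literature presets:
#' both metabolites at the requested preset column, a default tissue
#' (250 um diameter, 1.02 g/cm^3, preset cellular density), water-like
#' medium, a rule-of-thumb trap (w = 2d, h = 0.9w) and the 1 Pa shear
#' damage threshold.
#'
#' @param preset one of `"typical"`, `"minimum"`, `"maximum"`.
#' @param metabolite which metabolite the bundle's `$metabolite` slot points
#'   at; both are always present under `$metabolites`.
#' @return an object of class `mst_params`.
#' @examples
#' p <- default_parameters("typical", "oxygen")
#' p$metabolite$q_max   # 7.4e-17 mol/(cell s)
#' @export
default_parameters <- function(preset = "typical", metabolite = "glucose") {
  preset <- match.arg(preset, c("typical", "minimum", "maximum"))
  metabolite <- match.arg(metabolite, c("glucose", "oxygen"))
  rho_cell_uL <- .load_presets()$rho_cell_cells_per_uL[[preset]]
  tissue <- tissue_sample(d = 250e-6, rho_T = 1020,
                          rho_cell = rho_cell_uL * 1e9)
  mets <- list(glucose = metabolite_preset(preset, "glucose"),
               oxygen = metabolite_preset(preset, "oxygen"))
  trap <- trap_geometry(w = 2 * tissue$d, h = 0.9 * 2 * tissue$d,
                        V_M = 100 * tissue$V_T)
  structure(list(preset = preset,
                 tissue = tissue,
                 medium = medium_properties(),
                 trap = trap,
                 tau_max = 1.0,
                 metabolites = mets,
                 metabolite = mets[[metabolite]]),
            class = "mst_params")
}

# apply one config section's overrides onto a constructor call
.field <- function(section, name, kind, default) {
  if (!is.null(section[[name]])) parse_quantity(section[[name]], kind, name)
  else default
}

#' Load a parameter bundle from a YAML/JSON config
#'
#' Reads a configuration document with optional sections `tissue`, `medium`,
#' `trap` and `metabolites.{glucose,oxygen}`. Every field is optional;
#' missing values fall back to the `"typical"` presets. Values may be bare
#' numbers (internal SI units) or `"value unit"` strings such as `"250 um"`
#' or `"1.01 g/cm3"`.
#'
#' @param config a file path (`.yaml`/`.yml`/`.json`) or an already-parsed
#'   list.
#' @return an object of class `mst_params`.
#' @export
load_parameters <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("config file '%s' not found", config), call. = FALSE)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("config must be a file path or a list", call. = FALSE)
  base <- default_parameters("typical")

  ts <- config$tissue
  tissue <- tissue_sample(
    d = .field(ts, "d", "length", base$tissue$d),
    rho_T = .field(ts, "rho_T", "density", base$tissue$rho_T),
    rho_cell = .field(ts, "rho_cell", "cell_density", base$tissue$rho_cell))

  ms <- config$medium
  medium <- medium_properties(
    rho_M = .field(ms, "rho_M", "density", base$medium$rho_M),
    eta = .field(ms, "eta", "viscosity", base$medium$eta),
    g_eff = .field(ms, "g_eff", "acceleration", base$medium$g_eff))
  tau_max <- .field(ms, "tau_max", "stress", base$tau_max)

  tr <- config$trap
  w <- .field(tr, "w", "length", 2 * tissue$d)
  h <- .field(tr, "h", "length", 0.9 * w)
  L <- .field(tr, "L", "length", 4 * w)
  A <- if (!is.null(tr$A)) parse_quantity(tr$A, "area", "A") else w * h
  V_M <- if (!is.null(tr$V_M)) parse_quantity(tr$V_M, "volume", "V_M")
         else 100 * tissue$V_T
  trap <- trap_geometry(w = w, h = h, L = L, A = A, V_M = V_M)

  mets <- base$metabolites
  for (nm in intersect(names(config$metabolites), c("glucose", "oxygen"))) {
    ov <- config$metabolites[[nm]]
    cur <- mets[[nm]]
    mets[[nm]] <- metabolite_params(
      nm,
      q_max = .field(ov, "q_max", "uptake", cur$q_max),
      k_M = .field(ov, "k_M", "concentration", cur$k_M),
      D_M = .field(ov, "D_M", "diffusivity", cur$D_M),
      D_T = .field(ov, "D_T", "diffusivity", cur$D_T),
      c_sat_M = .field(ov, "c_sat_M", "concentration", cur$c_sat_M),
      c_sat_T = .field(ov, "c_sat_T", "concentration", cur$c_sat_T),
      c0 = .field(ov, "c0", "concentration", cur$c0))
  }

  structure(list(preset = "typical", tissue = tissue, medium = medium,
                 trap = trap, tau_max = tau_max, metabolites = mets,
                 metabolite = mets$glucose),
            class = "mst_params")
}

#' Serialize a parameter bundle
#'
#' Writes the bundle in the same schema that [load_parameters()] reads, in
#' internal SI units, so that saving and re-loading round-trips exactly.
#'
#' @param params an `mst_params` bundle.
#' @param path output file; format chosen by extension (`.yaml` or `.json`).
#' @return `path`, invisibly.
#' @export
save_parameters <- function(params, path) {
  stopifnot(inherits(params, "mst_params"))
  doc <- list(
    tissue = params$tissue[c("d", "rho_T", "rho_cell")],
    medium = c(params$medium[c("rho_M", "eta", "g_eff")],
               list(tau_max = params$tau_max)),
    trap = params$trap[c("w", "h", "L", "A", "V_M")],
    metabolites = lapply(params$metabolites, function(m)
      m[c("q_max", "k_M", "D_M", "D_T", "c_sat_M", "c_sat_T", "c0")]))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' @export
print.metabolite_params <- function(x, ...) {
  cat(sprintf("<metabolite_params: %s>\n", x$name))
  cat(sprintf("  q_max   %.3g mol/(cell s)\n", x$q_max))
  cat(sprintf("  k_M     %.3g mM\n", x$k_M))
  cat(sprintf("  D_M     %.3g m2/s   D_T %.3g m2/s\n", x$D_M, x$D_T))
  cat(sprintf("  c_sat   M %.3g / T %.3g mM   c0 %.3g mM\n",
              x$c_sat_M, x$c_sat_T, x$c0))
  invisible(x)
}

#' @export
print.tissue_sample <- function(x, ...) {
  cat(sprintf("<tissue_sample: d = %.4g um, rho_T = %.4g kg/m3, rho_cell = %.3g cells/uL, V_T = %.4g uL>\n",
              x$d * 1e6, x$rho_T, x$rho_cell / 1e9, x$V_T * 1e9))
  invisible(x)
}

#' @export
print.trap_geometry <- function(x, ...) {
  cat(sprintf("<trap_geometry: w = %.4g um, h = %.4g um, L = %.4g um, V_M = %.4g uL>\n",
              x$w * 1e6, x$h * 1e6, x$L * 1e6, x$V_M * 1e9))
  invisible(x)
}
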