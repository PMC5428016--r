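# Unit handling: the package works internally in SI with concentrations in
# mol/m^3 (numerically identical to mM), so model formulas can be written
# exactly as dimensional analysis gives them. User-facing I/O accepts
# "value unit" strings for the common lab units.

# factor tables: value_in_SI = value * factor
.unit_factors <- list(
  length = c("m" = 1, "cm" = 1e-2, "mm" = 1e-3, "um" = 1e-6, "µm" = 1e-6,
             "nm" = 1e-9),
  density = c("kg/m3" = 1, "g/cm3" = 1000, "g/ml" = 1000, "g/mL" = 1000),
  viscosity = c("Pa.s" = 1, "Pa*s" = 1, "mPa.s" = 1e-3, "cP" = 1e-3),
  concentration = c("mol/m3" = 1, "mM" = 1, "M" = 1000, "uM" = 1e-3),
  area = c("m2" = 1, "cm2" = 1e-4, "mm2" = 1e-6, "um2" = 1e-12),
  volume = c("m3" = 1, "L" = 1e-3, "mL" = 1e-6, "ml" = 1e-6,
             "uL" = 1e-9, "ul" = 1e-9, "nL" = 1e-12),
  flow = c("m3/s" = 1, "mL/min" = 1e-6 / 60, "ml/min" = 1e-6 / 60,
           "uL/min" = 1e-9 / 60, "mL/s" = 1e-6),
  time = c("s" = 1, "min" = 60, "h" = 3600, "d" = 86400),
  acceleration = c("m/s2" = 1, "g" = 9.81),
  stress = c("Pa" = 1, "mPa" = 1e-3, "kPa" = 1e3),
  diffusivity = c("m2/s" = 1, "cm2/s" = 1e-4, "mm2/s" = 1e-6),
  uptake = c("mol/(cell.s)" = 1, "mol/cell/s" = 1, "mol/(cell*s)" = 1),
  cell_density = c("cells/m3" = 1, "1/m3" = 1,
                   "cells/uL" = 1e9, "cells/ul" = 1e9, "1/uL" = 1e9,
                   "cells/mL" = 1e6, "cells/ml" = 1e6)
)

#' Parse a physical quantity into internal SI units
#'
#' Accepts either a bare number (taken to already be in internal units) or a
#' string of the form `"value unit"`, e.g. `"250 um"`, `"1.02 g/cm3"`,
#' `"0.5 mL/min"`. Concentrations are internally mol/m^3, which is
#' numerically equal to mM.
#'
#' @param x numeric or character scalar.
#' @param kind dimension of the quantity; one of
#'   `r paste0('"', names(.unit_factors), '"', collapse = ", ")`.
#' @param what name used in error messages.
#' @return numeric scalar in internal SI units.
#' @examples
#' parse_quantity("250 um", "length")     # 2.5e-4 m
#' parse_quantity("1.02 g/cm3", "density") # 1020 kg/m3
#' @export
parse_quantity <- function(x, kind, what = kind) {
  if (is.numeric(x)) {
    if (length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a finite scalar", what), call. = FALSE)
    return(as.numeric(x))
  }
  if (!is.character(x) || length(x) != 1L)
    stop(sprintf("'%s' must be a number or a \"value unit\" string", what),
         call. = FALSE)
  factors <- .unit_factors[[kind]]
  if (is.null(factors))
    stop(sprintf("unknown quantity kind '%s'", kind), call. = FALSE)
  m <- regmatches(x, regexec("^\\s*([-+0-9.eE]+)\\s*(\\S*)\\s*$", x))[[1]]
  if (length(m) != 3L || is.na(suppressWarnings(as.numeric(m[2]))))
    stop(sprintf("cannot parse quantity '%s' for '%s'", x, what), call. = FALSE)
  value <- as.numeric(m[2])
  unit <- m[3]
  if (unit == "") return(value)
  if (!unit %in% names(factors))
    stop(sprintf("unrecognized %s unit '%s' (known: %s)", kind, unit,
                 paste(names(factors), collapse = ", ")), call. = FALSE)
  value * factors[[unit]]
}

.check_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a positive finite number (got %s)",
                 what, format(x)), call. = FALSE)
  invisible(x)
}
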