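# Unit handling. Internally everything is CGS with concentrations in
# mol cm-3; the user-facing API speaks physiological units (mM, nm, um).
# All quantities entering from config files must carry a unit suffix so
# that silent scale errors (the classic mM vs mol/cm3 slip) are impossible.

# conversion factor tables: value[unit] * factor -> CGS
.unit_tables <- list(
  concentration = c("mM" = 1e-6, "M" = 1e-3, "mol/cm3" = 1, "osm/L" = 1e-3,
                    "mosm/L" = 1e-6),
  length        = c("nm" = 1e-7, "um" = 1e-4, "µm" = 1e-4, "mm" = 1e-1,
                    "cm" = 1, "m" = 1e2),
  diffusivity   = c("cm2/s" = 1, "um2/s" = 1e-8, "m2/s" = 1e4),
  molar_flux    = c("mol/cm2/s" = 1, "nmol/cm2/s" = 1e-9, "umol/cm2/s" = 1e-6,
                    "mol/m2/s" = 1e-4),
  volume_rate   = c("cm3/s" = 1, "um3/s" = 1e-12),
  areal_density = c("/cm2" = 1, "cm-2" = 1, "/um2" = 1e8, "um-2" = 1e8,
                    "/nm2" = 1e14),
  velocity      = c("cm/s" = 1, "um/s" = 1e-4, "m/s" = 1e2, "nm/s" = 1e-7),
  viscosity     = c("g/cm/s" = 1, "P" = 1, "cP" = 1e-2, "Pa.s" = 10),
  molar_energy  = c("erg/mol" = 1, "g.cm2/s2/mol" = 1, "J/mol" = 1e7),
  molar_volume  = c("cm3/mol" = 1, "L/mol" = 1e3, "mL/mol" = 1)
)

# dimension of each parameter field
.param_dims <- c(
  k_aq = "volume_rate", D = "diffusivity", n_aq = "areal_density",
  j = "molar_flux", b = "length", L = "length", mu = "viscosity",
  RT = "molar_energy", V_wat = "molar_volume", w_TJ = "length",
  P_f = "velocity", c1 = "concentration", c3 = "concentration",
  c4 = "concentration"
)

#' Parse a quantity string such as "600 mM" into internal CGS units
#'
#' @param x a string `"value unit"` (e.g. `"400 nm"`, `"18.5e-9 mol/cm2/s"`)
#'   or a bare numeric, which is taken to already be in CGS.
#' @param dimension one of `"concentration"`, `"length"`, `"diffusivity"`,
#'   `"molar_flux"`, `"volume_rate"`, `"areal_density"`, `"velocity"`,
#'   `"viscosity"`, `"molar_energy"`, `"molar_volume"`.
#' @param field name used in error messages.
#' @return numeric scalar in CGS units (lengths in cm, concentrations in
#'   mol cm-3, etc.).
#' @examples
#' parse_quantity("600 mM", "concentration")  # 6e-4 mol/cm3
#' parse_quantity("40 nm", "length")          # 4e-6 cm
#' @export
parse_quantity <- function(x, dimension, field = dimension) {
  tab <- .unit_tables[[dimension]]
  if (is.null(tab)) stop("unknown dimension: ", dimension, call. = FALSE)
  if (is.numeric(x)) {
    if (length(x) != 1L || !is.finite(x))
      stop("field '", field, "': expected a finite scalar", call. = FALSE)
    return(unname(as.numeric(x)))
  }
  if (!is.character(x) || length(x) != 1L)
    stop("field '", field, "': expected \"value unit\" string or numeric",
         call. = FALSE)
  m <- regmatches(x, regexec("^\\s*([-+0-9.eE]+)\\s*(\\S+)?\\s*$", x))[[1]]
  if (length(m) < 2L || m[2] == "")
    stop("field '", field, "': cannot parse quantity '", x, "'", call. = FALSE)
  val <- suppressWarnings(as.numeric(m[2]))
  if (is.na(val))
    stop("field '", field, "': cannot parse number in '", x, "'", call. = FALSE)
  unit <- if (length(m) >= 3L) m[3] else ""
  if (is.na(unit) || unit == "")
    stop("field '", field, "': unit suffix missing in '", x,
         "' (write e.g. \"", names(tab)[1], "\")", call. = FALSE)
  if (!unit %in% names(tab))
    stop("field '", field, "': unknown unit '", unit, "' (accepted: ",
         paste(names(tab), collapse = ", "), ")", call. = FALSE)
  unname(val * tab[[unit]])
}

#' Convert between CGS and display units
#'
#' `to_mM()` and `from_mM()` convert concentrations (1 mM = 1e-6 mol cm-3);
#' `to_um()`/`from_um()` convert lengths (1 um = 1e-4 cm). Round trips are
#' exact to floating-point.
#'
#' @param x numeric vector.
#' @return numeric vector in the target unit.
#' @export
to_mM <- function(x) x / 1e-6

#' @rdname to_mM
#' @export
from_mM <- function(x) x * 1e-6

#' @rdname to_mM
#' @export
to_um <- function(x) x / 1e-4

#' @rdname to_mM
#' @export
from_um <- function(x) x * 1e-4
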