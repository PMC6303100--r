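# Governing equations of the reduced first-order system and its residual
# functionals, independent of any solution strategy.
#
# State: concentration c(y) and cross-section-averaged velocity v(y) on
# y in [0, L], with y = 0 at the tight junction and y = L at the open end.
# After one integration of the convection-diffusion equation (using the
# zero axial ion flux at the inlet) the system is
#     -D c' + v c = 2 j y / b          (ion transport, first integral)
#      v'          = (2 f_aq / b)(c - c3)   (aquaporin volume influx)
# with boundary conditions c(L) = c4 and v(0) = k_TJ RT (c(0) - c1).
# Hydrostatic-pressure driving terms are neglected throughout: at typical
# osmotic differences of 100 mM, RT*dc ~ 2.6e6 CGS while physiological
# pressure differences are ~1e5 CGS, an order of magnitude smaller (see
# pressure_vs_osmotic_ratio()).

#' Right-hand side of the reduced cleft transport system
#'
#' Evaluates the derivatives `dc/dy = (v*c - 2*j*y/b)/D` and
#' `dv/dy = (2*f_aq/b)*(c - c3)` at a point. Pure function; the sign
#' convention is v > 0 from the tight junction toward the interstitium.
#'
#' @param y position in the cleft, cm (0 = TJ end).
#' @param c concentration, mol cm-3 (must be > 0).
#' @param v velocity, cm/s.
#' @param params a [cleft_params()] record.
#' @return list with elements `dc_dy` (mol cm-4) and `dv_dy` (s-1).
#' @export
cleft_rhs <- function(y, c, v, params) {
  if (any(c <= 0))
    stop("nonphysical state: concentration must be positive", call. = FALSE)
  f_aq <- compute_faq(params$k_aq, params$V_wat, params$n_aq)
  list(
    dc_dy = (v * c - 2 * params$j * y / params$b) / params$D,
    dv_dy = (2 * f_aq / params$b) * (c - params$c3)
  )
}

#' Water velocity through the tight junction
#'
#' `v_TJ = k_TJ * RT * (c(0) - c1)`: positive (absorption from the lumen)
#' when the cleft inlet is hyperosmotic relative to the lumen, negative
#' (secretion into the lumen) otherwise.
#'
#' @param c0 inlet concentration c(0), mol cm-3.
#' @param params a [cleft_params()] record.
#' @return velocity in cm/s.
#' @export
tj_velocity <- function(c0, params) {
  stopifnot(all(c0 > 0))
  k_TJ <- compute_ktj(params$P_f, params$V_wat, params$w_TJ, params$RT, params$b)
  k_TJ * params$RT * (c0 - params$c1)
}

#' Ratio of osmotic to hydrostatic driving forces
#'
#' Documents why pressure terms are omitted from the model: the osmotic
#' driving `RT * dc` at a typical `dc` dwarfs physiological hydrostatic
#' differences. At dc = 100 mM and dp = 0.1 atm the ratio is about 26.
#'
#' @param params a [cleft_params()] record (only RT is used).
#' @param dc osmotic difference, mol cm-3 (default 100 mM).
#' @param dp hydrostatic difference, dyn cm-2 (default 0.1 atm = 1e5 CGS).
#' @return list with `RT_dc` (erg/cm3), `dp`, and their `ratio`.
#' @export
pressure_vs_osmotic_ratio <- function(params, dc = from_mM(100), dp = 1e5) {
  RT_dc <- params$RT * dc
  list(RT_dc = RT_dc, dp = dp, ratio = RT_dc / dp)
}

#' Residual diagnostics of a concentration/velocity profile
#'
#' Measures how well a profile satisfies the governing system and its
#' boundary conditions:
#' \describe{
#'   \item{bc_outlet}{`|c(L) - c4|`, mol cm-3.}
#'   \item{bc_inlet_velocity}{`|v(0) - k_TJ RT (c(0) - c1)|`, cm/s.}
#'   \item{ion_flux_residual}{max over mesh intervals of the first-integral
#'     defect `|-D c' + v c - 2 j y / b|` evaluated at interval midpoints
#'     (midpoint differencing), normalized by the outlet ion flux `2jL/b`.}
#'   \item{volume_residual}{`|v(L) - v(0) - (2 f_aq/b) * trapz(c - c3)|`
#'     normalized by `max(|v(L)|, A*L)`.}
#' }
#'
#' @param profile a `cleft_profile`/`cleft_approx` object, or a data frame
#'   with columns `y`, `c`, `v` (CGS) covering `[0, L]`.
#' @param params a [cleft_params()] record.
#' @return named list of the four non-negative residuals.
#' @export
cleft_residuals <- function(profile, params) {
  d <- profile_data(profile)
  y <- d$y; c <- d$c; v <- d$v
  n <- length(y)
  if (n < 2L || is.unsorted(y, strictly = TRUE))
    stop("profile mesh must be strictly increasing", call. = FALSE)
  if (abs(y[1]) > 1e-12 * params$L || abs(y[n] - params$L) > 1e-9 * params$L)
    stop("profile mesh must cover [0, L]", call. = FALSE)
  f_aq <- compute_faq(params$k_aq, params$V_wat, params$n_aq)
  scales <- derived_scales(params)

  h  <- diff(y)
  cm <- (c[-1] + c[-n]) / 2
  vm <- (v[-1] + v[-n]) / 2
  ym <- (y[-1] + y[-n]) / 2
  dc <- diff(c) / h
  flux_scale <- if (params$j > 0) 2 * params$j * params$L / params$b else
    params$D * max(c) / params$L
  ion_res <- max(abs(-params$D * dc + vm * cm - 2 * params$j * ym / params$b)) /
    flux_scale

  lateral <- (2 * f_aq / params$b) * trapz(y, c - params$c3)
  v_scale <- max(abs(v[n]), scales$A * params$L, .Machine$double.eps)
  vol_res <- abs(v[n] - v[1] - lateral) / v_scale

  list(
    bc_outlet = abs(c[n] - params$c4),
    bc_inlet_velocity = abs(v[1] - tj_velocity(c[1], params)),
    ion_flux_residual = ion_res,
    volume_residual = vol_res
  )
}

# trapezoid rule
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

# accept cleft_profile, cleft_approx, or bare data frames
profile_data <- function(profile) {
  if (inherits(profile, "cleft_profile") || inherits(profile, "cleft_approx"))
    return(profile$data)
  if (is.data.frame(profile)) {
    stopifnot(all(c("y", "c", "v") %in% names(profile)))
    return(profile)
  }
  stop("expected a cleft_profile, cleft_approx, or data frame with y, c, v",
       call. = FALSE)
}

# Dimensionless groups of the nondimensionalized system
#   Y = y/L, C = c/c3, V = v L / D:
#   C' = V C - alpha Y,  V' = beta (C - 1),
#   C(1) = r4, V(0) = gamma (C(0) - r1)
nondim_groups <- function(params) {
  f_aq <- compute_faq(params$k_aq, params$V_wat, params$n_aq)
  k_TJ <- compute_ktj(params$P_f, params$V_wat, params$w_TJ, params$RT, params$b)
  with(params, list(
    alpha = 2 * j * L^2 / (b * D * c3),
    beta  = 2 * f_aq * c3 * L^2 / (b * D),
    gamma = k_TJ * RT * c3 * L / D,
    r1 = c1 / c3, r4 = c4 / c3
  ))
}
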