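# Closed-form and non-perturbative approximate solutions.
#
# Homogeneous solution (exact, boundary-free):
#   c = c_hom (positive root of c^2 - c3 c - j/f_aq = 0), v = A y with
#   A = 2j/(b c_hom); satisfies both ODEs identically.
# Long-cleft approximation: the outlet disturbance c4 - c_hom decays away
#   from y = L with envelope E(y) = exp((y^2 - L^2)/y_inh^2) * (y/L)^p,
#   p = f_aq c_hom^2 / j, using j/(c_hom b D) = 1/y_inh^2; the velocity
#   deviation (c4 - c_hom) E(y) D f_aq c_hom / (j y) follows from the
#   linearized ion balance. E(L) = 1 so c(L) = c4 exactly.
# Short-cleft parabolic approximations: variant 2 is fully explicit,
#   c = c_hom + (c4 - c_hom) [1 + (1 + f_aq c_hom c4 / j)(y^2 - L^2)/y_inh^2];
#   variant 1 keeps a free inlet-offset coefficient C0,
#   c = c_hom + c_hom C0 (1 - y^2/L^2) + (c4 - c_hom) y^2/L^2.
#   Velocities are obtained by integrating dv/dy = (2 f_aq/b)(c - c3) of the
#   ansatz with v(0) set by the TJ condition, so boundary conditions hold
#   exactly.

approx_kinds <- c("homogeneous", "long", "short1", "short2")

#' Analytical approximation of the cleft profile
#'
#' @param params a [cleft_params()] record.
#' @param y optional mesh (cm, covering `[0, L]`); defaults to the solver's
#'   graded mesh with `n` nodes.
#' @param n mesh size when `y` is not given.
#' @param kind one of `"homogeneous"`, `"long"`, `"short1"`, `"short2"`.
#' @param coeffs a [fit_C0()] result (required for `kind = "short1"`).
#' @param warn emit a warning when called outside the approximation's
#'   validity regime (it still evaluates; the regime check is recorded in
#'   `$validity`).
#' @return a `cleft_approx` object: `$data` tibble (`y`, `c`, `v` in CGS),
#'   `$approx_kind`, `$validity` (required vs actual regime), `$params`.
#' @export
approx_profile <- function(params, y = NULL, n = 513,
                           kind = c("homogeneous", "long", "short1", "short2"),
                           coeffs = NULL, warn = TRUE) {
  kind <- match.arg(kind)
  stopifnot(inherits(params, "cleft_params"))
  scales <- derived_scales(params)
  if (is.null(y)) {
    w <- 2 * scales$y_inh / params$L
    y <- mesh_graded(n, w, 4) * params$L
  }
  f_aq <- scales$f_aq; c_hom <- scales$c_hom; A <- scales$A
  yi2 <- scales$y_inh^2
  d4 <- params$c4 - c_hom
  L <- params$L

  if (kind == "homogeneous") {
    c_prof <- rep(c_hom, length(y))
    v_prof <- A * y
  } else if (kind == "long") {
    p <- f_aq * c_hom^2 / params$j
    E <- exp((y^2 - L^2) / yi2) * (y / L)^p
    c_prof <- c_hom + d4 * E
    vdev <- d4 * (params$D * f_aq * c_hom / params$j) *
      exp((y^2 - L^2) / yi2) * y^(p - 1) / L^p
    vdev[!is.finite(vdev)] <- 0
    v_prof <- A * y + vdev
  } else if (kind == "short2") {
    q <- 1 + f_aq * c_hom * params$c4 / params$j
    c_prof <- c_hom + d4 * (1 + q * (y^2 - L^2) / yi2)
    dv <- (2 * f_aq / params$b) * d4 * (y + q * (y^3 / 3 - L^2 * y) / yi2)
    c0 <- c_hom + d4 * (1 - q * L^2 / yi2)
    v_prof <- tj_velocity(max(c0, floor_conc(params)), params) + A * y + dv
  } else { # short1
    if (is.null(coeffs))
      stop("kind = \"short1\" requires coeffs from fit_C0()", call. = FALSE)
    C0 <- coeffs$C0
    c_prof <- c_hom + c_hom * C0 * (1 - y^2 / L^2) + d4 * y^2 / L^2
    dv <- (2 * f_aq / params$b) *
      (c_hom * C0 * (y - y^3 / (3 * L^2)) + d4 * y^3 / (3 * L^2))
    v_prof <- tj_velocity(c_hom * (1 + C0), params) + A * y + dv
  }

  required <- switch(kind, homogeneous = NA_character_, long = "long",
                     short1 = "short", short2 = "short")
  ok <- is.na(required) || identical(scales$regime, required)
  if (!ok && warn)
    warning("approximation '", kind, "' evaluated outside its validity ",
            "regime (regime is '", scales$regime, "')", call. = FALSE)
  structure(list(
    data = tibble::tibble(y = y, c = c_prof, v = v_prof),
    approx_kind = kind,
    validity = list(required_regime = required, actual_regime = scales$regime,
                    within_validity = ok),
    params = params, scales = scales
  ), class = "cleft_approx")
}

#' @rdname approx_profile
#' @export
homogeneous_profile <- function(params, y = NULL, n = 513)
  approx_profile(params, y = y, n = n, kind = "homogeneous")

#' @rdname approx_profile
#' @export
long_cleft_profile <- function(params, y = NULL, n = 513, warn = TRUE)
  approx_profile(params, y = y, n = n, kind = "long", warn = warn)

#' @rdname approx_profile
#' @param variant 1 (parabolic ansatz with free inlet coefficient `C0`) or
#'   2 (fully explicit).
#' @export
short_cleft_profile <- function(params, y = NULL, n = 513, variant = 2,
                                coeffs = NULL, warn = TRUE) {
  stopifnot(variant %in% c(1, 2))
  approx_profile(params, y = y, n = n,
                 kind = if (variant == 1) "short1" else "short2",
                 coeffs = coeffs, warn = warn)
}

#' Fit the short-cleft inlet-offset coefficient C0
#'
#' The variant-1 parabolic ansatz keeps one free dimensionless coefficient
#' C0 (the relative inlet offset: `c(0) = c_hom (1 + C0)`). Its closed form
#' is not available here, so it is determined by least squares against the
#' numerical solution of the full problem (trapezoid-weighted over the
#' mesh). For `c4 < c_hom`, C0 is negative: the outlet deficit pulls the
#' inlet concentration below c_hom.
#'
#' @param params a [cleft_params()] record.
#' @param profile optional converged `cleft_profile`; solved by relaxation
#'   if missing.
#' @param options solver options when `profile` is missing.
#' @return list of class `short_cleft_coeffs` with `C0` and
#'   `source = "fitted"`.
#' @export
fit_C0 <- function(params, profile = NULL, options = solver_options()) {
  scales <- derived_scales(params)
  if (is.null(profile)) profile <- solve_relaxation(params, options)
  d <- profile_data(profile)
  c_hom <- scales$c_hom
  phi <- 1 - d$y^2 / params$L^2
  base <- c_hom + (params$c4 - c_hom) * d$y^2 / params$L^2
  h <- diff(d$y)
  wts <- c(h / 2, 0) + c(0, h / 2)
  C0 <- sum(wts * phi * (d$c - base)) / (c_hom * sum(wts * phi^2))
  structure(list(C0 = C0, source = "fitted"), class = "short_cleft_coeffs")
}

#' Inlet concentration shift in short clefts
#'
#' In a short cleft the prescribed outlet concentration c4 propagates all
#' the way to the inlet:
#' `c(0) - c_hom = (c4 - c_hom) * (1 - (1 + f_aq c_hom c4 / j) L^2 / y_inh^2)`.
#' As L -> 0 the shift tends to `c4 - c_hom` (the whole cleft sits at c4);
#' the outlet inhomogeneity is always reduced at the inlet
#' (`|c(0) - c_hom| <= |c4 - c_hom|` within the validity regime).
#'
#' @param params a [cleft_params()] record (short regime intended).
#' @return the shift `c(0) - c_hom` in mol cm-3.
#' @export
inlet_shift <- function(params) {
  scales <- derived_scales(params)
  q <- 1 + scales$f_aq * scales$c_hom * params$c4 / params$j
  (params$c4 - scales$c_hom) * (1 - q * params$L^2 / scales$y_inh^2)
}
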