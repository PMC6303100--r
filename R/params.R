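# Physiological parameter record and the derived scales that organize the
# model's behaviour. Internal storage is CGS (cm, s, g, mol cm-3).

.default_params_user <- list(
  k_aq  = "5e-14 cm3/s",        # single-aquaporin water permeability
  n_aq  = "1e3 /um2",           # aquaporin areal density in lateral membrane
  j     = "18.5e-9 mol/cm2/s",  # ion flux through lateral membrane (pumps)
  D     = "1e-5 cm2/s",         # ion diffusion coefficient
  b     = "400 nm",             # cleft width
  L     = "100 um",             # cleft length
  mu    = "0.7e-2 g/cm/s",      # viscosity (carried, unused: pressure neglected)
  RT    = 310.15 * 8.314e7,     # erg/mol at 37 C
  V_wat = "18 cm3/mol",         # molar volume of water
  w_TJ  = "2 nm",               # tight-junction pore width
  P_f   = "13.1e-3 cm/s",       # TJ hydraulic permeability (leaky epithelium)
  c1    = "600 mM",             # lumen osmolarity
  c3    = "300 mM",             # cytosol osmolarity
  c4    = "300 mM"              # interstitial osmolarity
)

# fields that may be exactly zero (limiting cases: no pumping, no aquaporins,
# sealed tight junction); everything else must be strictly positive
.zero_ok_fields <- c("j", "n_aq", "P_f", "mu")

#' Physiological parameter set for the intercellular cleft model
#'
#' Builds a validated parameter record in internal CGS units. Values may be
#' given as `"value unit"` strings in physiological units (recommended) or as
#' bare CGS numerics. Unspecified fields take the defaults of the model's
#' reference parameter set for a leaky absorbing epithelium: aquaporin
#' permeability `k_aq` = 5e-14 cm3/s at density `n_aq` = 1e3/um2, pump flux
#' `j` = 18.5e-9 mol/cm2/s, `D` = 1e-5 cm2/s, cleft width `b` = 400 nm and
#' length `L` = 100 um, TJ pore width 2 nm with hydraulic permeability
#' `P_f` = 13.1e-3 cm/s, and osmolarities `c1` = 600 mM (lumen),
#' `c3` = `c4` = 300 mM (cytosol, interstitium).
#'
#' @param ... named fields to override, e.g. `b = "40 nm"`, `c1 = "900 mM"`.
#' @param config optional path to a YAML file or a named list whose entries are
#'   `"value unit"` strings; `...` overrides take precedence over `config`.
#' @return an object of class `cleft_params`: a named list of CGS numerics
#'   with fields `k_aq, n_aq, j, D, b, L, mu, RT, V_wat, w_TJ, P_f, c1, c3, c4`.
#' @details Validation enforces: strictly positive values (zero allowed only
#'   for `j`, `n_aq`, `P_f`, and `mu`), the narrow-channel geometry `b < L`,
#'   and concentrations within (0, 10000) mM — values outside that window are
#'   almost always unit-conversion mistakes and are rejected. Config entries
#'   *must* carry unit suffixes; unknown field names are rejected.
#' @examples
#' p <- cleft_params(b = "40 nm", c3 = "290 mM")
#' p$b      # 4e-6 cm
#' to_mM(p$c3)
#' @export
cleft_params <- function(..., config = NULL) {
  overrides <- list(...)
  cfg <- list()
  if (!is.null(config)) {
    if (is.character(config) && length(config) == 1L) {
      if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
      cfg <- yaml::read_yaml(config)
      # config files must be explicit about units: reject bare numbers
      for (k in names(cfg)) {
        if (is.numeric(cfg[[k]]) && k != "RT")
          stop("field '", k, "': config values must be \"value unit\" strings",
               call. = FALSE)
      }
    } else if (is.list(config)) {
      cfg <- config
    } else stop("config must be a file path or a named list", call. = FALSE)
  }
  user <- utils::modifyList(cfg, overrides)
  unknown <- setdiff(names(user), names(.param_dims))
  if (length(unknown))
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  spec <- utils::modifyList(.default_params_user, user)
  p <- lapply(names(.param_dims), function(f)
    parse_quantity(spec[[f]], .param_dims[[f]], field = f))
  names(p) <- names(.param_dims)
  validate_cleft_params(structure(p, class = "cleft_params"))
}

#' @rdname cleft_params
#' @param x object to validate.
#' @export
validate_cleft_params <- function(x) {
  stopifnot(inherits(x, "cleft_params"))
  for (f in names(.param_dims)) {
    v <- x[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("field '", f, "': must be a finite scalar", call. = FALSE)
    if (f %in% .zero_ok_fields) {
      if (v < 0) stop("field '", f, "': must be >= 0, got ", v, call. = FALSE)
    } else if (v <= 0) {
      stop("field '", f, "': must be strictly positive, got ", v, call. = FALSE)
    }
  }
  if (x$b >= x$L)
    stop("cleft width b (", x$b, " cm) must be smaller than length L (",
         x$L, " cm): narrow-channel geometry", call. = FALSE)
  for (f in c("c1", "c3", "c4")) {
    cmM <- to_mM(x[[f]])
    if (cmM <= 0 || cmM >= 1e4)
      stop("field '", f, "': ", cmM, " mM outside (0, 10000) mM — ",
           "likely a unit-conversion error", call. = FALSE)
  }
  x
}

#' @exportS3Method base::print
print.cleft_params <- function(x, ...) {
  cat("<cleft_params>  (internal CGS units)\n")
  cat(sprintf("  geometry : b = %g nm, L = %g um\n", x$b / 1e-7, to_um(x$L)))
  cat(sprintf("  osmolarities [mM]: c1 = %g, c3 = %g, c4 = %g\n",
              to_mM(x$c1), to_mM(x$c3), to_mM(x$c4)))
  cat(sprintf("  transport: j = %.3g mol/cm2/s, D = %.3g cm2/s\n", x$j, x$D))
  cat(sprintf("  aquaporin: k_aq = %.3g cm3/s, n_aq = %.3g /cm2 (f_aq = %.3g)\n",
              x$k_aq, x$n_aq, compute_faq(x$k_aq, x$V_wat, x$n_aq)))
  cat(sprintf("  TJ: P_f = %.3g cm/s, pore width = %g nm\n", x$P_f, x$w_TJ / 1e-7))
  invisible(x)
}

#' Aquaporin transport coefficient
#'
#' `f_aq = k_aq * V_wat * n_aq` converts an osmotic concentration difference
#' across the lateral membrane into a water velocity
#' (`v_lateral = f_aq * (c - c3)`). Units: cm4 mol-1 s-1.
#'
#' @param k_aq single-channel water permeability, cm3/s.
#' @param V_wat molar volume of water, cm3/mol.
#' @param n_aq aquaporin areal density, cm-2.
#' @return f_aq in cm4 mol-1 s-1.
#' @export
compute_faq <- function(k_aq, V_wat, n_aq) {
  stopifnot(k_aq >= 0, V_wat > 0, n_aq >= 0)
  k_aq * V_wat * n_aq
}

#' Tight-junction osmotic conductance
#'
#' `k_TJ = P_f * V_wat * w_TJ / (RT * b)`, so that `k_TJ * RT * dc` is the
#' water velocity through the TJ driven by an osmotic difference `dc`
#' (mol cm-3). The 1/b factor spreads the per-pore-strip flux over the cleft
#' cross-section. Units: cm2 s g-1.
#'
#' @param P_f TJ hydraulic permeability, cm/s.
#' @param V_wat molar volume of water, cm3/mol.
#' @param w_TJ TJ pore width, cm.
#' @param RT thermal energy per mole, erg/mol.
#' @param b cleft width, cm.
#' @return k_TJ in cm2 s g-1.
#' @export
compute_ktj <- function(P_f, V_wat, w_TJ, RT, b) {
  stopifnot(P_f >= 0, V_wat > 0, w_TJ > 0, RT > 0)
  if (b <= 0) stop("b must be positive", call. = FALSE)
  P_f * V_wat * w_TJ / (RT * b)
}

#' Homogeneous cleft concentration
#'
#' Far from both ends of a long cleft the concentration settles at the
#' positive root of `c^2 - c3*c - j/f_aq = 0`:
#' `c_hom = (c3/2) * (1 + sqrt(1 + 4j/(f_aq*c3^2)))`, which always exceeds
#' the cytosolic osmolarity c3 (equality only when j = 0). It is the balance
#' point at which convective washout of pumped ions by aquaporin-driven flow
#' matches the pump influx.
#'
#' @param c3 cytosol osmolarity, mol cm-3.
#' @param j pump ion flux, mol cm-2 s-1.
#' @param f_aq aquaporin transport coefficient, cm4 mol-1 s-1.
#' @return c_hom in mol cm-3.
#' @export
compute_chom <- function(c3, j, f_aq) {
  stopifnot(c3 > 0, j >= 0)
  if (j == 0) return(c3)
  if (f_aq <= 0)
    stop("c_hom undefined: f_aq = 0 with j > 0 (no lateral water flux to ",
         "balance pumping)", call. = FALSE)
  (c3 / 2) * (1 + sqrt(1 + 4 * j / (f_aq * c3^2)))
}

#' Inhomogeneity length of the outlet boundary layer
#'
#' `y_inh = sqrt(D * b * c_hom / j)` — the distance over which the
#' disturbance imposed by the outlet concentration c4 relaxes toward the
#' homogeneous concentration. Scales as sqrt(b): narrow clefts equilibrate
#' over shorter distances.
#'
#' @param D diffusion coefficient, cm2/s.
#' @param b cleft width, cm.
#' @param c_hom homogeneous concentration, mol cm-3.
#' @param j pump ion flux, mol cm-2 s-1.
#' @return y_inh in cm.
#' @export
compute_yinh <- function(D, b, c_hom, j) {
  stopifnot(D > 0, b > 0, c_hom > 0)
  if (j <= 0)
    stop("y_inh undefined for j = 0 (no pumping: classify the cleft as ",
         "short instead)", call. = FALSE)
  sqrt(D * b * c_hom / j)
}

#' Classify a cleft as long, short, or intermediate
#'
#' A cleft is *long* when `L >= r_long * y_inh` (the homogeneous plateau has
#' room to form before the outlet layer) and *short* when
#' `L <= r_short * y_mod` with `y_mod = y_inh * sqrt(2 * (1 + f_aq*c_hom^2/(2j)))`,
#' the scale on which the parabolic short-cleft description holds. Anything
#' between is *intermediate*. With the defaults `r_long = 1`, `r_short = 0.5`
#' this reproduces the reference classification (20 and 30 um clefts at
#' b = 400 nm are short; 80 and 100 um are long). A cleft with j = 0 is
#' classified short (no standing gradient at all).
#'
#' @param L cleft length, cm.
#' @param c_hom,y_inh derived scales (CGS).
#' @param f_aq aquaporin coefficient; `j` pump flux.
#' @param j pump ion flux, mol cm-2 s-1.
#' @param r_long,r_short dimensionless thresholds.
#' @return one of `"long"`, `"short"`, `"intermediate"`.
#' @export
classify_regime <- function(L, c_hom, y_inh, f_aq, j,
                            r_long = 1, r_short = 0.5) {
  stopifnot(L > 0, r_long > 0, r_short > 0)
  if (j <= 0) return("short")
  if (L >= r_long * y_inh) return("long")
  y_mod <- y_inh * sqrt(2 * (1 + f_aq * c_hom^2 / (2 * j)))
  if (L <= r_short * y_mod) return("short")
  "intermediate"
}

#' Derived scales of the standing-gradient model
#'
#' Computes the quantities that organize all model behaviour: the aquaporin
#' coefficient `f_aq`, TJ conductance `k_TJ`, homogeneous concentration
#' `c_hom`, homogeneous velocity slope `A = 2j/(b*c_hom)` and outlet velocity
#' `v_hom_L = A*L`, the inhomogeneity length `y_inh`, and the regime label.
#'
#' @param params a [cleft_params()] record.
#' @param r_long,r_short regime thresholds, see [classify_regime()].
#' @return a one-row tibble of class `cleft_scales` with columns
#'   `f_aq, k_TJ, c_hom, A, v_hom_L, y_inh, regime` (CGS units;
#'   `y_inh = Inf` and A = 0 when j = 0) plus display columns
#'   `c_hom_mM` and `y_inh_um`.
#' @examples
#' derived_scales(cleft_params(c3 = "290 mM"))
#' @export
derived_scales <- function(params, r_long = 1, r_short = 0.5) {
  stopifnot(inherits(params, "cleft_params"))
  f_aq <- compute_faq(params$k_aq, params$V_wat, params$n_aq)
  k_TJ <- compute_ktj(params$P_f, params$V_wat, params$w_TJ, params$RT, params$b)
  c_hom <- compute_chom(params$c3, params$j, f_aq)
  A <- if (params$j > 0) 2 * params$j / (params$b * c_hom) else 0
  y_inh <- if (params$j > 0) compute_yinh(params$D, params$b, c_hom, params$j) else Inf
  regime <- classify_regime(params$L, c_hom, y_inh, f_aq, params$j,
                            r_long = r_long, r_short = r_short)
  out <- tibble::tibble(
    f_aq = f_aq, k_TJ = k_TJ, c_hom = c_hom, A = A,
    v_hom_L = A * params$L, y_inh = y_inh, regime = regime,
    c_hom_mM = to_mM(c_hom), y_inh_um = to_um(y_inh)
  )
  class(out) <- c("cleft_scales", class(out))
  out
}
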