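# Computational experiments: flux partitioning, efflux concentration, and
# tidy parameter sweeps over cleft geometry and osmolarities.

#' Flux partitioning and efflux concentration of a solved profile
#'
#' Summarizes where the water goes: through the tight junction
#' (`Q_tj = v(0) * b`, per unit cleft depth), through the lateral membrane
#' via aquaporins (`Q_lateral = 2 f_aq * trapz(c - c3)`), and out of the open
#' end (`Q_out = v(L) * b`). Volume conservation requires
#' `Q_tj + Q_lateral = Q_out`. The efflux concentration
#' `c_e = 2 j L / (b v(L))` is the osmolarity of the emerging fluid (all
#' pumped ions leave through the open end); it is undefined (`NA`) when
#' `v(L) <= 0`. If the concentration crosses the cytosolic osmolarity c3
#' inside the cleft, the lateral flux reverses direction there;
#' `sign_switch_y` reports the (first) crossing position.
#'
#' @param profile a converged `cleft_profile`.
#' @param params the matching [cleft_params()] record; defaults to the one
#'   stored in the profile.
#' @return a one-row tibble: `v0`, `vL` (cm/s), `Q_tj`, `Q_lateral`, `Q_out`
#'   (cm2/s per unit depth), `c_e` (mol cm-3), `c_e_mM`, `tj_fraction`
#'   (`v0/vL`), `sign_switch_y` (cm, `NA` if no interior crossing),
#'   `c0_mM`, and `converged`.
#' @export
flux_summary <- function(profile, params = profile$params) {
  d <- profile_data(profile)
  f_aq <- compute_faq(params$k_aq, params$V_wat, params$n_aq)
  n <- nrow(d)
  v0 <- d$v[1]; vL <- d$v[n]
  Q_tj <- v0 * params$b
  Q_lateral <- 2 * f_aq * trapz(d$y, d$c - params$c3)
  Q_out <- vL * params$b
  c_e <- if (vL > 0) 2 * params$j * params$L / (params$b * vL) else NA_real_
  dev <- d$c - params$c3
  sw <- which(dev[-1] * dev[-n] < 0)
  sign_switch_y <- if (length(sw)) {
    i <- sw[1]
    d$y[i] + (d$y[i + 1] - d$y[i]) * dev[i] / (dev[i] - dev[i + 1])
  } else NA_real_
  tibble::tibble(
    v0 = v0, vL = vL, Q_tj = Q_tj, Q_lateral = Q_lateral, Q_out = Q_out,
    c_e = c_e, c_e_mM = to_mM(c_e), tj_fraction = v0 / vL,
    sign_switch_y = sign_switch_y, c0_mM = to_mM(d$c[1]),
    converged = isTRUE(profile$meta$converged)
  )
}

#' Sweep a parameter and tabulate flux summaries
#'
#' Reproduces the model's computational experiments: one converged solve per
#' value of the swept parameter (cleft length `L`, width `b`, lumen
#' osmolarity `c1`, or cytosol osmolarity `c3`), warm-started by
#' continuation from the previous value. Individual failures are recorded
#' (`converged = FALSE`, `NA` summaries) and the sweep continues.
#'
#' @param params base [cleft_params()] record.
#' @param vary one of `"L"`, `"b"`, `"c1"`, `"c3"`, `"c4"`.
#' @param values numeric CGS values or `"value unit"` strings,
#'   e.g. `c("40 nm", "100 nm")`.
#' @param options [solver_options()].
#' @param method solver dispatch, see [solve_cleft()].
#' @param keep_profiles retain the full profiles in the result's
#'   `profiles` attribute.
#' @return a tibble of class `cleft_sweep`, one row per sweep point:
#'   `varied`, `value` (CGS), `value_user` (mM or um as appropriate), the
#'   [flux_summary()] columns, and `regime`.
#' @examples
#' \donttest{
#' p <- cleft_params(c3 = "290 mM", c4 = "300 mM", c1 = "600 mM")
#' cleft_sweep(p, "L", c("20 um", "30 um", "80 um", "100 um"))
#' }
#' @export
cleft_sweep <- function(params, vary, values, options = solver_options(),
                        method = "auto", keep_profiles = FALSE) {
  vary <- match.arg(vary, c("L", "b", "c1", "c3", "c4"))
  vals <- vapply(values, function(v)
    parse_quantity(v, .param_dims[[vary]], field = vary), numeric(1),
    USE.NAMES = FALSE)
  prev <- NULL
  profiles <- vector("list", length(vals))
  rows <- purrr::map(seq_along(vals), function(i) {
    p_i <- params
    p_i[[vary]] <- vals[i]
    out <- tryCatch({
      p_i <- validate_cleft_params(p_i)
      opt <- options
      opt$init <- prev
      prof <- solve_cleft(p_i, opt, method = method)
      prev <<- prof
      if (keep_profiles) profiles[[i]] <<- prof
      dplyr::bind_cols(
        flux_summary(prof, p_i),
        tibble::tibble(regime = derived_scales(p_i)$regime)
      )
    }, error = function(e) {
      tibble::tibble(v0 = NA_real_, vL = NA_real_, Q_tj = NA_real_,
                     Q_lateral = NA_real_, Q_out = NA_real_, c_e = NA_real_,
                     c_e_mM = NA_real_, tj_fraction = NA_real_,
                     sign_switch_y = NA_real_, c0_mM = NA_real_,
                     converged = FALSE, regime = NA_character_)
    })
    dplyr::bind_cols(
      tibble::tibble(varied = vary, value = vals[i],
                     value_user = user_value(vary, vals[i])),
      out
    )
  })
  res <- dplyr::bind_rows(rows)
  class(res) <- c("cleft_sweep", class(res))
  attr(res, "params") <- params
  if (keep_profiles) attr(res, "profiles") <- profiles
  res
}

# display units per swept field: lengths in um (b in nm), concentrations mM
user_value <- function(field, cgs) {
  switch(field,
         b = cgs / 1e-7,   # nm
         L = to_um(cgs),
         to_mM(cgs))
}

#' Daily transported volume per epithelial area
#'
#' Converts a per-unit-depth cleft flux into a volume per epithelial area:
#' `volume = |v| * b * geometry * duration`, where `geometry` is the cleft
#' line density (cm of cleft perimeter per cm2 of epithelium; for square
#' cells of side s it is 2/s, i.e. 2000 cm-1 for 10 um cells — a stylized
#' default, not a measured quantity) and `v` is the TJ velocity `v0` or the
#' open-end velocity `vL` depending on `pathway`.
#'
#' @param summary a [flux_summary()] row.
#' @param geometry cleft line density, cm-1 (> 0).
#' @param duration seconds (default one day).
#' @param pathway `"tj"` (uses `|v0|`) or `"open"` (uses `vL`).
#' @param b cleft width, cm.
#' @return volume flux in cm3 per cm2 of epithelium per `duration`
#'   (multiply by 1e4 for mL per m2).
#' @export
volume_per_area <- function(summary, geometry = 2e3, duration = 86400,
                            pathway = c("tj", "open"), b) {
  pathway <- match.arg(pathway)
  stopifnot(geometry > 0, duration > 0, b > 0)
  v <- if (pathway == "tj") abs(summary$v0) else summary$vL
  v * b * geometry * duration
}

#' Link cytosolic osmolarity to the lumen
#'
#' Helper for scenarios where the cell osmolarity tracks the lumen:
#' `c3 = intercept + slope * c1` (all mol cm-3), clamped below at
#' `min_c3`. The linear link is a modelling convenience; the coupling is
#' physiological (osmotic equilibration of the cytosol) but its slope is not
#' a measured constant.
#'
#' @param c1 lumen osmolarity, mol cm-3.
#' @param slope,intercept linear map coefficients.
#' @param min_c3 lower clamp, mol cm-3.
#' @return c3 in mol cm-3.
#' @export
link_cytosol <- function(c1, slope = 0.5, intercept = from_mM(150),
                         min_c3 = from_mM(200)) {
  pmax(intercept + slope * c1, min_c3)
}
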