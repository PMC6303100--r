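# broom-style accessors and ggplot2 methods for solved and approximate
# profiles and for sweep tables.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a solved cleft profile
#'
#' @param x a `cleft_profile` or `cleft_approx` object.
#' @param ... unused.
#' @return a tibble with columns `y_um`, `c_mM`, `v_cm_per_s`.
#' @export
tidy.cleft_profile <- function(x, ...) {
  d <- x$data
  tibble::tibble(y_um = to_um(d$y), c_mM = to_mM(d$c), v_cm_per_s = d$v)
}

#' @rdname tidy.cleft_profile
#' @export
tidy.cleft_approx <- tidy.cleft_profile

#' One-row summary of a solved cleft profile
#'
#' @param x a `cleft_profile` object.
#' @param ... unused.
#' @return a one-row tibble: method, convergence, mesh size, iterations,
#'   inlet/outlet concentrations (mM) and velocities (cm/s), the regime, and
#'   the four residual diagnostics.
#' @export
glance.cleft_profile <- function(x, ...) {
  d <- x$data; r <- x$residuals; n <- nrow(d)
  tibble::tibble(
    method = x$meta$method, converged = x$meta$converged,
    n_mesh = x$meta$n_mesh, iterations = x$meta$iterations,
    c0_mM = to_mM(d$c[1]), cL_mM = to_mM(d$c[n]),
    v0 = d$v[1], vL = d$v[n], regime = x$scales$regime,
    bc_outlet = r$bc_outlet, bc_inlet_velocity = r$bc_inlet_velocity,
    ion_flux_residual = r$ion_flux_residual,
    volume_residual = r$volume_residual
  )
}

#' @exportS3Method base::print
print.cleft_profile <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<cleft_profile> %s solve, %s (mesh %d, %d iterations)\n",
              g$method, if (g$converged) "converged" else "NOT converged",
              g$n_mesh, g$iterations))
  cat(sprintf("  c(0) = %.4g mM, c(L) = %.4g mM  [%s cleft]\n",
              g$c0_mM, g$cL_mM, g$regime))
  cat(sprintf("  v(0) = %.4g cm/s, v(L) = %.4g cm/s\n", g$v0, g$vL))
  cat(sprintf("  residuals: ion %.2e, volume %.2e\n",
              g$ion_flux_residual, g$volume_residual))
  invisible(x)
}

#' @exportS3Method base::print
print.cleft_approx <- function(x, ...) {
  cat(sprintf("<cleft_approx> kind '%s'%s\n", x$approx_kind,
              if (isTRUE(x$validity$within_validity)) "" else
                sprintf(" (outside validity: regime is '%s')",
                        x$validity$actual_regime)))
  cat(sprintf("  c(0) = %.4g mM, c(L) = %.4g mM\n",
              to_mM(x$data$c[1]), to_mM(x$data$c[nrow(x$data)])))
  invisible(x)
}

#' Plot a cleft profile
#'
#' Concentration and velocity along the cleft, faceted; reference lines mark
#' the cytosolic (c3), interstitial (c4) and homogeneous (c_hom)
#' concentrations.
#'
#' @param object a `cleft_profile` or `cleft_approx`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cleft_profile <- function(object, ...) {
  td <- tidy(object)
  p <- object$params
  long <- dplyr::bind_rows(
    tibble::tibble(y_um = td$y_um, value = td$c_mM,
                   quantity = "concentration [mM]"),
    tibble::tibble(y_um = td$y_um, value = td$v_cm_per_s,
                   quantity = "velocity [cm/s]")
  )
  refs <- tibble::tibble(
    quantity = "concentration [mM]",
    ref = c(to_mM(p$c3), to_mM(p$c4), to_mM(compute_chom(
      p$c3, p$j, compute_faq(p$k_aq, p$V_wat, p$n_aq)))),
    label = c("c3", "c4", "c_hom")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$y_um, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(data = refs,
                        ggplot2::aes(yintercept = .data$ref),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "position along cleft y [um]", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cleft_profile
#' @export
autoplot.cleft_approx <- autoplot.cleft_profile

#' Plot a sweep result
#'
#' @param object a `cleft_sweep` tibble.
#' @param y_var column to plot against the swept value (default `v0`).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cleft_sweep <- function(object, y_var = "v0", ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$value_user, y = .data[[y_var]])) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = unique(object$varied), y = y_var) +
    ggplot2::theme_minimal()
}
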