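# Numerical solution of the two-point boundary value problem
#     C' = V C - alpha Y,   V' = beta (C - 1)   on Y in [0, 1]
#     C(1) = r4,            V(0) = gamma (C(0) - r1)
# (dimensionless form; Y = y/L, C = c/c3, V = v L / D).
#
# Two independent routes:
#   * solve_relaxation(): damped Newton on a second-order box (midpoint)
#     discretization, sparse Jacobian, mesh graded toward the outlet
#     boundary layer. Works in every regime.
#   * solve_shooting(): treats the inlet concentration as the single
#     unknown, integrates the IVP with an adaptive integrator and brackets
#     the outlet mismatch. Restricted to L/y_inh <= 3 because forward
#     deviations grow like exp((L/y_inh)^2).
# Agreement between the two on their common domain is the package's central
# numerical cross-validation.

#' Solver options
#'
#' @param n_mesh number of mesh nodes (>= 64).
#' @param tol dimensionless residual tolerance for convergence.
#' @param max_iter maximum Newton iterations.
#' @param refine_span width of the refined zone near y = L, in units of
#'   y_inh.
#' @param refine_amp mesh density amplification at the outlet relative to the
#'   bulk.
#' @param init optional profile (or data frame with `y`, `c`, `v`) used as a
#'   warm-start initial guess, e.g. the previous solution in a sweep.
#' @param monotone_check for the shooting method, verify that the outlet
#'   mismatch is monotone in the inlet concentration across the bracket.
#' @return a list of class `solver_options`.
#' @export
solver_options <- function(n_mesh = 2049, tol = 1e-6, max_iter = 50,
                           refine_span = 2, refine_amp = 4, init = NULL,
                           monotone_check = TRUE) {
  stopifnot(n_mesh >= 64, tol > 0, max_iter >= 1, refine_span > 0,
            refine_amp >= 1)
  structure(list(n_mesh = as.integer(n_mesh), tol = tol,
                 max_iter = as.integer(max_iter), refine_span = refine_span,
                 refine_amp = refine_amp, init = init,
                 monotone_check = isTRUE(monotone_check)),
            class = "solver_options")
}

# Dimensionless mesh on [0, 1], density amplified near Y = 1 over a zone of
# width w = min(refine_span * y_inh / L, 1). Smooth quantile-based grading.
mesh_graded <- function(n, w, amp = 4) {
  if (!is.finite(w) || w >= 1 || amp <= 1) return(seq(0, 1, length.out = n))
  t <- seq(0, 1, length.out = 4001)
  rho <- 1 + (amp - 1) * exp(-(1 - t) / (w / 4))
  cdf <- cumsum(c(0, diff(t) * (rho[-1] + rho[-length(rho)]) / 2))
  cdf <- cdf / cdf[length(cdf)]
  y <- stats::approx(cdf, t, xout = seq(0, 1, length.out = n), ties = "ordered")$y
  y[1] <- 0; y[n] <- 1
  y
}

# assemble profile object
new_cleft_profile <- function(y, c, v, params, method, iterations, converged,
                              extra_meta = list()) {
  scales <- derived_scales(params)
  prof <- structure(list(
    data = tibble::tibble(y = y, c = c, v = v),
    params = params, scales = scales,
    residuals = NULL,
    meta = c(list(method = method, iterations = iterations,
                  n_mesh = length(y), converged = converged), extra_meta)
  ), class = "cleft_profile")
  prof$residuals <- cleft_residuals(prof, params)
  prof
}

# interpolate a previous (dimensional) profile onto a new dimensional mesh,
# stretching its y axis to the new length so the outlet layer stays at the
# outlet; used for warm starts and continuation
interp_guess <- function(init, y_new, L_new) {
  d <- profile_data(init)
  L_old <- max(d$y)
  ys <- d$y * (L_new / L_old)
  list(c = stats::approx(ys, d$c, xout = y_new, rule = 2)$y,
       v = stats::approx(ys, d$v, xout = y_new, rule = 2)$y * 1)
}

# regime-appropriate initial guess (dimensional c, v on mesh y)
default_guess <- function(params, y, scales) {
  if (params$j <= 0) {
    c0 <- rep(params$c4, length(y))
    return(list(c = c0, v = rep(tj_velocity(params$c4, params), length(y))))
  }
  mk <- function(kind) {
    ap <- approx_profile(params, y = y, kind = kind, warn = FALSE)
    list(c = ap$data$c, v = ap$data$v)
  }
  lo <- floor_conc(params)
  blend <- function(g1, g2, w)
    list(c = w * g1$c + (1 - w) * g2$c, v = w * g1$v + (1 - w) * g2$v)
  g <- switch(scales$regime,
    long = mk("long"),
    short = mk("short2"),
    intermediate = blend(mk("long"), mk("short2"),
                         w = min(1, params$L / scales$y_inh))
  )
  g$c <- pmax(g$c, lo)
  g
}

floor_conc <- function(params) 0.05 * min(params$c1, params$c3, params$c4)

#' Solve the cleft transport problem by Newton relaxation
#'
#' Solves the nonlinear boundary value problem on a finite-difference (box
#' scheme, second order) discretization of the nondimensionalized system,
#' using damped Newton iteration with a sparse Jacobian. The mesh is graded
#' toward y = L to resolve the outlet boundary layer of width ~y_inh. The
#' initial guess comes from the regime-appropriate analytical approximation
#' (or `options$init`); on failure the solver falls back to continuation in
#' the cleft length.
#'
#' @param params a [cleft_params()] record.
#' @param options a [solver_options()] list.
#' @return a `cleft_profile` object: mesh `y` (cm), concentration `c`
#'   (mol cm-3), velocity `v` (cm/s), residual diagnostics and solver
#'   metadata. See [tidy.cleft_profile()] / [glance.cleft_profile()].
#' @export
solve_relaxation <- function(params, options = solver_options()) {
  stopifnot(inherits(params, "cleft_params"))
  scales <- derived_scales(params)
  res <- relax_attempt(params, options, scales)
  if (!res$converged) {
    # continuation in L from a shorter, easier cleft
    L_target <- params$L
    L0 <- min(L_target, if (is.finite(scales$y_inh)) scales$y_inh else L_target)
    L_seq <- unique(c(L0 * (L_target / L0)^seq(0, 1, length.out = 5)))
    guess <- options$init
    for (Lk in L_seq) {
      pk <- params; pk$L <- Lk
      pk <- validate_cleft_params(pk)
      ok <- solver_options(n_mesh = options$n_mesh, tol = options$tol,
                           max_iter = options$max_iter,
                           refine_span = options$refine_span,
                           refine_amp = options$refine_amp, init = guess)
      res_k <- relax_attempt(pk, ok, derived_scales(pk))
      if (!res_k$converged)
        stop("relaxation failed to converge (continuation step L = ",
             signif(to_um(Lk), 4), " um); last scaled residual ",
             signif(res_k$resid_norm, 3), call. = FALSE)
      guess <- tibble::tibble(y = res_k$y, c = res_k$c, v = res_k$v)
      res <- res_k
    }
    if (!res$converged)
      stop("relaxation failed to converge; last scaled residual ",
           signif(res$resid_norm, 3), call. = FALSE)
  }
  new_cleft_profile(res$y, res$c, res$v, params, "relaxation",
                    res$iterations, res$converged,
                    extra_meta = list(resid_norm = res$resid_norm))
}

# one Newton solve; returns list(y, c, v, converged, iterations, resid_norm)
relax_attempt <- function(params, options, scales) {
  g <- nondim_groups(params)
  n <- options$n_mesh
  w <- options$refine_span * scales$y_inh / params$L
  Y <- mesh_graded(n, w, options$refine_amp)
  y_dim <- Y * params$L

  guess <- if (!is.null(options$init))
    interp_guess(options$init, y_dim, params$L)
  else default_guess(params, y_dim, scales)
  C <- guess$c / params$c3
  V <- guess$v * params$L / params$D

  h  <- diff(Y)
  Ym <- (Y[-1] + Y[-n]) / 2
  # equation scales for the convergence test
  sC <- max(1, g$alpha); sV <- max(1, g$beta)
  scale_vec <- c(1, rep(c(sC, sV), n - 1L), 1)

  Ffun <- function(C, V) {
    Cm <- (C[-1] + C[-n]) / 2; Vm <- (V[-1] + V[-n]) / 2
    FC <- diff(C) / h - (Vm * Cm - g$alpha * Ym)
    FV <- diff(V) / h - g$beta * (Cm - 1)
    c(V[1] - g$gamma * (C[1] - g$r1),
      as.vector(rbind(FC, FV)),
      C[n] - g$r4)
  }

  # sparsity pattern (rows interleaved: eq1, [FC_i, FV_i]..., eq2N)
  iC <- function(i) 2L * i - 1L; iV <- function(i) 2L * i
  ii <- seq_len(n - 1L)
  rows <- c(1L, 1L,
            rep(2L * ii, each = 4L),       # FC_i rows
            rep(2L * ii + 1L, each = 4L),  # FV_i rows
            2L * n)
  cols <- c(iC(1L), iV(1L),
            as.vector(t(cbind(iC(ii), iC(ii + 1L), iV(ii), iV(ii + 1L)))),
            as.vector(t(cbind(iV(ii), iV(ii + 1L), iC(ii), iC(ii + 1L)))),
            iC(n))
  Jfun <- function(C, V) {
    Cm <- (C[-1] + C[-n]) / 2; Vm <- (V[-1] + V[-n]) / 2
    vals <- c(-g$gamma, 1,
              as.vector(t(cbind(-1 / h - Vm / 2, 1 / h - Vm / 2,
                                -Cm / 2, -Cm / 2))),
              as.vector(t(cbind(-1 / h, 1 / h,
                                rep(-g$beta / 2, n - 1L),
                                rep(-g$beta / 2, n - 1L)))),
              1)
    Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(2L * n, 2L * n))
  }

  Fv <- Ffun(C, V)
  rnorm0 <- max(abs(Fv / scale_vec))
  converged <- rnorm0 < options$tol
  iter <- 0L
  C_floor <- floor_conc(params) / params$c3
  while (!converged && iter < options$max_iter) {
    iter <- iter + 1L
    dx <- tryCatch(as.numeric(Matrix::solve(Jfun(C, V), -Fv)),
                   error = function(e) NULL)
    if (is.null(dx)) break
    dC <- dx[iC(seq_len(n))]; dV <- dx[iV(seq_len(n))]
    t_step <- 1; accepted <- FALSE
    for (k in 0:20) {
      Cn <- C + t_step * dC; Vn <- V + t_step * dV
      if (all(Cn > C_floor)) {
        Fn <- Ffun(Cn, Vn)
        if (max(abs(Fn / scale_vec)) < max(abs(Fv / scale_vec)) ||
            t_step == 1 && k == 0 && max(abs(Fn / scale_vec)) < options$tol) {
          C <- Cn; V <- Vn; Fv <- Fn; accepted <- TRUE; break
        }
      }
      t_step <- t_step / 2
    }
    if (!accepted) break
    converged <- max(abs(Fv / scale_vec)) < options$tol
  }
  list(y = y_dim, c = C * params$c3, v = V * params$D / params$L,
       converged = converged, iterations = iter,
       resid_norm = max(abs(Fv / scale_vec)))
}

#' Solve the cleft transport problem by shooting
#'
#' Independent oracle for the same boundary value problem: the inlet
#' concentration c(0) is the single unknown; the inlet velocity follows from
#' the TJ condition, the ODEs are integrated with an adaptive high-order
#' integrator (deSolve), and the outlet mismatch `c(L) - c4` is driven to
#' zero by bracketing. Refuses clefts with `L/y_inh > 3`, where forward
#' deviations grow like `exp((L/y_inh)^2)` and the initial-value problem is
#' too ill-conditioned; use [solve_relaxation()] there.
#'
#' @inheritParams solve_relaxation
#' @return a `cleft_profile` object.
#' @export
solve_shooting <- function(params, options = solver_options()) {
  stopifnot(inherits(params, "cleft_params"))
  scales <- derived_scales(params)
  ratio <- params$L / scales$y_inh
  if (is.finite(ratio) && ratio > 3)
    stop("shooting refused: L/y_inh = ", signif(ratio, 3),
         " > 3 (forward deviations grow ~exp((L/y_inh)^2); ",
         "use solve_relaxation())", call. = FALSE)
  g <- nondim_groups(params)
  n <- options$n_mesh
  w <- options$refine_span * scales$y_inh / params$L
  Y <- mesh_graded(n, w, options$refine_amp)

  lo <- min(params$c1, params$c3, params$c4) / 10 / params$c3
  hi <- 10 * scales$c_hom / params$c3
  # forward trajectories from a poor inlet guess blow up (or crash through
  # zero) before reaching the outlet; stop them there via root detection and
  # report a large signed mismatch so that bracketing still sees the sign
  C_cap <- 4 * hi
  C_floor <- 1e-6
  BIG <- 1e6
  deriv <- function(t, state, parms) {
    list(c(state[1] * state[2] - g$alpha * t,
           g$beta * (state[1] - 1)))
  }
  stopfun <- function(t, state, parms)
    c(state[1] - C_cap, state[1] - C_floor)
  integrate_to_L <- function(C0, times = c(0, 1)) {
    V0 <- g$gamma * (C0 - g$r1)
    sol <- tryCatch(suppressWarnings(
      deSolve::lsoda(c(C = C0, V = V0), times, deriv, parms = NULL,
                     rootfun = stopfun, rtol = 1e-11, atol = 1e-12,
                     maxsteps = 50000)),
      error = function(e) NULL)
    if (is.null(sol) || nrow(sol) < 2L) return(NULL)
    sol
  }
  mismatch <- function(C0) {
    sol <- integrate_to_L(C0)
    if (is.null(sol)) return(NA_real_)
    t_end <- sol[nrow(sol), 1]
    C_end <- sol[nrow(sol), "C"]
    if (t_end < 1 - 1e-12 || !is.finite(C_end)) {
      # terminated early at the cap or the floor
      if (is.finite(C_end) && C_end <= 2 * C_floor) return(-BIG)
      return(BIG)
    }
    C_end - g$r4
  }

  f_lo <- mismatch(lo)
  k <- 0
  while (is.na(f_lo) && k < 8) { lo <- lo * 2; f_lo <- mismatch(lo); k <- k + 1 }
  f_hi <- mismatch(hi)
  k <- 0
  while (is.na(f_hi) && k < 8) { hi <- hi * 0.7; f_hi <- mismatch(hi); k <- k + 1 }
  if (is.na(f_lo) || is.na(f_hi))
    stop("shooting: could not evaluate outlet mismatch on the bracket",
         call. = FALSE)
  if (f_lo * f_hi > 0)
    stop("shooting: no sign change of c(L) - c4 over the inlet bracket [",
         signif(lo * to_mM(params$c3), 4), ", ",
         signif(hi * to_mM(params$c3), 4), "] mM", call. = FALSE)

  monotone <- NA
  if (options$monotone_check) {
    grid <- seq(lo, hi, length.out = 5)
    fg <- vapply(grid, mismatch, numeric(1))
    fg <- fg[!is.na(fg)]
    monotone <- !is.unsorted(fg)
    if (!isTRUE(monotone))
      warning("shooting: outlet mismatch not monotone in c(0) over the ",
              "bracket; bracketing still valid but root may not be unique")
  }

  root <- stats::uniroot(mismatch, lower = lo, upper = hi,
                         f.lower = f_lo, f.upper = f_hi, tol = 1e-13)
  sol <- integrate_to_L(root$root, times = Y)
  if (is.null(sol) || nrow(sol) < length(Y))
    stop("shooting: final integration failed", call. = FALSE)
  converged <- abs(mismatch(root$root)) < options$tol * max(1, g$r4)
  new_cleft_profile(Y * params$L, sol[, "C"] * params$c3,
                    sol[, "V"] * params$D / params$L,
                    params, "shooting", root$iter, converged,
                    extra_meta = list(monotone_bracket = monotone,
                                      c0_root = root$root * params$c3))
}

#' Solve the cleft transport problem (dispatching solver)
#'
#' Chooses the method automatically: shooting for short clefts (fast and
#' independent of the relaxation machinery), Newton relaxation otherwise.
#'
#' @inheritParams solve_relaxation
#' @param method `"auto"` (default), `"relaxation"`, or `"shooting"`.
#' @return a `cleft_profile` object with a `ResidualReport` in
#'   `$residuals` and method metadata in `$meta`.
#' @examples
#' \donttest{
#' p <- cleft_params(L = "20 um", c3 = "290 mM", c4 = "300 mM")
#' prof <- solve_cleft(p)
#' glance(prof)
#' }
#' @export
solve_cleft <- function(params, options = solver_options(),
                        method = c("auto", "relaxation", "shooting")) {
  method <- match.arg(method)
  if (method == "auto") {
    scales <- derived_scales(params)
    ratio <- params$L / scales$y_inh
    method <- if (scales$regime == "short" && is.finite(ratio) && ratio <= 3)
      "shooting" else "relaxation"
  }
  switch(method,
         relaxation = solve_relaxation(params, options),
         shooting = solve_shooting(params, options))
}
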