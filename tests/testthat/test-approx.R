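# The approximations are validated against the numerical solvers (the
# solvers themselves are validated against exact fixtures and each other).

test_that("homogeneous profile is exact and matches the printed scales", {
  p <- fig_params()  # c3 = 290 mM
  ap <- homogeneous_profile(p)
  expect_equal(to_mM(ap$data$c[1]), 621.0, tolerance = 1e-3)
  expect_true(all(ap$data$c == ap$data$c[1]))
  # v(L) = 2jL/(b c_hom) at c3 = 300 mM, b = 400 nm, L = 100 um
  p2 <- cleft_params(c3 = "300 mM", b = "400 nm", L = "100 um")
  ap2 <- homogeneous_profile(p2)
  expect_equal(ap2$data$v[nrow(ap2$data)], 1.474e-2, tolerance = 1e-3)
  # satisfies the governing equations identically
  r <- cleft_residuals(ap2, cleft_params(c3 = "300 mM", b = "400 nm",
                                         L = "100 um",
                                         c1 = derived_scales(p2)$c_hom,
                                         c4 = derived_scales(p2)$c_hom))
  expect_lt(r$ion_flux_residual, 1e-12)
  expect_lt(r$volume_residual, 1e-12)
})

test_that("long-cleft approximation: exact outlet value, decay over y_inh", {
  p <- fig_params(L = "100 um", b = "40 nm")  # L/y_inh ~ 8.6, deep in regime
  sc <- derived_scales(p)
  ap <- long_cleft_profile(p)
  d <- ap$data; n <- nrow(d)
  expect_equal(d$c[n], p$c4, tolerance = 1e-12)      # c(L) = c4 exactly
  # five inhomogeneity lengths from the outlet the disturbance is < 1%
  y_probe <- p$L - 5 * sc$y_inh
  c_probe <- approx(d$y, d$c, xout = y_probe)$y
  expect_lt(abs(c_probe - sc$c_hom), 1e-2 * abs(p$c4 - sc$c_hom))
  # converges to the homogeneous profile away from the outlet
  inner <- d$y <= p$L - 6 * sc$y_inh
  expect_lt(max(abs(d$c[inner] - sc$c_hom)) / sc$c_hom, 1e-4)
})

test_that("long-cleft approximation tracks the solver within 2%", {
  p <- fig_params(L = "100 um", b = "400 nm")
  pr <- solve_relaxation(p, fast_opts(n_mesh = 2049))
  ap <- long_cleft_profile(p, y = pr$data$y)
  expect_lt(max(abs(ap$data$c - pr$data$c) / pr$data$c), 0.02)
})

test_that("short-cleft variant 2 is exact at the outlet and accurate at 10 um", {
  p <- fig_params(L = "10 um", b = "400 nm")
  pr <- solve_cleft(p, fast_opts())
  ap <- short_cleft_profile(p, y = pr$data$y, variant = 2)
  n <- nrow(ap$data)
  expect_equal(ap$data$c[n], p$c4, tolerance = 1e-12)
  expect_lt(max(abs(ap$data$c - pr$data$c) / pr$data$c), 0.05)
})

test_that("fitted variant 1 beats variant 2 on a 20 um cleft", {
  p <- fig_params(L = "20 um", b = "400 nm")
  pr <- solve_relaxation(p, fast_opts(n_mesh = 2049))
  cf <- fit_C0(p, profile = pr)
  ap1 <- short_cleft_profile(p, y = pr$data$y, variant = 1, coeffs = cf)
  ap2 <- short_cleft_profile(p, y = pr$data$y, variant = 2)
  e1 <- max(abs(ap1$data$c - pr$data$c) / pr$data$c)
  e2 <- max(abs(ap2$data$c - pr$data$c) / pr$data$c)
  expect_lt(e1, e2)
  # inlet concentration reproduced to 1%
  expect_lt(abs(ap1$data$c[1] - pr$data$c[1]) / pr$data$c[1], 0.01)
  # variant 1 requires the coefficient
  expect_error(short_cleft_profile(p, variant = 1), "fit_C0")
})

test_that("C0 is zero for the homogeneous fixture and negative when c4 < c_hom", {
  ph <- homogeneous_params(L = "20 um")
  cf0 <- fit_C0(ph, options = fast_opts())
  expect_lt(abs(cf0$C0), 1e-8)
  p <- fig_params(L = "20 um", b = "400 nm")  # c4 = 300 < c_hom = 621
  cf <- fit_C0(p, options = fast_opts())
  expect_lt(cf$C0, 0)
  expect_equal(cf$source, "fitted")
})

test_that("inlet shift: L -> 0 limit, monotone decay, solver agreement", {
  sc <- derived_scales(fig_params(L = "20 um"))
  d4 <- fig_params(L = "20 um")$c4 - sc$c_hom
  # as L -> 0 the shift approaches c4 - c_hom (whole cleft pinned at c4)
  sh_tiny <- inlet_shift(fig_params(L = "0.5 um"))
  expect_equal(sh_tiny, d4, tolerance = 2e-3)
  # magnitude decreases as the cleft lengthens (short regime)
  shifts <- vapply(c("2 um", "5 um", "8 um", "12 um"),
                   function(L) abs(inlet_shift(fig_params(L = L))),
                   numeric(1))
  expect_true(all(diff(shifts) < 0))
  # quantitative agreement with the solver at 10 um
  p10 <- fig_params(L = "10 um", b = "400 nm")
  pr <- solve_cleft(p10, fast_opts())
  sh_num <- pr$data$c[1] - derived_scales(p10)$c_hom
  expect_lt(abs(inlet_shift(p10) - sh_num) / abs(sh_num), 0.10)
})

test_that("outlet inhomogeneity is always reduced at the inlet (short clefts)", {
  for (L in c("5 um", "10 um", "15 um")) for (b in c("200 nm", "400 nm")) {
    p <- fig_params(L = L, b = b)
    sc <- derived_scales(p)
    pr <- solve_cleft(p, fast_opts())
    expect_lte(abs(pr$data$c[1] - sc$c_hom), abs(p$c4 - sc$c_hom))
    # and the closed-form shift obeys the same bound
    expect_lte(abs(inlet_shift(p)), abs(p$c4 - sc$c_hom))
  }
})

test_that("all approximations satisfy c(L) = c4 exactly", {
  p <- fig_params(L = "20 um", b = "400 nm")
  cf <- fit_C0(p, options = fast_opts())
  for (ap in list(long_cleft_profile(p, warn = FALSE),
                  short_cleft_profile(p, variant = 2),
                  short_cleft_profile(p, variant = 1, coeffs = cf))) {
    expect_equal(ap$data$c[nrow(ap$data)], p$c4, tolerance = 1e-12)
  }
  # the homogeneous profile has no boundary adjustment: c(L) = c_hom
  aph <- homogeneous_profile(p)
  expect_equal(aph$data$c[nrow(aph$data)], derived_scales(p)$c_hom)
})

test_that("validity bookkeeping flags out-of-regime evaluation", {
  p_short <- fig_params(L = "20 um", b = "400 nm")
  expect_warning(long_cleft_profile(p_short), "validity")
  ap <- long_cleft_profile(p_short, warn = FALSE)
  expect_false(ap$validity$within_validity)
  ap_ok <- short_cleft_profile(p_short, variant = 2)
  expect_true(ap_ok$validity$within_validity)
})
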