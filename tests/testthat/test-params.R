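test_that("quantity parsing converts physiological units to CGS", {
  expect_equal(parse_quantity("600 mM", "concentration"), 6e-4)
  expect_equal(parse_quantity("40 nm", "length"), 4e-6)
  expect_equal(parse_quantity("100 um", "length"), 1e-2)
  expect_equal(parse_quantity("1e3 /um2", "areal_density"), 1e11)
  expect_equal(parse_quantity("18.5e-9 mol/cm2/s", "molar_flux"), 1.85e-8)
  # bare numerics pass through as CGS
  expect_equal(parse_quantity(4e-6, "length"), 4e-6)
  # missing or unknown unit suffix is an error
  expect_error(parse_quantity("600", "concentration"), "unit suffix missing")
  expect_error(parse_quantity("600 bogus", "concentration"), "unknown unit")
})

test_that("unit round trips are exact to 1e-12 relative", {
  x <- c(1e-6, 2.9e-4, 6.21e-4, 1)
  expect_equal(from_mM(to_mM(x)), x, tolerance = 1e-12)
  expect_equal(from_um(to_um(x)), x, tolerance = 1e-12)
})

test_that("default parameters are the reference constants", {
  p <- cleft_params()
  expect_s3_class(p, "cleft_params")
  expect_equal(p$D, 1e-5)
  expect_equal(p$j, 18.5e-9)
  expect_equal(p$RT, RT_CGS)
  expect_equal(p$V_wat, 18)
  expect_equal(p$w_TJ, 2e-7)
  expect_equal(p$P_f, 13.1e-3)
  expect_equal(p$k_aq, 5e-14)
  expect_equal(p$n_aq, 1e11)
})

test_that("parameter validation rejects nonphysical input", {
  expect_error(cleft_params(b = "-40 nm"), "strictly positive")
  expect_error(cleft_params(D = 0), "strictly positive")
  expect_error(cleft_params(bogus_field = "1 mM"), "unknown parameter")
  # narrow-channel geometry: b < L
  expect_error(cleft_params(b = "30 um", L = "20 um"), "narrow-channel")
  # concentration window guards against unit slips (mol/cm3 passed as mM)
  expect_error(cleft_params(c1 = "600 M"), "unit-conversion")
  # zero allowed only for pump flux, aquaporin density, TJ permeability
  expect_silent(cleft_params(j = 0, n_aq = 0, P_f = 0))
})

test_that("config files load with overrides and reject bare numbers", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c('b: "40 nm"', 'c1: "900 mM"'), cfg)
  p <- cleft_params(config = cfg, c1 = "600 mM")
  expect_equal(p$b, 4e-6)
  expect_equal(p$c1, 6e-4)   # override wins
  writeLines("b: 40", cfg)
  expect_error(cleft_params(config = cfg), "value unit")
})

test_that("f_aq is the product k_aq * V_wat * n_aq", {
  expect_equal(compute_faq(5e-14, 18, 1e11), 0.09)
  expect_equal(compute_faq(5e-14, 18, 0), 0)        # no aquaporins
  expect_equal(compute_faq(5e-14, 18, 2e11), 0.18)  # linear in n_aq
})

test_that("k_TJ follows the TJ-pore permeability formula and scales as 1/b", {
  k40 <- compute_ktj(13.1e-3, 18, 2e-7, RT_CGS, 4e-6)
  # hand evaluation: 13.1e-3 * 18 * 2e-7 / (2.5786e10 * 4e-6)
  expect_equal(k40, 4.572271e-13, tolerance = 1e-6)
  k400 <- compute_ktj(13.1e-3, 18, 2e-7, RT_CGS, 4e-5)
  expect_equal(k400, k40 / 10, tolerance = 1e-12)
  expect_equal(k40 * 4e-6, k400 * 4e-5, tolerance = 1e-12)  # k_TJ*b constant
  expect_error(compute_ktj(13.1e-3, 18, 2e-7, RT_CGS, 0), "positive")
})

test_that("c_hom solves its quadratic and has the right limits", {
  f_aq <- 0.09
  j <- 1.85e-8
  for (c3_mM in c(200, 290, 300, 600, 1000)) {
    c3 <- from_mM(c3_mM)
    ch <- compute_chom(c3, j, f_aq)
    # defining quadratic satisfied to 1e-12 relative
    expect_lt(abs(ch^2 - c3 * ch - j / f_aq) / ch^2, 1e-12)
    expect_gt(ch, c3)
    # independent root-finding oracle
    root <- uniroot(function(x) x^2 - c3 * x - j / f_aq,
                    c(c3, 100 * c3), tol = 1e-18)$root
    expect_equal(ch, root, tolerance = 1e-9)
  }
  expect_equal(compute_chom(from_mM(300), 0, f_aq), from_mM(300))  # j = 0
  expect_error(compute_chom(from_mM(300), j, 0), "f_aq = 0")
})

test_that("c_hom is monotone in j and c3, antitone in f_aq", {
  grid_j <- c(0.5, 1, 2, 4) * 1.85e-8
  grid_c3 <- from_mM(c(200, 300, 500))
  grid_f <- c(0.045, 0.09, 0.18)
  for (c3 in grid_c3) for (f in grid_f) {
    ch <- vapply(grid_j, compute_chom, numeric(1), c3 = c3, f_aq = f)
    expect_true(all(diff(ch) > 0))
  }
  for (j in grid_j) for (f in grid_f) {
    ch <- vapply(grid_c3, compute_chom, numeric(1), j = j, f_aq = f)
    expect_true(all(diff(ch) > 0))
  }
  for (j in grid_j) for (c3 in grid_c3) {
    ch <- vapply(grid_f, function(f) compute_chom(c3, j, f), numeric(1))
    expect_true(all(diff(ch) < 0))
  }
})

test_that("y_inh matches direct evaluation and scales as sqrt(b)", {
  ch <- compute_chom(from_mM(290), 1.85e-8, 0.09)
  y400 <- compute_yinh(1e-5, 4e-5, ch, 1.85e-8)
  expect_equal(to_um(y400), 36.64, tolerance = 2e-3)
  y40 <- compute_yinh(1e-5, 4e-6, ch, 1.85e-8)
  expect_equal(y400 / y40, sqrt(10), tolerance = 1e-12)
  # doubling b multiplies y_inh by sqrt(2) exactly
  expect_equal(compute_yinh(1e-5, 8e-5, ch, 1.85e-8) / y400, sqrt(2),
               tolerance = 1e-12)
  expect_error(compute_yinh(1e-5, 4e-5, ch, 0), "j = 0")
})

test_that("regime classification reproduces the reference length experiments", {
  get_regime <- function(L, b) {
    p <- fig_params(L = L, b = b)
    derived_scales(p)$regime
  }
  expect_equal(get_regime("100 um", "400 nm"), "long")
  expect_equal(get_regime("80 um", "400 nm"), "long")
  expect_equal(get_regime("20 um", "400 nm"), "short")
  expect_equal(get_regime("30 um", "400 nm"), "short")
  # boundary L = y_inh is assigned to long (tie-break)
  p <- fig_params(b = "400 nm")
  sc <- derived_scales(p)
  expect_equal(classify_regime(sc$y_inh, sc$c_hom, sc$y_inh, sc$f_aq, p$j),
               "long")
  # no pumping -> short
  expect_equal(classify_regime(1e-2, from_mM(300), Inf, 0.09, 0), "short")
})

test_that("derived scales are internally consistent", {
  p <- fig_params()
  sc <- derived_scales(p)
  expect_gt(sc$c_hom, p$c3)
  expect_equal(sc$A * p$L, sc$v_hom_L, tolerance = 1e-15)
  expect_equal(sc$A, 2 * p$j / (p$b * sc$c_hom), tolerance = 1e-15)
})

test_that("TJ velocities for reference parameters sit at 1e-7 to 1e-6 cm/s", {
  # k_TJ*RT*dc across physiological widths and osmotic differences
  v <- c()
  for (b_nm in c(40, 100, 200, 400)) {
    k <- compute_ktj(13.1e-3, 18, 2e-7, RT_CGS, b_nm * 1e-7)
    for (dc_mM in c(100, 200, 400))
      v <- c(v, k * RT_CGS * from_mM(dc_mM))
  }
  expect_true(all(v > 1e-9 & v < 1e-4))
  expect_true(any(v >= 1e-7 & v <= 1e-6))
})
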