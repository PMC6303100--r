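# Shared fixtures. All tests build their inputs in code; no stored data.

# reference constants (CGS)
RT_CGS <- 310.15 * 8.314e7

# the baseline used throughout the length/width experiments:
# c3 = 290 mM, c4 = 300 mM, c1 = 600 mM
fig_params <- function(L = "100 um", b = "400 nm", c1 = "600 mM", ...) {
  cleft_params(c3 = "290 mM", c4 = "300 mM", c1 = c1, L = L, b = b, ...)
}

# an exactly solvable fixture: with c1 = c4 = c_hom the homogeneous solution
# c == c_hom, v = A y satisfies the full nonlinear problem including both
# boundary conditions
homogeneous_params <- function(L = "100 um", b = "400 nm") {
  p0 <- cleft_params(c3 = "290 mM", L = L, b = b)
  ch <- compute_chom(p0$c3, p0$j, compute_faq(p0$k_aq, p0$V_wat, p0$n_aq))
  cleft_params(c3 = "290 mM", c1 = ch, c4 = ch, L = L, b = b)
}

# fast solver options for tests that do many solves
fast_opts <- function(n_mesh = 1025) solver_options(n_mesh = n_mesh)

max_rel_diff <- function(a, b, scale = pmax(abs(a), abs(b))) {
  max(abs(a - b) / max(scale))
}
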