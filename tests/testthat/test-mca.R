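# Finite-perturbation MCA against independent closed-form oracles.

test_that("finite-perturbation FCCs match the control-matrix closed form", {
  for (n in 2:3) for (seed in c(11, 23)) {
    m <- fix_chain(n, seed)
    ss <- find_steady_state(m)
    expect_true(ss$converged)
    oracle <- chain_fcc_oracle(m, ss)
    got <- vapply(names(m$enzymes), function(e)
      flux_control_coefficient(m, ss, e)$value, 0)
    expect_equal(unname(got), unname(oracle[names(got)]), tolerance = 1e-4)
    expect_equal(sum(got), 1, tolerance = 1e-3)
  }
})

test_that("a near-irreversible unsaturated first step takes all control", {
  params <- list(Vmax = c(100, 400), Keq = c(1e6, 50),
                 Km_s = c(500, 20), Km_p = c(1e6, 40), X0 = 10, Xn = 0.1)
  m <- generate_linear_chain(2, params)
  ss <- find_steady_state(m)
  c1 <- flux_control_coefficient(m, ss, "E1")$value
  expect_equal(c1, 1, tolerance = 0.05)
})

test_that("plus/minus estimates are reported and gated at 1%", {
  m <- fix_chain(2)
  ss <- find_steady_state(m)
  est <- flux_control_coefficient(m, ss, "E1")
  expect_true(est$accepted)
  expect_lt(est$discrepancy, 0.01)
  expect_equal(est$value, (est$plus + est$minus) / 2, tolerance = 1e-12)
})

test_that("R for Vmax equals the FCC and an unused parameter has R = 0", {
  m <- fix_chain(2)
  sp <- rbind(m$species, species_row("Zunused", fixed = TRUE, value = 5))
  m2 <- kinetic_model(sp, m$enzymes, m$reactions, m$moieties, m$meta)
  ss <- find_steady_state(m2)
  fcc <- flux_control_coefficient(m2, ss, "E2")$value
  rc <- response_coefficient(m2, ss, "Vmax_E2")$value
  expect_equal(rc, fcc, tolerance = 1e-9)
  expect_equal(response_coefficient(m2, ss, "conc_Zunused")$value, 0,
               tolerance = 1e-9)
})

test_that("elasticities: finite difference matches analytic and the hand oracle", {
  m <- fix_mfao()
  set.seed(3)
  cm <- compile_model(m)
  st <- stats::setNames(stats::rlnorm(cm$n_var, log(8), 0.6), cm$var_names)
  for (rx in c("VLCAD_C16", "MCKAT_C4", "MSCHAD_C6")) {
    ligs <- unique(unlist(m$reactions[[rx]]$groups))
    for (lg in ligs[c(1, length(ligs))]) {
      efd <- elasticity(m, st, rx, lg, method = "fd")
      ean <- elasticity(m, st, rx, lg, method = "analytic")
      expect_equal(efd, ean, tolerance = 1e-6)
    }
  }
  # independent closed form for the reversible MM chain law
  ch <- fix_chain(2)
  en <- ch$enzymes$E1
  st2 <- c(S1 = 7.3)
  expect_equal(elasticity(ch, st2, "E1", "S1"),
               rmm_elasticity(en$Vmax, en$Km[["X0"]], en$Km[["S1"]], en$Keq,
                              100, 7.3, wrt = "P"),
               tolerance = 1e-6)
})

test_that("saturated irreversible Michaelis-Menten elasticity tends to zero", {
  params <- list(Vmax = c(100, 100), Keq = c(1e8, 1e8),
                 Km_s = c(0.01, 10), Km_p = c(1e8, 1e8), X0 = 100, Xn = 1e-6)
  m <- generate_linear_chain(2, params)
  eps <- elasticity(m, c(S1 = 10), "E1", "X0")
  expect_lt(abs(eps), 1e-3)
})

test_that("the response dissection closes onto the direct coefficient", {
  m <- fix_mfao(25)
  ss <- fix_mfao_ss(25)
  dd <- dissect_response(m, ss, "ratio_NAD_NADH")
  expect_true(attr(dd, "closure_ok"))
  expect_equal(attr(dd, "sum_terms"), attr(dd, "direct"),
               tolerance = 0.01 * max(abs(attr(dd, "direct")), 1e-6))
  # parameter entering a single reaction -> a single nonzero term
  d1 <- dissect_response(m, ss, "Km_CPT1_CarCYT")
  expect_identical(nrow(d1), 1L)
  expect_identical(d1$reaction, "CPT1")
})
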