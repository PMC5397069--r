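# Time integration of models, steady-state solving, scans, flux peak.

test_that("an empty pathway is a fixed point of the integrator", {
  m <- set_parameter(fix_mfao(), "conc_C16AcylCoACYT", 0)
  cm <- compile_model(m)
  st <- stats::setNames(rep(0, cm$n_var), cm$var_names)
  st[["CoAMAT"]] <- m$moieties[[1]]$total
  st[["CarMAT"]] <- m$moieties[[2]]$total
  tr <- simulate_model(m, init = st, t_end = 50)
  expect_lt(max(abs(sweep(tr$y, 2, as.numeric(st[colnames(tr$y)])))), 1e-9)
})

test_that("conserved moieties drift less than 1e-6 relative over 400 min", {
  m <- fix_mfao(30)
  tr <- simulate_model(m, t_end = 400)
  tot <- moiety_totals(m, tr)
  for (k in seq_along(m$moieties)) {
    ref <- m$moieties[[k]]$total
    expect_lt(max(abs(tot[, k] - ref)) / ref, 1e-6)
  }
})

test_that("long integration and the root finder agree on the steady state", {
  m <- fix_chain(3, seed = 23)
  ss <- find_steady_state(m)
  expect_true(ss$converged)
  expect_lt(ss$residual, 1e-9)
  tr <- simulate_model(m, t_end = 2000, rtol = 1e-10, atol = 1e-12)
  xe <- tr$y[nrow(tr$y), ]
  rel <- abs(xe - ss$state[colnames(tr$y)]) / pmax(abs(ss$state[colnames(tr$y)]), 1e-4)
  expect_lt(max(rel), 1e-6)
  expect_lt(fix_ladder42_ss()$residual, 1e-9)
})

test_that("zero substrate gives zero flux and a full free CoA pool", {
  m <- set_parameter(fix_mfao(), "conc_C16AcylCoACYT", 0)
  ss <- find_steady_state(m)
  expect_true(ss$converged)
  expect_equal(ss$J_uptake, 0, tolerance = 1e-9)
  expect_equal(unname(ss$state[["CoAMAT"]]), m$moieties[[1]]$total, tolerance = 1e-6)
})

test_that("J_NADH / J_uptake equals the cycle count of the ladder", {
  ss16 <- fix_ladder42_ss()
  expect_equal(ss16$J_NADH / ss16$J_uptake, 7, tolerance = 1e-9)
  m8 <- memo("ladder8", generate_ladder(generator_config(start_chain = 8, seed = 5)))
  ss8 <- find_steady_state(m8)
  expect_true(ss8$converged)
  expect_gt(ss8$J_uptake, 0)
  expect_equal(ss8$J_NADH / ss8$J_uptake, 3, tolerance = 1e-9)
})

test_that("scans continue from the previous solution and match single solves", {
  m <- fix_mfao()
  sc <- scan_steady_states(m, grid = c(10, 25), rescan = FALSE)
  expect_true(all(sc$converged))
  one <- scan_steady_states(m, grid = 25, rescan = FALSE)
  direct <- find_steady_state(set_parameter(m, "conc_C16AcylCoACYT", 25))
  expect_equal(one$J_uptake, direct$J_uptake, tolerance = 1e-8)
  expect_equal(sc$J_uptake[2], direct$J_uptake, tolerance = 1e-8)
  # flux readouts present for every reaction
  expect_true(all(paste0("flux.", names(m$reactions)) %in% names(sc)))
})

test_that("find_flux_peak distinguishes monotone scans from interior maxima", {
  sc <- data.frame(param_value = 1:6, J_uptake = c(1, 2, 3, 3.5, 3.8, 3.9),
                   converged = TRUE)
  expect_false(find_flux_peak(sc)$interior)
  # exact parabola: vertex recovered from three points
  x <- c(1, 2, 3, 4, 5)
  sc2 <- data.frame(param_value = x, J_uptake = -(x - 2.6)^2, converged = TRUE)
  pk <- find_flux_peak(sc2)
  expect_true(pk$interior)
  expect_equal(pk$param, 2.6, tolerance = 1e-9)
})
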