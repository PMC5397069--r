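# The TR-BDF2 integrator against problems with known solutions.

test_that("linear decay is integrated to tolerance with dense output", {
  lam <- c(-1, -10, -100)
  f <- function(y) lam * y
  tr <- ode_integrate(f, c(1, 1, 1), t_end = 2, rtol = 1e-8, atol = 1e-12)
  tt <- c(0.13, 0.5, 1.27, 2)
  exact <- t(sapply(tt, function(t) exp(lam * t)))
  got <- tr$interp(tt)
  expect_lt(max(abs(got - exact)), 1e-6)
})

test_that("a stiff two-timescale system is handled without step collapse", {
  # fast component relaxes onto the slow manifold; eigenvalues -1 and -1000
  f <- function(y) c(-1000 * (y[1] - cos(y[2])), -y[2])
  tr <- ode_integrate(f, c(2, 1), t_end = 10, rtol = 1e-7, atol = 1e-10)
  yT <- tr$y[nrow(tr$y), ]
  expect_lt(abs(yT[2] - exp(-10)), 1e-6)
  expect_lt(abs(yT[1] - cos(yT[2])), 1e-4)
  # stiffness must not force steps at the fast scale once relaxed
  expect_lt(tr$n_accept, 2000)
})

test_that("nonlinear oscillator energy and dense output stay accurate", {
  f <- function(y) c(y[2], -sin(y[1]))
  tr <- ode_integrate(f, c(1, 0), t_end = 5, rtol = 1e-7, atol = 1e-10)
  E <- function(y) 0.5 * y[2]^2 - cos(y[1])
  e0 <- E(c(1, 0))
  emax <- max(abs(apply(tr$interp(seq(0, 5, 0.1)), 1, E) - e0))
  expect_lt(emax, 1e-4)
})

test_that("the integrator reports failure states cleanly", {
  f <- function(y) c(y^2)          # finite-time blow-up at t = 1
  expect_error(ode_integrate(f, 1, t_end = 2, rtol = 1e-8, atol = 1e-10),
               "stalled|max_steps|finite")
})
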