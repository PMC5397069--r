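# Time-dependent regulation analysis on a small (C8) instance: the
# chain-rule closure, normalization, and the degenerate no-shift case.

fix_c8 <- function() memo("mfao8", mfao_model(8))

test_that("a transition onto itself yields identically zero contributions", {
  m <- fix_c8()
  tr <- regulation_trace(m, 5, 5, "MCKAT_C4", t_end = 50)
  # bounded by steady-state solver noise amplified through log-derivatives
  expect_lt(max(abs(tr$theta)), 1e-6)
})

test_that("contributions close the chain rule and shares sum to exactly 1", {
  m <- fix_c8()
  tr <- memo("trace8", suppressWarnings(
    regulation_trace(m, 0.1, 60, "MCKAT_C4", t_end = 400)))
  expect_equal(sum(tr$rel_share), 1, tolerance = 1e-12)

  # finite-difference d ln v/dt along the dense trajectory vs sum(theta)
  cm <- compile_model(set_parameter(m, m$meta$substrate_param, 60))
  j <- match("MCKAT_C4", names(cm$model$reactions))
  vat <- function(t) {
    y <- tr$trajectory$interp(t)
    apply(y, 1, function(s) {
      names(s) <- cm$var_names
      eval_rate(cm, cm$rx[[j]], full_concentrations(cm, s))
    })
  }
  ts <- exp(seq(log(0.05), log(0.95 * tr$t_end), length.out = 25))
  h <- pmax(1e-3 * ts, 1e-4)
  fd <- (log(vat(ts + h)) - log(vat(ts - h))) / (2 * h)
  st <- sapply(ts, function(t) {
    s <- tr$trajectory$interp(t)[1, ]; names(s) <- cm$var_names
    x <- full_concentrations(cm, s); dx <- model_rhs(cm, s)
    tot <- 0
    for (lg in intersect(tr$ligands, cm$var_names)) if (x[[lg]] > 0)
      tot <- tot + analytic_elasticity(cm, cm$rx[[j]], x, lg) * dx[[lg]] / x[[lg]]
    tot
  })
  expect_lt(max(abs(fd - st)), 1e-4 * max(abs(tr$dlnv_dt)))
})

test_that("fixed pools contribute exactly zero and quadrature is converged", {
  tr <- memo("trace8", suppressWarnings(
    regulation_trace(fix_c8(), 0.1, 60, "MCKAT_C4", t_end = 400)))
  fixed_ligs <- intersect(tr$ligands, c("NAD", "NADH", "FAD", "FADH2"))
  for (lg in fixed_ligs) expect_equal(unname(tr$abs_avg[[lg]]), 0)
  # doubling the grid changes the averages by < 0.1 %
  tr2 <- suppressWarnings(regulation_trace(fix_c8(), 0.1, 60, "MCKAT_C4",
                                           t_end = 400, n_grid = 6401L))
  expect_lt(max(abs(tr2$abs_avg - tr$abs_avg[names(tr2$abs_avg)])) /
              sum(tr$abs_avg), 1e-3)
})

test_that("regulation profiles have unit columns and world-consistent signs", {
  m <- fix_c8()
  pr <- suppressWarnings(regulation_profile(m, c(20, 60), "MCKAT_C4",
                                            from_conc = 0.1, t_end = 400))
  expect_equal(unname(colSums(pr)), rep(1, ncol(pr)), tolerance = 1e-12)
  # the focal substrate is among the dominant contributors in overload
  expect_gt(pr["C4KetoacylCoA", "60"], 0.2)
})
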