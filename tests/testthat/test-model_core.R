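# Rate law, right-hand side, validation, conserved moieties.

zero_site <- function(model, reaction) {
  # named vector setting every acyl-site ligand of `reaction` to zero
  r <- model$reactions[[reaction]]
  stats::setNames(rep(0, length(r$groups$acyl)), r$groups$acyl)
}

test_that("promiscuous rate law reproduces its closed-form special cases", {
  m <- fix_mfao()
  en <- m$enzymes$VLCAD
  base <- zero_site(m, "VLCAD_C16")

  # substrate and cofactor each at their Km, no products/competitors:
  # numerator 1*1, denominator (1+1)(1+1) -> sf*Vmax/4
  conc <- base
  conc[["C16AcylCoA"]] <- en$Km[["C16AcylCoA"]]
  conc[["FAD"]] <- en$Km[["FAD"]]
  conc[["FADH2"]] <- 0
  sf <- m$reactions$VLCAD_C16$sf
  expect_equal(promiscuous_rate(m, "VLCAD_C16", conc), sf * en$Vmax / 4)

  # one competitor at its Km in the acyl site -> acyl factor 3 -> sf*Vmax/6
  conc2 <- conc
  conc2[["C14AcylCoA"]] <- en$Km[["C14AcylCoA"]]
  expect_equal(promiscuous_rate(m, "VLCAD_C16", conc2), sf * en$Vmax / 6)

  # mass-action ratio at Keq -> thermodynamic equilibrium, v = 0 even
  # with arbitrary competitors present
  conc3 <- conc2
  conc3[["FADH2"]] <- 25
  conc3[["C16EnoylCoA"]] <- en$Keq * conc[["C16AcylCoA"]] * conc[["FAD"]] / 25
  conc3[["C12AcylCoA"]] <- 7.7         # arbitrary competitor
  expect_equal(promiscuous_rate(m, "VLCAD_C16", conc3), 0, tolerance = 1e-12)

  expect_error(promiscuous_rate(m, "VLCAD_C16", c(NoSuchLigand = 1)), "unknown ligand")
  expect_error(promiscuous_rate(m, "NoSuchReaction"), "unknown reaction")
})

test_that("competitors inhibit monotonically and the denominator bounds the rate", {
  m <- fix_mfao()
  en <- m$enzymes$MCKAT
  base <- zero_site(m, "MCKAT_C4")
  base[["C4KetoacylCoA"]] <- 20
  base[["CoAMAT"]] <- 100
  v0 <- promiscuous_rate(m, "MCKAT_C4", base)
  expect_true(v0 > 0)
  # |v| <= sf*alpha*Vmax*(forward + reverse) since every denominator >= 1
  expect_lt(v0, m$reactions$MCKAT_C4$sf * en$Vmax *
              (base[["C4KetoacylCoA"]] / en$Km[["C4KetoacylCoA"]]) *
              (base[["CoAMAT"]] / en$Km[["CoAMAT"]]))
  # adding any competitor strictly decreases |v|
  prev <- v0
  for (comp in c("C6KetoacylCoA", "C8AcylCoA", "AcetylCoAMAT")) {
    conc <- base; conc[[comp]] <- 15
    vc <- promiscuous_rate(m, "MCKAT_C4", conc)
    expect_lt(vc, prev)
    base <- conc; prev <- vc
  }
})

test_that("rhs is stoichiometry times rates and annihilates the moiety vectors", {
  m <- fix_mfao()
  cm <- compile_model(m)
  set.seed(1)
  for (k in 1:5) {
    st <- stats::setNames(stats::rlnorm(cm$n_var, log(5), 1), cm$var_names)
    d <- model_rhs(cm, st)
    for (mo in m$moieties)
      expect_equal(sum(d[mo$species]), 0, tolerance = 1e-10 * max(abs(d)))
  }
  # empty pathway: no esters, no substrate -> fixed point
  m0 <- set_parameter(m, "conc_C16AcylCoACYT", 0)
  cm0 <- compile_model(m0)
  st0 <- stats::setNames(rep(0, cm0$n_var), cm0$var_names)
  st0[["CoAMAT"]] <- m$moieties[[1]]$total
  st0[["CarMAT"]] <- m$moieties[[2]]$total
  expect_equal(unname(model_rhs(cm0, st0)), rep(0, cm0$n_var))
})

test_that("rhs matches the derivative of a high-accuracy trajectory", {
  m <- fix_ladder42()
  cm <- compile_model(m)
  set.seed(7)
  st <- stats::setNames(pmax(cm$init, 0.5) * stats::runif(cm$n_var, 0.5, 2),
                        cm$var_names)
  # damp the fastest relaxation modes first so the central difference of
  # the trajectory is in the resolved regime of the slow dynamics
  burn <- simulate_model(cm, init = st, t_end = 0.05, rtol = 1e-10, atol = 1e-12)
  st <- burn$y[nrow(burn$y), ]
  h <- 1e-6
  tr <- simulate_model(cm, init = st, t_end = 2 * h, rtol = 1e-12, atol = 1e-14)
  fd <- (tr$interp(2 * h)[1, ] - as.numeric(st)) / (2 * h)
  mid <- model_rhs(cm, tr$interp(h)[1, ])
  scale <- max(abs(mid))
  expect_lt(max(abs(fd - mid)) / scale, 1e-4)
})

test_that("validation reports specific structural violations", {
  m <- fix_mfao()
  expect_identical(nrow(validate_model(m)), 0L)

  bad <- m
  bad$enzymes$MCKAT$Km[["C4KetoacylCoA"]] <- 0
  rep1 <- validate_model(bad)
  expect_true(any(grepl("MCKAT", rep1$where) & grepl("Km", rep1$problem)))

  bad2 <- m
  bad2$moieties[[1]]$species <- setdiff(bad2$moieties[[1]]$species, "C4AcylCoA")
  rep2 <- validate_model(bad2)
  expect_true(any(grepl("CoA", rep2$where) & grepl("not conserved", rep2$problem)))

  bad3 <- m
  bad3$reactions$MCKAT_C4$sf <- 1.7
  expect_true(any(grepl("sf", validate_model(bad3)$problem)))
})

test_that("declared moieties span the stoichiometric left null space", {
  for (mod in list(fix_mfao(), fix_ladder42())) {
    ns <- find_conserved_moieties(mod)
    expect_length(ns, length(mod$moieties))
    # every declared moiety is in the span of the discovered basis
    B <- do.call(cbind, ns)
    cm <- compile_model(mod)
    for (mo in mod$moieties) {
      w <- as.numeric(cm$var_names %in% mo$species)
      resid <- w - B %*% qr.solve(B, w)
      expect_lt(max(abs(resid)), 1e-8)
    }
  }
})

test_that("negative round-off concentrations are clipped before rate evaluation", {
  m <- fix_chain(2)
  cm <- compile_model(m)
  v1 <- reaction_rates(cm, c(S1 = -1e-13))
  v2 <- reaction_rates(cm, c(S1 = 0))
  expect_identical(v1, v2)
  old <- options(mfao.warn_clip = TRUE)
  on.exit(options(old))
  expect_warning(reaction_rates(cm, c(S1 = -1)), "clipped")
})
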