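# The seeded generators.

test_that("the ladder generator is deterministic per seed and validates", {
  a <- generate_ladder(generator_config(seed = 42))
  b <- generate_ladder(generator_config(seed = 42))
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_model(a, f1); write_model(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(nrow(validate_model(a)), 0L)
  c <- generate_ladder(generator_config(seed = 43))
  expect_false(isTRUE(all.equal(a$enzymes$MCKAT$Vmax, c$enzymes$MCKAT$Vmax)))
})

test_that("printed mFAO constants are embedded, other parameters drawn", {
  m <- generate_ladder(generator_config(seed = 9))
  expect_equal(m$reactions$MCKAT_C4$sf, 0.49)
  expect_equal(m$reactions$MCKAT_C6$sf, 1)
  expect_equal(unname(m$enzymes$MCKAT$Km[["C4KetoacylCoA"]]), 12.4)
  expect_equal(unname(m$enzymes$MCKAT$Km[["C6KetoacylCoA"]]), 6.7)
  expect_equal(m$enzymes$MSCHAD$Keq, 2.17e-4)
  expect_equal(m$enzymes$CROT$Keq, 3.13)
})

test_that("generated ladders of several seeds reach a steady state", {
  ok <- 0L
  for (seed in 1:6) {
    m <- generate_ladder(generator_config(seed = seed))
    ss <- find_steady_state(m)
    if (ss$converged) ok <- ok + 1L
    expect_true(ss$converged, label = sprintf("seed %d converged", seed))
  }
  expect_gte(ok, 6L)
})

test_that("the chain-length structure follows the stated topology", {
  m <- generate_ladder(generator_config(start_chain = 16, seed = 1))
  enz_of <- vapply(m$reactions, `[[`, "", "enzyme")
  expect_identical(sum(enz_of == "MCKAT"), 7L)
  expect_identical(sum(enz_of == "CROT"), 7L)
  expect_identical(sum(enz_of == "MSCHAD"), 7L)
  expect_identical(sum(enz_of == "MTP"), 5L)
  vl <- vapply(m$reactions[enz_of == "VLCAD"], `[[`, 0L, "chain")
  expect_setequal(vl, c(12L, 14L, 16L))
  mt <- vapply(m$reactions[enz_of == "MTP"], `[[`, 0L, "chain")
  expect_setequal(mt, seq(8L, 16L, 2L))
  # thiolase stoichiometry: C4 gives two acetyl-CoA, Cn gives C(n-2) + acetyl
  expect_equal(m$reactions$MCKAT_C4$products, c(AcetylCoAMAT = 2))
  expect_equal(sort(names(m$reactions$MCKAT_C10$products)),
               c("AcetylCoAMAT", "C8AcylCoA"))
  expect_error(generator_config(start_chain = 7), "even|%%")
})

test_that("linear chains reject unsupported sizes", {
  expect_error(generate_linear_chain(4), "2 or 3")
})
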