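# Promiscuity-removal model surgery.

test_that("alpha is one over the enzyme's reaction count", {
  m <- fix_mfao()
  mv <- remove_promiscuity(m, c("MCKAT", "MTP"))
  expect_equal(mv$reactions$MCKAT_C4$alpha, 1 / 7)
  expect_equal(mv$reactions$MTP_C12$alpha, 1 / 5)
  # untreated enzymes untouched
  expect_identical(mv$reactions$VLCAD_C16, m$reactions$VLCAD_C16)
  # treated alphas sum to 1 per enzyme
  a <- vapply(mv$reactions, function(r)
    if (r$enzyme == "MCKAT") r$alpha else 0, 0)
  expect_equal(sum(a), 1)
})

test_that("treated denominators keep only the reaction's own ligands", {
  m <- fix_mfao()
  mv <- remove_promiscuity(m, "VLCAD")
  g <- mv$reactions$VLCAD_C16$groups
  expect_setequal(g$acyl, c("C16AcylCoA", "C16EnoylCoA"))
  expect_setequal(g$cofactor, c("FAD", "FADH2"))
  # MCKAT untreated here: full competitive site retained
  expect_gt(length(mv$reactions$MCKAT_C4$groups$acyl), 3)
})

test_that("surgery is idempotent and single-reaction enzymes are unchanged", {
  m <- fix_mfao()
  once <- remove_promiscuity(m, "all")
  twice <- remove_promiscuity(once, "all")
  expect_identical(once$reactions, twice$reactions)
  # CPT1 catalyses a single reaction: alpha 1, law unchanged
  expect_equal(once$reactions$CPT1$alpha, 1)
  expect_identical(once$reactions$CPT1$groups, m$reactions$CPT1$groups)
})

test_that("with no cross-chain competitors present the laws differ exactly by alpha", {
  m <- fix_mfao()
  mv <- remove_promiscuity(m, "MCKAT")
  conc <- stats::setNames(rep(0, length(m$reactions$MCKAT_C4$groups$acyl)),
                          m$reactions$MCKAT_C4$groups$acyl)
  conc[["C4KetoacylCoA"]] <- 9
  conc[["AcetylCoAMAT"]] <- 30
  conc[["CoAMAT"]] <- 120
  v_full <- promiscuous_rate(m, "MCKAT_C4", conc)
  v_var <- promiscuous_rate(mv, "MCKAT_C4", conc)
  expect_equal(v_var, v_full / 7, tolerance = 1e-12)
})

test_that("unknown enzymes are a configuration error", {
  expect_error(remove_promiscuity(fix_mfao(), "NOPE"), "unknown enzyme")
})
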