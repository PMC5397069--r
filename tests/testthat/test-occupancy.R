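# Active-site occupancy and flux breakdowns.

test_that("occupancy is normalized: ligands plus free site sum to one", {
  m <- fix_mfao()
  set.seed(4)
  cm <- compile_model(m)
  st <- stats::setNames(stats::rlnorm(cm$n_var, log(10), 1), cm$var_names)
  for (e in c("MCKAT", "MCAD", "SCAD")) {
    tbl <- active_site_occupancy(m, st, e)
    expect_true(all(tbl$occupancy >= 0 & tbl$occupancy <= 1))
    expect_equal(sum(tbl$occupancy) + attr(tbl, "free"), 1, tolerance = 1e-12)
  }
})

test_that("a single ligand at its Km occupies exactly half the sites", {
  m <- fix_mfao()
  lig <- m$reactions$MCKAT_C4$groups$acyl
  st <- stats::setNames(rep(0, length(lig)), lig)
  st[["C4KetoacylCoA"]] <- m$enzymes$MCKAT$Km[["C4KetoacylCoA"]]
  full <- stats::setNames(rep(0, sum(!m$species$fixed)),
                          m$species$name[!m$species$fixed])
  full[names(st)] <- st
  tbl <- active_site_occupancy(m, full, "MCKAT")
  expect_equal(tbl$occupancy[tbl$ligand == "C4KetoacylCoA"], 0.5)
  expect_equal(sum(tbl$occupancy), 0.5)
  # all ligands zero -> empty site
  tbl0 <- active_site_occupancy(m, full * 0, "MCKAT")
  expect_equal(sum(tbl0$occupancy), 0)
  expect_equal(attr(tbl0, "free"), 1)
})

test_that("occupancy is monotone in the focal ligand and decreasing in others", {
  m <- fix_mfao()
  base <- stats::setNames(rep(2, sum(!m$species$fixed)),
                          m$species$name[!m$species$fixed])
  occ <- function(st) {
    tbl <- active_site_occupancy(m, st, "MCKAT")
    tbl$occupancy[tbl$ligand == "C4KetoacylCoA"]
  }
  up <- base; up[["C4KetoacylCoA"]] <- 10
  other <- base; other[["C6AcylCoA"]] <- 50
  expect_gt(occ(up), occ(base))
  expect_lt(occ(other), occ(base))
})

test_that("the literal supplementary convention double-counts the focal ligand", {
  m <- fix_mfao()
  full <- stats::setNames(rep(0, sum(!m$species$fixed)),
                          m$species$name[!m$species$fixed])
  full[["C4KetoacylCoA"]] <- m$enzymes$MCKAT$Km[["C4KetoacylCoA"]]
  tbl <- active_site_occupancy(m, full, "MCKAT", convention = "literal")
  expect_equal(tbl$occupancy[tbl$ligand == "C4KetoacylCoA"], 1 / 3)
})

test_that("flux breakdown sums to enzyme totals and balances every node", {
  ss <- fix_ladder42_ss()
  m <- fix_ladder42()
  fb <- flux_breakdown(m, ss)
  by_e <- attr(fb, "by_enzyme")
  expect_equal(unname(by_e[["MCKAT"]]),
               sum(fb$flux[fb$enzyme == "MCKAT"]))
  expect_lt(max(abs(node_balance(m, ss))), 1e-9)
  # C4/C6 conversion runs only through the short-chain branch: the MTP
  # branch has no C4/C6 reactions by construction
  expect_false(any(fb$enzyme == "MTP" & fb$chain %in% c(4, 6)))
  # per chain, ketoacyl consumption is all MCKAT: flux equals the chain flux
  expect_gt(fb$flux[fb$reaction == "MCKAT_C4"], 0)
})
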