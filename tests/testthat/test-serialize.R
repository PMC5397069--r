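# JSON model serialization and SBML import.

test_that("native models round-trip through JSON losslessly", {
  m <- fix_mfao()
  f <- tempfile(fileext = ".json")
  write_model(m, f)
  m2 <- read_model(f)
  cm <- compile_model(m); cm2 <- compile_model(m2)
  expect_identical(cm$var_names, cm2$var_names)
  set.seed(2)
  st <- stats::setNames(stats::rlnorm(cm$n_var, log(5), 1), cm$var_names)
  expect_equal(reaction_rates(cm2, st), reaction_rates(cm, st),
               tolerance = 1e-12)
  expect_equal(vapply(m2$moieties, `[[`, 0, "total"),
               vapply(m$moieties, `[[`, 0, "total"))
  expect_identical(m2$meta$uptake_reaction, m$meta$uptake_reaction)
})

test_that("SBML import reproduces hand-computed kinetic-law values", {
  path <- system.file("extdata", "synthetic_chain.sbml.xml", package = "mfao")
  m <- import_sbml(path)
  expect_identical(sort(m$species$name), c("S1", "X0", "Xn"))
  expect_identical(m$species$fixed[match(c("X0", "Xn", "S1"), m$species$name)],
                   c(TRUE, TRUE, FALSE))
  cm <- compile_model(m)
  v <- reaction_rates(cm, c(S1 = 10))
  expect_equal(unname(v[["E1"]]), 100 * (100 / 10 - 10 / (10 * 10)) / (1 + 10 + 10 / 20))
  expect_equal(unname(v[["E2"]]), 200 * (10 / 15 - 1 / 75) / (1 + 10 / 15 + 1 / 30))
  expect_identical(unname(m$meta$checksum), unname(tools::md5sum(path)))
})

test_that("imported models solve to the same steady state as the native twin", {
  path <- system.file("extdata", "synthetic_chain.sbml.xml", package = "mfao")
  mi <- import_sbml(path)
  ss_i <- find_steady_state(mi)
  mn <- generate_linear_chain(2, params = list(
    Vmax = c(100, 200), Keq = c(10, 5), Km_s = c(10, 15), Km_p = c(20, 30),
    X0 = 100, Xn = 1))
  ss_n <- find_steady_state(mn)
  expect_true(ss_i$converged && ss_n$converged)
  expect_equal(ss_i$state[["S1"]], ss_n$state[["S1"]], tolerance = 1e-8)
  expect_equal(unname(ss_i$fluxes[["E2"]]), unname(ss_n$fluxes[["E2"]]),
               tolerance = 1e-8)
})

test_that("imported expression models round-trip through JSON", {
  path <- system.file("extdata", "synthetic_chain.sbml.xml", package = "mfao")
  m <- import_sbml(path)
  f <- tempfile(fileext = ".json")
  write_model(m, f)
  m2 <- read_model(f)
  expect_equal(reaction_rates(compile_model(m2), c(S1 = 10)),
               reaction_rates(compile_model(m), c(S1 = 10)), tolerance = 1e-12)
})

test_that("a canonical-name map renames and annotates imported species", {
  nm <- read_name_map(system.file("extdata", "synthetic_chain_name_map.tsv",
                                  package = "mfao"))
  m <- import_sbml(system.file("extdata", "synthetic_chain.sbml.xml",
                               package = "mfao"), name_map = nm)
  expect_setequal(m$species$name, c("BoundaryAcylCoA", "Intermediate", "ProductPool"))
  i <- match("BoundaryAcylCoA", m$species$name)
  expect_identical(m$species$class[i], "acyl-CoA")
  expect_identical(m$species$chain[i], 4L)
  v <- reaction_rates(compile_model(m), c(Intermediate = 10))
  expect_equal(unname(v[["E1"]]),
               100 * (100 / 10 - 10 / (10 * 10)) / (1 + 10 + 10 / 20))
})

test_that("unsupported MathML constructs raise an import error naming them", {
  bad <- tempfile(fileext = ".xml")
  writeLines(sub("<ci>V</ci>", "<apply><sin/><ci>V</ci></apply>",
                 readLines(system.file("extdata", "synthetic_chain.sbml.xml",
                                       package = "mfao"))), bad)
  expect_error(import_sbml(bad), "unsupported MathML")
})
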