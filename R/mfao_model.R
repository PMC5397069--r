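# The rat-liver mFAO network: a carnitine shuttle (CPT1, CACT, CPT2)
# importing the activated fatty acid into the matrix, four overlapping
# acyl-CoA dehydrogenases (VLCAD, LCAD, MCAD, SCAD), the lumped
# trifunctional protein MTP (hydratase + NAD+ dehydrogenase + thiolase,
# C8 and longer), and the short-chain branch CROT - M/SCHAD - MCKAT
# covering C4 through C16. Every enzyme is promiscuous: all CoA esters
# it can produce or consume compete for the acyl binding site.
#
# Free CoA plus all variable CoA esters (acetyl-CoA included) is a
# conserved moiety; matrix carnitine plus matrix acyl-carnitine is a
# second one. Acetyl-CoA is drained by an irreversible Krebs-cycle sink
# that returns free CoA, which keeps the CoA moiety exactly conserved
# while still providing the boundary sink the steady state needs.

chain_label <- function(n) paste0("C", n)

# paste0() coerces zero-length inputs to ""; ladders built for short
# start chains need genuinely empty name sets instead
chain_names <- function(ns, suffix) {
  if (length(ns)) paste0("C", ns, suffix) else character(0)
}

acad_ranges <- function(n0) {
  rng <- list(VLCAD = c(12, 14, 16), LCAD = seq(8, 16, 2),
              MCAD = seq(4, 12, 2), SCAD = c(4, 6))
  rng <- lapply(rng, function(r) r[r <= n0])
  rng[vapply(rng, length, 0L) > 0]
}

#' Enumerate the mFAO topology for a given starting chain length
#'
#' Pure structure: species, reactions with their ligand sets and
#' binding-site groups, and moiety membership. Parameter constructors
#' ([mfao_parameters()], the synthetic generator) consume this to know
#' which Km/sf values each enzyme needs.
#'
#' @param start_chain even starting chain length (4..16); 16 is
#'   palmitoyl-CoA, the full pathway.
#' @return list with `species`, `reactions` (skeletons without rates),
#'   `enzyme_chains` (named list of chain-length vectors), `moieties`.
#' @export
mfao_topology <- function(start_chain = 16) {
  n0 <- as.integer(start_chain)
  if (n0 %% 2 != 0 || n0 < 4 || n0 > 16)
    stop("start_chain must be even and in [4, 16]", call. = FALSE)
  chains <- seq(4L, n0, 2L)
  sub_cyt <- paste0("C", n0, "AcylCoACYT")
  acar_cyt <- paste0("C", n0, "AcylCarCYT")
  acar_mat <- paste0("C", n0, "AcylCarMAT")

  sp <- rbind(
    species_row(sub_cyt, "acyl-CoA", n0, "cyt", fixed = TRUE, value = 0.1),
    species_row("CarCYT", "carnitine", NA, "cyt", fixed = TRUE, value = 500),
    species_row("CoACYT", "coa", NA, "cyt", fixed = TRUE, value = 40),
    species_row("NAD", "cofactor", NA, "mit", fixed = TRUE, value = 240),
    species_row("NADH", "cofactor", NA, "mit", fixed = TRUE, value = 15),
    species_row("FAD", "cofactor", NA, "mit", fixed = TRUE, value = 100),
    species_row("FADH2", "cofactor", NA, "mit", fixed = TRUE, value = 10),
    species_row(acar_cyt, "acyl-carnitine", n0, "cyt", value = 0.01),
    species_row(acar_mat, "acyl-carnitine", n0, "mit", value = 0.01),
    species_row("CarMAT", "carnitine", NA, "mit", value = 0),
    species_row("CoAMAT", "coa", NA, "mit", value = 0),
    species_row("AcetylCoAMAT", "acetyl-CoA", 2, "mit", value = 0.1)
  )
  # chain = 2 is acetyl-CoA; ester ladder species:
  sp$chain[sp$name == "AcetylCoAMAT"] <- NA  # keep chain invariant 4..16 for esters
  for (n in rev(chains)) {
    sp <- rbind(sp,
      species_row(paste0("C", n, "AcylCoA"), "acyl-CoA", n, "mit", value = 0.01),
      species_row(paste0("C", n, "EnoylCoA"), "enoyl-CoA", n, "mit", value = 0.01),
      species_row(paste0("C", n, "HydroxyacylCoA"), "hydroxyacyl-CoA", n, "mit", value = 0.01),
      species_row(paste0("C", n, "KetoacylCoA"), "ketoacyl-CoA", n, "mit", value = 0.01))
  }

  acads <- acad_ranges(n0)
  ech <- c(list(CPT1 = n0, CACT = n0, CPT2 = n0), acads,
           if (n0 >= 8) list(MTP = seq(8L, n0, 2L)),
           list(CROT = chains, MSCHAD = chains, MCKAT = chains, ACS = NA))

  rx <- list()
  add <- function(r) rx[[length(rx) + 1L]] <<- r
  add(list(name = "CPT1", enzyme = "CPT1", chain = n0,
           substrates = stats::setNames(c(1, 1), c(sub_cyt, "CarCYT")),
           products = stats::setNames(c(1, 1), c(acar_cyt, "CoACYT")),
           groups = list(acyl = c(sub_cyt, acar_cyt), cofactor = c("CarCYT", "CoACYT"))))
  add(list(name = "CACT", enzyme = "CACT", chain = n0,
           substrates = stats::setNames(c(1, 1), c(acar_cyt, "CarMAT")),
           products = stats::setNames(c(1, 1), c(acar_mat, "CarCYT")),
           groups = list(acyl = c(acar_cyt, acar_mat), cofactor = c("CarMAT", "CarCYT"))))
  add(list(name = "CPT2", enzyme = "CPT2", chain = n0,
           substrates = stats::setNames(c(1, 1), c(acar_mat, "CoAMAT")),
           products = stats::setNames(c(1, 1), c(paste0("C", n0, "AcylCoA"), "CarMAT")),
           groups = list(acyl = c(acar_mat, paste0("C", n0, "AcylCoA")),
                         cofactor = c("CoAMAT", "CarMAT"))))
  for (e in names(acads)) {
    rng <- acads[[e]]
    site <- c(paste0("C", rng, "AcylCoA"), paste0("C", rng, "EnoylCoA"))
    for (n in rng)
      add(list(name = paste0(e, "_C", n), enzyme = e, chain = n,
               substrates = stats::setNames(c(1, 1), c(paste0("C", n, "AcylCoA"), "FAD")),
               products = stats::setNames(c(1, 1), c(paste0("C", n, "EnoylCoA"), "FADH2")),
               groups = list(acyl = site, cofactor = c("FAD", "FADH2"))))
  }
  if (n0 >= 8) {
    rng <- seq(8L, n0, 2L)
    site <- c(paste0("C", rng, "EnoylCoA"), paste0("C", rng - 2L, "AcylCoA"), "AcetylCoAMAT")
    for (n in rng)
      add(list(name = paste0("MTP_C", n), enzyme = "MTP", chain = n,
               substrates = stats::setNames(c(1, 1, 1),
                 c(paste0("C", n, "EnoylCoA"), "NAD", "CoAMAT")),
               products = stats::setNames(c(1, 1, 1),
                 c(paste0("C", n - 2L, "AcylCoA"), "NADH", "AcetylCoAMAT")),
               groups = list(acyl = unique(site), nad = c("NAD", "NADH"), coa = "CoAMAT")))
  }
  crot_site <- c(paste0("C", chains, "EnoylCoA"), paste0("C", chains, "HydroxyacylCoA"))
  for (n in chains)
    add(list(name = paste0("CROT_C", n), enzyme = "CROT", chain = n,
             substrates = stats::setNames(1, paste0("C", n, "EnoylCoA")),
             products = stats::setNames(1, paste0("C", n, "HydroxyacylCoA")),
             groups = list(acyl = crot_site)))
  had_site <- c(paste0("C", chains, "HydroxyacylCoA"), paste0("C", chains, "KetoacylCoA"))
  for (n in chains)
    add(list(name = paste0("MSCHAD_C", n), enzyme = "MSCHAD", chain = n,
             substrates = stats::setNames(c(1, 1), c(paste0("C", n, "HydroxyacylCoA"), "NAD")),
             products = stats::setNames(c(1, 1), c(paste0("C", n, "KetoacylCoA"), "NADH")),
             groups = list(acyl = had_site, cofactor = c("NAD", "NADH"))))
  mckat_site <- unique(c(paste0("C", chains, "KetoacylCoA"),
                         chain_names(setdiff(chains, 4L) - 2L, "AcylCoA"), "AcetylCoAMAT"))
  for (n in chains) {
    prods <- if (n == 4L) stats::setNames(2, "AcetylCoAMAT") else
      stats::setNames(c(1, 1), c(paste0("C", n - 2L, "AcylCoA"), "AcetylCoAMAT"))
    add(list(name = paste0("MCKAT_C", n), enzyme = "MCKAT", chain = n,
             substrates = stats::setNames(c(1, 1), c(paste0("C", n, "KetoacylCoA"), "CoAMAT")),
             products = prods,
             groups = list(acyl = mckat_site, coa = "CoAMAT")))
  }
  add(list(name = "ACS", enzyme = "ACS", chain = NA,
           substrates = stats::setNames(1, "AcetylCoAMAT"),
           products = stats::setNames(1, "CoAMAT"),
           groups = list(acyl = "AcetylCoAMAT"), irreversible = TRUE))

  esters <- c("CoAMAT", "AcetylCoAMAT",
              as.vector(t(outer(paste0("C", chains),
                                c("AcylCoA", "EnoylCoA", "HydroxyacylCoA", "KetoacylCoA"),
                                paste0))))
  moieties <- list(
    list(name = "CoA", species = esters, total = 8000, eliminate = "CoAMAT"),
    list(name = "Carnitine", species = c("CarMAT", acar_mat), total = 1000,
         eliminate = "CarMAT"))

  list(species = sp, reactions = rx, enzyme_chains = ech, moieties = moieties,
       start_chain = n0, substrate = sub_cyt)
}

#' Curated default parameterization of the mFAO instance
#'
#' The deposited parameterization of the published rat-liver model lives
#' on JWS Online and is imported with [import_sbml()] when available.
#' This function provides the package's self-contained stand-in: a
#' synthetic parameter set anchored to the four printed constants
#' (Keq of M/SCHAD = 2.17e-4, Keq of CROT = 3.13, sf of MCKAT for
#' C4 = 0.49 vs C6 = 1, Km of MCKAT for C4-/C6-ketoacyl-CoA =
#' 12.4 / 6.7 uM) and chosen so the instance exhibits the documented
#' substrate-overload phenotype: a low-capacity MCKAT fed by a strongly
#' amplifying near-equilibrium M/SCHAD. Units are uM and min throughout.
#'
#' @param start_chain starting chain length (default 16).
#' @return nested parameter list consumed by [build_mfao_topology()].
#' @export
mfao_parameters <- function(start_chain = 16) {
  topo <- mfao_topology(start_chain)
  n0 <- topo$start_chain
  chains <- seq(4L, n0, 2L)
  lab <- function(n) paste0("C", n)

  # ester Km (uM) per enzyme and species-class; MCKAT ketoacyl C4/C6 printed
  km_ladder <- function(species, value) stats::setNames(rep(value, length(species)), species)

  sf_map <- list(
    VLCAD = c(C12 = 0.4, C14 = 0.9, C16 = 1),
    LCAD = c(C8 = 0.6, C10 = 0.8, C12 = 1, C14 = 0.6, C16 = 0.3),
    MCAD = c(C4 = 0.25, C6 = 0.9, C8 = 1, C10 = 0.8, C12 = 0.4),
    SCAD = c(C4 = 1, C6 = 0.5),
    MTP = c(C8 = 1, C10 = 0.9, C12 = 0.8, C14 = 0.7, C16 = 0.6),
    CROT = stats::setNames(seq(1, 0.55, length.out = 7), lab(seq(4, 16, 2))),
    MSCHAD = stats::setNames(seq(1, 0.6, length.out = 7), lab(seq(4, 16, 2))),
    MCKAT = c(C4 = 0.49, C6 = 1, C8 = 0.7, C10 = 0.65, C12 = 0.6, C14 = 0.55, C16 = 0.5)
  )

  acads <- acad_ranges(n0)
  enz <- list()
  enz$CPT1 <- list(Vmax = 150, Keq = 0.45,
                   Km = c(stats::setNames(c(50, 30), c(topo$substrate, paste0("C", n0, "AcylCarCYT"))),
                          CarCYT = 125, CoACYT = 40))
  enz$CACT <- list(Vmax = 1500, Keq = 1,
                   Km = c(stats::setNames(c(15, 15),
                          paste0("C", n0, c("AcylCarCYT", "AcylCarMAT"))),
                          CarMAT = 500, CarCYT = 500))
  enz$CPT2 <- list(Vmax = 500, Keq = 2,
                   Km = c(stats::setNames(c(15, 25), c(paste0("C", n0, "AcylCarMAT"),
                                                       paste0("C", n0, "AcylCoA"))),
                          CoAMAT = 30, CarMAT = 350))
  acad_vmax <- c(VLCAD = 400, LCAD = 300, MCAD = 1500, SCAD = 600)
  for (e in names(acads)) {
    rng <- acads[[e]]
    enz[[e]] <- list(Vmax = unname(acad_vmax[e]), Keq = 10,
                     Km = c(km_ladder(paste0("C", rng, "AcylCoA"), 10),
                            km_ladder(paste0("C", rng, "EnoylCoA"), 60),
                            FAD = 80, FADH2 = 25),
                     sf = sf_map[[e]][lab(rng)])
  }
  if (n0 >= 8) {
    rng <- seq(8L, n0, 2L)
    enz$MTP <- list(Vmax = 2000, Keq = 6.8,
                    Km = c(km_ladder(paste0("C", rng, "EnoylCoA"), 25),
                           km_ladder(paste0("C", rng - 2L, "AcylCoA"), 50),
                           AcetylCoAMAT = 300, NAD = 60, NADH = 50, CoAMAT = 30),
                    sf = sf_map$MTP[lab(rng)])
  }
  enz$CROT <- list(Vmax = 2000, Keq = 3.13,
                   Km = c(km_ladder(paste0("C", chains, "EnoylCoA"), 25),
                          km_ladder(paste0("C", chains, "HydroxyacylCoA"), 45)),
                   sf = sf_map$CROT[lab(chains)])
  enz$MSCHAD <- list(Vmax = 3000, Keq = 2.17e-4,
                     Km = c(km_ladder(paste0("C", chains, "HydroxyacylCoA"), 12),
                            km_ladder(paste0("C", chains, "KetoacylCoA"), 20),
                            NAD = 30, NADH = 10),
                     sf = sf_map$MSCHAD[lab(chains)])
  mckat_keto <- km_ladder(paste0("C", chains, "KetoacylCoA"), 8)
  if (4L %in% chains) mckat_keto[["C4KetoacylCoA"]] <- 12.4
  if (6L %in% chains) mckat_keto[["C6KetoacylCoA"]] <- 6.7
  enz$MCKAT <- list(Vmax = 5000, Keq = 1e4,
                    Km = c(mckat_keto,
                           km_ladder(chain_names(setdiff(chains, 4L) - 2L, "AcylCoA"), 2.5),
                           AcetylCoAMAT = 200, CoAMAT = 25),
                    sf = sf_map$MCKAT[lab(chains)])
  enz$ACS <- list(Vmax = 1200, Keq = NA_real_, Km = c(AcetylCoAMAT = 100), sf = c(all = 1))

  list(start_chain = n0,
       boundary = stats::setNames(
         c(0.1, 500, 40, 240, 15, 100, 10),
         c(topo$substrate, "CarCYT", "CoACYT", "NAD", "NADH", "FAD", "FADH2")),
       totals = c(CoA = 8000, Carnitine = 1000),
       enzymes = enz)
}

#' Build an mFAO kinetic model from a parameter set
#'
#' Assembles the network of [mfao_topology()] with the supplied
#' parameters and validates the result. Raises a configuration error
#' naming the enzyme and chain length if a required parameter is absent.
#'
#' @param params parameter set as from [mfao_parameters()] or the
#'   synthetic generator.
#' @return a validated `kinetic_model`.
#' @export
build_mfao_topology <- function(params) {
  topo <- mfao_topology(params$start_chain)
  sp <- topo$species
  for (nm in names(params$boundary)) {
    i <- match(nm, sp$name)
    if (is.na(i)) stop("boundary species not in topology: ", nm, call. = FALSE)
    sp$value[i] <- params$boundary[[nm]]
  }
  enzymes <- list()
  for (e in names(params$enzymes)) {
    pe <- params$enzymes[[e]]
    enzymes[[e]] <- enzyme(e, Vmax = pe$Vmax, Keq = pe$Keq, Km = pe$Km)
  }
  reactions <- lapply(topo$reactions, function(r) {
    pe <- params$enzymes[[r$enzyme]]
    if (is.null(pe)) stop("missing parameters for enzyme ", r$enzyme, call. = FALSE)
    sf <- 1
    if (!is.null(pe$sf) && !is.na(r$chain)) {
      sf <- pe$sf[[chain_label(r$chain)]]
      if (is.null(sf) || is.na(sf))
        stop(sprintf("missing sf for enzyme %s chain C%d", r$enzyme, r$chain), call. = FALSE)
    }
    need <- c(names(r$substrates),
              if (!isTRUE(r$irreversible)) names(r$products))
    miss <- setdiff(unique(c(need, unlist(r$groups))), names(pe$Km))
    if (length(miss))
      stop(sprintf("enzyme %s (chain %s): missing Km for %s", r$enzyme,
                   ifelse(is.na(r$chain), "-", r$chain),
                   paste(miss, collapse = ", ")), call. = FALSE)
    reaction(r$name, r$enzyme, r$chain, r$substrates, r$products, r$groups,
             sf = sf, alpha = 1, reversible = !isTRUE(r$irreversible))
  })
  moieties <- topo$moieties
  moieties[[1]]$total <- unname(params$totals[["CoA"]])
  moieties[[2]]$total <- unname(params$totals[["Carnitine"]])

  # start the variable pools from a nearly empty pathway
  iCoA <- match("CoAMAT", sp$name); iCar <- match("CarMAT", sp$name)
  vmask <- !sp$fixed & sp$name %in% moieties[[1]]$species & sp$name != "CoAMAT"
  sp$value[iCoA] <- moieties[[1]]$total - sum(sp$value[vmask])
  sp$value[iCar] <- moieties[[2]]$total -
    sum(sp$value[match(setdiff(moieties[[2]]$species, "CarMAT"), sp$name)])

  m <- kinetic_model(sp, enzymes, reactions, moieties,
                     meta = list(name = sprintf("mFAO C%d ladder", topo$start_chain),
                                 uptake_reaction = "CACT",
                                 substrate_param = paste0("conc_", topo$substrate),
                                 start_chain = topo$start_chain))
  rep <- validate_model(m)
  if (nrow(rep)) stop("invalid mFAO model:\n",
                      paste(sprintf("  %s: %s", rep$where, rep$problem), collapse = "\n"),
                      call. = FALSE)
  m
}

#' The packaged default mFAO model instance
#'
#' @param start_chain starting chain length (16 = palmitoyl-CoA).
#' @param substrate cytosolic substrate concentration in uM.
#' @return a `kinetic_model`.
#' @export
mfao_model <- function(start_chain = 16, substrate = 0.1) {
  p <- mfao_parameters(start_chain)
  p$boundary[[1]] <- substrate
  build_mfao_topology(p)
}
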