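# Seeded generator of synthetic pathway instances: full beta-oxidation
# ladders with the mFAO topology but randomized kinetics, and tiny
# linear reversible Michaelis-Menten chains whose control coefficients
# have closed forms (the MCA oracle fixtures).

#' Configuration for the synthetic ladder generator
#'
#' Parameter distributions are the stated defaults: Km log-uniform on
#' \[1, 100\] uM, Vmax log-uniform on \[10, 1000\] uM/min, sf uniform on
#' (0.3, 1\]. Equilibrium constants are fixed per reaction class:
#' 2.17e-4 for the hydroxyacyl-CoA dehydrogenase class, 3.13 for the
#' crotonase class, 1 otherwise; the lumped MTP gets the product of its
#' three constituent classes. The four printed mFAO constants (MCKAT sf
#' and ketoacyl Km for C4/C6) are embedded as fixed defaults so the
#' synthetic C16 instance shows the amplification mechanism
#' qualitatively.
#'
#' @param start_chain even starting chain length in 4..16.
#' @param seed integer random seed (mandatory for reproducibility).
#' @param km_range,vmax_range log-uniform sampling ranges.
#' @param sf_range uniform sampling range for specificity factors.
#' @param keq hydroxyacyl-dehydrogenase / crotonase / other class Keq.
#' @param coa_total,carnitine_total conserved moiety totals (uM).
#' @param substrate boundary substrate concentration (uM).
#' @return list of class `generator_config`.
#' @export
generator_config <- function(start_chain = 16, seed = 1L,
                             km_range = c(1, 100), vmax_range = c(10, 1000),
                             sf_range = c(0.3, 1),
                             keq = c(mschad = 2.17e-4, crot = 3.13, other = 1),
                             coa_total = 8000, carnitine_total = 1000,
                             substrate = 20) {
  stopifnot(start_chain %% 2 == 0, start_chain >= 4, start_chain <= 16)
  structure(list(start_chain = as.integer(start_chain), seed = as.integer(seed),
                 km_range = km_range, vmax_range = vmax_range, sf_range = sf_range,
                 keq = keq, coa_total = coa_total, carnitine_total = carnitine_total,
                 substrate = substrate),
            class = "generator_config")
}

#' Generate a synthetic beta-oxidation ladder
#'
#' Same topology as the mFAO instance (carnitine shuttle, overlapping
#' dehydrogenases, MTP branch for C8+, short-chain branch, acetyl-CoA
#' sink, two conserved moieties), with kinetics drawn from the
#' configured distributions. Deterministic per seed.
#'
#' @param config a [generator_config()] (or a seed, as shorthand).
#' @return a validated `kinetic_model`.
#' @export
generate_ladder <- function(config = generator_config()) {
  if (is.numeric(config)) config <- generator_config(seed = config)
  cf <- config
  topo <- mfao_topology(cf$start_chain)
  set.seed(cf$seed)
  runif_log <- function(n, r) exp(stats::runif(n, log(r[1]), log(r[2])))

  base <- mfao_parameters(cf$start_chain)   # supplies structure + ligand names
  enz <- base$enzymes
  for (e in names(enz)) {
    enz[[e]]$Vmax <- runif_log(1, cf$vmax_range)
    enz[[e]]$Km[] <- runif_log(length(enz[[e]]$Km), cf$km_range)
    if (!is.null(enz[[e]]$sf))
      enz[[e]]$sf[] <- stats::runif(length(enz[[e]]$sf), cf$sf_range[1], cf$sf_range[2])
    enz[[e]]$Keq <- if (e == "MSCHAD") unname(cf$keq["mschad"])
      else if (e == "CROT") unname(cf$keq["crot"])
      else if (e == "MTP") unname(cf$keq["mschad"] * cf$keq["crot"] * cf$keq["other"])
      else if (e == "ACS") NA_real_
      else unname(cf$keq["other"])
  }
  # printed constants are fixed, not drawn
  if (!is.null(enz$MCKAT)) {
    if ("C4" %in% names(enz$MCKAT$sf)) enz$MCKAT$sf[["C4"]] <- 0.49
    if ("C6" %in% names(enz$MCKAT$sf)) enz$MCKAT$sf[["C6"]] <- 1
    if ("C4KetoacylCoA" %in% names(enz$MCKAT$Km)) enz$MCKAT$Km[["C4KetoacylCoA"]] <- 12.4
    if ("C6KetoacylCoA" %in% names(enz$MCKAT$Km)) enz$MCKAT$Km[["C6KetoacylCoA"]] <- 6.7
  }
  params <- list(start_chain = cf$start_chain,
                 boundary = base$boundary,
                 totals = c(CoA = cf$coa_total, Carnitine = cf$carnitine_total),
                 enzymes = enz)
  params$boundary[[topo$substrate]] <- cf$substrate
  m <- build_mfao_topology(params)
  m$meta$name <- sprintf("synthetic C%d ladder (seed %d)", cf$start_chain, cf$seed)
  m$meta$seed <- cf$seed
  m
}

#' Generate a short linear reversible Michaelis-Menten chain
#'
#' X0 (fixed) -> S1 -> ... -> Xn (fixed), every step a reversible
#' Michaelis-Menten law. With 2 or 3 enzymes the flux control
#' coefficients follow in closed form from the summation and
#' connectivity theorems given the analytic elasticities, which makes
#' these chains the oracle fixtures for the finite-perturbation MCA.
#'
#' @param n_enzymes 2 or 3.
#' @param params optional list with vectors `Vmax`, `Keq`, `Km_s`,
#'   `Km_p` (one entry per enzyme) and scalars `X0`, `Xn`.
#' @param seed seed used when `params` is `NULL`.
#' @return a `kinetic_model` whose reactions are named `E1..En`.
#' @export
generate_linear_chain <- function(n_enzymes = 2, params = NULL, seed = 1L) {
  if (!n_enzymes %in% c(2L, 3L)) stop("n_enzymes must be 2 or 3", call. = FALSE)
  n <- as.integer(n_enzymes)
  if (is.null(params)) {
    set.seed(seed)
    params <- list(Vmax = exp(stats::runif(n, log(50), log(500))),
                   Keq = exp(stats::runif(n, log(2), log(50))),
                   Km_s = exp(stats::runif(n, log(5), log(50))),
                   Km_p = exp(stats::runif(n, log(5), log(50))),
                   X0 = 100, Xn = 1)
  }
  spn <- c("X0", paste0("S", seq_len(n - 1L)), "Xn")
  sp <- rbind(
    species_row("X0", "other", NA, "mit", fixed = TRUE, value = params$X0),
    if (n >= 2) do.call(rbind, lapply(seq_len(n - 1L), function(i)
      species_row(paste0("S", i), "other", NA, "mit", value = 10))),
    species_row("Xn", "other", NA, "mit", fixed = TRUE, value = params$Xn))
  enzymes <- list(); reactions <- list()
  for (i in seq_len(n)) {
    s <- spn[i]; p <- spn[i + 1L]
    km <- stats::setNames(c(params$Km_s[i], params$Km_p[i]), c(s, p))
    enzymes[[i]] <- enzyme(paste0("E", i), Vmax = params$Vmax[i],
                           Keq = params$Keq[i], Km = km)
    reactions[[i]] <- reaction(paste0("E", i), paste0("E", i), NA,
                               substrates = stats::setNames(1, s),
                               products = stats::setNames(1, p),
                               groups = list(site = c(s, p)))
  }
  kinetic_model(sp, enzymes, reactions, moieties = list(),
                meta = list(name = sprintf("linear %d-enzyme chain", n),
                            uptake_reaction = "E1"))
}
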