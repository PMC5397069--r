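# Active-site occupancy of promiscuous enzymes and per-chain flux
# breakdowns.

#' Active-site occupancy of an enzyme
#'
#' Fraction of the acyl binding site occupied by each ligand at a given
#' state. With the default normalized convention,
#'   Occ_j = ([Xj]/Km_j) / (1 + sum_k [Xk]/Km_k),
#' so the occupancies plus the free-site fraction sum to exactly 1. The
#' `"literal"` convention additionally counts the focal ligand once more
#' in its own denominator (the printed supplementary form, which breaks
#' normalization and is kept only for comparison).
#'
#' @param model a `kinetic_model`.
#' @param state named concentrations (e.g. `steady_state$state`).
#' @param enzyme enzyme name.
#' @param group which binding-site group (default the first, the acyl
#'   site).
#' @param convention `"normalized"` (default) or `"literal"`.
#' @return data.frame of class `occupancy_table`: `ligand`, `occupancy`,
#'   `class`, `chain`; the free-site fraction is attribute `free`.
#' @export
active_site_occupancy <- function(model, state, enzyme, group = 1L,
                                  convention = c("normalized", "literal")) {
  convention <- match.arg(convention)
  cm <- as_compiled(model)
  rxs <- Filter(function(r) identical(r$enzyme, enzyme) && identical(r$law, "structured"),
                cm$rx)
  if (!length(rxs)) stop("unknown or non-structured enzyme: ", enzyme, call. = FALSE)
  x <- full_concentrations(cm, state)
  # ligand set: union of the requested site group across the enzyme's reactions
  idx <- integer(0); km <- numeric(0)
  for (r in rxs) {
    if (length(r$groups) < group) next
    g <- r$groups[[group]]
    new <- !(g$idx %in% idx)
    idx <- c(idx, g$idx[new]); km <- c(km, g$km[new])
  }
  load <- x[idx] / km
  D <- 1 + sum(load)
  occ <- switch(convention,
                normalized = load / D,
                literal = load / (D + load))
  free <- 1 - sum(load / D)
  out <- data.frame(ligand = cm$names[idx], occupancy = unname(occ),
                    class = cm$species$class[idx], chain = cm$species$chain[idx],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$occupancy), ]
  attr(out, "free") <- free
  attr(out, "convention") <- convention
  class(out) <- c("occupancy_table", class(out))
  out
}

#' Grouped occupancy summary
#'
#' Sums occupancies over named ligand groups, e.g. the C4+C6 acyl-CoA
#' esters versus all other acyl-CoA esters versus the ketoacyl-CoA
#' substrates.
#'
#' @param tbl an `occupancy_table`.
#' @param groups named list of ligand name vectors; remaining ligands
#'   are reported under `"other"`.
#' @return named numeric vector of summed occupancies.
#' @export
occupancy_summary <- function(tbl, groups) {
  out <- vapply(groups, function(g) sum(tbl$occupancy[tbl$ligand %in% g]), 0)
  rest <- setdiff(tbl$ligand, unlist(groups))
  c(out, other = sum(tbl$occupancy[tbl$ligand %in% rest]))
}

#' Per-chain flux breakdown at steady state
#'
#' @param model a `kinetic_model`.
#' @param ss a `steady_state`.
#' @return data.frame `reaction`, `enzyme`, `chain`, `flux` (uM/min),
#'   ordered by enzyme and chain; also carries attribute `by_enzyme`
#'   with total throughput per enzyme.
#' @export
flux_breakdown <- function(model, ss) {
  rx <- model$reactions
  out <- data.frame(reaction = names(rx),
                    enzyme = vapply(rx, `[[`, "", "enzyme"),
                    chain = vapply(rx, function(r) as.integer(r$chain), 0L),
                    flux = unname(ss$fluxes[names(rx)]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$enzyme, out$chain), ]
  rownames(out) <- NULL
  attr(out, "by_enzyme") <- tapply(out$flux, out$enzyme, sum)
  out
}

#' Net steady-state balance at each variable species
#'
#' At a converged steady state the inflow/outflow balance of every
#' variable species is zero; this returns the residual per species for
#' diagnostic use.
#'
#' @inheritParams flux_breakdown
#' @return named numeric vector (uM/min).
#' @export
node_balance <- function(model, ss) {
  cm <- as_compiled(model)
  drop(cm$S %*% ss$fluxes[colnames(cm$S)])
}
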