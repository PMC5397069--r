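# Finite-perturbation Metabolic Control Analysis.
#
# Control and response coefficients are estimated from +/-0.0001%
# parameter perturbations, each requiring a steady-state re-solve seeded
# from the reference state (continuation, to avoid branch jumps near the
# flux decline). Following the original acceptance rule, an entry is
# accepted only when the two one-sided estimates agree within 1%.

MCA_REL_STEP <- 1e-6   # the published 0.0001 % perturbation

perturbed_flux <- function(model, ref, param, rel) {
  p0 <- get_parameter(model, param)
  if (!is.finite(p0) || p0 == 0) return(NA_real_)
  mp <- set_parameter(model, param, p0 * (1 + rel))
  ss <- find_steady_state(mp, init = ref$state)
  if (!ss$converged) return(NA_real_)
  ss$J_uptake
}

mca_pair <- function(model, ref, param, rel = MCA_REL_STEP) {
  J0 <- ref$J_uptake
  if (!is.finite(J0) || abs(J0) < 1e-12)
    return(list(value = NA_real_, plus = NA_real_, minus = NA_real_,
                discrepancy = NA_real_, accepted = FALSE, flag = "zero reference flux"))
  Jp <- perturbed_flux(model, ref, param, +rel)
  Jm <- perturbed_flux(model, ref, param, -rel)
  if (!is.finite(Jp) || !is.finite(Jm))
    return(list(value = NA_real_, plus = NA_real_, minus = NA_real_,
                discrepancy = NA_real_, accepted = FALSE, flag = "perturbed solve failed"))
  plus <- (Jp - J0) / (rel * J0)
  minus <- (J0 - Jm) / (rel * J0)
  value <- (Jp - Jm) / (2 * rel * J0)
  disc <- abs(plus - minus) / max(abs(value), 1e-6)
  list(value = value, plus = plus, minus = minus, discrepancy = disc,
       accepted = is.finite(disc) && disc <= 0.01, flag = NA_character_)
}

#' Flux control coefficient of an enzyme
#'
#' C^J = dln J / dln Vmax of the enzyme, estimated by +/-0.0001% Vmax
#' perturbations with steady-state re-solves; both one-sided estimates
#' are reported and the entry is flagged unless they agree within 1%.
#'
#' @param model a `kinetic_model`.
#' @param ref converged reference `steady_state` with nonzero flux.
#' @param enzyme enzyme name.
#' @param rel relative perturbation (default 1e-6).
#' @return list with `value`, `plus`, `minus`, `discrepancy`, `accepted`.
#' @export
flux_control_coefficient <- function(model, ref, enzyme, rel = MCA_REL_STEP) {
  if (!enzyme %in% names(model$enzymes)) stop("unknown enzyme: ", enzyme, call. = FALSE)
  mca_pair(model, ref, paste0("Vmax_", enzyme), rel)
}

#' Chain-length-specific flux control coefficient
#'
#' As [flux_control_coefficient()] with the reaction's specificity
#' factor sf as the perturbed parameter; the chain-specific coefficients
#' of an enzyme sum to its overall coefficient.
#'
#' @inheritParams flux_control_coefficient
#' @param chain chain length of the targeted reaction.
#' @export
chain_specific_fcc <- function(model, ref, enzyme, chain, rel = MCA_REL_STEP) {
  rx <- paste0(enzyme, "_C", chain)
  if (is.null(model$reactions[[rx]])) {
    # single-reaction enzymes carry no chain suffix
    cand <- names(model$reactions)[vapply(model$reactions, function(r)
      identical(r$enzyme, enzyme) && identical(r$chain, as.integer(chain)), TRUE)]
    if (!length(cand)) stop("no reaction for ", enzyme, " chain C", chain, call. = FALSE)
    rx <- cand[[1]]
  }
  mca_pair(model, ref, paste0("sf_", rx), rel)
}

#' Flux response coefficient of an arbitrary parameter
#'
#' R^J = dln J / dln p for any model constant (Vmax, Km, Keq, sf, fixed
#' concentration, moiety total, or the joint NAD+/NADH ratio).
#'
#' @inheritParams flux_control_coefficient
#' @param parameter parameter name (see [model_parameters()]).
#' @export
response_coefficient <- function(model, ref, parameter, rel = MCA_REL_STEP) {
  mca_pair(model, ref, parameter, rel)
}

#' Table of control/response coefficients
#'
#' @inheritParams flux_control_coefficient
#' @param enzymes enzymes for overall FCCs (default: all).
#' @param chains logical: add chain-specific FCCs.
#' @param parameters extra parameters for response coefficients.
#' @return data.frame of class `control_table` with columns `entity`,
#'   `type`, `value`, `plus`, `minus`, `discrepancy`, `accepted`.
#' @export
control_table <- function(model, ref, enzymes = names(model$enzymes),
                          chains = FALSE, parameters = character(0),
                          rel = MCA_REL_STEP) {
  rows <- list()
  push <- function(entity, type, est) rows[[length(rows) + 1L]] <<- data.frame(
    entity = entity, type = type, value = est$value, plus = est$plus,
    minus = est$minus, discrepancy = est$discrepancy, accepted = est$accepted,
    stringsAsFactors = FALSE)
  for (e in enzymes)
    push(e, "FCC", flux_control_coefficient(model, ref, e, rel))
  if (chains) for (r in model$reactions) {
    if (!r$enzyme %in% enzymes || is.na(r$chain) || !identical(r$law, "structured")) next
    n_rx <- sum(vapply(model$reactions, function(q) identical(q$enzyme, r$enzyme), TRUE))
    if (n_rx < 2) next
    push(r$name, "FCC-chain", mca_pair(model, ref, paste0("sf_", r$name), rel))
  }
  for (p in parameters)
    push(p, "RC", response_coefficient(model, ref, p, rel))
  out <- do.call(rbind, rows)
  class(out) <- c("control_table", class(out))
  out
}

#' Rank parameters by absolute response coefficient
#'
#' @param tbl a `control_table` with RC rows.
#' @param n how many to keep (default 15).
#' @return the top rows, ordered by `|value|` descending, ties broken
#'   lexicographically by parameter name.
#' @export
top_responses <- function(tbl, n = 15) {
  rc <- tbl[tbl$type == "RC" & is.finite(tbl$value), , drop = FALSE]
  rc <- rc[order(-abs(rc$value), rc$entity), , drop = FALSE]
  utils::head(rc, n)
}

# -- elasticities ------------------------------------------------------------

#' Elasticity of one reaction rate
#'
#' Log-log sensitivity of the isolated rate law to one metabolite or
#' parameter at clamped concentrations. `method = "fd"` uses a central
#' finite difference with relative step 1e-6; `method = "analytic"`
#' differentiates the structured promiscuous law in closed form and is
#' available for metabolite ligands of structured reactions.
#'
#' @param model a `kinetic_model`.
#' @param state named concentrations at which to evaluate.
#' @param reaction reaction name.
#' @param variable species or parameter name (also `"ratio_NAD_NADH"`).
#' @param method `"fd"` or `"analytic"`.
#' @param rel finite-difference relative step.
#' @return elasticity (dimensionless).
#' @export
elasticity <- function(model, state, reaction, variable,
                       method = c("fd", "analytic"), rel = 1e-6) {
  method <- match.arg(method)
  cm <- as_compiled(model)
  j <- match(reaction, names(cm$model$reactions))
  if (is.na(j)) stop("unknown reaction: ", reaction, call. = FALSE)
  x <- full_concentrations(cm, state)
  v0 <- eval_rate(cm, cm$rx[[j]], x)
  if (!is.finite(v0) || v0 == 0)
    stop("rate of ", reaction, " is zero at this state; elasticity undefined", call. = FALSE)

  if (method == "analytic") {
    if (!variable %in% cm$names)
      stop("analytic elasticities are available for metabolite ligands only", call. = FALSE)
    return(analytic_elasticity(cm, cm$rx[[j]], x, variable))
  }

  if (variable %in% cm$names) {
    f <- function(h) {
      xx <- x; xx[variable] <- x[[variable]] * (1 + h)
      eval_rate(cm, cm$rx[[j]], xx)
    }
    if (x[[variable]] == 0) return(0)
  } else if (identical(variable, "ratio_NAD_NADH")) {
    r0 <- x[["NAD"]] / x[["NADH"]]
    tot <- x[["NAD"]] + x[["NADH"]]
    f <- function(h) {
      r <- r0 * (1 + h)
      xx <- x; xx[["NAD"]] <- tot * r / (1 + r); xx[["NADH"]] <- tot / (1 + r)
      eval_rate(cm, cm$rx[[j]], xx)
    }
  } else {
    p0 <- get_parameter(model, variable)
    f <- function(h) {
      mm <- set_parameter(model, variable, p0 * (1 + h))
      cmh <- compile_model(mm)
      xh <- x[cmh$names]
      eval_rate(cmh, cmh$rx[[j]], xh)
    }
  }
  vp <- f(rel); vm <- f(-rel)
  (vp - vm) / (2 * rel * v0)
}

analytic_elasticity <- function(cm, r, x, variable) {
  if (!identical(r$law, "structured"))
    stop("analytic elasticities need a structured rate law", call. = FALSE)
  i <- match(variable, cm$names)
  fwd <- prod((x[r$sub_idx] / r$sub_km)^r$sub_st)
  rev <- if (r$reversible) prod(x[r$prod_idx]^r$prod_st) / r$rev_const else 0
  num <- fwd - rev
  e <- 0
  ks <- which(r$sub_idx == i)
  if (length(ks)) e <- e + sum(r$sub_st[ks]) * fwd / num
  kp <- which(r$prod_idx == i)
  if (length(kp) && r$reversible) e <- e - sum(r$prod_st[kp]) * rev / num
  for (g in r$groups) {
    kg <- which(g$idx == i)
    if (length(kg)) {
      D <- 1 + sum(x[g$idx] / g$km)
      e <- e - sum(x[[i]] / g$km[kg]) / D
    }
  }
  e
}

#' Dissect a response coefficient into reaction terms
#'
#' Combined-response decomposition: R^J_p = sum_i C_i^J * eps_i,p, where
#' C_i^J is the control coefficient of reaction i (sf perturbation) and
#' eps_i,p the elasticity of its isolated rate to p. The sum of terms is
#' checked against the directly computed response coefficient (1%
#' connectivity tolerance).
#'
#' @inheritParams response_coefficient
#' @return data.frame with one row per reaction with nonzero elasticity
#'   plus attributes `direct` (the directly computed R) and `closure_ok`.
#' @export
dissect_response <- function(model, ref, parameter, rel = MCA_REL_STEP) {
  direct <- response_coefficient(model, ref, parameter, rel)
  rows <- list()
  for (r in model$reactions) {
    if (!identical(r$law, "structured")) next
    eps <- tryCatch(
      elasticity(model, ref$state, r$name, parameter),
      error = function(e) 0)
    if (!is.finite(eps) || abs(eps) < 1e-12) next
    ci <- mca_pair(model, ref, paste0("sf_", r$name), rel)
    rows[[length(rows) + 1L]] <- data.frame(
      reaction = r$name, enzyme = r$enzyme, chain = r$chain,
      C = ci$value, elasticity = eps, term = ci$value * eps,
      accepted = ci$accepted, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  tot <- sum(out$term)
  attr(out, "direct") <- direct$value
  attr(out, "sum_terms") <- tot
  attr(out, "closure_ok") <- is.finite(direct$value) &&
    abs(tot - direct$value) <= 0.01 * max(abs(direct$value), 1e-6)
  out
}
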