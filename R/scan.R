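# Steady-state parameter scans with continuation (each grid point seeded
# from the previous solution) and the Fig-2-style flux readouts.

#' Steady-state scan over a model parameter
#'
#' Solves the steady state at every grid value in ascending order,
#' seeding each solve from the previous solution. If an interior flux
#' maximum is detected, a descending re-scan is run over the decline
#' region and rows where the two directions disagree by more than
#' `hysteresis_tol` (possible multistability) are flagged, not averaged.
#'
#' @param model a `kinetic_model`.
#' @param parameter parameter name (see [model_parameters()]); defaults
#'   to the model's substrate concentration.
#' @param grid numeric vector of parameter values.
#' @param init optional named state seeding the first grid point.
#' @param rescan logical: run the descending consistency re-scan.
#' @return data.frame of class `mfao_scan`: one row per grid value with
#'   `param_value`, `J_uptake`, `J_NADH`, `freeCoA`, `sum_esters`,
#'   `sum_C4C6_esters`, `converged`, `hysteresis`, plus one `flux.<rxn>`
#'   column per reaction.
#' @export
scan_steady_states <- function(model, parameter = NULL, grid, init = NULL,
                               rescan = TRUE, hysteresis_tol = 1e-6) {
  if (is.null(parameter)) parameter <- model$meta$substrate_param
  if (is.null(parameter)) stop("no parameter given and model declares no substrate", call. = FALSE)
  ord <- order(grid)
  grid <- grid[ord]
  states <- vector("list", length(grid))
  rows <- vector("list", length(grid))
  cur <- init
  for (i in seq_along(grid)) {
    mi <- set_parameter(model, parameter, grid[i])
    ss <- find_steady_state(mi, init = cur)
    if (ss$converged) cur <- ss$state
    states[[i]] <- ss
    rows[[i]] <- scan_row(mi, ss, grid[i])
  }
  out <- do.call(rbind, rows)
  out$hysteresis <- FALSE

  if (rescan && nrow(out) >= 3) {
    jj <- out$J_uptake
    pk <- which.max(jj)
    if (pk > 1 && pk < length(jj) && all(is.finite(jj))) {
      cur <- states[[length(grid)]]$state
      for (i in rev(seq(from = max(pk - 1, 1), to = length(grid)))) {
        mi <- set_parameter(model, parameter, grid[i])
        ss <- find_steady_state(mi, init = cur)
        if (ss$converged) cur <- ss$state
        dJ <- abs(ss$J_uptake - out$J_uptake[i])
        if (is.finite(dJ) && dJ > hysteresis_tol * max(abs(out$J_uptake[i]), 1))
          out$hysteresis[i] <- TRUE
      }
    }
  }
  attr(out, "parameter") <- parameter
  attr(out, "states") <- lapply(states, `[[`, "state")
  class(out) <- c("mfao_scan", class(out))
  out
}

scan_row <- function(model, ss, value) {
  s <- ss$state
  sp <- model$species
  ester <- !sp$fixed & sp$class %in% c("acyl-CoA", "enoyl-CoA", "hydroxyacyl-CoA",
                                       "ketoacyl-CoA") & sp$compartment == "mit"
  ester46 <- ester & !is.na(sp$chain) & sp$chain %in% c(4, 6)
  d <- data.frame(param_value = value,
                  J_uptake = ss$J_uptake, J_NADH = ss$J_NADH,
                  freeCoA = if ("CoAMAT" %in% names(s)) unname(s[["CoAMAT"]]) else NA_real_,
                  sum_esters = sum(s[sp$name[ester]]),
                  sum_C4C6_esters = sum(s[sp$name[ester46]]),
                  converged = ss$converged,
                  residual = ss$residual)
  fx <- as.data.frame(as.list(ss$fluxes))
  names(fx) <- paste0("flux.", names(ss$fluxes))
  cbind(d, fx)
}

#' Locate the flux maximum of a scan
#'
#' Returns the interior maximum of `J_uptake`, refined (when the model
#' and parameter are supplied) by golden-section steady-state re-solves
#' in the bracket around the best grid point. A scan that is monotone up
#' to its last converged point has no interior peak.
#'
#' @param scan result of [scan_steady_states()].
#' @param model,parameter optional; enable sub-grid refinement.
#' @param tol relative bracket tolerance for the refinement.
#' @return list with `interior` (logical), `param` (peak location),
#'   `J` (peak flux); `param` is `NA` when no interior peak exists.
#' @export
find_flux_peak <- function(scan, model = NULL, parameter = NULL, tol = 1e-3) {
  ok <- scan$converged
  if (sum(ok) < 3) stop("need at least 3 converged scan rows", call. = FALSE)
  g <- scan$param_value[ok]; j <- scan$J_uptake[ok]
  k <- which.max(j)
  if (k == 1 || k == length(j))
    return(list(interior = FALSE, param = NA_real_, J = max(j),
                reason = "no interior peak in range"))
  lo <- g[k - 1]; hi <- g[k + 1]
  if (!is.null(model)) {
    if (is.null(parameter)) parameter <- attr(scan, "parameter")
    seed <- attr(scan, "states")[[which(ok)[k]]]
    f <- function(p) {
      ss <- find_steady_state(set_parameter(model, parameter, p), init = seed)
      if (!ss$converged) return(-Inf)
      ss$J_uptake
    }
    opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = tol * (hi - lo))
    return(list(interior = TRUE, param = opt$maximum, J = opt$objective))
  }
  # vertex of the parabola through the three best grid points
  xs <- g[(k - 1):(k + 1)]; ys <- j[(k - 1):(k + 1)]
  num <- (xs[2] - xs[1])^2 * (ys[2] - ys[3]) - (xs[2] - xs[3])^2 * (ys[2] - ys[1])
  den <- (xs[2] - xs[1]) * (ys[2] - ys[3]) - (xs[2] - xs[3]) * (ys[2] - ys[1])
  xv <- if (abs(den) > 0) xs[2] - 0.5 * num / den else xs[2]
  if (!is.finite(xv) || xv <= lo || xv >= hi) xv <- xs[2]
  list(interior = TRUE, param = xv, J = max(ys))
}

#' Default Fig-2-style substrate grid
#'
#' 100 log-spaced points over 0.1-100 uM of the cytosolic substrate.
#' @param from,to,n grid limits (uM) and size.
#' @return numeric vector.
#' @export
substrate_grid <- function(from = 0.1, to = 100, n = 100) {
  exp(seq(log(from), log(to), length.out = n))
}
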