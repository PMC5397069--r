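# Shared fixtures and independent oracles. Expensive objects are built
# lazily and memoised for the whole run.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

fix_mfao <- function(substrate = 0.1) {
  memo(paste0("mfao_", substrate), mfao_model(16, substrate))
}

fix_mfao_ss <- function(substrate) {
  memo(paste0("mfao_ss_", substrate),
       find_steady_state(fix_mfao(substrate)))
}

fix_ladder42 <- function() memo("ladder42", generate_ladder(generator_config(seed = 42)))
fix_ladder42_ss <- function() memo("ladder42_ss", find_steady_state(fix_ladder42()))

fix_chain <- function(n, seed = 11) memo(paste0("chain", n, "_", seed),
                                         generate_linear_chain(n, seed = seed))

# -- reversible Michaelis-Menten oracle --------------------------------------
# v = V (S/Ks - P/(Ks*Keq)) / (1 + S/Ks + P/Kp); hand-derived log-log
# elasticities, independent of the package's rate-law code path.

rmm_rate <- function(V, Ks, Kp, Keq, S, P) {
  V * (S / Ks - P / (Ks * Keq)) / (1 + S / Ks + P / Kp)
}

rmm_elasticity <- function(V, Ks, Kp, Keq, S, P, wrt = c("S", "P")) {
  wrt <- match.arg(wrt)
  num <- S / Ks - P / (Ks * Keq)
  den <- 1 + S / Ks + P / Kp
  if (wrt == "S") (S / Ks) / num - (S / Ks) / den
  else (-P / (Ks * Keq)) / num - (P / Kp) / den
}

# Closed-form flux control coefficients of an n-enzyme linear chain from
# the summation and connectivity theorems: C solves
#   [1 1 ... 1; E^T] C = [1; 0] with E[i, j] = elasticity of v_i to S_j.
chain_fcc_oracle <- function(model, ss) {
  n <- length(model$reactions)
  mets <- paste0("S", seq_len(n - 1L))
  E <- matrix(0, n, n - 1L)
  for (i in seq_len(n)) {
    en <- model$enzymes[[i]]
    r <- model$reactions[[i]]
    s <- names(r$substrates); p <- names(r$products)
    for (j in seq_len(n - 1L)) {
      Sj <- mets[j]
      if (Sj %in% c(s, p)) {
        conc_s <- ss$state[s]
        conc_s <- if (s %in% names(ss$state)) ss$state[[s]] else
          model$species$value[match(s, model$species$name)]
        conc_p <- if (p %in% names(ss$state)) ss$state[[p]] else
          model$species$value[match(p, model$species$name)]
        E[i, j] <- rmm_elasticity(en$Vmax, en$Km[[s]], en$Km[[p]], en$Keq,
                                  conc_s, conc_p,
                                  wrt = if (Sj == s) "S" else "P")
      }
    }
  }
  A <- rbind(rep(1, n), t(E))
  b <- c(1, rep(0, n - 1L))
  stats::setNames(solve(A, b), names(model$reactions))
}
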