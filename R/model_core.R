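#' @keywords internal
"_PACKAGE"

# -- species table -----------------------------------------------------------

#' Build a species table row
#'
#' Species are identified by name; variable species carry an initial
#' concentration, fixed (boundary) species a clamped concentration. All
#' concentrations are in uM.
#'
#' @param name character species identifier.
#' @param class one of `"acyl-CoA"`, `"enoyl-CoA"`, `"hydroxyacyl-CoA"`,
#'   `"ketoacyl-CoA"`, `"acetyl-CoA"`, `"acyl-carnitine"`, `"carnitine"`,
#'   `"coa"`, `"cofactor"`, `"other"`.
#' @param chain even carbon-chain length (4..16) or `NA` for non-esters.
#' @param compartment `"cyt"` or `"mit"`.
#' @param fixed logical; `TRUE` for clamped boundary pools.
#' @param value concentration in uM (initial value if variable).
#' @return one-row `data.frame`.
#' @export
species_row <- function(name, class = "other", chain = NA_integer_,
                        compartment = "mit", fixed = FALSE, value = 0) {
  data.frame(name = name, class = class, chain = as.integer(chain),
             compartment = compartment, fixed = fixed, value = as.numeric(value),
             stringsAsFactors = FALSE)
}

# -- reactions ---------------------------------------------------------------

#' Define a reaction with a promiscuous reversible rate law
#'
#' The structured rate law is
#' \deqn{v = sf \cdot \alpha \cdot V_{max} \cdot
#'   \frac{\prod_s ([S]/K_{m,S})^{\sigma_s} -
#'         \prod_p [P]^{\sigma_p} / (\prod_s K_{m,S}^{\sigma_s} K_{eq})}
#'        {\prod_g \left(1 + \sum_{x \in g} [X]/K_{m,x}\right)}}
#' where the denominator runs over independent binding-site groups. The
#' first group conventionally holds the CoA-ester ligands, including the
#' substrates and products of all competing chain lengths of the same
#' enzyme, so that their affinity constants double as competitive
#' inhibition constants. Km values are looked up in the enzyme's Km map,
#' so one Km parameter is shared by the numerator and by every
#' denominator occurrence of a ligand across the enzyme's reactions.
#'
#' @param name reaction identifier, e.g. `"MCKAT_C4"`.
#' @param enzyme enzyme name (key into the model's enzyme list).
#' @param chain chain length acted on, or `NA`.
#' @param substrates named numeric vector of substrate stoichiometries.
#' @param products named numeric vector of product stoichiometries.
#' @param groups named list of character vectors: ligands per binding-site
#'   group (e.g. `list(acyl = ..., cofactor = ...)`). Ligands absent from
#'   substrates/products act as pure competitive inhibitors.
#' @param sf chain-length specificity factor in (0, 1].
#' @param alpha promiscuity-removal partition factor (1 in intact models).
#' @param reversible logical; irreversible laws drop the numerator's
#'   reverse term and need no Keq.
#' @return a `list` describing the reaction.
#' @export
reaction <- function(name, enzyme, chain = NA_integer_, substrates, products,
                     groups, sf = 1, alpha = 1, reversible = TRUE) {
  stopifnot(is.numeric(substrates), length(names(substrates)) == length(substrates))
  if (length(products)) stopifnot(!is.null(names(products)))
  list(name = name, enzyme = enzyme, chain = as.integer(chain),
       substrates = substrates, products = products, groups = groups,
       sf = sf, alpha = alpha, reversible = reversible, law = "structured")
}

#' Define an enzyme parameter block
#'
#' @param name enzyme name.
#' @param Vmax maximal rate in uM/min shared by all the enzyme's reactions.
#' @param Keq equilibrium constant (dimensionless); `NA` for irreversible.
#' @param Km named numeric vector of Michaelis constants (uM) per ligand.
#' @return a `list`.
#' @export
enzyme <- function(name, Vmax, Keq = NA_real_, Km) {
  list(name = name, Vmax = Vmax, Keq = Keq, Km = Km)
}

#' Assemble a kinetic model
#'
#' @param species species table (`rbind` of [species_row()] rows).
#' @param enzymes named list of [enzyme()] blocks.
#' @param reactions list of [reaction()] definitions.
#' @param moieties list of conserved moieties, each
#'   `list(name=, species=, total=, eliminate=)`; `eliminate` names the
#'   species removed algebraically during steady-state solving.
#' @param meta free-form metadata (provenance, readout reaction names).
#' @return object of class `kinetic_model`.
#' @export
kinetic_model <- function(species, enzymes, reactions, moieties = list(),
                          meta = list()) {
  names(enzymes) <- vapply(enzymes, `[[`, "", "name")
  names(reactions) <- vapply(reactions, `[[`, "", "name")
  m <- structure(list(species = species, enzymes = enzymes,
                      reactions = reactions, moieties = moieties, meta = meta),
                 class = "kinetic_model")
  m
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat(sprintf("<kinetic_model> %d species (%d variable), %d reactions, %d enzymes, %d moieties\n",
              nrow(x$species), sum(!x$species$fixed), length(x$reactions),
              length(x$enzymes), length(x$moieties)))
  if (!is.null(x$meta$name)) cat("  name:", x$meta$name, "\n")
  if (!is.null(x$meta$surgery)) cat("  promiscuity removed:", paste(x$meta$surgery, collapse = ", "), "\n")
  invisible(x)
}

# -- compilation -------------------------------------------------------------

#' Compile a model into an index-based evaluator
#'
#' Precomputes integer indices into the full concentration vector
#' (variables first, then clamped pools) so that rate and right-hand-side
#' evaluation are cheap inside integrator and solver loops.
#'
#' @param model a `kinetic_model`.
#' @return object of class `compiled_model`.
#' @export
compile_model <- function(model) {
  sp <- model$species
  ord <- order(sp$fixed)            # variables first, stable
  sp <- sp[ord, , drop = FALSE]
  nm <- sp$name
  n_var <- sum(!sp$fixed)
  var_names <- nm[seq_len(n_var)]
  fixed_values <- sp$value[sp$fixed]

  idx <- function(x) {
    i <- match(x, nm)
    if (anyNA(i)) stop("unknown ligand(s): ", paste(x[is.na(i)], collapse = ", "),
                       call. = FALSE)
    i
  }

  rx <- lapply(model$reactions, function(r) {
    if (identical(r$law, "expr")) {
      return(list(name = r$name, law = "expr", expr = r$expr,
                  enzyme = r$enzyme))
    }
    en <- model$enzymes[[r$enzyme]]
    if (is.null(en)) stop("reaction ", r$name, ": unknown enzyme ", r$enzyme, call. = FALSE)
    km_of <- function(lig) {
      k <- en$Km[lig]
      if (anyNA(k)) stop("enzyme ", en$name, ": missing Km for ",
                         paste(lig[is.na(k)], collapse = ", "), call. = FALSE)
      if (any(k <= 0)) stop("enzyme ", en$name, ": non-positive Km for ",
                            paste(lig[k <= 0], collapse = ", "), call. = FALSE)
      unname(k)
    }
    subs <- r$substrates
    prods <- r$products
    groups <- lapply(r$groups, function(g) list(idx = idx(g), km = km_of(g)))
    list(name = r$name, law = "structured", enzyme = r$enzyme,
         V = r$sf * r$alpha * en$Vmax,
         sub_idx = idx(names(subs)), sub_st = unname(subs), sub_km = km_of(names(subs)),
         prod_idx = if (length(prods)) idx(names(prods)) else integer(0),
         prod_st = unname(prods),
         rev_const = if (r$reversible) prod(km_of(names(subs))^unname(subs)) * en$Keq else NA_real_,
         reversible = r$reversible,
         groups = groups)
  })

  # stoichiometry over variable species
  S <- matrix(0, n_var, length(model$reactions),
              dimnames = list(var_names, names(model$reactions)))
  for (j in seq_along(model$reactions)) {
    r <- model$reactions[[j]]
    for (s in names(r$substrates)) {
      i <- match(s, var_names)
      if (!is.na(i)) S[i, j] <- S[i, j] - r$substrates[[s]]
    }
    for (p in names(r$products)) {
      i <- match(p, var_names)
      if (!is.na(i)) S[i, j] <- S[i, j] + r$products[[p]]
    }
  }

  env_expr <- NULL
  if (any(vapply(rx, function(r) identical(r$law, "expr"), TRUE))) {
    env_expr <- new.env(parent = baseenv())
    for (p in names(model$meta$parameters)) assign(p, model$meta$parameters[[p]], envir = env_expr)
  }

  structure(list(model = model, species = sp, names = nm, n_var = n_var,
                 var_names = var_names, fixed_values = fixed_values,
                 rx = rx, S = S, env_expr = env_expr,
                 init = sp$value[seq_len(n_var)]),
            class = "compiled_model")
}

#' Evaluate all reaction rates
#'
#' @param cm a `compiled_model`.
#' @param state named (or ordered) numeric vector of variable
#'   concentrations (uM). Negative round-off values are clipped to zero
#'   before evaluation.
#' @return named numeric vector of rates (uM/min).
#' @export
reaction_rates <- function(cm, state) {
  x <- full_concentrations(cm, state)
  v <- numeric(length(cm$rx))
  for (j in seq_along(cm$rx)) v[j] <- eval_rate(cm, cm$rx[[j]], x)
  names(v) <- names(cm$model$reactions)
  v
}

full_concentrations <- function(cm, state) {
  if (!is.null(names(state))) state <- state[cm$var_names]
  x <- c(as.numeric(state), cm$fixed_values)
  if (anyNA(x)) stop("state does not cover all variable species", call. = FALSE)
  bad <- x < 0
  if (any(bad)) {
    floorv <- getOption("mfao.negative_floor", 1e-12)
    if (any(x < -floorv) && isTRUE(getOption("mfao.warn_clip", FALSE)))
      warning("negative concentration(s) clipped to 0", call. = FALSE)
    x[bad] <- 0
  }
  names(x) <- cm$names
  x
}

eval_rate <- function(cm, r, x) {
  if (identical(r$law, "expr")) {
    e <- cm$env_expr
    for (i in seq_along(x)) assign(cm$names[[i]], x[[i]], envir = e)
    return(eval(r$expr, e))
  }
  fwd <- prod((x[r$sub_idx] / r$sub_km)^r$sub_st)
  num <- if (r$reversible)
    fwd - prod(x[r$prod_idx]^r$prod_st) / r$rev_const
  else fwd
  den <- 1
  for (g in r$groups) den <- den * (1 + sum(x[g$idx] / g$km))
  r$V * num / den
}

#' Rate of one reaction under the generalized promiscuous law
#'
#' Evaluates a single reaction's rate law at clamped concentrations; the
#' workhorse behind [reaction_rates()], exposed for rate-law level tests
#' and elasticity calculations.
#'
#' @param model `kinetic_model` or `compiled_model`.
#' @param reaction reaction name.
#' @param concentrations named vector overriding any subset of species
#'   concentrations; unspecified species take model initial/clamped values.
#' @return rate in uM/min.
#' @export
promiscuous_rate <- function(model, reaction, concentrations = NULL) {
  cm <- as_compiled(model)
  state <- cm$init
  names(state) <- cm$var_names
  x <- c(state, cm$fixed_values)
  names(x) <- cm$names
  if (!is.null(concentrations)) {
    unknown <- setdiff(names(concentrations), cm$names)
    if (length(unknown)) stop("unknown ligand(s): ", paste(unknown, collapse = ", "),
                              call. = FALSE)
    x[names(concentrations)] <- concentrations
  }
  j <- match(reaction, names(cm$model$reactions))
  if (is.na(j)) stop("unknown reaction: ", reaction, call. = FALSE)
  eval_rate(cm, cm$rx[[j]], x)
}

as_compiled <- function(model) {
  if (inherits(model, "compiled_model")) model else compile_model(model)
}

#' ODE right-hand side
#'
#' Time-derivatives of all variable species: stoichiometry matrix times
#' the rate vector. Conserved-moiety directions have zero derivative
#' analytically.
#'
#' @inheritParams reaction_rates
#' @return named numeric vector d\[X\]/dt (uM/min).
#' @export
model_rhs <- function(cm, state) {
  cm <- as_compiled(cm)
  v <- reaction_rates(cm, state)
  drop(cm$S %*% v)
}

# -- validation --------------------------------------------------------------

#' Validate a kinetic model
#'
#' Report-only check of the structural invariants: even chain lengths in
#' 4..16, sf in (0,1], positive Vmax/Km/Keq, non-negative concentrations,
#' every declared conserved moiety in the left null space of the
#' stoichiometry matrix, rates finite at a strictly positive state.
#'
#' @param model a `kinetic_model`.
#' @return data.frame with columns `where` and `problem`; zero rows if the
#'   model is valid.
#' @export
validate_model <- function(model) {
  bad <- list()
  note <- function(where, problem) bad[[length(bad) + 1L]] <<- data.frame(
    where = where, problem = problem, stringsAsFactors = FALSE)

  sp <- model$species
  if (anyDuplicated(sp$name)) note("species", "duplicate species names")
  ch <- sp$chain[!is.na(sp$chain)]
  if (any(ch %% 2 != 0 | ch < 4 | ch > 16))
    note("species", "chain lengths must be even and in [4, 16]")
  if (any(sp$value < 0)) note("species", "negative concentration(s)")

  for (en in model$enzymes) {
    if (!is.numeric(en$Vmax) || en$Vmax <= 0) note(en$name, "Vmax must be > 0")
    if (any(en$Km <= 0)) {
      who <- names(en$Km)[en$Km <= 0]
      note(en$name, paste0("non-positive Km: ", paste(who, collapse = ", ")))
    }
    if (!is.na(en$Keq) && en$Keq <= 0) note(en$name, "Keq must be > 0")
  }
  for (r in model$reactions) {
    if (identical(r$law, "expr")) next
    if (is.null(model$enzymes[[r$enzyme]])) note(r$name, "unknown enzyme")
    if (!is.na(r$sf) && (r$sf <= 0 || r$sf > 1)) note(r$name, "sf must be in (0, 1]")
    lig <- unlist(r$groups, use.names = FALSE)
    nn <- c(names(r$substrates), if (isTRUE(r$reversible)) names(r$products))
    infreq <- vapply(nn, function(s) sum(lig == s), 0L)
    if (any(infreq != 1L))
      note(r$name, "each numerator ligand must appear in exactly one site group")
  }

  cm <- try(compile_model(model), silent = TRUE)
  if (inherits(cm, "try-error")) {
    note("model", paste("compilation failed:", attr(cm, "condition")$message))
  } else {
    for (mo in model$moieties) {
      w <- match(mo$species, cm$var_names)
      if (anyNA(w)) { note(mo$name, "moiety references unknown/fixed species"); next }
      res <- colSums(cm$S[w, , drop = FALSE])
      if (any(abs(res) > 1e-9)) {
        off <- names(model$reactions)[abs(res) > 1e-9]
        note(mo$name, paste0("moiety not conserved by reaction(s): ",
                             paste(off, collapse = ", ")))
      }
      if (!mo$eliminate %in% mo$species)
        note(mo$name, "eliminated species not a member of the moiety")
    }
    st <- pmax(cm$init, 1)
    v <- try(reaction_rates(cm, st), silent = TRUE)
    if (inherits(v, "try-error") || any(!is.finite(v)))
      note("model", "rates not finite at a strictly positive state")
  }
  if (length(bad)) do.call(rbind, bad) else
    data.frame(where = character(0), problem = character(0))
}

# -- moiety discovery --------------------------------------------------------

#' Conserved moieties from the stoichiometric left null space
#'
#' Row-reduces the transposed stoichiometry matrix to find a basis of the
#' left null space restricted to variable species. Entries are rounded to
#' integers when within 1e-9, which recovers the usual 0/1 moiety vectors
#' of CoA- and carnitine-type conservation.
#'
#' @param model `kinetic_model` or `compiled_model`.
#' @return list of named numeric weight vectors.
#' @export
find_conserved_moieties <- function(model) {
  cm <- as_compiled(model)
  S <- cm$S
  ns <- nullspace_left(S)
  lapply(seq_len(ncol(ns)), function(k) {
    w <- ns[, k]
    names(w) <- cm$var_names
    w[abs(w) < 1e-9] <- 0
    r <- round(w)
    if (max(abs(w - r)) < 1e-9) w <- r
    w
  })
}

# basis of {y : t(S) %*% y = 0} via Gaussian elimination on t(S)
nullspace_left <- function(S) {
  A <- t(S)
  m <- nrow(A); n <- ncol(A)
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(n)) {
    if (row > m) break
    p <- which.max(abs(A[row:m, col])) + row - 1L
    if (abs(A[p, col]) < 1e-10) next
    if (p != row) A[c(p, row), ] <- A[c(row, p), ]
    A[row, ] <- A[row, ] / A[row, col]
    others <- setdiff(seq_len(m), row)
    A[others, ] <- A[others, ] - outer(A[others, col], A[row, ])
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  free <- setdiff(seq_len(n), pivots)
  if (!length(free)) return(matrix(0, n, 0))
  B <- matrix(0, n, length(free))
  for (k in seq_along(free)) {
    fc <- free[k]
    B[fc, k] <- 1
    for (r in seq_along(pivots)) B[pivots[r], k] <- -A[r, fc]
  }
  B
}
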