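# In-silico removal of enzyme promiscuity. For every treated reaction
# the cross-chain competitive inhibition terms are deleted from the
# denominator (the reaction's own substrates and products stay), and the
# enzyme pool is partitioned evenly over its reactions with the factor
# alpha = 1 / (number of reactions the enzyme catalyses).

#' Remove promiscuity from selected enzymes
#'
#' @param model a `kinetic_model`.
#' @param enzymes character vector of enzyme names, or `"all"`.
#' @return variant `kinetic_model` tagged with the treated enzymes in
#'   `meta$surgery`. Idempotent: treating twice equals treating once.
#' @export
remove_promiscuity <- function(model, enzymes = "all") {
  all_enz <- names(model$enzymes)
  if (identical(enzymes, "all")) enzymes <- all_enz
  unknown <- setdiff(enzymes, all_enz)
  if (length(unknown)) stop("unknown enzyme(s): ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  counts <- table(vapply(model$reactions, `[[`, "", "enzyme"))
  for (i in seq_along(model$reactions)) {
    r <- model$reactions[[i]]
    if (!r$enzyme %in% enzymes || !identical(r$law, "structured")) next
    own <- c(names(r$substrates), names(r$products))
    r$groups <- lapply(r$groups, function(g) g[g %in% own])
    r$groups <- r$groups[vapply(r$groups, length, 0L) > 0]
    r$alpha <- 1 / as.numeric(counts[[r$enzyme]])
    model$reactions[[i]] <- r
  }
  model$meta$surgery <- sort(union(model$meta$surgery, enzymes))
  model
}

#' Remove promiscuity from all enzymes except some
#'
#' @param model a `kinetic_model`.
#' @param keep enzymes whose promiscuity is retained.
#' @return variant `kinetic_model`.
#' @export
remove_promiscuity_except <- function(model, keep) {
  remove_promiscuity(model, setdiff(names(model$enzymes), keep))
}

#' Scan suite over promiscuity variants
#'
#' Steady-state substrate scans for the published comparison set: the
#' full model, the model without any promiscuity, each enzyme
#' individually depromiscuized, and the model where only MCKAT (or
#' `only`) keeps its promiscuity.
#'
#' @param model a `kinetic_model`.
#' @param grid substrate grid (uM).
#' @param parameter scanned parameter (default: substrate concentration).
#' @param only the enzyme for the "only promiscuous" variant.
#' @param per_enzyme logical: include the each-enzyme-depromiscuized set.
#' @return named list of `mfao_scan` tables (`full`, `none`,
#'   `only_<only>`, and `no_<enzyme>` entries), each carrying its
#'   `find_flux_peak()` result as attribute `peak`.
#' @export
variant_scan_suite <- function(model, grid, parameter = NULL, only = "MCKAT",
                               per_enzyme = FALSE) {
  variants <- list(full = model,
                   none = remove_promiscuity(model, "all"))
  variants[[paste0("only_", only)]] <- remove_promiscuity_except(model, only)
  promiscuous <- names(which(table(vapply(model$reactions, `[[`, "", "enzyme")) > 1))
  if (per_enzyme) {
    for (e in promiscuous) variants[[paste0("no_", e)]] <- remove_promiscuity(model, e)
  } else {
    variants[[paste0("no_", only)]] <- remove_promiscuity(model, only)
  }
  lapply(variants, function(mv) {
    sc <- scan_steady_states(mv, parameter, grid)
    attr(sc, "peak") <- find_flux_peak(sc)
    sc
  })
}
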