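# Uniform access to perturbable model constants. Names follow the scheme
#   Vmax_<enzyme>, Keq_<enzyme>, Km_<enzyme>_<ligand>, sf_<reaction>,
#   conc_<fixed species>, moiety_<moiety name>, ratio_NAD_NADH
# The NAD+/NADH ratio is treated as a single parameter: both pools are
# adjusted jointly with NAD+ + NADH held fixed.

#' Enumerate perturbable parameters of a model
#'
#' @param model a `kinetic_model`.
#' @return character vector of parameter names.
#' @export
model_parameters <- function(model) {
  out <- character(0)
  for (en in model$enzymes) {
    out <- c(out, paste0("Vmax_", en$name))
    if (!is.na(en$Keq)) out <- c(out, paste0("Keq_", en$name))
    out <- c(out, paste0("Km_", en$name, "_", names(en$Km)))
  }
  st <- vapply(model$reactions, function(r) identical(r$law, "structured"), TRUE)
  out <- c(out, paste0("sf_", names(model$reactions)[st]))
  out <- c(out, paste0("conc_", model$species$name[model$species$fixed]))
  out <- c(out, paste0("moiety_", vapply(model$moieties, `[[`, "", "name")))
  if (all(c("NAD", "NADH") %in% model$species$name)) out <- c(out, "ratio_NAD_NADH")
  out
}

#' Get a model parameter value
#' @param model a `kinetic_model`.
#' @param name parameter name as listed by [model_parameters()].
#' @return numeric value.
#' @export
get_parameter <- function(model, name) {
  spl <- split_param(model, name)
  switch(spl$kind,
    Vmax = model$enzymes[[spl$enzyme]]$Vmax,
    Keq = model$enzymes[[spl$enzyme]]$Keq,
    Km = unname(model$enzymes[[spl$enzyme]]$Km[[spl$ligand]]),
    sf = model$reactions[[spl$reaction]]$sf,
    conc = model$species$value[match(spl$species, model$species$name)],
    moiety = model$moieties[[spl$moiety]]$total,
    ratio = {
      v <- model$species$value
      v[match("NAD", model$species$name)] / v[match("NADH", model$species$name)]
    },
    sbml = model$meta$parameters[[spl$sbml]]
  )
}

#' Set a model parameter value
#' @inheritParams get_parameter
#' @param value new numeric value.
#' @return modified `kinetic_model`.
#' @export
set_parameter <- function(model, name, value) {
  spl <- split_param(model, name)
  switch(spl$kind,
    Vmax = model$enzymes[[spl$enzyme]]$Vmax <- value,
    Keq = model$enzymes[[spl$enzyme]]$Keq <- value,
    Km = model$enzymes[[spl$enzyme]]$Km[[spl$ligand]] <- value,
    sf = model$reactions[[spl$reaction]]$sf <- value,
    conc = model$species$value[match(spl$species, model$species$name)] <- value,
    moiety = model$moieties[[spl$moiety]]$total <- value,
    ratio = {
      i <- match("NAD", model$species$name); j <- match("NADH", model$species$name)
      tot <- model$species$value[i] + model$species$value[j]
      model$species$value[i] <- tot * value / (1 + value)
      model$species$value[j] <- tot / (1 + value)
    },
    sbml = model$meta$parameters[[spl$sbml]] <- value
  )
  model
}

split_param <- function(model, name) {
  if (identical(name, "ratio_NAD_NADH")) return(list(kind = "ratio"))
  if (startsWith(name, "Vmax_")) {
    en <- substring(name, 6)
    if (!is.null(model$enzymes[[en]])) return(list(kind = "Vmax", enzyme = en))
  }
  if (startsWith(name, "Keq_")) {
    en <- substring(name, 5)
    if (!is.null(model$enzymes[[en]])) return(list(kind = "Keq", enzyme = en))
  }
  if (startsWith(name, "Km_")) {
    rest <- substring(name, 4)
    for (en in names(model$enzymes)) {
      pre <- paste0(en, "_")
      if (startsWith(rest, pre)) {
        lig <- substring(rest, nchar(pre) + 1)
        if (lig %in% names(model$enzymes[[en]]$Km))
          return(list(kind = "Km", enzyme = en, ligand = lig))
      }
    }
  }
  if (startsWith(name, "sf_")) {
    rx <- substring(name, 4)
    if (!is.null(model$reactions[[rx]])) return(list(kind = "sf", reaction = rx))
  }
  if (startsWith(name, "conc_")) {
    sp <- substring(name, 6)
    i <- match(sp, model$species$name)
    if (!is.na(i) && model$species$fixed[i]) return(list(kind = "conc", species = sp))
  }
  if (startsWith(name, "moiety_")) {
    mo <- substring(name, 8)
    nm <- vapply(model$moieties, `[[`, "", "name")
    i <- match(mo, nm)
    if (!is.na(i)) return(list(kind = "moiety", moiety = i))
  }
  if (name %in% names(model$meta$parameters)) return(list(kind = "sbml", sbml = name))
  stop("unknown parameter: ", name, call. = FALSE)
}
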