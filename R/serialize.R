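# Plain-text (JSON) model serialization; round-trips losslessly.

#' Write a kinetic model to JSON
#'
#' @param model a `kinetic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- list(
    format = "mfao-model", version = 1L,
    species = model$species,
    enzymes = lapply(model$enzymes, function(e)
      list(name = e$name, Vmax = e$Vmax, Keq = e$Keq, Km = as.list(e$Km))),
    reactions = lapply(model$reactions, function(r) {
      if (identical(r$law, "expr"))
        list(name = r$name, enzyme = r$enzyme, law = "expr",
             expr = deparse(r$expr),
             substrates = as.list(r$substrates), products = as.list(r$products))
      else
        list(name = r$name, enzyme = r$enzyme, chain = r$chain, law = "structured",
             substrates = as.list(r$substrates), products = as.list(r$products),
             groups = r$groups, sf = r$sf, alpha = r$alpha,
             reversible = r$reversible)
    }),
    moieties = model$moieties,
    meta = model$meta)
  if (!is.null(obj$meta$parameters))
    obj$meta$parameters <- as.list(obj$meta$parameters)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a kinetic model from JSON
#'
#' @param path file written by [write_model()].
#' @return a `kinetic_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "mfao-model"))
    stop(path, " is not an mfao model file", call. = FALSE)
  sp <- do.call(rbind, lapply(obj$species, function(s) species_row(
    s$name, s$class, if (is.null(s$chain)) NA_integer_ else s$chain,
    s$compartment, isTRUE(s$fixed), s$value)))
  enzymes <- lapply(obj$enzymes, function(e)
    enzyme(e$name, e$Vmax, if (is.null(e$Keq)) NA_real_ else e$Keq,
           unlist(e$Km)))
  reactions <- lapply(obj$reactions, function(r) {
    if (identical(r$law, "expr")) {
      rr <- list(name = r$name, enzyme = r$enzyme, chain = NA_integer_,
                 substrates = unlist(r$substrates), products = unlist(r$products),
                 groups = list(), sf = NA_real_, alpha = 1,
                 reversible = TRUE, law = "expr",
                 expr = str2lang(paste(unlist(r$expr), collapse = " ")))
      return(rr)
    }
    reaction(r$name, r$enzyme, if (is.null(r$chain)) NA_integer_ else r$chain,
             unlist(r$substrates),
             if (length(r$products)) unlist(r$products) else numeric(0),
             lapply(r$groups, function(g) unlist(g)),
             sf = r$sf, alpha = r$alpha, reversible = isTRUE(r$reversible))
  })
  moieties <- lapply(obj$moieties, function(mo)
    list(name = mo$name, species = unlist(mo$species), total = mo$total,
         eliminate = mo$eliminate))
  meta <- obj$meta
  meta$parameters <- if (!is.null(meta$parameters)) unlist(meta$parameters)
  kinetic_model(sp, enzymes, reactions, moieties, meta)
}

#' Load a model from any supported source
#'
#' Dispatch on file extension: `.json` native models, `.xml`/`.sbml`
#' SBML files.
#'
#' @param path model file.
#' @return a `kinetic_model`.
#' @export
load_model <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = read_model(path),
         xml = import_sbml(path),
         sbml = import_sbml(path),
         stop("unsupported model format: .", ext, call. = FALSE))
}
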