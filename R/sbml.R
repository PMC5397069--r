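# SBML Level 2/3 import built on xml2: species, compartments, global and
# local parameters, reaction stoichiometry, and kinetic laws translated
# from MathML into R expressions. Imported models carry generic
# expression rate laws; the simulation, steady-state and
# finite-difference MCA machinery work on them unchanged, while
# operations that need the structured promiscuous form (surgery,
# analytic elasticities) refuse them explicitly.

#' Import an SBML model
#'
#' @param path SBML file (Level 2 or 3).
#' @param name_map optional data.frame with columns `sbml_id`,
#'   `canonical_name` (plus optional `class`, `chain`) renaming species
#'   to the package's canonical ladder names.
#' @return a `kinetic_model` with expression rate laws; provenance
#'   (model id, file md5 checksum) in `meta`.
#' @export
import_sbml <- function(path, name_map = NULL) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  mdl <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mdl, "xml_missing")) stop("no <model> element in ", path, call. = FALSE)

  rename <- function(id) {
    if (is.null(name_map)) return(id)
    i <- match(id, name_map$sbml_id)
    ifelse(is.na(i), id, name_map$canonical_name[i])
  }

  sp_nodes <- xml2::xml_find_all(mdl, ".//listOfSpecies/species")
  if (!length(sp_nodes)) stop("SBML model declares no species", call. = FALSE)
  sp <- do.call(rbind, lapply(sp_nodes, function(nd) {
    id <- rename(xml2::xml_attr(nd, "id"))
    conc <- as.numeric(xml2::xml_attr(nd, "initialConcentration"))
    if (is.na(conc)) conc <- as.numeric(xml2::xml_attr(nd, "initialAmount"))
    if (is.na(conc)) conc <- 0
    fixed <- isTRUE(xml2::xml_attr(nd, "boundaryCondition") == "true") ||
      isTRUE(xml2::xml_attr(nd, "constant") == "true")
    cls <- "other"; chain <- NA_integer_
    if (!is.null(name_map)) {
      i <- match(xml2::xml_attr(nd, "id"), name_map$sbml_id)
      if (!is.na(i)) {
        if (!is.null(name_map$class)) cls <- name_map$class[i]
        if (!is.null(name_map$chain)) chain <- name_map$chain[i]
      }
    }
    species_row(id, cls, chain, xml2::xml_attr(nd, "compartment"), fixed, conc)
  }))

  pars <- list()
  for (nd in xml2::xml_find_all(mdl, ".//listOfParameters/parameter")) {
    pid <- xml2::xml_attr(nd, "id")
    pars[[pid]] <- as.numeric(xml2::xml_attr(nd, "value"))
  }
  for (nd in xml2::xml_find_all(mdl, ".//listOfCompartments/compartment")) {
    pid <- xml2::xml_attr(nd, "id")
    sz <- as.numeric(xml2::xml_attr(nd, "size"))
    pars[[pid]] <- if (is.na(sz)) 1 else sz
  }

  rx_nodes <- xml2::xml_find_all(mdl, ".//listOfReactions/reaction")
  reactions <- list()
  for (nd in rx_nodes) {
    rid <- xml2::xml_attr(nd, "id")
    sref <- function(xp) {
      refs <- xml2::xml_find_all(nd, xp)
      if (!length(refs)) return(numeric(0))
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      stats::setNames(st, rename(xml2::xml_attr(refs, "species")))
    }
    subs <- sref(".//listOfReactants/speciesReference")
    prods <- sref(".//listOfProducts/speciesReference")
    kl <- xml2::xml_find_first(nd, ".//kineticLaw")
    if (inherits(kl, "xml_missing"))
      stop("reaction ", rid, ": no kineticLaw; cannot import", call. = FALSE)
    # local parameters are prefixed with the reaction id to avoid collisions
    loc <- xml2::xml_find_all(kl, ".//listOfParameters/parameter|.//listOfLocalParameters/localParameter")
    loc_map <- character(0)
    for (lp in loc) {
      pid <- xml2::xml_attr(lp, "id")
      gname <- paste0(rid, "_", pid)
      pars[[gname]] <- as.numeric(xml2::xml_attr(lp, "value"))
      loc_map[pid] <- gname
    }
    math <- xml2::xml_find_first(kl, ".//math/*")
    if (inherits(math, "xml_missing"))
      stop("reaction ", rid, ": empty kinetic law", call. = FALSE)
    expr <- mathml_to_r(math, rename_ci = function(id) {
      if (id %in% names(loc_map)) loc_map[[id]] else rename(id)
    })
    reactions[[rid]] <- list(name = rid, enzyme = rid, chain = NA_integer_,
                             substrates = subs, products = prods,
                             groups = list(), sf = NA_real_, alpha = 1,
                             reversible = TRUE, law = "expr", expr = expr)
  }

  meta <- list(name = xml2::xml_attr(mdl, "id"),
               source = path,
               checksum = unname(tools::md5sum(path)),
               parameters = unlist(pars))
  m <- kinetic_model(sp, enzymes = list(), reactions = reactions,
                     moieties = list(), meta = meta)
  # declare conserved moieties discovered from the stoichiometry
  ns <- find_conserved_moieties(m)
  m$moieties <- lapply(seq_along(ns), function(k) {
    w <- ns[[k]]
    memb <- names(w)[w != 0]
    if (!all(w[memb] == 1)) return(NULL)      # only unit-weight pools are usable
    cm <- compile_model(m)
    tot <- sum(cm$init[match(memb, cm$var_names)])
    list(name = paste0("moiety", k), species = memb, total = tot,
         eliminate = memb[which.max(cm$init[match(memb, cm$var_names)])])
  })
  m$moieties <- Filter(Negate(is.null), m$moieties)
  m
}

#' Read a canonical-name mapping table
#'
#' Tab-separated table with columns `sbml_id`, `canonical_name` and
#' optionally `class` and `chain`, used by [import_sbml()] to rename
#' deposited species identifiers onto the package's canonical ladder
#' names and annotate their ester class/chain length.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_name_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sbml_id", "canonical_name")
  if (!all(need %in% names(df)))
    stop("name map needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  if ("chain" %in% names(df)) df$chain <- suppressWarnings(as.integer(df$chain))
  df
}

# Translate a MathML element into an R call. Covers the constructs that
# occur in kinetic laws: arithmetic, powers, unary minus, ci/cn symbols,
# exp/ln/log/sqrt/abs and e-notation constants.
mathml_to_r <- function(node, rename_ci = identity) {
  nm <- xml2::xml_name(node)
  if (nm == "ci") return(as.name(rename_ci(trimws(xml2::xml_text(node)))))
  if (nm == "cn") {
    type <- xml2::xml_attr(node, "type")
    if (identical(type, "e-notation")) {
      kids <- xml2::xml_contents(node)
      txt <- trimws(xml2::xml_text(kids[xml2::xml_name(kids) != "sep"]))
      txt <- txt[nzchar(txt)]
      return(as.numeric(txt[1]) * 10^as.numeric(txt[2]))
    }
    if (identical(type, "rational")) {
      kids <- xml2::xml_contents(node)
      txt <- trimws(xml2::xml_text(kids[xml2::xml_name(kids) != "sep"]))
      txt <- txt[nzchar(txt)]
      return(as.numeric(txt[1]) / as.numeric(txt[2]))
    }
    return(as.numeric(trimws(xml2::xml_text(node))))
  }
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    args <- lapply(kids[-1], mathml_to_r, rename_ci = rename_ci)
    comb <- function(f) Reduce(function(a, b) call(f, a, b), args)
    return(switch(op,
      times = comb("*"),
      plus = if (length(args) == 0) 0 else comb("+"),
      minus = if (length(args) == 1) call("-", args[[1]]) else comb("-"),
      divide = comb("/"),
      power = comb("^"),
      exp = call("exp", args[[1]]),
      ln = call("log", args[[1]]),
      log = if (length(args) == 1) call("log10", args[[1]]) else
        call("log", args[[2]], base = args[[1]]),
      root = call("sqrt", args[[length(args)]]),
      abs = call("abs", args[[1]]),
      stop("unsupported MathML operator: ", op, call. = FALSE)))
  }
  if (nm == "pi") return(pi)
  if (nm == "exponentiale") return(exp(1))
  stop("unsupported MathML element: ", nm, call. = FALSE)
}
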