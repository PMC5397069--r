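# Top-level pipeline: run selected analysis stages against one model and
# emit one CSV per figure-style panel plus a reproducibility manifest.

fmt_csv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 12))
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Resolve a model source specification
#'
#' @param src list with `type` in `"mfao"`, `"synth"`, `"file"` and the
#'   matching arguments (`start_chain`, `substrate`, `seed`, `path`).
#' @return a `kinetic_model`.
#' @export
resolve_model <- function(src) {
  type <- src$type %||% "mfao"
  switch(type,
    mfao = mfao_model(src$start_chain %||% 16, src$substrate %||% 0.1),
    synth = generate_ladder(generator_config(
      start_chain = src$start_chain %||% 16, seed = src$seed %||% 1L)),
    file = load_model(src$path),
    stop("unknown model source type: ", type, call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the analysis pipeline
#'
#' Executes the selected stages in order (scan, surgery, mca,
#' regulation, occupancy) and writes their CSV outputs and a manifest
#' (configuration, model checksum) into `outdir`. Outputs are
#' deterministic given (model, config, seed).
#'
#' @param config nested list (or path to a JSON file): fields `model`
#'   (see [resolve_model()]), `stages`, `outdir`, `grid` (substrate
#'   grid), `substrate` (MCA/occupancy reference concentration),
#'   `transition` (`c(from, to)` for regulation), `reaction` (regulation
#'   target), `seed`, `permissive`.
#' @return invisibly, a list of result objects; stops (unless
#'   `permissive`) if any stage reports non-convergence.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  set.seed(config$seed %||% 1L)
  outdir <- config$outdir %||% "mfao_results"
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages %||% c("scan", "surgery", "mca", "regulation", "occupancy")
  model <- resolve_model(config$model %||% list(type = "mfao"))
  grid <- config$grid %||% substrate_grid(0.1, 100, 40)
  ref_conc <- config$substrate %||% 60
  trans <- config$transition %||% c(0.1, 60)
  reaction <- config$reaction %||% "MCKAT_C4"
  flagged <- character(0)
  results <- list()

  model_path <- file.path(outdir, "model.json")
  write_model(model, model_path)

  if ("scan" %in% stages) {
    sc <- scan_steady_states(model, grid = grid)
    if (!all(sc$converged)) flagged <- c(flagged, "scan: non-converged rows")
    fmt_csv(as.data.frame(sc), file.path(outdir, "scan_flux.csv"))
    pk <- find_flux_peak(sc)
    results$scan <- sc; results$peak <- pk
  }
  if ("surgery" %in% stages) {
    suite <- variant_scan_suite(model, grid)
    for (nm in names(suite))
      fmt_csv(as.data.frame(suite[[nm]]), file.path(outdir, paste0("surgery_", nm, ".csv")))
    results$surgery <- suite
  }
  if (any(c("mca", "occupancy", "regulation") %in% stages)) {
    mref <- set_parameter(model, model$meta$substrate_param, ref_conc)
    ss <- find_steady_state(mref)
    if (!ss$converged) flagged <- c(flagged, "reference steady state non-converged")
  }
  if ("mca" %in% stages) {
    tbl <- control_table(mref, ss, chains = TRUE,
                         parameters = config$parameters %||% model_parameters(mref))
    if (!all(tbl$accepted | !is.finite(tbl$value)))
      flagged <- c(flagged, "mca: entries rejected by the +/- rule")
    fmt_csv(tbl, file.path(outdir, "mca_control.csv"))
    fmt_csv(top_responses(tbl), file.path(outdir, "mca_top_responses.csv"))
    results$mca <- tbl
  }
  if ("regulation" %in% stages) {
    tr <- regulation_trace(mref, trans[1], trans[2], reaction)
    long <- data.frame(t = rep(tr$times, ncol(tr$theta)),
                       metabolite = rep(colnames(tr$theta), each = length(tr$times)),
                       theta = as.vector(tr$theta))
    fmt_csv(long, file.path(outdir, "regulation_trace.csv"))
    fmt_csv(data.frame(metabolite = names(tr$abs_avg),
                       abs_avg_theta = unname(tr$abs_avg),
                       relative_share = unname(tr$rel_share)),
            file.path(outdir, "regulation_summary.csv"))
    results$regulation <- tr
  }
  if ("occupancy" %in% stages) {
    enzymes <- config$occupancy_enzymes %||%
      intersect(c("MCKAT", "MCAD", "SCAD"), names(model$enzymes))
    occ <- lapply(enzymes, function(e) {
      tbl <- active_site_occupancy(mref, ss$state, e)
      tbl$enzyme <- e
      tbl
    })
    fmt_csv(do.call(rbind, occ), file.path(outdir, "occupancy.csv"))
    fmt_csv(flux_breakdown(mref, ss), file.path(outdir, "flux_breakdown.csv"))
    results$occupancy <- occ
  }

  manifest <- list(config = config, stages = stages,
                   model_checksum = unname(tools::md5sum(model_path)),
                   flagged = flagged,
                   timestamp = format(Sys.time(), tz = "UTC"),
                   package_version = as.character(utils::packageVersion("mfao")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (length(flagged) && !isTRUE(config$permissive))
    stop("pipeline flagged: ", paste(flagged, collapse = "; "), call. = FALSE)
  invisible(results)
}

#' Command-line interface
#'
#' Subcommands: `synth`, `scan`, `surgery`, `mca`, `regulation`,
#' `occupancy`, `run`. Invoked by the `exec/mfao` script; arguments are
#' `--key value` pairs. Unseeded `synth` calls draw a seed and log it.
#'
#' @param args character vector (default: command-line arguments).
#' @return exit status, invisibly.
#' @export
mfao_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: mfao <synth|scan|surgery|mca|regulation|occupancy|run> [--key value ...]")
    return(invisible(1L))
  }
  cmd <- args[[1]]
  opt <- parse_cli_args(args[-1])
  getn <- function(k, d = NULL) if (!is.null(opt[[k]])) as.numeric(opt[[k]]) else d
  model_from_opt <- function() {
    if (!is.null(opt$model)) load_model(opt$model) else mfao_model()
  }
  status <- 0L
  switch(cmd,
    synth = {
      seed <- getn("seed")
      if (is.null(seed)) {
        seed <- sample.int(1e6, 1)
        message("no --seed given; drew seed ", seed)
      }
      m <- generate_ladder(generator_config(
        start_chain = getn("start-chain", 16), seed = as.integer(seed)))
      write_model(m, opt$out %||% "model.json")
      message("wrote ", opt$out %||% "model.json")
    },
    scan = {
      m <- model_from_opt()
      grid <- seq(getn("from", 0.1), getn("to", 100), length.out = getn("points", 50))
      sc <- scan_steady_states(m, opt$param, grid)
      fmt_csv(as.data.frame(sc), opt$out %||% "scan.csv")
      if (!all(sc$converged)) status <- 1L
    },
    surgery = {
      m <- model_from_opt()
      mode <- opt$mode %||% "all"
      mv <- if (identical(mode, "all")) remove_promiscuity(m, "all")
        else if (startsWith(mode, "only:")) remove_promiscuity_except(m, sub("^only:", "", mode))
        else if (startsWith(mode, "except:")) remove_promiscuity(m, sub("^except:", "", mode))
        else if (startsWith(mode, "list:"))
          remove_promiscuity(m, strsplit(sub("^list:", "", mode), ",")[[1]])
        else stop("unknown --mode: ", mode, call. = FALSE)
      write_model(mv, opt$out %||% "model_depromiscuized.json")
      message("wrote ", opt$out %||% "model_depromiscuized.json")
    },
    mca = {
      m <- model_from_opt()
      m <- set_parameter(m, m$meta$substrate_param, getn("substrate", 60))
      ss <- find_steady_state(m)
      pars <- if (is.null(opt$params) || identical(opt$params, "all"))
        model_parameters(m) else strsplit(opt$params, ",")[[1]]
      tbl <- control_table(m, ss, chains = TRUE, parameters = pars)
      fmt_csv(tbl, opt$out %||% "mca.csv")
      if (!ss$converged) status <- 1L
    },
    regulation = {
      m <- model_from_opt()
      tr <- regulation_trace(m, getn("from", 0.1), getn("to", 60),
                             opt$reaction %||% "MCKAT_C4", getn("t-end", 400))
      fmt_csv(data.frame(metabolite = names(tr$abs_avg),
                         abs_avg_theta = unname(tr$abs_avg),
                         relative_share = unname(tr$rel_share)),
              opt$out %||% "regulation.csv")
    },
    occupancy = {
      m <- model_from_opt()
      m <- set_parameter(m, m$meta$substrate_param, getn("substrate", 60))
      ss <- find_steady_state(m)
      tbl <- active_site_occupancy(m, ss$state, opt$enzyme %||% "MCKAT")
      fmt_csv(tbl, opt$out %||% "occupancy.csv")
      if (!ss$converged) status <- 1L
    },
    run = {
      cfg <- if (!is.null(opt$config)) opt$config else
        list(outdir = opt$out %||% "mfao_results",
             seed = as.integer(getn("seed", 1)))
      run_pipeline(cfg)
    },
    stop("unknown subcommand: ", cmd, call. = FALSE)
  )
  invisible(status)
}

parse_cli_args <- function(args) {
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (i < length(args) && !startsWith(args[[i + 1L]], "--")) {
        opt[[key]] <- args[[i + 1L]]; i <- i + 2L
      } else { opt[[key]] <- TRUE; i <- i + 1L }
    } else i <- i + 1L
  }
  opt
}
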