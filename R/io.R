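# Configuration files, output writers and the command-line entry point.

.known_config_keys <- c("params", "run", "grid1d", "grid2d", "variant",
                        "output", "seed")
.run_keys <- c("mode", "t_end_h", "dt_max", "out_every", "snapshot_every",
               "initial_width_um", "u0", "n_reps", "base_width_um",
               "jitter_um", "G0", "parameter", "h", "start_width_um",
               "horizon_h", "shape", "r", "center", "bc_left", "bc_top")

#' Read a simulation configuration
#'
#' YAML mapping with top-level keys `params` (parameter overrides in paper
#' units), `run` (mode and run controls), `grid1d`, `grid2d`, `variant`,
#' `output`, `seed`.  Unknown keys are errors (with a nearest-key hint) so
#' that misspelled parameter names cannot silently fall back to defaults.
#'
#' @param path YAML file; an empty file yields the full-default
#'   configuration (mode `simulate1d`, published parameter defaults).
#' @return list with `config` (filled defaults) and `params`
#'   (`biofilm_params`, internal units).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), .known_config_keys)
  if (length(unknown)) {
    hint <- vapply(unknown, function(u) {
      cand <- .known_config_keys[agrepl(u, .known_config_keys, max.distance = 2)]
      if (length(cand)) paste0(" (did you mean '", cand[[1]], "'?)") else ""
    }, character(1))
    stop("unknown config key(s) in ", path, ": ",
         paste0("'", unknown, "'", hint, collapse = ", "), call. = FALSE)
  }
  if (!is.null(raw$run)) {
    bad <- setdiff(names(raw$run), .run_keys)
    if (length(bad)) {
      hint <- vapply(bad, function(u) {
        cand <- .run_keys[agrepl(u, .run_keys, max.distance = 2)]
        if (length(cand)) paste0(" (did you mean '", cand[[1]], "'?)") else ""
      }, character(1))
      stop("unknown run key(s): ", paste0("'", bad, "'", hint, collapse = ", "),
           call. = FALSE)
    }
  }
  params <- load_parameters(if (is.null(raw$params)) list() else raw$params,
                            units_of_overrides = "paper")
  cfg <- list(
    run = utils::modifyList(list(mode = "simulate1d", t_end_h = 20,
                                 dt_max = 0.01, out_every = 0.05,
                                 initial_width_um = 200),
                            if (is.null(raw$run)) list() else raw$run),
    grid1d = utils::modifyList(list(dx_um = 2),
                               if (is.null(raw$grid1d)) list() else raw$grid1d),
    grid2d = utils::modifyList(list(Lx_mm = 3, Ly_mm = 3, h_um = 30),
                               if (is.null(raw$grid2d)) list() else raw$grid2d),
    variant = if (is.null(raw$variant)) list(kind = "full") else raw$variant,
    output = if (is.null(raw$output)) list() else raw$output,
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
    params_paper_units = as.list(unclass(denormalize_units(params))))
  modes <- c("simulate1d", "simulate2d", "onset-experiment", "sensitivity",
             "variants")
  if (!cfg$run$mode %in% modes)
    stop("unknown run mode '", cfg$run$mode, "'; expected one of ",
         paste(modes, collapse = ", "), call. = FALSE)
  list(config = cfg, params = params)
}

#' Write simulation outputs
#'
#' Writes the trace as CSV, optional full-field snapshots as per-time CSV
#' files under `snapshots/`, and the effective configuration (including the
#' seed) as JSON — enough metadata to reproduce the run exactly.  Re-running
#' with the same configuration and seed reproduces the CSV bit-identically.
#'
#' @param trace `oscillation_trace` data.frame (may have zero rows).
#' @param dir output directory (created if needed).
#' @param config effective configuration list (serialized to JSON).
#' @param snapshots optional list of snapshot states.
#' @return invisibly, the paths written.
#' @export
write_outputs <- function(trace, dir, config = list(), snapshots = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "trace.csv")
  write.csv(as.data.frame(trace), paths[1], row.names = FALSE)
  cfgp <- file.path(dir, "config.json")
  jsonlite::write_json(config, cfgp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, cfgp)
  if (!is.null(snapshots) && length(snapshots)) {
    sd <- file.path(dir, "snapshots")
    dir.create(sd, showWarnings = FALSE)
    for (nm in names(snapshots)) {
      s <- snapshots[[nm]]
      if (inherits(s, "state1d")) {
        df <- data.frame(x_mm = s$x)
        for (f in .field_names) df[[f]] <- s[[f]]
        write.csv(df, file.path(sd, paste0(nm, ".csv")), row.names = FALSE)
      }
    }
    paths <- c(paths, sd)
  }
  invisible(paths)
}

.cli_usage <- function() {
  cat("usage: biofilmosc <simulate1d|simulate2d|onset|sensitivity|variants>",
      "[--config FILE] [--param NAME=VALUE ...] [--seed N] [--out DIR]",
      "[--coarse]\n")
}

# Parse --flag value pairs and repeatable --param NAME=VALUE.
.parse_cli <- function(args) {
  out <- list(params = list())
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (a %in% c("--config", "--seed", "--out")) {
      if (i == length(args)) stop("missing value for ", a, call. = FALSE)
      out[[sub("^--", "", a)]] <- args[[i + 1L]]
      i <- i + 2L
    } else if (a == "--param") {
      if (i == length(args)) stop("missing value for --param", call. = FALSE)
      kv <- strsplit(args[[i + 1L]], "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("--param expects NAME=VALUE", call. = FALSE)
      out$params[[kv[1]]] <- as.numeric(kv[2])
      i <- i + 2L
    } else if (a == "--coarse") {
      out$coarse <- TRUE
      i <- i + 1L
    } else stop("unknown option ", a, call. = FALSE)
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate1d`, `simulate2d`, `onset`, `sensitivity`,
#' `variants`.  Flags: `--config FILE`, repeatable `--param NAME=VALUE`
#' (paper units), `--seed N`, `--out DIR`, `--coarse` (desk-scale 2D
#' grid).  Returns (rather than calls) the exit status so it can be tested
#' in-process; the installed script passes it to `quit()`.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit status (0 ok, 2 usage error, 1 runtime error).
#' @export
biofilm_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv) ||
      !argv[1] %in% c("simulate1d", "simulate2d", "onset", "sensitivity",
                      "variants")) {
    .cli_usage()
    return(2L)
  }
  sub <- argv[1]
  opts <- tryCatch(.parse_cli(argv[-1]), error = function(e) e)
  if (inherits(opts, "error")) {
    message(conditionMessage(opts)); .cli_usage(); return(2L)
  }
  status <- tryCatch({
    if (!is.null(opts$config)) {
      rc <- read_config(opts$config)
      cfg <- rc$config
      p <- rc$params
      if (length(opts$params)) {
        merged <- utils::modifyList(cfg$params_paper_units, opts$params)
        keep <- intersect(names(merged), .param_table()$name)
        p <- load_parameters(merged[keep], units_of_overrides = "paper")
      }
    } else {
      cfg <- read_config_defaults()
      p <- load_parameters(opts$params, units_of_overrides = "paper")
    }
    seed <- if (!is.null(opts$seed)) as.integer(opts$seed) else cfg$seed
    outdir <- if (!is.null(opts$out)) opts$out else "biofilmosc-out"
    run <- cfg$run
    message("biofilmosc ", as.character(utils::packageVersion("biofilmosc")),
            " | mode=", sub, " seed=", seed)
    if (sub == "simulate1d") {
      tr <- run_1d(run$initial_width_um / 1000, p, t_end_h = run$t_end_h,
                   variant = do.call(variant_spec, cfg$variant),
                   dt_max = run$dt_max, out_every = run$out_every)
      write_outputs(tr, outdir, config = c(cfg, list(seed = seed)),
                    snapshots = attr(tr, "snapshots"))
    } else if (sub == "simulate2d") {
      h <- if (isTRUE(opts$coarse)) 0.03 else cfg$grid2d$h_um / 1000
      g <- make_grid2d(cfg$grid2d$Lx_mm, cfg$grid2d$Ly_mm, h)
      shape <- shape_spec(if (is.null(run$shape)) "wall_half_disc" else run$shape,
                          r = if (is.null(run$r)) 0.6 else run$r)
      res <- run_2d(shape, p, t_end_h = run$t_end_h, grid = g,
                    u0 = if (is.null(run$u0)) p$u0 else run$u0)
      write_outputs(res$trace, outdir, config = c(cfg, list(seed = seed)))
    } else if (sub == "onset") {
      ex <- onset_experiment(p, n_reps = if (is.null(run$n_reps)) 53 else run$n_reps,
                             seed = seed)
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      write.csv(ex$replicates, file.path(outdir, "onsets.csv"),
                row.names = FALSE)
      jsonlite::write_json(c(cfg, list(seed = seed),
                             mean_doubled_width_um = ex$mean_doubled_width_um),
                           file.path(outdir, "config.json"),
                           auto_unbox = TRUE, digits = NA)
      message(sprintf("mean onset doubled width: %.1f um",
                      ex$mean_doubled_width_um))
    } else if (sub == "sensitivity") {
      target <- if (!is.null(opts$params$target)) names(opts$params)[1] else run$parameter
      pars <- if (is.null(target)) sensitivity_parameters() else target
      tab <- sensitivity_table(p, parameters = pars)
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      write.csv(tab, file.path(outdir, "sensitivity.csv"), row.names = FALSE)
      message("wrote sensitivity table (", nrow(tab), " rows)")
    } else if (sub == "variants") {
      for (vk in c("full", "constant_mgrow", "no_acclimation", "no_leak_uptake")) {
        tr <- run_1d(0.150, p, t_end_h = run$t_end_h, variant = vk,
                     on_blowup = "truncate")
        write_outputs(tr, file.path(outdir, vk),
                      config = c(cfg, list(seed = seed, variant = vk)))
      }
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  status
}

# Default configuration (no file).
read_config_defaults <- function() {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  writeLines("", tf)
  read_config(tf)$config
}
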