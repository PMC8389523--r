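config_defaults <- function() {
  list(t = 50, b = 200, a0 = 100,
       j_bb = 8, j_yy = 8, j_yb = 14, j_ym = 10, j_bm = 22, j_mm = 0,
       hamiltonian_order = 4, copy_order = 2,
       n_cells = 200, ratio_blue = 0.5, bc = "free", margin = NA,
       mcs_total = 1000, seed = 1, guard = TRUE,
       medium_exempt = TRUE, medium_area_term = FALSE,
       gamma_include_medium = FALSE)
}

#' Load a simulation configuration file
#'
#' Reads a flat key-value (YAML mapping) configuration; omitted keys take the
#' package defaults (T = 50, B = 200, A0 = 100, 4th-order Hamiltonian
#' stencil, guard on). Heterotypic keys may be given as either orientation
#' (`j_yb`/`j_by`); giving both with different values is an error, as is any
#' unknown key. A configuration violating the sorting inequalities loads with
#' a warning (see [check_sorting_inequalities()]).
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @return a validated configuration list with components `params`
#'   (a [cpm_params()]), `init` (`n_cells`, `ratio_blue`, `bc`, `a0`,
#'   `margin`) and `run` (`mcs_total`, `seed`, `guard`), plus the flat
#'   key-value list as attribute `"raw"`.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  names(raw) <- tolower(names(raw))
  # symmetric-alias keys
  for (al in list(c("j_by", "j_yb"), c("j_my", "j_ym"), c("j_mb", "j_bm"))) {
    if (al[1] %in% names(raw)) {
      if (al[2] %in% names(raw) && !isTRUE(all.equal(raw[[al[1]]], raw[[al[2]]])))
        stop("contact energies must be symmetric: ", al[1], " != ", al[2])
      raw[[al[2]]] <- raw[[al[1]]]
      raw[[al[1]]] <- NULL
    }
  }
  defaults <- config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, raw)
  if (!cfg$bc %in% c("free", "periodic")) stop("bc must be 'free' or 'periodic'")
  if (cfg$ratio_blue < 0 || cfg$ratio_blue > 1) stop("ratio_blue must be in [0, 1]")
  if (cfg$mcs_total < 0) stop("mcs_total must be non-negative")
  J <- default_J(cfg$j_bb, cfg$j_yy, cfg$j_yb, cfg$j_ym, cfg$j_bm, cfg$j_mm)
  params <- cpm_params(J = J, B = cfg$b, A0 = cfg$a0, T = cfg$t,
                       hamiltonian_order = cfg$hamiltonian_order,
                       copy_order = cfg$copy_order,
                       medium_area_term = cfg$medium_area_term,
                       medium_exempt = cfg$medium_exempt,
                       gamma_include_medium = cfg$gamma_include_medium)
  for (w in check_sorting_inequalities(J)) warning(w, call. = FALSE)
  structure(list(params = params,
                 init = list(n_cells = cfg$n_cells, ratio_blue = cfg$ratio_blue,
                             bc = cfg$bc, a0 = cfg$a0,
                             margin = if (is.na(cfg$margin)) NULL else cfg$margin),
                 run = list(mcs_total = cfg$mcs_total, seed = cfg$seed,
                            guard = cfg$guard)),
            raw = cfg, class = "cpm_config")
}

#' Save a configuration to a YAML file
#'
#' Round-trips with [load_config()]: `load_config(save_config(cfg, path))`
#' reproduces `cfg`.
#'
#' @param config a configuration from [load_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  raw <- attr(config, "raw")
  raw$margin <- if (is.null(config$init$margin)) NA else config$init$margin
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Build the initial state described by a configuration
#'
#' @param config a configuration from [load_config()].
#' @param seed optional seed overriding `config$run$seed`.
#' @return a [cpm_state()].
#' @export
build_initial_state <- function(config, seed = NULL) {
  if (is.null(seed)) seed <- config$run$seed
  init <- config$init
  if (init$bc == "periodic")
    build_periodic(init$n_cells, init$ratio_blue, init$a0, seed = seed)
  else
    build_aggregate(init$n_cells, init$ratio_blue, init$a0,
                    margin = init$margin, seed = seed)
}

#' Write a three-color PNG snapshot of a lattice state
#'
#' Blue cells render blue, yellow cells gold, medium white; cell-cell
#' boundaries are not drawn (type domains are what the eye should track).
#'
#' @param state a [cpm_state()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_snapshot_png <- function(state, path) {
  code <- matrix(state$type_of[state$grid + 1L], nrow(state$grid))
  cols <- rbind(M = c(1, 1, 1), B = c(0.13, 0.31, 0.76), Y = c(0.95, 0.82, 0.18))
  img <- array(0, c(nrow(code), ncol(code), 3))
  for (ch in 1:3) img[, , ch] <- matrix(cols[code + 1L, ch], nrow(code))
  png::writePNG(img, path)
  invisible(path)
}

#' Save / load a run checkpoint
#'
#' A checkpoint holds the complete resumable state of a run: the lattice
#' state, the attempt counter, the running energy, and the R RNG state, so
#' that a resumed run continues the exact same chain.
#'
#' @param state a [cpm_state()].
#' @param path checkpoint file path (RDS).
#' @param attempts cumulative copy-attempt count.
#' @param energy running total energy.
#' @return `path` invisibly for `save_checkpoint`; for `load_checkpoint` a
#'   list with `state`, `attempts`, `energy` (the RNG state is restored as a
#'   side effect).
#' @export
save_checkpoint <- function(state, path, attempts = 0, energy = NULL) {
  rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  saveRDS(list(state = state, attempts = attempts, energy = energy,
               rng = rng, version = as.character(utils::packageVersion("cpmsort"))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!is.null(ck$rng)) assign(".Random.seed", ck$rng, envir = globalenv())
  validate_state(ck$state)
  ck[c("state", "attempts", "energy")]
}

#' Write the file outputs of a run
#'
#' Emits into `outdir`: `trace.csv` (the kinetics trace),
#' `correlations.csv` (long-format autocorrelation curves, when recorded),
#' `final_state.png` (three-color snapshot), `checkpoint.rds` (resumable
#' final state), and `manifest.json` (configuration, seed, package version)
#' enabling an exact rerun.
#'
#' @param run a `cpm_run` from [run_cpm()].
#' @param outdir output directory, created if needed.
#' @return invisibly, the vector of file paths written.
#' @export
write_outputs <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(outdir, "trace.csv")
  write.csv(run$trace, p, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(run$correlations)) {
    p <- file.path(outdir, "correlations.csv")
    write.csv(run$correlations, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(outdir, "final_state.png")
  write_snapshot_png(run$state, p)
  paths <- c(paths, p)
  p <- file.path(outdir, "checkpoint.rds")
  tr <- run$trace
  save_checkpoint(run$state, p, attempts = run$attempts,
                  energy = tr$energy[nrow(tr)])
  paths <- c(paths, p)
  p <- file.path(outdir, "manifest.json")
  cfg <- run$config
  manifest <- list(mcs_total = cfg$mcs_total, seed = cfg$seed,
                   guard = cfg$guard, sample_times = cfg$sample_times,
                   max_r = cfg$max_r,
                   params = list(J = cfg$params$J, B = cfg$params$B,
                                 A0 = cfg$params$A0, T = cfg$params$T,
                                 hamiltonian_order = cfg$params$hamiltonian_order,
                                 copy_order = cfg$params$copy_order),
                   package_version = as.character(utils::packageVersion("cpmsort")))
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}
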