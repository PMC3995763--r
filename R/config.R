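# Run configuration: plain-text config files (JSON, TOML-style or bare
# key = value lines) mirroring the standard parameter names, resolved
# against the baseline defaults, with unknown keys rejected.

CONFIG_KEYS <- c("f_max", "k_L", "m", "alpha", "m_L", "T_max",
                 "E0", "L0", "E_min", "L_min", "u_min", "u_max",
                 "mesh_size", "refine_rounds", "tol", "n_starts", "seed",
                 "sweep_name", "sweep_n", "out_dir", "log_level")

#' Read a run configuration file
#'
#' Accepts JSON (`{"T_max": 20, ...}`) or TOML-style / bare `key = value`
#' lines (sections in square brackets are allowed and ignored; `#`
#' comments are stripped).  Keys mirror the standard model and problem
#' names: `f_max, k_L, m, alpha, m_L, T_max, E0, L0, E_min, L_min,
#' u_min, u_max`, plus solver keys (`mesh_size, refine_rounds, tol,
#' n_starts, seed`) and run keys (`sweep_name, sweep_n, out_dir,
#' log_level`).  Unknown keys are an error.  An empty configuration
#' reproduces the baseline problem.
#'
#' @param path Path to the configuration file, or `NULL` for an empty
#'   configuration.
#' @param overrides Named list applied on top of the file (e.g. parsed
#'   from `--set key=value` flags).
#' @return An object of class `run_config`: the fully-resolved
#'   configuration with `params`, `bc`, `options` constructors applied.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    txt <- readLines(path, warn = FALSE)
    trimmed <- trimws(paste(txt, collapse = "\n"))
    raw <- if (startsWith(trimmed, "{")) {
      jsonlite::fromJSON(trimmed, simplifyVector = TRUE)
    } else {
      parse_kv_config(txt)
    }
  }
  resolve_run_config(utils::modifyList(raw, overrides))
}

parse_kv_config <- function(lines) {
  out <- list()
  for (ln in lines) {
    ln <- sub("#.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "" || grepl("^\\[.*\\]$", ln)) next
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.+)$",
                                ln))[[1]]
    if (length(m) != 3L) stop("cannot parse config line: ", ln)
    val <- trimws(m[3])
    val <- gsub('^"|"$', "", val)
    num <- suppressWarnings(as.numeric(val))
    out[[m[2]]] <- if (!is.na(num)) num else val
  }
  out
}

#' Resolve a configuration list against the baseline defaults
#'
#' @param config Named list of overrides (see [read_run_config()] for
#'   the accepted keys).
#' @return A `run_config` object with `params` ([model_params()]), `bc`
#'   ([boundary_constraints()]), `options` ([solver_options()]), and the
#'   run keys.
#' @export
resolve_run_config <- function(config = list()) {
  unknown <- setdiff(names(config), CONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         "\n  accepted keys: ", paste(CONFIG_KEYS, collapse = ", "))
  grab <- function(keys, defaults) {
    v <- defaults
    for (k in intersect(keys, names(config))) v[[k]] <- config[[k]]
    v
  }
  pdef <- list(f_max = 1, k_L = 1, m = 0.02, alpha = 1, m_L = 0.08,
               T_max = 20)
  bdef <- list(E0 = 5.5, L0 = 0, E_min = 5, L_min = 0, u_min = 0,
               u_max = 1)
  odef <- list(mesh_size = 400L, refine_rounds = 2L, tol = 1e-8,
               n_starts = 1L, seed = 1L)
  pv <- grab(names(pdef), pdef)
  bv <- grab(names(bdef), bdef)
  ov <- grab(names(odef), odef)
  structure(list(
    params = do.call(model_params, pv),
    bc = do.call(boundary_constraints, bv),
    options = do.call(solver_options, ov),
    sweep_name = config[["sweep_name"]] %||% "T_max",
    sweep_n = as.integer(config[["sweep_n"]] %||% 16L),
    out_dir = config[["out_dir"]] %||% ".",
    log_level = config[["log_level"]] %||% "info",
    resolved = utils::modifyList(c(pdef, bdef, odef), config)),
    class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trajectory to CSV
#'
#' One row per grid point with columns `time,E,L,u`, at full double
#' precision (15 significant digits).
#'
#' @param traj A trajectory data.frame (`time`, `E`, `L`, `u`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(time = format(traj$time, digits = 15, trim = TRUE),
                   E = format(traj$E, digits = 15, trim = TRUE),
                   L = format(traj$L, digits = 15, trim = TRUE),
                   u = format(traj$u, digits = 15, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory or strategy CSV
#'
#' @param path CSV with at least `time` and `u` columns.
#' @return A data.frame.
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("time", "u") %in% names(df)))
    stop("malformed trajectory file (need at least time,u columns): ",
         path)
  df
}

#' Export a full solution (states, control, costates, switching value)
#'
#' Writes `<stem>.csv` with columns
#' `time,E,L,u,lambda_E,lambda_L,sigma` and a JSON sidecar
#' `<stem>.json` with the objective, diagnostics, options and parameter
#' echo.
#'
#' @param fit A `life_ocp` fit.
#' @param stem Output path without extension.
#' @return The two file paths, invisibly.
#' @export
write_solution <- function(fit, stem) {
  cs <- fit$costates
  df <- data.frame(time = fit$times, E = fit$E, L = fit$L, u = fit$u,
                   lambda_E = if (is.null(cs)) NA else cs$lambda_E,
                   lambda_L = if (is.null(cs)) NA else cs$lambda_L,
                   sigma = if (is.null(cs)) NA else cs$sigma)
  csv <- paste0(stem, ".csv")
  out <- lapply(df, function(col) format(col, digits = 15, trim = TRUE))
  utils::write.csv(as.data.frame(out), csv, row.names = FALSE,
                   quote = FALSE)
  side <- paste0(stem, ".json")
  jsonlite::write_json(
    list(objective = fit$objective,
         diagnostics = fit$diagnostics,
         params = unclass(fit$params),
         boundary_constraints = unclass(fit$bc),
         options = unclass(fit$options)),
    side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv, side))
}

#' Export a phase segmentation as JSON
#'
#' @param seg A `phase_segmentation`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_segmentation_json <- function(seg, path) {
  jsonlite::write_json(
    list(segments = seg$segments,
         fractions = as.list(seg$fractions),
         tolerances = seg$tolerances,
         n_forced_merges = seg$n_forced_merges),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

log_msg <- function(level, module, ..., threshold = "info") {
  levels <- c(debug = 1L, info = 2L, warn = 3L)
  if (levels[[level]] < levels[[threshold]]) return(invisible())
  cat(sprintf("%s [%s] %s: %s\n",
              format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), level, module,
              paste0(..., collapse = "")),
      file = stderr())
  invisible()
}
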