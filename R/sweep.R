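# Phase-diagram experiments: how the optimal phase structure over
# normalized age (0-1) responds to the life-history and environmental
# parameters T_max, m_L, k_L and alpha, holding everything else at the
# baseline.

SWEEPABLE <- c("T_max", "m_L", "k_L", "alpha")

#' Default sweep grid for a sweepable parameter
#'
#' 16 values spanning the studied range: log-spaced for the scale-like
#' parameters `k_L` and `m_L`, linear for `T_max` and `alpha`.
#'
#' @param name One of `"T_max"`, `"m_L"`, `"k_L"`, `"alpha"`.
#' @param n Number of values (default 16).
#' @return A numeric vector of parameter values.
#' @export
default_sweep_grid <- function(name, n = 16L) {
  if (!name %in% SWEEPABLE)
    stop("'", name, "' is not sweepable; choose one of ",
         paste(SWEEPABLE, collapse = ", "))
  r <- .param_ranges()[[name]]
  if (name %in% c("k_L", "m_L"))
    exp(seq(log(r[1]), log(r[2]), length.out = n))
  else
    seq(r[1], r[2], length.out = n)
}

#' Sweep one model parameter and classify the optimal phases per value
#'
#' For each value of the swept parameter the optimization problem is
#' solved with all other parameters at the baseline, the solution is
#' segmented into knowledge phases, and segment times are normalized by
#' that cell's lifespan.  Solver failures are recorded per cell and the
#' sweep continues.  Cells whose solution fails the Pontryagin
#' consistency check are re-solved at double mesh with a refinement
#' round before being accepted.
#'
#' @param name One of `"T_max"`, `"m_L"`, `"k_L"`, `"alpha"`.
#' @param values Parameter values; defaults to [default_sweep_grid()].
#' @param base Baseline [model_params()] (the swept entry is ignored).
#' @param bc [boundary_constraints()].
#' @param options [solver_options()] per cell; defaults to
#'   [reduced_options()].
#' @return An object of class `phase_sweep`: `name`, `values`, `cells`
#'   (per-value list with `fit`, `segmentation`, `fractions`, `status`)
#'   and `table` (see [sweep_to_table()]).
#' @export
#' @examples
#' \donttest{
#' sw <- sweep_parameter("T_max", values = c(10, 20, 40))
#' sweep_to_table(sw)
#' }
sweep_parameter <- function(name, values = NULL, base = model_params(),
                            bc = boundary_constraints(),
                            options = reduced_options()) {
  if (!name %in% SWEEPABLE)
    stop("'", name, "' is not sweepable; choose one of ",
         paste(SWEEPABLE, collapse = ", "))
  if (is.null(values)) values <- default_sweep_grid(name)
  values <- sort(values)
  base <- as_model_params(base)
  bc <- as_boundary_constraints(bc)

  cells <- lapply(values, function(v) {
    pars <- unclass(base)
    pars[[name]] <- v
    cell <- list(value = v, status = "ok", fit = NULL,
                 segmentation = NULL, fractions = NULL)
    res <- tryCatch({
      params <- suppressWarnings(do.call(model_params, pars))
      fit <- suppressWarnings(optimal_strategy(params, bc, options))
      pmp <- tryCatch(check_pmp(fit), error = function(e) NULL)
      if (is.null(pmp) || !pmp$pass) {
        retry <- solver_options(
          mesh_size = max(2L * options$mesh_size, 40L),
          refine_rounds = 2L, tol = options$tol, seed = options$seed,
          eps_schedule = options$eps_schedule,
          inner_maxit = options$inner_maxit, factr = options$factr,
          max_outer = options$max_outer)
        fit2 <- suppressWarnings(optimal_strategy(params, bc, retry))
        if (fit2$objective >= fit$objective) fit <- fit2
      }
      fit
    }, error = function(e) e)
    if (inherits(res, "error")) {
      cell$status <- paste("failed:", conditionMessage(res))
      return(cell)
    }
    cell$fit <- res
    seg <- tryCatch(classify_phases(res), error = function(e) e)
    if (inherits(seg, "error")) {
      cell$status <- paste("failed:", conditionMessage(seg))
      return(cell)
    }
    # normalize segment times by this cell's lifespan
    segn <- seg
    segn$segments$t_start <- seg$segments$t_start / res$params$T_max
    segn$segments$t_end <- seg$segments$t_end / res$params$T_max
    segn$T_max <- 1
    cell$segmentation <- segn
    cell$fractions <- seg$fractions
    cell
  })

  sw <- structure(list(name = name, values = values, cells = cells),
                  class = "phase_sweep")
  sw$table <- sweep_to_table(sw)
  sw
}

#' Long-format table of a phase sweep
#'
#' One record per (parameter value, phase label), in ascending parameter
#' order and canonical phase order.  Phases absent from a cell get
#' fraction 0 and an empty (`NA`) interval.  Failed cells carry their
#' status with `NA` fractions.
#'
#' @param res A `phase_sweep` from [sweep_parameter()].
#' @return A data.frame with columns `param_name`, `param_value`,
#'   `phase`, `frac`, `start_norm`, `end_norm`, `status`.
#' @export
sweep_to_table <- function(res) {
  stopifnot(inherits(res, "phase_sweep"))
  rows <- lapply(res$cells, function(cell) {
    out <- data.frame(param_name = res$name, param_value = cell$value,
                      phase = PHASE_LEVELS, frac = NA_real_,
                      start_norm = NA_real_, end_norm = NA_real_,
                      status = cell$status)
    if (!is.null(cell$segmentation)) {
      out$frac <- as.numeric(cell$fractions[PHASE_LEVELS])
      segs <- cell$segmentation$segments
      m <- match(PHASE_LEVELS, segs$label)
      out$start_norm <- segs$t_start[m]
      out$end_norm <- segs$t_end[m]
    }
    out
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab
}

#' @export
print.phase_sweep <- function(x, ...) {
  ok <- vapply(x$cells, function(c) identical(c$status, "ok"), TRUE)
  cat(sprintf("Phase sweep over %s: %d values in [%g, %g], %d solved\n",
              x$name, length(x$values), min(x$values), max(x$values),
              sum(ok)))
  wide <- do.call(rbind, lapply(x$cells, function(c)
    if (is.null(c$fractions)) rep(NA_real_, 4) else
      c$fractions[PHASE_LEVELS]))
  colnames(wide) <- abbreviate(PHASE_LEVELS, 6)
  print(round(data.frame(value = signif(x$values, 4), wide), 3),
        row.names = FALSE)
  invisible(x)
}

#' Stacked phase-fraction plot of a sweep
#'
#' Normalized-age composition of the lifespan (like a stacked area chart)
#' as a function of the swept parameter.
#'
#' @param x A `phase_sweep`.
#' @param ... Unused.
#' @export
plot.phase_sweep <- function(x, ...) {
  ok <- vapply(x$cells, function(c) identical(c$status, "ok"), TRUE)
  vals <- x$values[ok]
  segs <- lapply(x$cells[ok], `[[`, "segmentation")
  shades <- c(establishment = "#1f4e9c", accumulation = "#7fb2e5",
              maintenance = "#f2a44b", exploitation = "#d43d33")
  logx <- x$name %in% c("k_L", "m_L")
  graphics::plot(NA, xlim = range(vals), ylim = c(0, 1),
                 log = if (logx) "x" else "",
                 xlab = x$name, ylab = "normalized age")
  wid <- diff(range(vals)) / (2.5 * length(vals))
  for (i in seq_along(vals)) {
    s <- segs[[i]]$segments
    w <- if (logx) vals[i] * 0.12 else wid
    for (k in seq_len(nrow(s)))
      graphics::rect(vals[i] - w, s$t_start[k], vals[i] + w, s$t_end[k],
                     col = shades[[s$label[k]]], border = NA)
  }
  graphics::legend("topright", names(shades), fill = shades, cex = 0.7,
                   bg = "white")
  invisible(x)
}
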