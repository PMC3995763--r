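# Segmentation of a solved trajectory into the four knowledge phases:
#   establishment - all-in exploration (u at the ceiling, energy above floor)
#   accumulation  - learning while pinned at the survival floor
#   maintenance   - interior investment holding knowledge constant
#   exploitation  - zero investment, harvesting accumulated knowledge

PHASE_LEVELS <- c("establishment", "accumulation", "maintenance",
                  "exploitation")

#' Classify a solved trajectory into knowledge phases
#'
#' Labels every mesh point by the first matching rule:
#' \enumerate{
#'   \item `u >= ceiling - eps_u` and `E > E_min + eps_E`: establishment;
#'   \item `E <= E_min + eps_E`: accumulation (the survival floor is
#'     active and learning is throttled to what intake allows);
#'   \item `u <= eps_u`: exploitation;
#'   \item interior investment off the floor with
#'     `|dL/dt| = |alpha*u - m_L*L| <= eps_L`: maintenance.
#' }
#' Establishment is an opening phase and exploitation a closing one, so
#' rule 1 is restricted to the initial run of at-ceiling points and rule
#' 3 to the terminal run of below-threshold points: an isolated
#' one-cell dip of a tiny singular control below `eps_u` mid-life is
#' classifier noise, not a bout of exploitation.
#' Interior points whose knowledge rate is far from zero
#' (`|dL/dt| > eps_L`) are arc-junction transients: the transcription
#' smooths control discontinuities over a few mesh intervals, so such
#' points belong to no phase of their own and are absorbed into the
#' phase they are exiting (the preceding segment; the following one at
#' the start of the trajectory).  `dL/dt` is evaluated from the rate
#' law, not by numerical differencing, to avoid grid noise.  Runs
#' shorter than `min_duration` are then merged into the following run.
#' Rule 1 precedes rule 2 so that the instant at which the energy first
#' touches the floor while `u` is still at the ceiling counts as
#' establishment.
#'
#' If, after artifact merging, the label sequence still violates the
#' canonical order (establishment, accumulation, maintenance,
#' exploitation as a subsequence, no repeats), offending runs are merged
#' into their larger neighbour and counted in `n_forced_merges`; a clean
#' classification has `n_forced_merges == 0`.
#'
#' @param sol A `life_ocp` fit, or a data.frame with columns
#'   `time`, `E`, `L`, `u` (then `params` and `bc` must be given).
#' @param params,bc Model parameters and boundary constraints (defaulted
#'   from the fit).
#' @param eps_u Control tolerance; default `0.01 * ceiling`.
#' @param eps_E Energy-floor tolerance; default `0.02 * (E0 - E_min)`.
#' @param eps_L Knowledge-rate tolerance separating the singular
#'   (maintenance) arc from junction transients; default
#'   `0.1 * max(L) / T_max`, an order of magnitude above the knowledge-
#'   rate wobble that converged collocation solutions exhibit along
#'   singular arcs, and an order of magnitude below the knowledge rates
#'   seen inside junction transients.
#' @param min_duration Minimal segment duration; default `T_max / 100`.
#' @param feas_tol Feasibility tolerance; classification refuses
#'   trajectories violating the constraints by more than this.
#' @return An object of class `phase_segmentation`: a list with
#'   `segments` (data.frame `label`, `t_start`, `t_end`), `fractions`,
#'   `tolerances`, and `n_forced_merges`.
#' @export
#' @examples
#' \donttest{
#' fit <- optimal_strategy(options = reduced_options())
#' classify_phases(fit)
#' }
classify_phases <- function(sol, params = NULL, bc = NULL,
                            eps_u = NULL, eps_E = NULL, eps_L = NULL,
                            min_duration = NULL, feas_tol = 1e-4) {
  if (inherits(sol, "life_ocp")) {
    if (is.null(params)) params <- sol$params
    if (is.null(bc)) bc <- sol$bc
    traj <- data.frame(time = sol$times, E = sol$E, L = sol$L, u = sol$u)
  } else {
    traj <- as.data.frame(sol)
    if (is.null(params) || is.null(bc))
      stop("params and bc are required when sol is a plain trajectory")
  }
  params <- as_model_params(params)
  bc <- as_boundary_constraints(bc)
  if (nrow(traj) == 0L) stop("empty solution")
  rep <- check_feasibility(traj, NULL, bc, params, tol = feas_tol)
  if (!is_feasible(rep))
    stop("cannot classify an infeasible trajectory (",
         nrow(rep), " violations at tol ", feas_tol, ")")

  T_max <- params$T_max
  ceiling_u <- control_ceiling(bc, params)
  if (is.null(eps_u)) eps_u <- 0.01 * ceiling_u
  if (is.null(eps_E)) eps_E <- 0.02 * (bc$E0 - bc$E_min)
  if (is.null(eps_L)) eps_L <- 0.1 * max(traj$L, 1e-12) / T_max
  if (is.null(min_duration)) min_duration <- T_max / 100

  tt <- traj$time; E <- traj$E; L <- traj$L
  u <- pmax(traj$u, 0)
  np <- length(tt)
  dLdt <- params$alpha * u - params$m_L * L

  lab <- rep(NA_integer_, np)
  r1 <- u >= ceiling_u - eps_u & E > bc$E_min + eps_E
  if (r1[1]) {
    k <- which(!r1)[1]
    k <- if (is.na(k)) np else k - 1L
    lab[1:k] <- 1L
  }
  lab[is.na(lab) & E <= bc$E_min + eps_E] <- 2L
  r4 <- u <= eps_u
  if (r4[np]) {
    j <- rev(which(!r4))[1]
    j <- if (is.na(j)) 1L else j + 1L
    lab[j:np][is.na(lab[j:np])] <- 4L
  }
  trans <- is.na(lab) & abs(dLdt) > eps_L
  lab[is.na(lab) & !trans] <- 3L

  # junction transients inherit the label of the phase they exit
  if (any(trans)) {
    if (all(trans)) {
      lab[] <- 3L                      # wholly interior: call it maintenance
    } else {
      r <- rle(trans)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        src <- if (starts[k] > 1L) lab[starts[k] - 1L] else lab[ends[k] + 1L]
        lab[starts[k]:ends[k]] <- src
      }
    }
  }

  # each grid point owns the cell between the midpoints to its neighbours
  cell_l <- c(tt[1], (tt[-np] + tt[-1]) / 2)
  cell_r <- c((tt[-np] + tt[-1]) / 2, tt[np])
  cell_w <- cell_r - cell_l

  run_table <- function(lab) {
    r <- rle(lab)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    data.frame(label = r$values, i0 = starts, i1 = ends,
               dur = vapply(seq_along(starts), function(k)
                 sum(cell_w[starts[k]:ends[k]]), 0))
  }

  # merge runs shorter than the minimum duration into the following run
  repeat {
    runs <- run_table(lab)
    if (nrow(runs) <= 1L) break
    short <- which(runs$dur < min_duration)
    if (!length(short)) break
    k <- short[1]
    into <- if (k < nrow(runs)) k + 1L else k - 1L
    lab[runs$i0[k]:runs$i1[k]] <- runs$label[into]
  }

  # enforce the canonical subsequence order; forced merges are counted
  n_forced <- 0L
  repeat {
    runs <- run_table(lab)
    if (nrow(runs) <= 1L) break
    bad <- which(diff(runs$label) <= 0L)
    if (!length(bad)) break
    k <- bad[1]
    # merge the shorter member of the offending pair into the longer
    if (runs$dur[k] < runs$dur[k + 1L]) {
      lab[runs$i0[k]:runs$i1[k]] <- runs$label[k + 1L]
    } else {
      lab[runs$i0[k + 1L]:runs$i1[k + 1L]] <- runs$label[k]
    }
    n_forced <- n_forced + 1L
  }

  runs <- run_table(lab)
  segments <- data.frame(
    label = PHASE_LEVELS[runs$label],
    t_start = cell_l[runs$i0],
    t_end = cell_r[runs$i1])
  segments$t_start[1] <- tt[1]
  segments$t_end[nrow(segments)] <- tt[np]

  maint <- lab == 3L
  seg <- structure(
    list(segments = segments,
         tolerances = list(eps_u = eps_u, eps_E = eps_E, eps_L = eps_L,
                           min_duration = min_duration),
         n_forced_merges = n_forced,
         maintenance_dLdt = if (any(maint))
           c(mean = mean(abs(dLdt[maint])), max = max(abs(dLdt[maint])))
         else c(mean = NA_real_, max = NA_real_),
         T_max = T_max),
    class = "phase_segmentation")
  seg$fractions <- phase_fractions(seg, T_max)
  seg
}

#' Phase durations as fractions of the lifespan
#'
#' @param seg A `phase_segmentation` from [classify_phases()].
#' @param T_max Lifespan used for normalization (defaulted from `seg`).
#' @return A named numeric vector over all four phase labels (absent
#'   phases get 0); sums to 1.
#' @export
phase_fractions <- function(seg, T_max = seg$T_max) {
  fr <- stats::setNames(numeric(4), PHASE_LEVELS)
  dur <- seg$segments$t_end - seg$segments$t_start
  for (i in seq_len(nrow(seg$segments)))
    fr[seg$segments$label[i]] <- fr[seg$segments$label[i]] + dur[i]
  fr / T_max
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat("Knowledge-phase segmentation (", nrow(x$segments), " phases):\n",
      sep = "")
  for (i in seq_len(nrow(x$segments)))
    cat(sprintf("  %-13s [%8.4f, %8.4f]  fraction %.3f\n",
                x$segments$label[i], x$segments$t_start[i],
                x$segments$t_end[i],
                (x$segments$t_end[i] - x$segments$t_start[i]) / x$T_max))
  if (x$n_forced_merges > 0)
    cat("  note:", x$n_forced_merges,
        "out-of-order run(s) were forcibly merged\n")
  invisible(x)
}
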