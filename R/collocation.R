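# Direct Hermite-Simpson collocation transcription of the terminal-energy
# maximization problem, solved as a bound-constrained NLP by an augmented
# Lagrangian (equality defects) with L-BFGS-B inner iterations.
#
# Decision vector z = (E_1..E_{N+1}, L_1..L_{N+1}, u_1..u_{N+1}, um_1..um_N)
# on a uniform mesh with N intervals. The survival floor E >= E_min and the
# control bounds are simple box constraints on z; the dynamics enter as 2N
# Hermite-Simpson defect equalities. Both rate laws are independent of E,
# which keeps the compressed-midpoint form and its analytic gradient simple.

hs_index <- function(n) {
  n1 <- n + 1L
  list(E = 1:n1, L = n1 + 1:n1, u = 2L * n1 + 1:n1,
       um = 3L * n1 + 1:n, len = 3L * n1 + n)
}

hs_unpack <- function(z, n) {
  ix <- hs_index(n)
  list(E = z[ix$E], L = z[ix$L], u = z[ix$u], um = z[ix$um])
}

# Hermite-Simpson defect residuals; 2N-vector (energy defects, then
# knowledge defects).
hs_defects <- function(z, n, h, p) {
  s <- hs_unpack(z, n)
  l <- 1:n; r <- 2:(n + 1L)
  fE <- p$f_max * s$L / (s$L + p$k_L) - p$m - s$u
  fL <- p$alpha * s$u - p$m_L * s$L
  Lm <- (s$L[l] + s$L[r]) / 2 + (h / 8) * (fL[l] - fL[r])
  fEm <- p$f_max * Lm / (Lm + p$k_L) - p$m - s$um
  fLm <- p$alpha * s$um - p$m_L * Lm
  cE <- s$E[r] - s$E[l] - (h / 6) * (fE[l] + 4 * fEm + fE[r])
  cL <- s$L[r] - s$L[l] - (h / 6) * (fL[l] + 4 * fLm + fL[r])
  c(cE, cL)
}

# Midpoint (collocation-point) energies: the survival floor must hold at
# the Hermite midpoints too, or the interpolating polynomial dips below
# E_min between nodes and the NLP harvests spurious objective from it.
hs_midpoint_E <- function(z, n, h, p) {
  s <- hs_unpack(z, n)
  l <- 1:n; r <- 2:(n + 1L)
  fE <- p$f_max * s$L / (s$L + p$k_L) - p$m - s$u
  (s$E[l] + s$E[r]) / 2 + (h / 8) * (fE[l] - fE[r])
}

# Augmented Lagrangian value and gradient. Minimizes -E_end, so the
# reported objective is max terminal energy. Equality defects carry
# multipliers lambda; the midpoint floor inequalities E_min - Em <= 0 carry
# multipliers mu (Rockafellar form). All problem data travel in a single
# `ctx` list to keep optim()'s dots clean.
hs_al_value <- function(z, ctx) {
  n <- ctx$n; rho <- ctx$rho
  cc <- hs_defects(z, n, ctx$h, ctx$p)
  g <- ctx$p_bc$E_min - hs_midpoint_E(z, n, ctx$h, ctx$p)
  t_in <- pmax(0, ctx$mu + rho * g)
  val <- -z[hs_index(n)$E[n + 1L]] + sum(ctx$lambda * cc) +
    (rho / 2) * sum(cc * cc) +
    sum(t_in^2 - ctx$mu^2) / (2 * rho)
  if (ctx$eps > 0) {
    # H1 smoothing of the control, removed by continuation (eps -> 0).
    # The Hamiltonian is linear in u, so near the singular (maintenance)
    # arc the exact problem is second-order flat in broad control
    # directions; the vanishing penalty steers the iterates to the centre
    # of that valley without biasing the final answer.
    s <- hs_unpack(z, n); l <- 1:n; r <- 2:(n + 1L)
    val <- val + ctx$eps *
      sum(ctx$h * ((s$u[l] - s$um)^2 + (s$um - s$u[r])^2))
  }
  val
}

hs_al_grad <- function(z, ctx) {
  n <- ctx$n; h <- ctx$h; p <- ctx$p; lambda <- ctx$lambda; rho <- ctx$rho
  ix <- hs_index(n)
  s <- hs_unpack(z, n)
  n1 <- n + 1L
  l <- 1:n; r <- 2:n1

  fL <- p$alpha * s$u - p$m_L * s$L
  Lm <- (s$L[l] + s$L[r]) / 2 + (h / 8) * (fL[l] - fL[r])
  fE <- p$f_max * s$L / (s$L + p$k_L) - p$m - s$u
  fEm <- p$f_max * Lm / (Lm + p$k_L) - p$m - s$um
  fLm <- p$alpha * s$um - p$m_L * Lm
  cE <- s$E[r] - s$E[l] - (h / 6) * (fE[l] + 4 * fEm + fE[r])
  cL <- s$L[r] - s$L[l] - (h / 6) * (fL[l] + 4 * fLm + fL[r])
  vE <- lambda[1:n] + rho * cE
  vL <- lambda[n + 1:n] + rho * cL

  a  <- p$f_max * p$k_L / (s$L + p$k_L)^2   # d(intake)/dL at nodes
  am <- p$f_max * p$k_L / (Lm + p$k_L)^2    # ... at midpoints
  pL_l <- 0.5 - h * p$m_L / 8               # dLm/dL_left
  pL_r <- 0.5 + h * p$m_L / 8               # dLm/dL_right
  pu   <- h * p$alpha / 8                   # dLm/du_left (= -dLm/du_right)

  gE <- numeric(n1); gL <- numeric(n1); gu <- numeric(n1)
  gE[l] <- gE[l] - vE
  gE[r] <- gE[r] + vE

  dcE_Ll <- -(h / 6) * (a[l] + 4 * am * pL_l)
  dcE_Lr <- -(h / 6) * (a[r] + 4 * am * pL_r)
  dcL_Ll <- -1 + (h * p$m_L / 6) * (1 + 4 * pL_l)
  dcL_Lr <-  1 + (h * p$m_L / 6) * (1 + 4 * pL_r)
  gL[l] <- gL[l] + vE * dcE_Ll + vL * dcL_Ll
  gL[r] <- gL[r] + vE * dcE_Lr + vL * dcL_Lr

  dcE_ul <- (h / 6) * (1 - 4 * am * pu)
  dcE_ur <- (h / 6) * (1 + 4 * am * pu)
  dcL_ul <- -(h * p$alpha / 6) * (1 - h * p$m_L / 2)
  dcL_ur <- -(h * p$alpha / 6) * (1 + h * p$m_L / 2)
  gu[l] <- gu[l] + vE * dcE_ul + vL * dcL_ul
  gu[r] <- gu[r] + vE * dcE_ur + vL * dcL_ur

  gum <- vE * (2 * h / 3) - vL * (2 * h * p$alpha / 3)

  # midpoint floor terms: w_i = max(0, mu_i + rho * (E_min - Em_i))
  Em <- (s$E[l] + s$E[r]) / 2 + (h / 8) * (fE[l] - fE[r])
  w <- pmax(0, ctx$mu + rho * (ctx$p_bc$E_min - Em))
  if (any(w > 0)) {
    gE[l] <- gE[l] - w / 2
    gE[r] <- gE[r] - w / 2
    gL[l] <- gL[l] - w * (h / 8) * a[l]
    gL[r] <- gL[r] + w * (h / 8) * a[r]
    gu[l] <- gu[l] + w * (h / 8)
    gu[r] <- gu[r] - w * (h / 8)
  }

  if (ctx$eps > 0) {
    du1 <- s$u[l] - s$um; du2 <- s$um - s$u[r]
    gu[l] <- gu[l] + 2 * ctx$eps * h * du1
    gu[r] <- gu[r] - 2 * ctx$eps * h * du2
    gum <- gum + 2 * ctx$eps * h * (du2 - du1)
  }

  g <- numeric(ix$len)
  g[ix$E] <- gE; g[ix$L] <- gL; g[ix$u] <- gu; g[ix$um] <- gum
  g[ix$E[n1]] <- g[ix$E[n1]] - 1
  g
}

hs_bounds <- function(n, p, bc) {
  n1 <- n + 1L
  ceiling_u <- control_ceiling(bc, p)
  lower <- c(rep(bc$E_min, n1), rep(bc$L_min, n1),
             rep(bc$u_min, n1), rep(bc$u_min, n))
  upper <- c(rep(Inf, n1), rep(Inf, n1),
             rep(ceiling_u, n1), rep(ceiling_u, n))
  ix <- hs_index(n)
  lower[ix$E[1]] <- upper[ix$E[1]] <- bc$E0
  lower[ix$L[1]] <- upper[ix$L[1]] <- bc$L0
  list(lower = lower, upper = upper)
}

# Cheap fixed-step RK4 used only to turn a control guess into a state
# guess on the collocation mesh (4 substeps per interval).
hs_state_guess <- function(times, uvals, p, bc) {
  n <- length(times) - 1L
  E <- numeric(n + 1L); L <- numeric(n + 1L)
  E[1] <- bc$E0; L[1] <- bc$L0
  ufun <- stats::approxfun(times, uvals, rule = 2)
  for (i in 1:n) {
    h <- (times[i + 1L] - times[i]) / 4
    e <- E[i]; ll <- L[i]; tt <- times[i]
    for (k in 1:4) {
      rk <- function(t, st) {
        u <- ufun(t); Lc <- max(st[2], 0)
        c(p$f_max * Lc / (Lc + p$k_L) - p$m - u,
          p$alpha * u - p$m_L * Lc)
      }
      k1 <- rk(tt, c(e, ll))
      k2 <- rk(tt + h / 2, c(e, ll) + h / 2 * k1)
      k3 <- rk(tt + h / 2, c(e, ll) + h / 2 * k2)
      k4 <- rk(tt + h, c(e, ll) + h * k3)
      st <- c(e, ll) + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      e <- st[1]; ll <- st[2]; tt <- tt + h
    }
    E[i + 1L] <- e; L[i + 1L] <- ll
  }
  list(E = E, L = L)
}

# Build the initial decision vector from a control guess (values on the
# mesh nodes), clamped into the box.
hs_initial_z <- function(times, u_guess, n, p, bc) {
  ix <- hs_index(n)
  ceiling_u <- control_ceiling(bc, p)
  u_guess <- pmin(pmax(u_guess, bc$u_min), ceiling_u)
  st <- hs_state_guess(times, u_guess, p, bc)
  z <- numeric(ix$len)
  z[ix$E] <- pmax(st$E, bc$E_min)
  z[ix$L] <- pmax(st$L, bc$L_min)
  z[ix$u] <- u_guess
  z[ix$um] <- (u_guess[1:n] + u_guess[2:(n + 1L)]) / 2
  z[ix$E[1]] <- bc$E0; z[ix$L[1]] <- bc$L0
  z
}

# Augmented-Lagrangian outer loop around L-BFGS-B, wrapped in a
# regularization continuation: each entry of eps_schedule is an H1
# control-smoothing weight, solved to defect tolerance before moving to
# the next (smaller) one, ending at eps = 0 (the unregularized problem).
# Multipliers and the penalty parameter are carried across the schedule.
hs_solve_nlp <- function(z0, n, h, p, bc, tol = 1e-8, max_outer = 40L,
                         inner_maxit = 5000L, factr = 1e3, rho0 = 10,
                         eps_schedule = c(1e-2, 1e-4, 0), lmm = 20L) {
  bounds <- hs_bounds(n, p, bc)
  lambda <- numeric(2L * n)
  mu <- numeric(n)
  rho <- rho0
  z <- z0
  status <- "max_iterations"
  outers_total <- 0L
  if (length(h) == 1L) h <- rep(h, n)
  for (eps in eps_schedule) {
    cmax_prev <- Inf
    for (outer in seq_len(max_outer)) {
      outers_total <- outers_total + 1L
      ctx <- list(n = n, h = h, p = p, p_bc = bc,
                  lambda = lambda, mu = mu, rho = rho, eps = eps)
      res <- stats::optim(z, fn = hs_al_value, gr = hs_al_grad, ctx = ctx,
                          method = "L-BFGS-B",
                          lower = bounds$lower, upper = bounds$upper,
                          control = list(maxit = inner_maxit, factr = factr,
                                         pgtol = 1e-10, lmm = lmm))
      z <- res$par
      cc <- hs_defects(z, n, h, p)
      g <- bc$E_min - hs_midpoint_E(z, n, h, p)
      cmax <- max(max(abs(cc)), max(g, 0))
      lambda <- lambda + rho * cc
      mu <- pmax(0, mu + rho * g)
      if (cmax < tol) break
      if (cmax > 0.3 * cmax_prev) rho <- min(rho * 10, 1e9)
      cmax_prev <- cmax
    }
  }
  cc <- hs_defects(z, n, h, p)
  g <- bc$E_min - hs_midpoint_E(z, n, h, p)
  vfin <- max(max(abs(cc)), max(g, 0))
  if (vfin < 10 * tol) status <- "converged"
  s <- hs_unpack(z, n)
  list(z = z, E = s$E, L = s$L, u = s$u, um = s$um,
       objective = s$E[n + 1L], max_defect = vfin,
       lambda = lambda, mu = mu, rho = rho, status = status,
       outer_iters = outers_total)
}
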