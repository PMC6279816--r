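#' Simulation configuration
#'
#' @param dt Sampling/integration step, s, positive.
#' @param n_steps Number of steps; the trajectory has `n_steps + 1` samples.
#' @param n_runs Ensemble size.
#' @param seed Integer master seed.  Each run uses its own stream seeded by
#'   `(seed + 1000003 * run) mod (2^31 - 1)`, so ensembles are reproducible
#'   and order-independent.
#' @param init One of `"rest"` (start at the origin with zero velocity and
#'   zero angular velocity, orientation along x: the start-up experiment),
#'   `"stationary"` (draw the initial angular velocity from its stationary
#'   Gaussian, the angle uniformly, then discard a burn-in before
#'   recording), or `"explicit"` (use `init_state`).
#' @param init_state For `init = "explicit"`: a list with entries `x`, `y`,
#'   `vx`, `vy`, `phi`, `phi_dot`.
#' @param burn_in Burn-in time, s, for `init = "stationary"`.  Default
#'   `10 * max(tau, tau_r, 1/D_r)`, chosen at simulation time.
#' @param dt_policy What to do when `dt` exceeds a tenth of the fastest
#'   model time scale: `"warn"` (default), `"error"`, or `"none"`.  The
#'   rotational update is an exact Gaussian transition at any `dt`; the
#'   policy guards the O(dt^2) orientation-freezing error of the
#'   translational update.
#' @return A list of class `"abp_sim_config"`.
#' @export
sim_config <- function(dt, n_steps, n_runs = 1L, seed = 1L,
                       init = c("rest", "stationary", "explicit"),
                       init_state = NULL, burn_in = NULL,
                       dt_policy = c("warn", "error", "none")) {
  init <- match.arg(init)
  dt_policy <- match.arg(dt_policy)
  stopifnot(is.numeric(dt), length(dt) == 1L, dt > 0,
            n_steps >= 1L, n_runs >= 1L)
  if (init == "explicit") {
    need <- c("x", "y", "vx", "vy", "phi", "phi_dot")
    if (is.null(init_state) || !all(need %in% names(init_state)))
      stop("init = 'explicit' requires init_state with fields ",
           paste(need, collapse = ", "), call. = FALSE)
  }
  structure(list(dt = dt, n_steps = as.integer(n_steps),
                 n_runs = as.integer(n_runs), seed = as.integer(seed),
                 init = init, init_state = init_state, burn_in = burn_in,
                 dt_policy = dt_policy),
            class = "abp_sim_config")
}

# Exact conditional Gaussian moments of the (position-like, velocity-like)
# pair of an Ornstein-Uhlenbeck velocity process with relaxation time tau
# and diffusion coefficient Dc over a step h:
#   Var(v)   = (Dc/tau) (1 - beta^2),           beta = e^{-h/tau}
#   Cov(x,v) = Dc (1 - beta)^2
#   Var(x)   = 2 Dc (h - 2 tau (1 - beta) + tau (1 - beta^2) / 2)
ou_moments <- function(tau, Dc, h) {
  beta <- exp(-h / tau)
  vv <- Dc / tau * (1 - beta^2)
  xv <- Dc * (1 - beta)^2
  xx <- 2 * Dc * (h - 2 * tau * (1 - beta) + tau * (1 - beta^2) / 2)
  list(beta = beta, var_v = vv, cov_xv = xv, var_x = xx)
}

# Cholesky factors mapping two iid standard normals (z_x, z_v) to the
# correlated (position increment, velocity) noise pair.
ou_chol <- function(m) {
  sx <- sqrt(max(m$var_x, 0))
  c1 <- if (sx > 0) m$cov_xv / sx else 0
  c2 <- sqrt(max(m$var_v - c1^2, 0))
  list(sx = sx, c1 = c1, c2 = c2)
}

#' Single exact step of the rotational degrees of freedom
#'
#' Advances \eqn{(\phi, \dot\phi)} by the exact conditional Gaussian
#' transition of the inertial rotational Ornstein-Uhlenbeck process over a
#' step `dt`, including the cross-covariance between the angle increment
#' and the new angular velocity.  With `noise = c(0, 0)` the deterministic
#' conditional mean is returned.
#'
#' @param phi,phi_dot Current angle (rad) and angular velocity (rad/s).
#' @param p An [abp_params()] object.
#' @param dt Step, s.
#' @param noise Two standard normal draws.
#' @return Named numeric vector `c(phi = , phi_dot = )`.
#' @export
step_rotation <- function(phi, phi_dot, p, dt, noise = stats::rnorm(2)) {
  stopifnot(dt > 0, length(noise) == 2L)
  m <- ou_moments(p$tau_r, p$D_r, dt)
  ch <- ou_chol(m)
  phi_new <- phi + p$omega * dt +
    (phi_dot - p$omega) * p$tau_r * (1 - m$beta) +
    ch$sx * noise[1]
  phi_dot_new <- p$omega + (phi_dot - p$omega) * m$beta +
    ch$c1 * noise[1] + ch$c2 * noise[2]
  c(phi = phi_new, phi_dot = phi_dot_new)
}

#' Single step of the translational degrees of freedom
#'
#' Advances position and velocity by the exact integrated
#' Ornstein-Uhlenbeck transition with the propulsion direction `n_hat`
#' frozen over the step (splitting error O(dt^2)): the velocity relaxes
#' toward \eqn{V_p n} at rate \eqn{1/\tau} with stationary per-component
#' variance \eqn{D/\tau}, and the position advances consistently including
#' the position-velocity noise covariance.
#'
#' @param pos,vel Numeric length-2 position (m) and velocity (m/s).
#' @param n_hat Unit orientation vector for the step.
#' @param p An [abp_params()] object.
#' @param dt Step, s.
#' @param noise Four standard normal draws (x-pair then y-pair).
#' @return List with `pos` and `vel`.
#' @export
step_translation <- function(pos, vel, n_hat, p, dt,
                             noise = stats::rnorm(4)) {
  stopifnot(dt > 0, length(noise) == 4L)
  m <- ou_moments(p$tau, p$D, dt)
  ch <- ou_chol(m)
  vp <- p$v_p * n_hat
  zx <- noise[c(1, 3)]; zv <- noise[c(2, 4)]
  pos_new <- pos + vp * dt + (vel - vp) * p$tau * (1 - m$beta) +
    ch$sx * zx
  vel_new <- vp + (vel - vp) * m$beta + ch$c1 * zx + ch$c2 * zv
  list(pos = pos_new, vel = vel_new)
}

run_seed <- function(seed, run) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(run)) %% 2147483647)
}

#' Simulate trajectories of the underdamped active Brownian particle
#'
#' Generates sample paths of the coupled inertial Langevin equations.  The
#' rotational pair \eqn{(\phi, \dot\phi)} uses its exact conditional
#' Gaussian transition at every step; the translational pair uses the exact
#' integrated Ornstein-Uhlenbeck transition with the orientation frozen at
#' the step start, so the only discretisation error is the O(dt^2)
#' orientation-freezing splitting error.  Identical `(p, cfg)` give
#' bitwise-identical output.
#'
#' @param p An [abp_params()] object.
#' @param cfg A [sim_config()] object.
#' @param run Run index (determines the random stream).
#' @return `simulate_abp`: a data frame of class `"abp_trajectory"` with
#'   columns `t`, `x`, `y`, `vx`, `vy`, `phi`, `phi_dot` (`n_steps + 1`
#'   rows, uniform times) and attributes `params`, `dt`, `run`.
#'   `simulate_ensemble`: a list of trajectories of class `"abp_ensemble"`.
#' @export
#' @examples
#' p <- abp_preset("fig2")
#' cfg <- sim_config(dt = 0.005, n_steps = 200, seed = 42)
#' tr <- simulate_abp(p, cfg)
#' head(tr)
simulate_abp <- function(p, cfg, run = 1L) {
  stopifnot(inherits(p, "abp_params"), inherits(cfg, "abp_sim_config"))
  check_dt(p, cfg)
  set.seed(run_seed(cfg$seed, run))
  n <- cfg$n_steps
  dt <- cfg$dt

  # initial state
  st <- switch(cfg$init,
    rest = list(x = 0, y = 0, vx = 0, vy = 0, phi = 0, phi_dot = 0),
    explicit = cfg$init_state,
    stationary = {
      phi0 <- stats::runif(1, 0, 2 * pi)
      pd0 <- if (p$D_r > 0)
        stats::rnorm(1, p$omega, sqrt(p$D_r / p$tau_r)) else p$omega
      list(x = 0, y = 0, vx = p$v_p * cos(phi0), vy = p$v_p * sin(phi0),
           phi = phi0, phi_dot = pd0)
    })

  n_burn <- 0L
  if (cfg$init == "stationary") {
    tb <- if (!is.null(cfg$burn_in)) cfg$burn_in else
      10 * max(p$tau, p$tau_r, if (p$D_r > 0) 1 / p$D_r else 0)
    n_burn <- as.integer(ceiling(tb / dt))
  }
  ntot <- n + n_burn

  mr <- ou_moments(p$tau_r, p$D_r, dt); chr <- ou_chol(mr)
  mt <- ou_moments(p$tau, p$D, dt);     cht <- ou_chol(mt)

  # rotational path: angular velocity is AR(1); angle is a cumulative sum
  z1 <- stats::rnorm(ntot); z2 <- stats::rnorm(ntot)
  eta_phi <- chr$sx * z1
  eta_pd <- chr$c1 * z1 + chr$c2 * z2
  pd_dev <- as.numeric(stats::filter(eta_pd, mr$beta, method = "recursive",
                                     init = st$phi_dot - p$omega))
  pd <- c(st$phi_dot, p$omega + pd_dev)              # length ntot + 1
  dphi <- p$omega * dt + (pd[seq_len(ntot)] - p$omega) *
    p$tau_r * (1 - mr$beta) + eta_phi
  phi <- c(st$phi, st$phi + cumsum(dphi))

  # translational path: exact OU per component, orientation frozen at the
  # start of each step
  nx <- cos(phi[seq_len(ntot)]); ny <- sin(phi[seq_len(ntot)])
  zx1 <- stats::rnorm(ntot); zx2 <- stats::rnorm(ntot)
  zy1 <- stats::rnorm(ntot); zy2 <- stats::rnorm(ntot)
  adv <- function(v0, nvec, z1, z2) {
    eta_x <- cht$sx * z1
    eta_v <- cht$c1 * z1 + cht$c2 * z2
    drive <- p$v_p * nvec * (1 - mt$beta) + eta_v
    v <- c(v0, as.numeric(stats::filter(drive, mt$beta,
                                        method = "recursive", init = v0)))
    dxs <- p$v_p * nvec * dt +
      (v[seq_len(ntot)] - p$v_p * nvec) * p$tau * (1 - mt$beta) + eta_x
    list(v = v, x = cumsum(dxs))
  }
  ax <- adv(st$vx, nx, zx1, zx2)
  ay <- adv(st$vy, ny, zy1, zy2)
  x <- c(st$x, st$x + ax$x)
  y <- c(st$y, st$y + ay$x)

  keep <- (n_burn + 1L):(ntot + 1L)
  # recording starts at the origin after any burn-in
  x0 <- if (n_burn > 0L) x[keep[1L]] - st$x else 0
  y0 <- if (n_burn > 0L) y[keep[1L]] - st$y else 0
  out <- data.frame(t = (seq_along(keep) - 1L) * dt,
                    x = x[keep] - x0,
                    y = y[keep] - y0,
                    vx = ax$v[keep], vy = ay$v[keep],
                    phi = phi[keep], phi_dot = pd[keep])
  structure(out, params = p, dt = dt, run = run,
            class = c("abp_trajectory", "data.frame"))
}

#' @rdname simulate_abp
#' @export
simulate_ensemble <- function(p, cfg) {
  runs <- lapply(seq_len(cfg$n_runs), function(r) simulate_abp(p, cfg, r))
  structure(runs, params = p, dt = cfg$dt, class = "abp_ensemble")
}

check_dt <- function(p, cfg) {
  if (cfg$dt_policy == "none") return(invisible())
  scales <- c(p$tau, p$tau_r)
  if (p$D_r > 0) scales <- c(scales, 1 / p$D_r)
  if (p$omega != 0) scales <- c(scales, 1 / abs(p$omega))
  lim <- 0.1 * min(scales)
  if (cfg$dt > lim) {
    msg <- sprintf(
      "dt = %g exceeds 0.1 * fastest time scale (%g); the orientation-freezing error may be visible",
      cfg$dt, lim)
    if (cfg$dt_policy == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  invisible()
}

#' @export
print.abp_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("abp_trajectory: %d samples, dt = %g s, run %s\n",
              nrow(x), attr(x, "dt"), attr(x, "run")))
  NextMethod()
}

#' @export
print.abp_ensemble <- function(x, ...) {
  cat(sprintf("abp_ensemble: %d runs x %d samples, dt = %g s\n",
              length(x), nrow(x[[1]]), attr(x, "dt")))
  invisible(x)
}
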