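test_that("orientation correlation has the right limits", {
  p <- fig2_params()
  expect_equal(orientation_correlation(p, 0), 1)
  # D_r = 0: pure circling
  p0 <- abp_params(tau = 0.2, tau_r = 0.1, D = 1e-4, D_r = 0, v_p = 0.1,
                   omega = 1.3)
  tt <- seq(0, 3, by = 0.1)
  expect_equal(orientation_correlation(p0, tt), cos(1.3 * tt))
  # tau_r -> 0: overdamped exponential decay
  po <- abp_params(tau = 0.2, tau_r = 1e-9, D = 1e-4, D_r = 2, v_p = 0.1,
                   omega = 0.5)
  expect_equal(orientation_correlation(po, tt), cos(0.5 * tt) *
                 exp(-2 * tt), tolerance = 1e-6)
})

test_that("two-time orientation correlation reduces correctly", {
  p <- fig2_params()
  tt <- c(0, 0.05, 0.4, 2)
  # equal times: exactly 1 (unit orientation vector)
  expect_equal(orientation_correlation_cond(p, tt, tt, 1.2), rep(1, 4))
  # overdamped limit with phi_dot0 = omega: stationary form of the lag
  po <- abp_params(tau = 0.2, tau_r = 1e-10, D = 1e-4, D_r = 2, v_p = 0.1,
                   omega = 0.5)
  expect_equal(orientation_correlation_cond(po, 1 + tt, 1, po$omega),
               exp(-2 * tt) * cos(0.5 * tt), tolerance = 1e-6)
  # late times: depends only on the lag and equals the stationary form
  t1 <- 30 + tt
  expect_equal(orientation_correlation_cond(p, t1, 30, p$omega),
               orientation_correlation(p, tt), tolerance = 1e-10)
})

test_that("kinetic factor f is bounded, has the correct limits, and matches quadrature", {
  p <- fig2_params()
  # independent oracle: f = (1/tau) Int_0^inf e^{-r/tau} C_n(r) dr
  f_quad <- stats::integrate(function(r)
    exp(-r / p$tau) * orientation_correlation(p, r) / p$tau,
    0, Inf, rel.tol = 1e-12)$value
  expect_equal(f_delay(delay_numbers(p)), f_quad, tolerance = 1e-10)

  expect_identical(f_delay(c(0.48, 0.13, 0)), 0)
  expect_equal(f_delay(c(0.48, 0.13, 1e4)), 1, tolerance = 1e-2)
  # bounded on a grid of admissible delay-number triples
  grid <- expand.grid(d0 = seq(0, 10, length.out = 11),
                      d1 = seq(-5, 5, length.out = 11),
                      d2 = seq(0, 10, length.out = 11))
  fs <- mapply(function(a, b, c) f_delay(c(a, b, c)),
               grid$d0, grid$d1, grid$d2)
  expect_true(all(fs >= -1e-12 & fs <= 1 + 1e-12))
})

test_that("velocity second moment reproduces the small- and large-J limits", {
  base <- list(D = 1e-4, D_r = 1, v_p = 0.1, omega = 0, tau = 1 / 6.5)
  v2 <- function(tau_r) velocity_second_moment(
    abp_params(tau = base$tau, tau_r = tau_r, D = base$D, D_r = base$D_r,
               v_p = base$v_p, omega = base$omega))
  # J -> 0: 2D/tau + V_p^2 / (1 + tau D_r)
  expect_rel(v2(1e-7),
             2 * base$D / base$tau + base$v_p^2 / (1 + base$tau * base$D_r),
             1e-2)
  # J -> infinity: sum of thermal and injected kinetic energies
  expect_rel(v2(1e5), 2 * base$D / base$tau + base$v_p^2, 1e-2)
  # V_p = 0: passive equilibrium
  p0 <- abp_params(tau = 0.2, tau_r = 0.1, D = 3e-4, D_r = 1, v_p = 0,
                   omega = 0)
  expect_equal(velocity_second_moment(p0), 2 * 3e-4 / 0.2)
  expect_equal(short_time_msd(p0, 0.01), 2 * 3e-4 / 0.2 * 1e-4)
})

test_that("persistence time has the overdamped and inertial asymptotics", {
  # J -> 0, omega = 0: 1/D_r and D_L = D + V_p^2/(2 D_r)
  p <- abp_params(tau = 0.1, tau_r = 1e-8, D = 1e-4, D_r = 1.7, v_p = 0.1,
                  omega = 0)
  expect_rel(persistence_time(p), 1 / 1.7, 1e-6)
  expect_rel(long_time_diffusion(p), 1e-4 + 0.1^2 / (2 * 1.7), 1e-4)
  # persistence equals the integral of the orientational correlation
  pf <- fig2_params()
  pt_quad <- stats::integrate(function(r) orientation_correlation(pf, r),
                              0, Inf, rel.tol = 1e-12)$value
  expect_equal(persistence_time(pf), pt_quad, tolerance = 1e-10)
  # D_r = 0, omega = 0: infinite persistence signalled, not an error
  pb <- abp_params(tau = 0.1, tau_r = 0.1, D = 1e-4, D_r = 0, v_p = 0.1,
                   omega = 0)
  expect_identical(persistence_time(pb), Inf)
  expect_identical(long_time_diffusion(pb), Inf)
  # noise-free circle swimmer: active contribution averages out
  pc <- abp_params(tau = 0.1, tau_r = 0.1, D = 1e-4, D_r = 0, v_p = 0.1,
                   omega = 2)
  expect_equal(long_time_diffusion(pc), 1e-4)
})

test_that("long-time diffusivity interpolates its small- and large-J asymptotics", {
  mk <- function(J) abp_params(tau = 1 / 6.5, tau_r = J / 1.5e-7 * (1 / 5.5),
                               D = 1e-4, D_r = 1, v_p = 0.1, omega = 0,
                               J = J, xi_r = 1.5e-7 * 5.5)
  # small J: linear form within 1%
  J_small <- 1e-10
  expect_rel(long_time_diffusion(mk(J_small)),
             dl_asymptotic_small_J(mk(J_small)), 1e-2)
  # slope in J at the origin: V_p^2 / (2 xi_r)
  eps <- 1e-11
  slope <- (long_time_diffusion(mk(eps)) - long_time_diffusion(mk(eps / 2))) /
    (eps / 2)
  expect_rel(slope, 0.1^2 / (2 * 1.5e-7 * 5.5), 0.05)
  # large J: sqrt(J) form within 1% once D0 ~ 1e4
  J_big <- 1e4 * 1.5e-7 * 5.5 / 1      # D0 = D_r tau_r = 1e4
  expect_rel(long_time_diffusion(mk(J_big)),
             dl_asymptotic_large_J(mk(J_big)), 1e-2)
  # monotonically increasing in J
  Js <- 10^seq(-9, -2, length.out = 15)
  dls <- vapply(Js, function(J) long_time_diffusion(mk(J)), numeric(1))
  expect_true(all(diff(dls) > 0))
  # missing absolute scales -> explicit error
  expect_error(dl_asymptotic_small_J(fig2_params()), "absolute scales")
})

test_that("stationary analytic MSD has ballistic and diffusive limits", {
  p <- fig2_params()
  v2 <- velocity_second_moment(p)
  ts <- c(2e-4, 1e-3)
  expect_equal(msd_analytic(p, ts) / (v2 * ts^2), c(1, 1),
               tolerance = 1e-3)
  tb <- c(400, 800)
  slope <- diff(msd_analytic(p, tb)) / diff(tb)
  expect_rel(slope / 4, long_time_diffusion(p), 1e-6)
  # overdamped limit reproduces the standard active-Brownian MSD
  po <- abp_params(tau = 1e-6, tau_r = 1e-6, D = 1e-4, D_r = 2, v_p = 0.1,
                   omega = 0)
  tt <- c(0.05, 0.2, 1, 4)
  abp_od <- 4 * po$D * tt +
    2 * po$v_p^2 / po$D_r^2 * (po$D_r * tt + exp(-po$D_r * tt) - 1)
  expect_equal(msd_analytic(po, tt), abp_od, tolerance = 1e-3)
})

test_that("conditional MSD reproduces its closed-form special cases", {
  # V_p = 0, start at rest: the passive inertial closed form
  pp <- abp_params(tau = 0.2, tau_r = 0.3, D = 2e-4, D_r = 1.3, v_p = 0,
                   omega = 0)
  tt <- c(0.05, 0.5, 3)
  closed <- 4 * pp$D * tt + 4 * pp$D * pp$tau *
    (exp(-tt / pp$tau) - 1 - 0.5 * (exp(-tt / pp$tau) - 1)^2)
  expect_equal(msd_conditional(pp, tt), closed, tolerance = 1e-10)
  # noise-free propulsion from rest: x(t) = V_p (t - tau (1 - e^{-t/tau}))
  p0 <- abp_params(tau = 0.2, tau_r = 0.3, D = 0, D_r = 0, v_p = 0.1,
                   omega = 0)
  expect_equal(msd_conditional(p0, tt),
               (p0$v_p * (tt - p0$tau * (1 - exp(-tt / p0$tau))))^2,
               tolerance = 1e-6)
  # full conditional MSD against a Monte-Carlo ensemble with the same
  # explicit initial condition (3 s.e. agreement)
  p <- fig2_params()
  init <- list(x = 0, y = 0, vx = 0.4 * p$v_p, vy = 0.2 * p$v_p,
               phi = 0, phi_dot = 2)
  cfg <- sim_config(dt = 0.004, n_steps = 500, n_runs = 400, seed = 77,
                    init = "explicit", init_state = init,
                    dt_policy = "none")
  ens <- simulate_ensemble(p, cfg)
  idx <- c(50L, 150L, 500L)
  sq <- vapply(ens, function(tr)
    tr$x[idx + 1L]^2 + tr$y[idx + 1L]^2, numeric(3))
  mc <- rowMeans(sq)
  se <- apply(sq, 1L, stats::sd) / sqrt(ncol(sq))
  an <- msd_conditional(p, idx * 0.004, v0 = c(init$vx, init$vy),
                        phi_dot0 = init$phi_dot)
  expect_lt(max(abs(mc - an) / se), 3)
})

test_that("analytic delay function matches an independent quadrature oracle", {
  # C(t) = (V_p/tau) Int e^{-u/tau} [C_n(|t-u|) - C_n(t+u)] du
  oracle <- function(p, t) vapply(t, function(ti)
    stats::integrate(function(u)
      exp(-u / p$tau) * (orientation_correlation(p, abs(ti - u)) -
                           orientation_correlation(p, ti + u)) *
        p$v_p / p$tau,
      0, Inf, rel.tol = 1e-11, subdivisions = 500L)$value, numeric(1))
  tt <- c(0, 0.01, 0.05, 0.2, 0.5, 1, 2)
  p <- fig2_params()
  expect_equal(delay_function_analytic(p, tt), oracle(p, tt),
               tolerance = 1e-7)
  # pole-prone parameter sets (omega = 0, D2 - D0 near integers)
  for (prm in list(abp_params(tau = 0.1, tau_r = 0.2, D = 1e-5, D_r = 0.5,
                              v_p = 0.1, omega = 0),
                   abp_params(tau = 0.2, tau_r = 0.3, D = 1e-5,
                              D_r = 0.5 / 0.3, v_p = 0.1, omega = 0))) {
    expect_equal(delay_function_analytic(prm, tt), oracle(prm, tt),
                 tolerance = 1e-8)
  }
})

test_that("delay function starts at zero, vanishes when overdamped, peaks at the regression lag", {
  p <- fig2_params()
  expect_identical(delay_function_analytic(p, 0), 0)
  ps <- abp_params(tau = p$tau * 1e-3, tau_r = p$tau_r * 1e-3, D = p$D,
                   D_r = p$D_r, v_p = p$v_p, omega = p$omega)
  tt <- seq(0, 2, by = 0.01)
  expect_lt(max(abs(delay_function_analytic(ps, tt))),
            5e-3 * max(delay_function_analytic(p, tt)))
  # frozen regression value of the fig2 peak location (dense evaluation)
  tg <- seq(0, 2, by = 1e-4)
  cg <- delay_function_analytic(p, tg)
  expect_equal(tg[which.max(cg)], 0.3429, tolerance = 1e-3)
  expect_equal(max(cg), 0.0313147, tolerance = 1e-4)
})

test_that("angular statistics follow the Gaussian solution", {
  p <- fig2_params()
  # variance: tau_r -> 0 gives 2 D_r t
  po <- abp_params(tau = 0.2, tau_r = 1e-10, D = 1e-4, D_r = 2.59,
                   v_p = 0.1, omega = 0)
  tt <- c(0.1, 0.5, 2)
  expect_equal(angular_variance(po, tt), 2 * 2.59 * tt, tolerance = 1e-6)
  # small-t series: mu(t) = (2 D_r / (3 tau_r^2)) t^3 + O(t^4)
  h <- 1e-4
  expect_rel(angular_variance(p, h), 2 * p$D_r / (3 * p$tau_r^2) * h^3,
             1e-3)
  # angular pdf integrates to 1 and is centred on the conditional mean
  phi <- seq(-20, 20, by = 1e-3)
  dens <- angular_pdf(p, phi, t = 0.7, phi0 = 0.2, phi_dot0 = 1.5)
  expect_equal(sum(dens) * 1e-3, 1, tolerance = 1e-3)
  expect_equal(sum(phi * dens) * 1e-3,
               angular_mean(p, 0.7, 0.2, 1.5), tolerance = 1e-3)
  # stationary angular velocity: normalised, mean omega, variance D_r/tau_r
  pd <- seq(-30, 30, by = 1e-3)
  dens2 <- angular_velocity_pdf(p, pd)
  expect_equal(sum(dens2) * 1e-3, 1, tolerance = 1e-3)
  expect_equal(sum(pd * dens2) * 1e-3, p$omega, tolerance = 1e-3)
  expect_rel(sum((pd - p$omega)^2 * dens2) * 1e-3, p$D_r / p$tau_r, 1e-3)
  # stationary angular MSD: short-lag curvature omega^2 + D_r/tau_r
  expect_rel(angular_msd_analytic(p, h) / h^2,
             p$omega^2 + p$D_r / p$tau_r, 1e-3)
})

test_that("velocity mixture distributions are normalised with matched moments", {
  p <- fig2_params()
  qw <- match_qW(p)
  dv <- 5e-4
  v <- seq(-0.5, 0.5, by = dv)
  pdf <- linear_velocity_pdf(v, qw$q, qw$W)
  expect_equal(sum(pdf) * dv, 1, tolerance = 1e-3)
  expect_equal(sum(v^2 * pdf) * dv, qw$q + qw$W^2 / 2, tolerance = 1e-3)
  expect_equal(sum(v^4 * pdf) * dv,
               3 * qw$q^2 + 3 * qw$q * qw$W^2 + 3 / 8 * qw$W^4,
               tolerance = 1e-3)
  # matched moments equal the model moments
  expect_equal(qw$q + qw$W^2 / 2, qw$m2, tolerance = 1e-12)
  expect_rel(3 * qw$q^2 + 3 * qw$q * qw$W^2 + 3 / 8 * qw$W^4, qw$m4, 1e-10)
  # model second moment is half the velocity second moment
  expect_equal(qw$m2, velocity_second_moment(p) / 2, tolerance = 1e-12)
  # speed pdf: normalised, and the W = 0 case is the 2-D Maxwell speed law
  vv <- seq(0, 0.6, by = dv)
  spdf <- speed_pdf(vv, qw$q, qw$W)
  expect_equal(sum(spdf) * dv, 1, tolerance = 1e-3)
  expect_equal(speed_pdf(vv, 2e-4, 0), vv / 2e-4 * exp(-vv^2 / 4e-4))
  # W = 0: symmetric Gaussian
  expect_equal(linear_velocity_pdf(v, 3e-4, 0), dnorm(v, 0, sqrt(3e-4)))
  # q -> 0: arcsine law of W cos(phi) away from the edges
  W <- 0.1
  vi <- seq(-0.07, 0.07, by = 0.01)
  expect_equal(linear_velocity_pdf(vi, (1e-3 * W)^2, W, n_nodes = 4096L),
               1 / (pi * sqrt(W^2 - vi^2)), tolerance = 1e-3)
})

test_that("moment matching is exact in the passive and overdamped limits", {
  # passive: W = 0, q = D/tau
  p0 <- abp_params(tau = 0.2, tau_r = 0.1, D = 3e-4, D_r = 1, v_p = 0,
                   omega = 0)
  qw0 <- match_qW(p0)
  expect_equal(qw0$W, 0)
  expect_equal(qw0$q, 3e-4 / 0.2, tolerance = 1e-12)
  # rotational-inertia-dominated limit (D0 >> 1): the orientation is
  # frozen on the velocity relaxation scale, so W -> V_p, q -> D/tau
  pod <- abp_params(tau = 0.05, tau_r = 50, D = 1e-4, D_r = 1, v_p = 0.1,
                    omega = 0)
  qwo <- match_qW(pod)
  expect_rel(qwo$W, 0.1, 0.02)
  expect_rel(qwo$q, 1e-4 / 0.05, 0.05)
})
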