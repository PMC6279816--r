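make_traj <- function(t, x, y, phi) {
  structure(data.frame(t = t, x = x, y = y, phi = phi),
            dt = t[2] - t[1], run = 1L,
            class = c("abp_trajectory", "data.frame"))
}

test_that("finite-difference velocities recover linear motion for any k", {
  t <- seq(0, 1, by = 0.01)
  tr <- make_traj(t, 0.3 * t, 0 * t, 0 * t)
  for (k in c(1L, 2L, 4L)) {
    v <- fd_velocity(tr, k)
    expect_equal(nrow(v), length(t) - k)
    expect_equal(v$vx, rep(0.3, nrow(v)))
    expect_equal(v$vy, rep(0, nrow(v)))
    expect_equal(v$theta, rep(0, nrow(v)))
  }
  # two-point trajectory, k = 1: a single velocity sample
  tr2 <- make_traj(c(0, 0.1), c(0, 0.05), c(0, 0), c(0, 0))
  expect_equal(nrow(fd_velocity(tr2, 1L)), 1L)
  expect_equal(fd_velocity(tr2, 1L)$vx, 0.5)
  expect_error(fd_velocity(tr2, 2L))
})

test_that("empirical MSD is exact on ballistic input and zero at lag zero", {
  t <- seq(0, 2, by = 0.01)
  tr <- make_traj(t, 0.2 * t, -0.1 * t, 1.5 * t)
  lags <- c(0L, 1L, 10L, 50L)
  msd <- empirical_msd(tr, lags)
  expect_equal(msd$value, (0.2^2 + 0.1^2) * (lags * 0.01)^2,
               tolerance = 1e-12)
  msda <- empirical_msd(tr, lags, angular = TRUE)
  expect_equal(msda$value, 1.5^2 * (lags * 0.01)^2, tolerance = 1e-12)
  expect_error(empirical_msd(tr, 1000L), "lags")
})

test_that("MSD estimator is invariant under rotation and translation", {
  p <- fig2_params()
  tr <- simulate_abp(p, sim_config(dt = 0.01, n_steps = 500, seed = 12,
                                   dt_policy = "none"))
  a <- 0.73
  tr2 <- tr
  tr2$x <- cos(a) * tr$x - sin(a) * tr$y + 5
  tr2$y <- sin(a) * tr$x + cos(a) * tr$y - 2
  lags <- c(1L, 7L, 40L)
  expect_equal(empirical_msd(tr2, lags)$value,
               empirical_msd(tr, lags)$value, tolerance = 1e-12)
})

test_that("passive long-lag MSD slope recovers the input D", {
  p <- abp_params(tau = 0.05, tau_r = 0.05, D = 2e-4, D_r = 1, v_p = 0,
                  omega = 0)
  cfg <- sim_config(dt = 0.02, n_steps = 3000, n_runs = 40, seed = 8,
                    init = "stationary", dt_policy = "none")
  ens <- simulate_ensemble(p, cfg)
  lags <- seq(200L, 1000L, by = 200L)
  # per-run slope, between-run standard error: 3-s.e. criterion
  dt <- 0.02
  slopes <- vapply(ens, function(tr) {
    v <- vapply(lags, function(l) {
      i <- seq_len(nrow(tr) - l)
      mean((tr$x[i + l] - tr$x[i])^2 + (tr$y[i + l] - tr$y[i])^2)
    }, numeric(1))
    stats::coef(stats::lm(v ~ I(lags * dt)))[[2]]
  }, numeric(1))
  D_hat <- mean(slopes) / 4
  se <- stats::sd(slopes) / sqrt(length(slopes)) / 4
  expect_lt(abs(D_hat - p$D), 3 * se)
})

test_that("velocity histograms are normalised and rotation-invariant in law", {
  ens <- fig2_ensemble()
  d <- empirical_velocity_distributions(ens, k = 1L)
  for (curve in d[c("linear", "speed", "angular_velocity")]) {
    w <- diff(curve$grid)[1]
    expect_equal(sum(curve$value) * w, 1, tolerance = 0.02)
    expect_true(all(curve$sem >= 0))
  }
  # angular velocity histogram: shifted Gaussian with mean omega (3 s.e.)
  av <- d$angular_velocity
  w <- diff(av$grid)[1]
  m1 <- sum(av$grid * av$value * w)
  se <- sqrt(sum(av$grid^2 * av$sem^2) * w^2)
  expect_lt(abs(m1 - 0.7), 3 * max(se, 0.02))
  # the rotation leaves an isotropic field statistically unchanged
  d2 <- empirical_velocity_distributions(ens, k = 1L, rotate = FALSE,
                                         bins = d$linear$grid |>
                                           inertabp:::grid_to_breaks())
  d1 <- empirical_velocity_distributions(ens, k = 1L, rotate = TRUE,
                                         bins = d$linear$grid |>
                                           inertabp:::grid_to_breaks())
  z <- abs(d1$linear$value - d2$linear$value) /
    sqrt(d1$linear$sem^2 + d2$linear$sem^2 + 1e-12)
  expect_lt(stats::quantile(z, 0.95), 4)
})

test_that("active speed distribution departs from the Maxwell form", {
  # KS-type distance of the empirical speed law from the passive 2-D
  # Maxwell distribution with matched second moment: larger when V_p > 0
  ks_maxwell <- function(ens) {
    sp <- unlist(lapply(ens, function(tr) fd_velocity(tr, 1L)$speed))
    s2 <- mean(sp^2) / 2
    cdf <- stats::ecdf(sp)
    g <- seq(0, max(sp), length.out = 400)
    max(abs(cdf(g) - (1 - exp(-g^2 / (2 * s2)))))
  }
  p <- fig2_params()
  cfg <- sim_config(dt = 0.0066, n_steps = 2000, n_runs = 10, seed = 5,
                    init = "stationary", dt_policy = "none")
  act <- ks_maxwell(simulate_ensemble(p, cfg))
  p0 <- abp_params(tau = p$tau, tau_r = p$tau_r, D = p$D, D_r = p$D_r,
                   v_p = 0, omega = p$omega)
  pas <- ks_maxwell(simulate_ensemble(p0, cfg))
  expect_gt(act, 3 * pas)
})

test_that("empirical delay is zero at lag zero and antisymmetric by construction", {
  ens <- fig2_ensemble()
  lags <- c(0L, 5L, 20L, 60L)
  dc <- empirical_delay(ens, k = 1L, lags = lags)
  expect_identical(dc$value[1], 0)
  # swapping the roles of n and R' flips the sign of every per-run term
  swapped <- vapply(ens, function(tr) {
    v <- fd_velocity(tr, 1L)
    nv <- cbind(cos(tr$phi), sin(tr$phi))[seq_len(nrow(v)), ]
    vm <- cbind(v$vx, v$vy)
    l <- 20L
    i <- seq_len(nrow(vm) - l)
    mean(rowSums(nv[i + l, ] * vm[i, ])) -
      mean(rowSums(nv[i, ] * vm[i + l, ]))
  }, numeric(1))
  expect_equal(mean(swapped), -dc$value[dc$grid == 20L * 0.0066],
               tolerance = 1e-12)
})

test_that("underdamped delay curve matches the analytic solution within errors", {
  ens <- fig2_ensemble()
  p <- fig2_params()
  lags <- c(0L, 5L, 10L, 20L, 35L, 52L, 80L, 120L, 200L)
  dc <- empirical_delay(ens, k = 1L, lags = lags)
  an <- delay_function_analytic(p, dc$grid)
  z <- (dc$value[-1] - an[-1]) / dc$sem[-1]
  expect_lt(max(abs(z)), 3)
  # and the peak is positive and of the predicted size
  expect_gt(max(dc$value), 0.8 * max(an))
})

test_that("trajectory CSV IO round-trips and validates", {
  ens <- simulate_ensemble(fig2_params(),
                           sim_config(dt = 0.01, n_steps = 40, n_runs = 3,
                                      seed = 2, dt_policy = "none"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(ens, f)
  back <- read_trajectories(f)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_equal(back[[i]]$x, ens[[i]]$x, tolerance = 1e-13)
    expect_equal(back[[i]]$phi, ens[[i]]$phi, tolerance = 1e-13)
  }
  # malformed rows are reported with a line number
  df <- utils::read.csv(f)
  df$t[5] <- df$t[7]
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f2, row.names = FALSE)
  expect_error(read_trajectories(f2), "line")
  # missing columns
  f3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df[, c("run", "t", "x")], f3, row.names = FALSE)
  expect_error(read_trajectories(f3), "missing column")
})

test_that("tracking-noise emulation perturbs at the configured scale", {
  ens <- simulate_ensemble(fig2_params(),
                           sim_config(dt = 0.01, n_steps = 200, n_runs = 2,
                                      seed = 2, dt_policy = "none"))
  noisy <- add_tracking_noise(ens, seed = 9)
  dx <- noisy[[1]]$x - ens[[1]]$x
  dphi <- noisy[[1]]$phi - ens[[1]]$phi
  expect_rel(stats::sd(dx), 4.7e-4, 0.2)
  expect_rel(stats::sd(dphi), 0.013, 0.2)
})
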