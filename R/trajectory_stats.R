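#' Finite-difference velocities
#'
#' Velocities as measured in particle-tracking experiments: displacements of
#' successive positions, \eqn{v(t) = (r(t + k\Delta t_0) - r(t)) /
#' (k \Delta t_0)}, where \eqn{\Delta t_0} is the frame interval and `k` an
#' integer frame multiple.  The velocity direction is
#' \eqn{\Theta = \mathrm{atan2}(\dot Y, \dot X)}.  The angular analogue
#' differences the unwrapped angle.
#'
#' @param traj An `abp_trajectory` (or any data frame with columns `t`,
#'   `x`, `y`, `phi`).
#' @param k Positive integer frame multiple.
#' @return `fd_velocity`: data frame with `t`, `vx`, `vy`, `speed`,
#'   `theta` (`nrow(traj) - k` rows, timestamped at the interval start).
#'   `fd_angular_velocity`: data frame with `t`, `phi_dot`.
#' @export
fd_velocity <- function(traj, k = 1L) {
  k <- as.integer(k)
  stopifnot(k >= 1L, nrow(traj) > k)
  h <- (traj$t[1L + k] - traj$t[1L])
  i <- seq_len(nrow(traj) - k)
  vx <- (traj$x[i + k] - traj$x[i]) / h
  vy <- (traj$y[i + k] - traj$y[i]) / h
  data.frame(t = traj$t[i], vx = vx, vy = vy,
             speed = sqrt(vx^2 + vy^2), theta = atan2(vy, vx))
}

#' @rdname fd_velocity
#' @export
fd_angular_velocity <- function(traj, k = 1L) {
  k <- as.integer(k)
  stopifnot(k >= 1L, nrow(traj) > k)
  h <- (traj$t[1L + k] - traj$t[1L])
  i <- seq_len(nrow(traj) - k)
  data.frame(t = traj$t[i], phi_dot = (traj$phi[i + k] - traj$phi[i]) / h)
}

as_ensemble <- function(x) {
  if (inherits(x, "abp_ensemble")) return(x)
  if (inherits(x, "abp_trajectory") || is.data.frame(x))
    return(structure(list(x), dt = x$t[2] - x$t[1], class = "abp_ensemble"))
  stop("expected an abp_ensemble or abp_trajectory", call. = FALSE)
}

new_curve <- function(grid, value, sem, n, semantics, grid_label = "lag") {
  structure(data.frame(grid = grid, value = value, sem = sem, n = n),
            semantics = semantics, grid_label = grid_label,
            class = c("abp_curve", "data.frame"))
}

#' Empirical mean squared displacement
#'
#' Time-and-ensemble averaged MSD: within each run the squared displacement
#' at lag \eqn{\ell \Delta t} is averaged over all start times, then the
#' per-run means are averaged across runs; the error band is the standard
#' error of the mean over runs (for a single run, over non-overlapping
#' displacement blocks).  With `angular = TRUE` the squared increment of the
#' unwrapped angle is used instead.
#'
#' @param ens An `abp_ensemble` (or single trajectory).
#' @param lags Integer lags in frames; default a log-spaced set.
#' @param angular Use the angle instead of the position.
#' @return An `abp_curve` data frame with columns `grid` (lag, s), `value`,
#'   `sem`, `n`.
#' @export
empirical_msd <- function(ens, lags = NULL, angular = FALSE) {
  ens <- as_ensemble(ens)
  nt <- nrow(ens[[1]])
  dt <- ens[[1]]$t[2] - ens[[1]]$t[1]
  if (is.null(lags))
    lags <- sort(unique(pmax(1, round(exp(seq(0, log(nt / 2),
                                              length.out = 40L))))))
  lags <- as.integer(lags)
  if (any(lags < 0) || any(lags >= nt))
    stop("lags must lie in [0, n_samples - 1]", call. = FALSE)
  per_run <- vapply(ens, function(tr) {
    vapply(lags, function(l) {
      if (l == 0L) return(0)
      i <- seq_len(nrow(tr) - l)
      if (angular) {
        mean((tr$phi[i + l] - tr$phi[i])^2)
      } else {
        mean((tr$x[i + l] - tr$x[i])^2 + (tr$y[i + l] - tr$y[i])^2)
      }
    }, numeric(1))
  }, numeric(length(lags)))
  per_run <- matrix(per_run, nrow = length(lags))
  val <- rowMeans(per_run)
  sem <- if (ncol(per_run) > 1L)
    apply(per_run, 1L, stats::sd) / sqrt(ncol(per_run))
  else rep(NA_real_, length(lags))
  new_curve(lags * dt, val, sem, rep(ncol(per_run), length(lags)),
            if (angular) "msd_rad2" else "msd_m2")
}

#' Empirical velocity distributions
#'
#' Normalised histograms of the finite-difference velocities with
#' between-run standard-error bands: the linear (Cartesian component)
#' velocity distribution, the speed distribution, and the angular velocity
#' distribution.  Before pooling the components, each run is rotated by an
#' independent uniform random angle, mirroring the experimental practice of
#' removing residual anisotropy from the initial conditions; both rotated
#' components are pooled (\eqn{P(\dot X) = P(\dot Y)}).
#'
#' @param ens An `abp_ensemble`.
#' @param k Frame multiple for the finite differences.
#' @param bins Number of bins or vector of breaks; default Freedman-Diaconis.
#' @param rotate Apply the per-run random rotation (seeded).
#' @param seed Seed for the rotation angles.
#' @return List of `abp_curve`s: `linear`, `speed`, `angular_velocity`,
#'   plus `v2_mean`, the pooled second moment of the velocity vector.
#' @export
empirical_velocity_distributions <- function(ens, k = 1L, bins = NULL,
                                             rotate = TRUE, seed = 1L) {
  ens <- as_ensemble(ens)
  vels <- lapply(ens, fd_velocity, k = k)
  angs <- lapply(ens, fd_angular_velocity, k = k)
  set.seed(seed)
  rot <- if (rotate) stats::runif(length(vels), 0, 2 * pi)
         else rep(0, length(vels))
  lin_runs <- Map(function(v, a) {
    c(cos(a) * v$vx - sin(a) * v$vy, sin(a) * v$vx + cos(a) * v$vy)
  }, vels, rot)
  spd_runs <- lapply(vels, `[[`, "speed")
  ang_runs <- lapply(angs, `[[`, "phi_dot")
  list(linear = hist_curve(lin_runs, bins, "pdf_linear_velocity"),
       speed = hist_curve(spd_runs, bins, "pdf_speed"),
       angular_velocity = hist_curve(ang_runs, bins,
                                     "pdf_angular_velocity"),
       v2_mean = mean(unlist(lapply(vels, function(v) v$vx^2 + v$vy^2))))
}

# normalised histogram with between-run sem; common Freedman-Diaconis
# breaks over the pooled sample unless breaks are supplied
hist_curve <- function(run_samples, bins, semantics) {
  pooled <- unlist(run_samples)
  if (is.null(bins)) {
    bw <- 2 * stats::IQR(pooled) / length(pooled)^(1 / 3)
    if (bw <= 0) bw <- diff(range(pooled)) / 30 + .Machine$double.eps
    breaks <- seq(min(pooled) - bw, max(pooled) + bw, by = bw)
  } else if (length(bins) == 1L) {
    breaks <- seq(min(pooled), max(pooled), length.out = bins + 1L)
  } else breaks <- bins
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  width <- diff(breaks)
  dens <- vapply(run_samples, function(s) {
    h <- graphics::hist(s[s >= breaks[1] & s <= breaks[length(breaks)]],
                        breaks = breaks, plot = FALSE)
    h$counts / (length(s) * width)
  }, numeric(length(mids)))
  dens <- matrix(dens, nrow = length(mids))
  val <- rowMeans(dens)
  sem <- if (ncol(dens) > 1L) apply(dens, 1L, stats::sd) / sqrt(ncol(dens))
         else rep(NA_real_, length(mids))
  new_curve(mids, val, sem, rep(length(pooled), length(mids)), semantics,
            grid_label = "velocity")
}

#' Empirical inertial delay function
#'
#' The estimator of the orientation-velocity cross correlation
#' \eqn{C(\ell\Delta t) = \langle \dot R(t + \ell\Delta t) \cdot n(t)
#' \rangle_T - \langle \dot R(t) \cdot n(t + \ell\Delta t) \rangle_T},
#' averaged over start times within each run and then over runs, with
#' between-run standard errors.  Velocities are finite differences
#' ([fd_velocity()]).  At lag zero the two projections coincide and the
#' estimator is exactly zero; in overdamped systems it is zero at all lags,
#' while with inertia the velocity direction pursues the orientation and
#' the curve shows a positive peak near the relaxation times.
#'
#' @param ens An `abp_ensemble`.
#' @param k Frame multiple for the velocities.
#' @param lags Integer lags in frames.
#' @return An `abp_curve` with the lag (s) grid.
#' @export
empirical_delay <- function(ens, k = 1L, lags = NULL) {
  ens <- as_ensemble(ens)
  dt <- ens[[1]]$t[2] - ens[[1]]$t[1]
  if (is.null(lags)) lags <- 0:min(200L, nrow(ens[[1]]) %/% 4L)
  lags <- as.integer(lags)
  per_run <- vapply(ens, function(tr) {
    v <- fd_velocity(tr, k)
    nvec <- cbind(cos(tr$phi), sin(tr$phi))[seq_len(nrow(v)), , drop = FALSE]
    vm <- cbind(v$vx, v$vy)
    vapply(lags, function(l) {
      if (l >= nrow(vm)) return(NA_real_)
      i <- seq_len(nrow(vm) - l)
      mean(rowSums(vm[i + l, , drop = FALSE] * nvec[i, , drop = FALSE])) -
        mean(rowSums(vm[i, , drop = FALSE] * nvec[i + l, , drop = FALSE]))
    }, numeric(1))
  }, numeric(length(lags)))
  per_run <- matrix(per_run, nrow = length(lags))
  if (anyNA(per_run)) stop("insufficient samples at the requested lags",
                           call. = FALSE)
  val <- rowMeans(per_run)
  sem <- if (ncol(per_run) > 1L)
    apply(per_run, 1L, stats::sd) / sqrt(ncol(per_run))
  else rep(NA_real_, length(lags))
  new_curve(lags * dt, val, sem, rep(ncol(per_run), length(lags)),
            "delay")
}

#' Empirical orientational correlation function
#'
#' Time-and-ensemble average of \eqn{\cos(\phi(t + s) - \phi(t))} on the
#' unwrapped angle, the estimator of [orientation_correlation()].
#'
#' @param ens An `abp_ensemble`.
#' @param lags Integer lags in frames.
#' @return An `abp_curve`.
#' @export
empirical_orientation_correlation <- function(ens, lags = NULL) {
  ens <- as_ensemble(ens)
  dt <- ens[[1]]$t[2] - ens[[1]]$t[1]
  if (is.null(lags)) lags <- 0:min(300L, nrow(ens[[1]]) %/% 4L)
  lags <- as.integer(lags)
  per_run <- vapply(ens, function(tr) {
    vapply(lags, function(l) {
      i <- seq_len(nrow(tr) - l)
      mean(cos(tr$phi[i + l] - tr$phi[i]))
    }, numeric(1))
  }, numeric(length(lags)))
  per_run <- matrix(per_run, nrow = length(lags))
  val <- rowMeans(per_run)
  sem <- if (ncol(per_run) > 1L)
    apply(per_run, 1L, stats::sd) / sqrt(ncol(per_run))
  else rep(NA_real_, length(lags))
  new_curve(lags * dt, val, sem, rep(ncol(per_run), length(lags)),
            "correlation")
}

#' Full empirical curve set
#'
#' Computes the six observables used for parameter determination — the
#' translational and angular MSDs, the linear-velocity, speed and
#' angular-velocity distributions, and the delay function — plus the
#' orientational correlation, with common settings, and records the
#' sampling interval, frame multiple and pooled velocity second moment.
#'
#' @param ens An `abp_ensemble`.
#' @param k Frame multiple for velocities.
#' @param lags_msd,lags_delay Integer lag sets (frames).
#' @param bins Histogram bins (see [empirical_velocity_distributions()]).
#' @param rotation_seed Seed for the anisotropy-removing rotations.
#' @return A list of class `"abp_curveset"`.
#' @export
abp_curves <- function(ens, k = 1L, lags_msd = NULL, lags_delay = NULL,
                       bins = NULL, rotation_seed = 1L) {
  ens <- as_ensemble(ens)
  dists <- empirical_velocity_distributions(ens, k = k, bins = bins,
                                            seed = rotation_seed)
  structure(list(
    msd_trans = empirical_msd(ens, lags_msd, angular = FALSE),
    msd_ang = empirical_msd(ens, lags_msd, angular = TRUE),
    pdf_linear_velocity = dists$linear,
    pdf_speed = dists$speed,
    pdf_angular_velocity = dists$angular_velocity,
    delay_curve = empirical_delay(ens, k = k, lags = lags_delay),
    orientation_corr = empirical_orientation_correlation(ens),
    meta = list(dt = ens[[1]]$t[2] - ens[[1]]$t[1], k = k,
                n_runs = length(ens), n_frames = nrow(ens[[1]]),
                v2_mean = dists$v2_mean)),
    class = "abp_curveset")
}

#' @export
print.abp_curveset <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "abp_curveset: %d runs x %d frames, dt = %g s, k = %d, <v^2> = %.4g\n",
    m$n_runs, m$n_frames, m$dt, m$k, m$v2_mean))
  invisible(x)
}

#' Add synthetic tracking noise
#'
#' Adds independent Gaussian measurement noise to positions and angles,
#' emulating the finite accuracy of video tracking (defaults: 4.7e-4 m and
#' 0.013 rad).  Useful for realistic synthetic fixtures; off by default in
#' all other functions.
#'
#' @param ens An `abp_ensemble`.
#' @param sd_xy,sd_phi Noise standard deviations (m, rad).
#' @param seed Seed.
#' @return The perturbed ensemble.
#' @export
add_tracking_noise <- function(ens, sd_xy = 4.7e-4, sd_phi = 0.013,
                               seed = 1L) {
  ens <- as_ensemble(ens)
  set.seed(seed)
  out <- lapply(ens, function(tr) {
    n <- nrow(tr)
    tr$x <- tr$x + stats::rnorm(n, 0, sd_xy)
    tr$y <- tr$y + stats::rnorm(n, 0, sd_xy)
    tr$phi <- tr$phi + stats::rnorm(n, 0, sd_phi)
    tr
  })
  attributes(out) <- attributes(ens)
  out
}

#' Read and write trajectory ensembles as CSV
#'
#' Long-format CSV with a `run` column and columns `t`, `x`, `y`, `phi`
#' and optionally `phi_dot`, `vx`, `vy` (SI units, radians, one row per
#' sample).  Values round-trip losslessly to at least 12 significant
#' digits.  On read, times must be strictly increasing and uniform within
#' each run to 1e-9 s; violations are reported with the offending line
#' number.
#'
#' @param path CSV file path.
#' @param ens An `abp_ensemble`.
#' @param include_velocity Write the instantaneous velocity columns too.
#' @return `read_trajectories`: an `abp_ensemble`.
#'   `write_trajectories`: `path`, invisibly.
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t", "x", "y", "phi")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(df$run)) df$run <- 1L
  runs <- split(seq_len(nrow(df)), factor(df$run, levels = unique(df$run)))
  trajs <- lapply(names(runs), function(r) {
    idx <- runs[[r]]
    tr <- df[idx, setdiff(names(df), "run"), drop = FALSE]
    dts <- diff(tr$t)
    if (any(dts <= 0)) {
      bad <- idx[which(dts <= 0)[1] + 1L] + 1L   # +1 for the header line
      stop(sprintf("non-increasing time at line %d of %s", bad, path),
           call. = FALSE)
    }
    if (max(dts) - min(dts) > 1e-9) {
      bad <- idx[which.max(abs(dts - dts[1])) + 1L] + 1L
      stop(sprintf("non-uniform time step at line %d of %s", bad, path),
           call. = FALSE)
    }
    rownames(tr) <- NULL
    structure(tr, dt = dts[1], run = r,
              class = c("abp_trajectory", "data.frame"))
  })
  structure(trajs, dt = attr(trajs[[1]], "dt"), class = "abp_ensemble")
}

#' @rdname read_trajectories
#' @export
write_trajectories <- function(ens, path, include_velocity = FALSE) {
  ens <- as_ensemble(ens)
  cols <- c("t", "x", "y", "phi",
            if (!is.null(ens[[1]]$phi_dot)) "phi_dot",
            if (include_velocity) c("vx", "vy"))
  rows <- lapply(seq_along(ens), function(i) {
    tr <- ens[[i]]
    cbind(run = i, as.data.frame(tr)[, cols, drop = FALSE])
  })
  df <- do.call(rbind, rows)
  # 17 significant digits: lossless double round trip
  old <- options(scipen = 0, digits = 17)
  on.exit(options(old))
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
plot.abp_curve <- function(x, ..., log = "") {
  graphics::plot(x$grid, x$value, type = "l", log = log,
                 xlab = attr(x, "grid_label"),
                 ylab = attr(x, "semantics"), ...)
  if (!anyNA(x$sem)) {
    graphics::lines(x$grid, x$value + 2 * x$sem, lty = 3)
    graphics::lines(x$grid, x$value - 2 * x$sem, lty = 3)
  }
  invisible(x)
}

#' Export a curve as two-column CSV
#'
#' Writes `grid,value[,sem]` with a leading comment line recording the
#' curve semantics.
#'
#' @param curve An `abp_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# semantics: %s", attr(curve, "semantics")), con)
  utils::write.csv(as.data.frame(curve), con, row.names = FALSE)
  invisible(path)
}
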