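#' Stationary orientational correlation function
#'
#' \deqn{\langle n(t+s) \cdot n(s) \rangle =
#'   \cos(\omega t)\, e^{-D_r (t - \tau_r (1 - e^{-t/\tau_r}))}.}
#' The cosine reflects circling under the constant torque; the exponent is
#' half the stationary variance of the angle increment, whose growth is
#' ballistic below \eqn{\tau_r} (inertial memory of the angular velocity)
#' and diffusive above it.  For \eqn{\tau_r \to 0} the overdamped
#' active-Brownian form \eqn{\cos(\omega t) e^{-D_r t}} is recovered.
#'
#' @param p An [abp_params()] object.
#' @param t Non-negative lag(s), s.
#' @return Numeric vector of correlation values.
#' @export
orientation_correlation <- function(p, t) {
  stopifnot(inherits(p, "abp_params"), all(t >= 0))
  cos(p$omega * t) * exp(-p$D_r * (t - p$tau_r * (1 - exp(-t / p$tau_r))))
}

#' Two-time orientation correlation conditional on the initial angular velocity
#'
#' The conditional correlation \eqn{\langle n(t_1) \cdot n(t_2) \rangle}
#' entering the conditional mean squared displacement, for a particle started
#' at time 0 with known angular velocity \code{phi_dot0} (the initial angle
#' drops out by isotropy).  Reduces to 1 at \eqn{t_1 = t_2} and, for
#' \eqn{t_1, t_2 \gg \tau_r}, to the stationary form
#' [orientation_correlation()] of the lag \eqn{|t_1 - t_2|}.
#'
#' @param p An [abp_params()] object.
#' @param t1,t2 Non-negative times, s (recycled to a common length).
#' @param phi_dot0 Initial angular velocity, rad/s.
#' @return Numeric vector.
#' @export
orientation_correlation_cond <- function(p, t1, t2, phi_dot0 = p$omega) {
  stopifnot(inherits(p, "abp_params"), all(t1 >= 0), all(t2 >= 0))
  tr <- p$tau_r; d0 <- p$D_r * tr
  lag <- abs(t1 - t2)
  amp <- exp(-p$D_r * lag) * exp(d0) *
    exp(-d0 * (exp(-lag / tr) + exp(-(t1 + t2) / tr) -
                 0.5 * (exp(-2 * t1 / tr) + exp(-2 * t2 / tr))))
  phase <- p$omega * (t1 - t2) +
    (p$omega - phi_dot0) * tr * (exp(-t1 / tr) - exp(-t2 / tr))
  amp * cos(phase)
}

#' Short-time kinetic factor f(D0, D1, D2)
#'
#' The dimensionless fraction of the injected kinetic energy \eqn{V_p^2}
#' that survives in the stationary velocity second moment,
#' \deqn{f = \mathcal{D}_2\, e^{\mathcal{D}_0}\, \mathrm{Re}\left[
#'   \mathcal{D}_0^{-(\mathcal{D}_0 - i\mathcal{D}_1 + \mathcal{D}_2)}
#'   \gamma(\mathcal{D}_0 - i\mathcal{D}_1 + \mathcal{D}_2,
#'   \mathcal{D}_0)\right],}
#' confined to \eqn{[0, 1]}: zero at \eqn{\mathcal{D}_2 = 0} and approaching
#' 1 as \eqn{\mathcal{D}_2} grows.  Evaluated through the regularised Kummer
#' series \eqn{\sum_n \mathcal{D}_0^n / \prod_{k \le n}(s + k)} (the
#' combination \eqn{e^x x^{-s} \gamma(s,x)}), which has no overflow and a
#' finite limit at \eqn{\mathcal{D}_0 = 0}.
#'
#' @param d An `abp_delay_numbers` object, an [abp_params()] object, or a
#'   numeric vector `c(d0, d1, d2)`.
#' @return A number in \eqn{[0, 1]}.
#' @export
#' @examples
#' f_delay(delay_numbers(abp_preset("fig2")))
#' f_delay(c(0.48, 0.13, 1e4))   # ~ 1
f_delay <- function(d) {
  d <- as_delay_numbers(d)
  if (d$d0 < 0 || d$d2 < 0) stop("d0 and d2 must be non-negative",
                                 call. = FALSE)
  if (d$d2 == 0) return(0)
  s <- complex(real = d$d0 + d$d2, imaginary = -d$d1)
  d$d2 * Re(gstar_series(s, d$d0))
}

as_delay_numbers <- function(d) {
  if (inherits(d, "abp_delay_numbers")) return(d)
  if (inherits(d, "abp_params")) return(delay_numbers(d))
  if (is.numeric(d) && length(d) == 3L)
    return(structure(list(d0 = d[[1]], d1 = d[[2]], d2 = d[[3]]),
                     class = "abp_delay_numbers"))
  stop("cannot interpret 'd' as delay numbers", call. = FALSE)
}

#' Stationary velocity second moment and short-time MSD
#'
#' \eqn{\langle \dot R^2 \rangle = 2D/\tau + f(\mathcal{D}_0, \mathcal{D}_1,
#' \mathcal{D}_2) V_p^2}: the equilibrium (passive) contribution plus the
#' active part damped by the kinetic factor [f_delay()].  The short-time MSD
#' is ballistic, \eqn{\langle (R(t) - R_0)^2 \rangle =
#' \langle \dot R^2 \rangle t^2}.
#'
#' @param p An [abp_params()] object.
#' @param t Time(s), s, for `short_time_msd`.
#' @return Velocity second moment (m^2/s^2), or the ballistic MSD (m^2).
#' @export
velocity_second_moment <- function(p) {
  stopifnot(inherits(p, "abp_params"))
  2 * p$D / p$tau + f_delay(delay_numbers(p)) * p$v_p^2
}

#' @rdname velocity_second_moment
#' @export
short_time_msd <- function(p, t) velocity_second_moment(p) * t^2

#' Persistence time and long-time diffusion coefficient
#'
#' The propulsion direction decorrelates with effective persistence time
#' \deqn{\mathfrak{t} = \tau_r e^{\mathcal{D}_0}\,\mathrm{Re}\left[
#'   \mathcal{D}_0^{-(\mathcal{D}_0 - i \mathcal{D}_1)}
#'   \gamma(\mathcal{D}_0 - i \mathcal{D}_1, \mathcal{D}_0)\right]}
#' (equal to the time integral of [orientation_correlation()]), and the MSD
#' grows as \eqn{4 D_L t} at long times with
#' \deqn{D_L = D + \tfrac{1}{2} V_p^2\, \mathfrak{t}.}
#' In the overdamped, torque-free limit \eqn{\mathfrak{t} \to 1/D_r}; with
#' rotational inertia \eqn{D_L} grows without bound, asymptotically like
#' \eqn{\sqrt{J}}.  For \eqn{D_r = 0} and \eqn{\omega = 0} the orientation
#' never decorrelates: the persistence time is returned as \code{Inf}
#' (perpetually ballistic motion), not an error.
#'
#' @param p An [abp_params()] object.
#' @return Persistence time (s) or long-time diffusion coefficient (m^2/s).
#' @export
persistence_time <- function(p) {
  stopifnot(inherits(p, "abp_params"))
  d <- delay_numbers(p)
  if (d$d0 == 0 && d$d1 == 0) return(Inf)
  s <- complex(real = d$d0, imaginary = -d$d1)
  p$tau_r * Re(gstar_series(s, d$d0))
}

#' @rdname persistence_time
#' @export
long_time_diffusion <- function(p) {
  pt <- persistence_time(p)
  if (!is.finite(pt)) {
    if (p$v_p == 0) return(p$D)
    return(Inf)
  }
  p$D + p$v_p^2 / 2 * pt
}

#' Small- and large-inertia asymptotics of the long-time diffusivity
#'
#' Printed truncations of [long_time_diffusion()] in the moment of inertia
#' \eqn{J} at fixed \eqn{\xi_r}, \eqn{D}, \eqn{D_r}, \eqn{V_p} (torque-free
#' regime):
#' \deqn{D_L = D + \frac{V_p^2}{2 D_r} + \frac{V_p^2}{2 \xi_r} J + O(J^2),}
#' \deqn{D_L = D + V_p^2 \sqrt{\frac{\pi}{8 D_r \xi_r}} \sqrt{J}
#'       + O(1/\sqrt{J}).}
#' Both require the absolute rotational scales (\code{J} and \code{xi_r})
#' to be present in \code{p}.
#'
#' @param p An [abp_params()] object carrying \code{J} and \code{xi_r}.
#' @return Approximate long-time diffusion coefficient (m^2/s).
#' @export
dl_asymptotic_small_J <- function(p) {
  stopifnot(inherits(p, "abp_params"))
  if (is.null(p$J) || is.null(p$xi_r))
    stop("absolute scales J and xi_r are required", call. = FALSE)
  if (p$D_r <= 0) stop("D_r must be positive for the small-J expansion",
                       call. = FALSE)
  p$D + p$v_p^2 / (2 * p$D_r) + p$v_p^2 / (2 * p$xi_r) * p$J
}

#' @rdname dl_asymptotic_small_J
#' @export
dl_asymptotic_large_J <- function(p) {
  stopifnot(inherits(p, "abp_params"))
  if (is.null(p$J) || is.null(p$xi_r))
    stop("absolute scales J and xi_r are required", call. = FALSE)
  if (p$D_r <= 0) stop("D_r must be positive for the large-J expansion",
                       call. = FALSE)
  p$D + p$v_p^2 * sqrt(pi / (8 * p$D_r * p$xi_r)) * sqrt(p$J)
}

# --- stationary velocity autocorrelation -----------------------------------

# Stationary VACF: Z(s) = (2D/tau) e^{-s/tau}
#   + (V_p^2 / (2 tau)) Int e^{-|r|/tau} C_n(|s - r|) dr,
# obtained by writing the stationary velocity as the exponentially filtered
# orientation plus thermal noise.  The active integral is evaluated exactly
# in the tau scale with Gauss-Laguerre nodes; C_n is the stationary
# orientational correlation.
velocity_autocorrelation <- function(p, s, n_nodes = 48L) {
  stopifnot(inherits(p, "abp_params"), all(s >= 0))
  gl <- gl_cache(n_nodes)
  act <- vapply(s, function(si) {
    sum(gl$w * (orientation_correlation(p, abs(si - p$tau * gl$x)) +
                  orientation_correlation(p, si + p$tau * gl$x)))
  }, numeric(1))
  2 * p$D / p$tau * exp(-s / p$tau) + p$v_p^2 / 2 * act
}

gl_env <- new.env(parent = emptyenv())
gl_cache <- function(n) {
  key <- as.character(n)
  if (is.null(gl_env[[key]])) {
    g <- pracma::gaussLaguerre(n)
    gl_env[[key]] <- list(x = g$x, w = g$w)
  }
  gl_env[[key]]
}

#' Analytic mean squared displacement
#'
#' `msd_analytic` gives the stationary (time-averaged) translational MSD,
#' computed from the stationary velocity autocorrelation \eqn{Z(s)} as
#' \eqn{\mathrm{MSD}(t) = 2\int_0^t (t - s) Z(s)\, ds}; the passive part is
#' closed-form and the active part is integrated adaptively on
#' logarithmically spaced panels resolving every model time scale.  It obeys
#' \eqn{\mathrm{MSD}(t)/t^2 \to \langle\dot R^2\rangle} as \eqn{t \to 0} and
#' \eqn{\mathrm{MSD}(t)/(4t) \to D_L} as \eqn{t \to \infty}.
#'
#' `msd_conditional` evaluates the conditional MSD of a particle started at
#' the origin with velocity \code{v0} (components along and perpendicular to
#' the initial orientation) and angular velocity \code{phi_dot0}: the sum of
#' the deterministic velocity-relaxation term, the velocity-orientation
#' cross term, the active double integral of the conditional orientation
#' correlation, and the passive inertial terms.
#'
#' @param p An [abp_params()] object.
#' @param t Positive time(s), s.
#' @param rel_tol Relative quadrature tolerance per point.
#' @param v0 Initial velocity `c(parallel, perpendicular)` relative to the
#'   initial orientation, m/s.
#' @param phi_dot0 Initial angular velocity, rad/s.
#' @return Numeric vector of MSD values, m^2.
#' @export
msd_analytic <- function(p, t, rel_tol = 1e-8) {
  stopifnot(inherits(p, "abp_params"), all(t > 0))
  passive <- 4 * p$D * t - 4 * p$D * p$tau * (1 - exp(-t / p$tau))
  if (p$v_p == 0) return(passive)
  scales <- c(p$tau, p$tau_r)
  if (p$D_r > 0) scales <- c(scales, 1 / p$D_r)
  if (p$omega != 0) scales <- c(scales, 1 / abs(p$omega))
  smin <- min(scales) / 100
  active <- vapply(t, function(ti) {
    brk <- unique(c(0, exp(seq(log(smin), log(ti), length.out =
      max(2L, ceiling(2 * log(ti / smin))))), ti))
    brk <- brk[brk <= ti]
    if (brk[length(brk)] < ti) brk <- c(brk, ti)
    tot <- 0
    for (i in seq_len(length(brk) - 1L)) {
      tot <- tot + stats::integrate(function(s)
        (ti - s) * (velocity_autocorrelation(p, s) -
                      2 * p$D / p$tau * exp(-s / p$tau)),
        brk[i], brk[i + 1L], rel.tol = rel_tol, abs.tol = 0,
        subdivisions = 200L)$value
    }
    2 * tot
  }, numeric(1))
  passive + active
}

#' @rdname msd_analytic
#' @export
msd_conditional <- function(p, t, v0 = c(0, 0), phi_dot0 = 0,
                            rel_tol = 1e-6) {
  stopifnot(inherits(p, "abp_params"), all(t > 0), length(v0) == 2L)
  tau <- p$tau; tr <- p$tau_r
  mean_n <- function(u) {
    mu <- angular_variance(p, u)
    m <- p$omega * u + (p$omega - phi_dot0) * tr * (exp(-u / tr) - 1)
    exp(-mu / 2) * (v0[1] * cos(m) + v0[2] * sin(m))
  }
  vapply(t, function(ti) {
    Et <- exp(-ti / tau)
    term1 <- sum(v0^2) * tau^2 * (1 - Et)^2
    term2 <- if (all(v0 == 0) || p$v_p == 0) 0 else {
      2 * p$v_p * tau * (1 - Et) *
        stats::integrate(function(u)
          mean_n(u) * (1 - exp(-(ti - u) / tau)),
          0, ti, rel.tol = rel_tol, subdivisions = 400L)$value
    }
    term3 <- if (p$v_p == 0) 0 else {
      2 * p$v_p^2 * pracma::integral2(function(u, v)
        (1 - exp(-(ti - u) / tau)) * (1 - exp(-(ti - v) / tau)) *
          orientation_correlation_cond(p, u, v, phi_dot0),
        0, ti, 0, function(x) x, reltol = rel_tol)$Q
    }
    passive <- 4 * p$D * ti +
      4 * p$D * tau * (Et - 1 - 0.5 * (Et - 1)^2)
    term1 + term2 + term3 + passive
  }, numeric(1))
}

#' Analytic inertial delay function
#'
#' The orientation-velocity cross correlation
#' \deqn{C(t) = \langle \dot R(t) \cdot n(0) \rangle -
#'             \langle \dot R(0) \cdot n(t) \rangle}
#' of a stationary underdamped active particle: the average difference
#' between the projection of the velocity on the earlier orientation and of
#' the orientation on the earlier velocity.  It starts at zero, peaks after
#' a delay set by the relaxation times, and decays back to zero; in the
#' overdamped limit it vanishes identically.  The closed form is a
#' combination of four lower incomplete gamma functions of complex argument
#' \eqn{\mathcal{D}_0 - i\mathcal{D}_1 \pm \mathcal{D}_2} evaluated at
#' \eqn{\mathcal{D}_0} and \eqn{\mathcal{D}_0 e^{-t/\tau_r}}; it is computed
#' here in a regularised form with all exponential prefactors absorbed, so
#' no intermediate overflows occur, and with the poles of
#' \eqn{\gamma(s, \cdot)} at non-positive integer \eqn{s} (reachable when
#' \eqn{\mathcal{D}_1 = 0} and \eqn{\mathcal{D}_2 - \mathcal{D}_0} is a
#' non-negative integer) cancelled exactly through a difference series.
#'
#' @param p An [abp_params()] object.
#' @param t Non-negative lag(s), s.
#' @return Numeric vector, m/s.
#' @export
#' @examples
#' p <- abp_preset("fig2")
#' tt <- seq(0, 1, by = 0.05)
#' delay_function_analytic(p, tt)
delay_function_analytic <- function(p, t) {
  stopifnot(inherits(p, "abp_params"), all(t >= 0))
  d <- delay_numbers(p)
  d0 <- d$d0; d1 <- d$d1; d2 <- d$d2
  if (d2 == 0 || p$v_p == 0) return(numeric(length(t)))
  tau <- p$tau; tr <- p$tau_r
  if (d0 < 1e-12) {
    # noise-free circling limit: closed form
    if (d1 == 0) return(numeric(length(t)))
    return(p$v_p * d2 * 2 * d1 / (d1^2 + d2^2) * sin(d1 * t / tr))
  }
  a <- complex(real = d0 + d2, imaginary = -d1)
  b <- complex(real = d0 - d2, imaginary = -d1)
  xt <- d0 * exp(-t / tr)
  ga_d0 <- gstar_series(rep(a, length(t)), rep(d0, length(t)))[1]
  ga_xt <- gstar_series(rep(a, length(t)), xt)
  pref <- exp(complex(real = d0 - xt - d0 * t / tr,
                      imaginary = d1 * t / tr))
  a_part <- exp(-t / tau) * ga_d0 - pref * ga_xt
  # b branch: near the poles of gamma(b, .) switch to the difference series
  near_pole <- abs(d1) < 0.05 && Re(b) < 0.25 &&
    abs(Re(b) - round(Re(b))) < 0.1
  if (near_pole) {
    dg <- inc_gamma_lower_diff(b, rep(d0, length(t)), xt)
    b_part <- exp(-t / tau + d0 - b * log(d0)) * dg
  } else {
    gb_d0 <- gstar_series(rep(b, length(t)), rep(d0, length(t)))[1]
    gb_xt <- gstar_series(rep(b, length(t)), xt)
    b_part <- exp(-t / tau) * gb_d0 - pref * gb_xt
  }
  p$v_p * d2 * Re(a_part + b_part)
}

# --- angular statistics ----------------------------------------------------

#' Angular mean, variance, and probability distributions
#'
#' The angle is a Gaussian process: conditional on initial angle \code{phi0}
#' and angular velocity \code{phi_dot0},
#' \deqn{\langle\phi(t)\rangle = \phi_0 + \omega t + (\omega -
#'   \dot\phi_0)\,\tau_r (e^{-t/\tau_r} - 1),}
#' \deqn{\mu(t) = 2 D_r t + 2 D_r \tau_r \left(e^{-t/\tau_r} - 1 -
#'   \tfrac{1}{2}(e^{-t/\tau_r} - 1)^2\right),}
#' and \code{angular_pdf} is the Gaussian with this mean and variance.
#' The stationary angular velocity is Gaussian with mean \eqn{\omega} and
#' variance \eqn{D_r/\tau_r} (\code{angular_velocity_pdf}).
#' `angular_msd_analytic` is the stationary (time-averaged) angular MSD,
#' \eqn{\omega^2 t^2 + 2 D_r (t - \tau_r (1 - e^{-t/\tau_r}))}: ballistic
#' with curvature \eqn{\omega^2 + D_r/\tau_r} below \eqn{\tau_r}, diffusive
#' with slope \eqn{2 D_r} above.
#'
#' @param p An [abp_params()] object.
#' @param t Non-negative time(s), s.
#' @param phi0,phi_dot0 Initial angle (rad) and angular velocity (rad/s).
#' @param phi,phi_dot Evaluation points, rad and rad/s.
#' @return Numeric vector (mean: rad; variance: rad^2; pdfs: densities).
#' @export
angular_mean <- function(p, t, phi0 = 0, phi_dot0 = 0) {
  stopifnot(inherits(p, "abp_params"), all(t >= 0))
  phi0 + p$omega * t +
    (p$omega - phi_dot0) * p$tau_r * (exp(-t / p$tau_r) - 1)
}

#' @rdname angular_mean
#' @export
angular_variance <- function(p, t) {
  stopifnot(inherits(p, "abp_params"), all(t >= 0))
  E1 <- exp(-t / p$tau_r) - 1
  2 * p$D_r * t + 2 * p$D_r * p$tau_r * (E1 - E1^2 / 2)
}

#' @rdname angular_mean
#' @export
angular_pdf <- function(p, phi, t, phi0 = 0, phi_dot0 = 0) {
  stopifnot(length(t) == 1L, t > 0)
  stats::dnorm(phi, mean = angular_mean(p, t, phi0, phi_dot0),
               sd = sqrt(angular_variance(p, t)))
}

#' @rdname angular_mean
#' @export
angular_velocity_pdf <- function(p, phi_dot) {
  stopifnot(inherits(p, "abp_params"))
  if (p$D_r == 0)
    stop("the stationary angular velocity distribution is degenerate for D_r = 0",
         call. = FALSE)
  stats::dnorm(phi_dot, mean = p$omega, sd = sqrt(p$D_r / p$tau_r))
}

#' @rdname angular_mean
#' @export
angular_msd_analytic <- function(p, t) {
  stopifnot(inherits(p, "abp_params"), all(t >= 0))
  p$omega^2 * t^2 +
    2 * p$D_r * (t - p$tau_r * (1 - exp(-t / p$tau_r)))
}

# --- stationary velocity distributions -------------------------------------

#' Stationary velocity distributions of the mixture form
#'
#' The stationary distribution of one Cartesian velocity component is well
#' described by an isotropic Gaussian of variance \eqn{q} centred on a
#' circle of propulsion speed \eqn{W}:
#' \deqn{P(\dot X) = \frac{1}{2\pi\sqrt{2\pi q}} \int_{-\pi}^{\pi}
#'   \exp\left(-\frac{(\dot X - W\cos\phi)^2}{2q}\right) d\phi,}
#' which develops the characteristic double peak of active motion when
#' \eqn{W^2 \gg q}.  The corresponding speed distribution is the Rice
#' density \eqn{P(v) = (v/q) e^{-(v^2+W^2)/2q} I_0(v W / q)}.
#' `match_qW` fixes \eqn{(q, W)} by matching the second and fourth moments
#' of the mixture, \eqn{\langle\dot X^2\rangle = q + W^2/2} and
#' \eqn{\langle\dot X^4\rangle = 3q^2 + 3 q W^2 + \tfrac{3}{8} W^4}, to the
#' model moments: the second moment is \eqn{D/\tau + f V_p^2/2} and the
#' fourth moment is computed from the Gaussian four-point function of the
#' angle process by exact Gauss-Laguerre quadrature (see
#' \code{vignette("underdamped-abp")}).  The matching yields the closed
#' forms \eqn{W^4 = \tfrac{8}{3}(3 m_2^2 - m_4)}, \eqn{q = m_2 - W^2/2};
#' it is feasible whenever the model kurtosis lies between the circular
#' (3/2) and Gaussian (3) limits, and signals an error otherwise.
#'
#' @param v Velocity evaluation points, m/s.
#' @param q Gaussian variance, m^2/s^2, positive.
#' @param W Effective propulsion speed, m/s, non-negative.
#' @param n_nodes Number of Chebyshev nodes for the angular mixture.
#' @param p An [abp_params()] object.
#' @return Densities, or for `match_qW` a list with elements `q`, `W`,
#'   `m2`, `m4`.
#' @export
linear_velocity_pdf <- function(v, q, W, n_nodes = 256L) {
  stopifnot(q > 0, W >= 0)
  if (W == 0) return(stats::dnorm(v, 0, sqrt(q)))
  # (1/2pi) Int dphi f(cos phi) = (1/N) sum f(cos theta_k), Chebyshev nodes
  ck <- cos((2 * seq_len(n_nodes) - 1) * pi / (2 * n_nodes))
  rowMeans(outer(v, ck, function(vv, cc) stats::dnorm(vv, W * cc, sqrt(q))))
}

#' @rdname linear_velocity_pdf
#' @export
speed_pdf <- function(v, q, W) {
  stopifnot(q > 0, W >= 0)
  out <- numeric(length(v))
  i <- v > 0
  out[i] <- v[i] / q * exp(-(v[i] - W)^2 / (2 * q)) *
    besselI(v[i] * W / q, 0, expon.scaled = TRUE)
  out
}

#' @rdname linear_velocity_pdf
#' @export
match_qW <- function(p) {
  stopifnot(inherits(p, "abp_params"))
  sT2 <- p$D / p$tau
  m2a <- f_delay(delay_numbers(p)) * p$v_p^2 / 2
  m2 <- sT2 + m2a
  m4 <- 3 * sT2^2 + 6 * sT2 * m2a + active_fourth_moment(p)
  W4 <- 8 / 3 * (3 * m2^2 - m4)
  if (W4 < -1e-8 * m2^2)
    stop("moment matching infeasible: model kurtosis exceeds Gaussian",
         call. = FALSE)
  W <- max(W4, 0)^0.25
  q <- m2 - W^2 / 2
  if (q <= 0)
    stop("moment matching infeasible: non-positive Gaussian variance",
         call. = FALSE)
  list(q = q, W = W, m2 = m2, m4 = m4)
}

# Fourth moment of the active (orientation-filtered) part of one velocity
# component.  The stationary active velocity is the exponential filter of
# V_p cos(phi); since phi is Gaussian, the four-point function
# <cos phi_1 ... cos phi_4> reduces to three terms exp(-V/2) cos(omega m)
# over the sign patterns with zero net winding, with V a signed sum of the
# stationary angle structure function at the six pairwise lags.  Ordering
# times and integrating out the overall time shift leaves a 3-D integral
# over the inter-point gaps, done by tensor Gauss-Laguerre quadrature in
# units of tau.
active_fourth_moment <- function(p, n_nodes = 16L) {
  if (p$v_p == 0) return(0)
  gl <- gl_cache(n_nodes)
  tau <- p$tau
  g <- expand.grid(i = gl$x, j = gl$x, k = gl$x)
  wts <- expand.grid(i = gl$w, j = gl$w, k = gl$w)
  a <- tau * g$i / 3; b <- tau * g$j / 2; cc <- tau * g$k
  s2 <- function(h) 2 * p$D_r * (h - p$tau_r * (1 - exp(-h / p$tau_r)))
  sa <- s2(a); sb <- s2(b); sc <- s2(cc)
  sab <- s2(a + b); sbc <- s2(b + cc); sabc <- s2(a + b + cc)
  V1 <- sa + sb + sc + sabc - sab - sbc        # pattern + - + -
  V2 <- sa + sab + sbc + sc - sb - sabc        # pattern + - - +
  V3 <- sab + sabc + sb + sbc - sa - sc        # pattern + + - -
  G <- exp(-V1 / 2) * cos(p$omega * (a + cc)) +
    exp(-V2 / 2) * cos(p$omega * (a - cc)) +
    exp(-V3 / 2) * cos(p$omega * (a + 2 * b + cc))
  p$v_p^4 / 8 * sum(wts$i * wts$j * wts$k * G)
}
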