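#' Model parameters for an underdamped active Brownian particle
#'
#' The dynamics of an inertial self-propelled particle are governed by the
#' coupled Langevin equations
#' \deqn{M \ddot R + \xi \dot R = \xi V_p n + \xi \sqrt{2D} f(t),}
#' \deqn{J \ddot\phi + \xi_r \dot\phi = \tau_0 + \xi_r \sqrt{2 D_r}\, \eta(t),}
#' with orientation vector \eqn{n = (\cos\phi, \sin\phi)} and unit-variance
#' white noises \eqn{f}, \eqn{\eta}.  Trajectories only identify the six
#' rates and coefficients
#' \itemize{
#'   \item \code{tau}   translational relaxation time \eqn{\tau = M/\xi} (s),
#'   \item \code{tau_r} rotational relaxation time \eqn{\tau_r = J/\xi_r} (s),
#'   \item \code{D}     translational short-time diffusion coefficient (m^2/s),
#'   \item \code{D_r}   rotational diffusion coefficient (rad^2/s),
#'   \item \code{v_p}   propulsion speed \eqn{V_p} (m/s),
#'   \item \code{omega} mean angular velocity \eqn{\omega = \tau_0/\xi_r} (rad/s),
#' }
#' so the package parameterises the model by these six and carries the
#' absolute scales \code{M} (kg), \code{J} (kg m^2), \code{xi} (kg/s),
#' \code{xi_r} (kg m^2/s) and \code{tau_0} (N m) as optional metadata.  When
#' absolute scales are supplied they must be mutually consistent with the
#' rates (\code{tau * xi == M}, \code{tau_r * xi_r == J},
#' \code{omega * xi_r == tau_0}) to relative tolerance 1e-12.
#'
#' All quantities are SI; angles are radians and are stored unwrapped.
#'
#' @param tau Translational relaxation time (s), positive.
#' @param tau_r Rotational relaxation time (s), positive.
#' @param D Translational diffusion coefficient (m^2/s), non-negative.
#' @param D_r Rotational diffusion coefficient (rad^2/s), non-negative.
#' @param v_p Propulsion speed (m/s), non-negative.
#' @param omega Mean angular velocity (rad/s), any sign.
#' @param M,J,xi,xi_r,tau_0 Optional absolute scales (see Details).
#'
#' @return An object of class \code{"abp_params"}: a list with the six rates
#'   and any absolute scales provided (missing scales are completed when they
#'   follow from the ones given, e.g. \code{xi = M/tau}).
#' @seealso [as_abp_params()], [delay_numbers()], [abp_preset()]
#' @export
#' @examples
#' p <- abp_params(tau = 1/6.46, tau_r = 1/5.4, D = 8e-5, D_r = 2.59,
#'                 v_p = 0.092, omega = 0.7)
#' delay_numbers(p)
abp_params <- function(tau, tau_r, D, D_r, v_p, omega,
                       M = NULL, J = NULL, xi = NULL, xi_r = NULL,
                       tau_0 = NULL) {
  chk_num <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("%s must be a finite numeric scalar", nm), call. = FALSE)
    as.numeric(x)
  }
  tau   <- chk_num(tau, "tau");     tau_r <- chk_num(tau_r, "tau_r")
  D     <- chk_num(D, "D");         D_r   <- chk_num(D_r, "D_r")
  v_p   <- chk_num(v_p, "v_p");     omega <- chk_num(omega, "omega")
  if (tau <= 0)   stop("tau must be positive", call. = FALSE)
  if (tau_r <= 0) stop("tau_r must be positive", call. = FALSE)
  if (D < 0)      stop("D must be non-negative", call. = FALSE)
  if (D_r < 0)    stop("D_r must be non-negative", call. = FALSE)
  if (v_p < 0)    stop("v_p must be non-negative", call. = FALSE)

  # complete absolute scales where they follow from the ones given
  if (!is.null(M) && is.null(xi))    xi   <- M / tau
  if (!is.null(xi) && is.null(M))    M    <- xi * tau
  if (!is.null(J) && is.null(xi_r))  xi_r <- J / tau_r
  if (!is.null(xi_r) && is.null(J))  J    <- xi_r * tau_r
  if (!is.null(xi_r) && is.null(tau_0)) tau_0 <- omega * xi_r

  rel_ok <- function(a, b) {
    ref <- max(abs(a), abs(b))
    ref == 0 || abs(a - b) <= 1e-12 * ref
  }
  if (!is.null(M) && !is.null(xi) && !rel_ok(tau * xi, M))
    stop("inconsistent absolute scales: tau * xi != M", call. = FALSE)
  if (!is.null(J) && !is.null(xi_r) && !rel_ok(tau_r * xi_r, J))
    stop("inconsistent absolute scales: tau_r * xi_r != J", call. = FALSE)
  if (!is.null(tau_0) && !is.null(xi_r) && !rel_ok(omega * xi_r, tau_0))
    stop("inconsistent absolute scales: omega * xi_r != tau_0", call. = FALSE)

  structure(
    list(tau = tau, tau_r = tau_r, D = D, D_r = D_r, v_p = v_p,
         omega = omega, M = M, J = J, xi = xi, xi_r = xi_r, tau_0 = tau_0),
    class = "abp_params")
}

#' Build model parameters from a flat named list
#'
#' Accepts the six rates either directly (\code{tau}, \code{tau_r}) or as the
#' friction rates quoted in experimental work (\code{xi_over_M} = 1/tau,
#' \code{xir_over_J} = 1/tau_r), plus any of the optional absolute scales.
#' Unknown names are rejected.
#'
#' @param x Named list (or named numeric vector) of coefficients.
#' @return An [abp_params()] object.
#' @export
#' @examples
#' as_abp_params(list(xi_over_M = 6.5, xir_over_J = 5.5, D = 1e-4,
#'                    D_r = 1, v_p = 0.1, omega = 0))
as_abp_params <- function(x) {
  if (inherits(x, "abp_params")) return(x)
  if (is.numeric(x) && !is.null(names(x))) x <- as.list(x)
  if (!is.list(x) || is.null(names(x)) || any(names(x) == ""))
    stop("parameters must be a fully named list", call. = FALSE)
  known <- c("tau", "tau_r", "D", "D_r", "v_p", "omega",
             "xi_over_M", "xir_over_J",
             "M", "J", "xi", "xi_r", "tau_0")
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(x$xi_over_M)) {
    if (!is.null(x$tau)) stop("give either tau or xi_over_M, not both",
                              call. = FALSE)
    x$tau <- 1 / x$xi_over_M
    x$xi_over_M <- NULL
  }
  if (!is.null(x$xir_over_J)) {
    if (!is.null(x$tau_r)) stop("give either tau_r or xir_over_J, not both",
                                call. = FALSE)
    x$tau_r <- 1 / x$xir_over_J
    x$xir_over_J <- NULL
  }
  need <- c("tau", "tau_r", "D", "D_r", "v_p", "omega")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing parameter(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  do.call(abp_params, x)
}

#' Read or write model parameters as flat JSON
#'
#' The on-disk format is a flat JSON object whose keys are exactly the field
#' names accepted by [as_abp_params()].  A read of a written file reproduces
#' the parameters exactly (17 significant digits are written).
#'
#' @param path File path.
#' @param p An [abp_params()] object.
#' @return \code{read_abp_params} returns an [abp_params()] object;
#'   \code{write_abp_params} returns \code{path} invisibly.
#' @export
read_abp_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_abp_params(x)
}

#' @rdname read_abp_params
#' @export
write_abp_params <- function(p, path) {
  stopifnot(inherits(p, "abp_params"))
  x <- p[!vapply(p, is.null, logical(1))]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Dimensionless delay numbers
#'
#' The ratios comparing rotational diffusion, circling and translational
#' relaxation to the rotational relaxation time:
#' \deqn{\mathcal{D}_0 = D_r \tau_r,\quad \mathcal{D}_1 = \omega \tau_r,\quad
#'       \mathcal{D}_2 = \tau_r/\tau.}
#' They control the strength of the inertial delay between orientation and
#' velocity and enter every closed-form result of the model.
#'
#' @param p An [abp_params()] object.
#' @return Object of class \code{"abp_delay_numbers"}: list with elements
#'   \code{d0}, \code{d1}, \code{d2}.
#' @export
delay_numbers <- function(p) {
  stopifnot(inherits(p, "abp_params"))
  structure(list(d0 = p$D_r * p$tau_r,
                 d1 = p$omega * p$tau_r,
                 d2 = p$tau_r / p$tau),
            class = "abp_delay_numbers")
}

#' Reference parameter sets
#'
#' Two parameter sets used throughout the package examples and tests:
#' \describe{
#'   \item{\code{"fig2"}}{a generic vibrationally driven particle:
#'     \eqn{1/\tau} = 6.46 1/s, \eqn{1/\tau_r} = 5.4 1/s, D = 8e-5 m^2/s,
#'     D_r = 2.59 1/s, V_p = 0.092 m/s, omega = 0.7 rad/s.}
#'   \item{\code{"fig6"}}{a hypothetical particle used to expose the MSD
#'     regime structure: M = 4 g, J = 1.5e-7 kg m^2, \eqn{\xi/M} = 6.5 1/s,
#'     \eqn{\xi_r/J} = 5.5 1/s, D = 1e-4 m^2/s, D_r = 1 1/s, V_p = 0.1 m/s,
#'     omega = 0.  \code{"fig6_scaled"} reduces the material density: M and J
#'     (hence tau and tau_r) are multiplied by \code{fraction} at fixed
#'     \eqn{\xi}, \eqn{\xi_r}, D, D_r, V_p, omega.}
#' }
#'
#' @param name One of \code{"fig2"}, \code{"fig6"}, \code{"fig6_scaled"}.
#' @param fraction Density reduction factor for \code{"fig6_scaled"},
#'   positive.
#' @return An [abp_params()] object.
#' @export
#' @examples
#' abp_preset("fig2")
#' abp_preset("fig6_scaled", 1e-4)
abp_preset <- function(name = c("fig2", "fig6", "fig6_scaled"),
                       fraction = 1) {
  name <- match.arg(name)
  if (name == "fig2")
    return(abp_params(tau = 1 / 6.46, tau_r = 1 / 5.4, D = 8e-5, D_r = 2.59,
                      v_p = 0.092, omega = 0.7))
  base <- list(M = 4e-3, J = 1.5e-7, tau = 1 / 6.5, tau_r = 1 / 5.5,
               D = 1e-4, D_r = 1, v_p = 0.1, omega = 0)
  if (name == "fig6_scaled") {
    if (!is.numeric(fraction) || length(fraction) != 1L || fraction <= 0)
      stop("fraction must be a positive scalar", call. = FALSE)
    # density reduction at fixed xi, xi_r: M, J, tau, tau_r all scale
    base$M <- base$M * fraction
    base$J <- base$J * fraction
    base$tau <- base$tau * fraction
    base$tau_r <- base$tau_r * fraction
  }
  do.call(abp_params, base)
}

#' @export
print.abp_params <- function(x, ...) {
  cat("Underdamped active Brownian particle parameters\n")
  cat(sprintf("  tau   = %.6g s      (1/tau   = %.6g 1/s)\n",
              x$tau, 1 / x$tau))
  cat(sprintf("  tau_r = %.6g s      (1/tau_r = %.6g 1/s)\n",
              x$tau_r, 1 / x$tau_r))
  cat(sprintf("  D     = %.6g m^2/s\n", x$D))
  cat(sprintf("  D_r   = %.6g rad^2/s\n", x$D_r))
  cat(sprintf("  v_p   = %.6g m/s\n", x$v_p))
  cat(sprintf("  omega = %.6g rad/s\n", x$omega))
  opt <- c("M", "J", "xi", "xi_r", "tau_0")
  has <- opt[!vapply(x[opt], is.null, logical(1))]
  if (length(has))
    cat("  absolute scales:",
        paste(sprintf("%s = %.6g", has, unlist(x[has])), collapse = ", "),
        "\n")
  d <- delay_numbers(x)
  cat(sprintf("  delay numbers: D0 = %.4g, D1 = %.4g, D2 = %.4g\n",
              d$d0, d$d1, d$d2))
  invisible(x)
}

#' @export
print.abp_delay_numbers <- function(x, ...) {
  cat(sprintf("delay numbers: D0 = %.6g, D1 = %.6g, D2 = %.6g\n",
              x$d0, x$d1, x$d2))
  invisible(x)
}
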