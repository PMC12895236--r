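#' Exclusion rate from fitness-fluctuation statistics
#'
#' The compound parameter \eqn{\gamma = 2 \sigma_r^2 \tau} sets the pace of
#' fluctuation-driven dominance and extinction (the "rate of stochastic
#' exclusion"): the cross-species variance of time-integrated fitnesses grows
#' asymptotically as \eqn{\gamma t}.
#'
#' @param sigma_r stationary fitness standard deviation (1/time), >= 0.
#' @param tau fitness autocorrelation time (time), > 0.
#' @return The exclusion rate \eqn{\gamma} (1/time).
#' @seealso [sigma_from_gamma_tau()] for the inverse.
#' @examples
#' gamma_from_sigma_tau(0.05, 10)   # 0.05
#' @export
gamma_from_sigma_tau <- function(sigma_r, tau) {
  if (any(tau <= 0)) stop("tau must be positive")
  if (any(sigma_r < 0)) stop("sigma_r must be non-negative")
  2 * sigma_r^2 * tau
}

#' @rdname gamma_from_sigma_tau
#' @param gamma exclusion rate (1/time), >= 0.
#' @export
sigma_from_gamma_tau <- function(gamma, tau) {
  if (any(tau <= 0)) stop("tau must be positive")
  if (any(gamma < 0)) stop("gamma must be non-negative")
  sqrt(gamma / (2 * tau))
}

#' Fitness-noise parameter set
#'
#' Bundles the statistics of the fluctuating, density-independent part of the
#' per-capita growth rate ("fitness"): per-species mean \eqn{r_i^*},
#' stationary s.d. \eqn{\sigma_r}, autocorrelation time \eqn{\tau}, and the
#' derived exclusion rate \eqn{\gamma = 2\sigma_r^2\tau}.  Exactly one of
#' `sigma_r`, `gamma` must be supplied (the other is derived); supplying both
#' is accepted only if consistent.
#'
#' @param mean_fitness per-species mean fitness \eqn{r_i^*} (1/time); a scalar
#'   is recycled at simulation time.
#' @param sigma_r stationary fitness s.d. (1/time).
#' @param tau autocorrelation time (time), > 0 for `ou`/`periodic` modes.
#' @param gamma exclusion rate \eqn{2\sigma_r^2\tau} (1/time).
#' @param mode one of `"ou"` (Ornstein-Uhlenbeck, default), `"periodic"`
#'   (deterministic oscillation \eqn{r^* + \sqrt{2}\sigma_r\cos(t/\tau-\phi)}),
#'   `"white_limit"` (the \eqn{\tau \to 0} Stratonovich white-noise limit of
#'   amplitude \eqn{\sqrt\gamma}, handled inside the integrators).
#' @param phases per-species phases (radians), periodic mode only; drawn
#'   uniformly on \eqn{[0, 2\pi)} at simulation time when `NULL`.
#' @return An object of class `noise_params`.
#' @examples
#' noise_params(mean_fitness = 1, gamma = 0.05, tau = 10)
#' @export
noise_params <- function(mean_fitness = 1, sigma_r = NULL, tau = 10,
                         gamma = NULL, mode = c("ou", "periodic", "white_limit"),
                         phases = NULL) {
  mode <- match.arg(mode)
  if (!all(is.finite(mean_fitness))) stop("mean_fitness must be finite")
  if (tau <= 0 && mode != "white_limit") stop("tau must be positive")
  if (is.null(sigma_r) && is.null(gamma))
    stop("supply one of sigma_r, gamma")
  if (is.null(sigma_r)) {
    sigma_r <- sigma_from_gamma_tau(gamma, tau)
  } else if (is.null(gamma)) {
    gamma <- gamma_from_sigma_tau(sigma_r, tau)
  } else if (abs(gamma - gamma_from_sigma_tau(sigma_r, tau)) >
             1e-8 * max(gamma, 1e-12)) {
    stop("inconsistent (sigma_r, gamma, tau): gamma must equal 2*sigma_r^2*tau")
  }
  structure(list(mean_fitness = mean_fitness, sigma_r = sigma_r, tau = tau,
                 gamma = gamma, mode = mode, phases = phases),
            class = "noise_params")
}

#' @export
print.noise_params <- function(x, ...) {
  cat("<noise_params>", x$mode, "\n")
  cat(sprintf("  mean fitness r*: %s\n",
              paste(format(unique(x$mean_fitness)), collapse = ", ")))
  cat(sprintf("  sigma_r = %g, tau = %g, gamma = %g\n",
              x$sigma_r, x$tau, x$gamma))
  invisible(x)
}

# recycle per-species means; internal
expand_means <- function(params, n_species) {
  m <- params$mean_fitness
  if (length(m) == 1) rep(m, n_species)
  else if (length(m) == n_species) m
  else stop("mean_fitness has length ", length(m), ", expected 1 or ",
            n_species)
}

#' Sample Ornstein-Uhlenbeck fitness trajectories
#'
#' Draws per-species OU paths on an arbitrary strictly increasing time grid
#' using the exact discrete transition over each interval (mean reversion
#' \eqn{e^{-\Delta t/\tau}}, conditional s.d.
#' \eqn{\sigma_r\sqrt{1-e^{-2\Delta t/\tau}}}), so the step size never biases
#' the stationary statistics.  Species are independent.
#'
#' @param params a [noise_params()] with `mode = "ou"`.
#' @param n_species number of species (independent paths).
#' @param times strictly increasing time grid.
#' @param seed optional integer seed (`set.seed` is called when supplied).
#' @param init `"stationary"` draws \eqn{r(0) \sim N(r^*, \sigma_r^2)};
#'   `"mean"` starts every path at its mean \eqn{r^*}.
#' @param increments optional `(length(times)-1) x n_species` matrix of
#'   standard-normal increments.  Supplying the same matrix to calls with
#'   different `tau` realises the shared-randomness protocol: the paths are
#'   then deterministic functions of one common increment stream.
#' @return A `length(times) x n_species` fitness matrix (1/time).
#' @export
sample_fitness_paths <- function(params, n_species, times, seed = NULL,
                                 init = c("stationary", "mean"),
                                 increments = NULL) {
  init <- match.arg(init)
  if (params$mode == "white_limit")
    stop("white_limit mode has no finite-variance paths; ",
         "it is handled inside the integrators as a diffusion term")
  if (params$mode != "ou") stop("sample_fitness_paths requires mode = 'ou'")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!is.null(seed)) set.seed(seed)
  rs <- expand_means(params, n_species)
  if (!is.null(increments)) {
    increments <- as.matrix(increments)
    if (nrow(increments) != length(times) - 1 ||
        ncol(increments) != n_species)
      stop("increments must be (length(times)-1) x n_species")
  }
  r0 <- if (init == "stationary") rs + params$sigma_r * stats::rnorm(n_species)
        else rs
  ou_paths_cpp(r0, rs, params$sigma_r, params$tau, as.numeric(times),
               increments)
}

#' Deterministic periodic fitness trajectories
#'
#' \eqn{r_i(t) = r_i^* + \sqrt{2}\,\sigma_r \cos(t/\tau - \phi_i)}.  The
#' \eqn{\sqrt 2} amplitude makes the time-average variance over whole periods
#' equal \eqn{\sigma_r^2}, matching the OU stationary variance so that the
#' two noise types are compared at equal \eqn{\gamma}.
#'
#' @inheritParams sample_fitness_paths
#' @return A `length(times) x n_species` fitness matrix.
#' @export
periodic_fitness <- function(params, n_species, times, seed = NULL) {
  rs <- expand_means(params, n_species)
  phi <- params$phases
  if (is.null(phi)) {
    if (!is.null(seed)) set.seed(seed)
    phi <- stats::runif(n_species, 0, 2 * pi)
  }
  if (length(phi) != n_species) stop("phases must have length n_species")
  amp <- sqrt(2) * params$sigma_r
  outer(as.numeric(times) / params$tau, phi, function(t, p) cos(t - p)) *
    amp + matrix(rs, length(times), n_species, byrow = TRUE)
}

#' Draw heterogeneous mean fitnesses
#'
#' Breaks time-averaged neutrality by drawing species means i.i.d. uniform on
#' \eqn{[r^* - \delta r^*, r^* + \delta r^*]}; \eqn{\delta r^* = 0} returns
#' the neutral vector.
#'
#' @param r_star community mean fitness (1/time).
#' @param delta_r_star half-width \eqn{\delta r^*}, with
#'   \eqn{0 \le \delta r^* \le r^*} so fitness means stay positive.
#' @param n_species number of species.
#' @param seed optional integer seed.
#' @return Numeric vector of length `n_species`.
#' @export
draw_mean_fitnesses <- function(r_star, delta_r_star, n_species, seed = NULL) {
  if (delta_r_star < 0) stop("delta_r_star must be non-negative")
  if (delta_r_star > r_star)
    stop("delta_r_star must not exceed r_star (fitness means stay positive)")
  if (delta_r_star == 0) return(rep(r_star, n_species))
  if (!is.null(seed)) set.seed(seed)
  stats::runif(n_species, r_star - delta_r_star, r_star + delta_r_star)
}
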