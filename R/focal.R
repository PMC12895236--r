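#' Effective noise parameters of a focal species
#'
#' In the focal-species reduction, the community's influence on one species
#' is absorbed into an effective fluctuating environment
#' \eqn{\dot n = n\, r_{\rm eff}(t) - \varepsilon n^2 + \lambda}, with
#' \eqn{r_{\rm eff}} an OU process of mean `r_eff`, s.d. `sigma_eff` and
#' correlation time `tau_eff`; `gamma_eff = 2 sigma_eff^2 tau_eff` is
#' derived.
#'
#' @param r_eff mean effective fitness (1/time).
#' @param sigma_eff stationary s.d. of the effective fitness (1/time).
#' @param tau_eff effective correlation time (time), > 0.
#' @return Object of class `effective_params`.
#' @export
effective_params <- function(r_eff, sigma_eff, tau_eff) {
  if (sigma_eff < 0) stop("sigma_eff must be non-negative")
  if (tau_eff <= 0) stop("tau_eff must be positive")
  structure(list(r_eff = r_eff, sigma_eff = sigma_eff, tau_eff = tau_eff,
                 gamma_eff = 2 * sigma_eff^2 * tau_eff),
            class = "effective_params")
}

#' @export
print.effective_params <- function(x, ...) {
  cat(sprintf(
    "<effective_params> r_eff = %.4g, sigma_eff = %.4g, tau_eff = %.4g, gamma_eff = %.4g\n",
    x$r_eff, x$sigma_eff, x$tau_eff, x$gamma_eff))
  invisible(x)
}

# integrated autocorrelation time: dt * (1/2 + sum of normalized acf up to
# its first non-positive value); the half-weight on lag 0 removes the O(dt)
# discretization bias of the plain Riemann sum.
integrated_act <- function(x, dt, lag_max = NULL) {
  nx <- length(x)
  if (is.null(lag_max)) lag_max <- min(nx - 1, 5000L)
  ac <- stats::acf(x, lag.max = lag_max, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  rho <- ac[-1]
  cut <- which(rho <= 0)[1]
  if (!is.na(cut)) rho <- rho[seq_len(cut - 1)]
  dt * (0.5 + sum(rho))
}

# alternative estimator: exponential fit to the acf head (cross-check)
exp_fit_act <- function(x, dt, lag_max = NULL) {
  nx <- length(x)
  if (is.null(lag_max)) lag_max <- min(nx - 1, 5000L)
  ac <- stats::acf(x, lag.max = lag_max, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  keep <- which(ac > 0.05)
  keep <- keep[keep <= which.max(c(ac <= 0.05, TRUE))]
  lags <- (keep - 1) * dt
  -1 / stats::coef(stats::lm(log(ac[keep]) ~ lags))[["lags"]]
}

#' Estimate effective noise parameters from a trajectory
#'
#' Builds the effective-fitness series \eqn{x_i(t) = r_i(t) - \mu N(t)} for
#' the focal species (or pooled over all species under time-averaged
#' neutrality) after discarding a burn-in fraction, and estimates
#' `r_eff` (time mean), `sigma_eff` (s.d.) and `tau_eff` (integrated
#' autocorrelation time with first-zero-crossing cutoff; an exponential-fit
#' alternative is available via `method`).
#'
#' @param trajectory a `trajectory` with recorded fitness.
#' @param focal focal species index, or `NULL` to pool across species.
#' @param burn_in fraction of records discarded from the start.
#' @param method autocorrelation-time estimator: `"integrated"` (default)
#'   or `"exp_fit"`.
#' @return An [effective_params()].
#' @export
estimate_effective_params <- function(trajectory, focal = NULL,
                                      burn_in = 0.2,
                                      method = c("integrated", "exp_fit")) {
  method <- match.arg(method)
  times <- trajectory$times
  keep <- times >= min(times) + burn_in * (max(times) - min(times))
  r <- trajectory$fitness[keep, , drop = FALSE]
  n <- trajectory$abundance[keep, , drop = FALSE]
  mu <- trajectory$params$mu
  x <- r - mu * rowSums(n)
  dt <- stats::median(diff(times[keep]))
  act_fun <- if (method == "integrated") integrated_act else exp_fit_act
  if (!is.null(focal)) {
    if (focal < 1 || focal > ncol(x)) stop("focal index out of range")
    xi <- x[, focal]
    tau_eff <- act_fun(xi, dt)
    m <- mean(xi); v <- stats::var(xi)
  } else {
    m <- mean(colMeans(x))
    v <- mean(apply(x, 2, stats::var))
    tau_eff <- mean(apply(x, 2, act_fun, dt = dt))
  }
  if (nrow(x) * dt < 50 * tau_eff)
    stop("estimation unreliable: series shorter than 50 * tau_eff")
  effective_params(r_eff = m, sigma_eff = sqrt(v), tau_eff = tau_eff)
}

#' GIG shape predicted from effective parameters
#'
#' Fast-environment stationary-distribution map:
#' \eqn{\nu = 1 - 2 r_{\rm eff}^*/\gamma_{\rm eff}},
#' \eqn{a = \gamma_{\rm eff}/(2\varepsilon)}, \eqn{b = 2\lambda/\gamma_{\rm
#' eff}}.  Degenerate inputs (\eqn{\varepsilon = 0} or \eqn{\lambda = 0})
#' give the flagged `a = Inf` / `b = 0` limits, proper only for
#' \eqn{\nu > 1} / \eqn{\nu < 1} respectively.
#'
#' @param eff an [effective_params()] with `gamma_eff > 0`.
#' @param epsilon excess self-regulation.
#' @param lam immigration rate.
#' @return A [gig_params()].
#' @examples
#' gig_shape(effective_params(0, sqrt(0.05 / 20), 10), epsilon = 0.05,
#'           lam = 3.2e-5)
#' @export
gig_shape <- function(eff, epsilon, lam) {
  stopifnot(inherits(eff, "effective_params"))
  g <- eff$gamma_eff
  if (g <= 0) stop("gig_shape requires gamma_eff > 0")
  gig_params(nu = 1 - 2 * eff$r_eff / g,
             a = if (epsilon > 0) g / (2 * epsilon) else Inf,
             b = 2 * lam / g)
}

#' Simulate the focal-species effective model
#'
#' Integrates \eqn{\dot n = n\, r_{\rm eff}(t) - \varepsilon n^2 + \lambda}
#' with OU noise by the same splitting scheme as [simulate_community()]
#' (one species, no shared competition).  With `fast_limit = TRUE` the
#' \eqn{\tau \to 0} Stratonovich white-noise limit of amplitude
#' \eqn{\sqrt{\gamma_{\rm eff}}} is integrated by a Heun
#' predictor-corrector; its stationary histogram converges to [dgig()] with
#' the [gig_shape()] parameters.
#'
#' @param eff an [effective_params()].
#' @param epsilon,lam self-regulation and immigration of the focal equation.
#' @param horizon,dt,record_every,seed as in [simulate_community()]; the
#'   default step is `tau_eff/20` (OU) or `0.01/gamma_eff` (fast limit).
#' @param init initial abundance (default: the deterministic balance
#'   `r_eff/epsilon` when positive, else `sqrt(ab)`-like interior scale).
#' @param fast_limit use the white-noise limit.
#' @return A `trajectory` with a single species column.
#' @export
simulate_focal <- function(eff, epsilon, lam, horizon, dt = NULL,
                           record_every = 1L, seed = NULL, init = NULL,
                           fast_limit = FALSE) {
  stopifnot(inherits(eff, "effective_params"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dt))
    dt <- if (fast_limit) 0.01 / max(eff$gamma_eff, 1e-8)
          else eff$tau_eff / 20
  if (is.null(init)) {
    init <- if (eff$r_eff > 0 && epsilon > 0) eff$r_eff / epsilon
            else if (epsilon > 0) eff$gamma_eff / (2 * epsilon)
            else 1
  }
  n_steps <- max(1L, as.integer(round(horizon / dt)))
  record_every <- max(1L, as.integer(record_every))
  mode_code <- if (fast_limit) 2L else 0L
  r0 <- if (fast_limit) eff$r_eff
        else eff$r_eff + eff$sigma_eff * stats::rnorm(1)
  res <- sim_community_cpp(init, r0, eff$r_eff, eff$sigma_eff,
                           eff$tau_eff, eff$gamma_eff, 0, epsilon, lam, 0,
                           dt, n_steps, record_every, mode_code,
                           numeric(1), 0)
  params <- community_params(n_species = 1, r_star = max(eff$r_eff, 1e-12),
                             carrying_capacity = 1e12, epsilon = epsilon,
                             lam = lam, n_ext = 0,
                             noise = noise_params(
                               mean_fitness = eff$r_eff,
                               sigma_r = max(eff$sigma_eff, 0),
                               tau = eff$tau_eff,
                               mode = if (fast_limit) "white_limit" else "ou"))
  new_trajectory(res$times, res$abundance, res$fitness, params, seed,
                 state = list(n = res$n_final, r = res$r_final,
                              t = n_steps * dt, dt = dt))
}
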