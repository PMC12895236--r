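#' Community model parameters
#'
#' Parameters of the single-patch growth equation
#' \deqn{\dot n_i = n_i (r_i(t) - \mu N - \varepsilon n_i) + \lambda,}
#' where \eqn{N = \sum_j n_j}, heterospecific competition has strength
#' \eqn{\mu = r^*/K}, conspecifics compete with \eqn{\mu + \varepsilon}
#' ("excess self-regulation" \eqn{\varepsilon}), \eqn{\lambda} is a constant
#' net immigration rate, and abundances below the extinction threshold
#' `n_ext` are set to zero.
#'
#' @param n_species number of species S.
#' @param r_star community mean fitness \eqn{r^*} (1/time); per-species means
#'   can be set through `noise$mean_fitness`.
#' @param carrying_capacity K: total abundance at the deterministic neutral
#'   equilibrium; \eqn{\mu = r^*/K}.
#' @param epsilon excess self-regulation \eqn{\varepsilon}
#'   (1/(abundance x time)), >= 0.
#' @param lam immigration rate \eqn{\lambda} (abundance/time), >= 0.
#' @param n_ext extinction threshold (abundance); 0 disables the cutoff.
#' @param noise a [noise_params()]; defaults to the baseline OU noise
#'   \eqn{\gamma = 0.05}, \eqn{\tau = 10} at `mean_fitness = r_star`.
#' @return An object of class `community_params` with derived field `mu`.
#' @examples
#' community_params(n_species = 100, epsilon = 0, lam = 0)
#' @export
community_params <- function(n_species = 100, r_star = 1,
                             carrying_capacity = 1, epsilon = 0, lam = 0,
                             n_ext = 0, noise = NULL) {
  if (n_species < 1) stop("n_species must be >= 1")
  if (carrying_capacity <= 0) stop("carrying_capacity must be positive")
  if (epsilon < 0 || lam < 0 || n_ext < 0)
    stop("epsilon, lam and n_ext must be non-negative")
  if (is.null(noise))
    noise <- noise_params(mean_fitness = r_star, gamma = 0.05, tau = 10)
  stopifnot(inherits(noise, "noise_params"))
  structure(list(n_species = as.integer(n_species), r_star = r_star,
                 carrying_capacity = carrying_capacity,
                 mu = r_star / carrying_capacity,
                 epsilon = epsilon, lam = lam, n_ext = n_ext, noise = noise),
            class = "community_params")
}

#' @export
print.community_params <- function(x, ...) {
  cat(sprintf("<community_params> S = %d, r* = %g, K = %g (mu = %g)\n",
              x$n_species, x$r_star, x$carrying_capacity, x$mu))
  cat(sprintf("  epsilon = %g, lambda = %g, n_ext = %g\n",
              x$epsilon, x$lam, x$n_ext))
  print(x$noise)
  invisible(x)
}

default_dt <- function(params) {
  tau <- if (params$noise$mode == "white_limit") Inf else params$noise$tau
  min(tau, 1 / params$r_star) / 20
}

new_trajectory <- function(times, abundance, fitness, params, seed,
                           state = NULL) {
  colnames(abundance) <- paste0("sp", seq_len(ncol(abundance)))
  colnames(fitness) <- colnames(abundance)
  structure(list(times = times, abundance = abundance, fitness = fitness,
                 params = params, seed = seed, state = state),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d species, %d records, t in [%g, %g]\n",
              ncol(x$abundance), nrow(x$abundance),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Simulate the single-patch community
#'
#' Integrates the growth equation by operator splitting per step: (i) exact
#' OU fitness transition, (ii) multiplicative (exponential-Euler) growth
#' `n <- n * exp((r_mid - mu*N - eps*n) * dt)` with midpoint fitness, (iii)
#' additive immigration `n <- n + lam*dt`, (iv) extinction cutoff.  The
#' scheme preserves positivity and, because the recorded fitness grid is
#' integrated trapezoidally by [replicator_solution()], reproduces the
#' replicator formal solution exactly when `epsilon = lam = 0`.
#'
#' @param params a [community_params()].
#' @param init initial abundances; default is the perfectly even community
#'   `K/S`.  A `trajectory` may also be given to continue from its final
#'   state (its stored fitness state is reused).
#' @param horizon total simulated time.
#' @param dt integration step; default `min(tau, 1/r_star)/20`.  A warning is
#'   issued when `dt > tau` (noise under-resolved).
#' @param record_every record every k-th step (thins output, not dynamics).
#' @param seed optional integer seed controlling all randomness.
#' @param fitness_init `"stationary"` (default) draws
#'   \eqn{r(0) \sim N(r^*,\sigma_r^2)}; `"mean"` starts at \eqn{r(0)=r^*}
#'   (the even-start baseline protocol); ignored if `r_init` given.
#' @param r_init optional vector of initial fitness values.
#' @return A `trajectory`: aligned `times`, `abundance` and `fitness`
#'   matrices (rows = times), the parameters, the seed, and the exact final
#'   state for continuation.
#' @examples
#' p <- community_params(n_species = 20)
#' tr <- simulate_community(p, horizon = 50, seed = 1)
#' tr
#' @export
simulate_community <- function(params, init = NULL, horizon, dt = NULL,
                               record_every = 1L, seed = NULL,
                               fitness_init = c("stationary", "mean"),
                               r_init = NULL) {
  fitness_init <- match.arg(fitness_init)
  stopifnot(inherits(params, "community_params"))
  if (horizon <= 0) stop("horizon must be positive")
  if (is.null(dt)) dt <- default_dt(params)
  S <- params$n_species
  noise <- params$noise
  if (noise$mode != "white_limit" && dt > noise$tau)
    warning("dt > tau: fitness noise under-resolved")
  if (!is.null(seed)) set.seed(seed)

  state <- NULL
  if (inherits(init, "trajectory")) { state <- init$state; init <- NULL }
  if (is.null(init) && is.null(state))
    init <- rep(params$carrying_capacity / S, S)
  if (!is.null(state)) { init <- state$n; r_init <- state$r; t0 <- state$t }
  else t0 <- 0
  if (length(init) != S) stop("init must have length n_species")
  if (any(init < 0)) stop("initial abundances must be non-negative")

  rs <- expand_means(noise, S)
  mode_code <- match(noise$mode, c("ou", "periodic", "white_limit")) - 1L
  phases <- noise$phases
  if (mode_code == 1L) {
    if (is.null(phases)) phases <- stats::runif(S, 0, 2 * pi)
    if (length(phases) != S) stop("phases must have length n_species")
  } else phases <- numeric(S)
  if (is.null(r_init)) {
    r_init <- switch(noise$mode,
      ou = if (fitness_init == "stationary")
             rs + noise$sigma_r * stats::rnorm(S) else rs,
      periodic = rs + sqrt(2) * noise$sigma_r * cos(t0 / noise$tau - phases),
      white_limit = rs)
  }

  n_steps <- max(1L, as.integer(round(horizon / dt)))
  record_every <- max(1L, as.integer(record_every))
  res <- sim_community_cpp(as.numeric(init), as.numeric(r_init), rs,
                           noise$sigma_r,
                           if (noise$mode == "white_limit") 1 else noise$tau,
                           noise$gamma, params$mu, params$epsilon,
                           params$lam, params$n_ext,
                           dt, n_steps, record_every, mode_code, phases, t0)
  new_trajectory(res$times, res$abundance, res$fitness, params, seed,
                 state = list(n = res$n_final, r = res$r_final,
                              t = t0 + n_steps * dt, dt = dt))
}

#' Cumulative time-integrated fitness
#'
#' \eqn{R_i(t) = \int_0^t r_i \, dt'} by cumulative trapezoidal quadrature on
#' the recorded grid.  Across species with stationary OU fitness the variance
#' of \eqn{R_i(t)} grows with asymptotic slope \eqn{\gamma} for
#' \eqn{t \gg \tau} (closed form
#' \eqn{2\sigma_r^2\tau\,(t - \tau(1 - e^{-t/\tau}))}).
#'
#' @param fitness times x species fitness matrix.
#' @param times time grid aligned with `fitness` rows.
#' @return Matrix of the same shape; first row is zero.
#' @export
integrated_fitness <- function(fitness, times) {
  fitness <- as.matrix(fitness)
  if (nrow(fitness) != length(times))
    stop("fitness rows and times must align")
  dtv <- diff(times)
  mid <- (fitness[-1, , drop = FALSE] +
          fitness[-nrow(fitness), , drop = FALSE]) / 2
  out <- rbind(0, apply(mid * dtv, 2, cumsum))
  dimnames(out) <- dimnames(fitness)
  out
}

#' Exact replicator-equation solution
#'
#' Relative abundances under uniform competition obey the replicator equation
#' \eqn{\dot p_i = p_i (r_i - \rho)} with \eqn{\rho = \sum_j r_j p_j}, whose
#' formal solution is
#' \eqn{p_i(t) = p_i(0) e^{R_i(t)} / \sum_j p_j(0) e^{R_j(t)}} with
#' \eqn{R_i} the time-integrated fitness.  Computed with a log-sum-exp shift
#' for numerical safety; serves as an exact oracle for the integrator when
#' `epsilon = lam = n_ext = 0`.
#'
#' @inheritParams integrated_fitness
#' @param p0 initial relative abundances (on the simplex).
#' @param tol tolerance on `sum(p0) == 1`.
#' @return Times x species matrix of relative abundances; rows sum to 1.
#' @export
replicator_solution <- function(fitness, times, p0, tol = 1e-8) {
  fitness <- as.matrix(fitness)
  if (length(p0) != ncol(fitness)) stop("p0 must have one entry per species")
  if (any(p0 < 0) || abs(sum(p0) - 1) > tol)
    stop("p0 must lie on the simplex (non-negative, summing to 1)")
  R <- integrated_fitness(fitness, times)
  lw <- sweep(R, 2, log(ifelse(p0 > 0, p0, NA)), "+")
  lw[, p0 == 0] <- -Inf
  m <- apply(lw, 1, max)
  w <- exp(lw - m)
  out <- w / rowSums(w)
  dimnames(out) <- dimnames(fitness)
  out
}

#' Focal-species fitness advantage
#'
#' For a focal species \eqn{f}, \eqn{\Delta r_f(t) = r_f(t) -
#' \rho_{\setminus f}(t)}, where \eqn{\rho_{\setminus f}} averages fitness
#' over the non-focal species weighted by their within-subcommunity relative
#' abundances.  The focal relative abundance then obeys the two-species-like
#' closure \eqn{\dot p_f = \Delta r_f \, p_f (1 - p_f)}.  Because the weights
#' favour abundant (typically lucky) species, \eqn{\Delta r_f} has a negative
#' bias: every species is biased towards rarity.
#'
#' @param trajectory a `trajectory` (needs S >= 2).
#' @param focal focal species index.
#' @return Numeric vector \eqn{\Delta r_f(t)} on the trajectory's grid.
#' @export
focal_delta_r <- function(trajectory, focal) {
  n <- trajectory$abundance
  r <- trajectory$fitness
  S <- ncol(n)
  if (S < 2) stop("focal_delta_r requires at least 2 species")
  if (focal < 1 || focal > S) stop("focal index out of range")
  nn <- n[, -focal, drop = FALSE]
  tot <- rowSums(nn)
  w <- nn / ifelse(tot > 0, tot, NA)
  r[, focal] - rowSums(r[, -focal, drop = FALSE] * w)
}

#' Write / read a trajectory as delimited text
#'
#' The abundance (and optionally fitness) matrix is written as
#' tab-separated text with a `time` column and one column per species, plus
#' a JSON sidecar (`<file>.json`) holding the parameters and seed.
#'
#' @param trajectory a `trajectory`.
#' @param file path of the abundance table; fitness goes to
#'   `<file base>_fitness.tsv` when `fitness = TRUE`.
#' @param fitness also write the fitness matrix (default TRUE).
#' @return `file`, invisibly.
#' @export
write_trajectory <- function(trajectory, file, fitness = TRUE) {
  ab <- data.frame(time = trajectory$times, trajectory$abundance,
                   check.names = FALSE)
  utils::write.table(ab, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (fitness && !is.null(trajectory$fitness)) {
    ff <- data.frame(time = trajectory$times, trajectory$fitness,
                     check.names = FALSE)
    utils::write.table(ff, sub("(\\.[^.]+)?$", "_fitness.tsv", file),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  p <- trajectory$params
  side <- list(seed = trajectory$seed,
               params = list(n_species = p$n_species, r_star = p$r_star,
                             carrying_capacity = p$carrying_capacity,
                             epsilon = p$epsilon, lam = p$lam,
                             n_ext = p$n_ext,
                             noise = p$noise[c("sigma_r", "tau", "gamma",
                                               "mode")]))
  jsonlite::write_json(side, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(file)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(file) {
  ab <- utils::read.delim(file, check.names = FALSE)
  times <- ab$time
  abm <- as.matrix(ab[, -1, drop = FALSE])
  ffile <- sub("(\\.[^.]+)?$", "_fitness.tsv", file)
  fm <- if (file.exists(ffile)) {
    as.matrix(utils::read.delim(ffile, check.names = FALSE)[, -1,
                                                            drop = FALSE])
  } else matrix(NA_real_, nrow(abm), ncol(abm))
  params <- NULL
  seed <- NULL
  jfile <- paste0(file, ".json")
  if (file.exists(jfile)) {
    side <- jsonlite::read_json(jfile, simplifyVector = TRUE)
    seed <- side$seed
    pp <- side$params
    params <- community_params(
      n_species = pp$n_species, r_star = pp$r_star,
      carrying_capacity = pp$carrying_capacity, epsilon = pp$epsilon,
      lam = pp$lam, n_ext = pp$n_ext,
      noise = noise_params(mean_fitness = pp$r_star,
                           sigma_r = pp$noise$sigma_r, tau = pp$noise$tau,
                           mode = pp$noise$mode))
  }
  new_trajectory(times, abm, fm, params, seed)
}
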