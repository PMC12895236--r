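test_that("gig_params validates shapes and flags degenerate limits", {
  expect_equal(gig_params(1, 0.5, 1e-3)$limit, "proper")
  expect_equal(gig_params(0.5, 2, 0)$limit, "gamma")
  expect_equal(gig_params(2, Inf, 1e-2)$limit, "inverse_gamma")
  expect_error(gig_params(1.2, 2, 0), "nu < 1")
  expect_error(gig_params(0.8, Inf, 1e-2), "nu > 1")
  expect_error(gig_params(1, Inf, 0), "improper")
  expect_error(gig_params(1, -1, 0.1), "positive")
})

test_that("gig_pdf normalizes to 1 and matches its limiting forms", {
  sh <- gig_params(1, 0.5, 1.28e-3)
  expect_equal(integrate(function(x) dgig(x, sh), 0, Inf,
                         rel.tol = 1e-9)$value, 1, tolerance = 1e-6)
  # gamma limit: b -> 0 with nu < 1 equals dgamma(shape 1-nu, scale a)
  x <- 10^seq(-4, 1, by = 0.25)
  shg <- gig_params(0.4, 0.7, 0)
  expect_equal(dgig(x, shg), dgamma(x, shape = 0.6, scale = 0.7),
               tolerance = 1e-10)
  tiny <- gig_params(0.4, 0.7, 1e-12)
  expect_equal(dgig(x, tiny), dgamma(x, shape = 0.6, scale = 0.7),
               tolerance = 1e-4)
  # nu = 0: density matches quadrature-normalized kernel
  sh0 <- gig_params(0, 1, 0.05)
  kern <- function(x) exp(-x - 0.05 / x)
  Z <- integrate(kern, 0, Inf, rel.tol = 1e-10)$value
  expect_equal(dgig(x, sh0), kern(x) / Z, tolerance = 1e-6)
  # log density consistency and zero below support
  expect_equal(dgig(x, sh, log = TRUE), log(dgig(x, sh)))
  expect_equal(dgig(c(-1, 0), sh), c(0, 0))
})

test_that("pgig/qgig/rgig are mutually consistent", {
  sh <- gig_params(0.8, 1, 1e-2)
  p <- c(0.05, 0.25, 0.5, 0.9)
  expect_equal(pgig(qgig(p, sh), sh), p, tolerance = 1e-3)
  s <- rgig(20000, sh, seed = 5)
  ks <- suppressWarnings(ks.test(s, function(q) pgig(q, sh)))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("gig_shape maps effective parameters per the stationary solution", {
  # r_eff = 0 => nu = 1; bends from gamma_eff/(2 eps) and 2 lam/gamma_eff
  eff0 <- effective_params(0, sigma_from_gamma_tau(0.05, 10), 10)
  sh <- gig_shape(eff0, epsilon = 0.05, lam = 3.2e-5)
  expect_equal(sh$nu, 1)
  expect_equal(sh$a, 0.5)
  expect_equal(sh$b, 1.28e-3)
  # Ex-like immigration
  expect_equal(gig_shape(eff0, 0.05, 1e-8)$b, 4e-7)
  # negative mean effective fitness => nu > 1 (immigration-sustained)
  effn <- effective_params(-0.01, sigma_from_gamma_tau(0.05, 10), 10)
  expect_gt(gig_shape(effn, 0.05, 3.2e-5)$nu, 1)
  # degenerate flags propagate
  expect_equal(gig_shape(effn, 0, 3.2e-5)$limit, "inverse_gamma")
  expect_error(gig_shape(effective_params(0.1, 0, 1), 1, 1), "gamma_eff")
})

test_that("effective parameters are recovered within 10% from synthetic OU input", {
  m <- 0.3; s <- 0.2; tau <- 1
  np <- noise_params(m, sigma_r = s, tau = tau)
  times <- seq(0, 1e4, by = 0.25)   # length 1e4 * tau
  r <- sample_fitness_paths(np, 2, times, seed = 606)
  tr <- new_trajectory(times, matrix(0, length(times), 2), r,
                       community_params(n_species = 2), seed = 606)
  for (focal in list(1, NULL)) {   # single species and pooled
    eff <- estimate_effective_params(tr, focal = focal, burn_in = 0)
    expect_lt(abs(eff$r_eff - m), 0.1 * m)
    expect_lt(abs(eff$sigma_eff - s) / s, 0.1)
    expect_lt(abs(eff$tau_eff - tau) / tau, 0.1)
  }
  # noiseless neutral community at equilibrium: x = r* - mu K = 0
  pn <- community_params(n_species = 5,
                         noise = noise_params(1, sigma_r = 1e-9, tau = 10))
  trn <- simulate_community(pn, horizon = 4000, record_every = 20,
                            fitness_init = "mean")
  effn <- estimate_effective_params(trn, burn_in = 0.5)
  expect_lt(abs(effn$r_eff), 1e-6)
  # too-short series errors
  short <- new_trajectory(times[1:100], matrix(0, 100, 2), r[1:100, ],
                          community_params(n_species = 2), seed = 1)
  expect_error(estimate_effective_params(short, focal = 1, burn_in = 0),
               "unreliable")
})

test_that("noiseless focal dynamics settle at r_eff/epsilon", {
  eff <- effective_params(0.4, 0, 1)
  tr <- simulate_focal(eff, epsilon = 0.2, lam = 0, horizon = 100,
                       init = 0.01)
  expect_equal(unname(tr$abundance[nrow(tr$abundance), 1]), 2,
               tolerance = 1e-5)
})

test_that("fast-limit focal stationary distribution matches the GIG prediction", {
  eff <- effective_params(0, sigma_from_gamma_tau(0.05, 10), 10)
  sh <- gig_shape(eff, 0.05, 3.2e-5)   # nu = 1, a = 0.5, b = 1.28e-3
  tr <- simulate_focal(eff, 0.05, 3.2e-5, horizon = 3e5, seed = 99,
                       fast_limit = TRUE, record_every = 25)
  s <- tr$abundance[-seq_len(500), 1]
  ks <- suppressWarnings(ks.test(s, function(q) pgig(q, sh)))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("fast-limit histogram matches gig_pdf across a shape grid (Fokker-Planck oracle)", {
  # well-mixing shapes (gamma = 1) spanning nu < 1, = 1, > 1 and bend ratios
  grid <- expand.grid(r_eff = c(0.2, 0, -0.2), lam = c(2e-3, 2e-4))
  for (k in seq_len(nrow(grid))) {
    eff <- effective_params(grid$r_eff[k], sigma_from_gamma_tau(1, 0.5), 0.5)
    sh <- gig_shape(eff, epsilon = 0.5, lam = grid$lam[k])
    tr <- simulate_focal(eff, 0.5, grid$lam[k], horizon = 2e4, seed = 40 + k,
                         fast_limit = TRUE, record_every = 25)
    s <- tr$abundance[-seq_len(200), 1]
    ks <- suppressWarnings(ks.test(s, function(q) pgig(q, sh)))
    expect_lt(unname(ks$statistic), 0.05)
  }
})

test_that("finite-tau focal model still yields a bent power law of similar slope", {
  eff <- effective_params(0, sigma_from_gamma_tau(0.05, 10), 10)
  tr <- simulate_focal(eff, 0.05, 3.2e-5, horizon = 2e5, seed = 7,
                       record_every = 20)
  h <- sad_histogram(tr$abundance[-seq_len(1000), 1])
  si <- shape_indices(h)
  expect_lt(abs(si$nu_logfit - 1), 0.3)
})

test_that("maximum-likelihood GIG fit recovers parameters and nested limits", {
  sh <- gig_params(1, 0.5, 1e-3)
  s <- rgig(1e5, sh, seed = 314)
  fit <- fit_gig(s)
  expect_equal(fit$convergence, 0)
  expect_lt(abs(fit$shape$nu - 1), 0.1)
  expect_gt(fit$gof, 0.85)
  # gamma samples drive the lower bend to zero
  g <- rgamma(2e4, shape = 0.5, scale = 1)
  fitg <- fit_gig(g)
  expect_lt(fitg$shape$b, 1e-3 * median(g))
  expect_lt(abs(fitg$shape$nu - 0.5), 0.15)
  expect_error(fit_gig(rep(2, 1000)), "degenerate")
  expect_error(fit_gig(runif(100)), "500")
})

test_that("pooled and per-species effective estimates agree under time-averaged neutrality", {
  p <- fig1_params(S = 30)
  tr <- simulate_community(p, horizon = 3000, record_every = 10, seed = 55)
  pooled <- estimate_effective_params(tr, burn_in = 0.2)
  per <- lapply(c(3, 17), function(i)
    estimate_effective_params(tr, focal = i, burn_in = 0.2))
  for (e in per) {
    expect_lt(abs(e$sigma_eff - pooled$sigma_eff) / pooled$sigma_eff, 0.25)
    expect_lt(abs(e$tau_eff - pooled$tau_eff) / pooled$tau_eff, 0.5)
    expect_lt(abs(e$r_eff - pooled$r_eff), 3 * pooled$sigma_eff /
                sqrt(3000 / (2 * pooled$tau_eff)))
  }
})
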