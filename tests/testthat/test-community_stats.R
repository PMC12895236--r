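test_that("effective richness covers even, dominant and hand-computed cases", {
  expect_equal(effective_richness(rep(1, 100)), 100)
  expect_equal(effective_richness(c(1, rep(0, 9))), 1)
  expect_equal(effective_richness(c(0.5, 0.5, 0, 0)), 2)
  # scale invariance and bounds on random communities
  set.seed(10)
  for (k in 1:20) {
    x <- rexp(25)
    expect_equal(effective_richness(x), effective_richness(7.3 * x))
    expect_gte(effective_richness(x), 1)
    expect_lte(effective_richness(x), 25)
  }
  m <- rbind(rep(1, 4), c(1, 0, 0, 0))
  expect_equal(effective_richness(m), c(4, 1))
  expect_error(effective_richness(c(0, 0)), "all-zero")
})

test_that("dominance time interpolates the ensemble-mean crossing", {
  times <- 0:4
  seff <- rbind(c(12, 10, 8, 4, 2), c(8, 6, 4, 4, 2))  # mean: 10 8 6 4 2
  d <- dominance_time(seff, times, threshold = 5)
  expect_false(d$censored)
  expect_equal(d$tc, 2.5)   # crossing between (2,6) and (3,4)
  dc <- dominance_time(c(10, 9, 8), 0:2, threshold = 5)
  expect_true(dc$censored)
  expect_true(is.na(dc$tc))
})

test_that("log-binned histograms integrate to one and match a known density", {
  h1 <- sad_histogram(rep(2.5, 40))
  expect_equal(sum(h1$count > 0), 1)
  set.seed(3)
  x <- rgamma(5e4, shape = 0.5, scale = 1)
  h <- sad_histogram(x)
  w <- diff(attr(h, "edges"))
  expect_equal(sum(h$density * w), 1, tolerance = 1e-12)
  # density per log10(n) is n * P(n) * ln(10)
  big <- h$count > 100
  expected <- dgamma(h$center[big], 0.5, scale = 1) * h$center[big] * log(10)
  expect_equal(h$density[big], expected, tolerance = 0.15)
  expect_error(sad_histogram(numeric(0)), "empty")
  expect_error(sad_histogram(c(0, 0)), "positive")
  expect_equal(attr(sad_histogram(c(0, 1, 2)), "n_zero"), 1)
})

test_that("shape indices recover exponent, width and mode on known densities", {
  set.seed(4)
  x <- rgamma(1e5, shape = 0.5, scale = 1)
  si <- shape_indices(sad_histogram(x))
  expect_lt(abs(si$nu_logfit - 0.5), 0.15)
  # flat-in-log density has logfit nu = 1 (and spans its generation range)
  y <- 10^runif(1e5, -4, 2)
  siy <- shape_indices(sad_histogram(y))
  expect_lt(abs(siy$nu_logfit - 1), 0.1)
  expect_equal(siy$width_decades, 6, tolerance = 0.1)
  expect_true(siy$reliable)
  # narrow distribution flagged unreliable; mode near the mass center
  z <- 10^rnorm(1e5, 0, 0.2)
  siz <- shape_indices(sad_histogram(z))
  expect_false(siz$reliable)
  expect_lt(abs(log10(siz$modal_abundance)), 0.3)
  # eq-18 route and B-Sigma coordinates appear when context is supplied
  eff <- effective_params(0, sigma_from_gamma_tau(0.05, 10), 10)
  sib <- shape_indices(sad_histogram(x), eff = eff, params = bust_params())
  expect_equal(sib$nu_eq18, 1)
  expect_equal(sib$B, 0.32)
  expect_equal(sib$Sigma, 1000)
})

test_that("Bray-Curtis decay is 1 at lag zero, bounded, and label-invariant", {
  p <- fig1_params(S = 20)
  tr <- simulate_community(p, horizon = 1000, record_every = 20, seed = 66)
  bc <- bray_curtis_decay(tr, burn_in = 0.1)
  expect_equal(bc$curve$bc[bc$curve$lag == 0], 1)
  expect_true(all(bc$curve$bc >= 0 & bc$curve$bc <= 1))
  # permuting species labels leaves the curve unchanged
  tr2 <- tr
  perm <- sample(20)
  tr2$abundance <- tr$abundance[, perm]
  bc2 <- bray_curtis_decay(tr2, burn_in = 0.1)
  expect_equal(bc2$curve$bc, bc$curve$bc)
  expect_equal(bc2$asymptote, bc$asymptote)
})

test_that("Buffering-Stabilisation coordinates follow S lam/(K gamma) and K eps/gamma", {
  expect_equal(buffering_stabilisation(bust_params()),
               c(B = 0.32, Sigma = 1000))
  p0 <- community_params(100, lam = 0, epsilon = 1, noise = baseline_noise())
  expect_equal(buffering_stabilisation(p0)[["B"]], 0)
  # doubling gamma halves both coordinates
  p2 <- community_params(500, epsilon = 50, lam = 3.2e-5,
                         noise = noise_params(1, gamma = 0.1, tau = 10))
  expect_equal(unname(buffering_stabilisation(p2)),
               unname(buffering_stabilisation(bust_params())) / 2)
  pg0 <- community_params(10, noise = noise_params(1, sigma_r = 0, tau = 1))
  expect_error(buffering_stabilisation(pg0), "gamma = 0")
})

test_that("richness trajectory counts extant species and reports level crossings", {
  p <- fig1_params(S = 10)
  tr <- simulate_community(p, horizon = 100, record_every = 10, seed = 2)
  rt <- richness_trajectory(tr)   # n_ext = 0: constant S
  expect_true(all(rt$richness$richness == 10))
  pc <- community_params(n_species = 40, n_ext = 1e-4,
                         noise = baseline_noise())
  trc <- simulate_community(pc, horizon = 800, record_every = 20, seed = 13)
  rtc <- richness_trajectory(trc, levels = c(30, 20))
  expect_true(all(diff(rtc$richness$richness) <= 0))
  al <- rtc$at_levels
  expect_equal(al$level, c(30, 20))
  if (!any(is.na(al$time))) expect_true(diff(al$time) >= 0)
})

test_that("SAD pooled over snapshots coincides with a single species' FAD under TAN", {
  # stationary community: self-regulation and immigration give the SAD a
  # true steady state (pure exclusion keeps widening and has no FAD limit)
  p <- community_params(n_species = 40, epsilon = 1, lam = 1e-6,
                        noise = baseline_noise())
  tr <- simulate_community(p, horizon = 8000, record_every = 40, seed = 888)
  keep <- tr$times >= 1600
  hsad <- sad_histogram(tr$abundance[keep, ])
  # distribution-level agreement: log10 quartiles and mid-range slope
  qsad <- hist_quantile_log10(hsad, c(0.25, 0.5, 0.75))
  slopes <- vapply(c(3, 11, 25, 38), function(sp) {
    hfad <- fad_histogram(tr, species = sp, burn_in = 0.2)
    qfad <- hist_quantile_log10(hfad, c(0.25, 0.5, 0.75))
    expect_lt(max(abs(qsad - qfad)), 0.35)
    shape_indices(hfad)$nu_logfit
  }, numeric(1))
  # single-FAD slopes are noisy; their average matches the pooled SAD
  expect_lt(abs(mean(slopes) - shape_indices(hsad)$nu_logfit), 0.3)
})

test_that("mean-fitness heterogeneity biases FADs towards rarity or dominance", {
  rstars <- c(0.7, rep(1, 18), 1.3)   # one laggard, one front-runner
  p <- community_params(n_species = 20, epsilon = 1, lam = 1e-6,
                        noise = noise_params(rstars, gamma = 0.05, tau = 10))
  tr <- simulate_community(p, horizon = 5000, record_every = 20, seed = 4)
  keep <- tr$times > 1000
  lo <- median(tr$abundance[keep, 1])
  hi <- median(tr$abundance[keep, 20])
  mid <- median(tr$abundance[keep, 2:19])
  expect_lt(lo, mid)
  expect_gt(hi, mid)
})

test_that("B-Sigma reference corners land in their regime classes (fast-noise self-consistency)", {
  fast_noise <- noise_params(1, gamma = 0.05, tau = 0.1)
  corner <- function(eps, lam, horizon) {
    p <- community_params(n_species = 500, epsilon = eps, lam = lam,
                          noise = fast_noise)
    tr <- simulate_community(p, horizon = horizon, record_every = 200,
                             seed = 77)
    # tau_eff needs sampling finer than tau: short dense continuation
    trd <- simulate_community(p, init = tr, horizon = 100, record_every = 5)
    tau_eff <- estimate_effective_params(trd, burn_in = 0)$tau_eff
    keep <- tr$times >= 0.4 * horizon
    x <- tr$fitness[keep, ] - p$mu * rowSums(tr$abundance[keep, ])
    eff <- effective_params(mean(x), sd(x), tau_eff)
    shape_indices(sad_histogram(tr$abundance[keep, ]), eff = eff,
                  params = p)
  }
  cap <- function(eps) 1 / (500 + eps)   # single-species balance r*/(mu S + eps)

  # Exclusion: wide power law; predicted and fitted exponents agree
  ex <- corner(0.05, 1e-8, horizon = 5000)
  expect_gt(ex$width_decades, 2)
  expect_true(ex$reliable)
  expect_lt(abs(ex$nu_logfit - ex$nu_eq18), 0.3)
  expect_lt(abs(ex$nu_eq18 - 1), 0.5)

  # Stabilised: rising density (nu < 1, here negative), interior mode near
  # the single-species carrying capacity, narrow (flagged unreliable)
  st <- corner(50, 1e-8, horizon = 1200)
  expect_lt(st$nu_eq18, 1)
  expect_lt(abs(log10(st$modal_abundance / cap(50))), 0.5)
  expect_false(st$reliable)

  # Buffered: steeper power law (nu > 1), mode near the immigration bend
  bu <- corner(0.05, 1e-4, horizon = 1200)
  expect_gt(bu$nu_eq18, 1.1)
  expect_lt(abs(log10(bu$modal_abundance / (2 * 1e-4 / 0.05))), 0.8)

  # Buffered-and-Stabilised: narrow unimodal around the capacity scale
  bs <- corner(50, 1e-4, horizon = 1200)
  expect_lt(bs$width_decades, 2)
  expect_lt(abs(log10(bs$modal_abundance / cap(50))), 0.5)
})
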