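#' Validate and normalize an experiment configuration
#'
#' Accepts a list or a path to a JSON/YAML file.  Fills the baseline
#' defaults (S = 100, K = 1, r* = 1, gamma = 0.05, tau = 10, epsilon = 0,
#' lambda = 0, n_ext = 0; units: abundance in K, time in generations 1/r*),
#' resolves the (sigma_r, gamma, tau) triple through
#' \eqn{\gamma = 2\sigma_r^2\tau} (supplying both inconsistently is an
#' error), checks signs, and echoes derived quantities (`mu`, `sigma_r`).
#'
#' @param config list, or path to a `.json`/`.yaml`/`.yml` file; `NULL` or
#'   an empty list gives the full default set.
#' @return Normalized named list including a ready-made `params`
#'   ([community_params()]) element.
#' @examples
#' cfg <- validate_config(list(gamma = 0.1, tau = 5))
#' cfg$sigma_r   # filled in as sqrt(gamma / (2 tau))
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("config must be a list or a JSON/YAML path")
  defaults <- list(n_species = 100, r_star = 1, carrying_capacity = 1,
                   epsilon = 0, lam = 0, n_ext = 0, tau = 10,
                   gamma = NULL, sigma_r = NULL, mode = "ou",
                   horizon = 1000, dt = NULL, record_every = NULL,
                   delta_r_star = 0)
  unknown_ok <- c("n_runs", "S_values", "tau_values", "eps_factors",
                  "M_values", "d_values", "coupling_mode", "n_draws",
                  "delta_ratios", "burn_in", "threshold", "seed")
  bad <- setdiff(names(config), c(names(defaults), unknown_ok))
  if (length(bad) > 0)
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  for (f in c("n_species", "r_star", "carrying_capacity", "tau", "horizon"))
    if (!is.numeric(cfg[[f]]) || any(cfg[[f]] <= 0))
      stop("config field '", f, "' must be positive")
  for (f in c("epsilon", "lam", "n_ext", "delta_r_star"))
    if (!is.numeric(cfg[[f]]) || any(cfg[[f]] < 0))
      stop("config field '", f, "' must be non-negative")
  if (is.null(cfg$gamma) && is.null(cfg$sigma_r)) cfg$gamma <- 0.05
  noise <- noise_params(mean_fitness = cfg$r_star, sigma_r = cfg$sigma_r,
                        tau = cfg$tau, gamma = cfg$gamma, mode = cfg$mode)
  cfg$sigma_r <- noise$sigma_r
  cfg$gamma <- noise$gamma
  cfg$mu <- cfg$r_star / cfg$carrying_capacity
  cfg$params <- community_params(
    n_species = cfg$n_species, r_star = cfg$r_star,
    carrying_capacity = cfg$carrying_capacity, epsilon = cfg$epsilon,
    lam = cfg$lam, n_ext = cfg$n_ext, noise = noise)
  cfg
}

experiment_names <- c("fig1_baseline", "fig2_scaling", "fig3_tau",
                      "fig4_maintenance", "fig5_sweep",
                      "fig6_heterogeneity")

write_manifest <- function(outdir, name, cfg, scale, seed, files) {
  cfg_out <- cfg[setdiff(names(cfg), "params")]
  manifest <- list(experiment = name, scale = scale, seed = seed,
                   package_version =
                     as.character(utils::packageVersion("fluctcomm")),
                   config = cfg_out, files = files)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}

#' Run a named reference experiment
#'
#' Config-driven reproduction of the model's six in-silico protocols:
#' `fig1_baseline` (single even-start run, pure exclusion),
#' `fig2_scaling` (ensemble dominance-time vs ln S), `fig3_tau`
#' (shared-randomness tau comparison at fixed gamma), `fig4_maintenance`
#' (richness decay under self-regulation and under metacommunity dispersal),
#' `fig5_sweep` (random parameter sweep mapped to the
#' Buffering-Stabilisation plane) and `fig6_heterogeneity` (broken
#' time-averaged neutrality).  Every experiment accepts `scale` to shrink
#' ensembles and horizons deterministically; estimators are unchanged.
#' Outputs: statistics CSVs, trajectory tables where small, a byte-stable
#' `manifest.json` (parameters, seed, version) and a `run.log` with wall
#' times.
#'
#' @param name experiment name (see above).
#' @param config list or JSON/YAML path, normalized by [validate_config()].
#' @param outdir output directory (created if missing).
#' @param scale ensemble/horizon scaling factor in (0, 1].
#' @param seed master integer seed.
#' @return Invisibly, a list of result data.frames (also written to
#'   `outdir`).
#' @export
run_experiment <- function(name, config = list(), outdir, scale = 1,
                           seed = 1) {
  name <- match.arg(name, experiment_names)
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]")
  cfg <- validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t_start <- proc.time()[["elapsed"]]
  res <- switch(name,
    fig1_baseline = exp_fig1(cfg, outdir, scale, seed),
    fig2_scaling = exp_fig2(cfg, outdir, scale, seed),
    fig3_tau = exp_fig3(cfg, outdir, scale, seed),
    fig4_maintenance = exp_fig4(cfg, outdir, scale, seed),
    fig5_sweep = exp_fig5(cfg, outdir, scale, seed),
    fig6_heterogeneity = exp_fig6(cfg, outdir, scale, seed))
  write_manifest(outdir, name, cfg, scale, seed, names(res))
  cat(sprintf("%s: seed=%d scale=%g elapsed=%.1fs\n", name, seed, scale,
              proc.time()[["elapsed"]] - t_start),
      file = file.path(outdir, "run.log"), append = TRUE)
  invisible(res)
}

write_csv_out <- function(df, outdir, file) {
  utils::write.csv(df, file.path(outdir, file), row.names = FALSE)
}

exp_fig1 <- function(cfg, outdir, scale, seed) {
  horizon <- cfg$horizon * 5 * scale
  rec <- max(1L, as.integer(round(horizon / 2000 /
                                    default_dt(cfg$params))))
  tr <- simulate_community(cfg$params, horizon = horizon,
                           record_every = rec, seed = seed,
                           fitness_init = "mean")
  write_trajectory(tr, file.path(outdir, "trajectory.tsv"))
  seff <- data.frame(time = tr$times,
                     seff = effective_richness(tr$abundance))
  write_csv_out(seff, outdir, "seff.csv")
  list(seff = seff)
}

exp_fig2 <- function(cfg, outdir, scale, seed) {
  S_values <- cfg$S_values %||% c(25, 100, 400, 1600)
  n_runs <- cfg$n_runs %||% max(2L, as.integer(round(200 * scale)))
  threshold <- cfg$threshold %||% 5
  horizon <- cfg$horizon * 2.5
  tab <- do.call(rbind, lapply(S_values, function(S) {
    p <- community_params(n_species = S, r_star = cfg$r_star,
                          carrying_capacity = cfg$carrying_capacity,
                          noise = cfg$params$noise)
    rec <- max(1L, as.integer(round(2 / default_dt(p))))
    runs <- lapply(seq_len(n_runs), function(k) {
      tr <- simulate_community(p, horizon = horizon, record_every = rec,
                               seed = seed + 1000L * match(S, S_values) + k,
                               fitness_init = "mean")
      effective_richness(tr$abundance)
    })
    times <- seq(0, horizon, length.out = length(runs[[1]]))
    dres <- dominance_time(runs, times, threshold = threshold)
    data.frame(S = S, log_S = log(S), tc = dres$tc,
               censored = dres$censored, n_runs = n_runs)
  }))
  write_csv_out(tab, outdir, "tc_vs_lnS.csv")
  list(tc_vs_lnS = tab)
}

exp_fig3 <- function(cfg, outdir, scale, seed) {
  tau_values <- cfg$tau_values %||% c(1, 10, 100)
  horizon <- cfg$horizon * scale
  dt <- min(tau_values, 1 / cfg$r_star) / 20  # shared grid => shared draws
  out <- lapply(tau_values, function(tau) {
    p <- community_params(n_species = cfg$n_species, r_star = cfg$r_star,
                          carrying_capacity = cfg$carrying_capacity,
                          noise = noise_params(cfg$r_star,
                                               gamma = cfg$gamma,
                                               tau = tau))
    rec <- max(1L, as.integer(round(1 / dt)))
    tr <- simulate_community(p, horizon = horizon, dt = dt,
                             record_every = rec, seed = seed,
                             fitness_init = "mean")
    data.frame(time = tr$times, tau = tau,
               seff = effective_richness(tr$abundance))
  })
  tab <- do.call(rbind, out)
  write_csv_out(tab, outdir, "seff_by_tau.csv")
  list(seff_by_tau = tab)
}

exp_fig4 <- function(cfg, outdir, scale, seed) {
  n_runs <- cfg$n_runs %||% max(2L, as.integer(round(20 * scale)))
  horizon <- cfg$horizon * 20 * scale
  n_ext <- if (cfg$n_ext > 0) cfg$n_ext else 1e-12 * cfg$carrying_capacity
  eps_factors <- cfg$eps_factors %||% c(0, 0.25, 0.5, 1)
  mu <- cfg$mu
  tab_eps <- do.call(rbind, lapply(eps_factors, function(f) {
    p <- community_params(n_species = cfg$n_species, r_star = cfg$r_star,
                          carrying_capacity = cfg$carrying_capacity,
                          epsilon = f * mu, n_ext = n_ext,
                          noise = cfg$params$noise)
    rec <- max(1L, as.integer(round(horizon / 400 / default_dt(p))))
    rich <- sapply(seq_len(n_runs), function(k) {
      tr <- simulate_community(p, horizon = horizon, record_every = rec,
                               seed = seed + 100L * match(f, eps_factors)
                                 + k)
      richness_trajectory(tr)$richness$richness
    })
    data.frame(time = seq(0, horizon, length.out = nrow(as.matrix(rich))),
               eps_over_mu = f, mean_richness = rowMeans(as.matrix(rich)))
  }))
  write_csv_out(tab_eps, outdir, "richness_vs_eps.csv")

  M_values <- cfg$M_values %||% c(1, 2, 4)
  d_values <- cfg$d_values %||% 0.1
  cmode <- cfg$coupling_mode %||% "total"
  tab_meta <- do.call(rbind, lapply(M_values, function(M) {
    do.call(rbind, lapply(d_values, function(d) {
      base <- community_params(n_species = cfg$n_species,
                               r_star = cfg$r_star,
                               carrying_capacity = cfg$carrying_capacity,
                               n_ext = n_ext, noise = cfg$params$noise)
      mp <- meta_params(M, d, base, coupling_mode = cmode)
      rec <- max(1L, as.integer(round(horizon / 400 / default_dt(base))))
      mt <- simulate_metacommunity(mp, horizon = horizon,
                                   record_every = rec,
                                   seed = seed + 10L * M + 1L)
      rs <- regional_summary(mt)
      data.frame(time = mt$times, M = M, d = d,
                 mean_local_richness = rowMeans(rs$local_richness),
                 regional_richness = rs$regional_richness)
    }))
  }))
  write_csv_out(tab_meta, outdir, "richness_vs_patches.csv")
  list(richness_vs_eps = tab_eps, richness_vs_patches = tab_meta)
}

#' @keywords internal
sweep_draw <- function(n_draws, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    n_species = sample(100:1000, n_draws, replace = TRUE),
    gamma = 10^stats::runif(n_draws, -4, 2),
    tau = 10^stats::runif(n_draws, -2, 2),
    epsilon = 10^stats::runif(n_draws, -2, 2),
    lam = 10^stats::runif(n_draws, -10, -4))
}

exp_fig5 <- function(cfg, outdir, scale, seed) {
  n_draws <- cfg$n_draws %||% max(5L, as.integer(round(100 * scale)))
  draws <- sweep_draw(n_draws, seed = seed)
  burn <- cfg$burn_in %||% 0.2
  rows <- lapply(seq_len(n_draws), function(k) {
    d <- draws[k, ]
    p <- community_params(n_species = d$n_species, r_star = cfg$r_star,
                          carrying_capacity = cfg$carrying_capacity,
                          epsilon = d$epsilon, lam = d$lam,
                          noise = noise_params(cfg$r_star, gamma = d$gamma,
                                               tau = d$tau))
    dt <- max(default_dt(p), cfg$horizon / 2e5)  # bound cost per draw
    rec <- max(1L, as.integer(round(cfg$horizon / 500 / dt)))
    tr <- tryCatch(
      simulate_community(p, horizon = cfg$horizon, dt = dt,
                         record_every = rec, seed = seed + k),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(tr)) return(NULL)
    keep <- tr$times >= burn * cfg$horizon
    h <- tryCatch(sad_histogram(tr$abundance[keep, ]),
                  error = function(e) NULL)
    if (is.null(h)) return(NULL)
    eff <- tryCatch(estimate_effective_params(tr, burn_in = burn),
                    error = function(e) NULL)
    si <- shape_indices(h, eff = eff, params = p)
    bs <- buffering_stabilisation(p)
    data.frame(draw = k, S = d$n_species, gamma = d$gamma, tau = d$tau,
               epsilon = d$epsilon, lam = d$lam, B = bs[["B"]],
               Sigma = bs[["Sigma"]], W = si$width_decades,
               n_star = si$modal_abundance, nu_logfit = si$nu_logfit,
               nu_eq18 = si$nu_eq18, reliable = si$reliable,
               seed = seed + k)
  })
  tab <- do.call(rbind, rows)
  write_csv_out(tab, outdir, "shape_sweep.csv")
  list(shape_sweep = tab)
}

exp_fig6 <- function(cfg, outdir, scale, seed) {
  horizon <- 5e5 * scale
  delta_ratios <- cfg$delta_ratios %||% c(0, 2, 10)
  sets <- list(Ex = list(epsilon = 0.05, lam = 1e-8),
               BuSt = list(epsilon = 50, lam = 3.2e-5))
  # protocol default is S = 500; an explicit config value overrides
  S <- if (cfg$n_species != 100) cfg$n_species else 500
  rows <- list()
  for (set_name in names(sets)) {
    st <- sets[[set_name]]
    for (dr in delta_ratios) {
      noise0 <- noise_params(cfg$r_star, gamma = cfg$gamma, tau = cfg$tau)
      delta <- min(dr * noise0$sigma_r, cfg$r_star)
      rstars <- draw_mean_fitnesses(cfg$r_star, delta, S,
                                    seed = seed + 7L)
      p <- community_params(n_species = S, r_star = cfg$r_star,
                            carrying_capacity = cfg$carrying_capacity,
                            epsilon = st$epsilon, lam = st$lam,
                            noise = noise_params(rstars,
                                                 gamma = cfg$gamma,
                                                 tau = cfg$tau))
      rec <- max(1L, as.integer(round(horizon / 2000 / default_dt(p))))
      tr <- simulate_community(p, horizon = horizon, record_every = rec,
                               seed = seed + match(set_name, names(sets)))
      keep <- tr$times >= 0.2 * horizon
      h <- sad_histogram(tr$abundance[keep, ])
      rows[[paste(set_name, dr)]] <-
        data.frame(set = set_name, delta_ratio = dr,
                   log10_center = h$log10_center, density = h$density)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  write_csv_out(tab, outdir, "fad_heterogeneity.csv")
  list(fad_heterogeneity = tab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
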