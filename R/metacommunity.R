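#' Uniform fully-connected dispersal matrix
#'
#' Builds the M x M rate matrix `D[alpha, beta]` (dispersal from patch beta
#' to patch alpha, zero diagonal) for a fully connected network from a scalar
#' rate `d`.  Two conventions are supported for how `d` scales with M:
#' `"total"` keeps the net per-capita emigration rate equal to `d`
#' (off-diagonal entries `d/(M-1)`), `"per_patch"` keeps the per-target-patch
#' rate at `d/M` as M varies.
#'
#' @param n_patches number of patches M.
#' @param d scalar dispersal rate (1/time).
#' @param coupling_mode `"total"` or `"per_patch"`.
#' @return M x M numeric matrix with zero diagonal.
#' @export
uniform_dispersal <- function(n_patches, d,
                              coupling_mode = c("total", "per_patch")) {
  coupling_mode <- match.arg(coupling_mode)
  if (d < 0) stop("d must be non-negative")
  M <- as.integer(n_patches)
  if (M < 1) stop("n_patches must be >= 1")
  rate <- if (M == 1) 0
          else if (coupling_mode == "total") d / (M - 1) else d / M
  D <- matrix(rate, M, M)
  diag(D) <- 0
  D
}

#' Metacommunity parameters
#'
#' M patches share the single-patch dynamics of [community_params()] but the
#' immigration term is replaced by the net dispersal flux
#' \eqn{\sum_\beta d_{\alpha\beta} n_{i,\beta} - d_{\beta\alpha}
#' n_{i,\alpha}}.  Environmental noise is independent between patches.
#'
#' @param n_patches number of patches M.
#' @param dispersal scalar rate (expanded by [uniform_dispersal()]) or an
#'   M x M rate matrix with zero diagonal.
#' @param base shared [community_params()]; its `lam` should be 0 (dispersal
#'   replaces immigration).
#' @param coupling_mode passed to [uniform_dispersal()] for scalar input.
#' @return Object of class `meta_params`.
#' @export
meta_params <- function(n_patches, dispersal, base,
                        coupling_mode = c("total", "per_patch")) {
  coupling_mode <- match.arg(coupling_mode)
  stopifnot(inherits(base, "community_params"))
  M <- as.integer(n_patches)
  D <- if (is.matrix(dispersal)) dispersal
       else uniform_dispersal(M, dispersal, coupling_mode)
  if (nrow(D) != M || ncol(D) != M)
    stop("dispersal matrix must be ", M, " x ", M)
  if (any(D < 0)) stop("dispersal rates must be non-negative")
  if (any(diag(D) != 0)) stop("dispersal matrix must have zero diagonal")
  structure(list(n_patches = M, dispersal = D, base = base,
                 coupling_mode = coupling_mode),
            class = "meta_params")
}

#' Net dispersal flux between patches
#'
#' `flux[alpha, i] = sum_beta d[alpha,beta]*n[beta,i] -
#' d[beta,alpha]*n[alpha,i]`: immigration into a patch minus emigration out
#' of it.  Dispersal only redistributes individuals, so per-species column
#' sums over patches vanish.
#'
#' @param abundance M x S matrix of patch abundances (non-negative).
#' @param dispersal M x M rate matrix, zero diagonal.
#' @return M x S flux matrix (abundance/time).
#' @export
dispersal_flux <- function(abundance, dispersal) {
  abundance <- as.matrix(abundance)
  if (any(abundance < 0)) stop("abundances must be non-negative")
  if (nrow(dispersal) != nrow(abundance) ||
      ncol(dispersal) != nrow(abundance))
    stop("dispersal matrix shape mismatch")
  dispersal_flux_cpp(abundance, dispersal)
}

#' Simulate a dispersal-coupled metacommunity
#'
#' Each patch evolves by the single-patch splitting scheme of
#' [simulate_community()] with independent OU fitness streams; the dispersal
#' flux is applied to the post-growth abundances each step (positivity is
#' preserved while `max out-rate * dt < 1`), then the extinction cutoff per
#' patch.  Regionally extinct = below cutoff in every patch.
#'
#' @param meta a [meta_params()].
#' @param init M x S matrix of initial abundances; default even community
#'   `K/S` in every patch.
#' @param horizon,dt,record_every,seed as in [simulate_community()].
#' @return A `meta_trajectory`: list of per-patch `trajectory` objects plus
#'   the shared time grid and parameters.
#' @export
simulate_metacommunity <- function(meta, init = NULL, horizon, dt = NULL,
                                   record_every = 1L, seed = NULL) {
  stopifnot(inherits(meta, "meta_params"))
  base <- meta$base
  M <- meta$n_patches
  S <- base$n_species
  noise <- base$noise
  if (noise$mode != "ou")
    stop("metacommunity integration supports OU noise only")
  if (is.null(dt)) dt <- default_dt(base)
  out_max <- max(colSums(meta$dispersal))
  if (out_max * dt >= 1)
    stop("dt too large for dispersal rates (out-rate * dt must be < 1)")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init))
    init <- matrix(base$carrying_capacity / S, M, S)
  init <- as.matrix(init)
  if (nrow(init) != M || ncol(init) != S) stop("init must be M x S")

  rs <- expand_means(noise, S)
  r0 <- matrix(rs, M, S, byrow = TRUE) +
    noise$sigma_r * matrix(stats::rnorm(M * S), M, S)
  n_steps <- max(1L, as.integer(round(horizon / dt)))
  record_every <- max(1L, as.integer(record_every))
  res <- sim_meta_cpp(init, r0, rs, noise$sigma_r, noise$tau, base$mu,
                      base$epsilon, meta$dispersal, base$n_ext,
                      dt, n_steps, record_every)
  patches <- lapply(seq_len(M), function(a) {
    new_trajectory(res$times, res$abundance[, a, , drop = TRUE],
                   res$fitness[, a, , drop = TRUE], base, seed)
  })
  structure(list(patches = patches, times = res$times, meta = meta,
                 seed = seed),
            class = "meta_trajectory")
}

#' @export
print.meta_trajectory <- function(x, ...) {
  cat(sprintf("<meta_trajectory> %d patches x %d species, %d records\n",
              length(x$patches), ncol(x$patches[[1]]$abundance),
              length(x$times)))
  invisible(x)
}

#' Regional (all-patch) abundance and richness summaries
#'
#' @param mtraj a `meta_trajectory`.
#' @return A list with `regional` (times x species summed abundance matrix),
#'   `local_richness` (times x patches counts of species at or above the
#'   cutoff) and `regional_richness` (species extant in at least one patch).
#' @export
regional_summary <- function(mtraj) {
  cutoff <- mtraj$meta$base$n_ext
  thr <- if (cutoff > 0) cutoff else .Machine$double.xmin
  abs_list <- lapply(mtraj$patches, function(p) p$abundance)
  regional <- Reduce(`+`, abs_list)
  local_rich <- vapply(abs_list, function(a) rowSums(a >= thr),
                       numeric(length(mtraj$times)))
  extant_any <- Reduce(`+`, lapply(abs_list, function(a) (a >= thr) * 1L))
  list(regional = regional,
       local_richness = as.matrix(local_rich),
       regional_richness = rowSums(extant_any > 0))
}
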