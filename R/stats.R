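#' Simpson effective richness
#'
#' Reciprocal Simpson index \eqn{S_{\rm eff} = 1/\sum_i p_i^2} on relative
#' abundances; a proxy for the number of dominant species.  Always in
#' `[1, S]`; an even community gives S, monodominance gives 1.
#'
#' @param x non-negative abundance vector, or a times x species matrix
#'   (one value per row).
#' @return Scalar or per-row numeric vector.
#' @examples
#' effective_richness(rep(1, 100))   # 100
#' effective_richness(c(0.5, 0.5, 0))  # 2
#' @export
effective_richness <- function(x) {
  if (is.matrix(x)) return(apply(x, 1, effective_richness))
  if (any(x < 0)) stop("abundances must be non-negative")
  tot <- sum(x)
  if (tot == 0) stop("all-zero abundance vector")
  p <- x / tot
  1 / sum(p^2)
}

#' Time for the ensemble-mean effective richness to decay to a threshold
#'
#' Averages effective-richness series over an ensemble of runs and returns
#' the first time the mean crosses below `threshold`, linearly interpolated
#' between recorded times.  Under pure stochastic exclusion this dominance
#' time scales as \eqn{t_c \sim \ln S / \gamma}.
#'
#' @param seff matrix (runs x times) or list of per-run effective-richness
#'   series; a single series is treated as a one-run ensemble.
#' @param times recorded times (shared across runs).
#' @param threshold richness threshold (default 5, in (1, S)).
#' @return List with `tc` (NA when censored), `censored`, and the ensemble
#'   `mean` series.
#' @export
dominance_time <- function(seff, times, threshold = 5) {
  if (is.list(seff)) seff <- do.call(rbind, seff)
  if (!is.matrix(seff)) seff <- matrix(seff, nrow = 1)
  if (ncol(seff) != length(times)) stop("seff and times must align")
  m <- colMeans(seff)
  below <- which(m < threshold)
  if (length(below) == 0)
    return(list(tc = NA_real_, censored = TRUE, mean = m))
  k <- below[1]
  tc <- if (k == 1) times[1] else {
    # linear interpolation on the crossing segment
    times[k - 1] + (threshold - m[k - 1]) * (times[k] - times[k - 1]) /
      (m[k] - m[k - 1])
  }
  list(tc = tc, censored = FALSE, mean = m)
}

#' Log-binned species-abundance distribution (SAD)
#'
#' Histogram of positive abundances in logarithmic bins
#' (`bins_per_decade` bins per factor of 10), normalized so the integral of
#' the density over log10-abundance is 1.  A matrix input pools rows
#' (snapshots), giving the time-averaged SAD.  Zeros are dropped and counted
#' separately.
#'
#' @param x abundance snapshot (vector) or snapshots x species matrix.
#' @param bins_per_decade bins per decade of abundance.
#' @return A data.frame of class `abund_hist` with columns `center`
#'   (abundance at bin center), `log10_center`, `count` and `density`
#'   (per log10-abundance); attributes `edges` (log10), `n_zero`, `n_total`
#'   and `bins_per_decade`.
#' @export
sad_histogram <- function(x, bins_per_decade = 10) {
  x <- as.numeric(as.matrix(x))
  if (length(x) == 0 || all(is.na(x))) stop("empty input")
  n_zero <- sum(x == 0, na.rm = TRUE)
  x <- x[is.finite(x) & x > 0]
  if (length(x) == 0) stop("no positive abundances")
  lx <- log10(x)
  lo <- floor(min(lx) * bins_per_decade) / bins_per_decade
  hi <- ceiling(max(lx) * bins_per_decade) / bins_per_decade
  if (hi <= lo) hi <- lo + 1 / bins_per_decade
  edges <- seq(lo, hi, by = 1 / bins_per_decade)
  if (edges[length(edges)] < hi) edges <- c(edges, hi)
  cnt <- graphics::hist(lx, breaks = edges, plot = FALSE)$counts
  w <- diff(edges)
  dens <- cnt / sum(cnt) / w
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  out <- data.frame(center = 10^centers, log10_center = centers,
                    count = cnt, density = dens)
  structure(out, class = c("abund_hist", "data.frame"),
            edges = edges, n_zero = n_zero,
            n_total = length(x) + n_zero,
            bins_per_decade = bins_per_decade)
}

#' Frequency-abundance distribution (FAD) of one species
#'
#' Log-binned histogram of a single species' abundance across time, after
#' discarding a burn-in fraction.  Under time-averaged neutrality all
#' species share the same FAD, which coincides with the (time-pooled) SAD.
#'
#' @param trajectory a `trajectory`.
#' @param species species index.
#' @param burn_in fraction of records discarded from the start.
#' @param bins_per_decade bins per decade.
#' @return An `abund_hist` (see [sad_histogram()]).
#' @export
fad_histogram <- function(trajectory, species, burn_in = 0.2,
                          bins_per_decade = 10) {
  times <- trajectory$times
  keep <- times >= min(times) + burn_in * (max(times) - min(times))
  sad_histogram(trajectory$abundance[keep, species],
                bins_per_decade = bins_per_decade)
}

# distribution quantiles (log10 scale) from binned counts, interpolating
# within bins
hist_quantile_log10 <- function(h, probs) {
  edges <- attr(h, "edges")
  cf <- c(0, cumsum(h$count)) / sum(h$count)
  keep <- c(TRUE, diff(cf) > 0)
  stats::approx(cf[keep], edges[keep], xout = probs, rule = 2)$y
}

#' Shape indices of an abundance distribution
#'
#' Summarises an `abund_hist` by the width `W` (decades between the 0.5% and
#' 99.5% quantiles), the modal abundance `n*` (center of the highest-density
#' log-bin), and the power-law exponent \eqn{\nu} estimated two ways:
#' `nu_eq18` \eqn{= 1 - 2 r_{\rm eff}^*/\gamma_{\rm eff}} from effective
#' parameters (when supplied), and `nu_logfit`, one minus the least-squares
#' slope of log10-density versus log10-abundance over the mid-range
#' (`[5b, a/5]` when the predicted bends are proper, else the central half
#' of the spanned decades, which keeps clear of both bends).  `nu` is the positive downward exponent of
#' \eqn{P(n) \propto n^{-\nu}}; negative values mean rising density.
#' Distributions narrower than 2 decades get `reliable = FALSE`.
#'
#' @param density an `abund_hist` from [sad_histogram()]/[fad_histogram()].
#' @param eff optional [effective_params()] for `nu_eq18` and the mid-range.
#' @param params optional [community_params()]; with `eff`, supplies
#'   `epsilon` and `lam` for the predicted bends and the Buffering and
#'   Stabilisation coordinates.
#' @return List of class `shape_summary`: `width_decades`, `modal_abundance`,
#'   `nu_logfit`, `nu_eq18`, `B`, `Sigma`, `reliable`.
#' @export
shape_indices <- function(density, eff = NULL, params = NULL) {
  stopifnot(inherits(density, "abund_hist"))
  qs <- hist_quantile_log10(density, c(0.005, 0.25, 0.75, 0.995))
  W <- qs[4] - qs[1]
  n_star <- density$center[which.max(density$density)]
  shape <- NULL
  if (!is.null(eff) && !is.null(params))
    shape <- tryCatch(gig_shape(eff, params$epsilon, params$lam),
                      error = function(e) NULL)
  if (!is.null(shape) && shape$limit == "proper" &&
      5 * shape$b < shape$a / 5) {
    rng <- log10(c(5 * shape$b, shape$a / 5))
  } else {
    # central half of the spanned decades, clear of both bends
    rng <- c(qs[1] + W / 4, qs[4] - W / 4)
  }
  sel <- density$log10_center >= rng[1] & density$log10_center <= rng[2] &
    density$density > 0
  nu_logfit <- if (sum(sel) >= 3) {
    ld <- log10(density$density[sel])
    lc <- density$log10_center[sel]
    1 - unname(stats::coef(stats::lm(ld ~ lc))[2])
  } else NA_real_
  nu_eq18 <- if (!is.null(eff)) 1 - 2 * eff$r_eff / eff$gamma_eff
             else NA_real_
  bs <- if (!is.null(params))
          tryCatch(buffering_stabilisation(params),
                   error = function(e) c(B = NA_real_, Sigma = NA_real_))
        else c(B = NA_real_, Sigma = NA_real_)
  structure(list(width_decades = W, modal_abundance = n_star,
                 nu_logfit = nu_logfit, nu_eq18 = nu_eq18,
                 B = unname(bs["B"]), Sigma = unname(bs["Sigma"]),
                 reliable = W >= 2),
            class = "shape_summary")
}

#' @export
print.shape_summary <- function(x, ...) {
  cat(sprintf("<shape_summary> W = %.2f decades, n* = %.3g, nu(logfit) = %.3g, nu(eq18) = %.3g%s\n",
              x$width_decades, x$modal_abundance, x$nu_logfit, x$nu_eq18,
              if (!x$reliable) " [W < 2: nu unreliable]" else ""))
  if (is.finite(x$B) || is.finite(x$Sigma))
    cat(sprintf("  B = %.4g, Sigma = %.4g\n", x$B, x$Sigma))
  invisible(x)
}

#' Bray-Curtis similarity decay
#'
#' Average compositional similarity
#' \eqn{BC(t) = \langle \sum_i \min(p_i(s), p_i(s+t)) \rangle_s} between
#' community states a lag t apart, on relative abundances over the
#' stationary (post burn-in) segment.  Decays from 1 at lag 0 towards an
#' asymptote set by the abundance-distribution shape; the asymptote is
#' reported as the mean of BC over the largest quartile of lags.
#'
#' @param trajectory a `trajectory`.
#' @param lags lags in time units (rounded to the record grid); default is
#'   about 40 log-spaced lags spanning the usable range.
#' @param burn_in fraction of records discarded from the start.
#' @param min_pairs lags with fewer pairs are dropped with a warning.
#' @param max_pairs cap on time-pairs sampled per lag (stride subsampling).
#' @return List with `curve` (data.frame `lag`, `bc`, `n_pairs`) and
#'   `asymptote`.
#' @export
bray_curtis_decay <- function(trajectory, lags = NULL, burn_in = 0.2,
                              min_pairs = 10, max_pairs = 400) {
  times <- trajectory$times
  keep <- times >= min(times) + burn_in * (max(times) - min(times))
  n <- trajectory$abundance[keep, , drop = FALSE]
  tt <- times[keep]
  p <- n / rowSums(n)
  T_ <- nrow(p)
  dt <- stats::median(diff(tt))
  if (is.null(lags)) {
    kmax <- T_ - min_pairs
    ks <- unique(c(0, round(exp(seq(0, log(max(kmax, 1)),
                                    length.out = 40)))))
    lags <- ks * dt
  }
  ks <- unique(pmax(0, as.integer(round(lags / dt))))
  usable <- ks <= T_ - min_pairs
  if (any(!usable))
    warning(sum(!usable), " lag(s) dropped: fewer than ", min_pairs,
            " pairs")
  ks <- ks[usable]
  if (length(ks) == 0) stop("no usable lags")
  res <- vapply(ks, function(k) {
    idx <- seq_len(T_ - k)
    if (length(idx) > max_pairs)
      idx <- idx[seq(1, length(idx), length.out = max_pairs)]
    bc <- rowSums(pmin(p[idx, , drop = FALSE], p[idx + k, , drop = FALSE]))
    c(mean(bc), length(idx))
  }, numeric(2))
  curve <- data.frame(lag = ks * dt, bc = res[1, ], n_pairs = res[2, ])
  top <- curve$lag >= stats::quantile(curve$lag, 0.75)
  list(curve = curve, asymptote = mean(curve$bc[top]))
}

#' Buffering and Stabilisation coordinates
#'
#' Composite parameters summarising where a community sits relative to the
#' exclusion rate: Buffering \eqn{B = S\lambda/(K\gamma)} (immigration
#' pressure vs exclusion) and Stabilisation \eqn{\Sigma = K\varepsilon/\gamma}
#' (excess self-regulation vs exclusion).  SAD shape classes organise along
#' these two axes.
#'
#' @param params a [community_params()] with `noise$gamma > 0`.
#' @return Named vector `c(B, Sigma)`.
#' @examples
#' p <- community_params(500, epsilon = 50, lam = 3.2e-5,
#'                       noise = noise_params(1, gamma = 0.05, tau = 10))
#' buffering_stabilisation(p)  # B = 0.32, Sigma = 1000
#' @export
buffering_stabilisation <- function(params) {
  stopifnot(inherits(params, "community_params"))
  g <- params$noise$gamma
  if (g <= 0) stop("undefined for gamma = 0 (no exclusion)")
  K <- params$carrying_capacity
  c(B = params$n_species * params$lam / (K * g),
    Sigma = K * params$epsilon / g)
}

#' Extant-species count over time
#'
#' Number of species at or above the extinction threshold at each recorded
#' time, plus the effective richness evaluated when the count first drops
#' to given levels (the side-panel protocol of richness-decay figures).
#'
#' @param trajectory a `trajectory`.
#' @param n_ext threshold; defaults to the trajectory's own. 0 counts all
#'   species.
#' @param levels optional decreasing absolute-richness levels at which to
#'   report the effective richness.
#' @return List with `richness` (data.frame `time`, `richness`, `seff`) and
#'   `at_levels` (data.frame `level`, `time`, `seff`; NA when not reached).
#' @export
richness_trajectory <- function(trajectory, n_ext = NULL, levels = NULL) {
  if (is.null(n_ext)) n_ext <- trajectory$params$n_ext
  n <- trajectory$abundance
  rich <- if (n_ext > 0) rowSums(n >= n_ext) else rep(ncol(n), nrow(n))
  seff <- effective_richness(n)
  out <- data.frame(time = trajectory$times, richness = rich, seff = seff)
  at_levels <- NULL
  if (!is.null(levels)) {
    at_levels <- do.call(rbind, lapply(levels, function(L) {
      k <- which(rich <= L)[1]
      data.frame(level = L,
                 time = if (is.na(k)) NA_real_ else trajectory$times[k],
                 seff = if (is.na(k)) NA_real_ else seff[k])
    }))
  }
  list(richness = out, at_levels = at_levels)
}
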