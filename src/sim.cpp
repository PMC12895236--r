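#include <Rcpp.h>
using namespace Rcpp;

// Core step loops for the fluctuating-fitness Lotka-Volterra model.
//
// Single-patch dynamics:
//   dn_i/dt = n_i (r_i(t) - mu N - eps n_i) + lambda,   N = sum_j n_j
// with r_i(t) an Ornstein-Uhlenbeck process of mean r*_i, stationary sd
// sigma_r and correlation time tau (or a periodic / white-noise-limit
// stand-in).  Abundances are advanced by exponential-Euler splitting:
//   (i)  exact OU transition r -> r'
//   (ii) n <- n * exp[(r_mid - mu N - eps n) dt],  r_mid = (r + r')/2
//   (iii) n <- n + lambda dt
//   (iv) entries < n_ext set to 0
// The trapezoidal (midpoint) fitness makes the recorded fitness grid
// reproduce the replicator formal solution exactly when eps = lambda = 0.
//
// RNG comes from R (set.seed controls everything).  Draw order is fixed:
// one standard normal per species per step, species index fastest.  Hence
// two runs with equal seed, dt and S share their increment stream even if
// tau differs (the Fig-3 style shared-randomness protocol).

// noise modes
static const int NOISE_OU = 0;
static const int NOISE_PERIODIC = 1;
static const int NOISE_WHITE = 2;

// [[Rcpp::export]]
List sim_community_cpp(NumericVector n0, NumericVector r0,
                       NumericVector r_star, double sigma_r, double tau,
                       double gamma_excl, double mu, double eps,
                       double lambda, double n_ext,
                       double dt, int n_steps, int record_every,
                       int noise_mode, NumericVector phases, double t0) {
  const int S = n0.size();
  const int n_rec = n_steps / record_every;
  NumericMatrix ab(n_rec + 1, S);
  NumericMatrix fit(n_rec + 1, S);
  NumericVector times(n_rec + 1);

  std::vector<double> n(n0.begin(), n0.end());
  std::vector<double> r(r0.begin(), r0.end());

  const double e1 = (noise_mode == NOISE_OU) ? std::exp(-dt / tau) : 0.0;
  const double csd = (noise_mode == NOISE_OU)
    ? sigma_r * std::sqrt(1.0 - e1 * e1) : 0.0;
  const double amp = std::sqrt(2.0) * sigma_r;      // periodic amplitude
  const double sqg = std::sqrt(std::max(gamma_excl, 0.0));
  const double sqdt = std::sqrt(dt);

  times[0] = t0;
  for (int i = 0; i < S; ++i) { ab(0, i) = n[i]; fit(0, i) = r[i]; }

  int rec = 1;
  for (int step = 1; step <= n_steps; ++step) {
    const double t_new = t0 + step * dt;
    double N = 0.0;
    for (int i = 0; i < S; ++i) N += n[i];
    if (!std::isfinite(N))
      stop("integration failure: non-finite total abundance at step %d", step);

    if (noise_mode == NOISE_WHITE) {
      // Heun predictor-corrector for Stratonovich multiplicative noise
      // dn = f(n) dt + sqrt(gamma) n o dW ; f uses start-of-step N for the
      // shared competition term (uniform across species, order-consistent
      // with the splitting scheme).
      std::vector<double> npred(S);
      std::vector<double> dW(S);
      for (int i = 0; i < S; ++i) dW[i] = sqdt * norm_rand();
      double Npred = 0.0;
      for (int i = 0; i < S; ++i) {
        const double f0 = n[i] * (r_star[i] - mu * N - eps * n[i]) + lambda;
        npred[i] = n[i] + f0 * dt + sqg * n[i] * dW[i];
        if (npred[i] < 0.0) npred[i] = 0.0;
        Npred += npred[i];
      }
      for (int i = 0; i < S; ++i) {
        const double f0 = n[i] * (r_star[i] - mu * N - eps * n[i]) + lambda;
        const double f1 = npred[i] * (r_star[i] - mu * Npred - eps * npred[i])
          + lambda;
        double nn = n[i] + 0.5 * (f0 + f1) * dt
          + 0.5 * sqg * (n[i] + npred[i]) * dW[i];
        if (nn < 0.0) nn = 0.0;
        n[i] = nn;
        r[i] = r_star[i];              // fitness column holds the mean
      }
    } else {
      for (int i = 0; i < S; ++i) {
        double r_new;
        if (noise_mode == NOISE_OU) {
          r_new = r_star[i] + (r[i] - r_star[i]) * e1 + csd * norm_rand();
        } else {
          r_new = r_star[i] + amp * std::cos(t_new / tau - phases[i]);
        }
        const double r_mid = 0.5 * (r[i] + r_new);
        const double g = (r_mid - mu * N - eps * n[i]) * dt;
        double nn = n[i] * std::exp(g) + lambda * dt;
        if (!std::isfinite(nn))
          stop("integration failure: species %d non-finite at step %d",
               i + 1, step);
        n[i] = nn;
        r[i] = r_new;
      }
    }

    if (n_ext > 0.0) {
      for (int i = 0; i < S; ++i) if (n[i] < n_ext) n[i] = 0.0;
    }

    if (step % record_every == 0) {
      times[rec] = t_new;
      for (int i = 0; i < S; ++i) { ab(rec, i) = n[i]; fit(rec, i) = r[i]; }
      ++rec;
    }
  }

  return List::create(_["times"] = times, _["abundance"] = ab,
                      _["fitness"] = fit,
                      _["n_final"] = NumericVector(n.begin(), n.end()),
                      _["r_final"] = NumericVector(r.begin(), r.end()));
}

// Net dispersal flux into each patch, accumulated pairwise so that the
// contribution of the (alpha, beta) pair cancels its (beta, alpha) mirror:
// flux[a,i] = sum_b d_ab n[b,i] - d_ba n[a,i].
// [[Rcpp::export]]
NumericMatrix dispersal_flux_cpp(NumericMatrix n, NumericMatrix D) {
  const int M = n.nrow(), S = n.ncol();
  NumericMatrix flux(M, S);
  for (int i = 0; i < S; ++i) {
    for (int a = 0; a < M; ++a) {
      for (int b = a + 1; b < M; ++b) {
        const double v = D(a, b) * n(b, i) - D(b, a) * n(a, i);
        flux(a, i) += v;
        flux(b, i) -= v;
      }
    }
  }
  return flux;
}

// M patches coupled by dispersal matrix D (rate from column patch to row
// patch, zero diagonal); independent OU fitness per patch and species.
// Abundance slab is M x S; recorded as an (n_rec+1) x M x S array.
// [[Rcpp::export]]
List sim_meta_cpp(NumericMatrix n0, NumericMatrix r0, NumericVector r_star,
                  double sigma_r, double tau, double mu, double eps,
                  NumericMatrix D, double n_ext,
                  double dt, int n_steps, int record_every) {
  const int M = n0.nrow(), S = n0.ncol();
  const int n_rec = n_steps / record_every;
  NumericVector ab((n_rec + 1) * M * S);
  NumericVector fit((n_rec + 1) * M * S);
  ab.attr("dim") = IntegerVector::create(n_rec + 1, M, S);
  fit.attr("dim") = IntegerVector::create(n_rec + 1, M, S);
  NumericVector times(n_rec + 1);

  NumericMatrix n(clone(n0)), r(clone(r0));
  const double e1 = std::exp(-dt / tau);
  const double csd = sigma_r * std::sqrt(1.0 - e1 * e1);
  const int T1 = n_rec + 1;

  // out-rate per patch: total emigration rate sum_b d_ba
  std::vector<double> out_rate(M, 0.0);
  for (int a = 0; a < M; ++a)
    for (int b = 0; b < M; ++b) out_rate[a] += D(b, a);

  times[0] = 0.0;
  for (int a = 0; a < M; ++a)
    for (int i = 0; i < S; ++i) {
      ab[0 + T1 * (a + M * i)] = n(a, i);
      fit[0 + T1 * (a + M * i)] = r(a, i);
    }

  NumericMatrix rmid(M, S);
  int rec = 1;
  for (int step = 1; step <= n_steps; ++step) {
    // (i) OU update, patch-major then species (fixed draw order)
    for (int a = 0; a < M; ++a) {
      for (int i = 0; i < S; ++i) {
        const double r_new = r_star[i] + (r(a, i) - r_star[i]) * e1
          + csd * norm_rand();
        rmid(a, i) = 0.5 * (r(a, i) + r_new);
        r(a, i) = r_new;
      }
    }
    // (ii) growth per patch
    for (int a = 0; a < M; ++a) {
      double N = 0.0;
      for (int i = 0; i < S; ++i) N += n(a, i);
      if (!std::isfinite(N))
        stop("integration failure: non-finite total abundance, patch %d step %d",
             a + 1, step);
      for (int i = 0; i < S; ++i)
        n(a, i) *= std::exp((rmid(a, i) - mu * N - eps * n(a, i)) * dt);
    }
    // (iii) dispersal on the post-growth slab (positivity if out_rate*dt < 1)
    for (int i = 0; i < S; ++i) {
      for (int a = 0; a < M; ++a) {
        double in_flux = 0.0;
        for (int b = 0; b < M; ++b) in_flux += D(a, b) * n(b, i);
        rmid(a, i) = n(a, i) + dt * (in_flux - out_rate[a] * n(a, i));
      }
      for (int a = 0; a < M; ++a)
        n(a, i) = rmid(a, i) > 0.0 ? rmid(a, i) : 0.0;
    }
    // (iv) cutoff per patch
    if (n_ext > 0.0) {
      for (int a = 0; a < M; ++a)
        for (int i = 0; i < S; ++i) if (n(a, i) < n_ext) n(a, i) = 0.0;
    }

    if (step % record_every == 0) {
      times[rec] = step * dt;
      for (int a = 0; a < M; ++a)
        for (int i = 0; i < S; ++i) {
          ab[rec + T1 * (a + M * i)] = n(a, i);
          fit[rec + T1 * (a + M * i)] = r(a, i);
        }
      ++rec;
    }
  }

  return List::create(_["times"] = times, _["abundance"] = ab,
                      _["fitness"] = fit);
}

// OU sample paths on an arbitrary strictly increasing time grid, exact
// transition per interval.  increments: (length(times)-1) x S standard
// normals, or R_NilValue to draw from R's RNG (species fastest).
// [[Rcpp::export]]
NumericMatrix ou_paths_cpp(NumericVector r_init, NumericVector r_star,
                           double sigma_r, double tau, NumericVector times,
                           Nullable<NumericMatrix> increments) {
  const int S = r_init.size();
  const int T = times.size();
  NumericMatrix out(T, S);
  for (int i = 0; i < S; ++i) out(0, i) = r_init[i];
  const bool have_inc = increments.isNotNull();
  NumericMatrix inc;
  if (have_inc) inc = increments.get();
  for (int k = 1; k < T; ++k) {
    const double dtk = times[k] - times[k - 1];
    const double e1 = std::exp(-dtk / tau);
    const double csd = sigma_r * std::sqrt(1.0 - e1 * e1);
    for (int i = 0; i < S; ++i) {
      const double z = have_inc ? inc(k - 1, i) : norm_rand();
      out(k, i) = r_star[i] + (out(k - 1, i) - r_star[i]) * e1 + csd * z;
    }
  }
  return out;
}
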