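// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <deque>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Frequency-domain machinery
// ---------------------------------------------------------------------------

// Non-singular part of the spike cross-covariance spectrum at one frequency:
//   M(w) = (I - atil W)^-1 D (I - conj(atil) W^T)^-1
// With W real this equals G D G^H where G = (I - atil W)^-1, so M is Hermitian.
static arma::cx_mat spectrum_at(const arma::mat& W, const arma::vec& r,
                                std::complex<double> atil) {
  arma::uword N = W.n_rows;
  arma::cx_mat A = arma::cx_mat(arma::eye(N, N), arma::zeros(N, N)) - atil * W;
  arma::cx_mat G = arma::inv(A);
  arma::cx_mat GD = G;
  for (arma::uword k = 0; k < N; ++k) GD.col(k) *= r(k);
  return GD * G.t();  // .t() on cx_mat is the conjugate transpose
}

// [[Rcpp::export]]
arma::cx_cube cpp_correlation_spectrum(const arma::mat& W, const arma::vec& r,
                                       const arma::cx_vec& atil) {
  arma::uword N = W.n_rows, K = atil.n_elem;
  arma::cx_cube out(N, N, K);
  for (arma::uword k = 0; k < K; ++k)
    out.slice(k) = spectrum_at(W, r, atil(k));
  return out;
}

// Frequency integral of the exact STDP drift:
//   (1/2pi) * Int dw Ftil(-w) M(w)
// evaluated on a uniform grid of non-negative frequencies (omega[0] must be 0).
// The negative-frequency half is folded in via term(-w) = conj(term(w)).
// [[Rcpp::export]]
arma::mat cpp_drift_freq(const arma::mat& W, const arma::vec& r,
                         const arma::vec& omega, const arma::cx_vec& atil,
                         const arma::cx_vec& Fmw) {
  arma::uword N = W.n_rows, K = omega.n_elem;
  double dw = omega(1) - omega(0);
  arma::mat acc(N, N, arma::fill::zeros);
  for (arma::uword k = 0; k < K; ++k) {
    arma::cx_mat M = spectrum_at(W, r, atil(k));
    arma::mat re = arma::real(Fmw(k) * M);
    acc += (k == 0) ? re : 2.0 * re;
  }
  return acc * (dw / (2.0 * arma::datum::pi));
}

// ---------------------------------------------------------------------------
// Stochastic linear Poisson simulator
// ---------------------------------------------------------------------------

// Filtered synaptic activity is carried as two exponential traces per neuron:
//   a(t) = a0 (exp(-t/tau1) - exp(-t (1/tau1 + 1/tau2)))   (t from current onset)
// so no history buffer is needed and the 1-2 s saturation constants are exact.
struct SynTraces {
  arma::vec u, v;
  double du, dv, a0;
  SynTraces(int N, double a0_, double tau1, double tau2, double dt)
    : u(N, arma::fill::zeros), v(N, arma::fill::zeros),
      du(std::exp(-dt / tau1)), dv(std::exp(-dt * (1.0 / tau1 + 1.0 / tau2))),
      a0(a0_) {}
  void decay() { u *= du; v *= dv; }
  void add(int k) { u(k) += 1.0; v(k) += 1.0; }
  arma::vec value() const { return a0 * (u - v); }
};

// One Bernoulli spiking step: p = clip(lambda*dt, 0, 1), at most one spike
// per neuron per step.  Uses R's RNG so set.seed() governs reproducibility.
static inline void draw_spikes(const arma::vec& lambda, double dt,
                               std::vector<int>& fired) {
  fired.clear();
  for (arma::uword i = 0; i < lambda.n_elem; ++i) {
    double p = lambda(i) * dt;
    if (p <= 0.0) continue;
    if (p > 1.0) p = 1.0;
    if (unif_rand() < p) fired.push_back((int)i);
  }
}

// [[Rcpp::export]]
List cpp_simulate(const arma::mat& Weff, const arma::vec& b, double a0,
                  double tau1, double tau2, int dsteps, double duration,
                  double dt) {
  int N = Weff.n_rows;
  long nsteps = (long)std::floor(duration / dt + 0.5);
  SynTraces tr(N, a0, tau1, tau2, dt);
  int L = dsteps > 0 ? dsteps : 1;
  arma::imat ring(N, L, arma::fill::zeros);
  std::vector<double> times;
  std::vector<int> ids;
  std::vector<int> fired;
  times.reserve(1024); ids.reserve(1024);
  for (long n = 0; n < nsteps; ++n) {
    tr.decay();
    if (dsteps > 0 && n >= dsteps) {
      int c = (int)((n - dsteps) % L);
      for (int i = 0; i < N; ++i)
        if (ring(i, c)) { tr.add(i); ring(i, c) = 0; }
    }
    arma::vec lambda = Weff * tr.value() + b;
    draw_spikes(lambda, dt, fired);
    double t = n * dt;
    for (int id : fired) {
      times.push_back(t);
      ids.push_back(id + 1);
      if (dsteps > 0) ring(id, (int)(n % L)) = 1; else tr.add(id);
    }
  }
  return List::create(_["times"] = wrap(times), _["ids"] = wrap(ids));
}

// ---------------------------------------------------------------------------
// Pair-based STDP accumulation
// ---------------------------------------------------------------------------

// Trace-based all-to-all pair accumulation for difference-of-exponentials
// STDP windows: F(s) = h0*Ap*(exp(-s/t1p) - exp(-s(1/t1p+1/t2)))  for s > 0,
//               F(s) = h0*An*(exp(s/t1n)  - exp(s(1/t1n+1/t2)))   for s < 0.
// Exact in event time (no grid): traces decay analytically between spikes.
// [[Rcpp::export]]
arma::mat cpp_accumulate_exp(const arma::vec& times, const arma::ivec& ids,
                             int N, double h0, double Ap, double An,
                             double t1p, double t1n, double t2) {
  arma::mat dW(N, N, arma::fill::zeros);
  arma::vec e1(N, arma::fill::zeros), e2(N, arma::fill::zeros);
  arma::vec g1(N, arma::fill::zeros), g2(N, arma::fill::zeros);
  double tlast = times.n_elem ? times(0) : 0.0;
  double k1p = 1.0 / t1p, k2p = 1.0 / t1p + 1.0 / t2;
  double k1n = 1.0 / t1n, k2n = 1.0 / t1n + 1.0 / t2;
  for (arma::uword s = 0; s < times.n_elem; ++s) {
    double t = times(s);
    double d = t - tlast;
    if (d > 0) {
      e1 *= std::exp(-k1p * d); e2 *= std::exp(-k2p * d);
      g1 *= std::exp(-k1n * d); g2 *= std::exp(-k2n * d);
      tlast = t;
    }
    int m = ids(s) - 1;
    // spike in m as POST: pairs with all earlier PRE spikes, F(t - t_pre) > 0 side
    for (int j = 0; j < N; ++j)
      if (j != m) dW(m, j) += h0 * Ap * (e1(j) - e2(j));
    // spike in m as PRE: pairs with all earlier POST spikes, F(t_post - t) < 0 side
    for (int i = 0; i < N; ++i)
      if (i != m) dW(i, m) += h0 * An * (g1(i) - g2(i));
    e1(m) += 1.0; e2(m) += 1.0; g1(m) += 1.0; g2(m) += 1.0;
  }
  return dW;
}

// Windowed pair accumulation for the mexican-hat window
//   F(s) = A (1 - s^2/(c2 sigma^2)) exp(-p s^2)
// (F is even; `window` truncates negligible tails).
// [[Rcpp::export]]
arma::mat cpp_accumulate_mexhat(const arma::vec& times, const arma::ivec& ids,
                                int N, double A, double sigma, double c2,
                                double p, double window) {
  arma::mat dW(N, N, arma::fill::zeros);
  arma::uword lo = 0;
  for (arma::uword s = 0; s < times.n_elem; ++s) {
    double t = times(s);
    int m = ids(s) - 1;
    while (lo < s && t - times(lo) > window) ++lo;
    for (arma::uword q = lo; q < s; ++q) {
      int k = ids(q) - 1;
      if (k == m) continue;
      double d = t - times(q);
      double F = A * (1.0 - d * d / (c2 * sigma * sigma)) * std::exp(-p * d * d);
      dW(m, k) += F;  // m post, k pre, F(+d)
      dW(k, m) += F;  // k post, m pre, F(-d) = F(+d)
    }
  }
  return dW;
}

// ---------------------------------------------------------------------------
// Full stochastic plasticity loop (spiking + the full weight dynamics)
// ---------------------------------------------------------------------------

// family: 1 = difference-of-exponentials window (trace-based, parameters
// h0, Ap, An, t1p, t1n, t2); 2 = mexican hat (windowed pair scan, parameters
// A = h0, sigma = t1p, c2 = t1n, p = t2, window = Ap).
// Slow terms (psi competition, mu self-depression, gamma growth) are applied
// every step scaled by dt; `slow_scale` is eta if the learning rate multiplies
// all plasticity terms, else 1.
// [[Rcpp::export]]
List cpp_run_stochastic(const arma::mat& Wex0, const arma::vec& b, double a0,
                        double tau1, double tau2, int dsteps, int family,
                        double h0, double Ap, double An, double t1p,
                        double t1n, double t2, double eta, double psi,
                        double mu, double gamma, double wmax, double Wmax,
                        double duration, double dt, double slow_scale,
                        bool use_inhibition,
                        const arma::vec& checkpoint_times) {
  int N = Wex0.n_rows;
  long nsteps = (long)std::floor(duration / dt + 0.5);
  arma::mat Wex = Wex0;
  SynTraces tr(N, a0, tau1, tau2, dt);
  int L = dsteps > 0 ? dsteps : 1;
  arma::imat ring(N, L, arma::fill::zeros);
  std::vector<int> fired;
  // STDP traces (family 1)
  arma::vec e1(N, arma::fill::zeros), e2(N, arma::fill::zeros);
  arma::vec g1(N, arma::fill::zeros), g2(N, arma::fill::zeros);
  double de1 = std::exp(-dt / t1p), de2 = std::exp(-dt * (1.0 / t1p + 1.0 / t2));
  double dg1 = std::exp(-dt / t1n), dg2 = std::exp(-dt * (1.0 / t1n + 1.0 / t2));
  // recent-spike buffer (family 2)
  std::deque< std::pair<double,int> > recent;
  double mh_window = Ap;
  // checkpoints
  arma::cube cps(N, N, checkpoint_times.n_elem);
  arma::uword next_cp = 0;
  long total_spikes = 0;
  // preallocated buffers; row/column sums are maintained incrementally
  arma::vec lambda(N), x(N), rs = arma::sum(Wex, 1),
            cs = arma::sum(Wex, 0).t();
  double* W = Wex.memptr();
  const double hdt = dt * slow_scale;
  for (long n = 0; n < nsteps; ++n) {
    double t = n * dt;
    tr.decay();
    if (family == 1) { e1 *= de1; e2 *= de2; g1 *= dg1; g2 *= dg2; }
    if (dsteps > 0 && n >= dsteps) {
      int c = (int)((n - dsteps) % L);
      for (int i = 0; i < N; ++i)
        if (ring(i, c)) { tr.add(i); ring(i, c) = 0; }
    }
    x = tr.value();
    double S = use_inhibition ? arma::accu(x) / N : 0.0;
    for (int i = 0; i < N; ++i) lambda(i) = b(i) - rs(i) * S;
    for (int j = 0; j < N; ++j) {
      double xv = x(j);
      if (xv == 0.0) continue;
      const double* col = W + (size_t)j * N;
      for (int i = 0; i < N; ++i) lambda(i) += col[i] * xv;
    }
    draw_spikes(lambda, dt, fired);
    total_spikes += (long)fired.size();
    for (int m : fired) {
      if (family == 1) {
        for (int j = 0; j < N; ++j) {
          if (j == m) continue;
          double d1 = eta * h0 * Ap * (e1(j) - e2(j));
          double d2 = eta * h0 * An * (g1(j) - g2(j));
          Wex(m, j) += d1; rs(m) += d1; cs(j) += d1;
          Wex(j, m) += d2; rs(j) += d2; cs(m) += d2;
        }
        e1(m) += 1.0; e2(m) += 1.0; g1(m) += 1.0; g2(m) += 1.0;
      } else {
        while (!recent.empty() && t - recent.front().first > mh_window)
          recent.pop_front();
        for (auto& sp : recent) {
          int k = sp.second;
          if (k == m) continue;
          double d = t - sp.first;
          double F = eta * h0 * (1.0 - d * d / (t1n * t1p * t1p)) *
                     std::exp(-t2 * d * d);
          Wex(m, k) += F; rs(m) += F; cs(k) += F;
          Wex(k, m) += F; rs(k) += F; cs(m) += F;
        }
        recent.push_back(std::make_pair(t, m));
      }
      if (dsteps > 0) ring(m, (int)(n % L)) = 1; else tr.add(m);
    }
    // slow terms + hard bounds, every step; rebuild rs/cs in the same pass
    const double decay = 1.0 - hdt * mu;
    for (int i = 0; i < N; ++i) {
      double e = rs(i) - Wmax;
      lambda(i) = hdt * (gamma - psi * (e > 0.0 ? e : 0.0));  // reuse buffer
      rs(i) = 0.0;
    }
    for (int j = 0; j < N; ++j) {
      double e = cs(j) - Wmax;
      double aj = -hdt * psi * (e > 0.0 ? e : 0.0);
      double* col = W + (size_t)j * N;
      double csj = 0.0;
      for (int i = 0; i < N; ++i) {
        if (i == j) { col[i] = 0.0; continue; }
        double w = col[i] * decay + lambda(i) + aj;
        w = w < 0.0 ? 0.0 : (w > wmax ? wmax : w);
        col[i] = w;
        rs(i) += w;
        csj += w;
      }
      cs(j) = csj;
    }
    while (next_cp < checkpoint_times.n_elem &&
           t + dt >= checkpoint_times(next_cp)) {
      cps.slice(next_cp) = Wex;
      ++next_cp;
    }
  }
  return List::create(_["Wex"] = Wex, _["checkpoints"] = cps,
                      _["n_spikes"] = (double)total_spikes);
}

// ---------------------------------------------------------------------------
// Binned cross-correlogram counts
// ---------------------------------------------------------------------------

// For each spike t of train j, counts spikes of train i falling in
// [t + edges[k], t + edges[k+1]).  Both trains must be sorted.
// [[Rcpp::export]]
arma::vec cpp_correlogram_counts(const arma::vec& ti, const arma::vec& tj,
                                 const arma::vec& edges) {
  arma::uword nb = edges.n_elem - 1;
  arma::vec counts(nb, arma::fill::zeros);
  for (arma::uword s = 0; s < tj.n_elem; ++s) {
    double t = tj(s);
    // indices of first spike >= t + edges[0]
    const double* beg = ti.memptr();
    const double* end = beg + ti.n_elem;
    const double* p = std::lower_bound(beg, end, t + edges(0));
    for (; p != end && *p < t + edges(nb); ++p) {
      double d = *p - t;
      arma::uword k = (arma::uword)((d - edges(0)) / (edges(1) - edges(0)));
      if (k >= nb) k = nb - 1;
      counts(k) += 1.0;
    }
  }
  return counts;
}
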