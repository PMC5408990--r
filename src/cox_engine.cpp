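// Weighted Cox partial-likelihood engine.
//
// Counting-process data (entry, stop, status] on the age time scale with
// delayed entry, per-record sampling weights, baseline-hazard strata and
// Breslow handling of tied event ages.  Covariate columns may be fixed or
// time-varying: a column can be multiplied by attained age t (PRS-by-age
// interaction) or by an age-band indicator I(lo <= t < hi) (age-group
// effects).
//
// Three evaluation routes, all exact for the stated model:
//  * fixed covariates: O(n log n) running-sum sweep over event ages;
//  * time-varying columns: a windowed moment expansion -- within short age
//    windows the risk-set sums S0, S1, S2 are assembled from Taylor series
//    of the risk-set moments in the time-varying part of the linear
//    predictor, so each Newton pass costs O(n) exponentials instead of
//    O(n * events); window lengths are chosen so the truncated series is
//    accurate to well below double precision;
//  * a direct per-event rescan of the risk set, kept as an internal
//    reference route for validating the windowed sweep.
//
// Returns the Newton-Raphson maximum weighted partial-likelihood estimate,
// the observed information, and per-record weighted score residuals from
// which cluster-robust (sandwich) covariance is assembled on the R side.

// [[Rcpp::depends(RcppArmadillo)]]
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>

using namespace arma;

namespace {

const int MOM = 12;    // series order for the likelihood windows
const int MOM_R = 25;  // series order for the residual prefix sums
const double WIN_EXPONENT = 0.1;   // max |gamma| * window length
const double SEG_EXPONENT = 1.5;   // max |gamma| * residual segment halfspan

struct EventGroup {
  double time;
  std::vector<int> ids;  // record indices with an event at this time
};

struct StratumData {
  std::vector<int> by_stop;   // record indices sorted by stop, descending
  std::vector<int> by_entry;  // record indices sorted by entry, descending
  std::vector<int> ent_asc;   // sorted by entry, ascending
  std::vector<int> stop_asc;  // sorted by stop, ascending
  std::vector<EventGroup> events;      // distinct event times, descending
  std::vector<EventGroup> events_asc;  // ascending
};

// per-column design value multiplier at attained age t
inline double tfactor(int type, double lo, double hi, double t) {
  if (type == 1) return t;
  if (type == 2) return (t >= lo && t < hi) ? 1.0 : 0.0;
  return 1.0;
}

std::vector<StratumData> split_strata(const vec& entry, const vec& stop,
                                      const ivec& status, const ivec& strat,
                                      int n_strata) {
  std::vector<StratumData> out(n_strata);
  int n = entry.n_elem;
  for (int i = 0; i < n; ++i) {
    out[strat[i]].by_stop.push_back(i);
    out[strat[i]].by_entry.push_back(i);
  }
  for (int s = 0; s < n_strata; ++s) {
    StratumData& sd = out[s];
    std::sort(sd.by_stop.begin(), sd.by_stop.end(),
              [&](int a, int b) { return stop[a] > stop[b]; });
    std::sort(sd.by_entry.begin(), sd.by_entry.end(),
              [&](int a, int b) { return entry[a] > entry[b]; });
    sd.ent_asc.assign(sd.by_entry.rbegin(), sd.by_entry.rend());
    sd.stop_asc.assign(sd.by_stop.rbegin(), sd.by_stop.rend());
    std::vector<int> ev;
    for (int i : sd.by_stop) if (status[i] == 1) ev.push_back(i);
    size_t k = 0;
    while (k < ev.size()) {
      EventGroup g;
      g.time = stop[ev[k]];
      while (k < ev.size() && stop[ev[k]] == g.time) {
        g.ids.push_back(ev[k]);
        ++k;
      }
      sd.events.push_back(g);
    }
    sd.events_asc.assign(sd.events.rbegin(), sd.events.rend());
  }
  return out;
}

}  // namespace

// ---------------------------------------------------------------------------
// Fixed-covariate sweep: log-likelihood, score, information; optionally the
// per-event baseline quantities needed for score residuals.
static double loglik_fixed(const std::vector<StratumData>& strata,
                           const vec& entry, const vec& stop,
                           const mat& X, const vec& w, const vec& beta,
                           vec& U, mat& I, bool want_resid, mat& resid) {
  int n = X.n_rows, p = X.n_cols;
  vec eta = X * beta;
  vec r = w % exp(eta);
  double ll = 0.0;
  U.zeros(p);
  I.zeros(p, p);
  if (want_resid) resid.zeros(n, p);

  for (const StratumData& sd : strata) {
    if (sd.events.empty()) continue;
    double S0 = 0.0;
    vec S1(p, fill::zeros);
    mat S2(p, p, fill::zeros);
    size_t a = 0, b = 0;
    size_t K = sd.events.size();
    std::vector<double> evS0(K);
    std::vector<vec> evS1(K);
    std::vector<double> evD(K);

    for (size_t k = 0; k < K; ++k) {
      double t = sd.events[k].time;
      while (a < sd.by_stop.size() && stop[sd.by_stop[a]] >= t) {
        int i = sd.by_stop[a++];
        rowvec xi = X.row(i);
        S0 += r[i];
        S1 += r[i] * xi.t();
        S2 += r[i] * (xi.t() * xi);
      }
      while (b < sd.by_entry.size() && entry[sd.by_entry[b]] >= t) {
        int i = sd.by_entry[b++];
        rowvec xi = X.row(i);
        S0 -= r[i];
        S1 -= r[i] * xi.t();
        S2 -= r[i] * (xi.t() * xi);
      }
      double d = 0.0;
      vec dx(p, fill::zeros);
      for (int i : sd.events[k].ids) {
        d += w[i];
        dx += w[i] * X.row(i).t();
        ll += w[i] * eta[i];
      }
      ll -= d * std::log(S0);
      vec xbar = S1 / S0;
      U += dx - d * xbar;
      I += d * (S2 / S0 - xbar * xbar.t());
      evS0[k] = S0;
      evS1[k] = S1;
      evD[k] = d;
    }

    if (want_resid) {
      // cumulative hazard sums over event times (ascending)
      std::vector<double> tasc(K), cum0(K);
      std::vector<vec> cum1(K);
      double c0 = 0.0;
      vec c1(p, fill::zeros);
      for (size_t k = 0; k < K; ++k) {
        size_t j = K - 1 - k;  // ascending
        tasc[k] = sd.events[j].time;
        c0 += evD[j] / evS0[j];
        c1 += evD[j] * evS1[j] / (evS0[j] * evS0[j]);
        cum0[k] = c0;
        cum1[k] = c1;
        vec xbar = evS1[j] / evS0[j];
        for (int i : sd.events[j].ids)
          resid.row(i) += w[i] * (X.row(i) - xbar.t());
      }
      auto cum_at = [&](double t, double& g0, vec& g1) {
        int lo = -1, hi = (int)K;
        while (hi - lo > 1) {
          int mid = (lo + hi) / 2;
          if (tasc[mid] <= t) lo = mid; else hi = mid;
        }
        if (lo < 0) { g0 = 0.0; g1.zeros(p); }
        else { g0 = cum0[lo]; g1 = cum1[lo]; }
      };
      for (int i : sd.by_stop) {
        double g0s, g0e;
        vec g1s(p), g1e(p);
        cum_at(stop[i], g0s, g1s);
        cum_at(entry[i], g0e, g1e);
        double g0 = g0s - g0e;
        vec g1 = g1s - g1e;
        if (g0 != 0.0 || norm(g1) != 0.0)
          resid.row(i) -= r[i] * (g0 * X.row(i) - g1.t());
      }
    }
  }
  return ll;
}

// ---------------------------------------------------------------------------
// Direct time-varying sweep: risk set rescanned at each event age.
// Reference route; O(n * events) per pass.
static double loglik_direct(const std::vector<StratumData>& strata,
                            const vec& entry, const vec& stop,
                            const mat& X, const vec& w, const vec& beta,
                            const ivec& ttype, const vec& tlo, const vec& thi,
                            vec& U, mat& I, bool want_resid, mat& resid) {
  int n = X.n_rows, p = X.n_cols;
  double ll = 0.0;
  U.zeros(p);
  I.zeros(p, p);
  if (want_resid) resid.zeros(n, p);

  vec f(p), bf(p);
  for (const StratumData& sd : strata) {
    size_t m = 0;  // subjects with stop >= current event time (suffix)
    for (size_t k = 0; k < sd.events.size(); ++k) {
      double t = sd.events[k].time;
      while (m < sd.by_stop.size() && stop[sd.by_stop[m]] >= t) ++m;
      for (int j = 0; j < p; ++j) {
        f[j] = tfactor(ttype[j], tlo[j], thi[j], t);
        bf[j] = beta[j] * f[j];
      }
      double S0 = 0.0;
      vec S1(p, fill::zeros);
      mat S2(p, p, fill::zeros);
      for (size_t q = 0; q < m; ++q) {
        int i = sd.by_stop[q];
        if (entry[i] >= t) continue;
        double eta = 0.0;
        for (int j = 0; j < p; ++j) eta += bf[j] * X(i, j);
        double e = w[i] * std::exp(eta);
        S0 += e;
        for (int j = 0; j < p; ++j) {
          double xv = f[j] * X(i, j);
          S1[j] += e * xv;
          for (int j2 = 0; j2 <= j; ++j2) S2(j, j2) += e * xv * f[j2] * X(i, j2);
        }
      }
      for (int j = 0; j < p; ++j)
        for (int j2 = j + 1; j2 < p; ++j2) S2(j, j2) = S2(j2, j);

      double d = 0.0;
      vec dx(p, fill::zeros);
      for (int i : sd.events[k].ids) {
        d += w[i];
        double eta = 0.0;
        for (int j = 0; j < p; ++j) {
          double xv = f[j] * X(i, j);
          dx[j] += w[i] * xv;
          eta += beta[j] * xv;
        }
        ll += w[i] * eta;
      }
      ll -= d * std::log(S0);
      vec xbar = S1 / S0;
      U += dx - d * xbar;
      I += d * (S2 / S0 - xbar * xbar.t());

      if (want_resid) {
        for (int i : sd.events[k].ids)
          for (int j = 0; j < p; ++j)
            resid(i, j) += w[i] * (f[j] * X(i, j) - xbar[j]);
        double h = d / S0;
        for (size_t q = 0; q < m; ++q) {
          int i = sd.by_stop[q];
          if (entry[i] >= t) continue;
          double eta = 0.0;
          for (int j = 0; j < p; ++j) eta += bf[j] * X(i, j);
          double e = w[i] * std::exp(eta);
          for (int j = 0; j < p; ++j)
            resid(i, j) -= e * h * (f[j] * X(i, j) - xbar[j]);
        }
      }
    }
  }
  return ll;
}

// ---------------------------------------------------------------------------
// Windowed moment expansion for time-varying columns.
//
// Split the linear predictor at attained age t into
//   eta_i(t) = alpha_i + gamma_i * t,
// where gamma_i collects the "x * age" columns and alpha_i the fixed and
// (within a window) the age-band indicator columns.  Over an age window
// anchored at t0 with |gamma_i (t - t0)| <= WIN_EXPONENT, the risk-set sums
// are Taylor series in (t - t0) with coefficients given by the gamma-
// moments of the risk set, maintained incrementally as subjects enter and
// leave.  Windows also break at every band-indicator boundary so the
// indicator activity is constant within a window.
static double loglik_windowed(const std::vector<StratumData>& strata,
                              const vec& entry, const vec& stop,
                              const mat& X, const vec& w, const vec& beta,
                              const ivec& ttype, const vec& tlo,
                              const vec& thi, vec& U, mat& I,
                              bool want_resid, mat& resid) {
  int n = X.n_rows, p = X.n_cols;
  double ll = 0.0;
  U.zeros(p);
  I.zeros(p, p);
  if (want_resid) resid.zeros(n, p);

  // alpha0 (fixed part) and gamma per record
  vec alpha0(n, fill::zeros), gamma(n, fill::zeros);
  std::vector<int> band_cols;
  for (int j = 0; j < p; ++j) {
    if (ttype[j] == 0) alpha0 += beta[j] * X.col(j);
    else if (ttype[j] == 1) gamma += beta[j] * X.col(j);
    else band_cols.push_back(j);
  }
  double gmax = gamma.n_elem ? max(abs(gamma)) : 0.0;
  double win_len = gmax > 0 ? WIN_EXPONENT / gmax
                            : std::numeric_limits<double>::infinity();

  // band breakpoints
  std::vector<double> bps;
  for (int j : band_cols) { bps.push_back(tlo[j]); bps.push_back(thi[j]); }
  std::sort(bps.begin(), bps.end());
  bps.erase(std::unique(bps.begin(), bps.end()), bps.end());

  const int nser = 1 + p + p * (p + 1) / 2;
  std::vector<double> S(nser * (MOM + 1));
  std::vector<double> vser(nser), Ev(nser);
  std::vector<char> inrisk(n, 0);
  std::vector<int> active;

  // alpha for subject i given current band activity
  std::vector<double> act(p, 1.0);
  auto alpha_of = [&](int i) {
    double a = alpha0[i];
    for (int j : band_cols) if (act[j] != 0.0) a += beta[j] * X(i, j);
    return a;
  };
  auto series_values = [&](int i) {
    vser[0] = 1.0;
    for (int j = 0; j < p; ++j) vser[1 + j] = X(i, j);
    int s = 1 + p;
    for (int j = 0; j < p; ++j)
      for (int j2 = j; j2 < p; ++j2) vser[s++] = X(i, j) * X(i, j2);
  };
  double t0 = 0.0, window_end = 0.0;
  bool window_valid = false;
  auto accumulate = [&](int i, double sign) {
    double g = gamma[i];
    double u = sign * w[i] * std::exp(alpha_of(i) + g * t0);
    series_values(i);
    double gm = u;
    for (int m = 0; m <= MOM; ++m) {
      double* Sm = &S[(size_t)m * nser];
      for (int s = 0; s < nser; ++s) Sm[s] += vser[s] * gm;
      gm *= g / (m + 1);
    }
  };

  for (const StratumData& sd : strata) {
    if (sd.events_asc.empty()) continue;
    size_t K = sd.events_asc.size();
    size_t aptr = 0, rptr = 0;
    active.clear();
    window_valid = false;
    std::fill(S.begin(), S.end(), 0.0);

    // stored per event for residuals
    std::vector<double> ev_t(K), ev_a(K);
    mat ev_xbar(want_resid ? K : 0, p);

    for (size_t k = 0; k < K; ++k) {
      double t = sd.events_asc[k].time;
      while (aptr < sd.ent_asc.size() && entry[sd.ent_asc[aptr]] < t) {
        int i = sd.ent_asc[aptr++];
        inrisk[i] = 1;
        active.push_back(i);
        if (window_valid) accumulate(i, +1.0);
      }
      while (rptr < sd.stop_asc.size() && stop[sd.stop_asc[rptr]] < t) {
        int i = sd.stop_asc[rptr++];
        if (inrisk[i]) {
          inrisk[i] = 0;
          if (window_valid) accumulate(i, -1.0);
        }
      }
      if (!window_valid || t >= window_end) {
        t0 = t;
        for (int j : band_cols)
          act[j] = (t0 >= tlo[j] && t0 < thi[j]) ? 1.0 : 0.0;
        auto it = std::upper_bound(bps.begin(), bps.end(), t0);
        double nb = (it == bps.end()) ?
            std::numeric_limits<double>::infinity() : *it;
        window_end = std::min(t0 + win_len, nb);
        // compact the active list and rebuild sums
        size_t keep = 0;
        for (size_t q = 0; q < active.size(); ++q)
          if (inrisk[active[q]]) active[keep++] = active[q];
        active.resize(keep);
        std::fill(S.begin(), S.end(), 0.0);
        for (int i : active) accumulate(i, +1.0);
        window_valid = true;
      }
      double del = t - t0;
      // assemble E_v(t) = sum_m S[m][ser] * del^m
      std::fill(Ev.begin(), Ev.end(), 0.0);
      double dm = 1.0;
      for (int m = 0; m <= MOM; ++m) {
        const double* Sm = &S[(size_t)m * nser];
        for (int s = 0; s < nser; ++s) Ev[s] += Sm[s] * dm;
        dm *= del;
      }
      double S0 = Ev[0];
      vec S1(p), fac(p);
      mat S2(p, p);
      for (int j = 0; j < p; ++j)
        fac[j] = (ttype[j] == 0) ? 1.0 : (ttype[j] == 1 ? t : act[j]);
      for (int j = 0; j < p; ++j) S1[j] = fac[j] * Ev[1 + j];
      {
        int s = 1 + p;
        for (int j = 0; j < p; ++j)
          for (int j2 = j; j2 < p; ++j2) {
            S2(j, j2) = fac[j] * fac[j2] * Ev[s];
            S2(j2, j) = S2(j, j2);
            ++s;
          }
      }
      double d = 0.0;
      vec dx(p, fill::zeros);
      for (int i : sd.events_asc[k].ids) {
        d += w[i];
        double eta = alpha_of(i) + gamma[i] * t;
        ll += w[i] * eta;
        for (int j = 0; j < p; ++j) dx[j] += w[i] * fac[j] * X(i, j);
      }
      ll -= d * std::log(S0);
      vec xbar = S1 / S0;
      U += dx - d * xbar;
      I += d * (S2 / S0 - xbar * xbar.t());
      if (want_resid) {
        ev_t[k] = t;
        ev_a[k] = d / S0;
        ev_xbar.row(k) = xbar.t();
        for (int i : sd.events_asc[k].ids)
          for (int j = 0; j < p; ++j)
            resid(i, j) += w[i] * (fac[j] * X(i, j) - xbar[j]);
      }
    }
    for (int i : active) inrisk[i] = 0;  // reset for next stratum

    if (!want_resid) continue;

    // ---- residual integral via per-segment Taylor prefix sums ----
    // segments: intervals of constant band activity, further split so that
    // gmax * halfspan <= SEG_EXPONENT (controls series cancellation)
    std::vector<double> seg_edges;
    seg_edges.push_back(ev_t.front());
    for (double b : bps)
      if (b > ev_t.front() && b < ev_t.back()) seg_edges.push_back(b);
    seg_edges.push_back(ev_t.back() + 1e-9);
    std::sort(seg_edges.begin(), seg_edges.end());
    std::vector<double> edges;
    for (size_t s = 0; s + 1 < seg_edges.size(); ++s) {
      double lo = seg_edges[s], hi = seg_edges[s + 1];
      int pieces = 1;
      if (gmax > 0)
        pieces = std::max(1, (int)std::ceil(gmax * (hi - lo) / 2.0 /
                                            SEG_EXPONENT));
      for (int q = 0; q < pieces; ++q)
        edges.push_back(lo + (hi - lo) * q / pieces);
    }
    edges.push_back(seg_edges.back());
    int nseg = (int)edges.size() - 1;
    // event -> segment assignment (events ascending)
    std::vector<int> seg_start(nseg + 1, 0);
    {
      int s = 0;
      for (size_t k = 0; k < K; ++k) {
        while (s + 1 < nseg && ev_t[k] >= edges[s + 1]) {
          ++s;
          seg_start[s] = (int)k;
        }
      }
      for (int q = s + 1; q <= nseg; ++q) seg_start[q] = (int)K;
      seg_start[0] = 0;
    }
    std::vector<double> seg_tc(nseg), seg_act(nseg * p);
    for (int s = 0; s < nseg; ++s) {
      int k1 = seg_start[s], k2 = seg_start[s + 1];
      seg_tc[s] = (k2 > k1) ? 0.5 * (ev_t[k1] + ev_t[k2 - 1]) : edges[s];
      double tm = (k2 > k1) ? ev_t[k1] : edges[s];
      for (int j = 0; j < p; ++j)
        seg_act[s * p + j] =
            (ttype[j] == 2) ? ((tm >= tlo[j] && tm < thi[j]) ? 1.0 : 0.0)
                            : 1.0;
    }
    // prefix sums within segment:
    //   P[m][k]   = sum_{k' <= k in seg} a (t - tc)^m / m!
    //   Q[j][m][k] = same with factor xbar_j
    int nserr = 1 + p;
    std::vector<double> pref((size_t)(MOM_R + 2) * nserr * K, 0.0);
    auto PR = [&](int m, int s, size_t k) -> double& {
      return pref[((size_t)m * nserr + s) * K + k];
    };
    for (int s = 0; s < nseg; ++s) {
      int k1 = seg_start[s], k2 = seg_start[s + 1];
      for (int k = k1; k < k2; ++k) {
        double dt = ev_t[k] - seg_tc[s];
        double pw = ev_a[k];
        for (int m = 0; m <= MOM_R + 1; ++m) {
          PR(m, 0, k) = (k > k1 ? PR(m, 0, k - 1) : 0.0) + pw;
          for (int j = 0; j < p; ++j)
            PR(m, 1 + j, k) = (k > k1 ? PR(m, 1 + j, k - 1) : 0.0) +
                              pw * ev_xbar(k, j);
          pw *= dt / (m + 1);
        }
      }
    }
    // per-record integral over its at-risk event range
    auto count_le = [&](double t) {
      // number of events with time <= t
      size_t lo = 0, hi = K;
      while (lo < hi) {
        size_t mid = (lo + hi) / 2;
        if (ev_t[mid] <= t) lo = mid + 1; else hi = mid;
      }
      return (int)lo;
    };
    for (int i : sd.stop_asc) {
      int k_hi = count_le(stop[i]);
      int k_lo = count_le(entry[i]);
      if (k_hi <= k_lo) continue;
      double g = gamma[i];
      for (int s = 0; s < nseg; ++s) {
        int a1 = std::max(k_lo, seg_start[s]);
        int a2 = std::min(k_hi, seg_start[s + 1]);
        if (a2 <= a1) continue;
        // alpha under this segment's activity
        double alp = alpha0[i];
        for (int j : band_cols)
          if (seg_act[s * p + j] != 0.0) alp += beta[j] * X(i, j);
        double base = w[i] * std::exp(alp + g * seg_tc[s]);
        // E0 = sum a e^{g(t-tc)}, E1 = sum a (t-tc) e^{g(t-tc)},
        // EQ_j = sum a xbar_j e^{g(t-tc)} over events (a1, a2]
        double E0 = 0.0, E1 = 0.0;
        std::vector<double> EQ(p, 0.0);
        double gm = 1.0;
        for (int m = 0; m <= MOM_R; ++m) {
          double dP = PR(m, 0, a2 - 1) -
                      (a1 > seg_start[s] ? PR(m, 0, a1 - 1) : 0.0);
          double dP1 = PR(m + 1, 0, a2 - 1) -
                       (a1 > seg_start[s] ? PR(m + 1, 0, a1 - 1) : 0.0);
          E0 += gm * dP;
          E1 += gm * (m + 1) * dP1;
          for (int j = 0; j < p; ++j) {
            double dQ = PR(m, 1 + j, a2 - 1) -
                        (a1 > seg_start[s] ? PR(m, 1 + j, a1 - 1) : 0.0);
            EQ[j] += gm * dQ;
          }
          gm *= g;
        }
        for (int j = 0; j < p; ++j) {
          double xint;
          if (ttype[j] == 1)
            xint = X(i, j) * (seg_tc[s] * E0 + E1);
          else if (ttype[j] == 2)
            xint = X(i, j) * seg_act[s * p + j] * E0;
          else
            xint = X(i, j) * E0;
          resid(i, j) -= base * (xint - EQ[j]);
        }
      }
    }
  }
  return ll;
}

// ---------------------------------------------------------------------------
// [[Rcpp::export]]
Rcpp::List cox_fit_cpp(arma::vec entry, arma::vec stop,
                       arma::ivec status, arma::mat X, arma::vec w,
                       arma::ivec strat, arma::ivec ttype,
                       arma::vec tlo, arma::vec thi,
                       arma::vec init, double tol, int maxit,
                       bool direct = false) {
  int p = X.n_cols;
  int n_strata = strat.max() + 1;
  std::vector<StratumData> strata =
      split_strata(entry, stop, status, strat, n_strata);
  bool tv = any(ttype != 0);

  vec beta = init;
  vec U(p);
  mat I(p, p);
  mat resid;
  bool converged = false, separation = false;
  int iter = 0, n_slow = 0;

  auto evalfn = [&](const vec& b, vec& u, mat& im, bool wr, mat& rs) {
    if (!tv)
      return loglik_fixed(strata, entry, stop, X, w, b, u, im, wr, rs);
    if (direct)
      return loglik_direct(strata, entry, stop, X, w, b, ttype, tlo, thi,
                           u, im, wr, rs);
    return loglik_windowed(strata, entry, stop, X, w, b, ttype, tlo, thi,
                           u, im, wr, rs);
  };

  double ll = evalfn(beta, U, I, false, resid);
  double ll0 = ll;  // at init (null model when init = 0)

  for (iter = 1; iter <= maxit; ++iter) {
    if (norm(U, 2) < tol) { converged = true; break; }
    vec step;
    bool ok = solve(step, I, U, solve_opts::no_approx);
    if (!ok) { separation = true; break; }
    // numerical floor: the increment is far below any statistical scale
    if (norm(step, 2) < 1e-9) {
      beta += step;  // final polish
      converged = true;
      break;
    }
    double scale = 1.0;
    vec bnew;
    double llnew = 0.0;
    vec Unew(p);
    mat Inew(p, p);
    int halves = 0;
    for (; halves < 25; ++halves) {
      bnew = beta + scale * step;
      llnew = evalfn(bnew, Unew, Inew, false, resid);
      if (std::isfinite(llnew) && llnew >= ll - 1e-9) break;
      scale *= 0.5;
    }
    if (halves == 25) {
      // cannot improve the likelihood: converged if already at the
      // round-off floor of the gradient, otherwise report failure
      if (norm(step, 2) < 1e-6) converged = true;
      break;
    }
    double dll = std::fabs(llnew - ll);
    beta = bnew;
    ll = llnew;
    U = Unew;
    I = Inew;
    if (max(abs(beta)) > 15.0) { separation = true; break; }
    if (dll < 1e-11 * (std::fabs(ll) + 1.0) && norm(step, 2) < 1e-5) {
      if (++n_slow >= 2) { converged = true; break; }
    } else n_slow = 0;
  }
  if (!converged && norm(U, 2) < tol) converged = true;

  // score residuals at the estimate
  ll = evalfn(beta, U, I, true, resid);

  return Rcpp::List::create(
      Rcpp::Named("coef") = beta, Rcpp::Named("loglik") = ll,
      Rcpp::Named("loglik_init") = ll0, Rcpp::Named("score") = U,
      Rcpp::Named("imat") = I, Rcpp::Named("resid") = resid,
      Rcpp::Named("iter") = iter, Rcpp::Named("converged") = converged,
      Rcpp::Named("separation") = separation);
}
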