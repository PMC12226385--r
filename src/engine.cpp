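#include <Rcpp.h>
using namespace Rcpp;

// One full simulation run. The caller (run_sim) seeds R's RNG and performs all
// initialization draws in R; this loop consumes exactly three uniforms per
// step (agent selection, heuristic selection, action), so the pure-R reference
// engine can replay it draw-for-draw.
//
// Network arrives as 0-based CSR (offsets length P+1, neigh length 2E).
// Strategy coding: S = 1 low effort, S = 0 high effort.

static inline double clip01(double x) {
  if (x < 0.0) return 0.0;
  if (x > 1.0) return 1.0;
  return x;
}

// [[Rcpp::export]]
List run_engine_cpp(IntegerVector offsets, IntegerVector neigh,
                    NumericVector W, NumericVector vis,
                    IntegerVector S_init, IntegerVector H_init,
                    double n0, int T, double epsilon, double sigma,
                    double beta1, double beta2, double beta3,
                    double rho, double eta, double phi,
                    double dH0, double dL0, double DL1, double DH1,
                    int record_stride, int tail_window, int ah_window,
                    bool diagnostics) {
  const int P = S_init.size();
  const double eps_over_P = epsilon / (double)P;

  std::vector<int> S(S_init.begin(), S_init.end());
  std::vector<int> heur(P);     // 0-based internally
  std::vector<int> deg(P);
  // ledger snapshots are visibility-weighted: an agent's estimate of the
  // EFFECTIVE low-effort fraction weights each neighbour by vis_j = d_j^nu
  // (all 1 when nu = 0, reducing to the plain neighbourhood fraction)
  std::vector<double> lowW(P, 0.0), denomW(P, 0.0);
  for (int i = 0; i < P; ++i) {
    heur[i] = H_init[i] - 1;
    deg[i] = offsets[i + 1] - offsets[i];
  }
  for (int i = 0; i < P; ++i)
    for (int k = offsets[i]; k < offsets[i + 1]; ++k) {
      lowW[i] += vis[neigh[k]] * S[neigh[k]];
      denomW[i] += vis[neigh[k]];
    }

  // degree moments for the effort-degree correlation (population sd)
  double mean_d = 0.0, sd_d = 0.0;
  for (int i = 0; i < P; ++i) mean_d += deg[i];
  mean_d /= P;
  for (int i = 0; i < P; ++i) sd_d += (deg[i] - mean_d) * (deg[i] - mean_d);
  sd_d = std::sqrt(sd_d / P);

  std::vector<double> perceived(P, n0);
  std::vector<double> zprev(P), zprev2(P), zave(P), fc(4 * P), fit(4 * P, 0.0);
  std::vector<int> cnt(P, 1);
  for (int i = 0; i < P; ++i) {
    double obs0 = lowW[i] / denomW[i];
    zprev[i] = zprev2[i] = zave[i] = obs0;
    for (int h = 0; h < 4; ++h) fc[4 * i + h] = obs0;
  }

  double z = 0.0;
  for (int i = 0; i < P; ++i) z += S[i] * W[i];
  double n = n0;

  // effort-degree correlation bookkeeping: k_high = #{S=0}, sum of their degrees
  long k_high = 0; double sum_d_high = 0.0;
  for (int i = 0; i < P; ++i) if (S[i] == 0) { ++k_high; sum_d_high += deg[i]; }
  auto effort_cor = [&]() -> double {
    double p = k_high / (double)P;
    if (p <= 0.0 || p >= 1.0 || sd_d == 0.0) return 0.0;
    double cov = sum_d_high / P - p * mean_d;
    return cov / (std::sqrt(p * (1.0 - p)) * sd_d);
  };

  int n_rec = T / record_stride + 1;
  NumericVector rec_t(n_rec), rec_n(n_rec), rec_z(n_rec), rec_cor(n_rec);
  int ir = 0;
  rec_t[ir] = 0; rec_n[ir] = n; rec_z[ir] = z; rec_cor[ir] = effort_cor(); ++ir;

  int n_tail = std::min(T, tail_window);
  NumericVector tail_n(n_tail), tail_z(n_tail);
  int it = 0;

  std::vector<double> sumAH(P, 0.0);
  std::vector<int> cntAH(P, 0);

  NumericMatrix diag(diagnostics ? T : 0, 7);

  for (int t = 1; t <= T; ++t) {
    double u1 = unif_rand();
    int a = (int)(u1 * P);
    if (a >= P) a = P - 1;

    double s = clip01(lowW[a] / denomW[a]);
    double *fa = &fit[4 * a], *ca = &fc[4 * a];
    for (int h = 0; h < 4; ++h) {
      double e = s - ca[h];
      fa[h] = -(e * e) + eta * fa[h];
    }
    double zp2 = zprev[a];
    zprev2[a] = zp2; zprev[a] = s;
    cnt[a] += 1;
    zave[a] += (s - zave[a]) / cnt[a];

    // inertia + softmax heuristic selection (max-shifted: phi = 100 overflows raw)
    double maxf = fa[0];
    for (int h = 1; h < 4; ++h) if (fa[h] > maxf) maxf = fa[h];
    double w0 = std::exp(phi * (fa[0] - maxf));
    double w1 = std::exp(phi * (fa[1] - maxf));
    double w2 = std::exp(phi * (fa[2] - maxf));
    double w3 = std::exp(phi * (fa[3] - maxf));
    double Ssum = w0 + w1 + w2 + w3;
    double pr[4] = { (1.0 - rho) * (w0 / Ssum), (1.0 - rho) * (w1 / Ssum),
                     (1.0 - rho) * (w2 / Ssum), (1.0 - rho) * (w3 / Ssum) };
    pr[heur[a]] += rho;
    double u2 = unif_rand();
    int hsel = 3;
    double acc = 0.0;
    for (int k = 0; k < 4; ++k) {
      acc += pr[k];
      if (u2 <= acc) { hsel = k; break; }
    }
    heur[a] = hsel;

    // refresh all four forecasts from the updated snapshot history
    double old1 = ca[0];
    double d1 = s - zp2;
    ca[0] = clip01(beta1 * s + (1.0 - beta1) * old1);
    ca[1] = clip01(s + beta2 * d1);
    ca[2] = clip01(s + beta3 * d1);
    ca[3] = clip01(0.5 * (zave[a] + s) + d1);
    double ze = ca[hsel];

    double np = perceived[a];
    double advL = (1.0 - np) * (dL0 * ze + dH0 * (1.0 - ze))
                - np * (DL1 * ze + DH1 * (1.0 - ze));
    double AH = -advL;
    double x = deg[a] * sigma * AH;
    if (x > 500.0) x = 500.0;
    if (x < -500.0) x = -500.0;
    double PH = 1.0 / (1.0 + std::exp(-x));
    double u3 = unif_rand();
    int newS = (u3 < PH) ? 0 : 1;

    if (newS != S[a]) {
      z += (newS - S[a]) * W[a];
      double dlt = (double)(newS - S[a]) * vis[a];
      for (int k = offsets[a]; k < offsets[a + 1]; ++k) lowW[neigh[k]] += dlt;
      if (newS == 0) { ++k_high; sum_d_high += deg[a]; }
      else           { --k_high; sum_d_high -= deg[a]; }
      S[a] = newS;
    }

    n += eps_over_P * (z - n);
    for (int i = 0; i < P; ++i)
      perceived[i] += eps_over_P * (clip01(lowW[i] / denomW[i]) - perceived[i]);

    if (t > T - ah_window) { sumAH[a] += AH; cntAH[a] += 1; }
    if (diagnostics) {
      diag(t - 1, 0) = t;        diag(t - 1, 1) = a + 1;
      diag(t - 1, 2) = deg[a];   diag(t - 1, 3) = AH;
      diag(t - 1, 4) = ze;       diag(t - 1, 5) = hsel + 1;
      diag(t - 1, 6) = newS;
    }
    if (t % record_stride == 0) {
      rec_t[ir] = t; rec_n[ir] = n; rec_z[ir] = z; rec_cor[ir] = effort_cor();
      ++ir;
    }
    if (t > T - n_tail) { tail_n[it] = n; tail_z[it] = z; ++it; }
  }

  NumericVector meanAH(P);
  for (int i = 0; i < P; ++i)
    meanAH[i] = cntAH[i] > 0 ? sumAH[i] / cntAH[i] : NA_REAL;

  return List::create(
    _["t"] = rec_t, _["n"] = rec_n, _["z"] = rec_z, _["cor_dz"] = rec_cor,
    _["tail_n"] = tail_n, _["tail_z"] = tail_z,
    _["strategy"] = IntegerVector(S.begin(), S.end()),
    _["heuristic"] = IntegerVector(heur.begin(), heur.end()) + 1,
    _["perceived_n"] = NumericVector(perceived.begin(), perceived.end()),
    _["mean_AH"] = meanAH,
    _["diagnostics"] = diagnostics ? (SEXP)diag : R_NilValue);
}
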