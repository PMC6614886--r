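#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for the two-layer (ancestry, donor) copying HMM.
//
// State s = a*K + j for ancestry a in 0..A-1 and donor j in 0..K-1.
// Transition kernel between successive gridpoints, from (b, h_q) to (a, h_p):
//   a != b             : Pi(b,a) * mu(p,a)/N_p
//   a == b, h_p != h_q : ((1 - PiRow(a))*rho + Pi(a,a)) * mu(p,a)/N_p
//   a == b, h_p == h_q : previous case + (1 - PiRow(a))*(1 - rho)
// with PiRow(a) = sum_b Pi(a,b).  Rows sum to 1 whenever each column of mu
// sums to 1 and PiRow(a) <= 1.  The low-rank structure (switch destinations
// are independent of the source state) gives an O(G * (A^2 + A*K)) sweep,
// written with raw pointers: this loop is the package's hot spot.
//
// Emissions act per donor: a gridpoint carrying sites emits
// (1-theta)^n_match * theta^n_mismatch; empty gridpoints emit 1.
//
// Expected event counts decompose each pairwise transition posterior into
// its generative mechanisms (ancestry arrival incl. explicit a->a switches,
// within-ancestry haplotype switch, stay), which is required for the
// tied-parameter M-step because the a==b kernel entries are mixtures.

// [[Rcpp::export]]
List fb_engine_cpp(int G,
                   IntegerVector gp,
                   IntegerMatrix n_match,
                   IntegerMatrix n_mismatch,
                   IntegerVector donor_panel,
                   int P,
                   NumericMatrix Pi,
                   NumericMatrix mu,
                   double rho,
                   double theta,
                   NumericVector init_state,
                   bool want_gamma_donor,
                   bool gamma_obs_only = false,
                   bool want_X = true) {
  const int A = Pi.nrow();
  const int K = donor_panel.size();
  const int S = A * K;
  const int nne = gp.size();
  if (theta <= 0.0 || theta >= 1.0) stop("theta must lie in (0, 1)");
  if (Pi.ncol() != A) stop("Pi must be square");
  if (mu.ncol() != A || mu.nrow() != P) stop("mu must be P x A");
  if (init_state.size() != S) stop("init_state must have length A*K");

  std::vector<int> Nact(P, 0);
  for (int j = 0; j < K; ++j) {
    int p = donor_panel[j];
    if (p < 0 || p >= P) stop("donor_panel entry out of range");
    Nact[p]++;
  }
  std::vector<double> PiRow(A);
  for (int a = 0; a < A; ++a) {
    double s = 0.0;
    for (int b = 0; b < A; ++b) s += Pi(a, b);
    if (s > 1.0 + 1e-12) stop("Pi row sums must not exceed 1");
    PiRow[a] = s;
  }
  // muN[a*K + j] = mu(panel(j), a) / N_active(panel(j))
  std::vector<double> muN(S);
  for (int a = 0; a < A; ++a)
    for (int j = 0; j < K; ++j)
      muN[a * K + j] = mu(donor_panel[j], a) / Nact[donor_panel[j]];

  const double lm = std::log1p(-theta), lk = std::log(theta);

  // precompute emissions at observed gridpoints (K x nne)
  std::vector<double> E((size_t)K * nne);
  {
    const int *pm = n_match.begin(), *pk = n_mismatch.begin();
    for (size_t i = 0; i < (size_t)K * nne; ++i)
      E[i] = std::exp(pm[i] * lm + pk[i] * lk);
  }

  NumericMatrix F(S, G);                 // scaled forward variables
  std::vector<double> cvec(G), logc(G);
  double *Fp = F.begin();

  // ---- forward ----
  int ptr = 0;
  {
    bool obs = (nne > 0 && gp[0] == 0);
    const double *e = obs ? &E[0] : nullptr;
    double c = 0.0;
    double *f0 = Fp;
    const double *in = init_state.begin();
    for (int s = 0; s < S; ++s) {
      double v = in[s];
      if (obs) v *= e[s % K];
      f0[s] = v;
      c += v;
    }
    if (c <= 0.0) stop("all-zero forward column at gridpoint 1");
    const double ic = 1.0 / c;
    for (int s = 0; s < S; ++s) f0[s] *= ic;
    cvec[0] = c; logc[0] = std::log(c);
    if (obs) ptr = 1;
  }
  std::vector<double> Ssum(A), inflow(A);
  for (int g = 1; g < G; ++g) {
    bool obs = (ptr < nne && gp[ptr] == g);
    const double *e = obs ? &E[(size_t)ptr * K] : nullptr;
    const double *fprev = Fp + (size_t)(g - 1) * S;
    double *f = Fp + (size_t)g * S;
    for (int b = 0; b < A; ++b) {
      double s = 0.0;
      const double *fb = fprev + b * K;
      for (int j = 0; j < K; ++j) s += fb[j];
      Ssum[b] = s;
    }
    for (int a = 0; a < A; ++a) {
      double v = ((1.0 - PiRow[a]) * rho + Pi(a, a)) * Ssum[a];
      for (int b = 0; b < A; ++b)
        if (b != a) v += Pi(b, a) * Ssum[b];
      inflow[a] = v;
    }
    double c = 0.0;
    for (int a = 0; a < A; ++a) {
      const double stayf = (1.0 - PiRow[a]) * (1.0 - rho);
      const double infa = inflow[a];
      const double *fa = fprev + a * K;
      const double *mn = &muN[a * K];
      double *fo = f + a * K;
      if (obs) {
        for (int j = 0; j < K; ++j) {
          double v = (fa[j] * stayf + mn[j] * infa) * e[j];
          fo[j] = v; c += v;
        }
      } else {
        for (int j = 0; j < K; ++j) {
          double v = fa[j] * stayf + mn[j] * infa;
          fo[j] = v; c += v;
        }
      }
    }
    if (c <= 0.0) stop("all-zero forward column at gridpoint " +
                       std::to_string(g + 1));
    const double ic = 1.0 / c;
    for (int s = 0; s < S; ++s) f[s] *= ic;
    cvec[g] = c; logc[g] = std::log(c);
    if (obs) ptr++;
  }
  double loglik = 0.0;
  for (int g = 0; g < G; ++g) loglik += logc[g];

  // ---- backward with event-count accumulation ----
  NumericMatrix X(want_X ? G : 0, A);
  NumericMatrix gdon;
  const int grows = want_gamma_donor ? (gamma_obs_only ? nne : G) : 0;
  if (want_gamma_donor) gdon = NumericMatrix(grows, K);
  double *gd = want_gamma_donor ? gdon.begin() : nullptr;
  NumericMatrix sw(A, A);
  NumericVector hapsw(A), stay(A);
  NumericMatrix arr(P, A);
  double emit_m = 0.0, emit_k = 0.0;

  std::vector<double> beta(S, 1.0), betag(S), u(S), U(A), Up((size_t)P * A),
      Fb(A), infb(A);

  // helper lambda: posteriors/emission counts at gridpoint g given beta
  auto posteriors_at = [&](int g, int obs_ptr) {
    const double *f = Fp + (size_t)g * S;
    if (want_X) {
      for (int a = 0; a < A; ++a) {
        double s = 0.0;
        const double *fa = f + a * K;
        const double *ba = beta.data() + a * K;
        for (int j = 0; j < K; ++j) s += fa[j] * ba[j];
        X(g, a) = s;
      }
    }
    const bool need_g = want_gamma_donor && (!gamma_obs_only || obs_ptr >= 0);
    if (need_g || obs_ptr >= 0) {
      const int grow = gamma_obs_only ? obs_ptr : g;
      const int *pm = obs_ptr >= 0 ? &n_match.begin()[(size_t)obs_ptr * K]
                                   : nullptr;
      const int *pk = obs_ptr >= 0 ? &n_mismatch.begin()[(size_t)obs_ptr * K]
                                   : nullptr;
      for (int j = 0; j < K; ++j) {
        double gj = 0.0;
        for (int a = 0; a < A; ++a) gj += f[a * K + j] * beta[a * K + j];
        if (need_g) gd[grow + (size_t)grows * j] = gj;
        if (obs_ptr >= 0) {
          emit_m += gj * pm[j];
          emit_k += gj * pk[j];
        }
      }
    }
  };

  ptr = nne - 1;
  {
    int g = G - 1;
    bool obs = (nne > 0 && gp[nne - 1] == g);
    posteriors_at(g, obs ? nne - 1 : -1);
    if (obs) ptr = nne - 2;
  }

  for (int g = G - 2; g >= 0; --g) {
    const int g1 = g + 1;
    int ptr1 = ptr + 1;
    bool obs1 = (ptr1 < nne && gp[ptr1] == g1);
    const double *e1 = obs1 ? &E[(size_t)ptr1 * K] : nullptr;
    const double *f = Fp + (size_t)g * S;
    const double icc = 1.0 / cvec[g1];
    std::fill(Up.begin(), Up.end(), 0.0);
    // single fused sweep: u, U, per-panel U, forward sums and stay mass
    for (int a = 0; a < A; ++a) {
      double sU = 0.0, sF = 0.0, st = 0.0;
      const double *mn = &muN[a * K];
      const double *fa = f + a * K;
      const double *ba = beta.data() + a * K;
      double *ua = u.data() + a * K;
      double *upa = Up.data() + (size_t)a * P;
      for (int j = 0; j < K; ++j) {
        const double uj = obs1 ? e1[j] * ba[j] : ba[j];
        ua[j] = uj;
        const double t = mn[j] * uj;
        sU += t;
        upa[donor_panel[j]] += t;
        sF += fa[j];
        st += fa[j] * uj;
      }
      U[a] = sU;
      Fb[a] = sF;
      stay[a] += (1.0 - PiRow[a]) * (1.0 - rho) * st * icc;
    }
    for (int b = 0; b < A; ++b)
      for (int a = 0; a < A; ++a)
        sw(b, a) += Fb[b] * Pi(b, a) * U[a] * icc;
    for (int a = 0; a < A; ++a) {
      hapsw[a] += Fb[a] * (1.0 - PiRow[a]) * rho * U[a] * icc;
      double arrmass = Fb[a] * (1.0 - PiRow[a]) * rho;
      for (int b = 0; b < A; ++b) arrmass += Fb[b] * Pi(b, a);
      for (int p = 0; p < P; ++p)
        arr(p, a) += arrmass * Up[(size_t)a * P + p] * icc;
    }

    for (int b = 0; b < A; ++b) {
      double v = ((1.0 - PiRow[b]) * rho + Pi(b, b)) * U[b];
      for (int a = 0; a < A; ++a)
        if (a != b) v += Pi(b, a) * U[a];
      infb[b] = v;
    }
    for (int b = 0; b < A; ++b) {
      const double stayf = (1.0 - PiRow[b]) * (1.0 - rho);
      const double ib = infb[b];
      const double *ub = u.data() + b * K;
      double *bg = betag.data() + b * K;
      for (int j = 0; j < K; ++j) bg[j] = (stayf * ub[j] + ib) * icc;
    }
    std::swap(beta, betag);

    bool obs = (ptr >= 0 && gp[ptr] == g);
    posteriors_at(g, obs ? ptr : -1);
    if (obs) ptr--;
  }

  // backward-pass likelihood: sum_s init*e0*beta0 replaces c_0
  double bl = 0.0;
  {
    bool obs = (nne > 0 && gp[0] == 0);
    const double *e = obs ? &E[0] : nullptr;
    const double *in = init_state.begin();
    for (int s = 0; s < S; ++s)
      bl += in[s] * (obs ? e[s % K] : 1.0) * beta[s];
  }
  double loglik_back = G == 1 ? loglik : std::log(bl);
  for (int g = 1; g < G && G > 1; ++g) loglik_back += logc[g];

  return List::create(
      _["loglik"] = loglik, _["loglik_backward"] = loglik_back,
      _["X"] = want_X ? (SEXP)X : R_NilValue,
      _["gamma_donor"] = want_gamma_donor ? (SEXP)gdon : R_NilValue,
      _["switch_ba"] = sw, _["hapswitch_within"] = hapsw, _["stay"] = stay,
      _["arrivals_pa"] = arr, _["emit_match"] = emit_m,
      _["emit_mismatch"] = emit_k, _["logc"] = logc);
}
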