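#include <Rcpp.h>
using namespace Rcpp;

// Forward-backward smoother for the switching-dynamics position decoder.
// Joint latent state = (dynamic d in 0..D-1, position bin x in 0..B-1).
// Transition factorizes as P(d'|d) * K_{d'}(x -> x'): the switch matrix picks
// the next dynamic, whose own position kernel then moves the position.
// Emissions arrive as a B x T matrix of position log-likelihoods (columns are
// time bins, contiguous in memory).
//
// Returns per-time-bin MAP position (argmax of the position marginal, lowest
// index on ties), dynamic marginal, posterior spread (mean squared track
// distance from the MAP bin, cm^2), and optionally the full position marginal
// and joint posterior (both T-rowed).
// [[Rcpp::export]]
List fb_smoother(NumericMatrix logemit, List kernels, NumericMatrix sw,
                 NumericMatrix bindist, bool return_marginal = false,
                 bool return_joint = false) {
  const int B = logemit.nrow(), T = logemit.ncol(), D = sw.nrow();
  const int S = D * B;
  std::vector<NumericMatrix> K(D);
  for (int d = 0; d < D; ++d) K[d] = as<NumericMatrix>(kernels[d]);

  NumericMatrix alpha(S, T);  // scaled forward messages, one column per bin
  std::vector<double> e(B), pred(S), mix(S), beta(S), beta_new(S), v(S), g(S);

  auto emis = [&](int t) {  // emission column -> exp(log e - max)
    const double* col = &logemit(0, t);
    double m = col[0];
    for (int x = 1; x < B; ++x) m = std::max(m, col[x]);
    for (int x = 0; x < B; ++x) e[x] = std::exp(col[x] - m);
  };

  // forward pass, scaled; uniform initial state
  emis(0);
  double s0 = 0.0;
  for (int d = 0; d < D; ++d)
    for (int x = 0; x < B; ++x) { alpha(d * B + x, 0) = e[x]; s0 += e[x]; }
  for (int j = 0; j < S; ++j) alpha(j, 0) /= s0;

  for (int t = 1; t < T; ++t) {
    emis(t);
    const double* ap = &alpha(0, t - 1);
    // mix(d', x) = sum_d sw(d, d') alpha(t-1, d, x)
    for (int dp = 0; dp < D; ++dp)
      for (int x = 0; x < B; ++x) {
        double acc = 0.0;
        for (int d = 0; d < D; ++d) acc += sw(d, dp) * ap[d * B + x];
        mix[dp * B + x] = acc;
      }
    // pred(d', x') = sum_x mix(d', x) K_{d'}(x, x'); then * emission
    double sc = 0.0;
    for (int dp = 0; dp < D; ++dp) {
      NumericMatrix& Kd = K[dp];
      for (int xp = 0; xp < B; ++xp) {
        const double* kcol = &Kd(0, xp);  // column xp: K(from = x, to = xp)
        double acc = 0.0;
        for (int x = 0; x < B; ++x) acc += mix[dp * B + x] * kcol[x];
        double val = acc * e[xp];
        pred[dp * B + xp] = val;
        sc += val;
      }
    }
    double* an = &alpha(0, t);
    if (sc <= 0.0 || !R_finite(sc)) {
      for (int j = 0; j < S; ++j) an[j] = 1.0 / S;  // degenerate emission row
    } else {
      for (int j = 0; j < S; ++j) an[j] = pred[j] / sc;
    }
  }

  // backward pass + posteriors
  IntegerVector map_bin(T);
  NumericMatrix dyn(T, D);
  NumericVector spread(T);
  NumericMatrix marg, joint;
  if (return_marginal) marg = NumericMatrix(T, B);
  if (return_joint) joint = NumericMatrix(T, S);
  std::vector<double> pm(B);

  std::fill(beta.begin(), beta.end(), 1.0);
  for (int t = T - 1; t >= 0; --t) {
    const double* ap = &alpha(0, t);
    double tot = 0.0;
    for (int j = 0; j < S; ++j) { g[j] = ap[j] * beta[j]; tot += g[j]; }
    for (int j = 0; j < S; ++j) g[j] /= tot;
    for (int x = 0; x < B; ++x) pm[x] = 0.0;
    for (int d = 0; d < D; ++d) {
      double ds = 0.0;
      for (int x = 0; x < B; ++x) { pm[x] += g[d * B + x]; ds += g[d * B + x]; }
      dyn(t, d) = ds;
    }
    int mb = 0;
    for (int x = 1; x < B; ++x) if (pm[x] > pm[mb]) mb = x;
    map_bin[t] = mb + 1;  // 1-based
    double sp = 0.0;
    for (int x = 0; x < B; ++x) sp += pm[x] * bindist(x, mb) * bindist(x, mb);
    spread[t] = sp;
    if (return_marginal) for (int x = 0; x < B; ++x) marg(t, x) = pm[x];
    if (return_joint) for (int j = 0; j < S; ++j) joint(t, j) = g[j];

    if (t > 0) {
      emis(t);
      // v(d', x) = sum_x' K_{d'}(x, x') e(x') beta(d', x')
      for (int dp = 0; dp < D; ++dp) {
        NumericMatrix& Kd = K[dp];
        for (int x = 0; x < B; ++x) v[dp * B + x] = 0.0;
        for (int xp = 0; xp < B; ++xp) {
          double w = e[xp] * beta[dp * B + xp];
          if (w == 0.0) continue;
          const double* kcol = &Kd(0, xp);
          double* vd = &v[dp * B];
          for (int x = 0; x < B; ++x) vd[x] += kcol[x] * w;
        }
      }
      // beta_t(d, x) = sum_d' sw(d, d') v(d', x), rescaled
      double bs = 0.0;
      for (int d = 0; d < D; ++d)
        for (int x = 0; x < B; ++x) {
          double acc = 0.0;
          for (int dp = 0; dp < D; ++dp) acc += sw(d, dp) * v[dp * B + x];
          beta_new[d * B + x] = acc;
          bs += acc;
        }
      for (int j = 0; j < S; ++j) beta[j] = beta_new[j] * (S / bs);
    }
  }

  List out = List::create(_["map_bin"] = map_bin, _["dyn"] = dyn,
                          _["spread"] = spread);
  if (return_marginal) out["marginal"] = marg;
  if (return_joint) out["joint"] = joint;
  return out;
}
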