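#include <Rcpp.h>
using namespace Rcpp;

// RHS of the four-variable Notch-Wnt-YAP network.
// p order: kNotch kWntSC kWntTA kYAP kdNotch kdWntSC kdWntTA kdYAP
//          kPNotch kPWntSC kPWntTA kPYAP
static inline void nwy_rhs(const double *y, const double *p, double n,
                           double *f) {
  double AN = y[0], WS = y[1], WT = y[2], AY = y[3];
  double hN = std::pow(AN, n);
  double ws = std::pow(WS, n), wt = std::pow(WT, n), ay = std::pow(AY, n);
  f[0] = p[0] * ws / (1.0 + ws + ay + wt) - p[4] * AN + p[8];
  f[1] = p[1] * hN / (1.0 + hN) - p[5] * WS + p[9];
  f[2] = p[2] / (1.0 + hN) - p[6] * WT + p[10];
  f[3] = p[3] * hN / (1.0 + hN) - p[7] * AY + p[11];
}

// One Euler-Maruyama trajectory with fixed step dt, recording every
// record_every steps (including the initial state). Noise is drawn from
// R's RNG so that set.seed() in R controls the trajectory's substream.
// reflect = true mirrors negative excursions at zero.
// [[Rcpp::export]]
NumericMatrix em_trajectory_cpp(NumericVector y0, NumericVector p, double n,
                                double sigma, double dt, int nsteps,
                                int record_every, bool reflect) {
  if (y0.size() != 4 || p.size() != 12)
    stop("em_trajectory_cpp: bad input sizes");
  int nrec = nsteps / record_every + 1;
  NumericMatrix out(nrec, 4);
  double y[4], f[4];
  for (int j = 0; j < 4; ++j) { y[j] = y0[j]; out(0, j) = y[j]; }
  double sq = sigma * std::sqrt(dt);
  int row = 1;
  bool pow_int = (n == std::floor(n));
  for (int s = 1; s <= nsteps; ++s) {
    nwy_rhs(y, p.begin(), n, f);
    for (int j = 0; j < 4; ++j) {
      y[j] += f[j] * dt;
      if (sigma > 0.0) y[j] += sq * norm_rand();
      if (reflect && y[j] < 0.0) y[j] = -y[j];
      if (!pow_int && y[j] < 0.0) y[j] = 0.0;  // keep fractional powers real
    }
    if (s % record_every == 0) {
      for (int j = 0; j < 4; ++j) out(row, j) = y[j];
      ++row;
    }
    if (!R_finite(y[0]) || !R_finite(y[1]) || !R_finite(y[2]) ||
        !R_finite(y[3])) {
      for (int r = row; r < nrec; ++r)
        for (int j = 0; j < 4; ++j) out(r, j) = NA_REAL;
      break;
    }
  }
  return out;
}
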