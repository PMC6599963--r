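// Gibbs sampling kernels: truncated-normal liability draws and one full
// single-site sweep over all location effects. Both use R's RNG stream so
// chains are exactly reproducible from set.seed().

#include <Rcpp.h>
using namespace Rcpp;

// standard-deviation-1 normal truncated to one side of zero.
// side < 0: (-inf, 0); side > 0: [0, inf). Inverse-CDF with clamping.
static inline double rtnorm_side(double mu, int side) {
  double p0 = R::pnorm(0.0, mu, 1.0, 1, 0);
  double u;
  if (side < 0) {
    if (p0 < 1e-300) p0 = 1e-300;
    u = unif_rand() * p0;
  } else {
    u = p0 + unif_rand() * (1.0 - p0);
  }
  if (u < 1e-16) u = 1e-16;
  if (u > 1.0 - 1e-16) u = 1.0 - 1e-16;
  double x = R::qnorm(u, mu, 1.0, 1, 0);
  if (side < 0 && x >= 0) x = -1e-8;
  if (side > 0 && x < 0) x = 1e-8;
  return x;
}

// [[Rcpp::export]]
NumericVector cpp_rtrunc_liability(NumericVector eta, IntegerVector category) {
  int n = eta.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = rtnorm_side(eta[i], category[i] == 1 ? -1 : +1);
  return out;
}

// Redraw stayability liabilities in place. y holds the working liability
// for STAY data rows; e = y - W theta is kept consistent.
// [[Rcpp::export]]
void cpp_sample_liabilities(NumericVector y, NumericVector e,
                            IntegerVector rows, IntegerVector category) {
  int n = rows.size();
  for (int k = 0; k < n; ++k) {
    int r = rows[k] - 1;
    double eta = y[r] - e[r];
    double lam = rtnorm_side(eta, category[k] == 1 ? -1 : +1);
    e[r] += lam - y[r];
    y[r] = lam;
  }
}

// One full single-site sweep of every location effect, ascending columns.
// col_type: 0 fixed (flat prior), 1 genetic (A-inverse x C-inverse),
// 2 group (iid), 3 litter (I x K-inverse). theta and e are updated in
// place; e = y - W theta stays consistent throughout.
// [[Rcpp::export]]
void cpp_location_sweep(S4 W, NumericVector e, NumericVector theta,
                        NumericVector rinv, IntegerVector col_type,
                        IntegerVector col_unit, IntegerVector col_effect,
                        IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
                        NumericMatrix Cinv, NumericMatrix Kinv,
                        double group_prec, int gen_off, int lit_off) {
  IntegerVector Wp = W.slot("p"), Wi = W.slot("i");
  NumericVector Wx = W.slot("x");
  int ncol = Wp.size() - 1;
  for (int j = 0; j < ncol; ++j) {
    double wre = 0.0, wrw = 0.0;
    for (int k = Wp[j]; k < Wp[j + 1]; ++k) {
      double w = Wx[k];
      double ri = rinv[Wi[k]];
      wre += w * e[Wi[k]] * ri;
      wrw += w * w * ri;
    }
    double prec = wrw;
    double rhs = wre + wrw * theta[j];
    int type = col_type[j];
    if (type == 1) {
      int a = col_unit[j] - 1, t = col_effect[j] - 1;
      double aii = 0.0, cross = 0.0;
      for (int k = Ap[a]; k < Ap[a + 1]; ++k) {
        int nb = Ai[k];
        double av = Ax[k];
        if (nb == a) aii = av;
        double s = 0.0;
        int base = gen_off + 4 * nb;
        for (int tt = 0; tt < 4; ++tt) s += Cinv(t, tt) * theta[base + tt];
        cross += av * s;
      }
      double dprec = aii * Cinv(t, t);
      cross -= dprec * theta[j];
      prec += dprec;
      rhs -= cross;
    } else if (type == 2) {
      prec += group_prec;
    } else if (type == 3) {
      int L = col_unit[j] - 1, t = col_effect[j] - 1;
      double cross = 0.0;
      int base = lit_off + 4 * L;
      for (int tt = 0; tt < 4; ++tt)
        if (tt != t) cross += Kinv(t, tt) * theta[base + tt];
      prec += Kinv(t, t);
      rhs -= cross;
    }
    if (!(prec > 0.0) || !R_finite(prec))
      stop("non-finite conditional precision at column %d", j + 1);
    double val = rhs / prec + norm_rand() / std::sqrt(prec);
    double diff = val - theta[j];
    if (diff != 0.0)
      for (int k = Wp[j]; k < Wp[j + 1]; ++k) e[Wi[k]] -= Wx[k] * diff;
    theta[j] = val;
  }
}
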