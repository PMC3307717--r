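// Forward-algorithm likelihood over the 8 joint association states,
// compiled for use inside the MCMC loop. Mirrors the R reference
// implementation in R/likelihood.R exactly (same state order: index =
// 4*s1 + 2*s3p + s3d; same orientation mixture with prior 1/2 each).
//
// Per call, emissions are tabulated once per (site, observed-pair code)
// — the observed pair (parent, daughter) takes one of 9 codes (0/1/NA on
// each strand) — and transition matrices are cached per distinct gap and
// stored transposed so the forward matvec reads contiguously.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <map>
using namespace Rcpp;

namespace {

struct Mat2 {
  double a00, a01, a10, a11;  // rows: current state 0/1, cols: next state
};

// assoc -> assoc combines processivity (1 - d) with within-gap
// dissociation-reassociation (d * r)
Mat2 per_bp(double r, double d) {
  Mat2 m = {1.0 - r, r, d * (1.0 - r), 1.0 - d + d * r};
  return m;
}

Mat2 matmul(const Mat2& x, const Mat2& y) {
  Mat2 z;
  z.a00 = x.a00 * y.a00 + x.a01 * y.a10;
  z.a01 = x.a00 * y.a01 + x.a01 * y.a11;
  z.a10 = x.a10 * y.a00 + x.a11 * y.a10;
  z.a11 = x.a10 * y.a01 + x.a11 * y.a11;
  return z;
}

Mat2 matpow(Mat2 m, int L) {
  Mat2 out = {1.0, 0.0, 0.0, 1.0};
  while (L > 0) {
    if (L & 1) out = matmul(out, m);
    L >>= 1;
    if (L > 0) m = matmul(m, m);
  }
  return out;
}

inline double entry(const Mat2& m, int i, int j) {
  return i == 0 ? (j == 0 ? m.a00 : m.a01) : (j == 0 ? m.a10 : m.a11);
}

// stationary law of one chain; frozen unassociated when r = d = 0
inline void stationary(double r, double d, double* pi) {
  if (r + d <= 0.0) { pi[0] = 1.0; pi[1] = 0.0; return; }
  double f = r / (r + d * (1.0 - r));
  pi[0] = 1.0 - f; pi[1] = f;
}

inline int obs_code(int obs) { return obs == NA_INTEGER ? 2 : obs; }

}  // namespace

// theta order: r1 d1 r3p d3p r3d d3d mu1 delta1 mu3 delta3 e_fail e_inap
// [[Rcpp::export]]
double dataset_loglik_cpp(IntegerMatrix obs_a, IntegerMatrix obs_b,
                          IntegerVector mult, IntegerVector gaps,
                          NumericVector theta, NumericVector m) {
  const int n = obs_a.nrow(), S = obs_a.ncol();
  if (S < 1 || gaps.size() != S - 1 || m.size() != S)
    stop("inconsistent dimensions in likelihood core");
  const double r1 = theta[0], d1 = theta[1], r3p = theta[2], d3p = theta[3],
               r3d = theta[4], d3d = theta[5], mu1 = theta[6],
               delta1 = theta[7], mu3 = theta[8], delta3 = theta[9],
               e_fail = theta[10], e_inap = theta[11];

  // joint transition matrices per gap, transposed: AT[sp*8 + s]
  std::map<int, std::vector<double> > cache;
  std::vector<const double*> trans(S > 1 ? S - 1 : 0);
  for (int g = 0; g < S - 1; ++g) {
    int L = gaps[g];
    if (L < 1) stop("inter-site distance must be >= 1 bp");
    std::map<int, std::vector<double> >::iterator it = cache.find(L);
    if (it == cache.end()) {
      Mat2 T1 = matpow(per_bp(r1, d1), L);
      Mat2 T3p = matpow(per_bp(r3p, d3p), L);
      Mat2 T3d = matpow(per_bp(r3d, d3d), L);
      std::vector<double> A(64);
      for (int s = 0; s < 8; ++s)
        for (int sp = 0; sp < 8; ++sp)
          A[sp * 8 + s] = entry(T1, s >> 2, sp >> 2) *
                          entry(T3p, (s >> 1) & 1, (sp >> 1) & 1) *
                          entry(T3d, s & 1, sp & 1);
      it = cache.insert(std::make_pair(L, A)).first;
    }
    trans[g] = &it->second[0];
  }

  double pi1[2], pi3p[2], pi3d[2], init[8];
  stationary(r1, d1, pi1);
  stationary(r3p, d3p, pi3p);
  stationary(r3d, d3d, pi3d);
  for (int s = 0; s < 8; ++s)
    init[s] = pi1[s >> 2] * pi3p[(s >> 1) & 1] * pi3d[s & 1];

  // daughter-strand methylation probability per state, by z branch
  double pD1[8], pD0[8];
  for (int s = 0; s < 8; ++s) {
    int s1 = s >> 2, s3d = s & 1;
    pD1[s] = 1.0 - (1.0 - s1 * mu1) * (1.0 - s3d * mu3);
    pD0[s] = 1.0 - (1.0 - s1 * delta1) * (1.0 - s3d * delta3);
  }
  // P(observed | true) per strand; index [code][truth]; code 2 = missing
  const double slik[3][2] = {
    {1.0 - e_fail, e_inap}, {e_fail, 1.0 - e_inap}, {1.0, 1.0}};

  // emission table: etab[(i*9 + code)*8 + s], code = 3*cp + cd over the
  // observed (parent, daughter) pair
  std::vector<double> etab(S * 9 * 8);
  for (int i = 0; i < S; ++i) {
    double mi = m[i];
    for (int cp = 0; cp < 3; ++cp) for (int cd = 0; cd < 3; ++cd) {
      double* e = &etab[(i * 9 + cp * 3 + cd) * 8];
      const double* lp = slik[cp];
      const double* ld = slik[cd];
      for (int s = 0; s < 8; ++s) {
        int s3p = (s >> 1) & 1;
        // z = 1: parent truly methylated
        double e1 = lp[1] * (pD1[s] * ld[1] + (1.0 - pD1[s]) * ld[0]);
        // z = 0: parent truly methylated iff s3p associated
        double e0 = lp[s3p] * (pD0[s] * ld[1] + (1.0 - pD0[s]) * ld[0]);
        e[s] = mi * e1 + (1.0 - mi) * e0;
      }
    }
  }

  double total = 0.0;
  double alpha[8], tmp[8];
  std::vector<int> ca(S), cb(S);

  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < S; ++i) {
      ca[i] = obs_code(obs_a(j, i));
      cb[i] = obs_code(obs_b(j, i));
    }
    double ll_orient[2];
    for (int orient = 0; orient < 2; ++orient) {
      double loglik = 0.0, tot = 0.0;
      const double* e0v =
        &etab[(0 * 9 + (orient == 0 ? ca[0] * 3 + cb[0]
                                    : cb[0] * 3 + ca[0])) * 8];
      for (int s = 0; s < 8; ++s) { alpha[s] = init[s] * e0v[s]; tot += alpha[s]; }
      if (tot <= 0.0) { ll_orient[orient] = R_NegInf; continue; }
      loglik = std::log(tot);
      for (int s = 0; s < 8; ++s) alpha[s] /= tot;
      bool dead = false;
      for (int i = 1; i < S; ++i) {
        const double* AT = trans[i - 1];
        const double* ev =
          &etab[(i * 9 + (orient == 0 ? ca[i] * 3 + cb[i]
                                      : cb[i] * 3 + ca[i])) * 8];
        tot = 0.0;
        for (int sp = 0; sp < 8; ++sp) {
          const double* col = AT + sp * 8;
          double acc = 0.0;
          for (int s = 0; s < 8; ++s) acc += alpha[s] * col[s];
          tmp[sp] = acc * ev[sp];
          tot += tmp[sp];
        }
        if (tot <= 0.0) { dead = true; break; }
        loglik += std::log(tot);
        for (int sp = 0; sp < 8; ++sp) alpha[sp] = tmp[sp] / tot;
      }
      ll_orient[orient] = dead ? R_NegInf : loglik;
    }
    // log(0.5 exp(llA) + 0.5 exp(llB))
    double mx = ll_orient[0] > ll_orient[1] ? ll_orient[0] : ll_orient[1];
    double ll;
    if (mx == R_NegInf) ll = R_NegInf;
    else ll = mx + std::log(0.5 * std::exp(ll_orient[0] - mx) +
                            0.5 * std::exp(ll_orient[1] - mx));
    if (ll == R_NegInf) return R_NegInf;
    total += mult[j] * ll;
  }
  return total;
}
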