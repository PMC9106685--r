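// Streaming kernels for the measurement-weighted posterior computations.
// Posterior tables and measurement-weight matrices arrive as dgCMatrix
// objects; columns of the L matrices are measurements, columns of the P
// matrices are signal bins over the flattened (v, m) scene grid.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Csc {
  IntegerVector p, i;
  NumericVector x;
  int nrow, ncol;
  explicit Csc(const S4& m) {
    p = m.slot("p");
    i = m.slot("i");
    x = m.slot("x");
    IntegerVector dim = m.slot("Dim");
    nrow = dim[0];
    ncol = dim[1];
  }
};

// Accumulate sum_x L(x, j) * P[, x] into buf; touched cells recorded for
// O(nnz) reset.
inline void accumulate(const Csc& P, const Csc& L, int j,
                       std::vector<double>& buf, std::vector<int>& touched) {
  for (int k = L.p[j]; k < L.p[j + 1]; ++k) {
    const int col = L.i[k];
    const double w = L.x[k];
    if (w == 0.0) continue;
    for (int q = P.p[col]; q < P.p[col + 1]; ++q) {
      const int cell = P.i[q];
      if (buf[cell] == 0.0) touched.push_back(cell);
      buf[cell] += w * P.x[q];
    }
  }
}

}  // namespace

// Per measurement j: weighted posteriors B_cd = P_cd L_cd[, j],
// B_cs = P_cs L_cs[, j]; marginal means of m and v for each cue alone and
// for the renormalised elementwise product (combined). Masses are the
// pre-normalisation totals so callers can detect unsupported measurements.
// [[Rcpp::export]]
List cpp_joint_estimates(S4 Pcd_, S4 Pcs_, S4 Lcd_, S4 Lcs_,
                         NumericVector vm_v, NumericVector vm_m) {
  Csc Pcd(Pcd_), Pcs(Pcs_), Lcd(Lcd_), Lcs(Lcs_);
  const int n_vm = Pcd.nrow;
  const int n = Lcd.ncol;
  if (Lcs.ncol != n) stop("L matrices must have equal column counts");
  if (Pcs.nrow != n_vm || (int)vm_v.size() != n_vm || (int)vm_m.size() != n_vm)
    stop("scene-grid dimensions disagree");
  if (Lcd.nrow != Pcd.ncol || Lcs.nrow != Pcs.ncol)
    stop("signal-grid dimensions disagree");

  NumericVector m_cd(n), v_cd(n), mass_cd(n);
  NumericVector m_cs(n), v_cs(n), mass_cs(n);
  NumericVector m_comb(n), v_comb(n), mass_comb(n);

  std::vector<double> bufcd(n_vm, 0.0), bufcs(n_vm, 0.0);
  std::vector<int> tcd, tcs;
  tcd.reserve(4096);
  tcs.reserve(4096);

  for (int j = 0; j < n; ++j) {
    accumulate(Pcd, Lcd, j, bufcd, tcd);
    accumulate(Pcs, Lcs, j, bufcs, tcs);

    double scd = 0, scd_m = 0, scd_v = 0;
    for (int idx : tcd) {
      const double p = bufcd[idx];
      scd += p;
      scd_m += p * vm_m[idx];
      scd_v += p * vm_v[idx];
    }
    double scs = 0, scs_m = 0, scs_v = 0;
    for (int idx : tcs) {
      const double p = bufcs[idx];
      scs += p;
      scs_m += p * vm_m[idx];
      scs_v += p * vm_v[idx];
    }
    double sc = 0, sc_m = 0, sc_v = 0;
    const std::vector<int>& shorter = (tcd.size() < tcs.size()) ? tcd : tcs;
    for (int idx : shorter) {
      const double p = bufcd[idx] * bufcs[idx];
      if (p == 0.0) continue;
      sc += p;
      sc_m += p * vm_m[idx];
      sc_v += p * vm_v[idx];
    }

    mass_cd[j] = scd;
    mass_cs[j] = scs;
    mass_comb[j] = sc;
    m_cd[j] = scd > 0 ? scd_m / scd : NA_REAL;
    v_cd[j] = scd > 0 ? scd_v / scd : NA_REAL;
    m_cs[j] = scs > 0 ? scs_m / scs : NA_REAL;
    v_cs[j] = scs > 0 ? scs_v / scs : NA_REAL;
    m_comb[j] = sc > 0 ? sc_m / sc : NA_REAL;
    v_comb[j] = sc > 0 ? sc_v / sc : NA_REAL;

    for (int idx : tcd) bufcd[idx] = 0.0;
    for (int idx : tcs) bufcs[idx] = 0.0;
    tcd.clear();
    tcs.clear();
  }

  return List::create(
      _["m_cd"] = m_cd, _["v_cd"] = v_cd, _["mass_cd"] = mass_cd,
      _["m_cs"] = m_cs, _["v_cs"] = v_cs, _["mass_cs"] = mass_cs,
      _["m_comb"] = m_comb, _["v_comb"] = v_comb, _["mass_comb"] = mass_comb);
}

// Expected co-occurrence mass per measurement:
// sum_{a,b} L_cs(a, j) * C(a, b) * L_cd(b, j).
// [[Rcpp::export]]
NumericVector cpp_cooccur_prob(NumericMatrix C, S4 Lcs_, S4 Lcd_) {
  Csc Lcs(Lcs_), Lcd(Lcd_);
  const int n = Lcd.ncol;
  if (Lcs.ncol != n) stop("L matrices must have equal column counts");
  if (Lcs.nrow != C.nrow() || Lcd.nrow != C.ncol())
    stop("co-occurrence table dimensions disagree");
  NumericVector out(n);
  for (int j = 0; j < n; ++j) {
    double acc = 0;
    for (int kb = Lcd.p[j]; kb < Lcd.p[j + 1]; ++kb) {
      const int b = Lcd.i[kb];
      const double wb = Lcd.x[kb];
      double inner = 0;
      for (int ka = Lcs.p[j]; ka < Lcs.p[j + 1]; ++ka)
        inner += Lcs.x[ka] * C(Lcs.i[ka], b);
      acc += wb * inner;
    }
    out[j] = acc;
  }
  return out;
}

// Gram-factorised variant: the cross-cue sums over scene cells are
// precomputed as G(x, y) = sum_c Pcd(c, x) Pcs(c, y) (and m- and
// v-weighted versions), so each measurement costs only
// |supp(L_cd)| x |supp(L_cs)| operations. Per-cue estimates use the
// tables' per-bin masses and marginal means. Algebraically identical to
// cpp_joint_estimates.
// [[Rcpp::export]]
List cpp_joint_estimates_gram(NumericMatrix G, NumericMatrix Gm,
                              NumericMatrix Gv,
                              NumericVector mass_cd, NumericVector mmean_cd,
                              NumericVector vmean_cd,
                              NumericVector mass_cs, NumericVector mmean_cs,
                              NumericVector vmean_cs,
                              S4 Lcd_, S4 Lcs_) {
  Csc Lcd(Lcd_), Lcs(Lcs_);
  const int n = Lcd.ncol;
  if (Lcs.ncol != n) stop("L matrices must have equal column counts");
  if (Lcd.nrow != G.nrow() || Lcs.nrow != G.ncol())
    stop("signal-grid dimensions disagree with the Gram matrices");

  NumericVector m_cd(n), v_cd(n), out_mass_cd(n);
  NumericVector m_cs(n), v_cs(n), out_mass_cs(n);
  NumericVector m_comb(n), v_comb(n), mass_comb(n);

  for (int j = 0; j < n; ++j) {
    double scd = 0, scd_m = 0, scd_v = 0;
    for (int k = Lcd.p[j]; k < Lcd.p[j + 1]; ++k) {
      const int x = Lcd.i[k];
      const double w = Lcd.x[k] * mass_cd[x];
      scd += w;
      scd_m += w * mmean_cd[x];
      scd_v += w * vmean_cd[x];
    }
    double scs = 0, scs_m = 0, scs_v = 0;
    for (int k = Lcs.p[j]; k < Lcs.p[j + 1]; ++k) {
      const int y = Lcs.i[k];
      const double w = Lcs.x[k] * mass_cs[y];
      scs += w;
      scs_m += w * mmean_cs[y];
      scs_v += w * vmean_cs[y];
    }
    // outer loop over CS bins so the inner CD-bin loop walks each Gram
    // column contiguously (matrices are column-major with CD as rows)
    double sc = 0, sc_m = 0, sc_v = 0;
    const int nrowG = G.nrow();
    const double* pG = REAL(G);
    const double* pGm = REAL(Gm);
    const double* pGv = REAL(Gv);
    for (int ky = Lcs.p[j]; ky < Lcs.p[j + 1]; ++ky) {
      const int y = Lcs.i[ky];
      const double wy = Lcs.x[ky];
      if (wy == 0.0) continue;
      const double* colG = pG + (size_t)y * nrowG;
      const double* colGm = pGm + (size_t)y * nrowG;
      const double* colGv = pGv + (size_t)y * nrowG;
      double a = 0, am = 0, av = 0;
      for (int kx = Lcd.p[j]; kx < Lcd.p[j + 1]; ++kx) {
        const int x = Lcd.i[kx];
        const double wx = Lcd.x[kx];
        a += wx * colG[x];
        am += wx * colGm[x];
        av += wx * colGv[x];
      }
      sc += wy * a;
      sc_m += wy * am;
      sc_v += wy * av;
    }
    out_mass_cd[j] = scd;
    out_mass_cs[j] = scs;
    mass_comb[j] = sc;
    m_cd[j] = scd > 0 ? scd_m / scd : NA_REAL;
    v_cd[j] = scd > 0 ? scd_v / scd : NA_REAL;
    m_cs[j] = scs > 0 ? scs_m / scs : NA_REAL;
    v_cs[j] = scs > 0 ? scs_v / scs : NA_REAL;
    m_comb[j] = sc > 0 ? sc_m / sc : NA_REAL;
    v_comb[j] = sc > 0 ? sc_v / sc : NA_REAL;
  }

  return List::create(
      _["m_cd"] = m_cd, _["v_cd"] = v_cd, _["mass_cd"] = out_mass_cd,
      _["m_cs"] = m_cs, _["v_cs"] = v_cs, _["mass_cs"] = out_mass_cs,
      _["m_comb"] = m_comb, _["v_comb"] = v_comb, _["mass_comb"] = mass_comb);
}

namespace {

// CSC triplet accumulator for the weight-matrix builders.
struct CscBuilder {
  std::vector<int> p{0}, i;
  std::vector<double> x;
  void push_column(const std::vector<int>& rows, const std::vector<double>& w) {
    double tot = 0;
    for (double v : w) tot += v;
    if (tot <= 0) stop("measurement mass falls entirely outside the signal grid");
    for (size_t k = 0; k < rows.size(); ++k) {
      i.push_back(rows[k]);
      x.push_back(w[k] / tot);
    }
    p.push_back((int)i.size());
  }
  List as_list(int nrow) const {
    return List::create(_["p"] = wrap(p), _["i"] = wrap(i), _["x"] = wrap(x),
                        _["nrow"] = nrow);
  }
};

inline int find_bin(const NumericVector& edges, double v) {
  // index of the bin whose [edges[k], edges[k+1]) contains v, clamped
  int k = (int)(std::upper_bound(edges.begin(), edges.end(), v) - edges.begin()) - 1;
  if (k < 0) k = 0;
  const int nb = edges.size() - 1;
  if (k > nb - 1) k = nb - 1;
  return k;
}

inline double hinkley_ratio_density(double z, double mu_num, double mu_den,
                                    double sd) {
  const double s2 = sd * sd;
  const double a = std::sqrt(z * z / s2 + 1.0 / s2);
  const double b = mu_num * z / s2 + mu_den / s2;
  const double c = mu_num * mu_num / s2 + mu_den * mu_den / s2;
  const double d = std::exp((b * b - c * a * a) / (2.0 * a * a));
  return b * d / (a * a * a * std::sqrt(2.0 * M_PI) * s2) *
             (2.0 * R::pnorm(b / a, 0.0, 1.0, 1, 0) - 1.0) +
         std::exp(-c / 2.0) / (a * a * M_PI * s2);
}

}  // namespace

// Gaussian CDF-difference weights over the signal bins, one column per
// measurement mean; truncated at +/- span sd and column-normalised.
// [[Rcpp::export]]
List cpp_gaussian_weights(NumericVector means, double sd, NumericVector edges,
                          double span) {
  const int nb = edges.size() - 1;
  CscBuilder out;
  std::vector<int> rows;
  std::vector<double> w;
  for (int j = 0; j < means.size(); ++j) {
    rows.clear();
    w.clear();
    if (sd <= 0) {
      rows.push_back(find_bin(edges, means[j]));
      w.push_back(1.0);
    } else {
      const int lo = find_bin(edges, means[j] - span * sd);
      const int hi = find_bin(edges, means[j] + span * sd);
      double prev = R::pnorm(edges[lo], means[j], sd, 1, 0);
      for (int k = lo; k <= hi; ++k) {
        const double cur = R::pnorm(edges[k + 1], means[j], sd, 1, 0);
        rows.push_back(k);
        w.push_back(cur - prev);
        prev = cur;
      }
    }
    out.push_column(rows, w);
  }
  return out.as_list(nb);
}

// Gaussian-ratio (Hinkley) weights: density at bin centres times bin
// widths; distributions narrower than one bin fall back to the
// delta-method Gaussian CDF integration. Matches cs_measurement_weights.
// [[Rcpp::export]]
List cpp_ratio_weights(NumericVector mu_num, NumericVector mu_den, double sd,
                       NumericVector edges, double span) {
  const int nb = edges.size() - 1;
  CscBuilder out;
  std::vector<int> rows;
  std::vector<double> w;
  for (int j = 0; j < mu_num.size(); ++j) {
    rows.clear();
    w.clear();
    const double r0 = mu_num[j] / mu_den[j];
    if (sd <= 0) {
      rows.push_back(find_bin(edges, r0));
      w.push_back(1.0);
    } else {
      if (std::min(mu_num[j], mu_den[j]) <= 3.0 * sd)
        stop("sizes within 3 n_size of zero: ratio distribution ill-behaved");
      const double sd0 = std::fabs(r0) * sd *
          std::sqrt(1.0 / (mu_num[j] * mu_num[j]) +
                    1.0 / (mu_den[j] * mu_den[j]));
      const int lo = find_bin(edges, r0 - span * sd0);
      const int hi = find_bin(edges, r0 + span * sd0);
      const bool narrow = sd0 < (edges[lo + 1] - edges[lo]);
      if (narrow) {
        double prev = R::pnorm(edges[lo], r0, sd0, 1, 0);
        for (int k = lo; k <= hi; ++k) {
          const double cur = R::pnorm(edges[k + 1], r0, sd0, 1, 0);
          rows.push_back(k);
          w.push_back(cur - prev);
          prev = cur;
        }
      } else {
        for (int k = lo; k <= hi; ++k) {
          const double cent = 0.5 * (edges[k] + edges[k + 1]);
          rows.push_back(k);
          w.push_back(hinkley_ratio_density(cent, mu_num[j], mu_den[j], sd) *
                      (edges[k + 1] - edges[k]));
        }
      }
    }
    out.push_column(rows, w);
  }
  return out.as_list(nb);
}
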