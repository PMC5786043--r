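#include <Rcpp.h>
using namespace Rcpp;

// largest sign-homogeneous super-threshold cluster mass of a t series;
// clusters never bridge alignment segments (seg) and break on sign flips
static double max_cluster_mass(const double* tv, int n, double thr,
                               const int* seg) {
  double best = 0.0, cur = 0.0;
  int cursign = 0, curseg = -1;
  for (int j = 0; j < n; ++j) {
    const double t = tv[j];
    const int s = (t > thr) ? 1 : ((t < -thr) ? -1 : 0);
    if (s != 0 && s == cursign && seg[j] == curseg) {
      cur += std::fabs(t);
    } else if (s != 0) {
      if (cur > best) best = cur;
      cur = std::fabs(t);
      cursign = s;
      curseg = seg[j];
    } else {
      if (cur > best) best = cur;
      cur = 0.0;
      cursign = 0;
      curseg = -1;
    }
  }
  if (cur > best) best = cur;
  return best;
}

// pooled-variance t from group sums and sums of squares; zero denominator
// -> 0 if the means agree, else +/- infinity
static inline double pooled_t(double sa, double sqa, int na, double sb,
                              double sqb, int nb) {
  const double ma = sa / na, mb = sb / nb;
  double sp2 = (sqa - sa * sa / na) + (sqb - sb * sb / nb);
  sp2 /= (na + nb - 2);
  if (sp2 < 0) sp2 = 0;
  const double den = std::sqrt(sp2 * (1.0 / na + 1.0 / nb));
  const double num = ma - mb;
  if (den == 0.0) {
    if (num == 0.0) return 0.0;
    return num > 0 ? R_PosInf : R_NegInf;
  }
  return num / den;
}

// Max cluster masses for the two-group permutation null. g holds the
// group-A column sums for every partition (time x n_perm, from one matrix
// product in R); group B follows from the totals, and because the groups
// are complementary the pooled variance needs only the overall sums of
// squares: (n-2) sp2 = tot2 - sa^2/na - sb^2/nb.
// [[Rcpp::export]]
NumericVector cbpt_masses_two_group_cpp(NumericMatrix g, NumericVector tot,
                                        NumericVector tot2, int n_a, int n_b,
                                        double alpha, IntegerVector seg) {
  const int nt = g.nrow(), n_perm = g.ncol();
  const double df = n_a + n_b - 2.0;
  const double thr = R::qt(1.0 - alpha / 2.0, df, 1, 0);
  const double cfac = (1.0 / n_a + 1.0 / n_b) / df;
  std::vector<double> tv(nt);
  NumericVector out(n_perm);
  for (int p = 0; p < n_perm; ++p) {
    const double* sa = &g(0, p);
    for (int t = 0; t < nt; ++t) {
      const double a = sa[t];
      const double b = tot[t] - a;
      const double num = a / n_a - b / n_b;
      double sp2 = tot2[t] - a * a / n_a - b * b / n_b;
      if (sp2 < 0) sp2 = 0;
      const double den = std::sqrt(sp2 * cfac);
      tv[t] = (den == 0.0)
        ? (num == 0.0 ? 0.0 : (num > 0 ? R_PosInf : R_NegInf))
        : num / den;
    }
    out[p] = max_cluster_mass(tv.data(), nt, thr, &seg[0]);
  }
  return out;
}

// Max cluster masses for the multi-level null with preferred/non-preferred
// selection redone inside every partition. g is (2*T+1) x ((nlev-1)*n_perm):
// per level block l and partition p, rows 0..T-1 hold the level's column
// sums of x, rows T..2T-1 of x^2, and row 2T the sum of the selection
// statistic. The last level follows from the totals.
// [[Rcpp::export]]
NumericVector cbpt_masses_selected_cpp(NumericMatrix g, NumericVector tot,
                                       NumericVector tot2, double tot_tm,
                                       IntegerVector nl, int n_perm,
                                       double alpha, IntegerVector seg) {
  const int nt = tot.size();
  const int nlev = nl.size();
  std::vector<double> tv(nt), last_x(nt), last_x2(nt);
  std::vector<double> gm(nlev);
  NumericVector out(n_perm);
  for (int p = 0; p < n_perm; ++p) {
    double tm_acc = 0.0;
    for (int l = 0; l < nlev - 1; ++l) {
      const double s = g(2 * nt, l * n_perm + p);
      gm[l] = s / nl[l];
      tm_acc += s;
    }
    gm[nlev - 1] = (tot_tm - tm_acc) / nl[nlev - 1];
    int pref = 0, nonpref = 0;
    for (int l = 1; l < nlev; ++l) {
      if (gm[l] > gm[pref]) pref = l;
      if (gm[l] < gm[nonpref]) nonpref = l;
    }
    if (nonpref == pref) nonpref = (pref == 0) ? 1 : 0;
    const bool need_last = (pref == nlev - 1) || (nonpref == nlev - 1);
    if (need_last) {
      for (int t = 0; t < nt; ++t) {
        last_x[t] = tot[t];
        last_x2[t] = tot2[t];
      }
      for (int l = 0; l < nlev - 1; ++l) {
        const double* gx = &g(0, l * n_perm + p);
        for (int t = 0; t < nt; ++t) {
          last_x[t] -= gx[t];
          last_x2[t] -= gx[nt + t];
        }
      }
    }
    const double* ga = (pref < nlev - 1) ? &g(0, pref * n_perm + p) : nullptr;
    const double* gb = (nonpref < nlev - 1) ? &g(0, nonpref * n_perm + p) : nullptr;
    const int na = nl[pref], nb = nl[nonpref];
    const double thr = R::qt(1.0 - alpha / 2.0, na + nb - 2.0, 1, 0);
    for (int t = 0; t < nt; ++t) {
      const double sa = ga ? ga[t] : last_x[t];
      const double sqa = ga ? ga[nt + t] : last_x2[t];
      const double sb = gb ? gb[t] : last_x[t];
      const double sqb = gb ? gb[nt + t] : last_x2[t];
      tv[t] = pooled_t(sa, sqa, na, sb, sqb, nb);
    }
    out[p] = max_cluster_mass(tv.data(), nt, thr, &seg[0]);
  }
  return out;
}
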