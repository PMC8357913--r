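#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// median over finite entries; midpoint of the two central order statistics
// for even counts; NA_REAL when no finite entry exists.
static double na_median(std::vector<double>& buf) {
  if (buf.empty()) return NA_REAL;
  const size_t n = buf.size();
  const size_t h = n / 2;
  std::nth_element(buf.begin(), buf.begin() + h, buf.end());
  double hi = buf[h];
  if (n % 2 == 1) return hi;
  double lo = *std::max_element(buf.begin(), buf.begin() + h);
  return (lo + hi) / 2.0;
}

// Two-way median polish with NA cells skipped. Row sweep first, then
// re-centre column effects, then column sweep, then re-centre row effects;
// stop when the largest applied shift in one iteration falls below tol.
// Effects accumulate in t (overall), r (rows), c (columns); the fitted
// channel abundance is t + c[j] for columns with any observed cell.
struct PolishResult {
  double t;
  std::vector<double> r, c, fitted;
  int iterations;
  bool converged;
};

static PolishResult polish_core(const double* x, int nr, int nc,
                                double tol, int maxit) {
  PolishResult out;
  out.t = 0.0;
  out.r.assign(nr, 0.0);
  out.c.assign(nc, 0.0);
  std::vector<double> z(x, x + (size_t)nr * nc); // column-major like R
  std::vector<bool> col_has(nc, false);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (R_finite(z[(size_t)j * nr + i])) { col_has[j] = true; break; }

  std::vector<double> buf;
  buf.reserve(std::max(nr, nc));
  int iter = 0;
  bool converged = false;
  for (iter = 1; iter <= maxit; ++iter) {
    double dmax = 0.0;
    // row sweep
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int j = 0; j < nc; ++j) {
        double v = z[(size_t)j * nr + i];
        if (R_finite(v)) buf.push_back(v);
      }
      if (buf.empty()) continue;
      double d = na_median(buf);
      for (int j = 0; j < nc; ++j) {
        double& v = z[(size_t)j * nr + i];
        if (R_finite(v)) v -= d;
      }
      out.r[i] += d;
      dmax = std::max(dmax, std::fabs(d));
    }
    // re-centre column effects into the overall term
    buf.clear();
    for (int j = 0; j < nc; ++j) if (col_has[j]) buf.push_back(out.c[j]);
    if (!buf.empty()) {
      double d = na_median(buf);
      for (int j = 0; j < nc; ++j) if (col_has[j]) out.c[j] -= d;
      out.t += d;
      dmax = std::max(dmax, std::fabs(d));
    }
    // column sweep
    for (int j = 0; j < nc; ++j) {
      if (!col_has[j]) continue;
      buf.clear();
      for (int i = 0; i < nr; ++i) {
        double v = z[(size_t)j * nr + i];
        if (R_finite(v)) buf.push_back(v);
      }
      if (buf.empty()) continue;
      double d = na_median(buf);
      for (int i = 0; i < nr; ++i) {
        double& v = z[(size_t)j * nr + i];
        if (R_finite(v)) v -= d;
      }
      out.c[j] += d;
      dmax = std::max(dmax, std::fabs(d));
    }
    // re-centre row effects into the overall term
    buf.clear();
    for (int i = 0; i < nr; ++i) buf.push_back(out.r[i]);
    if (!buf.empty()) {
      double d = na_median(buf);
      for (int i = 0; i < nr; ++i) out.r[i] -= d;
      out.t += d;
      dmax = std::max(dmax, std::fabs(d));
    }
    if (dmax < tol) { converged = true; break; }
  }
  out.fitted.assign(nc, NA_REAL);
  for (int j = 0; j < nc; ++j)
    if (col_has[j]) out.fitted[j] = out.t + out.c[j];
  out.iterations = std::min(iter, maxit);
  out.converged = converged;
  return out;
}

// [[Rcpp::export(name = ".medpolish_cpp")]]
List medpolish_cpp(NumericMatrix x, double tol = 1e-9, int maxit = 200) {
  PolishResult res = polish_core(x.begin(), x.nrow(), x.ncol(), tol, maxit);
  return List::create(
    _["overall"] = res.t,
    _["row"] = wrap(res.r),
    _["col"] = wrap(res.c),
    _["fitted"] = wrap(res.fitted),
    _["iterations"] = res.iterations,
    _["converged"] = res.converged);
}

// Summarize many (protein x run) PSM blocks at once: rows of `x` carry log2
// reporter intensities over a shared channel-column layout, `group` assigns
// each row to a block (1..ngroups). Returns the ngroups x ncol matrix of
// median-polish channel abundances.
// [[Rcpp::export(name = ".summarize_groups_cpp")]]
NumericMatrix summarize_groups_cpp(NumericMatrix x, IntegerVector group,
                                   int ngroups, double tol = 1e-9,
                                   int maxit = 200) {
  const int nr = x.nrow(), nc = x.ncol();
  if (group.size() != nr) stop("group length must match nrow(x)");
  std::vector<std::vector<int>> idx(ngroups);
  for (int i = 0; i < nr; ++i) {
    int g = group[i];
    if (g < 1 || g > ngroups) stop("group id out of range");
    idx[g - 1].push_back(i);
  }
  NumericMatrix out(ngroups, nc);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<double> sub;
  for (int g = 0; g < ngroups; ++g) {
    const std::vector<int>& rows = idx[g];
    const int m = (int)rows.size();
    if (m == 0) continue;
    sub.assign((size_t)m * nc, NA_REAL);
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < m; ++i)
        sub[(size_t)j * m + i] = x(rows[i], j);
    PolishResult res = polish_core(sub.data(), m, nc, tol, maxit);
    for (int j = 0; j < nc; ++j) out(g, j) = res.fitted[j];
  }
  return out;
}
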