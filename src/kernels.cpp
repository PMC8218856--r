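#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Threshold-free cluster enhancement on a channels x samples map.
//
// For one sign, TFCE(p) = sum_h e_p(h)^E * h^H * dh over heights
// h = dh, 2dh, ..., <= max(v), where e_p(h) is the number of
// (channel, sample) points in the spatio-temporal connected component
// containing p at height h. Connectivity: same channel and |dt| = 1, or
// same sample and spatially adjacent channels. Implemented by activating
// points in descending height with a union-find, so each height step only
// merges components and the per-point extent is the size of its root.
// ---------------------------------------------------------------------------

namespace {

struct UF {
  std::vector<int> parent, size;
  void init(int n) {
    parent.resize(n);
    size.assign(n, 1);
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a;
    size[a] += size[b];
  }
};

void tfce_one_sign(const std::vector<double>& v, int nch, int ns,
                   const std::vector<std::vector<int>>& adj,
                   double E, double H, double dh,
                   std::vector<double>& out) {
  const int n = nch * ns;
  double vmax = 0.0;
  for (int i = 0; i < n; ++i) vmax = std::max(vmax, v[i]);
  if (vmax <= 0.0 || dh <= 0.0) return;
  const int K = static_cast<int>(std::floor(vmax / dh + 1e-12));
  if (K < 1) return;

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&v](int a, int b) { return v[a] > v[b]; });

  UF uf;
  uf.init(n);
  std::vector<char> active(n, 0);
  std::vector<int> active_pts;
  active_pts.reserve(n);
  int ptr = 0;

  for (int k = K; k >= 1; --k) {
    const double h = k * dh;
    while (ptr < n && v[order[ptr]] >= h) {
      const int p = order[ptr];
      active[p] = 1;
      active_pts.push_back(p);
      const int ch = p % nch, t = p / nch;
      if (t > 0 && active[p - nch]) uf.unite(p, p - nch);
      if (t < ns - 1 && active[p + nch]) uf.unite(p, p + nch);
      for (int nb : adj[ch]) {
        const int q = nb + nch * t;
        if (active[q]) uf.unite(p, q);
      }
      ++ptr;
    }
    const double hp = std::pow(h, H) * dh;
    for (int p : active_pts) out[p] += std::pow((double)uf.size[uf.find(p)], E) * hp;
  }
}

std::vector<std::vector<int>> adj_from_list(List adj0, int nch) {
  std::vector<std::vector<int>> adj(nch);
  if (adj0.size() == 0) return adj;
  if (adj0.size() != nch) stop("adjacency list length must equal channel count");
  for (int i = 0; i < nch; ++i) {
    IntegerVector nb = adj0[i];
    adj[i].assign(nb.begin(), nb.end());
  }
  return adj;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix tfce_cpp(NumericMatrix values, List adj0, double E, double H,
                       double dh, int nsteps) {
  const int nch = values.nrow(), ns = values.ncol(), n = nch * ns;
  std::vector<std::vector<int>> adj = adj_from_list(adj0, nch);

  double amax = 0.0;
  for (int i = 0; i < n; ++i) amax = std::max(amax, std::fabs(values[i]));
  double step = dh;
  if (step <= 0.0) {
    if (amax <= 0.0) return NumericMatrix(nch, ns);
    step = amax / nsteps;
  }

  std::vector<double> pos(n, 0.0), neg(n, 0.0), opos(n, 0.0), oneg(n, 0.0);
  for (int i = 0; i < n; ++i) {
    if (values[i] > 0) pos[i] = values[i];
    else if (values[i] < 0) neg[i] = -values[i];
  }
  tfce_one_sign(pos, nch, ns, adj, E, H, step, opos);
  tfce_one_sign(neg, nch, ns, adj, E, H, step, oneg);

  NumericMatrix out(nch, ns);
  for (int i = 0; i < n; ++i) out[i] = opos[i] - oneg[i];
  return out;
}

// ---------------------------------------------------------------------------
// Connected components of a boolean channels x samples mask under the same
// spatio-temporal connectivity (iterative flood fill). Returns 0 for
// background, 1..k component labels.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, List adj0) {
  const int nch = mask.nrow(), ns = mask.ncol(), n = nch * ns;
  std::vector<std::vector<int>> adj = adj_from_list(adj0, nch);
  IntegerMatrix lab(nch, ns);
  std::vector<int> stack;
  int next = 0;
  for (int s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      const int p = stack.back();
      stack.pop_back();
      const int ch = p % nch, t = p / nch;
      auto visit = [&](int q) {
        if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
      };
      if (t > 0) visit(p - nch);
      if (t < ns - 1) visit(p + nch);
      for (int nb : adj[ch]) visit(nb + nch * t);
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Artefact scan over a trials x channels x samples array.
// Rule 1: |x[i+1] - x[i]| > max_step on any channel.
// Rule 2: max - min over the whole segment > max_range on any channel.
// Rule 3: max - min within any sliding window of `win` samples < min_act
//         on any channel (flat / dead signal).
// Returns a trials x 3 0/1 matrix of violations.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix scan_artefacts_cpp(NumericVector arr, IntegerVector dims,
                                 double max_step, double max_range,
                                 double min_act, int win) {
  const int ntr = dims[0], nch = dims[1], ns = dims[2];
  if (win > ns) stop("activity window longer than epoch");
  IntegerMatrix viol(ntr, 3);
  std::vector<double> x(ns);
  std::vector<int> qmax(ns), qmin(ns);
  for (int tr = 0; tr < ntr; ++tr) {
    for (int ch = 0; ch < nch; ++ch) {
      const R_xlen_t base = tr + (R_xlen_t)ntr * ch;
      const R_xlen_t stride = (R_xlen_t)ntr * nch;
      for (int s = 0; s < ns; ++s) x[s] = arr[base + stride * s];

      double lo = x[0], hi = x[0];
      bool step = false;
      for (int s = 1; s < ns; ++s) {
        if (std::fabs(x[s] - x[s - 1]) > max_step) step = true;
        lo = std::min(lo, x[s]);
        hi = std::max(hi, x[s]);
      }
      if (step) viol(tr, 0) = 1;
      if (hi - lo > max_range) viol(tr, 1) = 1;

      // sliding peak-to-peak via monotonic deques
      if (!viol(tr, 2)) {
        int hmax = 0, tmax = 0, hmin = 0, tmin = 0;  // head/tail indices
        for (int s = 0; s < ns; ++s) {
          while (tmax > hmax && x[qmax[tmax - 1]] <= x[s]) --tmax;
          qmax[tmax++] = s;
          while (tmin > hmin && x[qmin[tmin - 1]] >= x[s]) --tmin;
          qmin[tmin++] = s;
          const int start = s - win + 1;
          if (start >= 0) {
            while (qmax[hmax] < start) ++hmax;
            while (qmin[hmin] < start) ++hmin;
            if (x[qmax[hmax]] - x[qmin[hmin]] < min_act) {
              viol(tr, 2) = 1;
              break;
            }
          }
        }
      }
    }
  }
  return viol;
}

// ---------------------------------------------------------------------------
// Zero-phase IIR filtering (forward-backward) of every (trial, channel)
// trace in a trials x channels x samples array, with odd-reflection padding
// at both ends. Direct form II transposed.
// ---------------------------------------------------------------------------

namespace {

void df2t(const std::vector<double>& b, const std::vector<double>& a,
          std::vector<double>& x) {
  const int nb = b.size(), na = a.size();
  const int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0);
  for (size_t i = 0; i < x.size(); ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + z[0];
    for (int k = 0; k < nz - 1; ++k)
      z[k] = (k + 1 < nb ? b[k + 1] * xi : 0.0) + z[k + 1] -
             (k + 1 < na ? a[k + 1] * yi : 0.0);
    z[nz - 1] = (nz < nb ? b[nz] * xi : 0.0) - (nz < na ? a[nz] * yi : 0.0);
    x[i] = yi;
  }
}

void filtfilt_trace(const std::vector<double>& b, const std::vector<double>& a,
                    std::vector<double>& x, int padlen,
                    std::vector<double>& buf) {
  const int n = x.size();
  const int pad = std::min(padlen, n - 1);
  buf.resize(n + 2 * pad);
  for (int i = 0; i < pad; ++i) buf[i] = 2 * x[0] - x[pad - i];
  for (int i = 0; i < n; ++i) buf[pad + i] = x[i];
  for (int i = 0; i < pad; ++i) buf[pad + n + i] = 2 * x[n - 1] - x[n - 2 - i];
  df2t(b, a, buf);
  std::reverse(buf.begin(), buf.end());
  df2t(b, a, buf);
  std::reverse(buf.begin(), buf.end());
  for (int i = 0; i < n; ++i) x[i] = buf[pad + i];
}

}  // namespace

// [[Rcpp::export]]
NumericVector filtfilt_arr_cpp(NumericVector arr, IntegerVector dims,
                               NumericVector bb, NumericVector aa,
                               int padlen) {
  const int ntr = dims[0], nch = dims[1], ns = dims[2];
  std::vector<double> b(bb.begin(), bb.end()), a(aa.begin(), aa.end());
  if (a.empty() || a[0] == 0.0) stop("invalid filter denominator");
  if (a[0] != 1.0) {
    for (auto& v : b) v /= a[0];
    for (auto& v : a) v /= a[0];
  }
  NumericVector out = clone(arr);
  std::vector<double> x(ns), buf;
  for (int tr = 0; tr < ntr; ++tr) {
    for (int ch = 0; ch < nch; ++ch) {
      const R_xlen_t base = tr + (R_xlen_t)ntr * ch;
      const R_xlen_t stride = (R_xlen_t)ntr * nch;
      for (int s = 0; s < ns; ++s) x[s] = out[base + stride * s];
      filtfilt_trace(b, a, x, padlen, buf);
      for (int s = 0; s < ns; ++s) out[base + stride * s] = x[s];
    }
  }
  return out;
}
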