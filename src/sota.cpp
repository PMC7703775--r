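#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// SOTA profile distances. For the pearson metric, d = (1 - r)/2, profiles
// and prototypes are kept as centred unit vectors so a distance is one dot
// product; a constant vector has no defined correlation and gets the
// uninformative midpoint d = 0.5. Euclidean uses the raw vectors.

struct ZCache {
  std::vector<double> z;     // centred, unit-norm (pearson) or raw copy
  std::vector<char> is_const;
  int S;
  void resize(int n, int s) { S = s; z.assign((size_t)n * s, 0.0);
                              is_const.assign(n, 0); }
  void set(int i, const double* x, int metric) {
    double* zi = &z[(size_t)i * S];
    if (metric == 1) { for (int s = 0; s < S; ++s) zi[s] = x[s]; return; }
    double m = 0.0;
    for (int s = 0; s < S; ++s) m += x[s];
    m /= S;
    double ss = 0.0;
    for (int s = 0; s < S; ++s) { double d = x[s] - m; zi[s] = d; ss += d * d; }
    if (ss <= 0.0) { is_const[i] = 1; for (int s = 0; s < S; ++s) zi[s] = 0.0; }
    else { is_const[i] = 0; double inv = 1.0 / std::sqrt(ss);
           for (int s = 0; s < S; ++s) zi[s] *= inv; }
  }
};

static inline double zdist(const ZCache& a, int i, const ZCache& b, int j,
                           int metric) {
  const double* x = &a.z[(size_t)i * a.S];
  const double* y = &b.z[(size_t)j * b.S];
  if (metric == 1) {
    double s = 0.0;
    for (int k = 0; k < a.S; ++k) { double d = x[k] - y[k]; s += d * d; }
    return std::sqrt(s);
  }
  if (a.is_const[i] || b.is_const[j]) return 0.5;
  double r = 0.0;
  for (int k = 0; k < a.S; ++k) r += x[k] * y[k];
  if (r > 1.0) r = 1.0; else if (r < -1.0) r = -1.0;
  return (1.0 - r) / 2.0;
}

// [[Rcpp::export(name = ".sota_fit_cpp")]]
List sota_fit_cpp(NumericMatrix X, int metric, double alpha_winner,
                  double alpha_mother, double alpha_sister,
                  double cycle_epsilon, int max_cells,
                  double variability_threshold, int max_epochs) {
  const int G = X.nrow(), S = X.ncol();
  std::vector<double> prof((size_t)G * S);
  for (int g = 0; g < G; ++g)
    for (int s = 0; s < S; ++s) prof[(size_t)g * S + s] = X(g, s);
  ZCache zprof; zprof.resize(G, S);
  for (int g = 0; g < G; ++g) zprof.set(g, &prof[(size_t)g * S], metric);

  // tree arrays (0-based; -1 = none); prototypes raw + z-cache
  std::vector<double> proto;
  std::vector<int> parent, left, right;
  std::vector<bool> is_cell;
  ZCache zproto; zproto.resize(0, S);

  std::vector<double> centroid(S, 0.0);
  for (int g = 0; g < G; ++g)
    for (int s = 0; s < S; ++s) centroid[s] += prof[(size_t)g * S + s];
  for (int s = 0; s < S; ++s) centroid[s] /= G;

  RNGScope rng;
  auto add_node = [&](const std::vector<double>& p, int par, bool jitter) {
    double nrm = 0.0;
    for (int s = 0; s < S; ++s) nrm += p[s] * p[s];
    double sd = 1e-6 * std::sqrt(nrm);
    for (int s = 0; s < S; ++s)
      proto.push_back(p[s] + (jitter ? sd * norm_rand() : 0.0));
    parent.push_back(par); left.push_back(-1); right.push_back(-1);
    is_cell.push_back(true);
    int id = (int)is_cell.size() - 1;
    zproto.resize(id + 1, S);  // re-zero; refresh all below
    for (int i = 0; i <= id; ++i) zproto.set(i, &proto[(size_t)i * S], metric);
    return id;
  };

  int root = add_node(centroid, -1, false);
  is_cell[root] = false;
  left[root] = add_node(centroid, root, true);
  right[root] = add_node(centroid, root, true);

  std::vector<int> cells = {left[root], right[root]};
  std::vector<int> assign(G, cells[0]);

  auto nearest_cell = [&](int g) {
    int best = cells[0];
    double bd = zdist(zprof, g, zproto, best, metric);
    for (size_t c = 1; c < cells.size(); ++c) {
      double d = zdist(zprof, g, zproto, cells[c], metric);
      if (d < bd - 1e-15 || (std::fabs(d - bd) <= 1e-15 && cells[c] < best)) {
        bd = d; best = cells[c];
      }
    }
    return best;
  };
  auto update_proto = [&](int node, const double* x, double alpha) {
    double* p = &proto[(size_t)node * S];
    for (int s = 0; s < S; ++s) p[s] += alpha * (x[s] - p[s]);
    zproto.set(node, p, metric);
  };

  double total_error = R_PosInf;
  while (true) {
    double prev_err = R_PosInf;
    for (int epoch = 0; epoch < max_epochs; ++epoch) {
      for (int g = 0; g < G; ++g) {
        const double* x = &prof[(size_t)g * S];
        int w = nearest_cell(g);
        update_proto(w, x, alpha_winner);
        int par = parent[w];
        if (par >= 0) {
          int sib = (left[par] == w) ? right[par] : left[par];
          if (sib >= 0 && is_cell[sib]) {
            update_proto(par, x, alpha_mother);
            update_proto(sib, x, alpha_sister);
          }
        }
      }
      double err = 0.0;
      for (int g = 0; g < G; ++g) {
        int w = nearest_cell(g);
        assign[g] = w;
        err += zdist(zprof, g, zproto, w, metric);
      }
      double rel = !R_finite(prev_err) ? R_PosInf
        : (prev_err == 0.0 ? 0.0 : std::fabs(prev_err - err) / prev_err);
      prev_err = err;
      if (rel < cycle_epsilon) break;
    }
    total_error = prev_err;

    if ((int)cells.size() >= max_cells) break;
    bool all_ok = true;
    int split_node = -1;
    double best_resource = -1.0;
    for (size_t c = 0; c < cells.size(); ++c) {
      int node = cells[c];
      std::vector<int> members;
      for (int g = 0; g < G; ++g) if (assign[g] == node) members.push_back(g);
      double variability = 0.0;
      for (size_t i = 0; i + 1 < members.size(); ++i)
        for (size_t j = i + 1; j < members.size(); ++j) {
          double d = zdist(zprof, members[i], zprof, members[j], metric);
          if (d > variability) variability = d;
        }
      if (variability > variability_threshold) all_ok = false;
      double resource = 0.0;
      for (int g : members) resource += zdist(zprof, g, zproto, node, metric);
      if (!members.empty()) resource /= members.size();
      if (resource > best_resource + 1e-15 ||
          (std::fabs(resource - best_resource) <= 1e-15 && split_node >= 0 &&
           node < split_node)) {
        best_resource = resource; split_node = node;
      }
    }
    if (all_ok) break;

    std::vector<double> p(S);
    for (int s = 0; s < S; ++s) p[s] = proto[(size_t)split_node * S + s];
    int l = add_node(p, split_node, true);
    int r = add_node(p, split_node, true);
    is_cell[split_node] = false;
    left[split_node] = l; right[split_node] = r;
    std::vector<int> new_cells;
    for (int node : cells) if (node != split_node) new_cells.push_back(node);
    new_cells.push_back(l); new_cells.push_back(r);
    cells = new_cells;
  }

  const int N = (int)is_cell.size();
  NumericMatrix P(N, S);
  for (int i = 0; i < N; ++i)
    for (int s = 0; s < S; ++s) P(i, s) = proto[(size_t)i * S + s];
  IntegerVector par1(N), l1(N), r1(N), asg(G);
  LogicalVector cellf(N);
  for (int i = 0; i < N; ++i) {
    par1[i] = parent[i] < 0 ? NA_INTEGER : parent[i] + 1;
    l1[i] = left[i] < 0 ? NA_INTEGER : left[i] + 1;
    r1[i] = right[i] < 0 ? NA_INTEGER : right[i] + 1;
    cellf[i] = is_cell[i];
  }
  for (int g = 0; g < G; ++g) asg[g] = assign[g] + 1;
  return List::create(_["prototypes"] = P, _["parent"] = par1,
                      _["left"] = l1, _["right"] = r1, _["isCell"] = cellf,
                      _["assignment"] = asg, _["totalError"] = total_error);
}

// Kernel MI on copula (rank-transformed) margins: Gaussian product kernel
// plug-in, MI = mean_i log f(u_i,v_i) / (fu(u_i) fv(v_i)), clipped at 0.
// [[Rcpp::export(name = ".kde_mi_cpp")]]
double kde_mi_cpp(NumericVector u, NumericVector v, double hu, double hv) {
  const int n = u.size();
  const double cu = 1.0 / (hu * std::sqrt(2.0 * M_PI));
  const double cv = 1.0 / (hv * std::sqrt(2.0 * M_PI));
  std::vector<double> ku((size_t)n * n), kv((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double zu = (u[i] - u[j]) / hu, zv = (v[i] - v[j]) / hv;
      ku[(size_t)i * n + j] = cu * std::exp(-0.5 * zu * zu);
      kv[(size_t)i * n + j] = cv * std::exp(-0.5 * zv * zv);
    }
  double mi = 0.0;
  for (int i = 0; i < n; ++i) {
    double fu = 0.0, fv = 0.0, fuv = 0.0;
    for (int j = 0; j < n; ++j) {
      double a = ku[(size_t)i * n + j], b = kv[(size_t)i * n + j];
      fu += a; fv += b; fuv += a * b;
    }
    fu /= n; fv /= n; fuv /= n;
    mi += std::log(fuv / (fu * fv));
  }
  mi /= n;
  return mi > 0.0 ? mi : 0.0;
}
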