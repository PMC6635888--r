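// Growing self-organizing map engine and fused training-cycle kernel.
//
// All stochasticity (initial weights, presentation orders, stimulus jitter)
// is generated on the R side; this kernel is deterministic, so a training
// run is reproducible from (config, seed, corpus) alone.

#include <Rcpp.h>
#include <cmath>
#include <map>
#include <utility>
#include <vector>

using namespace Rcpp;

typedef std::pair<int, int> Pos;

static const int DX[4] = {1, -1, 0, 0};
static const int DY[4] = {0, 0, 1, -1};

struct GrowingMap {
  int dim;
  std::vector<double> w;  // node-major, n * dim
  std::vector<int> px, py;
  std::map<Pos, int> index;
  std::vector<double> err;

  int n() const { return (int)px.size(); }
  double* wp(int i) { return &w[(size_t)i * dim]; }
  const double* wp(int i) const { return &w[(size_t)i * dim]; }

  double d2(int i, const double* x) const {
    const double* wi = wp(i);
    double s = 0.0;
    for (int k = 0; k < dim; ++k) {
      double d = wi[k] - x[k];
      s += d * d;
    }
    return s;
  }

  // partial distance with early abandonment once `bound` is exceeded
  double d2_bounded(int i, const double* x, double bound) const {
    const double* wi = wp(i);
    double s = 0.0;
    for (int k = 0; k < dim; ++k) {
      double d = wi[k] - x[k];
      s += d * d;
      if (s >= bound) return s;
    }
    return s;
  }

  // lowest index wins ties (strict < keeps the first minimum)
  int bmu(const double* x, double* out_d2 = 0) const {
    int best = 0;
    double bd = d2(0, x);
    for (int i = 1; i < n(); ++i) {
      double d = d2_bounded(i, x, bd);
      if (d < bd) {
        bd = d;
        best = i;
      }
    }
    if (out_d2) *out_d2 = bd;
    return best;
  }

  bool has(int x, int y) const { return index.count(Pos(x, y)) > 0; }
  int at(int x, int y) const {
    std::map<Pos, int>::const_iterator it = index.find(Pos(x, y));
    return it == index.end() ? -1 : it->second;
  }

  void add_node(int x, int y, const std::vector<double>& wt) {
    px.push_back(x);
    py.push_back(y);
    index[Pos(x, y)] = (int)px.size() - 1;
    w.insert(w.end(), wt.begin(), wt.end());
    err.push_back(0.0);
  }

  // Move the winner (and lattice neighbours within `radius`) toward x and
  // accumulate the winner's quantization error (Euclidean distance).
  void adapt(const double* x, int b, double lr, double radius) {
    err[b] += std::sqrt(d2(b, x));
    if (radius <= 0.0) {
      double* wb = wp(b);
      for (int k = 0; k < dim; ++k) wb[k] += lr * (x[k] - wb[k]);
      return;
    }
    double r2 = radius * radius;
    for (int i = 0; i < n(); ++i) {
      double dx = px[i] - px[b], dy = py[i] - py[b];
      double ld2 = dx * dx + dy * dy;
      if (ld2 <= r2 + 1e-12) {
        double h = std::exp(-ld2 / r2);
        double f = lr * h;
        double* wi = wp(i);
        for (int k = 0; k < dim; ++k) wi[k] += f * (x[k] - wi[k]);
      }
    }
  }

  // Edge-only growth: boundary nodes above threshold spawn nodes into their
  // free 4-neighbour positions (weights extrapolated past the parent from the
  // opposite neighbour; deterministic nudge toward the map mean if there is
  // none) and reset their error; interior nodes halve their error and push
  // the other half to their 4 neighbours so pressure migrates to the edge.
  std::vector<int> grow(double gt) {
    std::vector<int> added;
    int n0 = n();
    for (int i = 0; i < n0; ++i) {
      if (err[i] <= gt) continue;
      std::vector<int> freed;
      for (int d = 0; d < 4; ++d)
        if (!has(px[i] + DX[d], py[i] + DY[d])) freed.push_back(d);
      if (!freed.empty()) {
        for (size_t fi = 0; fi < freed.size(); ++fi) {
          int d = freed[fi];
          int nx = px[i] + DX[d], ny = py[i] + DY[d];
          if (has(nx, ny)) continue;  // may have been filled this pass
          std::vector<double> wt(dim);
          const double* wi = wp(i);
          int oi = at(px[i] - DX[d], py[i] - DY[d]);
          if (oi >= 0) {
            const double* wo = wp(oi);
            for (int k = 0; k < dim; ++k) wt[k] = 2.0 * wi[k] - wo[k];
          } else {
            std::vector<double> mean(dim, 0.0);
            for (int j = 0; j < n0; ++j) {
              const double* wj = wp(j);
              for (int k = 0; k < dim; ++k) mean[k] += wj[k];
            }
            for (int k = 0; k < dim; ++k)
              wt[k] = wi[k] + 0.05 * (mean[k] / n0 - wi[k]);
          }
          add_node(nx, ny, wt);
          added.push_back(n() - 1);
        }
        err[i] = 0.0;
      } else {
        double half = err[i] * 0.5;
        err[i] = half;
        for (int d = 0; d < 4; ++d) {
          int j = at(px[i] + DX[d], py[i] + DY[d]);
          if (j >= 0) err[j] += half * 0.25;
        }
      }
    }
    return added;
  }
};

struct AssocNet {
  int nr, nc;
  std::vector<std::vector<double> > rows;
  AssocNet(int r, int c) : nr(r), nc(c), rows(r, std::vector<double>(c, 0.0)) {}
  void resize(int r, int c) {
    rows.resize(r, std::vector<double>(c, 0.0));
    for (int i = 0; i < r; ++i) rows[i].resize(c, 0.0);
    nr = r;
    nc = c;
  }
  // bounded Hebbian update with competitive decay on the winner's row/column
  void update(int s, int p, double lr, double decay) {
    double keep = 1.0 - lr * decay;
    if (keep < 0.0) keep = 0.0;
    double v = rows[s][p];
    for (int j = 0; j < nc; ++j) rows[s][j] *= keep;
    for (int i = 0; i < nr; ++i) rows[i][p] *= keep;
    rows[s][p] = v + lr * (1.0 - v);
  }
};

static GrowingMap* get_map(SEXP ptr) {
  Rcpp::XPtr<GrowingMap> p(ptr);
  return p.get();
}
static AssocNet* get_assoc(SEXP ptr) {
  Rcpp::XPtr<AssocNet> p(ptr);
  return p.get();
}

// [[Rcpp::export]]
SEXP gsom_create_(int dim, IntegerMatrix pos, NumericMatrix weights,
                  NumericVector errors) {
  GrowingMap* m = new GrowingMap();
  m->dim = dim;
  int n = pos.nrow();
  std::vector<double> wt(dim);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < dim; ++k) wt[k] = weights(i, k);
    m->add_node(pos(i, 0), pos(i, 1), wt);
    m->err[i] = errors[i];
  }
  return Rcpp::XPtr<GrowingMap>(m, true);
}

// [[Rcpp::export]]
SEXP gsom_clone_(SEXP ptr) {
  GrowingMap* m = get_map(ptr);
  GrowingMap* c = new GrowingMap(*m);
  return Rcpp::XPtr<GrowingMap>(c, true);
}

// [[Rcpp::export]]
int gsom_size_(SEXP ptr) { return get_map(ptr)->n(); }

// [[Rcpp::export]]
int gsom_dim_(SEXP ptr) { return get_map(ptr)->dim; }

// [[Rcpp::export]]
NumericMatrix gsom_weights_(SEXP ptr) {
  GrowingMap* m = get_map(ptr);
  NumericMatrix out(m->n(), m->dim);
  for (int i = 0; i < m->n(); ++i) {
    const double* wi = m->wp(i);
    for (int k = 0; k < m->dim; ++k) out(i, k) = wi[k];
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix gsom_positions_(SEXP ptr) {
  GrowingMap* m = get_map(ptr);
  IntegerMatrix out(m->n(), 2);
  for (int i = 0; i < m->n(); ++i) {
    out(i, 0) = m->px[i];
    out(i, 1) = m->py[i];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector gsom_errors_(SEXP ptr) {
  GrowingMap* m = get_map(ptr);
  return NumericVector(m->err.begin(), m->err.end());
}

// [[Rcpp::export]]
void gsom_set_errors_(SEXP ptr, NumericVector e) {
  GrowingMap* m = get_map(ptr);
  for (int i = 0; i < m->n(); ++i) m->err[i] = e[i];
}

// [[Rcpp::export]]
int gsom_bmu_(SEXP ptr, NumericVector x) {
  GrowingMap* m = get_map(ptr);
  if ((int)x.size() != m->dim) stop("input dimensionality mismatch");
  return m->bmu(REAL(x)) + 1;
}

// [[Rcpp::export]]
IntegerVector gsom_bmu_batch_(SEXP ptr, NumericMatrix X) {
  GrowingMap* m = get_map(ptr);
  if (X.ncol() != m->dim) stop("input dimensionality mismatch");
  int n = X.nrow();
  IntegerVector out(n);
  std::vector<double> x(m->dim);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < m->dim; ++k) x[k] = X(i, k);
    out[i] = m->bmu(&x[0]) + 1;
  }
  return out;
}

// [[Rcpp::export]]
void gsom_adapt_(SEXP ptr, NumericVector x, int bmu, double lr, double radius) {
  GrowingMap* m = get_map(ptr);
  if ((int)x.size() != m->dim) stop("input dimensionality mismatch");
  m->adapt(REAL(x), bmu - 1, lr, radius);
}

// [[Rcpp::export]]
IntegerVector gsom_grow_(SEXP ptr, double gt) {
  GrowingMap* m = get_map(ptr);
  std::vector<int> added = m->grow(gt);
  IntegerVector out(added.size());
  for (size_t i = 0; i < added.size(); ++i) out[i] = added[i] + 1;
  return out;
}

// [[Rcpp::export]]
SEXP assoc_create_(int nr, int nc) {
  return Rcpp::XPtr<AssocNet>(new AssocNet(nr, nc), true);
}

// [[Rcpp::export]]
SEXP assoc_clone_(SEXP ptr) {
  AssocNet* a = get_assoc(ptr);
  return Rcpp::XPtr<AssocNet>(new AssocNet(*a), true);
}

// [[Rcpp::export]]
NumericMatrix assoc_matrix_(SEXP ptr) {
  AssocNet* a = get_assoc(ptr);
  NumericMatrix out(a->nr, a->nc);
  for (int i = 0; i < a->nr; ++i)
    for (int j = 0; j < a->nc; ++j) out(i, j) = a->rows[i][j];
  return out;
}

// [[Rcpp::export]]
void assoc_set_matrix_(SEXP ptr, NumericMatrix w) {
  AssocNet* a = get_assoc(ptr);
  a->resize(w.nrow(), w.ncol());
  for (int i = 0; i < a->nr; ++i)
    for (int j = 0; j < a->nc; ++j) a->rows[i][j] = w(i, j);
}

// [[Rcpp::export]]
void assoc_resize_(SEXP ptr, int nr, int nc) { get_assoc(ptr)->resize(nr, nc); }

// [[Rcpp::export]]
void assoc_update_(SEXP ptr, int s, int p, double lr, double decay) {
  AssocNet* a = get_assoc(ptr);
  if (s < 1 || s > a->nr || p < 1 || p > a->nc) stop("association index out of range");
  a->update(s - 1, p - 1, lr, decay);
}

// [[Rcpp::export]]
NumericVector assoc_row_(SEXP ptr, int s) {
  AssocNet* a = get_assoc(ptr);
  return NumericVector(a->rows[s - 1].begin(), a->rows[s - 1].end());
}

// One full training cycle: present items in `order`; per presentation adapt
// the S-MAP on the word's semantic vector, the P-MAP on the item vector,
// update the association at the two winners, run the per-step growth check
// and (optionally) the per-step GSOM check which re-presents items that
// collide on a P-MAP node with items of a different word.
//
// semMat: words x sdim, pMat: items x pdim, item_word: 1-based word per item,
// order: 1-based item indices, last_bmu: 1-based per-item P-BMU (0 = unseen).
// [[Rcpp::export]]
List run_cycle_(SEXP sm, SEXP pm, SEXP an, NumericMatrix semMat,
                NumericMatrix pMat, IntegerVector item_word,
                IntegerVector order, double lr_s, double lr_p, double radius_s,
                double radius_p, double gt_s, double gt_p, double assoc_lr,
                double assoc_decay, bool do_check, int extra_reps,
                int max_extra, IntegerVector last_bmu) {
  GrowingMap* S = get_map(sm);
  GrowingMap* P = get_map(pm);
  AssocNet* A = get_assoc(an);
  int n_items = pMat.nrow();
  int sdim = S->dim, pdim = P->dim;
  if (semMat.ncol() != sdim) stop("semantic dimensionality mismatch");
  if (pMat.ncol() != pdim) stop("item dimensionality mismatch");
  if (A->nr != S->n() || A->nc != P->n())
    stop("association shape out of step with map sizes");

  // row-major copies (R matrices are column-major)
  std::vector<double> sem((size_t)semMat.nrow() * sdim);
  for (int i = 0; i < semMat.nrow(); ++i)
    for (int k = 0; k < sdim; ++k) sem[(size_t)i * sdim + k] = semMat(i, k);
  std::vector<double> pv((size_t)n_items * pdim);
  for (int i = 0; i < n_items; ++i)
    for (int k = 0; k < pdim; ++k) pv[(size_t)i * pdim + k] = pMat(i, k);

  std::vector<int> last(n_items);
  for (int i = 0; i < n_items; ++i) last[i] = last_bmu[i] - 1;  // -1 = unseen

  int check_events = 0, extra_steps = 0, base_steps = 0;

  // full presentation step; returns the item's P-BMU (0-based)
  struct Step {
    GrowingMap *S, *P;
    AssocNet* A;
    std::vector<double>*sem, *pv;
    IntegerVector* item_word;
    int sdim, pdim;
    double lr_s, lr_p, radius_s, radius_p, gt_s, gt_p, assoc_decay;
    int present(int item, double alr) {
      int wd = (*item_word)[item] - 1;
      const double* sx = &(*sem)[(size_t)wd * sdim];
      int sb = S->bmu(sx);
      S->adapt(sx, sb, lr_s, radius_s);
      if (!S->grow(gt_s).empty()) A->resize(S->n(), P->n());
      const double* x = &(*pv)[(size_t)item * pdim];
      int pb = P->bmu(x);
      P->adapt(x, pb, lr_p, radius_p);
      if (!P->grow(gt_p).empty()) A->resize(S->n(), P->n());
      if (alr > 0) A->update(sb, pb, alr, assoc_decay);
      return pb;
    }
  } step;
  step.S = S;
  step.P = P;
  step.A = A;
  step.sem = &sem;
  step.pv = &pv;
  step.item_word = &item_word;
  step.sdim = sdim;
  step.pdim = pdim;
  step.lr_s = lr_s;
  step.lr_p = lr_p;
  step.radius_s = radius_s;
  step.radius_p = radius_p;
  step.gt_s = gt_s;
  step.gt_p = gt_p;
  step.assoc_decay = assoc_decay;

  for (int oi = 0; oi < order.size(); ++oi) {
    int item = order[oi] - 1;
    if (item < 0 || item >= n_items) stop("presentation order index out of range");
    int pb = step.present(item, assoc_lr);
    last[item] = pb;
    ++base_steps;
    if (do_check) {
      // items of a different word currently sharing this node -> unclear
      std::vector<int> conflicts;
      for (int j = 0; j < n_items; ++j)
        if (j != item && last[j] == pb && item_word[j] != item_word[item])
          conflicts.push_back(j);
      if (!conflicts.empty()) {
        ++check_events;
        conflicts.push_back(item);
        for (int r = 0; r < extra_reps; ++r) {
          for (size_t ci = 0; ci < conflicts.size(); ++ci) {
            if (extra_steps >= max_extra) break;
            int j = conflicts[ci];
            last[j] = step.present(j, assoc_lr);
            ++extra_steps;
          }
        }
      }
    }
  }

  IntegerVector last_out(n_items);
  for (int i = 0; i < n_items; ++i) last_out[i] = last[i] + 1;
  return List::create(_["last_bmu"] = last_out,
                      _["base_steps"] = base_steps,
                      _["check_events"] = check_events,
                      _["extra_steps"] = extra_steps);
}

// [[Rcpp::export]]
NumericVector assoc_col_(SEXP ptr, int p) {
  AssocNet* a = get_assoc(ptr);
  NumericVector out(a->nr);
  for (int i = 0; i < a->nr; ++i) out[i] = a->rows[i][p - 1];
  return out;
}

// BMU search restricted to a subset of input dimensions (1-based `cols`);
// X holds only those columns, in the same order. Used by the perception
// route, which matches on the auditory block only.
// [[Rcpp::export]]
IntegerVector gsom_bmu_batch_sub_(SEXP ptr, NumericMatrix X,
                                  IntegerVector cols) {
  GrowingMap* m = get_map(ptr);
  int nc = cols.size();
  if (X.ncol() != nc) stop("column subset mismatch");
  std::vector<int> cc(nc);
  for (int k = 0; k < nc; ++k) {
    cc[k] = cols[k] - 1;
    if (cc[k] < 0 || cc[k] >= m->dim) stop("column index out of range");
  }
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int best = 0;
    double bd = R_PosInf;
    for (int j = 0; j < m->n(); ++j) {
      const double* wj = m->wp(j);
      double s = 0.0;
      for (int k = 0; k < nc; ++k) {
        double d = wj[cc[k]] - X(i, k);
        s += d * d;
        if (s >= bd) break;
      }
      if (s < bd) {
        bd = s;
        best = j;
      }
    }
    out[i] = best + 1;
  }
  return out;
}
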