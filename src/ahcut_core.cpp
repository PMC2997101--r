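#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Side encoding throughout: 1 or 2 (0 = unassigned in greedy fill).
// W is the n x n symmetric weight (distance) matrix; absent pairs and the
// diagonal are NA. Absent pairs contribute to neither objective term.

static inline bool has_edge(double w) { return !ISNAN(w); }

static void full_eval(const NumericMatrix& W, const std::vector<int>& side,
                      double& cut, double& intra) {
  const int n = W.nrow();
  cut = 0.0; intra = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double w = W(i, j);
      if (!has_edge(w)) continue;
      if (side[i] == side[j]) intra += 1.0 / w; else cut += w;
    }
  }
}

// [[Rcpp::export]]
List cpp_evaluate(const NumericMatrix& W, const IntegerVector& side) {
  std::vector<int> s(side.begin(), side.end());
  double cut, intra;
  full_eval(W, s, cut, intra);
  return List::create(_["cut_sum"] = cut, _["intra_recip"] = intra,
                      _["value"] = cut * intra);
}

// Breakdown after flipping vertex v (0-based), given the current breakdown.
// O(degree(v)) incremental update.
// [[Rcpp::export]]
List cpp_move_delta(const NumericMatrix& W, const IntegerVector& side,
                    int v, double cut_sum, double intra_recip) {
  const int n = W.nrow();
  for (int u = 0; u < n; ++u) {
    if (u == v) continue;
    double w = W(v, u);
    if (!has_edge(w)) continue;
    if (side[u] == side[v]) { cut_sum += w; intra_recip -= 1.0 / w; }
    else                    { cut_sum -= w; intra_recip += 1.0 / w; }
  }
  return List::create(_["cut_sum"] = cut_sum, _["intra_recip"] = intra_recip,
                      _["value"] = cut_sum * intra_recip);
}

// Lexicographic comparison of two sorted rank sequences; true if a < b.
static bool lex_less(const std::vector<int>& a, const std::vector<int>& b) {
  size_t m = std::min(a.size(), b.size());
  for (size_t i = 0; i < m; ++i) {
    if (a[i] != b[i]) return a[i] < b[i];
  }
  return a.size() < b.size();
}

static std::vector<int> side1_ranks(const std::vector<int>& side,
                                    const IntegerVector& lex_rank) {
  std::vector<int> r;
  for (size_t i = 0; i < side.size(); ++i)
    if (side[i] == 1) r.push_back(lex_rank[i]);
  std::sort(r.begin(), r.end());
  return r;
}

// Exhaustive enumeration of all 2^(n-1) - 1 non-trivial bipartitions with
// vertex 0 fixed on side 1 (objective is symmetric under side swap).
// Gray-code order: each step flips one vertex, so the breakdown is updated
// in O(n). Ties on the optimum value resolve to the lexicographically
// smallest side-1 label set (lex_rank[i] = rank of label i).
// [[Rcpp::export]]
List cpp_enumerate(const NumericMatrix& W, const IntegerVector& lex_rank) {
  const int n = W.nrow();
  std::vector<int> side(n, 1);
  double cut, intra;
  full_eval(W, side, cut, intra);  // all on side 1: cut = 0

  double best_val = R_NegInf;
  std::vector<int> best_side;
  std::vector<int> best_ranks;
  const long long total = (1LL << (n - 1)) - 1;

  for (long long m = 1; m <= total; ++m) {
    // vertex flipped at gray-code step m: trailing zeros of m, offset by 1
    int tz = 0;
    while (!((m >> tz) & 1LL)) ++tz;
    int v = tz + 1;
    // incremental flip of v
    for (int u = 0; u < n; ++u) {
      if (u == v) continue;
      double w = W(v, u);
      if (!has_edge(w)) continue;
      if (side[u] == side[v]) { cut += w; intra -= 1.0 / w; }
      else                    { cut -= w; intra += 1.0 / w; }
    }
    side[v] = 3 - side[v];
    double val = cut * intra;
    double scale = std::max(std::fabs(best_val), std::max(std::fabs(val), 1.0));
    if (best_side.empty() || val > best_val + 1e-12 * scale) {
      best_val = val;
      best_side = side;
      best_ranks = side1_ranks(side, lex_rank);
    } else if (std::fabs(val - best_val) <= 1e-12 * scale) {
      std::vector<int> r = side1_ranks(side, lex_rank);
      if (lex_less(r, best_ranks)) { best_side = side; best_ranks = r; }
    }
  }

  // exact from-scratch breakdown for the winner (no gray-code drift)
  double bcut, bintra;
  full_eval(W, best_side, bcut, bintra);
  return List::create(_["side"] = IntegerVector(best_side.begin(), best_side.end()),
                      _["cut_sum"] = bcut, _["intra_recip"] = bintra,
                      _["value"] = bcut * bintra,
                      _["examined"] = (double)total);
}

// Greedy completion of a partial assignment (side0: 0 = unassigned).
// Vertex selection strategies: 1 = maximum total weight to assigned
// vertices, 2 = maximum single edge to an assigned vertex, 3 = fixed
// (lexicographic) order. Ties break to the smallest lex_rank, or uniformly
// at random when randomized = true. Side choice maximises the partial
// objective; ties go to side 1.
// [[Rcpp::export]]
List cpp_greedy_fill(const NumericMatrix& W, const IntegerVector& side0,
                     const IntegerVector& lex_rank, int strategy,
                     bool randomized) {
  const int n = W.nrow();
  std::vector<int> side(side0.begin(), side0.end());
  std::vector<bool> assigned(n);
  int n_left = 0;
  for (int i = 0; i < n; ++i) {
    assigned[i] = side[i] != 0;
    if (!assigned[i]) ++n_left;
  }

  double cut = 0.0, intra = 0.0;
  std::vector<double> attach(n, 0.0), best_edge(n, R_NegInf);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double w = W(i, j);
      if (!has_edge(w)) continue;
      if (assigned[i] && assigned[j]) {
        if (side[i] == side[j]) intra += 1.0 / w; else cut += w;
      } else if (assigned[i] && !assigned[j]) {
        attach[j] += w; best_edge[j] = std::max(best_edge[j], w);
      } else if (assigned[j] && !assigned[i]) {
        attach[i] += w; best_edge[i] = std::max(best_edge[i], w);
      }
    }
  }

  IntegerVector ord(n_left), ord_side(n_left);
  NumericVector partial(n_left);

  for (int step = 0; step < n_left; ++step) {
    // select next vertex
    std::vector<int> cand;
    if (strategy == 3) {
      int best = -1;
      for (int i = 0; i < n; ++i)
        if (!assigned[i] && (best < 0 || lex_rank[i] < lex_rank[best])) best = i;
      cand.push_back(best);
    } else {
      double best_key = R_NegInf;
      for (int i = 0; i < n; ++i) {
        if (assigned[i]) continue;
        double key = (strategy == 2) ? best_edge[i] : attach[i];
        if (key == R_NegInf) key = 0.0;  // isolated from assigned set
        double scale = std::max(std::fabs(best_key), std::max(std::fabs(key), 1.0));
        if (cand.empty() || key > best_key + 1e-12 * scale) {
          best_key = key; cand.clear(); cand.push_back(i);
        } else if (std::fabs(key - best_key) <= 1e-12 * scale) {
          cand.push_back(i);
        }
      }
    }
    int v;
    if (cand.size() == 1) {
      v = cand[0];
    } else if (randomized) {
      v = cand[(int)std::floor(unif_rand() * cand.size()) % cand.size()];
    } else {
      v = cand[0];
      for (size_t c = 1; c < cand.size(); ++c)
        if (lex_rank[cand[c]] < lex_rank[v]) v = cand[c];
    }

    // side choice: partial objective after placement
    double to1 = 0.0, to2 = 0.0, r1 = 0.0, r2 = 0.0;
    for (int u = 0; u < n; ++u) {
      if (!assigned[u] || u == v) continue;
      double w = W(v, u);
      if (!has_edge(w)) continue;
      if (side[u] == 1) { to1 += w; r1 += 1.0 / w; }
      else              { to2 += w; r2 += 1.0 / w; }
    }
    double val1 = (cut + to2) * (intra + r1);
    double val2 = (cut + to1) * (intra + r2);
    int s = (val1 >= val2) ? 1 : 2;
    if (s == 1) { cut += to2; intra += r1; } else { cut += to1; intra += r2; }
    side[v] = s; assigned[v] = true;
    for (int u = 0; u < n; ++u) {
      if (assigned[u]) continue;
      double w = W(v, u);
      if (!has_edge(w)) continue;
      attach[u] += w; best_edge[u] = std::max(best_edge[u], w);
    }
    ord[step] = v; ord_side[step] = s; partial[step] = cut * intra;
  }

  return List::create(_["side"] = IntegerVector(side.begin(), side.end()),
                      _["cut_sum"] = cut, _["intra_recip"] = intra,
                      _["value"] = cut * intra,
                      _["order"] = ord, _["order_side"] = ord_side,
                      _["partial_value"] = partial);
}

// Variable neighbourhood search. Order-k neighbours differ by flipping the
// side of exactly k vertices. k = 1: full first-improvement scan via the
// incremental delta; k >= 2: `vns_samples` random k-subsets. Any strict
// improvement (by more than eps) moves the incumbent and resets k to 1.
// Moves that would empty a side are never taken.
// [[Rcpp::export]]
List cpp_vns(const NumericMatrix& W, const IntegerVector& side_in, int k_max,
             int vns_samples, double eps) {
  const int n = W.nrow();
  std::vector<int> side(side_in.begin(), side_in.end());
  double cut, intra;
  full_eval(W, side, cut, intra);
  double val = cut * intra;
  int c1 = 0;
  for (int i = 0; i < n; ++i) if (side[i] == 1) ++c1;
  int c2 = n - c1;

  int k = 1;
  std::vector<int> pick(std::max(k_max, 1));
  while (k <= k_max) {
    bool improved = false;
    if (k == 1) {
      for (int v = 0; v < n; ++v) {
        if ((side[v] == 1 && c1 == 1) || (side[v] == 2 && c2 == 1)) continue;
        double ncut = cut, nintra = intra;
        for (int u = 0; u < n; ++u) {
          if (u == v) continue;
          double w = W(v, u);
          if (!has_edge(w)) continue;
          if (side[u] == side[v]) { ncut += w; nintra -= 1.0 / w; }
          else                    { ncut -= w; nintra += 1.0 / w; }
        }
        double nval = ncut * nintra;
        if (nval > val + eps) {
          if (side[v] == 1) { --c1; ++c2; } else { --c2; ++c1; }
          side[v] = 3 - side[v];
          cut = ncut; intra = nintra; val = nval;
          improved = true;
          break;
        }
      }
    } else {
      for (int s = 0; s < vns_samples && !improved; ++s) {
        // sample k distinct vertices (k is tiny; rejection is fine)
        int got = 0;
        while (got < k) {
          int cnd = (int)std::floor(unif_rand() * n) % n;
          bool dup = false;
          for (int t = 0; t < got; ++t) if (pick[t] == cnd) dup = true;
          if (!dup) pick[got++] = cnd;
        }
        int d1 = 0;
        for (int t = 0; t < k; ++t) d1 += (side[pick[t]] == 1) ? -1 : 1;
        if (c1 + d1 == 0 || c2 - d1 == 0) continue;
        // apply flips sequentially with incremental updates
        double ncut = cut, nintra = intra;
        for (int t = 0; t < k; ++t) {
          int v = pick[t];
          for (int u = 0; u < n; ++u) {
            if (u == v) continue;
            double w = W(v, u);
            if (!has_edge(w)) continue;
            if (side[u] == side[v]) { ncut += w; nintra -= 1.0 / w; }
            else                    { ncut -= w; nintra += 1.0 / w; }
          }
          side[v] = 3 - side[v];
        }
        double nval = ncut * nintra;
        if (nval > val + eps) {
          cut = ncut; intra = nintra; val = nval;
          c1 += d1; c2 -= d1;
          improved = true;
        } else {
          for (int t = 0; t < k; ++t) side[pick[t]] = 3 - side[pick[t]];
        }
      }
    }
    k = improved ? 1 : k + 1;
  }

  full_eval(W, side, cut, intra);  // discard incremental drift
  return List::create(_["side"] = IntegerVector(side.begin(), side.end()),
                      _["cut_sum"] = cut, _["intra_recip"] = intra,
                      _["value"] = cut * intra);
}
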