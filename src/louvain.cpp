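#include <Rcpp.h>
using namespace Rcpp;

// Two-phase greedy modularity maximization (local node moves, then graph
// aggregation) on a dense weighted graph, with a resolution parameter and an
// optional negative layer handled by a separate null model:
//
//   Q = (1/(2m+ + 2m-)) * [ sum_{jk} (w+_jk - g k+_j k+_k / 2m+) d(c_j,c_k)
//                         - sum_{jk} (w-_jk - g k-_j k-_k / 2m-) d(c_j,c_k) ]
//
// With an all-zero negative layer this reduces to classical weighted
// modularity with resolution g. Strengths and totals include self-loops
// (created by aggregation) once; the d-sum runs over all ordered pairs
// including j == k. Node visit order is shuffled with R's RNG, so results are
// reproducible under set.seed().

static void shuffle_order(std::vector<int>& ord) {
  int n = ord.size();
  for (int i = n - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(ord[i], ord[j]);
  }
}

// One level of local moving. comm is modified in place (0-based, arbitrary
// ids < n). Returns true if any node changed community.
static bool one_level(const NumericMatrix& Ap, const NumericMatrix& An,
                      double gamma, double tol, std::vector<int>& comm) {
  const int n = Ap.nrow();
  const bool has_neg = An.nrow() == n;

  std::vector<double> kp(n, 0.0), kn(n, 0.0);
  double m2p = 0.0, m2n = 0.0;
  for (int i = 0; i < n; ++i) {
    double sp = 0.0, sn = 0.0;
    for (int j = 0; j < n; ++j) {
      sp += Ap(i, j);
      if (has_neg) sn += An(i, j);
    }
    kp[i] = sp; kn[i] = sn;
    m2p += sp; m2n += sn;
  }
  const double norm = m2p + m2n;

  std::vector<double> totp(n, 0.0), totn(n, 0.0);
  std::vector<int> csize(n, 0);
  for (int i = 0; i < n; ++i) {
    totp[comm[i]] += kp[i];
    totn[comm[i]] += kn[i];
    csize[comm[i]] += 1;
  }
  std::vector<int> free_ids;
  for (int c = 0; c < n; ++c)
    if (csize[c] == 0) free_ids.push_back(c);

  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;

  std::vector<double> wposc(n), wnegc(n);
  std::vector<int> touched; touched.reserve(n);

  bool any_move = false;
  double pass_gain;
  do {
    pass_gain = 0.0;
    shuffle_order(ord);
    for (int oi = 0; oi < n; ++oi) {
      const int i = ord[oi];
      const int old_c = comm[i];

      // links from i to each current community (self-loop excluded: it is
      // community-independent)
      touched.clear();
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        const int c = comm[j];
        const double ap = Ap(i, j);
        const double an = has_neg ? An(i, j) : 0.0;
        if (ap != 0.0 || an != 0.0) {
          if (wposc[c] == 0.0 && wnegc[c] == 0.0) touched.push_back(c);
          wposc[c] += ap;
          wnegc[c] += an;
        }
      }
      bool old_touched = false;
      for (size_t t = 0; t < touched.size(); ++t)
        if (touched[t] == old_c) { old_touched = true; break; }
      if (!old_touched) touched.push_back(old_c);

      // remove i from its community
      totp[old_c] -= kp[i];
      totn[old_c] -= kn[i];
      csize[old_c] -= 1;
      if (csize[old_c] == 0) free_ids.push_back(old_c);

      double gain_old =
        (m2p > 0 ? wposc[old_c] - gamma * kp[i] * totp[old_c] / m2p : 0.0) -
        (m2n > 0 ? wnegc[old_c] - gamma * kn[i] * totn[old_c] / m2n : 0.0);

      // best candidate; staying alone scores 0
      int best_c = old_c;
      double best_gain = gain_old;
      for (size_t t = 0; t < touched.size(); ++t) {
        const int c = touched[t];
        if (c == old_c) continue;
        double g =
          (m2p > 0 ? wposc[c] - gamma * kp[i] * totp[c] / m2p : 0.0) -
          (m2n > 0 ? wnegc[c] - gamma * kn[i] * totn[c] / m2n : 0.0);
        if (g > best_gain) {
          best_gain = g;
          best_c = c;
        } else if (g == best_gain && best_c != old_c && c < best_c) {
          best_c = c; // deterministic tie-break toward the lower id
        }
      }

      // a fresh singleton community scores exactly 0; take it when every
      // occupied candidate has negative gain
      if (best_gain < 0.0 && !free_ids.empty()) {
        best_c = free_ids.back();
        best_gain = 0.0;
      }

      if (csize[best_c] == 0) {
        // claim the id from the free list (it is always the most recent)
        for (size_t t = 0; t < free_ids.size(); ++t)
          if (free_ids[t] == best_c) { free_ids.erase(free_ids.begin() + t); break; }
      }
      totp[best_c] += kp[i];
      totn[best_c] += kn[i];
      csize[best_c] += 1;
      comm[i] = best_c;
      if (best_c != old_c) {
        any_move = true;
        pass_gain += 2.0 * (best_gain - gain_old) / norm;
      }

      for (size_t t = 0; t < touched.size(); ++t) {
        wposc[touched[t]] = 0.0;
        wnegc[touched[t]] = 0.0;
      }
    }
  } while (pass_gain > tol);

  return any_move;
}

static int renumber(std::vector<int>& comm) {
  const int n = comm.size();
  std::vector<int> map(n, -1);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    if (map[comm[i]] < 0) map[comm[i]] = next++;
    comm[i] = map[comm[i]];
  }
  return next;
}

static NumericMatrix aggregate(const NumericMatrix& A,
                               const std::vector<int>& comm, int nc) {
  const int n = A.nrow();
  NumericMatrix B(nc, nc);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      B(comm[i], comm[j]) += A(i, j);
  return B;
}

// [[Rcpp::export]]
IntegerVector louvain_cpp(NumericMatrix wpos, NumericMatrix wneg,
                          double gamma, double tol) {
  int n = wpos.nrow();
  std::vector<int> node2comm(n);
  for (int i = 0; i < n; ++i) node2comm[i] = i;

  NumericMatrix Ap = clone(wpos);
  NumericMatrix An = wneg; // 0x0 matrix means "no negative layer"
  if (An.nrow() > 0) An = clone(wneg);

  std::vector<int> comm(n);
  for (int i = 0; i < n; ++i) comm[i] = i;

  while (true) {
    const int cur_n = Ap.nrow();
    std::vector<int> level(cur_n);
    for (int i = 0; i < cur_n; ++i) level[i] = i;

    bool moved = one_level(Ap, An, gamma, tol, level);
    int nc = renumber(level);
    for (int i = 0; i < n; ++i) node2comm[i] = level[node2comm[i]];
    if (!moved || nc == cur_n) break;

    Ap = aggregate(Ap, level, nc);
    if (An.nrow() > 0) An = aggregate(An, level, nc);
  }

  return IntegerVector(node2comm.begin(), node2comm.end());
}
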