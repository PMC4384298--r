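#include <Rcpp.h>
using namespace Rcpp;

// Log-space dynamic programming over a global profile HMM with silent states.
//
// State encoding contract (enforced by the R-side builder):
//  * states are 0-based in C++ (converted from the R 1-based ids);
//  * every edge whose target is non-emitting satisfies from < to, so a single
//    increasing (forward) / decreasing (backward) sweep per position resolves
//    all within-position dependencies among non-emitting states;
//  * emis is n_states x 5 (A,C,G,T,N) in log space; rows of non-emitting
//    states are ignored.

static inline double lse(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  return (a > b) ? a + log1p(exp(b - a)) : b + log1p(exp(a - b));
}

// [[Rcpp::export]]
List hmm_fwdbwd_cpp(int n_states, LogicalVector silent, NumericMatrix emis,
                    IntegerVector edge_from, IntegerVector edge_to,
                    NumericVector edge_logp, int start, int end,
                    IntegerVector x, bool do_backward) {
  const int L = x.size();
  const int ne = edge_from.size();

  // incoming adjacency (CSR-style)
  std::vector<int> in_cnt(n_states, 0);
  for (int e = 0; e < ne; ++e) in_cnt[edge_to[e]]++;
  std::vector<int> in_ofs(n_states + 1, 0);
  for (int s = 0; s < n_states; ++s) in_ofs[s + 1] = in_ofs[s] + in_cnt[s];
  std::vector<int> in_edge(ne);
  {
    std::vector<int> fill(in_ofs.begin(), in_ofs.end() - 1);
    for (int e = 0; e < ne; ++e) in_edge[fill[edge_to[e]]++] = e;
  }

  NumericMatrix f(n_states, L + 1);
  std::fill(f.begin(), f.end(), R_NegInf);

  // position 0: only non-emitting states reachable
  f(start, 0) = 0.0;
  for (int s = 0; s < n_states; ++s) {
    if (!silent[s] || s == start) continue;
    double v = R_NegInf;
    for (int k = in_ofs[s]; k < in_ofs[s + 1]; ++k) {
      int e = in_edge[k];
      v = lse(v, f(edge_from[e], 0) + edge_logp[e]);
    }
    f(s, 0) = v;
  }
  for (int i = 1; i <= L; ++i) {
    const int c = x[i - 1];
    for (int s = 0; s < n_states; ++s) {
      if (silent[s]) continue;
      double v = R_NegInf;
      for (int k = in_ofs[s]; k < in_ofs[s + 1]; ++k) {
        int e = in_edge[k];
        v = lse(v, f(edge_from[e], i - 1) + edge_logp[e]);
      }
      f(s, i) = v + emis(s, c);
    }
    for (int s = 0; s < n_states; ++s) {
      if (!silent[s]) continue;
      double v = R_NegInf;
      for (int k = in_ofs[s]; k < in_ofs[s + 1]; ++k) {
        int e = in_edge[k];
        v = lse(v, f(edge_from[e], i) + edge_logp[e]);
      }
      f(s, i) = (s == start && i == 0) ? lse(v, 0.0) : v;
    }
  }
  double logPf = f(end, L);

  if (!do_backward) {
    return List::create(_["f"] = f, _["logPxM"] = logPf);
  }

  // outgoing adjacency
  std::vector<int> out_cnt(n_states, 0);
  for (int e = 0; e < ne; ++e) out_cnt[edge_from[e]]++;
  std::vector<int> out_ofs(n_states + 1, 0);
  for (int s = 0; s < n_states; ++s) out_ofs[s + 1] = out_ofs[s] + out_cnt[s];
  std::vector<int> out_edge(ne);
  {
    std::vector<int> fill(out_ofs.begin(), out_ofs.end() - 1);
    for (int e = 0; e < ne; ++e) out_edge[fill[edge_from[e]]++] = e;
  }

  NumericMatrix b(n_states, L + 1);
  std::fill(b.begin(), b.end(), R_NegInf);
  for (int i = L; i >= 0; --i) {
    for (int s = n_states - 1; s >= 0; --s) {
      double v = R_NegInf;
      for (int k = out_ofs[s]; k < out_ofs[s + 1]; ++k) {
        int e = out_edge[k];
        int t = edge_to[e];
        if (silent[t]) {
          v = lse(v, edge_logp[e] + b(t, i));
        } else if (i < L) {
          v = lse(v, edge_logp[e] + emis(t, x[i]) + b(t, i + 1));
        }
      }
      if (s == end && i == L) v = lse(v, 0.0);
      b(s, i) = v;
    }
  }
  double logPb = b(start, 0);

  return List::create(_["f"] = f, _["b"] = b,
                      _["logPxM"] = logPf, _["logPxM_bwd"] = logPb);
}

// Per-position posterior mass summed over the states carrying each label.
// label: per-state 1-based label id, 0 = exclude (non-emitting states).
// [[Rcpp::export]]
NumericMatrix hmm_posterior_label_cpp(NumericMatrix f, NumericMatrix b,
                                      IntegerVector label, int n_label,
                                      double logPxM) {
  const int n_states = f.nrow();
  const int L = f.ncol() - 1;
  NumericMatrix post(L, n_label);
  for (int i = 1; i <= L; ++i) {
    for (int s = 0; s < n_states; ++s) {
      const int lab = label[s];
      if (lab <= 0) continue;
      double lp = f(s, i) + b(s, i) - logPxM;
      if (lp > -745.0) post(i - 1, lab - 1) += exp(lp);
    }
  }
  return post;
}

// Sample reads by walking the model from start to end using R's RNG.
// If read_match >= 0 and read_len > 0 the single-column read segment emits
// exactly read_len symbols (one from the match column, the rest from the
// insert column) instead of following its geometric length prior.
// [[Rcpp::export]]
CharacterVector hmm_emit_cpp(int n_states, LogicalVector silent,
                             NumericMatrix emis, IntegerVector edge_from,
                             IntegerVector edge_to, NumericVector edge_logp,
                             int start, int end, int n,
                             int read_match, int read_insert, int read_len,
                             int max_len) {
  const int ne = edge_from.size();
  std::vector<int> out_cnt(n_states, 0);
  for (int e = 0; e < ne; ++e) out_cnt[edge_from[e]]++;
  std::vector<int> out_ofs(n_states + 1, 0);
  for (int s = 0; s < n_states; ++s) out_ofs[s + 1] = out_ofs[s] + out_cnt[s];
  std::vector<int> out_edge(ne);
  {
    std::vector<int> fill(out_ofs.begin(), out_ofs.end() - 1);
    for (int e = 0; e < ne; ++e) out_edge[fill[edge_from[e]]++] = e;
  }
  const char *bases = "ACGT";
  RNGScope scope;
  CharacterVector out(n);

  for (int r = 0; r < n; ++r) {
    std::string seq;
    int s = start;
    int guard = 0;
    while (s != end && guard++ < max_len + n_states + 16) {
      if (s == read_match && read_len > 0) {
        // conditioned read-body emission
        for (int k = 0; k < read_len; ++k) {
          int src = (k == 0) ? read_match : read_insert;
          double u = unif_rand(), acc = 0.0;
          int base = 3;
          for (int bb = 0; bb < 4; ++bb) {
            acc += exp(emis(src, bb));
            if (u <= acc) { base = bb; break; }
          }
          seq.push_back(bases[base]);
        }
        // leave via the insert column's (or match column's) exit edge
        int from = (read_len == 1) ? read_match : read_insert;
        int nxt = -1;
        for (int k = out_ofs[from]; k < out_ofs[from + 1]; ++k) {
          int t = edge_to[out_edge[k]];
          if (t != read_insert && t != read_match) { nxt = t; break; }
        }
        s = nxt;
        continue;
      }
      if (!silent[s]) {
        double u = unif_rand(), acc = 0.0;
        int base = 3;
        for (int bb = 0; bb < 4; ++bb) {
          acc += exp(emis(s, bb));
          if (u <= acc) { base = bb; break; }
        }
        seq.push_back(bases[base]);
        if ((int)seq.size() > max_len) break;
      }
      // sample outgoing transition
      double u = unif_rand(), acc = 0.0;
      int nxt = edge_to[out_edge[out_ofs[s + 1] - 1]];
      for (int k = out_ofs[s]; k < out_ofs[s + 1]; ++k) {
        int e = out_edge[k];
        acc += exp(edge_logp[e]);
        if (u <= acc) { nxt = edge_to[e]; break; }
      }
      s = nxt;
    }
    out[r] = seq;
  }
  return out;
}
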