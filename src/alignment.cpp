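// Local alignment (Smith-Waterman with affine gaps, Gotoh) and the batch
// read-annotation kernel.  Gap convention: a gap of length L costs
// gap_open + (L-1) * gap_extend, both parameters negative.  Scores are
// integral (the R wrappers validate this); integer arithmetic roughly
// doubles DP throughput relative to doubles.
#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Scoring {
  int match, mismatch, gap_open, gap_extend;
};

const int NEG = -1000000000;

inline int subst(char a, char b, const Scoring& sc) {
  return a == b ? sc.match : sc.mismatch;
}

// Score-only pass.  Best end cell is the first (smallest query index, then
// target index) cell attaining the optimum.
int sw_score_only(const std::string& q, const std::string& t,
                  const Scoring& sc) {
  const int n = (int)q.size(), m = (int)t.size();
  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0), Fcol(m + 1, NEG);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int E = NEG;
    const char qc = q[i - 1];
    const int* hp = Hprev.data();
    int* hc = Hcur.data();
    int* fc = Fcol.data();
    hc[0] = 0;
    for (int j = 1; j <= m; ++j) {
      E = std::max(hc[j - 1] + sc.gap_open, E + sc.gap_extend);
      fc[j] = std::max(hp[j] + sc.gap_open, fc[j] + sc.gap_extend);
      int h = hp[j - 1] + subst(qc, t[j - 1], sc);
      h = std::max(std::max(h, E), std::max(fc[j], 0));
      hc[j] = h;
      if (h > best) best = h;
    }
    std::swap(Hprev, Hcur);
  }
  return best;
}

struct SwResult {
  int score;
  int q_start, q_end, t_start, t_end;  // 0-based half-open
  std::vector<int> map_q, map_t;       // diagonally aligned positions, 0-based
};

// Full DP with traceback.  Deterministic tie-breaking: end cell is the first
// best cell in row-major order; moves prefer diagonal, then gap-in-query,
// then gap-in-target; gap closure prefers opening over extension.
SwResult sw_traceback(const std::string& q, const std::string& t,
                      const Scoring& sc) {
  const int n = (int)q.size(), m = (int)t.size();
  std::vector<int> H((n + 1) * (m + 1), 0), E((n + 1) * (m + 1), NEG),
      F((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      E[at(i, j)] =
          std::max(H[at(i, j - 1)] + sc.gap_open, E[at(i, j - 1)] + sc.gap_extend);
      F[at(i, j)] =
          std::max(H[at(i - 1, j)] + sc.gap_open, F[at(i - 1, j)] + sc.gap_extend);
      int h = H[at(i - 1, j - 1)] + subst(q[i - 1], t[j - 1], sc);
      h = std::max(std::max(h, E[at(i, j)]), std::max(F[at(i, j)], 0));
      H[at(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  SwResult r;
  r.score = best;
  r.q_end = bi; r.t_end = bj;
  int i = bi, j = bj, state = 0;  // 0 = H, 1 = E (gap in query), 2 = F
  while (i > 0 && j > 0) {
    if (state == 0) {
      int h = H[at(i, j)];
      if (h == 0) break;
      int diag = H[at(i - 1, j - 1)] + subst(q[i - 1], t[j - 1], sc);
      if (h == diag) {
        r.map_q.push_back(i - 1);
        r.map_t.push_back(j - 1);
        --i; --j;
      } else if (h == E[at(i, j)]) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      // consumed target position j-1 against a gap
      if (E[at(i, j)] == H[at(i, j - 1)] + sc.gap_open) state = 0;
      --j;
    } else {
      if (F[at(i, j)] == H[at(i - 1, j)] + sc.gap_open) state = 0;
      --i;
    }
  }
  r.q_start = i; r.t_start = j;
  std::reverse(r.map_q.begin(), r.map_q.end());
  std::reverse(r.map_t.begin(), r.map_t.end());
  return r;
}

// Read position diagonally aligned to target (segment) position `tpos`,
// or -1 if that segment position is not covered by a match/mismatch column.
int mapped_read_pos(const SwResult& r, int tpos) {
  for (size_t k = 0; k < r.map_t.size(); ++k)
    if (r.map_t[k] == tpos) return r.map_q[k];
  return -1;
}

}  // namespace

// [[Rcpp::export]]
List sw_align_cpp(std::string query, std::string target, int match,
                  int mismatch, int gap_open, int gap_extend) {
  Scoring sc{match, mismatch, gap_open, gap_extend};
  SwResult r = sw_traceback(query, target, sc);
  return List::create(
      _["score"] = r.score, _["query_start"] = r.q_start,
      _["query_end"] = r.q_end, _["target_start"] = r.t_start,
      _["target_end"] = r.t_end,
      _["map_query"] = IntegerVector(r.map_q.begin(), r.map_q.end()),
      _["map_target"] = IntegerVector(r.map_t.begin(), r.map_t.end()));
}

// [[Rcpp::export]]
NumericVector sw_score_many_cpp(std::string read, CharacterVector segments,
                                int match, int mismatch, int gap_open,
                                int gap_extend) {
  Scoring sc{match, mismatch, gap_open, gap_extend};
  const int k = segments.size();
  NumericVector out(k);
  for (int s = 0; s < k; ++s)
    out[s] = sw_score_only(read, as<std::string>(segments[s]), sc);
  return out;
}

// Status codes: 0 ok, 1 no_v, 2 no_j, 3 anchor_missing.
// Segments must be pre-sorted by name: ties on score keep the first
// (lexicographically smallest) segment.  The V search is confined to the
// read prefix of length max(segment length) + v_prefix_margin (pass a
// negative margin for a full-read search); J segments are searched in the
// read suffix that starts at the end of the aligned V block when j_after_v
// is true.
// [[Rcpp::export]]
List annotate_batch_cpp(CharacterVector reads, CharacterVector v_seqs,
                        IntegerVector v_anchor, CharacterVector j_seqs,
                        IntegerVector j_anchor, int match, int mismatch,
                        int gap_open, int gap_extend, double min_score_v,
                        double min_score_j, bool j_after_v,
                        int v_prefix_margin) {
  Scoring sc{match, mismatch, gap_open, gap_extend};
  const int nr = reads.size(), nv = v_seqs.size(), nj = j_seqs.size();
  std::vector<std::string> V(nv), J(nj);
  size_t max_vlen = 0;
  for (int s = 0; s < nv; ++s) {
    V[s] = as<std::string>(v_seqs[s]);
    max_vlen = std::max(max_vlen, V[s].size());
  }
  for (int s = 0; s < nj; ++s) J[s] = as<std::string>(j_seqs[s]);

  IntegerVector v_idx(nr, NA_INTEGER), j_idx(nr, NA_INTEGER);
  NumericVector v_score(nr, NA_REAL), j_score(nr, NA_REAL);
  IntegerVector junc_start(nr, NA_INTEGER), junc_end(nr, NA_INTEGER);
  IntegerVector status(nr, 0);

  for (int ri = 0; ri < nr; ++ri) {
    const std::string read = as<std::string>(reads[ri]);
    const std::string vregion =
        (v_prefix_margin >= 0 && read.size() > max_vlen + v_prefix_margin)
            ? read.substr(0, max_vlen + v_prefix_margin)
            : read;
    int bestv = NEG, bv = -1;
    for (int s = 0; s < nv; ++s) {
      int sco = sw_score_only(vregion, V[s], sc);
      if (sco > bestv) { bestv = sco; bv = s; }
    }
    if (bv < 0 || bestv < min_score_v) { status[ri] = 1; continue; }
    SwResult valn = sw_traceback(vregion, V[bv], sc);
    v_idx[ri] = bv + 1; v_score[ri] = valn.score;

    const int j_from = j_after_v ? valn.q_end : 0;
    const std::string suffix = read.substr(j_from);
    int bestj = NEG, bj = -1;
    if (!suffix.empty()) {
      for (int s = 0; s < nj; ++s) {
        int sco = sw_score_only(suffix, J[s], sc);
        if (sco > bestj) { bestj = sco; bj = s; }
      }
    }
    if (bj < 0 || bestj < min_score_j) { status[ri] = 2; continue; }
    SwResult jaln = sw_traceback(suffix, J[bj], sc);
    j_idx[ri] = bj + 1; j_score[ri] = jaln.score;

    const int vpos = mapped_read_pos(valn, v_anchor[bv]);
    const int jpos_last = mapped_read_pos(jaln, j_anchor[bj] + 2);
    if (vpos < 0 || jpos_last < 0) { status[ri] = 3; continue; }
    const int je = j_from + jpos_last + 1;
    if (vpos >= je) { status[ri] = 3; continue; }
    junc_start[ri] = vpos;
    junc_end[ri] = je;
  }
  return List::create(_["v_idx"] = v_idx, _["j_idx"] = j_idx,
                      _["v_score"] = v_score, _["j_score"] = j_score,
                      _["junc_start"] = junc_start, _["junc_end"] = junc_end,
                      _["status"] = status);
}

// i.i.d. per-base substitution errors; uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export]]
CharacterVector mutate_reads_cpp(CharacterVector reads, double error_rate) {
  static const char bases[] = "ACGT";
  const int n = reads.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(reads[i]);
    for (size_t p = 0; p < s.size(); ++p) {
      if (unif_rand() < error_rate) {
        int cur = 0;
        switch (s[p]) {
          case 'A': cur = 0; break;
          case 'C': cur = 1; break;
          case 'G': cur = 2; break;
          default:  cur = 3; break;
        }
        int k = (int)(unif_rand() * 3.0);
        if (k > 2) k = 2;
        s[p] = bases[(cur + 1 + k) % 4];
      }
    }
    out[i] = s;
  }
  return out;
}
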