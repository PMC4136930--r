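// Global pairwise alignment engine (Needleman-Wunsch with affine gaps, Gotoh
// three-state recursion) plus the batch operations built on it: identity
// matrices, greedy incremental clustering and the two-parent chimera screen.
//
// Conventions shared with the R layer:
//   * scoring: match / mismatch per aligned pair; a gap run of length k costs
//     gap_open + k * gap_extend (open charged once per run);
//   * traceback tie-breaking prefers diagonal, then up (consume the first
//     sequence), then left;
//   * identity = matches / alignment columns after stripping the terminal gap
//     run at each end ("alignment" denominator), or matches over the full
//     alignment divided by the shorter sequence length ("shorter" denominator);
//   * 'N' (and any non-ACGT letter) never matches anything, including itself.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

namespace {

const double NEG = -1e30;

struct Scoring {
  double ma, mi, go, ge;
};

inline std::vector<uint8_t> encode(const char* s, size_t n) {
  std::vector<uint8_t> v(n);
  for (size_t i = 0; i < n; ++i) {
    switch (s[i]) {
    case 'A': v[i] = 0; break;
    case 'C': v[i] = 1; break;
    case 'G': v[i] = 2; break;
    case 'T': v[i] = 3; break;
    default:  v[i] = 4; // N or other: mismatches everything
    }
  }
  return v;
}

inline std::vector<uint8_t> encode(const std::string& s) {
  return encode(s.c_str(), s.size());
}

struct AlnOut {
  double score;
  int matches_trim, cols_trim;   // after terminal-gap trimming
  int matches_all, cols_all;     // full alignment
  std::vector<uint8_t> ops;      // 0 = diagonal, 1 = up (consume a), 2 = left
};

inline int hamming(const std::vector<uint8_t>& a, const std::vector<uint8_t>& b) {
  int h = 0;
  for (size_t i = 0; i < a.size(); ++i)
    if (a[i] != b[i] || a[i] >= 4) ++h;
  return h;
}

// Full or banded Gotoh DP with traceback. Scores kept in two rolling rows;
// predecessor choices packed into one byte per cell for the traceback.
//
// For equal-length inputs the DP is restricted, without loss of exactness, to
// the band |i - j| <= w: the all-diagonal alignment scores
// ma*(L-h) + mi*h (h = Hamming distance), while any path containing more than
// k insertion/deletion pairs scores at most ma*(L-k) + 2*go + 2*k*ge, so with
//   w = floor(((ma-mi)*h + 2*go) / (ma - 2*ge)) + 1
// every optimal path stays inside the band and the banded result (scores and
// preferred traceback) is identical to the full DP.
void gotoh(const std::vector<uint8_t>& a, const std::vector<uint8_t>& b,
           const Scoring& sc, AlnOut& out) {
  const int n = (int)a.size(), m = (int)b.size();
  int w = m > n ? m : n; // default: full DP
  if (n == m && sc.ma > sc.mi && sc.go <= 0 && sc.ge <= 0 &&
      sc.ma - 2.0 * sc.ge > 0) {
    const int h = hamming(a, b);
    const double kmax = ((sc.ma - sc.mi) * h + 2.0 * sc.go) / (sc.ma - 2.0 * sc.ge);
    int wb = (int)std::floor(kmax) + 1;
    if (wb < 1) wb = 1;
    if (wb < w) w = wb;
  }
  static std::vector<double> M0, X0, Y0, M1, X1, Y1;
  static std::vector<uint8_t> dir;
  M0.assign(m + 1, NEG); X0.assign(m + 1, NEG); Y0.assign(m + 1, NEG);
  M1.assign(m + 1, NEG); X1.assign(m + 1, NEG); Y1.assign(m + 1, NEG);
  if (dir.size() < (size_t)(n + 1) * (m + 1))
    dir.resize((size_t)(n + 1) * (m + 1));

  M0[0] = 0.0;
  const int j0max = m < w ? m : w;
  for (int j = 1; j <= j0max; ++j) {
    Y0[j] = sc.go + j * sc.ge;
    dir[j] = (uint8_t)((j == 1 ? 0 : 2) << 4);
  }

  double* Mprev = M0.data(); double* Xprev = X0.data(); double* Yprev = Y0.data();
  double* Mcur = M1.data();  double* Xcur = X1.data();  double* Ycur = Y1.data();

  for (int i = 1; i <= n; ++i) {
    const int jlo = (i - w) > 1 ? (i - w) : 1;
    const int jhi = (i + w) < m ? (i + w) : m;
    uint8_t* drow = &dir[(size_t)i * (m + 1)];
    if (jlo == 1) {
      Mcur[0] = NEG; Ycur[0] = NEG;
      Xcur[0] = sc.go + i * sc.ge;
      drow[0] = (uint8_t)((i == 1 ? 0 : 1) << 2);
    } else {
      // left band edge: out-of-band predecessors
      Mcur[jlo - 1] = NEG; Xcur[jlo - 1] = NEG; Ycur[jlo - 1] = NEG;
    }
    const uint8_t ai = a[i - 1];
    for (int j = jlo; j <= jhi; ++j) {
      const double sub = (ai == b[j - 1] && ai < 4) ? sc.ma : sc.mi;
      // match/mismatch state: strict '>' keeps the M,X,Y preference at ties
      double bm = Mprev[j - 1]; int dm = 0;
      if (Xprev[j - 1] > bm) { bm = Xprev[j - 1]; dm = 1; }
      if (Yprev[j - 1] > bm) { bm = Yprev[j - 1]; dm = 2; }
      Mcur[j] = sub + bm;
      // up state (gap in b, consume a)
      double vx = Mprev[j] + sc.go + sc.ge; int dx = 0;
      if (Xprev[j] + sc.ge > vx) { vx = Xprev[j] + sc.ge; dx = 1; }
      if (Yprev[j] + sc.go + sc.ge > vx) { vx = Yprev[j] + sc.go + sc.ge; dx = 2; }
      Xcur[j] = vx;
      // left state (gap in a, consume b)
      double vy = Mcur[j - 1] + sc.go + sc.ge; int dy = 0;
      if (Xcur[j - 1] + sc.go + sc.ge > vy) { vy = Xcur[j - 1] + sc.go + sc.ge; dy = 1; }
      if (Ycur[j - 1] + sc.ge > vy) { vy = Ycur[j - 1] + sc.ge; dy = 2; }
      Ycur[j] = vy;
      drow[j] = (uint8_t)(dm | (dx << 2) | (dy << 4));
    }
    if (jhi < m) { // right band edge sentinel read by the next row
      Mcur[jhi + 1] = NEG; Xcur[jhi + 1] = NEG; Ycur[jhi + 1] = NEG;
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  int state = 0;
  double best = Mprev[m];
  if (Xprev[m] > best) { best = Xprev[m]; state = 1; }
  if (Yprev[m] > best) { best = Yprev[m]; state = 2; }
  out.score = best;

  out.ops.clear();
  out.ops.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const uint8_t d = dir[(size_t)i * (m + 1) + j];
    if (state == 0) {
      out.ops.push_back(0);
      state = d & 3; --i; --j;
    } else if (state == 1) {
      out.ops.push_back(1);
      state = (d >> 2) & 3; --i;
    } else {
      out.ops.push_back(2);
      state = (d >> 4) & 3; --j;
    }
  }
  std::reverse(out.ops.begin(), out.ops.end());

  // match counts and terminal-gap trimming
  const int tot = (int)out.ops.size();
  int lead = 0, trail = 0;
  if (tot > 0 && out.ops.front() != 0) {
    const uint8_t v = out.ops.front();
    while (lead < tot && out.ops[lead] == v) ++lead;
  }
  if (tot > 0 && out.ops.back() != 0) {
    const uint8_t v = out.ops.back();
    while (trail < tot - lead && out.ops[tot - 1 - trail] == v) ++trail;
  }
  int ia = 0, ib = 0, matches_all = 0, matches_trim = 0;
  for (int k = 0; k < tot; ++k) {
    const uint8_t op = out.ops[k];
    if (op == 0) {
      const bool hit = (a[ia] == b[ib] && a[ia] < 4);
      if (hit) {
        ++matches_all;
        if (k >= lead && k < tot - trail) ++matches_trim;
      }
      ++ia; ++ib;
    } else if (op == 1) ++ia; else ++ib;
  }
  out.matches_all = matches_all;
  out.cols_all = tot;
  out.matches_trim = matches_trim;
  out.cols_trim = tot - lead - trail;
  if (out.cols_trim < 0) out.cols_trim = 0;
}

// For equal-length sequences whose Hamming distance h satisfies
//   ma - h * (ma - mi) >= 2 * (go + ge)
// no alignment containing a gap can out-score the all-diagonal alignment
// (a gapped alignment has at most L - 1 matches and pays at least two gap
// opens), and the preferred traceback is the diagonal itself. In that case
// identity is exactly (L - h) / L without running the DP. Returns -1 when the
// shortcut does not apply.
inline double try_diagonal(const std::vector<uint8_t>& a,
                           const std::vector<uint8_t>& b,
                           const Scoring& sc, bool shorter) {
  if (a.size() != b.size() || a.empty()) return -1.0;
  if (sc.ma <= sc.mi || sc.go > 0 || sc.ge > 0 || sc.ma < 2.0 * sc.ge) return -1.0;
  const double hmax = (sc.ma - 2.0 * (sc.go + sc.ge)) / (sc.ma - sc.mi);
  const int h = hamming(a, b);
  if ((double)h > hmax) return -1.0;
  const double L = (double)a.size();
  return (L - h) / L; // identical for both denominators (no gaps)
}

inline double identity_of(const AlnOut& o, int la, int lb, bool shorter) {
  if (shorter) {
    const int L = la < lb ? la : lb;
    return L > 0 ? (double)o.matches_all / (double)L : 0.0;
  }
  return o.cols_trim > 0 ? (double)o.matches_trim / (double)o.cols_trim : 0.0;
}

// Identity is computed in a canonical orientation (longer sequence first,
// ties broken lexicographically) so that identity(a, b) == identity(b, a)
// even when co-optimal alignments with different identities exist.
inline double pair_identity(const std::vector<uint8_t>& a,
                            const std::vector<uint8_t>& b,
                            const Scoring& sc, bool shorter) {
  const double d = try_diagonal(a, b, sc, shorter);
  if (d >= 0.0) return d;
  const bool swap = (b.size() > a.size()) || (b.size() == a.size() && b < a);
  const std::vector<uint8_t>& x = swap ? b : a;
  const std::vector<uint8_t>& y = swap ? a : b;
  AlnOut o;
  gotoh(x, y, sc, o);
  return identity_of(o, (int)x.size(), (int)y.size(), shorter);
}

std::vector<std::vector<uint8_t> > encode_all(const CharacterVector& x) {
  std::vector<std::vector<uint8_t> > out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const char* s = CHAR(STRING_ELT(x, i));
    out[i] = encode(s, strlen(s));
  }
  return out;
}

} // namespace

// [[Rcpp::export]]
List cpp_align_pair(std::string a, std::string b, double match, double mismatch,
                    double gap_open, double gap_extend) {
  if (a.empty() || b.empty()) stop("sequences must be non-empty");
  const Scoring sc = {match, mismatch, gap_open, gap_extend};
  const std::vector<uint8_t> ea = encode(a), eb = encode(b);
  AlnOut o;
  gotoh(ea, eb, sc, o);
  std::string ra, rb;
  ra.reserve(o.ops.size()); rb.reserve(o.ops.size());
  size_t ia = 0, ib = 0;
  for (size_t k = 0; k < o.ops.size(); ++k) {
    if (o.ops[k] == 0)      { ra += a[ia++]; rb += b[ib++]; }
    else if (o.ops[k] == 1) { ra += a[ia++]; rb += '-'; }
    else                    { ra += '-';     rb += b[ib++]; }
  }
  return List::create(
    _["aligned_a"] = ra, _["aligned_b"] = rb, _["score"] = o.score,
    _["matches"] = o.matches_trim, _["columns"] = o.cols_trim,
    _["matches_all"] = o.matches_all, _["columns_all"] = o.cols_all);
}

// [[Rcpp::export]]
NumericMatrix cpp_identity_many(CharacterVector queries, CharacterVector refs,
                                double match, double mismatch, double gap_open,
                                double gap_extend, bool shorter) {
  const Scoring sc = {match, mismatch, gap_open, gap_extend};
  const std::vector<std::vector<uint8_t> > eq = encode_all(queries);
  const std::vector<std::vector<uint8_t> > er = encode_all(refs);
  NumericMatrix out((int)eq.size(), (int)er.size());
  for (size_t i = 0; i < eq.size(); ++i) {
    for (size_t j = 0; j < er.size(); ++j)
      out((int)i, (int)j) = pair_identity(eq[i], er[j], sc, shorter);
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_identity_matrix(CharacterVector seqs, double match,
                                  double mismatch, double gap_open,
                                  double gap_extend, bool shorter) {
  const Scoring sc = {match, mismatch, gap_open, gap_extend};
  const std::vector<std::vector<uint8_t> > e = encode_all(seqs);
  const int n = (int)e.size();
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    out(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) {
      const double v = pair_identity(e[i], e[j], sc, shorter);
      out(i, j) = v; out(j, i) = v;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Greedy incremental clustering over sequences already sorted into canonical
// processing order (longest first, then lexicographic id). `uniq` maps each
// sequence to its 0-based unique-sequence index so identities are computed at
// most once per (unique sequence, seed) pair. A sequence joins the existing
// seed of highest identity when that identity meets the cutoff (ties at
// tie_tol resolved to the earliest seed), otherwise it founds a new cluster.
// [[Rcpp::export]]
List cpp_greedy_cluster(CharacterVector seqs, IntegerVector uniq, int n_uniq,
                        double cutoff, double match, double mismatch,
                        double gap_open, double gap_extend, bool shorter,
                        double tie_tol) {
  const Scoring sc = {match, mismatch, gap_open, gap_extend};
  const R_xlen_t n = seqs.size();
  std::vector<std::vector<uint8_t> > enc(n_uniq);
  std::vector<bool> have(n_uniq, false);
  std::vector<std::vector<float> > cache(n_uniq);
  std::vector<int> seed_u, seed_pos;
  IntegerVector assign(n);

  for (R_xlen_t s = 0; s < n; ++s) {
    const int u = uniq[s];
    if (!have[u]) {
      const char* cs = CHAR(STRING_ELT(seqs, s));
      enc[u] = encode(cs, strlen(cs));
      have[u] = true;
    }
    std::vector<float>& cv = cache[u];
    for (size_t k = cv.size(); k < seed_u.size(); ++k)
      cv.push_back((float)pair_identity(enc[u], enc[seed_u[k]], sc, shorter));
    double bestv = -1.0; int besti = -1;
    for (size_t k = 0; k < cv.size(); ++k) {
      if ((double)cv[k] > bestv + tie_tol) { bestv = (double)cv[k]; besti = (int)k; }
    }
    if (besti >= 0 && bestv >= cutoff - 1e-12) {
      assign[s] = besti;
    } else {
      assign[s] = (int)seed_u.size();
      seed_u.push_back(u);
      seed_pos.push_back((int)s);
    }
    if (s % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["assign"] = assign,
                      _["seed_index"] = IntegerVector(seed_pos.begin(), seed_pos.end()));
}

// Reference-based two-parent chimera screen. Each read is aligned globally to
// every reference; per-read-position match indicators are extracted from the
// alignments. At each scanned breakpoint the best 5' segment identity and the
// best 3' segment identity over two *different* references are combined
// (length-weighted); a read is flagged when the best combination exceeds its
// best full-length identity by at least `margin`.
// [[Rcpp::export]]
List cpp_chimera_screen(CharacterVector reads, CharacterVector refs,
                        double match, double mismatch, double gap_open,
                        double gap_extend, bool shorter,
                        NumericVector break_fracs, double margin) {
  const Scoring sc = {match, mismatch, gap_open, gap_extend};
  const std::vector<std::vector<uint8_t> > er = encode_all(refs);
  const int nr = (int)er.size();
  const R_xlen_t n = reads.size();
  LogicalVector flag(n);
  NumericVector gain(n), full_best(n);
  IntegerVector full_best_ref(n);

  std::vector<std::vector<int> > pre(nr);
  std::vector<double> full_id(nr);
  AlnOut o;

  for (R_xlen_t s = 0; s < n; ++s) {
    const char* cs = CHAR(STRING_ELT(reads, s));
    const std::vector<uint8_t> a = encode(cs, strlen(cs));
    const int L = (int)a.size();
    for (int r = 0; r < nr; ++r) {
      gotoh(a, er[r], sc, o);
      full_id[r] = identity_of(o, L, (int)er[r].size(), shorter);
      std::vector<int>& p = pre[r];
      p.assign(L + 1, 0);
      int ia = 0, ib = 0;
      for (size_t k = 0; k < o.ops.size(); ++k) {
        const uint8_t op = o.ops[k];
        if (op == 0) {
          p[ia + 1] = p[ia] + ((a[ia] == er[r][ib] && a[ia] < 4) ? 1 : 0);
          ++ia; ++ib;
        } else if (op == 1) {
          p[ia + 1] = p[ia];
          ++ia;
        } else ++ib;
      }
    }
    double fb = -1.0; int fbr = -1;
    for (int r = 0; r < nr; ++r)
      if (full_id[r] > fb) { fb = full_id[r]; fbr = r; }
    full_best[s] = fb;
    full_best_ref[s] = fbr + 1;

    double best_comb = -1.0;
    for (R_xlen_t q = 0; q < break_fracs.size(); ++q) {
      int bp = (int)(break_fracs[q] * L + 0.5);
      if (bp < 1) bp = 1;
      if (bp > L - 1) bp = L - 1;
      // best and runner-up over references for each segment
      double b5 = -1, b5b = -1, b3 = -1, b3b = -1;
      int i5 = -1, i3 = -1;
      for (int r = 0; r < nr; ++r) {
        const double s5 = (double)pre[r][bp] / bp;
        const double s3 = (double)(pre[r][L] - pre[r][bp]) / (L - bp);
        if (s5 > b5) { b5b = b5; b5 = s5; i5 = r; }
        else if (s5 > b5b) b5b = s5;
        if (s3 > b3) { b3b = b3; b3 = s3; i3 = r; }
        else if (s3 > b3b) b3b = s3;
      }
      double comb;
      if (i5 != i3) comb = (bp * b5 + (L - bp) * b3) / L;
      else {
        const double c1 = b5b >= 0 ? (bp * b5b + (L - bp) * b3) / L : -1;
        const double c2 = b3b >= 0 ? (bp * b5 + (L - bp) * b3b) / L : -1;
        comb = c1 > c2 ? c1 : c2;
      }
      if (comb > best_comb) best_comb = comb;
    }
    gain[s] = best_comb - fb;
    flag[s] = nr >= 2 && (best_comb - fb >= margin - 1e-12);
    if (s % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["flagged"] = flag, _["gain"] = gain,
                      _["full_best"] = full_best,
                      _["full_best_ref"] = full_best_ref);
}
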