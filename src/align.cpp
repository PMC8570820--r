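// Alignment kernels: Smith-Waterman (exact, affine gaps), X-drop ungapped
// extension, banded gapped extension from an anchor, and a batched
// seed-extension driver used by the chunk search loop.
//
// Conventions (shared with the R layer):
//  - coordinates are 0-based half-open internally;
//  - a gap run of length L costs gap_open + (L-1)*gap_extend;
//  - path strings are over {M, I, D}: M consumes one residue of query and
//    subject, I consumes query only (gap in subject), D consumes subject
//    only (gap in query);
//  - residues outside the matrix alphabet score as 'X'.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <climits>
using namespace Rcpp;

static const int NEG = INT_MIN / 4;

static void build_lut(const std::string& ab, int* lut) {
  int xi = 0;
  for (size_t i = 0; i < ab.size(); ++i) if (ab[i] == 'X') xi = (int)i;
  for (int c = 0; c < 256; ++c) lut[c] = xi;
  for (size_t i = 0; i < ab.size(); ++i) lut[(unsigned char)ab[i]] = (int)i;
}

static std::vector<int> enc(const std::string& s, const int* lut) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = lut[(unsigned char)s[i]];
  return v;
}

struct Replay {
  long score;
  int identities, match_cols, gap_opens, qlen, slen;
};

// Replay a path against encoded sequences starting at (qs, ss).
static Replay replay_path(const std::string& path,
                          const std::vector<int>& qi, const std::vector<int>& si,
                          int qs, int ss, const IntegerMatrix& S,
                          int gap_open, int gap_extend) {
  Replay r = {0, 0, 0, 0, 0, 0};
  int i = qs, j = ss;
  char prev = 'M';
  for (size_t p = 0; p < path.size(); ++p) {
    char c = path[p];
    if (c == 'M') {
      r.score += S(qi[i], si[j]);
      if (qi[i] == si[j]) r.identities++;
      r.match_cols++;
      i++; j++;
    } else if (c == 'I') {            // gap in subject
      r.score -= (prev == 'I') ? gap_extend : gap_open;
      if (prev != 'I') r.gap_opens++;
      i++;
    } else {                          // 'D', gap in query
      r.score -= (prev == 'D') ? gap_extend : gap_open;
      if (prev != 'D') r.gap_opens++;
      j++;
    }
    prev = c;
  }
  r.qlen = i - qs;
  r.slen = j - ss;
  return r;
}

// [[Rcpp::export]]
List cpp_replay(std::string path, std::string q, std::string s,
                int q_start, int s_start, IntegerMatrix S, std::string alphabet,
                int gap_open, int gap_extend) {
  int lut[256];
  build_lut(alphabet, lut);
  std::vector<int> qi = enc(q, lut), si = enc(s, lut);
  if (q_start < 0 || s_start < 0) stop("negative start coordinate");
  Replay r = replay_path(path, qi, si, q_start, s_start, S, gap_open, gap_extend);
  return List::create(_["score"] = (double)r.score,
                      _["identities"] = r.identities,
                      _["match_cols"] = r.match_cols,
                      _["gap_opens"] = r.gap_opens,
                      _["q_len"] = r.qlen,
                      _["s_len"] = r.slen);
}

// ---------------------------------------------------------------------------
// Smith-Waterman, score only (O(n) memory), one query vs many subjects.
// [[Rcpp::export]]
IntegerVector cpp_sw_score_many(std::string q, CharacterVector refs,
                                IntegerMatrix S, std::string alphabet,
                                int gap_open, int gap_extend) {
  int lut[256];
  build_lut(alphabet, lut);
  std::vector<int> qi = enc(q, lut);
  int m = (int)qi.size();
  IntegerVector out(refs.size());
  for (R_xlen_t r = 0; r < refs.size(); ++r) {
    std::string sref = as<std::string>(refs[r]);
    std::vector<int> si = enc(sref, lut);
    int n = (int)si.size();
    std::vector<int> H(n + 1, 0), F(n + 1, NEG);
    int best = 0;
    for (int i = 1; i <= m; ++i) {
      int diag = 0, e = NEG, hj;
      const int* srow = &S(qi[i - 1], 0);
      int step = S.nrow();
      for (int j = 1; j <= n; ++j) {
        e = std::max(H[j - 1] - gap_open, e - gap_extend);
        F[j] = std::max(H[j] - gap_open, F[j] - gap_extend);
        hj = diag + srow[(size_t)si[j - 1] * step];
        if (e > hj) hj = e;
        if (F[j] > hj) hj = F[j];
        if (hj < 0) hj = 0;
        diag = H[j];
        H[j] = hj;
        if (hj > best) best = hj;
      }
    }
    out[r] = best;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Full Smith-Waterman with traceback.  Cell ties keep the first maximum in
// row-major scan order (smallest q_end, then s_end); traceback prefers
// M over I over D.  Memory is O(m*n) bytes.
// [[Rcpp::export]]
List cpp_sw_pair(std::string q, std::string s, IntegerMatrix S,
                 std::string alphabet, int gap_open, int gap_extend) {
  int lut[256];
  build_lut(alphabet, lut);
  std::vector<int> qi = enc(q, lut), si = enc(s, lut);
  int m = (int)qi.size(), n = (int)si.size();
  if (m == 0 || n == 0) stop("both sequences must be non-empty");
  // traceback byte: bits 0-1 H source (0 stop, 1 diag, 2 E, 3 F);
  // bit 2: E extended from E; bit 3: F extended from F.
  std::vector<unsigned char> tb((size_t)(m + 1) * (n + 1), 0);
  std::vector<int> H(n + 1, 0), F(n + 1, NEG);
  int best = 0, bi = 0, bj = 0;
  int step = S.nrow();
  for (int i = 1; i <= m; ++i) {
    int diag = 0, e = NEG;
    unsigned char* trow = &tb[(size_t)i * (n + 1)];
    const int* srow = &S(qi[i - 1], 0);
    for (int j = 1; j <= n; ++j) {
      unsigned char t = 0;
      int eo = H[j - 1] - gap_open, ee = e - gap_extend;
      if (ee > eo) { e = ee; t |= 4; } else e = eo;
      int fo = H[j] - gap_open, fe = F[j] - gap_extend;
      if (fe > fo) { F[j] = fe; t |= 8; } else F[j] = fo;
      int hd = diag + srow[(size_t)si[j - 1] * step];
      int h = 0;      // source 0: local stop
      unsigned char src = 0;
      if (hd > h) { h = hd; src = 1; }
      if (e > h)  { h = e;  src = 2; }
      if (F[j] > h) { h = F[j]; src = 3; }
      trow[j] = (unsigned char)(t | src);
      diag = H[j];
      H[j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  // traceback
  std::string path;
  int i = bi, j = bj;
  int state = 0; // 0 = H, 1 = E, 2 = F
  while (i > 0 && j > 0) {
    unsigned char t = tb[(size_t)i * (n + 1) + j];
    if (state == 0) {
      int src = t & 3;
      if (src == 0) break;
      if (src == 1) { path.push_back('M'); i--; j--; }
      else if (src == 2) state = 1;
      else state = 2;
    } else if (state == 1) {          // E: gap in query, consumes subject
      path.push_back('D');
      bool ext = (t & 4) != 0;
      j--;
      if (!ext) state = 0;
    } else {                          // F: gap in subject, consumes query
      path.push_back('I');
      bool ext = (t & 8) != 0;
      i--;
      if (!ext) state = 0;
    }
  }
  std::reverse(path.begin(), path.end());
  Replay r = replay_path(path, qi, si, i, j, S, gap_open, gap_extend);
  return List::create(_["score"] = best,
                      _["q_start"] = i, _["q_end"] = bi,
                      _["s_start"] = j, _["s_end"] = bj,
                      _["path"] = path,
                      _["identities"] = r.identities,
                      _["match_cols"] = r.match_cols,
                      _["gap_opens"] = r.gap_opens,
                      _["replay_score"] = (double)r.score);
}

// ---------------------------------------------------------------------------
// Ungapped X-drop extension through an exact seed of length k.
struct Ungapped { int qs, qe, ss, se; long score; };

static Ungapped ungapped_core(const std::vector<int>& qi, const std::vector<int>& si,
                              int qpos, int spos, int k,
                              const IntegerMatrix& S, int xdrop) {
  long seed_score = 0;
  for (int t = 0; t < k; ++t) seed_score += S(qi[qpos + t], si[spos + t]);
  // right of seed
  long run = 0, best_r = 0;
  int best_re = 0;
  int i = qpos + k, j = spos + k, t = 0;
  while (i < (int)qi.size() && j < (int)si.size()) {
    run += S(qi[i], si[j]);
    ++t;
    if (run > best_r) { best_r = run; best_re = t; }
    if (best_r - run > xdrop) break;
    ++i; ++j;
  }
  // left of seed
  run = 0;
  long best_l = 0;
  int best_ls = 0;
  i = qpos - 1; j = spos - 1; t = 0;
  while (i >= 0 && j >= 0) {
    run += S(qi[i], si[j]);
    ++t;
    if (run > best_l) { best_l = run; best_ls = t; }
    if (best_l - run > xdrop) break;
    --i; --j;
  }
  Ungapped u;
  u.qs = qpos - best_ls;
  u.qe = qpos + k + best_re;
  u.ss = spos - best_ls;
  u.se = spos + k + best_re;
  u.score = seed_score + best_l + best_r;
  return u;
}

// [[Rcpp::export]]
List cpp_ungapped_extend(std::string q, std::string s, int qpos, int spos,
                         int k, IntegerMatrix S, std::string alphabet,
                         int xdrop) {
  int lut[256];
  build_lut(alphabet, lut);
  std::vector<int> qi = enc(q, lut), si = enc(s, lut);
  if (qpos < 0 || spos < 0 || qpos + k > (int)qi.size() || spos + k > (int)si.size())
    stop("seed outside sequence bounds");
  Ungapped u = ungapped_core(qi, si, qpos, spos, k, S, xdrop);
  return List::create(_["q_start"] = u.qs, _["q_end"] = u.qe,
                      _["s_start"] = u.ss, _["s_end"] = u.se,
                      _["score"] = (double)u.score);
}

// ---------------------------------------------------------------------------
// Banded gapped extension in one direction from an anchor.  Alignment must
// start at the anchor corner; the best-scoring prefix (possibly empty) is
// kept.  Band is |i - j| <= band_half in extension coordinates.  Rows stop
// when every in-band cell falls more than xdrop below the running best.
struct Ext { long score; int qlen, slen; std::string path; };

static Ext extend_dir(const std::vector<int>& qi, const std::vector<int>& si,
                      int aq, int as, int dir, const IntegerMatrix& S,
                      int gap_open, int gap_extend, int band_half, int xdrop) {
  int M, N;
  if (dir > 0) { M = (int)qi.size() - aq; N = (int)si.size() - as; }
  else { M = aq + 1; N = as + 1; }
  if (M < 0) M = 0;
  if (N < 0) N = 0;
  Ext out;
  out.score = 0; out.qlen = 0; out.slen = 0; out.path = "";
  if (M == 0 || N == 0) return out;
  auto Q = [&](int i) { return dir > 0 ? qi[aq + i - 1] : qi[aq - (i - 1)]; };
  auto Sc = [&](int j) { return dir > 0 ? si[as + j - 1] : si[as - (j - 1)]; };

  // tb bits: 0-1 H source (1 diag, 2 E, 3 F); bit 2 E-extends; bit 3 F-extends.
  std::vector<unsigned char> tb((size_t)(M + 1) * (N + 1), 0);
  std::vector<long> Hprev((size_t)N + 1, NEG), Hcur((size_t)N + 1, NEG);
  std::vector<long> Fprev((size_t)N + 1, NEG), Fcur((size_t)N + 1, NEG);
  // row 0: leading gaps in query (D columns)
  Hprev[0] = 0;
  for (int j = 1; j <= std::min(N, band_half); ++j)
    Hprev[j] = -(long)gap_open - (long)(j - 1) * gap_extend;
  long best = 0;
  int bi = 0, bj = 0, step = S.nrow();
  for (int i = 1; i <= M; ++i) {
    int jlo = std::max(0, i - band_half), jhi = std::min(N, i + band_half);
    std::fill(Hcur.begin(), Hcur.end(), NEG);
    std::fill(Fcur.begin(), Fcur.end(), NEG);
    long e = NEG, row_best = NEG;
    unsigned char* trow = &tb[(size_t)i * (N + 1)];
    const int* srow = &S(Q(i), 0);
    if (jlo == 0) {
      // column 0: leading gaps in subject (I columns)
      Hcur[0] = -(long)gap_open - (long)(i - 1) * gap_extend;
      if (Hcur[0] > row_best) row_best = Hcur[0];
      jlo = 1;
    }
    for (int j = jlo; j <= jhi; ++j) {
      unsigned char t = 0;
      long hl = Hcur[j - 1];
      long eo = (hl <= NEG / 2) ? NEG : hl - gap_open;
      long ee = (e <= NEG / 2) ? NEG : e - gap_extend;
      if (ee > eo) { e = ee; t |= 4; } else e = eo;
      long hu = Hprev[j];
      long fo = (hu <= NEG / 2) ? NEG : hu - gap_open;
      long fe = (Fprev[j] <= NEG / 2) ? NEG : Fprev[j] - gap_extend;
      long fv;
      if (fe > fo) { fv = fe; t |= 8; } else fv = fo;
      long hd = Hprev[j - 1];
      hd = (hd <= NEG / 2) ? NEG : hd + srow[(size_t)Sc(j) * step];
      long h = NEG;
      unsigned char src = 0;
      if (hd > h) { h = hd; src = 1; }
      if (e > h) { h = e; src = 2; }
      if (fv > h) { h = fv; src = 3; }
      trow[j] = (unsigned char)(t | src);
      Hcur[j] = h;
      Fcur[j] = fv;
      if (h > best) { best = h; bi = i; bj = j; }
      if (h > row_best) row_best = h;
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
    if (row_best < best - xdrop) break;
  }
  // traceback from (bi, bj) to (0, 0)
  std::string path;
  int i = bi, j = bj, state = 0;
  while (i > 0 || j > 0) {
    if (i == 0) { for (; j > 0; --j) path.push_back('D'); break; }
    if (j == 0) { for (; i > 0; --i) path.push_back('I'); break; }
    unsigned char t = tb[(size_t)i * (N + 1) + j];
    if (state == 0) {
      int src = t & 3;
      if (src == 1) { path.push_back('M'); i--; j--; }
      else if (src == 2) state = 1;
      else if (src == 3) state = 2;
      else break;  // defensive: malformed cell
    } else if (state == 1) {
      path.push_back('D');
      bool ext = (t & 4) != 0;
      j--;
      if (!ext) state = 0;
    } else {
      path.push_back('I');
      bool ext = (t & 8) != 0;
      i--;
      if (!ext) state = 0;
    }
  }
  out.score = best;
  out.qlen = bi;
  out.slen = bj;
  if (dir > 0) std::reverse(path.begin(), path.end());
  // for dir < 0 the path was built end->start in reversed coordinates, which
  // is already start->end in original coordinates.
  out.path = path;
  return out;
}

// Gapped extension from an ungapped HSP: anchor at its midpoint column, then
// banded extension left and right.  Raw score is the replay of the combined
// path (gap runs abutting the anchor merge into one open).
static List gapped_core(const std::vector<int>& qi, const std::vector<int>& si,
                        int qs, int qe, int ss, int se,
                        const IntegerMatrix& S, std::string alphabet_unused,
                        int gap_open, int gap_extend, int band_half, int xdrop) {
  int off = (qe - qs - 1) / 2;
  int aq = qs + off, as = ss + off;
  Ext right = extend_dir(qi, si, aq + 1, as + 1, +1, S, gap_open, gap_extend,
                         band_half, xdrop);
  Ext left = extend_dir(qi, si, aq - 1, as - 1, -1, S, gap_open, gap_extend,
                        band_half, xdrop);
  std::string path = left.path;
  path.push_back('M');
  path += right.path;
  int q_start = aq - left.qlen, s_start = as - left.slen;
  Replay r = replay_path(path, qi, si, q_start, s_start, S, gap_open, gap_extend);
  return List::create(_["q_start"] = q_start,
                      _["q_end"] = q_start + r.qlen,
                      _["s_start"] = s_start,
                      _["s_end"] = s_start + r.slen,
                      _["score"] = (double)r.score,
                      _["path"] = path,
                      _["identities"] = r.identities,
                      _["match_cols"] = r.match_cols,
                      _["gap_opens"] = r.gap_opens);
}

// [[Rcpp::export]]
List cpp_gapped_extend(std::string q, std::string s,
                       int q_start, int q_end, int s_start, int s_end,
                       IntegerMatrix S, std::string alphabet,
                       int gap_open, int gap_extend, int band_half, int xdrop) {
  int lut[256];
  build_lut(alphabet, lut);
  std::vector<int> qi = enc(q, lut), si = enc(s, lut);
  if (q_end <= q_start || s_end <= s_start) stop("empty seed HSP");
  if (q_end > (int)qi.size() || s_end > (int)si.size())
    stop("seed HSP outside sequence bounds");
  return gapped_core(qi, si, q_start, q_end, s_start, s_end, S, alphabet,
                     gap_open, gap_extend, band_half, xdrop);
}

// ---------------------------------------------------------------------------
// Batched driver: extend deduplicated seed matches of many queries against
// one reference sequence.  Seeds whose start falls inside an HSP already
// emitted for the same query are skipped (containment pruning).
// [[Rcpp::export]]
DataFrame cpp_extend_seeds(CharacterVector queries, std::string ref,
                           IntegerVector q_ord, IntegerVector q_pos,
                           IntegerVector s_pos, int k,
                           IntegerMatrix S, std::string alphabet,
                           int gap_open, int gap_extend,
                           int xdrop_ungapped, int xdrop_gapped,
                           int band_half, int trigger_raw) {
  int lut[256];
  build_lut(alphabet, lut);
  std::vector<int> si = enc(ref, lut);
  std::vector<std::vector<int> > qenc(queries.size());
  std::vector<bool> have(queries.size(), false);

  std::vector<int> o_ord, o_qs, o_qe, o_ss, o_se, o_id, o_mc, o_go;
  std::vector<double> o_raw;
  std::vector<std::string> o_path;

  R_xlen_t nseed = q_ord.size();
  for (R_xlen_t t = 0; t < nseed; ++t) {
    int ord = q_ord[t] - 1;           // R is 1-based
    if (!have[ord]) {
      qenc[ord] = enc(as<std::string>(queries[ord]), lut);
      have[ord] = true;
    }
    const std::vector<int>& qi = qenc[ord];
    int qp = q_pos[t], sp = s_pos[t];
    // containment pruning
    bool skip = false;
    for (size_t h = 0; h < o_ord.size(); ++h) {
      if (o_ord[h] == ord + 1 && qp >= o_qs[h] && qp + k <= o_qe[h] &&
          sp >= o_ss[h] && sp + k <= o_se[h]) { skip = true; break; }
    }
    if (skip) continue;
    Ungapped u = ungapped_core(qi, si, qp, sp, k, S, xdrop_ungapped);
    if (u.score < trigger_raw) continue;
    List g = gapped_core(qi, si, u.qs, u.qe, u.ss, u.se, S, alphabet,
                         gap_open, gap_extend, band_half, xdrop_gapped);
    o_ord.push_back(ord + 1);
    o_qs.push_back(as<int>(g["q_start"]));
    o_qe.push_back(as<int>(g["q_end"]));
    o_ss.push_back(as<int>(g["s_start"]));
    o_se.push_back(as<int>(g["s_end"]));
    o_raw.push_back(as<double>(g["score"]));
    o_id.push_back(as<int>(g["identities"]));
    o_mc.push_back(as<int>(g["match_cols"]));
    o_go.push_back(as<int>(g["gap_opens"]));
    o_path.push_back(as<std::string>(g["path"]));
  }
  return DataFrame::create(_["q_ord"] = o_ord,
                           _["q_start"] = o_qs, _["q_end"] = o_qe,
                           _["s_start"] = o_ss, _["s_end"] = o_se,
                           _["raw_score"] = o_raw,
                           _["identities"] = o_id,
                           _["match_cols"] = o_mc,
                           _["gap_opens"] = o_go,
                           _["path"] = o_path,
                           _["stringsAsFactors"] = false);
}
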