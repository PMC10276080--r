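#include <Rcpp.h>
#include <vector>
#include <string>
#include <functional>
#include <algorithm>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh). Penalties are positive; a gap of
// length L costs gap_open + L * gap_ext.

static const int NEG = -100000000;

// [[Rcpp::export]]
IntegerVector cpp_sw_score_batch(CharacterVector reads, std::string ref,
                                 int match, int mismatch,
                                 int gap_open, int gap_ext) {
  int m = ref.size();
  int nr = reads.size();
  IntegerVector out(nr);
  std::vector<int> H(m + 1), F(m + 1);
  int goe = gap_open + gap_ext;
  for (int r = 0; r < nr; ++r) {
    const char *a = CHAR(STRING_ELT(reads, r));
    int n = LENGTH(STRING_ELT(reads, r));
    std::fill(H.begin(), H.end(), 0);
    std::fill(F.begin(), F.end(), NEG);
    int best = 0;
    for (int i = 1; i <= n; ++i) {
      int diag = 0;      // H[i-1][j-1]
      int e = NEG;       // E[i][j] running along the row
      int hleft = 0;     // H[i][j-1]
      char ai = a[i - 1];
      for (int j = 1; j <= m; ++j) {
        e = std::max(e - gap_ext, hleft - goe);
        int f = std::max(F[j] - gap_ext, H[j] - goe);
        int h = diag + (ai == ref[j - 1] ? match : mismatch);
        if (e > h) h = e;
        if (f > h) h = f;
        if (h < 0) h = 0;
        diag = H[j];
        H[j] = h;
        F[j] = f;
        hleft = h;
        if (h > best) best = h;
      }
    }
    out[r] = best;
  }
  return out;
}

// Full alignment with traceback. Returns per-column read/ref coordinates
// (0-based; -1 in gap columns) and mismatch flags for aligned columns.
// [[Rcpp::export]]
List cpp_sw_align(std::string read, std::string ref,
                  int match, int mismatch, int gap_open, int gap_ext) {
  int n = read.size(), m = ref.size();
  std::vector<int> H((n + 1) * (m + 1), 0), E((n + 1) * (m + 1), NEG),
      F((n + 1) * (m + 1), NEG);
  // traceback states: 0 stop, 1 diag, 2 from E (gap in read: consumes ref),
  // 3 from F (gap in ref: consumes read); for E/F: whether opened (1) or extended (0)
  std::vector<unsigned char> tbH((n + 1) * (m + 1), 0),
      tbE((n + 1) * (m + 1), 0), tbF((n + 1) * (m + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int idx = i * (m + 1) + j;
      int openE = H[idx - 1] - gap_open - gap_ext;
      int extE = E[idx - 1] - gap_ext;
      E[idx] = openE >= extE ? openE : extE;
      tbE[idx] = openE >= extE ? 1 : 0;
      int openF = H[idx - (m + 1)] - gap_open - gap_ext;
      int extF = F[idx - (m + 1)] - gap_ext;
      F[idx] = openF >= extF ? openF : extF;
      tbF[idx] = openF >= extF ? 1 : 0;
      int s = H[idx - (m + 1) - 1] +
              (read[i - 1] == ref[j - 1] ? match : mismatch);
      int h = 0; unsigned char t = 0;
      if (s > h) { h = s; t = 1; }
      if (E[idx] > h) { h = E[idx]; t = 2; }
      if (F[idx] > h) { h = F[idx]; t = 3; }
      H[idx] = h; tbH[idx] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  std::vector<int> rpos, qpos;
  std::vector<int> mism;
  int i = bi, j = bj, state = 0; // 0 = in H
  while (i > 0 && j > 0) {
    int idx = i * (m + 1) + j;
    if (state == 0) {
      unsigned char t = tbH[idx];
      if (t == 0) break;
      if (t == 1) {
        qpos.push_back(i - 1); rpos.push_back(j - 1);
        mism.push_back(read[i - 1] == ref[j - 1] ? 0 : 1);
        --i; --j;
      } else if (t == 2) state = 2;
      else state = 3;
    } else if (state == 2) {
      qpos.push_back(-1); rpos.push_back(j - 1); mism.push_back(NA_INTEGER);
      if (tbE[idx] == 1) state = 0;
      --j;
    } else {
      qpos.push_back(i - 1); rpos.push_back(-1); mism.push_back(NA_INTEGER);
      if (tbF[idx] == 1) state = 0;
      --i;
    }
  }
  std::reverse(rpos.begin(), rpos.end());
  std::reverse(qpos.begin(), qpos.end());
  std::reverse(mism.begin(), mism.end());
  int cols = rpos.size(), matches = 0;
  for (int k = 0; k < cols; ++k)
    if (mism[k] == 0) ++matches;
  return List::create(
      _["score"] = best, _["columns"] = cols, _["matches"] = matches,
      _["read_start"] = i, _["read_end"] = bi,   // 0-based half-open
      _["ref_start"] = j, _["ref_end"] = bj,
      _["read_pos"] = IntegerVector(qpos.begin(), qpos.end()),
      _["ref_pos"] = IntegerVector(rpos.begin(), rpos.end()),
      _["mismatch"] = IntegerVector(mism.begin(), mism.end()));
}

// Slide a PSSM over translated reads; returns the best anchor position
// (0-based index of the first residue of the right half-window) and score.
// mat is 21 x width: rows = ACDEFGHIKLMNPQRSTVWY + catch-all row 21 for
// any other character. Positions where the window would leave the string
// are not considered; pos = -1 if no valid placement.
// [[Rcpp::export]]
List cpp_pssm_best(CharacterVector aa, NumericMatrix mat, int left_w) {
  static int lut[256];
  static bool init = false;
  const std::string letters = "ACDEFGHIKLMNPQRSTVWY";
  if (!init) {
    for (int i = 0; i < 256; ++i) lut[i] = 20;
    for (size_t i = 0; i < letters.size(); ++i)
      lut[(unsigned char)letters[i]] = i;
    init = true;
  }
  int width = mat.ncol();
  int nr = aa.size();
  IntegerVector pos(nr);
  NumericVector sc(nr);
  for (int r = 0; r < nr; ++r) {
    const char *s = CHAR(STRING_ELT(aa, r));
    int n = LENGTH(STRING_ELT(aa, r));
    int bestp = -1; double bests = R_NegInf;
    for (int p = left_w; p + (width - left_w) <= n; ++p) {
      double tot = 0;
      const char *w = s + p - left_w;
      for (int k = 0; k < width; ++k)
        tot += mat(lut[(unsigned char)w[k]], k);
      if (tot > bests) { bests = tot; bestp = p; }
    }
    pos[r] = bestp;
    sc[r] = bestp < 0 ? NA_REAL : bests;
  }
  return List::create(_["pos"] = pos, _["score"] = sc);
}

// [[Rcpp::export]]
int cpp_hamming(std::string a, std::string b) {
  if (a.size() != b.size()) stop("hamming: unequal lengths");
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i)
    if (a[i] != b[i]) ++d;
  return d;
}

// Single-linkage connected components among equal-length strings with
// Hamming distance <= max_d. Union-find over all pairs.
// [[Rcpp::export]]
IntegerVector cpp_hamming_components(CharacterVector s, int max_d) {
  int n = s.size();
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  std::vector<const char *> p(n);
  std::vector<int> len(n);
  for (int i = 0; i < n; ++i) {
    p[i] = CHAR(STRING_ELT(s, i));
    len[i] = LENGTH(STRING_ELT(s, i));
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (len[i] != len[j]) stop("hamming components: unequal lengths");
      int d = 0;
      for (int k = 0; k < len[i]; ++k) {
        if (p[i][k] != p[j][k] && ++d > max_d) break;
      }
      if (d <= max_d) {
        int ri = find(i), rj = find(j);
        if (ri != rj) parent[ri] = rj;
      }
    }
  }
  // relabel components 1..k in order of first appearance
  IntegerVector out(n);
  std::vector<int> label(n, 0);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    if (label[r] == 0) label[r] = ++next;
    out[i] = label[r];
  }
  return out;
}

// ---- batched V/J assignment with per-region mutation statistics ----
//
// For each read: rank references by a shared 8-mer prescreen (the same
// word-count heuristic the USEARCH family uses to order candidates),
// score the retained candidates by banded affine local alignment, rank by
// score (ties by reference order), traceback the best candidate and
// compute identity and region tallies; fall through to the next candidate
// while the current one fails the identity/score filters.
//
// band: half-width of the diagonal band (0 = full dynamic programming).
// The band is anchored on the main diagonal, which suits amplicons that
// start at the reference 5' end; pass 0 whenever that assumption fails
// (e.g. J genes matching a read suffix).
// prescreen: keep references sharing >= 60% of the best candidate's
// 8-mer count; when the best count is < 16 all references are kept.
// region_bounds: 6 x nrefs matrix (FR1,CDR1,FR2,CDR2,FR3 ungapped nt
// starts + FR3 end) for V references, or 0 x 0 for J references.
// gc64: 64-char genetic code string indexed by 16*b1 + 4*b2 + b3 (ACGT).
// smin: per-read minimum score implied by the E-value ceiling.

namespace {

struct AlnBuffers {
  std::vector<int> H, E, F;
  std::vector<unsigned char> tbH, tbE, tbF;
};

inline int nt_idx(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

int sw_score_only(const char *a, int n, const std::string &ref,
                  int match, int mismatch, int goe, int ge, int band,
                  std::vector<int> &H, std::vector<int> &F) {
  int m = ref.size();
  std::fill(H.begin(), H.begin() + m + 1, 0);
  std::fill(F.begin(), F.begin() + m + 1, NEG);
  int best = 0;
  const char *rf = ref.c_str();
  for (int i = 1; i <= n; ++i) {
    int jlo = 1, jhi = m;
    if (band > 0) {
      jlo = std::max(1, i - band);
      jhi = std::min(m, i + band);
      if (jlo > m) break;
      // columns first entered this row still hold the initial fill
      // (H = 0, F = NEG), which is the correct "outside band" value
    }
    int diag = (jlo == 1) ? 0 : H[jlo - 1];  // H[i-1][jlo-1], in-band last row
    int e = NEG;
    int hleft = 0;                           // H[i][jlo-1] is outside the band
    const char ai = a[i - 1];
    for (int j = jlo; j <= jhi; ++j) {
      e = std::max(e - ge, hleft - goe);
      int f = std::max(F[j] - ge, H[j] - goe);
      int h = diag + (ai == rf[j - 1] ? match : mismatch);
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      diag = H[j];
      H[j] = h;
      F[j] = f;
      hleft = h;
      if (h > best) best = h;
    }
  }
  return best;
}

struct AlnStats {
  int score, columns, matches;
  int read_start, read_end, ref_start, ref_end;
  int aa_matches, aa_cols, masked;
  int nt_mm[5], nt_al[5], aa_mm[5], aa_al[5];
};

// full (or banded) DP with traceback and per-region statistics
void sw_stats(const char *a, int n, const std::string &ref,
              int match, int mismatch, int goe, int ge, int band,
              int mask_nt, const int *bounds, bool has_regions,
              const std::string &gc64, AlnBuffers &buf, AlnStats &st) {
  int m = ref.size();
  size_t sz = (size_t)(n + 1) * (m + 1);
  if (buf.H.size() < sz) {
    buf.H.resize(sz); buf.E.resize(sz); buf.F.resize(sz);
    buf.tbH.resize(sz); buf.tbE.resize(sz); buf.tbF.resize(sz);
  }
  int *H = buf.H.data(); int *E = buf.E.data(); int *F = buf.F.data();
  unsigned char *tbH = buf.tbH.data(), *tbE = buf.tbE.data(),
                *tbF = buf.tbF.data();
  for (int j = 0; j <= m; ++j) { H[j] = 0; E[j] = NEG; F[j] = NEG; }
  int best = 0, bi = 0, bj = 0;
  const char *rf = ref.c_str();
  for (int i = 1; i <= n; ++i) {
    size_t row = (size_t)i * (m + 1), prow = row - (m + 1);
    int jlo = 1, jhi = m;
    if (band > 0) {
      jlo = std::max(1, i - band);
      jhi = std::min(m, i + band);
      if (jlo > m) break;
      // initialize boundary cells so the recurrences see "outside band"
      // as empty local alignments
      H[row + jlo - 1] = 0; E[row + jlo - 1] = NEG; F[row + jlo - 1] = NEG;
      tbH[row + jlo - 1] = 0;
      if (jhi == i + band && jhi <= m) {
        H[prow + jhi] = 0; F[prow + jhi] = NEG; E[prow + jhi] = NEG;
      }
    } else {
      H[row] = 0; E[row] = NEG; F[row] = NEG; tbH[row] = 0;
    }
    const char ai = a[i - 1];
    for (int j = jlo; j <= jhi; ++j) {
      int eo = H[row + j - 1] - goe, ee = E[row + j - 1] - ge;
      int e = eo >= ee ? eo : ee;
      E[row + j] = e; tbE[row + j] = eo >= ee ? 1 : 0;
      int fo = H[prow + j] - goe, fe = F[prow + j] - ge;
      int f = fo >= fe ? fo : fe;
      F[row + j] = f; tbF[row + j] = fo >= fe ? 1 : 0;
      int h = H[prow + j - 1] + (ai == rf[j - 1] ? match : mismatch);
      unsigned char t = 1;
      if (e > h) { h = e; t = 2; }
      if (f > h) { h = f; t = 3; }
      if (h < 0) { h = 0; t = 0; }
      H[row + j] = h; tbH[row + j] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  st.score = best;
  st.columns = 0; st.matches = 0; st.aa_matches = 0; st.aa_cols = 0;
  st.masked = 0;
  for (int k = 0; k < 5; ++k) {
    st.nt_mm[k] = st.nt_al[k] = st.aa_mm[k] = st.aa_al[k] = 0;
  }
  std::vector<int> q_of_r(m, -2);  // read pos aligned to each ref pos
  int i = bi, j = bj, state = 0;
  while (i > 0 && j > 0) {
    size_t idx = (size_t)i * (m + 1) + j;
    if (state == 0) {
      unsigned char t = tbH[idx];
      if (t == 0) break;
      if (t == 1) {
        ++st.columns;
        q_of_r[j - 1] = i - 1;
        if (a[i - 1] == rf[j - 1]) ++st.matches;
        --i; --j;
      } else if (t == 2) state = 2;
      else state = 3;
    } else if (state == 2) {
      ++st.columns; q_of_r[j - 1] = -1;
      if (tbE[idx] == 1) state = 0;
      --j;
    } else {
      ++st.columns;
      if (tbF[idx] == 1) state = 0;
      --i;
    }
  }
  st.read_start = i; st.read_end = bi;
  st.ref_start = j; st.ref_end = bj;
  int fr3_end = has_regions ? bounds[5] : 0;
  if (has_regions) {
    for (int r = st.ref_start; r < st.ref_end; ++r) {
      int q = q_of_r[r];
      if (q < 0) continue;                 // gap or uncovered
      if (r < mask_nt) { if (r < fr3_end) ++st.masked; continue; }
      if (r >= fr3_end) continue;
      int reg = 4;
      for (int k = 1; k < 5; ++k) {
        if (r < bounds[k]) { reg = k - 1; break; }
      }
      ++st.nt_al[reg];
      if (a[q] != rf[r]) ++st.nt_mm[reg];
    }
  }
  // codon-aware aa comparison over fully aligned, indel-free codons
  int ncod = m / 3;
  for (int c = 0; c < ncod; ++c) {
    int r0 = 3 * c;
    int q0 = q_of_r[r0], q1 = q_of_r[r0 + 1], q2 = q_of_r[r0 + 2];
    if (q0 < 0 || q1 != q0 + 1 || q2 != q0 + 2) continue;
    int ri0 = nt_idx(rf[r0]), ri1 = nt_idx(rf[r0 + 1]), ri2 = nt_idx(rf[r0 + 2]);
    int qi0 = nt_idx(a[q0]), qi1 = nt_idx(a[q1]), qi2 = nt_idx(a[q2]);
    char ref_aa = gc64[16 * ri0 + 4 * ri1 + ri2];
    char read_aa = (qi0 < 0 || qi1 < 0 || qi2 < 0)
                       ? 'X' : gc64[16 * qi0 + 4 * qi1 + qi2];
    bool mm = (read_aa != ref_aa);
    ++st.aa_cols;
    if (!mm) ++st.aa_matches;
    if (has_regions && r0 >= mask_nt && r0 < fr3_end) {
      int reg = 4;
      for (int k = 1; k < 5; ++k) {
        if (r0 < bounds[k]) { reg = k - 1; break; }
      }
      ++st.aa_al[reg];
      if (mm) ++st.aa_mm[reg];
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_assign_batch(CharacterVector reads, CharacterVector refs,
                      int match, int mismatch, int gap_open, int gap_ext,
                      double id_min, NumericVector smin,
                      IntegerMatrix region_bounds, int mask_nt,
                      std::string gc64, int band = 0, bool prescreen = true) {
  const int K = 8, NK = 1 << (2 * K);      // 8-mer prescreen
  int nr = reads.size(), ng = refs.size();
  if (ng > 32) prescreen = false;          // word masks hold 32 references
  bool has_regions = region_bounds.nrow() == 6;
  std::vector<std::string> R(ng);
  for (int g = 0; g < ng; ++g) R[g] = as<std::string>(refs[g]);
  int goe = gap_open + gap_ext, ge = gap_ext;
  int maxm = 0;
  for (int g = 0; g < ng; ++g) maxm = std::max(maxm, (int)R[g].size());
  std::vector<uint32_t> words;
  if (prescreen) {
    words.assign(NK, 0u);
    for (int g = 0; g < ng; ++g) {
      int code = 0, run = 0;
      for (size_t p = 0; p < R[g].size(); ++p) {
        int b = nt_idx(R[g][p]);
        if (b < 0) { run = 0; code = 0; continue; }
        code = ((code << 2) | b) & (NK - 1);
        if (++run >= K) words[code] |= (1u << g);
      }
    }
  }
  std::vector<int> Hrow(maxm + 1), Frow(maxm + 1);
  AlnBuffers buf;
  AlnStats st;
  IntegerVector winner(nr), score(nr), columns(nr), matches(nr),
      ref_start(nr), ref_end(nr), read_start(nr), read_end(nr),
      aa_matches(nr), aa_cols(nr), masked(nr);
  IntegerMatrix nt_mm(nr, 5), nt_al(nr, 5), aa_mm(nr, 5), aa_al(nr, 5);
  IntegerMatrix all_scores(nr, ng);
  std::vector<int> ord(ng), kcount(ng);
  for (int r = 0; r < nr; ++r) {
    const char *a = CHAR(STRING_ELT(reads, r));
    int n = LENGTH(STRING_ELT(reads, r));
    std::vector<char> use(ng, 1);
    if (prescreen) {
      std::fill(kcount.begin(), kcount.end(), 0);
      int code = 0, run = 0;
      for (int p = 0; p < n; ++p) {
        int b = nt_idx(a[p]);
        if (b < 0) { run = 0; code = 0; continue; }
        code = ((code << 2) | b) & (NK - 1);
        if (++run >= K) {
          uint32_t w = words[code];
          while (w) {
            int g = __builtin_ctz(w);
            ++kcount[g];
            w &= w - 1;
          }
        }
      }
      int kmax = *std::max_element(kcount.begin(), kcount.end());
      if (kmax >= 16) {
        for (int g = 0; g < ng; ++g)
          use[g] = kcount[g] * 10 >= kmax * 6;   // within 60% of the best
      }
    }
    for (int g = 0; g < ng; ++g) {
      all_scores(r, g) =
          use[g] ? sw_score_only(a, n, R[g], match, mismatch, goe, ge, band,
                                 Hrow, Frow)
                 : -1;
    }
    for (int g = 0; g < ng; ++g) ord[g] = g;
    std::stable_sort(ord.begin(), ord.end(), [&](int x, int y) {
      return all_scores(r, x) > all_scores(r, y);
    });
    winner[r] = 0;
    for (int k = 0; k < ng; ++k) {
      int g = ord[k];
      if (all_scores(r, g) < smin[r] || all_scores(r, g) < 0) break;
      const int *bptr = has_regions ? &region_bounds(0, g) : nullptr;
      sw_stats(a, n, R[g], match, mismatch, goe, ge, band, mask_nt, bptr,
               has_regions, gc64, buf, st);
      double ident = st.columns > 0 ? (double)st.matches / st.columns : 0.0;
      if (ident < id_min) continue;
      // tie on score: evaluate the other tied candidates, keep the one
      // with the highest identity (then earliest reference order)
      int kk = k + 1;
      while (kk < ng && all_scores(r, ord[kk]) == all_scores(r, g)) {
        AlnStats st2;
        const int *b2 = has_regions ? &region_bounds(0, ord[kk]) : nullptr;
        sw_stats(a, n, R[ord[kk]], match, mismatch, goe, ge, band, mask_nt,
                 b2, has_regions, gc64, buf, st2);
        double id2 = st2.columns > 0 ? (double)st2.matches / st2.columns : 0;
        if (id2 > ident && id2 >= id_min) {
          st = st2; ident = id2; g = ord[kk];
        }
        ++kk;
      }
      winner[r] = g + 1;
      score[r] = st.score; columns[r] = st.columns; matches[r] = st.matches;
      ref_start[r] = st.ref_start; ref_end[r] = st.ref_end;
      read_start[r] = st.read_start; read_end[r] = st.read_end;
      aa_matches[r] = st.aa_matches; aa_cols[r] = st.aa_cols;
      masked[r] = st.masked;
      for (int q = 0; q < 5; ++q) {
        nt_mm(r, q) = st.nt_mm[q]; nt_al(r, q) = st.nt_al[q];
        aa_mm(r, q) = st.aa_mm[q]; aa_al(r, q) = st.aa_al[q];
      }
      break;
    }
  }
  return List::create(
      _["winner"] = winner, _["score"] = score, _["columns"] = columns,
      _["matches"] = matches, _["read_start"] = read_start,
      _["read_end"] = read_end, _["ref_start"] = ref_start,
      _["ref_end"] = ref_end, _["aa_matches"] = aa_matches,
      _["aa_cols"] = aa_cols, _["masked"] = masked, _["nt_mm"] = nt_mm,
      _["nt_al"] = nt_al, _["aa_mm"] = aa_mm, _["aa_al"] = aa_al,
      _["scores"] = all_scores);
}

// expected sequencing errors per read from the quality string
// [[Rcpp::export]]
NumericVector cpp_expected_errors(CharacterVector quals, int offset) {
  double tab[256];
  for (int c = 0; c < 256; ++c) {
    int q = c - offset;
    tab[c] = q >= 0 ? std::pow(10.0, -q / 10.0) : -1.0;
  }
  int n = quals.size();
  NumericVector out(n);
  for (int r = 0; r < n; ++r) {
    const char *s = CHAR(STRING_ELT(quals, r));
    int len = LENGTH(STRING_ELT(quals, r));
    double e = 0;
    for (int p = 0; p < len; ++p) {
      double v = tab[(unsigned char)s[p]];
      if (v < 0) stop("negative Phred score (check phred_offset)");
      e += v;
    }
    out[r] = e;
  }
  return out;
}

// draw per-base qualities (clamped normal) and quality-driven errors for
// reads expanded from clone sequences; uses the R RNG
// [[Rcpp::export]]
List cpp_emit_reads(CharacterVector clone_seqs, IntegerVector counts,
                    double mean_q, double sd_q, bool error_from_quality) {
  static const char NTC[4] = {'A', 'C', 'G', 'T'};
  int nc = clone_seqs.size();
  long total = 0;
  for (int c = 0; c < nc; ++c) total += counts[c];
  CharacterVector seq_out(total), qual_out(total);
  double perr[42];
  for (int q = 0; q <= 41; ++q) perr[q] = std::pow(10.0, -q / 10.0);
  std::string sbuf, qbuf;
  long r = 0;
  for (int c = 0; c < nc; ++c) {
    const char *s = CHAR(STRING_ELT(clone_seqs, c));
    int len = LENGTH(STRING_ELT(clone_seqs, c));
    for (int k = 0; k < counts[c]; ++k) {
      sbuf.assign(s, len);
      qbuf.resize(len);
      for (int p = 0; p < len; ++p) {
        int q = (int)std::lround(R::rnorm(mean_q, sd_q));
        if (q < 2) q = 2;
        if (q > 41) q = 41;
        qbuf[p] = (char)(q + 33);
        if (error_from_quality && R::unif_rand() < perr[q]) {
          int b = nt_idx(sbuf[p]);
          if (b >= 0) {
            int d = 1 + (int)(R::unif_rand() * 3.0);
            if (d > 3) d = 3;
            sbuf[p] = NTC[(b + d) & 3];
          }
        }
      }
      seq_out[r] = sbuf;
      qual_out[r] = qbuf;
      ++r;
    }
  }
  return List::create(_["seq"] = seq_out, _["qual"] = qual_out);
}
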