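#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Symbol codes throughout: $=0, A=1, C=2, G=3, T=4.
// All positions and suffix-array ranks are 0-based at this layer.

// ---------------------------------------------------------------------------
// Suffix array by prefix doubling.  `keys` are initial integer keys; the
// caller assigns every sentinel a distinct key below all nucleotide keys so
// that sentinels sort by text position (multi-string SA convention).
// [[Rcpp::export]]
IntegerVector sa_prefix_doubling(IntegerVector keys) {
  const int n = keys.size();
  std::vector<int> sa(n), rk(n), tmp(n);
  for (int i = 0; i < n; ++i) { sa[i] = i; rk[i] = keys[i]; }
  for (int h = 1;; h <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rk[a] != rk[b]) return rk[a] < rk[b];
      int ra = a + h < n ? rk[a + h] : -1;
      int rb = b + h < n ? rk[b + h] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    for (int i = 0; i < n; ++i) rk[i] = tmp[i];
    if (rk[sa[n - 1]] == n - 1) break;
  }
  return IntegerVector(sa.begin(), sa.end());
}

// Occurrence counts of every symbol in B[0..pos] (inclusive); pos == -1 gives
// zeros.  `cp` is a 5 x nblocks checkpoint matrix (column-major), column j
// holding counts over B[0 .. j*rate-1]; the remainder is counted on the fly.
static inline void occ_all(const int* bwt, const int* cp, int rate, int pos,
                           int out[5]) {
  if (pos < 0) { for (int a = 0; a < 5; ++a) out[a] = 0; return; }
  const int blk = (pos + 1) / rate;
  for (int a = 0; a < 5; ++a) out[a] = cp[a + 5 * blk];
  for (int i = blk * rate; i <= pos; ++i) ++out[bwt[i]];
}

// Backward extension of a bi-interval by every symbol at once.  Row a of the
// result is the bi-interval [lower, lower_rc, size] of aP given omega(P).
// The reverse-complement lower bounds partition the interval of the reverse
// complement in complement order ($, T, G, C, A).
// [[Rcpp::export]]
IntegerMatrix fmd_ext_all_cpp(IntegerVector bwt, IntegerMatrix cp, int cprate,
                              IntegerVector C, int lower, int lower_rc,
                              int size) {
  int lo[5], hi[5], s[5], l[5], lrc[5];
  occ_all(bwt.begin(), cp.begin(), cprate, lower - 1, lo);
  occ_all(bwt.begin(), cp.begin(), cprate, lower + size - 1, hi);
  for (int a = 0; a < 5; ++a) { s[a] = hi[a] - lo[a]; l[a] = C[a] + lo[a]; }
  lrc[0] = lower_rc;
  lrc[4] = lower_rc + s[0];
  lrc[3] = lrc[4] + s[4];
  lrc[2] = lrc[3] + s[3];
  lrc[1] = lrc[2] + s[2];
  IntegerMatrix out(5, 3);
  for (int a = 0; a < 5; ++a) {
    out(a, 0) = l[a]; out(a, 1) = lrc[a]; out(a, 2) = s[a];
  }
  return out;
}

static inline int lf_step(const int* bwt, const int* cp, int cprate,
                          const int* C, const int* dpos, const int* dlf,
                          int ndollar, int k) {
  const int a = bwt[k];
  if (a == 0) {
    // sentinel in the BWT: use the exact map recorded at build time
    int lo = 0, hi = ndollar - 1;
    while (lo <= hi) {
      int mid = (lo + hi) / 2;
      if (dpos[mid] == k) return dlf[mid];
      if (dpos[mid] < k) lo = mid + 1; else hi = mid - 1;
    }
    return -1;  // unreachable for a consistent index
  }
  int cnt[5];
  occ_all(bwt, cp, cprate, k, cnt);
  return C[a] + cnt[a] - 1;
}

// SA[k] for each rank in `ks`, walking the LF-mapping from the nearest
// rank divisible by r; SA[x] + iter once x is sampled.  rank0 is the rank of
// suffix 0 (its SA value is 0, so the answer there is just `iter`).
// [[Rcpp::export]]
IntegerVector fmd_sa_lookup_cpp(IntegerVector bwt, IntegerMatrix cp, int cprate,
                                IntegerVector C, IntegerVector dollar_pos,
                                IntegerVector dollar_lf, int rank0,
                                IntegerVector sampled, int r,
                                IntegerVector ks) {
  const int m = ks.size(), nd = dollar_pos.size();
  IntegerVector out(m);
  for (int t = 0; t < m; ++t) {
    int k = ks[t], iter = 0;
    while (k % r != 0) {
      if (k == rank0) { k = -1; break; }
      k = lf_step(bwt.begin(), cp.begin(), cprate, C.begin(),
                  dollar_pos.begin(), dollar_lf.begin(), nd, k);
      ++iter;
    }
    out[t] = (k < 0) ? iter : sampled[k / r] + iter;
  }
  return out;
}

// One LF-mapping step per rank, with wrap-around at the rank of suffix 0
// (mapped to the rank of the last suffix) so that LF is a permutation.
// [[Rcpp::export]]
IntegerVector fmd_lf_cpp(IntegerVector bwt, IntegerMatrix cp, int cprate,
                         IntegerVector C, IntegerVector dollar_pos,
                         IntegerVector dollar_lf, int rank0, int rank_last,
                         IntegerVector ks) {
  const int m = ks.size(), nd = dollar_pos.size();
  IntegerVector out(m);
  for (int t = 0; t < m; ++t) {
    int k = ks[t];
    out[t] = (k == rank0)
      ? rank_last
      : lf_step(bwt.begin(), cp.begin(), cprate, C.begin(),
                dollar_pos.begin(), dollar_lf.begin(), nd, k);
  }
  return out;
}

// Depth-first construction of the 4^k-entry k-mer table by backward extension
// over the k-mer trie, pruning empty intervals.  Prepending symbol a to a
// word of length d adds (a-1)*4^d to its 2-bit code.
// [[Rcpp::export]]
List build_lookup_cpp(IntegerVector bwt, IntegerMatrix cp, int cprate,
                      IntegerVector C, int k, int n) {
  R_xlen_t N = 1;
  for (int i = 0; i < k; ++i) N *= 4;
  IntegerVector lo(N), lrc(N), sz(N);
  std::vector<long long> pow4(k + 1, 1);
  for (int i = 1; i <= k; ++i) pow4[i] = pow4[i - 1] * 4;
  struct Node { int lower, lower_rc, size, depth; long long code; };
  std::vector<Node> st;
  st.push_back({0, 0, n, 0, 0});
  int o0[5], o1[5], s[5], lrcv[5];
  while (!st.empty()) {
    Node nd = st.back(); st.pop_back();
    if (nd.depth == k) {
      lo[nd.code] = nd.lower; lrc[nd.code] = nd.lower_rc; sz[nd.code] = nd.size;
      continue;
    }
    occ_all(bwt.begin(), cp.begin(), cprate, nd.lower - 1, o0);
    occ_all(bwt.begin(), cp.begin(), cprate, nd.lower + nd.size - 1, o1);
    for (int a = 0; a < 5; ++a) s[a] = o1[a] - o0[a];
    lrcv[0] = nd.lower_rc;
    lrcv[4] = nd.lower_rc + s[0];
    lrcv[3] = lrcv[4] + s[4];
    lrcv[2] = lrcv[3] + s[3];
    lrcv[1] = lrcv[2] + s[2];
    for (int a = 1; a <= 4; ++a)
      if (s[a] > 0)
        st.push_back({C[a] + o0[a], lrcv[a], s[a], nd.depth + 1,
                      (long long)(a - 1) * pow4[nd.depth] + nd.code});
  }
  return List::create(_["lower"] = lo, _["lower_rc"] = lrc, _["size"] = sz);
}

// Two-sided ungapped X-drop extension from an exact seed.  A direction stops
// once the running score falls more than `xdrop` below its best; the best
// prefix in each direction is kept.  Ambiguous query symbols (code 0)
// mismatch everything.
// [[Rcpp::export]]
List ungapped_xdrop_cpp(IntegerVector q, IntegerVector s, int qpos, int spos,
                        int len, int reward, int penalty, int xdrop) {
  const int nq = q.size(), ns = s.size();
  int best = 0, run = 0, leftLen = 0, leftGain = 0;
  for (int i = qpos - 1, j = spos - 1, ext = 1; i >= 0 && j >= 0;
       --i, --j, ++ext) {
    run += (q[i] >= 1 && q[i] <= 4 && q[i] == s[j]) ? reward : penalty;
    if (run > best) { best = run; leftLen = ext; }
    if (best - run > xdrop) break;
  }
  leftGain = best;
  best = 0; run = 0;
  int rightLen = 0, rightGain = 0;
  for (int i = qpos + len, j = spos + len, ext = 1; i < nq && j < ns;
       ++i, ++j, ++ext) {
    run += (q[i] >= 1 && q[i] <= 4 && q[i] == s[j]) ? reward : penalty;
    if (run > best) { best = run; rightLen = ext; }
    if (best - run > xdrop) break;
  }
  rightGain = best;
  return List::create(_["q_start"] = qpos - leftLen,
                      _["s_start"] = spos - leftLen,
                      _["length"] = leftLen + len + rightLen,
                      _["score"] = len * reward + leftGain + rightGain);
}

// One-directional gapped X-drop extension with affine gaps, starting from the
// empty alignment at (0,0).  Gap of length g costs gopen + g*gext.  Cells
// whose score falls more than xdrop below the best seen are pruned, which
// keeps the explored band narrow.  Traceback recovers identity/mismatch/gap
// counts for the best endpoint.  The caller runs this twice (suffixes for the
// right direction, reversed prefixes for the left).
// [[Rcpp::export]]
List gapped_xdrop_cpp(IntegerVector q, IntegerVector s, int reward,
                      int penalty, int gopen, int gext, int xdrop) {
  const int nq = q.size(), ns = s.size();
  const long long NEG = -1000000000LL;
  std::vector<long long> Hp(ns + 2, NEG), Hc(ns + 2, NEG);
  std::vector<long long> Ec(ns + 2, NEG), Fp(ns + 2, NEG), Fc(ns + 2, NEG);
  std::vector<std::vector<uint8_t> > tb;
  long long best = 0;
  int bi = 0, bj = 0;

  // row 0: leading gap in the query
  tb.push_back(std::vector<uint8_t>(ns + 1, 0));
  Hc[0] = 0;
  int lo = 0, hi = 0;
  for (int j = 1; j <= ns; ++j) {
    long long v = -(long long)gopen - (long long)j * gext;
    if (best - v > xdrop) break;
    Hc[j] = v; Ec[j] = v;
    tb[0][j] = 2 | (j > 1 ? 4 : 0);
    hi = j;
  }

  for (int i = 1; i <= nq; ++i) {
    std::swap(Hp, Hc); std::swap(Fp, Fc);
    const int newlo = lo, newhi = std::min(hi + 1, ns);
    for (int j = std::max(0, newlo - 1); j <= std::min(ns, newhi + 1); ++j) {
      Hc[j] = NEG; Ec[j] = NEG; Fc[j] = NEG;
    }
    tb.push_back(std::vector<uint8_t>(ns + 1, 0));
    int rowlo = -1, rowhi = -1;
    for (int j = newlo; j <= newhi; ++j) {
      long long diag = NEG, e = NEG, f = NEG;
      bool ee_wins = false, fe_wins = false;
      if (j >= 1 && Hp[j - 1] > NEG / 2) {
        const int sub =
          (q[i - 1] >= 1 && q[i - 1] <= 4 && q[i - 1] == s[j - 1])
            ? reward : penalty;
        diag = Hp[j - 1] + sub;
      }
      if (j >= 1) {
        long long eo = Hc[j - 1] > NEG / 2 ? Hc[j - 1] - gopen - gext : NEG;
        long long ee = Ec[j - 1] > NEG / 2 ? Ec[j - 1] - gext : NEG;
        e = std::max(eo, ee);
        ee_wins = (ee >= eo);
      }
      {
        long long fo = Hp[j] > NEG / 2 ? Hp[j] - gopen - gext : NEG;
        long long fe = Fp[j] > NEG / 2 ? Fp[j] - gext : NEG;
        f = std::max(fo, fe);
        fe_wins = (fe >= fo);
      }
      long long h = std::max(diag, std::max(e, f));
      if (h <= NEG / 2 || best - h > xdrop) continue;  // pruned (left NEG)
      Hc[j] = h;
      Ec[j] = (e > NEG / 2 && best - e <= xdrop) ? e : NEG;
      Fc[j] = (f > NEG / 2 && best - f <= xdrop) ? f : NEG;
      uint8_t t = (h == diag) ? 1 : (h == e ? 2 : 3);
      if (ee_wins) t |= 4;
      if (fe_wins) t |= 8;
      tb[i][j] = t;
      if (h > best) { best = h; bi = i; bj = j; }
      if (rowlo < 0) rowlo = j;
      rowhi = j;
    }
    if (rowlo < 0) break;
    lo = rowlo; hi = rowhi;
  }

  // traceback from the best endpoint
  long long nid = 0, nmis = 0, nopen = 0, ngap = 0;
  int i = bi, j = bj, state = 0;  // 0 = H, 1 = E (gap in query), 2 = F
  while (i > 0 || j > 0) {
    const uint8_t t = tb[i][j];
    if (state == 0) {
      const int src = t & 3;
      if (src == 1) {
        if (q[i - 1] >= 1 && q[i - 1] <= 4 && q[i - 1] == s[j - 1]) ++nid;
        else ++nmis;
        --i; --j;
      } else if (src == 2) state = 1;
      else if (src == 3) state = 2;
      else break;
    } else if (state == 1) {
      ++ngap;
      const bool ext = t & 4;
      --j;
      if (!ext) { ++nopen; state = 0; }
    } else {
      ++ngap;
      const bool ext = t & 8;
      --i;
      if (!ext) { ++nopen; state = 0; }
    }
  }
  return List::create(_["score"] = (double)best, _["q_used"] = bi,
                      _["s_used"] = bj, _["nid"] = (double)nid,
                      _["nmis"] = (double)nmis, _["ngapopen"] = (double)nopen,
                      _["ngapletters"] = (double)ngap);
}
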