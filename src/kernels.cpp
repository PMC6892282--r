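// Low-level kernels: 64-bit hashing, k-mer encoding, sketch insertion and
// the synthetic-set streaming used by the benchmark harness.  All 64-bit
// values crossing the R boundary travel as 16-character hex strings; hot
// paths keep them as uint64_t throughout.
#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <string>
#include <vector>
#include <queue>
#include <algorithm>
#include <unordered_set>
using namespace Rcpp;

// ---------------------------------------------------------------- hex I/O

static uint64_t hex_to_u64(const std::string& s) {
  if (s.empty() || s.size() > 16)
    stop("hex64 value must have 1-16 hex digits, got '%s'", s.c_str());
  uint64_t v = 0;
  for (char c : s) {
    int d;
    if (c >= '0' && c <= '9') d = c - '0';
    else if (c >= 'a' && c <= 'f') d = c - 'a' + 10;
    else if (c >= 'A' && c <= 'F') d = c - 'A' + 10;
    else stop("invalid hex digit '%c' in hex64 value", c);
    v = (v << 4) | (uint64_t)d;
  }
  return v;
}

static std::string u64_to_hex(uint64_t v) {
  static const char* digits = "0123456789abcdef";
  std::string s(16, '0');
  for (int i = 15; i >= 0; --i) { s[i] = digits[v & 0xf]; v >>= 4; }
  return s;
}

static std::vector<uint64_t> hex_vec(const CharacterVector& xs) {
  std::vector<uint64_t> out(xs.size());
  for (R_xlen_t i = 0; i < xs.size(); ++i)
    out[i] = hex_to_u64(as<std::string>(xs[i]));
  return out;
}

// ------------------------------------------------------------- Wang hash

static inline uint64_t wang64(uint64_t k) {
  k = ~k + (k << 21);
  k = k ^ (k >> 24);
  k = (k + (k << 3)) + (k << 8);  // * 265
  k = k ^ (k >> 14);
  k = (k + (k << 2)) + (k << 4);  // * 21
  k = k ^ (k >> 28);
  k = k + (k << 31);
  return k;
}

static inline uint64_t inv_xorshift_right(uint64_t y, int s) {
  uint64_t x = y;
  for (int done = 0; done < 64; done += s) x = y ^ (x >> s);
  return x;
}

static inline uint64_t unwang64(uint64_t k) {
  k = k * 0x3fffffff80000001ULL;          // invert k += k << 31
  k = inv_xorshift_right(k, 28);
  k = k * 0xcf3cf3cf3cf3cf3dULL;          // invert * 21
  k = inv_xorshift_right(k, 14);
  k = k * 0xd38ff08b1c03dd39ULL;          // invert * 265
  k = inv_xorshift_right(k, 24);
  k = (k + 1) * 0x7ffffbffffdfffffULL;    // invert ~k + (k << 21)
  return k;
}

// splitmix64 output function: a bijection on 64-bit words, used to turn
// distinct counters into distinct pseudo-random values.
static inline uint64_t mix64(uint64_t z) {
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}
static const uint64_t GOLDEN = 0x9e3779b97f4a7c15ULL;

static inline int lzc_u64(uint64_t x, int q) {
  // leading zeros of x viewed as a q-bit string; requires x < 2^q
  if (x == 0) return q;
  return __builtin_clzll(x) - (64 - q);
}

static inline uint64_t rotl64(uint64_t x, int s) {
  s &= 63;
  return s ? (x << s) | (x >> (64 - s)) : x;
}

// [[Rcpp::export]]
CharacterVector cpp_wang_hash(CharacterVector xs, bool invert) {
  CharacterVector out(xs.size());
  for (R_xlen_t i = 0; i < xs.size(); ++i) {
    uint64_t v = hex_to_u64(as<std::string>(xs[i]));
    out[i] = u64_to_hex(invert ? unwang64(v) : wang64(v));
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_lzc(CharacterVector xs, int q) {
  if (q < 1 || q > 64) stop("width q must be in 1..64");
  IntegerVector out(xs.size());
  for (R_xlen_t i = 0; i < xs.size(); ++i) {
    uint64_t v = hex_to_u64(as<std::string>(xs[i]));
    if (q < 64 && v >= (1ULL << q))
      stop("lzc: value exceeds 2^%d", q);
    out[i] = lzc_u64(v, q);
  }
  return out;
}

// ------------------------------------------------------------ k-mer codes

static inline int base2(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline uint64_t revcomp_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3 - (code & 3));
    code >>= 2;
  }
  return rc;
}

// [[Rcpp::export]]
CharacterVector cpp_encode_kmers(CharacterVector kmers) {
  CharacterVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string w = as<std::string>(kmers[i]);
    if (w.size() < 1 || w.size() > 32)
      stop("k-mer length must be in 1..32, got %d", (int)w.size());
    uint64_t code = 0;
    for (char c : w) {
      int b = base2(c);
      if (b < 0) {
        stop("ambiguous base '%c' in k-mer '%s'", c, w.c_str());
      }
      code = (code << 2) | (uint64_t)b;
    }
    out[i] = u64_to_hex(code);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_decode_kmers(CharacterVector codes, int k) {
  static const char* b = "ACGT";
  CharacterVector out(codes.size());
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    uint64_t code = hex_to_u64(as<std::string>(codes[i]));
    std::string w(k, 'A');
    for (int j = k - 1; j >= 0; --j) { w[j] = b[code & 3]; code >>= 2; }
    out[i] = w;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp_codes(CharacterVector codes, int k) {
  CharacterVector out(codes.size());
  for (R_xlen_t i = 0; i < codes.size(); ++i)
    out[i] = u64_to_hex(revcomp_code(hex_to_u64(as<std::string>(codes[i])), k));
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_canonical_codes(CharacterVector codes, int k) {
  CharacterVector out(codes.size());
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    uint64_t c = hex_to_u64(as<std::string>(codes[i]));
    out[i] = u64_to_hex(std::min(c, revcomp_code(c, k)));
  }
  return out;
}

// Window iteration: emits one canonical code per k-window over ACGT
// stretches; any other character aborts the window, which restarts after it.
template <class F>
static void for_kmers(const char* s, size_t n, int k, bool canonical, F f) {
  uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  uint64_t code = 0, rc = 0;
  int len = 0;
  for (size_t i = 0; i < n; ++i) {
    int b = base2(s[i]);
    if (b < 0) { len = 0; code = 0; rc = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    if (++len >= k) f(canonical ? std::min(code, rc) : code);
  }
}

// [[Rcpp::export]]
CharacterVector cpp_seq_kmer_codes(std::string seq, int k, bool canonical) {
  std::vector<uint64_t> codes;
  for_kmers(seq.c_str(), seq.size(), k, canonical,
            [&](uint64_t c) { codes.push_back(c); });
  CharacterVector out(codes.size());
  for (size_t i = 0; i < codes.size(); ++i) out[i] = u64_to_hex(codes[i]);
  return out;
}

// --------------------------------------------------------------- HLL core

static inline void hll_ins(uint8_t* regs, int p, uint64_t h) {
  int q = 64 - p;
  uint64_t idx = h >> q;
  uint64_t suf = h & ((q == 64) ? ~0ULL : ((1ULL << q) - 1));
  uint8_t rho = (uint8_t)(lzc_u64(suf, q) + 1);
  if (rho > regs[idx]) regs[idx] = rho;
}

// [[Rcpp::export]]
RawVector cpp_hll_insert(RawVector regs, int p, CharacterVector hashes) {
  RawVector out = clone(regs);
  uint8_t* r = (uint8_t*)RAW(out);
  for (R_xlen_t i = 0; i < hashes.size(); ++i)
    hll_ins(r, p, hex_to_u64(as<std::string>(hashes[i])));
  return out;
}

// [[Rcpp::export]]
RawVector cpp_raw_max(RawVector a, RawVector b) {
  if (a.size() != b.size()) stop("register arrays differ in length");
  RawVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i)
    out[i] = a[i] > b[i] ? a[i] : b[i];
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_reg_hist(RawVector regs, int q) {
  IntegerVector h(q + 2);
  for (R_xlen_t i = 0; i < regs.size(); ++i) {
    int v = (int)regs[i];
    if (v > q + 1) stop("register value %d exceeds q+1 = %d", v, q + 1);
    h[v]++;
  }
  return h;
}

// [[Rcpp::export]]
IntegerMatrix cpp_joint_tally(RawVector a, RawVector b, int q) {
  if (a.size() != b.size()) stop("register arrays differ in length");
  IntegerMatrix t(q + 2, q + 2);
  for (R_xlen_t i = 0; i < a.size(); ++i)
    t((int)a[i], (int)b[i])++;
  return t;
}

// ------------------------------------------------------- bottom-k MinHash

struct BKBuild {
  size_t s;
  uint64_t threshold;                   // current greatest kept value once full
  std::priority_queue<uint64_t> heap;   // max-heap over kept values
  std::unordered_set<uint64_t> mem;     // kept values, for set semantics
  explicit BKBuild(size_t cap) : s(cap), threshold(UINT64_MAX) {}
  inline void add(uint64_t h) {
    if (h >= threshold) return;         // single-compare fast path
    if (mem.count(h)) return;
    if (heap.size() < s) {
      heap.push(h); mem.insert(h);
      if (heap.size() == s) threshold = heap.top();
    } else {
      mem.erase(heap.top()); heap.pop();
      heap.push(h); mem.insert(h);
      threshold = heap.top();
    }
  }
  RawVector dump() const {
    std::vector<uint64_t> v(mem.begin(), mem.end());
    std::sort(v.begin(), v.end());
    RawVector out(8 * v.size());
    if (!v.empty()) std::memcpy(RAW(out), v.data(), 8 * v.size());
    return out;
  }
};

static std::vector<uint64_t> bk_values(const RawVector& r) {
  std::vector<uint64_t> v(r.size() / 8);
  if (!v.empty()) std::memcpy(v.data(), RAW(r), 8 * v.size());
  return v;
}

// [[Rcpp::export]]
RawVector cpp_bk_insert(RawVector values, int s, CharacterVector hashes) {
  BKBuild bk((size_t)s);
  for (uint64_t v : bk_values(values)) bk.add(v);
  for (R_xlen_t i = 0; i < hashes.size(); ++i)
    bk.add(hex_to_u64(as<std::string>(hashes[i])));
  return bk.dump();
}

// [[Rcpp::export]]
RawVector cpp_bk_union(RawVector a, RawVector b, int s) {
  std::vector<uint64_t> va = bk_values(a), vb = bk_values(b), u;
  std::set_union(va.begin(), va.end(), vb.begin(), vb.end(),
                 std::back_inserter(u));
  if (u.size() > (size_t)s) u.resize(s);
  RawVector out(8 * u.size());
  if (!u.empty()) std::memcpy(RAW(out), u.data(), 8 * u.size());
  return out;
}

// Bottom-s of the union, counting how many of those values occur in both
// sketches; the bottom-k Jaccard estimate is shared / |X|.
// [[Rcpp::export]]
List cpp_bk_compare(RawVector a, RawVector b, int s) {
  std::vector<uint64_t> va = bk_values(a), vb = bk_values(b);
  size_t ia = 0, ib = 0, nx = 0, shared = 0;
  while (nx < (size_t)s && (ia < va.size() || ib < vb.size())) {
    uint64_t next;
    bool both = false;
    if (ia < va.size() && ib < vb.size()) {
      if (va[ia] == vb[ib]) { next = va[ia]; both = true; ++ia; ++ib; }
      else if (va[ia] < vb[ib]) next = va[ia++];
      else next = vb[ib++];
    } else if (ia < va.size()) next = va[ia++];
    else next = vb[ib++];
    (void)next;
    ++nx;
    if (both) ++shared;
  }
  return List::create(_["x_size"] = (double)nx, _["shared"] = (double)shared);
}

// Classic bottom-k cardinality estimator: if the sketch is full, the s-th
// smallest of n uniform 64-bit hashes is ~ s/(n+1) of the range, giving
// n ~ (s - 1) * 2^64 / v_s; an unfilled sketch holds the whole set.
// [[Rcpp::export]]
double cpp_bk_cardinality(RawVector values, int s) {
  std::vector<uint64_t> v = bk_values(values);
  if ((int)v.size() < s) return (double)v.size();
  return (double)(s - 1) * 18446744073709551616.0 / (double)v.back();
}

// [[Rcpp::export]]
CharacterVector cpp_bk_values_hex(RawVector values) {
  std::vector<uint64_t> v = bk_values(values);
  CharacterVector out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = u64_to_hex(v[i]);
  return out;
}

// ------------------------------------------------------------ Bloom filter

// h index derivations from one 64-bit hash: block-rotated variants.
static inline uint64_t bloom_idx(uint64_t H, int i, int h, int b) {
  return rotl64(H, i * (64 / h)) & ((1ULL << b) - 1);
}

// [[Rcpp::export]]
RawVector cpp_bloom_insert(RawVector bits, int b, int h, CharacterVector hashes) {
  RawVector out = clone(bits);
  uint8_t* bt = (uint8_t*)RAW(out);
  for (R_xlen_t i = 0; i < hashes.size(); ++i) {
    uint64_t H = hex_to_u64(as<std::string>(hashes[i]));
    for (int j = 0; j < h; ++j) {
      uint64_t idx = bloom_idx(H, j, h, b);
      bt[idx >> 3] |= (uint8_t)(1u << (idx & 7));
    }
  }
  return out;
}

// [[Rcpp::export]]
double cpp_popcount(RawVector bits) {
  double n = 0;
  for (R_xlen_t i = 0; i < bits.size(); ++i)
    n += __builtin_popcount((unsigned)bits[i]);
  return n;
}

// [[Rcpp::export]]
RawVector cpp_raw_or(RawVector a, RawVector b) {
  if (a.size() != b.size()) stop("bit arrays differ in length");
  RawVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i)
    out[i] = (Rbyte)(a[i] | b[i]);
  return out;
}

// --------------------------------------------------------- count-min sketch

static inline uint64_t cms_idx(uint64_t H, int row, uint64_t wmask) {
  return mix64(H + (uint64_t)(row + 1) * GOLDEN) & wmask;
}

// Conservative update: only rows at the current minimum are incremented.
// Returns list(counters = updated matrix, counts = estimate after each add).
// [[Rcpp::export]]
List cpp_cms_add(IntegerMatrix counters, CharacterVector keys) {
  IntegerMatrix cnt = clone(counters);
  int d = cnt.nrow(), w = cnt.ncol();
  if (w & (w - 1)) stop("count-min width must be a power of two");
  uint64_t wmask = (uint64_t)w - 1;
  IntegerVector est(keys.size());
  std::vector<int> idx(d);
  for (R_xlen_t i = 0; i < keys.size(); ++i) {
    uint64_t H = hex_to_u64(as<std::string>(keys[i]));
    int mn = INT_MAX;
    for (int r = 0; r < d; ++r) {
      idx[r] = (int)cms_idx(H, r, wmask);
      mn = std::min(mn, cnt(r, idx[r]));
    }
    int nv = (mn == INT_MAX - 0) ? mn : mn + 1;
    if (mn >= INT_MAX) nv = INT_MAX;  // saturate, never wrap
    for (int r = 0; r < d; ++r)
      if (cnt(r, idx[r]) == mn) cnt(r, idx[r]) = nv;
    est[i] = nv;
  }
  return List::create(_["counters"] = cnt, _["counts"] = est);
}

// ----------------------------------------------- sequence sketching paths

struct CMSCore {
  int d, log2w;
  uint64_t wmask;
  std::vector<uint32_t> cnt;
  CMSCore(int d_, int log2w_) : d(d_), log2w(log2w_),
    wmask((1ULL << log2w_) - 1), cnt((size_t)d_ << log2w_, 0) {}
  inline uint32_t add(uint64_t H) {
    uint32_t mn = UINT32_MAX;
    size_t base = 0;
    size_t idx[8];
    for (int r = 0; r < d; ++r, base += (size_t)1 << log2w) {
      idx[r] = base + (size_t)cms_idx(H, r, wmask);
      mn = std::min(mn, cnt[idx[r]]);
    }
    uint32_t nv = (mn == UINT32_MAX) ? mn : mn + 1;
    for (int r = 0; r < d; ++r)
      if (cnt[idx[r]] == mn) cnt[idx[r]] = nv;
    return nv;
  }
};

template <class F>
static void stream_file_kmers(const CharacterVector& seqs, int k, bool canonical,
                              int min_count, int cms_rows, int cms_log2w, F emit) {
  if (min_count > 1) {
    CMSCore cms(cms_rows, cms_log2w);
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
      const char* s = CHAR(STRING_ELT(seqs, i));
      for_kmers(s, std::strlen(s), k, canonical, [&](uint64_t c) {
        uint64_t H = wang64(c);
        if ((int)cms.add(H) >= min_count) emit(H);
      });
    }
  } else {
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
      const char* s = CHAR(STRING_ELT(seqs, i));
      for_kmers(s, std::strlen(s), k, canonical,
                [&](uint64_t c) { emit(wang64(c)); });
    }
  }
}

// [[Rcpp::export]]
RawVector cpp_sketch_seqs_hll(CharacterVector seqs, int k, bool canonical, int p,
                              int min_count, int cms_rows, int cms_log2w) {
  RawVector regs((R_xlen_t)1 << p);
  uint8_t* r = (uint8_t*)RAW(regs);
  stream_file_kmers(seqs, k, canonical, min_count, cms_rows, cms_log2w,
                    [&](uint64_t H) { hll_ins(r, p, H); });
  return regs;
}

// [[Rcpp::export]]
RawVector cpp_sketch_seqs_bk(CharacterVector seqs, int k, bool canonical, int s,
                             int min_count, int cms_rows, int cms_log2w) {
  BKBuild bk((size_t)s);
  stream_file_kmers(seqs, k, canonical, min_count, cms_rows, cms_log2w,
                    [&](uint64_t H) { bk.add(H); });
  return bk.dump();
}

// [[Rcpp::export]]
RawVector cpp_sketch_seqs_bloom(CharacterVector seqs, int k, bool canonical,
                                int b, int h, int min_count, int cms_rows,
                                int cms_log2w) {
  RawVector bits((R_xlen_t)1 << (b - 3));
  uint8_t* bt = (uint8_t*)RAW(bits);
  stream_file_kmers(seqs, k, canonical, min_count, cms_rows, cms_log2w,
                    [&](uint64_t H) {
                      for (int j = 0; j < h; ++j) {
                        uint64_t idx = bloom_idx(H, j, h, b);
                        bt[idx >> 3] |= (uint8_t)(1u << (idx & 7));
                      }
                    });
  return bits;
}

// Exact hash-set mode: canonical k-mer codes of both inputs, no sketching.
// [[Rcpp::export]]
NumericVector cpp_exact_pair_seqs(CharacterVector seqs_a, CharacterVector seqs_b,
                                  int k, bool canonical) {
  std::unordered_set<uint64_t> A, B;
  for (R_xlen_t i = 0; i < seqs_a.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs_a, i));
    for_kmers(s, std::strlen(s), k, canonical, [&](uint64_t c) { A.insert(c); });
  }
  for (R_xlen_t i = 0; i < seqs_b.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs_b, i));
    for_kmers(s, std::strlen(s), k, canonical, [&](uint64_t c) { B.insert(c); });
  }
  double inter = 0;
  for (uint64_t x : A) inter += B.count(x);
  double na = (double)A.size(), nb = (double)B.size();
  return NumericVector::create(na, nb, na + nb - inter, inter);
}

// ------------------------------------------- synthetic-set stream kernels

static inline uint64_t seed_base(double seed1, double seed2) {
  return mix64(mix64((uint64_t)seed1 + GOLDEN) ^ (uint64_t)seed2);
}

// Pair of random 64-bit sets with exact cardinalities and intersection:
// values are splitmix64 images of disjoint counter blocks (a bijection, so
// all values are distinct): shared block [0,i), A-only [i,na), B-only
// [na, na+nb-i).
// [[Rcpp::export]]
List cpp_make_set_pair(double na_, double nb_, double ni_, double seed1,
                       double seed2) {
  size_t na = (size_t)na_, nb = (size_t)nb_, ni = (size_t)ni_;
  uint64_t base = seed_base(seed1, seed2);
  CharacterVector a(na), b(nb);
  for (size_t j = 0; j < na; ++j)
    a[j] = u64_to_hex(mix64(base + (uint64_t)j * GOLDEN));
  for (size_t j = 0; j < ni; ++j) b[j] = a[j];
  for (size_t j = ni; j < nb; ++j)
    b[j] = u64_to_hex(mix64(base + (uint64_t)(na + j - ni) * GOLDEN));
  return List::create(_["a"] = a, _["b"] = b);
}

// One benchmark trial: stream the pair through the Wang-hash insert path of
// an HLL per prefix width in `ps` and a bottom-k per capacity in `ss`,
// for both sets, without materializing the sets.
// [[Rcpp::export]]
List cpp_pair_trial(double na_, double nb_, double ni_, double seed1,
                    double seed2, IntegerVector ps, IntegerVector ss) {
  size_t na = (size_t)na_, nb = (size_t)nb_, ni = (size_t)ni_;
  size_t ntot = na + nb - ni;
  uint64_t base = seed_base(seed1, seed2);

  int np = ps.size(), ns = ss.size();
  std::vector<RawVector> ha, hb;
  std::vector<uint8_t*> pa(np), pb(np);
  for (int i = 0; i < np; ++i) {
    ha.push_back(RawVector((R_xlen_t)1 << ps[i]));
    hb.push_back(RawVector((R_xlen_t)1 << ps[i]));
  }
  for (int i = 0; i < np; ++i) {
    pa[i] = (uint8_t*)RAW(ha[i]);
    pb[i] = (uint8_t*)RAW(hb[i]);
  }
  std::vector<BKBuild> ba, bb;
  for (int i = 0; i < ns; ++i) { ba.emplace_back(ss[i]); bb.emplace_back(ss[i]); }

  for (size_t j = 0; j < ntot; ++j) {
    uint64_t H = wang64(mix64(base + (uint64_t)j * GOLDEN));
    bool inA = j < na, inB = j < ni || j >= na;
    if (inA) {
      for (int i = 0; i < np; ++i) hll_ins(pa[i], ps[i], H);
      for (int i = 0; i < ns; ++i) ba[i].add(H);
    }
    if (inB) {
      for (int i = 0; i < np; ++i) hll_ins(pb[i], ps[i], H);
      for (int i = 0; i < ns; ++i) bb[i].add(H);
    }
  }
  List la(np), lb(np), ka(ns), kb(ns);
  for (int i = 0; i < np; ++i) { la[i] = ha[i]; lb[i] = hb[i]; }
  for (int i = 0; i < ns; ++i) { ka[i] = ba[i].dump(); kb[i] = bb[i].dump(); }
  return List::create(_["hll_a"] = la, _["hll_b"] = lb,
                      _["bk_a"] = ka, _["bk_b"] = kb);
}

// HLL sketch of n distinct random 64-bit values fed through the Wang hash.
// [[Rcpp::export]]
RawVector cpp_random_hll(double n_, double seed1, double seed2, int p) {
  size_t n = (size_t)n_;
  uint64_t base = seed_base(seed1, seed2);
  RawVector regs((R_xlen_t)1 << p);
  uint8_t* r = (uint8_t*)RAW(regs);
  for (size_t j = 0; j < n; ++j)
    hll_ins(r, p, wang64(mix64(base + (uint64_t)j * GOLDEN)));
  return regs;
}
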