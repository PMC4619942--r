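// Core bit-level machinery: 2-bit DNA codec, strand-folded hashing,
// spaced-seed Bloom filter, cascading counting Bloom filter, and the
// 1.4.3.-2 minifloat counter. R-facing orchestration lives in R/.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <cstring>

using namespace Rcpp;
typedef uint64_t u64;
typedef uint8_t u8;

// ---------------------------------------------------------------------------
// 2-bit codec: A=00, C=01, G=10, T=11 (MSB-first within each byte).
// Complement is the bitwise NOT restricted to 2 bits: A<->T, C<->G.
// ---------------------------------------------------------------------------

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static const char CODE_CHARS[4] = {'A', 'C', 'G', 'T'};

// Pack codes (already validated, values 0..3) MSB-first, 4 bases/byte,
// trailing bits zero.
static std::vector<u8> pack_codes(const int *codes, int n) {
  std::vector<u8> out((n + 3) / 4, 0);
  for (int i = 0; i < n; ++i)
    out[i >> 2] |= (u8)(codes[i] << (6 - 2 * (i & 3)));
  return out;
}

static std::vector<int> str_codes(const std::string &s, bool strict) {
  std::vector<int> codes(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int c = base_code(s[i]);
    if (c < 0 && strict)
      stop("non-ACGT character '%c' at position %d", s[i], (int)(i + 1));
    codes[i] = c;
  }
  return codes;
}

// [[Rcpp::export]]
RawVector cpp_pack(std::string s) {
  std::vector<int> codes = str_codes(s, true);
  std::vector<u8> bytes = pack_codes(codes.data(), (int)codes.size());
  RawVector out(bytes.size());
  std::copy(bytes.begin(), bytes.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
std::string cpp_unpack(RawVector bytes, int len) {
  if (len < 0 || (len + 3) / 4 > (int)bytes.size())
    stop("declared length does not fit the payload");
  std::string out(len, 'A');
  for (int i = 0; i < len; ++i) {
    int code = (bytes[i >> 2] >> (6 - 2 * (i & 3))) & 3;
    out[i] = CODE_CHARS[code];
  }
  return out;
}

// [[Rcpp::export]]
std::string cpp_revcomp_str(std::string s) {
  std::string out(s.size(), 'A');
  size_t n = s.size();
  for (size_t i = 0; i < n; ++i) {
    int c = base_code(s[n - 1 - i]);
    if (c < 0) stop("non-ACGT character in revcomp");
    out[i] = CODE_CHARS[3 - c];  // 2-bit bitwise NOT
  }
  return out;
}

// Lexicographic order of the 2-bit codes coincides with A<C<G<T.
// [[Rcpp::export]]
std::string cpp_canonical_str(std::string s) {
  std::string rc = cpp_revcomp_str(s);
  return (rc < s) ? rc : s;
}

// XOR fold: packed(x) XOR packed(revcomp(x)); strand-invariant by symmetry.
static std::vector<u8> fold_codes(const int *codes, int n) {
  std::vector<int> rc(n);
  for (int i = 0; i < n; ++i) rc[i] = 3 - codes[n - 1 - i];
  std::vector<u8> a = pack_codes(codes, n);
  std::vector<u8> b = pack_codes(rc.data(), n);
  for (size_t i = 0; i < a.size(); ++i) a[i] ^= b[i];
  return a;
}

// [[Rcpp::export]]
RawVector cpp_fold(std::string s) {
  std::vector<int> codes = str_codes(s, true);
  std::vector<u8> f = fold_codes(codes.data(), (int)codes.size());
  RawVector out(f.size());
  std::copy(f.begin(), f.end(), out.begin());
  return out;
}

// ---------------------------------------------------------------------------
// 64-bit hashing: FNV-1a accumulation + splitmix64 avalanche finalizer,
// salted. Deterministic and platform-independent.
// ---------------------------------------------------------------------------

static inline u64 splitmix64(u64 x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static u64 base_hash_u64(const u8 *p, size_t n, u64 salt) {
  u64 h = 0xcbf29ce484222325ULL ^ splitmix64(salt);
  for (size_t i = 0; i < n; ++i) {
    h ^= (u64)p[i];
    h *= 0x100000001b3ULL;
  }
  return splitmix64(h);
}

// Module-fixed salts: one for the folded quadruple, one (distinct) for the
// strand-sensitive pair used by the cascade's byte array.
static const u64 SEED_SALT = 0x5345454453414C54ULL;
static const u64 STRAND_SALT = 0x5354524E44484153ULL;

static std::string u64_hex(u64 x) {
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)x);
  return std::string(buf);
}

// [[Rcpp::export]]
std::string cpp_base_hash(RawVector data, double salt) {
  return u64_hex(base_hash_u64(data.length() ? &data[0] : (u8 *)"",
                               data.length(), (u64)salt));
}

// Avalanche diagnostic: hash random byte strings, flip one random bit,
// count flipped output bits. Uses the R RNG.
// [[Rcpp::export]]
IntegerVector cpp_avalanche(int trials, int nbytes) {
  IntegerVector out(trials);
  std::vector<u8> buf(nbytes);
  for (int t = 0; t < trials; ++t) {
    for (int i = 0; i < nbytes; ++i) buf[i] = (u8)(unif_rand() * 256);
    u64 h1 = base_hash_u64(buf.data(), nbytes, SEED_SALT);
    int bit = (int)(unif_rand() * (8 * nbytes));
    buf[bit >> 3] ^= (u8)(1 << (bit & 7));
    u64 h2 = base_hash_u64(buf.data(), nbytes, SEED_SALT);
    u64 d = h1 ^ h2;
    int pop = 0;
    while (d) { pop += (int)(d & 1); d >>= 1; }
    out[t] = pop;
  }
  return out;
}

// The four strand-folded hash values for a 2k-string: left and right k-mer
// folds, odd- and even-position folds. Under reverse complementation the
// (L,R) pair and the (O,E) pair each swap.
static void seed_hashes_u64(const int *codes, int k, u64 out[4]) {
  std::vector<int> sub(k);
  // left: positions 1..k
  std::vector<u8> f = fold_codes(codes, k);
  out[0] = base_hash_u64(f.data(), f.size(), SEED_SALT);
  // right: positions k+1..2k
  f = fold_codes(codes + k, k);
  out[1] = base_hash_u64(f.data(), f.size(), SEED_SALT);
  // odd: positions 1,3,...,2k-1
  for (int i = 0; i < k; ++i) sub[i] = codes[2 * i];
  f = fold_codes(sub.data(), k);
  out[2] = base_hash_u64(f.data(), f.size(), SEED_SALT);
  // even: positions 2,4,...,2k
  for (int i = 0; i < k; ++i) sub[i] = codes[2 * i + 1];
  f = fold_codes(sub.data(), k);
  out[3] = base_hash_u64(f.data(), f.size(), SEED_SALT);
}

static void strand_pair_u64(const int *codes, int n, u64 &hF, u64 &hR) {
  std::vector<u8> pf = pack_codes(codes, n);
  hF = base_hash_u64(pf.data(), pf.size(), STRAND_SALT);
  std::vector<int> rc(n);
  for (int i = 0; i < n; ++i) rc[i] = 3 - codes[n - 1 - i];
  std::vector<u8> pr = pack_codes(rc.data(), n);
  hR = base_hash_u64(pr.data(), pr.size(), STRAND_SALT);
}

// [[Rcpp::export]]
CharacterVector cpp_seed_hashes(std::string s2k, int k) {
  if ((int)s2k.size() != 2 * k)
    stop("s2k must have length 2k (got %d, expected %d)", (int)s2k.size(), 2 * k);
  std::vector<int> codes = str_codes(s2k, true);
  u64 h[4];
  seed_hashes_u64(codes.data(), k, h);
  CharacterVector out = CharacterVector::create(
    u64_hex(h[0]), u64_hex(h[1]), u64_hex(h[2]), u64_hex(h[3]));
  out.names() = CharacterVector::create("xL", "xR", "xO", "xE");
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_strand_hash_pair(std::string s2k) {
  std::vector<int> codes = str_codes(s2k, true);
  u64 hF, hR;
  strand_pair_u64(codes.data(), (int)codes.size(), hF, hR);
  CharacterVector out = CharacterVector::create(u64_hex(hF), u64_hex(hR));
  out.names() = CharacterVector::create("hF", "hR");
  return out;
}

// ---------------------------------------------------------------------------
// Spaced-seed window extraction over a read.
// ---------------------------------------------------------------------------

// Windows whose seed (non-gap) positions contain a non-ACGT base are skipped;
// gap bases are unconstrained because they are never stored.
struct SeedWindows {
  std::vector<int> origin;                 // 0-based
  std::vector<std::vector<int> > codes;    // 2k codes per window
};

static SeedWindows extract_windows(const std::string &read, int k, int delta) {
  SeedWindows w;
  int span = 2 * k + delta;
  int L = (int)read.size();
  if (L < span) return w;
  std::vector<int> codes = str_codes(read, false);
  // prefix of valid-run lengths for fast window validity
  for (int o = 0; o + span <= L; ++o) {
    std::vector<int> s2k(2 * k);
    bool ok = true;
    for (int i = 0; i < k && ok; ++i) {
      s2k[i] = codes[o + i];
      s2k[k + i] = codes[o + k + delta + i];
      if (s2k[i] < 0 || s2k[k + i] < 0) ok = false;
    }
    if (!ok) continue;
    w.origin.push_back(o);
    w.codes.push_back(std::move(s2k));
  }
  return w;
}

static std::string codes_str(const std::vector<int> &codes) {
  std::string s(codes.size(), 'A');
  for (size_t i = 0; i < codes.size(); ++i) s[i] = CODE_CHARS[codes[i]];
  return s;
}

// [[Rcpp::export]]
List cpp_extract_seeds(std::string read, int k, int delta) {
  SeedWindows w = extract_windows(read, k, delta);
  CharacterVector seeds(w.origin.size());
  IntegerVector origin(w.origin.size());
  for (size_t i = 0; i < w.origin.size(); ++i) {
    origin[i] = w.origin[i];
    seeds[i] = codes_str(w.codes[i]);
  }
  return List::create(_["origin"] = origin, _["s2k"] = seeds);
}

// ---------------------------------------------------------------------------
// Spaced-seed Bloom filter: m bits, the four folded hash values of a seed
// serve as the h = 4 hash functions. Strand-canonical by construction.
// ---------------------------------------------------------------------------

struct SeedBloom {
  std::vector<u64> bits;
  u64 m;
  int k, delta;
  u64 n_inserted;
  SeedBloom(u64 m_, int k_, int d_) : bits((m_ + 63) / 64, 0), m(m_), k(k_),
    delta(d_), n_inserted(0) {}
  bool get(u64 pos) const { return (bits[pos >> 6] >> (pos & 63)) & 1; }
  void set(u64 pos) { bits[pos >> 6] |= (1ULL << (pos & 63)); }
  // returns pre-insert hit pattern
  void insert(const int *codes, bool hit[4]) {
    u64 h[4];
    seed_hashes_u64(codes, k, h);
    for (int i = 0; i < 4; ++i) {
      u64 pos = h[i] % m;
      hit[i] = get(pos);
      set(pos);
    }
    ++n_inserted;
  }
  void query(const int *codes, bool hit[4]) const {
    u64 h[4];
    seed_hashes_u64(codes, k, h);
    for (int i = 0; i < 4; ++i) hit[i] = get(h[i] % m);
  }
};

static SeedBloom *bloom_ptr(SEXP xp) {
  XPtr<SeedBloom> p(xp);
  return p.get();
}

// [[Rcpp::export]]
SEXP cpp_bloom_new(double m, int k, int delta) {
  if (m < 1) stop("filter size m must be positive");
  if (k < 1 || delta < 0) stop("invalid seed template");
  XPtr<SeedBloom> p(new SeedBloom((u64)m, k, delta), true);
  return p;
}

// [[Rcpp::export]]
List cpp_bloom_params(SEXP xp) {
  SeedBloom *b = bloom_ptr(xp);
  u64 set = 0;
  for (size_t i = 0; i < b->bits.size(); ++i) {
    u64 w = b->bits[i];
    while (w) { set += w & 1; w >>= 1; }
  }
  return List::create(_["m"] = (double)b->m, _["k"] = b->k,
                      _["delta"] = b->delta,
                      _["n_inserted"] = (double)b->n_inserted,
                      _["bits_set"] = (double)set);
}

static std::vector<int> s2k_codes_checked(const std::string &s, int k) {
  if ((int)s.size() != 2 * k)
    stop("seed length %d does not match 2k = %d", (int)s.size(), 2 * k);
  return str_codes(s, true);
}

// [[Rcpp::export]]
LogicalMatrix cpp_bloom_insert(SEXP xp, CharacterVector seeds) {
  SeedBloom *b = bloom_ptr(xp);
  LogicalMatrix out(seeds.size(), 4);
  bool hit[4];
  for (int i = 0; i < seeds.size(); ++i) {
    std::vector<int> codes = s2k_codes_checked(as<std::string>(seeds[i]), b->k);
    b->insert(codes.data(), hit);
    for (int j = 0; j < 4; ++j) out(i, j) = hit[j];
  }
  colnames(out) = CharacterVector::create("xL", "xR", "xO", "xE");
  return out;
}

// [[Rcpp::export]]
LogicalMatrix cpp_bloom_query(SEXP xp, CharacterVector seeds) {
  SeedBloom *b = bloom_ptr(xp);
  LogicalMatrix out(seeds.size(), 4);
  bool hit[4];
  for (int i = 0; i < seeds.size(); ++i) {
    std::vector<int> codes = s2k_codes_checked(as<std::string>(seeds[i]), b->k);
    b->query(codes.data(), hit);
    for (int j = 0; j < 4; ++j) out(i, j) = hit[j];
  }
  colnames(out) = CharacterVector::create("xL", "xR", "xO", "xE");
  return out;
}

// [[Rcpp::export]]
List cpp_bloom_insert_read(SEXP xp, std::string read) {
  SeedBloom *b = bloom_ptr(xp);
  SeedWindows w = extract_windows(read, b->k, b->delta);
  int n = (int)w.origin.size();
  LogicalMatrix pre(n, 4);
  IntegerVector origin(n);
  bool hit[4];
  for (int i = 0; i < n; ++i) {
    origin[i] = w.origin[i];
    b->insert(w.codes[i].data(), hit);
    for (int j = 0; j < 4; ++j) pre(i, j) = hit[j];
  }
  colnames(pre) = CharacterVector::create("xL", "xR", "xO", "xE");
  return List::create(_["origin"] = origin, _["pre"] = pre);
}

// [[Rcpp::export]]
List cpp_bloom_query_read(SEXP xp, std::string read) {
  SeedBloom *b = bloom_ptr(xp);
  SeedWindows w = extract_windows(read, b->k, b->delta);
  int n = (int)w.origin.size();
  LogicalMatrix hits(n, 4);
  IntegerVector origin(n);
  bool hit[4];
  for (int i = 0; i < n; ++i) {
    origin[i] = w.origin[i];
    b->query(w.codes[i].data(), hit);
    for (int j = 0; j < 4; ++j) hits(i, j) = hit[j];
  }
  colnames(hits) = CharacterVector::create("xL", "xR", "xO", "xE");
  return List::create(_["origin"] = origin, _["hits"] = hits);
}

// For contig extension: `tail` is the last span-1 assembled bases; test the
// four 1-base extensions for full spaced-seed membership at scale 2k+delta.
// [[Rcpp::export]]
LogicalVector cpp_bloom_next(SEXP xp, std::string tail) {
  SeedBloom *b = bloom_ptr(xp);
  int span = 2 * b->k + b->delta;
  if ((int)tail.size() != span - 1)
    stop("tail must have length span-1 = %d", span - 1);
  std::vector<int> codes = str_codes(tail, true);
  codes.push_back(0);
  LogicalVector out(4);
  int k = b->k, delta = b->delta;
  std::vector<int> s2k(2 * k);
  for (int base = 0; base < 4; ++base) {
    codes[span - 1] = base;
    for (int i = 0; i < k; ++i) {
      s2k[i] = codes[i];
      s2k[k + i] = codes[k + delta + i];
    }
    bool hit[4];
    b->query(s2k.data(), hit);
    out[base] = hit[0] && hit[1] && hit[2] && hit[3];
  }
  out.names() = CharacterVector::create("A", "C", "G", "T");
  return out;
}

// Single-scale sub-query: probe a lone k-mer's folded hash against the same
// bit array (one hash value => elevated false positive rate).
// [[Rcpp::export]]
bool cpp_bloom_kmer_query(SEXP xp, std::string kmer) {
  SeedBloom *b = bloom_ptr(xp);
  if ((int)kmer.size() != b->k) stop("k-mer length must equal k");
  std::vector<int> codes = str_codes(kmer, true);
  std::vector<u8> f = fold_codes(codes.data(), (int)codes.size());
  u64 h = base_hash_u64(f.data(), f.size(), SEED_SALT);
  return b->get(h % b->m);
}

// [[Rcpp::export]]
RawVector cpp_bloom_bits(SEXP xp) {
  SeedBloom *b = bloom_ptr(xp);
  size_t nbytes = (size_t)((b->m + 7) / 8);
  RawVector out(nbytes);
  for (size_t i = 0; i < nbytes; ++i)
    out[i] = (u8)((b->bits[i >> 3] >> (8 * (i & 7))) & 0xFF);
  return out;
}

// [[Rcpp::export]]
SEXP cpp_bloom_from_bits(double m, int k, int delta, double n_inserted,
                         RawVector bytes) {
  XPtr<SeedBloom> p(new SeedBloom((u64)m, k, delta), true);
  size_t nbytes = (size_t)(((u64)m + 7) / 8);
  if (bytes.size() != (R_xlen_t)nbytes) stop("payload size mismatch");
  for (size_t i = 0; i < nbytes; ++i)
    p->bits[i >> 3] |= ((u64)bytes[i]) << (8 * (i & 7));
  p->n_inserted = (u64)n_inserted;
  return p;
}

// ---------------------------------------------------------------------------
// Minifloat 1.4.3.-2 counter: 1 sign bit (strand flag; -0 = collision flag),
// 4 exponent bits (top value 1111 reserved, never produced), 3 mantissa bits,
// exponent bias -2. Subnormal (e=0): value = t. Normalized: (1 + t/8)*2^(e+2).
// ---------------------------------------------------------------------------

static const double MF_MAX = 122880.0;  // e=1110, t=111

static inline int mf_e(int b) { return (b >> 3) & 0xF; }
static inline int mf_t(int b) { return b & 7; }
static inline int mf_sign(int b) { return (b >> 7) & 1; }

// decoded magnitude; -1 for the reserved e=1111 band
static double mf_value(int b) {
  int e = mf_e(b), t = mf_t(b);
  if (e == 0) return (double)t;
  if (e == 15) return -1.0;
  return (double)((u64)(8 + t) << (e - 1));
}

// next representable magnitude's bit pattern (sign preserved); -1 if maximal
static int mf_succ(int b) {
  int e = mf_e(b), t = mf_t(b), s = b & 0x80;
  if (e == 15) return -1;
  if (e == 0 && t < 7) return s | (t + 1);
  if (e == 0) return s | (1 << 3);          // 7 -> 8
  if (t < 7) return s | (e << 3) | (t + 1);
  if (e == 14) return -1;                   // 122,880 is maximal
  return s | ((e + 1) << 3);
}

// [[Rcpp::export]]
List cpp_mf_decode(IntegerVector b) {
  int n = b.size();
  NumericVector value(n);
  IntegerVector strand(n);
  LogicalVector collision(n), finite(n);
  for (int i = 0; i < n; ++i) {
    int x = b[i] & 0xFF;
    strand[i] = mf_sign(x);
    collision[i] = (x == 0x80);
    double v = mf_value(x);
    finite[i] = (v >= 0);
    value[i] = (v >= 0) ? v : NA_REAL;
  }
  return List::create(_["value"] = value, _["strand"] = strand,
                      _["collision"] = collision, _["finite"] = finite);
}

// [[Rcpp::export]]
IntegerVector cpp_mf_encode_exact(NumericVector c) {
  int n = c.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double v = c[i];
    int b = NA_INTEGER;
    if (v >= 0 && v <= MF_MAX && v == std::floor(v)) {
      u64 u = (u64)v;
      if (u <= 7) b = (int)u;
      else {
        for (int e = 1; e <= 14; ++e) {
          u64 step = 1ULL << (e - 1);
          if (u % step == 0) {
            u64 q = u / step;
            if (q >= 8 && q <= 15) { b = (e << 3) | (int)(q - 8); break; }
          }
        }
      }
    }
    out[i] = b;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_mf_successor(IntegerVector b) {
  IntegerVector out(b.size());
  for (int i = 0; i < b.size(); ++i) {
    int s = mf_succ(b[i] & 0xFF);
    out[i] = (s < 0) ? NA_INTEGER : s;
  }
  return out;
}

// Morris-style probabilistic increment: advance to the successor with
// probability 1/gap (deterministic while the gap is 1); saturate at maximum.
// Expected advance is exactly 1 at every state, so counting is unbiased.
static int mf_increment_one(int b) {
  int s = mf_succ(b);
  if (s < 0) return b;  // saturated
  double gap = mf_value(s) - mf_value(b);
  if (gap <= 1.0 || unif_rand() < 1.0 / gap) return s;
  return b;
}

// [[Rcpp::export]]
IntegerVector cpp_mf_increment(IntegerVector b) {
  IntegerVector out(b.size());
  for (int i = 0; i < b.size(); ++i) out[i] = mf_increment_one(b[i] & 0xFF);
  return out;
}

// Apply n true increments to a fresh counter, reps times; returns the final
// decoded value of each replicate. Geometric skip-ahead makes this O(states)
// per replicate instead of O(n) while drawing from the same distribution.
// [[Rcpp::export]]
NumericVector cpp_mf_count_stream(double n, int reps) {
  NumericVector out(reps);
  for (int r = 0; r < reps; ++r) {
    double remaining = n;
    int b = 0;
    while (remaining > 0) {
      int s = mf_succ(b);
      if (s < 0) break;
      double gap = mf_value(s) - mf_value(b);
      if (gap <= 1.0) { b = s; remaining -= 1.0; }
      else {
        double trials = 1.0 + R::rgeom(1.0 / gap);
        if (trials > remaining) remaining = 0;
        else { remaining -= trials; b = s; }
      }
    }
    out[r] = mf_value(b);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Cascading counting Bloom filter: stage 1 is the spaced-seed Bloom filter;
// on an all-hit insert the seed cascades to a byte array of minifloat
// counters at coordinates x = hF mod m2, x' = hR mod m2 (strand-sensitive
// hashes of S2k and its reverse complement).
// ---------------------------------------------------------------------------

struct Cascade {
  SeedBloom stage1;
  std::vector<u8> bytes;
  u64 m2;
  Cascade(u64 m, u64 m2_, int k, int d) : stage1(m, k, d), bytes(m2_, 0),
    m2(m2_) {}
};

// Table-1 update at byte states (vx, vxp). States: zero (+0), negzero (-0),
// nonzero (positive count). Returns an action label; mutates the bytes.
static const char *cascade_update(u8 &vx, u8 &vxp, bool same_coord) {
  bool x_zero = (vx == 0x00), x_neg = (vx == 0x80);
  bool p_zero = (vxp == 0x00), p_neg = (vxp == 0x80);
  if (same_coord) {
    // Degenerate pair (RC-palindromic seed or modulus collision of the two
    // coordinates): a single byte counts both strands; sign is never set.
    if (x_zero) { vx = 2; return "set_x"; }
    if (x_neg) return "none";
    vx = (u8)mf_increment_one(vx);
    return "increment_x";
  }
  if (x_zero && (p_zero || p_neg)) { vx = 2; return "set_x"; }
  if (!x_zero && !x_neg && (p_zero || p_neg)) {
    vx = (u8)((vx & 0x80) | mf_increment_one(vx & 0x7F));
    return "increment_x";
  }
  if ((x_zero || x_neg) && !p_zero && !p_neg) {
    vxp = (u8)(0x80 | mf_increment_one(vxp & 0x7F));
    return "increment_xp";
  }
  if (x_neg && p_zero) { vxp = 0x80 | 2; return "set_xp"; }
  // both nonzero (negative zero counts as nonzero here): hash collision
  vx = 0x80; vxp = 0x80;
  return "flag_collision";
}

// [[Rcpp::export]]
List cpp_update_rule(int vx, int vxp, bool same_coord) {
  u8 a = (u8)(vx & 0xFF), b = (u8)(vxp & 0xFF);
  const char *action = cascade_update(a, b, same_coord);
  return List::create(_["vx"] = (int)a, _["vxp"] = (int)b,
                      _["action"] = std::string(action));
}

static Cascade *cascade_get(SEXP xp) {
  XPtr<Cascade> p(xp);
  return p.get();
}

// [[Rcpp::export]]
SEXP cpp_cascade_new(double m, double m2, int k, int delta) {
  if (m < 1 || m2 < 1) stop("m and m2 must be positive");
  XPtr<Cascade> p(new Cascade((u64)m, (u64)m2, k, delta), true);
  return p;
}

// [[Rcpp::export]]
List cpp_cascade_params(SEXP xp) {
  Cascade *c = cascade_get(xp);
  return List::create(_["m"] = (double)c->stage1.m, _["m2"] = (double)c->m2,
                      _["k"] = c->stage1.k, _["delta"] = c->stage1.delta,
                      _["n_inserted"] = (double)c->stage1.n_inserted);
}

static int cascade_add_codes(Cascade *c, const int *codes) {
  bool hit[4];
  c->stage1.insert(codes, hit);
  if (!(hit[0] && hit[1] && hit[2] && hit[3])) return 1;
  u64 hF, hR;
  strand_pair_u64(codes, 2 * c->stage1.k, hF, hR);
  u64 x = hF % c->m2, xp = hR % c->m2;
  if (x == xp) {
    cascade_update(c->bytes[x], c->bytes[x], true);
  } else {
    cascade_update(c->bytes[x], c->bytes[xp], false);
  }
  return 2;
}

// [[Rcpp::export]]
IntegerVector cpp_cascade_add(SEXP xp, CharacterVector seeds) {
  Cascade *c = cascade_get(xp);
  IntegerVector out(seeds.size());
  for (int i = 0; i < seeds.size(); ++i) {
    std::vector<int> codes =
      s2k_codes_checked(as<std::string>(seeds[i]), c->stage1.k);
    out[i] = cascade_add_codes(c, codes.data());
  }
  return out;
}

// [[Rcpp::export]]
List cpp_cascade_add_read(SEXP xp, std::string read) {
  Cascade *c = cascade_get(xp);
  SeedWindows w = extract_windows(read, c->stage1.k, c->stage1.delta);
  int n = (int)w.origin.size();
  IntegerVector origin(n), stage(n);
  for (int i = 0; i < n; ++i) {
    origin[i] = w.origin[i];
    stage[i] = cascade_add_codes(c, w.codes[i].data());
  }
  return List::create(_["origin"] = origin, _["stage"] = stage);
}

// [[Rcpp::export]]
List cpp_cascade_count(SEXP xp, CharacterVector seeds) {
  Cascade *c = cascade_get(xp);
  int n = seeds.size();
  NumericVector estimate(n);
  LogicalVector both(n), collided(n);
  for (int i = 0; i < n; ++i) {
    std::vector<int> codes =
      s2k_codes_checked(as<std::string>(seeds[i]), c->stage1.k);
    u64 hF, hR;
    strand_pair_u64(codes.data(), 2 * c->stage1.k, hF, hR);
    u8 vx = c->bytes[hF % c->m2], vxp = c->bytes[hR % c->m2];
    if (vx == 0x80 || vxp == 0x80) {
      estimate[i] = NA_REAL; both[i] = NA_LOGICAL; collided[i] = true;
      continue;
    }
    collided[i] = false;
    u8 nz = (vx != 0) ? vx : vxp;
    if (nz != 0) {
      estimate[i] = mf_value(nz & 0x7F);
      both[i] = (nz & 0x80) != 0;
    } else {
      bool hit[4];
      c->stage1.query(codes.data(), hit);
      estimate[i] = (hit[0] && hit[1] && hit[2] && hit[3]) ? 1.0 : 0.0;
      both[i] = false;
    }
  }
  return List::create(_["estimate"] = estimate, _["both_strands"] = both,
                      _["collided"] = collided);
}

// Byte-array coordinates of a seed (for collision-free test construction).
// [[Rcpp::export]]
NumericVector cpp_cascade_coords(SEXP xp, std::string s2k) {
  Cascade *c = cascade_get(xp);
  std::vector<int> codes = s2k_codes_checked(s2k, c->stage1.k);
  u64 hF, hR;
  strand_pair_u64(codes.data(), 2 * c->stage1.k, hF, hR);
  return NumericVector::create(_["x"] = (double)(hF % c->m2),
                               _["xp"] = (double)(hR % c->m2));
}

// [[Rcpp::export]]
RawVector cpp_cascade_bytes(SEXP xp) {
  Cascade *c = cascade_get(xp);
  RawVector out(c->bytes.size());
  std::copy(c->bytes.begin(), c->bytes.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
RawVector cpp_cascade_stage1_bits(SEXP xp) {
  Cascade *c = cascade_get(xp);
  size_t nbytes = (size_t)((c->stage1.m + 7) / 8);
  RawVector out(nbytes);
  for (size_t i = 0; i < nbytes; ++i)
    out[i] = (u8)((c->stage1.bits[i >> 3] >> (8 * (i & 7))) & 0xFF);
  return out;
}

// [[Rcpp::export]]
SEXP cpp_cascade_from_state(double m, double m2, int k, int delta,
                            double n_inserted, RawVector bits,
                            RawVector bytes) {
  XPtr<Cascade> p(new Cascade((u64)m, (u64)m2, k, delta), true);
  size_t nbytes = (size_t)(((u64)m + 7) / 8);
  if (bits.size() != (R_xlen_t)nbytes || bytes.size() != (R_xlen_t)(u64)m2)
    stop("payload size mismatch");
  for (size_t i = 0; i < nbytes; ++i)
    p->stage1.bits[i >> 3] |= ((u64)bits[i]) << (8 * (i & 7));
  std::copy(bytes.begin(), bytes.end(), p->bytes.begin());
  p->stage1.n_inserted = (u64)n_inserted;
  return p;
}

// ---------------------------------------------------------------------------
// Genome census for the uniqueness profile: canonical seed at every valid
// position of a linear genome.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_canonical_seeds(std::string genome, int k, int delta) {
  SeedWindows w = extract_windows(genome, k, delta);
  int n = (int)w.origin.size();
  CharacterVector seeds(n);
  IntegerVector origin(n);
  for (int i = 0; i < n; ++i) {
    origin[i] = w.origin[i];
    seeds[i] = cpp_canonical_str(codes_str(w.codes[i]));
  }
  return List::create(_["origin"] = origin, _["seed"] = seeds);
}
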