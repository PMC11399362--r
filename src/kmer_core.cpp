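#include <Rcpp.h>
#include <cstdint>
#include <cstring>
using namespace Rcpp;

// 2-bit base codes: A=0, C=1, G=2, T=3 (lexicographic == numeric order).
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static const char BASES[5] = "ACGT";

// [[Rcpp::export]]
double encode_kmer_cpp(const std::string& s) {
  if (s.size() != 16)
    stop("k-mer must be exactly 16 bases (got %d)", (int)s.size());
  uint64_t v = 0;
  for (size_t i = 0; i < 16; ++i) {
    int b = base_code(s[i]);
    if (b < 0)
      stop("non-ACGT character '%c' at position %d", s[i], (int)(i + 1));
    v = (v << 2) | (uint64_t)b;
  }
  return (double)v;
}

// [[Rcpp::export]]
std::string decode_kmer_cpp(double code) {
  if (ISNAN(code) || code < 0 || code >= 4294967296.0 || code != std::floor(code))
    stop("k-mer code must be an integer in [0, 2^32)");
  uint64_t v = (uint64_t)code;
  std::string s(16, 'A');
  for (int i = 15; i >= 0; --i) {
    s[i] = BASES[v & 3];
    v >>= 2;
  }
  return s;
}

// All k-mer windows of s with step 1; windows containing a non-ACGT
// character are skipped but the start position still advances.
// Returns 0-based starts and packed 2-bit codes (k <= 26 so codes are
// exact in a double).
// [[Rcpp::export]]
List enumerate_kmers_cpp(const std::string& s, int k) {
  if (k < 1) stop("k must be >= 1");
  if (k > 26) stop("k must be <= 26 for exact integer codes");
  std::vector<int> starts;
  std::vector<double> codes;
  const size_t L = s.size();
  if (L >= (size_t)k) {
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    uint64_t v = 0;
    int run = 0;  // consecutive valid bases ending at i
    for (size_t i = 0; i < L; ++i) {
      int b = base_code(s[i]);
      if (b < 0) { run = 0; v = 0; continue; }
      v = ((v << 2) | (uint64_t)b) & mask;
      if (++run >= k) {
        starts.push_back((int)i - k + 1);
        codes.push_back((double)v);
      }
    }
  }
  return List::create(_["start"] = wrap(starts), _["code"] = wrap(codes));
}

// Set presence bits; returns the number of bits newly set.
// Bit layout: code c lives at bit (c & 7) of byte (c >> 3).
// [[Rcpp::export]]
double bitmap_set_codes(RawVector bits, NumericVector codes) {
  Rbyte* p = RAW(bits);
  const R_xlen_t nb = bits.size();
  double newly = 0;
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    uint64_t c = (uint64_t)codes[i];
    R_xlen_t byte = (R_xlen_t)(c >> 3);
    if (byte >= nb) stop("k-mer code out of range for bitmap");
    Rbyte m = (Rbyte)(1u << (c & 7));
    if (!(p[byte] & m)) { p[byte] |= m; newly += 1; }
  }
  return newly;
}

// [[Rcpp::export]]
LogicalVector bitmap_get_codes(RawVector bits, NumericVector codes) {
  const Rbyte* p = RAW(bits);
  const R_xlen_t nb = bits.size();
  LogicalVector out(codes.size());
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    uint64_t c = (uint64_t)codes[i];
    R_xlen_t byte = (R_xlen_t)(c >> 3);
    if (byte >= nb) stop("k-mer code out of range for bitmap");
    out[i] = (p[byte] >> (c & 7)) & 1;
  }
  return out;
}

// [[Rcpp::export]]
double bitmap_popcount(RawVector bits) {
  const uint8_t* p = (const uint8_t*)RAW(bits);
  const R_xlen_t n = bits.size();
  uint64_t total = 0;
  R_xlen_t i = 0;
  for (; i + 8 <= n; i += 8) {
    uint64_t w;
    std::memcpy(&w, p + i, 8);
    total += (uint64_t)__builtin_popcountll(w);
  }
  for (; i < n; ++i) total += (uint64_t)__builtin_popcount((unsigned)p[i]);
  return (double)total;
}

// [[Rcpp::export]]
RawVector bitmap_clone(RawVector bits) {
  return clone(bits);
}

// Longest single-base run per string (any characters; a run is a maximal
// stretch of one repeated character).
// [[Rcpp::export]]
IntegerVector max_run_cpp(CharacterVector seqs) {
  IntegerVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    int best = 0, cur = 0;
    char prev = '\0';
    for (const char* q = s; *q; ++q) {
      cur = (*q == prev) ? cur + 1 : 1;
      prev = *q;
      if (cur > best) best = cur;
    }
    out[i] = best;
  }
  return out;
}

// Pack codes as 4-byte little-endian unsigned ints (set-backend persistence).
// [[Rcpp::export]]
RawVector codes_to_raw_cpp(NumericVector codes) {
  RawVector out(codes.size() * 4);
  Rbyte* p = RAW(out);
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    uint64_t c = (uint64_t)codes[i];
    p[4 * i]     = (Rbyte)(c & 0xFF);
    p[4 * i + 1] = (Rbyte)((c >> 8) & 0xFF);
    p[4 * i + 2] = (Rbyte)((c >> 16) & 0xFF);
    p[4 * i + 3] = (Rbyte)((c >> 24) & 0xFF);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector raw_to_codes_cpp(RawVector raw) {
  if (raw.size() % 4 != 0) stop("code block length is not a multiple of 4");
  const Rbyte* p = RAW(raw);
  NumericVector out(raw.size() / 4);
  for (R_xlen_t i = 0; i < out.size(); ++i) {
    uint64_t c = (uint64_t)p[4 * i] | ((uint64_t)p[4 * i + 1] << 8) |
                 ((uint64_t)p[4 * i + 2] << 16) | ((uint64_t)p[4 * i + 3] << 24);
    out[i] = (double)c;
  }
  return out;
}
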