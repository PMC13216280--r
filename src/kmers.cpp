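// Hot loops for canonical k-mer work: counting, exact hit scanning, read
// scoring and a naive perfect-tandem scan. K-mers (k <= 64) are held as
// 2-bit packed 128-bit integers; since A<C<G<T maps to 0<1<2<3, numeric
// order equals lexicographic order, so the canonical form (min of window
// and reverse complement) agrees with the string definition. Windows
// containing a non-ACGT character are skipped.
#include <Rcpp.h>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

typedef unsigned __int128 u128;

struct U128Hash {
  size_t operator()(u128 x) const {
    uint64_t lo = (uint64_t)x, hi = (uint64_t)(x >> 64);
    uint64_t h = (lo ^ (hi * 0x9E3779B97F4A7C15ULL));
    h ^= h >> 33; h *= 0xFF51AFD7ED558CCDULL; h ^= h >> 33;
    return (size_t)h;
  }
};

static inline int baseCode(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static void checkK(int k) {
  if (k < 1 || k > 64) stop("k must be in 1..64");
}

// call f(start0, canonical) for every valid window; start0 is 0-based
template <typename F>
static void scanCanonical(const char* s, R_xlen_t n, int k, F f) {
  const u128 one = 1;
  const u128 mask = (k == 64) ? ~(u128)0 : ((one << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  u128 fwd = 0, rc = 0;
  int run = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    int c = baseCode(s[i]);
    if (c < 0) { run = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (u128)c) & mask;
    rc = (rc >> 2) | ((u128)(3 - c) << shift);
    if (++run >= k) f(i - k + 1, fwd < rc ? fwd : rc);
  }
}

static std::string decodeKmer(u128 x, int k) {
  static const char* B = "ACGT";
  std::string s(k, 'A');
  for (int j = k - 1; j >= 0; --j) { s[j] = B[(int)(x & 3)]; x >>= 2; }
  return s;
}

// encode an ACGT string; error on other characters
static u128 encodeKmer(const char* s, int k) {
  u128 x = 0;
  for (int j = 0; j < k; ++j) {
    int c = baseCode(s[j]);
    if (c < 0) stop("k-mer contains a non-ACGT character");
    x = (x << 2) | (u128)c;
  }
  return x;
}

typedef std::unordered_set<u128, U128Hash> KmerSet;

// collect every canonical window; counting is done by sort + run-length
// (faster and more memory-predictable than hashing at genome scale)
static void collectInto(std::vector<u128>& v, CharacterVector seqs, int k) {
  R_xlen_t total = 0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) total += LENGTH(STRING_ELT(seqs, i));
  v.reserve(v.size() + total);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    R_xlen_t n = LENGTH(STRING_ELT(seqs, i));
    scanCanonical(s, n, k, [&](R_xlen_t, u128 km) { v.push_back(km); });
  }
}

static KmerSet buildSet(CharacterVector kmers, int k) {
  KmerSet set;
  set.reserve(kmers.size() * 2);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    if (LENGTH(STRING_ELT(kmers, i)) != k) stop("k-mer of wrong length");
    set.insert(encodeKmer(CHAR(STRING_ELT(kmers, i)), k));
  }
  return set;
}

// [[Rcpp::export]]
NumericVector cpp_count_kmers(CharacterVector seqs, int k) {
  checkK(k);
  std::vector<u128> v;
  collectInto(v, seqs, k);
  std::sort(v.begin(), v.end());
  std::vector<double> cnt;
  std::vector<u128> uniq;
  for (size_t i = 0; i < v.size();) {
    size_t j = i;
    while (j < v.size() && v[j] == v[i]) ++j;
    uniq.push_back(v[i]);
    cnt.push_back((double)(j - i));
    i = j;
  }
  NumericVector out(uniq.size());
  CharacterVector nm(uniq.size());
  for (size_t i = 0; i < uniq.size(); ++i) {
    nm[i] = decodeKmer(uniq[i], k);
    out[i] = cnt[i];
  }
  out.attr("names") = nm;
  return out;
}

// joint counting over two sequence sets; returns only k-mers whose count
// reaches keep_min1 in set 1 or keep_min2 in set 2 (candidate markers),
// with both counts reported exactly.
// [[Rcpp::export]]
List cpp_count_kmers_pair(CharacterVector seqs1, CharacterVector seqs2,
                          int k, double keep_min1, double keep_min2) {
  checkK(k);
  std::vector<u128> v1, v2;
  collectInto(v1, seqs1, k);
  collectInto(v2, seqs2, k);
  std::sort(v1.begin(), v1.end());
  std::sort(v2.begin(), v2.end());
  std::vector<u128> keep;
  std::vector<double> kc1, kc2;
  size_t i = 0, j = 0;
  while (i < v1.size() || j < v2.size()) {
    u128 km;
    if (j >= v2.size() || (i < v1.size() && v1[i] <= v2[j])) km = v1[i];
    else km = v2[j];
    double c1 = 0, c2 = 0;
    while (i < v1.size() && v1[i] == km) { ++c1; ++i; }
    while (j < v2.size() && v2[j] == km) { ++c2; ++j; }
    if (c1 >= keep_min1 || c2 >= keep_min2) {
      keep.push_back(km);
      kc1.push_back(c1);
      kc2.push_back(c2);
    }
  }
  CharacterVector kmer(keep.size());
  for (size_t t = 0; t < keep.size(); ++t) kmer[t] = decodeKmer(keep[t], k);
  return List::create(_["kmer"] = kmer, _["count_a1"] = wrap(kc1),
                      _["count_a2"] = wrap(kc2));
}

// 1-based start positions of windows whose canonical form is in `kmers`
// [[Rcpp::export]]
IntegerVector cpp_kmer_hit_starts(std::string seq, CharacterVector kmers, int k) {
  checkK(k);
  KmerSet set = buildSet(kmers, k);
  std::vector<int> hits;
  scanCanonical(seq.c_str(), (R_xlen_t)seq.size(), k,
                [&](R_xlen_t p, u128 km) {
                  if (set.count(km)) hits.push_back((int)p + 1);
                });
  return wrap(hits);
}

// per-read number of windows whose canonical form is a member k-mer
// [[Rcpp::export]]
IntegerVector cpp_read_hit_counts(CharacterVector reads, CharacterVector kmers, int k) {
  checkK(k);
  KmerSet set = buildSet(kmers, k);
  IntegerVector out(reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    R_xlen_t n = LENGTH(STRING_ELT(reads, i));
    int hits = 0;
    scanCanonical(s, n, k, [&](R_xlen_t, u128 km) {
      if (set.count(km)) ++hits;
    });
    out[i] = hits;
  }
  return out;
}

// canonical k-mers present in `region` sequences but absent from `rest`;
// also reports how many distinct region k-mers occur elsewhere.
// [[Rcpp::export]]
List cpp_diagnostic_kmers(CharacterVector region, CharacterVector rest, int k) {
  checkK(k);
  KmerSet bg;
  for (R_xlen_t i = 0; i < rest.size(); ++i) {
    const char* s = CHAR(STRING_ELT(rest, i));
    R_xlen_t n = LENGTH(STRING_ELT(rest, i));
    scanCanonical(s, n, k, [&](R_xlen_t, u128 km) { bg.insert(km); });
  }
  KmerSet keep, dropped;
  for (R_xlen_t i = 0; i < region.size(); ++i) {
    const char* s = CHAR(STRING_ELT(region, i));
    R_xlen_t n = LENGTH(STRING_ELT(region, i));
    scanCanonical(s, n, k, [&](R_xlen_t, u128 km) {
      if (bg.count(km)) dropped.insert(km); else keep.insert(km);
    });
  }
  CharacterVector members(keep.size());
  R_xlen_t i = 0;
  for (const auto& m : keep) members[i++] = decodeKmer(m, k);
  return List::create(_["members"] = members,
                      _["background_excluded"] = (int)dropped.size());
}

// Maximal runs of exact head-to-tail unit repetition, one scan per unit
// length; 1-based inclusive coordinates. A run [rs, j) satisfies
// s[p] == s[p-u] for all p in [rs+u, j) with every base in ACGT.
// [[Rcpp::export]]
DataFrame cpp_find_tandems(std::string seq, IntegerVector unit_lengths, int min_copies) {
  const char* s = seq.c_str();
  R_xlen_t n = (R_xlen_t)seq.size();
  std::vector<int> starts, ends, periods;
  std::vector<double> copies;
  std::vector<std::string> units;
  for (R_xlen_t ui = 0; ui < unit_lengths.size(); ++ui) {
    int u = unit_lengths[ui];
    if (u < 1 || n < (R_xlen_t)u * min_copies) continue;
    R_xlen_t rs = 0;
    R_xlen_t j = u;
    while (j <= n) {
      bool ok = j < n && baseCode(s[j]) >= 0 && baseCode(s[j - u]) >= 0 &&
                s[j] == s[j - u];
      if (!ok) {
        R_xlen_t len = j - rs;
        if (len >= (R_xlen_t)u * min_copies) {
          bool valid = true;
          for (R_xlen_t p = rs; p < rs + u; ++p) {
            if (baseCode(s[p]) < 0) { valid = false; break; }
          }
          if (valid) {
            starts.push_back((int)rs + 1);
            ends.push_back((int)j);
            periods.push_back(u);
            copies.push_back((double)len / u);
            units.push_back(std::string(s + rs, s + rs + u));
          }
        }
        if (j >= n) break;
        rs = j - u + 1;
        ++j;
      } else {
        ++j;
      }
    }
  }
  return DataFrame::create(_["start"] = starts, _["end"] = ends,
                           _["period"] = periods, _["copy_number"] = copies,
                           _["unit"] = units,
                           _["stringsAsFactors"] = false);
}
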