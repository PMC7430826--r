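// Packed-kmer engine: 2 bits per base, kmer codes held as uint64 and
// exposed to R as (hi, lo) pairs of 32-bit integers so that bit patterns
// survive the round trip exactly. k is limited to 31 at the R level.
#include <Rcpp.h>
#include <cstdint>
#include <cstdio>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline int base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

static inline uint64_t pack_pair(int hi, int lo) {
  return (((uint64_t)(uint32_t)hi) << 32) | (uint64_t)(uint32_t)lo;
}

static inline int unpack_hi(uint64_t x) { return (int)(uint32_t)(x >> 32); }
static inline int unpack_lo(uint64_t x) { return (int)(uint32_t)(x & 0xffffffffULL); }

// All valid kmer codes of s in window order. Windows containing a
// non-ACGT character are skipped. canonical: min(code, revcomp code).
static void enumerate_codes(const std::string &s, int k, bool canonical,
                            std::vector<uint64_t> &out) {
  const long n = (long)s.size();
  if (n < k) return;
  const uint64_t mask = (1ULL << (2 * k)) - 1ULL;
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rc = 0;
  int valid = 0;
  for (long i = 0; i < n; i++) {
    int b = base2bit(s[i]);
    if (b < 0) { valid = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rc = (rc >> 2) | (((uint64_t)(3 - b)) << shift);
    if (++valid >= k) out.push_back(canonical ? std::min(fwd, rc) : fwd);
  }
}

static std::vector<uint64_t> codes_from_r(IntegerVector hi, IntegerVector lo) {
  if (hi.size() != lo.size()) stop("hi/lo length mismatch");
  std::vector<uint64_t> v(hi.size());
  for (R_xlen_t i = 0; i < hi.size(); i++) v[i] = pack_pair(hi[i], lo[i]);
  return v;
}

static List codes_to_r(const std::vector<uint64_t> &v) {
  IntegerVector hi(v.size()), lo(v.size());
  for (size_t i = 0; i < v.size(); i++) {
    hi[i] = unpack_hi(v[i]);
    lo[i] = unpack_lo(v[i]);
  }
  return List::create(_["hi"] = hi, _["lo"] = lo);
}

// Distinct kmer codes and their counts, sorted by code (unsigned order).
// circular: append the first k-1 characters to close the wrap.
// [[Rcpp::export]]
List cpp_kmer_count(std::string seq, int k, bool canonical, bool circular) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  std::string s = seq;
  if (circular && (long)s.size() >= k) s += s.substr(0, k - 1);
  std::vector<uint64_t> codes;
  enumerate_codes(s, k, canonical, codes);
  std::sort(codes.begin(), codes.end());
  std::vector<uint64_t> uniq;
  std::vector<int> cnt;
  for (size_t i = 0; i < codes.size();) {
    size_t j = i;
    while (j < codes.size() && codes[j] == codes[i]) j++;
    uniq.push_back(codes[i]);
    cnt.push_back((int)(j - i));
    i = j;
  }
  List out = codes_to_r(uniq);
  out["count"] = IntegerVector(cnt.begin(), cnt.end());
  out["n_total"] = (double)codes.size();
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_codes_to_strings(IntegerVector hi, IntegerVector lo, int k) {
  std::vector<uint64_t> v = codes_from_r(hi, lo);
  CharacterVector out(v.size());
  const char *alph = "ACGT";
  std::string buf(k, 'A');
  for (size_t i = 0; i < v.size(); i++) {
    uint64_t c = v[i];
    for (int j = k - 1; j >= 0; j--) {
      buf[j] = alph[c & 3ULL];
      c >>= 2;
    }
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_codes_to_hex(IntegerVector hi, IntegerVector lo) {
  std::vector<uint64_t> v = codes_from_r(hi, lo);
  CharacterVector out(v.size());
  char buf[17];
  for (size_t i = 0; i < v.size(); i++) {
    std::snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)v[i]);
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_hex_to_codes(CharacterVector hex) {
  std::vector<uint64_t> v(hex.size());
  for (R_xlen_t i = 0; i < hex.size(); i++) {
    std::string h = as<std::string>(hex[i]);
    if (h.size() != 16) stop("corrupt kmer record (expected 16 hex digits)");
    uint64_t x = 0;
    for (char c : h) {
      int d;
      if (c >= '0' && c <= '9') d = c - '0';
      else if (c >= 'a' && c <= 'f') d = c - 'a' + 10;
      else if (c >= 'A' && c <= 'F') d = c - 'A' + 10;
      else stop("corrupt kmer record (non-hex digit)");
      x = (x << 4) | (uint64_t)d;
    }
    v[i] = x;
  }
  return codes_to_r(v);
}

// Merge per-genome sorted distinct kmer sets into a CSR index:
// merged unique codes, offsets into a genome-id array, and per-taxon
// distinct-kmer counts. g2t maps genome index -> taxon index (0-based).
// [[Rcpp::export]]
List cpp_merge_index(List sets, IntegerVector g2t, int n_taxa) {
  const int ng = sets.size();
  std::vector<std::pair<uint64_t, int> > pairs;
  for (int g = 0; g < ng; g++) {
    List s = sets[g];
    std::vector<uint64_t> v = codes_from_r(s["hi"], s["lo"]);
    for (uint64_t c : v) pairs.push_back(std::make_pair(c, g));
  }
  std::sort(pairs.begin(), pairs.end());
  std::vector<uint64_t> uniq;
  std::vector<int> off, gid;
  off.push_back(0);
  NumericVector taxon_size(n_taxa);
  std::vector<int> tmark(n_taxa, -1);
  for (size_t i = 0; i < pairs.size();) {
    size_t j = i;
    uniq.push_back(pairs[i].first);
    int u = (int)uniq.size() - 1;
    while (j < pairs.size() && pairs[j].first == pairs[i].first) {
      int g = pairs[j].second;
      gid.push_back(g);
      int t = g2t[g];
      if (tmark[t] != u) { tmark[t] = u; taxon_size[t] += 1.0; }
      j++;
    }
    off.push_back((int)gid.size());
    i = j;
  }
  List out = codes_to_r(uniq);
  out["offsets"] = IntegerVector(off.begin(), off.end());
  out["gid"] = IntegerVector(gid.begin(), gid.end());
  out["taxon_set_size"] = taxon_size;
  return out;
}

// Match every read's kmers against a merged CSR index.
// Returns per-read kmer totals, per-read x per-genome matched counts,
// per-taxon matched kmer instances (a kmer occurrence matching >=1
// genome of the taxon counts once), per-taxon distinct matched kmers,
// and the grand total of queried kmers.
// [[Rcpp::export]]
List cpp_match_reads(CharacterVector reads, int k, bool canonical,
                     IntegerVector mhi, IntegerVector mlo,
                     IntegerVector offsets, IntegerVector gid,
                     IntegerVector g2t, int n_genomes, int n_taxa) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  std::vector<uint64_t> merged = codes_from_r(mhi, mlo);
  const R_xlen_t nr = reads.size();
  IntegerVector n_kmers(nr);
  IntegerMatrix matches(nr, n_genomes);
  NumericVector taxon_total(n_taxa), taxon_unique(n_taxa);
  std::vector<uint64_t> tmark(n_taxa, 0);
  std::vector<char> seen(merged.size(), 0);
  uint64_t stamp = 0;
  double total_kmers = 0.0;
  std::vector<uint64_t> codes;
  for (R_xlen_t i = 0; i < nr; i++) {
    codes.clear();
    enumerate_codes(as<std::string>(reads[i]), k, canonical, codes);
    n_kmers[i] = (int)codes.size();
    total_kmers += (double)codes.size();
    for (uint64_t c : codes) {
      std::vector<uint64_t>::iterator it =
          std::lower_bound(merged.begin(), merged.end(), c);
      if (it == merged.end() || *it != c) continue;
      int u = (int)(it - merged.begin());
      seen[u] = 1;
      ++stamp;
      for (int j = offsets[u]; j < offsets[u + 1]; j++) {
        int g = gid[j];
        matches(i, g)++;
        int t = g2t[g];
        if (tmark[t] != stamp) { tmark[t] = stamp; taxon_total[t] += 1.0; }
      }
    }
  }
  std::fill(tmark.begin(), tmark.end(), 0);
  stamp = 0;
  for (size_t u = 0; u < merged.size(); u++) {
    if (!seen[u]) continue;
    ++stamp;
    for (int j = offsets[u]; j < offsets[u + 1]; j++) {
      int t = g2t[gid[j]];
      if (tmark[t] != stamp) { tmark[t] = stamp; taxon_unique[t] += 1.0; }
    }
  }
  return List::create(_["n_kmers"] = n_kmers, _["matches"] = matches,
                      _["taxon_total"] = taxon_total,
                      _["taxon_unique"] = taxon_unique,
                      _["total_kmers"] = total_kmers);
}
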