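#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
#include <unordered_map>

using namespace Rcpp;

// 2-bit encoding of upper/lower-case A,C,G,T; -1 for anything else (N, gaps).
static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

struct KmerEntry {
  uint64_t key;
  uint32_t chrom;
  uint32_t pos;
};

struct KmerIndex {
  int k;
  std::vector<std::string> seqs;   // reference chromosomes, as given
  std::vector<KmerEntry> entries;  // sorted by (key, chrom, pos)
};

static inline bool entry_less(const KmerEntry& a, const KmerEntry& b) {
  if (a.key != b.key) return a.key < b.key;
  if (a.chrom != b.chrom) return a.chrom < b.chrom;
  return a.pos < b.pos;
}

// [[Rcpp::export]]
SEXP kmer_index_build(CharacterVector seqs, int k) {
  if (k < 2 || k > 31) stop("k must be between 2 and 31");
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  idx->seqs.reserve(seqs.size());
  size_t total = 0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    idx->seqs.push_back(as<std::string>(seqs[i]));
    if (idx->seqs.back().size() >= (size_t)k)
      total += idx->seqs.back().size() - k + 1;
  }
  idx->entries.reserve(total);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (size_t c = 0; c < idx->seqs.size(); ++c) {
    const std::string& s = idx->seqs[c];
    uint64_t kmer = 0;
    int valid = 0;
    for (size_t j = 0; j < s.size(); ++j) {
      int b = base2bits(s[j]);
      if (b < 0) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)b) & mask;
      if (++valid >= k) {
        KmerEntry e;
        e.key = kmer;
        e.chrom = (uint32_t)c;
        e.pos = (uint32_t)(j - k + 1);
        idx->entries.push_back(e);
      }
    }
  }
  std::sort(idx->entries.begin(), idx->entries.end(), entry_less);
  XPtr<KmerIndex> ptr(idx, true);
  return ptr;
}

// Total number of block positions covered by at least one exact match of
// length >= k against the indexed reference. Equivalent to the union of
// per-diagonal maximal equal runs of length >= k; matches are never counted
// twice on the block, so repeated reference hits cannot inflate the total.
// [[Rcpp::export]]
double kmer_match_coverage(SEXP idxp, std::string block, int max_hits = 16) {
  XPtr<KmerIndex> idx(idxp);
  const int k = idx->k;
  const long long Lb = (long long)block.size();
  if (Lb < k) return 0.0;
  const uint64_t mask = ((1ULL << (2 * k)) - 1);

  // per-diagonal memo of the known end (block coordinate, exclusive) of the
  // maximal run through that diagonal
  std::unordered_map<uint64_t, long long> memo;
  memo.reserve(1024);

  double covered = 0.0;
  long long cov_end = 0;  // exclusive end of covered prefix region
  uint64_t kmer = 0;
  int valid = 0;

  for (long long j = 0; j < Lb; ++j) {
    int b = base2bits(block[j]);
    if (b < 0) { valid = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)b) & mask;
    if (++valid < k) continue;
    const long long i = j - k + 1;  // match start on the block

    // binary search for entries with this key
    KmerEntry probe; probe.key = kmer; probe.chrom = 0; probe.pos = 0;
    auto lo = std::lower_bound(idx->entries.begin(), idx->entries.end(), probe,
                               [](const KmerEntry& a, const KmerEntry& b2) {
                                 return a.key < b2.key;
                               });
    if (lo == idx->entries.end() || lo->key != kmer) continue;

    long long best_end = 0;
    int hits = 0;
    for (auto it = lo; it != idx->entries.end() && it->key == kmer; ++it) {
      if (++hits > max_hits) break;
      const uint32_t c = it->chrom;
      const long long p = (long long)it->pos;
      const uint64_t dkey =
        ((uint64_t)c << 36) | (uint64_t)(p - i + (1LL << 35));
      long long end_here;
      auto m = memo.find(dkey);
      if (m != memo.end() && m->second > i) {
        end_here = m->second;
      } else {
        const std::string& S = idx->seqs[c];
        long long maxj = std::min(Lb - i, (long long)S.size() - p);
        long long ext = k;  // the seed itself matches
        while (ext < maxj && block[i + ext] == S[p + ext] &&
               base2bits(block[i + ext]) >= 0)
          ++ext;
        end_here = i + ext;
        memo[dkey] = end_here;
      }
      if (end_here > best_end) best_end = end_here;
    }
    if (best_end > cov_end) {
      covered += (double)(best_end - std::max(cov_end, i));
      cov_end = best_end;
    }
  }
  return covered;
}
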