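// Built-in desk-scale read mapper: sampled k-mer seeds over the reference,
// ungapped extension scored by identity (Hamming; no indels). A read is
// mapped when its best location reaches min_identity, unique when the best
// strictly beats the second best; ties are reported at the lexicographically
// smallest (replicon, pos, strand). Replicons must be supplied sorted by
// name so that index order equals lexicographic order.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default: return 'N';
  }
}

typedef std::unordered_map< uint64_t, std::vector<uint64_t> > SeedIndex;

// index sampled k-mers of each replicon; entries pack (replicon, pos)
static void build_index(const std::vector<std::string>& seqs, int k, int step,
                        SeedIndex& index) {
  for (size_t r = 0; r < seqs.size(); ++r) {
    const std::string& s = seqs[r];
    if ((int)s.size() < k) continue;
    for (size_t p = 0; p + k <= s.size(); p += step) {
      uint64_t key = 0;
      bool ok = true;
      for (int j = 0; j < k; ++j) {
        int c = base_code(s[p + j]);
        if (c < 0) { ok = false; break; }
        key = (key << 2) | (uint64_t)c;
      }
      if (ok) index[key].push_back(((uint64_t)r << 40) | (uint64_t)p);
    }
  }
}

// [[Rcpp::export(name = ".cpp_map_reads")]]
DataFrame cpp_map_reads(CharacterVector replicon_seqs, CharacterVector reads,
                        int kmer, int step, double min_identity) {
  const int n_rep = replicon_seqs.size();
  std::vector<std::string> seqs(n_rep);
  for (int i = 0; i < n_rep; ++i) seqs[i] = as<std::string>(replicon_seqs[i]);

  SeedIndex index;
  build_index(seqs, kmer, step, index);

  const int n_reads = reads.size();
  IntegerVector out_rep(n_reads, NA_INTEGER);
  IntegerVector out_pos(n_reads, NA_INTEGER);
  CharacterVector out_strand(n_reads);
  IntegerVector out_matches(n_reads, 0);
  IntegerVector out_nbest(n_reads, 0);
  LogicalVector out_mapped(n_reads, false);
  LogicalVector out_unique(n_reads, false);

  std::vector<uint64_t> cands;
  for (int i = 0; i < n_reads; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    const int len = (int)fwd.size();
    out_strand[i] = "+";
    if (len < kmer) continue;  // too short to seed: unmapped
    std::string rev(len, 'N');
    for (int j = 0; j < len; ++j) rev[len - 1 - j] = comp_base(fwd[j]);

    cands.clear();
    const std::string* strands[2] = { &fwd, &rev };
    for (int s = 0; s < 2; ++s) {
      const std::string& rd = *strands[s];
      for (int off = 0; off + kmer <= len; ++off) {
        uint64_t key = 0;
        bool ok = true;
        for (int j = 0; j < kmer; ++j) {
          int c = base_code(rd[off + j]);
          if (c < 0) { ok = false; break; }
          key = (key << 2) | (uint64_t)c;
        }
        if (!ok) continue;
        SeedIndex::const_iterator it = index.find(key);
        if (it == index.end()) continue;
        for (size_t h = 0; h < it->second.size(); ++h) {
          uint64_t packed = it->second[h];
          int r = (int)(packed >> 40);
          long gpos = (long)(packed & ((1ULL << 40) - 1));
          long start = gpos - off;
          if (start < 0 || start + len > (long)seqs[r].size()) continue;
          cands.push_back(((uint64_t)r << 42) | ((uint64_t)start << 1) |
                          (uint64_t)s);
        }
      }
    }
    if (cands.empty()) continue;
    std::sort(cands.begin(), cands.end());
    cands.erase(std::unique(cands.begin(), cands.end()), cands.end());

    // evaluate candidates; packed keys sort in lexicographic
    // (replicon, pos, strand) order, so the first best seen is the reported one
    int min_matches = (int)std::ceil(min_identity * len);
    int best_matches = -1, n_best = 0;
    int best_rep = -1; long best_pos = -1; int best_strand = 0;
    for (size_t ci = 0; ci < cands.size(); ++ci) {
      uint64_t packed = cands[ci];
      int r = (int)(packed >> 42);
      long start = (long)((packed >> 1) & ((1ULL << 41) - 1));
      int s = (int)(packed & 1ULL);
      const std::string& rd = *strands[s];
      const std::string& g = seqs[r];
      int matches = 0;
      for (int j = 0; j < len; ++j)
        if (rd[j] == g[start + j]) ++matches;
      if (matches < min_matches) continue;
      if (matches > best_matches) {
        best_matches = matches; n_best = 1;
        best_rep = r; best_pos = start; best_strand = s;
      } else if (matches == best_matches) {
        ++n_best;
      }
    }
    if (best_matches < 0) continue;
    out_mapped[i] = true;
    out_unique[i] = (n_best == 1);
    out_rep[i] = best_rep + 1;       // 1-based into the sorted replicon list
    out_pos[i] = (int)best_pos + 1;  // 1-based reference coordinate
    out_strand[i] = best_strand == 0 ? "+" : "-";
    out_matches[i] = best_matches;
    out_nbest[i] = n_best;
  }

  return DataFrame::create(
    _["rep"] = out_rep, _["pos"] = out_pos, _["strand"] = out_strand,
    _["matches"] = out_matches, _["n_best"] = out_nbest,
    _["is_mapped"] = out_mapped, _["is_unique"] = out_unique,
    _["stringsAsFactors"] = false);
}
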