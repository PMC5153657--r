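// k-mer seeded, substitution-only end-to-end matcher.
//
// Seeds are non-overlapping k-mers taken from max_mm+1 disjoint segments of
// the read (pigeonhole: a placement with <= max_mm substitutions leaves at
// least one segment exact), candidates are verified by direct comparison
// with early abort. No indels by design.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char revcomp_base(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    r[s.size() - 1 - i] = revcomp_base(s[i]);
  return r;
}

static inline bool encode_kmer(const std::string& s, size_t pos, int k,
                               uint64_t* out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bits(s[pos + i]);
    if (b < 0) return false;
    v = (v << 2) | (uint64_t)b;
  }
  *out = v;
  return true;
}

struct KmerIndex {
  int k;
  std::vector<std::string> seqs;
  std::vector<std::string> names;
  // kmer -> packed (seq_id << 32 | pos)
  std::unordered_map<uint64_t, std::vector<uint64_t>> map;
};

// [[Rcpp::export]]
SEXP kmer_index_build(CharacterVector seqs, int k) {
  if (k < 4 || k > 31) stop("k must be in [4, 31]");
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  CharacterVector nm = seqs.names();
  for (int i = 0; i < seqs.size(); ++i) {
    idx->seqs.push_back(as<std::string>(seqs[i]));
    idx->names.push_back(nm.size() ? as<std::string>(nm[i]) : "");
  }
  for (size_t sid = 0; sid < idx->seqs.size(); ++sid) {
    const std::string& s = idx->seqs[sid];
    if ((int)s.size() < k) continue;
    for (size_t p = 0; p + k <= s.size(); ++p) {
      uint64_t key;
      if (!encode_kmer(s, p, k, &key)) continue;
      idx->map[key].push_back(((uint64_t)sid << 32) | (uint64_t)p);
    }
  }
  XPtr<KmerIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
List kmer_index_info(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  IntegerVector lens(idx->seqs.size());
  CharacterVector nms(idx->seqs.size());
  for (size_t i = 0; i < idx->seqs.size(); ++i) {
    lens[i] = (int)idx->seqs[i].size();
    nms[i] = idx->names[i];
  }
  return List::create(_["k"] = idx->k, _["names"] = nms, _["lengths"] = lens);
}

static inline int count_mm(const std::string& read, const std::string& tgt,
                           size_t pos, int max_mm) {
  int mm = 0;
  for (size_t i = 0; i < read.size(); ++i) {
    char a = read[i], b = tgt[pos + i];
    if (a >= 'a') a -= 32;
    if (b >= 'a') b -= 32;
    if (a != b || a == 'N') {
      if (++mm > max_mm) return mm;
    }
  }
  return mm;
}

// Enumerate end-to-end placements of one oriented read; append to output.
static void find_placements(const KmerIndex* idx, const std::string& read,
                            int max_mm, int strand_code,
                            std::unordered_set<uint64_t>& seen,
                            std::vector<int>& out_sid,
                            std::vector<int>& out_pos,
                            std::vector<int>& out_strand,
                            std::vector<int>& out_mm, int max_hits,
                            int& n_found) {
  const int k = idx->k;
  const int L = (int)read.size();
  if (L < k) return;
  int nseg = max_mm + 1;
  if (L < nseg * k) nseg = L / k;  // degraded sensitivity for short reads
  if (nseg < 1) return;
  for (int s = 0; s < nseg; ++s) {
    int sp = (int)((double)s * L / nseg);
    if (sp + k > L) sp = L - k;
    uint64_t key;
    if (!encode_kmer(read, sp, k, &key)) continue;
    auto it = idx->map.find(key);
    if (it == idx->map.end()) continue;
    for (uint64_t packed : it->second) {
      int sid = (int)(packed >> 32);
      long p = (long)(packed & 0xffffffffULL);
      long pos0 = p - sp;
      if (pos0 < 0) continue;
      const std::string& tgt = idx->seqs[sid];
      if (pos0 + L > (long)tgt.size()) continue;
      uint64_t ck = ((uint64_t)sid << 40) | ((uint64_t)pos0 << 2) |
                    (uint64_t)strand_code;
      if (!seen.insert(ck).second) continue;
      int mm = count_mm(read, tgt, (size_t)pos0, max_mm);
      if (mm <= max_mm) {
        ++n_found;
        if ((int)out_sid.size() < max_hits) {
          out_sid.push_back(sid + 1);
          out_pos.push_back((int)pos0);
          out_strand.push_back(strand_code);
          out_mm.push_back(mm);
        }
      }
    }
  }
}

// For each read, all distinct end-to-end placements with <= max_mm
// substitutions (strand "-" means the reverse complement of the read matches
// the forward target at the reported position). Returns a hits data.frame
// plus per-read total hit counts.
// [[Rcpp::export]]
List kmer_match_reads(SEXP xp, CharacterVector reads, int max_mm,
                      bool both_strands, int max_hits_per_read) {
  XPtr<KmerIndex> idx(xp);
  std::vector<int> h_read, h_sid, h_pos, h_strand, h_mm;
  IntegerVector nhits(reads.size());
  for (int r = 0; r < reads.size(); ++r) {
    std::string fw = as<std::string>(reads[r]);
    std::unordered_set<uint64_t> seen;
    std::vector<int> sid, pos, strand, mm;
    int n_found = 0;
    find_placements(idx, fw, max_mm, 0, seen, sid, pos, strand, mm,
                    max_hits_per_read, n_found);
    if (both_strands) {
      std::string rc = revcomp(fw);
      find_placements(idx, rc, max_mm, 1, seen, sid, pos, strand, mm,
                      max_hits_per_read, n_found);
    }
    nhits[r] = n_found;
    for (size_t i = 0; i < sid.size(); ++i) {
      h_read.push_back(r + 1);
      h_sid.push_back(sid[i]);
      h_pos.push_back(pos[i]);
      h_strand.push_back(strand[i]);
      h_mm.push_back(mm[i]);
    }
  }
  return List::create(
      _["hits"] = DataFrame::create(
          _["read"] = wrap(h_read), _["seq"] = wrap(h_sid),
          _["pos"] = wrap(h_pos), _["strand"] = wrap(h_strand),
          _["mm"] = wrap(h_mm)),
      _["n_hits"] = nhits);
}

// Exact hits of k-length anchors, both strands.
// [[Rcpp::export]]
DataFrame kmer_anchor_hits(SEXP xp, CharacterVector anchors) {
  XPtr<KmerIndex> idx(xp);
  const int k = idx->k;
  std::vector<int> h_anchor, h_sid, h_pos, h_strand;
  for (int a = 0; a < anchors.size(); ++a) {
    std::string fw = as<std::string>(anchors[a]);
    if ((int)fw.size() != k) stop("anchor length must equal index k");
    for (int strand_code = 0; strand_code < 2; ++strand_code) {
      std::string q = strand_code ? revcomp(fw) : fw;
      uint64_t key;
      if (!encode_kmer(q, 0, k, &key)) continue;
      auto it = idx->map.find(key);
      if (it == idx->map.end()) continue;
      for (uint64_t packed : it->second) {
        h_anchor.push_back(a + 1);
        h_sid.push_back((int)(packed >> 32) + 1);
        h_pos.push_back((int)(packed & 0xffffffffULL));
        h_strand.push_back(strand_code);
      }
    }
  }
  return DataFrame::create(_["anchor"] = wrap(h_anchor),
                           _["seq"] = wrap(h_sid), _["pos"] = wrap(h_pos),
                           _["strand"] = wrap(h_strand));
}
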