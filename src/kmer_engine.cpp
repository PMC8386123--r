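#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// 2-bit base encoding; -1 for anything outside {A,C,G,T}
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

// k-mer index shared by the screening, mapping and homology-search code:
// an exact hash of reference k-mer start positions plus a small bitmap
// prefilter that rejects most non-matching windows with one memory probe.
struct KIndex {
  int k;
  uint64_t mask;
  std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > map;
  std::vector<uint64_t> bloom;  // 2^24-bit presence filter
  bool maybe(uint64_t key) const {
    uint32_t b = (uint32_t)(key ^ (key >> 24)) & 0xFFFFFFu;
    return (bloom[b >> 6] >> (b & 63)) & 1ULL;
  }
  void mark(uint64_t key) {
    uint32_t b = (uint32_t)(key ^ (key >> 24)) & 0xFFFFFFu;
    bloom[b >> 6] |= 1ULL << (b & 63);
  }
};

static KIndex *build_index(CharacterVector refs, int k) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  KIndex *idx = new KIndex();
  idx->k = k;
  idx->mask = (1ULL << (2 * k)) - 1;
  idx->bloom.assign(1u << 18, 0ULL);
  for (int r = 0; r < refs.size(); ++r) {
    const char *s = CHAR(STRING_ELT(refs, r));
    int len = LENGTH(STRING_ELT(refs, r));
    uint64_t key = 0;
    int valid = 0;
    for (int i = 0; i < len; ++i) {
      int c = base_code(s[i]);
      if (c < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & idx->mask;
      if (++valid >= k) {
        idx->map[key].push_back(std::make_pair(r + 1, i - k + 2));
        idx->mark(key);
      }
    }
  }
  return idx;
}

static DataFrame scan_reads(const KIndex &index, CharacterVector reads,
                            CharacterVector quals, int min_q,
                            int qual_offset) {
  int k = index.k;
  const uint64_t mask = index.mask;
  bool use_qual = quals.size() > 0;
  if (use_qual && quals.size() != reads.size())
    stop("quals must be empty or match reads in length");

  std::vector<int> out_read, out_rpos, out_ref, out_refpos;
  std::vector<int> out_fwd;

  for (int q = 0; q < reads.size(); ++q) {
    const char *s = CHAR(STRING_ELT(reads, q));
    int len = LENGTH(STRING_ELT(reads, q));
    const char *qs = NULL;
    if (use_qual) {
      qs = CHAR(STRING_ELT(quals, q));
      if (LENGTH(STRING_ELT(quals, q)) != len)
        stop("quality string length differs from read length");
    }
    uint64_t fkey = 0, rkey = 0;
    int valid = 0;
    for (int i = 0; i < len; ++i) {
      int c = base_code(s[i]);
      if (c < 0) { valid = 0; fkey = 0; rkey = 0; continue; }
      fkey = ((fkey << 2) | (uint64_t)c) & mask;
      rkey = (rkey >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
      if (++valid < k) continue;
      int win_start = i - k + 1;  // 0-based
      bool fhit = index.maybe(fkey);
      bool rhit = (rkey != fkey) && index.maybe(rkey);
      if (!fhit && !rhit) continue;
      if (use_qual) {
        bool ok = true;
        for (int j = win_start; j <= i; ++j)
          if ((int)qs[j] - qual_offset < min_q) { ok = false; break; }
        if (!ok) continue;
      }
      std::unordered_map<uint64_t,
                         std::vector<std::pair<int, int> > >::const_iterator it;
      if (fhit) {
        it = index.map.find(fkey);
        if (it != index.map.end()) {
          for (size_t h = 0; h < it->second.size(); ++h) {
            out_read.push_back(q + 1);
            out_rpos.push_back(win_start + 1);
            out_ref.push_back(it->second[h].first);
            out_refpos.push_back(it->second[h].second);
            out_fwd.push_back(1);
          }
        }
      }
      if (rhit) {
        it = index.map.find(rkey);
        if (it != index.map.end()) {
          for (size_t h = 0; h < it->second.size(); ++h) {
            out_read.push_back(q + 1);
            out_rpos.push_back(win_start + 1);
            out_ref.push_back(it->second[h].first);
            out_refpos.push_back(it->second[h].second);
            out_fwd.push_back(0);
          }
        }
      }
    }
  }

  return DataFrame::create(
    Named("read") = wrap(out_read),
    Named("read_pos") = wrap(out_rpos),
    Named("ref") = wrap(out_ref),
    Named("ref_pos") = wrap(out_refpos),
    Named("fwd") = LogicalVector(out_fwd.begin(), out_fwd.end()));
}

// Exact k-mer hits of every read against a set of reference sequences,
// both strands. Reverse-complement hits are reported at the forward-strand
// start of the reference k-mer (strand = FALSE). If `quals` is non-empty a
// hit is only reported when every base of the matching read window has
// Phred >= min_q. All positions are 1-based. k <= 31.
// [[Rcpp::export]]
DataFrame kmer_hits_cpp(CharacterVector refs, CharacterVector reads, int k,
                        CharacterVector quals, int min_q, int qual_offset) {
  KIndex *idx = build_index(refs, k);
  DataFrame out = scan_reads(*idx, reads, quals, min_q, qual_offset);
  delete idx;
  return out;
}

// Prebuild a reference k-mer index for repeated scans.
// [[Rcpp::export]]
SEXP kmer_index_build_cpp(CharacterVector refs, int k) {
  XPtr<KIndex> ptr(build_index(refs, k), true);
  return ptr;
}

// Scan reads against a prebuilt index.
// [[Rcpp::export]]
DataFrame kmer_hits_prebuilt_cpp(SEXP index_ptr, CharacterVector reads,
                                 CharacterVector quals, int min_q,
                                 int qual_offset) {
  XPtr<KIndex> ptr(index_ptr);
  return scan_reads(*ptr, reads, quals, min_q, qual_offset);
}

// Union-find over n elements with unions (a[i], b[i]); returns component
// labels relabelled to consecutive integers in order of first appearance.
// [[Rcpp::export]]
IntegerVector uf_components_cpp(int n, IntegerVector a, IntegerVector b) {
  if (a.size() != b.size()) stop("a and b must have equal length");
  std::vector<int> parent(n + 1);
  for (int i = 0; i <= n; ++i) parent[i] = i;
  struct Find {
    std::vector<int> &p;
    Find(std::vector<int> &p_) : p(p_) {}
    int operator()(int x) {
      int root = x;
      while (p[root] != root) root = p[root];
      while (p[x] != root) { int nxt = p[x]; p[x] = root; x = nxt; }
      return root;
    }
  } find(parent);
  for (int j = 0; j < a.size(); ++j) {
    int ra = find(a[j]), rb = find(b[j]);
    if (ra != rb) parent[ra > rb ? ra : rb] = ra < rb ? ra : rb;
  }
  IntegerVector out(n);
  std::unordered_map<int, int> relabel;
  int next = 0;
  for (int i = 1; i <= n; ++i) {
    int r = find(i);
    std::unordered_map<int, int>::iterator it = relabel.find(r);
    if (it == relabel.end()) { relabel[r] = ++next; out[i - 1] = next; }
    else out[i - 1] = it->second;
  }
  return out;
}

// BWA-style 3' quality trim: for each read return the length of the kept
// prefix, i.e. the argmax over trim points of sum(cutoff - q) over the
// removed suffix (no trimming when all suffix sums are <= 0).
// [[Rcpp::export]]
IntegerVector trim_len_cpp(CharacterVector quals, int cutoff, int qual_offset) {
  int n = quals.size();
  IntegerVector out(n);
  for (int r = 0; r < n; ++r) {
    const char *qs = CHAR(STRING_ELT(quals, r));
    int len = LENGTH(STRING_ELT(quals, r));
    long best = 0, s = 0;
    int keep = len;
    for (int i = len - 1; i >= 0; --i) {
      s += cutoff - ((int)qs[i] - qual_offset);
      if (s < 0) break;
      if (s > best) { best = s; keep = i; }
    }
    out[r] = keep;
  }
  return out;
}

// Hamming distance between paired strings over their common prefix length.
// [[Rcpp::export]]
IntegerVector mismatch_pairs_cpp(CharacterVector a, CharacterVector b) {
  if (a.size() != b.size()) stop("a and b must have equal length");
  int n = a.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *sa = CHAR(STRING_ELT(a, i));
    const char *sb = CHAR(STRING_ELT(b, i));
    int la = LENGTH(STRING_ELT(a, i)), lb = LENGTH(STRING_ELT(b, i));
    int l = la < lb ? la : lb, m = 0;
    for (int j = 0; j < l; ++j) if (sa[j] != sb[j]) ++m;
    out[i] = m;
  }
  return out;
}

// Simulate Phred quality strings: per-base Gaussian around a position-
// dependent mean, clamped to [floor, ceiling]. The Gaussian is quantized
// to 256 inverse-CDF levels per position (one uniform draw per base), so
// generation is fast while remaining reproducible under set.seed().
// [[Rcpp::export]]
CharacterVector qual_strings_cpp(int n, NumericVector mean_curve, double sd,
                                 int q_floor, int q_ceiling, int qual_offset) {
  int len = mean_curve.size();
  // per-position lookup table of output characters over 256 quantiles
  std::vector<char> table((size_t)len * 256);
  for (int i = 0; i < len; ++i) {
    for (int s = 0; s < 256; ++s) {
      double z = R::qnorm((s + 0.5) / 256.0, 0.0, 1.0, 1, 0);
      int qv = (int)(mean_curve[i] + sd * z + 0.5);
      if (qv < q_floor) qv = q_floor;
      if (qv > q_ceiling) qv = q_ceiling;
      table[(size_t)i * 256 + s] = (char)(qv + qual_offset);
    }
  }
  CharacterVector out(n);  // RNGScope is provided by the Rcpp wrapper
  std::string buf(len, '!');
  for (int r = 0; r < n; ++r) {
    for (int i = 0; i < len; ++i) {
      int s = (int)(unif_rand() * 256.0);
      if (s > 255) s = 255;
      buf[i] = table[(size_t)i * 256 + s];
    }
    out[r] = buf;
  }
  return out;
}
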