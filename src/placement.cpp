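// Seed-and-verify read placement against a concatenated multi-chromosome
// reference. A sorted table of every forward-strand k-mer serves as the seed
// index; candidate locations from non-overlapping seed offsets (read and
// reverse complement) are verified by full-length Hamming distance.
//
// With s = floor(read_length / k) disjoint seeds per strand and
// max_mismatch < s, every location within max_mismatch mismatches shares at
// least one exact seed with the read (pigeonhole), so unique/multi/unplaced
// status is exact with respect to an exhaustive scan.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

// FNV-1a over all sequences; used as the index's reference checksum
// [[Rcpp::export]]
std::string cpp_reference_digest(CharacterVector seqs) {
  uint64_t h = 1469598103934665603ULL;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    for (const char* p = s; *p; ++p) {
      h ^= (uint64_t)(unsigned char)(*p);
      h *= 1099511628211ULL;
    }
    h ^= 0xFFULL;  // record separator
    h *= 1099511628211ULL;
  }
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return std::string(buf);
}

// [[Rcpp::export]]
List cpp_build_index(CharacterVector seqs, int k) {
  if (k < 1) stop("k must be positive");
  R_xlen_t n = seqs.size();
  std::vector<uint64_t> offsets(n + 1, 0);
  uint64_t total = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t len = LENGTH(STRING_ELT(seqs, i));
    offsets[i + 1] = offsets[i] + len;
    if (len >= (uint64_t)k) total += len - k + 1;
  }

  std::vector<std::pair<uint64_t, uint64_t> > tab;
  tab.reserve(total);
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    uint64_t len = LENGTH(STRING_ELT(seqs, i));
    uint64_t kmer = 0;
    int valid = 0;
    for (uint64_t j = 0; j < len; ++j) {
      int c = base_code(s[j]);
      if (c < 0) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)c) & mask;
      if (++valid >= k) {
        tab.push_back(std::make_pair(kmer, offsets[i] + j - k + 1));
      }
    }
  }
  std::sort(tab.begin(), tab.end());

  NumericVector kmers(tab.size()), gpos(tab.size());
  for (size_t i = 0; i < tab.size(); ++i) {
    kmers[i] = (double)tab[i].first;
    gpos[i] = (double)tab[i].second;
  }
  NumericVector off(n + 1);
  for (R_xlen_t i = 0; i <= n; ++i) off[i] = (double)offsets[i];
  return List::create(_["kmers"] = kmers, _["gpos"] = gpos,
                      _["offsets"] = off, _["k"] = k);
}

struct Candidate {
  uint64_t gpos;
  int mismatches;
  char strand;
};

static void gather_candidates(const std::string& read,
                              const std::vector<double>& kmers,
                              const std::vector<double>& gpos,
                              int k, char strand,
                              std::vector<std::pair<uint64_t, char> >& out) {
  int len = (int)read.size();
  if (len < k) return;
  std::vector<int> offs;
  for (int o = 0; o + k <= len; o += k) offs.push_back(o);
  if (offs.empty() || offs.back() != len - k) offs.push_back(len - k);
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  for (size_t oi = 0; oi < offs.size(); ++oi) {
    int o = offs[oi];
    uint64_t kmer = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int c = base_code(read[o + j]);
      if (c < 0) { ok = false; break; }
      kmer = ((kmer << 2) | (uint64_t)c) & mask;
    }
    if (!ok) continue;
    double key = (double)kmer;
    std::vector<double>::const_iterator lo =
        std::lower_bound(kmers.begin(), kmers.end(), key);
    for (; lo != kmers.end() && *lo == key; ++lo) {
      uint64_t hit = (uint64_t)gpos[lo - kmers.begin()];
      if (hit >= (uint64_t)o) out.push_back(std::make_pair(hit - o, strand));
    }
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
      case 'A': r[i] = 'T'; break;
      case 'C': r[i] = 'G'; break;
      case 'G': r[i] = 'C'; break;
      case 'T': r[i] = 'A'; break;
    }
  }
  return r;
}

// [[Rcpp::export]]
List cpp_place_reads(CharacterVector reads, List index, CharacterVector seqs,
                     int max_mismatch) {
  NumericVector kmers_nv = index["kmers"];
  NumericVector gpos_nv = index["gpos"];
  NumericVector off_nv = index["offsets"];
  int k = as<int>(index["k"]);
  std::vector<double> kmers(kmers_nv.begin(), kmers_nv.end());
  std::vector<double> gpos(gpos_nv.begin(), gpos_nv.end());
  std::vector<uint64_t> offsets(off_nv.size());
  for (R_xlen_t i = 0; i < off_nv.size(); ++i) offsets[i] = (uint64_t)off_nv[i];

  // concatenated reference for Hamming verification
  std::string genome;
  genome.reserve(offsets.back());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) genome += CHAR(STRING_ELT(seqs, i));

  R_xlen_t n = reads.size();
  IntegerVector chrom_idx(n), start(n), mism(n);
  CharacterVector strand(n), status(n);

  std::vector<std::pair<uint64_t, char> > cands;
  for (R_xlen_t ri = 0; ri < n; ++ri) {
    std::string fwd = CHAR(STRING_ELT(reads, ri));
    int len = (int)fwd.size();
    if (len < k) stop("read shorter than seed length k");
    std::string rc = revcomp_str(fwd);

    cands.clear();
    gather_candidates(fwd, kmers, gpos, k, '+', cands);
    gather_candidates(rc, kmers, gpos, k, '-', cands);
    std::sort(cands.begin(), cands.end());
    cands.erase(std::unique(cands.begin(), cands.end()), cands.end());

    // score candidates; locations are deduplicated by gpos so a +/- tie at
    // the same start counts as one location
    std::vector<Candidate> scored;
    for (size_t ci = 0; ci < cands.size(); ++ci) {
      uint64_t g = cands[ci].first;
      char st = cands[ci].second;
      // containing chromosome; alignment must stay within it
      size_t ch = std::upper_bound(offsets.begin(), offsets.end(), g) -
                  offsets.begin() - 1;
      if (g + len > offsets[ch + 1]) continue;
      const std::string& q = (st == '+') ? fwd : rc;
      int mm = 0;
      for (int j = 0; j < len && mm <= max_mismatch; ++j) {
        if (genome[g + j] != q[j]) ++mm;
      }
      if (mm > max_mismatch) continue;
      bool merged = false;
      for (size_t si = 0; si < scored.size(); ++si) {
        if (scored[si].gpos == g) {
          if (mm < scored[si].mismatches) {
            scored[si].mismatches = mm;
            scored[si].strand = st;
          }
          merged = true;
          break;
        }
      }
      if (!merged) {
        Candidate c;
        c.gpos = g; c.mismatches = mm; c.strand = st;
        scored.push_back(c);
      }
    }

    if (scored.empty()) {
      chrom_idx[ri] = NA_INTEGER; start[ri] = NA_INTEGER;
      mism[ri] = NA_INTEGER; strand[ri] = NA_STRING;
      status[ri] = "unplaced";
      continue;
    }
    int best = max_mismatch + 1;
    for (size_t si = 0; si < scored.size(); ++si) {
      best = std::min(best, scored[si].mismatches);
    }
    int nbest = 0;
    size_t bi = 0;
    for (size_t si = 0; si < scored.size(); ++si) {
      if (scored[si].mismatches == best) {
        if (nbest == 0) bi = si;
        ++nbest;
      }
    }
    uint64_t g = scored[bi].gpos;
    size_t ch = std::upper_bound(offsets.begin(), offsets.end(), g) -
                offsets.begin() - 1;
    chrom_idx[ri] = (int)ch + 1;
    start[ri] = (int)(g - offsets[ch]);
    mism[ri] = best;
    strand[ri] = std::string(1, scored[bi].strand);
    status[ri] = (nbest >= 2) ? "multi" : "unique";
  }

  return List::create(_["chrom_idx"] = chrom_idx, _["start"] = start,
                      _["strand"] = strand, _["mismatches"] = mism,
                      _["status"] = status);
}

// per-base substitution errors at `rate`, drawing from R's RNG so results are
// reproducible under set.seed()
// [[Rcpp::export]]
CharacterVector cpp_add_errors(CharacterVector seqs, double rate) {
  const char* bases = "ACGT";
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = CHAR(STRING_ELT(seqs, i));
    for (size_t j = 0; j < s.size(); ++j) {
      if (unif_rand() < rate) {
        int cur = base_code(s[j]);
        int shift = 1 + (int)(unif_rand() * 3.0);
        if (shift > 3) shift = 3;
        s[j] = bases[(cur + shift) % 4];
      }
    }
    out[i] = s;
  }
  return out;
}
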