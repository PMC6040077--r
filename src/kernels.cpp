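#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Base encoding: A=0, C=1, G=2, T=3, anything else (incl. N) = -1.
static inline int enc(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char dec(int b) {
  static const char L[4] = {'A', 'C', 'G', 'T'};
  return L[b];
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    int b = enc(c);
    c = (b < 0) ? 'N' : dec(3 - b);
  }
  return r;
}

// -------------------------------------------------------------------
// Markov-chain sequence generation (order 0..3), driven by R's RNG so
// that set.seed() governs reproducibility.
// trans has 4^order rows (context, base-4 big-endian) and 4 columns,
// each row a probability distribution over the next base.
// [[Rcpp::export]]
std::string cpp_markov_seq(int len, int order, NumericMatrix trans) {
  if (len < 1) stop("len must be >= 1");
  if (order < 0 || order > 3) stop("order must be in 0..3");
  int nctx = 1;
  for (int i = 0; i < order; ++i) nctx *= 4;
  if (trans.nrow() != nctx || trans.ncol() != 4)
    stop("transition matrix must be 4^order x 4");
  std::string s(len, 'A');
  int ctx = 0;
  int mask = nctx - 1; // nctx is a power of 4
  for (int i = 0; i < len; ++i) {
    // before `order` bases exist the context is zero-padded (A-padded)
    int row = ctx & mask;
    double u = unif_rand();
    double acc = 0.0;
    int b = 3;
    for (int j = 0; j < 4; ++j) {
      acc += trans(row, j);
      if (u <= acc) { b = j; break; }
    }
    s[i] = dec(b);
    ctx = ((ctx << 2) | b) & mask;
  }
  return s;
}

// -------------------------------------------------------------------
// k-mer index over a set of subject sequences.
struct KmerIndex {
  int k;
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> map; // kmer -> (seq, pos)
};

static void index_sequences(const std::vector<std::string>& seqs, int k,
                            int stride, KmerIndex& idx) {
  idx.k = k;
  for (size_t s = 0; s < seqs.size(); ++s) {
    const std::string& g = seqs[s];
    int n = (int)g.size();
    if (n < k) continue;
    for (int i = 0; i + k <= n; i += stride) {
      uint64_t key = 0;
      bool ok = true;
      for (int j = 0; j < k; ++j) {
        int b = enc(g[i + j]);
        if (b < 0) { ok = false; break; }
        key = (key << 2) | (uint64_t)b;
      }
      if (ok) idx.map[key].push_back({(int)s, i});
    }
  }
}

// Best ungapped local segment along one diagonal (Kadane, match +1,
// mismatch/N -2).  Returns score; fills matches, columns, gstart.
static int diag_best_segment(const std::string& read, const std::string& gen,
                             long diag, int& matches, int& columns,
                             long& gstart) {
  long Lr = (long)read.size(), Lg = (long)gen.size();
  long lo = std::max(0L, -diag);
  long hi = std::min(Lr, Lg - diag);
  if (hi <= lo) { matches = 0; columns = 0; gstart = -1; return -1; }
  long best_s = -1, best_e = -1;
  int best = -1, cur = 0;
  long cur_start = lo;
  for (long i = lo; i < hi; ++i) {
    int br = enc(read[i]);
    int bg = enc(gen[i + diag]);
    int sc = (br >= 0 && br == bg) ? 1 : -2;
    if (cur + sc < 0) { cur = 0; cur_start = i + 1; }
    else {
      cur += sc;
      if (cur > best) { best = cur; best_s = cur_start; best_e = i; }
    }
  }
  if (best < 0) { matches = 0; columns = 0; gstart = -1; return -1; }
  matches = 0;
  for (long i = best_s; i <= best_e; ++i) {
    int br = enc(read[i]);
    if (br >= 0 && br == enc(gen[i + diag])) ++matches;
  }
  columns = (int)(best_e - best_s + 1);
  gstart = best_s + diag;
  return best;
}

// -------------------------------------------------------------------
// Read recruitment: best qualifying hit per read over a set of subject
// sequences (genomes, contigs or gene references), both strands,
// seed-and-extend with ungapped maximal-scoring segment per diagonal.
// Subjects are assumed pre-sorted by id by the caller; score ties break
// toward the lower subject index.
// [[Rcpp::export]]
DataFrame cpp_recruit(CharacterVector reads, CharacterVector subjects,
                      double min_identity, int min_aln_len,
                      int k, int seed_stride) {
  std::vector<std::string> subj(subjects.size());
  for (int i = 0; i < subjects.size(); ++i) subj[i] = as<std::string>(subjects[i]);
  KmerIndex idx;
  index_sequences(subj, k, 1, idx);

  std::vector<int> o_read, o_subj, o_len, o_match, o_strand;
  std::vector<double> o_ident, o_gstart;

  int nr = reads.size();
  for (int r = 0; r < nr; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    std::string rev = revcomp(fwd);
    int best_subj = -1, best_score = -1, best_len = 0, best_match = 0, best_strand = 1;
    long best_gstart = -1;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& rd = strand == 0 ? fwd : rev;
      int Lr = (int)rd.size();
      if (Lr < k) continue;
      // collect candidate (subject, diagonal) pairs
      std::vector<std::pair<int,long>> cand;
      for (int i = 0; i + k <= Lr; i += seed_stride) {
        uint64_t key = 0; bool ok = true;
        for (int j = 0; j < k; ++j) {
          int b = enc(rd[i + j]);
          if (b < 0) { ok = false; break; }
          key = (key << 2) | (uint64_t)b;
        }
        if (!ok) continue;
        auto it = idx.map.find(key);
        if (it == idx.map.end()) continue;
        for (auto& hit : it->second)
          cand.push_back({hit.first, (long)hit.second - i});
      }
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      for (auto& c : cand) {
        int matches, columns; long gstart;
        int sc = diag_best_segment(rd, subj[c.first], c.second,
                                   matches, columns, gstart);
        if (sc < 0 || columns < min_aln_len) continue;
        double ident = 100.0 * matches / columns;
        if (ident < min_identity) continue;
        bool better = sc > best_score ||
          (sc == best_score && c.first < best_subj);
        if (better) {
          best_subj = c.first; best_score = sc; best_len = columns;
          best_match = matches; best_strand = strand == 0 ? 1 : -1;
          best_gstart = gstart;
        }
      }
    }
    if (best_subj >= 0) {
      o_read.push_back(r + 1);
      o_subj.push_back(best_subj + 1);
      o_len.push_back(best_len);
      o_match.push_back(best_match);
      o_strand.push_back(best_strand);
      o_ident.push_back(100.0 * best_match / best_len);
      o_gstart.push_back((double)best_gstart);
    }
  }
  return DataFrame::create(
    _["read"] = o_read, _["subject"] = o_subj,
    _["identity"] = o_ident, _["aln_len"] = o_len,
    _["matches"] = o_match, _["strand"] = o_strand,
    _["subject_start"] = o_gstart);
}

// -------------------------------------------------------------------
// Read-vs-read end-to-end matching for whole-metagenome similarity.
// Global identity of query q against target t placed at diagonal d:
// columns = full alignment span including end gaps, matches counted in
// the overlap.  Returns, per query read, the best global identity over
// candidate targets and strands (0 when no seed candidate).  Candidates
// whose span alone caps identity below `min_identity` are skipped, and
// the scan stops early once a match at or above it is found, so the
// returned value is exact with respect to the >= min_identity test.
// [[Rcpp::export]]
NumericVector cpp_read_best_global(CharacterVector queries,
                                   CharacterVector targets,
                                   int k, int seed_stride,
                                   double min_identity) {
  std::vector<std::string> tg(targets.size());
  for (int i = 0; i < targets.size(); ++i) tg[i] = as<std::string>(targets[i]);
  KmerIndex idx;
  index_sequences(tg, k, 1, idx);

  int nq = queries.size();
  NumericVector out(nq);
  for (int q = 0; q < nq; ++q) {
    std::string fwd = as<std::string>(queries[q]);
    std::string rev = revcomp(fwd);
    double best = 0.0;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& rd = strand == 0 ? fwd : rev;
      long Lq = (long)rd.size();
      if (Lq < k) continue;
      std::vector<std::pair<int,long>> cand;
      for (int i = 0; i + k <= (int)Lq; i += seed_stride) {
        uint64_t key = 0; bool ok = true;
        for (int j = 0; j < k; ++j) {
          int b = enc(rd[i + j]);
          if (b < 0) { ok = false; break; }
          key = (key << 2) | (uint64_t)b;
        }
        if (!ok) continue;
        auto it = idx.map.find(key);
        if (it == idx.map.end()) continue;
        for (auto& hit : it->second) {
          long d = (long)i - hit.second; // d: t[j] ~ q[j+d]
          long Lt = (long)tg[hit.first].size();
          long ov = std::min(Lq, Lt + d) - std::max(0L, d);
          long columns = std::max(Lq, Lt + d) - std::min(0L, d);
          if (ov <= 0 || 100.0 * ov / columns < min_identity) continue;
          cand.push_back({hit.first, d});
        }
      }
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      for (auto& c : cand) {
        const std::string& t = tg[c.first];
        long Lt = (long)t.size(), d = c.second;
        long ov_lo = std::max(0L, d);
        long ov_hi = std::min(Lq, Lt + d);
        long columns = std::max(Lq, Lt + d) - std::min(0L, d);
        long matches = 0;
        for (long i = ov_lo; i < ov_hi; ++i) {
          int bq = enc(rd[i]);
          if (bq >= 0 && bq == enc(t[i - d])) ++matches;
        }
        double ident = 100.0 * matches / columns;
        if (ident > best) best = ident;
        if (best >= min_identity) break;
      }
      if (best >= min_identity) break;
    }
    out[q] = best;
  }
  return out;
}

// -------------------------------------------------------------------
// Best ungapped placement of each read along a positional log-odds
// profile (4 x W).  Positions with non-ACGT bases contribute 0.  Both
// strands are scored; the per-base mean of the best placement is
// returned.
// [[Rcpp::export]]
NumericVector cpp_pwm_best(CharacterVector reads, NumericMatrix pwm) {
  if (pwm.nrow() != 4) stop("pwm must have 4 rows (A,C,G,T)");
  int W = pwm.ncol();
  int nr = reads.size();
  NumericVector out(nr);
  for (int r = 0; r < nr; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    std::string rev = revcomp(fwd);
    int L = (int)fwd.size();
    double best = R_NegInf;
    if (L <= W) {
      for (int strand = 0; strand < 2; ++strand) {
        const std::string& rd = strand == 0 ? fwd : rev;
        for (int off = 0; off + L <= W; ++off) {
          double s = 0.0; int nb = 0;
          for (int i = 0; i < L; ++i) {
            int b = enc(rd[i]);
            if (b >= 0) { s += pwm(b, off + i); ++nb; }
          }
          if (nb > 0) {
            double m = s / nb;
            if (m > best) best = m;
          }
        }
      }
    }
    out[r] = (best == R_NegInf) ? NA_REAL : best;
  }
  return out;
}

// -------------------------------------------------------------------
// Canonical tetranucleotide frequencies: 4-mers and their reverse
// complements pooled into 136 canonical keys; windows containing N are
// skipped; each row normalised to sum to 1 (all-zero rows left as-is).
// [[Rcpp::export]]
NumericMatrix cpp_tnf(CharacterVector seqs) {
  // canonical map over the 256 4-mer codes
  std::vector<int> canon(256, -1);
  std::vector<int> col_of(256, -1);
  int ncol = 0;
  for (int code = 0; code < 256; ++code) {
    int rc = 0, c = code;
    for (int j = 0; j < 4; ++j) { rc = (rc << 2) | (3 - (c & 3)); c >>= 2; }
    int key = std::min(code, rc);
    canon[code] = key;
    if (code == key) col_of[code] = ncol++;
  }
  int ns = seqs.size();
  NumericMatrix out(ns, ncol);
  for (int s = 0; s < ns; ++s) {
    std::string g = as<std::string>(seqs[s]);
    int n = (int)g.size();
    double tot = 0.0;
    std::vector<double> counts(ncol, 0.0);
    int code = 0, valid = 0;
    for (int i = 0; i < n; ++i) {
      int b = enc(g[i]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | b) & 0xFF;
      if (++valid >= 4) {
        counts[col_of[canon[code]]] += 1.0;
        tot += 1.0;
      }
    }
    if (tot > 0) for (int j = 0; j < ncol; ++j) out(s, j) = counts[j] / tot;
  }
  // column names: canonical 4-mers
  CharacterVector cn(ncol);
  for (int code = 0; code < 256; ++code) {
    if (col_of[code] >= 0) {
      std::string km(4, 'A');
      int c = code;
      for (int j = 3; j >= 0; --j) { km[j] = dec(c & 3); c >>= 2; }
      cn[col_of[code]] = km;
    }
  }
  colnames(out) = cn;
  return out;
}

// -------------------------------------------------------------------
// Substitution noise on a set of reads, driven by R's RNG.  Each base
// is substituted with probability `rate` by one of the three other
// bases, uniformly.  N bases are left untouched.
// [[Rcpp::export]]
CharacterVector cpp_add_errors(CharacterVector reads, double rate) {
  if (rate < 0 || rate > 1) stop("rate must be in [0,1]");
  int nr = reads.size();
  CharacterVector out(nr);
  for (int r = 0; r < nr; ++r) {
    std::string s = as<std::string>(reads[r]);
    if (rate > 0) {
      for (size_t i = 0; i < s.size(); ++i) {
        int b = enc(s[i]);
        if (b < 0) continue;
        if (unif_rand() < rate) {
          int nb = (b + 1 + (int)(unif_rand() * 3)) & 3;
          if (nb == b) nb = (b + 1) & 3;
          s[i] = dec(nb);
        }
      }
    }
    out[r] = s;
  }
  return out;
}
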