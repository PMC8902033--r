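// Ungapped seed-and-extend local alignment on diagonals.
//
// The alignment model is deliberately ungapped: the simulators in this
// package mutate by substitution only, so every true homology lies on a
// single diagonal and "alignment columns" always equals aligned length.
// A hit is the maximum-scoring run (match +1, mismatch -2) on a diagonal;
// at most one hit per (strand, diagonal) can pass a >50% query-coverage
// filter, so reporting the single best run per diagonal is lossless.
// Candidate diagonals are found by exact shared k-mers; correctness is
// checked in the test suite against an all-diagonals oracle.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4; // never matches anything, excluded from k-mers
  }
}

static std::vector<uint8_t> encode(const std::string& s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (uint8_t) base_code(s[i]);
  return v;
}

static std::vector<uint8_t> revcomp(const std::vector<uint8_t>& v) {
  std::vector<uint8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    uint8_t b = v[v.size() - 1 - i];
    r[i] = b < 4 ? (uint8_t)(3 - b) : (uint8_t)4;
  }
  return r;
}

// k-mers as 2-bit packed integers; returns (kmer, position) pairs,
// skipping windows containing an ambiguous base.
static void collect_kmers(const std::vector<uint8_t>& seq, int k,
                          std::vector<std::pair<uint64_t,int> >& out) {
  out.clear();
  if ((int) seq.size() < k) return;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t cur = 0;
  int valid = 0;
  for (size_t i = 0; i < seq.size(); ++i) {
    if (seq[i] > 3) { valid = 0; cur = 0; continue; }
    cur = ((cur << 2) | seq[i]) & mask;
    if (++valid >= k) out.push_back(std::make_pair(cur, (int)(i - k + 1)));
  }
}

struct Segment {
  int q_start, q_end;   // 0-based half-open, in the oriented query
  int matches;
  bool found;
};

// Best-scoring run on diagonal d (query position i aligns target i + d).
// Ties resolved by first-encountered maximum in a left-to-right scan.
static Segment best_on_diagonal(const std::vector<uint8_t>& q,
                                const std::vector<uint8_t>& t,
                                int d) {
  int n = (int) q.size(), m = (int) t.size();
  int lo = std::max(0, -d), hi = std::min(n, m - d);
  Segment best; best.found = false; best.matches = 0;
  best.q_start = 0; best.q_end = 0;
  if (lo >= hi) return best;
  long cur = 0; int cur_start = lo, cur_matches = 0;
  long best_score = 0; // only positive-scoring runs qualify
  for (int i = lo; i < hi; ++i) {
    bool match = (q[i] < 4) && (q[i] == t[i + d]);
    long add = match ? 1 : -2;
    if (cur <= 0 && add > 0) { cur = 0; cur_start = i; cur_matches = 0; }
    cur += add;
    if (match) ++cur_matches;
    if (cur < 0) { cur = 0; cur_matches = 0; cur_start = i + 1; }
    else if (cur > best_score) {
      best_score = cur;
      best.q_start = cur_start;
      best.q_end = i + 1;
      best.matches = cur_matches;
      best.found = true;
    }
  }
  // trim leading mismatches kept by the bookkeeping (cur_start may sit on a
  // mismatch only when add<=0 started the run; guard by re-trimming edges)
  while (best.found && best.q_start < best.q_end &&
         !(q[best.q_start] < 4 && q[best.q_start] == t[best.q_start + d]))
    ++best.q_start;
  while (best.found && best.q_end > best.q_start &&
         !(q[best.q_end - 1] < 4 && q[best.q_end - 1] == t[best.q_end - 1 + d]))
    --best.q_end;
  return best;
}

struct Hit {
  int q_start, q_end, t_start, t_end, length, matches;
  double identity;
  char strand;
};

// Hits of one oriented query against a target, restricted to the given
// candidate diagonals; filters: identity > min_identity (strict),
// length >= min_hit_len, length/n > min_coverage (strict).
static void hits_for_orientation(const std::vector<uint8_t>& q,
                                 const std::vector<uint8_t>& t,
                                 const std::vector<int>& diagonals,
                                 double min_identity, double min_coverage,
                                 int min_hit_len, char strand, int n_orig,
                                 std::vector<Hit>& out) {
  int n = (int) q.size();
  for (size_t di = 0; di < diagonals.size(); ++di) {
    int d = diagonals[di];
    Segment s = best_on_diagonal(q, t, d);
    if (!s.found) continue;
    int len = s.q_end - s.q_start;
    if (len < min_hit_len || len < 1) continue;
    double identity = (double) s.matches / (double) len;
    if (!(identity > min_identity)) continue;
    if (!((double) len / (double) n > min_coverage)) continue;
    Hit h;
    h.length = len; h.matches = s.matches; h.identity = identity;
    h.strand = strand;
    h.t_start = s.q_start + d; h.t_end = s.q_end + d;
    if (strand == '+') { h.q_start = s.q_start; h.q_end = s.q_end; }
    else { h.q_start = n_orig - s.q_end; h.q_end = n_orig - s.q_start; }
    out.push_back(h);
  }
}

// Candidate diagonals from exact shared k-mers between oriented query and
// target (index built over the query, single scan of the target).
static std::vector<int> seed_diagonals(const std::vector<uint8_t>& q,
                                       const std::vector<uint8_t>& t,
                                       int k) {
  std::vector<std::pair<uint64_t,int> > qk, tk;
  collect_kmers(q, k, qk);
  std::unordered_map<uint64_t, std::vector<int> > index;
  index.reserve(qk.size() * 2);
  for (size_t i = 0; i < qk.size(); ++i) index[qk[i].first].push_back(qk[i].second);
  collect_kmers(t, k, tk);
  std::unordered_set<int> diags;
  for (size_t i = 0; i < tk.size(); ++i) {
    std::unordered_map<uint64_t, std::vector<int> >::iterator it =
      index.find(tk[i].first);
    if (it == index.end()) continue;
    const std::vector<int>& qpos = it->second;
    for (size_t j = 0; j < qpos.size(); ++j)
      diags.insert(tk[i].second - qpos[j]);
  }
  std::vector<int> out(diags.begin(), diags.end());
  std::sort(out.begin(), out.end());
  return out;
}

static DataFrame hits_to_df(std::vector<Hit>& hits,
                            const IntegerVector* read_idx = 0,
                            const std::vector<int>* read_of_hit = 0) {
  // sort by target position, then strand, then query start
  std::vector<size_t> ord(hits.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (hits[a].t_start != hits[b].t_start) return hits[a].t_start < hits[b].t_start;
    if (hits[a].strand != hits[b].strand) return hits[a].strand < hits[b].strand;
    return hits[a].q_start < hits[b].q_start;
  });
  size_t n = hits.size();
  IntegerVector qs(n), qe(n), ts(n), te(n), len(n), mat(n);
  NumericVector id(n);
  CharacterVector st(n);
  for (size_t i = 0; i < n; ++i) {
    const Hit& h = hits[ord[i]];
    qs[i] = h.q_start; qe[i] = h.q_end; ts[i] = h.t_start; te[i] = h.t_end;
    len[i] = h.length; mat[i] = h.matches; id[i] = h.identity;
    st[i] = std::string(1, h.strand);
  }
  return DataFrame::create(
    _["q_start"] = qs, _["q_end"] = qe, _["t_start"] = ts, _["t_end"] = te,
    _["length"] = len, _["matches"] = mat, _["identity"] = id,
    _["strand"] = st, _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
DataFrame cpp_local_align(std::string query, std::string target,
                          double min_identity, double min_coverage,
                          int min_hit_len, int seed_k) {
  std::vector<uint8_t> q = encode(query), t = encode(target);
  std::vector<uint8_t> qr = revcomp(q);
  std::vector<Hit> hits;
  std::vector<int> df = seed_diagonals(q, t, seed_k);
  hits_for_orientation(q, t, df, min_identity, min_coverage, min_hit_len,
                       '+', (int) q.size(), hits);
  std::vector<int> dr = seed_diagonals(qr, t, seed_k);
  hits_for_orientation(qr, t, dr, min_identity, min_coverage, min_hit_len,
                       '-', (int) q.size(), hits);
  return hits_to_df(hits);
}

// Map many reads against one contig; contig k-mer index is built once.
// Returns all per-hit records (identity/length filtered only); read-level
// coverage filtering is done by the caller.
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, std::string target,
                        double min_identity, int min_hit_len, int seed_k) {
  std::vector<uint8_t> t = encode(target);
  std::vector<std::pair<uint64_t,int> > tk;
  collect_kmers(t, seed_k, tk);
  std::unordered_map<uint64_t, std::vector<int> > tindex;
  tindex.reserve(tk.size() * 2);
  for (size_t i = 0; i < tk.size(); ++i) tindex[tk[i].first].push_back(tk[i].second);

  std::vector<Hit> hits;
  std::vector<int> read_of_hit;
  std::vector<std::pair<uint64_t,int> > qk;
  for (int r = 0; r < reads.size(); ++r) {
    std::string rs = as<std::string>(reads[r]);
    std::vector<uint8_t> q = encode(rs);
    for (int ori = 0; ori < 2; ++ori) {
      std::vector<uint8_t> qo = (ori == 0) ? q : revcomp(q);
      collect_kmers(qo, seed_k, qk);
      std::unordered_set<int> diags;
      for (size_t i = 0; i < qk.size(); ++i) {
        std::unordered_map<uint64_t, std::vector<int> >::iterator it =
          tindex.find(qk[i].first);
        if (it == tindex.end()) continue;
        for (size_t j = 0; j < it->second.size(); ++j)
          diags.insert(it->second[j] - qk[i].second);
      }
      std::vector<int> dv(diags.begin(), diags.end());
      std::sort(dv.begin(), dv.end());
      size_t before = hits.size();
      hits_for_orientation(qo, t, dv, min_identity, 0.0, min_hit_len,
                           ori == 0 ? '+' : '-', (int) q.size(), hits);
      for (size_t i = before; i < hits.size(); ++i) read_of_hit.push_back(r + 1);
    }
  }
  // assemble with read column, ordered by read then target position
  std::vector<size_t> ord(hits.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (read_of_hit[a] != read_of_hit[b]) return read_of_hit[a] < read_of_hit[b];
    if (hits[a].t_start != hits[b].t_start) return hits[a].t_start < hits[b].t_start;
    return hits[a].strand < hits[b].strand;
  });
  size_t n = hits.size();
  IntegerVector rd(n), qs(n), qe(n), ts(n), te(n), len(n), mat(n);
  NumericVector id(n);
  CharacterVector st(n);
  for (size_t i = 0; i < n; ++i) {
    const Hit& h = hits[ord[i]];
    rd[i] = read_of_hit[ord[i]];
    qs[i] = h.q_start; qe[i] = h.q_end; ts[i] = h.t_start; te[i] = h.t_end;
    len[i] = h.length; mat[i] = h.matches; id[i] = h.identity;
    st[i] = std::string(1, h.strand);
  }
  return DataFrame::create(
    _["read"] = rd, _["q_start"] = qs, _["q_end"] = qe,
    _["t_start"] = ts, _["t_end"] = te, _["length"] = len,
    _["matches"] = mat, _["identity"] = id, _["strand"] = st,
    _["stringsAsFactors"] = false);
}

// Similarity-graph edges for read clustering. Candidate pairs share at
// least one canonical k-mer (a lossless prefilter); a pair becomes an edge
// when some diagonal of either orientation carries an ungapped run with
// identity >= min_identity covering >= min_overlap_frac of the shorter read.
// [[Rcpp::export]]
List cpp_cluster_edges(CharacterVector reads, int k, double min_identity,
                       double min_overlap_frac, int bucket_cap) {
  int n = reads.size();
  std::vector<std::vector<uint8_t> > enc(n), enc_rc(n);
  std::vector<std::vector<std::pair<uint64_t,int> > > fwd_kmers(n);
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  std::unordered_map<uint64_t, std::vector<int> > buckets;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(reads[i]);
    enc[i] = encode(s);
    enc_rc[i] = revcomp(enc[i]);
    collect_kmers(enc[i], k, fwd_kmers[i]);
    std::unordered_set<uint64_t> canon_seen;
    for (size_t j = 0; j < fwd_kmers[i].size(); ++j) {
      uint64_t km = fwd_kmers[i][j].first;
      // reverse complement of the packed k-mer
      uint64_t rc = 0, x = km;
      for (int b = 0; b < k; ++b) { rc = (rc << 2) | (3 - (x & 3)); x >>= 2; }
      rc &= mask;
      uint64_t canon = std::min(km, rc);
      if (canon_seen.insert(canon).second) buckets[canon].push_back(i);
    }
  }

  std::unordered_set<uint64_t> seen_pairs;
  std::vector<int> from, to;
  std::unordered_map<uint64_t, std::vector<int> > qindex;

  for (std::unordered_map<uint64_t, std::vector<int> >::iterator bi =
         buckets.begin(); bi != buckets.end(); ++bi) {
    const std::vector<int>& v = bi->second;
    if ((int) v.size() < 2 || (int) v.size() > bucket_cap) continue;
    for (size_t a = 0; a < v.size(); ++a) {
      for (size_t b = a + 1; b < v.size(); ++b) {
        int i = v[a], j = v[b];
        uint64_t key = (uint64_t) i * (uint64_t) n + (uint64_t) j;
        if (!seen_pairs.insert(key).second) continue;
        // evaluate pair i, j
        qindex.clear();
        for (size_t q = 0; q < fwd_kmers[i].size(); ++q)
          qindex[fwd_kmers[i][q].first].push_back(fwd_kmers[i][q].second);
        int min_len = (int) std::min(enc[i].size(), enc[j].size());
        int need = (int) std::ceil(min_overlap_frac * (double) min_len);
        if (need < k) need = k;
        bool edge = false;
        for (int ori = 0; ori < 2 && !edge; ++ori) {
          const std::vector<uint8_t>& qj = (ori == 0) ? enc[j] : enc_rc[j];
          std::vector<std::pair<uint64_t,int> > jk;
          collect_kmers(qj, k, jk);
          std::unordered_set<int> diags;
          for (size_t q = 0; q < jk.size(); ++q) {
            std::unordered_map<uint64_t, std::vector<int> >::iterator it =
              qindex.find(jk[q].first);
            if (it == qindex.end()) continue;
            for (size_t w = 0; w < it->second.size(); ++w)
              diags.insert(it->second[w] - jk[q].second);
          }
          for (std::unordered_set<int>::iterator di = diags.begin();
               di != diags.end() && !edge; ++di) {
            Segment s = best_on_diagonal(qj, enc[i], *di);
            if (!s.found) continue;
            int len = s.q_end - s.q_start;
            if (len >= need &&
                (double) s.matches / (double) len >= min_identity)
              edge = true;
          }
        }
        if (edge) { from.push_back(i + 1); to.push_back(j + 1); }
      }
    }
  }
  return List::create(_["from"] = wrap(from), _["to"] = wrap(to));
}
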