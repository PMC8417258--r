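#include <Rcpp.h>
#include <unordered_set>
#include <unordered_map>
#include <vector>
#include <string>
#include <climits>
#include <cstdint>
#include <memory>

using namespace Rcpp;

// Local (Smith-Waterman) alignment with affine gaps, Gotoh recurrences.
// A gap of length L costs gap_open + L * gap_ext (both supplied as positive
// penalties). Coordinates are 0-based half-open. CIGAR ops: = X I D, where
// I consumes query only and D consumes reference only.

struct AlnResult {
  int score;
  int q_start, q_end, r_start, r_end;
  std::string cigar;
  int n_match, n_mismatch, n_ins, n_del;
};

static AlnResult sw_core(const std::string& q, const std::string& r,
                         int match, int mismatch, int gap_open, int gap_ext) {
  AlnResult out;
  out.score = 0; out.q_start = out.q_end = out.r_start = out.r_end = 0;
  out.n_match = out.n_mismatch = out.n_ins = out.n_del = 0;
  const int n = (int)q.size(), m = (int)r.size();
  if (n == 0 || m == 0) return out;
  if ((double)(n + 1) * (double)(m + 1) > 2.5e8)
    stop("alignment problem too large (%d x %d)", n, m);

  const int NEG = INT_MIN / 4;
  std::vector<int> Hp(m + 1, 0), Hc(m + 1, 0);
  std::vector<int> Ec(m + 1, NEG);            // gap in query (consumes ref)
  std::vector<int> Fp(m + 1, NEG), Fc(m + 1, NEG); // gap in ref (consumes query)
  // pointer matrices, (n+1) x (m+1), row-major; left uninitialised except
  // pH's border (every interior cell is written before it can be read)
  const size_t psz = (size_t)(n + 1) * (m + 1);
  std::unique_ptr<uint8_t[]> pH(new uint8_t[psz]); // 0 stop, 1 diag, 2 from E, 3 from F
  std::unique_ptr<uint8_t[]> pE(new uint8_t[psz]); // 1 opened from H, 0 extended
  std::unique_ptr<uint8_t[]> pF(new uint8_t[psz]);
  for (int j = 0; j <= m; ++j) pH[j] = 0;
  for (int i = 1; i <= n; ++i) pH[(size_t)i * (m + 1)] = 0;

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    Hc[0] = 0; Ec[0] = NEG; Fc[0] = NEG;
    const char qc = q[i - 1];
    const size_t row = (size_t)i * (m + 1);
    for (int j = 1; j <= m; ++j) {
      // E: consume reference (D op)
      int e_open = Hc[j - 1] - gap_open - gap_ext;
      int e_ext  = Ec[j - 1] - gap_ext;
      int e = (e_open >= e_ext) ? e_open : e_ext;
      pE[row + j] = (e_open >= e_ext) ? 1 : 0;
      Ec[j] = e;
      // F: consume query (I op)
      int f_open = Hp[j] - gap_open - gap_ext;
      int f_ext  = Fp[j] - gap_ext;
      int f = (f_open >= f_ext) ? f_open : f_ext;
      pF[row + j] = (f_open >= f_ext) ? 1 : 0;
      Fc[j] = f;
      // H
      int diag = Hp[j - 1] + ((qc == r[j - 1]) ? match : mismatch);
      int h = 0; uint8_t p = 0;
      if (diag > h) { h = diag; p = 1; }
      if (e > h)    { h = e;    p = 2; }
      if (f > h)    { h = f;    p = 3; }
      Hc[j] = h;
      pH[row + j] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hp, Hc);
    std::swap(Fp, Fc);
  }

  out.score = best;
  if (best <= 0) return out;

  // traceback
  std::string ops;
  int i = bi, j = bj;
  char state = 'H';
  while (true) {
    const size_t row = (size_t)i * (m + 1);
    if (state == 'H') {
      uint8_t p = pH[row + j];
      if (p == 0) break;
      if (p == 1) {
        ops.push_back(q[i - 1] == r[j - 1] ? '=' : 'X');
        --i; --j;
      } else if (p == 2) {
        state = 'E';
      } else {
        state = 'F';
      }
    } else if (state == 'E') {
      ops.push_back('D');
      uint8_t p = pE[row + j];
      --j;
      if (p == 1) state = 'H';
    } else { // F
      ops.push_back('I');
      uint8_t p = pF[row + j];
      --i;
      if (p == 1) state = 'H';
    }
  }
  std::reverse(ops.begin(), ops.end());
  out.q_start = i; out.r_start = j;
  out.q_end = bi; out.r_end = bj;

  // run-length encode, count ops
  std::string cig;
  size_t k2 = 0;
  while (k2 < ops.size()) {
    size_t k3 = k2;
    while (k3 < ops.size() && ops[k3] == ops[k2]) ++k3;
    cig += std::to_string(k3 - k2);
    cig.push_back(ops[k2]);
    switch (ops[k2]) {
      case '=': out.n_match    += (int)(k3 - k2); break;
      case 'X': out.n_mismatch += (int)(k3 - k2); break;
      case 'I': out.n_ins      += (int)(k3 - k2); break;
      case 'D': out.n_del      += (int)(k3 - k2); break;
    }
    k2 = k3;
  }
  out.cigar = cig;
  return out;
}

static List aln_to_list(const AlnResult& a) {
  return List::create(
    _["score"] = a.score,
    _["q_start"] = a.q_start, _["q_end"] = a.q_end,
    _["r_start"] = a.r_start, _["r_end"] = a.r_end,
    _["cigar"] = a.cigar,
    _["n_match"] = a.n_match, _["n_mismatch"] = a.n_mismatch,
    _["n_ins"] = a.n_ins, _["n_del"] = a.n_del);
}

// [[Rcpp::export]]
List sw_align_cpp(std::string query, std::string ref,
                  int match, int mismatch, int gap_open, int gap_ext) {
  return aln_to_list(sw_core(query, ref, match, mismatch, gap_open, gap_ext));
}

// Banded Levenshtein distance (Ukkonen). Returns max_d + 1 when the true
// distance exceeds max_d.
// [[Rcpp::export]]
int banded_edit_cpp(std::string a, std::string b, int max_d) {
  const int n = (int)a.size(), m = (int)b.size();
  if (std::abs(n - m) > max_d) return max_d + 1;
  const int INF = max_d + 1;
  const int w = 2 * max_d + 1;
  std::vector<int> prev(w, INF), cur(w, INF);
  // column index j maps to band slot j - i + max_d
  for (int j = 0; j <= std::min(m, max_d); ++j) prev[j + max_d] = j;
  if (n == 0) return std::min(m, INF);
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    int lo = std::max(0, i - max_d), hi = std::min(m, i + max_d);
    int rowmin = INF;
    for (int j = lo; j <= hi; ++j) {
      int s = j - i + max_d;
      int v = INF;
      if (j == 0) {
        v = i;
      } else {
        int del = (s + 1 < w) ? prev[s + 1] : INF;            // (i-1, j)
        int ins = (s - 1 >= 0) ? cur[s - 1] : INF;            // (i, j-1)
        int sub = prev[s];                                    // (i-1, j-1)
        v = sub + ((a[i - 1] == b[j - 1]) ? 0 : 1);
        if (del + 1 < v) v = del + 1;
        if (ins + 1 < v) v = ins + 1;
        if (v > INF) v = INF;
      }
      cur[s] = v;
      if (v < rowmin) rowmin = v;
    }
    if (rowmin >= INF) return INF;
    std::swap(prev, cur);
  }
  int s = m - n + max_d;
  int d = (s >= 0 && s < w) ? prev[s] : INF;
  return std::min(d, INF);
}

static inline int base2bits(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// Count how many k-mers of each read are present in each reference sequence.
// Rows = reads, columns = refs. Non-ACGT characters break k-mers.
// [[Rcpp::export]]
IntegerMatrix kmer_hits_cpp(CharacterVector reads, CharacterVector refs, int k) {
  if (k < 4 || k > 31) stop("k must be in [4, 31]");
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int nref = refs.size(), nread = reads.size();
  std::vector<std::unordered_set<uint64_t>> sets(nref);
  for (int r = 0; r < nref; ++r) {
    std::string s = as<std::string>(refs[r]);
    uint64_t kmer = 0; int run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base2bits(s[i]);
      if (b < 0) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)b) & mask;
      if (++run >= k) sets[r].insert(kmer);
    }
  }
  IntegerMatrix out(nread, nref);
  for (int q = 0; q < nread; ++q) {
    std::string s = as<std::string>(reads[q]);
    uint64_t kmer = 0; int run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base2bits(s[i]);
      if (b < 0) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)b) & mask;
      if (++run >= k) {
        for (int r = 0; r < nref; ++r)
          if (sets[r].count(kmer)) out(q, r) += 1;
      }
    }
  }
  return out;
}

// One consensus pass: align every read to the scaffold, tally per-column base
// votes (A,C,G,T,gap), coverage, and insertion events keyed by the reference
// position the insertion precedes (0 .. L). Reads scoring below min_score are
// ignored and counted separately.
// [[Rcpp::export]]
List consensus_pass_cpp(std::string scaffold, CharacterVector reads,
                        int match, int mismatch, int gap_open, int gap_ext,
                        int min_score) {
  const int L = (int)scaffold.size();
  const int MAXEXT = 30; // cap on end-extension votes per pass
  IntegerMatrix counts(5, L); // rows: A C G T gap
  IntegerVector cov(L);
  IntegerMatrix pre(4, MAXEXT), suf(4, MAXEXT);
  std::vector<std::unordered_map<std::string, int>> ins(L + 1);
  std::vector<int> ins_total(L + 1, 0);
  int n_used = 0, n_skipped = 0;

  for (int q = 0; q < reads.size(); ++q) {
    std::string rd = as<std::string>(reads[q]);
    AlnResult a = sw_core(rd, scaffold, match, mismatch, gap_open, gap_ext);
    if (a.score < min_score) { ++n_skipped; continue; }
    ++n_used;
    for (int p = a.r_start; p < a.r_end; ++p) cov[p] += 1;
    // soft-clipped read ends vote on extensions beyond the scaffold ends
    if (a.r_start == 0 && a.q_start > 0) {
      int dmax = std::min(a.q_start, MAXEXT);
      for (int d = 1; d <= dmax; ++d) {
        int b = base2bits(rd[a.q_start - d]);
        if (b >= 0) pre(b, d - 1) += 1;
      }
    }
    if (a.r_end == L && a.q_end < (int)rd.size()) {
      int dmax = std::min((int)rd.size() - a.q_end, MAXEXT);
      for (int d = 1; d <= dmax; ++d) {
        int b = base2bits(rd[a.q_end + d - 1]);
        if (b >= 0) suf(b, d - 1) += 1;
      }
    }
    // walk cigar
    int qi = a.q_start, rj = a.r_start;
    size_t i = 0;
    while (i < a.cigar.size()) {
      size_t j = i;
      int len = 0;
      while (j < a.cigar.size() && a.cigar[j] >= '0' && a.cigar[j] <= '9') {
        len = len * 10 + (a.cigar[j] - '0');
        ++j;
      }
      char op = a.cigar[j];
      if (op == '=' || op == 'X') {
        for (int t = 0; t < len; ++t) {
          int b = base2bits(rd[qi + t]);
          if (b >= 0) counts(b, rj + t) += 1;
        }
        qi += len; rj += len;
      } else if (op == 'D') {
        for (int t = 0; t < len; ++t) counts(4, rj + t) += 1;
        rj += len;
      } else { // I
        std::string s = rd.substr(qi, len);
        ins[rj][s] += 1;
        ins_total[rj] += 1;
        qi += len;
      }
      i = j + 1;
    }
  }

  CharacterVector ins_best(L + 1);
  IntegerVector ins_best_count(L + 1), ins_any(L + 1);
  for (int p = 0; p <= L; ++p) {
    ins_any[p] = ins_total[p];
    std::string bs; int bc = 0;
    for (auto& kv : ins[p]) {
      if (kv.second > bc || (kv.second == bc && (bc == 0 || kv.first < bs))) {
        bs = kv.first; bc = kv.second;
      }
    }
    ins_best[p] = bs;
    ins_best_count[p] = bc;
  }
  return List::create(
    _["counts"] = counts, _["cov"] = cov,
    _["ins_best"] = ins_best, _["ins_best_count"] = ins_best_count,
    _["ins_any"] = ins_any, _["pre"] = pre, _["suf"] = suf,
    _["n_used"] = n_used, _["n_skipped"] = n_skipped);
}
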