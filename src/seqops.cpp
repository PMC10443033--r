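#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
#include <limits>

using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

// Merge one read pair. r2 is reverse-complemented; every relative offset of
// r2rc against r1 whose overlap reaches min_overlap is scanned; an offset is
// valid when the number of mismatching overlap bases (N matches nothing) is
// <= max_mismatch. Among valid offsets the largest overlap wins; an exact
// tie at the maximal overlap is rejected as ambiguous. Reads too short to
// ever reach min_overlap are rejected as too_short. Dovetail offsets (s < 0,
// r2rc starting before r1) are trimmed to the span covered by both reads.
// status: 0 merged, 1 no_perfect_overlap, 2 too_short, 3 ambiguous
struct MergeOne {
  int status;
  std::string seq, qual;
  int overlap;
};

static MergeOne merge_one(const std::string& s1, const std::string& q1,
                          const std::string& s2, const std::string& q2,
                          int min_overlap, int max_mismatch, int max_qual) {
  MergeOne out{1, "", "", 0};
  const int l1 = (int)s1.size(), l2 = (int)s2.size();
  if (l1 == 0 || l2 == 0) return out;
  if (std::min(l1, l2) < min_overlap) {
    out.status = 2; out.overlap = std::min(l1, l2);
    return out;
  }
  std::string s2rc = revcomp(s2);
  std::string q2r(q2.rbegin(), q2.rend());

  int best_ov = -1, best_s = 0, n_best = 0;
  for (int s = -(l2 - 1); s <= l1 - 1; ++s) {
    int a = std::max(0, s);            // overlap start in r1 coords
    int b = std::min(l1, s + l2);      // overlap end in r1 coords
    int ov = b - a;
    if (ov < min_overlap || ov < best_ov) continue;
    int mism = 0;
    bool valid = true;
    for (int k = 0; k < ov; ++k) {
      char c1 = s1[a + k], c2 = s2rc[a - s + k];
      if (c1 == 'N' || c2 == 'N' || c1 != c2) {
        if (++mism > max_mismatch) { valid = false; break; }
      }
    }
    if (!valid) continue;
    if (ov > best_ov) { best_ov = ov; best_s = s; n_best = 1; }
    else if (ov == best_ov) { ++n_best; }
  }

  if (best_ov < 0) { out.status = 1; return out; }
  if (n_best > 1) { out.status = 3; out.overlap = best_ov; return out; }

  const int s = best_s;
  const int a = std::max(0, s), b = std::min(l1, s + l2);
  std::string seq, qual;
  seq.reserve(l1 + l2); qual.reserve(l1 + l2);
  char qcap = (char)(max_qual + 33);
  if (s >= 0) { // r1 prefix outside the overlap
    seq.append(s1, 0, a);
    qual.append(q1, 0, a);
  }
  for (int k = a; k < b; ++k) {
    char c1 = s1[k], c2 = s2rc[k - s];
    char x1 = q1[k], x2 = q2r[k - s];
    if (c1 == c2) {
      seq.push_back(c1);
      char q = std::max(x1, x2);
      qual.push_back(q > qcap ? qcap : q);
    } else { // only reachable when max_mismatch > 0
      seq.push_back(x1 >= x2 ? c1 : c2);
      char q = (char)(std::abs((int)x1 - (int)x2) + 33);
      qual.push_back(q > qcap ? qcap : q);
    }
  }
  if (s >= 0 && s + l2 > l1) { // r2rc suffix outside the overlap
    seq.append(s2rc, l1 - s, l2 - (l1 - s));
    qual.append(q2r, l1 - s, l2 - (l1 - s));
  }
  out.status = 0; out.seq = seq; out.qual = qual; out.overlap = best_ov;
  return out;
}

// [[Rcpp::export(name = ".merge_pairs_cpp")]]
List merge_pairs_cpp(CharacterVector seq1, CharacterVector qual1,
                     CharacterVector seq2, CharacterVector qual2,
                     int min_overlap, int max_mismatch, int max_qual) {
  int n = seq1.size();
  IntegerVector status(n), overlap(n);
  CharacterVector mseq(n), mqual(n);
  for (int i = 0; i < n; ++i) {
    MergeOne m = merge_one(as<std::string>(seq1[i]), as<std::string>(qual1[i]),
                           as<std::string>(seq2[i]), as<std::string>(qual2[i]),
                           min_overlap, max_mismatch, max_qual);
    status[i] = m.status;
    overlap[i] = m.overlap;
    if (m.status == 0) { mseq[i] = m.seq; mqual[i] = m.qual; }
    else { mseq[i] = NA_STRING; mqual[i] = NA_STRING; }
  }
  return List::create(_["status"] = status, _["seq"] = mseq,
                      _["qual"] = mqual, _["overlap_len"] = overlap);
}

// Glocal (global in read, local in reference) affine-gap alignment, Gotoh
// recurrences. A gap of length g costs gap_open + g * gap_extend. Reference
// prefix/suffix are free; the read is consumed in full. Ties prefer the
// smallest end column and, during traceback, diagonal over deletion over
// insertion (substitutions before indels, leftmost reference offset).
// Returns per read: score, ref_start (0-based), cigar over ops = X I D.
// [[Rcpp::export(name = ".align_glocal_cpp")]]
List align_glocal_cpp(CharacterVector reads, std::string ref,
                      double match, double mismatch,
                      double gap_open, double gap_extend) {
  const int m = (int)ref.size();
  const double NEG = -1e30;
  int nreads = reads.size();
  NumericVector score_out(nreads);
  IntegerVector start_out(nreads);
  CharacterVector cigar_out(nreads);

  for (int r = 0; r < nreads; ++r) {
    std::string read = as<std::string>(reads[r]);
    const int n = (int)read.size();
    // DP matrices (n+1) x (m+1); H main, E gap-in-ref (I, consumes read),
    // F gap-in-read (D, consumes ref).
    std::vector<double> H((n + 1) * (m + 1), NEG);
    std::vector<double> E((n + 1) * (m + 1), NEG);
    std::vector<double> F((n + 1) * (m + 1), NEG);
    // traceback: which matrix each cell's max came from
    // for H: 0 diag, 1 from E, 2 from F; for E: 0 open, 1 extend; same for F
    std::vector<unsigned char> tbH((n + 1) * (m + 1), 0);
    std::vector<unsigned char> tbE((n + 1) * (m + 1), 0);
    std::vector<unsigned char> tbF((n + 1) * (m + 1), 0);
    auto idx = [m](int i, int j) { return i * (m + 1) + j; };

    for (int j = 0; j <= m; ++j) H[idx(0, j)] = 0.0; // free reference prefix
    for (int i = 1; i <= n; ++i) {
      // column 0: read consumed by insertion only
      {
        double eo = H[idx(i - 1, 0)] + gap_open + gap_extend;
        double ee = E[idx(i - 1, 0)] + gap_extend;
        if (eo >= ee) { E[idx(i, 0)] = eo; tbE[idx(i, 0)] = 0; }
        else          { E[idx(i, 0)] = ee; tbE[idx(i, 0)] = 1; }
      }
      H[idx(i, 0)] = E[idx(i, 0)];
      tbH[idx(i, 0)] = 1;
      for (int j = 1; j <= m; ++j) {
        double eo = H[idx(i - 1, j)] + gap_open + gap_extend;
        double ee = E[idx(i - 1, j)] + gap_extend;
        if (eo >= ee) { E[idx(i, j)] = eo; tbE[idx(i, j)] = 0; }
        else          { E[idx(i, j)] = ee; tbE[idx(i, j)] = 1; }
        double fo = H[idx(i, j - 1)] + gap_open + gap_extend;
        double fe = F[idx(i, j - 1)] + gap_extend;
        if (fo >= fe) { F[idx(i, j)] = fo; tbF[idx(i, j)] = 0; }
        else          { F[idx(i, j)] = fe; tbF[idx(i, j)] = 1; }
        char rc = read[i - 1], gc = ref[j - 1];
        double sub = (rc == gc && rc != 'N') ? match : mismatch;
        double hd = H[idx(i - 1, j - 1)] + sub;
        double best = hd; unsigned char tb = 0;
        if (F[idx(i, j)] > best) { best = F[idx(i, j)]; tb = 2; }
        if (E[idx(i, j)] > best) { best = E[idx(i, j)]; tb = 1; }
        H[idx(i, j)] = best; tbH[idx(i, j)] = tb;
      }
    }
    // best end: max over row n, smallest j on ties
    double best = NEG; int endj = 0;
    for (int j = 0; j <= m; ++j) {
      if (H[idx(n, j)] > best) { best = H[idx(n, j)]; endj = j; }
    }
    // traceback
    std::string ops; // one char per aligned column, reversed at the end
    int i = n, j = endj; int state = 0; // 0 = H, 1 = E, 2 = F
    while (i > 0) {
      if (state == 0) {
        unsigned char tb = tbH[idx(i, j)];
        if (tb == 1) { state = 1; continue; }
        if (tb == 2) { state = 2; continue; }
        char rc = read[i - 1], gc = ref[j - 1];
        ops.push_back((rc == gc && rc != 'N') ? '=' : 'X');
        --i; --j;
      } else if (state == 1) { // insertion: consumes read
        unsigned char tb = tbE[idx(i, j)];
        ops.push_back('I');
        --i;
        state = (tb == 1) ? 1 : 0;
      } else { // deletion: consumes reference
        unsigned char tb = tbF[idx(i, j)];
        ops.push_back('D');
        --j;
        state = (tb == 1) ? 2 : 0;
      }
    }
    std::reverse(ops.begin(), ops.end());
    // run-length encode
    std::string cigar;
    size_t k = 0;
    while (k < ops.size()) {
      size_t k2 = k;
      while (k2 < ops.size() && ops[k2] == ops[k]) ++k2;
      cigar += std::to_string(k2 - k);
      cigar.push_back(ops[k]);
      k = k2;
    }
    score_out[r] = best;
    start_out[r] = j;
    cigar_out[r] = cigar;
  }
  return List::create(_["score"] = score_out, _["ref_start"] = start_out,
                      _["cigar"] = cigar_out);
}

// Accumulate a weighted allele pileup from cigar-aligned reads.
// Matrix columns: A C G T del ins N. depth = A+C+G+T+del is capped at
// max_depth in input order; the read crossing the cap contributes the
// remaining headroom at that position. Insertions are counted at the
// reference position following their anchor and do not add depth.
// [[Rcpp::export(name = ".pileup_cpp")]]
NumericMatrix pileup_cpp(int ref_len, IntegerVector ref_start,
                         CharacterVector cigar, CharacterVector seq,
                         NumericVector count, double max_depth) {
  NumericMatrix M(ref_len, 7); // A C G T del ins N
  std::vector<double> depth(ref_len, 0.0);
  auto base_col = [](char c) -> int {
    switch (c) {
      case 'A': return 0; case 'C': return 1;
      case 'G': return 2; case 'T': return 3;
      default: return 6;
    }
  };
  for (int r = 0; r < cigar.size(); ++r) {
    std::string cg = as<std::string>(cigar[r]);
    std::string sq = as<std::string>(seq[r]);
    double w = count[r];
    int p = ref_start[r], q = 0;
    size_t k = 0;
    while (k < cg.size()) {
      int len = 0;
      while (k < cg.size() && isdigit(cg[k])) { len = len * 10 + (cg[k] - '0'); ++k; }
      char op = cg[k++];
      if (op == '=' || op == 'X') {
        for (int t = 0; t < len; ++t, ++p, ++q) {
          if (p < 0 || p >= ref_len) continue;
          int col = base_col(sq[q]);
          if (col == 6) { M(p, 6) += w; continue; } // N: excluded from depth
          double take = std::min(w, max_depth - depth[p]);
          if (take <= 0) continue;
          M(p, col) += take;
          depth[p] += take;
        }
      } else if (op == 'D') {
        for (int t = 0; t < len; ++t, ++p) {
          if (p < 0 || p >= ref_len) continue;
          double take = std::min(w, max_depth - depth[p]);
          if (take <= 0) continue;
          M(p, 4) += take;
          depth[p] += take;
        }
      } else if (op == 'I') {
        if (p >= 0 && p < ref_len) M(p, 5) += w;
        q += len;
      }
    }
  }
  return M;
}
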