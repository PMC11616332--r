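#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Pairwise affine-gap alignment of reads against a single amplicon reference.
// Semantics: the read is aligned end to end; the reference is either fully
// consumed (global, the default: merged reads span the complete PCR product)
// or its unaligned flanks are free (fitting, free_ref_ends). Identity is
// matches over aligned columns where a multi-base indel counts as one column
// (one repair event). Reported identity is matches over READ bases: a read
// base either matches the reference or it does not, while deleted reference
// segments involve no read base — so a legitimate whole-tract excision scores
// ~1 and random DNA lands at 0.25-0.4.
// A gap of length L costs gap_open + L * gap_extend. Tie-break during traceback prefers
// mismatch over insertion (extra read base) over deletion (skipped ref base);
// indels are subsequently left-normalised on the R side.

static const double NEG_INF = -1e18;

// state codes for traceback
enum { ST_M = 0, ST_I = 1, ST_D = 2 };

// [[Rcpp::export]]
List cpp_align_batch(CharacterVector reads, std::string ref,
                     double match, double mismatch,
                     double gap_open, double gap_extend,
                     bool free_ref_ends) {
  const int m = ref.size();
  const int nreads = reads.size();
  List out(nreads);

  // reusable DP buffers sized for the longest read
  int nmax = 0;
  for (int r = 0; r < nreads; ++r) {
    int L = LENGTH(STRING_ELT(reads, r));
    if (L > nmax) nmax = L;
  }
  std::vector<double> M((nmax + 1) * (m + 1)), I((nmax + 1) * (m + 1)),
      D((nmax + 1) * (m + 1));

  for (int r = 0; r < nreads; ++r) {
    const char *read = CHAR(STRING_ELT(reads, r));
    const int n = std::strlen(read);
    if (n == 0) { out[r] = R_NilValue; continue; }
    const int W = m + 1;
    // row 0: leading reference bases are free (fitting) or an affine
    // leading deletion (global; the amplicon is a complete PCR product)
    M[0] = 0.0; I[0] = NEG_INF; D[0] = NEG_INF;
    for (int j = 1; j <= m; ++j) {
      if (free_ref_ends) { M[j] = 0.0; D[j] = NEG_INF; }
      else { M[j] = NEG_INF; D[j] = gap_open + j * gap_extend; }
      I[j] = NEG_INF;
    }
    for (int i = 1; i <= n; ++i) {
      const char rb = read[i - 1];
      M[i * W] = NEG_INF;
      D[i * W] = NEG_INF;
      // read base unmatched at ref position 0 -> leading insertion
      {
        double fromM = M[(i - 1) * W] + gap_open + gap_extend;
        double fromI = I[(i - 1) * W] + gap_extend;
        I[i * W] = fromM > fromI ? fromM : fromI;
      }
      for (int j = 1; j <= m; ++j) {
        const int ij = i * W + j;
        // M: diagonal from best of three
        double s = (rb == ref[j - 1] && rb != 'N') ? match : mismatch;
        double dM = M[(i - 1) * W + j - 1], dI = I[(i - 1) * W + j - 1],
               dD = D[(i - 1) * W + j - 1];
        double best = dM;
        if (dI > best) best = dI;
        if (dD > best) best = dD;
        M[ij] = best + s;
        // I: consume read base (gap in ref)
        double iM = M[(i - 1) * W + j] + gap_open + gap_extend;
        double iI = I[(i - 1) * W + j] + gap_extend;
        double iD = D[(i - 1) * W + j] + gap_open + gap_extend;
        double bi = iM;
        if (iI > bi) bi = iI;
        if (iD > bi) bi = iD;
        I[ij] = bi;
        // D: consume ref base (gap in read)
        double dMh = M[i * W + j - 1] + gap_open + gap_extend;
        double dDh = D[i * W + j - 1] + gap_extend;
        double dIh = I[i * W + j - 1] + gap_open + gap_extend;
        double bd = dMh;
        if (dDh > bd) bd = dDh;
        if (dIh > bd) bd = dIh;
        D[ij] = bd;
      }
    }
    // terminal cell: global ends at column m; fitting scans the last row
    // (leftmost column wins ties)
    int jbest = free_ref_ends ? 0 : m, sbest = ST_M;
    double best = NEG_INF;
    const int jlo = free_ref_ends ? 0 : m;
    for (int j = jlo; j <= m; ++j) {
      double vM = M[n * W + j], vI = I[n * W + j], vD = D[n * W + j];
      double v = vM;
      int st = ST_M;
      if (vI > v) { v = vI; st = ST_I; }
      if (vD > v) { v = vD; st = ST_D; }
      if (v > best + 1e-12) { best = v; jbest = j; sbest = st; }
    }
    // traceback
    int i = n, j = jbest, st = sbest;
    int n_match = 0, n_col = 0;       // n_col: M/MM columns + 1 per indel event
    int in_gap = 0;
    std::vector<int> ins_pos, del_start, del_end;
    std::vector<std::string> ins_seq;
    std::string cur_ins;
    int cur_del_end = -1;
    const double eps = 1e-9;
    while (i > 0) {
      const int ij = i * W + j;
      if (st == ST_M) {
        if (j == 0) break; // hit free boundary (shouldn't happen with i>0)
        if (cur_ins.size()) {
          std::reverse(cur_ins.begin(), cur_ins.end());
          ins_pos.push_back(j);
          ins_seq.push_back(cur_ins);
          cur_ins.clear();
        }
        if (cur_del_end >= 0) {
          del_start.push_back(j);
          del_end.push_back(cur_del_end);
          cur_del_end = -1;
        }
        ++n_col;
        in_gap = 0;
        if (read[i - 1] == ref[j - 1] && read[i - 1] != 'N') ++n_match;
        double s = (read[i - 1] == ref[j - 1] && read[i - 1] != 'N') ? match
                                                                     : mismatch;
        double tgt = M[ij] - s;
        double dM = M[(i - 1) * W + j - 1], dI = I[(i - 1) * W + j - 1],
               dD = D[(i - 1) * W + j - 1];
        if (dM >= tgt - eps) st = ST_M;
        else if (dI >= tgt - eps) st = ST_I;
        else st = ST_D;
        --i; --j;
      } else if (st == ST_I) {
        if (in_gap != 1) { ++n_col; in_gap = 1; }
        cur_ins.push_back(read[i - 1]);
        double tgt_open = I[ij] - gap_open - gap_extend;
        double tgt_ext = I[ij] - gap_extend;
        double dM = M[(i - 1) * W + j], dI = I[(i - 1) * W + j],
               dD = D[(i - 1) * W + j];
        if (dM >= tgt_open - eps) st = ST_M;
        else if (dI >= tgt_ext - eps) st = ST_I;
        else st = ST_D;
        --i;
      } else { // ST_D
        if (in_gap != 2) { ++n_col; in_gap = 2; }
        if (cur_del_end < 0) cur_del_end = j;
        double tgt_open = D[ij] - gap_open - gap_extend;
        double tgt_ext = D[ij] - gap_extend;
        double dM = M[i * W + j - 1], dD = D[i * W + j - 1],
               dI = I[i * W + j - 1];
        if (dM >= tgt_open - eps) st = ST_M;
        else if (dD >= tgt_ext - eps) st = ST_D;
        else st = ST_I;
        --j;
      }
    }
    // flush pending events at the left boundary; in global mode any
    // unconsumed reference prefix is a leading deletion
    if (cur_ins.size()) {
      std::reverse(cur_ins.begin(), cur_ins.end());
      ins_pos.push_back(j);
      ins_seq.push_back(cur_ins);
    }
    if (!free_ref_ends && j > 0) {
      if (cur_del_end < 0) { cur_del_end = j; ++n_col; }
      j = 0;
    }
    if (cur_del_end >= 0) {
      del_start.push_back(j);
      del_end.push_back(cur_del_end);
    }
    std::reverse(ins_pos.begin(), ins_pos.end());
    std::reverse(ins_seq.begin(), ins_seq.end());
    std::reverse(del_start.begin(), del_start.end());
    std::reverse(del_end.begin(), del_end.end());
    out[r] = List::create(
        _["score"] = best, _["identity"] = (double)n_match / n,
        _["n_match"] = n_match, _["n_col"] = n_col,
        _["ref_start"] = j, _["ref_end"] = jbest,
        _["ins_pos"] = IntegerVector(ins_pos.begin(), ins_pos.end()),
        _["ins_seq"] = CharacterVector(ins_seq.begin(), ins_seq.end()),
        _["del_start"] = IntegerVector(del_start.begin(), del_start.end()),
        _["del_end"] = IntegerVector(del_end.begin(), del_end.end()));
  }
  return out;
}

// Best ungapped overlap merge of read pairs (r2 already reverse-complemented).
// Offsets place r2rc relative to r1; the offset maximising matches wins, ties
// broken toward the longer overlap. Disagreements resolve to the higher-quality
// base (tie: r1); merged quality is the max of the two.
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector r1, CharacterVector r2rc,
                     List q1, List q2rc, int min_overlap,
                     double max_mismatch) {
  const int n = r1.size();
  CharacterVector mseq(n);
  List mqual(n);
  IntegerVector status(n); // 1 merged, 0 unmerged
  for (int k = 0; k < n; ++k) {
    const char *a = CHAR(STRING_ELT(r1, k));
    const char *b = CHAR(STRING_ELT(r2rc, k));
    const int L1 = std::strlen(a), L2 = std::strlen(b);
    IntegerVector qa = q1[k], qb = q2rc[k];
    int best_d = 0, best_match = -1, best_ov = 0;
    for (int d = -(L2 - min_overlap); d <= L1 - min_overlap; ++d) {
      int lo = d > 0 ? d : 0;
      int hi = (d + L2 < L1) ? d + L2 : L1;
      int ov = hi - lo;
      if (ov < min_overlap) continue;
      int nm = 0;
      for (int i = lo; i < hi; ++i)
        if (a[i] == b[i - d]) ++nm;
      if (nm > best_match || (nm == best_match && ov > best_ov)) {
        best_match = nm; best_d = d; best_ov = ov;
      }
    }
    if (best_match < 0 ||
        (best_ov - best_match) > max_mismatch * best_ov) {
      mseq[k] = NA_STRING; mqual[k] = R_NilValue; status[k] = 0;
      continue;
    }
    const int d = best_d;
    const int start = d < 0 ? d : 0;
    const int stop = (d + L2 > L1) ? d + L2 : L1;
    std::string s;
    std::vector<int> q;
    s.reserve(stop - start);
    for (int i = start; i < stop; ++i) {
      bool in1 = i >= 0 && i < L1;
      bool in2 = i - d >= 0 && i - d < L2;
      if (in1 && in2) {
        int qa_i = qa[i], qb_i = qb[i - d];
        if (a[i] == b[i - d]) {
          s.push_back(a[i]);
          q.push_back(qa_i > qb_i ? qa_i : qb_i);
        } else if (qb_i > qa_i) {
          s.push_back(b[i - d]); q.push_back(qb_i);
        } else {
          s.push_back(a[i]); q.push_back(qa_i);
        }
      } else if (in1) {
        s.push_back(a[i]); q.push_back(qa[i]);
      } else {
        s.push_back(b[i - d]); q.push_back(qb[i - d]);
      }
    }
    mseq[k] = s;
    mqual[k] = IntegerVector(q.begin(), q.end());
    status[k] = 1;
  }
  return List::create(_["seq"] = mseq, _["qual"] = mqual,
                      _["merged"] = status);
}

// Hamming distance of one sequence against many (equal lengths assumed).
// [[Rcpp::export]]
IntegerVector cpp_hamming_one_many(std::string x, CharacterVector ys) {
  const int n = ys.size();
  IntegerVector out(n);
  const int L = x.size();
  for (int k = 0; k < n; ++k) {
    const char *y = CHAR(STRING_ELT(ys, k));
    int d = 0;
    for (int i = 0; i < L; ++i)
      if (x[i] != y[i]) ++d;
    out[k] = d;
  }
  return out;
}
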