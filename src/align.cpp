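#include <Rcpp.h>
using namespace Rcpp;

// Ungapped exhaustive placement scan shared by the exported entry points.
// Sequences are integer-coded (A=1, C=2, G=3, T=4; anything else 0, which
// never matches). Every offset with at least one overlapping base is
// scored as matches - penalty * mismatches over the overlapping span
// (overhangs ignored); the smallest offset wins ties.
struct Hit {
  double score;
  int offset, matches, mismatches, span_start, span_end;
};

static Hit scan(const int *read, int L, const int *ref, int R, double penalty) {
  Hit best;
  best.score = R_NegInf;
  best.offset = best.matches = best.mismatches = 0;
  best.span_start = best.span_end = 0;
  for (int off = -(L - 1); off <= R - 1; ++off) {
    const int s = off > 0 ? off : 0;
    const int e = (off + L < R) ? off + L : R;
    int m = 0;
    for (int j = s; j < e; ++j)
      if (ref[j] == read[j - off]) ++m;
    const int mm = (e - s) - m;
    const double score = m - penalty * mm;
    if (score > best.score) {
      best.score = score;
      best.offset = off; best.matches = m; best.mismatches = mm;
      best.span_start = s; best.span_end = e;
    }
  }
  return best;
}

// Best placement over both strands: forward first, strict improvement
// required to switch (deterministic tie-break). `rc` receives true when
// the reverse complement won.
static Hit scan_both(const std::vector<int> &fwd, const std::vector<int> &rev,
                     const int *ref, int R, double penalty, bool &rc) {
  Hit f = scan(fwd.data(), (int)fwd.size(), ref, R, penalty);
  Hit r = scan(rev.data(), (int)rev.size(), ref, R, penalty);
  rc = r.score > f.score;
  return rc ? r : f;
}

static std::vector<int> as_vec(const IntegerVector &x) {
  return std::vector<int>(x.begin(), x.end());
}

static std::vector<int> revcomp_vec(const std::vector<int> &x) {
  std::vector<int> out(x.size());
  for (size_t i = 0; i < x.size(); ++i) {
    const int b = x[x.size() - 1 - i];
    out[i] = b == 0 ? 0 : 5 - b;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector scan_offsets(IntegerVector read, IntegerVector ref, double penalty) {
  if (read.size() == 0 || ref.size() == 0) stop("empty read or reference");
  Hit h = scan(INTEGER(read), read.size(), INTEGER(ref), ref.size(), penalty);
  return NumericVector::create(
    Named("offset") = h.offset, Named("matches") = h.matches,
    Named("mismatches") = h.mismatches, Named("score") = h.score,
    Named("span_start") = h.span_start, Named("span_end") = h.span_end);
}

// Dual-reference junction classification of a read batch. For each read:
// align (both strands) against the deletion and non-deletion references,
// take the higher-scoring reference as candidate (equal scores carry no
// junction information -> uninformative), then require the aligned span to
// extend >= min_overlap bases on each side of the junction (deletion) or
// of the inserted interval [ins_start, ins_end) (non-deletion), and the
// mismatch rate over the span to be <= max_mm.
//
// Returns an n x 5 matrix: best allele (0 uninformative, 1 deletion,
// 2 non-deletion), score_del, score_non, overlap_left, overlap_right
// (NA when the scores tie).
// [[Rcpp::export]]
NumericMatrix classify_batch(List reads, IntegerVector del_ref,
                             IntegerVector non_ref, int junction,
                             int ins_start, int ins_end,
                             IntegerVector min_overlap, double penalty,
                             double max_mm) {
  const int n = reads.size();
  NumericMatrix out(n, 5);
  colnames(out) = CharacterVector::create(
    "best", "score_del", "score_non", "overlap_left", "overlap_right");
  for (int i = 0; i < n; ++i) {
    IntegerVector rv = reads[i];
    if (rv.size() == 0) stop("empty read");
    std::vector<int> fwd = as_vec(rv), rev = revcomp_vec(fwd);
    bool rc;
    Hit hd = scan_both(fwd, rev, INTEGER(del_ref), del_ref.size(), penalty, rc);
    Hit hn = scan_both(fwd, rev, INTEGER(non_ref), non_ref.size(), penalty, rc);
    out(i, 1) = hd.score;
    out(i, 2) = hn.score;
    if (hd.score == hn.score) {
      out(i, 0) = 0;
      out(i, 3) = NA_REAL;
      out(i, 4) = NA_REAL;
      continue;
    }
    const bool del = hd.score > hn.score;
    const Hit &h = del ? hd : hn;
    const int left = (del ? junction : ins_start) - h.span_start;
    const int right = h.span_end - (del ? junction : ins_end);
    out(i, 3) = left;
    out(i, 4) = right;
    const int aligned = h.matches + h.mismatches;
    const bool ok = left >= min_overlap[i] && right >= min_overlap[i] &&
      aligned > 0 && (double)h.mismatches / aligned <= max_mm;
    out(i, 0) = ok ? (del ? 1 : 2) : 0;
  }
  return out;
}
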