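#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Local (Smith-Waterman) alignment under a Gotoh affine gap model where a
// k-base gap costs gap_open + k * gap_extend (the opening charge is paid on
// top of the first extension). Among equal-scoring optima the canonical
// row-major convention applies: the first optimal cell scanning query
// positions then reference positions wins (smallest query end, then
// smallest reference end); traceback ties prefer diagonal moves, then gaps
// in the query (ref base vs gap), then gaps in the reference. Deliberately
// NOT biased toward reference-3'-anchored placements: the same scoring is
// applied to SL references and random background controls, and resolving
// short ambiguous matches toward the reference 3' end would hand every
// coincidental prefix/suffix match the maximal positional weight,
// inflating the background score distribution.
//
// Column status codes: 0 = match, 1 = mismatch,
//                      2 = query base vs gap (insertion),
//                      3 = gap vs ref base (deletion).

namespace {

struct Trace {
  int qstart;
  std::vector<int> status; // in alignment order
};

const double NEG = -1e18;

Trace traceback(int ei, int ej,
                const std::vector<std::vector<double> > &H,
                const std::vector<std::vector<double> > &E,
                const std::vector<std::vector<double> > &F,
                const std::string &q, const std::string &r,
                double match, double mismatch, double go, double ge) {
  Trace tr;
  int i = ei, j = ej;
  int state = 0; // 0 = H, 1 = E (gap vs ref base), 2 = F (query base vs gap)
  while (true) {
    if (state == 0) {
      if (H[i][j] <= 0) break;
      double s = (q[i - 1] == r[j - 1]) ? match : -mismatch;
      if (i > 0 && j > 0 && H[i][j] == H[i - 1][j - 1] + s) {
        tr.status.push_back(q[i - 1] == r[j - 1] ? 0 : 1);
        --i; --j;
      } else if (H[i][j] == E[i][j]) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      // gap in query consuming ref base j
      tr.status.push_back(3);
      if (j > 1 && E[i][j] == E[i][j - 1] - ge) {
        --j;
      } else {
        --j;
        state = 0;
        // we came from H[i][j] - go - ge at the (already decremented) j
      }
    } else {
      tr.status.push_back(2);
      if (i > 1 && F[i][j] == F[i - 1][j] - ge) {
        --i;
      } else {
        --i;
        state = 0;
      }
    }
  }
  tr.qstart = i; // 0-based start in query
  std::reverse(tr.status.begin(), tr.status.end());
  return tr;
}

} // namespace

// [[Rcpp::export]]
List sw_align_cpp(std::string query, std::string ref,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  int m = query.size(), n = ref.size();
  std::vector<std::vector<double> > H(m + 1, std::vector<double>(n + 1, 0.0));
  std::vector<std::vector<double> > E(m + 1, std::vector<double>(n + 1, NEG));
  std::vector<std::vector<double> > F(m + 1, std::vector<double>(n + 1, NEG));
  double best = 0.0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      E[i][j] = std::max(H[i][j - 1] - gap_open - gap_extend,
                         E[i][j - 1] - gap_extend);
      F[i][j] = std::max(H[i - 1][j] - gap_open - gap_extend,
                         F[i - 1][j] - gap_extend);
      double s = (query[i - 1] == ref[j - 1]) ? match : -mismatch;
      double h = H[i - 1][j - 1] + s;
      if (E[i][j] > h) h = E[i][j];
      if (F[i][j] > h) h = F[i][j];
      if (h < 0) h = 0;
      H[i][j] = h;
      if (h > best) best = h;
    }
  }
  if (best <= 0) {
    return List::create(_["score"] = 0.0,
                        _["query_start"] = 0, _["query_end"] = 0,
                        _["ref_start"] = 0, _["ref_end"] = 0,
                        _["status"] = IntegerVector(0));
  }
  // first optimal cell in row-major order (smallest query end, then
  // smallest ref end)
  int bi = -1, bj = -1;
  for (int i = 1; i <= m && bi < 0; ++i)
    for (int j = 1; j <= n; ++j)
      if (H[i][j] == best) { bi = i; bj = j; break; }
  Trace sel_tr = traceback(bi, bj, H, E, F, query, ref,
                           match, mismatch, gap_open, gap_extend);
  int sel_qstart = sel_tr.qstart;
  // recover ref_start from status columns
  int ref_consumed = 0, q_consumed = 0;
  for (size_t k = 0; k < sel_tr.status.size(); ++k) {
    int st = sel_tr.status[k];
    if (st == 0 || st == 1 || st == 3) ++ref_consumed;
    if (st == 0 || st == 1 || st == 2) ++q_consumed;
  }
  int rstart = bj - ref_consumed;
  return List::create(_["score"] = best,
                      _["query_start"] = sel_qstart,
                      _["query_end"] = sel_qstart + q_consumed,
                      _["ref_start"] = rstart,
                      _["ref_end"] = bj,
                      _["status"] = wrap(sel_tr.status));
}
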