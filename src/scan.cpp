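#include <Rcpp.h>
using namespace Rcpp;

// Ungapped full-length scans of encoded fragments against an encoded
// transcript strand. Bases are encoded A=1, C=2, G=3, T=4, N=0; an N on
// either side never counts as an identity. Placements with more than
// max_mm mismatches are abandoned early (mismatch-budget abort), which is
// what makes exhaustive scanning of every offset affordable. A single
// mismatch buffer is reused across offsets; per-hit vectors are only
// materialized for placements that survive the budget.

static inline int scan_one(const int* frag, const int* txp, int k, int s,
                           int max_mm, int* mmbuf) {
  int n_mm = 0;
  for (int j = 0; j < k; ++j) {
    const int a = frag[j];
    const int b = txp[s + j];
    if (a == 0 || b == 0 || a != b) {
      if (n_mm == max_mm) return -1; // budget exceeded
      mmbuf[n_mm++] = j + 1;
    }
  }
  return n_mm;
}

// [[Rcpp::export(name = ".scan_core")]]
List scan_core(IntegerVector frag, IntegerVector txp, int max_mm) {
  const int k = frag.size();
  const int n = txp.size();
  std::vector<int> starts;
  std::vector< std::vector<int> > mms;
  std::vector<int> mmbuf(max_mm > 0 ? max_mm : 1);

  if (n >= k) {
    const int* fp = INTEGER(frag);
    const int* tp = INTEGER(txp);
    for (int s = 0; s + k <= n; ++s) {
      const int n_mm = scan_one(fp, tp, k, s, max_mm, mmbuf.data());
      if (n_mm >= 0) {
        starts.push_back(s + 1);
        mms.push_back(std::vector<int>(mmbuf.begin(), mmbuf.begin() + n_mm));
      }
    }
  }

  const int h = (int)starts.size();
  IntegerVector out_start(h);
  List out_mm(h);
  for (int i = 0; i < h; ++i) {
    out_start[i] = starts[i];
    out_mm[i] = wrap(mms[i]);
  }
  return List::create(_["t_start"] = out_start, _["mismatches"] = out_mm);
}

// Batch variant: scans many same-length fragments against one transcript in
// a single call to keep R-level dispatch out of the database loop. frag_mat
// is a k x n_frag integer matrix (one fragment per column).
//
// [[Rcpp::export(name = ".scan_batch_core")]]
List scan_batch_core(IntegerMatrix frag_mat, IntegerVector txp, int max_mm) {
  const int k = frag_mat.nrow();
  const int nf = frag_mat.ncol();
  const int n = txp.size();
  std::vector<int> out_frag, out_start;
  std::vector< std::vector<int> > mms;
  std::vector<int> mmbuf(max_mm > 0 ? max_mm : 1);

  if (n >= k) {
    const int* fm = INTEGER(frag_mat);
    const int* tp = INTEGER(txp);
    for (int f = 0; f < nf; ++f) {
      const int* frag = fm + (size_t)f * k;
      for (int s = 0; s + k <= n; ++s) {
        const int n_mm = scan_one(frag, tp, k, s, max_mm, mmbuf.data());
        if (n_mm >= 0) {
          out_frag.push_back(f + 1);
          out_start.push_back(s + 1);
          mms.push_back(std::vector<int>(mmbuf.begin(),
                                         mmbuf.begin() + n_mm));
        }
      }
    }
  }

  const int h = (int)out_start.size();
  IntegerVector rs(h), rf(h);
  List rmm(h);
  for (int i = 0; i < h; ++i) {
    rf[i] = out_frag[i];
    rs[i] = out_start[i];
    rmm[i] = wrap(mms[i]);
  }
  return List::create(_["frag"] = rf, _["t_start"] = rs,
                      _["mismatches"] = rmm);
}
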