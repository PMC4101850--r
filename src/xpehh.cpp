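#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// Partition of a fixed haplotype subset, refined one SNP at a time.
// Class ids stay dense in [0, ncls); refine() returns the haplotype
// homozygosity (probability two distinct members share the full prefix
// string) after adding one allele column.
struct Partition {
  std::vector<int> rows;  // row indices into the allele matrix
  std::vector<int> cls;   // class id per member
  std::vector<int> remap; // scratch: old_id * 2 + allele -> new id
  std::vector<int> cnt;   // scratch: class sizes
  int ncls;

  void init(const std::vector<int>& rows_) {
    rows = rows_;
    cls.assign(rows.size(), 0);
    ncls = 1;
  }
  void reset() {
    std::fill(cls.begin(), cls.end(), 0);
    ncls = 1;
  }
  double refine(const int* col) {
    const int n = (int)rows.size();
    remap.assign((size_t)ncls * 2, -1);
    cnt.clear();
    int nn = 0;
    for (int t = 0; t < n; ++t) {
      const int key = cls[t] * 2 + col[rows[t]];
      int m = remap[key];
      if (m < 0) {
        m = nn++;
        remap[key] = m;
        cnt.push_back(0);
      }
      cls[t] = m;
      ++cnt[m];
    }
    ncls = nn;
    double hom = 0.0;
    for (int c = 0; c < nn; ++c) hom += (double)cnt[c] * (cnt[c] - 1.0);
    return hom / ((double)n * (n - 1.0));
  }
};

} // namespace

// Raw XP-EHH log-ratio at every SNP.  H is haplotypes x SNPs (0/1),
// chrom_id marks contiguous chromosome blocks, sel/ref rows are 1-based.
// Integration boundaries are set on the pooled panel: extension stops
// after the first step where pooled EHH drops below `truncation`, past
// `max_extension` bp, or at the chromosome end; both group curves are
// integrated (trapezoid vs physical offset, starting from EHH = 1 at
// offset 0) over exactly those SNPs.  NA where either integral is zero.
// [[Rcpp::export]]
NumericVector cpp_xpehh_scan(const IntegerMatrix& H, const NumericVector& pos,
                             const IntegerVector& chrom_id,
                             const IntegerVector& sel_rows,
                             const IntegerVector& ref_rows,
                             double truncation, double max_extension) {
  const int nsnp = H.ncol();
  const int nhap = H.nrow();
  const int* Hp = INTEGER(H);

  std::vector<int> rs(sel_rows.size()), rr(ref_rows.size()), rp;
  for (int i = 0; i < sel_rows.size(); ++i) rs[i] = sel_rows[i] - 1;
  for (int i = 0; i < ref_rows.size(); ++i) rr[i] = ref_rows[i] - 1;
  rp = rs;
  rp.insert(rp.end(), rr.begin(), rr.end());

  if ((int)rs.size() < 2 || (int)rr.size() < 2)
    stop("each group needs at least 2 haplotypes");

  // chromosome block bounds per SNP
  std::vector<int> lo(nsnp), hi(nsnp);
  for (int j = 0; j < nsnp; ++j) {
    lo[j] = (j > 0 && chrom_id[j] == chrom_id[j - 1]) ? lo[j - 1] : j;
  }
  for (int j = nsnp - 1; j >= 0; --j) {
    hi[j] = (j < nsnp - 1 && chrom_id[j] == chrom_id[j + 1]) ? hi[j + 1] : j;
  }

  Partition pool, sel, ref;
  pool.init(rp);
  sel.init(rs);
  ref.init(rr);

  NumericVector out(nsnp);
  for (int j = 0; j < nsnp; ++j) {
    if ((j & 255) == 0) Rcpp::checkUserInterrupt();
    double i_sel = 0.0, i_ref = 0.0;
    const int* corecol = Hp + (size_t)j * nhap;
    for (int dir = -1; dir <= 1; dir += 2) {
      pool.reset();
      sel.reset();
      ref.reset();
      pool.refine(corecol);
      sel.refine(corecol);
      ref.refine(corecol);
      double prev_off = 0.0, prev_es = 1.0, prev_er = 1.0;
      for (int b = j + dir; b >= lo[j] && b <= hi[j]; b += dir) {
        const double off = std::fabs(pos[b] - pos[j]);
        if (off > max_extension) break;
        const int* col = Hp + (size_t)b * nhap;
        const double ep = pool.refine(col);
        const double es = sel.refine(col);
        const double er = ref.refine(col);
        i_sel += 0.5 * (prev_es + es) * (off - prev_off);
        i_ref += 0.5 * (prev_er + er) * (off - prev_off);
        prev_off = off;
        prev_es = es;
        prev_er = er;
        if (ep < truncation) break;
      }
    }
    out[j] = (i_sel > 0.0 && i_ref > 0.0) ? std::log(i_sel / i_ref) : NA_REAL;
  }
  return out;
}
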