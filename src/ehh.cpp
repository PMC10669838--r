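#include <Rcpp.h>
using namespace Rcpp;

// Extended haplotype homozygosity machinery.
//
// EHH at site x relative to a core site is the probability that two
// haplotypes drawn without replacement are identical at every site from
// the core out to x:  EHH(x) = sum_h C(c_h, 2) / C(n, 2), where c_h are
// the sizes of the identity classes. The partition is refined one site at
// a time while walking away from the core, so each step costs O(n).

namespace {

// Refine the class partition by the alleles at column `site` (0/1).
// `cls` holds a class id per haplotype; returns the updated number of
// classes and the homozygosity sum_h C(c_h,2).
double refine(std::vector<int>& cls, int& n_classes,
              const IntegerMatrix& hap, int site) {
  int n = cls.size();
  // new class id = 2*old + allele, then compact
  std::vector<int> key(n);
  for (int i = 0; i < n; ++i) key[i] = cls[i] * 2 + hap(i, site);
  std::vector<int> remap(2 * n_classes, -1);
  int next = 0;
  std::vector<int> count;
  for (int i = 0; i < n; ++i) {
    if (remap[key[i]] < 0) {
      remap[key[i]] = next++;
      count.push_back(0);
    }
    cls[i] = remap[key[i]];
    count[cls[i]] += 1;
  }
  n_classes = next;
  double pairs = 0.0;
  for (int k = 0; k < next; ++k)
    pairs += 0.5 * count[k] * (count[k] - 1.0);
  return pairs;
}

// One-sided EHH decay curve from `core` in direction dir (+1/-1).
// Appends (distance, ehh) points for each informative site reached;
// stops at cutoff crossing (point at the sub-cutoff site is included so R
// can interpolate), at a gap > max_gap (last in-range site is final), or
// at the chromosome end.
void side_curve(const IntegerMatrix& hap, const NumericVector& pos,
                int core, int dir, double cutoff, double max_gap,
                std::vector<double>& dist, std::vector<double>& ehh) {
  int n = hap.nrow(), m = hap.ncol();
  double tot_pairs = 0.5 * n * (n - 1.0);
  std::vector<int> cls(n, 0);
  int n_classes = 1;
  double prev_pos = pos[core];
  for (int s = core + dir; s >= 0 && s < m; s += dir) {
    if (std::abs(pos[s] - prev_pos) > max_gap) break;
    double e = refine(cls, n_classes, hap, s) / tot_pairs;
    dist.push_back(std::abs(pos[s] - pos[core]));
    ehh.push_back(e);
    if (e < cutoff) break;
    prev_pos = pos[s];
  }
}

// Integrate one side by trapezoids from (0, 1). If the last point fell
// below the cutoff, integrate only to the linearly interpolated crossing.
// Returns NA when the side has no points (no flanking site).
double side_ihh(const std::vector<double>& dist,
                const std::vector<double>& ehh, double cutoff) {
  if (dist.empty()) return NA_REAL;
  double area = 0.0, d0 = 0.0, e0 = 1.0;
  for (size_t k = 0; k < dist.size(); ++k) {
    double d1 = dist[k], e1 = ehh[k];
    if (e1 < cutoff) {
      // crossing between (d0,e0) and (d1,e1); e0 >= cutoff > e1
      double dcross = d0 + (d1 - d0) * (e0 - cutoff) /
                      std::max(e0 - e1, 1e-300);
      area += 0.5 * (dcross - d0) * (e0 + cutoff);
      return area;
    }
    area += 0.5 * (d1 - d0) * (e0 + e1);
    d0 = d1; e0 = e1;
  }
  return area;
}

}  // namespace

// [[Rcpp::export]]
List ehh_side_cpp(IntegerMatrix hap, NumericVector pos, int core, int dir,
                  double cutoff, double max_gap) {
  std::vector<double> dist, ehh;
  side_curve(hap, pos, core - 1, dir, cutoff, max_gap, dist, ehh);
  return List::create(_["distance"] = dist, _["ehh"] = ehh);
}

// Integrated EHH (both sides summed) at every site of one chromosome.
// NA where neither side has a flanking site; one-sided integral at
// chromosome edges.
// [[Rcpp::export]]
NumericVector ihh_scan_cpp(IntegerMatrix hap, NumericVector pos,
                           double cutoff, double max_gap) {
  int m = hap.ncol();
  NumericVector out(m);
  for (int core = 0; core < m; ++core) {
    std::vector<double> dl, el, dr, er;
    side_curve(hap, pos, core, -1, cutoff, max_gap, dl, el);
    side_curve(hap, pos, core, +1, cutoff, max_gap, dr, er);
    double left = side_ihh(dl, el, cutoff);
    double right = side_ihh(dr, er, cutoff);
    if (ISNA(left) && ISNA(right)) out[core] = NA_REAL;
    else out[core] = (ISNA(left) ? 0.0 : left) +
                     (ISNA(right) ? 0.0 : right);
  }
  return out;
}
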