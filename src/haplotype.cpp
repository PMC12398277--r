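#include <Rcpp.h>
using namespace Rcpp;

// Haplotype-homozygosity inner loops. Everything here works on a binary
// haplotype-by-site matrix (rows = haplotypes, cols = sites, entries 0/1,
// no missing data). EHH group refinement is the usual prefix-partition
// walk: haplotypes carrying the core allele start in one group and split
// whenever their alleles diverge while extending away from the core.

static std::vector<int> core_carriers(const IntegerMatrix &H, int core,
                                      int allele) {
  std::vector<int> idx;
  for (int i = 0; i < H.nrow(); ++i)
    if (H(i, core) == allele) idx.push_back(i);
  return idx;
}

// EHH = sum_h C(c_h,2) / C(n,2); numerator/denominator are exact integers,
// so the double division is bit-reproducible against an R oracle that
// computes the same ratio.
static double ehh_from_groups(const std::vector<int> &grp, int ngroups,
                              long long den) {
  std::vector<long long> cnt(ngroups, 0);
  for (size_t i = 0; i < grp.size(); ++i) cnt[grp[i]]++;
  long long num = 0;
  for (int g = 0; g < ngroups; ++g) num += cnt[g] * (cnt[g] - 1) / 2;
  return (double)num / (double)den;
}

// One arm of the EHH decay curve. dir = +1 (right) or -1 (left). The curve
// always starts at the core itself (EHH = 1). With clip = false the walk
// stops after recording the first site whose EHH drops below the cutoff;
// with clip = true it continues to the chromosome edge (or to EHH = 0,
// beyond which the curve cannot change).
// [[Rcpp::export]]
List ehh_arm_cpp(IntegerMatrix H, int core, int allele, int dir,
                 double cutoff, bool clip) {
  int nsite = H.ncol();
  std::vector<int> carriers = core_carriers(H, core, allele);
  int n = (int)carriers.size();
  if (n < 2) stop("fewer than 2 haplotypes carry the core allele");
  long long den = (long long)n * (n - 1) / 2;

  std::vector<int> site_out;
  std::vector<double> ehh_out;
  site_out.push_back(core);
  ehh_out.push_back(1.0);

  std::vector<int> grp(n, 0);
  int ngroups = 1;
  bool decayed = false;

  for (int t = core + dir; t >= 0 && t < nsite; t += dir) {
    // refine: new key = old group * 2 + allele at t, then compact labels
    std::vector<int> relabel(2 * ngroups, -1);
    int next = 0;
    for (int i = 0; i < n; ++i) {
      int key = grp[i] * 2 + H(carriers[i], t);
      if (relabel[key] < 0) relabel[key] = next++;
      grp[i] = relabel[key];
    }
    ngroups = next;
    double e = ehh_from_groups(grp, ngroups, den);
    site_out.push_back(t);
    ehh_out.push_back(e);
    if (e < cutoff) decayed = true;
    if (!clip && e < cutoff) break;
    if (e == 0.0) break;  // cannot recover; remaining trapezoids are zero
  }

  return List::create(_["site"] = wrap(site_out), _["ehh"] = wrap(ehh_out),
                      _["decayed"] = decayed, _["n_carriers"] = n);
}

static double arm_area(const List &arm, const IntegerVector &pos) {
  IntegerVector s = arm["site"];
  NumericVector e = arm["ehh"];
  double area = 0.0;
  for (int i = 1; i < s.size(); ++i) {
    double d = std::abs((double)pos[s[i]] - (double)pos[s[i - 1]]);
    area += 0.5 * (e[i] + e[i - 1]) * d;
  }
  return area;
}

// Unstandardized iHS at one core site: ln(iHH_ancestral / iHH_derived),
// trapezoid-integrated over physical distance. Returns c(daf, raw, valid,
// ihh_a, ihh_d); valid encodes carrier-count, decay (skip policy) and
// zero-area checks.
// [[Rcpp::export]]
NumericVector ihs_site_cpp(IntegerMatrix H, IntegerVector pos, int core,
                           double cutoff, bool clip) {
  int nhap = H.nrow();
  int n1 = 0;
  for (int i = 0; i < nhap; ++i) n1 += H(i, core);
  int n0 = nhap - n1;
  double daf = (double)n1 / (double)nhap;

  NumericVector out =
      NumericVector::create(_["daf"] = daf, _["raw"] = NA_REAL,
                            _["valid"] = 0.0, _["ihh_a"] = NA_REAL,
                            _["ihh_d"] = NA_REAL);
  if (n0 < 2 || n1 < 2) return out;

  bool all_decayed = true;
  double ihh[2];
  for (int allele = 0; allele <= 1; ++allele) {
    List left = ehh_arm_cpp(H, core, allele, -1, cutoff, clip);
    List right = ehh_arm_cpp(H, core, allele, +1, cutoff, clip);
    if (!as<bool>(left["decayed"]) || !as<bool>(right["decayed"]))
      all_decayed = false;
    ihh[allele] = arm_area(left, pos) + arm_area(right, pos);
  }
  out["ihh_a"] = ihh[0];
  out["ihh_d"] = ihh[1];
  if ((!clip && !all_decayed) || ihh[0] <= 0.0 || ihh[1] <= 0.0) return out;
  out["raw"] = std::log(ihh[0] / ihh[1]);
  out["valid"] = 1.0;
  return out;
}

// Mean pairwise shared-segment length (in sites, core inclusive) among the
// haplotypes carrying `allele` at the core. NA if fewer than 2 carriers.
// [[Rcpp::export]]
double sl_mean_cpp(IntegerMatrix H, int core, int allele) {
  int nsite = H.ncol();
  std::vector<int> carriers = core_carriers(H, core, allele);
  int n = (int)carriers.size();
  if (n < 2) return NA_REAL;
  long long total = 0;
  for (int a = 0; a < n - 1; ++a) {
    for (int b = a + 1; b < n; ++b) {
      int i = carriers[a], j = carriers[b];
      long long L = 1;
      for (int t = core - 1; t >= 0 && H(i, t) == H(j, t); --t) L++;
      for (int t = core + 1; t < nsite && H(i, t) == H(j, t); ++t) L++;
      total += L;
    }
  }
  long long npairs = (long long)n * (n - 1) / 2;
  return (double)total / (double)npairs;
}
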