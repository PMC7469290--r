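#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

// 64-bit mixing (splitmix64 finalizer); seed folded in by xor so sketches
// are deterministic across platforms for a fixed seed.
static inline uint64_t mix64(uint64_t x) {
  x ^= x >> 30; x *= 0xBF58476D1CE4E5B9ULL;
  x ^= x >> 27; x *= 0x94D049BB133111EBULL;
  x ^= x >> 31;
  return x;
}

static inline int base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Hash all distinct canonical k-mers of a sequence. k <= 31 (2-bit packed).
// Returned values are hashes >> 11: 53 bits, exactly representable as
// doubles, strictly increasing after sort.
static std::vector<double> canonical_hashes(const std::string &seq, int k,
                                            uint64_t seed) {
  const size_t n = seq.size();
  std::unordered_set<uint64_t> codes;
  if (n < (size_t)k) return std::vector<double>();
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int run = 0;  // length of current valid (ACGT) run
  for (size_t i = 0; i < n; ++i) {
    int b = base2bit(seq[i]);
    if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
    if (++run >= k) codes.insert(fwd < rev ? fwd : rev);
  }
  std::vector<double> out;
  out.reserve(codes.size());
  for (uint64_t c : codes) out.push_back((double)(mix64(c ^ seed) >> 11));
  std::sort(out.begin(), out.end());
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sketch(std::string seq, int k, double s, double seed) {
  std::vector<double> h = canonical_hashes(seq, k, (uint64_t)seed);
  size_t keep = h.size();
  if (R_finite(s) && (double)keep > s) keep = (size_t)s;
  return NumericVector(h.begin(), h.begin() + keep);
}

// Mash-style Jaccard estimate: among the s smallest distinct hashes of the
// union of two sketches, the fraction present in both.
// [[Rcpp::export]]
double cpp_jaccard(NumericVector a, NumericVector b, double s) {
  size_t i = 0, j = 0, considered = 0, shared = 0;
  const size_t na = a.size(), nb = b.size();
  while ((i < na || j < nb) && (!R_finite(s) || (double)considered < s)) {
    if (i < na && (j >= nb || a[i] < b[j])) { ++i; }
    else if (j < nb && (i >= na || b[j] < a[i])) { ++j; }
    else { ++shared; ++i; ++j; }
    ++considered;
  }
  if (considered == 0) return NA_REAL;
  return (double)shared / (double)considered;
}

// Symmetric matrix of Mash distances d = min(1, -(1/k) log(2j/(1+j)))
// over a list of sketches (sorted hash vectors sharing k and s).
// [[Rcpp::export]]
NumericMatrix cpp_pairwise_mash(List sketches, int k, double s) {
  const int n = sketches.size();
  std::vector<NumericVector> sk(n);
  for (int i = 0; i < n; ++i) sk[i] = as<NumericVector>(sketches[i]);
  NumericMatrix d(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double jac = cpp_jaccard(sk[i], sk[j], s);
      double dist = 1.0;
      if (jac > 0) {
        dist = -std::log(2.0 * jac / (1.0 + jac)) / (double)k;
        if (dist > 1.0) dist = 1.0;
        if (dist < 0.0) dist = 0.0;
      }
      d(i, j) = dist;
      d(j, i) = dist;
    }
  }
  return d;
}

// PERMANOVA machinery. d2 is the squared-distance matrix; groups are
// 0-based integer labels. Returns SS_total, SS_within for a labelling.
static void perm_ss(const NumericMatrix &d2, const std::vector<int> &g,
                    int n_groups, double *ss_total, double *ss_within) {
  const int n = d2.nrow();
  std::vector<double> ssw(n_groups, 0.0);
  std::vector<int> cnt(n_groups, 0);
  double sst = 0.0;
  for (int i = 0; i < n; ++i) {
    cnt[g[i]]++;
    for (int j = i + 1; j < n; ++j) {
      sst += d2(i, j);
      if (g[i] == g[j]) ssw[g[i]] += d2(i, j);
    }
  }
  double ssw_tot = 0.0;
  for (int a = 0; a < n_groups; ++a) ssw_tot += ssw[a] / (double)cnt[a];
  *ss_total = sst / (double)n;
  *ss_within = ssw_tot;
}

// [[Rcpp::export]]
NumericVector cpp_permanova_stat(NumericMatrix d2, IntegerVector groups,
                                 int n_groups) {
  std::vector<int> g(groups.begin(), groups.end());
  double sst, ssw;
  perm_ss(d2, g, n_groups, &sst, &ssw);
  const int n = d2.nrow();
  double ssb = sst - ssw;
  double F = (ssb / (double)(n_groups - 1)) / (ssw / (double)(n - n_groups));
  return NumericVector::create(F, ssb / sst, sst, ssw);
}

// Permutation F distribution under free relabelling; uses R's RNG so
// set.seed() at the R level controls it.
// [[Rcpp::export]]
NumericVector cpp_permanova_perms(NumericMatrix d2, IntegerVector groups,
                                  int n_groups, int n_perm) {
  const int n = d2.nrow();
  std::vector<int> g(groups.begin(), groups.end());
  NumericVector Fs(n_perm);
  RNGScope scope;
  for (int p = 0; p < n_perm; ++p) {
    // Fisher-Yates shuffle of labels
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(g[i], g[j]);
    }
    double sst, ssw;
    perm_ss(d2, g, n_groups, &sst, &ssw);
    double ssb = sst - ssw;
    Fs[p] = (ssb / (double)(n_groups - 1)) / (ssw / (double)(n - n_groups));
  }
  return Fs;
}
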