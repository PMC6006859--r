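#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Haplotype storage convention: RawMatrix of dimension L x 2n (loci in rows,
// haplotypes in columns) so that one gamete is a set of contiguous column
// segments and segment copying is cache-friendly. Individual i (0-based) owns
// columns 2i and 2i + 1.

namespace {

// One meiosis for parent `parent` (0-based individual index) of `haps`,
// written into `out` (pointer to L bytes). Crossover count per chromosome is
// Binomial(max_xo, len_Morgan / max_xo), positions i.i.d. uniform on the
// chromosome, starting strand fair. Mutation flips each locus independently
// with probability mu (reversible).
void make_gamete(const unsigned char* haps, int L, int parent,
                 const std::vector<double>& pos,
                 const std::vector<int>& chr_off,
                 const std::vector<double>& chr_len,
                 int max_xo, double mu, unsigned char* out) {
  const unsigned char* h0 = haps + (size_t)(2 * parent) * L;
  const unsigned char* h1 = haps + (size_t)(2 * parent + 1) * L;
  int nchr = (int)chr_len.size();
  std::vector<double> xo;
  for (int c = 0; c < nchr; ++c) {
    int lo = chr_off[c], hi = chr_off[c + 1];
    double len = chr_len[c];
    double p = (len / 100.0) / max_xo;  // map length in Morgan over cap
    int k = (int)R::rbinom(max_xo, p);
    xo.clear();
    for (int t = 0; t < k; ++t) xo.push_back(unif_rand() * len);
    std::sort(xo.begin(), xo.end());
    int cur = (unif_rand() < 0.5) ? 0 : 1;
    int seg_start = lo;
    for (int t = 0; t <= k; ++t) {
      // segment ends at first locus with pos >= crossover t (or chromosome end)
      int seg_end;
      if (t < k) {
        const double* pb = pos.data() + lo;
        seg_end = lo + (int)(std::lower_bound(pb, pos.data() + hi, xo[t]) - pb);
      } else {
        seg_end = hi;
      }
      if (seg_end > seg_start) {
        const unsigned char* src = (cur == 0 ? h0 : h1);
        std::copy(src + seg_start, src + seg_end, out + seg_start);
      }
      seg_start = seg_end;
      cur ^= 1;
    }
  }
  if (mu > 0) {
    if (mu >= 0.01) {
      for (int l = 0; l < L; ++l)
        if (unif_rand() < mu) out[l] ^= 1;
    } else {
      // rare mutations: draw the count, then distinct positions
      int m = (int)R::rbinom(L, mu);
      std::vector<int> hit;
      while ((int)hit.size() < m) {
        int idx = (int)(unif_rand() * L);
        if (idx >= L) idx = L - 1;
        if (std::find(hit.begin(), hit.end(), idx) == hit.end()) hit.push_back(idx);
      }
      for (int idx : hit) out[idx] ^= 1;
    }
  }
}

}  // namespace

// [[Rcpp::export]]
RawMatrix cpp_make_gametes(RawMatrix haps, IntegerVector parents,
                           NumericVector pos, IntegerVector chr_off,
                           NumericVector chr_len, int max_xo, double mu) {
  int L = haps.nrow();
  if ((int)pos.size() != L) stop("position vector does not match locus count");
  int ng = parents.size();
  RawMatrix out(L, ng);
  std::vector<double> vpos(pos.begin(), pos.end());
  std::vector<int> voff(chr_off.begin(), chr_off.end());
  std::vector<double> vlen(chr_len.begin(), chr_len.end());
  const unsigned char* hp = (const unsigned char*)RAW(haps);
  unsigned char* op = (unsigned char*)RAW(out);
  int n_ind = haps.ncol() / 2;
  for (int g = 0; g < ng; ++g) {
    int par = parents[g];
    if (par < 0 || par >= n_ind) stop("parent index out of range");
    make_gamete(hp, L, par, vpos, voff, vlen, max_xo, mu, op + (size_t)g * L);
  }
  return out;
}

// Constant-size random-mating phase run entirely in C++ (burn-in and breed
// drift). Monoecious random union without selfing; no pedigree is recorded.
// [[Rcpp::export]]
RawMatrix cpp_random_mate_phase(RawMatrix haps, int n_generations,
                                NumericVector pos, IntegerVector chr_off,
                                NumericVector chr_len, int max_xo, double mu) {
  int L = haps.nrow();
  int n = haps.ncol() / 2;
  if (n < 2) stop("need at least two parents");
  std::vector<double> vpos(pos.begin(), pos.end());
  std::vector<int> voff(chr_off.begin(), chr_off.end());
  std::vector<double> vlen(chr_len.begin(), chr_len.end());
  std::vector<unsigned char> cur((size_t)L * 2 * n), nxt((size_t)L * 2 * n);
  std::copy(RAW(haps), RAW(haps) + cur.size(), cur.begin());
  for (int g = 0; g < n_generations; ++g) {
    for (int i = 0; i < n; ++i) {
      int sire = (int)(unif_rand() * n);
      if (sire >= n) sire = n - 1;
      int dam;
      do {
        dam = (int)(unif_rand() * n);
        if (dam >= n) dam = n - 1;
      } while (dam == sire);
      make_gamete(cur.data(), L, sire, vpos, voff, vlen, max_xo, mu,
                  nxt.data() + (size_t)(2 * i) * L);
      make_gamete(cur.data(), L, dam, vpos, voff, vlen, max_xo, mu,
                  nxt.data() + (size_t)(2 * i + 1) * L);
    }
    cur.swap(nxt);
    if ((g & 63) == 0) Rcpp::checkUserInterrupt();
  }
  RawMatrix out(L, 2 * n);
  std::copy(cur.begin(), cur.end(), RAW(out));
  return out;
}

// Genotype dosage matrix (n x L, counts of the '1' allele).
// [[Rcpp::export]]
IntegerMatrix cpp_genotypes(RawMatrix haps) {
  int L = haps.nrow();
  int n = haps.ncol() / 2;
  IntegerMatrix W(n, L);
  const unsigned char* hp = (const unsigned char*)RAW(haps);
  for (int i = 0; i < n; ++i) {
    const unsigned char* a = hp + (size_t)(2 * i) * L;
    const unsigned char* b = hp + (size_t)(2 * i + 1) * L;
    for (int l = 0; l < L; ++l) W(i, l) = a[l] + b[l];
  }
  return W;
}

// Tabular-method additive relationship matrix. sire/dam are 1-based indices
// into the (generation-sorted) pedigree, 0 for unknown; founders are assumed
// unrelated and non-inbred.
// [[Rcpp::export]]
NumericMatrix cpp_tabular_A(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i], d = dam[i];
    if (s > i || d > i) stop("pedigree not sorted: parent after offspring");
    A(i, i) = 1.0 + (s > 0 && d > 0 ? 0.5 * A(s - 1, d - 1) : 0.0);
    for (int j = 0; j < i; ++j) {
      double v = 0.0;
      if (s > 0) v += 0.5 * A(j, s - 1);
      if (d > 0) v += 0.5 * A(j, d - 1);
      A(i, j) = v;
      A(j, i) = v;
    }
  }
  return A;
}
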