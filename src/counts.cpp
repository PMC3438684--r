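#include <Rcpp.h>
using namespace Rcpp;

// Single-pass range check of a genotype matrix (NA ignored).
// Returns TRUE when all non-missing values are in {0, 1, 2}.
// [[Rcpp::export(name = ".geno_codes_ok")]]
bool geno_codes_ok(const IntegerMatrix& G) {
  const R_xlen_t len = (R_xlen_t)G.nrow() * G.ncol();
  const int* g = INTEGER(G);
  for (R_xlen_t i = 0; i < len; ++i) {
    if (g[i] != NA_INTEGER && (g[i] < 0 || g[i] > 2)) return false;
  }
  return true;
}

// Class-conditional genotype counts.
// G: subjects x SNPs integer matrix, values 0/1/2 or NA (missing, skipped).
// cls: 1-based class index per subject (length = nrow(G)), K classes.
// Returns integer array [3, K, m].
// [[Rcpp::export(name = ".count_geno")]]
IntegerVector count_geno(const IntegerMatrix& G, const IntegerVector& cls,
                         int K) {
  const int n = G.nrow(), m = G.ncol();
  if (cls.size() != n) stop("class vector length mismatch");
  IntegerVector out(3 * K * m);
  int* o = INTEGER(out);
  for (int j = 0; j < m; ++j) {
    const int* gj = &G(0, j);
    int* oj = o + (size_t)j * 3 * K;
    for (int i = 0; i < n; ++i) {
      const int g = gj[i];
      if (g == NA_INTEGER) continue;
      oj[g + 3 * (cls[i] - 1)]++;
    }
  }
  out.attr("dim") = IntegerVector::create(3, K, m);
  return out;
}

// As count_geno but additionally split by cross-validation fold.
// Returns integer array [3, K, F, m]; training counts for fold f are the
// totals minus slice f.
// [[Rcpp::export(name = ".count_geno_folds")]]
IntegerVector count_geno_folds(const IntegerMatrix& G,
                               const IntegerVector& cls, int K,
                               const IntegerVector& fold, int F) {
  const int n = G.nrow(), m = G.ncol();
  if (cls.size() != n || fold.size() != n) stop("index length mismatch");
  IntegerVector out((size_t)3 * K * F * m);
  int* o = INTEGER(out);
  for (int j = 0; j < m; ++j) {
    const int* gj = &G(0, j);
    int* oj = o + (size_t)j * 3 * K * F;
    for (int i = 0; i < n; ++i) {
      const int g = gj[i];
      if (g == NA_INTEGER) continue;
      oj[g + 3 * ((cls[i] - 1) + K * (fold[i] - 1))]++;
    }
  }
  out.attr("dim") = IntegerVector::create(3, K, F, m);
  return out;
}

// Draw genotypes from per-class categorical distributions.
// cum: numeric array [2, K, m]; cum(0,k,j) = P(g=0), cum(1,k,j) = P(g<=1)
// for SNP j in class k.  cls: 1-based class per subject.
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export(name = ".gen_genotypes")]]
IntegerMatrix gen_genotypes(const NumericVector& cum,
                            const IntegerVector& cls, int K, int m) {
  const int n = cls.size();
  IntegerMatrix G(n, m);
  const double* cp = REAL(cum);
  RNGScope scope;
  for (int j = 0; j < m; ++j) {
    int* gj = &G(0, j);
    const double* cpj = cp + (size_t)j * 2 * K;
    for (int i = 0; i < n; ++i) {
      const double* c2 = cpj + 2 * (cls[i] - 1);
      const double u = unif_rand();
      gj[i] = (u > c2[0]) + (u > c2[1]);
    }
  }
  return G;
}

// Cumulative per-class log-posteriors along a ranked SNP list.
// logcpt: [K, 3, r] log P(g | class, SNP_i) for the genotypic coding;
// G: test subjects x r ranked SNPs (0/1/2/NA; NA contributes nothing);
// logprior: length K.  Returns numeric array [n, r, K] of
// log prior + sum_{i<=r} log P(g_i | class).
// [[Rcpp::export(name = ".cum_logpost")]]
NumericVector cum_logpost(const NumericVector& logcpt, const IntegerMatrix& G,
                          const NumericVector& logprior) {
  const int n = G.nrow(), r = G.ncol(), K = logprior.size();
  NumericVector out((size_t)n * r * K);
  double* o = REAL(out);
  const double* lc = REAL(logcpt);
  std::vector<double> acc((size_t)n * K);
  for (int k = 0; k < K; ++k)
    for (int i = 0; i < n; ++i) acc[(size_t)k * n + i] = logprior[k];
  for (int j = 0; j < r; ++j) {
    const int* gj = &G(0, j);
    const double* lcj = lc + (size_t)j * K * 3;
    for (int k = 0; k < K; ++k) {
      double* a = &acc[(size_t)k * n];
      double* oj = o + (size_t)k * n * r + (size_t)j * n;
      const double* lck = lcj + k;
      for (int i = 0; i < n; ++i) {
        const int g = gj[i];
        if (g != NA_INTEGER) a[i] += lck[(size_t)K * g];
        oj[i] = a[i];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(n, r, K);
  return out;
}
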