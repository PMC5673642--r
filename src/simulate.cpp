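// Sequence simulation kernels. All randomness goes through R's RNG so that
// set.seed() in R makes every generator reproducible.

#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

static const char BASES[4] = {'A', 'C', 'G', 'T'};

static inline int rbase_from(const double *p) {
  // p: 4 cumulative probabilities (last == 1)
  double u = unif_rand();
  for (int b = 0; b < 3; ++b) if (u < p[b]) return b;
  return 3;
}

// Order-2 Markov chain over {A,C,G,T}. trans: 16 x 4 row-stochastic matrix,
// row index = 4 * code(prev2) + code(prev1). init: length-4 marginal.
// [[Rcpp::export]]
std::string cpp_markov_chain(int length, NumericMatrix trans, NumericVector init) {
  if (length < 2) stop("length must be >= 2");
  if (trans.nrow() != 16 || trans.ncol() != 4) stop("trans must be 16 x 4");
  // cumulative rows
  double cinit[4]; double acc = 0.0;
  for (int b = 0; b < 4; ++b) { acc += init[b]; cinit[b] = acc; }
  std::vector<double> ctr(16 * 4);
  for (int r = 0; r < 16; ++r) {
    double a = 0.0;
    for (int b = 0; b < 4; ++b) { a += trans(r, b); ctr[r * 4 + b] = a; }
  }
  std::string out(length, 'A');
  int p2 = rbase_from(cinit), p1 = rbase_from(cinit);
  out[0] = BASES[p2]; out[1] = BASES[p1];
  for (int i = 2; i < length; ++i) {
    int b = rbase_from(&ctr[(p2 * 4 + p1) * 4]);
    out[i] = BASES[b];
    p2 = p1; p1 = b;
  }
  return out;
}

// Substitution-only mutation at per-site rate mu; N bases left untouched.
// [[Rcpp::export]]
std::string cpp_mutate(std::string seq, double mu) {
  if (mu < 0 || mu > 1) stop("mu must be in [0, 1]");
  if (mu == 0) return seq;
  for (size_t i = 0; i < seq.size(); ++i) {
    char c = seq[i];
    int b;
    switch (c) {
      case 'A': b = 0; break; case 'C': b = 1; break;
      case 'G': b = 2; break; case 'T': b = 3; break;
      default: continue;
    }
    if (unif_rand() < mu) {
      int nb = (b + 1 + (int)(unif_rand() * 3)) & 3;  // one of the other three
      seq[i] = BASES[nb];
    }
  }
  return seq;
}

// i.i.d. substitution errors applied to every read.
// [[Rcpp::export]]
CharacterVector cpp_add_errors(CharacterVector reads, double rate) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]");
  if (rate == 0) return reads;
  CharacterVector out(reads.size());
  for (int i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    out[i] = cpp_mutate(s, rate);
  }
  return out;
}
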