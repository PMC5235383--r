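#include <Rcpp.h>
using namespace Rcpp;

// Sample a first-order Markov chain of the given length.
// cumtrans: k x k row-wise cumulative transition probabilities;
// cuminit:  cumulative initial distribution (length k).
// Uses R's RNG, so set.seed() on the R side governs reproducibility.
// Returns 1-based state indices.
// [[Rcpp::export]]
IntegerVector markov_chain_sample(NumericMatrix cumtrans,
                                  NumericVector cuminit,
                                  int len) {
  if (len < 1) stop("`len` must be >= 1");
  const int k = cumtrans.ncol();
  if (cumtrans.nrow() != k || cuminit.size() != k)
    stop("dimension mismatch between transition table and initial distribution");
  IntegerVector out(len);

  double u = unif_rand();
  int s = 0;
  while (s < k - 1 && u > cuminit[s]) ++s;
  out[0] = s + 1;

  for (int t = 1; t < len; ++t) {
    u = unif_rand();
    int j = 0;
    while (j < k - 1 && u > cumtrans(s, j)) ++j;
    s = j;
    out[t] = s + 1;
  }
  return out;
}
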