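#include <Rcpp.h>
using namespace Rcpp;

// Sample an index in [0, n) from cumulative probabilities cum (cum[n-1] == 1).
static inline int sample_cum(const double *cum, int n) {
  double u = unif_rand();
  for (int i = 0; i < n - 1; ++i)
    if (u < cum[i]) return i;
  return n - 1;
}

//' @useDynLib parcubin, .registration = TRUE
//' @importFrom Rcpp sourceCpp
// [[Rcpp::export(name = ".markov_sequence")]]
std::string markov_sequence(int length, int order, NumericMatrix trans,
                            NumericVector base_probs) {
  if (length < 1) stop("length must be positive");
  const int ncontext = trans.nrow();
  if (order > 0 && ncontext != (int)std::pow(4.0, order))
    stop("transition matrix must have 4^order rows");
  RNGScope scope;

  // Row-wise cumulative transition probabilities.
  std::vector<double> cum(ncontext * 4);
  for (int r = 0; r < ncontext; ++r) {
    double acc = 0.0;
    for (int c = 0; c < 4; ++c) {
      acc += trans(r, c);
      cum[r * 4 + c] = acc;
    }
    for (int c = 0; c < 4; ++c) cum[r * 4 + c] /= acc;
  }
  double cum0[4];
  {
    double acc = 0.0;
    for (int c = 0; c < 4; ++c) { acc += base_probs[c]; cum0[c] = acc; }
    for (int c = 0; c < 4; ++c) cum0[c] /= acc;
  }

  static const char alphabet[] = "ACGT";
  std::string out(length, 'A');
  int context = 0;
  const int mask = (order > 0) ? (ncontext - 1) : 0;
  for (int i = 0; i < length; ++i) {
    int b;
    if (i < order) {
      b = sample_cum(cum0, 4);  // burn-in bases drawn from the marginal
    } else {
      b = sample_cum(&cum[context * 4], 4);
    }
    out[i] = alphabet[b];
    if (order > 0) context = ((context << 2) | b) & mask;
  }
  return out;
}
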