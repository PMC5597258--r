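#include <Rcpp.h>
#include "rng.h"
using namespace Rcpp;

// R-facing handles to the counter-seeded streams, mainly so tests can assert
// the reproducibility contract (same seed + stream id -> same draws).

// [[Rcpp::export]]
SEXP rng_stream_create(double seed, double stream_id) {
  Xoshiro *x = new Xoshiro();
  x->seed((uint64_t)seed, (uint64_t)stream_id);
  XPtr<Xoshiro> ptr(x, true);
  return ptr;
}

// [[Rcpp::export]]
NumericVector rng_stream_unif(SEXP handle, int n) {
  XPtr<Xoshiro> ptr(handle);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = ptr->unif();
  return out;
}

// [[Rcpp::export]]
IntegerVector rng_stream_binom(SEXP handle, IntegerVector size, NumericVector prob) {
  XPtr<Xoshiro> ptr(handle);
  int n = size.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rbinom_stream(*ptr, size[i], prob[i]);
  return out;
}
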