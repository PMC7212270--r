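# Shared fixtures, memoized across test files within one run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Small processed bundle used by several unit tests.
small_bundle <- function() {
  memo("small", {
    fx <- standard_fixture("small", seed = 7)
    fx$pt <- suppressWarnings(preprocess_features(fx$table))
    fx
  })
}

# Separable two-feature toy problem for classifier-contract tests.
toy_separable <- function(n = 60, seed = 42) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  X <- cbind(f1 = rnorm(n, mean = 3 * y), f2 = rnorm(n, mean = -3 * y))
  list(X = X, y = y)
}

# Independent enumeration oracle for the upper hypergeometric tail:
# builds the probability mass function from binomial coefficients and sums
# the tail, never touching phyper.
hyper_tail_oracle <- function(N, K, n, k) {
  ks <- max(0, n - (N - K)):min(n, K)
  dens <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(dens[ks >= k])
}
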