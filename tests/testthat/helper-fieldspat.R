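# Brute-force Moran's I with inverse-distance weights, written as the naive
# double loop, to serve as an oracle for the vectorized implementation.
moran_brute <- function(z, xy) {
  n <- length(z)
  num <- 0
  sw <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      w <- 1 / sqrt(sum((xy[i, ] - xy[j, ])^2))
      num <- num + w * z[i] * z[j]
      sw <- sw + w
    }
  }
  (n / sw) * num / sum(z^2)
}

# Elastic-net objective with unpenalized intercept, the quantity en_core /
# elastic_net minimize: 1/(2n) ||y - b0 - X b||^2 + lambda (a|b|_1 + (1-a)/2 |b|_2^2)
en_objective <- function(y, X, beta0, beta, lambda, alpha = 0.5) {
  n <- length(y)
  sum((y - beta0 - drop(X %*% beta))^2) / (2 * n) +
    lambda * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
}

# Dense multivariate-normal negative log density, the textbook formula, as an
# oracle for neg_log_likelihood(method = "ML").
mvn_nll_dense <- function(y, mu, sigma) {
  n <- length(y)
  e <- y - mu
  0.5 * (n * log(2 * pi) + determinant(sigma, logarithm = TRUE)$modulus[1] +
           drop(e %*% solve(sigma, e)))
}

expect_tbl <- function(x) {
  expect_s3_class(x, "tbl_df")
}

# Plain data frame with only its column values: drops class, truth/seed/config
# attributes so that comparisons look at the data, not the metadata.
strip_attrs <- function(df) {
  df <- as.data.frame(df)
  attributes(df) <- attributes(df)[c("names", "class", "row.names")]
  rownames(df) <- NULL
  df
}
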