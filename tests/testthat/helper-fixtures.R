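# small constructors shared across test files

toy_matrix <- function(n, p, seed = 1, prefix = "S") {
  set.seed(seed)
  v <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("%s%02d", prefix, seq_len(n)),
                              sprintf("f%02d", seq_len(p))))
  v
}

toy_fused <- function(W, ids = sprintf("S%02d", seq_len(nrow(W)))) {
  multigatae:::new_similarity_network(W, "fused", ids)
}

# embedding with k well-separated Gaussian blobs: centres on orthogonal
# axes, so every pair of centres is exactly sep*sqrt(2) apart
blob_embedding <- function(n, k, d = 8, sep = 10, spread = 1, seed = 1) {
  stopifnot(k <= d)
  set.seed(seed)
  centers <- diag(d)[seq_len(k), , drop = FALSE] * sep
  lab <- rep_len(seq_len(k), n)
  X <- centers[lab, , drop = FALSE] + matrix(rnorm(n * d, 0, spread), n, d)
  rownames(X) <- sprintf("S%03d", seq_len(n))
  list(X = X, labels = lab)
}
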