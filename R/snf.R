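#' Similarity network fusion configuration
#'
#' @param alpha Kernel bandwidth hyperparameter (> 0). 0.5 is the midpoint of
#'   the range recommended for the scaled exponential kernel.
#' @param K_neighbors Neighbourhood size for local scaling and the local
#'   affinity matrix (default 20).
#' @param T_iterations Number of fusion iterations (default 20).
#' @return An `snf_config` list.
#' @export
snf_config <- function(alpha = 0.5, K_neighbors = 20, T_iterations = 20) {
  stopifnot(alpha > 0, K_neighbors >= 1, T_iterations >= 1)
  structure(list(alpha = alpha, K_neighbors = as.integer(K_neighbors),
                 T_iterations = as.integer(T_iterations)),
            class = "snf_config")
}

new_similarity_network <- function(w, kind, ids) {
  dimnames(w) <- list(ids, ids)
  structure(w, kind = kind, class = c("similarity_network", "matrix", "array"))
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf("<similarity_network '%s'> %d samples\n", network_kind(x), nrow(x)))
  invisible(x)
}

#' Kind of a similarity network
#' @param x A `similarity_network`.
#' @return One of "kernel_W", "normalized_P", "local_S", "fused".
#' @export
network_kind <- function(x) attr(x, "kind")

#' Patient affinity kernel
#'
#' Builds the n x n similarity matrix
#' \deqn{W_{ij} = \exp(-d_{ij}^2 / (\alpha \epsilon_{ij}^2))}
#' where \eqn{d_{ij}} is the Euclidean distance between patients and
#' \eqn{\epsilon_{ij} = (\bar d_i + \bar d_j + d_{ij})/3} is the local scaling
#' term, \eqn{\bar d_i} being the mean distance of patient i to its
#' `K_neighbors` nearest neighbours. Squaring \eqn{\epsilon} keeps the
#' exponent dimensionless; at \eqn{\alpha = 0.5} the exponent coincides with
#' the scaled exponential kernel used by similarity network fusion. The local
#' scaling removes the need for a global bandwidth.
#'
#' @param m A preprocessed (imputed, standardised) [omics_matrix()] or plain
#'   numeric matrix with sample rownames.
#' @param cfg An [snf_config()].
#' @return A `similarity_network` of kind `kernel_W`: symmetric, unit
#'   diagonal, entries in (0, 1].
#' @export
affinity_kernel <- function(m, cfg = snf_config()) {
  v <- unclass(as_omics(m))
  n <- nrow(v)
  if (n < 3) stop("affinity_kernel: need at least 3 samples for local scaling")
  K <- min(cfg$K_neighbors, n - 1)
  d <- as.matrix(stats::dist(v))
  # mean distance of each sample to its K nearest neighbours (self excluded)
  dbar <- apply(d, 1, function(r) mean(sort(r)[2:(K + 1)]))
  eps <- (outer(dbar, dbar, "+") + d) / 3
  eps <- pmax(eps, .Machine$double.eps)
  W <- exp(-d^2 / (cfg$alpha * eps^2))
  W <- (W + t(W)) / 2
  new_similarity_network(W, "kernel_W", rownames(v))
}

#' Row-stochastic normalisation of a kernel
#'
#' Off-diagonal entries become \eqn{P_{ij} = W_{ij} / (2\sum_{k\ne i} W_{ik})}
#' and the diagonal is set to 1/2, so each row sums to exactly 1 while the
#' self-similarity carries half the mass.
#'
#' @param w A `kernel_W` [affinity_kernel()] network.
#' @return A `similarity_network` of kind `normalized_P`.
#' @export
normalize_P <- function(w) {
  stopifnot(identical(network_kind(w), "kernel_W"))
  W <- unclass(w)
  n <- nrow(W)
  off <- rowSums(W) - diag(W)
  if (any(off <= 0))
    stop("normalize_P: row(s) with zero off-diagonal mass: ",
         paste(rownames(W)[off <= 0], collapse = ", "))
  P <- W / (2 * off)
  diag(P) <- 0.5
  new_similarity_network(P, "normalized_P", rownames(W))
}

#' Local affinity matrix
#'
#' Sparsifies a kernel to each patient's `K_neighbors` nearest neighbours (by
#' kernel weight, self excluded) and row-normalises over that neighbourhood:
#' \eqn{S_{ij} = W_{ij} / \sum_{k \in N_i} W_{ik}} for \eqn{j \in N_i}, else
#' 0. This is the sparse diffusion operator used in the fusion iterations.
#'
#' @inheritParams normalize_P
#' @param cfg An [snf_config()]; `K_neighbors` must be < n.
#' @return A `similarity_network` of kind `local_S` with exactly
#'   `K_neighbors` nonzeros per row, each row summing to 1.
#' @export
local_affinity <- function(w, cfg = snf_config()) {
  stopifnot(identical(network_kind(w), "kernel_W"))
  W <- unclass(w)
  n <- nrow(W)
  K <- cfg$K_neighbors
  if (K >= n) stop("local_affinity: K_neighbors must be < number of samples")
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    wi <- W[i, ]
    wi[i] <- -Inf                               # self never a neighbour
    nb <- order(wi, decreasing = TRUE)[seq_len(K)]
    S[i, nb] <- W[i, nb] / sum(W[i, nb])
  }
  new_similarity_network(S, "local_S", rownames(W))
}

# Eq. 2's rule applied to an arbitrary nonnegative matrix, used to keep
# iterates row-stochastic with diagonal 1/2.
renormalize_P <- function(M) {
  off <- rowSums(M) - diag(M)
  off[off <= 0] <- .Machine$double.eps
  P <- M / (2 * off)
  diag(P) <- 0.5
  P
}

#' Similarity network fusion
#'
#' Iteratively diffuses each omics' normalised similarity through its local
#' affinity operator while averaging in the other omics' networks:
#' \deqn{P^{(h)} \leftarrow S^{(h)} \Big(\sum_{k \ne h} P^{(k)}/(m-1)\Big) S^{(h)\top}}
#' After each update the iterates are symmetrised and re-normalised
#' (row-stochastic, diagonal 1/2) for numerical stability. The fused network
#' is the symmetrised average of the m matrices after `T_iterations` rounds.
#' With a single omics the normalised network is passed through unchanged so
#' single-omics ablations run the same pipeline.
#'
#' @param P_list List of `normalized_P` networks, one per omics.
#' @param S_list List of matching `local_S` networks.
#' @param cfg An [snf_config()].
#' @return A `similarity_network` of kind `fused`: symmetric, nonnegative.
#' @export
snf_fuse <- function(P_list, S_list, cfg = snf_config()) {
  m <- length(P_list)
  stopifnot(m >= 1, length(S_list) == m)
  ids <- rownames(P_list[[1]])
  for (x in c(P_list, S_list)) {
    if (!identical(rownames(x), ids))
      stop("snf_fuse: sample IDs/order differ between networks")
  }
  if (m == 1) {
    out <- unclass(P_list[[1]])
    return(new_similarity_network(out, "fused", ids))
  }
  P <- lapply(P_list, unclass)
  S <- lapply(S_list, unclass)
  for (t in seq_len(cfg$T_iterations)) {
    Pnew <- vector("list", m)
    for (h in seq_len(m)) {
      others <- Reduce(`+`, P[-h]) / (m - 1)
      M <- S[[h]] %*% others %*% t(S[[h]])
      M <- (M + t(M)) / 2
      Pnew[[h]] <- renormalize_P(M)
    }
    P <- Pnew
  }
  fused <- Reduce(`+`, P) / m
  fused <- (fused + t(fused)) / 2
  new_similarity_network(fused, "fused", ids)
}

#' Build per-omics similarity networks and fuse them
#'
#' Runs [affinity_kernel()], [normalize_P()] and [local_affinity()] for each
#' omics layer and fuses the results with [snf_fuse()].
#'
#' @param ms List of preprocessed, sample-aligned [omics_matrix()] objects.
#' @param cfg An [snf_config()].
#' @return A fused `similarity_network`.
#' @export
fuse_omics <- function(ms, cfg = snf_config()) {
  stopifnot(length(ms) >= 1)
  Ws <- lapply(ms, affinity_kernel, cfg = cfg)
  Ps <- lapply(Ws, normalize_P)
  Ss <- lapply(Ws, local_affinity, cfg = cfg)
  snf_fuse(Ps, Ss, cfg)
}

#' Export a similarity network as TSV
#'
#' @param w A `similarity_network`.
#' @param path Output file path.
#' @param edge_list If `TRUE`, write a three-column edge list
#'   (`sample_a`, `sample_b`, `weight`) over the upper triangle instead of
#'   the full adjacency matrix.
#' @return `path`, invisibly.
#' @export
write_network <- function(w, path, edge_list = FALSE) {
  W <- unclass(w)
  if (edge_list) {
    ut <- which(upper.tri(W), arr.ind = TRUE)
    df <- data.frame(sample_a = rownames(W)[ut[, 1]],
                     sample_b = colnames(W)[ut[, 2]],
                     weight = W[ut])
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(as.data.frame(W), path, sep = "\t", quote = FALSE,
                       row.names = TRUE, col.names = NA)
  }
  invisible(path)
}
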