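#' Sparsify a fused network into a reconstruction graph
#'
#' Keeps each node's `K_graph` strongest off-diagonal weights, symmetrises the
#' edge set by union, and adds self-loops. The binarised result is the
#' autoencoder's reconstruction target \eqn{\tilde A = A + I}; edge weights
#' retain the fused values.
#'
#' @param fused A `fused` [similarity_network()].
#' @param K_graph Number of neighbours kept per node (1 <= K_graph < n).
#' @return A `graph_spec` list with fields `n`, `sample_ids`, `src`, `dst`
#'   (edge endpoints, self-loops included, sorted by `src`), `edge_weights`,
#'   `target` (binary n x n adjacency with unit diagonal) and `deg_norm`
#'   (per-node \eqn{\tilde D^{-1/2}}).
#' @export
build_graph <- function(fused, K_graph) {
  stopifnot(identical(network_kind(fused), "fused"))
  W <- unclass(fused)
  n <- nrow(W)
  K_graph <- as.integer(K_graph)
  if (K_graph < 1 || K_graph >= n)
    stop("build_graph: K_graph must satisfy 1 <= K_graph < n")
  mask <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    wi <- W[i, ]
    wi[i] <- -Inf
    nb <- order(wi, decreasing = TRUE)[seq_len(K_graph)]
    mask[i, nb] <- 1L
  }
  mask <- pmax(mask, t(mask))        # union symmetrisation
  diag(mask) <- 1L                   # self-loops
  idx <- which(mask == 1L, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  src <- idx[ord, 1]
  dst <- idx[ord, 2]
  deg <- rowSums(mask)
  structure(list(
    n = n,
    sample_ids = rownames(W),
    src = src,
    dst = dst,
    edge_weights = W[cbind(src, dst)],
    target = mask,
    deg_norm = 1 / sqrt(deg)
  ), class = "graph_spec")
}

#' @export
print.graph_spec <- function(x, ...) {
  cat(sprintf("<graph_spec> %d nodes, %d directed edges (self-loops included)\n",
              x$n, length(x$src)))
  invisible(x)
}
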