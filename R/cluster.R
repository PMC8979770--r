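kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(X, 2, X[centers[1], ], "-")^2)
  for (j in seq_len(k - 1)) {
    if (sum(d2) <= 0) {
      centers[j + 1] <- sample.int(n, 1)
    } else {
      centers[j + 1] <- sample.int(n, 1, prob = d2 / sum(d2))
    }
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[centers[j + 1], ], "-")^2))
  }
  X[centers, , drop = FALSE]
}

#' K-means clustering of an embedding
#'
#' K-means with k-means++ seeding, 10 restarts, best within-cluster sum of
#' squares kept. Deterministic for a fixed seed.
#'
#' @param emb An [omics_attention()] embedding or plain numeric matrix
#'   (samples x dims).
#' @param k Number of clusters (2 <= k <= n - 1).
#' @param seed Integer seed.
#' @param nstart Number of restarts.
#' @return Integer vector of cluster labels in 1..k, named by sample ID when
#'   available.
#' @export
kmeans_cluster <- function(emb, k, seed = 1L, nstart = 10L) {
  X <- if (inherits(emb, "omics_embedding")) emb$Z_final else as.matrix(emb)
  n <- nrow(X)
  stopifnot(k >= 2, k <= n - 1)
  ndistinct <- nrow(unique(X))
  if (k > ndistinct)
    stop(sprintf("kmeans_cluster: k = %d exceeds %d distinct embedding rows", k, ndistinct))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(nstart)) {
    cen <- kmeanspp_centers(X, k)
    km <- tryCatch(
      stats::kmeans(X, centers = cen, iter.max = 100),
      error = function(e) NULL)
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("kmeans_cluster: all restarts failed")
  labels <- best$cluster
  ids <- if (inherits(emb, "omics_embedding")) emb$sample_ids else rownames(X)
  if (!is.null(ids)) names(labels) <- ids
  labels
}

#' Mean silhouette width of a clustering
#'
#' @param X Numeric matrix (samples x dims).
#' @param labels Cluster labels.
#' @return Mean silhouette width (Euclidean distance), in [-1, 1].
#' @export
mean_silhouette <- function(X, labels) {
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(X))
  mean(sil[, "sil_width"])
}

#' Select the number of clusters by silhouette width
#'
#' Clusters the embedding with [kmeans_cluster()] for every k in `k_range`,
#' scores each partition by mean silhouette width, and keeps the k with the
#' largest score (ties broken toward the smallest k). The default scan range
#' 2..10 reflects that modest cohort sizes cannot support many subtypes.
#'
#' @inheritParams kmeans_cluster
#' @param k_range Integer vector of cluster numbers to scan (default 2:10,
#'   truncated to n - 1).
#' @return A `subtype_result` list: `sample_ids`, `labels`, `k_selected`,
#'   `silhouette_by_k` (data.frame k, mean_silhouette; `NA` for a k that
#'   failed to cluster) and `embedding_ref`.
#' @export
select_k <- function(emb, k_range = 2:10, seed = 1L) {
  X <- if (inherits(emb, "omics_embedding")) emb$Z_final else as.matrix(emb)
  n <- nrow(X)
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) stop("select_k: no valid k in range for n = ", n)
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max - 1, length(k_range))
  sils <- rep(NA_real_, length(k_range))
  labs <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    res <- tryCatch({
      lab <- kmeans_cluster(X, k_range[i], seed = subseeds[i])
      list(lab = lab, sil = mean_silhouette(X, lab))
    }, error = function(e) NULL)
    if (!is.null(res)) {
      labs[[i]] <- res$lab
      sils[i] <- res$sil
    }
  }
  if (all(is.na(sils))) stop("select_k: clustering failed for every k")
  best <- which(sils == max(sils, na.rm = TRUE))[1]   # ties -> smallest k
  ids <- if (inherits(emb, "omics_embedding")) emb$sample_ids else rownames(X)
  labels <- labs[[best]]
  if (!is.null(ids)) names(labels) <- ids
  structure(list(
    sample_ids = ids,
    labels = labels,
    k_selected = k_range[best],
    silhouette_by_k = data.frame(k = k_range, mean_silhouette = sils),
    embedding_ref = sprintf("%d x %d embedding", nrow(X), ncol(X))
  ), class = "subtype_result")
}

#' @export
print.subtype_result <- function(x, ...) {
  cat(sprintf("<subtype_result> %d samples, k = %d (silhouette %.3f)\n",
              length(x$labels), x$k_selected,
              x$silhouette_by_k$mean_silhouette[x$silhouette_by_k$k == x$k_selected]))
  invisible(x)
}
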