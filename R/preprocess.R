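#' Filter features and samples by missingness
#'
#' Removes features whose fraction of missing values strictly exceeds
#' `feature_threshold`, then removes samples whose missing fraction over the
#' *remaining* features strictly exceeds `sample_threshold`. Row and column
#' order is otherwise preserved. The 20% defaults mirror standard TCGA
#' multi-omics preprocessing.
#'
#' @param m An [omics_matrix()].
#' @param feature_threshold,sample_threshold Fractions in (0, 1]; a
#'   feature/sample is dropped when its missing fraction is strictly greater.
#' @return A filtered `omics_matrix`.
#' @export
filter_missing <- function(m, feature_threshold = 0.20, sample_threshold = 0.20) {
  m <- as_omics(m)
  stopifnot(feature_threshold > 0, feature_threshold <= 1,
            sample_threshold > 0, sample_threshold <= 1)
  feat_frac <- colMeans(is.na(m))
  keep_f <- feat_frac <= feature_threshold
  if (!any(keep_f))
    stop(sprintf("filter_missing: feature filtering (> %.0f%% missing) removed all features of '%s'",
                 100 * feature_threshold, omics_name(m)))
  v <- unclass(m)[, keep_f, drop = FALSE]
  samp_frac <- rowMeans(is.na(v))
  keep_s <- samp_frac <= sample_threshold
  if (!any(keep_s))
    stop(sprintf("filter_missing: sample filtering (> %.0f%% missing) removed all samples of '%s'",
                 100 * sample_threshold, omics_name(m)))
  restore_omics(v[keep_s, , drop = FALSE], m)
}

#' K-nearest-neighbour imputation
#'
#' Replaces every missing cell by the mean of that feature over the `k`
#' samples nearest in Euclidean distance, computed on features observed in
#' both samples. Neighbours missing the target feature are skipped (the next
#' nearest with an observed value stand in). Observed cells are never altered.
#'
#' @param m An [omics_matrix()] where every sample has at least one observed
#'   feature and no feature is entirely missing.
#' @param k Number of neighbours (default 5).
#' @return A fully observed `omics_matrix`.
#' @export
knn_impute <- function(m, k = 5) {
  m <- as_omics(m)
  stopifnot(k >= 1)
  v <- unclass(m)
  if (!anyNA(v)) return(m)
  all_na_feat <- colSums(!is.na(v)) == 0
  if (any(all_na_feat))
    stop("knn_impute: feature(s) missing in all samples: ",
         paste(colnames(v)[all_na_feat], collapse = ", "))
  if (any(rowSums(!is.na(v)) == 0))
    stop("knn_impute: sample(s) with no observed features")
  n <- nrow(v)
  obs <- !is.na(v)
  # pairwise distances on mutually observed features, scaled to full width
  d <- matrix(Inf, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- obs[i, ] & obs[j, ]
      if (any(shared)) {
        d[i, j] <- d[j, i] <- sqrt(sum((v[i, shared] - v[j, shared])^2))
      }
    }
  }
  out <- v
  for (i in seq_len(n)) {
    miss_j <- which(!obs[i, ])
    if (!length(miss_j)) next
    ord <- order(d[i, ])            # ascending; self excluded via Inf? d[i,i]=Inf? set:
    ord <- ord[ord != i]
    for (j in miss_j) {
      donors <- ord[obs[ord, j]]
      if (!length(donors))
        stop(sprintf("knn_impute: no donor for sample '%s' feature '%s'",
                     rownames(v)[i], colnames(v)[j]))
      use <- donors[seq_len(min(k, length(donors)))]
      out[i, j] <- mean(v[use, j])
    }
  }
  restore_omics(out, m)
}

#' Z-score normalisation
#'
#' Standardises each feature to mean 0 and unit variance using the population
#' (1/n) variance. Zero-variance features cannot be scaled and are dropped
#' with a warning.
#'
#' @param m A fully observed [omics_matrix()].
#' @return A standardised `omics_matrix`.
#' @export
zscore <- function(m) {
  m <- as_omics(m)
  v <- unclass(m)
  if (anyNA(v)) stop("zscore: matrix contains missing values; impute first")
  n <- nrow(v)
  mu <- colMeans(v)
  va <- colMeans(v^2) - mu^2          # population variance
  va <- pmax(va, 0)
  zero <- va < 1e-24
  if (any(zero)) {
    warning(sprintf("zscore: dropping %d zero-variance feature(s) of '%s': %s",
                    sum(zero), omics_name(m),
                    paste(utils::head(colnames(v)[zero], 5), collapse = ", ")))
    v <- v[, !zero, drop = FALSE]
    mu <- mu[!zero]; va <- va[!zero]
    if (!ncol(v)) stop("zscore: all features had zero variance")
  }
  z <- sweep(sweep(v, 2, mu, "-"), 2, sqrt(va), "/")
  restore_omics(z, m)
}

#' Align omics matrices and the clinical table on shared samples
#'
#' Restricts every omics matrix and the clinical table to the intersection of
#' their sample IDs, all in one canonical order (the order of appearance in
#' the first omics matrix).
#'
#' @param ms List of [omics_matrix()] objects.
#' @param clinical Optional data.frame with columns `sample_id`, `time`,
#'   `event` (see [read_clinical()]).
#' @return List with elements `omics` (list of aligned matrices) and
#'   `clinical` (aligned table or `NULL`).
#' @export
align_samples <- function(ms, clinical = NULL) {
  stopifnot(is.list(ms), length(ms) >= 1)
  ms <- lapply(ms, as_omics)
  id_sets <- lapply(ms, rownames)
  if (!is.null(clinical)) id_sets <- c(id_sets, list(as.character(clinical$sample_id)))
  common <- Reduce(intersect, id_sets)
  if (!length(common)) {
    counts <- vapply(id_sets, length, integer(1))
    stop("align_samples: empty sample intersection (input sample counts: ",
         paste(counts, collapse = ", "), ")")
  }
  # canonical order: order of appearance in the first omics matrix
  common <- rownames(ms[[1]])[rownames(ms[[1]]) %in% common]
  out <- lapply(ms, function(m) restore_omics(unclass(m)[common, , drop = FALSE], m))
  clin <- NULL
  if (!is.null(clinical)) {
    clin <- clinical[match(common, clinical$sample_id), , drop = FALSE]
    rownames(clin) <- NULL
  }
  list(omics = out, clinical = clin)
}

#' Full preprocessing pipeline for one omics layer
#'
#' Convenience wrapper: [filter_missing()] then [knn_impute()] then
#' [zscore()].
#'
#' @inheritParams filter_missing
#' @inheritParams knn_impute
#' @return A filtered, imputed, standardised `omics_matrix`.
#' @export
preprocess_omics <- function(m, feature_threshold = 0.20,
                             sample_threshold = 0.20, k = 5) {
  zscore(knn_impute(filter_missing(m, feature_threshold, sample_threshold), k = k))
}
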