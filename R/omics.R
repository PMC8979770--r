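#' Construct an omics matrix
#'
#' An `omics_matrix` is a numeric samples x features matrix with unique sample
#' IDs as rownames, unique feature IDs as colnames, and an omics-layer name.
#' Missing cells are encoded as `NA`.
#'
#' @param values Numeric matrix, samples in rows, features in columns. Must
#'   carry rownames (sample IDs) and colnames (feature IDs).
#' @param name Character scalar naming the omics layer (e.g. "mRNA").
#' @return An `omics_matrix` object.
#' @export
omics_matrix <- function(values, name = "omics") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have sample IDs as rownames and feature IDs as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated sample IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicated feature IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  structure(values, omics_name = as.character(name)[1],
            class = c("omics_matrix", "matrix", "array"))
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix '%s'> %d samples x %d features, %.1f%% missing\n",
              omics_name(x), nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Omics layer name
#' @param x An `omics_matrix`.
#' @return Character scalar.
#' @export
omics_name <- function(x) {
  nm <- attr(x, "omics_name")
  if (is.null(nm)) "omics" else nm
}

# rebuild the class/attribute wrapper after a matrix op strips it
restore_omics <- function(values, template) {
  omics_matrix(values, omics_name(template))
}

as_omics <- function(x, name = "omics") {
  if (inherits(x, "omics_matrix")) x else omics_matrix(x, name)
}

#' Sample identifiers of an omics matrix or similarity network
#' @param x An `omics_matrix` or `similarity_network`.
#' @return Character vector of sample IDs.
#' @export
sample_ids <- function(x) rownames(x)
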