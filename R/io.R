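guess_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an omics matrix from TSV/CSV
#'
#' Expects sample IDs in the first column and feature IDs in the header row.
#' Empty strings, `NA` and `NaN` cells become missing values. Use
#' `transpose = TRUE` for the features-in-rows dialect.
#'
#' @param path File path (.tsv/.txt tab-separated, .csv comma-separated).
#' @param name Omics layer name; defaults to the file stem.
#' @param transpose Set when the file stores features in rows.
#' @return An [omics_matrix()].
#' @export
read_omics <- function(path, name = NULL,
                       transpose = FALSE) {
  if (!file.exists(path)) stop("read_omics: file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.table(path, header = TRUE, sep = guess_sep(path),
                          row.names = 1, check.names = FALSE,
                          na.strings = c("", "NA", "NaN"),
                          stringsAsFactors = FALSE, comment.char = "")
  bad <- !vapply(df, is.numeric, logical(1))
  if (any(bad))
    stop("read_omics: non-numeric column(s) in ", path, ": ",
         paste(utils::head(colnames(df)[bad], 5), collapse = ", "))
  v <- as.matrix(df)
  if (transpose) v <- t(v)
  omics_matrix(v, name)
}

#' Write an omics matrix as TSV/CSV
#'
#' @param m An [omics_matrix()].
#' @param path Output path; extension selects the separator.
#' @return `path`, invisibly.
#' @export
write_omics <- function(m, path) {
  utils::write.table(as.data.frame(unclass(m)), path, sep = guess_sep(path),
                     quote = FALSE, row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Read a clinical survival table
#'
#' TSV/CSV with columns `sample_id`, `time` (days, positive real) and
#' `event` (1 = death observed, 0 = censored).
#'
#' @param path File path.
#' @return Validated data.frame.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("read_clinical: file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = guess_sep(path),
                          stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df)))
    stop("read_clinical: missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("read_clinical: duplicated sample IDs: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (anyNA(df$time) || !is.numeric(df$time) || any(df$time <= 0))
    stop("read_clinical: non-positive or missing time for sample(s): ",
         paste(df$sample_id[is.na(df$time) | df$time <= 0], collapse = ", "))
  if (!all(df$event %in% c(0, 1)))
    stop("read_clinical: event must be 0 or 1; offending sample(s): ",
         paste(df$sample_id[!df$event %in% c(0, 1)], collapse = ", "))
  df[c("sample_id", "time", "event")]
}

#' Write a clinical survival table as TSV
#' @param clinical Data.frame with `sample_id`, `time`, `event`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = guess_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an embedding as TSV
#' @param emb An [omics_attention()] embedding or numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(emb, path) {
  Z <- if (inherits(emb, "omics_embedding")) emb$Z_final else as.matrix(emb)
  ids <- if (inherits(emb, "omics_embedding")) emb$sample_ids else rownames(Z)
  df <- data.frame(sample_id = ids, Z, check.names = FALSE)
  colnames(df) <- c("sample_id", paste0("dim", seq_len(ncol(Z))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a similarity network written by [write_network()]
#'
#' @param path TSV adjacency matrix with sample-ID headers.
#' @param kind Network kind to stamp on the result (default `"fused"`).
#' @return A `similarity_network`.
#' @export
read_network <- function(path, kind = "fused") {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  w <- as.matrix(df)
  if (nrow(w) != ncol(w) || !identical(rownames(w), colnames(w)))
    stop("read_network: not a square adjacency matrix with matching IDs: ", path)
  new_similarity_network(w, kind, rownames(w))
}
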