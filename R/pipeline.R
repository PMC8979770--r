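#' Pipeline run configuration
#'
#' Bundles every stage's settings. Defaults equal the method's stated
#' choices where they exist: 20% missingness filters, 2 encoder layers,
#' learning rate 0.01, dropout 0.5, cluster number scanned over 2..10.
#'
#' @param omics_paths Named character vector/list of omics matrix file paths
#'   (ignored when matrices are passed to [run_pipeline()] directly).
#' @param clinical_path Optional clinical table path.
#' @param feature_threshold,sample_threshold Missingness filters, see
#'   [filter_missing()].
#' @param impute_k Neighbours for [knn_impute()].
#' @param snf An [snf_config()].
#' @param K_graph Neighbours kept when sparsifying the fused network
#'   ([build_graph()]); `NULL` (default) uses round(n/4), capped at n - 1:
#'   neighbourhoods at roughly 80% of a typical subtype's size collapse
#'   subtypes into tight blobs without forcing cross-subtype edges.
#' @param gae A [gae_config()] (its seed is overridden by `seed`).
#' @param k_range Cluster numbers scanned by [select_k()].
#' @param seed Master seed for the whole run.
#' @param outdir Output directory, or `NULL` to skip writing.
#' @return A `run_config` list.
#' @export
run_config <- function(omics_paths = NULL, clinical_path = NULL,
                       feature_threshold = 0.20, sample_threshold = 0.20,
                       impute_k = 5, snf = snf_config(), K_graph = NULL,
                       gae = gae_config(), k_range = 2:10, seed = 1L,
                       outdir = NULL) {
  structure(list(omics_paths = omics_paths, clinical_path = clinical_path,
                 feature_threshold = feature_threshold,
                 sample_threshold = sample_threshold, impute_k = impute_k,
                 snf = snf,
                 K_graph = if (is.null(K_graph)) NULL else as.integer(K_graph),
                 gae = gae,
                 k_range = as.integer(k_range), seed = as.integer(seed),
                 outdir = outdir),
            class = "run_config")
}

config_as_list <- function(cfg) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  strip(cfg)
}

#' Run the full subtype-discovery pipeline
#'
#' Stages: (A) preprocess each omics layer (missingness filter, KNN
#' imputation, z-scoring) and align all layers and the clinical table on the
#' shared samples, then build and fuse per-omics similarity networks; (B)
#' sparsify the fused network and train the graph-attention autoencoder to
#' obtain the patient embedding; (C) cluster the embedding with
#' silhouette-selected K-means and, when survival data are present, score
#' the subtypes by log-rank -log10 p and C-index. A single omics layer runs
#' the same path in ablation mode (fusion pass-through, beta = 1).
#'
#' On a stage failure, partial outputs already written are retained and the
#' manifest records the failed stage before the error is re-raised.
#'
#' @param cfg A [run_config()].
#' @param omics Optional list of [omics_matrix()] objects (bypasses
#'   `cfg$omics_paths`).
#' @param clinical Optional clinical data.frame (bypasses
#'   `cfg$clinical_path`).
#' @return List with `subtypes` ([select_k()] result), `embedding`,
#'   `fused`, `graph`, `loss_trajectory`, `metrics` (survival metrics or
#'   `NULL`), `km` (Kaplan-Meier tables or `NULL`), `preprocessed`,
#'   `clinical` and `manifest`.
#' @export
run_pipeline <- function(cfg = run_config(), omics = NULL, clinical = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  outdir <- cfg$outdir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  manifest <- list(
    config = config_as_list(cfg),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("multigatae")),
    r_version = R.version.string,
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stage = "init")
  finish <- function(res) {
    if (!is.null(outdir)) {
      cfg_path <- file.path(outdir, "config.json")
      jsonlite::write_json(manifest$config, cfg_path, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      manifest$config_md5 <<- unname(tools::md5sum(cfg_path))
      jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    res$manifest <- manifest
    res
  }
  on_fail <- function(stage, e) {
    manifest$stage <<- paste0("failed:", stage)
    manifest$error <<- conditionMessage(e)
    if (!is.null(outdir))
      jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }

  # stage A1: load + preprocess + align
  manifest$stage <- "preprocess"
  aligned <- tryCatch({
    if (is.null(omics)) {
      if (is.null(cfg$omics_paths)) stop("no omics inputs given")
      omics <- Map(read_omics, cfg$omics_paths,
                   name = names(cfg$omics_paths) %||% seq_along(cfg$omics_paths))
    }
    if (is.null(clinical) && !is.null(cfg$clinical_path))
      clinical <- read_clinical(cfg$clinical_path)
    pre <- lapply(omics, preprocess_omics,
                  feature_threshold = cfg$feature_threshold,
                  sample_threshold = cfg$sample_threshold, k = cfg$impute_k)
    align_samples(pre, clinical)
  }, error = function(e) on_fail("preprocess", e))

  # stage A2: similarity network fusion
  manifest$stage <- "fuse"
  fused <- tryCatch(fuse_omics(aligned$omics, cfg$snf),
                    error = function(e) on_fail("fuse", e))
  if (!is.null(outdir)) write_network(fused, file.path(outdir, "fused_network.tsv"))

  # stage B: graph + embedding
  manifest$stage <- "embed"
  emb_res <- tryCatch({
    Kg <- cfg$K_graph %||% round(fused_n(fused) / 4)
    g <- build_graph(fused, min(Kg, fused_n(fused) - 1L))
    gcfg <- cfg$gae
    gcfg$seed <- cfg$seed
    tr <- gae_train(aligned$omics, g, gcfg)
    list(g = g, tr = tr)
  }, error = function(e) on_fail("embed", e))
  if (!is.null(outdir)) {
    write_embedding(emb_res$tr$embedding, file.path(outdir, "embedding.tsv"))
    utils::write.csv(emb_res$tr$loss_trajectory,
                     file.path(outdir, "loss_trajectory.csv"), row.names = FALSE)
  }

  # stage C1: clustering
  manifest$stage <- "cluster"
  subtypes <- tryCatch(
    select_k(emb_res$tr$embedding, cfg$k_range, seed = cfg$seed),
    error = function(e) on_fail("cluster", e))
  if (!is.null(outdir)) {
    utils::write.table(
      data.frame(sample_id = subtypes$sample_ids,
                 subtype_label = unname(subtypes$labels)),
      file.path(outdir, "subtypes.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.csv(subtypes$silhouette_by_k,
                     file.path(outdir, "silhouette.csv"), row.names = FALSE)
  }

  # stage C2: survival evaluation
  metrics <- km <- NULL
  if (!is.null(aligned$clinical)) {
    manifest$stage <- "evaluate"
    metrics <- tryCatch(
      survival_metrics(aligned$clinical, subtypes$labels),
      error = function(e) on_fail("evaluate", e))
    km <- km_curves(aligned$clinical, subtypes$labels)
    if (!is.null(outdir)) {
      jsonlite::write_json(metrics, file.path(outdir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      utils::write.csv(km, file.path(outdir, "km_curves.csv"), row.names = FALSE)
    }
  }

  manifest$stage <- "done"
  finish(list(subtypes = subtypes, embedding = emb_res$tr$embedding,
              fused = fused, graph = emb_res$g,
              loss_trajectory = emb_res$tr$loss_trajectory,
              metrics = metrics, km = km,
              preprocessed = aligned$omics, clinical = aligned$clinical))
}

fused_n <- function(fused) nrow(unclass(fused))

`%||%` <- function(a, b) if (is.null(a)) b else a
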