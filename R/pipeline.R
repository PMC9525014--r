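# End-to-end orchestration: inputs -> features -> VAE -> GNN -> clustering
# -> bins + metrics. One run seed governs every stochastic stage.

#' Run the full binning pipeline
#'
#' Reads the assembly graph, sequences and depth table, builds contig
#' features, trains the VAE and the coverage-weighted GraphSAGE network,
#' clusters the concatenated embeddings with iterative medoid clustering,
#' and writes the bin TSV plus loss traces (and a metrics table when gold
#' labels are given). Checkpoint selection uses gold labels when provided,
#' else the marker table, else the last epoch.
#'
#' @param gfa Path to the GFA assembly graph (required).
#' @param fasta Optional FASTA path; when given its sequences override the
#'   GFA segment sequences.
#' @param depth Path to the MetaBAT2/VAMB-style depth table (required).
#' @param markers,labels Optional marker CSV / gold-label TSV paths (or
#'   pre-read tibbles).
#' @param outdir Output directory; `NULL` writes nothing.
#' @param seed Single integer seed for all stochastic stages.
#' @param vae A [vae_config()]; its seed is overridden by `seed`.
#' @param gnn A [gnn_config()]; its seed is overridden by `seed`.
#' @param threshold Clustering cosine-distance radius (`NULL` = automatic).
#' @param min_contig_length Drop contigs shorter than this many bp.
#' @param verbose Log one line per stage.
#' @return A `pipeline_result` list: `bins` (tibble `contig_id`, `bin_id`),
#'   `vae_fit`, `gnn_fit`, `embedding` (concatenated matrix),
#'   `marker_quality`, `label_metrics`, `ari`, `files`.
#' @export
run_pipeline <- function(gfa, fasta = NULL, depth, markers = NULL,
                         labels = NULL, outdir = NULL, seed = 1,
                         vae = vae_config(), gnn = gnn_config(),
                         threshold = NULL, min_contig_length = 0,
                         verbose = TRUE) {
  say <- function(...) if (verbose) inform(sprintf(...))
  t0 <- Sys.time()
  stage <- function(what, expr) {
    t1 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      abort(sprintf("pipeline stage '%s' failed: %s", what,
                    conditionMessage(e))))
    say("[%s] done in %.1fs", what,
        as.numeric(difftime(Sys.time(), t1, units = "secs")))
    res
  }
  if (is.null(gfa) || !file.exists(gfa))
    abort("assembly graph GFA not found (argument `gfa`)")
  if (is.null(depth) || (is.character(depth) && !file.exists(depth)))
    abort("depth table not found (argument `depth`)")

  graph <- stage("read_graph", read_gfa(gfa))
  if (!is.null(fasta)) {
    fa <- read_fasta(fasta)
    keep <- graph$contigs$contig_id %in% fa$contig_id
    graph$contigs <- graph$contigs[keep, ]
    graph$contigs$sequence <- fa$sequence[match(graph$contigs$contig_id,
                                                fa$contig_id)]
    graph$contigs$length <- nchar(graph$contigs$sequence)
  }
  if (min_contig_length > 0) {
    keep_ids <- graph$contigs$contig_id[graph$contigs$length >= min_contig_length]
    graph$contigs <- dplyr::filter(graph$contigs,
                                   .data$contig_id %in% keep_ids)
    graph$edges <- dplyr::filter(graph$edges, .data$from %in% keep_ids,
                                 .data$to %in% keep_ids)
  }
  dt <- stage("read_depth", if (is.character(depth)) read_depth(depth) else depth)
  mk <- if (is.character(markers)) read_markers(markers) else markers
  lb <- if (is.character(labels)) read_labels(labels) else labels

  feats <- stage("features",
                 contig_features(graph$contigs[, c("contig_id", "sequence")],
                                 dt))
  vae$seed <- seed; gnn$seed <- seed
  vfit <- stage("vae", train_vae(feats, vae))
  gfit <- stage("gnn", train_gnn(graph, vfit, gnn, markers = mk, labels = lb,
                                 cluster_args = list(threshold = threshold)))
  emb <- concat_embeddings(vfit, gfit)
  bins <- stage("cluster",
                cluster_embeddings(emb, threshold = threshold,
                                   seed = derive_seed(seed, "cluster")))

  lengths <- setNames(graph$contigs$length, graph$contigs$contig_id)
  mq <- if (!is.null(mk) && nrow(mk)) marker_quality(bins, mk) else NULL
  lm <- if (!is.null(lb)) label_metrics(bins, lb, lengths) else NULL
  ari <- if (!is.null(lb)) bin_ari(bins, lb) else NA_real_

  files <- list()
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    files$bins <- file.path(outdir, "bins.tsv")
    write_bins(bins, files$bins)
    files$vae_trace <- file.path(outdir, "vae_loss.csv")
    readr::write_csv(vfit$trace, files$vae_trace, progress = FALSE)
    files$gnn_trace <- file.path(outdir, "gnn_loss.csv")
    readr::write_csv(gfit$trace, files$gnn_trace, progress = FALSE)
    if (!is.null(mq)) {
      files$marker_quality <- file.path(outdir, "marker_quality.tsv")
      readr::write_tsv(mq, files$marker_quality, progress = FALSE)
    }
    if (!is.null(lm)) {
      files$metrics <- file.path(outdir, "label_metrics.tsv")
      readr::write_tsv(glance(lm), files$metrics, progress = FALSE)
    }
  }
  say("[pipeline] %d contigs -> %d bins in %.1fs%s",
      nrow(bins), dplyr::n_distinct(bins$bin_id),
      as.numeric(difftime(Sys.time(), t0, units = "secs")),
      if (!is.na(ari)) sprintf(" (ARI %.3f)", ari) else "")
  structure(list(bins = bins, vae_fit = vfit, gnn_fit = gfit,
                 embedding = emb, marker_quality = mq, label_metrics = lm,
                 ari = ari, files = files),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d contigs, %d bins%s\n", nrow(x$bins),
              dplyr::n_distinct(x$bins$bin_id),
              if (!is.na(x$ari)) sprintf(", ARI %.3f", x$ari) else ""))
  invisible(x)
}

#' Grid search over GNN hyper-parameters
#'
#' Re-runs the graph stage and clustering for every combination of hidden
#' dimension, output dimension and learning rate (features and the VAE are
#' fitted once and shared), scoring each cell with the marker-based
#' checkpoint score, or bp-weighted F1 when gold labels are given. Default
#' ranges span hidden 128-512, embedding 32-128 and learning rates
#' 1e-2 to 1e-5.
#'
#' @inheritParams run_pipeline
#' @param hidden_dim,output_dim,learning_rate Grid axes.
#' @param gnn Base [gnn_config()] providing the remaining settings.
#' @return Tibble (`hidden_dim`, `output_dim`, `learning_rate`, `n_hq`,
#'   `sum_completeness`, `f1`, `n_bins`), sorted best-first; written to
#'   `outdir/grid.tsv` when `outdir` is given.
#' @export
run_grid <- function(gfa, fasta = NULL, depth, markers = NULL, labels = NULL,
                     outdir = NULL, seed = 1, vae = vae_config(),
                     gnn = gnn_config(),
                     hidden_dim = c(128, 256, 512),
                     output_dim = c(32, 64, 128),
                     learning_rate = 10^seq(-2, -5), threshold = NULL,
                     verbose = FALSE) {
  graph <- read_gfa(gfa)
  if (!is.null(fasta)) {
    fa <- read_fasta(fasta)
    graph$contigs$sequence <- fa$sequence[match(graph$contigs$contig_id,
                                                fa$contig_id)]
  }
  dt <- if (is.character(depth)) read_depth(depth) else depth
  mk <- if (is.character(markers)) read_markers(markers) else markers
  lb <- if (is.character(labels)) read_labels(labels) else labels
  feats <- contig_features(graph$contigs[, c("contig_id", "sequence")], dt)
  vae$seed <- seed
  vfit <- train_vae(feats, vae)
  lengths <- setNames(graph$contigs$length, graph$contigs$contig_id)

  grid <- tidyr::expand_grid(hidden_dim = hidden_dim,
                             output_dim = output_dim,
                             learning_rate = learning_rate)
  rows <- purrr::pmap(grid, function(hidden_dim, output_dim, learning_rate) {
    cfg <- gnn
    cfg$hidden_dim <- hidden_dim; cfg$output_dim <- output_dim
    cfg$learning_rate <- learning_rate; cfg$seed <- seed
    gfit <- train_gnn(graph, vfit, cfg, markers = mk, labels = lb,
                      cluster_args = list(threshold = threshold))
    bins <- cluster_embeddings(concat_embeddings(vfit, gfit),
                               threshold = threshold,
                               seed = derive_seed(seed, "cluster"))
    sc <- if (!is.null(mk) && nrow(mk)) checkpoint_score(marker_quality(bins, mk))
          else list(n_hq = NA_integer_, sum_completeness = NA_real_)
    f1 <- if (!is.null(lb)) label_metrics(bins, lb, lengths)$f1 else NA_real_
    tibble::tibble(hidden_dim = hidden_dim, output_dim = output_dim,
                   learning_rate = learning_rate, n_hq = sc$n_hq,
                   sum_completeness = sc$sum_completeness, f1 = f1,
                   n_bins = dplyr::n_distinct(bins$bin_id))
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(dplyr::coalesce(.data$n_hq, -1L)),
                   dplyr::desc(dplyr::coalesce(.data$sum_completeness, -1)),
                   dplyr::desc(dplyr::coalesce(.data$f1, -1)))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(out, file.path(outdir, "grid.tsv"), progress = FALSE)
  }
  out
}
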