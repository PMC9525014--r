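# Iterative medoid clustering of concatenated embeddings, cosine distance.

#' Concatenate contig-specific and graph embeddings
#'
#' L2-normalizes each block independently per contig, then concatenates,
#' so both embedding types contribute on the same scale regardless of
#' dimension. Contig sets must match.
#'
#' @param vae Matrix (or `vae_fit`) of contig-specific embeddings,
#'   rownames = contig ids.
#' @param gnn Matrix (or `gnn_fit`) of graph embeddings.
#' @return Matrix, contigs x (dim_vae + dim_gnn), rows ordered as `vae`.
#' @export
concat_embeddings <- function(vae, gnn) {
  if (inherits(vae, "vae_fit")) vae <- vae$embedding
  if (inherits(gnn, "gnn_fit")) gnn <- gnn$embedding
  dv <- setdiff(rownames(vae), rownames(gnn))
  dg <- setdiff(rownames(gnn), rownames(vae))
  if (length(dv) || length(dg))
    abort(sprintf("contig sets differ; only in first: %s; only in second: %s",
                  paste(head(dv, 5), collapse = ","),
                  paste(head(dg, 5), collapse = ",")))
  gnn <- gnn[rownames(vae), , drop = FALSE]
  cbind(l2_normalize_rows(vae), l2_normalize_rows(gnn))
}

#' Pick a clustering distance threshold from the pairwise-distance histogram
#'
#' Samples up to `max_pairs` contig pairs, computes their cosine distances
#' and looks for the deepest valley of the histogram between the intra- and
#' inter-cluster modes. Falls back to `fallback` when no interior valley
#' exists (e.g. unimodal distances).
#'
#' @param embedding Numeric matrix, contigs x dims.
#' @param max_pairs Number of sampled pairs.
#' @param fallback Threshold used when no valley is found.
#' @return A scalar cosine-distance threshold.
#' @export
auto_threshold <- function(embedding, max_pairs = 20000, fallback = 0.1) {
  n <- nrow(embedding)
  if (n < 3) return(fallback)
  u <- l2_normalize_rows(embedding)
  i <- sample.int(n, max_pairs, replace = TRUE)
  j <- sample.int(n, max_pairs, replace = TRUE)
  keep <- i != j
  d <- 1 - rowSums(u[i[keep], , drop = FALSE] * u[j[keep], , drop = FALSE])
  dens <- stats::density(d, n = 256, from = 0)
  cnt <- dens$y
  peaks <- which(diff(sign(diff(c(-1, cnt, -1)))) == -2)
  if (length(peaks) < 2) return(fallback)
  # the intra-cluster mode is the first (smallest-distance) peak; the
  # inter-cluster mode is the strongest peak beyond it; the threshold is
  # the deepest valley between them
  lo <- peaks[1]
  later <- peaks[peaks > lo]
  hi <- later[which.max(cnt[later])]
  if (hi - lo < 2) return(fallback)
  valley <- lo + which.min(cnt[(lo + 1):(hi - 1)])
  dens$x[valley]
}

#' Iterative medoid clustering
#'
#' Repeats until every contig is assigned: pick a random unassigned seed
#' contig; iteratively move the medoid to the unassigned contig that has
#' the most unassigned contigs within `threshold` cosine distance (local
#' density), until the medoid is stable or `max_steps` is reached; emit all
#' unassigned contigs within `threshold` of the final medoid as one bin.
#' The medoid always belongs to its own bin, so singleton bins are legal
#' and the result is a partition. No cluster count is required.
#'
#' @param embedding Numeric matrix, contigs x dims, rownames = contig ids.
#' @param threshold Cosine-distance radius; `NULL` uses [auto_threshold()].
#' @param max_steps Bound on medoid-update iterations per bin.
#' @param seed RNG seed for the seed-contig order.
#' @return A `bin_assignment` tibble: columns `contig_id`, `bin_id`
#'   (dense integers from 0); attribute `threshold` records the radius used.
#' @export
cluster_embeddings <- function(embedding, threshold = NULL, max_steps = 25,
                               seed = 1) {
  n <- nrow(embedding)
  stopifnot(n >= 1)
  ids <- rownames(embedding) %||% as.character(seq_len(n))
  set.seed(seed)
  if (is.null(threshold)) threshold <- auto_threshold(embedding)
  u <- l2_normalize_rows(embedding)

  assigned <- rep(NA_integer_, n)
  order0 <- sample.int(n)   # seed-contig order, drawn once per run
  next_bin <- 0L
  while (anyNA(assigned)) {
    # next still-unassigned contig in the fixed random order; the medoid
    # may drift away from it, so a contig can be revisited as a seed
    s <- order0[match(TRUE, is.na(assigned[order0]))]
    free <- which(is.na(assigned))
    medoid <- s
    d <- cosine_distance_to(u[free, , drop = FALSE], u[medoid, ])
    for (step in seq_len(max_steps)) {
      inside <- free[d <= threshold]
      if (length(inside) <= 1) break
      # candidate medoid: the unassigned contig covering the most
      # unassigned contigs within the radius
      dens <- vapply(inside, function(c0) {
        sum(cosine_distance_to(u[free, , drop = FALSE], u[c0, ]) <= threshold)
      }, numeric(1))
      best <- inside[which.max(dens)]
      if (best == medoid) break
      cur_dens <- sum(d <= threshold)
      if (max(dens) < cur_dens) break
      medoid <- best
      d <- cosine_distance_to(u[free, , drop = FALSE], u[medoid, ])
    }
    members <- free[d <= threshold]
    if (!medoid %in% members) members <- c(medoid, members)
    assigned[members] <- next_bin
    next_bin <- next_bin + 1L
  }
  out <- tibble::tibble(contig_id = ids, bin_id = assigned)
  attr(out, "threshold") <- threshold
  class(out) <- c("bin_assignment", class(out))
  out
}

#' Summarise a bin assignment
#' @param assignment A `bin_assignment` tibble.
#' @param lengths Optional named vector of contig lengths (bp) to add
#'   per-bin totals.
#' @return Tibble: `bin_id`, `n_contigs`, and `total_bp` when lengths given.
#' @export
bin_summary <- function(assignment, lengths = NULL) {
  out <- dplyr::count(assignment, .data$bin_id, name = "n_contigs")
  if (!is.null(lengths)) {
    out <- assignment |>
      dplyr::mutate(bp = as.numeric(lengths[.data$contig_id])) |>
      dplyr::group_by(.data$bin_id) |>
      dplyr::summarise(n_contigs = dplyr::n(), total_bp = sum(.data$bp),
                       .groups = "drop")
  }
  dplyr::arrange(out, .data$bin_id)
}
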