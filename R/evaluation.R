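# Bin quality scoring: single-copy marker genes for checkpoint selection,
# bp-weighted purity/completeness against gold labels for validation.

#' Marker-gene completeness and contamination per bin
#'
#' Follows the single-copy marker convention: a bin's completeness is the
#' percentage of the marker universe present at least once, and its
#' contamination is the percentage of duplicated marker observations
#' (total count minus distinct count, over the universe size).
#'
#' @param bins A `bin_assignment` tibble (`contig_id`, `bin_id`).
#' @param markers Marker tibble from [read_markers()] (`contig_id`,
#'   `marker_id`), multiset semantics.
#' @param universe Marker universe; defaults to the table's `universe`
#'   attribute or the distinct observed markers.
#' @return A `bin_quality` tibble: `bin_id`, `completeness`,
#'   `contamination` (both percentages), `n_markers`.
#' @export
marker_quality <- function(bins, markers, universe = NULL) {
  universe <- universe %||% attr(markers, "universe") %||%
    sort(unique(markers$marker_id))
  if (!length(universe)) abort("marker universe is empty")
  nu <- length(universe)
  joined <- dplyr::inner_join(bins, markers, by = "contig_id")
  out <- bins |>
    dplyr::distinct(.data$bin_id) |>
    dplyr::left_join(
      joined |>
        dplyr::group_by(.data$bin_id) |>
        dplyr::summarise(n_markers = dplyr::n(),
                         n_distinct_markers = dplyr::n_distinct(.data$marker_id),
                         .groups = "drop"),
      by = "bin_id") |>
    dplyr::mutate(
      n_markers = dplyr::coalesce(.data$n_markers, 0L),
      n_distinct_markers = dplyr::coalesce(.data$n_distinct_markers, 0L),
      completeness = 100 * .data$n_distinct_markers / nu,
      contamination = 100 * (.data$n_markers - .data$n_distinct_markers) / nu) |>
    dplyr::select("bin_id", "completeness", "contamination", "n_markers") |>
    dplyr::arrange(.data$bin_id)
  class(out) <- c("bin_quality", class(out))
  out
}

#' Call high-quality bins
#'
#' HQ bins have completeness strictly greater than 90% and contamination
#' strictly below 5%; boundary values (exactly 90 or exactly 5) are
#' excluded.
#'
#' @param quality A `bin_quality` tibble (percent scale).
#' @return The `bin_id`s of HQ bins.
#' @export
hq_call <- function(quality) {
  quality$bin_id[quality$completeness > 90 & quality$contamination < 5]
}

#' Score a checkpoint from marker-based bin quality
#'
#' Primary score is the number of HQ bins (completeness > 90,
#' contamination < 5); ties between checkpoints are broken by the summed
#' completeness over those HQ bins.
#'
#' @param quality A `bin_quality` tibble.
#' @return List with `n_hq` and `sum_completeness`.
#' @export
checkpoint_score <- function(quality) {
  hq <- hq_call(quality)
  list(n_hq = length(hq),
       sum_completeness = sum(quality$completeness[quality$bin_id %in% hq]))
}

#' Gold-label bin metrics, bp-weighted
#'
#' Each bin's purity is the base pairs of its majority genome divided by
#' the bin's total base pairs (contamination = 1 - purity); its
#' completeness is the base pairs of that majority genome in the bin over
#' the genome's total base pairs. The average purity weights bins by bin
#' bp; the average completeness weights bins by their majority genome's
#' total bp. F1 is the harmonic mean of the two averages. HQ bins require
#' completeness > 0.9 and contamination < 0.05; MQ bins completeness >=
#' 0.5 and contamination < 0.1.
#'
#' @param bins A `bin_assignment` tibble.
#' @param gold Tibble (`contig_id`, `genome_id`) covering every binned
#'   contig.
#' @param lengths Named numeric vector of contig lengths in bp.
#' @return A `label_metrics` list: `per_bin` tibble (`bin_id`, `genome_id`,
#'   `purity`, `completeness`, `bin_bp`), `average_purity`,
#'   `average_completeness`, `f1`, `hq_count`, `mq_count`.
#' @export
label_metrics <- function(bins, gold, lengths) {
  unlabeled <- setdiff(bins$contig_id, gold$contig_id)
  if (length(unlabeled))
    abort(sprintf("unlabeled contigs: %s",
                  paste(head(unlabeled, 5), collapse = ", ")))
  df <- bins |>
    dplyr::inner_join(gold, by = "contig_id") |>
    dplyr::mutate(bp = as.numeric(lengths[.data$contig_id]))
  genome_bp <- df |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::summarise(genome_bp = sum(.data$bp), .groups = "drop")
  per_bin <- df |>
    dplyr::group_by(.data$bin_id, .data$genome_id) |>
    dplyr::summarise(bp = sum(.data$bp), .groups = "drop_last") |>
    dplyr::mutate(bin_bp = sum(.data$bp)) |>
    dplyr::slice_max(.data$bp, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::left_join(genome_bp, by = "genome_id") |>
    dplyr::mutate(purity = .data$bp / .data$bin_bp,
                  completeness = .data$bp / .data$genome_bp) |>
    dplyr::select("bin_id", "genome_id", "purity", "completeness",
                  "bin_bp", "genome_bp")
  p <- sum(per_bin$purity * per_bin$bin_bp) / sum(per_bin$bin_bp)
  cmp <- sum(per_bin$completeness * per_bin$genome_bp) / sum(per_bin$genome_bp)
  f1 <- if (p + cmp > 0) 2 * p * cmp / (p + cmp) else 0
  structure(list(
    per_bin = per_bin,
    average_purity = p, average_completeness = cmp, f1 = f1,
    hq_count = sum(per_bin$completeness > 0.9 & (1 - per_bin$purity) < 0.05),
    mq_count = sum(per_bin$completeness >= 0.5 & (1 - per_bin$purity) < 0.1)
  ), class = "label_metrics")
}

#' @export
print.label_metrics <- function(x, ...) {
  cat(sprintf(paste0("<label_metrics> purity %.3f, completeness %.3f, ",
                     "F1 %.3f, HQ %d, MQ %d (%d bins)\n"),
              x$average_purity, x$average_completeness, x$f1,
              x$hq_count, x$mq_count, nrow(x$per_bin)))
  invisible(x)
}

#' @rdname tidy.gnn_fit
#' @method tidy label_metrics
#' @export
tidy.label_metrics <- function(x, ...) x$per_bin

#' @rdname glance.gnn_fit
#' @method glance label_metrics
#' @export
glance.label_metrics <- function(x, ...) {
  tibble::tibble(average_purity = x$average_purity,
                 average_completeness = x$average_completeness,
                 f1 = x$f1, hq_count = x$hq_count, mq_count = x$mq_count,
                 n_bins = nrow(x$per_bin))
}

#' Adjusted Rand index between a bin assignment and gold labels
#' @param bins A `bin_assignment` tibble.
#' @param gold Tibble (`contig_id`, `genome_id`).
#' @return Scalar ARI.
#' @export
bin_ari <- function(bins, gold) {
  df <- dplyr::inner_join(bins, gold, by = "contig_id")
  mclust::adjustedRandIndex(df$bin_id, df$genome_id)
}
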