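# Canonical tetranucleotide composition + abundance featureization.

canonical_kmer_map <- function(k = 4) {
  bases <- c("A", "C", "G", "T")
  kmers <- do.call(paste0, expand.grid(rep(list(bases), k),
                                       stringsAsFactors = FALSE)[, k:1])
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  canon <- pmin(kmers, rc)
  list(kmers = kmers, canon = canon, classes = sort(unique(canon)))
}

#' Canonical k-mer composition of sequences
#'
#' Counts overlapping k-mer windows (windows containing `N` are skipped),
#' identifies each k-mer with its reverse complement (canonical classes;
#' 136 classes for k = 4) and divides by the number of valid windows, so a
#' sequence's composition equals that of its reverse complement. Sequences
#' with no valid window (shorter than k, or all-N) get a zero row and are
#' flagged in the `degenerate` attribute.
#'
#' @param sequences Character vector of nucleotide sequences (ACGTN), or a
#'   tibble with columns `contig_id` and `sequence` as returned by
#'   [read_fasta()].
#' @param k K-mer length; default 4.
#' @return Numeric matrix, sequences x canonical classes; rows sum to 1
#'   (or 0 for degenerate sequences). Rownames are contig ids when given.
#' @examples
#' kmer_composition(c(x = "AAAA"))  # 1 at the AAAA/TTTT class
#' @export
kmer_composition <- function(sequences, k = 4) {
  ids <- NULL
  if (is.data.frame(sequences)) {
    ids <- sequences$contig_id
    sequences <- sequences$sequence
  } else if (!is.null(names(sequences))) ids <- names(sequences)
  map <- canonical_kmer_map(k)
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(sequences), width = k)
  # collapse the 4^k columns onto canonical classes
  collapse <- t(rowsum(t(counts), group = map$canon[match(colnames(counts), map$kmers)]))
  collapse <- collapse[, map$classes, drop = FALSE]
  rownames(collapse) <- ids
  totals <- rowSums(collapse)
  freq <- collapse / ifelse(totals > 0, totals, 1)
  attr(freq, "degenerate") <- which(totals == 0)
  freq
}

#' Z-score a composition matrix per dimension
#'
#' Standard pre-conditioning before the auto-encoder: each column is
#' centred and scaled to unit standard deviation; constant columns are set
#' to zero. A single-row matrix is returned unchanged with a warning.
#'
#' @param x Numeric matrix (contigs x features).
#' @return Matrix of the same shape.
#' @export
normalize_composition <- function(x) {
  if (nrow(x) < 2) {
    warn("fewer than 2 contigs: composition returned un-normalized")
    return(x)
  }
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  out <- sweep(x, 2, mu, "-")
  nz <- sdv > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, sdv[nz], "/")
  out[, !nz] <- 0
  out
}

#' Normalize multi-sample abundance profiles
#'
#' With more than one sample, each contig's mean-depth vector is divided by
#' its sum, giving a scale-free differential-abundance profile (all-zero
#' contigs get the uniform profile `1/S`). With a single sample, depths are
#' transformed with `log1p` and min-max scaled over contigs, since a
#' one-column profile carries only absolute scale.
#'
#' @param depth A `depth_table` from [read_depth()], or a numeric matrix of
#'   per-sample mean depths (contigs x samples).
#' @return Numeric matrix, contigs x samples, rownames preserved.
#' @export
normalize_abundance <- function(depth) {
  m <- if (is.matrix(depth)) depth else depth_matrix(depth)
  if (any(m < 0)) abort("negative depths are not allowed")
  s <- ncol(m)
  if (s > 1) {
    tot <- rowSums(m)
    out <- m / ifelse(tot > 0, tot, 1)
    out[tot == 0, ] <- 1 / s
  } else {
    lg <- log1p(m)
    rng <- range(lg)
    out <- if (diff(rng) > 0) (lg - rng[1]) / diff(rng) else lg * 0
  }
  out
}

#' Assemble the contig feature matrix
#'
#' Joins z-scored canonical tetranucleotide composition with normalized
#' abundance into the feature matrix consumed by [train_vae()]. Variance
#' columns of the depth table are parsed upstream but not used unless
#' `include_variance = TRUE`, in which case log1p variances are appended
#' z-scored.
#'
#' @param fasta Tibble from [read_fasta()] (columns `contig_id`, `sequence`).
#' @param depth A `depth_table` covering at least the FASTA contigs.
#' @param k K-mer length for composition (default 4).
#' @param include_variance Append per-sample depth variances as features.
#' @return A `contig_features` object: list with `features` (matrix,
#'   contigs x dims), `composition_cols`, `abundance_cols` (column index
#'   vectors) and `contig_ids`.
#' @export
contig_features <- function(fasta, depth, k = 4, include_variance = FALSE) {
  comp_raw <- kmer_composition(fasta, k = k)
  comp <- normalize_composition(comp_raw)
  ab <- normalize_abundance(depth_matrix(depth, fasta$contig_id))
  if (include_variance) {
    s <- n_samples(depth)
    v <- as.matrix(depth[, paste0("var_", seq_len(s)), drop = FALSE])
    rownames(v) <- depth$contig_id
    v <- normalize_composition(log1p(v[fasta$contig_id, , drop = FALSE]))
    ab <- cbind(ab, v)
  }
  feats <- cbind(comp, ab)
  rownames(feats) <- fasta$contig_id
  structure(list(
    features = feats,
    composition_cols = seq_len(ncol(comp)),
    abundance_cols = ncol(comp) + seq_len(ncol(ab)),
    contig_ids = fasta$contig_id
  ), class = "contig_features")
}

#' @export
print.contig_features <- function(x, ...) {
  cat(sprintf("<contig_features> %d contigs, %d composition + %d abundance dims\n",
              length(x$contig_ids), length(x$composition_cols),
              length(x$abundance_cols)))
  invisible(x)
}
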