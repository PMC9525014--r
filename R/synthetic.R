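# Planted-truth synthetic communities: Markov-chain genomes split into
# contigs, an assembly graph with coverage-weighted true and spurious
# links, multi-sample depth tables, marker tables and gold labels.

#' Synthetic community parameters
#'
#' Genomes are sampled from genome-specific 3rd-order Markov chains, each
#' interpolated between one shared base chain and an independent random
#' chain by `composition_divergence` (0 = all genomes compositionally
#' identical, 1 = fully independent). Consecutive contigs of a genome are
#' linked with coverage ~ Normal(`intra_edge_coverage`, 10% relative sd),
#' truncated positive; spurious inter-genome links are added at
#' `spurious_edge_rate` (relative to the number of true links) with
#' coverage around `spurious_edge_coverage`. Per-contig depth in each
#' sample is the genome's profile value times Normal(1, 0.05) noise.
#'
#' @param n_genomes,genome_length_bp,contigs_per_genome Community shape.
#' @param composition_divergence In `[0, 1]`, see above.
#' @param n_samples Number of abundance samples.
#' @param abundance_profile Optional matrix (genomes x samples) of mean
#'   depths; `NULL` draws each entry uniformly in `[5, 50]`.
#' @param intra_edge_rate Fraction of consecutive-contig links kept
#'   (1 = full path graph per genome; 0 = no edges).
#' @param intra_edge_coverage,spurious_edge_coverage Mean link coverages.
#' @param spurious_edge_rate Spurious links per true link.
#' @param markers_per_genome Size of the shared single-copy marker
#'   universe; each genome carries each marker exactly once.
#' @param seed RNG seed; the whole community is a deterministic function
#'   of the config.
#' @return A `community_config` list.
#' @export
community_config <- function(n_genomes = 5, genome_length_bp = 200000,
                             contigs_per_genome = 20,
                             composition_divergence = 0.6, n_samples = 2,
                             abundance_profile = NULL, intra_edge_rate = 1,
                             intra_edge_coverage = 20,
                             spurious_edge_rate = 0,
                             spurious_edge_coverage = 2,
                             markers_per_genome = 10, seed = 1) {
  stopifnot(n_genomes >= 1, contigs_per_genome >= 1, n_samples >= 1,
            composition_divergence >= 0, composition_divergence <= 1,
            spurious_edge_rate >= 0, intra_edge_rate >= 0, intra_edge_rate <= 1,
            intra_edge_coverage > 0, spurious_edge_coverage > 0)
  structure(list(n_genomes = n_genomes, genome_length_bp = genome_length_bp,
                 contigs_per_genome = contigs_per_genome,
                 composition_divergence = composition_divergence,
                 n_samples = n_samples, abundance_profile = abundance_profile,
                 intra_edge_rate = intra_edge_rate,
                 intra_edge_coverage = intra_edge_coverage,
                 spurious_edge_rate = spurious_edge_rate,
                 spurious_edge_coverage = spurious_edge_coverage,
                 markers_per_genome = markers_per_genome, seed = seed),
            class = "community_config")
}

#' Named community stress profiles
#'
#' * `easy`: divergent composition, distinct abundance, clean path graph.
#' * `graph_only`: zero composition divergence — genome composition
#'   profiles are statistically identical, so only abundance and the graph
#'   can separate genomes.
#' * `composition_only`: no graph edges at all.
#' * `hard`: near-identical composition plus abundant mid-coverage
#'   spurious cross-genome links.
#'
#' @param name One of `"easy"`, `"graph_only"`, `"composition_only"`,
#'   `"hard"`.
#' @param ... Overrides passed to [community_config()].
#' @return A `community_config`.
#' @export
stress_profile <- function(name = c("easy", "graph_only", "composition_only",
                                    "hard"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    easy = list(),
    graph_only = list(composition_divergence = 0),
    composition_only = list(intra_edge_rate = 0, spurious_edge_rate = 0),
    hard = list(composition_divergence = 0.05, spurious_edge_rate = 0.3,
                spurious_edge_coverage = 10))
  do.call(community_config, utils::modifyList(args, list(...)))
}

# sample one genome sequence from an order-3 chain (64 contexts x 4 bases);
# inverse-CDF draws against a pre-generated uniform stream keep the loop cheap
sample_markov_genome <- function(P, len) {
  bases <- c("A", "C", "G", "T")
  cum <- t(apply(P, 1, cumsum))
  u <- runif(len)
  out <- integer(len)
  out[1:3] <- sample.int(4, 3, replace = TRUE)
  ctx <- (out[1] - 1) * 16 + (out[2] - 1) * 4 + (out[3] - 1) + 1
  for (i in 4:len) {
    ui <- u[i]
    b <- 1L + (ui > cum[ctx, 1]) + (ui > cum[ctx, 2]) + (ui > cum[ctx, 3])
    out[i] <- b
    ctx <- (ctx - 1) %% 16 * 4 + (b - 1) + 1
  }
  paste(bases[out], collapse = "")
}

random_chain <- function() {
  m <- matrix(stats::rgamma(64 * 4, shape = 1), 64, 4)
  m / rowSums(m)
}

#' Generate a planted-truth synthetic community
#'
#' Writes the FASTA, GFA (segments carrying `dp:f:` depth tags, links
#' carrying `dp:f:` coverage tags), MetaBAT2-style depth table, marker CSV
#' and gold-label TSV for a community drawn from the config, and returns
#' them together with the in-memory gold partition. Byte-identical output
#' for a fixed config.
#'
#' @param config A [community_config()] or [stress_profile()].
#' @param dir Output directory (created if needed).
#' @return A `synthetic_community` list: `files` (named paths: `fasta`,
#'   `gfa`, `depth`, `markers`, `labels`), `gold` (tibble `contig_id`,
#'   `genome_id`), `config`.
#' @export
generate_community <- function(config = community_config(),
                               dir = tempfile("community")) {
  set.seed(derive_seed(config$seed, "synth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- config$n_genomes; cpg <- config$contigs_per_genome
  base_chain <- random_chain()

  ab <- config$abundance_profile
  if (is.null(ab)) {
    ab <- matrix(runif(g * config$n_samples, 5, 50), g, config$n_samples)
  } else if (identical(ab, "flat")) {
    ab <- matrix(20, g, config$n_samples)
  }
  stopifnot(nrow(ab) == g, ncol(ab) == config$n_samples)

  contig_id <- character(); sequence <- character(); genome_id <- character()
  edge_from <- character(); edge_to <- character(); edge_cov <- numeric()
  trunc_norm <- function(n, mean, rel_sd) pmax(mean * 0.01, rnorm(n, mean, rel_sd * mean))

  for (gi in seq_len(g)) {
    P <- (1 - config$composition_divergence) * base_chain +
      config$composition_divergence * random_chain()
    seq_g <- sample_markov_genome(P, config$genome_length_bp)
    # random breakpoints; resplit until every contig is at least 4 bp
    repeat {
      cuts <- sort(sample.int(nchar(seq_g) - 1, cpg - 1))
      bounds <- c(0, cuts, nchar(seq_g))
      if (cpg == 1 || all(diff(bounds) >= 4)) break
    }
    ids_g <- sprintf("g%d_c%d", gi, seq_len(cpg))
    contig_id <- c(contig_id, ids_g)
    sequence <- c(sequence, substring(seq_g, bounds[-length(bounds)] + 1,
                                      bounds[-1]))
    genome_id <- c(genome_id, rep(sprintf("genome%d", gi), cpg))
    if (cpg > 1 && config$intra_edge_rate > 0) {
      keep <- runif(cpg - 1) < config$intra_edge_rate
      if (any(keep)) {
        edge_from <- c(edge_from, ids_g[-cpg][keep])
        edge_to <- c(edge_to, ids_g[-1][keep])
        edge_cov <- c(edge_cov, trunc_norm(sum(keep),
                                           config$intra_edge_coverage, 0.1))
      }
    }
  }
  gold <- tibble::tibble(contig_id = contig_id, genome_id = genome_id)

  n_spur <- round(config$spurious_edge_rate * length(edge_from))
  if (n_spur > 0 && g > 1) {
    made <- 0L
    while (made < n_spur) {
      i <- sample.int(length(contig_id), 1); j <- sample.int(length(contig_id), 1)
      if (genome_id[i] == genome_id[j]) next
      edge_from <- c(edge_from, contig_id[i]); edge_to <- c(edge_to, contig_id[j])
      edge_cov <- c(edge_cov, trunc_norm(1, config$spurious_edge_coverage, 0.1))
      made <- made + 1L
    }
  }

  # per-contig depth: genome profile x Normal(1, 0.05) noise
  gidx <- as.integer(factor(genome_id, levels = sprintf("genome%d", seq_len(g))))
  depth_means <- ab[gidx, , drop = FALSE] *
    matrix(rnorm(length(contig_id) * config$n_samples, 1, 0.05),
           ncol = config$n_samples)
  depth_means <- pmax(depth_means, 0)
  seg_depth <- rowMeans(depth_means)

  # markers: shared universe, each genome carries each marker once
  mk_contig <- character(); mk_id <- character()
  for (gi in seq_len(g)) {
    own <- which(gidx == gi)
    mk_contig <- c(mk_contig, contig_id[sample(own, config$markers_per_genome,
                                               replace = TRUE)])
    mk_id <- c(mk_id, sprintf("marker%d", seq_len(config$markers_per_genome)))
  }

  files <- list(fasta = file.path(dir, "assembly.fasta"),
                gfa = file.path(dir, "assembly.gfa"),
                depth = file.path(dir, "depth.tsv"),
                markers = file.path(dir, "markers.csv"),
                labels = file.path(dir, "labels.tsv"))

  writeLines(paste0(">", contig_id, "\n", sequence), files$fasta)

  gfa <- c(sprintf("S\t%s\t%s\tdp:f:%.4f", contig_id, sequence, seg_depth),
           if (length(edge_from))
             sprintf("L\t%s\t+\t%s\t+\t0M\tdp:f:%.4f", edge_from, edge_to,
                     edge_cov))
  writeLines(gfa, files$gfa)

  hdr <- c("contigName", "contigLen", "totalAvgDepth",
           as.vector(rbind(sprintf("sample%d.bam", seq_len(config$n_samples)),
                           sprintf("sample%d.bam-var", seq_len(config$n_samples)))))
  dm <- matrix(0, length(contig_id), 2 * config$n_samples)
  dm[, seq(1, ncol(dm), 2)] <- depth_means
  dm[, seq(2, ncol(dm), 2)] <- (0.1 * depth_means)^2
  depth_lines <- c(paste(hdr, collapse = "\t"),
                   paste(contig_id, nchar(sequence),
                         sprintf("%.4f", rowMeans(depth_means)),
                         apply(dm, 1, function(r)
                           paste(sprintf("%.4f", r), collapse = "\t")),
                         sep = "\t"))
  writeLines(depth_lines, files$depth)

  writeLines(paste(mk_contig, mk_id, sep = ","), files$markers)
  writeLines(paste(contig_id, genome_id, sep = "\t"), files$labels)

  structure(list(files = files, gold = gold, config = config),
            class = "synthetic_community")
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat(sprintf("<synthetic_community> %d genomes x %d contigs, %d samples (%s)\n",
              x$config$n_genomes, x$config$contigs_per_genome,
              x$config$n_samples, dirname(x$files$fasta)))
  invisible(x)
}
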