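# Shared fixtures: tiny hand-written input files and a cached community.

write_tmp <- function(lines, ext) {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

gfa_two_segments <- function(cov = TRUE, link = TRUE) {
  lines <- if (cov) {
    c("S\tedge_1\tACGT\tdp:i:10", "S\tedge_2\tTTTT\tdp:i:30")
  } else {
    c("S\tedge_1\tACGT", "S\tedge_2\tTTTT")
  }
  if (link) lines <- c(lines, "L\tedge_1\t+\tedge_2\t+\t0M")
  lines
}

depth_lines <- function(ids, means, vars = NULL, lens = NULL) {
  s <- ncol(means)
  if (is.null(vars)) vars <- matrix(1, nrow(means), s)
  if (is.null(lens)) lens <- rep(1000L, length(ids))
  hdr <- paste(c("contigName", "contigLen", "totalAvgDepth",
                 as.vector(rbind(sprintf("s%d.bam", 1:s),
                                 sprintf("s%d.bam-var", 1:s)))),
               collapse = "\t")
  body <- vapply(seq_along(ids), function(i) {
    paste(c(ids[i], lens[i], mean(means[i, ]),
            as.vector(rbind(means[i, ], vars[i, ]))), collapse = "\t")
  }, character(1))
  c(hdr, body)
}

# a small community reused by several tests (generated once per run)
small_community <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- community_config(n_genomes = 3, genome_length_bp = 30000,
                              contigs_per_genome = 8, seed = 11)
      cache <<- generate_community(cfg, dir = file.path(tempdir(), "comm11"))
    }
    cache
  }
})

# independent brute-force canonical k-mer counter (test oracle)
oracle_kmer <- function(seq, k = 4) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  revcomp <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  bases <- c("A", "C", "G", "T")
  all_k <- apply(expand.grid(rep(list(bases), k))[, k:1], 1, paste, collapse = "")
  canon_of <- vapply(all_k, function(m) min(m, revcomp(m)), character(1))
  classes <- sort(unique(canon_of))
  counts <- setNames(numeric(length(classes)), classes)
  n_valid <- 0
  for (i in seq_len(nchar(seq) - k + 1)) {
    w <- substr(seq, i, i + k - 1)
    if (grepl("N", w)) next
    counts[[canon_of[[w]]]] <- counts[[canon_of[[w]]]] + 1
    n_valid <- n_valid + 1
  }
  if (n_valid > 0) counts <- counts / n_valid
  counts
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

revcomp_str <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# independent brute-force oracle: repeatedly take the candidate medoid
# covering the most unassigned points (exhaustive over all unassigned
# candidates), emit its threshold-ball as a bin
oracle_medoid <- function(u, threshold) {
  u <- u / sqrt(rowSums(u^2))
  n <- nrow(u)
  D <- 1 - tcrossprod(u)
  assigned <- rep(NA_integer_, n)
  b <- 0L
  while (anyNA(assigned)) {
    free <- which(is.na(assigned))
    cover <- vapply(free, function(i) sum(D[i, free] <= threshold), numeric(1))
    m <- free[which.max(cover)]
    assigned[free[D[m, free] <= threshold]] <- b
    assigned[m] <- b
    b <- b + 1L
  }
  assigned
}

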