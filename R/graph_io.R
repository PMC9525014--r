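#' Read an assembly graph from a GFA v1 file
#'
#' Parses segment (`S`) and link (`L`) lines of a GFA v1 file into an
#' `assembly_graph` object. Segments are the binning units ("edge sequences"
#' in Flye terminology); path (`P`) lines are ignored. Per-segment read
#' coverage is taken from `dp:i:`, `dp:f:` or `KC:i:` tags when present
#' (`KC` is divided by segment length to give per-base coverage). A link's
#' coverage is its own tag if it carries one, otherwise the arithmetic mean
#' of its two endpoints' segment coverages; if the file carries no coverage
#' information at all, every edge gets coverage 1 so that all edges have the
#' same relevance. Links are collapsed to undirected edges, self-loops are
#' dropped, and duplicate links over the same unordered pair keep the
#' maximum coverage.
#'
#' @param path Path to a GFA v1 file.
#' @param strict If `TRUE`, malformed lines and links naming unknown
#'   segments raise an error identifying the line number; if `FALSE`
#'   (default) they are skipped with a warning.
#' @return An `assembly_graph` object: a list with `contigs` (tibble:
#'   `contig_id`, `sequence`, `length`, `coverage`) and `edges` (tibble:
#'   `from`, `to`, `coverage`, one row per undirected edge with
#'   `from < to` lexicographically).
#' @examples
#' gfa <- tempfile(fileext = ".gfa")
#' writeLines(c("S\tc1\tACGT\tdp:i:10", "S\tc2\tTTTT\tdp:i:30",
#'              "L\tc1\t+\tc2\t+\t0M"), gfa)
#' g <- read_gfa(gfa)
#' g$edges$coverage  # 20: mean of the endpoint coverages
#' @export
read_gfa <- function(path, strict = FALSE) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  fail <- function(msg, i) {
    if (strict) abort(sprintf("GFA parse error at line %d: %s", i, msg))
    warn(sprintf("GFA line %d skipped: %s", i, msg))
  }

  seg_id <- character(); seg_seq <- character(); seg_cov <- numeric()
  link_from <- character(); link_to <- character(); link_cov <- numeric()

  parse_cov_tag <- function(fields, len) {
    dp <- grep("^dp:[if]:", fields, value = TRUE)
    if (length(dp)) return(as.numeric(sub("^dp:[if]:", "", dp[1])))
    kc <- grep("^KC:i:", fields, value = TRUE)
    if (length(kc) && len > 0) return(as.numeric(sub("^KC:i:", "", kc[1])) / len)
    NA_real_
  }

  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln)) next
    type <- substr(ln, 1, 1)
    if (!type %in% c("S", "L")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (type == "S") {
      if (length(fields) < 3 || !nzchar(fields[2])) { fail("malformed S line", i); next }
      sq <- clean_sequence(fields[3])
      seg_id <- c(seg_id, fields[2]); seg_seq <- c(seg_seq, sq)
      seg_cov <- c(seg_cov, parse_cov_tag(fields[-(1:3)], nchar(sq)))
    } else {
      if (length(fields) < 5) { fail("malformed L line", i); next }
      link_from <- c(link_from, fields[2]); link_to <- c(link_to, fields[4])
      link_cov <- c(link_cov,
                    parse_cov_tag(if (length(fields) > 6) fields[-(1:6)] else character(), 0))
    }
  }

  if (anyDuplicated(seg_id)) {
    fail(sprintf("duplicate segment id(s): %s",
                 paste(unique(seg_id[duplicated(seg_id)]), collapse = ", ")), NA)
    keep <- !duplicated(seg_id)
    seg_id <- seg_id[keep]; seg_seq <- seg_seq[keep]; seg_cov <- seg_cov[keep]
  }

  contigs <- tibble::tibble(
    contig_id = seg_id, sequence = seg_seq,
    length = nchar(seg_seq), coverage = seg_cov
  )

  edges <- tibble::tibble(from = character(), to = character(), coverage = numeric())
  if (length(link_from)) {
    known <- link_from %in% seg_id & link_to %in% seg_id
    if (any(!known)) {
      for (j in which(!known)) fail(sprintf("link references unknown segment (%s -- %s)",
                                            link_from[j], link_to[j]), NA)
      link_from <- link_from[known]; link_to <- link_to[known]; link_cov <- link_cov[known]
    }
    if (length(link_from)) {
      a <- pmin(link_from, link_to); b <- pmax(link_from, link_to)
      seg_cov_of <- setNames(seg_cov, seg_id)
      # fall back to the mean of endpoint segment coverages, then to 1.0
      ep_mean <- (seg_cov_of[a] + seg_cov_of[b]) / 2
      cov <- ifelse(is.na(link_cov), ep_mean, link_cov)
      cov[is.na(cov)] <- 1.0
      edges <- tibble::tibble(from = a, to = b, coverage = as.numeric(cov)) |>
        dplyr::filter(.data$from != .data$to) |>
        dplyr::group_by(.data$from, .data$to) |>
        dplyr::summarise(coverage = max(.data$coverage), .groups = "drop")
    }
  }

  structure(list(contigs = contigs, edges = edges), class = "assembly_graph")
}

#' @export
print.assembly_graph <- function(x, ...) {
  cat(sprintf("<assembly_graph> %d contigs, %d edges, %.0f bp total\n",
              nrow(x$contigs), nrow(x$edges), sum(x$contigs$length)))
  invisible(x)
}

clean_sequence <- function(s) {
  s <- toupper(s)
  stringr::str_replace_all(s, "[^ACGTN]", "N")
}

#' Read contig sequences from a FASTA file
#'
#' Headers are truncated at the first whitespace token. Sequences are
#' uppercased and any character outside `ACGTN` (IUPAC ambiguity codes
#' included) is mapped to `N`.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `contig_id`, `sequence`, `length`.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) abort(sprintf("empty FASTA file: %s", path))
  ids <- stringr::str_split_i(names(ss), "\\s+", 1)
  if (anyDuplicated(ids))
    abort(sprintf("duplicate FASTA header(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  seqs <- clean_sequence(as.character(ss))
  tibble::tibble(contig_id = ids, sequence = unname(seqs),
                 length = nchar(seqs))
}

#' Read a MetaBAT2/VAMB-style depth table
#'
#' Expects a tab- or comma-delimited file with a header row and columns
#' `contigName`, `contigLen`, `totalAvgDepth`, followed by alternating
#' per-sample mean and variance columns (`<sample>.bam`,
#' `<sample>.bam-var`). The number of samples is `(ncol - 3) / 2`.
#'
#' @param path Path to the depth file.
#' @return A `depth_table`: tibble with `contig_id`, `length`, `total_avg_depth`
#'   and one `mean_<s>` / `var_<s>` column pair per sample; attribute
#'   `n_samples` carries the sample count.
#' @export
read_depth <- function(path) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1L)
  delim <- if (stringr::str_detect(first, "\t")) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (ncol(df) < 5 || (ncol(df) - 3) %% 2 != 0)
    abort(sprintf("depth table must have 3 + 2*S columns; found %d", ncol(df)))
  s <- (ncol(df) - 3L) %/% 2L
  vals <- df[, -(1:3), drop = FALSE]
  if (!all(vapply(vals, is.numeric, logical(1))))
    abort("non-numeric depth values in sample columns")
  if (any(as.matrix(vals) < 0, na.rm = TRUE))
    abort("negative depth values are not allowed")
  out <- tibble::tibble(
    contig_id = as.character(df[[1]]),
    length = as.integer(df[[2]]),
    total_avg_depth = as.numeric(df[[3]])
  )
  for (k in seq_len(s)) {
    out[[paste0("mean_", k)]] <- as.numeric(vals[[2 * k - 1]])
    out[[paste0("var_", k)]]  <- as.numeric(vals[[2 * k]])
  }
  attr(out, "n_samples") <- s
  class(out) <- c("depth_table", class(out))
  out
}

#' Number of samples in a depth table
#' @param depth A `depth_table` from [read_depth()].
#' @return Integer sample count.
#' @export
n_samples <- function(depth) attr(depth, "n_samples")

#' Extract the per-sample mean-depth matrix from a depth table
#' @param depth A `depth_table`.
#' @param contig_ids Optional ids to select (errors on missing ids).
#' @return Numeric matrix, contigs x samples, rownames = contig ids.
#' @export
depth_matrix <- function(depth, contig_ids = NULL) {
  s <- n_samples(depth)
  m <- as.matrix(depth[, paste0("mean_", seq_len(s)), drop = FALSE])
  rownames(m) <- depth$contig_id
  if (!is.null(contig_ids)) {
    missing <- setdiff(contig_ids, depth$contig_id)
    if (length(missing))
      abort(sprintf("contigs missing from depth table: %s",
                    paste(missing, collapse = ", ")))
    m <- m[contig_ids, , drop = FALSE]
  }
  m
}

#' Read a single-copy marker-gene table
#'
#' Accepts two dialects, auto-detected per row: long format with one
#' `(contig_id, marker_id)` pair per row, or wide format with a contig id
#' followed by a `;`- or `,`-joined marker list in the second field.
#' Multiset semantics: the same marker twice on one contig counts twice.
#'
#' @param path Path to the marker CSV.
#' @return A tibble with columns `contig_id`, `marker_id` (one row per
#'   marker occurrence); attribute `universe` holds the distinct marker ids.
#' @export
read_markers <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    out <- tibble::tibble(contig_id = character(), marker_id = character())
    attr(out, "universe") <- character()
    return(out)
  }
  rows <- purrr::map(lines, function(ln) {
    fields <- trimws(strsplit(ln, ",", fixed = TRUE)[[1]])
    fields <- fields[nzchar(fields)]
    if (length(fields) < 2)
      abort(paste0("unrecognised marker row: ", ln,
                   "\nAccepted forms: 'contig,marker' or 'contig,m1;m2;m1'"))
    markers <- unlist(strsplit(fields[-1], ";", fixed = TRUE))
    tibble::tibble(contig_id = fields[1], marker_id = trimws(markers))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "universe") <- sort(unique(out$marker_id))
  out
}

#' Read gold contig labels
#' @param path Two-column TSV (`contig_id`, `genome_id`), no header required;
#'   a header row is detected and dropped if the first field is `contig_id`.
#' @return Tibble with columns `contig_id`, `genome_id`.
#' @export
read_labels <- function(path) {
  df <- readr::read_tsv(path, col_names = c("contig_id", "genome_id"),
                        col_types = "cc", progress = FALSE)
  if (nrow(df) && df$contig_id[1] == "contig_id") df <- df[-1, ]
  df
}

#' Write a bin assignment to TSV
#'
#' Writes a two-column tab-separated file (`contig_id` TAB `bin_id`), one
#' row per contig, ordered by contig id. No size filtering is applied.
#'
#' @param assignment Tibble with columns `contig_id`, `bin_id` (each contig
#'   exactly once).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_bins <- function(assignment, path) {
  if (nrow(assignment) == 0) {
    warn("writing an empty bin assignment")
    writeLines(character(), path)
    return(invisible(path))
  }
  if (anyDuplicated(assignment$contig_id))
    abort("assignment maps some contig to more than one bin")
  out <- dplyr::arrange(assignment[, c("contig_id", "bin_id")], .data$contig_id)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a bin assignment written by [write_bins()]
#' @param path Two-column TSV path.
#' @return Tibble with columns `contig_id`, `bin_id`.
#' @export
read_bins <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0)
    return(tibble::tibble(contig_id = character(), bin_id = integer()))
  readr::read_tsv(path, col_names = c("contig_id", "bin_id"),
                  col_types = "ci", progress = FALSE)
}
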