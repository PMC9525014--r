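test_that("GFA segments, links and coverage tags are parsed", {
  g <- read_gfa(write_tmp(gfa_two_segments(), ".gfa"), strict = TRUE)
  expect_equal(nrow(g$contigs), 2)
  expect_equal(nrow(g$edges), 1)
  # link without its own tag takes the mean of endpoint segment coverages
  expect_equal(g$edges$coverage, 20)
  expect_equal(g$contigs$length, c(4L, 4L))

  # no links -> disconnected contigs
  g2 <- read_gfa(write_tmp(gfa_two_segments(link = FALSE), ".gfa"))
  expect_equal(nrow(g2$edges), 0)
  expect_true(all(build_sampling(g2)$disconnected))

  # no coverage information anywhere -> every edge weighted 1
  g3 <- read_gfa(write_tmp(gfa_two_segments(cov = FALSE), ".gfa"))
  expect_equal(g3$edges$coverage, 1.0)

  # KC tag is per-base-normalized by segment length
  g4 <- read_gfa(write_tmp(c("S\ta\tACGTACGT\tKC:i:80", "S\tb\tACGT\tKC:i:40",
                             "L\ta\t+\tb\t+\t0M"), ".gfa"))
  expect_equal(g4$contigs$coverage, c(10, 10))
  expect_equal(g4$edges$coverage, 10)
})

test_that("GFA edge cases: strict errors, duplicates, self-loops", {
  bad_s <- write_tmp(c("S\tonly_id", "S\tok\tACGT"), ".gfa")
  expect_error(read_gfa(bad_s, strict = TRUE), "line 1")
  expect_warning(g <- read_gfa(bad_s, strict = FALSE), "skipped")
  expect_equal(g$contigs$contig_id, "ok")

  orphan <- write_tmp(c("S\ta\tACGT", "L\ta\t+\tmissing\t+\t0M"), ".gfa")
  expect_error(read_gfa(orphan, strict = TRUE), "unknown segment")
  expect_warning(g <- read_gfa(orphan), "unknown segment")
  expect_equal(nrow(g$edges), 0)

  # duplicate links over the same unordered pair keep the max coverage;
  # self-loops are dropped
  dup <- write_tmp(c("S\ta\tACGT", "S\tb\tACGT",
                     "L\ta\t+\tb\t+\t0M\tdp:i:5", "L\tb\t-\ta\t+\t0M\tdp:i:9",
                     "L\ta\t+\ta\t+\t0M\tdp:i:3"), ".gfa")
  g <- read_gfa(dup, strict = TRUE)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$coverage, 9)
})

test_that("FASTA reading uppercases, truncates headers and maps IUPAC to N", {
  fa <- write_tmp(c(">a desc here", "acgt", ">b", "ACRT"), ".fasta")
  x <- read_fasta(fa)
  expect_equal(x$contig_id, c("a", "b"))
  expect_equal(x$sequence, c("ACGT", "ACNT"))
  expect_error(read_fasta(write_tmp(c(">a", "ACGT", ">a", "TTTT"), ".fa")),
               "duplicate")
  empty <- withr::local_tempfile(fileext = ".fa")
  file.create(empty)
  expect_error(read_fasta(empty))
})

test_that("depth tables parse with S samples and validate", {
  d1 <- read_depth(write_tmp(depth_lines("c1", matrix(5)), ".tsv"))
  expect_equal(n_samples(d1), 1)
  expect_equal(unname(depth_matrix(d1)[1, 1]), 5)

  d2 <- read_depth(write_tmp(depth_lines(c("c1", "c2"),
                                         matrix(c(3, 1, 6, 2), 2)), ".tsv"))
  expect_equal(n_samples(d2), 2)
  expect_equal(dim(depth_matrix(d2)), c(2L, 2L))
  expect_error(depth_matrix(d2, c("c1", "ghost")), "ghost")

  odd <- write_tmp(c("contigName\tcontigLen\ttotalAvgDepth\ts1.bam",
                     "c1\t100\t5\t5"), ".tsv")
  expect_error(read_depth(odd), "columns")
  neg <- write_tmp(depth_lines("c1", matrix(-2)), ".tsv")
  expect_error(read_depth(neg), "negative")
})

test_that("marker tables keep multiset semantics in both dialects", {
  m <- read_markers(write_tmp(c("c1,m1", "c1,m2", "c2,m1"), ".csv"))
  expect_setequal(attr(m, "universe"), c("m1", "m2"))
  expect_equal(sum(m$contig_id == "c1"), 2)

  wide <- read_markers(write_tmp("c1,m1;m1", ".csv"))
  expect_equal(wide$marker_id, c("m1", "m1"))

  empty <- withr::local_tempfile(fileext = ".csv")
  file.create(empty)
  m0 <- read_markers(empty)
  expect_equal(nrow(m0), 0)
  expect_length(attr(m0, "universe"), 0)

  expect_error(read_markers(write_tmp("just_one_field", ".csv")), "Accepted")
})

test_that("bin TSV writing is deterministic and round-trips", {
  bins <- tibble::tibble(contig_id = c("c2", "c1"), bin_id = c(0L, 0L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_bins(bins, path)
  expect_equal(readLines(path), c("c1\t0", "c2\t0"))
  back <- read_bins(path)
  expect_equal(back, dplyr::arrange(bins, contig_id), ignore_attr = TRUE)

  expect_warning(write_bins(bins[0, ], path), "empty")
  expect_equal(file.info(path)$size, 0)
  dup <- tibble::tibble(contig_id = c("c1", "c1"), bin_id = 0:1)
  expect_error(write_bins(dup, path), "more than one")
})

test_that("generated GFA round-trips exactly and degree sums match", {
  comm <- small_community()
  expect_no_warning(g <- read_gfa(comm$files$gfa, strict = TRUE))
  cfg <- comm$config
  expect_equal(nrow(g$contigs), cfg$n_genomes * cfg$contigs_per_genome)
  expect_equal(nrow(g$edges), cfg$n_genomes * (cfg$contigs_per_genome - 1))
  dist <- build_sampling(g)
  expect_equal(sum(lengths(dist$neighbors)), 2 * nrow(g$edges))
  n_l_lines <- sum(startsWith(readLines(comm$files$gfa), "L"))
  expect_lte(max(lengths(dist$neighbors)), n_l_lines)
  # readers are pure: same file, identical structures
  expect_identical(read_gfa(comm$files$gfa), g)
  expect_identical(read_depth(comm$files$depth), read_depth(comm$files$depth))
})
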