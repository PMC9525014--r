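graph_from_lines <- function(lines) read_gfa(write_tmp(lines, ".gfa"))

star_graph <- function() {
  # u connected to v1 (cov 3) and v2 (cov 1)
  graph_from_lines(c("S\tu\tACGT", "S\tv1\tACGT", "S\tv2\tACGT", "S\tw\tACGT",
                     "L\tu\t+\tv1\t+\t0M\tdp:f:3",
                     "L\tu\t+\tv2\t+\t0M\tdp:f:1"))
}

test_that("sampling distributions are coverage-proportional and inverse", {
  dist <- build_sampling(star_graph())
  u <- which(dist$contig_ids == "u")
  expect_equal(dist$p_pos[[u]], c(0.75, 0.25))
  expect_equal(dist$p_neg[[u]], c(0.25, 0.75))
  # single neighbor: both distributions are the point mass
  v1 <- which(dist$contig_ids == "v1")
  expect_equal(dist$p_pos[[v1]], 1)
  expect_equal(dist$p_neg[[v1]], 1)
  # disconnected contig
  w <- which(dist$contig_ids == "w")
  expect_true(dist$disconnected[w])
  expect_length(dist$p_pos[[w]], 0)

  # tag-free graph: uniform both ways
  g <- graph_from_lines(c("S\ta\tAC", "S\tb\tAC", "S\tc\tAC",
                          "L\ta\t+\tb\t+\t0M", "L\ta\t+\tc\t+\t0M"))
  d2 <- build_sampling(g)
  a <- which(d2$contig_ids == "a")
  expect_equal(d2$p_pos[[a]], c(0.5, 0.5))
  expect_equal(d2$p_neg[[a]], c(0.5, 0.5))
})

test_that("edge sampling obeys the stated law", {
  dist <- build_sampling(star_graph())
  u <- which(dist$contig_ids == "u")
  v1 <- which(dist$contig_ids == "v1")
  set.seed(101)
  pos <- replicate(10000, sample_edges(dist, u, 1)$positive)
  expect_lt(abs(mean(pos == v1) - 0.75), 0.02)

  # negatives follow the inverse-coverage distribution (chi-square GOF)
  set.seed(202)
  negs <- unlist(replicate(2000, sample_edges(dist, u, 5)$negatives,
                           simplify = FALSE))
  counts <- table(factor(negs, levels = dist$neighbors[[u]]))
  gof <- suppressWarnings(chisq.test(counts, p = dist$p_neg[[u]]))
  expect_gt(gof$p.value, 0.001)

  # fixed seed: identical streams
  set.seed(7); a <- replicate(50, sample_edges(dist, u, 3)$negatives)
  set.seed(7); b <- replicate(50, sample_edges(dist, u, 3)$negatives)
  expect_identical(a, b)

  # degree-1 node: negatives are uniform over non-neighbors
  set.seed(3)
  nn <- unlist(replicate(200, sample_edges(dist, v1, 2)$negatives,
                         simplify = FALSE))
  expect_true(all(!nn %in% c(v1, u)))
  # disconnected node: positive NA
  w <- which(dist$contig_ids == "w")
  s <- sample_edges(dist, w, 4)
  expect_true(is.na(s$positive))
  expect_length(s$negatives, 4)
})

test_that("sage_layer computes act([h || mean(neighbors)] W)", {
  h <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  # no neighbors: aggregate is zero, identity-like weights pass h through
  W <- rbind(diag(2), matrix(0, 2, 2))
  agg0 <- aggregate_neighbors(h, list(integer(), integer()))
  expect_equal(agg0, matrix(0, 2, 2))
  expect_equal(sage_layer(h, agg0, W, activation = NULL), h)

  # all neighbors identical to self: aggregate equals h
  agg1 <- aggregate_neighbors(h, list(1L, 2L))
  expect_equal(agg1, h)

  # hand-set 4x2 weight matrix against explicit matrix arithmetic
  W2 <- matrix(c(0.5, -1, 2, 0, 1, 1, -0.5, 0.25), 4, 2)
  agg <- aggregate_neighbors(h, list(2L, 1L))
  out <- sage_layer(h, agg, W2)
  expect_equal(out, pmax(cbind(h, h[c(2, 1), ]) %*% W2, 0))
  expect_error(sage_layer(h, agg, matrix(0, 3, 2)), "dimension mismatch")
})

test_that("edge_loss matches the coverage-scaled objective", {
  # zero embeddings: sigma(0) = 1/2 on both terms
  z0 <- c(0, 0)
  expect_equal(edge_loss(z0, z0, 1, matrix(0, 1, 2), Q = 1), 2 * log(2))
  # rc_norm = 0: positive term vanishes
  zu <- c(1, 0); zv <- c(1, 0)
  negs <- rbind(c(-1, 0), c(0, 0))
  expect_equal(edge_loss(zu, zv, 0, negs, Q = 2),
               -2 * mean(log(plogis(c(1, 0)))))
  # independent scalar evaluation of the full form
  got <- edge_loss(zu, zv, 0.5, negs, Q = 2)
  want <- -0.5 * log(plogis(1)) - 2 * mean(log(plogis(-c(-1, 0))))
  expect_equal(got, want)
  expect_error(edge_loss(c(NA, 1), zv, 0.5, negs), "non-finite")
})

test_that("edge_loss invariants: non-negativity, monotonicity, affinity", {
  set.seed(11)
  for (i in 1:20) {
    zu <- rnorm(4); zv <- rnorm(4)
    negs <- matrix(rnorm(12), 3)
    rc <- runif(1)
    expect_gte(edge_loss(zu, zv, rc, negs), 0)
  }
  zu <- c(1, 0); negs <- matrix(c(0.5, 0), 1)
  # larger positive dot product decreases J
  expect_gt(edge_loss(zu, c(0.1, 0), 1, negs),
            edge_loss(zu, c(2, 0), 1, negs))
  # larger negative dot product increases J
  expect_gt(edge_loss(zu, c(1, 0), 1, matrix(c(3, 0), 1)),
            edge_loss(zu, c(1, 0), 1, matrix(c(0.5, 0), 1)))
  # J is affine in rc_norm with slope -log sigma(zu . zv)
  zv <- c(0.7, 0)
  j0 <- edge_loss(zu, zv, 0, negs)
  j1 <- edge_loss(zu, zv, 1, negs)
  jh <- edge_loss(zu, zv, 0.37, negs)
  expect_equal(jh, j0 + 0.37 * (j1 - j0))
  expect_equal(j1 - j0, -log(plogis(sum(zu * zv))))
})

test_that("coverage normalization divides by the graph maximum", {
  g <- graph_from_lines(c("S\ta\tAC", "S\tb\tAC", "S\tc\tAC", "S\td\tAC",
                          "L\ta\t+\tb\t+\t0M\tdp:f:2",
                          "L\tb\t+\tc\t+\t0M\tdp:f:4",
                          "L\tc\t+\td\t+\t0M\tdp:f:8"))
  expect_equal(sort(normalize_coverage(g)$rc_norm), c(0.25, 0.5, 1))
  g1 <- graph_from_lines(c("S\ta\tAC", "S\tb\tAC", "L\ta\t+\tb\t+\t0M\tdp:f:7"))
  expect_equal(normalize_coverage(g1)$rc_norm, 1)
  g0 <- graph_from_lines(c("S\ta\tAC", "S\tb\tAC"))
  expect_equal(nrow(normalize_coverage(g0)), 0)
})

test_that("analytic GNN gradients match numerical differentiation", {
  # tiny fixed problem: 4 nodes, 2 layers, frozen edge samples
  set.seed(21)
  g <- graph_from_lines(c("S\ta\tAC", "S\tb\tAC", "S\tc\tAC", "S\td\tAC",
                          "L\ta\t+\tb\t+\t0M\tdp:f:2",
                          "L\tb\t+\tc\t+\t0M\tdp:f:1",
                          "L\tc\t+\td\t+\t0M\tdp:f:2"))
  dist <- build_sampling(g)
  n <- 4
  h0 <- matrix(rnorm(n * 3), n)
  ops <- list(binsage:::aggregation_operator(dist$neighbors, n),
              binsage:::aggregation_operator(dist$neighbors, n))
  params <- list(W1 = matrix(rnorm(6 * 5), 6, 5) * 0.3,
                 W2 = matrix(rnorm(10 * 2), 10, 2) * 0.3)
  draws <- list(list(u = 1, v = 2, rc = 1, negs = c(3, 4)),
                list(u = 3, v = 4, rc = 0.5, negs = c(1, 1)))
  loss_of <- function(p) {
    fw <- binsage:::gnn_forward(p, h0, ops, 2)
    z <- fw$hs[[3]]
    sum(vapply(draws, function(d)
      edge_loss(z[d$u, ], z[d$v, ], d$rc, z[d$negs, , drop = FALSE]),
      numeric(1)))
  }
  # analytic dJ/dz accumulated the same way train_gnn does
  fw <- binsage:::gnn_forward(params, h0, ops, 2)
  z <- fw$hs[[3]]
  dz <- matrix(0, n, 2)
  for (d in draws) {
    p <- plogis(sum(z[d$u, ] * z[d$v, ]))
    dz[d$u, ] <- dz[d$u, ] - d$rc * (1 - p) * z[d$v, ]
    dz[d$v, ] <- dz[d$v, ] - d$rc * (1 - p) * z[d$u, ]
    for (vn in d$negs) {
      s <- plogis(sum(z[d$u, ] * z[vn, ]))
      dz[d$u, ] <- dz[d$u, ] + s * z[vn, ]
      dz[vn, ] <- dz[vn, ] + s * z[d$u, ]
    }
  }
  grads <- binsage:::gnn_backward(params, fw, dz, ops, 2)
  eps <- 1e-6
  for (nm in names(params)) {
    for (idx in c(1, 7, length(params[[nm]]))) {
      pp <- params; pp[[nm]][idx] <- pp[[nm]][idx] + eps
      pm <- params; pm[[nm]][idx] <- pm[[nm]][idx] - eps
      num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
      expect_equal(grads[[nm]][idx], num, tolerance = 1e-4)
    }
  }
})

test_that("train_gnn contract: determinism, checkpoint fallback, errors", {
  comm <- small_community()
  g <- read_gfa(comm$files$gfa)
  set.seed(1)
  init <- matrix(rnorm(nrow(g$contigs) * 6), ncol = 6,
                 dimnames = list(g$contigs$contig_id, NULL))
  cfg <- gnn_config(n_layers = 2, hidden_dim = 16, output_dim = 4,
                    epochs = 3, neighbors_per_layer = c(5, 5), seed = 9)
  f1 <- train_gnn(g, init, cfg)
  f2 <- train_gnn(g, init, cfg)
  expect_identical(f1$embedding, f2$embedding)
  expect_equal(ncol(f1$embedding), 4)
  # no markers: the last trained epoch is the selected checkpoint
  expect_equal(f1$selected_epoch, nrow(f1$trace))

  cfg0 <- cfg; cfg0$epochs <- 0
  u1 <- train_gnn(g, init, cfg0)
  u2 <- train_gnn(g, init, cfg0)
  expect_identical(u1$embedding, u2$embedding)

  empty <- structure(list(contigs = g$contigs[0, ], edges = g$edges[0, ]),
                     class = "assembly_graph")
  expect_error(train_gnn(empty, init, cfg), "no contigs")
  expect_error(train_gnn(g, init[-1, , drop = FALSE], cfg), "missing contigs")
})

test_that("marker checkpointing selects the best-scoring epoch", {
  comm <- small_community()
  g <- read_gfa(comm$files$gfa)
  mk <- read_markers(comm$files$markers)
  set.seed(2)
  init <- matrix(rnorm(nrow(g$contigs) * 6), ncol = 6,
                 dimnames = list(g$contigs$contig_id, NULL))
  cfg <- gnn_config(n_layers = 2, hidden_dim = 16, output_dim = 4,
                    epochs = 4, neighbors_per_layer = c(5, 5), seed = 4)
  fit <- train_gnn(g, init, cfg, markers = mk)
  scored <- fit$trace[!is.na(fit$trace$marker_score), ]
  expect_equal(fit$selected_epoch,
               scored$epoch[which.max(scored$marker_score)])
})
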