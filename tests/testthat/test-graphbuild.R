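# Batch-graph construction: distances, combination rule, k-NN/radius
# edges, and the brute-force oracle.

# Independent brute-force edge enumeration used as the oracle: O(n^2)
# loops, no shared code with build_graph beyond the distance definitions.
oracle_edges <- function(z, beta, k, radius) {
  n <- nrow(z)
  d_sp <- matrix(0, n, n)
  d_se <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d_sp[i, j] <- sqrt(sum((z[i, ] - z[j, ])^2))
    ni <- sqrt(sum(z[i, ]^2)); nj <- sqrt(sum(z[j, ]^2))
    sim <- if (ni == 0 && nj == 0) 1 else if (ni == 0 || nj == 0) 0 else
      sum(z[i, ] * z[j, ]) / (ni * nj)
    d_se[i, j] <- max(0, 1 - sim)
  }
  mm <- function(d) {
    if (n == 1) return(d)
    off <- d[row(d) != col(d)]
    lo <- min(off); hi <- max(off)
    if (hi - lo < 1e-12) d <- pmin(pmax(d, 0), 1)
    else { d <- (d - lo) / (hi - lo); d[d < 0] <- 0; d[d > 1] <- 1 }
    diag(d) <- 0
    d
  }
  D <- beta * mm(d_sp) + (1 - beta) * mm(d_se)
  adj <- matrix(FALSE, n, n); diag(adj) <- TRUE
  if (n > 1) {
    ke <- min(k, n - 1)
    for (i in seq_len(n)) {
      others <- setdiff(seq_len(n), i)
      nb <- others[order(D[i, others], others)][seq_len(ke)]
      adj[i, nb] <- TRUE; adj[nb, i] <- TRUE
    }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && D[i, j] <= radius) adj[i, j] <- TRUE
    }
  }
  adj
}

test_that("distance matrices are symmetric, zero-diagonal, in [0,1]", {
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    d <- sample(2:8, 1)
    z <- matrix(rnorm(n * d), n, d)
    dd <- pairwise_distances(z)
    for (d in dd) {
      expect_equal(d, t(d))
      expect_equal(diag(d), rep(0, nrow(d)))
      expect_true(all(d >= 0 & d <= 1))
    }
  }
  # identical vectors at distance zero under both metrics
  z <- rbind(c(1, 2), c(1, 2), c(5, -1))
  dd <- pairwise_distances(z)
  expect_equal(dd$d_sp[1, 2], 0)
  expect_equal(dd$d_se[1, 2], 0)
  # degenerate single-node batch
  d1 <- pairwise_distances(matrix(1:3, 1))
  expect_identical(d1$d_sp, matrix(0, 1, 1))
  # orthogonal unit vectors sit at the cosine maximum
  z <- rbind(c(1, 0), c(0, 1), c(1, 0.1))
  expect_equal(max(pairwise_distances(z)$d_se), 1)
})

test_that("combined distance follows the weighted mix exactly", {
  expect_equal(combined_distance(0.2, 0.4, 0.5), 0.3)
  expect_equal(combined_distance(0.7, 0.1, 1), 0.7)
  expect_equal(combined_distance(0.7, 0.1, 0), 0.1)
  expect_error(combined_distance(0.1, 0.1, 1.5), "beta")
})

test_that("build_graph honours self-loops, clamped k and the radius rule", {
  set.seed(12)
  z <- matrix(rnorm(12), 6, 2)
  g <- build_graph(z, k = 10)                # k >= n clamps to n-1
  expect_true(all(g$adj))                    # complete graph + self-loops
  expect_true(all(diag(g$adj)))
  expect_true(all(g$deg >= 1))

  # coincident points are always joined by the radius rule
  z2 <- rbind(c(0, 0), c(0, 0), c(3, 1), c(-2, 4), c(1, -5))
  g2 <- build_graph(z2, k = 1, radius = 0.0)
  expect_true(g2$adj[1, 2])

  expect_error(build_graph(z, radius = -0.1), "radius")
})

test_that("five collinear points with k=2 link to their adjacent neighbours", {
  z <- cbind(1:5, 0)                          # unit spacing on a line
  g <- build_graph(z, beta = 1, k = 2, radius = 0.01)
  expect_true(g$adj[2, 1] && g$adj[2, 3])
  expect_true(g$adj[3, 2] && g$adj[3, 4])
  expect_true(g$adj[4, 3] && g$adj[4, 5])
  expect_true(g$adj[1, 2] && g$adj[5, 4])
  expect_false(g$adj[1, 4] || g$adj[1, 5] || g$adj[2, 5])
})

test_that("edge sets match the brute-force oracle over random batches", {
  set.seed(123)
  for (rep in 1:60) {
    n <- sample(1:24, 1)
    d <- sample(2:16, 1)
    z <- matrix(rnorm(n * d), n, d)
    beta <- runif(1)
    k <- sample(1:6, 1)
    radius <- runif(1, 0, 0.4)
    g <- build_graph(z, beta = beta, k = k, radius = radius)
    expect_identical(unname(g$adj), oracle_edges(z, beta, k, radius))
  }
})

test_that("adjacency is symmetric and monotone in k and radius", {
  set.seed(31)
  for (rep in 1:20) {
    z <- matrix(rnorm(16 * 6), 16, 6)
    g <- build_graph(z, k = 2, radius = 0.05)
    expect_identical(g$adj, t(g$adj))
    g_k <- build_graph(z, k = 4, radius = 0.05)
    g_r <- build_graph(z, k = 2, radius = 0.3)
    expect_true(all(g$adj <= g_k$adj))       # growing k never removes edges
    expect_true(all(g$adj <= g_r$adj))       # growing radius never removes edges
  }
})

test_that("edge-list dump writes 0-based `i j weight` lines", {
  set.seed(5)
  z <- matrix(rnorm(8), 4, 2)
  g <- build_graph(z, k = 1, radius = 0)
  path <- withr::local_tempfile()
  write_edge_list(g, path)
  lines <- readLines(path)
  expect_equal(length(lines), nrow(g$edges))
  first <- as.numeric(strsplit(lines[1], " ")[[1]])
  expect_equal(first[1:2], g$edges[1, ] - 1)
  expect_equal(first[3], g$weights[1], tolerance = 1e-9)
})
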