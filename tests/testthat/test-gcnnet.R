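# GCN layer/refinement and the two heads.

# Dense oracle for one layer: sigma(S H W' + b) with
# S_ij = 1/sqrt(deg i * deg j) on edges (incl. self-loops), else 0.
dense_layer_oracle <- function(h, adj, W, b) {
  deg <- rowSums(adj)
  S <- matrix(0, nrow(adj), ncol(adj))
  for (i in seq_len(nrow(adj))) for (j in seq_len(ncol(adj))) {
    if (adj[i, j]) S[i, j] <- 1 / sqrt(deg[i] * deg[j])
  }
  out <- S %*% h %*% t(W)
  out <- out + matrix(b, nrow(h), length(b), byrow = TRUE)
  pmax(out, 0)
}

random_graph <- function(n, p_edge = 0.3) {
  adj <- matrix(runif(n * n) < p_edge, n, n)
  adj <- adj | t(adj)
  diag(adj) <- TRUE
  adj
}

graph_from_adj <- function(adj) {
  # build a batch_graph-compatible object directly from an adjacency
  n <- nrow(adj)
  deg <- rowSums(adj)
  structure(list(n = n, ids = as.character(1:n), adj = adj,
                 deg = deg, S = adj / sqrt(outer(deg, deg)),
                 dist = matrix(0, n, n),
                 edges = which(adj & upper.tri(adj), arr.ind = TRUE),
                 params = list(beta = 0.5, k = 1L, radius = 0)),
            class = "batch_graph")
}

test_that("gcn_layer reproduces hand-computed two-node aggregation", {
  # nodes joined by one edge plus self-loops: deg = 2 each, W = I, b = 0
  adj <- matrix(TRUE, 2, 2)
  g <- graph_from_adj(adj)
  h <- rbind(c(1, 0), c(0, 1))
  out <- gcn_layer(h, g, diag(2), c(0, 0))
  expect_equal(unname(as.matrix(out)), rbind(c(0.5, 0.5), c(0.5, 0.5)))

  # single node with only the self-loop: identity transform returns h
  g1 <- graph_from_adj(matrix(TRUE, 1, 1))
  h1 <- matrix(c(2, 3), 1)
  expect_equal(unname(as.matrix(gcn_layer(h1, g1, diag(2), c(0, 0)))), h1)
})

test_that("gcn_layer equals the dense oracle on random graphs", {
  set.seed(77)
  for (rep in 1:40) {
    n <- sample(2:12, 1)
    d_in <- sample(2:6, 1)
    d_out <- sample(2:6, 1)
    adj <- random_graph(n)
    h <- matrix(rnorm(n * d_in), n, d_in)
    W <- matrix(rnorm(d_out * d_in), d_out, d_in)
    b <- rnorm(d_out)
    got <- gcn_layer(h, graph_from_adj(adj), W, b)
    expect_equal(unname(as.matrix(got)), dense_layer_oracle(h, adj, W, b),
                 tolerance = 1e-5)
  }
})

test_that("gcn_layer validates shapes and rejects L = 0 stacks", {
  g <- graph_from_adj(random_graph(4))
  expect_error(gcn_layer(matrix(0, 3, 2), g, diag(2), c(0, 0)), "match")
  expect_error(gcn_layer(matrix(0, 4, 3), g, diag(2), c(0, 0)), "dim")
  expect_error(gcn_params(8, hidden = integer(0)), "L >= 1")
})

test_that("refine is deterministic with dropout off and matches an MLP on
           an edgeless graph", {
  set.seed(42)
  params <- gcn_params(4, hidden = c(6, 5))
  n <- 7
  z <- matrix(rnorm(n * 4), n, 4)
  adj <- diag(n) > 0                         # self-loops only, deg = 1
  g <- graph_from_adj(adj)
  h1 <- refine(z, g, params)
  h2 <- refine(z, g, params)
  expect_identical(h1, h2)

  # with S = I the stack is a per-node 2-layer MLP; check rows separately
  mlp <- function(x) {
    a <- pmax(params$W[[1]] %*% x + params$b[[1]], 0)
    pmax(as.vector(params$W[[2]] %*% a + params$b[[2]]), 0)
  }
  for (i in seq_len(n)) {
    expect_equal(unname(h1[i, ]), mlp(z[i, ]), tolerance = 1e-10)
  }
})

test_that("refinement is node-permutation equivariant", {
  set.seed(9)
  params <- gcn_params(3, hidden = c(5, 4))
  n <- 8
  z <- matrix(rnorm(n * 3), n, 3)
  adj <- random_graph(n)
  perm <- sample(n)
  h <- refine(z, graph_from_adj(adj), params)
  hp <- refine(z[perm, ], graph_from_adj(adj[perm, perm]), params)
  expect_equal(unname(hp), unname(h[perm, ]), tolerance = 1e-10)
})

test_that("classifier softmax rows behave as probabilities", {
  set.seed(10)
  heads <- heads_params(6, 5, 0.3)
  h <- matrix(rnorm(4 * 6), 4, 6)
  # zero weights/bias: uniform rows
  p <- classify(h, heads)
  expect_equal(unname(p), matrix(0.2, 4, 5))
  # dominant bias wins every row
  heads$b_cls <- c(0, 0, 10, 0, 0)
  p <- classify(h, heads)
  expect_true(all(max.col(p) == 3))
  # any weights: rows sum to one
  heads$W_cls <- matrix(rnorm(30), 5, 6)
  p <- classify(h, heads)
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)
})

test_that("quality head is a logistic scalar strictly inside (0,1)", {
  heads <- heads_params(6, 5, 0.3)
  h <- matrix(rnorm(10 * 6), 10, 6)
  expect_equal(quality_score(h, heads), rep(0.5, 10))      # zero weights
  heads$b_qa <- 30
  expect_true(all(quality_score(h, heads) > 0.99))         # monotone in bias
  heads$b_qa <- 0
  heads$W_qa <- rnorm(6, 0, 1)
  q <- quality_score(h, heads)
  expect_true(all(q > 0 & q < 1))
})
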