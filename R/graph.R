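# Batch-graph construction over feature vectors.
#
# Nodes are the feature vectors of one mini-batch; edges combine a
# magnitude-sensitive "spatial" distance (Euclidean) and a
# direction-sensitive "semantic" distance (cosine) through a beta-weighted
# mix, then k-nearest-neighbour and radius rules decide adjacency.

#' Pairwise spatial and semantic distance matrices
#'
#' Computes the Euclidean (spatial) and cosine (semantic) distance between
#' every pair of feature vectors, each min–max normalised per batch to
#' \[0,1\] over the off-diagonal entries (the diagonal stays 0).  When all
#' off-diagonal distances are equal the scale is undefined and the raw
#' values, clipped to \[0,1\], are returned instead.
#'
#' @param features Numeric matrix, one row per sample.
#' @param metric_sp,metric_se Distance choices; `"euclidean"` or `"cosine"`
#'   for either slot (defaults: Euclidean spatial, cosine semantic).
#' @return List with symmetric `n x n` matrices `d_sp` and `d_se`.
#' @export
pairwise_distances <- function(features, metric_sp = "euclidean",
                               metric_se = "cosine") {
  features <- as.matrix(features)
  if (!all(is.finite(features))) stopf("feature matrix contains non-finite values")
  list(d_sp = normalize_dist(raw_dist(features, metric_sp)),
       d_se = normalize_dist(raw_dist(features, metric_se)))
}

raw_dist <- function(z, metric) {
  n <- nrow(z)
  if (n == 1L) return(matrix(0, 1, 1))
  if (metric == "euclidean") {
    d <- unname(as.matrix(stats::dist(z)))
  } else if (metric == "cosine") {
    nrm <- sqrt(rowSums(z^2))
    zn <- z / ifelse(nrm > 0, nrm, 1)
    sim <- tcrossprod(zn)
    zero <- nrm == 0
    if (any(zero)) {             # zero vectors: similar only to other zeros
      sim[zero, ] <- 0
      sim[, zero] <- 0
      sim[zero, zero] <- 1
    }
    d <- 1 - sim
    d[d < 0] <- 0
  } else {
    stopf("unknown distance metric '%s'", metric)
  }
  diag(d) <- 0
  d
}

normalize_dist <- function(d) {
  n <- nrow(d)
  if (n == 1L) return(d)
  off <- d[upper.tri(d)]
  lo <- min(off)
  hi <- max(off)
  if (hi - lo < 1e-12) {
    d <- pmin(pmax(d, 0), 1)     # degenerate batch: raw values, clipped
  } else {
    d <- (d - lo) / (hi - lo)
    d[d < 0] <- 0
    d[d > 1] <- 1
  }
  diag(d) <- 0
  d
}

#' Combined node distance
#'
#' `d_comb = beta * d_sp + (1 - beta) * d_se` with `beta` in \[0,1\]
#' weighting the spatial against the semantic distance.
#'
#' @param d_sp,d_se Non-negative distances (scalars or matrices).
#' @param beta Mixing weight in \[0,1\].
#' @return The combined distance, same shape as the inputs.
#' @export
combined_distance <- function(d_sp, d_se, beta = 0.5) {
  if (length(beta) != 1L || is.na(beta) || beta < 0 || beta > 1) {
    stopf("beta must be a single value in [0,1]")
  }
  beta * d_sp + (1 - beta) * d_se
}

#' Build the batch graph
#'
#' Edges are the union of (i) a self-loop at every node, (ii) symmetrised
#' k-nearest-neighbour pairs under the combined distance, and (iii) every
#' pair whose combined distance is at most `radius`.  k-NN ties break by
#' ascending node index.  `k >= n` is clamped to `n - 1`.
#'
#' @param features Numeric matrix of feature vectors (rows = nodes), or a
#'   list as returned by [pairwise_distances()].
#' @param beta Spatial/semantic mixing weight (default 0.5).
#' @param k Number of nearest neighbours (default 4).
#' @param radius Distance threshold for extra edges (default 0.1, on the
#'   normalised distance scale).
#' @param ids Optional character vector of node identifiers.
#' @param weighted Use affinity weights `1 - d_comb` in the aggregation
#'   normalisation instead of binary adjacency (off by default; the update
#'   rule normalises by degrees only).
#' @return An object of class `batch_graph` with fields `n`, `ids`, `adj`
#'   (logical adjacency including self-loops), `edges` (m x 2, i < j),
#'   `weights` (combined distance per edge), `dist` (full combined-distance
#'   matrix), `deg`, `S` (degree-normalised aggregation matrix) and
#'   `params`.
#' @export
build_graph <- function(features, beta = 0.5, k = 4L, radius = 0.1,
                        ids = NULL, weighted = FALSE) {
  if (length(radius) != 1L || is.na(radius) || radius < 0) {
    stopf("radius must be a single non-negative value")
  }
  if (k < 1L) stopf("k must be at least 1")
  if (is.list(features) && !is.null(features$d_sp)) {
    dists <- features
    n <- nrow(dists$d_sp)
  } else {
    features <- as.matrix(features)
    n <- nrow(features)
    dists <- pairwise_distances(features)
  }
  D <- combined_distance(dists$d_sp, dists$d_se, beta)
  adj <- diag(n) > 0                      # self-loops always present
  if (n > 1L) {
    k_eff <- min(as.integer(k), n - 1L)
    for (i in seq_len(n)) {
      ord <- order(D[i, ], seq_len(n))    # ties: ascending node index
      ord <- ord[ord != i]
      nb <- ord[seq_len(k_eff)]
      adj[i, nb] <- TRUE
      adj[nb, i] <- TRUE                  # symmetrise the k-NN relation
    }
    within <- D <= radius
    diag(within) <- FALSE
    adj <- adj | within
  }
  deg <- rowSums(adj)
  if (weighted) {
    A <- (1 - D) * adj
    diag(A) <- 1
    degw <- rowSums(A)
    S <- A / sqrt(outer(degw, degw))
  } else {
    S <- adj / sqrt(outer(deg, deg))
  }
  eidx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  structure(
    list(n = n, ids = ids %||% as.character(seq_len(n)), adj = adj,
         edges = unname(eidx), weights = D[eidx], dist = D, deg = deg, S = S,
         params = list(beta = beta, k = as.integer(k), radius = radius,
                       weighted = weighted)),
    class = "batch_graph"
  )
}

#' @export
print.batch_graph <- function(x, ...) {
  cat(sprintf(
    "Batch graph: %d nodes, %d undirected edges (+%d self-loops)\n",
    x$n, nrow(x$edges), x$n))
  cat(sprintf("  beta=%g, k=%d, radius=%g; degree range %d..%d\n",
              x$params$beta, x$params$k, x$params$radius,
              min(x$deg), max(x$deg)))
  invisible(x)
}

#' Dump a graph as an edge-list text file
#'
#' One `i j weight` line per undirected edge, 0-based node indices;
#' self-loops are not written.
#'
#' @param graph A `batch_graph`.
#' @param path Output file path.
#' @export
write_edge_list <- function(graph, path) {
  lines <- sprintf("%d %d %.10g", graph$edges[, 1] - 1L,
                   graph$edges[, 2] - 1L, graph$weights)
  writeLines(lines, path)
  invisible(path)
}
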