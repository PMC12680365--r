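# Graph-convolutional refinement and the classification / quality heads.
#
# Layer update (degree-normalised aggregation over the neighbourhood,
# which always includes the self-loop):
#   h_i^(l+1) = act( sum_{j in N(i)} 1/sqrt(deg i * deg j) * W_l h_j + b_l )
# i.e. in matrix form H' = act(S H W' + b) with S = D^-1/2 A D^-1/2.

he_init <- function(n_out, n_in, gain = 1) {
  matrix(stats::rnorm(n_out * n_in, 0, gain * sqrt(2 / n_in)), n_out, n_in)
}

#' GCN parameter set
#'
#' Hidden weights use He (fan-in) initialisation drawn from the current
#' RNG stream; biases start at zero.
#'
#' @param input_dim Embedding dimension of the backbone features.
#' @param hidden Integer vector of layer widths (default `c(512, 256)`,
#'   giving the two-layer refinement with a final 256-d embedding).
#' @param p_gcn Dropout rate applied after each layer activation
#'   (default 0.2).
#' @param proj_dim Optional linear projection applied after the last layer
#'   (e.g. 1024); `NULL` (default) disables it.
#' @param gain Multiplier on the fan-in initialisation scale.
#' @return An object of class `gcn_params`.
#' @export
gcn_params <- function(input_dim, hidden = c(512L, 256L), p_gcn = 0.2,
                       proj_dim = NULL, gain = 1) {
  if (length(hidden) < 1L) stopf("at least one GCN layer is required (L >= 1)")
  if (p_gcn < 0 || p_gcn >= 1) stopf("dropout rate must lie in [0,1)")
  dims <- c(as.integer(input_dim), as.integer(hidden))
  W <- lapply(seq_along(hidden), function(l) he_init(dims[l + 1L], dims[l], gain))
  b <- lapply(seq_along(hidden), function(l) numeric(dims[l + 1L]))
  proj <- NULL
  if (!is.null(proj_dim)) {
    proj <- list(W = he_init(as.integer(proj_dim), dims[length(dims)]),
                 b = numeric(as.integer(proj_dim)))
  }
  structure(list(W = W, b = b, dims = dims, L = length(hidden),
                 p_gcn = p_gcn, proj = proj),
            class = "gcn_params")
}

#' Classification and quality-head parameters
#'
#' Head weights start at zero so that the initial classifier output is
#' uniform over the grades and the initial quality score is 0.5; training
#' then shapes the logits directly from the first step.
#'
#' @param input_dim Final embedding dimension (default 256).
#' @param n_class Number of grades (default 5).
#' @param p_clf Dropout rate on the classifier-head input (default 0.3).
#' @return An object of class `heads_params`.
#' @export
heads_params <- function(input_dim = 256L, n_class = 5L, p_clf = 0.3) {
  if (p_clf < 0 || p_clf >= 1) stopf("dropout rate must lie in [0,1)")
  structure(list(W_cls = matrix(0, n_class, input_dim),
                 b_cls = numeric(n_class),
                 W_qa = numeric(input_dim), b_qa = 0,
                 n_class = as.integer(n_class), p_clf = p_clf),
            class = "heads_params")
}

add_bias <- function(M, b) M + rep(b, each = nrow(M))

dropout_mask <- function(n, m, p) {
  if (p <= 0) return(NULL)
  matrix(stats::rbinom(n * m, 1L, 1 - p) / (1 - p), n, m)
}

#' One graph-convolution layer
#'
#' @param h Node embeddings, `n x dim` matrix.
#' @param graph A [build_graph()] result with matching node count.
#' @param W,b Layer weight matrix (`dim' x dim`) and bias (`dim'`).
#' @param activation Elementwise nonlinearity (default rectifier).
#' @return The updated embeddings, `n x dim'`.
#' @export
gcn_layer <- function(h, graph, W, b, activation = relu) {
  h <- as.matrix(h)
  if (nrow(h) != graph$n) {
    stopf("embedding rows (%d) must match graph nodes (%d)", nrow(h), graph$n)
  }
  if (ncol(h) != ncol(W)) {
    stopf("weight matrix expects dim %d, embeddings have %d", ncol(W), ncol(h))
  }
  activation(add_bias(graph$S %*% h %*% t(W), b))
}

#' Refine embeddings through the GCN stack
#'
#' Applies the `L` graph-convolution layers with inverted dropout (rate
#' `p_gcn`) after each activation when `dropout_active`; dropout draws come
#' from the current RNG stream.
#'
#' @param features Initial node embeddings `h^(0)` (the backbone feature
#'   vectors), `n x d`.
#' @param graph A [build_graph()] result over the same batch.
#' @param params A [gcn_params()] object.
#' @param dropout_active Sample dropout masks (training / MC-dropout mode)?
#' @return Final embeddings, `n x hidden[L]` (or `n x proj_dim` when a
#'   projection is configured).
#' @export
refine <- function(features, graph, params, dropout_active = FALSE) {
  stopifnot(inherits(params, "gcn_params"))
  h <- as.matrix(features)
  if (ncol(h) != params$dims[1]) {
    stopf("features have dim %d, GCN expects %d", ncol(h), params$dims[1])
  }
  for (l in seq_len(params$L)) {
    h <- gcn_layer(h, graph, params$W[[l]], params$b[[l]])
    if (dropout_active && params$p_gcn > 0) {
      m <- dropout_mask(nrow(h), ncol(h), params$p_gcn)
      h <- h * m
    }
  }
  if (!is.null(params$proj)) h <- add_bias(h %*% t(params$proj$W), params$proj$b)
  h
}

#' Grade probabilities from refined embeddings
#'
#' Softmax over `W_cls h + b_cls`; with `dropout_active` the head input is
#' dropped out at rate `p_clf` first.
#'
#' @param h Refined embeddings, `n x dim`.
#' @param heads A [heads_params()] object.
#' @param dropout_active Sample the head dropout mask?
#' @return `n x n_class` matrix of probabilities; each row sums to 1.
#' @export
classify <- function(h, heads, dropout_active = FALSE) {
  stopifnot(inherits(heads, "heads_params"))
  h <- as.matrix(h)
  if (dropout_active && heads$p_clf > 0) {
    h <- h * dropout_mask(nrow(h), ncol(h), heads$p_clf)
  }
  softmax_rows(add_bias(h %*% t(heads$W_cls), heads$b_cls))
}

#' Quality score from refined embeddings
#'
#' Logistic output of the quality-assessment head,
#' `q = sigmoid(W_qa h + b_qa)`, strictly inside (0,1).
#'
#' @param h Refined embeddings, `n x dim`.
#' @param heads A [heads_params()] object.
#' @return Numeric vector of per-sample quality scores.
#' @export
quality_score <- function(h, heads) {
  stopifnot(inherits(heads, "heads_params"))
  as.vector(sigmoid(as.matrix(h) %*% heads$W_qa + heads$b_qa))
}
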