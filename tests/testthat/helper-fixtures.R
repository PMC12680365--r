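# Shared fixtures.  Heavier artefacts (the desk-scale trained model) are
# built once per test run and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

# Small in-memory phantom set: `n_per` images per grade at `size` px.
small_phantoms <- function(n_per = 4, size = 48, seed = 7) {
  spec <- phantom_spec(size, rep(n_per, 5), seed = seed)
  phantom_samples(spec)
}

# Random probability rows (softmax of Gaussian logits).
random_probs <- function(n, k = 5) {
  m <- matrix(stats::rnorm(n * k), n, k)
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

# Desk-scale trained model shared by the acceptance tests: the built-in
# tiny backbone + 2-layer GCN trained on 1,000 phantoms (5 balanced
# classes, 64 px, seed 42, 10 epochs, batch 32, published settings
# otherwise).  Optionally with training-label noise.
desk_scale_run <- function(label_noise = 0) {
  key <- sprintf("run_noise%g", label_noise)
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  if (is.null(.fixtures$desk_samples)) {
    spec <- phantom_spec(64, rep(200L, 5), seed = 42L)
    .fixtures$desk_samples <- phantom_samples(spec)
  }
  samples <- .fixtures$desk_samples
  part <- stratified_split(samples, seed = 42L)
  if (label_noise > 0) {
    set.seed(4242)
    n <- length(part$train)
    flip <- sample.int(n, round(label_noise * n))
    for (i in flip) {
      wrong <- setdiff(0:4, part$train[[i]]$grade)
      part$train[[i]]$grade <- sample(wrong, 1)
    }
  }
  cfg <- train_config(epochs = 10L, batch_size = 32L, seed = 42L)
  model <- fundus_gcn(part, config = cfg)
  out <- list(model = model, partition = part, config = cfg)
  .fixtures[[key]] <- out
  out
}
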