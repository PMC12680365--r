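# Feature-extraction backbone.
#
# The built-in backbone is a small trainable CNN: four 3x3 stride-2
# convolution blocks with rectifier activations, followed by global
# average pooling (GAP) to a d-dimensional embedding (d = channels of the
# last block, default 64).  It trains on one CPU in minutes while keeping
# the backbone -> GAP -> embedding contract of larger pretrained networks.
# Adapters for other backbones plug in by implementing the same forward
# contract (pooled vector + pre-pool spatial activation map, the latter
# required for Grad-CAM).

# First-layer filter bank: centre-surround (difference-of-Gaussians) and
# oriented edge filters applied to colour-opponent channel combinations.
# This is what the early layers of ImageNet-pretrained networks converge
# to, and it makes the untrained backbone a usable lesion detector: bright
# dots/patches, dark blobs and red neovascular tufts each light up
# different (filter x opponency) combinations.
detector_bank <- function(c_out, c_in = 3L) {
  W <- array(0, c(c_out, c_in, 3L, 3L))
  b <- numeric(c_out)
  cs <- matrix(c(-1, -1, -1, -1, 8, -1, -1, -1, -1), 3, 3) / 8
  ed <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3) / 4
  box <- matrix(1 / 9, 3, 3)
  # Colour-opponent directions.  The "yellow lesion" axis is the direction
  # orthogonal to both the fundus background hue and the optic-disc hue,
  # so punctate exudate-like lesions stand out against both — the kind of
  # domain-tuned colour selectivity pretraining on fundus imagery
  # produces in early layers.
  od_hue <- c(1, 0.86, 0.55)
  bg_hue <- c(0.82, 0.44, 0.18)
  w_y <- c(od_hue[2] * bg_hue[3] - od_hue[3] * bg_hue[2],
           od_hue[3] * bg_hue[1] - od_hue[1] * bg_hue[3],
           od_hue[1] * bg_hue[2] - od_hue[2] * bg_hue[1])
  w_y <- w_y / sqrt(sum(w_y^2))
  lum <- c(1, 1, 1) / sqrt(3)
  rg <- c(1, -1, 0) / sqrt(2)
  gb <- c(0, 1, -1) / sqrt(2)
  # (filter, opponent, threshold) units.  Box filters are matched filters
  # for small blob lesions; their thresholds (multiple levels, against the
  # background noise floor) make the pooled activation a soft lesion-area
  # count at several salience levels — the statistics that grade the
  # disease.  Centre-surround and edge units capture texture (vessels,
  # neovascular tufts).
  units <- list(
    list(cs, lum, 0), list(cs, rg, 0), list(cs, gb, 0), list(cs, w_y, 0),
    list(-cs, lum, 0), list(-cs, rg, 0), list(-cs, gb, 0), list(-cs, w_y, 0),
    list(ed, lum, 0), list(t(ed), lum, 0), list(ed, rg, 0), list(t(ed), rg, 0),
    list(box, w_y, 0.01), list(box, w_y, 0.02),
    list(box, w_y, 0.03), list(box, w_y, 0.05),
    list(-box, w_y, 0.01), list(-box, w_y, 0.02),
    list(-box, w_y, 0.03), list(-box, w_y, 0.05),
    list(box, lum, 0), list(-box, lum, 0),
    list(box, rg, 0.02), list(box, gb, 0.02)
  )
  i <- 0L
  for (u in units) {
    i <- i + 1L
    if (i > c_out) break
    for (ch in 1:min(3L, c_in)) W[i, ch, , ] <- u[[1]] * u[[2]][ch]
    # thresholded units: bias sets the detection level and compensates for
    # the -0.5 input centring (0.5 * sum(W))
    if (u[[3]] > 0) b[i] <- 0.5 * sum(W[i, , , ]) - u[[3]]
  }
  if (i < c_out) {
    left <- c_out - i
    W[(i + 1L):c_out, , , ] <-
      array(stats::rnorm(left * c_in * 9L, 0, sqrt(2 / (c_in * 9L))),
            c(left, c_in, 3L, 3L))
  }
  list(W = W, b = b)
}

# Deeper-layer initialisation: channel-preserving 3x3 averaging (cycled
# when widths differ) plus small symmetry-breaking perturbation of the
# averaging kernel itself, so that at initialisation GAP of the final map
# measures the activation area of each first-layer detector.  Cross-channel
# weights start at exactly zero: any leakage would swamp the small
# lesion-area channels; gradients still reach those weights, so training
# can grow cross-channel mixing.
aggregator_init <- function(c_out, c_in, noise = 0.05) {
  W <- array(0, c(c_out, c_in, 3L, 3L))
  box <- matrix(1 / 9, 3, 3)
  for (o in seq_len(c_out)) {
    W[o, (o - 1L) %% c_in + 1L, , ] <-
      box + matrix(stats::rnorm(9L, 0, noise / 9), 3, 3)
  }
  W
}

#' Built-in tiny convolutional backbone
#'
#' Four 3x3 stride-2 blocks with rectifier activations and GAP.  The
#' default `"detector"` initialisation builds a centre-surround / edge
#' filter bank over colour-opponent channels in the first layer and
#' channel-preserving averaging kernels in the deeper layers, so the
#' untrained network already embeds lesion-area statistics — the
#' desk-scale analogue of starting from a pretrained extractor, as the
#' full-scale pipeline does.  `"he"` gives plain random He initialisation.
#' Random draws come from the current RNG stream; call [set.seed()]
#' beforehand for reproducibility.
#'
#' @param channels Output channels of the four blocks; the last entry is
#'   the embedding dimension `d` (default `c(24, 48, 64, 64)`, d = 64).
#' @param in_channels Input image channels (3 for RGB).
#' @param init `"detector"` (default) or `"he"`.
#' @return An object of class `c("tiny_backbone", "backbone_adapter")` with
#'   fields `name`, `output_dim`, `trainable` and `params`.
#' @export
backbone_tiny <- function(channels = c(24L, 48L, 64L, 64L), in_channels = 3L,
                          init = c("detector", "he")) {
  init <- match.arg(init)
  channels <- as.integer(channels)
  dims <- c(as.integer(in_channels), channels)
  params <- lapply(seq_along(channels), function(l) {
    if (init == "he" || (l == 1L && dims[1] != 3L)) {
      W <- array(stats::rnorm(dims[l + 1L] * dims[l] * 9L, 0,
                              sqrt(2 / (dims[l] * 9L))),
                 c(dims[l + 1L], dims[l], 3L, 3L))
      list(W = W, b = numeric(dims[l + 1L]))
    } else if (l == 1L) {
      detector_bank(dims[2L], dims[1L])
    } else {
      list(W = aggregator_init(dims[l + 1L], dims[l]),
           b = numeric(dims[l + 1L]))
    }
  })
  structure(list(name = "tiny_cnn", output_dim = channels[length(channels)],
                 trainable = TRUE, channels = channels,
                 in_channels = as.integer(in_channels), init = init,
                 stride = 2L, pad = 1L, params = params),
            class = c("tiny_backbone", "backbone_adapter"))
}

#' @export
print.backbone_adapter <- function(x, ...) {
  cat(sprintf("Backbone adapter '%s': d = %d, %s\n", x$name, x$output_dim,
              if (isTRUE(x$trainable)) "trainable" else "frozen"))
  invisible(x)
}

# Stack a list of labelled samples (or bare H x W x 3 arrays) into the
# channels-first batch array (C, H, W, N) used by the conv engine, centring
# intensities to [-0.5, 0.5].
images_to_batch <- function(samples) {
  imgs <- lapply(samples, function(s) if (is.list(s)) s$image else s)
  d1 <- dim(imgs[[1]])
  same <- vapply(imgs, function(im) identical(dim(im), d1), logical(1))
  if (!all(same)) stopf("all images in a batch must share the same shape")
  n <- length(imgs)
  x <- array(0, c(d1[3], d1[1], d1[2], n))
  for (i in seq_len(n)) x[, , , i] <- aperm(imgs[[i]], c(3, 1, 2)) - 0.5
  x
}

# One stride-2 padded 3x3 convolution + ReLU.  Implemented as nine
# (C_out x C_in) GEMMs over shifted slices of the padded input, which keeps
# everything inside BLAS.  Returns the activation and the cache needed for
# the backward pass.
conv_fwd <- function(x, W, b, stride = 2L, pad = 1L) {
  dm <- dim(x)
  c_in <- dm[1]; h <- dm[2]; w <- dm[3]; n <- dm[4]
  c_out <- dim(W)[1]
  hp <- h + 2L * pad; wp <- w + 2L * pad
  xp <- array(0, c(c_in, hp, wp, n))
  xp[, pad + seq_len(h), pad + seq_len(w), ] <- x
  h_o <- (h + 2L * pad - 3L) %/% stride + 1L
  w_o <- (w + 2L * pad - 3L) %/% stride + 1L
  p <- h_o * w_o * n
  ymat <- matrix(b, c_out, p)
  for (du in 1:3) {
    rows <- du + stride * (seq_len(h_o) - 1L)
    for (dv in 1:3) {
      cols <- dv + stride * (seq_len(w_o) - 1L)
      xs <- xp[, rows, cols, , drop = FALSE]
      dim(xs) <- c(c_in, p)
      ymat <- ymat + matrix(W[, , du, dv], c_out, c_in) %*% xs
    }
  }
  mask <- ymat > 0
  ymat[!mask] <- 0
  list(out = array(ymat, c(c_out, h_o, w_o, n)), xp = xp, mask = mask,
       dims = c(c_in = c_in, h = h, w = w, n = n, h_o = h_o, w_o = w_o),
       stride = stride, pad = pad)
}

conv_bwd <- function(d_out, W, cache) {
  dm <- cache$dims
  stride <- cache$stride; pad <- cache$pad
  c_out <- dim(W)[1]; c_in <- dm[["c_in"]]
  h_o <- dm[["h_o"]]; w_o <- dm[["w_o"]]; n <- dm[["n"]]
  p <- h_o * w_o * n
  dy <- matrix(d_out, c_out, p)
  dy[!cache$mask] <- 0
  dW <- array(0, dim(W))
  dxp <- array(0, dim(cache$xp))
  for (du in 1:3) {
    rows <- du + stride * (seq_len(h_o) - 1L)
    for (dv in 1:3) {
      cols <- dv + stride * (seq_len(w_o) - 1L)
      xs <- cache$xp[, rows, cols, , drop = FALSE]
      dim(xs) <- c(c_in, p)
      dW[, , du, dv] <- dy %*% t(xs)
      dxs <- crossprod(matrix(W[, , du, dv], c_out, c_in), dy)
      dim(dxs) <- c(c_in, h_o, w_o, n)
      dxp[, rows, cols, ] <- dxp[, rows, cols, ] + dxs
    }
  }
  list(dW = dW, db = rowSums(dy),
       dx = dxp[, pad + seq_len(dm[["h"]]), pad + seq_len(dm[["w"]]), ,
                drop = FALSE])
}

gap_pool <- function(map) {                 # (C, h, w, N) -> (N x C)
  dm <- dim(map)
  a <- map
  dim(a) <- c(dm[1], dm[2] * dm[3], dm[4])
  t(apply(a, 3, rowMeans))
}

gap_bwd <- function(dz, dm) {               # (N x C) -> (C, h, w, N)
  sp <- dm[2] * dm[3]
  a <- aperm(array(t(dz) / sp, c(dm[1], dm[4], sp)), c(1, 3, 2))
  dim(a) <- dm
  a
}

# Full backbone forward; returns the pooled embedding, the final spatial
# activation map, and per-layer caches for the backward pass.
backbone_fwd <- function(adapter, x) {
  caches <- vector("list", length(adapter$params))
  for (l in seq_along(adapter$params)) {
    pl <- adapter$params[[l]]
    cl <- conv_fwd(x, pl$W, pl$b, adapter$stride, adapter$pad)
    caches[[l]] <- cl
    x <- cl$out
  }
  z <- gap_pool(x)
  if (nrow(z) == 1L && length(dim(x)) == 4L && dim(x)[4] == 1L) {
    z <- matrix(z, 1L)                       # keep n=1 batches as 1 x d
  }
  list(z = z, map = x, caches = caches)
}

backbone_bwd <- function(adapter, dz, fwd) {
  d_out <- gap_bwd(dz, dim(fwd$map))
  grads <- vector("list", length(adapter$params))
  for (l in rev(seq_along(adapter$params))) {
    bl <- conv_bwd(d_out, adapter$params[[l]]$W, fwd$caches[[l]])
    grads[[l]] <- list(W = bl$dW, b = bl$db)
    d_out <- bl$dx
  }
  grads
}

#' Extract pooled feature vectors and spatial maps
#'
#' Runs the backbone over a batch of images and returns the
#' global-average-pooled embedding together with the final convolutional
#' activation map (needed for Grad-CAM).  The pooled vector equals the
#' spatial mean of that map by construction.
#'
#' @param images List of labelled samples (or bare `H x W x 3` arrays in
#'   \[0,1\]), all sharing one shape.
#' @param adapter A backbone adapter, e.g. [backbone_tiny()].
#' @return List with `z` (`n x d` feature matrix) and `map`
#'   (`C x h x w x n` spatial activations).
#' @export
extract_features <- function(images, adapter) {
  stopifnot(inherits(adapter, "backbone_adapter"))
  fwd <- backbone_fwd(adapter, images_to_batch(images))
  list(z = fwd$z, map = fwd$map)
}
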