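# Small numeric helpers shared across the package.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Row-wise softmax
#'
#' Numerically stable softmax applied to each row of a matrix of logits.
#'
#' @param x Numeric matrix (rows = samples, columns = classes).
#' @return Matrix of the same shape; each row is non-negative and sums to 1.
#' @keywords internal
#' @noRd
softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  ex <- exp(x)
  ex / rowSums(ex)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# argmax with ties broken by the lowest index (stated tie rule)
argmax_row <- function(x) max.col(x, ties.method = "first")

# Derive a reproducible 32-bit substream seed from (seed, index).
substream_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483647)
}

# Bilinear upsampling of a 2-D matrix to (out_h, out_w); used for Grad-CAM
# heatmaps and image resizing (per-channel).
bilinear_resize <- function(m, out_h, out_w) {
  in_h <- nrow(m)
  in_w <- ncol(m)
  if (in_h == out_h && in_w == out_w) return(m)
  # align-corners-free mapping: output pixel centres onto input pixel centres
  ys <- (seq_len(out_h) - 0.5) * in_h / out_h + 0.5
  xs <- (seq_len(out_w) - 0.5) * in_w / out_w + 0.5
  y0 <- pmin(pmax(floor(ys), 1L), in_h)
  x0 <- pmin(pmax(floor(xs), 1L), in_w)
  y1 <- pmin(y0 + 1L, in_h)
  x1 <- pmin(x0 + 1L, in_w)
  wy <- pmin(pmax(ys - y0, 0), 1)
  wx <- pmin(pmax(xs - x0, 0), 1)
  a <- m[y0, x0, drop = FALSE] * ((1 - wy) %o% (1 - wx))
  b <- m[y1, x0, drop = FALSE] * (wy %o% (1 - wx))
  cc <- m[y0, x1, drop = FALSE] * ((1 - wy) %o% wx)
  d <- m[y1, x1, drop = FALSE] * (wy %o% wx)
  a + b + cc + d
}

resize_image <- function(img, size) {
  if (dim(img)[1] == size && dim(img)[2] == size) return(img)
  out <- array(0, c(size, size, dim(img)[3]))
  for (ch in seq_len(dim(img)[3])) {
    out[, , ch] <- bilinear_resize(img[, , ch], size, size)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
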