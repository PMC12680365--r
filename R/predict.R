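# Monte-Carlo-dropout prediction, quality scoring and Grad-CAM saliency.

#' Monte-Carlo dropout prediction
#'
#' Embeds each batch with the backbone, builds the batch graph once from
#' those (dropout-free) features, then runs `T` stochastic GCN/head passes
#' with dropout forced on.  The reported probability vector is the mean
#' over passes and the per-class uncertainty is the standard deviation
#' with divisor `T` (population convention).  The quality score comes from
#' the dropout-off pass.  Rebuilding the graph per pass would change
#' nothing here: the backbone has no stochastic layers, so the graph
#' inputs are identical across passes.
#'
#' @param model A fitted [fundus_gcn()] model.
#' @param samples List of labelled samples or bare `H x W x 3` arrays.
#' @param T_passes Number of stochastic passes (default from the model
#'   config, 10).
#' @param seed Optional seed for the dropout draws.
#' @param batch_size Batch size for graph construction (default from the
#'   model config).
#' @return A `prediction_bundle` data frame with columns
#'   `id, pred_grade, p0..p4, quality, uncertainty_sd`; matrices `ybar`,
#'   `sigma` (per-class sd) and `yhat` (single dropout-off pass) are
#'   attached as attributes.
#' @export
mc_dropout_predict <- function(model, samples, T_passes = NULL, seed = NULL,
                               batch_size = NULL) {
  stopifnot(inherits(model, "fundus_gcn"))
  T_passes <- as.integer(T_passes %||% model$config$T_passes)
  if (is.na(T_passes) || T_passes < 1L) stopf("T_passes must be at least 1")
  batch_size <- batch_size %||% model$config$batch_size
  if (!is.null(seed)) set.seed(seed)
  n <- length(samples)
  ids <- vapply(seq_len(n), function(i) {
    s <- samples[[i]]
    if (is.list(s) && !is.null(s$id)) s$id else sprintf("sample_%d", i)
  }, character(1))
  ybar <- sig <- yhat1 <- matrix(0, n, 5)
  qual <- numeric(n)
  cfg <- model$config
  for (bi in batch_indices(n, batch_size)) {
    x <- images_to_batch(samples[bi])
    bb <- backbone_fwd(model$backbone, x)
    zhat <- feat_norm_fwd(bb$z, model$feat_stats)$zhat
    graph <- build_graph(zhat, beta = cfg$beta, k = cfg$k,
                         radius = cfg$radius, weighted = cfg$weighted_graph)
    det <- gcn_head_forward(zhat, graph, model$gcn, model$heads,
                            dropout_active = FALSE)
    passes <- array(0, c(T_passes, length(bi), 5))
    for (t in seq_len(T_passes)) {
      gh <- gcn_head_forward(zhat, graph, model$gcn, model$heads,
                             dropout_active = TRUE)
      passes[t, , ] <- gh$yhat
    }
    mu <- apply(passes, c(2, 3), mean)
    dev <- sweep(passes, c(2, 3), mu)
    ybar[bi, ] <- mu
    sig[bi, ] <- sqrt(apply(dev^2, c(2, 3), mean))   # divisor T
    yhat1[bi, ] <- det$yhat
    qual[bi] <- det$qhat
  }
  out <- data.frame(id = ids, pred_grade = argmax_row(ybar) - 1L,
                    stringsAsFactors = FALSE)
  for (k in 1:5) out[[paste0("p", k - 1L)]] <- ybar[, k]
  out$quality <- qual
  out$uncertainty_sd <- rowMeans(sig)
  attr(out, "ybar") <- ybar
  attr(out, "sigma") <- sig
  attr(out, "yhat") <- yhat1
  attr(out, "T_passes") <- T_passes
  class(out) <- c("prediction_bundle", "data.frame")
  out
}

#' Predict method for fitted graders
#'
#' @param object A fitted [fundus_gcn()] model.
#' @param newdata List of labelled samples or image arrays.
#' @param type `"bundle"` (default, full [mc_dropout_predict()] output),
#'   `"prob"` (mean probability matrix) or `"class"` (predicted grades).
#' @param ... Passed to [mc_dropout_predict()] (`T_passes`, `seed`, ...).
#' @return See `type`.
#' @export
predict.fundus_gcn <- function(object, newdata,
                               type = c("bundle", "prob", "class"), ...) {
  type <- match.arg(type)
  bundle <- mc_dropout_predict(object, newdata, ...)
  switch(type,
         bundle = bundle,
         prob = attr(bundle, "ybar"),
         class = bundle$pred_grade)
}

#' Write predictions as CSV
#'
#' Columns `id,pred_grade,p0,p1,p2,p3,p4,quality,uncertainty_sd`.
#'
#' @param bundle A `prediction_bundle`.
#' @param path Output CSV path.
#' @export
write_predictions_csv <- function(bundle, path) {
  df <- as.data.frame(bundle)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Grad-CAM heatmap for one sample
#'
#' Computes the gradient of the target-class score (the pre-softmax logit)
#' with respect to the backbone's final convolutional activation map,
#' spatially averages it into channel weights, and forms the rectified
#' weighted channel sum, upsampled to the input size and min-max
#' normalised to \[0,1\].  A constant raw map yields an all-zero heatmap.
#' The forward pass runs dropout-off on the single-sample graph (one node
#' with its self-loop).
#'
#' @param model A fitted [fundus_gcn()] model.
#' @param sample A labelled sample or bare `H x W x 3` array.
#' @param target_class Grade in 0..4 whose evidence is localised; default
#'   is the model's predicted grade.
#' @return An object of class `gradcam_heatmap`: list with `id`,
#'   `heatmap` (`H x W` in \[0,1\]), `target_class` and `pred_grade`.
#' @export
gradcam <- function(model, sample, target_class = NULL) {
  stopifnot(inherits(model, "fundus_gcn"))
  if (is.null(model$backbone$params)) {
    stopf("backbone adapter does not expose a spatial activation map")
  }
  x <- images_to_batch(list(sample))
  bb <- backbone_fwd(model$backbone, x)
  norm <- feat_norm_fwd(bb$z, model$feat_stats)
  cfg <- model$config
  graph <- build_graph(norm$zhat, beta = cfg$beta, k = cfg$k,
                       radius = cfg$radius)
  gh <- gcn_head_forward(norm$zhat, graph, model$gcn, model$heads,
                         dropout_active = FALSE)
  pred <- argmax_row(gh$yhat) - 1L
  target_class <- as.integer(target_class %||% pred)
  if (!target_class %in% 0:4) stopf("target_class must be in 0..4")
  # gradient of the target logit w.r.t. the pooled embedding z
  dlogits <- matrix(0, 1, model$heads$n_class)
  dlogits[1, target_class + 1L] <- 1
  da <- dlogits %*% model$heads$W_cls
  for (l in rev(seq_len(model$gcn$L))) {
    dp <- da * (gh$P[[l]] > 0)
    da <- graph$S %*% (dp %*% model$gcn$W[[l]])
  }
  dz <- as.vector(feat_norm_bwd(as.matrix(da), norm))   # length d
  map <- bb$map                             # (d, h, w, 1)
  dm <- dim(map)
  alpha <- dz / (dm[2] * dm[3])             # spatial mean of d logit / d map
  heat <- matrix(0, dm[2], dm[3])
  for (ch in seq_len(dm[1])) heat <- heat + alpha[ch] * map[ch, , , 1]
  heat <- relu(heat)
  img_dim <- dim(if (is.list(sample)) sample$image else sample)
  heat <- bilinear_resize(heat, img_dim[1], img_dim[2])
  rng <- range(heat)
  heat <- if (rng[2] - rng[1] < 1e-12) heat * 0 else
    (heat - rng[1]) / (rng[2] - rng[1])
  structure(list(id = if (is.list(sample)) sample$id %||% "sample" else "sample",
                 heatmap = heat, target_class = target_class,
                 pred_grade = pred),
            class = "gradcam_heatmap")
}

#' @export
print.gradcam_heatmap <- function(x, ...) {
  cat(sprintf("Grad-CAM heatmap for '%s' (target grade %d, predicted %d), %d x %d\n",
              x$id, x$target_class, x$pred_grade,
              nrow(x$heatmap), ncol(x$heatmap)))
  invisible(x)
}

#' @export
plot.gradcam_heatmap <- function(x, ...) {
  graphics::image(t(x$heatmap[nrow(x$heatmap):1, ]),
                  col = grDevices::hcl.colors(64, "inferno"),
                  axes = FALSE, asp = 1, ...)
  graphics::title(sprintf("%s: grade %d evidence", x$id, x$target_class))
  invisible(x)
}

#' Write a Grad-CAM heatmap (optionally overlaid on its image) as PNG
#'
#' @param hm A `gradcam_heatmap`.
#' @param path Output PNG path.
#' @param sample Optional source sample; when given, the heatmap is
#'   blended in red over the image, otherwise the bare heatmap is written.
#' @export
write_heatmap_png <- function(hm, path, sample = NULL) {
  h <- hm$heatmap
  if (is.null(sample)) {
    png::writePNG(h, path)
  } else {
    img <- if (is.list(sample)) sample$image else sample
    w <- 0.6 * h
    out <- img
    out[, , 1] <- img[, , 1] * (1 - w) + w        # red overlay
    out[, , 2] <- img[, , 2] * (1 - w)
    out[, , 3] <- img[, , 3] * (1 - w)
    png::writePNG(clip01(out), path)
  }
  invisible(path)
}
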