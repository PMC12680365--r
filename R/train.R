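# Training configuration, the joint forward/backward pass, AdamW, and the
# model-fitting entry point `fundus_gcn()`.

#' Training configuration
#'
#' Defaults follow the published hyperparameter set: 50 epochs, batch 32,
#' AdamW with learning rate 5e-5 and decoupled weight decay 0.01,
#' reduce-on-plateau scheduling (patience 7, minimum learning rate 1e-7)
#' on the validation loss, early stopping after 15 non-improving epochs,
#' quality-loss weight lambda = 0.1, T = 10 Monte-Carlo dropout passes,
#' graph parameters k = 4 / radius = 0.1 / beta = 0.5, GCN hidden sizes
#' 512 and 256 with dropout 0.2, classifier-head dropout 0.3, seed 42.
#'
#' @param epochs,batch_size,lr,weight_decay,sched_patience,sched_factor,min_lr,early_stop
#'   Optimisation settings (see above).
#' @param lambda Quality-loss weight in the combined objective.
#' @param T_passes Monte-Carlo dropout passes at prediction time.
#' @param seed Global RNG seed for the run.
#' @param beta,k,radius Batch-graph construction parameters.
#' @param p_gcn,p_clf Dropout rates inside the GCN and on the classifier
#'   head input.
#' @param hidden GCN hidden layer widths.
#' @param gcn_gain Multiplier on the fan-in scale of the GCN weight
#'   initialisation (default 2): it sets the dynamic range the logits can
#'   reach under the small published learning rate, which matters when
#'   training from scratch at desk scale.
#' @param weighted_graph Use affinity-weighted aggregation (default off;
#'   the update rule normalises by degrees only).
#' @param optimizer `"adamw"` (default) or `"sgd"`.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 32L, lr = 5e-5,
                         weight_decay = 0.01, sched_patience = 7L,
                         sched_factor = 0.1, min_lr = 1e-7,
                         early_stop = 15L, lambda = 0.1, T_passes = 10L,
                         seed = 42L, beta = 0.5, k = 4L, radius = 0.1,
                         p_gcn = 0.2, p_clf = 0.3, hidden = c(512L, 256L),
                         gcn_gain = 2, weighted_graph = FALSE,
                         optimizer = "adamw") {
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0, weight_decay >= 0,
            sched_patience >= 1, min_lr > 0, early_stop >= 1,
            lambda >= 0, T_passes >= 1)
  if (early_stop <= sched_patience) {
    stopf("early-stop patience (%d) must exceed scheduler patience (%d)",
          early_stop, sched_patience)
  }
  optimizer <- match.arg(optimizer, c("adamw", "sgd"))
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, weight_decay = weight_decay,
                 sched_patience = as.integer(sched_patience),
                 sched_factor = sched_factor, min_lr = min_lr,
                 early_stop = as.integer(early_stop), lambda = lambda,
                 T_passes = as.integer(T_passes), seed = as.integer(seed),
                 beta = beta, k = as.integer(k), radius = radius,
                 p_gcn = p_gcn, p_clf = p_clf, hidden = as.integer(hidden),
                 gcn_gain = gcn_gain, weighted_graph = weighted_graph,
                 optimizer = optimizer),
            class = "train_config")
}

#' Read/write a plain-text (DCF) config file with the standard keys
#'
#' @param path File path.
#' @param config For writing, a [train_config()].
#' @return `read_config` returns a `train_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file '%s' not found", path)
  kv <- as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  defaults <- train_config()
  args <- list()
  for (nm in setdiff(names(defaults), c("hidden", "optimizer", "weighted_graph"))) {
    if (!is.null(kv[[nm]])) args[[nm]] <- num(kv[[nm]])
  }
  if (!is.null(kv$hidden)) {
    args$hidden <- as.integer(strsplit(kv$hidden, ",")[[1]])
  }
  if (!is.null(kv$optimizer)) args$optimizer <- kv$optimizer
  if (!is.null(kv$weighted_graph)) {
    args$weighted_graph <- as.logical(kv$weighted_graph)
  }
  do.call(train_config, args)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "train_config"))
  flat <- unclass(config)
  flat$hidden <- paste(config$hidden, collapse = ",")
  write.dcf(as.data.frame(flat, stringsAsFactors = FALSE), path)
  invisible(path)
}

# --- feature standardisation ------------------------------------------------
#
# Pretrained backbones end in a normalisation stage; the desk-scale
# pipeline mirrors that by standardising each embedding coordinate before
# graph construction and refinement.  Training batches use their own
# statistics (population variance) while running exponential-moving
# averages are accumulated for use at validation/prediction time.
# Standardised values are winsorised at +-FEAT_CLIP: no single feature can
# dominate, and far-out-of-distribution inputs (which would otherwise
# saturate the logits into spurious confidence) stay on the clamp where
# Monte-Carlo dropout can still express uncertainty.

FEAT_EPS <- 1e-5
FEAT_CLIP <- 3

feat_norm_fwd <- function(z, stats = NULL) {
  if (is.null(stats)) {
    mu <- colMeans(z)
    v <- colMeans(z^2) - mu^2
    v[v < 0] <- 0
  } else {
    mu <- stats$mean
    v <- stats$var
  }
  istd <- 1 / sqrt(v + FEAT_EPS)
  zraw <- sweep(sweep(z, 2L, mu), 2L, istd, `*`)
  zhat <- pmin(pmax(zraw, -FEAT_CLIP), FEAT_CLIP)
  list(zhat = zhat, zraw = zraw, mu = mu, var = v, istd = istd,
       batch_stats = is.null(stats))
}

feat_norm_bwd <- function(dzhat, cache) {
  dzhat <- dzhat * (abs(cache$zraw) < FEAT_CLIP)
  if (!cache$batch_stats) {
    return(sweep(dzhat, 2L, cache$istd, `*`))
  }
  n <- nrow(dzhat)
  zraw <- cache$zraw
  s1 <- colSums(dzhat)
  s2 <- colSums(dzhat * zraw)
  dz <- dzhat - rep(s1 / n, each = n) - zraw * rep(s2 / n, each = n)
  sweep(dz, 2L, cache$istd, `*`)
}

# --- joint forward / backward ----------------------------------------------

# GCN + heads forward over precomputed features and graph.  Dropout draws
# come from the current RNG stream.  Returns every intermediate needed by
# the backward pass.
gcn_head_forward <- function(z, graph, gcn, heads, dropout_active = FALSE) {
  S <- graph$S
  a <- z
  L <- gcn$L
  SA <- P <- M <- vector("list", L)
  for (l in seq_len(L)) {
    SA[[l]] <- S %*% a
    P[[l]] <- add_bias(SA[[l]] %*% t(gcn$W[[l]]), gcn$b[[l]])
    h <- relu(P[[l]])
    if (dropout_active && gcn$p_gcn > 0) {
      M[[l]] <- dropout_mask(nrow(h), ncol(h), gcn$p_gcn)
      h <- h * M[[l]]
    }
    a <- h
  }
  h_fin <- a
  mc <- NULL
  hc <- h_fin
  if (dropout_active && heads$p_clf > 0) {
    mc <- dropout_mask(nrow(hc), ncol(hc), heads$p_clf)
    hc <- hc * mc
  }
  logits <- add_bias(hc %*% t(heads$W_cls), heads$b_cls)
  yhat <- softmax_rows(logits)
  qhat <- as.vector(sigmoid(h_fin %*% heads$W_qa + heads$b_qa))
  list(SA = SA, P = P, M = M, h_fin = h_fin, mc = mc, hc = hc,
       logits = logits, yhat = yhat, qhat = qhat, graph = graph)
}

# Gradients of L_total = CE(yhat, y) + lambda * BCE(qhat, q) w.r.t. all
# parameters, mirroring the nested theta structure.  Returns the gradient
# of the loss w.r.t. the backbone features as `dz`.
gcn_head_backward <- function(gh, gcn, heads, y, q, lambda) {
  n <- nrow(gh$yhat)
  S <- gh$graph$S
  y1 <- matrix(0, n, heads$n_class)
  y1[cbind(seq_len(n), y + 1L)] <- 1
  dlogits <- (gh$yhat - y1) / n
  g_heads <- list(W_cls = crossprod(dlogits, gh$hc),
                  b_cls = colSums(dlogits))
  d_hfin <- dlogits %*% heads$W_cls
  if (!is.null(gh$mc)) d_hfin <- d_hfin * gh$mc
  dq <- lambda * (gh$qhat - q) / n
  g_heads$W_qa <- as.vector(crossprod(gh$h_fin, dq))
  g_heads$b_qa <- sum(dq)
  d_hfin <- d_hfin + outer(dq, heads$W_qa)
  gW <- gb <- vector("list", gcn$L)
  da <- d_hfin
  for (l in rev(seq_len(gcn$L))) {
    if (!is.null(gh$M[[l]])) da <- da * gh$M[[l]]
    dp <- da * (gh$P[[l]] > 0)
    gW[[l]] <- crossprod(dp, gh$SA[[l]])
    gb[[l]] <- colSums(dp)
    da <- S %*% (dp %*% gcn$W[[l]])
  }
  list(gcn = list(W = gW, b = gb), heads = g_heads, dz = da)
}

# --- AdamW ------------------------------------------------------------------

zeros_like <- function(x) {
  if (is.list(x)) return(lapply(x, zeros_like))
  if (is.null(dim(x))) numeric(length(x)) else array(0, dim(x))
}

# Decoupled-weight-decay Adam step, applied recursively over the nested
# parameter list.  Decay touches weight matrices only (leaf names starting
# with "W"), never biases.
adamw_step <- function(theta, grads, state, lr, wd, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(th, g, m, v, nm) {
    if (is.list(th)) {
      nms <- names(th) %||% rep("", length(th))
      for (i in seq_along(th)) {
        r <- walk(th[[i]], g[[i]], m[[i]], v[[i]],
                  if (nzchar(nms[i])) nms[i] else nm)
        th[[i]] <- r$th; m[[i]] <- r$m; v[[i]] <- r$v
      }
      return(list(th = th, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    th <- th - lr * mh / (sqrt(vh) + eps)
    if (startsWith(nm, "W")) th <- th - lr * wd * th
    list(th = th, m = m, v = v)
  }
  walk(theta, grads, state$m, state$v, "")
}

sgd_step <- function(theta, grads, lr, wd) {
  walk <- function(th, g, nm) {
    if (is.list(th)) {
      nms <- names(th) %||% rep("", length(th))
      for (i in seq_along(th)) {
        th[[i]] <- walk(th[[i]], g[[i]], if (nzchar(nms[i])) nms[i] else nm)
      }
      return(th)
    }
    if (startsWith(nm, "W")) g <- g + wd * th
    th - lr * g
  }
  walk(theta, grads, "")
}

# --- fitting ----------------------------------------------------------------

batch_indices <- function(n, batch_size) {
  split(seq_len(n), ceiling(seq_len(n) / batch_size))
}

# Forward over a list of samples with current parameters; used for both
# training steps and validation.  `dropout_active` controls GCN/head masks;
# `stats` holds running feature statistics (NULL = use batch statistics).
model_forward <- function(adapter, gcn, heads, cfg, samples, dropout_active,
                          stats = NULL) {
  x <- images_to_batch(samples)
  bb <- backbone_fwd(adapter, x)
  norm <- feat_norm_fwd(bb$z, stats)
  graph <- build_graph(norm$zhat, beta = cfg$beta, k = cfg$k,
                       radius = cfg$radius, weighted = cfg$weighted_graph)
  gh <- gcn_head_forward(norm$zhat, graph, gcn, heads, dropout_active)
  list(bb = bb, norm = norm, gh = gh)
}

#' Fit the graph-convolutional fundus grader
#'
#' Trains the backbone, GCN and both heads jointly by minimising
#' `L_total = L_cls + lambda * L_q` with mini-batch AdamW.  Each batch is
#' embedded by the backbone, a graph is built over the batch's feature
#' vectors, the GCN refines the embeddings, and the classification and
#' quality heads produce the predictions entering the loss.  A
#' reduce-on-plateau schedule monitors the validation loss and the best
#' validation parameters are kept (early stopping after
#' `config$early_stop` non-improving epochs).
#'
#' @param x A `dataset_partition` from [stratified_split()], or a list of
#'   labelled training samples.
#' @param val Validation samples (ignored when `x` is a partition; may be
#'   `NULL`, which disables the scheduler and early stopping).
#' @param config A [train_config()].
#' @param backbone A backbone adapter; default is a fresh [backbone_tiny()]
#'   initialised under `config$seed`.
#' @param quality_policy Function `(probs, grades) -> 0/1` producing the
#'   binary quality targets; the default is prediction correctness
#'   ([derive_quality_targets()]).
#' @return An object of class `fundus_gcn`: the trained adapter, GCN and
#'   head parameters, the config, and a per-epoch training log with
#'   columns `epoch, train_loss, train_cls, train_q, val_loss, lr`.
#' @seealso [predict.fundus_gcn()], [evaluate()], [gradcam()]
#' @export
fundus_gcn <- function(x, val = NULL, config = train_config(),
                       backbone = NULL,
                       quality_policy = derive_quality_targets) {
  stopifnot(inherits(config, "train_config"))
  if (inherits(x, "dataset_partition")) {
    train <- x$train
    val <- x$val
  } else {
    train <- x
  }
  if (!length(train)) stopf("training partition is empty")
  set.seed(config$seed)
  adapter <- backbone %||% backbone_tiny()
  stopifnot(inherits(adapter, "backbone_adapter"))
  gcn <- gcn_params(adapter$output_dim, config$hidden, config$p_gcn,
                    gain = config$gcn_gain %||% 1)
  heads <- heads_params(config$hidden[length(config$hidden)], 5L, config$p_clf)
  theta <- list(bb = adapter$params,
                gcn = list(W = gcn$W, b = gcn$b),
                heads = heads[c("W_cls", "b_cls", "W_qa", "b_qa")])
  state <- list(m = zeros_like(theta), v = zeros_like(theta))
  y_train <- vapply(train, `[[`, integer(1), "grade")
  y_val <- vapply(val, `[[`, integer(1), "grade")

  sync <- function(theta) {
    adapter$params <- theta$bb
    gcn$W <- theta$gcn$W
    gcn$b <- theta$gcn$b
    heads[c("W_cls", "b_cls", "W_qa", "b_qa")] <-
      theta$heads[c("W_cls", "b_cls", "W_qa", "b_qa")]
    list(adapter = adapter, gcn = gcn, heads = heads)
  }

  run_stats <- NULL   # exponential moving average of feature mean/variance

  val_metrics <- function(mdl) {
    if (!length(val)) return(c(loss = NA_real_))
    tot <- 0
    for (bi in batch_indices(length(val), config$batch_size)) {
      fw <- model_forward(mdl$adapter, mdl$gcn, mdl$heads, config,
                          val[bi], dropout_active = FALSE, stats = run_stats)
      q <- quality_policy(fw$gh$yhat, y_val[bi])
      l <- total_loss(cross_entropy_loss(fw$gh$yhat, y_val[bi]),
                      quality_loss(fw$gh$qhat, q), config$lambda)
      tot <- tot + l * length(bi)
    }
    c(loss = tot / length(val))
  }

  lr <- config$lr
  log <- NULL
  best_val <- Inf
  best_theta <- theta
  best_stats <- NULL
  best_epoch <- 0L
  since_best <- 0L
  sched_since <- 0L
  step_t <- 0L

  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(length(train))
    ep_tot <- ep_cls <- ep_q <- 0
    for (bi in batch_indices(length(train), config$batch_size)) {
      idx <- perm[bi]
      mdl <- sync(theta)
      fw <- model_forward(mdl$adapter, mdl$gcn, mdl$heads, config,
                          train[idx], dropout_active = TRUE)
      yb <- y_train[idx]
      q <- quality_policy(fw$gh$yhat, yb)
      l_cls <- cross_entropy_loss(fw$gh$yhat, yb)
      l_q <- quality_loss(fw$gh$qhat, q)
      l <- total_loss(l_cls, l_q, config$lambda)
      if (!is.finite(l)) {
        stopf("training diverged (non-finite loss) at epoch %d, batch %d",
              epoch, bi[1] %/% config$batch_size + 1L)
      }
      bw <- gcn_head_backward(fw$gh, mdl$gcn, mdl$heads, yb, q, config$lambda)
      dz <- feat_norm_bwd(bw$dz, fw$norm)
      g_bb <- backbone_bwd(mdl$adapter, dz, fw$bb)
      grads <- list(bb = g_bb, gcn = bw$gcn, heads = bw$heads)
      step_t <- step_t + 1L
      if (config$optimizer == "adamw") {
        r <- adamw_step(theta, grads, state, lr, config$weight_decay, step_t)
        theta <- r$th
        state <- list(m = r$m, v = r$v)
      } else {
        theta <- sgd_step(theta, grads, lr, config$weight_decay)
      }
      run_stats <- if (is.null(run_stats)) {
        list(mean = fw$norm$mu, var = fw$norm$var)
      } else {
        list(mean = 0.9 * run_stats$mean + 0.1 * fw$norm$mu,
             var = 0.9 * run_stats$var + 0.1 * fw$norm$var)
      }
      ep_tot <- ep_tot + l * length(idx)
      ep_cls <- ep_cls + l_cls * length(idx)
      ep_q <- ep_q + l_q * length(idx)
    }
    mdl <- sync(theta)
    vm <- val_metrics(mdl)
    log <- rbind(log, data.frame(
      epoch = epoch, train_loss = ep_tot / length(train),
      train_cls = ep_cls / length(train), train_q = ep_q / length(train),
      val_loss = unname(vm["loss"]), lr = lr))
    if (length(val)) {
      if (vm["loss"] < best_val - 1e-12) {
        best_val <- vm["loss"]
        best_theta <- theta
        best_stats <- run_stats
        best_epoch <- epoch
        since_best <- 0L
        sched_since <- 0L
      } else {
        since_best <- since_best + 1L
        sched_since <- sched_since + 1L
      }
      if (sched_since >= config$sched_patience && lr > config$min_lr) {
        lr <- max(lr * config$sched_factor, config$min_lr)
        sched_since <- 0L
      }
      if (since_best >= config$early_stop) break
    } else {
      best_theta <- theta
      best_stats <- run_stats
      best_epoch <- epoch
    }
  }

  mdl <- sync(best_theta)
  structure(list(backbone = mdl$adapter, gcn = mdl$gcn, heads = mdl$heads,
                 feat_stats = best_stats %||% run_stats,
                 config = config, log = log, best_epoch = best_epoch,
                 best_val = if (is.finite(best_val)) best_val else NA_real_,
                 n_train = length(train), grades = 0:4),
            class = "fundus_gcn")
}

#' @export
print.fundus_gcn <- function(x, ...) {
  cat("Graph-convolutional fundus grader\n")
  cat(sprintf("  backbone '%s' (d = %d) -> GCN [%s] -> 5 grades + quality head\n",
              x$backbone$name, x$backbone$output_dim,
              paste(x$config$hidden, collapse = ", ")))
  cat(sprintf("  trained on %d samples, %d epoch(s); best epoch %d",
              x$n_train, nrow(x$log), x$best_epoch))
  if (!is.na(x$best_val)) cat(sprintf(" (val loss %.4f)", x$best_val))
  cat("\n")
  invisible(x)
}

#' @export
summary.fundus_gcn <- function(object, ...) {
  n_par <- sum(unlist(lapply(
    list(object$backbone$params, object$gcn$W, object$gcn$b,
         object$heads$W_cls, object$heads$W_qa),
    function(p) if (is.list(p)) sum(lengths(rapply(p, length, how = "list")))
                else length(p))))
  out <- list(model = object, n_parameters = n_par,
              log = object$log)
  class(out) <- "summary.fundus_gcn"
  out
}

#' @export
print.summary.fundus_gcn <- function(x, ...) {
  print(x$model)
  cat(sprintf("  ~%d trainable parameters\n", x$n_parameters))
  cat("\nTraining log (last 5 epochs):\n")
  print(utils::tail(x$log, 5), row.names = FALSE)
  invisible(x)
}

#' @export
coef.fundus_gcn <- function(object, ...) {
  list(backbone = object$backbone$params,
       gcn = list(W = object$gcn$W, b = object$gcn$b),
       heads = object$heads[c("W_cls", "b_cls", "W_qa", "b_qa")])
}

#' Plot training curves
#'
#' @param x A fitted `fundus_gcn` model.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.fundus_gcn <- function(x, ...) {
  log <- x$log
  graphics::matplot(log$epoch, cbind(log$train_loss, log$val_loss),
                    type = "b", pch = c(1, 2), lty = 1,
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("train", "validation"),
                   pch = c(1, 2), col = 1:2, bty = "n")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' @param model A fitted `fundus_gcn`.
#' @param path Checkpoint file path.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "fundus_gcn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param config Optional [train_config()] to check the checkpoint against;
#'   mismatching architecture fields raise an error naming them.
#' @export
load_checkpoint <- function(path, config = NULL) {
  if (!file.exists(path)) stopf("checkpoint file '%s' not found", path)
  model <- readRDS(path)
  if (!inherits(model, "fundus_gcn")) stopf("'%s' is not a model checkpoint", path)
  if (!is.null(config)) {
    fields <- c("hidden", "p_gcn", "p_clf", "beta", "k", "radius")
    bad <- fields[!vapply(fields, function(f) {
      isTRUE(all.equal(model$config[[f]], config[[f]]))
    }, logical(1))]
    if (length(bad)) {
      stopf("checkpoint/config mismatch in field(s): %s",
            paste(bad, collapse = ", "))
    }
  }
  model
}

#' Write the training log as CSV
#'
#' Columns `epoch,train_loss,train_cls,train_q,val_loss,lr`.
#'
#' @param model A fitted `fundus_gcn`.
#' @param path Output CSV path.
#' @export
write_training_log <- function(model, path) {
  utils::write.csv(model$log, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
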