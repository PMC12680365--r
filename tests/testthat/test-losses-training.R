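# Loss closed forms, quality targets, optimiser behaviour, training loop.

test_that("quality loss matches its closed forms", {
  expect_equal(quality_loss(0.5, 1), log(2), tolerance = 1e-9)
  expect_lt(quality_loss(1 - 1e-7, 1), 1e-6)   # perfect-prediction limit
  expect_equal(quality_loss(0.9, 0), -log(0.1), tolerance = 1e-9)
  expect_equal(quality_loss(c(0.5, 0.5), c(1, 0)), log(2), tolerance = 1e-9)
  expect_error(quality_loss(0.5, 0.3), "binary")
})

test_that("total loss is the exact weighted sum", {
  expect_identical(total_loss(1.23, 0.77, 0), 1.23)
  expect_equal(total_loss(1.0, 0.5, 0.1), 1.05, tolerance = 1e-12)
  expect_identical(total_loss(0.9, 0, 7), 0.9)
  expect_error(total_loss(1, 1, -0.1), "lambda")
})

test_that("quality targets are arg-max correctness with low-index ties", {
  p <- rbind(c(0.1, 0.7, 0.1, 0.05, 0.05),
             c(0.1, 0.7, 0.1, 0.05, 0.05),
             c(0.4, 0.4, 0.1, 0.05, 0.05))   # tie: class 0 wins
  expect_identical(derive_quality_targets(p, c(1L, 3L, 0L)), c(1L, 0L, 1L))
  expect_identical(derive_quality_targets(p[3, , drop = FALSE], 1L), 0L)
})

test_that("with lambda = 0 the quality branch is inert", {
  set.seed(20)
  samples <- small_phantoms(n_per = 4, size = 32, seed = 20)
  y <- vapply(samples, `[[`, integer(1), "grade")
  cfg <- train_config(epochs = 1, batch_size = 10, lambda = 0)
  ad <- backbone_tiny(channels = c(4L, 4L, 6L, 6L))
  gcn <- gcn_params(6, c(8L, 7L), 0.2)
  heads <- heads_params(7, 5, 0.3)
  heads$W_cls <- matrix(rnorm(35, 0, 0.3), 5, 7)
  heads$W_qa <- rnorm(7, 0, 0.3)
  fw <- fundusgcn:::model_forward(ad, gcn, heads, cfg, samples, TRUE)
  q <- derive_quality_targets(fw$gh$yhat, y)
  bw <- fundusgcn:::gcn_head_backward(fw$gh, gcn, heads, y, q, lambda = 0)
  expect_identical(unname(bw$heads$W_qa), rep(0, 7))
  expect_identical(bw$heads$b_qa, 0)
  # and L_total reduces to L_cls bitwise
  l_cls <- cross_entropy_loss(fw$gh$yhat, y)
  expect_identical(total_loss(l_cls, quality_loss(fw$gh$qhat, q), 0), l_cls)
})

test_that("network gradients match finite differences end to end", {
  set.seed(31)
  cfg <- train_config(epochs = 1)
  ad <- backbone_tiny(channels = c(3L, 4L), init = "he")
  gcn <- gcn_params(4, c(6L, 5L), 0)
  heads <- heads_params(5, 5, 0)
  heads$W_cls <- matrix(rnorm(25, 0, 0.3), 5, 5)
  heads$W_qa <- rnorm(5, 0, 0.3)
  imgs <- lapply(1:5, function(i) array(runif(32 * 32 * 3), c(32, 32, 3)))
  y <- c(0L, 1L, 2L, 3L, 4L)
  base <- fundusgcn:::model_forward(ad, gcn, heads, cfg, imgs, FALSE)
  q0 <- derive_quality_targets(base$gh$yhat, y)
  loss_at <- function(ad, gcn, heads) {
    fw <- fundusgcn:::model_forward(ad, gcn, heads, cfg, imgs, FALSE)
    total_loss(cross_entropy_loss(fw$gh$yhat, y),
               quality_loss(fw$gh$qhat, q0), 0.1)
  }
  bw <- fundusgcn:::gcn_head_backward(base$gh, gcn, heads, y, q0, 0.1)
  dz <- fundusgcn:::feat_norm_bwd(bw$dz, base$norm)
  gbb <- fundusgcn:::backbone_bwd(ad, dz, base$bb)
  eps <- 1e-5
  # a few coordinates from every parameter group
  for (l in 1:2) {
    for (i in sample(length(ad$params[[l]]$W), 3)) {
      adp <- ad; adp$params[[l]]$W[i] <- adp$params[[l]]$W[i] + eps
      adm <- ad; adm$params[[l]]$W[i] <- adm$params[[l]]$W[i] - eps
      fd <- (loss_at(adp, gcn, heads) - loss_at(adm, gcn, heads)) / (2 * eps)
      expect_equal(gbb[[l]]$W[i], fd, tolerance = 1e-4)
    }
    for (i in sample(length(gcn$W[[l]]), 3)) {
      gp <- gcn; gp$W[[l]][i] <- gp$W[[l]][i] + eps
      gm <- gcn; gm$W[[l]][i] <- gm$W[[l]][i] - eps
      fd <- (loss_at(ad, gp, heads) - loss_at(ad, gm, heads)) / (2 * eps)
      expect_equal(bw$gcn$W[[l]][i], fd, tolerance = 1e-4)
    }
  }
  for (i in sample(length(heads$W_cls), 4)) {
    hp <- heads; hp$W_cls[i] <- hp$W_cls[i] + eps
    hm <- heads; hm$W_cls[i] <- hm$W_cls[i] - eps
    fd <- (loss_at(ad, gcn, hp) - loss_at(ad, gcn, hm)) / (2 * eps)
    expect_equal(bw$heads$W_cls[i], fd, tolerance = 1e-4)
  }
})

test_that("training bookkeeping: log rows, early stop, determinism", {
  samples <- small_phantoms(n_per = 6, size = 32, seed = 3)
  part <- stratified_split(samples, seed = 3)
  cfg <- train_config(epochs = 1, batch_size = 10, seed = 11)
  m <- fundus_gcn(part, config = cfg)
  expect_equal(nrow(m$log), 1)
  expect_identical(names(m$log),
                   c("epoch", "train_loss", "train_cls", "train_q",
                     "val_loss", "lr"))

  # identical seeds give identical logs
  m2 <- fundus_gcn(part, config = cfg)
  expect_equal(m$log, m2$log, tolerance = 1e-6)

  # training loss decreases over the first epochs of an easy run
  cfg5 <- train_config(epochs = 5, batch_size = 10, seed = 11)
  m5 <- fundus_gcn(part, config = cfg5)
  expect_lt(m5$log$train_loss[5], m5$log$train_loss[1])
})

test_that("config invariants and scheduler floor hold", {
  expect_error(train_config(early_stop = 5, sched_patience = 7), "exceed")
  expect_error(train_config(lambda = -1), "lambda|positive|>=")
  # learning rate never drops below min_lr: simulate the scheduler rule
  cfg <- train_config(sched_patience = 1, early_stop = 2, min_lr = 1e-7,
                      sched_factor = 1e-4)
  lr <- cfg$lr
  lr <- max(lr * cfg$sched_factor, cfg$min_lr)
  lr <- max(lr * cfg$sched_factor, cfg$min_lr)
  expect_gte(lr, cfg$min_lr)
})

test_that("checkpoints round-trip and config mismatches are named", {
  samples <- small_phantoms(n_per = 4, size = 32, seed = 5)
  part <- stratified_split(samples, seed = 5)
  cfg <- train_config(epochs = 1, batch_size = 10)
  m <- fundus_gcn(part, config = cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path, config = cfg)
  expect_s3_class(m2, "fundus_gcn")
  bad <- train_config(epochs = 1, hidden = c(64L, 32L))
  expect_error(load_checkpoint(path, config = bad), "hidden")
})

test_that("config files round-trip through DCF", {
  cfg <- train_config(epochs = 3, lr = 1e-4, hidden = c(32L, 16L))
  path <- withr::local_tempfile(fileext = ".dcf")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$epochs, 3)
  expect_equal(cfg2$lr, 1e-4)
  expect_equal(cfg2$hidden, c(32L, 16L))
  expect_equal(cfg2$lambda, cfg$lambda)
})
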