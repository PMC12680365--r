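# Dataset loading, stratified splitting, class balancing and augmentation.

#' Load labelled fundus images
#'
#' Reads an APTOS-style label CSV (`id_code,diagnosis`) and the matching
#' PNG/JPEG files, resizing every image to `target_size` x `target_size`
#' with intensities in \[0,1\].  Output order matches CSV order.
#'
#' @param image_dir Directory containing one image per CSV row, named
#'   `<id_code>.png` / `.jpg` / `.jpeg`.
#' @param label_csv Path to the label CSV.
#' @param target_size Square resize target in pixels (default 224).
#' @return List of labelled samples (`id`, `image`, `grade`).
#' @export
load_labeled_images <- function(image_dir, label_csv, target_size = 224L) {
  labels <- utils::read.csv(label_csv, stringsAsFactors = FALSE)
  if (!all(c("id_code", "diagnosis") %in% names(labels))) {
    stopf("label CSV must have columns id_code,diagnosis")
  }
  bad <- !labels$diagnosis %in% 0:4
  if (any(bad)) {
    stopf("grade outside 0..4 for id '%s'", labels$id_code[which(bad)[1]])
  }
  lapply(seq_len(nrow(labels)), function(i) {
    id <- labels$id_code[i]
    img <- read_image_file(image_dir, id)
    list(id = id, image = resize_image(img, target_size),
         grade = as.integer(labels$diagnosis[i]))
  })
}

read_image_file <- function(image_dir, id) {
  exts <- c("png", "jpg", "jpeg")
  for (ext in exts) {
    path <- file.path(image_dir, paste0(id, ".", ext))
    if (file.exists(path)) {
      img <- if (ext == "png") png::readPNG(path) else jpeg::readJPEG(path)
      if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
      if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
      return(img)
    }
  }
  stopf("no image file found for id '%s' under '%s'", id, image_dir)
}

#' Stratified train/validation/test split
#'
#' Shuffles within each grade under `seed`, then allocates
#' `floor(fraction * class size)` samples per class to validation and test,
#' with the remainder going to train (keeps test deterministic and
#' non-empty for rare classes).
#'
#' @param samples List of labelled samples.
#' @param fractions Length-3 numeric `(train, val, test)` summing to 1;
#'   default `c(0.70, 0.15, 0.15)`.
#' @param seed Integer seed controlling the shuffle.
#' @return An object of class `dataset_partition` with elements `train`,
#'   `val`, `test`, `fractions`, `seed`.
#' @export
stratified_split <- function(samples, fractions = c(0.70, 0.15, 0.15),
                             seed = 42L) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8)
  grades <- vapply(samples, `[[`, integer(1), "grade")
  counts <- table(factor(grades, levels = 0:4))
  present <- counts > 0
  if (any(counts[present] < 3L)) {
    stopf("stratified split needs at least 3 samples per class; grade %s has %d",
          names(counts[present])[which(counts[present] < 3L)[1]],
          min(counts[present]))
  }
  set.seed(seed)
  idx <- list(train = integer(0), val = integer(0), test = integer(0))
  for (g in as.integer(names(counts[present]))) {
    cls <- which(grades == g)
    cls <- cls[sample.int(length(cls))]
    n_val <- floor(fractions[2] * length(cls))
    n_test <- floor(fractions[3] * length(cls))
    idx$val <- c(idx$val, cls[seq_len(n_val)])
    idx$test <- c(idx$test, cls[n_val + seq_len(n_test)])
    taken <- seq_len(n_val + n_test)
    idx$train <- c(idx$train, if (length(taken)) cls[-taken] else cls)
  }
  structure(list(train = samples[sort(idx$train)],
                 val = samples[sort(idx$val)],
                 test = samples[sort(idx$test)],
                 fractions = fractions, seed = as.integer(seed)),
            class = "dataset_partition")
}

#' @export
print.dataset_partition <- function(x, ...) {
  fmt <- function(ss) {
    g <- table(factor(vapply(ss, `[[`, integer(1), "grade"), levels = 0:4))
    sprintf("%4d  (%s)", length(ss), paste(g, collapse = "/"))
  }
  cat("Stratified dataset partition (per-grade counts 0..4)\n")
  cat("  train:", fmt(x$train), "\n  val  :", fmt(x$val),
      "\n  test :", fmt(x$test), "\n")
  invisible(x)
}

#' Augmentation policy
#'
#' Label-preserving photometric/geometric jitter used when oversampling
#' minority classes.  Defaults are mild enough to keep lesions visible:
#' rotations within ±30 degrees, flips with probability 0.5 per axis, a
#' box blur of 3–5 px applied with probability 0.5, and ±20%
#' brightness/contrast jitter.
#'
#' @param rotation Max absolute rotation in degrees.
#' @param flip_h,flip_v Flip probabilities per axis, in \[0,1\].
#' @param blur_range Integer kernel range (px) for the box blur.
#' @param blur_prob Probability of applying the blur.
#' @param brightness,contrast Jitter half-ranges (fractions).
#' @return An object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(rotation = 30, flip_h = 0.5, flip_v = 0.5,
                                blur_range = c(3L, 5L), blur_prob = 0.5,
                                brightness = 0.2, contrast = 0.2) {
  probs <- c(flip_h, flip_v, blur_prob)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0,1]")
  structure(list(rotation = rotation, flip_h = flip_h, flip_v = flip_v,
                 blur_range = as.integer(blur_range), blur_prob = blur_prob,
                 brightness = brightness, contrast = contrast),
            class = "augmentation_policy")
}

identity_policy <- function() {
  augmentation_policy(rotation = 0, flip_h = 0, flip_v = 0,
                      blur_range = c(0L, 0L), blur_prob = 0,
                      brightness = 0, contrast = 0)
}

rotate_image <- function(img, angle_deg) {
  if (angle_deg == 0) return(img)
  s <- dim(img)[1]
  th <- angle_deg * pi / 180
  c0 <- (s + 1) / 2
  ys <- matrix(seq_len(s), s, s) - c0
  xs <- t(matrix(seq_len(s), s, s)) - c0
  # inverse map with nearest-neighbour sampling; outside pixels -> background
  sy <- round(-sin(th) * xs + cos(th) * ys + c0)
  sx <- round(cos(th) * xs + sin(th) * ys + c0)
  ok <- sy >= 1 & sy <= s & sx >= 1 & sx <= s
  lin <- (pmin(pmax(sx, 1), s) - 1) * s + pmin(pmax(sy, 1), s)
  out <- img
  for (ch in 1:3) {
    plane <- img[, , ch]
    rot <- plane[lin]
    rot[!ok] <- 0.04
    out[, , ch] <- matrix(rot, s, s)
  }
  out
}

box_blur <- function(img, k) {
  if (k < 2) return(img)
  s <- dim(img)[1]
  half <- (k - 1) %/% 2
  kern <- rep(1 / k, k)
  for (ch in 1:3) {
    plane <- img[, , ch]
    # separable box filter with edge replication
    pad <- rbind(plane[rep(1, half), , drop = FALSE], plane,
                 plane[rep(s, half + (k %% 2 == 0)), , drop = FALSE])
    v <- apply(pad, 2, function(col) stats::filter(col, kern, sides = 2))
    v <- v[half + seq_len(s), , drop = FALSE]
    pad <- cbind(v[, rep(1, half), drop = FALSE], v,
                 v[, rep(s, half + (k %% 2 == 0)), drop = FALSE])
    h <- t(apply(pad, 1, function(row) stats::filter(row, kern, sides = 2)))
    plane <- h[, half + seq_len(s), drop = FALSE]
    img[, , ch] <- plane
  }
  img
}

#' Apply label-preserving augmentation to one sample
#'
#' Draws from the current RNG stream; the grade label is never changed and
#' intensities are clipped back to \[0,1\].
#'
#' @param sample A labelled sample.
#' @param policy An [augmentation_policy()].
#' @return The augmented sample (same shape, same grade).
#' @export
apply_augmentation <- function(sample, policy) {
  stopifnot(inherits(policy, "augmentation_policy"))
  img <- sample$image
  if (policy$rotation > 0) {
    img <- rotate_image(img, stats::runif(1, -policy$rotation, policy$rotation))
  }
  if (policy$flip_h > 0 && stats::runif(1) < policy$flip_h) {
    img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
  }
  if (policy$flip_v > 0 && stats::runif(1) < policy$flip_v) {
    img <- img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
  }
  if (policy$blur_prob > 0 && stats::runif(1) < policy$blur_prob) {
    ks <- seq.int(policy$blur_range[1], policy$blur_range[2])
    ks <- ks[ks %% 2 == 1]  # odd kernels keep the image centred
    if (length(ks)) img <- box_blur(img, sample(ks, 1))
  }
  if (policy$brightness > 0) {
    img <- img + stats::runif(1, -policy$brightness, policy$brightness)
  }
  if (policy$contrast > 0) {
    f <- 1 + stats::runif(1, -policy$contrast, policy$contrast)
    img <- (img - mean(img)) * f + mean(img)
  }
  sample$image <- clip01(img)
  sample
}

#' Balance a training set by oversampling with augmentation
#'
#' Duplicates and augments minority-class samples until every grade matches
#' the majority-class count `N_max`.  Originals are preserved unchanged;
#' additions carry `synthetic = TRUE` and an `origin_id` recording their
#' source sample, and ids gain an `_aug<k>` suffix so no id collides across
#' partitions.  Balancing an already balanced set returns it unchanged.
#'
#' @param train_samples List of labelled samples (training partition only).
#' @param policy An [augmentation_policy()] for the synthetic copies.
#' @param seed Integer seed; the whole operation is deterministic under it.
#' @return List of labelled samples with equal per-grade counts.
#' @export
balance_by_oversampling <- function(train_samples,
                                    policy = augmentation_policy(),
                                    seed = 42L) {
  grades <- vapply(train_samples, `[[`, integer(1), "grade")
  counts <- table(factor(grades, levels = sort(unique(grades))))
  if (any(counts == 0)) stopf("every class present must have at least one sample")
  n_max <- max(counts)
  if (all(counts == n_max)) return(train_samples)
  set.seed(seed)
  extras <- list()
  for (g in as.integer(names(counts))) {
    deficit <- n_max - counts[[as.character(g)]]
    if (deficit == 0) next
    pool <- train_samples[grades == g]
    for (j in seq_len(deficit)) {
      src <- pool[[(j - 1L) %% length(pool) + 1L]]
      aug <- apply_augmentation(src, policy)
      aug$origin_id <- src$id
      aug$synthetic <- TRUE
      aug$id <- sprintf("%s_aug%d", src$id, j)
      extras[[length(extras) + 1L]] <- aug
    }
  }
  c(train_samples, extras)
}

#' Write a partition manifest CSV
#'
#' @param partition A `dataset_partition`.
#' @param path Output CSV path; columns `id_code,diagnosis,split`.
#' @return Invisibly, the manifest data frame.
#' @export
write_partition_manifest <- function(partition, path) {
  rows <- do.call(rbind, lapply(c("train", "val", "test"), function(sp) {
    ss <- partition[[sp]]
    if (!length(ss)) return(NULL)
    data.frame(id_code = vapply(ss, `[[`, character(1), "id"),
               diagnosis = vapply(ss, `[[`, integer(1), "grade"),
               split = sp, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(rows)
}
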