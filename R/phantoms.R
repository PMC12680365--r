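# Synthetic fundus-like phantom generator.
#
# Emulates the visual grammar of colour fundus photographs at desk scale:
# a circular retina disc on a dark background, an optic-disc ellipse, dark
# random-walk vessels, and grade-dependent lesion primitives —
#   bright dots    ~ microaneurysms / small hard exudates,
#   dark blobs     ~ dot/blot haemorrhages,
#   bright patches ~ larger hard-exudate plaques,
#   vessel tufts   ~ neovascular fronds (proliferative disease only).
# Lesion counts rise with grade so that severity is decodable from pixel
# statistics, which keeps the downstream learning problem solvable on a CPU.

#' Default per-grade lesion profile
#'
#' Counts are drawn uniformly from the closed integer range `[lo, hi]` for
#' each lesion type.  The ladder is monotone in grade for dots and blobs;
#' grade 4 is distinguished from grade 3 only by neovascular tufts, so a
#' grader must use lesion shape, not just total count.
#'
#' @return Named list with one entry per grade `"0".."4"`, each holding
#'   integer ranges for `dots`, `blobs`, `patches` and `tufts`.
#' @export
default_lesion_profile <- function() {
  list(
    `0` = list(dots = c(0L, 0L),  blobs = c(0L, 0L), patches = c(0L, 0L), tufts = c(0L, 0L)),
    `1` = list(dots = c(1L, 3L),  blobs = c(0L, 0L), patches = c(0L, 0L), tufts = c(0L, 0L)),
    `2` = list(dots = c(4L, 8L),  blobs = c(1L, 3L), patches = c(1L, 2L), tufts = c(0L, 0L)),
    `3` = list(dots = c(9L, 15L), blobs = c(4L, 8L), patches = c(2L, 4L), tufts = c(0L, 0L)),
    `4` = list(dots = c(9L, 15L), blobs = c(4L, 8L), patches = c(2L, 4L), tufts = c(2L, 5L))
  )
}

#' Specification of a phantom dataset
#'
#' @param image_size Pixels per side (square images), at least 32.
#'   Default 224, the resize target used for real fundus datasets.
#' @param class_counts Named integer vector, images per grade `"0".."4"`.
#'   The default mirrors the APTOS2019 class imbalance
#'   (1805/999/370/295/193, total 3662).
#' @param lesion_profile Per-grade lesion count ranges; see
#'   [default_lesion_profile()].
#' @param background_noise_sd Additive Gaussian pixel noise, in \[0,1\]
#'   intensity units.
#' @param seed Integer RNG seed for the whole dataset.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 224L,
                         class_counts = c(`0` = 1805L, `1` = 999L, `2` = 370L,
                                          `3` = 295L, `4` = 193L),
                         lesion_profile = default_lesion_profile(),
                         background_noise_sd = 0.02,
                         seed = 42L) {
  image_size <- as.integer(image_size)
  if (is.na(image_size) || image_size < 32L) {
    stopf("image_size must be at least 32 pixels, got %s", image_size)
  }
  if (is.null(names(class_counts))) names(class_counts) <- as.character(0:4)
  class_counts <- class_counts[as.character(0:4)]
  if (anyNA(class_counts) || any(class_counts < 1) ||
      any(class_counts != round(class_counts))) {
    stopf("class_counts must contain a positive integer for each grade 0..4")
  }
  validate_lesion_profile(lesion_profile)
  structure(
    list(image_size = image_size,
         grades = 0:4,
         class_counts = as.integer(class_counts),
         lesion_profile = lesion_profile,
         background_noise_sd = background_noise_sd,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

validate_lesion_profile <- function(profile) {
  need <- as.character(0:4)
  if (!all(need %in% names(profile))) {
    stopf("lesion_profile must have entries for grades 0..4")
  }
  g0 <- profile[["0"]]
  if (any(unlist(g0) != 0)) stopf("grade-0 lesion profile must be all-zero")
  for (type in c("dots", "blobs")) {
    lo <- vapply(need, function(g) profile[[g]][[type]][1], numeric(1))
    hi <- vapply(need, function(g) profile[[g]][[type]][2], numeric(1))
    if (any(diff(lo) < 0) || any(diff(hi) < 0)) {
      stopf("lesion count ranges for %s must be non-decreasing in grade", type)
    }
  }
  invisible(TRUE)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Phantom dataset specification\n")
  cat(sprintf("  image size : %d x %d px\n", x$image_size, x$image_size))
  cat(sprintf("  per grade  : %s (total %d)\n",
              paste(x$class_counts, collapse = "/"), sum(x$class_counts)))
  cat(sprintf("  noise sd   : %g, seed %d\n", x$background_noise_sd, x$seed))
  invisible(x)
}

# --- drawing primitives -----------------------------------------------------

# Blend a Gaussian-weighted blob of `colour` into `img` at (cx, cy).
# mode "add" adds amplitude*colour; "blend" mixes toward colour.
blob_into <- function(img, cx, cy, sigma, colour, strength, mode = "blend") {
  s <- dim(img)[1]
  r <- ceiling(3 * sigma)
  ys <- max(1, floor(cy - r)):min(s, ceiling(cy + r))
  xs <- max(1, floor(cx - r)):min(s, ceiling(cx + r))
  if (!length(ys) || !length(xs)) return(img)
  d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
  w <- exp(-d2 / (2 * sigma^2)) * strength
  for (ch in 1:3) {
    patch <- img[ys, xs, ch]
    if (mode == "add") {
      img[ys, xs, ch] <- patch + w * colour[ch]
    } else {
      img[ys, xs, ch] <- patch * (1 - w) + colour[ch] * w
    }
  }
  img
}

# Random-walk curve drawn as a chain of small blended discs.
walk_into <- function(img, x, y, angle, n_steps, step, curvature,
                      colour, width, strength, inside) {
  for (i in seq_len(n_steps)) {
    angle <- angle + stats::rnorm(1, 0, curvature)
    x2 <- x + step * cos(angle)
    y2 <- y + step * sin(angle)
    if (!inside(x2, y2)) break
    x <- x2; y <- y2
    img <- blob_into(img, x, y, width, colour, strength, mode = "blend")
  }
  img
}

# --- phantom generation -----------------------------------------------------

#' Generate one synthetic fundus phantom
#'
#' Draws from the current R RNG stream, so results are deterministic given
#' the RNG state (call [set.seed()] first for reproducibility).
#'
#' @param grade Integer disease grade in 0..4.
#' @param image_size Pixels per side, at least 32.
#' @param lesion_profile Per-grade lesion ranges; see
#'   [default_lesion_profile()].
#' @param background_noise_sd Additive Gaussian noise scale.
#' @param id Optional sample identifier string.
#' @return A labelled sample: list with `id`, `image` (H x W x 3 array of
#'   intensities in \[0,1\]) and `grade`; the total number of lesion
#'   elements drawn is attached as attribute `n_lesions`.
#' @export
generate_phantom <- function(grade, image_size = 224L,
                             lesion_profile = default_lesion_profile(),
                             background_noise_sd = 0.02,
                             id = NULL) {
  if (length(grade) != 1L || is.na(grade) || !grade %in% 0:4) {
    stopf("grade must be a single integer in 0..4, got %s", toString(grade))
  }
  image_size <- as.integer(image_size)
  if (is.na(image_size) || image_size < 32L) {
    stopf("image_size must be at least 32 pixels, got %s", image_size)
  }
  validate_lesion_profile(lesion_profile)
  s <- image_size
  cx <- (s + 1) / 2
  cy <- (s + 1) / 2
  retina_r <- 0.47 * s

  # retina disc with radial shading on dark background
  yy <- matrix(seq_len(s), s, s)
  xx <- t(yy)
  d2 <- (xx - cx)^2 + (yy - cy)^2
  disc <- d2 <= retina_r^2
  shade <- 1 - 0.35 * sqrt(d2) / retina_r
  base <- c(0.82, 0.44, 0.18)  # orange-red fundus hue
  img <- array(0.04, c(s, s, 3))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[disc] <- base[ch] * shade[disc]
    img[, , ch] <- plane
  }
  inside <- function(x, y) (x - cx)^2 + (y - cy)^2 <= (0.96 * retina_r)^2

  # optic disc: bright ellipse offset to one side
  od_ang <- stats::runif(1, -0.5, 0.5) + sample(c(0, pi), 1)
  od_x <- cx + 0.62 * retina_r * cos(od_ang)
  od_y <- cy + 0.62 * retina_r * sin(od_ang)
  img <- blob_into(img, od_x, od_y, 0.07 * s, c(1.0, 0.86, 0.55), 0.9)

  # vessels: dark random walks radiating from the optic disc
  n_vessel <- sample(5:7, 1)
  for (v in seq_len(n_vessel)) {
    ang <- stats::runif(1, 0, 2 * pi)
    img <- walk_into(img, od_x, od_y, ang,
                     n_steps = round(0.9 * s), step = max(1, s / 120),
                     curvature = 0.12, colour = c(0.45, 0.12, 0.08),
                     width = max(0.8, s / 200), strength = 0.55,
                     inside = inside)
  }

  # lesion placement helper: uniform position within the retina disc
  rand_pos <- function(margin = 0.88) {
    repeat {
      px <- stats::runif(1, cx - retina_r, cx + retina_r)
      py <- stats::runif(1, cy - retina_r, cy + retina_r)
      if ((px - cx)^2 + (py - cy)^2 <= (margin * retina_r)^2) return(c(px, py))
    }
  }
  draw_count <- function(range) {
    if (range[2] <= 0) 0L else sample(seq.int(range[1], range[2]), 1)
  }

  prof <- lesion_profile[[as.character(grade)]]
  # Lesion sizes are specified at the 224-px reference scale, with a 1-px
  # floor: real fundus photographs downsampled for training still show
  # microaneurysms at >= 1 px, so lesions never vanish at small phantom
  # sizes.
  scale <- s / 224
  lsz <- function(lo, hi) max(stats::runif(1, lo, hi) * scale, 1)
  n_lesions <- 0L

  n_dots <- draw_count(prof$dots)
  for (i in seq_len(n_dots)) {
    p <- rand_pos()
    img <- blob_into(img, p[1], p[2], lsz(1.6, 3.2),
                     c(1.0, 0.95, 0.5), stats::runif(1, 0.65, 0.9))
  }
  n_blobs <- draw_count(prof$blobs)
  for (i in seq_len(n_blobs)) {
    p <- rand_pos()
    img <- blob_into(img, p[1], p[2], lsz(3.0, 6.5),
                     c(0.22, 0.04, 0.04), stats::runif(1, 0.6, 0.9))
  }
  n_patches <- draw_count(prof$patches)
  for (i in seq_len(n_patches)) {
    p <- rand_pos()
    img <- blob_into(img, p[1], p[2], lsz(5.0, 9.0),
                     c(1.0, 0.9, 0.45), stats::runif(1, 0.5, 0.75))
  }
  n_tufts <- draw_count(prof$tufts)
  for (i in seq_len(n_tufts)) {
    p <- rand_pos()
    n_branch <- sample(3:5, 1)
    for (b in seq_len(n_branch)) {
      img <- walk_into(img, p[1], p[2], stats::runif(1, 0, 2 * pi),
                       n_steps = round(0.12 * s), step = max(1, s / 160),
                       curvature = 0.85, colour = c(0.8, 0.1, 0.08),
                       width = max(0.8, s / 180), strength = 0.8,
                       inside = inside)
    }
  }
  n_lesions <- n_dots + n_blobs + n_patches + n_tufts

  if (background_noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, background_noise_sd), dim(img))
  }
  img <- clip01(img)
  out <- list(id = id %||% sprintf("phantom_g%d", grade),
              image = img, grade = as.integer(grade))
  attr(out, "n_lesions") <- n_lesions
  out
}

#' Generate a phantom dataset in memory
#'
#' @param spec A [phantom_spec()].
#' @return List of labelled samples (id, image, grade), grouped by grade in
#'   ascending order; bit-reproducible from `spec$seed`.
#' @export
phantom_samples <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  out <- vector("list", sum(spec$class_counts))
  n <- 0L
  for (g in 0:4) {
    for (i in seq_len(spec$class_counts[g + 1L])) {
      n <- n + 1L
      out[[n]] <- generate_phantom(
        g, spec$image_size, spec$lesion_profile, spec$background_noise_sd,
        id = sprintf("ph_g%d_%04d", g, i))
    }
  }
  out
}

#' Write a phantom dataset to disk
#'
#' Writes one 8-bit RGB PNG per sample plus an APTOS-style label CSV
#' (`id_code,diagnosis`, comma-separated, LF line endings) named
#' `labels.csv`, and the spec itself as `phantom_spec.dcf`.
#'
#' @param spec A [phantom_spec()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a manifest data frame with columns `id_code`,
#'   `diagnosis` and `file`.
#' @export
generate_dataset <- function(spec, out_dir) {
  stopifnot(inherits(spec, "phantom_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0) {
    stopf("output directory '%s' is not writable", out_dir)
  }
  samples <- phantom_samples(spec)
  ids <- vapply(samples, `[[`, character(1), "id")
  grades <- vapply(samples, `[[`, integer(1), "grade")
  files <- file.path(out_dir, paste0(ids, ".png"))
  for (i in seq_along(samples)) {
    png::writePNG(samples[[i]]$image, files[i])
  }
  csv <- file.path(out_dir, "labels.csv")
  con <- file(csv, open = "wb")  # binary mode forces LF endings
  writeLines(c("id_code,diagnosis", paste(ids, grades, sep = ",")),
             con, sep = "\n")
  close(con)
  write.dcf(data.frame(image_size = spec$image_size,
                       class_counts = paste(spec$class_counts, collapse = ","),
                       background_noise_sd = spec$background_noise_sd,
                       seed = spec$seed),
            file.path(out_dir, "phantom_spec.dcf"))
  invisible(data.frame(id_code = ids, diagnosis = grades, file = files,
                       stringsAsFactors = FALSE))
}
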