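# Loading, stratified splitting, balancing, augmentation.

test_that("load_labeled_images reads, resizes and orders by CSV", {
  dir <- withr::local_tempdir()
  spec <- phantom_spec(40, rep(1L, 5), seed = 3)
  generate_dataset(spec, dir)
  samples <- load_labeled_images(dir, file.path(dir, "labels.csv"),
                                 target_size = 32)
  expect_length(samples, 5)
  for (s in samples) expect_identical(dim(s$image), c(32L, 32L, 3L))
  expect_equal(vapply(samples, `[[`, integer(1), "grade"), 0:4)

  # missing image file: error names the offending id
  csv <- file.path(dir, "labels.csv")
  writeLines(c(readLines(csv), "ghost_sample,2"), csv)
  expect_error(load_labeled_images(dir, csv), "ghost_sample")
  # out-of-range grade: label error
  writeLines(c("id_code,diagnosis", "x,7"), csv)
  expect_error(load_labeled_images(dir, csv), "grade|x")
})

test_that("stratified split matches the floor/remainder allocation", {
  samples <- small_phantoms(n_per = 20, size = 40, seed = 1)
  part <- stratified_split(samples, seed = 42)
  counts <- function(ss) table(factor(vapply(ss, `[[`, integer(1), "grade"),
                                      levels = 0:4))
  expect_equal(as.vector(counts(part$train)), rep(14, 5))
  expect_equal(as.vector(counts(part$val)), rep(3, 5))
  expect_equal(as.vector(counts(part$test)), rep(3, 5))

  # disjoint by id; union is the full set
  ids <- lapply(list(part$train, part$val, part$test),
                function(ss) vapply(ss, `[[`, character(1), "id"))
  expect_equal(sum(lengths(ids)), length(samples))
  expect_false(any(duplicated(unlist(ids))))

  # determinism
  part2 <- stratified_split(samples, seed = 42)
  expect_identical(vapply(part$test, `[[`, character(1), "id"),
                   vapply(part2$test, `[[`, character(1), "id"))
})

test_that("remainder rows land in train and totals are conserved", {
  # class sizes 23, 20, 20, 20, 20 -> 103 samples
  spec <- phantom_spec(40, c(23L, 20L, 20L, 20L, 20L), seed = 9)
  samples <- phantom_samples(spec)
  part <- stratified_split(samples, seed = 1)
  # per class: floor(0.15*n) to val and test, remainder to train
  expect_equal(length(part$val), 3 + 4 * 3)
  expect_equal(length(part$test), 3 + 4 * 3)
  expect_equal(length(part$train), 103 - 2 * 15)
  g <- vapply(part$train, `[[`, integer(1), "grade")
  expect_equal(sum(g == 0), 23 - 6)          # 23 - floor(3.45)*2
})

test_that("splitting rejects classes with under 3 samples", {
  samples <- c(small_phantoms(n_per = 3, size = 40),
               list(list(id = "solo", image = array(0.5, c(40, 40, 3)),
                         grade = 2L)))
  samples <- samples[vapply(samples, `[[`, integer(1), "grade") != 0 |
                       seq_along(samples) <= 2]
  expect_error(stratified_split(samples), "at least 3")
})

test_that("augmentation preserves label, shape and range", {
  set.seed(5)
  s <- generate_phantom(2, 48)
  pol <- augmentation_policy()
  set.seed(10)
  a <- apply_augmentation(s, pol)
  expect_identical(a$grade, s$grade)
  expect_identical(dim(a$image), dim(s$image))
  expect_true(all(a$image >= 0 & a$image <= 1))

  # identity policy returns the image unchanged
  idp <- augmentation_policy(rotation = 0, flip_h = 0, flip_v = 0,
                             blur_prob = 0, brightness = 0, contrast = 0)
  expect_identical(apply_augmentation(s, idp)$image, s$image)

  # pure horizontal flip is an involution
  flip <- augmentation_policy(rotation = 0, flip_h = 1, flip_v = 0,
                              blur_prob = 0, brightness = 0, contrast = 0)
  once <- apply_augmentation(s, flip)
  expect_false(identical(once$image, s$image))
  expect_identical(apply_augmentation(once, flip)$image, s$image)
})

test_that("oversampling balances to N_max, preserves originals, is idempotent", {
  spec <- phantom_spec(40, c(4L, 1L, 2L, 3L, 4L), seed = 13)
  train <- phantom_samples(spec)
  bal <- balance_by_oversampling(train, seed = 99)
  g <- vapply(bal, `[[`, integer(1), "grade")
  expect_equal(as.vector(table(factor(g, levels = 0:4))), rep(4, 5))

  # originals are present untouched
  orig_ids <- vapply(train, `[[`, character(1), "id")
  bal_ids <- vapply(bal, `[[`, character(1), "id")
  expect_true(all(orig_ids %in% bal_ids))
  expect_identical(bal[[which(bal_ids == orig_ids[1])]]$image, train[[1]]$image)

  # copies are tagged and trace their origin; the single grade-1 image
  # spawns exactly 3 copies of itself
  copies <- bal[vapply(bal, function(s) isTRUE(s$synthetic), logical(1))]
  expect_length(copies, 20 - length(train))
  g1 <- copies[vapply(copies, `[[`, integer(1), "grade") == 1L]
  expect_length(g1, 3)
  expect_true(all(vapply(g1, `[[`, character(1), "origin_id") ==
                    train[[5]]$id))

  # balanced input is returned unchanged
  expect_identical(balance_by_oversampling(bal, seed = 99), bal)
  # determinism
  bal2 <- balance_by_oversampling(train, seed = 99)
  expect_identical(bal, bal2)
})
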