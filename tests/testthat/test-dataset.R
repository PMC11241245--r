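make_tree <- function(counts = c(3, 4, 5), classes = c("A", "DC", "F"),
                      side = 32, seed = 21) {
  spec <- fixture_spec(classes = classes, counts = counts, side = side,
                       seed = seed)
  root <- withr::local_tempdir(.local_envir = parent.frame())
  generate_dataset(spec, root, force = TRUE)
  root
}

test_that("indexing enumerates classes deterministically with counts", {
  root <- make_tree()
  idx <- index_dataset(root, "40X")
  expect_s3_class(idx, "dataset_index")
  cc <- class_counts(idx)
  expect_equal(as.character(cc$label), c("A", "DC", "F"))
  expect_equal(cc$n, c(3L, 4L, 5L))
  expect_false(is.unsorted(idx$path[idx$label == "A"]))

  # non-image files are skipped by the extension whitelist
  writeLines("not an image", file.path(root, "40X", "A", "notes.txt"))
  idx2 <- index_dataset(root, "40X")
  expect_equal(class_counts(idx2)$n, c(3L, 4L, 5L))
  expect_equal(length(list.files(file.path(root, "40X", "A"))), 4L)
})

test_that("indexing errors name the offending class", {
  root <- make_tree()
  expect_error(index_dataset(root, "40X", classes = c("A", "DC", "F", "LC")),
               "LC", class = "ecsanet_layout_error")
  dir.create(file.path(root, "40X", "ZZ"))
  expect_error(index_dataset(root, "40X"), "ZZ", class = "ecsanet_empty_class")
  expect_error(index_dataset(root, "999X"), class = "ecsanet_layout_error")
})

test_that("stratified split uses floor/floor/remainder per class", {
  root <- make_tree(counts = c(10, 10, 10))
  idx <- stratified_split(index_dataset(root, "40X"), seed = 3)
  for (cls in c("A", "DC", "F")) {
    s <- idx$split[idx$label == cls]
    expect_equal(sum(s == "train"), 7L)   # floor(0.7 * 10)
    expect_equal(sum(s == "val"), 2L)     # floor(0.2 * 10)
    expect_equal(sum(s == "test"), 1L)    # remainder
  }
})

test_that("split is deterministic in the seed and leak-free", {
  root <- make_tree(counts = c(6, 8, 9))
  idx <- index_dataset(root, "40X")
  s1 <- stratified_split(idx, seed = 42)
  s2 <- stratified_split(idx, seed = 42)
  expect_identical(s1$split, s2$split)
  s3 <- stratified_split(idx, seed = 43)
  expect_false(identical(s1$split, s3$split))
  # pairwise disjoint, union is the full index
  expect_setequal(s1$path, idx$path)
  expect_false(any(duplicated(s1$path)))
  expect_true(all(s1$split %in% c("train", "val", "test")))
})

test_that("split rejects too-small classes and bad ratios", {
  root <- make_tree(counts = c(2, 5, 5))
  idx <- index_dataset(root, "40X")
  expect_error(stratified_split(idx), class = "ecsanet_split_error")
  root2 <- make_tree(counts = c(5, 5, 5))
  expect_error(stratified_split(index_dataset(root2, "40X"),
                                ratios = c(0.5, 0.2, 0.2)),
               class = "ecsanet_invalid_input")
})

test_that("balance plan follows the three-times-max target rule", {
  plan <- plan_balance(tibble::tibble(label = c("A", "B"), n = c(2L, 3L)))
  expect_equal(plan$max_class_count, 3L)
  expect_equal(plan$oversample_target, 9L)
  expect_equal(unname(plan$augment_with_mix), c(TRUE, FALSE))
  expect_equal(plan$epoch_length, 18L)

  eq <- plan_balance(tibble::tibble(label = c("A", "B", "C"), n = c(4L, 4L, 4L)))
  expect_equal(eq$oversample_target, 12L)
  expect_false(any(eq$augment_with_mix))

  expect_error(plan_balance(tibble::tibble(label = "A", n = 0L)),
               class = "ecsanet_invalid_input")
})

test_that("the stream cycles images by position modulo class size", {
  root <- make_tree(counts = c(5, 6, 7))
  idx <- stratified_split(index_dataset(root, "40X"), seed = 1)
  plan <- plan_balance(idx)          # train counts 3, 4, 4
  cfg <- stream_config(side = 32L, stain_target = NULL, augment = FALSE)
  n_a <- plan$train_counts[["A"]]
  it <- get_item(plan, "A", n_a + 2L, cfg)   # position wraps to index 2
  expect_equal(it$path, plan$files[["A"]][3L])
  expect_equal(it$label, "A")
  expect_equal(dim(it$x), c(32L, 32L, 3L))
  expect_error(get_item(plan, "A", plan$oversample_target, cfg),
               class = "ecsanet_index_error")
  expect_error(get_item(plan, "Q", 0, cfg), class = "ecsanet_invalid_input")
})

test_that("one balanced epoch yields exactly target items per class", {
  plan <- plan_balance(tibble::tibble(label = c("A", "B", "C"),
                                      n = c(2L, 3L, 5L)))
  sched <- epoch_schedule(plan)
  expect_equal(nrow(sched), plan$epoch_length)
  tab <- table(sched$class)
  expect_true(all(tab == plan$oversample_target))
  # shuffled schedule is a permutation of the same multiset
  sh <- epoch_schedule(plan, seed = 9)
  expect_setequal(paste(sh$class, sh$i), paste(sched$class, sched$i))
})

test_that("evaluation items are preprocessed and standardized only", {
  root <- make_tree(counts = c(5, 5, 5))
  idx <- stratified_split(index_dataset(root, "40X"), seed = 2)
  cfg <- stream_config(side = 32L, stain_target = NULL, augment = TRUE)
  p <- idx$path[idx$split == "val"][1]
  x <- eval_item(p, cfg)
  manual <- standardize(preprocess_image(read_image_rgb(p), 32L) / 255,
                        cfg$stats)
  expect_identical(x, manual)          # augment flag never touches eval items
})

test_that("preprocessing resizes the shorter side then center-crops", {
  img <- tiny_rgb(4, h = 70, w = 46)
  out <- preprocess_image(img, side = 32L)
  expect_equal(dim(out), c(32L, 32L, 3L))
  same <- preprocess_image(tiny_rgb(5, 32, 32), side = 32L)
  expect_equal(dim(same), c(32L, 32L, 3L))
  expect_equal(same, tiny_rgb(5, 32, 32))  # no-op without stain target
  # stain normalization hook
  tgt <- default_stain_target()
  normed <- preprocess_image(he_image(9, 40), side = 32L, stain_target = tgt)
  st <- compute_lab_stats(rgb_to_lab(normed))
  expect_lt(max(abs(st$mean - tgt$stats$mean)), 1.0)
})

test_that("standardization matches the per-pixel definition", {
  st <- channel_stats(c(0, 0, 0), c(1, 1, 1))
  x <- tiny_rgb(6, 4, 4)
  expect_identical(standardize(x, st), x)

  mu <- c(0.3, 0.5, 0.7)
  stats <- channel_stats(mu, c(0.1, 0.2, 0.3))
  const <- array(rep(mu, each = 16), dim = c(4, 4, 3))
  expect_equal(max(abs(standardize(const, stats))), 0)

  x <- withr::with_seed(7, array(runif(48), dim = c(4, 4, 3)))
  got <- standardize(x, stats)
  want <- array(0, dim = dim(x))
  for (i in 1:4) for (j in 1:4) for (c in 1:3)
    want[i, j, c] <- (x[i, j, c] - stats$mean[c]) / stats$std[c]
  expect_equal(got, want, tolerance = 1e-12)

  expect_error(standardize(x, channel_stats(0, 1)), class = "ecsanet_invalid_input")
  expect_error(channel_stats(c(0, 0, 0), c(1, 0, 1)), class = "ecsanet_invalid_input")
})
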