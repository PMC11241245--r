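test_that("cross-entropy matches closed forms and a per-element loop", {
  p <- matrix(0, 4, 3); p[cbind(1:4, c(1, 2, 3, 1))] <- 1
  y <- p
  expect_equal(cross_entropy(p, y), 0)

  u <- matrix(1 / 8, 5, 8)
  y8 <- matrix(0, 5, 8); y8[cbind(1:5, c(1, 3, 5, 7, 8))] <- 1
  expect_equal(cross_entropy(u, y8), log(8), tolerance = 1e-12)

  pr <- withr::with_seed(1, matrix(runif(40), 5, 8))
  pr <- pr / rowSums(pr)
  want <- 0
  for (o in 1:5) for (c in 1:8) want <- want - y8[o, c] * log(pr[o, c])
  expect_equal(cross_entropy(pr, y8), want / 5, tolerance = 1e-12)

  bad <- y8; bad[1, ] <- 0.5
  expect_error(cross_entropy(pr, bad), class = "ecsanet_invalid_input")
})

test_that("the SGD update follows the stated rule", {
  st <- optimizer_state(c(1, 2), lr = 0.1, weight_decay = 0)
  expect_equal(sgd_step(st, c(0, 0))$weights, c(1, 2))

  st2 <- optimizer_state(1, lr = 0.001, weight_decay = 0)
  expect_equal(sgd_step(st2, 0.5)$weights, 0.9995)

  # quadratic loss Q(w) = w^2 / 2, gradient w: w_k = w0 (1 - lr)^k
  st3 <- optimizer_state(2, lr = 0.1, weight_decay = 0)
  for (i in 1:10) st3 <- sgd_step(st3, st3$weights)
  expect_equal(st3$weights, 2 * (1 - 0.1)^10, tolerance = 1e-12)

  # decoupled weight decay adds decay * w to the gradient
  st4 <- optimizer_state(1, lr = 0.1, weight_decay = 0.01)
  expect_equal(sgd_step(st4, 0)$weights, 1 - 0.1 * 0.01)

  expect_error(sgd_step(st, c(NaN, 0)), class = "ecsanet_nonfinite_gradient")
})

test_that("plateau scheduling cuts the learning rate after patience epochs", {
  cfg <- training_config(lr = 1e-3, scheduler_patience = 2)
  st <- ecsanet:::new_progress_state(cfg)
  # strictly decreasing losses: never a cut
  for (l in c(1, 0.9, 0.8, 0.7)) st <- reduce_lr_on_plateau(st, l)
  expect_equal(st$lr, 1e-3)
  # flat losses: cut at the 3rd flat epoch, then again two epochs later
  st <- ecsanet:::new_progress_state(cfg)
  st <- reduce_lr_on_plateau(st, 1)     # first value improves on Inf
  st <- reduce_lr_on_plateau(st, 1)
  expect_equal(st$lr, 1e-3)
  st <- reduce_lr_on_plateau(st, 1)
  expect_equal(st$lr, 1e-4)
  st <- reduce_lr_on_plateau(st, 1)
  st <- reduce_lr_on_plateau(st, 1)
  expect_equal(st$lr, 1e-5)             # second consecutive plateau
})

test_that("early stopping counts epochs without improvement", {
  cfg <- training_config(early_stop_patience = 25)
  st <- ecsanet:::new_progress_state(cfg)
  st <- reduce_lr_on_plateau(st, 1)
  for (i in 1:24) st <- reduce_lr_on_plateau(st, 1)
  expect_false(early_stopping(st))
  st <- reduce_lr_on_plateau(st, 1)     # 25th non-improving epoch
  expect_true(early_stopping(st))
  # improvement resets the counter
  st2 <- ecsanet:::new_progress_state(cfg)
  st2 <- reduce_lr_on_plateau(st2, 1)
  for (i in 1:24) st2 <- reduce_lr_on_plateau(st2, 1)
  st2 <- reduce_lr_on_plateau(st2, 0.5)
  expect_false(early_stopping(st2))
  expect_equal(st2$epochs_since_improvement, 0L)
})

rand_stream <- function(n_per_class, side, seed, sep = 3) {
  # two blobs in feature space: class "a" negative, class "b" positive offset
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    x <- array(rnorm(side * side * 3 * n, 0, 0.3), dim = c(side, side, 3, n))
    y <- rep(c("a", "b"), each = n_per_class)
    x[, , 1, y == "b"] <- x[, , 1, y == "b"] + sep
    x[, , 1, y == "a"] <- x[, , 1, y == "a"] - sep
    tensor_stream(x, y)
  })
}

test_that("training reduces loss, improves accuracy, and is seed-deterministic", {
  cfg <- architecture_config(num_classes = 2, width_scale = 0.25,
                             depth_scale = 0.2, input_side = 32L, dropout = 0)
  m <- assemble_ecsanet(cfg, seed = 11, class_labels = c("a", "b"))
  tr <- rand_stream(12, 32, 101)
  val <- rand_stream(4, 32, 102)
  tc <- training_config(lr = 0.01, momentum = 0.9, batch_size = 8,
                        max_epochs = 3, scheduler_patience = 10, seed = 9)
  run <- train_ecsanet(m, list(train = tr, val = val), tc)
  h <- run$history
  expect_equal(nrow(h), 3L)
  expect_gt(h$train_acc[3], h$train_acc[1])
  expect_lt(h$train_loss[3], h$train_loss[1])
  expect_true(all(diff(h$lr) <= 0))          # lr never increases

  run2 <- train_ecsanet(m, list(train = tr, val = val), tc)
  expect_identical(run$history$train_loss[1], run2$history$train_loss[1])

  expect_s3_class(tidy(run), "tbl_df")
  g <- glance(run)
  expect_equal(g$epochs, 3L)
})

test_that("training history exposes early stopping through its length", {
  # a run whose validation loss can never improve more than once
  cfg <- architecture_config(num_classes = 2, width_scale = 0.25,
                             depth_scale = 0.2, input_side = 32L, dropout = 0)
  m <- assemble_ecsanet(cfg, seed = 12, class_labels = c("a", "b"))
  tr <- rand_stream(4, 32, 103, sep = 0)     # no signal
  val <- rand_stream(2, 32, 104, sep = 0)
  tc <- training_config(lr = 1e-5, momentum = 0, batch_size = 8,
                        max_epochs = 6, early_stop_patience = 2,
                        scheduler_patience = 10, seed = 13)
  run <- train_ecsanet(m, list(train = tr, val = val), tc)
  expect_lte(nrow(run$history), 6L)
  if (run$stopped_early) expect_lt(nrow(run$history), 6L)
})
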