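rand_map <- function(C, H, W, seed) {
  withr::with_seed(seed, array(rnorm(C * H * W), dim = c(C, H, W)))
}

test_that("attention maps have the contracted shapes and open-interval range", {
  mod <- cbam_module(6, reduction_ratio = 2, seed = 1)
  f <- rand_map(6, 5, 4, 2)
  mc <- channel_attention(f, mod)
  ms <- spatial_attention(f, mod)
  expect_equal(dim(mc), c(6L, 1L, 1L))
  expect_equal(dim(ms), c(1L, 5L, 4L))
  expect_true(all(mc > 0 & mc < 1))
  expect_true(all(ms > 0 & ms < 1))
  out <- cbam(f, mod)
  expect_equal(dim(out), dim(f))
  expect_error(cbam_module(6, spatial_kernel = 4), class = "ecsanet_config_error")
  f[1, 1, 1] <- NaN
  expect_error(channel_attention(f, mod), class = "ecsanet_invalid_input")
})

test_that("spatially constant maps degenerate to a single MLP evaluation", {
  mod <- cbam_module(3, reduction_ratio = 1, seed = 3)
  v <- c(0.4, -1.2, 2.0)
  f <- array(rep(v, 6), dim = c(3, 2, 3))       # every channel constant
  mc <- channel_attention(f, mod)
  p <- mod$params
  mlp <- function(u) as.numeric(p$w2 %*% pmax(p$w1 %*% u + p$b1, 0) + p$b2)
  expect_equal(as.numeric(mc), 1 / (1 + exp(-2 * mlp(matrix(v)))),
               tolerance = 1e-12)
})

test_that("hand-set weights reproduce hand-computed attention values", {
  # channel: C = 2, H = W = 1, explicit MLP weights
  mod <- cbam_module(2, reduction_ratio = 2, spatial_kernel = 3,
                     weights = list(w1 = matrix(c(1, -1), 1, 2), b1 = 0.5,
                                    w2 = matrix(c(2, -1), 2, 1), b2 = c(0, 0.25)))
  f <- array(c(0.6, -0.2), dim = c(2, 1, 1))
  mc <- channel_attention(f, mod)
  h <- max(1 * 0.6 + (-1) * (-0.2) + 0.5, 0)    # avg == max here
  # both MLP branches coincide, so the pre-sigmoid sum is 2 * mlp(v)
  expect_equal(as.numeric(mc), 1 / (1 + exp(-2 * c(2 * h, -1 * h + 0.25))),
               tolerance = 1e-12)

  # spatial: 1 x 2 x 2 input, hand-set 3x3 conv
  w_sp <- array(0, dim = c(3, 3, 2, 1))
  w_sp[2, 2, 1, 1] <- 1; w_sp[2, 2, 2, 1] <- -0.5
  mod2 <- cbam_module(1, reduction_ratio = 1, spatial_kernel = 3,
                      weights = list(w_sp = w_sp, b_sp = 0.1))
  f2 <- array(c(1, 2, 3, 4), dim = c(1, 2, 2))
  ms <- spatial_attention(f2, mod2)
  # avg plane == max plane == f2, so z = f2 * (1 - 0.5) + 0.1
  expect_equal(as.numeric(ms), as.numeric(1 / (1 + exp(-(f2 * 0.5 + 0.1)))),
               tolerance = 1e-12)

  # channel-constant input: both pooled planes coincide
  fc <- array(rep(c(1, 2, 3, 4), each = 2), dim = c(2, 2, 2))
  mod3 <- cbam_module(2, reduction_ratio = 1, spatial_kernel = 3, seed = 5)
  expect_equal(apply(fc, c(2, 3), mean), apply(fc, c(2, 3), max))
})

test_that("the full module matches a scalar brute-force unroll", {
  for (case in list(c(2, 2, 2, 11), c(3, 4, 4, 12), c(5, 3, 4, 13))) {
    mod <- cbam_module(case[1], reduction_ratio = 2, spatial_kernel = 3,
                       seed = case[4])
    f <- rand_map(case[1], case[2], case[3], case[4] + 100)
    got <- cbam(f, mod)
    want <- brute_cbam_oracle(f, mod)
    expect_equal(as.numeric(attr(got, "attention")$mc), want$mc, tolerance = 1e-10)
    expect_equal(array(attr(got, "attention")$ms, dim = dim(f)[2:3]), want$ms,
                 tolerance = 1e-10)
    expect_equal(unclass(got), want$out, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("saturated gates reduce to the identity; gates attenuate", {
  mod <- cbam_module(3, reduction_ratio = 1, spatial_kernel = 3, seed = 7)
  mod$params$b2 <- rep(50, 3)     # saturate channel gate
  mod$params$b_sp <- 50           # saturate spatial gate
  f <- abs(rand_map(3, 4, 4, 8))
  out <- cbam(f, mod)
  expect_lt(max(abs(out - f)), 1e-3)

  mod2 <- cbam_module(3, reduction_ratio = 1, spatial_kernel = 3, seed = 9)
  out2 <- cbam(f, mod2)
  expect_true(all(abs(out2) <= abs(f)))   # both gates lie in (0, 1)
})

test_that("channel-then-spatial ordering differs from the swapped order", {
  mod <- cbam_module(4, reduction_ratio = 2, spatial_kernel = 3, seed = 10)
  f <- rand_map(4, 3, 3, 20)
  out <- cbam(f, mod)
  # swapped: spatial attention first, then channel attention
  ms <- spatial_attention(f, mod)
  f1 <- sweep(f, c(2, 3), array(ms, dim = dim(f)[2:3]), "*")
  mc <- channel_attention(f1, mod)
  swapped <- f1 * as.numeric(mc)
  expect_gt(max(abs(unclass(out) - swapped)), 1e-6)
})

test_that("the in-network attention layer agrees with the functional module", {
  mod <- cbam_module(4, reduction_ratio = 2, spatial_kernel = 3, seed = 21)
  f <- rand_map(4, 5, 6, 22)
  x <- array(aperm(f, c(2, 3, 1)), dim = c(5, 6, 4, 1))
  r <- ecsanet:::nn_forward(mod, x, training = FALSE)
  got <- aperm(array(r$y, dim = c(5, 6, 4)), c(3, 1, 2))
  expect_equal(got, unclass(cbam(f, mod)), tolerance = 1e-12, ignore_attr = TRUE)
})
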