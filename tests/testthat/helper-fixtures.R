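# Shared fixtures, built in code.

tiny_rgb <- function(seed = 1, h = 16, w = 16) {
  withr::with_seed(seed, array(as.double(sample(0:255, h * w * 3, TRUE)),
                               dim = c(h, w, 3)))
}

he_image <- function(seed = 2, side = 48, class = "A") {
  generate_image(fixture_spec(counts = 1, side = side), class, seed = seed)
}

# contrast-compressed variant whose Reinhard transfer stays inside the sRGB
# gamut (the idempotence contract holds up to quantization only when no
# pixel is gamut-clipped)
soft_image <- function(seed = 2, side = 48) {
  img <- he_image(seed, side)
  array(round(127.5 + (img - 127.5) * 0.55), dim = dim(img))
}

soft_target <- function() fit_stain_target(soft_image(733), "soft reference")

# three-class spec with widely separated nucleus densities and per-class
# color casts: linearly separable by color and by texture
separable_spec <- function(counts = 60, side = 64, seed = 11) {
  fixture_spec(
    classes = c("C1", "C2", "C3"), counts = counts, side = side, seed = seed,
    texture_params = tibble::tibble(
      class = c("C1", "C2", "C3"),
      density_min = c(3, 20, 45), density_max = c(6, 24, 50),
      radius_min = 2, radius_max = 4, ecc_min = 0.1, ecc_max = 0.6,
      cast_r = c(25, 0, -20), cast_g = c(0, 0, 0), cast_b = c(-20, 0, 25)))
}

local_fixture_tree <- function(spec, env = parent.frame()) {
  root <- withr::local_tempdir(.local_envir = env)
  generate_dataset(spec, root, force = TRUE)
  root
}

# brute-force population stats of a Lab plane stack (two-pass loop)
brute_lab_stats <- function(lab) {
  d <- dim(lab)
  out <- list(mean = numeric(3), std = numeric(3))
  for (c in 1:3) {
    s <- 0; n <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) { s <- s + lab[i, j, c]; n <- n + 1 }
    m <- s / n
    ss <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) ss <- ss + (lab[i, j, c] - m)^2
    out$mean[c] <- m; out$std[c] <- sqrt(ss / n)
  }
  out
}

# scalar brute-force unroll of the CBAM computation (independent oracle)
brute_cbam_oracle <- function(f, mod) {
  C <- dim(f)[1]; H <- dim(f)[2]; W <- dim(f)[3]
  p <- mod$params
  mlp <- function(v) {
    h <- pmax(p$w1 %*% matrix(v, ncol = 1) + p$b1, 0)
    as.numeric(p$w2 %*% h + p$b2)
  }
  avg <- numeric(C); mx <- numeric(C)
  for (c in 1:C) { avg[c] <- mean(f[c, , ]); mx[c] <- max(f[c, , ]) }
  mc <- 1 / (1 + exp(-(mlp(avg) + mlp(mx))))
  f1 <- array(0, dim = dim(f))
  for (c in 1:C) f1[c, , ] <- f[c, , ] * mc[c]
  sa <- apply(f1, c(2, 3), mean); sm <- apply(f1, c(2, 3), max)
  k <- mod$k_sp; pad <- k %/% 2
  z <- matrix(mod$params$b_sp, H, W)
  for (i in 1:H) for (j in 1:W) for (ki in 1:k) for (kj in 1:k) {
    ii <- i + ki - 1 - pad; jj <- j + kj - 1 - pad
    if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
      z[i, j] <- z[i, j] + sa[ii, jj] * p$w_sp[ki, kj, 1, 1] +
        sm[ii, jj] * p$w_sp[ki, kj, 2, 1]
  }
  ms <- 1 / (1 + exp(-z))
  f2 <- array(0, dim = dim(f))
  for (c in 1:C) f2[c, , ] <- f1[c, , ] * ms
  list(mc = mc, ms = ms, out = f2)
}
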