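# Convolutional block attention: sequential channel attention (which feature
# channels matter) then spatial attention (where they matter), each producing
# a sigmoid gate that multiplies the feature map element-wise:
#   F'  = Mc(F)  (x) F
#   F'' = Ms(F') (x) F'
# The public surface operates on single C x H x W feature maps; the same
# parameters drive the in-network layer used by the assembled model.

assert_feature_map <- function(f) {
  if (!is.array(f) || length(dim(f)) != 3L)
    abort("Feature map must be a C x H x W array.", class = "ecsanet_invalid_input")
  if (!all(is.finite(f)))
    abort("Feature map contains non-finite values.", class = "ecsanet_invalid_input")
  invisible(f)
}

#' Create a CBAM attention module
#'
#' Channel attention uses a shared two-layer bottleneck MLP
#' (`C -> C/r -> C`, ReLU in the bottleneck) applied to both the
#' spatially average-pooled and max-pooled channel descriptors; spatial
#' attention applies a `k x k` convolution (default 7, odd required) to the
#' channel-wise average/max planes. Both gates are sigmoids.
#'
#' @param channels Number of input channels C.
#' @param reduction_ratio Bottleneck reduction ratio r (default 16; the
#'   hidden size is clamped to at least 1).
#' @param spatial_kernel Odd spatial kernel size (default 7).
#' @param seed Optional seed for weight initialization.
#' @param weights Optional named list overriding parameters
#'   (`w1`, `b1`, `w2`, `b2`, `w_sp`, `b_sp`).
#' @return A `cbam_module` object.
#' @export
cbam_module <- function(channels, reduction_ratio = 16L, spatial_kernel = 7L,
                        seed = NULL, weights = NULL) {
  build <- function() ly_cbam(channels, reduction_ratio, spatial_kernel)
  layer <- if (is.null(seed)) build() else withr::with_seed(as.integer(seed), build())
  if (!is.null(weights))
    for (nm in names(weights)) layer$params[[nm]] <- weights[[nm]]
  class(layer) <- c("cbam_module", "list")
  layer
}

to_hwcn <- function(f) array(aperm(f, c(2, 3, 1)), dim = c(dim(f)[2], dim(f)[3], dim(f)[1], 1))

#' Channel attention map
#'
#' `Mc = sigmoid(MLP(avgpool(F)) + MLP(maxpool(F)))`, pooling over the
#' spatial dimensions.
#'
#' @param f A `C x H x W` feature map.
#' @param module A [cbam_module()] with matching channel count.
#' @return The channel gate as a `C x 1 x 1` array, entries strictly in (0, 1).
#' @export
channel_attention <- function(f, module) {
  assert_feature_map(f)
  C <- dim(f)[1]
  pa <- matrix(apply(f, 1, mean), ncol = 1)
  pm <- matrix(apply(f, 1, max), ncol = 1)
  p <- module$params
  z <- (p$w2 %*% pmax(p$w1 %*% pa + p$b1, 0) + p$b2) +
       (p$w2 %*% pmax(p$w1 %*% pm + p$b1, 0) + p$b2)
  array(sigmoid_(z), dim = c(C, 1, 1))
}

#' Spatial attention map
#'
#' `Ms = sigmoid(conv_kxk(concat(channel-avg(F'), channel-max(F'))))` with
#' same-padding, so spatial dimensions are preserved.
#'
#' @param f The channel-refined `C x H x W` feature map F'.
#' @param module A [cbam_module()].
#' @return The spatial gate as a `1 x H x W` array, entries strictly in (0, 1).
#' @export
spatial_attention <- function(f, module) {
  assert_feature_map(f)
  d <- dim(f); H <- d[2]; W <- d[3]
  stack2 <- array(0, dim = c(H, W, 2, 1))
  stack2[, , 1, 1] <- apply(f, c(2, 3), mean)
  stack2[, , 2, 1] <- apply(f, c(2, 3), max)
  z <- conv2d_fwd(stack2, module$params$w_sp, 1L, module$k_sp %/% 2L, 1L) +
    module$params$b_sp
  array(aperm(array(z, dim = c(H, W, 1)), c(3, 1, 2)), dim = c(1, H, W)) |>
    sigmoid_()
}

#' Apply CBAM to a feature map
#'
#' Channel attention strictly first, then spatial attention:
#' `F' = Mc (x) F`, `F'' = Ms(F') (x) F'`. Shape is preserved; the two
#' attention maps are attached as the `"attention"` attribute.
#'
#' @param f A `C x H x W` feature map.
#' @param module A [cbam_module()].
#' @return The refined `C x H x W` map with attribute `attention`
#'   (list `mc`, `ms`).
#' @export
cbam <- function(f, module) {
  assert_feature_map(f)
  mc <- channel_attention(f, module)
  f1 <- f * as.numeric(mc)                # (C,H,W) * C broadcasts over H, W
  ms <- spatial_attention(f1, module)
  f2 <- sweep(f1, c(2, 3), array(ms, dim = dim(f)[2:3]), "*")
  structure(f2, attention = list(mc = mc, ms = ms))
}
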