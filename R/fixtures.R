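# Synthetic BreakHis-layout fixture generation.
#
# Images emulate H&E-stained tissue at a cartoon level: an eosin-pink stroma
# background carrying hematoxylin-purple nucleus-like elliptical blobs whose
# density / size / eccentricity distributions differ by class, so classes are
# statistically separable by texture and a simple density threshold. A global
# color cast can be applied to exercise stain normalization.

#' Tumor class vocabulary and magnifications of the BreakHis layout
#'
#' Benign: adenosis (A), fibroadenoma (F), phyllodes tumor (PT), tubular
#' adenoma (TA); malignant: ductal (DC), lobular (LC), mucinous (MC),
#' papillary (PC) carcinoma.
#' @export
breakhis_classes <- c("A", "F", "PT", "TA", "DC", "LC", "MC", "PC")

#' @rdname breakhis_classes
#' @export
breakhis_magnifications <- c("40X", "100X", "200X", "400X")

default_texture_params <- function(classes, hardness = 0) {
  k <- length(classes)
  # disjoint, ordered density bands; hardness in [0,1] shrinks the gaps
  lo <- seq(4, 4 + 5 * (k - 1), by = 5)
  hi <- lo + 3 + hardness * 1.9
  mid <- (lo + hi) / 2
  lo <- mid + (lo - mid) * (1 - 0.0) - hardness * (mid - lo) * 0  # keep lo
  tibble::tibble(
    class = classes,
    density_min = lo + hardness * 1.5,
    density_max = hi + hardness * 1.5,
    radius_min = 2 + 0.2 * seq_len(k) %% 3,
    radius_max = 4 + 0.3 * seq_len(k) %% 3,
    ecc_min = 0.1, ecc_max = 0.7
  )
}

#' Specify a synthetic fixture dataset
#'
#' The default per-class counts reproduce the published 40x class distribution
#' of the BreakHis benchmark (total 1995 images) so the balancing pipeline can
#' be exercised at the real imbalance ratios; tests typically pass much
#' smaller counts.
#'
#' @param classes Ordered class labels.
#' @param counts Per-class image counts (recycled if length 1).
#' @param side Image side length in pixels (>= 32; default 96, divisible by 32
#'   so the network's stride-32 spatial contract holds).
#' @param magnification Magnification folder name.
#' @param palette Base colors: list with `stroma` and `nucleus` RGB 3-vectors
#'   (0-255), an H&E-like pink/purple pair by default.
#' @param texture_params Per-class tibble of blob density/size/eccentricity
#'   ranges; defaults to disjoint density bands per class.
#' @param hardness In `[0, 1]`: narrows inter-class texture gaps to make the
#'   task harder (exercises confusion-matrix paths).
#' @param cast Global RGB color-shift 3-vector added to every image.
#' @param seed Integer seed; a fixed seed yields a byte-identical dataset.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(classes = breakhis_classes,
                         counts = c(114, 253, 109, 149, 864, 156, 205, 145),
                         side = 96L,
                         magnification = "40X",
                         palette = list(stroma = c(231, 180, 202),
                                        nucleus = c(112, 66, 148)),
                         texture_params = NULL,
                         hardness = 0,
                         cast = c(0, 0, 0),
                         seed = 2024L) {
  if (side < 32L) abort("`side` must be >= 32.", class = "ecsanet_invalid_input")
  counts <- rep_len(as.integer(counts), length(classes))
  if (any(counts < 1L)) abort("counts must be positive.", class = "ecsanet_invalid_input")
  if (is.null(texture_params))
    texture_params <- default_texture_params(classes, hardness)
  structure(list(classes = classes,
                 counts = stats::setNames(counts, classes),
                 side = as.integer(side), magnification = magnification,
                 palette = palette, texture_params = texture_params,
                 hardness = hardness, cast = cast, seed = as.integer(seed)),
            class = "fixture_spec")
}

# deterministic per-image seed below 2^31
image_seed <- function(seed, class_idx, i) {
  (as.double(seed) * 7919 + class_idx * 104729 + i * 31) %% 2147483647
}

#' Generate one synthetic tissue image
#'
#' @param spec A [fixture_spec()].
#' @param class Class label to draw texture parameters from.
#' @param seed Integer seed for this image.
#' @return `H x W x 3` RGB array in `[0, 255]` (integer-valued).
#' @export
generate_image <- function(spec, class, seed = spec$seed) {
  if (!class %in% spec$classes)
    abort(sprintf("Unknown class '%s'.", class), class = "ecsanet_invalid_input")
  tp <- spec$texture_params[spec$texture_params$class == class, ]
  side <- spec$side
  withr::with_seed(as.integer(seed %% 2147483647), {
    img <- array(0, dim = c(side, side, 3))
    # stroma background with mild texture noise and a soft illumination gradient
    grad <- outer(seq(-1, 1, length.out = side), seq(-1, 1, length.out = side),
                  function(a, b) 6 * a + 4 * b)
    for (c in 1:3)
      img[, , c] <- spec$palette$stroma[c] + grad +
        matrix(stats::rnorm(side^2, 0, 5), side, side)
    # nucleus-like elliptical blobs; density band scaled to the 96px reference area
    n_ref <- stats::runif(1, tp$density_min, tp$density_max)
    n_blobs <- max(1L, round(n_ref * (side / 96)^2))
    ys <- matrix(rep(seq_len(side), side), side, side)
    xs <- t(ys)
    for (b in seq_len(n_blobs)) {
      cy <- stats::runif(1, 1, side); cx <- stats::runif(1, 1, side)
      r <- stats::runif(1, tp$radius_min, tp$radius_max) * side / 96
      ecc <- stats::runif(1, tp$ecc_min, tp$ecc_max)
      th <- stats::runif(1, 0, pi)
      a_ax <- r / sqrt(1 - ecc^2); b_ax <- r * sqrt(sqrt(1 - ecc^2))
      u <- (ys - cy) * cos(th) + (xs - cx) * sin(th)
      v <- -(ys - cy) * sin(th) + (xs - cx) * cos(th)
      d2 <- (u / a_ax)^2 + (v / b_ax)^2
      alpha <- pmax(0, 1 - d2)        # soft-edged ellipse
      jit <- stats::rnorm(3, 0, 8)
      for (c in 1:3)
        img[, , c] <- img[, , c] * (1 - alpha) +
          alpha * (spec$palette$nucleus[c] + jit[c])
    }
    # optional per-class color cast (columns cast_r/g/b of texture_params)
    ccast <- c(tp[["cast_r"]] %||% 0, tp[["cast_g"]] %||% 0, tp[["cast_b"]] %||% 0)
    img <- sweep(img, 3L, as.numeric(spec$cast) + ccast, "+")
    array(round(pmin(pmax(img, 0), 255)), dim = dim(img))
  })
}

#' Apply a global stain-like color cast
#'
#' Channel-wise affine shift `scale * x + offset`, clipped to `[0, 255]`;
#' used to test that [stain_normalize()] removes dataset-level casts.
#'
#' @param image `H x W x 3` RGB array.
#' @param cast Numeric 3-vector of per-channel offsets.
#' @param scale Numeric 3-vector (or scalar) of per-channel scales.
#' @return Shifted RGB array, clipped and rounded to 8-bit levels.
#' @export
apply_stain_shift <- function(image, cast, scale = 1) {
  assert_rgb(image)
  scale <- rep_len(scale, 3L)
  out <- image
  for (c in 1:3) out[, , c] <- out[, , c] * scale[c] + cast[c]
  array(round(pmin(pmax(out, 0), 255)), dim = dim(image))
}

#' Generate a BreakHis-layout fixture dataset on disk
#'
#' Writes `root/<magnification>/<class>/<class>_<i>.png` for every class, a
#' layout consumable by [index_dataset()], plus a `manifest.json` recording
#' every generation parameter.
#'
#' @param spec A [fixture_spec()].
#' @param root Output directory (created; must be empty unless `force`).
#' @param force Overwrite into a non-empty root.
#' @return Invisibly, the manifest list.
#' @export
generate_dataset <- function(spec, root, force = FALSE) {
  stopifnot(inherits(spec, "fixture_spec"))
  mag_dir <- file.path(root, spec$magnification)
  if (dir.exists(mag_dir) && length(list.files(mag_dir)) > 0 && !force)
    abort(sprintf("'%s' is not empty; use force = TRUE to overwrite.", mag_dir),
          class = "ecsanet_refuse_overwrite")
  for (ci in seq_along(spec$classes)) {
    cls <- spec$classes[ci]
    cdir <- file.path(mag_dir, cls)
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(spec$counts[[cls]])) {
      img <- generate_image(spec, cls, seed = image_seed(spec$seed, ci, i))
      write_image_rgb(img, file.path(cdir, sprintf("%s_%04d.png", cls, i)))
    }
  }
  manifest <- list(classes = spec$classes, counts = as.list(spec$counts),
                   side = spec$side, magnification = spec$magnification,
                   palette = spec$palette, hardness = spec$hardness,
                   cast = as.numeric(spec$cast), seed = spec$seed,
                   texture_params = spec$texture_params)
  jsonlite::write_json(manifest, file.path(root, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}

#' Deterministic synthetic reference image for stain normalization
#'
#' A seed-fixed H&E-like synthetic image (not real tissue) whose Lab
#' statistics serve as the package's default stain-normalization reference.
#' The fitted target is also shipped as `inst/extdata/synthetic_stain_target.json`.
#'
#' @param side Side length in pixels.
#' @return `H x W x 3` RGB array in `[0, 255]`.
#' @export
reference_stain_image <- function(side = 96L) {
  spec <- fixture_spec(classes = "REF", counts = 1L, side = side, seed = 733L)
  spec$texture_params <- tibble::tibble(class = "REF", density_min = 18,
                                        density_max = 18, radius_min = 2.5,
                                        radius_max = 4, ecc_min = 0.1, ecc_max = 0.5)
  generate_image(spec, "REF", seed = 733L)
}

#' The package's default stain-normalization target
#'
#' Fitted from [reference_stain_image()] (synthetic; label your own reference
#' via [fit_stain_target()] for real pipelines).
#' @return A `stain_target`.
#' @export
default_stain_target <- function() {
  fit_stain_target(reference_stain_image(),
                   provenance = "ecsanet synthetic reference (seed 733)")
}
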