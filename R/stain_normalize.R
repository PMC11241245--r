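#' @useDynLib ecsanet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn .data !!!
#' @importFrom dplyr %>%
#' @importFrom ggplot2 autoplot
NULL

#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance

# ---- image array helpers ----------------------------------------------------

assert_rgb <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    abort(sprintf("`%s` must be an H x W x 3 RGB array.", arg),
          class = "ecsanet_invalid_input")
  if (any(dim(image)[1:2] < 1L))
    abort(sprintf("`%s` has zero-sized dimensions.", arg),
          class = "ecsanet_invalid_input")
  invisible(image)
}

#' Read / write an 8-bit RGB image
#'
#' Thin wrappers around [EBImage::readImage()] / [EBImage::writeImage()] that
#' present images as `H x W x 3` numeric arrays with values in `[0, 255]`,
#' the convention used throughout this package.
#'
#' @param path File path (PNG, also TIFF/JPEG via EBImage).
#' @return `read_image_rgb()`: an `H x W x 3` array in `[0, 255]`.
#' @export
read_image_rgb <- function(path) {
  if (!file.exists(path))
    abort(sprintf("Cannot read image: '%s' does not exist.", path),
          class = "ecsanet_read_error")
  img <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  aperm(img, c(2L, 1L, 3L)) * 255
}

#' @param image `H x W x 3` array in `[0, 255]`.
#' @rdname read_image_rgb
#' @return `write_image_rgb()`: the input, invisibly.
#' @export
write_image_rgb <- function(image, path) {
  assert_rgb(image)
  EBImage::writeImage(
    EBImage::Image(aperm(clip01(image / 255), c(2L, 1L, 3L)), colormode = "Color"),
    path)
  invisible(image)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# ---- RGB <-> CIELAB ---------------------------------------------------------

#' Convert an 8-bit RGB image to CIELAB
#'
#' Conversion is sRGB -> CIELAB under the D65 white point via
#' [grDevices::convertColor()]. The L plane lies in `[0, 100]`; a and b are
#' signed chroma planes. The white point maps to `L = 100, a = b = 0`.
#'
#' @param image `H x W x 3` RGB array with values in `[0, 255]`.
#' @return An `H x W x 3` array of class `lab_image`, planes ordered L, a, b.
#' @export
rgb_to_lab <- function(image) {
  assert_rgb(image)
  d <- dim(image)
  m <- matrix(image / 255, ncol = 3L)
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  structure(array(lab, dim = d), class = "lab_image")
}

#' Convert a CIELAB image back to 8-bit RGB
#'
#' Out-of-gamut values are clipped into `[0, 255]` (never wrapped) and
#' quantized to whole 8-bit levels.
#'
#' @param lab An `H x W x 3` CIELAB array (as produced by [rgb_to_lab()]).
#' @return `H x W x 3` RGB array with integer values in `[0, 255]`.
#' @export
lab_to_rgb <- function(lab) {
  if (!is.array(lab) || length(dim(lab)) != 3L || dim(lab)[3] != 3L)
    abort("`lab` must be an H x W x 3 Lab array.", class = "ecsanet_invalid_input")
  d <- dim(lab)
  m <- matrix(as.numeric(lab), ncol = 3L)
  rgb <- grDevices::convertColor(m, from = "Lab", to = "sRGB")
  array(round(clip01(rgb) * 255), dim = d)
}

# ---- Lab statistics ---------------------------------------------------------

#' Per-channel mean and standard deviation of a Lab image
#'
#' Statistics are population statistics (divide by N) over all pixels of each
#' plane, matching the transfer rule's unqualified standard deviation.
#'
#' @param lab An `H x W x 3` Lab array.
#' @return A `lab_stats` list with numeric 3-vectors `mean` and `std`
#'   (named L, a, b).
#' @export
compute_lab_stats <- function(lab) {
  if (!is.array(lab) || length(dim(lab)) != 3L || dim(lab)[3] != 3L)
    abort("`lab` must be an H x W x 3 Lab array.", class = "ecsanet_invalid_input")
  n <- prod(dim(lab)[1:2])
  if (n < 2L)
    abort("Lab statistics need at least 2 pixels.", class = "ecsanet_degenerate_input")
  m <- matrix(as.numeric(lab), ncol = 3L)
  mu <- colMeans(m)
  sd_pop <- sqrt(colMeans(sweep(m, 2L, mu)^2))
  structure(list(mean = stats::setNames(mu, c("L", "a", "b")),
                 std  = stats::setNames(sd_pop, c("L", "a", "b"))),
            class = "lab_stats")
}

#' @export
print.lab_stats <- function(x, ...) {
  cat("Lab statistics\n")
  print(round(rbind(mean = x$mean, std = x$std), 4))
  invisible(x)
}

# ---- stain target -----------------------------------------------------------

#' Fit a stain-normalization target from a reference image
#'
#' Captures the reference color distribution (per-channel Lab mean and
#' standard deviation) that [stain_normalize()] transfers onto source images.
#' A constant-color reference is rejected: its zero standard deviation would
#' make the scaling step undefined.
#'
#' @param target_image `H x W x 3` RGB array in `[0, 255]`.
#' @param provenance Free-text identifier of the reference image.
#' @param rgb2lab Pluggable RGB-to-Lab conversion (default CIELAB/D65).
#' @return A `stain_target` object: fields `stats` ([compute_lab_stats()]
#'   result), `provenance`, and `colorspace`.
#' @export
fit_stain_target <- function(target_image, provenance = "unnamed reference",
                             rgb2lab = rgb_to_lab) {
  assert_rgb(target_image, "target_image")
  stats <- compute_lab_stats(rgb2lab(target_image))
  if (any(stats$std <= 0))
    abort("Degenerate reference: a Lab channel has zero variance.",
          class = "ecsanet_degenerate_target")
  structure(list(stats = stats, provenance = provenance, colorspace = "CIELAB-D65"),
            class = "stain_target")
}

#' @export
print.stain_target <- function(x, ...) {
  cat("Stain target (", x$colorspace, ") from: ", x$provenance, "\n", sep = "")
  print(x$stats)
  invisible(x)
}

#' Serialize / restore a stain target
#'
#' @param target A `stain_target`.
#' @param path JSON file path.
#' @return `read_stain_target()`: the restored `stain_target`.
#' @export
write_stain_target <- function(target, path) {
  stopifnot(inherits(target, "stain_target"))
  jsonlite::write_json(
    list(mean = unclass(target$stats$mean), std = unclass(target$stats$std),
         provenance = target$provenance, colorspace = target$colorspace),
    path, auto_unbox = TRUE, digits = NA)
  invisible(target)
}

#' @rdname write_stain_target
#' @export
read_stain_target <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    stats = structure(list(mean = stats::setNames(as.numeric(j$mean), c("L", "a", "b")),
                           std  = stats::setNames(as.numeric(j$std), c("L", "a", "b"))),
                      class = "lab_stats"),
    provenance = j$provenance, colorspace = j$colorspace),
    class = "stain_target")
}

# ---- Reinhard transfer ------------------------------------------------------

#' Reinhard stain color normalization
#'
#' Transfers the per-channel Lab statistics of a reference distribution onto a
#' source image: each Lab channel C is recentred and rescaled,
#' `C' = (C - mu_src) * (sd_ref / sd_src) + mu_ref`, then converted back to
#' 8-bit RGB. This matches the source image's global color distribution to the
#' reference while leaving structure untouched, the standard remedy for
#' lab-to-lab H&E staining variability.
#'
#' If a source channel is constant (zero variance) the scale ratio is treated
#' as 1 and only the mean shift is applied, with a warning.
#'
#' @param source `H x W x 3` RGB array in `[0, 255]`.
#' @param target A fitted [fit_stain_target()] object.
#' @param rgb2lab,lab2rgb Pluggable color conversions.
#' @return Normalized `H x W x 3` RGB array (integers in `[0, 255]`).
#' @export
stain_normalize <- function(source, target,
                            rgb2lab = rgb_to_lab, lab2rgb = lab_to_rgb) {
  assert_rgb(source, "source")
  if (!inherits(target, "stain_target"))
    abort("`target` must be a fitted stain_target.", class = "ecsanet_invalid_input")
  lab <- rgb2lab(source)
  src <- compute_lab_stats(lab)
  ratio <- target$stats$std / src$std
  if (any(src$std == 0)) {
    warn("Zero-variance source channel: applying mean shift without scaling.")
    ratio[src$std == 0] <- 1
  }
  out <- unclass(lab)
  for (c in 1:3)
    out[, , c] <- (out[, , c] - src$mean[c]) * ratio[c] + target$stats$mean[c]
  lab2rgb(structure(out, class = "lab_image"))
}
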