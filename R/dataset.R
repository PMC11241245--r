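# Dataset pipeline: index a magnification/class image tree, stratified
# 70/20/10 split, balanced oversampling stream with AugMix, geometric
# augmentation, and channel standardization.

IMAGE_EXT_RE <- "\\.(png|tif|tiff|jpg|jpeg)$"

norm_magnification <- function(magnification) {
  m <- toupper(as.character(magnification))
  if (!grepl("X$", m)) m <- paste0(m, "X")
  m
}

#' Index a BreakHis-layout image tree
#'
#' Enumerates `root/<magnification>/<class>/<image>` deterministically
#' (lexicographically sorted classes and file names), applying an image
#' extension whitelist (png/tif/tiff/jpg/jpeg).
#'
#' @param root Dataset root containing one directory per magnification.
#' @param magnification Magnification folder, e.g. `"40X"` (or `40`).
#' @param classes Optional closed class vocabulary; every named class must
#'   exist as a sub-directory. Default: discover sub-directories.
#' @return A `dataset_index` tibble with columns `path`, `label`,
#'   `magnification`, `split` (initially `NA`).
#' @export
index_dataset <- function(root, magnification, classes = NULL) {
  mag <- norm_magnification(magnification)
  mag_dir <- file.path(root, mag)
  if (!dir.exists(mag_dir))
    abort(sprintf("No magnification directory '%s' under '%s'.", mag, root),
          class = "ecsanet_layout_error")
  found <- sort(list.dirs(mag_dir, recursive = FALSE, full.names = FALSE))
  if (is.null(classes)) {
    classes <- found
  } else {
    missing <- setdiff(classes, found)
    if (length(missing) > 0)
      abort(sprintf("Missing class directories: %s.",
                    paste(missing, collapse = ", ")),
            class = "ecsanet_layout_error")
    classes <- sort(classes)
  }
  if (length(classes) == 0)
    abort("No class directories found.", class = "ecsanet_layout_error")
  recs <- purrr::map_dfr(classes, function(cls) {
    files <- sort(list.files(file.path(mag_dir, cls), full.names = TRUE))
    files <- files[grepl(IMAGE_EXT_RE, files, ignore.case = TRUE)]
    if (length(files) == 0)
      abort(sprintf("Class '%s' has no images.", cls),
            class = "ecsanet_empty_class")
    tibble::tibble(path = files, label = cls)
  })
  out <- dplyr::mutate(recs,
                       label = factor(.data$label, levels = classes),
                       magnification = mag, split = NA_character_)
  new_dataset_index(out, classes, mag)
}

new_dataset_index <- function(tbl, classes, magnification) {
  structure(tbl, class = c("dataset_index", class(tibble::as_tibble(tbl))),
            classes = classes, magnification = magnification)
}

#' Per-class image counts of a dataset index
#'
#' @param index A `dataset_index` tibble.
#' @param split Optional split name to restrict to.
#' @return Tibble with columns `label`, `n` (every class present, even if 0).
#' @export
class_counts <- function(index, split = NULL) {
  classes <- levels(index$label)
  x <- index
  if (!is.null(split)) x <- dplyr::filter(x, .data$split == !!split)
  dplyr::count(tibble::as_tibble(x), .data$label, .drop = FALSE, name = "n") %>%
    dplyr::rename(label = "label")
}

#' Stratified train/validation/test split
#'
#' Per class: `floor(r_train * n)` images to train, `floor(r_val * n)` to
#' validation, the remainder to test -- the rounding scheme that makes the
#' balanced training-set sizes come out exactly as published for the BreakHis
#' class counts. Shuffling within each class is driven only by `seed`, so the
#' same `(index, seed)` always yields the same membership.
#'
#' @param index A `dataset_index`.
#' @param ratios Numeric 3-vector `(train, val, test)` summing to 1.
#' @param seed Integer seed.
#' @return The index with its `split` column filled in.
#' @export
stratified_split <- function(index, ratios = c(train = 0.7, val = 0.2, test = 0.1),
                             seed = 1L) {
  if (abs(sum(ratios) - 1) > 1e-9)
    abort("`ratios` must sum to 1.", class = "ecsanet_invalid_input")
  classes <- levels(index$label)
  tbl <- tibble::as_tibble(index)
  withr::with_seed(as.integer(seed), {
    parts <- lapply(classes, function(cls) {
      rows <- tbl[tbl$label == cls, ]
      n <- nrow(rows)
      if (n < 3L)
        abort(sprintf("Class '%s' has %d image(s); need >= 3 to split.", cls, n),
              class = "ecsanet_split_error")
      rows <- rows[sample.int(n), ]
      n_train <- floor(ratios[[1]] * n)
      n_val <- floor(ratios[[2]] * n)
      rows$split <- rep(c("train", "val", "test"),
                        c(n_train, n_val, n - n_train - n_val))
      rows
    })
  })
  out <- dplyr::arrange(dplyr::bind_rows(parts), .data$label, .data$path)
  new_dataset_index(out, classes, attr(index, "magnification"))
}

# ---- balance plan -----------------------------------------------------------

#' Plan the oversampled balanced training stream
#'
#' From the per-class training counts: the common oversampling target is three
#' times the largest class's training count; every class is streamed up to
#' that target by cycling its images, and classes smaller than the largest
#' one are flagged for AugMix-based balancing augmentation. One balanced
#' epoch therefore yields `n_classes * oversample_target` items.
#'
#' @param x A `dataset_index` (its `"train"` rows are used if the split has
#'   been computed, otherwise all rows), or a tibble with columns
#'   `label` and `n` for count-only planning.
#' @return A `balance_plan` with fields `classes`, `train_counts`,
#'   `max_class_count`, `oversample_target`, `augment_with_mix`,
#'   `epoch_length`, and (when paths are available) `files`.
#' @export
plan_balance <- function(x) {
  files <- NULL
  if (inherits(x, "dataset_index")) {
    tbl <- tibble::as_tibble(x)
    if (any(!is.na(tbl$split))) tbl <- tbl[tbl$split %in% "train", ]
    if (nrow(tbl) == 0)
      abort("Empty training split.", class = "ecsanet_invalid_input")
    counts <- dplyr::count(tbl, .data$label, .drop = FALSE, name = "n")
    files <- lapply(split(tbl$path, tbl$label), sort)
  } else {
    counts <- tibble::as_tibble(x)[, c("label", "n")]
    if (nrow(counts) == 0 || any(counts$n <= 0))
      abort("Counts must be positive for every class.",
            class = "ecsanet_invalid_input")
  }
  n <- stats::setNames(as.integer(counts$n), as.character(counts$label))
  if (any(n == 0))
    abort("Empty class in training split.", class = "ecsanet_invalid_input")
  max_count <- max(n)
  target <- 3L * max_count
  structure(list(classes = names(n), train_counts = n,
                 max_class_count = max_count,
                 oversample_target = target,
                 augment_with_mix = n < max_count,
                 epoch_length = length(n) * target,
                 files = files),
            class = "balance_plan")
}

#' @export
print.balance_plan <- function(x, ...) {
  cat("Balanced oversampling plan\n")
  cat("  classes:", length(x$classes),
      " max class count:", x$max_class_count,
      " target/class:", x$oversample_target,
      " epoch length:", x$epoch_length, "\n")
  print(tibble::tibble(label = x$classes, n_train = unname(x$train_counts),
                       augment_with_mix = unname(x$augment_with_mix)))
  invisible(x)
}

# ---- stream configuration ---------------------------------------------------

#' Per-channel standardization statistics
#'
#' @param mean,std Numeric vectors of equal length; `std` strictly positive.
#' @return A `channel_stats` list.
#' @export
channel_stats <- function(mean, std) {
  if (length(mean) != length(std))
    abort("mean and std must have equal length.", class = "ecsanet_invalid_input")
  if (any(std <= 0))
    abort("std must be strictly positive.", class = "ecsanet_invalid_input")
  structure(list(mean = as.numeric(mean), std = as.numeric(std)),
            class = "channel_stats")
}

#' Canonical ImageNet channel statistics (on the `[0, 1]` scale)
#' @export
imagenet_channel_stats <- function() {
  channel_stats(c(0.485, 0.456, 0.406), c(0.229, 0.224, 0.225))
}

#' Configuration of the image stream
#'
#' @param side Output side length after resize + center crop (default 384).
#' @param stain_target A `stain_target` for Reinhard normalization, or `NULL`
#'   to skip normalization.
#' @param stats `channel_stats` for standardization (on `[0, 1]` pixel scale).
#' @param augment Master switch for training-stream augmentation
#'   (validation/test streams never augment); `FALSE` disables both
#'   component flags below.
#' @param balance_aug Apply AugMix to classes flagged for balancing.
#' @param geometric_aug Apply the geometric transform to every training item.
#' @param augmix_params List of AugMix settings (`width`, `depth` range,
#'   `severity`, `alpha`).
#' @param seed Integer seed driving every random augmentation draw.
#' @return A `stream_config` list.
#' @export
stream_config <- function(side = 384L, stain_target = default_stain_target(),
                          stats = imagenet_channel_stats(), augment = TRUE,
                          balance_aug = TRUE, geometric_aug = TRUE,
                          augmix_params = list(width = 3L, depth = c(1L, 3L),
                                               severity = 3, alpha = 1),
                          seed = 1L) {
  structure(list(side = as.integer(side), stain_target = stain_target,
                 stats = stats,
                 balance_aug = isTRUE(augment) && isTRUE(balance_aug),
                 geometric_aug = isTRUE(augment) && isTRUE(geometric_aug),
                 augmix_params = augmix_params, seed = as.integer(seed)),
            class = "stream_config")
}

#' Stream configuration honoring an architecture's pipeline switches
#'
#' Translates the `pipeline` component switches of an
#' [architecture_config()] (possibly modified by [ablation_variant()]) into a
#' [stream_config()]: `stain_norm = FALSE` drops the stain target,
#' `balance_aug`/`geometric_aug` toggle the corresponding augmentations.
#'
#' @param arch An [architecture_config()].
#' @param side,stain_target,stats,augmix_params,seed As in [stream_config()].
#' @return A `stream_config`.
#' @export
configure_stream <- function(arch, side = arch$input_side,
                             stain_target = default_stain_target(),
                             stats = imagenet_channel_stats(),
                             augmix_params = list(width = 3L, depth = c(1L, 3L),
                                                  severity = 3, alpha = 1),
                             seed = 1L) {
  pl <- arch$pipeline
  stream_config(side = side,
                stain_target = if (isTRUE(pl$stain_norm)) stain_target else NULL,
                stats = stats, balance_aug = isTRUE(pl$balance_aug),
                geometric_aug = isTRUE(pl$geometric_aug),
                augmix_params = augmix_params, seed = seed)
}

# ---- preprocessing ----------------------------------------------------------

ebi <- function(image) EBImage::Image(aperm(image, c(2L, 1L, 3L)) / 255,
                                      colormode = "Color")
unebi <- function(img) aperm(EBImage::imageData(img), c(2L, 1L, 3L)) * 255

#' Resize, center-crop and stain-normalize an image
#'
#' Resizes the shorter side to `side` (preserving aspect ratio, bilinear),
#' center-crops to `side x side`, then applies Reinhard stain normalization
#' against `stain_target` when one is given.
#'
#' @param image `H x W x 3` RGB array in `[0, 255]`.
#' @param side Output side length.
#' @param stain_target `stain_target` or `NULL`.
#' @return `side x side x 3` RGB array.
#' @export
preprocess_image <- function(image, side = 384L, stain_target = NULL) {
  assert_rgb(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h != side || w != side) {
    s <- side / min(h, w)
    nh <- max(side, round(h * s)); nw <- max(side, round(w * s))
    img <- unebi(EBImage::resize(ebi(image), w = nw, h = nh))
    top <- floor((nh - side) / 2); left <- floor((nw - side) / 2)
    image <- img[top + seq_len(side), left + seq_len(side), , drop = FALSE]
    image <- array(round(pmin(pmax(image, 0), 255)), dim = c(side, side, 3L))
  }
  if (!is.null(stain_target)) image <- stain_normalize(image, stain_target)
  image
}

#' Standardize an image tensor channel-wise
#'
#' Per channel c: `(x - mean_c) / std_c`.
#'
#' @param x Array whose last dimension is the channel dimension.
#' @param stats A [channel_stats()] object matching the channel count.
#' @return Standardized array of the same shape.
#' @export
standardize <- function(x, stats) {
  nd <- length(dim(x))
  if (dim(x)[nd] != length(stats$mean))
    abort("Channel count does not match stats length.",
          class = "ecsanet_invalid_input")
  if (any(stats$std == 0))
    abort("Zero std in channel stats.", class = "ecsanet_invalid_input")
  sweep(sweep(x, nd, stats$mean, "-"), nd, stats$std, "/")
}

# ---- geometric augmentation -------------------------------------------------

# one random parameter draw of the geometric training augmentation
sample_geom_params <- function() list(
  flip_h = stats::runif(1) < 0.5, flip_v = stats::runif(1) < 0.5,
  angle = stats::runif(1, -45, 45),
  trans_x = stats::runif(1, -0.10, 0.10), trans_y = stats::runif(1, -0.10, 0.10),
  scale = stats::runif(1, 0.8, 1.2), shear = stats::runif(1, 0, 10))

#' Sample or apply the geometric training augmentation
#'
#' With random parameters: horizontal / vertical flips each with probability
#' 0.5, rotation uniform in `[-45, 45]` degrees, translation up to 10% of
#' each axis, scaling in `[0.8, 1.2]`, shear in `[0, 10]` degrees. Dimensions
#' are always preserved. Pass `params` explicitly for deterministic
#' transforms (identity parameters return the input pixel-identically).
#'
#' @param image `H x W x 3` RGB array.
#' @param params Optional list `(flip_h, flip_v, angle, trans_x, trans_y,
#'   scale, shear)`; sampled when `NULL`.
#' @param seed Optional seed for the sampling.
#' @return Transformed image array of identical dimensions.
#' @export
geometric_transform <- function(image, params = NULL, seed = NULL) {
  assert_rgb(image)
  if (is.null(params)) {
    params <- if (is.null(seed)) sample_geom_params() else
      withr::with_seed(as.integer(seed), sample_geom_params())
  }
  if (isTRUE(params$flip_h)) image <- image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
  if (isTRUE(params$flip_v)) image <- image[rev(seq_len(dim(image)[1])), , , drop = FALSE]
  ident <- abs(params$angle) < 1e-12 && abs(params$trans_x) < 1e-12 &&
    abs(params$trans_y) < 1e-12 && abs(params$scale - 1) < 1e-12 &&
    abs(params$shear) < 1e-12
  if (ident) return(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  th <- params$angle * pi / 180; sh <- tan(params$shear * pi / 180)
  s <- params$scale
  # map in EBImage (x, y) = (column, row) coordinates, about the image center
  rot <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  shear_m <- matrix(c(1, sh, 0, 1), 2, 2, byrow = TRUE)
  a2 <- s * rot %*% shear_m
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  off <- c(cx + params$trans_x * w, cy + params$trans_y * h) - a2 %*% c(cx, cy)
  m <- rbind(t(a2), as.numeric(off))  # 3 x 2 as expected by EBImage::affine
  out <- EBImage::affine(ebi(image), m, filter = "bilinear",
                         output.dim = c(w, h), bg.col = "black")
  array(round(pmin(pmax(unebi(out), 0), 255)), dim = dim(image))
}

# ---- AugMix -----------------------------------------------------------------

dirichlet_weights <- function(n, alpha) {
  g <- stats::rgamma(n, shape = alpha)
  if (sum(g) == 0) g <- rep(1, n)
  g / sum(g)
}

augmix_op <- function(image, op, level) {
  # level in [0, 1] scales every operation away from identity; level 0 is exact identity
  h <- dim(image)[1]; w <- dim(image)[2]
  switch(op,
    rotate = geometric_transform(image, params = list(
      flip_h = FALSE, flip_v = FALSE, angle = level * 30 * sample(c(-1, 1), 1),
      trans_x = 0, trans_y = 0, scale = 1, shear = 0)),
    shear_x = , shear_y = {
      sgn <- sample(c(-1, 1), 1)
      p <- list(flip_h = FALSE, flip_v = FALSE, angle = 0, trans_x = 0,
                trans_y = 0, scale = 1, shear = sgn * level * 17)
      if (op == "shear_x") geometric_transform(image, params = p)
      else aperm(geometric_transform(aperm(image, c(2, 1, 3)), params = p),
                 c(2, 1, 3)) },
    translate_x = geometric_transform(image, params = list(
      flip_h = FALSE, flip_v = FALSE, angle = 0,
      trans_x = level * sample(c(-1, 1), 1) / 3, trans_y = 0, scale = 1, shear = 0)),
    translate_y = geometric_transform(image, params = list(
      flip_h = FALSE, flip_v = FALSE, angle = 0, trans_x = 0,
      trans_y = level * sample(c(-1, 1), 1) / 3, scale = 1, shear = 0)),
    posterize = {
      bits <- 8 - round(level * 4)
      if (bits >= 8) image else {
        q <- 2^(8 - bits)
        array(pmin(floor(image / q) * q + q / 2, 255), dim = dim(image))
      } },
    solarize = {
      thr <- 256 - level * 128
      out <- image; sel <- out >= thr; out[sel] <- 255 - out[sel]; out },
    brightness = pmin(pmax(image + level * 60 * sample(c(-1, 1), 1), 0), 255),
    contrast = {
      f <- 1 + level * 0.8 * sample(c(-1, 1), 1)
      pmin(pmax((image - 127.5) * f + 127.5, 0), 255) },
    image)
}

AUGMIX_OPS <- c("rotate", "shear_x", "shear_y", "translate_x", "translate_y",
                "posterize", "solarize", "brightness", "contrast")

#' AugMix image augmentation
#'
#' Blends `width` stochastic augmentation chains (rotation, shear,
#' translation, posterize, solarize, brightness, contrast at the given
#' severity) with Dirichlet-sampled weights, then mixes the blend with the
#' original image via a Beta-sampled weight. Severity 0 makes every operation
#' the identity, so the output equals the input.
#'
#' @param image `H x W x 3` RGB array in `[0, 255]`.
#' @param width Number of parallel chains.
#' @param depth Chain length range `c(min, max)` (drawn per chain).
#' @param severity Operation severity on a 0-10 scale.
#' @param alpha Dirichlet / Beta concentration.
#' @param seed Optional seed; fixed seed gives bit-identical output.
#' @return Augmented image array, same shape and 8-bit quantization.
#' @export
augmix <- function(image, width = 3L, depth = c(1L, 3L), severity = 3,
                   alpha = 1, seed = NULL) {
  assert_rgb(image)
  run <- function() {
    level <- max(0, min(1, severity / 10))
    ws <- dirichlet_weights(width, alpha)
    m <- stats::rbeta(1, alpha, alpha)
    mix <- array(0, dim = dim(image))
    for (k in seq_len(width)) {
      d <- if (length(depth) > 1) sample(seq(depth[1], depth[2]), 1) else depth
      chain <- image
      for (j in seq_len(d))
        chain <- augmix_op(chain, sample(AUGMIX_OPS, 1), level)
      mix <- mix + ws[k] * chain
    }
    out <- (1 - m) * image + m * mix
    array(round(pmin(pmax(out, 0), 255)), dim = dim(image))
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

# ---- balanced stream --------------------------------------------------------

#' Fetch one item of the balanced training stream
#'
#' Position `i` (0-based, `0 <= i < oversample_target`) of class `class`
#' resolves to the class's sorted image `i mod n_images`; the image is
#' preprocessed, balance-augmented with AugMix iff the class is smaller than
#' the largest class, geometrically transformed, and standardized. With
#' `config$augment = FALSE` (or for validation/test use) only preprocessing
#' and standardization are applied.
#'
#' @param plan A [plan_balance()] result carrying file lists.
#' @param class Class label.
#' @param i 0-based epoch position within the class.
#' @param config A [stream_config()].
#' @return List with `x` (standardized `side x side x 3` tensor), `label`,
#'   and `path`.
#' @export
get_item <- function(plan, class, i, config = stream_config()) {
  if (is.null(plan$files))
    abort("This plan was built from counts only; no image paths available.",
          class = "ecsanet_invalid_input")
  if (!class %in% plan$classes)
    abort(sprintf("Unknown class '%s'.", class), class = "ecsanet_invalid_input")
  if (i < 0 || i >= plan$oversample_target)
    abort(sprintf("Position %d outside [0, %d).", i, plan$oversample_target),
          class = "ecsanet_index_error")
  n_c <- plan$train_counts[[class]]
  idx <- i %% n_c
  path <- plan$files[[class]][idx + 1L]
  img <- read_image_rgb(path)
  img <- preprocess_image(img, side = config$side,
                          stain_target = config$stain_target)
  item_seed <- (as.double(config$seed) * 65537 +
                  match(class, plan$classes) * 9973 + i * 7) %% 2147483647
  if (config$balance_aug && plan$augment_with_mix[[class]]) {
    ap <- config$augmix_params
    img <- augmix(img, width = ap$width, depth = ap$depth,
                  severity = ap$severity, alpha = ap$alpha, seed = item_seed)
  }
  if (config$geometric_aug)
    img <- geometric_transform(img, seed = item_seed + 1)
  list(x = standardize(img / 255, config$stats), label = class, path = path)
}

#' Schedule of one balanced epoch
#'
#' @param plan A [plan_balance()] result.
#' @param seed Shuffle seed (`NULL` keeps class-major order).
#' @return Tibble with one row per item: columns `class`, `i`.
#' @export
epoch_schedule <- function(plan, seed = NULL) {
  sched <- tidyr::expand_grid(class = plan$classes,
                              i = seq_len(plan$oversample_target) - 1L)
  if (!is.null(seed))
    sched <- withr::with_seed(as.integer(seed),
                              sched[sample.int(nrow(sched)), ])
  sched
}

#' Evaluation-stream item: preprocess + standardize only
#'
#' @param path Image file path.
#' @param config A [stream_config()]; its `augment` flag is ignored --
#'   evaluation items are never augmented.
#' @return Standardized `side x side x 3` tensor.
#' @export
eval_item <- function(path, config = stream_config()) {
  img <- preprocess_image(read_image_rgb(path), side = config$side,
                          stain_target = config$stain_target)
  standardize(img / 255, config$stats)
}

#' Write the split manifest as CSV
#'
#' @param index A split `dataset_index`.
#' @param path Output CSV path (columns path,label,magnification,split).
#' @export
write_split_manifest <- function(index, path) {
  utils::write.csv(tibble::as_tibble(index), path, row.names = FALSE)
  invisible(index)
}
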