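# Assembly of the attention-augmented classifier: an EfficientNetV2-S style
# backbone (stem + Fused-MBConv and MBConv+SE stages), one CBAM block on the
# final 256-channel feature map, a 1x1 expansion to 1280, global average
# pooling, and a fully connected head with two hidden layers.

make_divisible <- function(v, divisor = 8L) {
  new <- max(divisor, as.integer(v + divisor / 2) %/% divisor * divisor)
  if (new < 0.9 * v) new <- new + divisor
  as.integer(new)
}

backbone_stage_table <- function() {
  tibble::tibble(
    block = c("fused", "fused", "fused", "mbconv", "mbconv", "mbconv"),
    expansion = c(1, 4, 4, 4, 6, 6),
    layers = c(2L, 4L, 4L, 6L, 9L, 15L),
    stride = c(1L, 2L, 2L, 2L, 1L, 2L),
    channels = c(24L, 48L, 64L, 128L, 160L, 256L))
}

#' Architecture configuration
#'
#' @param num_classes Output classes (default 8, the BreakHis sub-types).
#' @param reduction_ratio CBAM channel reduction ratio (default 16).
#' @param hidden_width Width of the two hidden fully connected layers
#'   (default 1024).
#' @param width_scale In `(0, 1]`: scales all channel counts (rounded to
#'   multiples of 8) for CPU-scale tests. 1 reproduces the published
#'   configuration; `pretrained` requires 1.
#' @param depth_scale In `(0, 1]`: scales per-stage layer counts (minimum 1
#'   layer per stage), a desk-scale knob analogous to `width_scale`.
#' @param input_side Input image side (must be divisible by 32; default 384).
#' @param pretrained Initialize the backbone from pretrained weights. No
#'   weight source ships with the package; pass a checkpoint produced by
#'   [save_checkpoint()] via `weights_from` instead, or leave `FALSE`
#'   (random initialization).
#' @param dropout Dropout probability before the first hidden FC (0 disables).
#' @param use_cbam,extra_fc Component switches used by [ablation_variant()].
#' @param se_ratio Squeeze-and-excitation ratio inside MBConv stages.
#' @param spatial_kernel CBAM spatial kernel (odd).
#' @param pipeline Pipeline component switches (`stain_norm`, `balance_aug`,
#'   `geometric_aug`), toggled by [ablation_variant()].
#' @return An `architecture_config` list.
#' @export
architecture_config <- function(num_classes = 8L, reduction_ratio = 16L,
                                hidden_width = 1024L, width_scale = 1,
                                depth_scale = 1, input_side = 384L,
                                pretrained = FALSE, dropout = 0.2,
                                use_cbam = TRUE, extra_fc = TRUE,
                                se_ratio = 0.25, spatial_kernel = 7L,
                                pipeline = list(stain_norm = TRUE,
                                                balance_aug = TRUE,
                                                geometric_aug = TRUE)) {
  if (num_classes < 2) abort("num_classes must be >= 2.", class = "ecsanet_config_error")
  if (width_scale <= 0 || width_scale > 1)
    abort("width_scale must be in (0, 1].", class = "ecsanet_config_error")
  if (depth_scale <= 0 || depth_scale > 1)
    abort("depth_scale must be in (0, 1].", class = "ecsanet_config_error")
  if (pretrained && (width_scale != 1 || depth_scale != 1))
    abort("pretrained weights require width_scale = depth_scale = 1.",
          class = "ecsanet_config_error")
  if (input_side %% 32L != 0L)
    abort("input_side must be divisible by 32 (the backbone's stride product).",
          class = "ecsanet_config_error")
  structure(list(num_classes = as.integer(num_classes),
                 reduction_ratio = as.integer(reduction_ratio),
                 hidden_width = as.integer(hidden_width),
                 width_scale = width_scale, depth_scale = depth_scale,
                 input_side = as.integer(input_side),
                 pretrained = isTRUE(pretrained), dropout = dropout,
                 use_cbam = isTRUE(use_cbam), extra_fc = isTRUE(extra_fc),
                 se_ratio = se_ratio, spatial_kernel = as.integer(spatial_kernel),
                 pipeline = pipeline),
            class = "architecture_config")
}

scaled_channels <- function(config) {
  st <- backbone_stage_table()
  ws <- config$width_scale
  stem <- if (ws == 1) 24L else make_divisible(24 * ws)
  ch <- if (ws == 1) st$channels else vapply(st$channels * ws, make_divisible, integer(1))
  list(stem = stem, stages = as.integer(ch),
       layers = pmax(1L, as.integer(round(st$layers * config$depth_scale))),
       head = if (ws == 1) 1280L else make_divisible(1280 * ws))
}

#' Build the convolutional backbone
#'
#' Stem (3x3, stride 2) followed by three Fused-MBConv stages (expansions
#' 1, 4, 4) and three MBConv+SE stages (expansions 4, 6, 6; SE ratio 0.25),
#' with per-stage strides 1,2,2,2,1,2 -- total downsampling 32x. At
#' `width_scale < 1` every channel count is scaled and rounded to a multiple
#' of 8.
#'
#' @param config An [architecture_config()].
#' @return A backbone layer (named stages `stem`, `stage1` ... `stage6`) with
#'   attribute `stage_channels`.
#' @export
build_backbone <- function(config) {
  if (config$pretrained)
    abort(paste("No pretrained weight source is available;",
                "load weights from a checkpoint with load_checkpoint()."),
          class = "ecsanet_config_error")
  sc <- scaled_channels(config)
  st <- backbone_stage_table()
  stages <- list(ly_seq(list(ly_conv(3L, sc$stem, 3L, stride = 2L),
                             ly_bn(sc$stem), ly_act("silu")), name = "stem"))
  cin <- sc$stem
  for (i in seq_len(nrow(st))) {
    blocks <- list()
    for (j in seq_len(sc$layers[i])) {
      stride <- if (j == 1) st$stride[i] else 1L
      cout <- sc$stages[i]
      e <- st$expansion[i]
      if (st$block[i] == "fused") {
        body <- if (e == 1) {
          ly_seq(list(ly_conv(cin, cout, 3L, stride = stride),
                      ly_bn(cout), ly_act("silu")))
        } else {
          cexp <- cin * e
          ly_seq(list(ly_conv(cin, cexp, 3L, stride = stride),
                      ly_bn(cexp), ly_act("silu"),
                      ly_conv(cexp, cout, 1L), ly_bn(cout)))
        }
      } else {
        cexp <- cin * e
        body <- ly_seq(list(
          ly_conv(cin, cexp, 1L), ly_bn(cexp), ly_act("silu"),
          ly_conv(cexp, cexp, 3L, stride = stride, groups = cexp),
          ly_bn(cexp), ly_act("silu"),
          ly_se(cexp, cin, ratio = config$se_ratio),
          ly_conv(cexp, cout, 1L), ly_bn(cout)))
      }
      blocks[[j]] <- ly_block(body, use_res = stride == 1L && cin == cout)
      cin <- cout
    }
    stages[[i + 1]] <- ly_seq(blocks, name = paste0("stage", i))
  }
  structure(ly_seq(stages, name = "backbone"),
            stage_channels = c(sc$stem, sc$stages))
}

#' Assemble the full attention-augmented classifier
#'
#' Backbone -> CBAM (on the final 256-channel map) -> 1x1 convolution to 1280
#' -> global average pooling -> dropout -> FC(1280 -> hidden) -> FC(hidden ->
#' hidden) -> FC(hidden -> num_classes). With `extra_fc = FALSE` the head is
#' a single FC(1280 -> num_classes); with `use_cbam = FALSE` the CBAM block
#' is bypassed entirely.
#'
#' @param config An [architecture_config()].
#' @param seed Integer seed for weight initialization.
#' @param class_labels Optional class label vector of length `num_classes`.
#' @return An `ecsanet_model`: fields `net`, `config`, `summary`,
#'   `class_labels`.
#' @export
assemble_ecsanet <- function(config = architecture_config(), seed = 1L,
                             class_labels = NULL) {
  if (is.null(class_labels))
    class_labels <- if (config$num_classes == 8L) breakhis_classes else
      as.character(seq_len(config$num_classes))
  stopifnot(length(class_labels) == config$num_classes)
  sc <- scaled_channels(config)
  net <- withr::with_seed(as.integer(seed), {
    backbone <- build_backbone(config)
    parts <- list(backbone)
    if (config$use_cbam)
      parts <- c(parts, list(
        ly_cbam(sc$stages[6], config$reduction_ratio, config$spatial_kernel,
                name = "cbam")))
    parts <- c(parts, list(
      ly_seq(list(ly_conv(sc$stages[6], sc$head, 1L), ly_bn(sc$head),
                  ly_act("silu")), name = "head_conv"),
      ly_gap(name = "pool")))
    head <- if (config$extra_fc) {
      ly_seq(list(ly_dropout(config$dropout),
                  ly_linear(sc$head, config$hidden_width), ly_act("silu"),
                  ly_linear(config$hidden_width, config$hidden_width),
                  ly_act("silu"),
                  ly_linear(config$hidden_width, config$num_classes)),
             name = "classifier")
    } else {
      ly_seq(list(ly_dropout(config$dropout),
                  ly_linear(sc$head, config$num_classes)), name = "classifier")
    }
    ly_seq(c(parts, list(head)), name = "net")
  })
  stage_channels <- c(attr(net$layers[[1]], "stage_channels"),
                      if (config$use_cbam) sc$stages[6], sc$head)
  head_widths <- if (config$extra_fc)
    c(sc$head, config$hidden_width, config$hidden_width, config$num_classes)
  else c(sc$head, config$num_classes)
  model <- structure(list(net = net, config = config,
                          class_labels = class_labels), class = "ecsanet_model")
  model$summary <- structure(list(
    stage_channels = stage_channels,
    head_widths = head_widths,
    total_parameters = n_params(net),
    logits_width = config$num_classes,
    downsampling = 32L,
    feature_side = config$input_side %/% 32L), class = "model_summary")
  model
}

#' @export
print.model_summary <- function(x, ...) {
  cat("Model summary\n")
  cat("  stage channels:", paste(x$stage_channels, collapse = ", "), "\n")
  cat("  head widths:   ", paste(x$head_widths, collapse = ", "), "\n")
  cat("  parameters:    ", format(x$total_parameters, big.mark = ","), "\n")
  cat("  logits width:  ", x$logits_width,
      "  final feature map:", x$feature_side, "x", x$feature_side, "\n")
  invisible(x)
}

#' @export
print.ecsanet_model <- function(x, ...) {
  cat("<ecsanet_model> classes:", paste(x$class_labels, collapse = ", "), "\n")
  print(x$summary)
  invisible(x)
}

#' Model summary
#'
#' @param model An `ecsanet_model`.
#' @return The `model_summary`: per-stage output channel counts, head widths,
#'   total parameter count, logits width, spatial contract.
#' @export
model_summary <- function(model) model$summary

#' @importFrom generics glance
#' @export
glance.ecsanet_model <- function(x, ...) {
  tibble::tibble(total_parameters = x$summary$total_parameters,
                 logits_width = x$summary$logits_width,
                 n_stages = length(x$summary$stage_channels),
                 input_side = x$config$input_side,
                 width_scale = x$config$width_scale,
                 use_cbam = x$config$use_cbam,
                 extra_fc = x$config$extra_fc)
}

# internal: full forward with caches (for training / grad-cam)
forward_pass <- function(model, x, training = FALSE) {
  d <- dim(x)
  side <- model$config$input_side
  if (length(d) != 4L || d[3] != 3L || d[1] != side || d[2] != side)
    abort(sprintf("Batch must be %d x %d x 3 x N (got %s).", side, side,
                  paste(d, collapse = " x ")), class = "ecsanet_shape_error")
  nn_forward(model$net, x, training = training)
}

#' Compute logits for a batch of standardized images
#'
#' @param model An `ecsanet_model`.
#' @param x Batch array `side x side x 3 x N` of standardized images.
#' @param type `"logits"`, `"prob"` (softmax rows), or `"class"`.
#' @param ... Unused.
#' @return For `"logits"`/`"prob"`: an `N x num_classes` matrix with class
#'   column names; for `"class"`: a character vector of predicted labels.
#'   Inference mode (no dropout, running batch-norm statistics), so results
#'   are deterministic for fixed weights.
#' @export
predict.ecsanet_model <- function(object, x, type = c("logits", "prob", "class"), ...) {
  type <- match.arg(type)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  r <- forward_pass(object, x, training = FALSE)
  logits <- t(r$y)                      # N x K
  colnames(logits) <- object$class_labels
  if (type == "logits") return(logits)
  p <- softmax_rows(logits)
  if (type == "prob") return(p)
  object$class_labels[max.col(p, ties.method = "first")]
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Intermediate feature map of a stage
#'
#' Runs the network in inference mode and returns the activation emitted by
#' the named stage (`stem`, `stage1` ... `stage6`, `cbam`, `head_conv`,
#' `pool`, `classifier`).
#'
#' @param model An `ecsanet_model`.
#' @param x Input tensor `side x side x 3` (or with a trailing batch dim).
#' @param layer Stage name.
#' @return The stage output array (spatial stages: `H x W x C x N`).
#' @export
feature_map <- function(model, x, layer = "stage6") {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  stages <- model$net$layers
  h <- x
  for (s in stages) {
    if (identical(s$name, "backbone")) {
      for (q in s$layers) {
        h <- nn_forward(q, h, training = FALSE)$y
        if (identical(q$name, layer)) return(h)
      }
    } else {
      h <- nn_forward(s, h, training = FALSE)$y
      if (identical(s$name, layer)) return(h)
    }
  }
  abort(sprintf("Unknown layer '%s'.", layer), class = "ecsanet_invalid_input")
}

#' Derive a single-component ablation variant
#'
#' Removes exactly one component from the model or pipeline configuration:
#' `"cbam"` (attention bypassed), `"fc_layers"` (head reduced to one FC),
#' `"stain_norm"` (Reinhard normalization skipped), `"balance_aug"` (AugMix
#' balancing skipped), or `"all_aug"` (balancing and geometric augmentation
#' both skipped). Everything else is left identical.
#'
#' @param config An [architecture_config()].
#' @param drop One component name.
#' @return The modified configuration.
#' @export
ablation_variant <- function(config, drop) {
  if (length(drop) != 1 ||
      !drop %in% c("cbam", "fc_layers", "stain_norm", "balance_aug", "all_aug"))
    abort("`drop` must name exactly one of: cbam, fc_layers, stain_norm, balance_aug, all_aug.",
          class = "ecsanet_config_error")
  switch(drop,
    cbam = { config$use_cbam <- FALSE; config },
    fc_layers = { config$extra_fc <- FALSE; config },
    stain_norm = { config$pipeline$stain_norm <- FALSE; config },
    balance_aug = { config$pipeline$balance_aug <- FALSE; config },
    all_aug = { config$pipeline$balance_aug <- FALSE
                config$pipeline$geometric_aug <- FALSE; config })
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds weights, configuration and summary; a JSON sidecar
#' (`<path>.json`) records configuration and summary for inspection.
#'
#' @param model An `ecsanet_model`.
#' @param path Checkpoint file path.
#' @return `load_checkpoint()`: the restored model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(list(config = unclass(model$config),
                            summary = unclass(model$summary),
                            class_labels = model$class_labels),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(model)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
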