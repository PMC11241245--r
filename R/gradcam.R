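# Grad-CAM: gradient-weighted class activation maps. The class logit is
# backpropagated to a chosen convolutional stage; channels of that stage's
# activation are weighted by their spatially pooled gradients, rectified,
# upsampled to the input size and min-max normalized.

#' Grad-CAM heat map for a prediction
#'
#' @param model An `ecsanet_model`.
#' @param x A standardized input tensor `side x side x 3` (e.g. from
#'   [eval_item()]).
#' @param target_class Class whose logit is explained; default the predicted
#'   class.
#' @param layer Name of the stage whose activation is explained. Default
#'   `"cbam"` (the attention-refined 256-channel map) when present, else the
#'   last backbone stage.
#' @return A `gradcam_heatmap`: `values` (`side x side`, in `[0, 1]`; a
#'   constant map collapses to all zeros), `target_class`, `layer_name`.
#'   Deterministic for fixed weights and input.
#' @export
grad_cam <- function(model, x, target_class = NULL, layer = NULL) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  stages <- model$net$layers
  stage_names <- vapply(stages, function(s) s$name %||% "", character(1))
  if (is.null(layer))
    layer <- if ("cbam" %in% stage_names) "cbam" else "stage6"
  # the backbone is itself a named sequence; expose its stages too
  flat <- list(); flat_names <- character()
  for (s in stages) {
    if (identical(s$name, "backbone")) {
      flat <- c(flat, s$layers)
      flat_names <- c(flat_names, vapply(s$layers, function(q) q$name %||% "",
                                         character(1)))
    } else {
      flat <- c(flat, list(s))
      flat_names <- c(flat_names, s$name %||% "")
    }
  }
  ti <- match(layer, flat_names)
  if (is.na(ti))
    abort(sprintf("Unknown layer '%s'. Valid layers: %s.", layer,
                  paste(flat_names[nzchar(flat_names)], collapse = ", ")),
          class = "ecsanet_invalid_input")
  # forward through the flattened stages, keeping caches
  acts <- vector("list", length(flat)); caches <- vector("list", length(flat))
  h <- x
  for (i in seq_along(flat)) {
    r <- nn_forward(flat[[i]], h, training = FALSE)
    h <- r$y; acts[[i]] <- h; caches[[i]] <- r$cache; flat[[i]] <- r$layer
  }
  logits <- drop(h)
  if (is.null(target_class))
    target_class <- model$class_labels[which.max(logits)]
  ci <- match(target_class, model$class_labels)
  if (is.na(ci))
    abort(sprintf("Unknown class '%s'.", target_class),
          class = "ecsanet_invalid_input")
  dout <- matrix(0, nrow = length(model$class_labels), ncol = 1)
  dout[ci, 1] <- 1
  for (i in rev(seq_along(flat))) {
    if (i == ti) break
    r <- nn_backward(flat[[i]], dout, caches[[i]])
    dout <- r$dx
  }
  a <- acts[[ti]]                      # (H, W, C, 1)
  g <- dout                            # gradient wrt that activation
  d <- dim(a)
  w <- colMeans(matrix(g, nrow = d[1] * d[2]))          # per (C) pooled grads
  w <- matrix(w, nrow = d[3])[, 1]
  cam <- matrix(0, d[1], d[2])
  for (c in seq_len(d[3])) cam <- cam + w[c] * a[, , c, 1]
  cam <- pmax(cam, 0)
  rng <- range(cam)
  cam <- if (diff(rng) > 0) (cam - rng[1]) / diff(rng) else cam * 0
  side <- dim(x)[1]
  if (!all(dim(cam) == c(side, side))) {
    camimg <- EBImage::resize(EBImage::Image(t(cam)), w = side, h = side)
    cam <- t(EBImage::imageData(camimg))
    cam <- pmin(pmax(cam, 0), 1)
  }
  structure(list(values = cam, target_class = target_class, layer_name = layer),
            class = "gradcam_heatmap")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

gradcam_colormap <- function(v) {
  ramp <- grDevices::colorRamp(c("#00008b", "#00bfff", "#ffff00", "#ff0000"))
  m <- ramp(as.numeric(v))
  array(m, dim = c(dim(v), 3))
}

#' Overlay a Grad-CAM heat map on its image
#'
#' Color-maps the heat map (blue -> red) and alpha-blends it onto the RGB
#' image: `out = (1 - alpha) * image + alpha * colormap`.
#'
#' @param heatmap A [grad_cam()] result (or a matrix in `[0, 1]`).
#' @param image `H x W x 3` RGB array in `[0, 255]` with matching spatial
#'   size.
#' @param alpha Blend weight in `[0, 1]`; 0 returns the image, 1 the pure
#'   color-mapped heat map.
#' @return Blended `H x W x 3` RGB array (PNG-writable via
#'   [write_image_rgb()]).
#' @export
overlay_heatmap <- function(heatmap, image, alpha = 0.5) {
  v <- if (inherits(heatmap, "gradcam_heatmap")) heatmap$values else heatmap
  assert_rgb(image)
  if (!all(dim(v) == dim(image)[1:2]))
    abort("Heat map and image spatial sizes differ.",
          class = "ecsanet_invalid_input")
  cmap <- gradcam_colormap(v)
  (1 - alpha) * image + alpha * cmap
}

#' @export
print.gradcam_heatmap <- function(x, ...) {
  cat(sprintf("<gradcam_heatmap> class %s @ layer %s, %d x %d, range [%.2f, %.2f]\n",
              x$target_class, x$layer_name, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Heat-map raster plot
#'
#' @param object A `gradcam_heatmap`.
#' @param ... Unused.
#' @export
autoplot.gradcam_heatmap <- function(object, ...) {
  df <- tibble::as_tibble(expand.grid(row = seq_len(nrow(object$values)),
                                      col = seq_len(ncol(object$values))))
  df$value <- as.numeric(object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradientn(colors = c("#00008b", "#00bfff", "#ffff00",
                                             "#ff0000"), limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Grad-CAM: %s @ %s", object$target_class,
                                  object$layer_name),
                  x = NULL, y = NULL, fill = "activation") +
    ggplot2::theme_minimal()
}
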