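# Reference tables of the BreakHis benchmark study configuration, embedded
# as code-constructed tibbles. They are inputs to count-level pipeline
# checks (class distribution) and to consistency checks of the metric
# aggregation routines (reported per-class test metrics).

#' Published BreakHis class distribution by magnification
#'
#' Per-class image counts of the BreakHis benchmark at each magnification
#' (40x/100x/200x/400x), totalling 7909 images. These counts drive the
#' count-level balancing checks: applying the 70% training split and the
#' balancing target rule to them reproduces the published balanced
#' training-set sizes.
#'
#' @return Tibble with columns `magnification`, `label`, `n`.
#' @export
breakhis_class_distribution <- function() {
  counts <- rbind(
    `40X`  = c(114, 253, 109, 149, 864, 156, 205, 145),
    `100X` = c(113, 260, 121, 150, 903, 170, 222, 142),
    `200X` = c(111, 264, 108, 140, 896, 163, 196, 135),
    `400X` = c(106, 237, 115, 130, 788, 137, 169, 138))
  colnames(counts) <- c("A", "F", "PT", "TA", "DC", "LC", "MC", "PC")
  tibble::as_tibble(as.data.frame.table(counts, stringsAsFactors = FALSE)) %>%
    stats::setNames(c("magnification", "label", "n")) %>%
    dplyr::mutate(n = as.integer(.data$n)) %>%
    dplyr::arrange(factor(.data$magnification, levels = rownames(counts)))
}

#' Reference per-class test metrics of the benchmark model
#'
#' The reported per-class test-set results (precision, sensitivity,
#' specificity, F1 in percent; support) of the reference attention-augmented
#' classifier on BreakHis, by magnification. Used as fixed inputs for
#' consistency checks: recomputing F1 from each precision/sensitivity pair
#' and re-aggregating macro/weighted rows from the per-class entries must
#' reproduce the printed values at their printed precision.
#'
#' @param magnification One of `"40X"`, `"100X"`, `"200X"`, `"400X"`.
#' @return Tibble with columns `label`, `precision`, `sensitivity`,
#'   `specificity`, `f1`, `support`.
#' @export
reference_class_report <- function(magnification = "40X") {
  mag <- norm_magnification(magnification)
  rows <- switch(mag,
    "40X" = list(
      c("A", 100, 100, 100, 100, 13), c("DC", 96, 92, 97.48, 94, 88),
      c("F", 96, 100, 99.45, 98, 26), c("LC", 71, 94, 96.86, 81, 16),
      c("MC", 95, 95, 99.46, 95, 21), c("PC", 93, 87, 99.48, 90, 15),
      c("PT", 100, 92, 100, 96, 12), c("TA", 100, 100, 100, 100, 16)),
    "100X" = list(
      c("A", 100, 92, 100, 96, 12), c("DC", 93, 96, 94.26, 94, 91),
      c("F", 96, 88, 99.47, 92, 26), c("LC", 78, 78, 97.95, 78, 18),
      c("MC", 95, 91, 99.47, 93, 23), c("PC", 94, 100, 99.49, 97, 15),
      c("PT", 92, 92, 99.50, 92, 13), c("TA", 100, 100, 100, 100, 15)),
    "200X" = list(
      c("A", 92, 92, 99.49, 92, 12), c("DC", 89, 94, 90.6, 91, 90),
      c("F", 86, 86, 97.77, 86, 28), c("LC", 71, 71, 97.37, 71, 17),
      c("MC", 88, 75, 98.93, 81, 20), c("PC", 100, 86, 100, 92, 14),
      c("PT", 100, 83, 100, 91, 12), c("TA", 93, 100, 99.48, 97, 14)),
    "400X" = list(
      c("A", 100, 100, 100, 100, 11), c("DC", 89, 95, 91.74, 92, 80),
      c("F", 85, 88, 97.56, 86, 25), c("LC", 77, 67, 98.28, 71, 15),
      c("MC", 89, 94, 98.83, 92, 18), c("PC", 100, 80, 100, 89, 15),
      c("PT", 100, 83, 100, 91, 12), c("TA", 85, 85, 98.86, 85, 13)),
    abort(sprintf("Unknown magnification '%s'.", mag),
          class = "ecsanet_invalid_input"))
  purrr::map_dfr(rows, function(r)
    tibble::tibble(label = r[1], precision = as.numeric(r[2]),
                   sensitivity = as.numeric(r[3]),
                   specificity = as.numeric(r[4]), f1 = as.numeric(r[5]),
                   support = as.integer(r[6])))
}

#' Count-level balancing summary for published class counts
#'
#' Applies the stratified 70% training split (floor rounding) and the
#' balancing target rule (three times the largest training class) to a
#' class-count table, without touching any images.
#'
#' @param counts Tibble with columns `label`, `n` (e.g. one magnification of
#'   [breakhis_class_distribution()]).
#' @param train_ratio Training fraction (default 0.7).
#' @return List with `train_counts` tibble, `plan` ([plan_balance()] result),
#'   `oversample_target`, `epoch_length`.
#' @export
balance_from_counts <- function(counts, train_ratio = 0.7) {
  train_counts <- dplyr::mutate(tibble::as_tibble(counts),
                                n = as.integer(floor(train_ratio * .data$n)))
  plan <- plan_balance(train_counts)
  list(train_counts = train_counts, plan = plan,
       oversample_target = plan$oversample_target,
       epoch_length = plan$epoch_length)
}
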