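small_cfg <- function(...) {
  architecture_config(num_classes = 3, width_scale = 0.25, depth_scale = 0.2,
                      input_side = 32L, dropout = 0, ...)
}

test_that("the published configuration emits the contracted shapes", {
  m <- assemble_ecsanet(architecture_config(), seed = 1)
  s <- model_summary(m)
  expect_equal(s$stage_channels, c(24L, 24L, 48L, 64L, 128L, 160L, 256L, 256L, 1280L))
  expect_equal(s$head_widths, c(1280L, 1024L, 1024L, 8L))
  expect_equal(s$logits_width, 8L)
  expect_equal(s$feature_side, 12L)           # 384 / 32
  expect_equal(m$class_labels, breakhis_classes)
})

test_that("width scaling rounds every stage to a multiple of 8", {
  cfg <- architecture_config(width_scale = 0.25, input_side = 32L)
  m <- assemble_ecsanet(cfg, seed = 1)
  expect_equal(m$summary$stage_channels, c(8L, 8L, 16L, 16L, 32L, 40L, 64L, 64L, 320L))
  cfg2 <- architecture_config(num_classes = 2, width_scale = 0.25, input_side = 32L)
  m2 <- assemble_ecsanet(cfg2, seed = 1)
  expect_equal(m2$summary$logits_width, 2L)
  expect_equal(m2$summary$stage_channels, m$summary$stage_channels)
})

test_that("configuration contracts are enforced", {
  expect_error(architecture_config(num_classes = 1), class = "ecsanet_config_error")
  expect_error(architecture_config(width_scale = 1.5), class = "ecsanet_config_error")
  expect_error(architecture_config(width_scale = 0.5, pretrained = TRUE),
               class = "ecsanet_config_error")
  expect_error(architecture_config(input_side = 100L), class = "ecsanet_config_error")
  expect_error(build_backbone(architecture_config(pretrained = TRUE)),
               class = "ecsanet_config_error")
})

test_that("forward emits finite deterministic logits and checks shapes", {
  m <- assemble_ecsanet(small_cfg(), seed = 2, class_labels = c("a", "b", "c"))
  x <- array(0, dim = c(32, 32, 3, 2))
  l1 <- predict(m, x)
  expect_equal(dim(l1), c(2L, 3L))
  expect_true(all(is.finite(l1)))
  expect_identical(l1, predict(m, x))        # inference is deterministic
  expect_error(predict(m, array(0, dim = c(64, 64, 3, 1))), "32",
               class = "ecsanet_shape_error")
})

test_that("saturated attention gates reduce to the attention-free network", {
  cfg <- small_cfg()
  m <- assemble_ecsanet(cfg, seed = 3)
  # saturate both CBAM gates
  ci <- which(vapply(m$net$layers, function(l) identical(l$name, "cbam"), TRUE))
  m_sat <- m
  m_sat$net$layers[[ci]]$params$b2 <- rep(50, m$net$layers[[ci]]$c)
  m_sat$net$layers[[ci]]$params$b_sp <- 50
  # identical weights with the CBAM stage excised
  m_no <- m
  m_no$net$layers <- m$net$layers[-ci]
  x <- withr::with_seed(4, array(rnorm(32 * 32 * 3), dim = c(32, 32, 3, 1)))
  expect_lt(max(abs(predict(m_sat, x) - predict(m_no, x))), 1e-3)
})

test_that("intermediate feature maps respect the spatial contract", {
  m <- assemble_ecsanet(small_cfg(), seed = 5)
  x <- array(0, dim = c(32, 32, 3, 1))
  f6 <- feature_map(m, x, "stage6")
  expect_equal(dim(f6), c(1L, 1L, 64L, 1L))  # 32 / 32 = 1
  fc <- feature_map(m, x, "cbam")
  expect_equal(dim(fc), dim(f6))
  expect_error(feature_map(m, x, "nope"), class = "ecsanet_invalid_input")
})

test_that("ablation variants remove exactly one component", {
  cfg <- small_cfg()
  full <- assemble_ecsanet(cfg, seed = 6)
  no_fc <- assemble_ecsanet(ablation_variant(cfg, "fc_layers"), seed = 6)
  expect_equal(no_fc$summary$head_widths, c(320L, 3L))
  expect_lt(no_fc$summary$total_parameters, full$summary$total_parameters)

  no_cbam <- assemble_ecsanet(ablation_variant(cfg, "cbam"), seed = 6)
  expect_equal(length(no_cbam$summary$stage_channels),
               length(full$summary$stage_channels) - 1L)
  expect_lt(no_cbam$summary$total_parameters, full$summary$total_parameters)

  ns <- ablation_variant(cfg, "stain_norm")
  expect_false(ns$pipeline$stain_norm)
  expect_true(ns$pipeline$balance_aug)
  expect_null(configure_stream(ns, side = 32L)$stain_target)

  aa <- ablation_variant(cfg, "all_aug")
  sc <- configure_stream(aa, side = 32L)
  expect_false(sc$balance_aug); expect_false(sc$geometric_aug)
  expect_error(ablation_variant(cfg, "everything"), class = "ecsanet_config_error")
})

test_that("checkpoints round-trip through disk", {
  m <- assemble_ecsanet(small_cfg(), seed = 7, class_labels = c("x", "y", "z"))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_checkpoint(path)
  x <- withr::with_seed(8, array(rnorm(32 * 32 * 3), dim = c(32, 32, 3, 1)))
  expect_identical(predict(back, x), predict(m, x))
})
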