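# Network assembly: stage/bottleneck shape arithmetic, skip-residue wiring,
# seeded rebuild identity, parameter-count monotonicity, config validation,
# variant construction, and checkpoint round trips.

test_that("encoder produces the documented skip and bottleneck geometry", {
  cfg <- tiny_config(seed = 2)
  m <- build_model(cfg)
  x <- array(stats::rnorm(1 * 1 * 64 * 64), c(1, 1, 64, 64))
  enc <- encoder_forward(m, x)
  expect_identical(dim(enc$skips[[1]]), c(1L, 8L, 32L, 32L))
  expect_identical(dim(enc$skips[[2]]), c(1L, 16L, 16L, 16L))
  expect_identical(dim(enc$skips[[3]]), c(1L, 32L, 8L, 8L))
  expect_identical(dim(enc$bottleneck), c(1L, 32L, 4L, 4L))

  logits <- decoder_forward(m, enc$bottleneck, enc$skips)
  expect_identical(dim(logits), c(1L, 4L, 64L, 64L))
  expect_true(all(is.finite(logits)))

  # 224-pixel geometry: three halvings then patching, channels x4
  cfg224 <- model_config(input_size = 224, base_channels = 64, patch_size = 2)
  expect_equal(cfg224$input_size %/% 8L, 28L)
  expect_error(model_config(input_size = 100), "divisible")
  expect_error(model_config(input_size = 64, patch_size = 3), "patch_size")
})

test_that("all-zero input stays finite through the normalised transformer path", {
  m <- build_model(tiny_fast_config(seed = 3))
  x <- array(0, c(1, 1, 32, 32))
  logits <- predict(m, x, type = "logits")
  expect_true(all(is.finite(logits)))
})

test_that("encoder MIPC flag changes values but not shapes, and adds parameters", {
  cfg_on <- tiny_fast_config(seed = 4, use_encoder_mipc = TRUE)
  cfg_off <- tiny_fast_config(seed = 4, use_encoder_mipc = FALSE)
  m_on <- build_model(cfg_on)
  m_off <- build_model(cfg_off)
  x <- array(stats::rnorm(1 * 1 * 32 * 32), c(1, 1, 32, 32))
  e_on <- encoder_forward(m_on, x)
  e_off <- encoder_forward(m_off, x)
  expect_identical(dim(e_on$bottleneck), dim(e_off$bottleneck))
  expect_false(isTRUE(all.equal(e_on$bottleneck, e_off$bottleneck)))
  expect_gt(n_parameters(m_on$layers), n_parameters(m_off$layers))
})

test_that("skip-residue injection is identity when unconfigured and additive otherwise", {
  m0 <- build_model(tiny_fast_config(seed = 5,
                                     skip_residue_layers = integer()))
  skip <- array(stats::rnorm(1 * 4 * 16 * 16), c(1, 4, 16, 16))
  dec <- array(stats::rnorm(1 * 4 * 16 * 16), c(1, 4, 16, 16))
  expect_identical(skip_residue_inject(m0, 1L, dec, skip), skip)

  m1 <- build_model(tiny_fast_config(seed = 5, skip_residue_layers = 1L))
  # zeroing the projection makes the injection vanish
  zero_params(m1$layers$sr_proj1)
  expect_equal(skip_residue_inject(m1, 1L, dec, skip), skip, tolerance = 1e-12)
  # default configuration builds exactly one injection site, at level 1
  expect_false(is.null(m1$layers$sr_mipc1))
  expect_null(m1$layers$sr_mipc2)
  expect_null(m1$layers$sr_mipc3)
  expect_error(skip_residue_inject(m1, 1L, dec[, , 1:8, , drop = FALSE], skip),
               "spatial dims")
})

test_that("same config and seed rebuild identical weights; binary heads work", {
  cfg <- tiny_fast_config(seed = 6)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  for (i in seq_along(m1$params)) {
    expect_identical(m1$params[[i]]$value, m2$params[[i]]$value)
  }

  mb <- build_model(tiny_fast_config(seed = 6, num_classes = 1L))
  x <- array(stats::runif(2 * 1 * 32 * 32), c(2, 1, 32, 32))
  logits <- predict(mb, x, type = "logits")
  expect_identical(dim(logits), c(2L, 1L, 32L, 32L))
  lab <- predict(mb, x)
  expect_true(all(lab %in% 0:1))
})

test_that("ablation grids enumerate 2, 4 and 6 distinct constructible variants", {
  base <- tiny_fast_config(seed = 7)
  g5 <- ablation_grid("mutual_inclusion", base)
  g6 <- ablation_grid("mix", base)
  g7 <- ablation_grid("skip_residue", base)
  expect_length(g5, 2); expect_length(g6, 4); expect_length(g7, 6)
  expect_false(g5$pc_net$mutual_inclusion)
  expect_true(g5$mipc_net$mutual_inclusion)
  expect_setequal(sapply(unname(g6), `[[`, "mix_variant"),
                  c("pam_cpool.cam_ppool", "pam_cpool.ppool_cam",
                    "cpool_pam.cam_ppool", "cpool_pam.ppool_cam"))
  srs <- lapply(g7, `[[`, "skip_residue_layers")
  expect_identical(unname(srs),
                   list(integer(), 1L, 2L, 3L, 1:3, integer()))
  expect_false(g7$baseline$da_skip)
  expect_false(g7$baseline$use_encoder_mipc)
  expect_true(g7$none$da_skip)

  x <- array(stats::rnorm(1 * 1 * 32 * 32), c(1, 1, 32, 32))
  for (cfg in c(g5, g6, g7)) {
    lab <- predict(build_model(cfg), x)
    expect_identical(dim(lab), c(1L, 32L, 32L))
  }
})

test_that("invalid configurations produce informative errors", {
  expect_error(tiny_fast_config(skip_residue_layers = c(1, 4)), "subset")
  expect_error(tiny_fast_config(mix_variant = "pam_only"), "mix_variant")
  expect_error(tiny_fast_config(num_classes = 0), "num_classes")
  expect_error(model_config(embed_dim = 30, transformer_heads = 4),
               "divisible")
})

test_that("checkpoints restore an identical model", {
  cfg <- tiny_fast_config(seed = 8)
  m <- build_model(cfg)
  ds <- tiny_fast_phantoms(2)
  fit <- train_model(m, ds, run_config(batch_size = 2L, epochs = 1L,
                                       seed = 8), eval_every = 0L)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  td <- dataset_tensors(ds)
  expect_identical(predict(m, td$images, type = "logits"),
                   predict(m2, td$images, type = "logits"))
  expect_error(load_checkpoint(tempfile()), "not found")
})

test_that("conv stages halve resolution and double width, and zero weights give zero", {
  m64 <- build_model(tiny_config(seed = 9))
  x <- array(stats::rnorm(1 * 1 * 64 * 64), c(1, 1, 64, 64))
  s1 <- conv_stage(m64, x, 1L)
  expect_identical(dim(s1), c(1L, 8L, 32L, 32L))
  expect_error(conv_stage(m64, s1, 1L), "input channels")

  # the halve/double law chains across all three stages at 224-pixel input
  m224 <- build_model(model_config(input_size = 224, base_channels = 8,
                                   embed_dim = 32, transformer_depth = 1,
                                   transformer_heads = 2, mlp_dim = 64,
                                   seed = 9))
  f <- array(stats::rnorm(224 * 224), c(1, 1, 224, 224))
  for (s in 1:3) f <- conv_stage(m224, f, s)
  expect_identical(dim(f), c(1L, 32L, 28L, 28L))

  mz <- build_model(tiny_fast_config(seed = 10))
  zero_params(mz$layers$stage1)
  x32 <- array(stats::rnorm(32 * 32), c(1, 1, 32, 32))
  expect_true(all(conv_stage(mz, x32, 1L) == 0))
})
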