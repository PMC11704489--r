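# The mutual-inclusion block and its parts: analytic limits at zero weights,
# equivalence with independent brute-force attention references, composition,
# shape preservation, gate boundedness and gradient flow.

ap_small <- attention_params(reduction_ratio = 2L, spatial_kernel = 3L)

test_that("channel gate: zero weights give 0.5, identity FCs give sigmoid of channel means", {
  set.seed(10)
  f <- array(rnorm(1 * 4 * 8 * 8), c(1, 4, 8, 8))
  cg <- channel_gate_layer(4, ap_small, seed = 1)
  zero_params(cg)
  g <- channel_pool_gate(f, cg)
  expect_equal(dim(g$gate), c(1, 4))
  expect_true(all(g$gate == 0.5))

  # r = 1: hidden width equals channels; set both FCs to identity
  cg1 <- channel_gate_layer(2, attention_params(reduction_ratio = 1L), seed = 1)
  cg1$fc1$W$value <- diag(2); cg1$fc1$b$value <- c(0, 0)
  cg1$fc2$W$value <- diag(2); cg1$fc2$b$value <- c(0, 0)
  f2 <- array(0, c(1, 2, 4, 4))
  f2[1, 2, , ] <- 10
  g2 <- channel_pool_gate(f2, cg1)
  expect_equal(as.numeric(g2$gate), c(0.5, 1 / (1 + exp(-10))), tolerance = 1e-12)

  expect_error(channel_pool_gate(array(0, c(2, 2)), cg), "4-axis")
})

test_that("spatial gate: zero conv gives 0.5; constant input pools to the constant", {
  f <- array(0.3, c(1, 3, 5, 5))
  sg <- spatial_gate_layer(attention_params(spatial_kernel = 7L), seed = 2)
  zero_params(sg)
  g <- position_pool_map(f, sg)
  expect_equal(dim(g$gate), c(1, 1, 5, 5))
  expect_true(all(g$gate == 0.5))

  # max-over-channels and mean-over-channels agree on a constant input
  mx <- tn_channel_max(tn(f))$value
  mn <- tn_channel_mean(tn(f))$value
  expect_equal(mx, mn)
  expect_true(all(mx == 0.3))

  set.seed(11)
  fr <- array(rnorm(1 * 3 * 5 * 5), c(1, 3, 5, 5))
  gr <- position_pool_map(fr, spatial_gate_layer(seed = 3))
  expect_true(all(gr$gate > 0 & gr$gate < 1))
})

test_that("position attention: scale-zero identity, zero input, and oracle equivalence", {
  set.seed(12)
  f <- array(rnorm(1 * 2 * 2 * 2), c(1, 2, 2, 2))
  pam0 <- pam_layer(2, attention_params(scale_init = 0), seed = 4)
  expect_equal(position_attention(f, pam0), f, tolerance = 1e-12)

  z <- array(0, c(1, 2, 2, 2))
  pam1 <- pam_layer(2, attention_params(scale_init = 1), seed = 5)
  expect_equal(position_attention(z, pam1), z)

  # brute-force affinity-softmax reference with the same projections
  for (C in c(2L, 3L)) {
    pam <- pam_layer(C, attention_params(scale_init = 1), seed = 6 + C)
    pam$q$b$value[] <- 0; pam$k$b$value[] <- 0; pam$v$b$value[] <- 0
    x <- array(rnorm(1 * C * 2 * 2), c(1, C, 2, 2))
    ck <- max(1, C %/% 8)
    ref <- oracle_position_attention(
      x, matrix(pam$q$W$value, ck, C), matrix(pam$k$W$value, ck, C),
      matrix(pam$v$W$value, C, C), gamma = 1)
    expect_equal(position_attention(x, pam), ref, tolerance = 1e-6)
  }
})

test_that("channel attention: scale-zero identity, zero input, and oracle equivalence", {
  set.seed(13)
  f <- array(rnorm(1 * 3 * 2 * 2), c(1, 3, 2, 2))
  cam0 <- cam_layer(attention_params(scale_init = 0))
  expect_equal(channel_attention(f, cam0), f, tolerance = 1e-12)

  z <- array(0, c(1, 3, 2, 2))
  cam1 <- cam_layer(attention_params(scale_init = 1))
  expect_equal(channel_attention(z, cam1), z)

  expect_equal(channel_attention(f, cam1),
               oracle_channel_attention(f, 1), tolerance = 1e-6)
})

test_that("parts A and C: zero-weight halving, forced-gate identity, composition", {
  set.seed(14)
  f <- array(rnorm(1 * 4 * 4 * 4), c(1, 4, 4, 4))
  blk <- mipc_layer(4, attention_params(reduction_ratio = 2, spatial_kernel = 3,
                                        scale_init = 0), seed = 20)

  zblk <- mipc_layer(4, ap_small, seed = 21)
  zero_params(zblk)
  expect_equal(part_a(f, zblk), 0.5 * f, tolerance = 1e-12)
  expect_equal(part_c(f, zblk), 0.5 * f, tolerance = 1e-12)

  # gate forced to one with attention scale zero: exact identity
  expect_equal(part_a(f, blk, gate_override = 1), f, tolerance = 1e-12)
  expect_equal(part_c(f, blk, gate_override = 1), f, tolerance = 1e-12)

  # composition from independently computed sub-operations
  blk2 <- mipc_layer(4, ap_small, seed = 22)
  gate <- channel_pool_gate(f, blk2$channel_gate)$gate
  pam_out <- position_attention(f, blk2$pam)
  manual_a <- pam_out * array(gate, dim(f))
  expect_equal(part_a(f, blk2), manual_a, tolerance = 1e-9)

  sgate <- position_pool_map(f, blk2$spatial_gate)$gate
  cam_out <- channel_attention(f, blk2$cam)
  manual_c <- cam_out * sgate[, rep(1, 4), , , drop = FALSE]
  expect_equal(part_c(f, blk2), manual_c, tolerance = 1e-9)
})

test_that("part B: zero convs give zero, identity convs square the input, oracle conv", {
  set.seed(15)
  f <- array(rnorm(1 * 2 * 4 * 4), c(1, 2, 4, 4))
  pb <- part_b_layer(2, seed = 30)
  zero_params(pb)
  expect_true(all(part_b(f, pb) == 0))

  # single-channel identity 1x1-like configuration inside 3x3 kernels
  f1 <- array(rnorm(1 * 1 * 4 * 4), c(1, 1, 4, 4))
  pb1 <- part_b_layer(1, seed = 31)
  zero_params(pb1)
  pb1$conv_a$W$value[1, 1, 2, 2] <- 1  # centre tap = identity
  pb1$conv_c$W$value[1, 1, 2, 2] <- 1
  pb1$conv_out$W$value[1, 1, 2, 2] <- 1
  expect_equal(part_b(f1, pb1), f1 * f1, tolerance = 1e-12)

  # direct convolution reference for one output position
  pb2 <- part_b_layer(2, seed = 32)
  got <- part_b(f, pb2)
  a <- tn_conv2d(tn(f), pb2$conv_a$W, pb2$conv_a$b)$value
  c2 <- tn_conv2d(tn(f), pb2$conv_c$W, pb2$conv_c$b)$value
  Wv <- pb2$conv_out$W$value
  prod <- a * c2
  ref_22 <- pb2$conv_out$b$value[1]
  for (ci in 1:2) for (di in 1:3) for (dj in 1:3) {
    ref_22 <- ref_22 + Wv[1, ci, di, dj] * prod[1, ci, 1 + di, 1 + dj]
  }
  expect_equal(got[1, 1, 3, 3], ref_22, tolerance = 1e-9)
})

test_that("residual tail: zero weights reduce to relu, zero input maps to zero", {
  set.seed(16)
  f <- array(rnorm(1 * 3 * 4 * 4), c(1, 3, 4, 4))
  rt <- residual_tail_layer(3, seed = 40)
  zero_params(rt)
  rt$bn1$gamma$value[] <- 1; rt$bn2$gamma$value[] <- 1
  expect_equal(residual_tail(f, rt), pmax(f, 0), tolerance = 1e-9)
  expect_true(all(residual_tail(array(0, dim(f)), rt) == 0))
})

test_that("mipc block: zero-weight configuration equals relu, composition holds", {
  set.seed(17)
  f <- array(rnorm(1 * 4 * 8 * 8), c(1, 4, 8, 8))
  zblk <- mipc_layer(4, ap_small, seed = 50)
  zero_params(zblk)
  zblk$tail$bn1$gamma$value[] <- 1; zblk$tail$bn2$gamma$value[] <- 1
  # parts A and C each contribute 0.5 f, part B zero, tail is a relu shortcut
  expect_equal(mipc_block(f, zblk), pmax(f, 0), tolerance = 1e-9)

  blk <- mipc_layer(4, ap_small, seed = 51)
  manual <- residual_tail(part_a(f, blk) + part_b(f, blk) + part_c(f, blk),
                          blk$tail)
  expect_equal(mipc_block(f, blk), manual, tolerance = 1e-9)
})

test_that("da block: identity branches double the input, composition holds", {
  set.seed(18)
  f <- array(rnorm(1 * 3 * 4 * 4), c(1, 3, 4, 4))
  dab <- da_layer(3, attention_params(scale_init = 0), seed = 60)
  for (nm in c("p_in", "p_out", "c_in", "c_out")) {
    dab[[nm]]$W$value[] <- 0
    for (c in 1:3) dab[[nm]]$W$value[c, c, 1, 1] <- 1
    dab[[nm]]$b$value[] <- 0
  }
  expect_equal(da_block(f, dab), 2 * f, tolerance = 1e-12)
  expect_true(all(da_block(array(0, dim(f)), dab) == 0))

  dab2 <- da_layer(3, ap_small, seed = 61)
  p_branch <- tn_conv2d(tn(position_attention(
    tn_conv2d(tn(f), dab2$p_in$W, dab2$p_in$b)$value, dab2$pam)),
    dab2$p_out$W, dab2$p_out$b)$value
  c_branch <- tn_conv2d(tn(channel_attention(
    tn_conv2d(tn(f), dab2$c_in$W, dab2$c_in$b)$value, dab2$cam)),
    dab2$c_out$W, dab2$c_out$b)$value
  expect_equal(da_block(f, dab2), p_branch + c_branch, tolerance = 1e-9)
})

test_that("shape preservation and gate boundedness over random shapes", {
  set.seed(19)
  for (i in 1:5) {
    N <- sample(1:2, 1); C <- sample(c(2, 3, 5), 1)
    H <- sample(c(4, 6), 1); W <- sample(c(4, 6), 1)
    f <- array(rnorm(N * C * H * W), c(N, C, H, W))
    blk <- mipc_layer(C, ap_small, seed = 70 + i)
    dab <- da_layer(C, ap_small, seed = 80 + i)
    expect_identical(dim(mipc_block(f, blk)), dim(f))
    expect_identical(dim(da_block(f, dab)), dim(f))
    expect_identical(dim(part_a(f, blk)), dim(f))
    expect_identical(dim(part_b(f, blk)), dim(f))
    expect_identical(dim(part_c(f, blk)), dim(f))
    g <- channel_pool_gate(f, blk)$gate
    s <- position_pool_map(f, blk)$gate
    expect_true(all(g > 0 & g < 1))
    expect_true(all(s > 0 & s < 1))
  }
})

test_that("every block parameter receives a finite gradient", {
  set.seed(20)
  f <- array(rnorm(2 * 4 * 8 * 8), c(2, 4, 8, 8))
  blk <- mipc_layer(4, ap_small, seed = 90)
  ps <- collect_params(blk)
  tn_zero_grad(ps)
  loss <- tn_sum(tn_mul(mipc_fwd(blk, tn(f), train = TRUE),
                        tn(array(rnorm(length(f)), dim(f)))))
  tn_backward(loss)
  for (p in ps) {
    expect_false(is.null(p$grad), info = p$name)
    expect_true(all(is.finite(p$grad)), info = p$name)
  }
})

test_that("all four mix variants compute and preserve shape", {
  set.seed(21)
  f <- array(rnorm(1 * 4 * 4 * 4), c(1, 4, 4, 4))
  for (v in c("pam_cpool.cam_ppool", "pam_cpool.ppool_cam",
              "cpool_pam.cam_ppool", "cpool_pam.ppool_cam")) {
    blk <- mipc_layer(4, ap_small, seed = 100, mix_variant = v)
    out <- mipc_block(f, blk)
    expect_identical(dim(out), dim(f))
    expect_true(all(is.finite(out)))
  }
  expect_error(mipc_layer(4, ap_small, mix_variant = "bogus"), "mix_variant")
})
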