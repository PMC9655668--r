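# Channel and spatial attention operators against scalar brute-force oracles
# and their closed-form special cases.

test_that("global pooling matches closed forms and loop oracles", {
  x <- array(c(1, 2, 3, 4), c(1, 1, 2, 2))
  x[1, 1, , ] <- matrix(c(1, 2, 3, 4), 2, byrow = TRUE)
  expect_equal(global_average_pool(x)[1, 1], 2.5)
  expect_equal(global_max_pool(x)[1, 1], 4)

  const <- array(3.7, c(2, 3, 4, 5))
  expect_equal(global_average_pool(const), matrix(3.7, 2, 3))

  neg <- -abs(random_feature_map(11, c(1, 2, 3, 3))) - 1
  expect_equal(global_max_pool(neg), oracle_gmp(neg))

  set.seed(5)
  big <- array(rnorm(512 * 13 * 13), c(1, 512, 13, 13))
  expect_equal(global_average_pool(big), oracle_gap(big), tolerance = 1e-6)
  expect_equal(global_max_pool(big), oracle_gmp(big))

  expect_error(global_average_pool(array(Inf, c(1, 1, 2, 2))), "finite")
  expect_error(global_average_pool(matrix(1, 2, 2)), "4-D")
})

test_that("SE excitation: zero weights give 0.5 gates and random weights match the scalar oracle", {
  w0 <- mlp_weights(4, 2, W1 = matrix(0, 2, 4), W2 = matrix(0, 4, 2))
  expect_equal(se_excitation(c(1, -2, 3, 0), w0), matrix(0.5, 1, 4))

  wi <- mlp_weights(2, 1, W1 = diag(2), W2 = diag(2))
  expect_equal(se_excitation(c(0, 0), wi), matrix(0.5, 1, 2))

  set.seed(21)
  w <- mlp_weights(4, 2)
  z <- matrix(rnorm(3 * 4), 3, 4)
  expect_equal(se_excitation(z, w), oracle_se(z, w), tolerance = 1e-6)
  expect_error(se_excitation(c(1, 2, 3), w), "does not match")
})

test_that("CAM shares one MLP across the two pooled branches", {
  x <- random_feature_map(31, c(2, 4, 3, 3))
  w0 <- mlp_weights(4, 2, W1 = matrix(0, 2, 4), W2 = matrix(0, 4, 2))
  expect_equal(cam_attention(x, w0), matrix(0.5, 2, 4))

  # constant map: avg = max = c, so P = sigma(2 MLP(c 1))
  set.seed(32)
  w <- mlp_weights(4, 2)
  cc <- array(1.3, c(1, 4, 2, 2))
  expect_equal(cam_attention(cc, w),
               matrix(sigmoid(2 * oracle_mlp(rep(1.3, 4), w)), 1),
               tolerance = 1e-12)
  expect_equal(cam_attention(x, w), oracle_cam(x, w), tolerance = 1e-6)
})

test_that("ECAM descriptor gates the average pool through sigmoid(max)", {
  z0 <- array(0, c(1, 2, 3, 3))
  expect_equal(ecam_descriptor(z0), matrix(0, 1, 2))
  one <- array(1, c(1, 1, 2, 2))
  expect_equal(ecam_descriptor(one)[1, 1], 0.731059, tolerance = 1e-6)
  x <- array(0, c(1, 1, 2, 2))
  x[1, 1, , ] <- matrix(c(1, 2, 3, 4), 2, byrow = TRUE)
  expect_equal(ecam_descriptor(x)[1, 1], 2.455034, tolerance = 1e-6)
})

test_that("ECAM attention uses one MLP and reduces bitwise to SE when the gate is forced to 1", {
  set.seed(40)
  x <- random_feature_map(40)
  w0 <- mlp_weights(8, 2, W1 = matrix(0, 4, 8), W2 = matrix(0, 8, 4))
  expect_equal(ecam_attention(x, w0), matrix(0.5, 4, 8))

  w <- mlp_weights(8, 2)
  expect_identical(ecam_attention(x, w, max_gate = "one"),
                   se_excitation(global_average_pool(x), w))
  expect_equal(ecam_attention(x, w),
               oracle_se(oracle_ecam_desc(x), w), tolerance = 1e-6)
})

test_that("ECAM gate is strictly increasing in the max descriptor for positive averages", {
  # fixed z_c > 0, sweep m_c
  z <- 2.0
  m <- seq(-4, 4, length.out = 50)
  vals <- sigmoid(m) * z
  expect_true(all(diff(vals) > 0))
})

test_that("ECA: identity kernel, zero kernel, adaptive size", {
  x <- random_feature_map(50, c(2, 8, 4, 4))
  expect_equal(eca_attention(x, weights = rep(0, 3)), matrix(0.5, 2, 8))
  expect_equal(eca_attention(x, weights = 1, kernel = 1),
               sigmoid(global_average_pool(x)))
  expect_equal(eca_kernel_size(512), 5L)
  expect_equal(attention_param_count(attention_config("eca", channels = 512)), 5L)
  set.seed(51)
  wk <- rnorm(5)
  expect_equal(eca_attention(x, weights = wk, kernel = 5), oracle_eca(x, wk),
               tolerance = 1e-6)
  expect_error(eca_attention(x, kernel = 4), "odd")
})

test_that("spatial attention matches a direct convolution oracle", {
  t <- random_feature_map(60, c(2, 3, 5, 5))
  w0 <- sam_weights(3, w = array(0, c(1, 2, 3, 3)), b = 0)
  expect_equal(spatial_attention(t, w0), array(0.5, c(2, 1, 5, 5)))

  # single channel: avg = max = t; center tap on the avg channel passes t through
  t1 <- random_feature_map(61, c(1, 1, 4, 4))
  wc <- array(0, c(1, 2, 3, 3)); wc[1, 1, 2, 2] <- 1
  expect_equal(spatial_attention(t1, sam_weights(3, w = wc, b = 0))[1, 1, , ],
               sigmoid(t1[1, 1, , ]), tolerance = 1e-12)

  set.seed(62)
  w <- sam_weights(3)
  expect_equal(spatial_attention(t, w), oracle_sam(t, w), tolerance = 1e-5)
  expect_error(sam_weights(4), "odd")
})

test_that("channel gates rescale features exactly", {
  x <- random_feature_map(70, c(2, 3, 4, 4))
  expect_identical(apply_channel_attention(x, matrix(1, 2, 3)), x)
  expect_equal(apply_channel_attention(x, matrix(0, 2, 3)), x * 0)
  p <- matrix(runif(6), 2, 3)
  expect_equal(apply_channel_attention(x, p), oracle_apply_channel(x, p),
               tolerance = 1e-12)
  expect_error(apply_channel_attention(x, matrix(1, 2, 4)), "does not match")
})

test_that("ECBAM/CBAM: zero weights scale by 0.25, shapes are preserved, composition matches oracles", {
  cfg <- attention_config("ecbam", channels = 6, reduction = 2,
                          spatial_kernel = 3)
  w0 <- mlp_weights(6, 2, W1 = matrix(0, 3, 6), W2 = matrix(0, 6, 3))
  s0 <- sam_weights(3, w = array(0, c(1, 2, 3, 3)), b = 0)
  for (d in list(c(1, 6, 3, 3), c(2, 6, 5, 4), c(3, 6, 2, 7))) {
    x <- random_feature_map(80 + d[1], d)
    out <- ecbam_forward(x, cfg, w0, s0)
    expect_equal(dim(out), d)
    expect_equal(out, 0.25 * x, tolerance = 1e-12)
  }

  set.seed(90)
  x <- random_feature_map(90, c(2, 6, 4, 4))
  w <- mlp_weights(6, 2); s <- sam_weights(3)
  for (kind in c("ecbam", "cbam")) {
    cfgk <- attention_config(kind, channels = 6, reduction = 2,
                             spatial_kernel = 3)
    p <- if (kind == "ecbam") oracle_se(oracle_ecam_desc(x), w)
         else oracle_cam(x, w)
    t <- oracle_apply_channel(x, p)
    ps <- oracle_sam(t, s)
    ref <- t
    for (c in 1:6) ref[, c, , ] <- t[, c, , ] * ps[, 1, , ]
    expect_equal(ecbam_forward(x, cfgk, w, s), ref, tolerance = 1e-6)
  }
})

test_that("attention gates always lie strictly inside (0, 1)", {
  for (seed in 1:20) {
    x <- random_feature_map(seed) * 5
    w <- mlp_weights(8, 4)
    gates <- rbind(se_excitation(global_average_pool(x), w),
                   cam_attention(x, w), ecam_attention(x, w),
                   eca_attention(x, kernel = 3))
    expect_true(all(gates > 0 & gates < 1))
    s <- spatial_attention(x, sam_weights(3))
    expect_true(all(s > 0 & s < 1))
  }
})

test_that("attention parameter counts follow the enumerated weight shapes", {
  expect_equal(attention_param_count(attention_config("ecam")), 33312L)
  expect_equal(attention_param_count(attention_config("sam")), 99L)
  expect_equal(attention_param_count(attention_config("ecbam")), 33411L)
  expect_lt(attention_param_count(attention_config("ecbam")) / 1e6, 0.04)
  expect_equal(attention_param_count(attention_config("none")), 0L)
  expect_error(attention_config("bogus"), "unknown")
})
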