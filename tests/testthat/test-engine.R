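# The C++ compute engine against pure-R oracles: layer forwards, the
# attention encoders as instruction tapes, and finite-difference gradients.

ne <- asNamespace("encanet")

build_single_op_net <- function(build) {
  nb <- ne$new_net()
  out <- build(nb)
  ne$nb_finish(nb, outputs = list(out = out))
}

run_net <- function(net, params, x, training = FALSE) {
  st <- ne$init_net_state(net)
  ne$net_forward(net, params, st, x, training = training,
                 precision = "double")$values$out
}

test_that("engine convolution matches the quadruple-loop oracle across strides, padding and dilation", {
  set.seed(1)
  cases <- list(list(k = 1, s = 1, p = 0, d = 1), list(k = 3, s = 1, p = 1, d = 1),
                list(k = 3, s = 2, p = 1, d = 1), list(k = 5, s = 1, p = 4, d = 2),
                list(k = 3, s = 1, p = 2, d = 2))
  for (cs in cases) {
    net <- build_single_op_net(function(nb)
      ne$nb_conv(nb, 1L, 3, 4, cs$k, stride = cs$s, pad = cs$p,
                 dilation = cs$d, bias = TRUE, name = "c", group = "g"))
    params <- ne$init_net_params(net, seed = 2)
    params[["c.b"]] <- rnorm(4)
    x <- array(rnorm(2 * 3 * 8 * 8), c(2, 3, 8, 8))
    ref <- oracle_conv2d(x, params[["c.w"]], params[["c.b"]],
                         stride = cs$s, pad = cs$p, dil = cs$d)
    expect_equal(run_net(net, params, x), ref, tolerance = 1e-10)
  }
})

test_that("engine depthwise convolution matches its loop oracle", {
  set.seed(3)
  for (cs in list(list(k = 3, s = 1, p = 1), list(k = 5, s = 2, p = 2))) {
    net <- build_single_op_net(function(nb)
      ne$nb_dwconv(nb, 1L, 4, cs$k, stride = cs$s, pad = cs$p,
                   name = "dw", group = "g"))
    params <- ne$init_net_params(net, seed = 4)
    x <- array(rnorm(2 * 4 * 9 * 9), c(2, 4, 9, 9))
    ref <- oracle_dwconv(x, params[["dw.w"]], stride = cs$s, pad = cs$p)
    expect_equal(run_net(net, params, x), ref, tolerance = 1e-10)
  }
})

test_that("engine batch norm matches the closed form in training and eval modes", {
  net <- build_single_op_net(function(nb)
    ne$nb_bn(nb, 1L, 3, "bn", "g", eps = 1e-3, momentum = 0.1))
  params <- ne$init_net_params(net, seed = 5)
  params[["bn.gamma"]] <- c(1.5, 0.5, 2)
  params[["bn.beta"]] <- c(0.1, -0.2, 0)
  set.seed(6)
  x <- array(rnorm(4 * 3 * 5 * 5, mean = 2, sd = 3), c(4, 3, 5, 5))
  st <- ne$init_net_state(net)
  res <- ne$net_forward(net, params, st, x, training = TRUE, precision = "double")
  for (c in 1:3) {
    v <- x[, c, , ]
    m <- mean(v); va <- mean((v - m)^2)
    ref <- params[["bn.gamma"]][c] * (x[, c, , ] - m) / sqrt(va + 1e-3) +
      params[["bn.beta"]][c]
    expect_equal(res$values$out[, c, , ], ref, tolerance = 1e-8)
    # running stats: one momentum-0.1 update from (0, 1)
    expect_equal(res$state[["bn.rmean"]][c], 0.1 * m, tolerance = 1e-8)
    expect_equal(res$state[["bn.rvar"]][c],
                 0.9 + 0.1 * va * 100 / 99, tolerance = 1e-8)
  }
  # eval mode uses the running statistics
  res2 <- ne$net_forward(net, params, res$state, x, training = FALSE,
                         precision = "double")
  for (c in 1:3) {
    ref <- params[["bn.gamma"]][c] *
      (x[, c, , ] - res$state[["bn.rmean"]][c]) /
      sqrt(res$state[["bn.rvar"]][c] + 1e-3) + params[["bn.beta"]][c]
    expect_equal(res2$values$out[, c, , ], ref, tolerance = 1e-8)
  }
})

test_that("engine attention encoders reproduce the pure-R operators", {
  set.seed(7)
  x <- array(rnorm(2 * 8 * 5 * 5), c(2, 8, 5, 5))
  for (kind in c("se", "cam", "ecam", "eca", "sam", "cbam", "ecbam")) {
    nb <- ne$new_net()
    acfg <- attention_config(kind, channels = 8, reduction = 2,
                             spatial_kernel = 3)
    out <- ne$build_attention_encoder(nb, 1L, acfg)
    net <- ne$nb_finish(nb, outputs = list(out = out))
    params <- ne$init_net_params(net, seed = 8)
    eng <- run_net(net, params, x)
    pr <- function(n) params[[n]]
    w <- if (kind %in% c("se", "cam", "ecam", "cbam", "ecbam"))
      mlp_weights(8, 2, W1 = matrix(pr("encoder.mlp.fc1.w"), 4, 8),
                  b1 = pr("encoder.mlp.fc1.b"),
                  W2 = matrix(pr("encoder.mlp.fc2.w"), 8, 4),
                  b2 = pr("encoder.mlp.fc2.b"))
    ref <- switch(kind,
      se = apply_channel_attention(x, se_excitation(global_average_pool(x), w)),
      cam = apply_channel_attention(x, cam_attention(x, w)),
      ecam = apply_channel_attention(x, ecam_attention(x, w)),
      eca = apply_channel_attention(x, eca_attention(x, weights = pr("encoder.eca.w"))),
      sam = apply_spatial_attention(x, spatial_attention(x,
        sam_weights(3, w = pr("encoder.sam.conv.w"), b = pr("encoder.sam.conv.b")))),
      cbam = ecbam_forward(x, acfg, w,
        sam_weights(3, w = pr("encoder.sam.conv.w"), b = pr("encoder.sam.conv.b"))),
      ecbam = ecbam_forward(x, acfg, w,
        sam_weights(3, w = pr("encoder.sam.conv.w"), b = pr("encoder.sam.conv.b"))))
    expect_equal(eng, ref, tolerance = 1e-10,
                 label = paste("engine", kind))
  }
})

test_that("single-precision path agrees with the double path", {
  set.seed(9)
  nb <- ne$new_net()
  out <- ne$build_attention_encoder(nb, 1L, attention_config("ecbam",
    channels = 8, reduction = 2, spatial_kernel = 3))
  net <- ne$nb_finish(nb, outputs = list(out = out))
  params <- ne$init_net_params(net, seed = 10)
  st <- ne$init_net_state(net)
  x <- array(rnorm(2 * 8 * 5 * 5), c(2, 8, 5, 5))
  d <- ne$net_forward(net, params, st, x, precision = "double")$values$out
  f <- ne$net_forward(net, params, st, x, precision = "float")$values$out
  expect_equal(f, d, tolerance = 1e-5)
})

test_that("engine backward gradients agree with finite differences", {
  nb <- ne$new_net()
  v <- ne$nb_conv(nb, 1L, 3, 4, 3, stride = 2, pad = 1, bias = TRUE,
                  name = "c1", group = "g")
  v <- ne$nb_bn(nb, v, 4, "bn1", "g")
  v <- ne$nb_act(nb, v, "silu")
  v <- ne$nb_dwconv(nb, v, 4, 3, pad = 1, name = "dw", group = "g")
  d <- ne$nb_gap(nb, v)
  d <- ne$nb_conv(nb, d, 4, 2, 1, bias = TRUE, name = "fc1", group = "g")
  d <- ne$nb_act(nb, d, "relu")
  d <- ne$nb_conv(nb, d, 2, 4, 1, bias = TRUE, name = "fc2", group = "g")
  d <- ne$nb_act(nb, d, "sigmoid")
  v <- ne$nb_mul(nb, v, d)
  s <- ne$nb_chstat(nb, v)
  s <- ne$nb_conv(nb, s, 2, 1, 3, pad = 1, bias = TRUE, name = "sam", group = "g")
  s <- ne$nb_act(nb, s, "sigmoid")
  v <- ne$nb_mul(nb, v, s)
  net <- ne$nb_finish(nb, outputs = list(out = v))
  params <- ne$init_net_params(net, seed = 11)
  st <- ne$init_net_state(net)
  set.seed(12)
  x <- array(rnorm(2 * 3 * 8 * 8), c(2, 3, 8, 8))
  r0 <- ne$net_forward(net, params, st, x, training = TRUE, keep_cache = TRUE,
                       precision = "double")
  wts <- array(rnorm(length(r0$values$out)), dim(r0$values$out))
  pg <- ne$net_backward(r0$cache, list(wts), unlist(net$outputs))
  lossfn <- function(p) {
    sum(ne$net_forward(net, p, st, x, training = TRUE,
                       precision = "double")$values$out * wts)
  }
  h <- 1e-5
  set.seed(13)
  for (i in seq_along(params)) {
    for (j in sample(length(params[[i]]), min(3, length(params[[i]])))) {
      pp <- params; pp[[i]][j] <- pp[[i]][j] + h
      pm <- params; pm[[i]][j] <- pm[[i]][j] - h
      gn <- (lossfn(pp) - lossfn(pm)) / (2 * h)
      expect_equal(pg[[i]][j], gn, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", names(params)[i], j))
    }
  }
})
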