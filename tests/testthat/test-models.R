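test_that("network spec validates its invariants", {
  expect_error(network_spec(c(8, 4)), "increasing")
  expect_error(network_spec(c(4, 8), dense_blocks = 4), "dense_blocks")
  expect_error(network_spec(c(4, 8), input_size = 9), "divisible")
  expect_error(network_spec(c(4, 8), growth = 0.5), "growth")
  sp <- network_spec()
  expect_equal(sp$stage_widths, 2^(4:10))
  expect_equal(sp$growth, pmin(2^(4:10) / 8, 26))   # calibrated auto convention
})

test_that("forward pass satisfies the shape and softmax contracts", {
  set.seed(11)
  net <- build_dense_unet(tiny_spec(dense_blocks = 1, input_size = 16))
  x <- matrix(rnorm(16 * 16), 16, 16)
  p <- predict_slice(net, x)
  expect_equal(dim(p), c(16, 16, 3))
  expect_true(all(p >= 0 & p <= 1))
  expect_lt(max(abs(apply(p, c(1, 2), sum) - 1)), 1e-5)
  lab <- apply(p, c(1, 2), which.max) - 1L
  expect_true(all(lab %in% 0:2))
  expect_error(predict_slice(net, matrix(0, 8, 8)), "16x16")
  # deterministic under a fixed init seed
  set.seed(11)
  net2 <- build_dense_unet(tiny_spec(dense_blocks = 1, input_size = 16))
  expect_identical(predict_slice(net2, x), p)
})

test_that("parameter counts match layer-by-layer hand enumeration", {
  # lone 3x3 conv, 1 -> 16 channels, with bias
  expect_equal(oracle_conv(3, 1, 16), 160)
  for (spec in list(tiny_spec(dense_blocks = 0, n_classes = 1),
                    tiny_spec(dense_blocks = 1),
                    tiny_spec(dense_blocks = 2, widths = c(2, 4), growth = 1),
                    network_spec(c(4, 8, 16), dense_blocks = 3, growth = 2,
                                 input_size = 16))) {
    net <- if (spec$dense_blocks == 0) build_classical_unet(spec)
    else build_dense_unet(spec)
    expect_equal(count_parameters(net), oracle_count(spec))
  }
})

test_that("parameter count is independent of input size (fully convolutional)", {
  s1 <- tiny_spec(dense_blocks = 2, input_size = 8)
  s2 <- tiny_spec(dense_blocks = 2, input_size = 32)
  expect_equal(count_parameters(build_dense_unet(s1)),
               count_parameters(build_dense_unet(s2)))
})

test_that("dense blocks concatenate all previous layer outputs", {
  # single block, 1 input channel, growth 2: layer i sees 1 + 2*(i-1) channels
  spec <- network_spec(c(4, 8), dense_blocks = 1, growth = 2, input_size = 8,
                       n_classes = 2)
  net <- build_dense_unet(spec)
  convs <- Filter(function(nd) nd$op == "conv", net$nodes)
  first_block_cins <- vapply(convs[1:4], `[[`, numeric(1), "cin")
  expect_equal(first_block_cins, c(1, 3, 5, 7))
  # the transition that follows compresses input + 4 layers to the stage width
  expect_equal(convs[[5]]$k, 1)
  expect_equal(convs[[5]]$cin, 1 + 4 * 2)
  expect_equal(convs[[5]]$cout, 4)
})

test_that("builders reject mismatched specs", {
  expect_error(build_classical_unet(tiny_spec(dense_blocks = 1)), "dense_blocks = 0")
  expect_error(build_dense_unet(tiny_spec(dense_blocks = 0)), ">= 1")
})

test_that("one optimisation step decreases the training loss for every variant", {
  set.seed(3)
  x <- array(rnorm(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  cls <- array(sample(0:2, 8 * 8 * 2, TRUE), c(8, 8, 2))
  tt <- array(0, c(8, 8, 3, 2))
  for (ch in 1:3) tt[, , ch, ] <- cls == (ch - 1)
  lc <- loss_config("cross_entropy")
  for (X in 0:3) {
    spec <- tiny_spec(dense_blocks = X)
    net <- if (X == 0) build_classical_unet(spec) else build_dense_unet(spec)
    st <- adam_init_for_test(net)
    fw <- nn_forward_for_test(net, x)
    l0 <- combined_loss(fw$out, tt, lc)
    pg <- nn_backward_for_test(net, fw, combined_loss_grad_for_test(fw$out, tt, lc))
    upd <- adam_step_for_test(net, pg, st, 1e-3)
    l1 <- combined_loss(nn_forward_for_test(upd$net, x)$out, tt, lc)
    expect_lt(l1, l0, label = sprintf("X=%d", X))
  }
})

test_that("backpropagated gradients match finite differences", {
  set.seed(21)
  spec <- network_spec(c(3, 5), dense_blocks = 1, growth = 2, input_size = 8,
                       n_classes = 2)
  net <- build_dense_unet(spec)
  x <- array(rnorm(8 * 8 * 1 * 1), c(8, 8, 1, 1))
  cls <- array(sample(0:1, 64, TRUE), c(8, 8, 1))
  tt <- array(0, c(8, 8, 2, 1))
  for (ch in 1:2) tt[, , ch, 1] <- cls[, , 1] == (ch - 1)
  lc <- loss_config("dice+ce")
  fw <- nn_forward_for_test(net, x)
  pg <- nn_backward_for_test(net, fw, combined_loss_grad_for_test(fw$out, tt, lc))
  loss_of <- function(n) combined_loss(nn_forward_for_test(n, x)$out, tt, lc)
  for (nd in net$nodes) {
    if (is.null(nd$W)) next
    i <- sample(length(nd$W), 1)
    eps <- 1e-6
    np <- net; np$nodes[[nd$id]]$W[i] <- np$nodes[[nd$id]]$W[i] + eps
    nm <- net; nm$nodes[[nd$id]]$W[i] <- nm$nodes[[nd$id]]$W[i] - eps
    num <- (loss_of(np) - loss_of(nm)) / (2 * eps)
    expect_lt(abs(num - pg[[nd$id]]$dw[i]), 1e-5 * max(1, abs(num)),
              label = sprintf("node %d (%s)", nd$id, nd$op))
  }
})
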