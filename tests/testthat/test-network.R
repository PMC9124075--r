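test_that("dense blocks and transitions follow the channel bookkeeping exactly", {
  set.seed(1)
  x <- array(rnorm(4 * 4 * 64), c(4, 4, 64))
  y <- dense_block_forward(x, n_layers = 6, k = 32, seed = 2)
  expect_equal(dim(y), c(4, 4, 64 + 6 * 32))          # 256
  x2 <- array(rnorm(4 * 4 * 128), c(4, 4, 128))
  expect_equal(dim(dense_block_forward(x2, 12, 32, seed = 2))[3], 512)
  expect_identical(dense_block_forward(x, 0, 32), x)   # empty block = identity
  # the input passes through unchanged as the first channels
  expect_equal(y[, , 1:64], x)

  t1 <- transition_forward(array(rnorm(8 * 8 * 256), c(8, 8, 256)), 0.5, seed = 3)
  expect_equal(dim(t1), c(4, 4, 128))
  t2 <- transition_forward(array(rnorm(8 * 8 * 30), c(8, 8, 30)), 1.0, seed = 3)
  expect_equal(dim(t2)[3], 30)                        # compression 1 keeps channels
})

test_that("average pooling of a constant map returns the constant", {
  pool <- ns$layer_avgpool(2L, 2L)
  f <- ns$fm(matrix(3.25, 6 * 6, 5), 6L, 6L, 1L)
  out <- ns$net_forward(pool, f)$out
  expect_true(all(out$x == 3.25))
  expect_equal(c(out$H, out$W), c(3L, 3L))
})

test_that("squeeze statistics match hand-computed values and scaling laws", {
  # 2x2 single-channel map with values {0,0,1,1}
  x <- array(c(0, 0, 1, 1), c(2, 2, 1))
  s <- squeeze_statistics(x)
  expect_equal(unname(s[1, ]), c(0.5, 0.5, 0.25))     # mean, local max, variance
  # constant channel: (c, c, 0)
  s_const <- squeeze_statistics(array(2.5, c(4, 4, 3)))
  expect_equal(unname(s_const), cbind(rep(2.5, 3), rep(2.5, 3), rep(0, 3)),
               ignore_attr = TRUE)
  # scaling by alpha scales mean/local-max by alpha, variance by alpha^2
  set.seed(8)
  z <- array(runif(6 * 6 * 4), c(6, 6, 4))
  a <- 3.7
  s1 <- squeeze_statistics(z); s2 <- squeeze_statistics(z * a)
  expect_equal(s2[, "global_mean"], a * s1[, "global_mean"])
  expect_equal(s2[, "local_max"], a * s1[, "local_max"])
  expect_equal(s2[, "variance"], a^2 * s1[, "variance"])
  # plain squeeze: means only, length C
  expect_equal(squeeze_statistics(z, optimized = FALSE), s1[, "global_mean"],
               ignore_attr = TRUE)
})

test_that("SE gates sit at 0.5 for zero weights, stay in (0,1), and length C", {
  stats <- squeeze_statistics(array(runif(8 * 8 * 16), c(8, 8, 16)))
  zero_blk <- se_block(16, r = 4, zero_init = TRUE)
  expect_equal(se_gate(stats, zero_blk), rep(0.5, 16))
  blk <- se_block(16, r = 4, seed = 9)
  g <- se_gate(stats, blk)
  expect_length(g, 16)
  expect_true(all(g > 0 & g < 1))
  plain <- se_block(16, r = 4, optimized = FALSE, seed = 9)
  expect_length(se_gate(stats[, "global_mean"], plain), 16)
  expect_warning(se_block(4, r = 8), "clamped")
})

test_that("applying an SE block equals the channel-wise product computed by a loop", {
  set.seed(3)
  x <- array(rnorm(6 * 6 * 8), c(6, 6, 8))
  blk <- se_block(8, r = 2, seed = 4)
  out <- apply_se_block(x, blk)
  gates <- se_gate(squeeze_statistics(x), blk)
  oracle <- x
  for (c in 1:8) for (h in 1:6) for (w in 1:6)
    oracle[h, w, c] <- x[h, w, c] * gates[c]
  expect_equal(out, oracle, tolerance = 1e-12)
  expect_equal(dim(out), dim(x))
  expect_error(apply_se_block(array(0, c(4, 4, 5)), blk), "channels")
})

test_that("count_parameters matches closed forms for single layers", {
  conv <- ns$with_seed(1, ns$layer_conv(3L, 2L, 1L, bias = TRUE))
  expect_equal(count_parameters(conv), 3 * 2 + 2)                 # 8
  se_plain <- se_block(128, r = 16, optimized = FALSE)
  expect_equal(count_parameters(se_plain), 128 * 8 + 8 + 8 * 128 + 128)  # 2184
  se_opt <- se_block(128, r = 16)
  expect_equal(count_parameters(se_opt), 3 * 128 * 8 + 8 + 8 * 128 + 128)
  bn <- ns$layer_bn(10L)
  expect_equal(count_parameters(bn), 20)                          # scale + shift only
})

test_that("forward pass returns num_classes scores whose softmax sums to one", {
  model <- build_network(tiny_arch("A", num_classes = 3L), seed = 6)
  set.seed(2)
  imgs <- lapply(1:2, function(i) array(runif(32 * 32 * 3), c(32, 32, 3)))
  scores <- network_forward(model, imgs)
  expect_equal(dim(scores), c(2, 3))
  expect_equal(rowSums(softmax(scores)), c(1, 1), tolerance = 1e-6)
  # deterministic
  expect_identical(scores, network_forward(model, imgs))
})

test_that("SE overhead is additive (A = B + C over baseline) and class-invariant across configs", {
  configs <- list(
    list(growth_rate = 8L, block_config = c(2L, 2L, 2L, 2L), se_reduction = 8L),
    list(growth_rate = 12L, block_config = c(3L, 4L, 6L, 5L), se_reduction = 4L))
  for (cf in configs) {
    counts <- sapply(c(2L, 8L), function(nc) {
      sapply(c("baseline", "A", "B", "C"), function(v) {
        sp <- architecture_spec(v, num_classes = nc, growth_rate = cf$growth_rate,
                                block_config = cf$block_config,
                                se_reduction = cf$se_reduction, input_size = 64L)
        build_network(sp, seed = 0)$parameter_count
      })
    })
    over <- unname(sweep(counts[c("A", "B", "C"), , drop = FALSE], 2, counts["baseline", ]))
    expect_equal(over[1, 1], over[2, 1] + over[3, 1])   # additivity, 2-class
    expect_equal(over[1, 2], over[2, 2] + over[3, 2])   # additivity, 8-class
    expect_equal(over[, 1], over[, 2])                  # class-count invariance
  }
})

test_that("stripping SE blocks from variant A reproduces the baseline forward exactly", {
  mA <- build_network(tiny_arch("A"), seed = 3)
  stripped <- strip_se_blocks(mA)
  base <- build_network(tiny_arch("baseline"), seed = 99)
  expect_equal(stripped$parameter_count, base$parameter_count)
  base$modules <- ns$assign_params(base$modules, ns$flatten_params(stripped$modules))$mod
  set.seed(5)
  imgs <- lapply(1:2, function(i) array(runif(32 * 32 * 3), c(32, 32, 3)))
  expect_identical(network_forward(stripped, imgs), network_forward(base, imgs))
})

test_that("one optimizer step on a synthetic batch strictly decreases the training loss", {
  model <- build_network(tiny_arch("A"), seed = 1)
  p <- synth_params(image_size = 32, n_classes = 2, seed = 2)
  imgs <- c(lapply(1:4, function(i) generate_patch(p, 1, seed = i)$image / 255),
            lapply(1:4, function(i) generate_patch(p, 2, seed = 100 + i)$image / 255))
  y <- rep(1:2, each = 4)
  f <- ns$fm_from_images(imgs)
  mod <- model$modules
  fwd <- ns$net_forward(mod, f, training = TRUE)
  l0 <- ns$softmax_xent(fwd$out$x, y)$loss
  bwd <- ns$net_backward(fwd$mod, fwd$cache, ns$softmax_xent(fwd$out$x, y)$dlogits)
  params <- ns$flatten_params(fwd$mod)
  st <- ns$adam_step(params, ns$flatten_grads(bwd$grads), ns$adam_init(params), 1e-4)
  mod2 <- ns$assign_params(fwd$mod, st$params)$mod
  l1 <- ns$softmax_xent(ns$net_forward(mod2, f, training = TRUE)$out$x, y)$loss
  expect_lt(l1, l0)
})

test_that("architecture specs serialize through JSON", {
  sp <- architecture_spec("B", num_classes = 8, growth_rate = 16,
                          block_config = c(2, 3, 4, 5), se_reduction = 8,
                          head_width = 100)
  path <- withr::local_tempfile(fileext = ".json")
  write_architecture_spec(sp, path)
  expect_equal(read_architecture_spec(path), sp)
})
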