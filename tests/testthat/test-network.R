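test_that("forward pass returns a probability distribution per input", {
  net <- avatar_net(avatar_spec(), seed = 1)
  set.seed(2)
  p <- predict(net, matrix(rnorm(3 * 400), 3), matrix(abs(rnorm(3 * 500)), 3))
  expect_equal(dim(p), c(3, 42))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-9)
  # zero input still yields a valid distribution (softmax of biases)
  p0 <- predict(net, matrix(0, 1, 400), matrix(0, 1, 500))
  expect_equal(sum(p0), 1, tolerance = 1e-9)
  # a fresh network is near-uniform: no output dominates
  expect_lt(max(p0), 0.2)
  expect_error(predict(net, matrix(0, 1, 300), matrix(0, 1, 500)),
    class = "tactileavatar_invalid_argument")
})

test_that("weight initialization is seeded and He-scaled", {
  n1 <- avatar_net(avatar_spec(), seed = 9)
  n2 <- avatar_net(avatar_spec(), seed = 9)
  expect_identical(n1$weights, n2$weights)
  n3 <- avatar_net(avatar_spec(), seed = 10)
  expect_false(identical(n1$weights, n3$weights))
  expect_equal(stats::sd(n1$weights$slide1), sqrt(2 / 500), tolerance = 0.05)
})

test_that("compiled conv kernels agree with the im2col/BLAS path", {
  set.seed(5)
  a <- array(rnorm(6 * 40 * 3), c(6, 40, 3))
  w <- matrix(rnorm(4 * 3 * 5), 12, 5)
  b <- rnorm(5)
  ref <- tactileavatar:::conv_forward(a, w, b)
  got <- tactileavatar:::conv1d_fwd(a, w, b, 4L)
  expect_equal(got, ref$out, tolerance = 1e-12, ignore_attr = TRUE)
  # backward: scalar kernel vs im2col full-convolution matmul
  dy <- array(rnorm(prod(dim(ref$out))), dim(ref$out))
  bk_ref <- tactileavatar:::conv_backward(dy, ref$x2, w, dim(a))
  bk_got <- tactileavatar:::conv1d_bwd(dy, a, w, 4L)
  expect_equal(bk_got$dw, bk_ref$dw, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(bk_got$db, bk_ref$db, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(bk_got$da, bk_ref$da, tolerance = 1e-10, ignore_attr = TRUE)
  # pure-R im2col gather agrees with the compiled gather
  expect_equal(tactileavatar:::im2col_ref(a, 4), tactileavatar:::im2col(a, 4),
    tolerance = 1e-15, ignore_attr = TRUE)
})

test_that("compiled max pooling agrees with the R reference", {
  set.seed(6)
  a <- array(rnorm(5 * 23 * 4), c(5, 23, 4))
  ref <- tactileavatar:::maxpool_forward_ref(a, 4)
  got <- tactileavatar:::maxpool1d_fwd(a, 4L)
  expect_equal(got$out, ref$out, tolerance = 1e-15, ignore_attr = TRUE)
  dy <- array(rnorm(prod(dim(ref$out))), dim(ref$out))
  da_ref <- tactileavatar:::maxpool_backward_ref(dy, ref)
  da_got <- tactileavatar:::maxpool1d_bwd(dy, got$arg, 23L, 4L)
  expect_equal(da_got, da_ref, tolerance = 1e-15, ignore_attr = TRUE)
})

test_that("backpropagation matches finite differences in both loss modes", {
  sp <- tiny_spec()
  net <- avatar_net(sp, seed = 3)
  set.seed(1)
  touch <- matrix(rnorm(4 * 24), 4)
  slide <- matrix(abs(rnorm(4 * 16)), 4)
  tg <- matrix(stats::runif(4 * 5), 4)
  tg <- tg / rowSums(tg)
  for (loss in c("histogram", "categorical")) {
    sp$loss <- loss
    net$spec <- sp
    tg2 <- if (loss == "categorical") {
      m <- matrix(0, 4, 5)
      m[cbind(1:4, max.col(tg))] <- 1
      m
    } else {
      tg
    }
    fwd <- tactileavatar:::net_forward(net, touch, slide)
    dz <- tactileavatar:::loss_grad_logits(fwd$p, tg2, loss)
    g <- tactileavatar:::net_backward(net, fwd, dz)
    eps <- 1e-6
    for (nm in c("conv1", "conv3", "slide1", "trunk2", "out", "b_out")) {
      w0 <- net$weights[[nm]]
      for (j in c(1, length(w0))) {
        net$weights[[nm]][j] <- w0[j] + eps
        lp <- tactileavatar:::loss_value(
          tactileavatar:::net_forward(net, touch, slide)$p, tg2, loss)
        net$weights[[nm]][j] <- w0[j] - eps
        lm <- tactileavatar:::loss_value(
          tactileavatar:::net_forward(net, touch, slide)$p, tg2, loss)
        net$weights[[nm]][j] <- w0[j]
        num <- (lp - lm) / (2 * eps)
        expect_equal(g[[nm]][j], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("training reduces the loss and is deterministic given the seed", {
  sp <- tiny_spec(epochs = 40, batch_size = 8, learning_rate = 5)
  net <- avatar_net(sp, seed = 2)
  withr::with_seed(7, {
    touch <- matrix(rnorm(40 * 24), 40)
    slide <- matrix(abs(rnorm(40 * 16)), 40)
    labels <- sample(1:5, 40, replace = TRUE)
  })
  tg <- matrix(0, 40, 5)
  tg[cbind(1:40, labels)] <- 1
  fit1 <- fit_avatar(net, touch, slide, tg, seed = 4)
  expect_lt(tail(fit1$history$loss, 1), fit1$history$loss[1])
  expect_true(all(is.finite(fit1$history$loss)))
  fit2 <- fit_avatar(net, touch, slide, tg, seed = 4)
  expect_identical(fit1$weights, fit2$weights)
  # single-material corpus converges toward its target histogram
  tg1 <- matrix(rep(c(0.2, 0.5, 0.3, 0, 0), each = 10), 10)
  sp1 <- tiny_spec(epochs = 60, batch_size = 5, learning_rate = 50)
  fit3 <- fit_avatar(avatar_net(sp1, seed = 1), touch[1:10, ], slide[1:10, ],
    tg1, seed = 1)
  p <- predict(fit3, touch[1:10, ], slide[1:10, ])
  expect_lt(mean((colMeans(p) - tg1[1, ])^2), 1e-3)
})

test_that("target validation rejects malformed histograms", {
  sp <- tiny_spec(epochs = 1)
  net <- avatar_net(sp, seed = 1)
  touch <- matrix(0, 4, 24)
  slide <- matrix(0, 4, 16)
  bad <- matrix(0.5, 4, 5)
  expect_error(fit_avatar(net, touch, slide, bad),
    class = "tactileavatar_invalid_argument")
  expect_error(fit_avatar(net, touch, slide, matrix(0.2, 3, 5)),
    class = "tactileavatar_invalid_argument")
  # categorical mode requires one-hot rows
  spc <- tiny_spec(epochs = 1, loss = "categorical")
  soft <- matrix(0.2, 4, 5)
  expect_error(fit_avatar(avatar_net(spc, seed = 1), touch, slide, soft),
    class = "tactileavatar_invalid_argument")
  # one-hot targets are accepted in histogram mode as degenerate histograms
  oh <- matrix(0, 4, 5)
  oh[cbind(1:4, 1:4)] <- 1
  expect_no_error(fit_avatar(net, touch, slide, oh, epochs = 1))
})

test_that("stratified split keeps proportions within every material", {
  ids <- rep(1:6, each = 10)
  sp <- stratified_split(ids, 0.8, seed = 3)
  expect_length(sp$train, 48)
  expect_length(sp$test, 12)
  expect_equal(unname(table(ids[sp$train])), rep(8L, 6), ignore_attr = TRUE)
  expect_equal(unname(table(ids[sp$test])), rep(2L, 6), ignore_attr = TRUE)
  expect_identical(sp, stratified_split(ids, 0.8, seed = 3))
})

test_that("histogram targets align recordings with their material", {
  fxp <- fixture_participant()
  ids <- c(3L, 1L, 3L, 42L)
  tg <- histogram_targets(ids, fxp$hist)
  hm <- histogram_matrix(fxp$hist)
  expect_equal(tg[1, ], unname(hm["3", ]))
  expect_equal(tg[4, ], unname(hm["42", ]))
  expect_equal(rowSums(tg), rep(1, 4), tolerance = 1e-9)
  # categorical mode collapses to a one-hot at the rounded mean rank
  tgc <- histogram_targets(ids, fxp$hist, mode = "categorical")
  expect_true(all(rowSums(tgc) == 1))
  expect_true(all(apply(tgc, 1, max) == 1))
  means <- colSums(t(tg) * (1:42))
  expect_equal(apply(tgc, 1, which.max), round(means), tolerance = 0.51)
  expect_error(histogram_targets(c(1L, 99L), fxp$hist),
    class = "tactileavatar_invalid_argument")
})

test_that("tidy and glance summarise a fit", {
  sp <- tiny_spec(epochs = 3, batch_size = 8)
  net <- avatar_net(sp, seed = 2)
  set.seed(1)
  fit <- fit_avatar(net, matrix(rnorm(8 * 24), 8), matrix(abs(rnorm(8 * 16)), 8),
    matrix(rep(c(1, 0, 0, 0, 0), each = 8), 8), seed = 1)
  h <- tidy(fit)
  expect_named(h, c("epoch", "loss", "val_loss"))
  expect_equal(nrow(h), 3)
  g <- glance(fit)
  expect_equal(g$loss_mode, "histogram")
  expect_equal(g$epochs, 3)
})
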