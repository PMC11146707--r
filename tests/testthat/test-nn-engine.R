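# The convolution engine and the built blocks/networks: correctness
# against a naive oracle, gradient checks, shape contracts, determinism.

naive_conv1d <- function(x, w, b, stride, dil) {
  L <- dim(x)[1]; Cin <- dim(x)[2]; B <- dim(x)[3]
  k <- dim(w)[1]; Cout <- dim(w)[3]
  Lout <- floor((L - (k - 1) * dil - 1) / stride) + 1
  y <- array(0, c(Lout, Cout, B))
  for (s in seq_len(B)) for (o in seq_len(Cout)) for (t in seq_len(Lout)) {
    acc <- b[o]
    for (i in 0:(k - 1)) for (c in seq_len(Cin))
      acc <- acc + x[(t - 1) * stride + i * dil + 1, c, s] * w[i + 1, c, o]
    y[t, o, s] <- acc
  }
  y
}

test_that("compiled dilated convolution matches a naive R oracle", {
  set.seed(11)
  for (case in list(c(k = 3, d = 1, s = 1), c(k = 5, d = 2, s = 1),
                    c(k = 4, d = 3, s = 2), c(k = 1, d = 5, s = 1))) {
    k <- unname(case["k"]); d <- unname(case["d"]); s <- unname(case["s"])
    x <- array(rnorm(30 * 2 * 2), c(30, 2, 2))
    w <- array(rnorm(k * 2 * 3), c(k, 2, 3))
    b <- rnorm(3)
    got <- afmsdc:::conv1d_forward(x, w, b, stride = s, dilation = d,
                                   padding = "valid")$y
    expect_equal(got, naive_conv1d(x, w, b, s, d), tolerance = 1e-12)
  }
})

test_that("convolution gradients agree with central differences", {
  set.seed(12)
  x <- array(rnorm(24 * 2 * 2), c(24, 2, 2))
  w <- array(rnorm(4 * 2 * 3), c(4, 2, 3))
  b <- rnorm(3)
  fw <- afmsdc:::conv1d_forward(x, w, b, stride = 1, dilation = 2,
                                padding = "same")
  dy <- array(rnorm(length(fw$y)), dim(fw$y))
  bk <- afmsdc:::conv1d_backward(fw$cache, dy)
  eps <- 1e-6
  num_grad <- function(get, set) {
    v <- get()
    set(v + eps)
    up <- sum(afmsdc:::conv1d_forward(x, w, b, 1, 2, "same")$y * dy)
    set(v - eps)
    dn <- sum(afmsdc:::conv1d_forward(x, w, b, 1, 2, "same")$y * dy)
    set(v)
    (up - dn) / (2 * eps)
  }
  for (i in c(1, 7, 20))
    expect_equal(bk$dw[i],
                 num_grad(function() w[i],
                          function(v) w[i] <<- v), tolerance = 1e-5)
  for (i in c(1, 13))
    expect_equal(bk$dx[i],
                 num_grad(function() x[i],
                          function(v) x[i] <<- v), tolerance = 1e-5)
  expect_equal(bk$db[2],
               num_grad(function() b[2], function(v) b[2] <<- v),
               tolerance = 1e-5)
})

test_that("full-model gradients agree with central differences", {
  spec <- network_spec("msdc_a", n_blocks = 2, n_classes = 2,
                       downsample_schedule = 2L, stem_stride = 2L)
  m <- build_network(spec, seed = 3)
  set.seed(4)
  x <- array(rnorm(80 * 3), c(80, 1, 3))
  y <- c(1L, 2L, 1L)
  fw <- model_forward(m, x, training = TRUE)
  sx <- afmsdc:::softmax_xent(fw$scores, y)
  gr <- afmsdc:::model_backward(m, fw$caches, sx$dscores)
  loss_at <- function(nm, i, v) {
    mm <- m
    mm$params[[nm]][i] <- v
    afmsdc:::softmax_xent(model_forward(mm, x, TRUE)$scores, y)$loss
  }
  eps <- 1e-5
  for (nm in c("stem_W", "b1_br2_W", "b2_bn_gamma", "b2_proj_W",
               "head_W", "head_b")) {
    i <- 2L
    num <- (loss_at(nm, i, m$params[[nm]][i] + eps) -
              loss_at(nm, i, m$params[[nm]][i] - eps)) / (2 * eps)
    expect_equal(gr[[nm]][i], num, tolerance = 1e-4,
                 label = sprintf("grad %s", nm))
  }
})

test_that("blocks preserve shape under same-length padding", {
  for (nm in c("residual", "msdc_a", "msdc_b", "msdc_c")) {
    u <- build_block(msdc_block(nm), in_channels = 32, seed = 1)
    x <- array(rnorm(120 * 32 * 2), c(120, 32, 2))
    y <- unit_forward(u, x)$y
    expect_identical(dim(y), c(120L, 32L, 2L))
  }
})

test_that("zero input maps to the shortcut transform of zero", {
  # pre-activation BN of a zero input is a constant (beta) channel map;
  # strip normalization to isolate the additive identity of the shortcut
  u <- build_block(msdc_block("msdc_a"), in_channels = 32, seed = 5,
                   norm = FALSE)
  x <- array(0, c(50, 32, 1))
  y <- unit_forward(u, x)$y
  expect_true(all(y == 0))   # conv of 0 is 0 (zero biases), skip adds 0
})

test_that("valid padding errors when the input is shorter than the span", {
  u <- build_block(msdc_block("msdc_a"), in_channels = 4, seed = 1,
                   padding = "valid", skip = FALSE)
  expect_error(unit_forward(u, array(0, c(10, 4, 1))), "too short")
})

test_that("networks produce (batch, n_classes) scores for any admissible length", {
  spec <- network_spec("msdc_b", n_blocks = 15, n_classes = 2,
                       input_length = "variable")
  m <- build_network(spec, seed = 1)
  s1 <- model_forward(m, array(rnorm(2500), c(2500, 1, 1)))$scores
  expect_identical(dim(s1), c(1L, 2L))
  s2 <- model_forward(m, array(rnorm(2 * 700), c(700, 1, 2)))$scores
  expect_identical(dim(s2), c(2L, 2L))
  # degenerate single-block four-class net runs forward
  m4 <- build_network(network_spec("msdc_a", n_blocks = 1, n_classes = 4,
                                   downsample_schedule = integer(0)),
                      seed = 2)
  expect_identical(dim(model_forward(m4,
    array(rnorm(300), c(300, 1, 1)))$scores), c(1L, 4L))
})

test_that("spec validation rejects bad schedules and class counts", {
  expect_error(network_spec("msdc_a", n_blocks = 4,
                            downsample_schedule = 5L), "1..n_blocks")
  expect_error(network_spec("msdc_a", n_classes = 3), "2 or 4")
})

test_that("builds are bit-identical under a fixed seed", {
  spec <- afmsdc_network("msdc_c", "reduced", classes = c("normal", "af"))
  m1 <- build_network(spec, seed = 99)
  m2 <- build_network(spec, seed = 99)
  expect_identical(m1$params, m2$params)
  m3 <- build_network(spec, seed = 100)
  expect_false(identical(m1$params, m3$params))
})

test_that("checkpoints round-trip the spec and weights losslessly", {
  spec <- network_spec("msdc_b", n_blocks = 3, n_classes = 4,
                       downsample_schedule = 2L, stem_stride = 4L,
                       input_rate = 300)
  m <- build_network(spec, seed = 7)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_identical(m2$spec, m$spec)
  expect_identical(m2$params, m$params)
  x <- array(rnorm(200), c(200, 1, 1))
  expect_identical(model_forward(m, x)$scores,
                   model_forward(m2, x)$scores)
})
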