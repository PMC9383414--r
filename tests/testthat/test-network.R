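test_that("layer geometry follows the valid-conv / pool arithmetic", {
  g22 <- conv_geometry(22)
  expect_identical(g22$sizes, c(22L, 21L, 20L, 19L, 9L, 8L, 7L))
  expect_identical(g22$flatten_dim, 3136L)
  g12 <- conv_geometry(12)
  expect_identical(g12$sizes, c(12L, 11L, 10L, 9L, 4L, 3L, 2L))
  expect_identical(g12$flatten_dim, 256L)
  expect_error(conv_geometry(8), "Conv5")
  expect_error(build_params(8, 4), "Conv5")
})

test_that("learnable parameter count is the exact architecture arithmetic", {
  p <- build_params(22, 4, seed = 1)
  conv_count <- (4 * 1 * 4 + 4) + (8 * 4 * 4 + 8) + (16 * 8 * 4 + 16) +
    (32 * 16 * 4 + 32) + (64 * 32 * 4 + 64)
  expect_identical(conv_count, 11020)
  fc_count <- 3136 * 32 + 32 + 32 * 4 + 4
  expect_identical(count_params(p), as.integer(conv_count + fc_count))
  p12 <- build_params(12, 4, seed = 1)
  expect_identical(count_params(p12), as.integer(11020 + 256 * 32 + 32 + 32 * 4 + 4))
  # SS scalars are identity at build time and excluded from the count
  expect_identical(p$ss, list(scale = rep(1, 5), shift = rep(0, 5)))
})

test_that("initialization is deterministic in the seed", {
  expect_identical(build_params(12, 4, seed = 3), build_params(12, 4, seed = 3))
  expect_false(identical(build_params(12, 4, seed = 3)$extractor[[1]]$W,
                         build_params(12, 4, seed = 4)$extractor[[1]]$W))
})

test_that("ss_conv implements the scaled/shifted convolution algebra", {
  X <- matrix(1, 2, 2)
  W <- array(1, c(2, 2, 1, 1))
  expect_equal(as.numeric(ss_conv(X, W, b = 1, scale = 3, shift = 0.5)), 13.5)
  # identity element reproduces the plain convolution
  X2 <- spdcnn:::with_seed(5, matrix(rnorm(25), 5, 5))
  W2 <- spdcnn:::with_seed(6, array(rnorm(2 * 2 * 1 * 3), c(2, 2, 1, 3)))
  plain <- ss_conv(X2, W2, b = c(0.1, -0.2, 0.3), scale = 1, shift = 0)
  for (oc in 1:3) for (i in 1:4) for (j in 1:4) {
    expect_equal(plain[i, j, oc],
                 sum(W2[, , 1, oc] * X2[i:(i + 1), j:(j + 1)]) +
                   c(0.1, -0.2, 0.3)[oc],
                 tolerance = 1e-12)
  }
  # scale 0 annihilates the input
  zeroed <- ss_conv(X2, W2, b = c(1, 2, 3), scale = 0, shift = 0.5)
  for (oc in 1:3) expect_true(all(zeroed[, , oc] == oc + 0.5))
  expect_error(ss_conv(X, W, b = NaN, scale = 1, shift = 0), "non-finite")
})

test_that("forward returns a softmax distribution and predicts with low-index ties", {
  p <- build_params(12, 4, seed = 2)
  s <- random_spd_sample(12, 7)
  probs <- forward(p, s)
  expect_length(probs, 4)
  expect_true(all(probs >= 0 & probs <= 1))
  expect_equal(sum(probs), 1, tolerance = 1e-9)
  expect_identical(forward(p, s), probs)  # deterministic
  # zero parameters -> uniform output and tie broken to class 0
  pz <- zero_params(p)
  expect_equal(forward(pz, s), rep(0.25, 4), tolerance = 1e-12)
  expect_identical(predict_class(pz, s), 0L)
  # unnormalized input warns by default, errors on request
  raw <- random_spd_sample(12, 8, normalized = FALSE)
  expect_warning(forward(p, raw), "normalized")
  expect_error(forward(p, raw, on_unnormalized = "error"), "normalized")
  expect_error(forward(p, random_spd_sample(9, 9)), "does not match")
})

test_that("batched forward agrees with an independent looped reference", {
  p <- build_params(9, 3, seed = 11)
  p$ss$scale <- c(1.2, 0.8, 1.05, 0.9, 1.1)
  p$ss$shift <- c(0.05, -0.1, 0, 0.2, -0.02)
  for (rep in 1:10) {
    M <- spdcnn:::with_seed(200 + rep, {
      A <- matrix(rnorm(81), 9, 9); (A + t(A)) / 2
    })
    got <- forward(p, spd_sample(M, normalized = TRUE), on_unnormalized = "ignore")
    expect_equal(got, ref_forward(p, M), tolerance = 1e-10)
  }
})

test_that("forward is sensitive to channel order", {
  p <- build_params(12, 4, seed = 13)
  M <- random_spd_sample(12, 21)$matrix
  perm <- c(2:12, 1)
  s1 <- spd_sample(M, normalized = TRUE)
  s2 <- spd_sample(M[perm, perm], normalized = TRUE)
  expect_false(isTRUE(all.equal(forward(p, s1), forward(p, s2))))
})

test_that("analytic gradients match central finite differences", {
  p <- build_params(9, 3, seed = 7)
  p$ss$scale <- spdcnn:::with_seed(1, runif(5, 0.7, 1.3))
  p$ss$shift <- spdcnn:::with_seed(2, runif(5, -0.2, 0.2))
  x <- spdcnn:::with_seed(3, array(rnorm(9 * 9 * 4), c(9, 9, 4)))
  y <- c(0L, 2L, 1L, 0L)
  fw <- spdcnn:::net_forward(p, x, keep_cache = TRUE)
  g <- spdcnn:::net_backward(p, fw, y)
  loss_at <- function(pp) cross_entropy(spdcnn:::net_forward(pp, x)$probs, y)
  eps <- 1e-6
  numgrad <- function(setter) {
    (loss_at(setter(p, eps)) - loss_at(setter(p, -eps))) / (2 * eps)
  }
  checks <- list(
    list(function(q, e) { q$extractor[[1]]$W[1, 2, 1, 1] <- q$extractor[[1]]$W[1, 2, 1, 1] + e; q },
         g$extractor[[1]]$W[1, 2, 1, 1]),
    list(function(q, e) { q$extractor[[4]]$b[3] <- q$extractor[[4]]$b[3] + e; q },
         g$extractor[[4]]$b[3]),
    list(function(q, e) { q$ss$scale[3] <- q$ss$scale[3] + e; q }, g$ss$scale[3]),
    list(function(q, e) { q$ss$shift[5] <- q$ss$shift[5] + e; q }, g$ss$shift[5]),
    list(function(q, e) { q$classifier$W1[10, 4] <- q$classifier$W1[10, 4] + e; q },
         g$classifier$W1[10, 4]),
    list(function(q, e) { q$classifier$W2[7, 2] <- q$classifier$W2[7, 2] + e; q },
         g$classifier$W2[7, 2]),
    list(function(q, e) { q$classifier$b2[1] <- q$classifier$b2[1] + e; q },
         g$classifier$b2[1])
  )
  for (chk in checks) {
    expect_equal(numgrad(chk[[1]]), chk[[2]], tolerance = 1e-5)
  }
})
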