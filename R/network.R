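# The SPD-CNN classifier.
#
# Feature extractor: five valid (no padding, stride 1) 2x2 convolutions with
# output channels 4, 8, 16, 32, 64 and ReLU after each, with one 2x2/stride-2
# max-pool after the third convolution.  Classifier: flatten, FC -> 32 with
# ReLU, FC -> K, softmax.  Each conv layer additionally carries one scaling
# scalar applied to all its weights and one shifting scalar added to all its
# biases (the SS reparameterization used by the meta phase); scale 1 / shift 0
# is the identity.
#
# Feature maps are stored as (height, width, channels, batch) arrays; the
# convolutions run via im2col + matrix multiplication, which keeps this
# desk-scale network fast in plain R.

CONV_CHANNELS <- c(4L, 8L, 16L, 32L, 64L)

#' Layer geometry of the feature extractor
#'
#' Spatial sizes along Conv1..Conv3, MaxPool, Conv4..Conv5 for a `d x d`
#' input: each valid 2x2 convolution shrinks the side by 1 and the 2x2
#' stride-2 pool halves it (floor).  Errors if any layer's input would drop
#' below 2 (the kernel size), naming the offending layer; the smallest
#' feasible input is `d = 9`.
#'
#' @param d Input side length (number of channels of the EEG montage).
#' @return List with `sizes` (length 7: input, after each layer) and
#'   `flatten_dim` (`64 * m^2`, `m` the final side).
#' @export
conv_geometry <- function(d) {
  d <- as.integer(d)
  layers <- c("Conv1", "Conv2", "Conv3", "MaxPool", "Conv4", "Conv5")
  sizes <- integer(7)
  sizes[1] <- d
  s <- d
  for (i in seq_along(layers)) {
    if (layers[i] == "MaxPool") {
      s <- s %/% 2L
    } else {
      if (s < 2L) {
        stopf("input size %d is too small: spatial size %d reaches %s (need >= 2 for a 2x2 kernel)",
              d, s, layers[i])
      }
      s <- s - 1L
    }
    if (s < 1L) {
      stopf("input size %d is too small: spatial size reaches 0 after %s", d, layers[i])
    }
    sizes[i + 1] <- s
  }
  list(sizes = sizes, flatten_dim = 64L * s * s)
}

#' Build SPD-CNN parameters
#'
#' He-style (fan-in, normal) initialization of the five conv layers and the
#' two fully connected layers; biases start at zero and the per-layer SS
#' scalars at their identity (scale 1, shift 0).  Deterministic given `seed`.
#'
#' @param d Input side length (>= 9).
#' @param K Number of classes (>= 2).
#' @param seed Integer seed.
#' @return An object of class `model_params` with fields `extractor`
#'   (list of 5 layers, each `W` `(2,2,in,out)` and `b`), `classifier`
#'   (`W1`, `b1`, `W2`, `b2`), `ss` (`scale`, `shift`, length 5 each),
#'   `input_dim`, `n_classes`, `flatten_dim`.
#' @export
build_params <- function(d, K, seed = 1L) {
  if (K < 2) stopf("need at least 2 classes")
  geom <- conv_geometry(d)
  with_seed(seed, {
    in_ch <- c(1L, CONV_CHANNELS[-5])
    extractor <- lapply(seq_len(5), function(l) {
      fan_in <- in_ch[l] * 4L
      list(W = array(stats::rnorm(4 * in_ch[l] * CONV_CHANNELS[l], sd = sqrt(2 / fan_in)),
                     dim = c(2L, 2L, in_ch[l], CONV_CHANNELS[l])),
           b = numeric(CONV_CHANNELS[l]))
    })
    classifier <- list(
      W1 = matrix(stats::rnorm(geom$flatten_dim * 32L, sd = sqrt(2 / geom$flatten_dim)),
                  geom$flatten_dim, 32L),
      b1 = numeric(32L),
      W2 = matrix(stats::rnorm(32L * K, sd = sqrt(2 / 32)), 32L, K),
      b2 = numeric(K)
    )
    structure(
      list(extractor = extractor, classifier = classifier,
           ss = list(scale = rep(1, 5), shift = rep(0, 5)),
           input_dim = as.integer(d), n_classes = as.integer(K),
           flatten_dim = geom$flatten_dim),
      class = "model_params"
    )
  })
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> d=%d, K=%d, flatten_dim=%d, %d learnable parameters\n",
              x$input_dim, x$n_classes, x$flatten_dim, count_params(x)))
  invisible(x)
}

#' Learnable parameter count
#'
#' Conv and fully-connected weights and biases; the 10 SS scalars are
#' excluded (they are the meta phase's transfer parameters, not part of the
#' base network).
#'
#' @param params A `model_params` object.
#' @return Integer.
#' @export
count_params <- function(params) {
  n <- sum(vapply(params$extractor, function(l) length(l$W) + length(l$b), numeric(1)))
  n <- n + with(params$classifier, length(W1) + length(b1) + length(W2) + length(b2))
  as.integer(n)
}

# ---- conv primitives -------------------------------------------------------

# im2col for 2x2 valid convolution: (H, W, C, B) -> (4C, Ho*Wo*B) with row
# order (di, dj, channel).
im2col2x2 <- function(X) {
  dm <- dim(X)
  Ho <- dm[1] - 1L; Wo <- dm[2] - 1L; C <- dm[3]; B <- dm[4]
  P <- array(0, dim = c(2L, 2L, C, Ho, Wo, B))
  for (di in 1:2) for (dj in 1:2) {
    sl <- X[di:(di + Ho - 1L), dj:(dj + Wo - 1L), , , drop = FALSE]
    P[di, dj, , , , ] <- aperm(sl, c(3, 1, 2, 4))
  }
  dim(P) <- c(4L * C, Ho * Wo * B)
  P
}

# Scatter-add adjoint of im2col2x2: (4C, Ho*Wo*B) -> (H, W, C, B).
col2im2x2 <- function(dP, H, W, C, B) {
  Ho <- H - 1L; Wo <- W - 1L
  dim(dP) <- c(2L, 2L, C, Ho, Wo, B)
  dX <- array(0, dim = c(H, W, C, B))
  for (di in 1:2) for (dj in 1:2) {
    sl <- dP[di, dj, , , , , drop = FALSE]
    dim(sl) <- c(C, Ho, Wo, B)
    dX[di:(di + Ho - 1L), dj:(dj + Wo - 1L), , ] <-
      dX[di:(di + Ho - 1L), dj:(dj + Wo - 1L), , , drop = FALSE] +
      aperm(sl, c(2, 3, 1, 4))
  }
  dX
}

#' Scaling-and-shifting convolution
#'
#' One valid stride-1 2x2 cross-correlation whose weights are all multiplied
#' by the layer's scaling scalar and whose biases are all incremented by its
#' shifting scalar: `SS(X; W, b; s, t) = (W * s) .conv. X + (b + t)`.
#' Scale 1 / shift 0 reduces to the plain convolution.
#'
#' @param X Input feature map: `(H, W, C_in)` or `(H, W, C_in, B)` array, or
#'   an `H x W` matrix (single channel).
#' @param W Kernel array `(2, 2, C_in, C_out)`.
#' @param b Bias vector, length `C_out`.
#' @param scale,shift The layer's SS scalars.
#' @return Output feature map `(H-1, W-1, C_out, B)` (batch dimension dropped
#'   if the input had none).
#' @export
ss_conv <- function(X, W, b, scale = 1, shift = 0) {
  if (!all(is.finite(W)) || !all(is.finite(b)) ||
      !is.finite(scale) || !is.finite(shift)) {
    stopf("non-finite convolution parameters")
  }
  drop_batch <- FALSE
  if (is.matrix(X)) {
    dim(X) <- c(dim(X), 1L)
  }
  if (length(dim(X)) == 3L) {
    dim(X) <- c(dim(X), 1L)
    drop_batch <- TRUE
  }
  out <- conv_forward(X, W, b, scale, shift)$out
  if (drop_batch) dim(out) <- dim(out)[1:3]
  out
}

# Core batched conv: returns pre-activation Z = scale*V + (b + shift) along
# with the linear response V and patches P needed by the backward pass.
conv_forward <- function(X, W, b, scale, shift, keep_cache = FALSE) {
  dm <- dim(X)
  Ho <- dm[1] - 1L; Wo <- dm[2] - 1L; Cin <- dm[3]; B <- dm[4]
  Cout <- dim(W)[4]
  P <- im2col2x2(X)
  Wmat <- W
  dim(Wmat) <- c(4L * Cin, Cout)
  V <- crossprod(Wmat, P)              # (Cout, Ho*Wo*B)
  Z <- scale * V + (b + shift)         # b recycles down the Cout dimension
  out <- aperm(array(Z, dim = c(Cout, Ho, Wo, B)), c(2, 3, 1, 4))
  if (keep_cache) list(out = out, V = V, P = P, in_dim = dm) else list(out = out)
}

conv_backward <- function(dOut, W, scale, cache, want_input = TRUE) {
  Cout <- dim(W)[4]
  Cin <- dim(W)[3]
  dZ <- aperm(dOut, c(3, 1, 2, 4))
  dim(dZ) <- c(Cout, length(dZ) / Cout)
  dscale <- sum(dZ * cache$V)
  dshift <- sum(dZ)
  db <- rowSums(dZ)
  dV <- scale * dZ
  dW <- cache$P %*% t(dV)
  dim(dW) <- c(2L, 2L, Cin, Cout)
  dX <- NULL
  if (want_input) {
    Wmat <- W
    dim(Wmat) <- c(4L * Cin, Cout)
    dP <- Wmat %*% dV
    dX <- col2im2x2(dP, cache$in_dim[1], cache$in_dim[2], Cin, cache$in_dim[4])
  }
  list(dW = dW, db = db, dscale = dscale, dshift = dshift, dX = dX)
}

maxpool_forward <- function(X, keep_cache = FALSE) {
  dm <- dim(X)
  Ho <- dm[1] %/% 2L; Wo <- dm[2] %/% 2L
  ri <- seq_len(Ho) * 2L - 1L
  ci <- seq_len(Wo) * 2L - 1L
  s11 <- X[ri, ci, , , drop = FALSE]
  s21 <- X[ri + 1L, ci, , , drop = FALSE]
  s12 <- X[ri, ci + 1L, , , drop = FALSE]
  s22 <- X[ri + 1L, ci + 1L, , , drop = FALSE]
  out <- pmax(s11, s21, s12, s22)
  if (!keep_cache) return(list(out = out))
  list(out = out, slices = list(s11, s21, s12, s22), in_dim = dm,
       ri = ri, ci = ci)
}

maxpool_backward <- function(dOut, cache) {
  dX <- array(0, dim = cache$in_dim)
  out <- pmax(cache$slices[[1]], cache$slices[[2]], cache$slices[[3]], cache$slices[[4]])
  taken <- array(FALSE, dim = dim(out))
  offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (k in 1:4) {
    m <- (cache$slices[[k]] == out) & !taken
    taken <- taken | m
    dX[cache$ri + offs[[k]][1], cache$ci + offs[[k]][2], , ] <-
      dX[cache$ri + offs[[k]][1], cache$ci + offs[[k]][2], , , drop = FALSE] + dOut * m
  }
  dX
}

softmax_cols <- function(L) {
  L <- L - rep(apply(L, 2, max), each = nrow(L))
  E <- exp(L)
  E / rep(colSums(E), each = nrow(E))
}

# ---- full network ----------------------------------------------------------

# Batched forward pass.  x: (d, d, B).  Returns probs (K, B); with
# keep_cache, every intermediate needed by net_backward.
net_forward <- function(params, x, keep_cache = FALSE) {
  B <- dim(x)[3]
  A <- x
  dim(A) <- c(dim(x)[1], dim(x)[2], 1L, B)
  caches <- vector("list", 6)
  acts <- vector("list", 6)
  li <- 0L
  for (step in c(1L, 2L, 3L, 0L, 4L, 5L)) {   # 0 marks the pool
    li <- li + 1L
    if (step == 0L) {
      pc <- maxpool_forward(A, keep_cache)
      caches[[li]] <- pc
      A <- pc$out
      acts[[li]] <- NULL
    } else {
      layer <- params$extractor[[step]]
      cc <- conv_forward(A, layer$W, layer$b,
                         params$ss$scale[step], params$ss$shift[step], keep_cache)
      caches[[li]] <- cc
      Z <- cc$out
      A <- Z * (Z > 0)                     # ReLU
      acts[[li]] <- if (keep_cache) (Z > 0) else NULL
    }
  }
  Fl <- A
  dim(Fl) <- c(params$flatten_dim, B)
  H1 <- crossprod(params$classifier$W1, Fl) + params$classifier$b1
  H1r <- H1 * (H1 > 0)
  logits <- crossprod(params$classifier$W2, H1r) + params$classifier$b2
  probs <- softmax_cols(logits)
  if (!keep_cache) return(list(probs = probs))
  list(probs = probs, caches = caches, relu_masks = acts,
       Fl = Fl, H1 = H1, H1r = H1r, B = B)
}

# Convolutional features only (flatten output), for the classifier-only
# inner loops where the extractor and SS scalars are frozen.
net_features <- function(params, x) {
  B <- dim(x)[3]
  A <- x
  dim(A) <- c(dim(x)[1], dim(x)[2], 1L, B)
  for (step in c(1L, 2L, 3L, 0L, 4L, 5L)) {
    if (step == 0L) {
      A <- maxpool_forward(A)$out
    } else {
      layer <- params$extractor[[step]]
      Z <- conv_forward(A, layer$W, layer$b,
                        params$ss$scale[step], params$ss$shift[step])$out
      A <- Z * (Z > 0)
    }
  }
  dim(A) <- c(params$flatten_dim, B)
  A
}

# Backward pass for the mean cross-entropy over the batch.
# want: subset of c("extractor", "classifier", "ss").
net_backward <- function(params, fw, labels, want = c("extractor", "classifier", "ss")) {
  B <- fw$B
  K <- params$n_classes
  dlogits <- fw$probs
  dlogits[cbind(labels + 1L, seq_len(B))] <- dlogits[cbind(labels + 1L, seq_len(B))] - 1
  dlogits <- dlogits / B
  clf <- params$classifier
  grads <- list()
  dH1r <- clf$W2 %*% dlogits
  dH1 <- dH1r * (fw$H1 > 0)
  if ("classifier" %in% want) {
    grads$classifier <- list(
      W1 = fw$Fl %*% t(dH1),
      b1 = rowSums(dH1),
      W2 = fw$H1r %*% t(dlogits),
      b2 = rowSums(dlogits)
    )
  }
  need_conv <- any(c("extractor", "ss") %in% want)
  if (need_conv) {
    dFl <- clf$W1 %*% dH1
    geom <- conv_geometry(params$input_dim)
    m <- geom$sizes[7]
    dA <- array(dFl, dim = c(m, m, 64L, B))
    ext_g <- vector("list", 5)
    ss_g <- list(scale = numeric(5), shift = numeric(5))
    steps <- c(1L, 2L, 3L, 0L, 4L, 5L)
    for (li in 6:1) {
      step <- steps[li]
      if (step == 0L) {
        dA <- maxpool_backward(dA, fw$caches[[li]])
      } else {
        dZ <- dA * fw$relu_masks[[li]]
        bk <- conv_backward(dZ, params$extractor[[step]]$W,
                            params$ss$scale[step], fw$caches[[li]],
                            want_input = (li > 1L))
        ext_g[[step]] <- list(W = bk$dW, db = bk$db)
        ss_g$scale[step] <- bk$dscale
        ss_g$shift[step] <- bk$dshift
        dA <- bk$dX
      }
    }
    if ("extractor" %in% want) {
      grads$extractor <- lapply(ext_g, function(g) list(W = g$W, b = g$db))
    }
    if ("ss" %in% want) grads$ss <- ss_g
  }
  grads
}

# ---- user-facing inference -------------------------------------------------

#' Class probabilities for one descriptor
#'
#' Runs the full SPD-CNN forward pass on a single normalized descriptor.
#'
#' @param params A [build_params()] object (possibly trained).
#' @param sample An [spd_sample()] of matching dimension.
#' @param on_unnormalized `"warn"` (default), `"error"` or `"ignore"` when
#'   the sample has not been standardized.
#' @return Numeric vector of `K` class probabilities (sums to 1).
#' @export
forward <- function(params, sample, on_unnormalized = c("warn", "error", "ignore")) {
  on_unnormalized <- match.arg(on_unnormalized)
  if (!isTRUE(sample$normalized)) {
    msg <- "descriptor has not been normalized; the network expects standardized inputs"
    if (on_unnormalized == "error") stopf(msg)
    if (on_unnormalized == "warn") warnf(msg)
  }
  if (nrow(sample$matrix) != params$input_dim) {
    stopf("descriptor dimension %d does not match network input %d",
          nrow(sample$matrix), params$input_dim)
  }
  x <- array(sample$matrix, dim = c(params$input_dim, params$input_dim, 1L))
  as.numeric(net_forward(params, x)$probs)
}

#' Predicted class for one descriptor
#'
#' Argmax of [forward()], ties broken toward the lowest class index.
#'
#' @inheritParams forward
#' @return 0-based class id.
#' @export
predict_class <- function(params, sample, on_unnormalized = "warn") {
  p <- forward(params, sample, on_unnormalized)
  which.max(p) - 1L
}

# Batched prediction on a list of samples; returns 0-based labels.
predict_batch <- function(params, samples) {
  st <- stack_samples(samples)
  probs <- net_forward(params, st$x)$probs
  max.col(t(probs), ties.method = "first") - 1L
}
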