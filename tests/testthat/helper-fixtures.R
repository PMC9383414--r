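# Shared fixtures: all synthetic, built in code at test time.

# Small multi-subject study in the generator's default (calibrated) regime.
tiny_study <- function(n_subjects = 4, n_trials = 12, d = 12, K = 4,
                       mixing = 0.3, seed = 42, n_samples = 256,
                       noise_sd = 0.4, separation = 0.25) {
  classes <- make_class_covariances(d, K, separation = separation, seed = 5)
  generate_study(n_subjects, classes, n_trials, mixing_strength = mixing,
                 n_samples = n_samples, noise_sd = noise_sd, seed = seed)
}

# Normalized descriptors for a study, with the per-sample subject vector.
study_descriptors <- function(study, fit_subjects = NULL) {
  descs <- compute_descriptors(study$dataset)
  subj <- vapply(descs, function(s) s$subject, character(1))
  pool <- if (is.null(fit_subjects)) descs else descs[subj %in% fit_subjects]
  stats <- fit_normalizer(pool)
  list(samples = normalize_samples(descs, stats), subjects = subj, stats = stats)
}

# Independent slow reference for the full network forward pass: plain loops,
# no im2col, no shared code with the package's batched implementation.
ref_forward <- function(params, M) {
  conv_ref <- function(X, W, b, scale, shift) {
    dm <- dim(X)
    Cout <- dim(W)[4]
    out <- array(0, c(dm[1] - 1L, dm[2] - 1L, Cout))
    for (oc in seq_len(Cout)) {
      for (i in seq_len(dm[1] - 1L)) for (j in seq_len(dm[2] - 1L)) {
        acc <- 0
        for (ic in seq_len(dm[3])) for (di in 1:2) for (dj in 1:2) {
          acc <- acc + scale * W[di, dj, ic, oc] * X[i + di - 1L, j + dj - 1L, ic]
        }
        out[i, j, oc] <- acc + b[oc] + shift
      }
    }
    out
  }
  pool_ref <- function(X) {
    dm <- dim(X)
    Ho <- dm[1] %/% 2L; Wo <- dm[2] %/% 2L
    out <- array(0, c(Ho, Wo, dm[3]))
    for (c in seq_len(dm[3])) for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
      out[i, j, c] <- max(X[2 * i - 1L, 2 * j - 1L, c], X[2 * i, 2 * j - 1L, c],
                          X[2 * i - 1L, 2 * j, c], X[2 * i, 2 * j, c])
    }
    out
  }
  A <- array(M, c(nrow(M), ncol(M), 1L))
  order <- c(1L, 2L, 3L, 0L, 4L, 5L)
  for (step in order) {
    if (step == 0L) {
      A <- pool_ref(A)
    } else {
      l <- params$extractor[[step]]
      A <- conv_ref(A, l$W, l$b, params$ss$scale[step], params$ss$shift[step])
      A <- pmax(A, 0)
    }
  }
  v <- as.numeric(A)
  h <- pmax(as.numeric(crossprod(params$classifier$W1, v)) + params$classifier$b1, 0)
  logits <- as.numeric(crossprod(params$classifier$W2, h)) + params$classifier$b2
  e <- exp(logits - max(logits))
  e / sum(e)
}

# Zero out every learnable parameter (softmax then returns uniform output).
zero_params <- function(params) {
  params$extractor <- lapply(params$extractor, function(l) {
    list(W = l$W * 0, b = l$b * 0)
  })
  params$classifier <- lapply(params$classifier, function(x) x * 0)
  params
}

random_spd_sample <- function(d, seed, normalized = TRUE, label = 0L) {
  m <- spdcnn:::with_seed(seed, {
    A <- matrix(rnorm(d * d), d, d)
    if (normalized) (A + t(A)) / 2 else tcrossprod(A) / d
  })
  spd_sample(m, label = label, subject = "T1", normalized = normalized)
}
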