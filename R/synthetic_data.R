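# Multi-subject synthetic EEG generator.
#
# Class identity is carried entirely by the spatial covariance of the trial:
# class k draws zero-mean Gaussian sources with covariance Sigma_k.  Subject
# identity perturbs the forward model through a linear mixing A_s = I + eps*R_s
# (R_s fixed per subject), emulating electrode/forward-model variability
# between subjects.  Isotropic Gaussian sensor noise is added after mixing,
# so the expected trial covariance is A_s Sigma_k A_s' + noise_sd^2 I.

#' Subject specification for the synthetic generator
#'
#' @param subject_id Identifier (character or integer-like); kept opaque.
#' @param mixing_strength Nonnegative scalar `eps`, the magnitude of the
#'   subject-specific mixing perturbation.  `eps = 0` means every subject
#'   shares the identical forward model.
#' @param seed Integer seed from which the subject's fixed perturbation
#'   matrix is drawn.
#' @return An object of class `subject_spec`.
#' @export
subject_spec <- function(subject_id, mixing_strength = 0.3, seed = 1L) {
  if (!is.numeric(mixing_strength) || length(mixing_strength) != 1 ||
      is.na(mixing_strength) || mixing_strength < 0) {
    stopf("mixing_strength must be a single nonnegative number")
  }
  structure(
    list(subject_id = as.character(subject_id),
         mixing_strength = as.numeric(mixing_strength),
         seed = as.integer(seed)),
    class = "subject_spec"
  )
}

#' Class specification: a source covariance
#'
#' @param class_id Integer class label in `0..K-1`.
#' @param source_covariance Symmetric positive-definite `d x d` matrix
#'   `Sigma_k` generating the class's zero-mean sources.
#' @return An object of class `class_spec`.
#' @export
class_spec <- function(class_id, source_covariance) {
  if (!is_symmetric_tol(source_covariance, 1e-8)) {
    stopf("source_covariance must be a symmetric square matrix")
  }
  ev <- eigen(source_covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stopf("source_covariance must be positive definite")
  structure(
    list(class_id = as.integer(class_id),
         source_covariance = unname(source_covariance)),
    class = "class_spec"
  )
}

#' Default well-separated class covariances
#'
#' Builds `K` distinct SPD source covariances `Sigma_k = I + s * u_k u_k'`
#' with `u_k` orthonormal directions drawn from `seed`, so classes differ by
#' where (spatially) their power is concentrated and `s` controls separation.
#'
#' The default `separation = 0.25` keeps the class signal subtle relative to
#' the shared background power, so that — together with the default sensor
#' noise — cross-subject zero-shot classification is measurably degraded by
#' the subject shift while within-subject classification stays learnable,
#' the qualitative regime of real motor-imagery data.
#'
#' @param d Number of channels.
#' @param K Number of classes.
#' @param separation Strength `s` of the class-specific power boost.
#' @param seed Integer seed.
#' @return List of `K` [class_spec()] objects with labels `0..K-1`.
#' @export
make_class_covariances <- function(d, K, separation = 0.25, seed = 1L) {
  if (K > d) stopf("need K <= d orthonormal class directions (K=%d, d=%d)", K, d)
  U <- with_seed(seed, qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))[, seq_len(K), drop = FALSE])
  lapply(seq_len(K), function(k) {
    class_spec(k - 1L, diag(d) + separation * tcrossprod(U[, k]))
  })
}

# Per-subject mixing matrix A_s = I + eps * R_s, with R_s entries
# N(0, 1/d^2) drawn from the subject's own seed (fixed across datasets).
subject_mixing <- function(subject, d) {
  R <- with_seed(subject$seed, matrix(stats::rnorm(d * d, sd = 1 / d), d, d))
  diag(d) + subject$mixing_strength * R
}

#' Expected trial covariance for a subject/class pair
#'
#' Closed form `A_s Sigma_k A_s' + noise_sd^2 I` against which empirical
#' trial covariances can be checked.
#'
#' @param subject A [subject_spec()].
#' @param class_spec A [class_spec()].
#' @param noise_sd Sensor noise standard deviation.
#' @return A `d x d` matrix.
#' @export
expected_trial_covariance <- function(subject, class_spec, noise_sd = 0) {
  d <- nrow(class_spec$source_covariance)
  A <- subject_mixing(subject, d)
  A %*% class_spec$source_covariance %*% t(A) + noise_sd^2 * diag(d)
}

#' EEG dataset container
#'
#' @param trials List of trials; each a list with fields `data`
#'   (channels x samples matrix), `label` (class id, 0-based) and `subject`.
#' @param n_channels,n_classes Geometry metadata.
#' @param sampling_rate Sampling rate in Hz (metadata only).
#' @param class_names Optional class names.
#' @return An object of class `eeg_dataset`.
#' @export
eeg_dataset <- function(trials, n_channels, n_classes,
                        sampling_rate = 250, class_names = NULL) {
  for (tr in trials) {
    if (!is.matrix(tr$data) || nrow(tr$data) != n_channels) {
      stopf("all trials must be matrices with %d channel rows", n_channels)
    }
    if (tr$label < 0 || tr$label >= n_classes) {
      stopf("trial label %s outside 0..%d", tr$label, n_classes - 1)
    }
  }
  structure(
    list(trials = trials,
         n_channels = as.integer(n_channels),
         n_classes = as.integer(n_classes),
         sampling_rate = as.numeric(sampling_rate),
         class_names = class_names %||% paste0("class", seq_len(n_classes) - 1L)),
    class = "eeg_dataset"
  )
}

#' @export
print.eeg_dataset <- function(x, ...) {
  cat(sprintf("<eeg_dataset> %d trials, %d channels, %d classes, %d subject(s)\n",
              length(x$trials), x$n_channels, x$n_classes,
              length(unique(dataset_subjects(x)))))
  invisible(x)
}

#' Subject id of every trial
#' @param dataset An `eeg_dataset`.
#' @return Character vector, one entry per trial.
#' @export
dataset_subjects <- function(dataset) {
  vapply(dataset$trials, function(tr) as.character(tr$subject), character(1))
}

#' Class label of every trial
#' @param dataset An `eeg_dataset`.
#' @return Integer vector of 0-based labels.
#' @export
dataset_labels <- function(dataset) {
  vapply(dataset$trials, function(tr) as.integer(tr$label), integer(1))
}

#' Restrict a dataset to one subject
#' @param dataset An `eeg_dataset`.
#' @param subject_id Subject identifier.
#' @return An `eeg_dataset` with only that subject's trials.
#' @export
subset_subject <- function(dataset, subject_id) {
  keep <- dataset_subjects(dataset) == as.character(subject_id)
  out <- dataset
  out$trials <- dataset$trials[keep]
  out
}

#' Generate one subject's synthetic trials
#'
#' For each class `k` emits `n_trials_per_class` trials `X = A_s Z + E`:
#' `A_s = I + eps R_s` is the subject's fixed mixing perturbation, `Z` has
#' `n_samples` columns drawn iid from `N(0, Sigma_k)`, and `E` is iid
#' `N(0, noise_sd^2)` sensor noise.  Bit-reproducible given
#' `(subject$seed, seed)`.
#'
#' @param subject A [subject_spec()].
#' @param classes List of [class_spec()] objects sharing one dimension `d`.
#' @param n_trials_per_class Trials per class (may be 0).
#' @param n_samples Samples `T` per trial (>= 2).
#' @param noise_sd Nonnegative sensor noise standard deviation.
#' @param seed Integer seed for the source and noise draws.
#' @param sampling_rate Metadata, Hz.
#' @return An [eeg_dataset()] with `K * n_trials_per_class` trials.
#' @export
generate_subject_dataset <- function(subject, classes, n_trials_per_class,
                                     n_samples = 1024, noise_sd = 0.4,
                                     seed = 1L, sampling_rate = 250) {
  dims <- vapply(classes, function(cs) nrow(cs$source_covariance), integer(1))
  if (length(unique(dims)) != 1) {
    stopf("all class covariances must share one dimension (got %s)",
          paste(unique(dims), collapse = ", "))
  }
  if (noise_sd < 0) stopf("noise_sd must be nonnegative")
  if (n_samples < 2) stopf("need at least 2 samples per trial")
  d <- dims[1]
  A <- subject_mixing(subject, d)
  chols <- lapply(classes, function(cs) t(chol(cs$source_covariance)))
  trials <- with_seed(seed, {
    out <- list()
    for (ci in seq_along(classes)) {
      L <- chols[[ci]]
      for (r in seq_len(n_trials_per_class)) {
        Z <- L %*% matrix(stats::rnorm(d * n_samples), d, n_samples)
        X <- A %*% Z
        if (noise_sd > 0) X <- X + matrix(stats::rnorm(d * n_samples, sd = noise_sd), d, n_samples)
        out[[length(out) + 1L]] <- list(data = X,
                                        label = classes[[ci]]$class_id,
                                        subject = subject$subject_id)
      }
    }
    out
  })
  eeg_dataset(trials, n_channels = d, n_classes = length(classes),
              sampling_rate = sampling_rate)
}

#' Generate a multi-subject synthetic study
#'
#' Convenience wrapper producing one pooled dataset over `n_subjects`
#' subjects that share the class covariances but differ by their mixing
#' perturbation.  Per-subject trial seeds are derived deterministically from
#' `seed`, so the whole study is reproducible from `(seed, subject seeds)`.
#'
#' @param n_subjects Number of subjects (ids `S1..Sn`).
#' @param classes List of [class_spec()]; see [make_class_covariances()].
#' @param n_trials_per_class Trials per class per subject.
#' @param mixing_strength Domain-shift magnitude `eps` shared by all subjects.
#' @param n_samples,noise_sd,seed,sampling_rate As in
#'   [generate_subject_dataset()].
#' @return List with `dataset` (pooled [eeg_dataset()]) and `subjects`
#'   (list of [subject_spec()]).
#' @export
generate_study <- function(n_subjects, classes, n_trials_per_class,
                           mixing_strength = 0.3, n_samples = 1024,
                           noise_sd = 0.4, seed = 1L, sampling_rate = 250) {
  subjects <- lapply(seq_len(n_subjects), function(i) {
    subject_spec(paste0("S", i), mixing_strength, seed = derive_seed(seed, i))
  })
  parts <- lapply(seq_len(n_subjects), function(i) {
    generate_subject_dataset(subjects[[i]], classes, n_trials_per_class,
                             n_samples = n_samples, noise_sd = noise_sd,
                             seed = derive_seed(seed, 100000 + i),
                             sampling_rate = sampling_rate)
  })
  pooled <- parts[[1]]
  pooled$trials <- do.call(c, lapply(parts, `[[`, "trials"))
  list(dataset = pooled, subjects = subjects)
}

#' Quadratic (Gaussian log-likelihood) oracle classifier
#'
#' Classifies a zero-mean trial by the Gaussian log-likelihood of its columns
#' under each candidate covariance: the Bayes rule when the generative
#' covariances are known.  Used to verify that the generator's class signal
#' is genuinely covariance-borne.
#'
#' @param X Channels x samples matrix.
#' @param covariances List of candidate `d x d` covariance matrices, ordered
#'   by class id.
#' @return 0-based index of the most likely class.
#' @export
bayes_classify_trial <- function(X, covariances) {
  n <- ncol(X)
  S <- tcrossprod(X) / n
  scores <- vapply(covariances, function(Sig) {
    -0.5 * n * (determinant(Sig, logarithm = TRUE)$modulus[1] +
                  sum(diag(solve(Sig, S))))
  }, numeric(1))
  which.max(scores) - 1L
}
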