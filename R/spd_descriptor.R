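# Spatial covariance (SPD) descriptor: C = X X' / T on channel-centered
# trials, followed by elementwise standardization against statistics fitted
# on a reference sample set.

#' SPD descriptor sample
#'
#' @param matrix `d x d` real symmetric matrix: the spatial covariance of a
#'   trial (or its elementwise-standardized version once `normalized`).
#' @param label 0-based class id (or `NA`).
#' @param subject Subject identifier (or `NA`).
#' @param normalized Logical; `FALSE` for a raw covariance (then the matrix
#'   must be positive semidefinite), `TRUE` after standardization.
#' @return An object of class `spd_sample`.
#' @export
spd_sample <- function(matrix, label = NA_integer_, subject = NA_character_,
                       normalized = FALSE) {
  if (!is_symmetric_tol(matrix, 1e-9)) {
    stopf("descriptor matrix must be symmetric (tolerance 1e-9)")
  }
  if (!normalized) {
    ev <- eigen((matrix + t(matrix)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-9) {
      stopf("unnormalized descriptor must be positive semidefinite (min eigenvalue %.3g)",
            min(ev))
    }
  }
  structure(
    list(matrix = unname(matrix), label = label, subject = subject,
         normalized = isTRUE(normalized)),
    class = "spd_sample"
  )
}

#' Center a trial per channel
#'
#' Subtracts each channel's own mean so the zero-mean premise of the
#' covariance descriptor holds.
#'
#' @param trial A trial list with a `data` matrix (channels x samples), or a
#'   bare matrix.
#' @return Same shape as the input with zero-mean rows.
#' @export
center_trial <- function(trial) {
  X <- if (is.matrix(trial)) trial else trial$data
  if (ncol(X) < 2) stopf("degenerate trial: need at least 2 samples to center")
  Xc <- X - rowMeans(X)
  if (is.matrix(trial)) return(Xc)
  trial$data <- Xc
  trial
}

#' Spatial covariance descriptor of a trial
#'
#' Computes `C = (1/T) X X'`, the `d x d` spatial covariance of a d-channel,
#' T-sample trial.  Channels are mean-centered first by default.  The
#' descriptor size is `d x d` regardless of `T`.
#'
#' @param trial Trial list (fields `data`, `label`, `subject`) or bare matrix.
#' @param center Center channels internally (default `TRUE`).
#' @return An [spd_sample()] with `normalized = FALSE`, carrying the trial's
#'   label and subject.
#' @export
compute_covariance <- function(trial, center = TRUE) {
  X <- if (is.matrix(trial)) trial else trial$data
  assert_finite(X, "trial data")
  if (ncol(X) < 2) stopf("degenerate trial: need at least 2 samples")
  if (center) X <- X - rowMeans(X)
  C <- tcrossprod(X) / ncol(X)
  C <- (C + t(C)) / 2
  spd_sample(C,
             label = if (is.matrix(trial)) NA_integer_ else trial$label,
             subject = if (is.matrix(trial)) NA_character_ else trial$subject,
             normalized = FALSE)
}

#' Descriptors for every trial of a dataset
#'
#' @param dataset An [eeg_dataset()].
#' @param center Passed to [compute_covariance()].
#' @return List of [spd_sample()] objects.
#' @export
compute_descriptors <- function(dataset, center = TRUE) {
  lapply(dataset$trials, compute_covariance, center = center)
}

#' Fit elementwise normalization statistics
#'
#' Computes the elementwise mean and population (divide-by-n) standard
#' deviation of a set of covariance descriptors.  Standard-deviation entries
#' below `epsilon` are replaced by 1 so constant entries pass through as
#' zeros after normalization.
#'
#' @param samples List of unnormalized [spd_sample()] objects, all `d x d`.
#' @param epsilon Guard below which a standard deviation counts as zero.
#' @return An object of class `normalizer_stats` with fields `mean`, `std`,
#'   `guarded` (logical matrix), `n_fitted` and `epsilon`.
#' @export
fit_normalizer <- function(samples, epsilon = 1e-8) {
  if (length(samples) == 0) stopf("cannot fit normalizer on an empty sample set")
  dims <- vapply(samples, function(s) nrow(s$matrix), integer(1))
  if (length(unique(dims)) != 1) {
    stopf("mixed descriptor dimensions: %s", paste(unique(dims), collapse = ", "))
  }
  if (any(vapply(samples, function(s) isTRUE(s$normalized), logical(1)))) {
    stopf("normalizer must be fitted on unnormalized descriptors")
  }
  d <- dims[1]
  n <- length(samples)
  arr <- array(unlist(lapply(samples, `[[`, "matrix")), dim = c(d, d, n))
  m <- apply(arr, c(1, 2), mean)
  s <- sqrt(pmax(apply(arr, c(1, 2), function(v) mean((v - mean(v))^2)), 0))
  guarded <- s < epsilon
  s[guarded] <- 1
  structure(
    list(mean = (m + t(m)) / 2, std = (s + t(s)) / 2, guarded = guarded,
         n_fitted = n, epsilon = epsilon),
    class = "normalizer_stats"
  )
}

#' Standardize one descriptor
#'
#' Applies `C* = (C - C_mean) / C_std` elementwise.
#'
#' @param sample An unnormalized [spd_sample()].
#' @param stats A [fit_normalizer()] result of matching dimension.
#' @return The normalized [spd_sample()].
#' @export
apply_normalizer <- function(sample, stats) {
  if (isTRUE(sample$normalized)) stopf("descriptor is already normalized")
  if (!identical(dim(sample$matrix), dim(stats$mean))) {
    stopf("descriptor dimension %dx%d does not match normalizer %dx%d",
          nrow(sample$matrix), ncol(sample$matrix),
          nrow(stats$mean), ncol(stats$mean))
  }
  out <- sample
  out$matrix <- (sample$matrix - stats$mean) / stats$std
  out$normalized <- TRUE
  out
}

#' Standardize a list of descriptors
#' @param samples List of unnormalized [spd_sample()] objects.
#' @param stats A [fit_normalizer()] result.
#' @return List of normalized samples.
#' @export
normalize_samples <- function(samples, stats) {
  lapply(samples, apply_normalizer, stats = stats)
}

# Stack spd samples into (d, d, N) array plus label/subject vectors for the
# batched network routines.
stack_samples <- function(samples) {
  d <- nrow(samples[[1]]$matrix)
  n <- length(samples)
  x <- array(unlist(lapply(samples, `[[`, "matrix")), dim = c(d, d, n))
  list(x = x,
       labels = vapply(samples, function(s) as.integer(s$label), integer(1)),
       subjects = vapply(samples, function(s) as.character(s$subject), character(1)))
}
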