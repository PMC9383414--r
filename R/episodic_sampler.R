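# Cross-subject folds and subject-specific N-way K-shot episodic tasks.
#
# A fold assigns every subject one of three roles (train / validation /
# test); an episodic task draws class-balanced disjoint support and query
# sets from a single subject, so each task is an independent sample of the
# same classification problem under that subject's domain shift.

#' Build random cross-subject folds
#'
#' Each fold draws `n_val` validation and `n_test` test subjects at random
#' without replacement; the remainder train.  Folds are drawn independently;
#' when the number of requested folds exceeds the number of distinct
#' (validation, test) assignments, duplicates are allowed with a warning.
#' With `balanced = TRUE` test subjects are instead cycled round-robin so
#' every subject serves as a test user about equally often.
#'
#' @param subjects Vector of subject ids.
#' @param n_val,n_test Validation/test set sizes (defaults 3 and 2).
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @param balanced Round-robin test users instead of fully random folds.
#' @return List of folds; each has `train_subjects`, `val_subjects`,
#'   `test_subjects` and `fold_index`.
#' @export
make_folds <- function(subjects, n_val = 3, n_test = 2, n_folds = 18,
                       seed = 1L, balanced = FALSE) {
  subjects <- as.character(subjects)
  n <- length(subjects)
  if (n_folds < 1) stopf("n_folds must be >= 1")
  if (n_val + n_test >= n) {
    stopf("cannot partition %d subjects into %d validation + %d test + >=1 training",
          n, n_val, n_test)
  }
  n_combos <- choose(n, n_val) * choose(n - n_val, n_test)
  if (n_folds > n_combos) {
    warnf("requested %d folds but only %g distinct (val, test) assignments exist; sampling with repetition",
          n_folds, n_combos)
  }
  with_seed(seed, {
    folds <- list()
    seen <- character(0)
    attempts <- 0L
    while (length(folds) < n_folds) {
      attempts <- attempts + 1L
      if (balanced) {
        k <- length(folds)
        test <- subjects[((k * n_test + seq_len(n_test) - 1L) %% n) + 1L]
        val <- sample(setdiff(subjects, test), n_val)
      } else {
        val <- sample(subjects, n_val)
        test <- sample(setdiff(subjects, val), n_test)
      }
      sig <- paste(c(sort(val), "|", sort(test)), collapse = ",")
      if (sig %in% seen && length(seen) < n_combos && attempts < 1000L * n_folds) {
        next  # retry while unseen (val, test) assignments remain
      }
      seen <- c(seen, sig)
      folds[[length(folds) + 1L]] <- structure(
        list(train_subjects = setdiff(subjects, c(val, test)),
             val_subjects = val, test_subjects = test,
             fold_index = length(folds) + 1L),
        class = "cs_fold"
      )
    }
    folds
  })
}

# Labels/subjects for either an eeg_dataset or a plain list of spd_samples.
sample_pool <- function(data) {
  if (inherits(data, "eeg_dataset")) {
    list(items = data$trials,
         labels = dataset_labels(data),
         subjects = dataset_subjects(data))
  } else {
    list(items = data,
         labels = vapply(data, function(s) as.integer(s$label), integer(1)),
         subjects = vapply(data, function(s) as.character(s$subject), character(1)))
  }
}

#' Sample one subject-specific N-way K-shot task
#'
#' Draws class-balanced, disjoint support (`k_shot` per class) and query
#' (`n_query` per class) sets uniformly from a single subject's samples.
#' When `n_way` is less than the number of available classes, the task's
#' classes are themselves sampled.
#'
#' @param data An [eeg_dataset()] or list of [spd_sample()] objects.
#' @param subject Subject id; required if `data` holds several subjects.
#' @param n_way Number of classes in the task.
#' @param k_shot Support samples per class.
#' @param n_query Query samples per class.
#' @param seed Integer seed.
#' @param task_id Optional integer tag.
#' @return An `episodic_task` with `subject`, `support`, `query`, `classes`,
#'   `task_id`.
#' @export
sample_task <- function(data, subject = NULL, n_way, k_shot, n_query,
                        seed = 1L, task_id = NA_integer_) {
  pool <- sample_pool(data)
  if (is.null(subject)) {
    us <- unique(pool$subjects)
    if (length(us) != 1) stopf("data holds %d subjects; pass `subject`", length(us))
    subject <- us
  }
  keep <- pool$subjects == as.character(subject)
  if (!any(keep)) stopf("no samples for subject %s", subject)
  labels <- pool$labels[keep]
  items <- pool$items[keep]
  avail <- sort(unique(labels))
  if (n_way > length(avail)) {
    stopf("subject %s has %d classes, cannot build a %d-way task",
          subject, length(avail), n_way)
  }
  with_seed(seed, {
    classes <- if (n_way < length(avail)) sort(sample(avail, n_way)) else avail
    support <- list()
    query <- list()
    for (cl in classes) {
      idx <- which(labels == cl)
      need <- k_shot + n_query
      if (length(idx) < need) {
        stopf("subject %s, class %d: %d samples available but %d needed (k_shot + n_query)",
              subject, cl, length(idx), need)
      }
      pick <- sample(idx, need)
      support <- c(support, items[pick[seq_len(k_shot)]])
      query <- c(query, items[pick[k_shot + seq_len(n_query)]])
    }
    structure(
      list(subject = as.character(subject), support = support, query = query,
           classes = classes, n_way = n_way, k_shot = k_shot,
           n_query = n_query, task_id = task_id),
      class = "episodic_task"
    )
  })
}

#' Partition tasks into meta-batches
#'
#' @param tasks List of tasks.
#' @param batch_size Tasks per meta-batch.
#' @param strict Require `batch_size` to divide the task count (default);
#'   otherwise the final batch may be partial.
#' @return List of task lists.
#' @export
build_meta_batches <- function(tasks, batch_size, strict = TRUE) {
  if (batch_size <= 0) stopf("batch_size must be positive")
  n <- length(tasks)
  if (strict && n %% batch_size != 0) {
    stopf("%d tasks do not divide into meta-batches of %d", n, batch_size)
  }
  split(tasks, ceiling(seq_len(n) / batch_size))
}

# Cycle training subjects so each contributes evenly to a loop of n tasks.
subject_cycle <- function(subjects, n) {
  rep(subjects, length.out = n)
}
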