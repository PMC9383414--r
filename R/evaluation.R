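# Accuracy evaluation across folds and transfer strategies, and the
# inter-subject distance analysis: per class, all subjects' samples are
# pooled, projected to 2D by PCA, and the mean Euclidean distance over all
# inter-subject sample pairs measures how far apart the subjects' sample
# clouds sit in that feature space.  Comparing raw flattened trials with
# covariance descriptors quantifies how much of the between-subject gap the
# descriptor closes.

#' Accuracy of an adapted model on one user's query set
#'
#' @param params `model_params` (e.g. from [domain_adapt()]).
#' @param query Nonempty list of the user's normalized descriptors.
#' @return Fraction of correct predictions.
#' @export
evaluate_user <- function(params, query) {
  if (length(query) == 0) stopf("empty query set")
  st <- stack_samples(query)
  mean(predict_batch(params, query) == st$labels)
}

#' Aggregate per-fold accuracies
#'
#' @param fold_accuracies Numeric vector, one accuracy per fold (each fold's
#'   value being the mean over its test users).
#' @return List with `mean`, `sd` (sample standard deviation; 0 with
#'   `degenerate = TRUE` for a single fold) and `n_folds`.
#' @export
aggregate_folds <- function(fold_accuracies) {
  if (length(fold_accuracies) == 0) stopf("no fold accuracies")
  degenerate <- length(fold_accuracies) < 2
  list(mean = mean(fold_accuracies),
       sd = if (degenerate) 0 else stats::sd(fold_accuracies),
       n_folds = length(fold_accuracies),
       degenerate = degenerate)
}

# Flatten one sample of either representation to a feature vector.
flatten_sample <- function(s) {
  if (inherits(s, "spd_sample")) as.numeric(s$matrix) else as.numeric(s$data)
}

#' Inter-subject distance of a representation in 2D PCA space
#'
#' For each class: pools every subject's samples of that class, centers the
#' pooled feature matrix, fits a 2-component PCA, projects all samples, and
#' averages the Euclidean distance over all pairs of samples belonging to
#' different subjects.  Smaller values mean the representation pulls
#' subjects' sample clouds together.
#'
#' @param samples_by_subject Named list: subject id -> list of samples
#'   (either [spd_sample()] descriptors or raw trials with a `data` matrix
#'   and `label`).
#' @param representation Tag recorded in the report (`"spd"` or `"raw"`).
#' @return A `distance_report`: per-class mean inter-subject distance,
#'   projections, and the representation tag.
#' @export
subject_distance <- function(samples_by_subject, representation = "spd") {
  if (length(samples_by_subject) < 2) stopf("need at least 2 subjects")
  subjects <- names(samples_by_subject) %||% paste0("S", seq_along(samples_by_subject))
  labels_of <- function(lst) vapply(lst, function(s) as.integer(s$label), integer(1))
  classes <- sort(unique(unlist(lapply(samples_by_subject, labels_of))))
  distances <- stats::setNames(numeric(length(classes)), paste0("class", classes))
  projections <- list()
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    feats <- list()
    subj_tags <- character(0)
    for (si in seq_along(samples_by_subject)) {
      lst <- samples_by_subject[[si]]
      keep <- labels_of(lst) == cl
      if (!any(keep)) {
        warnf("subject %s has no samples of class %d; excluded", subjects[si], cl)
        next
      }
      m <- t(vapply(lst[keep], flatten_sample, numeric(length(flatten_sample(lst[[1]])))))
      feats[[length(feats) + 1L]] <- m
      subj_tags <- c(subj_tags, rep(subjects[si], nrow(m)))
    }
    if (length(feats) < 2) stopf("fewer than 2 subjects have samples of class %d", cl)
    X <- do.call(rbind, feats)
    X <- scale(X, center = TRUE, scale = FALSE)
    pc <- stats::prcomp(X, center = FALSE, rank. = 2)
    proj <- pc$x[, 1:2, drop = FALSE]
    # fix the sign convention so the projection is deterministic
    for (j in 1:2) if (proj[which.max(abs(proj[, j])), j] < 0) proj[, j] <- -proj[, j]
    D <- as.matrix(stats::dist(proj))
    inter <- outer(subj_tags, subj_tags, `!=`)
    distances[ci] <- mean(D[inter & upper.tri(D)])
    projections[[paste0("class", cl)]] <- data.frame(subject = subj_tags,
                                                     pc1 = proj[, 1], pc2 = proj[, 2])
  }
  structure(list(distances = distances, projections = projections,
                 representation = representation),
            class = "distance_report")
}

#' @export
print.distance_report <- function(x, ...) {
  cat(sprintf("<distance_report> representation = %s\n", x$representation))
  print(round(x$distances, 4))
  invisible(x)
}

# ---- fold-level experiment harness -----------------------------------------

#' Run one cross-subject fold under ML / TL / MTL strategies
#'
#' Full pipeline on one fold of a multi-subject dataset of raw trials:
#' descriptors are computed for every trial, normalization statistics are
#' fitted on the training subjects only (set `norm_scope = "all"` for the
#' leakier whole-sample variant), the network is pre-trained on the pooled
#' training subjects, the SS scalars are meta-learned against the validation
#' subjects, and each test user is evaluated under the requested strategies:
#' `ml` = pre-trained network zero-shot; `tl` = pre-train + classifier
#' fine-tuning on the user's k-shot support; `mtl` = the meta-trained model
#' with the same fine-tuning.
#'
#' @param dataset Pooled multi-subject [eeg_dataset()].
#' @param fold A fold from [make_folds()].
#' @param config A [training_config()]; `k_shot` may be a vector of shot
#'   counts to evaluate (e.g. `c(5, 10)`).
#' @param strategies Subset of `c("ml", "tl", "mtl")`.
#' @param norm_scope `"train"` (default) or `"all"`.
#' @return List with `results` (data frame: strategy, shots, subject,
#'   accuracy), `fold`, `pretrain_fit`, `meta_fit`.
#' @export
run_fold_experiment <- function(dataset, fold, config = training_config(),
                                strategies = c("ml", "tl", "mtl"),
                                norm_scope = c("train", "all")) {
  norm_scope <- match.arg(norm_scope)
  strategies <- match.arg(strategies, several.ok = TRUE)
  descs <- compute_descriptors(dataset)
  subj <- vapply(descs, function(s) as.character(s$subject), character(1))
  fit_pool <- if (norm_scope == "train") descs[subj %in% fold$train_subjects] else descs
  stats <- fit_normalizer(fit_pool)
  descs <- normalize_samples(descs, stats)
  train <- descs[subj %in% fold$train_subjects]
  val <- descs[subj %in% fold$val_subjects]

  shots <- sort(unique(config$k_shot))
  k_max <- max(shots, 1L)
  fit <- pretrain(train, config)
  meta_fit <- NULL
  if ("mtl" %in% strategies) {
    cfg_meta <- config
    cfg_meta$k_shot <- k_max
    meta_fit <- meta_update(fit$params, train, val, cfg_meta)
  }
  rows <- list()
  for (u in fold$test_subjects) {
    user_samples <- descs[subj == u]
    # one task per user: every strategy and shot count shares the same query
    # set, and smaller support sets are nested in larger ones, so strategy
    # comparisons are not confounded by query resampling noise
    task <- sample_task(user_samples, subject = u, n_way = config$n_way,
                        k_shot = k_max, n_query = config$n_query,
                        seed = derive_seed(config$seed, 7000L + string_to_int(u)))
    sup_labels <- vapply(task$support, function(s) as.integer(s$label), integer(1))
    for (strategy in strategies) {
      strat_shots <- if (strategy == "ml") 0 else shots
      for (k in strat_shots) {
        model <- if (strategy == "ml") {
          fit$params
        } else {
          keep <- unlist(lapply(task$classes, function(cl) {
            which(sup_labels == cl)[seq_len(k)]
          }))
          base <- if (strategy == "tl") fit$params else meta_fit$params
          # both transfer strategies fine-tune the pre-trained classifier
          # head, so TL and MTL differ only by the meta-learned SS scalars
          domain_adapt(base, task$support[keep], config)$params
        }
        rows[[length(rows) + 1L]] <- data.frame(
          strategy = strategy, shots = k, subject = u,
          accuracy = evaluate_user(model, task$query))
      }
    }
  }
  list(results = do.call(rbind, rows), fold = fold,
       pretrain_fit = fit, meta_fit = meta_fit)
}

string_to_int <- function(s) {
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 10000L
}
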