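# Three-phase meta-transfer training.
#
# Phase 1 (pre-train): all training subjects' descriptors are pooled and the
# full network F(Theta, theta) is trained jointly by Adam on mini-batch
# cross-entropy.  Phase 2 (meta-update): the classifier head theta* is
# re-initialized, the conv weights of Theta^pre are frozen, and only the ten
# SS scalars (one scale + one shift per conv layer) are meta-learned: each
# meta-batch adapts a transient classifier copy per subject-specific task on
# its support set (inner loop, plain gradient descent), sums the resulting
# query losses into the meta-loss, and takes one first-order Adam step on the
# SS scalars; the SS snapshot with the best validation-task accuracy is kept.
# Phase 3 (domain adaptation): for a new user, only the classifier head is
# fine-tuned on a few support samples with the whole feature extractor
# (conv weights and SS scalars) fixed.

#' Training configuration
#'
#' Defaults follow the study protocol: all three learning rates start at
#' 0.001 and drop by 1\% every 10 epochs; pre-training runs 50 epochs at
#' batch size 64; the meta phase runs 40 epochs of 60 tasks grouped into 12
#' meta-batches of 5, with 30 validation tasks per epoch; inner adaptation
#' uses 5 plain gradient steps at rate 0.01; domain adaptation runs 50
#' full-support Adam passes.
#'
#' @param lr_pretrain,lr_ss,lr_adapt Learning rates (alpha, lambda, beta).
#' @param lr_decay,decay_every Multiplicative decay and its epoch period.
#' @param pretrain_epochs,meta_epochs,adapt_epochs Phase lengths.
#' @param batch_size Pre-training mini-batch size.
#' @param inner_steps,lr_inner Inner-loop gradient steps and rate.
#' @param n_way,k_shot,n_query Episode composition.
#' @param tasks_per_loop,meta_batch_size,n_val_tasks Meta-phase episode
#'   budget per epoch.
#' @param seed Integer master seed.
#' @return A `training_config` list.
#' @export
training_config <- function(lr_pretrain = 0.001, lr_ss = 0.001, lr_adapt = 0.001,
                            lr_decay = 0.99, decay_every = 10,
                            pretrain_epochs = 50, meta_epochs = 40,
                            adapt_epochs = 50, batch_size = 64,
                            inner_steps = 5, lr_inner = 0.01,
                            n_way = 4, k_shot = 5, n_query = 10,
                            tasks_per_loop = 60, meta_batch_size = 5,
                            n_val_tasks = 30, seed = 1L) {
  cfg <- list(lr_pretrain = lr_pretrain, lr_ss = lr_ss, lr_adapt = lr_adapt,
              lr_decay = lr_decay, decay_every = decay_every,
              pretrain_epochs = pretrain_epochs, meta_epochs = meta_epochs,
              adapt_epochs = adapt_epochs, batch_size = batch_size,
              inner_steps = inner_steps, lr_inner = lr_inner,
              n_way = n_way, k_shot = k_shot, n_query = n_query,
              tasks_per_loop = tasks_per_loop, meta_batch_size = meta_batch_size,
              n_val_tasks = n_val_tasks, seed = as.integer(seed))
  if (any(c(cfg$lr_pretrain, cfg$lr_ss, cfg$lr_adapt) < 0)) {
    stopf("learning rates must be nonnegative")
  }
  if (cfg$lr_decay <= 0 || cfg$lr_decay > 1) stopf("lr_decay must be in (0, 1]")
  if (any(c(cfg$pretrain_epochs, cfg$meta_epochs, cfg$adapt_epochs) < 1)) {
    stopf("epoch counts must be >= 1")
  }
  structure(cfg, class = "training_config")
}

#' Cross-entropy loss
#'
#' `-log p[label]` with the probability floored at 1e-12; for a probability
#' matrix (classes x batch) and a label vector, the batch mean.
#'
#' @param probs Probability vector, or `K x B` matrix of column
#'   distributions.
#' @param label 0-based class id(s).
#' @return Nonnegative scalar loss.
#' @export
cross_entropy <- function(probs, label) {
  if (is.matrix(probs)) {
    if (any(label < 0 | label >= nrow(probs))) stopf("label out of range")
    p <- probs[cbind(label + 1L, seq_len(ncol(probs)))]
    return(mean(-log(pmax(p, 1e-12))))
  }
  if (label < 0 || label >= length(probs)) stopf("label out of range")
  -log(max(probs[label + 1L], 1e-12))
}

# ---- phase 1: pre-train ----------------------------------------------------

#' Pre-train the full network on pooled source subjects
#'
#' Merges all training subjects' normalized descriptors, shuffles them each
#' epoch, and trains extractor and classifier jointly by Adam on mini-batch
#' cross-entropy with the decayed learning rate.  The SS scalars stay at
#' their identity throughout.
#'
#' @param samples List of normalized [spd_sample()] objects (all training
#'   subjects pooled).
#' @param config A [training_config()].
#' @param params Optional starting `model_params`; built fresh from the
#'   config seed when omitted.
#' @return List with `params` (class `model_params`), `loss_trace`
#'   (per-epoch mean loss) and `train_accuracy` (final accuracy on the
#'   pooled training set).
#' @export
pretrain <- function(samples, config = training_config(), params = NULL) {
  if (length(samples) == 0) stopf("no training samples")
  st <- stack_samples(samples)
  K <- max(st$labels) + 1L
  d <- dim(st$x)[1]
  if (is.null(params)) params <- build_params(d, max(K, 2L), derive_seed(config$seed, 1L))
  opt_params <- list(extractor = params$extractor, classifier = params$classifier)
  opt <- adam_init(opt_params)
  n <- dim(st$x)[3]
  loss_trace <- numeric(config$pretrain_epochs)
  with_seed(derive_seed(config$seed, 2L), {
    for (epoch in seq_len(config$pretrain_epochs)) {
      lr <- lr_at_epoch(config$lr_pretrain, epoch, config$lr_decay, config$decay_every)
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        xb <- st$x[, , idx, drop = FALSE]
        yb <- st$labels[idx]
        fw <- net_forward(params, xb, keep_cache = TRUE)
        losses <- c(losses, cross_entropy(fw$probs, yb))
        if (lr > 0) {
          g <- net_backward(params, fw, yb, want = c("extractor", "classifier"))
          stepped <- adam_step(opt, list(extractor = params$extractor,
                                         classifier = params$classifier),
                               list(extractor = g$extractor,
                                    classifier = g$classifier), lr)
          opt <- stepped$state
          params$extractor <- stepped$params$extractor
          params$classifier <- stepped$params$classifier
        }
      }
      loss_trace[epoch] <- mean(losses)
    }
  })
  preds <- predict_batch(params, samples)
  list(params = params, loss_trace = loss_trace,
       train_accuracy = mean(preds == st$labels))
}

# ---- phase 2: inner loop and meta-update -----------------------------------

# Gradients of the mean cross-entropy wrt the two FC layers only, with the
# flattened conv features given (the extractor is frozen inside tasks).
classifier_forward <- function(clf, feats) {
  H1 <- crossprod(clf$W1, feats) + clf$b1
  H1r <- H1 * (H1 > 0)
  logits <- crossprod(clf$W2, H1r) + clf$b2
  list(probs = softmax_cols(logits), H1 = H1, H1r = H1r)
}

classifier_grads <- function(clf, feats, labels) {
  B <- ncol(feats)
  fw <- classifier_forward(clf, feats)
  dlogits <- fw$probs
  dlogits[cbind(labels + 1L, seq_len(B))] <- dlogits[cbind(labels + 1L, seq_len(B))] - 1
  dlogits <- dlogits / B
  dH1 <- (clf$W2 %*% dlogits) * (fw$H1 > 0)
  list(grads = list(W1 = feats %*% t(dH1), b1 = rowSums(dH1),
                    W2 = fw$H1r %*% t(dlogits), b2 = rowSums(dlogits)),
       loss = cross_entropy(fw$probs, labels),
       probs = fw$probs)
}

#' Adapt a transient classifier to one task
#'
#' Runs `inner_steps` plain gradient-descent steps on the support-set
#' cross-entropy, updating only a copy of the classifier head; the feature
#' extractor (conv weights and SS scalars) is frozen, so conv features are
#' computed once per task.  Returns the adapted head and its query loss.
#'
#' @param task An `episodic_task` of normalized descriptors.
#' @param params `model_params` providing the frozen extractor.
#' @param theta_init Classifier list (`W1`, `b1`, `W2`, `b2`) to start from;
#'   defaults to `params$classifier`.
#' @param inner_steps,lr_inner Inner-loop schedule.
#' @return List with `theta`, `query_loss`, `query_accuracy` and
#'   `support_losses` (loss before each step).
#' @export
inner_adapt <- function(task, params, theta_init = NULL,
                        inner_steps = 5, lr_inner = 0.01) {
  if (length(task$support) == 0) stopf("task has an empty support set")
  theta <- theta_init %||% params$classifier
  sup <- stack_samples(task$support)
  qry <- stack_samples(task$query)
  fs <- net_features(params, sup$x)
  fq <- net_features(params, qry$x)
  support_losses <- numeric(inner_steps)
  if (inner_steps > 0) {
    for (s in seq_len(inner_steps)) {
      cg <- classifier_grads(theta, fs, sup$labels)
      support_losses[s] <- cg$loss
      theta <- tree_map2(function(p, g) p - lr_inner * g, theta, cg$grads)
    }
  }
  qf <- classifier_forward(theta, fq)
  preds <- max.col(t(qf$probs), ties.method = "first") - 1L
  list(theta = theta,
       query_loss = cross_entropy(qf$probs, qry$labels),
       query_accuracy = mean(preds == qry$labels),
       support_losses = support_losses)
}

#' Meta-loss of a task batch
#'
#' Sum of the per-task query losses.
#'
#' @param task_losses Numeric vector of query losses.
#' @return Scalar sum.
#' @export
meta_loss <- function(task_losses) {
  if (length(task_losses) == 0) stopf("no task losses")
  sum(task_losses)
}

# Query-loss gradient wrt the SS scalars for one task, with the adapted
# classifier held fixed (first-order meta-gradient).
ss_query_grad <- function(params, theta_task, task) {
  p <- params
  p$classifier <- theta_task
  qry <- stack_samples(task$query)
  fw <- net_forward(p, qry$x, keep_cache = TRUE)
  g <- net_backward(p, fw, qry$labels, want = "ss")
  list(ss = g$ss, loss = cross_entropy(fw$probs, qry$labels))
}

#' Meta-learn the SS scalars over subject-specific tasks
#'
#' Freezes the pre-trained conv weights, re-initializes the classifier head
#' once, and for each meta epoch samples `tasks_per_loop` episodic tasks
#' cycled evenly over the training subjects, grouped into meta-batches.  Each
#' meta-batch adapts a transient classifier per task ([inner_adapt()]),
#' sums the query losses into the meta-loss, and takes one first-order Adam
#' step on the ten SS scalars at the decayed rate `lr_ss`.  After every
#' epoch, mean query accuracy on `n_val_tasks` validation-subject tasks is
#' measured (the identity-SS starting point is scored the same way), and the
#' best SS snapshot under a conservative one-standard-error rule is
#' returned: a snapshot replaces the incumbent only when its validation
#' accuracy exceeds it by more than the standard error of the task-level
#' accuracy estimate, so noisy validation wins do not displace the simpler
#' earlier candidate.
#'
#' @param params Pre-trained `model_params` (from [pretrain()]).
#' @param train_samples Normalized descriptors of the training subjects.
#' @param val_samples Normalized descriptors of the validation subjects.
#' @param config A [training_config()].
#' @return List with `params` (conv weights bit-identical to the input, SS
#'   replaced by the selected snapshot), `theta_star` (the re-initialized
#'   head), `meta_loss_trace`, `val_accuracy_trace` and `selected_epoch`
#'   (0 = the identity-SS start).
#' @export
meta_update <- function(params, train_samples, val_samples,
                        config = training_config()) {
  train_subjects <- sort(unique(vapply(train_samples, function(s) as.character(s$subject),
                                       character(1))))
  val_subjects <- sort(unique(vapply(val_samples, function(s) as.character(s$subject),
                                     character(1))))
  if (length(val_subjects) == 0) stopf("meta_update needs at least one validation subject")
  # randomly re-initialize theta*; conv weights stay frozen from here on
  fresh <- build_params(params$input_dim, params$n_classes, derive_seed(config$seed, 3L))
  theta_star <- fresh$classifier
  ss <- list(scale = rep(1, 5), shift = rep(0, 5))
  opt <- adam_init(ss)

  eval_val <- function(ss_now, seed0) {
    p <- params
    p$ss <- ss_now
    vapply(seq_len(config$n_val_tasks), function(i) {
      subj <- subject_cycle(val_subjects, config$n_val_tasks)[i]
      task <- sample_task(val_samples, subject = subj, n_way = config$n_way,
                         k_shot = config$k_shot, n_query = config$n_query,
                         seed = derive_seed(seed0, i), task_id = i)
      inner_adapt(task, p, theta_init = theta_star,
                  inner_steps = config$inner_steps,
                  lr_inner = config$lr_inner)$query_accuracy
    }, numeric(1))
  }

  # snapshot selection: the identity-SS starting point is a candidate, and a
  # later snapshot replaces the incumbent only if its validation accuracy
  # beats it by more than one standard error of the task-level estimate
  # (the usual conservative one-SE model-selection rule)
  best_ss <- ss
  best_epoch <- 0L
  acc0 <- eval_val(ss, derive_seed(config$seed, 4L))
  best_val <- mean(acc0)
  val_margin <- stats::sd(acc0) / sqrt(length(acc0))
  val_trace <- best_val
  loss_trace <- numeric(config$meta_epochs)

  for (epoch in seq_len(config$meta_epochs)) {
    lr <- lr_at_epoch(config$lr_ss, epoch, config$lr_decay, config$decay_every)
    task_subjects <- subject_cycle(train_subjects, config$tasks_per_loop)
    task_seed0 <- derive_seed(config$seed, 1000L + epoch)
    tasks <- lapply(seq_len(config$tasks_per_loop), function(i) {
      sample_task(train_samples, subject = task_subjects[i], n_way = config$n_way,
                  k_shot = config$k_shot, n_query = config$n_query,
                  seed = derive_seed(task_seed0, i), task_id = i)
    })
    batches <- build_meta_batches(tasks, config$meta_batch_size, strict = FALSE)
    epoch_losses <- c()
    p <- params
    for (batch in batches) {
      p$ss <- ss
      batch_grads <- list(scale = numeric(5), shift = numeric(5))
      batch_losses <- numeric(length(batch))
      for (bi in seq_along(batch)) {
        ad <- inner_adapt(batch[[bi]], p, theta_init = theta_star,
                          inner_steps = config$inner_steps,
                          lr_inner = config$lr_inner)
        qg <- ss_query_grad(p, ad$theta, batch[[bi]])
        batch_grads$scale <- batch_grads$scale + qg$ss$scale
        batch_grads$shift <- batch_grads$shift + qg$ss$shift
        batch_losses[bi] <- qg$loss
      }
      epoch_losses <- c(epoch_losses, meta_loss(batch_losses))
      if (lr > 0) {
        stepped <- adam_step(opt, ss, batch_grads, lr)
        opt <- stepped$state
        ss <- stepped$params
      }
    }
    loss_trace[epoch] <- sum(epoch_losses)
    val_acc <- mean(eval_val(ss, derive_seed(config$seed, 2000L + epoch)))
    val_trace <- c(val_trace, val_acc)
    if (val_acc > best_val + val_margin) {
      best_val <- val_acc
      best_ss <- ss
      best_epoch <- epoch
    }
  }
  out <- params
  out$ss <- best_ss
  list(params = out, theta_star = theta_star,
       meta_loss_trace = loss_trace, val_accuracy_trace = val_trace,
       selected_epoch = best_epoch, val_accuracy = best_val)
}

# ---- phase 3: domain adaptation --------------------------------------------

#' Few-shot adaptation of the classifier head to a new user
#'
#' Fine-tunes only the classifier on the user's support descriptors by Adam
#' (`adapt_epochs` full-support passes at the decayed rate `lr_adapt`); the
#' feature extractor — conv weights and SS scalars — is fixed throughout.
#'
#' @param params `model_params` (typically the meta-trained model).
#' @param support List of the user's normalized support descriptors
#'   (class-balanced k-shot set).
#' @param config A [training_config()].
#' @param theta_init Optional starting head; defaults to the model's own
#'   classifier, i.e. plain fine-tuning.
#' @return List with `params` (extractor bit-identical to the input,
#'   classifier adapted) and `loss_trace`.
#' @export
domain_adapt <- function(params, support, config = training_config(),
                         theta_init = NULL) {
  if (length(support) == 0) stopf("empty support set")
  theta <- theta_init %||% params$classifier
  sup <- stack_samples(support)
  feats <- net_features(params, sup$x)
  opt <- adam_init(theta)
  loss_trace <- numeric(config$adapt_epochs)
  for (epoch in seq_len(config$adapt_epochs)) {
    lr <- lr_at_epoch(config$lr_adapt, epoch, config$lr_decay, config$decay_every)
    cg <- classifier_grads(theta, feats, sup$labels)
    loss_trace[epoch] <- cg$loss
    if (lr > 0) {
      stepped <- adam_step(opt, theta, cg$grads, lr)
      opt <- stepped$state
      theta <- stepped$params
    }
  }
  out <- params
  out$classifier <- theta
  list(params = out, loss_trace = loss_trace)
}
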