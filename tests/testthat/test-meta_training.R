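# Shared small training fixture: 4 subjects, calibrated default regime,
# shortened schedules so each phase runs in seconds.
mt_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      study <- tiny_study(n_subjects = 4, n_trials = 16, n_samples = 256,
                         mixing = 0.3, seed = 77)
      dd <- study_descriptors(study, fit_subjects = c("S1", "S2"))
      cfg <- training_config(pretrain_epochs = 4, meta_epochs = 2,
                             adapt_epochs = 10, tasks_per_loop = 10,
                             meta_batch_size = 5, n_val_tasks = 6,
                             k_shot = 3, n_query = 5, seed = 99)
      fit <- pretrain(dd$samples[dd$subjects %in% c("S1", "S2")], cfg)
      cache <<- list(study = study, dd = dd, cfg = cfg, fit = fit)
    }
    cache
  }
})

test_that("cross-entropy matches its closed forms and validates labels", {
  expect_equal(cross_entropy(rep(0.25, 4), 0L), log(4), tolerance = 1e-12)
  expect_equal(cross_entropy(c(0, 1, 0), 1L), 0)
  expect_equal(cross_entropy(c(exp(-1), 1 - exp(-1)), 0L), 1, tolerance = 1e-12)
  expect_equal(cross_entropy(matrix(c(1, 0, 0, 1), 2, 2), c(0L, 1L)), 0)
  expect_error(cross_entropy(rep(0.25, 4), 4L), "out of range")
  # floored probability keeps the loss finite
  expect_true(is.finite(cross_entropy(c(0, 1), 0L)))
})

test_that("the learning-rate schedule drops by 1% every 10 epochs", {
  expect_equal(lr_at_epoch(0.001, 1), 0.001)
  expect_equal(lr_at_epoch(0.001, 10), 0.001)
  expect_equal(lr_at_epoch(0.001, 11), 0.00099)
  for (k in 1:5) expect_equal(lr_at_epoch(0.001, 10 * k + 1), 0.001 * 0.99^k)
})

test_that("zero-initialized logits give the uniform-predictor loss", {
  p <- zero_params(build_params(12, 4, seed = 1))
  s <- random_spd_sample(12, 5)
  expect_equal(cross_entropy(forward(p, s), 2L), log(4), tolerance = 1e-9)
})

test_that("pretraining at zero learning rate leaves parameters untouched", {
  fx <- mt_fixture()
  cfg0 <- fx$cfg
  cfg0$lr_pretrain <- 0
  cfg0$pretrain_epochs <- 2
  init <- build_params(12, 4, seed = 123)
  fit <- pretrain(fx$dd$samples[fx$dd$subjects == "S1"], cfg0, params = init)
  expect_identical(param_checksum(fit$params), param_checksum(init))
})

test_that("pretraining reduces loss and never touches the SS scalars", {
  fx <- mt_fixture()
  expect_lt(tail(fx$fit$loss_trace, 1), fx$fit$loss_trace[1])
  expect_identical(fx$fit$params$ss, list(scale = rep(1, 5), shift = rep(0, 5)))
  # deterministic given the seed
  refit <- pretrain(fx$dd$samples[fx$dd$subjects %in% c("S1", "S2")], fx$cfg)
  expect_identical(refit$loss_trace, fx$fit$loss_trace)
  expect_identical(param_checksum(refit$params), param_checksum(fx$fit$params))
})

test_that("inner adaptation updates only a classifier copy and reduces support loss", {
  fx <- mt_fixture()
  task <- sample_task(fx$dd$samples[fx$dd$subjects == "S3"], subject = "S3",
                      n_way = 4, k_shot = 3, n_query = 5, seed = 8)
  before <- param_checksum(list(fx$fit$params$extractor, fx$fit$params$ss))
  noop <- inner_adapt(task, fx$fit$params, inner_steps = 0)
  expect_identical(noop$theta, fx$fit$params$classifier)
  adapted <- inner_adapt(task, fx$fit$params, inner_steps = 8, lr_inner = 0.05)
  expect_identical(param_checksum(list(fx$fit$params$extractor, fx$fit$params$ss)),
                   before)
  expect_lt(tail(adapted$support_losses, 1), adapted$support_losses[1])
  expect_false(identical(adapted$theta, fx$fit$params$classifier))
  expect_error(inner_adapt(list(support = list(), query = list()), fx$fit$params),
               "empty support")
})

test_that("meta-loss is the plain sum and is partition-additive", {
  expect_equal(meta_loss(c(0.5, 1.5)), 2)
  expect_equal(meta_loss(0), 0)
  losses <- spdcnn:::with_seed(1, runif(60))
  by_batch <- vapply(split(losses, rep(1:12, each = 5)), meta_loss, numeric(1))
  expect_equal(sum(by_batch), meta_loss(losses))
  expect_error(meta_loss(numeric(0)), "no task losses")
})

test_that("the meta phase learns only the SS scalars and freezes conv weights", {
  fx <- mt_fixture()
  train <- fx$dd$samples[fx$dd$subjects %in% c("S1", "S2")]
  val <- fx$dd$samples[fx$dd$subjects == "S3"]
  conv_before <- param_checksum(fx$fit$params$extractor)
  clf_before <- param_checksum(fx$fit$params$classifier)
  meta <- meta_update(fx$fit$params, train, val, fx$cfg)
  expect_identical(param_checksum(meta$params$extractor), conv_before)
  expect_identical(param_checksum(meta$params$classifier), clf_before)
  expect_length(meta$val_accuracy_trace, fx$cfg$meta_epochs + 1)
  # zero meta learning rate: SS stays at identity
  cfg0 <- fx$cfg
  cfg0$lr_ss <- 0
  meta0 <- meta_update(fx$fit$params, train, val, cfg0)
  expect_identical(meta0$params$ss, list(scale = rep(1, 5), shift = rep(0, 5)))
  expect_error(meta_update(fx$fit$params, train, list(), fx$cfg),
               "validation subject")
})

test_that("domain adaptation freezes the feature extractor", {
  fx <- mt_fixture()
  user <- fx$dd$samples[fx$dd$subjects == "S4"]
  task <- sample_task(user, subject = "S4", n_way = 4, k_shot = 3, n_query = 5,
                      seed = 12)
  ext_before <- param_checksum(list(fx$fit$params$extractor, fx$fit$params$ss))
  ad <- domain_adapt(fx$fit$params, task$support, fx$cfg)
  expect_identical(param_checksum(list(ad$params$extractor, ad$params$ss)),
                   ext_before)
  cfg0 <- fx$cfg
  cfg0$lr_adapt <- 0
  ad0 <- domain_adapt(fx$fit$params, task$support, cfg0)
  expect_identical(ad0$params$classifier, fx$fit$params$classifier)
  expect_error(domain_adapt(fx$fit$params, list(), fx$cfg), "empty support")
})

test_that("few-shot adaptation on a shifted user beats zero-shot on its query", {
  study <- tiny_study(n_subjects = 5, n_trials = 30, n_samples = 1024,
                      mixing = 0.3, seed = 3)
  dd <- study_descriptors(study, fit_subjects = paste0("S", 1:4))
  cfg <- training_config(pretrain_epochs = 10, adapt_epochs = 50,
                         k_shot = 10, n_query = 10, seed = 3)
  fit <- pretrain(dd$samples[dd$subjects %in% paste0("S", 1:4)], cfg)
  user <- dd$samples[dd$subjects == "S5"]
  task <- sample_task(user, subject = "S5", n_way = 4, k_shot = 10,
                      n_query = 10, seed = 30)
  zero_shot <- evaluate_user(fit$params, task$query)
  adapted <- domain_adapt(fit$params, task$support, cfg)
  expect_gte(evaluate_user(adapted$params, task$query), zero_shot)
})

test_that("training configuration rejects invalid settings", {
  expect_error(training_config(lr_pretrain = -1), "nonnegative")
  expect_error(training_config(lr_decay = 0), "lr_decay")
  expect_error(training_config(pretrain_epochs = 0), "epoch counts")
})
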