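test_that("folds partition subjects with the configured role sizes", {
  subjects <- paste0("S", 1:9)
  folds <- make_folds(subjects, n_val = 3, n_test = 2, n_folds = 18, seed = 4)
  expect_length(folds, 18)
  for (f in folds) {
    expect_length(f$train_subjects, 4)
    expect_length(f$val_subjects, 3)
    expect_length(f$test_subjects, 2)
    expect_length(intersect(f$val_subjects, f$test_subjects), 0)
    expect_length(intersect(f$train_subjects, c(f$val_subjects, f$test_subjects)), 0)
    expect_setequal(c(f$train_subjects, f$val_subjects, f$test_subjects), subjects)
  }
  expect_identical(make_folds(subjects, 3, 2, 18, seed = 4),
                   make_folds(subjects, 3, 2, 18, seed = 4))
})

test_that("the larger cohort protocol yields 28 folds of 7 training subjects", {
  folds <- make_folds(paste0("S", 1:14), n_val = 5, n_test = 2, n_folds = 28, seed = 1)
  expect_length(folds, 28)
  expect_true(all(vapply(folds, function(f) length(f$train_subjects), integer(1)) == 7L))
})

test_that("fold construction rejects impossible partitions and warns on repetition", {
  expect_error(make_folds(paste0("S", 1:4), n_val = 3, n_test = 2, n_folds = 2),
               "cannot partition")
  expect_warning(make_folds(paste0("S", 1:4), n_val = 2, n_test = 1, n_folds = 100,
                            seed = 1), "repetition")
})

test_that("balanced folds cycle every subject through the test role", {
  subjects <- paste0("S", 1:6)
  folds <- make_folds(subjects, n_val = 2, n_test = 2, n_folds = 3, seed = 9,
                      balanced = TRUE)
  tested <- unlist(lapply(folds, `[[`, "test_subjects"))
  expect_setequal(tested, subjects)
})

test_that("episodic tasks have exact composition and disjoint balanced splits", {
  study <- tiny_study(n_subjects = 2, n_trials = 16, n_samples = 64)
  task <- sample_task(study$dataset, subject = "S1", n_way = 4, k_shot = 5,
                      n_query = 10, seed = 2)
  expect_length(task$support, 20)
  expect_length(task$query, 40)
  sup_lab <- vapply(task$support, `[[`, integer(1), "label")
  qry_lab <- vapply(task$query, `[[`, integer(1), "label")
  expect_identical(as.integer(table(sup_lab)), rep(5L, 4))
  expect_identical(as.integer(table(qry_lab)), rep(10L, 4))
  # disjointness via matrix identity: no support trial reappears in the query
  sup_keys <- vapply(task$support, function(s) paste(s$data[1, 1:4], collapse = ","),
                     character(1))
  qry_keys <- vapply(task$query, function(s) paste(s$data[1, 1:4], collapse = ","),
                     character(1))
  expect_length(intersect(sup_keys, qry_keys), 0)
  expect_identical(sample_task(study$dataset, "S1", 4, 5, 10, seed = 2),
                   sample_task(study$dataset, "S1", 4, 5, 10, seed = 2))
})

test_that("a 5-way 10-shot task has a 50-sample support set", {
  classes <- make_class_covariances(10, 5, seed = 8)
  ds <- generate_subject_dataset(subject_spec("U", 0.2, seed = 3), classes, 15,
                                 n_samples = 64, seed = 5)
  task <- sample_task(ds, subject = "U", n_way = 5, k_shot = 10, n_query = 5, seed = 1)
  expect_length(task$support, 50)
})

test_that("tasks are subject-pure and class-balanced over many draws", {
  study <- tiny_study(n_subjects = 3, n_trials = 16, n_samples = 64)
  descs <- study_descriptors(study)
  for (i in 1:50) {
    subj <- paste0("S", (i %% 3) + 1)
    task <- sample_task(descs$samples, subject = subj, n_way = 4, k_shot = 2,
                        n_query = 3, seed = i)
    all_samples <- c(task$support, task$query)
    expect_true(all(vapply(all_samples, `[[`, character(1), "subject") == subj))
    expect_identical(as.integer(table(vapply(task$support, `[[`, integer(1), "label"))),
                     rep(2L, 4))
  }
})

test_that("insufficient trials raise an error naming subject and class", {
  study <- tiny_study(n_subjects = 1, n_trials = 4, n_samples = 64)
  expect_error(sample_task(study$dataset, "S1", 4, 5, 10, seed = 1),
               "subject S1, class 0")
})

test_that("meta-batch partitioning enforces divisibility in strict mode", {
  tasks <- as.list(1:60)
  batches <- build_meta_batches(tasks, 5)
  expect_length(batches, 12)
  expect_true(all(lengths(batches) == 5))
  expect_length(build_meta_batches(as.list(1:5), 5), 1)
  expect_error(build_meta_batches(as.list(1:7), 5), "divide")
  expect_length(build_meta_batches(as.list(1:7), 5, strict = FALSE), 2)
  expect_error(build_meta_batches(tasks, 0), "positive")
})
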