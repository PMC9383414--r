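# spdcnn

Cross-subject EEG motor-imagery classification from spatial covariance
descriptors, with a plain convolutional classifier and a three-phase
meta-transfer-learning procedure for few-shot adaptation to new users.

EEG classifiers trained on one group of subjects transfer poorly to a new
user: electrode placement and individual brain dynamics shift the data
distribution per subject. This package addresses the few-shot cross-subject
setting in three steps:

* **SPD descriptor** — each trial `X` (`d` channels × `T` samples, channels
  centered) becomes its spatial covariance `C = X Xᵀ / T`, a `d × d`
  symmetric positive semidefinite matrix, standardized elementwise against
  statistics fitted on the training subjects.
* **SPD-CNN** — a small plain CNN over the `d × d` matrix: five valid 2×2
  convolutions (4, 8, 16, 32, 64 channels, ReLU), one 2×2 max-pool after the
  third, then a 32-unit fully connected layer and a softmax over `K`
  classes. Each conv layer carries one *scaling* scalar (on its weights) and
  one *shifting* scalar (on its biases).
* **Meta-transfer learning** — (1) pre-train the whole network on pooled
  training subjects; (2) freeze the conv weights and meta-learn only the ten
  scaling/shifting scalars over subject-specific N-way K-shot episodic
  tasks, selecting the snapshot by validation subjects; (3) for a new user,
  fine-tune only the classifier head on `k` labeled trials per class.

A synthetic multi-subject generator (class identity carried by the source
covariance, subject identity by a linear mixing perturbation `I + εR`)
makes the whole pipeline testable without external recordings. See
`vignettes/spdcnn-methods.Rmd` for the model, protocol and design choices.

## Worked example

```r
library(spdcnn)

# a synthetic 10-subject, 4-class study with subject shift eps = 0.3
classes <- make_class_covariances(d = 12, K = 4, seed = 5)
study   <- generate_study(10, classes, n_trials_per_class = 40,
                          mixing_strength = 0.3, seed = 1)

fold <- list(train_subjects = paste0("S", 1:6),
             val_subjects   = paste0("S", 7:8),
             test_subjects  = paste0("S", 9:10), fold_index = 1L)
cfg  <- training_config(seed = 1, pretrain_epochs = 15, meta_epochs = 10,
                        k_shot = c(5, 10))
res  <- run_fold_experiment(study$dataset, fold, cfg)
with(res$results, tapply(accuracy, paste(strategy, shots), mean))
```

```
  ml 0  mtl 10   mtl 5   tl 10    tl 5
0.6750  0.7750  0.6875  0.7750  0.6875
```

Reading: the zero-shot pre-trained model (`ml 0`) reaches 67.5% on the two
held-out users' query sets; fine-tuning the classifier head on 10 labeled
trials per class (`tl 10`) lifts it to 77.5%; the meta-trained model
(`mtl 10`) matches or exceeds that (here its validation-selected
scaling/shifting scalars coincide with the identity, so it ties TL). With
half the calibration data (`* 5`) accuracy drops, as expected.

The distance analysis behind the descriptor's motivation:

```r
rep_spd <- subject_distance(split_descriptors_by_subject)  # see ?subject_distance
```

returns the per-class mean inter-subject Euclidean distance in a 2D PCA
projection; on the synthetic study it is roughly fifty times smaller for
descriptors than for raw flattened trials, i.e. the covariance
representation closes most of the between-subject gap.

## Command line

A thin launcher over the same functions:

```sh
Rscript inst/cli/spdcnn.R simulate --subjects 10 --classes 4 --seed 1 --out trials.json
Rscript inst/cli/spdcnn.R describe --in trials.json --norm-scope train \
        --train-subjects S1,S2,S3,S4,S5,S6 --out descs.json
Rscript inst/cli/spdcnn.R pretrain --in descs.json --subjects S1,S2,S3,S4,S5,S6 \
        --out pre.json
Rscript inst/cli/spdcnn.R meta-train --in descs.json --model pre.json \
        --train-subjects S1,S2,S3,S4,S5,S6 --val-subjects S7,S8 --out meta.json
Rscript inst/cli/spdcnn.R evaluate --in descs.json --strategy mtl --shots 10 \
        --meta-model meta.json --test-subjects S9,S10 --out results.tsv
Rscript inst/cli/spdcnn.R distance --in trials.json --out distances.tsv
```

Every artifact embeds the seed and configuration hash that produced it, and
`evaluate` refuses artifacts whose geometry does not match the data.

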