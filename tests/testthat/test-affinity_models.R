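make_dataset <- function(reps, seqs = NULL) {
  n <- nrow(reps)
  df <- data.frame(id = paste0("s", seq_len(n)),
                   sequence = seqs %||% replicate(n, paste(sample(aa_alphabet(), 8, TRUE), collapse = "")),
                   stringsAsFactors = FALSE)
  colnames(reps) <- paste0("rep", seq_len(ncol(reps)))
  affinity_dataset(cbind(df, as.data.frame(reps)))
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("preprocess implements the drop and median-impute policies", {
  set.seed(1)
  # dataset-wide median of non-missing values is 4.0 by construction
  ds <- make_dataset(rbind(c(1.0, NA), c(4.0, 4.0)))
  expect_equal(preprocess(ds, "impute")$target, c((1 + 4) / 2, 4))
  expect_equal(preprocess(ds, "drop")$target, c(1.0, 4.0))

  ds2 <- make_dataset(rbind(c(1, 2, 3)))
  expect_equal(preprocess(ds2, "drop")$target, 2)
  expect_equal(preprocess(ds2, "impute")$target, 2)

  # a fully censored record is excluded by drop but retained by impute
  ds3 <- make_dataset(rbind(c(NA, NA), c(2, 2)))
  expect_equal(nrow(preprocess(ds3, "drop")), 1L)
  expect_equal(preprocess(ds3, "impute")$target, c(2, 2))
  expect_false(anyNA(preprocess(ds3, "impute")$target))

  ds4 <- make_dataset(rbind(c(NA, NA), c(NA, NA)))
  expect_error(preprocess(ds4, "drop"), class = "empty_training_set")
})

test_that("split_dataset partitions by sequence with the requested sizes", {
  set.seed(2)
  ds <- make_dataset(matrix(rnorm(3000), ncol = 3),
                     seqs = paste0("S", 1:1000))
  parts <- split_dataset(ds, c(0.8, 0.1, 0.1), seed = 9L)
  expect_identical(vapply(parts, length, integer(1)),
                   c(train = 800L, validation = 100L, test = 100L))
  all_seqs <- c(parts$train$sequence, parts$validation$sequence, parts$test$sequence)
  expect_setequal(all_seqs, ds$sequence)
  expect_false(anyDuplicated(all_seqs) > 0)
  parts2 <- split_dataset(ds, c(0.8, 0.1, 0.1), seed = 9L)
  expect_identical(parts$train$sequence, parts2$train$sequence)
  expect_error(split_dataset(make_dataset(matrix(1, 2, 2)), c(0.5, 0.3, 0.2)),
               class = "insufficient_data")
})

test_that("ensemble member count is |encoders| x 2 losses x 2 policies", {
  sp <- toy_space(L = 8L, nd = 4L, seed = 3L)
  land <- synthetic_landscape(sp, seed = 3L)
  ds <- affinity_dataset(generate_training_data(land, 60L, 1:2, seed = 4L))
  ens3 <- train_ensemble(ds, sp)
  expect_length(ens3$members, 12L)
  ens1 <- train_ensemble(ds, sp, encoders = list(onehot = encoder_onehot(sp)))
  expect_length(ens1$members, 4L)
})

test_that("ensemble prediction is the member mean with population sd", {
  sp <- toy_space(L = 6L, nd = 3L, seed = 5L)
  enc <- encoder_onehot(sp)
  mk_member <- function(intercept) {
    list(encoder_index = 1L, loss = "mse", policy = "drop",
         fit = list(beta = rep(0, enc$dim), intercept = intercept))
  }
  ens <- structure(list(members = list(mk_member(1), mk_member(3)),
                        encoders = list(enc), space = sp),
                   class = "ensemble_model")
  p <- predict(ens, sp$template)
  expect_equal(p$mean, 2)       # mean of {1, 3}
  expect_equal(p$sd, 1)         # population sd of {1, 3}
  ens_same <- structure(list(members = list(mk_member(2), mk_member(2)),
                             encoders = list(enc), space = sp),
                        class = "ensemble_model")
  p2 <- predict(ens_same, sp$template)
  expect_equal(p2$mean, 2)
  expect_equal(p2$sd, 0)
  # member-order invariance and batch consistency
  ens_rev <- structure(list(members = list(mk_member(3), mk_member(1)),
                            encoders = list(enc), space = sp),
                       class = "ensemble_model")
  expect_equal(predict(ens_rev, sp$template), p)
  seqs <- k1_neighbors(sp)[1:5]
  batch <- predict(ens, seqs)
  for (i in seq_along(seqs)) {
    expect_equal(predict(ens, seqs[i]), batch[i, ], ignore_attr = TRUE)
  }
})

test_that("ensemble learns a noiseless additive landscape (held-out Spearman >= 0.9)", {
  set.seed(6)
  sp <- benchmark_space(30L, seed = 61L)
  land <- synthetic_landscape(sp, noise_sd = 0, detection_limit = Inf,
                              n_epistatic = 0L, seed = 62L)
  ds <- affinity_dataset(generate_training_data(land, 2000L, 1:3, seed = 63L))
  parts <- split_dataset(ds, seed = 64L)
  ens <- train_ensemble(parts$train, sp)
  ev <- evaluate_model(ens, parts$test, sp$template)
  expect_gte(ev$spearman, 0.9)
})

test_that("GP attains strong held-out accuracy on a CDR-loop-sized space", {
  set.seed(7)
  sp <- design_space(paste(sample(aa_alphabet(), 40, TRUE), collapse = ""),
                     16:25)
  land <- synthetic_landscape(sp, seed = 71L)
  ds <- affinity_dataset(generate_training_data(land, 1500L, 1:3, seed = 72L))
  parts <- split_dataset(ds, seed = 73L)
  gp <- train_gp(parts$train, sp, seed = 74L)
  # test records all lie at mutational distance <= 3 by construction
  ev <- evaluate_model(gp, parts$test, sp$template)
  expect_gte(ev$spearman, 0.8)
  # posterior sd is strictly positive away from the training data
  far <- exact_k_mutant(sp, sp$template, k = 8L, n = 5L, seed = 75L)
  expect_true(all(predict(gp, far)$sd > 0))
  # extrapolation error grows with distance: MAE beyond distance 8 exceeds
  # MAE within the training shell (distances <= 3)
  near <- parts$test$sequence
  mae <- function(seqs) mean(abs(predict(gp, seqs)$mean - true_affinity(land, seqs)))
  far_big <- exact_k_mutant(sp, sp$template, k = 8L, n = 200L, seed = 76L)
  expect_gt(mae(far_big), mae(near[seq_len(min(200, length(near)))]))
  expect_error(train_gp(parts$train, sp, pca_dim = 0L), class = "invalid_config")
})

test_that("model evaluation reports Spearman, MAE and distance bins correctly", {
  sp <- toy_space(L = 6L, nd = 4L, seed = 8L)
  seqs <- c(sp$template, k1_neighbors(sp)[c(1, 20, 40)])
  ds <- make_dataset(matrix(c(1, 2, 3, 4), 4, 3), seqs = seqs)

  perfect <- stub_model(function(s) {
    data.frame(mean = c(1, 2, 3, 4)[match(s, seqs)], sd = 0)
  })
  ev <- evaluate_model(perfect, ds, sp$template)
  expect_equal(ev$spearman, 1)
  expect_equal(ev$mae_overall, 0)
  expect_identical(sum(ev$mae_by_distance$n), 4L)
  expect_setequal(ev$mae_by_distance$distance, c(0L, 1L))

  negated <- stub_model(function(s) {
    data.frame(mean = -c(1, 2, 3, 4)[match(s, seqs)], sd = 0)
  })
  expect_equal(evaluate_model(negated, ds, sp$template)$spearman, -1)

  # hand-computed Spearman for ranks (1,2,4,3): 1 - 6*2/(4*15) = 0.8
  swapped <- stub_model(function(s) {
    data.frame(mean = c(1, 2, 4, 3)[match(s, seqs)], sd = 0)
  })
  expect_equal(evaluate_model(swapped, ds, sp$template)$spearman, 0.8)
})
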