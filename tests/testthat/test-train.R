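# Small corpora keep these training tests to seconds; the full-scale
# behaviour is exercised by the synthetic recovery experiment.

make_tiny_corpus <- function(n_samples = 6, n_cells = 40, seed = 10) {
  spec <- default_generator_spec(
    n_samples_per_class = c(control = n_samples / 2, case = n_samples / 2),
    cells_per_sample = c(n_cells, n_cells), seed = seed)
  generate_corpus(spec)$samples
}

test_that("pretraining descends and is reproducible from the seed", {
  corpus <- make_tiny_corpus()
  model <- tiny_model(V = 8)
  model$vocabulary <- default_generator_spec()$vocabulary
  model <- init_cytoformer(model$vocabulary, model$config,
                           classes = c("control", "case"), seed = 3)
  cfg <- pretrain_config(epochs = 4, max_cells = 40,
                         validation_fraction = 0)
  m1 <- pretrain(model, corpus, cfg, seed = 21)
  h <- m1$history$pretrain
  expect_true(m1$pretrained)
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  m2 <- pretrain(model, corpus, cfg, seed = 21)
  expect_identical(m1$history$pretrain, m2$history$pretrain)
  expect_true(cytoformer:::tree_identical(m1$params, m2$params))
})

test_that("pretraining on a functionally dependent marker beats the mean predictor", {
  # marker m2 = 0.8 * m1 + small noise: after pretraining, the model's
  # masked prediction of m2 should beat predicting the column mean
  voc <- marker_vocabulary(c("a1", "a2"))
  set.seed(77)
  corpus <- lapply(1:6, function(i) {
    x <- runif(60)
    cyto_sample(cbind(x, 0.8 * x + rnorm(60, sd = 0.05)), c("a1", "a2"),
                sample_id = paste0("s", i))
  })
  model <- init_cytoformer(voc, model_config(hidden_size = 16L,
                                             encoder_layers = 1L,
                                             decoder_layers = 1L,
                                             heads = 2L,
                                             feedforward_multiplier = 2L),
                           seed = 5)
  model <- pretrain(model, corpus,
                    pretrain_config(epochs = 30, max_cells = 60, lr = 3e-3,
                                    validation_fraction = 0),
                    seed = 9)
  # present only marker a1; ask the X head for masked marker a2
  test_x <- runif(200)
  s <- cyto_sample(matrix(test_x), "a1", sample_id = "probe")
  z <- encode(model, s)
  pred_m2 <- pretrain_heads(model, z)$X$mean[, 2]
  truth_m2 <- 0.8 * test_x
  mse_model <- mean((pred_m2 - truth_m2)^2)
  mse_mean <- mean((mean(truth_m2) - truth_m2)^2)
  expect_lt(mse_model, mse_mean)
})

test_that("downstream training descends, freezes the encoder bitwise, and predicts deterministically", {
  corpus <- make_tiny_corpus(n_samples = 8)
  voc <- default_generator_spec()$vocabulary
  model <- init_cytoformer(voc, model_config(16L, 1L, 1L, 2L, 2L),
                           classes = c("control", "case"), seed = 4)
  cfg <- downstream_config(epochs = 4, lr = 1e-3, validation_fraction = 0,
                           max_cells = 40)
  fit <- finetune(model, corpus, cfg, seed = 2)
  expect_true(fit$finetuned)
  frozen <- c("mu", "proj", "enc", "enc_ln", "heads")
  expect_true(cytoformer:::tree_identical(fit$params[frozen],
                                          model$params[frozen]))
  # changed: decoder parameters moved
  expect_false(cytoformer:::tree_identical(fit$params["dec"],
                                           model$params["dec"]))
  # evaluation mode is deterministic
  p1 <- predict(fit, corpus[1:2], type = "prob")
  p2 <- predict(fit, corpus[1:2], type = "prob")
  expect_identical(p1, p2)
  # unfreezing moves the encoder
  cfg2 <- cfg; cfg2$freeze_encoder <- FALSE
  fit2 <- finetune(model, corpus, cfg2, seed = 2)
  expect_false(cytoformer:::tree_identical(fit2$params[frozen],
                                           model$params[frozen]))
})

test_that("single-class corpora and missing labels are configuration errors", {
  corpus <- make_tiny_corpus(n_samples = 4)
  one_class <- corpus[vapply(corpus, function(s) s$label == "case",
                             logical(1))]
  voc <- default_generator_spec()$vocabulary
  model <- init_cytoformer(voc, model_config(8L, 1L, 1L, 2L, 2L), seed = 1)
  expect_error(finetune(model, one_class,
                        downstream_config(validation_fraction = 0)),
               class = "cytoformer_configuration_error")
  unlabelled <- lapply(corpus, function(s) {s$label <- NA; s})
  expect_error(finetune(model, unlabelled),
               class = "cytoformer_configuration_error")
})

test_that("classification metrics match hand-computed values", {
  # confusion TP=3 FP=1 FN=1 TN=3 at threshold 0.5
  truth <- c(rep("pos", 4), rep("neg", 4))
  prob_pos <- c(0.9, 0.8, 0.7, 0.2, 0.1, 0.15, 0.3, 0.6)
  prob <- cbind(neg = 1 - prob_pos, pos = prob_pos)
  m <- classification_metrics(truth, prob, classes = c("neg", "pos"))
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$macro_f1, 0.75)
  expect_equal(unname(m$confusion["pos", "pos"]), 3)
  # perfect predictions
  perfect <- cbind(neg = as.numeric(truth == "neg"),
                   pos = as.numeric(truth == "pos"))
  mp <- classification_metrics(truth, perfect, c("neg", "pos"))
  expect_equal(mp$accuracy, 1); expect_equal(mp$macro_f1, 1)
  expect_equal(mp$auc, 1)
})

test_that("random scores on balanced labels give AUC near one half", {
  set.seed(123)
  n <- 4000
  truth <- rep(c("x", "y"), n / 2)
  p <- runif(n)
  m <- classification_metrics(truth, cbind(x = 1 - p, y = p), c("x", "y"))
  expect_lt(abs(m$auc - 0.5), 3 / sqrt(n))
})

test_that("batch-grouped splits never leak a batch across fold sides", {
  corpus <- make_tiny_corpus(n_samples = 12, n_cells = 10)
  splits <- make_splits(corpus, type = "kfold", k = 3)
  batches <- vapply(corpus, function(s) s$batch_id, character(1))
  names(batches) <- vapply(corpus, function(s) s$sample_id, character(1))
  for (sp in splits) {
    expect_length(intersect(batches[sp$train], batches[sp$test]), 0)
    expect_setequal(c(sp$train, sp$test), names(batches))
  }
  lobo <- make_splits(corpus, type = "leave_one_batch_out")
  expect_length(lobo, length(unique(batches)))
  for (sp in lobo)
    expect_length(unique(batches[sp$test]), 1)
  lopo <- make_splits(corpus, type = "leave_one_panel_out")
  panels <- vapply(corpus, function(s) paste(sort(s$markers), collapse = "+"),
                   character(1))
  expect_length(lopo, length(unique(panels)))
  fh <- make_splits(corpus, type = "fixed_holdout",
                    test_ids = names(batches)[1:3])
  expect_length(fh, 1)
  expect_setequal(fh[[1]]$test, names(batches)[1:3])
})

test_that("cross-validated evaluation aggregates predictions over folds", {
  corpus <- make_tiny_corpus(n_samples = 8, n_cells = 30)
  voc <- default_generator_spec()$vocabulary
  model <- init_cytoformer(voc, model_config(8L, 1L, 1L, 2L, 2L),
                           classes = c("control", "case"), seed = 2)
  splits <- make_splits(corpus, type = "kfold", k = 2)
  res <- evaluate_model(corpus, model,
                        splits,
                        config = downstream_config(epochs = 2,
                                                   validation_fraction = 0,
                                                   max_cells = 30),
                        seed = 3)
  expect_equal(nrow(res$predictions), length(corpus))
  expect_length(res$per_fold, 2)
  expect_true(all(c("accuracy", "macro_f1", "auc", "confusion") %in%
                    names(res$metrics)))
})
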