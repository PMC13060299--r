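#' Predict sample-level labels
#'
#' Runs the full pipeline (embedding, encoder, cross-attention decoder) in
#' evaluation mode: no marker dropout, no activation dropout, so repeated
#' calls give identical predictions. For binary classification the decision
#' threshold on the positive-class probability is 0.5 (equivalently, the
#' argmax of the two softmax probabilities).
#'
#' @param object a trained [cytoformer].
#' @param newdata a [cyto_sample] or list of them.
#' @param type `"response"` (class label / numeric prediction), `"prob"`
#'   (class probability matrix) or `"score"` (raw class scores).
#' @param attention also return attention maps (list column).
#' @param ... unused.
#' @return predictions; a vector/matrix with one row per sample, or, with
#'   `attention = TRUE`, a list with `prediction` and `attention`.
#' @export
predict.cytoformer <- function(object, newdata, type = "response",
                               attention = FALSE, ...) {
  samples <- if (inherits(newdata, "cyto_sample")) list(newdata) else newdata
  res <- lapply(samples, function(s) {
    z <- encode(object, s)
    decode_predict(object, z)
  })
  out <- if (object$task == "regression") {
    vapply(res, function(r) r$prediction, numeric(1))
  } else if (type == "prob") {
    pm <- do.call(rbind, lapply(res, function(r) r$probabilities))
    colnames(pm) <- object$classes
    rownames(pm) <- vapply(samples, function(s) s$sample_id, character(1))
    pm
  } else if (type == "score") {
    do.call(rbind, lapply(res, function(r) r$prediction))
  } else {
    factor(object$classes[vapply(res, function(r)
      which.max(r$probabilities), integer(1))], levels = object$classes)
  }
  if (attention) list(prediction = out,
                      attention = lapply(res, function(r) r$attention))
  else out
}

#' Classification metrics from pooled predictions
#'
#' Accuracy, macro-averaged F1 and AUC (one-vs-rest macro-averaged for more
#' than two classes), plus the confusion matrix. F1 for a class with no
#' predicted and no true instances is treated as 0 in the macro average.
#'
#' @param truth factor or character vector of true labels.
#' @param prob matrix of class probabilities (columns named by class).
#' @param classes class levels, default from `colnames(prob)`.
#' @return list with `accuracy`, `macro_f1`, `auc`, `confusion`.
#' @export
classification_metrics <- function(truth, prob, classes = colnames(prob)) {
  truth <- factor(as.character(truth), levels = classes)
  pred <- factor(classes[apply(prob, 1, which.max)], levels = classes)
  conf <- table(truth = truth, predicted = pred)
  acc <- mean(pred == truth)
  f1s <- vapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (tp == 0 && (fp > 0 || fn > 0)) return(0)
    if (tp == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  auc <- if (length(classes) == 2) {
    as.numeric(pROC::auc(pROC::roc(response = truth,
                                   predictor = prob[, classes[2]],
                                   levels = classes, direction = "<",
                                   quiet = TRUE)))
  } else {
    mean(vapply(classes, function(cl) {
      resp <- factor(ifelse(truth == cl, cl, "rest"),
                     levels = c("rest", cl))
      as.numeric(pROC::auc(pROC::roc(response = resp,
                                     predictor = prob[, cl],
                                     levels = c("rest", cl),
                                     direction = "<", quiet = TRUE)))
    }, numeric(1)))
  }
  list(accuracy = acc, macro_f1 = mean(f1s), auc = auc, confusion = conf)
}

#' Cross-validation split specifications
#'
#' Builds fold definitions over a labelled corpus. Supported types:
#' `kfold` (batch-grouped, class-stratified at the batch level),
#' `leave_one_batch_out`, `leave_one_panel_out` (one fold per panel, or the
#' given `panel` only) and `fixed_holdout` (explicit `test_ids`). With batch
#' grouping, no batch appears on both sides of a fold; if stratification is
#' infeasible a warning is given and a best-effort grouping returned.
#'
#' @param corpus list of [cyto_sample] objects.
#' @param type split type (above).
#' @param k folds for `kfold`.
#' @param panel optional panel fingerprint (sorted markers joined by `+`) for
#'   `leave_one_panel_out`.
#' @param test_ids sample ids for `fixed_holdout`.
#' @param seed integer seed.
#' @return list of folds, each with `train` and `test` sample-id vectors.
#' @export
make_splits <- function(corpus, type = "kfold", k = 5L, panel = NULL,
                        test_ids = NULL, seed = 1L) {
  ids <- vapply(corpus, function(s) s$sample_id, character(1))
  labels <- vapply(corpus, function(s) as.character(s$label), character(1))
  batches <- vapply(corpus, function(s) as.character(s$batch_id),
                    character(1))
  panels <- vapply(corpus, function(s) paste(sort(s$markers), collapse = "+"),
                   character(1))
  if (type == "fixed_holdout") {
    stopifnot(!is.null(test_ids))
    return(list(list(train = setdiff(ids, test_ids), test = test_ids)))
  }
  if (type == "leave_one_batch_out") {
    ub <- unique(batches)
    return(lapply(ub, function(b)
      list(train = ids[batches != b], test = ids[batches == b])))
  }
  if (type == "leave_one_panel_out") {
    up <- if (is.null(panel)) unique(panels) else panel
    return(lapply(up, function(p)
      list(train = ids[panels != p], test = ids[panels == p])))
  }
  # batch-grouped stratified k-fold: assign whole batches to folds, greedily
  # balancing per-class counts
  ub <- unique(batches)
  if (any(is.na(ub)) || length(ub) < k) {
    if (length(ub) < k)
      warning("fewer batches than folds; grouping is best-effort")
    ub <- unique(batches)
  }
  bsize <- vapply(ub, function(b) sum(batches == b), numeric(1))
  bclass <- lapply(ub, function(b) table(factor(labels[batches == b],
                                                levels = unique(labels))))
  ord <- order(bsize, decreasing = TRUE)
  fold_counts <- matrix(0, k, length(unique(labels)))
  fold_of <- integer(length(ub))
  for (i in ord) {
    tot <- rowSums(fold_counts)
    # fold whose class balance benefits most: smallest total, tie-break by
    # count of this batch's majority class
    maj <- which.max(bclass[[i]])
    f <- order(tot, fold_counts[, maj])[1]
    fold_of[i] <- f
    fold_counts[f, ] <- fold_counts[f, ] + as.numeric(bclass[[i]])
  }
  if (any(apply(fold_counts, 1, function(r) any(r == 0))))
    warning("some folds miss a class; batch-grouped stratification is ",
            "best-effort for this corpus")
  lapply(seq_len(k), function(f) {
    test_b <- ub[fold_of == f]
    list(train = ids[!(batches %in% test_b)],
         test = ids[batches %in% test_b])
  })
}

#' Cross-validated evaluation
#'
#' For each fold, fine-tunes the given (typically pretrained) model on the
#' training side, predicts the test side, then pools predictions across folds
#' and computes accuracy, macro-F1 and AUC, plus per-fold and pooled
#' confusion matrices.
#'
#' @param corpus labelled list of [cyto_sample] objects.
#' @param model a [cytoformer] (pretrained or not; it is fine-tuned per
#'   fold).
#' @param splits fold list from [make_splits()], or a single-fold list for a
#'   fixed holdout.
#' @param config a [downstream_config()].
#' @param seed integer seed.
#' @return list with pooled `metrics`, `per_fold` confusion matrices, and the
#'   pooled prediction table (`sample_id`, `truth`, class probabilities).
#' @export
evaluate_model <- function(corpus, model, splits,
                           config = downstream_config(), seed = 1L) {
  ids <- vapply(corpus, function(s) s$sample_id, character(1))
  names(corpus) <- ids
  truth_all <- c(); prob_all <- NULL; id_all <- c(); per_fold <- list()
  for (f in seq_along(splits)) {
    sp <- splits[[f]]
    fit <- finetune(model, corpus[sp$train], config = config,
                    seed = derive_seed(seed, "fold", f))
    prob <- predict(fit, corpus[sp$test], type = "prob")
    truth <- vapply(corpus[sp$test], function(s) as.character(s$label),
                    character(1))
    mt <- classification_metrics(truth, prob, fit$classes)
    per_fold[[f]] <- mt$confusion
    truth_all <- c(truth_all, truth)
    prob_all <- rbind(prob_all, prob)
    id_all <- c(id_all, sp$test)
  }
  metrics <- classification_metrics(truth_all, prob_all)
  list(metrics = metrics, per_fold = per_fold,
       predictions = data.frame(sample_id = id_all, truth = truth_all,
                                prob_all, check.names = FALSE,
                                row.names = NULL))
}
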