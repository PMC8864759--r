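#' Three stratified 1:1 train/validation splits
#'
#' The evaluation protocol splits the data 1:1 into training and validation,
#' stratified by diagnostic label, and repeats the random split three times.
#' The default split unit is the case: all images of a case stay on one side
#' of the split, so no case leaks between training and validation. An
#' image-level split is available for protocol variants but leaks case
#' identity across the split and should be interpreted accordingly.
#'
#' @param table Feature table from [build_feature_table()].
#' @param unit `"case"` (default) or `"image"`.
#' @param seeds Integer vector, one seed per repeat (length sets the number
#'   of repeats; default 3).
#' @param positive_label Label of the positive class.
#' @return List of split plans; each has `repeat_index`, `seed`, `unit`,
#'   `train` and `validation` (vectors of case or image ids).
#' @export
make_splits <- function(table, unit = c("case", "image"),
                        seeds = c(101L, 202L, 303L),
                        positive_label = "adenoma") {
  unit <- match.arg(unit)
  id_col <- if (unit == "case") "case_id" else "image_id"
  units <- unique(table[, c(id_col, "label")])
  for (lb in unique(units$label))
    if (sum(units$label == lb) < 2)
      stop("need at least 2 ", unit, "s per class to split 1:1")
  lapply(seq_along(seeds), function(r) {
    with_seed(seeds[r], {
      train <- character(0)
      for (lb in sort(unique(units$label))) {
        ids <- units[[id_col]][units$label == lb]
        train <- c(train, sample(ids, floor(length(ids) / 2)))
      }
      list(repeat_index = r, seed = seeds[r], unit = unit,
           train = sort(train),
           validation = sort(setdiff(units[[id_col]], train)))
    })
  })
}

#' Model specification
#'
#' @param learner `"gbc"` (gradient boosting, via xgboost) or `"etc"`
#'   (extremely randomized trees, via ranger with `splitrule =
#'   "extratrees"`). Hyperparameters default to the backing
#'   implementations' defaults; override through `params`.
#' @param feature_subset Subset name for [schema_subset()] or a character
#'   vector of feature names.
#' @param params Named list of hyperparameter overrides.
#' @param seed Integer seed; fixed seed + single-threaded training makes the
#'   fit deterministic.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(learner = c("gbc", "etc"), feature_subset = "high_power",
                       params = list(), seed = 1L) {
  learner <- match.arg(learner)
  structure(list(learner = learner, feature_subset = feature_subset,
                 params = params, seed = as.integer(seed)),
            class = "model_spec")
}

subset_features <- function(feature_subset, schema = feature_schema()) {
  if (length(feature_subset) == 1 && !feature_subset %in% schema$name)
    schema_subset(feature_subset, schema)
  else feature_subset
}

# Median imputation: medians learned on the training rows only, applied to
# both sides; a feature with no observed training value falls back to 0.
impute_median <- function(train_x, val_x) {
  med <- vapply(train_x, function(v) {
    m <- median(v, na.rm = TRUE)
    if (is.na(m)) 0 else m
  }, numeric(1))
  fill <- function(df) {
    for (j in seq_along(df)) df[[j]][is.na(df[[j]])] <- med[j]
    df
  }
  list(train = fill(train_x), validation = fill(val_x))
}

fit_predict <- function(learner, train_x, train_y, val_x, params, seed) {
  if (learner == "gbc") {
    defaults <- list(nrounds = 100L, max_depth = 6L, eta = 0.3,
                     objective = "binary:logistic", nthread = 1L,
                     verbosity = 0L)
    p <- utils::modifyList(defaults, params)
    dtrain <- xgboost::xgb.DMatrix(as.matrix(train_x), label = as.numeric(train_y))
    fit <- with_seed(seed, xgboost::xgb.train(
      params = p[setdiff(names(p), "nrounds")], data = dtrain,
      nrounds = p$nrounds))
    list(scores = predict(fit, as.matrix(val_x)), fit = fit)
  } else {
    defaults <- list(num.trees = 500L, splitrule = "extratrees",
                     num.random.splits = 1L, replace = FALSE,
                     sample.fraction = 1, min.node.size = 1L)
    p <- utils::modifyList(defaults, params)
    df <- cbind(train_x, .y = factor(train_y, levels = c(FALSE, TRUE)))
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = df, probability = TRUE,
      num.trees = p$num.trees, splitrule = p$splitrule,
      num.random.splits = p$num.random.splits, replace = p$replace,
      sample.fraction = p$sample.fraction, min.node.size = p$min.node.size,
      seed = seed, num.threads = 1L)
    list(scores = predict(fit, val_x, num.threads = 1L)$predictions[, "TRUE"],
         fit = fit)
  }
}

#' Train on one split and score the validation side
#'
#' Fits the specified learner on the training rows of the plan and scores
#' the validation rows with class probabilities. Accuracy, precision and
#' recall use the 0.5 probability threshold; the ROC curve and AUC sweep all
#' thresholds. Follicular adenoma is the positive class.
#'
#' @param mspec A [model_spec()].
#' @param table Feature table.
#' @param plan One split plan from [make_splits()].
#' @param config A [dia_config()] (positive label, schema).
#' @return List: `metrics` (named vector: accuracy, precision, recall, auc),
#'   `confusion` (2x2 matrix), `roc` (data frame), `n_train`, `n_validation`.
#' @export
train_eval <- function(mspec, table, plan, config = dia_config()) {
  feats <- subset_features(mspec$feature_subset, config$schema)
  mag <- unique(config$schema$magnification[config$schema$name %in% feats])
  rows <- table[table$magnification %in% mag, , drop = FALSE]
  id_col <- if (plan$unit == "case") "case_id" else "image_id"
  tr <- rows[rows[[id_col]] %in% plan$train, , drop = FALSE]
  va <- rows[rows[[id_col]] %in% plan$validation, , drop = FALSE]
  y_tr <- tr$label == config$positive_label
  y_va <- va$label == config$positive_label
  if (length(unique(y_tr)) < 2) stop("degenerate single-class training split")
  imp <- impute_median(tr[, feats, drop = FALSE], va[, feats, drop = FALSE])
  pred <- fit_predict(mspec$learner, imp$train, y_tr, imp$validation,
                      mspec$params, mspec$seed)
  scores <- pred$scores
  yhat <- scores >= 0.5
  tp <- sum(yhat & y_va); fp <- sum(yhat & !y_va)
  fn <- sum(!yhat & y_va); tn <- sum(!yhat & !y_va)
  metrics <- c(accuracy = (tp + tn) / length(y_va),
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = tp / (tp + fn),
               auc = roc_auc(scores, y_va))
  list(metrics = metrics,
       confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                          dimnames = list(predicted = c("pos", "neg"),
                                          actual = c("pos", "neg"))),
       roc = roc_curve(scores, y_va),
       n_train = nrow(tr), n_validation = nrow(va))
}

#' ROC AUC by the rank (Mann-Whitney) convention
#'
#' The trapezoidal area under the full-threshold ROC curve equals the
#' Mann-Whitney probability that a random positive outscores a random
#' negative, with ties counted 1/2 - computed here from midranks.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Logical (or 0/1) true labels; both classes required.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full-threshold ROC curve
#'
#' @inheritParams roc_auc
#' @return Data frame with `threshold`, `fpr`, `tpr`, starting at (0, 0).
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  keep <- c(s[-1] != s[-length(s)], TRUE)  # one point per distinct score
  tpr <- cumsum(y)[keep] / sum(labels)
  fpr <- cumsum(!y)[keep] / sum(!labels)
  data.frame(threshold = c(Inf, s[keep]), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Evaluate a feature subset under the repeated-split protocol
#'
#' Runs both learners (gradient boosting and extremely randomized trees, or
#' any subset) across the three stratified 1:1 split repeats and summarises
#' the validation metrics.
#'
#' @param table Feature table.
#' @param feature_subset Subset name or feature-name vector.
#' @param learners Character vector of learners.
#' @param unit Split unit (`"case"` default).
#' @param seed Master seed: split seeds and learner seeds derive from it.
#' @param n_repeats Number of split repeats (default 3).
#' @param config A [dia_config()].
#' @param params Hyperparameter overrides passed to every [model_spec()].
#' @return List of class `eval_report`: `per_repeat` (data frame of metrics
#'   per learner x repeat), `summary` (mean/min/max per learner and pooled),
#'   `roc` (per repeat x learner curves), `confusions`.
#' @export
evaluate_subset <- function(table, feature_subset, learners = c("gbc", "etc"),
                            unit = "case", seed = 1L, n_repeats = 3L,
                            config = dia_config(), params = list()) {
  plans <- make_splits(table, unit,
                       seeds = vapply(seq_len(n_repeats), function(r)
                         derive_seed(seed, 7L, r), 1L),
                       positive_label = config$positive_label)
  per <- list(); rocs <- list(); confs <- list()
  for (lrn in learners) for (plan in plans) {
    ms <- model_spec(lrn, feature_subset, params,
                     seed = derive_seed(seed, 11L, plan$repeat_index,
                                        match(lrn, learners)))
    ev <- train_eval(ms, table, plan, config)
    per[[length(per) + 1L]] <- data.frame(
      learner = lrn, repeat_index = plan$repeat_index, t(ev$metrics),
      stringsAsFactors = FALSE)
    rocs[[length(rocs) + 1L]] <- cbind(ev$roc, learner = lrn,
                                       repeat_index = plan$repeat_index)
    confs[[paste(lrn, plan$repeat_index, sep = "_")]] <- ev$confusion
  }
  per <- do.call(rbind, per)
  structure(list(per_repeat = per, summary = summarize_metrics(per),
                 roc = do.call(rbind, rocs), confusions = confs,
                 feature_subset = feature_subset),
            class = "eval_report")
}

#' Summarise per-repeat metrics as mean (min-max)
#'
#' @param per_repeat Data frame with `learner` and metric columns.
#' @return Data frame: one row per learner plus a pooled row, with
#'   `<metric>_mean`, `<metric>_min`, `<metric>_max` columns.
#' @export
summarize_metrics <- function(per_repeat) {
  mets <- c("accuracy", "precision", "recall", "auc")
  one <- function(df, who) {
    out <- data.frame(learner = who, stringsAsFactors = FALSE)
    for (m in mets) {
      v <- df[[m]]
      out[[paste0(m, "_mean")]] <- mean(v, na.rm = TRUE)
      out[[paste0(m, "_min")]] <- min(v, na.rm = TRUE)
      out[[paste0(m, "_max")]] <- max(v, na.rm = TRUE)
    }
    out
  }
  rows <- lapply(split(per_repeat, per_repeat$learner),
                 function(d) one(d, d$learner[1]))
  rbind(do.call(rbind, rows), one(per_repeat, "pooled"))
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation of feature subset:",
      paste(x$feature_subset, collapse = ","), "\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-8s acc %.2f (%.2f-%.2f)  prec %.2f  rec %.2f  AUC %.2f (%.2f-%.2f)\n",
                s$learner[i], s$accuracy_mean[i], s$accuracy_min[i], s$accuracy_max[i],
                s$precision_mean[i], s$recall_mean[i],
                s$auc_mean[i], s$auc_min[i], s$auc_max[i]))
  invisible(x)
}

#' Feature importance with class means and t-tests
#'
#' Fits the extremely randomized trees learner on all rows (no split) and
#' reports normalised impurity importances, per-class feature means and
#' two-sided Student's t-test p-values comparing the positive and negative
#' class, one row per feature. No multiple-testing correction is applied;
#' the p-values are reported raw.
#'
#' @param table Feature table.
#' @param feature_subset Subset name or feature names (default all
#'   high-power features).
#' @param seed Learner seed.
#' @param config A [dia_config()].
#' @param welch Use the Welch (unequal-variance) t-test instead of the
#'   pooled-variance Student's test.
#' @return Data frame: `feature`, `gate`, `aggregation`, `importance`
#'   (sums to 1), `mean_pos`, `mean_neg`, `p_value`.
#' @export
feature_importance <- function(table, feature_subset = "high_power",
                               seed = 1L, config = dia_config(),
                               welch = FALSE) {
  feats <- subset_features(feature_subset, config$schema)
  mag <- unique(config$schema$magnification[config$schema$name %in% feats])
  rows <- table[table$magnification %in% mag, , drop = FALSE]
  y <- rows$label == config$positive_label
  x <- impute_median(rows[, feats, drop = FALSE],
                     rows[, feats, drop = FALSE])$train
  df <- cbind(x, .y = factor(y, levels = c(FALSE, TRUE)))
  fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                        probability = TRUE, num.trees = 500L,
                        splitrule = "extratrees", num.random.splits = 1L,
                        replace = FALSE, sample.fraction = 1,
                        importance = "impurity", seed = seed, num.threads = 1L)
  imp <- fit$variable.importance[feats]
  imp <- pmax(imp, 0); imp <- imp / sum(imp)
  sch <- config$schema[match(feats, config$schema$name), ]
  data.frame(feature = feats, gate = sch$gate, aggregation = sch$aggregation,
             importance = unname(imp),
             mean_pos = vapply(feats, function(f) mean(rows[[f]][y], na.rm = TRUE), 1),
             mean_neg = vapply(feats, function(f) mean(rows[[f]][!y], na.rm = TRUE), 1),
             p_value = vapply(feats, function(f)
               ttest_feature(rows[[f]][y], rows[[f]][!y], welch = welch), 1),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-sample Student's t-test p-value for one feature
#'
#' Classic pooled-variance two-sided Student's t-test of the positive versus
#' negative class values (Welch's correction optional). Degenerate inputs
#' with zero pooled variance return p = 1 when the group means agree and
#' p = 0 otherwise.
#'
#' @param values_pos,values_neg Numeric vectors (NA dropped; >= 2 values per
#'   group required).
#' @param welch Use Welch's unequal-variance test.
#' @return Two-sided p-value.
#' @export
ttest_feature <- function(values_pos, values_neg, welch = FALSE) {
  values_pos <- values_pos[!is.na(values_pos)]
  values_neg <- values_neg[!is.na(values_neg)]
  if (length(values_pos) < 2 || length(values_neg) < 2) return(NA_real_)
  if (sd(values_pos) == 0 && sd(values_neg) == 0)
    return(if (mean(values_pos) == mean(values_neg)) 1 else 0)
  t.test(values_pos, values_neg, var.equal = !welch)$p.value
}

#' Reconstruct a confusion matrix from printed recall and precision
#'
#' Given a rater's recall and precision over known class sizes, recovers the
#' integer confusion matrix: `TP = round(recall * n_pos)`, `FP` the integer
#' in \[0, n_neg\] whose implied precision is closest to the printed value,
#' and the remaining cells by complement - then reports the implied
#' accuracy. Useful for checking the internal consistency of published
#' reader-study metrics.
#'
#' @param recall,precision Printed metrics in (0, 1\].
#' @param n_pos,n_neg Class sizes.
#' @return List: `tp`, `fp`, `fn`, `tn`, `accuracy`.
#' @export
reconstruct_confusion <- function(recall, precision, n_pos, n_neg) {
  stopifnot(recall > 0, recall <= 1, precision > 0, precision <= 1,
            n_pos > 0, n_neg > 0)
  tp <- round(recall * n_pos)
  fp_cand <- 0:n_neg
  fp <- fp_cand[which.min(abs(tp / (tp + fp_cand) - precision))]
  list(tp = tp, fp = fp, fn = n_pos - tp, tn = n_neg - fp,
       accuracy = (tp + (n_neg - fp)) / (n_pos + n_neg))
}

#' Average per-image feature rows to one row per case
#'
#' Optional case-level representation: the feature vectors of a case's
#' fields (per magnification tier) are averaged, mirroring how a reader
#' integrates all fields of a case.
#'
#' @param table Feature table.
#' @return Collapsed table, one row per case x magnification; `image_id`
#'   becomes `"<case>_<mag>"`.
#' @export
collapse_cases <- function(table) {
  key <- interaction(table$case_id, table$magnification, drop = TRUE)
  feats <- setdiff(names(table), c("image_id", "case_id", "label", "magnification"))
  rows <- lapply(split(table, key), function(d) {
    cbind(data.frame(image_id = paste0(d$case_id[1], "_", d$magnification[1]),
                     case_id = d$case_id[1], label = d$label[1],
                     magnification = d$magnification[1],
                     stringsAsFactors = FALSE),
          as.data.frame(lapply(d[, feats, drop = FALSE],
                               function(v) mean(v, na.rm = TRUE))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
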