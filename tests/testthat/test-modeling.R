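# table with one informative feature and one noise feature, at case level
sep_table <- function(shift, seed = 1L) {
  toy_table(function(cls, n) {
    mu <- if (cls == "adenoma") shift else 0
    list(AreaSingleMean = rnorm(n, mu, 1), AreaSingleStdDv = rnorm(n, 0, 1))
  }, n_cases_per_class = 20, images_per_case = 2, seed = seed)
}

test_that("case-level splits are stratified 1:1 with no case leakage", {
  tab <- sep_table(0)
  plans <- make_splits(tab, "case", seeds = c(11L, 22L, 33L))
  expect_length(plans, 3L)
  for (p in plans) {
    expect_length(p$train, 20L)
    expect_length(p$validation, 20L)
    expect_length(intersect(p$train, p$validation), 0L)
    lab <- function(ids) substr(ids, 1, 3)
    expect_equal(sum(lab(p$train) == "ade"), 10L)
    expect_equal(sum(lab(p$validation) == "ade"), 10L)
    # no image of a training case appears on the validation side
    expect_length(intersect(tab$image_id[tab$case_id %in% p$train],
                            tab$image_id[tab$case_id %in% p$validation]), 0L)
  }
  # identical seeds give identical plans
  expect_identical(plans, make_splits(tab, "case", seeds = c(11L, 22L, 33L)))
  tiny <- tab[tab$case_id %in% c("adenoma_001", "benign_001", "benign_002"), ]
  expect_error(make_splits(tiny), "at least 2")
})

test_that("AUC equals the brute-force Mann-Whitney statistic, with tie handling", {
  expect_equal(roc_auc(c(rep(0.9, 5), rep(0.1, 5)),
                       c(rep(TRUE, 5), rep(FALSE, 5))), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  for (s in 1:25) {
    set.seed(s)
    n <- sample(6:50, 1)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
  }
  expect_error(roc_auc(c(0.1, 0.2), c(TRUE, TRUE)), "both classes")
})

test_that("the ROC curve sweeps from (0,0) to (1,1) and integrates to the AUC", {
  set.seed(3)
  scores <- runif(30); labels <- rep(c(TRUE, FALSE), 15)
  rc <- roc_curve(scores, labels)
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1); expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
  trap <- sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
  expect_equal(trap, roc_auc(scores, labels), tolerance = 1e-12)
})

test_that("a perfectly separating feature is classified perfectly by both learners", {
  # discrete separator: tree learners place the cut between the two values
  tab <- toy_table(function(cls, n) {
    list(AreaSingleMean = rep(if (cls == "adenoma") 1 else 0, n),
         AreaSingleStdDv = rnorm(n))
  }, n_cases_per_class = 20, images_per_case = 2, seed = 1)
  plan <- make_splits(tab, "case", seeds = 5L)[[1]]
  for (lrn in c("gbc", "etc")) {
    ev <- train_eval(model_spec(lrn, "size", seed = 2), tab, plan)
    expect_equal(unname(ev$metrics["accuracy"]), 1)
    expect_equal(unname(ev$metrics["auc"]), 1)
  }
})

test_that("large class separation yields validation AUC above 0.9", {
  tab <- sep_table(3)
  rep <- evaluate_subset(tab, "size", learners = "gbc", seed = 4)
  expect_gt(rep$summary$auc_mean[rep$summary$learner == "pooled"], 0.9)
})

test_that("permuted labels give chance-level AUC", {
  set.seed(42)
  tab <- sep_table(3)
  aucs <- replicate(20, {
    perm <- tab
    case_lab <- unique(tab[, c("case_id", "label")])
    case_lab$label <- sample(case_lab$label)
    perm$label <- case_lab$label[match(perm$case_id, case_lab$case_id)]
    perm$case_id <- paste0(perm$label, "_", perm$case_id)  # keep ids labelled
    rep <- evaluate_subset(perm, "size", learners = "gbc",
                           seed = sample.int(1e6, 1))
    per <- rep$per_repeat
    expect_true(all(abs(per$auc - 0.5) <= 0.25))
    mean(per$auc)
  })
  expect_gte(mean(aucs), 0.45)
  expect_lte(mean(aucs), 0.55)
})

test_that("training is deterministic under fixed seeds", {
  tab <- sep_table(1)
  r1 <- evaluate_subset(tab, "size", seed = 31)
  r2 <- evaluate_subset(tab, "size", seed = 31)
  expect_identical(r1$per_repeat, r2$per_repeat)
  expect_identical(r1$summary, r2$summary)
})

test_that("degenerate single-class training splits are refused", {
  tab <- sep_table(0)
  plan <- make_splits(tab, "case", seeds = 1L)[[1]]
  plan$train <- plan$train[substr(plan$train, 1, 3) == "ade"]
  expect_error(train_eval(model_spec("gbc", "size"), tab, plan), "single-class")
})

test_that("the Student's t-test matches its closed form", {
  expect_equal(ttest_feature(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(ttest_feature(c(5, 5, 5), c(5, 5, 5)), 1)
  expect_equal(ttest_feature(c(5, 5, 5), c(4, 4, 4)), 0)
  set.seed(10)
  expect_lt(ttest_feature(rnorm(50, 5, 1), rnorm(50, 0, 1)), 1e-10)
  # hand-computable 3 + 3 example against the closed form
  x <- c(1, 2, 3); y <- c(2, 4, 6)
  expect_equal(ttest_feature(x, y), oracle_student_p(x, y), tolerance = 1e-12)
  expect_equal(ttest_feature(x, y), 0.1961, tolerance = 1e-3)
  expect_true(is.na(ttest_feature(1, c(1, 2))))
})

test_that("feature importance ranks a perfect separator first and sums to one", {
  tab <- toy_table(function(cls, n) {
    list(AreaSingleMean = rnorm(n, if (cls == "adenoma") 8 else 0, 0.5),
         AreaSingleStdDv = rnorm(n),
         CircSingleMean = rep(0.5, n))   # constant: zero importance
  }, n_cases_per_class = 15, seed = 2)
  imp <- feature_importance(tab, c("AreaSingleMean", "AreaSingleStdDv",
                                   "CircSingleMean"), seed = 3)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_equal(imp$feature[which.max(imp$importance)], "AreaSingleMean")
  expect_lt(imp$importance[imp$feature == "CircSingleMean"], 0.01)
  expect_lt(imp$p_value[imp$feature == "AreaSingleMean"], 1e-6)
  expect_gt(imp$mean_pos[imp$feature == "AreaSingleMean"],
            imp$mean_neg[imp$feature == "AreaSingleMean"])
})

test_that("printed reader metrics reconstruct to a consistent confusion matrix", {
  r <- reconstruct_confusion(1, 1, 10, 10)
  expect_equal(r[c("tp", "fp", "accuracy")], list(tp = 10, fp = 0L, accuracy = 1))
  r2 <- reconstruct_confusion(0.5, 0.5, 10, 10)
  expect_equal(r2$tp, 5); expect_equal(r2$fp, 5L); expect_equal(r2$accuracy, 0.5)
})

test_that("metric summaries report mean and min-max per learner and pooled", {
  per <- data.frame(learner = rep(c("gbc", "etc"), each = 3),
                    repeat_index = rep(1:3, 2),
                    accuracy = c(0.7, 0.8, 0.9, 0.6, 0.6, 0.6),
                    precision = 0.5, recall = 0.5,
                    auc = c(0.7, 0.75, 0.8, 0.65, 0.7, 0.75))
  s <- summarize_metrics(per)
  expect_equal(s$accuracy_mean[s$learner == "gbc"], 0.8)
  expect_equal(s$accuracy_min[s$learner == "gbc"], 0.7)
  expect_equal(s$accuracy_max[s$learner == "gbc"], 0.9)
  expect_equal(s$auc_mean[s$learner == "pooled"], mean(per$auc))
})

test_that("case collapsing averages a case's fields per magnification", {
  tab <- sep_table(0)
  cc <- collapse_cases(tab)
  expect_equal(nrow(cc), 40L)
  one <- tab[tab$case_id == "adenoma_001", ]
  expect_equal(cc$AreaSingleMean[cc$case_id == "adenoma_001"],
               mean(one$AreaSingleMean))
})
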