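test_that("train/test split is a reproducible 3:1 partition", {
  sim <- small_sim(seed = 71, n = 8)
  sp <- split_train_test(sim$enc, split_spec(99))
  expect_equal(nrow(sp$train$encounters), 6)
  expect_equal(nrow(sp$test$encounters), 2)
  # same seed -> identical partition; partition laws hold
  sp2 <- split_train_test(sim$enc, split_spec(99))
  expect_identical(sort(sp$train$encounters$encounter_id),
                   sort(sp2$train$encounters$encounter_id))
  ids <- sim$enc$encounters$encounter_id
  expect_setequal(c(sp$train$encounters$encounter_id,
                    sp$test$encounters$encounter_id), ids)
  expect_length(intersect(sp$train$encounters$encounter_id,
                          sp$test$encounters$encounter_id), 0)
  expect_error(split_train_test(subset_encounters(sim$enc, ids[1:2]),
                                split_spec(1)), "at least 4")
  # diagnoses follow their encounters
  expect_setequal(unique(sp$train$diagnoses$encounter_id),
                  intersect(ids[ids %in% sp$train$encounters$encounter_id],
                            unique(sim$enc$diagnoses$encounter_id)))
})

test_that("stratified splitting keeps the class ratio exactly", {
  sim <- small_sim(seed = 72, n = 400)
  sp <- split_train_test(sim$enc, split_spec(7, stratified = TRUE))
  y <- binarize_outcome(sim$enc$encounters$discharge_soi)
  for (cls in 0:1) {
    n_cls <- sum(y == cls)
    in_train <- sum(binarize_outcome(sp$train$encounters$discharge_soi) == cls)
    expect_equal(in_train, round(0.75 * n_cls))
  }
})

test_that("ROC area equals Mann-Whitney concordance, including ties", {
  set.seed(81)
  for (i in 1:60) {
    n <- sample(10:50, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    labels <- rbinom(n, 1, 0.5)
    if (sum(labels) %in% c(0, n)) next
    roc <- roc_curve(scores, labels)
    expect_equal(roc$auc, mw_auc(scores, labels), tolerance = 1e-12)
    # reversing scores flips the area
    expect_equal(roc_curve(-scores, labels)$auc, 1 - roc$auc,
                 tolerance = 1e-12)
  }
})

test_that("ROC endpoints and monotonicity hold; separation gives AUC 1", {
  roc <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(roc$auc, 1.0)
  expect_equal(roc$points$fpr[1], 0)
  expect_equal(roc$points$tpr[1], 0)
  n <- nrow(roc$points)
  expect_equal(roc$points$fpr[n], 1)
  expect_equal(roc$points$tpr[n], 1)
  expect_true(all(diff(roc$points$fpr) >= 0))
  expect_true(all(diff(roc$points$tpr) >= 0))
  expect_error(roc_curve(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("ROC AUC agrees with pROC on a moderate instance", {
  skip_if_not_installed("pROC")
  set.seed(82)
  scores <- runif(200)
  labels <- rbinom(200, 1, plogis(3 * scores - 1.5))
  ours <- roc_curve(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("PR area matches a brute-force step sum; degenerate cases", {
  set.seed(83)
  for (i in 1:40) {
    n <- sample(10:50, 1)
    scores <- sample(seq(0, 1, by = 0.2), n, replace = TRUE)
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0) next
    pr <- pr_curve(scores, labels)
    expect_equal(pr$auc, ap_oracle(scores, labels), tolerance = 1e-12)
  }
  expect_equal(pr_curve(c(0.9, 0.8, 0.2), c(1, 1, 0))$auc, 1.0)
  # all-positive labels: precision is 1 at every threshold
  pr1 <- pr_curve(c(0.2, 0.5, 0.9), c(1, 1, 1))
  expect_true(all(pr1$points$precision == 1))
  expect_equal(pr1$auc, 1.0)
  expect_error(pr_curve(c(0.1, 0.9), c(0, 0)), "positive")
})

test_that("optimal cutoff equals the exhaustive-scan argmin", {
  set.seed(84)
  for (i in 1:60) {
    n <- sample(10:100, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
    labels <- rbinom(n, 1, 0.5)
    if (sum(labels) %in% c(0, n)) next
    expect_equal(optimal_cutoff(roc_curve(scores, labels)),
                 scan_cutoff(scores, labels))
  }
  # perfect classifier: the cutoff separates the classes at distance 0
  roc <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  cut <- optimal_cutoff(roc)
  expect_equal(cut, 0.8)
  m <- classification_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), cut)
  expect_equal(m$fpr + m$fnr, 0)
  # a single distinct score -> that score is returned
  expect_equal(optimal_cutoff(roc_curve(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))),
               0.5)
  # ties break toward the larger threshold
  tie <- roc_curve(c(0.9, 0.6, 0.4, 0.1), c(1, 0, 1, 0))
  expect_equal(optimal_cutoff(tie), 0.9)
})

test_that("classification metrics match direct confusion counting", {
  m <- classification_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(m$accuracy, 1.0)
  expect_equal(m$fpr, 0)
  expect_equal(m$fnr, 0)
  # cutoff above every score: everything predicted low
  m2 <- classification_metrics(c(0.3, 0.4), c(1, 0), 0.9)
  expect_equal(m2$fnr, 1)
  expect_equal(m2$fpr, 0)
  set.seed(85)
  for (i in 1:25) {
    scores <- runif(30)
    labels <- rbinom(30, 1, 0.5)
    cut <- runif(1)
    m <- classification_metrics(scores, labels, cut)
    pred <- as.integer(scores >= cut)
    fp <- sum(pred & !labels); tn <- sum(!pred & !labels)
    fn <- sum(!pred & labels); tp <- sum(pred & labels)
    expect_equal(m$accuracy, mean(pred == labels))
    if (fp + tn > 0) expect_equal(m$fpr, fp / (fp + tn))
    if (fn + tp > 0) expect_equal(m$fnr, fn / (fn + tp))
  }
})

test_that("raising the cutoff never raises FPR nor lowers FNR", {
  set.seed(86)
  scores <- runif(100)
  labels <- rbinom(100, 1, 0.5)
  cuts <- sort(runif(12))
  ms <- lapply(cuts, function(ct) classification_metrics(scores, labels, ct))
  fpr <- vapply(ms, `[[`, numeric(1), "fpr")
  fnr <- vapply(ms, `[[`, numeric(1), "fnr")
  expect_true(all(diff(fpr) <= 0))
  expect_true(all(diff(fnr) >= 0))
})

test_that("descriptive comparison reproduces hand-worked statistics", {
  sim <- small_sim(seed = 87, n = 600)
  sp <- split_train_test(sim$enc, split_spec(3))
  tab <- descriptive_comparison(sp$train, sp$test)
  # proportions per categorical variable sum to 1
  for (v in c("sex", "race", "admit_soi", "discharge_soi")) {
    expect_equal(sum(tab$train_prop[tab$variable == v]), 1,
                 tolerance = 1e-12)
    expect_equal(sum(tab$test_prop[tab$variable == v]), 1,
                 tolerance = 1e-12)
  }
  # identical sets -> identical proportions and p ~ 1
  same <- descriptive_comparison(sp$train, sp$train)
  expect_equal(same$train_prop, same$test_prop)
  expect_true(all(same$p_value[same$variable != "age"] > 0.999))

  # hand-worked 2x2 chi-square with Yates continuity correction
  a <- sp$train; b <- sp$test
  a$encounters$sex <- rep(c("Female", "Male"), c(300, 150))
  b$encounters$sex <- rep(c("Female", "Male"), c(70, 80))
  tab2 <- descriptive_comparison(a, b)
  o <- matrix(c(300, 150, 70, 80), 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  x2 <- sum((abs(o - e) - 0.5)^2 / e)
  p_hand <- stats::pchisq(x2, df = 1, lower.tail = FALSE)
  expect_equal(unique(tab2$p_value[tab2$variable == "sex"]), p_hand,
               tolerance = 1e-12)
})

test_that("variant evaluation derives the cutoff from training data only", {
  sim <- small_sim(seed = 88, n = 1200)
  sp <- split_train_test(sim$enc, split_spec(11))
  rep_bs <- evaluate_variant(sp$train, sp$test, sim$maps, "body_system",
                             "discharge")
  expect_s3_class(rep_bs, "eval_report")
  expect_equal(rep_bs$n_variables, 18)
  # the accuracy identity against the confusion counts
  f_te <- build_features(sp$test, sim$maps, "discharge")
  y_te <- binarize_outcome(sp$test$encounters$discharge_soi)
  p_te <- predict_probability(rep_bs$model, f_te)
  m <- classification_metrics(p_te, y_te, rep_bs$optimal_cutoff)
  expect_equal(rep_bs$accuracy,
               1 - (m$fp + m$fn) / length(y_te))
  # train == test -> test metrics equal training metrics at the cutoff
  rep_same <- evaluate_variant(sp$train, sp$train, sim$maps, "body_system",
                               "discharge")
  expect_equal(rep_same$accuracy, rep_same$train_accuracy)
  # evaluation is invariant to test-set row order
  shuf <- sp$test
  o <- sample(nrow(shuf$encounters))
  shuf$encounters <- shuf$encounters[o, ]
  rep_shuf <- evaluate_variant(sp$train, shuf, sim$maps, "body_system",
                               "discharge")
  expect_equal(rep_shuf$accuracy, rep_bs$accuracy)
  expect_equal(rep_shuf$fpr, rep_bs$fpr)
})

test_that("a body-system-driven cohort favours body-system models", {
  sim <- small_sim(seed = 89, n = 3000)
  sp <- split_train_test(sim$enc, split_spec(17))
  acc <- vapply(c("body_system", "full", "comorbidity"), function(v) {
    evaluate_variant(sp$train, sp$test, sim$maps, v, "discharge")$accuracy
  }, numeric(1))
  expect_gt(acc["body_system"], acc["comorbidity"])
  expect_gt(acc["full"], acc["comorbidity"])
})
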