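test_that("AUC/AP/MCC/BA match brute-force oracles on random instances", {
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(4:50, 1)
    prob <- round(runif(n), sample(c(1, 2, 6), 1)) # induce ties sometimes
    label <- rbinom(n, 1, 0.5)
    if (length(unique(label)) < 2) label[1:2] <- c(0L, 1L)
    expect_equal(roc_auc(prob, label), oracle_auc(prob, label),
                 tolerance = 1e-9)
    expect_equal(average_precision(prob, label), oracle_ap(prob, label),
                 tolerance = 1e-9)
    cm <- confusion_counts(prob, label)
    expect_equal(mcc_from_confusion(cm), oracle_mcc(prob, label),
                 tolerance = 1e-9)
    expect_equal(balanced_accuracy_from_confusion(cm),
                 oracle_ba(prob, label), tolerance = 1e-9)
    expect_equal(sum(cm), n)
  }
})

test_that("published confusion example evaluates exactly", {
  # TP=2 FP=1 FN=1 TN=2
  prob <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.2)
  label <- c(1, 1, 0, 1, 0, 0)
  e <- evaluate_predictions(prob, label, threshold = 0.5)
  expect_equal(unname(e$confusion), c(2L, 1L, 1L, 2L))
  expect_equal(e$mcc, 1 / 3)
  expect_equal(e$balanced_accuracy, 2 / 3)
})

test_that("degenerate probability patterns behave as defined", {
  expect_equal(evaluate_predictions(c(1, 1, 0, 0), c(1, 1, 0, 0))$auc, 1)
  expect_equal(evaluate_predictions(c(1, 1, 0, 0), c(1, 1, 0, 0))$ap, 1)
  expect_equal(evaluate_predictions(c(1, 1, 0, 0), c(1, 1, 0, 0))$mcc, 1)
  # constant 0.5 on balanced labels: predicted all-positive at >= 0.5
  e <- evaluate_predictions(rep(0.5, 10), rep(c(0, 1), 5))
  expect_equal(e$balanced_accuracy, 0.5)
  # single-class labels: explicit undefined marker, not a number
  expect_true(is.na(roc_auc(runif(5), rep(1, 5))))
  expect_true(is.na(average_precision(runif(5), rep(0, 5))))
})

test_that("AUC is invariant under strictly monotone probability transforms", {
  set.seed(7)
  for (i in 1:20) {
    prob <- runif(30); label <- rbinom(30, 1, 0.4)
    if (length(unique(label)) < 2) next
    a0 <- roc_auc(prob, label)
    expect_equal(roc_auc(plogis(5 * prob - 2), label), a0)
    expect_equal(roc_auc(prob^3, label), a0)
  }
})

test_that("Brier score has its closed-form degenerate values", {
  y <- rbinom(40, 1, 0.5)
  expect_equal(brier_score(as.numeric(y), y), 0)
  expect_equal(brier_score(rep(0.5, 40), y), 0.25)
})

test_that("calibration bins conserve counts and collapse correctly", {
  set.seed(5)
  prob <- runif(200); y <- rbinom(200, 1, prob)
  cal <- calibrate(prob, y)
  expect_equal(sum(cal$curve$n), 200L)
  expect_true(all(cal$curve$mean_predicted >= cal$curve$lo &
                  cal$curve$mean_predicted <= cal$curve$hi))
  # all probabilities in one bin -> one curve point
  cal1 <- calibrate(rep(0.42, 17), rbinom(17, 1, 0.5))
  expect_equal(nrow(cal1$curve), 1L)
  expect_equal(cal1$curve$n, 17L)
  # perfect 0/1 probabilities matching labels -> Brier 0
  expect_equal(calibrate(c(0, 1, 1, 0), c(0, 1, 1, 0))$brier, 0)
})

test_that("threshold selection matches an exhaustive sweep on tiny inputs", {
  set.seed(11)
  for (rep in 1:40) {
    n <- sample(3:8, 1)
    prob <- round(runif(n), 2)
    label <- rbinom(n, 1, 0.5)
    if (length(unique(label)) < 2) label[1:2] <- c(0L, 1L)
    sel <- select_threshold(prob, label, "mcc")
    u <- sort(unique(prob))
    cand <- unique(c(0, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, 1))
    brute <- max(sapply(cand, function(t) oracle_mcc(prob, label, t)))
    expect_equal(sel$oof_value, brute, tolerance = 1e-12)
    # every threshold between distinct probabilities is dominated
    dense <- seq(0, 1, by = 0.005)
    expect_gte(sel$oof_value + 1e-12,
               max(sapply(dense, function(t) oracle_mcc(prob, label, t))))
  }
})

test_that("threshold selection separates perfectly separable OOF sets", {
  prob <- c(0.9, 0.8, 0.75, 0.2, 0.1)
  label <- c(1, 1, 1, 0, 0)
  sel <- select_threshold(prob, label, "mcc")
  expect_equal(sel$oof_value, 1)
  # criterion switch keeps the same candidate machinery
  sel_ba <- select_threshold(prob, label, "balanced_accuracy")
  expect_equal(sel_ba$oof_value, 1)
  expect_error(select_threshold(prob, rep(1, 5)), "both classes")
})

test_that("frozen threshold transfers to test metrics", {
  oofp <- c(0.9, 0.7, 0.6, 0.3, 0.2, 0.1)
  oofy <- c(1, 1, 1, 0, 0, 0)
  sel <- select_threshold(oofp, oofy, "mcc",
                          test_prob = c(0.8, 0.4), test_label = c(1, 0))
  expect_equal(sel$test_metrics$mcc, 1)
  expect_equal(sel$test_metrics$precision, 1)
  expect_equal(sel$test_metrics$recall, 1)
  expect_equal(sel$test_metrics$f1, 1)
  expect_equal(sel$test_metrics$specificity, 1)
})

test_that("package metrics agree with an independent ROC library", {
  set.seed(13)
  prob <- runif(80); label <- rbinom(80, 1, 0.4)
  ref <- as.numeric(pROC::auc(pROC::roc(label, prob, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(prob, label), ref, tolerance = 1e-9)
})
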