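# Seeded tuning/fitting harness over fingerprint classifiers. Three model
# families are provided (random forest via ranger, penalized logistic
# regression via glmnet, gradient boosting via xgboost); any list with the
# same sample/fit/predict contract plugs in. All stochastic steps (parameter
# sampling, CV fold shuffling, learner seeds) derive from the split seed.

.family_random_forest <- list(
  name = "random_forest",
  sample = function() list(
    num_trees = sample(c(200L, 300L, 500L, 800L), 1L),
    mtry_frac = sample(c(0.02, 0.05, 0.1, 0.2), 1L),
    min_node_size = sample(c(1L, 3L, 5L, 10L), 1L),
    sample_fraction = sample(c(0.632, 0.8, 1.0), 1L)
  ),
  default = list(num_trees = 300L, mtry_frac = 0.05, min_node_size = 5L,
                 sample_fraction = 1.0),
  fit = function(x, y, params, seed) {
    ranger::ranger(
      x = x, y = factor(y, levels = c(0L, 1L)), probability = TRUE,
      num.trees = params$num_trees,
      mtry = max(1L, floor(params$mtry_frac * ncol(x))),
      min.node.size = params$min_node_size,
      sample.fraction = params$sample_fraction,
      seed = seed, num.threads = 1L, verbose = FALSE
    )
  },
  predict = function(fit, x) {
    unname(stats::predict(fit, x, num.threads = 1L,
                          verbose = FALSE)$predictions[, "1"])
  }
)

.family_logistic_regression <- list(
  name = "logistic_regression",
  sample = function() list(
    alpha = sample(c(0, 0.5, 1), 1L),
    lambda = 10^stats::runif(1, -4, 0)
  ),
  default = list(alpha = 0, lambda = 1e-3),
  fit = function(x, y, params, seed) {
    glmnet::glmnet(x, factor(y, levels = c(0L, 1L)), family = "binomial",
                   alpha = params$alpha, lambda = params$lambda,
                   standardize = TRUE)
  },
  predict = function(fit, x) {
    as.numeric(stats::predict(fit, x, type = "response")[, 1])
  }
)

.family_gradient_boosting <- list(
  name = "gradient_boosting",
  sample = function() list(
    nrounds = sample(c(100L, 200L, 400L), 1L),
    eta = sample(c(0.03, 0.1, 0.3), 1L),
    max_depth = sample(c(3L, 4L, 6L, 8L), 1L),
    subsample = sample(c(0.7, 0.9, 1.0), 1L),
    colsample_bytree = sample(c(0.3, 0.6, 1.0), 1L)
  ),
  default = list(nrounds = 200L, eta = 0.1, max_depth = 6L, subsample = 1.0,
                 colsample_bytree = 0.6),
  fit = function(x, y, params, seed) {
    xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = params$eta,
                    max_depth = params$max_depth,
                    subsample = params$subsample,
                    colsample_bytree = params$colsample_bytree,
                    nthread = 1L, seed = seed),
      data = xgboost::xgb.DMatrix(x, label = as.integer(y), nthread = 1L),
      nrounds = params$nrounds, verbose = 0
    )
  },
  predict = function(fit, x) {
    as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(x, nthread = 1L)))
  }
)

#' Registered model families
#' @return named list of family definitions.
#' @export
model_families <- function() {
  list(random_forest = .family_random_forest,
       logistic_regression = .family_logistic_regression,
       gradient_boosting = .family_gradient_boosting)
}

#' Model/tuning configuration
#'
#' @param family one of `names(model_families())`.
#' @param n_iter randomized-search iterations (25 sampled configurations).
#' @param cv_folds stratified cross-validation folds.
#' @param seed integer seed (normally the split seed).
#' @return list of class `ns_model_config`.
#' @export
model_config <- function(family = "random_forest", n_iter = 25L,
                         cv_folds = 5L, seed = 1L) {
  if (!family %in% names(model_families())) stop("unknown family: ", family)
  stopifnot(n_iter >= 1L, cv_folds >= 2L)
  cfg <- list(family = family, n_iter = as.integer(n_iter),
              cv_folds = as.integer(cv_folds), seed = as.integer(seed))
  class(cfg) <- "ns_model_config"
  cfg
}

# stratified fold ids (1..k), seeded
stratified_folds <- function(y, k, seed) {
  y <- as.integer(y)
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Randomized search with stratified CV, then refit
#'
#' Samples `n_iter` configurations from the family's search space, scores
#' each by mean out-of-fold ROC-AUC under seeded stratified `cv_folds`-fold
#' CV on the supplied (train+val) rows, and refits the best configuration on
#' all rows. Test rows must never be passed in.
#'
#' @param x feature matrix (train+val rows only).
#' @param y 0/1 labels; both classes must be present.
#' @param config a [model_config()].
#' @return list of class `ns_model`: `family`, `params`, `fit`, `cv_record`
#'   (data.frame of sampled configurations and CV AUC), `seed`.
#' @export
tune_and_fit <- function(x, y, config = model_config()) {
  stopifnot(inherits(config, "ns_model_config"))
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("single-class input")
  fam <- model_families()[[config$family]]
  fold <- stratified_folds(y, config$cv_folds, config$seed)
  draws <- with_seed(config$seed + 1L,
                     lapply(seq_len(config$n_iter), function(i) fam$sample()))
  cv_auc <- numeric(config$n_iter)
  for (i in seq_len(config$n_iter)) {
    aucs <- vapply(seq_len(config$cv_folds), function(f) {
      tr <- fold != f
      fit <- fam$fit(x[tr, , drop = FALSE], y[tr], draws[[i]], config$seed)
      roc_auc(fam$predict(fit, x[!tr, , drop = FALSE]), y[!tr])
    }, numeric(1))
    cv_auc[i] <- mean(aucs)
  }
  best <- which.max(cv_auc)
  cv_record <- data.frame(iter = seq_len(config$n_iter), cv_auc = cv_auc)
  cv_record$params <- I(draws)
  fit <- fam$fit(x, y, draws[[best]], config$seed)
  out <- list(family = config$family, params = draws[[best]], fit = fit,
              cv_record = cv_record, best_iter = best,
              cv_auc = cv_auc[best], seed = config$seed,
              config = config)
  class(out) <- "ns_model"
  out
}

#' Fit a family with fixed (default or given) hyperparameters
#'
#' Bypasses the randomized search; used for the fixed-budget evaluation runs.
#' @inheritParams tune_and_fit
#' @param family family name.
#' @param params hyperparameter list (family defaults when NULL).
#' @param seed integer seed.
#' @return an `ns_model`.
#' @export
fit_model <- function(x, y, family = "random_forest", params = NULL,
                      seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("single-class input")
  fam <- model_families()[[family]]
  if (is.null(fam)) stop("unknown family: ", family)
  params <- params %||% fam$default
  out <- list(family = family, params = params,
              fit = fam$fit(x, y, params, seed), cv_record = NULL,
              seed = as.integer(seed),
              config = model_config(family, n_iter = 1L, seed = seed))
  class(out) <- "ns_model"
  out
}

#' Predict positive-class probabilities from an `ns_model`
#' @param model an `ns_model`.
#' @param x feature matrix.
#' @return numeric probabilities in \[0,1\].
#' @export
predict_prob <- function(model, x) {
  stopifnot(inherits(model, "ns_model"))
  model_families()[[model$family]]$predict(model$fit, x)
}

#' Out-of-fold probabilities
#'
#' Every row receives exactly one probability, produced by a fold model that
#' excluded it; folds are the seeded stratified partition used for tuning.
#'
#' @inheritParams tune_and_fit
#' @param params hyperparameters to use for every fold model.
#' @param family family name.
#' @param cv_folds,seed fold count and seed.
#' @return numeric vector aligned with the rows of `x`.
#' @export
oof_predict <- function(x, y, family = "random_forest", params = NULL,
                        cv_folds = 5L, seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("single-class input")
  fam <- model_families()[[family]]
  params <- params %||% fam$default
  fold <- stratified_folds(y, cv_folds, seed)
  out <- rep(NA_real_, length(y))
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    fit <- fam$fit(x[tr, , drop = FALSE], y[tr], params, seed)
    out[!tr] <- fam$predict(fit, x[!tr, , drop = FALSE])
  }
  out
}

#' Aggregate per-seed evaluations across seeds
#'
#' @param evals data.frame with columns `model`, `seed` and numeric metric
#'   columns (e.g. `test_auc`, `test_ap`, `oof_auc`, `oof_ap`, `mcc`,
#'   `balanced_accuracy`).
#' @return data.frame, one row per model, with `<metric>_mean` and
#'   `<metric>_sd` (sample SD; 0 with `single_seed = TRUE` flag when only one
#'   seed), ranked by mean test AUC then mean test AP.
#' @export
aggregate_seeds <- function(evals) {
  stopifnot(all(c("model", "seed") %in% names(evals)))
  metrics <- setdiff(names(evals), c("model", "seed"))
  metrics <- metrics[vapply(evals[metrics], is.numeric, logical(1))]
  models <- unique(evals$model)
  rows <- lapply(models, function(m) {
    e <- evals[evals$model == m, , drop = FALSE]
    r <- data.frame(model = m, n_seeds = nrow(e),
                    single_seed = nrow(e) == 1L)
    for (mt in metrics) {
      v <- e[[mt]]
      r[[paste0(mt, "_mean")]] <- mean(v)
      r[[paste0(mt, "_sd")]] <- if (length(v) > 1L) stats::sd(v) else 0
    }
    r
  })
  out <- do.call(rbind, rows)
  if ("test_auc_mean" %in% names(out)) {
    ord <- order(-out$test_auc_mean,
                 if ("test_ap_mean" %in% names(out)) -out$test_ap_mean
                 else seq_len(nrow(out)))
    out <- out[ord, , drop = FALSE]
    out$rank <- seq_len(nrow(out))
  }
  rownames(out) <- NULL
  out
}
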