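# Gradient-boosted stacking classifier on concatenated CNN features.
#
# Trees are grown leaf-wise (xgboost's lossguide policy with a leaf
# budget), the growth strategy that converges fastest on wide feature
# matrices; hyperparameters are tuned by seeded random search scored by
# validation AUPRC, the metric of interest on imbalanced window labels.

stacker_search_space <- function() {
  list(
    num_leaves = c(7L, 15L, 31L, 63L),
    learning_rate = c(0.03, 0.05, 0.1, 0.2),
    min_child_samples = c(5L, 10L, 20L, 40L),
    feature_fraction = c(0.6, 0.8, 1.0),
    n_estimators = c(50L, 100L, 200L)
  )
}

#' Fit the gradient-boosted stacking classifier
#'
#' Random search over `search_budget` configurations drawn from a fixed
#' space (num_leaves, learning_rate, min_child_samples,
#' feature_fraction, n_estimators); each candidate is fitted on the
#' training features and scored by AUPRC on the validation features, and
#' the best is refitted and returned.
#'
#' @param features,labels Training feature matrix (windows x features)
#'   and 0/1 labels (balanced, per the training protocol).
#' @param val_features,val_labels Validation split used for model
#'   selection; defaults to a seeded 80/20 row split of the training
#'   data when omitted.
#' @param search_budget Number of random configurations (>= 1).
#' @param seed Seed for the search and the tree fitting.
#' @return A `stacker_model` with the chosen hyperparameters.
#' @export
fit_stacker <- function(features, labels, val_features = NULL,
                        val_labels = NULL, search_budget = 8L, seed = 1L) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop_validation("stacker needs both classes in the training labels")
  }
  if (any(!is.finite(features))) stop_validation("features must be finite")
  assert_that(is_count(search_budget) && search_budget >= 1,
              "search_budget must be >= 1")
  if (is.null(val_features)) {
    idx <- with_seed(derive_seed(seed, 911L),
                     sample.int(nrow(features), max(1L, round(0.2 * nrow(features)))))
    val_features <- features[idx, , drop = FALSE]
    val_labels <- labels[idx]
    features <- features[-idx, , drop = FALSE]
    labels <- labels[-idx]
  }

  space <- stacker_search_space()
  draws <- with_seed(derive_seed(seed, 137L), {
    lapply(seq_len(search_budget), function(i) {
      lapply(space, function(v) v[[sample.int(length(v), 1L)]])
    })
  })

  fit_one <- function(h, X, y) {
    xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    tree_method = "hist",
                    grow_policy = "lossguide",
                    max_leaves = h$num_leaves,
                    max_depth = 0L,
                    eta = h$learning_rate,
                    min_child_weight = h$min_child_samples,
                    colsample_bytree = h$feature_fraction,
                    nthread = 1L,
                    seed = derive_seed(seed, 7L)),
      data = xgboost::xgb.DMatrix(X, label = y),
      nrounds = h$n_estimators,
      verbose = 0
    )
  }

  best <- NULL; best_score <- -Inf; best_h <- NULL
  for (h in draws) {
    booster <- fit_one(h, features, labels)
    pv <- stats::predict(booster, xgboost::xgb.DMatrix(val_features))
    score <- if (length(unique(val_labels)) < 2L) 0 else pr_auc(pv, val_labels)
    if (score > best_score + 1e-12) {
      best_score <- score; best <- booster; best_h <- h
    }
  }
  structure(list(booster = best, hyperparams = best_h,
                 val_auprc = best_score, n_features = ncol(features),
                 trained = TRUE),
            class = "stacker_model")
}

#' Event probability per window from the stacker
#'
#' @param stacker A `stacker_model`.
#' @param features Feature matrix with the training-time width.
#' @return Probabilities in \[0, 1\], one per row.
#' @export
predict_proba <- function(stacker, features) {
  stopifnot(inherits(stacker, "stacker_model"))
  features <- as.matrix(features)
  if (ncol(features) != stacker$n_features) {
    stop_validation("feature width ", ncol(features),
                    " does not match training width ", stacker$n_features)
  }
  stats::predict(stacker$booster, xgboost::xgb.DMatrix(features))
}
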