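# Seed-deterministic wrapper around gradient-boosted regression trees
# (xgboost). The shipped default configuration is deliberately
# conservative for small-n pharmacogenomics cases: a low learning rate
# compensated by many trees, with row and column subsampling per
# boosting iteration.

#' Booster configuration
#'
#' The default configuration used for both the OMC complexity search and
#' the all-features baseline: learning rate 0.05, 700 trees, maximal
#' tree depth 6, and 0.8 row and column subsampling per boosting
#' iteration without replacement. All other learner settings stay at the
#' learner's defaults. Test-scale work can lower `n_trees`; the values
#' are configuration, never code changes.
#'
#' @param learning_rate shrinkage per boosting step, in (0, 1].
#' @param n_trees number of boosting rounds (>= 1).
#' @param max_depth maximal tree depth.
#' @param row_subsample,col_subsample fractions of rows (cell lines) and
#'   columns (features) sampled per boosting iteration, in (0, 1].
#' @param seed integer seed for the learner's subsampling RNG.
#' @param aggregate how a multi-seed ensemble combines per-seed
#'   predictions: `"mean"` (default) or `"median"`.
#' @return a `booster_config` list.
#' @export
booster_config <- function(learning_rate = 0.05, n_trees = 700L,
                           max_depth = 6L, row_subsample = 0.8,
                           col_subsample = 0.8, seed = 0L,
                           aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  stopifnot(learning_rate > 0, learning_rate <= 1,
            n_trees >= 1,
            max_depth >= 1,
            row_subsample > 0, row_subsample <= 1,
            col_subsample > 0, col_subsample <= 1)
  structure(list(learning_rate = learning_rate,
                 n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 row_subsample = row_subsample,
                 col_subsample = col_subsample,
                 seed = as.integer(seed),
                 aggregate = aggregate),
            class = "booster_config")
}

#' Train a gradient-boosted tree regressor
#'
#' Deterministic given `(X, y, config)` including the seed; single
#' threaded so results are platform-stable.
#'
#' @param X numeric feature matrix with column names.
#' @param y numeric response vector.
#' @param config a [booster_config()].
#' @return an `omc_booster` wrapping the fitted learner and the training
#'   feature names.
#' @export
train_booster <- function(X, y, config = booster_config()) {
  X <- as.matrix(X)
  if (ncol(X) < 1) stop("empty feature set")
  if (is.null(colnames(X))) stop("X must have column names")
  if (nrow(X) != length(y) || nrow(X) < 2)
    stop("need rows(X) == length(y) >= 2")
  if (anyNA(X) || anyNA(y) || any(!is.finite(X)) || any(!is.finite(y)))
    stop("non-finite values in training data")
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  params <- list(objective = "reg:squarederror",
                 eta = config$learning_rate,
                 max_depth = config$max_depth,
                 subsample = config$row_subsample,
                 colsample_bytree = config$col_subsample,
                 seed = config$seed,
                 nthread = 1)
  model <- xgboost::xgb.train(params = params, data = dtrain,
                              nrounds = config$n_trees, verbose = 0)
  structure(list(model = model, feature_names = colnames(X)),
            class = "omc_booster")
}

#' Predict from a fitted booster
#'
#' Columns of `newdata` are addressed by name and reordered to the
#' training layout, so predictions are invariant to column order.
#'
#' @param object an `omc_booster`.
#' @param newdata numeric matrix containing at least the training
#'   features (by name).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.omc_booster <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  missing <- setdiff(object$feature_names, colnames(newdata))
  if (length(missing) > 0)
    stop("newdata lacks training feature(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  newdata <- newdata[, object$feature_names, drop = FALSE]
  predict(object$model, xgboost::xgb.DMatrix(newdata, nthread = 1))
}

#' Aggregate predictions of a multi-seed ensemble
#'
#' The final model of a case is an ensemble of boosters trained with
#' different seeds on identical data; its prediction for each instance
#' is the per-instance mean (or median) of the per-seed predictions.
#'
#' @param models list of `omc_booster` objects sharing feature columns.
#' @param X_new matrix to predict.
#' @param aggregate `"mean"` (default) or `"median"`.
#' @return numeric vector of aggregated predictions.
#' @export
predict_ensemble <- function(models, X_new, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  if (length(models) < 1) stop("need at least one model")
  preds <- vapply(models, predict, numeric(nrow(X_new)), newdata = X_new)
  if (length(models) == 1) return(as.vector(preds))
  if (aggregate == "mean") rowMeans(preds) else apply(preds, 1, median)
}

#' Detect constant model output
#'
#' Models that predict a constant value regardless of input carry no
#' ranking information (their Spearman correlation is undefined) and are
#' rejected by the complexity search.
#'
#' @param pred numeric prediction vector (length >= 2).
#' @param tol variance threshold on the log10 IC50 scale.
#' @return `TRUE` iff the sample variance of `pred` is below `tol`.
#' @export
is_constant_prediction <- function(pred, tol = 1e-8) {
  if (length(pred) < 2) stop("need at least 2 predictions")
  var(pred) < tol
}
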