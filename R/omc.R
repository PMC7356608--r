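# The optimal-model-complexity (OMC) search. For each candidate
# complexity k in 2..floor(n/2), features are re-ranked inside each
# cross-validation fold using only the four non-validation folds, the
# booster is trained on the top-k features, and the validation fold is
# scored by Spearman correlation. A complexity passes only if every
# fold exceeds Rs 0.25 (strictly) and no fold's model predicts a
# constant; among passing complexities the one with the highest median
# fold Rs wins, ties going to the smaller (more parsimonious) k.

#' Per-fold feature rankings for the complexity search
#'
#' One ranking per fold, each computed on the rows of the four
#' non-validation folds only, so the validation fold never influences
#' feature selection. Because top-k subsets are nested along a ranking,
#' one ranking per fold serves every candidate k.
#'
#' @param X training-set feature matrix.
#' @param y training-set response vector.
#' @param folds a [make_cv_folds()] assignment over the rows of `X`.
#' @param kind `"binary"` or `"continuous"` (see [rank_features()]).
#' @return list of `feature_ranking` objects, one per fold.
#' @export
fold_rankings <- function(X, y, folds, kind) {
  lapply(seq_len(folds$n_folds), function(f) {
    keep <- folds$fold_of != f
    rank_features(X[keep, , drop = FALSE], y[keep], kind = kind)
  })
}

#' Evaluate one candidate model complexity on the cross-validation folds
#'
#' @param k candidate complexity, in \[2, floor(n/2)\].
#' @param X,y training-set feature matrix and response.
#' @param folds a [make_cv_folds()] assignment.
#' @param config a [booster_config()]; its seed is ignored in favour of
#'   `fold_seeds`.
#' @param kind feature encoding, `"binary"` or `"continuous"`.
#' @param rankings optional precomputed [fold_rankings()]; computed here
#'   when `NULL`.
#' @param fold_seeds integer vector of per-fold booster seeds (recycled
#'   from `config$seed` when `NULL`).
#' @param rs_min minimum per-fold Spearman correlation that must be
#'   strictly exceeded (default 0.25).
#' @return a `complexity_profile`: list with `k`, `fold_rs`,
#'   `constant_flagged`, `median_rs`, `passes`.
#' @export
evaluate_complexity <- function(k, X, y, folds, config = booster_config(),
                                kind = c("binary", "continuous"),
                                rankings = NULL, fold_seeds = NULL,
                                rs_min = 0.25) {
  kind <- match.arg(kind)
  n <- nrow(X)
  if (k < 2 || k > floor(n / 2))
    stop("k must lie in [2, ", floor(n / 2), "], got ", k)
  if (is.null(rankings)) rankings <- fold_rankings(X, y, folds, kind)
  if (is.null(fold_seeds)) fold_seeds <- rep(config$seed, folds$n_folds)

  fold_rs <- rep(NA_real_, folds$n_folds)
  constant_flagged <- logical(folds$n_folds)
  for (f in seq_len(folds$n_folds)) {
    val <- folds$fold_of == f
    feats <- top_k(rankings[[f]], k)
    cfg <- config
    cfg$seed <- fold_seeds[f]
    model <- train_booster(X[!val, feats, drop = FALSE], y[!val], cfg)
    pred <- predict(model, X[val, feats, drop = FALSE])
    constant_flagged[f] <- is_constant_prediction(pred)
    fold_rs[f] <- spearman_rs(pred, y[val])
  }
  complexity_profile(k, fold_rs, constant_flagged, rs_min)
}

#' Construct a complexity profile from per-fold results
#'
#' A complexity passes only when no fold's model was flagged as
#' constant-output and the minimum fold Spearman correlation strictly
#' exceeds `rs_min` ("exceeded": a fold sitting exactly at the threshold
#' fails).
#'
#' @param k the complexity evaluated.
#' @param fold_rs numeric vector of validation-fold Spearman values
#'   (`NA` where undefined).
#' @param constant_flagged logical vector, per-fold constant-output flags.
#' @param rs_min the per-fold gate (default 0.25).
#' @return a `complexity_profile`.
#' @export
complexity_profile <- function(k, fold_rs, constant_flagged = logical(length(fold_rs)),
                               rs_min = 0.25) {
  passes <- !any(constant_flagged) && !anyNA(fold_rs) && min(fold_rs) > rs_min
  structure(list(k = as.integer(k),
                 fold_rs = fold_rs,
                 constant_flagged = constant_flagged,
                 median_rs = median(fold_rs),
                 passes = passes),
            class = "complexity_profile")
}

#' Select the optimal model complexity from evaluated profiles
#'
#' Among profiles that pass the per-fold gates, the complexity with the
#' highest median fold Spearman correlation is chosen; ties are broken
#' toward the smallest k (parsimony). If no profile passes, the case has
#' no optimal complexity and is not potentially predictive.
#'
#' @param profiles list of `complexity_profile` objects covering the
#'   full candidate grid.
#' @return an `omc_selection`: list with `k_opt` (integer or `NA`),
#'   `selected_features` (filled by [run_case()]), and `profiles`.
#' @export
select_omc <- function(profiles) {
  if (length(profiles) == 0) stop("empty profile list")
  passing <- Filter(function(p) isTRUE(p$passes), profiles)
  if (length(passing) == 0) {
    k_opt <- NA_integer_
  } else {
    meds <- vapply(passing, function(p) p$median_rs, numeric(1))
    ks <- vapply(passing, function(p) p$k, integer(1))
    best <- which(meds == max(meds))
    k_opt <- min(ks[best])
  }
  structure(list(k_opt = k_opt, selected_features = character(0),
                 profiles = profiles),
            class = "omc_selection")
}

#' Run the full OMC workflow for one case
#'
#' Executes, in order: rank-stratified test split; rank-stratified
#' five-fold assignment of the training set; evaluation of every
#' complexity k in 2..floor(n/2) (feature ranking per fold on
#' non-validation rows only); selection of the optimal complexity; then
#' — when an optimal complexity exists — ranking on the entire training
#' set, training of a 10-seed booster ensemble on the top-k_opt
#' features, and evaluation on the held-out test set. An all-features
#' 10-seed baseline ensemble is trained and evaluated on the identical
#' split unless `mode = "omc_only"`. All randomness flows from
#' `master_seed` via [derive_seed()].
#'
#' @param dataset an eligible `case_dataset` (>= 45 cell lines).
#' @param master_seed integer master seed.
#' @param config a [booster_config()].
#' @param rs_min per-fold and test-set Spearman gate (default 0.25,
#'   strictly exceeded).
#' @param n_final_seeds ensemble size for the final models (default 10).
#' @param mode `"full"` (OMC plus all-features baseline),
#'   `"omc_only"`, or `"all_features_only"`.
#' @return a `case_result`: list carrying the case id, split, folds,
#'   complexity profiles, selection, final evaluations (`evaluation_omc`,
#'   `evaluation_all`), predictive classification, and all seeds used.
#' @export
run_case <- function(dataset, master_seed, config = booster_config(),
                     rs_min = 0.25, n_final_seeds = 10L,
                     mode = c("full", "omc_only", "all_features_only")) {
  mode <- match.arg(mode)
  if (!is_eligible(dataset))
    stop("ineligible case: ", length(dataset$y),
         " cell lines (at least 45 required)")
  m <- length(dataset$y)
  kind <- if (omics_is_binary(dataset$omics)) "binary" else "continuous"

  split_seed <- derive_seed(master_seed, 1)
  folds_seed <- derive_seed(master_seed, 2)
  fold_seeds <- vapply(1:5, function(f) derive_seed(master_seed, 2 + f),
                       integer(1))
  final_seeds <- vapply(seq_len(n_final_seeds),
                        function(i) derive_seed(master_seed, 7 + i),
                        integer(1))

  split <- make_test_split(dataset$y, seed = split_seed, ids = dataset$cell_ids)
  tr <- split$train_idx
  te <- split$test_idx
  X_tr <- dataset$X[tr, , drop = FALSE]
  y_tr <- dataset$y[tr]
  X_te <- dataset$X[te, , drop = FALSE]
  y_te <- dataset$y[te]
  n <- length(tr)

  folds <- make_cv_folds(y_tr, seed = folds_seed, ids = dataset$cell_ids[tr])
  rankings <- fold_rankings(X_tr, y_tr, folds, kind)
  k_grid <- seq.int(2L, floor(n / 2))
  profiles <- lapply(k_grid, function(k) {
    evaluate_complexity(k, X = X_tr, y = y_tr, folds = folds, config = config,
                        kind = kind, rankings = rankings,
                        fold_seeds = fold_seeds, rs_min = rs_min)
  })
  selection <- select_omc(profiles)

  evaluation_omc <- NULL
  if (!is.na(selection$k_opt) && mode != "all_features_only") {
    full_ranking <- rank_features(X_tr, y_tr, kind = kind)
    selection$selected_features <- top_k(full_ranking, selection$k_opt)
    models <- lapply(final_seeds, function(s) {
      cfg <- config
      cfg$seed <- s
      train_booster(X_tr[, selection$selected_features, drop = FALSE], y_tr, cfg)
    })
    pred <- predict_ensemble(models,
                             X_te[, selection$selected_features, drop = FALSE],
                             aggregate = config$aggregate)
    names(pred) <- dataset$cell_ids[te]
    evaluation_omc <- evaluate_predictions(pred, y_te)
  }

  evaluation_all <- NULL
  if (mode != "omc_only") {
    models <- lapply(final_seeds, function(s) {
      cfg <- config
      cfg$seed <- s
      train_booster(X_tr, y_tr, cfg)
    })
    pred <- predict_ensemble(models, X_te, aggregate = config$aggregate)
    names(pred) <- dataset$cell_ids[te]
    evaluation_all <- evaluate_predictions(pred, y_te)
  }

  result <- structure(
    list(case_id = list(drug = dataset$drug,
                        cancer_type = dataset$cancer_type,
                        omics = dataset$omics),
         m = m, n = n, p = ncol(dataset$X),
         rs_min = rs_min,
         split = list(train_ids = dataset$cell_ids[tr],
                      test_ids = dataset$cell_ids[te],
                      test_ranks = split$test_ranks),
         fold_of = stats::setNames(folds$fold_of, dataset$cell_ids[tr]),
         selection = selection,
         evaluation_omc = evaluation_omc,
         evaluation_all = evaluation_all,
         seeds = list(master = as.integer(master_seed), split = split_seed,
                      folds = folds_seed, fold_boosters = fold_seeds,
                      final = final_seeds),
         config = config,
         mode = mode),
    class = "case_result")
  result$classification <- classify_case(result)
  result
}

#' @export
print.case_result <- function(x, ...) {
  cat(sprintf("case_result: %s / %s / %s  (m = %d, p = %d)\n",
              x$case_id$drug, x$case_id$cancer_type, x$case_id$omics,
              x$m, x$p))
  if (is.na(x$selection$k_opt)) {
    cat("  no complexity passed the per-fold gates (k_opt = none)\n")
  } else {
    cat(sprintf("  k_opt = %d; test Rs (OMC) = %.3f, R2 = %.3f\n",
                x$selection$k_opt, x$evaluation_omc$rs, x$evaluation_omc$r2))
  }
  if (!is.null(x$evaluation_all))
    cat(sprintf("  test Rs (all %d features) = %.3f, R2 = %.3f\n",
                x$p, x$evaluation_all$rs, x$evaluation_all$r2))
  cat("  classification:", x$classification, "\n")
  invisible(x)
}
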