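# Evidence machinery: the two-gate predictive classification,
# y-randomization (label-permutation) control, and the OMC-vs-all
# complementarity bookkeeping across a panel of cases.

#' Classify a case result as predictive / potentially predictive / neither
#'
#' Two gates: a case is *potentially predictive* when some complexity
#' passed the per-fold Spearman threshold (k_opt exists), and
#' *predictive* when in addition the final OMC model's test-set Spearman
#' correlation strictly exceeds the threshold (default 0.25). Cases with
#' no passing complexity are *not potentially predictive*.
#'
#' @param result a `case_result` from [run_case()].
#' @param rs_min the test-set gate; defaults to the threshold recorded
#'   in the result.
#' @return one of `"not_potentially_predictive"`,
#'   `"potentially_predictive"`, `"predictive"`.
#' @export
classify_case <- function(result, rs_min = result$rs_min) {
  if (is.na(result$selection$k_opt)) return("not_potentially_predictive")
  rs <- if (!is.null(result$evaluation_omc)) result$evaluation_omc$rs else NA_real_
  if (!is.na(rs) && rs > rs_min) "predictive" else "potentially_predictive"
}

#' y-randomization validation of a selected feature subset
#'
#' Estimates how much of a model's accuracy comes from real signal.
#' On the full case dataset (training and test rows merged), `runs`
#' five-fold cross-validations with real labels are compared against
#' `runs` cross-validations with uniformly shuffled labels (a fresh
#' shuffle per run). Folds are rank-stratified exactly as in the main
#' workflow; for permuted runs the stratification uses the permuted
#' values' own ranks. Each run is summarized by the mean of its five
#' validation-fold Spearman correlations (a constant-output fold
#' contributes 0, carrying no rank information), and the two lists of
#' run summaries are compared by a two-sided paired t-test.
#'
#' @param dataset the full `case_dataset`.
#' @param features non-empty character vector of feature names (the
#'   selected OMC subset).
#' @param runs number of cross-validation runs per condition (default 10).
#' @param config a [booster_config()].
#' @param seed integer master seed for this validation.
#' @param permute permutation hook, a `function(n)` returning an index
#'   permutation; the default is a uniform shuffle. (Passing
#'   `seq_len` makes the "permuted" arm identical to the real arm,
#'   useful for testing.)
#' @return a `y_randomization_result`: list with `real_rs`,
#'   `permuted_rs` (length `runs` each) and `t_p`.
#' @export
y_randomize <- function(dataset, features, runs = 10L,
                        config = booster_config(), seed = 0L,
                        permute = sample.int) {
  if (length(features) == 0) stop("empty feature list")
  missing <- setdiff(features, dataset$feature_names)
  if (length(missing) > 0)
    stop("unknown feature(s): ", paste(utils::head(missing, 5), collapse = ", "))
  X <- dataset$X[, features, drop = FALSE]
  y <- dataset$y
  ids <- dataset$cell_ids

  cv_mean_rs <- function(y_run, run_seed) {
    folds <- make_cv_folds(y_run, seed = run_seed, ids = ids)
    rs <- vapply(seq_len(folds$n_folds), function(f) {
      val <- folds$fold_of == f
      cfg <- config
      cfg$seed <- derive_seed(run_seed, f)
      model <- train_booster(X[!val, , drop = FALSE], y_run[!val], cfg)
      pred <- predict(model, X[val, , drop = FALSE])
      if (is_constant_prediction(pred)) 0 else spearman_rs(pred, y_run[val])
    }, numeric(1))
    mean(rs)
  }

  real_rs <- vapply(seq_len(runs), function(r) {
    cv_mean_rs(y, derive_seed(seed, r))
  }, numeric(1))

  permuted_rs <- vapply(seq_len(runs), function(r) {
    run_seed <- derive_seed(seed, 1000L + r)
    perm <- withr::with_seed(run_seed, permute(length(y)))
    cv_mean_rs(y[perm], derive_seed(run_seed, 1))
  }, numeric(1))

  structure(list(real_rs = real_rs, permuted_rs = permuted_rs,
                 t_p = paired_t_p(real_rs, permuted_rs)),
            class = "y_randomization_result")
}

# two-sided paired t-test p-value, with the degenerate zero-variance
# case mapped to 1 (no evidence of difference) or 0 (constant nonzero
# difference)
paired_t_p <- function(a, b) {
  d <- a - b
  if (sd(d) < 1e-12) return(if (abs(mean(d)) < 1e-12) 1 else 0)
  t.test(a, b, paired = TRUE)$p.value
}

#' Complementarity summary of OMC and all-features models over a panel
#'
#' Quadrant counts of cases predictive (test-set Spearman strictly above
#' the gate) by both methods, by OMC only, by the all-features baseline
#' only, or by neither; the mean paired difference in test Spearman
#' (OMC minus all-features) with a two-sided paired t-test over cases
#' carrying both evaluations; and the mean feature-reduction fraction
#' `1 - k_opt / p` over OMC-predictive cases.
#'
#' @param results list of `case_result` objects (mode `"full"`).
#' @param rs_min test-set gate (default 0.25).
#' @return a `complementarity_summary`: list with `counts` (named
#'   integer vector: both, omc_only, all_only, neither), `mean_rs_diff`,
#'   `t_p`, `mean_feature_reduction`, and the per-case table `cases`.
#' @export
complementarity <- function(results, rs_min = 0.25) {
  rs_of <- function(ev) if (is.null(ev) || is.na(ev$rs)) NA_real_ else ev$rs
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(drug = r$case_id$drug,
               cancer_type = r$case_id$cancer_type,
               omics = r$case_id$omics,
               k_opt = r$selection$k_opt,
               p = r$p,
               rs_omc = rs_of(r$evaluation_omc),
               rs_all = rs_of(r$evaluation_all),
               classification = r$classification,
               stringsAsFactors = FALSE)
  }))
  omc_pred <- !is.na(tab$rs_omc) & tab$rs_omc > rs_min
  all_pred <- !is.na(tab$rs_all) & tab$rs_all > rs_min
  counts <- c(both = sum(omc_pred & all_pred),
              omc_only = sum(omc_pred & !all_pred),
              all_only = sum(!omc_pred & all_pred),
              neither = sum(!omc_pred & !all_pred))
  paired <- !is.na(tab$rs_omc) & !is.na(tab$rs_all)
  if (any(paired)) {
    diff_mean <- mean(tab$rs_omc[paired] - tab$rs_all[paired])
    t_p <- if (sum(paired) >= 2)
      paired_t_p(tab$rs_omc[paired], tab$rs_all[paired]) else NA_real_
  } else {
    diff_mean <- NA_real_
    t_p <- NA_real_
  }
  reduction <- if (any(omc_pred))
    mean(1 - tab$k_opt[omc_pred] / tab$p[omc_pred]) else NA_real_
  structure(list(counts = counts,
                 mean_rs_diff = diff_mean,
                 t_p = t_p,
                 mean_feature_reduction = reduction,
                 cases = tab),
            class = "complementarity_summary")
}

#' @export
print.complementarity_summary <- function(x, ...) {
  cat("complementarity over", nrow(x$cases), "cases:\n")
  print(x$counts)
  cat(sprintf("  mean test-Rs difference (OMC - all): %.4f (paired t p = %.3g)\n",
              x$mean_rs_diff, x$t_p))
  if (!is.na(x$mean_feature_reduction))
    cat(sprintf("  mean feature reduction among OMC-predictive cases: %.1f%%\n",
                100 * x$mean_feature_reduction))
  invisible(x)
}
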