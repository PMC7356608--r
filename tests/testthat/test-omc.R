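test_that("the complexity grid covers exactly 2..floor(n/2)", {
  ds <- generate_case(strong_case_spec(seed = 501))
  res <- run_case(ds, master_seed = 601, config = tiny_config(), mode = "omc_only")
  expect_equal(res$n, 35)
  ks <- vapply(res$selection$profiles, function(p) p$k, integer(1))
  expect_identical(ks, 2:17)
  for (pr in res$selection$profiles) {
    expect_length(pr$fold_rs, 5)
    expect_length(pr$constant_flagged, 5)
    expect_identical(pr$passes,
                     !any(pr$constant_flagged) && !anyNA(pr$fold_rs) &&
                       min(pr$fold_rs) > 0.25)
    if (!anyNA(pr$fold_rs)) expect_equal(pr$median_rs, median(pr$fold_rs))
  }
})

test_that("per-fold top-k subsets are nested for every k", {
  ds <- generate_case(strong_case_spec(seed = 502))
  sp <- make_test_split(ds$y, ids = ds$cell_ids)
  ytr <- ds$y[sp$train_idx]
  folds <- make_cv_folds(ytr, seed = 9, ids = ds$cell_ids[sp$train_idx])
  rankings <- fold_rankings(ds$X[sp$train_idx, ], ytr, folds, "continuous")
  for (rk in rankings) {
    for (k in 2:16) {
      expect_identical(top_k(rk, k), top_k(rk, k + 1)[1:k])
    }
  }
})

test_that("planted signal passes the per-fold gates; pure noise does not", {
  cfg <- tiny_config()
  ds <- generate_case(strong_case_spec(seed = 501))
  sp <- make_test_split(ds$y, ids = ds$cell_ids)
  Xtr <- ds$X[sp$train_idx, ]
  ytr <- ds$y[sp$train_idx]
  folds <- make_cv_folds(ytr, seed = derive_seed(601L, 2), ids = ds$cell_ids[sp$train_idx])
  rankings <- fold_rankings(Xtr, ytr, folds, "continuous")
  profiles <- lapply(3:8, function(k) {
    evaluate_complexity(k, Xtr, ytr, folds, cfg, kind = "continuous",
                        rankings = rankings)
  })
  passing <- Filter(function(p) p$passes, profiles)
  expect_gte(length(passing), 1)
  for (pr in passing) expect_gt(pr$median_rs, 0.5)

  # pure-null cases: no complexity should survive the gates
  for (i in 1:5) {
    spec <- strong_case_spec(seed = 700 + i)
    spec$k_true <- 0L
    spec$effect_sizes <- numeric(0)
    rn <- run_case(generate_case(spec), master_seed = 800 + i,
                   config = cfg, mode = "omc_only")
    expect_equal(rn$classification, "not_potentially_predictive")
    expect_true(is.na(rn$selection$k_opt))
  }
})

test_that("evaluate_complexity validates the k range", {
  ds <- generate_case(strong_case_spec(seed = 503))
  sp <- make_test_split(ds$y, ids = ds$cell_ids)
  ytr <- ds$y[sp$train_idx]
  folds <- make_cv_folds(ytr, seed = 1, ids = ds$cell_ids[sp$train_idx])
  expect_error(evaluate_complexity(1, ds$X[sp$train_idx, ], ytr, folds,
                                   tiny_config(), "continuous"), "k must")
  expect_error(evaluate_complexity(18, ds$X[sp$train_idx, ], ytr, folds,
                                   tiny_config(), "continuous"), "k must")
})

test_that("selection picks the highest median among passing complexities", {
  p1 <- complexity_profile(5, c(0.4, 0.5, 0.3, 0.6, 0.45))
  expect_true(p1$passes)
  p2 <- complexity_profile(9, c(0.1, 0.5, 0.3, 0.6, 0.45))  # fails the gate
  expect_false(p2$passes)
  sel <- select_omc(list(p2, p1))
  expect_equal(sel$k_opt, 5L)                    # unique survivor

  # tie on the median goes to the smaller k (parsimony)
  p4 <- complexity_profile(4, c(0.30, 0.40, 0.50, 0.60, 0.70))
  p9 <- complexity_profile(9, c(0.35, 0.45, 0.50, 0.55, 0.65))
  expect_equal(p4$median_rs, p9$median_rs)
  expect_equal(select_omc(list(p9, p4))$k_opt, 4L)

  # nothing passes: no optimal complexity
  expect_true(is.na(select_omc(list(p2))$k_opt))
  expect_error(select_omc(list()), "empty")
})

test_that("the 0.25 per-fold gate is strict and constant output disqualifies", {
  at_threshold <- complexity_profile(5, c(0.25, 0.5, 0.5, 0.5, 0.5))
  expect_false(at_threshold$passes)
  above <- complexity_profile(5, c(0.2500001, 0.5, 0.5, 0.5, 0.5))
  expect_true(above$passes)
  flagged <- complexity_profile(5, c(0.5, 0.5, 0.5, 0.5, 0.5),
                                constant_flagged = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_false(flagged$passes)
  undefined <- complexity_profile(5, c(NA, 0.5, 0.5, 0.5, 0.5))
  expect_false(undefined$passes)
})

test_that("run_case recovers planted features and fills a coherent result", {
  cfg <- tiny_config()
  predictive <- 0
  recovered <- integer(0)
  for (i in 1:10) {
    ds <- generate_case(strong_case_spec(seed = 500 + i))
    res <- run_case(ds, master_seed = 600 + i, config = cfg, mode = "omc_only")
    if (res$classification == "predictive") predictive <- predictive + 1
    if (!is.na(res$selection$k_opt)) {
      expect_length(res$selection$selected_features, res$selection$k_opt)
      expect_true(res$selection$k_opt >= 2 && res$selection$k_opt <= 17)
      recovered <- c(recovered,
                     sum(attr(ds, "ground_truth")$informative %in%
                           res$selection$selected_features))
    }
  }
  expect_gte(predictive, 6)
  expect_gte(mean(recovered >= 2), 0.7)   # of the 3 planted features
})

test_that("rerunning with the same master seed gives a byte-identical document", {
  ds <- generate_case(strong_case_spec(seed = 504))
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "r1.json")
  f2 <- file.path(dir, "r2.json")
  write_case_result(run_case(ds, 77L, config = tiny_config()), f1,
                    timestamp = FALSE)
  write_case_result(run_case(ds, 77L, config = tiny_config()), f2,
                    timestamp = FALSE)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("test-set feature values influence nothing before final evaluation", {
  ds <- generate_case(strong_case_spec(seed = 505))
  res1 <- run_case(ds, 88L, config = tiny_config(), mode = "omc_only")
  # corrupt the feature values of the held-out cell lines only
  ds2 <- ds
  test_rows <- match(res1$split$test_ids, ds$cell_ids)
  ds2$X[test_rows, ] <- ds2$X[test_rows, sample(ncol(ds2$X))] + 5
  res2 <- run_case(ds2, 88L, config = tiny_config(), mode = "omc_only")
  expect_identical(res1$split, res2$split)
  expect_identical(res1$fold_of, res2$fold_of)
  expect_identical(res1$selection$k_opt, res2$selection$k_opt)
  expect_identical(res1$selection$selected_features,
                   res2$selection$selected_features)
  expect_identical(vapply(res1$selection$profiles, `[[`, numeric(5), "fold_rs"),
                   vapply(res2$selection$profiles, `[[`, numeric(5), "fold_rs"))
})

test_that("ineligible datasets are refused", {
  spec <- strong_case_spec(seed = 1)
  spec$m <- 40L
  expect_error(run_case(generate_case(spec), 1L, config = tiny_config()),
               "ineligible")
})
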