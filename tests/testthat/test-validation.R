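test_that("the two-gate classification follows k_opt and the test-set threshold", {
  expect_equal(fake_result(k_opt = 5L, rs_omc = 0.3)$classification,
               "predictive")
  # exactly at the threshold is not enough (strict inequality)
  expect_equal(fake_result(k_opt = 5L, rs_omc = 0.25)$classification,
               "potentially_predictive")
  expect_equal(fake_result(k_opt = 5L, rs_omc = 0.10)$classification,
               "potentially_predictive")
  expect_equal(fake_result(k_opt = NA_integer_)$classification,
               "not_potentially_predictive")
  # undefined test correlation (constant ensemble output) fails the gate
  expect_equal(fake_result(k_opt = 5L, rs_omc = NA_real_)$classification,
               "potentially_predictive")
})

test_that("y-randomization separates real labels from shuffled labels", {
  ds <- generate_case(strong_case_spec(seed = 501))
  truth <- attr(ds, "ground_truth")$informative
  yr <- y_randomize(ds, truth, runs = 8, config = tiny_config(), seed = 77)
  expect_length(yr$real_rs, 8)
  expect_length(yr$permuted_rs, 8)
  expect_gt(mean(yr$real_rs), 0.5)
  expect_lt(abs(mean(yr$permuted_rs)), 0.15)
  expect_lt(yr$t_p, 0.01)
})

test_that("an identity 'shuffle' makes the two arms indistinguishable", {
  ds <- generate_case(strong_case_spec(seed = 502))
  truth <- attr(ds, "ground_truth")$informative
  yr <- y_randomize(ds, truth, runs = 6, config = tiny_config(), seed = 78,
                    permute = function(n) seq_len(n))
  # same labels on both arms; only fold assignments and booster seeds differ
  expect_lt(abs(mean(yr$real_rs) - mean(yr$permuted_rs)), 0.2)
  expect_gt(yr$t_p, 0.05)
})

test_that("y-randomization on a null case shows no significant signal", {
  spec <- strong_case_spec(seed = 703)
  spec$k_true <- 0L
  spec$effect_sizes <- numeric(0)
  ds <- generate_case(spec)
  yr <- y_randomize(ds, ds$feature_names[1:5], runs = 8,
                    config = tiny_config(), seed = 79)
  expect_lt(abs(mean(yr$real_rs) - mean(yr$permuted_rs)), 0.3)
  expect_lt(abs(mean(yr$permuted_rs)), 0.15)
})

test_that("y-randomization rejects empty or unknown feature sets", {
  ds <- generate_case(strong_case_spec(seed = 504))
  expect_error(y_randomize(ds, character(0), config = tiny_config()), "empty")
  expect_error(y_randomize(ds, "NOPE", config = tiny_config()), "unknown feature")
})

test_that("complementarity counts the predictive quadrants", {
  results <- list(fake_result(5L, rs_omc = 0.3, rs_all = 0.3),
                  fake_result(5L, rs_omc = 0.3, rs_all = 0.1),
                  fake_result(5L, rs_omc = 0.1, rs_all = 0.3))
  cs <- complementarity(results)
  expect_identical(cs$counts,
                   c(both = 1L, omc_only = 1L, all_only = 1L, neither = 0L))
  # hand recount from the per-case table
  tab <- cs$cases
  expect_equal(sum(tab$rs_omc > 0.25 & tab$rs_all > 0.25), cs$counts[["both"]])
  expect_equal(cs$mean_rs_diff, mean(c(0, 0.2, -0.2)))

  # identical pairs: zero mean difference, degenerate paired t -> 1
  same <- list(fake_result(4L, rs_omc = 0.4, rs_all = 0.4),
               fake_result(6L, rs_omc = 0.4, rs_all = 0.4))
  cs2 <- complementarity(same)
  expect_equal(cs2$mean_rs_diff, 0)
  expect_equal(cs2$t_p, 1)

  # cases with no optimal complexity land in 'neither'
  with_null <- complementarity(list(fake_result(NA_integer_, rs_all = 0.5),
                                    fake_result(NA_integer_)))
  expect_identical(with_null$counts[["all_only"]], 1L)
  expect_identical(with_null$counts[["neither"]], 1L)
})

test_that("feature reduction is averaged over OMC-predictive cases", {
  results <- list(fake_result(5L, rs_omc = 0.5, rs_all = 0.1, p = 100L),
                  fake_result(20L, rs_omc = 0.6, rs_all = 0.7, p = 200L),
                  fake_result(9L, rs_omc = 0.1, rs_all = 0.1, p = 100L))
  cs <- complementarity(results)
  expect_equal(cs$mean_feature_reduction, mean(c(1 - 5 / 100, 1 - 20 / 200)))
})

test_that("a panel run matches an independent recount of its result documents", {
  dir <- withr::local_tempdir()
  cfg <- tiny_config()
  panel <- generate_panel(4, strong_case_spec(seed = 0L),
                          signal_fraction = 0.5, seed = 91L)
  for (i in seq_along(panel$cases)) {
    res <- run_case(panel$cases[[i]], master_seed = 900L + i, config = cfg)
    write_case_result(res, file.path(dir, sprintf("case%02d.json", i)))
  }
  docs <- lapply(list.files(dir, full.names = TRUE), read_case_result)
  cs <- complementarity(docs)
  # independent recount straight from the JSON text
  raw <- lapply(list.files(dir, full.names = TRUE),
                jsonlite::read_json, simplifyVector = TRUE)
  omc_pred <- vapply(raw, function(d) {
    !is.null(d$evaluation_omc) && length(d$evaluation_omc) > 0 &&
      d$evaluation_omc$rs > 0.25
  }, logical(1))
  all_pred <- vapply(raw, function(d) {
    !is.null(d$evaluation_all) && length(d$evaluation_all) > 0 &&
      d$evaluation_all$rs > 0.25
  }, logical(1))
  expect_equal(cs$counts[["both"]], sum(omc_pred & all_pred))
  expect_equal(cs$counts[["omc_only"]], sum(omc_pred & !all_pred))
  expect_equal(cs$counts[["all_only"]], sum(!omc_pred & all_pred))
  expect_equal(cs$counts[["neither"]], sum(!omc_pred & !all_pred))
})
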