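# Shared fixtures and independent oracles for the test suite.

# Reduced booster configuration for test speed; hyperparameters other
# than the tree count match the shipped defaults.
tiny_config <- function(seed = 0L, n_trees = 30L) {
  booster_config(n_trees = n_trees, seed = seed)
}

# A compact planted-signal case with strong, reliably recoverable
# univariate signal: 3 informative features among 40, large effects,
# low noise. Used for unit tests of the search machinery.
strong_case_spec <- function(seed = 0L) {
  synthetic_case_spec(m = 45L, p = 40L, omics = "GEX", k_true = 3L,
                      effect_sizes = c(2, 1.5, 1), noise_sd = 0.3,
                      link = "linear", seed = seed)
}

# Independent Wilcoxon rank-sum oracle: two-sided exact p-value by full
# enumeration of all group assignments of the pooled sample (valid for
# tie-free data; the null distribution of W is then symmetric).
enumerated_wilcox_p <- function(y1, y0) {
  pooled <- c(y1, y0)
  n1 <- length(y1)
  r <- rank(pooled)
  obs_w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y0) / 2
  combos <- utils::combn(length(pooled), n1)
  ws <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(ws - mu) >= abs(obs_w - mu) - 1e-9)
}

# Rank-then-Pearson oracle for the Spearman correlation.
rank_pearson <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# Minimal case_result skeleton for classification / complementarity
# tests.
fake_result <- function(k_opt, rs_omc = NA_real_, rs_all = NA_real_,
                        p = 100L, drug = "d", rs_min = 0.25) {
  res <- structure(
    list(case_id = list(drug = drug, cancer_type = "CT", omics = "GEX"),
         m = 45L, n = 35L, p = p, rs_min = rs_min,
         selection = list(k_opt = k_opt, selected_features = character(0),
                          profiles = list()),
         evaluation_omc = if (is.na(rs_omc)) NULL else list(rs = rs_omc, r2 = 0),
         evaluation_all = if (is.na(rs_all)) NULL else list(rs = rs_all, r2 = 0)),
    class = "case_result")
  res$classification <- classify_case(res)
  res
}
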