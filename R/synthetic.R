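# Seeded generator of synthetic pharmacogenomics cases with known
# ground truth. It emulates the shapes of real drug-response cases —
# binary Bernoulli mutation features or continuous Gaussian
# expression-like features, a response driven by a small planted subset
# of features plus Gaussian noise, and pure-null cases — so the whole
# workflow is testable without any external download.

#' Specification of a synthetic case
#'
#' @param m number of cell lines (default 45, the eligibility floor, so
#'   the default training set has n = 35 and complexity grid 2..17).
#' @param p number of features; defaults to 470 for binary omics and 450
#'   for continuous, the sizes typical of curated mutation and
#'   expression panels.
#' @param omics one of `"SNV"`, `"CNA"`, `"GEX"`, `"METHY"`.
#' @param k_true number of informative (planted) features; 0 gives a
#'   pure-null case.
#' @param effect_sizes numeric vector of length `k_true`.
#' @param noise_sd standard deviation of the additive Gaussian noise on
#'   the log10 IC50 scale.
#' @param mutation_rate Bernoulli rate of binary features, in (0, 1).
#' @param link response link: `"linear"` (weighted sum of the planted
#'   features), `"threshold"` (weighted sum of median-step indicators —
#'   tree-friendly), or `"interaction"` (the product of the first two
#'   planted features, weighted by the first effect size, plus the
#'   linear remainder).
#' @param seed integer seed; the generated case is a pure function of
#'   the spec.
#' @return a `synthetic_case_spec` list.
#' @export
synthetic_case_spec <- function(m = 45L, p = NULL,
                                omics = c("GEX", "METHY", "SNV", "CNA"),
                                k_true = 0L, effect_sizes = numeric(0),
                                noise_sd = 0.5, mutation_rate = 0.2,
                                link = c("linear", "threshold", "interaction"),
                                seed = 0L) {
  omics <- match.arg(omics)
  link <- match.arg(link)
  if (is.null(p)) p <- if (omics_is_binary(omics)) 470L else 450L
  if (k_true < 0 || k_true > p) stop("k_true must lie in [0, p]")
  if (length(effect_sizes) != k_true)
    stop("length(effect_sizes) [", length(effect_sizes),
         "] must equal k_true [", k_true, "]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (mutation_rate <= 0 || mutation_rate >= 1)
    stop("mutation_rate must lie in (0, 1)")
  structure(list(m = as.integer(m), p = as.integer(p), omics = omics,
                 k_true = as.integer(k_true), effect_sizes = effect_sizes,
                 noise_sd = noise_sd, mutation_rate = mutation_rate,
                 link = link, seed = as.integer(seed)),
            class = "synthetic_case_spec")
}

#' Reference synthetic-case specification
#'
#' The documented reference conditions used throughout the package's
#' validation runs: m = 45 cell lines, p = 200 continuous
#' expression-like features, 5 planted features with effect sizes
#' (1, 1, 0.8, 0.8, 0.6), linear link, noise standard deviation 0.5.
#' With `signal = FALSE` the same shape is generated with no planted
#' features (a pure-null case).
#'
#' @param seed integer seed.
#' @param signal plant the 5 informative features (default) or none.
#' @return a `synthetic_case_spec`.
#' @export
reference_case_spec <- function(seed = 0L, signal = TRUE) {
  if (signal) {
    synthetic_case_spec(m = 45L, p = 200L, omics = "GEX", k_true = 5L,
                        effect_sizes = c(1, 1, 0.8, 0.8, 0.6),
                        noise_sd = 0.5, link = "linear", seed = seed)
  } else {
    synthetic_case_spec(m = 45L, p = 200L, omics = "GEX", k_true = 0L,
                        noise_sd = 0.5, link = "linear", seed = seed)
  }
}

#' Generate a synthetic case with known ground truth
#'
#' Binary features are i.i.d. Bernoulli(`mutation_rate`); continuous
#' features are i.i.d. standard Gaussian. The response is
#' `link(planted features; effect_sizes)` plus Gaussian noise. The
#' planted feature columns are chosen at random and recorded in the
#' ground-truth attachment.
#'
#' @param spec a [synthetic_case_spec()].
#' @return a `case_dataset` with attribute `"ground_truth"`: list with
#'   `informative` (feature names), `link`, and `snr` (variance of the
#'   noiseless signal over the noise variance; `Inf` for zero noise).
#' @export
generate_case <- function(spec) {
  stopifnot(inherits(spec, "synthetic_case_spec"))
  cell_ids <- sprintf("CL%04d", seq_len(spec$m))
  feature_names <- sprintf("F%04d", seq_len(spec$p))
  parts <- withr::with_seed(spec$seed, {
    X <- if (omics_is_binary(spec$omics)) {
      matrix(rbinom(spec$m * spec$p, 1, spec$mutation_rate), spec$m, spec$p)
    } else {
      matrix(rnorm(spec$m * spec$p), spec$m, spec$p)
    }
    dimnames(X) <- list(cell_ids, feature_names)
    informative <- if (spec$k_true > 0)
      sort(sample.int(spec$p, spec$k_true)) else integer(0)
    signal <- planted_signal(X, informative, spec$effect_sizes, spec$link)
    y <- signal + rnorm(spec$m, sd = spec$noise_sd)
    list(X = X, y = y, informative = informative, signal = signal)
  })
  dataset <- case_dataset(parts$X, parts$y,
                          drug = sprintf("synthetic-drug-%d", spec$seed),
                          cancer_type = "SYNTH", omics = spec$omics)
  attr(dataset, "ground_truth") <-
    list(informative = feature_names[parts$informative],
         link = spec$link,
         snr = if (spec$noise_sd > 0) var(parts$signal) / spec$noise_sd^2 else Inf)
  dataset
}

planted_signal <- function(X, informative, effects, link) {
  m <- nrow(X)
  if (length(informative) == 0) return(numeric(m))
  Z <- X[, informative, drop = FALSE]
  switch(link,
    linear = as.vector(Z %*% effects),
    threshold = {
      S <- vapply(seq_len(ncol(Z)),
                  function(j) as.numeric(Z[, j] > median(Z[, j])),
                  numeric(m))
      as.vector(S %*% effects)
    },
    interaction = {
      s <- effects[1] * Z[, 1] * Z[, min(2, ncol(Z))]
      if (ncol(Z) >= 3)
        s <- s + as.vector(Z[, -(1:2), drop = FALSE] %*% effects[-(1:2)])
      s
    })
}

#' Generate a panel of synthetic cases with a known signal subset
#'
#' A desk-scale stand-in for a large drug-by-cancer-type screen: a fixed
#' fraction of the cases carries planted signal (per the template spec)
#' and the rest are pure null. The signal/null identity of every case is
#' recorded, so panel-level classification counts have a known truth —
#' with `signal_fraction = 0` the panel estimates the workflow's
#' false-positive rate.
#'
#' @param n_cases number of cases.
#' @param spec_template a `synthetic_case_spec` with `k_true > 0`; null
#'   cases reuse its shape with `k_true = 0`.
#' @param signal_fraction fraction of cases carrying signal, in \[0, 1\];
#'   the signal count is `round(n_cases * signal_fraction)`.
#' @param seed integer panel seed; per-case seeds and the position of
#'   signal cases are derived from it.
#' @return list with `cases` (list of `case_dataset`) and `signal`
#'   (logical vector).
#' @export
generate_panel <- function(n_cases, spec_template, signal_fraction, seed = 0L) {
  if (signal_fraction < 0 || signal_fraction > 1)
    stop("signal_fraction must lie in [0, 1]")
  n_signal <- round(n_cases * signal_fraction)
  signal <- rep(FALSE, n_cases)
  if (n_signal > 0)
    signal[withr::with_seed(as.integer(seed),
                            sample.int(n_cases, n_signal))] <- TRUE
  cases <- lapply(seq_len(n_cases), function(i) {
    sp <- spec_template
    sp$seed <- derive_seed(seed, i)
    if (!signal[i]) {
      sp$k_true <- 0L
      sp$effect_sizes <- numeric(0)
    }
    generate_case(sp)
  })
  list(cases = cases, signal = signal)
}
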