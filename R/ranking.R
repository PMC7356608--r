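# Univariate feature pre-ranking against the response. Raw p-values are
# used purely as an ordering device (no multiple-testing correction):
# the top-k subsets fed to the booster are nested along this ranking.

#' Rank features by univariate association with the response
#'
#' Binary features (mutation / copy-number status) are scored with a
#' two-sided Wilcoxon rank-sum test comparing responses of carriers
#' (value 1) against non-carriers (value 0): exact null distribution
#' when both groups have at most 25 members and the response has no
#' ties, normal approximation with continuity correction otherwise.
#' Continuous features are scored with a two-sided Spearman
#' rank-correlation test (t approximation on rho with n - 2 degrees of
#' freedom). Features are sorted by ascending p-value; ties are broken
#' by descending absolute effect size, then by feature name, so the
#' ordering is fully deterministic.
#'
#' Degenerate features — constant across the supplied rows, or binary
#' features whose carrier or non-carrier group is empty — carry no
#' information and receive p = 1 (ranked last) rather than being
#' dropped, keeping the feature set stable across folds.
#'
#' @param X numeric feature matrix (rows = instances) with column names.
#' @param y numeric response vector, `length(y) == nrow(X)`.
#' @param kind `"binary"` or `"continuous"`; must match the encoding of
#'   `X`.
#' @return a `feature_ranking`: data frame with columns `feature`, `p`,
#'   and `effect` (rank-biserial difference for binary features,
#'   Spearman rho for continuous), rows in rank order.
#' @export
rank_features <- function(X, y, kind = c("binary", "continuous")) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  if (nrow(X) == 0 || ncol(X) == 0) stop("empty feature matrix")
  if (nrow(X) != length(y)) stop("rows(X) != length(y)")
  if (is.null(colnames(X))) stop("X must have column names")
  if (kind == "binary" && any(X != 0 & X != 1))
    stop("kind = 'binary' but X contains values outside {0,1}")

  if (kind == "binary") {
    stats <- binary_feature_stats(X, y)
  } else {
    stats <- continuous_feature_stats(X, y)
  }
  ord <- order(stats$p, -abs(stats$effect), colnames(X), method = "radix")
  structure(data.frame(feature = colnames(X)[ord],
                       p = stats$p[ord],
                       effect = stats$effect[ord],
                       stringsAsFactors = FALSE),
            class = c("feature_ranking", "data.frame"))
}

binary_feature_stats <- function(X, y) {
  p <- numeric(ncol(X))
  effect <- numeric(ncol(X))
  y_has_ties <- anyDuplicated(y) > 0
  for (j in seq_len(ncol(X))) {
    carrier <- X[, j] == 1
    n1 <- sum(carrier)
    n0 <- sum(!carrier)
    if (n1 == 0 || n0 == 0) {       # one-sided group: no information
      p[j] <- 1
      effect[j] <- 0
      next
    }
    use_exact <- max(n1, n0) <= 25 && !y_has_ties
    wt <- suppressWarnings(
      wilcox.test(y[carrier], y[!carrier], alternative = "two.sided",
                  exact = use_exact, correct = TRUE))
    p[j] <- min(wt$p.value, 1)
    # rank-biserial difference: 2 U / (n1 n0) - 1 in [-1, 1]
    effect[j] <- 2 * unname(wt$statistic) / (n1 * n0) - 1
  }
  list(p = p, effect = effect)
}

continuous_feature_stats <- function(X, y) {
  n <- nrow(X)
  ry <- rank(y)
  if (var(ry) == 0) {
    return(list(p = rep(1, ncol(X)), effect = rep(0, ncol(X))))
  }
  RX <- apply(X, 2, rank)
  rho <- suppressWarnings(as.vector(cor(RX, ry)))   # NA for constant columns
  p <- rep(1, ncol(X))
  effect <- rep(0, ncol(X))
  ok <- !is.na(rho)
  if (any(ok)) {
    r <- rho[ok]
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
    tt[abs(r) >= 1] <- Inf * sign(r[abs(r) >= 1])
    p[ok] <- pmin(2 * pt(-abs(tt), df = n - 2), 1)
    effect[ok] <- r
  }
  list(p = p, effect = effect)
}

#' Top k features of a ranking
#'
#' The first `k` names of a [rank_features()] ordering. Subsets are
#' nested: `top_k(r, k)` is always a prefix of `top_k(r, k + 1)`.
#'
#' @param ranking a `feature_ranking`.
#' @param k integer in \[1, p\].
#' @return character vector of `k` feature names.
#' @export
top_k <- function(ranking, k) {
  p <- nrow(ranking)
  if (length(k) != 1 || is.na(k) || k < 1 || k > p)
    stop("k must be a single integer in [1, ", p, "]")
  ranking$feature[seq_len(as.integer(k))]
}
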