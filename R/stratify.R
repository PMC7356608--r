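# Rank-stratified partitioning. Both the external test split and the
# cross-validation folds are built on the ascending ranks of the response
# so that every partition covers the full drug-response range.

round_half_up <- function(x) floor(x + 0.5)

# ascending response order with a deterministic cell-id tie-break
response_order <- function(y, ids) order(y, ids, method = "radix")

#' Rank-stratified external test split
#'
#' Instances are sorted by ascending response (ties broken by cell-id,
#' stable). The global minimum and maximum stay in the training set; the
#' second most extreme values (ranks 2 and m-1) anchor the test set, and
#' the eight remaining test members sit at equidistant interior ranks
#' `round(2 + j (m-3) / 9)` for j = 1..8 (round half away from zero;
#' a rank already taken advances to the next unused interior rank). The
#' test set therefore spans the response range without ever holding the
#' extremes.
#'
#' @param y numeric response vector (log10 IC50), length m >= 45.
#' @param seed integer; recorded in the split object. The split itself
#'   is a deterministic function of `y` and `ids`.
#' @param ids cell-line identifiers used for tie-breaking; defaults to
#'   `names(y)` or, failing that, zero-padded index labels.
#' @param test_size test-set size; 10 is the supported default.
#' @return a `train_test_split`: list with integer `train_idx`,
#'   `test_idx` (positions in `y`), `test_ranks`, and `seed`.
#' @export
make_test_split <- function(y, seed = 0L, ids = NULL, test_size = 10L) {
  m <- length(y)
  if (m < 12)
    stop("impossible split: need at least 12 instances, got ", m)
  if (m < 45)
    stop("ineligible case: the workflow requires at least 45 instances, got ", m)
  if (test_size != 10L)
    stop("only the 10-instance test set is supported")
  ids <- default_ids(y, ids)
  ord <- response_order(y, ids)            # ord[r] = index at ascending rank r

  taken <- c(2L, m - 1L)
  for (j in 1:8) {
    r <- as.integer(round_half_up(2 + j * (m - 3) / 9))
    while (r %in% taken) {
      r <- r + 1L
      if (r > m - 2L) r <- 3L              # wrap within interior ranks
    }
    taken <- c(taken, r)
  }
  test_ranks <- sort(taken)
  test_idx <- ord[test_ranks]
  structure(list(train_idx = sort(setdiff(seq_len(m), test_idx)),
                 test_idx = sort(test_idx),
                 test_ranks = test_ranks,
                 seed = as.integer(seed)),
            class = "train_test_split")
}

#' Rank-stratified five-fold cross-validation assignment
#'
#' Training instances are sorted by ascending response (cell-id
#' tie-break), the ranked list is cut into consecutive blocks of five,
#' and within each block the members are dealt to the five folds by a
#' seeded random permutation (a final partial block is dealt to a seeded
#' random subset of distinct folds). Every fold therefore samples the
#' whole response range and fold sizes differ by at most one.
#'
#' @param y_train numeric response vector of the training set (n >= 10).
#' @param seed integer seed driving the block permutations.
#' @param ids identifiers for tie-breaking; defaults as in
#'   [make_test_split()].
#' @param n_folds number of folds; 5 is the supported default.
#' @return a `fold_assignment`: list with integer vector `fold_of`
#'   (fold label per instance, in input order) and `seed`.
#' @export
make_cv_folds <- function(y_train, seed = 0L, ids = NULL, n_folds = 5L) {
  n <- length(y_train)
  if (n < 2 * n_folds)
    stop("too few training instances (", n, ") for ", n_folds, " folds")
  ids <- default_ids(y_train, ids)
  ord <- response_order(y_train, ids)
  fold_of <- integer(n)
  withr::with_seed(as.integer(seed), {
    nblocks <- ceiling(n / n_folds)
    for (b in seq_len(nblocks)) {
      block <- ord[(n_folds * (b - 1) + 1):min(n_folds * b, n)]
      fold_of[block] <- sample.int(n_folds)[seq_along(block)]
    }
  })
  structure(list(fold_of = fold_of, seed = as.integer(seed),
                 n_folds = as.integer(n_folds)),
            class = "fold_assignment")
}

default_ids <- function(y, ids) {
  if (!is.null(ids)) {
    if (length(ids) != length(y)) stop("ids and y differ in length")
    return(as.character(ids))
  }
  if (!is.null(names(y))) return(names(y))
  sprintf("i%06d", seq_along(y))
}
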