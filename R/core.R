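#' Construct a drug-response case dataset
#'
#' A case couples one drug and cancer type with one omics view of a
#' cell-line panel: a feature matrix `X` (cell lines in rows) and the
#' log10 IC50 response `y`. Binary omics (`SNV`, `CNA`) must be coded
#' strictly in \{0, 1\}; expression (`GEX`) and methylation (`METHY`)
#' matrices are real-valued.
#'
#' @param X numeric matrix, m cell lines by p features, with row and
#'   column names (or supply `cell_ids` / `feature_names`).
#' @param y numeric vector of length m, log10 IC50 per cell line.
#' @param drug,cancer_type character scalars identifying the case.
#' @param omics one of `"SNV"`, `"CNA"`, `"GEX"`, `"METHY"`.
#' @param cell_ids,feature_names identifiers; default to dimnames of `X`.
#' @return An object of class `case_dataset`.
#' @export
case_dataset <- function(X, y, drug, cancer_type, omics,
                         cell_ids = rownames(X),
                         feature_names = colnames(X)) {
  omics <- match.arg(omics, c("SNV", "CNA", "GEX", "METHY"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(cell_ids)) stop("cell_ids are required (row names of X)")
  if (is.null(feature_names)) stop("feature_names are required (column names of X)")
  if (nrow(X) != length(y))
    stop("rows(X) [", nrow(X), "] != length(y) [", length(y), "]")
  if (nrow(X) != length(cell_ids) || ncol(X) != length(feature_names))
    stop("dimension mismatch between X and its identifiers")
  if (anyDuplicated(cell_ids)) stop("duplicated cell_ids")
  if (anyDuplicated(feature_names)) stop("duplicated feature_names")
  if (anyNA(X) || anyNA(y)) stop("missing entries in X or y are not allowed")
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("non-finite entries in X or y are not allowed")
  if (omics_is_binary(omics)) {
    bad <- which(X != 0 & X != 1, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      cols <- unique(feature_names[bad[, 2]])
      stop("binary omics '", omics, "' requires entries in {0,1}; offending feature(s): ",
           paste(utils::head(cols, 5), collapse = ", "))
    }
  }
  rownames(X) <- cell_ids
  colnames(X) <- feature_names
  structure(
    list(X = X, y = as.numeric(y), drug = drug, cancer_type = cancer_type,
         omics = omics, cell_ids = as.character(cell_ids),
         feature_names = as.character(feature_names)),
    class = "case_dataset")
}

#' @export
print.case_dataset <- function(x, ...) {
  cat(sprintf("case_dataset: %s / %s / %s\n  %d cell lines x %d features (%s)\n",
              x$drug, x$cancer_type, x$omics, nrow(x$X), ncol(x$X),
              if (omics_is_binary(x$omics)) "binary" else "continuous"))
  invisible(x)
}

omics_is_binary <- function(omics) omics %in% c("SNV", "CNA")

#' Is a case eligible for the full modeling workflow?
#'
#' Eligibility requires at least 45 response-annotated cell lines, so
#' that removing the 10-cell-line external test set leaves a training
#' set of at least 35.
#'
#' @param dataset a `case_dataset`.
#' @return logical scalar.
#' @export
is_eligible <- function(dataset) length(dataset$y) >= 45L

#' Spearman rank correlation between predictions and observations
#'
#' Computed as the Pearson correlation of the two vectors' mid-ranks
#' (average ranks on ties). Returns `NA_real_` when either vector is
#' constant, where the correlation is undefined; constant model output
#' is handled separately via [is_constant_prediction()].
#'
#' @param pred,obs numeric vectors of equal length (>= 3).
#' @return a value in \[-1, 1\], or `NA_real_` if undefined.
#' @export
spearman_rs <- function(pred, obs) {
  if (length(pred) != length(obs))
    stop("length(pred) [", length(pred), "] != length(obs) [", length(obs), "]")
  if (length(pred) < 3) stop("at least 3 paired values are required")
  if (var(pred) == 0 || var(obs) == 0) return(NA_real_)
  cor(rank(pred), rank(obs))
}

#' Coefficient of determination on an evaluation set
#'
#' `1 - SS_res / SS_tot` with the total sum of squares centered on the
#' mean of the observed values. Unlike a squared correlation this can be
#' negative, when the model predicts worse than the observed mean.
#'
#' @param pred,obs numeric vectors of equal length (>= 2); `obs` must
#'   not be constant.
#' @return a value <= 1.
#' @export
r_squared <- function(pred, obs) {
  if (length(pred) != length(obs))
    stop("length(pred) [", length(pred), "] != length(obs) [", length(obs), "]")
  if (length(pred) < 2) stop("at least 2 paired values are required")
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) stop("observed values are constant; R^2 is undefined")
  1 - sum((obs - pred)^2) / ss_tot
}

#' Convert natural-log IC50 values to log10
#'
#' Elementwise multiplication by log10(e). Response tables consumed by
#' this package carry log10 IC50; this converter is an explicit
#' pre-processing step for sources that report natural logarithms, and
#' is never applied implicitly.
#'
#' @param values numeric vector of natural-log IC50 values.
#' @return numeric vector of log10 IC50 values.
#' @export
natural_log_to_log10 <- function(values) {
  if (anyNA(values) || any(!is.finite(values)))
    stop("non-finite input to natural_log_to_log10")
  values * log10(exp(1))
}

#' Evaluate predictions against observed responses
#'
#' @param pred,obs numeric vectors of equal length.
#' @return a `model_evaluation`: list with `rs` (Spearman), `r2`
#'   (coefficient of determination) and `predictions`.
#' @export
evaluate_predictions <- function(pred, obs) {
  structure(list(rs = spearman_rs(pred, obs),
                 r2 = r_squared(pred, obs),
                 predictions = pred),
            class = "model_evaluation")
}

# ---- delimited-text I/O ----------------------------------------------------

#' Read a case from a feature-matrix file and a response file
#'
#' The matrix file is tab-delimited with a header row of feature names
#' and a first column named `cell_id`; the response file is tab-delimited
#' with columns `cell_id` and `log10_ic50`. Rows are aligned by cell-line
#' identifier, not by file order.
#'
#' @param matrix_path path to the feature matrix (TSV).
#' @param response_path path to the response table (TSV).
#' @param drug,cancer_type,omics case metadata (see [case_dataset()]).
#' @return a validated `case_dataset`.
#' @export
read_case <- function(matrix_path, response_path, drug, cancer_type, omics) {
  mat <- read.delim(matrix_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(mat)[1] != "cell_id")
    stop("matrix file must have 'cell_id' as its first column, found '",
         names(mat)[1], "'")
  resp <- read.delim(response_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "log10_ic50") %in% names(resp)))
    stop("response file must have columns 'cell_id' and 'log10_ic50'")
  ids <- as.character(mat$cell_id)
  missing_resp <- setdiff(ids, as.character(resp$cell_id))
  if (length(missing_resp) > 0)
    stop("cell id(s) missing from response file: ",
         paste(missing_resp, collapse = ", "))
  missing_mat <- setdiff(as.character(resp$cell_id), ids)
  if (length(missing_mat) > 0)
    stop("cell id(s) missing from matrix file: ",
         paste(missing_mat, collapse = ", "))
  X <- as.matrix(mat[, -1, drop = FALSE])
  if (!is.numeric(X)) {
    bad <- names(mat)[-1][!vapply(mat[-1], is.numeric, logical(1))]
    stop("non-numeric matrix column(s): ", paste(bad, collapse = ", "))
  }
  if (anyNA(X))
    stop("missing cells in matrix file (rows ",
         paste(unique(which(is.na(X), arr.ind = TRUE)[, 1]), collapse = ", "), ")")
  rownames(X) <- ids
  y <- resp$log10_ic50[match(ids, as.character(resp$cell_id))]
  case_dataset(X, y, drug = drug, cancer_type = cancer_type, omics = omics)
}

#' Write a case's feature matrix and response table
#'
#' Canonical tab-delimited formatting: UTF-8, header row, cell-line
#' identifier column named `cell_id`, no quoting. `read_case()` followed
#' by `write_case()` reproduces a canonically formatted input byte for
#' byte.
#'
#' @param dataset a `case_dataset`.
#' @param matrix_path,response_path output paths; either may be `NULL`
#'   to skip that file.
#' @return `dataset`, invisibly.
#' @export
write_case <- function(dataset, matrix_path = NULL, response_path = NULL) {
  if (!is.null(matrix_path)) {
    df <- data.frame(cell_id = dataset$cell_ids, dataset$X,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, matrix_path, sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
  }
  if (!is.null(response_path)) {
    df <- data.frame(cell_id = dataset$cell_ids, log10_ic50 = dataset$y,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, response_path, sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(dataset)
}

# ---- seed management -------------------------------------------------------

#' Derive a reproducible sub-seed from a master seed
#'
#' A counter-based linear-congruential scheme: the master seed is
#' advanced `index` times through the multiplicative generator
#' s -> (16807 s + 12345) mod (2^31 - 1). Every stage of the workflow
#' (split, fold assignment, per-fold booster, final ensemble seeds,
#' y-randomization) draws its own sub-seed from the invocation's master
#' seed, so each component is independently reproducible.
#'
#' @param master integer master seed.
#' @param index positive integer counter.
#' @return an integer seed in \[0, 2^31 - 2\].
#' @export
derive_seed <- function(master, index) {
  stopifnot(length(master) == 1, length(index) == 1, index >= 1)
  s <- as.double(master) %% 2147483647
  for (i in seq_len(index)) s <- (s * 16807 + 12345) %% 2147483647
  as.integer(s)
}
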