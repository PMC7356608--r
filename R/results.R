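# JSON result documents: one per case, carrying the split, fold
# assignment, per-k complexity profiles, the selection, final test-set
# evaluations, classification, and every seed used, under a versioned
# schema with a run manifest.

omc_schema_version <- 1L

#' Convert a case result to a plain (JSON-ready) list
#'
#' @param result a `case_result`.
#' @param timestamp include a creation timestamp in the manifest
#'   (default `TRUE`; disable for byte-stable documents).
#' @return a nested list mirroring the result JSON schema.
#' @export
case_result_to_list <- function(result, timestamp = TRUE) {
  manifest <- list(tool = "omcdr",
                   version = as.character(packageVersion("omcdr")),
                   schema_version = omc_schema_version,
                   master_seed = result$seeds$master)
  if (timestamp) manifest$created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  eval_to_list <- function(ev) {
    if (is.null(ev)) return(NULL)
    list(rs = ev$rs, r2 = ev$r2, predictions = as.list(ev$predictions))
  }
  list(manifest = manifest,
       case_id = result$case_id,
       m = result$m, n = result$n, p = result$p,
       rs_min = result$rs_min,
       split = result$split,
       fold_of = as.list(result$fold_of),
       profiles = lapply(result$selection$profiles, function(pr) {
         list(k = pr$k, fold_rs = pr$fold_rs,
              constant_flagged = pr$constant_flagged,
              median_rs = pr$median_rs, passes = pr$passes)
       }),
       k_opt = if (is.na(result$selection$k_opt)) NULL
               else result$selection$k_opt,
       selected_features = result$selection$selected_features,
       evaluation_omc = eval_to_list(result$evaluation_omc),
       evaluation_all = eval_to_list(result$evaluation_all),
       classification = result$classification,
       seeds = result$seeds,
       config = unclass(result$config),
       mode = result$mode)
}

#' Write a case result document to JSON
#'
#' @param result a `case_result`.
#' @param path output path.
#' @param timestamp see [case_result_to_list()].
#' @return `path`, invisibly.
#' @export
write_case_result <- function(result, path, timestamp = TRUE) {
  jsonlite::write_json(case_result_to_list(result, timestamp = timestamp),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a case result document
#'
#' Rejects documents written under a newer schema than this package
#' understands.
#'
#' @param path path to a result JSON written by [write_case_result()].
#' @return a `case_result`-compatible list usable by
#'   [complementarity()].
#' @export
read_case_result <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  sv <- doc$manifest$schema_version
  if (is.null(sv) || sv > omc_schema_version)
    stop("result document at '", path, "' has schema version ",
         if (is.null(sv)) "<missing>" else sv,
         "; this package reads versions <= ", omc_schema_version)
  k_opt <- if (is.null(doc$k_opt)) NA_integer_ else as.integer(doc$k_opt)
  eval_from <- function(ev) {
    if (is.null(ev) || length(ev) == 0) return(NULL)
    list(rs = ev$rs, r2 = ev$r2, predictions = unlist(ev$predictions))
  }
  structure(
    list(case_id = doc$case_id, m = doc$m, n = doc$n, p = doc$p,
         rs_min = doc$rs_min, split = doc$split, fold_of = unlist(doc$fold_of),
         selection = list(k_opt = k_opt,
                          selected_features = as.character(doc$selected_features),
                          profiles = doc$profiles),
         evaluation_omc = eval_from(doc$evaluation_omc),
         evaluation_all = eval_from(doc$evaluation_all),
         classification = doc$classification,
         seeds = doc$seeds, config = doc$config, mode = doc$mode),
    class = "case_result")
}
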