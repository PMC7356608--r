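# Construction of case feature matrices from pre-processed
# pharmacogenomics tables exported to delimited text: binary mutation
# (SNV) and copy-number (CNA) event matrices, and filtered continuous
# expression / methylation matrices. Feature sets are restricted to
# what is observed in both cell lines and primary tumors, keeping
# features clinically relevant.

#' Build a binary mutation (SNV) feature matrix
#'
#' One column per whitelisted gene; a cell line gets 1 for a gene iff
#' any variant row links the two, 0 (wild type) otherwise. Variant
#' classes (missense, nonsense, ...) are deliberately pooled: the binary
#' encoding records only mutated vs wild-type status, and no
#' driver/passenger distinction is made.
#'
#' @param variants data frame with columns `cell_id`, `gene` (and
#'   optionally `variant_class`, ignored here but kept by parsers).
#' @param gene_whitelist non-empty character vector of genes to encode
#'   (typically the census of cancer genes mutated in both cell lines
#'   and primary tumors).
#' @param cell_ids cell lines to encode (matrix row order).
#' @return binary matrix, `length(cell_ids)` by `length(gene_whitelist)`.
#' @export
build_snv_matrix <- function(variants, gene_whitelist, cell_ids) {
  if (length(gene_whitelist) == 0) stop("empty gene whitelist")
  if (anyNA(variants$cell_id) || anyNA(variants$gene))
    stop("missing cell_id or gene in variant table")
  unknown <- !(variants$cell_id %in% cell_ids)
  if (any(unknown)) {
    warning("dropping ", sum(unknown),
            " variant row(s) for cell line(s) not in cell_ids: ",
            paste(utils::head(unique(variants$cell_id[unknown]), 5),
                  collapse = ", "))
    variants <- variants[!unknown, , drop = FALSE]
  }
  X <- matrix(0, nrow = length(cell_ids), ncol = length(gene_whitelist),
              dimnames = list(cell_ids, gene_whitelist))
  hit <- variants$gene %in% gene_whitelist
  if (any(hit))
    X[cbind(match(variants$cell_id[hit], cell_ids),
            match(variants$gene[hit], gene_whitelist))] <- 1
  X
}

#' Intersect cell-line features with primary-tumor features
#'
#' Features observed only in cell lines are discarded as less relevant
#' for application to patient tumors. The cell-line order is preserved.
#'
#' @param cell_feature_ids features observed in cell lines.
#' @param tumor_feature_ids features observed in primary tumors.
#' @return `cell_feature_ids` restricted to those also present in
#'   `tumor_feature_ids`, in their original order.
#' @export
intersect_with_primary <- function(cell_feature_ids, tumor_feature_ids) {
  cell_feature_ids[cell_feature_ids %in% tumor_feature_ids]
}

#' Build a binary copy-number alteration (CNA) feature matrix
#'
#' Copy-number segments are cancer-type specific: the columns are the
#' segments observed for `cancer_type` in cell lines, restricted to
#' those also altered in primary tumors. An entry is 1 iff the segment
#' table marks that segment altered in that cell line.
#'
#' @param segments data frame with columns `cancer_type`, `region_id`,
#'   `cell_id`, `altered` (logical or 0/1).
#' @param tumor_region_ids segment identifiers altered in primary tumors.
#' @param cancer_type the cancer type to build features for.
#' @param cell_ids cell lines to encode (matrix row order).
#' @return binary matrix, cells by post-intersection segments.
#' @export
build_cna_matrix <- function(segments, tumor_region_ids, cancer_type, cell_ids) {
  if (any(!nzchar(segments$region_id)))
    stop("empty region_id in segment table")
  seg <- segments[segments$cancer_type == cancer_type, , drop = FALSE]
  if (nrow(seg) == 0)
    stop("no segments recorded for cancer type '", cancer_type, "'")
  regions <- intersect_with_primary(unique(seg$region_id), tumor_region_ids)
  if (length(regions) == 0)
    stop("no segment of cancer type '", cancer_type,
         "' is shared with primary tumors")
  X <- matrix(0, nrow = length(cell_ids), ncol = length(regions),
              dimnames = list(cell_ids, regions))
  hit <- seg$region_id %in% regions & as.logical(seg$altered) &
    seg$cell_id %in% cell_ids
  if (any(hit))
    X[cbind(match(seg$cell_id[hit], cell_ids),
            match(seg$region_id[hit], regions))] <- 1
  X
}

#' Build a filtered continuous feature matrix (expression or methylation)
#'
#' Restricts a feature-by-cell value table to a requested feature list
#' and cell-line set, optionally translating feature identifiers through
#' a namespace map (e.g. gene symbol to array identifier). Values pass
#' through unchanged — inputs are expected already normalized (RMA
#' intensities, or averaged methylation beta-values). Requested features
#' that cannot be mapped or found are dropped and reported rather than
#' failing, mirroring the manual curation such identifier mismatches
#' require; a missing cell line is an error.
#'
#' @param values numeric matrix, features in rows (row names = feature
#'   ids in the table's namespace), cells in columns.
#' @param keep_features requested feature identifiers.
#' @param id_map optional data frame with columns `from`, `to` mapping
#'   requested identifiers to the table's namespace.
#' @param cell_ids cells to keep (output row order).
#' @param beta check that all kept values lie in \[0, 1\]
#'   (methylation beta-value semantics); default `FALSE`.
#' @return list with `X` (cells by kept features; columns named by the
#'   requested identifiers) and `unmapped` (character vector of dropped
#'   requested features).
#' @export
build_continuous_matrix <- function(values, keep_features, id_map = NULL,
                                    cell_ids, beta = FALSE) {
  if (length(keep_features) == 0) stop("empty feature list")
  values <- as.matrix(values)
  if (is.null(id_map)) {
    table_ids <- keep_features
  } else {
    table_ids <- id_map$to[match(keep_features, id_map$from)]
  }
  found <- !is.na(table_ids) & table_ids %in% rownames(values)
  unmapped <- keep_features[!found]
  if (all(!found))
    stop("none of the requested features could be mapped")
  missing_cells <- setdiff(cell_ids, colnames(values))
  if (length(missing_cells) > 0)
    stop("cell line(s) missing from value table: ",
         paste(utils::head(missing_cells, 5), collapse = ", "))
  X <- t(values[table_ids[found], cell_ids, drop = FALSE])
  colnames(X) <- keep_features[found]
  if (beta && (min(X) < 0 || max(X) > 1))
    stop("beta-values outside [0, 1] in value table")
  list(X = X, unmapped = unmapped)
}
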