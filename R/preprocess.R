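#' @title Expression preprocessing
#' @description Global scaling to a target mean intensity, intensity
#'   flooring, low-signal filtering, ORF selection and mean-normalized
#'   profiles for a genes x samples intensity matrix.
#' @name preprocess
NULL

check_expression_matrix <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("expression data must be a numeric matrix (genes x samples)")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(mat))) stop("duplicate gene ids in matrix")
  if (anyDuplicated(colnames(mat))) stop("duplicate sample ids in matrix")
  if (any(!is.finite(mat)) || any(mat < 0))
    stop("expression values must be finite and non-negative")
  invisible(mat)
}

check_sample_metadata <- function(meta, mat = NULL) {
  need <- c("sample_id", "growth_rate", "mode", "replicate")
  if (!all(need %in% names(meta)))
    stop("sample metadata must have columns: ", paste(need, collapse = ", "))
  if (any(meta$growth_rate <= 0)) stop("growth_rate must be positive")
  if (!all(meta$mode %in% c("chemostat", "retentostat")))
    stop("mode must be 'chemostat' or 'retentostat'")
  if (!is.null(mat)) {
    missing <- setdiff(colnames(mat), meta$sample_id)
    if (length(missing))
      stop("samples absent from metadata: ", paste(missing, collapse = ", "))
  }
  invisible(meta)
}

#' Globally scale each array to a target mean intensity
#'
#' Multiplies each sample (column) by `target / mean(column)` so that the
#' average signal over all gene features equals `target`. This is the
#' classic global-scaling normalization for single-channel arrays; it
#' assumes the overall mRNA pool is comparable between samples (checked
#' downstream via housekeeping-gene stability, [housekeeping_cv()]).
#'
#' @param mat genes x samples numeric matrix.
#' @param target target mean intensity (default 300).
#' @return the scaled matrix; every column mean equals `target`.
#' @export
global_scale <- function(mat, target = 300) {
  check_expression_matrix(mat)
  m <- colMeans(mat)
  if (any(m == 0))
    stop("cannot scale zero-mean sample(s): ",
         paste(colnames(mat)[m == 0], collapse = ", "))
  sweep(mat, 2, target / m, `*`)
}

#' Floor low intensities and drop never-expressed genes
#'
#' Values below `floor` are raised to `floor`; genes whose maximum across
#' all samples is below `min_max` are discarded as never reliably
#' expressed.
#'
#' @param mat genes x samples numeric matrix (already scaled).
#' @param floor intensity floor (default 12).
#' @param min_max minimum across-sample maximum to keep a gene (default 20).
#' @return list with `matrix` (floored, filtered) and `removed` (ids).
#' @export
floor_and_filter <- function(mat, floor = 12, min_max = 20) {
  check_expression_matrix(mat)
  keep <- apply(mat, 1, max) >= min_max
  removed <- rownames(mat)[!keep]
  out <- mat[keep, , drop = FALSE]
  out[out < floor] <- floor
  if (nrow(out) == 0) warning("all genes removed by the min-max filter")
  list(matrix = out, removed = removed)
}

#' Restrict the matrix to a list of ORFs
#'
#' Keeps only rows whose ids appear in `orf_list`, preserving the matrix
#' row order (used to go from all array features to verified open
#' reading frames).
#'
#' @param mat genes x samples numeric matrix.
#' @param orf_list character vector of ORF ids.
#' @return the row-subset matrix.
#' @export
select_orfs <- function(mat, orf_list) {
  check_expression_matrix(mat)
  if (length(orf_list) == 0) stop("orf_list is empty")
  keep <- rownames(mat) %in% orf_list
  if (!any(keep)) stop("no matrix rows overlap the ORF list")
  mat[keep, , drop = FALSE]
}

#' Condition table from sample metadata
#'
#' One condition per (mode, growth rate, retentostat day), ordered by
#' increasing growth rate (retentostat time points first), the order in
#' which growth-rate profiles are displayed.
#' @param meta sample metadata data.frame.
#' @return data.frame `condition`, `mode`, `growth_rate`, `time_d`.
#' @export
condition_table <- function(meta) {
  check_sample_metadata(meta)
  if (is.null(meta$time_d)) meta$time_d <- NA_real_
  key <- paste(meta$mode, meta$growth_rate, meta$time_d, sep = "|")
  first <- !duplicated(key)
  cond <- data.frame(condition = character(sum(first)),
                     mode = meta$mode[first],
                     growth_rate = meta$growth_rate[first],
                     time_d = meta$time_d[first],
                     stringsAsFactors = FALSE)
  cond$condition <- ifelse(cond$mode == "retentostat",
                           sprintf("retentostat_d%g", cond$time_d),
                           sprintf("chemostat_mu%g", cond$growth_rate))
  cond[order(cond$growth_rate, cond$condition), , drop = FALSE]
}

#' Mean-normalized expression profiles
#'
#' Optionally averages replicates into one column per condition, then
#' divides each gene's profile by its across-condition mean so that
#' profiles describe shape, not level (row means become 1). Mean
#' normalization makes profiles of differently expressed genes directly
#' comparable and is the representation used for clustering.
#'
#' @param mat genes x samples numeric matrix.
#' @param meta sample metadata with `sample_id`, `growth_rate`, `mode`,
#'   `replicate` and optional `time_d`.
#' @param collapse_replicates average replicate columns per condition
#'   (default TRUE).
#' @return genes x conditions matrix with row means 1; the matching
#'   [condition_table()] is attached as attribute `"conditions"`.
#' @export
mean_normalize_profiles <- function(mat, meta, collapse_replicates = TRUE) {
  check_expression_matrix(mat)
  check_sample_metadata(meta, mat)
  meta <- meta[match(colnames(mat), meta$sample_id), , drop = FALSE]
  if (collapse_replicates) {
    cond <- condition_table(meta)
    if (is.null(meta$time_d)) meta$time_d <- NA_real_
    key <- ifelse(meta$mode == "retentostat",
                  sprintf("retentostat_d%g", meta$time_d),
                  sprintf("chemostat_mu%g", meta$growth_rate))
    prof <- vapply(cond$condition, function(cn)
      rowMeans(mat[, key == cn, drop = FALSE]), numeric(nrow(mat)))
    if (!is.matrix(prof))   # single-gene matrix: vapply drops to a vector
      prof <- matrix(prof, nrow = nrow(mat),
                     dimnames = list(rownames(mat), cond$condition))
    rownames(prof) <- rownames(mat)
  } else {
    cond <- data.frame(condition = colnames(mat), mode = meta$mode,
                       growth_rate = meta$growth_rate,
                       time_d = if (is.null(meta$time_d)) NA_real_ else meta$time_d,
                       stringsAsFactors = FALSE)
    prof <- mat
  }
  rm <- rowMeans(prof)
  if (any(rm <= 0))
    stop("gene(s) with non-positive mean cannot be mean-normalized: ",
         paste(utils::head(rownames(prof)[rm <= 0]), collapse = ", "))
  prof <- prof / rm
  attr(prof, "conditions") <- cond
  prof
}

#' Coefficient of variation of housekeeping genes
#'
#' Per-gene CV (sample standard deviation over mean) across all arrays;
#' stable housekeeping genes (CV below ~0.20) indicate that global
#' scaling was safe, i.e. the mRNA pool did not change massively.
#'
#' @param mat genes x samples numeric matrix.
#' @param gene_ids housekeeping gene ids, all present in the matrix.
#' @return named numeric vector of CVs.
#' @export
housekeeping_cv <- function(mat, gene_ids) {
  check_expression_matrix(mat)
  missing <- setdiff(gene_ids, rownames(mat))
  if (length(missing))
    stop("housekeeping gene(s) not in matrix: ", paste(missing, collapse = ", "))
  sub <- mat[gene_ids, , drop = FALSE]
  apply(sub, 1, stats::sd) / rowMeans(sub)
}
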