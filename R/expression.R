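# Normalization (median-of-ratios, CPM, SRPBM), low-expression filtering,
# tissue-wise ECDF scores and the pan-tissue circRNA-miRNA co-expression
# score.

#' Median-of-ratios count normalization
#'
#' Size-factor normalization as used for bulk RNA-seq count matrices: each
#' sample's size factor is the median, over features with all-positive
#' counts, of that sample's count divided by the feature's geometric mean
#' across samples. Each column is then divided by its size factor. Only the
#' size-factor scaling is performed (no dispersion estimation or design),
#' since only the relative scaling of samples affects the downstream ECDF
#' scores.
#'
#' @param counts A [count_panel()] with at least two samples.
#' @return An [expression_panel()] of normalized counts, with the size
#'   factors attached as attribute `size_factors`.
#' @export
median_of_ratios_normalize <- function(counts) {
  stopifnot(inherits(counts, "count_panel"))
  m <- counts$counts
  if (ncol(m) < 2L)
    stop("median_of_ratios_normalize: need >= 2 samples")
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos))
    stop("median_of_ratios_normalize: no feature has positive counts in ",
         "every sample; consider cpm() instead")
  ref <- exp(rowMeans(log(m[all_pos, , drop = FALSE])))
  sf <- apply(m[all_pos, , drop = FALSE] / ref, 2L, stats::median)
  norm <- sweep(m, 2L, sf, "/")
  out <- expression_panel(norm, counts$feature_class,
                          unit_label = "median-of-ratios normalized counts")
  attr(out, "size_factors") <- sf
  out
}

#' Counts per million
#'
#' `value = count / column_sum * 1e6`. Used for miRNA and linear-RNA (gene)
#' expression reporting.
#'
#' @param counts A [count_panel()].
#' @return An [expression_panel()] in CPM.
#' @export
cpm <- function(counts) {
  stopifnot(inherits(counts, "count_panel"))
  m <- counts$counts
  libsize <- colSums(m)
  if (any(libsize == 0))
    stop("cpm: zero column sum for sample(s): ",
         paste(colnames(m)[libsize == 0], collapse = ", "))
  expression_panel(sweep(m, 2L, libsize, "/") * 1e6,
                   counts$feature_class, unit_label = "CPM")
}

#' Spliced reads per billion mapped reads
#'
#' circRNA expression from back-splicing (BS) junction reads:
#' `value = junction_count / total_mapped_reads * 1e9`. The denominator is
#' the per-sample total mapped read count of the originating library, not
#' the junction-count column sum, so it must be supplied on the panel.
#'
#' @param bs_junction_counts A [count_panel()] of BS-junction read counts
#'   with `total_mapped` set for every sample.
#' @return An [expression_panel()] in SRPBM.
#' @export
srpbm <- function(bs_junction_counts) {
  stopifnot(inherits(bs_junction_counts, "count_panel"))
  tm <- bs_junction_counts$total_mapped
  m <- bs_junction_counts$counts
  if (is.null(tm))
    stop("srpbm: per-sample total mapped reads are required")
  missing <- setdiff(colnames(m), names(tm))
  if (length(missing))
    stop("srpbm: missing total mapped reads for sample(s): ",
         paste(missing, collapse = ", "))
  expression_panel(sweep(m, 2L, tm[colnames(m)], "/") * 1e9,
                   bs_junction_counts$feature_class, unit_label = "SRPBM")
}

#' Filter low-expressing features
#'
#' Two-stage filter applied to genes and miRNAs before scoring: a feature is
#' retained when its total raw count is at least `min_total_count` and its
#' mean normalized value is at least `min_mean_norm` (features failing either
#' bound, i.e. strictly below it, are dropped).
#'
#' @param counts A [count_panel()] of raw counts.
#' @param normalized An [expression_panel()] over the same features.
#' @param min_total_count Minimum total raw count (default 10).
#' @param min_mean_norm Minimum mean normalized value (default 10).
#' @return Character vector of retained feature ids, in panel order.
#' @export
filter_low_expression <- function(counts, normalized,
                                  min_total_count = 10, min_mean_norm = 10) {
  stopifnot(inherits(counts, "count_panel"),
            inherits(normalized, "expression_panel"))
  if (!identical(sort(rownames(counts$counts)),
                 sort(rownames(normalized$values))))
    stop("filter_low_expression: feature sets of counts and normalized ",
         "panels differ")
  total <- rowSums(counts$counts)
  mean_norm <- rowMeans(normalized$values)[rownames(counts$counts)]
  keep <- total >= min_total_count & mean_norm >= min_mean_norm
  rownames(counts$counts)[keep]
}

#' Tissue-wise ECDF expression scores
#'
#' Per tissue, features with zero expression are excluded; each expressed
#' feature is scored by the empirical cumulative distribution function of
#' the expressed values evaluated at its own value:
#' `score = #(expressed values <= own value) / #(expressed values)`.
#' Scores therefore lie in (0, 1]; the (tied-)maximal expressed feature of a
#' tissue scores exactly 1, and ties share the higher score
#' (right-continuous ECDF). Tissues with no expressed feature are omitted
#' with a warning.
#'
#' @param panel An [expression_panel()] of per-tissue mean normalized
#'   expression (replicates already averaged into one column per tissue).
#' @return A data.frame of class `tissue_score_table` with columns
#'   `feature_id`, `tissue_id`, `score`, one row per expressed
#'   feature-tissue pair.
#' @export
tissue_ecdf_scores <- function(panel) {
  stopifnot(inherits(panel, "expression_panel"))
  v <- panel$values
  out <- vector("list", ncol(v))
  for (j in seq_len(ncol(v))) {
    x <- setNames(v[, j], rownames(v))
    expressed <- x > 0
    if (!any(expressed)) {
      warning("tissue_ecdf_scores: tissue '", colnames(v)[j],
              "' has no expressed feature; omitted")
      next
    }
    xe <- x[expressed]
    # right-continuous ECDF at own value: rank by "count <= x" / n
    score <- stats::ecdf(xe)(xe)
    out[[j]] <- data.frame(feature_id = names(xe),
                           tissue_id = colnames(v)[j],
                           score = score,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    stop("tissue_ecdf_scores: no tissue has any expressed feature")
  rownames(res) <- NULL
  class(res) <- c("tissue_score_table", "data.frame")
  res
}

#' Pan-tissue circRNA-miRNA co-expression score
#'
#' For each (circRNA, miRNA) pair the per-tissue score is the minimum of the
#' two features' ECDF scores in that tissue; the final score is the maximum
#' of the per-tissue scores over all tissues in which both are expressed.
#' A high score therefore certifies that both partners are relatively highly
#' expressed in at least one common tissue. Pairs with no shared expressed
#' tissue score 0.
#'
#' @param circ_scores,mir_scores `tissue_score_table`s from
#'   [tissue_ecdf_scores()] for the circRNA and miRNA panels.
#' @param pairs Optional two-column data.frame (`circ_id`, `mir_id`)
#'   restricting which pairs are scored; by default all circRNA x miRNA
#'   combinations present in the two tables are scored.
#' @return An [interaction_table()] with edge type `"circ-mir"` and one
#'   criterion column `S_exp`.
#' @export
coexpression_score <- function(circ_scores, mir_scores, pairs = NULL) {
  stopifnot(is.data.frame(circ_scores), is.data.frame(mir_scores))
  circ_ids <- unique(circ_scores$feature_id)
  mir_ids <- unique(mir_scores$feature_id)
  tissues <- union(unique(circ_scores$tissue_id), unique(mir_scores$tissue_id))
  # dense score matrices with 0 = not expressed in that tissue
  cmat <- matrix(0, length(circ_ids), length(tissues),
                 dimnames = list(circ_ids, tissues))
  cmat[cbind(match(circ_scores$feature_id, circ_ids),
             match(circ_scores$tissue_id, tissues))] <- circ_scores$score
  mmat <- matrix(0, length(mir_ids), length(tissues),
                 dimnames = list(mir_ids, tissues))
  mmat[cbind(match(mir_scores$feature_id, mir_ids),
             match(mir_scores$tissue_id, tissues))] <- mir_scores$score
  if (is.null(pairs)) {
    pairs <- expand.grid(circ_id = circ_ids, mir_id = mir_ids,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("circ_id", "mir_id") %in% names(pairs)))
    pairs <- pairs[pairs$circ_id %in% circ_ids & pairs$mir_id %in% mir_ids, ,
                   drop = FALSE]
  }
  score <- numeric(nrow(pairs))
  ci <- match(pairs$circ_id, circ_ids)
  mi <- match(pairs$mir_id, mir_ids)
  # max over tissues of min(circ, mir); zeros (unexpressed) never win the max
  # unless no tissue is shared, in which case the score is exactly 0
  for (j in seq_along(tissues)) {
    score <- pmax(score, pmin(cmat[ci, j], mmat[mi, j]))
  }
  interaction_table(pairs$circ_id, pairs$mir_id,
                    criteria = list(S_exp = score), edge_type = "circ-mir")
}
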