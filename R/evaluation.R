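# Ranking-method comparison: order edges by a chosen score and measure
# precision/recall of a reference circRNA list among the distinct circRNAs
# appearing in the top-n edges.

#' Order interaction edges by a ranking method
#'
#' Supported methods: `"pareto"` (the combined Pareto score), `"nMRE"`
#' (raw MRE count) and `"nMRE_per_kb"` (length-normalized MRE count).
#' Edges are sorted by descending score with ties broken deterministically
#' by (source_id, target_id).
#'
#' @param table A data.frame of edges carrying the required score column:
#'   `pareto_score` for `"pareto"`, `n_mre` for `"nMRE"`, `mre_per_kb` for
#'   `"nMRE_per_kb"`.
#' @param method Ranking method.
#' @return The table reordered, best edge first.
#' @export
rank_edges <- function(table, method = c("pareto", "nMRE", "nMRE_per_kb")) {
  method <- match.arg(method)
  col <- switch(method, pareto = "pareto_score", nMRE = "n_mre",
                nMRE_per_kb = "mre_per_kb")
  if (!col %in% names(table))
    stop("rank_edges: method '", method, "' needs column '", col, "'")
  out <- table[order(-table[[col]], table$source_id, table$target_id), ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Precision/recall curves of reference circRNAs among top-n edges
#'
#' For each ranking and each n in 1..n_max, the distinct circRNAs
#' (source ids) among the top-n edges are intersected with the reference
#' list: `recall = |intersection| / |reference|`,
#' `precision = |intersection| / |distinct circRNAs in top-n|`.
#'
#' @param rankings Named list of ordered edge tables (best first), e.g.
#'   from [rank_edges()].
#' @param reference Character vector of "known" circRNA ids.
#' @param n_max Largest top-n to evaluate (capped at the number of edges).
#' @return A data.frame of class `ranking_comparison` with columns
#'   `method`, `n`, `recall`, `precision`.
#' @export
precision_recall_curves <- function(rankings, reference, n_max) {
  reference <- unique(as.character(reference))
  if (!length(reference)) stop("precision_recall_curves: empty reference")
  if (is.null(names(rankings)) || !length(rankings))
    stop("precision_recall_curves: rankings must be a named list")
  out <- lapply(names(rankings), function(nm) {
    rk <- rankings[[nm]]
    nn <- min(n_max, nrow(rk))
    src <- rk$source_id[seq_len(nn)]
    first_seen <- !duplicated(src)
    n_distinct <- cumsum(first_seen)
    hit_new <- first_seen & src %in% reference
    n_hit <- cumsum(hit_new)
    data.frame(method = nm, n = seq_len(nn),
               recall = n_hit / length(reference),
               precision = n_hit / pmax(n_distinct, 1L),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("ranking_comparison", "data.frame")
  res
}
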