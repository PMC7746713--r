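# Functional annotation of an individual circRNA: propagate Pareto scores
# through its miRNAs to genes, assess per-gene significance by permuting
# the miRNA subset, and test pathway over-representation of the
# significant genes.

#' Select the miRNA set of a circRNA
#'
#' The miRNAs eligible to carry signal from a circRNA to genes are those
#' with a positive circRNA-miRNA Pareto score. Three selection modes are
#' offered: all such miRNAs, those at or above a score threshold
#' (`top_score`), or the `top_n` highest-scoring (ties broken by id).
#'
#' @param circ_id circRNA identifier.
#' @param ranking Scored circ-mir ranking from [pareto_rank()].
#' @param mode One of `"all"`, `"top_score"`, `"top_n"`.
#' @param top_score Score threshold for `mode = "top_score"` (inclusive,
#'   `>=`); e.g. 0.95 keeps only near-front partners.
#' @param top_n Number of partners for `mode = "top_n"`.
#' @return Character vector of miRNA ids, ordered by decreasing score then
#'   id.
#' @export
mirna_set_for_circ <- function(circ_id, ranking,
                               mode = c("all", "top_score", "top_n"),
                               top_score = 0.95, top_n = 10L) {
  mode <- match.arg(mode)
  stopifnot("pareto_score" %in% names(ranking))
  sub <- ranking[ranking$source_id == circ_id & ranking$pareto_score > 0, ,
                 drop = FALSE]
  if (!nrow(sub))
    stop("mirna_set_for_circ: no ceRNA edges for circRNA '", circ_id, "'")
  sub <- sub[order(-sub$pareto_score, sub$target_id), , drop = FALSE]
  ids <- sub$target_id
  switch(mode,
         all = ids,
         top_score = ids[sub$pareto_score >= top_score],
         top_n = utils::head(ids, top_n))
}

#' Build the gene x miRNA Pareto score matrix
#'
#' @param mir_gene_ranking Scored mir-gene ranking from [pareto_rank()]
#'   (source = miRNA, target = gene).
#' @param mirna_ids Optional miRNA universe (columns); default all miRNAs
#'   in the ranking.
#' @param gene_ids Optional gene universe (rows); default all genes in the
#'   ranking.
#' @return Numeric matrix, genes x miRNAs, of Pareto scores; absent pairs
#'   are 0.
#' @export
mir_gene_score_matrix <- function(mir_gene_ranking, mirna_ids = NULL,
                                  gene_ids = NULL) {
  stopifnot("pareto_score" %in% names(mir_gene_ranking))
  if (is.null(mirna_ids)) mirna_ids <- sort(unique(mir_gene_ranking$source_id))
  if (is.null(gene_ids)) gene_ids <- sort(unique(mir_gene_ranking$target_id))
  m <- matrix(0, length(gene_ids), length(mirna_ids),
              dimnames = list(gene_ids, mirna_ids))
  keep <- mir_gene_ranking$source_id %in% mirna_ids &
    mir_gene_ranking$target_id %in% gene_ids
  sub <- mir_gene_ranking[keep, , drop = FALSE]
  m[cbind(match(sub$target_id, gene_ids), match(sub$source_id, mirna_ids))] <-
    sub$pareto_score
  m
}

#' circRNA-gene association scores
#'
#' For a circRNA c and its selected miRNA set M_k, the association score of
#' gene g is the inner product of the circ-mir score vector with the
#' gene's row of the mir-gene score matrix:
#' `S(c, g) = sum_i S(c, m_i) * S(m_i, g)`. Genes targeted by none of the
#' selected miRNAs score 0.
#'
#' @param circ_mir_scores Named numeric vector of circ-mir Pareto scores
#'   for the miRNAs in M_k (names = miRNA ids, all > 0).
#' @param score_matrix Gene x miRNA score matrix from
#'   [mir_gene_score_matrix()]; miRNAs of M_k absent from its columns
#'   contribute 0.
#' @return Named numeric vector of gene scores (one per matrix row).
#' @export
gene_scores <- function(circ_mir_scores, score_matrix) {
  if (!length(circ_mir_scores))
    stop("gene_scores: empty miRNA set")
  if (is.null(names(circ_mir_scores)))
    stop("gene_scores: circ_mir_scores must be named by miRNA id")
  cols <- match(names(circ_mir_scores), colnames(score_matrix))
  v <- circ_mir_scores[!is.na(cols)]
  if (!length(v)) return(setNames(numeric(nrow(score_matrix)),
                                  rownames(score_matrix)))
  sub <- score_matrix[, cols[!is.na(cols)], drop = FALSE]
  drop(sub %*% v)
}

#' Permutation p-values for circRNA-gene scores
#'
#' The null distribution of each gene score is approximated by redrawing
#' the miRNA subset: each of N iterations samples k miRNAs uniformly
#' without replacement from the full miRNA universe, substitutes their
#' columns of the full gene x miRNA score matrix while keeping the observed
#' circ-mir score vector fixed, and recomputes the gene scores. The
#' p-value of gene g is `(#(null >= observed) + 1) / (N + 1)`, so p is
#' never below `1/(N+1)` and a gene with observed score 0 has p = 1.
#'
#' @param observed Named numeric vector of observed gene scores from
#'   [gene_scores()].
#' @param circ_mir_scores The observed circ-mir score vector (length k).
#' @param full_matrix Gene x miRNA score matrix over the FULL miRNA
#'   universe (all miRNAs with any positive mir-gene score).
#' @param n_perm Number of permutations N (default 10000).
#' @param seed Random seed; mandatory for reproducibility.
#' @return A data.frame of class `gene_score_vector` with columns
#'   `gene_id`, `score`, `p_value`, `n_permutations`.
#' @export
permutation_pvalues <- function(observed, circ_mir_scores, full_matrix,
                                n_perm = 10000L, seed) {
  if (missing(seed) || is.null(seed))
    stop("permutation_pvalues: a seed is required")
  if (n_perm < 1L) stop("permutation_pvalues: n_perm must be >= 1")
  k <- length(circ_mir_scores)
  n_univ <- ncol(full_matrix)
  if (k > n_univ)
    stop("permutation_pvalues: k = ", k, " exceeds miRNA universe size ",
         n_univ)
  if (!identical(names(observed), rownames(full_matrix)))
    observed <- observed[rownames(full_matrix)]
  v <- unname(circ_mir_scores)
  exceed <- integer(nrow(full_matrix))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (i in seq_len(n_perm)) {
    # a draw is a k-subset; columns enter in index order so the null
    # depends only on which miRNAs are drawn, not on a random assignment
    idx <- sort(sample.int(n_univ, k))
    null_score <- drop(full_matrix[, idx, drop = FALSE] %*% v)
    exceed <- exceed + (null_score >= observed)
  }
  res <- data.frame(gene_id = rownames(full_matrix),
                    score = unname(observed),
                    p_value = (exceed + 1) / (n_perm + 1),
                    n_permutations = as.integer(n_perm),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("gene_score_vector", "data.frame")
  res
}

# save/restore the global RNG state so scoring functions do not disturb
# the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Genes surviving the significance threshold
#'
#' @param scored A `gene_score_vector` from [permutation_pvalues()].
#' @param alpha Significance level; genes with raw `p_value <= alpha`
#'   (inclusive) are kept. No multiplicity adjustment is applied here by
#'   default; see [fisher_enrichment()] for set-level BH adjustment.
#' @param adjust If `TRUE`, threshold Benjamini-Hochberg adjusted p-values
#'   instead of raw ones.
#' @return Character vector of significant gene ids (possibly empty).
#' @export
significant_genes <- function(scored, alpha = 0.05, adjust = FALSE) {
  stopifnot(is.data.frame(scored), all(c("gene_id", "p_value") %in% names(scored)))
  p <- if (adjust) stats::p.adjust(scored$p_value, method = "BH") else scored$p_value
  scored$gene_id[p <= alpha]
}

#' Gene-set over-representation by Fisher's exact test
#'
#' For each gene set, a one-sided (greater) Fisher's exact test on the 2x2
#' table (significant-and-in-set, significant-not-in-set,
#' in-set-not-significant, neither), over a fixed gene universe. Sets are
#' intersected with the universe first; sets left empty are skipped with a
#' warning. Benjamini-Hochberg adjusted p-values are reported alongside the
#' raw ones.
#'
#' @param sig_genes Character vector of significant gene ids (must be a
#'   subset of `universe`).
#' @param sets A [gene_set_collection()].
#' @param universe Character vector: the gene universe (e.g. all genes of
#'   the mir-gene score matrix).
#' @return A data.frame of class `enrichment_result` with columns
#'   `set_name`, `n_hits`, `n_sig_genes`, `n_set_in_universe`,
#'   `n_universe`, `odds_ratio`, `p_value`, `adjusted_p`, ordered by
#'   `p_value`.
#' @export
fisher_enrichment <- function(sig_genes, sets, universe) {
  stopifnot(inherits(sets, "gene_set_collection"))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("fisher_enrichment: empty universe")
  sig_genes <- unique(as.character(sig_genes))
  if (!all(sig_genes %in% universe))
    stop("fisher_enrichment: sig_genes must be a subset of the universe")
  n_univ <- length(universe)
  n_sig <- length(sig_genes)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    if (!length(members)) {
      warning("fisher_enrichment: set '", nm,
              "' is disjoint from the universe; skipped")
      return(NULL)
    }
    n_set <- length(members)
    n_hit <- length(intersect(sig_genes, members))
    tab <- matrix(c(n_hit, n_sig - n_hit,
                    n_set - n_hit, n_univ - n_sig - n_set + n_hit),
                  nrow = 2L)
    ft <- stats::fisher.test(tab, alternative = "greater")
    data.frame(set_name = nm, n_hits = n_hit, n_sig_genes = n_sig,
               n_set_in_universe = n_set, n_universe = n_univ,
               odds_ratio = unname(ft$estimate), p_value = ft$p.value,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    stop("fisher_enrichment: no gene set overlaps the universe")
  res <- do.call(rbind, rows)
  res$adjusted_p <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value, res$set_name), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Annotate one circRNA with significant genes and enriched sets
#'
#' End-to-end annotation for a single circRNA: select its miRNA set, form
#' gene association scores, compute permutation p-values, threshold, and
#' test set over-representation.
#'
#' @param circ_id circRNA identifier.
#' @param circ_mir_ranking Scored circ-mir ranking from [pareto_rank()].
#' @param mir_gene_ranking Scored mir-gene ranking from [pareto_rank()].
#' @param sets A [gene_set_collection()].
#' @param mode,top_score,top_n Passed to [mirna_set_for_circ()].
#' @param n_perm,seed Passed to [permutation_pvalues()].
#' @param alpha Gene-level significance threshold.
#' @param universe Gene universe for enrichment; default all genes in the
#'   mir-gene ranking.
#' @return A list with elements `mirna_set`, `genes` (a
#'   `gene_score_vector`), `sig_genes` and `enrichment` (an
#'   `enrichment_result`, or `NULL` when no gene is significant).
#' @export
annotate_circrna <- function(circ_id, circ_mir_ranking, mir_gene_ranking,
                             sets, mode = c("all", "top_score", "top_n"),
                             top_score = 0.95, top_n = 10L,
                             n_perm = 10000L, seed, alpha = 0.05,
                             universe = NULL) {
  mode <- match.arg(mode)
  mk <- mirna_set_for_circ(circ_id, circ_mir_ranking, mode = mode,
                           top_score = top_score, top_n = top_n)
  if (!length(mk))
    stop("annotate_circrna: miRNA selection for '", circ_id, "' is empty; ",
         "lower top_score or raise top_n")
  full_matrix <- mir_gene_score_matrix(mir_gene_ranking)
  if (is.null(universe)) universe <- rownames(full_matrix)
  cm <- setNames(pareto_score_of(circ_mir_ranking, rep(circ_id, length(mk)), mk),
                 mk)
  obs <- gene_scores(cm, full_matrix)
  genes <- permutation_pvalues(obs, cm, full_matrix, n_perm = n_perm,
                               seed = seed)
  sig <- significant_genes(genes, alpha = alpha)
  enr <- if (length(sig)) fisher_enrichment(sig, sets, universe) else NULL
  list(circ_id = circ_id, mirna_set = mk, genes = genes,
       sig_genes = sig, enrichment = enr)
}
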