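# Pareto Frontier Analysis: stratify interaction edges into successive
# non-dominated fronts over two or more criteria, then convert front
# membership into a single rank-derived score in (0, 1].
#
# All criteria are maximized; callers pre-orient their scores so that
# larger is better. The method is rank-based: applying any strictly
# increasing transform to a single criterion leaves fronts and scores
# unchanged.

#' Pareto dominance of criterion vectors
#'
#' `x` dominates `y` when `x >= y` in every criterion and `x > y` in at
#' least one. Equal vectors never dominate each other.
#'
#' @param x,y Numeric vectors of equal length (one value per criterion).
#' @return `TRUE` iff `x` Pareto-dominates `y`.
#' @export
dominates <- function(x, y) {
  if (length(x) != length(y))
    stop("dominates: criterion vectors of unequal dimension")
  all(x >= y) && any(x > y)
}

# Indices of the non-dominated rows of criterion matrix m (maximization).
# Pairwise vectorized; used for >= 3 criteria and as a clarity reference.
non_dominated <- function(m) {
  n <- nrow(m)
  if (n == 1L) return(1L)
  dominated <- logical(n)
  ord <- order(-m[, 1L], -rowSums(m))
  m_ord <- m[ord, , drop = FALSE]
  for (i in seq_len(n)) {
    if (dominated[i]) next
    xi <- m_ord[i, ]
    # rows after i in this order can never dominate row i on criterion 1 ties
    ge <- rep(TRUE, n)
    gt <- rep(FALSE, n)
    for (k in seq_len(ncol(m))) {
      ge <- ge & m_ord[, k] <= xi[k]
      gt <- gt | m_ord[, k] < xi[k]
    }
    newly <- ge & gt & !dominated
    dominated[newly] <- TRUE
  }
  sort(ord[!dominated])
}

# Front indices for a 2-criterion matrix by sort-and-sweep peeling.
fronts_2d <- function(m) {
  n <- nrow(m)
  front <- integer(n)
  remaining <- seq_len(n)
  k <- 0L
  while (length(remaining)) {
    k <- k + 1L
    sub <- m[remaining, , drop = FALSE]
    # a point is non-dominated iff its c2 strictly exceeds the best c2 of
    # all points with strictly larger c1, and it attains the max c2 within
    # its own c1 tie group
    o <- order(-sub[, 1L], -sub[, 2L])
    c1 <- sub[o, 1L]; c2 <- sub[o, 2L]
    grp <- cumsum(c(TRUE, c1[-1L] != c1[-length(c1)]))
    grp_max <- tapply(c2, grp, max)
    best_before <- c(-Inf, cummax(as.numeric(grp_max)))[grp]
    nd <- (c2 > best_before) & (c2 == grp_max[grp])
    idx <- remaining[o[nd]]
    front[idx] <- k
    remaining <- setdiff(remaining, idx)
  }
  front
}

#' Assign interaction edges to Pareto fronts
#'
#' Front 1 is the set of edges dominated by no other edge; front k is the
#' non-dominated set once fronts 1..k-1 are removed. Every edge lands on
#' exactly one front, and edges with identical criterion vectors always
#' share a front.
#'
#' @param edges An [interaction_table()] whose criterion columns are all
#'   finite and pre-oriented so larger is better.
#' @param criteria Character vector of criterion column names to rank on;
#'   default: all criterion columns of the table.
#' @return The table with an integer `front_index` column added, carrying
#'   class `pareto_ranking`.
#' @export
pareto_fronts <- function(edges, criteria = interaction_criteria(edges)) {
  stopifnot(is.data.frame(edges), length(criteria) >= 1L)
  missing <- setdiff(criteria, names(edges))
  if (length(missing))
    stop("pareto_fronts: criteria not in table: ", paste(missing, collapse = ", "))
  m <- as.matrix(edges[, criteria, drop = FALSE])
  if (!is.numeric(m) || anyNA(m) || any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1L, 1L]
    stop("pareto_fronts: non-finite criterion for edge ",
         edges$source_id[bad], "-", edges$target_id[bad])
  }
  n <- nrow(m)
  if (!n) stop("pareto_fronts: empty interaction table")
  if (ncol(m) == 1L) {
    # single criterion: fronts are the distinct values, descending
    front <- match(-m[, 1L], sort(unique(-m[, 1L])))
  } else if (ncol(m) == 2L) {
    front <- fronts_2d(m)
  } else {
    front <- integer(n)
    remaining <- seq_len(n)
    k <- 0L
    while (length(remaining)) {
      k <- k + 1L
      nd <- non_dominated(m[remaining, , drop = FALSE])
      front[remaining[nd]] <- k
      remaining <- remaining[-nd]
    }
  }
  edges$front_index <- as.integer(front)
  attr(edges, "criteria") <- criteria
  class(edges) <- unique(c("pareto_ranking", class(edges)))
  edges
}

#' Rescale Pareto fronts into interaction scores
#'
#' Converts front membership into a score in (0, 1]: every edge on front k
#' receives `(n_total - c) / n_total` where `c` is the number of edges on
#' strictly better fronts (1..k-1) and `n_total` the total number of ranked
#' edges. Front 1 therefore always scores exactly 1, all edges of one front
#' share one score, and scores strictly decrease with front index. Pairs
#' absent from the ranking have, by convention, score 0 (no evidence).
#'
#' An alternative rescaling by front index itself
#' (`score = (K - k + 1) / K` over K fronts) is available via
#' `method = "front_rank"`.
#'
#' @param ranking A table with `front_index`, as from [pareto_fronts()].
#' @param method `"cumulative"` (default; fraction of edges not on a
#'   strictly better front) or `"front_rank"`.
#' @return The table with a numeric `pareto_score` column added.
#' @export
pareto_scores <- function(ranking, method = c("cumulative", "front_rank")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(ranking), "front_index" %in% names(ranking))
  n <- nrow(ranking)
  if (!n) stop("pareto_scores: empty ranking")
  if (method == "cumulative") {
    sizes <- table(ranking$front_index)
    k_levels <- as.integer(names(sizes))
    cum_before <- c(0, cumsum(as.numeric(sizes)))[match(ranking$front_index, k_levels)]
    ranking$pareto_score <- (n - cum_before) / n
  } else {
    K <- max(ranking$front_index)
    ranking$pareto_score <- (K - ranking$front_index + 1) / K
  }
  ranking
}

#' Rank edges by Pareto frontier analysis
#'
#' One-call wrapper: [pareto_fronts()] then [pareto_scores()].
#'
#' @inheritParams pareto_fronts
#' @inheritParams pareto_scores
#' @return The input table with `front_index` and `pareto_score` columns.
#' @export
pareto_rank <- function(edges, criteria = interaction_criteria(edges),
                        method = c("cumulative", "front_rank")) {
  pareto_scores(pareto_fronts(edges, criteria), method = match.arg(method))
}

#' Look up Pareto scores for pairs, absent pairs scoring 0
#'
#' @param ranking A scored ranking from [pareto_rank()].
#' @param source_id,target_id Character vectors of pairs to look up.
#' @return Numeric vector of scores; 0 for pairs not in the ranking.
#' @export
pareto_score_of <- function(ranking, source_id, target_id) {
  key <- paste(ranking$source_id, ranking$target_id, sep = "\r")
  hit <- match(paste(source_id, target_id, sep = "\r"), key)
  out <- ranking$pareto_score[hit]
  out[is.na(out)] <- 0
  out
}
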