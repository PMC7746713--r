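# Independent brute-force oracles used across test files. These are kept
# deliberately naive (loops, O(n^2) peeling, exhaustive enumeration) and
# share no code with the implementation they check.

# O(n^2) dominance-peeling front assignment on a criterion matrix
# (maximization).
bf_pareto_fronts <- function(m) {
  n <- nrow(m)
  front <- integer(n)
  remaining <- seq_len(n)
  k <- 0L
  while (length(remaining)) {
    k <- k + 1L
    nd <- vapply(seq_along(remaining), function(i) {
      xi <- m[remaining[i], ]
      others <- remaining[-i]
      !any(vapply(others, function(j) {
        y <- m[j, ]
        all(y >= xi) && any(y > xi)
      }, logical(1)))
    }, logical(1))
    front[remaining[nd]] <- k
    remaining <- remaining[!nd]
  }
  front
}

# same peeling oracle, but on a precomputed n x n dominance matrix so it
# scales to n = 500; D[i, j] = TRUE iff row j dominates row i
bf_dominance_matrix <- function(m) {
  n <- nrow(m)
  ge <- matrix(TRUE, n, n)
  gt <- matrix(FALSE, n, n)
  for (k in seq_len(ncol(m))) {
    ge_k <- outer(m[, k], m[, k], "<=")
    ge <- ge & ge_k
    gt <- gt | outer(m[, k], m[, k], "<")
  }
  ge & gt
}

bf_pareto_fronts_mat <- function(m) {
  D <- bf_dominance_matrix(m)
  n <- nrow(m)
  front <- integer(n)
  remaining <- rep(TRUE, n)
  k <- 0L
  while (any(remaining)) {
    k <- k + 1L
    has_dom <- rowSums(D[, remaining, drop = FALSE]) > 0
    nd <- remaining & !has_dom
    front[nd] <- k
    remaining <- remaining & !nd
  }
  front
}

# block-maximum rescaling of fronts into scores, straight from the formula
bf_pareto_scores <- function(front) {
  n <- length(front)
  vapply(front, function(k) (n - sum(front < k)) / n, numeric(1))
}

# exhaustive per-offset seed-site classifier; completely string-based
bf_seed_sites <- function(mirna, target, circular = FALSE) {
  comp <- function(s) chartr("ACGU", "UGCA", s)
  rc <- function(s) paste(rev(strsplit(comp(s), "")[[1]]), collapse = "")
  mirna <- chartr("T", "U", toupper(mirna))
  target <- chartr("T", "U", toupper(target))
  L <- nchar(target)
  if (L < 6) return(data.frame(core_position = integer(0),
                               site_type = character(0)))
  seed_site <- rc(substr(mirna, 2, 7))
  m8_site <- comp(substr(mirna, 8, 8))
  base_at <- function(i) {
    # i may fall outside 1..L; circular wraps, linear returns NA
    if (circular) substr(target, ((i - 1) %% L) + 1, ((i - 1) %% L) + 1)
    else if (i >= 1 && i <= L) substr(target, i, i) else NA_character_
  }
  offsets <- if (circular) 1:L else 1:(L - 5)
  out <- list()
  for (p in offsets) {
    core <- paste(vapply(p:(p + 5), base_at, character(1)), collapse = "")
    if (is.na(core) || core != seed_site) next
    m8 <- base_at(p - 1)
    a1 <- base_at(p + 6)
    has_m8 <- !is.na(m8) && m8 == m8_site
    has_a1 <- !is.na(a1) && a1 == "A"
    type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8"
            else if (has_a1) "7mer-A1" else "6mer"
    out[[length(out) + 1L]] <- data.frame(core_position = p - 1L,
                                          site_type = type,
                                          stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(core_position = integer(0),
                                      site_type = character(0)))
  do.call(rbind, out)
}

# exact permutation p-values by enumerating every k-subset of the miRNA
# universe (columns taken in index order, as the sampler does). The
# observed score is recomputed internally from the observed columns so the
# oracle is self-consistent in its tie handling.
bf_exact_perm_p <- function(v, full_matrix, obs_cols, n_perm) {
  k <- length(obs_cols)
  subsets <- utils::combn(ncol(full_matrix), k, simplify = FALSE)
  exceed_prob <- vapply(seq_len(nrow(full_matrix)), function(g) {
    obs_g <- sum(v * full_matrix[g, obs_cols])
    mean(vapply(subsets, function(ss) {
      sum(v * full_matrix[g, ss]) >= obs_g
    }, logical(1)))
  }, numeric(1))
  # expected Monte-Carlo p under the (count+1)/(N+1) estimator
  (n_perm * exceed_prob + 1) / (n_perm + 1)
}

random_rna <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# small interaction table around a criterion matrix
it_from_matrix <- function(m) {
  colnames(m) <- paste0("c", seq_len(ncol(m)))
  interaction_table(sprintf("s%04d", seq_len(nrow(m))),
                    sprintf("t%04d", seq_len(nrow(m))),
                    as.data.frame(m))
}
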