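# small scored ranking builder: edges circX -> mirY with given scores
toy_ranking <- function(circ, mir, score) {
  data.frame(source_id = circ, target_id = mir, front_index = 1L,
             pareto_score = score, stringsAsFactors = FALSE)
}

test_that("miRNA selection honours all / top-score / top-n modes", {
  rk <- toy_ranking("c1", c("mB", "mA", "mC", "mD", "mE"),
                    c(0.99, 0.95, 0.40, 0.95, 0.10))
  expect_identical(mirna_set_for_circ("c1", rk, "top_score", top_score = 0.95),
                   c("mB", "mA", "mD"))   # inclusive >=, ties by id
  expect_identical(mirna_set_for_circ("c1", rk, "all"),
                   c("mB", "mA", "mD", "mC", "mE"))
  expect_identical(mirna_set_for_circ("c1", rk, "top_n", top_n = 2),
                   c("mB", "mA"))
  # zero-score partners never qualify, absent circ errors
  rk0 <- rbind(rk, toy_ranking("c1", "mZ", 0))
  expect_false("mZ" %in% mirna_set_for_circ("c1", rk0, "all"))
  expect_error(mirna_set_for_circ("c9", rk, "all"), "no ceRNA edges")
})

test_that("gene scores are the circ-mir / mir-gene score product", {
  M <- matrix(c(0.5, 0, 1,
                0,   0, 0.2), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("m1", "m2")))
  expect_equal(gene_scores(c(m1 = 1), M),
               c(g1 = 0.5, g2 = 0, g3 = 1))
  # 3x4 toy matrices against an independent matrix multiply
  set.seed(13)
  M2 <- matrix(round(runif(12), 2), 4, 3,
               dimnames = list(paste0("g", 1:4), paste0("m", 1:3)))
  v <- c(m1 = 0.9, m2 = 0.4, m3 = 0.7)
  manual <- vapply(1:4, function(g) sum(v * M2[g, names(v)]), numeric(1))
  expect_equal(unname(gene_scores(v, M2)), manual)
  # miRNAs absent from the matrix contribute zero
  expect_equal(gene_scores(c(m1 = 1, mX = 5), M),
               c(g1 = 0.5, g2 = 0, g3 = 1))
  expect_error(gene_scores(numeric(0), M), "empty")
})

test_that("permutation p-values honour the (count+1)/(N+1) formula edges", {
  M <- matrix(c(1, 0, 0.5, 0, 0.2, 0), 2, 3,
              dimnames = list(c("g1", "g2"), c("m1", "m2", "m3")))
  v <- c(m1 = 1)
  obs <- gene_scores(v, M)
  # observed score 0 -> every null >= 0 -> p = 1
  res <- permutation_pvalues(obs, v, M, n_perm = 200, seed = 1)
  expect_equal(res$p_value[res$gene_id == "g2"], 1)
  expect_true(all(res$p_value >= 1 / 201))

  # null never reaches an unattainably large observed score -> p = 1/(N+1)
  obs_big <- c(g1 = 99, g2 = 99)
  res2 <- permutation_pvalues(obs_big, v, M, n_perm = 999, seed = 2)
  expect_equal(res2$p_value, c(1 / 1000, 1 / 1000))

  expect_error(permutation_pvalues(obs, c(m1 = 1, m2 = 1, m3 = 1, m4 = 1), M,
                                   n_perm = 10, seed = 1), "exceeds")
  expect_error(permutation_pvalues(obs, v, M, n_perm = 0, seed = 1), ">= 1")
  expect_error(permutation_pvalues(obs, v, M, n_perm = 10), "seed")
})

test_that("Monte-Carlo p-values agree with exhaustive subset enumeration", {
  set.seed(19)
  n_gene <- 8
  M <- matrix(runif(n_gene * 5), n_gene, 5,
              dimnames = list(paste0("g", 1:n_gene), paste0("m", 1:5)))
  v <- c(m2 = 0.9, m4 = 0.6)
  obs <- gene_scores(v, M)
  n_perm <- 4000
  res <- permutation_pvalues(obs, v, M, n_perm = n_perm, seed = 77)
  exact <- bf_exact_perm_p(unname(v), M, match(names(v), colnames(M)), n_perm)
  p_ex <- (exact * (n_perm + 1) - 1) / n_perm   # underlying exceedance prob
  se <- sqrt(p_ex * (1 - p_ex) / n_perm)
  expect_true(all(abs(res$p_value - exact) <= 3 * se + 1e-12))
})

test_that("p-values are invariant to common scaling of the circ-mir vector", {
  set.seed(23)
  M <- matrix(runif(30), 10, 3,
              dimnames = list(paste0("g", 1:10), paste0("m", 1:3)))
  v <- c(m1 = 0.8, m2 = 0.5)
  obs <- gene_scores(v, M)
  r1 <- permutation_pvalues(obs, v, M, n_perm = 500, seed = 5)
  r2 <- permutation_pvalues(2 * obs, 2 * v, M, n_perm = 500, seed = 5)
  expect_equal(2 * r1$score, r2$score)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("significance threshold is inclusive and may select nothing", {
  scored <- data.frame(gene_id = c("g1", "g2"), score = c(1, 1),
                       p_value = c(0.05, 0.051), n_permutations = 999L)
  expect_identical(significant_genes(scored, alpha = 0.05), "g1")
  expect_identical(significant_genes(scored, alpha = 0.01), character(0))
  # brute-force filter agreement on a random vector
  set.seed(3)
  sc <- data.frame(gene_id = paste0("g", 1:50), score = runif(50),
                   p_value = runif(50), n_permutations = 99L)
  expect_identical(significant_genes(sc, alpha = 0.2),
                   sc$gene_id[sc$p_value <= 0.2])
})

test_that("Fisher enrichment equals the hypergeometric tail", {
  # 2x2 table (3,1,1,15): one-sided p by direct tail summation
  sets <- gene_set_collection(list(S = paste0("g", 1:4)))
  universe <- paste0("g", 1:20)
  sig <- c("g1", "g2", "g3", "g20")
  res <- fisher_enrichment(sig, sets, universe)
  tail_terms <- sapply(3:4, function(h)
    choose(4, h) * choose(16, 4 - h) / choose(20, 4))
  expect_equal(res$p_value, sum(tail_terms), tolerance = 1e-12)
  expect_equal(res$n_hits, 3)

  # significant set = a set covering half the universe
  sets2 <- gene_set_collection(list(half = paste0("g", 1:10)))
  res2 <- fisher_enrichment(paste0("g", 1:10), sets2, universe)
  expect_equal(res2$p_value,
               phyper(9, 10, 10, 10, lower.tail = FALSE), tolerance = 1e-12)

  # disjoint set skipped with a warning
  sets3 <- gene_set_collection(list(S = "g1", out = "zz"))
  expect_warning(res3 <- fisher_enrichment("g1", sets3, universe), "out")
  expect_identical(res3$set_name, "S")
  expect_error(fisher_enrichment("g1", sets, character(0)), "empty universe")
  expect_error(fisher_enrichment("zz", sets, universe), "subset")
})

test_that("enrichment matches phyper on all margins up to 12", {
  # full sweep of small 2x2 tables against the closed-form tail
  for (n_univ in c(8, 12)) {
    universe <- paste0("g", seq_len(n_univ))
    for (n_set in c(2, 5)) {
      for (n_sig in c(1, 4, 6)) {
        for (n_hit in 0:min(n_set, n_sig)) {
          if (n_sig - n_hit > n_univ - n_set) next
          sig <- c(if (n_hit > 0) paste0("g", seq_len(n_hit)),
                   if (n_sig > n_hit) paste0("g", n_set + seq_len(n_sig - n_hit)))
          sets <- gene_set_collection(list(S = paste0("g", seq_len(n_set))))
          res <- fisher_enrichment(sig, sets, universe)
          expected <- phyper(n_hit - 1, n_set, n_univ - n_set, n_sig,
                             lower.tail = FALSE)
          expect_equal(res$p_value, expected, tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("annotate_circrna wires selection, permutation and enrichment", {
  set.seed(31)
  cm <- toy_ranking("c1", paste0("m", 1:6),
                    c(1, 1, 0.98, 0.2, 0.1, 0.05))
  genes <- paste0("g", 1:30)
  mg <- do.call(rbind, lapply(1:6, function(i)
    toy_ranking(paste0("m", i), sample(genes, 12),
                round(runif(12, 0.1, 1), 2))))
  # make m1/m2 strongly target the first ten genes
  mg$pareto_score[mg$source_id %in% c("m1", "m2") &
                    mg$target_id %in% genes[1:10]] <- 1
  sets <- gene_set_collection(list(first = genes[1:10], rest = genes[11:30]))
  ann <- annotate_circrna("c1", cm, mg, sets, mode = "top_score",
                          top_score = 0.95, n_perm = 300, seed = 9)
  expect_identical(ann$mirna_set, c("m1", "m2", "m3"))
  expect_true(all(ann$genes$p_value >= 1 / 301))
  expect_true(is.null(ann$enrichment) ||
                all(c("set_name", "adjusted_p") %in% names(ann$enrichment)))
})
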