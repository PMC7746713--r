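toy_counts <- function(m, class = "gene", total = NULL) {
  count_panel(m, class, total_mapped = total)
}

test_that("median-of-ratios size factors match the formula", {
  m <- matrix(c(10, 20, 5, 0,
                10, 20, 5, 0,
                10, 20, 5, 0), 4, 3,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  norm <- median_of_ratios_normalize(toy_counts(m))
  expect_equal(unname(attr(norm, "size_factors")), c(1, 1, 1))
  expect_equal(norm$values, m)

  # sample B = 2 x sample A: size factors proportional to the scaling and
  # normalized panels equal
  a <- c(4, 8, 2, 6)
  m2 <- cbind(s1 = a, s2 = 2 * a)
  rownames(m2) <- paste0("g", 1:4)
  norm2 <- median_of_ratios_normalize(toy_counts(m2))
  sf <- attr(norm2, "size_factors")
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(norm2$values[, 1], norm2$values[, 2])

  # 4x3 integer toy panel against independent hand computation
  m3 <- matrix(c(2, 4, 8, 0,
                 4, 4, 16, 1,
                 8, 16, 8, 2), 4, 3,
               dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  geo <- apply(m3, 1, function(x) exp(mean(log(x))))
  usable <- apply(m3, 1, function(x) all(x > 0))
  expected_sf <- apply(m3, 2, function(col) median((col / geo)[usable]))
  norm3 <- median_of_ratios_normalize(toy_counts(m3))
  expect_equal(unname(attr(norm3, "size_factors")), unname(expected_sf))
  expect_equal(norm3$values, sweep(m3, 2, expected_sf, "/"))

  # no feature positive everywhere -> actionable error
  m4 <- matrix(c(1, 0, 0, 1), 2, 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(median_of_ratios_normalize(toy_counts(m4)), "cpm")
})

test_that("size factors agree with the reference bulk RNA-seq estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(97)
  # an odd number of all-positive features keeps the two median
  # conventions (arithmetic vs log-scale interpolation) coincident
  m <- matrix(rpois(80, 50) + 1, 20, 4,
              dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:4)))
  m[1:5, 1] <- 0
  norm <- median_of_ratios_normalize(toy_counts(m))
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(attr(norm, "size_factors")), unname(ref),
               tolerance = 1e-12)
})

test_that("cpm and srpbm follow their defining formulas", {
  m <- matrix(c(1, 3), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(unname(cpm(toy_counts(m))$values[, 1]), c(250000, 750000))

  m2 <- matrix(c(250, 750, 10, 90), 2, 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(unname(colSums(cpm(toy_counts(m2))$values)), c(1e6, 1e6))
  m0 <- matrix(c(1, 0, 0, 0), 2, 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(cpm(toy_counts(m0)), "zero column sum")

  j <- matrix(c(1, 0, 12, 30), 2, 2,
              dimnames = list(c("c1", "c2"), c("s1", "s2")))
  tot <- c(s1 = 1e9, s2 = 4e8)
  sr <- srpbm(toy_counts(j, "circRNA", tot))
  expect_equal(unname(sr$values), cbind(c(1, 0), c(30, 75)))
  expect_error(srpbm(toy_counts(j, "circRNA")), "total mapped")
})

test_that("low-expression filter keeps features passing both bounds", {
  set.seed(3)
  m <- matrix(rpois(300, 12), 30, 10,
              dimnames = list(sprintf("g%02d", 1:30), paste0("s", 1:10)))
  m[1, ] <- c(9, rep(0, 9))           # total 9 < 10: dropped
  cp <- toy_counts(m)
  norm <- expression_panel(m * 1.0, "gene", "norm")
  kept <- filter_low_expression(cp, norm)
  # independent double loop
  expected <- rownames(m)[vapply(seq_len(nrow(m)), function(i)
    sum(m[i, ]) >= 10 && mean(m[i, ]) >= 10, logical(1))]
  expect_identical(kept, expected)
  expect_false("g01" %in% kept)

  # boundary: mean exactly at the threshold is retained
  mb <- matrix(10, 1, 2, dimnames = list("gb", c("s1", "s2")))
  expect_identical(
    filter_low_expression(toy_counts(mb),
                          expression_panel(mb * 1.0, "gene", "n")),
    "gb")
  expect_error(
    filter_low_expression(cp, expression_panel(m[-1, ] * 1.0, "gene", "n")),
    "feature sets")
})

test_that("tissue ECDF scores follow the right-continuous convention", {
  v <- cbind(t1 = c(a = 1, b = 2, c = 3))
  s <- tissue_ecdf_scores(expression_panel(v, "circRNA", "x"))
  expect_equal(s$score[match(c("a", "b", "c"), s$feature_id)],
               c(1 / 3, 2 / 3, 1))

  # ties share the higher score
  v2 <- cbind(t1 = c(a = 2, b = 2, c = 5))
  s2 <- tissue_ecdf_scores(expression_panel(v2, "circRNA", "x"))
  expect_equal(s2$score[match(c("a", "b", "c"), s2$feature_id)],
               c(2 / 3, 2 / 3, 1))

  # single expressed feature scores 1; zeros are excluded
  v3 <- cbind(t1 = c(a = 0, b = 7, c = 0))
  s3 <- tissue_ecdf_scores(expression_panel(v3, "miRNA", "x"))
  expect_identical(s3$feature_id, "b")
  expect_equal(s3$score, 1)

  # all-zero tissue omitted with a warning, others kept
  v4 <- cbind(t1 = c(a = 0, b = 0), t2 = c(a = 1, b = 2))
  expect_warning(s4 <- tissue_ecdf_scores(expression_panel(v4, "gene", "x")),
                 "t1")
  expect_identical(unique(s4$tissue_id), "t2")
})

test_that("ECDF scores are in (0,1] and monotone in expression", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(3:40, 1)
    v <- matrix(rlnorm(n * 3) * rbinom(n * 3, 1, 0.7), n, 3,
                dimnames = list(sprintf("f%02d", 1:n), paste0("t", 1:3)))
    if (any(colSums(v) == 0)) next
    s <- tissue_ecdf_scores(expression_panel(v, "circRNA", "x"))
    expect_true(all(s$score > 0 & s$score <= 1))
    # per tissue, scores are a non-decreasing function of expression
    for (tt in unique(s$tissue_id)) {
      sub <- s[s$tissue_id == tt, ]
      ord <- order(v[sub$feature_id, tt])
      expect_true(all(diff(sub$score[ord]) >= -1e-12))
    }
    # raising one feature's expression never lowers its score
    f <- sample(rownames(v)[v[, 1] > 0], 1)
    v2 <- v; v2[f, 1] <- v2[f, 1] * 2
    s2 <- tissue_ecdf_scores(expression_panel(v2, "circRNA", "x"))
    before <- s$score[s$feature_id == f & s$tissue_id == "t1"]
    after <- s2$score[s2$feature_id == f & s2$tissue_id == "t1"]
    expect_gte(after, before)
  }
})

test_that("co-expression score is the max over tissues of the pair minimum", {
  st <- function(df) structure(df, class = c("tissue_score_table", "data.frame"))
  circ <- st(data.frame(feature_id = c("c1", "c1"), tissue_id = c("A", "C"),
                        score = c(0.9, 0.6)))
  mir <- st(data.frame(feature_id = c("m1", "m1"), tissue_id = c("B", "C"),
                       score = c(0.8, 0.5)))
  # no shared tissue for (A,B); shared tissue C gives min(0.6, 0.5)
  sc <- coexpression_score(circ, mir)
  expect_equal(sc$S_exp, 0.5)

  circ2 <- st(data.frame(feature_id = "c1", tissue_id = "A", score = 0.9))
  mir2 <- st(data.frame(feature_id = "m1", tissue_id = "B", score = 0.7))
  expect_equal(coexpression_score(circ2, mir2)$S_exp, 0)

  # two shared tissues (0.9, 0.4) and (0.6, 0.5): max of mins = 0.5
  circ3 <- st(data.frame(feature_id = c("c1", "c1"), tissue_id = c("A", "B"),
                         score = c(0.9, 0.6)))
  mir3 <- st(data.frame(feature_id = c("m1", "m1"), tissue_id = c("A", "B"),
                        score = c(0.4, 0.5)))
  expect_equal(coexpression_score(circ3, mir3)$S_exp, 0.5)
})

test_that("co-expression equals brute-force max-min on enumerated toy tables", {
  set.seed(5)
  for (rep in 1:25) {
    n_t <- sample(1:4, 1)
    tissues <- paste0("t", seq_len(n_t))
    n_c <- sample(1:4, 1); n_m <- sample(1:4, 1)
    cv <- matrix(round(rlnorm(n_c * n_t), 2) * rbinom(n_c * n_t, 1, 0.6),
                 n_c, n_t, dimnames = list(paste0("c", 1:n_c), tissues))
    mv <- matrix(round(rlnorm(n_m * n_t), 2) * rbinom(n_m * n_t, 1, 0.6),
                 n_m, n_t, dimnames = list(paste0("m", 1:n_m), tissues))
    if (all(cv == 0) || all(mv == 0)) next
    cs <- suppressWarnings(tissue_ecdf_scores(expression_panel(cv, "circRNA", "x")))
    ms <- suppressWarnings(tissue_ecdf_scores(expression_panel(mv, "miRNA", "x")))
    got <- coexpression_score(cs, ms)
    for (r in seq_len(nrow(got))) {
      ci <- got$source_id[r]; mi <- got$target_id[r]
      best <- 0
      for (tt in tissues) {
        a <- cs$score[cs$feature_id == ci & cs$tissue_id == tt]
        b <- ms$score[ms$feature_id == mi & ms$tissue_id == tt]
        if (length(a) && length(b)) best <- max(best, min(a, b))
      }
      expect_equal(got$S_exp[r], best)
    }
    # symmetry in the two arguments (modulo column roles)
    swapped <- coexpression_score(ms, cs)
    key1 <- paste(got$source_id, got$target_id)
    key2 <- paste(swapped$target_id, swapped$source_id)
    expect_equal(got$S_exp[order(key1)], swapped$S_exp[order(key2)])
  }
})

test_that("co-expression is 1 exactly when a tissue has both at its maximum", {
  v <- cbind(t1 = c(c1 = 5, c2 = 2), t2 = c(c1 = 1, c2 = 3))
  w <- cbind(t1 = c(m1 = 9, m2 = 1), t2 = c(m1 = 2, m2 = 8))
  cs <- tissue_ecdf_scores(expression_panel(v, "circRNA", "x"))
  ms <- tissue_ecdf_scores(expression_panel(w, "miRNA", "x"))
  sc <- coexpression_score(cs, ms)
  key <- paste(sc$source_id, sc$target_id)
  expect_equal(sc$S_exp[key == "c1 m1"], 1)  # both maximal in t1
  expect_equal(sc$S_exp[key == "c2 m2"], 1)  # both maximal in t2
  expect_lt(sc$S_exp[key == "c1 m2"], 1)
  expect_lt(sc$S_exp[key == "c2 m1"], 1)
})
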