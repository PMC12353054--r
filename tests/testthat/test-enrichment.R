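test_that("ranking is stable, tie-broken lexicographically, order-invariant", {
  s <- c(b = 2, a = 5, c = 1)
  r <- rank_features(s)
  expect_identical(r$feature_id, c("a", "b", "c"))
  tied <- c(z = 1, y = 1, x = 2)
  expect_identical(rank_features(tied)$feature_id, c("x", "y", "z"))
  set.seed(61)
  s2 <- stats::setNames(sample(c(1, 1, 2, 3, 3)), letters[1:5])
  perm <- sample(5)
  expect_identical(rank_features(s2)$feature_id, rank_features(s2[perm])$feature_id)
  expect_error(rank_features(c(a = NaN, b = 1)), "non-finite")
  expect_error(rank_features(c(1, 2)), "named")
})

test_that("enrichment score matches the hand-enumerated running sum", {
  r <- rank_features(c(A = 5, B = 4, C = 3, D = 2, E = 1))
  # set = top 2 at weight 0: +1/2, +1/2 then three -1/3 steps
  out <- gsea_es(r, c("A", "B"), weight = 0)
  expect_equal(out$running, c(0.5, 1, 1 - 1/3, 1 - 2/3, 0))
  expect_identical(out$es, 1)
  expect_setequal(out$leading_edge, c("A", "B"))
  # mirror: bottom 2 gives -1
  out2 <- gsea_es(r, c("D", "E"), weight = 0)
  expect_identical(out2$es, -1)
  expect_setequal(out2$leading_edge, c("D", "E"))
})

test_that("reversing the ranking negates the weight-0 enrichment score", {
  set.seed(62)
  for (i in 1:20) {
    s <- stats::setNames(stats::rnorm(50), sprintf("f%02d", 1:50))
    set <- sample(names(s), 8)
    es_f <- gsea_es(rank_features(s), set, weight = 0)$es
    es_r <- gsea_es(rank_features(s, descending = FALSE), set, weight = 0)$es
    expect_equal(es_f, -es_r, tolerance = 1e-12)
    expect_lte(abs(es_f), 1)
  }
})

test_that("weighted enrichment scores agree with the reference implementation", {
  skip_if_not_installed("fgsea")
  set.seed(63)
  for (i in 1:20) {
    s <- sort(stats::rnorm(200), decreasing = TRUE)
    names(s) <- sprintf("f%03d", 1:200)
    set <- sample(names(s), 20)
    mine <- gsea_es(rank_features(s), set, weight = 1)$es
    ref <- fgsea::calcGseaStat(s, selectedStats = which(names(s) %in% set),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("size filters mirror the two analysis modes (25 and 5)", {
  g <- gen_ranked_with_sets(n_features = 200, n_sets = 1, planted_set_size = 10,
                            planted_shift = 2, seed = 64)
  wide <- gsea_permutation_test(g$ranked, g$sets, n_perm = 100, min_size = 25,
                                seed = 1)
  expect_identical(nrow(wide), 0L)
  narrow <- gsea_permutation_test(g$ranked, g$sets, n_perm = 100, min_size = 5,
                                  seed = 1)
  expect_identical(nrow(narrow), 1L)
  expect_identical(narrow$size, 10L)
})

test_that("permutation p agrees with exhaustive enumeration on a tiny universe", {
  # N = 8 features, set of 3: all C(8,3) = 56 memberships enumerable
  s <- stats::setNames(c(3, 2.5, 2, 1, 0.5, -0.5, -1, -2), letters[1:8])
  r <- rank_features(s)
  set <- c("a", "b", "c")
  es_obs <- gsea_es(r, set, weight = 1)$es
  combos <- utils::combn(letters[1:8], 3)
  null_es <- apply(combos, 2, function(m) gsea_es(r, m, weight = 1)$es)
  same <- if (es_obs >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  # exhaustive conditional exceedance probability over all memberships
  p_exact <- sum(abs(same) >= abs(es_obs) - 1e-12) / length(same)
  res <- gsea_permutation_test(r, gene_set_collection(list(S = set)),
                               n_perm = 2000, min_size = 2, seed = 65)
  n_eff <- 2000 * length(same) / ncol(combos)   # same-sign draws only
  se <- sqrt(p_exact * (1 - p_exact) / n_eff)
  expect_lt(abs(res$p_perm - p_exact), 3 * se + 2 / n_eff)
})

test_that("null gene sets give uniform permutation p-values", {
  set.seed(66)
  s <- stats::setNames(stats::rnorm(1000), sprintf("f%04d", 1:1000))
  r <- rank_features(s)
  sets <- lapply(1:500, function(i) sample(names(s), 20))
  names(sets) <- sprintf("null%03d", 1:500)
  res <- gsea_permutation_test(r, gene_set_collection(sets), n_perm = 1000,
                               min_size = 5, seed = 67)
  ks <- suppressWarnings(stats::ks.test(res$p_perm, "punif"))  # ties expected
  expect_gt(ks$p.value, 0.01)
})

test_that("a planted set is reliably detected at q < 0.05", {
  hits <- vapply(1:50, function(sd) {
    g <- gen_ranked_with_sets(n_features = 1000, n_sets = 10,
                              planted_set_size = 25, planted_shift = 2, seed = sd)
    res <- gsea_permutation_test(g$ranked, g$sets, n_perm = 500, min_size = 5,
                                 seed = sd + 500)
    planted <- names(which(g$truth))
    res$q[res$set == planted] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("fixed seeds reproduce permutation results exactly", {
  g <- gen_ranked_with_sets(n_features = 300, n_sets = 5, planted_set_size = 20,
                            planted_shift = 1, seed = 68)
  a <- gsea_permutation_test(g$ranked, g$sets, n_perm = 200, min_size = 5, seed = 9)
  b <- gsea_permutation_test(g$ranked, g$sets, n_perm = 200, min_size = 5, seed = 9)
  expect_identical(a, b)
})

test_that("overrepresentation equals the one-sided Fisher exact test", {
  set.seed(69)
  for (i in 1:100) {
    N <- sample(50:500, 1)
    bg <- sprintf("f%04d", 1:N)
    K <- sample(5:40, 1)
    n <- sample(5:40, 1)
    set <- sample(bg, K)
    query <- sample(bg, n)
    res <- ora_hypergeometric(query, bg, gene_set_collection(list(S = set)))
    k <- res$overlap
    fisher_p <- stats::fisher.test(
      matrix(c(k, K - k, n - k, N - K - n + k), 2), alternative = "greater")$p.value
    expect_lt(abs(res$p_hyper - fisher_p), 1e-12)
  }
})

test_that("overrepresentation handles boundary configurations exactly", {
  bg <- sprintf("b%03d", 1:100)
  # query entirely inside a set of the same size: p = 1 / C(N, n)
  set <- bg[1:5]
  res <- ora_hypergeometric(bg[1:5], bg, gene_set_collection(list(S = set)))
  expect_equal(res$p_hyper, 1 / choose(100, 5), tolerance = 1e-12)
  # disjoint set: k = 0, p = 1
  res0 <- ora_hypergeometric(bg[1:5], bg, gene_set_collection(list(S = bg[50:60])))
  expect_identical(res0$overlap, 0L)
  expect_identical(res0$p_hyper, 1)
  expect_error(ora_hypergeometric(c("zzz"), bg, gene_set_collection(list(S = set))),
               "outside background")
})

test_that("quantile marker sets recover the planted top fraction", {
  v <- stats::setNames(1:100, sprintf("m%03d", 1:100))
  gs <- quantile_marker_sets(list(grp = v), q = 0.95)
  expect_identical(length(gs$sets$grp), 5L)
  expect_setequal(gs$sets$grp, sprintf("m%03d", 96:100))
  # constant statistic: nothing strictly above the quantile
  const <- stats::setNames(rep(2, 30), paste0("c", 1:30))
  gs2 <- quantile_marker_sets(list(a = const, b = v), q = 0.95)
  expect_identical(names(gs2$sets), "b")
})

test_that("mean-expression ranking reproduces hand-computed means", {
  v <- matrix(c(1, 2, 3, 4,
                4, 4, 4, 4,
                0, 0, NA, 8,
                7, 1, 1, 1,
                2, 2, 2, 6), 5, 4, byrow = TRUE)
  em <- make_em(v)
  r <- mean_expression_ranking(em)
  mu <- c(g01 = 2.5, g02 = 4, g03 = 8 / 3, g04 = 2.5, g05 = 3)
  expect_identical(r$feature_id[1], "g02")
  expect_equal(r$stat, unname(sort(mu, decreasing = TRUE)))
  # tie between g01 and g04 broken lexicographically
  expect_lt(which(r$feature_id == "g01"), which(r$feature_id == "g04"))
  r1 <- mean_expression_ranking(em, samples = "s02")
  expect_equal(r1$stat, unname(sort(v[, 2], decreasing = TRUE)))
  expect_error(mean_expression_ranking(em, samples = character(0)), "empty")
})
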