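test_that("ora matches the hypergeometric enumeration oracle", {
  uni <- gene_ids(20)
  sets <- list(hit = uni[1:5], other = uni[6:10])
  res <- suppressMessages(ora(uni[c(1:4, 15)], uni, sets, min_size = 1))
  expect_equal(res$p[res$set == "hit"], enum_overlap_p(4, 5, 5, 20),
               tolerance = 1e-12)
  # a query equal to one full set is that size's most extreme outcome
  res2 <- ora(uni[1:5], uni, sets, min_size = 1)
  expect_equal(res2$set[1], "hit")
  expect_equal(res2$p[1], enum_overlap_p(5, 5, 5, 20), tolerance = 1e-12)
  expect_error(ora(character(), uni, sets), class = "comorbidome_input_error")
})

test_that("ora p-values are uniform for random queries", {
  set.seed(5)
  uni <- gene_ids(1000)
  sets <- sim_gene_sets(uni, n_sets = 1000, size_range = c(20, 60), seed = 6)
  query <- sample(uni, 100)
  res <- ora(query, uni, sets, min_size = 1, max_size = 1000)
  # the hypergeometric p is discrete, hence super-uniform; smooth it with the
  # randomized probability integral transform P(K > k) + U * P(K = k), which
  # is exactly U(0, 1) when the null overlap distribution is correct
  p_gt <- vapply(seq_len(nrow(res)), function(i) {
    k1 <- res$overlap[i] + 1
    if (k1 > min(100, res$n_set[i])) 0 else {
      overlap_test_p(k1, 100, res$n_set[i], 1000)
    }
  }, numeric(1))
  u <- p_gt + runif(nrow(res)) * (res$p - p_gt)
  ks <- suppressWarnings(ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.01)
  # and no anti-conservative excess at the nominal level
  expect_lte(mean(res$p < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("module overlap test agrees with the one-sided Fisher test", {
  uni <- gene_ids(20)
  res <- module_overlap_test(uni[1:8], uni[5:12], uni)
  ft <- fisher.test(matrix(c(4, 4, 4, 8), 2), alternative = "greater")
  expect_equal(res$p, ft$p.value, tolerance = 1e-10)
  expect_equal(module_overlap_test(uni[1:8], uni[1:8], uni)$overlap, 8)
  expect_equal(module_overlap_test(uni[1:10], uni[11:20], uni)$p, 1)
  expect_error(module_overlap_test(character(), uni[1:3], uni),
               class = "comorbidome_input_error")
})

test_that("the running-sum enrichment score matches hand computation", {
  scores <- c(a = 3, b = 2, c = 1, d = -1, e = -2)
  res <- gsea_preranked(scores, list(top = c("a", "b")), n_perm = 200,
                        seed = 1, min_size = 1, max_size = 5)
  # hits weight 3/5 then 2/5; running sum 0.6, 1.0, then decreasing
  expect_equal(res$ES, 1.0, tolerance = 1e-12)
  expect_setequal(res$leading_edge[[1]], c("a", "b"))

  whole <- gsea_preranked(scores, list(all = names(scores)), n_perm = 100,
                          seed = 1, min_size = 1, max_size = 5)
  expect_equal(whole$ES, 1.0)

  bottom <- gsea_preranked(scores, list(low = c("d", "e")), n_perm = 200,
                           seed = 1, min_size = 1, max_size = 5)
  expect_lt(bottom$ES, 0)
  expect_equal(sign(bottom$NES), sign(bottom$ES))
})

test_that("enrichment scores agree with fgsea's statistic", {
  skip_if_not_installed("fgsea")
  set.seed(8)
  scores <- setNames(rnorm(200), gene_ids(200))
  ord <- order(-scores, names(scores))
  ranked <- scores[ord]
  for (i in 1:10) {
    members <- sample(names(scores), 15)
    res <- gsea_preranked(scores, list(s = members), n_perm = 100, seed = 2,
                          min_size = 1, max_size = 200)
    ref <- fgsea::calcGseaStat(unname(ranked),
                               sort(match(members, names(ranked))),
                               gseaParam = 1)
    expect_equal(res$ES, ref, tolerance = 1e-10)
  }
})

test_that("ES invariances hold for the two weighting modes", {
  set.seed(9)
  scores <- setNames(rnorm(100), gene_ids(100))
  members <- sample(names(scores), 12)
  es <- function(sc, wp) {
    gsea_preranked(sc, list(s = members), weight_p = wp, n_perm = 100,
                   seed = 3, min_size = 1, max_size = 100)$ES
  }
  # weight 0: invariant to any strictly monotone transform
  expect_equal(es(scores, 0), es(sign(scores) * abs(scores)^3 + 2, 0),
               tolerance = 1e-12)
  # weight 1: invariant to positive rescaling
  expect_equal(es(scores, 1), es(scores * 7.3, 1), tolerance = 1e-12)
})

test_that("permutation p-values detect a planted top set and stay honest", {
  scores <- setNames(sort(rnorm(500), decreasing = TRUE), gene_ids(500))
  sets <- c(list(planted = names(scores)[1:20]),
            sim_gene_sets(names(scores), 10, c(20, 40), seed = 4))
  res <- gsea_preranked(scores, sets, n_perm = 500, seed = 5,
                        min_size = 15, max_size = 100)
  planted <- res[res$set == "planted", ]
  expect_gt(planted$NES, 0)
  expect_lt(planted$padj, 0.05)
  expect_gte(min(res$p), 1 / 501)

  # random sets should not be enriched at the nominal level too often
  rand <- res[res$set != "planted", ]
  expect_lte(mean(rand$p < 0.05), 0.3)
})

test_that("gsea is deterministic given a seed and skips tiny sets", {
  scores <- setNames(rnorm(100), gene_ids(100))
  sets <- list(big = names(scores)[1:20], tiny = names(scores)[1:3])
  r1 <- suppressMessages(gsea_preranked(scores, sets, n_perm = 100, seed = 11))
  r2 <- suppressMessages(gsea_preranked(scores, sets, n_perm = 100, seed = 11))
  expect_identical(r1, r2)
  expect_false("tiny" %in% r1$set)
  expect_message(gsea_preranked(scores, sets, n_perm = 100, seed = 1),
                 "skipped")
})
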