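test_that("quadrant counts are computed over the shared universe", {
  uni <- gene_ids(120)
  sig_a <- toy_signature("A", uni, up = uni[1:10], down = uni[21:30])
  # identity pair
  qa <- quadrant_counts(sig_a, sig_a)
  expect_equal(unname(qa$counts), c(10, 10, 0, 0))
  # forced overlap of 5
  sig_b <- toy_signature("B", uni, up = c(uni[1:5], uni[90:94]),
                         down = uni[31:40])
  qb <- quadrant_counts(sig_a, sig_b)
  expect_equal(qb$counts[["uu"]], 5)
  expect_equal(qb$counts[["ud"]], 0)
  # relabeling genes leaves counts unchanged
  relab <- setNames(rev(uni), uni)
  sig_a2 <- toy_signature("A", unname(relab[uni]), unname(relab[sig_a$up]),
                          unname(relab[sig_a$down]))
  sig_b2 <- toy_signature("B", unname(relab[uni]), unname(relab[sig_b$up]),
                          unname(relab[sig_b$down]))
  expect_equal(quadrant_counts(sig_a2, sig_b2)$counts, qb$counts)
  # universe floor
  expect_error(quadrant_counts(sig_a, sig_b, min_universe = 500),
               class = "comorbidome_input_error")
})

test_that("quadrant Fisher p-values match exact enumeration", {
  # N = 20, |A| = 5, |B| = 5, overlap = 4: p = 76/15504
  expect_equal(overlap_test_p(4, 5, 5, 20), 76 / 15504, tolerance = 1e-12)
  expect_equal(overlap_test_p(0, 5, 5, 20), 1)
  expect_error(overlap_test_p(6, 5, 5, 20), class = "comorbidome_input_error")

  # random tables with N <= 30 against the counting oracle and fisher.test
  set.seed(13)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    sa <- sample(1:n, 1)
    sb <- sample(1:n, 1)
    ov_range <- max(0, sa + sb - n):min(sa, sb)
    ov <- ov_range[sample.int(length(ov_range), 1)]
    p <- overlap_test_p(ov, sa, sb, n)
    expect_equal(p, enum_overlap_p(ov, sa, sb, n), tolerance = 1e-12)
    ft <- fisher.test(matrix(c(ov, sa - ov, sb - ov, n - sa - sb + ov), 2),
                      alternative = "greater")
    expect_equal(p, ft$p.value, tolerance = 1e-10)
  }
})

test_that("increasing overlap at fixed margins never increases p", {
  for (sa in c(3, 8)) {
    for (sb in c(5, 10)) {
      n <- 25
      ovs <- max(0, sa + sb - n):min(sa, sb)
      ps <- overlap_test_p(ovs, sa, sb, n)
      expect_true(all(diff(ps) <= 1e-15))
    }
  }
})

test_that("pair classification follows the quadrant decision rule", {
  expect_equal(classify_pair(c(uu = 0.001, dd = 0.003, ud = 0.4, du = 0.6)),
               "SDDC")
  expect_equal(classify_pair(c(uu = 0.4, dd = 0.6, ud = 0.001, du = 0.003)),
               "ODDC")
  expect_equal(classify_pair(c(uu = 0.01, dd = 0.01, ud = 0.01, du = 0.01)),
               "mixed")
  expect_equal(classify_pair(c(uu = 0.01, dd = 0.5, ud = 0.5, du = 0.04)),
               "none")
  expect_equal(classify_pair(c(uu = 0.01, dd = 0.5, ud = 0.01, du = 0.04)),
               "ODDC")
  expect_error(classify_pair(c(0.1, 0.2, 0.3)),
               class = "comorbidome_input_error")
})

test_that("profile correlations match the textbook formulas", {
  mu <- setNames(rnorm(20), gene_ids(20))
  expect_equal(profile_correlation(mu, mu)$r, 1)
  expect_equal(profile_correlation(mu, -mu)$r, -1)
  a <- setNames(c(1.2, -0.5, 0.3, 2.1, -1.7, 0.9, -0.2, 1.5, -0.8, 0.1),
                gene_ids(10))
  b <- setNames(c(0.7, 0.2, -0.9, 1.8, -1.1, 0.4, 0.6, 1.2, -1.4, -0.3),
                gene_ids(10))
  r_ref <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(profile_correlation(a, b)$r, r_ref, tolerance = 1e-12)
  rs_ref <- cor(rank(a), rank(b))
  expect_equal(profile_correlation(a, b, "spearman")$r, rs_ref,
               tolerance = 1e-12)
  expect_error(profile_correlation(a[1:2], b[1:2]),
               class = "comorbidome_input_error")
})

test_that("swapping diseases mirrors the cross quadrants only", {
  uni <- gene_ids(200)
  sig_a <- toy_signature("A", uni, uni[1:15], uni[31:45])
  sig_b <- toy_signature("B", uni, c(uni[1:6], uni[61:66]),
                         c(uni[31:36], uni[81:88]))
  ab <- fisher_quadrant_tests(quadrant_counts(sig_a, sig_b))
  ba <- fisher_quadrant_tests(quadrant_counts(sig_b, sig_a))
  get <- function(df, qd, col) df[[col]][df$quadrant == qd]
  expect_equal(get(ab, "uu", "p"), get(ba, "uu", "p"))
  expect_equal(get(ab, "dd", "p"), get(ba, "dd", "p"))
  expect_equal(get(ab, "ud", "overlap"), get(ba, "du", "overlap"))
  expect_equal(get(ab, "ud", "p"), get(ba, "du", "p"))
})

test_that("compare_all recovers planted pair structure end to end", {
  res_same <- pair_signatures(61, "same")
  out_same <- compare_all(list(A = res_same$a), list(B = res_same$b))
  expect_equal(out_same$label, "SDDC")
  expect_gt(out_same$r, 0)

  res_opp <- pair_signatures(62, "opposite")
  out_opp <- compare_all(list(A = res_opp$a), list(B = res_opp$b))
  expect_equal(out_opp$label, "ODDC")
  expect_lt(out_opp$r, 0)

  res_none <- pair_signatures(63, "none")
  out_none <- compare_all(list(A = res_none$a), list(B = res_none$b))
  expect_equal(out_none$label, "none")
})

test_that("null pairs are rarely labeled, controlling the error rate", {
  # planted-null signatures built directly: independent random up/down sets
  set.seed(99)
  uni <- gene_ids(2000)
  rand_sig <- function(id) {
    picks <- sample(uni, 300)
    toy_signature(id, uni, picks[1:150], picks[151:300])
  }
  ndg <- rand_sig("NDG")
  cancers <- lapply(1:100, function(i) rand_sig(paste0("C", i)))
  names(cancers) <- paste0("C", 1:100)
  out <- compare_all(list(NDG = ndg), cancers)
  frac <- mean(out$label != "none")
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / 100))
})
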