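test_that("hedges_g matches the standardized-mean-difference formulas", {
  # degenerate and symmetric cases
  expect_error(hedges_g(c(5, 5, 5), c(5, 5, 5)),
               class = "comorbidome_degenerate_error")
  expect_error(hedges_g(c(1), c(0, 1)), class = "comorbidome_input_error")
  eq <- hedges_g(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$d, 0)
  expect_equal(eq$var_d, (3 + 3) / (3 * 3))

  # direct evaluation of the stated formulas, written out independently
  case <- c(2, 3, 4)
  ctrl <- c(0, 1, 2)
  sp <- sqrt(((3 - 1) * var(case) + (3 - 1) * var(ctrl)) / (3 + 3 - 2))
  j <- 1 - 3 / (4 * 6 - 9)
  d_ref <- j * (mean(case) - mean(ctrl)) / sp
  v_ref <- 6 / 9 + d_ref^2 / 12
  got <- hedges_g(case, ctrl)
  expect_equal(got$d, d_ref, tolerance = 1e-12)
  expect_equal(got$var_d, v_ref, tolerance = 1e-12)
})

test_that("hedges_g agrees with metafor's SMD computation", {
  skip_if_not_installed("metafor")
  set.seed(42)
  for (i in 1:5) {
    case <- rnorm(6 + i, mean = 0.5)
    ctrl <- rnorm(9 - i)
    ref <- metafor::escalc(
      measure = "SMD", m1i = mean(case), m2i = mean(ctrl),
      sd1i = sd(case), sd2i = sd(ctrl),
      n1i = length(case), n2i = length(ctrl), vtype = "LS"
    )
    got <- hedges_g(case, ctrl)
    # metafor applies the exact gamma-function bias correction; ours is the
    # standard 1 - 3/(4m - 1) approximation, so agreement is near, not exact
    expect_equal(got$d, as.numeric(ref$yi), tolerance = 1e-2)
    expect_equal(got$var_d, as.numeric(ref$vi), tolerance = 1e-2)
  }
})

test_that("dersimonian_laird reproduces its closed-form worked example", {
  one <- dersimonian_laird(0.8, 0.04)
  expect_equal(one$mu_hat, 0.8)
  expect_equal(one$se, 0.2)
  expect_equal(one$tau2, 0)
  expect_equal(one$Q, 0)

  hom <- dersimonian_laird(rep(1.2, 4), rep(0.1, 4))
  expect_equal(hom$Q, 0)
  expect_equal(hom$tau2, 0)
  expect_equal(hom$mu_hat, 1.2)

  # stepwise hand evaluation: w = (4, 4); d_FE = 1; Q = 2;
  # tau2 = (2 - 1) / (8 - 32/8) = 0.25; w* = (2, 2); mu = 1; se = 0.5
  ex <- dersimonian_laird(c(0.5, 1.5), c(0.25, 0.25))
  expect_equal(ex$Q, 2, tolerance = 1e-12)
  expect_equal(ex$tau2, 0.25, tolerance = 1e-12)
  expect_equal(ex$mu_hat, 1.0, tolerance = 1e-12)
  expect_equal(ex$se, 0.5, tolerance = 1e-12)

  expect_error(dersimonian_laird(numeric(), numeric()),
               class = "comorbidome_input_error")
})

test_that("dersimonian_laird agrees with metafor's DL estimator", {
  skip_if_not_installed("metafor")
  set.seed(7)
  for (i in 1:5) {
    d <- rnorm(5, 0.5, 0.5)
    v <- runif(5, 0.05, 0.3)
    ref <- suppressWarnings(metafor::rma(yi = d, vi = v, method = "DL"))
    got <- dersimonian_laird(d, v)
    expect_equal(got$mu_hat, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(got$se, as.numeric(ref$se), tolerance = 1e-10)
    expect_equal(got$tau2, as.numeric(ref$tau2), tolerance = 1e-10)
    expect_equal(got$Q, as.numeric(ref$QE), tolerance = 1e-10)
  }
})

test_that("bh_adjust performs the step-up procedure", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.8)),
               c(0.04, 0.04, 4 * 0.04 / 3, 0.8),
               tolerance = 1e-12)
  p <- c(0.3, 0.001, 0.04, 0.7, 0.02)
  perm <- c(4, 2, 5, 1, 3)
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  expect_error(bh_adjust(c(0.5, 1.2)), class = "comorbidome_input_error")
  # monotone in p after sorting
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= 0))
})

test_that("meta_analyze recovers planted genes with the right sign", {
  cfg <- toy_cohort(21)
  m <- suppressMessages(meta_analyze(sim_expression_cohort(cfg),
                                     disease_id = "toy"))
  expect_gte(mean(cfg$up_set %in% m$signature$up), 0.9)
  expect_gte(mean(cfg$down_set %in% m$signature$down), 0.9)
  hits <- m$table[m$table$gene %in% cfg$up_set & m$table$q < 0.05, ]
  expect_true(all(hits$mu_hat > 0))
  # weighted-mean property: mu_hat within the per-study effect range
  eff <- comorbidome:::effect_matrices(sim_expression_cohort(cfg),
                                       m$table$gene)
  rng_lo <- apply(eff$d, 1, min)
  rng_hi <- apply(eff$d, 1, max)
  expect_true(all(m$table$mu_hat >= rng_lo - 1e-12 &
                    m$table$mu_hat <= rng_hi + 1e-12))
})

test_that("a homogeneous null cohort matches chi-square heterogeneity", {
  cfg <- cohort_config(n_studies = 6, n_cases = 20, n_controls = 20,
                       n_genes = 5000, n_up = 0, n_down = 0,
                       effect_mu = 0, tau = 0, seed = 31)
  m <- suppressMessages(meta_analyze(sim_expression_cohort(cfg)))
  # E[Q] = k - 1 under homogeneity
  expect_lt(abs(mean(m$table$Q) - 5) / 5, 0.05)
  expect_equal(sum(m$table$q < 0.05), 0)
})

test_that("meta-analysis estimator concentrates as the cohort grows", {
  est <- vapply(list(c(3, 8), c(8, 30)), function(sz) {
    cfg <- cohort_config(n_studies = sz[1], n_cases = sz[2],
                         n_controls = sz[2], n_genes = 300, n_up = 50,
                         n_down = 0, effect_mu = 1, tau = 0.05, seed = 17)
    m <- suppressMessages(meta_analyze(sim_expression_cohort(cfg)))
    mean(m$table$mu_hat[m$table$gene %in% cfg$up_set])
  }, numeric(1))
  expect_lt(abs(est[2] - 1), abs(est[1] - 1))
})

test_that("study-level QC flags a scrambled, effect-inverted study", {
  cfg <- toy_cohort(41, n_studies = 5)
  studies <- sim_expression_cohort(cfg)
  clean <- qc_filter_studies(studies)
  expect_length(clean$excluded, 0)
  expect_true(all(clean$scores$score < 7))

  flagged <- vapply(1:20, function(s) {
    cfg_s <- toy_cohort(400 + s, n_studies = 5)
    st <- sim_expression_cohort(cfg_s)
    bad <- st[[3]]
    ci <- bad$groups == "case"
    flipped <- bad$matrix
    flipped[, ci] <- bad$matrix[, !ci]
    flipped[, !ci] <- bad$matrix[, ci]
    st[[3]] <- expression_study(bad$study_id, flipped, bad$groups)
    sc <- qc_filter_studies(st)$scores
    which.max(sc$score) == 3
  }, logical(1))
  expect_gte(mean(flagged), 0.9)

  ident <- qc_filter_studies(studies, srm_threshold = Inf)
  expect_length(ident$kept, length(studies))
})

test_that("sample outlier detection removes a pure-noise sample", {
  cfg <- toy_cohort(51, n_studies = 1)
  clean <- sim_expression_cohort(cfg)[[1]]
  expect_length(detect_sample_outliers(clean)$removed, 0)
  expect_length(detect_sample_outliers(clean, mad_k = Inf)$removed, 0)

  hit <- vapply(1:20, function(s) {
    st <- sim_expression_cohort(toy_cohort(500 + s, n_studies = 1))[[1]]
    mat <- st$matrix
    set.seed(9000 + s)
    mat[, 4] <- rnorm(nrow(mat), 8, 2)
    noisy <- expression_study(st$study_id, mat, st$groups)
    out <- detect_sample_outliers(noisy)
    identical(out$removed, colnames(mat)[4])
  }, logical(1))
  expect_gte(mean(hit), 0.95)

  tiny <- expression_study("t", matrix(rnorm(40), 10, 4,
                                       dimnames = list(letters[1:10], NULL)),
                           c("case", "case", "control", "control"))
  expect_error(detect_sample_outliers(tiny, mad_k = 0),
               class = "comorbidome_input_error")
})

test_that("external DE tables enter through as_disease_signature", {
  tab <- tibble::tibble(gene = gene_ids(10),
                        effect = c(2, -2, 1, 0.1, -0.1, 3, -3, 0.2, 0, 1),
                        q = c(0.01, 0.01, 0.2, 0.6, 0.7, 0.001, 0.001,
                              0.9, 1, 0.04))
  sig <- as_disease_signature(tab, "ext")
  expect_setequal(sig$up, c("g00001", "g00006", "g00010"))
  expect_setequal(sig$down, c("g00002", "g00007"))
  expect_equal(unname(sig$mu["g00003"]), 1)
})
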