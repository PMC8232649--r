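#' Construct an expression study
#'
#' One cohort's gene-by-sample log2 expression matrix with case/control labels.
#'
#' @param study_id Study identifier.
#' @param matrix Numeric matrix, rows named by gene, columns by sample.
#' @param groups Character vector (`"case"`/`"control"`) aligned to columns.
#' @return An `expression_study` object.
#' @export
expression_study <- function(study_id, matrix, groups) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    abort_input("`matrix` must be a numeric matrix.")
  }
  if (is.null(rownames(matrix)) || anyDuplicated(rownames(matrix))) {
    abort_input("Rows must carry unique gene identifiers.")
  }
  if (!all(is.finite(matrix))) abort_input("Expression values must be finite.")
  groups <- as.character(groups)
  if (length(groups) != ncol(matrix) || !all(groups %in% c("case", "control"))) {
    abort_input("`groups` must label every column as case or control.")
  }
  if (sum(groups == "case") < 2 || sum(groups == "control") < 2) {
    abort_input("Need at least 2 cases and 2 controls.")
  }
  if (is.null(colnames(matrix))) {
    colnames(matrix) <- sprintf("%s_smp%03d", study_id, seq_len(ncol(matrix)))
  }
  structure(
    list(study_id = as.character(study_id), matrix = matrix, groups = groups),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> %s: %d genes, %d cases / %d controls\n",
              x$study_id, nrow(x$matrix),
              sum(x$groups == "case"), sum(x$groups == "control")))
  invisible(x)
}

#' Hedges' g standardized mean difference
#'
#' Computes the small-sample-corrected standardized mean difference between
#' cases and controls, `d = J * (mean_case - mean_control) / s_pooled` with
#' `J = 1 - 3 / (4 * (n1 + n2) - 9)`, and its sampling variance
#' `var_d = (n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2))`. Positive `d`
#' means higher expression in cases.
#'
#' @param case_values,control_values Numeric vectors with at least 2 finite
#'   values each.
#' @return A list with elements `d` and `var_d`.
#' @examples
#' hedges_g(c(2, 3, 4), c(0, 1, 2))
#' @export
hedges_g <- function(case_values, control_values) {
  n1 <- length(case_values)
  n2 <- length(control_values)
  if (n1 < 2 || n2 < 2 ||
      !all(is.finite(case_values)) || !all(is.finite(control_values))) {
    abort_input("Each group needs >= 2 finite values.")
  }
  sp2 <- ((n1 - 1) * var(case_values) + (n2 - 1) * var(control_values)) /
    (n1 + n2 - 2)
  if (sp2 <= 0) {
    abort_degenerate("Pooled variance is zero; effect size undefined.")
  }
  j <- 1 - 3 / (4 * (n1 + n2) - 9)
  d <- j * (mean(case_values) - mean(control_values)) / sqrt(sp2)
  var_d <- (n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2))
  list(d = d, var_d = var_d)
}

# vectorized per-gene Hedges g for one study; returns list(d, var_d) vectors
hedges_g_matrix <- function(mat, case_idx, ctrl_idx) {
  n1 <- length(case_idx)
  n2 <- length(ctrl_idx)
  m1 <- rowMeans(mat[, case_idx, drop = FALSE])
  m2 <- rowMeans(mat[, ctrl_idx, drop = FALSE])
  v1 <- rowSums((mat[, case_idx, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((mat[, ctrl_idx, drop = FALSE] - m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  j <- 1 - 3 / (4 * (n1 + n2) - 9)
  d <- ifelse(sp2 > 0, j * (m1 - m2) / sqrt(sp2), NA_real_)
  var_d <- (n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2))
  list(d = d, var_d = var_d)
}

#' DerSimonian-Laird random-effects combination
#'
#' Combines k study-level effect sizes under the random-effects model:
#' fixed-effect weights `w_i = 1/var_i` give the Cochran heterogeneity
#' statistic `Q = sum(w_i * (d_i - d_FE)^2)`; the between-study variance is
#' `tau2 = max(0, (Q - (k - 1)) / (sum(w) - sum(w^2)/sum(w)))` (truncated at
#' zero, the DL convention); random-effect weights `1/(var_i + tau2)` yield
#' the combined effect and its standard error. With `k = 1` the single effect
#' is passed through with `Q = tau2 = 0`.
#'
#' @param d Numeric vector of study effect sizes.
#' @param var_d Their sampling variances (all positive).
#' @return A list with `mu_hat`, `se`, `Q`, `tau2`, `k`.
#' @examples
#' dersimonian_laird(c(0.5, 1.5), c(0.25, 0.25))
#' @export
dersimonian_laird <- function(d, var_d) {
  if (length(d) == 0) abort_input("Need at least one effect size.")
  if (length(d) != length(var_d) || anyNA(d) || anyNA(var_d) ||
      any(var_d <= 0)) {
    abort_input("`d` and `var_d` must align, be complete, with var_d > 0.")
  }
  k <- length(d)
  if (k == 1) {
    return(list(mu_hat = d, se = sqrt(var_d), Q = 0, tau2 = 0, k = 1L))
  }
  w <- 1 / var_d
  d_fe <- sum(w * d) / sum(w)
  q <- sum(w * (d - d_fe)^2)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (var_d + tau2)
  mu <- sum(ws * d) / sum(ws)
  list(mu_hat = mu, se = 1 / sqrt(sum(ws)), Q = q, tau2 = tau2, k = k)
}

# row-wise DL over effect/variance matrices (genes x studies, NA = missing)
dl_rows <- function(d_mat, v_mat) {
  obs <- is.finite(d_mat) & is.finite(v_mat)
  w <- ifelse(obs, 1 / v_mat, 0)
  dz <- ifelse(obs, d_mat, 0)
  k <- rowSums(obs)
  sw <- rowSums(w)
  d_fe <- ifelse(sw > 0, rowSums(w * dz) / sw, NA_real_)
  q <- rowSums(w * (dz - d_fe)^2)
  cdenom <- sw - rowSums(w^2) / sw
  tau2 <- pmax(0, (q - (k - 1)) / cdenom)
  tau2[k <= 1 | !is.finite(tau2)] <- 0
  ws <- ifelse(obs, 1 / (v_mat + tau2), 0)
  sws <- rowSums(ws)
  mu <- ifelse(sws > 0, rowSums(ws * dz) / sws, NA_real_)
  se <- ifelse(sws > 0, 1 / sqrt(sws), NA_real_)
  q[k <= 1] <- 0
  list(mu_hat = unname(mu), se = unname(se), Q = unname(q),
       tau2 = unname(tau2), k = unname(k))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH procedure (via [stats::p.adjust()]) with input validation.
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @return Adjusted q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  check_probs(p_values, "p_values")
  stats::p.adjust(p_values, method = "BH")
}

#' Construct a disease signature
#'
#' Up/down significant gene sets at an FDR threshold plus the full vector of
#' combined effects over the tested universe.
#'
#' @param disease_id Identifier.
#' @param universe Character vector of tested genes.
#' @param up,down Significant gene sets (`q < alpha`, split by effect sign).
#' @param mu Named numeric vector of combined effects over the universe.
#' @param alpha FDR threshold the sets were extracted at.
#' @return A `disease_signature` object.
#' @export
disease_signature <- function(disease_id, universe, up, down, mu,
                              alpha = 0.05) {
  universe <- as.character(universe)
  up <- as.character(up)
  down <- as.character(down)
  if (length(intersect(up, down)) > 0) {
    abort_input("`up` and `down` must be disjoint.")
  }
  if (!all(c(up, down) %in% universe)) {
    abort_input("Signature genes must lie inside the universe.")
  }
  if (is.null(names(mu)) || !all(universe %in% names(mu))) {
    abort_input("`mu` must cover the universe with named values.")
  }
  structure(
    list(disease_id = as.character(disease_id), universe = universe,
         up = up, down = down, mu = mu[universe], alpha = alpha),
    class = "disease_signature"
  )
}

#' @export
print.disease_signature <- function(x, ...) {
  cat(sprintf("<disease_signature> %s: %d genes tested, %d up / %d down (q < %g)\n",
              x$disease_id, length(x$universe), length(x$up),
              length(x$down), x$alpha))
  invisible(x)
}

#' Build a disease signature from a plain differential-expression table
#'
#' Entry point for externally produced DE results (columns `gene`, `effect`,
#' `q`), e.g. a validation cohort analyzed elsewhere.
#'
#' @param table Data frame with columns `gene`, `effect`, `q`.
#' @param disease_id Identifier.
#' @param alpha FDR threshold for membership in the up/down sets.
#' @return A [disease_signature()].
#' @export
as_disease_signature <- function(table, disease_id, alpha = 0.05) {
  if (!all(c("gene", "effect", "q") %in% names(table))) {
    abort_input("`table` needs columns gene, effect, q.")
  }
  sig <- table$q < alpha & is.finite(table$effect)
  disease_signature(
    disease_id,
    universe = table$gene,
    up = table$gene[sig & table$effect > 0],
    down = table$gene[sig & table$effect < 0],
    mu = setNames(table$effect, table$gene),
    alpha = alpha
  )
}

#' Random-effects differential-expression meta-analysis
#'
#' Per gene, per-study Hedges' g effects are combined by DerSimonian-Laird;
#' `z = mu_hat / se` gives a two-sided normal p-value, adjusted by BH across
#' the genes tested in at least `min_k` studies. Genes observed in fewer than
#' `min_k` studies are kept in the table but flagged (`analyzed = FALSE`) and
#' excluded from FDR adjustment and the signature.
#'
#' @param studies List of [expression_study()] objects.
#' @param alpha FDR threshold for the extracted signature.
#' @param min_k Minimum number of contributing studies per gene.
#' @param disease_id Identifier carried into the signature.
#' @return A `meta_dge` object: `table` (tibble with columns `gene`, `k`,
#'   `mu_hat`, `se`, `z`, `p`, `q`, `Q`, `tau2`, `analyzed`), `signature`
#'   (a [disease_signature()]), and bookkeeping fields. [tidy()] returns the
#'   gene table; [glance()] a one-row cohort summary.
#' @export
meta_analyze <- function(studies, alpha = 0.05, min_k = 2,
                         disease_id = "disease") {
  if (length(studies) == 0 ||
      !all(vapply(studies, inherits, TRUE, "expression_study"))) {
    abort_input("`studies` must be a non-empty list of expression_study.")
  }
  alpha <- check_number(alpha, "alpha", 0, 1)
  min_k <- check_count(min_k, "min_k")
  genes <- sort(unique(unlist(lapply(studies, function(s) rownames(s$matrix)))))
  if (length(genes) == 0) abort_input("Empty gene universe.")
  k_obs <- rowSums(vapply(studies,
                          function(s) genes %in% rownames(s$matrix),
                          logical(length(genes))))
  if (!any(k_obs >= min_k)) {
    abort_input("No gene is observed in `min_k` studies.")
  }
  eff <- effect_matrices(studies, genes)
  dl <- dl_rows(eff$d, eff$v)
  z <- dl$mu_hat / dl$se
  p <- 2 * pnorm(-abs(z))
  analyzed <- dl$k >= min_k & is.finite(p)
  q <- rep(NA_real_, length(genes))
  q[analyzed] <- bh_adjust(p[analyzed])
  n_flagged <- sum(!analyzed)
  if (n_flagged > 0) {
    inform(sprintf("%d gene(s) observed in fewer than %d studies were flagged and excluded from FDR adjustment.",
                   n_flagged, min_k))
  }
  table <- tibble(
    gene = genes, k = as.integer(dl$k), mu_hat = dl$mu_hat, se = dl$se,
    z = z, p = p, q = q, Q = dl$Q, tau2 = dl$tau2, analyzed = analyzed
  )
  sig_genes <- table$gene[analyzed]
  mu <- setNames(table$mu_hat, table$gene)[sig_genes]
  sig <- disease_signature(
    disease_id,
    universe = sig_genes,
    up = table$gene[analyzed & !is.na(table$q) & table$q < alpha & table$mu_hat > 0],
    down = table$gene[analyzed & !is.na(table$q) & table$q < alpha & table$mu_hat < 0],
    mu = mu, alpha = alpha
  )
  structure(
    list(table = table, signature = sig, alpha = alpha, min_k = min_k,
         disease_id = disease_id, n_studies = length(studies),
         n_flagged = n_flagged),
    class = "meta_dge"
  )
}

# per-study effect and variance matrices over a common gene vector
effect_matrices <- function(studies, genes) {
  k <- length(studies)
  d_mat <- matrix(NA_real_, length(genes), k,
                  dimnames = list(genes, vapply(studies, `[[`, "", "study_id")))
  v_mat <- d_mat
  for (i in seq_len(k)) {
    s <- studies[[i]]
    idx <- match(rownames(s$matrix), genes)
    hg <- hedges_g_matrix(s$matrix, which(s$groups == "case"),
                          which(s$groups == "control"))
    d_mat[idx, i] <- hg$d
    v_mat[idx, i] <- hg$var_d
  }
  list(d = d_mat, v = v_mat)
}

#' @export
print.meta_dge <- function(x, ...) {
  cat(sprintf("<meta_dge> %s: %d studies, %d genes (%d up / %d down at q < %g)\n",
              x$disease_id, x$n_studies, nrow(x$table),
              length(x$signature$up), length(x$signature$down), x$alpha))
  invisible(x)
}

#' Study-level quality-control filter
#'
#' Scores each study by the mean absolute standardized leave-one-out residual:
#' the study's gene-wise effect vector is compared to the meta-analytic effect
#' recomputed without that study, standardized by the study's per-gene sampling
#' standard deviation, and summarized by the mean absolute value. Studies with
#' scores above `srm_threshold` are excluded. A concordant study scores near
#' the standard-normal mean absolute deviation (about 0.8); a study with
#' inverted or scrambled effects scores the highest of its cohort.
#'
#' @param studies List of [expression_study()] objects.
#' @param srm_threshold Exclusion threshold (default 7).
#' @return A list with `kept`, `excluded` (lists of studies) and `scores`
#'   (tibble `study_id`, `score`, `excluded`).
#' @export
qc_filter_studies <- function(studies, srm_threshold = 7) {
  if (length(studies) == 0) abort_input("Need at least one study.")
  if (length(srm_threshold) != 1 || is.na(srm_threshold) ||
      srm_threshold < 0) {
    abort_input("`srm_threshold` must be a single non-negative number.")
  }
  ids <- vapply(studies, `[[`, "", "study_id")
  if (length(studies) < 3) {
    scores <- rep(NA_real_, length(studies))
  } else {
    genes <- sort(unique(unlist(lapply(studies,
                                       function(s) rownames(s$matrix)))))
    eff <- effect_matrices(studies, genes)
    scores <- vapply(seq_along(studies), function(i) {
      loo <- dl_rows(eff$d[, -i, drop = FALSE], eff$v[, -i, drop = FALSE])
      zres <- (eff$d[, i] - loo$mu_hat) / sqrt(eff$v[, i])
      mean(abs(zres), na.rm = TRUE)
    }, numeric(1))
  }
  out <- !is.na(scores) & scores > srm_threshold
  list(
    kept = studies[!out],
    excluded = studies[out],
    scores = tibble(study_id = ids, score = scores, excluded = out)
  )
}

#' Detect outlying samples within a study
#'
#' Samples whose mean correlation with the other samples falls more than
#' `mad_k` median absolute deviations below the study median are removed; one
#' removal pass is performed.
#'
#' @param study An [expression_study()].
#' @param mad_k MAD multiplier (default 5; `Inf` disables removal).
#' @return A list with `kept`, `removed` (sample ids) and `scores`
#'   (tibble `sample_id`, `group`, `mean_cor`, `kept`).
#' @export
detect_sample_outliers <- function(study, mad_k = 5) {
  if (!inherits(study, "expression_study")) {
    abort_input("`study` must be an expression_study.")
  }
  if (ncol(study$matrix) < 4) abort_input("Need at least 4 samples.")
  if (length(mad_k) != 1 || is.na(mad_k) || mad_k < 0) {
    abort_input("`mad_k` must be a single non-negative number.")
  }
  cm <- cor(study$matrix)
  n <- ncol(cm)
  mean_cor <- (colSums(cm) - 1) / (n - 1)
  med <- median(mean_cor)
  madv <- mad(mean_cor)
  cut <- if (is.infinite(mad_k)) -Inf else med - mad_k * madv
  keep <- mean_cor >= cut
  kept_groups <- study$groups[keep]
  if (sum(kept_groups == "case") < 2 || sum(kept_groups == "control") < 2) {
    abort_input("Outlier removal would leave fewer than 2 cases or controls.")
  }
  list(
    kept = colnames(study$matrix)[keep],
    removed = colnames(study$matrix)[!keep],
    scores = tibble(sample_id = colnames(study$matrix),
                    group = study$groups, mean_cor = mean_cor, kept = keep)
  )
}

#' Drop flagged samples from a study
#'
#' @param study An [expression_study()].
#' @param keep Sample identifiers to retain.
#' @return A new [expression_study()] restricted to `keep`.
#' @export
subset_samples <- function(study, keep) {
  idx <- match(keep, colnames(study$matrix))
  if (anyNA(idx)) abort_input("Unknown sample identifiers.")
  expression_study(study$study_id, study$matrix[, idx, drop = FALSE],
                   study$groups[idx])
}
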