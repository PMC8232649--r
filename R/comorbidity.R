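#' Four-quadrant intersection counts for a disease pair
#'
#' Restricts both signatures to their shared tested universe and counts the
#' genes at the four intersections of significantly up- and downregulated
#' genes: up/up, down/down, up(A)/down(B), and down(A)/up(B).
#'
#' @param sig_a,sig_b [disease_signature()] objects.
#' @param min_universe Minimum size of the shared universe (floor, default
#'   100).
#' @return A `quadrant_counts` list: pair ids, shared universe size `n`,
#'   restricted set sizes, and the four counts `n_uu`, `n_dd`, `n_ud`, `n_du`.
#' @export
quadrant_counts <- function(sig_a, sig_b, min_universe = 100) {
  if (!inherits(sig_a, "disease_signature") ||
      !inherits(sig_b, "disease_signature")) {
    abort_input("Both inputs must be disease_signatures.")
  }
  shared <- intersect(sig_a$universe, sig_b$universe)
  if (length(shared) == 0) abort_input("Empty shared universe.")
  if (length(shared) < min_universe) {
    abort_input(sprintf("Shared universe (%d) below the floor of %d genes.",
                        length(shared), min_universe))
  }
  up_a <- intersect(sig_a$up, shared)
  dn_a <- intersect(sig_a$down, shared)
  up_b <- intersect(sig_b$up, shared)
  dn_b <- intersect(sig_b$down, shared)
  structure(
    list(
      pair = c(sig_a$disease_id, sig_b$disease_id),
      n = length(shared),
      sizes = c(up_a = length(up_a), down_a = length(dn_a),
                up_b = length(up_b), down_b = length(dn_b)),
      counts = c(uu = length(intersect(up_a, up_b)),
                 dd = length(intersect(dn_a, dn_b)),
                 ud = length(intersect(up_a, dn_b)),
                 du = length(intersect(dn_a, up_b)))
    ),
    class = "quadrant_counts"
  )
}

#' One-sided overlap p-value for a 2x2 table
#'
#' Upper-tail hypergeometric probability `P(K >= overlap)` of seeing at least
#' the observed overlap between a set of `size_a` and a set of `size_b` drawn
#' from a universe of `n` genes — the one-sided Fisher enrichment p-value.
#' Vectorized over its arguments.
#'
#' @param overlap Observed intersection size(s).
#' @param size_a,size_b Set sizes.
#' @param n Universe size.
#' @return Numeric p-value(s).
#' @export
overlap_test_p <- function(overlap, size_a, size_b, n) {
  bad <- overlap > pmin(size_a, size_b) | size_a > n | size_b > n |
    overlap < 0 | overlap < size_a + size_b - n
  if (any(bad)) abort_input("Inconsistent 2x2 margins.")
  phyper(overlap - 1, size_b, n - size_b, size_a, lower.tail = FALSE)
}

hyper_overlap_test <- overlap_test_p

#' One-sided Fisher tests for the four quadrants
#'
#' For each quadrant (X in A, Y in B), the 2x2 table
#' `[overlap, |X| - overlap; |Y| - overlap, N - |X| - |Y| + overlap]` is tested
#' against the enrichment (greater-overlap) alternative; the one-sided p-value
#' is the upper-tail hypergeometric probability `P(K >= overlap)`. The odds
#' ratio is the sample cross-product ratio of that table (not the conditional
#' maximum-likelihood estimate).
#'
#' @param counts A [quadrant_counts()] result.
#' @return Tibble with one row per quadrant: `quadrant`, `overlap`, `size_a`,
#'   `size_b`, `n`, `odds_ratio`, `p`.
#' @export
fisher_quadrant_tests <- function(counts) {
  if (!inherits(counts, "quadrant_counts")) {
    abort_input("`counts` must come from quadrant_counts().")
  }
  spec <- list(
    uu = c("up_a", "up_b"), dd = c("down_a", "down_b"),
    ud = c("up_a", "down_b"), du = c("down_a", "up_b")
  )
  purrr::map_dfr(names(spec), function(qd) {
    sa <- counts$sizes[[spec[[qd]][1]]]
    sb <- counts$sizes[[spec[[qd]][2]]]
    ov <- counts$counts[[qd]]
    n <- counts$n
    a <- ov
    b <- sa - ov
    cc <- sb - ov
    d <- n - sa - sb + ov
    tibble(
      quadrant = qd, overlap = ov, size_a = sa, size_b = sb, n = n,
      odds_ratio = (a * d) / (b * cc),
      p = hyper_overlap_test(ov, sa, sb, n)
    )
  })
}

#' Classify a disease pair from its adjusted quadrant p-values
#'
#' A pair is a same-direction deregulated pair (`"SDDC"`) when both
#' same-direction quadrants (up/up and down/down) are significant and the two
#' cross quadrants are not both significant; an opposite-direction pair
#' (`"ODDC"`) when both cross quadrants (up/down and down/up) are significant
#' and the same-direction quadrants are not both significant; `"mixed"` when
#' all four are significant; `"none"` otherwise.
#'
#' @param q Numeric vector of four adjusted p-values named (or ordered)
#'   `uu`, `dd`, `ud`, `du`.
#' @param alpha Significance threshold.
#' @return One of `"SDDC"`, `"ODDC"`, `"mixed"`, `"none"`.
#' @export
classify_pair <- function(q, alpha = 0.05) {
  if (length(q) != 4) abort_input("Need exactly four adjusted p-values.")
  check_probs(q, "q")
  if (!is.null(names(q))) q <- q[c("uu", "dd", "ud", "du")]
  same <- q[1] < alpha && q[2] < alpha
  cross <- q[3] < alpha && q[4] < alpha
  if (same && cross) return("mixed")
  if (same) return("SDDC")
  if (cross) return("ODDC")
  "none"
}

#' Correlation between two combined-effect profiles
#'
#' Pairwise-complete correlation of the full mu-hat vectors over the shared
#' universe (all tested genes, not only the significant ones); Spearman uses
#' average ranks for ties.
#'
#' @param mu_a,mu_b Named numeric vectors of combined effects.
#' @param method `"pearson"` (default for disease-disease comparisons) or
#'   `"spearman"`.
#' @return A list with `method`, `r`, and `n` (shared genes used).
#' @export
profile_correlation <- function(mu_a, mu_b,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.null(names(mu_a)) || is.null(names(mu_b))) {
    abort_input("Profiles must be named by gene.")
  }
  shared <- intersect(names(mu_a), names(mu_b))
  a <- mu_a[shared]
  b <- mu_b[shared]
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) abort_input("Fewer than 3 shared finite genes.")
  list(method = method, r = cor(a[ok], b[ok], method = method), n = sum(ok))
}

#' Compare disease signatures pairwise
#'
#' Runs the quadrant counting, one-sided Fisher tests, FDR adjustment, pair
#' classification, and profile correlation for every pair of one
#' neurodegeneration-side and one cancer-side signature. By default the BH
#' adjustment family is all quadrant tests belonging to one
#' neurodegeneration-side signature (4 x number of cancers p-values per
#' family); `"per_pair"` and `"global"` families are available.
#'
#' @param sigs_ndg,sigs_cancer Named lists of [disease_signature()]s.
#' @param alpha Significance threshold applied to adjusted p-values.
#' @param family Multiple-testing family: `"per_ndg"` (default),
#'   `"per_pair"`, or `"global"`.
#' @param cor_method Correlation method for the mu-hat profiles.
#' @param min_universe Floor for the shared universe size.
#' @return A tibble of class `comorbidity_pairs`: one row per pair with the
#'   four counts, per-quadrant odds ratios, p- and q-values, the
#'   SDDC/ODDC/mixed/none label, and the profile correlation.
#' @export
compare_all <- function(sigs_ndg, sigs_cancer, alpha = 0.05,
                        family = c("per_ndg", "per_pair", "global"),
                        cor_method = c("pearson", "spearman"),
                        min_universe = 100) {
  family <- match.arg(family)
  cor_method <- match.arg(cor_method)
  if (length(sigs_ndg) == 0 || length(sigs_cancer) == 0) {
    abort_input("Need at least one signature on each side.")
  }
  rows <- purrr::map_dfr(sigs_ndg, function(sa) {
    purrr::map_dfr(sigs_cancer, function(sb) {
      qc <- quadrant_counts(sa, sb, min_universe = min_universe)
      ft <- fisher_quadrant_tests(qc)
      pc <- profile_correlation(sa$mu, sb$mu, method = cor_method)
      tibble(
        ndg = sa$disease_id, cancer = sb$disease_id, n_universe = qc$n,
        quadrant = ft$quadrant, overlap = ft$overlap,
        odds_ratio = ft$odds_ratio, p = ft$p,
        r = pc$r, n_cor = pc$n
      )
    })
  })
  rows$q <- switch(family,
    per_pair = {
      grp <- paste(rows$ndg, rows$cancer)
      stats::ave(rows$p, grp, FUN = bh_adjust)
    },
    per_ndg = stats::ave(rows$p, rows$ndg, FUN = bh_adjust),
    global = bh_adjust(rows$p)
  )
  wide <- rows |>
    tidyr::pivot_wider(
      names_from = "quadrant",
      values_from = c("overlap", "odds_ratio", "p", "q"),
      names_glue = "{.value}_{quadrant}"
    ) |>
    dplyr::rename(n_uu = "overlap_uu", n_dd = "overlap_dd",
                  n_ud = "overlap_ud", n_du = "overlap_du")
  wide$label <- vapply(seq_len(nrow(wide)), function(i) {
    classify_pair(c(uu = wide$q_uu[i], dd = wide$q_dd[i],
                    ud = wide$q_ud[i], du = wide$q_du[i]), alpha)
  }, character(1))
  wide$cor_method <- cor_method
  structure(
    dplyr::relocate(wide, "label", .after = "n_universe"),
    class = c("comorbidity_pairs", class(wide))
  )
}
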