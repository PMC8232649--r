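#' Overrepresentation analysis
#'
#' Upper-tail hypergeometric test of each gene set against a query set, with
#' BH adjustment across the tested sets. Sets are intersected with the
#' universe and size-filtered before testing; query genes outside the
#' universe are dropped with a message.
#'
#' @param query Character vector of query genes.
#' @param universe Character vector, the tested gene universe.
#' @param sets Named list of gene sets (e.g. [sim_gene_sets()] or
#'   [read_gmt()]).
#' @param min_size,max_size Size bounds applied after intersecting with the
#'   universe.
#' @return Tibble sorted by p: `set`, `n_set`, `overlap`, `expected`, `p`,
#'   `padj`.
#' @export
ora <- function(query, universe, sets, min_size = 5, max_size = 500) {
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  dropped <- setdiff(query, universe)
  if (length(dropped) > 0) {
    inform(sprintf("%d query gene(s) outside the universe dropped.",
                   length(dropped)))
    query <- intersect(query, universe)
  }
  if (length(query) == 0) abort_input("Empty query after universe filtering.")
  sets <- lapply(sets, function(s) intersect(unique(s), universe))
  sizes <- lengths(sets)
  sets <- sets[sizes >= min_size & sizes <= max_size]
  if (length(sets) == 0) abort_input("No gene set survives size filtering.")
  n <- length(universe)
  res <- purrr::map_dfr(names(sets), function(nm) {
    s <- sets[[nm]]
    ov <- length(intersect(query, s))
    tibble(
      set = nm, n_set = length(s), overlap = ov,
      expected = length(query) * length(s) / n,
      p = hyper_overlap_test(ov, length(query), length(s), n)
    )
  })
  res$padj <- bh_adjust(res$p)
  dplyr::arrange(res, .data$p)
}

#' Hypergeometric overlap test between two module gene lists
#'
#' Used to compare disease-associated co-expression modules between disorders;
#' the caller applies BH across all tested module pairs.
#'
#' @param module_a,module_b Non-empty gene sets, subsets of `universe`.
#' @param universe Gene universe.
#' @return One-row tibble: `n_a`, `n_b`, `n_universe`, `overlap`, `expected`,
#'   `p`.
#' @export
module_overlap_test <- function(module_a, module_b, universe) {
  universe <- unique(as.character(universe))
  module_a <- unique(as.character(module_a))
  module_b <- unique(as.character(module_b))
  if (length(module_a) == 0 || length(module_b) == 0) {
    abort_input("Modules must be non-empty.")
  }
  if (!all(c(module_a, module_b) %in% universe)) {
    abort_input("Modules must be subsets of the universe.")
  }
  ov <- length(intersect(module_a, module_b))
  tibble(
    n_a = length(module_a), n_b = length(module_b),
    n_universe = length(universe), overlap = ov,
    expected = length(module_a) * length(module_b) / length(universe),
    p = hyper_overlap_test(ov, length(module_a), length(module_b),
                           length(universe))
  )
}

# weighted Kolmogorov-Smirnov-style running-sum enrichment score.
# pos: ranked positions of the hits (ascending); w_ranked: |score|^weight_p in
# rank order for the whole list. Returns the signed maximum deviation and the
# index of the hit at (or after) which it is attained.
es_running_sum <- function(pos, w_ranked, n, weight_p) {
  pos <- sort(pos)
  nh <- length(pos)
  w <- if (weight_p == 0) rep(1, nh) else w_ranked[pos]
  tot <- sum(w)
  w <- if (tot > 0) w / tot else rep(1 / nh, nh)
  miss <- if (n > nh) 1 / (n - nh) else 0
  after <- cumsum(w) - (pos - seq_len(nh)) * miss
  before <- after - w
  cand <- c(after, before)
  i <- which.max(abs(cand))
  list(es = unname(cand[i]), at_hit = ((i - 1) %% nh) + 1)
}

#' Preranked gene set enrichment analysis
#'
#' Genes are ranked by decreasing score (ties broken by gene identifier, so
#' the ranking is deterministic). The enrichment score (ES) is the maximum
#' deviation of a running sum that increments by `|score|^weight_p`
#' (normalized by the in-set total) at set members and decrements by
#' `1/(N - N_hits)` elsewhere. Significance comes from gene-label
#' permutations: the normalized enrichment score (NES) divides ES by the mean
#' absolute permuted ES of matching sign, and the permutation p-value is the
#' matching-sign tail frequency with +1 smoothing (so `p >= 1/(n_perm + 1)`).
#' Sets whose matching-sign permutation mean is zero or absent get `NES = NA`.
#'
#' @param scores Named numeric vector of per-gene ranking scores (e.g. the
#'   `z` column of a meta-analysis table).
#' @param sets Named list of gene sets.
#' @param weight_p Hit-weight exponent (0 gives the unweighted statistic).
#' @param n_perm Number of gene-label permutations.
#' @param seed Integer seed; results are deterministic given it.
#' @param min_size,max_size Size bounds after intersection with the ranked
#'   list; sets outside the bounds are skipped with a message.
#' @return Tibble: `set`, `n_set`, `ES`, `NES`, `p`, `padj`, `leading_edge`
#'   (list-column of genes up to the ES extremum).
#' @export
gsea_preranked <- function(scores, sets, weight_p = 1, n_perm = 1000,
                           seed = 1, min_size = 15, max_size = 500) {
  if (is.null(names(scores)) || anyDuplicated(names(scores)) ||
      !all(is.finite(scores))) {
    abort_input("`scores` must be finite, uniquely named per gene.")
  }
  n_perm <- check_count(n_perm, "n_perm")
  ord <- order(-scores, names(scores))
  ranked_genes <- names(scores)[ord]
  w_ranked <- abs(scores[ord])^weight_p
  n <- length(scores)
  sets <- lapply(sets, function(s) intersect(unique(s), ranked_genes))
  sizes <- lengths(sets)
  skip <- sizes < min_size | sizes > max_size
  if (any(skip)) {
    inform(sprintf("%d set(s) outside [%d, %d] genes after filtering skipped.",
                   sum(skip), min_size, max_size))
  }
  sets <- sets[!skip]
  if (length(sets) == 0) abort_input("No gene set left to test.")
  res <- with_seed(seed, {
    purrr::map_dfr(names(sets), function(nm) {
      members <- sets[[nm]]
      pos <- sort(match(members, ranked_genes))
      obs <- es_running_sum(pos, w_ranked, n, weight_p)
      perm <- vapply(seq_len(n_perm), function(i) {
        es_running_sum(sample.int(n, length(pos)), w_ranked, n, weight_p)$es
      }, numeric(1))
      same_sign <- if (obs$es >= 0) perm[perm >= 0] else perm[perm < 0]
      nes <- if (length(same_sign) == 0 || mean(abs(same_sign)) == 0) {
        NA_real_
      } else {
        obs$es / mean(abs(same_sign))
      }
      p <- (1 + sum(abs(same_sign) >= abs(obs$es))) / (1 + length(same_sign))
      le <- if (obs$es >= 0) {
        ranked_genes[pos[seq_len(obs$at_hit)]]
      } else {
        ranked_genes[pos[pos >= pos[obs$at_hit]]]
      }
      tibble(set = nm, n_set = length(pos), ES = obs$es, NES = nes, p = p,
             leading_edge = list(le))
    })
  })
  res$padj <- bh_adjust(res$p)
  dplyr::relocate(dplyr::arrange(res, .data$p), "padj", .after = "p")
}
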