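#' Restrict an interactome to its largest connected component
#'
#' Module statistics are computed on the largest connected component so that
#' unreachable node pairs do not dominate distance means; genes outside it are
#' dropped by the mapping step and counted.
#'
#' @param graph An undirected igraph with node names.
#' @return The induced subgraph of the largest component.
#' @export
interactome_lcc <- function(graph) {
  comp <- igraph::components(graph)
  keep <- which(comp$membership == which.max(comp$csize))
  igraph::induced_subgraph(graph, keep)
}

map_genes <- function(graph, genes) {
  genes <- unique(as.character(genes))
  mapped <- intersect(genes, igraph::V(graph)$name)
  attr(mapped, "n_unmapped") <- length(genes) - length(mapped)
  mapped
}

#' Size of the largest connected induced subgraph
#'
#' The localization statistic S: the order of the largest connected component
#' of the subgraph induced by a gene set. Unmapped genes are dropped; an
#' empty mapped set gives 0.
#'
#' @param graph Interactome (igraph with node names).
#' @param gene_set Character vector of genes.
#' @return Integer S.
#' @export
induced_lcc_size <- function(graph, gene_set) {
  mapped <- map_genes(graph, gene_set)
  if (length(mapped) == 0) return(0L)
  sub <- igraph::induced_subgraph(graph, mapped)
  as.integer(max(igraph::components(sub)$csize))
}

#' Mean shortest distance to the nearest same-set gene
#'
#' The localization statistic d_aa: for each mapped member, the unweighted
#' shortest-path distance to the nearest other member; members unreachable
#' from every other member are excluded (their count is attached as the
#' `n_excluded` attribute) and the mean of the remaining values is returned.
#'
#' @param graph Interactome.
#' @param gene_set Character vector with at least 2 mapped members.
#' @return Numeric d_aa (>= 1) with attribute `n_excluded`.
#' @export
mean_intra_distance <- function(graph, gene_set) {
  mapped <- map_genes(graph, gene_set)
  if (length(mapped) < 2) abort_input("Need >= 2 mapped members.")
  dm <- igraph::distances(graph, v = mapped, to = mapped)
  diag(dm) <- Inf
  nearest <- apply(dm, 1, min)
  usable <- is.finite(nearest)
  if (!any(usable)) abort_input("All members mutually unreachable.")
  structure(mean(nearest[usable]), n_excluded = sum(!usable))
}

#' Network separation of two disease gene sets
#'
#' Computes `s_AB = d_AB - (d_AA + d_BB) / 2`, where `d_AA` and `d_BB` are the
#' mean nearest-neighbor distances within each set ([mean_intra_distance()])
#' and `d_AB` is the mean, over all members of each set, of the shortest
#' distance to the nearest member of the other set (genes shared by both sets
#' contribute distance 0). Negative `s_AB` with a significant null z-score
#' indicates overlapping disease modules.
#'
#' @param graph Interactome.
#' @param set_a,set_b Gene sets with at least 2 mapped members each.
#' @return A `separation_result` list: `d_aa`, `d_bb`, `d_ab`, `s_ab`, and
#'   mapping counts.
#' @export
separation <- function(graph, set_a, set_b) {
  a <- map_genes(graph, set_a)
  b <- map_genes(graph, set_b)
  if (length(a) < 2 || length(b) < 2) {
    abort_input("Both sets need >= 2 mapped members.")
  }
  d_aa <- mean_intra_distance(graph, a)
  d_bb <- mean_intra_distance(graph, b)
  dm <- igraph::distances(graph, v = a, to = b)
  cross <- c(apply(dm, 1, min), apply(dm, 2, min))
  usable <- is.finite(cross)
  if (!any(usable)) abort_input("Sets mutually unreachable.")
  d_ab <- mean(cross[usable])
  structure(
    list(
      d_aa = as.numeric(d_aa), d_bb = as.numeric(d_bb), d_ab = d_ab,
      s_ab = d_ab - (as.numeric(d_aa) + as.numeric(d_bb)) / 2,
      n_a = length(a), n_b = length(b),
      n_cross_excluded = sum(!usable)
    ),
    class = "separation_result"
  )
}

#' @export
print.separation_result <- function(x, ...) {
  cat(sprintf("<separation_result> d_AA=%.3f d_BB=%.3f d_AB=%.3f s_AB=%.3f\n",
              x$d_aa, x$d_bb, x$d_ab, x$s_ab))
  invisible(x)
}

# log2 degree bins merged upward until each holds >= bin_min nodes
degree_bins <- function(graph, bin_min) {
  deg <- igraph::degree(graph)
  b <- floor(log2(pmax(deg, 1)))
  levels_sorted <- sort(unique(b))
  merged <- b
  for (i in seq_along(levels_sorted)) {
    lv <- levels_sorted[i]
    if (sum(merged == lv) < bin_min && i < length(levels_sorted)) {
      merged[merged == lv] <- levels_sorted[i + 1]
    }
  }
  # topmost bin may still be small: merge it down into the nearest occupied bin
  occ <- sort(unique(merged))
  if (length(occ) > 1) {
    top <- occ[length(occ)]
    if (sum(merged == top) < bin_min) {
      merged[merged == top] <- occ[length(occ) - 1]
    }
  }
  split(igraph::V(graph)$name, merged)
}

#' Degree-preserving random gene sets
#'
#' Samples sets matching a reference set's degree-bin composition: nodes are
#' binned by log2 degree (bins merged upward until each holds at least
#' `bin_min` nodes) and each draw samples, without replacement, the same
#' number of nodes per bin as the reference set. Deterministic given `seed`.
#'
#' @param graph Interactome.
#' @param reference_set Gene set whose bin composition is matched.
#' @param n_draws Number of random sets (>= 100).
#' @param seed Integer seed.
#' @param bin_min Minimum nodes per degree bin.
#' @return List of character vectors, one per draw.
#' @export
degree_preserving_null <- function(graph, reference_set, n_draws = 1000,
                                   seed = 1, bin_min = 25) {
  n_draws <- check_count(n_draws, "n_draws", min = 100)
  bin_min <- check_count(bin_min, "bin_min")
  if (bin_min > igraph::gorder(graph)) {
    abort_input("`bin_min` exceeds the graph order.")
  }
  mapped <- map_genes(graph, reference_set)
  if (length(mapped) == 0) abort_input("Reference set does not map.")
  bins <- degree_bins(graph, bin_min)
  bin_of <- rep(names(bins), lengths(bins))
  names(bin_of) <- unlist(bins)
  need <- table(bin_of[mapped])
  with_seed(seed, {
    lapply(seq_len(n_draws), function(i) {
      unlist(lapply(names(need), function(bn) {
        sample(bins[[bn]], need[[bn]])
      }), use.names = FALSE)
    })
  })
}

null_z <- function(observed, null_values) {
  null_values <- null_values[is.finite(null_values)]
  s <- sd(null_values)
  if (!is.finite(s) || s == 0) return(NA_real_)
  (observed - mean(null_values)) / s
}

#' Interactome localization of a disease gene set
#'
#' Observed S ([induced_lcc_size()]) and d_aa ([mean_intra_distance()]) with
#' z-scores against the degree-preserving null. Large positive `z_S` and
#' negative `z_d` indicate a localized disease module.
#'
#' @param graph Interactome.
#' @param gene_set Disease gene set.
#' @param n_draws,seed,bin_min Passed to [degree_preserving_null()].
#' @param disease_id Identifier carried into the output.
#' @return One-row tibble: `disease`, `n_mapped`, `n_unmapped`, `S`, `d_aa`,
#'   `z_S`, `z_d`, `n_draws`.
#' @export
localization <- function(graph, gene_set, n_draws = 1000, seed = 1,
                         bin_min = 25, disease_id = "disease") {
  mapped <- map_genes(graph, gene_set)
  if (length(mapped) < 2) abort_input("Need >= 2 mapped genes.")
  s_obs <- induced_lcc_size(graph, mapped)
  d_obs <- as.numeric(mean_intra_distance(graph, mapped))
  draws <- degree_preserving_null(graph, mapped, n_draws, seed, bin_min)
  s_null <- vapply(draws, function(g) induced_lcc_size(graph, g), integer(1))
  d_null <- vapply(draws, function(g) {
    as.numeric(mean_intra_distance(graph, g))
  }, numeric(1))
  tibble(
    disease = disease_id, n_mapped = length(mapped),
    n_unmapped = attr(mapped, "n_unmapped"),
    S = s_obs, d_aa = d_obs,
    z_S = null_z(s_obs, s_null), z_d = null_z(d_obs, d_null),
    n_draws = n_draws
  )
}

#' Separation of two disease modules with null significance
#'
#' Observed `s_AB` ([separation()]) with a z-score against pairs of
#' independent degree-preserving random sets matching each disease's bin
#' composition.
#'
#' @param graph Interactome.
#' @param set_a,set_b Disease gene sets.
#' @param n_draws,seed,bin_min Null-model parameters.
#' @param ids Pair identifiers.
#' @return One-row tibble: pair ids, `d_aa`, `d_bb`, `d_ab`, `s_ab`, `z_s`,
#'   `n_draws`.
#' @export
separation_test <- function(graph, set_a, set_b, n_draws = 1000, seed = 1,
                            bin_min = 25, ids = c("A", "B")) {
  obs <- separation(graph, set_a, set_b)
  draws_a <- degree_preserving_null(graph, set_a, n_draws, seed, bin_min)
  draws_b <- degree_preserving_null(graph, set_b, n_draws, seed + 1, bin_min)
  s_null <- vapply(seq_len(n_draws), function(i) {
    separation(graph, draws_a[[i]], draws_b[[i]])$s_ab
  }, numeric(1))
  tibble(
    disease_a = ids[1], disease_b = ids[2],
    d_aa = obs$d_aa, d_bb = obs$d_bb, d_ab = obs$d_ab, s_ab = obs$s_ab,
    z_s = null_z(obs$s_ab, s_null), n_draws = n_draws
  )
}
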