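# shared fixtures, built in code at test time

# small planted cohort configuration used across modules
toy_cohort <- function(seed, n_studies = 4, n_genes = 600, n_up = 50,
                       n_down = 50, effect_mu = 1.5, tau = 0.1,
                       n_cases = 15, n_controls = 15) {
  cohort_config(
    n_studies = n_studies, n_cases = n_cases, n_controls = n_controls,
    n_genes = n_genes, n_up = n_up, n_down = n_down,
    effect_mu = effect_mu, tau = tau, seed = seed
  )
}

# a hand-made disease signature over an explicit universe
toy_signature <- function(id, universe, up, down, mu = NULL) {
  if (is.null(mu)) {
    mu <- setNames(rep(0, length(universe)), universe)
    mu[up] <- 1
    mu[down] <- -1
  }
  disease_signature(id, universe, up, down, mu)
}

# named path graph A-B-C-D-E
path5 <- function() {
  igraph::make_graph(~ A - B, B - C, C - D, D - E)
}

# enumeration oracle for the upper-tail hypergeometric overlap p-value,
# written from the counting definition (independent of phyper)
enum_overlap_p <- function(overlap, size_a, size_b, n) {
  ks <- seq(overlap, min(size_a, size_b))
  sum(exp(lchoose(size_a, ks) + lchoose(n - size_a, size_b - ks) -
            lchoose(n, size_b)))
}

# Floyd-Warshall all-pairs shortest paths on an adjacency matrix
# (independent of igraph's BFS distances)
fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  }
  d
}

# separation statistics from a precomputed distance matrix, by definition
ref_separation <- function(d, ia, ib) {
  nearest_other <- function(idx) {
    vapply(idx, function(i) {
      min(d[i, setdiff(idx, i)])
    }, numeric(1))
  }
  d_aa <- mean(nearest_other(ia)[is.finite(nearest_other(ia))])
  d_bb <- mean(nearest_other(ib)[is.finite(nearest_other(ib))])
  cross <- c(apply(d[ia, ib, drop = FALSE], 1, min),
             apply(d[ia, ib, drop = FALSE], 2, min))
  d_ab <- mean(cross[is.finite(cross)])
  list(d_aa = d_aa, d_bb = d_bb, d_ab = d_ab,
       s_ab = d_ab - (d_aa + d_bb) / 2)
}

# quick meta-analysis of a planted pair, returning the two signatures
pair_signatures <- function(seed, direction, shared_fraction = 0.6,
                            n_genes = 800, n_up = 60, n_down = 60) {
  pc <- pair_config(
    toy_cohort(seed, n_genes = n_genes, n_up = n_up, n_down = n_down),
    toy_cohort(seed + 5000, n_genes = n_genes, n_up = n_up, n_down = n_down),
    shared_fraction = shared_fraction, direction = direction
  )
  pr <- sim_disease_pair(pc)
  list(
    a = suppressMessages(meta_analyze(pr$studies_a, disease_id = "A"))$signature,
    b = suppressMessages(meta_analyze(pr$studies_b, disease_id = "B"))$signature,
    truth = pr$truth
  )
}
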