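#' Configuration for a synthetic multi-study case/control cohort
#'
#' Describes one disease's simulated cohort: the number of studies, per-study
#' sample sizes, the planted up- and downregulated gene sets, the standardized
#' effect magnitude, and the between-study heterogeneity. Expression values are
#' simulated directly on the log2 scale at the gene level; each planted gene's
#' case-minus-control mean difference in study *s* is an independent draw from
#' Normal(`effect_mu`, `tau^2`) (negated for the down set), which is exactly
#' the random-effects model estimated downstream.
#'
#' @param n_studies Number of independent studies in the cohort.
#' @param n_cases,n_controls Per-study group sizes.
#' @param n_genes Number of genes on the simulated platform.
#' @param up_set,down_set Planted gene sets (character vectors of identifiers
#'   from [gene_ids()]). When `NULL`, the first `n_up` identifiers form the up
#'   set and the following `n_down` the down set.
#' @param n_up,n_down Sizes of the default planted sets (ignored when explicit
#'   sets are given).
#' @param effect_mu Mean standardized effect magnitude (dimensionless).
#' @param tau Between-study standard deviation of the per-study effect.
#' @param noise_sd Within-group residual standard deviation (log2 units).
#' @param baseline_sd Standard deviation of per-gene baseline expression
#'   around the grand mean of 8 log2 units; shared by all studies so samples
#'   of the same study are strongly correlated, as on a real platform.
#' @param seed Integer seed; the generator is a pure function of config + seed.
#' @return A validated `cohort_config` list.
#' @examples
#' cfg <- cohort_config(n_studies = 3, n_genes = 200, n_up = 10, n_down = 10)
#' studies <- sim_expression_cohort(cfg)
#' @export
cohort_config <- function(n_studies = 6, n_cases = 20, n_controls = 20,
                          n_genes = 2000, up_set = NULL, down_set = NULL,
                          n_up = 100, n_down = 100, effect_mu = 1.5,
                          tau = 0.1, noise_sd = 1, baseline_sd = 2, seed = 1) {
  n_studies <- check_count(n_studies, "n_studies")
  n_cases <- check_count(n_cases, "n_cases", min = 2)
  n_controls <- check_count(n_controls, "n_controls", min = 2)
  n_genes <- check_count(n_genes, "n_genes")
  effect_mu <- check_number(effect_mu, "effect_mu")
  tau <- check_number(tau, "tau", min = 0)
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0, strict_min = TRUE)
  baseline_sd <- check_number(baseline_sd, "baseline_sd", min = 0)
  seed <- check_count(seed, "seed", min = 0)
  genes <- gene_ids(n_genes)
  if (is.null(up_set) && is.null(down_set)) {
    n_up <- check_count(n_up, "n_up", min = 0)
    n_down <- check_count(n_down, "n_down", min = 0)
    if (n_up + n_down > n_genes) {
      abort_input("Planted sets cannot exceed the gene universe.")
    }
    up_set <- genes[seq_len(n_up)]
    down_set <- genes[n_up + seq_len(n_down)]
  }
  up_set <- as.character(up_set %||% character())
  down_set <- as.character(down_set %||% character())
  if (length(intersect(up_set, down_set)) > 0) {
    abort_input("`up_set` and `down_set` must be disjoint.")
  }
  if (!all(c(up_set, down_set) %in% genes)) {
    abort_input("Planted sets must be drawn from the gene universe.")
  }
  structure(
    list(
      n_studies = n_studies, n_cases = n_cases, n_controls = n_controls,
      n_genes = n_genes, genes = genes, up_set = up_set, down_set = down_set,
      effect_mu = effect_mu, tau = tau, noise_sd = noise_sd,
      baseline_sd = baseline_sd, seed = seed
    ),
    class = "cohort_config"
  )
}

#' Simulate a multi-study case/control expression cohort
#'
#' Generates `n_studies` gene-by-sample log2 expression matrices. Per-gene
#' baselines are shared across studies; in study *s*, each up-set gene's case
#' mean is shifted by an independent draw delta ~ Normal(`effect_mu`, `tau^2`)
#' and each down-set gene by the negated draw; residuals are
#' Normal(0, `noise_sd^2`). Deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param id_prefix Study identifier prefix.
#' @return A list of [expression_study()] objects.
#' @export
sim_expression_cohort <- function(config, id_prefix = "study") {
  if (!inherits(config, "cohort_config")) {
    abort_input("`config` must be a cohort_config.")
  }
  with_seed(config$seed, {
    genes <- config$genes
    baseline <- 8 + rnorm(config$n_genes, 0, config$baseline_sd)
    lapply(seq_len(config$n_studies), function(s) {
      study_id <- sprintf("%s%02d", id_prefix, s)
      n <- config$n_cases + config$n_controls
      mat <- baseline +
        matrix(rnorm(config$n_genes * n, 0, config$noise_sd), config$n_genes, n)
      delta <- numeric(config$n_genes)
      i_up <- match(config$up_set, genes)
      i_dn <- match(config$down_set, genes)
      delta[i_up] <- rnorm(length(i_up), config$effect_mu, config$tau)
      delta[i_dn] <- -rnorm(length(i_dn), config$effect_mu, config$tau)
      case_cols <- seq_len(config$n_cases)
      # planted shift scales with noise_sd so delta stays a *standardized* effect
      mat[, case_cols] <- mat[, case_cols] + delta * config$noise_sd
      dimnames(mat) <- list(genes, sprintf("%s_smp%03d", study_id, seq_len(n)))
      groups <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
      expression_study(study_id, mat, groups)
    })
  })
}

#' Configuration for a planted disease pair
#'
#' Couples two cohort configurations so that disease B's planted gene sets
#' share a fixed fraction of disease A's, either in the same direction
#' (the transcriptomic structure of a same-direction deregulated pair), in the
#' opposite direction (up in A appears down in B and vice versa), or not at all.
#'
#' @param config_a,config_b [cohort_config()]s for the two diseases. B's
#'   planted set sizes are kept but their membership is rewritten.
#' @param shared_fraction Fraction in `[0, 1]` of A's planted genes shared by B.
#' @param direction One of `"same"`, `"opposite"`, `"none"`.
#' @return A `pair_config` list.
#' @export
pair_config <- function(config_a, config_b,
                        shared_fraction = 0.6,
                        direction = c("same", "opposite", "none")) {
  direction <- match.arg(direction)
  if (!inherits(config_a, "cohort_config") ||
      !inherits(config_b, "cohort_config")) {
    abort_input("Both configs must be cohort_configs.")
  }
  if (config_a$n_genes != config_b$n_genes) {
    abort_input("Both diseases must share one gene universe.")
  }
  shared_fraction <- check_number(shared_fraction, "shared_fraction", 0, 1)
  if (direction == "none") shared_fraction <- 0
  structure(
    list(config_a = config_a, config_b = config_b,
         shared_fraction = shared_fraction, direction = direction),
    class = "pair_config"
  )
}

# rewrite B's planted sets relative to A's; deterministic (no RNG):
# shared members are the first ceiling(f * |set_A|) of each of A's sets, and
# the remainder of B's sets is filled with the first unused identifiers.
derive_pair_sets <- function(up_a, down_a, n_up_b, n_down_b,
                             shared_fraction, direction, genes) {
  n_su <- ceiling(shared_fraction * length(up_a))
  n_sd <- ceiling(shared_fraction * length(down_a))
  if (direction == "none") n_su <- n_sd <- 0
  shared_up <- head(up_a, n_su)
  shared_dn <- head(down_a, n_sd)
  pool <- setdiff(genes, c(up_a, down_a))
  if (direction == "opposite") {
    up_b <- c(shared_dn, head(pool, max(0, n_up_b - n_sd)))
    pool <- setdiff(pool, up_b)
    down_b <- c(shared_up, head(pool, max(0, n_down_b - n_su)))
  } else {
    up_b <- c(shared_up, head(pool, max(0, n_up_b - n_su)))
    pool <- setdiff(pool, up_b)
    down_b <- c(shared_dn, head(pool, max(0, n_down_b - n_sd)))
  }
  list(up_b = up_b, down_b = down_b)
}

#' Simulate a pair of diseases with planted shared deregulation
#'
#' @param config A [pair_config()].
#' @return A list with `studies_a`, `studies_b` (lists of
#'   [expression_study()]), and `truth`, a list recording the planted
#'   memberships and the pair structure.
#' @export
sim_disease_pair <- function(config) {
  if (!inherits(config, "pair_config")) {
    abort_input("`config` must be a pair_config.")
  }
  ca <- config$config_a
  cb <- config$config_b
  sets <- derive_pair_sets(ca$up_set, ca$down_set,
                           length(cb$up_set), length(cb$down_set),
                           config$shared_fraction, config$direction, ca$genes)
  cb$up_set <- sets$up_b
  cb$down_set <- sets$down_b
  list(
    studies_a = sim_expression_cohort(ca, id_prefix = "A_study"),
    studies_b = sim_expression_cohort(cb, id_prefix = "B_study"),
    truth = list(
      up_a = ca$up_set, down_a = ca$down_set,
      up_b = cb$up_set, down_b = cb$down_set,
      shared_fraction = config$shared_fraction,
      direction = config$direction
    )
  )
}

#' Simulate a scale-free interactome
#'
#' Builds a connected preferential-attachment (Barabasi-Albert) graph. The
#' heavy-tailed degree distribution is what the degree-preserving null models
#' downstream are designed for.
#'
#' @param n_nodes Number of nodes (named with [gene_ids()]).
#' @param attach_m Edges added per incoming node; must satisfy
#'   `n_nodes > attach_m >= 1`.
#' @param seed Integer seed.
#' @return An undirected simple `igraph` with character node names.
#' @export
sim_interactome <- function(n_nodes, attach_m = 2, seed = 1) {
  n_nodes <- check_count(n_nodes, "n_nodes", min = 2)
  attach_m <- check_count(attach_m, "attach_m", min = 1)
  if (attach_m >= n_nodes) abort_input("`n_nodes` must exceed `attach_m`.")
  with_seed(seed, {
    g <- igraph::sample_pa(n_nodes, m = attach_m, directed = FALSE)
    g <- igraph::simplify(g)
    igraph::V(g)$name <- gene_ids(n_nodes)
    g
  })
}

#' Plant a disease module in an interactome
#'
#' Grows a gene set of `module_size` nodes. At each step, with probability
#' `locality` the next member is drawn uniformly from the neighborhood of the
#' current members (yielding a connected module at `locality = 1`), otherwise
#' uniformly from the remaining nodes (`locality = 0` gives a uniform random
#' set). An `include` set can force shared membership with another module.
#'
#' @param graph Interactome (igraph with node names).
#' @param module_size Number of genes in the module.
#' @param locality Probability in `[0, 1]` of neighborhood growth per step.
#' @param seed Integer seed.
#' @param include Genes that must be in the module (growth starts from them).
#' @param exclude Genes that must not be added (e.g. another module's private
#'   members, to pin the intersection size exactly).
#' @return Character vector of module genes.
#' @export
sim_disease_module <- function(graph, module_size, locality = 1, seed = 1,
                               include = NULL, exclude = NULL) {
  module_size <- check_count(module_size, "module_size")
  locality <- check_number(locality, "locality", 0, 1)
  nodes <- igraph::V(graph)$name
  if (module_size > length(nodes)) {
    abort_input("`module_size` exceeds the graph order.")
  }
  include <- as.character(include %||% character())
  exclude <- setdiff(as.character(exclude %||% character()), include)
  if (!all(include %in% nodes)) abort_input("`include` genes not in graph.")
  if (length(include) > module_size) {
    abort_input("`include` larger than `module_size`.")
  }
  with_seed(seed, {
    members <- include
    if (length(members) == 0) {
      members <- sample(setdiff(nodes, exclude), 1)
    }
    free <- function() setdiff(nodes, c(members, exclude))
    while (length(members) < module_size) {
      nb <- setdiff(
        unique(unlist(lapply(igraph::adjacent_vertices(graph, members),
                             igraph::as_ids))),
        c(members, exclude)
      )
      candidates <- if (stats::runif(1) <= locality && length(nb) > 0) {
        nb
      } else {
        free()
      }
      if (length(candidates) == 0) {
        abort_input("Graph too constrained to grow the requested module.")
      }
      members <- c(members, sample(candidates, 1))
    }
    sort(members)
  })
}

#' Simulate a gene set collection
#'
#' Random sets drawn uniformly from the universe, with an optional planted set
#' included verbatim under the name `"planted_set"`. The collection round-trips
#' through [write_gmt()] / [read_gmt()].
#'
#' @param universe Gene universe (character).
#' @param n_sets Number of random sets.
#' @param size_range Two-element integer range of set sizes.
#' @param planted Optional gene set included verbatim.
#' @param seed Integer seed.
#' @return Named list of character vectors with class `gene_set_collection`.
#' @export
sim_gene_sets <- function(universe, n_sets = 50, size_range = c(15, 100),
                          planted = NULL, seed = 1) {
  n_sets <- check_count(n_sets, "n_sets")
  universe <- unique(as.character(universe))
  if (max(size_range) > length(universe)) {
    abort_input("Set sizes cannot exceed the universe.")
  }
  sets <- with_seed(seed, {
    sizes <- sample(seq(size_range[1], size_range[2]), n_sets, replace = TRUE)
    out <- lapply(sizes, function(k) sample(universe, k))
    names(out) <- sprintf("set%04d", seq_len(n_sets))
    out
  })
  if (!is.null(planted)) {
    planted <- unique(as.character(planted))
    if (!all(planted %in% universe)) {
      abort_input("`planted` must lie inside the universe.")
    }
    sets <- c(sets, list(planted_set = planted))
  }
  structure(sets, class = c("gene_set_collection", "list"),
            source = "synthetic")
}

#' Simulate replicate drug perturbation signatures
#'
#' Emulates level-5-style replicate differential-expression signatures: each
#' replicate is the true per-gene signal plus independent Normal(0,
#' `noise_sd^2`) noise, tagged with a synthetic cell context.
#'
#' @param true_signal Named numeric vector of per-gene z-scores.
#' @param n_replicates Number of replicate signatures.
#' @param noise_sd Noise standard deviation.
#' @param seed Integer seed.
#' @param drug_id Drug identifier recorded in the output.
#' @param cells Cell-context labels recycled across replicates.
#' @return Long-format tibble with columns `perturbation_id`, `drug`, `cell`,
#'   `gene`, `z`.
#' @export
sim_drug_signatures <- function(true_signal, n_replicates = 5, noise_sd = 1,
                                seed = 1, drug_id = "drug01",
                                cells = sprintf("CELL%02d", 1:3)) {
  n_replicates <- check_count(n_replicates, "n_replicates")
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0)
  if (is.null(names(true_signal)) || anyNA(true_signal)) {
    abort_input("`true_signal` must be a named, complete numeric vector.")
  }
  genes <- names(true_signal)
  with_seed(seed, {
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      tibble(
        perturbation_id = sprintf("%s_rep%02d", drug_id, r),
        drug = drug_id,
        cell = cells[(r - 1) %% length(cells) + 1],
        gene = genes,
        z = as.numeric(true_signal) + rnorm(length(genes), 0, noise_sd)
      )
    })
  })
}
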