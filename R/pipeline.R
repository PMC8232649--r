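#' Demo run configuration
#'
#' A complete, validated configuration for an end-to-end demonstration run:
#' one neurodegeneration-like disease plus three cancer-like diseases planted
#' as a same-direction pair, an opposite-direction pair, and an unrelated
#' pair, followed by meta-analysis, pair comparison, enrichment, interactome
#' module statistics, and a drug screen with one planted reversal drug. All
#' randomness derives from `seed`.
#'
#' @param seed Master integer seed.
#' @return A named configuration list accepted by [run_pipeline()].
#' @export
demo_run_config <- function(seed = 1) {
  list(
    seed = seed,
    alpha = 0.05,
    stages = list(simulate = TRUE, meta = TRUE, compare = TRUE,
                  enrich = TRUE, network = TRUE, drugs = TRUE),
    simulate = list(
      n_genes = 1500, n_studies = 4, n_cases = 15, n_controls = 15,
      n_up = 100, n_down = 100, effect_mu = 1.5, tau = 0.1, noise_sd = 1,
      shared_fraction = 0.6,
      interactome = list(n_nodes = 1000, attach_m = 2),
      module_size = 15, module_overlap = 5,
      gene_sets = list(n_sets = 30, size_min = 15, size_max = 80),
      drug = list(n_replicates = 5, noise_sd = 0.5)
    ),
    meta = list(min_k = 2, srm_threshold = 7),
    compare = list(ndg = "NDG1",
                   cancer = c("CAN_SAME", "CAN_OPP", "CAN_NULL")),
    enrich = list(n_perm = 500, min_size = 15, max_size = 500, weight_p = 1),
    network = list(n_draws = 200, bin_min = 25),
    drugs = list(threshold = 0.2, min_shared = 10),
    inputs = list()
  )
}

#' Read a run configuration from YAML
#'
#' Fields present in the file override the [demo_run_config()] defaults
#' (recursively); everything else keeps its default.
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_input("Config file not found.")
  utils::modifyList(demo_run_config(), yaml::read_yaml(path))
}

#' Validate a run configuration
#'
#' Schema and cross-field checks; issues are returned as data, not raised.
#' An empty tibble (or only warning-level rows) means the configuration is
#' runnable.
#'
#' @param config Configuration list.
#' @return Tibble with columns `field`, `severity` (`"error"`/`"warning"`),
#'   `message`.
#' @export
validate_run_config <- function(config) {
  issues <- list()
  note <- function(field, severity, message) {
    issues[[length(issues) + 1]] <<- tibble(field = field,
                                            severity = severity,
                                            message = message)
  }
  al <- config$alpha
  if (is.null(al) || !is.numeric(al) || length(al) != 1 ||
      is.na(al) || al <= 0 || al >= 1) {
    note("alpha", "error", "alpha must lie strictly inside (0, 1)")
  }
  sd <- config$seed
  if (is.null(sd) || length(sd) != 1 || !is.finite(sd) || sd != round(sd)) {
    note("seed", "error", "seed must be a single integer")
  }
  st <- config$stages
  if (is.null(st) || !all(vapply(st, is.logical, TRUE))) {
    note("stages", "error", "stage toggles must be logical")
  }
  np <- config$enrich$n_perm
  if (!is.null(np) && np < 100) {
    note("enrich.n_perm", "warning",
         "fewer than 100 permutations gives coarse p-values")
  }
  nd <- config$network$n_draws
  if (!is.null(nd) && nd < 100) {
    note("network.n_draws", "error", "null model needs at least 100 draws")
  }
  for (nm in names(config$inputs)) {
    paths <- unlist(config$inputs[[nm]])
    missing <- paths[!file.exists(paths)]
    for (p in missing) {
      note(paste0("inputs.", nm), "error", sprintf("path does not exist: %s", p))
    }
  }
  if (length(issues) == 0) {
    tibble(field = character(), severity = character(), message = character())
  } else {
    dplyr::bind_rows(issues)
  }
}

#' Run the full comorbidity pipeline
#'
#' Executes the stages in dependency order (simulate, meta-analysis, pair
#' comparison, enrichment, network statistics, drug screen) and writes flat
#' TSV/JSON outputs plus a machine-readable run report. Every output table
#' carries a header comment with the package version and the configuration
#' digest; the run is deterministic given the configuration (two runs with
#' the same config produce byte-identical tables). The simulate stage can be
#' skipped by supplying `config$inputs$cohorts` (named list of directories
#' written by [write_cohort()]).
#'
#' @param config Configuration list (see [demo_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the run report list (also written as
#'   `run_report.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  issues <- validate_run_config(config)
  if (any(issues$severity == "error")) {
    abort(paste0("Invalid configuration:\n",
                 paste(sprintf("- %s: %s", issues$field, issues$message),
                       collapse = "\n")),
          class = "comorbidome_input_error")
  }
  for (i in which(issues$severity == "warning")) {
    warn(sprintf("%s: %s", issues$field[i], issues$message[i]))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  digest <- digest32(config)
  report <- list(
    tool = "comorbidome", version = pkg_version(),
    config_digest = digest, config = config,
    stages = list(), warnings = list()
  )
  seed <- config$seed
  sim <- config$simulate

  # --- simulate -------------------------------------------------------------
  cohorts <- NULL
  truth <- NULL
  if (isTRUE(config$stages$simulate)) {
    cfg_a <- cohort_config(
      n_studies = sim$n_studies, n_cases = sim$n_cases,
      n_controls = sim$n_controls, n_genes = sim$n_genes,
      n_up = sim$n_up, n_down = sim$n_down, effect_mu = sim$effect_mu,
      tau = sim$tau, noise_sd = sim$noise_sd, seed = seed
    )
    directions <- c(CAN_SAME = "same", CAN_OPP = "opposite", CAN_NULL = "none")
    cohorts <- list(NDG1 = sim_expression_cohort(cfg_a))
    truth <- list(NDG1 = list(up = cfg_a$up_set, down = cfg_a$down_set))
    for (i in seq_along(directions)) {
      nm <- names(directions)[i]
      cfg_b <- cfg_a
      cfg_b$seed <- seed + 100 * i
      sets <- derive_pair_sets(cfg_a$up_set, cfg_a$down_set,
                               length(cfg_a$up_set), length(cfg_a$down_set),
                               sim$shared_fraction, directions[[i]],
                               cfg_a$genes)
      cfg_b$up_set <- sets$up_b
      cfg_b$down_set <- sets$down_b
      cohorts[[nm]] <- sim_expression_cohort(cfg_b)
      truth[[nm]] <- list(up = cfg_b$up_set, down = cfg_b$down_set,
                          direction = directions[[i]],
                          shared_fraction = sim$shared_fraction)
    }
    for (nm in names(cohorts)) {
      write_cohort(cohorts[[nm]], file.path(out_dir, "cohorts", nm))
    }
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE)
    report$stages$simulate <- list(diseases = names(cohorts))
  } else {
    dirs <- config$inputs$cohorts
    if (is.null(dirs)) abort_input("simulate disabled but no input cohorts.")
    cohorts <- lapply(dirs, read_cohort)
    report$stages$simulate <- list(skipped = TRUE, diseases = names(cohorts))
  }

  # --- meta-analysis --------------------------------------------------------
  metas <- NULL
  if (isTRUE(config$stages$meta)) {
    metas <- lapply(names(cohorts), function(nm) {
      qc <- qc_filter_studies(cohorts[[nm]],
                              srm_threshold = config$meta$srm_threshold)
      meta_analyze(qc$kept, alpha = config$alpha,
                   min_k = config$meta$min_k, disease_id = nm)
    })
    names(metas) <- names(cohorts)
    for (nm in names(metas)) {
      write_meta_table(metas[[nm]],
                       file.path(out_dir, sprintf("meta_%s.tsv", nm)))
      write_signature_json(metas[[nm]]$signature,
                           file.path(out_dir, sprintf("signature_%s.json", nm)))
    }
    report$stages$meta <- lapply(metas, function(m) {
      list(n_genes = nrow(m$table), n_flagged = m$n_flagged,
           n_up = length(m$signature$up), n_down = length(m$signature$down))
    })
  }

  sigs <- lapply(metas, `[[`, "signature")

  # --- pair comparison ------------------------------------------------------
  pairs <- NULL
  if (isTRUE(config$stages$compare)) {
    ndg_ids <- config$compare$ndg
    can_ids <- config$compare$cancer
    pairs <- compare_all(sigs[ndg_ids], sigs[can_ids], alpha = config$alpha)
    write_stamped_tsv(pairs, file.path(out_dir, "pairs.tsv"), digest)
    report$stages$compare <- list(labels = setNames(pairs$label, pairs$cancer))
  }

  # --- enrichment -----------------------------------------------------------
  if (isTRUE(config$stages$enrich)) {
    ndg_id <- config$compare$ndg[1]
    meta_tab <- metas[[ndg_id]]$table
    universe <- meta_tab$gene[meta_tab$analyzed]
    planted <- if (!is.null(truth)) {
      intersect(truth[[ndg_id]]$up, universe)
    } else {
      NULL
    }
    gs <- sim_gene_sets(universe, n_sets = sim$gene_sets$n_sets,
                        size_range = c(sim$gene_sets$size_min,
                                       sim$gene_sets$size_max),
                        planted = planted, seed = seed + 7)
    write_gmt(gs, file.path(out_dir, "gene_sets.gmt"))
    scores <- setNames(meta_tab$z, meta_tab$gene)[universe]
    gsea <- gsea_preranked(scores, gs, weight_p = config$enrich$weight_p,
                           n_perm = config$enrich$n_perm, seed = seed + 8,
                           min_size = config$enrich$min_size,
                           max_size = config$enrich$max_size)
    write_stamped_tsv(gsea, file.path(out_dir, "gsea.tsv"), digest)
    ora_res <- ora(sigs[[ndg_id]]$up, universe, gs,
                   min_size = config$enrich$min_size,
                   max_size = config$enrich$max_size)
    write_stamped_tsv(ora_res, file.path(out_dir, "ora.tsv"), digest)
    report$stages$enrich <- list(n_sets_tested = nrow(gsea))
  }

  # --- network --------------------------------------------------------------
  if (isTRUE(config$stages$network)) {
    graph <- sim_interactome(sim$interactome$n_nodes,
                             sim$interactome$attach_m, seed = seed + 11)
    write_edge_list(graph, file.path(out_dir, "interactome.tsv"))
    mod_ndg <- sim_disease_module(graph, sim$module_size, locality = 0.9,
                                  seed = seed + 12)
    shared <- head(mod_ndg, sim$module_overlap)
    mod_same <- sim_disease_module(graph, sim$module_size, locality = 0.9,
                                   seed = seed + 13, include = shared,
                                   exclude = setdiff(mod_ndg, shared))
    mod_null <- sim_disease_module(graph, sim$module_size, locality = 0,
                                   seed = seed + 14, exclude = mod_ndg)
    modules <- list(NDG1 = mod_ndg, CAN_SAME = mod_same, CAN_NULL = mod_null)
    loc <- purrr::map_dfr(names(modules), function(nm) {
      localization(graph, modules[[nm]], n_draws = config$network$n_draws,
                   seed = seed + 15, bin_min = config$network$bin_min,
                   disease_id = nm)
    })
    write_stamped_tsv(loc, file.path(out_dir, "localization.tsv"), digest)
    sep <- purrr::map_dfr(c("CAN_SAME", "CAN_NULL"), function(nm) {
      separation_test(graph, modules$NDG1, modules[[nm]],
                      n_draws = config$network$n_draws, seed = seed + 16,
                      bin_min = config$network$bin_min, ids = c("NDG1", nm))
    })
    write_stamped_tsv(sep, file.path(out_dir, "separation.tsv"), digest)
    report$stages$network <- list(n_modules = length(modules))
  }

  # --- drug screen ----------------------------------------------------------
  if (isTRUE(config$stages$drugs)) {
    profiles <- lapply(sigs, `[[`, "mu")
    ndg_id <- config$compare$ndg[1]
    target <- profiles[[ndg_id]]
    rev_sig <- sim_drug_signatures(-target, sim$drug$n_replicates,
                                   sim$drug$noise_sd, seed = seed + 21,
                                   drug_id = "drug_reversal")
    rand_signal <- with_seed(seed + 22, {
      setNames(rnorm(length(target)), names(target))
    })
    rand_sig <- sim_drug_signatures(rand_signal, sim$drug$n_replicates,
                                    sim$drug$noise_sd, seed = seed + 23,
                                    drug_id = "drug_random")
    signatures <- dplyr::bind_rows(rev_sig, rand_sig)
    write_signatures_tsv(signatures, file.path(out_dir, "drug_signatures.tsv"))
    indications <- tibble(
      drug = c("drug_reversal", "drug_random", "drug_untested"),
      disease = ndg_id, source = "synthetic"
    )
    scr <- drug_screen(indications, signatures, profiles,
                       threshold = config$drugs$threshold,
                       min_shared = config$drugs$min_shared)
    write_stamped_tsv(scr$matches, file.path(out_dir, "drug_matches.tsv"),
                      digest)
    report$stages$drugs <- list(untested = scr$untested,
                                n_reversal = sum(scr$matches$flag == "reversal"))
    report$warnings$untested_drugs <- scr$untested
  }

  # --- report ---------------------------------------------------------------
  outputs <- sort(setdiff(
    list.files(out_dir, recursive = TRUE), "run_report.json"
  ))
  report$outputs <- lapply(setNames(outputs, outputs), function(f) {
    unname(tools::md5sum(file.path(out_dir, f)))
  })
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
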