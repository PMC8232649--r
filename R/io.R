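#' Write a cohort of expression studies to TSV files
#'
#' One `expression_<study_id>.tsv` per study (first column `gene`, one column
#' per sample) plus a single `samples.tsv` (`sample_id`, `group`, `study_id`).
#'
#' @param studies List of [expression_study()] objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(studies, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(studies, function(s) {
    df <- tibble::as_tibble(s$matrix, rownames = "gene")
    # 17 significant digits so doubles survive the text round-trip bit-exactly
    df[-1] <- lapply(df[-1], function(x) sprintf("%.17g", x))
    path <- file.path(dir, sprintf("expression_%s.tsv", s$study_id))
    readr::write_tsv(df, path)
    path
  }, character(1))
  meta <- purrr::map_dfr(studies, function(s) {
    tibble(sample_id = colnames(s$matrix), group = s$groups,
           study_id = s$study_id)
  })
  meta_path <- file.path(dir, "samples.tsv")
  readr::write_tsv(meta, meta_path)
  invisible(c(paths, meta_path))
}

#' Read a cohort of expression studies written by [write_cohort()]
#'
#' @param dir Directory holding `expression_*.tsv` files and `samples.tsv`.
#' @return List of [expression_study()] objects.
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "samples.tsv")
  if (!file.exists(meta_path)) abort_input("`samples.tsv` not found.")
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE)
  lapply(split(meta, meta$study_id), function(m) {
    sid <- m$study_id[1]
    # base parser: exact strtod round-trip of the 17-digit representation
    df <- utils::read.delim(file.path(dir, sprintf("expression_%s.tsv", sid)),
                            sep = "\t", check.names = FALSE)
    mat <- as.matrix(df[-1])
    rownames(mat) <- df$gene
    mat <- mat[, m$sample_id, drop = FALSE]
    expression_study(sid, mat, m$group)
  })
}

#' Read a GMT gene set file
#'
#' Tab-separated lines: set name, description, then member genes.
#'
#' @param path File path.
#' @return Named list of character vectors with class `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1)
  if (any(lengths(sets) == 0)) abort_input("GMT contains an empty set.")
  structure(sets, class = c("gene_set_collection", "list"), source = path)
}

#' Write a gene set collection as GMT
#'
#' @param sets Named list of gene sets.
#' @param path Output path.
#' @param description Description field written for every set.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write an interactome as a two-column edge list TSV
#'
#' @param graph igraph with node names.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  readr::write_tsv(tibble(from = el[, 1], to = el[, 2]), path)
  invisible(path)
}

#' Read an interactome from a two-column edge list TSV
#'
#' Self-loops and duplicate edges are removed; the graph is undirected.
#'
#' @param path File path.
#' @return An igraph object.
#' @export
read_edge_list <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  if (ncol(df) < 2) abort_input("Edge list needs two columns.")
  g <- igraph::graph_from_data_frame(df[1:2], directed = FALSE)
  igraph::simplify(g)
}

#' Write a disease signature as JSON
#'
#' @param sig A [disease_signature()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_signature_json <- function(sig, path) {
  jsonlite::write_json(
    list(disease_id = sig$disease_id, alpha = sig$alpha,
         universe = sig$universe, up = sig$up, down = sig$down,
         mu = as.list(sig$mu)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a disease signature written by [write_signature_json()]
#'
#' @param path File path.
#' @return A [disease_signature()].
#' @export
read_signature_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  disease_signature(x$disease_id, x$universe, x$up, x$down,
                    unlist(x$mu), alpha = x$alpha)
}

#' Write a meta-analysis gene table as TSV
#'
#' Fixed column order: gene, k, mu_hat, se, z, p, q, Q, tau2.
#'
#' @param meta A [meta_analyze()] result (or its `table`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_meta_table <- function(meta, path) {
  tab <- if (inherits(meta, "meta_dge")) meta$table else meta
  readr::write_tsv(
    tab[c("gene", "k", "mu_hat", "se", "z", "p", "q", "Q", "tau2")], path
  )
  invisible(path)
}

#' Write / read long-format drug signature TSVs
#'
#' Columns: `perturbation_id`, `drug`, `cell`, `gene`, `z`.
#'
#' @param signatures Long-format tibble.
#' @param path File path.
#' @return Invisibly `path` (writer) or the tibble (reader).
#' @export
write_signatures_tsv <- function(signatures, path) {
  readr::write_tsv(
    signatures[c("perturbation_id", "drug", "cell", "gene", "z")], path
  )
  invisible(path)
}

#' @rdname write_signatures_tsv
#' @export
read_signatures_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(z = "d", .default = "c"))
}

# write a tibble as TSV with a provenance header comment
write_stamped_tsv <- function(df, path, digest) {
  # list-columns (e.g. leading-edge genes) are comma-joined for the flat file
  df <- dplyr::mutate(df, dplyr::across(
    dplyr::where(is.list), ~ vapply(.x, paste, "", collapse = ",")
  ))
  header <- sprintf("# comorbidome %s config=%s", pkg_version(), digest)
  readr::write_lines(c(header, readr::format_tsv(df)), path)
  invisible(path)
}
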