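#' Tidy a meta-analysis result
#'
#' @param x A [meta_analyze()] result.
#' @param ... Unused.
#' @return The per-gene tibble (`gene`, `k`, `mu_hat`, `se`, `z`, `p`, `q`,
#'   `Q`, `tau2`, `analyzed`).
#' @export
tidy.meta_dge <- function(x, ...) {
  x$table
}

#' One-row summary of a meta-analysis
#'
#' `mean_Q` and `mean_tau` are the per-disease averages, over analyzed genes,
#' of the per-gene Cochran Q and between-study SD (the square root of tau2) —
#' the cohort-level heterogeneity summaries usually reported next to DEG
#' counts.
#'
#' @param x A [meta_analyze()] result.
#' @param ... Unused.
#' @return One-row tibble: `disease`, `n_studies`, `n_genes`, `n_analyzed`,
#'   `n_up`, `n_down`, `mean_Q`, `mean_tau`, `alpha`.
#' @export
glance.meta_dge <- function(x, ...) {
  tab <- x$table[x$table$analyzed, ]
  tibble(
    disease = x$disease_id, n_studies = x$n_studies,
    n_genes = nrow(x$table), n_analyzed = nrow(tab),
    n_up = length(x$signature$up), n_down = length(x$signature$down),
    mean_Q = mean(tab$Q), mean_tau = mean(sqrt(tab$tau2)),
    alpha = x$alpha
  )
}

#' Tidy a drug screen
#'
#' @param x A [drug_screen()] result.
#' @param ... Unused.
#' @return The matches tibble.
#' @export
tidy.drug_screen <- function(x, ...) {
  x$matches
}

#' One-row summary of a drug screen
#'
#' @param x A [drug_screen()] result.
#' @param ... Unused.
#' @return Tibble with drug/disease/flag counts and the threshold used.
#' @export
glance.drug_screen <- function(x, ...) {
  tibble(
    n_drugs = length(unique(x$matches$drug)),
    n_diseases = length(unique(x$matches$disease)),
    n_untested = length(x$untested),
    n_reversal = sum(x$matches$flag == "reversal"),
    n_mimic = sum(x$matches$flag == "mimic"),
    threshold = x$threshold
  )
}

#' Volcano plot of a meta-analysis
#'
#' Combined effect against -log10 FDR, with the significance threshold drawn.
#'
#' @param object A [meta_analyze()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.meta_dge <- function(object, ...) {
  tab <- object$table[object$table$analyzed & !is.na(object$table$q), ]
  tab$status <- dplyr::case_when(
    tab$q < object$alpha & tab$mu_hat > 0 ~ "up",
    tab$q < object$alpha & tab$mu_hat < 0 ~ "down",
    TRUE ~ "ns"
  )
  ggplot2::ggplot(tab, ggplot2::aes(.data$mu_hat, -log10(.data$q),
                                    colour = .data$status)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(object$alpha),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(up = "#b2182b", down = "#2166ac", ns = "grey60")
    ) +
    ggplot2::labs(
      title = object$disease_id,
      x = "combined effect (mu-hat)", y = "-log10(q)", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Quadrant heatmap of pairwise comorbidity tests
#'
#' Tile plot of -log10 adjusted p per quadrant and pair, annotated with the
#' SDDC/ODDC/mixed/none label.
#'
#' @param object A [compare_all()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.comorbidity_pairs <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("ndg", "cancer", "label",
                                "q_uu", "q_dd", "q_ud", "q_du")],
    dplyr::starts_with("q_"), names_to = "quadrant", values_to = "q",
    names_prefix = "q_"
  )
  long$quadrant <- factor(long$quadrant, c("uu", "dd", "ud", "du"))
  ggplot2::ggplot(long, ggplot2::aes(.data$quadrant, .data$cancer,
                                     fill = -log10(.data$q))) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(
      data = dplyr::distinct(long, .data$ndg, .data$cancer, .data$label),
      ggplot2::aes(x = 4.7, y = .data$cancer, label = .data$label),
      inherit.aes = FALSE, hjust = 0, size = 3
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$ndg)) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_cartesian(clip = "off") +
    ggplot2::labs(x = "quadrant", y = NULL, fill = "-log10(q)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(plot.margin = ggplot2::margin(5, 60, 5, 5))
}

#' Correlation heatmap of a drug screen
#'
#' @param object A [drug_screen()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.drug_screen <- function(object, ...) {
  ggplot2::ggplot(object$matches,
                  ggplot2::aes(.data$disease, .data$drug, fill = .data$rho)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rho)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal()
}
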