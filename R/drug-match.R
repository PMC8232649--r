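#' Consensus signature from replicate perturbation profiles
#'
#' Correlation-weighted (MODZ-style) average of replicate z-score vectors:
#' each replicate's weight is proportional to its mean Spearman correlation
#' with the other replicates, floored at 0.01 before normalization so no
#' replicate is silently discarded; weights sum to 1 and the consensus is the
#' weighted sum. A single replicate is returned unchanged with weight 1.
#'
#' @param replicates A genes-by-replicates numeric matrix (rownames = genes),
#'   or a list of identically named numeric vectors, or a long tibble with
#'   columns `perturbation_id`, `gene`, `z`.
#' @param drug_id Identifier carried into the result.
#' @param method `"modz"` (default) or `"mean"` (plain average, for
#'   sensitivity checks).
#' @return A `consensus_signature` list: `drug_id`, `z` (named vector),
#'   `n_replicates`, `weights`.
#' @export
modz_consensus <- function(replicates, drug_id = "drug",
                           method = c("modz", "mean")) {
  method <- match.arg(method)
  m <- replicate_matrix(replicates)
  k <- ncol(m)
  if (method == "mean" || k == 1) {
    w <- rep(1 / k, k)
  } else {
    rho <- cor(m, method = "spearman")
    diag(rho) <- NA
    w <- colMeans(rho, na.rm = TRUE)
    w <- pmax(w, 0.01)
    w <- w / sum(w)
  }
  structure(
    list(
      drug_id = drug_id,
      z = setNames(as.numeric(m %*% w), rownames(m)),
      n_replicates = k,
      weights = setNames(w, colnames(m))
    ),
    class = "consensus_signature"
  )
}

replicate_matrix <- function(replicates) {
  if (is.matrix(replicates)) {
    m <- replicates
  } else if (is.data.frame(replicates)) {
    if (!all(c("perturbation_id", "gene", "z") %in% names(replicates))) {
      abort_input("Long input needs columns perturbation_id, gene, z.")
    }
    wide <- tidyr::pivot_wider(
      replicates[c("perturbation_id", "gene", "z")],
      names_from = "perturbation_id", values_from = "z"
    )
    m <- as.matrix(wide[-1])
    rownames(m) <- wide$gene
  } else if (is.list(replicates)) {
    if (length(replicates) == 0) abort_input("Need >= 1 replicate.")
    genes <- names(replicates[[1]])
    same <- vapply(replicates, function(r) identical(names(r), genes),
                   logical(1))
    if (is.null(genes) || !all(same)) {
      abort_input("Replicates must share one named gene space.")
    }
    m <- do.call(cbind, replicates)
    rownames(m) <- genes
    if (is.null(colnames(m))) colnames(m) <- sprintf("rep%02d", seq_len(ncol(m)))
  } else {
    abort_input("Unsupported replicate container.")
  }
  if (ncol(m) < 1) abort_input("Need >= 1 replicate.")
  if (is.null(rownames(m)) || anyNA(m) || !all(is.finite(m))) {
    abort_input("Replicate z-scores must be finite and named by gene.")
  }
  m
}

#' @export
print.consensus_signature <- function(x, ...) {
  cat(sprintf("<consensus_signature> %s: %d genes from %d replicate(s)\n",
              x$drug_id, length(x$z), x$n_replicates))
  invisible(x)
}

#' Match a drug consensus signature against a disease profile
#'
#' Spearman correlation (average ranks for ties) over the genes shared by the
#' consensus signature and the disease's combined-effect profile. The match is
#' flagged `"reversal"` when `rho < -threshold` (the drug pushes expression
#' against the disease), `"mimic"` when `rho > threshold`, `"none"` otherwise.
#'
#' @param consensus A [modz_consensus()] result.
#' @param disease_mu Named numeric vector of combined effects.
#' @param disease_id Identifier carried into the result.
#' @param threshold Absolute-correlation flag threshold (default 0.2).
#' @param min_shared Minimum shared genes (default 10).
#' @return One-row tibble: `drug`, `disease`, `rho`, `n_shared`, `flag`.
#' @export
match_drug_disease <- function(consensus, disease_mu, disease_id = "disease",
                               threshold = 0.2, min_shared = 10) {
  if (!inherits(consensus, "consensus_signature")) {
    abort_input("`consensus` must come from modz_consensus().")
  }
  if (is.null(names(disease_mu))) abort_input("`disease_mu` must be named.")
  shared <- intersect(names(consensus$z), names(disease_mu))
  a <- consensus$z[shared]
  b <- disease_mu[shared]
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < min_shared) {
    abort_input(sprintf("Fewer than %d shared genes.", min_shared))
  }
  rho <- cor(a[ok], b[ok], method = "spearman")
  flag <- if (rho < -threshold) "reversal" else if (rho > threshold) "mimic" else "none"
  tibble(drug = consensus$drug_id, disease = disease_id, rho = rho,
         n_shared = sum(ok), flag = flag)
}

#' Screen indicated drugs against disease profiles
#'
#' Builds one consensus signature per drug from a long-format replicate
#' collection and scores it against every disease profile. Drugs listed in the
#' indications table but absent from the signature collection are reported as
#' untested rather than raising an error.
#'
#' @param indications Tibble with columns `drug`, `disease` (optionally
#'   `source`).
#' @param signatures Long tibble: `perturbation_id`, `drug`, `cell`, `gene`,
#'   `z` (e.g. [sim_drug_signatures()] output, possibly row-bound per drug).
#' @param profiles Named list of disease mu-hat vectors, or of
#'   [disease_signature()]s.
#' @param threshold,min_shared Passed to [match_drug_disease()].
#' @param method Consensus aggregator, `"modz"` or `"mean"`.
#' @return A `drug_screen` list: `matches` (tibble `drug`, `disease`, `rho`,
#'   `n_shared`, `flag`, `indicated`), `rho_matrix` (drugs x diseases tibble),
#'   `untested` (drug ids without signatures). [tidy()] returns `matches`.
#' @export
drug_screen <- function(indications, signatures, profiles, threshold = 0.2,
                        min_shared = 10, method = c("modz", "mean")) {
  method <- match.arg(method)
  if (!all(c("drug", "disease") %in% names(indications))) {
    abort_input("`indications` needs columns drug, disease.")
  }
  if (!all(c("perturbation_id", "drug", "gene", "z") %in% names(signatures))) {
    abort_input("`signatures` needs perturbation_id, drug, gene, z.")
  }
  if (length(profiles) == 0 || is.null(names(profiles))) {
    abort_input("`profiles` must be a non-empty named list.")
  }
  profiles <- lapply(profiles, function(p) {
    if (inherits(p, "disease_signature")) p$mu else p
  })
  listed <- unique(indications$drug)
  with_sig <- unique(signatures$drug)
  untested <- setdiff(listed, with_sig)
  tested <- union(intersect(listed, with_sig), setdiff(with_sig, listed))
  if (length(tested) == 0) abort_input("No drug has signatures to test.")
  matches <- purrr::map_dfr(tested, function(dr) {
    cons <- modz_consensus(signatures[signatures$drug == dr, ],
                           drug_id = dr, method = method)
    purrr::map_dfr(names(profiles), function(ds) {
      match_drug_disease(cons, profiles[[ds]], disease_id = ds,
                         threshold = threshold, min_shared = min_shared)
    })
  })
  matches$indicated <- purrr::map2_lgl(matches$drug, matches$disease,
    function(dr, ds) any(indications$drug == dr & indications$disease == ds))
  rho_matrix <- tidyr::pivot_wider(matches[c("drug", "disease", "rho")],
                                   names_from = "disease",
                                   values_from = "rho")
  structure(
    list(matches = matches, rho_matrix = rho_matrix, untested = untested,
         threshold = threshold, method = method),
    class = "drug_screen"
  )
}

#' @export
print.drug_screen <- function(x, ...) {
  cat(sprintf("<drug_screen> %d drug(s) x %d disease(s); %d untested; %d reversal / %d mimic flags\n",
              length(unique(x$matches$drug)),
              length(unique(x$matches$disease)), length(x$untested),
              sum(x$matches$flag == "reversal"),
              sum(x$matches$flag == "mimic")))
  invisible(x)
}
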