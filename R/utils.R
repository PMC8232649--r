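# internal helpers shared across modules

pkg_version <- function() {
  as.character(utils::packageVersion("comorbidome"))
}

#' Generate zero-padded synthetic gene identifiers
#'
#' @param n Number of identifiers.
#' @param prefix Identifier prefix.
#' @return Character vector `prefix00001 ...`.
#' @export
gene_ids <- function(n, prefix = "g") {
  stopifnot(n >= 1)
  sprintf("%s%05d", prefix, seq_len(n))
}

abort_input <- function(msg) {
  abort(msg, class = "comorbidome_input_error")
}

abort_degenerate <- function(msg) {
  abort(msg, class = "comorbidome_degenerate_error")
}

check_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != round(x)) {
    abort_input(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (length(x) != 1 || !is.numeric(x) || !is.finite(x)) {
    abort_input(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < min || (strict_min && x <= min) || x > max) {
    abort_input(sprintf("`%s` out of range.", name))
  }
  as.numeric(x)
}

check_probs <- function(p, name = "p") {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    abort_input(sprintf("`%s` must be numeric values in [0, 1].", name))
  }
  invisible(p)
}

# deterministic 32-bit polynomial hash of an R object (for config digests)
digest32 <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# evaluate `expr` with the RNG seeded locally, restoring global state after
with_seed <- function(seed, expr) {
  seed <- check_count(seed, "seed", min = 0)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
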