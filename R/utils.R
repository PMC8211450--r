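#' @keywords internal
"_PACKAGE"

#' @importFrom rlang %||% abort warn .data
#' @import dplyr
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_chr map2 imap list_rbind
#' @importFrom stats median rnorm runif sd var fft approx setNames coef
NULL

OUTCOME_LEVELS <- c("escape", "failure", "spontaneous")

# Scalar checks used across constructors; stop with the offending field name so
# configuration errors are actionable.
check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}

check_outcomes <- function(outcomes) {
  outcomes <- as.character(outcomes)
  bad <- setdiff(unique(outcomes), OUTCOME_LEVELS)
  if (length(bad) > 0) {
    abort(sprintf(
      "unknown outcome label(s): %s (expected %s)",
      paste(bad, collapse = ", "), paste(OUTCOME_LEVELS, collapse = "/")
    ))
  }
  outcomes
}

# Row-stochastic 3x3 matrix over the outcome alphabet.
check_transition_matrix <- function(m, name = "transition_matrix", tol = 1e-9) {
  if (!is.matrix(m) || !all(dim(m) == c(3L, 3L)) || !is.numeric(m)) {
    abort(sprintf("`%s` must be a numeric 3x3 matrix", name))
  }
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1)) {
    abort(sprintf("`%s` entries must be probabilities in [0, 1]", name))
  }
  rs <- rowSums(m)
  off <- which(abs(rs - 1) > tol)
  if (length(off) > 0) {
    abort(sprintf(
      "`%s` rows must sum to 1: row(s) %s sum to %s",
      name, paste(off, collapse = ", "),
      paste(signif(rs[off], 6), collapse = ", ")
    ))
  }
  dimnames(m) <- list(OUTCOME_LEVELS, OUTCOME_LEVELS)
  m
}

# Deterministic per-subject substream: derive a 32-bit seed from the master
# seed and subject index so adding subjects never perturbs existing ones.
subject_seed <- function(master_seed, subject_index, salt = 0L) {
  s <- (as.double(master_seed) * 48271 + as.double(subject_index) * 16807 +
          as.double(salt) * 69621) %% 2147483647
  as.integer(s)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
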