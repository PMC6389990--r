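# Internal helpers: validation, seed management, small numerics.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_semdec <- function(msg, class) {
  abort(msg, class = c(class, "semdecode_error"))
}

assert_finite_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_semdec(sprintf("`%s` must be a numeric matrix.", name), "semdecode_validation_error")
  }
  if (!all(is.finite(x))) {
    stop_semdec(sprintf("`%s` contains non-finite values.", name), "semdecode_validation_error")
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != as.integer(x)) {
    stop_semdec(sprintf("`%s` must be a single integer >= %d.", name, min),
                "semdecode_validation_error")
  }
  invisible(as.integer(x))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Hierarchical seed splitting: a parent seed deterministically yields `n` child
# seeds, so any stage can be rerun in isolation with identical results.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a * a))
  nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) {
    stop_semdec("Cosine distance is undefined for a zero-norm vector.",
                "semdecode_degenerate_vector_error")
  }
  sum(a * b) / (na * nb)
}

#' Cosine distance between two vectors
#'
#' Returns `1 - cos(a, b)`, the dissimilarity used both by the leave-two-out
#' pair rule and by semantic model RDMs. Values lie in `[0, 2]`.
#'
#' @param a,b Numeric vectors of equal length; neither may have zero norm.
#' @return A single number in `[0, 2]`.
#' @export
cosine_distance <- function(a, b) {
  1 - cosine_similarity(a, b)
}

# Empirical percentile used for permutation thresholds: the order statistic at
# ceiling(p * n) (type-1 quantile), reproducible from the stored null values.
empirical_percentile <- function(x, p) {
  unname(quantile(x, probs = p, type = 1, names = FALSE))
}
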