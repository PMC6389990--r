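# Shared fixtures, built in code. All randomness is seeded.

# A tiny hand-made semantic space over named tokens.
toy_space <- function(D = 5, tokens = c("dog", "cat", "leg", "tail", "fur",
                                        "bark", "purr", "whisker", "paw")) {
  set.seed(99)
  v <- matrix(rnorm(length(tokens) * D), nrow = length(tokens),
              dimnames = list(tokens, NULL))
  semantic_space(v)
}

# Hand-made norms/map for two targets with 4 clue + 2 non-clue features each
# (clues_per_target = 3 variants are built inline where needed).
toy_norms <- function() {
  feats <- c("has legs", "has a tail", "has fur", "barks loud",
             "purrs softly", "has whiskers")
  tokens <- c("leg", "tail", "fur", "bark", "purr", "whisker")
  norms <- tibble::tibble(
    target = rep(c("dog", "cat"), each = 3),
    category = rep(c("canine", "feline"), each = 3),
    feature = c("has legs", "barks loud", "has a tail",
                "purrs softly", "has whiskers", "has fur"),
    token = c("leg", "bark", "tail", "purr", "whisker", "fur"),
    rank = rep(1:3, 2),
    is_clue = rep(c(TRUE, TRUE, FALSE), 2)
  )
  map <- tibble::tibble(text = c(feats, "dog", "cat"),
                        token = c(tokens, "dog", "cat"))
  list(norms = norms, map = map)
}

# A small generated dataset reused across tests (computed once per run).
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_categories = 4, items_per_category = 3, dim = 24,
                        grid = c(10, 10, 10), n_informative = 60,
                        noise_sd = 20, seed = 404)
      cache <<- simulate_experiment(cfg, n_subjects = 2)
    }
    cache
  }
})

# Independent brute-force oracle for stability scores: plain nested loops
# over repetition pairs with stats::cor().
oracle_stability <- function(arr, training) {
  R <- dim(arr)[2]; V <- dim(arr)[3]
  out <- numeric(V)
  pairs <- utils::combn(R, 2)
  for (v in seq_len(V)) {
    rs <- numeric(ncol(pairs))
    for (p in seq_len(ncol(pairs))) {
      x <- arr[training, pairs[1, p], v]
      y <- arr[training, pairs[2, p], v]
      if (sd(x) == 0 || sd(y) == 0) rs[p] <- 0 else rs[p] <- cor(x, y)
    }
    out[v] <- mean(rs)
  }
  out
}

# Independent brute-force oracle for sphere neighborhoods: exhaustive pairwise
# distance scan over all masked voxels.
oracle_neighborhoods <- function(coords, voxel_mm, radius_mm) {
  V <- nrow(coords)
  lapply(seq_len(V), function(v) {
    d2 <- colSums((t(coords) - coords[v, ])^2) * voxel_mm^2
    which(d2 <= radius_mm^2)
  })
}
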