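test_that("word2vec text format round-trips exactly and rejects malformed files", {
  sp <- toy_space(D = 3, tokens = c("dog", "cat", "fish", "bird", "mouse"))
  f <- tempfile(fileext = ".txt")
  write_word2vec(sp, f)
  sp2 <- read_word2vec(f)
  expect_identical(dim(sp2$vectors), dim(sp$vectors))
  expect_equal(sp2$vectors, sp$vectors, tolerance = 0)
  expect_identical(sp2$dim, 3L)

  writeLines(c("2 3", "dog 1 0 0", "cat 0 1 0"), f)
  sp3 <- read_word2vec(f)
  expect_identical(nrow(sp3$vectors), 2L)
  expect_equal(as.numeric(lookup_vectors(sp3, "cat")), c(0, 1, 0))

  writeLines(c("two 3", "dog 1 0 0"), f)
  expect_error(read_word2vec(f), class = "semdecode_format_error")
  writeLines(c("2 3", "dog 1 0 0", "cat 0 1"), f)
  err <- tryCatch(read_word2vec(f), error = identity)
  expect_s3_class(err, "semdecode_format_error")
  expect_match(conditionMessage(err), "line 3")
  writeLines(c("3 3", "dog 1 0 0", "cat 0 1 0"), f)
  expect_error(read_word2vec(f), class = "semdecode_format_error")
})

test_that("token lookup is lower-cased, exact, and errors name missing tokens", {
  sp <- toy_space(D = 3, tokens = c("Dog", "CAT"))
  expect_identical(rownames(sp$vectors), c("dog", "cat"))
  expect_equal(lookup_vectors(sp, "DOG"), lookup_vectors(sp, "dog"))
  err <- tryCatch(lookup_vectors(sp, c("dog", "gerbil")), error = identity)
  expect_s3_class(err, "semdecode_missing_token_error")
  expect_match(conditionMessage(err), "gerbil")
})

test_that("feature-vector summation is exact, linear and unnormalized", {
  sp <- semantic_space(matrix(c(1, 0, 0, 2), nrow = 2, byrow = TRUE,
                              dimnames = list(c("a", "b"), NULL)))
  map <- tibble::tibble(text = c("feat a", "feat b"), token = c("a", "b"))
  expect_equal(sum_feature_vectors("feat a", map, sp), c(1, 0))
  expect_equal(sum_feature_vectors(rep("feat a", 3), map, sp), c(3, 0))
  expect_equal(sum_feature_vectors(c("feat a", "feat b"), map, sp), c(1, 2))
  err <- tryCatch(sum_feature_vectors("feat c", map, sp), error = identity)
  expect_s3_class(err, "semdecode_missing_token_error")
  expect_match(conditionMessage(err), "feat c")
})

test_that("the six coordinate models follow their defining sums", {
  tn <- toy_norms()
  sp <- toy_space()
  trials <- tibble::tibble(
    trial = c("dog_b1", "dog_b2"), target = "dog", category = "canine",
    block = 1:2, set = 1L,
    clue1 = c("has legs", "barks loud"),
    clue2 = c("barks loud", "has legs"),
    clue3 = c("has legs", "barks loud"),
    donor = c("dog_b2", "dog_b1")
  )
  v <- function(tok) as.numeric(lookup_vectors(sp, tok))
  tr <- trials[1, ]
  expect_equal(trial_coordinate(tr, "CLUE3", tn$norms, tn$map, sp), v("leg"))
  expect_equal(trial_coordinate(tr, "CLUE123", tn$norms, tn$map, sp),
               2 * v("leg") + v("bark"))
  expect_equal(trial_coordinate(tr, "TARGET", tn$norms, tn$map, sp), v("dog"))
  expect_equal(trial_coordinate(tr, "ALL_FEATURES", tn$norms, tn$map, sp),
               v("leg") + v("bark") + v("tail"))
  expect_equal(trial_coordinate(tr, "ALL_NONCLUES", tn$norms, tn$map, sp),
               v("tail"))
})

test_that("MIXED_CLUES uses the donor trial's disjoint clues and errors otherwise", {
  tn <- toy_norms()
  sp <- toy_space()
  trials <- tibble::tibble(
    trial = c("cat_b1", "cat_b2"), target = "cat", category = "feline",
    block = 1:2, set = 1L,
    clue1 = c("purrs softly", "has whiskers"),
    clue2 = c("has whiskers", "purrs softly"),
    clue3 = c("purrs softly", "has whiskers"),
    donor = c("cat_b2", "cat_b1")
  )
  # donor shares clues here -> configuration error (disjointness is asserted)
  expect_error(
    trial_coordinate(trials[1, ], "MIXED_CLUES", tn$norms, tn$map, sp, trials),
    class = "semdecode_configuration_error")
  # a generated design provides genuinely disjoint donors
  ds <- tiny_dataset()
  tr1 <- ds$trials[1, ]
  donor <- ds$trials[ds$trials$trial == tr1$donor, ]
  own <- unlist(tr1[c("clue1", "clue2", "clue3")])
  dcl <- unlist(donor[c("clue1", "clue2", "clue3")])
  expect_length(intersect(own, dcl), 0)
  expect_equal(
    trial_coordinate(tr1, "MIXED_CLUES", ds$norms, ds$map, ds$space, ds$trials),
    sum_feature_vectors(dcl, ds$map, ds$space))
  tr_bad <- tr1
  tr_bad$donor <- NA_character_
  expect_error(
    trial_coordinate(tr_bad, "MIXED_CLUES", ds$norms, ds$map, ds$space, ds$trials),
    class = "semdecode_configuration_error")
})

test_that("ALL_NONCLUES is the exact set-difference of ALL_FEATURES and the clue sum", {
  ds <- tiny_dataset()
  some_targets <- unique(ds$trials$target)[1:5]
  for (tg in some_targets) {
    tr <- ds$trials[match(tg, ds$trials$target), ]
    af <- trial_coordinate(tr, "ALL_FEATURES", ds$norms, ds$map, ds$space)
    an <- trial_coordinate(tr, "ALL_NONCLUES", ds$norms, ds$map, ds$space)
    # independent brute-force sum over the clue-flagged features
    nf <- ds$norms[ds$norms$target == tg & ds$norms$is_clue, ]
    clue_sum <- colSums(lookup_vectors(ds$space, nf$token))
    expect_equal(af, an + clue_sum, tolerance = 1e-12)
  }
})

test_that("a target whose features are all clues yields a degenerate zero ALL_NONCLUES", {
  tn <- toy_norms()
  sp <- toy_space()
  norms_allclue <- tn$norms
  norms_allclue$is_clue <- TRUE
  tr <- list(target = "dog", clue1 = "has legs", clue2 = "barks loud",
             clue3 = "has a tail")
  expect_warning(
    out <- trial_coordinate(tr, "ALL_NONCLUES", norms_allclue, tn$map, sp),
    class = "semdecode_degenerate_coordinate_warning")
  expect_equal(out, rep(0, sp$dim))
})

test_that("design matrices have the right shape, order and equivariance", {
  ds <- tiny_dataset()
  X <- design_matrix(ds$trials, "CLUE123", ds$norms, ds$map, ds$space)
  expect_identical(dim(X), c(nrow(ds$trials), ds$config$dim))
  expect_identical(rownames(X), ds$trials$trial)

  Xt <- design_matrix(ds$trials, "ALL_FEATURES", ds$norms, ds$map, ds$space,
                      level = "target")
  expect_identical(dim(Xt), c(nrow(ds$targets), ds$config$dim))
  expect_identical(rownames(Xt), unique(ds$trials$target))

  perm <- sample(nrow(ds$trials))
  Xp <- design_matrix(ds$trials[perm, ], "CLUE123", ds$norms, ds$map, ds$space)
  expect_equal(Xp, X[perm, ], tolerance = 0)

  expect_error(design_matrix(ds$trials[0, ], "TARGET", ds$norms, ds$map, ds$space),
               class = "semdecode_validation_error")
  expect_error(design_matrix(ds$trials, "CLUE3", ds$norms, ds$map, ds$space,
                             level = "target"),
               class = "semdecode_validation_error")
})
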