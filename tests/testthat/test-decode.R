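test_that("unregularized fit on well-posed noise-free data recovers the weights", {
  set.seed(21)
  X <- matrix(rnorm(40 * 6), 40, 6)
  B <- matrix(rnorm(6 * 4), 6, 4)
  Y <- X %*% B + matrix(rep(c(1, -2, 0, 3), each = 40), 40, 4)
  m <- fit_mapping(X, Y, lambda = 0)
  expect_equal(m$weights, B, tolerance = 1e-8)
  expect_equal(m$intercept, c(1, -2, 0, 3), tolerance = 1e-8)
  expect_equal(predict(m, X), Y, tolerance = 1e-8)
})

test_that("infinite regularization shrinks predictions to the training mean", {
  set.seed(22)
  X <- matrix(rnorm(30 * 5), 30, 5)
  Y <- matrix(rnorm(30 * 3), 30, 3)
  m <- fit_mapping(X, Y, lambda = 1e12)
  expect_lt(max(abs(m$weights)), 1e-6)
  pred <- predict(m, matrix(rnorm(10 * 5), 10, 5))
  expect_equal(pred, matrix(colMeans(Y), 10, 3, byrow = TRUE), tolerance = 1e-4)
})

test_that("gram-form ridge equals the primal solution", {
  set.seed(23)
  X <- matrix(rnorm(20 * 50), 20, 50)   # V > n: kernel regime
  Y <- matrix(rnorm(20 * 3), 20, 3)
  train <- 1:16; test <- 17:20
  for (lam in c(0.5, 10, 1000)) {
    m <- fit_mapping(X[train, ], Y[train, ], lambda = lam)
    gp <- semdecode:::ridge_gram_predict(tcrossprod(X), train, test, Y, lam)
    expect_equal(unname(gp$pred), unname(predict(m, X[test, ])),
                 tolerance = 1e-7)
  }
  # GCV agrees between the two forms as well
  m <- fit_mapping(X[train, ], Y[train, ], lambda = "gcv")
  gp <- semdecode:::ridge_gram_predict(tcrossprod(X), train, test, Y, "gcv")
  expect_equal(gp$lambda, m$lambda, tolerance = 1e-6)
  expect_equal(unname(gp$pred), unname(predict(m, X[test, ])), tolerance = 1e-6)
})

test_that("GCV-regularized decoding recovers held-out coordinates on noise-free data", {
  set.seed(24)
  Y <- matrix(rnorm(30 * 5), 30, 5)
  M <- matrix(rnorm(5 * 80), 5, 80)
  X <- Y %*% M                         # voxel patterns are a linear image
  m <- fit_mapping(X[1:28, ], Y[1:28, ], lambda = "gcv")
  pred <- predict(m, X[29:30, ])
  expect_equal(unname(pred), unname(Y[29:30, ]), tolerance = 1e-2)
  expect_error(fit_mapping(X * NA, Y), class = "semdecode_validation_error")
})

test_that("the cosine pair rule decides, ties and rejects degenerate vectors", {
  t1 <- c(1, 0, 0); t2 <- c(0.2, 1, 0)
  expect_identical(pair_decision(t1, t2, t1, t2)$decision, "correct")
  expect_identical(pair_decision(t2, t1, t1, t2)$decision, "incorrect")
  expect_identical(pair_decision(c(1, 1, 0), c(0, 1, 1), t1, t1)$decision, "tie")
  expect_error(pair_decision(c(0, 0, 0), t2, t1, t2),
               class = "semdecode_degenerate_vector_error")
  pd <- pair_decision(t1, t2, t1, t2)
  expect_true(all(unlist(pd[c("d11", "d22", "d12", "d21")]) >= 0))
  expect_true(all(unlist(pd[c("d11", "d22", "d12", "d21")]) <= 2))
})

test_that("the pair rule is symmetric in the order of the held-out items", {
  set.seed(25)
  for (i in 1:25) {
    p1 <- rnorm(4); p2 <- rnorm(4); t1 <- rnorm(4); t2 <- rnorm(4)
    a <- pair_decision(p1, p2, t1, t2)$decision
    b <- pair_decision(p2, p1, t2, t1)$decision
    expect_identical(a, b)
  }
})

test_that("averaged decoding enumerates all leave-two-out folds and is perfect without noise", {
  cfg <- sim_config(n_categories = 2, items_per_category = 2, dim = 12,
                    grid = c(6, 6, 6), n_informative = 12, noise_sd = 0,
                    seed = 31)
  ds <- simulate_experiment(cfg, 1)
  res <- decode_l2o_averaged(ds$subjects[[1]], ds$target_coordinates, k = 12)
  expect_identical(nrow(res$pairs), as.integer(choose(4, 2)))
  expect_equal(glance(res)$accuracy, 100)
  expect_identical(sort(unique(res$pairs$relation)), c("across", "within"))
})

test_that("ROI decoding equals the averaged scheme without stability selection", {
  ds <- tiny_dataset()
  Y <- ds$target_coordinates
  all_vox <- seq_len(ncol(ds$subjects[[1]]$betas))
  a <- roi_decode(ds$subjects[[1]], all_vox, Y, lambda = 50)
  b <- decode_l2o_averaged(ds$subjects[[1]], Y, lambda = 50, stability = FALSE)
  expect_equal(a$pairs, b$pairs, tolerance = 0)
  expect_identical(nrow(a$pairs), as.integer(choose(nrow(Y), 2)))
  expect_error(roi_decode(ds$subjects[[1]], integer(0), Y),
               class = "semdecode_validation_error")
  # informative-voxel ROI at modest noise decodes almost perfectly
  roi <- roi_decode(ds$subjects[[1]], ds$truths[[1]]$informative, Y)
  expect_gt(glance(roi)$accuracy, 95)
})

test_that("single-trial decoding enumerates all pairs with zero-shot training sets", {
  ds <- tiny_dataset()     # 12 targets x 6 trials = 72 trials
  Y <- design_matrix(ds$trials, "ALL_FEATURES", ds$norms, ds$map, ds$space)
  res <- decode_l2o_single_trial(ds$subjects[[1]], Y, lambda = 100)
  n_trials <- nrow(ds$trials)
  expect_identical(nrow(res$pairs), as.integer(choose(n_trials, 2)))
  g <- glance(res)
  expect_identical(g$n_pairs + g$n_same_target, as.integer(choose(n_trials, 2)))
  expect_identical(g$n_same_target, as.integer(12 * choose(6, 2)))
  expect_identical(res$info$n_train, n_trials - 12L)
})

test_that("the C++ fold loop reproduces the R gram-ridge predictions", {
  ds <- tiny_dataset()
  stack <- ds$subjects[[1]]
  Y <- design_matrix(ds$trials, "CLUE123", ds$norms, ds$map, ds$space)
  lam <- 500
  res <- decode_l2o_single_trial(stack, Y, lambda = lam, same_target = FALSE)
  # recompute the fold holding out the first two targets, in R
  tg <- unique(ds$trials$target)[1:2]
  test_rows <- which(ds$trials$target %in% tg)
  train <- setdiff(seq_len(nrow(Y)), test_rows)
  gp <- semdecode:::ridge_gram_predict(tcrossprod(stack$betas), train,
                                       test_rows, Y, lam)
  i <- test_rows[1]; j <- test_rows[7]   # one trial of each held-out target
  pd <- pair_decision(gp$pred[1, ], gp$pred[7, ], Y[i, ], Y[j, ])
  row <- res$pairs[res$pairs$item1 == ds$trials$trial[i] &
                   res$pairs$item2 == ds$trials$trial[j], ]
  expect_equal(c(row$d11, row$d22, row$d12, row$d21),
               c(pd$d11, pd$d22, pd$d12, pd$d21), tolerance = 1e-8)
})

test_that("trial-invariant coordinates force ties on same-target pairs", {
  ds <- tiny_dataset()
  Yt <- design_matrix(ds$trials, "TARGET", ds$norms, ds$map, ds$space)
  res <- decode_l2o_single_trial(ds$subjects[[1]], Yt, lambda = 100)
  same <- res$pairs[res$pairs$stratum == "same_target", ]
  expect_true(all(same$decision == "tie"))
})

test_that("ridge strength and selection ignore the held-out targets' data", {
  ds <- tiny_dataset()
  arr <- beta_array(ds$subjects[[1]])
  avg <- average_repetitions(arr)
  Y <- ds$target_coordinates
  train <- 3:12
  g1 <- semdecode:::ridge_gram_predict(tcrossprod(avg), train, 1:2, Y, "gcv")
  avg2 <- avg
  avg2[1:2, ] <- avg2[1:2, ] * 100 + 5
  g2 <- semdecode:::ridge_gram_predict(tcrossprod(avg2), train, 1:2, Y, "gcv")
  expect_identical(g1$lambda, g2$lambda)
})

test_that("permutation nulls are seeded, reproducible and bounded by their percentile", {
  ds <- tiny_dataset()
  Y <- ds$target_coordinates
  p1 <- permutation_null(ds$subjects[[1]], Y, "averaged", n_iter = 30,
                         seed = 6, k = 40)
  p2 <- permutation_null(ds$subjects[[1]], Y, "averaged", n_iter = 30,
                         seed = 6, k = 40)
  expect_identical(p1$accuracies, p2$accuracies)
  expect_gte(p1$threshold, stats::median(p1$accuracies$accuracy))
  expect_identical(p1$threshold,
                   semdecode:::empirical_percentile(p1$accuracies$accuracy, 0.95))
  # single-trial permutations run the same scheme with shuffled training labels
  Ytr <- design_matrix(ds$trials, "ALL_FEATURES", ds$norms, ds$map, ds$space)
  ps <- permutation_null(ds$subjects[[1]], analysis = "single_trial",
                         coords = Ytr, n_iter = 5, seed = 2, lambda = 1000)
  expect_length(ps$accuracies$accuracy, 5)
  expect_true(all(ps$accuracies$accuracy >= 0 & ps$accuracies$accuracy <= 100))
})

test_that("activation prediction inverts the mapping as an affine map", {
  set.seed(26)
  Y <- matrix(rnorm(25 * 4), 25, 4)
  M <- matrix(rnorm(4 * 30), 4, 30)
  X <- Y %*% M
  m <- fit_mapping(X, Y, lambda = 1e-8)
  y <- Y[3, ]
  x_hat <- predict_activation(m, y)
  expect_equal(as.numeric(predict(m, x_hat)), y, tolerance = 1e-5)
  a <- rnorm(4); b <- rnorm(4)
  lhs <- predict_activation(m, a + b)
  rhs <- predict_activation(m, a) + predict_activation(m, b) -
    predict_activation(m, rep(0, 4))
  expect_equal(lhs, rhs, tolerance = 1e-8)
  expect_error(predict_activation(m, rep(0, 5)),
               class = "semdecode_validation_error")
})

test_that("model comparison handles degenerate accuracy patterns by convention", {
  acc <- tibble::tibble(
    subject = rep(1:4, times = 3),
    model = rep(c("A", "B", "C"), each = 4),
    accuracy = c(80, 82, 78, 81, 80, 82, 78, 81, 70, 72, 68, 71)
  )
  cmp <- compare_models(acc)
  tt <- tidy(cmp)
  ab <- tt[tt$model1 == "A" & tt$model2 == "B", ]
  expect_identical(ab$t, 0)
  expect_identical(ab$p_bonferroni, 1)
  ac <- tt[tt$model1 == "A" & tt$model2 == "C", ]
  expect_identical(ac$t, Inf)
  expect_identical(ac$p_bonferroni, 0)
  expect_identical(cmp$ranking$model[cmp$ranking$rank == 3], "C")
  expect_identical(cmp$n_comparisons, 3L)
  expect_error(compare_models(acc[acc$subject == 1, ]),
               class = "semdecode_validation_error")
  # Bonferroni multiplier matches the number of comparisons performed
  expect_equal(tt$p_bonferroni, pmin(1, tt$p_value * 3))
})

test_that("tidy and glance expose the per-pair and summary views", {
  ds <- tiny_dataset()
  res <- decode_l2o_averaged(ds$subjects[[1]], ds$target_coordinates, k = 40)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("item1", "item2", "decision", "d11") %in% names(td)))
  g <- glance(res)
  manual <- 100 * mean(semdecode:::decision_score(td$decision))
  expect_equal(g$accuracy, manual)
  ca <- category_accuracy(res)
  expect_true(all(ca$category %in% ds$targets$category))
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
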