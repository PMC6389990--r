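# Zero-shot leave-two-out decoding: pair rule, exhaustive evaluation schemes
# (averaged, single-trial, ROI), permutation nulls and model comparison.

#' Decide a leave-two-out pair by the cosine distance rule
#'
#' The pairing is correct iff
#' `d(p1,t1) + d(p2,t2) < d(p1,t2) + d(p2,t1)` with `d` the cosine distance;
#' exact equality of the two sums is a tie (which scores 0.5 towards
#' accuracy). Zero-norm vectors are rejected.
#'
#' @param pred1,pred2 Predicted semantic coordinates of the two held-out items.
#' @param true1,true2 Their true coordinates.
#' @return A list with the four distances (`d11`, `d22`, `d12`, `d21`) and
#'   `decision` (`"correct"`, `"incorrect"` or `"tie"`).
#' @examples
#' t1 <- c(1, 0, 0); t2 <- c(0, 1, 0)
#' pair_decision(t1, t2, t1, t2)$decision   # perfect predictions
#' pair_decision(t2, t1, t1, t2)$decision   # swapped predictions
#' @export
pair_decision <- function(pred1, pred2, true1, true2) {
  d11 <- cosine_distance(pred1, true1)
  d22 <- cosine_distance(pred2, true2)
  d12 <- cosine_distance(pred1, true2)
  d21 <- cosine_distance(pred2, true1)
  list(d11 = d11, d22 = d22, d12 = d12, d21 = d21,
       decision = decide_from_distances(d11, d22, d12, d21))
}

decide_from_distances <- function(d11, d22, d12, d21) {
  s_match <- d11 + d22
  s_swap <- d12 + d21
  dplyr::case_when(s_match < s_swap ~ "correct",
                   s_match > s_swap ~ "incorrect",
                   TRUE ~ "tie")
}

decision_score <- function(decision) {
  ifelse(decision == "correct", 1, ifelse(decision == "tie", 0.5, 0))
}

new_decoding <- function(pairs, analysis, ...) {
  structure(list(pairs = pairs, analysis = analysis, info = list(...)),
            class = "semdec_decoding")
}

pair_accuracy <- function(pairs) {
  if (nrow(pairs) == 0) return(NA_real_)
  100 * mean(decision_score(pairs$decision))
}

#' @export
print.semdec_decoding <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<semdec_decoding: %s analysis, %d pairs, accuracy %.1f%%>\n",
              x$analysis, nrow(x$pairs), g$accuracy))
  invisible(x)
}

#' Per-pair outcomes of a decoding run
#'
#' @param x A `semdec_decoding`.
#' @param ... Unused.
#' @return Tibble with one row per evaluated pair: items, targets, categories,
#'   stratum (`"distinct"` or `"same_target"`), category relation, the four
#'   cosine distances and the decision.
#' @export
tidy.semdec_decoding <- function(x, ...) {
  x$pairs
}

#' Accuracy summary of a decoding run
#'
#' Headline accuracy is computed over distinct-target pairs (ties score 0.5);
#' same-target pairs, where defined identity cannot be decided, are reported
#' separately. Within/across-category accuracies stratify the distinct pairs
#' by whether the two targets share a semantic category.
#'
#' @param x A `semdec_decoding`.
#' @param ... Unused.
#' @return One-row tibble: analysis, pair/fold counts, overall,
#'   within-category and across-category accuracy (in %), tie count, and the
#'   same-target accuracy where that stratum exists.
#' @export
glance.semdec_decoding <- function(x, ...) {
  p <- x$pairs
  distinct <- p[p$stratum == "distinct", ]
  tibble(
    analysis = x$analysis,
    n_pairs = nrow(distinct),
    n_same_target = sum(p$stratum == "same_target"),
    accuracy = pair_accuracy(distinct),
    accuracy_within = pair_accuracy(distinct[distinct$relation == "within", ]),
    accuracy_across = pair_accuracy(distinct[distinct$relation == "across", ]),
    n_ties = sum(distinct$decision == "tie"),
    accuracy_same_target = pair_accuracy(p[p$stratum == "same_target", ])
  )
}

#' Per-category decoding accuracy
#'
#' Accuracy over distinct-target pairs in which both targets belong to the
#' same category, reported per category.
#'
#' @param x A `semdec_decoding`.
#' @return Tibble with `category`, `n_pairs`, `accuracy`.
#' @export
category_accuracy <- function(x) {
  stopifnot(inherits(x, "semdec_decoding"))
  p <- x$pairs
  p <- p[p$stratum == "distinct" & p$relation == "within", ]
  p |>
    dplyr::group_by(category = .data$category1) |>
    dplyr::summarise(n_pairs = dplyr::n(),
                     accuracy = 100 * mean(decision_score(.data$decision)),
                     .groups = "drop")
}

#' @export
autoplot.semdec_decoding <- function(object, ...) {
  g <- glance(object)
  df <- tibble(
    stratum = factor(c("overall", "within category", "across category"),
                     levels = c("overall", "within category", "across category")),
    accuracy = c(g$accuracy, g$accuracy_within, g$accuracy_across)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Decoding accuracy (%)",
                  title = sprintf("Leave-two-out decoding (%s)", object$analysis)) +
    ggplot2::theme_minimal()
}

category_lookup <- function(trials) {
  u <- !duplicated(trials$target)
  setNames(trials$category[u], trials$target[u])
}

# Shared fold loop of the averaged-data scheme. `Y_train` (defaults to `Y`)
# supplies the coordinates the decoder is *fitted* on, which permutation nulls
# replace with a shuffled assignment; decisions are always made against the
# true `Y`. Returns the pair table, plus per-fold metadata when `keep_folds`.
l2o_averaged_engine <- function(avg, Y, categories, ss, k, lambda,
                                Y_train = NULL, keep_folds = FALSE) {
  targets <- rownames(avg)
  Tn <- length(targets)
  combos <- utils::combn(Tn, 2)
  n_folds <- ncol(combos)
  rows <- vector("list", n_folds)
  folds <- if (keep_folds) vector("list", n_folds) else NULL
  Yfit <- Y_train %||% Y
  for (f in seq_len(n_folds)) {
    i <- combos[1, f]; j <- combos[2, f]
    train <- setdiff(seq_len(Tn), c(i, j))
    if (!is.null(ss)) {
      scores <- stability_from_suffstats(ss, c(i, j))
      sel <- select_stable_voxels(scores, k)
    } else {
      sel <- seq_len(ncol(avg))
    }
    Gf <- tcrossprod(avg[, sel, drop = FALSE])
    rp <- ridge_gram_predict(Gf, train, c(i, j), Yfit, lambda,
                             return_operator = keep_folds)
    pd <- pair_decision(rp$pred[1, ], rp$pred[2, ], Y[i, ], Y[j, ])
    rows[[f]] <- tibble(
      item1 = targets[i], item2 = targets[j],
      target1 = targets[i], target2 = targets[j],
      category1 = unname(categories[targets[i]]),
      category2 = unname(categories[targets[j]]),
      stratum = "distinct",
      relation = ifelse(categories[targets[i]] == categories[targets[j]],
                        "within", "across"),
      d11 = pd$d11, d22 = pd$d22, d12 = pd$d12, d21 = pd$d21,
      decision = pd$decision, lambda = rp$lambda
    )
    if (keep_folds) {
      folds[[f]] <- list(test = c(i, j), train = train, sel = sel,
                         lambda = rp$lambda, A = rp$A)
    }
  }
  list(pairs = dplyr::bind_rows(rows), folds = folds)
}

#' Zero-shot leave-two-out decoding on repetition-averaged data
#'
#' For every unordered pair of targets: voxel stability is recomputed on the
#' remaining training targets only, the `k` most stable voxels are selected,
#' repetition-averaged patterns of the training targets are regressed onto
#' their semantic coordinates (ridge, in-fold GCV by default), both held-out
#' targets are predicted, and the pairing is decided by the cosine rule. With
#' `n` targets this runs `choose(n, 2)` folds (1,770 for 60 targets). No
#' trial, statistic or selection ever uses the held-out targets.
#'
#' @param stack A `beta_stack` with a complete repetition structure.
#' @param Y Target-level coordinate matrix (`n_targets x D`, rows named by
#'   target; see [design_matrix()] with `level = "target"`).
#' @param k Number of stable voxels to select (default 500).
#' @param lambda `"gcv"` or a fixed non-negative ridge strength.
#' @param stability Recompute stability selection per fold (default TRUE;
#'   FALSE uses all supplied voxels, as in ROI decoding).
#' @param voxels Optional voxel index subset to restrict the analysis to.
#' @return A `semdec_decoding` (see [glance.semdec_decoding()]).
#' @export
decode_l2o_averaged <- function(stack, Y, k = 500L, lambda = "gcv",
                                stability = TRUE, voxels = NULL) {
  stopifnot(inherits(stack, "beta_stack"))
  arr <- beta_array(stack)
  if (!is.null(voxels)) {
    if (length(voxels) == 0) {
      stop_semdec("Empty voxel set.", "semdecode_validation_error")
    }
    arr <- arr[, , voxels, drop = FALSE]
  }
  targets <- dimnames(arr)[[1]]
  Y <- Y[targets, , drop = FALSE]
  cats <- category_lookup(stack$trials)
  avg <- average_repetitions(arr)
  ss <- if (stability) stability_suffstats(arr) else NULL
  eng <- l2o_averaged_engine(avg, Y, cats, ss, k, lambda)
  new_decoding(eng$pairs, "averaged", k = if (stability) k else NA_integer_,
               n_folds = nrow(eng$pairs), lambda = lambda,
               stability = stability)
}

#' Region-of-interest zero-shot decoding
#'
#' Restricts the averaged-data scheme to a voxel mask (for example left+right
#' anatomical labels concatenated) and disables stability selection, so every
#' ROI voxel enters the regression.
#'
#' @inheritParams decode_l2o_averaged
#' @param roi Integer indices (into the masked voxels) of the ROI; must be
#'   non-empty.
#' @return A `semdec_decoding`.
#' @export
roi_decode <- function(stack, roi, Y, lambda = "gcv") {
  if (is.null(roi) || length(roi) == 0) {
    stop_semdec("Empty ROI mask.", "semdecode_validation_error")
  }
  out <- decode_l2o_averaged(stack, Y, lambda = lambda, stability = FALSE,
                             voxels = roi)
  out$analysis <- "roi"
  out
}

#' Zero-shot leave-two-out decoding on single trials
#'
#' Enumerates all unordered trial pairs. For a pair of trials of distinct
#' targets, the decoder is trained on the trials of all other targets (348 of
#' 360 in the full design: all 12 trials of the two tested targets are
#' excluded), with no stability selection and all supplied voxels. Same-target
#' pairs are enumerated and reported as their own stratum, excluded from the
#' headline accuracy. The ridge factorization of each fold is shared across
#' coordinate models, so passing a named list of model matrices evaluates all
#' models at once.
#'
#' @param stack A `beta_stack`.
#' @param coords Trial-level coordinate matrix (`n_trials x D`, row order
#'   matching `stack$trials`) or a named list of such matrices (one per
#'   coordinate model).
#' @param lambda `"gcv"` (selected per fold and model) or a fixed value.
#' @param same_target Include the same-target stratum (default TRUE).
#' @return A `semdec_decoding`, or a named list of them when `coords` is a
#'   list.
#' @export
decode_l2o_single_trial <- function(stack, coords, lambda = "gcv",
                                    same_target = TRUE) {
  stopifnot(inherits(stack, "beta_stack"))
  single <- !is.list(coords)
  Ys <- if (single) list(model = as.matrix(coords)) else lapply(coords, as.matrix)
  n_trials <- nrow(stack$betas)
  for (nm in names(Ys)) {
    if (nrow(Ys[[nm]]) != n_trials) {
      stop_semdec(sprintf("Coordinate matrix '%s' must have one row per trial.", nm),
                  "semdecode_validation_error")
    }
  }
  trials <- stack$trials
  tcode <- match(trials$target, unique(trials$target))
  G <- tcrossprod(stack$betas)
  use_gcv <- identical(lambda, "gcv")
  lam <- if (use_gcv) -1 else as.numeric(lambda)
  raw <- .l2o_single_gram(G, Ys, Ys, as.integer(tcode), lam, use_gcv,
                          same_target)
  cats <- category_lookup(trials)
  res <- purrr::imap(Ys, function(Y, nm) {
    M <- raw[[match(nm, names(Ys))]]
    i <- as.integer(M[, 1]); j <- as.integer(M[, 2])
    t1 <- trials$target[i]; t2 <- trials$target[j]
    same <- t1 == t2
    pairs <- tibble(
      item1 = trials$trial[i], item2 = trials$trial[j],
      target1 = t1, target2 = t2,
      category1 = unname(cats[t1]), category2 = unname(cats[t2]),
      stratum = ifelse(same, "same_target", "distinct"),
      relation = ifelse(same, "same_target",
                        ifelse(cats[t1] == cats[t2], "within", "across")),
      d11 = M[, 3], d22 = M[, 4], d12 = M[, 5], d21 = M[, 6],
      decision = decide_from_distances(M[, 3], M[, 4], M[, 5], M[, 6])
    )
    new_decoding(pairs, "single_trial",
                 n_train = n_trials - 2L * sum(tcode == 1L),
                 lambda = lambda,
                 fold_lambdas = attr(raw, "lambdas"))
  })
  if (single) res[[1]] else res
}

permute_trial_rows <- function(trials, perm) {
  targets <- unique(trials$target)
  rows <- seq_len(nrow(trials))
  out <- rows
  for (t in seq_along(targets)) {
    own <- which(trials$target == targets[t])
    don <- which(trials$target == targets[perm[t]])
    out[own[order(trials$block[own])]] <- don[order(trials$block[don])]
  }
  out
}

#' Permutation null distribution of decoding accuracy
#'
#' Each iteration randomly permutes the coordinate-to-target assignment in the
#' training set only (held-out pairs keep their true coordinates), reruns the
#' leave-two-out scheme and records the overall accuracy. Voxel stability
#' depends only on the betas, so the per-fold voxel selection (and the
#' GCV-chosen ridge strength of the unpermuted fit) is reused across
#' iterations. The significance threshold is the empirical 95th percentile of
#' the null accuracies.
#'
#' @inheritParams decode_l2o_averaged
#' @param analysis `"averaged"` or `"single_trial"`.
#' @param coords Trial-level coordinates, required for `"single_trial"`.
#' @param n_iter Number of permutations (paper-scale default 1000).
#' @param seed RNG seed for the permutation stream.
#' @return Object of class `semdec_permnull`: tibble of null accuracies,
#'   `threshold` (%), the observed accuracy, and bookkeeping.
#' @export
permutation_null <- function(stack, Y = NULL, analysis = c("averaged", "single_trial"),
                             coords = NULL, n_iter = 1000L, seed = 1L,
                             k = 500L, lambda = "gcv", voxels = NULL) {
  analysis <- match.arg(analysis)
  n_iter <- assert_count(n_iter, "n_iter")
  if (analysis == "averaged") {
    arr <- beta_array(stack)
    if (!is.null(voxels)) arr <- arr[, , voxels, drop = FALSE]
    targets <- dimnames(arr)[[1]]
    Y <- Y[targets, , drop = FALSE]
    cats <- category_lookup(stack$trials)
    avg <- average_repetitions(arr)
    ss <- stability_suffstats(arr)
    base <- l2o_averaged_engine(avg, Y, cats, ss, k, lambda, keep_folds = TRUE)
    observed <- pair_accuracy(base$pairs)
    Tn <- length(targets)
    null_acc <- with_seed(seed, {
      vapply(seq_len(n_iter), function(it) {
        perm <- sample.int(Tn)
        score <- 0
        for (fd in base$folds) {
          Ytr <- Y[perm[fd$train], , drop = FALSE]
          pred <- fd$A %*% Ytr
          pd <- pair_decision(pred[1, ], pred[2, ], Y[fd$test[1], ], Y[fd$test[2], ])
          score <- score + decision_score(pd$decision)
        }
        100 * score / length(base$folds)
      }, numeric(1))
    })
  } else {
    if (is.null(coords)) {
      stop_semdec("Single-trial permutations need trial-level `coords`.",
                  "semdecode_validation_error")
    }
    coords <- as.matrix(coords)
    base <- decode_l2o_single_trial(stack, coords, lambda = lambda,
                                    same_target = FALSE)
    observed <- glance(base)$accuracy
    lam_fixed <- if (identical(lambda, "gcv")) {
      stats::median(base$info$fold_lambdas)
    } else {
      as.numeric(lambda)
    }
    trials <- stack$trials
    tcode <- match(trials$target, unique(trials$target))
    Tn <- max(tcode)
    G <- tcrossprod(stack$betas)
    null_acc <- with_seed(seed, {
      vapply(seq_len(n_iter), function(it) {
        perm <- sample.int(Tn)
        Yperm <- coords[permute_trial_rows(trials, perm), , drop = FALSE]
        raw <- .l2o_single_gram(G, list(Yperm), list(coords),
                                as.integer(tcode), lam_fixed, FALSE, FALSE)
        M <- raw[[1]]
        dec <- decide_from_distances(M[, 3], M[, 4], M[, 5], M[, 6])
        100 * mean(decision_score(dec))
      }, numeric(1))
    })
  }
  structure(list(accuracies = tibble(iteration = seq_len(n_iter),
                                     accuracy = null_acc),
                 threshold = empirical_percentile(null_acc, 0.95),
                 observed = observed, analysis = analysis,
                 n_iter = n_iter, seed = seed),
            class = "semdec_permnull")
}

#' @export
print.semdec_permnull <- function(x, ...) {
  cat(sprintf("<semdec_permnull: %s, %d iterations, null mean %.1f%%, 95th pct %.1f%% (observed %.1f%%)>\n",
              x$analysis, x$n_iter, mean(x$accuracies$accuracy), x$threshold,
              x$observed))
  invisible(x)
}

#' @export
tidy.semdec_permnull <- function(x, ...) x$accuracies

#' @export
glance.semdec_permnull <- function(x, ...) {
  tibble(analysis = x$analysis, n_iter = x$n_iter,
         null_mean = mean(x$accuracies$accuracy),
         null_sd = sd(x$accuracies$accuracy),
         threshold = x$threshold, observed = x$observed,
         p_value = (1 + sum(x$accuracies$accuracy >= x$observed)) / (1 + x$n_iter))
}

#' Compare coordinate models across subjects
#'
#' Paired two-sided t-tests between the per-subject mean accuracies of every
#' model pair, Bonferroni-corrected for the number of pairwise comparisons
#' performed (15 for the six models). Zero-variance differences use the
#' limiting convention: all-zero differences give `t = 0`, `p = 1`; a constant
#' nonzero offset gives `t = +/-Inf`, `p = 0`.
#'
#' @param accuracies Long tibble with columns `subject`, `model`, `accuracy`
#'   (one row per subject and model, accuracies in %).
#' @return Object of class `semdec_comparison`: the test table (tibble with
#'   `model1`, `model2`, `mean_diff`, `t`, `df`, `p_value`, `p_bonferroni`),
#'   a ranking tibble by mean accuracy, and the input data.
#' @export
compare_models <- function(accuracies) {
  req <- c("subject", "model", "accuracy")
  if (!all(req %in% names(accuracies))) {
    stop_semdec("`accuracies` needs columns subject, model, accuracy.",
                "semdecode_validation_error")
  }
  wide <- tidyr::pivot_wider(accuracies[req], names_from = "model",
                             values_from = "accuracy")
  models <- setdiff(names(wide), "subject")
  n <- nrow(wide)
  if (n < 2L) {
    stop_semdec("Model comparison needs at least 2 subjects.",
                "semdecode_validation_error")
  }
  combos <- utils::combn(models, 2)
  n_comp <- ncol(combos)
  rows <- lapply(seq_len(n_comp), function(c_) {
    m1 <- combos[1, c_]; m2 <- combos[2, c_]
    d <- wide[[m1]] - wide[[m2]]
    s <- sd(d)
    if (s == 0) {
      tval <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      p <- if (mean(d) == 0) 1 else 0
    } else {
      tval <- mean(d) / (s / sqrt(n))
      p <- 2 * pt(-abs(tval), df = n - 1)
    }
    tibble(model1 = m1, model2 = m2, mean_diff = mean(d), t = tval,
           df = n - 1L, p_value = p, p_bonferroni = min(1, p * n_comp))
  })
  ranking <- accuracies |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(mean_accuracy = mean(.data$accuracy), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_accuracy)) |>
    dplyr::mutate(rank = dplyr::row_number())
  structure(list(tests = dplyr::bind_rows(rows), ranking = ranking,
                 data = as_tibble(accuracies), n_comparisons = n_comp),
            class = "semdec_comparison")
}

#' @export
print.semdec_comparison <- function(x, ...) {
  cat(sprintf("<semdec_comparison: %d models, %d subjects, %d pairwise t-tests>\n",
              nrow(x$ranking), length(unique(x$data$subject)), x$n_comparisons))
  print(x$ranking)
  invisible(x)
}

#' @export
tidy.semdec_comparison <- function(x, ...) x$tests

#' @export
glance.semdec_comparison <- function(x, ...) {
  tibble(n_models = nrow(x$ranking),
         n_subjects = length(unique(x$data$subject)),
         n_comparisons = x$n_comparisons,
         best_model = x$ranking$model[1],
         best_mean_accuracy = x$ranking$mean_accuracy[1])
}

#' Accuracy-by-model figure for a model comparison
#'
#' Jittered per-subject accuracies with a boxplot per model and the mean
#' marked, models ordered by mean accuracy.
#'
#' @param object A [compare_models()] result.
#' @param chance Reference line (default 50%).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.semdec_comparison <- function(object, chance = 50, ...) {
  df <- object$data
  df$model <- factor(df$model, levels = rev(object$ranking$model))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$accuracy,
                                   colour = .data$model)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 17, size = 3,
                          colour = "black") +
    ggplot2::geom_hline(yintercept = chance, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = NULL, y = "Decoding accuracy (%)") +
    ggplot2::theme_minimal()
}
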