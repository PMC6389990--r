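#' Configuration for the synthetic experiment generator
#'
#' The generator emulates the statistical structure of a clue-based "guessing
#' game" design: `n_categories * items_per_category` target objects, nine clue
#' features per target arranged into six clue triplets (two sets of three
#' blocks, position-preserving recombination between sets), a D-dimensional
#' embedding space, and voxel beta patterns that are a noisy linear image of
#' each target's summed-feature (pattern-completion) semantic coordinate.
#'
#' Dispersions are in embedding units: category centroids are drawn
#' `N(0, sigma_category^2 I)`, target vectors sit at `centroid +
#' N(0, sigma_item^2 I)`, and each feature vector is `alpha * target +
#' N(0, sigma_feature^2 I)`. Forward weights on informative voxels have
#' variance `1/D`, which makes the per-voxel signal scale independent of `D`;
#' `noise_sd` is the trial-level beta noise standard deviation in the same
#' (arbitrary BOLD beta) units.
#'
#' @param n_categories Number of semantic categories (default 4).
#' @param items_per_category Targets per category (default 15, so 60 targets).
#' @param clues_per_target Clue features per target (default 9; must be
#'   divisible by 3, and at least 6 so that set recombination is possible).
#' @param nonclues_per_target Additional non-clue norm features per target
#'   (default 10).
#' @param dim Embedding dimensionality D (default 300; reducible).
#' @param grid Integer vector of 3 voxel-grid extents (default `c(24,24,24)`).
#' @param voxel_mm Isotropic voxel size in millimetres (default 3.1).
#' @param n_informative Number of voxels carrying signal (default 500).
#' @param noise_sd Trial-level beta noise SD (default 60; chosen so that
#'   default-noise decoding lands between chance and ceiling).
#' @param sigma_category,sigma_item,sigma_feature Dispersion SDs of category
#'   centroids, items around their centroid, and features around
#'   `alpha * target` (defaults 1, 0.5, 0.6).
#' @param alpha Feature-on-target loading (default 0.8).
#' @param informative_layout `"random"` (uniform within the mask; used for
#'   decoding studies) or `"blob"` (one spatially contiguous cluster; used for
#'   searchlight localization studies).
#' @param seed Master seed; together with the other fields it fully
#'   determines every generated artifact.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_categories = 4L,
                       items_per_category = 15L,
                       clues_per_target = 9L,
                       nonclues_per_target = 10L,
                       dim = 300L,
                       grid = c(24L, 24L, 24L),
                       voxel_mm = 3.1,
                       n_informative = 500L,
                       noise_sd = 60,
                       sigma_category = 1,
                       sigma_item = 0.5,
                       sigma_feature = 0.6,
                       alpha = 0.8,
                       informative_layout = c("random", "blob"),
                       seed = 1L) {
  informative_layout <- match.arg(informative_layout)
  cfg <- list(
    n_categories = assert_count(n_categories, "n_categories"),
    items_per_category = assert_count(items_per_category, "items_per_category"),
    clues_per_target = assert_count(clues_per_target, "clues_per_target", min = 3L),
    nonclues_per_target = assert_count(nonclues_per_target, "nonclues_per_target", min = 0L),
    dim = assert_count(dim, "dim", min = 2L),
    grid = vapply(grid, assert_count, integer(1), name = "grid", min = 2L),
    voxel_mm = as.numeric(voxel_mm),
    n_informative = assert_count(n_informative, "n_informative"),
    noise_sd = as.numeric(noise_sd),
    sigma_category = as.numeric(sigma_category),
    sigma_item = as.numeric(sigma_item),
    sigma_feature = as.numeric(sigma_feature),
    alpha = as.numeric(alpha),
    informative_layout = informative_layout,
    seed = assert_count(seed, "seed")
  )
  if (length(cfg$grid) != 3L) {
    stop_semdec("`grid` must have exactly 3 extents.", "semdecode_validation_error")
  }
  if (cfg$clues_per_target %% 3L != 0L) {
    stop_semdec("`clues_per_target` must be divisible by 3 (clues are shown as triplets).",
                "semdecode_validation_error")
  }
  if (cfg$voxel_mm <= 0 || cfg$noise_sd < 0 || cfg$sigma_category < 0 ||
      cfg$sigma_item < 0 || cfg$sigma_feature < 0) {
    stop_semdec("Scales must be non-negative (voxel_mm strictly positive).",
                "semdecode_validation_error")
  }
  structure(cfg, class = "sim_config")
}

default_categories <- function(n) {
  base <- c("animal", "fruitveg", "tool", "vehicle")
  if (n <= length(base)) base[seq_len(n)] else c(base, sprintf("category%02d", seq_len(n - length(base))))
}

#' Generate a synthetic semantic space, feature norms and keyword map
#'
#' Category centroids, target vectors and feature vectors are drawn under the
#' hierarchical Gaussian model described in [sim_config()]. Each target gets
#' `clues_per_target` clue-flagged features carrying distinctiveness ranks
#' (1 = least distinctive) plus `nonclues_per_target` non-clue features. The
#' keyword map sends each feature's text to its single key token, emulating
#' the table-driven key-word resolution used with behavioural feature norms.
#'
#' @param config A [sim_config()].
#' @return List with elements `space` ([semantic_space()]), `norms` (tibble:
#'   `target`, `category`, `feature`, `token`, `rank`, `is_clue`), `map`
#'   (tibble: `text`, `token`) and `targets` (tibble: `target`, `category`).
#' @export
generate_space_and_norms <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- derive_seeds(config$seed, 4L)
  with_seed(seeds[1L], {
    D <- config$dim
    cats <- default_categories(config$n_categories)
    n_feat <- config$clues_per_target + config$nonclues_per_target
    targets <- tibble(
      target = character(0), category = character(0)
    )
    vec_list <- list()
    norm_list <- list()
    for (ci in seq_along(cats)) {
      centroid <- rnorm(D, 0, config$sigma_category)
      for (ii in seq_len(config$items_per_category)) {
        tgt <- sprintf("%s_%02d", cats[ci], ii)
        tv <- centroid + rnorm(D, 0, config$sigma_item)
        vec_list[[tgt]] <- tv
        fk <- sprintf("%s_f%02d", tgt, seq_len(n_feat))
        for (k in seq_len(n_feat)) {
          vec_list[[fk[k]]] <- config$alpha * tv + rnorm(D, 0, config$sigma_feature)
        }
        norm_list[[tgt]] <- tibble(
          target = tgt,
          category = cats[ci],
          feature = gsub("_", " ", fk),
          token = fk,
          rank = seq_len(n_feat),
          is_clue = seq_len(n_feat) <= config$clues_per_target
        )
        targets <- rbind(targets, tibble(target = tgt, category = cats[ci]))
      }
    }
    vecs <- do.call(rbind, vec_list)
    rownames(vecs) <- names(vec_list)
    norms <- dplyr::bind_rows(norm_list)
    map <- tibble(
      text = c(norms$feature, targets$target),
      token = c(norms$token, targets$target)
    )
    map <- dplyr::distinct(map)
    list(space = semantic_space(vecs), norms = norms, map = map, targets = targets)
  })
}

# Position-preserving recombination of clue triplets between the two stimulus
# sets. Clues ranked 1..k are split into three position groups of m = k/3;
# set 1 block j shows (g1[j], g2[j], g3[j]); set 2 block j shows
# (g1[j], g2[j+1], g3[j+2]) with cyclic shifts, so every clue keeps its
# within-triplet position while the groupings differ.
triplet_sets <- function(m) {
  set1 <- cbind(seq_len(m), m + seq_len(m), 2L * m + seq_len(m))
  shift <- function(v, s) v[(seq_len(m) + s - 1L) %% m + 1L]
  set2 <- cbind(seq_len(m), shift(m + seq_len(m), 1L), shift(2L * m + seq_len(m), 2L))
  rbind(set1, set2)
}

#' Assemble the clue-triplet trial table
#'
#' Produces `2 * clues_per_target / 3` trials per target (six with the default
#' nine clues): two sets of blocks whose triplets recombine the same clues with
#' positions retained, each clue appearing exactly once per set, and triplets
#' within a target pairwise distinct. Each trial is also assigned a donor
#' trial of the same target from another block with a fully disjoint clue set,
#' used by the `MIXED_CLUES` coordinate model.
#'
#' @param norms Feature norms as produced by [generate_space_and_norms()].
#' @param config A [sim_config()].
#' @return Tibble with columns `trial`, `target`, `category`, `block`, `set`,
#'   `clue1`, `clue2`, `clue3` (feature texts) and `donor` (trial id).
#' @export
assemble_trials <- function(norms, config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$clues_per_target %/% 3L
  if (m < 2L) {
    stop_semdec("Triplet recombination between sets needs at least 6 clues per target.",
                "semdecode_generation_error")
  }
  plan <- triplet_sets(m)
  n_blocks <- nrow(plan)
  per_target <- function(df) {
    clues <- df$feature[df$is_clue][order(df$rank[df$is_clue])]
    if (anyDuplicated(clues)) {
      stop_semdec(sprintf("Target '%s' has duplicated clue texts; recombination impossible.",
                          df$target[1]), "semdecode_generation_error")
    }
    tb <- tibble(
      trial = sprintf("%s_b%d", df$target[1], seq_len(n_blocks)),
      target = df$target[1],
      category = df$category[1],
      block = seq_len(n_blocks),
      set = rep(1:2, each = m),
      clue1 = clues[plan[, 1]],
      clue2 = clues[plan[, 2]],
      clue3 = clues[plan[, 3]]
    )
    # donor: next block within the same set (cyclic); within-set triplets
    # partition the clues, so donor clue sets are disjoint from the trial's own
    donor_block <- ifelse(tb$block %% m == 0L, tb$block - m + 1L, tb$block + 1L)
    tb$donor <- sprintf("%s_b%d", df$target[1], donor_block)
    tb
  }
  out <- norms |>
    dplyr::group_by(.data$target) |>
    dplyr::group_split() |>
    purrr::map(per_target) |>
    dplyr::bind_rows()
  out[order(match(out$target, unique(norms$target)), out$block), ]
}

grid_coords <- function(grid) {
  as.matrix(expand.grid(x = seq_len(grid[1]), y = seq_len(grid[2]), z = seq_len(grid[3])))
}

# Inscribed-sphere analysis mask: a crude stand-in for a gray-matter mask.
default_mask <- function(grid) {
  co <- grid_coords(grid)
  centre <- (grid + 1) / 2
  r <- min(grid) / 2 - 0.5
  d2 <- (co[, 1] - centre[1])^2 + (co[, 2] - centre[2])^2 + (co[, 3] - centre[3])^2
  array(d2 <= r^2, dim = grid)
}

#' Generate the forward model ("ground truth") for one synthetic subject
#'
#' Picks the informative voxel set inside the mask (uniformly at random, or as
#' one contiguous blob around a random in-mask centre) and draws the forward
#' weight matrix mapping semantic coordinates to voxel betas. Rows outside the
#' informative set are all zero.
#'
#' @param config A [sim_config()].
#' @param target_coordinates `n_targets x D` matrix of the per-target
#'   summed-feature (`ALL_FEATURES`) coordinates that drive the voxels.
#' @param seed Seed for this subject's weights.
#' @param informative Optional pre-drawn informative voxel index set. In a
#'   multi-subject experiment the informative *locations* are shared across
#'   subjects (see [pick_informative()]) while the weights stay
#'   subject-specific, mirroring shared functional anatomy with individual
#'   response patterns.
#' @return List of class `ground_truth`: `weights` (`V_masked x D`),
#'   `informative` (indices into masked voxels), `mask` (logical array),
#'   `coords` (`V_masked x 3` grid indices), `voxel_mm`,
#'   `target_coordinates`, `categories`.
#' @export
generate_ground_truth <- function(config, target_coordinates, seed,
                                  informative = NULL) {
  stopifnot(inherits(config, "sim_config"))
  mask <- default_mask(config$grid)
  co <- grid_coords(config$grid)[as.vector(mask), , drop = FALSE]
  V <- nrow(co)
  if (config$n_informative > V) {
    stop_semdec(sprintf("n_informative (%d) exceeds masked voxel count (%d).",
                        config$n_informative, V), "semdecode_validation_error")
  }
  D <- ncol(target_coordinates)
  seeds <- derive_seeds(seed, 2L)
  if (is.null(informative)) {
    informative <- pick_informative(config, co, seeds[1L])
  }
  with_seed(seeds[2L], {
    W <- matrix(0, nrow = V, ncol = D)
    W[informative, ] <- rnorm(length(informative) * D, 0, 1 / sqrt(D))
    structure(list(weights = W, informative = informative, mask = mask,
                   coords = co, voxel_mm = config$voxel_mm,
                   target_coordinates = target_coordinates),
              class = "ground_truth")
  })
}

#' Draw the informative voxel index set
#'
#' Either uniformly at random within the mask (`"random"`; the decoder makes
#' no spatial claim) or as one spatially contiguous blob around a random
#' in-mask centre (`"blob"`; used to validate searchlight localization).
#'
#' @param config A [sim_config()].
#' @param coords `V x 3` grid indices of the masked voxels.
#' @param seed RNG seed.
#' @return Sorted integer vector of `n_informative` voxel indices.
#' @export
pick_informative <- function(config, coords, seed) {
  if (config$n_informative > nrow(coords)) {
    stop_semdec(sprintf("n_informative (%d) exceeds masked voxel count (%d).",
                        config$n_informative, nrow(coords)),
                "semdecode_validation_error")
  }
  with_seed(seed, {
    V <- nrow(coords)
    if (config$informative_layout == "random") {
      sort(sample.int(V, config$n_informative))
    } else {
      centre <- coords[sample.int(V, 1L), ]
      d2 <- (coords[, 1] - centre[1])^2 + (coords[, 2] - centre[2])^2 +
        (coords[, 3] - centre[3])^2
      sort(order(d2)[seq_len(config$n_informative)])
    }
  })
}

#' Simulate a stack of trial beta maps from a forward model
#'
#' The beta row of trial `t` is `W s_t + N(0, noise_sd^2 I)`, where `s_t` is
#' the `ALL_FEATURES` coordinate of the trial's target. Driving every trial of
#' a target with the full summed-feature coordinate -- rather than with the
#' clues actually shown -- encodes the pattern-completion hypothesis as the
#' generative assumption, so that recovery of the model ordering downstream is
#' a meaningful check. Non-informative voxels carry pure noise.
#'
#' @param trials Trial table from [assemble_trials()].
#' @param truth A [generate_ground_truth()] result.
#' @param config A [sim_config()].
#' @param seed Seed for the noise draw.
#' @return A `beta_stack`: list with `betas` (`n_trials x V_masked`), `trials`,
#'   `coords`, `mask`, `voxel_mm`, `grid`.
#' @export
simulate_betas <- function(trials, truth, config, seed) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  Y <- truth$target_coordinates
  if (ncol(truth$weights) != ncol(Y)) {
    stop_semdec("Dimension mismatch between forward weights and coordinates.",
                "semdecode_configuration_error")
  }
  idx <- match(trials$target, rownames(Y))
  if (anyNA(idx)) {
    stop_semdec("Trial table names targets absent from the ground-truth coordinates.",
                "semdecode_configuration_error")
  }
  S <- Y[idx, , drop = FALSE]
  signal <- S %*% t(truth$weights)
  with_seed(seed, {
    noise <- matrix(rnorm(length(signal), 0, config$noise_sd), nrow = nrow(signal))
    betas <- signal + noise
  })
  rownames(betas) <- trials$trial
  structure(list(betas = betas, trials = trials, coords = truth$coords,
                 mask = truth$mask, voxel_mm = truth$voxel_mm, grid = config$grid),
            class = "beta_stack")
}

#' @export
print.beta_stack <- function(x, ...) {
  cat(sprintf("<beta_stack: %d trials x %d masked voxels (grid %s, %.1f mm)>\n",
              nrow(x$betas), ncol(x$betas), paste(x$grid, collapse = "x"), x$voxel_mm))
  invisible(x)
}

#' Simulate a complete multi-subject experiment
#'
#' Generates the shared semantic space, feature norms and trial design once,
#' and draws the informative voxel locations once, then gives each subject
#' independent forward weights and noise: stimuli and functional anatomy are
#' shared across subjects, response patterns are not.
#'
#' @param config A [sim_config()].
#' @param n_subjects Number of synthetic subjects.
#' @return List of class `semdec_dataset`: `space`, `norms`, `map`, `targets`,
#'   `trials`, `target_coordinates` (`ALL_FEATURES`, targets x D), `truths`
#'   (per subject), `subjects` (per-subject `beta_stack`s), `config`.
#' @examples
#' cfg <- sim_config(n_categories = 2, items_per_category = 2, dim = 10,
#'                   grid = c(6, 6, 6), n_informative = 12, seed = 1)
#' ds <- simulate_experiment(cfg, n_subjects = 1)
#' ds$subjects[[1]]
#' glance(decode_l2o_averaged(ds$subjects[[1]], ds$target_coordinates, k = 12))
#' @export
simulate_experiment <- function(config, n_subjects = 1L) {
  n_subjects <- assert_count(n_subjects, "n_subjects")
  gen <- generate_space_and_norms(config)
  trials <- assemble_trials(gen$norms, config)
  Yt <- design_matrix(trials, "ALL_FEATURES", gen$norms, gen$map, gen$space,
                      level = "target")
  seeds <- derive_seeds(config$seed + 1L, 2L * n_subjects + 1L)
  mask <- default_mask(config$grid)
  co <- grid_coords(config$grid)[as.vector(mask), , drop = FALSE]
  informative <- pick_informative(config, co, seeds[2L * n_subjects + 1L])
  truths <- vector("list", n_subjects)
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    truths[[s]] <- generate_ground_truth(config, Yt, seed = seeds[2L * s - 1L],
                                         informative = informative)
    subjects[[s]] <- simulate_betas(trials, truths[[s]], config, seed = seeds[2L * s])
  }
  structure(list(space = gen$space, norms = gen$norms, map = gen$map,
                 targets = gen$targets, trials = trials,
                 target_coordinates = Yt, truths = truths, subjects = subjects,
                 config = config),
            class = "semdec_dataset")
}

#' @export
print.semdec_dataset <- function(x, ...) {
  cat(sprintf("<semdec_dataset: %d targets, %d trials, %d subject(s), D=%d>\n",
              nrow(x$targets), nrow(x$trials), length(x$subjects), x$config$dim))
  invisible(x)
}

mask_to_volume <- function(values, mask) {
  vol <- array(0, dim = dim(mask))
  vol[mask] <- values
  vol
}

#' Write a synthetic dataset to standard neuroimaging files
#'
#' Betas go into one 4-D NIfTI (trial along the 4th axis), the mask into a 3-D
#' NIfTI (both with the voxel size on the affine diagonal); the trial table,
#' feature norms and keyword map into TSV; the semantic space into word2vec
#' text format; and the ground truth into a small documented archive (a
#' directory with `meta.json`, informative-voxel indices and the nonzero
#' forward-weight rows as TSV). Reading the files back reproduces the beta
#' matrix exactly.
#'
#' @param stack A `beta_stack`.
#' @param dir Output directory (created if needed).
#' @param norms,map,space Optional tables/space to write alongside.
#' @param truth Optional `ground_truth` to archive.
#' @return Invisibly, a named list of the paths written.
#' @export
write_fixtures <- function(stack, dir, norms = NULL, map = NULL, space = NULL,
                           truth = NULL) {
  stopifnot(inherits(stack, "beta_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  vol4 <- array(0, dim = c(stack$grid, nrow(stack$betas)))
  for (t in seq_len(nrow(stack$betas))) {
    vol4[, , , t] <- mask_to_volume(stack$betas[t, ], stack$mask)
  }
  beta_img <- RNifti::asNifti(vol4)
  RNifti::pixdim(beta_img) <- c(rep(stack$voxel_mm, 3), 1)
  paths$betas <- file.path(dir, "betas.nii")
  RNifti::writeNifti(beta_img, paths$betas)
  mask_img <- RNifti::asNifti(array(as.integer(stack$mask), dim = stack$grid))
  RNifti::pixdim(mask_img) <- rep(stack$voxel_mm, 3)
  paths$mask <- file.path(dir, "mask.nii")
  RNifti::writeNifti(mask_img, paths$mask)
  paths$trials <- file.path(dir, "trials.tsv")
  utils::write.table(stack$trials, paths$trials, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(norms)) {
    paths$norms <- file.path(dir, "norms.tsv")
    utils::write.table(norms, paths$norms, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(map)) {
    paths$map <- file.path(dir, "keyword_map.tsv")
    utils::write.table(map, paths$map, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(space)) {
    paths$space <- file.path(dir, "vectors.w2v.txt")
    write_word2vec(space, paths$space)
  }
  if (!is.null(truth)) {
    tdir <- file.path(dir, "ground_truth")
    dir.create(tdir, showWarnings = FALSE)
    jsonlite::write_json(
      list(n_voxels = nrow(truth$weights), dim = ncol(truth$weights),
           voxel_mm = truth$voxel_mm, informative = truth$informative),
      file.path(tdir, "meta.json"), auto_unbox = TRUE, digits = NA)
    utils::write.table(
      cbind(voxel = truth$informative, truth$weights[truth$informative, , drop = FALSE]),
      file.path(tdir, "weights.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      cbind(target = rownames(truth$target_coordinates), as.data.frame(truth$target_coordinates)),
      file.path(tdir, "target_coordinates.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    paths$ground_truth <- tdir
  }
  invisible(paths)
}

#' Read a beta stack written by [write_fixtures()]
#'
#' @param dir Directory containing `betas.nii`, `mask.nii` and `trials.tsv`.
#' @return A `beta_stack`.
#' @export
read_fixtures <- function(dir) {
  bp <- file.path(dir, "betas.nii")
  mp <- file.path(dir, "mask.nii")
  tp <- file.path(dir, "trials.tsv")
  for (p in c(bp, mp, tp)) {
    if (!file.exists(p)) stop_semdec(sprintf("Missing fixture file: %s", p), "semdecode_io_error")
  }
  beta_img <- RNifti::readNifti(bp)
  mask_img <- RNifti::readNifti(mp)
  grid <- dim(mask_img)
  mask <- array(as.array(mask_img) != 0, dim = grid)
  voxel_mm <- RNifti::pixdim(mask_img)[1]
  trials <- as_tibble(utils::read.delim(tp, stringsAsFactors = FALSE))
  arr <- as.array(beta_img)
  n_trials <- dim(arr)[4]
  betas <- t(apply(arr, 4, function(v) v[mask]))
  if (n_trials == 1L) betas <- matrix(arr[, , , 1][mask], nrow = 1)
  rownames(betas) <- trials$trial
  co <- grid_coords(grid)[as.vector(mask), , drop = FALSE]
  structure(list(betas = betas, trials = trials, coords = co, mask = mask,
                 voxel_mm = voxel_mm, grid = as.integer(grid)),
            class = "beta_stack")
}
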