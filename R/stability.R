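#' Arrange a beta stack as a target x repetition x voxel array
#'
#' Trials of each target are ordered by block, giving the repetition axis.
#' Requires a complete design (the same number of trials per target).
#'
#' @param stack A `beta_stack`.
#' @return Numeric array `[n_targets, n_repetitions, V]` with target ids in
#'   `dimnames[[1]]`.
#' @export
beta_array <- function(stack) {
  stopifnot(inherits(stack, "beta_stack"))
  tr <- stack$trials
  targets <- unique(tr$target)
  reps <- table(tr$target)
  if (length(unique(reps)) != 1L) {
    stop_semdec("Incomplete repetition structure: targets have unequal trial counts.",
                "semdecode_validation_error")
  }
  R <- unname(reps[1])
  V <- ncol(stack$betas)
  arr <- array(NA_real_, dim = c(length(targets), R, V),
               dimnames = list(targets, NULL, NULL))
  for (i in seq_along(targets)) {
    rows <- which(tr$target == targets[i])
    rows <- rows[order(tr$block[rows])]
    arr[i, , ] <- stack$betas[rows, , drop = FALSE]
  }
  arr
}

pair_indices <- function(R) {
  p <- utils::combn(R, 2)
  list(a = p[1, ], b = p[2, ])
}

#' Per-voxel stability scores
#'
#' For every voxel, the repetition profiles over the training targets are
#' correlated pairwise (all `choose(R, 2)` Pearson correlations between the
#' `R` repetition profiles) and the correlations are averaged. Pairs in which
#' either profile has zero variance contribute r = 0: a flat voxel carries
#' no stable signal. Held-out targets must be excluded from `training` so that
#' voxel selection never sees the test items.
#'
#' @param betas Array `[targets, repetitions, voxels]` (see [beta_array()]).
#' @param training Indices of training targets (default: all).
#' @return Numeric vector of per-voxel mean correlations in `[-1, 1]`.
#' @export
stability_scores <- function(betas, training = seq_len(dim(betas)[1])) {
  stopifnot(length(dim(betas)) == 3L)
  R <- dim(betas)[2]
  if (R < 2L) {
    stop_semdec("Stability needs at least 2 repetitions.", "semdecode_validation_error")
  }
  if (length(training) < 3L) {
    stop_semdec("Stability needs at least 3 training targets.", "semdecode_validation_error")
  }
  V <- dim(betas)[3]
  pr <- pair_indices(R)
  acc <- numeric(V)
  n <- length(training)
  for (p in seq_along(pr$a)) {
    x <- betas[training, pr$a[p], , drop = TRUE]
    y <- betas[training, pr$b[p], , drop = TRUE]
    x <- sweep(matrix(x, nrow = n), 2, colMeans(matrix(x, nrow = n)))
    y <- sweep(matrix(y, nrow = n), 2, colMeans(matrix(y, nrow = n)))
    num <- colSums(x * y)
    den <- sqrt(colSums(x * x) * colSums(y * y))
    r <- ifelse(den > 0, num / den, 0)
    acc <- acc + r
  }
  acc / length(pr$a)
}

#' Select the most stable voxels
#'
#' Indices of the `k` largest stability scores; ties are broken by ascending
#' voxel index. If `k` exceeds the voxel count, all voxels are selected with a
#' warning.
#'
#' @param scores Per-voxel stability scores.
#' @param k Number of voxels to keep (default 500).
#' @return Sorted integer vector of selected voxel indices.
#' @export
select_stable_voxels <- function(scores, k = 500L) {
  k <- assert_count(k, "k")
  V <- length(scores)
  if (k > V) {
    warn(sprintf("k = %d exceeds the voxel count (%d); selecting all voxels.", k, V),
         class = "semdecode_selection_warning")
    return(seq_len(V))
  }
  ord <- order(-scores, seq_along(scores), method = "radix")
  sort(ord[seq_len(k)])
}

#' Average betas over repetitions
#'
#' @param betas Array `[targets, repetitions, voxels]`.
#' @return Matrix `[targets, voxels]` of arithmetic means over the repetition
#'   axis, rows named by target.
#' @export
average_repetitions <- function(betas) {
  stopifnot(length(dim(betas)) == 3L)
  R <- dim(betas)[2]
  out <- betas[, 1L, , drop = TRUE]
  out <- matrix(out, nrow = dim(betas)[1])
  if (R > 1L) {
    for (r in 2:R) out <- out + matrix(betas[, r, , drop = TRUE], nrow = dim(betas)[1])
  }
  out <- out / R
  rownames(out) <- dimnames(betas)[[1]]
  out
}

# Sufficient statistics for fast leave-two-out stability: per repetition pair,
# the running sums over *all* targets of x, y, x^2, y^2 and x*y per voxel.
# A fold's training-set correlations are then obtained by downdating the sums
# with the two held-out targets' rows (O(pairs * V) per fold instead of a full
# recomputation).
stability_suffstats <- function(betas) {
  R <- dim(betas)[2]
  pr <- pair_indices(R)
  np <- length(pr$a)
  V <- dim(betas)[3]
  sx <- sy <- sxx <- syy <- sxy <- matrix(0, nrow = np, ncol = V)
  for (p in seq_len(np)) {
    x <- matrix(betas[, pr$a[p], , drop = TRUE], nrow = dim(betas)[1])
    y <- matrix(betas[, pr$b[p], , drop = TRUE], nrow = dim(betas)[1])
    sx[p, ] <- colSums(x)
    sy[p, ] <- colSums(y)
    sxx[p, ] <- colSums(x * x)
    syy[p, ] <- colSums(y * y)
    sxy[p, ] <- colSums(x * y)
  }
  list(pairs = pr, sx = sx, sy = sy, sxx = sxx, syy = syy, sxy = sxy,
       n = dim(betas)[1], betas = betas)
}

stability_from_suffstats <- function(ss, holdout) {
  pr <- ss$pairs
  np <- length(pr$a)
  n <- ss$n - length(holdout)
  sx <- ss$sx; sy <- ss$sy; sxx <- ss$sxx; syy <- ss$syy; sxy <- ss$sxy
  for (h in holdout) {
    xa <- matrix(ss$betas[h, pr$a, , drop = TRUE], nrow = np)
    xb <- matrix(ss$betas[h, pr$b, , drop = TRUE], nrow = np)
    sx <- sx - xa
    sy <- sy - xb
    sxx <- sxx - xa * xa
    syy <- syy - xb * xb
    sxy <- sxy - xa * xb
  }
  num <- sxy - sx * sy / n
  vx <- sxx - sx * sx / n
  vy <- syy - sy * sy / n
  vx[vx < 0] <- 0
  vy[vy < 0] <- 0
  den <- sqrt(vx * vy)
  r <- num
  ok <- den > .Machine$double.eps * pmax(sxx, syy, 1)
  r[ok] <- num[ok] / den[ok]
  r[!ok] <- 0
  colMeans(r)
}

#' Write a selected-voxel mask as NIfTI for inspection
#'
#' @param stack The `beta_stack` the selection refers to.
#' @param voxels Integer indices into the masked voxels.
#' @param path Output `.nii` path.
#' @return Invisibly, `path`.
#' @export
write_selection_mask <- function(stack, voxels, path) {
  stopifnot(inherits(stack, "beta_stack"))
  sel <- numeric(ncol(stack$betas))
  sel[voxels] <- 1
  img <- RNifti::asNifti(mask_to_volume(sel, stack$mask))
  RNifti::pixdim(img) <- rep(stack$voxel_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}
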