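# Searchlight representational similarity analysis with nonparametric
# sign-flip group inference (pseudo-t, FWE by the maximum statistic).

new_rdm <- function(m, metric) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > 1e-10 || max(abs(diag(m))) > 1e-10) {
    stop_semdec("RDM must be symmetric with a zero diagonal.",
                "semdecode_validation_error")
  }
  m <- (m + t(m)) / 2
  diag(m) <- 0
  structure(m, metric = metric, class = c("semdec_rdm", "matrix"))
}

#' Semantic model RDM (pairwise cosine distances)
#'
#' @param coordinates Matrix `n x D` of semantic coordinates (no zero-norm
#'   rows).
#' @return An `n x n` `semdec_rdm` of cosine distances (entries in `[0, 2]`,
#'   zero diagonal).
#' @examples
#' model_rdm(rbind(a = c(1, 0), b = c(0, 1), c = c(1, 1)))
#' @export
model_rdm <- function(coordinates) {
  coordinates <- as.matrix(coordinates)
  norms <- sqrt(rowSums(coordinates^2))
  if (any(norms == 0)) {
    stop_semdec(sprintf("Zero-norm coordinate row(s): %s",
                        paste(which(norms == 0), collapse = ", ")),
                "semdecode_degenerate_coordinate_error")
  }
  cosim <- tcrossprod(coordinates / norms)
  cosim[cosim > 1] <- 1
  cosim[cosim < -1] <- -1
  d <- 1 - cosim
  diag(d) <- 0
  new_rdm(d, "cosine")
}

#' Activation-pattern RDM (1 - Pearson correlation)
#'
#' @param patterns Matrix `n x v` of activation patterns (rows = conditions or
#'   trials). Rows with zero variance get distance 1 to everything (r treated
#'   as 0) with a warning.
#' @return An `n x n` `semdec_rdm` of correlation distances in `[0, 2]`.
#' @export
activation_rdm <- function(patterns) {
  patterns <- as.matrix(patterns)
  v <- apply(patterns, 1, sd)
  cc <- suppressWarnings(cor(t(patterns)))
  if (any(v == 0)) {
    warn(sprintf("%d zero-variance pattern(s); their correlation distance is set to 1.",
                 sum(v == 0)),
         class = "semdecode_degenerate_pattern_warning")
    cc[v == 0, ] <- 0
    cc[, v == 0] <- 0
  }
  d <- 1 - cc
  diag(d) <- 0
  new_rdm(d, "one-minus-pearson")
}

lower_tri <- function(m) m[lower.tri(m)]

# Integer offsets whose centre-to-centre distance is within `radius_mm` on an
# isotropic grid of `voxel_mm` spacing.
sphere_offsets <- function(radius_mm, voxel_mm) {
  if (radius_mm < voxel_mm) {
    warn(sprintf("Radius %.2f mm is below the voxel size %.2f mm; spheres contain a single voxel.",
                 radius_mm, voxel_mm),
         class = "semdecode_searchlight_warning")
  }
  r <- floor(radius_mm / voxel_mm)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  keep <- voxel_mm^2 * (g$dx^2 + g$dy^2 + g$dz^2) <= radius_mm^2
  as.matrix(g[keep, , drop = FALSE])
}

#' Spherical searchlight neighborhoods on a masked voxel grid
#'
#' For each masked voxel, all masked voxels whose centre-to-centre Euclidean
#' distance is at most `radius_mm` (the centre included). Neighborhoods of
#' edge voxels are clipped by the mask.
#'
#' @param coords Integer matrix `V x 3` of grid indices of the masked voxels.
#' @param grid Integer vector of 3 grid extents.
#' @param voxel_mm Isotropic voxel size in mm.
#' @param radius_mm Sphere radius in mm (default 7).
#' @return List of `V` integer vectors of voxel indices (into `coords` rows).
#' @export
sphere_neighborhoods <- function(coords, grid, voxel_mm, radius_mm = 7) {
  # a radius beyond the grid diagonal adds nothing; cap the offset enumeration
  r_eff <- min(radius_mm, voxel_mm * (sqrt(sum((grid - 1)^2)) + 1))
  off <- sphere_offsets(r_eff, voxel_mm)
  V <- nrow(coords)
  vol <- array(0L, dim = grid)
  vol[coords] <- seq_len(V)
  neigh <- matrix(0L, nrow = V, ncol = nrow(off))
  for (o in seq_len(nrow(off))) {
    nx <- coords[, 1] + off[o, 1]
    ny <- coords[, 2] + off[o, 2]
    nz <- coords[, 3] + off[o, 3]
    ok <- nx >= 1 & nx <= grid[1] & ny >= 1 & ny <= grid[2] & nz >= 1 & nz <= grid[3]
    idx <- integer(V)
    idx[ok] <- vol[cbind(nx[ok], ny[ok], nz[ok])]
    neigh[, o] <- idx
  }
  lapply(seq_len(V), function(v) {
    n <- neigh[v, ]
    sort(n[n > 0L])
  })
}

#' Searchlight RSA map
#'
#' For each mask voxel with at least two in-sphere voxels, the activation
#' RDM over the sphere is compared to the semantic model RDM by Spearman rank
#' correlation of the strictly-lower-triangle vectors (average ranks for
#' ties); the correlation is Fisher-transformed (`z = atanh(rho)`, with
#' `|rho| = 1` capped just below 1 to stay finite) and assigned to the centre
#' voxel. Constant RDM vectors yield 0 with a warning.
#'
#' @param stack A `beta_stack`; RDM row order follows `stack$trials`.
#' @param model A [model_rdm()] with one row per trial.
#' @param radius_mm Searchlight radius in mm (default 7).
#' @return Object of class `semdec_slmap`: `z` and `rho` vectors over masked
#'   voxels (NA where the sphere has fewer than 2 voxels), plus geometry.
#' @export
searchlight_rsa <- function(stack, model, radius_mm = 7) {
  stopifnot(inherits(stack, "beta_stack"), inherits(model, "semdec_rdm"))
  n <- nrow(stack$betas)
  if (nrow(model) != n) {
    stop_semdec("Model RDM size must match the trial count.",
                "semdecode_validation_error")
  }
  nb <- sphere_neighborhoods(stack$coords, stack$grid, stack$voxel_mm, radius_mm)
  model_ranks <- rank(lower_tri(unclass(model)))
  mr_c <- model_ranks - mean(model_ranks)
  mr_ss <- sqrt(sum(mr_c^2))
  rho <- rep(NA_real_, length(nb))
  n_constant <- 0L
  for (v in seq_along(nb)) {
    sphere <- nb[[v]]
    if (length(sphere) < 2L) next
    P <- stack$betas[, sphere, drop = FALSE]
    a <- suppressWarnings(activation_rdm_fast(P))
    av <- rank(lower_tri(a))
    ac <- av - mean(av)
    den <- sqrt(sum(ac^2)) * mr_ss
    if (den == 0) {
      n_constant <- n_constant + 1L
      rho[v] <- 0
    } else {
      rho[v] <- sum(ac * mr_c) / den
    }
  }
  if (n_constant > 0L) {
    warn(sprintf("%d searchlight(s) had a constant RDM vector; their correlation is set to 0.",
                 n_constant),
         class = "semdecode_searchlight_warning")
  }
  cap <- 1 - 1e-15
  z <- atanh(pmin(pmax(rho, -cap), cap))
  structure(list(z = z, rho = rho, coords = stack$coords, grid = stack$grid,
                 mask = stack$mask, voxel_mm = stack$voxel_mm,
                 radius_mm = radius_mm),
            class = "semdec_slmap")
}

# activation RDM without the S3 overhead/validation, for the inner loop
activation_rdm_fast <- function(P) {
  cc <- suppressWarnings(cor(t(P)))
  cc[!is.finite(cc)] <- 0
  d <- 1 - cc
  diag(d) <- 0
  d
}

#' @export
print.semdec_slmap <- function(x, ...) {
  cat(sprintf("<semdec_slmap: %d voxels, radius %.1f mm, peak z = %.3f>\n",
              length(x$z), x$radius_mm, max(x$z, na.rm = TRUE)))
  invisible(x)
}

#' Gaussian smoothing restricted to the mask
#'
#' Builds (or applies) a mask-renormalized Gaussian kernel: weights are
#' computed only between in-mask voxels and each row is renormalized to sum to
#' one, so no signal bleeds in from outside the mask. The FWHM-to-sigma
#' conversion is `sigma = fwhm / (2 * sqrt(2 * log(2)))`.
#'
#' @param coords,grid,voxel_mm Mask geometry (see [sphere_neighborhoods()]).
#' @param fwhm_mm Kernel full width at half maximum in mm.
#' @return A sparse `V x V` row-stochastic smoothing matrix
#'   ([Matrix::sparseMatrix()]).
#' @export
smoothing_matrix <- function(coords, grid, voxel_mm, fwhm_mm) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  cutoff <- 3 * sigma
  off <- sphere_offsets(cutoff, voxel_mm)
  V <- nrow(coords)
  vol <- array(0L, dim = grid)
  vol[coords] <- seq_len(V)
  ii <- jj <- vector("list", nrow(off))
  ww <- vector("list", nrow(off))
  for (o in seq_len(nrow(off))) {
    nx <- coords[, 1] + off[o, 1]
    ny <- coords[, 2] + off[o, 2]
    nz <- coords[, 3] + off[o, 3]
    ok <- nx >= 1 & nx <= grid[1] & ny >= 1 & ny <= grid[2] & nz >= 1 & nz <= grid[3]
    idx <- integer(V)
    idx[ok] <- vol[cbind(nx[ok], ny[ok], nz[ok])]
    hit <- which(idx > 0L)
    d2 <- voxel_mm^2 * sum(off[o, ]^2)
    ii[[o]] <- hit
    jj[[o]] <- idx[hit]
    ww[[o]] <- rep(exp(-d2 / (2 * sigma^2)), length(hit))
  }
  W <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(ww),
                            dims = c(V, V))
  rs <- Matrix::rowSums(W)
  Matrix::Diagonal(x = 1 / rs) %*% W
}

#' Smooth a masked statistic image
#'
#' @param values Numeric vector (or `V x m` matrix of images in columns) over
#'   the masked voxels; NAs are treated as 0.
#' @inheritParams smoothing_matrix
#' @return Smoothed values, same shape as the input.
#' @export
smooth_within_mask <- function(values, coords, grid, voxel_mm, fwhm_mm) {
  W <- smoothing_matrix(coords, grid, voxel_mm, fwhm_mm)
  v <- as.matrix(values)
  v[is.na(v)] <- 0
  out <- as.matrix(W %*% v)
  if (is.null(dim(values))) as.numeric(out) else out
}

sign_patterns <- function(n, n_perm, seed) {
  if (n_perm >= 2^n) {
    S <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    exhaustive <- TRUE
  } else {
    S <- with_seed(seed, {
      rbind(rep(1, n),
            matrix(sample(c(1, -1), (n_perm - 1L) * n, replace = TRUE),
                   ncol = n))
    })
    exhaustive <- FALSE
  }
  list(S = t(unname(as.matrix(S))), exhaustive = exhaustive)  # n x P
}

#' Group-level sign-flip pseudo-t inference with FWE control
#'
#' One-sample nonparametric test over subjects' (pre-smoothed) searchlight
#' Fisher-z maps. The pseudo-t statistic divides the subject mean by a
#' variance-smoothed standard error (`pseudo_t = mean / sqrt(smoothed_var /
#' n)`; the variance image is smoothed within the mask at `variance_fwhm_mm`).
#' The null is built by random sign flips of the subject maps (the identity
#' flip included; if `n_perm >= 2^n` all distinct sign patterns are enumerated
#' exhaustively instead), FWE is controlled by the distribution of the maximum
#' statistic, and the significance threshold is its empirical 95th percentile.
#'
#' @param z_maps `V x n_subjects` matrix of subject statistic maps over the
#'   masked voxels (use [smooth_within_mask()] beforehand if map smoothing is
#'   wanted).
#' @param coords,grid,voxel_mm Mask geometry.
#' @param variance_fwhm_mm Variance-smoothing FWHM in mm (default 6).
#' @param n_perm Number of sign-flip permutations (default 10000).
#' @param seed RNG seed for the sign flips.
#' @param alpha FWE level (default 0.05).
#' @return Object of class `semdec_groupstat`: `pseudo_t`, `threshold`,
#'   `flagged` (logical), per-voxel `fwe_p`, the max-statistic null
#'   distribution, and geometry.
#' @export
group_pseudo_t <- function(z_maps, coords, grid, voxel_mm,
                           variance_fwhm_mm = 6, n_perm = 10000L, seed = 1L,
                           alpha = 0.05) {
  z_maps <- as.matrix(z_maps)
  n <- ncol(z_maps)
  if (n < 2L) {
    stop_semdec("Group inference needs at least 2 subjects.",
                "semdecode_validation_error")
  }
  z_maps[is.na(z_maps)] <- 0
  V <- nrow(z_maps)
  W <- smoothing_matrix(coords, grid, voxel_mm, variance_fwhm_mm)
  sp <- sign_patterns(n, n_perm, seed)
  S <- sp$S
  P <- ncol(S)
  rss <- rowSums(z_maps^2)      # invariant under sign flips
  max_null <- numeric(P)
  t_obs <- NULL
  block <- 512L
  for (start in seq(1L, P, by = block)) {
    cols <- start:min(start + block - 1L, P)
    M <- z_maps %*% S[, cols, drop = FALSE] / n
    Vhat <- (rss - n * M^2) / (n - 1)
    Vhat[Vhat < 0] <- 0
    SV <- as.matrix(W %*% Vhat)
    Tm <- M / sqrt(SV / n)
    Tm[!is.finite(Tm)] <- 0
    max_null[cols] <- apply(Tm, 2, max)
    if (start == 1L) t_obs <- Tm[, 1]
  }
  threshold <- empirical_percentile(max_null, 1 - alpha)
  fwe_p <- vapply(t_obs, function(t) mean(max_null >= t), numeric(1))
  structure(list(pseudo_t = t_obs, threshold = threshold,
                 flagged = t_obs > threshold, fwe_p = fwe_p,
                 max_null = max_null, n_perm = P, exhaustive = sp$exhaustive,
                 variance_fwhm_mm = variance_fwhm_mm, alpha = alpha,
                 coords = coords, grid = grid, voxel_mm = voxel_mm,
                 n_subjects = n),
            class = "semdec_groupstat")
}

#' @export
print.semdec_groupstat <- function(x, ...) {
  cat(sprintf("<semdec_groupstat: %d voxels, %d subjects, %d sign flips%s, FWE threshold pseudo-t > %.2f, %d voxel(s) flagged>\n",
              length(x$pseudo_t), x$n_subjects, x$n_perm,
              if (x$exhaustive) " (exhaustive)" else "", x$threshold,
              sum(x$flagged)))
  invisible(x)
}

#' Cluster table of a thresholded group map
#'
#' Connected components (6-connectivity) of the voxels exceeding the FWE
#' threshold, with cluster extent, peak pseudo-t, peak location (grid indices
#' and mm) and the peak's FWE-corrected p value.
#'
#' @param x A [group_pseudo_t()] result.
#' @return Tibble sorted by peak pseudo-t: `cluster`, `extent`,
#'   `peak_pseudo_t`, `x`, `y`, `z` (grid), `x_mm`, `y_mm`, `z_mm`,
#'   `peak_fwe_p`.
#' @export
cluster_table <- function(x) {
  stopifnot(inherits(x, "semdec_groupstat"))
  V <- length(x$pseudo_t)
  vol <- array(0L, dim = x$grid)
  vol[x$coords] <- seq_len(V)
  flagged <- which(x$flagged)
  labels <- integer(V)
  n_cl <- 0L
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  for (v in flagged) {
    if (labels[v] != 0L) next
    n_cl <- n_cl + 1L
    queue <- v
    labels[v] <- n_cl
    while (length(queue) > 0) {
      cur <- queue[[1]]
      queue <- queue[-1]
      for (o in seq_len(6)) {
        p <- x$coords[cur, ] + offs[o, ]
        if (any(p < 1) || any(p > x$grid)) next
        w <- vol[p[1], p[2], p[3]]
        if (w > 0L && labels[w] == 0L && x$flagged[w]) {
          labels[w] <- n_cl
          queue <- c(queue, w)
        }
      }
    }
  }
  if (n_cl == 0L) {
    return(tibble(cluster = integer(0), extent = integer(0),
                  peak_pseudo_t = numeric(0), x = integer(0), y = integer(0),
                  z = integer(0), x_mm = numeric(0), y_mm = numeric(0),
                  z_mm = numeric(0), peak_fwe_p = numeric(0)))
  }
  rows <- lapply(seq_len(n_cl), function(cl) {
    members <- which(labels == cl)
    peak <- members[which.max(x$pseudo_t[members])]
    pc <- x$coords[peak, ]
    vm <- x$voxel_mm
    pt <- x$pseudo_t[peak]
    fp <- x$fwe_p[peak]
    tibble(cluster = cl, extent = length(members), peak_pseudo_t = pt,
           x = pc[1], y = pc[2], z = pc[3],
           x_mm = pc[1] * vm, y_mm = pc[2] * vm, z_mm = pc[3] * vm,
           peak_fwe_p = fp)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, dplyr::desc(.data$peak_pseudo_t))
  out$cluster <- seq_len(nrow(out))
  out
}

#' Write a masked statistic vector as a NIfTI image
#'
#' @param values Numeric vector over masked voxels.
#' @param mask Logical mask array.
#' @param voxel_mm Isotropic voxel size.
#' @param path Output `.nii` path.
#' @return Invisibly, `path`.
#' @export
write_stat_image <- function(values, mask, voxel_mm, path) {
  v <- values
  v[is.na(v)] <- 0
  img <- RNifti::asNifti(mask_to_volume(v, mask))
  RNifti::pixdim(img) <- rep(voxel_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Axial-slice map of a group pseudo-t image
#'
#' Shows the axial slice through the peak voxel with flagged voxels outlined.
#'
#' @param object A [group_pseudo_t()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.semdec_groupstat <- function(object, ...) {
  peak <- which.max(object$pseudo_t)
  zslice <- object$coords[peak, 3]
  sel <- object$coords[, 3] == zslice
  df <- tibble(x = object$coords[sel, 1], y = object$coords[sel, 2],
               pseudo_t = object$pseudo_t[sel],
               flagged = object$flagged[sel])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$pseudo_t)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = df[df$flagged, ], fill = NA, colour = "red",
                       linewidth = 0.3) +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Group pseudo-t, axial slice z = %d", zslice),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
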