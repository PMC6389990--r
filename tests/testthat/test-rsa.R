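test_that("model RDMs are cosine distances with enforced symmetry and zero diagonal", {
  X <- rbind(c(1, 0), c(0, 2), c(1, 0), c(-3, 0))
  r <- model_rdm(X)
  expect_equal(r[1, 2], 1)              # orthogonal rows
  expect_equal(r[1, 3], 0)              # identical direction
  expect_equal(r[1, 4], 2)              # opposite direction
  expect_equal(unclass(r), t(unclass(r)))
  expect_equal(diag(r), rep(0, 4))
  expect_error(model_rdm(rbind(c(1, 0), c(0, 0))),
               class = "semdecode_degenerate_coordinate_error")
  expect_error(semdecode:::new_rdm(matrix(c(0, 1, 2, 0), 2, 2), "cosine"),
               class = "semdecode_validation_error")
})

test_that("activation RDM entries match hand-computed correlation distances", {
  P <- rbind(c(1, 2, 3), c(1, 2, 4), c(-1, -2, -3))
  r <- activation_rdm(P)
  expect_equal(r[1, 1], 0)
  expect_equal(r[1, 3], 2)                        # perfect anticorrelation
  d_expected <- 1 - 9 / (2 * sqrt(21))            # hand Pearson on the toys
  expect_equal(r[1, 2], d_expected, tolerance = 1e-10)
  expect_equal(round(r[1, 2], 5), 0.01802)
  Pz <- rbind(c(1, 1, 1), c(1, 2, 3))
  expect_warning(rz <- activation_rdm(Pz),
                 class = "semdecode_degenerate_pattern_warning")
  expect_equal(rz[1, 2], 1)
})

test_that("sphere neighborhoods match an exhaustive distance-scan oracle", {
  grid <- c(9, 9, 9)
  mask <- semdecode:::default_mask(grid)
  co <- semdecode:::grid_coords(grid)[as.vector(mask), , drop = FALSE]
  nb <- sphere_neighborhoods(co, grid, voxel_mm = 3.1, radius_mm = 7)
  oracle <- oracle_neighborhoods(co, 3.1, 7)
  expect_identical(nb, lapply(oracle, as.integer))
  # interior voxels see the full offset count; edge voxels strict subsets
  sizes <- lengths(nb)
  centre <- which(co[, 1] == 5 & co[, 2] == 5 & co[, 3] == 5)
  expect_identical(max(sizes), sizes[centre])
  corner <- which.min(co[, 1] + co[, 2] + co[, 3])
  expect_lt(sizes[corner], sizes[centre])
})

test_that("a radius below the voxel size degrades to single-voxel spheres", {
  expect_warning(off <- semdecode:::sphere_offsets(2, 3.1),
                 class = "semdecode_searchlight_warning")
  expect_identical(nrow(off), 1L)
})

test_that("searchlight maps are invariant to monotone transforms of model distances", {
  ds <- tiny_dataset()
  stack <- ds$subjects[[1]]
  Y <- design_matrix(ds$trials, "ALL_FEATURES", ds$norms, ds$map, ds$space)
  m1 <- model_rdm(Y)
  m2 <- semdecode:::new_rdm(unclass(m1)^3, "cosine")   # strictly monotone on [0,2]
  s1 <- searchlight_rsa(stack, m1, radius_mm = 6.5)
  s2 <- searchlight_rsa(stack, m2, radius_mm = 6.5)
  expect_equal(s1$z, s2$z, tolerance = 1e-10)
})

test_that("a model RDM identical to the activation structure gives capped rho = 1", {
  ds <- tiny_dataset()
  stack <- ds$subjects[[1]]
  stack$betas <- stack$betas[1:10, , drop = FALSE]
  stack$trials <- stack$trials[1:10, ]
  model <- activation_rdm(stack$betas)    # same patterns, same metric
  sl <- searchlight_rsa(stack, model, radius_mm = 1000)  # sphere = whole mask
  expect_equal(sl$rho, rep(1, length(sl$rho)), tolerance = 1e-12)
  expect_true(all(is.finite(sl$z)))
  # rho at (or within rounding of) 1 is capped to keep the Fisher z finite
  expect_equal(max(sl$z), atanh(1 - 1e-15))
})

test_that("model distances unrelated to the activations give near-zero mean rho", {
  ds <- tiny_dataset()
  stack <- ds$subjects[[1]]
  set.seed(55)
  Yrand <- matrix(rnorm(nrow(stack$betas) * 10), ncol = 10)
  sl <- searchlight_rsa(stack, model_rdm(Yrand), radius_mm = 6.5)
  expect_lt(abs(mean(sl$rho, na.rm = TRUE)), 0.02)
})

test_that("constant activation RDM vectors yield rho 0 with a warning", {
  ds <- tiny_dataset()
  stack <- ds$subjects[[1]]
  stack$betas <- matrix(1, nrow = 12, ncol = ncol(stack$betas))  # flat patterns
  stack$trials <- stack$trials[1:12, ]
  set.seed(1)
  model <- model_rdm(matrix(rnorm(12 * 5), 12, 5))
  expect_warning(sl <- searchlight_rsa(stack, model, radius_mm = 6.5),
                 class = "semdecode_searchlight_warning")
  expect_true(all(sl$rho == 0))
})

test_that("mask-restricted smoothing kernels are renormalized and Gaussian", {
  grid <- c(7, 7, 7)
  mask <- semdecode:::default_mask(grid)
  co <- semdecode:::grid_coords(grid)[as.vector(mask), , drop = FALSE]
  W <- smoothing_matrix(co, grid, voxel_mm = 3.1, fwhm_mm = 6)
  expect_equal(as.numeric(Matrix::rowSums(W)), rep(1, nrow(co)), tolerance = 1e-12)
  # the weight ratio between a centre voxel and an axial neighbour follows
  # exp(-d^2 / (2 sigma^2)) with sigma = fwhm / (2 sqrt(2 log 2))
  centre <- which(co[, 1] == 4 & co[, 2] == 4 & co[, 3] == 4)
  nbr <- which(co[, 1] == 5 & co[, 2] == 4 & co[, 3] == 4)
  sigma <- 6 / (2 * sqrt(2 * log(2)))
  expect_equal(W[centre, nbr] / W[centre, centre],
               exp(-3.1^2 / (2 * sigma^2)), tolerance = 1e-10)
  # smoothing a constant image within the mask leaves it unchanged (no bleed)
  sm <- smooth_within_mask(rep(2.5, nrow(co)), co, grid, 3.1, 6)
  expect_equal(sm, rep(2.5, nrow(co)), tolerance = 1e-12)
})

test_that("group pseudo-t is zero on zero maps and enumerates exhaustively for small n", {
  grid <- c(6, 6, 6)
  mask <- semdecode:::default_mask(grid)
  co <- semdecode:::grid_coords(grid)[as.vector(mask), , drop = FALSE]
  gz <- group_pseudo_t(matrix(0, nrow(co), 3), co, grid, 3.1, n_perm = 8,
                       seed = 1)
  expect_true(all(gz$pseudo_t == 0))
  expect_identical(sum(gz$flagged), 0L)
  g2 <- group_pseudo_t(matrix(rnorm(nrow(co) * 2), ncol = 2), co, grid, 3.1,
                       n_perm = 100, seed = 1)
  expect_identical(g2$n_perm, 4L)       # 2^2 distinct sign patterns
  expect_true(g2$exhaustive)
  expect_error(group_pseudo_t(matrix(0, nrow(co), 1), co, grid, 3.1),
               class = "semdecode_validation_error")
})

test_that("the FWE threshold is reproducible from the stored null distribution", {
  grid <- c(6, 6, 6)
  mask <- semdecode:::default_mask(grid)
  co <- semdecode:::grid_coords(grid)[as.vector(mask), , drop = FALSE]
  set.seed(10)
  Z <- matrix(rnorm(nrow(co) * 5), ncol = 5)
  g <- group_pseudo_t(Z, co, grid, 3.1, n_perm = 64, seed = 4)
  expect_identical(g$threshold,
                   semdecode:::empirical_percentile(g$max_null, 0.95))
  expect_identical(g$flagged, g$pseudo_t > g$threshold)
  expect_true(all(g$fwe_p >= 0 & g$fwe_p <= 1))
  # sign-flip determinism
  g2 <- group_pseudo_t(Z, co, grid, 3.1, n_perm = 64, seed = 4)
  expect_identical(g$max_null, g2$max_null)
})

test_that("cluster labelling uses 6-connectivity with peaks per component", {
  grid <- c(8, 8, 8)
  mask <- array(TRUE, dim = grid)
  co <- semdecode:::grid_coords(grid)
  t_map <- rep(0, nrow(co))
  cube1 <- which(co[, 1] %in% 2:3 & co[, 2] %in% 2:3 & co[, 3] == 2)
  lone <- which(co[, 1] == 5 & co[, 2] == 5 & co[, 3] == 5)
  diag_nb <- which(co[, 1] == 6 & co[, 2] == 6 & co[, 3] == 6) # diagonal only
  t_map[cube1] <- c(5, 6, 7, 8)
  t_map[lone] <- 9
  t_map[diag_nb] <- 4.5
  gs <- structure(list(pseudo_t = t_map, threshold = 4,
                       flagged = t_map > 4,
                       fwe_p = ifelse(t_map > 4, 0.01, 0.9),
                       coords = co, grid = grid, voxel_mm = 3.1),
                  class = "semdec_groupstat")
  tab <- cluster_table(gs)
  expect_identical(nrow(tab), 3L)       # diagonal contact does not merge
  expect_identical(tab$extent[tab$peak_pseudo_t == 9], 1L)
  expect_identical(tab$extent[tab$peak_pseudo_t == 8], 4L)
  expect_equal(tab$x_mm, tab$x * 3.1)
})
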