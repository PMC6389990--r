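# Regularized linear mapping between voxel patterns and semantic coordinates.
#
# The decoder is per-dimension ridge regression with an intercept obtained by
# centering both predictors and responses with training statistics. The
# regularization strength is either fixed or chosen by generalized
# cross-validation (GCV) over a logarithmic grid, always inside the training
# fold. For n << V the same solution is computed in gram (kernel) form, which
# is what makes the exhaustive leave-two-out schemes tractable.

default_lambda_grid <- function(scale) {
  scale * 10^seq(-5, 5, length.out = 41)
}

# GCV over a lambda grid given the spectrum (eigenvalues of Xc'Xc, i.e. squared
# singular values), the per-eigenvector response energy T_i = rowSums((U'Yc)^2)
# and the total response energy. df includes +1 for the intercept.
gcv_select <- function(evals, Tvec, total, n, grid) {
  scores <- vapply(grid, function(lambda) {
    f <- evals / (evals + lambda)
    rss <- max(total - sum((2 * f - f^2) * Tvec), 0)
    df <- sum(f) + 1
    if (n - df <= 0) return(Inf)
    n * rss / (n - df)^2
  }, numeric(1))
  grid[which.min(scores)]
}

#' Fit the ridge mapping from voxel patterns to semantic coordinates
#'
#' Solves, for every semantic dimension jointly, the ridge problem
#' `min ||Yc - Xc W||^2 + lambda ||W||^2` on training-centered `Xc`, `Yc`,
#' with the intercept recovered from the training means. With `lambda = "gcv"`
#' the strength is selected by generalized cross-validation on a logarithmic
#' grid scaled to the spectrum of `Xc` (never using any held-out data).
#'
#' @param X Numeric matrix `n x V` of voxel patterns (n >= 2, finite).
#' @param Y Numeric matrix `n x D` of semantic coordinates.
#' @param lambda `"gcv"` or a single non-negative number.
#' @return Object of class `semdec_mapping`: `weights` (`V x D`), `intercept`
#'   (`D`), `lambda`, `x_center`, `y_center`, and the voxel count.
#' @export
fit_mapping <- function(X, Y, lambda = "gcv") {
  X <- as.matrix(X); Y <- as.matrix(Y)
  assert_finite_matrix(X, "X")
  assert_finite_matrix(Y, "Y")
  if (nrow(X) < 2L || nrow(X) != nrow(Y)) {
    stop_semdec("X and Y must have the same number of rows (>= 2).",
                "semdecode_validation_error")
  }
  n <- nrow(X)
  xc <- colMeans(X)
  yc <- colMeans(Y)
  Xc <- sweep(X, 2, xc)
  Yc <- sweep(Y, 2, yc)
  sv <- svd(Xc)
  keep <- sv$d > max(sv$d[1], 1) * 1e-12
  d <- sv$d[keep]
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  B <- crossprod(U, Yc)                     # r x D
  if (identical(lambda, "gcv")) {
    grid <- default_lambda_grid(mean(d^2))
    lambda <- gcv_select(d^2, rowSums(B^2), sum(Yc^2), n, grid)
  } else {
    lambda <- as.numeric(lambda)
    if (length(lambda) != 1L || is.na(lambda) || lambda < 0) {
      stop_semdec("`lambda` must be \"gcv\" or a single non-negative number.",
                  "semdecode_validation_error")
    }
  }
  shrink <- if (lambda == 0) 1 / d else d / (d^2 + lambda)
  W <- V %*% (shrink * B)
  intercept <- as.numeric(yc - crossprod(W, xc))
  structure(list(weights = W, intercept = intercept, lambda = lambda,
                 x_center = xc, y_center = yc, n_voxels = ncol(X),
                 n_train = n),
            class = "semdec_mapping")
}

#' @export
print.semdec_mapping <- function(x, ...) {
  cat(sprintf("<semdec_mapping: %d voxels -> %d semantic dimensions, lambda = %.4g>\n",
              x$n_voxels, length(x$intercept), x$lambda))
  invisible(x)
}

#' Predict semantic coordinates from voxel patterns
#'
#' @param object A [fit_mapping()] result.
#' @param newdata Matrix `m x V` of voxel patterns.
#' @param ... Unused.
#' @return Matrix `m x D` of predicted coordinates.
#' @export
predict.semdec_mapping <- function(object, newdata, ...) {
  newdata <- matrix(newdata, ncol = object$n_voxels)
  newdata %*% object$weights +
    matrix(object$intercept, nrow = nrow(newdata), ncol = length(object$intercept),
           byrow = TRUE)
}

#' Tidy the fitted decoder weights
#'
#' @param x A `semdec_mapping`.
#' @param ... Unused.
#' @return Tibble with columns `voxel`, `dimension`, `weight`.
#' @export
tidy.semdec_mapping <- function(x, ...) {
  tibble(
    voxel = rep(seq_len(nrow(x$weights)), times = ncol(x$weights)),
    dimension = rep(seq_len(ncol(x$weights)), each = nrow(x$weights)),
    weight = as.numeric(x$weights)
  )
}

#' One-row summary of a fitted decoder
#'
#' @param x A `semdec_mapping`.
#' @param ... Unused.
#' @return One-row tibble: `n_voxels`, `n_dimensions`, `n_train`, `lambda`.
#' @export
glance.semdec_mapping <- function(x, ...) {
  tibble(n_voxels = x$n_voxels, n_dimensions = length(x$intercept),
         n_train = x$n_train, lambda = x$lambda)
}

#' Predict a voxel activation pattern from a semantic coordinate
#'
#' Reverses the fitted linear mapping: returns the minimum-norm least-squares
#' inverse image of `coordinate` under the decoder (Moore-Penrose
#' pseudo-inverse of the weight matrix), which predicts the activation pattern
#' of a novel concept from its corpus coordinates alone. A rank-deficient
#' mapping is handled by the pseudo-inverse without failure; the zero
#' coordinate maps to the intercept-only pattern.
#'
#' @param mapping A [fit_mapping()] result.
#' @param coordinate Numeric vector of length D.
#' @return Numeric vector of length `n_voxels`.
#' @export
predict_activation <- function(mapping, coordinate) {
  stopifnot(inherits(mapping, "semdec_mapping"))
  if (length(coordinate) != length(mapping$intercept)) {
    stop_semdec("Coordinate length must equal the mapping's semantic dimension.",
                "semdecode_validation_error")
  }
  Winv <- MASS::ginv(t(mapping$weights))    # V x D
  as.numeric(Winv %*% (coordinate - mapping$intercept))
}

# --- gram-form ridge -------------------------------------------------------

# Double-center a gram matrix over the training rows and produce the centered
# test-by-train cross products, so that gram-form ridge equals primal ridge on
# column-centered predictors.
center_gram <- function(G, train, test) {
  Gtt <- G[train, train, drop = FALSE]
  rm <- colMeans(Gtt)
  mm <- mean(rm)
  Kc <- sweep(sweep(Gtt, 1, rm), 2, rm) + mm
  Gxt <- G[test, train, drop = FALSE]
  tm <- rowMeans(Gxt)
  kc <- sweep(sweep(Gxt, 1, tm), 2, rm) + mm
  list(Kc = Kc, kc = kc)
}

# Ridge prediction in gram form. Returns predictions for the test rows, the
# lambda used, and (optionally) the linear operator A with pred = A %*% Ytrain,
# which permutation nulls reuse.
ridge_gram_predict <- function(G, train, test, Y, lambda = "gcv",
                               return_operator = FALSE) {
  cg <- center_gram(G, train, test)
  n <- length(train)
  Ytr <- Y[train, , drop = FALSE]
  ybar <- colMeans(Ytr)
  Yc <- sweep(Ytr, 2, ybar)
  eg <- eigen(cg$Kc, symmetric = TRUE)
  w <- pmax(eg$values, 0)
  Q <- eg$vectors
  B <- crossprod(Q, Yc)
  if (identical(lambda, "gcv")) {
    pos <- w > max(w[1], 1) * 1e-12
    grid <- default_lambda_grid(mean(w[pos]))
    lambda <- gcv_select(w, rowSums(B^2), sum(Yc^2), n, grid)
  }
  inv <- ifelse(w + lambda > 0, 1 / (w + lambda), 0)
  M <- Q %*% (inv * t(Q))                   # (Kc + lambda I)^-1
  H <- cg$kc %*% M                          # test x train
  pred <- H %*% Yc + matrix(ybar, nrow = length(test), ncol = ncol(Y), byrow = TRUE)
  out <- list(pred = pred, lambda = lambda)
  if (return_operator) {
    out$A <- H + matrix((1 - rowSums(H)) / n, nrow = nrow(H), ncol = n)
  }
  out
}
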