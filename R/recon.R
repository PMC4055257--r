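## Inversion of the encoding system and deviation metrics.

#' Minimum-norm least-squares solve by truncated SVD (regularized pseudo-inverse)
#'
#' Singular values below `rel_tol` times the largest are discarded; the
#' returned solution is the minimum-norm least-squares solution restricted to
#' the kept singular subspace.
#'
#' @param E Encoding matrix (real or complex), `I x J`.
#' @param D Measurement vector of length `I`.
#' @param rel_tol Relative singular-value cutoff.
#' @return The solution vector with attributes `rank`, `cond`
#'   (sigma_max / sigma_min over all J singular values) and `rel_residual`.
#' @export
solve_pinv <- function(E, D, rel_tol = 1e-6) {
  if (length(D) != nrow(E)) stop("dimension mismatch between E and D")
  if (length(D) == 0L || ncol(E) == 0L) stop("empty system")
  if (is.complex(E) && !is.complex(D)) D <- D + 0i
  if (!is.complex(E) && is.complex(D)) E <- E + 0i
  sv <- svd(E)
  keep <- sv$d > rel_tol * sv$d[1]
  x <- sv$v[, keep, drop = FALSE] %*%
    ((Conj(t(sv$u[, keep, drop = FALSE])) %*% D) / sv$d[keep])
  x <- drop(x)
  res <- sqrt(sum(Mod(E %*% x - D)^2)) / sqrt(sum(Mod(D)^2))
  attr(x, "rank") <- sum(keep)
  attr(x, "cond") <- sv$d[1] / sv$d[min(dim(E))]
  attr(x, "rel_residual") <- res
  x
}

#' Iterative least-squares solve (LSQR)
#'
#' Paige-Saunders LSQR for real or complex systems, stopping at the relative
#' residual tolerance or the iteration cap (defaults: 400 iterations,
#' residual 1e-6 — the stopping rule of the reference reconstruction).
#'
#' @inheritParams solve_pinv
#' @param max_iter Iteration cap (>= 1).
#' @param residual_tol Relative residual stopping tolerance.
#' @return The solution vector with attributes `iterations` and
#'   `rel_residual`.
#' @export
solve_lsqr <- function(E, D, max_iter = 400L, residual_tol = 1e-6) {
  if (length(D) != nrow(E)) stop("dimension mismatch between E and D")
  if (length(D) == 0L || ncol(E) == 0L) stop("empty system")
  stopifnot(max_iter >= 1)
  if (is.complex(E) && !is.complex(D)) D <- D + 0i
  cE <- Conj(t(E))
  nrm <- function(v) sqrt(sum(Mod(v)^2))
  x <- if (is.complex(E) || is.complex(D)) complex(ncol(E)) else numeric(ncol(E))
  beta <- nrm(D)
  if (beta == 0) {
    attr(x, "iterations") <- 0L; attr(x, "rel_residual") <- 0
    return(x)
  }
  u <- D / beta
  v <- drop(cE %*% u)
  alpha <- nrm(v); v <- v / alpha
  w <- v
  phibar <- beta; rhobar <- alpha
  it <- 0L
  for (it in seq_len(max_iter)) {
    u <- drop(E %*% v) - alpha * u
    beta <- nrm(u)
    if (beta > 0) {
      u <- u / beta
      v <- drop(cE %*% u) - beta * v
      alpha <- nrm(v)
      if (alpha > 0) v <- v / alpha
    }
    rho <- sqrt(rhobar^2 + beta^2)
    cs <- rhobar / rho; sn <- beta / rho
    theta <- sn * alpha; rhobar <- -cs * alpha
    phi <- cs * phibar; phibar <- sn * phibar
    x <- x + (phi / rho) * w
    w <- v - (theta / rho) * w
    if (phibar / nrm(D) < residual_tol) break
  }
  attr(x, "iterations") <- it
  attr(x, "rel_residual") <- phibar / nrm(D)
  x
}

#' Fit an image to pseudo k-space data
#'
#' The central estimator: solves the linear encoding system `D = E G` for the
#' masked voxel intensities `G` by the regularized pseudo-inverse or LSQR and
#' wraps the result, its diagnostics and the back-mapping to image space in a
#' classed object.
#'
#' @param E Encoding matrix, `I x J` (rows = acquisition events, columns =
#'   masked voxels; typically from [build_encoding_matrix()], which attaches
#'   the mask scan order).
#' @param D Measurement vector of length `I`.
#' @param method `"pinv"` or `"lsqr"`.
#' @param mask Optional `b1_mask` used to restore the solution to the grid;
#'   if missing, the `mask_index` attribute of `E` must be present together
#'   with `grid`.
#' @param grid Optional [grid_spec()] accompanying `mask_index`.
#' @param rel_tol,max_iter,residual_tol Solver controls, see [solve_pinv()]
#'   and [solve_lsqr()].
#' @return An object of class `rrfc_fit` with components `coefficients`
#'   (complex masked-voxel solution), `image` (a [scalar_image()] of the
#'   magnitude, zero outside the mask), `fitted.values`, `residuals`,
#'   `method` and solver diagnostics.
#' @export
rrfc_fit <- function(E, D, method = c("pinv", "lsqr"), mask = NULL,
                     grid = NULL, rel_tol = 1e-6, max_iter = 400L,
                     residual_tol = 1e-6) {
  method <- match.arg(method)
  x <- if (method == "pinv") solve_pinv(E, D, rel_tol)
       else solve_lsqr(E, D, max_iter, residual_tol)
  diag_attrs <- attributes(x)[c("rank", "cond", "iterations", "rel_residual")]
  attributes(x) <- NULL
  fitted <- drop(E %*% x)
  img <- NULL
  idx <- attr(E, "mask_index")
  if (!is.null(mask)) {
    idx <- which(mask$values); grid <- mask$grid
  }
  if (!is.null(idx) && !is.null(grid)) {
    vals <- array(0, grid_dim(grid))
    vals[idx] <- Mod(x)
    img <- scalar_image(grid, vals)
  }
  structure(list(coefficients = x, image = img, fitted.values = fitted,
                 residuals = D - fitted, method = method,
                 mask_index = idx, grid = grid,
                 diagnostics = diag_attrs[!vapply(diag_attrs, is.null, TRUE)]),
            class = "rrfc_fit")
}

#' @export
print.rrfc_fit <- function(x, ...) {
  d <- x$diagnostics
  extra <- if (x$method == "pinv")
    sprintf("rank %d, cond %.3g", d$rank, d$cond)
  else
    sprintf("%d iterations", d$iterations)
  cat(sprintf("<rrfc_fit> %s solve of %d voxels from %d events (%s, rel. residual %.2e)\n",
              x$method, length(x$coefficients), length(x$fitted.values),
              extra, d$rel_residual))
  invisible(x)
}

#' @export
summary.rrfc_fit <- function(object, ...) {
  print(object)
  m <- Mod(object$coefficients)
  cat(sprintf("  |G|: min %.4g, median %.4g, max %.4g\n",
              min(m), stats::median(m), max(m)))
  invisible(object)
}

#' @export
coef.rrfc_fit <- function(object, ...) object$coefficients

#' @export
fitted.rrfc_fit <- function(object, ...) object$fitted.values

#' @export
residuals.rrfc_fit <- function(object, ...) object$residuals

#' Predict measurements for a (possibly new) encoding matrix
#'
#' @param object An `rrfc_fit`.
#' @param newE Optional encoding matrix with the same column space; defaults
#'   to returning the fitted values.
#' @param ... Unused.
#' @export
predict.rrfc_fit <- function(object, newE = NULL, ...) {
  if (is.null(newE)) return(object$fitted.values)
  drop(newE %*% object$coefficients)
}

#' @export
plot.rrfc_fit <- function(x, ...) {
  if (is.null(x$image)) stop("fit carries no grid information to plot")
  plot(x$image, main = sprintf("|G| (%s)", x$method), ...)
}

#' Percentage deviation of a reconstruction from the original image
#'
#' Both magnitude images are normalized to unit peak over the mask; the
#' per-voxel deviation is `100 * (|recon| - |original|)` in percent of full
#' scale.  Signed statistics (mean, sd) and the maximum absolute deviation
#' are computed over the mask, together with a pixel-frequency histogram of
#' the signed deviations.
#'
#' @param recon An `rrfc_fit`, [scalar_image()], or numeric array on the grid.
#' @param original A [scalar_image()] on the same grid.
#' @param mask A `b1_mask`; statistics are restricted to its in-voxels.
#' @param n_bins Number of histogram bins.
#' @return An object of class `deviation_metrics` with fields `map` (signed
#'   percentage deviation, NA outside the mask), `max_abs`, `mean`, `sd`,
#'   and `histogram` (`$breaks`, `$mids`, `$counts`).
#' @export
deviation_metrics <- function(recon, original, mask, n_bins = 50L) {
  stopifnot(inherits(original, "scalar_image"), inherits(mask, "b1_mask"),
            n_bins >= 1)
  if (!same_grid(original$grid, mask$grid)) stop("grids differ")
  rv <- if (inherits(recon, "rrfc_fit")) recon$image$values
        else if (inherits(recon, "scalar_image")) recon$values
        else check_values_shape(original$grid, recon)
  sel <- which(mask$values)
  a <- Mod(rv[sel]); b <- original$values[sel]
  if (max(a) > 0) a <- a / max(a)
  if (max(b) > 0) b <- b / max(b)
  dev <- 100 * (a - b)
  brk <- seq(min(dev) - 1e-9, max(dev) + 1e-9, length.out = n_bins + 1L)
  h <- hist(dev, breaks = brk, plot = FALSE)
  map <- array(NA_real_, grid_dim(mask$grid))
  map[sel] <- dev
  structure(list(map = map, max_abs = max(abs(dev)), mean = mean(dev),
                 sd = stats::sd(dev),
                 histogram = list(breaks = h$breaks, mids = h$mids,
                                  counts = h$counts)),
            class = "deviation_metrics")
}

#' @export
print.deviation_metrics <- function(x, ...) {
  cat(sprintf("<deviation_metrics> max |dev| %.3f%%, mean %.3f%%, sd %.3f%%\n",
              x$max_abs, x$mean, x$sd))
  invisible(x)
}

#' @export
plot.deviation_metrics <- function(x, ...) {
  graphics::barplot(x$histogram$counts, names.arg = round(x$histogram$mids, 1),
                    xlab = "deviation (%)", ylab = "pixel frequency", ...)
  invisible(x)
}
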