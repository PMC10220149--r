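#' Arctangent relative speed error
#'
#' Mean over fluid voxels of `atan(||v' - v|| / (||v|| + epsilon))` where
#' `v'` is the predicted and `v` the reference velocity vector. The
#' arctangent bounds the contribution of near-zero reference speeds by
#' pi/2, and the small `epsilon` (default 1e-4) avoids division by zero.
#'
#' @param pred,target Velocity arrays `[x, y, z, 3]` in m/s.
#' @param mask Logical fluid mask (the metric is only defined over fluid).
#' @param epsilon Denominator stabiliser in m/s.
#' @return Mean error in radians, in `[0, pi/2)`.
#' @export
#' @examples
#' v <- array(0, c(1, 1, 1, 3)); v[1, 1, 1, 1] <- 1
#' p <- v; p[1, 1, 1, 2] <- 1
#' relative_speed_error(p, v, array(TRUE, c(1, 1, 1)))  # ~0.78535
relative_speed_error <- function(pred, target, mask, epsilon = 1e-4) {
  if (!identical(dim(pred), dim(target))) stop("pred/target shape mismatch")
  if (!any(mask)) stop("empty fluid mask")
  d2 <- (pred - target)^2
  errn <- sqrt(d2[, , , 1] + d2[, , , 2] + d2[, , , 3])
  spd <- sqrt(target[, , , 1]^2 + target[, , , 2]^2 + target[, , , 3]^2)
  ang <- atan(errn / (spd + epsilon))
  mean(ang[mask])
}

#' Per-component root-mean-square error
#'
#' RMSE of each Cartesian velocity component over fluid voxels.
#'
#' @inheritParams relative_speed_error
#' @return Named numeric length-3 vector (m/s).
#' @export
rmse_components <- function(pred, target, mask) {
  if (!identical(dim(pred), dim(target))) stop("pred/target shape mismatch")
  if (!any(mask)) stop("empty fluid mask")
  out <- vapply(1:3, function(j) {
    d <- (pred[, , , j] - target[, , , j])[mask]
    sqrt(mean(d^2))
  }, numeric(1))
  names(out) <- c("x", "y", "z")
  out
}

# Gaussian-windowed local statistics via the separable compiled filter,
# renormalised at the edges by the filtered indicator.
ssim3d <- function(x, y, data_range = NULL, sigma = 1.5, width = 11,
                   K1 = 0.01, K2 = 0.03) {
  stopifnot(identical(dim(x), dim(y)))
  if (is.null(data_range)) data_range <- diff(range(y))
  if (data_range == 0) {
    if (isTRUE(all.equal(as.vector(x), as.vector(y)))) return(1)
    data_range <- diff(range(x))
    if (data_range == 0) return(0)
  }
  h <- (width - 1) / 2
  kern <- dnorm(seq(-h, h), sd = sigma)
  kern <- kern / sum(kern)
  f <- function(a) sep_filter3_cpp(a, kern)
  ones <- f(array(1, dim(x)))
  mx <- f(x) / ones; my <- f(y) / ones
  vx <- f(x * x) / ones - mx^2
  vy <- f(y * y) / ones - my^2
  cxy <- f(x * y) / ones - mx * my
  C1 <- (K1 * data_range)^2; C2 <- (K2 * data_range)^2
  s <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
       ((mx^2 + my^2 + C1) * (vx + vy + C2))
  mean(s)
}

#' Per-component structural similarity
#'
#' Standard SSIM (Gaussian window, sigma 1.5, width 11, stabilising
#' constants K1 = 0.01, K2 = 0.03) computed in 3D for each velocity
#' component and averaged over voxels. The data range defaults to
#' `max - min` of the reference (`target`) component.
#'
#' @param pred,target Velocity arrays `[x, y, z, 3]`.
#' @param data_range Optional fixed data range (shared by all components).
#' @return Named numeric length-3 vector in `[-1, 1]`.
#' @export
ssim_components <- function(pred, target, data_range = NULL) {
  if (!identical(dim(pred), dim(target))) stop("pred/target shape mismatch")
  out <- vapply(1:3, function(j)
    ssim3d(pred[, , , j], target[, , , j], data_range), numeric(1))
  names(out) <- c("x", "y", "z")
  out
}

ba_core <- function(p, t) {
  if (length(p) < 2) stop("need at least 2 fluid voxels")
  fit <- lm(p ~ t)
  d <- p - t
  bias <- mean(d); s <- sd(d)
  c(slope = unname(coef(fit)[2]), offset = unname(coef(fit)[1]),
    bias = bias, loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s)
}

#' Regression and Bland-Altman agreement of SR against HR velocities
#'
#' Ordinary least squares of the predicted on the reference voxel values
#' and Bland-Altman statistics (bias = mean difference, limits of
#' agreement = bias +/- 1.96 SD) for each velocity component and for the
#' speed, over fluid voxels. Supplying `region_x` (a 1-based inclusive
#' voxel range along the flow axis, e.g. the constricted section) restricts
#' the analysis to that axial slab.
#'
#' @inheritParams relative_speed_error
#' @param region_x Optional `c(from, to)` axial voxel range.
#' @return Data frame with one row per component (`x`, `y`, `z`, `speed`)
#'   and columns `slope`, `offset`, `bias`, `loa_lower`, `loa_upper`.
#' @export
regression_bland_altman <- function(pred, target, mask, region_x = NULL) {
  if (!identical(dim(pred), dim(target))) stop("pred/target shape mismatch")
  m <- mask
  if (!is.null(region_x)) {
    keep <- array(FALSE, dim(mask))
    keep[region_x[1]:region_x[2], , ] <- TRUE
    m <- m & keep
  }
  if (sum(m) < 2) stop("need at least 2 fluid voxels")
  rows <- lapply(1:3, function(j)
    ba_core(pred[, , , j][m], target[, , , j][m]))
  spd <- function(a) sqrt(a[, , , 1]^2 + a[, , , 2]^2 + a[, , , 3]^2)
  rows[[4]] <- ba_core(spd(pred)[m], spd(target)[m])
  out <- as.data.frame(do.call(rbind, rows))
  out$component <- c("x", "y", "z", "speed")
  out[, c("component", "slope", "offset", "bias", "loa_lower", "loa_upper")]
}

#' Axial voxel range of the constricted section
#'
#' @param flow A [synthesize_flow()] result.
#' @return `c(from, to)` 1-based voxel indices along the flow axis.
#' @export
constriction_region <- function(flow) {
  xs <- grid_axis(flow$grid, 1)
  x0 <- flow$geom$upstream_length
  x1 <- x0 + flow$geom$constriction_length
  range(which(xs >= x0 & xs <= x1))
}

#' Full evaluation report for one SR prediction
#'
#' @inheritParams relative_speed_error
#' @param region_x Optional axial slab for the agreement analysis (see
#'   [regression_bland_altman()]).
#' @return An `eval_report` list: `re` (radians), `rmse` and `ssim`
#'   (per component), and `agreement` (data frame).
#' @export
evaluate_sr <- function(pred, target, mask, region_x = NULL) {
  structure(list(re = relative_speed_error(pred, target, mask),
                 rmse = rmse_components(pred, target, mask),
                 ssim = ssim_components(pred, target),
                 agreement = regression_bland_altman(pred, target, mask,
                                                     region_x)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("relative speed error: %.4f rad\n", x$re))
  cat(sprintf("RMSE (m/s):  x %.4f  y %.4f  z %.4f\n",
              x$rmse[1], x$rmse[2], x$rmse[3]))
  cat(sprintf("SSIM:        x %.4f  y %.4f  z %.4f\n",
              x$ssim[1], x$ssim[2], x$ssim[3]))
  print(x$agreement, row.names = FALSE, digits = 4)
  invisible(x)
}
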