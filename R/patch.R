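#' The 24 proper cube rotations
#'
#' Orientation-preserving axis-aligned rotations (the rotation group of the
#' cube) as signed permutation matrices with determinant +1. Element 1 is
#' the identity.
#'
#' @return List of 24 integer 3x3 matrices.
#' @export
cube_rotations <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (p in perms)
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
      R <- matrix(0L, 3, 3)
      signs <- c(s1, s2, s3)
      for (i in 1:3) R[i, p[i]] <- signs[i]
      if (round(det(R)) == 1) out[[length(out) + 1]] <- R
    }
  out
}

rotation_matrix <- function(rotation) {
  if (is.matrix(rotation)) {
    R <- rotation
    if (!all(R %in% c(-1, 0, 1)) || any(colSums(R != 0) != 1) ||
        any(rowSums(R != 0) != 1) || round(det(R)) != 1)
      stop("rotation must be one of the 24 proper cube rotations")
    R
  } else cube_rotations()[[rotation]]
}

# Spatially transform a cube array [n, n, n, C(, N)] by a signed
# permutation matrix (active rotation); channels untouched.
rotate_spatial <- function(arr, R) {
  src <- apply(R != 0, 1, which)
  sgn <- R[cbind(1:3, src)]
  d <- dim(arr)
  extra <- seq_along(d)[-(1:3)]
  out <- aperm(arr, c(src, extra))
  idx <- lapply(1:3, function(a)
    if (sgn[a] < 0) rev(seq_len(dim(out)[a])) else seq_len(dim(out)[a]))
  do.call(`[`, c(list(out), idx,
                 rep(list(quote(expr = )), length(extra)),
                 list(drop = FALSE)))
}

# Rotate a vector field: spatial transform plus component mixing v' = R v.
rotate_vector_field <- function(arr, R) {
  sp <- rotate_spatial(arr, R)
  src <- apply(R != 0, 1, which)
  sgn <- R[cbind(1:3, src)]
  out <- sp
  for (a in 1:3) out[, , , a] <- sgn[a] * sp[, , , src[a]]
  out
}

#' Rotate an LR/HR patch pair
#'
#' Applies one of the 24 proper cube rotations to both members of a
#' [sample_patches()] pair: spatial axes are permuted/flipped and the three
#' velocity channels are transformed by the same rotation matrix (component
#' permutation with sign flips), so voxelwise speed is preserved exactly.
#' Magnitude channels are rotated spatially only. The per-component VENC is
#' permuted along with the velocity components.
#'
#' @param pair A `patch_pair`.
#' @param rotation Index 1-24 into [cube_rotations()], or such a matrix.
#' @return The rotated `patch_pair`.
#' @export
rotate_pair <- function(pair, rotation) {
  R <- rotation_matrix(rotation)
  src <- apply(R != 0, 1, which)
  out <- pair
  lr <- pair$lr
  lr[, , , 1:3] <- rotate_vector_field(pair$lr[, , , 1:3, drop = FALSE], R)
  lr[, , , 4:6] <- rotate_spatial(pair$lr[, , , 4:6, drop = FALSE], R)
  out$lr <- lr
  out$hr <- rotate_vector_field(pair$hr, R)
  out$hr_mask <- array(rotate_spatial(array(pair$hr_mask,
                                            c(dim(pair$hr_mask), 1)), R),
                       dim(pair$hr_mask))
  out$venc <- pair$venc[src]
  out$rotation <- if (is.matrix(rotation)) NA_integer_ else
    as.integer(rotation)
  out
}

#' Sample paired LR/HR training patches from one frame
#'
#' Draws `n_base` patch corners uniformly at random over the LR volume,
#' rejecting corners whose 12-voxel LR cube contains less than `min_fluid`
#' fluid (at most `max_attempts` draws per patch), and pairs each LR patch
#' (velocity + magnitude channels) with the HR velocity cube at four times
#' the scale. Each accepted patch is followed by a randomly rotated
#' duplicate, so `2 * n_base` pairs are returned per frame.
#'
#' @param lr An [simulate_lr()] `lr_sample`.
#' @param hr_velocity HR velocity array `[x, y, z, 3]` of the same frame.
#' @param hr_mask Logical HR fluid mask.
#' @param n_base Number of base patches (default 10).
#' @param min_fluid Minimum fluid fraction of the LR patch (default 0.20).
#' @param patch_lr LR patch side in voxels (default 12).
#' @param max_attempts Corner draws allowed per patch before erroring.
#' @return List of `2 * n_base` objects of class `patch_pair`, each with
#'   elements `lr` (`[n, n, n, 6]`), `hr` (`[4n, 4n, 4n, 3]` m/s),
#'   `hr_mask`, `venc`, `fluid_fraction`, `origin` (0-based LR corner) and
#'   `rotation` (index into [cube_rotations()]; 1 = unrotated).
#' @export
sample_patches <- function(lr, hr_velocity, hr_mask, n_base = 10,
                           min_fluid = 0.20, patch_lr = 12,
                           max_attempts = 1000) {
  stopifnot(inherits(lr, "lr_sample"))
  f <- lr$factor
  ld <- dim(lr$velocity_lr)[1:3]
  if (any(ld < patch_lr)) stop("LR volume smaller than the patch size")
  hd <- dim(hr_velocity)[1:3]
  stopifnot(identical(dim(hr_mask), hd))
  n <- patch_lr; nh <- n * f
  venc <- lr$acquisition$venc
  pairs <- vector("list", 2 * n_base)
  for (i in seq_len(n_base)) {
    found <- FALSE
    for (att in seq_len(max_attempts)) {
      o <- vapply(1:3, function(a) sample.int(ld[a] - n + 1, 1) - 1L,
                  integer(1))
      sel <- lapply(1:3, function(a) o[a] + seq_len(n))
      ff <- mean(lr$mask_lr[sel[[1]], sel[[2]], sel[[3]]])
      if (ff >= min_fluid) { found <- TRUE; break }
    }
    if (!found)
      stop("no patch corner reached a fluid fraction of ", min_fluid,
           " within ", max_attempts, " attempts")
    lrp <- array(0, c(n, n, n, 6))
    lrp[, , , 1:3] <- lr$velocity_lr[sel[[1]], sel[[2]], sel[[3]], ,
                                     drop = FALSE]
    lrp[, , , 4:6] <- lr$magnitude_lr[sel[[1]], sel[[2]], sel[[3]], ,
                                      drop = FALSE]
    hsel <- lapply(1:3, function(a) o[a] * f + seq_len(nh))
    pair <- structure(
      list(lr = lrp,
           hr = hr_velocity[hsel[[1]], hsel[[2]], hsel[[3]], , drop = FALSE],
           hr_mask = hr_mask[hsel[[1]], hsel[[2]], hsel[[3]]],
           venc = venc, fluid_fraction = ff, origin = o, rotation = 1L),
      class = "patch_pair")
    pairs[[2 * i - 1]] <- pair
    pairs[[2 * i]] <- rotate_pair(pair, sample.int(24, 1))
  }
  pairs
}

#' Patch-lattice origins along one axis
#'
#' 0-based origins of `n`-voxel patches covering an axis of length `len`
#' with stride `n - 4`; a final patch flush with the end is appended when
#' the stride lattice does not land there exactly.
#'
#' @param len Axis length in LR voxels.
#' @param n Patch size in LR voxels.
#' @param stride Lattice stride (default `n - 4`).
#' @return Integer vector of origins.
#' @export
split_origins <- function(len, n, stride = n - 4) {
  if (len < n) stop("axis shorter than the patch size")
  if (stride < 1) stop("stride must be positive")
  o <- seq(0L, len - n, by = stride)
  if (o[length(o)] != len - n) o <- c(o, len - n)
  as.integer(o)
}

#' Stitch overlapping SR patches into a volume
#'
#' Writes each patch into the output with `strip` HR voxels removed from
#' every patch face that does not touch the volume boundary (boundary faces
#' keep their un-stripped values so the volume has no holes). Residual
#' overlaps of the stride lattice are resolved deterministically by
#' last-writer-wins in patch order.
#'
#' @param patches List of `list(origin = 0-based HR corner, data = [p, p,
#'   p, C] array)`.
#' @param out_shape Integer vector of 3 HR output axis lengths.
#' @param strip HR voxels stripped per interior patch face (default 4).
#' @return Array `[out_shape, C]`.
#' @export
stitch_patches <- function(patches, out_shape, strip = 4) {
  stopifnot(length(patches) >= 1)
  p <- dim(patches[[1]]$data)[1]
  C <- dim(patches[[1]]$data)[4]
  out <- array(0, c(out_shape, C))
  covered <- array(FALSE, out_shape)
  for (pt in patches) {
    o <- pt$origin
    lo <- integer(3); hi <- integer(3)
    for (a in 1:3) {
      lo[a] <- if (o[a] > 0) strip else 0
      hi[a] <- if (o[a] + p < out_shape[a]) strip else 0
      if (o[a] < 0 || o[a] + p > out_shape[a])
        stop("patch extends beyond the output volume")
    }
    src <- lapply(1:3, function(a) (1 + lo[a]):(p - hi[a]))
    dst <- lapply(1:3, function(a) o[a] + src[[a]])
    out[dst[[1]], dst[[2]], dst[[3]], ] <-
      pt$data[src[[1]], src[[2]], src[[3]], , drop = FALSE]
    covered[dst[[1]], dst[[2]], dst[[3]]] <- TRUE
  }
  if (!all(covered))
    stop("patch lattice does not cover the output volume (",
         sum(!covered), " voxels unwritten)")
  out
}
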