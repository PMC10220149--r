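# Elementary tensor ops for the static-graph CNN engine. Activations are
# dense arrays dim (nx, ny, nz, channels, batch); convolution runs through
# the compiled im2col+GEMM kernels.

LRELU_ALPHA <- 0.2

act_lrelu <- function(x) {
  d <- dim(x)
  y <- pmax(x, 0) + LRELU_ALPHA * pmin(x, 0)
  dim(y) <- d
  y
}

# derivative of leaky ReLU from its *output* (valid because alpha > 0
# preserves sign)
lrelu_grad <- function(y, g) {
  d <- dim(g)
  out <- g * (LRELU_ALPHA + (1 - LRELU_ALPHA) * (y > 0))
  dim(out) <- d
  out
}

ensure_batch <- function(x) {
  if (length(dim(x)) == 4) dim(x) <- c(dim(x), 1)
  x
}

concat_channels <- function(xs) {
  d <- dim(xs[[1]])
  chans <- vapply(xs, function(x) dim(x)[4], integer(1))
  out <- array(0, c(d[1:3], sum(chans), d[5]))
  at <- 0
  for (i in seq_along(xs)) {
    out[, , , at + seq_len(chans[i]), ] <- xs[[i]]
    at <- at + chans[i]
  }
  out
}

upsample_nearest <- function(x, f) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = f), rep(seq_len(d[2]), each = f),
    rep(seq_len(d[3]), each = f), , , drop = FALSE]
}

# adjoint of nearest-neighbour upsampling: sum gradients over each f^3 block
block_sum <- function(g, f) {
  d <- dim(g)
  n <- d[1:3] %/% f
  cn <- d[4] * d[5]
  a <- array(g, c(f, n[1], f, n[2], f, n[3], cn))
  s <- colSums(a)                                  # (n1, f, n2, f, n3, cn)
  s <- colSums(aperm(s, c(2, 1, 3, 4, 5, 6)))     # (n1, n2, f, n3, cn)
  s <- colSums(aperm(s, c(3, 1, 2, 4, 5)))        # (n1, n2, n3, cn)
  array(s, c(n, d[4], d[5]))
}

# Dense 1D linear-interpolation matrix (half-voxel-centre convention,
# clamped at the ends), N = n * f rows.
interp_matrix <- function(n, f) {
  o <- ((seq_len(n * f) - 1) + 0.5) / f - 0.5
  o <- pmin(pmax(o, 0), n - 1)
  i0 <- pmin(floor(o), max(n - 2, 0))
  w <- o - i0
  M <- matrix(0, n * f, n)
  M[cbind(seq_len(n * f), i0 + 1)] <- 1 - w
  M[cbind(seq_len(n * f), pmin(i0 + 2, n))] <-
    M[cbind(seq_len(n * f), pmin(i0 + 2, n))] + w
  M
}

# multiply a 5-D tensor by a matrix along one spatial axis
apply_axis <- function(x, M, axis) {
  d <- dim(x)
  perm <- c(axis, setdiff(seq_along(d), axis))
  xp <- aperm(x, perm)
  y <- M %*% matrix(xp, nrow = d[axis])
  dim(y) <- c(nrow(M), d[perm[-1]])
  aperm(y, order(perm))
}

# trilinear resize of (nx,ny,nz,C,N) tensors (separable), and its adjoint
upsample_linear <- function(x, f) {
  d <- dim(x)
  for (a in 1:3) x <- apply_axis(x, interp_matrix(d[a], f), a)
  x
}

upsample_linear_bwd <- function(g, f) {
  d <- dim(g)
  for (a in 1:3) g <- apply_axis(g, t(interp_matrix(d[a] %/% f, f)), a)
  g
}

#' Trilinear interpolation upsampling
#'
#' Non-learned trilinear (half-voxel-aligned) upsampling of a velocity
#' volume by an integer factor; the conventional interpolation baseline
#' that super-resolution predictions are compared against.
#'
#' @param x Array `[x, y, z]` or `[x, y, z, channels]`.
#' @param factor Integer upsampling factor.
#' @return Array with each spatial axis scaled by `factor`.
#' @export
interp_upsample <- function(x, factor) {
  d <- dim(x)
  squeeze <- length(d) == 3
  if (squeeze) dim(x) <- c(d, 1)
  n <- dim(x)[1:3]; C <- dim(x)[4]
  ax <- lapply(n, function(n1) {
    o <- ((seq_len(n1 * factor) - 1) + 0.5) / factor - 0.5
    o <- pmin(pmax(o, 0), n1 - 1)
    i0 <- pmin(floor(o), max(n1 - 2, 0))
    list(i0 = i0 + 1, w = o - i0)
  })
  N <- n * factor
  out <- array(0, c(N, C))
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    ix <- pmin(ax[[1]]$i0 + a, n[1])
    iy <- pmin(ax[[2]]$i0 + b, n[2])
    iz <- pmin(ax[[3]]$i0 + cc, n[3])
    wx <- if (a == 0) 1 - ax[[1]]$w else ax[[1]]$w
    wy <- if (b == 0) 1 - ax[[2]]$w else ax[[2]]$w
    wz <- if (cc == 0) 1 - ax[[3]]$w else ax[[3]]$w
    w <- as.vector(outer(outer(wx, wy), wz))
    out <- out + x[ix, iy, iz, , drop = FALSE] * w
  }
  if (squeeze) dim(out) <- N
  out
}
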