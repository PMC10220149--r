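#' Specify a super-resolution network
#'
#' All three variants share the same backbone: two input branches (velocity
#' and magnitude, three channels each) of two 3x3x3 convolutions, a 1x1x1
#' concatenation convolution, one further 3x3x3 convolution, `lr_blocks`
#' blocks operating in the low-resolution space (pre-processing/denoising),
#' a central non-learned x`upsample_factor` resize, `hr_blocks` blocks
#' refining in the high-resolution space, and three single-component output
#' heads (3x3x3 conv to `channels` then to 1). The variants differ only in
#' the block family:
#' \describe{
#'   \item{res}{two 3x3x3 convolutions with an identity skip connection.}
#'   \item{dense}{four convolutions each emitting `growth_rate` feature
#'     maps with cumulative concatenation, then a 1x1x1 transition back to
#'     `channels`.}
#'   \item{csp}{cross-stage-partial: a quarter of the feature maps pass
#'     through a partial dense block and are re-merged with the bypassed
#'     three quarters through 1x1x1 transitions.}
#' }
#' With the defaults (12 blocks split 8/4, 64 channels, growth 16) the res
#' variant has 3,343,619 trainable parameters (3.34 M), the dense variant
#' 2.56 M and the csp variant 1.58 M.
#'
#' @param variant `"res"`, `"dense"` or `"csp"`.
#' @param lr_blocks,hr_blocks Blocks before/after the central upsampling.
#' @param channels Feature maps per convolution in the backbone.
#' @param growth_rate Feature maps per dense-layer (default `channels / 4`).
#' @param upsample_factor Spatial upsampling factor (default 4).
#' @param in_patch Training input patch side in LR voxels (default 12; the
#'   network itself is fully convolutional and accepts any size at
#'   prediction time).
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(variant = c("res", "dense", "csp"), lr_blocks = 8,
                         hr_blocks = 4, channels = 64,
                         growth_rate = max(channels %/% 4, 1),
                         upsample_factor = 4, in_patch = 12) {
  variant <- match.arg(variant)
  stopifnot(lr_blocks >= 0, hr_blocks >= 0, channels >= 4,
            growth_rate >= 1, upsample_factor >= 1, in_patch >= 3)
  structure(list(variant = variant, lr_blocks = lr_blocks,
                 hr_blocks = hr_blocks, channels = channels,
                 growth_rate = growth_rate,
                 upsample_factor = upsample_factor,
                 in_patch = as.integer(in_patch),
                 out_patch = as.integer(in_patch * upsample_factor)),
            class = "network_spec")
}

add_block <- function(gb, spec, prefix, input) {
  C <- spec$channels; g <- spec$growth_rate
  nm <- function(s) paste0(prefix, "_", s)
  switch(spec$variant,
    res = {
      gb_conv(gb, nm("c1"), input, C, C)
      gb_conv(gb, nm("c2"), nm("c1"), C, C, act = "linear")
      gb_add(gb, nm("add"), "add", c(input, nm("c2")))
      gb_add(gb, nm("out"), "lrelu", nm("add"))
    },
    dense = {
      cur <- input; cin <- C; grown <- character(0)
      for (l in 1:4) {
        gb_conv(gb, nm(paste0("l", l)), cur, cin, g)
        grown <- c(grown, nm(paste0("l", l)))
        if (l < 4) {
          cur <- gb_add(gb, nm(paste0("cat", l)), "concat",
                        c(input, grown))
          cin <- C + l * g
        }
      }
      gb_add(gb, nm("catg"), "concat", grown)
      gb_conv(gb, nm("out"), nm("catg"), 4 * g, C, k = 1)
    },
    csp = {
      q <- max(C %/% 4, 1)
      gb_add(gb, nm("s1"), "slice", input, range = seq_len(C - q))
      gb_add(gb, nm("s2"), "slice", input, range = (C - q + 1):C)
      cur <- nm("s2"); cin <- q; grown <- character(0)
      for (l in 1:4) {
        gb_conv(gb, nm(paste0("d", l)), cur, cin, g)
        grown <- c(grown, nm(paste0("d", l)))
        if (l < 4) {
          cur <- gb_add(gb, nm(paste0("cat", l)), "concat",
                        c(nm("s2"), grown))
          cin <- q + l * g
        }
      }
      gb_add(gb, nm("pcat"), "concat", grown)
      gb_conv(gb, nm("pt"), nm("pcat"), 4 * g, q, k = 1)
      gb_add(gb, nm("merge"), "concat", c(nm("s1"), nm("pt")))
      gb_conv(gb, nm("out"), nm("merge"), C, C, k = 1)
    })
  nm("out")
}

#' Build a super-resolution network
#'
#' Instantiates the computation graph of a [network_spec()] and initialises
#' all convolution weights with symmetric fan-in-scaled uniform draws
#' (biases zero) under the given seed.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `sr_network`.
#' @export
build_network <- function(spec, seed = 42) {
  stopifnot(inherits(spec, "network_spec"))
  C <- spec$channels
  gb <- graph_builder()
  gb_conv(gb, "pv1", "in_vel", 3, C)
  gb_conv(gb, "pv2", "pv1", C, C)
  gb_conv(gb, "pm1", "in_mag", 3, C)
  gb_conv(gb, "pm2", "pm1", C, C)
  gb_add(gb, "cc", "concat", c("pv2", "pm2"))
  gb_conv(gb, "c1", "cc", 2 * C, C, k = 1)
  gb_conv(gb, "c2", "c1", C, C)
  cur <- "c2"
  for (b in seq_len(spec$lr_blocks))
    cur <- add_block(gb, spec, paste0("lb", b), cur)
  gb_add(gb, "up", "upsample", cur, f = spec$upsample_factor)
  cur <- "up"
  for (b in seq_len(spec$hr_blocks))
    cur <- add_block(gb, spec, paste0("hb", b), cur)
  heads <- character(3)
  for (j in 1:3) {
    gb_conv(gb, paste0("h", j), cur, C, C)
    gb_conv(gb, paste0("o", j), paste0("h", j), C, 1, act = "linear",
            init_scale = 0.1)
    heads[j] <- paste0("o", j)
  }
  gb_add(gb, "out", "concat", heads)
  nodes <- gb$nodes
  structure(list(spec = spec, graph = nodes,
                 params = init_graph_params(nodes, seed), seed = seed),
            class = "sr_network")
}

#' @export
print.sr_network <- function(x, ...) {
  cat(sprintf(
    "sr_network (%s): %d+%d blocks, %d channels, x%d upsample, %s parameters\n",
    x$spec$variant, x$spec$lr_blocks, x$spec$hr_blocks, x$spec$channels,
    x$spec$upsample_factor, format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' Total number of trainable scalars (all convolution weights and biases).
#'
#' @param model An [build_network()] model, or a bare list with a `params`
#'   element; a model without parameters counts 0.
#' @return Integer-valued parameter count.
#' @export
#' @examples
#' count_parameters(build_network(network_spec("res", channels = 8)))
count_parameters <- function(model) {
  p <- if (!is.null(model$params)) model$params else list()
  sum(vapply(p, function(q) length(q$w) + length(q$b), numeric(1)))
}

#' Forward pass on normalised tensors
#'
#' Runs the network on VENC-normalised velocity channels and scaled
#' magnitude channels. Mostly internal; end users call [predict_patch()] or
#' [predict_volume()], which handle the normalisation.
#'
#' @param model An `sr_network`.
#' @param vel,mag Arrays `[x, y, z, 3]` or `[x, y, z, 3, batch]`.
#' @param keep Keep the activation tape (needed for backpropagation).
#' @return List with `out` (HR tensor `[X, Y, Z, 3, batch]`) and `tape`.
#' @export
network_forward <- function(model, vel, mag, keep = FALSE) {
  nn_forward(model, vel, mag, keep = keep)
}

MAG_SCALE <- 240  # magnitude channels are divided by the maximum intensity

#' Super-resolve one LR patch
#'
#' Normalises velocity channels by the per-component VENC (and magnitude by
#' the maximum intensity level), runs the model, and rescales the output to
#' m/s.
#'
#' @param model An `sr_network`, or an [sr_stub()] for testing.
#' @param lr_patch Array `[n, n, n, 6]`: three decoded velocity channels
#'   (m/s) then three magnitude channels.
#' @param venc Length-3 VENC in m/s.
#' @return HR velocity array `[N, N, N, 3]` in m/s with
#'   `N = n * upsample_factor`.
#' @export
predict_patch <- function(model, lr_patch, venc) UseMethod("predict_patch")

#' @export
predict_patch.sr_network <- function(model, lr_patch, venc) {
  stopifnot(length(dim(lr_patch)) == 4, dim(lr_patch)[4] == 6,
            length(venc) == 3)
  vel <- lr_patch[, , , 1:3, drop = FALSE]
  for (j in 1:3) vel[, , , j] <- vel[, , , j] / venc[j]
  mag <- lr_patch[, , , 4:6, drop = FALSE] / MAG_SCALE
  out <- nn_forward(model, vel, mag, keep = FALSE)$out
  d <- dim(out)[1:4]
  dim(out) <- d
  for (j in 1:3) out[, , , j] <- out[, , , j] * venc[j]
  out
}

#' Stub model for plumbing tests
#'
#' Wraps a plain function `fn(lr_patch, venc)` so it can stand in for a
#' trained network in [predict_volume()] (e.g. trilinear upsampling of the
#' velocity channels, or an identity feed of ground-truth patches).
#'
#' @param fn Function of `(lr_patch, venc)` returning an HR
#'   `[N, N, N, 3]` array.
#' @param factor Upsampling factor the stub emulates.
#' @param in_patch Patch size the stub expects.
#' @return An object of class `sr_stub`.
#' @export
sr_stub <- function(fn, factor = 4, in_patch = 12) {
  structure(list(fn = fn,
                 spec = list(upsample_factor = factor,
                             in_patch = as.integer(in_patch))),
            class = "sr_stub")
}

#' @export
predict_patch.sr_stub <- function(model, lr_patch, venc) {
  model$fn(lr_patch, venc)
}

#' Super-resolve a whole LR volume by patch stitching
#'
#' Splits the LR volume into overlapping `n`-voxel patches on the
#' stride-(`n - 4`) lattice, super-resolves each patch, and stitches the
#' results with [stitch_patches()] (4 HR voxels stripped from interior
#' patch faces).
#'
#' @param model An `sr_network` or `sr_stub`.
#' @param lr An [simulate_lr()] `lr_sample`.
#' @param n LR patch side (default: the model's `in_patch`).
#' @param strip HR voxels stripped per interior patch face.
#' @return SR velocity array with each LR axis scaled by the model's
#'   upsampling factor.
#' @export
predict_volume <- function(model, lr, n = model$spec$in_patch, strip = 4) {
  stopifnot(inherits(lr, "lr_sample"))
  f <- model$spec$upsample_factor
  d <- dim(lr$velocity_lr)[1:3]
  if (any(d < n)) stop("LR volume smaller than the patch size")
  venc <- lr$acquisition$venc
  origins <- expand.grid(x = split_origins(d[1], n),
                         y = split_origins(d[2], n),
                         z = split_origins(d[3], n))
  patches <- vector("list", nrow(origins))
  for (i in seq_len(nrow(origins))) {
    o <- as.integer(origins[i, ])
    lrp <- array(0, c(n, n, n, 6))
    ix <- o[1] + seq_len(n); iy <- o[2] + seq_len(n); iz <- o[3] + seq_len(n)
    lrp[, , , 1:3] <- lr$velocity_lr[ix, iy, iz, , drop = FALSE]
    lrp[, , , 4:6] <- lr$magnitude_lr[ix, iy, iz, , drop = FALSE]
    patches[[i]] <- list(origin = o * f,
                         data = predict_patch(model, lrp, venc))
  }
  stitch_patches(patches, out_shape = d * f, strip = strip)
}
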