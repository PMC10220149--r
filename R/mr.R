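#' Velocity-encoding (VENC) grid
#'
#' The discrete set of VENC values available to the augmentation policy:
#' 0.3 to 6.0 m/s in steps of 0.3.
#' @return Numeric vector of length 20.
#' @export
venc_grid <- function() seq(0.3, 6, by = 0.3)

#' Encode velocity as signal phase
#'
#' Maps velocity to phase `pi * v / venc`, wrapped into `(-pi, pi]`; a
#' velocity equal to the VENC corresponds to a 180 degree shift, and
#' velocities beyond it alias (wrap to apparently opposite values). The
#' encoding is invertible iff `|v| < venc`.
#'
#' @param v Velocity in m/s (vectorised).
#' @param venc VENC in m/s (> 0).
#' @return Phase in radians in `(-pi, pi]`.
#' @export
#' @examples
#' velocity_to_phase(1.5 * 2, 2)         # wraps
#' decode_velocity(velocity_to_phase(1.5 * 2, 2), 2)  # -0.5 * venc
velocity_to_phase <- function(v, venc) {
  if (!is.numeric(venc) || any(venc <= 0)) stop("venc must be positive")
  phi <- pi * v / venc
  pi - ((pi - phi) %% (2 * pi))
}

#' Decode signal phase to velocity
#'
#' Linear inverse of [velocity_to_phase()]: `venc * phase / pi`.
#' @param phase Phase in radians.
#' @param venc VENC in m/s.
#' @return Velocity in m/s (wrap-limited to `[-venc, venc]`).
#' @export
decode_velocity <- function(phase, venc) venc * phase / pi

#' Describe one simulated MR acquisition
#'
#' @param venc Length-3 numeric, per-component VENC in m/s (values from
#'   [venc_grid()]).
#' @param snr_db Signal-to-noise ratio in dB (fluid magnitude over the
#'   standard deviation of the complex noise).
#' @param intensity Constant magnitude level of fluid voxels.
#' @param seed Integer RNG seed recorded with the acquisition.
#' @return An object of class `acquisition`.
#' @export
acquisition <- function(venc, snr_db, intensity, seed = NA_integer_) {
  stopifnot(length(venc) == 3, all(venc > 0), snr_db > 0, intensity > 0)
  structure(list(venc = as.numeric(venc), snr_db = snr_db,
                 intensity = intensity, seed = seed), class = "acquisition")
}

#' Draw a random acquisition under the augmentation policy
#'
#' Per velocity component: with probability `1 - alias_prob`, the smallest
#' grid VENC strictly greater than the component's peak speed (or, with
#' `venc_rule = "uniform"`, a uniform choice among all larger grid values);
#' with probability `alias_prob` (default 10 %) a deliberately aliasing
#' VENC 0.3-0.6 m/s *below* the peak speed, snapped to the 0.3 grid and
#' floored at 0.3. Magnitude intensity is uniform on {60, ..., 240} and SNR
#' uniform on [14, 17] dB. Uses the current R RNG stream.
#'
#' @param max_speed Length-3 numeric, per-component peak absolute velocity
#'   in m/s (must be finite and non-negative; a zero component receives the
#'   minimum VENC).
#' @param alias_prob Probability of the deliberate-aliasing branch.
#' @param venc_rule `"smallest_above"` (default) or `"uniform"`.
#' @return An [acquisition()] .
#' @export
sample_acquisition <- function(max_speed, alias_prob = 0.10,
                               venc_rule = c("smallest_above", "uniform")) {
  venc_rule <- match.arg(venc_rule)
  if (length(max_speed) == 1) max_speed <- rep(max_speed, 3)
  if (length(max_speed) != 3 || any(!is.finite(max_speed)) ||
      any(max_speed < 0))
    stop("max_speed must be 3 finite non-negative speeds")
  if (alias_prob < 0 || alias_prob > 1) stop("alias_prob must be in [0, 1]")
  grid <- venc_grid()
  venc <- numeric(3)
  for (j in 1:3) {
    ms <- max_speed[j]
    alias <- runif(1) < alias_prob && ms > min(grid)
    if (alias) {
      cand <- grid[grid >= ms - 0.6 & grid <= ms - 0.3]
      if (length(cand) == 0)
        cand <- max(min(grid), grid[findInterval(ms - 0.3, grid)])
      venc[j] <- if (length(cand) > 1) sample(cand, 1) else cand
    } else {
      above <- grid[grid > ms]
      if (length(above) == 0) above <- max(grid)
      venc[j] <- if (venc_rule == "smallest_above") min(above)
                 else if (length(above) > 1) sample(above, 1) else above
    }
  }
  acquisition(venc,
              snr_db = runif(1, 14, 17),
              intensity = sample(60:240, 1))
}

# Central k-space indices of an axis of length n cropped to length m.
# The sorted result leaves the cropped spectrum in standard (unshifted)
# m-point frequency order.
kspace_keep <- function(n, m) {
  shift <- (seq_len(n) - 1 + floor(n / 2)) %% n + 1   # fftshift order
  centre <- floor(n / 2) + 1
  shifted <- seq(centre - floor(m / 2), length.out = m)
  sort(shift[shifted])
}

# Frequencies (cycles per HR grid) of the cropped m-point spectrum.
kspace_freq <- function(m) {
  q <- seq_len(m) - 1
  ifelse(q < ceiling(m / 2), q, q - m)
}

# Phase ramp aligning the LR samples with HR block centres: the inverse
# DFT of the truncated spectrum samples the low-passed image at HR
# positions m*factor; shifting by (factor-1)/2 voxels per axis puts each
# LR sample at the centre of its factor^3 block, matching the voxel
# convention used by the patch pairing, stitching and interpolation
# baselines.
kspace_centre_ramp <- function(lrdims, hrdims, factor) {
  s <- (factor - 1) / 2
  r <- lapply(1:3, function(a)
    exp(2i * pi * kspace_freq(lrdims[a]) * s / hrdims[a]))
  outer(outer(r[[1]], r[[2]]), r[[3]])
}

# Block-majority downsampling of a logical mask by an integer factor.
downsample_mask <- function(mask, factor) {
  d <- dim(mask)
  ld <- d %/% factor
  a <- array(mask[seq_len(ld[1] * factor), seq_len(ld[2] * factor),
                  seq_len(ld[3] * factor)],
             c(factor, ld[1], factor, ld[2], factor, ld[3]))
  s <- colSums(a)                       # (ld1, f, ld2, f, ld3)
  s <- colSums(aperm(s, c(2, 1, 3, 4, 5)))
  s <- colSums(aperm(s, c(3, 1, 2, 4)))
  array(s >= factor^3 / 2, ld)
}

#' Simulate a low-resolution MR acquisition of one HR frame
#'
#' Forward model per velocity component: a complex image
#' `intensity_map * exp(i * pi * v / venc)` is formed on the HR grid
#' (magnitude `intensity` in fluid, `intensity / 3` in static tissue within
#' the vessel domain, ~0 outside), its k-space is truncated to the central
#' `1/factor` cube per axis and inverse-transformed to the LR grid,
#' independent zero-mean Gaussian noise of standard deviation
#' `intensity / 10^(snr_db / 20)` is added to the real and imaginary parts,
#' and velocity is decoded from the noisy phase (so it is wrap-limited to
#' the VENC). The per-component `aliased` flag records whether the VENC was
#' below the component's true peak speed.
#'
#' @param velocity HR velocity array `[x, y, z, 3]` in m/s.
#' @param mask Logical HR fluid mask.
#' @param acq An [acquisition()].
#' @param factor Integer downsampling factor (default 4). HR axes that are
#'   not divisible by it are zero-padded up to the next multiple, giving LR
#'   lengths `ceiling(hr / factor)`.
#' @param domain Optional logical HR array marking the static-tissue region
#'   (defaults to everything).
#' @param noise Logical; set `FALSE` for a noiseless simulation.
#' @return An object of class `lr_sample`: `velocity_lr` (`[x', y', z', 3]`
#'   m/s), `magnitude_lr` (`[x', y', z', 3]`, one magnitude image per
#'   encoding), `mask_lr`, `acquisition`, `factor`, `aliased` (logical 3).
#' @export
simulate_lr <- function(velocity, mask, acq, factor = 4, domain = NULL,
                        noise = TRUE) {
  stopifnot(inherits(acq, "acquisition"))
  if (!is.numeric(factor) || length(factor) != 1 || factor < 1 ||
      factor != round(factor))
    stop("factor must be a positive integer")
  d <- dim(velocity)[1:3]
  if (!identical(dim(mask), d)) stop("mask/velocity shape mismatch")
  if (is.null(domain)) domain <- array(TRUE, d)
  pad <- (factor - d %% factor) %% factor
  dp <- d + pad
  ld <- dp %/% factor
  keep <- lapply(1:3, function(a) kspace_keep(dp[a], ld[a]))
  ramp <- kspace_centre_ramp(ld, dp, factor)
  mag <- acq$intensity * (mask + (domain & !mask) / 3)
  vel_lr <- array(0, c(ld, 3))
  mag_lr <- array(0, c(ld, 3))
  aliased <- logical(3)
  sigma <- acq$intensity / 10^(acq$snr_db / 20)
  for (j in 1:3) {
    v <- velocity[, , , j]
    aliased[j] <- acq$venc[j] < max(abs(v))
    phi <- pi * v / acq$venc[j]
    cplx <- mag * complex(real = cos(phi), imaginary = sin(phi))
    if (any(pad > 0)) {
      tmp <- array(0 + 0i, dp)
      tmp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- cplx
      cplx <- tmp
    }
    ks <- fft(cplx)[keep[[1]], keep[[2]], keep[[3]]] * ramp
    lr <- fft(ks, inverse = TRUE) / prod(dp)
    if (noise)
      lr <- lr + complex(real = rnorm(length(lr), 0, sigma),
                         imaginary = rnorm(length(lr), 0, sigma))
    vel_lr[, , , j] <- decode_velocity(Arg(lr), acq$venc[j])
    mag_lr[, , , j] <- Mod(lr)
  }
  mask_p <- mask
  if (any(pad > 0)) {
    mask_p <- array(FALSE, dp)
    mask_p[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- mask
  }
  structure(list(velocity_lr = vel_lr, magnitude_lr = mag_lr,
                 mask_lr = downsample_mask(mask_p, factor),
                 acquisition = acq, factor = as.integer(factor),
                 aliased = aliased, hr_dim = d),
            class = "lr_sample")
}

#' @export
print.lr_sample <- function(x, ...) {
  cat(sprintf(
    "lr_sample %s, venc %s m/s, snr %.1f dB, intensity %d%s\n",
    paste(dim(x$velocity_lr)[1:3], collapse = "x"),
    paste(format(x$acquisition$venc), collapse = "/"),
    x$acquisition$snr_db, x$acquisition$intensity,
    if (any(x$aliased)) sprintf(", aliased [%s]",
                                paste(which(x$aliased), collapse = ",")) else ""))
  invisible(x)
}
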