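#' Catalogue of constriction geometries
#'
#' Returns the 20 Venturi-style geometries used to synthesise regurgitant-jet
#' training flows. Geometries 1-10 are radially symmetric ("basic") and vary
#' the maximum inlet velocity `v_I` (m/s), inlet radius `R_I` (mm) and
#' constricted-section radius `R_C` (mm). Geometries 11-20 are derived from
#' geometry 3 and add an inclination `theta` (degrees between the constricted
#' section and the inlet normal), a centreline offset `delta` (mm) and an
#' offset/inclination direction, modelling eccentric jets. `v_peak_ref` is
#' the reference peak constricted-section velocity (m/s) of the original CFD
#' runs; it is carried for context and is not a property the analytic flow
#' surrogate reproduces exactly.
#'
#' @return A data frame with 20 rows and columns `id`, `shape_class`
#'   (`basic`, `angled`, `offset`, `combined`), `v_I`, `R_I`, `R_C`,
#'   `theta`, `delta`, `direction` (`none`, `upward`, `downward`,
#'   `sideways`) and `v_peak_ref`.
#' @seealso [geometry_config()], [synthesize_flow()]
#' @export
#' @examples
#' cat20 <- geometry_catalogue()
#' nrow(cat20)
#' cat20[cat20$id == 1, c("v_I", "R_I", "R_C")]
geometry_catalogue <- function() {
  basic <- data.frame(
    id = 1:10,
    v_I = c(0.30, 0.15, 0.50, 0.10, 0.10, 0.45, 0.45, 0.10, 0.15, 0.10),
    R_I = c(5, 5, 5, 5, 5, 8, 6, 8, 10, 10),
    R_C = c(1.00, 1.00, 1.50, 0.75, 0.60, 2.00, 2.00, 1.00, 2.00, 1.50),
    theta = 0, delta = 0, direction = "none",
    v_peak_ref = c(3.82, 1.92, 2.88, 2.29, 3.58, 2.22, 2.09, 2.27, 2.62, 2.96)
  )
  shaped <- data.frame(
    id = 11:20,
    v_I = 0.50, R_I = 5, R_C = 1.50,  # inherited from geometry 3
    theta = c(20, 40, 0, 0, 20, 40, 20, 40, 30, 30),
    delta = c(0, 0, 1.5, 3, 1.5, 1.5, 3, 3, 2.25, 2.25),
    direction = c("upward", "upward", "none", "none", "upward", "upward",
                  "upward", "upward", "sideways", "downward"),
    v_peak_ref = c(3.47, 4.65, 3.27, 3.18, 3.37, 4.32, 3.28, 4.12, 3.88, 4.48)
  )
  out <- rbind(basic, shaped)
  out$shape_class <- ifelse(out$theta > 0 & out$delta > 0, "combined",
                     ifelse(out$theta > 0, "angled",
                     ifelse(out$delta > 0, "offset", "basic")))
  # offset-only geometries still need a displacement direction for delta
  out$direction[out$shape_class == "offset"] <- "upward"
  out[, c("id", "shape_class", "v_I", "R_I", "R_C", "theta", "delta",
          "direction", "v_peak_ref")]
}

#' Build a single geometry configuration
#'
#' @param id Geometry number 1-20 from [geometry_catalogue()], or a one-row
#'   data frame with the same columns (allowing custom geometries).
#' @param upstream_length Length in mm of the straight inlet section before
#'   the constriction (flow becomes near-fully developed over it).
#' @param constriction_length Length in mm of the constricted section.
#' @param n_frames Number of time frames of the synthesised series.
#' @param dt Time step in seconds between frames.
#' @return An object of class `geometry_config`.
#' @export
geometry_config <- function(id, upstream_length = 20, constriction_length = 10,
                            n_frames = 71, dt = 0.001) {
  row <- if (is.data.frame(id)) id else {
    cat20 <- geometry_catalogue()
    if (!id %in% cat20$id) stop("unknown geometry id: ", id)
    cat20[cat20$id == id, ]
  }
  g <- as.list(row)
  stopifnot(g$R_C < g$R_I, g$v_I > 0, g$theta >= 0, g$delta >= 0)
  if (g$shape_class == "basic" && (g$theta != 0 || g$delta != 0))
    stop("basic geometries must have theta = 0 and delta = 0")
  g$upstream_length <- upstream_length
  g$constriction_length <- constriction_length
  g$n_frames <- as.integer(n_frames)
  g$dt <- dt
  class(g) <- "geometry_config"
  g
}

#' @export
print.geometry_config <- function(x, ...) {
  cat(sprintf(
    "geometry %s (%s): v_I=%.2f m/s, R_I=%.1f mm, R_C=%.2f mm, theta=%.0f deg, delta=%.2f mm (%s)\n",
    x$id, x$shape_class, x$v_I, x$R_I, x$R_C, x$theta, x$delta, x$direction))
  invisible(x)
}

#' Parabolic inlet velocity profile
#'
#' Axial speed of the fully developed parabolic profile at in-plane position
#' (x, y) on the inlet disc: `v_I - (x^2 + y^2) * v_I / R_I^2`. Maximal
#' (`v_I`) at the centre, zero on the rim.
#'
#' @param x,y In-plane coordinates in mm (vectorised).
#' @param v_I Maximum (centre) inlet velocity in m/s.
#' @param R_I Inlet radius in mm.
#' @return Axial speed in m/s.
#' @export
#' @examples
#' inlet_profile(0, 0, 0.30, 5)    # centre: v_I
#' inlet_profile(3, 4, 0.30, 5)    # rim: 0
inlet_profile <- function(x, y, v_I, R_I) {
  r2 <- x^2 + y^2
  if (any(r2 > R_I^2 + 1e-12)) stop("point outside the inlet disc")
  v_I - r2 * v_I / R_I^2
}

#' Diastolic temporal envelope
#'
#' Dimensionless gamma-variate-like waveform `g(t) = (t/tau) exp(1 - t/tau)`
#' scaling the whole flow field over the regurgitant (diastolic) phase:
#' a rapid initial rise to a unique peak `g(tau) = 1` followed by a slow
#' decay.
#'
#' @param t Time in seconds (vectorised, `t >= 0`).
#' @param tau Time-to-peak in seconds (`tau > 0`).
#' @return Values in `[0, 1]`.
#' @export
temporal_envelope <- function(t, tau) {
  if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau) || tau <= 0)
    stop("tau must be a positive number")
  stopifnot(all(t >= 0))
  (t / tau) * exp(1 - t / tau)
}

#' Define a uniform Cartesian voxel grid
#'
#' Voxel-centred, 0-based, isotropic grid. Axis order is x (flow axis),
#' y, z.
#'
#' @param shape Integer vector of 3 voxel counts.
#' @param spacing Voxel size in mm (isotropic, > 0).
#' @param origin mm coordinates of the centre of voxel (0, 0, 0). Default
#'   puts x = 0 at the first voxel and centres the y/z cross-section on 0.
#' @return An object of class `voxel_grid`.
#' @export
flow_grid <- function(shape, spacing,
                      origin = c(0, -(shape[2] - 1) * spacing / 2,
                                 -(shape[3] - 1) * spacing / 2)) {
  stopifnot(length(shape) == 3, all(shape >= 1), spacing > 0)
  structure(list(shape = as.integer(shape), spacing = spacing,
                 origin = origin), class = "voxel_grid")
}

#' Default synthesis grid for a geometry
#'
#' HR spacing defaults to 0.25 mm so that a 12-voxel LR patch (at the x4
#' downsampling of the MR simulator) spans 12 mm -- small enough that the
#' narrowest catalogue vessels can fill the 20 % minimum fluid fraction used
#' by the patch sampler. Cross-section spans `2 * (R_I + margin)` mm; all
#' axes are rounded to multiples of the downsampling factor.
#'
#' @param geom A [geometry_config()].
#' @param spacing HR voxel size in mm.
#' @param length_mm Domain length along the flow axis in mm.
#' @param margin_mm Radial tissue margin beyond the inlet radius in mm.
#' @param factor Downsampling factor the grid must be divisible by.
#' @return A [flow_grid()].
#' @export
default_flow_grid <- function(geom, spacing = 0.25, length_mm = 96,
                              margin_mm = 2, factor = 4) {
  round_up <- function(n) as.integer(ceiling(n / factor) * factor)
  nx <- round_up(length_mm / spacing)
  nyz <- round_up(2 * (geom$R_I + margin_mm) / spacing)
  flow_grid(c(nx, nyz, nyz), spacing)
}

#' Voxel-centre coordinates of a grid axis
#' @keywords internal
grid_axis <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing
}

#' Binary fluid mask by k-nearest-neighbour classification
#'
#' Labels each voxel centre of `grid` as fluid when the majority of its `k`
#' nearest labelled points (Euclidean distance, fluid and wall point clouds
#' pooled) are fluid points.
#'
#' @param fluid_points,wall_points Numeric matrices (n x 3) of mm
#'   coordinates; both must be non-empty.
#' @param grid A [flow_grid()].
#' @param k Odd integer >= 1; number of neighbours (default 1, i.e.
#'   nearest-neighbour classification).
#' @return A logical array of dim `grid$shape`; `TRUE` marks fluid.
#' @export
knn_mask <- function(fluid_points, wall_points, grid, k = 1) {
  fluid_points <- as.matrix(fluid_points)
  wall_points <- as.matrix(wall_points)
  if (nrow(fluid_points) == 0 || nrow(wall_points) == 0)
    stop("fluid and wall point sets must be non-empty")
  if (k < 1 || k %% 2 != 1) stop("k must be an odd integer >= 1")
  xs <- grid_axis(grid, 1); ys <- grid_axis(grid, 2); zs <- grid_axis(grid, 3)
  q <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  lab <- knn_label_cpp(q, fluid_points, wall_points, as.integer(k))
  array(lab, dim = grid$shape)
}
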