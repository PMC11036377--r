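#' Sample random affine parameters
#'
#' Per-axis scaling factors from U\[0.9, 1.1\], rotations from
#' U\[-20, 20\] degrees and translations from U\[-10, 10\] mm, all
#' independent.
#'
#' @return Object of class `affine_params`: list with `scale`, `rotation`
#'   (degrees) and `translation` (mm), each length 3.
#' @export
sample_affine <- function() {
  structure(list(scale = runif(3, 0.9, 1.1),
                 rotation = runif(3, -20, 20),
                 translation = runif(3, -10, 10)),
            class = "affine_params")
}

#' Identity affine parameters
#' @return An `affine_params` object representing the identity.
#' @export
identity_affine <- function() {
  structure(list(scale = c(1, 1, 1), rotation = c(0, 0, 0),
                 translation = c(0, 0, 0)),
            class = "affine_params")
}

rotation_matrix <- function(deg) {
  r <- deg * pi / 180
  rx <- matrix(c(1, 0, 0, 0, cos(r[1]), sin(r[1]), 0, -sin(r[1]),
                 cos(r[1])), 3)
  ry <- matrix(c(cos(r[2]), 0, -sin(r[2]), 0, 1, 0, sin(r[2]), 0,
                 cos(r[2])), 3)
  rz <- matrix(c(cos(r[3]), sin(r[3]), 0, -sin(r[3]), cos(r[3]), 0, 0, 0,
                 1), 3)
  rz %*% ry %*% rx
}

# world coordinates of every voxel centre, as an n x 3 matrix
voxel_world_coords <- function(d, w) {
  cbind(rep(axis_coords(d[1], w[1]), times = d[2] * d[3]),
        rep(rep(axis_coords(d[2], w[2]), each = d[1]), times = d[3]),
        rep(axis_coords(d[3], w[3]), each = d[1] * d[2]))
}

resample_at_world <- function(volume, src_world, interpolation) {
  vox <- as_vox_array(volume)
  w <- volume$voxel_size
  d <- dim(vox)
  xi <- src_world[, 1] / w[1] + (d[1] + 1) / 2
  yi <- src_world[, 2] / w[2] + (d[2] + 1) / 2
  zi <- src_world[, 3] / w[3] + (d[3] + 1) / 2
  if (inherits(volume, "label_map")) {
    out <- sample_volume_cpp(vox + 0.0, xi, yi, zi, 0L,
                             volume$palette[["background"]])
    dim(out) <- d
    label_map(array(as.integer(out), d), w, volume$palette)
  } else {
    method <- if (interpolation == "nearest") 0L else 1L
    out <- sample_volume_cpp(vox, xi, yi, zi, method, 0)
    dim(out) <- d
    mri_image(out, w)
  }
}

check_interp <- function(volume, interpolation) {
  interpolation <- match.arg(interpolation, c("nearest", "linear"))
  if (inherits(volume, "label_map") && interpolation != "nearest")
    stop("label maps must be resampled with nearest-neighbour ",
         "interpolation")
  interpolation
}

#' Apply an affine transform to a volume
#'
#' Resamples onto the input grid.  The forward map is
#' `y = R S (x - c) + c + t` with `c` the volume centre in world
#' coordinates, `R` the rotation (applied as Rz Ry Rx), `S` the diagonal
#' scaling and `t` the translation; the volume is resampled through the
#' inverse map.  Out-of-field voxels are filled with the background label
#' (label maps) or zero (images).
#'
#' @param volume a [label_map] or [mri_image].
#' @param params an `affine_params` object.
#' @param interpolation `"nearest"` (required for label maps) or
#'   `"linear"`.
#' @return Same type as `volume`.
#' @export
apply_affine <- function(volume, params,
                         interpolation = if (inherits(volume, "label_map"))
                           "nearest" else "linear") {
  interpolation <- check_interp(volume, interpolation)
  d <- dim(as_vox_array(volume)); w <- volume$voxel_size
  A <- rotation_matrix(params$rotation) %*% diag(params$scale, 3)
  Ainv <- solve(A)
  tgt <- voxel_world_coords(d, w)
  tgt[, 1] <- tgt[, 1] - params$translation[1]
  tgt[, 2] <- tgt[, 2] - params$translation[2]
  tgt[, 3] <- tgt[, 3] - params$translation[3]
  src <- tgt %*% t(Ainv)
  resample_at_world(volume, src, interpolation)
}

#' Sample random elastic (free-form) deformation parameters
#'
#' A coarse grid of `control_points^3` displacement vectors with each
#' component drawn from U\[-max_displacement, max_displacement\] mm.  The
#' dense field is obtained by clamped cubic B-spline interpolation of the
#' control grid, so its per-component magnitude never exceeds the control
#' values.
#'
#' @param control_points control points per axis (default 12).
#' @param max_displacement maximum displacement per component in mm
#'   (default 8).
#' @return Object of class `elastic_params`: list with `control_points`,
#'   `max_displacement` and `displacement_grid` (4D array,
#'   `control_points^3 x 3`).
#' @export
sample_elastic <- function(control_points = 12, max_displacement = 8) {
  cp <- as.integer(control_points)
  grid <- array(runif(cp^3 * 3, -max_displacement, max_displacement),
                c(cp, cp, cp, 3))
  structure(list(control_points = cp, max_displacement = max_displacement,
                 displacement_grid = grid),
            class = "elastic_params")
}

#' Zero elastic parameters (identity deformation)
#' @inheritParams sample_elastic
#' @return An `elastic_params` object with an all-zero control grid.
#' @export
zero_elastic <- function(control_points = 12) {
  cp <- as.integer(control_points)
  structure(list(control_points = cp, max_displacement = 0,
                 displacement_grid = array(0, c(cp, cp, cp, 3))),
            class = "elastic_params")
}

#' Densify an elastic control grid to a full voxel grid
#'
#' @param params an `elastic_params` object.
#' @param grid_shape target grid (3 integers).
#' @return 4D array `grid_shape x 3` of mm displacements.
#' @export
densify_elastic <- function(params, grid_shape) {
  d <- as.integer(grid_shape)
  out <- array(0, c(d, 3))
  for (a in 1:3)
    out[, , , a] <- ffd_densify_cpp(params$displacement_grid[, , , a],
                                    d[1], d[2], d[3])
  out
}

#' Apply an elastic deformation to a volume
#'
#' Backward warp: the voxel at target position `x` takes its value from
#' `x + u(x)` where `u` is the densified displacement field in mm.
#'
#' @inheritParams apply_affine
#' @param params an `elastic_params` object.
#' @return Same type as `volume`.
#' @export
apply_elastic <- function(volume, params,
                          interpolation = if (inherits(volume, "label_map"))
                            "nearest" else "linear") {
  interpolation <- check_interp(volume, interpolation)
  d <- dim(as_vox_array(volume)); w <- volume$voxel_size
  u <- densify_elastic(params, d)
  src <- voxel_world_coords(d, w)
  src[, 1] <- src[, 1] + as.vector(u[, , , 1])
  src[, 2] <- src[, 2] + as.vector(u[, , , 2])
  src[, 3] <- src[, 3] + as.vector(u[, , , 3])
  resample_at_world(volume, src, interpolation)
}
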