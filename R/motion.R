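#' Sample motion amplitude parameters
#'
#' Maximum displacement of the simulated head movement: translation
#' magnitude from U\[3, 8\] mm and rotation magnitude from U\[3, 8\]
#' degrees.
#'
#' @return Object of class `motion_params`: list with `max_translation`
#'   (mm) and `max_rotation` (degrees).
#' @export
sample_motion_params <- function() {
  structure(list(max_translation = runif(1, 3, 8),
                 max_rotation = runif(1, 3, 8)),
            class = "motion_params")
}

smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

#' Sample a rigid-motion time course over k-space segments
#'
#' Simulates a single sudden head movement during the acquisition: the
#' head is still until a random event segment, moves along a smooth ramp
#' over a few segments, then stays at a constant plateau.  The plateau
#' translation vector has Euclidean norm `max_translation` (direction
#' uniform on the sphere) and the rotation vector norm `max_rotation`, so
#' the peak displacement of the trajectory equals the sampled maxima.
#' The event segment is uniform over segments; the ramp width is uniform
#' over `1..max(2, n_segments %/% 10)` and truncated so the plateau is
#' always reached.
#'
#' @param params a `motion_params` object.
#' @param n_segments number of k-space segments (>= 2), one rigid state
#'   per segment.
#' @return Object of class `motion_trajectory`: list with `translations`
#'   (`n_segments x 3`, mm), `rotations` (`n_segments x 3`, degrees),
#'   `event`, `ramp` and the generating `params`.
#' @export
sample_trajectory <- function(params, n_segments) {
  n <- as.integer(n_segments)
  if (n < 2) stop("n_segments must be at least 2")
  event <- sample.int(n, 1)
  ramp <- sample.int(max(2L, n %/% 10L), 1)
  ramp <- min(ramp, n - event + 1L)
  dir_t <- rnorm(3); dir_t <- dir_t / sqrt(sum(dir_t^2))
  dir_r <- rnorm(3); dir_r <- dir_r / sqrt(sum(dir_r^2))
  s <- seq_len(n)
  f <- ifelse(s < event, 0, smoothstep((s - event + 1) / ramp))
  structure(list(translations = outer(f, dir_t * params$max_translation),
                 rotations = outer(f, dir_r * params$max_rotation),
                 event = event, ramp = ramp, params = params),
            class = "motion_trajectory")
}

#' Identity trajectory (no motion)
#' @param n_segments number of k-space segments.
#' @return A `motion_trajectory` with all-zero transforms.
#' @export
identity_trajectory <- function(n_segments) {
  n <- as.integer(n_segments)
  structure(list(translations = matrix(0, n, 3),
                 rotations = matrix(0, n, 3),
                 event = NA_integer_, ramp = NA_integer_,
                 params = structure(list(max_translation = 0,
                                         max_rotation = 0),
                                    class = "motion_params")),
            class = "motion_trajectory")
}

# wrapped DFT frequency indices for axis length n
fft_freq <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n %/% 2, k, k - n)
}

# phase ramp implementing a spatial shift by tau voxels along each axis
phase_ramp <- function(d, tau) {
  px <- exp(-2i * pi * fft_freq(d[1]) * tau[1] / d[1])
  py <- exp(-2i * pi * fft_freq(d[2]) * tau[2] / d[2])
  pz <- exp(-2i * pi * fft_freq(d[3]) * tau[3] / d[3])
  outer(outer(px, py), pz)
}

#' Corrupt an image with k-space rigid-motion artifacts
#'
#' Simulates the tissue mixing induced by head motion during a line-by-line
#' acquisition: k-space is partitioned into segments of phase-encode lines
#' (second array axis); for each segment the object is rigidly transformed
#' by that segment's state (rotations by spatial resampling with linear
#' interpolation, translations as linear phase ramps in k-space), the
#' transform's spectrum is computed, and the segment's lines are taken
#' from it.  The magnitude of the inverse transform is returned.
#' Background voxels should be zeroed beforehand (pass `background_mask`).
#'
#' @param image an [mri_image].
#' @param traj a `motion_trajectory` whose length equals the number of
#'   segments.
#' @param n_segments number of k-space segments; defaults to one segment
#'   per phase-encode line.
#' @param ordering mapping of segments (time) to phase-encode lines:
#'   `"linear"` (sequential) or `"centric"` (centre-out).
#' @param background_mask optional logical array; voxels where `TRUE` are
#'   set to zero before the simulation.
#' @param magnitude return the magnitude image (default) or the complex
#'   array.
#' @return An [mri_image] (or complex array when `magnitude = FALSE`).
#' @export
apply_motion <- function(image, traj, n_segments = NULL,
                         ordering = c("linear", "centric"),
                         background_mask = NULL, magnitude = TRUE) {
  ordering <- match.arg(ordering)
  vox <- as_vox_array(image)
  d <- dim(vox)
  w <- if (inherits(image, "mri_image")) image$voxel_size else c(1, 1, 1)
  n_seg <- nrow(traj$translations)
  if (!is.null(n_segments) && n_segments != n_seg)
    stop("trajectory length (", n_seg, ") does not match n_segments (",
         n_segments, ")")
  if (d[2] %% n_seg != 0)
    stop("number of phase-encode lines (", d[2],
         ") must be a multiple of the number of segments (", n_seg, ")")
  if (!is.null(background_mask)) vox[background_mask] <- 0

  lines_per_seg <- d[2] / n_seg
  line_order <- switch(ordering,
    linear = seq_len(d[2]),
    centric = order(abs(seq_len(d[2]) - (d[2] + 1) / 2)))
  seg_of_line <- integer(d[2])
  seg_of_line[line_order] <- rep(seq_len(n_seg), each = lines_per_seg)

  # group segments sharing (numerically) the same rigid state
  key <- apply(round(cbind(traj$translations, traj$rotations), 9), 1,
               paste, collapse = ",")
  groups <- split(seq_len(n_seg), key)

  kspace <- array(0i, d)
  for (g in groups) {
    seg <- g[1]
    rot <- traj$rotations[seg, ]
    tr <- traj$translations[seg, ]
    obj <- vox
    if (any(rot != 0)) {
      p <- structure(list(scale = c(1, 1, 1), rotation = rot,
                          translation = c(0, 0, 0)),
                     class = "affine_params")
      obj <- resample_rot(obj, w, p)
    }
    spec <- fft(obj)
    if (any(tr != 0)) spec <- spec * phase_ramp(d, tr / w)
    lines <- which(seg_of_line %in% g)
    kspace[, lines, ] <- spec[, lines, ]
  }
  out <- fft(kspace, inverse = TRUE) / prod(d)
  if (!magnitude) return(out)
  mri_image(array(Mod(out), d), w)
}

# rotation-only resample on the native grid (linear interpolation, zero fill)
resample_rot <- function(vox, w, params) {
  d <- dim(vox)
  Ainv <- solve(rotation_matrix(params$rotation))
  src <- voxel_world_coords(d, w) %*% t(Ainv)
  xi <- src[, 1] / w[1] + (d[1] + 1) / 2
  yi <- src[, 2] / w[2] + (d[2] + 1) / 2
  zi <- src[, 3] / w[3] + (d[3] + 1) / 2
  out <- sample_volume_cpp(vox, xi, yi, zi, 1L, 0)
  dim(out) <- d
  out
}
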