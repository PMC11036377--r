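#' Specification of a neonatal-like label phantom
#'
#' The phantom emulates the nested geometry of a neonatal head: an
#' extra-cerebral `head` shell, a CSF compartment, a folded cortical GM
#' shell between pial and white surfaces, the WM interior, and deep
#' structures (ventricles, deep GM, cerebellum, brainstem,
#' hippocampus+amygdala) embedded in the WM.  The `folding` parameter in
#' `[0, 1]` controls the amplitude and frequency of a sinusoidal radial
#' perturbation of the cortical shell and stands in for gestational age
#' (0 = smooth, immature shell; 1 = maximally folded).
#'
#' @param grid_shape integer length 1 or 3, voxels per axis (each >= 32).
#' @param voxel_size mm per voxel (length 1 or 3, > 0).
#' @param folding real in `[0, 1]`.
#' @param cortical_thickness cortical GM thickness in mm.
#' @param seed integer seed controlling the phantom's random phases and
#'   the jitter of the deep structures.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64), voxel_size = 1,
                         folding = 0.5, cortical_thickness = 3, seed = 1) {
  if (length(grid_shape) == 1) grid_shape <- rep(grid_shape, 3)
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  stopifnot(length(grid_shape) == 3, length(voxel_size) == 3)
  if (any(grid_shape < 32))
    stop("grid_shape must be at least 32 voxels per axis")
  if (any(voxel_size <= 0)) stop("voxel_size must be positive")
  if (folding < 0 || folding > 1) stop("folding must lie in [0, 1]")
  if (cortical_thickness <= 0) stop("cortical_thickness must be positive")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = as.numeric(voxel_size),
                 folding = folding,
                 cortical_thickness = cortical_thickness,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# deep-structure layout in phantom units (scaled by H / 32), as
# ellipsoids: label, centre (mm), semi-axes (mm)
phantom_blobs <- function(s) {
  list(
    list(label = "ventricles", centre = c(-4, 2, 2) * s,
         semi = c(2, 5, 2.5) * s),
    list(label = "ventricles", centre = c(4, 2, 2) * s,
         semi = c(2, 5, 2.5) * s),
    list(label = "deepgm", centre = c(-7.5, -2, -1) * s,
         semi = c(3, 3.5, 3) * s),
    list(label = "deepgm", centre = c(7.5, -2, -1) * s,
         semi = c(3, 3.5, 3) * s),
    list(label = "cerebellum", centre = c(0, -8, -7) * s,
         semi = c(5, 3.5, 3) * s),
    list(label = "brainstem", centre = c(0, -2, -9) * s,
         semi = c(2, 2, 5) * s),
    list(label = "hipamy", centre = c(-9, -7, -3) * s,
         semi = c(1.8, 1.8, 1.8) * s),
    list(label = "hipamy", centre = c(9, -7, -3) * s,
         semi = c(1.8, 1.8, 1.8) * s))
}

#' Generate a seeded neonatal-like label phantom
#'
#' Builds the full label map together with the inner (white) and outer
#' (pial) cortical boundaries as signed-distance volumes.  The cortical
#' shell is a radially perturbed sphere: the pial radius is
#' `R0 + a(folding) * g(direction)` with `g` a product of sinusoids in the
#' spherical angles (vanishing at the poles), and the white surface lies
#' `cortical_thickness` mm deeper along the radius.  GM voxels are exactly
#' those with `outer_sdf < 0` and `inner_sdf >= 0`.  Deep structures are
#' disjoint ellipsoids confined to the WM interior.  Deterministic for a
#' fixed seed.
#'
#' @param spec a [phantom_spec].
#' @return List with elements `labels` (a [label_map]), `surfaces`
#'   (a [surface_pair]), `age_weeks` (pseudo-age, `26 + folding * 19`),
#'   and `spec`.
#' @export
#' @examples
#' ph <- make_phantom(phantom_spec(grid_shape = 32, cortical_thickness = 2))
#' ph$labels
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape; w <- spec$voxel_size
  H <- min(d * w) / 2          # half extent, mm
  s <- H / 32                  # layout scale relative to the 64 mm design
  r_head <- 0.92 * H
  r_csf  <- 0.80 * H
  r_pial <- 0.68 * H
  thick  <- spec$cortical_thickness
  amp    <- spec$folding * 2.5 * s
  freq   <- 3 + round(7 * spec$folding)
  r_wm_min <- r_pial - amp - thick
  if (r_wm_min < 0.35 * H)
    stop("grid too small to host all structures: the cortical shell ",
         "(radius ", signif(r_pial, 3), " mm, amplitude ", signif(amp, 3),
         " mm, thickness ", thick, " mm) leaves less than 0.35 * ",
         signif(H, 3), " mm of WM interior for the deep structures; ",
         "reduce cortical_thickness or enlarge the grid")

  phases <- with_seed(spec$seed, runif(2, 0, 2 * pi))
  jitter <- with_seed(spec$seed + 1L,
                      matrix(runif(3 * 8, -0.5, 0.5) * s, ncol = 3))

  cx <- axis_coords(d[1], w[1])
  cy <- axis_coords(d[2], w[2])
  cz <- axis_coords(d[3], w[3])
  X <- array(cx, d)
  Y <- array(rep(cy, each = d[1]), d)
  Z <- array(rep(cz, each = d[1] * d[2]), d)
  r <- sqrt(X^2 + Y^2 + Z^2)

  theta <- acos(ifelse(r > 0, Z / pmax(r, 1e-9), 1))
  phi <- atan2(Y, X)
  g <- sin(theta)^2 * sin(freq * theta + phases[1]) *
    cos(freq * phi + phases[2])
  r_pial_dir <- r_pial + amp * g

  outer_sdf <- r - r_pial_dir
  inner_sdf <- outer_sdf + thick
  surfaces <- surface_pair(inner_sdf, outer_sdf, w, check = FALSE)

  pal <- default_palette()
  vox <- array(pal[["background"]], d)
  vox[r <= r_head] <- pal[["head"]]
  vox[r <= r_csf & outer_sdf >= 0] <- pal[["csf"]]
  vox[outer_sdf < 0 & inner_sdf >= 0] <- pal[["gm"]]
  vox[inner_sdf < 0] <- pal[["wm"]]

  wm_interior <- inner_sdf < -1 * s   # 1 mm safety margin at design scale
  blobs <- phantom_blobs(s)
  for (b in seq_along(blobs)) {
    bl <- blobs[[b]]
    ct <- bl$centre + jitter[b, ]
    inside <- ((X - ct[1]) / bl$semi[1])^2 + ((Y - ct[2]) / bl$semi[2])^2 +
      ((Z - ct[3]) / bl$semi[3])^2 <= 1
    take <- inside & wm_interior & vox == pal[["wm"]]
    vox[take] <- pal[[bl$label]]
  }

  labels <- label_map(vox, w, pal)
  missing <- names(pal)[!pal %in% unique(as.integer(vox))]
  if (length(missing))
    stop("grid too small to host all structures: missing label(s) ",
         paste(missing, collapse = ", "))
  list(labels = labels, surfaces = surfaces,
       age_weeks = 26 + spec$folding * 19, spec = spec)
}

#' Paired tight/large ground-truth variants
#'
#' Builds two ground-truth label maps from the same phantom: a `tight`
#' variant in which GM is the surface-derived partial-volume segmentation
#' binarized at 0.5, and a `large` variant in which the outer boundary is
#' displaced outward and the inner boundary inward by `bias_mm` before
#' thresholding, emulating a systematically over-segmented cortex.  All
#' structures other than GM/WM/CSF are identical between the two variants.
#'
#' @param labels a [label_map] (typically from [make_phantom]).
#' @param surfaces the matching [surface_pair].
#' @param bias_mm outward/inward boundary displacement in mm (>= 0).
#' @param supersample sub-voxel sampling factor for the partial-volume
#'   computation.
#' @return List with label maps `tight` and `large` and the GM volume
#'   ratio `ratio` (large / tight).
#' @seealso [calibrate_gt_bias] to choose `bias_mm` for a target ratio.
#' @export
make_gt_variants <- function(labels, surfaces, bias_mm, supersample = 4) {
  stopifnot(bias_mm >= 0)
  pv_tight <- partial_volume_gm(surfaces, supersample = supersample)
  tight <- binarize_and_fuse(labels, pv_tight)
  if (bias_mm == 0) {
    large <- tight
  } else {
    big <- surface_pair(surfaces$inner_sdf + bias_mm,
                        surfaces$outer_sdf - bias_mm,
                        surfaces$voxel_size, check = FALSE)
    head_id <- labels$palette[["head"]]
    if (any(big$outer_sdf < 0 & labels$voxels == head_id))
      stop("bias_mm too large: enlarged GM reaches the head label")
    pv_large <- partial_volume_gm(big, supersample = supersample)
    large <- binarize_and_fuse(labels, pv_large)
  }
  vt <- label_volumes(tight, "gm")
  vl <- label_volumes(large, "gm")
  list(tight = tight, large = large, ratio = unname(vl / vt))
}

#' Calibrate the ground-truth bias for a target GM volume ratio
#'
#' Finds the boundary displacement `bias_mm` such that the GM volume of
#' the `large` variant exceeds the `tight` variant by the requested factor
#' (default 1.25, i.e. a 25% volume increase).  The ratio is monotone
#' non-decreasing in `bias_mm`, so a bracketing root search is used.
#'
#' @inheritParams make_gt_variants
#' @param target_ratio desired large/tight GM volume ratio.
#' @param interval search interval for `bias_mm` in mm.
#' @param tol volume-ratio tolerance of the root search.
#' @return The calibrated `bias_mm` (numeric scalar).
#' @export
calibrate_gt_bias <- function(labels, surfaces, target_ratio = 1.25,
                              interval = c(0, 2), supersample = 4,
                              tol = 1e-3) {
  pv_tight <- partial_volume_gm(surfaces, supersample = supersample)
  tight <- binarize_and_fuse(labels, pv_tight)
  vt <- label_volumes(tight, "gm")
  f <- function(b) {
    if (b <= 0) return(1 - target_ratio)
    big <- surface_pair(surfaces$inner_sdf + b, surfaces$outer_sdf - b,
                        surfaces$voxel_size, check = FALSE)
    pv <- partial_volume_gm(big, supersample = supersample)
    large <- binarize_and_fuse(labels, pv)
    unname(label_volumes(large, "gm") / vt) - target_ratio
  }
  uniroot(f, interval, extendInt = "upX", tol = tol)$root
}
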