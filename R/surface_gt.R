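#' Partial-volume GM map from cortical boundary surfaces
#'
#' Estimates, for every voxel, the fraction occupied by cortical GM — the
#' region between the inner (white) and outer (pial) boundaries — by
#' counting `supersample^3` sub-voxel centres with `outer_sdf < 0` and
#' `inner_sdf >= 0`.  The signed-distance volumes are interpolated
#' trilinearly at sub-voxel positions.  Voxels farther from both
#' boundaries than the voxel diagonal are filled without supersampling.
#'
#' @param surfaces a [surface_pair].
#' @param supersample integer >= 2, sub-voxel sampling factor per axis.
#' @return Object of class `pv_map`: list with `voxels` (3D array of GM
#'   fractions in `[0, 1]`) and `voxel_size`.
#' @export
partial_volume_gm <- function(surfaces, supersample = 4) {
  stopifnot(inherits(surfaces, "surface_pair"))
  supersample <- as.integer(supersample)
  if (supersample < 2) stop("supersample must be at least 2")
  inner <- surfaces$inner_sdf; outer <- surfaces$outer_sdf
  if (any(inner < 0 & outer >= 0))
    stop("surface nesting violated: {inner_sdf < 0} must lie inside ",
         "{outer_sdf < 0}")
  d <- dim(inner); w <- surfaces$voxel_size
  buffer <- sqrt(sum(w^2))  # voxel diagonal, mm

  pv <- array(0, d)
  certain_in <- outer < -buffer & inner >= buffer
  pv[certain_in] <- 1
  # voxels that may straddle a boundary
  unc <- which(!(certain_in |
                   (outer >= buffer) |          # fully outside pial
                   (inner < -buffer)))          # fully inside white
  if (length(unc)) {
    idx <- arrayInd(unc, d)
    s <- supersample
    off <- (seq_len(s) - 0.5) / s - 0.5          # sub-voxel offsets, index units
    grid <- expand.grid(dx = off, dy = off, dz = off)
    frac <- numeric(length(unc))
    # chunk over sub-voxel offsets to bound memory
    for (g in seq_len(nrow(grid))) {
      # clamp to the hull of voxel centres: the SDF extends smoothly, so
      # edge sub-samples take the nearest in-grid value
      xi <- pmin(pmax(idx[, 1] + grid$dx[g], 1), d[1])
      yi <- pmin(pmax(idx[, 2] + grid$dy[g], 1), d[2])
      zi <- pmin(pmax(idx[, 3] + grid$dz[g], 1), d[3])
      so <- sample_volume_cpp(outer, xi, yi, zi, 1L, Inf)
      si <- sample_volume_cpp(inner, xi, yi, zi, 1L, Inf)
      frac <- frac + (so < 0 & si >= 0)
    }
    pv[unc] <- frac / nrow(grid)
  }
  structure(list(voxels = pv, voxel_size = w), class = "pv_map")
}

#' Binarize a partial-volume map and fuse it into a label map
#'
#' Replaces the GM of `label_map` with the thresholded partial-volume
#' segmentation while preserving the remaining structures: voxels that
#' lose their GM label are reassigned to the nearest of WM or CSF
#' (Euclidean distance in mm to the respective input mask, ties to WM),
#' and voxels that gain GM may only overwrite WM or CSF.  Protected
#' structures (ventricles, deep GM, cerebellum, brainstem,
#' hippocampus+amygdala, head, background) are never modified; conflicts
#' are counted in the `protected_conflicts` attribute.
#'
#' @param label_map a [label_map].
#' @param pv a `pv_map` from [partial_volume_gm] (or a 3D array of GM
#'   fractions).
#' @param threshold GM decision threshold in `(0, 1)`; comparison is
#'   `pv >= threshold`.
#' @return The fused [label_map].
#' @export
binarize_and_fuse <- function(label_map, pv, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  pvv <- if (inherits(pv, "pv_map")) pv$voxels else pv
  stopifnot(identical(dim(pvv), dim(label_map$voxels)))
  pal <- label_map$palette
  vox <- label_map$voxels
  new_gm <- pvv >= threshold

  gm <- vox == pal[["gm"]]
  wm <- vox == pal[["wm"]]
  csf <- vox == pal[["csf"]]
  soft <- gm | wm | csf

  out <- vox
  gained <- new_gm & soft & !gm
  out[gained] <- pal[["gm"]]
  conflicts <- sum(new_gm & !soft)

  lost <- gm & !new_gm
  if (any(lost)) {
    dim(wm) <- dim(csf) <- dim(vox)
    d_wm <- edt_cpp(wm, label_map$voxel_size)
    d_csf <- edt_cpp(csf, label_map$voxel_size)
    to_wm <- lost & (d_wm <= d_csf)
    out[to_wm] <- pal[["wm"]]
    out[lost & !to_wm] <- pal[["csf"]]
  }
  res <- label_map(out, label_map$voxel_size, pal)
  attr(res, "protected_conflicts") <- conflicts
  res
}
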