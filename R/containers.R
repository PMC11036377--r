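#' Canonical tissue palette
#'
#' Integer label identifiers for the ten tissue classes used throughout the
#' package: the nine brain tissue classes of a neonatal segmentation
#' (CSF, cortical GM, WM, ventricles, deep GM, cerebellum, brainstem,
#' hippocampus+amygdala) plus a `head` class for all extra-cerebral tissue
#' and `background` for air.
#'
#' @return Named integer vector mapping label names to label ids.
#' @export
#' @examples
#' default_palette()
default_palette <- function() {
  c(background = 0L, head = 1L, csf = 2L, gm = 3L, wm = 4L,
    ventricles = 5L, deepgm = 6L, cerebellum = 7L, brainstem = 8L,
    hipamy = 9L)
}

#' Construct a label map
#'
#' A label map is a 3D integer array of tissue identifiers together with its
#' voxel geometry (isotropic or anisotropic voxel size in mm) and the palette
#' of admissible labels.  The world coordinate of voxel `(i, j, k)` is
#' `(i - (n + 1) / 2) * voxel_size` per axis, i.e. the origin sits at the
#' volume centre.
#'
#' @param voxels 3D integer array of label ids.
#' @param voxel_size numeric length 1 or 3, mm per voxel.
#' @param palette named integer vector of admissible labels.
#' @return Object of class `label_map`.
#' @export
label_map <- function(voxels, voxel_size = 1, palette = default_palette()) {
  stopifnot(length(dim(voxels)) == 3)
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  stopifnot(all(voxel_size > 0))
  vox <- as.integer(voxels)
  bad <- setdiff(unique(vox), unname(palette))
  if (length(bad))
    stop("label map contains ids absent from the palette: ",
         paste(bad, collapse = ", "))
  dim(vox) <- dim(voxels)
  structure(list(voxels = vox, voxel_size = as.numeric(voxel_size),
                 palette = palette),
            class = "label_map")
}

#' Construct an intensity image
#'
#' @param voxels 3D numeric array.
#' @param voxel_size numeric length 1 or 3, mm per voxel.
#' @return Object of class `mri_image`.
#' @export
mri_image <- function(voxels, voxel_size = 1) {
  stopifnot(length(dim(voxels)) == 3)
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  stopifnot(all(voxel_size > 0), all(is.finite(voxels)))
  structure(list(voxels = voxels + 0.0, voxel_size = as.numeric(voxel_size)),
            class = "mri_image")
}

#' Construct a cortical surface pair
#'
#' Holds the inner (white) and outer (pial) cortical boundaries as signed
#' distance volumes in mm, negative inside the enclosed region.  The region
#' enclosed by the inner surface must be contained in the region enclosed by
#' the outer surface.
#'
#' @param inner_sdf,outer_sdf 3D numeric arrays, signed distance in mm.
#' @param voxel_size numeric length 1 or 3, mm per voxel.
#' @param check check the nesting invariant (`{inner < 0}` within
#'   `{outer < 0}`).
#' @return Object of class `surface_pair`.
#' @export
surface_pair <- function(inner_sdf, outer_sdf, voxel_size = 1, check = TRUE) {
  stopifnot(identical(dim(inner_sdf), dim(outer_sdf)))
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  if (check && any(inner_sdf < 0 & outer_sdf >= 0))
    stop("surface nesting violated: {inner_sdf < 0} must lie inside ",
         "{outer_sdf < 0}")
  structure(list(inner_sdf = inner_sdf, outer_sdf = outer_sdf,
                 voxel_size = as.numeric(voxel_size)),
            class = "surface_pair")
}

#' @export
print.label_map <- function(x, ...) {
  cat("<label_map> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, ", paste(signif(x$voxel_size, 3), collapse = " x "),
      " mm\n", sep = "")
  tab <- table(factor(x$voxels, levels = unname(x$palette),
                      labels = names(x$palette)))
  present <- tab[tab > 0]
  cat("  labels: ", paste(names(present), present, sep = "=",
                          collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.mri_image <- function(x, ...) {
  cat("<mri_image> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, range [", signif(min(x$voxels), 4), ", ",
      signif(max(x$voxels), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
print.surface_pair <- function(x, ...) {
  cat("<surface_pair> ", paste(dim(x$inner_sdf), collapse = " x "),
      " voxels; inner volume ", sum(x$inner_sdf < 0), " vox, outer ",
      sum(x$outer_sdf < 0), " vox\n", sep = "")
  invisible(x)
}

#' Per-label voxel volumes
#'
#' @param map a [label_map].
#' @param labels label names to report (default: all in the palette).
#' @return Named numeric vector of volumes in mm^3.
#' @export
label_volumes <- function(map, labels = names(map$palette)) {
  vv <- prod(map$voxel_size)
  counts <- vapply(labels, function(l)
    sum(map$voxels == map$palette[[l]]), numeric(1))
  counts * vv
}

label_mask <- function(map, label) {
  m <- map$voxels == map$palette[[label]]
  dim(m) <- dim(map$voxels)
  m
}

world_affine <- function(dim3, voxel_size) {
  # voxel index (1-based) -> world mm, origin at the volume centre
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(voxel_size, 3)
  aff[1:3, 4] <- -voxel_size * (dim3 + 1) / 2
  aff
}

#' Write a volume as NIfTI-1
#'
#' Label maps are written as integer volumes, images and signed-distance
#' volumes as float32.  The world affine (origin at the volume centre) is
#' recorded in the header.
#'
#' @param x a [label_map], [mri_image] or [surface_pair] (the latter writes
#'   two files with `_inner`/`_outer` suffixes).
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "surface_pair")) {
    base <- sub("\\.nii(\\.gz)?$", "", path)
    ext <- substr(path, nchar(base) + 1, nchar(path))
    write_volume(mri_image(x$inner_sdf, x$voxel_size),
                 paste0(base, "_inner", ext))
    write_volume(mri_image(x$outer_sdf, x$voxel_size),
                 paste0(base, "_outer", ext))
    return(invisible(path))
  }
  vox <- x$voxels
  aff <- world_affine(dim(vox), x$voxel_size)
  img <- RNifti::asNifti(vox)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  dt <- if (inherits(x, "label_map")) "int16" else "float"
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path file path.
#' @param type `"label"` to return a [label_map], `"image"` for an
#'   [mri_image].
#' @param palette palette for label maps.
#' @return A [label_map] or [mri_image].
#' @export
read_volume <- function(path, type = c("image", "label"),
                        palette = default_palette()) {
  type <- match.arg(type)
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1:3]
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  if (type == "label")
    label_map(array(as.integer(round(arr)), dim(arr)), vs, palette)
  else mri_image(arr, vs)
}
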