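#' Sample a random tissue contrast
#'
#' Draws one Gaussian intensity model per label: the mean of each tissue is
#' sampled from U\[0, 1\] and its standard deviation from U\[0.02, 0.1\],
#' independently across tissues.  One contrast sample defines the
#' appearance of one generated volume.
#'
#' @param labels label ids (integer vector) or a [label_map], in which case
#'   all palette labels present in the map are used.
#' @return Object of class `contrast_sample`: a data frame with columns
#'   `label`, `mean`, `sd`.
#' @export
#' @examples
#' set.seed(1)
#' sample_contrast(c(0L, 1L, 2L))
sample_contrast <- function(labels) {
  if (inherits(labels, "label_map"))
    labels <- sort(unique(as.integer(labels$voxels)))
  labels <- as.integer(labels)
  if (!length(labels)) stop("label set must be non-empty")
  out <- data.frame(label = labels,
                    mean = runif(length(labels), 0, 1),
                    sd = runif(length(labels), 0.02, 0.1))
  class(out) <- c("contrast_sample", "data.frame")
  out
}

#' Fixed contrast from a named mean table
#'
#' Builds a deterministic [sample_contrast]-shaped object from named
#' per-tissue means, used for the canonical "T1-like" / "T2-like"
#' renderings of phantom subjects.
#'
#' @param means named numeric vector (names from [default_palette]).
#' @param sd per-tissue standard deviation (recycled).
#' @param palette palette resolving names to ids.
#' @return A `contrast_sample`.
#' @export
fixed_contrast <- function(means, sd = 0.03, palette = default_palette()) {
  ids <- palette[names(means)]
  if (anyNA(ids)) stop("unknown tissue name in `means`")
  out <- data.frame(label = unname(ids), mean = unname(means),
                    sd = rep_len(sd, length(means)))
  class(out) <- c("contrast_sample", "data.frame")
  out
}

#' Canonical T1-like / T2-like phantom contrasts
#'
#' Two fixed, disjoint contrast configurations emulating the tissue
#' ordering of T1- and T2-weighted neonatal images (in T2w, CSF is bright
#' and unmyelinated WM brighter than GM is not yet established, so WM is
#' kept dark here and bright in the T1-like table; the point is that the
#' two contrasts are far apart, not radiological fidelity).
#'
#' @param which `"t1"` or `"t2"`.
#' @return A `contrast_sample`.
#' @export
canonical_contrast <- function(which = c("t2", "t1")) {
  which <- match.arg(which)
  means <- switch(which,
    t2 = c(background = 0.05, head = 0.25, csf = 0.90, gm = 0.55,
           wm = 0.30, ventricles = 0.90, deepgm = 0.48, cerebellum = 0.58,
           brainstem = 0.42, hipamy = 0.52),
    t1 = c(background = 0.05, head = 0.40, csf = 0.12, gm = 0.45,
           wm = 0.78, ventricles = 0.12, deepgm = 0.58, cerebellum = 0.48,
           brainstem = 0.65, hipamy = 0.55))
  fixed_contrast(means)
}

#' Render a random-contrast image from a label map
#'
#' The intensity of every voxel with label `l` is an independent draw from
#' `Normal(mean_l, sd_l)` as given by the contrast sample.  This is the
#' core of the generative model: the rendered image carries no intensity
#' information beyond the label geometry and the sampled contrast.
#'
#' @param label_map a [label_map].
#' @param contrast a `contrast_sample` covering every label present.
#' @return An [mri_image] with the geometry of `label_map`.
#' @export
render_image <- function(label_map, contrast) {
  vox <- label_map$voxels
  present <- sort(unique(as.integer(vox)))
  miss <- setdiff(present, contrast$label)
  if (length(miss))
    stop("contrast sample lacks label(s): ", paste(miss, collapse = ", "))
  out <- array(0, dim(vox))
  for (i in seq_len(nrow(contrast))) {
    idx <- which(vox == contrast$label[i])
    if (length(idx))
      out[idx] <- rnorm(length(idx), contrast$mean[i], contrast$sd[i])
  }
  mri_image(out, label_map$voxel_size)
}

#' Min-max intensity normalization
#'
#' Affinely rescales an image so that its minimum is 0 and its maximum 1,
#' the final step of every generated volume.  Constant images are mapped
#' to all zeros with a warning.
#'
#' @param image an [mri_image] or 3D numeric array.
#' @return Same type as the input, rescaled.
#' @export
normalize_intensity <- function(image) {
  vox <- as_vox_array(image)
  rg <- range(vox)
  if (rg[1] == rg[2]) {
    warning("constant image: normalization returns all zeros")
    vox[] <- 0
  } else {
    vox <- (vox - rg[1]) / (rg[2] - rg[1])
  }
  if (inherits(image, "mri_image")) mri_image(vox, image$voxel_size) else vox
}

#' Serialize a contrast sample to a plain-text key-value config
#'
#' @param contrast a `contrast_sample`.
#' @param path output file; when `NULL` the lines are returned.
#' @return The text lines, invisibly when written.
#' @export
write_contrast <- function(contrast, path = NULL) {
  lines <- sprintf("label_%d = mean %.17g sd %.17g",
                   contrast$label, contrast$mean, contrast$sd)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
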