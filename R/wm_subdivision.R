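#' Subdivide white matter into intensity-derived sub-labels
#'
#' Fits a one-dimensional Gaussian mixture with `n_clusters` components to
#' the intensities within the WM mask by expectation-maximization and
#' assigns every WM voxel to its maximum-responsibility component.  Each
#' sub-region is then treated as a distinct tissue by the generative model
#' (emulating maturation-related WM inhomogeneity), while the grouping maps
#' all sub-labels back to WM for the segmentation objective.
#'
#' EM is initialized by k-means started from intensity quantiles and
#' stops when the relative log-likelihood change falls below `tol` or
#' after `max_iter` iterations; responsibility ties break toward the
#' lower-mean component.  Deterministic for fixed inputs.
#'
#' @param label_map a [label_map] containing WM.
#' @param intensity an [mri_image] on the same grid (the reference, e.g.
#'   T2-weighted, volume whose WM intensities are clustered).
#' @param n_clusters number of sub-regions, in `1..6`; 1 returns the input
#'   unchanged.  If the WM has fewer distinct intensities the number is
#'   reduced with a warning.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @return Object of class `wm_subdivision`: list with `relabeled` (the
#'   [label_map] with WM replaced by sub-labels `wm1..wmN`), `grouping`
#'   (named integer vector mapping every generation label id to its
#'   target class id), `n_clusters`, and the EM fit (`means`, `sds`,
#'   `weights`, `loglik_trace`).
#' @export
subdivide_wm <- function(label_map, intensity, n_clusters, tol = 1e-6,
                         max_iter = 200) {
  stopifnot(inherits(label_map, "label_map"),
            identical(dim(label_map$voxels), dim(as_vox_array(intensity))))
  n_clusters <- as.integer(n_clusters)
  if (n_clusters < 1 || n_clusters > 6)
    stop("n_clusters must be in 1..6")
  pal <- label_map$palette
  wm_id <- pal[["wm"]]
  wm_idx <- which(label_map$voxels == wm_id)
  if (!length(wm_idx)) stop("label map contains no WM voxels")

  identity_grouping <- setNames(unname(pal), as.character(unname(pal)))
  if (n_clusters == 1)
    return(structure(list(relabeled = label_map,
                          grouping = identity_grouping,
                          n_clusters = 1L, means = NULL, sds = NULL,
                          weights = NULL, loglik_trace = numeric(0)),
                     class = "wm_subdivision"))

  x <- as_vox_array(intensity)[wm_idx]
  ndistinct <- length(unique(x))
  if (ndistinct < n_clusters) {
    warning("only ", ndistinct, " distinct WM intensities; reducing ",
            "n_clusters from ", n_clusters, " to ", ndistinct)
    n_clusters <- ndistinct
  }
  fit <- em_gmm1d(x, n_clusters, tol = tol, max_iter = max_iter)

  sub_ids <- max(pal) + seq_len(n_clusters)
  new_pal <- c(pal, setNames(sub_ids, paste0("wm", seq_len(n_clusters))))
  vox <- label_map$voxels
  vox[wm_idx] <- sub_ids[fit$assignment]
  relabeled <- label_map(vox, label_map$voxel_size, new_pal)

  grouping <- c(identity_grouping,
                setNames(rep(wm_id, n_clusters), as.character(sub_ids)))
  structure(list(relabeled = relabeled, grouping = grouping,
                 n_clusters = n_clusters, means = fit$means,
                 sds = fit$sds, weights = fit$weights,
                 loglik_trace = fit$loglik_trace),
            class = "wm_subdivision")
}

# 1D k-means (Lloyd) from given centers; empty clusters keep their
# centre, so degenerate intensity distributions cannot abort the fit
kmeans1d <- function(x, centers, iter_max = 50) {
  mu <- sort(centers)
  for (i in seq_len(iter_max)) {
    cl <- max.col(-abs(outer(x, mu, "-")), ties.method = "first")
    new_mu <- vapply(seq_along(mu), function(j)
      if (any(cl == j)) mean(x[cl == j]) else mu[j], numeric(1))
    if (max(abs(new_mu - mu)) < 1e-12) break
    mu <- sort(new_mu)
  }
  cl <- max.col(-abs(outer(x, mu, "-")), ties.method = "first")
  list(centers = mu, cluster = cl)
}

# 1D Gaussian mixture by EM; k-means-on-quantiles initialization; ties in
# the hard assignment break toward the lower-mean component.
em_gmm1d <- function(x, k, tol = 1e-6, max_iter = 200, min_sd = 1e-6) {
  n <- length(x)
  q <- quantile(x, probs = (2 * seq_len(k) - 1) / (2 * k), names = FALSE)
  km <- kmeans1d(x, unique(q))
  mu <- km$centers
  k <- length(mu)
  sg <- vapply(seq_len(k), function(j) {
    v <- x[km$cluster == j]
    if (length(v) > 1 && !is.na(sd(v))) max(sd(v), min_sd) else min_sd
  }, numeric(1))
  pw <- pmax(vapply(seq_len(k), function(j) mean(km$cluster == j),
                    numeric(1)), 1 / n)
  pw <- pw / sum(pw)

  loglik <- numeric(0)
  prev <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) pw[j] * dnorm(x, mu[j], sg[j]),
                   numeric(n))
    rowsum_ <- rowSums(dens)
    rowsum_[rowsum_ == 0] <- .Machine$double.xmin
    ll <- sum(log(rowsum_))
    loglik <- c(loglik, ll)
    if (is.finite(prev) && abs(ll - prev) < tol * abs(prev)) break
    prev <- ll
    resp <- dens / rowsum_
    nk <- pmax(colSums(resp), 1e-12)
    pw <- nk / n
    mu <- colSums(resp * x) / nk
    sg <- sqrt(colSums(resp * (x - rep(mu, each = n))^2) / nk)
    sg <- pmax(sg, min_sd)
  }
  ord <- order(mu)
  mu <- mu[ord]; sg <- sg[ord]; pw <- pw[ord]
  dens <- vapply(seq_len(k), function(j) pw[j] * dnorm(x, mu[j], sg[j]),
                 numeric(n))
  # max.col with ties.method "first" picks the lower-mean component
  assignment <- max.col(dens, ties.method = "first")
  list(assignment = assignment, means = mu, sds = sg, weights = pw,
       loglik_trace = loglik)
}

#' Collapse WM sub-labels back to the target classes
#'
#' Applies the grouping of a [subdivide_wm] result to a label map,
#' mapping every WM sub-label to WM and all other labels to themselves.
#' Idempotent.
#'
#' @param prediction a [label_map] (possibly containing sub-labels).
#' @param grouping named integer vector from [subdivide_wm] (names are
#'   generation label ids, values the target class ids).
#' @param palette target palette (default [default_palette]).
#' @return A [label_map] over the target palette.
#' @export
regroup <- function(prediction, grouping, palette = default_palette()) {
  vox <- prediction$voxels
  present <- unique(as.integer(vox))
  unknown <- setdiff(as.character(present), names(grouping))
  if (length(unknown))
    stop("no grouping entry for label(s): ", paste(unknown, collapse = ", "))
  lut <- grouping[as.character(vox)]
  out <- array(as.integer(lut), dim(vox))
  label_map(out, prediction$voxel_size, palette)
}

#' Write the label grouping beside a relabeled map
#'
#' @param subdivision a `wm_subdivision`.
#' @param path output TSV path (columns: generation label id, target class
#'   id, target name).
#' @return `path`, invisibly.
#' @export
write_grouping <- function(subdivision, path) {
  g <- subdivision$grouping
  pal <- default_palette()
  tgt_name <- names(pal)[match(unname(g), pal)]
  df <- data.frame(generation_label = names(g), target_label = unname(g),
                   target_name = tgt_name)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
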