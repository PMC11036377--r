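#' Binary dice similarity
#'
#' `2 |X ∩ Y| / (|X| + |Y|)` for two binary masks on the same grid.
#' Both masks empty gives 1 by convention; exactly one empty gives 0.
#'
#' @param pred_mask,gt_mask logical arrays of identical dimension.
#' @return Dice similarity in `[0, 1]`.
#' @export
dice_score <- function(pred_mask, gt_mask) {
  if (!identical(dim(pred_mask), dim(gt_mask)))
    stop("masks must share the same grid")
  sx <- sum(pred_mask); sy <- sum(gt_mask)
  if (sx + sy == 0) return(1)
  2 * sum(pred_mask & gt_mask) / (sx + sy)
}

#' Merge CSF and ventricles for evaluation
#'
#' The delineation between CSF and ventricles is tedious and their
#' intensity distributions similar, so the two labels are collapsed into
#' a single class for evaluation only.  Idempotent; all other labels are
#' untouched.
#'
#' @param map a [label_map].
#' @return The merged [label_map] (ventricle voxels relabelled as CSF).
#' @export
merge_for_eval <- function(map) {
  vox <- map$voxels
  vox[vox == map$palette[["ventricles"]]] <- map$palette[["csf"]]
  out <- label_map(vox, map$voxel_size, map$palette)
  attr(out, "eval_merge") <- c("csf", "ventricles")
  out
}

#' Symmetric average surface distance
#'
#' Boundary voxels are mask voxels with an exposed 6-connectivity face
#' (array borders count as exposed).  The distance of every boundary
#' voxel of each mask to the nearest boundary voxel of the other mask is
#' computed with an exact anisotropic Euclidean distance transform, and
#' the pooled mean over both boundary sets is returned, in mm.
#'
#' @param pred_mask,gt_mask non-empty logical arrays on the same grid.
#' @param voxel_size mm per voxel (length 1 or 3).
#' @return Average surface distance in mm; `NA` with a warning if either
#'   mask is empty.
#' @export
average_surface_distance <- function(pred_mask, gt_mask, voxel_size = 1) {
  if (!identical(dim(pred_mask), dim(gt_mask)))
    stop("masks must share the same grid")
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  if (!any(pred_mask) || !any(gt_mask)) {
    warning("empty mask: average surface distance is undefined")
    return(NA_real_)
  }
  ba <- boundary_voxels(pred_mask)
  bb <- boundary_voxels(gt_mask)
  da <- edt_cpp(bb, voxel_size)[ba]   # pred boundary -> gt boundary
  db <- edt_cpp(ba, voxel_size)[bb]
  (sum(da) + sum(db)) / (length(da) + length(db))
}

#' Pearson correlation and slope between paired volume estimates
#'
#' Used to quantify the consistency of per-subject structure volumes
#' estimated from two image contrasts of the same subjects.
#'
#' @param volumes_a,volumes_b paired numeric vectors (>= 3 subjects).
#' @return List with `pearson_r` and `slope` (least-squares slope of
#'   `volumes_b` on `volumes_a`); both `NA` with a warning when a vector
#'   has zero variance.
#' @export
volume_correlation <- function(volumes_a, volumes_b) {
  stopifnot(length(volumes_a) == length(volumes_b))
  if (length(volumes_a) < 3)
    stop("at least 3 paired subjects are required")
  if (sd(volumes_a) == 0 || sd(volumes_b) == 0) {
    warning("zero variance: correlation is undefined")
    return(list(pearson_r = NA_real_, slope = NA_real_))
  }
  list(pearson_r = cor(volumes_a, volumes_b),
       slope = unname(coef(lm(volumes_b ~ volumes_a))[2]))
}

#' Age-binned summaries of structure-averaged dice
#'
#' Averages the dice over structures within each subject x model, then
#' summarizes per age bin.  Bins are closed on the left; the last bin is
#' closed on both ends.  Records outside the binned range are excluded
#' with a warning.
#'
#' @param records data frame with columns `subject`, `model`, `dice`,
#'   `age` (weeks), one row per subject x model x structure.
#' @param bin_edges increasing numeric bin edges (default
#'   `c(26, 32, 36, 40, 45)` weeks).
#' @return data frame with one row per model x bin: `n`, `mean_dice`,
#'   `q25`, `median`, `q75`.
#' @export
age_binned_summary <- function(records,
                               bin_edges = c(26, 32, 36, 40, 45)) {
  per <- aggregate(dice ~ subject + model + age, data = records, FUN = mean)
  out_of_range <- per$age < bin_edges[1] | per$age > tail(bin_edges, 1)
  if (any(out_of_range)) {
    warning(sum(out_of_range), " record(s) outside the age range ",
            "excluded")
    per <- per[!out_of_range, , drop = FALSE]
  }
  nb <- length(bin_edges) - 1
  bin <- findInterval(per$age, bin_edges, rightmost.closed = TRUE)
  res <- do.call(rbind, lapply(split(per, list(per$model, bin, drop = TRUE)),
    function(g) {
      b <- findInterval(g$age[1], bin_edges, rightmost.closed = TRUE)
      q <- quantile(g$dice, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(model = g$model[1],
                 bin = sprintf("[%g,%g%s", bin_edges[b], bin_edges[b + 1],
                               if (b == nb) "]" else ")"),
                 n = nrow(g), mean_dice = mean(g$dice),
                 q25 = q[1], median = q[2], q75 = q[3])
    }))
  rownames(res) <- NULL
  res[order(res$model, res$bin), ]
}

#' Flag outlier subjects by structure-averaged dice
#'
#' Subjects whose structure-averaged dice deviates from the cohort mean
#' by more than `k` standard deviations.
#'
#' @param records data frame as in [age_binned_summary] (>= 5 records).
#' @param k deviation threshold in standard deviations (default 3).
#' @return Character vector of flagged subject ids.
#' @export
flag_outliers <- function(records, k = 3) {
  if (nrow(records) < 5) stop("at least 5 records are required")
  per <- aggregate(dice ~ subject, data = records, FUN = mean)
  s <- sd(per$dice)
  if (is.na(s) || s == 0) return(character(0))
  m <- mean(per$dice)
  as.character(per$subject[abs(per$dice - m) > k * s])
}

#' Between-model consistency dice
#'
#' Dice between the predictions of two models for one structure; no
#' ground truth is involved.  Symmetric in its arguments.
#'
#' @param pred_model1,pred_model2 [label_map] predictions on the same
#'   grid.
#' @param structure structure name (in the palette).
#' @return Dice similarity in `[0, 1]`.
#' @export
consistency_dice <- function(pred_model1, pred_model2, structure) {
  dice_score(label_mask(pred_model1, structure),
             label_mask(pred_model2, structure))
}

#' Evaluate a prediction against a ground truth
#'
#' Builds one evaluation record per structure: binary dice, symmetric
#' average surface distance (mm) and predicted volume (mm^3).  CSF and
#' ventricles are merged beforehand (see [merge_for_eval]).
#'
#' @param pred,gt [label_map]s on the same grid.
#' @param subject,model identifiers stored in the records.
#' @param age age in weeks (phantoms: pseudo-age from folding).
#' @param structures structure names to evaluate (default: all brain
#'   structures after merging, plus head).
#' @param asd also compute the average surface distance (slower).
#' @return data frame with columns `subject`, `model`, `structure`,
#'   `dice`, `asd`, `volume`, `age`.
#' @export
evaluate_prediction <- function(pred, gt, subject = "s1", model = "model",
                                age = NA_real_,
                                structures = c("csf", "gm", "wm",
                                               "deepgm", "cerebellum",
                                               "brainstem", "hipamy",
                                               "head"),
                                asd = FALSE) {
  predm <- merge_for_eval(pred)
  gtm <- merge_for_eval(gt)
  vv <- prod(predm$voxel_size)
  do.call(rbind, lapply(structures, function(st) {
    pm <- label_mask(predm, st)
    gm <- label_mask(gtm, st)
    data.frame(subject = subject, model = model, structure = st,
               dice = dice_score(pm, gm),
               asd = if (asd && any(pm) && any(gm))
                 average_surface_distance(pm, gm, predm$voxel_size)
               else NA_real_,
               volume = sum(pm) * vv, age = age)
  }))
}
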