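#' Generative model recipes
#'
#' Configures one of the five training-set generation recipes:
#' * `Synth` — random per-tissue Gaussian contrast, affine + elastic
#'   shape augmentation, polynomial bias field and Gaussian noise.
#' * `SynthMot` — `Synth` enriched with k-space motion simulation,
#'   applied with probability 0.5.
#' * `SynthInh` — `Synth` with the WM label subdivided into
#'   intensity-derived sub-labels (probability 0.5) to emulate WM
#'   inhomogeneity.
#' * `SynthMotInh` — both enrichments, each with probability 0.5.
#' * `DataT2` — baseline trained on the subjects' real (reference)
#'   images with the same augmentations except random contrast and
#'   motion, plus a random gamma perturbation.
#'
#' @param name recipe name.
#' @param p_motion,p_inh probability gates (defaults set by `name`).
#' @param inh_clusters candidate numbers of WM sub-regions; one value is
#'   drawn per sample when the subdivision gate fires.
#' @param motion_segments number of k-space segments for the motion
#'   transform (`NULL`: one per phase-encode line).
#' @param max_log_gamma gamma-perturbation range (DataT2 only).
#' @return Object of class `recipe_config`.
#' @export
recipe_config <- function(name = c("Synth", "SynthMot", "SynthInh",
                                   "SynthMotInh", "DataT2"),
                          p_motion = NULL, p_inh = NULL,
                          inh_clusters = 2:6, motion_segments = NULL,
                          max_log_gamma = 0.3) {
  name <- match.arg(name)
  defaults <- list(
    Synth       = list(p_motion = 0,   p_inh = 0),
    SynthMot    = list(p_motion = 0.5, p_inh = 0),
    SynthInh    = list(p_motion = 0,   p_inh = 0.5),
    SynthMotInh = list(p_motion = 0.5, p_inh = 0.5),
    DataT2      = list(p_motion = 0,   p_inh = 0))[[name]]
  structure(list(name = name,
                 random_contrast = name != "DataT2",
                 gamma = name == "DataT2",
                 p_motion = p_motion %||% defaults$p_motion,
                 p_inh = p_inh %||% defaults$p_inh,
                 inh_clusters = as.integer(inh_clusters),
                 motion_segments = motion_segments,
                 max_log_gamma = max_log_gamma),
            class = "recipe_config")
}

# Draw the per-sample plan: gate outcomes and transform parameters.
# Shares the RNG stream with the executing code so a plan drawn here is
# exactly the one generate_training_sample() executes.
draw_plan <- function(recipe) {
  plan <- list(recipe = recipe$name)
  plan$inh_fired <- recipe$p_inh > 0 && runif(1) < recipe$p_inh
  if (plan$inh_fired)
    plan$inh_clusters <- recipe$inh_clusters[
      sample.int(length(recipe$inh_clusters), 1)]
  plan$affine <- sample_affine()
  plan$elastic <- sample_elastic()
  plan$bias <- sample_bias_field()
  plan$noise <- sample_noise()
  plan$motion_fired <- recipe$p_motion > 0 && runif(1) < recipe$p_motion
  if (plan$motion_fired) plan$motion <- sample_motion_params()
  if (recipe$gamma) plan$log_gamma <- sample_log_gamma(recipe$max_log_gamma)
  plan
}

#' Sample the probability gates of a recipe
#'
#' Draws `n` per-sample plans (the same code path used by
#' [generate_training_sample]) and reports which probability gates fired.
#' Cheap: no volume is rendered.
#'
#' @param recipe a [recipe_config].
#' @param n number of draws.
#' @return data frame with logical columns `motion_fired`, `inh_fired`.
#' @export
sample_gates <- function(recipe, n) {
  res <- lapply(seq_len(n), function(i) {
    p <- draw_plan(recipe)
    data.frame(motion_fired = p$motion_fired, inh_fired = p$inh_fired)
  })
  do.call(rbind, res)
}

#' Generate one training sample from a recipe
#'
#' Executes the generative chain in its documented order: (optional) WM
#' subdivision of the label map, spatial augmentation (affine then
#' elastic, nearest-neighbour on labels), random-contrast rendering (or
#' the subject's real image, resampled with the same deformations, for
#' `DataT2`), bias field, noise, (optional) k-space motion with the
#' background forced to zero, gamma (DataT2), and final min-max
#' normalization.  The returned provenance records every transform, its
#' parameters and whether the probability gates fired; together with
#' `seed` it makes the sample exactly regenerable.
#'
#' @param recipe a [recipe_config].
#' @param subject a subject as built by [make_phantom_cohort]: list with
#'   `labels` (a [label_map]), optionally `image` (reference
#'   [mri_image], required for `DataT2` and WM subdivision) and `id`.
#' @param seed optional integer; when `NULL` a seed is drawn from the
#'   session RNG and recorded.
#' @return List with `image` (normalized [mri_image]), `labels` (the
#'   deformed target [label_map], sub-labels regrouped), and
#'   `provenance`.
#' @export
generate_training_sample <- function(recipe, subject, seed = NULL) {
  if (is.null(seed))
    seed <- sample.int(.Machine$integer.max, 1)
  needs_image <- recipe$name == "DataT2" || recipe$p_inh > 0
  if (needs_image && is.null(subject$image))
    stop("recipe ", recipe$name, " requires a subject intensity volume")
  with_seed(seed, {
    plan <- draw_plan(recipe)
    labels_gen <- subject$labels
    grouping <- NULL
    if (plan$inh_fired) {
      sub <- subject_subdivision(subject, plan$inh_clusters)
      labels_gen <- sub$relabeled
      grouping <- sub$grouping
    }
    labels_def <- apply_elastic(apply_affine(labels_gen, plan$affine),
                                plan$elastic)
    target <- if (is.null(grouping)) labels_def
              else regroup(labels_def, grouping,
                           palette = subject$labels$palette)
    if (recipe$random_contrast) {
      contrast <- sample_contrast(labels_def)
      plan$contrast <- contrast
      img <- render_image(labels_def, contrast)
    } else {
      img <- apply_elastic(apply_affine(subject$image, plan$affine,
                                        "linear"),
                           plan$elastic, "linear")
    }
    img <- apply_bias(img, plan$bias)
    img <- apply_noise(img, plan$noise)
    if (plan$motion_fired) {
      bg <- label_mask(target, "background")
      traj <- sample_trajectory(plan$motion,
                                recipe$motion_segments %||%
                                  dim(img$voxels)[2])
      plan$trajectory <- traj
      img <- apply_motion(img, traj, background_mask = bg)
    }
    if (recipe$gamma)
      img <- apply_gamma(normalize_intensity(img), plan$log_gamma)
    img <- normalize_intensity(img)
    plan$seed <- seed
    plan$subject <- subject$id %||% NA_character_
    list(image = img, labels = target, provenance = plan)
  })
}

# per-subject cache of WM subdivisions (a fixed modification of the
# input labels, computed once per subject and cluster count)
subject_subdivision <- function(subject, n_clusters) {
  key <- as.character(n_clusters)
  env <- subject$cache_env
  if (!is.null(env) && !is.null(env[[key]])) return(env[[key]])
  sub <- subdivide_wm(subject$labels, subject$image, n_clusters)
  if (!is.null(env)) env[[key]] <- sub
  sub
}

#' Write a provenance sidecar
#'
#' Serializes a provenance record to a plain-text key-value file from
#' which, together with the package version, the sample is exactly
#' regenerable (it contains the recipe, the seed and every parameter).
#'
#' @param provenance provenance list from [generate_training_sample].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(provenance, path) {
  fmt <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  lines <- c(
    paste0("recipe = ", provenance$recipe),
    paste0("seed = ", provenance$seed),
    paste0("subject = ", provenance$subject),
    paste0("inh_fired = ", provenance$inh_fired),
    if (isTRUE(provenance$inh_fired))
      paste0("inh_clusters = ", provenance$inh_clusters),
    paste0("affine_scale = ", fmt(provenance$affine$scale)),
    paste0("affine_rotation_deg = ", fmt(provenance$affine$rotation)),
    paste0("affine_translation_mm = ", fmt(provenance$affine$translation)),
    paste0("elastic_control_points = ", provenance$elastic$control_points),
    paste0("elastic_max_displacement_mm = ",
           provenance$elastic$max_displacement),
    paste0("bias_coefficients = ", fmt(provenance$bias$coefficients)),
    paste0("noise_std = ", fmt(provenance$noise$std)),
    paste0("motion_fired = ", provenance$motion_fired),
    if (isTRUE(provenance$motion_fired)) c(
      paste0("motion_max_translation_mm = ",
             fmt(provenance$motion$max_translation)),
      paste0("motion_max_rotation_deg = ",
             fmt(provenance$motion$max_rotation)),
      paste0("motion_event_segment = ", provenance$trajectory$event),
      paste0("motion_ramp_segments = ", provenance$trajectory$ramp)),
    if (!is.null(provenance$log_gamma))
      paste0("log_gamma = ", fmt(provenance$log_gamma)),
    if (!is.null(provenance$contrast))
      write_contrast(provenance$contrast))
  writeLines(lines, path)
  invisible(path)
}

#' Build a cohort of phantom subjects
#'
#' Generates `n` seeded phantoms with folding values on a uniform grid
#' over `folding_range` (emulating subjects uniformly distributed across
#' the age range).  Each subject carries its tight (surface-derived)
#' ground truth, optionally the large (biased) variant calibrated to the
#' target GM volume ratio, and a reference image rendered with the
#' canonical T2-like contrast plus mild noise.
#'
#' @param n number of subjects.
#' @param grid_shape,voxel_size,cortical_thickness passed to
#'   [phantom_spec].
#' @param folding_range folding interval covered by the cohort.
#' @param seed_base subject `i` uses phantom seed `seed_base + i`.
#' @param gt_variants also build the calibrated large-GM ground truth
#'   (slower).
#' @param target_ratio GM volume ratio for the large variant.
#' @param reference_noise_sd noise added to the reference rendering.
#' @return List of subjects: `id`, `labels` (tight GT), `labels_large`
#'   (if requested), `surfaces`, `image`, `age`, `folding`.
#' @export
make_phantom_cohort <- function(n, grid_shape = 64, voxel_size = 1,
                                cortical_thickness = 3,
                                folding_range = c(0.1, 0.9),
                                seed_base = 0, gt_variants = FALSE,
                                target_ratio = 1.25,
                                reference_noise_sd = 0.01) {
  foldings <- if (n == 1) mean(folding_range)
              else seq(folding_range[1], folding_range[2], length.out = n)
  lapply(seq_len(n), function(i) {
    sp <- phantom_spec(grid_shape = grid_shape, voxel_size = voxel_size,
                       folding = foldings[i],
                       cortical_thickness = cortical_thickness,
                       seed = seed_base + i)
    ph <- make_phantom(sp)
    pv <- partial_volume_gm(ph$surfaces)
    tight <- binarize_and_fuse(ph$labels, pv)
    labels_large <- NULL
    if (gt_variants) {
      b <- calibrate_gt_bias(ph$labels, ph$surfaces,
                             target_ratio = target_ratio)
      labels_large <- make_gt_variants(ph$labels, ph$surfaces, b)$large
    }
    img <- with_seed(seed_base + i + 500000L, {
      r <- render_image(tight, canonical_contrast("t2"))
      r <- apply_noise(r, structure(list(mean = 0,
                                         std = reference_noise_sd),
                                    class = "noise_params"))
      normalize_intensity(r)
    })
    subj <- list(id = sprintf("phantom%03d", seed_base + i),
                 labels = tight, labels_large = labels_large,
                 surfaces = ph$surfaces, image = img,
                 age = ph$age_weeks, folding = foldings[i],
                 cache_env = new.env(parent = emptyenv()))
    subj
  })
}
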