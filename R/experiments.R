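#' Default desk-scale experiment configuration
#'
#' Settings for the toy replications of the three experiments
#' (synthesis-vs-real training, contrast robustness, ground-truth bias)
#' on phantom cohorts.  Any element can be overridden through the
#' `config` argument of [run_experiment].
#'
#' @param seed master seed; all phantom, training and rendering seeds are
#'   derived from it, with disjoint train/test phantom seed ranges.
#' @return Named list of settings.
#' @export
experiment_defaults <- function(seed = 1) {
  list(
    seed = seed,
    n_train = 3, n_test = 4,
    grid_shape = 32, voxel_size = 1, cortical_thickness = 2,
    folding_range = c(0.1, 0.9),
    recipes = c("Synth", "DataT2"),
    unet_cfg = unet_config(levels = 3, convs_per_level = 1,
                           base_features = 8, dropout = 0,
                           bn_eval = "input"),
    train_cfg = train_config(patch_size = 24, patches_per_volume = 2,
                             batch_size = 2, learning_rate = 3e-3,
                             max_iterations = 400, seed = seed),
    contrasts = list(seen = canonical_contrast("t2"),
                     unseen = canonical_contrast("t1")),
    target_ratio = 1.25,
    asd = FALSE,
    out_dir = NULL)
}

merge_config <- function(config, seed = 1) {
  def <- experiment_defaults(seed)
  for (nm in names(config)) def[[nm]] <- config[[nm]]
  def
}

train_seed_base <- function(cfg) cfg$seed * 10000L
test_seed_base <- function(cfg) cfg$seed * 10000L + 5000L

assert_disjoint_seeds <- function(cfg) {
  tr <- train_seed_base(cfg) + seq_len(cfg$n_train)
  te <- test_seed_base(cfg) + seq_len(cfg$n_test)
  if (length(intersect(tr, te)))
    stop("train and test phantom seeds overlap")
  invisible(TRUE)
}

#' Train the recipe models for an experiment
#'
#' @param cfg merged experiment configuration (see
#'   [experiment_defaults]).
#' @param subjects training subjects.
#' @param gt `"tight"` or `"large"` — which ground-truth variant the
#'   models are trained on.
#' @return Named list of [train_unet] fits, one per recipe.
#' @export
train_recipe_models <- function(cfg, subjects, gt = "tight") {
  if (gt == "large")
    subjects <- lapply(subjects, function(s) {
      if (is.null(s$labels_large))
        stop("subjects lack the large ground-truth variant")
      s$labels <- s$labels_large
      s$cache_env <- new.env(parent = emptyenv())
      s
    })
  fits <- lapply(seq_along(cfg$recipes), function(i) {
    tc <- cfg$train_cfg
    # matched seeds across ground-truth variants: the tight- and
    # large-trained member of a pair see identical augmentation and
    # contrast streams and differ only in their target labels, so the
    # ground-truth effect is isolated from training stochasticity
    tc$seed <- tc$seed + 100L * i
    train_unet(recipe_config(cfg$recipes[i]), subjects, cfg$unet_cfg, tc)
  })
  names(fits) <- cfg$recipes
  fits
}

render_test_image <- function(subject, contrast, seed) {
  with_seed(seed, {
    img <- render_image(subject$labels, contrast)
    img <- apply_noise(img, structure(list(mean = 0, std = 0.01),
                                      class = "noise_params"))
    normalize_intensity(img)
  })
}

#' Run a desk-scale experiment on phantoms
#'
#' Toy replications of the three study designs:
#' * `1` — train every recipe on the tight ground truth and evaluate on
#'   the test subjects' reference (T2-like) renderings: per-model,
#'   per-structure dice records and age-binned summaries.
#' * `2` — evaluate the same trained models on two different contrast
#'   renderings (`contrasts$seen`, `contrasts$unseen`) of the same test
#'   subjects: per-model dice on both renderings, the per-model mean-dice
#'   gap, and the cross-contrast Pearson correlation of predicted GM
#'   volumes.
#' * `3` — train the recipes on paired tight/large ground truths and
#'   compare: per-model dice against its own ground truth, the GM
#'   consistency dice between the tight- and large-trained predictions
#'   of each recipe, and the inter-ground-truth GM dice.
#'
#' @param exp_id 1, 2 or 3.
#' @param config list of overrides of [experiment_defaults].
#' @param models optional pre-trained models: for experiments 1 and 2 a
#'   named list of fits (as from [train_recipe_models]); for experiment 3
#'   a list with elements `tight` and `large`, each such a named list.
#' @param seed master seed used when `config$seed` is absent.
#' @return Object of class `neosynth_experiment`: list with `records`
#'   and experiment-specific summaries; written as CSV when
#'   `config$out_dir` is set.
#' @export
run_experiment <- function(exp_id, config = list(), models = NULL,
                           seed = 1) {
  stopifnot(exp_id %in% 1:3)
  cfg <- merge_config(config, seed = config$seed %||% seed)
  assert_disjoint_seeds(cfg)
  need_large <- exp_id == 3
  train_subj <- make_phantom_cohort(
    cfg$n_train, grid_shape = cfg$grid_shape, voxel_size = cfg$voxel_size,
    cortical_thickness = cfg$cortical_thickness,
    folding_range = cfg$folding_range, seed_base = train_seed_base(cfg),
    gt_variants = need_large, target_ratio = cfg$target_ratio)
  test_subj <- make_phantom_cohort(
    cfg$n_test, grid_shape = cfg$grid_shape, voxel_size = cfg$voxel_size,
    cortical_thickness = cfg$cortical_thickness,
    folding_range = cfg$folding_range, seed_base = test_seed_base(cfg),
    gt_variants = need_large, target_ratio = cfg$target_ratio)

  out <- switch(as.character(exp_id),
    "1" = run_exp1(cfg, train_subj, test_subj, models),
    "2" = run_exp2(cfg, train_subj, test_subj, models),
    "3" = run_exp3(cfg, train_subj, test_subj, models))
  out$exp_id <- exp_id
  out$config <- cfg
  class(out) <- "neosynth_experiment"
  if (!is.null(cfg$out_dir)) write_experiment(out, cfg$out_dir)
  out
}

run_exp1 <- function(cfg, train_subj, test_subj, models) {
  fits <- models %||% train_recipe_models(cfg, train_subj)
  records <- do.call(rbind, lapply(names(fits), function(m) {
    do.call(rbind, lapply(test_subj, function(s) {
      pred <- predict_volume(fits[[m]], s$image)
      evaluate_prediction(pred, s$labels, subject = s$id, model = m,
                          age = s$age, asd = cfg$asd)
    }))
  }))
  summary <- aggregate(dice ~ model + structure, records, mean)
  list(records = records, summary = summary,
       age_summary = age_binned_summary(records), models = fits)
}

run_exp2 <- function(cfg, train_subj, test_subj, models) {
  fits <- models %||% train_recipe_models(cfg, train_subj)
  records <- do.call(rbind, lapply(names(fits), function(m) {
    do.call(rbind, lapply(seq_along(test_subj), function(i) {
      s <- test_subj[[i]]
      rseed <- test_seed_base(cfg) + 900000L + i
      do.call(rbind, lapply(names(cfg$contrasts), function(ct) {
        img <- render_test_image(s, cfg$contrasts[[ct]], rseed)
        pred <- predict_volume(fits[[m]], img)
        rec <- evaluate_prediction(pred, s$labels, subject = s$id,
                                   model = m, age = s$age, asd = cfg$asd)
        rec$contrast <- ct
        rec
      }))
    }))
  }))
  per <- aggregate(dice ~ model + contrast, records, mean)
  gaps <- vapply(unique(per$model), function(m) {
    d <- per$dice[per$model == m]
    abs(diff(d))
  }, numeric(1))
  vol_cor <- lapply(setNames(nm = unique(records$model)), function(m) {
    g <- records[records$model == m & records$structure == "gm", ]
    va <- g$volume[g$contrast == names(cfg$contrasts)[1]]
    vb <- g$volume[g$contrast == names(cfg$contrasts)[2]]
    if (length(va) < 3 || sd(va) == 0 || sd(vb) == 0)
      list(pearson_r = NA_real_, slope = NA_real_)
    else volume_correlation(va, vb)
  })
  list(records = records, summary = per, dice_gap = gaps,
       gm_volume_correlation = vol_cor, models = fits)
}

run_exp3 <- function(cfg, train_subj, test_subj, models) {
  fits <- models %||% list(tight = train_recipe_models(cfg, train_subj,
                                                       "tight"),
                           large = train_recipe_models(cfg, train_subj,
                                                       "large"))
  inter_gt <- vapply(test_subj, function(s)
    consistency_dice(s$labels, s$labels_large, "gm"), numeric(1))
  rows <- list(); records <- list()
  for (m in cfg$recipes) {
    cons <- numeric(length(test_subj))
    for (i in seq_along(test_subj)) {
      s <- test_subj[[i]]
      pt <- predict_volume(fits$tight[[m]], s$image)
      pl <- predict_volume(fits$large[[m]], s$image)
      cons[i] <- consistency_dice(pt, pl, "gm")
      records[[length(records) + 1]] <- rbind(
        evaluate_prediction(pt, s$labels, s$id, paste0(m, "_tight"),
                            s$age, asd = cfg$asd),
        evaluate_prediction(pl, s$labels_large, s$id, paste0(m, "_large"),
                            s$age, asd = cfg$asd))
    }
    rows[[m]] <- data.frame(model = m, consistency_gm = mean(cons))
  }
  records <- do.call(rbind, records)
  own_gt <- aggregate(dice ~ model, records[records$structure == "gm", ],
                      mean)
  list(records = records,
       consistency = do.call(rbind, rows),
       inter_gt_gm_dice = mean(inter_gt),
       own_gt_gm_dice = own_gt, models = fits)
}

write_experiment <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(out$records,
            file.path(dir, sprintf("exp%d_records.csv", out$exp_id)),
            row.names = FALSE)
  for (nm in c("summary", "age_summary", "consistency", "own_gt_gm_dice"))
    if (!is.null(out[[nm]]) && is.data.frame(out[[nm]]))
      write.csv(out[[nm]],
                file.path(dir, sprintf("exp%d_%s.csv", out$exp_id, nm)),
                row.names = FALSE)
  md <- file.path(dir, sprintf("exp%d_summary.md", out$exp_id))
  con <- file(md, "w")
  writeLines(sprintf("# Experiment %d summary\n", out$exp_id), con)
  writeLines(utils::capture.output(print(out)), con)
  close(con)
  invisible(dir)
}

#' @export
print.neosynth_experiment <- function(x, ...) {
  cat("<neosynth_experiment> experiment #", x$exp_id, "\n", sep = "")
  if (!is.null(x$summary)) {
    cat("mean dice:\n")
    print(x$summary, row.names = FALSE)
  }
  if (!is.null(x$dice_gap)) {
    cat("mean-dice gap between contrasts:\n")
    print(round(x$dice_gap, 4))
  }
  if (!is.null(x$consistency)) {
    cat("GM consistency dice between tight/large-trained models:\n")
    print(x$consistency, row.names = FALSE)
    cat("inter-ground-truth GM dice: ",
        round(x$inter_gt_gm_dice, 4), "\n", sep = "")
  }
  invisible(x)
}
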