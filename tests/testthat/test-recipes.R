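test_that("recipe defaults encode the five model definitions", {
  expect_equal(recipe_config("Synth")$p_motion, 0)
  expect_equal(recipe_config("SynthMot")$p_motion, 0.5)
  expect_equal(recipe_config("SynthInh")$p_inh, 0.5)
  r <- recipe_config("SynthMotInh")
  expect_equal(c(r$p_motion, r$p_inh), c(0.5, 0.5))
  d <- recipe_config("DataT2")
  expect_false(d$random_contrast)
  expect_true(d$gamma)
  expect_equal(d$p_motion, 0)
})

test_that("probability gates fire at the configured rate", {
  gates <- withr::with_seed(1,
    sample_gates(recipe_config("SynthMotInh"), 2000))
  expect_lt(abs(mean(gates$motion_fired) - 0.5),
            3 * sqrt(0.25 / 2000))
  expect_lt(abs(mean(gates$inh_fired) - 0.5), 3 * sqrt(0.25 / 2000))
  expect_true(all(!withr::with_seed(2, sample_gates(
    recipe_config("Synth"), 100))$motion_fired))
})

test_that("generation is exactly regenerable from its seed", {
  subj <- make_phantom_cohort(1, grid_shape = 32, cortical_thickness = 2,
                              seed_base = 40)[[1]]
  s1 <- generate_training_sample(recipe_config("SynthMot"), subj,
                                 seed = 123)
  s2 <- generate_training_sample(recipe_config("SynthMot"), subj,
                                 seed = 123)
  expect_identical(s1$image$voxels, s2$image$voxels)
  expect_identical(s1$labels$voxels, s2$labels$voxels)
  expect_identical(s1$provenance, s2$provenance)
})

test_that("the generative chain reduces to its documented transform order", {
  subj <- make_phantom_cohort(1, grid_shape = 32, cortical_thickness = 2,
                              seed_base = 41)[[1]]
  rc <- recipe_config("Synth")
  seed <- 77
  s <- generate_training_sample(rc, subj, seed = seed)
  # replay the chain by hand from the recorded plan
  draw_plan <- getFromNamespace("draw_plan", "neosynth")
  with_seed <- getFromNamespace("with_seed", "neosynth")
  manual <- with_seed(seed, {
    plan <- draw_plan(rc)
    labels <- apply_elastic(apply_affine(subj$labels, plan$affine),
                            plan$elastic)
    contrast <- sample_contrast(labels)
    img <- render_image(labels, contrast)
    img <- apply_bias(img, plan$bias)
    img <- apply_noise(img, plan$noise)
    list(img = normalize_intensity(img), labels = labels)
  })
  expect_identical(s$image$voxels, manual$img$voxels)
  expect_identical(s$labels$voxels, manual$labels$voxels)
  expect_equal(range(s$image$voxels), c(0, 1))
})

test_that("WM subdivision only alters the generation labels, not the target", {
  subj <- make_phantom_cohort(1, grid_shape = 32, cortical_thickness = 2,
                              seed_base = 42)[[1]]
  rc <- recipe_config("SynthInh", p_inh = 1)   # force the gate
  s <- generate_training_sample(rc, subj, seed = 5)
  expect_true(s$provenance$inh_fired)
  # target labels stay within the base palette
  expect_true(all(unique(as.integer(s$labels$voxels)) %in%
                    unname(default_palette())))
})

test_that("DataT2 requires a subject image and skips synthesis transforms", {
  subj <- make_phantom_cohort(1, grid_shape = 32, cortical_thickness = 2,
                              seed_base = 43)[[1]]
  noimg <- subj; noimg$image <- NULL
  expect_error(generate_training_sample(recipe_config("DataT2"), noimg),
               "intensity volume")
  s <- generate_training_sample(recipe_config("DataT2"), subj, seed = 3)
  expect_null(s$provenance$contrast)
  expect_false(s$provenance$motion_fired)
  expect_true(is.numeric(s$provenance$log_gamma))
})

test_that("provenance sidecars list every transform of the sample", {
  subj <- make_phantom_cohort(1, grid_shape = 32, cortical_thickness = 2,
                              seed_base = 44)[[1]]
  s <- generate_training_sample(recipe_config("SynthMot", p_motion = 1),
                                subj, seed = 8)
  path <- withr::local_tempfile(fileext = ".txt")
  write_provenance(s$provenance, path)
  txt <- readLines(path)
  for (key in c("recipe = SynthMot", "seed = 8", "motion_fired = TRUE",
                "affine_scale", "elastic_control_points = 12",
                "noise_std", "motion_event_segment"))
    expect_true(any(grepl(key, txt, fixed = TRUE)), info = key)
})

test_that("volumes and provenance survive a NIfTI round trip", {
  subj <- make_phantom_cohort(1, grid_shape = 32, cortical_thickness = 2,
                              seed_base = 45)[[1]]
  dir <- withr::local_tempdir()
  write_volume(subj$labels, file.path(dir, "labels.nii.gz"))
  write_volume(subj$image, file.path(dir, "image.nii.gz"))
  lab <- read_volume(file.path(dir, "labels.nii.gz"), "label")
  img <- read_volume(file.path(dir, "image.nii.gz"))
  expect_identical(lab$voxels, subj$labels$voxels)
  expect_equal(img$voxels, subj$image$voxels, tolerance = 1e-6)
  expect_equal(lab$voxel_size, subj$labels$voxel_size)
  write_volume(subj$surfaces, file.path(dir, "surf.nii.gz"))
  expect_true(file.exists(file.path(dir, "surf_inner.nii.gz")))
})
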