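test_that("smooth phantom GM shell matches the analytic sphere-shell volume", {
  ph <- make_phantom(phantom_spec(grid_shape = 64, voxel_size = 1,
                                  folding = 0, cortical_thickness = 3,
                                  seed = 1))
  vols <- label_volumes(ph$labels)
  H <- 32; r_out <- 0.68 * H; r_in <- r_out - 3
  analytic <- 4 / 3 * pi * (r_out^3 - r_in^3)
  expect_lt(abs(vols[["gm"]] - analytic) / analytic, 0.05)
  # all ten labels present
  expect_true(all(unname(default_palette()) %in%
                    unique(as.integer(ph$labels$voxels))))
})

test_that("phantom generation is bit-identical under a fixed seed", {
  sp <- phantom_spec(grid_shape = 32, folding = 0.6,
                     cortical_thickness = 2, seed = 7)
  a <- make_phantom(sp)
  b <- make_phantom(sp)
  expect_identical(a$labels$voxels, b$labels$voxels)
  expect_identical(a$surfaces$outer_sdf, b$surfaces$outer_sdf)
})

test_that("folding increases the GM/WM interface area", {
  smooth <- make_phantom(phantom_spec(grid_shape = 64, folding = 0,
                                      seed = 1))
  folded <- make_phantom(phantom_spec(grid_shape = 64, folding = 0.8,
                                      seed = 1))
  area <- function(ph) {
    gm <- ph$labels$voxels == ph$labels$palette[["gm"]]
    wm <- ph$labels$voxels == ph$labels$palette[["wm"]]
    dim(gm) <- dim(wm) <- dim(ph$labels$voxels)
    interface_area <- getFromNamespace("interface_area", "neosynth")
    interface_area(gm, wm, ph$labels$voxel_size)
  }
  expect_gt(area(folded), area(smooth))
})

test_that("GM equals the voxelized inter-surface region and surfaces nest", {
  ph <- get_phantom()
  gm <- ph$labels$voxels == ph$labels$palette[["gm"]]
  between <- ph$surfaces$outer_sdf < 0 & ph$surfaces$inner_sdf >= 0
  expect_identical(as.vector(gm), as.vector(between))
  expect_false(any(ph$surfaces$inner_sdf < 0 & ph$surfaces$outer_sdf >= 0))
})

test_that("deep structures are disjoint blobs inside the WM interior", {
  ph <- get_phantom(folding = 0.7, seed = 5)
  pal <- ph$labels$palette
  deep <- c("ventricles", "deepgm", "cerebellum", "brainstem", "hipamy")
  inner <- ph$surfaces$inner_sdf < 0
  for (l in deep) {
    m <- ph$labels$voxels == pal[[l]]
    expect_gt(sum(m), 0)
    expect_true(all(inner[m]))      # confined to the WM interior
  }
  # pairwise disjoint by construction of a label map (one label per voxel)
  counts <- label_volumes(ph$labels, deep)
  expect_true(all(counts > 0))
})

test_that("smooth GM shell is hole-free (exterior flood fill stays out of WM)", {
  ph <- make_phantom(phantom_spec(grid_shape = 48, folding = 0,
                                  cortical_thickness = 2.5, seed = 2))
  vox <- ph$labels$voxels
  pal <- ph$labels$palette
  not_gm <- vox != pal[["gm"]]
  dim(not_gm) <- dim(vox)
  seed_mask <- array(FALSE, dim(vox)); seed_mask[1, 1, 1] <- TRUE
  flood_fill <- getFromNamespace("flood_fill", "neosynth")
  outside <- flood_fill(seed_mask, not_gm)
  wm_interior <- ph$surfaces$inner_sdf < 0
  expect_false(any(outside & wm_interior))
})

test_that("degenerate phantom specs are rejected with diagnostics", {
  expect_error(phantom_spec(grid_shape = 16), "at least 32")
  expect_error(phantom_spec(folding = 1.5), "folding")
  expect_error(phantom_spec(voxel_size = 0), "voxel_size")
  # cortex so thick the deep structures cannot fit
  expect_error(
    make_phantom(phantom_spec(grid_shape = 32, cortical_thickness = 9)),
    "grid too small")
})

test_that("gt variants: zero bias is exact identity and bias is monotone", {
  ph <- get_phantom()
  gv0 <- make_gt_variants(ph$labels, ph$surfaces, 0)
  expect_identical(gv0$tight$voxels, gv0$large$voxels)
  expect_equal(gv0$ratio, 1)
  vols <- vapply(c(0, 0.3, 0.8), function(b)
    label_volumes(make_gt_variants(ph$labels, ph$surfaces, b)$large,
                  "gm"), numeric(1))
  expect_true(all(diff(vols) > 0))
})

test_that("calibrated bias reproduces the target GM volume ratio", {
  ph <- get_phantom()
  b <- calibrate_gt_bias(ph$labels, ph$surfaces, target_ratio = 1.25)
  gv <- make_gt_variants(ph$labels, ph$surfaces, b)
  expect_lt(abs(gv$ratio - 1.25), 0.05)
})

test_that("gt variants keep all non-cortical structures bit-identical", {
  ph <- get_phantom()
  gv <- make_gt_variants(ph$labels, ph$surfaces, 0.5)
  pal <- gv$tight$palette
  for (l in c("ventricles", "deepgm", "cerebellum", "brainstem",
              "hipamy", "head")) {
    mt <- gv$tight$voxels == pal[[l]]
    ml <- gv$large$voxels == pal[[l]]
    expect_equal(dice_score(mt, ml), 1)
  }
})

test_that("excessive bias is rejected when GM would reach the head", {
  ph <- get_phantom()
  expect_error(make_gt_variants(ph$labels, ph$surfaces, 8), "head")
})
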