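test_that("partial volume is 1 strictly between the surfaces, 0 far outside", {
  ph <- get_phantom(folding = 0)
  pv <- partial_volume_gm(ph$surfaces)
  expect_true(all(pv$voxels >= 0 & pv$voxels <= 1))
  deep_inside <- ph$surfaces$outer_sdf < -3 & ph$surfaces$inner_sdf >= 3
  expect_true(all(pv$voxels[deep_inside] == 1))
  outside <- ph$surfaces$outer_sdf > 3
  expect_true(all(pv$voxels[outside] == 0))
})

test_that("an axis-aligned planar boundary through voxel centres gives 1/2", {
  # odd grid: the plane x = 0 passes exactly through the centres of
  # column i = 5
  n <- 9
  co <- seq_len(n) - (n + 1) / 2
  X <- array(co, c(n, n, n))
  sp <- surface_pair(X + 100, X, voxel_size = 1, check = FALSE)
  sp$inner_sdf <- X + 100
  pv <- partial_volume_gm(sp, supersample = 4)
  centre_col <- pv$voxels[5, , ]   # voxel centres exactly on the plane
  expect_true(all(abs(centre_col - 0.5) <= 1 / 4 + 1e-9))
})

test_that("sphere-shell partial volume integrates to the analytic volume", {
  ph <- make_phantom(phantom_spec(grid_shape = 64, folding = 0,
                                  cortical_thickness = 3, seed = 1))
  pv <- partial_volume_gm(ph$surfaces, supersample = 4)
  H <- 32; r_out <- 0.68 * H; r_in <- r_out - 3
  analytic <- 4 / 3 * pi * (r_out^3 - r_in^3)
  expect_lt(abs(sum(pv$voxels) - analytic) / analytic, 0.02)
})

test_that("surfaces violating the nesting invariant are rejected", {
  n <- 8
  good <- array(1, c(n, n, n)); bad <- array(-1, c(n, n, n))
  sp <- surface_pair(good, good, check = FALSE)
  sp$inner_sdf <- bad   # inner region outside outer region
  expect_error(partial_volume_gm(sp), "nesting")
  expect_error(surface_pair(bad, good), "nesting")
})

test_that("fusing the indicator of the current GM changes nothing", {
  ph <- get_phantom()
  ind <- array(as.numeric(ph$labels$voxels == ph$labels$palette[["gm"]]),
               dim(ph$labels$voxels))
  fused <- binarize_and_fuse(ph$labels, ind)
  expect_identical(fused$voxels, ph$labels$voxels)
})

test_that("empty partial volume sends former GM to the nearest of WM/CSF", {
  ph <- get_phantom(folding = 0)
  lm <- ph$labels
  fused <- binarize_and_fuse(lm, array(0, dim(lm$voxels)))
  pal <- lm$palette
  expect_equal(sum(fused$voxels == pal[["gm"]]), 0)
  former <- which(lm$voxels == pal[["gm"]])
  # brute-force nearest-mask oracle on a subsample of former GM voxels
  wm_idx <- which(lm$voxels == pal[["wm"]])
  csf_idx <- which(lm$voxels == pal[["csf"]])
  d <- dim(lm$voxels)
  wm_pos <- arrayInd(wm_idx, d); csf_pos <- arrayInd(csf_idx, d)
  withr::with_seed(1, check <- sample(former, 50))
  for (v in check) {
    p <- arrayInd(v, d)[1, ]
    dw <- min(sqrt(colSums((t(wm_pos) - p)^2)))
    dc <- min(sqrt(colSums((t(csf_pos) - p)^2)))
    expected <- if (dw <= dc) pal[["wm"]] else pal[["csf"]]
    expect_identical(fused$voxels[v], expected)
  }
})

test_that("lowering the threshold never shrinks the fused GM", {
  ph <- get_phantom()
  pv <- partial_volume_gm(ph$surfaces)
  vols <- vapply(c(0.7, 0.5, 0.3), function(th)
    sum(binarize_and_fuse(ph$labels, pv, th)$voxels ==
          ph$labels$palette[["gm"]]), numeric(1))
  expect_true(all(diff(vols) >= 0))
})

test_that("protected structures survive fusion bit-identically", {
  ph <- get_phantom()
  pv <- partial_volume_gm(ph$surfaces)
  fused <- binarize_and_fuse(ph$labels, pv)
  pal <- ph$labels$palette
  for (l in c("ventricles", "deepgm", "cerebellum", "brainstem",
              "hipamy", "head", "background")) {
    expect_identical(fused$voxels == pal[[l]],
                     ph$labels$voxels == pal[[l]])
  }
})

test_that("fusion reproduces the tight/large construction of the phantoms", {
  ph <- get_phantom()
  gv <- make_gt_variants(ph$labels, ph$surfaces, 0.4)
  big <- surface_pair(ph$surfaces$inner_sdf + 0.4,
                      ph$surfaces$outer_sdf - 0.4,
                      ph$surfaces$voxel_size, check = FALSE)
  pv <- partial_volume_gm(big)
  direct <- binarize_and_fuse(ph$labels, pv)
  expect_identical(direct$voxels, gv$large$voxels)
})
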