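test_that("parameter counts match hand computations", {
  layer_param_count <- getFromNamespace("layer_param_count", "neosynth")
  # single 3^3 convolution, 1 -> 24 channels, with bias
  expect_equal(layer_param_count(list(k = 3, cin = 1, cout = 24,
                                      bn = FALSE)), 672)
  # toy network, counted layer by layer by hand:
  # enc1 conv 27*1*4+4 = 112, bn 8; enc2 conv 27*4*8+8 = 872, bn 16;
  # up transpose 8*8*8+8 = 520, bn 16; dec conv 27*12*4+4 = 1300, bn 8;
  # dec projection 12*4+4 = 52; final 4*2+2 = 10
  toy <- unet_config(levels = 2, convs_per_level = 1, base_features = 4,
                     n_classes = 2, class_labels = c(bg = 0L, fg = 1L))
  expect_equal(count_parameters(toy), 112 + 8 + 872 + 16 + 520 + 16 +
                 1300 + 8 + 52 + 10)
})

test_that("the five-level architecture reproduces the published size", {
  cfg <- unet_config()  # frozen convention
  expect_lt(abs(count_parameters(cfg) / 1e6 - 21.6), 0.05)
  sw <- unet_parameter_sweep()
  # the frozen convention is the sweep's closest match
  expect_equal(sw$parameters[1] == count_parameters(cfg) ||
                 sw$parameters[2] == count_parameters(cfg), TRUE)
})

test_that("instantiated counts equal planned counts and respect freezing", {
  cfg <- tiny_unet_config()
  net <- build_unet(cfg, seed = 1)
  expect_equal(count_parameters(net), count_parameters(cfg))
  n_all <- count_parameters(net)
  freeze_layers(net, "enc1_conv1")
  expect_lt(count_parameters(net), n_all)
  expect_equal(count_parameters(net, trainable_only = FALSE), n_all)
  expect_error(freeze_layers(net, "nope"), "unknown layer")
})

test_that("count is invariant to the input volume size (fully convolutional)", {
  cfg <- tiny_unet_config()
  net <- build_unet(cfg, seed = 1)
  unet_forward <- getFromNamespace("unet_forward", "neosynth")
  invisible(unet_forward(net, array(0, c(8, 8, 8))))
  n1 <- count_parameters(net)
  invisible(unet_forward(net, array(0, c(16, 16, 16))))
  expect_equal(count_parameters(net), n1)
})

test_that("softmax channels sum to one and bad shapes are diagnosed", {
  cfg <- tiny_unet_config()
  net <- build_unet(cfg, seed = 2)
  unet_forward <- getFromNamespace("unet_forward", "neosynth")
  f <- unet_forward(net, array(rnorm(8^3), c(8, 8, 8)))
  sums <- rowSums(matrix(f$prob, ncol = cfg$n_classes))
  expect_lt(max(abs(sums - 1)), 1e-5)
  expect_error(unet_forward(net, array(0, c(7, 8, 8))), "divisible")
})

test_that("analytic gradients match finite differences", {
  cfg <- tiny_unet_config()
  net <- build_unet(cfg, seed = 2)
  unet_forward <- getFromNamespace("unet_forward", "neosynth")
  unet_backward <- getFromNamespace("unet_backward", "neosynth")
  x <- withr::with_seed(1, array(rnorm(4^3), c(4, 4, 4)))
  y <- array(0, c(4, 4, 4, 3))
  cls <- withr::with_seed(2, sample(1:3, 64, TRUE))
  y[cbind(arrayInd(1:64, c(4, 4, 4)), cls)] <- 1
  f <- unet_forward(net, x, training = FALSE)
  l <- dice_loss(f$prob, y, gradient = TRUE)
  grads <- unet_backward(net, f$cache, attr(l, "gradient"))
  lossfn <- function() dice_loss(unet_forward(net, x)$prob, y)
  withr::with_seed(1, {   # seed chosen away from ReLU kinks, where
    # finite differences of a piecewise-linear network are ill-defined
    for (nm in sample(names(net$par), 6)) {
      g <- get0(nm, grads)
      idx <- sample(length(net$par[[nm]]), 1)
      eps <- 1e-5
      orig <- net$par[[nm]][idx]
      net$par[[nm]][idx] <- orig + eps; lp <- lossfn()
      net$par[[nm]][idx] <- orig - eps; lm <- lossfn()
      net$par[[nm]][idx] <- orig
      num <- (lp - lm) / (2 * eps)
      expect_lt(abs(num - g[idx]) /
                  max(abs(num), abs(g[idx]), 1e-8), 1e-5)
    }
  })
})

test_that("dice loss follows the printed formula on hand cases", {
  y <- array(0, c(2, 2, 1, 2)); y[, , , 1] <- 1
  expect_equal(dice_loss(y, y), 0)
  # binary masks |X| = |Y| = 2, overlap 1 -> class term 1 - 2/4 = 0.5
  p <- array(0, c(4, 1, 1, 2))
  t <- array(0, c(4, 1, 1, 2))
  p[1:2, 1, 1, 1] <- 1; p[3:4, 1, 1, 2] <- 1
  t[2:3, 1, 1, 1] <- 1; t[c(1, 4), 1, 1, 2] <- 1
  expect_equal(dice_loss(p, t), 0.5)
  # fully disjoint prediction and target -> class terms 1
  p2 <- array(c(1, 0), c(1, 1, 1, 2)); t2 <- array(c(0, 1), c(1, 1, 1, 2))
  expect_equal(dice_loss(p2, t2), 1)
  # class empty in both contributes 0
  p3 <- array(0, c(2, 1, 1, 3)); t3 <- array(0, c(2, 1, 1, 3))
  p3[, , , 1] <- 1; t3[, , , 1] <- 1
  expect_equal(dice_loss(p3, t3), 0)
})

test_that("balanced patch sampling contains and equalizes structures", {
  ph <- get_phantom()
  img <- withr::with_seed(1, render_image(ph$labels,
                                          canonical_contrast("t2")))
  tc <- train_config(patch_size = 16, patches_per_volume = 500)
  patches <- withr::with_seed(2, sample_patches(ph$labels, img, tc))
  pal <- ph$labels$palette
  for (p in patches[1:50])
    expect_gt(sum(p$labels == pal[[p$structure]]), 0)
  expect_true(all(vapply(patches, function(p)
    all(dim(p$image) == 16), logical(1))))
  # structure draw is uniform (chi-square at alpha = 0.01, 1e4 draws)
  # small patches: only the drawn structure matters for this check
  draws <- withr::with_seed(3, vapply(
    sample_patches(ph$labels, img,
                   train_config(patch_size = 8,
                                patches_per_volume = 1e4)),
    `[[`, character(1), "structure"))
  tab <- table(factor(draws, levels = names(pal)))
  expect_gt(chisq.test(tab)$p.value, 0.01)
  # the smallest structure appears in far more patches than under
  # uniform-voxel sampling
  hip_frac_balanced <- mean(draws == "hipamy")
  hip_frac_voxels <- label_volumes(ph$labels, "hipamy") /
    prod(dim(ph$labels$voxels))
  expect_gt(hip_frac_balanced, 10 * hip_frac_voxels)
})

test_that("patch sampling falls back to the full volume and warns", {
  ph <- get_phantom()
  img <- withr::with_seed(1, render_image(ph$labels,
                                          canonical_contrast("t2")))
  tc <- train_config(patch_size = 128, patches_per_volume = 1)
  expect_warning(p <- sample_patches(ph$labels, img, tc), "full volume")
  expect_equal(dim(p[[1]]$image), dim(ph$labels$voxels))
  # absent structures excluded with a warning
  vox <- ph$labels$voxels
  vox[vox == ph$labels$palette[["hipamy"]]] <-
    ph$labels$palette[["wm"]]
  nohip <- label_map(vox, ph$labels$voxel_size, ph$labels$palette)
  expect_warning(sample_patches(nohip, img,
                                train_config(patch_size = 16,
                                             patches_per_volume = 1)),
                 "hipamy")
})

test_that("full-volume inference is deterministic and patch-consistent", {
  cfg <- tiny_unet_config(n_classes = 4, base = 4)
  net <- build_unet(cfg, seed = 5)
  img <- mri_image(withr::with_seed(6, array(rnorm(24^3), c(24, 24, 24))),
                   1)
  p1 <- predict_volume(net, img)
  p2 <- predict_volume(net, img)
  expect_identical(p1$voxels, p2$voxels)
  expect_true(all(unique(as.integer(p1$voxels)) %in%
                    unname(cfg$class_labels)))
  # interior of a patch prediction equals the full-volume prediction
  # (single-level net: its receptive radius of 2 fits inside the margin)
  cfg1 <- unet_config(levels = 1, convs_per_level = 2, base_features = 4,
                      n_classes = 4,
                      class_labels = setNames(0:3, paste0("c", 1:4)),
                      dropout = 0)
  net1 <- build_unet(cfg1, seed = 7)
  f1 <- predict_volume(net1, img)
  sub <- mri_image(img$voxels[1:16, 1:16, 1:16], 1)
  ps <- predict_volume(net1, sub)
  margin <- 4:13   # exclude the receptive-field margin
  expect_identical(ps$voxels[margin, margin, margin],
                   f1$voxels[margin, margin, margin])
})
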