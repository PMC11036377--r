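test_that("motion amplitude sampler stays in [3, 8]", {
  withr::with_seed(1, {
    for (i in 1:200) {
      p <- sample_motion_params()
      expect_true(p$max_translation >= 3 && p$max_translation <= 8)
      expect_true(p$max_rotation >= 3 && p$max_rotation <= 8)
    }
  })
})

test_that("trajectory peaks equal the sampled maxima and events are uniform", {
  withr::with_seed(2, {
    for (i in 1:50) {
      p <- sample_motion_params()
      tr <- sample_trajectory(p, 32)
      expect_equal(max(sqrt(rowSums(tr$translations^2))),
                   p$max_translation, tolerance = 1e-12)
      expect_equal(max(sqrt(rowSums(tr$rotations^2))),
                   p$max_rotation, tolerance = 1e-12)
    }
    # event segment uniform over 1..n (chi-square GOF at alpha = 0.01)
    n <- 16
    ev <- replicate(1e4, sample_trajectory(sample_motion_params(), n)$event)
    expect_gt(chisq.test(tabulate(ev, n))$p.value, 0.01)
  })
  a <- withr::with_seed(7, sample_trajectory(sample_motion_params(), 20))
  b <- withr::with_seed(7, sample_trajectory(sample_motion_params(), 20))
  expect_identical(a, b)
  expect_error(sample_trajectory(sample_motion_params(), 1), "at least 2")
})

test_that("identity trajectory reproduces the input within FFT tolerance", {
  img <- cube_image(32)
  out <- apply_motion(img, identity_trajectory(32))
  expect_lt(max(abs(out$voxels - img$voxels)), 1e-6)
})

test_that("constant integer translation equals the array-shift oracle", {
  img <- cube_image(32)  # compact support, wide zero margin
  tj <- identity_trajectory(32)
  tj$translations <- matrix(rep(c(2, 0, -3), each = 32), 32)
  out <- apply_motion(img, tj)
  shift_array <- getFromNamespace("shift_array", "neosynth")
  oracle <- shift_array(img$voxels, c(2, 0, -3), 0)
  nrmse <- sqrt(mean((out$voxels - oracle)^2)) / diff(range(oracle))
  expect_lt(nrmse, 1e-3)
})

test_that("sub-voxel constant translation matches the spatial sinc oracle", {
  # odd grid so the Dirichlet kernel is real and the oracle separable
  n <- 15
  arr <- array(0, c(n, n, n))
  withr::with_seed(3, arr[5:11, 5:11, 5:11] <-
                     array(runif(7^3, 0.2, 1), c(7, 7, 7)))
  tau <- c(0.4, -0.3, 0.25)
  tj <- identity_trajectory(n)
  tj$translations <- matrix(rep(tau, each = n), n)
  out <- apply_motion(mri_image(arr, 1), tj, magnitude = FALSE)
  fft_freq <- getFromNamespace("fft_freq", "neosynth")
  dirichlet <- function(n, t) {
    D <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n)
      D[i, j] <- Re(mean(exp(2i * pi * fft_freq(n) * ((i - t) - j) / n)))
    D
  }
  o <- arr
  o <- apply(o, c(2, 3), function(v) dirichlet(n, tau[1]) %*% v)
  o <- aperm(apply(o, c(1, 3), function(v) dirichlet(n, tau[2]) %*% v),
             c(2, 1, 3))
  o <- aperm(apply(o, c(1, 2), function(v) dirichlet(n, tau[3]) %*% v),
             c(2, 3, 1))
  nrmse <- sqrt(mean((Re(out) - o)^2)) / diff(range(o))
  expect_lt(nrmse, 1e-3)
})

test_that("pure-translation trajectories conserve image energy (Parseval)", {
  img <- cube_image(32)
  tj <- withr::with_seed(4,
    sample_trajectory(sample_motion_params(), 32))
  tj$rotations[] <- 0
  out <- apply_motion(img, tj)
  e0 <- sum(img$voxels^2); e1 <- sum(out$voxels^2)
  expect_lt(abs(e1 - e0) / e0, 1e-6)
})

test_that("corruption severity grows with the translation amplitude", {
  img <- cube_image(32)
  tj <- withr::with_seed(5,
    sample_trajectory(sample_motion_params(), 32))
  shape <- sqrt(rowSums(tj$translations^2))
  shape <- shape / max(shape)
  sev <- vapply(c(3, 5, 8), function(a) {
    t2 <- tj
    t2$translations <- outer(shape * a, c(1, 0, 0))
    t2$rotations[] <- 0
    mean(abs(apply_motion(img, t2)$voxels - img$voxels))
  }, numeric(1))
  expect_true(all(diff(sev) > 0))
})

test_that("rotations mix tissue but preserve rough image statistics", {
  img <- cube_image(32)
  tj <- withr::with_seed(6,
    sample_trajectory(sample_motion_params(), 32))
  out <- apply_motion(img, tj)
  expect_true(all(is.finite(out$voxels)))
  expect_gt(mean(abs(out$voxels - img$voxels)), 0)  # artifacts present
})

test_that("trajectory length must match the number of segments", {
  img <- cube_image(16)
  tj <- identity_trajectory(8)
  expect_error(apply_motion(img, tj, n_segments = 16), "does not match")
  tj5 <- identity_trajectory(5)   # 16 lines not divisible by 5
  expect_error(apply_motion(img, tj5), "multiple")
})
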