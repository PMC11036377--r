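test_that("dice handles the hand-checkable cases", {
  m <- function(v) array(v, c(2, 2, 1))
  a <- m(c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(dice_score(a, a), 1)
  expect_equal(dice_score(a, m(c(FALSE, FALSE, TRUE, TRUE))), 0)
  # |X| = |Y| = 2 with overlap 1 -> 2*1/(2+2) = 0.5
  expect_equal(dice_score(a, m(c(TRUE, FALSE, TRUE, FALSE))), 0.5)
  expect_equal(dice_score(m(rep(FALSE, 4)), m(rep(FALSE, 4))), 1)
  expect_equal(dice_score(a, m(rep(FALSE, 4))), 0)
  expect_error(dice_score(a, array(TRUE, c(2, 1, 1))), "same grid")
})

test_that("CSF/ventricle merge is idempotent and only touches those labels", {
  ph <- get_phantom()
  merged <- merge_for_eval(ph$labels)
  pal <- ph$labels$palette
  expect_equal(sum(merged$voxels == pal[["ventricles"]]), 0)
  expect_equal(sum(merged$voxels == pal[["csf"]]),
               sum(ph$labels$voxels %in% pal[c("csf", "ventricles")]))
  others <- setdiff(names(pal), c("csf", "ventricles"))
  for (l in others)
    expect_identical(merged$voxels == pal[[l]],
                     ph$labels$voxels == pal[[l]])
  expect_identical(merge_for_eval(merged)$voxels, merged$voxels)
  # a map without ventricles is unchanged
  expect_identical(merge_for_eval(merged)$voxels, merged$voxels)
})

test_that("merging CSF and ventricles cannot hurt the dice of the union", {
  # nested phantom case: prediction displaces the ventricle/CSF boundary
  ph <- get_phantom()
  pal <- ph$labels$palette
  pred <- ph$labels
  vox <- pred$voxels
  vent <- which(vox == pal[["ventricles"]])
  flip <- vent[seq_len(length(vent) %/% 2)]
  vox[flip] <- pal[["csf"]]    # half the ventricles called CSF
  pred <- label_map(vox, pred$voxel_size, pal)
  d_before <- c(
    dice_score(pred$voxels == pal[["csf"]],
               ph$labels$voxels == pal[["csf"]]),
    dice_score(pred$voxels == pal[["ventricles"]],
               ph$labels$voxels == pal[["ventricles"]]))
  pm <- merge_for_eval(pred); gm <- merge_for_eval(ph$labels)
  d_after <- dice_score(pm$voxels == pal[["csf"]],
                        gm$voxels == pal[["csf"]])
  expect_gte(d_after, min(d_before))
})

test_that("average surface distance matches the brute-force oracle", {
  a <- array(FALSE, c(12, 12, 12)); a[3:6, 3:6, 3:6] <- TRUE
  b <- array(FALSE, c(12, 12, 12)); b[4:7, 3:6, 3:6] <- TRUE
  expect_equal(average_surface_distance(a, a, 1), 0)
  boundary_voxels <- getFromNamespace("boundary_voxels", "neosynth")
  brute <- function(x, y, w) {
    bx <- which(boundary_voxels(x)); by <- which(boundary_voxels(y))
    px <- arrayInd(bx, dim(x)) %*% diag(w)
    py <- arrayInd(by, dim(y)) %*% diag(w)
    dmat <- as.matrix(dist(rbind(px, py)))
    cross <- dmat[seq_len(nrow(px)), nrow(px) + seq_len(nrow(py)),
                  drop = FALSE]
    (sum(apply(cross, 1, min)) + sum(apply(cross, 2, min))) /
      (nrow(px) + nrow(py))
  }
  expect_equal(average_surface_distance(a, b, 1), brute(a, b, c(1, 1, 1)))
  # anisotropic voxels: doubling the voxel size doubles the distance
  expect_equal(average_surface_distance(a, b, 2),
               2 * average_surface_distance(a, b, 1))
  expect_warning(res <- average_surface_distance(
    a, array(FALSE, c(12, 12, 12)), 1), "empty")
  expect_true(is.na(res))
})

test_that("dice and surface distance rank an erosion series consistently", {
  ph <- get_phantom(folding = 0)
  wm <- ph$labels$voxels == ph$labels$palette[["wm"]]
  dim(wm) <- dim(ph$labels$voxels)
  erode <- function(m, k) {
    for (i in seq_len(k)) {
      inner <- m
      for (a in 1:3) for (s in c(-1, 1)) {
        by <- c(0, 0, 0); by[a] <- s
        shift_array <- getFromNamespace("shift_array", "neosynth")
        inner <- inner & shift_array(m, by, FALSE)
      }
      m <- inner
    }
    m
  }
  dices <- asds <- numeric(3)
  for (k in 1:3) {
    e <- erode(wm, k)
    dices[k] <- dice_score(e, wm)
    asds[k] <- average_surface_distance(e, wm, 1)
  }
  expect_true(all(diff(dices) < 0))
  expect_true(all(diff(asds) > 0))
})

test_that("volume correlation recovers exact linear relations", {
  a <- c(10, 12, 15, 18, 22)
  expect_equal(volume_correlation(a, a),
               list(pearson_r = 1, slope = 1))
  r <- volume_correlation(a, 1.05 * a)
  expect_equal(r$pearson_r, 1)
  expect_equal(r$slope, 1.05)
  expect_equal(volume_correlation(a, -a)$pearson_r, -1)
  expect_error(volume_correlation(a[1:2], a[1:2]), "3 paired")
  expect_warning(res <- volume_correlation(a, rep(1, 5)), "zero variance")
  expect_true(is.na(res$pearson_r))
})

test_that("age bins follow the closed-left convention with hand means", {
  rec <- data.frame(subject = paste0("s", 1:6),
                    model = "m",
                    structure = "gm",
                    dice = c(0.9, 0.8, 0.85, 0.7, 0.95, 0.75),
                    age = c(30, 33, 37, 41, 32, 45))
  out <- age_binned_summary(rec)
  expect_equal(sum(out$n), 6)
  # boundary age 32 falls in the second bin; 45 in the (closed) last bin
  b2 <- out[out$bin == "[32,36)", ]
  expect_equal(b2$n, 2)
  expect_equal(b2$mean_dice, mean(c(0.8, 0.95)))
  b4 <- out[out$bin == "[40,45]", ]
  expect_equal(b4$n, 2)
  expect_equal(b4$mean_dice, mean(c(0.7, 0.75)))
  expect_warning(age_binned_summary(rbind(rec,
    data.frame(subject = "s7", model = "m", structure = "gm",
               dice = 0.5, age = 50))), "outside")
})

test_that("outlier flagging isolates extreme subjects", {
  rec <- data.frame(subject = paste0("s", 1:30), model = "m",
                    structure = "gm", dice = 0.9, age = 35)
  expect_length(flag_outliers(rec), 0)
  rec$dice[1:29] <- withr::with_seed(8, rnorm(29, 0.9, 0.005))
  # one subject far below the rest (5 SD of the others)
  rec$dice[30] <- mean(rec$dice[1:29]) - 5 * sd(rec$dice[1:29])
  expect_equal(flag_outliers(rec), "s30")
  expect_length(flag_outliers(rec, k = Inf), 0)
  expect_error(flag_outliers(rec[1:3, ]), "at least 5")
})

test_that("consistency dice delegates to dice and is symmetric", {
  ph <- get_phantom()
  expect_equal(consistency_dice(ph$labels, ph$labels, "gm"), 1)
  shift_array <- getFromNamespace("shift_array", "neosynth")
  moved <- label_map(shift_array(ph$labels$voxels, c(1, 0, 0), 0L),
                     ph$labels$voxel_size, ph$labels$palette)
  d1 <- consistency_dice(ph$labels, moved, "gm")
  d2 <- consistency_dice(moved, ph$labels, "gm")
  expect_equal(d1, d2)
  expect_equal(d1, dice_score(ph$labels$voxels == 3, moved$voxels == 3))
})

test_that("metrics are invariant to a consistent relabelling of ids", {
  ph <- get_phantom()
  pal <- ph$labels$palette
  pal2 <- setNames(pal + 100L, names(pal))
  relab <- label_map(array(ph$labels$voxels + 100L,
                           dim(ph$labels$voxels)),
                     ph$labels$voxel_size, pal2)
  expect_equal(consistency_dice(relab, relab, "gm"), 1)
  expect_equal(label_volumes(relab, "gm"), label_volumes(ph$labels, "gm"))
})
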