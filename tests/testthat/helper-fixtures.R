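# shared fixtures, built once per test run

fixture_env <- new.env()

# 48^3 phantom with moderate folding; cached across test files
get_phantom <- function(folding = 0.4, grid = 48, thickness = 2.5,
                        seed = 3) {
  key <- paste("ph", folding, grid, thickness, seed, sep = "_")
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- make_phantom(
      phantom_spec(grid_shape = grid, voxel_size = 1, folding = folding,
                   cortical_thickness = thickness, seed = seed))
  fixture_env[[key]]
}

# compact cube image with wide zero margins (motion oracles)
cube_image <- function(n = 32, lo = n %/% 4 + 1, hi = 3 * n %/% 4,
                       seed = 11) {
  arr <- array(0, c(n, n, n))
  withr::with_seed(seed, {
    arr[lo:hi, lo:hi, lo:hi] <-
      0.5 + array(runif((hi - lo + 1)^3), rep(hi - lo + 1, 3)) / 2
  })
  mri_image(arr, 1)
}

tiny_unet_config <- function(n_classes = 3, convs = 2, base = 2,
                             dropout = 0) {
  unet_config(levels = 2, convs_per_level = convs, base_features = base,
              n_classes = n_classes,
              class_labels = setNames(seq_len(n_classes) - 1L,
                                      paste0("c", seq_len(n_classes))),
              dropout = dropout)
}
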