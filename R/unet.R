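#' 3D UNet configuration
#'
#' Describes the encoder-decoder segmentation network: `levels` resolution
#' levels separated by 2x2x2 max-pooling (encoder) and upsampling
#' (decoder), `convs_per_level` 3x3x3 convolutions per level, each
#' followed by batch normalization, ReLU and dropout (except the final
#' 1x1x1 classifier, which is followed only by a softmax), feature maps
#' doubling after each pooling and halving after each upsampling, and
#' residual skip connections within the blocks.
#'
#' Conventions left open by the prose description are explicit fields,
#' resolved empirically by [unet_parameter_sweep]:
#' * `upsampling`: `"transpose"` (2^3 transposed convolution preserving
#'   channels, then concatenation — the default), `"transpose_halve"`
#'   (transposed convolution halving channels) or `"trilinear"`
#'   (parameter-free trilinear upsampling + 1^3 halving convolution).
#' * `residual_projection`: shortcut mapping used when a block changes
#'   width — `"conv1"` (1^3 projection, default), `"conv3"`, or `"none"`
#'   (shortcut restricted to the constant-width tail of the block).
#' * `projection_site`: `"decoder"` (default) applies projection
#'   shortcuts only to the channel-changing decoder blocks; encoder
#'   blocks then use identity shortcuts over their constant-width tail;
#'   `"all"` projects everywhere the width changes.
#'
#' @param levels number of resolution levels (default 5).
#' @param convs_per_level convolutions per level (default 3).
#' @param kernel convolution kernel (3 integers, default `c(3, 3, 3)`;
#'   only cubic odd kernels are supported).
#' @param base_features feature maps of the first block (default 24).
#' @param dropout dropout probability after each convolution (default
#'   0.1).
#' @param n_classes number of output classes (default 10: nine tissue
#'   classes with all extra-cerebral tissue as `head`, plus background).
#' @param class_labels named integer vector mapping class names to label
#'   ids; its length must equal `n_classes`.
#' @param residual_skips use residual skip connections within blocks.
#' @param upsampling,residual_projection,projection_site see Details.
#' @param batchnorm include batch normalization.
#' @param bn_eval normalization statistics used at inference:
#'   `"running"` (training-time running averages; fully convolutional,
#'   patch/volume consistent) or `"input"` (statistics of the volume
#'   being predicted; appropriate for contrast-agnostic inference, where
#'   no single running average can match an arbitrary unseen contrast).
#'   Both are deterministic in evaluation mode.
#' @return Object of class `unet_config`.
#' @export
unet_config <- function(levels = 5, convs_per_level = 3, kernel = c(3, 3, 3),
                        base_features = 24, dropout = 0.1, n_classes = 10,
                        class_labels = default_palette(),
                        residual_skips = TRUE,
                        upsampling = c("transpose", "transpose_halve",
                                       "trilinear"),
                        residual_projection = c("conv1", "conv3", "none"),
                        projection_site = c("decoder", "all"),
                        batchnorm = TRUE,
                        bn_eval = c("running", "input")) {
  upsampling <- match.arg(upsampling)
  residual_projection <- match.arg(residual_projection)
  projection_site <- match.arg(projection_site)
  bn_eval <- match.arg(bn_eval)
  stopifnot(levels >= 1, convs_per_level >= 1, base_features >= 1,
            length(kernel) == 3, kernel[1] == kernel[2],
            kernel[2] == kernel[3], kernel[1] %% 2 == 1)
  if (length(class_labels) != n_classes)
    stop("class_labels must have length n_classes")
  structure(list(levels = as.integer(levels),
                 convs_per_level = as.integer(convs_per_level),
                 kernel = as.integer(kernel),
                 base_features = as.integer(base_features),
                 dropout = dropout, n_classes = as.integer(n_classes),
                 class_labels = class_labels,
                 residual_skips = residual_skips,
                 upsampling = upsampling,
                 residual_projection = residual_projection,
                 projection_site = projection_site,
                 batchnorm = batchnorm, bn_eval = bn_eval),
            class = "unet_config")
}

# layer dimension plan: list of entries (name, type, k, cin, cout, bn, act)
unet_layer_plan <- function(config) {
  f <- config$base_features * 2^(0:(config$levels - 1))
  k <- config$kernel[1]
  nconv <- config$convs_per_level
  plan <- list()
  add <- function(name, type, k, cin, cout, bn, act, dropout) {
    plan[[length(plan) + 1]] <<- list(name = name, type = type, k = k,
                                      cin = cin, cout = cout, bn = bn,
                                      act = act, dropout = dropout)
  }
  block <- function(prefix, cin, cout, site_projects) {
    add(paste0(prefix, "_conv1"), "conv", k, cin, cout, config$batchnorm,
        TRUE, config$dropout)
    if (nconv > 1)
      for (i in 2:nconv)
        add(paste0(prefix, "_conv", i), "conv", k, cout, cout,
            config$batchnorm, TRUE, config$dropout)
    if (config$residual_skips && site_projects && cin != cout &&
        config$residual_projection != "none") {
      pk <- if (config$residual_projection == "conv1") 1L else k
      add(paste0(prefix, "_proj"), "proj", pk, cin, cout, FALSE, FALSE, 0)
    }
  }
  cin <- 1L
  for (l in seq_len(config$levels)) {
    block(paste0("enc", l), cin, f[l],
          site_projects = config$projection_site == "all")
    cin <- f[l]
  }
  if (config$levels > 1)
    for (l in (config$levels - 1):1) {
      fin <- f[l + 1]
      up_out <- switch(config$upsampling,
        transpose = fin, transpose_halve = f[l], trilinear = f[l])
      if (config$upsampling %in% c("transpose", "transpose_halve"))
        add(paste0("dec", l, "_up"), "upconv", 2L, fin, up_out,
            config$batchnorm, TRUE, config$dropout)
      else
        add(paste0("dec", l, "_up"), "conv", 1L, fin, f[l],
            config$batchnorm, TRUE, config$dropout)
      block(paste0("dec", l), up_out + f[l], f[l], site_projects = TRUE)
    }
  add("final", "conv", 1L, f[1], config$n_classes, FALSE, FALSE, 0)
  plan
}

layer_param_count <- function(e) {
  n <- e$k^3 * e$cin * e$cout + e$cout        # weights + bias
  if (isTRUE(e$bn)) n <- n + 2 * e$cout       # gamma, beta
  n
}

#' Count trainable parameters
#'
#' @param x a `unet_config`, an instantiated `unet`, or a `unet_fit`.
#' @param trainable_only for instantiated networks, exclude frozen layers.
#' @return Integer count of trainable scalars.
#' @export
count_parameters <- function(x, trainable_only = TRUE) {
  if (inherits(x, "unet_fit")) x <- x$net
  if (inherits(x, "unet_config"))
    return(sum(vapply(unet_layer_plan(x), layer_param_count, numeric(1))))
  stopifnot(inherits(x, "unet"))
  total <- 0
  for (nm in names(x$par)) {
    lname <- sub("\\.(w|b|gamma|beta)$", "", nm)
    if (trainable_only && lname %in% x$frozen) next
    total <- total + length(x$par[[nm]])
  }
  total
}

#' Sweep architecture conventions against a target parameter count
#'
#' Enumerates the documented convention variants (class count, upsampling
#' form, residual projection form and site, batch normalization) of the
#' five-level network and reports the trainable parameter count of each,
#' ordered by distance to `target` (default 21.6 million).
#'
#' @param target target parameter count.
#' @param n_classes class counts to try.
#' @return `data.frame` with the convention fields, `parameters` and
#'   `millions`, ordered by `|parameters - target|`.
#' @export
unet_parameter_sweep <- function(target = 21.6e6,
                                 n_classes = c(9, 10, 19)) {
  grid <- expand.grid(n_classes = n_classes,
                      upsampling = c("transpose", "transpose_halve",
                                     "trilinear"),
                      residual_projection = c("conv1", "conv3", "none"),
                      projection_site = c("decoder", "all"),
                      batchnorm = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
  grid$parameters <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- unet_config(
      n_classes = grid$n_classes[i],
      class_labels = setNames(seq_len(grid$n_classes[i]) - 1L,
                              paste0("c", seq_len(grid$n_classes[i]))),
      upsampling = grid$upsampling[i],
      residual_projection = grid$residual_projection[i],
      projection_site = grid$projection_site[i],
      batchnorm = grid$batchnorm[i])
    count_parameters(cfg)
  }, numeric(1))
  grid$millions <- grid$parameters / 1e6
  grid[order(abs(grid$parameters - target)), ]
}

#' Build (instantiate) a 3D UNet
#'
#' Allocates and initializes all network parameters (He initialization
#' for convolution weights, zero biases, unit-gamma/zero-beta batch
#' norm).  The network maps a single-channel volume of shape
#' `(X, Y, Z)` to per-voxel class probabilities `(X, Y, Z, n_classes)`
#' for any shape divisible by `2^(levels - 1)`.
#'
#' @param config a [unet_config].
#' @param seed optional seed for the weight initialization.
#' @return Object of class `unet` (an environment holding the parameters,
#'   batch-norm running statistics and the layer plan).
#' @export
build_unet <- function(config, seed = NULL) {
  plan <- unet_layer_plan(config)
  net <- new.env(parent = emptyenv())
  net$config <- config
  net$plan <- plan
  net$par <- list()
  net$state <- list()
  net$frozen <- character(0)
  with_seed(seed, {
    for (e in plan) {
      fan_in <- e$k^3 * e$cin
      w <- matrix(rnorm(fan_in * e$cout, 0, sqrt(2 / fan_in)),
                  fan_in, e$cout)
      net$par[[paste0(e$name, ".w")]] <- w
      net$par[[paste0(e$name, ".b")]] <- numeric(e$cout)
      if (isTRUE(e$bn)) {
        net$par[[paste0(e$name, ".gamma")]] <- rep(1, e$cout)
        net$par[[paste0(e$name, ".beta")]] <- numeric(e$cout)
        net$state[[paste0(e$name, ".rmean")]] <- numeric(e$cout)
        net$state[[paste0(e$name, ".rvar")]] <- rep(1, e$cout)
      }
    }
  })
  class(net) <- "unet"
  net
}

#' Freeze layers of a network
#'
#' Frozen layers keep their parameters fixed during training and are
#' excluded from [count_parameters] when `trainable_only = TRUE`.
#'
#' @param net a `unet`.
#' @param layer_names layer names (see `net$plan`).
#' @return The network, invisibly.
#' @export
freeze_layers <- function(net, layer_names) {
  known <- vapply(net$plan, `[[`, character(1), "name")
  bad <- setdiff(layer_names, known)
  if (length(bad)) stop("unknown layer(s): ", paste(bad, collapse = ", "))
  net$frozen <- union(net$frozen, layer_names)
  invisible(net)
}

#' @export
print.unet <- function(x, ...) {
  cfg <- x$config
  cat("<unet> ", cfg$levels, " levels, ", cfg$convs_per_level,
      " convs/level, ", cfg$base_features, " base features, ",
      cfg$n_classes, " classes\n", sep = "")
  cat("  upsampling: ", cfg$upsampling, "; residual: ",
      if (cfg$residual_skips) cfg$residual_projection else "off",
      " (", cfg$projection_site, "); batchnorm: ", cfg$batchnorm,
      "\n", sep = "")
  cat("  trainable parameters: ",
      format(count_parameters(x), big.mark = ","), "\n", sep = "")
  invisible(x)
}
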