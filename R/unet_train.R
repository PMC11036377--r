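#' Training configuration
#'
#' @param patch_size cubic patch edge in voxels (default 128).  Volumes
#'   smaller than the patch are used whole, with a warning.
#' @param patches_per_volume patches sampled from each generated volume
#'   (default 8).
#' @param batch_size patches per optimizer step (default 4).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param learning_rate_end optional final learning rate: when given, the
#'   rate decays exponentially from `learning_rate` to this value over
#'   the run (useful at small iteration budgets, where the gradient noise
#'   of random-contrast training otherwise dominates the endpoint).
#' @param max_iterations optimizer steps.
#' @param seed RNG seed for the whole training run.
#' @return Object of class `train_config`.
#' @export
train_config <- function(patch_size = 128, patches_per_volume = 8,
                         batch_size = 4, learning_rate = 1e-4,
                         learning_rate_end = NULL,
                         max_iterations = 100, seed = 1) {
  structure(list(patch_size = as.integer(patch_size),
                 patches_per_volume = as.integer(patches_per_volume),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 learning_rate_end = learning_rate_end,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Average soft dice loss
#'
#' For each class `c`, the soft dice term is
#' `1 - 2 * sum(p_c * y_c) / (sum(p_c^2) + sum(y_c^2))`; the loss is the
#' mean over classes.  A class empty in both the prediction and the
#' target contributes 0.
#'
#' @param soft_prediction 4D array `(X, Y, Z, C)` of class probabilities
#'   (channels summing to 1).
#' @param one_hot_target 4D array of the same shape, one-hot.
#' @param gradient also return the gradient with respect to the
#'   prediction.
#' @return The loss (numeric in `[0, 1]`), with attribute `"gradient"`
#'   when requested.
#' @export
dice_loss <- function(soft_prediction, one_hot_target, gradient = FALSE) {
  C <- dim(soft_prediction)[4]
  pm <- matrix(soft_prediction, ncol = C)
  ym <- matrix(one_hot_target, ncol = C)
  spq <- colSums(pm * ym)
  spp <- colSums(pm * pm)
  sqq <- colSums(ym * ym)
  den <- spp + sqq
  term <- ifelse(den > 0, 1 - 2 * spq / den, 0)
  loss <- mean(term)
  if (gradient) {
    g <- matrix(0, nrow(pm), C)
    nz <- which(den > 0)
    for (c in nz)
      g[, c] <- -2 * (ym[, c] * den[c] - 2 * pm[, c] * spq[c]) /
        (den[c]^2) / C
    attr(loss, "gradient") <- array(g, dim(soft_prediction))
  }
  loss
}

one_hot <- function(label_vox, class_labels) {
  C <- length(class_labels)
  m <- matrix(0, length(label_vox), C)
  idx <- match(as.integer(label_vox), unname(class_labels))
  if (anyNA(idx))
    stop("labels outside the configured classes: ",
         paste(unique(label_vox[is.na(idx)]), collapse = ", "))
  m[cbind(seq_along(idx), idx)] <- 1
  array(m, c(dim(label_vox), C))
}

crop_patch <- function(arr, centre, ps, fill) {
  d <- dim(arr)
  out <- array(fill, rep(ps, 3))
  lo <- centre - ps %/% 2
  hi <- lo + ps - 1
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    s1 <- max(1, lo[a]); s2 <- min(d[a], hi[a])
    if (s1 > s2) return(out)
    src[[a]] <- s1:s2
    dst[[a]] <- (s1 - lo[a] + 1):(s2 - lo[a] + 1)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    arr[src[[1]], src[[2]], src[[3]]]
  out
}

#' Sample structure-balanced training patches
#'
#' For each patch a target structure is drawn uniformly among the
#' structures present in the volume, then a centre voxel uniformly within
#' that structure; the patch is cropped around it (background label /
#' zero intensity padding at the borders).  Every returned patch
#' therefore contains at least one voxel of its drawn structure.
#'
#' @param label_map a [label_map] (the target segmentation).
#' @param image the matching [mri_image].
#' @param train_cfg a [train_config] (`patch_size`, `patches_per_volume`).
#' @return List of patches, each `list(image, labels, structure)` with
#'   3D arrays `image`, `labels`.
#' @export
sample_patches <- function(label_map, image, train_cfg) {
  vox <- label_map$voxels
  img <- as_vox_array(image)
  pal <- label_map$palette
  present <- names(pal)[vapply(names(pal), function(l)
    any(vox == pal[[l]]), logical(1))]
  absent <- setdiff(names(pal), present)
  if (length(absent))
    warning("structure(s) absent from volume, excluded from sampling: ",
            paste(absent, collapse = ", "))
  ps <- train_cfg$patch_size
  if (ps > min(dim(vox))) {
    warning("patch_size ", ps, " exceeds volume extent ",
            paste(dim(vox), collapse = "x"), "; using the full volume")
    ps <- min(dim(vox))
  }
  idx_by_label <- lapply(present, function(l) which(vox == pal[[l]]))
  names(idx_by_label) <- present
  lapply(seq_len(train_cfg$patches_per_volume), function(i) {
    st <- present[sample.int(length(present), 1)]
    pool <- idx_by_label[[st]]
    centre <- arrayInd(pool[sample.int(length(pool), 1)], dim(vox))[1, ]
    list(image = crop_patch(img, centre, ps, 0),
         labels = crop_patch(vox, centre, ps, pal[["background"]]),
         structure = st)
  })
}

adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0), t = 0)
}

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(net$par)) {
    g <- get0(nm, grads, inherits = FALSE)
    if (is.null(g)) next
    lname <- sub("\\.(w|b|gamma|beta)$", "", nm)
    if (lname %in% net$frozen) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    net$par[[nm]] <- net$par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

#' Train a UNet on a generative recipe
#'
#' Runs dice-loss training with the Adam optimizer.  Each iteration
#' generates one synthetic (or augmented real) volume from the recipe,
#' samples structure-balanced patches from it, and performs one optimizer
#' step on a batch.  Fully seeded; the per-iteration loss trace is
#' recorded and training aborts with a diagnostic if the loss becomes
#' non-finite.
#'
#' @param recipe a [recipe_config].
#' @param subjects list of training subjects (see
#'   [make_phantom_cohort]).
#' @param unet_cfg a [unet_config].
#' @param train_cfg a [train_config].
#' @param checkpoint_path optional RDS path; the fit is saved there every
#'   `checkpoint_every` iterations and at the end.
#' @param checkpoint_every iterations between checkpoints.
#' @param trace_path optional CSV path for the per-iteration loss trace.
#' @param verbose print the loss every 10 iterations.
#' @return Object of class `unet_fit`: list with `net`, `loss_trace`,
#'   `recipe`, `unet_cfg`, `train_cfg`.
#' @export
train_unet <- function(recipe, subjects, unet_cfg, train_cfg,
                       checkpoint_path = NULL, checkpoint_every = 100,
                       trace_path = NULL, verbose = FALSE) {
  set.seed(train_cfg$seed)
  net <- build_unet(unet_cfg)
  adam <- adam_init(net$par)
  trace <- numeric(train_cfg$max_iterations)
  nb <- train_cfg$batch_size
  for (it in seq_len(train_cfg$max_iterations)) {
    subj <- subjects[[(it - 1) %% length(subjects) + 1]]
    samp <- generate_training_sample(recipe, subj)
    patches <- suppressWarnings(
      sample_patches(samp$labels, samp$image, train_cfg))
    batch <- patches[((seq_len(nb) - 1) %% length(patches)) + 1]
    grads <- new.env()
    loss <- 0
    for (p in batch) {
      fwd <- unet_forward(net, p$image, training = TRUE)
      oh <- one_hot(p$labels, unet_cfg$class_labels)
      l <- dice_loss(fwd$prob, oh, gradient = TRUE)
      loss <- loss + as.numeric(l) / nb
      unet_backward(net, fwd$cache, attr(l, "gradient") / nb, grads)
    }
    if (!is.finite(loss))
      stop("training diverged at iteration ", it,
           ": loss is not finite (learning rate too high or degenerate ",
           "inputs)")
    lr <- train_cfg$learning_rate
    if (!is.null(train_cfg$learning_rate_end) &&
        train_cfg$max_iterations > 1)
      lr <- lr * (train_cfg$learning_rate_end / lr)^
        ((it - 1) / (train_cfg$max_iterations - 1))
    adam <- adam_step(net, grads, adam, lr)
    trace[it] <- loss
    if (verbose && it %% 10 == 0)
      message("iter ", it, " loss ", signif(loss, 4))
    if (!is.null(checkpoint_path) &&
        (it %% checkpoint_every == 0 || it == train_cfg$max_iterations))
      saveRDS(list(net = list(par = net$par, state = net$state,
                              plan = net$plan, config = net$config,
                              frozen = net$frozen),
                   iteration = it, trace = trace[1:it],
                   unet_cfg = unet_cfg, train_cfg = train_cfg,
                   recipe = recipe),
              checkpoint_path)
  }
  if (!is.null(trace_path))
    write.csv(data.frame(iteration = seq_along(trace), loss = trace),
              trace_path, row.names = FALSE)
  structure(list(net = net, loss_trace = trace, recipe = recipe,
                 unet_cfg = unet_cfg, train_cfg = train_cfg),
            class = "unet_fit")
}

#' @export
print.unet_fit <- function(x, ...) {
  cat("<unet_fit> recipe ", x$recipe$name, ", ",
      length(x$loss_trace), " iterations, final loss ",
      signif(tail(x$loss_trace, 1), 4), "\n", sep = "")
  print(x$net)
  invisible(x)
}

#' Full-volume inference
#'
#' Pads the volume with zeros to a pooling-compatible shape, runs the
#' network in evaluation mode (dropout off, batch-norm running
#' statistics), takes the per-voxel argmax over the softmax channels and
#' crops the padding away.
#'
#' @param net a `unet` or `unet_fit`.
#' @param image an [mri_image].
#' @return A [label_map] over the configured class labels.
#' @export
predict_volume <- function(net, image) {
  if (inherits(net, "unet_fit")) net <- net$net
  vox <- as_vox_array(image)
  d <- dim(vox)
  fac <- 2^(net$config$levels - 1)
  dp <- as.integer(ceiling(d / fac) * fac)
  if (any(dp != d)) {
    padded <- array(0, dp)
    padded[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- vox
  } else padded <- vox
  fwd <- unet_forward(net, padded, training = FALSE)
  C <- net$config$n_classes
  pm <- matrix(fwd$prob, ncol = C)
  cls <- max.col(pm, ties.method = "first")
  ids <- unname(net$config$class_labels)[cls]
  lab <- array(as.integer(ids), dp)
  lab <- lab[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])]
  vs <- if (inherits(image, "mri_image")) image$voxel_size else c(1, 1, 1)
  label_map(lab, vs, net$config$class_labels)
}

#' @export
predict.unet_fit <- function(object, newdata, ...) {
  predict_volume(object, newdata)
}

#' @export
predict.unet <- function(object, newdata, ...) {
  predict_volume(object, newdata)
}
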