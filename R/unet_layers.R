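# forward / backward passes of the UNet (single sample; batching is an
# outer loop with gradient accumulation)

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

plan_entry <- function(net, name) {
  for (e in net$plan) if (e$name == name) return(e)
  stop("no layer named ", name)
}

row_max <- function(m) {
  out <- m[, 1]
  if (ncol(m) > 1) for (c in 2:ncol(m)) out <- pmax(out, m[, c])
  out
}

# conv / upconv / proj unit: linear op [+ BN + ReLU + dropout]
unit_forward <- function(net, e, x, training) {
  w <- net$par[[paste0(e$name, ".w")]]
  b <- net$par[[paste0(e$name, ".b")]]
  if (e$type == "upconv") {
    z <- upconv2_forward_cpp(x, w, b)
    cache <- list(x = x)
  } else if (training) {
    zc <- conv3_forward_cpp(x, w, b, e$k, TRUE)
    z <- zc$y
    cache <- list(x = x, col = zc$col)
  } else {
    z <- conv3_forward_cpp(x, w, b, e$k)
    cache <- list(x = x)
  }
  d <- dim(z)
  cache$zdim <- d
  zm <- matrix(z, ncol = e$cout)
  if (isTRUE(e$bn)) {
    input_stats <- training ||
      identical(net$config$bn_eval %||% "running", "input")
    if (input_stats) {
      mu <- colMeans(zm)
      v <- colMeans(zm^2) - mu^2
    } else {
      mu <- net$state[[paste0(e$name, ".rmean")]]
      v <- net$state[[paste0(e$name, ".rvar")]]
    }
    if (training) {
      rm <- paste0(e$name, ".rmean"); rv <- paste0(e$name, ".rvar")
      net$state[[rm]] <- (1 - BN_MOMENTUM) * net$state[[rm]] + BN_MOMENTUM * mu
      net$state[[rv]] <- (1 - BN_MOMENTUM) * net$state[[rv]] + BN_MOMENTUM * v
    }
    s <- sqrt(v + BN_EPS)
    xhat <- sweep(sweep(zm, 2, mu, "-"), 2, s, "/")
    gam <- net$par[[paste0(e$name, ".gamma")]]
    bet <- net$par[[paste0(e$name, ".beta")]]
    ym <- sweep(sweep(xhat, 2, gam, "*"), 2, bet, "+")
    cache$xhat <- xhat; cache$s <- s; cache$bn_train <- training
  } else ym <- zm
  if (isTRUE(e$act)) {
    mask <- ym > 0
    ym[!mask] <- 0
    cache$relu <- mask
  }
  if (training && e$dropout > 0) {
    dmask <- (runif(length(ym)) >= e$dropout) / (1 - e$dropout)
    ym <- ym * dmask
    cache$drop <- dmask
  }
  y <- array(ym, d)
  list(y = y, cache = cache)
}

unit_backward <- function(net, e, cache, gy, grads) {
  gm <- matrix(gy, ncol = e$cout)
  if (!is.null(cache$drop)) gm <- gm * cache$drop
  if (!is.null(cache$relu)) gm[!cache$relu] <- 0
  if (isTRUE(e$bn)) {
    gam <- net$par[[paste0(e$name, ".gamma")]]
    grads[[paste0(e$name, ".gamma")]] <-
      (grads[[paste0(e$name, ".gamma")]] %||% 0) + colSums(gm * cache$xhat)
    grads[[paste0(e$name, ".beta")]] <-
      (grads[[paste0(e$name, ".beta")]] %||% 0) + colSums(gm)
    gxh <- sweep(gm, 2, gam, "*")
    if (isTRUE(cache$bn_train)) {
      n <- nrow(gm)
      t1 <- colSums(gxh)
      t2 <- colSums(gxh * cache$xhat)
      gm <- sweep(gxh, 2, t1 / n, "-") -
        sweep(cache$xhat, 2, t2 / n, "*")
      gm <- sweep(gm, 2, cache$s, "/")
    } else {
      gm <- sweep(gxh, 2, cache$s, "/")
    }
  }
  gz <- array(gm, cache$zdim)
  w <- net$par[[paste0(e$name, ".w")]]
  res <- if (e$type == "upconv") upconv2_backward_cpp(cache$x, w, gz)
         else conv3_backward_cpp(cache$x, w, gz, e$k, cache$col)
  grads[[paste0(e$name, ".w")]] <-
    (grads[[paste0(e$name, ".w")]] %||% 0) + res$gw
  grads[[paste0(e$name, ".b")]] <-
    (grads[[paste0(e$name, ".b")]] %||% 0) + res$gb
  res$gx
}

block_forward <- function(net, prefix, x, training) {
  cfg <- net$config
  nconv <- cfg$convs_per_level
  caches <- list()
  u <- unit_forward(net, plan_entry(net, paste0(prefix, "_conv1")), x,
                    training)
  caches$conv1 <- u$cache
  x1 <- u$y
  h <- x1
  if (nconv > 1)
    for (i in 2:nconv) {
      u <- unit_forward(net, plan_entry(net, paste0(prefix, "_conv", i)),
                        h, training)
      caches[[paste0("conv", i)]] <- u$cache
      h <- u$y
    }
  shortcut <- "none"
  if (cfg$residual_skips) {
    proj_name <- paste0(prefix, "_proj")
    has_proj <- any(vapply(net$plan, function(e) e$name == proj_name,
                           logical(1)))
    cin <- plan_entry(net, paste0(prefix, "_conv1"))$cin
    cout <- plan_entry(net, paste0(prefix, "_conv1"))$cout
    if (has_proj) {
      p <- unit_forward(net, plan_entry(net, proj_name), x, training)
      caches$proj <- p$cache
      h <- h + p$y
      shortcut <- "proj"
    } else if (cin == cout) {
      h <- h + x
      shortcut <- "input"
    } else if (nconv > 1) {
      h <- h + x1
      shortcut <- "tail"
    }
  }
  list(y = h, caches = caches, shortcut = shortcut)
}

block_backward <- function(net, prefix, fwd, gy, grads) {
  cfg <- net$config
  nconv <- cfg$convs_per_level
  g <- gy
  gx_extra <- NULL
  if (fwd$shortcut == "proj")
    gx_extra <- unit_backward(net, plan_entry(net, paste0(prefix, "_proj")),
                              fwd$caches$proj, gy, grads)
  if (nconv > 1)
    for (i in nconv:2)
      g <- unit_backward(net, plan_entry(net, paste0(prefix, "_conv", i)),
                         fwd$caches[[paste0("conv", i)]], g, grads)
  if (fwd$shortcut == "tail") g <- g + gy
  gx <- unit_backward(net, plan_entry(net, paste0(prefix, "_conv1")),
                      fwd$caches$conv1, g, grads)
  if (fwd$shortcut == "input") gx <- gx + gy
  if (!is.null(gx_extra)) gx <- gx + gx_extra
  gx
}

concat4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1:3], da[4] + db[4]))
}

check_input_shape <- function(net, d) {
  fac <- 2^(net$config$levels - 1)
  if (any(d[1:3] %% fac != 0))
    stop("input shape (", paste(d[1:3], collapse = "x"),
         ") must be divisible by ", fac,
         "; pad to (", paste(ceiling(d[1:3] / fac) * fac, collapse = "x"),
         ")")
}

unet_forward <- function(net, x, training = FALSE) {
  cfg <- net$config
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  check_input_shape(net, dim(x))
  L <- cfg$levels
  enc <- vector("list", L)
  pool <- vector("list", L)
  a <- x
  for (l in seq_len(L)) {
    enc[[l]] <- block_forward(net, paste0("enc", l), a, training)
    if (l < L) {
      p <- maxpool2_forward_cpp(enc[[l]]$y)
      pool[[l]] <- list(idx = p$idx, in_dim = dim(enc[[l]]$y))
      a <- p$y
    }
  }
  d <- enc[[L]]$y
  dec <- vector("list", L)
  if (L > 1)
    for (l in (L - 1):1) {
      e_up <- plan_entry(net, paste0("dec", l, "_up"))
      if (cfg$upsampling == "trilinear") {
        ut <- upsample2_forward_cpp(d)
        u <- unit_forward(net, e_up, ut, training)
        up_cache <- list(unit = u$cache, tri_dim = dim(d))
      } else {
        u <- unit_forward(net, e_up, d, training)
        up_cache <- list(unit = u$cache)
      }
      cat_in <- concat4(enc[[l]]$y, u$y)
      blk <- block_forward(net, paste0("dec", l), cat_in, training)
      dec[[l]] <- list(up = up_cache, block = blk,
                       skip_ch = dim(enc[[l]]$y)[4])
      d <- blk$y
    }
  fin <- unit_forward(net, plan_entry(net, "final"), d, training)
  logits <- fin$y
  C <- cfg$n_classes
  zm <- matrix(logits, ncol = C)
  zm <- zm - row_max(zm)
  ez <- exp(zm)
  pm <- ez / rowSums(ez)
  prob <- array(pm, dim(logits))
  list(prob = prob,
       cache = list(enc = enc, pool = pool, dec = dec, fin = fin$cache,
                    pm = pm, pdim = dim(logits)))
}

# gprob: gradient of the loss w.r.t. the softmax probabilities
unet_backward <- function(net, cache, gprob, grads = new.env()) {
  cfg <- net$config
  C <- cfg$n_classes
  gm <- matrix(gprob, ncol = C)
  pm <- cache$pm
  glogit <- pm * (gm - rowSums(gm * pm))
  g <- array(glogit, cache$pdim)
  g <- unit_backward(net, plan_entry(net, "final"), cache$fin, g, grads)
  L <- cfg$levels
  g_enc <- vector("list", L) # gradients flowing into encoder outputs
  if (L > 1)
    for (l in seq_len(L - 1)) {
      blk <- cache$dec[[l]]
      gcat <- block_backward(net, paste0("dec", l), blk$block, g, grads)
      sc <- blk$skip_ch
      dgc <- dim(gcat)
      gskip <- array(gcat[, , , seq_len(sc), drop = FALSE],
                     c(dgc[1:3], sc))
      gup <- array(gcat[, , , (sc + 1):dgc[4], drop = FALSE],
                   c(dgc[1:3], dgc[4] - sc))
      e_up <- plan_entry(net, paste0("dec", l, "_up"))
      if (cfg$upsampling == "trilinear") {
        gtri <- unit_backward(net, e_up, blk$up$unit, gup, grads)
        g <- upsample2_backward_cpp(gtri, blk$up$tri_dim)
      } else {
        g <- unit_backward(net, e_up, blk$up$unit, gup, grads)
      }
      g_enc[[l]] <- gskip
      # g now flows to the next deeper decoder/bottleneck output
    }
  # bottleneck and encoder chain
  for (l in L:1) {
    gl <- if (l == L) g else g_enc[[l]] +
      maxpool2_backward_cpp(g, cache$pool[[l]]$idx, cache$pool[[l]]$in_dim)
    g <- block_backward(net, paste0("enc", l), cache$enc[[l]], gl, grads)
  }
  grads
}
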