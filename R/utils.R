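# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Voxel-centre world coordinates (mm), origin at the volume centre.
axis_coords <- function(n, w) (seq_len(n) - (n + 1) / 2) * w

# Shift a 3D array by integer voxels, filling vacated voxels with `fill`.
shift_array <- function(x, by, fill = 0) {
  d <- dim(x)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    s <- by[a]
    if (abs(s) >= d[a]) return(out)
    if (s >= 0) {
      dst[[a]] <- (1 + s):d[a]; src[[a]] <- 1:(d[a] - s)
    } else {
      dst[[a]] <- 1:(d[a] + s); src[[a]] <- (1 - s):d[a]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

# Logical 6-neighbourhood dilation (array borders treated as FALSE).
dilate6 <- function(m) {
  out <- m
  for (a in 1:3) for (s in c(-1, 1)) {
    by <- c(0, 0, 0); by[a] <- s
    out <- out | shift_array(m, by, FALSE)
  }
  out
}

# Connected region grown from `seed_mask` through `allowed`, 6-connectivity.
flood_fill <- function(seed_mask, allowed) {
  cur <- seed_mask & allowed
  repeat {
    nxt <- (cur | dilate6(cur)) & allowed
    if (identical(nxt, cur)) return(cur)
    cur <- nxt
  }
}

# Boundary voxels of a mask: mask voxels with an exposed 6-face.
boundary_voxels <- function(mask) {
  interior <- mask
  for (a in 1:3) for (s in c(-1, 1)) {
    by <- c(0, 0, 0); by[a] <- s
    interior <- interior & shift_array(mask, by, FALSE)
  }
  mask & !interior
}

# Total area (mm^2) of faces between two disjoint masks.
interface_area <- function(mask_a, mask_b, voxel_size = c(1, 1, 1)) {
  face <- c(voxel_size[2] * voxel_size[3],
            voxel_size[1] * voxel_size[3],
            voxel_size[1] * voxel_size[2])
  total <- 0
  for (a in 1:3) for (s in c(-1, 1)) {
    by <- c(0, 0, 0); by[a] <- s
    total <- total + sum(mask_a & shift_array(mask_b, by, FALSE)) * face[a]
  }
  total
}

as_vox_array <- function(x) {
  if (inherits(x, c("mri_image", "label_map"))) x$voxels else x
}
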