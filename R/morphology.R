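# Binary morphology on 3-D logical arrays (6-connectivity), pure vectorized R.

# shift a 3-D array by one voxel along an axis, filling with `fill`
shift1 <- function(a, axis, dir, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  idx_src <- idx_dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  n <- d[axis]
  if (n < 2L) return(out)
  if (dir > 0) {           # contents move toward larger index
    idx_src[[axis]] <- 1:(n - 1L)
    idx_dst[[axis]] <- 2:n
  } else {
    idx_src[[axis]] <- 2:n
    idx_dst[[axis]] <- 1:(n - 1L)
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

border_mask <- function(shape) {
  m <- array(FALSE, shape)
  m[c(1, shape[1]), , ] <- TRUE
  m[, c(1, shape[2]), ] <- TRUE
  m[, , c(1, shape[3])] <- TRUE
  m
}

# directional sweep: propagate `reach` through `allowed` along one axis,
# one full scan in each direction (vectorized over the other two axes)
sweep_axis <- function(reach, allowed, axis) {
  d <- dim(reach)
  n <- d[axis]
  idx <- function(i) switch(axis,
                            list(i, seq_len(d[2]), seq_len(d[3])),
                            list(seq_len(d[1]), i, seq_len(d[3])),
                            list(seq_len(d[1]), seq_len(d[2]), i))
  for (i in 2:n) {
    j0 <- idx(i); j1 <- idx(i - 1L)
    reach[j0[[1]], j0[[2]], j0[[3]]] <-
      reach[j0[[1]], j0[[2]], j0[[3]]] |
      (reach[j1[[1]], j1[[2]], j1[[3]]] & allowed[j0[[1]], j0[[2]], j0[[3]]])
  }
  for (i in (n - 1L):1L) {
    j0 <- idx(i); j1 <- idx(i + 1L)
    reach[j0[[1]], j0[[2]], j0[[3]]] <-
      reach[j0[[1]], j0[[2]], j0[[3]]] |
      (reach[j1[[1]], j1[[2]], j1[[3]]] & allowed[j0[[1]], j0[[2]], j0[[3]]])
  }
  reach
}

# 6-connected flood fill: all voxels of `allowed` reachable from `seeds`.
# Alternating raster sweeps along the three axes until fixpoint; converges
# in a handful of passes for anatomical shapes.
flood_fill6 <- function(allowed, seeds) {
  stopifnot(identical(dim(allowed), dim(seeds)))
  reach <- seeds & allowed
  if (!any(reach)) return(reach)
  repeat {
    prev <- reach
    for (ax in 1:3) reach <- sweep_axis(reach, allowed, ax)
    if (identical(reach, prev)) break
  }
  reach
}

# one-step 6-connectivity erosion along the given axes
erode1 <- function(m, axes = 1:3) {
  out <- m
  for (ax in axes) {
    out <- out & shift1(m, ax, +1L, fill = FALSE) & shift1(m, ax, -1L, fill = FALSE)
  }
  out
}

# erosion by an anisotropic radius (voxels per axis)
erode_mask <- function(m, radius_vox) {
  radius_vox <- as.integer(radius_vox)
  stopifnot(length(radius_vox) == 3L, all(radius_vox >= 0L))
  out <- m
  for (ax in 1:3) {
    r <- radius_vox[ax]
    while (r > 0L) {
      out <- out & shift1(out, ax, +1L) & shift1(out, ax, -1L)
      r <- r - 1L
    }
  }
  out
}

# label connected components of a logical mask (6-connectivity); returns an
# integer array, 0 = background, components numbered by decreasing size
label_components6 <- function(mask, max_components = 32L) {
  lab <- array(0L, dim(mask))
  remaining <- mask
  k <- 0L
  sizes <- integer(0)
  while (any(remaining) && k < max_components) {
    k <- k + 1L
    seed_idx <- which(remaining)[1]
    seeds <- array(FALSE, dim(mask)); seeds[seed_idx] <- TRUE
    comp <- flood_fill6(remaining, seeds)
    lab[comp] <- k
    sizes <- c(sizes, sum(comp))
    remaining <- remaining & !comp
  }
  if (any(remaining))
    stop("label_components6(): more than ", max_components, " components")
  # renumber by decreasing size
  ord <- order(sizes, decreasing = TRUE)
  relab <- integer(k); relab[ord] <- seq_len(k)
  out <- lab
  for (i in seq_len(k)) out[lab == i] <- relab[i]
  out
}
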