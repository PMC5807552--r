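# Small 3D array routines used by spot segmentation. Arrays are indexed
# [z, y, x]; voxel coordinates reported to users are 0-based with the
# origin at voxel (0,0,0), physical position = coordinate * voxel size.

# slice an array along one axis with an index vector
index_axis3 <- function(a, axis, idx) {
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

gaussian_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian smoothing with edge-replicate padding
blur3d <- function(a, sigma) {
  stopifnot(length(dim(a)) == 3, sigma > 0)
  d <- dim(a)
  k <- gaussian_kernel1d(sigma)
  r <- (length(k) - 1L) / 2L
  for (axis in 1:3) {
    out <- array(0, d)
    for (j in seq_along(k)) {
      idx <- pmin(pmax(seq_len(d[axis]) + (j - r - 1L), 1L), d[axis])
      out <- out + k[j] * index_axis3(a, axis, idx)
    }
    a <- out
  }
  a
}

# Otsu threshold: maximizes between-class variance over a 256-bin histogram
otsu_threshold <- function(x, nbins = 256L) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  h <- tabulate(pmin(as.integer((x - rng[1]) / diff(rng) * nbins) + 1L,
                     nbins), nbins)
  w <- h / sum(h)
  mids <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  cw <- cumsum(w)
  cm <- cumsum(w * mids)
  mu <- cm[nbins]
  bcv <- (mu * cw - cm)^2 / (cw * (1 - cw))
  bcv[!is.finite(bcv)] <- -Inf
  mids[which.max(bcv[-nbins])]
}

# shift a logical array by (dz, dy, dx), filling exposed voxels with `fill`
shift3 <- function(a, dz, dy, dx, fill) {
  d <- dim(a)
  src <- function(n, s) {
    i <- seq_len(n) - s
    i[i < 1 | i > n] <- NA
    i
  }
  out <- a[src(d[1], dz), src(d[2], dy), src(d[3], dx), drop = FALSE]
  out[is.na(out)] <- fill
  out
}

box_op3 <- function(mask, op, fill) {
  acc <- NULL
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    s <- shift3(mask, dz, dy, dx, fill)
    acc <- if (is.null(acc)) s else op(acc, s)
  }
  acc
}

# morphological closing with a 3x3x3 box (dilate, then erode)
close3d <- function(mask) {
  box_op3(box_op3(mask, `|`, FALSE), `&`, TRUE)
}

# connected-component labelling, 26-connectivity, BFS over linear indices
label_components_3d <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, d)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  n_off <- nrow(offs)
  cur <- 0L
  for (s in which(mask)) {
    if (labels[s] > 0L) next
    cur <- cur + 1L
    labels[s] <- cur
    frontier <- s
    while (length(frontier) > 0) {
      co <- arrayInd(frontier, d)
      nb <- co[rep(seq_len(nrow(co)), each = n_off), , drop = FALSE] +
        offs[rep(seq_len(n_off), nrow(co)), , drop = FALSE]
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
        nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- unique(nb[, 1] + (nb[, 2] - 1L) * d[1] +
                      (nb[, 3] - 1L) * d[1] * d[2])
      lin <- lin[mask[lin] & labels[lin] == 0L]
      labels[lin] <- cur
      frontier <- lin
    }
  }
  labels
}

# trilinear interpolation at continuous 0-based (z, y, x) positions
trilinear3 <- function(a, pz, py, px) {
  d <- dim(a)
  stopifnot(all(pz >= 0 & pz <= d[1] - 1),
            all(py >= 0 & py <= d[2] - 1),
            all(px >= 0 & px <= d[3] - 1))
  z0 <- pmin(floor(pz), d[1] - 2); z0 <- pmax(z0, 0)
  y0 <- pmin(floor(py), d[2] - 2); y0 <- pmax(y0, 0)
  x0 <- pmin(floor(px), d[3] - 2); x0 <- pmax(x0, 0)
  fz <- pz - z0; fy <- py - y0; fx <- px - x0
  at <- function(dz, dy, dx)
    a[cbind(pmin(z0 + dz, d[1] - 1) + 1, pmin(y0 + dy, d[2] - 1) + 1,
            pmin(x0 + dx, d[3] - 1) + 1)]
  (1 - fz) * ((1 - fy) * ((1 - fx) * at(0, 0, 0) + fx * at(0, 0, 1)) +
                fy * ((1 - fx) * at(0, 1, 0) + fx * at(0, 1, 1))) +
    fz * ((1 - fy) * ((1 - fx) * at(1, 0, 0) + fx * at(1, 0, 1)) +
            fy * ((1 - fx) * at(1, 1, 0) + fx * at(1, 1, 1)))
}
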