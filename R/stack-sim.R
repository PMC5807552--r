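#' Configuration for the 3D two-channel stack simulator
#'
#' Spots are spherical objects; the binary support of a spot is the set of
#' voxels whose centre lies within `radius` of the spot centre. With
#' `profile = "flat"` (default) a spot has uniform intensity `peak` over
#' its support -- the rendered intensity support then coincides with the
#' binary support on which overlap ground truth is defined. With
#' `profile = "gaussian"` the intensity falls off as
#' `peak * exp(-d^2 / (2 * (radius/2)^2))`, truncated at `radius`.
#' Centres and radii are in (continuous, 0-based) voxel coordinates.
#'
#' @param dim Stack dimensions `(z, y, x)` in voxels.
#' @param voxel_size Voxel edge length(s) in micrometres.
#' @param spots data.frame with columns `channel` (1 or 2), `z`, `y`, `x`,
#'   `radius`, `peak`; may have zero rows for a blank stack.
#' @param profile Radial intensity profile, `"flat"` or `"gaussian"`.
#' @param poisson_noise Apply Poisson shot noise to the rendered
#'   intensities.
#' @param gaussian_sd Standard deviation of additive Gaussian read noise
#'   (0 = off).
#' @param seed Integer seed; fixed seed gives a bit-identical stack.
#' @return A list of class `image_sim_config`.
#' @export
image_sim_config <- function(dim = c(16, 64, 64), voxel_size = 0.2,
                             spots = data.frame(channel = integer(0),
                                                z = numeric(0),
                                                y = numeric(0),
                                                x = numeric(0),
                                                radius = numeric(0),
                                                peak = numeric(0)),
                             profile = c("flat", "gaussian"),
                             poisson_noise = FALSE, gaussian_sd = 0,
                             seed = 1) {
  profile <- match.arg(profile)
  stopifnot(length(dim) == 3, all(dim >= 1),
            all(c("channel", "z", "y", "x", "radius", "peak") %in%
                  colnames(spots)),
            gaussian_sd >= 0)
  if (nrow(spots) > 0) {
    lim <- matrix(dim - 1, nrow(spots), 3, byrow = TRUE)
    pos <- as.matrix(spots[, c("z", "y", "x")])
    if (any(pos - spots$radius < 0) || any(pos + spots$radius > lim))
      stop("spot(s) extend beyond the stack bounds")
    stopifnot(all(spots$radius > 0), all(spots$peak > 0),
              all(spots$channel %in% 1:2))
  }
  structure(list(dim = dim, voxel_size = rep_len(voxel_size, 3),
                 spots = spots, profile = profile,
                 poisson_noise = poisson_noise,
                 gaussian_sd = gaussian_sd, seed = seed),
            class = "image_sim_config")
}

# linear voxel indices of a voxelized sphere, [z,y,x] grid, 0-based centre
sphere_voxels <- function(dim, center, radius) {
  lo <- pmax(floor(center - radius), 0)
  hi <- pmin(ceiling(center + radius), dim - 1)
  g <- expand.grid(z = lo[1]:hi[1], y = lo[2]:hi[2], x = lo[3]:hi[3])
  d2 <- (g$z - center[1])^2 + (g$y - center[2])^2 + (g$x - center[3])^2
  g <- g[d2 <= radius^2, , drop = FALSE]
  g$z + 1 + g$y * dim[1] + g$x * dim[1] * dim[2]
}

#' Centre distance achieving a target voxelized sphere overlap
#'
#' Searches (by bisection on the centre-to-centre distance) for the offset
#' at which two voxelized spheres overlap by the target fraction,
#' `|A intersect B| / |A|`. The voxelized overlap is a non-increasing step
#' function of distance, so the search converges to the step nearest the
#' target; if no distance reaches within `tol` of the target (e.g. sphere B
#' too small to cover the target fraction of A), an error is raised.
#'
#' @param radius_a,radius_b Sphere radii in voxels.
#' @param overlap Target overlap fraction in `[0, 1]`.
#' @param tol Acceptable deviation of the achieved fraction (default 0.05).
#' @return list with `distance` (voxels, along x), `achieved` overlap
#'   fraction.
#' @export
spot_pair_distance <- function(radius_a, radius_b = radius_a, overlap,
                               tol = 0.05) {
  stopifnot(radius_a > 0, radius_b > 0, overlap >= 0, overlap <= 1)
  # integer-aligned scratch centre so the voxelization matches spots
  # rendered at integer centres
  ext <- ceiling(2 * (radius_a + radius_b)) + 5
  dim <- c(ext, ext, 2 * ext)
  ca <- floor(c(ext / 2, ext / 2, ext / 2))
  frac_at <- function(d) {
    a <- sphere_voxels(dim, ca, radius_a)
    b <- sphere_voxels(dim, ca + c(0, 0, d), radius_b)
    sum(a %in% b) / length(a)
  }
  lo <- 0; hi <- radius_a + radius_b + 1
  f_lo <- frac_at(lo)
  if (f_lo < overlap - tol)
    stop(sprintf("target overlap %.2f unreachable: maximum achievable is %.2f (radius mismatch)",
                 overlap, f_lo))
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (frac_at(mid) >= overlap) lo <- mid else hi <- mid
  }
  cand <- c(lo, hi)
  ach <- vapply(cand, frac_at, numeric(1))
  best <- which.min(abs(ach - overlap))
  if (abs(ach[best] - overlap) > tol)
    stop(sprintf("target overlap %.2f unreachable within tolerance %.2f (closest %.2f)",
                 overlap, tol, ach[best]))
  list(distance = cand[best], achieved = ach[best])
}

#' Place a spot pair at a target overlap fraction
#'
#' Convenience wrapper around [spot_pair_distance()]: returns two spot-spec
#' rows (channel 1 and channel 2) centred around `center`, offset along x
#' so that their binary supports overlap by the target fraction.
#'
#' @param center Length-3 `(z, y, x)` 0-based voxel centre of channel-1
#'   spot.
#' @param radius Sphere radius (voxels) of both spots.
#' @param overlap Target overlap fraction.
#' @param peak Peak intensity of both spots.
#' @return data.frame of two spot-spec rows for [image_sim_config()].
#' @export
spot_pair_at_overlap <- function(center, radius, overlap, peak = 100) {
  d <- spot_pair_distance(radius, radius, overlap)$distance
  data.frame(channel = c(1L, 2L),
             z = center[1], y = center[2], x = c(center[3], center[3] + d),
             radius = radius, peak = peak)
}

#' Simulate a two-channel 3D image stack with ground truth
#'
#' Renders every spot of the configuration into its channel, applies the
#' noise model last (Poisson shot noise then additive Gaussian), and
#' returns the true spot table along with the pairwise overlap fractions
#' `|A intersect B| / |A|` of the noise-free binary supports between
#' channel-1 and channel-2 spots.
#'
#' @param cfg An [image_sim_config()].
#' @return list of class `sim_stack`: `stack` (4D array
#'   `[channel, z, y, x]`), `truth` (list with `spots` data.frame including
#'   voxel volumes, and `overlaps` data.frame `spot_a`, `spot_b`,
#'   `overlap`), `cfg`.
#' @export
simulate_image_stack <- function(cfg = image_sim_config()) {
  stopifnot(inherits(cfg, "image_sim_config"))
  set.seed(cfg$seed)
  d <- cfg$dim
  channels <- list(array(0, d), array(0, d))
  supports <- vector("list", nrow(cfg$spots))
  for (i in seq_len(nrow(cfg$spots))) {
    sp <- cfg$spots[i, ]
    vox <- sphere_voxels(d, c(sp$z, sp$y, sp$x), sp$radius)
    supports[[i]] <- vox
    ch <- sp$channel
    if (cfg$profile == "flat") {
      channels[[ch]][vox] <- channels[[ch]][vox] + sp$peak
    } else {
      co <- arrayInd(vox, d) - 1
      dist2 <- (co[, 1] - sp$z)^2 + (co[, 2] - sp$y)^2 + (co[, 3] - sp$x)^2
      sigma <- sp$radius / 2
      channels[[ch]][vox] <- channels[[ch]][vox] +
        sp$peak * exp(-dist2 / (2 * sigma^2))
    }
  }
  ia <- which(cfg$spots$channel == 1L)
  ib <- which(cfg$spots$channel == 2L)
  overlaps <- expand.grid(spot_a = ia, spot_b = ib)
  overlaps$overlap <- mapply(function(a, b)
    sum(supports[[a]] %in% supports[[b]]) / length(supports[[a]]),
    overlaps$spot_a, overlaps$spot_b)
  if (nrow(overlaps) == 0)
    overlaps <- data.frame(spot_a = integer(0), spot_b = integer(0),
                           overlap = numeric(0))
  truth_spots <- cfg$spots
  truth_spots$volume_vox <- vapply(supports, length, integer(1))

  stack <- array(0, c(2, d))
  for (ch in 1:2) {
    a <- channels[[ch]]
    if (cfg$poisson_noise) a <- array(rpois(length(a), a), d)
    if (cfg$gaussian_sd > 0)
      a <- a + array(rnorm(length(a), 0, cfg$gaussian_sd), d)
    stack[ch, , , ] <- a
  }
  structure(list(stack = stack,
                 truth = list(spots = truth_spots, overlaps = overlaps,
                              supports = supports),
                 cfg = cfg), class = "sim_stack")
}

#' Write / read a two-channel stack as multi-page TIFF + JSON sidecar
#'
#' Pages are channel-major (all z slices of channel 1, then channel 2).
#' Sample values are stored scaled into `[0, 1]` by the stack maximum; the
#' scale factor, dimensions, channel count and voxel size are recorded in a
#' `<path>.json` sidecar and the original scale is restored on read
#' (32-bit storage; round-trip exact to ~2^-32 relative).
#'
#' @param stack 4D array `[channel, z, y, x]` (or a `sim_stack`).
#' @param path TIFF file path; the sidecar is written at `<path>.json`.
#' @param voxel_size Voxel edge length(s) in micrometres.
#' @return `write_stack` returns `path` invisibly; `read_stack` a list with
#'   `stack` (4D array) and `voxel_size`.
#' @export
write_stack <- function(stack, path, voxel_size = 1) {
  if (inherits(stack, "sim_stack")) {
    voxel_size <- stack$cfg$voxel_size
    stack <- stack$stack
  }
  stopifnot(length(dim(stack)) == 4)
  d <- dim(stack)
  mx <- max(stack, 1e-12)
  if (min(stack) < 0) stop("negative intensities cannot be stored")
  pages <- list()
  for (ch in seq_len(d[1])) for (z in seq_len(d[2]))
    pages[[length(pages) + 1]] <- matrix(stack[ch, z, , ] / mx,
                                         d[3], d[4])
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  meta <- list(n_channels = d[1], dim_zyx = d[2:4],
               voxel_size_um = rep_len(voxel_size, 3), scale = mx)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- c(meta$n_channels, meta$dim_zyx)
  stack <- array(0, d)
  k <- 0
  for (ch in seq_len(d[1])) for (z in seq_len(d[2])) {
    k <- k + 1
    stack[ch, z, , ] <- pages[[k]] * meta$scale
  }
  list(stack = stack, voxel_size = meta$voxel_size_um)
}
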