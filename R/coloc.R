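#' Detect 3D spots in a single-channel stack
#'
#' Segments vesicle-like objects: the stack is band-pass filtered as a
#' difference of Gaussian smoothings (`sigma_low` minus `sigma_high`), a
#' threshold is applied (Otsu on the filtered stack by default), the binary
#' mask is reshaped by a 3x3x3 morphological closing, and connected
#' components (26-connectivity) become candidate objects. Candidates
#' failing `volume >= min_size`, `mean intensity >= intensity_min` or
#' `CV <= cv_max` are dropped as false positives. All retained-object
#' statistics (mean intensity, CV) are computed on the original,
#' unfiltered intensities.
#'
#' The mean-intensity and CV filters are off by default
#' (`intensity_min = 0`, `cv_max = Inf`); their working values depend on
#' the imaging setup and must be calibrated per dataset.
#'
#' @param stack 3D numeric array `[z, y, x]` of one channel.
#' @param voxel_size Voxel edge length(s) in micrometres; scalar or length-3
#'   `(z, y, x)`.
#' @param sigma_low,sigma_high Gaussian sigmas (voxels) of the band-pass;
#'   `sigma_low < sigma_high`.
#' @param threshold Either `"otsu"` or a numeric threshold applied to the
#'   band-pass-filtered stack.
#' @param min_size Minimum object volume in voxels.
#' @param intensity_min Minimum object mean intensity (original scale).
#' @param cv_max Maximum coefficient of variation (SD/mean of member voxel
#'   intensities).
#' @param channel Channel id stored with the result.
#' @return Object of class `spot_set`: list with `spots` (data.frame:
#'   `spot_id`, `volume_vox`, `volume_um3`, `mean_intensity`, `cv`,
#'   `centroid_z/y/x` in 0-based voxel coordinates), `voxels` (list of
#'   linear-index vectors), `dim`, `voxel_size`, `channel`.
#' @export
detect_spots <- function(stack, voxel_size = 1, sigma_low = 1,
                         sigma_high = 5, threshold = "otsu",
                         min_size = 5, intensity_min = 0, cv_max = Inf,
                         channel = 1L) {
  if (length(dim(stack)) != 3)
    stop("stack must be a 3D single-channel array [z, y, x]")
  if (sigma_low >= sigma_high)
    stop("sigma_low must be smaller than sigma_high")
  voxel_size <- rep_len(voxel_size, 3)

  dog <- blur3d(stack, sigma_low) - blur3d(stack, sigma_high)
  thr <- if (identical(threshold, "otsu")) otsu_threshold(dog)
         else as.numeric(threshold)
  mask <- dog > thr
  if (any(mask)) mask <- close3d(mask)
  labels <- label_components_3d(mask)
  n <- max(labels)
  spots <- list(); voxels <- list()
  d <- dim(stack)
  for (i in seq_len(n)) {
    vox <- which(labels == i)
    vals <- stack[vox]
    m <- mean(vals)
    cv <- if (m > 0) sd(vals) / m else 0
    if (length(vals) == 1) cv <- 0
    if (length(vox) < min_size || m < intensity_min || cv > cv_max) next
    co <- arrayInd(vox, d) - 1  # 0-based
    spots[[length(spots) + 1]] <- data.frame(
      volume_vox = length(vox),
      volume_um3 = length(vox) * prod(voxel_size),
      mean_intensity = m, cv = cv,
      centroid_z = mean(co[, 1]), centroid_y = mean(co[, 2]),
      centroid_x = mean(co[, 3]))
    voxels[[length(spots)]] <- vox
  }
  spots <- if (length(spots) > 0) do.call(rbind, spots) else
    data.frame(volume_vox = integer(0), volume_um3 = numeric(0),
               mean_intensity = numeric(0), cv = numeric(0),
               centroid_z = numeric(0), centroid_y = numeric(0),
               centroid_x = numeric(0))
  spots <- cbind(spot_id = seq_len(nrow(spots)), spots)
  rownames(spots) <- NULL
  structure(list(spots = spots, voxels = voxels, dim = d,
                 voxel_size = voxel_size, channel = channel),
            class = "spot_set")
}

#' Build a spot set from explicit voxel membership
#'
#' Constructor used for simulated ground truth and for tests; statistics
#' are computed from the voxel sets and an optional intensity stack.
#'
#' @param voxels List of integer vectors of linear voxel indices (disjoint
#'   within the set).
#' @param dim Stack dimensions `(z, y, x)`.
#' @param stack Optional intensity array for mean/CV statistics.
#' @param voxel_size Voxel size in micrometres.
#' @param channel Channel id.
#' @return A `spot_set`.
#' @export
spot_set <- function(voxels, dim, stack = NULL, voxel_size = 1,
                     channel = 1L) {
  voxel_size <- rep_len(voxel_size, 3)
  all_vox <- unlist(voxels)
  if (anyDuplicated(all_vox) > 0)
    stop("objects within one channel must be disjoint")
  rows <- lapply(voxels, function(vox) {
    vals <- if (is.null(stack)) rep(1, length(vox)) else stack[vox]
    m <- mean(vals)
    co <- arrayInd(vox, dim) - 1
    data.frame(volume_vox = length(vox),
               volume_um3 = length(vox) * prod(voxel_size),
               mean_intensity = m,
               cv = if (length(vals) > 1 && m > 0) sd(vals) / m else 0,
               centroid_z = mean(co[, 1]), centroid_y = mean(co[, 2]),
               centroid_x = mean(co[, 3]))
  })
  spots <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(volume_vox = integer(0), volume_um3 = numeric(0),
               mean_intensity = numeric(0), cv = numeric(0),
               centroid_z = numeric(0), centroid_y = numeric(0),
               centroid_x = numeric(0))
  spots <- cbind(spot_id = seq_len(nrow(spots)), spots)
  rownames(spots) <- NULL
  structure(list(spots = spots, voxels = voxels, dim = dim,
                 voxel_size = voxel_size, channel = channel),
            class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("spot set (channel %s): %d object(s), %s voxels total\n",
              x$channel, nrow(x$spots),
              format(sum(x$spots$volume_vox), big.mark = ",")))
  invisible(x)
}

#' Classify two-channel spot overlap (double-positive calling)
#'
#' Overlap is computed on binary voxel supports, so it is invariant to any
#' global intensity rescaling. For each spot in `spots_a` the overlap
#' fraction against the union of all `spots_b` voxels is
#' `|A intersect B_union| / |A|`. Matched pairs (A-spot, B-spot with a
#' non-empty intersection) carry both directional fractions
#' `|A intersect B| / |A|` and `|A intersect B| / |B|`; a pair is double
#' positive when either directional fraction strictly exceeds `threshold`
#' ("more than 40% overlap" by default -- exactly 40% does not qualify).
#' An A-spot is double positive when its union fraction or any of its
#' pairs' B-directional fractions strictly exceeds the threshold.
#'
#' @param spots_a,spots_b `spot_set` objects on the same voxel grid.
#' @param threshold Strict overlap threshold (default 0.40).
#' @param cells Optional integer array (same grid) of cell labels; per-cell
#'   double-positive counts are aggregated by the cell label at each
#'   A-spot's rounded centroid.
#' @return Object of class `coloc_result`: list with `spots` (per A-spot:
#'   `spot_id`, `overlap_union`, `double_positive`, `cell`), `pairs`
#'   (`spot_a`, `spot_b`, `n_intersect`, `frac_a`, `frac_b`,
#'   `double_positive`), `cell_counts` (`cell`, `n_double_positive`), and
#'   `threshold`.
#' @export
overlap_classify <- function(spots_a, spots_b, threshold = 0.40,
                             cells = NULL) {
  stopifnot(inherits(spots_a, "spot_set"), inherits(spots_b, "spot_set"))
  if (!identical(spots_a$dim, spots_b$dim))
    stop("spot sets come from different voxel grids")
  b_union <- unique(unlist(spots_b$voxels))
  n_a <- length(spots_a$voxels)

  pairs <- list()
  overlap_union <- numeric(n_a)
  dp <- logical(n_a)
  for (i in seq_len(n_a)) {
    a_vox <- spots_a$voxels[[i]]
    inter_union <- sum(a_vox %in% b_union)
    overlap_union[i] <- inter_union / length(a_vox)
    best_b_frac <- 0
    for (j in seq_along(spots_b$voxels)) {
      n_int <- sum(a_vox %in% spots_b$voxels[[j]])
      if (n_int == 0) next
      fa <- n_int / length(a_vox)
      fb <- n_int / length(spots_b$voxels[[j]])
      pairs[[length(pairs) + 1]] <- data.frame(
        spot_a = i, spot_b = j, n_intersect = n_int,
        frac_a = fa, frac_b = fb,
        double_positive = max(fa, fb) > threshold)
      best_b_frac <- max(best_b_frac, fb)
    }
    dp[i] <- max(overlap_union[i], best_b_frac) > threshold
  }
  pairs <- if (length(pairs) > 0) do.call(rbind, pairs) else
    data.frame(spot_a = integer(0), spot_b = integer(0),
               n_intersect = integer(0), frac_a = numeric(0),
               frac_b = numeric(0), double_positive = logical(0))

  cell <- rep("all", n_a)
  if (!is.null(cells)) {
    stopifnot(identical(dim(cells), spots_a$dim))
    cen <- round(as.matrix(spots_a$spots[, c("centroid_z", "centroid_y",
                                             "centroid_x")])) + 1
    cell <- as.character(cells[cen])
  }
  spots_df <- data.frame(spot_id = seq_len(n_a),
                         overlap_union = overlap_union,
                         double_positive = dp, cell = cell,
                         stringsAsFactors = FALSE)
  if (n_a == 0) {
    counts <- data.frame(cell = character(0), n_double_positive = integer(0))
  } else {
    counts <- aggregate(spots_df$double_positive,
                        by = list(cell = spots_df$cell), FUN = sum)
    names(counts)[2] <- "n_double_positive"
  }
  structure(list(spots = spots_df, pairs = pairs, cell_counts = counts,
                 threshold = threshold), class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("colocalization: %d A-spot(s), %d double positive (> %.0f%% overlap)\n",
              nrow(x$spots), sum(x$spots$double_positive),
              100 * x$threshold))
  invisible(x)
}

#' Percentage of vesicles containing a cargo spot
#'
#' A vesicle contains cargo when at least one cargo-spot centroid, rounded
#' to the nearest voxel, lies inside the vesicle's voxel set (e.g.
#' LAMP2-positive vesicles containing LC3B-positive aggregates, a proxy for
#' autolysosome formation).
#'
#' @param vesicles,cargo `spot_set` objects on the same grid.
#' @return Percentage (0-100) of vesicles containing cargo.
#' @export
containment_percent <- function(vesicles, cargo) {
  stopifnot(inherits(vesicles, "spot_set"), inherits(cargo, "spot_set"))
  if (!identical(vesicles$dim, cargo$dim))
    stop("spot sets come from different voxel grids")
  if (length(vesicles$voxels) == 0)
    stop("empty vesicle set: containment percentage undefined")
  if (length(cargo$voxels) == 0) return(0)
  d <- vesicles$dim
  cen <- round(as.matrix(cargo$spots[, c("centroid_z", "centroid_y",
                                         "centroid_x")]))
  cen_lin <- cen[, 1] + 1 + cen[, 2] * d[1] + cen[, 3] * d[1] * d[2]
  containing <- vapply(vesicles$voxels, function(vox)
    any(cen_lin %in% vox), logical(1))
  100 * sum(containing) / length(containing)
}

#' Intensity line profile through a stack
#'
#' Samples one or more channels along a straight segment by trilinear
#' interpolation at equally spaced points. With segment length `L` and
#' sample spacing `s`, `round(L / s) + 1` samples are taken from start to
#' end. Positions are physical (micrometres); voxel `(0,0,0)`'s centre is
#' the origin.
#'
#' @param stack A 3D array, a list of 3D arrays (channels), or a 4D array
#'   `[channel, z, y, x]`.
#' @param start_um,end_um Numeric length-3 `(z, y, x)` endpoints in
#'   micrometres.
#' @param spacing_um Sample spacing in micrometres.
#' @param voxel_size Voxel edge length(s) in micrometres.
#' @return Object of class `line_profile`: list with `distance_um` (length
#'   n) and `intensity` (n x channels matrix), plus `spacing_um`.
#' @examples
#' a <- array(5, c(4, 8, 8))
#' p <- line_profile(a, c(1, 1, 1), c(1, 1, 6), spacing_um = 0.5)
#' all(p$intensity == 5)
#' @export
line_profile <- function(stack, start_um, end_um, spacing_um = 0.1,
                         voxel_size = 1) {
  if (is.array(stack) && length(dim(stack)) == 4)
    stack <- lapply(seq_len(dim(stack)[1]), function(c_)
      array(stack[c_, , , ], dim(stack)[-1]))
  if (!is.list(stack)) stack <- list(stack)
  stopifnot(all(vapply(stack, function(a) length(dim(a)) == 3, logical(1))),
            length(start_um) == 3, length(end_um) == 3, spacing_um > 0)
  voxel_size <- rep_len(voxel_size, 3)
  len <- sqrt(sum((end_um - start_um)^2))
  n <- round(len / spacing_um) + 1
  t <- if (n == 1) 0 else seq(0, 1, length.out = n)
  pts_um <- outer(t, end_um - start_um) +
    matrix(start_um, n, 3, byrow = TRUE)
  pz <- pts_um[, 1] / voxel_size[1]
  py <- pts_um[, 2] / voxel_size[2]
  px <- pts_um[, 3] / voxel_size[3]
  d <- dim(stack[[1]])
  if (any(pz < 0 | pz > d[1] - 1 | py < 0 | py > d[2] - 1 |
            px < 0 | px > d[3] - 1))
    stop("segment leaves the stack bounds")
  intensity <- vapply(stack, function(a) trilinear3(a, pz, py, px),
                      numeric(n))
  intensity <- matrix(intensity, nrow = n,
                      dimnames = list(NULL, sprintf("channel_%d",
                                                    seq_along(stack))))
  structure(list(distance_um = t * len, intensity = intensity,
                 spacing_um = spacing_um), class = "line_profile")
}
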