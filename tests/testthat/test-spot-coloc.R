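# voxel-set helpers: axis-aligned boxes make intersection sizes exact
box_voxels <- function(dim, z, y, x) {
  g <- expand.grid(z = z, y = y, x = x)
  g$z + 1 + g$y * dim[1] + g$x * dim[1] * dim[2]
}

test_that("a blank stack yields an empty spot set", {
  s <- detect_spots(array(0, c(6, 12, 12)))
  expect_equal(nrow(s$spots), 0)
  expect_equal(length(s$voxels), 0)
})

test_that("detect_spots validates its input", {
  expect_error(detect_spots(matrix(0, 4, 4)), "3D")
  expect_error(detect_spots(array(0, c(4, 4, 4)), sigma_low = 5,
                            sigma_high = 2), "sigma_low")
})

test_that("a single simulated spot is recovered with its centroid within one voxel", {
  spot <- data.frame(channel = 1L, z = 7, y = 15, x = 12, radius = 3,
                     peak = 100)
  sim <- simulate_image_stack(image_sim_config(dim = c(15, 30, 30),
                                               spots = spot, seed = 1))
  det <- detect_spots(array(sim$stack[1, , , ], c(15, 30, 30)))
  expect_equal(nrow(det$spots), 1)
  expect_lt(abs(det$spots$centroid_z - 7), 1)
  expect_lt(abs(det$spots$centroid_y - 15), 1)
  expect_lt(abs(det$spots$centroid_x - 12), 1)
})

test_that("the mean-intensity filter removes dim flat objects", {
  a <- array(0, c(10, 20, 20))
  dimv <- box_voxels(c(10, 20, 20), 3:6, 4:9, 4:9)
  a[dimv] <- 5       # large flat dim blob (CV ~ 0)
  bright <- box_voxels(c(10, 20, 20), 3:6, 13:16, 13:16)
  a[bright] <- 100
  without <- detect_spots(a, threshold = 1)
  expect_equal(nrow(without$spots), 2)
  dim_mean <- min(without$spots$mean_intensity)
  bright_mean <- max(without$spots$mean_intensity)
  with_filter <- detect_spots(a, threshold = 1,
                              intensity_min = (dim_mean + bright_mean) / 2)
  expect_equal(nrow(with_filter$spots), 1)
  expect_equal(with_filter$spots$mean_intensity, bright_mean)
  # the CV filter drops high-variability objects the same way: the bright
  # object's mask carries a dim halo (high CV), the flat blob does not
  cvs <- sort(without$spots$cv)
  cv_filtered <- detect_spots(a, threshold = 1, cv_max = mean(cvs))
  expect_equal(nrow(cv_filtered$spots), 1)
  expect_equal(cv_filtered$spots$cv, cvs[1])
})

test_that("overlap fractions follow set arithmetic and the strict 40% rule", {
  d <- c(8, 16, 16)
  a_vox <- box_voxels(d, 2:5, 2:6, 2:6)   # 4 x 5 x 5 = 100 voxels
  same <- spot_set(list(a_vox), d)
  res_same <- overlap_classify(same, same)
  expect_equal(res_same$spots$overlap_union, 1.0)
  expect_true(res_same$spots$double_positive)
  disjoint <- spot_set(list(box_voxels(d, 2:5, 10:14, 10:14)), d)
  res_dis <- overlap_classify(same, disjoint)
  expect_equal(res_dis$spots$overlap_union, 0.0)
  expect_false(res_dis$spots$double_positive)
  expect_equal(nrow(res_dis$pairs), 0)
  # exactly 40% overlap in both directions is NOT double positive
  b_vox <- box_voxels(d, 2:5, 2:6, c(2, 3, 9, 10, 11))  # shares 2 of 5 x-planes
  b <- spot_set(list(b_vox), d)
  res_40 <- overlap_classify(same, b)
  expect_equal(res_40$pairs$frac_a, 0.40)
  expect_equal(res_40$pairs$frac_b, 0.40)
  expect_false(res_40$pairs$double_positive)
  expect_false(res_40$spots$double_positive)
  # just above the threshold flips the call
  b41 <- spot_set(list(box_voxels(d, 2:5, 2:6, c(2, 3, 4, 9, 10))), d)
  expect_true(overlap_classify(same, b41)$pairs$double_positive)
})

test_that("overlap classification uses the more permissive direction", {
  d <- c(8, 16, 16)
  big <- spot_set(list(box_voxels(d, 2:5, 2:6, 2:6)), d)    # 100 voxels
  small <- spot_set(list(box_voxels(d, 2:3, 2:3, 2:3)), d)  # 8, all inside
  res <- overlap_classify(big, small)
  expect_equal(res$pairs$frac_a, 0.08)
  expect_equal(res$pairs$frac_b, 1.0)
  expect_true(res$pairs$double_positive)  # |A:B|/|B| > 0.4
  expect_true(res$spots$double_positive)
})

test_that("shrinking the partner set never increases an overlap fraction", {
  d <- c(8, 16, 16)
  set.seed(11)
  a <- spot_set(list(box_voxels(d, 2:6, 2:8, 2:8)), d)
  full <- box_voxels(d, 3:5, 4:9, 4:9)
  for (keep in c(0.8, 0.5, 0.2)) {
    b_full <- spot_set(list(full), d)
    b_small <- spot_set(list(sample(full, round(keep * length(full)))), d)
    f_full <- overlap_classify(a, b_full)$spots$overlap_union
    f_small <- overlap_classify(a, b_small)$spots$overlap_union
    expect_lte(f_small, f_full)
  }
})

test_that("double-positive counts are invariant to object relabelling", {
  d <- c(8, 16, 16)
  vox <- list(box_voxels(d, 2:4, 2:4, 2:4),
              box_voxels(d, 5:7, 9:12, 9:12),
              box_voxels(d, 2:4, 9:12, 2:4))
  b <- spot_set(list(box_voxels(d, 2:4, 2:4, 2:4),
                     box_voxels(d, 5:7, 9:12, 9:12)), d)
  res1 <- overlap_classify(spot_set(vox, d), b)
  res2 <- overlap_classify(spot_set(rev(vox), d), b)
  expect_equal(sum(res1$spots$double_positive),
               sum(res2$spots$double_positive))
  expect_equal(res1$cell_counts$n_double_positive,
               res2$cell_counts$n_double_positive)
})

test_that("overlap is invariant to global intensity rescaling of the stacks", {
  pair <- spot_pair_at_overlap(center = c(8, 14, 12), radius = 4,
                               overlap = 0.6)
  sim <- simulate_image_stack(image_sim_config(dim = c(16, 28, 32),
                                               spots = pair, seed = 4))
  ch1 <- array(sim$stack[1, , , ], c(16, 28, 32))
  ch2 <- array(sim$stack[2, , , ], c(16, 28, 32))
  r1 <- overlap_classify(detect_spots(ch1), detect_spots(ch2, channel = 2))
  r2 <- overlap_classify(detect_spots(ch1 * 50),
                         detect_spots(ch2 * 50, channel = 2))
  expect_equal(r2$spots$overlap_union, r1$spots$overlap_union)
  expect_equal(r2$pairs$frac_a, r1$pairs$frac_a)
})

test_that("detection closes the loop with the simulator on noise-free stacks", {
  for (target in c(0.3, 0.5, 0.8)) {
    pair <- spot_pair_at_overlap(center = c(8, 14, 12), radius = 4,
                                 overlap = target)
    sim <- simulate_image_stack(image_sim_config(dim = c(16, 28, 36),
                                                 spots = pair, seed = 5))
    a <- detect_spots(array(sim$stack[1, , , ], c(16, 28, 36)))
    b <- detect_spots(array(sim$stack[2, , , ], c(16, 28, 36)),
                      channel = 2)
    expect_equal(nrow(a$spots), 1)
    expect_equal(nrow(b$spots), 1)
    res <- overlap_classify(a, b)
    expect_lt(abs(res$pairs$frac_a - sim$truth$overlaps$overlap), 0.05)
  }
})

test_that("containment percentage counts vesicles holding a cargo centroid", {
  d <- c(10, 24, 24)
  vesicles <- spot_set(list(box_voxels(d, 2:4, 2:5, 2:5),
                            box_voxels(d, 2:4, 10:13, 2:5),
                            box_voxels(d, 6:8, 2:5, 10:13),
                            box_voxels(d, 6:8, 10:13, 10:13)), d)
  # cargo centroids inside vesicles 1 and 3 only
  cargo <- spot_set(list(box_voxels(d, 2:4, 3:4, 3:4),
                         box_voxels(d, 6:8, 3:4, 11:12)), d)
  expect_equal(containment_percent(vesicles, cargo), 50)
  all_in <- spot_set(lapply(vesicles$voxels, function(v) v), d)
  expect_equal(containment_percent(vesicles, all_in), 100)
  none <- spot_set(list(), d)
  expect_equal(containment_percent(vesicles, none), 0)
  expect_error(containment_percent(none, cargo), "empty vesicle set")
})

test_that("line profiles sample trilinearly at the stated spacing", {
  flat <- array(7, c(6, 12, 12))
  p <- line_profile(flat, c(2, 4, 1), c(2, 4, 7), spacing_um = 0.1,
                    voxel_size = 1)
  expect_equal(length(p$distance_um), 61)  # round(6 / 0.1) + 1
  expect_true(all(p$intensity == 7))
  # a 6 um segment at 0.1 um spacing through colocalized spots peaks at
  # the same sample in both channels
  same <- data.frame(channel = 1:2, z = 5, y = 10, x = 10, radius = 3,
                     peak = c(100, 60))
  sim <- simulate_image_stack(image_sim_config(dim = c(11, 20, 20),
                                               voxel_size = 0.5,
                                               spots = same,
                                               profile = "gaussian",
                                               seed = 2))
  prof <- line_profile(sim$stack, start_um = c(5, 10, 4) * 0.5,
                       end_um = c(5, 10, 16) * 0.5, spacing_um = 0.1,
                       voxel_size = 0.5)
  expect_equal(length(prof$distance_um), 61)
  expect_lte(abs(which.max(prof$intensity[, 1]) -
                   which.max(prof$intensity[, 2])), 1)
  expect_error(line_profile(flat, c(0, 0, 0), c(0, 0, 50)), "bounds")
})
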