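test_that("simulate_library builds the full-scale manifest with unique parts", {
  lib <- simulate_library(680, 30, 4184, 22, seed = 1)
  expect_equal(nrow(lib$genes), 710)
  expect_equal(nrow(lib$shrnas), 4184)
  expect_equal(anyDuplicated(lib$shrnas$guide), 0)
  expect_equal(anyDuplicated(lib$shrnas$shrna_id), 0)
  expect_true(all(nchar(lib$shrnas$guide) == 22))
  # as-even-as-possible allocation: per-gene counts differ by at most 1,
  # extras on the first genes in order
  per_gene <- table(factor(lib$shrnas$gene, levels = lib$genes$gene))
  expect_true(max(per_gene) - min(per_gene) <= 1)
  expect_equal(sum(per_gene), 4184)
  n_extra <- 4184 %% 710
  expect_true(all(per_gene[seq_len(n_extra)] == max(per_gene)))
})

test_that("simulate_library handles the degenerate one-gene case and errors on impossible uniqueness", {
  lib1 <- simulate_library(1, 0, 1, 22, seed = 1)
  expect_equal(nrow(lib1$genes), 1)
  expect_equal(nrow(lib1$shrnas), 1)
  expect_equal(nchar(lib1$shrnas$guide), 22)
  expect_error(simulate_library(2, 0, 100, 8, barcode_length = 6, seed = 1,
                                guide_length = 3),
               "guide_length")
  # 4^8 = 65536 < 70000 distinct guides requested
  expect_error(simulate_library(2, 0, 70000, 8, seed = 1), "unique guides")
})

test_that("library generation is deterministic under a fixed seed and round-trips TSV", {
  a <- tiny_library(seed = 9)
  b <- tiny_library(seed = 9)
  expect_identical(a, b)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_library(a, f)
  expect_identical(read_library(f), a)
})

test_that("plan_experiment reproduces the screen's bench arithmetic", {
  plan <- plan_experiment(n_shrna = 4184, coverage = 1000,
                          efficiency = 0.085)
  expect_equal(plan$transduced_cells_needed, 4184000)
  expect_equal(plan$seeded_cells_needed, ceiling(4184000 / 0.085))
  plan2 <- plan_experiment(n_shrna = 4184, representation = 1000,
                           genome_mass_pg = 6.5)
  expect_equal(plan2$pcr_template_ug_rounded, 27)
  trivial <- plan_experiment(1, coverage = 1, efficiency = 1,
                             representation = 1, genome_mass_pg = 6.5)
  expect_equal(trivial$transduced_cells_needed, 1)
  expect_equal(trivial$seeded_cells_needed, 1)
  expect_equal(trivial$pcr_template_ug, 6.5e-6)
})

test_that("screen counts conserve sequencing depth per sorted sample and respect depth 0", {
  lib <- tiny_library()
  eff <- true_effect_model(lib)
  cfg <- screen_sim_config(coverage = 50, sequencing_depth = 5000, seed = 3)
  sim <- simulate_screen_counts(lib, eff, cfg)
  expect_true(all(colSums(sim$counts) == 5000))
  expect_equal(colnames(sim$counts),
               c("rep1_high", "rep1_low", "rep2_high", "rep2_low"))
  cfg0 <- screen_sim_config(coverage = 50, sequencing_depth = 0, seed = 3)
  sim0 <- simulate_screen_counts(lib, eff, cfg0)
  expect_true(all(sim0$counts == 0))
})

test_that("screen simulation is deterministic and null effects centre fold changes at 1", {
  lib <- tiny_library(n_ub = 20, n_atg = 0, shrnas_per_gene = 4)
  eff <- true_effect_model(lib)  # all gene effects 0
  cfg <- screen_sim_config(coverage = 100, sequencing_depth = 80 * 200,
                           seed = 5)
  sim <- simulate_screen_counts(lib, eff, cfg)
  expect_identical(simulate_screen_counts(lib, eff, cfg)$counts, sim$counts)
  norm <- normalize_rpm(sim$counts)
  sc <- score_shrnas(norm, lib)
  # under the null the mean per-shRNA log fold change is 0 up to Monte
  # Carlo error; 3 standard errors of the observed log geomeans
  lg <- log(sc$geomean)
  expect_lt(abs(mean(lg)), 3 * sd(lg) / sqrt(length(lg)) + 1e-9)
})

test_that("a fully penetrant regulator gene enriches in the GFP-high gate in every replicate", {
  lib <- tiny_library(n_ub = 11, n_atg = 1, shrnas_per_gene = 4)
  reg <- lib$genes$gene[lib$genes$class == "autophagy_control"]
  eff <- true_effect_model(lib, regulators = reg, effect = 1, efficacy = 1,
                           quench_factor = 0.2)
  cfg <- screen_sim_config(coverage = 100, sequencing_depth = 200 * 48,
                           seed = 8)
  sim <- simulate_screen_counts(lib, eff, cfg)
  sc <- score_shrnas(normalize_rpm(sim$counts), lib)
  fc_cols <- grep("^fc_rep", colnames(sc))
  reg_rows <- sc$gene == reg
  expect_true(all(sc[reg_rows, fc_cols] > 1))
})

test_that("event simulation follows the quench model", {
  # flux_block = 0: mean starved GFP is quench_factor x mean basal GFP
  q <- 0.2
  ev <- simulate_events(n_events = 5000, flux_block = 0, quench_factor = q,
                        replicates = 1, seed = 21)
  fm <- ev$gfp[ev$condition == "FM"]
  st <- ev$gfp[ev$condition == "Starv"]
  se <- sqrt(sd(st)^2 / length(st) + q^2 * sd(fm)^2 / length(fm))
  expect_lt(abs(mean(st) - q * mean(fm)), 3 * se)
  # flux_block = 1: starved GFP distribution equals the basal distribution
  ev1 <- simulate_events(n_events = 5000, flux_block = 1, quench_factor = q,
                         replicates = 1, seed = 22)
  fm1 <- ev1$gfp[ev1$condition == "FM"]
  st1 <- ev1$gfp[ev1$condition == "Starv"]
  se1 <- sqrt(sd(st1)^2 / length(st1) + sd(fm1)^2 / length(fm1))
  expect_lt(abs(mean(st1) - mean(fm1)), 3 * se1)
  # mCherry is pH-insensitive: means equal across conditions
  mc_fm <- ev$mcherry[ev$condition == "FM"]
  mc_st <- ev$mcherry[ev$condition == "Starv"]
  se_mc <- sqrt(sd(mc_fm)^2 / length(mc_fm) + sd(mc_st)^2 / length(mc_st))
  expect_lt(abs(mean(mc_fm) - mean(mc_st)), 3 * se_mc)
  # determinism and CSV round trip
  expect_identical(simulate_events(n_events = 100, seed = 4),
                   simulate_events(n_events = 100, seed = 4))
  f <- withr::local_tempfile(fileext = ".csv")
  small <- simulate_events(n_events = 50, seed = 4)
  write_events(small, f)
  expect_equal(read_events(f), small, tolerance = 1e-12)
})

test_that("image stack simulator renders spots at controlled overlap with ground truth", {
  # no spots: blank stack
  blank <- simulate_image_stack(image_sim_config(dim = c(6, 12, 12)))
  expect_true(all(blank$stack == 0))
  # identical spot specs in both channels: overlap exactly 1
  same <- data.frame(channel = 1:2, z = 3, y = 6, x = 6, radius = 2,
                     peak = 50)
  sim_same <- simulate_image_stack(image_sim_config(dim = c(7, 13, 13),
                                                    spots = same))
  expect_equal(sim_same$truth$overlaps$overlap, 1.0)
  # target overlap 0.5 achieved within +-0.05 (brute-force voxel count)
  pair <- spot_pair_at_overlap(center = c(8, 16, 14), radius = 4,
                               overlap = 0.5)
  cfg <- image_sim_config(dim = c(16, 32, 32), spots = pair, seed = 2)
  sim <- simulate_image_stack(cfg)
  v1 <- sim$truth$supports[[1]]
  v2 <- sim$truth$supports[[2]]
  brute <- sum(v1 %in% v2) / length(v1)
  expect_equal(sim$truth$overlaps$overlap, brute)
  expect_lt(abs(brute - 0.5), 0.05)
  # determinism with noise on
  cfgn <- image_sim_config(dim = c(16, 32, 32), spots = pair,
                           poisson_noise = TRUE, gaussian_sd = 1, seed = 7)
  expect_identical(simulate_image_stack(cfgn)$stack,
                   simulate_image_stack(cfgn)$stack)
  # unreachable overlap: tiny B sphere cannot cover half of a large A
  expect_error(spot_pair_distance(6, 1, overlap = 0.5), "unreachable")
})

test_that("stacks round-trip through TIFF plus sidecar", {
  pair <- spot_pair_at_overlap(center = c(5, 10, 8), radius = 3,
                               overlap = 0.7)
  sim <- simulate_image_stack(image_sim_config(dim = c(10, 20, 20),
                                               voxel_size = 0.25,
                                               spots = pair,
                                               gaussian_sd = 0))
  f <- withr::local_tempfile(fileext = ".tif")
  write_stack(sim, f)
  rt <- read_stack(f)
  expect_equal(rt$voxel_size, rep(0.25, 3))
  expect_lt(max(abs(rt$stack - sim$stack)) / max(sim$stack), 1e-8)
})
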