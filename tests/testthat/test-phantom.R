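test_that("invalid specs fail naming the violated constraint", {
  expect_error(phantom_spec(canal_radius = 50), "canal_radius")
  expect_error(phantom_spec(gray_means = c(100, 90, 200)), "gray_means")
  expect_error(phantom_spec(gray_means = c(10, 20, 30), gray_sds = c(8, 8, 8)),
               "separation")
  expect_error(phantom_spec(front_profile = list(type = "linear_ramp",
                                                 start = 1, width = 0)),
               "width")
  expect_error(phantom_spec(n_canaliculi = -1), "n_canaliculi")
})

test_that("identical spec and seed give bit-identical phantoms", {
  spec <- small_ramp_spec(seed = 3L)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$gray, b$volume$gray)
  expect_identical(a$truth$compartments$labels, b$truth$compartments$labels)
  expect_identical(a$truth$matrix_class_truth, b$truth$matrix_class_truth)
})

test_that("compartments are disjoint and tile the volume", {
  spec <- phantom_spec(volume_shape = c(64L, 64L, 32L), canal_radius = 0.6,
                       osteoid_thickness = 0.4,
                       front_profile = list(type = "linear_ramp", start = 0.4,
                                            width = 0.8),
                       n_canaliculi = 8L, seed = 2L)
  ph <- generate_phantom(spec)
  lab <- ph$truth$compartments$labels
  counts <- tabulate(lab + 1L, 3L)
  expect_true(all(lab %in% c(COMP_MATRIX, COMP_HAVERSIAN, COMP_LCN)))
  expect_identical(sum(counts), length(lab))
  expect_gt(counts[2], 0)  # canal present
  expect_gt(counts[3], 0)  # canaliculi present
  # truth classes defined exactly on matrix voxels
  tc <- ph$truth$matrix_class_truth
  expect_true(all(tc[lab != COMP_MATRIX] == CLS_NON_MATRIX))
  expect_true(all(tc[lab == COMP_MATRIX] %in% c(CLS_UNMINERALIZED,
                                                CLS_MINERALIZED)))
})

test_that("step front with no canaliculi/osteoid gives an exact shell partition", {
  spec <- phantom_spec(volume_shape = c(64L, 64L, 16L), canal_radius = 0.5,
                       osteoid_thickness = 0,
                       front_profile = list(type = "step", start = 0.6),
                       n_canaliculi = 0L, seed = 1L)
  ph <- generate_phantom(spec)
  h <- 0.04
  ctr <- c(64, 64) * h / 2
  xs <- (seq_len(64) - 0.5) * h
  r2d <- sqrt(outer((xs - ctr[1])^2, (xs - ctr[2])^2, "+"))
  dsurf <- r2d - 0.5
  tc <- ph$truth$matrix_class_truth
  expected2d <- ifelse(r2d <= 0.5, CLS_NON_MATRIX,
                       ifelse(dsurf >= 0.6, CLS_MINERALIZED,
                              CLS_UNMINERALIZED))
  for (k in c(1, 8, 16))
    expect_identical(tc[, , k], array(as.integer(expected2d), c(64L, 64L)))
  # mineral fraction beyond the step is exactly 1
  beyond <- tc[rep(dsurf >= 0.6, 16)]
  expect_true(all(beyond == CLS_MINERALIZED))
})

test_that("ground-truth transition width follows the analytic identities", {
  lin <- small_ramp_spec()
  expect_equal(generate_phantom(lin)$truth$front_width_5_95, 0.9 * 1.0)
  lg <- phantom_spec(volume_shape = c(48L, 48L, 16L), canal_radius = 0.4,
                     osteoid_thickness = 0,
                     front_profile = list(type = "logistic", start = 0.5,
                                          scale = 0.1),
                     n_canaliculi = 0L, seed = 1L)
  expect_equal(generate_phantom(lg)$truth$front_width_5_95,
               2 * log(19) * 0.1)
})

test_that("empirical mineral fraction is binomially calibrated to the front profile", {
  spec <- phantom_spec(volume_shape = c(192L, 192L, 48L), canal_radius = 0.8,
                       osteoid_thickness = 0.4,
                       front_profile = list(type = "linear_ramp", start = 0.4,
                                            width = 2.4),
                       n_canaliculi = 0L, seed = 11L)
  ph <- generate_phantom(spec)
  h <- 0.04
  xs <- (seq_len(192) - 0.5) * h
  r2d <- sqrt(outer((xs - 192 * h / 2)^2, (xs - 192 * h / 2)^2, "+"))
  p2d <- pmin(pmax((r2d - 0.8 - 0.4) / 2.4, 0), 1)
  p2d[r2d - 0.8 < 0.4] <- 0
  tc <- ph$truth$matrix_class_truth
  pvox <- rep(as.vector(p2d), 48)
  mat <- as.vector(tc) != CLS_NON_MATRIX
  # bin by expected probability and compare within 3 binomial SEs
  bins <- findInterval(pvox[mat], seq(0.05, 0.95, by = 0.1))
  minr <- as.vector(tc)[mat] == CLS_MINERALIZED
  for (b in unique(bins)) {
    sel <- bins == b
    n <- sum(sel)
    if (n < 1000) next
    pbar <- mean(pvox[mat][sel])
    expect_lt(abs(mean(minr[sel]) - pbar),
              3 * sqrt(pbar * (1 - pbar) / n) + 1e-12)
  }
  # the spec's single-radius check at p ~= 0.4
  sel <- abs(pvox[mat] - 0.4) < 0.02
  expect_gt(sum(sel), 1e4)
  pbar <- mean(pvox[mat][sel])
  expect_lt(abs(mean(minr[sel]) - pbar),
            3 * sqrt(pbar * (1 - pbar) / sum(sel)))
})

test_that("no ground-truth mineral lies inside a halo sleeve", {
  halo <- 0.3
  spec <- phantom_spec(volume_shape = c(64L, 64L, 32L), canal_radius = 0.5,
                       osteoid_thickness = 0.2,
                       front_profile = list(type = "linear_ramp", start = 0.2,
                                            width = 0.6),
                       n_canaliculi = 6L, canaliculus_radius = 0.16,
                       halo_radius_by_stage = c("0" = halo, "I" = halo,
                                                "II" = halo, "III" = halo,
                                                "IV" = halo, "V" = halo),
                       seed = 5L)
  ph <- generate_phantom(spec)
  tc <- ph$truth$matrix_class_truth
  idx <- which(tc == CLS_MINERALIZED, arr.ind = TRUE)
  set.seed(1)
  idx <- idx[sample.int(nrow(idx), min(4000, nrow(idx))), ]
  pts <- (idx - 0.5) * 0.04
  dax <- bf_canaliculus_axis_dist(pts, ph$truth$canaliculi)
  expect_true(all(dax >= 0.16 + halo))
})

test_that("foci mode reproduces the expected fraction at low mineralization", {
  spec <- phantom_spec(volume_shape = c(96L, 96L, 48L), canal_radius = 0.6,
                       osteoid_thickness = 0.2,
                       front_profile = list(type = "linear_ramp", start = 0.2,
                                            width = 30),
                       n_canaliculi = 0L, mineral_mode = "foci",
                       foci_radius_distribution = list(type = "fixed",
                                                       radius = 0.12),
                       seed = 9L)
  ph <- generate_phantom(spec)
  expect_gt(nrow(ph$truth$foci), 0)
  tc <- ph$truth$matrix_class_truth
  h <- 0.04
  xs <- (seq_len(96) - 0.5) * h
  r2d <- sqrt(outer((xs - 96 * h / 2)^2, (xs - 96 * h / 2)^2, "+"))
  p2d <- pmin(pmax((r2d - 0.6 - 0.2) / 30, 0), 1)
  pvox <- rep(as.vector(p2d), 48)
  mat <- as.vector(tc) != CLS_NON_MATRIX
  realized <- mean(as.vector(tc)[mat] == CLS_MINERALIZED)
  expected <- mean(pvox[mat])
  # Poisson sphere coverage: realized ~= expected at low fractions; sphere
  # granularity makes this noisier than Bernoulli, allow 25% relative
  expect_lt(abs(realized - expected) / expected, 0.25)
})

test_that("zero-amplitude artifacts are the identity", {
  ph <- generate_phantom(small_ramp_spec())
  art <- artifact_spec(drift_per_slice = 0, stripe_amplitude = 0,
                       noise_sd_extra = 0)
  out <- add_artifacts(ph$volume, art)
  expect_identical(out$gray, ph$volume$gray)
  expect_true(all(attr(out, "shift_trace")[, c("dx_um", "dy_um")] == 0))
})

test_that("injected drift is recoverable by brute-force correlation", {
  ph <- generate_phantom(phantom_spec(volume_shape = c(48L, 48L, 6L),
                                      canal_radius = 0.4,
                                      osteoid_thickness = 0.2,
                                      front_profile = list(type = "linear_ramp",
                                                           start = 0.2,
                                                           width = 3),
                                      n_canaliculi = 0L,
                                      mineral_mode = "foci",
                                      foci_radius_distribution =
                                        list(type = "fixed", radius = 0.14),
                                      seed = 4L))
  art <- artifact_spec(drift_per_slice = 0.1, stripe_amplitude = 0,
                       noise_sd_extra = 0, seed = 2L)
  shifted <- add_artifacts(ph$volume, art)
  trace <- attr(shifted, "shift_trace")
  vox <- cbind(trace$dx_um, trace$dy_um) / 0.04
  expect_true(any(vox != 0))
  # brute-force: best integer offset between consecutive slices
  for (k in 2:6) {
    a <- shifted$gray[, , k - 1]; b <- shifted$gray[, , k]
    best <- c(NA, NA); bestv <- -Inf
    for (dx in -6:6) for (dy in -6:6) {
      i1 <- max(1, 1 + dx):min(48, 48 + dx)
      j1 <- max(1, 1 + dy):min(48, 48 + dy)
      v <- sum((b[i1, j1] - mean(b)) * (a[i1 - dx, j1 - dy] - mean(a)))
      if (v > bestv) { bestv <- v; best <- c(dx, dy) }
    }
    # brute-force peak sits at the injected displacement (within one
    # voxel: margin fill biases correlation on small slices)
    expect_lte(max(abs(best - (vox[k, ] - vox[k - 1, ]))), 1)
  }
})

test_that("stripes raise affected column means and spare distant columns", {
  gray <- array(128L, dim = c(64L, 64L, 4L))
  v <- voxel_volume(gray, 0.04)
  art <- artifact_spec(drift_per_slice = 0, stripe_amplitude = 20,
                       n_stripes = 1L, noise_sd_extra = 0, seed = 6L)
  out <- add_artifacts(v, art)
  dev <- colMeans(out$gray[, , 1]) - 128
  peak <- which.max(abs(dev))
  expect_gte(max(abs(dev)), 9)        # amplitude drawn in [0.5, 1] * 20
  expect_lte(max(abs(dev)), 20.5)
  far <- abs(seq_len(64) - peak) > 12
  expect_true(all(abs(dev[far]) < 1))
})

test_that("canal axis permutation preserves content", {
  s3 <- phantom_spec(volume_shape = c(40L, 40L, 24L), canal_radius = 0.4,
                     osteoid_thickness = 0.2,
                     front_profile = list(type = "step", start = 0.3),
                     n_canaliculi = 0L, seed = 8L, canal_axis = 3L)
  s1 <- phantom_spec(volume_shape = c(24L, 40L, 40L), canal_radius = 0.4,
                     osteoid_thickness = 0.2,
                     front_profile = list(type = "step", start = 0.3),
                     n_canaliculi = 0L, seed = 8L, canal_axis = 1L)
  a <- generate_phantom(s3)
  b <- generate_phantom(s1)
  expect_identical(dim(b$volume$gray), c(24L, 40L, 40L))
  expect_identical(aperm(b$volume$gray, c(2, 3, 1)), a$volume$gray)
  expect_identical(aperm(b$truth$compartments$labels, c(2, 3, 1)),
                   a$truth$compartments$labels)
})
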