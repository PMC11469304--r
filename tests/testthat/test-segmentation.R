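# deterministic volume whose histogram is three discretized Gaussians
three_peak_volume <- function(means = c(20, 80, 200), sds = c(8, 8, 8),
                              n_per_class = 20000L) {
  counts <- lapply(1:3, function(i)
    round(n_per_class * stats::dnorm(0:255, means[i], sds[i])))
  gray <- unlist(lapply(1:3, function(i) rep(0:255, counts[[i]])))
  comp <- unlist(lapply(1:3, function(i)
    rep(if (i == 1) COMP_HAVERSIAN else COMP_MATRIX, sum(counts[[i]]))))
  n <- length(gray)
  d <- c(n, 1L, 1L)
  list(volume = voxel_volume(array(as.integer(gray), d), 0.04),
       comp = compartment_map(array(as.integer(comp), d), 0.04))
}

test_that("three balanced peaks are fitted at their exact positions", {
  tp <- three_peak_volume()
  mod <- fit_histogram_model(tp$volume, tp$comp)
  expect_identical(mod$p, 20)
  expect_identical(mod$u, 80)
  expect_identical(mod$q, 200)
  expect_identical(mod$m, 140)   # midpoint by symmetry of equal-mass peaks
  expect_identical(mod$d, 120)
  expect_identical(mod$delta_m, 6)
  expect_true(mod$p < mod$u && mod$u < mod$m - mod$delta_m &&
              mod$m + mod$delta_m < mod$q)
})

test_that("delta_m is exactly five percent of the peak distance", {
  mod <- histogram_model(p = 10, u = 100, q = 200, m = 150)
  expect_identical(mod$delta_m, 5)
  expect_identical(mod$delta_m_threshold, 5)
  mod2 <- histogram_model(p = 5, u = 90, q = 201, m = 150)
  expect_equal(mod2$delta_m, 0.05 * 111)
  expect_identical(mod2$delta_m_threshold, 6)  # rounded for thresholding
})

test_that("a single-peaked matrix histogram raises a model-fit error", {
  counts <- round(20000 * stats::dnorm(0:255, 80, 8))
  gray <- c(rep(20L, 5000), rep(0:255, counts))
  comp <- c(rep(COMP_HAVERSIAN, 5000), rep(COMP_MATRIX, sum(counts)))
  d <- c(length(gray), 1L, 1L)
  v <- voxel_volume(array(gray, d), 0.04)
  cm <- compartment_map(array(comp, d), 0.04)
  expect_error(fit_histogram_model(v, cm),
               class = "mineralfront_model_fit_error")
})

test_that("classification is strict at the thresholds and partitions the matrix", {
  mod <- histogram_model(p = 10, u = 100, q = 200, m = 150)
  gray <- array(c(156L, 145L, 100L, 155L, 146L, 90L, 170L, 130L), c(2, 2, 2))
  labs <- array(COMP_MATRIX, c(2, 2, 2))
  labs[2, 2, 2] <- COMP_LCN
  v <- voxel_volume(gray, 0.04)
  cm <- classify_matrix(v, compartment_map(labs, 0.04), mod)
  expect_identical(cm$class[1, 1, 1], CLS_MINERALIZED)     # 156 > 155
  expect_identical(cm$class[2, 1, 1], CLS_INTERMEDIATE)    # 145 boundary
  expect_identical(cm$class[1, 2, 1], CLS_UNMINERALIZED)   # 100 < 145
  expect_identical(cm$class[2, 2, 1], CLS_INTERMEDIATE)    # 155 boundary
  expect_identical(cm$class[1, 1, 2], CLS_INTERMEDIATE)    # 146 inside band
  expect_identical(cm$class[2, 2, 2], CLS_NON_MATRIX)      # LCN wins over gray

  # partition property on random volumes
  for (s in 1:5) {
    set.seed(s)
    g <- array(sample.int(256, 1000, replace = TRUE) - 1L, c(10, 10, 10))
    l <- array(sample(c(COMP_MATRIX, COMP_HAVERSIAN, COMP_LCN), 1000,
                      replace = TRUE, prob = c(0.8, 0.1, 0.1)), c(10, 10, 10))
    cm <- classify_matrix(voxel_volume(g, 0.04),
                          compartment_map(l, 0.04), mod)
    tb <- tabulate(cm$class + 1L, 6L)
    expect_identical(tb[4] + tb[5] + tb[6], sum(l == COMP_MATRIX))
    expect_identical(tb[1], sum(l != COMP_MATRIX))
  }
})

test_that("gray normalization anchors p at 0 and q at 1 and inverts exactly", {
  mod <- histogram_model(p = 30, u = 120, q = 230, m = 170)
  expect_identical(normalize_gray(mod$p, mod), 0)
  expect_identical(normalize_gray(mod$q, mod), 1)
  expect_identical(normalize_gray(130, mod), 0.5)
  xs <- seq(0, 255, by = 0.5)
  ys <- normalize_gray(xs, mod)
  expect_true(all(diff(ys) > 0))
  expect_equal(denormalize_gray(ys, mod), xs)
  degen <- histogram_model(p = 30, u = 120, q = 230, m = 170)
  degen$q <- degen$p
  expect_error(normalize_gray(100, degen), "degenerate")
})

test_that("matrix classification agrees with phantom ground truth", {
  ph <- generate_phantom(phantom_spec(volume_shape = c(96L, 96L, 48L),
                                      canal_radius = 0.8,
                                      osteoid_thickness = 0.5,
                                      front_profile = list(type = "linear_ramp",
                                                           start = 0.5,
                                                           width = 1.2),
                                      n_canaliculi = 8L, seed = 12L))
  mod <- fit_histogram_model(ph$volume, ph$truth$compartments)
  cm <- classify_matrix(ph$volume, ph$truth$compartments, mod)
  tc <- ph$truth$matrix_class_truth
  decided <- tc != CLS_NON_MATRIX & cm$class != CLS_INTERMEDIATE
  expect_gt(mean((cm$class == tc)[decided]), 0.95)
})

test_that("automatic reference segmentation recovers the phantom compartments", {
  ph <- generate_phantom(phantom_spec(volume_shape = c(96L, 96L, 48L),
                                      canal_radius = 0.8,
                                      osteoid_thickness = 0.5,
                                      front_profile = list(type = "linear_ramp",
                                                           start = 0.5,
                                                           width = 1.2),
                                      n_canaliculi = 8L, seed = 13L))
  mod <- fit_histogram_model(ph$volume, ph$truth$compartments)
  seg <- segment_reference_compartments(ph$volume, mod)
  agree <- mean(seg$labels == ph$truth$compartments$labels)
  expect_gt(agree, 0.99)
  # the canal itself must be found as Haversian
  truth_canal <- ph$truth$compartments$labels == COMP_HAVERSIAN
  expect_gt(mean(seg$labels[truth_canal] == COMP_HAVERSIAN), 0.95)
})

test_that("face-touching dark component becomes the canal, floating ones LCN", {
  d <- c(40L, 40L, 40L)
  gray <- array(200L, d)
  gray[14:29, 14:29, ] <- 20L          # wide column through all z faces
  gray[5:8, 5:8, 10:14] <- 20L         # floating dark blob, canaliculus-thin
  v <- voxel_volume(gray, 0.04)
  mod <- histogram_model(p = 20, u = 200, q = 240, m = 220)
  seg <- segment_reference_compartments(v, mod)
  expect_identical(seg$labels[21, 21, 20], COMP_HAVERSIAN)
  expect_identical(seg$labels[6, 6, 12], COMP_LCN)
  expect_identical(seg$labels[35, 35, 30], COMP_MATRIX)
})

test_that("a volume with no dark voxels yields empty compartments with a warning", {
  v <- voxel_volume(array(200L, c(12L, 12L, 12L)), 0.04)
  mod <- histogram_model(p = 20, u = 200, q = 240, m = 220)
  expect_warning(seg <- segment_reference_compartments(v, mod),
                 "no voxels below")
  expect_true(all(seg$labels == COMP_MATRIX))
})
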