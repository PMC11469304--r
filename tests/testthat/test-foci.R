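random_classmap <- function(seed, d = c(14L, 12L, 10L), p = 0.25) {
  set.seed(seed)
  cls <- array(ifelse(runif(prod(d)) < p, CLS_MINERALIZED,
                      CLS_UNMINERALIZED), d)
  matrix_class_map(cls, 0.04)
}

test_that("component labeling equals the flood-fill oracle", {
  for (s in 1:8) {
    cm <- random_classmap(s)
    lf <- label_foci(cm, min_size = 1L)
    oracle <- bf_label(cm$class == CLS_MINERALIZED, 26L)
    expect_identical(canonical_labels(lf$labels), canonical_labels(oracle))
    # voxel bookkeeping: component sizes exhaust the mineralized voxels
    expect_identical(sum(lf$table$voxel_count),
                     sum(cm$class == CLS_MINERALIZED))
  }
  # 6-connectivity differs where only corners touch
  cls <- array(CLS_UNMINERALIZED, c(4L, 4L, 4L))
  cls[1, 1, 1] <- CLS_MINERALIZED
  cls[2, 2, 2] <- CLS_MINERALIZED
  cm <- matrix_class_map(cls, 0.04)
  expect_identical(nrow(label_foci(cm, min_size = 1L,
                                   connectivity = 26L)$table), 1L)
  expect_identical(nrow(label_foci(cm, min_size = 1L,
                                   connectivity = 6L)$table), 2L)
})

test_that("singletons are discarded and clipping is flagged", {
  cls <- array(CLS_UNMINERALIZED, c(10L, 10L, 10L))
  cls[5, 5, 5] <- CLS_MINERALIZED                 # singleton
  cls[2:3, 2, 2] <- CLS_MINERALIZED               # interior pair
  cls[1, 8:9, 8] <- CLS_MINERALIZED               # touches the boundary
  cm <- matrix_class_map(cls, 0.04)
  lf <- label_foci(cm)
  expect_identical(nrow(lf$table), 2L)
  expect_identical(sum(lf$table$clipped), 1L)
  expect_true(all(lf$table$voxel_count == 2))
})

test_that("separated spheres stay apart and overlapping ones coalesce", {
  d <- c(40L, 20L, 20L)
  mk <- function(centers, r) {
    cls <- array(CLS_UNMINERALIZED, d)
    for (cc in centers) {
      for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
        if ((i - cc[1])^2 + (j - cc[2])^2 + (k - cc[3])^2 <= r^2)
          cls[i, j, k] <- CLS_MINERALIZED
    }
    matrix_class_map(cls, 0.04)
  }
  apart <- mk(list(c(10, 10, 10), c(28, 10, 10)), r = 4)
  expect_identical(nrow(label_foci(apart)$table), 2L)
  merged <- mk(list(c(10, 10, 10), c(16, 10, 10)), r = 4)
  expect_identical(nrow(label_foci(merged)$table), 1L)
})

test_that("rasterized sphere volumes approach the analytic value", {
  for (r in c(3, 4, 5)) {
    d <- c(2L * r + 9L, 2L * r + 9L, 2L * r + 9L)
    cls <- array(CLS_UNMINERALIZED, d)
    ctr <- (d + 1) / 2
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
      if ((i - ctr[1])^2 + (j - ctr[2])^2 + (k - ctr[3])^2 <= r^2)
        cls[i, j, k] <- CLS_MINERALIZED
    lf <- label_foci(matrix_class_map(cls, 0.04))
    expect_identical(nrow(lf$table), 1L)
    expect_lt(abs(lf$table$voxel_count - 4 / 3 * pi * r^3),
              0.15 * 4 / 3 * pi * r^3)
  }
})

test_that("local mineral fraction counts voxel centers inside the cube", {
  d <- c(40L, 40L, 40L)
  h <- 0.04
  cls <- array(CLS_UNMINERALIZED, d)
  ctr_vox <- c(20L, 20L, 20L)
  ctr <- (ctr_vox - 0.5) * h
  # 1 um cube at 40 nm voxels spans exactly 25 voxels per edge
  cube <- lapply(ctr_vox, function(i) (i - 12L):(i + 12L))
  cls[cube[[1]][1:5], cube[[2]][1:5], cube[[3]][1:2]] <- CLS_MINERALIZED
  cm <- matrix_class_map(cls, h)
  f <- local_mineral_fraction(cm, ctr)
  expect_equal(as.numeric(f), 50 / 25^3)
  expect_false(attr(f, "clipped"))
  # fully mineralized cube
  cls2 <- array(CLS_MINERALIZED, d)
  expect_equal(as.numeric(local_mineral_fraction(
    matrix_class_map(cls2, h), ctr)), 1)
  # non-matrix voxels leave the denominator
  cls3 <- cls
  cls3[cube[[1]], cube[[2]], cube[[3]][14:25]] <- CLS_NON_MATRIX
  f3 <- local_mineral_fraction(matrix_class_map(cls3, h), ctr)
  expect_equal(as.numeric(f3), 50 / (25 * 25 * 13))
  # a center nearer than half a cube to the face is clipped
  f4 <- local_mineral_fraction(cm, c(0.3, ctr[2], ctr[3]))
  expect_true(attr(f4, "clipped"))
})

test_that("focus groups follow the half-open intervals", {
  expect_identical(assign_focus_group(c(0.02, 0.07, 0.15)),
                   c("G1", "G2", "G3"))
  expect_identical(assign_focus_group(c(0.001, 0.05, 0.10)),
                   c("G1", "G2", "G3"))
  expect_identical(assign_focus_group(c(0.0005, 0.20, 0.5)),
                   rep("OUT_OF_RANGE", 3))
})

test_that("foci histograms are volume-weighted probabilities", {
  recs <- data.frame(id = 1:3, voxel_count = c(16L, 47L, 16L),
                     volume = c(0.001, 0.003, 0.001),
                     x = 1, y = 1, z = 1,
                     dist_lcn = c(0.05, 0.5, 1.0),
                     local_fraction = c(0.02, 0.02, 0.3),
                     group = c("G1", "G1", "OUT_OF_RANGE"),
                     boundary_clipped = FALSE)
  fh <- foci_histogram(recs, "G1")
  expect_equal(sum(fh$cells), 1)
  expect_setequal(fh$cells[fh$cells > 0], c(0.25, 0.75))
  single <- foci_histogram(recs[3, ], "OUT_OF_RANGE")
  expect_equal(sum(single$cells), 1)
  expect_identical(max(single$cells), 1)
  empty <- foci_histogram(recs, "G2")
  expect_identical(empty$n_foci, 0L)
})

test_that("detected foci avoid halo sleeves more than geometry predicts", {
  spec <- phantom_spec(volume_shape = c(128L, 128L, 64L), canal_radius = 0.6,
                       osteoid_thickness = 0.2,
                       front_profile = list(type = "linear_ramp", start = 0.2,
                                            width = 25),
                       n_canaliculi = 10L, canaliculus_radius = 0.16,
                       halo_radius_by_stage = c("0" = 0.3, "I" = 0.3,
                                                "II" = 0.3, "III" = 0.3,
                                                "IV" = 0.3, "V" = 0.3),
                       mineral_mode = "foci",
                       foci_radius_distribution = list(type = "fixed",
                                                       radius = 0.1),
                       seed = 31L)
  ph <- generate_phantom(spec)
  dml <- distance_transform(ph$truth$compartments, COMP_LCN)
  cls <- matrix_class_map(ph$truth$matrix_class_truth, 0.04)
  recs <- analyze_foci(cls, dml, roi = list(x = c(5L, 124L), y = c(5L, 124L),
                                            z = c(5L, 60L)))
  recs <- recs[!recs$boundary_clipped, ]
  expect_gt(nrow(recs), 30)
  # geometric null: share of matrix volume lying within the sleeve distance
  mat <- ph$truth$compartments$labels == COMP_MATRIX
  p0 <- mean(dml$dist[mat] < 0.3)
  expect_gt(p0, 0.01)
  x <- sum(recs$dist_lcn < 0.3)
  pv <- stats::binom.test(x, nrow(recs), p0, alternative = "less")$p.value
  expect_lt(pv, 0.01)
})
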