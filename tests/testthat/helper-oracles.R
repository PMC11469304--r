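# Brute-force oracles and shared fixtures, independent of the package's
# compiled kernels.

# exhaustive nearest-reference search (voxel units)
bf_distance <- function(mask) {
  d <- dim(mask)
  ref <- which(mask, arr.ind = TRUE)
  out <- array(NA_real_, d)
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      for (k in seq_len(d[3]))
        out[i, j, k] <- sqrt(min((ref[, 1] - i)^2 + (ref[, 2] - j)^2 +
                                   (ref[, 3] - k)^2))
  out
}

# breadth-first flood fill labeling, 6 or 26 connectivity
bf_label <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, ]
  lab <- array(0L, d)
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      ci <- arrayInd(cur, d)
      nb <- sweep(offs, 2, as.integer(ci), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
      hit <- lin[mask[lin] & lab[lin] == 0L]
      lab[hit] <- nxt
      queue <- c(queue, hit)
    }
  }
  lab
}

# canonical relabeling (components numbered by smallest member voxel) so
# two labelings can be compared exactly
canonical_labels <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  first <- vapply(ids, function(i) min(which(lab == i)), integer(1))
  remap <- integer(max(ids))
  remap[ids[order(first)]] <- seq_along(ids)
  out <- lab
  out[lab > 0L] <- remap[lab[lab > 0L]]
  out
}

# distance of points to the nearest canaliculus axis, from the truth table
bf_canaliculus_axis_dist <- function(pts, canaliculi) {
  apply(pts, 1, function(p) {
    min(apply(canaliculi, 1, function(cn) {
      dx <- cos(cn[["theta"]]); dy <- sin(cn[["theta"]])
      w <- p - c(cn[["x_origin"]], cn[["y_origin"]], cn[["z_origin"]])
      t <- min(max(w[1] * dx + w[2] * dy, 0), cn[["length"]])
      sqrt((w[1] - t * dx)^2 + (w[2] - t * dy)^2 + w[3]^2)
    }))
  })
}

# small fast ramp phantom reused across tests
small_ramp_spec <- function(seed = 1L, ...) {
  phantom_spec(volume_shape = c(96L, 96L, 48L), canal_radius = 0.8,
               osteoid_thickness = 0.6,
               front_profile = list(type = "linear_ramp", start = 0.6,
                                    width = 1.0),
               n_canaliculi = 0L, seed = seed, ...)
}

# build a distance_map object around a precomputed array
fake_dmap <- function(dist, voxel_size = 0.04, reference = COMP_HAVERSIAN) {
  structure(list(dist = dist, reference = reference,
                 voxel_size = voxel_size),
            class = "distance_map")
}

# single staged region covering a full array
whole_volume_region <- function(d, stage, vmm = NA_real_) {
  data.frame(region_id = 1L, direction = "+x", x0 = 1L, x1 = d[1],
             y0 = 1L, y1 = d[2], z0 = 1L, z1 = d[3],
             n_matrix = prod(d), vmm_vtm = vmm, stage = stage)
}
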