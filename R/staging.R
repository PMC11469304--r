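#' Assign a mineralization stage from an overall V_MM/V_TM fraction
#'
#' Six stages describe progressing tissue mineralization: `"0"`
#' (unmineralized, fraction exactly 0), `"I"` lowly mineralized
#' (5-35%), `"II"` medium (35-65%), `"III"` highly (65-95%), `"IV"`
#' almost fully (95-99.9%) and `"V"` fully mineralized (>= 99.9%).
#' Fractions strictly between 0 and 5% fall outside the scheme and are
#' labelled `"UNSTAGED"`.
#'
#' @param fraction numeric vector of V_MM/V_TM values in `[0, 1]`.
#' @return Character vector of stage labels.
#' @export
assign_stage <- function(fraction) {
  stopifnot(all(fraction >= 0 & fraction <= 1))
  ifelse(fraction == 0, "0",
    ifelse(fraction < 0.05, "UNSTAGED",
      ifelse(fraction < 0.35, "I",
        ifelse(fraction < 0.65, "II",
          ifelse(fraction < 0.95, "III",
            ifelse(fraction < 0.999, "IV", "V"))))))
}

#' Tile staged subvolumes along the mineralization gradient
#'
#' Cuboid regions with an 8 x 8 um^2 cross-section are tiled along the
#' direction of increasing distance from the Haversian canal (the radial
#' axis, used as the normal of the mineralization front) and each region
#' is assigned a stage from its overall V_MM/V_TM. Several radial
#' directions yield replicate regions for standard errors.
#'
#' @param classmap a [matrix_class_map()].
#' @param dmap_canal canal [distance_map()][distance_transform()]; its
#'   zero set defines the canal position and axis.
#' @param front optional [transition_zone][detect_transition_zone()] used
#'   to annotate each region with its distance from the mineralization
#'   front.
#' @param step region extent along the radial direction, um.
#' @param cross_section side length of the quadratic cross-section, um.
#' @param directions radial directions to tile, subset of
#'   `"+x", "-x", "+y", "-y"` expressed in the cross-sectional plane.
#' @param min_matrix smallest matrix voxel count for a region to be kept.
#' @return Data frame of regions: voxel bounds (`x0..z1`), direction,
#'   matrix voxel count, `vmm_vtm`, `stage` and (if `front` given)
#'   `dist_from_front` of the region center, um.
#' @export
stage_subvolumes <- function(classmap, dmap_canal, front = NULL, step = 2,
                             cross_section = 8,
                             directions = c("+x", "-x", "+y", "-y"),
                             min_matrix = 500L) {
  stopifnot(inherits(classmap, "matrix_class_map"),
            inherits(dmap_canal, "distance_map"))
  h <- classmap$voxel_size
  d <- dim(classmap$class)
  canal_idx <- which(dmap_canal$dist == 0, arr.ind = TRUE)
  if (nrow(canal_idx) == 0) stop("canal distance map has no zero voxels")
  # canal axis = coordinate with the largest spread of canal voxels
  spans <- apply(canal_idx, 2, function(v) diff(range(v)))
  axis <- which.max(spans)
  plane <- setdiff(1:3, axis)
  center <- colMeans(canal_idx)
  cs_vox <- round(cross_section / h)
  step_vox <- max(1L, round(step / h))

  # region bounds along non-tiled axes: cross-section centered on canal
  clamp_range <- function(mid, half, n) {
    lo <- max(1L, floor(mid - half)); hi <- min(n, ceiling(mid + half))
    c(lo, hi)
  }
  ax_range <- clamp_range(center[axis], cs_vox / 2, d[axis])
  if (diff(ax_range) + 1 < cs_vox)
    warning("volume thinner than the requested cross-section along axis ",
            axis, "; using ", (diff(ax_range) + 1) * h, " um")

  dirs <- list("+x" = c(plane[1], +1), "-x" = c(plane[1], -1),
               "+y" = c(plane[2], +1), "-y" = c(plane[2], -1))
  rows <- list()
  rid <- 0L
  for (dn in directions) {
    dd <- dirs[[dn]]
    tile_axis <- dd[1]; sgn <- dd[2]
    other <- setdiff(plane, tile_axis)
    ot_range <- clamp_range(center[other], cs_vox / 2, d[other])
    # start just outside the canal extent along this direction
    canal_extent <- if (sgn > 0) max(canal_idx[, tile_axis])
                    else min(canal_idx[, tile_axis])
    pos0 <- canal_extent + sgn
    repeat {
      pos1 <- pos0 + sgn * (step_vox - 1L)
      if (pos1 < 1L || pos1 > d[tile_axis]) break
      rng <- sort(c(pos0, pos1))
      bounds <- vector("list", 3)
      bounds[[axis]] <- ax_range
      bounds[[tile_axis]] <- rng
      bounds[[other]] <- ot_range
      sub <- classmap$class[bounds[[1]][1]:bounds[[1]][2],
                            bounds[[2]][1]:bounds[[2]][2],
                            bounds[[3]][1]:bounds[[3]][2]]
      tb <- tabulate(sub[sub != CLS_NON_MATRIX] - 2L, 3L)  # classes 3,4,5
      n_mat <- sum(tb)
      if (n_mat >= min_matrix) {
        frac <- tb[3] / n_mat
        rid <- rid + 1L
        rows[[rid]] <- data.frame(
          region_id = rid, direction = dn,
          x0 = bounds[[1]][1], x1 = bounds[[1]][2],
          y0 = bounds[[2]][1], y1 = bounds[[2]][2],
          z0 = bounds[[3]][1], z1 = bounds[[3]][2],
          n_matrix = n_mat, vmm_vtm = frac, stage = assign_stage(frac))
      }
      pos0 <- pos0 + sgn * step_vox
    }
  }
  if (length(rows) == 0)
    stop("volume too small to hold a single staged region")
  out <- do.call(rbind, rows)
  if (!is.null(front)) {
    mid <- vapply(seq_len(nrow(out)), function(i) {
      sub <- dmap_canal$dist[out$x0[i]:out$x1[i], out$y0[i]:out$y1[i],
                             out$z0[i]:out$z1[i]]
      mean(sub)
    }, numeric(1))
    out$dist_from_front <- mid - front$front
  }
  out
}

#' Ring-shell V_MM/V_TM profile around canaliculi per stage
#'
#' For each staged region and each shell center distance D, tallies the
#' matrix voxels whose distance to the nearest canaliculus falls in the
#' ring `[D - w/2, D + w/2)` and computes their V_MM/V_TM; replicate
#' regions of the same stage are aggregated into a mean and standard
#' error. Shells capturing no voxels are excluded from aggregation.
#'
#' @param classmap a [matrix_class_map()].
#' @param dmap_lcn LCN [distance_map()][distance_transform()].
#' @param regions output of [stage_subvolumes()].
#' @param shell_centers shell center distances D, um.
#' @param ring_width shell width w, um.
#' @param min_count shells with fewer pooled voxels are flagged
#'   `low_support`.
#' @return An object of class `shell_profile`: data frame with `stage`,
#'   `D`, `mean_fraction`, `se`, `n_voxels`, `n_regions`, `low_support`;
#'   per-region fractions are attached as attribute `"by_region"`.
#' @export
shell_profile <- function(classmap, dmap_lcn, regions,
                          shell_centers = c(0.1, 0.25, 0.5, 2),
                          ring_width = 0.095, min_count = 100L) {
  stopifnot(inherits(classmap, "matrix_class_map"),
            inherits(dmap_lcn, "distance_map"))
  half <- ring_width / 2
  detail <- list()
  n <- 0L
  for (i in seq_len(nrow(regions))) {
    cls <- classmap$class[regions$x0[i]:regions$x1[i],
                          regions$y0[i]:regions$y1[i],
                          regions$z0[i]:regions$z1[i]]
    dst <- dmap_lcn$dist[regions$x0[i]:regions$x1[i],
                         regions$y0[i]:regions$y1[i],
                         regions$z0[i]:regions$z1[i]]
    mat <- cls != CLS_NON_MATRIX
    for (D in shell_centers) {
      in_shell <- mat & dst >= D - half & dst < D + half
      nv <- sum(in_shell)
      if (nv == 0) next
      frac <- sum(cls[in_shell] == CLS_MINERALIZED) / nv
      n <- n + 1L
      detail[[n]] <- data.frame(region_id = regions$region_id[i],
                                stage = regions$stage[i], D = D,
                                fraction = frac, n_voxels = nv)
    }
  }
  if (n == 0) stop("no shell captured any matrix voxel")
  by_region <- do.call(rbind, detail)
  agg <- do.call(rbind, lapply(split(by_region,
                                     list(by_region$stage, by_region$D),
                                     drop = TRUE), function(g) {
    data.frame(stage = g$stage[1], D = g$D[1],
               mean_fraction = mean(g$fraction),
               se = if (nrow(g) > 1) sd(g$fraction) / sqrt(nrow(g))
                    else NA_real_,
               n_voxels = sum(g$n_voxels), n_regions = nrow(g))
  }))
  agg$low_support <- agg$n_voxels < min_count
  stage_order <- c("0", "UNSTAGED", "I", "II", "III", "IV", "V")
  agg <- agg[order(match(agg$stage, stage_order), agg$D), ]
  rownames(agg) <- NULL
  attr(agg, "by_region") <- by_region
  class(agg) <- c("shell_profile", "data.frame")
  agg
}

#' Width of the mineral-poor halo zone around canaliculi
#'
#' The halo zone is the sleeve of matrix around canaliculi that stays
#' poor in mineral while the surrounding tissue mineralizes. Its width at
#' a given stage is measured as the canaliculus-wall distance at which
#' the shell V_MM/V_TM profile first reaches half of its far-field
#' plateau (mean of shells at D >= `plateau_from` um), interpolating
#' linearly and anchoring the profile at zero fraction on the
#' canaliculus wall (D = 0).
#'
#' @param profile a [shell_profile()].
#' @param stage stage label to evaluate.
#' @param plateau_from smallest D (um) included in the plateau estimate.
#' @return Halo width in um, with the plateau value attached as attribute
#'   `"plateau"`; `NA` (with attribute `"reason"`) when the profile never
#'   reaches half plateau or no plateau shells exist.
#' @export
halo_width <- function(profile, stage, plateau_from = 1.5) {
  rows <- profile[profile$stage == stage, , drop = FALSE]
  if (nrow(rows) < 3)
    stop("need at least 3 shells for stage ", stage)
  rows <- rows[order(rows$D), ]
  plat <- rows$mean_fraction[rows$D >= plateau_from]
  if (length(plat) == 0) {
    out <- NA_real_
    attr(out, "reason") <- "no shells beyond the plateau distance"
    return(out)
  }
  plateau <- mean(plat)
  target <- plateau / 2
  D <- c(0, rows$D)
  f <- c(0, rows$mean_fraction)
  if (max(f) < target || plateau <= 0) {
    out <- NA_real_
    attr(out, "reason") <- "profile never reaches half of its plateau"
    attr(out, "plateau") <- plateau
    return(out)
  }
  out <- first_crossing(D, f, target)
  attr(out, "plateau") <- plateau
  out
}
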