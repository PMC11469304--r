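# normalize an roi spec (list x=,y=,z= of c(lo,hi)) against a volume dim
roi_bounds <- function(roi, d) {
  if (is.null(roi)) {
    list(x = c(1L, d[1]), y = c(1L, d[2]), z = c(1L, d[3]))
  } else {
    stopifnot(all(c("x", "y", "z") %in% names(roi)))
    b <- lapply(roi[c("x", "y", "z")], function(v) as.integer(sort(v[1:2])))
    for (i in 1:3)
      if (b[[i]][1] < 1L || b[[i]][2] > d[i])
        stop("roi exceeds the volume along axis ", i)
    b
  }
}

#' Label discrete mineralization foci
#'
#' Mineralization foci are the first sub-micrometer mineral agglomerations
#' in lowly mineralized tissue; they are detected as connected components
#' of mineralized voxels (26-connectivity by default) within a region of
#' interest. Single-voxel components are discarded as noise. Components
#' touching the roi boundary are kept but flagged `clipped`, since their
#' volume is truncated.
#'
#' @param classmap a [matrix_class_map()].
#' @param roi region of interest: `list(x = c(lo, hi), y = ..., z = ...)`
#'   in voxel indices, or `NULL` for the full volume.
#' @param connectivity 26 (edges, faces and corners) or 6 (faces only).
#' @param min_size smallest component kept, voxels.
#' @return A list with `labels` (integer array over the roi, 0 =
#'   background, components numbered from 1), `table` (data frame of
#'   `id`, `voxel_count`, `clipped`) and `offset` (voxel offset of the roi
#'   corner, for mapping back to full-volume indices).
#' @export
label_foci <- function(classmap, roi = NULL, connectivity = 26L,
                       min_size = 2L) {
  stopifnot(inherits(classmap, "matrix_class_map"),
            connectivity %in% c(6L, 26L))
  d <- dim(classmap$class)
  b <- roi_bounds(roi, d)
  sub <- classmap$class[b$x[1]:b$x[2], b$y[1]:b$y[2], b$z[1]:b$z[2],
                        drop = FALSE]
  ds <- dim(sub)
  lab <- array(label3d_cpp(as.vector(sub == CLS_MINERALIZED), ds,
                           as.integer(connectivity)), dim = ds)
  nlab <- max(lab)
  if (nlab == 0)
    return(list(labels = lab,
                table = data.frame(id = integer(0), voxel_count = integer(0),
                                   clipped = logical(0)),
                offset = c(b$x[1], b$y[1], b$z[1]) - 1L))
  sizes <- tabulate(lab[lab > 0L], nlab)
  drop <- which(sizes < min_size)
  if (length(drop) > 0) lab[array(lab %in% drop, dim = ds)] <- 0L
  keep <- which(sizes >= min_size)
  # relabel compactly in original discovery order
  remap <- integer(nlab)
  remap[keep] <- seq_along(keep)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  boundary_labs <- unique(c(lab[1, , ], lab[ds[1], , ], lab[, 1, ],
                            lab[, ds[2], ], lab[, , 1], lab[, , ds[3]]))
  tab <- data.frame(id = seq_along(keep), voxel_count = sizes[keep],
                    clipped = seq_along(keep) %in% boundary_labs)
  list(labels = lab, table = tab, offset = c(b$x[1], b$y[1], b$z[1]) - 1L)
}

#' Local mineral fraction in a cube around a point
#'
#' V_MM/V_TM over the matrix voxels whose centers fall inside an
#' axis-aligned cube (edge `cube_edge`, default 1 um so the cube has unit
#' volume) centered at the given physical point. If the cube extends
#' beyond the roi, the fraction is computed on the intersection and the
#' result is flagged via attribute `"clipped"`.
#'
#' @param classmap a [matrix_class_map()].
#' @param center point `c(x, y, z)` in um.
#' @param cube_edge cube edge length, um.
#' @param roi optional roi (as in [label_foci()]) bounding the cube.
#' @return Fraction in `[0, 1]` with attribute `clipped`; `NA` if the
#'   cube contains no matrix voxels.
#' @export
local_mineral_fraction <- function(classmap, center, cube_edge = 1,
                                   roi = NULL) {
  stopifnot(inherits(classmap, "matrix_class_map"))
  h <- classmap$voxel_size
  d <- dim(classmap$class)
  b <- roi_bounds(roi, d)
  half <- cube_edge / 2
  # voxel centers at (i - 0.5) h fall in [c - half, c + half)
  lo <- ceiling((center - half) / h + 0.5)
  hi <- ceiling((center + half) / h - 0.5)
  lim <- rbind(c(b$x[1], b$y[1], b$z[1]), c(b$x[2], b$y[2], b$z[2]))
  clipped <- any(lo < lim[1, ]) || any(hi > lim[2, ])
  lo <- pmax(lo, lim[1, ]); hi <- pmin(hi, lim[2, ])
  if (any(hi < lo)) {
    out <- NA_real_; attr(out, "clipped") <- TRUE; return(out)
  }
  sub <- classmap$class[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  n_mat <- sum(sub != CLS_NON_MATRIX)
  if (n_mat == 0) {
    out <- NA_real_; attr(out, "clipped") <- clipped; return(out)
  }
  out <- sum(sub == CLS_MINERALIZED) / n_mat
  attr(out, "clipped") <- clipped
  out
}

#' Allocate a focus to a local-mineralization group
#'
#' Foci are grouped by the V_MM/V_TM of their 1 um^3 neighborhood:
#' `G1` = 0.1-5%, `G2` = 5-10%, `G3` = 10-20% (half-open intervals);
#' anything outside returns `OUT_OF_RANGE`.
#'
#' @param fraction local V_MM/V_TM in `[0, 1]`.
#' @return Character vector of group labels.
#' @export
assign_focus_group <- function(fraction) {
  stopifnot(all(is.na(fraction) | (fraction >= 0 & fraction <= 1)))
  ifelse(is.na(fraction), NA_character_,
    ifelse(fraction >= 0.001 & fraction < 0.05, "G1",
      ifelse(fraction >= 0.05 & fraction < 0.10, "G2",
        ifelse(fraction >= 0.10 & fraction < 0.20, "G3", "OUT_OF_RANGE"))))
}

#' Detect and characterize mineralization foci
#'
#' Runs [label_foci()], then derives one record per focus: voxel count and
#' physical volume, centroid, distance of the centroid to the nearest
#' canaliculus, local mineral fraction in the surrounding cube, group and
#' clipping status. Foci whose cube contains no matrix voxels are dropped
#' with a warning.
#'
#' @param classmap a [matrix_class_map()].
#' @param dmap_lcn LCN [distance_map()][distance_transform()].
#' @param roi optional roi (as in [label_foci()]).
#' @param cube_edge neighborhood cube edge, um.
#' @param connectivity,min_size passed to [label_foci()].
#' @return Data frame with one row per focus: `id`, `voxel_count`,
#'   `volume` (um^3), `x`, `y`, `z` (centroid, um), `dist_lcn` (um),
#'   `local_fraction`, `group`, `boundary_clipped`.
#' @export
analyze_foci <- function(classmap, dmap_lcn, roi = NULL, cube_edge = 1,
                         connectivity = 26L, min_size = 2L) {
  stopifnot(inherits(dmap_lcn, "distance_map"))
  h <- classmap$voxel_size
  lf <- label_foci(classmap, roi, connectivity, min_size)
  if (nrow(lf$table) == 0)
    return(data.frame(id = integer(0), voxel_count = integer(0),
                      volume = numeric(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), dist_lcn = numeric(0),
                      local_fraction = numeric(0), group = character(0),
                      boundary_clipped = logical(0)))
  idx <- which(lf$labels > 0L, arr.ind = TRUE)
  labs <- factor(lf$labels[lf$labels > 0L], levels = lf$table$id)
  cent <- apply(idx, 2, function(v) tapply(v, labs, mean))
  cent <- matrix(cent, ncol = 3)
  # to full-volume physical coordinates
  cent_um <- sweep(cent, 2, lf$offset, "+")
  cent_um <- (cent_um - 0.5) * h
  d <- dim(classmap$class)
  dropped <- 0L
  rows <- lapply(seq_len(nrow(lf$table)), function(i) {
    ctr <- cent_um[i, ]
    vi <- pmin(pmax(round(ctr / h + 0.5), 1L), d)
    frac <- local_mineral_fraction(classmap, ctr, cube_edge, roi)
    if (is.na(frac)) return(NULL)
    data.frame(id = lf$table$id[i], voxel_count = lf$table$voxel_count[i],
               volume = lf$table$voxel_count[i] * h^3,
               x = ctr[1], y = ctr[2], z = ctr[3],
               dist_lcn = dmap_lcn$dist[vi[1], vi[2], vi[3]],
               local_fraction = as.numeric(frac),
               group = assign_focus_group(as.numeric(frac)),
               boundary_clipped = lf$table$clipped[i] ||
                 isTRUE(attr(frac, "clipped")))
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (any(!keep))
    warning(sum(!keep), " focus/foci dropped: neighborhood cube contains no matrix voxels")
  do.call(rbind, rows[keep])
}

#' Volume-weighted distance-size histogram of foci
#'
#' For one local-mineralization group, builds the 2D histogram over
#' (distance to nearest canaliculus) x (focus volume) in which each focus
#' contributes weight proportional to its volume; cells sum to one. This
#' is the probability, weighted by focus volume, of finding a focus of a
#' given size at a given distance from the canaliculi. Boundary-clipped
#' foci are excluded.
#'
#' @param records output of [analyze_foci()].
#' @param group group label (`"G1"`, `"G2"` or `"G3"`).
#' @param dist_bin distance bin width, um.
#' @param vol_bins_per_decade volume bins per decade (logarithmic axis).
#' @return An object of class `foci_histogram`: list with `cells`
#'   (distance bins x volume bins, summing to 1), `dist_breaks`,
#'   `vol_breaks`, `group` and `n_foci`; `n_foci = 0` flags an empty
#'   histogram.
#' @export
foci_histogram <- function(records, group, dist_bin = 0.095,
                           vol_bins_per_decade = 10L) {
  sel <- records[!records$boundary_clipped & records$group == group, ,
                 drop = FALSE]
  if (nrow(sel) == 0) {
    out <- list(cells = matrix(numeric(0), 0, 0), dist_breaks = numeric(0),
                vol_breaks = numeric(0), group = group, n_foci = 0L)
    class(out) <- "foci_histogram"
    return(out)
  }
  dist_breaks <- seq(0, max(sel$dist_lcn) + dist_bin, by = dist_bin)
  lv <- log10(sel$volume)
  step <- 1 / vol_bins_per_decade
  vlo <- floor(min(lv) / step) * step
  vhi <- ceiling(max(lv) / step) * step + step / 2
  vol_breaks <- 10^seq(vlo, max(vhi, vlo + step), by = step)
  di <- findInterval(sel$dist_lcn, dist_breaks, rightmost.closed = FALSE)
  vi <- findInterval(sel$volume, vol_breaks, rightmost.closed = TRUE)
  vi[vi > length(vol_breaks) - 1] <- length(vol_breaks) - 1
  cells <- matrix(0, length(dist_breaks) - 1, length(vol_breaks) - 1)
  w <- sel$volume / sum(sel$volume)
  for (i in seq_len(nrow(sel)))
    cells[di[i], vi[i]] <- cells[di[i], vi[i]] + w[i]
  out <- list(cells = cells, dist_breaks = dist_breaks,
              vol_breaks = vol_breaks, group = group, n_foci = nrow(sel))
  class(out) <- "foci_histogram"
  out
}

#' @export
print.foci_histogram <- function(x, ...) {
  cat(sprintf("<foci_histogram> group %s, %d foci, %d x %d cells%s\n",
              x$group, x$n_foci, nrow(x$cells), ncol(x$cells),
              if (x$n_foci == 0) " (empty)" else ""))
  invisible(x)
}
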