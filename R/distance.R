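#' Exact Euclidean distance transform from a reference compartment
#'
#' Computes, for every voxel, the exact Euclidean distance (in um, voxel
#' center to voxel center) to the nearest voxel of the reference
#' compartment, over the full volume. The voxel-center convention leaves a
#' systematic half-voxel offset against a sub-voxel surface definition;
#' downstream statistics only depend on distance differences at the bin
#' scale, which are unaffected.
#'
#' @param compartments a [compartment_map()].
#' @param reference compartment code, [COMP_HAVERSIAN] or [COMP_LCN].
#' @param voxel_size override of the map's voxel size, um.
#' @return An object of class `distance_map`: list with `dist` (3D array,
#'   um; zero on reference voxels), `reference` and `voxel_size`.
#' @export
distance_transform <- function(compartments, reference = COMP_HAVERSIAN,
                               voxel_size = NULL) {
  stopifnot(inherits(compartments, "compartment_map"))
  if (is.null(voxel_size)) voxel_size <- compartments$voxel_size
  d <- dim(compartments$labels)
  mask <- compartments$labels == reference
  if (!any(mask))
    stop("reference compartment ", reference, " is empty")
  dist <- array(edt3d_cpp(as.vector(mask), d) * voxel_size, dim = d)
  structure(list(dist = dist, reference = reference,
                 voxel_size = voxel_size),
            class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  cat(sprintf("<distance_map> reference=%d, range %.3f-%.3f um\n",
              x$reference, min(x$dist), max(x$dist)))
  invisible(x)
}

#' Distance-conditioned gray value probability distribution (GVPD)
#'
#' Tallies matrix voxels into half-open distance bins `[i*w, (i+1)*w)` and
#' gray values 0-255, then normalizes each nonempty distance bin to sum
#' to one, so that row `i` is the probability of observing each gray value
#' at that distance. Empty bins are flagged as undefined rather than
#' zero-filled.
#'
#' @param volume a [voxel_volume()].
#' @param dmap a [distance_map()][distance_transform()].
#' @param compartments a [compartment_map()]; only matrix voxels enter.
#' @param bin_width distance bin width, um (0.27 for the Haversian canal,
#'   0.095 for canaliculi).
#' @return An object of class `gvpd`: list with `counts` (bins x 256
#'   matrix), `probs` (same shape, rows summing to 1, `NA` rows for empty
#'   bins), `bin_centers` (um), `bin_width` and `nonempty` (logical).
#' @export
compute_gvpd <- function(volume, dmap, compartments, bin_width = 0.27) {
  stopifnot(inherits(volume, "voxel_volume"),
            inherits(dmap, "distance_map"),
            inherits(compartments, "compartment_map"))
  mm <- compartments$labels == COMP_MATRIX
  if (!any(mm)) stop("no matrix voxels")
  g <- volume$gray[mm]
  bin <- floor(dmap$dist[mm] / bin_width)
  nb <- max(bin) + 1L
  counts <- matrix(tabulate(bin * 256L + g + 1L, nb * 256L),
                   nrow = nb, ncol = 256L, byrow = TRUE)
  tot <- rowSums(counts)
  nonempty <- tot > 0
  probs <- counts / tot
  probs[!nonempty, ] <- NA_real_
  structure(list(counts = counts, probs = probs,
                 bin_centers = (seq_len(nb) - 0.5) * bin_width,
                 bin_width = bin_width, nonempty = nonempty),
            class = "gvpd")
}

#' Moving-average gray value versus distance
#'
#' Sorts the selected voxels by their distance-map value and reports the
#' centered moving average of the gray values over a window of 5% (by
#' default) of all selected voxels, placed at the window's median
#' distance. Restricting to the unmineralized or mineralized class
#' deliberately excludes intermediate voxels, which cannot be attributed
#' to either phase.
#'
#' @param volume a [voxel_volume()].
#' @param dmap a [distance_map()][distance_transform()].
#' @param classmap a [matrix_class_map()].
#' @param window_fraction window width as a fraction of the selected
#'   voxel count.
#' @param restriction `"ALL"` (all matrix voxels), `"UNMINERALIZED"` or
#'   `"MINERALIZED"`.
#' @param max_points largest number of curve points returned (windows are
#'   subsampled evenly beyond this).
#' @return Data frame with `distance` (um), `mean_gray` and `n_window`.
#' @export
moving_average_curve <- function(volume, dmap, classmap,
                                 window_fraction = 0.05,
                                 restriction = c("ALL", "UNMINERALIZED",
                                                 "MINERALIZED"),
                                 max_points = 2000L) {
  stopifnot(inherits(volume, "voxel_volume"),
            inherits(dmap, "distance_map"),
            inherits(classmap, "matrix_class_map"))
  restriction <- match.arg(restriction)
  sel <- switch(restriction,
    ALL = classmap$class != CLS_NON_MATRIX,
    UNMINERALIZED = classmap$class == CLS_UNMINERALIZED,
    MINERALIZED = classmap$class == CLS_MINERALIZED)
  n <- sum(sel)
  if (n < 20)
    stop("restriction ", restriction, " selects fewer than 20 voxels")
  dist <- dmap$dist[sel]
  gray <- as.numeric(volume$gray[sel])
  ord <- order(dist)
  dist <- dist[ord]; gray <- gray[ord]
  w <- ceiling(window_fraction * n)
  if (w < 1) w <- 1L
  if (w > n) w <- n
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w - 1L - half_lo
  centers <- (1L + half_lo):(n - half_hi)
  if (length(centers) > max_points)
    centers <- centers[unique(round(seq(1, length(centers),
                                        length.out = max_points)))]
  cs <- c(0, cumsum(gray))
  means <- (cs[centers + half_hi + 1L] - cs[centers - half_lo]) / w
  data.frame(distance = dist[centers], mean_gray = means, n_window = w)
}

#' Mineralized volume fraction versus distance
#'
#' Per half-open distance bin, the volume fraction of mineralized matrix
#' per total matrix, V_MM/V_TM = n_mineralized / (n_mineralized +
#' n_unmineralized + n_intermediate): intermediate voxels count in the
#' denominator but never in the numerator. Bins without matrix voxels are
#' omitted.
#'
#' @param classmap a [matrix_class_map()].
#' @param dmap a co-registered [distance_map()][distance_transform()].
#' @param bin_width distance bin width, um.
#' @return Data frame with `bin_center` (um), per-class counts and
#'   `fraction`.
#' @export
mineral_profile <- function(classmap, dmap, bin_width = 0.27) {
  stopifnot(inherits(classmap, "matrix_class_map"),
            inherits(dmap, "distance_map"))
  mm <- classmap$class != CLS_NON_MATRIX
  cls <- classmap$class[mm]
  bin <- floor(dmap$dist[mm] / bin_width)
  nb <- max(bin) + 1L
  n_min <- tabulate(bin[cls == CLS_MINERALIZED] + 1L, nb)
  n_unm <- tabulate(bin[cls == CLS_UNMINERALIZED] + 1L, nb)
  n_int <- tabulate(bin[cls == CLS_INTERMEDIATE] + 1L, nb)
  tot <- n_min + n_unm + n_int
  keep <- tot > 0
  data.frame(bin_center = ((seq_len(nb) - 0.5) * bin_width)[keep],
             n_mineralized = n_min[keep], n_unmineralized = n_unm[keep],
             n_intermediate = n_int[keep], n_total = tot[keep],
             fraction = (n_min / tot)[keep])
}

incomplete_transition_error <- function(front) {
  stop(structure(
    list(message = sprintf(
           "profile never reaches 95%% mineralized (front%s)",
           if (is.na(front)) " not found either"
           else sprintf(" found at %.3f um", front)),
         call = NULL, front = front),
    class = c("mineralfront_incomplete_transition", "error", "condition")))
}

# first upward crossing of `level` at or after index `from`, linearly
# interpolated between bin centers; NA if never crossed
first_crossing <- function(x, f, level, from = 1L) {
  n <- length(f)
  idx <- which(f[from:n] >= level)
  if (length(idx) == 0) return(NA_real_)
  i <- idx[1] + from - 1L
  j <- i - 1L
  if (j < 1L || f[j] >= level) return(x[i])
  x[j] + (level - f[j]) / (f[i] - f[j]) * (x[i] - x[j])
}

#' Locate the mineralization front and transition zone
#'
#' The transition zone is bracketed by the distances where the
#' mineralized-matrix fraction V_MM/V_TM first reaches 5% (the
#' "mineralization front") and 95%. Crossings are located by linear
#' interpolation between adjacent bin centers, optionally after a 3-bin
#' running-median smoothing that guards against single-bin noise.
#'
#' @param profile output of [mineral_profile()].
#' @param smooth apply the 3-bin median pre-smoothing.
#' @param lower,upper fraction levels defining the zone.
#' @return An object of class `transition_zone`: list with `front`, `end`
#'   and `width`, all in um.
#' @export
detect_transition_zone <- function(profile, smooth = TRUE, lower = 0.05,
                                   upper = 0.95) {
  stopifnot(is.data.frame(profile), nrow(profile) >= 1)
  x <- profile$bin_center
  f <- profile$fraction
  if (smooth && length(f) >= 3) f <- runmed(f, 3)
  front <- first_crossing(x, f, lower)
  if (is.na(front)) incomplete_transition_error(NA_real_)
  i_front <- which(f >= lower)[1]
  end <- first_crossing(x, f, upper, from = i_front)
  if (is.na(end)) incomplete_transition_error(front)
  structure(list(front = front, end = end, width = end - front),
            class = "transition_zone")
}

#' @export
print.transition_zone <- function(x, ...) {
  cat(sprintf(
    "<transition_zone> front %.3f um, end %.3f um, width %.3f um\n",
    x$front, x$end, x$width))
  invisible(x)
}

#' Crop an interior subvolume
#'
#' Distance transforms are computed on the full volume but statistics are
#' best restricted to an interior subvolume so that voxels near the faces,
#' whose nearest reference structure may lie outside the imaged field, do
#' not bias distance-conditioned quantities.
#'
#' @param x a [voxel_volume()], [compartment_map()], [matrix_class_map()]
#'   or `distance_map`.
#' @param margin margin to strip from every face, um.
#' @return The same class of object, cropped.
#' @export
crop_margin <- function(x, margin) {
  h <- x$voxel_size
  m <- as.integer(round(margin / h))
  fld <- intersect(names(x), c("gray", "labels", "class", "dist"))[1]
  d <- dim(x[[fld]])
  if (any(2 * m >= d)) stop("margin removes the entire volume")
  idx <- lapply(d, function(n) (1L + m):(n - m))
  x[[fld]] <- x[[fld]][idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  x
}
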