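# centered moving-average smoothing of a 256-bin histogram, reflected ends
smooth_histogram <- function(counts, window = 5L) {
  if (window <= 1) return(as.numeric(counts))
  running_mean_reflect(as.numeric(counts), window)
}

# local maxima of a histogram with plateau handling; returns data frame of
# gray value (0-based), height and prominence
histogram_peaks <- function(s) {
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  nruns <- length(r$values)
  peaks <- integer(0)
  for (i in seq_len(nruns)) {
    left <- if (i == 1) -Inf else r$values[i - 1]
    right <- if (i == nruns) -Inf else r$values[i + 1]
    if (r$values[i] > left && r$values[i] > right)
      peaks <- c(peaks, round((starts[i] + ends[i]) / 2))
  }
  if (length(peaks) == 0)
    return(data.frame(gray = integer(0), height = numeric(0),
                      prominence = numeric(0)))
  prom <- vapply(peaks, function(p) {
    hp <- s[p]
    key <- -Inf
    for (dir in c(-1L, 1L)) {
      i <- p; low <- hp
      while (i + dir >= 1 && i + dir <= length(s)) {
        i <- i + dir
        if (s[i] > hp) break
        low <- min(low, s[i])
      }
      key <- max(key, low)
    }
    hp - key
  }, numeric(1))
  data.frame(gray = peaks - 1L, height = s[peaks], prominence = prom)
}

# argmin of s on the open gray-value interval (a, b); plateaus resolve to
# the midpoint gray value
argmin_between <- function(s, a, b) {
  if (b - a < 2)
    model_fit_error(sprintf("no gray levels between peaks at %d and %d", a, b))
  idx <- (a + 2):(b)              # gray a+1 .. b-1, 1-based indices
  sub <- s[idx]
  pos <- idx[sub == min(sub)]
  round(mean(pos)) - 1L
}

model_fit_error <- function(msg) {
  stop(structure(
    list(message = paste0(msg,
           " (supply thresholds manually via histogram_model())"),
         call = NULL),
    class = c("mineralfront_model_fit_error", "error", "condition")))
}

#' Construct a three-peak histogram model directly
#'
#' Normally produced by [fit_histogram_model()]; direct construction is
#' the escape hatch when the histogram does not show two matrix peaks and
#' thresholds must be supplied manually.
#'
#' @param p PMMA (embedding medium) peak gray value.
#' @param u unmineralized-matrix peak gray value.
#' @param q mineralized-matrix peak gray value.
#' @param m gray value of the minimum between `u` and `q`.
#' @param counts optional 256-bin matrix-voxel histogram.
#' @return An object of class `histogram_model` with derived fields `d`
#'   (`q - u`), `delta_m` (`0.05 * d`, unrounded) and `delta_m_threshold`
#'   (`delta_m` rounded to the nearest gray level, used for thresholding).
#' @export
histogram_model <- function(p, u, q, m, counts = NULL) {
  d <- q - u
  delta_m <- 0.05 * d
  if (!(p < u && u < m && m < q))
    model_fit_error(sprintf("peak ordering violated: need p < u < m < q, got p=%s u=%s m=%s q=%s",
                            p, u, m, q))
  if (m - delta_m <= p)
    model_fit_error("lower threshold m - delta_m does not exceed the PMMA peak")
  structure(list(p = as.numeric(p), u = as.numeric(u), q = as.numeric(q),
                 m = as.numeric(m), d = as.numeric(d), delta_m = delta_m,
                 delta_m_threshold = round(delta_m), counts = counts),
            class = "histogram_model")
}

#' @export
print.histogram_model <- function(x, ...) {
  cat(sprintf(
    "<histogram_model> p=%g u=%g m=%g q=%g | d=%g delta_m=%g (threshold %g)\n",
    x$p, x$u, x$m, x$q, x$d, x$delta_m, x$delta_m_threshold))
  invisible(x)
}

#' Fit the three-peak gray-value histogram model
#'
#' The gray-value probability distribution of an embedded, stained sample
#' shows three peaks: a sharp one at low gray values from the PMMA
#' embedding medium filling canal and LCN porosity, and two matrix peaks
#' from unmineralized and mineralized tissue. The model locates the PMMA
#' peak `p` on the histogram of reference-compartment voxels, the two
#' matrix peaks `u < q` as the two highest-prominence maxima of the
#' smoothed matrix-voxel histogram, the minimum `m` between them, and
#' derives the classification margin `delta_m = 0.05 * d` with
#' `d = q - u`.
#'
#' @param volume a [voxel_volume()].
#' @param compartments a [compartment_map()]; if `NULL`, all three peaks
#'   are sought on the full-volume histogram and `p` is taken as the
#'   lowest-gray peak among the three most prominent.
#' @param smoothing_window width (gray levels) of the centered moving
#'   average applied before peak and minimum search.
#' @return A [histogram_model()]; its `counts` field holds the raw
#'   matrix-voxel histogram (256 bins), with the PMMA-voxel histogram in
#'   `counts_pmma` and the smoothed matrix histogram in `smoothed`.
#' @export
fit_histogram_model <- function(volume, compartments = NULL,
                                smoothing_window = 5L) {
  stopifnot(inherits(volume, "voxel_volume"))
  g <- volume$gray
  if (!is.null(compartments)) {
    stopifnot(inherits(compartments, "compartment_map"))
    ref <- compartments$labels != COMP_MATRIX
    counts_pmma <- tabulate(g[ref] + 1L, 256L)
    counts <- tabulate(g[!ref] + 1L, 256L)
    if (sum(counts_pmma) == 0)
      model_fit_error("no reference (PMMA) voxels to locate the p peak")
    p <- which.max(counts_pmma) - 1L
    s <- smooth_histogram(counts, smoothing_window)
    pk <- histogram_peaks(s)
    pk <- pk[order(-pk$prominence, pk$gray), ]
    if (nrow(pk) < 2)
      model_fit_error("fewer than two peaks in the matrix histogram")
    two <- pk$gray[1:2]
  } else {
    counts_pmma <- NULL
    counts <- tabulate(g + 1L, 256L)
    s <- smooth_histogram(counts, smoothing_window)
    pk <- histogram_peaks(s)
    pk <- pk[order(-pk$prominence, pk$gray), ]
    if (nrow(pk) < 3)
      model_fit_error("fewer than three peaks in the full histogram")
    three <- sort(pk$gray[1:3])
    p <- three[1]
    two <- three[2:3]
  }
  u <- min(two); q <- max(two)
  m <- argmin_between(s, u, q)
  mod <- histogram_model(p = p, u = u, q = q, m = m, counts = counts)
  mod$counts_pmma <- counts_pmma
  mod$smoothed <- s
  mod$smoothing_window <- smoothing_window
  mod
}

#' Classify matrix voxels as unmineralized, intermediate or mineralized
#'
#' Matrix voxels with gray value strictly above `m + delta_m` are
#' mineralized, strictly below `m - delta_m` unmineralized, and otherwise
#' intermediate (gray values close to the inter-peak minimum cannot be
#' attributed reliably because of noise and partial-volume effects).
#' Thresholding uses `delta_m` rounded to the nearest gray level;
#' boundary values are intermediate. Non-matrix voxels get
#' [CLS_NON_MATRIX].
#'
#' @param volume a [voxel_volume()].
#' @param compartments a [compartment_map()].
#' @param model a [histogram_model()].
#' @return A [matrix_class_map()].
#' @export
classify_matrix <- function(volume, compartments, model) {
  stopifnot(inherits(volume, "voxel_volume"),
            inherits(compartments, "compartment_map"),
            inherits(model, "histogram_model"))
  hi <- model$m + model$delta_m_threshold
  lo <- model$m - model$delta_m_threshold
  d <- dim(volume$gray)
  cls <- array(CLS_NON_MATRIX, dim = d)
  mm <- compartments$labels == COMP_MATRIX
  gm <- volume$gray[mm]
  cl <- rep(CLS_INTERMEDIATE, length(gm))
  cl[gm > hi] <- CLS_MINERALIZED
  cl[gm < lo] <- CLS_UNMINERALIZED
  cls[mm] <- cl
  matrix_class_map(cls, volume$voxel_size)
}

#' Normalize gray values against the fitted histogram model
#'
#' Linear rescaling `Y = (X - p) / (q - p)` anchoring the PMMA peak at 0
#' and the mineralized-matrix peak at 1, which makes gray-value curves
#' comparable across datasets acquired with different brightness/contrast
#' or staining intensity.
#'
#' @param x gray value(s).
#' @param model a [histogram_model()].
#' @return Normalized value(s); affine and order-preserving, inverted
#'   exactly by [denormalize_gray()].
#' @export
normalize_gray <- function(x, model) {
  stopifnot(inherits(model, "histogram_model"))
  if (model$q == model$p)
    stop("degenerate model: q equals p, normalization undefined")
  (x - model$p) / (model$q - model$p)
}

#' @rdname normalize_gray
#' @param y normalized value(s).
#' @export
denormalize_gray <- function(y, model) {
  stopifnot(inherits(model, "histogram_model"))
  y * (model$q - model$p) + model$p
}

#' Segment the PMMA-filled reference compartments automatically
#'
#' Thresholds the volume below the histogram minimum between the PMMA peak
#' and the unmineralized-matrix peak, applies a morphological closing
#' (radius 1 voxel), and labels the dark phase. Because the LCN porosity
#' joins the canal wall, the Haversian canal is first isolated by a
#' morphological opening wider than a canaliculus: the largest eroded core
#' touching a volume face, regrown by bounded dilation, becomes the canal;
#' all remaining dark components above the minimum size become LCN. This
#' is an automated stand-in for interactive tracing of the canal and LCN.
#'
#' @param volume a [voxel_volume()].
#' @param model a [histogram_model()] fitted on this volume.
#' @param min_size smallest component (voxels) kept as LCN.
#' @param closing apply the radius-1 closing before labeling.
#' @param opening_radius erosion radius (um) used to isolate the canal
#'   core; must exceed the canaliculus radius and stay below the canal
#'   radius.
#' @return A [compartment_map()].
#' @export
segment_reference_compartments <- function(volume, model, min_size = 30L,
                                           closing = TRUE,
                                           opening_radius = 0.25) {
  stopifnot(inherits(volume, "voxel_volume"),
            inherits(model, "histogram_model"))
  d <- dim(volume$gray)
  s <- if (!is.null(model$smoothed) && is.null(model$counts_pmma)) {
    model$smoothed   # model fitted on the full histogram already
  } else {
    smooth_histogram(tabulate(volume$gray + 1L, 256L),
                     if (is.null(model$smoothing_window)) 5L
                     else model$smoothing_window)
  }
  thr <- argmin_between(s, model$p, model$u)
  dark <- volume$gray < thr
  if (!any(dark)) {
    warning("no voxels below the PMMA/matrix threshold; empty reference compartments")
    return(compartment_map(array(COMP_MATRIX, dim = d), volume$voxel_size))
  }
  if (closing) {
    dark <- morph3d_cpp(as.vector(dark), d, 0L, 1L)   # dilate
    dark <- morph3d_cpp(dark, d, 1L, 1L)              # erode
  }
  dark <- array(dark, dim = d)
  out <- array(COMP_MATRIX, dim = d)
  open_r <- max(1L, as.integer(round(opening_radius / volume$voxel_size)))
  core <- array(morph3d_cpp(as.vector(dark), d, 1L, open_r), dim = d)
  hav_mask <- NULL
  if (any(core)) {
    lab <- array(label3d_cpp(as.vector(core), d, 26L), dim = d)
    nlab <- max(lab)
    sizes <- tabulate(lab[lab > 0L], nlab)
    face_labs <- setdiff(unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ],
                                  lab[, d[2], ], lab[, , 1], lab[, , d[3]])),
                         0L)
    if (length(face_labs) > 0) {
      hav <- face_labs[which.max(sizes[face_labs])]
      grown <- morph3d_cpp(as.vector(lab == hav), d, 0L, open_r + 1L)
      hav_mask <- array(grown, dim = d) & dark
      out[hav_mask] <- COMP_HAVERSIAN
    }
  }
  if (is.null(hav_mask)) {
    warning("no face-touching canal core found; labeling all dark components as LCN")
    hav_mask <- array(FALSE, dim = d)
  }
  rest <- dark & !hav_mask
  if (any(rest)) {
    lab <- array(label3d_cpp(as.vector(rest), d, 26L), dim = d)
    nlab <- max(lab)
    sizes <- tabulate(lab[lab > 0L], nlab)
    keep <- which(sizes >= min_size)
    if (length(keep) > 0) out[array(lab %in% keep, dim = d)] <- COMP_LCN
  }
  compartment_map(out, volume$voxel_size)
}
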