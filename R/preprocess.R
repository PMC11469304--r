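#' Estimate the in-plane shift between two slices
#'
#' Zero-mean circular cross-correlation via FFT, maximized over integer
#' offsets within `max_shift`. Returns the displacement `c(dx, dy)` of `b`
#' relative to `a` (i.e., `b` looks like `a` translated by that amount).
#' Featureless (constant) slices return `NA`.
#'
#' @param a,b numeric matrices of equal size.
#' @param max_shift largest offset searched, voxels.
#' @return Integer vector `c(dx, dy)`, or `c(NA, NA)`.
#' @export
estimate_slice_shift <- function(a, b, max_shift = 10L) {
  if (sd(a) == 0 || sd(b) == 0) return(c(NA_integer_, NA_integer_))
  a <- a - mean(a); b <- b - mean(b)
  n1 <- nrow(a); n2 <- ncol(a)
  cc <- Re(fft(fft(b) * Conj(fft(a)), inverse = TRUE)) / length(a)
  m1 <- min(max_shift, n1 %/% 2 - 1L)
  m2 <- min(max_shift, n2 %/% 2 - 1L)
  offs1 <- -m1:m1; offs2 <- -m2:m2
  sub <- cc[(offs1 %% n1) + 1, (offs2 %% n2) + 1, drop = FALSE]
  best <- arrayInd(which.max(sub), dim(sub))
  c(offs1[best[1]], offs2[best[2]])
}

#' Align a stack against cumulative inter-slice drift
#'
#' Estimates the displacement of each slice relative to its predecessor by
#' cross-correlation, accumulates the displacements into a per-slice drift
#' trajectory, and resamples each slice by the negative trajectory after
#' subtracting its mean (the aligned stack is recentered rather than
#' pinned to the first slice). Shifts are integer voxels. A featureless
#' slice pair triggers a warning and carries the displacement forward as
#' zero.
#'
#' @param volume a [voxel_volume()] with at least 2 slices.
#' @param max_shift largest per-slice-pair offset searched, voxels.
#' @return A list with `volume` (aligned [voxel_volume()]) and `trace`, a
#'   data frame of the estimated cumulative drift per slice in um (first
#'   slice zero). The integer correction applied to each slice is attached
#'   to the trace as attribute `"applied_correction"`.
#' @export
align_stack <- function(volume, max_shift = 10L) {
  stopifnot(inherits(volume, "voxel_volume"))
  d <- dim(volume$gray)
  nz <- d[3]
  if (nz < 2) stop("align_stack needs at least 2 slices")
  h <- volume$voxel_size
  pos <- matrix(0, nz, 2)
  for (k in 2:nz) {
    s <- estimate_slice_shift(volume$gray[, , k - 1], volume$gray[, , k],
                              max_shift)
    if (any(is.na(s))) {
      warning("featureless slice pair ", k - 1, "/", k,
              ": displacement carried forward as zero")
      s <- c(0L, 0L)
    }
    pos[k, ] <- pos[k - 1, ] + s
  }
  # subtract the rounded mean so corrections are integers and relative
  # displacements between slices are preserved exactly
  corr <- -sweep(pos, 2, round(colMeans(pos)))
  gray <- volume$gray
  for (k in seq_len(nz)) {
    if (any(corr[k, ] != 0)) {
      sl <- gray[, , k]
      gray[, , k] <- translate_slice(sl, corr[k, 1], corr[k, 2],
                                     fill = median(sl))
    }
  }
  trace <- data.frame(slice = seq_len(nz), dx_um = pos[, 1] * h,
                      dy_um = pos[, 2] * h)
  attr(trace, "applied_correction") <- corr
  list(volume = voxel_volume(gray, h), trace = trace)
}

# centered running mean with reflected ends
running_mean_reflect <- function(x, window) {
  if (window %% 2 == 0) window <- window + 1
  half <- window %/% 2
  n <- length(x)
  if (n == 1 || half == 0) return(x)
  pad <- c(x[pmin(half:1 + 1, n)], x, x[pmax(n - (1:half), 1)])
  as.numeric(stats::filter(pad, rep(1 / window, window),
                           sides = 2)[(half + 1):(half + n)])
}

#' Remove curtaining stripes by column-statistic destriping
#'
#' FIB milling leaves "curtains": stripes that run along the milling
#' direction and are nearly constant within a slice. Per slice, the
#' operator takes the mean profile across the stripe direction, removes
#' its structural component with a wide running median, and subtracts the
#' remaining narrow-band residual from every row of the slice. Real
#' structure survives because features wider than about half the window
#' pass through a running median unchanged, while stripes a few voxels
#' wide are rejected entirely; on stripe-free inputs the change is under
#' one gray level RMS at default settings.
#'
#' @param volume a [voxel_volume()].
#' @param strength multiplier on the subtracted stripe profile.
#' @param stripe_axis in-plane axis (1 or 2) the stripes run along.
#' @param window width (voxels, odd) of the running median defining the
#'   structural baseline; stripes narrower than about half this width are
#'   removed.
#' @return A destriped [voxel_volume()].
#' @export
destripe <- function(volume, strength = 1, stripe_axis = 1L, window = 15L) {
  stopifnot(inherits(volume, "voxel_volume"))
  d <- dim(volume$gray)
  gray <- volume$gray
  for (k in seq_len(d[3])) {
    sl <- gray[, , k]
    w <- if (window %% 2 == 0) window + 1L else as.integer(window)
    if (stripe_axis == 1L) {
      prof <- colMeans(sl)
      resid <- prof - runmed(prof, min(w, length(prof) - 1 + length(prof) %% 2))
      sl <- sl - strength * rep(resid, each = d[1])
    } else {
      prof <- rowMeans(sl)
      resid <- prof - runmed(prof, min(w, length(prof) - 1 + length(prof) %% 2))
      sl <- sl - strength * rep(resid, times = d[2])
    }
    gray[, , k] <- pmin(pmax(round(sl), 0), 255)
  }
  voxel_volume(gray, volume$voxel_size)
}

#' Denoise a volume with a 3D neighborhood filter
#'
#' @param volume a [voxel_volume()].
#' @param method `"median"` (box-neighborhood median) or `"gaussian"`
#'   (separable Gaussian with `sigma = radius` voxels).
#' @param radius neighborhood radius in voxels; 0 returns the input
#'   unchanged.
#' @return A denoised [voxel_volume()].
#' @export
denoise <- function(volume, method = c("median", "gaussian"), radius = 1L) {
  stopifnot(inherits(volume, "voxel_volume"))
  method <- match.arg(method)
  if (radius < 0) stop("radius must be >= 0")
  if (radius == 0) return(volume)
  d <- dim(volume$gray)
  x <- as.numeric(volume$gray)
  out <- if (method == "median") median3d_cpp(x, d, as.integer(radius))
         else gaussian3d_cpp(x, d, as.numeric(radius))
  gray <- array(as.integer(pmin(pmax(round(out), 0), 255)), dim = d)
  voxel_volume(gray, volume$voxel_size)
}
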