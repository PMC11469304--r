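#' Specify a synthetic forming-osteon phantom
#'
#' Builds and validates the parameter set for [generate_phantom()]. The
#' phantom emulates a forming osteon imaged at isotropic sub-50 nm voxels:
#' a cylindrical Haversian canal along one grid axis, an unmineralized
#' osteoid seam, a mineralized-matrix fraction that rises with distance
#' from the canal surface following a configurable front profile, straight
#' canaliculi radiating from the canal wall with mineral-free "halo"
#' sleeves whose radius shrinks as the surrounding tissue matures, and a
#' three-phase gray-value model (embedding medium, unmineralized matrix,
#' mineralized matrix) with per-class Gaussian noise.
#'
#' All lengths are in micrometers and measured from the relevant surface:
#' `osteoid_thickness` and the `front_profile` coordinate from the canal
#' wall, halo radii from the canaliculus wall.
#'
#' @param volume_shape integer vector of voxels per axis.
#' @param voxel_size isotropic voxel edge, um.
#' @param canal_radius Haversian canal radius, um.
#' @param canal_axis grid axis (1, 2 or 3) the canal runs along.
#' @param osteoid_thickness width of the mineral-free osteoid seam, um.
#' @param front_profile list with `type` one of `"linear_ramp"` (fields
#'   `start`, `width`), `"logistic"` (fields `start` = 50% midpoint,
#'   `scale`) or `"step"` (field `start`); gives the probability that a
#'   matrix voxel at a given canal-wall distance is mineralized.
#' @param n_canaliculi number of canaliculi.
#' @param canaliculus_radius canaliculus radius, um (canaliculi are about
#'   300 nm across in human osteons).
#' @param halo_radius_by_stage named numeric, mineral-free sleeve radius
#'   (um, from the canaliculus wall) for tissue stages `"0"`, `"I"` ...
#'   `"V"`; the sleeve shrinks as mineralization progresses.
#' @param mineral_mode `"bernoulli"` draws each matrix voxel independently
#'   with the front-profile probability; `"foci"` instead places spherical
#'   mineralization foci by a Poisson point process whose intensity
#'   reproduces the same expected mineral fraction.
#' @param foci_radius_distribution list with `type = "fixed"` (field
#'   `radius`, um) or `type = "lognormal"` (fields `meanlog`, `sdlog` on
#'   the um scale).
#' @param gray_means gray values (0-255) of the PMMA, unmineralized and
#'   mineralized phases, strictly increasing.
#' @param gray_sds per-phase Gaussian noise SD in gray levels.
#' @param seed integer seed; geometry, mineral placement and gray noise
#'   use independent sub-streams derived from it, so toggling noise does
#'   not change the geometry.
#' @return A validated object of class `phantom_spec`.
#' @export
phantom_spec <- function(volume_shape = c(512L, 512L, 256L),
                         voxel_size = 0.04,
                         canal_radius = 2,
                         canal_axis = 3L,
                         osteoid_thickness = 3,
                         front_profile = list(type = "linear_ramp",
                                              start = 3, width = 4.078),
                         n_canaliculi = 80L,
                         canaliculus_radius = 0.2,
                         halo_radius_by_stage = c("0" = 0.6, "I" = 0.6,
                                                  "II" = 0.5, "III" = 0.4,
                                                  "IV" = 0.2, "V" = 0.05),
                         mineral_mode = c("bernoulli", "foci"),
                         foci_radius_distribution = list(type = "lognormal",
                                                         meanlog = log(0.2),
                                                         sdlog = 0.25),
                         gray_means = c(pmma = 30, unmineralized = 110,
                                        mineralized = 210),
                         gray_sds = c(6, 8, 8),
                         seed = 1L) {
  fail <- function(what) stop("phantom_spec: invalid configuration: ", what,
                              call. = FALSE)
  if (length(volume_shape) != 3L || any(volume_shape < 4))
    fail("volume_shape must be three axis sizes of at least 4 voxels")
  if (voxel_size <= 0) fail("voxel_size must be > 0")
  if (!canal_axis %in% 1:3) fail("canal_axis must be 1, 2 or 3")
  cross <- setdiff(1:3, canal_axis)
  half_extent <- min(volume_shape[cross]) * voxel_size / 2
  if (canal_radius <= 0 || canal_radius >= half_extent)
    fail("canal_radius must be > 0 and smaller than the half-extent of the cross-section")
  if (osteoid_thickness < 0) fail("osteoid_thickness must be >= 0")
  if (!is.list(front_profile) ||
      !front_profile$type %in% c("linear_ramp", "logistic", "step"))
    fail("front_profile$type must be linear_ramp, logistic or step")
  if (front_profile$type == "linear_ramp" &&
      (is.null(front_profile$width) || front_profile$width <= 0))
    fail("linear_ramp front_profile needs width > 0")
  if (front_profile$type == "logistic" &&
      (is.null(front_profile$scale) || front_profile$scale <= 0))
    fail("logistic front_profile needs scale > 0")
  if (is.null(front_profile$start) || front_profile$start < 0)
    fail("front_profile needs start >= 0")
  if (n_canaliculi < 0) fail("n_canaliculi must be >= 0")
  if (canaliculus_radius <= 0 || canaliculus_radius >= half_extent)
    fail("canaliculus_radius must be > 0 and smaller than the cross-section half-extent")
  if (!all(c("0", "I", "II", "III", "IV", "V") %in% names(halo_radius_by_stage)))
    fail("halo_radius_by_stage must name stages 0, I, II, III, IV, V")
  if (any(halo_radius_by_stage < 0)) fail("halo radii must be >= 0")
  mineral_mode <- match.arg(mineral_mode)
  if (!is.list(foci_radius_distribution) ||
      !foci_radius_distribution$type %in% c("fixed", "lognormal"))
    fail("foci_radius_distribution$type must be fixed or lognormal")
  if (length(gray_means) != 3L || any(diff(gray_means) <= 0))
    fail("gray_means must be strictly increasing (PMMA < unmineralized < mineralized)")
  if (any(gray_means < 0) || any(gray_means > 255))
    fail("gray_means must lie in [0, 255]")
  if (length(gray_sds) != 3L || any(gray_sds < 0))
    fail("gray_sds must be three non-negative values")
  if (min(diff(gray_means)) <= 3 * max(gray_sds))
    fail("gray class mean separation must exceed 3x the largest gray_sd")
  structure(list(volume_shape = as.integer(volume_shape),
                 voxel_size = voxel_size, canal_radius = canal_radius,
                 canal_axis = as.integer(canal_axis),
                 osteoid_thickness = osteoid_thickness,
                 front_profile = front_profile,
                 n_canaliculi = as.integer(n_canaliculi),
                 canaliculus_radius = canaliculus_radius,
                 halo_radius_by_stage = halo_radius_by_stage,
                 mineral_mode = mineral_mode,
                 foci_radius_distribution = foci_radius_distribution,
                 gray_means = unname(gray_means), gray_sds = unname(gray_sds),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# mineralization probability as a function of distance from the canal wall
front_profile_fun <- function(fp) {
  switch(fp$type,
    linear_ramp = function(d) pmin(pmax((d - fp$start) / fp$width, 0), 1),
    logistic = function(d) 1 / (1 + exp(-(d - fp$start) / fp$scale)),
    step = function(d) as.numeric(d >= fp$start))
}

# analytic 5%-95% span of the front profile
front_width_5_95 <- function(fp) {
  switch(fp$type,
    linear_ramp = 0.9 * fp$width,
    logistic = 2 * log(19) * fp$scale,
    step = 0)
}

# tissue stage implied by an expected mineral fraction; used to look up the
# halo sleeve radius during generation (the unstaged 0-5% gap is folded
# into stage I here because the generator needs a total function)
stage_of_fraction <- function(p) {
  ifelse(p <= 0, "0",
    ifelse(p < 0.35, "I",
      ifelse(p < 0.65, "II",
        ifelse(p < 0.95, "III",
          ifelse(p < 0.999, "IV", "V")))))
}

mean_focus_volume <- function(frd) {
  if (frd$type == "fixed") 4 / 3 * pi * frd$radius^3
  else 4 / 3 * pi * exp(3 * frd$meanlog + 4.5 * frd$sdlog^2)
}

draw_focus_radii <- function(frd, n) {
  if (frd$type == "fixed") rep(frd$radius, n)
  else rlnorm(n, frd$meanlog, frd$sdlog)
}

#' Generate a synthetic forming-osteon volume with ground truth
#'
#' Realizes a [phantom_spec()] into a gray-value stack plus complete ground
#' truth: the compartment labels, the per-voxel mineralization truth, the
#' analytic transition-zone width implied by the front profile, the
#' canaliculus geometry and (in foci mode) the list of true foci.
#'
#' Matrix voxels are mineralized by independent Bernoulli draws with
#' probability given by the front profile at the voxel's distance from the
#' canal wall, forced to zero inside the osteoid seam, inside the halo
#' sleeves around canaliculi, and outside the matrix. In `"foci"` mode,
#' spheres are instead placed by a Poisson point process whose local
#' intensity reproduces the same expected mineral fraction (suited to the
#' low fractions where discrete foci exist; sphere overlap makes the
#' realized fraction fall slightly below the target as it approaches 1).
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` (a [voxel_volume()]) and `truth`,
#'   the latter holding `compartments` (a [compartment_map()]),
#'   `matrix_class_truth` (integer array: 0 outside the matrix, 3
#'   unmineralized, 5 mineralized), `front_start_radius`,
#'   `front_width_5_95`, `halo_radius_by_stage`, `canaliculi` (data frame)
#'   and `foci` (data frame, empty in Bernoulli mode).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ax <- spec$canal_axis
  ord <- c(setdiff(1:3, ax), ax)         # internal order: canal along dim 3
  shp <- spec$volume_shape[ord]
  res <- generate_phantom_axis3(spec, shp)
  if (ax != 3L) {
    inv <- order(ord)                    # permutation back to user order
    res$volume$gray <- aperm(res$volume$gray, inv)
    res$truth$compartments$labels <- aperm(res$truth$compartments$labels, inv)
    res$truth$matrix_class_truth <- aperm(res$truth$matrix_class_truth, inv)
    # coordinate columns were produced with the canal along internal axis 3;
    # relabel them so x/y/z refer to the user's axis order again
    axis_letter <- c("x", "y", "z")
    for (tab in c("canaliculi", "foci")) {
      df <- res$truth[[tab]]
      xyz <- grep("^[xyz]_", names(df))
      if (length(xyz) > 0) {
        internal_letter <- sub("_.*$", "", names(df)[xyz])
        suffix <- sub("^[xyz]_", "", names(df)[xyz])
        user_axis <- ord[match(internal_letter, axis_letter)]
        names(df)[xyz] <- paste0(axis_letter[user_axis], "_", suffix)
        res$truth[[tab]] <- df
      }
    }
  }
  res
}

generate_phantom_axis3 <- function(spec, shp) {
  nx <- shp[1]; ny <- shp[2]; nz <- shp[3]
  h <- spec$voxel_size
  nxy <- nx * ny
  set.seed(spec$seed)
  substreams <- sample.int(.Machine$integer.max - 1L, 3L)

  cx <- nx * h / 2; cy <- ny * h / 2
  xs <- voxel_centers(nx, h); ys <- voxel_centers(ny, h)
  zs <- voxel_centers(nz, h)
  r2d <- sqrt(outer((xs - cx)^2, (ys - cy)^2, "+"))   # nx x ny, um from axis
  dsurf2d <- r2d - spec$canal_radius                  # um from canal wall
  fprof <- front_profile_fun(spec$front_profile)
  p2d <- fprof(dsurf2d)
  p2d[dsurf2d < spec$osteoid_thickness] <- 0          # osteoid is mineral-free
  canal2d <- r2d <= spec$canal_radius

  comp <- array(ifelse(canal2d, COMP_HAVERSIAN, COMP_MATRIX), dim = shp)
  suppress <- array(FALSE, dim = shp)

  # --- canaliculi: straight cylinders radiating in-plane from the canal wall
  set.seed(substreams[1])
  canaliculi <- data.frame(id = integer(0), theta = numeric(0),
                           x_origin = numeric(0), y_origin = numeric(0),
                           z_origin = numeric(0), length = numeric(0),
                           radius = numeric(0))
  if (spec$n_canaliculi > 0) {
    theta <- runif(spec$n_canaliculi, 0, 2 * pi)
    z0 <- runif(spec$n_canaliculi, h, nz * h - h)
    halo2d <- matrix(spec$halo_radius_by_stage[stage_of_fraction(p2d)],
                     nx, ny)
    max_sleeve <- spec$canaliculus_radius + max(spec$halo_radius_by_stage)
    rows <- vector("list", spec$n_canaliculi)
    for (k in seq_len(spec$n_canaliculi)) {
      dx <- cos(theta[k]); dy <- sin(theta[k])
      x0 <- cx + spec$canal_radius * dx
      y0 <- cy + spec$canal_radius * dy
      tx <- if (dx > 0) (nx * h - x0) / dx else if (dx < 0) -x0 / dx else Inf
      ty <- if (dy > 0) (ny * h - y0) / dy else if (dy < 0) -y0 / dy else Inf
      L <- min(tx, ty)
      x1 <- x0 + L * dx; y1 <- y0 + L * dy
      pad <- max_sleeve + 2 * h
      ix <- max(1L, floor((min(x0, x1) - pad) / h)):min(nx, ceiling((max(x0, x1) + pad) / h))
      iy <- max(1L, floor((min(y0, y1) - pad) / h)):min(ny, ceiling((max(y0, y1) + pad) / h))
      iz <- max(1L, floor((z0[k] - pad) / h)):min(nz, ceiling((z0[k] + pad) / h))
      A <- outer(xs[ix] - x0, rep(1, length(iy)))
      B <- outer(rep(1, length(ix)), ys[iy] - y0)
      tt <- pmin(pmax(A * dx + B * dy, 0), L)
      perp2 <- (A - tt * dx)^2 + (B - tt * dy)^2
      dz2 <- (zs[iz] - z0[k])^2
      nbx <- length(ix) * length(iy)
      d2 <- rep(as.vector(perp2), length(iz)) + rep(dz2, each = nbx)
      lcn_box <- d2 <= spec$canaliculus_radius^2
      sleeve2d <- (spec$canaliculus_radius + halo2d[ix, iy, drop = FALSE])^2
      sup_box <- d2 < rep(as.vector(sleeve2d), length(iz))
      cm <- comp[ix, iy, iz]
      cm[lcn_box & cm == COMP_MATRIX] <- COMP_LCN
      comp[ix, iy, iz] <- cm
      sp <- suppress[ix, iy, iz]
      suppress[ix, iy, iz] <- sp | sup_box
      rows[[k]] <- data.frame(id = k, theta = theta[k], x_origin = x0,
                              y_origin = y0, z_origin = z0[k], length = L,
                              radius = spec$canaliculus_radius)
    }
    canaliculi <- do.call(rbind, rows)
  }

  # --- mineralization ground truth
  set.seed(substreams[2])
  mineral <- array(FALSE, dim = shp)
  foci <- data.frame(id = integer(0), x_center = numeric(0),
                     y_center = numeric(0), z_center = numeric(0),
                     radius = numeric(0), volume = numeric(0))
  p2dv <- as.vector(p2d)
  if (spec$mineral_mode == "bernoulli") {
    for (k in seq_len(nz)) {
      sl <- comp[, , k] == COMP_MATRIX & !suppress[, , k]
      mineral[, , k] <- sl & (runif(nxy) < p2dv)
    }
  } else {
    allowed <- (comp == COMP_MATRIX) & !suppress
    lam <- rep(p2dv, nz) * allowed * h^3 /
      mean_focus_volume(spec$foci_radius_distribution)
    n_foci <- rpois(1, sum(lam))
    if (n_foci > 0) {
      pos <- which(lam > 0)
      idx <- sample(pos, n_foci, replace = TRUE, prob = lam[pos])
      ixv <- (idx - 1) %% nx + 1
      iyv <- ((idx - 1) %/% nx) %% ny + 1
      izv <- (idx - 1) %/% nxy + 1
      cxs <- (ixv - 0.5 + runif(n_foci, -0.5, 0.5)) * h
      cys <- (iyv - 0.5 + runif(n_foci, -0.5, 0.5)) * h
      czs <- (izv - 0.5 + runif(n_foci, -0.5, 0.5)) * h
      radii <- draw_focus_radii(spec$foci_radius_distribution, n_foci)
      for (k in seq_len(n_foci)) {
        r <- radii[k]
        ix <- max(1L, floor((cxs[k] - r) / h)):min(nx, ceiling((cxs[k] + r) / h) + 1L)
        iy <- max(1L, floor((cys[k] - r) / h)):min(ny, ceiling((cys[k] + r) / h) + 1L)
        iz <- max(1L, floor((czs[k] - r) / h)):min(nz, ceiling((czs[k] + r) / h) + 1L)
        d2 <- outer(outer((xs[ix] - cxs[k])^2, (ys[iy] - cys[k])^2, "+"),
                    (zs[iz] - czs[k])^2, "+")
        inside <- d2 <= r^2 & allowed[ix, iy, iz]
        mb <- mineral[ix, iy, iz]
        mineral[ix, iy, iz] <- mb | inside
      }
      foci <- data.frame(id = seq_len(n_foci), x_center = cxs, y_center = cys,
                         z_center = czs, radius = radii,
                         volume = 4 / 3 * pi * radii^3)
    }
  }

  # --- gray values: class mean + i.i.d. Gaussian noise, clipped to [0,255]
  set.seed(substreams[3])
  gm <- spec$gray_means; gs <- spec$gray_sds
  gray <- array(0L, dim = shp)
  for (k in seq_len(nz)) {
    cls <- comp[, , k]
    mu <- ifelse(cls != COMP_MATRIX, gm[1], ifelse(mineral[, , k], gm[3], gm[2]))
    sdv <- ifelse(cls != COMP_MATRIX, gs[1], ifelse(mineral[, , k], gs[3], gs[2]))
    g <- round(mu + rnorm(nxy) * sdv)
    gray[, , k] <- pmin(pmax(g, 0), 255)
  }

  truth_class <- array(CLS_NON_MATRIX, dim = shp)
  is_matrix <- comp == COMP_MATRIX
  truth_class[is_matrix] <- ifelse(mineral[is_matrix], CLS_MINERALIZED,
                                   CLS_UNMINERALIZED)

  list(volume = voxel_volume(gray, h),
       truth = structure(list(
         compartments = compartment_map(comp, h),
         matrix_class_truth = truth_class,
         front_start_radius = spec$front_profile$start,
         front_width_5_95 = front_width_5_95(spec$front_profile),
         halo_radius_by_stage = spec$halo_radius_by_stage,
         canaliculi = canaliculi, foci = foci, spec = spec),
         class = "phantom_truth"))
}

#' Specify imaging artifacts for a phantom stack
#'
#' Parameters of the three artifact families seen in serial surface
#' imaging: cumulative per-slice lateral drift, additive Gaussian image
#' noise, and "curtaining" stripes that run along the milling direction.
#' Zero amplitudes everywhere make [add_artifacts()] the identity.
#'
#' @param drift_per_slice SD of the per-slice lateral drift increment, um.
#' @param stripe_amplitude peak stripe amplitude in gray levels.
#' @param stripe_axis in-plane axis (1 or 2) the stripes run along.
#' @param n_stripes number of stripe bumps across the field.
#' @param noise_sd_extra SD of additional Gaussian noise, gray levels.
#' @param seed integer seed.
#' @return An object of class `artifact_spec`.
#' @export
artifact_spec <- function(drift_per_slice = 0.05, stripe_amplitude = 8,
                          stripe_axis = 1L, n_stripes = 12L,
                          noise_sd_extra = 4, seed = 1L) {
  if (drift_per_slice < 0 || stripe_amplitude < 0 || noise_sd_extra < 0)
    stop("artifact amplitudes must be >= 0")
  if (!stripe_axis %in% 1:2) stop("stripe_axis must be 1 or 2")
  structure(list(drift_per_slice = drift_per_slice,
                 stripe_amplitude = stripe_amplitude,
                 stripe_axis = as.integer(stripe_axis),
                 n_stripes = as.integer(n_stripes),
                 noise_sd_extra = noise_sd_extra, seed = as.integer(seed)),
            class = "artifact_spec")
}

# translate a slice by whole voxels, filling uncovered margins
translate_slice <- function(m, dx, dy, fill) {
  if (dx == 0 && dy == 0) return(m)
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(fill, n1, n2)
  src1 <- max(1, 1 - dx):min(n1, n1 - dx)
  src2 <- max(1, 1 - dy):min(n2, n2 - dy)
  if (length(src1) > 0 && length(src2) > 0)
    out[src1 + dx, src2 + dy] <- m[src1, src2]
  out
}

#' Add imaging artifacts to a volume
#'
#' Applies, in order: cumulative per-slice lateral shifts along the slicing
#' axis (axis 3), rounded to whole voxels; an additive stripe pattern that
#' is constant along the milling direction within each slice and identical
#' across slices; and extra Gaussian noise. The output is clipped to
#' `[0, 255]`. The applied per-slice shift sequence is attached as
#' attribute `"shift_trace"` (data frame of um shifts, first slice zero)
#' for use as alignment ground truth.
#'
#' @param volume a [voxel_volume()].
#' @param art an [artifact_spec()].
#' @return A [voxel_volume()] with attribute `shift_trace`.
#' @export
add_artifacts <- function(volume, art) {
  stopifnot(inherits(volume, "voxel_volume"), inherits(art, "artifact_spec"))
  d <- dim(volume$gray)
  nz <- d[3]; h <- volume$voxel_size
  set.seed(art$seed)
  gray <- volume$gray
  shifts_vox <- matrix(0L, nz, 2)

  if (art$drift_per_slice > 0 && nz > 1) {
    inc <- matrix(rnorm(2 * (nz - 1), 0, art$drift_per_slice), ncol = 2)
    pos <- rbind(c(0, 0), apply(inc, 2, cumsum))
    shifts_vox <- matrix(as.integer(round(pos / h)), ncol = 2)
    for (k in seq_len(nz)) {
      if (any(shifts_vox[k, ] != 0L)) {
        sl <- gray[, , k]
        gray[, , k] <- translate_slice(sl, shifts_vox[k, 1], shifts_vox[k, 2],
                                       fill = median(sl))
      }
    }
  }

  if (art$stripe_amplitude > 0) {
    nacross <- if (art$stripe_axis == 1L) d[2] else d[1]
    centers <- sample.int(nacross, min(art$n_stripes, nacross))
    widths <- sample(1:3, length(centers), replace = TRUE)
    amps <- art$stripe_amplitude * runif(length(centers), 0.5, 1) *
      sample(c(-1, 1), length(centers), replace = TRUE)
    u <- seq_len(nacross)
    prof <- rep(0, nacross)
    for (j in seq_along(centers))
      prof <- prof + amps[j] * exp(-(u - centers[j])^2 / (2 * widths[j]^2))
    add <- if (art$stripe_axis == 1L) rep(prof, each = d[1]) else rep(prof, d[2])
    for (k in seq_len(nz)) gray[, , k] <- gray[, , k] + add
  }

  if (art$noise_sd_extra > 0)
    for (k in seq_len(nz))
      gray[, , k] <- gray[, , k] + rnorm(d[1] * d[2], 0, art$noise_sd_extra)

  gray <- array(pmin(pmax(round(gray), 0), 255), dim = d)
  out <- voxel_volume(gray, h)
  attr(out, "shift_trace") <- data.frame(slice = seq_len(nz),
                                         dx_um = shifts_vox[, 1] * h,
                                         dy_um = shifts_vox[, 2] * h)
  out
}
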