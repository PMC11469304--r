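#' Label codes for compartments and matrix classes
#'
#' Integer codes used throughout the package and in exported label TIFFs:
#' compartments are `COMP_MATRIX` (0), `COMP_HAVERSIAN` (1) and `COMP_LCN`
#' (2); matrix mineralization classes are `CLS_UNMINERALIZED` (3),
#' `CLS_INTERMEDIATE` (4) and `CLS_MINERALIZED` (5), with `CLS_NON_MATRIX`
#' (0) marking voxels outside the bone matrix (canal or LCN porosity).
#'
#' @name label-codes
#' @keywords datasets
NULL

#' @rdname label-codes
#' @export
COMP_MATRIX <- 0L
#' @rdname label-codes
#' @export
COMP_HAVERSIAN <- 1L
#' @rdname label-codes
#' @export
COMP_LCN <- 2L
#' @rdname label-codes
#' @export
CLS_NON_MATRIX <- 0L
#' @rdname label-codes
#' @export
CLS_UNMINERALIZED <- 3L
#' @rdname label-codes
#' @export
CLS_INTERMEDIATE <- 4L
#' @rdname label-codes
#' @export
CLS_MINERALIZED <- 5L

#' Construct a voxel volume
#'
#' A `voxel_volume` is the package's container for a 3D gray-value image
#' stack: an integer array with values in 0--255 plus the physical edge
#' length of its isotropic voxels.
#'
#' @param gray 3D integer array of gray values in `[0, 255]`.
#' @param voxel_size isotropic voxel edge length in micrometers.
#' @return An object of class `voxel_volume` with elements `gray` and
#'   `voxel_size`.
#' @export
voxel_volume <- function(gray, voxel_size) {
  if (length(dim(gray)) != 3L)
    stop("`gray` must be a 3D array")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (micrometers)")
  rng <- range(gray)
  if (rng[1] < 0 || rng[2] > 255)
    stop("gray values must lie in [0, 255]")
  storage.mode(gray) <- "integer"
  structure(list(gray = gray, voxel_size = as.numeric(voxel_size)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$gray)
  cat(sprintf(
    "<voxel_volume> %d x %d x %d voxels, %.0f nm voxels (%.1f x %.1f x %.1f um)\n",
    d[1], d[2], d[3], x$voxel_size * 1000,
    d[1] * x$voxel_size, d[2] * x$voxel_size, d[3] * x$voxel_size))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$gray)

#' Construct a compartment map
#'
#' A `compartment_map` holds a per-voxel structural label distinguishing
#' the Haversian canal, the lacunocanalicular network (LCN) and the bone
#' matrix; it must be co-registered with its gray volume.
#'
#' @param labels 3D integer array over the compartment codes
#'   [COMP_MATRIX], [COMP_HAVERSIAN], [COMP_LCN].
#' @param voxel_size isotropic voxel edge length in micrometers.
#' @return An object of class `compartment_map`.
#' @export
compartment_map <- function(labels, voxel_size) {
  if (length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  if (!all(labels %in% c(COMP_MATRIX, COMP_HAVERSIAN, COMP_LCN)))
    stop("compartment labels must be 0 (matrix), 1 (Haversian) or 2 (LCN)")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, voxel_size = as.numeric(voxel_size)),
            class = "compartment_map")
}

#' @export
print.compartment_map <- function(x, ...) {
  d <- dim(x$labels)
  tb <- tabulate(x$labels + 1L, 3L)
  cat(sprintf(
    "<compartment_map> %d x %d x %d voxels: %d matrix, %d Haversian, %d LCN\n",
    d[1], d[2], d[3], tb[1], tb[2], tb[3]))
  invisible(x)
}

#' @export
dim.compartment_map <- function(x) dim(x$labels)

#' Construct a matrix class map
#'
#' Per-voxel mineralization class resulting from histogram thresholding:
#' unmineralized, intermediate or mineralized on matrix voxels and
#' `CLS_NON_MATRIX` elsewhere.
#'
#' @param class 3D integer array over [CLS_NON_MATRIX],
#'   [CLS_UNMINERALIZED], [CLS_INTERMEDIATE], [CLS_MINERALIZED].
#' @param voxel_size isotropic voxel edge length in micrometers.
#' @return An object of class `matrix_class_map`.
#' @export
matrix_class_map <- function(class, voxel_size) {
  if (length(dim(class)) != 3L)
    stop("`class` must be a 3D array")
  storage.mode(class) <- "integer"
  structure(list(class = class, voxel_size = as.numeric(voxel_size)),
            class = "matrix_class_map")
}

#' @export
dim.matrix_class_map <- function(x) dim(x$class)

#' @export
print.matrix_class_map <- function(x, ...) {
  tb <- tabulate(x$class + 1L, 6L)
  cat(sprintf(
    "<matrix_class_map> %d unmineralized, %d intermediate, %d mineralized, %d non-matrix\n",
    tb[4], tb[5], tb[6], tb[1]))
  invisible(x)
}

# voxel centers: voxel i spans [(i-1)*h, i*h], center at (i - 0.5)*h
voxel_centers <- function(n, voxel_size) (seq_len(n) - 0.5) * voxel_size
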