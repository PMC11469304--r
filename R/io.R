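collect_tiff_slices <- function(path) {
  if (length(path) == 1 && dir.exists(path))
    path <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                            ignore.case = TRUE))
  if (length(path) == 0) stop("no TIFF files found")
  missing <- path[!file.exists(path)]
  if (length(missing) > 0)
    stop("input file not found: ", paste(missing, collapse = ", "))
  slices <- list()
  for (p in path) {
    r <- tiff::readTIFF(p, all = TRUE, as.is = TRUE)
    if (!is.list(r)) r <- list(r)
    slices <- c(slices, r)
  }
  slices
}

#' Read a gray-value volume from TIFF
#'
#' Accepts a multi-page 8-bit grayscale TIFF, a directory of numbered
#' single-page TIFFs, or a vector of file paths (slices are stacked in
#' lexical order). Writing with [write_volume()] and reading back is
#' bit-identical.
#'
#' @param path file, directory or vector of files.
#' @param voxel_size isotropic voxel edge, um.
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path, voxel_size = 0.04) {
  slices <- collect_tiff_slices(path)
  if (any(vapply(slices, function(s) length(dim(s)) != 2L, logical(1))))
    stop("expected single-channel grayscale slices")
  rng <- range(vapply(slices, range, numeric(2)))
  if (rng[2] > 255)
    stop("input is not 8-bit (gray values up to ", rng[2],
         "); convert it to 8-bit gray before loading")
  d <- dim(slices[[1]])
  gray <- array(0L, dim = c(d[1], d[2], length(slices)))
  for (k in seq_along(slices)) gray[, , k] <- as.integer(slices[[k]])
  voxel_volume(gray, voxel_size)
}

#' Write a volume (or label array) as multi-page 8-bit TIFF
#'
#' @param volume a [voxel_volume()], [compartment_map()],
#'   [matrix_class_map()] or plain 3D integer array with values in
#'   0-255.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_volume <- function(volume, path) {
  arr <- if (inherits(volume, "voxel_volume")) volume$gray
         else if (inherits(volume, "compartment_map")) volume$labels
         else if (inherits(volume, "matrix_class_map")) volume$class
         else volume
  stopifnot(length(dim(arr)) == 3L, min(arr) >= 0, max(arr) <= 255)
  slices <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k] / 255)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(slices, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a label volume from TIFF
#'
#' @param path file, directory or vector of files.
#' @param voxel_size isotropic voxel edge, um.
#' @param kind `"compartment"` or `"class"`.
#' @return A [compartment_map()] or [matrix_class_map()].
#' @export
read_labels <- function(path, voxel_size = 0.04,
                        kind = c("compartment", "class")) {
  kind <- match.arg(kind)
  vol <- read_volume(path, voxel_size)
  if (kind == "compartment") compartment_map(vol$gray, voxel_size)
  else matrix_class_map(vol$gray, voxel_size)
}

#' Persist a histogram model as key-value text
#'
#' @param model a [histogram_model()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_model <- function(model, path) {
  keys <- c("p", "u", "q", "m", "d", "delta_m", "delta_m_threshold")
  lines <- vapply(keys, function(k)
    sprintf("%s = %.10g", k, model[[k]]), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  parts <- strsplit(readLines(path), " = ", fixed = TRUE)
  kv <- setNames(vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
                 vapply(parts, `[`, character(1), 1))
  histogram_model(p = kv[["p"]], u = kv[["u"]], q = kv[["q"]], m = kv[["m"]])
}

#' Write a generated phantom and its ground truth to disk
#'
#' Writes the gray volume and the compartment/mineralization label volumes
#' as multi-page 8-bit TIFF, the scalar ground truth as a plain-text
#' key-value metadata file, and the true foci and canaliculi as CSV.
#'
#' @param phantom output of [generate_phantom()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(phantom$volume, file.path(dir, "gray.tif"))
  write_volume(phantom$truth$compartments, file.path(dir, "compartments.tif"))
  write_volume(phantom$truth$matrix_class_truth,
               file.path(dir, "matrix_class_truth.tif"))
  tr <- phantom$truth
  halo <- tr$halo_radius_by_stage
  meta <- c(sprintf("voxel_size_um = %.10g", phantom$volume$voxel_size),
            sprintf("front_start_radius_um = %.10g", tr$front_start_radius),
            sprintf("front_width_5_95_um = %.10g", tr$front_width_5_95),
            sprintf("halo_radius_um_stage_%s = %.10g", names(halo), halo),
            sprintf("n_canaliculi = %d", nrow(tr$canaliculi)),
            sprintf("n_foci = %d", nrow(tr$foci)),
            sprintf("seed = %d", tr$spec$seed))
  writeLines(meta, file.path(dir, "ground_truth.txt"))
  write.csv(tr$foci, file.path(dir, "foci.csv"), row.names = FALSE)
  write.csv(tr$canaliculi, file.path(dir, "canaliculi.csv"),
            row.names = FALSE)
  invisible(dir)
}
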