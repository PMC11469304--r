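#' Build a pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with defaults set to
#' the standard analysis constants: 0.27 um distance bins against the
#' Haversian canal and 0.095 um against the canaliculi, a 5-gray-level
#' histogram smoothing window, 5% moving-average windows, shell centers
#' at D = 0.1, 0.25, 0.5 and 2 um with 0.095 um ring width, 8 x 8 um^2
#' staged cross-sections, a 1 um^3 focus neighborhood cube and
#' 26-connectivity with a 2-voxel minimum focus size.
#'
#' @param gray_path path to the gray volume (TIFF).
#' @param compartments_path optional path to a co-registered compartment
#'   label TIFF (codes 0 = matrix, 1 = Haversian, 2 = LCN); if `NULL` the
#'   reference compartments are segmented automatically.
#' @param out_dir output directory.
#' @param voxel_size isotropic voxel edge, um.
#' @param bin_width_canal,bin_width_lcn distance bin widths, um.
#' @param smoothing_window histogram smoothing window, gray levels.
#' @param window_fraction moving-average window as a data fraction.
#' @param shell_centers shell center distances D, um.
#' @param ring_width shell ring width, um.
#' @param stage_step,cross_section staged-region extent and cross-section
#'   side, um.
#' @param cube_edge focus neighborhood cube edge, um.
#' @param connectivity,min_focus_size focus labeling parameters.
#' @param margin interior margin stripped before canalicular and foci
#'   statistics, um.
#' @param align,destripe_strength,denoise_method,denoise_radius optional
#'   preprocessing: rigid per-slice alignment, destriping strength (0
#'   disables), and denoising (`"none"`, `"median"` or `"gaussian"` with
#'   the given radius).
#' @param plots also write diagnostic plots (PNG).
#' @param stop_after last stage to execute (`"segmentation"`,
#'   `"distance"`, `"profiles"`, `"canaliculi"` or `NULL` for the full
#'   pipeline).
#' @param seed integer seed recorded in the manifest.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(gray_path = NULL, compartments_path = NULL,
                            out_dir = "mineralfront-out", voxel_size = 0.04,
                            bin_width_canal = 0.27, bin_width_lcn = 0.095,
                            smoothing_window = 5L, window_fraction = 0.05,
                            shell_centers = c(0.1, 0.25, 0.5, 2),
                            ring_width = 0.095, stage_step = 2,
                            cross_section = 8, cube_edge = 1,
                            connectivity = 26L, min_focus_size = 2L,
                            margin = 1, align = FALSE,
                            destripe_strength = 0,
                            denoise_method = "none", denoise_radius = 1L,
                            plots = FALSE, stop_after = NULL, seed = 1L) {
  cfg <- list(gray_path = gray_path, compartments_path = compartments_path,
              out_dir = out_dir, voxel_size = voxel_size,
              bin_width_canal = bin_width_canal,
              bin_width_lcn = bin_width_lcn,
              smoothing_window = as.integer(smoothing_window),
              window_fraction = window_fraction,
              shell_centers = shell_centers, ring_width = ring_width,
              stage_step = stage_step, cross_section = cross_section,
              cube_edge = cube_edge, connectivity = as.integer(connectivity),
              min_focus_size = as.integer(min_focus_size), margin = margin,
              align = isTRUE(align), destripe_strength = destripe_strength,
              denoise_method = denoise_method,
              denoise_radius = as.integer(denoise_radius),
              plots = isTRUE(plots), stop_after = stop_after,
              seed = as.integer(seed))
  num <- c("voxel_size", "bin_width_canal", "bin_width_lcn",
           "window_fraction", "ring_width", "stage_step", "cross_section",
           "cube_edge")
  for (k in num)
    if (cfg[[k]] <= 0) stop("pipeline_config: ", k, " must be > 0")
  if (!cfg$denoise_method %in% c("none", "median", "gaussian"))
    stop("pipeline_config: denoise_method must be none, median or gaussian")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unspecified keys keep
#' their defaults.
#'
#' @param path YAML file.
#' @param ... overrides applied on top of the file.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  dots <- list(...)
  vals[names(dots)] <- dots
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

write_csv_units <- function(df, path, units) {
  # units line as a structured comment above the header keeps every
  # numeric column's physical unit machine-readable
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ", units), con)
  write.csv(df, con, row.names = FALSE)
}

#' Run the full mineralization-quantification pipeline
#'
#' Executes, in order: loading, optional preprocessing (alignment,
#' destriping, denoising), histogram-model segmentation, canal and LCN
#' distance transforms, distance profiles (GVPD, moving averages,
#' V_MM/V_TM, transition zone), canalicular staging with shell profiles
#' and halo widths, and foci analysis. Every product is written as CSV
#' (units in the header comment) under `out_dir`, together with a YAML
#' run manifest echoing the configuration, per-stage timing and warnings.
#' A failing stage aborts with a stage-named error; products of earlier
#' stages are retained.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "mineralfront",
                   version = as.character(utils::packageVersion("mineralfront")),
                   seed = config$seed,
                   config = unclass(config), stages = list())
  res <- list()
  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    warns <- character(0)
    out <- withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    manifest$stages[[name]] <<- list(
      status = "completed",
      seconds = round(proc.time()[["elapsed"]] - t0, 2),
      warnings = if (length(warns)) warns else NULL)
    yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
    out
  }

  finish <- function() {
    yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
    invisible(list(results = res, manifest = manifest))
  }

  res$volume <- run_stage("load", {
    if (is.null(config$gray_path)) stop("config$gray_path is not set")
    read_volume(config$gray_path, config$voxel_size)
  })

  do_preprocess <- config$align || config$destripe_strength > 0 ||
    config$denoise_method != "none"
  if (do_preprocess) {
    res$volume <- run_stage("preprocess", {
      v <- res$volume
      if (config$align) {
        al <- align_stack(v)
        v <- al$volume
        write_csv_units(al$trace, file.path(config$out_dir, "shift_trace.csv"),
                        "slice [index], dx_um [um], dy_um [um]")
      }
      if (config$destripe_strength > 0)
        v <- destripe(v, strength = config$destripe_strength)
      if (config$denoise_method != "none")
        v <- denoise(v, config$denoise_method, config$denoise_radius)
      v
    })
  }

  seg <- run_stage("segmentation", {
    if (!is.null(config$compartments_path)) {
      comp <- read_labels(config$compartments_path, config$voxel_size,
                          "compartment")
      model <- fit_histogram_model(res$volume, comp, config$smoothing_window)
    } else {
      bootstrap <- fit_histogram_model(res$volume, NULL,
                                       config$smoothing_window)
      comp <- segment_reference_compartments(res$volume, bootstrap)
      model <- fit_histogram_model(res$volume, comp, config$smoothing_window)
    }
    classmap <- classify_matrix(res$volume, comp, model)
    write_model(model, file.path(config$out_dir, "histogram_model.txt"))
    write_volume(classmap, file.path(config$out_dir, "matrix_class.tif"))
    writeLines(c("# label codes in matrix_class.tif",
                 "0 = non-matrix (Haversian canal or LCN)",
                 "3 = unmineralized matrix", "4 = intermediate",
                 "5 = mineralized matrix"),
               file.path(config$out_dir, "matrix_class_codes.txt"))
    list(comp = comp, model = model, classmap = classmap)
  })
  res <- c(res, seg)
  if (identical(config$stop_after, "segmentation")) return(finish())

  dmaps <- run_stage("distance", {
    list(canal = distance_transform(res$comp, COMP_HAVERSIAN),
         lcn = if (any(res$comp$labels == COMP_LCN))
           distance_transform(res$comp, COMP_LCN) else NULL)
  })
  res <- c(res, dmaps)
  if (identical(config$stop_after, "distance")) return(finish())

  prof <- run_stage("profiles", {
    gv <- compute_gvpd(res$volume, res$canal, res$comp,
                       config$bin_width_canal)
    gv_df <- data.frame(bin_center_um = gv$bin_centers[gv$nonempty],
                        gv$probs[gv$nonempty, , drop = FALSE])
    names(gv_df)[-1] <- paste0("gray_", 0:255)
    write_csv_units(gv_df, file.path(config$out_dir, "gvpd_canal.csv"),
                    "bin_center_um [um], gray_* [probability]")
    curves <- lapply(c(ALL = "ALL", UNMINERALIZED = "UNMINERALIZED",
                       MINERALIZED = "MINERALIZED"), function(r)
      tryCatch(moving_average_curve(res$volume, res$canal, res$classmap,
                                    config$window_fraction, r),
               error = function(e) NULL))
    for (nm in names(curves))
      if (!is.null(curves[[nm]]))
        write_csv_units(curves[[nm]],
                        file.path(config$out_dir,
                                  sprintf("gray_vs_distance_%s.csv",
                                          tolower(nm))),
                        "distance [um], mean_gray [gray], n_window [voxels]")
    mp <- mineral_profile(res$classmap, res$canal, config$bin_width_canal)
    write_csv_units(mp, file.path(config$out_dir, "mineral_profile.csv"),
                    "bin_center [um], n_* [voxels], fraction [V_MM/V_TM]")
    tz <- detect_transition_zone(mp)
    write_csv_units(data.frame(front_um = tz$front, end_um = tz$end,
                               width_um = tz$width),
                    file.path(config$out_dir, "transition_zone.csv"),
                    "front_um/end_um/width_um [um]")
    if (config$plots) {
      save_plot(plot_gvpd(gv, curves$ALL),
                file.path(config$out_dir, "gvpd_canal.png"))
      save_plot(plot_mineral_profile(mp, tz),
                file.path(config$out_dir, "mineral_profile.png"))
    }
    list(gvpd = gv, curves = curves, profile = mp, transition = tz)
  })
  res <- c(res, prof)
  if (identical(config$stop_after, "profiles")) return(finish())

  canalicular <- run_stage("canaliculi", {
    if (is.null(res$lcn)) {
      warning("no LCN compartment; skipping canalicular statistics")
      NULL
    } else {
      cm <- crop_margin(res$classmap, config$margin)
      dl <- crop_margin(res$lcn, config$margin)
      dc <- crop_margin(res$canal, config$margin)
      regions <- stage_subvolumes(cm, dc, res$transition,
                                  step = config$stage_step,
                                  cross_section = config$cross_section)
      write_csv_units(regions, file.path(config$out_dir, "stage_regions.csv"),
                      "bounds [voxel index], vmm_vtm [V_MM/V_TM]")
      shells <- shell_profile(cm, dl, regions, config$shell_centers,
                              config$ring_width)
      write_csv_units(as.data.frame(shells),
                      file.path(config$out_dir, "shell_profile.csv"),
                      "D [um], mean_fraction [V_MM/V_TM], se [V_MM/V_TM], n_voxels [voxels]")
      hw <- do.call(rbind, lapply(intersect(c("I", "II", "III", "IV", "V"),
                                            unique(shells$stage)),
        function(st) {
          w <- tryCatch(halo_width(shells, st), error = function(e) NA_real_)
          data.frame(stage = st, halo_width_um = as.numeric(w),
                     plateau = if (is.null(attr(w, "plateau"))) NA_real_
                               else attr(w, "plateau"))
        }))
      if (!is.null(hw))
        write_csv_units(hw, file.path(config$out_dir, "halo_width.csv"),
                        "halo_width_um [um], plateau [V_MM/V_TM]")
      if (config$plots)
        save_plot(plot_shell_profile(shells),
                  file.path(config$out_dir, "shell_profile.png"))
      list(regions = regions, shells = shells, halo = hw)
    }
  })
  res$canalicular <- canalicular
  if (identical(config$stop_after, "canaliculi")) return(finish())

  res$foci <- run_stage("foci", {
    if (is.null(res$lcn)) {
      warning("no LCN compartment; skipping foci analysis")
      NULL
    } else {
      d <- dim(res$classmap$class)
      mv <- as.integer(round(config$margin / config$voxel_size))
      roi <- list(x = c(1L + mv, d[1] - mv), y = c(1L + mv, d[2] - mv),
                  z = c(1L + mv, d[3] - mv))
      recs <- analyze_foci(res$classmap, res$lcn, roi, config$cube_edge,
                           config$connectivity, config$min_focus_size)
      write_csv_units(recs, file.path(config$out_dir, "foci.csv"),
                      "volume [um^3], x/y/z [um], dist_lcn [um], local_fraction [V_MM/V_TM]")
      hists <- lapply(c(G1 = "G1", G2 = "G2", G3 = "G3"), function(g)
        foci_histogram(recs, g, dist_bin = config$bin_width_lcn))
      for (g in names(hists)) {
        hh <- hists[[g]]
        if (hh$n_foci > 0) {
          df <- data.frame(dist_bin_center_um =
                             head(hh$dist_breaks, -1) +
                             diff(hh$dist_breaks) / 2, hh$cells)
          names(df)[-1] <- sprintf("vol_bin_%d", seq_len(ncol(hh$cells)))
          write_csv_units(df, file.path(config$out_dir,
                                        sprintf("foci_histogram_%s.csv", g)),
                          "dist_bin_center_um [um], vol_bin_* [probability]")
        }
      }
      list(records = recs, histograms = hists)
    }
  })

  finish()
}
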