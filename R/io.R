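# Plain-text readers/writers: trajectory, ROI and dwell tables round-trip
# losslessly as CSV; fitted objects serialize to JSON with unit annotations.

trajectory_cols <- c("track_id", "frame", "x_um", "y_um", "cell_id")

#' Read a trajectory set from CSV
#'
#' @param path localization CSV with header
#'   `track_id,frame,x_um,y_um,cell_id` (an optional `state` column is
#'   preserved).
#' @param rois_path ROI CSV with header `cell_id,cx_um,cy_um,r_um`; if
#'   missing, one bounding circle per cell is derived from the localizations.
#' @param dt_frame,sigma_loc acquisition metadata, s and um.
#' @return a [trajectory_set()].
#' @export
read_trajectories <- function(path, rois_path = NULL, dt_frame = 0.04,
                              sigma_loc = 0.02) {
  locs <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(trajectory_cols, names(locs))
  if (length(miss)) {
    stop_sptk("'", path, "' missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(!stats::complete.cases(locs[trajectory_cols]))
  if (length(bad)) {
    stop_sptk("malformed row(s) in '", path, "' at data line(s) ",
              paste(utils::head(bad, 5L), collapse = ", "))
  }
  # whole-number id/frame columns come back as integers so that write/read
  # round trips are type-identical
  for (cl in c("track_id", "frame", "cell_id", "state")) {
    if (cl %in% names(locs) && is.numeric(locs[[cl]]) &&
        all(locs[[cl]] == round(locs[[cl]]))) {
      locs[[cl]] <- as.integer(locs[[cl]])
    }
  }
  rois <- if (!is.null(rois_path)) {
    readr::read_csv(rois_path, show_col_types = FALSE, progress = FALSE)
  } else {
    locs |>
      dplyr::summarise(cx_um = mean(range(.data$x_um)),
                       cy_um = mean(range(.data$y_um)),
                       r_um = max(sqrt((.data$x_um - mean(range(.data$x_um)))^2 +
                                         (.data$y_um - mean(range(.data$y_um)))^2)) +
                         1e-6,
                       .by = "cell_id")
  }
  trajectory_set(locs, rois, dt_frame = dt_frame, sigma_loc = sigma_loc)
}

#' Write a trajectory set to CSV
#'
#' @param data a `trajectory_set`.
#' @param path output localization CSV.
#' @param rois_path optional output ROI CSV.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(data, path, rois_path = NULL) {
  stopifnot(inherits(data, "trajectory_set"))
  readr::write_csv(data$locs, path, progress = FALSE)
  if (!is.null(rois_path)) readr::write_csv(data$rois, rois_path,
                                            progress = FALSE)
  invisible(path)
}

#' Read/write dwell-time observations
#'
#' CSV header: `tau_tl_s,tau_int_s,n_frames`.
#' @param path CSV path.
#' @return tibble of dwell observations.
#' @export
read_dwells <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("tau_tl_s", "tau_int_s", "n_frames"), names(d))
  if (length(miss)) stop_sptk("'", path, "' missing column(s): ",
                              paste(miss, collapse = ", "))
  d
}

#' @rdname read_dwells
#' @param dwells tibble of dwell observations.
#' @export
write_dwells <- function(dwells, path) {
  readr::write_csv(dwells, path, progress = FALSE)
  invisible(path)
}

#' Serialize fitted objects to annotated JSON
#'
#' Writes a `mobility_model`, `rate_posterior` or `dwell_fit` as JSON with
#' explicit unit annotations and the provenance hash of the configuration
#' that produced it.
#'
#' @param x fitted object.
#' @param path output JSON path.
#' @param config_hash optional provenance string embedded in the file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(x, path, config_hash = NULL) {
  payload <- if (inherits(x, "mobility_model")) {
    list(type = "mobility_model", K = x$K,
         D_um2_s = x$D, D_sd_um2_s = x$D_sd,
         pi = x$pi, T_frame = x$T_frame,
         dt_frame_s = x$dt_frame, sigma_loc_um = x$sigma_loc,
         loglik = x$loglik, bic = x$bic,
         diagnostics = x$mcmc_diagnostics, seed = x$seed)
  } else if (inherits(x, "rate_posterior")) {
    list(type = "rate_posterior", K = x$K,
         rates_per_s = as.list(x$rates),
         hdi95_per_s = x$hdi95,
         acceptance_rate = x$acceptance_rate)
  } else if (inherits(x, "dwell_fit")) {
    list(type = "dwell_fit",
         k_diss_per_s = x$k_diss, k_diss_se_per_s = x$k_diss_se,
         k_bleaching_per_s = x$k_bleaching,
         k_bleaching_se_per_s = x$k_bleaching_se,
         mean_dwell_s = x$mean_dwell, flagged = x$flagged,
         per_interval = x$per_interval)
  } else stop_sptk("unsupported object of class ", class(x)[1L])
  payload$config_hash <- config_hash
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Write a heatmap as a plain-text matrix
#'
#' @param img a `heatmap_image`.
#' @param path output path (tab-separated matrix, one row per x grid line).
#' @export
write_heatmap_txt <- function(img, path) {
  stopifnot(inherits(img, "heatmap_image"))
  utils::write.table(img$z, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read/write configuration objects as JSON or YAML
#'
#' The format is chosen from the file extension (`.json`, `.yaml`/`.yml`).
#' @param path config file path.
#' @return a plain named list of configuration values.
#' @export
read_config_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else stop_sptk("unsupported config extension '", ext, "'")
}

#' @rdname read_config_file
#' @param config a config object (any of the `*_config()` lists).
#' @export
write_config_file <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  x <- unclass(config)
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, matrix = "rowmajor")
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path)
  } else stop_sptk("unsupported config extension '", ext, "'")
  invisible(path)
}
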