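#' Construct a trajectory set
#'
#' A `trajectory_set` bundles single-molecule localization records with the
#' acquisition metadata every downstream stage needs: the frame interval, the
#' localization precision, and one circular nucleus ROI per cell.
#'
#' @param locs tibble/data frame of localizations with columns `track_id`,
#'   `frame` (0-based, strictly increasing within a track), `x_um`, `y_um`,
#'   `cell_id`, and optionally `state` (ground-truth step labels from
#'   simulation).
#' @param rois tibble with columns `cell_id`, `cx_um`, `cy_um`, `r_um`.
#' @param dt_frame frame interval, s.
#' @param sigma_loc localization error s.d. per coordinate, um.
#' @param seed seed recorded for provenance (optional).
#' @return object of class `trajectory_set`.
#' @export
trajectory_set <- function(locs, rois, dt_frame, sigma_loc, seed = NA_integer_) {
  locs <- tibble::as_tibble(locs)
  rois <- tibble::as_tibble(rois)
  need <- c("track_id", "frame", "x_um", "y_um", "cell_id")
  miss <- setdiff(need, names(locs))
  if (length(miss)) stop_sptk("locs missing columns: ", paste(miss, collapse = ", "))
  miss <- setdiff(c("cell_id", "cx_um", "cy_um", "r_um"), names(rois))
  if (length(miss)) stop_sptk("rois missing columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(locs$x_um)) || !all(is.finite(locs$y_um))) {
    stop_sptk("non-finite coordinates in locs")
  }
  locs <- dplyr::arrange(locs, .data$track_id, .data$frame)
  dup <- duplicated(locs[, c("track_id", "frame")])
  if (any(dup)) {
    stop_sptk("duplicated (track_id, frame) pair at row ", which(dup)[1L])
  }
  bad <- locs |>
    dplyr::summarise(ok = all(diff(.data$frame) > 0) || dplyr::n() == 1L,
                     n = dplyr::n(), .by = "track_id")
  if (any(!bad$ok)) {
    stop_sptk("frames not strictly increasing in track ",
              bad$track_id[!bad$ok][1L])
  }
  if (any(bad$n < 2L)) {
    stop_sptk(sum(bad$n < 2L), " track(s) with a single localization; ",
              "drop them before constructing a trajectory_set")
  }
  orphan <- setdiff(unique(locs$cell_id), rois$cell_id)
  if (length(orphan)) stop_sptk("no ROI for cell_id ", orphan[1L])
  if (dt_frame <= 0) stop_sptk("dt_frame must be > 0")
  structure(
    list(locs = locs, rois = rois, dt_frame = dt_frame,
         sigma_loc = sigma_loc, seed = seed),
    class = "trajectory_set"
  )
}

#' @export
print.trajectory_set <- function(x, ...) {
  nt <- dplyr::n_distinct(x$locs$track_id)
  cat("<trajectory_set> ", nrow(x$locs), " localizations in ", nt,
      " tracks across ", nrow(x$rois), " cell(s)\n", sep = "")
  cat("  dt_frame = ", x$dt_frame, " s, sigma_loc = ", x$sigma_loc, " um",
      if ("state" %in% names(x$locs)) ", ground-truth states present", "\n",
      sep = "")
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.trajectory_set <- function(x, ...) x$locs

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.trajectory_set <- function(x, ...) x$locs

#' @export
glance.trajectory_set <- function(x, ...) {
  tibble::tibble(
    n_locs = nrow(x$locs),
    n_tracks = dplyr::n_distinct(x$locs$track_id),
    n_cells = nrow(x$rois),
    n_steps = nrow(track_steps(x)),
    dt_frame = x$dt_frame,
    sigma_loc = x$sigma_loc
  )
}

#' Per-step displacements of a trajectory set
#'
#' Converts localizations into single-frame displacement records, the unit of
#' analysis for mobility-state inference. Only consecutive frames contribute a
#' step; gaps are skipped. When ground-truth labels are present the step
#' inherits the label of its destination localization.
#'
#' @param data a `trajectory_set`.
#' @return tibble with columns `track_id`, `frame` (destination frame),
#'   `cell_id`, `x_um`, `y_um` (destination position), `dx_um`, `dy_um`,
#'   `step_um`, and `state` when available.
#' @export
track_steps <- function(data) {
  stopifnot(inherits(data, "trajectory_set"))
  locs <- data$locs
  has_state <- "state" %in% names(locs)
  out <- locs |>
    dplyr::group_by(.data$track_id) |>
    dplyr::mutate(
      dx_um = .data$x_um - dplyr::lag(.data$x_um),
      dy_um = .data$y_um - dplyr::lag(.data$y_um),
      dframe = .data$frame - dplyr::lag(.data$frame)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$dx_um), .data$dframe == 1L) |>
    dplyr::mutate(step_um = sqrt(.data$dx_um^2 + .data$dy_um^2))
  cols <- c("track_id", "frame", "cell_id", "x_um", "y_um",
            "dx_um", "dy_um", "step_um", if (has_state) "state")
  out[, cols]
}

#' @rdname plot_helpers
#' @description `plot_trajectories()` draws tracks colored by track (or
#'   ground-truth state) inside their nucleus ROIs.
#' @param data a `trajectory_set`.
#' @param color_by `"track"` or `"state"`.
#' @param max_tracks subsample cap for readability.
#' @export
plot_trajectories <- function(data, color_by = c("track", "state"),
                              max_tracks = 200L) {
  stopifnot(inherits(data, "trajectory_set"))
  color_by <- match.arg(color_by)
  locs <- data$locs
  keep <- utils::head(unique(locs$track_id), max_tracks)
  locs <- dplyr::filter(locs, .data$track_id %in% keep)
  circ <- data$rois |>
    dplyr::reframe(theta = seq(0, 2 * pi, length.out = 181),
                   x_um = .data$cx_um + .data$r_um * cos(.data$theta),
                   y_um = .data$cy_um + .data$r_um * sin(.data$theta),
                   .by = "cell_id")
  aes_col <- if (color_by == "state" && "state" %in% names(locs)) "factor(state)"
             else "factor(track_id)"
  ggplot2::ggplot(locs, ggplot2::aes(.data$x_um, .data$y_um)) +
    ggplot2::geom_path(ggplot2::aes(group = .data$track_id,
                                    color = !!rlang::parse_expr(aes_col)),
                       linewidth = 0.3, show.legend = color_by == "state") +
    ggplot2::geom_path(data = circ,
                       ggplot2::aes(group = .data$cell_id), color = "grey40") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  color = if (color_by == "state") "state" else NULL) +
    ggplot2::theme_minimal()
}
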