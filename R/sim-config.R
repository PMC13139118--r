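#' Simulation configuration for synthetic neutrophil time-lapse sequences
#'
#' Builds and validates the full parameterization of the synthetic time-lapse
#' generator. Defaults emulate the acquisition regime the pipeline targets:
#' 512 x 512 frames at 1-minute intervals, 120 frames per sequence, and a
#' cell density in the 10--40 cells/frame range.
#'
#' @param image_size Integer vector `c(height, width)` in pixels.
#' @param n_frames Number of frames in the sequence (>= 2).
#' @param n_cells_initial Number of cells present in the first frame.
#' @param cell_radius_range Numeric `c(min, max)` cell radius in pixels; the
#'   radius is the 20%-of-peak contour of the Gaussian intensity profile.
#' @param peak_intensity Peak intensity of a cell, arbitrary units.
#' @param background_level Constant background intensity, arbitrary units
#'   (default 0, i.e. background-subtracted fluorescence).
#' @param noise_sigma Standard deviation of additive Gaussian noise.
#' @param speed_mean Cell speed in pixels/frame.
#' @param persistence Directional correlation of the random walk in `[0, 1]`;
#'   1 = straight-line migration, 0 = uncorrelated headings.
#' @param p_appear Probability per frame that a new cell enters at the image
#'   border.
#' @param p_disappear Probability per frame that an existing cell leaves the
#'   field of view.
#' @param scripted_events List of [sim_event()] objects forcing appear,
#'   disappear, merge or split events at given frames.
#' @param min_separation Minimum center-to-center distance (pixels) enforced
#'   between cells; 0 disables enforcement and allows incidental collisions.
#' @param pixel_size Physical pixel size in micrometres/pixel.
#' @param frame_interval Time between frames in minutes.
#' @param seed Integer seed; identical seed and configuration produce
#'   bit-identical output.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_sequence()], [sim_event()]
#' @examples
#' cfg <- sim_config(image_size = c(128, 128), n_frames = 10,
#'                   n_cells_initial = 4, seed = 1)
#' @export
sim_config <- function(image_size = c(512L, 512L),
                       n_frames = 120L,
                       n_cells_initial = 20L,
                       cell_radius_range = c(4, 7),
                       peak_intensity = 1,
                       background_level = 0,
                       noise_sigma = 0.02,
                       speed_mean = 3,
                       persistence = 0.7,
                       p_appear = 0.02,
                       p_disappear = 0.02,
                       scripted_events = list(),
                       min_separation = 0,
                       pixel_size = 0.9,
                       frame_interval = 1,
                       seed = 1L) {
  cfg <- list(
    image_size = as.integer(image_size),
    n_frames = as.integer(n_frames),
    n_cells_initial = as.integer(n_cells_initial),
    cell_radius_range = as.numeric(cell_radius_range),
    peak_intensity = peak_intensity,
    background_level = background_level,
    noise_sigma = noise_sigma,
    speed_mean = speed_mean,
    persistence = persistence,
    p_appear = p_appear,
    p_disappear = p_disappear,
    scripted_events = scripted_events,
    min_separation = min_separation,
    pixel_size = pixel_size,
    frame_interval = frame_interval,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(
    length(cfg$image_size) == 2L, all(cfg$image_size >= 16L),
    cfg$n_frames >= 2L,
    cfg$n_cells_initial >= 0L,
    length(cfg$cell_radius_range) == 2L, all(cfg$cell_radius_range > 0),
    diff(cfg$cell_radius_range) >= 0,
    cfg$persistence >= 0, cfg$persistence <= 1,
    cfg$p_appear >= 0, cfg$p_appear <= 1,
    cfg$p_disappear >= 0, cfg$p_disappear <= 1,
    cfg$noise_sigma >= 0, cfg$speed_mean >= 0,
    cfg$pixel_size > 0, cfg$frame_interval > 0
  )
  # Packing feasibility: cells (plus enforced spacing) must fit the frame
  # without forced overlap, unless merges are deliberately scripted.
  has_merge <- any(vapply(cfg$scripted_events,
                          function(e) identical(e$kind, "merge"), logical(1)))
  rmax <- max(cfg$cell_radius_range)
  footprint <- max((2 * rmax)^2, cfg$min_separation^2 / 2) * cfg$n_cells_initial
  if (!has_merge && footprint > 0.5 * prod(cfg$image_size)) {
    stop("cell count x radius cannot fit the image without forced overlap",
         call. = FALSE)
  }
  for (e in cfg$scripted_events) {
    if (!inherits(e, "sim_event")) stop("scripted_events must be sim_event objects", call. = FALSE)
    if (e$frame < 0L || e$frame >= cfg$n_frames) {
      stop("event frame outside [0, n_frames)", call. = FALSE)
    }
  }
  cfg
}

#' Scripted cell behavioral event
#'
#' Describes one forced event in a simulated sequence, covering the five
#' behavioral patterns cells exhibit: persistent migration (no event),
#' appearance, disappearance, merging and splitting.
#'
#' @param kind One of `"appear"`, `"disappear"`, `"merge"`, `"split"`.
#' @param frame 0-based frame index at which the event takes place.
#' @param track_ids Integer ids of the tracks involved: `merge` needs at
#'   least two, `split` exactly one (the track leaving a merged group),
#'   `appear`/`disappear` exactly one.
#'
#' @return An object of class `sim_event`.
#' @export
sim_event <- function(kind, frame, track_ids) {
  kind <- match.arg(kind, c("appear", "disappear", "merge", "split"))
  track_ids <- as.integer(track_ids)
  if (kind == "merge" && length(track_ids) < 2L) {
    stop("merge events reference >= 2 tracks", call. = FALSE)
  }
  if (kind == "split" && length(track_ids) != 1L) {
    stop("split events reference exactly 1 track", call. = FALSE)
  }
  structure(list(kind = kind, frame = as.integer(frame),
                 track_ids = track_ids),
            class = "sim_event")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$image_size[1], "x", x$image_size[2], ", ",
      x$n_frames, " frames, ", x$n_cells_initial, " initial cells, seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}
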