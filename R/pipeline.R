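#' Full pipeline configuration
#'
#' Collects every stage's parameters into one serializable object that
#' round-trips losslessly through YAML ([write_config()]/[read_config()]).
#'
#' @param sim A [sim_config()] (used when the run simulates its input);
#'   may be a plain list when read back from YAML.
#' @param low_pct,high_pct,median_radius,gaussian_sigma Pre-processing
#'   parameters, see [preprocess_frame()].
#' @param seg_t,min_area Segmentation parameters, see [segment_reference()].
#' @param search_radius,normalize Scoring parameters, see
#'   [score_sequence()].
#' @param method Linkage method, see [link_tracks()].
#' @param T_truncated,T_merge,end_threshold,reroute_factor Linkage
#'   thresholds, see [linkage_params()].
#' @param match_radius Identification radius, see [match_identities()].
#' @param pixel_size,frame_interval,distant_threshold Migration parameters,
#'   see [migration_stats()].
#' @param seed Integer seed for the run.
#'
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sim_config(),
                       low_pct = 1, high_pct = 99.8,
                       median_radius = 1L, gaussian_sigma = 1,
                       seg_t = 0.1, min_area = 5L,
                       search_radius = 10, normalize = "pred",
                       method = "viterbi_ext",
                       T_truncated = 0.001, T_merge = 0.875,
                       end_threshold = 0.001, reroute_factor = 1,
                       match_radius = 10,
                       pixel_size = 0.9, frame_interval = 1,
                       distant_threshold = 2.4,
                       seed = 1L) {
  if (!inherits(sim, "sim_config")) {
    sim <- if (is.list(sim)) {
      sim$scripted_events <- lapply(sim$scripted_events, function(e) {
        if (inherits(e, "sim_event")) e else sim_event(e$kind, e$frame, e$track_ids)
      })
      do.call(sim_config, sim)
    } else {
      stop("`sim` must be a sim_config or list", call. = FALSE)
    }
  }
  structure(list(sim = sim, low_pct = low_pct, high_pct = high_pct,
                 median_radius = median_radius,
                 gaussian_sigma = gaussian_sigma, seg_t = seg_t,
                 min_area = min_area, search_radius = search_radius,
                 normalize = normalize, method = method,
                 T_truncated = T_truncated, T_merge = T_merge,
                 end_threshold = end_threshold,
                 reroute_factor = reroute_factor,
                 match_radius = match_radius, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 distant_threshold = distant_threshold,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full tracking pipeline
#'
#' Executes simulate (or load) -> preprocess -> segment -> score -> link ->
#' evaluate -> measure, writing every intermediate artifact plus a JSON
#' provenance record (configuration, per-stage counts) to `out_dir`.
#' Stage failures are reported with the stage name; artifacts written
#' before the failure are preserved.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param input Optional `sim_output` (or list with `frames`/`masks`/
#'   `tracks`) to use instead of simulating.
#' @param write_images Also write TIFF frame/mask stacks (default `TRUE`).
#'
#' @return Invisibly, a list with the in-memory stage results: `sim`,
#'   `masks`, `matrices`, `result`, `metrics`, `migration`, `provenance`.
#' @export
run_pipeline <- function(config, out_dir, input = NULL, write_images = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  prov <- list(config = unclass_config(config), stages = list())

  sim <- stage("simulate", {
    if (is.null(input)) simulate_sequence(config$sim) else input
  })
  prov$stages$simulate <- list(n_frames = length(sim$frames),
                               n_tracks = dplyr::n_distinct(sim$tracks$track_id))
  if (write_images) {
    stage("write_input", {
      write_frames(sim$frames, file.path(out_dir, "frames_raw.tif"))
      write_masks(sim$masks, file.path(out_dir, "gt_masks.tif"))
    })
  }
  write_tracks(sim$tracks, file.path(out_dir, "gt_tracks.csv"))
  readr::write_csv(sim$events, file.path(out_dir, "events.csv"))

  pre <- stage("preprocess", lapply(sim$frames, preprocess_frame,
                                    low_pct = config$low_pct,
                                    high_pct = config$high_pct,
                                    median_radius = config$median_radius,
                                    gaussian_sigma = config$gaussian_sigma))
  masks <- stage("segment", lapply(pre, segment_reference,
                                   t = config$seg_t,
                                   min_area = config$min_area))
  prov$stages$segment <- list(
    mean_cells = mean(vapply(masks, function(m) length(unique(m[m > 0])),
                             numeric(1))))
  if (write_images) {
    stage("write_segmentation", {
      write_frames(pre, file.path(out_dir, "frames_preprocessed.tif"))
      write_masks(masks, file.path(out_dir, "pred_masks.tif"))
    })
  }

  matrices <- stage("score", score_sequence(masks,
                                            search_radius = config$search_radius,
                                            normalize = config$normalize))
  prov$stages$score <- list(n_matrices = length(matrices))
  write_score_matrices(matrices, file.path(out_dir, "scores"))

  params <- linkage_params(config$T_truncated, config$T_merge,
                           config$end_threshold, config$reroute_factor)
  result <- stage("link", link_tracks(matrices, method = config$method,
                                      params = params))
  pred <- stage("positions", attach_positions(result, masks))
  write_tracks(pred, file.path(out_dir, "tracks.csv"))
  prov$stages$link <- as.list(glance(result))

  metrics <- stage("evaluate", compute_metrics(pred, sim$tracks,
                                               radius = config$match_radius))
  readr::write_csv(metrics, file.path(out_dir, "metrics.csv"))

  migration <- stage("measure", migration_stats(
    pred, pixel_size = config$pixel_size,
    frame_interval = config$frame_interval,
    distant_threshold = config$distant_threshold))
  readr::write_csv(migration, file.path(out_dir, "migration.csv"))

  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(sim = sim, masks = masks, matrices = matrices,
                 result = result, pred = pred, metrics = metrics,
                 migration = migration, provenance = prov))
}

unclass_config <- function(config) {
  obj <- unclass(config)
  obj$sim <- unclass(obj$sim)
  obj$sim$scripted_events <- lapply(obj$sim$scripted_events, unclass)
  obj
}

#' Render trajectory overlays as PNG frames
#'
#' Writes one PNG per frame with the intensity image in gray and each
#' track's trail up to that frame as a colored polyline; colors are keyed
#' deterministically to track ids.
#'
#' @param frames List of intensity matrices.
#' @param tracks Tibble with `track_id`, `frame`, `x`, `y`.
#' @param out_dir Output directory.
#'
#' @return Invisibly, the written file paths.
#' @export
render_overlay <- function(frames, tracks, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  h <- nrow(frames[[1]])
  w <- ncol(frames[[1]])
  rng <- range(unlist(lapply(frames, range)))
  ids <- sort(unique(tracks$track_id))
  hues <- (0.61803398875 * seq_along(ids)) %% 1  # golden-ratio spacing
  cols <- grDevices::hsv(hues, 0.9, 1)
  paths <- character(length(frames))
  for (t in seq_along(frames) - 1L) {
    g <- (frames[[t + 1L]] - rng[1]) / max(rng[2] - rng[1], 1e-12)
    img <- array(rep(g, 3L), dim = c(h, w, 3L))
    trail <- tracks[tracks$frame <= t, , drop = FALSE]
    for (k in seq_along(ids)) {
      tr <- trail[trail$track_id == ids[k], , drop = FALSE]
      if (nrow(tr) == 0L) next
      tr <- tr[order(tr$frame), ]
      rgbcol <- grDevices::col2rgb(cols[k]) / 255
      pts <- polyline_pixels(tr$x, tr$y, h, w)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[pts] <- rgbcol[ch]
        img[, , ch] <- plane
      }
    }
    paths[t + 1L] <- file.path(out_dir, sprintf("frame_%04d.png", t))
    png::writePNG(img, paths[t + 1L])
  }
  invisible(paths)
}

# Linear pixel indices of the polyline through (x, y) vertices (0-based).
polyline_pixels <- function(x, y, h, w) {
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  if (length(x) == 1L) {
    return(round(x) * h + round(y) + 1L)
  }
  idx <- integer(0)
  for (i in seq_len(length(x) - 1L)) {
    n <- max(2L, ceiling(max(abs(x[i + 1] - x[i]), abs(y[i + 1] - y[i]))) + 1L)
    xs <- round(seq(x[i], x[i + 1], length.out = n))
    ys <- round(seq(y[i], y[i + 1], length.out = n))
    idx <- c(idx, xs * h + ys + 1L)
  }
  unique(idx)
}
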