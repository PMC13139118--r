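#' Read and write image sequences as multi-page TIFF
#'
#' Intensity frames are stored as 32-bit float TIFF pages; labeled masks as
#' 16-bit pages (labels up to 65535). Both round-trip exactly.
#'
#' @param frames List of numeric matrices.
#' @param path Output file.
#' @name tiff_io
#' @return `write_frames`/`write_masks` return `path` invisibly;
#'   `read_frames` returns a list of numeric matrices, `read_masks` a list
#'   of integer matrices.
NULL

#' @rdname tiff_io
#' @export
write_frames <- function(frames, path) {
  rng <- range(unlist(lapply(frames, range)))
  if (rng[1] < 0 || rng[2] > 1) {
    # TIFF float samples only represent [0, 1] reliably here; rescale and
    # record the affine transform in a sidecar so reads invert it
    span <- max(rng[2] - rng[1], .Machine$double.eps)
    frames <- lapply(frames, function(f) (f - rng[1]) / span)
    jsonlite::write_json(list(min = rng[1], max = rng[2]),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else if (file.exists(paste0(path, ".json"))) {
    unlink(paste0(path, ".json"))
  }
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname tiff_io
#' @export
read_frames <- function(path) {
  out <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(out)) out <- list(out)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    rng <- jsonlite::read_json(sidecar)
    out <- lapply(out, function(f) f * (rng$max - rng$min) + rng$min)
  }
  out
}

#' @rdname tiff_io
#' @param masks List of integer-labeled matrices (labels < 65536).
#' @export
write_masks <- function(masks, path) {
  scaled <- lapply(masks, function(m) {
    if (max(m) > 65535L) stop("labels exceed 16-bit range", call. = FALSE)
    m / 65535
  })
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' @rdname tiff_io
#' @export
read_masks <- function(path) {
  out <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(out)) out <- list(out)
  lapply(out, function(m) {
    storage.mode(m) <- "double"
    matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
  })
}

#' Read and write track tables as CSV
#'
#' The single interchange schema for predicted and ground-truth tracks:
#' `track_id, frame, cell_label, x, y, step_score, accumulated_score,
#' status`. Ground-truth tables may omit the score and status columns,
#' which are then written empty.
#'
#' @param tracks Tibble of tracks.
#' @param path CSV file path.
#' @name tracks_io
#' @return `write_tracks` returns `path` invisibly; `read_tracks` a tibble.
NULL

#' @rdname tracks_io
#' @export
write_tracks <- function(tracks, path) {
  cols <- c("track_id", "frame", "cell_label", "x", "y",
            "step_score", "accumulated_score", "status")
  if (!"cell_label" %in% names(tracks) && "label" %in% names(tracks)) {
    tracks <- dplyr::rename(tracks, cell_label = "label")
  }
  for (cn in setdiff(cols, names(tracks))) {
    tracks[[cn]] <- if (cn == "status") NA_character_ else NA_real_
  }
  readr::write_csv(tracks[, cols], path, na = "")
  invisible(path)
}

#' @rdname tracks_io
#' @export
read_tracks <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    track_id = readr::col_integer(),
    frame = readr::col_integer(),
    cell_label = readr::col_integer(),
    x = readr::col_double(),
    y = readr::col_double(),
    step_score = readr::col_double(),
    accumulated_score = readr::col_double(),
    status = readr::col_character()
  ))
}

#' Read and write score-matrix chains
#'
#' Each adjacent-frame matrix is one CSV (row/column headers are cell
#' labels) plus a manifest CSV listing the frame pairs and file names.
#'
#' @param matrices List of score matrices with label dimnames.
#' @param dir Output directory (created if missing).
#' @name score_io
#' @return `write_score_matrices` returns the manifest path invisibly;
#'   `read_score_matrices` the list of matrices.
NULL

#' @rdname score_io
#' @export
write_score_matrices <- function(matrices, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("scores_%04d.csv", seq_along(matrices) - 1L)
  for (i in seq_along(matrices)) {
    m <- matrices[[i]]
    df <- as.data.frame(m)
    df <- cbind(label = rownames(m), df)
    readr::write_csv(tibble::as_tibble(df), file.path(dir, files[i]))
  }
  manifest <- tibble::tibble(frame_t = seq_along(matrices) - 1L,
                             frame_t1 = seq_along(matrices),
                             file = files)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(file.path(dir, "manifest.csv"))
}

#' @rdname score_io
#' @export
read_score_matrices <- function(dir) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              col_types = "iic")
  lapply(manifest$file, function(f) {
    df <- readr::read_csv(file.path(dir, f), col_types = readr::cols(
      label = readr::col_character(), .default = readr::col_double()
    ))
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$label
    m
  })
}

#' Read and write run configurations as YAML
#'
#' @param config A named list (e.g. a [sim_config()] or [run_config()]).
#' @param path YAML file path.
#' @name config_io
#' @return `write_config` returns `path` invisibly; `read_config` the list.
NULL

#' @rdname config_io
#' @export
write_config <- function(config, path) {
  cls <- class(config)[1]
  obj <- unclass(config)
  if (!is.null(obj$scripted_events)) {
    obj$scripted_events <- lapply(obj$scripted_events, unclass)
  }
  if (!is.null(obj$sim)) {
    obj$sim <- unclass(obj$sim)
    obj$sim$scripted_events <- lapply(obj$sim$scripted_events, unclass)
  }
  yaml::write_yaml(c(list(.class = cls), obj), path)
  invisible(path)
}

#' @rdname config_io
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  cls <- obj$.class
  obj$.class <- NULL
  if (identical(cls, "sim_config")) {
    obj$scripted_events <- lapply(obj$scripted_events, function(e) {
      sim_event(e$kind, e$frame, e$track_ids)
    })
    return(do.call(sim_config, obj))
  }
  if (identical(cls, "run_config")) return(do.call(run_config, obj))
  obj
}
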