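#' Simulate a synthetic neutrophil time-lapse sequence
#'
#' Generates an intensity image sequence together with ground-truth labeled
#' masks, ground-truth trajectories and an event log. Cells are rendered as
#' Gaussian-profile discs moving under a persistent random walk; they can
#' appear at and disappear through the image border (probabilistically or by
#' scripted event), and scripted merge/split events make two or more cells
#' share a single connected detection for a frame interval.
#'
#' @param config A [sim_config()] object.
#'
#' @return An object of class `sim_output`: a list with
#'   \describe{
#'     \item{frames}{list of `n_frames` intensity matrices,}
#'     \item{masks}{list of integer-labeled segmentation matrices (0 =
#'       background), one connected component per positive label,}
#'     \item{tracks}{tibble of ground-truth trajectories with columns
#'       `track_id`, `frame`, `x`, `y`, `label` (the mask label covering the
#'       cell at that frame),}
#'     \item{events}{tibble of all events (scripted and spontaneous),}
#'     \item{config}{the input configuration.}
#'   }
#' @examples
#' out <- simulate_sequence(sim_config(image_size = c(96, 96), n_frames = 5,
#'                                     n_cells_initial = 3, seed = 7))
#' out$tracks
#' @export
simulate_sequence <- function(config) {
  config <- validate_sim_config(config)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  h <- config$image_size[1]
  w <- config$image_size[2]
  rmin <- config$cell_radius_range[1]
  rmax <- config$cell_radius_range[2]
  n0 <- config$n_cells_initial
  minsep <- config$min_separation

  # --- initial placement (rejection sampling with spacing) ---------------
  margin <- rmax + 1
  cells <- list()  # per track: list(x, y, radius, vx, vy, alive, group)
  place_sep <- max(minsep, 2 * rmax + 1)
  pos <- matrix(NA_real_, 0, 2)
  tries <- 0L
  while (nrow(pos) < n0 && tries < 20000L) {
    cand <- c(runif(1, margin, w - 1 - margin), runif(1, margin, h - 1 - margin))
    ok <- nrow(pos) == 0L ||
      all(sqrt((pos[, 1] - cand[1])^2 + (pos[, 2] - cand[2])^2) >=
            (if (minsep > 0) place_sep else 2 * rmin))
    if (ok) pos <- rbind(pos, cand)
    tries <- tries + 1L
  }
  if (nrow(pos) < n0) stop("could not place initial cells without overlap", call. = FALSE)

  next_id <- 0L
  new_cell <- function(x, y) {
    next_id <<- next_id + 1L
    th <- runif(1, 0, 2 * pi)
    list(id = next_id, x = x, y = y,
         radius = runif(1, rmin, rmax),
         vx = cos(th), vy = sin(th), alive = TRUE, group = NA_integer_)
  }
  for (i in seq_len(n0)) cells[[length(cells) + 1L]] <- new_cell(pos[i, 1], pos[i, 2])

  events <- list()
  log_event <- function(kind, frame, ids) {
    events[[length(events) + 1L]] <<- list(kind = kind, frame = frame,
                                           track_ids = paste(ids, collapse = ";"))
  }
  scripted <- config$scripted_events
  groups <- list()  # group id -> member track ids
  next_group <- 0L

  border_entry <- function() {
    side <- sample.int(4L, 1L)
    along <- runif(1, margin, if (side <= 2L) w - 1 - margin else h - 1 - margin)
    switch(side,
           c(along, margin),            # top
           c(along, h - 1 - margin),    # bottom
           c(margin, along),            # left
           c(w - 1 - margin, along))    # right
  }

  track_rows <- list()
  frames <- vector("list", config$n_frames)
  masks <- vector("list", config$n_frames)

  idx_of <- function(id) which(vapply(cells, `[[`, integer(1), "id") == id)

  for (t in seq_len(config$n_frames) - 1L) {
    # --- scripted events due at this frame -------------------------------
    for (e in scripted) {
      if (e$frame != t) next
      if (e$kind == "appear") {
        p <- border_entry()
        cl <- new_cell(p[1], p[2])
        cells[[length(cells) + 1L]] <- cl
        log_event("appear", t, cl$id)
      } else if (e$kind == "disappear") {
        for (id in e$track_ids) {
          i <- idx_of(id)
          if (length(i)) cells[[i]]$alive <- FALSE
        }
        log_event("disappear", t, e$track_ids)
      } else if (e$kind == "merge") {
        next_group <- next_group + 1L
        groups[[next_group]] <- e$track_ids
        members <- vapply(e$track_ids, idx_of, integer(1))
        cx <- mean(vapply(cells[members], `[[`, numeric(1), "x"))
        cy <- mean(vapply(cells[members], `[[`, numeric(1), "y"))
        for (i in members) {
          cells[[i]]$x <- cx; cells[[i]]$y <- cy
          cells[[i]]$group <- next_group
        }
        log_event("merge", t, e$track_ids)
      } else if (e$kind == "split") {
        id <- e$track_ids[1]
        i <- idx_of(id)
        if (length(i) && !is.na(cells[[i]]$group)) {
          g <- cells[[i]]$group
          groups[[g]] <- setdiff(groups[[g]], id)
          # leave the group along the member's own heading; clear the mask
          # contour (1.196 x nominal radius) so the regions separate
          d <- 2 * rmax * mask_radius_factor + 2
          nv <- sqrt(cells[[i]]$vx^2 + cells[[i]]$vy^2)
          cells[[i]]$x <- cells[[i]]$x + d * cells[[i]]$vx / max(nv, 1e-9)
          cells[[i]]$y <- cells[[i]]$y + d * cells[[i]]$vy / max(nv, 1e-9)
          cells[[i]]$group <- NA_integer_
          if (length(groups[[g]]) == 1L) {
            j <- idx_of(groups[[g]][1])
            cells[[j]]$group <- NA_integer_
            groups[[g]] <- integer(0)
          }
          log_event("split", t, id)
        }
      }
    }
    # --- spontaneous appear/disappear ------------------------------------
    if (t > 0L) {
      if (runif(1) < config$p_appear) {
        p <- border_entry()
        cl <- new_cell(p[1], p[2])
        cells[[length(cells) + 1L]] <- cl
        log_event("appear", t, cl$id)
      }
      for (i in seq_along(cells)) {
        if (cells[[i]]$alive && is.na(cells[[i]]$group) &&
            runif(1) < config$p_disappear) {
          cells[[i]]$alive <- FALSE
          log_event("disappear", t, cells[[i]]$id)
        }
      }
    }

    alive <- which(vapply(cells, `[[`, logical(1), "alive"))

    # --- record + render --------------------------------------------------
    df <- tibble::tibble(
      track_id = vapply(cells[alive], `[[`, integer(1), "id"),
      x = vapply(cells[alive], `[[`, numeric(1), "x"),
      y = vapply(cells[alive], `[[`, numeric(1), "y"),
      radius = vapply(cells[alive], `[[`, numeric(1), "radius")
    )
    bw <- render_cell_mask(df, c(h, w))
    lab <- label_components(bw)
    img <- config$background_level +
      render_cells(df, c(h, w), peak = config$peak_intensity)
    if (config$noise_sigma > 0) {
      img <- img + matrix(rnorm(h * w, 0, config$noise_sigma), h, w)
    }
    img[img < 0] <- 0
    frames[[t + 1L]] <- img
    masks[[t + 1L]] <- lab
    if (nrow(df)) {
      df$label <- lab[cbind(pmin(pmax(round(df$y) + 1L, 1L), h),
                            pmin(pmax(round(df$x) + 1L, 1L), w))]
      df$frame <- t
      track_rows[[length(track_rows) + 1L]] <-
        df[, c("track_id", "frame", "x", "y", "label")]
    }

    # --- move ------------------------------------------------------------
    if (t < config$n_frames - 1L) {
      move_one <- function(i) {
        th <- runif(1, 0, 2 * pi)
        vx <- config$persistence * cells[[i]]$vx + (1 - config$persistence) * cos(th)
        vy <- config$persistence * cells[[i]]$vy + (1 - config$persistence) * sin(th)
        nv <- sqrt(vx^2 + vy^2)
        if (nv < 1e-9) { vx <- cos(th); vy <- sin(th); nv <- 1 }
        c(vx / nv, vy / nv)
      }
      for (i in seq_along(cells)) {
        if (!cells[[i]]$alive) next
        g <- cells[[i]]$group
        if (!is.na(g) && length(groups[[g]]) && groups[[g]][1] != cells[[i]]$id) {
          next  # followers adopt the group leader's motion below
        }
        accept <- FALSE
        for (try in 1:30) {
          v <- move_one(i)
          nx <- cells[[i]]$x + config$speed_mean * v[1]
          ny <- cells[[i]]$y + config$speed_mean * v[2]
          # reflect at borders
          if (nx < margin) { nx <- 2 * margin - nx; v[1] <- -v[1] }
          if (nx > w - 1 - margin) { nx <- 2 * (w - 1 - margin) - nx; v[1] <- -v[1] }
          if (ny < margin) { ny <- 2 * margin - ny; v[2] <- -v[2] }
          if (ny > h - 1 - margin) { ny <- 2 * (h - 1 - margin) - ny; v[2] <- -v[2] }
          ok <- TRUE
          if (minsep > 0) {
            for (j in seq_along(cells)) {
              if (j == i || !cells[[j]]$alive) next
              if (!is.na(g) && identical(cells[[j]]$group, g)) next
              if (sqrt((cells[[j]]$x - nx)^2 + (cells[[j]]$y - ny)^2) < minsep) {
                ok <- FALSE; break
              }
            }
          }
          if (ok) {
            cells[[i]]$x <- nx; cells[[i]]$y <- ny
            cells[[i]]$vx <- v[1]; cells[[i]]$vy <- v[2]
            accept <- TRUE
            break
          }
        }
        if (!accept) { cells[[i]]$vx <- -cells[[i]]$vx; cells[[i]]$vy <- -cells[[i]]$vy }
        if (!is.na(g)) {
          for (id in groups[[g]]) {
            j <- idx_of(id)
            cells[[j]]$x <- cells[[i]]$x; cells[[j]]$y <- cells[[i]]$y
            cells[[j]]$vx <- cells[[i]]$vx; cells[[j]]$vy <- cells[[i]]$vy
          }
        }
      }
    }
  }

  tracks <- dplyr::arrange(dplyr::bind_rows(track_rows), .data$track_id, .data$frame)
  ev <- if (length(events)) {
    dplyr::bind_rows(lapply(events, tibble::as_tibble))
  } else {
    tibble::tibble(kind = character(), frame = integer(), track_ids = character())
  }
  structure(list(frames = frames, masks = masks, tracks = tracks,
                 events = ev, config = config, score_matrices = NULL),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat("<sim_output> ", length(x$frames), " frames ",
      nrow(x$frames[[1]]), "x", ncol(x$frames[[1]]), ", ",
      dplyr::n_distinct(x$tracks$track_id), " ground-truth tracks, ",
      nrow(x$events), " events\n", sep = "")
  invisible(x)
}
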