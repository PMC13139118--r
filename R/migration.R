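#' Cell-migration statistics per track
#'
#' Computes, for every track with at least two positions: net displacement
#' (Euclidean distance between first and last positions), total distance
#' traveled (sum of step lengths), meandering index (net / total; 1 for a
#' perfectly straight path, 0 when the cell returns to its start), mean
#' speed (total distance / travel time, with travel time = number of steps
#' x frame interval), mean step displacement (total / number of steps), and
#' the distant-cell flag.
#'
#' Distant cells — cells migrating far rather than residing locally — are
#' classified by their average per-frame displacement. Two readings of the
#' average are offered: `"mean_step"` (mean step path length, the default)
#' and `"net_per_frame"` (net displacement divided by the number of steps).
#'
#' @param tracks Tibble with columns `track_id`, `frame`, `x`, `y`
#'   (positions in pixels).
#' @param pixel_size Pixel size in micrometres/pixel (default 0.9).
#' @param frame_interval Frame interval in minutes (default 1).
#' @param distant_threshold Threshold on the average per-frame displacement
#'   in micrometres (default 2.4).
#' @param distant_rule `"mean_step"` or `"net_per_frame"`.
#'
#' @return Tibble with one row per track: `track_id`, `n_frames`,
#'   `net_displacement`, `total_distance` (micrometres), `meandering_index`,
#'   `mean_speed` (micrometres/minute), `avg_step_displacement`
#'   (micrometres/frame), `is_distant`. Single-point tracks are dropped
#'   with a warning.
#' @examples
#' tr <- tibble::tibble(track_id = 1, frame = 0:2,
#'                      x = c(0, 3, 3), y = c(0, 0, 4))
#' migration_stats(tr, pixel_size = 1)  # 3-4-5 path: MI = 5/7
#' @export
migration_stats <- function(tracks, pixel_size = 0.9, frame_interval = 1,
                            distant_threshold = 2.4,
                            distant_rule = c("mean_step", "net_per_frame")) {
  distant_rule <- match.arg(distant_rule)
  stopifnot(pixel_size > 0, frame_interval > 0)
  lens <- tracks |> dplyr::count(.data$track_id)
  if (any(lens$n < 2L)) {
    warning("dropping ", sum(lens$n < 2L), " single-point track(s)")
    tracks <- tracks |>
      dplyr::filter(.data$track_id %in% lens$track_id[lens$n >= 2L])
  }
  if (nrow(tracks) == 0L) stop("no track has >= 2 positions", call. = FALSE)
  tracks |>
    dplyr::arrange(.data$track_id, .data$frame) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      n_frames = dplyr::n(),
      net_displacement = sqrt((dplyr::last(.data$x) - dplyr::first(.data$x))^2 +
                                (dplyr::last(.data$y) - dplyr::first(.data$y))^2) *
        pixel_size,
      total_distance = sum(sqrt(diff(.data$x)^2 + diff(.data$y)^2)) * pixel_size,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      meandering_index = dplyr::if_else(.data$total_distance > 0,
                                        .data$net_displacement / .data$total_distance,
                                        0),
      mean_speed = .data$total_distance / ((.data$n_frames - 1L) * frame_interval),
      avg_step_displacement = .data$total_distance / (.data$n_frames - 1L),
      is_distant = (if (distant_rule == "mean_step") {
        .data$avg_step_displacement
      } else {
        .data$net_displacement / (.data$n_frames - 1L)
      }) > distant_threshold
    )
}

#' Two-group comparison of migration properties
#'
#' Independent-samples t-test per migration property, reporting group means
#' with standard deviations. Properties with zero variance in both groups
#' are reported with `p = NA`.
#'
#' @param stats_a,stats_b Outputs of [migration_stats()] for the two
#'   groups (>= 2 tracks each).
#' @param properties Property columns to compare.
#' @param var_equal Use the pooled-variance (classical independent-samples)
#'   t-test (default `TRUE`); `FALSE` gives Welch's test.
#'
#' @return Tibble with one row per property: group means and SDs, `t`,
#'   `df`, `p_value`.
#' @export
group_compare <- function(stats_a, stats_b,
                          properties = c("net_displacement",
                                         "meandering_index", "mean_speed"),
                          var_equal = TRUE) {
  if (nrow(stats_a) < 2L || nrow(stats_b) < 2L) {
    stop("need >= 2 tracks per group", call. = FALSE)
  }
  rows <- lapply(properties, function(p) {
    a <- stats_a[[p]]
    b <- stats_b[[p]]
    base <- tibble::tibble(property = p,
                           mean_a = mean(a), sd_a = sd(a),
                           mean_b = mean(b), sd_b = sd(b))
    if (sd(a) == 0 && sd(b) == 0) {
      if (mean(a) == mean(b)) {
        return(dplyr::mutate(base, t = 0, df = length(a) + length(b) - 2,
                             p_value = 1))
      }
      return(dplyr::mutate(base, t = NA_real_, df = NA_real_,
                           p_value = NA_real_))
    }
    tt <- t.test(a, b, var.equal = var_equal)
    dplyr::mutate(base, t = unname(tt$statistic),
                  df = unname(tt$parameter), p_value = tt$p.value)
  })
  dplyr::bind_rows(rows)
}
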