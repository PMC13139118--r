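#' Attach spatial positions to a tracking result
#'
#' Maps each trajectory node (frame, cell label) to the centroid of that
#' detection in the corresponding labeled mask, producing the position table
#' used by the tracking-quality and migration metrics.
#'
#' @param result A `tracking_result`.
#' @param masks List of labeled masks, one per frame (0-based frame index
#'   `f` is `masks[[f + 1]]`).
#'
#' @return The node tibble of the result with `x` and `y` columns added.
#' @export
attach_positions <- function(result, masks) {
  cents <- dplyr::bind_rows(lapply(seq_along(masks), function(i) {
    extract_detections(masks[[i]], frame_index = i - 1L)
  }))
  tidy(result) |>
    dplyr::left_join(cents |> dplyr::select("frame", "label", "x", "y"),
                     by = c(frame = "frame", cell_label = "label"))
}

#' Frame-level identification of ground-truth objects by predicted tracks
#'
#' A predicted node identifies a ground-truth object when the node position
#' lies within `radius` of the object's position at that frame and is the
#' nearest such object. Each predicted track is then matched to the
#' ground-truth object it identifies in the majority of its frames (ties
#' toward the smaller ground-truth id; tracks identifying nothing stay
#' unmatched).
#'
#' @param pred Tibble with columns `track_id`, `frame`, `x`, `y` (e.g. from
#'   [attach_positions()] or a ground-truth-formatted table).
#' @param gt Tibble of ground-truth tracks with columns `track_id`, `frame`,
#'   `x`, `y`.
#' @param radius Identification radius in pixels (default 10).
#'
#' @return A list with `events` (tibble `frame`, `track_id`, `gt_id`,
#'   `dist`: one row per identifying node) and `matching` (tibble
#'   `track_id`, `matched_gt`, `n_support`).
#' @export
match_identities <- function(pred, gt, radius = 10) {
  joined <- pred |>
    dplyr::select("track_id", "frame", "x", "y") |>
    dplyr::inner_join(gt |>
                        dplyr::select(gt_id = "track_id", "frame",
                                      gx = "x", gy = "y"),
                      by = "frame", relationship = "many-to-many") |>
    dplyr::mutate(dist = sqrt((.data$x - .data$gx)^2 +
                                (.data$y - .data$gy)^2)) |>
    dplyr::filter(.data$dist <= radius)
  events <- joined |>
    dplyr::group_by(.data$track_id, .data$frame) |>
    dplyr::slice_min(.data$dist, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("frame", "track_id", "gt_id", "dist")
  matching <- events |>
    dplyr::count(.data$track_id, .data$gt_id, name = "n_support") |>
    dplyr::group_by(.data$track_id) |>
    dplyr::arrange(dplyr::desc(.data$n_support), .data$gt_id,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::rename(matched_gt = "gt_id")
  list(events = events, matching = matching)
}

#' Tracking-quality metrics
#'
#' Computes the four identification metrics plus the average track length:
#' \describe{
#'   \item{track purity (`tp`)}{per predicted track, the fraction of its
#'     frames in which it identifies its matched ground-truth object,
#'     averaged over tracks;}
#'   \item{object purity (`op`)}{per ground-truth object, the fraction of
#'     its frames in which it is identified by a track matched to it,
#'     averaged over objects;}
#'   \item{falsely identified tracker (`fit`)}{number of (frame, object)
#'     identifications made by a track whose matched object differs,
#'     normalized per frame per cell;}
#'   \item{falsely identified object (`fio`)}{number of (frame, track)
#'     events in which a track follows an object other than its matched
#'     one, normalized per frame per cell.}
#' }
#' The per-frame-per-cell normalization divides raw error counts by
#' `n_frames * mean cells per frame` (cells counted from the ground truth);
#' purities are already ratios and are not normalized further.
#'
#' @inheritParams match_identities
#' @param assignment Optional result of [match_identities()]; computed if
#'   missing.
#'
#' @return A one-row tibble `fit`, `fio`, `tp`, `op`, `avg_track_length`,
#'   `n_tracks`, with the per-track breakdown in attribute `"per_track"`.
#' @export
compute_metrics <- function(pred, gt, radius = 10, assignment = NULL) {
  if (is.null(assignment)) assignment <- match_identities(pred, gt, radius)
  events <- assignment$events
  matching <- assignment$matching
  track_lengths <- pred |> dplyr::count(.data$track_id, name = "length")
  n_tracks <- nrow(track_lengths)
  if (n_tracks == 0L) {
    warning("empty prediction set: purities undefined, reported as 0")
    return(tibble::tibble(fit = 0, fio = 0, tp = 0, op = 0,
                          avg_track_length = NA_real_, n_tracks = 0L))
  }
  ev <- events |> dplyr::left_join(matching, by = "track_id")
  correct <- ev |> dplyr::filter(.data$gt_id == .data$matched_gt)
  wrong <- ev |> dplyr::filter(.data$gt_id != .data$matched_gt)

  per_track <- track_lengths |>
    dplyr::left_join(matching, by = "track_id") |>
    dplyr::left_join(correct |> dplyr::count(.data$track_id, name = "n_correct"),
                     by = "track_id") |>
    dplyr::mutate(n_correct = dplyr::coalesce(.data$n_correct, 0L),
                  purity = .data$n_correct / .data$length)
  tp <- mean(per_track$purity)

  gt_lengths <- gt |> dplyr::count(.data$track_id, name = "length")
  per_object <- gt_lengths |>
    dplyr::left_join(correct |> dplyr::distinct(.data$frame, .data$gt_id) |>
                       dplyr::count(.data$gt_id, name = "n_correct"),
                     by = c(track_id = "gt_id")) |>
    dplyr::mutate(n_correct = dplyr::coalesce(.data$n_correct, 0L),
                  purity = .data$n_correct / .data$length)
  op <- mean(per_object$purity)

  n_frames <- dplyr::n_distinct(gt$frame)
  mean_cells <- nrow(gt) / n_frames
  norm <- n_frames * mean_cells
  fit <- nrow(wrong |> dplyr::distinct(.data$frame, .data$gt_id)) / norm
  fio <- nrow(wrong |> dplyr::distinct(.data$frame, .data$track_id)) / norm

  out <- tibble::tibble(fit = fit, fio = fio, tp = tp, op = op,
                        avg_track_length = mean(track_lengths$length),
                        n_tracks = n_tracks)
  attr(out, "per_track") <- per_track
  out
}

#' Nonparametric comparison of linkage methods
#'
#' For each metric, runs the Kruskal-Wallis omnibus test across methods;
#' when the omnibus p-value is below `alpha`, Dunn's post-hoc z-tests are
#' computed for all method pairs with Benjamini-Hochberg adjustment. Ties
#' are handled by rank averaging (with the tie correction in Dunn's
#' standard error); identical samples across all groups yield p = 1 and no
#' post-hoc.
#'
#' @param data Tibble with a `method` column and one numeric column per
#'   metric (one row per sequence/sample).
#' @param metrics Character vector of metric column names; default all
#'   numeric columns.
#' @param alpha Omnibus significance level gating the post-hoc (default
#'   0.05).
#'
#' @return A list with `omnibus` (tibble `metric`, `statistic`, `df`,
#'   `p_value`) and `posthoc` (tibble `metric`, `method_a`, `method_b`,
#'   `z`, `p_value`, `p_adjusted`).
#' @export
compare_methods <- function(data, metrics = NULL, alpha = 0.05) {
  stopifnot("method" %in% names(data))
  if (is.null(metrics)) {
    metrics <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                       "method")
  }
  methods <- unique(data$method)
  if (length(methods) < 2L) stop("need >= 2 methods", call. = FALSE)
  omnibus <- list()
  posthoc <- list()
  for (met in metrics) {
    x <- data[[met]]
    g <- factor(data$method, levels = methods)
    if (length(unique(x)) == 1L) {
      omnibus[[met]] <- tibble::tibble(metric = met, statistic = 0,
                                       df = length(methods) - 1L, p_value = 1)
      next
    }
    kw <- kruskal.test(x, g)
    omnibus[[met]] <- tibble::tibble(metric = met,
                                     statistic = unname(kw$statistic),
                                     df = unname(kw$parameter),
                                     p_value = kw$p.value)
    if (is.na(kw$p.value) || kw$p.value >= alpha) next
    posthoc[[met]] <- dunn_test(x, g) |>
      dplyr::mutate(metric = met, .before = 1)
  }
  list(
    omnibus = dplyr::bind_rows(omnibus),
    posthoc = if (length(posthoc)) dplyr::bind_rows(posthoc) else
      tibble::tibble(metric = character(), method_a = character(),
                     method_b = character(), z = numeric(),
                     p_value = numeric(), p_adjusted = numeric())
  )
}

# Dunn's post-hoc z-tests on pooled ranks with tie correction and BH
# adjustment; two-sided p-values.
dunn_test <- function(x, g) {
  r <- rank(x)
  n <- length(x)
  tie_tab <- table(x)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (n - 1))
  lv <- levels(droplevels(g))
  mean_rank <- tapply(r, g, mean)[lv]
  n_g <- tapply(r, g, length)[lv]
  pairs <- utils::combn(lv, 2)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]
    b <- pairs[2, k]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / n_g[[a]] + 1 / n_g[[b]]))
    z <- (mean_rank[[a]] - mean_rank[[b]]) / se
    tibble::tibble(method_a = a, method_b = b, z = z,
                   p_value = 2 * pnorm(-abs(z)))
  })
  out <- dplyr::bind_rows(res)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out
}

#' Corrupt a perfect prediction by swapping track positions
#'
#' Test utility: swaps the positions of track pairs in a nested, growing
#' set of frames, so that higher corruption levels strictly contain lower
#' ones. Used to verify that the purity metrics degrade monotonically.
#'
#' @param tracks Ground-truth-formatted tibble (`track_id`, `frame`, `x`,
#'   `y`).
#' @param fraction Fraction of frames to corrupt, in `[0, 1]`.
#'
#' @return Corrupted copy of `tracks`.
#' @export
corrupt_tracks <- function(tracks, fraction) {
  stopifnot(fraction >= 0, fraction <= 1)
  ids <- sort(unique(tracks$track_id))
  if (length(ids) < 2L) return(tracks)
  frames <- sort(unique(tracks$frame))
  n_bad <- floor(fraction * length(frames))
  bad <- frames[seq_len(n_bad)]
  a <- ids[1]
  b <- ids[2]
  out <- tracks
  ia <- which(out$track_id == a & out$frame %in% bad)
  ib <- which(out$track_id == b & out$frame %in% bad)
  fa <- out$frame[ia]
  fb <- out$frame[ib]
  common <- intersect(fa, fb)
  ia <- ia[match(common, fa)]
  ib <- ib[match(common, fb)]
  tmp <- out[ia, c("x", "y")]
  out[ia, c("x", "y")] <- out[ib, c("x", "y")]
  out[ib, c("x", "y")] <- tmp
  out
}
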