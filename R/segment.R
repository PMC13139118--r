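#' Deterministic reference segmentation
#'
#' A classical intensity-threshold segmenter: the frame is min-max
#' normalized to `[0, 1]`, pixels above the threshold `t` become foreground,
#' 8-connected components are labeled, and components smaller than
#' `min_area` pixels are discarded (labels stay contiguous). An all-
#' background result is valid and returns an empty mask.
#'
#' @param frame 2D numeric matrix.
#' @param t Foreground threshold on the normalized intensity, in `[0, 1]`.
#'   The default 0.1 balances missed dim cells against fused bright ones.
#' @param min_area Minimum component area in pixels (default 5) to suppress
#'   noise specks.
#'
#' @return Integer-labeled mask matrix (0 = background).
#' @examples
#' img <- matrix(0, 32, 32); img[10:14, 10:14] <- 1
#' max(segment_reference(img))
#' @export
segment_reference <- function(frame, t = 0.1, min_area = 5L) {
  stopifnot(t >= 0, t <= 1)
  rng <- range(frame)
  norm <- if (rng[2] > rng[1]) (frame - rng[1]) / (rng[2] - rng[1]) else frame * 0
  lab <- label_components(norm > t)
  if (max(lab) > 0L && min_area > 1L) {
    areas <- tabulate(lab, nbins = max(lab))
    keep <- which(areas >= min_area)
    map <- integer(max(lab))
    map[keep] <- seq_along(keep)
    lab[lab > 0L] <- map[lab[lab > 0L]]
  }
  lab
}

#' Extract per-cell detections from a labeled mask
#'
#' @param mask Integer-labeled mask matrix (0 = background).
#' @param frame_index Optional 0-based frame index recorded with each
#'   detection.
#'
#' @return A tibble with one row per positive label: `frame`, `label`,
#'   `x`, `y` (centroid, 0-based pixel coordinates), `area`.
#' @export
extract_detections <- function(mask, frame_index = 0L) {
  idx <- which(mask > 0L)
  if (length(idx) == 0L) {
    return(tibble::tibble(frame = integer(), label = integer(),
                          x = numeric(), y = numeric(), area = integer()))
  }
  nr <- nrow(mask)
  lab <- mask[idx]
  row <- ((idx - 1L) %% nr)        # 0-based y
  col <- ((idx - 1L) %/% nr)       # 0-based x
  tibble::tibble(label = lab, x = col, y = row) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(x = mean(.data$x), y = mean(.data$y),
                     area = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(frame = as.integer(frame_index), .before = 1) |>
    dplyr::arrange(.data$label)
}

# Pixel sets of every label as a named list of linear indices.
label_pixel_sets <- function(mask) {
  idx <- which(mask > 0L)
  split(idx, mask[idx])
}

#' Evaluate a predicted segmentation against ground truth
#'
#' Computes the semantic Jaccard index on the binary foregrounds, the
#' object-level F1 with its true-positive/false-positive/false-negative
#' counts, and under-/over-segmentation counts. Object matching uses the
#' mutual-maximal-overlap rule: a (truth, prediction) pair counts as a true
#' positive when each is the other's largest overlap partner. A predicted
#' object overlapping two or more truth objects is an under-segmentation
#' (cell merge); a truth object overlapped by two or more predictions is an
#' over-segmentation (cell split).
#'
#' @param pred,truth Integer-labeled masks of the same shape.
#'
#' @return A one-row tibble: `iou`, `f1`, `true_pos`, `fp`, `fn`,
#'   `n_under`, `n_over`.
#' @export
evaluate_segmentation <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("mask shape mismatch", call. = FALSE)
  pb <- pred > 0L
  tb <- truth > 0L
  inter <- sum(pb & tb)
  uni <- sum(pb | tb)
  iou <- if (uni > 0) inter / uni else 1

  both <- which(pb & tb)
  ov <- if (length(both)) {
    as.data.frame(table(truth = truth[both], pred = pred[both]),
                  stringsAsFactors = FALSE)
  } else {
    data.frame(truth = character(), pred = character(), Freq = integer())
  }
  ov <- ov[ov$Freq > 0, , drop = FALSE]
  n_truth <- length(unique(truth[tb]))
  n_pred <- length(unique(pred[pb]))

  tp <- 0L
  if (nrow(ov)) {
    best_for_truth <- tapply(seq_len(nrow(ov)), ov$truth, function(i) {
      i[which.max(ov$Freq[i])]
    })
    best_for_pred <- tapply(seq_len(nrow(ov)), ov$pred, function(i) {
      i[which.max(ov$Freq[i])]
    })
    tp <- sum(unlist(best_for_truth) %in% unlist(best_for_pred))
  }
  fp <- n_pred - tp
  fn <- n_truth - tp
  n_under <- if (nrow(ov)) sum(table(ov$pred) >= 2L) else 0L
  n_over <- if (nrow(ov)) sum(table(ov$truth) >= 2L) else 0L
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 1

  tibble::tibble(iou = iou, f1 = f1, true_pos = as.integer(tp),
                 fp = as.integer(fp), fn = as.integer(fn),
                 n_under = as.integer(n_under), n_over = as.integer(n_over))
}

#' Per-object intersection-over-union table
#'
#' IoU for every overlapping (truth, prediction) object pair; exposed for
#' inspection, not used in the headline (semantic) IoU.
#'
#' @inheritParams evaluate_segmentation
#' @return Tibble with columns `truth`, `pred`, `intersection`, `union`,
#'   `iou`.
#' @export
object_iou <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("mask shape mismatch", call. = FALSE)
  both <- which(pred > 0L & truth > 0L)
  if (!length(both)) {
    return(tibble::tibble(truth = integer(), pred = integer(),
                          intersection = integer(), union = integer(),
                          iou = numeric()))
  }
  ov <- as.data.frame(table(truth = truth[both], pred = pred[both]),
                      stringsAsFactors = FALSE)
  ov <- ov[ov$Freq > 0, , drop = FALSE]
  ta <- tabulate(truth[truth > 0L], nbins = max(truth))
  pa <- tabulate(pred[pred > 0L], nbins = max(pred))
  ti <- as.integer(ov$truth)
  pj <- as.integer(ov$pred)
  uni <- ta[ti] + pa[pj] - ov$Freq
  tibble::tibble(truth = ti, pred = pj, intersection = as.integer(ov$Freq),
                 union = as.integer(uni), iou = ov$Freq / uni) |>
    dplyr::arrange(.data$truth, .data$pred)
}

#' Train/validation/test counts for an 8:2 split
#'
#' Splits `n` items with the test side rounded up, the convention under
#' which 240 images give a 192/48 train/test split and 192 give 153/39.
#'
#' @param n Number of items.
#' @param test_fraction Fraction assigned to the held-out side (default 0.2).
#'
#' @return Named integer vector `c(train = ..., test = ...)`.
#' @examples
#' split_train_test(240)
#' split_train_test(192)
#' @export
split_train_test <- function(n, test_fraction = 0.2) {
  stopifnot(n >= 0, test_fraction >= 0, test_fraction <= 1)
  n_test <- as.integer(ceiling(n * test_fraction))
  c(train = as.integer(n) - n_test, test = n_test)
}
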