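#' Proximity-based motion prediction for one detection
#'
#' Predicts where a cell may be in the next frame by dilating its current
#' pixel set with a Euclidean disc of radius `search_radius`. This is a
#' deterministic spatial-proximity prior; the linkage layer is agnostic to
#' the predictor, so externally supplied per-cell prediction masks (e.g.
#' from a learned motion model) can be substituted via
#' [prune_prediction()] and the same scoring path.
#'
#' @param label Positive cell label in `mask_t`.
#' @param mask_t Labeled mask of the source frame.
#' @param search_radius Dilation radius in pixels; should exceed the largest
#'   expected per-frame displacement.
#'
#' @return A list: `source_label`, `pixels` (linear indices of the predicted
#'   mask), `dim` (image dimensions).
#' @export
proxy_predict <- function(label, mask_t, search_radius = 10) {
  idx <- which(mask_t == label)
  if (length(idx) == 0L) stop("label not present in mask", call. = FALSE)
  list(source_label = as.integer(label),
       pixels = dilate_indices(idx, dim(mask_t), search_radius),
       dim = dim(mask_t))
}

#' Overlap score matrix between predicted cells and next-frame detections
#'
#' The raw score of a (prediction, detection) pair is the number of shared
#' pixels; normalization turns it into a `[0, 1]` linkage score. Rows are
#' cells of frame `t` (in ascending label order), columns cells of frame
#' `t + 1`.
#'
#' @param preds List of predictions from [proxy_predict()] (all for the same
#'   source frame).
#' @param mask_t1 Labeled mask of frame `t + 1`.
#' @param normalize Normalization of the raw overlap: `"pred"` divides by
#'   the predicted-mask area (default), `"target"` by the detection area,
#'   `"union"` by the union area (IoU).
#'
#' @return Numeric matrix with `dimnames` giving source/target labels;
#'   entries in `[0, 1]`.
#' @export
overlap_score_matrix <- function(preds, mask_t1,
                                 normalize = c("pred", "target", "union")) {
  normalize <- match.arg(normalize)
  to_labels <- sort(unique(mask_t1[mask_t1 > 0L]))
  from_labels <- vapply(preds, `[[`, integer(1), "source_label")
  ord <- order(from_labels)
  preds <- preds[ord]
  from_labels <- from_labels[ord]
  m <- matrix(0, length(preds), length(to_labels),
              dimnames = list(as.character(from_labels),
                              as.character(to_labels)))
  if (length(to_labels) == 0L || length(preds) == 0L) return(m)
  areas_t1 <- tabulate(mask_t1[mask_t1 > 0L], nbins = max(to_labels))
  for (i in seq_along(preds)) {
    px <- preds[[i]]$pixels
    hit <- mask_t1[px]
    hit <- hit[hit > 0L]
    if (!length(hit)) next
    raw <- tabulate(hit, nbins = max(to_labels))[to_labels]
    denom <- switch(normalize,
                    pred = rep(max(1L, length(px)), length(to_labels)),
                    target = pmax(1L, areas_t1[to_labels]),
                    union = pmax(1L, length(px) + areas_t1[to_labels] - raw))
    m[i, ] <- raw / denom
  }
  m
}

#' Score matrices for a whole sequence
#'
#' Builds one overlap score matrix per adjacent frame pair; a sequence of
#' `n` frames yields exactly `n - 1` matrices in temporal order. Frames with
#' zero cells produce degenerate (0-row or 0-column) matrices, which the
#' linkers handle.
#'
#' @param masks List of labeled masks (>= 2 frames).
#' @param search_radius Passed to [proxy_predict()].
#' @param normalize Passed to [overlap_score_matrix()].
#' @param predictor Optional custom predictor
#'   `function(label, mask_t, frame_index)` returning the [proxy_predict()]
#'   structure; defaults to the dilation prior.
#'
#' @return List of score matrices of length `length(masks) - 1`.
#' @examples
#' fix <- scripted_scenario("clean_separated")
#' mats <- score_sequence(fix$masks, search_radius = 6)
#' length(mats)  # n_frames - 1
#' @export
score_sequence <- function(masks, search_radius = 10,
                           normalize = c("pred", "target", "union"),
                           predictor = NULL) {
  if (length(masks) < 2L) stop("need at least 2 frames", call. = FALSE)
  normalize <- match.arg(normalize)
  lapply(seq_len(length(masks) - 1L), function(t) {
    labs <- sort(unique(masks[[t]][masks[[t]] > 0L]))
    preds <- lapply(labs, function(l) {
      if (is.null(predictor)) {
        proxy_predict(l, masks[[t]], search_radius)
      } else {
        predictor(l, masks[[t]], t - 1L)
      }
    })
    overlap_score_matrix(preds, masks[[t + 1L]], normalize = normalize)
  })
}

#' Reduce a multi-blob prediction to its dominant component
#'
#' Adapter rule for externally supplied prediction masks: when a prediction
#' contains more than one connected component, keep only the component with
#' the highest mean intensity in the raw frame.
#'
#' @param pred_mask Binary matrix (a predicted cell location).
#' @param frame Raw intensity frame of the same shape.
#'
#' @return Binary matrix with at most one connected component.
#' @export
prune_prediction <- function(pred_mask, frame) {
  lab <- label_components(pred_mask > 0)
  n <- max(lab)
  if (n <= 1L) return(pred_mask > 0)
  means <- vapply(seq_len(n), function(k) mean(frame[lab == k]), numeric(1))
  lab == which.max(means)
}
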