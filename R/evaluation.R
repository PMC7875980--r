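# Detection evaluation: centroid-distance matching with separate lateral
# and axial tolerances, and precision/recall/F1.

#' Match 3D detections to ground truth by centroid distance
#'
#' A detection can pair with a ground-truth object when their centroids are
#' within `lateral_tol_um` in the XY plane (Euclidean) and within `z_tol_um`
#' along Z (the two tolerances are tested separately). Pairing is greedy
#' one-to-one by ascending lateral distance. Unmatched detections are false
#' positives; unmatched ground-truth objects are false negatives.
#'
#' Greedy pairing equals the optimal assignment whenever the tolerance
#' neighbourhoods of ground-truth objects are disjoint (objects further than
#' twice the lateral tolerance apart, or Z-separated).
#'
#' @param dets data frame with columns `x_um, y_um, z_um` (e.g. from
#'   [merge_boxes_3d()]).
#' @param gts data frame with columns `x_um, y_um, z_um`, same frame.
#' @param lateral_tol_um lateral tolerance (default 5).
#' @param z_tol_um axial tolerance (default 3).
#' @return A list with `pairs` (data frame `det, gt, lateral_um, dz_um`),
#'   `fp` (unmatched detection indices) and `fn` (unmatched ground-truth
#'   indices).
#' @export
match_detections <- function(dets, gts, lateral_tol_um = 5, z_tol_um = 3) {
  nd <- nrow(dets); ng <- nrow(gts)
  if (nd && ng) {
    lat <- outer(seq_len(nd), seq_len(ng), function(i, j)
      sqrt((dets$x_um[i] - gts$x_um[j])^2 + (dets$y_um[i] - gts$y_um[j])^2))
    dz <- outer(seq_len(nd), seq_len(ng), function(i, j)
      abs(dets$z_um[i] - gts$z_um[j]))
    ok <- which(lat <= lateral_tol_um & dz <= z_tol_um, arr.ind = TRUE)
  } else ok <- matrix(integer(), 0, 2)
  pairs <- data.frame(det = integer(), gt = integer(),
                      lateral_um = numeric(), dz_um = numeric())
  if (nrow(ok)) {
    cand <- data.frame(det = ok[, 1], gt = ok[, 2],
                       lateral_um = lat[ok], dz_um = dz[ok])
    cand <- cand[order(cand$lateral_um, cand$det, cand$gt), , drop = FALSE]
    used_d <- logical(nd); used_g <- logical(ng)
    for (i in seq_len(nrow(cand))) {
      di <- cand$det[i]; gi <- cand$gt[i]
      if (!used_d[di] && !used_g[gi]) {
        used_d[di] <- TRUE; used_g[gi] <- TRUE
        pairs <- rbind(pairs, cand[i, ])
      }
    }
  } else {
    used_d <- logical(nd); used_g <- logical(ng)
  }
  rownames(pairs) <- NULL
  list(pairs = pairs, fp = which(!used_d), fn = which(!used_g))
}

#' Precision, recall and F1 from match counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`, each defined as 0
#' when its denominator is 0. Values are reported as percentages.
#'
#' @param TP,FP,FN non-negative integer counts.
#' @return A `detection_metrics` list with fields `TP, FP, FN, precision,
#'   recall, f1` (percent).
#' @examples
#' precision_recall_f1(7, 3, 1)
#' @export
precision_recall_f1 <- function(TP, FP, FN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  P <- if (TP + FP > 0) 100 * TP / (TP + FP) else 0
  R <- if (TP + FN > 0) 100 * TP / (TP + FN) else 0
  structure(list(TP = as.integer(TP), FP = as.integer(FP),
                 FN = as.integer(FN), precision = P, recall = R,
                 f1 = f1_score(P, R)),
            class = "detection_metrics")
}

#' Harmonic-mean F1 score
#'
#' @param precision,recall percentages (or any common scale).
#' @return `2 * P * R / (P + R)`, or 0 when `P + R == 0`.
#' @examples
#' f1_score(70, 87.5)   # 77.78
#' f1_score(75, 70.59)  # 72.73
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d | precision %.2f%%  recall %.2f%%  F1 %.2f%%\n",
              x$TP, x$FP, x$FN, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Evaluate detections against ground truth
#'
#' Convenience composition of [match_detections()] and
#' [precision_recall_f1()].
#'
#' @inheritParams match_detections
#' @return A `detection_metrics` list.
#' @export
evaluate_detections <- function(dets, gts, lateral_tol_um = 5, z_tol_um = 3) {
  m <- match_detections(dets, gts, lateral_tol_um, z_tol_um)
  precision_recall_f1(nrow(m$pairs), length(m$fp), length(m$fn))
}

#' Inter-annotator agreement over a stack
#'
#' Treats annotation set A as ground truth and set B as detections: both
#' sets are Z-merged with [merge_boxes_3d()] and evaluated with the
#' standard centroid-distance matching. Swapping A and B swaps precision
#' and recall.
#'
#' @param boxes_a,boxes_b [scored_boxes] annotation sets over the same
#'   stack.
#' @param pixel_size_um,z_step_um shared stack calibration.
#' @param lateral_tol_um,z_tol_um matching tolerances.
#' @return A `detection_metrics` list.
#' @export
annotator_agreement <- function(boxes_a, boxes_b, pixel_size_um,
                                z_step_um = 1, lateral_tol_um = 5,
                                z_tol_um = 3) {
  a3 <- merge_boxes_3d(boxes_a, pixel_size_um, z_step_um)
  b3 <- merge_boxes_3d(boxes_b, pixel_size_um, z_step_um)
  evaluate_detections(b3, a3, lateral_tol_um, z_tol_um)
}
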