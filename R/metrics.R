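#' Region-level confusion counts
#'
#' @param tp,tn,fp,fn Nonnegative integer counts of true positives, true
#'   negatives, false positives and false negatives at the region level.
#' @return A list of class `"confusion_counts"`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v))) {
    stop("confusion counts must be nonnegative integers")
  }
  structure(as.list(v), class = "confusion_counts")
}

#' Sensitivity, specificity and precision from confusion counts
#'
#' Exact ratios `TP/(TP+FN)`, `TN/(TN+FP)` and `TP/(TP+FP)`. A rate whose
#' denominator is zero is *undefined* and reported as `NA` (never silently
#' coerced to 0, which would inflate e.g. specificity on an all-positive
#' cohort).
#'
#' @param c A [confusion_counts()].
#' @return Named numeric vector `(sensitivity, specificity, precision)`
#'   with `NA` marking undefined rates.
#' @export
rates <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  c(sensitivity = safe(c$tp, c$tp + c$fn),
    specificity = safe(c$tn, c$tn + c$fp),
    precision = safe(c$tp, c$tp + c$fp))
}

#' Average number of false positives per patient
#'
#' @param total_fp Total false-positive region count over the cohort.
#' @param n_patients Number of patients (must be >= 1).
#' @return `total_fp / n_patients`.
#' @export
fpavg <- function(total_fp, n_patients) {
  stopifnot(is.numeric(total_fp), total_fp >= 0)
  if (!is.numeric(n_patients) || n_patients < 1) {
    stop("n_patients must be at least 1")
  }
  total_fp / n_patients
}

#' Per-patient prediction record
#'
#' @param patient_id Unique patient identifier.
#' @param has_cmbs Ground-truth flag: does the patient have any CMB?
#' @param slice_index Integer vector, one entry per predicted-positive
#'   region, giving its 0-based slice index.
#' @param is_tp Logical vector parallel to `slice_index`: was the
#'   prediction a true CMB region?
#' @param S Number of slices per patient (default 130).
#' @return A list of class `"patient_predictions"`.
#' @export
patient_predictions <- function(patient_id, has_cmbs, slice_index = integer(),
                                is_tp = logical(), S = 130L) {
  stopifnot(length(slice_index) == length(is_tp), S >= 1L)
  if (length(slice_index) && (any(slice_index < 0) || any(slice_index >= S))) {
    stop("slice indices must lie in [0, S)")
  }
  structure(list(patient_id = as.character(patient_id),
                 has_cmbs = isTRUE(has_cmbs),
                 slice_index = as.integer(slice_index),
                 is_tp = as.logical(is_tp), S = as.integer(S)),
            class = "patient_predictions")
}

#' Patient-level accuracy
#'
#' A CMB-positive patient is judged correctly iff at least one predicted
#' region is a true CMB. For CMB-negative patients the two modes differ:
#' `"literal"` scores a negative patient correct iff the number of *true*
#' CMB predictions is zero -- which is vacuously true for any patient
#' without CMBs, so the literal rule can only add credit; `"strict"`
#' scores a negative patient correct only when there are zero positive
#' predictions of any kind, i.e. no false alarm was raised. The strict
#' rule matches the error-judgment intent (flagging a healthy patient is a
#' mistake); both are reported by the pipeline.
#'
#' @param preds List of [patient_predictions()], unique patient ids.
#' @param mode `"strict"` (default) or `"literal"`.
#' @return Mean per-patient score in \[0, 1\].
#' @export
ppatient <- function(preds, mode = c("strict", "literal")) {
  mode <- match.arg(mode)
  stopifnot(length(preds) >= 1L)
  ids <- vapply(preds, function(p) p$patient_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate patient_ids")
  score <- vapply(preds, function(p) {
    stopifnot(inherits(p, "patient_predictions"))
    n_tp <- sum(p$is_tp)
    if (p$has_cmbs) {
      as.numeric(n_tp > 0)
    } else if (mode == "literal") {
      as.numeric(n_tp == 0)
    } else {
      as.numeric(length(p$slice_index) == 0)
    }
  }, numeric(1))
  mean(score)
}

#' Detection precision, recall and mean average precision
#'
#' Greedy one-to-one matching per image: detections are visited in order
#' of descending score and matched to the not-yet-matched ground-truth box
#' of highest IoU, provided that IoU reaches the threshold. AP uses
#' 101-point interpolation (mean over recalls 0, 0.01, ..., 1 of the
#' maximum precision at recall at least that value). `map50` is the AP at
#' IoU 0.5 and `map50_95` the mean AP over thresholds 0.50, 0.55, ...,
#' 0.95. Reported precision/recall are the final counts at IoU 0.5.
#'
#' @param detections Data frame with columns `image_id`, `x1`, `y1`, `x2`,
#'   `y2`, `score`.
#' @param ground_truth Data frame with columns `image_id`, `x1`, `y1`,
#'   `x2`, `y2`.
#' @param iou_thresholds Thresholds for the mAP average.
#' @return List with `precision`, `recall`, `ap` (per threshold), `map50`,
#'   `map50_95`.
#' @export
match_and_map <- function(detections, ground_truth,
                          iou_thresholds = seq(0.5, 0.95, by = 0.05)) {
  n_gt <- nrow(ground_truth)
  n_det <- if (is.null(detections)) 0L else nrow(detections)
  if (n_det == 0L) {
    z <- rep(0, length(iou_thresholds))
    names(z) <- sprintf("%.2f", iou_thresholds)
    return(list(precision = 0, recall = 0, ap = z, map50 = 0, map50_95 = 0))
  }
  det <- detections[order(-detections$score), , drop = FALSE]
  ap <- numeric(length(iou_thresholds))
  pr50 <- NULL
  for (k in seq_along(iou_thresholds)) {
    thr <- iou_thresholds[k]
    tp_flags <- logical(nrow(det))
    for (img in unique(det$image_id)) {
      di <- which(det$image_id == img)
      gi <- which(ground_truth$image_id == img)
      if (!length(gi)) next
      gt_used <- logical(length(gi))
      gb <- as.matrix(ground_truth[gi, c("x1", "y1", "x2", "y2")])
      for (d in di) {
        db <- matrix(as.numeric(det[d, c("x1", "y1", "x2", "y2")]),
                     nrow(gb), 4, byrow = TRUE)
        ious <- iou_family(db, gb, "iou")
        ious[gt_used] <- -1
        j <- which.max(ious)
        if (ious[j] >= thr) {
          tp_flags[d] <- TRUE
          gt_used[j] <- TRUE
        }
      }
    }
    cum_tp <- cumsum(tp_flags)
    cum_fp <- cumsum(!tp_flags)
    prec <- cum_tp / (cum_tp + cum_fp)
    rec <- if (n_gt > 0) cum_tp / n_gt else rep(0, length(cum_tp))
    # 101-point interpolated AP
    rec_grid <- seq(0, 1, by = 0.01)
    prec_env <- rev(cummax(rev(prec)))   # best precision at >= this rank
    ap[k] <- mean(vapply(rec_grid, function(r) {
      i <- which(rec >= r)
      if (length(i)) max(prec_env[i]) else 0
    }, numeric(1)))
    if (abs(thr - 0.5) < 1e-9) {
      pr50 <- c(precision = prec[length(prec)],
                recall = if (n_gt > 0) rec[length(rec)] else 0)
    }
  }
  names(ap) <- sprintf("%.2f", iou_thresholds)
  if (is.null(pr50)) pr50 <- c(precision = NA_real_, recall = NA_real_)
  list(precision = unname(pr50["precision"]), recall = unname(pr50["recall"]),
       ap = ap,
       map50 = if ("0.50" %in% names(ap)) unname(ap["0.50"]) else NA_real_,
       map50_95 = mean(ap))
}

#' Assemble an evaluation report
#'
#' @param counts A [confusion_counts()] at region level.
#' @param preds List of [patient_predictions()].
#' @param map_result Optional result of [match_and_map()].
#' @return A list of class `"eval_report"` with region rates, `fpavg`,
#'   both patient-level accuracies and (optionally) mAP values.
#' @export
eval_report <- function(counts, preds, map_result = NULL) {
  r <- rates(counts)
  rep <- list(sensitivity = unname(r["sensitivity"]),
              specificity = unname(r["specificity"]),
              precision = unname(r["precision"]),
              fpavg = fpavg(counts$fp, length(preds)),
              ppatient_strict = ppatient(preds, "strict"),
              ppatient_literal = ppatient(preds, "literal"),
              map50 = if (is.null(map_result)) NA_real_ else map_result$map50,
              map50_95 = if (is.null(map_result)) NA_real_ else map_result$map50_95,
              counts = counts, n_patients = length(preds))
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.3f", v)
  cat("Screening evaluation report\n")
  cat(sprintf("  patients: %d   region counts: TP=%d TN=%d FP=%d FN=%d\n",
              x$n_patients, x$counts$tp, x$counts$tn, x$counts$fp, x$counts$fn))
  cat(sprintf("  sensitivity %s  specificity %s  precision %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$precision)))
  cat(sprintf("  FPavg %.3f  Ppatient strict %.3f / literal %.3f\n",
              x$fpavg, x$ppatient_strict, x$ppatient_literal))
  if (!is.na(x$map50)) {
    cat(sprintf("  mAP50 %.3f  mAP50-95 %.3f\n", x$map50, x$map50_95))
  }
  invisible(x)
}
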