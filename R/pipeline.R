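# End-to-end two-stage execution per patient: detect on SWI, crop
# candidate volumes, build and encode prompts, classify, report.

# crop a side x side window centered at (cx, cy) from an H x W matrix,
# zero-padding outside the image (0-based continuous center coordinates)
crop_window <- function(img, cx, cy, side) {
  H <- nrow(img); W <- ncol(img)
  x0 <- round(cx) - side %/% 2L       # 0-based left edge
  y0 <- round(cy) - side %/% 2L
  out <- matrix(0, side, side)
  xs <- (x0 + 1L):(x0 + side)         # 1-based column range
  ys <- (y0 + 1L):(y0 + side)
  vx <- xs >= 1L & xs <= W
  vy <- ys >= 1L & ys <= H
  out[which(vy), which(vx)] <- img[ys[vy], xs[vx], drop = FALSE]
  out
}

# crop side for one detection under the configured crop mode
candidate_crop_side <- function(cfg, box_w, box_h) {
  switch(cfg$crop_mode,
         fixed32 = 32L,
         fixed64 = 64L,
         dynamic = {
           s <- ceiling(2 * max(box_w, box_h))
           as.integer(max(16L, ceiling(s / 4) * 4))
         })
}

#' Extract the candidate volume for one detection
#'
#' Crops the slices (i-1, i, i+1) of the SWI stack and phase slice i,
#' centered on the detection box center (rounded to integer pixels);
#' windows reaching outside the image are zero-padded, and missing
#' neighbor slices at stack edges are zero-padded and flagged.
#'
#' @param swi_stack,phase_stack Lists of `H x W` matrices (0--255).
#' @param slice_index 0-based slice of the detection.
#' @param box The detection [box()].
#' @param cfg A [cf_config()] (its `crop_mode` decides the window side).
#' @return A [candidate_volume()].
#' @export
extract_candidate_volume <- function(swi_stack, phase_stack, slice_index,
                                     box, cfg) {
  m <- as_box_matrix(box)
  cx <- (m[1, 1] + m[1, 3]) / 2; cy <- (m[1, 2] + m[1, 4]) / 2
  side <- candidate_crop_side(cfg, m[1, 3] - m[1, 1], m[1, 4] - m[1, 2])
  i <- slice_index + 1L                       # 1-based
  S <- length(swi_stack)
  grab <- function(s) if (s >= 1L && s <= S)
    crop_window(swi_stack[[s]], cx, cy, side) else NULL
  candidate_volume(grab(i - 1L), grab(i), grab(i + 1L),
                   crop_window(phase_stack[[i]], cx, cy, side))
}

# adjacency flags: a detection on slice i +/- 1 whose center lies within
# max(box side, 5 px) of this candidate's center
adjacency_flags <- function(detections, k) {
  d <- detections[k, ]
  cx <- (d$x1 + d$x2) / 2; cy <- (d$y1 + d$y2) / 2
  tol <- max(d$x2 - d$x1, d$y2 - d$y1, 5)
  near <- function(offset) {
    o <- detections[detections$slice_index == d$slice_index + offset, ,
                    drop = FALSE]
    if (!nrow(o)) return(FALSE)
    any(sqrt(((o$x1 + o$x2) / 2 - cx)^2 + ((o$y1 + o$y2) / 2 - cy)^2) <= tol)
  }
  c(prev = near(-1L), next_ = near(1L))
}

#' Run the two-stage pipeline on one patient
#'
#' Stage one detects candidates on the SWI stack only (the phase stack
#' never reaches the detector). For each surviving candidate a 4-slice
#' volume is cropped, the text prompts are built from the patient
#' metadata, the box geometry and the *raw* detection adjacency, and the
#' classifier filters false positives. Region- and patient-level counts
#' are computed against the ground-truth boxes.
#'
#' @param rec A [generate_patient()] record (or any list with `swi`,
#'   `phase`, `meta`, `gt_boxes`).
#' @param detector A trained `"cmb_detector"`.
#' @param classifier A trained `"cmbsformer"`.
#' @param encoder Sentence encoder for the prompts (default
#'   [hash_encoder()]).
#' @param match_iou IoU at which a classified-positive region counts as a
#'   true CMB on its center slice (default 0.5).
#' @return List with `detections`, `classifications`, `counts`
#'   ([confusion_counts()]), `patient` ([patient_predictions()]) and
#'   `map` ([match_and_map()] on the raw detections).
#' @export
run_patient <- function(rec, detector, classifier, encoder = hash_encoder(),
                        match_iou = 0.5) {
  if (length(rec$swi) != length(rec$phase)) {
    stop("SWI and phase stacks must have the same slice count")
  }
  S <- length(rec$swi)
  det <- detect_patient(detector, rec$swi)
  has_gt <- vapply(rec$gt_boxes, nrow, 0L)
  n_gt <- sum(has_gt)

  cls <- NULL
  tp_flags <- logical(0)
  if (nrow(det)) {
    volumes <- vector("list", nrow(det))
    texts <- vector("list", nrow(det))
    for (k in seq_len(nrow(det))) {
      d <- det[k, ]
      volumes[[k]] <- extract_candidate_volume(
        rec$swi, rec$phase, d$slice_index, c(d$x1, d$y1, d$x2, d$y2),
        classifier$cfg)
      adj <- adjacency_flags(det, k)
      pr <- build_prompts(rec$meta, c(d$x1, d$y1, d$x2, d$y2),
                          prev_hit = adj[["prev"]], next_hit = adj[["next_"]])
      texts[[k]] <- encode_prompts(pr, encoder)
    }
    if (classifier$cfg$crop_mode == "dynamic") {
      # pad dynamic crops to the batch maximum so they stack
      sides <- vapply(volumes, function(v) dim(v)[3], 0L)
      smax <- max(sides)
      volumes <- lapply(volumes, function(v) {
        if (dim(v)[3] == smax) return(v)
        out <- array(0, c(3L, 4L, smax, smax))
        o <- (smax - dim(v)[3]) %/% 2L
        out[, , o + seq_len(dim(v)[3]), o + seq_len(dim(v)[4])] <- v
        structure(out, padded = attr(v, "padded"),
                  class = c("candidate_volume", "array"))
      })
    }
    cls <- classify_candidates(
      classifier, volumes,
      if (classifier$cfg$with_text) texts,
      provenance = data.frame(detection_id = seq_len(nrow(det)),
                              slice_index = det$slice_index))
    # region-level truth for each classified-positive candidate
    pos_idx <- which(cls$label == 1L)
    tp_flags <- vapply(pos_idx, function(k) {
      d <- det[k, ]
      g <- rec$gt_boxes[[d$slice_index + 1L]]
      if (!nrow(g)) return(FALSE)
      any(iou_family(matrix(as.numeric(d[c("x1", "y1", "x2", "y2")]),
                            nrow(g), 4, byrow = TRUE), g, "iou") >= match_iou)
    }, logical(1))
  }
  pos_idx <- if (is.null(cls)) integer() else which(cls$label == 1L)
  tp <- sum(tp_flags)
  fp <- sum(!tp_flags)
  # negatives: detector candidates the classifier (correctly) rejected
  neg_idx <- if (is.null(cls)) integer() else which(cls$label == 0L)
  neg_truth <- vapply(neg_idx, function(k) {
    d <- det[k, ]
    g <- rec$gt_boxes[[d$slice_index + 1L]]
    nrow(g) > 0 &&
      any(iou_family(matrix(as.numeric(d[c("x1", "y1", "x2", "y2")]),
                            nrow(g), 4, byrow = TRUE), g, "iou") >= match_iou)
  }, logical(1))
  tn <- sum(!neg_truth)
  fn <- max(n_gt - tp, 0)

  gt_df <- do.call(rbind, lapply(seq_len(S), function(s) {
    g <- rec$gt_boxes[[s]]
    if (!nrow(g)) return(NULL)
    data.frame(image_id = s - 1L, x1 = g[, 1], y1 = g[, 2], x2 = g[, 3],
               y2 = g[, 4])
  }))
  map <- if (!is.null(gt_df) && nrow(det)) {
    det_df <- data.frame(image_id = det$slice_index, det[, c("x1", "y1", "x2",
                                                             "y2", "score")])
    match_and_map(det_df, gt_df)
  } else NULL

  list(detections = det, classifications = cls,
       counts = confusion_counts(tp, tn, fp, fn),
       patient = patient_predictions(
         rec$patient_id, has_cmbs = n_gt > 0,
         slice_index = if (length(pos_idx)) det$slice_index[pos_idx] else integer(),
         is_tp = tp_flags, S = S),
       map = map)
}

#' Evaluate the pipeline over a cohort
#'
#' @param results List of [run_patient()] results.
#' @return An [eval_report()] aggregating region counts, FPavg, both
#'   patient-level accuracies and pooled mAP.
#' @export
evaluate_cohort <- function(results) {
  stopifnot(length(results) >= 1L)
  agg <- function(f) sum(vapply(results, function(r) r$counts[[f]], 0))
  counts <- confusion_counts(agg("tp"), agg("tn"), agg("fp"), agg("fn"))
  preds <- lapply(results, `[[`, "patient")
  maps <- Filter(Negate(is.null), lapply(results, `[[`, "map"))
  mp <- if (length(maps)) {
    list(map50 = mean(vapply(maps, `[[`, 0, "map50")),
         map50_95 = mean(vapply(maps, `[[`, 0, "map50_95")))
  } else NULL
  eval_report(counts, preds, mp)
}

#' Closed-form per-patient inference-time model
#'
#' @param num_image Slices per patient (default 130).
#' @param d_image Detection time per slice in milliseconds.
#' @param c_image Classification time per candidate region in
#'   milliseconds.
#' @param candidates Fixed candidate budget per patient (default 100).
#' @return A list of class `"timing_model"`.
#' @export
timing_model <- function(num_image = 130, d_image, c_image,
                         candidates = 100) {
  v <- c(num_image, d_image, c_image, candidates)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("all timing-model fields must be positive")
  }
  structure(list(num_image = num_image, d_image = d_image,
                 c_image = c_image, candidates = candidates),
            class = "timing_model")
}

#' Per-patient inference time in seconds
#'
#' `(num_image * d_image + candidates * c_image) / 1000`, rounded to two
#' decimals: the per-slice detection cost over the stack plus the
#' classification cost of the standardized candidate budget.
#'
#' @param t A [timing_model()].
#' @return Seconds per patient (2 d.p.).
#' @examples
#' estimate_infertime(timing_model(130, d_image = 14.6, c_image = 26.12))
#' @export
estimate_infertime <- function(t) {
  stopifnot(inherits(t, "timing_model"))
  round((t$num_image * t$d_image + t$candidates * t$c_image) / 1000, 2)
}

#' Combination bookkeeping row for a detector/classifier pairing
#'
#' @param det_params_millions,cls_params_millions Stage parameter counts
#'   in millions (MB in the common reporting convention).
#' @param timing A [timing_model()] for the pairing.
#' @param fpavg,ppatient Optional measured patient-level metrics.
#' @return A one-row data frame with `total_parameters` (sum of the two
#'   stages) and `infertime_s`.
#' @export
combination_report <- function(det_params_millions, cls_params_millions,
                               timing, fpavg = NA_real_,
                               ppatient = NA_real_) {
  stopifnot(det_params_millions >= 0, cls_params_millions >= 0)
  data.frame(det_params = det_params_millions,
             cls_params = cls_params_millions,
             total_parameters = det_params_millions + cls_params_millions,
             infertime_s = estimate_infertime(timing),
             fpavg = fpavg, ppatient = ppatient)
}
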