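## Evaluation protocol: sq-thresholded detection matching (TP/FP/FN with
## precision and recall), confusion matrices with per-class accuracies, and
## reproduction of the reference results shipped as fixtures.

#' Match detections against labeled boxes by segmentation quality
#'
#' Greedy one-to-one matching in descending score order: each detection
#' claims the unmatched label with the highest [sq_score()] provided that sq
#' meets the threshold (ties by smaller detection index); otherwise the
#' detection is a false positive. Unmatched labels are false negatives.
#'
#' @param detections data frame from [detect()] (score-sorted boxes).
#' @param labels list of ground-truth [bbox()]es (same coordinate frame).
#' @param sq_threshold minimum sq for a true positive (reference protocol:
#'   0.5).
#' @param comparison `">="` (default) or `">"` for the threshold test.
#' @return object of class `"detection_eval"`: counts `tp`, `fp`, `fn`,
#'   fractions `precision`, `recall`, and `matches` (data frame: detection
#'   index, label index, sq).
#' @export
match_detections <- function(detections, labels, sq_threshold = 0.5,
                             comparison = c(">=", ">")) {
  comparison <- match.arg(comparison)
  cmp <- if (comparison == ">=") `>=` else `>`
  nd <- nrow(detections)
  nl <- length(labels)
  if (nd > 1L && is.unsorted(-detections$score))
    detections <- detections[order(-detections$score), , drop = FALSE]
  taken <- logical(nl)
  matches <- data.frame(detection = integer(0), label = integer(0),
                        sq = numeric(0))
  for (i in seq_len(nd)) {
    b <- bbox(detections$x_min[i], detections$y_min[i],
              detections$x_max[i], detections$y_max[i])
    if (nl > 0L) {
      sqs <- vapply(labels, function(g) sq_score(b, g)$sq, numeric(1))
      sqs[taken] <- -Inf
      j <- which.max(sqs)
      if (length(j) == 1L && cmp(sqs[j], sq_threshold)) {
        taken[j] <- TRUE
        matches <- rbind(matches,
                         data.frame(detection = i, label = j, sq = sqs[j]))
      }
    }
  }
  tp <- nrow(matches); fp <- nd - tp; fn <- nl - tp
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 matches = matches),
            class = "detection_eval")
}

#' @export
print.detection_eval <- function(x, ...) {
  cat(sprintf("<detection_eval: TP %d FP %d FN %d; precision %s recall %s>\n",
              x$tp, x$fp, x$fn,
              render_percent_int(x$precision, "round"),
              render_percent_int(x$recall, "truncate")))
  invisible(x)
}

## Integer-percent rendering used for headline precision ("95%", nearest
## integer) and recall ("80%", truncated).
render_percent_int <- function(frac, mode = c("round", "truncate")) {
  mode <- match.arg(mode)
  if (is.na(frac)) return(NA_character_)
  pct <- frac * 100
  v <- if (mode == "round") round(pct) else floor(pct + 1e-9)
  sprintf("%d%%", as.integer(v))
}

#' Confusion matrix from label vectors
#'
#' @param true_labels,predicted_labels vectors (coercible to character) of
#'   equal length, drawn from `class_order`.
#' @param class_order class labels fixing row/column order (rows = true
#'   class, columns = predicted).
#' @return object of class `"confusion_matrix"` (integer matrix with
#'   dimnames).
#' @export
confusion_matrix <- function(true_labels, predicted_labels,
                             class_order = rot_class_levels(3)) {
  t_ <- as.character(true_labels); p_ <- as.character(predicted_labels)
  if (length(t_) != length(p_))
    stop("label vectors must have equal length", call. = FALSE)
  bad <- setdiff(unique(c(t_, p_)), class_order)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  tf <- factor(t_, levels = class_order)
  pf <- factor(p_, levels = class_order)
  m <- table(tf, pf)
  cm <- matrix(as.integer(m), nrow = length(class_order),
               dimnames = list(true = class_order, predicted = class_order))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

## Wrap a bare count matrix (e.g. from fixtures) as a confusion_matrix.
as_confusion_matrix <- function(counts, class_order) {
  cm <- matrix(as.integer(as.matrix(counts)), nrow = length(class_order),
               dimnames = list(true = class_order, predicted = class_order))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(unclass(x))
  acc <- per_class_accuracy(x)
  cat("per-class accuracy:",
      paste(sprintf("%s %s", rownames(x), acc$rendered), collapse = ", "),
      "\n")
  invisible(x)
}

#' Per-class accuracies of a confusion matrix
#'
#' Class accuracy is the diagonal count over the row sum. The rendered
#' string truncates to one decimal in percent, the convention of the
#' reference result tables; exact fractions are always retained.
#'
#' @param cm a [confusion_matrix()] (or square count matrix).
#' @param allow_empty if `TRUE`, classes with no samples get `NA` accuracy
#'   instead of an error.
#' @return data frame with `class`, `correct`, `total`, `accuracy`
#'   (fraction) and `rendered` (e.g. `"91.2%"`).
#' @export
per_class_accuracy <- function(cm, allow_empty = FALSE) {
  cm <- unclass(cm)
  rs <- rowSums(cm)
  if (any(rs == 0) && !allow_empty)
    stop("row with zero total: accuracy undefined for class ",
         paste(rownames(cm)[rs == 0], collapse = ", "), call. = FALSE)
  acc <- ifelse(rs > 0, diag(cm) / rs, NA_real_)
  data.frame(class = rownames(cm) %||% as.character(seq_len(nrow(cm))),
             correct = as.integer(diag(cm)), total = as.integer(rs),
             accuracy = as.numeric(acc),
             rendered = vapply(acc, function(a)
               if (is.na(a)) NA_character_ else render_percent_1dec(a),
               character(1)),
             row.names = NULL)
}

## Truncate a fraction to one decimal in percent: 61/73 -> "83.5%".
render_percent_1dec <- function(frac) {
  sprintf("%.1f%%", floor(frac * 1000 + 1e-9) / 10)
}

#' Reference results shipped with the package
#'
#' Loads the bundled fixtures: twelve confusion matrices from a published
#' field study of this pipeline on 1000 stump photographs (three classifier
#' approaches x 2-/3-class mode x manual-crop / detector-crop evaluation)
#' and its detector counts (TP 162, FP 9, FN 39).
#'
#' @return list with `tables` (list of fixtures: `id`, `approach`, `mode`,
#'   `counts`, `printed_accuracy`) and `detection` (tp, fp, fn and printed
#'   precision/recall strings).
#' @export
reference_results <- function() {
  path <- system.file("extdata", "reference_tables.json", package = "stumpRBR")
  det <- system.file("extdata", "reference_detection_counts.json",
                     package = "stumpRBR")
  list(tables = jsonlite::read_json(path, simplifyVector = FALSE),
       detection = jsonlite::read_json(det, simplifyVector = TRUE))
}

#' Recompute the reference tables from their count matrices
#'
#' Recomputes every per-class accuracy of the bundled reference confusion
#' matrices from raw counts, alongside the accuracy strings printed in the
#' source tables, and the detection precision/recall from the reference
#' TP/FP/FN counts.
#'
#' @return list with `accuracies` (data frame: table id, approach, mode,
#'   class, counts, exact fraction, `rendered`, `printed`, `consistent`) and
#'   `detection` (list: counts, exact fractions, rendered precision/recall).
#' @examples
#' rt <- reproduce_reference_tables()
#' subset(rt$accuracies, table == "1c")[, c("class", "rendered", "printed")]
#' rt$detection$precision_rendered
#' @export
reproduce_reference_tables <- function() {
  ref <- reference_results()
  rows <- list()
  for (tb in ref$tables) {
    n <- length(tb$classes)
    counts <- matrix(unlist(tb$counts), nrow = n, byrow = TRUE)
    cm <- as_confusion_matrix(counts, unlist(tb$classes))
    acc <- per_class_accuracy(cm)
    printed <- unlist(tb$printed_accuracy)
    ## consistency is numeric ("26%" and "26.0%" agree): the printed value
    ## equals the truncated one-decimal percentage recomputed from counts
    recomputed <- floor(acc$accuracy * 1000 + 1e-9) / 10
    rows[[length(rows) + 1L]] <- data.frame(
      table = tb$id, approach = tb$approach, mode = tb$mode,
      class = acc$class, correct = acc$correct, total = acc$total,
      accuracy = acc$accuracy, rendered = acc$rendered, printed = printed,
      consistent = as.numeric(sub("%", "", printed)) == recomputed)
  }
  det <- ref$detection
  detection <- list(
    tp = det$tp, fp = det$fp, fn = det$fn,
    precision = det$tp / (det$tp + det$fp),
    recall = det$tp / (det$tp + det$fn),
    precision_rendered = render_percent_int(det$tp / (det$tp + det$fp), "round"),
    recall_rendered = render_percent_int(det$tp / (det$tp + det$fn), "truncate"))
  list(accuracies = do.call(rbind, rows), detection = detection)
}

#' Evaluate the full pipeline on labeled scenes
#'
#' Runs the detector on every scene, matches detections to ground truth at
#' the sq threshold, and evaluates the classifier in the two reference
#' modes: on manually cropped stumps (all ground-truth boxes) and on the
#' detector's true-positive crops.
#'
#' @param scenes list of labeled scenes.
#' @param detector a trained [train_detector()] model.
#' @param classifier a trained [train_rot_classifier()] model.
#' @param sq_threshold matching threshold.
#' @return list with `detection` (aggregate counts/precision/recall),
#'   `manual` and `detector_tp` (each: `confusion` matrix + `accuracy` data
#'   frame).
#' @export
evaluate_pipeline <- function(scenes, detector, classifier,
                              sq_threshold = 0.5) {
  n_classes <- length(classifier$class_levels)
  tp <- fp <- fn <- 0L
  man_true <- man_pred <- det_true <- det_pred <- character(0)
  for (sc in scenes) {
    gt_boxes <- lapply(sc$stumps, `[[`, "bbox")
    gt_lab <- vapply(sc$stumps, function(s) as.character(s$rot_class),
                     character(1))
    gt_lab <- as.character(project_labels(gt_lab, n_classes))
    dets <- detect(detector, sc$image)
    ev <- match_detections(dets, gt_boxes, sq_threshold)
    tp <- tp + ev$tp; fp <- fp + ev$fp; fn <- fn + ev$fn
    ## manual-crop mode: classify ground-truth crops
    man_crops <- lapply(gt_boxes, function(b) crop_scene(sc$image, b))
    if (length(man_crops)) {
      man_true <- c(man_true, gt_lab)
      man_pred <- c(man_pred,
                    as.character(predict(classifier, man_crops)))
    }
    ## detector-TP mode: classify the matched detections' crops
    if (ev$tp > 0L) {
      tp_crops <- lapply(ev$matches$detection, function(i)
        crop_scene(sc$image, bbox(dets$x_min[i], dets$y_min[i],
                                  dets$x_max[i], dets$y_max[i])))
      det_true <- c(det_true, gt_lab[ev$matches$label])
      det_pred <- c(det_pred,
                    as.character(predict(classifier, tp_crops)))
    }
  }
  lv <- classifier$class_levels
  man_cm <- confusion_matrix(man_true, man_pred, lv)
  det_cm <- confusion_matrix(det_true, det_pred, lv)
  list(detection = list(tp = tp, fp = fp, fn = fn,
                        precision = if (tp + fp > 0) tp / (tp + fp) else NA,
                        recall = if (tp + fn > 0) tp / (tp + fn) else NA),
       manual = list(confusion = man_cm,
                     accuracy = per_class_accuracy(man_cm, allow_empty = TRUE)),
       detector_tp = list(confusion = det_cm,
                          accuracy = per_class_accuracy(det_cm,
                                                        allow_empty = TRUE)))
}

## Crop a box out of a scene image (no resampling).
crop_scene <- function(image, b) {
  H <- dim(image)[1]; W <- dim(image)[2]
  ys <- max(1L, floor(b[["y_min"]]) + 1L):min(H, ceiling(b[["y_max"]]))
  xs <- max(1L, floor(b[["x_min"]]) + 1L):min(W, ceiling(b[["x_max"]]))
  image[ys, xs, , drop = FALSE]
}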