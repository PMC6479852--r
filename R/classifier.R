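## The three rot-severity classification approaches:
##   BS - bag-of-visual-words histograms + multiclass SVM
##   VS - CNN penultimate-layer features + multiclass SVM
##   VF - the CNN backbone fine-tuned end-to-end with a replaced head
## in 2-class (rot / no rot) or 3-class severity mode, with per-class
## balancing of the training set.

#' Classifier specification
#'
#' @param approach `"BS"` (BoF + SVM), `"VS"` (CNN features + SVM) or
#'   `"VF"` (fine-tuned CNN).
#' @param n_classes 2 (rot vs no rot) or 3 (severity classes).
#' @param balance_per_class training crops drawn per class (reference
#'   configuration: 160, the size of the smallest class); `NULL` uses the
#'   smallest class size.
#' @param svm_kernel SVM kernel for BS/VS (linear by default; libsvm
#'   pairwise-voting multiclass).
#' @param svm_cost SVM misclassification cost; the default 100 suits
#'   small-magnitude features such as normalized word histograms, where
#'   libsvm's default of 1 underfits badly.
#' @param bof_k visual vocabulary size for BS.
#' @param finetune VF settings: `batch_size`, `initial_lr`, `max_epochs`,
#'   `lr_boost_new_layers` (learning-rate multiplier of the freshly attached
#'   head relative to the pretrained layers). The desk-scale defaults are
#'   batch 16, rate 2e-3, 30 epochs, boost 10; a full-scale backbone would
#'   use rate 1e-4 and up to 300 epochs.
#' @return object of class `"classifier_spec"`.
#' @export
classifier_spec <- function(approach = c("VF", "BS", "VS"), n_classes = 3L,
                            balance_per_class = 160L,
                            svm_kernel = "linear", svm_cost = 100,
                            bof_k = 500L,
                            finetune = list(batch_size = 16L,
                                            initial_lr = 2e-3,
                                            max_epochs = 30L,
                                            lr_boost_new_layers = 10)) {
  approach <- match.arg(approach)
  if (!n_classes %in% c(2L, 3L))
    stop("n_classes must be 2 or 3", call. = FALSE)
  if (!is.null(balance_per_class) && balance_per_class < 1)
    stop("balance_per_class must be >= 1", call. = FALSE)
  structure(list(approach = approach, n_classes = as.integer(n_classes),
                 balance_per_class = balance_per_class,
                 svm_kernel = svm_kernel, svm_cost = svm_cost,
                 bof_k = as.integer(bof_k), finetune = finetune),
            class = "classifier_spec")
}

#' Balance classes by subsampling
#'
#' Draws exactly `per_class` samples per class without replacement,
#' deterministically for a given seed.
#'
#' @param labels factor (or character) class label per sample.
#' @param per_class samples to keep per class; `NULL` uses the smallest
#'   class size.
#' @param seed integer seed.
#' @return integer vector of kept sample indices (grouped by class level).
#' @export
balance_classes <- function(labels, per_class = NULL, seed = 1L) {
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  sizes <- table(labels)
  if (is.null(per_class)) per_class <- min(sizes)
  if (any(sizes < per_class))
    stop(sprintf("class '%s' has %d samples, fewer than per_class = %d",
                 names(sizes)[which.min(sizes)], min(sizes), per_class),
         call. = FALSE)
  with_seed(seed, {
    unlist(lapply(levels(labels), function(lv) {
      i <- which(labels == lv)
      sort(i[sample.int(length(i), per_class)])
    }), use.names = FALSE)
  })
}

## Collapse 3-class severity labels to the requested class set.
project_labels <- function(labels, n_classes) {
  labels <- as.character(labels)
  if (n_classes == 2L)
    labels <- ifelse(labels == "NO_ROT", "NO_ROT", "ROT")
  factor(labels, levels = rot_class_levels(n_classes))
}

#' Train a rot-severity classifier
#'
#' Balances the training crops per class, then trains the approach given in
#' `spec`: BS builds a visual vocabulary on the training crops' descriptors
#' and fits a multiclass SVM on their word histograms; VS fits the SVM on
#' the backbone's penultimate-layer features; VF replaces the backbone's
#' classification layer with a fresh head (FC-64, ReLU, FC-n, softmax) and
#' continues training all layers, with the new head's learning rate boosted.
#'
#' @param spec a [classifier_spec()].
#' @param crops list of stump crop images (original resolution).
#' @param labels 3-level severity factor per crop (see
#'   [rot_class_levels()]); collapsed automatically in 2-class mode.
#' @param seed integer seed (balancing, vocabulary, head init, batches).
#' @param backbone a [train_backbone()] model for VS/VF; trained on the
#'   auxiliary synthetic task if `NULL`.
#' @param verbose print fine-tuning progress.
#' @return object of class `"rot_classifier"`.
#' @export
train_rot_classifier <- function(spec, crops, labels, seed = 1L,
                                 backbone = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "classifier_spec"), length(crops) == length(labels))
  if (length(crops) == 0L) stop("no training crops", call. = FALSE)
  y3 <- factor(as.character(labels), levels = ROT_CLASSES)
  y <- project_labels(y3, spec$n_classes)
  if (any(table(y) == 0L)) stop("a class has no training crops", call. = FALSE)
  seeds <- derive_seeds(seed, 4L)
  keep <- balance_classes(y, spec$balance_per_class, seed = seeds[1])
  crops <- crops[keep]; y <- droplevels(y[keep])

  model <- list(spec = spec, class_levels = levels(y))
  if (spec$approach == "BS") {
    descs <- lapply(crops, function(cr) extract_descriptors(cr)$descriptors)
    vocab <- build_vocabulary(descs, k = spec$bof_k, seed = seeds[2])
    X <- t(vapply(descs, function(d) encode_bof(d, vocab),
                  numeric(vocab$k)))
    model$vocab <- vocab
    model$svm <- e1071::svm(X, y, kernel = spec$svm_kernel,
                            cost = spec$svm_cost, scale = FALSE)
  } else {
    if (is.null(backbone)) backbone <- train_backbone(seed = seeds[3])
    if (spec$approach == "VS") {
      X <- extract_cnn_features(crops, backbone)
      model$backbone <- backbone
      model$svm <- e1071::svm(X, y, kernel = spec$svm_kernel,
                              cost = spec$svm_cost, scale = FALSE)
    } else {                                   # VF: fine-tune with new head
      net <- backbone$net
      nl <- length(net$layers)
      ## drop the pretrained classification layer, attach FC-64/ReLU/FC-n
      head <- list(nn_fc(64L), nn_relu(), nn_fc(spec$n_classes))
      tail_net <- nn_init(head, 128L, seed = seeds[2])
      net$layers <- c(net$layers[-nl], tail_net$layers)
      boost <- spec$finetune$lr_boost_new_layers %||% 10
      for (i in (nl):(nl + 2L)) net$layers[[i]]$lr_mult <- boost
      net$out_dim <- spec$n_classes
      s <- backbone$input_size
      X <- array(0, dim = c(s, s, 3L, length(crops)))
      for (i in seq_along(crops)) X[, , , i] <- resize_image(crops[[i]], s, s)
      sched <- list(nn_sched_step(spec$finetune$initial_lr,
                                  spec$finetune$max_epochs,
                                  spec$finetune$batch_size))
      net <- nn_train(net, X, as.integer(y), sched, seed = seeds[4],
                      verbose = verbose)
      model$net <- net
      model$input_size <- s
      model$backbone <- backbone["input_size"]   # provenance only
    }
  }
  structure(model, class = "rot_classifier")
}

#' @export
print.rot_classifier <- function(x, ...) {
  cat(sprintf("<rot_classifier %s, %d classes: %s>\n", x$spec$approach,
              length(x$class_levels), paste(x$class_levels, collapse = ", ")))
  invisible(x)
}

#' Predict rot severity for stump crops
#'
#' @param object a trained [train_rot_classifier()] model.
#' @param crops one crop image or a list of crop images.
#' @param ... unused.
#' @return factor of predicted class labels.
#' @export
predict.rot_classifier <- function(object, crops, ...) {
  if (!is.list(crops)) crops <- list(crops)
  spec <- object$spec
  if (spec$approach == "BS") {
    X <- t(vapply(crops, function(cr) encode_bof(cr, object$vocab),
                  numeric(object$vocab$k)))
    p <- stats::predict(object$svm, X)
  } else if (spec$approach == "VS") {
    X <- extract_cnn_features(crops, object$backbone)
    p <- stats::predict(object$svm, X)
  } else {
    s <- object$input_size
    X <- array(0, dim = c(s, s, 3L, length(crops)))
    for (i in seq_along(crops)) X[, , , i] <- resize_image(crops[[i]], s, s)
    P <- nn_predict(object$net, X)
    p <- object$class_levels[max.col(t(P), ties.method = "first")]
  }
  factor(as.character(p), levels = object$class_levels)
}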