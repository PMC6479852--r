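## End-to-end workflow: simulate -> split -> train detector -> detect ->
## crop -> train classifiers -> classify -> evaluate, seed-reproducible from
## a single configuration.

#' Stratified train/test split
#'
#' Splits scene indices into disjoint, exhaustive train and test sets,
#' stratified by rot class, deterministically for a given seed. The total
#' training count is `floor(fraction * n)` (never all samples), allocated
#' across strata proportionally with largest-remainder rounding.
#'
#' @param labels per-scene class labels (factor or character).
#' @param fraction training fraction in (0, 1) (reference protocol: 0.8).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_dataset <- function(labels, fraction = 0.8, seed = 1L) {
  if (length(labels) == 0L) stop("empty dataset", call. = FALSE)
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie in (0, 1)", call. = FALSE)
  labels <- droplevels(as.factor(labels))
  n <- length(labels)
  n_train <- min(floor(fraction * n), n - 1L)  # always >= 1 test sample
  sizes <- as.integer(table(labels))
  raw <- n_train * sizes / n
  per <- floor(raw)
  rem <- n_train - sum(per)
  if (rem > 0) {
    add <- order(raw - per, decreasing = TRUE)[seq_len(rem)]
    per[add] <- per[add] + 1L
  }
  per <- pmin(per, sizes)
  with_seed(seed, {
    train <- sort(unlist(lapply(seq_along(levels(labels)), function(k) {
      i <- which(labels == levels(labels)[k])
      sort(i[sample.int(length(i), per[k])])
    }), use.names = FALSE))
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

#' Pipeline configuration
#'
#' Bundles every stage's parameters. Defaults give a desk-scale synthetic
#' experiment that runs end to end on one CPU.
#'
#' @param n_per_class scenes per severity class (class order of
#'   [rot_class_levels()]).
#' @param scene scene generation parameters ([scene_params()]).
#' @param detector detector configuration ([detector_config()]).
#' @param approaches classifier approaches to train (subset of BS, VS, VF).
#' @param n_classes class settings to evaluate (subset of 2:3).
#' @param balance_per_class training crops per class (`NULL` = smallest
#'   class).
#' @param bof_k visual vocabulary size for the BS approach.
#' @param split_fraction training fraction.
#' @param sq_threshold detection-matching threshold.
#' @param master_seed master seed; all stage seeds derive from it.
#' @return object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(n_per_class = c(25, 10, 15),
                            scene = scene_params(),
                            detector = detector_config(),
                            approaches = "VF",
                            n_classes = c(2L, 3L),
                            balance_per_class = NULL,
                            bof_k = 500L,
                            split_fraction = 0.8,
                            sq_threshold = 0.5,
                            master_seed = 1L) {
  stopifnot(all(approaches %in% c("BS", "VS", "VF")),
            all(n_classes %in% 2:3),
            split_fraction > 0, split_fraction < 1)
  structure(list(n_per_class = n_per_class, scene = scene,
                 detector = detector, approaches = approaches,
                 n_classes = as.integer(n_classes),
                 balance_per_class = balance_per_class,
                 bof_k = as.integer(bof_k),
                 split_fraction = split_fraction,
                 sq_threshold = sq_threshold,
                 master_seed = as.integer(master_seed)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Generates (or accepts) labeled scenes, splits them stratified by class,
#' trains the stump detector on the training fold, trains the configured
#' rot classifiers on manually cropped training stumps, and evaluates on
#' the test fold in both reference modes (manual crops and detector
#' true-positive crops), for each configured class setting.
#'
#' @param config a [pipeline_config()].
#' @param scenes optional pre-generated scenes (bypasses simulation).
#' @param out_dir optional directory: writes `report.json` and the dataset
#'   annotation index there.
#' @param verbose log stage progress.
#' @return list: `config_hash`, `counts`, `detection`, and `results` — one
#'   entry per (approach, n_classes) with the two evaluation modes.
#' @export
run_pipeline <- function(config = pipeline_config(), scenes = NULL,
                         out_dir = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  seeds <- derive_seeds(config$master_seed, 6L)
  if (is.null(scenes)) {
    say("simulating %d scenes", sum(config$n_per_class))
    scenes <- generate_scene_set(config$n_per_class, config$scene,
                                 seed = seeds[1])
  }
  labels <- vapply(scenes, function(s)
    if (length(s$stumps)) as.character(s$stumps[[1]]$rot_class) else "NO_ROT",
    character(1))
  sp <- split_dataset(labels, config$split_fraction, seed = seeds[2])
  say("split: %d train / %d test", length(sp$train), length(sp$test))

  say("training detector")
  det_model <- train_detector(scenes[sp$train], config$detector,
                              seed = seeds[3])

  train_crops <- list(); train_labels <- character(0)
  for (sc in scenes[sp$train]) for (st in sc$stumps) {
    train_crops[[length(train_crops) + 1L]] <- crop_scene(sc$image, st$bbox)
    train_labels <- c(train_labels, as.character(st$rot_class))
  }

  backbone <- if (any(config$approaches %in% c("VS", "VF")))
    train_backbone(seed = seeds[4]) else NULL

  results <- list()
  detection <- NULL
  for (nc in config$n_classes) {
    for (ap in config$approaches) {
      say("training %s (%d classes) on %d crops", ap, nc, length(train_crops))
      spec <- classifier_spec(approach = ap, n_classes = nc,
                              balance_per_class = config$balance_per_class,
                              bof_k = config$bof_k)
      clf <- train_rot_classifier(spec, train_crops, train_labels,
                                  seed = seeds[5], backbone = backbone)
      say("evaluating %s (%d classes)", ap, nc)
      ev <- evaluate_pipeline(scenes[sp$test], det_model, clf,
                              sq_threshold = config$sq_threshold)
      detection <- detection %||% ev$detection
      results[[sprintf("%s_%dclass", ap, nc)]] <- list(
        approach = ap, n_classes = nc,
        manual = list(counts = unclass(ev$manual$confusion),
                      accuracy = ev$manual$accuracy),
        detector_tp = list(counts = unclass(ev$detector_tp$confusion),
                           accuracy = ev$detector_tp$accuracy))
    }
  }
  report <- list(
    config_hash = config_hash(config),
    counts = list(n_scenes = length(scenes), n_train = length(sp$train),
                  n_test = length(sp$test)),
    detection = detection,
    results = results)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         force = TRUE)
  }
  report
}

## Short deterministic hash of a configuration (stamped into outputs):
## a polynomial rolling hash over the deparsed configuration.
config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror [pipeline_config()]
#' arguments; `scene` and `detector` sub-maps are passed to their
#' constructors.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("n_per_class", "approaches", "n_classes", "balance_per_class",
              "bof_k", "split_fraction", "sq_threshold", "master_seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$scene)) args$scene <- do.call(scene_params, y$scene)
  if (!is.null(y$detector)) args$detector <- do.call(detector_config, y$detector)
  do.call(pipeline_config, args)
}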