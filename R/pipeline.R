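# End-to-end orchestration: phantom generation -> detector training ->
# detection -> scale-normalized cropping -> classifier cross-validation ->
# pooled reports. Every stage writes its artifacts into the run directory
# and is skipped on re-run when its artifacts already exist under the same
# config hash, so a run is resumable; all stage seeds derive
# deterministically from the single global seed.

#' Build crops for one assessment from a manifest
#'
#' Loads every hand, obtains joint centers either from the ground-truth
#' annotations or from a trained detector, scale-normalizes, and crops all
#' target joints. With a detector, detections whose box does not contain
#' the ground-truth center are discarded (excluded from the crop set), as
#' downstream experiments must not see misdetected joints.
#'
#' @param manifest Dataset manifest.
#' @param assessment `"erosion"` or `"jsn"`.
#' @param detector Optional trained [train_detector()] model; `NULL` uses
#'   ground-truth centers.
#' @param L_ref Scale-normalization reference length.
#' @return List of `joint_crop` objects.
#' @export
crops_from_manifest <- function(manifest, assessment, detector = NULL,
                                L_ref = 100) {
  out <- list()
  for (i in seq_len(nrow(manifest))) {
    h <- load_hand(manifest, i)
    gt <- h$annotations[h$annotations$assessment == assessment, ]
    if (is.null(detector)) {
      centers <- gt[, c("name", "x", "y")]
    } else {
      det <- detect(detector, h$image, h$side)
      sn_gt <- gt
      # flag misdetections by the box criterion at normalized scale
      sn <- scale_normalize(h$image, det, L_ref = L_ref)
      sn_gt$x <- rescale_coords(gt$x, ncol(h$image), ncol(sn$image))
      sn_gt$y <- rescale_coords(gt$y, nrow(h$image), nrow(sn$image))
      ev <- evaluate_detection(sn$centers, sn_gt, assessment)
      centers <- det
      centers$discarded <- ev$per_joint$discarded[
        match(centers$name, ev$per_joint$name)]
    }
    cr <- crop_hand(h$image, centers, h$annotations, assessment, h$side,
                    patient_id = h$patient_id, exam_idx = h$exam_idx,
                    L_ref = L_ref)
    out <- c(out, cr)
  }
  out
}

clone_with_seed <- function(obj, seed) {
  obj$seed <- as.integer(seed)
  obj
}

#' Patient-disjoint cross-validated training of one classifier
#'
#' For each fold rotation: assembles tuples from the training, validation
#' and test patients, balances the training and validation tuples by
#' augmentation, trains the model, and predicts the (un-augmented) test
#' tuples. Per-rotation seeds derive from the config and policy seeds.
#'
#' @param crops Crop list (one assessment).
#' @param folds A [make_patient_folds()] split.
#' @param config A [classifier_config()].
#' @param policy An [augmentation_policy()].
#' @return List with `predictions` (pooled test predictions, one row per
#'   joint slot, with `fold`), `metrics` ([aggregate_cv()] table) and
#'   `n_excluded` (incomplete exams dropped during tuple assembly).
#' @export
crossval_classification <- function(crops, folds, config, policy) {
  preds <- list()
  n_excluded <- 0L
  for (i in seq_along(folds$rotations)) {
    rot <- folds$rotations[[i]]
    crops_of <- function(ids) {
      Filter(function(cr) cr$patient_id %in% ids, crops)
    }
    tr <- assemble_tuples(crops_of(rot$train), config$architecture,
                          config$assessment, config$group)
    va <- assemble_tuples(crops_of(rot$validation), config$architecture,
                          config$assessment, config$group)
    te <- assemble_tuples(crops_of(rot$test), config$architecture,
                          config$assessment, config$group)
    n_excluded <- n_excluded + tr$n_excluded + va$n_excluded + te$n_excluded
    trb <- balance_tuples(tr$tuples, clone_with_seed(
      policy, derive_seed(policy$seed, paste0("train", i))))
    vab <- balance_tuples(va$tuples, clone_with_seed(
      policy, derive_seed(policy$seed, paste0("val", i))))
    model <- build_model(clone_with_seed(
      config, derive_seed(config$seed, paste0("fold", i))))
    trained <- train_classifier(model, trb, vab)
    p <- predict(trained, te$tuples)
    p$fold <- i
    preds[[i]] <- p
  }
  predictions <- do.call(rbind, preds)
  list(predictions = predictions,
       metrics = aggregate_cv(predictions, config$assessment),
       n_excluded = n_excluded)
}

#' Cross-validated comparison of classifier architectures
#'
#' Trains all requested architectures fold by fold with a shared
#' feature-extractor initialization: the single-joint (SISO) model is
#' trained first on each rotation and the contextual (MIMO) models start
#' from its convolutional weights before fine-tuning on their own
#' objective. This mirrors transfer-learning practice where every
#' architecture fine-tunes the same pretrained backbone, and puts the
#' architectures on an equal feature footing so the comparison isolates
#' the value of contextual wiring.
#'
#' @param crops Crop list (one assessment).
#' @param folds A [make_patient_folds()] split.
#' @param configs Named list of [classifier_config()]s, one per
#'   architecture; must contain `"siso"`.
#' @param policy An [augmentation_policy()].
#' @return Named list per architecture, each as in
#'   [crossval_classification()].
#' @export
compare_architectures <- function(crops, folds, configs, policy) {
  stopifnot("siso" %in% names(configs))
  archs <- names(configs)
  preds <- setNames(lapply(archs, function(a) list()), archs)
  for (i in seq_along(folds$rotations)) {
    rot <- folds$rotations[[i]]
    crops_of <- function(ids) Filter(function(cr) cr$patient_id %in% ids, crops)
    tr_crops <- crops_of(rot$train)
    va_crops <- crops_of(rot$validation)
    te_crops <- crops_of(rot$test)
    siso_model <- NULL
    for (arch in c("siso", setdiff(archs, "siso"))) {
      config <- configs[[arch]]
      tr <- assemble_tuples(tr_crops, arch, config$assessment, config$group)
      va <- assemble_tuples(va_crops, arch, config$assessment, config$group)
      te <- assemble_tuples(te_crops, arch, config$assessment, config$group)
      trb <- balance_tuples(tr$tuples, clone_with_seed(
        policy, derive_seed(policy$seed, paste0(arch, "train", i))))
      vab <- balance_tuples(va$tuples, clone_with_seed(
        policy, derive_seed(policy$seed, paste0(arch, "val", i))))
      model <- build_model(clone_with_seed(
        config, derive_seed(config$seed, paste0(arch, "fold", i))))
      if (arch != "siso") model$backbone <- siso_model$backbone
      trained <- train_classifier(model, trb, vab)
      if (arch == "siso") siso_model <- trained
      p <- predict(trained, te$tuples)
      p$fold <- i
      preds[[arch]][[i]] <- p
    }
  }
  lapply(preds, function(pl) {
    predictions <- do.call(rbind, pl)
    list(predictions = predictions,
         metrics = aggregate_cv(predictions,
                                configs[[1]]$assessment))
  })
}

#' Stratified report in the standard layout
#'
#' Pools predictions and reports sensitivity, specificity, F-measure and
#' PR-AUC for the combined finger strata, the wrist, and all joints.
#'
#' @param predictions Pooled prediction data frame (see
#'   [crossval_classification()]).
#' @param assessment `"erosion"` or `"jsn"`.
#' @return Data frame with one row per stratum.
#' @export
classification_report <- function(predictions, assessment) {
  groups <- unique(target_joints(assessment, "right")$group)
  nonwrist <- setdiff(groups, "Wrist")
  strata <- list(paste(nonwrist, collapse = "+"), "Wrist", "All joints")
  predictions$group <- joint_group(assessment, predictions$name)
  rows <- lapply(strata, function(st) {
    sub <- if (st == "All joints") predictions
      else if (st == "Wrist") predictions[predictions$group == "Wrist", ]
      else predictions[predictions$group %in% nonwrist, ]
    sm <- summarize_counts(confusion_counts(sub$label, sub$call))
    auc <- if (length(unique(sub$label)) == 2L)
      pr_auc(sub$prob, sub$label)$auc else NA_real_
    data.frame(stratum = st, n = nrow(sub),
               sensitivity = sm$sensitivity, specificity = sm$specificity,
               f_measure = sm$f_measure, pr_auc = auc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pipeline run configuration
#'
#' @param output_dir Run directory.
#' @param seed Global seed; every stage seed derives from it.
#' @param n_patients,exams_per_patient Cohort shape.
#' @param phantom A [phantom_config()] (its seed is overridden).
#' @param assessments Assessments to run.
#' @param n_detector_train Number of hand images used to train detectors.
#' @param detector_args Named list of extra [detector_config()] arguments.
#' @param groups Joint groups to model per assessment (`NULL` = all).
#' @param architectures Classifier architectures to compare.
#' @param classifier_args Named list of extra [classifier_config()]
#'   arguments.
#' @param policy_args Named list of extra [augmentation_policy()] arguments.
#' @param k Cross-validation folds.
#' @param use_detector Use trained detectors for cropping (`FALSE` crops at
#'   ground-truth centers).
#' @param L_ref Scale-normalization reference length.
#' @return Object of class `run_config`.
#' @export
run_config <- function(output_dir, seed = 1L, n_patients = 10,
                       exams_per_patient = 1L,
                       phantom = phantom_config(image_size = 256),
                       assessments = "erosion",
                       n_detector_train = 8,
                       detector_args = list(input_size = 64, max_epochs = 60),
                       groups = list(erosion = "MCP", jsn = "MCP"),
                       architectures = c("siso", "mimo_local"),
                       classifier_args = list(max_epochs = 12),
                       policy_args = list(n_total = 400L),
                       k = 3, use_detector = TRUE, L_ref = 100) {
  structure(list(
    output_dir = output_dir, seed = as.integer(seed),
    n_patients = n_patients, exams_per_patient = exams_per_patient,
    phantom = phantom, assessments = assessments,
    n_detector_train = n_detector_train, detector_args = detector_args,
    groups = groups, architectures = architectures,
    classifier_args = classifier_args, policy_args = policy_args,
    k = k, use_detector = use_detector, L_ref = L_ref
  ), class = "run_config")
}

config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  sprintf("%x", h)
}

stage_done <- function(dir, stage, hash) {
  f <- file.path(dir, paste0(".", stage, ".done"))
  file.exists(f) && identical(readLines(f, warn = FALSE)[1], hash)
}

mark_done <- function(dir, stage, hash) {
  writeLines(hash, file.path(dir, paste0(".", stage, ".done")))
}

#' Run the full pipeline
#'
#' Executes phantom generation, detector training, detection, cropping,
#' cross-validated classifier training and report aggregation. Stages
#' whose artifacts already exist under the same configuration hash are
#' skipped, so an interrupted run resumes where it stopped; a re-run under
#' the same config and seed reproduces byte-identical reports.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return The run directory, invisibly; reports are written under it
#'   (`detection_report_<assessment>.json`, `predictions_<assessment>.csv`,
#'   `metrics_<assessment>.csv`/`.json`, `provenance.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  say <- function(...) if (!quiet) message("[shscontext] ", ...)

  # stage 1: phantom dataset
  ds_dir <- file.path(config$output_dir, "dataset")
  if (!stage_done(config$output_dir, "dataset", hash)) {
    say("generating phantom dataset")
    ph <- clone_with_seed(config$phantom, derive_seed(config$seed, "phantom"))
    generate_dataset(ph, config$n_patients, config$exams_per_patient, ds_dir)
    mark_done(config$output_dir, "dataset", hash)
  }
  manifest <- read_manifest(file.path(ds_dir, "manifest.csv"))

  findings <- validate_manifest(manifest)
  if (nrow(findings) > 0) {
    stop("generated manifest failed validation: ", findings$message[1],
         call. = FALSE)
  }

  provenance <- list(config_hash = hash, seed = config$seed,
                     package_version = as.character(utils::packageVersion("shscontext")),
                     stages = list())

  for (assessment in config$assessments) {
    detector <- NULL
    if (config$use_detector) {
      # stage 2: detector
      det_file <- file.path(config$output_dir,
                            paste0("detector_", assessment, ".rds"))
      if (!stage_done(config$output_dir, paste0("detector_", assessment), hash)) {
        say("training ", assessment, " detector")
        dcfg <- do.call(detector_config, c(
          list(assessment = assessment,
               seed = derive_seed(config$seed, paste0("detector_", assessment))),
          config$detector_args))
        idx <- with_seed(derive_seed(config$seed, "detector_split"),
                         sample(nrow(manifest)))
        train_idx <- idx[seq_len(min(config$n_detector_train, nrow(manifest)))]
        hands <- lapply(train_idx, function(i) {
          h <- load_hand(manifest, i)
          list(image = h$image, annotations = h$annotations, side = h$side)
        })
        model <- train_detector(hands, dcfg)
        saveRDS(model, det_file)
        mark_done(config$output_dir, paste0("detector_", assessment), hash)
      }
      detector <- readRDS(det_file)

      # stage 3: detection report on all images
      rep_file <- file.path(config$output_dir,
                            paste0("detection_report_", assessment, ".json"))
      if (!stage_done(config$output_dir, paste0("detect_", assessment), hash)) {
        say("running ", assessment, " detection")
        per <- lapply(seq_len(nrow(manifest)), function(i) {
          h <- load_hand(manifest, i)
          det <- detect(detector, h$image, h$side)
          sn <- scale_normalize(h$image, det, L_ref = config$L_ref)
          gt <- h$annotations[h$annotations$assessment == assessment, ]
          gt$x <- rescale_coords(gt$x, ncol(h$image), ncol(sn$image))
          gt$y <- rescale_coords(gt$y, nrow(h$image), nrow(sn$image))
          evaluate_detection(sn$centers, gt, assessment)$per_joint
        })
        pooled <- do.call(rbind, per)
        jsonlite::write_json(pool_detection_summary(pooled, assessment),
                             rep_file, dataframe = "rows", digits = NA,
                             na = "null")
        mark_done(config$output_dir, paste0("detect_", assessment), hash)
      }
    }

    # stage 4+5: crops and cross-validated classification
    pred_file <- file.path(config$output_dir,
                           paste0("predictions_", assessment, ".csv"))
    if (!stage_done(config$output_dir, paste0("classify_", assessment), hash)) {
      say("cropping and training ", assessment, " classifiers")
      crops <- crops_from_manifest(manifest, assessment, detector,
                                   L_ref = config$L_ref)
      folds <- make_patient_folds(unique(manifest$patient_id), k = config$k,
                                  seed = derive_seed(config$seed, "folds"))
      groups <- config$groups[[assessment]]
      if (is.null(groups)) {
        groups <- unique(target_joints(assessment, "right")$group)
      }
      all_preds <- list()
      for (grp in groups) {
        say("  ", assessment, " / ", grp)
        archs <- unique(c("siso", config$architectures))
        configs <- setNames(lapply(archs, function(arch) {
          do.call(classifier_config, c(
            list(architecture = arch, assessment = assessment, group = grp,
                 seed = derive_seed(config$seed,
                                    paste(assessment, grp, arch))),
            config$classifier_args))
        }), archs)
        pol <- do.call(augmentation_policy, c(
          list(seed = derive_seed(config$seed,
                                  paste("policy", assessment, grp))),
          config$policy_args))
        cv <- compare_architectures(crops, folds, configs, pol)
        for (arch in intersect(config$architectures, names(cv))) {
          p <- cv[[arch]]$predictions
          p$architecture <- arch
          all_preds[[length(all_preds) + 1L]] <- p
        }
      }
      predictions <- do.call(rbind, all_preds)
      write.csv(predictions, pred_file, row.names = FALSE)
      mark_done(config$output_dir, paste0("classify_", assessment), hash)
    }

    # stage 6: reports
    predictions <- read.csv(pred_file, stringsAsFactors = FALSE)
    reports <- lapply(split(predictions, predictions$architecture),
                      classification_report, assessment = assessment)
    tab <- do.call(rbind, lapply(names(reports), function(a) {
      cbind(architecture = a, reports[[a]])
    }))
    write.csv(tab, file.path(config$output_dir,
                             paste0("metrics_", assessment, ".csv")),
              row.names = FALSE)
    jsonlite::write_json(tab, file.path(config$output_dir,
                                        paste0("metrics_", assessment, ".json")),
                         dataframe = "rows", digits = NA, na = "null")
  }

  jsonlite::write_json(provenance,
                       file.path(config$output_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(config$output_dir)
}

#' Validate a dataset manifest
#'
#' Structural checks: exactly two hand records per exam, existing image and
#' annotation files, complete joint sets (16 erosion / 15 JSN, correct
#' sides) and labels in the legal domain. Returns findings rather than
#' raising.
#'
#' @param manifest Manifest data frame (with `root` attribute).
#' @return Data frame of findings (`where`, `message`); zero rows when the
#'   manifest is clean.
#' @export
validate_manifest <- function(manifest) {
  root <- manifest_root(manifest)
  findings <- list()
  note <- function(where, msg) {
    findings[[length(findings) + 1L]] <<- data.frame(
      where = where, message = msg, stringsAsFactors = FALSE)
  }

  exams <- split(manifest, paste(manifest$patient_id, manifest$exam_idx))
  for (key in names(exams)) {
    sides <- sort(exams[[key]]$side)
    if (!identical(sides, c("left", "right"))) {
      note(key, paste0("exam must have exactly one left and one right hand, got: ",
                       paste(sides, collapse = ", ")))
    }
  }

  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    ipath <- file.path(root, row$image_path)
    apath <- file.path(root, row$annotation_path)
    if (!file.exists(ipath)) {
      note(row$image_path, "image file missing")
      next
    }
    if (!file.exists(apath)) {
      note(row$annotation_path, "annotation file missing")
      next
    }
    ann <- read_annotations(apath)
    for (a in c("erosion", "jsn")) {
      tj <- target_joints(a, row$side)
      have <- ann$name[ann$assessment == a]
      missing <- setdiff(tj$name, have)
      if (length(missing)) {
        note(row$image_path,
             paste0("annotation missing ", a, " joint(s): ",
                    paste(missing, collapse = ", ")))
      }
      extra <- table(have)
      if (any(extra > 1)) {
        note(row$image_path,
             paste0("duplicated ", a, " joint(s): ",
                    paste(names(extra[extra > 1]), collapse = ", ")))
      }
    }
    if (!all(ann$label %in% c("intact", "non-intact"))) {
      note(row$image_path, "labels outside {intact, non-intact}")
    }
    bad_side <- ann$joint_id[!endsWith(ann$joint_id, row$side)]
    if (length(bad_side)) {
      note(row$image_path, "annotation joint ids carry the wrong side")
    }
  }
  if (length(findings) == 0L) {
    return(data.frame(where = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}
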