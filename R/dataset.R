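# Dataset generation and manifest / annotation IO. A dataset directory
# holds images/ (8-bit grayscale PNG), annotations/ (one JSON per image)
# and manifest.csv (patient_id, exam_idx, side, image_path, annotation_path,
# paths relative to the dataset root). Every exam contributes exactly two
# hand images.

#' Reference visit schedule
#'
#' Per-patient exam counts of the 40-patient study cohort: 3 patients
#' X-rayed once, 5 twice, 30 three times, 1 four times and 1 six times —
#' 113 two-hand exams, i.e. 226 one-hand images.
#' @return Integer vector of length 40.
#' @export
reference_visit_schedule <- function() {
  c(rep(1L, 3), rep(2L, 5), rep(3L, 30), 4L, 6L)
}

#' Generate a phantom dataset
#'
#' Samples correlated destruction states, renders every hand of every exam,
#' and writes images, per-image annotation JSON and a manifest CSV.
#' Generation is byte-for-byte reproducible under a fixed config seed.
#'
#' @param config A [phantom_config()].
#' @param n_patients Number of patients.
#' @param exams_per_patient Single count or per-patient vector of visits
#'   (e.g. [reference_visit_schedule()]).
#' @param output_dir Writable output directory (created if missing).
#' @return The manifest data frame (invisibly carries the dataset root as
#'   attribute `root`), with one row per hand image.
#' @export
generate_dataset <- function(config, n_patients, exams_per_patient,
                             output_dir) {
  stopifnot(inherits(config, "phantom_config"))
  ok <- dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(output_dir)) {
    stop("cannot create output directory: ", output_dir, call. = FALSE)
  }
  dir.create(file.path(output_dir, "images"), showWarnings = FALSE)
  dir.create(file.path(output_dir, "annotations"), showWarnings = FALSE)
  if (length(exams_per_patient) == 1L) {
    exams_per_patient <- rep(as.integer(exams_per_patient), n_patients)
  }

  with_seed(config$seed, {
    states <- sample_states_impl(config, n_patients, exams_per_patient)
    pid <- sprintf("P%03d", seq_len(n_patients))
    rows <- list()
    for (p in seq_len(n_patients)) {
      for (e in seq_len(exams_per_patient[p])) {
        for (side in c("right", "left")) {
          st <- states[states$patient_id == pid[p] & states$exam_idx == e &
                         states$side == side, , drop = FALSE]
          rh <- render_hand(st, side, config)
          stem <- sprintf("%s_e%d_%s", pid[p], e, side)
          ipath <- file.path("images", paste0(stem, ".png"))
          apath <- file.path("annotations", paste0(stem, ".json"))
          write_image(rh$image, file.path(output_dir, ipath))
          write_annotations(rh$annotations, file.path(output_dir, apath))
          rows[[length(rows) + 1L]] <- data.frame(
            patient_id = pid[p], exam_idx = e, side = side,
            image_path = ipath, annotation_path = apath,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    manifest <- do.call(rbind, rows)
    write.csv(manifest, file.path(output_dir, "manifest.csv"),
              row.names = FALSE)
    attr(manifest, "root") <- output_dir
    manifest
  })
}

#' Read and write per-image joint annotations
#'
#' JSON: an array of objects with fields `joint_id`, `assessment`, `name`,
#' `group`, `x`, `y`, `axis`, `grade`, `label` (coordinates 0-based
#' subpixel floats, x rightward, y downward).
#'
#' @param ann Annotation data frame.
#' @param path File path.
#' @return `read_annotations()` returns the data frame.
#' @export
write_annotations <- function(ann, path) {
  jsonlite::write_json(ann, path, dataframe = "rows", digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!"axis" %in% names(out)) out$axis <- NA_real_
  out$axis <- as.numeric(out$axis)
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Read a dataset manifest
#'
#' @param path Path to a `manifest.csv` (its directory becomes the dataset
#'   root for resolving relative paths).
#' @return Manifest data frame with attribute `root`.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  attr(m, "root") <- dirname(path)
  m
}

manifest_root <- function(manifest) {
  root <- attr(manifest, "root")
  if (is.null(root)) stop("manifest has no dataset root", call. = FALSE)
  root
}

#' Load one hand record
#'
#' @param manifest A manifest data frame (with `root` attribute).
#' @param i Row index.
#' @return List with `image`, `annotations`, and the manifest row fields.
#' @export
load_hand <- function(manifest, i) {
  root <- manifest_root(manifest)
  row <- manifest[i, ]
  list(
    image = read_image(file.path(root, row$image_path)),
    annotations = read_annotations(file.path(root, row$annotation_path)),
    patient_id = row$patient_id, exam_idx = row$exam_idx, side = row$side
  )
}

#' Count scored joint instances in a manifest
#'
#' Each hand image carries 16 erosion and 15 JSN target joints.
#' @param manifest Manifest data frame.
#' @return Named vector with elements `erosion` and `jsn`.
#' @export
count_joint_instances <- function(manifest) {
  n <- nrow(manifest)
  c(erosion = n * nrow(.erosion_joints), jsn = n * nrow(.jsn_joints))
}
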