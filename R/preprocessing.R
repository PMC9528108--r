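# Joint-window cropping and class-balancing geometric augmentation.
# Crops are taken on scale-normalized images with the joint-specific box
# sizes; left-hand crops are mirrored to right-hand orientation so one
# classifier serves both sides. Augmentation is purely geometric (small
# rotation, translation, isotropic scaling), matching radiographic reading
# conditions where intensity is calibrated but pose varies.

#' Geometric augmentation policy
#'
#' @param rotation Inclusive rotation range in degrees.
#' @param translation Inclusive per-axis translation range in pixels.
#' @param scale Inclusive isotropic scale range.
#' @param n_total Target total crop count after balancing (split evenly
#'   between the two classes; must be even).
#' @param seed Integer seed for parameter sampling.
#' @return Object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(rotation = c(-3, 3), translation = c(-5, 5),
                                scale = c(0.97, 1.03), n_total = 10000L,
                                seed = 1L) {
  if (n_total %% 2 != 0) stop("n_total must be even", call. = FALSE)
  structure(list(rotation = rotation, translation = translation,
                 scale = scale, n_total = as.integer(n_total),
                 seed = as.integer(seed)),
            class = "augmentation_policy")
}

new_joint_crop <- function(pixels, joint_id, name, assessment, side, label,
                           grade = NA_integer_, patient_id = NA_character_,
                           exam_idx = NA_integer_,
                           augmentation = "original") {
  structure(list(pixels = pixels, joint_id = joint_id, name = name,
                 assessment = assessment, side = side, label = label,
                 grade = grade, patient_id = patient_id, exam_idx = exam_idx,
                 augmentation = augmentation),
            class = "joint_crop")
}

#' Crop a joint window
#'
#' Extracts the joint-specific box (see [joint_box()]) centered on `center`
#' from a scale-normalized image, zero-padding outside the image. Left-hand
#' crops are mirrored to right-hand orientation.
#'
#' @param image Scale-normalized image matrix.
#' @param center Joint center `c(x, y)` (0-based, subpixel allowed).
#' @param name Joint site name.
#' @param side `"left"` or `"right"`.
#' @param label Optional `"intact"`/`"non-intact"` label.
#' @param assessment Assessment the crop belongs to.
#' @param grade,patient_id,exam_idx Provenance fields.
#' @return A `joint_crop` object.
#' @export
crop_joint <- function(image, center, name, side = "right", label = NA,
                       assessment = NA_character_, grade = NA_integer_,
                       patient_id = NA_character_, exam_idx = NA_integer_) {
  box <- joint_box(name)  # errors on unknown joint
  check_side(side)
  w <- box[["width"]]; h <- box[["height"]]
  a <- c(1, 0, center[1] - (w - 1) / 2,
         0, 1, center[2] - (h - 1) / 2)
  win <- cpp_warp_affine(image, a, as.integer(h), as.integer(w))
  if (side == "left") win <- mirror_image(win)
  new_joint_crop(win, paste(assessment, name, side, sep = "."), name,
                 assessment, side, label, grade, patient_id, exam_idx)
}

#' Apply a geometric augmentation to a crop
#'
#' Rotation about the window center, translation, isotropic scaling about
#' the center; bilinear interpolation, zero fill. The label and joint
#' identity never change; the augmentation record is populated.
#'
#' @param crop A `joint_crop`.
#' @param rotation Rotation in degrees.
#' @param translation Length-2 translation `c(dx, dy)` in pixels.
#' @param scale Isotropic scale factor.
#' @param policy Optional [augmentation_policy()]; when given, parameters
#'   outside its ranges are rejected.
#' @return The augmented `joint_crop`.
#' @export
augment_crop <- function(crop, rotation = 0, translation = c(0, 0),
                         scale = 1, policy = NULL) {
  stopifnot(inherits(crop, "joint_crop"))
  if (!is.null(policy)) {
    inr <- function(v, r) all(v >= r[1] - 1e-9 & v <= r[2] + 1e-9)
    if (!inr(rotation, policy$rotation) ||
        !inr(translation, policy$translation) ||
        !inr(scale, policy$scale)) {
      stop("augmentation parameters outside policy ranges", call. = FALSE)
    }
  }
  img <- crop$pixels
  h <- nrow(img); w <- ncol(img)
  C <- c((w - 1) / 2, (h - 1) / 2)
  th <- deg2rad(rotation)
  # output pixel p samples input at C + R(-th) ((p - C - t) / s)
  ct <- cos(th); st <- sin(th)
  a11 <- ct / scale; a12 <- st / scale
  a21 <- -st / scale; a22 <- ct / scale
  ox <- C[1] - a11 * (C[1] + translation[1]) - a12 * (C[2] + translation[2])
  oy <- C[2] - a21 * (C[1] + translation[1]) - a22 * (C[2] + translation[2])
  out <- cpp_warp_affine(img, c(a11, a12, ox, a21, a22, oy), h, w)
  crop$pixels <- out
  crop$augmentation <- list(rotation = rotation, translation = translation,
                            scale = scale,
                            parent = if (is.character(crop$augmentation))
                              "original" else "augmented")
  crop
}

sample_aug_params <- function(policy) {
  list(rotation = runif(1, policy$rotation[1], policy$rotation[2]),
       translation = runif(2, policy$translation[1], policy$translation[2]),
       scale = runif(1, policy$scale[1], policy$scale[2]))
}

crop_labels <- function(crops) {
  vapply(crops, function(cr) cr$label, character(1))
}

#' Balance a crop set by augmentation
#'
#' Returns exactly `n_total / 2` crops per class: all originals are
#' retained and the remainder is filled with freshly augmented copies,
#' sampled round-robin over the originals of the class that needs more.
#' Deterministic under the policy seed.
#'
#' @param crops List of labeled `joint_crop` objects.
#' @param policy An [augmentation_policy()].
#' @return List of `joint_crop` objects, `n_total / 2` per class.
#' @export
balance_dataset <- function(crops, policy) {
  stopifnot(inherits(policy, "augmentation_policy"))
  labels <- crop_labels(crops)
  target <- policy$n_total / 2
  out <- list()
  with_seed(policy$seed, {
    for (cls in c("intact", "non-intact")) {
      idx <- which(labels == cls)
      if (length(idx) == 0L) {
        stop("cannot balance: no originals of class '", cls, "'",
             call. = FALSE)
      }
      if (length(idx) > target) {
        stop("class '", cls, "' has more originals (", length(idx),
             ") than the per-class target (", target,
             "); increase n_total", call. = FALSE)
      }
      out <- c(out, crops[idx])
      need <- target - length(idx)
      if (need > 0) {
        src <- rep(idx, length.out = need)  # round-robin over originals
        for (s in src) {
          p <- sample_aug_params(policy)
          out[[length(out) + 1L]] <-
            augment_crop(crops[[s]], p$rotation, p$translation, p$scale,
                         policy = policy)
        }
      }
    }
  })
  out
}

#' Crop all target joints of one hand
#'
#' Scale-normalizes the image using the supplied centers and crops every
#' target joint of the assessment. Centers flagged `discarded` (failed
#' detection) are skipped.
#'
#' @param image Raw hand image.
#' @param centers Data frame `name`, `x`, `y` (ground truth or detections)
#'   including the MCP2-5 / PIP2-5 centers needed for normalization;
#'   optional logical column `discarded`.
#' @param annotations Ground-truth annotation data frame supplying labels.
#' @param assessment,side,patient_id,exam_idx Provenance.
#' @param L_ref Scale-normalization reference length.
#' @return List of `joint_crop` objects.
#' @export
crop_hand <- function(image, centers, annotations, assessment, side,
                      patient_id = NA_character_, exam_idx = NA_integer_,
                      L_ref = 100) {
  sn <- scale_normalize(image, centers, L_ref = L_ref)
  tj <- target_joints(assessment, side)
  ann <- annotations[annotations$assessment == assessment, ]
  out <- list()
  for (nm in tj$name) {
    ctr <- sn$centers[sn$centers$name == nm, ][1, ]
    if (!is.null(ctr$discarded) && isTRUE(ctr$discarded)) next
    a <- ann[ann$name == nm, ][1, ]
    out[[length(out) + 1L]] <- crop_joint(
      sn$image, c(ctr$x, ctr$y), nm, side = side, label = a$label,
      assessment = assessment, grade = a$grade,
      patient_id = patient_id, exam_idx = exam_idx
    )
  }
  out
}

#' Resample a crop to the classifier input size
#'
#' @param crop A `joint_crop`.
#' @param side_px Output square side in pixels.
#' @return The crop with resampled pixels.
#' @export
crop_to_input <- function(crop, side_px) {
  crop$pixels <- resize_image(crop$pixels, side_px, side_px)
  crop
}
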