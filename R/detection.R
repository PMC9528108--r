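# Keypoint detection by heatmap regression. One detector per assessment:
# a small fully convolutional encoder-decoder predicts one Gaussian
# scoremap per target joint; joint centers are read off as per-channel
# argmaxes with quadratic subpixel refinement. Left hands are mirrored to
# right-hand orientation before detection and the result mirrored back, so
# a single side-agnostic channel set covers both hands.

#' Detector configuration
#'
#' @param assessment `"erosion"` or `"jsn"`; fixes the output channel set
#'   (16 or 15 joints, canonical order).
#' @param input_size Square side the image is resized to before the network
#'   (must be divisible by 4).
#' @param sigma Standard deviation of the target Gaussian heatmaps, in
#'   input-resolution pixels.
#' @param width Base channel width of the encoder.
#' @param lr Adam learning rate.
#' @param max_epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param peak_weight Loss up-weighting of heatmap peaks: pixel weight is
#'   `1 + peak_weight * target`, preventing collapse onto the all-background
#'   solution that plain MSE favours on sparse scoremaps.
#' @param seed Integer seed (weights, shuffling).
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(assessment, input_size = 256, sigma = 2,
                            width = 16, lr = 3e-3, max_epochs = 150,
                            batch_size = 8, peak_weight = 30, seed = 1L) {
  check_assessment(assessment)
  if (input_size %% 4 != 0) stop("input_size must be divisible by 4", call. = FALSE)
  structure(list(
    assessment = assessment, input_size = as.integer(input_size),
    sigma = sigma, width = as.integer(width), lr = lr,
    max_epochs = as.integer(max_epochs), batch_size = as.integer(batch_size),
    peak_weight = peak_weight,
    n_joints = nrow(target_joints(assessment, "right")),
    seed = as.integer(seed)
  ), class = "detector_config")
}

#' Build target heatmaps for one annotated image
#'
#' Channel `c` is `exp(-d^2 / (2 sigma^2))` of the distance to joint `c`'s
#' center, so the continuous maximum is 1 at the center. Channels follow
#' the canonical joint order of the assessment.
#'
#' @param annotations Data frame with columns `name`, `x`, `y` in
#'   heatmap-resolution coordinates; must contain every target joint of the
#'   assessment exactly once.
#' @param sigma Gaussian standard deviation in pixels.
#' @param size Heatmap side in pixels.
#' @param assessment `"erosion"` or `"jsn"`.
#' @return Array `(size, size, n_joints)`.
#' @export
make_target_heatmaps <- function(annotations, sigma, size, assessment) {
  tj <- target_joints(assessment, "right")
  cnt <- table(annotations$name)[tj$name]
  cnt[is.na(cnt)] <- 0
  if (any(cnt != 1)) {
    bad <- tj$name[cnt != 1]
    stop("annotations must contain each target joint exactly once; bad: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  xs <- 0:(size - 1)
  X <- matrix(xs, size, size, byrow = TRUE)
  Y <- matrix(xs, size, size)
  hm <- array(0, dim = c(size, size, nrow(tj)))
  for (j in seq_len(nrow(tj))) {
    a <- annotations[annotations$name == tj$name[j], ]
    hm[, , j] <- exp(-((X - a$x)^2 + (Y - a$y)^2) / (2 * sigma^2))
  }
  hm
}

build_detector_net <- function(config) {
  w <- config$width
  J <- config$n_joints
  list(
    layer_conv(3, 3, 1, w), layer_relu(),
    layer_pool(),
    layer_conv(3, 3, w, 2 * w), layer_relu(),
    layer_pool(),
    layer_conv(3, 3, 2 * w, 2 * w), layer_relu(),
    layer_conv(3, 3, 2 * w, 2 * w), layer_relu(),
    layer_conv(3, 3, 2 * w, 2 * w), layer_relu(),
    layer_upsample(),
    layer_conv(3, 3, 2 * w, w), layer_relu(),
    layer_upsample(),
    layer_conv(3, 3, w, w), layer_relu(),
    layer_conv(1, 1, w, J, pad = 0L)
  )
}

# Prepare one training sample: mirror left hands, resize to the network
# input, rescale annotation coordinates.
prep_detection_sample <- function(image, annotations, side, config) {
  S <- nrow(image)
  if (side == "left") {
    image <- mirror_image(image)
    annotations$x <- mirror_x(annotations$x, ncol(image))
  }
  inS <- config$input_size
  img <- resize_image(image, inS, inS)
  ann <- annotations[annotations$assessment == config$assessment, , drop = FALSE]
  ann$x <- rescale_coords(ann$x, S, inS)
  ann$y <- rescale_coords(ann$y, S, inS)
  list(image = img, annotations = ann)
}

#' Train a joint detector
#'
#' Minimizes mean squared heatmap error with Adam. Deterministic under the
#' config seed.
#'
#' @param hands List of training hands, each a list with elements `image`
#'   (matrix), `annotations` (data frame with `assessment`, `name`, `x`,
#'   `y` in original-image coordinates) and `side`.
#' @param config A [detector_config()].
#' @return Object of class `shs_detector` with the trained layers, the
#'   config, the per-epoch training-loss history and the taxonomy hash.
#' @export
train_detector <- function(hands, config) {
  stopifnot(inherits(config, "detector_config"))
  if (length(hands) < 2) stop("need at least 2 annotated images", call. = FALSE)
  inS <- config$input_size
  n <- length(hands)
  x <- array(0, dim = c(n, inS, inS, 1))
  yt <- array(0, dim = c(n, inS, inS, config$n_joints))
  for (i in seq_len(n)) {
    h <- hands[[i]]
    ps <- prep_detection_sample(h$image, h$annotations, h$side, config)
    if (nrow(ps$annotations) != config$n_joints) {
      stop("image ", i, " does not carry the full ", config$assessment,
           " joint set", call. = FALSE)
    }
    x[i, , , 1] <- ps$image
    yt[i, , , ] <- make_target_heatmaps(ps$annotations, config$sigma, inS,
                                        config$assessment)
  }

  with_seed(config$seed, {
    layers <- build_detector_net(config)
    state <- adam_init(layers)
    losses <- numeric(config$max_epochs)
    t <- 0
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(n)
      ep_loss <- 0
      nb <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        xb <- x[idx, , , , drop = FALSE]
        yb <- yt[idx, , , , drop = FALSE]
        fw <- seq_forward(layers, xb, train = TRUE)
        ls <- mse_loss(fw$out, yb, peak_weight = config$peak_weight)
        bw <- seq_backward(layers, fw$caches, ls$grad)
        t <- t + 1
        upd <- adam_update(layers, bw$grads, state, config$lr, t)
        layers <- upd$layers
        state <- upd$state
        ep_loss <- ep_loss + ls$loss
        nb <- nb + 1
      }
      losses[epoch] <- ep_loss / nb
    }
    structure(list(layers = layers, config = config, loss_history = losses,
                   taxonomy = taxonomy_hash()),
              class = "shs_detector")
  })
}

#' Read peaks off a heatmap stack
#'
#' Per-channel argmax (ties broken toward the lowest y, then lowest x) with
#' quadratic 3x3 subpixel refinement; confidence is the peak value clipped
#' to `[0, 1]`.
#'
#' @param hm Array `(H, W, C)`.
#' @return Data frame with columns `channel`, `x`, `y`, `confidence`
#'   (0-based heatmap coordinates).
#' @export
heatmap_peaks <- function(hm) {
  d <- dim(hm)
  out <- lapply(seq_len(d[3]), function(ch) {
    m <- hm[, , ch]
    mx <- max(m)
    pos <- which(m == mx, arr.ind = TRUE)  # (row=y+1, col=x+1)
    pos <- pos[order(pos[, 1], pos[, 2]), , drop = FALSE]
    iy <- pos[1, 1]; ix <- pos[1, 2]
    x <- ix - 1; y <- iy - 1
    refine <- function(fm1, f0, fp1) {
      den <- fm1 - 2 * f0 + fp1
      if (abs(den) < 1e-12) return(0)
      max(-0.5, min(0.5, 0.5 * (fm1 - fp1) / den))
    }
    if (ix > 1 && ix < d[2]) x <- x + refine(m[iy, ix - 1], m[iy, ix], m[iy, ix + 1])
    if (iy > 1 && iy < d[1]) y <- y + refine(m[iy - 1, ix], m[iy, ix], m[iy + 1, ix])
    data.frame(channel = ch, x = x, y = y,
               confidence = min(max(mx, 0), 1))
  })
  do.call(rbind, out)
}

#' Detect target joints on a hand image
#'
#' Always returns exactly one detection per target joint; low confidence
#' flags uncertainty rather than suppressing output.
#'
#' @param model A trained [train_detector()] model.
#' @param image Hand image matrix.
#' @param side `"left"` or `"right"` (left hands are mirrored internally).
#' @return Data frame with `joint_id`, `name`, `x`, `y`, `confidence` in
#'   original-image coordinates.
#' @export
detect <- function(model, image, side = "right") {
  stopifnot(inherits(model, "shs_detector"))
  if (model$taxonomy != taxonomy_hash()) {
    stop("model was trained under a different joint taxonomy", call. = FALSE)
  }
  check_side(side)
  cfg <- model$config
  S <- nrow(image)
  img <- if (side == "left") mirror_image(image) else image
  inS <- cfg$input_size
  xin <- array(resize_image(img, inS, inS), dim = c(1, inS, inS, 1))
  hm <- seq_forward(model$layers, xin)$out
  hm <- array(hm[1, , , ], dim = dim(hm)[2:4])
  pk <- heatmap_peaks(hm)
  tj <- target_joints(cfg$assessment, side)
  x <- rescale_coords(pk$x, inS, ncol(image))
  y <- rescale_coords(pk$y, inS, S)
  if (side == "left") x <- mirror_x(x, ncol(image))
  data.frame(joint_id = tj$joint_id, name = tj$name, x = x, y = y,
             confidence = pk$confidence, stringsAsFactors = FALSE)
}

#' Scale-normalize a hand image by proximal-phalanx length
#'
#' Computes the four proximal-phalanx lengths as the Euclidean distances
#' between the MCP and PIP centers of fingers 2-5, takes their median
#' (even-count convention: mean of the two middle values), and rescales the
#' image so the median matches the package reference length.
#'
#' @param image Image matrix.
#' @param centers Data frame with columns `name`, `x`, `y` containing
#'   `mcp2`..`mcp5` and `pip2`..`pip5` (ground truth or detections).
#' @param L_ref Reference proximal-phalanx length in pixels.
#' @return List with `image` (resampled), `scale` (the applied factor) and
#'   `centers` (all input centers mapped to the new resolution).
#' @export
scale_normalize <- function(image, centers, L_ref = 100) {
  need <- c(paste0("mcp", 2:5), paste0("pip", 2:5))
  if (!all(need %in% centers$name)) {
    stop("centers must include ", paste(setdiff(need, centers$name),
                                        collapse = ", "), call. = FALSE)
  }
  at <- function(nm) {
    r <- centers[centers$name == nm, ][1, ]
    c(r$x, r$y)
  }
  lengths <- vapply(2:5, function(d) {
    norm2(at(paste0("mcp", d)) - at(paste0("pip", d)))
  }, numeric(1))
  scale <- L_ref / median(lengths)
  out_h <- max(1L, round(nrow(image) * scale))
  out_w <- max(1L, round(ncol(image) * scale))
  img <- resize_image(image, out_h, out_w)
  centers$x <- rescale_coords(centers$x, ncol(image), out_w)
  centers$y <- rescale_coords(centers$y, nrow(image), out_h)
  list(image = img, scale = scale, centers = centers)
}

#' Evaluate detections against ground truth
#'
#' A detection is correct when the ground-truth center lies inside the
#' joint-specific box centered on the detected point (250 x 250 for
#' PIP/IP/MCP/CMC-M, 500 x 300 for the radius, 300 x 300 otherwise, at
#' scale-normalized resolution). Incorrect detections are flagged
#' `discarded` for downstream stages. Distance error is the Euclidean
#' detected-to-truth distance; per-class stratification uses the binarized
#' ground-truth label.
#'
#' @param detections Data frame `name`, `x`, `y` (scale-normalized).
#' @param truth Data frame `name`, `x`, `y`, `label` (and optionally
#'   `group`), same coordinates.
#' @param assessment `"erosion"` or `"jsn"`.
#' @return Object of class `shs_detection_eval`: `per_joint` (one row per
#'   joint with `correct`, `discarded`, `dist`) and `summary` (per group
#'   and overall, per class and total: counts, rates, distance mean/sd).
#' @export
evaluate_detection <- function(detections, truth, assessment) {
  tj <- target_joints(assessment, "right")
  if (!setequal(detections$name, tj$name) || !setequal(truth$name, tj$name)) {
    stop("detections and truth must cover exactly the ", assessment,
         " joint set", call. = FALSE)
  }
  m <- merge(detections[, c("name", "x", "y")],
             truth[, c("name", "x", "y", "label")],
             by = "name", suffixes = c("_det", "_gt"))
  m$group <- joint_group(assessment, m$name)
  box <- t(vapply(m$name, joint_box, numeric(2)))
  m$correct <- abs(m$x_gt - m$x_det) <= box[, 1] / 2 &
    abs(m$y_gt - m$y_det) <= box[, 2] / 2
  m$discarded <- !m$correct
  m$dist <- sqrt((m$x_gt - m$x_det)^2 + (m$y_gt - m$y_det)^2)

  structure(list(per_joint = m,
                 summary = pool_detection_summary(m, assessment),
                 assessment = assessment),
            class = "shs_detection_eval")
}

#' Train/evaluate a detector on a phantom manifest
#'
#' Convenience wrapper: trains on the first `n_train` manifest rows and
#' evaluates on the remaining rows (or a supplied subset). Evaluation
#' follows the standard procedure: detect on the raw image, scale-normalize
#' by the detected proximal phalanges, and compare against the equally
#' normalized ground truth.
#'
#' @param manifest Dataset manifest (with `root` attribute).
#' @param config A [detector_config()].
#' @param train_idx,test_idx Row indices into the manifest.
#' @param L_ref Scale-normalization reference length.
#' @return List with `model`, `eval` (pooled [evaluate_detection()] report)
#'   and `per_image` evaluations.
#' @export
run_detection_experiment <- function(manifest, config, train_idx, test_idx,
                                     L_ref = 100) {
  hands <- lapply(train_idx, function(i) {
    h <- load_hand(manifest, i)
    list(image = h$image, annotations = h$annotations, side = h$side)
  })
  model <- train_detector(hands, config)

  per_image <- lapply(test_idx, function(i) {
    h <- load_hand(manifest, i)
    det <- detect(model, h$image, h$side)
    sn <- scale_normalize(h$image, det, L_ref = L_ref)
    gt <- h$annotations[h$annotations$assessment == config$assessment, ]
    gt$x <- rescale_coords(gt$x, ncol(h$image), ncol(sn$image))
    gt$y <- rescale_coords(gt$y, nrow(h$image), nrow(sn$image))
    evaluate_detection(sn$centers, gt, config$assessment)
  })
  pooled <- do.call(rbind, lapply(per_image, function(e) e$per_joint))
  # rebuild the pooled report from the concatenated per-joint table
  ev <- list(per_joint = pooled,
             summary = pool_detection_summary(pooled, config$assessment),
             assessment = config$assessment)
  class(ev) <- "shs_detection_eval"
  list(model = model, eval = ev, per_image = per_image)
}

pool_detection_summary <- function(m, assessment) {
  tj <- target_joints(assessment, "right")
  strata <- c(unique(tj$group), "All joints")
  rows <- list()
  for (g in strata) {
    sub <- if (g == "All joints") m else m[m$group == g, , drop = FALSE]
    for (cls in c("intact", "non-intact", "total")) {
      s2 <- if (cls == "total") sub else sub[sub$label == cls, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, class = cls, n = nrow(s2),
        n_correct = sum(s2$correct),
        rate = if (nrow(s2)) sum(s2$correct) / nrow(s2) else NA_real_,
        dist_mean = if (nrow(s2)) mean(s2$dist) else NA_real_,
        dist_sd = if (nrow(s2) > 1) sd(s2$dist) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
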