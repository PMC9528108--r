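# Synthetic hand-phantom generator. Renders stylized single-hand
# "radiographs" (bright bones on a dark background, additive noise) whose
# joint centers are known analytically, with per-joint destruction states
# drawn from a latent-Gaussian model that gives independently tunable
# bilateral, within-group and patient-level label correlation at exact
# marginal prevalence. Erosion is rendered as a marginal notch at the bone
# end; joint space narrowing (JSN) shrinks the local inter-bone gap.

#' Phantom generator configuration
#'
#' @param image_size Square image side in pixels.
#' @param gap Nominal joint-space gap g0 in pixels; a JSN grade k shrinks a
#'   joint's gap to `g0 * (1 - k/4)`.
#' @param prox_phalanx_len Middle-finger proximal phalanx length in pixels;
#'   other bones scale proportionally. The default makes the median
#'   proximal-phalanx length approximately the scale-normalization
#'   reference, so the standard crop-box sizes are meaningful fractions of
#'   the hand.
#' @param bone_width Reference bone half-width in pixels.
#' @param prevalence Per-group non-intact probability. Either a single
#'   number, or a list with elements `erosion` and `jsn`, each a named
#'   vector over that assessment's groups. Defaults are the per-group
#'   non-intact rates of a 40-patient clinical cohort of 226 hand
#'   radiographs.
#' @param rho_sym Bilateral (contralateral-pair) latent correlation share.
#' @param rho_grp Within-group, hand-agnostic latent correlation share.
#' @param rho_pat Patient-severity latent correlation share.
#'   `rho_sym + rho_grp + rho_pat` must not exceed 1; the remainder is
#'   joint-specific noise variance.
#' @param noise_sd Additive pixel noise standard deviation (intensity units,
#'   images live in `[0, 1]`).
#' @param contrast Visibility of the destruction signature: 0 renders
#'   destruction invisibly, 1 at full amplitude.
#' @param mimic_rate Probability that an intact erosion site carries a
#'   benign cortical margin irregularity visually similar to a mild
#'   erosion. Mimics occur independently on each hand, whereas true
#'   destruction is bilaterally correlated, so they make single-view
#'   classification of mild disease genuinely ambiguous — the regime in
#'   which contextual (contralateral) reading is known to help.
#' @param ulnar_drift Ulnar-drift severity in `[0, 1]`: severely damaged
#'   hands get their finger rays rotated ulnarly by up to 18 degrees.
#' @param grade_step Latent-exceedance width mapped to one grade step.
#' @param jitter_scale,jitter_shift,jitter_rot,jitter_finger Per-image
#'   geometric variability: global scale (multiplicative half-range),
#'   translation (fraction of image), rotation (degrees, half-range) and
#'   per-finger length jitter (multiplicative half-range).
#' @param seed Integer seed making dataset generation fully reproducible.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 768,
                           gap = round(0.012 * image_size),
                           prox_phalanx_len = 0.138 * image_size,
                           bone_width = 0.016 * image_size,
                           prevalence = NULL,
                           rho_sym = 0.5,
                           rho_grp = 0.2,
                           rho_pat = 0.15,
                           noise_sd = 0.05,
                           contrast = 1,
                           mimic_rate = 0.25,
                           ulnar_drift = 0,
                           grade_step = 0.6,
                           jitter_scale = 0.06,
                           jitter_shift = 0.025,
                           jitter_rot = 5,
                           jitter_finger = 0.05,
                           seed = NULL) {
  if (rho_sym < 0 || rho_grp < 0 || rho_pat < 0 ||
      rho_sym + rho_grp + rho_pat > 1 + 1e-12) {
    stop("latent variance shares must be non-negative and sum to at most 1",
         call. = FALSE)
  }
  if (mimic_rate < 0 || mimic_rate > 1) {
    stop("mimic_rate must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(prevalence)) prevalence <- default_prevalence()
  prevalence <- resolve_prevalence(prevalence)
  pv <- unlist(prevalence)
  if (any(pv < 0 | pv > 1)) stop("prevalences must lie in [0, 1]", call. = FALSE)
  structure(list(
    image_size = as.integer(image_size), gap = gap,
    prox_phalanx_len = prox_phalanx_len, bone_width = bone_width,
    prevalence = prevalence,
    rho_sym = rho_sym, rho_grp = rho_grp, rho_pat = rho_pat,
    noise_sd = noise_sd, contrast = contrast, mimic_rate = mimic_rate,
    ulnar_drift = ulnar_drift,
    grade_step = grade_step,
    jitter_scale = jitter_scale, jitter_shift = jitter_shift,
    jitter_rot = jitter_rot, jitter_finger = jitter_finger,
    seed = seed
  ), class = "phantom_config")
}

# Per-group non-intact rates observed in a 40-patient / 226-radiograph
# cohort (instance counts per group: erosion 125/1130, 143/1130, 131/452,
# 470/904; JSN 342/904, 254/1130, 350/678, 461/678).
default_prevalence <- function() {
  list(
    erosion = c("PIP-IP" = 125 / 1130, "MCP" = 143 / 1130,
                "CMC-M" = 131 / 452, "Wrist" = 470 / 904),
    jsn = c("PIP" = 342 / 904, "MCP" = 254 / 1130,
            "CMC" = 350 / 678, "Wrist" = 461 / 678)
  )
}

resolve_prevalence <- function(prevalence) {
  groups <- list(erosion = unique(.erosion_joints$group),
                 jsn = unique(.jsn_joints$group))
  if (is.numeric(prevalence) && length(prevalence) == 1L) {
    return(lapply(groups, function(g) setNames(rep(prevalence, length(g)), g)))
  }
  stopifnot(is.list(prevalence), all(c("erosion", "jsn") %in% names(prevalence)))
  out <- list()
  for (a in c("erosion", "jsn")) {
    p <- prevalence[[a]]
    if (length(p) == 1L && is.null(names(p))) {
      p <- setNames(rep(p, length(groups[[a]])), groups[[a]])
    }
    if (!all(groups[[a]] %in% names(p))) {
      stop("prevalence for ", a, " must name groups ",
           paste(groups[[a]], collapse = ", "), call. = FALSE)
    }
    out[[a]] <- p[groups[[a]]]
  }
  out
}

#' Sample correlated per-joint destruction states
#'
#' Latent-Gaussian threshold model. Each joint instance gets a latent score
#' \deqn{z = \sqrt{\rho_{pat}} U + \sqrt{\rho_{grp}} G + \sqrt{\rho_{sym}} S
#'        + \sqrt{1-\rho_{pat}-\rho_{grp}-\rho_{sym}}\,\epsilon}
#' with independent standard-normal components: `U` per patient, `G` per
#' patient x assessment-group (hand-agnostic), `S` per patient x joint name
#' (shared by the two hands), and `epsilon` per joint instance. The grade is
#' 0 when `z` falls below the `1 - p_g` normal quantile of the joint's group
#' prevalence, and otherwise grows with the exceedance in steps of
#' `grade_step`, capped at the top of the grade scale.
#'
#' @param config A [phantom_config()].
#' @param n_patients Number of patients.
#' @param exams_per_patient Single count or per-patient vector of visits.
#' @return Data frame with one row per (patient, exam, side, assessment,
#'   joint): columns `patient_id`, `exam_idx`, `side`, `assessment`,
#'   `name`, `group`, `grade`, `label`.
#' @export
sample_destruction_states <- function(config, n_patients,
                                      exams_per_patient = 1L) {
  stopifnot(inherits(config, "phantom_config"), n_patients >= 1)
  if (length(exams_per_patient) == 1L) {
    exams_per_patient <- rep(as.integer(exams_per_patient), n_patients)
  }
  stopifnot(length(exams_per_patient) == n_patients, all(exams_per_patient >= 1))
  with_seed(config$seed, sample_states_impl(config, n_patients, exams_per_patient))
}

sample_states_impl <- function(config, n_patients, exams_per_patient) {
  rp <- config$rho_pat; rg <- config$rho_grp; rs <- config$rho_sym
  re <- 1 - rp - rg - rs
  pid <- sprintf("P%03d", seq_len(n_patients))

  tax <- rbind(
    target_joints("erosion", "right")[, c("assessment", "name", "group")],
    target_joints("jsn", "right")[, c("assessment", "name", "group")]
  )
  n_j <- nrow(tax)  # 31 scored sites per hand
  grp_key <- paste(tax$assessment, tax$group)
  grp_levels <- unique(grp_key)

  U <- rnorm(n_patients)
  G <- matrix(rnorm(n_patients * length(grp_levels)), n_patients,
              dimnames = list(pid, grp_levels))
  S <- matrix(rnorm(n_patients * n_j), n_patients, n_j)

  rows <- vector("list", sum(exams_per_patient) * 2L)
  k <- 0L
  for (p in seq_len(n_patients)) {
    for (e in seq_len(exams_per_patient[p])) {
      for (side in c("right", "left")) {
        eps <- rnorm(n_j)
        z <- sqrt(rp) * U[p] + sqrt(rg) * G[p, grp_key] +
          sqrt(rs) * S[p, ] + sqrt(re) * eps
        p_g <- vapply(seq_len(n_j), function(j) {
          config$prevalence[[tax$assessment[j]]][[tax$group[j]]]
        }, numeric(1))
        thr <- qnorm(1 - p_g)
        maxg <- ifelse(tax$assessment == "erosion", 5L, 4L)
        grade <- ifelse(z < thr, 0L,
                        1L + pmin(floor((z - thr) / config$grade_step), maxg - 1L))
        k <- k + 1L
        rows[[k]] <- data.frame(
          patient_id = pid[p], exam_idx = e, side = side,
          assessment = tax$assessment, name = tax$name, group = tax$group,
          grade = as.integer(grade),
          label = ifelse(grade == 0, "intact", "non-intact"),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- Skeleton geometry -----------------------------------------------------
# Base layout of a right hand (thumb at low x) in normalized coordinates,
# x rightward, y downward, hand occupying roughly [0.25, 0.75] x [0.3, 0.9].

hand_layout <- function() {
  list(
    mcp = list(c(0.300, 0.615), c(0.400, 0.470), c(0.500, 0.440),
               c(0.600, 0.465), c(0.690, 0.510)),
    base = list(c(0.372, 0.695), c(0.450, 0.655), c(0.500, 0.650),
                c(0.565, 0.655), c(0.630, 0.665)),
    finger_angle = c(-40, -6, 0, 7, 14),   # degrees from vertical, + = ulnar
    prox_len = c(0.085, 0.125, 0.140, 0.130, 0.100),
    mid_frac = 0.62, dist_frac = 0.45, thumb_dist_len = 0.070,
    phalanx_hw = c(0.020, 0.016, 0.017, 0.016, 0.014),
    meta_hw = c(0.020, 0.018, 0.018, 0.016, 0.015),
    trapezium = list(c = c(0.405, 0.730), r = 0.027),
    navicular = list(c = c(0.465, 0.765), r = 0.032),
    lunate    = list(c = c(0.545, 0.770), r = 0.028),
    capitate  = list(c = c(0.520, 0.715), r = 0.033),
    radius = list(end = c(0.470, 0.845), far = c(0.440, 1.050), hw = 0.050),
    ulna   = list(end = c(0.615, 0.850), far = c(0.640, 1.050), hw = 0.032)
  )
}

deg2rad <- function(d) d * pi / 180
unitv <- function(a_deg) c(sin(deg2rad(a_deg)), -cos(deg2rad(a_deg)))
norm2 <- function(v) sqrt(sum(v^2))

# Build the full right-hand skeleton: bone capsules and analytic joint
# centers, in normalized coordinates. `jsn_gap` is a named vector of gap
# lengths (normalized units) for the JSN joints; other articulations use g0.
build_skeleton <- function(config, finger_len = rep(1, 5), drift_deg = 0,
                           jsn_gap = NULL) {
  L <- hand_layout()
  S <- config$image_size
  len_scale <- config$prox_phalanx_len / (0.140 * S)
  wid_scale <- config$bone_width / (0.016 * S)
  g0 <- config$gap / S

  gap_of <- function(joint) {
    if (!is.null(jsn_gap) && joint %in% names(jsn_gap)) jsn_gap[[joint]] else g0
  }

  ang <- L$finger_angle + c(0.3, 1, 1, 1, 1) * drift_deg
  u <- lapply(ang, unitv)
  Lp <- L$prox_len * len_scale * finger_len
  hw <- L$phalanx_hw * wid_scale
  mhw <- L$meta_hw * wid_scale

  bones <- list()
  joints <- list()
  axes <- list()
  add_bone <- function(p1, p2, w) bones[[length(bones) + 1L]] <<- list(p1 = p1, p2 = p2, w = w)

  mcp <- L$mcp
  # distal-joint centers of the finger rays
  pipc <- lapply(1:5, function(d) mcp[[d]] + u[[d]] * Lp[d])
  for (d in 1:5) {
    jn_mcp <- paste0("mcp", d)
    g_mcp <- gap_of(jn_mcp)
    joints[[jn_mcp]] <- mcp[[d]]
    axes[[jn_mcp]] <- ang[d]
    if (d == 1) {
      joints[["ip1"]] <- pipc[[1]]
      axes[["ip1"]] <- ang[1]
      g_ip <- gap_of("ip1")
      add_bone(mcp[[1]] + u[[1]] * (g_mcp / 2 + hw[1]),
               pipc[[1]] - u[[1]] * (g_ip / 2 + hw[1]), hw[1])
      tip <- pipc[[1]] + u[[1]] * L$thumb_dist_len * len_scale
      add_bone(pipc[[1]] + u[[1]] * (g_ip / 2 + hw[1] * 0.9),
               tip, hw[1] * 0.9)
    } else {
      jn_pip <- paste0("pip", d)
      g_pip <- gap_of(jn_pip)
      joints[[jn_pip]] <- pipc[[d]]
      axes[[jn_pip]] <- ang[d]
      add_bone(mcp[[d]] + u[[d]] * (g_mcp / 2 + hw[d]),
               pipc[[d]] - u[[d]] * (g_pip / 2 + hw[d]), hw[d])
      dip <- pipc[[d]] + u[[d]] * Lp[d] * L$mid_frac
      add_bone(pipc[[d]] + u[[d]] * (g_pip / 2 + hw[d] * 0.85),
               dip - u[[d]] * (g0 / 2 + hw[d] * 0.85), hw[d] * 0.85)
      tip <- dip + u[[d]] * Lp[d] * L$dist_frac
      add_bone(dip + u[[d]] * (g0 / 2 + hw[d] * 0.7), tip, hw[d] * 0.7)
    }
  }

  # metacarpals; CMC articulations for rays 1 (erosion target) and 3-5 (JSN)
  for (d in 1:5) {
    b <- L$base[[d]]
    v <- (mcp[[d]] - b); v <- v / norm2(v)
    g_mcp <- gap_of(paste0("mcp", d))
    distal <- mcp[[d]] - v * (g_mcp / 2 + mhw[d])
    if (d == 1) {
      trap <- L$trapezium$c
      cmc1 <- (b + trap) / 2
      joints[["cmc1"]] <- cmc1
      axes[["cmc1"]] <- atan2(v[1], -v[2]) / pi * 180
      prox <- cmc1 + v * (gap_of("cmc1") / 2 + mhw[1])
    } else if (d >= 3) {
      jn <- paste0("cmc", d)
      cmc <- b + c(0, 0.015)
      joints[[jn]] <- cmc
      axes[[jn]] <- atan2(v[1], -v[2]) / pi * 180
      prox <- cmc + v * (gap_of(jn) / 2 + mhw[d])
    } else {
      prox <- b
    }
    add_bone(prox, distal, mhw[d])
  }

  # carpal blobs (zero-length capsules = discs)
  for (nm in c("trapezium", "navicular", "lunate", "capitate")) {
    blob <- L[[nm]]
    add_bone(blob$c, blob$c, blob$r * wid_scale)
  }
  joints[["multangular"]] <- L$trapezium$c
  joints[["navicular"]] <- L$navicular$c
  joints[["lunate"]] <- L$lunate$c
  axes[["multangular"]] <- NA_real_
  axes[["navicular"]] <- NA_real_
  axes[["lunate"]] <- NA_real_

  add_bone(L$radius$end + c(0, L$radius$hw * wid_scale * 0.2), L$radius$far,
           L$radius$hw * wid_scale)
  add_bone(L$ulna$end + c(0, L$ulna$hw * wid_scale * 0.2), L$ulna$far,
           L$ulna$hw * wid_scale)
  joints[["radius"]] <- L$radius$end
  joints[["ulna"]] <- L$ulna$end
  axes[["radius"]] <- NA_real_
  axes[["ulna"]] <- NA_real_

  # JSN wrist composite joints (between carpal blobs / radius)
  joints[["multangular_navicular"]] <-
    (L$trapezium$c + L$navicular$c) / 2
  joints[["capitate_navicular_lunate"]] <-
    (L$capitate$c + L$navicular$c + L$lunate$c) / 3
  joints[["radiocarpal"]] <-
    (L$radius$end + (L$navicular$c + L$lunate$c) / 2) / 2
  axes[["multangular_navicular"]] <- NA_real_
  axes[["capitate_navicular_lunate"]] <- NA_real_
  axes[["radiocarpal"]] <- NA_real_

  list(bones = bones, joints = joints, axes = axes)
}

# Apply a similarity transform (scale about center, rotate, shift) to the
# skeleton; widths scale with the global scale.
transform_skeleton <- function(sk, scale = 1, rot_deg = 0, shift = c(0, 0),
                               center = c(0.5, 0.62)) {
  th <- deg2rad(rot_deg)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  tp <- function(p) as.numeric(R %*% ((p - center) * scale)) + center + shift
  sk$bones <- lapply(sk$bones, function(b) {
    list(p1 = tp(b$p1), p2 = tp(b$p2), w = b$w * scale)
  })
  sk$joints <- lapply(sk$joints, tp)
  sk$axes <- lapply(sk$axes, function(a) if (is.na(a)) a else a + rot_deg)
  sk
}

# ---- Rasterization ---------------------------------------------------------

# Draw an anti-aliased filled capsule (p1, p2 in pixel coords, half-width w)
# by max-compositing; computes only within the capsule's bounding box.
draw_capsule <- function(img, p1, p2, w, intensity, aa = 1) {
  H <- nrow(img); W <- ncol(img)
  x0 <- max(1, floor(min(p1[1], p2[1]) - w - aa) + 1)
  x1 <- min(W, ceiling(max(p1[1], p2[1]) + w + aa) + 1)
  y0 <- max(1, floor(min(p1[2], p2[2]) - w - aa) + 1)
  y1 <- min(H, ceiling(max(p1[2], p2[2]) + w + aa) + 1)
  if (x0 > x1 || y0 > y1) return(img)
  xs <- (x0:x1) - 1; ys <- (y0:y1) - 1
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys, length(ys), length(xs))
  v <- p2 - p1
  L2 <- sum(v^2)
  if (L2 < 1e-12) {
    d <- sqrt((X - p1[1])^2 + (Y - p1[2])^2)
  } else {
    t <- pmin(pmax(((X - p1[1]) * v[1] + (Y - p1[2]) * v[2]) / L2, 0), 1)
    d <- sqrt((X - p1[1] - t * v[1])^2 + (Y - p1[2] - t * v[2])^2)
  }
  cov <- pmin(pmax((w - d) / aa + 0.5, 0), 1)
  img[y0:y1, x0:x1] <- pmax(img[y0:y1, x0:x1], intensity * cov)
  img
}

# Carve an anti-aliased disc out of the image (multiplicative darkening).
carve_disc <- function(img, center, r, depth, aa = 1) {
  H <- nrow(img); W <- ncol(img)
  x0 <- max(1, floor(center[1] - r - aa) + 1)
  x1 <- min(W, ceiling(center[1] + r + aa) + 1)
  y0 <- max(1, floor(center[2] - r - aa) + 1)
  y1 <- min(H, ceiling(center[2] + r + aa) + 1)
  if (x0 > x1 || y0 > y1) return(img)
  xs <- (x0:x1) - 1; ys <- (y0:y1) - 1
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys, length(ys), length(xs))
  d <- sqrt((X - center[1])^2 + (Y - center[2])^2)
  cov <- pmin(pmax((r - d) / aa + 0.5, 0), 1)
  img[y0:y1, x0:x1] <- img[y0:y1, x0:x1] * (1 - depth * cov)
  img
}

.bone_intensity <- 0.78
.background_intensity <- 0.08

#' Render one hand phantom
#'
#' Draws the hand skeleton as anti-aliased bright capsules on a dark
#' background and returns the analytic joint centers as the ground-truth
#' annotation. A JSN grade k shrinks the joint's gap to `g0 * (1 - k/4)`
#' (for the composite carpal joints the approximation of articulating
#' surfaces is rendered as a bridging blob); an erosion grade k carves a
#' marginal defect whose size grows with k and whose depth scales with the
#' configured contrast. Severely damaged hands acquire ulnar drift when the
#' configured drift severity is positive. Left hands are exact mirror
#' images of right-hand geometry.
#'
#' @param states Data frame with columns `assessment`, `name`, `grade` for
#'   one hand (as produced by [sample_destruction_states()] for one
#'   patient/exam/side).
#' @param side `"left"` or `"right"`.
#' @param config A [phantom_config()].
#' @param jitter Optional list with elements `scale`, `rot`, `shift`,
#'   `finger` overriding the per-image geometric jitter; by default jitter
#'   is drawn from the current RNG stream.
#' @return List with `image` (matrix in `[0,1]`) and `annotations` (data
#'   frame: `joint_id`, `assessment`, `name`, `group`, `x`, `y`, `axis`,
#'   `grade`, `label`; coordinates 0-based, x rightward, y downward).
#' @export
render_hand <- function(states, side, config, jitter = NULL) {
  check_side(side)
  stopifnot(all(c("assessment", "name", "grade") %in% names(states)))
  for (a in unique(states$assessment)) {
    g <- states$grade[states$assessment == a]
    if (any(!(g %in% grade_scale(a)))) {
      stop("grade outside the ", a, " scale", call. = FALSE)
    }
  }
  S <- config$image_size
  g0 <- config$gap / S

  if (is.null(jitter)) {
    jitter <- list(
      scale = runif(1, 1 - config$jitter_scale, 1 + config$jitter_scale),
      rot = runif(1, -config$jitter_rot, config$jitter_rot),
      shift = runif(2, -config$jitter_shift, config$jitter_shift),
      finger = runif(5, 1 - config$jitter_finger, 1 + config$jitter_finger)
    )
  }

  jsn <- states[states$assessment == "jsn", , drop = FALSE]
  ero <- states[states$assessment == "erosion", , drop = FALSE]
  jsn_grade <- setNames(jsn$grade, jsn$name)
  jsn_gap <- setNames(g0 * (1 - jsn_grade / 4), names(jsn_grade))

  mean_grade <- mean(states$grade)
  drift_deg <- config$ulnar_drift * 18 * min(1, mean_grade / 2)

  sk <- build_skeleton(config, finger_len = jitter$finger,
                       drift_deg = drift_deg, jsn_gap = jsn_gap)
  sk <- transform_skeleton(sk, scale = jitter$scale, rot_deg = jitter$rot,
                           shift = jitter$shift)

  img <- matrix(.background_intensity, S, S)
  for (b in sk$bones) {
    img <- draw_capsule(img, b$p1 * S, b$p2 * S, b$w * S, .bone_intensity)
  }

  # JSN approximation blobs at the composite carpal joints
  carpal_jsn <- c("multangular_navicular", "capitate_navicular_lunate",
                  "radiocarpal")
  for (jn in intersect(carpal_jsn, names(jsn_grade))) {
    k <- jsn_grade[[jn]]
    if (k > 0) {
      c_px <- sk$joints[[jn]] * S
      r <- 0.6 * (k / 4) * config$gap * jitter$scale + 1
      img <- draw_capsule(img, c_px, c_px, r,
                          .bone_intensity * config$contrast)
    }
  }

  # erosion notches: a marginal bite carved into the bone end adjacent to
  # the joint, centered on the cortical margin so roughly half the defect
  # disc removes bone
  wref <- config$bone_width * jitter$scale
  notch_at <- function(img, jn, size_mult, depth) {
    c_px <- sk$joints[[jn]] * S
    ax <- sk$axes[[jn]]
    r <- wref * size_mult
    if (is.na(ax)) {
      # bone-blob target: defect on the radial margin of the blob
      off <- c(-1, -0.3) / norm2(c(-1, -0.3)) * wref * 1.2
      pos <- c_px + off
    } else {
      u <- unitv(ax)
      lat <- c(-u[2], u[1])
      # corner of the proximal bone's end cap (45 degrees off-axis)
      pos <- c_px - u * (config$gap / 2 + wref * (1 - cos(pi / 4))) +
        lat * wref * sin(pi / 4)
    }
    carve_disc(img, pos, r, depth)
  }
  for (i in seq_len(nrow(ero))) {
    k <- ero$grade[i]
    if (k == 0) next
    img <- notch_at(img, ero$name[i], 0.55 + 0.25 * k,
                    config$contrast * min(1, 0.6 + 0.1 * k))
  }
  # benign margin irregularities: mild-erosion lookalikes on intact sites,
  # drawn independently per hand. Every joint consumes exactly three
  # uniform draws so the mimic pattern is invariant to the grades of the
  # other joints under a fixed seed.
  if (config$mimic_rate > 0 && nrow(ero) > 0) {
    for (i in seq_len(nrow(ero))) {
      u <- runif(3)
      if (ero$grade[i] > 0) next
      if (u[1] < config$mimic_rate) {
        img <- notch_at(img, ero$name[i],
                        0.80 * (0.8 + 0.35 * u[2]),
                        config$contrast * 0.7 * (0.8 + 0.3 * u[3]))
      }
    }
  }

  if (config$noise_sd > 0) {
    img <- img + matrix(rnorm(S * S, 0, config$noise_sd), S, S)
  }
  img <- clip01(img)

  # annotations for both assessments, in the canonical taxonomy order
  ann <- do.call(rbind, lapply(c("erosion", "jsn"), function(a) {
    tj <- target_joints(a, side)
    xy <- t(vapply(tj$name, function(nm) sk$joints[[nm]], numeric(2)))
    st <- states[states$assessment == a, , drop = FALSE]
    gr <- st$grade[match(tj$name, st$name)]
    data.frame(
      joint_id = tj$joint_id, assessment = a, name = tj$name,
      group = tj$group,
      x = xy[, 1] * S, y = xy[, 2] * S,
      axis = vapply(tj$name, function(nm) sk$axes[[nm]], numeric(1)),
      grade = gr, label = binarize_grade(gr, a),
      stringsAsFactors = FALSE
    )
  }))
  rownames(ann) <- NULL

  if (side == "left") {
    img <- mirror_image(img)
    ann$x <- mirror_x(ann$x, S)
    ann$axis <- -ann$axis
  }
  list(image = img, annotations = ann)
}

#' Measure a rendered joint gap
#'
#' Samples the intensity profile along the joint axis through the joint
#' center (bilinear interpolation, quarter-pixel steps) and returns the
#' length of the below-threshold run containing the center, with
#' subpixel threshold-crossing interpolation. Used to verify that rendered
#' gaps match the configured geometry.
#'
#' @param img Image matrix.
#' @param center Joint center `c(x, y)` (0-based).
#' @param axis_deg Joint axis direction in degrees from vertical.
#' @param span Half-length of the scanned profile in pixels.
#' @param threshold Intensity threshold separating gap from bone.
#' @return Gap length in pixels (0 if the center itself is above threshold).
#' @export
measure_joint_gap <- function(img, center, axis_deg, span = 30,
                              threshold = .bone_intensity / 2) {
  u <- unitv(axis_deg)
  step <- 0.25
  t <- seq(-span, span, by = step)
  xs <- center[1] + t * u[1]
  ys <- center[2] + t * u[2]
  prof <- bilinear_sample(img, xs, ys)
  i0 <- which.min(abs(t))
  if (prof[i0] >= threshold) return(0)
  lo <- i0
  while (lo > 1 && prof[lo - 1] < threshold) lo <- lo - 1
  hi <- i0
  while (hi < length(t) && prof[hi + 1] < threshold) hi <- hi + 1
  # subpixel crossing on each side
  left <- t[lo]
  if (lo > 1) {
    f <- (threshold - prof[lo - 1]) / (prof[lo] - prof[lo - 1])
    left <- t[lo - 1] + f * step
  }
  right <- t[hi]
  if (hi < length(t)) {
    f <- (threshold - prof[hi + 1]) / (prof[hi] - prof[hi + 1])
    right <- t[hi + 1] - f * step
  }
  right - left
}

bilinear_sample <- function(img, xs, ys) {
  H <- nrow(img); W <- ncol(img)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  val <- numeric(length(xs))
  for (dy in 0:1) for (dx in 0:1) {
    xx <- x0 + dx; yy <- y0 + dy
    ok <- xx >= 0 & xx < W & yy >= 0 & yy < H
    wgt <- (dx * fx + (1 - dx) * (1 - fx)) * (dy * fy + (1 - dy) * (1 - fy))
    v <- numeric(length(xs))
    v[ok] <- img[cbind(yy[ok] + 1, xx[ok] + 1)]
    val <- val + wgt * v
  }
  val
}
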