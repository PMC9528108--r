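erosion_ann_stub <- function(size = 32) {
  tj <- target_joints("erosion", "right")
  with_seed(91, data.frame(
    name = tj$name,
    x = runif(16, 2, size - 3),
    y = runif(16, 2, size - 3),
    stringsAsFactors = FALSE
  ))
}

test_that("target heatmaps peak at the annotated centers", {
  ann <- erosion_ann_stub()
  ann$x[1] <- 10; ann$y[1] <- 20  # exact pixel center
  hm <- make_target_heatmaps(ann, sigma = 2, size = 32, assessment = "erosion")
  expect_equal(dim(hm), c(32, 32, 16))
  expect_equal(hm[21, 11, 1], 1.0)  # value 1 at the (pixel-aligned) center
  # channel mass approximates the Gaussian integral 2*pi*sigma^2 for an
  # interior keypoint (numeric-integral oracle)
  interior <- which(ann$x > 8 & ann$x < 24 & ann$y > 8 & ann$y < 24)
  for (j in interior) {
    expect_equal(sum(hm[, , j]), 2 * pi * 4, tolerance = 1e-3)
  }
  # corner keypoint: channel max at that corner
  ann2 <- ann
  ann2$x[3] <- 0; ann2$y[3] <- 0
  hm2 <- make_target_heatmaps(ann2, 2, 32, "erosion")
  expect_equal(which(hm2[, , 3] == max(hm2[, , 3]), arr.ind = TRUE)[1, ],
               c(row = 1, col = 1))
  # missing / duplicated joints rejected with the joint named
  expect_error(make_target_heatmaps(ann[-1, ], 2, 32, "erosion"), "ip1")
  expect_error(make_target_heatmaps(rbind(ann, ann[2, ]), 2, 32, "erosion"),
               "pip2")
})

test_that("peak reading refines subpixel positions and breaks ties low-y-then-x", {
  # delta input: single 1.0 peak
  hm <- array(0, dim = c(64, 64, 1))
  hm[51, 101 - 64 + 26, 1] <- 0  # no-op guard
  hm <- array(0, dim = c(64, 128, 1))
  hm[51, 101, 1] <- 1
  pk <- heatmap_peaks(hm)
  expect_equal(pk$x, 100)
  expect_equal(pk$y, 50)
  expect_equal(pk$confidence, 1)
  # two equal maxima: the lower (y, x) wins
  hm2 <- array(0, dim = c(32, 32, 1))
  hm2[11, 11, 1] <- 0.8
  hm2[21, 21, 1] <- 0.8
  pk2 <- heatmap_peaks(hm2)
  expect_equal(c(pk2$x, pk2$y), c(10, 10))
  # confidence clipped to [0, 1]
  hm3 <- array(0, dim = c(8, 8, 1)); hm3[4, 4, 1] <- 1.7
  expect_equal(heatmap_peaks(hm3)$confidence, 1)
  # subpixel: a Gaussian centered off-grid is recovered to ~0.1 px
  xs <- 0:31
  cx <- 14.4; cy <- 9.7
  g <- outer(xs, xs, function(y, x) exp(-((x - cx)^2 + (y - cy)^2) / 8))
  pk4 <- heatmap_peaks(array(g, dim = c(32, 32, 1)))
  expect_lt(abs(pk4$x - cx), 0.1)
  expect_lt(abs(pk4$y - cy), 0.1)
})

test_that("scale normalization uses the median proximal-phalanx length", {
  mk_centers <- function(lengths) {
    data.frame(
      name = c(paste0("mcp", 2:5), paste0("pip", 2:5)),
      x = c(10, 30, 50, 70, 10, 30, 50, 70),
      y = c(rep(100, 4), 100 - lengths),
      stringsAsFactors = FALSE
    )
  }
  img <- matrix(runif(150 * 150), 150, 150)
  sn <- scale_normalize(img, mk_centers(c(100, 100, 100, 100)), L_ref = 80)
  expect_equal(sn$scale, 0.8)
  expect_equal(dim(sn$image), c(120, 120))
  # even-count median: mean of the two middle lengths
  sn2 <- scale_normalize(img, mk_centers(c(90, 100, 110, 120)), L_ref = 105)
  expect_equal(sn2$scale, 105 / 105)
  sn3 <- scale_normalize(img, mk_centers(c(90, 100, 110, 120)), L_ref = 84)
  expect_equal(sn3$scale, 0.8)
  # image already at reference scale: unchanged
  sn4 <- scale_normalize(img, mk_centers(rep(80, 4)), L_ref = 80)
  expect_equal(sn4$scale, 1)
  expect_equal(sn4$image, img)
  expect_error(scale_normalize(img, mk_centers(rep(80, 4))[-1, ]),
               "must include mcp2")
})

test_that("detection correctness follows the joint-specific box rule", {
  tj <- target_joints("erosion", "right")
  with_seed(92, truth <- data.frame(
    name = tj$name,
    x = runif(16, 300, 500), y = runif(16, 300, 500),
    label = ifelse(runif(16) < 0.3, "non-intact", "intact"),
    stringsAsFactors = FALSE
  ))
  det <- truth[, c("name", "x", "y")]
  # exact detection: all correct, zero distance
  ev <- evaluate_detection(det, truth, "erosion")
  expect_true(all(ev$per_joint$correct))
  expect_equal(max(ev$per_joint$dist), 0)
  tot <- ev$summary[ev$summary$group == "All joints" & ev$summary$class == "total", ]
  expect_equal(tot$rate, 1)
  # a PIP offset of 130 px exceeds the 125 px half-width
  det2 <- det
  det2$x[det2$name == "pip2"] <- det2$x[det2$name == "pip2"] + 130
  ev2 <- evaluate_detection(det2, truth, "erosion")
  expect_false(ev2$per_joint$correct[ev2$per_joint$name == "pip2"])
  expect_true(ev2$per_joint$discarded[ev2$per_joint$name == "pip2"])
  # 3-4-5 triangle distance
  det3 <- det
  det3$x[det3$name == "mcp3"] <- det3$x[det3$name == "mcp3"] + 3
  det3$y[det3$name == "mcp3"] <- det3$y[det3$name == "mcp3"] + 4
  ev3 <- evaluate_detection(det3, truth, "erosion")
  expect_equal(ev3$per_joint$dist[ev3$per_joint$name == "mcp3"], 5)
  expect_error(evaluate_detection(det[-1, ], truth, "erosion"),
               "exactly the erosion joint set")
})

test_that("box correctness agrees with a brute-force point-in-rectangle oracle", {
  tj <- target_joints("jsn", "right")
  with_seed(93, {
    for (rep in 1:12) {
      truth <- data.frame(name = tj$name,
                          x = runif(15, 200, 600), y = runif(15, 200, 600),
                          label = "intact", stringsAsFactors = FALSE)
      det <- truth
      det$x <- det$x + rnorm(15, 0, 120)
      det$y <- det$y + rnorm(15, 0, 120)
      ev <- evaluate_detection(det[, 1:3], truth, "jsn")
      for (i in seq_len(15)) {
        box <- joint_box(tj$name[i])
        d <- det[det$name == tj$name[i], ]
        g <- truth[truth$name == tj$name[i], ]
        inside <- g$x >= d$x - box[["width"]] / 2 &
          g$x <= d$x + box[["width"]] / 2 &
          g$y >= d$y - box[["height"]] / 2 &
          g$y <= d$y + box[["height"]] / 2
        expect_equal(ev$per_joint$correct[ev$per_joint$name == tj$name[i]],
                     inside)
      }
    }
  })
  # rate bookkeeping: intact + non-intact = total
  with_seed(94, {
    truth <- data.frame(name = tj$name, x = runif(15, 200, 600),
                        y = runif(15, 200, 600),
                        label = ifelse(runif(15) < 0.4, "non-intact", "intact"),
                        stringsAsFactors = FALSE)
    det <- truth
    det$x <- det$x + rnorm(15, 0, 150)
  })
  ev <- evaluate_detection(det[, 1:3], truth, "jsn")
  s <- ev$summary
  for (g in unique(s$group)) {
    expect_equal(s$n_correct[s$group == g & s$class == "intact"] +
                   s$n_correct[s$group == g & s$class == "non-intact"],
                 s$n_correct[s$group == g & s$class == "total"])
  }
})

test_that("detector training reduces the loss and is seed-deterministic", {
  m <- fixture_clean_manifest()
  hands <- lapply(1:2, function(i) {
    h <- load_hand(m, i)
    list(image = h$image, annotations = h$annotations, side = h$side)
  })
  cfg <- detector_config("jsn", input_size = 32, sigma = 2, max_epochs = 6,
                         width = 6, seed = 3)
  mod <- train_detector(hands, cfg)
  expect_lt(mod$loss_history[6], mod$loss_history[1])
  mod2 <- train_detector(hands, cfg)
  expect_identical(mod$loss_history, mod2$loss_history)
  # inference returns one point per JSN joint with in-range confidence
  det <- detect(mod, hands[[1]]$image, hands[[1]]$side)
  expect_equal(nrow(det), 15L)
  expect_true(all(det$confidence >= 0 & det$confidence <= 1))
  expect_error(train_detector(hands[1], cfg), "at least 2")
})

test_that("detection is approximately equivariant to image translation", {
  ds <- fixture_detection_study()
  model <- ds$model
  dir <- file.path(tempdir(), "shs_detstudy_erosion_1")
  m <- read_manifest(file.path(dir, "manifest.csv"))
  shift <- c(6, -4)  # pixels, (x, y)
  # tolerance: 2 sigma expressed in original-image pixels
  tol <- 2 * model$config$sigma * (256 / model$config$input_size)
  for (i in 21:23) {
    h <- load_hand(m, i)
    base <- detect(model, h$image, h$side)
    a <- c(1, 0, -shift[1], 0, 1, -shift[2])  # output (x,y) samples input (x-dx, y-dy)
    moved_img <- shscontext:::cpp_warp_affine(h$image, a,
                                              nrow(h$image), ncol(h$image))
    moved <- detect(model, moved_img, h$side)
    dx <- moved$x - base$x
    dy <- moved$y - base$y
    expect_lt(mean(abs(dx - shift[1])), tol)
    expect_lt(mean(abs(dy - shift[2])), tol)
  }
})

test_that("mirroring maps left-hand annotations onto the right-hand channel set", {
  m <- fixture_clean_manifest()
  left_i <- which(m$side == "left")[1]
  h <- load_hand(m, left_i)
  cfg <- detector_config("erosion", input_size = 48, sigma = 2)
  ps <- shscontext:::prep_detection_sample(h$image, h$annotations, "left", cfg)
  expect_equal(nrow(ps$annotations), 16L)
  expect_true(all(ps$annotations$x >= 0 & ps$annotations$x < 48))
  # the mirrored thumb column sits on the low-x side, as on a right hand
  right_i <- which(m$side == "right")[1]
  hr <- load_hand(m, right_i)
  psr <- shscontext:::prep_detection_sample(hr$image, hr$annotations, "right", cfg)
  xl <- ps$annotations$x[ps$annotations$name == "mcp1"]
  xr <- psr$annotations$x[psr$annotations$name == "mcp1"]
  expect_lt(abs(xl - xr), 6)
})
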