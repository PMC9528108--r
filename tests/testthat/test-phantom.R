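phi_corr <- function(a, b) {
  # binary (phi) correlation between two 0/1 vectors
  suppressWarnings(stats::cor(a, b))
}

contralateral_pairs <- function(states, assessment, name) {
  sub <- states[states$assessment == assessment & states$name == name, ]
  r <- sub[sub$side == "right", ]
  l <- sub[sub$side == "left", ]
  key <- function(d) paste(d$patient_id, d$exam_idx)
  l <- l[match(key(r), key(l)), ]
  cbind(as.numeric(r$label == "non-intact"), as.numeric(l$label == "non-intact"))
}

test_that("state sampler enforces the variance-share constraint", {
  expect_error(phantom_config(rho_sym = 0.6, rho_grp = 0.3, rho_pat = 0.3),
               "sum to at most 1")
  expect_error(phantom_config(prevalence = 1.4), "lie in")
})

test_that("perfect bilateral correlation duplicates contralateral labels", {
  cfg <- phantom_config(rho_sym = 1, rho_grp = 0, rho_pat = 0,
                        prevalence = 0.4, seed = 71)
  st <- sample_destruction_states(cfg, 40, 1)
  for (nm in c("mcp2", "navicular")) {
    pr <- contralateral_pairs(st, "erosion", nm)
    expect_equal(pr[, 1], pr[, 2])
  }
})

test_that("independent joints show near-zero contralateral correlation", {
  # Monte-Carlo: 5000 pairs at prevalence 0.5; the phi correlation of
  # independent binary labels has SE ~ 1/sqrt(n)
  cfg <- phantom_config(rho_sym = 0, rho_grp = 0, rho_pat = 0,
                        prevalence = 0.5, seed = 72)
  st <- sample_destruction_states(cfg, 5000, 1)
  pr <- contralateral_pairs(st, "erosion", "mcp3")
  expect_lt(abs(phi_corr(pr[, 1], pr[, 2])), 3 / sqrt(5000))
})

test_that("contralateral label correlation is monotone in rho_sym", {
  for (seed in c(81, 82, 83)) {
    phis <- vapply(c(0, 0.5, 0.9), function(rs) {
      cfg <- phantom_config(rho_sym = rs, rho_grp = 0, rho_pat = 0,
                            prevalence = 0.3, seed = seed)
      st <- sample_destruction_states(cfg, 2000, 1)
      pr <- contralateral_pairs(st, "jsn", "pip2")
      phi_corr(pr[, 1], pr[, 2])
    }, numeric(1))
    expect_true(all(diff(phis) > 0))
  }
})

test_that("marginal prevalence matches the configured group rate", {
  # erosion PIP-IP prevalence from a 226-image cohort: 125/1130
  p <- 125 / 1130
  cfg <- phantom_config(prevalence = list(
    erosion = c("PIP-IP" = p, "MCP" = 0.2, "CMC-M" = 0.2, "Wrist" = 0.2),
    jsn = 0.3), rho_sym = 0.4, rho_grp = 0.1, rho_pat = 0.1, seed = 73)
  st <- sample_destruction_states(cfg, 600, 1)
  sub <- st[st$assessment == "erosion" & st$group == "PIP-IP", ]
  k <- sum(sub$label == "non-intact")
  n <- nrow(sub)
  ci <- qbinom(c(0.005, 0.995), n, p)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
})

test_that("rendered joint gaps follow the JSN narrowing law", {
  # geometry check: no noise and no benign mimics, so the profile through
  # the joint reflects the constructed gap alone
  cfg <- phantom_config(image_size = 512, noise_sd = 0, mimic_rate = 0,
                        seed = 74)
  base <- sample_destruction_states(
    phantom_config(image_size = 512, prevalence = 0, seed = 74), 1, 1)
  h <- base[base$side == "right", ]
  rh0 <- render_hand(h, "right", cfg, jitter = no_jitter)
  ann <- rh0$annotations
  g0 <- cfg$gap
  for (nm in c("pip2", "mcp3", "ip1")) {
    a <- ann[ann$name == nm, ][1, ]
    expect_equal(measure_joint_gap(rh0$image, c(a$x, a$y), a$axis), g0,
                 tolerance = 0.5 / g0)
  }
  # grade-4 narrowing closes the gap completely
  h4 <- h
  h4$grade[h4$assessment == "jsn" & h4$name == "pip2"] <- 4L
  rh4 <- render_hand(h4, "right", cfg, jitter = no_jitter)
  a <- rh4$annotations[rh4$annotations$name == "pip2", ][1, ]
  expect_equal(measure_joint_gap(rh4$image, c(a$x, a$y), a$axis), 0)
  # gap-window brightness grows monotonically as the gap closes
  means <- vapply(0:4, function(k) {
    hk <- h
    hk$grade[hk$assessment == "jsn" & hk$name == "pip3"] <- k
    rhk <- render_hand(hk, "right", cfg, jitter = no_jitter)
    ak <- rhk$annotations[rhk$annotations$name == "pip3", ][1, ]
    win_y <- round(ak$y) + (-4:4) + 1
    win_x <- round(ak$x) + (-4:4) + 1
    mean(rhk$image[win_y, win_x])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_error(render_hand(transform(h, grade = 9L), "right", cfg),
               "outside")
})

test_that("annotations carry the analytic centers and full joint sets", {
  rh <- fixture_hand()
  ann <- rh$annotations
  expect_equal(sum(ann$assessment == "erosion"), 16L)
  expect_equal(sum(ann$assessment == "jsn"), 15L)
  expect_true(all(ann$x >= 0 & ann$x < ncol(rh$image)))
  expect_true(all(ann$y >= 0 & ann$y < nrow(rh$image)))
  # left hand mirrors the right-hand geometry exactly (same RNG stream so
  # mimic placement and pixel noise coincide)
  cfg <- phantom_config(image_size = 256, seed = 7)
  st <- sample_destruction_states(cfg, 1, 1)
  hr <- st[st$side == "right", ]
  hl <- hr; hl$side <- "left"
  rr <- with_seed(31, render_hand(hr, "right", cfg, jitter = no_jitter))
  rl <- with_seed(31, render_hand(hl, "left", cfg, jitter = no_jitter))
  expect_equal(rl$image, rr$image[, rev(seq_len(ncol(rr$image)))],
               tolerance = 1e-12)
  expect_equal(rl$annotations$x, 255 - rr$annotations$x)
  expect_equal(rl$annotations$y, rr$annotations$y)
})

test_that("dataset generation is reproducible and structurally sound", {
  cfg <- phantom_config(image_size = 128, seed = 75)
  d1 <- file.path(tempdir(), "shs_rep1")
  d2 <- file.path(tempdir(), "shs_rep2")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- generate_dataset(cfg, 2, c(1, 2), d1)
  m2 <- generate_dataset(cfg, 2, c(1, 2), d2)
  expect_equal(nrow(m1), 6L)  # (1+2 exams) x 2 hands
  expect_identical(m1$image_path, m2$image_path)
  for (i in seq_len(nrow(m1))) {
    b1 <- readBin(file.path(d1, m1$image_path[i]), "raw", 1e6)
    b2 <- readBin(file.path(d2, m2$image_path[i]), "raw", 1e6)
    expect_identical(b1, b2)
  }
  expect_equal(nrow(validate_manifest(m1)), 0L)
  expect_equal(unname(count_joint_instances(m1)), c(6L * 16L, 6L * 15L))
  # single patient, single exam -> exactly 2 hand records
  d3 <- file.path(tempdir(), "shs_rep3")
  unlink(d3, recursive = TRUE)
  expect_equal(nrow(generate_dataset(cfg, 1, 1, d3)), 2L)
})

test_that("manifest validation reports missing hands and joints", {
  m <- fixture_clean_manifest()
  broken <- m[m$side == "right" | m$patient_id != "P001", ]
  attr(broken, "root") <- attr(m, "root")
  f <- validate_manifest(broken)
  expect_true(any(grepl("exactly one left and one right", f$message)))
  # annotation missing the lunate
  root <- attr(m, "root")
  tmp_dir <- file.path(tempdir(), "shs_broken_ann")
  unlink(tmp_dir, recursive = TRUE)
  dir.create(file.path(tmp_dir, "annotations"), recursive = TRUE)
  file.copy(file.path(root, "images"), tmp_dir, recursive = TRUE)
  for (p in m$annotation_path) {
    ann <- read_annotations(file.path(root, p))
    write_annotations(ann[ann$name != "lunate", ], file.path(tmp_dir, p))
  }
  m2 <- m
  attr(m2, "root") <- tmp_dir
  f2 <- validate_manifest(m2)
  expect_true(any(grepl("missing erosion joint\\(s\\): lunate", f2$message)))
})
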