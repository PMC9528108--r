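# Shared fixtures, built lazily and cached for the whole test run so the
# expensive ones (rendered datasets) are generated once.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A small clean (destruction-free) phantom dataset: 6 patients, 12 hands,
# 192 px images.
fixture_clean_manifest <- function() {
  fixture("clean_manifest", function() {
    dir <- file.path(tempdir(), "shs_fix_clean")
    cfg <- phantom_config(image_size = 192, prevalence = 0, noise_sd = 0.02,
                          seed = 404)
    generate_dataset(cfg, 3, 1, dir)
  })
}

# One rendered hand with mixed grades, deterministic jitter.
fixture_hand <- function() {
  fixture("hand", function() {
    cfg <- phantom_config(image_size = 256, seed = 7)
    st <- sample_destruction_states(cfg, 1, 1)
    h <- st[st$side == "right", ]
    with_seed(7, render_hand(h, "right", cfg))
  })
}

no_jitter <- list(scale = 1, rot = 0, shift = c(0, 0), finger = rep(1, 5))

# The trained-detector study is the most expensive fixture; train it once
# and share it between the held-out performance check and the
# equivariance smoke test.
fixture_detection_study <- function() {
  fixture("detstudy", function() detection_study(seed = 1,
                                                 assessment = "erosion",
                                                 n_train = 20, n_test = 10))
}

# A synthetic labeled crop set: non-intact windows carry a dark central
# patch (a structural signature that survives mean centering), convenient
# for balancing and toy-training tests.
make_toy_crops <- function(n_intact, n_nonintact, side_px = 16,
                           separation = 0.5, noise = 0.02, seed = 1) {
  with_seed(seed, {
    mk <- function(i, label) {
      px <- matrix(0.6 + rnorm(side_px^2, 0, noise), side_px, side_px)
      if (label == "non-intact") {
        q <- (side_px %/% 4):(3 * side_px %/% 4)
        px[q, q] <- px[q, q] - separation
      }
      shscontext:::new_joint_crop(
        px, paste0("erosion.mcp2.right"), "mcp2", "erosion", "right",
        label, grade = if (label == "intact") 0L else 2L,
        patient_id = sprintf("P%03d", i), exam_idx = 1L)
    }
    c(lapply(seq_len(n_intact), function(i) mk(i, "intact")),
      lapply(seq_len(n_nonintact), function(i) mk(n_intact + i, "non-intact")))
  })
}
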