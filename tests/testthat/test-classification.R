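toy_pair_tuples <- function(n, seed = 1, correlated = FALSE, side_px = 16) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      labs <- if (correlated) rep(sample(c("intact", "non-intact"), 1), 2)
        else sample(c("intact", "non-intact"), 2, replace = TRUE)
      crs <- lapply(1:2, function(s) {
        px <- matrix(0.6 + rnorm(side_px^2, 0, 0.05), side_px, side_px)
        if (labs[s] == "non-intact") {
          q <- (side_px %/% 4):(3 * side_px %/% 4)
          px[q, q] <- px[q, q] - 0.4
        }
        shscontext:::new_joint_crop(px, "erosion.mcp2.right", "mcp2",
                                    "erosion", c("right", "left")[s],
                                    labs[s], 0L, sprintf("P%03d", i), 1L)
      })
      list(crops = crs, labels = labs, names = c("mcp2", "mcp2"),
           sides = c("right", "left"), patient_id = sprintf("P%03d", i),
           exam_idx = 1L)
    })
  })
}

test_that("architectures expose the documented slot counts", {
  expect_equal(n_slots("siso", 5), 1L)
  expect_equal(n_slots("mimo_local", 5), 2L)
  expect_equal(n_slots("mimo_one_hand", 4), 4L)
  expect_equal(n_slots("mimo_both_hands", 5), 10L)
  m <- build_model(classifier_config("mimo_local", "erosion", "MCP",
                                     input_side = 16))
  expect_equal(m$n_slots, 2L)
  m2 <- build_model(classifier_config("mimo_one_hand", "erosion", "Wrist",
                                      input_side = 16))
  expect_equal(m2$n_slots, 4L)
  m3 <- build_model(classifier_config("mimo_both_hands", "jsn", "MCP",
                                      input_side = 16))
  expect_equal(m3$n_slots, 10L)
  expect_error(classifier_config("mimo_local", "erosion", "Metatarsals"),
               "unknown erosion group")
  expect_error(classifier_config("dnn", "erosion", "MCP"),
               "unknown architecture")
})

test_that("tuple assembly pairs, orders and excludes as specified", {
  # build crops for 2 exams; drop left mcp2 of exam 2
  crops <- list()
  for (pid in c("P001", "P002")) {
    for (side in c("right", "left")) {
      for (nm in paste0("mcp", 1:5)) {
        if (pid == "P002" && side == "left" && nm == "mcp2") next
        crops[[length(crops) + 1L]] <- shscontext:::new_joint_crop(
          matrix(0.5, 8, 8), paste("erosion", nm, side, sep = "."), nm,
          "erosion", side, "intact", 0L, pid, 1L)
      }
    }
  }
  loc <- assemble_tuples(crops, "mimo_local", "erosion", "MCP")
  # exam 1 pairs all five joints; exam 2 loses only mcp2
  expect_equal(length(loc$tuples), 9L)
  expect_equal(loc$n_excluded, 1L)
  expect_true(all(vapply(loc$tuples, function(t)
    identical(t$sides, c("right", "left")), logical(1))))
  # siso keeps the orphaned right mcp2
  sis <- assemble_tuples(crops, "siso", "erosion", "MCP")
  expect_equal(length(sis$tuples), 19L)
  # one-hand tuples follow canonical order; left hand of exam 2 incomplete
  oh <- assemble_tuples(crops, "mimo_one_hand", "erosion", "MCP")
  expect_equal(length(oh$tuples), 3L)
  expect_true(all(vapply(oh$tuples, function(t)
    identical(t$names, paste0("mcp", 1:5)), logical(1))))
  # both hands: exam 2 excluded entirely
  bh <- assemble_tuples(crops, "mimo_both_hands", "erosion", "MCP")
  expect_equal(length(bh$tuples), 1L)
  expect_equal(bh$tuples[[1]]$sides, rep(c("right", "left"), each = 5))
  expect_error(assemble_tuples(crops, "siso", "erosion", "Wrist"),
               "no crops")
})

test_that("tuple balancing equalizes slot labels and keeps originals", {
  tps <- toy_pair_tuples(40, seed = 5, correlated = TRUE)
  # skew: drop most non-intact pairs
  lab1 <- vapply(tps, function(t) sum(t$labels == "non-intact"), numeric(1))
  tps <- c(head(tps[lab1 == 0], 16), head(tps[lab1 == 2], 5))
  pol <- augmentation_policy(n_total = 120L, seed = 6)
  out <- balance_tuples(tps, pol)
  expect_gte(length(out), 60L)
  labs <- table(unlist(lapply(out, `[[`, "labels")))
  expect_lte(abs(labs[["intact"]] - labs[["non-intact"]]), 2)
  expect_error(balance_tuples(tps[1:16], pol), "single class")
})

test_that("the early-stopping rule reproduces patience arithmetic exactly", {
  # strictly decreasing trace runs to the cap
  dec <- early_stop_epoch(seq(1, 0.01, length.out = 100), 10, 100)
  expect_equal(dec$stop_epoch, 100L)
  expect_equal(dec$best_epoch, 100L)
  # improvement only at epoch 1: stop after 1 + patience epochs
  flat <- early_stop_epoch(c(0.5, rep(0.6, 50)), 10, 100)
  expect_equal(flat$stop_epoch, 11L)
  expect_equal(flat$best_epoch, 1L)
  # improvement resets the counter
  tr <- c(0.5, rep(0.6, 9), 0.4, rep(0.6, 10))
  es <- early_stop_epoch(tr, 10, 100)
  expect_equal(es$stop_epoch, 21L)
  expect_equal(es$best_epoch, 11L)
  # cap truncates even while improving
  cap <- early_stop_epoch(seq(1, 0.5, length.out = 300), 10, 100)
  expect_equal(cap$stop_epoch, 100L)
})

test_that("MIMO training loss is the sum of independent per-slot BCE terms", {
  m <- build_model(classifier_config("mimo_local", "erosion", "MCP",
                                     input_side = 16, seed = 2))
  tps <- toy_pair_tuples(8, seed = 7)
  b <- shscontext:::tuples_to_batch(tps, 16)
  fw <- shscontext:::classifier_forward(m, b$x)
  got <- shscontext:::bce_with_logits(fw$logits, b$y)$loss
  per_slot <- vapply(1:2, function(s) {
    z <- fw$logits[, s]
    p <- 1 / (1 + exp(-z))
    -mean(b$y[, s] * log(p) + (1 - b$y[, s]) * log(1 - p))
  }, numeric(1))
  expect_equal(got, sum(per_slot), tolerance = 1e-10)
})

test_that("training separates linearly separable toy crops and is deterministic", {
  tr <- toy_pair_tuples(30, seed = 8)
  va <- toy_pair_tuples(10, seed = 9)
  cfg <- classifier_config("mimo_local", "erosion", "MCP", input_side = 16,
                           max_epochs = 40, lr = 2e-3, seed = 4)
  t1 <- train_classifier(build_model(cfg), tr, va)
  p <- predict(t1, tr)
  expect_equal(mean(p$call == p$label), 1)
  # training history sane; kept epoch is the validation minimum
  expect_equal(t1$best_epoch, which.min(t1$history$val_loss))
  expect_lt(t1$history$train_loss[nrow(t1$history)], t1$history$train_loss[1])
  # determinism under the same seed
  t2 <- train_classifier(build_model(cfg), tr, va)
  expect_identical(t1$history, t2$history)
  p2 <- predict(t2, tr)
  expect_identical(p$prob, p2$prob)
})

test_that("predictions respect the threshold convention and slot order", {
  tr <- toy_pair_tuples(20, seed = 10)
  cfg <- classifier_config("mimo_local", "erosion", "MCP", input_side = 16,
                           max_epochs = 15, seed = 5)
  tm <- train_classifier(build_model(cfg), tr, toy_pair_tuples(8, seed = 11))
  p <- predict(tm, tr[1:4])
  expect_true(all(p$call[p$prob >= 0.5] == "non-intact"))
  expect_true(all(p$call[p$prob < 0.5] == "intact"))
  expect_equal(p$side[p$slot == 1], rep("right", 4))
  expect_equal(p$side[p$slot == 2], rep("left", 4))
  # probabilities invariant to batch composition
  p1 <- predict(tm, tr[1])
  expect_equal(p$prob[p$tuple == 1], p1$prob, tolerance = 1e-12)
})
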