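# Binary intact/non-intact classifiers. Four architectures share one
# internal wiring: a weight-shared convolutional feature extractor applied
# to every input slot, slot features concatenated into a fully-connected
# trunk, and one independent sigmoid output per slot. Each slot's output
# head (weights shared across slots) reads the trunk's pooled context
# together with that slot's own feature vector; without the own-feature
# path, jointly trained outputs on strongly correlated joints collapse
# onto a slot-symmetric "pair average" that cannot rank the two joints of
# a disagreeing pair. The architectures differ only in what the slots
# are: a single joint (SISO), the same joint of both hands (MIMO local),
# the same-hand joint group (MIMO one-hand), or the joint group of both
# hands (MIMO both-hands). One model is trained per (assessment, group,
# architecture). Loss is binary cross-entropy, summed over output slots
# for the MIMO variants, optimized with Adam and validation-loss early
# stopping.

.architectures <- c("siso", "mimo_local", "mimo_one_hand", "mimo_both_hands")

#' Classifier configuration
#'
#' @param architecture One of `"siso"`, `"mimo_local"`, `"mimo_one_hand"`,
#'   `"mimo_both_hands"`.
#' @param assessment `"erosion"` or `"jsn"`.
#' @param group Joint group the model serves (e.g. `"MCP"`, `"Wrist"`).
#' @param input_side Square side crops are resampled to before the network.
#' @param feature_width Per-slot feature vector length.
#' @param trunk_width Width of the fully connected trunk layers.
#' @param n_fc_layers Number of hidden fully connected trunk layers.
#' @param init Initialization scheme for fully connected layers:
#'   `"he"` (He normal) or `"random"`.
#' @param dropout Dropout rate in the trunk (0 disables).
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param patience Early-stopping patience: training stops once the
#'   validation loss has failed to improve this many epochs in a row.
#' @param max_epochs Hard epoch cap.
#' @param threshold Decision threshold on the sigmoid output; a joint is
#'   called non-intact when its probability is `>= threshold`.
#' @param seed Integer seed (weights, shuffling, dropout).
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(architecture, assessment, group,
                              input_side = 32, feature_width = 24,
                              trunk_width = 48, n_fc_layers = 1,
                              init = "he", dropout = 0, batch_size = 32,
                              lr = 1e-3, patience = 10, max_epochs = 100,
                              threshold = 0.5, seed = 1L) {
  if (!architecture %in% .architectures) {
    stop("unknown architecture: ", architecture, call. = FALSE)
  }
  check_assessment(assessment)
  members <- group_members(assessment, group)  # errors on bad group
  if (patience < 1) stop("patience must be >= 1", call. = FALSE)
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  if (input_side %% 4 != 0) stop("input_side must be divisible by 4", call. = FALSE)
  structure(list(
    architecture = architecture, assessment = assessment, group = group,
    group_size = nrow(members), input_side = as.integer(input_side),
    feature_width = as.integer(feature_width),
    trunk_width = as.integer(trunk_width),
    n_fc_layers = as.integer(n_fc_layers), init = init, dropout = dropout,
    batch_size = as.integer(batch_size), lr = lr,
    patience = as.integer(patience), max_epochs = as.integer(max_epochs),
    threshold = threshold, seed = as.integer(seed)
  ), class = "classifier_config")
}

#' Number of input/output slots of an architecture
#' @param architecture Architecture name.
#' @param group_size Number of joints in the group.
#' @return Integer slot count.
#' @export
n_slots <- function(architecture, group_size) {
  switch(architecture,
    siso = 1L,
    mimo_local = 2L,
    mimo_one_hand = as.integer(group_size),
    mimo_both_hands = 2L * as.integer(group_size),
    stop("unknown architecture: ", architecture, call. = FALSE)
  )
}

#' Build an untrained classifier
#'
#' @param config A [classifier_config()].
#' @return Object of class `shs_classifier` with untrained weights.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "classifier_config"))
  S <- n_slots(config$architecture, config$group_size)
  side <- config$input_side
  with_seed(config$seed, {
    backbone <- list(
      layer_conv(3, 3, 1, 8), layer_relu(),
      layer_pool(),
      layer_conv(3, 3, 8, 16), layer_relu(),
      layer_pool(),
      layer_flatten(),
      layer_dense((side / 4)^2 * 16, config$feature_width, init = config$init),
      layer_relu()
    )
    trunk <- list()
    nin <- S * config$feature_width
    for (i in seq_len(config$n_fc_layers)) {
      trunk <- c(trunk, list(layer_dense(nin, config$trunk_width,
                                         init = config$init),
                             layer_relu()))
      if (config$dropout > 0) trunk <- c(trunk, list(layer_dropout(config$dropout)))
      nin <- config$trunk_width
    }
    head <- list(
      layer_dense(nin + config$feature_width, config$trunk_width,
                  init = config$init),
      layer_relu(),
      layer_dense(config$trunk_width, 1, init = config$init)
    )
    structure(list(config = config, n_slots = S, backbone = backbone,
                   trunk = trunk, head = head, taxonomy = taxonomy_hash()),
              class = "shs_classifier")
  })
}

classifier_forward <- function(model, x, train = FALSE) {
  S <- model$n_slots
  d <- dim(x)
  feats <- vector("list", S)
  bcaches <- vector("list", S)
  for (s in seq_len(S)) {
    xs <- array(x[, , , s], dim = c(d[1], d[2], d[3], 1))
    fw <- seq_forward(model$backbone, xs, train)
    feats[[s]] <- fw$out
    bcaches[[s]] <- fw$caches
  }
  tf <- seq_forward(model$trunk, do.call(cbind, feats), train)
  logits <- matrix(0, d[1], S)
  hcaches <- vector("list", S)
  for (s in seq_len(S)) {
    hf <- seq_forward(model$head, cbind(tf$out, feats[[s]]), train)
    logits[, s] <- hf$out
    hcaches[[s]] <- hf$caches
  }
  list(logits = logits, feats = feats, bcaches = bcaches,
       tcaches = tf$caches, hcaches = hcaches)
}

classifier_backward <- function(model, fwres, dlogits) {
  S <- model$n_slots
  Fw <- model$config$feature_width
  hgrads <- NULL
  dtrunk_out <- NULL
  dskip <- vector("list", S)
  for (s in seq_len(S)) {
    hb <- seq_backward(model$head, fwres$hcaches[[s]],
                       dlogits[, s, drop = FALSE])
    hgrads <- grads_add(hgrads, hb$grads)
    nh <- ncol(hb$dx)
    dtr <- hb$dx[, seq_len(nh - Fw), drop = FALSE]
    dskip[[s]] <- hb$dx[, (nh - Fw + 1):nh, drop = FALSE]
    dtrunk_out <- if (is.null(dtrunk_out)) dtr else dtrunk_out + dtr
  }
  tb <- seq_backward(model$trunk, fwres$tcaches, dtrunk_out)
  bgrads <- NULL
  for (s in seq_len(S)) {
    ds <- tb$dx[, ((s - 1) * Fw + 1):(s * Fw), drop = FALSE] + dskip[[s]]
    bb <- seq_backward(model$backbone, fwres$bcaches[[s]], ds)
    bgrads <- grads_add(bgrads, bb$grads)
  }
  list(backbone = bgrads, trunk = tb$grads, head = hgrads)
}

# ---- tuple assembly --------------------------------------------------------

tuple_key <- function(cr) paste(cr$patient_id, cr$exam_idx, sep = "|")

#' Assemble classifier input tuples from a crop set
#'
#' Groups crops into architecture-specific examples keyed by
#' (patient, exam): SISO uses every group crop on its own; MIMO local pairs
#' each joint with its contralateral (slot order right, left); MIMO
#' one-hand tuples a hand's group members in canonical order; MIMO
#' both-hands concatenates the right-hand group then the left-hand group.
#' Exams missing any required slot (e.g. a discarded detection) are
#' excluded and counted.
#'
#' @param crops List of `joint_crop` objects (one assessment).
#' @param architecture Architecture name.
#' @param assessment,group Model identity.
#' @return List with `tuples` (each: `crops` list, `labels`, `names`,
#'   `sides`, `patient_id`, `exam_idx`) and `n_excluded`.
#' @export
assemble_tuples <- function(crops, architecture, assessment, group) {
  members <- group_members(assessment, group)$name
  crops <- Filter(function(cr) {
    cr$assessment == assessment && cr$name %in% members
  }, crops)
  if (length(crops) == 0L) {
    stop("no crops available for ", assessment, " group ", group,
         call. = FALSE)
  }
  keys <- vapply(crops, tuple_key, character(1))
  lookup <- split(seq_along(crops), keys)

  find_crop <- function(idx, nm, sd) {
    for (i in idx) {
      if (crops[[i]]$name == nm && crops[[i]]$side == sd) return(i)
    }
    NA_integer_
  }
  make_tuple <- function(idx_vec) {
    cs <- crops[idx_vec]
    list(crops = cs,
         labels = vapply(cs, function(c) c$label, character(1)),
         names = vapply(cs, function(c) c$name, character(1)),
         sides = vapply(cs, function(c) c$side, character(1)),
         patient_id = cs[[1]]$patient_id, exam_idx = cs[[1]]$exam_idx)
  }

  tuples <- list()
  n_excluded <- 0L
  if (architecture == "siso") {
    tuples <- lapply(seq_along(crops), function(i) make_tuple(i))
  } else {
    for (key in names(lookup)) {
      idx <- lookup[[key]]
      if (architecture == "mimo_local") {
        for (nm in members) {
          r <- find_crop(idx, nm, "right")
          l <- find_crop(idx, nm, "left")
          if (is.na(r) || is.na(l)) {
            if (!is.na(r) || !is.na(l)) n_excluded <- n_excluded + 1L
            next
          }
          tuples[[length(tuples) + 1L]] <- make_tuple(c(r, l))
        }
      } else if (architecture == "mimo_one_hand") {
        for (sd in c("right", "left")) {
          slots <- vapply(members, function(nm) find_crop(idx, nm, sd),
                          integer(1))
          if (anyNA(slots)) {
            if (!all(is.na(slots))) n_excluded <- n_excluded + 1L
            next
          }
          tuples[[length(tuples) + 1L]] <- make_tuple(slots)
        }
      } else {  # mimo_both_hands
        slots <- c(vapply(members, function(nm) find_crop(idx, nm, "right"),
                          integer(1)),
                   vapply(members, function(nm) find_crop(idx, nm, "left"),
                          integer(1)))
        if (anyNA(slots)) {
          n_excluded <- n_excluded + 1L
          next
        }
        tuples[[length(tuples) + 1L]] <- make_tuple(slots)
      }
    }
  }
  if (length(tuples) == 0L) {
    stop("tuple assembly produced no examples for ", architecture, " / ",
         assessment, " / ", group, " (", n_excluded, " incomplete exams)",
         call. = FALSE)
  }
  list(tuples = tuples, n_excluded = n_excluded)
}

#' Balance tuples by augmentation
#'
#' Retains all original tuples and adds augmented copies (fresh geometric
#' parameters per slot) until roughly `n_total` crops are reached, choosing
#' source tuples round-robin among those richest in the currently
#' under-represented class so the slot-label counts end as close to even
#' as the tuple composition allows. Deterministic under the policy seed.
#'
#' @param tuples Tuple list from [assemble_tuples()].
#' @param policy An [augmentation_policy()].
#' @return Balanced tuple list.
#' @export
balance_tuples <- function(tuples, policy) {
  S <- length(tuples[[1]]$labels)
  target_tuples <- max(length(tuples), ceiling(policy$n_total / S))
  lab1 <- vapply(tuples, function(t) sum(t$labels == "non-intact"), numeric(1))
  if (all(lab1 == 0) || all(lab1 == S)) {
    stop("cannot balance: tuples contain a single class", call. = FALSE)
  }
  out <- tuples
  c1 <- sum(lab1)
  c0 <- length(tuples) * S - c1
  # candidate pools: tuples that shift the slot-label balance toward the
  # non-intact (pool1) or intact (pool0) side; fall back to the closest
  # available composition when no tuple strictly helps
  ord <- order(-lab1)
  pool1 <- ord[lab1[ord] * 2 > S]
  if (length(pool1) == 0L) pool1 <- ord[lab1[ord] == max(lab1)]
  ord0 <- order(lab1)
  pool0 <- ord0[lab1[ord0] * 2 < S]
  if (length(pool0) == 0L) pool0 <- ord0[lab1[ord0] == min(lab1)]
  # mixed tuples (both classes present) are class-balance-neutral but are
  # the examples that force per-slot discrimination on correlated joints,
  # so they are interleaved into the oversampling stream
  poolm <- which(lab1 > 0 & lab1 < S)
  i1 <- 0L; i0 <- 0L; im <- 0L; step <- 0L
  with_seed(policy$seed, {
    while (length(out) < target_tuples) {
      step <- step + 1L
      if (length(poolm) > 0L && step %% 3L == 0L && abs(c1 - c0) <= S) {
        im <- im %% length(poolm) + 1L
        src <- tuples[[poolm[im]]]
      } else if (c1 <= c0) {
        i1 <- i1 %% length(pool1) + 1L
        src <- tuples[[pool1[i1]]]
      } else {
        i0 <- i0 %% length(pool0) + 1L
        src <- tuples[[pool0[i0]]]
      }
      src$crops <- lapply(src$crops, function(cr) {
        p <- sample_aug_params(policy)
        augment_crop(cr, p$rotation, p$translation, p$scale, policy = policy)
      })
      out[[length(out) + 1L]] <- src
      c1 <- c1 + sum(src$labels == "non-intact")
      c0 <- c0 + sum(src$labels == "intact")
    }
  })
  out
}

# Convert tuples to training arrays: x (N, side, side, S), y (N, S) with
# non-intact = 1. Each crop is mean-centered after resampling; removing
# the per-crop brightness offset conditions the optimization and reflects
# that exposure is uninformative on radiographs.
tuples_to_batch <- function(tuples, input_side) {
  N <- length(tuples)
  S <- length(tuples[[1]]$crops)
  x <- array(0, dim = c(N, input_side, input_side, S))
  y <- matrix(0, N, S)
  for (i in seq_len(N)) {
    for (s in seq_len(S)) {
      px <- tuples[[i]]$crops[[s]]$pixels
      if (nrow(px) != input_side || ncol(px) != input_side) {
        px <- resize_image(px, input_side, input_side)
      }
      x[i, , , s] <- px - mean(px)
    }
    y[i, ] <- as.numeric(tuples[[i]]$labels == "non-intact")
  }
  list(x = x, y = y)
}

#' Early-stopping rule
#'
#' Given a validation-loss trace, returns the epoch at which training stops
#' (validation loss failed to improve `patience` epochs in a row, or the
#' epoch cap) and the best epoch whose weights are kept.
#'
#' @param val_losses Numeric vector of per-epoch validation losses.
#' @param patience Consecutive non-improving epochs tolerated.
#' @param max_epochs Hard cap.
#' @return List with `stop_epoch` and `best_epoch`.
#' @export
early_stop_epoch <- function(val_losses, patience = 10, max_epochs = 100) {
  best <- Inf
  best_epoch <- 0L
  since <- 0L
  n <- min(length(val_losses), max_epochs)
  for (e in seq_len(n)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]
      best_epoch <- e
      since <- 0L
    } else {
      since <- since + 1L
      if (since >= patience) return(list(stop_epoch = e, best_epoch = best_epoch))
    }
  }
  list(stop_epoch = n, best_epoch = best_epoch)
}

#' Train a classifier
#'
#' Adam on binary cross-entropy (summed over output slots for MIMO
#' architectures, averaged over the batch). After each epoch the
#' validation loss is evaluated; training stops when it has not improved
#' for `patience` consecutive epochs or at `max_epochs`, and the weights
#' of the best validation epoch are kept. Deterministic under the config
#' seed.
#'
#' @param model An untrained [build_model()] classifier.
#' @param train_tuples,val_tuples Balanced tuple lists.
#' @param config Optional override of `model$config`.
#' @return The trained `shs_classifier`, with `history` (per-epoch train
#'   and validation loss), `stopped_epoch` and `best_epoch` fields.
#' @export
train_classifier <- function(model, train_tuples, val_tuples,
                             config = model$config) {
  stopifnot(inherits(model, "shs_classifier"))
  tr <- tuples_to_batch(train_tuples, config$input_side)
  va <- tuples_to_batch(val_tuples, config$input_side)
  n <- dim(tr$x)[1]

  with_seed(derive_seed(config$seed, "train"), {
    state_b <- adam_init(model$backbone)
    state_t <- adam_init(model$trunk)
    state_h <- adam_init(model$head)
    best <- Inf
    best_epoch <- 0L
    best_weights <- list(backbone = model$backbone, trunk = model$trunk,
                         head = model$head)
    since <- 0L
    hist_train <- numeric(0)
    hist_val <- numeric(0)
    t <- 0
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(n)
      ep_loss <- 0; nb <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        xb <- tr$x[idx, , , , drop = FALSE]
        yb <- tr$y[idx, , drop = FALSE]
        fw <- classifier_forward(model, xb, train = TRUE)
        ls <- bce_with_logits(fw$logits, yb)
        if (!is.finite(ls$loss)) {
          stop("non-finite training loss at epoch ", epoch, call. = FALSE)
        }
        gr <- classifier_backward(model, fw, ls$grad)
        t <- t + 1
        ub <- adam_update(model$backbone, gr$backbone, state_b, config$lr, t)
        model$backbone <- ub$layers; state_b <- ub$state
        ut <- adam_update(model$trunk, gr$trunk, state_t, config$lr, t)
        model$trunk <- ut$layers; state_t <- ut$state
        uh <- adam_update(model$head, gr$head, state_h, config$lr, t)
        model$head <- uh$layers; state_h <- uh$state
        ep_loss <- ep_loss + ls$loss; nb <- nb + 1
      }
      hist_train[epoch] <- ep_loss / nb
      vfw <- classifier_forward(model, va$x, train = FALSE)
      vls <- bce_with_logits(vfw$logits, va$y)
      hist_val[epoch] <- vls$loss
      if (vls$loss < best) {
        best <- vls$loss
        best_epoch <- epoch
        best_weights <- list(backbone = model$backbone, trunk = model$trunk,
                             head = model$head)
        since <- 0L
      } else {
        since <- since + 1L
        if (since >= config$patience) break
      }
    }
    model$backbone <- best_weights$backbone
    model$trunk <- best_weights$trunk
    model$head <- best_weights$head
    model$history <- data.frame(epoch = seq_along(hist_train),
                                train_loss = hist_train,
                                val_loss = hist_val)
    model$stopped_epoch <- length(hist_train)
    model$best_epoch <- best_epoch
    model
  })
}

#' Predict intact/non-intact per slot
#'
#' @param object A trained `shs_classifier`.
#' @param tuples Tuple list matching the model architecture.
#' @param ... Unused.
#' @return Data frame with one row per (tuple, slot): `tuple`, `slot`,
#'   `name`, `side`, `patient_id`, `exam_idx`, `label`, `prob`, `call`.
#'   A slot is called `"non-intact"` when its probability is at or above
#'   the configured threshold.
#' @export
predict.shs_classifier <- function(object, tuples, ...) {
  b <- tuples_to_batch(tuples, object$config$input_side)
  fw <- classifier_forward(object, b$x, train = FALSE)
  prob <- sigmoid(fw$logits)
  S <- object$n_slots
  rows <- lapply(seq_along(tuples), function(i) {
    tp <- tuples[[i]]
    data.frame(tuple = i, slot = seq_len(S), name = tp$names,
               side = tp$sides, patient_id = tp$patient_id,
               exam_idx = tp$exam_idx, label = tp$labels,
               prob = prob[i, ],
               call = ifelse(prob[i, ] >= object$config$threshold,
                             "non-intact", "intact"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
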