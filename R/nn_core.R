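# A small, dependency-free neural-network engine: stride-1 convolutions
# (compiled), 2x2 average pooling, nearest-neighbour upsampling, dense
# layers, ReLU, inverted dropout, Adam, and binary-cross-entropy /
# mean-squared-error losses. Tensors are (N, H, W, C) arrays; dense
# activations are N x F matrices. Weight initialization draws from the
# caller's RNG stream so builds are reproducible under with_seed().

he_normal <- function(n, fan_in) rnorm(n, sd = sqrt(2 / fan_in))
small_uniform <- function(n, fan_in) runif(n, -0.05, 0.05)

init_fun <- function(init) {
  switch(init,
    he     = he_normal,
    random = small_uniform,
    stop("unknown initialization scheme: ", init, call. = FALSE)
  )
}

layer_conv <- function(kh, kw, cin, cout, pad = (kh - 1L) %/% 2L, init = "he") {
  f <- init_fun(init)
  W <- array(f(kh * kw * cin * cout, kh * kw * cin), dim = c(kh, kw, cin, cout))
  list(type = "conv", W = W, b = numeric(cout), pad = as.integer(pad))
}

layer_dense <- function(nin, nout, init = "he") {
  f <- init_fun(init)
  list(type = "dense",
       W = matrix(f(nin * nout, nin), nin, nout),
       b = numeric(nout))
}

layer_relu <- function() list(type = "relu")
layer_pool <- function() list(type = "pool")
layer_upsample <- function() list(type = "upsample")
layer_flatten <- function() list(type = "flatten")
layer_dropout <- function(rate) list(type = "dropout", rate = rate)

# Forward pass through a layer list. Returns list(out, caches).
seq_forward <- function(layers, x, train = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    res <- switch(l$type,
      conv = {
        y <- cpp_conv2d_fw(x, l$W, l$b, l$pad)
        list(y = y, cache = x)
      },
      dense = {
        y <- x %*% l$W
        y <- sweep(y, 2, l$b, "+")
        list(y = y, cache = x)
      },
      relu = {
        y <- x * (x > 0)
        list(y = y, cache = (x > 0))
      },
      pool = list(y = cpp_avgpool2_fw(x), cache = NULL),
      upsample = list(y = cpp_upsample2_fw(x), cache = NULL),
      flatten = {
        d <- dim(x)
        list(y = matrix(x, nrow = d[1]), cache = d)
      },
      dropout = {
        if (train && l$rate > 0) {
          keep <- 1 - l$rate
          mask <- (runif(length(x)) < keep) / keep
          dim(mask) <- dim(x)
          list(y = x * mask, cache = mask)
        } else {
          list(y = x, cache = NULL)
        }
      },
      stop("unknown layer type: ", l$type)
    )
    x <- res$y
    caches[[i]] <- res$cache
  }
  list(out = x, caches = caches)
}

# Backward pass. Returns list(dx, grads) where grads[[i]] holds dW/db for
# parametric layers and NULL otherwise.
seq_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    if (l$type == "conv") {
      bw <- cpp_conv2d_bw(caches[[i]], l$W, dout, l$pad)
      grads[[i]] <- list(dW = bw$dw, db = bw$db)
      dout <- bw$dx
    } else if (l$type == "dense") {
      x <- caches[[i]]
      grads[[i]] <- list(dW = crossprod(x, dout), db = colSums(dout))
      dout <- dout %*% t(l$W)
    } else if (l$type == "relu") {
      dout <- dout * caches[[i]]
    } else if (l$type == "pool") {
      dout <- cpp_avgpool2_bw(dout)
    } else if (l$type == "upsample") {
      dout <- cpp_upsample2_bw(dout)
    } else if (l$type == "flatten") {
      dout <- array(dout, dim = caches[[i]])
    } else if (l$type == "dropout") {
      if (!is.null(caches[[i]])) dout <- dout * caches[[i]]
    }
  }
  list(dx = dout, grads = grads)
}

# Adam optimizer state for a layer list.
adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (!is.null(l$W)) {
      list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
    } else NULL
  })
}

adam_update <- function(layers, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    layers[[i]]$W <- layers[[i]]$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    layers[[i]]$b <- layers[[i]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[i]] <- s
  }
  list(layers = layers, state = state)
}

# Elementwise sum of two gradient lists (slot sharing in MIMO backbones).
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (i in seq_along(a)) {
    if (is.null(a[[i]])) next
    a[[i]]$dW <- a[[i]]$dW + b[[i]]$dW
    a[[i]]$db <- a[[i]]$db + b[[i]]$db
  }
  a
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Binary cross-entropy with logits, summed over output slots and averaged
# over the batch; returns the loss and the gradient wrt logits.
bce_with_logits <- function(logits, labels) {
  n <- nrow(logits)
  # numerically stable: log(1 + exp(z)) = max(z,0) + log1p(exp(-|z|))
  sp <- pmax(logits, 0) + log1p(exp(-abs(logits)))
  loss <- sum(sp - labels * logits) / n
  grad <- (sigmoid(logits) - labels) / n
  list(loss = loss, grad = grad)
}

# Mean squared error over all elements (heatmap regression target).
# `peak_weight` up-weights elements in proportion to the target value,
# counteracting the overwhelming background majority of heatmap pixels
# (weight = 1 + peak_weight * target).
mse_loss <- function(pred, target, peak_weight = 0) {
  d <- pred - target
  if (peak_weight > 0) {
    w <- 1 + peak_weight * target
    list(loss = sum(w * d^2) / length(d), grad = 2 * w * d / length(d))
  } else {
    list(loss = mean(d^2), grad = 2 * d / length(d))
  }
}
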