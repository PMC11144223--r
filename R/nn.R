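# Per-channel 1-D convolutional feature extractors.
#
# A native implementation (im2col convolutions, manual backpropagation,
# Adam) of a 1-D adaptation of the EfficientNetV2 stage structure:
# fused-MBConv blocks (k3 expansion conv + 1x1 projection) in the early
# stages and MBConv blocks (1x1 expansion + depthwise k3 + 1x1
# projection) later, SiLU activations, residuals on stride-1
# shape-preserving blocks, a 1x1 head convolution into the feature
# width, global average pooling and a 2-logit classification head.
# Squeeze-and-excitation and batch normalisation are omitted: inputs are
# already normalised to [0, 1] and the desk-scale profiles train without
# them. Kernel size is 3 throughout, with the 2-D architecture's stride
# schedule applied along time.
#
# Batch layout everywhere: arrays of dim (batch, time, channels).

sigmoid <- function(x) 1 / (1 + exp(-x))

new_id <- local({
  counter <- 0L
  function(prefix) {
    counter <<- counter + 1L
    paste0(prefix, counter)
  }
})

node_conv <- function(cin, cout, k = 3L, stride = 1L) {
  list(kind = "conv", id = new_id("conv"), cin = cin, cout = cout,
       k = as.integer(k), stride = as.integer(stride))
}
node_dwconv <- function(c, k = 3L, stride = 1L) {
  list(kind = "dwconv", id = new_id("dw"), c = c, k = as.integer(k),
       stride = as.integer(stride))
}
node_act <- function() list(kind = "act", id = new_id("act"))
node_gap <- function() list(kind = "gap", id = new_id("gap"))
node_dense <- function(cin, cout) {
  list(kind = "dense", id = new_id("fc"), cin = cin, cout = cout)
}
node_res <- function(layers) list(kind = "res", id = new_id("res"), layers = layers)

fused_mbconv <- function(cin, cout, expand, stride) {
  inner <- if (expand == 1) {
    list(node_conv(cin, cout, 3L, stride), node_act())
  } else {
    list(node_conv(cin, cin * expand, 3L, stride), node_act(),
         node_conv(cin * expand, cout, 1L, 1L))
  }
  if (stride == 1 && cin == cout) list(node_res(inner)) else inner
}

mbconv <- function(cin, cout, expand, stride) {
  inner <- list(node_conv(cin, cin * expand, 1L, 1L), node_act(),
                node_dwconv(cin * expand, 3L, stride), node_act(),
                node_conv(cin * expand, cout, 1L, 1L))
  if (stride == 1 && cin == cout) list(node_res(inner)) else inner
}

repeat_block <- function(builder, cin, cout, expand, stride, times) {
  out <- builder(cin, cout, expand, stride)
  if (times > 1) {
    for (i in seq_len(times - 1)) {
      out <- c(out, builder(cout, cout, expand, 1L))
    }
  }
  out
}

# profile -> list(stem width, stage spec, head/feature width)
extractor_profiles <- function() {
  list(
    tiny = list(
      stem = 8L,
      stages = list(list("fused", 16L, 1L, 2L, 1L),
                    list("mb", 32L, 2L, 2L, 1L)),
      head = 64L),
    small = list(
      stem = 16L,
      stages = list(list("fused", 16L, 1L, 1L, 1L),
                    list("fused", 32L, 4L, 2L, 2L),
                    list("mb", 64L, 4L, 2L, 2L)),
      head = 256L),
    full = list(
      stem = 24L,
      stages = list(list("fused", 24L, 1L, 1L, 2L),
                    list("fused", 48L, 4L, 2L, 4L),
                    list("fused", 64L, 4L, 2L, 4L),
                    list("mb", 128L, 4L, 2L, 6L),
                    list("mb", 160L, 6L, 1L, 9L),
                    list("mb", 256L, 6L, 2L, 15L)),
      head = 1280L)
  )
}

#' Configuration of a 1-D feature extractor
#'
#' @param profile Network size: `"full"` mirrors the EfficientNetV2-S
#'   stage widths in 1-D and yields 1280 features per channel from its
#'   last global-average-pooling layer; `"small"` (256 features) and
#'   `"tiny"` (64 features) shrink depth and width for desk-scale
#'   training while keeping the stage structure.
#' @param input_samples Samples per window (window seconds x rate).
#' @param feature_layer `"last_gap"` (pooled head output) or
#'   `"third_last"` (pooled activation entering the head convolution).
#' @param epochs_patience Early-stopping patience in epochs.
#' @param batch_size,learning_rate,max_epochs Adam training parameters.
#' @param seed Seed controlling initialisation and batch order.
#' @export
extractor_config <- function(profile = c("tiny", "small", "full"),
                             input_samples = 1920L,
                             feature_layer = c("last_gap", "third_last"),
                             epochs_patience = 8L, batch_size = 32L,
                             learning_rate = 1e-3, max_epochs = 30L,
                             seed = 1L) {
  profile <- match.arg(profile)
  feature_layer <- match.arg(feature_layer)
  assert_that(epochs_patience >= 1, "patience must be >= 1")
  list(profile = profile, input_samples = as.integer(input_samples),
       feature_layer = feature_layer,
       epochs_patience = as.integer(epochs_patience),
       batch_size = as.integer(batch_size),
       learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
       seed = as.integer(seed))
}

collect_param_nodes <- function(nodes) {
  out <- list()
  for (nd in nodes) {
    if (nd$kind == "res") {
      out <- c(out, collect_param_nodes(nd$layers))
    } else if (nd$kind %in% c("conv", "dwconv", "dense")) {
      out[[nd$id]] <- nd
    }
  }
  out
}

init_params <- function(nodes) {
  params <- list()
  for (nd in collect_param_nodes(nodes)) {
    if (nd$kind == "conv") {
      fan_in <- nd$k * nd$cin
      params[[nd$id]] <- list(
        W = matrix(stats::rnorm(fan_in * nd$cout, 0, sqrt(2 / fan_in)),
                   fan_in, nd$cout),
        b = numeric(nd$cout))
    } else if (nd$kind == "dwconv") {
      params[[nd$id]] <- list(
        W = matrix(stats::rnorm(nd$k * nd$c, 0, sqrt(2 / nd$k)), nd$k, nd$c),
        b = numeric(nd$c))
    } else {
      params[[nd$id]] <- list(
        W = matrix(stats::rnorm(nd$cin * nd$cout, 0, sqrt(2 / nd$cin)),
                   nd$cin, nd$cout),
        b = numeric(nd$cout))
    }
  }
  params
}

#' Build a 1-D convolutional feature extractor
#'
#' @param config An [extractor_config()].
#' @return An `extractor_model` with queryable `feature_width`,
#'   `third_last_width` and [n_params()].
#' @export
build_extractor <- function(config = extractor_config()) {
  prof <- extractor_profiles()[[config$profile]]
  n_strides <- 1L + sum(vapply(prof$stages, function(s) s[[4]] == 2L, TRUE))
  min_len <- 2^n_strides
  if (config$input_samples < min_len) {
    stop_validation("input_samples too short for the downsampling stack; ",
                    "minimum supported length is ", min_len)
  }
  nodes <- list(node_conv(1L, prof$stem, 3L, 2L), node_act())
  cin <- prof$stem
  for (st in prof$stages) {
    builder <- if (st[[1]] == "fused") fused_mbconv else mbconv
    nodes <- c(nodes, repeat_block(builder, cin, st[[2]], st[[3]], st[[4]], st[[5]]))
    cin <- st[[2]]
  }
  third_last_width <- cin
  nodes <- c(nodes, list(node_conv(cin, prof$head, 1L, 1L), node_act(),
                         node_gap(), node_dense(prof$head, 2L)))
  head_conv_id <- nodes[[length(nodes) - 3L]]$id
  params <- with_seed(config$seed, init_params(nodes))
  structure(list(nodes = nodes, params = params, config = config,
                 feature_width = prof$head,
                 third_last_width = third_last_width,
                 head_conv_id = head_conv_id,
                 trained = FALSE),
            class = "extractor_model")
}

#' Number of trainable parameters of an extractor
#' @param model An `extractor_model`.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, function(p) length(p$W) + length(p$b), numeric(1)))
}

#' @export
print.extractor_model <- function(x, ...) {
  cat(sprintf("1-D CNN extractor (profile %s): %d parameters, %d features (%s)\n",
              x$config$profile, n_params(x), x$feature_width,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

conv_pads <- function(L, k, stride) {
  Lout <- ceiling(L / stride)
  pad <- max(0L, (Lout - 1L) * stride + k - L)
  c(pad %/% 2L, pad - pad %/% 2L, Lout)  # left, right, output length
}

pad_time <- function(X, pl, pr) {
  if (pl == 0 && pr == 0) return(X)
  d <- dim(X)
  Xp <- array(0, c(d[1], d[2] + pl + pr, d[3]))
  Xp[, pl + seq_len(d[2]), ] <- X
  Xp
}

im2col <- function(Xp, k, stride, Lout) {
  d <- dim(Xp)  # N, Lp, C
  M <- matrix(0, d[1] * Lout, k * d[3])
  for (j in seq_len(k)) {
    S <- Xp[, (seq_len(Lout) - 1L) * stride + j, , drop = FALSE]
    dim(S) <- c(d[1] * Lout, d[3])
    M[, ((j - 1L) * d[3] + 1L):(j * d[3])] <- S
  }
  M
}

col2im <- function(dM, d, k, stride, Lout) {
  dXp <- array(0, d)
  for (j in seq_len(k)) {
    S <- dM[, ((j - 1L) * d[3] + 1L):(j * d[3]), drop = FALSE]
    dim(S) <- c(d[1], Lout, d[3])
    idx <- (seq_len(Lout) - 1L) * stride + j
    dXp[, idx, ] <- dXp[, idx, , drop = FALSE] + S
  }
  dXp
}

forward_nodes <- function(nodes, params, X, keep_cache = TRUE, taps = NULL) {
  caches <- vector("list", length(nodes))
  tap_out <- list()
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    if (!is.null(taps) && nd$id %in% taps) tap_out[[nd$id]] <- X
    if (nd$kind == "conv") {
      p <- params[[nd$id]]
      d <- dim(X)
      pads <- conv_pads(d[2], nd$k, nd$stride)
      Xp <- pad_time(X, pads[1], pads[2])
      M <- im2col(Xp, nd$k, nd$stride, pads[3])
      Y <- M %*% p$W
      Y <- sweep(Y, 2, p$b, "+")
      dim(Y) <- c(d[1], pads[3], ncol(p$W))
      if (keep_cache) caches[[i]] <- list(M = M, dims = dim(Xp), pads = pads,
                                          in_len = d[2])
      X <- Y
    } else if (nd$kind == "dwconv") {
      p <- params[[nd$id]]
      d <- dim(X)
      pads <- conv_pads(d[2], nd$k, nd$stride)
      Xp <- pad_time(X, pads[1], pads[2])
      NL <- d[1] * pads[3]
      acc <- matrix(rep(p$b, each = NL), NL, d[3])
      slices <- vector("list", nd$k)
      for (j in seq_len(nd$k)) {
        S <- Xp[, (seq_len(pads[3]) - 1L) * nd$stride + j, , drop = FALSE]
        dim(S) <- c(NL, d[3])
        if (keep_cache) slices[[j]] <- S
        acc <- acc + S * matrix(p$W[j, ], NL, d[3], byrow = TRUE)
      }
      dim(acc) <- c(d[1], pads[3], d[3])
      if (keep_cache) caches[[i]] <- list(slices = slices, dims = dim(Xp),
                                          pads = pads, in_len = d[2])
      X <- acc
    } else if (nd$kind == "act") {
      if (keep_cache) caches[[i]] <- list(x = X)
      sg <- sigmoid(X)
      X <- X * sg
    } else if (nd$kind == "gap") {
      d <- dim(X)
      if (keep_cache) caches[[i]] <- list(dims = d)
      X <- colMeans(aperm(X, c(2, 1, 3)), dims = 1)
      dim(X) <- c(d[1], d[3])
    } else if (nd$kind == "dense") {
      p <- params[[nd$id]]
      if (keep_cache) caches[[i]] <- list(x = X)
      X <- sweep(X %*% p$W, 2, p$b, "+")
    } else if (nd$kind == "res") {
      inner <- forward_nodes(nd$layers, params, X, keep_cache, taps)
      tap_out <- c(tap_out, inner$taps)
      if (keep_cache) caches[[i]] <- inner$caches
      X <- X + inner$out
    }
  }
  list(out = X, caches = caches, taps = tap_out)
}

backward_nodes <- function(nodes, params, caches, dY, grads) {
  for (i in rev(seq_along(nodes))) {
    nd <- nodes[[i]]
    cc <- caches[[i]]
    if (nd$kind == "conv") {
      p <- params[[nd$id]]
      d_out <- dim(dY)
      dYm <- dY
      dim(dYm) <- c(d_out[1] * d_out[2], d_out[3])
      grads[[nd$id]]$W <- grads[[nd$id]]$W + crossprod(cc$M, dYm)
      grads[[nd$id]]$b <- grads[[nd$id]]$b + colSums(dYm)
      dM <- tcrossprod(dYm, p$W)
      dXp <- col2im(dM, cc$dims, nd$k, nd$stride, cc$pads[3])
      dY <- dXp[, cc$pads[1] + seq_len(cc$in_len), , drop = FALSE]
    } else if (nd$kind == "dwconv") {
      p <- params[[nd$id]]
      d_out <- dim(dY)
      NL <- d_out[1] * d_out[2]
      dYm <- dY
      dim(dYm) <- c(NL, d_out[3])
      dXp <- array(0, cc$dims)
      for (j in seq_len(nd$k)) {
        grads[[nd$id]]$W[j, ] <- grads[[nd$id]]$W[j, ] +
          colSums(dYm * cc$slices[[j]])
        dS <- dYm * matrix(p$W[j, ], NL, d_out[3], byrow = TRUE)
        dim(dS) <- d_out
        idx <- (seq_len(d_out[2]) - 1L) * nd$stride + j
        dXp[, idx, ] <- dXp[, idx, , drop = FALSE] + dS
      }
      grads[[nd$id]]$b <- grads[[nd$id]]$b + colSums(dYm)
      dY <- dXp[, cc$pads[1] + seq_len(cc$in_len), , drop = FALSE]
    } else if (nd$kind == "act") {
      sg <- sigmoid(cc$x)
      dY <- dY * (sg * (1 + cc$x * (1 - sg)))
    } else if (nd$kind == "gap") {
      d <- cc$dims
      dX <- array(0, d)
      scale <- dY / d[2]
      for (l in seq_len(d[2])) dX[, l, ] <- scale
      dY <- dX
    } else if (nd$kind == "dense") {
      p <- params[[nd$id]]
      grads[[nd$id]]$W <- grads[[nd$id]]$W + crossprod(cc$x, dY)
      grads[[nd$id]]$b <- grads[[nd$id]]$b + colSums(dY)
      dY <- tcrossprod(dY, p$W)
    } else if (nd$kind == "res") {
      inner <- backward_nodes(nd$layers, params, cc, dY, grads)
      grads <- inner$grads
      dY <- dY + inner$dX
    }
  }
  list(dX = dY, grads = grads)
}

zero_grads <- function(params) {
  lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
}

softmax_ce <- function(logits, labels01) {
  m <- apply(logits, 1, max)
  ex <- exp(logits - m)
  p <- ex / rowSums(ex)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), labels01 + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  grad <- p
  grad[idx] <- grad[idx] - 1
  list(loss = loss, grad = grad / n, probs = p)
}

as_batch_array <- function(X) {
  if (length(dim(X)) == 2L) {
    dim(X) <- c(dim(X), 1L)
  }
  X
}

#' Forward pass of an extractor: 2-class logits
#'
#' @param model An `extractor_model`.
#' @param X Window matrix (n x samples) or array (n x samples x 1).
#' @return Matrix of logits (n x 2).
#' @export
extractor_logits <- function(model, X) {
  X <- as_batch_array(X)
  forward_nodes(model$nodes, model$params, X, keep_cache = FALSE)$out
}

#' Train a feature extractor on labelled windows
#'
#' Mini-batch Adam on the categorical cross-entropy. Training stops when
#' the validation loss has not decreased for `epochs_patience`
#' consecutive epochs, and the weights of the best validation epoch are
#' restored.
#'
#' @param model An `extractor_model` from [build_extractor()].
#' @param X,y Training windows (n x samples) and 0/1 labels; the set
#'   should be balanced (a warning is raised otherwise).
#' @param X_val,y_val Validation windows from disjoint patients.
#' @param verbose Print per-epoch losses.
#' @return The trained model, with a `history` data.frame of epoch
#'   losses attached.
#' @export
train_extractor <- function(model, X, y, X_val, y_val, verbose = FALSE) {
  cfg <- model$config
  X <- as_batch_array(X); X_val <- as_batch_array(X_val)
  if (dim(X_val)[1] == 0) stop_validation("validation set is empty")
  if (abs(mean(y) - 0.5) > 0.05) {
    warning("training labels are not balanced (positive fraction ",
            round(mean(y), 3), ")")
  }
  n <- dim(X)[1]
  params <- model$params
  mstate <- zero_grads(params)
  vstate <- zero_grads(params)
  t_step <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best_loss <- Inf; best_params <- params; best_epoch <- 0L
  stall <- 0L

  val_loss_of <- function(params) {
    out <- forward_nodes(model$nodes, params, X_val, keep_cache = FALSE)$out
    softmax_ce(out, y_val)$loss
  }

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, epoch), sample.int(n))
    epoch_loss <- 0; n_batches <- 0L
    for (b0 in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[b0:min(n, b0 + cfg$batch_size - 1L)]
      Xb <- X[idx, , , drop = FALSE]
      fw <- forward_nodes(model$nodes, params, Xb, keep_cache = TRUE)
      ce <- softmax_ce(fw$out, y[idx])
      grads <- backward_nodes(model$nodes, params, fw$caches, ce$grad,
                              zero_grads(params))$grads
      t_step <- t_step + 1
      corr1 <- 1 - b1^t_step; corr2 <- 1 - b2^t_step
      for (id in names(params)) {
        for (f in c("W", "b")) {
          g <- grads[[id]][[f]]
          mstate[[id]][[f]] <- b1 * mstate[[id]][[f]] + (1 - b1) * g
          vstate[[id]][[f]] <- b2 * vstate[[id]][[f]] + (1 - b2) * g^2
          params[[id]][[f]] <- params[[id]][[f]] -
            cfg$learning_rate * (mstate[[id]][[f]] / corr1) /
            (sqrt(vstate[[id]][[f]] / corr2) + eps)
        }
      }
      epoch_loss <- epoch_loss + ce$loss
      n_batches <- n_batches + 1L
    }
    vl <- val_loss_of(params)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = epoch_loss / n_batches,
                                         val_loss = vl))
    if (verbose) {
      message(sprintf("epoch %d: train %.4f val %.4f", epoch,
                      epoch_loss / n_batches, vl))
    }
    if (vl < best_loss - 1e-9) {
      best_loss <- vl; best_params <- params; best_epoch <- epoch
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$epochs_patience) break
    }
  }
  model$params <- best_params
  model$trained <- TRUE
  model$history <- history
  model$best_epoch <- best_epoch
  model
}

#' Extract deep features from windows
#'
#' Deterministic inference pass. `"last_gap"` returns the global average
#' pooling of the head convolution (the layer the classification head
#' reads, e.g. 1280-wide for the full profile); `"third_last"` pools the
#' activation entering the head convolution instead.
#'
#' @param model A trained `extractor_model`.
#' @param X Window matrix (n x samples).
#' @param feature_layer Overrides the config's feature layer.
#' @return Feature matrix (n x width).
#' @export
extract_features <- function(model, X,
                             feature_layer = model$config$feature_layer) {
  X <- as_batch_array(X)
  if (dim(X)[2] != model$config$input_samples) {
    stop_validation("window length ", dim(X)[2], " does not match the ",
                    "extractor's input_samples ", model$config$input_samples)
  }
  if (feature_layer == "last_gap") {
    dense_id <- model$nodes[[length(model$nodes)]]$id
    out <- forward_nodes(model$nodes, model$params, X, keep_cache = FALSE,
                         taps = dense_id)
    feats <- out$taps[[dense_id]]  # GAP output feeding the logits
  } else {
    out <- forward_nodes(model$nodes, model$params, X, keep_cache = FALSE,
                         taps = model$head_conv_id)
    act <- out$taps[[model$head_conv_id]]
    d <- dim(act)
    feats <- colMeans(aperm(act, c(2, 1, 3)), dims = 1)
    dim(feats) <- c(d[1], d[3])
  }
  feats
}
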