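# Reduced-scale deep probability stage: a compact seeded 3D convolutional
# network (im2col convolutions, ReLU, global average pooling, sigmoid head)
# trained with SGD + momentum and a stepped learning-rate schedule, plus
# ingestion of externally computed probabilities. The two paths share one
# interface contract: a scorer mapping subjects to P(high risk).

#' Deep-stage configuration
#'
#' Defaults reproduce the modeled training schedule: SGD with momentum 0.9,
#' batch size 2, 200 epochs, initial learning rate 0.001 decreased by a
#' factor of 10 every 30 epochs, inputs resized to 96^3. `desk = TRUE`
#' switches to the compact tested scale (32^3 inputs, 30 epochs) with the
#' same optimizer settings.
#'
#' @param input_shape Integer length-3 input shape.
#' @param optimizer Only `"sgd"` is provided.
#' @param momentum SGD momentum.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param lr Initial learning rate (> 0).
#' @param lr_step Epochs between learning-rate drops.
#' @param lr_factor Multiplicative drop (0.1 = divide by 10).
#' @param architecture `"tiny3d"` (three stride-2 conv blocks, global average
#'   pooling, sigmoid head) or an adapter function taking `(volumes, labels,
#'   config)` and returning a scorer, for users supplying larger backbones.
#' @param channels Channels per conv block for `"tiny3d"`.
#' @param seed Integer seed for initialization and shuffling.
#' @param desk Use the compact tested scale.
#' @return List of class `dl_config`.
#' @export
dl_config <- function(input_shape = c(96L, 96L, 96L), optimizer = "sgd",
                      momentum = 0.9, batch_size = 2L, epochs = 200L,
                      lr = 0.001, lr_step = 30L, lr_factor = 0.1,
                      architecture = "tiny3d", channels = c(4L, 8L, 16L),
                      seed = 1L, desk = FALSE) {
  if (isTRUE(desk)) {
    if (missing(input_shape)) input_shape <- c(32L, 32L, 32L)
    if (missing(epochs)) epochs <- 30L
  }
  stopifnot(lr > 0, epochs >= 1, batch_size >= 1)
  structure(
    list(input_shape = as.integer(input_shape), optimizer = optimizer,
         momentum = momentum, batch_size = as.integer(batch_size),
         epochs = as.integer(epochs), lr = lr, lr_step = as.integer(lr_step),
         lr_factor = lr_factor, architecture = architecture,
         channels = as.integer(channels), seed = as.integer(seed)),
    class = "dl_config"
  )
}

# Patch-index matrix for a 3x3x3, stride-2, pad-1 convolution: rows are the
# 27 kernel positions, columns the output voxels; 0 marks a zero-padded tap.
make_conv_idx <- function(in_dim, k = 3L, stride = 2L, pad = 1L) {
  out_dim <- (in_dim + 2L * pad - k) %/% stride + 1L
  M <- prod(out_dim)
  offs <- as.matrix(expand.grid(kx = 0:(k - 1), ky = 0:(k - 1), kz = 0:(k - 1)))
  ogrid <- as.matrix(expand.grid(ox = 0:(out_dim[1] - 1), oy = 0:(out_dim[2] - 1),
                                 oz = 0:(out_dim[3] - 1)))
  idx <- matrix(0L, nrow(offs), M)
  for (r in seq_len(nrow(offs))) {
    px <- ogrid[, 1] * stride - pad + offs[r, 1]
    py <- ogrid[, 2] * stride - pad + offs[r, 2]
    pz <- ogrid[, 3] * stride - pad + offs[r, 3]
    ok <- px >= 0 & px < in_dim[1] & py >= 0 & py < in_dim[2] & pz >= 0 & pz < in_dim[3]
    idx[r, ok] <- 1L + px[ok] + in_dim[1] * (py[ok] + in_dim[2] * pz[ok])
  }
  list(idx = idx, out_dim = out_dim, n_taps = nrow(offs))
}

# x: C x V matrix -> patches (C * n_taps) x M
im2col3 <- function(x, conv) {
  C <- nrow(x)
  xp <- cbind(0, x)                    # column 1 = zero pad
  p <- xp[, as.integer(conv$idx) + 1L, drop = FALSE]   # C x (taps * M)
  dim(p) <- c(C * conv$n_taps, ncol(conv$idx))
  p
}

# scatter-add of patch gradients back to the input grid
col2im3 <- function(dp, conv, C, V) {
  dx <- matrix(0, C, V)
  M <- ncol(conv$idx)
  dim(dp) <- c(C, conv$n_taps, M)
  for (r in seq_len(conv$n_taps)) {
    cols <- conv$idx[r, ]
    ok <- cols > 0L
    if (any(ok)) {
      dx[, cols[ok]] <- dx[, cols[ok]] + dp[, r, ok]
    }
  }
  dx
}

cnn_forward <- function(net, x, keep_cache = FALSE) {
  cache <- list()
  for (l in seq_along(net$convs)) {
    conv <- net$geom[[l]]
    p <- im2col3(x, conv)
    z <- net$convs[[l]]$W %*% p + net$convs[[l]]$b   # b recycles down columns
    a <- pmax(z, 0)
    if (keep_cache) cache[[l]] <- list(p = p, z = z, v = ncol(x))
    x <- a
  }
  pooled <- rowMeans(x)
  z_out <- sum(net$dense$w * pooled) + net$dense$b
  prob <- 1 / (1 + exp(-z_out))
  list(prob = prob, pooled = pooled, cache = cache, last = x)
}

cnn_backward <- function(net, fwd, target) {
  gr <- list(convs = vector("list", length(net$convs)), dense = NULL)
  dz_out <- fwd$prob - target                       # BCE + sigmoid
  gr$dense <- list(w = dz_out * fwd$pooled, b = dz_out)
  M_last <- ncol(fwd$last)
  da <- matrix(net$dense$w * dz_out / M_last, nrow = nrow(fwd$last), ncol = M_last)
  for (l in rev(seq_along(net$convs))) {
    ch <- fwd$cache[[l]]
    dz <- da * (ch$z > 0)
    gr$convs[[l]] <- list(W = dz %*% t(ch$p), b = rowSums(dz))
    if (l > 1L) {
      dp <- t(net$convs[[l]]$W) %*% dz
      da <- col2im3(dp, net$geom[[l]], C = nrow(fwd$cache[[l - 1]]$z), V = ch$v)
    }
  }
  gr
}

init_tiny3d <- function(input_shape, channels) {
  geom <- list()
  convs <- list()
  in_dim <- input_shape
  c_in <- 1L
  for (l in seq_along(channels)) {
    g <- make_conv_idx(in_dim)
    fan_in <- c_in * g$n_taps
    convs[[l]] <- list(
      W = matrix(stats::rnorm(channels[l] * fan_in, sd = sqrt(2 / fan_in)),
                 channels[l], fan_in),
      b = numeric(channels[l])
    )
    geom[[l]] <- g
    in_dim <- g$out_dim
    c_in <- channels[l]
  }
  c_last <- channels[length(channels)]
  list(convs = convs, geom = geom,
       dense = list(w = stats::rnorm(c_last, sd = sqrt(1 / c_last)), b = 0))
}

prep_dl_input <- function(v, input_shape) {
  a <- if (is_volume_grid(v)) v$data else v
  if (!identical(dim(a), as.integer(input_shape))) {
    stop("volume shape does not match config$input_shape; crop_resize_roi() first",
         call. = FALSE)
  }
  s <- stats::sd(a)
  a <- if (s > 0) (a - mean(a)) / s else a - mean(a)
  matrix(as.numeric(a), nrow = 1)                   # 1 channel x V
}

#' Train the convolutional probability scorer
#'
#' Seeded end-to-end training of the compact 3D CNN on cropped/resized ROI
#' volumes: binary cross-entropy loss, SGD with momentum, per-epoch
#' shuffling, and the configured stepped learning-rate schedule. Inputs are
#' standardized per volume.
#'
#' @param volumes List of [volume_grid()]s (or arrays) of shape
#'   `config$input_shape`, typically from [crop_resize_roi()].
#' @param labels Binary labels (0/1), at least 2 subjects per class.
#' @param config A [dl_config()].
#' @return Object of class `cnn_scorer` with a [predict()] method returning
#'   P(high risk) in \[0, 1\].
#' @export
train_cnn_scorer <- function(volumes, labels, config = dl_config(desk = TRUE)) {
  labels <- as.integer(labels)
  stopifnot(length(volumes) == length(labels))
  if (min(table(factor(labels, levels = 0:1))) < 2L) {
    stop("need at least 2 subjects per class", call. = FALSE)
  }
  if (is.function(config$architecture)) {
    return(config$architecture(volumes, labels, config))
  }
  xs <- lapply(volumes, prep_dl_input, input_shape = config$input_shape)
  n <- length(xs)

  with_seed_local(config$seed, {
    net <- init_tiny3d(config$input_shape, config$channels)
    vel <- rapply(list(convs = lapply(net$convs, function(l) list(W = l$W * 0, b = l$b * 0)),
                       dense = list(w = net$dense$w * 0, b = 0)),
                  identity, how = "replace")
    for (epoch in seq_len(config$epochs)) {
      lr <- config$lr * config$lr_factor^((epoch - 1) %/% config$lr_step)
      ord <- sample.int(n)
      for (b0 in seq(1, n, by = config$batch_size)) {
        batch <- ord[b0:min(b0 + config$batch_size - 1L, n)]
        acc <- NULL
        for (i in batch) {
          fwd <- cnn_forward(net, xs[[i]], keep_cache = TRUE)
          g <- cnn_backward(net, fwd, labels[i])
          acc <- if (is.null(acc)) g else add_grads(acc, g)
        }
        m <- length(batch)
        for (l in seq_along(net$convs)) {
          vel$convs[[l]]$W <- config$momentum * vel$convs[[l]]$W - lr * acc$convs[[l]]$W / m
          vel$convs[[l]]$b <- config$momentum * vel$convs[[l]]$b - lr * acc$convs[[l]]$b / m
          net$convs[[l]]$W <- net$convs[[l]]$W + vel$convs[[l]]$W
          net$convs[[l]]$b <- net$convs[[l]]$b + vel$convs[[l]]$b
        }
        vel$dense$w <- config$momentum * vel$dense$w - lr * acc$dense$w / m
        vel$dense$b <- config$momentum * vel$dense$b - lr * acc$dense$b / m
        net$dense$w <- net$dense$w + vel$dense$w
        net$dense$b <- net$dense$b + vel$dense$b
      }
    }
    structure(list(net = net, config = config), class = "cnn_scorer")
  })
}

add_grads <- function(a, b) {
  for (l in seq_along(a$convs)) {
    a$convs[[l]]$W <- a$convs[[l]]$W + b$convs[[l]]$W
    a$convs[[l]]$b <- a$convs[[l]]$b + b$convs[[l]]$b
  }
  a$dense$w <- a$dense$w + b$dense$w
  a$dense$b <- a$dense$b + b$dense$b
  a
}

#' @export
predict.cnn_scorer <- function(object, newdata, ...) {
  if (is_volume_grid(newdata) || (is.array(newdata) && length(dim(newdata)) == 3L)) {
    newdata <- list(newdata)
  }
  vapply(newdata, function(v) {
    cnn_forward(object$net, prep_dl_input(v, object$config$input_shape))$prob
  }, numeric(1))
}

#' Load externally computed probabilities
#'
#' Lets users fuse probabilities from any external model (for example a
#' large-scale CNN trained elsewhere) without retraining: validates and
#' aligns a `subject_id, prob` table to the cohort subject order. The result
#' is interchangeable with [train_cnn_scorer()] predictions everywhere
#' downstream.
#'
#' @param scores CSV path or data frame with columns `subject_id`, `prob`.
#' @param subjects Subject table (tibble with `subject_id`) defining the
#'   output order.
#' @return Numeric probability vector aligned to `subjects$subject_id`.
#' @export
load_external_scores <- function(scores, subjects) {
  if (is.character(scores)) scores <- utils::read.csv(scores, stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "prob") %in% names(scores)))
  if (anyDuplicated(scores$subject_id)) {
    stop(sprintf("duplicate subject id(s): %s",
                 paste(unique(scores$subject_id[duplicated(scores$subject_id)]),
                       collapse = ", ")), call. = FALSE)
  }
  missing_ids <- setdiff(subjects$subject_id, scores$subject_id)
  if (length(missing_ids)) {
    stop(sprintf("missing score(s) for subject(s): %s",
                 paste(missing_ids, collapse = ", ")), call. = FALSE)
  }
  p <- scores$prob[match(subjects$subject_id, scores$subject_id)]
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  p
}
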