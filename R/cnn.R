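# Two small convolutional networks, written from scratch on top of the
# package's im2col/BLAS kernels (src/ops.cpp): a 16-layer / 3-convolution
# image classifier and an 11-layer / 3-convolution pixel labeller. Training
# is seeded Adam; every named layer counts toward the layer total (the
# MATLAB-style counting idiom), and both layer lists are overridable only
# through the knobs in netConfig -- the 3-convolution skeleton is fixed.
#
# Batches are arrays [H, W, C, B]; images enter scaled to [0, 1].

#' Network configuration
#'
#' Hyperparameters of the two networks. The classifier maps a 256 x 256
#' grayscale image to 3 class probabilities through three
#' conv(3x3)-batchnorm-relu-maxpool blocks and a dense softmax head
#' (16 named layers). The segmenter maps the image to a per-pixel
#' tumor-probability map through conv-batchnorm-relu-maxpool,
#' conv-relu, nearest upsample, a 2-channel conv and a per-pixel softmax
#' (11 named layers).
#'
#' @param task `"classify"` or `"segment"`.
#' @param image_size Input side length in pixels (default 256; must be a
#'   multiple of 8 for the classifier, of 2 for the segmenter).
#' @param channels Convolution width (default 8 feature maps).
#' @param n_classes Classes: 3 for classify, 2 pixel classes for segment.
#' @param iterations Optimizer steps (desk-scale defaults; the counts are
#'   configurable up to the thousands used for full runs).
#' @param batch_size Images per step. When `batch_size >= n_train` every
#'   step uses the full training set in fixed order.
#' @param lr Adam learning rate.
#' @param val_fraction Fraction of the training images held out for
#'   checkpoint validation (best-checkpoint weights are returned).
#' @param eval_every Validation cadence in iterations.
#' @param pos_weight Loss weight for tumor pixels (segment only); `NULL`
#'   means derive it from the training masks (inverse frequency, capped at
#'   20) to counter the rarity of tumor pixels.
#' @param seed Integer seed; fixes initial weights, batch order and the
#'   validation split.
#' @return Configuration list of class `"NetConfig"`.
#' @export
netConfig <- function(task = c("classify", "segment"),
                      image_size = 256L, channels = 8L,
                      n_classes = if (task[1] == "classify") 3L else 2L,
                      iterations = 300L, batch_size = if (task[1] == "classify") 8L else 2L,
                      lr = 1e-3, val_fraction = 0.2, eval_every = 25L,
                      pos_weight = NULL, seed = 1L) {
  task <- match.arg(task)
  image_size <- as.integer(image_size)
  div <- if (task == "classify") 8L else 2L
  if (image_size %% div != 0L)
    stop("image_size must be a multiple of ", div, " for task ", task)
  structure(list(task = task, image_size = image_size,
                 channels = as.integer(channels),
                 n_classes = as.integer(n_classes),
                 iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size), lr = lr,
                 val_fraction = val_fraction, eval_every = as.integer(eval_every),
                 pos_weight = pos_weight, seed = as.integer(seed)),
            class = "NetConfig")
}

#' Named layer list of a configuration
#'
#' Every named layer counts: the classifier has 16 (input, three
#' conv-bn-relu-pool blocks, fc, softmax, output), the segmenter 11 (input,
#' conv-bn-relu-pool, conv-relu, upsample, conv, softmax, output); both
#' contain exactly three convolutions.
#'
#' @param cfg A [netConfig()].
#' @return Character vector of layer names.
#' @export
layerNames <- function(cfg) {
  if (cfg$task == "classify")
    c("input", "conv1", "bn1", "relu1", "pool1", "conv2", "bn2", "relu2",
      "pool2", "conv3", "bn3", "relu3", "pool3", "fc", "softmax", "output")
  else
    c("input", "conv1", "bn1", "relu1", "pool1", "conv2", "relu2", "up1",
      "conv3", "softmax", "output")
}

heInit <- function(dims, fan_in) array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)

initParams <- function(cfg) {
  C <- cfg$channels
  if (cfg$task == "classify") {
    d_fc <- (cfg$image_size / 8L)^2 * C
    list(W1 = heInit(c(3, 3, 1, C), 9), b1 = numeric(C),
         g1 = rep(1, C), be1 = numeric(C),
         W2 = heInit(c(3, 3, C, C), 9 * C), b2 = numeric(C),
         g2 = rep(1, C), be2 = numeric(C),
         W3 = heInit(c(3, 3, C, C), 9 * C), b3 = numeric(C),
         g3 = rep(1, C), be3 = numeric(C),
         Wfc = matrix(rnorm(d_fc * cfg$n_classes, 0, sqrt(2 / d_fc)),
                      d_fc, cfg$n_classes),
         bfc = numeric(cfg$n_classes))
  } else {
    list(W1 = heInit(c(3, 3, 1, C), 9), b1 = numeric(C),
         g1 = rep(1, C), be1 = numeric(C),
         W2 = heInit(c(3, 3, C, C), 9 * C), b2 = numeric(C),
         W3 = heInit(c(3, 3, C, 2), 9 * C), b3 = numeric(2))
  }
}

initState <- function(cfg) {
  C <- cfg$channels
  bn <- function() list(mean = numeric(C), var = rep(1, C))
  if (cfg$task == "classify") list(bn1 = bn(), bn2 = bn(), bn3 = bn())
  else list(bn1 = bn())
}

#' Build an untrained network
#'
#' Initializes seeded He-normal weights; the same seed always gives
#' identical initial weights.
#'
#' @param cfg A [netConfig()] with the matching task.
#' @return An [EchoNet-class].
#' @export
buildClassifierNet <- function(cfg = netConfig("classify")) {
  stopifnot(inherits(cfg, "NetConfig"), cfg$task == "classify")
  params <- withr::with_seed(cfg$seed, initParams(cfg))
  new("EchoNet", cfg = unclass(cfg), params = params, state = initState(cfg),
      fitted = FALSE, trace = data.frame())
}

#' @rdname buildClassifierNet
#' @export
buildSegmenterNet <- function(cfg = netConfig("segment")) {
  stopifnot(inherits(cfg, "NetConfig"), cfg$task == "segment")
  params <- withr::with_seed(cfg$seed, initParams(cfg))
  new("EchoNet", cfg = unclass(cfg), params = params, state = initState(cfg),
      fitted = FALSE, trace = data.frame())
}

#' Total number of trainable parameters
#'
#' @param net An [EchoNet-class].
#' @return Integer parameter count.
#' @export
parameterCount <- function(net) sum(vapply(net@params, length, integer(1)))

# ---- layer primitives (R side) --------------------------------------------

bnForward <- function(x, gamma, beta, run, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x); C <- d[3]
  y <- x
  xhat <- x
  invstd <- numeric(C)
  for (c in seq_len(C)) {
    xc <- x[, , c, , drop = FALSE]
    if (training) {
      m <- mean(xc); v <- mean((xc - m)^2)
      run$mean[c] <- (1 - momentum) * run$mean[c] + momentum * m
      run$var[c] <- (1 - momentum) * run$var[c] + momentum * v
    } else {
      m <- run$mean[c]; v <- run$var[c]
    }
    invstd[c] <- 1 / sqrt(v + eps)
    xh <- (xc - m) * invstd[c]
    xhat[, , c, ] <- xh
    y[, , c, ] <- gamma[c] * xh + beta[c]
  }
  list(y = y, cache = list(xhat = xhat, invstd = invstd, gamma = gamma),
       run = run)
}

bnBackward <- function(dy, cache) {
  d <- dim(dy); C <- d[3]
  dx <- dy
  dgamma <- numeric(C); dbeta <- numeric(C)
  for (c in seq_len(C)) {
    dyc <- dy[, , c, , drop = FALSE]
    xh <- cache$xhat[, , c, , drop = FALSE]
    dgamma[c] <- sum(dyc * xh)
    dbeta[c] <- sum(dyc)
    dxh <- dyc * cache$gamma[c]
    dx[, , c, ] <- cache$invstd[c] * (dxh - mean(dxh) - xh * mean(dxh * xh))
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# stack a list of [0,1]-scaled image matrices into [H, W, 1, B]
batchArray <- function(imgs, idx) {
  H <- nrow(imgs[[1]]); W <- ncol(imgs[[1]])
  x <- array(0, dim = c(H, W, 1L, length(idx)))
  for (k in seq_along(idx)) x[, , 1L, k] <- imgs[[idx[k]]]
  x
}

# ---- classifier forward / backward ----------------------------------------

fwdClassifier <- function(params, state, x, training) {
  caches <- list(x = x)
  h <- conv2d_fwd(x, params$W1, params$b1); caches$c1_in <- x
  bn <- bnForward(h, params$g1, params$be1, state$bn1, training)
  state$bn1 <- bn$run; caches$bn1 <- bn$cache
  r <- pmax(bn$y, 0); caches$r1 <- bn$y > 0
  p <- maxpool2_fwd(r); caches$p1 <- p; caches$p1_in_dim <- dim(r)

  h <- conv2d_fwd(p$y, params$W2, params$b2); caches$c2_in <- p$y
  bn <- bnForward(h, params$g2, params$be2, state$bn2, training)
  state$bn2 <- bn$run; caches$bn2 <- bn$cache
  r <- pmax(bn$y, 0); caches$r2 <- bn$y > 0
  p <- maxpool2_fwd(r); caches$p2 <- p; caches$p2_in_dim <- dim(r)

  h <- conv2d_fwd(p$y, params$W3, params$b3); caches$c3_in <- p$y
  bn <- bnForward(h, params$g3, params$be3, state$bn3, training)
  state$bn3 <- bn$run; caches$bn3 <- bn$cache
  r <- pmax(bn$y, 0); caches$r3 <- bn$y > 0
  p <- maxpool2_fwd(r); caches$p3 <- p; caches$p3_in_dim <- dim(r)

  B <- dim(x)[4]
  Xm <- t(matrix(p$y, nrow = length(p$y) / B, ncol = B))
  caches$Xm <- Xm
  logits <- sweep(Xm %*% params$Wfc, 2L, params$bfc, "+")
  list(logits = logits, probs = softmaxRows(logits), caches = caches,
       state = state)
}

bwdClassifier <- function(params, caches, dlogits) {
  g <- list()
  g$Wfc <- t(caches$Xm) %*% dlogits
  g$bfc <- colSums(dlogits)
  dX <- dlogits %*% t(params$Wfc)
  d3 <- dim(caches$p3$y)
  dy <- array(t(dX), dim = d3)

  dy <- maxpool2_bwd(dy, caches$p3$idx, caches$p3_in_dim)
  dy <- dy * caches$r3
  bb <- bnBackward(dy, caches$bn3); g$g3 <- bb$dgamma; g$be3 <- bb$dbeta
  cb <- conv2d_bwd(caches$c3_in, params$W3, bb$dx)
  g$W3 <- cb$dw; g$b3 <- cb$db; dy <- cb$dx

  dy <- maxpool2_bwd(dy, caches$p2$idx, caches$p2_in_dim)
  dy <- dy * caches$r2
  bb <- bnBackward(dy, caches$bn2); g$g2 <- bb$dgamma; g$be2 <- bb$dbeta
  cb <- conv2d_bwd(caches$c2_in, params$W2, bb$dx)
  g$W2 <- cb$dw; g$b2 <- cb$db; dy <- cb$dx

  dy <- maxpool2_bwd(dy, caches$p1$idx, caches$p1_in_dim)
  dy <- dy * caches$r1
  bb <- bnBackward(dy, caches$bn1); g$g1 <- bb$dgamma; g$be1 <- bb$dbeta
  cb <- conv2d_bwd(caches$c1_in, params$W1, bb$dx)
  g$W1 <- cb$dw; g$b1 <- cb$db
  g
}

# ---- segmenter forward / backward -----------------------------------------

fwdSegmenter <- function(params, state, x, training) {
  caches <- list(x = x)
  h <- conv2d_fwd(x, params$W1, params$b1); caches$c1_in <- x
  bn <- bnForward(h, params$g1, params$be1, state$bn1, training)
  state$bn1 <- bn$run; caches$bn1 <- bn$cache
  r <- pmax(bn$y, 0); caches$r1 <- bn$y > 0
  p <- maxpool2_fwd(r); caches$p1 <- p; caches$p1_in_dim <- dim(r)

  h <- conv2d_fwd(p$y, params$W2, params$b2); caches$c2_in <- p$y
  r <- pmax(h, 0); caches$r2 <- h > 0
  u <- upsample_fwd(r, 2L); caches$u1_in_dim <- dim(r)

  logits <- conv2d_fwd(u, params$W3, params$b3); caches$c3_in <- u
  # per-pixel softmax over the 2 channels
  m <- pmax(logits[, , 1L, , drop = FALSE], logits[, , 2L, , drop = FALSE])
  e1 <- exp(logits[, , 1L, , drop = FALSE] - m)
  e2 <- exp(logits[, , 2L, , drop = FALSE] - m)
  p_tumor <- e2 / (e1 + e2)
  list(logits = logits, p_tumor = p_tumor, caches = caches, state = state)
}

bwdSegmenter <- function(params, caches, dlogits) {
  g <- list()
  cb <- conv2d_bwd(caches$c3_in, params$W3, dlogits)
  g$W3 <- cb$dw; g$b3 <- cb$db
  dy <- upsample_bwd(cb$dx, 2L)
  dy <- dy * caches$r2
  cb <- conv2d_bwd(caches$c2_in, params$W2, dy)
  g$W2 <- cb$dw; g$b2 <- cb$db
  dy <- maxpool2_bwd(cb$dx, caches$p1$idx, caches$p1_in_dim)
  dy <- dy * caches$r1
  bb <- bnBackward(dy, caches$bn1); g$g1 <- bb$dgamma; g$be1 <- bb$dbeta
  cb <- conv2d_bwd(caches$c1_in, params$W1, bb$dx)
  g$W1 <- cb$dw; g$b1 <- cb$db
  g
}

# ---- Adam ------------------------------------------------------------------

adamInit <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adamStep <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  opt$t <- opt$t + 1L
  corr1 <- 1 - beta1^opt$t
  corr2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    gmat <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * gmat
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * gmat^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / corr1) / (sqrt(opt$v[[nm]] / corr2) + eps)
  }
  list(params = params, opt = opt)
}

# ---- data plumbing ---------------------------------------------------------

resolveImages <- function(x, dir, col = "file") {
  if (is.data.frame(x)) {
    lapply(x[[col]], function(f) loadImage(file.path(dir, f)) / 255)
  } else {
    lapply(x, function(m) {
      stopifnot(is.matrix(m))
      if (max(m) > 1) m / 255 else m
    })
  }
}

# ---- training --------------------------------------------------------------

#' Train the CNN classifier
#'
#' Seeded Adam on softmax cross-entropy. A validation subset
#' (`val_fraction`, stratified) of the training images is held out and the
#' best-checkpoint weights by validation accuracy are returned; the full
#' per-iteration trace (loss, batch accuracy, sparse validation accuracy)
#' is stored on the net.
#'
#' @param net An untrained [buildClassifierNet()].
#' @param x Either a manifest `data.frame` (columns `file`, `class`; rows
#'   already restricted to the training split) or a list of image matrices.
#' @param labels Class labels in {0, 1, 2} (taken from `x$class` when `x`
#'   is a manifest). All configured classes must be present.
#' @param dir Image directory when `x` is a manifest.
#' @return The fitted [EchoNet-class].
#' @export
trainClassifierNet <- function(net, x, labels = NULL, dir = NULL) {
  stopifnot(is(net, "EchoNet"), net@cfg$task == "classify")
  cfg <- net@cfg
  imgs <- resolveImages(x, dir)
  if (is.data.frame(x)) labels <- x$class
  y <- as.integer(factor(labels, levels = sort(unique(labels))))
  if (length(unique(y)) < cfg$n_classes)
    stop("a class is missing from the training split")
  n <- length(imgs)
  params <- net@params; state <- net@state
  opt <- adamInit(params)
  trace <- data.frame(iteration = integer(0), loss = numeric(0),
                      accuracy = numeric(0), val_accuracy = numeric(0))
  withr::with_seed(cfg$seed, {
    val_idx <- integer(0)
    if (cfg$val_fraction > 0 && n >= 5L) {
      val_idx <- unlist(lapply(split(seq_len(n), y), function(ix)
        sample(ix)[seq_len(max(1L, floor(cfg$val_fraction * length(ix))))]))
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    best <- list(acc = -Inf, params = params, state = state)
    full_batch <- cfg$batch_size >= length(tr_idx)
    for (it in seq_len(cfg$iterations)) {
      bidx <- if (full_batch) tr_idx else tr_idx[sample.int(length(tr_idx), cfg$batch_size)]
      xb <- batchArray(imgs, bidx)
      fw <- fwdClassifier(params, state, xb, training = TRUE)
      state <- fw$state
      B <- length(bidx)
      Y <- matrix(0, B, cfg$n_classes)
      Y[cbind(seq_len(B), y[bidx])] <- 1
      loss <- -mean(log(pmax(fw$probs[Y == 1], 1e-12)))
      acc <- mean(max.col(fw$probs) == y[bidx])
      dlogits <- (fw$probs - Y) / B
      grads <- bwdClassifier(params, fw$caches, dlogits)
      st <- adamStep(params, grads, opt, cfg$lr)
      params <- st$params; opt <- st$opt
      val_acc <- NA_real_
      if (length(val_idx) && (it %% cfg$eval_every == 0L || it == cfg$iterations)) {
        vp <- fwdClassifier(params, state, batchArray(imgs, val_idx),
                            training = FALSE)
        val_acc <- mean(max.col(vp$probs) == y[val_idx])
        if (val_acc >= best$acc)
          best <- list(acc = val_acc, params = params, state = state)
      }
      trace[nrow(trace) + 1L, ] <- list(it, loss, acc, val_acc)
    }
    if (length(val_idx) && best$acc > -Inf) {
      params <- best$params; state <- best$state
    }
  })
  initialize(net, params = params, state = state, fitted = TRUE, trace = trace)
}

#' Predict class probabilities with the CNN classifier
#'
#' @param net A fitted classifier [EchoNet-class].
#' @param x Manifest `data.frame`, list of matrices, or single matrix.
#' @param dir Image directory for manifests.
#' @return Numeric matrix, one row per image, columns summing to 1.
#' @export
predictClasses <- function(net, x, dir = NULL) {
  stopifnot(is(net, "EchoNet"), net@cfg$task == "classify")
  if (is.matrix(x)) x <- list(x)
  imgs <- resolveImages(x, dir)
  out <- matrix(0, length(imgs), net@cfg$n_classes)
  step <- 16L
  for (s in seq(1L, length(imgs), by = step)) {
    idx <- s:min(s + step - 1L, length(imgs))
    fw <- fwdClassifier(net@params, net@state, batchArray(imgs, idx),
                        training = FALSE)
    out[idx, ] <- fw$probs
  }
  colnames(out) <- as.character(seq_len(net@cfg$n_classes) - 1L)
  out
}

#' Train the CNN segmenter
#'
#' Seeded Adam on per-pixel weighted softmax cross-entropy (tumor pixels are
#' up-weighted by `pos_weight` because they are rare). Validation uses mean
#' per-image pixel accuracy; best-checkpoint weights are returned.
#'
#' @param net An untrained [buildSegmenterNet()].
#' @param x Manifest `data.frame` (columns `file`, `mask_file`) or list of
#'   image matrices.
#' @param masks List of ground-truth masks when `x` is a list.
#' @param dir Image directory for manifests.
#' @return The fitted [EchoNet-class].
#' @export
trainSegmenterNet <- function(net, x, masks = NULL, dir = NULL) {
  stopifnot(is(net, "EchoNet"), net@cfg$task == "segment")
  cfg <- net@cfg
  imgs <- resolveImages(x, dir)
  if (is.data.frame(x)) {
    if (!"mask_file" %in% names(x) || anyNA(x$mask_file))
      stop("masks must be available for all training images")
    masks <- lapply(x$mask_file, function(f) loadImage(file.path(dir, f)))
  }
  if (length(masks) != length(imgs)) stop("image/mask count mismatch")
  targets <- lapply(masks, function(m) {
    if (!all(dim(m) == dim(imgs[[1]]))) stop("image/mask shape mismatch")
    decodeMask(m)$tumor * 1
  })
  pos_weight <- cfg$pos_weight
  if (is.null(pos_weight)) {
    n_pos <- sum(vapply(targets, sum, numeric(1)))
    n_tot <- length(targets) * length(targets[[1]])
    pos_weight <- if (n_pos == 0) 1 else min(20, (n_tot - n_pos) / n_pos)
  }
  n <- length(imgs)
  params <- net@params; state <- net@state
  opt <- adamInit(params)
  trace <- data.frame(iteration = integer(0), loss = numeric(0),
                      accuracy = numeric(0), val_accuracy = numeric(0))
  withr::with_seed(cfg$seed, {
    val_idx <- if (cfg$val_fraction > 0 && n >= 5L)
      sample.int(n, max(1L, floor(cfg$val_fraction * n))) else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)
    best <- list(acc = -Inf, params = params, state = state)
    full_batch <- cfg$batch_size >= length(tr_idx)
    H <- nrow(imgs[[1]])
    for (it in seq_len(cfg$iterations)) {
      bidx <- if (full_batch) tr_idx else tr_idx[sample.int(length(tr_idx), cfg$batch_size)]
      xb <- batchArray(imgs, bidx)
      fw <- fwdSegmenter(params, state, xb, training = TRUE)
      state <- fw$state
      B <- length(bidx)
      yb <- array(0, dim = c(H, ncol(imgs[[1]]), 1L, B))
      for (k in seq_len(B)) yb[, , 1L, k] <- targets[[bidx[k]]]
      w <- yb * (pos_weight - 1) + 1
      wsum <- sum(w)
      pt <- fw$p_tumor
      loss <- -sum(w * (yb * log(pmax(pt, 1e-12)) +
                        (1 - yb) * log(pmax(1 - pt, 1e-12)))) / wsum
      acc <- mean(((pt >= 0.5) * 1) == yb)
      dlogits <- fw$logits * 0
      dlogits[, , 2L, ] <- w * (pt - yb) / wsum
      dlogits[, , 1L, ] <- -dlogits[, , 2L, , drop = FALSE]
      grads <- bwdSegmenter(params, fw$caches, dlogits)
      st <- adamStep(params, grads, opt, cfg$lr)
      params <- st$params; opt <- st$opt
      val_acc <- NA_real_
      if (length(val_idx) && (it %% cfg$eval_every == 0L || it == cfg$iterations)) {
        vp <- fwdSegmenter(params, state, batchArray(imgs, val_idx),
                           training = FALSE)
        vy <- array(0, dim = dim(vp$p_tumor))
        for (k in seq_along(val_idx)) vy[, , 1L, k] <- targets[[val_idx[k]]]
        val_acc <- mean(((vp$p_tumor >= 0.5) * 1) == vy)
        if (val_acc >= best$acc)
          best <- list(acc = val_acc, params = params, state = state)
      }
      trace[nrow(trace) + 1L, ] <- list(it, loss, acc, val_acc)
    }
    if (length(val_idx) && best$acc > -Inf) {
      params <- best$params; state <- best$state
    }
  })
  initialize(net, params = params, state = state, fitted = TRUE, trace = trace)
}

#' Predict a tumor-probability map and thresholded mask
#'
#' @param net A fitted segmenter [EchoNet-class].
#' @param img Grayscale matrix (0..255 or already scaled to \[0, 1\]).
#' @param threshold Probability cutoff; pixels with probability `>=
#'   threshold` become tumor (255), others 0.
#' @return List with `prob` (numeric matrix in \[0, 1\]) and `mask`
#'   (integer matrix over {0, 255}).
#' @export
predictMask <- function(net, img, threshold = 0.5) {
  stopifnot(is(net, "EchoNet"), net@cfg$task == "segment")
  if (!net@fitted) stop("segmenter has not been trained")
  imgs <- resolveImages(list(img), NULL)
  fw <- fwdSegmenter(net@params, net@state, batchArray(imgs, 1L),
                     training = FALSE)
  prob <- fw$p_tumor[, , 1L, 1L]
  mask <- matrix(0L, nrow(prob), ncol(prob))
  mask[prob >= threshold] <- 255L
  list(prob = prob, mask = mask)
}
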