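## The filtering model: a compact convolutional network with three
## convolution blocks (3x3 kernel over the 3 input channels, ReLU, 2x2
## max-pool), two fully connected layers each followed by dropout, and a
## single sigmoid output unit. Implemented directly on BLAS matrix algebra
## (im2col convolutions); training uses Adam on binary cross-entropy.

#' Network architecture specification
#'
#' @param conv_channels widths of the three convolution blocks.
#' @param fc widths of the two fully connected layers.
#' @param dropout dropout rate applied after each FC layer during training.
#' @return a list consumed by \code{\link{buildNetwork}}.
#' @export
networkSpec <- function(conv_channels = c(16L, 32L, 64L),
                        fc = c(256L, 64L), dropout = 0.5) {
  stopifnot(length(conv_channels) == 3L, length(fc) == 2L,
            dropout >= 0, dropout < 1)
  list(conv_channels = as.integer(conv_channels), fc = as.integer(fc),
       dropout = dropout)
}

## ---- low-level layers ------------------------------------------------

## X: (N, H, W, C) -> (N*H*W, 9C) patch matrix, zero padding 1.
im2col3 <- function(X) {
  d <- dim(X); N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  Xp <- array(0, c(N, H + 2L, W + 2L, C))
  Xp[, 2:(H + 1L), 2:(W + 1L), ] <- X
  cols <- matrix(0, N * H * W, 9L * C)
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    block <- Xp[, di + seq_len(H), dj + seq_len(W), , drop = FALSE]
    dim(block) <- c(N * H * W, C)
    cols[, ((k - 1L) * C + 1L):(k * C)] <- block
  }
  cols
}

col2im3 <- function(dcols, dims) {
  N <- dims[1]; H <- dims[2]; W <- dims[3]; C <- dims[4]
  dXp <- array(0, c(N, H + 2L, W + 2L, C))
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    block <- dcols[, ((k - 1L) * C + 1L):(k * C), drop = FALSE]
    dim(block) <- c(N, H, W, C)
    dXp[, di + seq_len(H), dj + seq_len(W), ] <-
      dXp[, di + seq_len(H), dj + seq_len(W), , drop = FALSE] + block
  }
  dXp[, 2:(H + 1L), 2:(W + 1L), , drop = FALSE]
}

convForward <- function(X, W, b) {
  d <- dim(X)
  cols <- im2col3(X)
  Y <- cols %*% W
  Y <- Y + rep(b, each = nrow(Y))
  dim(Y) <- c(d[1], d[2], d[3], length(b))
  list(Y = Y, cols = cols, xdim = d)
}

convBackward <- function(dY, cache, W) {
  f <- ncol(W)
  dYm <- dY; dim(dYm) <- c(prod(dim(dY)[1:3]), f)
  dW <- crossprod(cache$cols, dYm)
  db <- colSums(dYm)
  dX <- col2im3(dYm %*% t(W), cache$xdim)
  list(dX = dX, dW = dW, db = db)
}

poolForward <- function(X) {
  d <- dim(X); N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  io <- seq(1L, H, 2L); jo <- seq(1L, W, 2L)
  a <- X[, io, jo, , drop = FALSE]; b <- X[, io + 1L, jo, , drop = FALSE]
  cc <- X[, io, jo + 1L, , drop = FALSE]; dd <- X[, io + 1L, jo + 1L, , drop = FALSE]
  M <- pmax(a, b, cc, dd)
  s1 <- a == M; s2 <- !s1 & b == M; s3 <- !s1 & !s2 & cc == M
  s4 <- !s1 & !s2 & !s3
  list(Y = M, sel = list(s1, s2, s3, s4), xdim = d)
}

poolBackward <- function(dY, cache) {
  d <- cache$xdim
  io <- seq(1L, d[2], 2L); jo <- seq(1L, d[3], 2L)
  dX <- array(0, d)
  dX[, io, jo, ] <- dY * cache$sel[[1]]
  dX[, io + 1L, jo, ] <- dY * cache$sel[[2]]
  dX[, io, jo + 1L, ] <- dY * cache$sel[[3]]
  dX[, io + 1L, jo + 1L, ] <- dY * cache$sel[[4]]
  dX
}

#' Build an untrained classifier
#'
#' Weight initialization is He-scaled Gaussian under the given seed, so an
#' untrained network is a deterministic function of (spec, dims, seed).
#'
#' @param image_dims integer height/width; both must be divisible by 8
#'   (three 2x2 pooling stages).
#' @param spec a \code{\link{networkSpec}}.
#' @param seed RNG seed for initialization.
#' @return a \linkS4class{CNNClassifier}.
#' @export
buildNetwork <- function(image_dims = c(128L, 128L), spec = networkSpec(),
                         seed = 1L) {
  image_dims <- as.integer(image_dims)
  if (any(image_dims %% 8L != 0L))
    stop("image dimensions (", paste(image_dims, collapse = "x"),
         ") must be divisible by 8: three 2x2 max-pool stages each halve them")
  set.seed(seed)
  ch <- c(3L, spec$conv_channels)
  w <- list()
  for (k in 1:3) {
    fan_in <- 9L * ch[k]
    w[[paste0("Wc", k)]] <- matrix(stats::rnorm(fan_in * ch[k + 1L], 0,
                                                sqrt(2 / fan_in)),
                                   fan_in, ch[k + 1L])
    w[[paste0("bc", k)]] <- rep(0, ch[k + 1L])
  }
  flat <- (image_dims[1] %/% 8L) * (image_dims[2] %/% 8L) * ch[4]
  dims <- c(flat, spec$fc, 1L)
  for (k in 1:3) {
    w[[paste0("Wf", k)]] <- matrix(stats::rnorm(dims[k] * dims[k + 1L], 0,
                                                sqrt(2 / dims[k])),
                                   dims[k], dims[k + 1L])
    w[[paste0("bf", k)]] <- rep(0, dims[k + 1L])
  }
  new("CNNClassifier", spec = spec, inputDim = image_dims, weights = w,
      trained = FALSE)
}

#' Number of trainable parameters
#' @param classifier a \linkS4class{CNNClassifier}.
#' @export
parameterCount <- function(classifier) {
  sum(vapply(classifier@weights, length, 1L))
}

## Forward pass. X: (N, H, W, 3) in [0, 1]. In training mode dropout masks
## are drawn from the current RNG stream and caches are kept for backprop.
netForward <- function(w, spec, X, train = FALSE) {
  caches <- list()
  A <- X
  for (k in 1:3) {
    cv <- convForward(A, w[[paste0("Wc", k)]], w[[paste0("bc", k)]])
    R <- cv$Y; mask <- R > 0; R[!mask] <- 0
    pl <- poolForward(R)
    caches[[k]] <- list(conv = cv, relu = mask, pool = pl)
    A <- pl$Y
  }
  d <- dim(A); N <- d[1]
  flat <- A; dim(flat) <- c(N, prod(d[2:4]))
  caches$flatdim <- d
  h <- flat
  fc <- list()
  for (k in 1:2) {
    z <- h %*% w[[paste0("Wf", k)]] + rep(w[[paste0("bf", k)]], each = N)
    m <- z > 0; z[!m] <- 0
    if (train && spec$dropout > 0) {
      dm <- matrix(stats::rbinom(length(z), 1L, 1 - spec$dropout),
                   nrow(z), ncol(z)) / (1 - spec$dropout)
      z <- z * dm
    } else dm <- NULL
    fc[[k]] <- list(input = h, relu = m, drop = dm)
    h <- z
  }
  zout <- h %*% w$Wf3 + rep(w$bf3, each = N)
  caches$fc <- fc
  caches$flat <- flat
  caches$last <- h
  list(z = as.numeric(zout), caches = caches)
}

netBackward <- function(w, spec, dz, caches) {
  N <- length(dz)
  g <- list()
  dh <- matrix(dz, N, 1)
  g$Wf3 <- crossprod(caches$last, dh)
  g$bf3 <- colSums(dh)
  dh <- dh %*% t(w$Wf3)
  for (k in 2:1) {
    fc <- caches$fc[[k]]
    if (!is.null(fc$drop)) dh <- dh * fc$drop
    dh <- dh * fc$relu
    g[[paste0("Wf", k)]] <- crossprod(fc$input, dh)
    g[[paste0("bf", k)]] <- colSums(dh)
    dh <- dh %*% t(w[[paste0("Wf", k)]])
  }
  d <- caches$flatdim
  dA <- dh; dim(dA) <- d
  for (k in 3:1) {
    cc <- caches[[k]]
    dR <- poolBackward(dA, cc$pool)
    dR <- dR * cc$relu
    cb <- convBackward(dR, cc$conv, w[[paste0("Wc", k)]])
    g[[paste0("Wc", k)]] <- cb$dW
    g[[paste0("bc", k)]] <- cb$db
    dA <- cb$dX
  }
  g
}

sigmoid <- function(z) 1 / (1 + exp(-z))

bceLoss <- function(z, y) {
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

stackImages <- function(images) {
  if (is(images, "SVImageSet")) images <- imageList(images)
  d <- dim(images[[1]])
  A <- array(unlist(images, use.names = FALSE), c(d, length(images)))
  aperm(A, c(4, 1, 2, 3)) / 255
}

#' Train the filtering model
#'
#' Minimizes binary cross-entropy with Adam under a fixed seed; a stratified
#' held-out fraction tracks AUC per epoch and the best-AUC weights are kept.
#' Fully reproducible given the seed.
#'
#' @param classifier an untrained (or warm) \linkS4class{CNNClassifier}.
#' @param images a labeled \linkS4class{SVImageSet} with both classes.
#' @param valid_fraction held-out fraction (default 0.2).
#' @param epochs training epochs (default 30).
#' @param batch_size minibatch size (default 64).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed RNG seed controlling split, shuffling, dropout.
#' @return list(classifier = best-AUC model, report = data.frame(epoch, loss,
#'   auc), seed).
#' @export
trainClassifier <- function(classifier, images, valid_fraction = 0.2,
                            epochs = 30L, batch_size = 64L, lr = 1e-3,
                            seed = 1L) {
  y <- ifelse(imageLabels(images) == "positive", 1, 0)
  if (any(is.na(y))) stop("training images must be labeled")
  if (length(unique(y)) < 2L)
    stop("training set has a single class (all ",
         if (y[1] == 1) "positive" else "negative",
         "); a binary classifier cannot be fit")
  d <- dim(imageList(images)[[1]])
  if (!all(d[1:2] == classifier@inputDim))
    stop("image size ", paste(d[1:2], collapse = "x"),
         " does not match network input ",
         paste(classifier@inputDim, collapse = "x"))
  X <- stackImages(images)
  n <- length(y)
  set.seed(seed)
  vidx <- unlist(lapply(split(seq_len(n), y), function(idx)
    sample(idx, max(1L, round(length(idx) * valid_fraction)))))
  tidx <- setdiff(seq_len(n), vidx)
  Xt <- X[tidx, , , , drop = FALSE]; yt <- y[tidx]
  Xv <- X[vidx, , , , drop = FALSE]; yv <- y[vidx]

  w <- classifier@weights
  mom <- lapply(w, function(p) p * 0)
  vel <- lapply(w, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
  report <- data.frame(epoch = integer(), loss = numeric(), auc = numeric())
  best_auc <- -Inf; best_loss <- Inf; best_w <- w
  for (ep in seq_len(epochs)) {
    ord <- sample(length(yt))
    losses <- numeric(0)
    for (b0 in seq(1L, length(ord), by = batch_size)) {
      idx <- ord[b0:min(b0 + batch_size - 1L, length(ord))]
      Xb <- Xt[idx, , , , drop = FALSE]; yb <- yt[idx]
      fw <- netForward(w, classifier@spec, Xb, train = TRUE)
      losses <- c(losses, bceLoss(fw$z, yb))
      dz <- (sigmoid(fw$z) - yb) / length(yb)
      g <- netBackward(w, classifier@spec, dz, fw$caches)
      t <- t + 1
      for (nm in names(w)) {
        mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * g[[nm]]
        vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * g[[nm]]^2
        mhat <- mom[[nm]] / (1 - b1^t)
        vhat <- vel[[nm]] / (1 - b2^t)
        w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    sv <- batchScores(w, classifier@spec, Xv)
    a <- if (length(unique(yv)) > 1L) {
      as.numeric(pROC::auc(pROC::roc(yv, sv, levels = c(0, 1),
                                     direction = "<", quiet = TRUE)))
    } else NA_real_
    report <- rbind(report, data.frame(epoch = ep, loss = mean(losses), auc = a))
    ## best held-out AUC; ties broken toward lower training loss so later,
    ## better-calibrated weights win once AUC saturates
    if (!is.na(a) &&
        (a > best_auc || (a == best_auc && mean(losses) < best_loss))) {
      best_auc <- a; best_loss <- mean(losses); best_w <- w
    }
  }
  out <- classifier
  out@weights <- best_w
  out@trained <- TRUE
  list(classifier = out, report = report, seed = seed, best_auc = best_auc)
}

batchScores <- function(w, spec, X, chunk = 256L) {
  n <- dim(X)[1]
  out <- numeric(n)
  for (b0 in seq(1L, n, by = chunk)) {
    idx <- b0:min(b0 + chunk - 1L, n)
    out[idx] <- sigmoid(netForward(w, spec, X[idx, , , , drop = FALSE])$z)
  }
  out
}

#' Score images with a trained classifier
#'
#' @param classifier a trained \linkS4class{CNNClassifier}.
#' @param images an \linkS4class{SVImageSet} or list of pixel arrays.
#' @return numeric scores in (0, 1), one per image, in input order.
#' @export
predictScores <- function(classifier, images) {
  if (is(images, "SVImageSet") && !length(imageList(images)))
    return(numeric(0))
  X <- stackImages(images)
  if (!all(dim(X)[2:3] == classifier@inputDim))
    stop("image size ", paste(dim(X)[2:3], collapse = "x"),
         " does not match checkpoint input ",
         paste(classifier@inputDim, collapse = "x"))
  batchScores(classifier@weights, classifier@spec, X)
}

#' Keep/drop decision per candidate
#'
#' A candidate is kept when its score strictly exceeds the threshold (a score
#' of exactly 0.5 is dropped). Decisions are invariant to batch size and
#' ordering.
#'
#' @param classifier a trained \linkS4class{CNNClassifier}.
#' @param images an \linkS4class{SVImageSet}.
#' @param threshold decision threshold (default 0.5).
#' @return data.frame(id, score, keep) in input order.
#' @export
predictFilter <- function(classifier, images, threshold = 0.5) {
  scores <- predictScores(classifier, images)
  ids <- if (is(images, "SVImageSet")) imageIDs(images)
         else as.character(seq_along(scores))
  data.frame(id = ids, score = scores, keep = scores > threshold,
             stringsAsFactors = FALSE)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the architecture spec and input dimensions; loading
#' reconstructs a classifier whose predictions are identical to the saved
#' one.
#'
#' @param classifier a \linkS4class{CNNClassifier}.
#' @param path checkpoint file.
#' @export
saveCheckpoint <- function(classifier, path) {
  saveRDS(list(spec = classifier@spec, inputDim = classifier@inputDim,
               weights = classifier@weights, trained = classifier@trained),
          path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  x <- readRDS(path)
  new("CNNClassifier", spec = x$spec, inputDim = x$inputDim,
      weights = x$weights, trained = x$trained)
}
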