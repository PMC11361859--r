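# Compact convolutional regressor for PSR images, written directly in
# vectorized base R: convolutions are im2col gathers followed by BLAS
# matrix multiplies, so training a 32x32 model stays CPU-friendly.
# Layout conventions: a batch activation is a B x (H*H*C) matrix whose
# columns are channel blocks of H*H pixels in column-major spatial order.

# Gather indices mapping each of the H*H output positions x 9 kernel taps
# into a zero-padded (H+2)^2 image.
make_conv_index <- function(H) {
  Hp <- H + 2L
  r <- rep(seq_len(H), times = H)
  cc <- rep(seq_len(H), each = H)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  idx <- matrix(0L, H * H, 9L)
  for (k in 1:9)
    idx[, k] <- (r + 1L + offs$dr[k]) + (cc + offs$dc[k]) * Hp
  interior <- (r + 1L) + cc * Hp
  list(idx = idx, interior = interior, Hp2 = Hp * Hp)
}

# 2x2 average-pooling gather indices (each input pixel belongs to one pool).
make_pool_index <- function(H) {
  H2 <- H %/% 2L
  r2 <- rep(seq_len(H2), times = H2)
  c2 <- rep(seq_len(H2), each = H2)
  lapply(list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)), function(d) {
    (2L * r2 - 1L + d[1]) + (2L * c2 - 2L + d[2]) * H
  })
}

conv_forward <- function(A, W, b, H, Cin, ci_idx) {
  B <- nrow(A); HW <- H * H
  Cout <- ncol(W)
  Cmat <- matrix(0, B * HW, 9L * Cin)
  col <- 0L
  for (ci in seq_len(Cin)) {
    P <- matrix(0, B, ci_idx$Hp2)
    P[, ci_idx$interior] <- A[, ((ci - 1L) * HW + 1L):(ci * HW)]
    for (k in 1:9) {
      col <- col + 1L
      Cmat[, col] <- as.vector(P[, ci_idx$idx[, k]])
    }
  }
  Z <- Cmat %*% W
  Z <- Z + rep(b, each = nrow(Z))
  list(A = matrix(Z, B, HW * Cout), Cmat = Cmat)
}

conv_backward <- function(dA, Cmat, W, B, H, Cin, ci_idx, need_dinput = TRUE) {
  HW <- H * H
  Cout <- ncol(W)
  dZ <- matrix(dA, B * HW, Cout)
  out <- list(dW = crossprod(Cmat, dZ), db = colSums(dZ))
  if (need_dinput) {
    dCmat <- dZ %*% t(W)
    dIn <- matrix(0, B, HW * Cin)
    col <- 0L
    for (ci in seq_len(Cin)) {
      dP <- matrix(0, B, ci_idx$Hp2)
      for (k in 1:9) {
        col <- col + 1L
        dP[, ci_idx$idx[, k]] <- dP[, ci_idx$idx[, k]] +
          matrix(dCmat[, col], B, HW)
      }
      dIn[, ((ci - 1L) * HW + 1L):(ci * HW)] <- dP[, ci_idx$interior]
    }
    out$dIn <- dIn
  }
  out
}

pool_forward <- function(A, H, C, pidx) {
  B <- nrow(A); HW <- H * H; HW2 <- HW %/% 4L
  O <- matrix(0, B, HW2 * C)
  for (c in seq_len(C)) {
    blk <- A[, ((c - 1L) * HW + 1L):(c * HW), drop = FALSE]
    O[, ((c - 1L) * HW2 + 1L):(c * HW2)] <-
      (blk[, pidx[[1]]] + blk[, pidx[[2]]] +
       blk[, pidx[[3]]] + blk[, pidx[[4]]]) / 4
  }
  O
}

pool_backward <- function(dO, H, C, pidx) {
  B <- nrow(dO); HW <- H * H; HW2 <- HW %/% 4L
  dA <- matrix(0, B, HW * C)
  for (c in seq_len(C)) {
    dblk <- dO[, ((c - 1L) * HW2 + 1L):(c * HW2), drop = FALSE] / 4
    for (p in pidx)
      dA[, (c - 1L) * HW + p] <- dblk
  }
  dA
}

#' Model specification for the PSR-image T:R regressor
#'
#' Architecture: two 3x3 convolution blocks (`filters[1]` then `filters[2]`
#' feature maps, ReLU, 2x average pooling each), a dense ReLU layer with
#' `dense_units` units, and a scalar linear output whose predictions are
#' clamped at zero (T:R is non-negative).  Trained with squared-error loss
#' and Adam.
#'
#' @param filters feature-map counts of the two convolution blocks
#' @param dense_units width of the dense layer
#' @param epochs,batch_size,lr training schedule (Adam)
#' @param folds cross-validation fold count (default 10)
#' @param seed integer seed controlling weight initialization, batch order
#'   and fold assignment; training is deterministic given the seed
#' @return an object of class `model_spec`
#' @export
model_spec <- function(filters = c(16L, 32L), dense_units = 64L,
                       epochs = 10L, batch_size = 128L, lr = 1e-3,
                       folds = 10L, seed = 1L) {
  stop_if_not(length(filters) == 2 && all(filters >= 1),
              "filters must give two positive counts")
  structure(list(filters = as.integer(filters),
                 dense_units = as.integer(dense_units),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr = lr, folds = as.integer(folds), seed = as.integer(seed)),
            class = "model_spec")
}

init_cnn_params <- function(grid_size, spec) {
  F1 <- spec$filters[1]; F2 <- spec$filters[2]
  flat <- (grid_size %/% 4L)^2 * F2
  he <- function(nr, nc, fan_in) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  list(W1 = he(9L, F1, 9),            b1 = numeric(F1),
       W2 = he(9L * F1, F2, 9 * F1),  b2 = numeric(F2),
       W3 = he(flat, spec$dense_units, flat), b3 = numeric(spec$dense_units),
       W4 = he(spec$dense_units, 1L, spec$dense_units), b4 = numeric(1L))
}

cnn_geometry <- function(grid_size) {
  H1 <- as.integer(grid_size)
  H2 <- H1 %/% 2L
  list(H1 = H1, H2 = H2,
       ci1 = make_conv_index(H1), ci2 = make_conv_index(H2),
       pi1 = make_pool_index(H1), pi2 = make_pool_index(H2))
}

cnn_forward <- function(par, X, geom, F1, F2, keep = FALSE) {
  c1 <- conv_forward(X, par$W1, par$b1, geom$H1, 1L, geom$ci1)
  m1 <- c1$A > 0
  a1 <- c1$A * m1
  p1 <- pool_forward(a1, geom$H1, F1, geom$pi1)
  c2 <- conv_forward(p1, par$W2, par$b2, geom$H2, F1, geom$ci2)
  m2 <- c2$A > 0
  a2 <- c2$A * m2
  p2 <- pool_forward(a2, geom$H2, F2, geom$pi2)
  z3 <- p2 %*% par$W3 + rep(par$b3, each = nrow(p2))
  m3 <- z3 > 0
  a3 <- z3 * m3
  yhat <- as.vector(a3 %*% par$W4 + par$b4)
  if (!keep) return(yhat)
  list(yhat = yhat, c1 = c1, m1 = m1, p1 = p1, c2 = c2, m2 = m2, p2 = p2,
       m3 = m3, a3 = a3)
}

cnn_backward <- function(par, X, y, geom, F1, F2) {
  B <- nrow(X)
  fw <- cnn_forward(par, X, geom, F1, F2, keep = TRUE)
  dy <- matrix(2 * (fw$yhat - y) / B, ncol = 1)
  g <- list()
  g$W4 <- crossprod(fw$a3, dy); g$b4 <- sum(dy)
  da3 <- (dy %*% t(par$W4)) * fw$m3
  g$W3 <- crossprod(fw$p2, da3); g$b3 <- colSums(da3)
  dp2 <- da3 %*% t(par$W3)
  da2 <- pool_backward(dp2, geom$H2, F2, geom$pi2) * fw$m2
  bk2 <- conv_backward(da2, fw$c2$Cmat, par$W2, B, geom$H2, F1, geom$ci2,
                       need_dinput = TRUE)
  g$W2 <- bk2$dW; g$b2 <- bk2$db
  da1 <- pool_backward(bk2$dIn, geom$H1, F1, geom$pi1) * fw$m1
  bk1 <- conv_backward(da1, fw$c1$Cmat, par$W1, B, geom$H1, 1L, geom$ci1,
                       need_dinput = FALSE)
  g$W1 <- bk1$dW; g$b1 <- bk1$db
  list(grads = g, loss = mean((fw$yhat - y)^2))
}

#' Fit the convolutional T:R regressor
#'
#' Low-level fit on an image matrix (rows = flattened images).  Inputs are
#' standardized by the global pixel mean/SD of the training set (stored in
#' the model and reapplied at prediction time).
#'
#' @param X numeric matrix, one flattened `grid^2` image per row
#' @param y numeric vector of T:R labels
#' @param spec a [model_spec()]
#' @param grid_size image side length (inferred from `ncol(X)` when NULL)
#' @return an object of class `tr_model`
#' @export
fit_cnn <- function(X, y, spec = model_spec(), grid_size = NULL) {
  stop_if_not(nrow(X) == length(y) && nrow(X) >= 1,
              "X rows and labels must match and be non-empty")
  g <- as.integer(grid_size %||% round(sqrt(ncol(X))))
  stop_if_not(g * g == ncol(X), "ncol(X) must be a square grid size")
  F1 <- spec$filters[1]; F2 <- spec$filters[2]
  geom <- cnn_geometry(g)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  mu <- mean(X); sdv <- stats::sd(as.vector(X))
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  Xn <- (X - mu) / sdv

  par <- init_cnn_params(g, spec)
  mstate <- lapply(par, function(p) p * 0)
  vstate <- lapply(par, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0
  n <- nrow(Xn)
  bs <- min(spec$batch_size, n)
  for (ep in seq_len(spec$epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = bs)) {
      ii <- ord[start:min(start + bs - 1, n)]
      bw <- cnn_backward(par, Xn[ii, , drop = FALSE], y[ii], geom, F1, F2)
      step <- step + 1
      for (p in names(par)) {
        gr <- bw$grads[[p]]
        mstate[[p]] <- b1 * mstate[[p]] + (1 - b1) * gr
        vstate[[p]] <- b2 * vstate[[p]] + (1 - b2) * gr^2
        mhat <- mstate[[p]] / (1 - b1^step)
        vhat <- vstate[[p]] / (1 - b2^step)
        par[[p]] <- par[[p]] - spec$lr * mhat / (sqrt(vhat) + eps)
      }
    }
  }
  structure(list(par = par, spec = spec, grid_size = g, norm = c(mu = mu, sd = sdv)),
            class = "tr_model")
}

#' @export
print.tr_model <- function(x, ...) {
  cat(sprintf(
    "<tr_model> conv(%d)-conv(%d)-dense(%d) on %dx%d PSR images (%d weights)\n",
    x$spec$filters[1], x$spec$filters[2], x$spec$dense_units,
    x$grid_size, x$grid_size,
    sum(vapply(x$par, length, integer(1)))))
  invisible(x)
}

#' Predict T:R for a matrix of flattened images
#'
#' @param object a `tr_model`
#' @param X image matrix (rows = flattened images, same grid as training)
#' @param ... unused
#' @return numeric vector of non-negative T:R predictions (linear output
#'   clamped at zero)
#' @export
predict.tr_model <- function(object, X, ...) {
  if (is.list(X) && !is.matrix(X)) X <- images_to_matrix(X)
  if (ncol(X) != object$grid_size^2)
    stop("shape error: image size does not match the model input (",
         object$grid_size, "x", object$grid_size, ")", call. = FALSE)
  Xn <- (X - object$norm["mu"]) / object$norm["sd"]
  yhat <- cnn_forward(object$par, Xn, cnn_geometry(object$grid_size),
                      object$spec$filters[1], object$spec$filters[2])
  pmax(0, yhat)
}
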