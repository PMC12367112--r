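# Minimal CNN engine for the patch classifiers.
#
# The canonical architecture is fixed: four 3x3 "same"-padded convolutions
# (filters 32, 32, 64, 64), each followed by ReLU and 2x2 max pooling, then
# flatten, a ReLU dense layer, dropout, and a 2-unit linear output trained
# with softmax cross-entropy. Convolutions are evaluated as im2col gathers
# followed by a single BLAS matrix product; gradients are exact analytic
# backpropagation (checked against finite differences in the test suite).
# Images are arrays (H, W, C, N); weights are matrices with conv rows
# ordered kernel-position-within-channel, matching the im2col columns.

nn_new <- function(input_px, channels = 3L, filters = c(32L, 32L, 64L, 64L),
                   dense_units = 512L, n_classes = 2L, dropout_rate = 0.5,
                   seed = 1L) {
  if (input_px %% 2^length(filters) != 0) {
    stop("input_px must be divisible by ", 2^length(filters))
  }
  with_seed(seed, {
    w <- list()
    cin <- channels
    px <- input_px
    for (l in seq_along(filters)) {
      cout <- filters[l]
      k <- 9L * cin
      w[[paste0("cW", l)]] <- matrix(stats::rnorm(k * cout, 0, sqrt(2 / k)),
                                     k, cout)
      w[[paste0("cb", l)]] <- numeric(cout)
      cin <- cout
      px <- px %/% 2L
    }
    flat <- px * px * cin
    w$dW1 <- matrix(stats::rnorm(flat * dense_units, 0, sqrt(2 / flat)),
                    flat, dense_units)
    w$db1 <- numeric(dense_units)
    w$dW2 <- matrix(stats::rnorm(dense_units * n_classes, 0,
                                 sqrt(2 / dense_units)),
                    dense_units, n_classes)
    w$db2 <- numeric(n_classes)
    structure(list(input_px = as.integer(input_px),
                   channels = as.integer(channels),
                   filters = as.integer(filters),
                   dense_units = as.integer(dense_units),
                   n_classes = as.integer(n_classes),
                   dropout_rate = dropout_rate, w = w,
                   idx_cache = new.env(parent = emptyenv())),
              class = "nestmargin_net")
  })
}

# im2col gather indices for one image: (H*W) x (9*C) positions into the
# zero-padded (H+2) x (W+2) x C array, output positions row-index-fastest.
conv_index_single <- function(H, W, C) {
  Hp <- H + 2L
  pos_i <- rep(seq_len(H), times = W)
  pos_j <- rep(seq_len(W), each = H)
  di <- rep(0:2, times = 3)
  dj <- rep(0:2, each = 3)
  M <- matrix(0L, H * W, 9L * C)
  plane_len <- Hp * (W + 2L)
  for (k in 1:9) {
    plane <- (pos_i + di[k]) + Hp * (pos_j + dj[k] - 1L)
    for (ch in seq_len(C)) {
      M[, (ch - 1L) * 9L + k] <- plane + (ch - 1L) * plane_len
    }
  }
  M
}

conv_index_batch <- function(net, H, W, C, N) {
  key <- sprintf("H%d_C%d_N%d", H, C, N)
  cached <- net$idx_cache[[key]]
  if (!is.null(cached)) return(cached)
  M <- conv_index_single(H, W, C)
  img_len <- (H + 2L) * (W + 2L) * C
  IDX <- M[rep(seq_len(H * W), N), , drop = FALSE] +
    rep((0:(N - 1L)) * img_len, each = H * W)
  net$idx_cache[[key]] <- IDX
  IDX
}

pad_batch <- function(A) {
  d <- dim(A)
  P <- array(0, c(d[1L] + 2L, d[2L] + 2L, d[3L], d[4L]))
  P[2:(d[1L] + 1L), 2:(d[2L] + 1L), , ] <- A
  P
}

# (H*W*N) x F matrix (rows: position-within-image fastest, then image)
# -> array (H, W, F, N)
mat_to_maps <- function(M, H, W, N) {
  F <- ncol(M)
  A <- array(M, c(H, W, N, F))
  aperm(A, c(1L, 2L, 4L, 3L))
}

maps_to_mat <- function(A) {
  d <- dim(A)
  M <- aperm(A, c(1L, 2L, 4L, 3L))
  dim(M) <- c(d[1L] * d[2L] * d[4L], d[3L])
  M
}

pool_fw <- function(A) {
  d <- dim(A)
  H2 <- d[1L] %/% 2L; W2 <- d[2L] %/% 2L
  dim(A) <- c(2L, H2, 2L, W2, d[3L], d[4L])
  sub <- function(a, b) {
    x <- A[a, , b, , , , drop = FALSE]
    dim(x) <- c(H2, W2, d[3L], d[4L])
    x
  }
  x11 <- sub(1L, 1L); x21 <- sub(2L, 1L)
  x12 <- sub(1L, 2L); x22 <- sub(2L, 2L)
  out <- pmax(x11, x21, x12, x22)
  list(out = out, x11 = x11, x21 = x21, x12 = x12, x22 = x22)
}

pool_bw <- function(pc, dOut) {
  m11 <- pc$x11 == pc$out
  m21 <- (pc$x21 == pc$out) & !m11
  m12 <- (pc$x12 == pc$out) & !m11 & !m21
  m22 <- (pc$x22 == pc$out) & !m11 & !m21 & !m12
  d <- dim(pc$out)
  G <- array(0, c(2L, d[1L], 2L, d[2L], d[3L], d[4L]))
  G[1L, , 1L, , , ] <- dOut * m11
  G[2L, , 1L, , , ] <- dOut * m21
  G[1L, , 2L, , , ] <- dOut * m12
  G[2L, , 2L, , , ] <- dOut * m22
  dim(G) <- c(2L * d[1L], 2L * d[2L], d[3L], d[4L])
  G
}

softmax_rows <- function(Z) {
  Zm <- Z - apply(Z, 1L, max)
  E <- exp(Zm)
  E / rowSums(E)
}

# Forward pass. cache = "none" (predict), "gradcam" (dense-side cache plus
# last conv activations), or "train" (everything needed for backprop).
nn_forward <- function(net, X, train = FALSE, cache = "none",
                       dropout_mask = NULL) {
  d <- dim(X)
  if (length(d) == 3L) {
    dim(X) <- c(d, 1L)
    d <- dim(X)
  }
  N <- d[4L]
  nconv <- length(net$filters)
  conv_cache <- if (cache == "train") vector("list", nconv) else NULL
  A <- X
  cin <- net$channels
  for (l in seq_len(nconv)) {
    H <- dim(A)[1L]; W <- dim(A)[2L]
    P <- pad_batch(A)
    Pflat <- as.vector(P)
    IDX <- conv_index_batch(net, H, W, cin, N)
    cols <- Pflat[IDX]
    dim(cols) <- dim(IDX)
    Z <- cols %*% net$w[[paste0("cW", l)]]
    Z <- Z + rep(net$w[[paste0("cb", l)]], each = nrow(Z))
    mask <- Z > 0
    Z[!mask] <- 0
    Amaps <- mat_to_maps(Z, H, W, N)
    pc <- pool_fw(Amaps)
    if (cache == "train") {
      conv_cache[[l]] <- list(cols = cols, mask = mask, pool = pc,
                              H = H, W = W, cin = cin, N = N)
    }
    last_pool <- pc
    last_act <- if (cache %in% c("train", "gradcam") && l == nconv) {
      Amaps
    } else {
      NULL
    }
    A <- pc$out
    cin <- net$filters[l]
  }
  dflat <- dim(A)
  flat <- prod(dflat[1:3])
  dim(A) <- c(flat, N)
  V <- t(A)
  Z1 <- V %*% net$w$dW1
  Z1 <- Z1 + rep(net$w$db1, each = N)
  dmask1 <- Z1 > 0
  A1 <- Z1
  A1[!dmask1] <- 0
  drop_mask <- NULL
  A1d <- A1
  if (train && net$dropout_rate > 0) {
    drop_mask <- if (is.null(dropout_mask)) {
      matrix(stats::runif(length(A1)) >= net$dropout_rate, nrow(A1), ncol(A1))
    } else {
      dropout_mask
    }
    A1d <- A1 * drop_mask / (1 - net$dropout_rate)
  }
  logits <- A1d %*% net$w$dW2
  logits <- logits + rep(net$w$db2, each = N)
  out <- list(logits = logits, probs = softmax_rows(logits), N = N)
  if (cache != "none") {
    out$V <- V
    out$dmask1 <- dmask1
    out$A1d <- A1d
    out$drop_mask <- drop_mask
    out$last_pool <- last_pool
    out$last_act <- last_act
    out$map_dim <- dflat[1:3]
    out$conv_cache <- conv_cache
  }
  out
}

# Backprop dlogits (N x n_classes) through the dense head and the final
# pooling, returning the gradient w.r.t. the last conv layer's post-ReLU
# activations (H/8, W/8, F, N). Used by Grad-CAM.
nn_grad_last_conv <- function(net, fw, dlogits) {
  dA1d <- dlogits %*% t(net$w$dW2)
  if (!is.null(fw$drop_mask)) {
    dA1d <- dA1d * fw$drop_mask / (1 - net$dropout_rate)
  }
  dZ1 <- dA1d * fw$dmask1
  dV <- dZ1 %*% t(net$w$dW1)
  dA <- t(dV)
  dim(dA) <- c(fw$map_dim, fw$N)
  pool_bw(fw$last_pool, dA)
}

nn_backward <- function(net, fw, Y) {
  N <- fw$N
  dlogits <- (fw$probs - Y) / N
  g <- list()
  g$dW2 <- crossprod(fw$A1d, dlogits)
  g$db2 <- colSums(dlogits)
  dA1d <- dlogits %*% t(net$w$dW2)
  if (!is.null(fw$drop_mask)) {
    dA1d <- dA1d * fw$drop_mask / (1 - net$dropout_rate)
  }
  dZ1 <- dA1d * fw$dmask1
  g$dW1 <- crossprod(fw$V, dZ1)
  g$db1 <- colSums(dZ1)
  dV <- dZ1 %*% t(net$w$dW1)
  dA <- t(dV)
  dim(dA) <- c(fw$map_dim, N)
  nconv <- length(net$filters)
  for (l in nconv:1) {
    cc <- fw$conv_cache[[l]]
    dAct <- pool_bw(cc$pool, dA)          # grad w.r.t. post-ReLU maps
    dZmat <- maps_to_mat(dAct)
    dZmat <- dZmat * cc$mask              # through ReLU
    g[[paste0("cW", l)]] <- crossprod(cc$cols, dZmat)
    g[[paste0("cb", l)]] <- colSums(dZmat)
    if (l > 1L) {
      dcols <- dZmat %*% t(net$w[[paste0("cW", l)]])
      IDX <- conv_index_batch(net, cc$H, cc$W, cc$cin, cc$N)
      acc <- rowsum(as.vector(dcols), group = as.vector(IDX))
      padded_len <- (cc$H + 2L) * (cc$W + 2L) * cc$cin * cc$N
      dP <- numeric(padded_len)
      dP[as.integer(rownames(acc))] <- acc
      dim(dP) <- c(cc$H + 2L, cc$W + 2L, cc$cin, cc$N)
      dA <- dP[2:(cc$H + 1L), 2:(cc$W + 1L), , , drop = FALSE]
    }
  }
  g
}

nn_loss <- function(probs, Y) {
  -mean(log(pmax(rowSums(probs * Y), 1e-12)))
}

adam_init <- function(w) {
  list(m = lapply(w, function(x) x * 0),
       v = lapply(w, function(x) x * 0), t = 0L)
}

adam_step <- function(w, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(g)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(w = w, st = st)
}

nn_predict_probs <- function(net, X, batch_size = 64L) {
  d <- dim(X)
  if (length(d) == 3L) dim(X) <- c(d, 1L)
  N <- dim(X)[4L]
  out <- matrix(0, N, net$n_classes)
  i <- 1L
  while (i <= N) {
    j <- min(i + batch_size - 1L, N)
    fw <- nn_forward(net, X[, , , i:j, drop = FALSE], train = FALSE)
    out[i:j, ] <- fw$probs
    i <- j + 1L
  }
  out
}

nn_train <- function(net, X, y, epochs = 10L, batch_size = 32L, lr = 1e-4,
                     Xval = NULL, yval = NULL, patience = Inf,
                     seed = 1L, verbose = FALSE) {
  N <- dim(X)[4L]
  Y <- diag(net$n_classes)[y + 1L, , drop = FALSE]
  st <- adam_init(net$w)
  hist <- NULL
  best_val <- Inf
  stale <- 0L
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      ep_loss <- 0
      ep_correct <- 0L
      i <- 1L
      while (i <= N) {
        j <- min(i + batch_size - 1L, N)
        b <- ord[i:j]
        fw <- nn_forward(net, X[, , , b, drop = FALSE], train = TRUE,
                         cache = "train")
        ep_loss <- ep_loss + nn_loss(fw$probs, Y[b, , drop = FALSE]) *
          length(b)
        ep_correct <- ep_correct +
          sum(max.col(fw$probs) == y[b] + 1L)
        g <- nn_backward(net, fw, Y[b, , drop = FALSE])
        upd <- adam_step(net$w, g, st, lr)
        net$w <- upd$w
        st <- upd$st
        i <- j + 1L
      }
      val_loss <- NA_real_; val_acc <- NA_real_
      if (!is.null(Xval)) {
        pv <- nn_predict_probs(net, Xval)
        Yv <- diag(net$n_classes)[yval + 1L, , drop = FALSE]
        val_loss <- nn_loss(pv, Yv)
        val_acc <- mean(max.col(pv) == yval + 1L)
      }
      hist <- rbind(hist, data.frame(
        epoch = ep, loss = ep_loss / N, accuracy = ep_correct / N,
        val_loss = val_loss, val_accuracy = val_acc))
      if (verbose) {
        message(sprintf(
          "epoch %d: loss %.4f acc %.3f val_loss %.4f val_acc %.3f",
          ep, ep_loss / N, ep_correct / N, val_loss, val_acc))
      }
      if (!is.null(Xval) && is.finite(patience)) {
        if (val_loss < best_val - 1e-6) {
          best_val <- val_loss
          stale <- 0L
        } else {
          stale <- stale + 1L
          if (stale >= patience) break
        }
      }
    }
  })
  list(net = net, history = hist)
}
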