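#' Describe the canonical patch-classification CNN
#'
#' The patch classifier is a VGG-style binary CNN: four 3x3 "same"-padded
#' convolutions with 32, 32, 64, and 64 filters, each followed by 2x2 max
#' pooling that halves both spatial dimensions, then flatten, a 512-unit
#' dense layer, dropout, and a 2-unit output. At the canonical 512 px RGB
#' input the layer parameter counts are 896, 9,248, 18,496, 36,928 for
#' the convolutions, 33,554,944 and 1,026 for the dense layers, and
#' 33,621,538 in total. Counts are computed by closed form, so the
#' architecture is checkable without training.
#'
#' @param input_px Input side length in pixels; must be divisible by 16.
#' @param channels Input channels (default 3, RGB).
#' @param filters Convolution filter counts.
#' @param dense_units Hidden dense layer width.
#' @param n_classes Output units (2 for the binary classifiers).
#' @return A `model_summary`: data.frame of layers (name, kind, output
#'   shape, parameter count) with attribute `total_params`.
#' @examples
#' m <- build_model()
#' attr(m, "total_params")  # 33621538
#' @export
build_model <- function(input_px = 512, channels = 3,
                        filters = c(32, 32, 64, 64), dense_units = 512,
                        n_classes = 2) {
  if (input_px %% 2^length(filters) != 0) {
    stop("input_px must be divisible by ", 2^length(filters))
  }
  rows <- list()
  px <- input_px
  cin <- channels
  for (l in seq_along(filters)) {
    cout <- filters[l]
    rows[[length(rows) + 1L]] <- data.frame(
      name = if (l == 1) "conv2d" else sprintf("conv2d_%d", l - 1),
      kind = "conv", out_h = px, out_w = px, out_units = cout,
      params = layer_param_count("conv", c_in = cin, c_out = cout))
    px <- px %/% 2L
    rows[[length(rows) + 1L]] <- data.frame(
      name = if (l == 1) "max_pooling2d" else
        sprintf("max_pooling2d_%d", l - 1),
      kind = "maxpool", out_h = px, out_w = px, out_units = cout,
      params = 0L)
    cin <- cout
  }
  flat <- px * px * cin
  rows[[length(rows) + 1L]] <- data.frame(
    name = "flatten", kind = "flatten", out_h = NA, out_w = NA,
    out_units = flat, params = 0L)
  rows[[length(rows) + 1L]] <- data.frame(
    name = "dense", kind = "dense", out_h = NA, out_w = NA,
    out_units = dense_units,
    params = layer_param_count("dense", n_in = flat, n_out = dense_units))
  rows[[length(rows) + 1L]] <- data.frame(
    name = "dropout", kind = "dropout", out_h = NA, out_w = NA,
    out_units = dense_units, params = 0L)
  rows[[length(rows) + 1L]] <- data.frame(
    name = "dense_1", kind = "dense", out_h = NA, out_w = NA,
    out_units = n_classes,
    params = layer_param_count("dense", n_in = dense_units,
                               n_out = n_classes))
  out <- do.call(rbind, rows)
  attr(out, "total_params") <- sum(out$params)
  attr(out, "input_shape") <- c(input_px, input_px, channels)
  class(out) <- c("model_summary", "data.frame")
  out
}

#' Closed-form per-layer parameter counts
#'
#' Convolutions have `kh * kw * c_in * c_out + c_out` parameters (weights
#' plus one bias per filter); dense layers `n_in * n_out + n_out`;
#' pooling, flatten, and dropout layers have none.
#'
#' @param kind One of `"conv"`, `"dense"`, `"maxpool"`, `"flatten"`,
#'   `"dropout"`.
#' @param kernel Convolution kernel `(h, w)` (default 3x3).
#' @param c_in,c_out Convolution channel counts.
#' @param n_in,n_out Dense layer fan-in / fan-out.
#' @return Integer parameter count.
#' @examples
#' layer_param_count("conv", c_in = 3, c_out = 32)        # 896
#' layer_param_count("dense", n_in = 65536, n_out = 512)  # 33554944
#' @export
layer_param_count <- function(kind, kernel = c(3, 3), c_in = NULL,
                              c_out = NULL, n_in = NULL, n_out = NULL) {
  kind <- match.arg(kind, c("conv", "dense", "maxpool", "flatten",
                            "dropout"))
  if (kind == "conv") {
    if (any(c(kernel, c_in, c_out) <= 0)) stop("dimensions must be > 0")
    return(as.integer(kernel[1] * kernel[2] * c_in * c_out + c_out))
  }
  if (kind == "dense") {
    if (any(c(n_in, n_out) <= 0)) stop("dimensions must be > 0")
    return(as.integer(n_in * n_out + n_out))
  }
  0L
}

#' @export
print.model_summary <- function(x, ...) {
  shp <- attr(x, "input_shape")
  cat(sprintf("Binary patch CNN, input (%d, %d, %d)\n",
              shp[1], shp[2], shp[3]))
  df <- as.data.frame(x)
  df$output <- ifelse(is.na(df$out_h),
                      as.character(df$out_units),
                      sprintf("%dx%dx%d", df$out_h, df$out_w, df$out_units))
  print(df[, c("name", "kind", "output", "params")], row.names = FALSE)
  cat(sprintf("Total params: %s\n",
              format(attr(x, "total_params"), big.mark = ",")))
  invisible(x)
}

as_image_stack <- function(images) {
  if (is.list(images)) {
    d <- dim(images[[1L]])
    X <- array(0, c(d, length(images)))
    for (i in seq_along(images)) X[, , , i] <- images[[i]]
    X
  } else if (length(dim(images)) == 4L) {
    images
  } else {
    stop("images must be a 4-d array (H, W, C, N) or a list of arrays")
  }
}

coerce_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.logical(labels)) labels <- as.integer(labels)
  u <- sort(unique(labels))
  if (!all(u %in% c(0L, 1L))) stop("labels must be binary (0/1)")
  as.integer(labels)
}

#' Train a binary patch classifier
#'
#' Performs a stratified 8:2 train/validation split (seeded), trains the
#' canonical CNN with Adam on softmax cross-entropy, and records
#' per-epoch training and validation loss/accuracy. Optional early
#' stopping monitors validation loss.
#'
#' @param images 4-d array `(H, W, 3, N)` or list of `H x W x 3` arrays;
#'   `H` must be divisible by 16.
#' @param labels Binary labels (0/1, logical, or 2-level factor); both
#'   classes must be present.
#' @param split Training fraction (default 0.8).
#' @param hyper Named list overriding `lr` (1e-4), `epochs` (10),
#'   `batch_size` (32), `dropout` (0.5), `patience` (2), `verbose`.
#' @param seed Seed controlling split, initialization, shuffling, dropout.
#' @return A `trained_model`: list with the fitted network, `summary`
#'   ([build_model()] at this input size), `history` (per-epoch metrics),
#'   `split_seed`, and the split index vectors.
#' @export
train_classifier <- function(images, labels, split = 0.8, hyper = list(),
                             seed = 1L) {
  X <- as_image_stack(images)
  y <- coerce_binary_labels(labels)
  N <- dim(X)[4L]
  if (length(y) != N) stop("labels length must match image count")
  if (length(unique(y)) < 2L) {
    stop("both classes must be present to train a binary classifier")
  }
  hp <- utils::modifyList(
    list(lr = 1e-4, epochs = 10L, batch_size = 32L, dropout = 0.5,
         patience = 2L, verbose = FALSE),
    hyper)
  idx_tr <- with_seed(seed, {
    unlist(lapply(split(seq_len(N), y), function(ix) {
      n_tr <- round(split * length(ix))
      n_tr <- max(1L, min(length(ix) - 1L, n_tr))
      sort(sample(ix, n_tr))
    }), use.names = FALSE)
  })
  idx_tr <- sort(idx_tr)
  idx_val <- setdiff(seq_len(N), idx_tr)
  net <- nn_new(dim(X)[1L], channels = dim(X)[3L],
                dropout_rate = hp$dropout, seed = seed)
  fit <- nn_train(net, X[, , , idx_tr, drop = FALSE], y[idx_tr],
                  epochs = hp$epochs, batch_size = hp$batch_size,
                  lr = hp$lr,
                  Xval = X[, , , idx_val, drop = FALSE],
                  yval = y[idx_val], patience = hp$patience,
                  seed = seed + 1L, verbose = hp$verbose)
  structure(list(net = fit$net, summary = build_model(dim(X)[1L]),
                 history = fit$history, split_seed = seed,
                 train_idx = idx_tr, val_idx = idx_val),
            class = "trained_model")
}

#' Initialize an untrained classifier
#'
#' Builds the canonical network with seeded He-initialized weights but no
#' training — useful for architecture checks, Grad-CAM plumbing tests at
#' full input size, and warm starts.
#'
#' @inheritParams build_model
#' @param dropout Dropout rate between the dense layers.
#' @param seed Initialization seed.
#' @return A `trained_model` with empty history.
#' @export
init_classifier <- function(input_px = 512, channels = 3, dropout = 0.5,
                            seed = 1L) {
  net <- nn_new(input_px, channels = channels, dropout_rate = dropout,
                seed = seed)
  structure(list(net = net, summary = build_model(input_px, channels),
                 history = NULL, split_seed = seed,
                 train_idx = integer(0), val_idx = integer(0)),
            class = "trained_model")
}

#' Predict class probabilities for patches
#'
#' @param model A [train_classifier()] result.
#' @param images 4-d array or list of images at the model's input size.
#' @return Numeric vector of probabilities for the positive class
#'   (label 1).
#' @export
predict_classifier <- function(model, images) {
  stopifnot(inherits(model, "trained_model"))
  X <- as_image_stack(images)
  nn_predict_probs(model$net, X)[, 2L]
}

#' ROC curve summary with AUC confidence interval
#'
#' The AUC is the Mann-Whitney probability that a positive's score
#' exceeds a negative's (ties counting one half), computed from ranks.
#' The confidence interval uses the DeLong placement-value variance by
#' default, or a seeded stratified bootstrap.
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels; both classes required.
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param conf_level Confidence level (default 0.95).
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Bootstrap seed.
#' @return A `roc_result` list: `auc`, `ci_low`, `ci_high`, `n_pos`,
#'   `n_neg`, `ci_method`.
#' @examples
#' evaluate_roc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
evaluate_roc <- function(scores, labels, ci_method = c("delong",
                                                       "bootstrap"),
                         conf_level = 0.95, n_boot = 2000L, seed = 1L) {
  ci_method <- match.arg(ci_method)
  y <- coerce_binary_labels(labels)
  if (length(scores) != length(y)) stop("scores/labels length mismatch")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  pos <- scores[y == 1L]
  neg <- scores[y == 0L]
  auc <- auc_rank(scores, y)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (ci_method == "delong") {
    # placement values: per-positive and per-negative empirical AUCs
    v10 <- vapply(pos, function(s) {
      mean((s > neg) + 0.5 * (s == neg))
    }, 0)
    v01 <- vapply(neg, function(s) {
      mean((pos > s) + 0.5 * (pos == s))
    }, 0)
    se <- sqrt(stats::var(v10) / length(pos) +
                 stats::var(v01) / length(neg))
    if (!is.finite(se)) se <- 0
    ci <- c(auc - z * se, auc + z * se)
  } else {
    ip <- which(y == 1L); ineg <- which(y == 0L)
    reps <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        bi <- c(sample(ip, replace = TRUE), sample(ineg, replace = TRUE))
        auc_rank(scores[bi], y[bi])
      }, 0)
    })
    ci <- unname(stats::quantile(reps, c((1 - conf_level) / 2,
                                         1 - (1 - conf_level) / 2)))
  }
  ci <- pmin(pmax(ci, 0), 1)
  structure(list(auc = auc, ci_low = min(ci[1], auc),
                 ci_high = max(ci[2], auc), conf_level = conf_level,
                 n_pos = length(pos), n_neg = length(neg),
                 ci_method = ci_method),
            class = "roc_result")
}

auc_rank <- function(scores, y) {
  r <- rank(scores)
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.4f (%d%% CI %.4f-%.4f, %s; %d pos / %d neg)\n",
              x$auc, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$ci_method, x$n_pos, x$n_neg))
  invisible(x)
}

#' Grad-CAM heatmap for one patch
#'
#' Gradient-weighted class activation mapping over the last convolutional
#' layer: each feature map is weighted by the spatial mean of the
#' gradient of the target class score with respect to that map, the
#' weighted sum is rectified (ReLU), and the native map (input size / 8,
#' e.g. 64 x 64 for 512 px input) is nearest-neighbor upsampled to the
#' input size for overlay.
#'
#' @param model A [train_classifier()] result.
#' @param tile `H x W x 3` array at the model's input size.
#' @param target_class Class label to explain (0 or 1).
#' @return List with `heatmap` (native resolution, nonnegative matrix),
#'   `upsampled` (input resolution), and `alpha` (per-map weights).
#' @export
grad_cam <- function(model, tile, target_class = 1L) {
  stopifnot(inherits(model, "trained_model"))
  net <- model$net
  if (!target_class %in% 0:(net$n_classes - 1L)) {
    stop("target_class must be a valid class label (0-based)")
  }
  X <- tile
  if (length(dim(X)) == 3L) dim(X) <- c(dim(X), 1L)
  fw <- nn_forward(net, X, train = FALSE, cache = "gradcam")
  dlogits <- matrix(0, 1L, net$n_classes)
  dlogits[1L, target_class + 1L] <- 1
  dA <- nn_grad_last_conv(net, fw, dlogits)   # H/8 x W/8 x F x 1
  A <- fw$last_act
  n_f <- dim(A)[3L]
  alpha <- vapply(seq_len(n_f), function(k) mean(dA[, , k, 1L]), 0)
  cam <- matrix(0, dim(A)[1L], dim(A)[2L])
  for (k in seq_len(n_f)) cam <- cam + alpha[k] * A[, , k, 1L]
  cam[cam < 0] <- 0
  fac <- dim(X)[1L] %/% nrow(cam)
  list(heatmap = cam,
       upsampled = kronecker(cam, matrix(1, fac, fac)),
       alpha = alpha)
}
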