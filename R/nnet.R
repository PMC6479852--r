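## Minimal CNN engine used by the stump detector, the desk-scale backbone and
## the fine-tuned rot classifier. Forward/backward passes are expressed as
## BLAS matrix products.
##
## Public batches are (H, W, C, N) arrays; internally activations live in
## channel-first layout (C, H, W, N), so that a convolution's (filters,
## positions x N) output matrix becomes the next layer's input by a plain
## dim<- with no transposition. Convolution runs as chunked im2col forward
## (memory-bounded for large proposal batches) and as per-kernel-offset
## accumulation backward.

## ---- layer constructors -------------------------------------------------

nn_conv <- function(filters, ksize = 3L) {
  list(type = "conv", filters = as.integer(filters), ksize = as.integer(ksize),
       lr_mult = 1)
}
nn_relu <- function() list(type = "relu", lr_mult = 1)
nn_pool <- function() list(type = "pool", lr_mult = 1)       # 2x2 max, stride 2
nn_flatten <- function() list(type = "flatten", lr_mult = 1)
nn_fc <- function(out) list(type = "fc", out = as.integer(out), lr_mult = 1)

## Initialise parameters (He) for an architecture given the input shape
## (H, W, C). Returns a "nn_net" list: layers with weights + shape metadata.
nn_init <- function(arch, input_shape, seed = 1L) {
  with_seed(seed, {
    shape <- input_shape       # c(H, W, C), or a single flat feature length
    flat <- length(input_shape) == 1L
    layers <- lapply(arch, function(l) {
      if (l$type == "conv") {
        stopifnot(!flat)
        k <- l$ksize; cin <- shape[3]
        fan_in <- k * k * cin
        l$W <- matrix(stats::rnorm(l$filters * fan_in, 0, sqrt(2 / fan_in)),
                      nrow = l$filters)
        l$b <- numeric(l$filters)
        l$cin <- cin
        shape <<- c(shape[1] - k + 1L, shape[2] - k + 1L, l$filters)
      } else if (l$type == "pool") {
        stopifnot(!flat)
        shape <<- c(shape[1] %/% 2L, shape[2] %/% 2L, shape[3])
      } else if (l$type == "flatten") {
        stopifnot(!flat)
        shape <<- prod(shape); flat <<- TRUE
      } else if (l$type == "fc") {
        stopifnot(flat)
        fan_in <- shape
        l$W <- matrix(stats::rnorm(l$out * fan_in, 0, sqrt(2 / fan_in)),
                      nrow = l$out)
        l$b <- numeric(l$out)
        shape <<- l$out
      }
      l
    })
    structure(list(layers = layers, input_shape = input_shape,
                   out_dim = shape),
              class = "nn_net")
  })
}

## ---- conv / pool on channel-first activations ---------------------------
##
## Patch packing/unpacking and pooling run in compiled code (src/conv_ops.cpp);
## weight products go through BLAS. Patch element order is (c, dy, dx) with c
## fastest; positions are column-major over (Ho, Wo), then image index. Weight
## matrix columns follow the same (c, dy, dx) order.

conv_forward <- function(l, A, keep_cache = FALSE) {
  d <- dim(A); C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  k <- l$ksize; Ho <- H - k + 1L; Wo <- W - k + 1L
  npos <- Ho * Wo
  per_img <- k * k * C * npos
  chunk <- if (keep_cache) N else max(1L, floor(3e7 / per_img))
  P_cache <- NULL
  if (chunk >= N) {
    P <- cpp_im2col(A, C, H, W, N, k)
    out_mat <- l$W %*% P + l$b
    if (keep_cache) P_cache <- P
  } else {
    out_mat <- matrix(0, nrow = l$filters, ncol = npos * N)
    for (c0 in seq(1L, N, by = chunk)) {
      cols <- c0:min(c0 + chunk - 1L, N)
      P <- cpp_im2col(A[, , , cols, drop = FALSE],
                      C, H, W, length(cols), k)
      out_mat[, (c0 - 1L) * npos + seq_len(npos * length(cols))] <-
        l$W %*% P + l$b
    }
  }
  dim(out_mat) <- c(l$filters, Ho, Wo, N)
  list(out = out_mat, A = A, P = P_cache)
}

conv_backward <- function(l, cache, dOut, need_dA = TRUE) {
  d <- dim(cache$A); C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  k <- l$ksize
  dZ <- matrix(dOut, nrow = l$filters)
  P <- cache$P %||% cpp_im2col(cache$A, C, H, W, N, k)
  dW <- tcrossprod(dZ, P)
  dA <- NULL
  if (need_dA) {
    dP <- crossprod(l$W, dZ)                   # (k*k*C, npos*N)
    dA <- cpp_col2im(dP, C, H, W, N, k)
    dim(dA) <- d
  }
  list(dA = dA, dW = dW, db = rowSums(dZ))
}

pool_forward <- function(A) {
  d <- dim(A)
  pf <- cpp_pool_fwd(A, d[1], d[2], d[3], d[4])
  out <- pf$out
  dim(out) <- c(d[1], d[2] %/% 2L, d[3] %/% 2L, d[4])
  list(out = out, code = pf$code, in_dim = d)
}

pool_backward <- function(cache, dOut) {
  d <- cache$in_dim
  dA <- cpp_pool_bwd(dOut, cache$code, d[1], d[2], d[3], d[4])
  dim(dA) <- d
  dA
}

## ---- full network forward / backward ------------------------------------

## Forward pass; `upto` stops after that many layers (for feature taps).
## X is (H, W, C, N) as seen by callers; converted to channel-first here.
nn_forward <- function(net, X, keep_cache = FALSE, upto = Inf) {
  A <- if (length(dim(X)) == 4L) aperm(X, c(3L, 1L, 2L, 4L)) else X
  caches <- if (keep_cache) vector("list", length(net$layers)) else NULL
  for (i in seq_along(net$layers)) {
    if (i > upto) break
    l <- net$layers[[i]]
    if (l$type == "conv") {
      cf <- conv_forward(l, A, keep_cache)
      if (keep_cache) caches[[i]] <- cf[c("A", "P")]
      A <- cf$out
    } else if (l$type == "relu") {
      if (keep_cache) caches[[i]] <- list(mask = A > 0)
      A <- A * (A > 0)
    } else if (l$type == "pool") {
      pf <- pool_forward(A)
      if (keep_cache) caches[[i]] <- pf[c("code", "in_dim")]
      A <- pf$out
    } else if (l$type == "flatten") {
      d <- dim(A)
      if (keep_cache) caches[[i]] <- list(in_dim = d)
      A <- matrix(A, nrow = prod(d[1:3]), ncol = d[4])
    } else if (l$type == "fc") {
      if (keep_cache) caches[[i]] <- list(A = A)
      A <- l$W %*% A + l$b
    }
  }
  list(out = A, caches = caches)
}

## Backward pass from dOut (gradient w.r.t. final output). Returns a list of
## per-layer gradients (NULL for parameterless layers).
nn_backward <- function(net, caches, dOut) {
  grads <- vector("list", length(net$layers))
  dA <- dOut
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    if (l$type == "conv") {
      g <- conv_backward(l, caches[[i]], dA, need_dA = i > 1L)
      grads[[i]] <- list(dW = g$dW, db = g$db)
      dA <- g$dA
    } else if (l$type == "relu") {
      dA <- dA * caches[[i]]$mask
    } else if (l$type == "pool") {
      dA <- pool_backward(caches[[i]], dA)
    } else if (l$type == "flatten") {
      dA <- array(dA, dim = caches[[i]]$in_dim)
    } else if (l$type == "fc") {
      A <- caches[[i]]$A
      grads[[i]] <- list(dW = tcrossprod(dA, A), db = rowSums(dA))
      dA <- crossprod(l$W, dA)
    }
  }
  grads
}

softmax_cols <- function(Z) {
  Z <- Z - matrix(apply(Z, 2, max), nrow(Z), ncol(Z), byrow = TRUE)
  E <- exp(Z)
  E / matrix(colSums(E), nrow(E), ncol(E), byrow = TRUE)
}

## Class probabilities for a batch; X is (H, W, C, N) or (features, N).
nn_predict <- function(net, X) {
  softmax_cols(nn_forward(net, X)$out)
}

#' One training-schedule step
#'
#' Describes one step of an SGD-with-momentum schedule: the learning rate,
#' the number of epochs, and the mini-batch size. Lists of steps configure
#' [detector_config()], [train_backbone()] and the fine-tuning stage.
#'
#' @param lr learning rate.
#' @param epochs epochs for this step.
#' @param batch mini-batch size.
#' @return list with `lr`, `epochs`, `batch`.
#' @export
nn_sched_step <- function(lr, epochs, batch = 16L) {
  list(lr = lr, epochs = as.integer(epochs), batch = as.integer(batch))
}

## Train with softmax cross-entropy under SGD with momentum. `y` is an
## integer class vector (1..K). `schedule` is a list of nn_sched_step()s;
## per-layer lr_mult scales the step's base rate (used to boost a freshly
## attached head during fine-tuning).
nn_train <- function(net, X, y, schedule, momentum = 0.9, seed = 1L,
                     verbose = FALSE) {
  N <- dim(X)[length(dim(X))]
  stopifnot(length(y) == N)
  K <- net$out_dim
  vel <- lapply(net$layers, function(l)
    if (!is.null(l$W)) list(vW = l$W * 0, vb = l$b * 0) else NULL)
  with_seed(seed, {
    for (st in schedule) {
      for (ep in seq_len(st$epochs)) {
        ord <- sample.int(N)
        for (b0 in seq(1L, N, by = st$batch)) {
          idx <- ord[b0:min(b0 + st$batch - 1L, N)]
          Xb <- if (length(dim(X)) == 4L) X[, , , idx, drop = FALSE]
                else X[, idx, drop = FALSE]
          fw <- nn_forward(net, Xb, keep_cache = TRUE)
          P <- softmax_cols(fw$out)
          Yb <- matrix(0, K, length(idx))
          Yb[cbind(y[idx], seq_along(idx))] <- 1
          dZ <- (P - Yb) / length(idx)
          grads <- nn_backward(net, fw$caches, dZ)
          for (i in seq_along(net$layers)) {
            if (is.null(grads[[i]])) next
            l <- net$layers[[i]]
            lr <- st$lr * l$lr_mult
            vel[[i]]$vW <- momentum * vel[[i]]$vW - lr * grads[[i]]$dW
            vel[[i]]$vb <- momentum * vel[[i]]$vb - lr * grads[[i]]$db
            net$layers[[i]]$W <- l$W + vel[[i]]$vW
            net$layers[[i]]$b <- l$b + vel[[i]]$vb
          }
        }
        if (verbose) {
          P <- nn_predict(net, X)
          acc <- mean(max.col(t(P)) == y)
          message(sprintf("  epoch %d (lr %g): train acc %.3f", ep, st$lr, acc))
        }
      }
    }
  })
  net
}

#' Save / load a trained model
#'
#' Models (detector, backbone, rot classifier) are plain R lists; they are
#' persisted with `saveRDS()` as a single file holding configuration and
#' weights together.
#'
#' @param model a model object from this package.
#' @param path file path.
#' @return `load_model()` returns the model; `save_model()` the path,
#'   invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
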