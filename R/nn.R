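# A compact 1D convolutional network for learned BLT inversion, implemented
# directly on dense linear algebra: strided 1D convolutions (im2col + GEMM),
# ReLU activations, a fully connected output read out through a sigmoid,
# binary cross-entropy (or squared-error) loss, and Adam.
#
# Shapes: batches of surface flux vectors are (B, C, L) arrays with C = 1 on
# input; convolution weights are ((kernel * in_ch) x out_ch) matrices whose
# row index runs kernel-position-fastest.

conv_out_len <- function(L, kernel, stride) {
  if (kernel > L) return(0L)
  as.integer((L - kernel) %/% stride + 1L)
}

#' Architecture specification of the 1D convolutional inverse operator
#'
#' Exactly three strided convolution layers (no pooling), a flatten, and one
#' fully connected output layer with a sigmoid read-out.
#'
#' @param conv List of three `list(out_ch, kernel, stride)` layer specs.
#' @param param_budget Soft target for the total trainable-parameter count;
#'   recorded for reporting, enforced by [default_model_spec()] when it
#'   derives a spec.
#' @return A `blt_model_spec`.
#' @export
model_spec <- function(conv, param_budget = 1e5) {
  if (length(conv) != 3) stop("the architecture uses exactly 3 conv layers")
  for (ly in conv) {
    if (!all(c("out_ch", "kernel", "stride") %in% names(ly)) ||
        any(unlist(ly[c("out_ch", "kernel", "stride")]) < 1)) {
      stop("each conv layer needs positive out_ch, kernel, stride")
    }
  }
  structure(list(conv = conv, param_budget = param_budget),
            class = "blt_model_spec")
}

#' Default architecture for a given problem size
#'
#' Strided convolutions (stride roughly the cube root of the input length
#' per layer, kernels about twice the stride) compress the surface flux
#' vector to a short sequence; the final channel count is chosen so that the
#' fully connected output layer dominates the parameter budget, i.e. the
#' flattened feature width is about `param_budget / M`.
#'
#' @param N Input length (number of surface nodes).
#' @param M Output length (number of mesh nodes).
#' @param param_budget Target total trainable parameters (default 1e5).
#' @return A `blt_model_spec`.
#' @export
default_model_spec <- function(N, M, param_budget = 1e5) {
  width <- min(max(round(param_budget / (M + 1)), 8), 128)
  s1 <- max(2L, ceiling(N^(1 / 3)))
  k1 <- min(N, 2L * s1 + 1L)
  L1 <- conv_out_len(N, k1, s1)
  s2 <- max(2L, ceiling(sqrt(L1)))
  k2 <- min(L1, 2L * s2 + 1L)
  L2 <- conv_out_len(L1, k2, s2)
  # third layer collapses the remaining sequence; final channels set the
  # flattened width
  L3 <- 1L
  c3 <- as.integer(width)
  model_spec(list(
    list(out_ch = 16L, kernel = k1, stride = s1),
    list(out_ch = 32L, kernel = k2, stride = s2),
    list(out_ch = c3, kernel = max(1L, L2), stride = max(1L, L2))),
    param_budget = param_budget)
}

init_mat <- function(nr, nc, fan_in) {
  s <- sqrt(6 / fan_in)
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

#' Build the 1D convolutional inverse operator
#'
#' @param N Input length (surface nodes).
#' @param M Output length (mesh nodes).
#' @param spec A `blt_model_spec`; default derived from `N`, `M`.
#' @param seed Seed for the fan-in-scaled uniform weight initialization.
#' @return A `blt_model` ready for [train_model()] / [predict()].
#' @export
build_1dcnn <- function(N, M, spec = default_model_spec(N, M), seed = 1) {
  stopifnot(inherits(spec, "blt_model_spec"), N >= 1, M >= 1)
  set.seed(derive_seed(seed, "init"))
  layers <- list()
  L <- as.integer(N)
  in_ch <- 1L
  for (li in seq_along(spec$conv)) {
    cv <- spec$conv[[li]]
    k <- as.integer(cv$kernel)
    s <- as.integer(cv$stride)
    Lout <- conv_out_len(L, k, s)
    if (Lout < 1) {
      stop("conv layer ", li, " (kernel ", k, ", stride ", s,
           ") reduces the sequence below length 1 (input length ", L, ")")
    }
    idx <- outer(seq.int(0L, by = s, length.out = Lout), seq_len(k), `+`)
    layers[[li]] <- list(
      type = "conv", in_ch = in_ch, out_ch = as.integer(cv$out_ch),
      kernel = k, stride = s, Lin = L, Lout = Lout, idx = idx,
      W = init_mat(k * in_ch, cv$out_ch, fan_in = k * in_ch),
      b = numeric(cv$out_ch), activation = "relu")
    L <- Lout
    in_ch <- as.integer(cv$out_ch)
  }
  flat <- L * in_ch
  layers[[length(layers) + 1]] <- list(
    type = "dense", Din = flat, Dout = as.integer(M),
    W = init_mat(flat, M, fan_in = flat), b = numeric(M),
    activation = "linear")
  structure(list(kind = "1dcnn", layers = layers, N = as.integer(N),
                 M = as.integer(M), spec = spec, init_seed = seed),
            class = "blt_model")
}

#' Build the multilayer-perceptron baseline
#'
#' A fully connected ReLU stack with sigmoid read-out, trained with the same
#' harness as the convolutional model; stands in for inverse-problem
#' simulation (IPS) reconstruction. Its parameter count grows with
#' `N * hidden[1]` and is typically far above the convolutional model's.
#'
#' @param N,M Input/output lengths.
#' @param hidden Integer vector of hidden-layer widths.
#' @param seed Initialization seed.
#' @return A `blt_model`.
#' @export
build_mlp_baseline <- function(N, M, hidden = c(512, 256), seed = 1) {
  stopifnot(N >= 1, M >= 1, all(hidden >= 1))
  set.seed(derive_seed(seed, "init-mlp"))
  dims <- c(N, hidden, M)
  layers <- lapply(seq_len(length(dims) - 1), function(i) {
    list(type = "dense", Din = as.integer(dims[i]),
         Dout = as.integer(dims[i + 1]),
         W = init_mat(dims[i], dims[i + 1], fan_in = dims[i]),
         b = numeric(dims[i + 1]),
         activation = if (i < length(dims) - 1) "relu" else "linear")
  })
  structure(list(kind = "mlp", layers = layers, N = as.integer(N),
                 M = as.integer(M), spec = list(hidden = hidden),
                 init_seed = seed),
            class = "blt_model")
}

#' Count trainable parameters
#' @param model A `blt_model` or `blt_trained_model`.
#' @return Integer count of weight and bias scalars.
#' @export
count_parameters <- function(model) {
  if (inherits(model, "blt_trained_model")) model <- model$model
  sum(vapply(model$layers, function(l) length(l$W) + length(l$b), numeric(1)))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

conv_forward <- function(layer, X) {
  B <- dim(X)[1]
  A <- X[, , as.vector(layer$idx), drop = FALSE]
  dim(A) <- c(B, layer$in_ch, layer$Lout, layer$kernel)
  A <- aperm(A, c(1, 3, 4, 2))
  dim(A) <- c(B * layer$Lout, layer$kernel * layer$in_ch)
  Z <- A %*% layer$W
  Z <- Z + rep(layer$b, each = nrow(Z))
  dim(Z) <- c(B, layer$Lout, layer$out_ch)
  out <- aperm(Z, c(1, 3, 2))
  act <- relu(out)
  list(out = act, cache = list(A = A, pre = out))
}

conv_backward <- function(layer, cache, dOut) {
  B <- dim(dOut)[1]
  dOut[cache$pre <= 0] <- 0
  dZ <- aperm(dOut, c(1, 3, 2))
  dim(dZ) <- c(B * layer$Lout, layer$out_ch)
  dW <- crossprod(cache$A, dZ)
  db <- colSums(dZ)
  dA <- dZ %*% t(layer$W)
  dim(dA) <- c(B, layer$Lout, layer$kernel, layer$in_ch)
  dX <- array(0, c(B, layer$in_ch, layer$Lin))
  for (kp in seq_len(layer$kernel)) {
    sl <- aperm(dA[, , kp, , drop = FALSE], c(1, 4, 2, 3))
    dim(sl) <- c(B, layer$in_ch, layer$Lout)
    pos <- layer$idx[, kp]
    dX[, , pos] <- dX[, , pos, drop = FALSE] + sl
  }
  list(dW = dW, db = db, dX = dX)
}

dense_forward <- function(layer, X) {
  Z <- X %*% layer$W
  Z <- Z + rep(layer$b, each = nrow(Z))
  out <- if (layer$activation == "relu") relu(Z) else Z
  list(out = out, cache = list(A = X, pre = Z))
}

dense_backward <- function(layer, cache, dOut) {
  if (layer$activation == "relu") dOut[cache$pre <= 0] <- 0
  list(dW = crossprod(cache$A, dOut), db = colSums(dOut),
       dX = dOut %*% t(layer$W))
}

# Forward pass on a (B x N) matrix of inputs; returns logits and, when
# requested, the per-layer caches needed for backpropagation.
nn_forward <- function(model, phi_mat, keep_cache = FALSE) {
  B <- nrow(phi_mat)
  caches <- if (keep_cache) vector("list", length(model$layers)) else NULL
  x <- phi_mat
  first_conv <- model$layers[[1]]$type == "conv"
  if (first_conv) {
    dim(x) <- c(B, 1L, ncol(phi_mat))
  }
  for (li in seq_along(model$layers)) {
    layer <- model$layers[[li]]
    if (layer$type == "conv") {
      fw <- conv_forward(layer, x)
    } else {
      if (!is.matrix(x)) {
        d <- dim(x)
        x <- aperm(x, c(1, 3, 2))      # (B, L, C): channel-fastest features
        dim(x) <- c(d[1], d[2] * d[3])
      }
      fw <- dense_forward(layer, x)
    }
    if (keep_cache) caches[[li]] <- fw$cache
    x <- fw$out
  }
  list(logits = x, caches = caches)
}

nn_backward <- function(model, caches, dLogits) {
  grads <- vector("list", length(model$layers))
  d <- dLogits
  conv_dims <- NULL
  for (li in rev(seq_along(model$layers))) {
    layer <- model$layers[[li]]
    if (layer$type == "dense") {
      bw <- dense_backward(layer, caches[[li]], d)
      d <- bw$dX
    } else {
      if (is.matrix(d)) {             # re-fold flatten: (B, L*C) -> (B,C,L)
        B <- nrow(d)
        dim(d) <- c(B, layer$out_ch, layer$Lout)[c(1, 3, 2)]
        d <- aperm(d, c(1, 3, 2))
      }
      bw <- conv_backward(layer, caches[[li]], d)
      d <- bw$dX
    }
    grads[[li]] <- bw[c("dW", "db")]
  }
  grads
}

# Binary cross-entropy on logits (numerically stable) and its gradient,
# averaged over batch entries and output nodes.
bce_loss <- function(logits, target) {
  n <- length(logits)
  loss <- sum(pmax(logits, 0) - logits * target + log1p(exp(-abs(logits)))) / n
  grad <- (sigmoid(logits) - target) / n
  list(loss = loss, grad = grad)
}

l2_loss <- function(logits, target) {
  n <- length(logits)
  p <- sigmoid(logits)
  list(loss = sum((p - target)^2) / n,
       grad = 2 * (p - target) * p * (1 - p) / n)
}

#' Training configuration
#'
#' Defaults follow the training protocol used throughout: Adam with
#' `lr = 0.001`, `beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`, 200 epochs,
#' batch size 32, binary cross-entropy loss, and model selection by minimum
#' validation loss.
#'
#' @param lr,beta1,beta2,eps Adam hyperparameters.
#' @param epochs,batch_size Training length and minibatch size.
#' @param loss `"bce"` (default) or `"l2"`.
#' @param seed Seed for shuffling (weight initialization is seeded by
#'   [build_1dcnn()]).
#' @return A `blt_train_config`.
#' @export
train_config <- function(lr = 0.001, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         epochs = 200, batch_size = 32,
                         loss = c("bce", "l2"), seed = 1) {
  loss <- match.arg(loss)
  stopifnot(lr > 0, beta1 > 0, beta2 > 0, eps > 0, epochs >= 1,
            batch_size >= 1)
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), loss = loss,
                 seed = as.integer(seed)),
            class = "blt_train_config")
}

adam_init <- function(model) {
  lapply(model$layers, function(l) {
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
}

adam_step <- function(model, state, grads, cfg, t) {
  b1t <- 1 - cfg$beta1^t
  b2t <- 1 - cfg$beta2^t
  for (li in seq_along(model$layers)) {
    g <- grads[[li]]
    s <- state[[li]]
    s$mW <- cfg$beta1 * s$mW + (1 - cfg$beta1) * g$dW
    s$vW <- cfg$beta2 * s$vW + (1 - cfg$beta2) * g$dW^2
    s$mb <- cfg$beta1 * s$mb + (1 - cfg$beta1) * g$db
    s$vb <- cfg$beta2 * s$vb + (1 - cfg$beta2) * g$db^2
    model$layers[[li]]$W <- model$layers[[li]]$W -
      cfg$lr * (s$mW / b1t) / (sqrt(s$vW / b2t) + cfg$eps)
    model$layers[[li]]$b <- model$layers[[li]]$b -
      cfg$lr * (s$mb / b1t) / (sqrt(s$vb / b2t) + cfg$eps)
    state[[li]] <- s
  }
  list(model = model, state = state)
}

eval_loss <- function(model, phi, X, loss_fn, chunk = 512L) {
  n <- nrow(phi)
  tot <- 0
  for (st in seq(1, n, by = chunk)) {
    en <- min(st + chunk - 1, n)
    lg <- nn_forward(model, phi[st:en, , drop = FALSE])$logits
    tot <- tot + loss_fn(lg, as.matrix(X[st:en, , drop = FALSE]))$loss *
      (en - st + 1)
  }
  tot / n
}

#' Train a model on a dataset
#'
#' Minibatch Adam with per-epoch training and validation losses recorded;
#' the returned weights are those of the epoch with minimum validation loss
#' (final epoch when the validation split is empty). Fully seeded: repeated
#' runs with the same dataset, model and configuration are identical.
#'
#' @param model A `blt_model` from [build_1dcnn()] or
#'   [build_mlp_baseline()].
#' @param dataset A `blt_dataset` with `train` (and normally `val`) splits.
#' @param cfg A [train_config()].
#' @param verbose Print progress every 25 epochs.
#' @return A `blt_trained_model`: `model` (best weights), `history`
#'   (per-epoch losses), `selected_epoch`, `cfg`, provenance.
#' @export
train_model <- function(model, dataset, cfg = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(model, "blt_model"), inherits(dataset, "blt_dataset"),
            inherits(cfg, "blt_train_config"))
  tr <- dataset$splits$train
  va <- dataset$splits$val
  if (!length(tr)) stop("dataset has an empty training split")
  if (ncol(dataset$phi) != model$N) {
    stop("model input length ", model$N, " does not match dataset surface ",
         "dimension ", ncol(dataset$phi))
  }
  loss_fn <- if (cfg$loss == "bce") bce_loss else l2_loss
  phi_tr <- dataset$phi[tr, , drop = FALSE]
  X_tr <- as.matrix(dataset$X[tr, , drop = FALSE])  # densify once
  phi_va <- dataset$phi[va, , drop = FALSE]
  X_va <- as.matrix(dataset$X[va, , drop = FALSE])
  state <- adam_init(model)
  t_step <- 0L
  hist <- data.frame(epoch = seq_len(cfg$epochs), train_loss = NA_real_,
                     val_loss = NA_real_)
  best <- list(loss = Inf, epoch = NA_integer_, layers = NULL)
  set.seed(derive_seed(cfg$seed, "shuffle"))
  n <- length(tr)
  for (ep in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0
    for (st in seq(1, n, by = cfg$batch_size)) {
      en <- min(st + cfg$batch_size - 1, n)
      bi <- perm[st:en]
      fw <- nn_forward(model, phi_tr[bi, , drop = FALSE], keep_cache = TRUE)
      lo <- loss_fn(fw$logits, X_tr[bi, , drop = FALSE])
      if (!is.finite(lo$loss)) {
        stop("non-finite loss at epoch ", ep, ", batch starting ", st,
             " (lr = ", cfg$lr, "); aborting training")
      }
      ep_loss <- ep_loss + lo$loss * length(bi)
      grads <- nn_backward(model, fw$caches, lo$grad)
      t_step <- t_step + 1L
      upd <- adam_step(model, state, grads, cfg, t_step)
      model <- upd$model
      state <- upd$state
    }
    hist$train_loss[ep] <- ep_loss / n
    if (length(va)) {
      vl <- eval_loss(model, phi_va, X_va, loss_fn)
      hist$val_loss[ep] <- vl
      if (vl < best$loss) {
        best <- list(loss = vl, epoch = ep, layers = model$layers)
      }
    }
    if (verbose && (ep %% 25 == 0 || ep == 1)) {
      message(sprintf("epoch %3d  train %.5f  val %s", ep,
                      hist$train_loss[ep],
                      if (length(va)) sprintf("%.5f", hist$val_loss[ep])
                      else "-"))
    }
  }
  if (is.null(best$layers)) {
    best <- list(loss = NA_real_, epoch = cfg$epochs, layers = model$layers)
  }
  model$layers <- best$layers
  structure(list(model = model, history = hist,
                 selected_epoch = best$epoch, cfg = cfg,
                 provenance = list(dataset_hash =
                                     dataset$provenance$config_hash,
                                   n_train = n, n_val = length(va))),
            class = "blt_trained_model")
}

#' @exportS3Method base::print
print.blt_trained_model <- function(x, ...) {
  cat("blt_trained_model (", x$model$kind, "): ",
      count_parameters(x$model), " parameters, selected epoch ",
      x$selected_epoch, " (val loss ",
      format(min(x$history$val_loss, na.rm = TRUE), digits = 4), ")\n",
      sep = "")
  invisible(x)
}

#' Predict source distributions from surface flux
#'
#' @param object A `blt_model` or `blt_trained_model`.
#' @param phi Length-N flux vector (normalized the same way as the training
#'   data) or a matrix with one sample per row.
#' @param ... Unused.
#' @return Vector (or matrix) of per-node source scores in (0, 1).
#' @export
predict.blt_model <- function(object, phi, ...) {
  v <- is.null(dim(phi))
  pm <- if (v) matrix(phi, nrow = 1) else as.matrix(phi)
  if (ncol(pm) != object$N) {
    stop("flux length ", ncol(pm), " does not match model input length ",
         object$N)
  }
  out <- sigmoid(nn_forward(object, pm)$logits)
  if (v) drop(out) else out
}

#' @export
predict.blt_trained_model <- function(object, phi, ...) {
  predict.blt_model(object$model, phi, ...)
}

#' Save / load a trained model checkpoint
#' @param trained A `blt_trained_model`.
#' @param path Checkpoint file path.
#' @return `path` (write) or the model (read).
#' @export
save_model <- function(trained, path) {
  stopifnot(inherits(trained, "blt_trained_model"))
  saveRDS(trained, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "blt_trained_model")) stop("not a model checkpoint: ",
                                              path)
  m
}
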