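# Stacked-LSTM binary classifier for multivariate physiological sequences.
#
# The network is implemented natively: a vectorized batched forward pass,
# full backpropagation through time, and Adam. A literal per-step
# gating-equation reference cell (lstm_cell_step) provides an independent
# implementation of the recurrence against which the vectorized trainer cell
# is verified.
#
# Gate order inside the stacked weight matrices is [f, i, g, o] with the
# concatenated input [h_{t-1}, x_t], i.e. z = [h, x] %*% W + b and
#   f = sigmoid(z_f), i = sigmoid(z_i), g = tanh(z_g), o = sigmoid(z_o),
#   C = f * C_prev + i * g,  h = o * tanh(C).

sigmoid <- function(x) 1 / (1 + exp(-x))

#' LSTM training configuration
#'
#' @param layers hidden units per stacked LSTM layer.
#' @param dense units of the ReLU dense layer before the sigmoid output.
#' @param dropout dropout rate in `[0, 1)` applied to each LSTM layer's
#'   output during training.
#' @param batch_norm apply batch normalization to the final hidden state.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation-loss
#'   improvement); best-validation weights are restored.
#' @return List of class `lstm_config`.
#' @export
lstm_config <- function(layers = c(64, 32), dense = 16, dropout = 0.5,
                        batch_norm = TRUE, learning_rate = 1e-3,
                        batch_size = 16, max_epochs = 200, patience = 20) {
  stopifnot(all(layers >= 1), dense >= 1, dropout >= 0, dropout < 1,
            learning_rate > 0, batch_size >= 1, max_epochs >= 1, patience >= 0)
  structure(list(layers = as.integer(layers), dense = as.integer(dense),
                 dropout = dropout, batch_norm = isTRUE(batch_norm),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience)),
            class = "lstm_config")
}

#' Reference LSTM cell step (gating equations)
#'
#' Literal single-vector implementation of the gate recurrence:
#' `f = sigmoid(Wf [h, x] + bf)`, `i = sigmoid(Wi [h, x] + bi)`,
#' `ctilde = tanh(Wc [h, x] + bc)`, `C = f * C_prev + i * ctilde`,
#' `o = sigmoid(Wo [h, x] + bo)`, `h = o * tanh(C)`. Used as the independent
#' oracle for the vectorized trainer cell.
#'
#' @param x input vector (length D).
#' @param state list with `h` and `C` vectors (length H).
#' @param weights list with `Wf`, `Wi`, `Wc`, `Wo` (each H x (H + D), acting
#'   on `c(h, x)`) and `bf`, `bi`, `bc`, `bo` (length H).
#' @return List: `h`, `C`, and gate activations `f`, `i`, `o`, `ctilde`.
#' @export
lstm_cell_step <- function(x, state, weights) {
  hx <- c(state$h, x)
  H <- length(state$h)
  stopifnot(ncol(weights$Wf) == length(hx), length(state$C) == H)
  f <- sigmoid(drop(weights$Wf %*% hx) + weights$bf)
  i <- sigmoid(drop(weights$Wi %*% hx) + weights$bi)
  ctilde <- tanh(drop(weights$Wc %*% hx) + weights$bc)
  C <- f * state$C + i * ctilde
  o <- sigmoid(drop(weights$Wo %*% hx) + weights$bo)
  h <- o * tanh(C)
  list(h = h, C = C, f = f, i = i, o = o, ctilde = ctilde)
}

# Vectorized forward pass of one LSTM layer over a batch.
# X: list over t of n x D matrices. Returns states and caches for BPTT.
lstm_layer_forward <- function(X, W, b) {
  Tn <- length(X)
  n <- nrow(X[[1]])
  H <- length(b) / 4L
  h <- matrix(0, n, H); C <- matrix(0, n, H)
  bm <- matrix(b, n, 4L * H, byrow = TRUE)
  st <- list(f = vector("list", Tn), i = vector("list", Tn),
             g = vector("list", Tn), o = vector("list", Tn),
             C = vector("list", Tn), h = vector("list", Tn))
  for (t in seq_len(Tn)) {
    z <- cbind(h, X[[t]]) %*% W + bm
    f <- sigmoid(z[, 1:H, drop = FALSE])
    i <- sigmoid(z[, H + 1:H, drop = FALSE])
    g <- tanh(z[, 2L * H + 1:H, drop = FALSE])
    o <- sigmoid(z[, 3L * H + 1:H, drop = FALSE])
    C <- f * C + i * g
    h <- o * tanh(C)
    st$f[[t]] <- f; st$i[[t]] <- i; st$g[[t]] <- g; st$o[[t]] <- o
    st$C[[t]] <- C; st$h[[t]] <- h
  }
  st
}

# BPTT through one layer. dH: list over t of gradients w.r.t. the layer's
# hidden outputs (zeros where unused). Returns dW, db, dX (list over t).
lstm_layer_backward <- function(X, W, st, dH) {
  Tn <- length(X)
  n <- nrow(X[[1]])
  H <- ncol(st$h[[1]])
  D <- nrow(W) - H
  dW <- matrix(0, nrow(W), ncol(W)); db <- numeric(4L * H)
  dX <- vector("list", Tn)
  dh_next <- matrix(0, n, H); dC_next <- matrix(0, n, H)
  for (t in rev(seq_len(Tn))) {
    f <- st$f[[t]]; i <- st$i[[t]]; g <- st$g[[t]]; o <- st$o[[t]]
    tc <- tanh(st$C[[t]])
    dh <- dH[[t]] + dh_next
    do_ <- dh * tc
    dC <- dC_next + dh * o * (1 - tc^2)
    Cprev <- if (t > 1L) st$C[[t - 1L]] else matrix(0, n, H)
    hprev <- if (t > 1L) st$h[[t - 1L]] else matrix(0, n, H)
    df <- dC * Cprev
    di <- dC * g
    dg <- dC * i
    dC_next <- dC * f
    dZ <- cbind(df * f * (1 - f), di * i * (1 - i),
                dg * (1 - g^2), do_ * o * (1 - o))
    inp <- cbind(hprev, X[[t]])
    dW <- dW + crossprod(inp, dZ)
    db <- db + colSums(dZ)
    dinp <- dZ %*% t(W)
    dh_next <- dinp[, 1:H, drop = FALSE]
    dX[[t]] <- dinp[, H + 1:D, drop = FALSE]
  }
  list(dW = dW, db = db, dX = dX)
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Build an (untrained) LSTM classifier
#'
#' Stacked LSTM layers, optional batch normalization of the final hidden
#' state, dropout, a ReLU dense layer, and a sigmoid output unit. Forget-gate
#' biases are initialized to 1.
#'
#' @param cfg an [lstm_config()].
#' @param V number of input features per time step.
#' @param seed integer seed for weight initialization.
#' @return An object of class `lstm_model`.
#' @export
lstm_build <- function(cfg, V, seed = 1L) {
  stopifnot(inherits(cfg, "lstm_config"), V >= 1)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  p <- list()
  D <- V
  for (l in seq_along(cfg$layers)) {
    H <- cfg$layers[l]
    p[[paste0("l", l, ".W")]] <- glorot(D + H, 4L * H)
    b <- numeric(4L * H)
    b[1:H] <- 1  # forget-gate bias
    p[[paste0("l", l, ".b")]] <- b
    D <- H
  }
  if (cfg$batch_norm) {
    p[["bn.gamma"]] <- rep(1, D)
    p[["bn.beta"]] <- rep(0, D)
  }
  p[["d1.W"]] <- glorot(D, cfg$dense)
  p[["d1.b"]] <- numeric(cfg$dense)
  p[["d2.W"]] <- glorot(cfg$dense, 1L)
  p[["d2.b"]] <- 0
  structure(list(params = p, cfg = cfg, V = as.integer(V),
                 bn_stats = list(mean = rep(0, D), var = rep(1, D)),
                 trained = FALSE, history = NULL),
            class = "lstm_model")
}

#' Trainable parameter count of an LSTM model
#' @param model an [lstm_build()] result.
#' @return Integer number of trainable scalars.
#' @export
lstm_parameter_count <- function(model) {
  stopifnot(inherits(model, "lstm_model"))
  sum(vapply(model$params, length, 0L))
}

tensor_to_xy <- function(tensor) {
  vals <- tensor$values
  n <- dim(vals)[1]; Tn <- dim(vals)[2]
  X <- lapply(seq_len(Tn), function(t) matrix(vals[, t, ], nrow = n))
  list(X = X, y = as.numeric(tensor$labels == "cancer"), n = n)
}

# Full network forward. Returns probabilities and (optionally) caches.
lstm_forward <- function(model, X, training = FALSE, cache = FALSE,
                         bn_momentum = 0.9) {
  p <- model$params; cfg <- model$cfg
  n <- nrow(X[[1]])
  caches <- list(inputs = list(), states = list(), masks = list())
  cur <- X
  for (l in seq_along(cfg$layers)) {
    W <- p[[paste0("l", l, ".W")]]; b <- p[[paste0("l", l, ".b")]]
    st <- lstm_layer_forward(cur, W, b)
    out <- st$h
    if (training && cfg$dropout > 0) {
      keep <- 1 - cfg$dropout
      masks <- lapply(out, function(m)
        matrix(stats::rbinom(length(m), 1L, keep), nrow(m), ncol(m)) / keep)
      out <- mapply(`*`, out, masks, SIMPLIFY = FALSE)
      caches$masks[[l]] <- masks
    }
    caches$inputs[[l]] <- cur
    caches$states[[l]] <- st
    cur <- out
  }
  hT <- cur[[length(cur)]]
  bn <- NULL
  if (cfg$batch_norm) {
    eps <- 1e-5
    if (training) {
      mu <- colMeans(hT)
      va <- colMeans(hT^2) - mu^2
      model$bn_stats$mean <- bn_momentum * model$bn_stats$mean +
        (1 - bn_momentum) * mu
      model$bn_stats$var <- bn_momentum * model$bn_stats$var +
        (1 - bn_momentum) * va
    } else {
      mu <- model$bn_stats$mean
      va <- model$bn_stats$var
    }
    ivstd <- 1 / sqrt(va + eps)
    xc <- sweep(hT, 2L, mu)
    xhat <- sweep(xc, 2L, ivstd, `*`)
    xb <- sweep(sweep(xhat, 2L, p[["bn.gamma"]], `*`), 2L, p[["bn.beta"]], `+`)
    bn <- list(xc = xc, xhat = xhat, ivstd = ivstd)
  } else {
    xb <- hT
  }
  a1pre <- sweep(xb %*% p[["d1.W"]], 2L, p[["d1.b"]], `+`)
  a1 <- pmax(a1pre, 0)
  zout <- a1 %*% p[["d2.W"]] + p[["d2.b"]]
  prob <- sigmoid(drop(zout))
  res <- list(prob = prob, model = model)
  if (cache) {
    res$cache <- c(caches, list(hT = hT, bn = bn, xb = xb, a1pre = a1pre,
                                a1 = a1, n = n))
  }
  res
}

# Gradients of mean binary cross-entropy w.r.t. all trainable parameters.
lstm_backward <- function(model, X, y, fw) {
  p <- model$params; cfg <- model$cfg; ca <- fw$cache
  n <- ca$n
  g <- list()
  dz <- matrix((fw$prob - y) / n, n, 1L)
  g[["d2.W"]] <- crossprod(ca$a1, dz)
  g[["d2.b"]] <- sum(dz)
  da1 <- dz %*% t(p[["d2.W"]])
  da1 <- da1 * (ca$a1pre > 0)
  g[["d1.W"]] <- crossprod(ca$xb, da1)
  g[["d1.b"]] <- colSums(da1)
  dxb <- da1 %*% t(p[["d1.W"]])
  if (cfg$batch_norm) {
    bn <- ca$bn
    g[["bn.gamma"]] <- colSums(dxb * bn$xhat)
    g[["bn.beta"]] <- colSums(dxb)
    dxhat <- sweep(dxb, 2L, p[["bn.gamma"]], `*`)
    dvar <- colSums(dxhat * bn$xc) * (-0.5) * bn$ivstd^3
    dmu <- -colSums(dxhat) * bn$ivstd - dvar * 2 * colMeans(bn$xc)
    dhT <- sweep(dxhat, 2L, bn$ivstd, `*`) +
      sweep(bn$xc, 2L, dvar * 2 / n, `*`) +
      matrix(dmu / n, n, length(dmu), byrow = TRUE)
  } else {
    dhT <- dxb
  }
  Tn <- length(X)
  nl <- length(cfg$layers)
  # gradient w.r.t. each layer's (post-dropout) outputs
  dOut <- lapply(seq_len(Tn), function(t) matrix(0, n, cfg$layers[nl]))
  dOut[[Tn]] <- dhT
  for (l in rev(seq_along(cfg$layers))) {
    # convert post-dropout gradient to pre-dropout
    if (length(ca$masks) >= l && !is.null(ca$masks[[l]]))
      dOut <- mapply(`*`, dOut, ca$masks[[l]], SIMPLIFY = FALSE)
    bl <- lstm_layer_backward(ca$inputs[[l]], p[[paste0("l", l, ".W")]],
                              ca$states[[l]], dOut)
    g[[paste0("l", l, ".W")]] <- bl$dW
    g[[paste0("l", l, ".b")]] <- bl$db
    dOut <- bl$dX
  }
  g
}

bce_loss <- function(prob, y) {
  prob <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -mean(y * log(prob) + (1 - y) * log(1 - prob))
}

#' Train an LSTM classifier
#'
#' Adam minibatch training with binary cross-entropy loss and early stopping
#' on validation loss; the weights of the best validation epoch are restored.
#' Deterministic given the seed.
#'
#' @param model an [lstm_build()] model (or `NULL` to build from `cfg`).
#' @param train a `cohort_tensor` (already standardized/augmented).
#' @param val a `cohort_tensor` used for early stopping.
#' @param cfg an [lstm_config()] (used when `model` is `NULL`).
#' @param seed integer seed (initialization, shuffling, dropout).
#' @return The fitted `lstm_model`, with a `history` data frame
#'   (`epoch`, `train_loss`, `val_loss`).
#' @export
lstm_train <- function(model = NULL, train, val, cfg = lstm_config(),
                       seed = 1L) {
  stopifnot(inherits(train, "cohort_tensor"), inherits(val, "cohort_tensor"))
  V <- dim(train$values)[3]
  if (is.null(model)) model <- lstm_build(cfg, V, seed = seed)
  cfg <- model$cfg
  tr <- tensor_to_xy(train)
  va <- tensor_to_xy(val)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed + 1L)

  mom1 <- lapply(model$params, function(x) x * 0)
  mom2 <- lapply(model$params, function(x) x * 0)
  step <- 0L
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  best_loss <- Inf; best <- model; wait <- 0L
  hist <- list()

  for (epoch in seq_len(cfg$max_epochs)) {
    idx <- sample.int(tr$n)
    batches <- split(idx, ceiling(seq_along(idx) / cfg$batch_size))
    ep_loss <- 0
    for (bi in batches) {
      Xb <- lapply(tr$X, function(m) m[bi, , drop = FALSE])
      yb <- tr$y[bi]
      fw <- lstm_forward(model, Xb, training = TRUE, cache = TRUE)
      model <- fw$model  # running BN stats
      loss <- bce_loss(fw$prob, yb)
      if (!is.finite(loss))
        stop("NaN/Inf training loss at epoch ", epoch, call. = FALSE)
      ep_loss <- ep_loss + loss * length(bi)
      grads <- lstm_backward(model, Xb, yb, fw)
      step <- step + 1L
      for (nm in names(model$params)) {
        mom1[[nm]] <- beta1 * mom1[[nm]] + (1 - beta1) * grads[[nm]]
        mom2[[nm]] <- beta2 * mom2[[nm]] + (1 - beta2) * grads[[nm]]^2
        mhat <- mom1[[nm]] / (1 - beta1^step)
        vhat <- mom2[[nm]] / (1 - beta2^step)
        model$params[[nm]] <- model$params[[nm]] -
          cfg$learning_rate * mhat / (sqrt(vhat) + adam_eps)
      }
    }
    val_loss <- bce_loss(lstm_forward(model, va$X)$prob, va$y)
    hist[[epoch]] <- data.frame(epoch = epoch,
                                train_loss = ep_loss / tr$n,
                                val_loss = val_loss)
    if (val_loss < best_loss - 1e-12) {
      best_loss <- val_loss
      best <- model
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > cfg$patience) break
    }
  }
  best$trained <- TRUE
  best$history <- do.call(rbind, hist)
  best
}

#' Predict cancer probabilities with a trained LSTM
#'
#' @param object a trained `lstm_model`.
#' @param tensor a `cohort_tensor` on the same feature scale as training.
#' @param ... unused.
#' @return `data.frame` with `subject`, `score` (cancer probability in
#'   (0, 1)), and `label` (threshold 0.5).
#' @export
predict.lstm_model <- function(object, tensor, ...) {
  stopifnot(inherits(object, "lstm_model"), inherits(tensor, "cohort_tensor"))
  if (dim(tensor$values)[3] != object$V)
    stop("tensor feature count does not match the model", call. = FALSE)
  xy <- tensor_to_xy(tensor)
  prob <- lstm_forward(object, xy$X)$prob
  data.frame(subject = tensor$subjects, score = prob,
             label = factor(ifelse(prob > 0.5, "cancer", "control"),
                            levels = c("control", "cancer")))
}

#' @export
print.lstm_model <- function(x, ...) {
  cat(sprintf("LSTM classifier: layers [%s] -> dense %d -> sigmoid; %s; %d parameters%s\n",
              paste(x$cfg$layers, collapse = ", "), x$cfg$dense,
              if (x$cfg$batch_norm) "batch norm" else "no batch norm",
              lstm_parameter_count(x),
              if (x$trained) " (trained)" else ""))
  invisible(x)
}

#' Cross-validation pipeline wrapper for the LSTM
#'
#' Packages the full fold-local protocol for [cross_validate()]: feature
#' standardization fitted on the training fold only, a stratified carve-out
#' of the training fold as the early-stopping validation set, optional 3x
#' augmentation of the inner training partition, LSTM training, and
#' prediction on (standardized) held-out data.
#'
#' @param cfg an [lstm_config()].
#' @param augment apply the 3x augmentation policy to the inner training
#'   partition.
#' @param noise_sd Gaussian augmentation sd.
#' @param val_frac fraction of the training fold carved out (stratified, by
#'   subject) for early stopping.
#' @return A `ts_pipeline` list with `fit(train, seed)` and
#'   `predict(model, test)`.
#' @export
lstm_pipeline <- function(cfg = lstm_config(), augment = TRUE,
                          noise_sd = 0.05, val_frac = 0.2) {
  structure(list(
    name = "lstm",
    fit = function(train, seed) {
      std <- standardize_tensor(train)
      strain <- std$train
      # stratified inner split before augmentation: no augmented copy of a
      # validation subject ever enters training
      idx_val <- stratified_holdout(strain$labels, val_frac, seed)
      inner_train <- tensor_subset(strain, setdiff(seq_along(strain$labels),
                                                   idx_val))
      inner_val <- tensor_subset(strain, idx_val)
      if (augment)
        inner_train <- expand_training_set(inner_train, noise_sd = noise_sd,
                                           seed = seed)
      model <- lstm_train(NULL, inner_train, inner_val, cfg = cfg, seed = seed)
      list(model = model, center = std$center, scale = std$scale)
    },
    predict = function(fitted, test) {
      out <- test$values
      for (v in seq_along(test$features))
        out[, , v] <- (out[, , v] - fitted$center[v]) / fitted$scale[v]
      stest <- new_cohort_tensor(out, test$labels, test$subjects,
                                 test$features)
      predict(fitted$model, stest)
    }
  ), class = "ts_pipeline")
}

# indices of a stratified holdout of at least one subject per class
stratified_holdout <- function(labels, frac, seed) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed + 7L)
  unlist(lapply(levels(labels), function(lv) {
    pool <- which(labels == lv)
    take <- max(1L, round(frac * length(pool)))
    pool[sample.int(length(pool), take)]
  }), use.names = FALSE)
}
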