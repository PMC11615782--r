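#' Configuration for the dual-tower network
#'
#' The model has two towers: a linear abundance tower `f_A = a(W x_A + b)`
#' mapping the m-dimensional relative-abundance vector to width `h`, and a
#' convolutional phylogeny tower applying `h` 1D filters of length `l` along
#' the tree-ordered embeddings of the OTUs present in the sample, followed by
#' max-pooling over positions. The towers are fused by element-wise
#' multiplication `f = f_A * f_P` (which forces both widths to `h`) and an
#' output head maps `f` to the prediction. Trained with minibatch AdamW
#' (decoupled weight decay on weights only) and early stopping on validation
#' loss.
#'
#' @param m number of OTUs (abundance input dimension).
#' @param d embedding dimension.
#' @param h hidden width: abundance-tower output size and filter count.
#' @param l convolution filter size (window of adjacent tree-ordered OTUs).
#' @param activation `"relu"`, `"tanh"` or `"identity"`.
#' @param n_output_layers 1 = single affine output map; 2 = one hidden
#'   linear+activation layer before the output map.
#' @param task `"regression"`, `"binary"` or `"multilabel"`.
#' @param n_labels number of labels (multilabel task).
#' @param dropout dropout rate on the fused features during training.
#' @param weight_decay decoupled L2 coefficient lambda (weights only).
#' @param learning_rate AdamW step size.
#' @param batch_size minibatch size.
#' @param max_epochs,patience early-stopping budget on validation loss.
#' @param seed integer seed controlling init, shuffling and dropout.
#' @param use_phylo `FALSE` turns the model into the plain feed-forward
#'   abundance baseline: the phylo-tower output is fixed to the all-ones
#'   vector, leaving the same number of fully connected layers.
#' @return a `pf_config` list.
#' @export
pf_config <- function(m, d, h = 64L, l = 3L, activation = "relu",
                      n_output_layers = 1L, task = "binary", n_labels = 1L,
                      dropout = 0.1, weight_decay = 1e-4,
                      learning_rate = 1e-3, batch_size = 32L,
                      max_epochs = 200L, patience = 20L, seed = 1L,
                      use_phylo = TRUE) {
  task <- match.arg(task, c("regression", "binary", "multilabel"))
  activation <- match.arg(activation, c("relu", "tanh", "identity"))
  if (h < 1L) stop("`h` must be >= 1", call. = FALSE)
  if (l < 1L) stop("`l` must be >= 1", call. = FALSE)
  if (weight_decay < 0) stop("`weight_decay` must be >= 0", call. = FALSE)
  n_out <- if (task == "multilabel") as.integer(n_labels) else 1L
  structure(list(m = as.integer(m), d = as.integer(d), h = as.integer(h),
                 l = as.integer(l), activation = activation,
                 n_output_layers = as.integer(n_output_layers), task = task,
                 n_labels = n_out, dropout = dropout,
                 weight_decay = weight_decay, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 use_phylo = isTRUE(use_phylo)),
            class = "pf_config")
}

act_id <- function(name) switch(name, identity = 0L, relu = 1L, tanh = 2L)
act_f <- function(x, name) switch(name, identity = x, relu = pmax(x, 0),
                                  tanh = tanh(x))
act_d <- function(x, name) switch(name, identity = x * 0 + 1,
                                  relu = (x > 0) * 1, tanh = 1 - tanh(x)^2)

#' Initialize network parameters
#'
#' He-style scaled normal initialization for weights, zero biases.
#'
#' @param config a `pf_config`.
#' @return named list of parameter matrices/vectors.
#' @export
pf_init_params <- function(config) {
  with_seed(config$seed, {
    rn <- function(r, c, fan_in) {
      matrix(stats::rnorm(r * c, sd = sqrt(2 / max(1, fan_in))), r, c)
    }
    # The conv tower starts as a near-identity gate: unit biases and small
    # filter weights give f_P ~= 1 at init, so the multiplicative fusion
    # reduces to the abundance tower and phylogenetic modulation is learned
    # rather than imposed as noise.
    p <- list(
      W1 = rn(config$h, config$m, config$m), b1 = numeric(config$h),
      Wc = 0.1 * rn(config$l * config$d, config$h, config$l * config$d),
      bc = rep(1, config$h)
    )
    if (config$n_output_layers >= 2L) {
      p$Wh <- rn(config$h, config$h, config$h)
      p$bh <- numeric(config$h)
    }
    p$Wo <- rn(config$n_labels, config$h, config$h)
    p$bo <- numeric(config$n_labels)
    p
  })
}

# Forward pass on a batch. XA: m x B (relative abundances); idx_list: list of
# per-sample integer vectors of present OTUs in canonical tree order; E: m x d
# embedding matrix. Returns prediction plus the cache needed for backprop.
pf_forward <- function(params, XA, idx_list, E, config, dropout_mask = NULL) {
  B <- ncol(XA)
  A_pre <- params$W1 %*% XA + params$b1
  fA <- act_f(A_pre, config$activation)
  if (config$use_phylo) {
    cv <- conv_forward(E, idx_list, params$Wc, params$bc, config$l,
                       act_id(config$activation))
    fP <- cv$fP
  } else {
    cv <- NULL
    fP <- matrix(1, config$h, B)
  }
  f <- fA * fP
  if (!is.null(dropout_mask)) f <- f * dropout_mask
  if (config$n_output_layers >= 2L) {
    H_pre <- params$Wh %*% f + params$bh
    H <- act_f(H_pre, config$activation)
    S <- params$Wo %*% H + params$bo
  } else {
    H_pre <- NULL
    H <- f
    S <- params$Wo %*% f + params$bo
  }
  pred <- if (config$task == "regression") S else sigmoid(S)
  list(pred = pred, S = S, f = f, fA = fA, fP = fP, A_pre = A_pre,
       H_pre = H_pre, H = H, cv = cv, dropout_mask = dropout_mask)
}

#' Training/evaluation loss
#'
#' Mean squared error for regression; mean binary cross-entropy for binary;
#' mean over labels and samples of BCE for multilabel. Probabilities are
#' clamped to `[1e-7, 1 - 1e-7]` before the log.
#'
#' @param pred predictions (`n_labels x B` matrix or vector).
#' @param y targets of matching shape.
#' @param task task name.
#' @return nonnegative scalar loss.
#' @export
pf_loss <- function(pred, y, task) {
  pred <- as.matrix(pred)
  y <- as.matrix(y)
  stopifnot(all(dim(pred) == dim(y)))
  if (task == "regression") {
    mean((y - pred)^2)
  } else {
    eps <- 1e-7
    p <- pmin(pmax(pred, eps), 1 - eps)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
}

# Backward pass: analytic gradients of pf_loss w.r.t. all parameters.
pf_backward <- function(params, cache, XA, idx_list, E, Y, config) {
  B <- ncol(XA)
  n_out <- config$n_labels
  # dL/dS: for (multi)label BCE through sigmoid, (p - y) / (B * n_out);
  # for MSE, 2 (s - y) / (B * n_out)
  dS <- if (config$task == "regression") {
    2 * (cache$S - Y) / (B * n_out)
  } else {
    (cache$pred - Y) / (B * n_out)
  }
  grads <- list()
  grads$Wo <- dS %*% t(cache$H)
  grads$bo <- rowSums(dS)
  dH <- t(params$Wo) %*% dS
  if (config$n_output_layers >= 2L) {
    dHpre <- dH * act_d(cache$H_pre, config$activation)
    grads$Wh <- dHpre %*% t(cache$f)
    grads$bh <- rowSums(dHpre)
    df <- t(params$Wh) %*% dHpre
  } else {
    df <- dH
  }
  if (!is.null(cache$dropout_mask)) df <- df * cache$dropout_mask
  dfA <- df * cache$fP
  dA_pre <- dfA * act_d(cache$A_pre, config$activation)
  grads$W1 <- dA_pre %*% t(XA)
  grads$b1 <- rowSums(dA_pre)
  if (config$use_phylo) {
    dfP <- df * cache$fA
    cb <- conv_backward(E, idx_list, dfP, cache$cv$amax, cache$cv$zmax,
                        config$l, config$d, act_id(config$activation))
    grads$Wc <- cb$dWc
    grads$bc <- as.numeric(cb$dbc)
  } else {
    grads$Wc <- params$Wc * 0
    grads$bc <- params$bc * 0
  }
  grads
}

# One AdamW step. Decay is decoupled and applied to weight matrices only.
adamw_step <- function(params, grads, state, config, t) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  decay_set <- c("W1", "Wc", "Wh", "Wo")
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^t)
    vhat <- state$v[[nm]] / (1 - b2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    if (nm %in% decay_set && config$weight_decay > 0) {
      params[[nm]] <- params[[nm]] - lr * config$weight_decay * params[[nm]]
    }
  }
  list(params = params, state = state)
}

#' Assemble model inputs from a table, embeddings and targets
#'
#' Orders the abundance rows by the embedding's canonical OTU order, converts
#' to relative abundances, and precomputes each sample's present-OTU index
#' vector (the convolution input).
#'
#' @param X abundance matrix (OTUs x samples; counts or relative abundances).
#' @param embedding a `pf_embedding` covering the table's OTUs, rows in
#'   canonical tree order.
#' @param y targets: numeric vector (regression/binary) or matrix
#'   (samples x n_labels, multilabel).
#' @return a `pf_data` list: `XA` (m x n), `idx_list`, `E`, `Y`
#'   (n_labels x n), `sample_labels`.
#' @export
pf_data <- function(X, embedding, y) {
  validate_abundance(X)
  stopifnot(inherits(embedding, "pf_embedding"))
  missing <- setdiff(rownames(X), rownames(embedding$X))
  if (length(missing)) {
    stop("OTUs absent from embeddings: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ord <- intersect(rownames(embedding$X), rownames(X))
  X <- X[ord, , drop = FALSE]
  E <- embedding$X[ord, , drop = FALSE]
  XA <- sweep(X, 2, colSums(X), `/`)
  idx_list <- lapply(seq_len(ncol(X)), function(i) which(X[, i] > 0))
  if (any(lengths(idx_list) == 0L)) {
    stop("sample(s) with zero present OTUs", call. = FALSE)
  }
  Y <- if (is.matrix(y)) t(y) else matrix(as.numeric(y), nrow = 1)
  stopifnot(ncol(Y) == ncol(X))
  structure(list(XA = XA, idx_list = idx_list, E = E, Y = Y,
                 sample_labels = colnames(X)), class = "pf_data")
}

#' Train the dual-tower network
#'
#' Minibatch AdamW with early stopping: after each epoch the validation loss
#' is computed (no dropout); training stops when it has not improved for
#' `patience` epochs or `max_epochs` is reached, and the best-validation
#' parameters are restored. Fully reproducible under `config$seed`.
#'
#' @param data a `pf_data`.
#' @param config a `pf_config` (its `m`/`d` must match the data).
#' @param train_idx,val_idx disjoint sample index vectors.
#' @return a `pf_model`: `params`, `config`, `report` (per-epoch train and
#'   validation loss, `best_epoch`).
#' @export
pf_train <- function(data, config, train_idx, val_idx) {
  stopifnot(inherits(data, "pf_data"), inherits(config, "pf_config"))
  if (length(intersect(train_idx, val_idx))) {
    stop("train and validation sets overlap", call. = FALSE)
  }
  if (length(train_idx) == 0L) stop("empty training set", call. = FALSE)
  if (config$m != nrow(data$XA) || config$d != ncol(data$E)) {
    stop("config m/d do not match the data", call. = FALSE)
  }
  XA_tr <- data$XA[, train_idx, drop = FALSE]
  idx_tr <- data$idx_list[train_idx]
  Y_tr <- data$Y[, train_idx, drop = FALSE]
  XA_va <- data$XA[, val_idx, drop = FALSE]
  idx_va <- data$idx_list[val_idx]
  Y_va <- data$Y[, val_idx, drop = FALSE]

  params <- pf_init_params(config)
  state <- list(m = lapply(params, function(x) x * 0),
                v = lapply(params, function(x) x * 0))
  n_tr <- length(train_idx)
  best <- list(loss = Inf, params = params, epoch = 0L)
  train_losses <- numeric(0)
  val_losses <- numeric(0)
  t_step <- 0L
  with_seed(child_seed(config$seed, 7L), {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n_tr)
      epoch_loss <- 0
      n_batches <- 0L
      for (start in seq(1, n_tr, by = config$batch_size)) {
        bi <- ord[start:min(start + config$batch_size - 1, n_tr)]
        mask <- if (config$dropout > 0) {
          matrix(stats::rbinom(config$h * length(bi), 1, 1 - config$dropout),
                 config$h, length(bi)) / (1 - config$dropout)
        } else {
          NULL
        }
        cache <- pf_forward(params, XA_tr[, bi, drop = FALSE], idx_tr[bi],
                            data$E, config, dropout_mask = mask)
        loss <- pf_loss(cache$pred, Y_tr[, bi, drop = FALSE], config$task)
        if (!is.finite(loss)) {
          stop("training diverged (non-finite loss) at epoch ", epoch,
               call. = FALSE)
        }
        grads <- pf_backward(params, cache, XA_tr[, bi, drop = FALSE],
                             idx_tr[bi], data$E,
                             Y_tr[, bi, drop = FALSE], config)
        t_step <- t_step + 1L
        upd <- adamw_step(params, grads, state, config, t_step)
        params <- upd$params
        state <- upd$state
        epoch_loss <- epoch_loss + loss
        n_batches <- n_batches + 1L
      }
      train_losses[epoch] <- epoch_loss / n_batches
      va_cache <- pf_forward(params, XA_va, idx_va, data$E, config)
      val_losses[epoch] <- pf_loss(va_cache$pred, Y_va, config$task)
      if (val_losses[epoch] < best$loss - 1e-12) {
        best <- list(loss = val_losses[epoch], params = params, epoch = epoch)
      } else if (epoch - best$epoch >= config$patience) {
        break
      }
    }
  })
  structure(list(params = best$params, config = config,
                 report = list(train_loss = train_losses,
                               val_loss = val_losses,
                               best_epoch = best$epoch,
                               best_val_loss = best$loss)),
            class = "pf_model")
}

#' Predict with a trained model
#'
#' @param object a `pf_model`.
#' @param data a `pf_data` (same OTU universe and order as training).
#' @param idx optional sample indices (default all).
#' @param ... unused.
#' @return predictions: numeric vector (regression/binary) or
#'   `n x n_labels` matrix (multilabel).
#' @export
predict.pf_model <- function(object, data, idx = NULL, ...) {
  stopifnot(inherits(data, "pf_data"))
  if (is.null(idx)) idx <- seq_len(ncol(data$XA))
  cache <- pf_forward(object$params, data$XA[, idx, drop = FALSE],
                      data$idx_list[idx], data$E, object$config)
  if (object$config$n_labels > 1L) {
    out <- t(cache$pred)
    rownames(out) <- data$sample_labels[idx]
    out
  } else {
    stats::setNames(as.numeric(cache$pred), data$sample_labels[idx])
  }
}

#' @export
print.pf_model <- function(x, ...) {
  cat("pf_model:", x$config$task,
      if (x$config$use_phylo) "(dual-tower)" else "(abundance baseline)",
      "- h =", x$config$h, ", l =", x$config$l,
      ", best epoch", x$report$best_epoch, "\n")
  invisible(x)
}

#' Flatten parameters / gradients for finite-difference checking
#'
#' @param params named list of arrays.
#' @return numeric vector (`pf_flatten`); list with original shapes
#'   (`pf_unflatten`).
#' @keywords internal
pf_flatten <- function(params) unlist(params, use.names = FALSE)

#' @rdname pf_flatten
#' @param theta flat numeric vector.
#' @param template parameter list supplying shapes.
#' @keywords internal
pf_unflatten <- function(theta, template) {
  out <- template
  pos <- 0L
  for (nm in names(template)) {
    len <- length(template[[nm]])
    vals <- theta[pos + seq_len(len)]
    out[[nm]] <- if (is.matrix(template[[nm]])) {
      matrix(vals, nrow(template[[nm]]), ncol(template[[nm]]))
    } else {
      vals
    }
    pos <- pos + len
  }
  out
}
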