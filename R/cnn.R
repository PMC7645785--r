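# Person identification from error maps with a small convolutional network.
#
# Architecture (fixed by design): 2-channel 5x20 input -> 3x3 convolution
# with 13 filters (valid padding) -> batch normalization -> ReLU -> dropout
# -> fully connected layer -> softmax. Trained with cross-entropy loss and
# stochastic gradient descent with momentum at an initial learning rate of
# 0.01 for 250-500 epochs (350 by default), shuffling the input sequence
# every epoch. Implemented directly in base-R matrix algebra (im2col): the
# inputs are tiny (a 2x5x20 map per subject and session), so no compiled
# deep-learning backend is needed.

#' Classifier configuration
#'
#' @param kernel_size convolution kernel size (square), default 3.
#' @param n_filters number of convolution output filters, default 13.
#' @param dropout_rate dropout probability after the ReLU, default 0.5.
#' @param learning_rate initial SGD learning rate, default 0.01.
#' @param momentum SGD momentum coefficient, default 0.9.
#' @param epochs training epochs, default 350 (conventionally 250-500 for
#'   training sets of this size).
#' @param batch_size minibatch size; default `min(128, n_training_maps)`.
#' @param seed RNG seed governing initialization, per-epoch shuffling and
#'   dropout masks.
#' @return an object of class `classifier_config`.
#' @export
classifier_config <- function(kernel_size = 3, n_filters = 13, dropout_rate = 0.5,
                              learning_rate = 0.01, momentum = 0.9, epochs = 350,
                              batch_size = NULL, seed = 1L) {
  if (dropout_rate < 0 || dropout_rate >= 1) stop_("dropout_rate must be in [0, 1)")
  if (learning_rate <= 0) stop_("learning_rate must be positive")
  if (epochs < 1) stop_("epochs must be at least 1")
  structure(list(kernel_size = as.integer(kernel_size),
                 n_filters = as.integer(n_filters),
                 dropout_rate = dropout_rate, learning_rate = learning_rate,
                 momentum = momentum, epochs = as.integer(epochs),
                 batch_size = if (is.null(batch_size)) NULL else as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

glorot_uniform <- function(n_row, n_col, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(n_row * n_col, -lim, lim), n_row, n_col)
}

#' Build an (untrained) CNN classifier
#'
#' @param n_classes number of subjects to discriminate (>= 2).
#' @param config a [classifier_config()].
#' @param input_dim input array dimensions `c(channels, rows, cols)`,
#'   default `c(2, 5, 20)` for a standard error map.
#' @return an object of class `cnn_classifier` with Glorot-uniform seeded
#'   parameters.
#' @export
build_classifier <- function(n_classes, config = classifier_config(),
                             input_dim = c(2L, 5L, 20L)) {
  if (n_classes < 2) stop_("n_classes must be at least 2")
  ks <- config$kernel_size
  C <- input_dim[1]; H <- input_dim[2]; W <- input_dim[3]
  oh <- H - ks + 1L; ow <- W - ks + 1L
  if (oh < 1 || ow < 1) stop_("input too small for the convolution kernel")
  patch <- ks * ks * C
  n_hidden <- oh * ow * config$n_filters
  # patch index template: for each output position, the linear indices into
  # a flattened c(C, H, W) array of its kernel_size^2 x C receptive field
  pos <- expand.grid(r = seq_len(oh), c = seq_len(ow))
  kern <- expand.grid(ch = seq_len(C), dr = 0:(ks - 1), dc = 0:(ks - 1))
  idx <- matrix(0L, nrow(pos), patch)
  for (p in seq_len(nrow(pos))) {
    rr <- pos$r[p] + kern$dr; cc <- pos$c[p] + kern$dc
    idx[p, ] <- kern$ch + C * (rr - 1L) + C * H * (cc - 1L)
  }
  params <- with_seed(config$seed, list(
    Wc = glorot_uniform(patch, config$n_filters, patch, ks * ks * config$n_filters),
    bc = numeric(config$n_filters),
    gamma = rep(1, config$n_filters),
    beta = numeric(config$n_filters),
    Wf = glorot_uniform(n_hidden, n_classes, n_hidden, n_classes),
    bf = numeric(n_classes)))
  structure(list(params = params,
                 run_mean = numeric(config$n_filters),
                 run_var = rep(1, config$n_filters),
                 config = config, input_dim = as.integer(input_dim),
                 conv_out = c(oh, ow), n_positions = nrow(pos),
                 patch_idx = idx, n_classes = as.integer(n_classes),
                 classes = NULL, trained = FALSE, loss_history = NULL),
            class = "cnn_classifier")
}

# Stack error maps (list of error_map or of plain arrays) into a matrix with
# one flattened c(C, H, W) map per column, checking the input shape.
maps_to_matrix <- function(maps, input_dim) {
  arrs <- lapply(maps, function(m) if (inherits(m, "error_map")) m$errors else m)
  for (a in arrs)
    if (!identical(as.integer(dim(a)), as.integer(input_dim)))
      stop_("input shape (%s) does not match the classifier input (%s)",
            paste(dim(a), collapse = "x"), paste(input_dim, collapse = "x"))
  vapply(arrs, function(a) as.vector(aperm(a, c(1, 2, 3))), numeric(prod(input_dim)))
}

# im2col: rows are (sample-major) output positions, columns patch elements
build_patches <- function(model, X) {
  n <- ncol(X)
  op <- model$n_positions
  P <- matrix(0, n * op, ncol(model$patch_idx))
  for (s in seq_len(n))
    P[((s - 1L) * op + 1L):(s * op), ] <- matrix(X[model$patch_idx, s],
                                                 op, ncol(model$patch_idx))
  P
}

cnn_forward <- function(model, P, n, training = FALSE, eps = 1e-5) {
  pr <- model$params
  Z <- sweep(P %*% pr$Wc, 2, pr$bc, "+")
  if (training) {
    mu <- colMeans(Z)
    v <- colMeans(Z^2) - mu^2
  } else {
    mu <- model$run_mean
    v <- model$run_var
  }
  inv <- 1 / sqrt(v + eps)
  Zh <- sweep(sweep(Z, 2, mu, "-"), 2, inv, "*")
  Y <- sweep(sweep(Zh, 2, pr$gamma, "*"), 2, pr$beta, "+")
  Hh <- pmax(Y, 0)
  op <- model$n_positions
  A <- matrix(0, n, op * model$config$n_filters)
  for (s in seq_len(n))
    A[s, ] <- as.vector(Hh[((s - 1L) * op + 1L):(s * op), ])
  list(Z = Z, Zh = Zh, Y = Y, H = Hh, A = A, mu = mu, v = v, inv = inv)
}

cnn_logits <- function(model, A) sweep(A %*% model$params$Wf, 2, model$params$bf, "+")

softmax_rows <- function(L) {
  E <- exp(L - apply(L, 1, max))
  E / rowSums(E)
}

#' Train the CNN classifier
#'
#' Minimizes the cross-entropy loss with stochastic gradient descent with
#' momentum, shuffling the training sequence every epoch. Deterministic
#' given the config seed.
#'
#' @param model a [build_classifier()] model.
#' @param maps list of `error_map`s (or plain `c(2, 5, 20)` arrays).
#' @param labels factor (or coercible) of subject labels, one per map.
#' @param config optional [classifier_config()] overriding the model's.
#' @return the trained `cnn_classifier`, with `loss_history` attached.
#' @export
train_classifier <- function(model, maps, labels, config = model$config) {
  labels <- as.factor(labels)
  if (nlevels(labels) != model$n_classes)
    stop_("number of label levels (%d) does not match n_classes (%d)",
          nlevels(labels), model$n_classes)
  if (any(table(labels) == 0))
    stop_("class absent from training set: %s",
          paste(levels(labels)[table(labels) == 0], collapse = ", "))
  X <- maps_to_matrix(maps, model$input_dim)
  n <- ncol(X)
  if (n != length(labels)) stop_("labels must match maps")
  y <- as.integer(labels)
  P_all <- build_patches(model, X)
  op <- model$n_positions
  bs <- config$batch_size %||% min(128L, n)
  lr <- config$learning_rate; mom <- config$momentum
  drop_p <- config$dropout_rate
  vel <- lapply(model$params, function(p) p * 0)
  loss_hist <- numeric(config$epochs)
  model$config <- config
  with_seed(derive_seed(config$seed, purpose = 7), {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = bs)) {
        sel <- perm[start:min(start + bs - 1L, n)]
        nb <- length(sel)
        rows <- as.vector(outer(seq_len(op), (sel - 1L) * op, "+"))
        P <- P_all[rows, , drop = FALSE]
        fw <- cnn_forward(model, P, nb, training = TRUE)
        # running statistics for inference
        model$run_mean <- 0.9 * model$run_mean + 0.1 * fw$mu
        model$run_var <- 0.9 * model$run_var + 0.1 * fw$v
        mask <- if (drop_p > 0)
          matrix((stats::runif(length(fw$A)) >= drop_p) / (1 - drop_p),
                 nrow(fw$A), ncol(fw$A)) else 1
        A_drop <- fw$A * mask
        logits <- cnn_logits(model, A_drop)
        probs <- softmax_rows(logits)
        yb <- y[sel]
        ep_loss <- ep_loss - sum(log(pmax(probs[cbind(seq_len(nb), yb)], 1e-12)))
        # backward pass
        G <- probs
        G[cbind(seq_len(nb), yb)] <- G[cbind(seq_len(nb), yb)] - 1
        G <- G / nb
        grads <- list()
        grads$Wf <- crossprod(A_drop, G)
        grads$bf <- colSums(G)
        dA <- (G %*% t(model$params$Wf)) * mask
        dH <- matrix(0, nb * op, model$config$n_filters)
        for (s in seq_len(nb))
          dH[((s - 1L) * op + 1L):(s * op), ] <-
            matrix(dA[s, ], op, model$config$n_filters)
        dY <- dH * (fw$Y > 0)
        grads$gamma <- colSums(dY * fw$Zh)
        grads$beta <- colSums(dY)
        dZh <- sweep(dY, 2, model$params$gamma, "*")
        M <- nrow(dZh)
        sum_d <- colSums(dZh)
        sum_dz <- colSums(dZh * fw$Zh)
        dZ <- sweep(M * dZh, 2, sum_d, "-") - sweep(fw$Zh, 2, sum_dz, "*")
        dZ <- sweep(dZ, 2, fw$inv / M, "*")
        grads$Wc <- crossprod(P, dZ)
        grads$bc <- colSums(dZ)
        for (nm in names(grads)) {
          vel[[nm]] <- mom * vel[[nm]] - lr * grads[[nm]]
          model$params[[nm]] <- model$params[[nm]] + vel[[nm]]
        }
      }
      loss_hist[epoch] <- ep_loss / n
    }
  })
  model$classes <- levels(labels)
  model$trained <- TRUE
  model$loss_history <- loss_hist
  model
}

#' Predict subject identities for error maps
#'
#' @param object a trained `cnn_classifier`.
#' @param maps list of `error_map`s or arrays.
#' @param type `"class"` for hard labels, `"prob"` for the softmax matrix.
#' @param ... unused.
#' @return factor of predicted labels, or a probability matrix.
#' @export
predict.cnn_classifier <- function(object, maps, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- maps_to_matrix(maps, object$input_dim)
  P <- build_patches(object, X)
  fw <- cnn_forward(object, P, ncol(X), training = FALSE)
  probs <- softmax_rows(cnn_logits(object, fw$A))
  if (!is.null(object$classes)) colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  cls <- object$classes %||% as.character(seq_len(object$n_classes))
  factor(cls[max.col(probs, ties.method = "first")], levels = cls)
}

#' Evaluate identification accuracy on a test set
#'
#' @param model a trained `cnn_classifier`.
#' @param maps list of test `error_map`s or arrays.
#' @param labels true subject labels.
#' @return an object of class `identification_result`: `accuracy`,
#'   `n_correct`, `n_test`, `chance` (1 / number of classes), and a
#'   `predictions` data frame.
#' @export
evaluate_classifier <- function(model, maps, labels) {
  if (length(maps) == 0) stop_("test set is empty")
  labels <- factor(as.character(labels), levels = model$classes)
  if (anyNA(labels)) stop_("test labels outside the training classes")
  pred <- predict(model, maps)
  correct <- pred == labels
  structure(list(accuracy = mean(correct), n_correct = sum(correct),
                 n_test = length(labels), chance = 1 / model$n_classes,
                 predictions = data.frame(true = labels, predicted = pred,
                                          correct = correct),
                 seed = model$config$seed),
            class = "identification_result")
}

#' Run a session-split identification protocol
#'
#' Trains the classifier on the maps of `train_sessions` (labels = subject
#' identity) and evaluates it on the maps of `test_session`, e.g. sessions
#' 1+2 as training and session 3 as test.
#'
#' @param maps list of `error_map`s covering all subjects and sessions.
#' @param train_sessions session labels forming the training set.
#' @param test_session the held-out session.
#' @param config a [classifier_config()].
#' @return an `identification_result`, with the split and config recorded.
#' @export
identification_protocol <- function(maps, train_sessions, test_session,
                                    config = classifier_config()) {
  if (test_session %in% train_sessions)
    stop_("test session %s overlaps the training sessions", test_session)
  sess <- vapply(maps, function(m) as.character(m$session), character(1))
  subj <- vapply(maps, function(m) m$subject_id, character(1))
  tr <- sess %in% as.character(train_sessions)
  te <- sess == as.character(test_session)
  if (!any(tr) || !any(te)) stop_("requested sessions absent from the maps")
  labels <- factor(subj[tr])
  model <- build_classifier(nlevels(labels), config)
  model <- train_classifier(model, maps[tr], labels, config)
  res <- evaluate_classifier(model, maps[te], subj[te])
  res$split <- list(train = train_sessions, test = test_session)
  res$config <- config
  res$final_training_loss <- utils::tail(model$loss_history, 1)
  res
}

#' @export
print.identification_result <- function(x, ...) {
  cat(sprintf("identification: %d/%d correct (%.2f%%), chance %.2f%%\n",
              x$n_correct, x$n_test, 100 * x$accuracy, 100 * x$chance))
  invisible(x)
}
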