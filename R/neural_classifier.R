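#' MLBPNN configuration
#'
#' The multilayer backpropagation neural network used as a comparison
#' classifier: one input layer, three hidden layers holding five nodes
#' arranged 2-1-2, and a 3-unit output layer (one per class). The 1-node
#' middle layer is a deliberate bottleneck, implemented as printed; a
#' different \code{hidden_layout} is accepted as an escape hatch.
#'
#' @param input_dim Feature dimension (default 15).
#' @param hidden_layout Integer vector of hidden layer sizes (default
#'   \code{c(2, 1, 2)}).
#' @param learning_rate Gradient-descent step size (default 0.2).
#' @param momentum Momentum coefficient (default 0.9).
#' @param max_epochs Training epoch cap (default 500).
#' @param patience Early-stopping patience on validation loss (default 6).
#' @param val_fraction Held-out validation fraction (default 0.2).
#' @param seed Integer seed for the weight initialisation and split.
#' @param restarts Number of seeded initialisations to try; the fit with
#'   the best training accuracy wins (the 1-node bottleneck makes single
#'   initialisations occasionally collapse).
#' @return An object of class \code{pf_mlbpnn_config}.
#' @export
mlbpnn_config <- function(input_dim = 15L, hidden_layout = c(2L, 1L, 2L),
                          learning_rate = 0.2, momentum = 0.9,
                          max_epochs = 500L, patience = 6L,
                          val_fraction = 0.2, seed = 1L, restarts = 5L) {
  if (learning_rate <= 0)
    pf_stop("pf_config_error", "learning_rate must be positive")
  structure(list(input_dim = as.integer(input_dim),
                 hidden_layout = as.integer(hidden_layout),
                 output_dim = 3L, learning_rate = learning_rate,
                 momentum = momentum, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction, seed = as.integer(seed),
                 restarts = as.integer(restarts)),
            class = "pf_mlbpnn_config")
}

pf_sigmoid <- function(x) 1 / (1 + exp(-x))

pf_softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# forward pass; returns activations per layer (a[[1]] = input)
pf_mlbpnn_forward <- function(net, X) {
  a <- list(X)
  L <- length(net$W)
  for (l in seq_len(L)) {
    z <- a[[l]] %*% net$W[[l]] + matrix(net$b[[l]], nrow(X),
                                        length(net$b[[l]]), byrow = TRUE)
    a[[l + 1]] <- if (l == L) pf_softmax(z) else pf_sigmoid(z)
  }
  a
}

#' Train the MLBPNN
#'
#' Fully connected network with sigmoid hidden activations, softmax
#' output and cross-entropy loss, trained by full-batch backpropagation
#' with momentum from a seeded Gaussian initialisation. The data are
#' split 80/20 into training and validation (seeded), and training stops
#' early when the validation loss has not improved for \code{patience}
#' epochs; the best-validation weights are returned. Labels follow the
#' class codes 1 = neutral_face, 2 = pain_face, 3 = not_pain_face.
#'
#' @param X Numeric matrix (frames x features) or list of
#'   \code{pf_frame_features}.
#' @param labels Integer class codes aligned with the rows of \code{X}.
#' @param config A \code{\link{mlbpnn_config}}.
#' @return An object of class \code{pf_mlbpnn} with the trained weights,
#'   normalisation statistics, per-epoch loss trace (\code{trace}:
#'   epoch, train_loss, val_loss) and the config.
#' @export
train_mlbpnn <- function(X, labels, config = mlbpnn_config()) {
  best <- NULL; best_acc <- -1
  for (r in seq_len(max(1L, config$restarts %||% 1L))) {
    cfg_r <- config
    cfg_r$seed <- config$seed + (r - 1L) * 1009L
    cfg_r$restarts <- 1L
    net <- pf_train_mlbpnn_once(X, labels, cfg_r)
    acc <- mean(predict_mlbpnn(net,
                               if (is.matrix(X)) X else features_matrix(X)) ==
                  as.integer(labels))
    if (acc > best_acc) { best_acc <- acc; best <- net }
    if (best_acc >= 0.999) break
  }
  best$config <- config
  best
}

pf_train_mlbpnn_once <- function(X, labels, config) {
  if (is.list(X) && !is.matrix(X)) X <- features_matrix(X)
  labels <- as.integer(labels)
  if (any(!labels %in% PF_CLASSES))
    pf_stop("pf_contract_error", "labels must be class codes 1, 2 or 3")
  if (nrow(X) != length(labels))
    pf_stop("pf_contract_error", "X rows and labels must align")
  center <- colMeans(X)
  scale <- pmax(apply(X, 2, stats::sd), 1e-6)
  Z <- sweep(sweep(X, 2, center), 2, scale, `/`)
  n <- nrow(Z)
  Y <- matrix(0, n, 3L); Y[cbind(seq_len(n), labels)] <- 1

  old <- .Random.seed_exists()
  set.seed(config$seed)
  on.exit(.Random.seed_restore(old), add = TRUE)

  sizes <- c(config$input_dim, config$hidden_layout, config$output_dim)
  L <- length(sizes) - 1L
  net <- list(W = vector("list", L), b = vector("list", L))
  for (l in seq_len(L)) {
    net$W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], sd = 1 / sqrt(sizes[l])),
                         sizes[l], sizes[l + 1])
    net$b[[l]] <- rep(0, sizes[l + 1])
  }
  vW <- lapply(net$W, function(w) w * 0)
  vb <- lapply(net$b, function(b) b * 0)

  val_idx <- sample.int(n, size = max(1L, round(config$val_fraction * n)))
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- Z[tr_idx, , drop = FALSE]; Ytr <- Y[tr_idx, , drop = FALSE]
  Xva <- Z[val_idx, , drop = FALSE]; Yva <- Y[val_idx, , drop = FALSE]

  xent <- function(P, Y) -mean(rowSums(Y * log(pmax(P, 1e-12))))
  trace <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_loss = numeric(0))
  best_val <- Inf; best_net <- net; stall <- 0L
  for (ep in seq_len(config$max_epochs)) {
    a <- pf_mlbpnn_forward(net, Xtr)
    P <- a[[L + 1]]
    if (!all(is.finite(P)))
      pf_stop("pf_divergence_error",
              "non-finite loss during training; try a smaller learning rate")
    delta <- (P - Ytr) / nrow(Xtr)  # softmax + cross-entropy gradient
    for (l in L:1) {
      gW <- crossprod(a[[l]], delta)
      gb <- colSums(delta)
      if (l > 1L)
        delta <- (delta %*% t(net$W[[l]])) * a[[l]] * (1 - a[[l]])
      vW[[l]] <- config$momentum * vW[[l]] - config$learning_rate * gW
      vb[[l]] <- config$momentum * vb[[l]] - config$learning_rate * gb
      net$W[[l]] <- net$W[[l]] + vW[[l]]
      net$b[[l]] <- net$b[[l]] + vb[[l]]
    }
    tr_loss <- xent(P, Ytr)
    va_loss <- xent(pf_mlbpnn_forward(net, Xva)[[L + 1]], Yva)
    trace <- rbind(trace, data.frame(epoch = ep, train_loss = tr_loss,
                                     val_loss = va_loss))
    if (va_loss < best_val - 1e-9) {
      best_val <- va_loss; best_net <- net; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience && ep > 150L) break  # after burn-in
    }
  }
  structure(list(W = best_net$W, b = best_net$b, center = center,
                 scale = scale, trace = trace, config = config),
            class = "pf_mlbpnn")
}

#' Predict class labels with a trained MLBPNN
#'
#' Argmax of the softmax outputs, mapped to the class codes; an exact tie
#' goes to the lowest class index.
#'
#' @param network A trained \code{pf_mlbpnn}.
#' @param X Feature matrix or list of \code{pf_frame_features}.
#' @return Integer class codes (1/2/3), one per row.
#' @export
predict_mlbpnn <- function(network, X) {
  if (is.list(X) && !is.matrix(X)) X <- features_matrix(X)
  if (ncol(X) != nrow(network$W[[1]]))
    pf_stop("pf_contract_error", "feature dimension mismatch (%d vs %d)",
            ncol(X), nrow(network$W[[1]]))
  Z <- sweep(sweep(X, 2, network$center), 2, network$scale, `/`)
  P <- pf_mlbpnn_forward(network, Z)[[length(network$W) + 1]]
  apply(P, 1, which.max)  # which.max takes the lowest index on ties
}

# save/restore the global RNG state so seeded training does not perturb
# the caller's random stream
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
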