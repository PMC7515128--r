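# The two MLP branches: a 2-hidden-layer perceptron per feature branch,
# trained with inverted dropout and Adam on a class-balanced subsample,
# five times with derived seeds; predictions are the ensemble mean.
#
# All arithmetic is plain double-precision matrix algebra, so a fixed
# master seed reproduces weights bit-for-bit.

#' MLP hyperparameter configuration
#'
#' Presets matching the two published branches are available via
#' \code{\link{mlp1_config}} (sequence properties: hidden [12,12],
#' dropout keep 0.5, learning rate 1e-3) and \code{\link{mlp2_config}}
#' (profile branch: hidden [25,25], keep 0.7, learning rate 1e-4).
#'
#' @param input_dim number of input features (48 or 60 at defaults).
#' @param hidden_sizes two hidden-layer widths.
#' @param dropout_keep keep probability p_d in (0,1] for hidden units.
#' @param learning_rate Adam step size.
#' @param epochs training epochs (default 200).
#' @param batch_size minibatch size (default 128).
#' @param seed master seed; member m trains with seed + m - 1.
#' @param inverted_dropout scale kept activations by 1/p_d during
#'   training (default TRUE) so eval-mode needs no rescaling; FALSE gives
#'   the literal unscaled mask.
#' @return object of class \code{MLPConfig}.
#' @export
mlp_config <- function(input_dim, hidden_sizes = c(12L, 12L),
                       dropout_keep = 0.5, learning_rate = 1e-3,
                       epochs = 200L, batch_size = 128L, seed = 1L,
                       inverted_dropout = TRUE) {
  hidden_sizes <- as.integer(hidden_sizes)
  if (length(hidden_sizes) != 2L || any(hidden_sizes < 1L))
    abort2("hidden_sizes must be two integers >= 1", "morfmlp_config_error")
  if (!is.numeric(dropout_keep) || dropout_keep <= 0 || dropout_keep > 1)
    abort2("dropout_keep must lie in (0, 1]", "morfmlp_config_error")
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    abort2("learning_rate must be positive", "morfmlp_config_error")
  structure(list(input_dim = as.integer(input_dim),
                 hidden_sizes = hidden_sizes,
                 dropout_keep = as.numeric(dropout_keep),
                 learning_rate = as.numeric(learning_rate),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 inverted_dropout = isTRUE(inverted_dropout)),
            class = "MLPConfig")
}

#' @rdname mlp_config
#' @param ... overrides passed to \code{mlp_config}.
#' @export
mlp1_config <- function(input_dim = 48L, ...) {
  do.call(mlp_config, modifyList(
    list(input_dim = input_dim, hidden_sizes = c(12L, 12L),
         dropout_keep = 0.5, learning_rate = 1e-3), list(...)))
}

#' @rdname mlp_config
#' @export
mlp2_config <- function(input_dim = 60L, ...) {
  do.call(mlp_config, modifyList(
    list(input_dim = input_dim, hidden_sizes = c(25L, 25L),
         dropout_keep = 0.7, learning_rate = 1e-4), list(...)))
}

# He-style scaled-uniform init, biases zero; draws from the current RNG
init_params <- function(config) {
  dims <- c(config$input_dim, config$hidden_sizes, 1L)
  init_w <- function(fan_in, fan_out) {
    lim <- sqrt(6 / fan_in)
    matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
  }
  list(W1 = init_w(dims[1], dims[2]), b1 = numeric(dims[2]),
       W2 = init_w(dims[2], dims[3]), b2 = numeric(dims[3]),
       W3 = init_w(dims[3], dims[4]), b3 = numeric(dims[4]))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

check_dims <- function(params, X) {
  if (ncol(X) != nrow(params$W1))
    abort2(sprintf("feature dimension %d does not match model input %d",
                   ncol(X), nrow(params$W1)), "morfmlp_shape_error")
}

#' Forward pass of one MLP member
#'
#' Hidden layers use ReLU, the output unit a sigmoid.  In train mode each
#' hidden activation is multiplied elementwise by a Bernoulli(p_d) mask
#' drawn from the current RNG (scaled by 1/p_d when inverted dropout is
#' enabled); eval mode applies no mask.  With \code{keep = 1} train and
#' eval modes coincide exactly.
#'
#' @param params member parameter list (W1,b1,W2,b2,W3,b3).
#' @param features numeric matrix, rows = residues (already standardized
#'   when coming from a trained model).
#' @param mode "eval" or "train".
#' @param keep dropout keep probability (train mode).
#' @param inverted use inverted-dropout scaling.
#' @return numeric vector of per-row scores in [0,1].
#' @export
forward <- function(params, features, mode = c("eval", "train"), keep = 1,
                    inverted = TRUE) {
  mode <- match.arg(mode)
  X <- as.matrix(features)
  check_dims(params, X)
  fwd <- forward_full(params, X, dropout = (mode == "train" && keep < 1),
                      keep = keep, inverted = inverted)
  as.numeric(fwd$p)
}

forward_full <- function(params, X, dropout = FALSE, keep = 1,
                         inverted = TRUE) {
  n <- nrow(X)
  Z1 <- X %*% params$W1
  Z1 <- sweep(Z1, 2L, params$b1, `+`)
  A1 <- pmax(Z1, 0)
  M1 <- NULL
  if (dropout) {
    M1 <- matrix(as.numeric(runif(length(A1)) < keep), n, ncol(A1))
    if (inverted) M1 <- M1 / keep
    A1 <- A1 * M1
  }
  Z2 <- A1 %*% params$W2
  Z2 <- sweep(Z2, 2L, params$b2, `+`)
  A2 <- pmax(Z2, 0)
  M2 <- NULL
  if (dropout) {
    M2 <- matrix(as.numeric(runif(length(A2)) < keep), n, ncol(A2))
    if (inverted) M2 <- M2 / keep
    A2 <- A2 * M2
  }
  Z3 <- A2 %*% params$W3 + params$b3
  list(p = sigmoid(Z3), Z1 = Z1, A1 = A1, M1 = M1,
       Z2 = Z2, A2 = A2, M2 = M2)
}

# gradient of mean binary cross-entropy wrt all parameters
backward <- function(params, X, y, fwd) {
  n <- nrow(X)
  dZ3 <- matrix((as.numeric(fwd$p) - y) / n, ncol = 1L)
  gW3 <- crossprod(fwd$A2, dZ3)
  gb3 <- sum(dZ3)
  dA2 <- dZ3 %*% t(params$W3)
  dZ2 <- dA2 * (fwd$Z2 > 0)
  if (!is.null(fwd$M2)) dZ2 <- dZ2 * fwd$M2
  gW2 <- crossprod(fwd$A1, dZ2)
  gb2 <- colSums(dZ2)
  dA1 <- dZ2 %*% t(params$W2)
  dZ1 <- dA1 * (fwd$Z1 > 0)
  if (!is.null(fwd$M1)) dZ1 <- dZ1 * fwd$M1
  gW1 <- crossprod(X, dZ1)
  gb1 <- colSums(dZ1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
}

bce_loss <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Class-balanced training subsample
#'
#' Keeps every positive (MoRF) residue and a uniformly random,
#' seed-reproducible sample of negatives of the same count (all negatives
#' when fewer exist, with a warning), then shuffles the row order.
#'
#' @param features feature matrix (rows = residues).
#' @param labels 0/1 vector.
#' @param seed RNG seed.
#' @return list with \code{features}, \code{labels}, \code{rows} (indices
#'   into the input).
#' @export
balanced_subsample <- function(features, labels, seed = 1L) {
  labels <- as.integer(labels)
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  if (length(pos) == 0L)
    abort2("cannot train: no positive (MoRF) residues in labels",
           "morfmlp_training_error")
  if (length(neg) == 0L)
    abort2("cannot train: no negative residues in labels",
           "morfmlp_training_error")
  rows <- local({
    set.seed(seed)
    take <- if (length(neg) <= length(pos)) neg
            else sample(neg, length(pos))
    if (length(neg) < length(pos))
      warning("fewer negatives than positives; keeping all negatives",
              call. = FALSE)
    sample(c(pos, take))
  })
  list(features = features[rows, , drop = FALSE], labels = labels[rows],
       rows = rows)
}

#' Train a 5-member ensemble MLP
#'
#' Draws one balanced subsample (master seed), fits the per-feature
#' z-score standardizer on it, then trains \code{n_members} independent
#' MLPs with member seeds \code{seed, seed+1, ...} controlling weight
#' initialization, dropout masks and batch order.  Each member minimizes
#' binary cross-entropy with Adam (beta1 0.9, beta2 0.999, eps 1e-8).
#'
#' @param features residue x feature matrix (raw, unstandardized).
#' @param labels 0/1 per-residue labels.
#' @param config an \code{\link{mlp_config}}.
#' @param n_members ensemble size (default 5).
#' @param branch optional branch tag stored in the model.
#' @return object of class \code{EnsembleModel}: \code{members},
#'   \code{standardizer} (mean/sd), \code{config}, \code{branch}.
#' @export
train_mlp <- function(features, labels, config, n_members = 5L,
                      branch = NA_character_) {
  features <- as.matrix(features)
  if (ncol(features) != config$input_dim)
    abort2(sprintf("config expects %d features, data has %d",
                   config$input_dim, ncol(features)), "morfmlp_shape_error")
  sub <- balanced_subsample(features, labels, seed = config$seed)
  mu <- colMeans(sub$features)
  sd_ <- apply(sub$features, 2L, stats::sd)
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  Xs <- sweep(sweep(sub$features, 2L, mu), 2L, sd_, `/`)
  y <- sub$labels
  members <- lapply(seq_len(n_members), function(m)
    train_member(Xs, y, config, seed = config$seed + m - 1L))
  structure(list(members = members,
                 standardizer = list(mean = unname(mu), sd = unname(sd_)),
                 config = config, branch = branch),
            class = "EnsembleModel")
}

train_member <- function(Xs, y, config, seed) {
  set.seed(seed)
  params <- init_params(config)
  adam <- lapply(params, function(p) list(m = p * 0, v = p * 0))
  lr <- config$learning_rate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t <- 0L
  n <- nrow(Xs)
  bs <- min(config$batch_size, n)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(n)
    for (start in seq(1L, n, by = bs)) {
      rows <- ord[start:min(start + bs - 1L, n)]
      Xb <- Xs[rows, , drop = FALSE]
      yb <- y[rows]
      fwd <- forward_full(params, Xb,
                          dropout = config$dropout_keep < 1,
                          keep = config$dropout_keep,
                          inverted = config$inverted_dropout)
      if (any(!is.finite(fwd$p)))
        abort2(sprintf(
          "non-finite forward output at epoch %d (seed %d); loss so far %g",
          epoch, seed, bce_loss(fwd$p[is.finite(fwd$p)], yb[is.finite(fwd$p)])),
          "morfmlp_training_error")
      grads <- backward(params, Xb, yb, fwd)
      t <- t + 1L
      for (nm in names(params)) {
        adam[[nm]]$m <- b1 * adam[[nm]]$m + (1 - b1) * grads[[nm]]
        adam[[nm]]$v <- b2 * adam[[nm]]$v + (1 - b2) * grads[[nm]]^2
        mhat <- adam[[nm]]$m / (1 - b1^t)
        vhat <- adam[[nm]]$v / (1 - b2^t)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
  }
  if (any(!vapply(params, function(p) all(is.finite(p)), logical(1))))
    abort2(sprintf("non-finite parameters after training (seed %d)", seed),
           "morfmlp_training_error")
  params
}

#' Ensemble prediction
#'
#' Standardizes the features with the model's stored statistics and
#' returns the arithmetic mean of the members' eval-mode forward scores.
#'
#' @param object an \code{EnsembleModel}.
#' @param features raw residue x feature matrix.
#' @param ... unused.
#' @return numeric per-residue scores in [0,1].
#' @export
predict.EnsembleModel <- function(object, features, ...) {
  X <- as.matrix(features)
  if (ncol(X) != object$config$input_dim)
    abort2(sprintf("model expects %d features, data has %d",
                   object$config$input_dim, ncol(X)), "morfmlp_shape_error")
  Xs <- sweep(sweep(X, 2L, object$standardizer$mean), 2L,
              object$standardizer$sd, `/`)
  scores <- vapply(object$members, function(p)
    forward(p, Xs, mode = "eval"), numeric(nrow(Xs)))
  if (nrow(Xs) == 1L) mean(scores) else rowMeans(scores)
}

#' @export
print.EnsembleModel <- function(x, ...) {
  cat(sprintf(
    "EnsembleModel [%s]: %d members, %d -> %d -> %d -> 1, p_d=%g, lr=%g\n",
    x$branch %||% "?", length(x$members), x$config$input_dim,
    x$config$hidden_sizes[1], x$config$hidden_sizes[2],
    x$config$dropout_keep, x$config$learning_rate))
  invisible(x)
}
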