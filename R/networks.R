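#' Initialize parameters of a one-hidden-layer network
#'
#' All three approximators (actor, critic, supervisor) are feed-forward
#' networks with one rectified-linear hidden layer. Weights are drawn from
#' the Glorot uniform scheme `U(-l, l)` with `l = sqrt(6 / (fan_in +
#' fan_out))`; biases start at zero. Reproducible given `seed`.
#'
#' @param d_in Input dimension.
#' @param d_hidden Hidden-layer width (20 for actor/critic, 9 for the
#'   supervisor).
#' @param d_out Output dimension (2 or 4 softmax classes; 1 for the
#'   critic's linear value head).
#' @param seed Optional integer seed; when given, initialization does not
#'   disturb the caller's RNG stream.
#' @return List `W1, b1, W2, b2` of class `mlp_params`, with attributes
#'   `d_in`, `d_hidden`, `d_out`.
#' @export
init_params <- function(d_in, d_hidden, d_out, seed = NULL) {
  draw <- function() {
    l1 <- sqrt(6 / (d_in + d_hidden))
    l2 <- sqrt(6 / (d_hidden + d_out))
    structure(list(
      W1 = matrix(runif(d_in * d_hidden, -l1, l1), d_in, d_hidden),
      b1 = numeric(d_hidden),
      W2 = matrix(runif(d_hidden * d_out, -l2, l2), d_hidden, d_out),
      b2 = numeric(d_out)),
      class = "mlp_params", d_in = d_in, d_hidden = d_hidden, d_out = d_out)
  }
  if (is.null(seed)) return(draw())
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  draw()
}

as_matrix_input <- function(x, d_in, what) {
  X <- if (is.matrix(x)) x else matrix(as.numeric(x), nrow = 1)
  if (ncol(X) != d_in) {
    stop(what, ": input dimension ", ncol(X), " does not match network (",
         d_in, ")")
  }
  X
}

relu <- function(x) (x > 0) * x

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

mlp_hidden <- function(params, X) {
  relu(sweep(X %*% params$W1, 2, params$b1, "+"))
}

mlp_logits <- function(params, H) {
  sweep(H %*% params$W2, 2, params$b2, "+")
}

#' Actor (or supervisor) forward pass: action probabilities
#'
#' Rectified hidden layer followed by a softmax output, so the result is a
#' valid probability vector over action classes (2 for ventilation, 4 for
#' sedation). The greedy action is the argmax with lowest-index tie-break.
#'
#' @param params `mlp_params` with a softmax-sized output.
#' @param state State vector, or matrix with one state per row.
#' @return Probability matrix (rows sum to 1); a single state gives a 1-row
#'   matrix.
#' @export
#' @examples
#' th <- init_params(13, 20, 2, seed = 1)
#' actor_forward(th, as.numeric(example_state()))
actor_forward <- function(params, state) {
  X <- as_matrix_input(state, attr(params, "d_in"), "actor_forward")
  softmax_rows(mlp_logits(params, mlp_hidden(params, X)))
}

#' Greedy action classes of an actor
#'
#' @param params Actor `mlp_params`.
#' @param states State matrix (one per row).
#' @return Integer vector of 0-based action classes (argmax probability,
#'   lowest index on ties).
#' @export
greedy_action <- function(params, states) {
  p <- actor_forward(params, states)
  max.col(p, ties.method = "first") - 1L
}

#' Critic forward pass: scalar action value
#'
#' The critic scores a state--action pair: the input is the state
#' concatenated with the action's one-hot block, the output a linear (no
#' activation) scalar Q.
#'
#' @param params Critic `mlp_params` (output dimension 1).
#' @param state State vector or matrix.
#' @param action_onehot One-hot action vector or matrix (row-aligned with
#'   `state`).
#' @return Numeric vector of Q values.
#' @export
critic_forward <- function(params, state, action_onehot) {
  S <- if (is.matrix(state)) state else matrix(as.numeric(state), nrow = 1)
  A <- if (is.matrix(action_onehot)) action_onehot else
    matrix(as.numeric(action_onehot), nrow = 1)
  X <- as_matrix_input(cbind(S, A), attr(params, "d_in"), "critic_forward")
  as.numeric(mlp_logits(params, mlp_hidden(params, X)))
}

# backprop through the one-hidden-layer net given d(loss)/d(logits);
# returns gradients with the same shapes as the parameters
mlp_backward <- function(params, X, H, dlogits) {
  dW2 <- crossprod(H, dlogits)
  dH <- (dlogits %*% t(params$W2)) * (H > 0)
  dW1 <- crossprod(X, dH)
  dimnames(dW1) <- dimnames(dW2) <- NULL
  list(W1 = dW1, b1 = unname(colSums(dH)), W2 = dW2,
       b2 = unname(colSums(dlogits)))
}

# rescale a gradient so its global L2 norm is at most max_norm
clip_grad <- function(g, max_norm) {
  if (!is.finite(max_norm)) return(g)
  nrm <- sqrt(sum(g$W1^2) + sum(g$b1^2) + sum(g$W2^2) + sum(g$b2^2))
  if (nrm > max_norm) {
    s <- max_norm / nrm
    g$W1 <- g$W1 * s; g$b1 <- g$b1 * s
    g$W2 <- g$W2 * s; g$b2 <- g$b2 * s
  }
  g
}

add_params <- function(p, g, scale = 1) {
  p$W1 <- p$W1 + scale * g$W1; p$b1 <- p$b1 + scale * g$b1
  p$W2 <- p$W2 + scale * g$W2; p$b2 <- p$b2 + scale * g$b2
  p
}

#' Supervised (behavior-cloning) cross-entropy loss and gradient
#'
#' Measures the deviation of the predicted action distribution from the
#' clinician's labeled action: the mean cross-entropy
#' `-mean(log p(label | state))`. Zero exactly when the prediction puts all
#' mass on the label; otherwise positive.
#'
#' @param params Softmax-output `mlp_params` (actor or supervisor).
#' @param states State matrix (one per row).
#' @param labels Integer vector of 0-based label classes.
#' @return List with `loss` (scalar) and `grad` (parameter-shaped list,
#'   the gradient of the loss, i.e. the descent direction is `-grad`).
#' @export
supervised_loss <- function(params, states, labels) {
  X <- as_matrix_input(states, attr(params, "d_in"), "supervised_loss")
  k <- attr(params, "d_out")
  labels <- as.integer(labels)
  if (any(labels < 0L | labels >= k)) {
    stop("labels must be 0-based classes below ", k)
  }
  n <- nrow(X)
  H <- mlp_hidden(params, X)
  P <- softmax_rows(mlp_logits(params, H))
  idx <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-300)))
  Y <- matrix(0, n, k); Y[idx] <- 1
  dlogits <- (P - Y) / n
  list(loss = loss, grad = mlp_backward(params, X, H, dlogits))
}

# gradient (ascent direction) of the blended actor objective
#   (1-eps) * mean(td * log pi(a|s))  -  eps * CE(pi(.|s), label)
# both terms share one backward pass through dlogits
actor_blended_grad <- function(params, states, actions, td_errors, labels,
                               epsilon) {
  X <- as_matrix_input(states, attr(params, "d_in"), "actor_update")
  k <- attr(params, "d_out")
  n <- nrow(X)
  H <- mlp_hidden(params, X)
  P <- softmax_rows(mlp_logits(params, H))
  Ya <- matrix(0, n, k); Ya[cbind(seq_len(n), as.integer(actions) + 1L)] <- 1
  Yl <- matrix(0, n, k); Yl[cbind(seq_len(n), as.integer(labels) + 1L)] <- 1
  drl <- (Ya - P) * td_errors        # d/dlogits of td * log pi(a|s), per row
  dsl <- (Yl - P)                    # d/dlogits of -CE, per row
  dlogits <- ((1 - epsilon) * drl + epsilon * dsl) / n
  mlp_backward(params, X, H, dlogits)
}

# gradient of the critic's squared TD loss mean((Q - y)^2), descent direction
critic_loss_grad <- function(params, states, action_onehots, targets) {
  S <- if (is.matrix(states)) states else matrix(as.numeric(states), nrow = 1)
  A <- if (is.matrix(action_onehots)) action_onehots else
    matrix(as.numeric(action_onehots), nrow = 1)
  X <- as_matrix_input(cbind(S, A), attr(params, "d_in"), "critic_update")
  n <- nrow(X)
  H <- mlp_hidden(params, X)
  Q <- as.numeric(mlp_logits(params, H))
  loss <- mean((Q - targets)^2)
  dlogits <- matrix(2 * (Q - targets) / n, ncol = 1)
  list(loss = loss, q = Q, grad = mlp_backward(params, X, H, dlogits))
}

#' Save / load network parameters as a JSON checkpoint
#'
#' Flat key-to-array archive with a manifest (layer sizes, activation
#' names, package version); plain text, exactly restorable.
#'
#' @param params `mlp_params`.
#' @param path Output `.json` file.
#' @export
save_checkpoint <- function(params, path) {
  obj <- list(
    manifest = list(d_in = attr(params, "d_in"),
                    d_hidden = attr(params, "d_hidden"),
                    d_out = attr(params, "d_out"),
                    hidden_activation = "relu",
                    package = as.character(packageVersion("icusac"))),
    W1 = params$W1, b1 = params$b1, W2 = params$W2, b2 = params$b2)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- obj$manifest
  structure(list(W1 = matrix(obj$W1, m$d_in, m$d_hidden),
                 b1 = as.numeric(obj$b1),
                 W2 = matrix(obj$W2, m$d_hidden, m$d_out),
                 b2 = as.numeric(obj$b2)),
            class = "mlp_params", d_in = m$d_in, d_hidden = m$d_hidden,
            d_out = m$d_out)
}
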