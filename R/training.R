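#' Training configuration for SAC / AC
#'
#' The actor objective blends the reinforcement-learning policy gradient
#' with the supervised behavior-cloning term,
#' \eqn{J(\theta) = (1-\epsilon) J_{RL}(\theta) + \epsilon (-J_{SL}(\theta))},
#' and parameters follow the stochastic-gradient update
#' \eqn{\theta \leftarrow \theta + \alpha[(1-\epsilon)\nabla J_{RL} -
#' \epsilon \nabla J_{SL}]}. `algorithm = "AC"` is the \eqn{\epsilon = 0}
#' special case and forces `epsilon = 0`.
#'
#' @param algorithm `"SAC"` or `"AC"`.
#' @param epsilon Blend weight in \[0, 1\] (default 0.5). Ignored (forced
#'   0) for AC.
#' @param alpha_actor,alpha_critic SGD learning rates (default 0.05 each;
#'   plain SGD on z-scored inputs).
#' @param gamma Discount factor (default 0.95).
#' @param target_sync_every Critic steps between hard target-network
#'   copies (default 100).
#' @param batch_size Minibatch size (default 32).
#' @param n_episodes Training episodes; each episode is a pass over the
#'   transitions of `episode_admissions` sampled admissions (default 50).
#' @param episode_admissions Admissions sampled per episode (default 20).
#' @param seed Integer seed controlling initialization, the train/holdout
#'   split, and the batch stream.
#' @param stage `"vent"` (13-dim state, 2 actions) or `"sed"` (14-dim
#'   state, 4 dose bins).
#' @param holdout_frac Fraction of admissions held out for the per-episode
#'   accuracy/MSE evaluation (default 0.2).
#' @param joint_supervisor Also train the 9-hidden-unit supervisor network
#'   jointly by cross-entropy (default TRUE).
#' @param use_supervisor_labels Use the supervisor network's predicted
#'   classes instead of raw clinician labels in the actor's supervised term
#'   (default FALSE).
#' @param next_action How the critic target picks the successor action:
#'   `"greedy"` (deterministic argmax of the current actor, the default) or
#'   `"expectation"` (probability-weighted Q).
#' @param td_clip TD errors fed to the actor are clamped to
#'   `[-td_clip, td_clip]` (default 5). Clamping happens before the
#'   \eqn{\epsilon} blend, so the update stays affine in \eqn{\epsilon}.
#' @param critic_grad_clip Maximum global L2 norm of the critic gradient
#'   (default 5); `Inf` disables clipping.
#' @return List of class `train_config`.
#' @export
train_config <- function(algorithm = c("SAC", "AC"), epsilon = 0.5,
                         alpha_actor = 0.05, alpha_critic = 0.05,
                         gamma = 0.95, target_sync_every = 100,
                         batch_size = 32, n_episodes = 50,
                         episode_admissions = 20, seed = 1,
                         stage = c("vent", "sed"), holdout_frac = 0.2,
                         joint_supervisor = TRUE,
                         use_supervisor_labels = FALSE,
                         next_action = c("greedy", "expectation"),
                         td_clip = 5, critic_grad_clip = 5) {
  algorithm <- match.arg(algorithm)
  stage <- match.arg(stage)
  next_action <- match.arg(next_action)
  if (epsilon < 0 || epsilon > 1) stop("epsilon must lie in [0, 1]")
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  if (alpha_actor <= 0 || alpha_critic <= 0) stop("learning rates must be > 0")
  if (algorithm == "AC") epsilon <- 0
  structure(list(algorithm = algorithm, epsilon = epsilon,
                 alpha_actor = alpha_actor, alpha_critic = alpha_critic,
                 gamma = gamma, target_sync_every = as.integer(target_sync_every),
                 batch_size = as.integer(batch_size),
                 n_episodes = as.integer(n_episodes),
                 episode_admissions = as.integer(episode_admissions),
                 seed = as.integer(seed), stage = stage,
                 holdout_frac = holdout_frac,
                 joint_supervisor = joint_supervisor,
                 use_supervisor_labels = use_supervisor_labels,
                 next_action = next_action, td_clip = td_clip,
                 critic_grad_clip = critic_grad_clip),
            class = "train_config")
}

#' Extract (state, action, reward, next-state) transitions from a cohort
#'
#' Consecutive row pairs of each admission's trajectory become transitions.
#' The ventilation stage uses the 13-dimensional state and the binary
#' ventilation action; the sedation stage augments the state with the
#' recorded ventilation action (14 dimensions) and uses the 4-class
#' sedative bin. Recorded clinician actions double as supervision labels.
#'
#' @param cohort An `icu_cohort` or trajectory data frame.
#' @param stage `"vent"` or `"sed"`.
#' @return List of class `transition_set`: matrices `S`, `S_next`, integer
#'   `action` (0-based), `labels`, one-hot `A`, rewards `r`, logical
#'   `terminal`, `admission_id`, class count `k`.
#' @export
build_transitions <- function(cohort, stage = c("vent", "sed")) {
  stage <- match.arg(stage)
  df <- if (is.data.frame(cohort)) cohort else cohort_to_df(cohort)
  n <- nrow(df)
  if (n < 2L) stop("need at least two trajectory rows")
  same_next <- c(df$admission_id[-1] == df$admission_id[-n], FALSE)
  cur <- which(same_next)
  nxt <- cur + 1L
  M <- as.matrix(df[, state_features(), drop = FALSE])
  if (stage == "vent") {
    S <- M[cur, , drop = FALSE]
    Sn <- M[nxt, , drop = FALSE]
    a <- as.integer(df$vent_action[cur]); k <- 2L
  } else {
    S <- cbind(M[cur, , drop = FALSE], vent_action = df$vent_action[cur])
    Sn <- cbind(M[nxt, , drop = FALSE], vent_action = df$vent_action[nxt])
    a <- as.integer(df$sed_bin[cur]); k <- 4L
  }
  r <- df$reward_total[cur]
  if (anyNA(r)) stop("transitions carry NA rewards; run annotate_rewards()")
  terminal <- !same_next[nxt]
  structure(list(S = S, S_next = Sn, action = a, labels = a,
                 A = one_hot(a, 0:(k - 1L)), r = r, terminal = terminal,
                 admission_id = df$admission_id[cur], k = k),
            class = "transition_set")
}

subset_transitions <- function(ts, idx) {
  structure(list(S = ts$S[idx, , drop = FALSE],
                 S_next = ts$S_next[idx, , drop = FALSE],
                 action = ts$action[idx], labels = ts$labels[idx],
                 A = ts$A[idx, , drop = FALSE], r = ts$r[idx],
                 terminal = ts$terminal[idx],
                 admission_id = ts$admission_id[idx], k = ts$k),
            class = "transition_set")
}

scaler_fit <- function(S) {
  mu <- colMeans(S)
  sdev <- apply(S, 2, sd)
  sdev[!is.finite(sdev) | sdev < 1e-8] <- 1
  list(mean = mu, sd = sdev)
}

scaler_apply <- function(scaler, S) {
  if (!is.matrix(S)) S <- matrix(as.numeric(S), nrow = 1)
  sweep(sweep(S, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

#' Bootstrapped TD target
#'
#' \eqn{y_t = r} for terminal transitions, otherwise
#' \eqn{y_t = r + \gamma\, Q^{tar}_w(s_{t+1}, \mu_\theta(s_{t+1}))} where
#' \eqn{\mu_\theta} is the current actor's greedy action (or, with
#' `next_action = "expectation"`, the probability-weighted target Q).
#'
#' @param r Reward vector.
#' @param s_next Successor-state matrix (already on the network's input
#'   scale).
#' @param theta Actor parameters.
#' @param w_tar Target-critic parameters.
#' @param gamma Discount in \[0, 1\].
#' @param terminal Logical vector.
#' @param next_action `"greedy"` or `"expectation"`.
#' @return Numeric vector of targets.
#' @export
td_target <- function(r, s_next, theta, w_tar, gamma, terminal,
                      next_action = "greedy") {
  if (!is.matrix(s_next)) s_next <- matrix(as.numeric(s_next), nrow = 1)
  k <- attr(theta, "d_out")
  boot <- if (next_action == "expectation") {
    P <- actor_forward(theta, s_next)
    q <- matrix(0, nrow(s_next), k)
    for (a in seq_len(k)) {
      oh <- matrix(0, nrow(s_next), k); oh[, a] <- 1
      q[, a] <- critic_forward(w_tar, s_next, oh)
    }
    rowSums(P * q)
  } else {
    a_star <- greedy_action(theta, s_next)
    critic_forward(w_tar, s_next, one_hot(a_star, 0:(k - 1L)))
  }
  r + gamma * boot * (1 - as.numeric(terminal))
}

#' One critic gradient step on a transition batch
#'
#' Descends the squared-TD loss `mean((Q_w(s,a) - y_t)^2)`; the reported
#' loss and TD errors are evaluated before the step. The target network is
#' not touched.
#'
#' @param w Critic parameters.
#' @param batch A `transition_set` (states on network scale).
#' @param theta Actor parameters (for the successor action in the target).
#' @param w_tar Target-critic parameters.
#' @param cfg A [train_config()].
#' @return List `w` (updated), `loss`, `td_error` (`y_t - Q_w(s,a)`).
#' @export
critic_update <- function(w, batch, theta, w_tar, cfg) {
  if (length(batch$r) == 0L) stop("empty batch")
  y <- td_target(batch$r, batch$S_next, theta, w_tar, cfg$gamma,
                 batch$terminal, cfg$next_action)
  cg <- critic_loss_grad(w, batch$S, batch$A, y)
  g <- clip_grad(cg$grad, cfg$critic_grad_clip %||% Inf)
  list(w = add_params(w, g, -cfg$alpha_critic), loss = cg$loss,
       td_error = y - cg$q)
}

#' One blended actor gradient step
#'
#' Ascends \eqn{(1-\epsilon)\,\mathrm{mean}(\delta_t \log
#' \pi_\theta(a_t|s_t)) - \epsilon\, J_{SL}(\theta)} where \eqn{\delta_t}
#' are the critic's TD errors and \eqn{J_{SL}} is the cross-entropy toward
#' the clinician labels. \eqn{\epsilon = 0} is the plain actor-critic step;
#' \eqn{\epsilon = 1} the pure behavior-cloning step.
#'
#' @param theta Actor parameters.
#' @param batch A `transition_set` (states on network scale).
#' @param td_errors TD-error vector aligned with the batch.
#' @param labels 0-based clinician label classes aligned with the batch.
#' @param cfg A [train_config()].
#' @return Updated actor parameters.
#' @export
actor_update <- function(theta, batch, td_errors, labels, cfg) {
  if (cfg$epsilon < 0 || cfg$epsilon > 1) stop("epsilon must lie in [0, 1]")
  clip <- cfg$td_clip %||% Inf
  td_errors <- pmin(pmax(td_errors, -clip), clip)
  g <- actor_blended_grad(theta, batch$S, batch$action, td_errors, labels,
                          cfg$epsilon)
  add_params(theta, g, cfg$alpha_actor)
}

#' Hard target-network copy
#'
#' @param w Critic parameters.
#' @return An exact copy to be used as the target network.
#' @export
sync_target <- function(w) w

# deterministic per-episode batch schedule; shared by train_policy and
# behavior_clone so their RNG streams coincide
episode_batches <- function(train_ids, admission_id, episode_admissions,
                            batch_size) {
  ep_ids <- if (length(train_ids) <= episode_admissions) train_ids else
    sample(train_ids, episode_admissions)
  idx <- which(admission_id %in% ep_ids)
  idx <- idx[sample.int(length(idx))]
  split(idx, ceiling(seq_along(idx) / batch_size))
}

split_holdout <- function(ids, holdout_frac, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n_hold <- max(1L, round(holdout_frac * length(ids)))
  hold <- sample(ids, n_hold)
  list(train = setdiff(ids, hold), holdout = hold)
}

#' Train a ventilation or sedation policy by (supervised) actor-critic
#'
#' Offline learning on a fixed labeled cohort: each episode samples
#' `episode_admissions` training admissions and sweeps their transitions in
#' shuffled minibatches. Per batch: one critic TD step (target network
#' synced every `target_sync_every` steps), one blended actor step driven
#' by the critic's TD errors and the clinician labels, and (optionally) one
#' supervisor cross-entropy step. After each episode the held-out accuracy
#' rate, dose MSE (sedation stage), mean Q of an evaluation batch, and mean
#' critic loss are recorded. Fully reproducible given `cfg$seed`.
#'
#' @param cohort An `icu_cohort` (or trajectory data frame with rewards).
#' @param cfg A [train_config()].
#' @return List of class `sac_model`: actor `theta`, critic `w`, target
#'   `w_tar`, `supervisor`, input `scaler`, `cfg`, learning `curve`
#'   (`episode, mean_q, ar, mse, critic_loss`), and the held-out
#'   `transition_set`.
#' @export
#' @examples
#' coh <- simulate_cohort(simulator_config(n_admissions = 8, seed = 3,
#'                                         mean_stay = 40))
#' m <- train_policy(coh, train_config(n_episodes = 2, seed = 1))
#' m$curve
train_policy <- function(cohort, cfg = train_config()) {
  stopifnot(inherits(cfg, "train_config"))
  ts <- if (inherits(cohort, "transition_set")) cohort else
    build_transitions(cohort, cfg$stage)
  if (length(ts$r) == 0L) stop("empty dataset")
  ids <- unique(ts$admission_id)
  sp <- split_holdout(ids, cfg$holdout_frac, cfg$seed + 4L)
  tr <- subset_transitions(ts, ts$admission_id %in% sp$train)
  held <- subset_transitions(ts, ts$admission_id %in% sp$holdout)
  scaler <- scaler_fit(tr$S)
  tr$S <- scaler_apply(scaler, tr$S)
  tr$S_next <- scaler_apply(scaler, tr$S_next)
  held_scaled <- held
  held_scaled$S <- scaler_apply(scaler, held$S)
  d <- ncol(tr$S); k <- ts$k
  theta <- init_params(d, 20L, k, seed = cfg$seed + 1L)
  w <- init_params(d + k, 20L, 1L, seed = cfg$seed + 2L)
  w_tar <- sync_target(w)
  supervisor <- if (cfg$joint_supervisor) {
    init_params(d, 9L, k, seed = cfg$seed + 5L)
  } else NULL
  n_eval <- min(512L, length(held_scaled$r))
  eval_idx <- seq_len(n_eval)
  set.seed(cfg$seed + 3L)
  steps <- 0L
  curve <- vector("list", cfg$n_episodes)
  for (ep in seq_len(cfg$n_episodes)) {
    batches <- episode_batches(sp$train, tr$admission_id,
                               cfg$episode_admissions, cfg$batch_size)
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      batch <- subset_transitions(tr, batches[[bi]])
      cu <- critic_update(w, batch, theta, w_tar, cfg)
      losses[bi] <- cu$loss
      labels <- batch$labels
      if (cfg$use_supervisor_labels && !is.null(supervisor)) {
        labels <- greedy_action(supervisor, batch$S)
      }
      theta <- actor_update(theta, batch, cu$td_error, labels, cfg)
      if (!is.null(supervisor)) {
        sg <- supervised_loss(supervisor, batch$S, batch$labels)
        supervisor <- add_params(supervisor, sg$grad, -cfg$alpha_actor)
      }
      w <- cu$w
      steps <- steps + 1L
      if (steps %% cfg$target_sync_every == 0L) w_tar <- sync_target(w)
    }
    pred <- greedy_action(theta, held_scaled$S)
    ar <- mean(pred == held_scaled$labels)
    mse <- if (cfg$stage == "sed") mean((pred - held_scaled$labels)^2)
           else NA_real_
    a_eval <- pred[eval_idx]
    mean_q <- mean(critic_forward(w, held_scaled$S[eval_idx, , drop = FALSE],
                                  one_hot(a_eval, 0:(k - 1L))))
    curve[[ep]] <- data.frame(episode = ep, mean_q = mean_q, ar = ar,
                              mse = mse, critic_loss = mean(losses))
  }
  structure(list(theta = theta, w = w, w_tar = w_tar,
                 supervisor = supervisor, scaler = scaler, cfg = cfg,
                 curve = do.call(rbind, curve), holdout = held, k = k),
            class = "sac_model")
}

#' Pure behavior cloning (supervised policy learning)
#'
#' Independent supervised trainer: the actor network is fit by plain
#' cross-entropy SGD toward the clinician labels, with the same seeded
#' initialization, holdout split, and batch schedule as [train_policy()].
#' This is the \eqn{\epsilon = 1} limit of the supervised actor-critic.
#'
#' @param cohort An `icu_cohort` or `transition_set`.
#' @param cfg A [train_config()] (its `epsilon`/critic fields are unused).
#' @return List of class `sac_model` (critic fields `NULL`; `mean_q` and
#'   `critic_loss` columns `NA`).
#' @export
behavior_clone <- function(cohort, cfg = train_config()) {
  ts <- if (inherits(cohort, "transition_set")) cohort else
    build_transitions(cohort, cfg$stage)
  if (length(ts$r) == 0L) stop("empty dataset")
  ids <- unique(ts$admission_id)
  sp <- split_holdout(ids, cfg$holdout_frac, cfg$seed + 4L)
  tr <- subset_transitions(ts, ts$admission_id %in% sp$train)
  held <- subset_transitions(ts, ts$admission_id %in% sp$holdout)
  scaler <- scaler_fit(tr$S)
  tr$S <- scaler_apply(scaler, tr$S)
  held_scaled_S <- scaler_apply(scaler, held$S)
  d <- ncol(tr$S); k <- ts$k
  theta <- init_params(d, 20L, k, seed = cfg$seed + 1L)
  set.seed(cfg$seed + 3L)
  curve <- vector("list", cfg$n_episodes)
  for (ep in seq_len(cfg$n_episodes)) {
    batches <- episode_batches(sp$train, tr$admission_id,
                               cfg$episode_admissions, cfg$batch_size)
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      sl <- supervised_loss(theta, tr$S[idx, , drop = FALSE], tr$labels[idx])
      theta <- add_params(theta, sl$grad, -cfg$alpha_actor)
    }
    pred <- greedy_action(theta, held_scaled_S)
    ar <- mean(pred == held$labels)
    mse <- if (cfg$stage == "sed") mean((pred - held$labels)^2) else NA_real_
    curve[[ep]] <- data.frame(episode = ep, mean_q = NA_real_, ar = ar,
                              mse = mse, critic_loss = NA_real_)
  }
  structure(list(theta = theta, w = NULL, w_tar = NULL, supervisor = NULL,
                 scaler = scaler, cfg = cfg, curve = do.call(rbind, curve),
                 holdout = held, k = k),
            class = "sac_model")
}

#' @export
print.sac_model <- function(x, ...) {
  last <- x$curve[nrow(x$curve), ]
  cat(sprintf("<sac_model %s stage=%s eps=%.2f: %d episodes, final AR %.3f%s>\n",
              x$cfg$algorithm, x$cfg$stage, x$cfg$epsilon, nrow(x$curve),
              last$ar,
              if (!is.na(last$mse)) sprintf(", MSE %.3f", last$mse) else ""))
  invisible(x)
}
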