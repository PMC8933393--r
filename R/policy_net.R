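#' Encode one K-step context for the recurrent models
#'
#' Actions are one-hot over the 4 options; in \code{action_reward} mode a
#' fifth component carries the reward scaled by \code{reward_max} (so inputs
#' lie in (0, 1]). The \code{action_only} (reward-oblivious) encoding never
#' sees the reward channel.
#'
#' @param actions integer vector of K actions in 1..4.
#' @param rewards numeric vector of K rewards (ignored in
#'   \code{action_only} mode).
#' @param input_mode \code{"action_reward"} or \code{"action_only"}.
#' @param reward_max scaling constant (default 98, the task's maximum).
#' @return K x D matrix (D = 5 or 4), rows in trial order.
#' @examples
#' encode_input(c(3, 1), c(98, 49))  # rows (0,0,1,0,1) and (1,0,0,0,0.5)
#' @export
encode_input <- function(actions, rewards = NULL,
                         input_mode = c("action_reward", "action_only"),
                         reward_max = 98) {
  input_mode <- match.arg(input_mode)
  if (any(!(actions %in% 1:4))) stop("actions must be in 1..4")
  K <- length(actions)
  onehot <- matrix(0, K, 4)
  onehot[cbind(seq_len(K), actions)] <- 1
  if (input_mode == "action_only") return(onehot)
  if (is.null(rewards) || length(rewards) != K) {
    stop("`rewards` must match `actions` in action_reward mode")
  }
  cbind(onehot, rewards / reward_max)
}

# Window data.frame -> list of K batch matrices (N x D) + target vector.
.encode_samples <- function(samples, input_mode, reward_max) {
  K <- sum(grepl("^a[0-9]+$", names(samples)))
  N <- nrow(samples)
  X <- vector("list", K)
  for (t in seq_len(K)) {
    a <- samples[[paste0("a", t)]]
    if (any(!(a %in% 1:4))) stop("actions must be in 1..4")
    M <- matrix(0, N, 4)
    M[cbind(seq_len(N), a)] <- 1
    if (input_mode == "action_reward") {
      M <- cbind(M, samples[[paste0("r", t)]] / reward_max)
    }
    X[[t]] <- M
  }
  list(X = X, y = samples$target_action, K = K)
}

#' Fit a recurrent next-action policy model
#'
#' Trains a single-layer LSTM (64 hidden units by default) with a 4-way
#' softmax readout to predict the next action from a K-step context of
#' (action, reward) pairs — the exploratory, high-capacity model — or from
#' actions alone — the reward-oblivious model. The mean categorical
#' cross-entropy between the softmax output and the one-hot target action is
#' minimised with Adam on shuffled mini-batches.
#'
#' @param samples window data.frame from \code{\link{build_dataset}}
#'   (training extraction uses the sliding window).
#' @param input_mode \code{"action_reward"} (exploratory) or
#'   \code{"action_only"} (reward-oblivious).
#' @param hidden_units LSTM hidden size (default 64).
#' @param epochs training epochs. The task-faithful configuration is 300;
#'   the default here is 50, which suffices for the synthetic populations
#'   this package targets.
#' @param batch_size mini-batch size (default 2048).
#' @param learning_rate,adam_beta1,adam_beta2 Adam settings (defaults 0.001,
#'   0.9, 0.99).
#' @param reward_max reward scaling constant (default 98).
#' @param seed integer seed controlling initialisation and batch order; the
#'   fit is deterministic given seed and data.
#' @return object of class \code{policy_net}: list with \code{params}
#'   (weights), \code{input_mode}, \code{K}, \code{hidden_units},
#'   \code{training_log} (per-epoch mean loss), \code{config}.
#' @export
policy_net <- function(samples,
                       input_mode = c("action_reward", "action_only"),
                       hidden_units = 64, epochs = 50, batch_size = 2048,
                       learning_rate = 0.001, adam_beta1 = 0.9,
                       adam_beta2 = 0.99, reward_max = 98, seed = 1) {
  input_mode <- match.arg(input_mode)
  if (nrow(samples) < 1) stop("need at least one training sample")
  if (epochs < 1) stop("`epochs` must be >= 1")
  enc <- .encode_samples(samples, input_mode, reward_max)
  if (length(unique(enc$y)) == 1L) {
    warning("all targets are one class; the trivial constant predictor is optimal")
  }
  N <- nrow(samples)
  D <- ncol(enc$X[[1]])

  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  par <- .lstm_init(D, hidden_units)
  st <- .adam_init(par)
  log_loss <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(N)
    starts <- seq.int(1L, N, by = batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1L, N)]
      Xb <- lapply(enc$X, function(M) M[idx, , drop = FALSE])
      yb <- enc$y[idx]
      fwd <- .lstm_forward(par, Xb, keep_cache = TRUE)
      ep_loss <- ep_loss + .lstm_loss(fwd$probs, yb) * length(idx)
      grads <- .lstm_backward(par, Xb, yb, fwd)
      upd <- .adam_step(par, grads, st, learning_rate, adam_beta1, adam_beta2)
      par <- upd$par
      st <- upd$st
    }
    log_loss[ep] <- ep_loss / N
  }
  structure(list(params = par, input_mode = input_mode, K = enc$K,
                 hidden_units = hidden_units,
                 training_log = log_loss,
                 config = list(epochs = epochs, batch_size = batch_size,
                               learning_rate = learning_rate,
                               adam_beta1 = adam_beta1,
                               adam_beta2 = adam_beta2,
                               reward_max = reward_max, seed = seed,
                               n_samples = N)),
            class = "policy_net")
}

#' @export
print.policy_net <- function(x, ...) {
  cat(sprintf(
    "Recurrent policy model (%s): K=%d, %d hidden units, %d epochs\n",
    x$input_mode, x$K, x$hidden_units, x$config$epochs))
  cat(sprintf("  trained on %d samples; final epoch loss %.4f (ln 4 = %.4f)\n",
              x$config$n_samples, utils::tail(x$training_log, 1), log(4)))
  invisible(x)
}

#' @export
summary.policy_net <- function(object, ...) {
  print(object)
  n <- length(object$training_log)
  show <- unique(pmin(n, c(1, ceiling(n / 4), ceiling(n / 2), n)))
  cat("  loss trajectory:\n")
  for (e in show) {
    cat(sprintf("    epoch %3d: %.4f\n", e, object$training_log[e]))
  }
  invisible(object)
}

#' Predict next-action probabilities or classes
#'
#' @param object a fitted \code{policy_net}.
#' @param newdata window data.frame (columns \code{a1..aK}, and
#'   \code{r1..rK} for the action_reward mode).
#' @param type \code{"prob"} for an N x 4 probability matrix (rows sum to
#'   1), \code{"class"} for the argmax action (ties broken toward the lowest
#'   action index).
#' @param ... unused.
#' @return matrix or integer vector.
#' @export
predict.policy_net <- function(object, newdata,
                               type = c("prob", "class"), ...) {
  type <- match.arg(type)
  enc <- .encode_samples(newdata, object$input_mode,
                         object$config$reward_max)
  if (enc$K != object$K) {
    stop(sprintf("context length %d does not match model K=%d",
                 enc$K, object$K))
  }
  probs <- .lstm_forward(object$params, enc$X)$probs
  if (type == "prob") return(probs)
  apply(probs, 1, which.max)
}

#' Evaluate a recurrent policy model on held-out samples
#'
#' The prediction is the argmax of the output distribution; correctness is
#' aggregated per participant and per target trial as well as pooled.
#'
#' @param model a fitted \code{policy_net}.
#' @param samples held-out window data.frame (the evaluation extraction
#'   uses non-overlapping windows so each trial is predicted at most once).
#' @return list of class \code{policy_eval}: \code{predictions} (long
#'   data.frame with participant_id, target_trial, prediction, actual,
#'   correct), \code{accuracy}, \code{by_participant}, \code{by_trial}.
#' @export
evaluate_policy <- function(model, samples) {
  if (nrow(samples) == 0) stop("`samples` must be non-empty")
  cls <- predict(model, samples, type = "class")
  predictions <- data.frame(participant_id = samples$participant_id,
                            target_trial = samples$target_trial,
                            prediction = as.integer(cls),
                            actual = samples$target_action,
                            correct = cls == samples$target_action,
                            stringsAsFactors = FALSE)
  by_p <- stats::aggregate(correct ~ participant_id, predictions, mean)
  names(by_p)[2] <- "accuracy"
  by_t <- stats::aggregate(correct ~ target_trial, predictions, mean)
  names(by_t)[2] <- "accuracy"
  structure(list(predictions = predictions,
                 accuracy = mean(predictions$correct),
                 by_participant = by_p, by_trial = by_t),
            class = "policy_eval")
}

#' @export
print.policy_eval <- function(x, ...) {
  cat(sprintf("Policy evaluation: %.1f%% accuracy over %d predictions (%d participants)\n",
              100 * x$accuracy, nrow(x$predictions),
              nrow(x$by_participant)))
  invisible(x)
}
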