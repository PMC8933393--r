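#' Delta-rule value update
#'
#' Updates the chosen option's expected value by the learning-rate-scaled
#' prediction error (obtained reward minus current value); all other entries
#' are untouched.
#'
#' @param q numeric length-4 value vector.
#' @param action chosen action in 1..4.
#' @param reward obtained reward (points).
#' @param alpha learning rate in [0, 1].
#' @return updated value vector.
#' @examples
#' q_update(c(50, 50, 50, 50), 1, 40, 0.5)  # first entry becomes 45
#' @export
q_update <- function(q, action, reward, alpha) {
  if (alpha < 0 || alpha > 1) stop("`alpha` must be in [0, 1]")
  if (!(action %in% 1:4)) stop("`action` must be in 1..4")
  q[action] <- q[action] + alpha * (reward - q[action])
  q
}

#' Softmax choice probabilities
#'
#' @param q numeric length-4 value vector (finite).
#' @param beta inverse temperature, > 0; larger values give greedier
#'   choices, beta near 0 gives uniform choice.
#' @return probability vector over the 4 actions (sums to 1). Computed with
#'   max-subtraction for numerical stability.
#' @export
action_probs <- function(q, beta) {
  if (beta <= 0) stop("`beta` must be > 0")
  if (any(!is.finite(q))) stop("`q` must be finite")
  z <- beta * q
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Trial-by-trial Q-learning trace for one record
#'
#' Values start at 50 (the middle of the reward range); the choice
#' probabilities and the argmax prediction for each trial are computed from
#' the pre-choice values, and the update is applied only on non-missed
#' trials (a missed round contributes no outcome).
#'
#' @param record a \code{behavioural_record}.
#' @param alpha,beta model parameters.
#' @return list of class \code{q_trace}: \code{Q} (T x 4 pre-choice values),
#'   \code{probs} (T x 4), \code{pred} (argmax prediction per trial, ties
#'   broken toward the lowest action index), \code{final_q}.
#' @export
q_trace <- function(record, alpha, beta) {
  n <- length(record$actions)
  Q <- matrix(NA_real_, n, 4)
  P <- matrix(NA_real_, n, 4)
  pred <- integer(n)
  q <- rep(50, 4)
  for (t in seq_len(n)) {
    Q[t, ] <- q
    P[t, ] <- action_probs(q, beta)
    pred[t] <- which.max(q)  # which.max breaks ties at the lowest index
    if (!record$missed[t] && !is.na(record$actions[t])) {
      q <- q_update(q, record$actions[t], record$rewards[t], alpha)
    }
  }
  structure(list(Q = Q, probs = P, pred = pred, final_q = q),
            class = "q_trace")
}

# Pad records into aligned matrices for the vectorised group likelihood.
.stack_records <- function(records) {
  Tmax <- max(vapply(records, function(r) length(r$actions), integer(1)))
  n <- length(records)
  A <- matrix(NA_integer_, n, Tmax)
  R <- matrix(NA_real_, n, Tmax)
  for (i in seq_len(n)) {
    r <- records[[i]]
    k <- length(r$actions)
    A[i, seq_len(k)] <- ifelse(r$missed, NA_integer_, r$actions)
    R[i, seq_len(k)] <- r$rewards
  }
  list(A = A, R = R)
}

#' Group-level negative log-likelihood of the Q-learning model
#'
#' Sum over all participants and all non-missed trials of minus the log
#' softmax probability of the observed action, with values updated trial by
#' trial from the all-50 initialisation. Missed trials contribute nothing
#' and trigger no update.
#'
#' @param records list of \code{behavioural_record}s.
#' @param alpha,beta parameters.
#' @return scalar negative log-likelihood (nats).
#' @export
qlearn_nll <- function(records, alpha, beta) {
  if (length(records) == 0) stop("`records` must be non-empty")
  st <- if (!is.null(attr(records, "stacked"))) attr(records, "stacked") else
    .stack_records(records)
  .qlearn_nll_stacked(st, alpha, beta)
}

.qlearn_nll_stacked <- function(st, alpha, beta) {
  A <- st$A; R <- st$R
  n <- nrow(A)
  Q <- matrix(50, n, 4)
  nll <- 0
  for (t in seq_len(ncol(A))) {
    a <- A[, t]
    obs <- which(!is.na(a))
    if (length(obs) == 0) next
    Z <- beta * Q[obs, , drop = FALSE]
    Z <- Z - apply(Z, 1, max)
    E <- exp(Z)
    logp <- Z[cbind(seq_along(obs), a[obs])] - log(rowSums(E))
    nll <- nll - sum(logp)
    idx <- cbind(obs, a[obs])
    Q[idx] <- Q[idx] + alpha * (R[cbind(obs, t)] - Q[idx])
  }
  nll
}

#' Fit the reward-oriented Q-learning model
#'
#' Group-level maximum-likelihood fit: a single (alpha, beta) pair is
#' estimated for the entire population by pooling all participants' trials
#' into one likelihood, minimised with bounded quasi-Newton (L-BFGS-B) from
#' \code{n_starts} random initialisations.
#'
#' @param records list of \code{behavioural_record}s.
#' @param alpha_bounds search box for the learning rate (default [0, 1]).
#' @param beta_bounds search box for the inverse temperature (default
#'   (1e-6, 1]; the 1-98 point reward scale makes beta around 0.1 typical).
#' @param n_starts number of random initialisations (default 5).
#' @param seed integer seed for the starts.
#' @param per_participant if \code{TRUE}, fit each participant separately
#'   and return a list of fits (non-default; the group fit is the primary
#'   analysis).
#' @return object of class \code{qlearn}: list with \code{alpha},
#'   \code{beta}, \code{nll}, \code{n_records}, \code{n_trials} (non-missed
#'   trials entering the likelihood), \code{convergence} (per start),
#'   \code{starts} (per-start results), \code{bounds}.
#' @examples
#' \donttest{
#' pop <- generate_population(20, c(q_learning = 1), seed = 1)
#' fit <- qlearn(pop, seed = 1)
#' coef(fit)
#' }
#' @export
qlearn <- function(records, alpha_bounds = c(0, 1),
                   beta_bounds = c(1e-6, 1), n_starts = 5, seed = 1,
                   per_participant = FALSE) {
  if (length(records) == 0) stop("`records` must be non-empty")
  if (per_participant) {
    return(lapply(records, function(r)
      qlearn(list(r), alpha_bounds, beta_bounds, n_starts, seed)))
  }
  st <- .stack_records(records)
  n_trials <- sum(!is.na(st$A))
  obj <- function(par) .qlearn_nll_stacked(st, par[1], par[2])
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  inits <- cbind(stats::runif(n_starts, alpha_bounds[1], alpha_bounds[2]),
                 stats::runif(n_starts, max(beta_bounds[1], 1e-4),
                              beta_bounds[2]))
  starts <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    fit <- tryCatch(
      stats::optim(inits[s, ], obj, method = "L-BFGS-B",
                   lower = c(alpha_bounds[1], beta_bounds[1]),
                   upper = c(alpha_bounds[2], beta_bounds[2])),
      error = function(e) NULL)
    starts[[s]] <- fit
  }
  ok <- !vapply(starts, is.null, logical(1))
  if (!any(ok)) stop("Q-learning fit failed: no start converged")
  nlls <- vapply(starts, function(f) if (is.null(f)) Inf else f$value,
                 numeric(1))
  best <- starts[[which.min(nlls)]]
  structure(list(alpha = unname(best$par[1]), beta = unname(best$par[2]),
                 nll = best$value, n_records = length(records),
                 n_trials = n_trials,
                 convergence = vapply(starts, function(f)
                   if (is.null(f)) NA_integer_ else f$convergence,
                   integer(1)),
                 starts = starts,
                 bounds = list(alpha = alpha_bounds, beta = beta_bounds)),
            class = "qlearn")
}

#' @export
print.qlearn <- function(x, ...) {
  cat("Group-level Q-learning fit\n")
  cat(sprintf("  alpha (learning rate)      : %.4f\n", x$alpha))
  cat(sprintf("  beta  (inverse temperature): %.4f\n", x$beta))
  cat(sprintf("  NLL %.2f over %d trials from %d participants\n",
              x$nll, x$n_trials, x$n_records))
  invisible(x)
}

#' @export
summary.qlearn <- function(object, ...) {
  print(object)
  cat(sprintf("  per-trial mean NLL: %.4f (uniform choice = %.4f)\n",
              object$nll / object$n_trials, log(4)))
  cat(sprintf("  starts converged: %d/%d\n",
              sum(object$convergence == 0, na.rm = TRUE),
              length(object$convergence)))
  invisible(object)
}

#' @export
coef.qlearn <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta)
}

#' @export
logLik.qlearn <- function(object, ...) {
  structure(-object$nll, df = 2, nobs = object$n_trials, class = "logLik")
}

#' Argmax predictions and accuracy of a fitted Q-learning model
#'
#' The model's prediction at each trial is the option with the highest
#' pre-choice value (ties broken toward the lowest action index; the
#' first-trial prediction under the all-50 initialisation is tie-broken and
#' flagged). Accuracy is computed over non-missed trials only; a record with
#' no usable trial gets an \code{NA} accuracy.
#'
#' @param object a \code{qlearn} fit (or any list with \code{alpha},
#'   \code{beta}).
#' @param records list of \code{behavioural_record}s.
#' @return list of class \code{qlearn_score}: \code{predictions} (long
#'   data.frame: participant_id, target_trial, prediction, actual, correct,
#'   first_trial), \code{accuracy} (pooled over non-missed trials),
#'   \code{by_participant}.
#' @export
qlearn_score <- function(object, records) {
  stopifnot(!is.null(object$alpha), !is.null(object$beta))
  rows <- lapply(records, function(r) {
    tr <- q_trace(r, object$alpha, object$beta)
    use <- which(!r$missed & !is.na(r$actions))
    if (length(use) == 0) return(NULL)
    data.frame(participant_id = r$participant_id,
               target_trial = use,
               prediction = tr$pred[use],
               actual = r$actions[use],
               correct = tr$pred[use] == r$actions[use],
               first_trial = use == 1L,
               stringsAsFactors = FALSE)
  })
  predictions <- do.call(rbind, rows)
  by_p <- stats::aggregate(correct ~ participant_id, predictions, mean)
  names(by_p)[2] <- "accuracy"
  structure(list(predictions = predictions,
                 accuracy = mean(predictions$correct),
                 by_participant = by_p),
            class = "qlearn_score")
}

#' @export
predict.qlearn <- function(object, newdata, type = c("score", "probe"), ...) {
  type <- match.arg(type)
  if (type == "score") return(qlearn_score(object, newdata))
  simulate_probe(newdata$actions, newdata$rewards, object)
}

#' Fifth-choice distribution for a 4-step probe
#'
#' Applies four delta-rule updates from a fresh all-50 initialisation and
#' returns the softmax choice distribution for the fifth trial. This is the
#' reward-oriented model's answer to an experimental-simulation stimulus.
#'
#' @param actions four actions in 1..4.
#' @param rewards four rewards (points).
#' @param params a \code{qlearn} fit or \code{list(alpha, beta)}.
#' @return probability vector over the 4 actions.
#' @examples
#' simulate_probe(1:4, c(40, 40, 40, 40), list(alpha = 0.3, beta = 0.15))
#' # uniform: equal rewards on all-different actions leave all values equal
#' @export
simulate_probe <- function(actions, rewards, params) {
  stopifnot(length(actions) == 4, length(rewards) == 4)
  q <- rep(50, 4)
  for (i in 1:4) q <- q_update(q, actions[i], rewards[i], params$alpha)
  action_probs(q, params$beta)
}
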