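#' One Q-learning agent step
#'
#' Applies the delta-rule update to the last outcome's action (if any) and
#' samples the next action from the softmax of the updated values with
#' inverse temperature \code{beta}. Only the chosen entry of \code{q_values}
#' is changed by the update.
#'
#' @param q_values numeric length-4 vector of current action values.
#' @param alpha learning rate in [0, 1].
#' @param beta inverse temperature, > 0.
#' @param last_outcome \code{list(action, reward)} from the previous trial,
#'   or \code{NULL} on the first trial.
#' @return \code{list(action, q_values)} with the sampled action and the
#'   post-update values.
#' @export
q_agent_step <- function(q_values, alpha, beta, last_outcome = NULL) {
  if (beta <= 0) stop("`beta` must be > 0")
  if (!is.null(last_outcome)) {
    q_values <- q_update(q_values, last_outcome$action, last_outcome$reward,
                         alpha)
  }
  p <- action_probs(q_values, beta)
  list(action = sample.int(4L, 1L, prob = p), q_values = q_values)
}

#' One pattern-following (reward-oblivious) agent step
#'
#' Deterministic given the history and the agent's fixed option roles:
#' \code{constant} repeats one option, \code{alternating} alternates between
#' two options, \code{cycle} cycles 1 -> 2 -> 3 -> 4 -> 1 (starting at
#' \code{options[1]} on an empty history).
#'
#' @param action_history integer vector of the agent's past actions
#'   (most recent last; may be empty).
#' @param pattern_type one of \code{"constant"}, \code{"alternating"},
#'   \code{"cycle"}.
#' @param options the agent's fixed option(s): length 1 for constant,
#'   length 2 for alternating, length 1 (starting option) for cycle.
#' @return action in 1..4.
#' @export
pattern_agent_step <- function(action_history, pattern_type,
                               options = c(1L, 2L)) {
  pattern_type <- match.arg(pattern_type,
                            c("constant", "alternating", "cycle"))
  n <- length(action_history)
  last <- if (n > 0) action_history[n] else NA_integer_
  switch(pattern_type,
    constant = as.integer(options[1]),
    alternating = {
      if (n == 0 || is.na(last)) as.integer(options[1])
      else if (last == options[1]) as.integer(options[2])
      else as.integer(options[1])
    },
    cycle = {
      if (n == 0 || is.na(last)) as.integer(options[1])
      else as.integer(last %% 4L + 1L)
    })
}

#' One hybrid agent step
#'
#' Value-gap switching rule: when the learned values clearly separate the
#' best option (gap between the best and second-best value at least
#' \code{value_gap_threshold} points) the agent behaves as a Q-learner;
#' otherwise it falls back to its motor pattern. This is a synthetic-only
#' construct emulating participants who rely on action patterns when rewards
#' indicate no clear best option.
#'
#' @param q_values,alpha,beta as in \code{\link{q_agent_step}}.
#' @param action_history,pattern_type,options as in
#'   \code{\link{pattern_agent_step}}.
#' @param value_gap_threshold gap in points above which the reward-oriented
#'   mode is used.
#' @param last_outcome previous \code{list(action, reward)} or \code{NULL};
#'   the value update is applied in both modes so learning continues.
#' @return \code{list(action, q_values, mode)} where \code{mode} is
#'   \code{"reward"} or \code{"pattern"}.
#' @export
hybrid_agent_step <- function(q_values, action_history, alpha, beta,
                              pattern_type, options, value_gap_threshold,
                              last_outcome = NULL) {
  if (!is.null(last_outcome)) {
    q_values <- q_update(q_values, last_outcome$action, last_outcome$reward,
                         alpha)
  }
  s <- sort(q_values, decreasing = TRUE)
  if (s[1] - s[2] >= value_gap_threshold) {
    p <- action_probs(q_values, beta)
    list(action = sample.int(4L, 1L, prob = p), q_values = q_values,
         mode = "reward")
  } else {
    list(action = pattern_agent_step(action_history, pattern_type, options),
         q_values = q_values, mode = "pattern")
  }
}

#' Build a stateful agent policy from a specification
#'
#' @param spec list with \code{kind} in \code{{"q_learning", "pattern",
#'   "hybrid", "random"}} and the parameters that kind requires:
#'   \code{alpha}, \code{beta} (q_learning/hybrid), \code{pattern_type} and
#'   \code{options} (pattern/hybrid), \code{value_gap_threshold} (hybrid).
#' @return a policy function \code{function(trial, last_outcome)} suitable
#'   for \code{\link{run_episode}}; it carries its Q-values and action
#'   history in a closure. Hybrid agents additionally log their per-choice
#'   mode in \code{attr(policy, "state")$modes}.
#' @export
make_agent <- function(spec) {
  kind <- match.arg(spec$kind, c("q_learning", "pattern", "hybrid", "random"))
  state <- new.env(parent = emptyenv())
  state$q <- rep(50, 4)   # middle of the 1-98 reward range
  state$history <- integer(0)
  state$modes <- character(0)
  fn <- switch(kind,
    q_learning = function(trial, last_outcome) {
      st <- q_agent_step(state$q, spec$alpha, spec$beta, last_outcome)
      state$q <- st$q_values
      st$action
    },
    pattern = function(trial, last_outcome) {
      a <- pattern_agent_step(state$history, spec$pattern_type, spec$options)
      state$history <- c(state$history, a)
      a
    },
    hybrid = function(trial, last_outcome) {
      st <- hybrid_agent_step(state$q, state$history, spec$alpha, spec$beta,
                              spec$pattern_type, spec$options,
                              spec$value_gap_threshold, last_outcome)
      state$q <- st$q_values
      state$history <- c(state$history, st$action)
      state$modes <- c(state$modes, st$mode)
      st$action
    },
    random = function(trial, last_outcome) sample.int(4L, 1L))
  attr(fn, "state") <- state
  attr(fn, "spec") <- spec
  fn
}

.draw_agent_spec <- function(kind, param_ranges) {
  spec <- list(kind = kind)
  if (kind %in% c("q_learning", "hybrid")) {
    spec$alpha <- stats::runif(1, param_ranges$alpha[1], param_ranges$alpha[2])
    spec$beta <- stats::runif(1, param_ranges$beta[1], param_ranges$beta[2])
  }
  if (kind %in% c("pattern", "hybrid")) {
    spec$pattern_type <- sample(c("constant", "alternating", "cycle"), 1)
    spec$options <- switch(spec$pattern_type,
      constant = sample.int(4L, 1L),
      alternating = sample.int(4L, 2L),
      cycle = sample.int(4L, 1L))
  }
  if (kind == "hybrid") {
    spec$value_gap_threshold <- stats::runif(
      1, param_ranges$value_gap_threshold[1],
      param_ranges$value_gap_threshold[2])
  }
  spec
}

#' Generate a heterogeneous synthetic population
#'
#' Each participant is assigned one payoff structure (round-robin) and one
#' agent drawn from the mixture, with per-kind parameters drawn from
#' \code{param_ranges}. Records carry full agent provenance and the whole
#' population is reproducible from \code{seed}.
#'
#' @param n_participants number of participants.
#' @param mixture named proportions over agent kinds (must sum to 1), e.g.
#'   \code{c(q_learning = .4, pattern = .3, hybrid = .2, random = .1)}
#'   (the default).
#' @param payoffs list of \code{payoff_structure}s
#'   (default \code{\link{default_payoff_structures}()}).
#' @param config an \code{\link{episode_config}}.
#' @param param_ranges list of uniform draw ranges: \code{alpha}
#'   (default [0.1, 0.6]), \code{beta} (default [0.05, 0.3]; the 1-98 point
#'   reward scale makes small inverse temperatures appropriate),
#'   \code{value_gap_threshold} (default [5, 20] points).
#' @param seed integer seed.
#' @return list of \code{behavioural_record}s.
#' @export
generate_population <- function(n_participants,
                                mixture = c(q_learning = 0.4, pattern = 0.3,
                                            hybrid = 0.2, random = 0.1),
                                payoffs = default_payoff_structures(),
                                config = episode_config(),
                                param_ranges = list(
                                  alpha = c(0.1, 0.6),
                                  beta = c(0.05, 0.3),
                                  value_gap_threshold = c(5, 20)),
                                seed = 1) {
  if (length(payoffs) == 0) stop("`payoffs` must be a non-empty list")
  if (abs(sum(mixture) - 1) > 1e-8) stop("`mixture` must sum to 1")
  if (is.null(names(mixture)) ||
      !all(names(mixture) %in% c("q_learning", "pattern", "hybrid", "random"))) {
    stop("`mixture` must be named with valid agent kinds")
  }
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  kinds <- sample(names(mixture), n_participants, replace = TRUE,
                  prob = mixture)
  records <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    spec <- .draw_agent_spec(kinds[i], param_ranges)
    spec$seed <- as.integer(seed)
    payoff <- payoffs[[(i - 1L) %% length(payoffs) + 1L]]
    policy <- make_agent(spec)
    rec <- run_episode(policy, payoff, config,
                       participant_id = sprintf("S%04d", i))
    rec$agent <- spec
    records[[i]] <- rec
  }
  records
}
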