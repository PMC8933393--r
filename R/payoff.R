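#' Generate a restless-bandit payoff structure
#'
#' Each option's reward series is an independent Gaussian random walk with
#' per-step standard deviation \code{drift_sd}, initialised uniformly within
#' \code{bounds} and reflected at the bounds so every value stays in range.
#' Reflection (rather than clipping) is used because clipping accumulates
#' probability mass at the edges and shrinks the realised per-step drift.
#'
#' @param n_trials number of trials (rows); must be >= 5.
#' @param drift_sd per-trial drift standard deviation in reward points
#'   (default 2.8).
#' @param bounds length-2 numeric, (reward_min, reward_max); default
#'   \code{c(1, 98)}.
#' @param seed integer seed; the structure is reproducible given the seed.
#' @param n_options number of arms (columns); the task uses 4.
#' @param structure_id small integer label carried through records.
#' @return An object of class \code{payoff_structure}: a list with elements
#'   \code{rewards} (\code{n_trials} x \code{n_options} matrix),
#'   \code{drift_sd}, \code{bounds}, \code{seed}, \code{structure_id}.
#' @examples
#' p <- generate_payoff_structure(150, seed = 1)
#' range(p$rewards) # within [1, 98]
#' @export
generate_payoff_structure <- function(n_trials = 150, drift_sd = 2.8,
                                      bounds = c(1, 98), seed = 1,
                                      n_options = 4, structure_id = 1L) {
  if (!is.numeric(n_trials) || length(n_trials) != 1 || n_trials < 5) {
    stop("`n_trials` must be a single number >= 5")
  }
  if (drift_sd < 0) stop("`drift_sd` must be non-negative")
  if (length(bounds) != 2 || bounds[1] >= bounds[2]) {
    stop("`bounds` must be an ordered pair (min, max)")
  }
  if (n_options < 1) stop("`n_options` must be positive")
  n_trials <- as.integer(n_trials)

  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))

  x <- stats::runif(n_options, bounds[1], bounds[2])
  rewards <- matrix(NA_real_, nrow = n_trials, ncol = n_options)
  rewards[1, ] <- x
  if (n_trials > 1) {
    steps <- matrix(stats::rnorm((n_trials - 1) * n_options, 0, drift_sd),
                    nrow = n_trials - 1)
    for (t in 2:n_trials) {
      x <- .reflect(x + steps[t - 1, ], bounds[1], bounds[2])
      rewards[t, ] <- x
    }
  }
  structure(list(rewards = rewards, drift_sd = drift_sd, bounds = bounds,
                 seed = as.integer(seed),
                 structure_id = as.integer(structure_id)),
            class = "payoff_structure")
}

# Fold a value into [lo, hi] by repeated reflection at both edges.
.reflect <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' The package's three default payoff structures
#'
#' The task uses three payoff structures generated from three fixed,
#' documented seeds (101, 202, 303) with the default drift (sd = 2.8 points
#' per trial) and bounds [1, 98].
#'
#' @param n_trials trials per structure (default 150).
#' @return list of three \code{payoff_structure} objects.
#' @export
default_payoff_structures <- function(n_trials = 150) {
  seeds <- c(101L, 202L, 303L)
  lapply(seq_along(seeds), function(i) {
    generate_payoff_structure(n_trials = n_trials, seed = seeds[i],
                              structure_id = i)
  })
}

#' @export
print.payoff_structure <- function(x, ...) {
  cat(sprintf(
    "Payoff structure %d: %d trials x %d options, drift sd %.2f, bounds [%g, %g], seed %d\n",
    x$structure_id, nrow(x$rewards), ncol(x$rewards), x$drift_sd,
    x$bounds[1], x$bounds[2], x$seed))
  invisible(x)
}

#' Write / read a payoff structure as CSV (+ JSON sidecar)
#'
#' Columns: \code{trial} (1-based), \code{option_1..option_k}. Rewards are
#' kept real-valued internally and rounded to integer points on export.
#' Generation parameters are echoed to \code{<path>.json}.
#'
#' @param payoff a \code{payoff_structure}.
#' @param path CSV path.
#' @return \code{path}, invisibly.
#' @export
write_payoff_structure <- function(payoff, path) {
  stopifnot(inherits(payoff, "payoff_structure"))
  df <- data.frame(trial = seq_len(nrow(payoff$rewards)),
                   round(payoff$rewards))
  names(df) <- c("trial", paste0("option_", seq_len(ncol(payoff$rewards))))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- payoff[c("drift_sd", "bounds", "seed", "structure_id")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_payoff_structure
#' @export
read_payoff_structure <- function(path) {
  df <- utils::read.csv(path)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else
    list(drift_sd = NA_real_, bounds = list(1, 98), seed = NA_integer_,
         structure_id = 1L)
  structure(list(rewards = as.matrix(df[, -1, drop = FALSE]),
                 drift_sd = as.numeric(meta$drift_sd),
                 bounds = as.numeric(unlist(meta$bounds)),
                 seed = as.integer(meta$seed),
                 structure_id = as.integer(meta$structure_id)),
            class = "payoff_structure")
}

#' Episode configuration
#'
#' @param n_trials rounds per episode (default 150).
#' @param miss_probability per-trial probability of a missed trial (no
#'   response within the deadline; no action, no reward). Default 0.01,
#'   which makes about 4\% of extracted 4-step windows span a gap.
#' @return list of class \code{episode_config}.
#' @export
episode_config <- function(n_trials = 150, miss_probability = 0.01) {
  if (n_trials < 5) stop("`n_trials` must be >= 5")
  if (miss_probability < 0 || miss_probability >= 1) {
    stop("`miss_probability` must be in [0, 1)")
  }
  structure(list(n_trials = as.integer(n_trials),
                 miss_probability = miss_probability),
            class = "episode_config")
}

#' Run one agent through a bandit episode
#'
#' Per trial: with probability \code{miss_probability} the trial is marked
#' missed (no action, no reward, the agent is not consulted); otherwise the
#' policy's action is recorded together with the payoff grid's reward for
#' that option and trial. A missed trial simply moves the agent to the next
#' round; its next decision still conditions on its last realised outcome.
#'
#' @param policy a step function \code{function(trial, last_outcome)}
#'   returning an action in 1..4; \code{last_outcome} is
#'   \code{list(action, reward)} from the most recent non-missed trial, or
#'   \code{NULL} before the first choice. See \code{\link{make_agent}}.
#' @param payoff a \code{payoff_structure} with at least
#'   \code{config$n_trials} rows.
#' @param config an \code{\link{episode_config}}.
#' @param participant_id id string stored on the record.
#' @param seed optional integer seed for the miss process and any policy
#'   randomness.
#' @return A \code{behavioural_record}: list with \code{participant_id},
#'   \code{structure_id}, \code{actions}, \code{rewards}, \code{missed},
#'   \code{agent} (provenance, may be NULL).
#' @export
run_episode <- function(policy, payoff, config = episode_config(),
                        participant_id = "S0001", seed = NULL) {
  stopifnot(inherits(payoff, "payoff_structure"))
  n <- config$n_trials
  if (nrow(payoff$rewards) < n) stop("payoff has fewer rows than n_trials")
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(as.integer(seed))
  }
  actions <- rep(NA_integer_, n)
  rewards <- rep(NA_real_, n)
  missed <- stats::runif(n) < config$miss_probability
  last_outcome <- NULL
  for (t in seq_len(n)) {
    if (missed[t]) next
    a <- policy(t, last_outcome)
    if (!is.numeric(a) || length(a) != 1 || is.na(a) || !(a %in% 1:4)) {
      stop("policy returned an action outside {1..4} at trial ", t)
    }
    a <- as.integer(a)
    r <- payoff$rewards[t, a]
    actions[t] <- a
    rewards[t] <- r
    last_outcome <- list(action = a, reward = r)
  }
  new_behavioural_record(participant_id, payoff$structure_id,
                         actions, rewards, missed)
}

new_behavioural_record <- function(participant_id, structure_id,
                                   actions, rewards, missed, agent = NULL) {
  stopifnot(length(actions) == length(rewards),
            length(actions) == length(missed))
  if (any(missed & !is.na(actions))) {
    stop("missed trials must have no action")
  }
  structure(list(participant_id = participant_id,
                 structure_id = structure_id,
                 actions = as.integer(actions),
                 rewards = as.numeric(rewards),
                 missed = as.logical(missed),
                 agent = agent),
            class = "behavioural_record")
}

#' @export
print.behavioural_record <- function(x, ...) {
  cat(sprintf("Behavioural record %s: %d trials (%d missed), structure %s%s\n",
              x$participant_id, length(x$actions), sum(x$missed),
              as.character(x$structure_id),
              if (!is.null(x$agent)) paste0(", agent ", x$agent$kind) else ""))
  invisible(x)
}
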