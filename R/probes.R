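#' Enumerate experimental-simulation probes
#'
#' Builds the 3 x 3 grid of action-pattern x reward-pattern stimuli:
#' action patterns \emph{constant} (a-a-a-a), \emph{alternating} (a-b-a-b)
#' and \emph{all_different} (a-b-c-d), crossed with reward patterns
#' \emph{constant} (r1 = r2 = r3 = r4), \emph{ascending}
#' (r1 < r2 < r3 < r4) and \emph{descending} (r1 > r2 > r3 > r4). Within
#' each cell, variants differ in the concrete reward values (constant
#' rewards include levels below and above the 50-point midpoint) and in
#' which options play the roles a, b, c, d. All-different assignments are
#' the four rotations of the 1-2-3-4 cycle, so the pattern-completing next
#' action is always the window's first action.
#'
#' @param variants_per_cell probes per category cell (default 8).
#' @param reward_levels list with components \code{constant} (scalar
#'   levels; default \code{c(20, 30, 40, 60, 70, 80)}) and \code{ascending}
#'   (list of increasing 4-vectors; descending probes use their reverses;
#'   default includes the canonical 20-30-70-80).
#' @param seed integer seed for the deterministic choice of variants when
#'   the grid exceeds \code{variants_per_cell}.
#' @return data.frame: probe_id, action_category, reward_category,
#'   a1..a4, r1..r4, completion (the pattern-completing fifth action).
#' @export
enumerate_probes <- function(variants_per_cell = 8,
                             reward_levels = list(
                               constant = c(20, 30, 40, 60, 70, 80),
                               ascending = list(c(20, 30, 70, 80),
                                                c(10, 30, 50, 70),
                                                c(35, 45, 55, 65),
                                                c(50, 60, 70, 80))),
                             seed = 1) {
  if (variants_per_cell < 1) stop("`variants_per_cell` must be >= 1")
  cl <- unlist(reward_levels$constant)
  if (any(cl < 1 | cl > 98)) stop("reward levels must lie in [1, 98]")
  for (v in reward_levels$ascending) {
    if (any(diff(v) <= 0)) stop("ascending reward variants must strictly increase")
    if (any(v < 1 | v > 98)) stop("reward levels must lie in [1, 98]")
  }

  action_sets <- list(
    constant = lapply(1:4, function(a) rep(a, 4)),
    alternating = {
      prs <- utils::combn(4, 2)
      c(lapply(seq_len(ncol(prs)), function(i)
          rep(prs[, i], 2)),
        lapply(seq_len(ncol(prs)), function(i)
          rep(rev(prs[, i]), 2)))
    },
    all_different = lapply(0:3, function(s) (s + 0:3) %% 4 + 1))
  reward_sets <- list(
    constant = lapply(reward_levels$constant, rep, times = 4),
    ascending = reward_levels$ascending,
    descending = lapply(reward_levels$ascending, rev))

  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  rows <- list()
  for (ac in names(action_sets)) {
    for (rc in names(reward_sets)) {
      grid <- expand.grid(ai = seq_along(action_sets[[ac]]),
                          ri = seq_along(reward_sets[[rc]]))
      take <- if (nrow(grid) <= variants_per_cell) seq_len(nrow(grid)) else
        sample.int(nrow(grid), variants_per_cell)
      for (g in take) {
        a <- action_sets[[ac]][[grid$ai[g]]]
        r <- reward_sets[[rc]][[grid$ri[g]]]
        completion <- switch(ac,
          constant = a[1],
          alternating = a[1],       # a-b-a-b continues with a
          all_different = a[1])     # the cycle returns to its first action
        rows[[length(rows) + 1L]] <- data.frame(
          action_category = ac, reward_category = rc,
          a1 = a[1], a2 = a[2], a3 = a[3], a4 = a[4],
          r1 = r[1], r2 = r[2], r3 = r[3], r4 = r[4],
          completion = completion, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- cbind(probe_id = sprintf("P%03d", seq_len(nrow(out))), out)
  out$probe_id <- as.character(out$probe_id)
  out
}

#' Fifth-choice distribution of a model for one probe
#'
#' Dispatches on the model class: a \code{policy_net} encodes the probe in
#' its own input mode (the reward-oblivious model therefore never sees the
#' rewards); a \code{qlearn} fit applies four value updates from the all-50
#' initialisation and returns the softmax distribution.
#'
#' @param model a \code{policy_net} or \code{qlearn} object.
#' @param actions,rewards the probe's four actions and rewards.
#' @return probability vector over the 4 actions.
#' @export
predict_probe <- function(model, actions, rewards) {
  UseMethod("predict_probe")
}

#' @export
predict_probe.policy_net <- function(model, actions, rewards) {
  df <- as.data.frame(c(stats::setNames(as.list(actions), paste0("a", 1:4)),
                        stats::setNames(as.list(rewards), paste0("r", 1:4))))
  drop(predict(model, df, type = "prob"))
}

#' @export
predict_probe.qlearn <- function(model, actions, rewards) {
  simulate_probe(actions, rewards, model)
}

#' Collect all models' predictions on a probe set
#'
#' @param probes probe data.frame from \code{\link{enumerate_probes}}.
#' @param models named list of models supporting
#'   \code{\link{predict_probe}} (canonically \code{exploratory},
#'   \code{reward_oblivious}, \code{q_model}).
#' @return long data.frame: probe_id, action_category, reward_category,
#'   model, p1..p4 (each row a distribution summing to 1). A model failing
#'   on a probe is recorded as missing with a warning and the run
#'   continues.
#' @export
collect_predictions <- function(probes, models) {
  stopifnot(nrow(probes) >= 1, length(models) >= 1, !is.null(names(models)))
  rows <- list()
  for (i in seq_len(nrow(probes))) {
    a <- as.integer(probes[i, paste0("a", 1:4)])
    r <- as.numeric(probes[i, paste0("r", 1:4)])
    for (nm in names(models)) {
      p <- tryCatch(predict_probe(models[[nm]], a, r),
                    error = function(e) {
                      warning(sprintf("model '%s' failed on probe %s: %s",
                                      nm, probes$probe_id[i],
                                      conditionMessage(e)))
                      rep(NA_real_, 4)
                    })
      rows[[length(rows) + 1L]] <- data.frame(
        probe_id = probes$probe_id[i],
        action_category = probes$action_category[i],
        reward_category = probes$reward_category[i],
        model = nm, p1 = p[1], p2 = p[2], p3 = p[3], p4 = p[4],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Symmetric Kullback-Leibler distance between two choice distributions
#'
#' The average of the two directed KL divergences,
#' \code{0.5 KL(p||q) + 0.5 KL(q||p)}, in nats. Components are floored at
#' \code{eps} before the logs; softmax outputs never reach exact zero, so
#' the floor is a safety net only.
#'
#' @param p,q probability vectors over the 4 actions (non-negative, each
#'   summing to 1).
#' @param eps floor applied to components (default 1e-10).
#' @return non-negative scalar; 0 iff p = q (after flooring).
#' @export
sym_kl <- function(p, q, eps = 1e-10) {
  if (length(p) != length(q)) stop("`p` and `q` must have equal length")
  if (any(p < 0) || any(q < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    stop("`p` and `q` must each sum to 1")
  }
  p <- pmax(p, eps)
  q <- pmax(q, eps)
  0.5 * sum(p * log(p / q)) + 0.5 * sum(q * log(q / p))
}

#' Pairwise model distances aggregated by probe category
#'
#' @param predictions long table from \code{\link{collect_predictions}}.
#' @param pairs optional list of length-2 character vectors naming the
#'   model pairs to score; default all unordered pairs.
#' @return list: \code{cells} (data.frame model_a, model_b,
#'   action_category, reward_category, mean_distance, n_probes — the mean
#'   symmetric KL over the cell's probes) and \code{per_probe} (the full
#'   per-probe distance table). Cells with no scored probe are absent, with
#'   a warning.
#' @export
distance_matrix <- function(predictions, pairs = NULL) {
  models <- unique(predictions$model)
  if (is.null(pairs)) {
    pairs <- list()
    for (i in seq_along(models)) for (j in seq_along(models)) {
      if (i < j) pairs[[length(pairs) + 1L]] <- c(models[i], models[j])
    }
  }
  per <- list()
  for (pr in pairs) {
    d1 <- predictions[predictions$model == pr[1], , drop = FALSE]
    d2 <- predictions[predictions$model == pr[2], , drop = FALSE]
    d2 <- d2[match(d1$probe_id, d2$probe_id), , drop = FALSE]
    for (i in seq_len(nrow(d1))) {
      p <- as.numeric(d1[i, paste0("p", 1:4)])
      q <- as.numeric(d2[i, paste0("p", 1:4)])
      dist <- if (anyNA(p) || anyNA(q)) NA_real_ else sym_kl(p, q)
      per[[length(per) + 1L]] <- data.frame(
        model_a = pr[1], model_b = pr[2], probe_id = d1$probe_id[i],
        action_category = d1$action_category[i],
        reward_category = d1$reward_category[i],
        distance = dist, stringsAsFactors = FALSE)
    }
  }
  per <- do.call(rbind, per)
  scored <- per[!is.na(per$distance), , drop = FALSE]
  if (nrow(scored) < nrow(per)) {
    warning("some probes could not be scored and are absent from cell means")
  }
  cells <- stats::aggregate(
    distance ~ model_a + model_b + action_category + reward_category,
    scored, function(z) c(m = mean(z), n = length(z)))
  cells <- data.frame(cells[, 1:4],
                      mean_distance = cells$distance[, "m"],
                      n_probes = as.integer(cells$distance[, "n"]),
                      stringsAsFactors = FALSE)
  list(cells = cells, per_probe = per)
}

#' Label each probe cell by which explicit model the black box tracks
#'
#' For each action x reward category cell, compares the exploratory model's
#' distance to the reward-oblivious model and to the reward-oriented
#' (Q-learning) model: the label is \code{both} when the two explicit
#' models are themselves within \code{both_tol} of each other,
#' \code{neither} when both distances exceed \code{neither_threshold}, and
#' otherwise the nearer explicit model.
#'
#' @param cells cell table from \code{\link{distance_matrix}}, containing
#'   the pairs (exploratory, reward_oblivious), (exploratory, q_model) and
#'   (reward_oblivious, q_model).
#' @param exploratory,reward_oblivious,q_model model names as used in the
#'   cell table.
#' @param both_tol distance (nats) under which the explicit models count as
#'   agreeing (default 0.05).
#' @param neither_threshold distance (nats) above which the exploratory
#'   model matches no explicit model (default 1.0).
#' @return data.frame: action_category, reward_category, d_reward_oblivious,
#'   d_reward_oriented, d_explicit_pair, label.
#' @export
classify_convergence <- function(cells, exploratory = "exploratory",
                                 reward_oblivious = "reward_oblivious",
                                 q_model = "q_model",
                                 both_tol = 0.05, neither_threshold = 1.0) {
  get_d <- function(m1, m2, ac, rc) {
    hit <- (cells$model_a == m1 & cells$model_b == m2) |
      (cells$model_a == m2 & cells$model_b == m1)
    hit <- hit & cells$action_category == ac & cells$reward_category == rc
    if (!any(hit)) return(NA_real_)
    cells$mean_distance[hit][1]
  }
  grid <- unique(cells[, c("action_category", "reward_category")])
  out <- list()
  for (i in seq_len(nrow(grid))) {
    ac <- grid$action_category[i]
    rc <- grid$reward_category[i]
    d_ro <- get_d(exploratory, reward_oblivious, ac, rc)
    d_q <- get_d(exploratory, q_model, ac, rc)
    d_ex <- get_d(reward_oblivious, q_model, ac, rc)
    label <- if (is.na(d_ro) || is.na(d_q)) NA_character_
      else if (min(d_ro, d_q) > neither_threshold) "neither"
      else if (!is.na(d_ex) && d_ex <= both_tol) "both"
      else if (d_ro <= d_q) "reward_oblivious" else "reward_oriented"
    out[[i]] <- data.frame(action_category = ac, reward_category = rc,
                           d_reward_oblivious = d_ro,
                           d_reward_oriented = d_q,
                           d_explicit_pair = d_ex,
                           label = label, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
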