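#' Extract K-step context windows from a behavioural record
#'
#' Missed trials are removed from the action stream first; windows are then
#' consecutive over the remaining trials. A window is flagged
#' \code{has_gap = TRUE} when its span (context plus target) skips over one
#' or more removed trials. \code{sliding} advances the window by one kept
#' trial; \code{non_overlapping} advances by K + 1 so no trial is reused
#' between samples (the evaluation-time extraction).
#'
#' @param record a \code{behavioural_record}.
#' @param K context length (default 4).
#' @param mode \code{"sliding"} (training) or \code{"non_overlapping"}
#'   (evaluation).
#' @param max_gap optional maximum number of missed trials a window may
#'   span; windows exceeding it are dropped. Default \code{Inf} (keep all,
#'   flagged) — with a slow reward drift, windows spanning a single missed
#'   round remain informative.
#' @return data.frame with columns \code{participant_id},
#'   \code{target_trial} (1-based original trial index),
#'   \code{a1..aK}, \code{r1..rK}, \code{target_action}, \code{has_gap}.
#'   A record with fewer than K + 1 usable trials yields zero rows.
#' @export
make_windows <- function(record, K = 4,
                         mode = c("sliding", "non_overlapping"),
                         max_gap = Inf) {
  stopifnot(inherits(record, "behavioural_record"), K >= 1)
  mode <- match.arg(mode)
  keep <- which(!record$missed & !is.na(record$actions))
  n <- length(keep)
  if (n < K + 1) return(.empty_windows(K))
  a <- record$actions[keep]
  r <- record$rewards[keep]
  starts <- if (mode == "sliding") seq_len(n - K) else
    seq.int(1L, n - K, by = K + 1L)
  ctx_a <- matrix(0L, length(starts), K)
  ctx_r <- matrix(0, length(starts), K)
  for (j in seq_len(K)) {
    ctx_a[, j] <- a[starts + j - 1L]
    ctx_r[, j] <- r[starts + j - 1L]
  }
  span <- keep[starts + K] - keep[starts]   # original-index span; K if gap-free
  gap_n <- span - K
  res <- data.frame(participant_id = record$participant_id,
                    target_trial = keep[starts + K],
                    ctx_a, ctx_r,
                    target_action = a[starts + K],
                    has_gap = gap_n > 0L,
                    stringsAsFactors = FALSE)
  names(res)[3:(2 + 2 * K)] <- c(paste0("a", 1:K), paste0("r", 1:K))
  res[gap_n <= max_gap, , drop = FALSE]
}

.empty_windows <- function(K) {
  res <- data.frame(participant_id = character(0),
                    target_trial = integer(0))
  for (nm in paste0("a", 1:K)) res[[nm]] <- integer(0)
  for (nm in paste0("r", 1:K)) res[[nm]] <- numeric(0)
  res$target_action <- integer(0)
  res$has_gap <- logical(0)
  res
}

#' Build a window dataset over a whole population
#'
#' @param records list of \code{behavioural_record}s.
#' @inheritParams make_windows
#' @return row-bound data.frame of \code{\link{make_windows}} output.
#' @export
build_dataset <- function(records, K = 4,
                          mode = c("sliding", "non_overlapping"),
                          max_gap = Inf) {
  mode <- match.arg(mode)
  do.call(rbind, lapply(records, make_windows, K = K, mode = mode,
                        max_gap = max_gap))
}

#' Participant-wise cross-validation folds
#'
#' Participants are shuffled by seed and partitioned into \code{k}
#' near-equal test sets; each fold trains on the complement, so a model is
#' never evaluated on a participant it saw during training, and across folds
#' every participant is evaluated exactly once.
#'
#' @param records list of \code{behavioural_record}s (or character vector of
#'   participant ids).
#' @param k number of folds (default 5).
#' @param seed integer seed for the shuffle.
#' @return list of folds, each \code{list(fold_id, train_participants,
#'   test_participants)}.
#' @export
split_by_participant <- function(records, k = 5, seed = 1) {
  ids <- if (is.character(records)) records else
    vapply(records, function(r) r$participant_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate participant ids")
  if (k < 2) stop("`k` must be >= 2")
  if (length(ids) < k) stop("need at least `k` participants")
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  ids <- sample(ids)
  grp <- rep(seq_len(k), length.out = length(ids))  # sizes differ by <= 1
  grp <- sort(grp)
  lapply(seq_len(k), function(i) {
    list(fold_id = i,
         train_participants = ids[grp != i],
         test_participants = ids[grp == i])
  })
}

#' Shuffle window samples across participants
#'
#' The extracted sequences carry no continuity beyond their K steps, so
#' training batches are drawn from a global shuffle.
#'
#' @param samples window data.frame from \code{\link{build_dataset}}.
#' @param seed integer seed.
#' @return the same rows in a seed-reproducible random order.
#' @export
shuffle_samples <- function(samples, seed = 1) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  out <- samples[sample.int(nrow(samples)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
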