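#' Align prediction tables from several models
#'
#' Restricts each model's long prediction table (participant_id,
#' target_trial, prediction, actual, correct) to the (participant, trial)
#' pairs every model scored, so accuracy comparisons are paired. Trials a
#' model cannot score (the first K trials, or gap-filtered windows) are
#' dropped for all models.
#'
#' @param predictions named list of prediction data.frames (e.g. from
#'   \code{\link{evaluate_policy}}\code{$predictions} and
#'   \code{\link{qlearn_score}}\code{$predictions}).
#' @return named list of data.frames with identical, sorted key sets.
#' @export
align_predictions <- function(predictions) {
  stopifnot(is.list(predictions), !is.null(names(predictions)))
  keys <- lapply(predictions, function(d)
    paste(d$participant_id, d$target_trial, sep = "\r"))
  common <- Reduce(intersect, keys)
  lapply(seq_along(predictions), function(i) {
    d <- predictions[[i]][match(common, keys[[i]]), , drop = FALSE]
    rownames(d) <- NULL
    d
  }) |> stats::setNames(names(predictions))
}

.check_aligned <- function(predictions) {
  keys <- lapply(predictions, function(d)
    paste(d$participant_id, d$target_trial, sep = "\r"))
  for (i in seq_along(keys)[-1]) {
    if (!identical(keys[[1]], keys[[i]])) {
      stop("prediction sets are not aligned on identical (participant, trial) pairs; ",
           "run align_predictions() first")
    }
  }
}

#' Per-participant accuracy table with paired model differences
#'
#' @param predictions named list of aligned prediction data.frames (see
#'   \code{\link{align_predictions}}).
#' @return list: \code{table} (long data.frame model x participant:
#'   n_predictions, n_correct, accuracy), \code{paired} (wide data.frame of
#'   per-participant accuracies, one column per model, plus all pairwise
#'   difference columns \code{A_minus_B}), \code{pooled} (named vector of
#'   pooled accuracies, the prediction-weighted means of the participant
#'   accuracies).
#' @export
accuracy_by_participant <- function(predictions) {
  .check_aligned(predictions)
  long <- do.call(rbind, lapply(names(predictions), function(nm) {
    d <- predictions[[nm]]
    agg <- stats::aggregate(correct ~ participant_id, d,
                            function(z) c(n = length(z), k = sum(z)))
    data.frame(model = nm, participant_id = agg$participant_id,
               n_predictions = agg$correct[, "n"],
               n_correct = agg$correct[, "k"],
               accuracy = agg$correct[, "k"] / agg$correct[, "n"],
               stringsAsFactors = FALSE)
  }))
  wide <- stats::reshape(long[, c("model", "participant_id", "accuracy")],
                         direction = "wide", idvar = "participant_id",
                         timevar = "model")
  names(wide) <- sub("^accuracy\\.", "", names(wide))
  nms <- names(predictions)
  if (length(nms) > 1) {
    for (i in seq_along(nms)) for (j in seq_along(nms)) {
      if (i < j) {
        wide[[paste0(nms[i], "_minus_", nms[j])]] <-
          wide[[nms[i]]] - wide[[nms[j]]]
      }
    }
  }
  pooled <- vapply(predictions, function(d) mean(d$correct), numeric(1))
  list(table = long, paired = wide, pooled = pooled)
}

#' Per-trial accuracy curves
#'
#' Accuracy of each model at each target trial across participants —
#' aligned with the payoff structure, these curves localise the periods of
#' reward uncertainty where models diverge.
#'
#' @param predictions named list of aligned prediction data.frames.
#' @param payoff optional \code{payoff_structure} attached to the result
#'   for plotting against reward dominance.
#' @return data.frame: model, target_trial, n, accuracy; the payoff (if
#'   given) in \code{attr(, "payoff")}.
#' @export
accuracy_by_time <- function(predictions, payoff = NULL) {
  .check_aligned(predictions)
  out <- do.call(rbind, lapply(names(predictions), function(nm) {
    d <- predictions[[nm]]
    agg <- stats::aggregate(correct ~ target_trial, d,
                            function(z) c(n = length(z), acc = mean(z)))
    data.frame(model = nm, target_trial = agg$target_trial,
               n = agg$correct[, "n"], accuracy = agg$correct[, "acc"],
               stringsAsFactors = FALSE)
  }))
  if (!is.null(payoff)) attr(out, "payoff") <- payoff
  out
}

#' Trial-wise prediction similarity of two models
#'
#' For each trial, the fraction of participants on which the two models
#' agree in correctness — both correct or both wrong counts as agreement —
#' divided by the number M of participants with a defined prediction that
#' trial. (Equivalently 1 minus the mean XOR of the two correctness flags.)
#' Trials with M = 0 are absent from the result.
#'
#' @param pred1,pred2 aligned prediction data.frames of the two models.
#' @return data.frame: target_trial, similarity in [0, 1], M.
#' @export
similarity_over_time <- function(pred1, pred2) {
  .check_aligned(list(a = pred1, b = pred2))
  agree <- as.numeric(pred1$correct == pred2$correct)
  agg <- stats::aggregate(agree ~ target_trial,
                          data.frame(agree = agree,
                                     target_trial = pred1$target_trial),
                          function(z) c(M = length(z), s = mean(z)))
  data.frame(target_trial = agg$target_trial,
             similarity = agg$agree[, "s"],
             M = agg$agree[, "M"])
}
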