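#' Write a population to long CSV (+ agent manifest)
#'
#' Columns: participant_id, trial, action, reward, missed, structure_id.
#' Missed trials keep their row with empty action/reward. Rewards are
#' rounded to integer points on export. Agent provenance goes to a JSON
#' manifest at \code{<path>.manifest.json}.
#'
#' @param records list of \code{behavioural_record}s.
#' @param path CSV path.
#' @return \code{path}, invisibly.
#' @export
write_population <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r) {
    data.frame(participant_id = r$participant_id,
               trial = seq_along(r$actions),
               action = r$actions,
               reward = ifelse(is.na(r$rewards), NA, round(r$rewards)),
               missed = r$missed,
               structure_id = r$structure_id,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  manifest <- lapply(records, function(r)
    c(list(participant_id = r$participant_id), r$agent))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load behavioural records from long CSV
#'
#' Accepts the format written by \code{\link{write_population}} (and the
#' equivalent long format of openly shared bandit datasets): columns
#' \code{participant_id} (or \code{participant}), \code{trial},
#' \code{action}, \code{reward}; optional \code{missed} and
#' \code{structure_id}. Rows with an empty action are treated as missed
#' trials. Out-of-range actions or trials are rejected with their row
#' numbers.
#'
#' @param path CSV path.
#' @return list of \code{behavioural_record}s.
#' @export
load_real_records <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop("cannot parse '", path, "': ", conditionMessage(e)))
  pid_col <- intersect(c("participant_id", "participant"), names(df))[1]
  if (is.na(pid_col) || !all(c("trial", "action", "reward") %in% names(df))) {
    stop("'", path,
         "' must have participant(_id), trial, action, reward columns")
  }
  bad <- which(!is.na(df$action) & !(df$action %in% 1:4))
  if (length(bad)) {
    stop("action outside 1..4 at data row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  bad <- which(is.na(df$trial) | df$trial < 1)
  if (length(bad)) {
    stop("invalid trial index at data row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  if (is.null(df$missed)) df$missed <- is.na(df$action)
  if (is.null(df$structure_id)) df$structure_id <- NA_integer_
  lapply(split(df, df[[pid_col]]), function(d) {
    d <- d[order(d$trial), , drop = FALSE]
    n <- max(d$trial)
    actions <- rep(NA_integer_, n)
    rewards <- rep(NA_real_, n)
    missed <- rep(TRUE, n)   # absent rows count as missed rounds
    actions[d$trial] <- as.integer(d$action)
    rewards[d$trial] <- as.numeric(d$reward)
    missed[d$trial] <- as.logical(d$missed) | is.na(d$action)
    rewards[missed] <- NA_real_
    actions[missed] <- NA_integer_
    new_behavioural_record(d[[pid_col]][1], d$structure_id[1],
                           actions, rewards, missed)
  }) |> unname()
}

#' Persist window samples as CSV
#'
#' @param samples window data.frame from \code{\link{build_dataset}}.
#' @param path CSV path.
#' @return \code{path}, invisibly.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}

#' Save / load a fitted recurrent policy model
#'
#' Weights are written as flat JSON arrays with a metadata header
#' (input mode, dimensions, training configuration), so saved models are
#' plain text and portable.
#'
#' @param model a \code{policy_net}.
#' @param path file path (JSON).
#' @return \code{path} invisibly; \code{read_policy_net} returns the model.
#' @export
write_policy_net <- function(model, path) {
  stopifnot(inherits(model, "policy_net"))
  obj <- list(input_mode = model$input_mode, K = model$K,
              hidden_units = model$hidden_units,
              config = model$config,
              training_log = model$training_log,
              params = lapply(model$params, function(p) {
                if (is.matrix(p)) list(dim = dim(p), x = as.numeric(p))
                else list(dim = length(p), x = as.numeric(p))
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_policy_net
#' @export
read_policy_net <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(obj$params, function(p) {
    if (length(p$dim) == 2) matrix(p$x, p$dim[1], p$dim[2]) else p$x
  })
  structure(list(params = params, input_mode = obj$input_mode,
                 K = obj$K, hidden_units = obj$hidden_units,
                 training_log = obj$training_log,
                 config = as.list(obj$config)),
            class = "policy_net")
}
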