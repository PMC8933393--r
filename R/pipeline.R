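#' Study run configuration
#'
#' One configuration object drives \code{\link{run_bandit_study}}. All
#' randomness flows from \code{seed} via fixed named substreams
#' (population, folds, network weights, probes), so stages are
#' independently reproducible. The configuration round-trips losslessly
#' through JSON (\code{\link{write_bandit_config}}).
#'
#' @param n_participants population size (default 300).
#' @param mixture agent-kind proportions (default 0.4 q_learning,
#'   0.3 pattern, 0.2 hybrid, 0.1 random).
#' @param n_trials trials per episode (default 150).
#' @param drift_sd payoff drift sd in points per trial (default 2.8).
#' @param bounds reward bounds (default [1, 98]).
#' @param miss_probability per-trial miss probability (default 0.01).
#' @param n_structures number of payoff structures (default 3).
#' @param K context length (default 4).
#' @param n_folds participant-wise cross-validation folds (default 5).
#' @param epochs,batch_size,hidden_units recurrent training settings.
#' @param q_n_starts random starts for the Q-learning fit.
#' @param variants_per_cell probes per category cell.
#' @param exclude_gaps_at_test drop gap-spanning windows from evaluation
#'   (default FALSE; gapped windows are kept but flagged).
#' @param seed global integer seed.
#' @return list of class \code{bandit_config}.
#' @export
bandit_config <- function(n_participants = 300,
                          mixture = c(q_learning = 0.4, pattern = 0.3,
                                      hybrid = 0.2, random = 0.1),
                          n_trials = 150, drift_sd = 2.8, bounds = c(1, 98),
                          miss_probability = 0.01, n_structures = 3,
                          K = 4, n_folds = 5,
                          epochs = 50, batch_size = 512, hidden_units = 64,
                          q_n_starts = 5, variants_per_cell = 8,
                          exclude_gaps_at_test = FALSE, seed = 1) {
  structure(list(n_participants = n_participants, mixture = mixture,
                 n_trials = n_trials, drift_sd = drift_sd, bounds = bounds,
                 miss_probability = miss_probability,
                 n_structures = n_structures, K = K, n_folds = n_folds,
                 epochs = epochs, batch_size = batch_size,
                 hidden_units = hidden_units, q_n_starts = q_n_starts,
                 variants_per_cell = variants_per_cell,
                 exclude_gaps_at_test = exclude_gaps_at_test,
                 seed = as.integer(seed)),
            class = "bandit_config")
}

#' @rdname bandit_config
#' @param config a \code{bandit_config}.
#' @param path JSON path.
#' @export
write_bandit_config <- function(config, path) {
  obj <- unclass(config)
  obj$mixture <- as.list(obj$mixture)   # keep kind names in the JSON object
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname bandit_config
#' @export
read_bandit_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$mixture <- unlist(obj$mixture)
  obj$bounds <- as.numeric(obj$bounds)
  obj$seed <- as.integer(obj$seed)
  do.call(bandit_config, obj)
}

# Named seed substreams derived from the global seed (kept below 2^31).
.substream <- function(seed, name) {
  offs <- c(population = 11L, folds = 23L, weights = 37L, probes = 53L,
            payoffs = 71L, shuffle = 89L)
  (as.integer(seed) * 1000L + offs[[name]]) %% 2147483647L
}

#' Run the full synthetic study
#'
#' End-to-end pipeline: generate the synthetic population, extract sliding
#' windows per training fold and non-overlapping windows for evaluation,
#' train the exploratory (actions + rewards) and reward-oblivious
#' (actions only) recurrent models with participant-wise cross-validation
#' (each participant is predicted exactly once, by the fold that held it
#' out), fit the group-level Q-learning model on the population, align the
#' three models' predictions, compute accuracy tables and the trial-wise
#' similarity series, run the probe simulations, and label each probe cell
#' by which explicit model the black box tracks.
#'
#' @param config a \code{\link{bandit_config}}.
#' @param output_dir optional directory; when given, all tables are written
#'   as CSV/JSON and declared in a manifest with content hashes.
#' @param verbose print per-stage progress (default TRUE).
#' @return list of class \code{bandit_study}: population, folds, q_fit,
#'   fold_models (per-fold policy_net pair), predictions (aligned),
#'   accuracy, accuracy_time, similarity (pairwise list), probes,
#'   probe_predictions, distances, convergence, summary.
#' @export
run_bandit_study <- function(config = bandit_config(), output_dir = NULL,
                             verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stopifnot(inherits(config, "bandit_config"))

  say("[1/6] generating population (n=%d)", config$n_participants)
  payoffs <- lapply(seq_len(config$n_structures), function(i)
    generate_payoff_structure(config$n_trials, config$drift_sd,
                              config$bounds,
                              seed = .substream(config$seed, "payoffs") + i,
                              structure_id = i))
  pop <- generate_population(
    config$n_participants, config$mixture, payoffs,
    episode_config(config$n_trials, config$miss_probability),
    seed = .substream(config$seed, "population"))

  say("[2/6] building folds and datasets (K=%d, %d folds)",
      config$K, config$n_folds)
  folds <- split_by_participant(pop, k = config$n_folds,
                                seed = .substream(config$seed, "folds"))
  ids <- vapply(pop, function(r) r$participant_id, character(1))
  max_gap <- if (config$exclude_gaps_at_test) 0 else Inf

  say("[3/6] training recurrent models per fold (%d epochs)", config$epochs)
  fold_models <- vector("list", length(folds))
  pred_exp <- list()
  pred_ro <- list()
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    train_rec <- pop[ids %in% fold$train_participants]
    test_rec <- pop[ids %in% fold$test_participants]
    train_s <- shuffle_samples(
      build_dataset(train_rec, K = config$K, mode = "sliding"),
      seed = .substream(config$seed, "shuffle") + f)
    test_s <- build_dataset(test_rec, K = config$K,
                            mode = "non_overlapping", max_gap = max_gap)
    wseed <- .substream(config$seed, "weights") + f
    m_exp <- policy_net(train_s, "action_reward",
                        hidden_units = config$hidden_units,
                        epochs = config$epochs,
                        batch_size = config$batch_size, seed = wseed)
    m_ro <- policy_net(train_s, "action_only",
                       hidden_units = config$hidden_units,
                       epochs = config$epochs,
                       batch_size = config$batch_size, seed = wseed + 1L)
    fold_models[[f]] <- list(exploratory = m_exp, reward_oblivious = m_ro)
    pred_exp[[f]] <- evaluate_policy(m_exp, test_s)$predictions
    pred_ro[[f]] <- evaluate_policy(m_ro, test_s)$predictions
    say("    fold %d/%d done", f, length(folds))
  }
  pred_exp <- do.call(rbind, pred_exp)
  pred_ro <- do.call(rbind, pred_ro)

  say("[4/6] fitting group-level Q-learning model")
  q_fit <- qlearn(pop, n_starts = config$q_n_starts, seed = config$seed)
  pred_q <- qlearn_score(q_fit, pop)$predictions

  preds <- align_predictions(list(exploratory = pred_exp,
                                  reward_oblivious = pred_ro,
                                  q_model = pred_q[, names(pred_q) != "first_trial"]))
  accuracy <- accuracy_by_participant(preds)
  accuracy_time <- accuracy_by_time(preds, payoffs[[1]])
  similarity <- list(
    exploratory_vs_q = similarity_over_time(preds$exploratory, preds$q_model),
    exploratory_vs_ro = similarity_over_time(preds$exploratory,
                                             preds$reward_oblivious),
    ro_vs_q = similarity_over_time(preds$reward_oblivious, preds$q_model))

  say("[5/6] probe simulations (%d variants per cell)",
      config$variants_per_cell)
  probes <- enumerate_probes(config$variants_per_cell,
                             seed = .substream(config$seed, "probes"))
  probe_models <- list(exploratory = fold_models[[1]]$exploratory,
                       reward_oblivious = fold_models[[1]]$reward_oblivious,
                       q_model = q_fit)
  probe_pred <- collect_predictions(probes, probe_models)
  dists <- distance_matrix(probe_pred)
  convergence <- classify_convergence(dists$cells)

  say("[6/6] assembling summary")
  summary_tbl <- list(
    pooled_accuracy = as.list(accuracy$pooled),
    q_params = list(alpha = q_fit$alpha, beta = q_fit$beta,
                    nll = q_fit$nll),
    n_predictions = nrow(preds$exploratory),
    convergence = stats::setNames(
      as.list(convergence$label),
      paste(convergence$action_category, convergence$reward_category,
            sep = ".")),
    seed = config$seed)

  study <- structure(list(config = config, population = pop, folds = folds,
                          q_fit = q_fit, fold_models = fold_models,
                          predictions = preds, accuracy = accuracy,
                          accuracy_time = accuracy_time,
                          similarity = similarity, probes = probes,
                          probe_predictions = probe_pred,
                          distances = dists, convergence = convergence,
                          summary = summary_tbl),
                     class = "bandit_study")
  if (!is.null(output_dir)) .write_study(study, output_dir)
  study
}

.write_study <- function(study, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(output_dir, x)
  write_bandit_config(study$config, fp("config.json"))
  write_population(study$population, fp("population.csv"))
  jsonlite::write_json(study$folds, fp("folds.json"), auto_unbox = TRUE)
  utils::write.csv(study$accuracy$table, fp("accuracy_by_participant.csv"),
                   row.names = FALSE)
  utils::write.csv(study$accuracy_time, fp("accuracy_by_trial.csv"),
                   row.names = FALSE)
  for (nm in names(study$similarity)) {
    utils::write.csv(study$similarity[[nm]],
                     fp(sprintf("similarity_%s.csv", nm)), row.names = FALSE)
  }
  utils::write.csv(study$probes, fp("probes.csv"), row.names = FALSE)
  utils::write.csv(study$probe_predictions, fp("probe_predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(study$distances$cells, fp("distance_cells.csv"),
                   row.names = FALSE)
  utils::write.csv(study$convergence, fp("convergence.csv"),
                   row.names = FALSE)
  write_policy_net(study$fold_models[[1]]$exploratory,
                   fp("model_exploratory_fold1.json"))
  write_policy_net(study$fold_models[[1]]$reward_oblivious,
                   fp("model_reward_oblivious_fold1.json"))
  jsonlite::write_json(study$summary, fp("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  files <- setdiff(list.files(output_dir), "manifest.json")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(output_dir,
                                                              files))),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE)
  invisible(output_dir)
}

#' @export
print.bandit_study <- function(x, ...) {
  cat("Synthetic restless-bandit study\n")
  cat(sprintf("  population: %d participants, %d trials, mixture [%s]\n",
              x$config$n_participants, x$config$n_trials,
              paste(sprintf("%s=%.2f", names(x$config$mixture),
                            x$config$mixture), collapse = ", ")))
  acc <- x$summary$pooled_accuracy
  cat(sprintf("  held-out accuracy: exploratory %.3f | reward-oblivious %.3f | q-model %.3f\n",
              acc$exploratory, acc$reward_oblivious, acc$q_model))
  cat(sprintf("  fitted q-model: alpha=%.3f beta=%.3f\n",
              x$q_fit$alpha, x$q_fit$beta))
  cat("  probe-cell convergence labels:\n")
  for (i in seq_len(nrow(x$convergence))) {
    cat(sprintf("    %-13s x %-10s -> %s\n",
                x$convergence$action_category[i],
                x$convergence$reward_category[i], x$convergence$label[i]))
  }
  invisible(x)
}
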