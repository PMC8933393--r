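test_that("the delta rule moves only the chosen value", {
  expect_equal(q_update(rep(50, 4), 1, 40, 0.5), c(45, 50, 50, 50))
  expect_equal(q_update(rep(50, 4), 2, 90, 0), rep(50, 4))
  expect_equal(q_update(rep(50, 4), 3, 77, 1), c(50, 50, 77, 50))
  expect_error(q_update(rep(50, 4), 1, 40, 1.2), "alpha")
  expect_error(q_update(rep(50, 4), 5, 40, 0.5), "action")
})

test_that("softmax probabilities follow the inverse-temperature rule", {
  expect_equal(action_probs(rep(50, 4), 0.2), rep(0.25, 4))
  p <- action_probs(c(60, 50, 50, 50), 0.1)
  expect_equal(p[1], exp(1) / (exp(1) + 3), tolerance = 1e-10)
  expect_equal(p[2], 1 / (exp(1) + 3), tolerance = 1e-10)
  expect_equal(sum(p), 1)
  # greedy limit, stable under large beta thanks to max-subtraction
  expect_gt(action_probs(c(60, 50, 50, 50), 50)[1], 0.999999)
  expect_error(action_probs(c(Inf, 0, 0, 0), 0.1), "finite")
  expect_error(action_probs(rep(50, 4), 0), "beta")
})

test_that("the trace reproduces the equal-reward all-different anchor", {
  rec <- make_record(1:4, rep(40, 4))
  for (pars in list(c(0.1, 0.05), c(0.5, 0.3), c(0.9, 1))) {
    tr <- q_trace(rec, pars[1], pars[2])
    # after 1-2-3-4 at equal rewards, all values equal 50 - 10*alpha
    expect_equal(tr$final_q, rep(50 - 10 * pars[1], 4))
    expect_equal(action_probs(tr$final_q, pars[2]), rep(0.25, 4))
  }
  expect_equal(q_trace(rec, 0.3, 0.15)$Q[1, ], rep(50, 4))
})

test_that("missed trials freeze the values", {
  rec <- make_record(rep(NA_integer_, 5), rep(NA_real_, 5), rep(TRUE, 5))
  tr <- q_trace(rec, 0.5, 0.2)
  expect_true(all(tr$Q == 50))
})

test_that("repeated choices follow the geometric recursion", {
  rec <- make_record(rep(1L, 4), rep(40, 4))
  tr <- q_trace(rec, 0.5, 0.2)
  expect_equal(tr$final_q[1], 50 * 0.5^4 + 40 * (1 - 0.5^4))  # 40.625
  expect_equal(tr$final_q[2:4], rep(50, 3))
})

test_that("the trace is order-sensitive", {
  r1 <- make_record(c(1L, 1L, 2L), c(90, 10, 50))
  r2 <- make_record(c(1L, 1L, 2L), c(10, 90, 50))
  expect_false(isTRUE(all.equal(q_trace(r1, 0.4, 0.1)$final_q,
                                q_trace(r2, 0.4, 0.1)$final_q)))
})

test_that("the group likelihood reduces to N log 4 at the noise limit", {
  rec <- make_record(c(1L, 3L, 2L, 4L, 1L), runif(5, 1, 98))
  expect_equal(qlearn_nll(list(rec), 0.3, 1e-9), 5 * log(4),
               tolerance = 1e-6)
  recs <- generate_population(10, c(q_learning = 1), seed = 40,
                              config = episode_config(50, 0.02))
  n_obs <- sum(vapply(recs, function(r) sum(!r$missed), integer(1)))
  expect_equal(qlearn_nll(recs, 0.5, 1e-9), n_obs * log(4),
               tolerance = 1e-6)
})

test_that("the vectorised likelihood matches a per-record trace", {
  recs <- generate_population(5, c(q_learning = 1), seed = 41,
                              config = episode_config(40, 0.05))
  by_trace <- sum(vapply(recs, function(r) {
    tr <- q_trace(r, 0.35, 0.12)
    use <- !r$missed
    -sum(log(tr$probs[cbind(which(use), r$actions[use])]))
  }, numeric(1)))
  expect_equal(qlearn_nll(recs, 0.35, 0.12), by_trace, tolerance = 1e-10)
})

test_that("the likelihood peaks near the generating parameters", {
  recs <- generate_population(40, c(q_learning = 1), seed = 42,
                              config = episode_config(150, 0),
                              param_ranges = list(alpha = c(0.3, 0.3),
                                                  beta = c(0.15, 0.15),
                                                  value_gap_threshold = c(5, 20)))
  at_truth <- qlearn_nll(recs, 0.3, 0.15)
  expect_lt(at_truth, qlearn_nll(recs, 0.3, 0.30))
  expect_lt(at_truth, qlearn_nll(recs, 0.3, 0.075))
  expect_lt(at_truth, qlearn_nll(recs, 0.8, 0.15))
})

test_that("fitting uniform-random choices drives beta to the noise bound", {
  pays <- default_payoff_structures()
  recs <- lapply(1:40, function(i)
    run_episode(make_agent(list(kind = "random")), pays[[1]],
                episode_config(100, 0), sprintf("R%03d", i), seed = 600 + i))
  fit <- qlearn(recs, n_starts = 3, seed = 43)
  expect_lte(fit$beta, 0.01)
  expect_gte(fit$alpha, 0)
  expect_lte(fit$alpha, 1)
  expect_lte(fit$beta, fit$bounds$beta[2])
})

test_that("argmax scoring breaks ties low, flags trial 1, skips misses", {
  rec <- make_record(c(2L, 2L, NA, 2L), c(80, 80, NA, 80),
                     missed = c(FALSE, FALSE, TRUE, FALSE))
  sc <- qlearn_score(q_star, list(rec))
  expect_equal(sc$predictions$prediction[1], 1L)   # all-50 tie -> lowest
  expect_true(sc$predictions$first_trial[1])
  expect_false(3 %in% sc$predictions$target_trial)
  expect_equal(sc$predictions$prediction[sc$predictions$target_trial == 2],
               2L)
  # accuracy over non-missed trials only
  expect_equal(nrow(sc$predictions), 3)
})

test_that("a greedy agent on a dominant arm is predicted almost perfectly", {
  pay <- generate_payoff_structure(150, drift_sd = 0, seed = 50)
  pay$rewards[, 2] <- 95
  pay$rewards[, c(1, 3, 4)] <- 10
  spec <- list(kind = "q_learning", alpha = 0.5, beta = 5)
  rec <- run_episode(make_agent(spec), pay, episode_config(150, 0),
                     seed = 51)
  sc <- qlearn_score(q_star, list(rec))
  late <- sc$predictions[sc$predictions$target_trial > 20, ]
  expect_gt(mean(late$correct), 0.95)
})

test_that("reward-blind cycling defeats the reward-oriented model", {
  recs <- cycle_population()
  sc <- qlearn_score(q_star, recs)
  expect_lt(sc$accuracy, 0.45)   # near chance; far below pattern models
})

test_that("pre-choice values stay inside the convex hull of init and rewards", {
  recs <- generate_population(10, c(q_learning = 1), seed = 44,
                              config = episode_config(80, 0))
  for (r in recs[1:3]) {
    tr <- q_trace(r, 0.6, 0.1)
    expect_true(all(tr$Q >= min(50, 1) & tr$Q <= max(50, 98)))
    expect_true(all(abs(rowSums(tr$probs) - 1) < 1e-9))
  }
})

test_that("recovery error shrinks with more data", {
  gen <- function(n, t, seed) {
    generate_population(n, c(q_learning = 1), seed = seed,
                        config = episode_config(t, 0),
                        param_ranges = list(alpha = c(0.3, 0.3),
                                            beta = c(0.15, 0.15),
                                            value_gap_threshold = c(5, 20)))
  }
  f_small <- qlearn(gen(8, 40, 60), n_starts = 2, seed = 61)
  f_large <- qlearn(gen(80, 150, 62), n_starts = 2, seed = 63)
  err <- function(f) abs(f$alpha - 0.3) / 0.3 + abs(f$beta - 0.15) / 0.15
  expect_lt(err(f_large), err(f_small))
  expect_lt(err(f_large), 0.15)
})
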