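test_that("a symmetric value vector yields uniform choice frequencies", {
  set.seed(1)
  draws <- replicate(10000,
    q_agent_step(rep(50, 4), alpha = 0.3, beta = 0.2)$action)
  tab <- tabulate(draws, 4)
  expect_gt(stats::chisq.test(tab)$p.value, 1e-4)
})

test_that("the q step applies the delta rule before sampling", {
  set.seed(2)
  st <- q_agent_step(c(50, 50, 50, 50), alpha = 0.5, beta = 0.1,
                     last_outcome = list(action = 1, reward = 40))
  expect_equal(st$q_values, c(45, 50, 50, 50))
  expect_error(q_agent_step(rep(50, 4), 0.3, beta = 0), "beta")
})

test_that("choice frequencies follow the softmax of the values", {
  # q=(60,50,50,50), beta=0.1 -> p1 = e/(e+3) = 0.4754
  set.seed(3)
  draws <- replicate(20000,
    q_agent_step(c(60, 50, 50, 50), alpha = 0.3, beta = 0.1)$action)
  expect_equal(mean(draws == 1), exp(1) / (exp(1) + 3), tolerance = 0.03)
  expect_equal(mean(draws == 2), 1 / (exp(1) + 3), tolerance = 0.10)
})

test_that("pattern agents are deterministic completions of their history", {
  expect_equal(pattern_agent_step(c(1, 2, 3, 4), "cycle", 1L), 1L)
  expect_equal(pattern_agent_step(c(2, 3, 4), "cycle", 2L), 1L)
  expect_equal(pattern_agent_step(integer(0), "cycle", 3L), 3L)
  expect_equal(pattern_agent_step(c(1, 4, 2), "constant", 3L), 3L)
  expect_equal(pattern_agent_step(c(4, 2), "alternating", c(2L, 4L)), 4L)
  expect_equal(pattern_agent_step(c(2, 4), "alternating", c(2L, 4L)), 2L)
})

test_that("hybrid agents switch mode on the value gap", {
  set.seed(4)
  # gap 60 >= 20: reward mode, argmax-heavy at beta = 1
  st <- hybrid_agent_step(c(90, 30, 30, 30), c(1, 2, 3, 4), alpha = 0.3,
                          beta = 1, pattern_type = "cycle", options = 1L,
                          value_gap_threshold = 20)
  expect_equal(st$mode, "reward")
  expect_equal(st$action, 1L)
  # gap 0 < 20: pattern mode completes the cycle
  st2 <- hybrid_agent_step(rep(50, 4), c(1, 2, 3, 4), alpha = 0.3,
                           beta = 1, pattern_type = "cycle", options = 1L,
                           value_gap_threshold = 20)
  expect_equal(st2$mode, "pattern")
  expect_equal(st2$action, 1L)
})

test_that("hybrids use their pattern more when option values are close", {
  pays <- default_payoff_structures()
  modes <- list()
  gaps <- list()
  for (i in 1:12) {
    spec <- list(kind = "hybrid", alpha = 0.4, beta = 0.15,
                 pattern_type = "cycle", options = 1L,
                 value_gap_threshold = 10)
    pol <- make_agent(spec)
    run_episode(pol, pays[[(i - 1) %% 3 + 1]], episode_config(150, 0),
                seed = 500 + i)
    st <- attr(pol, "state")
    modes[[i]] <- st$modes
  }
  modes <- unlist(modes)
  expect_setequal(unique(modes), c("reward", "pattern"))
  expect_gt(mean(modes == "pattern"), 0.05)
})

test_that("population generation is reproducible and keeps provenance", {
  a <- generate_population(30, c(q_learning = 1), seed = 10,
                           config = episode_config(60, 0.01))
  expect_length(a, 30)
  expect_true(all(vapply(a, function(r) r$agent$kind, "") == "q_learning"))
  b <- generate_population(30, c(q_learning = 1), seed = 10,
                           config = episode_config(60, 0.01))
  expect_identical(lapply(a, `[[`, "actions"), lapply(b, `[[`, "actions"))
  expect_identical(lapply(a, `[[`, "rewards"), lapply(b, `[[`, "rewards"))
})

test_that("mixture proportions are recovered from provenance tags", {
  pop <- generate_population(300, c(q_learning = 0.5, pattern = 0.3,
                                    hybrid = 0.2), seed = 20,
                            config = episode_config(20, 0))
  kinds <- vapply(pop, function(r) r$agent$kind, "")
  p_hat <- mean(kinds == "pattern")
  expect_lt(abs(p_hat - 0.3), 3 * sqrt(0.3 * 0.7 / 300))
  expect_error(generate_population(10, c(q_learning = 0.5)), "sum to 1")
  expect_error(generate_population(10, c(q_learning = 1), payoffs = list()),
               "non-empty")
})

test_that("a pattern population is fully predictable from its last actions", {
  pop <- pattern_population()
  w <- build_dataset(pop, mode = "sliding")
  # oracle: re-derive the next action from each agent's generative rule
  specs <- lapply(pop, `[[`, "agent")
  names(specs) <- vapply(pop, `[[`, "", "participant_id")
  pred <- vapply(seq_len(nrow(w)), function(i) {
    sp <- specs[[w$participant_id[i]]]
    pattern_agent_step(as.integer(w[i, paste0("a", 1:4)]), sp$pattern_type,
                       sp$options)
  }, integer(1))
  expect_equal(mean(pred == w$target_action), 1)
})

test_that("the default miss process puts about 4% of windows over a gap", {
  pop <- generate_population(150, c(q_learning = 1), seed = 30)
  w <- build_dataset(pop, mode = "sliding")
  expect_equal(mean(w$has_gap), 0.039, tolerance = 0.012 / 0.039)
})
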