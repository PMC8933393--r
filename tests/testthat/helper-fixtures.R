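# Shared fixtures, built once per test run and cached. Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# Deterministic pattern-only population (no misses): every next action is a
# pure function of the last actions.
pattern_population <- function() {
  fixture("pattern_pop", function() {
    generate_population(60, c(pattern = 1), seed = 3,
                        config = episode_config(150, 0))
  })
}

# Pure cycle agents over all four starting phases.
cycle_population <- function() {
  fixture("cycle_pop", function() {
    pays <- default_payoff_structures()
    lapply(1:24, function(i) {
      spec <- list(kind = "pattern", pattern_type = "cycle",
                   options = (i - 1L) %% 4L + 1L)
      rec <- run_episode(make_agent(spec), pays[[(i - 1) %% 3 + 1]],
                         episode_config(150, 0), sprintf("C%03d", i),
                         seed = 100 + i)
      rec$agent <- spec
      rec
    })
  })
}

# A small reward-oblivious net trained on the pattern population; reused by
# the recurrent, comparison and probe tests.
pattern_ro_net <- function() {
  fixture("pattern_ro_net", function() {
    w <- build_dataset(pattern_population(), mode = "sliding")
    policy_net(shuffle_samples(w, seed = 4)[1:4000, ], "action_only",
               epochs = 40, batch_size = 256, seed = 5)
  })
}

# Hand-built record: explicit actions/rewards/missed.
make_record <- function(actions, rewards, missed = rep(FALSE, length(actions)),
                        id = "X001", structure_id = 1L) {
  actions[missed] <- NA_integer_
  rewards[missed] <- NA_real_
  banditlens:::new_behavioural_record(id, structure_id, actions, rewards,
                                      missed)
}

q_star <- list(alpha = 0.3, beta = 0.15)
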