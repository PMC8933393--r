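test_that("one variant per cell yields the nine canonical cells", {
  pr <- enumerate_probes(1, seed = 1)
  expect_equal(nrow(pr), 9)
  expect_equal(nrow(unique(pr[, c("action_category", "reward_category")])), 9)
})

test_that("probe templates satisfy their category invariants", {
  pr <- enumerate_probes(8, seed = 2)
  A <- as.matrix(pr[, paste0("a", 1:4)])
  R <- as.matrix(pr[, paste0("r", 1:4)])
  expect_true(all(R >= 1 & R <= 98))
  cst <- pr$action_category == "constant"
  expect_true(all(A[cst, 1] == A[cst, 2] & A[cst, 2] == A[cst, 3] &
                    A[cst, 3] == A[cst, 4]))
  alt <- pr$action_category == "alternating"
  expect_true(all(A[alt, 1] == A[alt, 3] & A[alt, 2] == A[alt, 4] &
                    A[alt, 1] != A[alt, 2]))
  ad <- pr$action_category == "all_different"
  expect_true(all(apply(A[ad, , drop = FALSE], 1,
                        function(z) length(unique(z)) == 4)))
  asc <- pr$reward_category == "ascending"
  expect_true(all(apply(R[asc, , drop = FALSE], 1,
                        function(z) all(diff(z) > 0))))
  dsc <- pr$reward_category == "descending"
  expect_true(all(apply(R[dsc, , drop = FALSE], 1,
                        function(z) all(diff(z) < 0))))
  # constant rewards include both low (<50) and high (>50) levels
  lev <- R[pr$reward_category == "constant", 1]
  expect_true(any(lev < 50) && any(lev > 50))
  expect_error(enumerate_probes(1, reward_levels = list(
    constant = 40, ascending = list(c(10, 10, 20, 30)))), "increase")
})

test_that("symmetric KL is a proper symmetric premetric with the known value", {
  u <- rep(0.25, 4)
  p <- c(0.7, 0.1, 0.1, 0.1)
  expect_equal(sym_kl(u, u), 0)
  expect_equal(sym_kl(p, u), 0.4378, tolerance = 2e-4)
  set.seed(3)
  for (i in 1:25) {
    a <- rgamma(4, 1)
    a <- a / sum(a)
    b <- rgamma(4, 1)
    b <- b / sum(b)
    expect_gte(sym_kl(a, b), 0)
    expect_equal(sym_kl(a, b), sym_kl(b, a), tolerance = 1e-12)
  }
  expect_error(sym_kl(c(-0.1, 0.5, 0.3, 0.3), u), "non-negative")
  expect_error(sym_kl(c(0.5, 0.5, 0.5, 0.5), u), "sum to 1")
})

test_that("the reward-oriented probe anchors hold over the search box", {
  for (alpha in c(0.05, 0.3, 0.6, 0.95)) {
    for (beta in c(0.01, 0.15, 0.5, 1)) {
      ps <- list(alpha = alpha, beta = beta)
      expect_equal(simulate_probe(1:4, rep(40, 4), ps), rep(0.25, 4))
      expect_equal(which.max(simulate_probe(1:4, c(20, 30, 70, 80), ps)), 4L)
      expect_equal(which.max(simulate_probe(1:4, c(80, 60, 40, 20), ps)), 1L)
    }
  }
})

test_that("probe collection keeps the reward-oblivious model reward-blind", {
  m <- pattern_ro_net()
  pr <- enumerate_probes(2, seed = 4)
  got <- collect_predictions(pr, list(reward_oblivious = m,
                                      q_model = structure(q_star,
                                                          class = "qlearn")))
  expect_true(all(abs(rowSums(as.matrix(got[, paste0("p", 1:4)])) - 1) < 1e-6))
  # same action pattern under different reward categories -> same output
  ro <- got[got$model == "reward_oblivious", ]
  key <- apply(pr[match(ro$probe_id, pr$probe_id), paste0("a", 1:4)], 1,
               paste, collapse = "-")
  for (k in unique(key)) {
    block <- as.matrix(ro[key == k, paste0("p", 1:4)])
    expect_true(all(abs(sweep(block, 2, block[1, ])) < 1e-12))
  }
})

test_that("distances aggregate by cell mean with a zero diagonal", {
  m <- pattern_ro_net()
  pr <- enumerate_probes(2, seed = 5)
  got <- collect_predictions(pr, list(a = m, b = m))
  d <- distance_matrix(got)
  expect_true(all(d$cells$mean_distance < 1e-12))
  expect_true(all(d$per_probe$distance >= 0))
  # cell mean equals the arithmetic mean of its per-probe distances
  got2 <- collect_predictions(pr, list(
    ro = m, q = structure(q_star, class = "qlearn")))
  d2 <- distance_matrix(got2)
  for (i in seq_len(nrow(d2$cells))) {
    cell <- d2$cells[i, ]
    rows <- d2$per_probe[
      d2$per_probe$action_category == cell$action_category &
        d2$per_probe$reward_category == cell$reward_category, ]
    expect_equal(cell$mean_distance, mean(rows$distance), tolerance = 1e-12)
    expect_equal(cell$n_probes, nrow(rows))
  }
})

test_that("equal rewards on all-different actions leave the q-probe uniform", {
  for (alpha in c(0.1, 0.5, 0.9)) {
    p <- simulate_probe(c(2, 3, 4, 1), rep(63, 4),
                        list(alpha = alpha, beta = 0.2))
    expect_equal(p, rep(0.25, 4))
  }
})

test_that("convergence labels follow the nearest-explicit-model rule", {
  cells <- data.frame(
    model_a = c("exploratory", "exploratory", "reward_oblivious"),
    model_b = c("reward_oblivious", "q_model", "q_model"),
    action_category = "constant", reward_category = "constant",
    mean_distance = c(0.05, 0.90, 0.85), n_probes = 4,
    stringsAsFactors = FALSE)
  expect_equal(classify_convergence(cells)$label, "reward_oblivious")
  cells$mean_distance <- c(0.02, 0.03, 0.01)
  expect_equal(classify_convergence(cells)$label, "both")
  cells$mean_distance <- c(2.0, 3.0, 1.5)
  expect_equal(classify_convergence(cells)$label, "neither")
  cells$mean_distance <- c(0.9, 0.1, 0.8)
  expect_equal(classify_convergence(cells)$label, "reward_oriented")
})
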