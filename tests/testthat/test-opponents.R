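test_that("scripted policies return legal moves and respect forced moves", {
  st <- make_state(1, 3, coins = 1, participant = c(0, 0), ai = c(2, 0),
                   fpp = 1)
  expect_equal(nrow(legal_moves(st)), 1)
  for (spec in list(opponent_spec("random"), opponent_spec("greedy"),
                    opponent_spec("mcts_standard", budget = 20))) {
    mv <- policy_move(st, spec, seed = 3)
    expect_equal(mv$to, c(1, 0))
  }
  expect_error(policy_move(fixture_terminal(), opponent_spec("random")),
               "terminal")
})

test_that("the random policy is reproducible and uniform over legal moves", {
  # a figure with exactly three destinations on a 1x4 strip
  st <- make_state(1, 4, coins = 1, participant = c(0, 0), fpp = 1)
  expect_equal(nrow(legal_moves(st)), 3)
  m1 <- random_policy(st, seed = 99)
  expect_identical(m1, random_policy(st, seed = 99))

  draws <- vapply(1:10000, function(i) random_policy(st, seed = i)$to[1],
                  numeric(1))
  counts <- table(factor(draws, levels = 1:3))
  p <- stats::chisq.test(counts, p = rep(1 / 3, 3))$p.value
  expect_gt(p, 0.01)
})

test_that("the greedy policy maximizes destination coins, ties uniform", {
  st <- make_state(1, 4, coins = c(1, 1, 2, 3), participant = c(0, 0),
                   fpp = 1)
  for (i in 1:10) expect_equal(greedy_policy(st, seed = i)$to, c(3, 0))

  tie <- make_state(1, 4, coins = 1, participant = c(0, 0), fpp = 1)
  picks <- vapply(1:50, function(i) greedy_policy(tie, seed = i)$to[1],
                  numeric(1))
  expect_setequal(unique(picks), 1:3)
})

test_that("greedy beats random head-to-head on the standard board", {
  n <- 200
  w <- 0
  for (i in seq_len(n)) {
    st <- standard_game(5000 + i)
    r <- play_policy_match(st, opponent_spec("greedy"),
                           opponent_spec("random"), seed = 6000 + i)
    w <- w + (r$result == "player_win")
  }
  expect_gte(w / n, 0.6)
})

test_that("win rate vs random is non-decreasing along the skill ladder", {
  n <- 200
  ladder <- list(opponent_spec("random"),
                 opponent_spec("greedy"),
                 opponent_spec("mcts_standard", budget = 100),
                 opponent_spec("mcts_standard", budget = 1000))
  wins <- vapply(ladder, function(spec) {
    w <- 0
    for (i in seq_len(n)) {
      st <- standard_game(7000 + i)
      r <- play_policy_match(st, spec, opponent_spec("random"),
                             seed = 8000 + i)
      w <- w + (r$result == "player_win")
    }
    w
  }, numeric(1))
  expect_true(all(diff(wins) >= 0))
})

test_that("opponent pools sample reproducibly", {
  pool <- list(opponent_spec("random"), opponent_spec("greedy"),
               opponent_spec("mcts_standard", budget = 50))
  a <- sample_opponents(pool, 10, seed = 4)
  b <- sample_opponents(pool, 10, seed = 4)
  expect_identical(a, b)
  one <- sample_opponents(opponent_spec("greedy"), 5, seed = 1)
  expect_true(all(vapply(one, function(o) o$label, character(1)) == "greedy"))
  expect_error(opponent_spec("mcts_standard", budget = 0), "budget")
})
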