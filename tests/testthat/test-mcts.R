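test_that("urgency follows the UCB1 rule with exploration-first", {
  unvisited <- search_node(visits = 0)
  parent <- search_node(visits = 100, player_to_move = "ai")
  expect_identical(urgency(unvisited, parent), Inf)

  child <- search_node(visits = 10, total_reward = c(participant = 1, ai = 5))
  expect_equal(urgency(child, parent, c = sqrt(2)),
               0.5 + sqrt(2 * log(100) / 10))
  # hand value of the same expression
  expect_equal(round(urgency(child, parent, c = sqrt(2)), 4), 1.4597)

  # c = 0 ranks children purely by mean reward
  children <- list(
    search_node(4, c(participant = 0, ai = 1)),
    search_node(50, c(participant = 0, ai = 40)),
    search_node(10, c(participant = 0, ai = 3)))
  u0 <- vapply(children, urgency, numeric(1), parent = parent, c = 0)
  means <- vapply(children, function(ch) ch$total_reward[["ai"]] / ch$visits,
                  numeric(1))
  expect_equal(order(u0), order(means))
})

test_that("search finds the unique immediately winning move (minimax-verified)", {
  st <- fixture_forced_win_3x3()
  # oracle: enumerate all moves, value each exactly; exactly one wins
  moves <- legal_moves(st)
  vals <- vapply(seq_len(nrow(moves)), function(i) {
    oracle_minimax(apply_move(st, moves[i, ]), searcher = 0L)
  }, numeric(1))
  expect_equal(sum(vals == 1), 1L)
  best <- moves[which.max(vals), ]

  res <- mcts_search(st, search_config(iterations = 500, seed = 11),
                     reward_spec("standard"))
  expect_equal(res$move$to, c(best$to_col, best$to_row))
  expect_equal(res$move$from, c(best$from_col, best$from_row))
})

test_that("the compiled minimax agrees with the rules-level oracle", {
  states <- list(
    fixture_forced_win_3x3(),
    fixture_stranding(),
    make_state(3, 3, coins = c(2, 1, 3, 1, 1, 1, 1, 2, 1), lava = c(4),
               participant = c(0, 0), ai = c(2, 2), fpp = 1))
  for (st in states) {
    for (searcher in 0:1) {
      expect_equal(minimax_value(st, searcher)$value,
                   oracle_minimax(st, searcher))
    }
  }
})

test_that("a forced move is returned regardless of budget", {
  # participant figure with exactly one destination
  st <- make_state(1, 3, coins = 1, participant = c(0, 0), ai = c(2, 0),
                   fpp = 1)
  expect_equal(nrow(legal_moves(st)), 1)
  res <- mcts_search(st, search_config(iterations = 5, seed = 1),
                     reward_spec("standard"))
  expect_equal(res$move$to, c(1, 0))
})

test_that("search is deterministic given state, config and seed", {
  st <- standard_game(3)
  a <- mcts_search(st, search_config(iterations = 300, seed = 42),
                   condition_spec("balanced"), return_children = TRUE)
  b <- mcts_search(st, search_config(iterations = 300, seed = 42),
                   condition_spec("balanced"), return_children = TRUE)
  expect_identical(a$move, b$move)
  expect_identical(a$children, b$children)
  c <- mcts_search(st, search_config(iterations = 300, seed = 43),
                   condition_spec("balanced"), return_children = TRUE)
  expect_false(identical(a$children, c$children))
})

test_that("visit bookkeeping and reward bounds hold over the tree", {
  st <- tutorial_game(2)
  k <- 400
  res <- mcts_search(st, search_config(iterations = k, seed = 7),
                     condition_spec("tutorial"),
                     return_children = TRUE, return_tree = TRUE)
  expect_equal(res$root_visits, k)
  expect_equal(sum(res$children$visits), k)
  expect_true(all(res$children$mean_searcher >= 0 &
                  res$children$mean_searcher <= 1))
  tr <- res$tree
  expect_lte(nrow(tr), k + 1)
  # per-node: accumulated rewards bounded by visits, and each non-root
  # node's visits no greater than its parent's
  expect_true(all(tr$reward_participant >= 0 &
                  tr$reward_participant <= tr$visits))
  expect_true(all(tr$reward_ai >= 0 & tr$reward_ai <= tr$visits))
  nonroot <- tr$parent >= 0
  expect_true(all(tr$visits[nonroot] <= tr$visits[tr$parent[nonroot] + 1]))
})

test_that("expansion stops at terminal children", {
  # the lone figure's only slide ends the game (it strands itself), so the
  # root's single child is terminal and the tree never grows deeper
  st <- make_state(1, 2, coins = 1, participant = c(0, 0), fpp = 1)
  expect_equal(nrow(legal_moves(st)), 1)
  res <- mcts_search(st, search_config(iterations = 200, seed = 5),
                     reward_spec("standard"), return_tree = TRUE)
  expect_equal(res$n_nodes, 2L)
  expect_equal(res$root_visits, 200)
})

test_that("search rejects terminal states", {
  expect_error(mcts_search(fixture_terminal(), search_config(iterations = 10)),
               "terminal")
})

test_that("more search makes a strictly stronger standard player", {
  n <- 200
  wins <- function(budget) {
    w <- 0
    for (i in seq_len(n)) {
      st <- standard_game(3000 + i)
      r <- play_match(st, reward_spec("standard"), opponent_spec("random"),
                      search_config(iterations = budget), seed = 4000 + i)
      w <- w + (r$result == "player_loss")  # AI won
    }
    w
  }
  w100 <- wins(100)
  w1000 <- wins(1000)
  expect_gt(w1000, w100)
})
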