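test_that("legal placements are the open unoccupied one-coin tiles", {
  st <- standard_game(42)
  pl <- legal_placements(st)
  expect_equal(nrow(pl), 26)  # standard config has 26 one-coin tiles

  st2 <- apply_move(st, move_place(c(pl$col[1], pl$row[1])))
  expect_equal(nrow(legal_placements(st2)), 25)

  no_ones <- make_state(3, 3, coins = 2, phase = "placement", fpp = 1)
  expect_equal(nrow(legal_placements(no_ones)), 0)
})

test_that("placement/phase preconditions are enforced", {
  st <- make_state(3, 3, coins = 1, participant = c(0, 0), ai = c(2, 2))
  expect_error(legal_placements(st), "placement phase")
  expect_error(apply_move(st, move_place(c(1, 1))), "placement phase")
  fresh <- standard_game(1)
  expect_error(legal_moves(fresh), "movement phase")
})

test_that("slide generation matches the brute-force direction/distance oracle", {
  # lone figure near the centre of an open 4x4 board
  st <- make_state(4, 4, coins = 1, participant = c(1, 1), ai = c(3, 3),
                   fpp = 1)
  got <- legal_moves(st, "participant")
  want <- oracle_slide_destinations(st, 1, 1)
  expect_equal(sorted_coords(got[, c("to_col", "to_row")] |>
                               stats::setNames(c("col", "row"))),
               sorted_coords(want))

  # the AI figure too, and on a board with lava
  st2 <- make_state(5, 5, coins = 1, lava = c(6, 7, 12),
                    participant = c(0, 0), ai = c(3, 2), fpp = 1)
  got2 <- legal_moves(st2, "ai")
  want2 <- oracle_slide_destinations(st2, 3, 2)
  expect_equal(sorted_coords(got2[, c("to_col", "to_row")] |>
                               stats::setNames(c("col", "row"))),
               sorted_coords(want2))
})

test_that("a fully surrounded figure has no moves", {
  # centre of a 3x3 board with all six neighbours lava
  st <- make_state(3, 3, coins = 1, participant = c(1, 1), ai = c(0, 0),
                   fpp = 1)
  nb <- hex_neighbours(1, 1, 3, 3)
  st <- make_state(3, 3, coins = 1, lava = nb$row * 3 + nb$col,
                   participant = c(1, 1), fpp = 1)
  expect_equal(nrow(legal_moves(st, "participant")), 0)
})

test_that("an own figure blocks the line beyond it", {
  # two participant figures in one row: (0,0) and (2,0); slides right from
  # (0,0) stop strictly before the blocker
  st <- make_state(1, 5, coins = 1, participant = rbind(c(0, 0), c(2, 0)),
                   ai = c(4, 0), fpp = 2)
  mv <- legal_moves(st, "participant")
  from0 <- mv[mv$from_col == 0, ]
  expect_equal(sort(from0$to_col), 1)  # only distance 1
})

test_that("slides score destination coins and burn the origin", {
  st <- make_state(1, 4, coins = c(1, 1, 1, 3),
                   participant = c(0, 0), ai = c(1, 0), fpp = 1,
                   to_move = "ai")
  # AI slides (1,0) -> (3,0)? blocked by nothing; destination has 3 coins
  st2 <- apply_move(st, move_slide(c(1, 0), c(3, 0)))
  expect_equal(st2$scores[2] - st$scores[2], 3)
  expect_equal(st2$lava[2], 1L)  # origin tile (1,0) is lava
  expect_equal(st2$scores[1], 0L)
})

test_that("sealing a figure's last exit removes it in the same transition", {
  st <- fixture_stranding()
  st2 <- apply_move(st, move_slide(c(1, 1), c(1, 2)))
  figs <- state_figures(st2)
  expect_equal(figs$status[figs$owner == "ai"], "removed")
  # the stranded figure's tile turned to lava and its coin was forfeited
  expect_equal(st2$lava[2 * 3 + 0 + 1], 1L)
  expect_equal(st2$scores[2], 0L)
})

test_that("illegal moves raise rule-violation errors", {
  st <- make_state(1, 5, coins = 1, participant = c(0, 0), ai = c(2, 0),
                   fpp = 1)
  # sliding through (or onto) the occupied tile
  expect_error(apply_move(st, move_slide(c(0, 0), c(2, 0))), "not reachable")
  expect_error(apply_move(st, move_slide(c(0, 0), c(3, 0))), "not reachable")
  # moving the opponent's figure
  expect_error(apply_move(st, move_slide(c(2, 0), c(3, 0))), "belong")
  term <- fixture_terminal()
  expect_error(apply_move(term, move_slide(c(0, 0), c(1, 0))), "terminal")
})

test_that("players alternate placements, participant first, then movement opens with the participant", {
  st <- standard_game(5)
  expect_equal(st$to_move, 0L)
  for (k in 1:6) {
    expect_equal(st$phase, 0L)
    expect_equal(st$to_move, (k - 1L) %% 2L)
    pl <- legal_placements(st)
    st <- apply_move(st, move_place(c(pl$col[1], pl$row[1])))
    expect_equal(st$scores, c(0L, 0L))  # placements never score
  }
  expect_equal(st$phase, 1L)
  expect_equal(st$to_move, 0L)
  expect_equal(sum(state_figures(st)$status == "alive"), 6)
})

test_that("outcome classifies terminal scores and rejects live games", {
  term <- function(p, a) make_state(3, 3, coins = 1, lava = 0:8,
                                    scores = c(p, a), phase = "terminal")
  expect_equal(game_outcome(term(30, 30))$result, "draw")
  expect_equal(game_outcome(term(45, 30))$result, "player_win")
  expect_equal(game_outcome(term(15, 30))$result, "player_loss")
  expect_error(game_outcome(standard_game(1)), "terminal")
})

test_that("pwm is the participant-minus-AI margin", {
  expect_equal(pwm(45, 30), 15)
  expect_equal(pwm(30, 30), 0)
  expect_equal(pwm(0, 81), -81)
  expect_error(pwm(-1, 3))
})

test_that("random playouts preserve engine invariants", {
  for (i in 1:25) {
    st <- standard_game(100 + i)
    po <- random_playout(st, seed = 200 + i, trace = TRUE)
    expect_true(po$conserved)
    expect_true(all(diff(po$lava_trace) >= 0))
    # every action after the 6 placements is a slide: lava grows every time
    expect_true(all(diff(po$lava_trace)[-(1:6)] >= 1))
    expect_true(all(diff(po$p_trace) >= 0) && all(diff(po$a_trace) >= 0))
    expect_lte(po$moves, 49 + 6)
    expect_lte(abs(po$pwm), 81)
    expect_equal(po$state$phase, 2L)
  }
})

test_that("playouts are reproducible from their seed", {
  st <- standard_game(9)
  a <- random_playout(st, seed = 4)
  b <- random_playout(st, seed = 4)
  expect_identical(unclass(a$state), unclass(b$state))
  expect_identical(a$moves, b$moves)
})
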