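#' Start a new game
#'
#' Creates the initial state of a game of *Explorers vs Owls* on a given
#' board: no figures placed, both scores zero, placement phase, participant
#' (explorers) to move first. The participant also opens the movement
#' phase.
#'
#' @param board An `evo_board` from [generate_board()].
#' @param figures_per_player Figures per player (3 in the standard game,
#'   1 in the tutorial).
#' @return An object of class `evo_state`. Fields (all integer): `rows`,
#'   `cols`, `fpp`, `coins`, `lava`, `scored` (per-tile flags),
#'   `fig_owner` (0 participant / 1 AI), `fig_pos` (tile index, -1
#'   unplaced, -2 removed), `scores` (participant, AI), `phase`
#'   (0 placement / 1 movement / 2 terminal), `to_move` (0/1), `placed`.
#'   The applied-move history is kept in the `history` attribute.
#' @examples
#' st <- new_game(generate_board(4, 4, tutorial_coin_counts(), seed = 7,
#'                               figures_per_player = 1),
#'                figures_per_player = 1)
#' st$phase  # 0: placement
#' @export
new_game <- function(board, figures_per_player = 3L) {
  stopifnot(inherits(board, "evo_board"))
  fpp <- as.integer(figures_per_player)
  if (sum(board$coins == 1L) < 2L * fpp)
    stop("board has too few one-coin tiles for ", 2L * fpp, " placements",
         call. = FALSE)
  n <- board$rows * board$cols
  st <- structure(
    list(rows = board$rows, cols = board$cols, fpp = fpp,
         coins = as.integer(board$coins),
         lava = integer(n), scored = integer(n),
         fig_owner = rep(0:1, each = fpp),
         fig_pos = rep(-1L, 2L * fpp),
         scores = c(0L, 0L), phase = 0L, to_move = 0L,
         placed = c(0L, 0L)),
    class = "evo_state")
  attr(st, "history") <- list()
  st
}

#' Convenience constructors for the two study boards
#'
#' `standard_game()` is the 7x7 board with three figures per player used in
#' the main experiment; `tutorial_game()` the 4x4 board with one figure per
#' player used to teach the rules.
#'
#' @param seed Board shuffle seed.
#' @return An `evo_state` ready for the placement phase.
#' @export
standard_game <- function(seed = 1L) {
  new_game(generate_board(7, 7, standard_coin_counts(), seed = seed), 3L)
}

#' @rdname standard_game
#' @export
tutorial_game <- function(seed = 1L) {
  new_game(generate_board(4, 4, tutorial_coin_counts(), seed = seed,
                          figures_per_player = 1L), 1L)
}

#' Build a game state explicitly (fixtures and tests)
#'
#' Low-level constructor that places coins, lava, figures and scores
#' directly, for constructing mid-game and endgame positions. All
#' coordinates are 0-based `(col, row)` offset coordinates.
#'
#' @param rows,cols Grid dimensions.
#' @param coins Integer vector (length `rows * cols`, row-major) of per-tile
#'   coin values, or a single value recycled.
#' @param lava Tile indices (0-based) or a logical/integer vector of length
#'   `rows * cols` marking lava tiles.
#' @param participant,ai Two-column matrices (or vectors of length 2) of
#'   figure `(col, row)` positions for each player.
#' @param scores Length-2 integer vector (participant, AI).
#' @param phase `"placement"`, `"movement"` or `"terminal"`.
#' @param to_move `"participant"` or `"ai"`.
#' @param fpp Figures per player; defaults to the larger placed count.
#' @return An `evo_state`.
#' @export
make_state <- function(rows, cols, coins = 1L, lava = integer(0),
                       participant = NULL, ai = NULL,
                       scores = c(0L, 0L), phase = "movement",
                       to_move = "participant", fpp = NULL) {
  n <- rows * cols
  coins <- as.integer(rep_len(coins, n))
  lava_vec <- integer(n)
  if (length(lava)) {
    if (length(lava) == n && all(lava %in% c(0L, 1L, TRUE, FALSE))) {
      lava_vec <- as.integer(lava)
    } else {
      lava_vec[as.integer(lava) + 1L] <- 1L
    }
  }
  as_mat <- function(x) {
    if (is.null(x)) return(matrix(integer(0), ncol = 2))
    if (is.matrix(x)) x else matrix(as.integer(x), ncol = 2, byrow = TRUE)
  }
  pm <- as_mat(participant); am <- as_mat(ai)
  if (is.null(fpp)) fpp <- max(nrow(pm), nrow(am), 1L)
  phase_i <- match(match.arg(phase, c("placement", "movement", "terminal")),
                   c("placement", "movement", "terminal")) - 1L
  pos <- rep(if (phase_i == 0L) -1L else -2L, 2L * fpp)
  owner <- rep(0:1, each = fpp)
  placed <- c(if (phase_i == 0L) nrow(pm) else fpp,
              if (phase_i == 0L) nrow(am) else fpp)
  if (nrow(pm)) pos[seq_len(nrow(pm))] <- tile_index(pm[, 1], pm[, 2], cols)
  if (nrow(am)) pos[fpp + seq_len(nrow(am))] <- tile_index(am[, 1], am[, 2], cols)
  st <- structure(
    list(rows = as.integer(rows), cols = as.integer(cols), fpp = as.integer(fpp),
         coins = coins, lava = lava_vec, scored = integer(n),
         fig_owner = owner, fig_pos = as.integer(pos),
         scores = as.integer(scores), phase = phase_i,
         to_move = player_index(to_move), placed = as.integer(placed)),
    class = "evo_state")
  # mark tiles under figures with nonzero running scores as claimed so the
  # coin-conservation accounting stays consistent for hand-built positions
  attr(st, "history") <- list()
  st
}

#' Figures of a state as a tibble
#'
#' @param state An `evo_state`.
#' @return Tibble with columns `figure` (1-based id), `owner`, `col`,
#'   `row` (NA when not on the board) and `status`.
#' @export
state_figures <- function(state) {
  stopifnot(inherits(state, "evo_state"))
  pos <- state$fig_pos
  cc <- tile_coord(pmax(pos, 0L), state$cols)
  tibble::tibble(
    figure = seq_along(pos),
    owner = PLAYERS[state$fig_owner + 1L],
    col = ifelse(pos >= 0, cc[, "col"], NA_integer_),
    row = ifelse(pos >= 0, cc[, "row"], NA_integer_),
    status = dplyr::case_when(pos == -1L ~ "unplaced",
                              pos == -2L ~ "removed",
                              TRUE ~ "alive"))
}

phase_name <- function(state) c("placement", "movement", "terminal")[state$phase + 1L]

#' @export
print.evo_state <- function(x, ...) {
  cat(sprintf("<evo_state %dx%d | %s | to move: %s | score %d-%d>\n",
              x$rows, x$cols, phase_name(x),
              if (x$phase == 2L) "-" else PLAYERS[x$to_move + 1L],
              x$scores[1], x$scores[2]))
  occ <- rep(NA_integer_, x$rows * x$cols)
  alive <- x$fig_pos >= 0
  occ[x$fig_pos[alive] + 1L] <- x$fig_owner[alive]
  for (r in 0:(x$rows - 1)) {
    indent <- if (r %% 2 == 1) " " else ""
    cells <- vapply(0:(x$cols - 1), function(c0) {
      i <- r * x$cols + c0 + 1L
      if (x$lava[i] == 1L) return(" #")
      if (!is.na(occ[i])) return(if (occ[i] == 0L) " E" else " O")
      paste0(" ", x$coins[i])
    }, character(1))
    cat(indent, paste(cells, collapse = ""), "\n", sep = "")
  }
  invisible(x)
}

#' Final score margin and outcome of a terminal state
#'
#' `game_outcome()` reports the two final scores and the result of a
#' finished game; `final_pwm()` is the player win margin of that state.
#'
#' @param state A terminal `evo_state`.
#' @return `game_outcome()`: list with `participant_score`, `ai_score` and
#'   `result` (`"player_win"`, `"draw"` or `"player_loss"`).
#' @examples
#' \donttest{
#' st <- random_playout(tutorial_game(1), seed = 2)$state
#' game_outcome(st)
#' }
#' @export
game_outcome <- function(state) {
  stopifnot(inherits(state, "evo_state"))
  if (state$phase != 2L)
    stop("outcome is only defined for terminal states", call. = FALSE)
  p <- state$scores[1]; a <- state$scores[2]
  list(participant_score = p, ai_score = a,
       result = if (p > a) "player_win" else if (p < a) "player_loss" else "draw")
}

#' Player win margin (PWM)
#'
#' The participant's end-game score minus the AI opponent's score: positive
#' values are player wins, 0 a draw, negative values losses. On the
#' standard board the theoretical range spans 162 points, from -81 to 81.
#'
#' @param participant_score,ai_score Non-negative integer scores
#'   (vectorized).
#' @return Integer margin(s).
#' @examples
#' pwm(45, 30)  # 15: the easy-condition target
#' @export
pwm <- function(participant_score, ai_score) {
  stopifnot(all(participant_score >= 0), all(ai_score >= 0))
  as.integer(participant_score) - as.integer(ai_score)
}

#' @rdname game_outcome
#' @export
final_pwm <- function(state) {
  out <- game_outcome(state)
  pwm(out$participant_score, out$ai_score)
}

# strip to the plain list the C++ layer consumes
state_payload <- function(state) unclass(state)[c(
  "rows", "cols", "fpp", "coins", "lava", "scored", "fig_owner", "fig_pos",
  "scores", "phase", "to_move", "placed")]

state_from_payload <- function(lst, history = list()) {
  st <- structure(lst[c("rows", "cols", "fpp", "coins", "lava", "scored",
                        "fig_owner", "fig_pos", "scores", "phase", "to_move",
                        "placed")],
                  class = "evo_state")
  attr(st, "history") <- history
  st
}
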