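#' MCTS search configuration
#'
#' @param iterations Number of search iterations (complete playouts) per
#'   move decision. 7500 gives a strong opponent on the standard board.
#' @param exploration_constant UCB1 exploration constant `c` of the urgency
#'   function; `sqrt(2)` is the canonical choice.
#' @param seed Integer seed for the search's internal generator.
#' @param final_selection How the root move is chosen after the budget is
#'   spent: highest mean reward (default) or highest visit count. Ties go
#'   to the child with more visits, then seeded random.
#' @return An object of class `evo_search_config`.
#' @export
search_config <- function(iterations = 7500L,
                          exploration_constant = sqrt(2),
                          seed = 1L,
                          final_selection = c("max_mean_reward", "max_visits")) {
  stopifnot(iterations >= 1, exploration_constant >= 0)
  structure(list(iterations = as.integer(iterations),
                 exploration_constant = exploration_constant,
                 seed = as.integer(seed),
                 final_selection = match.arg(final_selection)),
            class = "evo_search_config")
}

#' @export
print.evo_search_config <- function(x, ...) {
  cat(sprintf("<search_config %d iterations | c = %.3f | %s | seed %d>\n",
              x$iterations, x$exploration_constant, x$final_selection, x$seed))
  invisible(x)
}

#' UCB1 urgency of a tree node
#'
#' The selection rule used during tree descent: unvisited children have
#' infinite urgency (exploration-first), otherwise
#' `mean_reward + c * sqrt(log(parent_visits) / child_visits)`, where the
#' mean reward is taken for the player to move at the parent node.
#'
#' @param child,parent Node summaries as returned by [search_node()]:
#'   lists with `visits`, `total_reward` (named numeric, one entry per
#'   player) and `player_to_move`.
#' @param c Exploration constant.
#' @return The urgency score (possibly `Inf`).
#' @examples
#' ch <- search_node(visits = 10, total_reward = c(participant = 2, ai = 5))
#' pa <- search_node(visits = 100, player_to_move = "ai")
#' urgency(ch, pa, c = sqrt(2))  # 0.5 + sqrt(2 * log(100) / 10)
#' @export
urgency <- function(child, parent, c = sqrt(2)) {
  stopifnot(parent$visits >= 1)
  if (child$visits == 0) return(Inf)
  mean_reward <- child$total_reward[[parent$player_to_move]] / child$visits
  mean_reward + c * sqrt(log(parent$visits) / child$visits)
}

#' @rdname urgency
#' @param visits,total_reward,player_to_move Node bookkeeping fields.
#' @export
search_node <- function(visits = 0L,
                        total_reward = c(participant = 0, ai = 0),
                        player_to_move = "ai") {
  list(visits = visits, total_reward = total_reward,
       player_to_move = match.arg(player_to_move, PLAYERS))
}

#' Monte Carlo Tree Search for the best move
#'
#' Runs `config$iterations` iterations of selection (UCB1 urgency),
#' expansion (one random untried move), simulation (uniform-random playout
#' to a terminal state) and backpropagation, then returns the root move
#' maximizing the configured final-selection criterion for the searching
#' player (the player to move in `state`).
#'
#' Terminal evaluation produces a per-player reward pair: the searcher's
#' side uses `reward` (e.g. a True POSAS cone), the opponent's side a
#' standard win/draw/loss reward — the AI does not assume the human
#' cooperates with its outcome target. During descent each node is scored
#' with the reward of the player to move at its parent.
#'
#' @param state A non-terminal `evo_state`.
#' @param config An [search_config()].
#' @param reward An [reward_spec()]; defaults to standard strongest play.
#' @param return_children Attach a tibble of root-child statistics.
#' @param return_tree Attach a per-node dump of the whole search tree
#'   (parent index, incoming move, visits, per-player total rewards).
#' @return An object of class `evo_search`: list with `move` (an
#'   `evo_move`), `root_visits`, `n_nodes`, `searcher`, and optionally
#'   `children` / `tree` tibbles.
#' @examples
#' \donttest{
#' st <- tutorial_game(3)
#' res <- mcts_search(st, search_config(iterations = 200, seed = 1))
#' res$move
#' }
#' @export
mcts_search <- function(state, config = search_config(),
                        reward = reward_spec("standard"),
                        return_children = FALSE, return_tree = FALSE) {
  stopifnot(inherits(state, "evo_state"), inherits(config, "evo_search_config"),
            inherits(reward, "evo_reward_spec"))
  if (state$phase == 2L) stop("search on a terminal state", call. = FALSE)
  out <- cpp_mcts_search(
    state_payload(state), config$iterations, config$exploration_constant,
    config$seed, reward_mode_code(reward), reward$target_pwm,
    reward$max_move_score, reward$span, reward$draw_reward,
    match(config$final_selection, c("max_mean_reward", "max_visits")) - 1L,
    return_children, return_tree)
  out$move <- decode_move(out$move, state)
  if (!is.null(out$children)) out$children <- decode_move_table(out$children, state)
  if (!is.null(out$tree)) out$tree <- decode_move_table(out$tree, state)
  structure(out, class = "evo_search")
}

#' @export
print.evo_search <- function(x, ...) {
  cat(sprintf("<evo_search %d iterations | %d nodes | searcher: %s>\n",
              x$iterations, x$n_nodes, PLAYERS[x$searcher + 1L]))
  print(x$move)
  invisible(x)
}

#' @export
tidy.evo_search <- function(x, ...) {
  if (is.null(x$children))
    stop("run mcts_search(..., return_children = TRUE) to tidy a search",
         call. = FALSE)
  x$children
}

# C++ move (tile indices) -> evo_move with 0-based (col,row) coordinates
decode_move <- function(m, state) {
  to <- tile_coord(m$to, state$cols)[1, ]
  if (m$kind == 0L) {
    mv <- move_place(c(to[["col"]], to[["row"]]), figure = m$fig + 1L)
  } else {
    fr <- tile_coord(m$from, state$cols)[1, ]
    mv <- move_slide(c(fr[["col"]], fr[["row"]]), c(to[["col"]], to[["row"]]),
                     figure = m$fig + 1L)
  }
  mv
}

decode_move_table <- function(df, state) {
  df <- tibble::as_tibble(df)
  fr <- tile_coord(pmax(df$from, 0L), state$cols)
  to <- tile_coord(pmax(df$to, 0L), state$cols)
  df$kind <- c("root", "place", "slide")[df$kind + 2L]
  df$figure <- ifelse(df$fig >= 0, df$fig + 1L, NA_integer_)
  df$from_col <- ifelse(df$from >= 0, fr[, "col"], NA_integer_)
  df$from_row <- ifelse(df$from >= 0, fr[, "row"], NA_integer_)
  df$to_col <- ifelse(df$to >= 0, to[, "col"], NA_integer_)
  df$to_row <- ifelse(df$to >= 0, to[, "row"], NA_integer_)
  df$fig <- df$from <- df$to <- NULL
  df
}

#' Exact minimax value of a position (oracle)
#'
#' Brute-force game-tree search of the standard win/draw/loss reward for
#' `searcher`, with the opponent minimizing it. Exponential in the number
#' of open tiles: only use on tiny boards (roughly <= 10 open tiles with
#' one figure per player).
#'
#' @param state An `evo_state`.
#' @param searcher Player whose reward is maximized; defaults to the
#'   player to move.
#' @return List with `value` (exact game-theoretic reward in `[0, 1]`),
#'   `move` (an optimal move for the player to move, `NULL` if terminal)
#'   and `nodes_visited`.
#' @export
minimax_value <- function(state, searcher = NULL) {
  stopifnot(inherits(state, "evo_state"))
  s <- if (is.null(searcher)) -1L else player_index(searcher)
  out <- cpp_minimax(state_payload(state), s)
  if (!is.null(out$move)) out$move <- decode_move(out$move, state)
  out
}
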