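#' Legal placements
#'
#' During the placement phase a figure may be placed on any open,
#' unoccupied tile containing exactly one coin.
#'
#' @param state An `evo_state` in the placement phase.
#' @return Tibble of legal target tiles with 0-based columns `col`, `row`.
#' @examples
#' nrow(legal_placements(standard_game(42)))  # 26 one-coin tiles
#' @export
legal_placements <- function(state) {
  stopifnot(inherits(state, "evo_state"))
  idx <- cpp_legal_placements(state_payload(state))
  cc <- tile_coord(idx, state$cols)
  tibble::tibble(col = as.integer(cc[, "col"]), row = as.integer(cc[, "row"]))
}

#' Legal slides
#'
#' A slide moves one of the player's figures any number of tiles in a
#' straight hexagonal line; every tile along the path, including the
#' destination, must be open (not lava) and unoccupied.
#'
#' @param state An `evo_state` in the movement phase.
#' @param player `"participant"`, `"ai"`, or 0/1. Defaults to the player to
#'   move.
#' @return Tibble of moves: `figure` (1-based id), `from_col`, `from_row`,
#'   `to_col`, `to_row` (0-based coordinates). Zero rows when the player has
#'   no mobile figure.
#' @export
legal_moves <- function(state, player = NULL) {
  stopifnot(inherits(state, "evo_state"))
  p <- if (is.null(player)) state$to_move else player_index(player)
  m <- cpp_legal_slides(state_payload(state), p)
  fr <- tile_coord(m[, "from"], state$cols)
  to <- tile_coord(m[, "to"], state$cols)
  tibble::tibble(
    figure = as.integer(m[, "fig"]) + 1L,
    from_col = as.integer(fr[, "col"]), from_row = as.integer(fr[, "row"]),
    to_col = as.integer(to[, "col"]), to_row = as.integer(to[, "row"]))
}

#' Construct move objects
#'
#' `move_place()` places the next unplaced figure (or `figure`) on tile
#' `to`; `move_slide()` slides the figure standing on `from` to `to`.
#' Coordinates are 0-based `c(col, row)`.
#'
#' @param to,from Length-2 integer vectors `c(col, row)`.
#' @param figure Optional 1-based figure id; inferred when omitted.
#' @return A list of class `evo_move`.
#' @export
move_place <- function(to, figure = NULL) {
  structure(list(kind = "place", figure = figure, from = NULL,
                 to = as.integer(to)), class = "evo_move")
}

#' @rdname move_place
#' @export
move_slide <- function(from, to, figure = NULL) {
  structure(list(kind = "slide", figure = figure, from = as.integer(from),
                 to = as.integer(to)), class = "evo_move")
}

#' @export
print.evo_move <- function(x, ...) {
  if (x$kind == "place") {
    cat(sprintf("<place -> (%d,%d)>\n", x$to[1], x$to[2]))
  } else {
    cat(sprintf("<slide (%d,%d) -> (%d,%d)>\n", x$from[1], x$from[2],
                x$to[1], x$to[2]))
  }
  invisible(x)
}

# accept evo_move, a bare list, or a one-row tibble from legal_moves()
as_move <- function(move, state) {
  if (is.data.frame(move)) {
    stopifnot(nrow(move) == 1)
    if (all(c("from_col", "to_col") %in% names(move))) {
      return(move_slide(c(move$from_col, move$from_row),
                        c(move$to_col, move$to_row), move$figure))
    }
    return(move_place(c(move$col, move$row)))
  }
  stopifnot(is.list(move), !is.null(move$kind))
  move
}

resolve_figure <- function(state, move) {
  if (!is.null(move$figure)) return(as.integer(move$figure) - 1L)
  if (move$kind == "place") {
    cand <- which(state$fig_owner == state$to_move & state$fig_pos == -1L)
    if (!length(cand)) stop("no unplaced figure for the player to move", call. = FALSE)
    return(cand[1] - 1L)
  }
  idx <- tile_index(move$from[1], move$from[2], state$cols)
  f <- which(state$fig_pos == idx)
  if (!length(f)) stop("no figure on the slide origin tile", call. = FALSE)
  f[1] - 1L
}

#' Apply a move
#'
#' Applies a placement or slide and returns the successor state. A slide
#' turns its origin tile to lava and scores the destination tile's coins
#' for the mover; placements do not score. After every move a stranding
#' sweep (row-major scan, run to fixed point, both players) removes every
#' figure with no legal slide: its tile turns to lava and any uncollected
#' coins on it are forfeited. The game ends when all figures are removed.
#'
#' @param state An `evo_state`.
#' @param move An `evo_move`, a one-row tibble from [legal_moves()] /
#'   [legal_placements()], or a bare list with `kind`, `from`, `to`.
#' @return The successor `evo_state` (move appended to its history).
#' @examples
#' st <- make_state(3, 3, coins = 1, participant = c(0, 0), ai = c(2, 2))
#' st2 <- apply_move(st, move_slide(c(0, 0), c(1, 0)))
#' st2$scores  # participant scored 1 coin
#' @export
apply_move <- function(state, move) {
  stopifnot(inherits(state, "evo_state"))
  move <- as_move(move, state)
  if (state$phase == 2L)
    stop("illegal move: game is over (terminal state)", call. = FALSE)
  if (move$kind == "place" && state$phase != 0L)
    stop("illegal move: placements are only legal in the placement phase",
         call. = FALSE)
  if (move$kind == "slide" && state$phase != 1L)
    stop("illegal move: slides are only legal in the movement phase",
         call. = FALSE)
  fig <- resolve_figure(state, move)
  kind <- match(move$kind, c("place", "slide")) - 1L
  from <- if (kind == 1L) tile_index(move$from[1], move$from[2], state$cols) else -1L
  to <- tile_index(move$to[1], move$to[2], state$cols)
  nxt <- cpp_apply_move(state_payload(state), kind, fig, from, to)
  state_from_payload(nxt, c(attr(state, "history"), list(move)))
}

#' Uniform-random playout to a terminal state
#'
#' Plays uniformly random legal actions (placements and slides) for both
#' players until the game ends; the workhorse behind MCTS simulations and
#' the engine's property-based invariant checks.
#'
#' @param state A non-terminal `evo_state`.
#' @param seed Integer seed.
#' @param trace Record per-action lava counts and scores.
#' @return List with `state` (terminal), `moves` (action count), `pwm`, and
#'   when `trace = TRUE` the vectors `lava_trace`, `p_trace`, `a_trace` and
#'   the coin-conservation flag `conserved`.
#' @export
random_playout <- function(state, seed = 1L, trace = FALSE) {
  stopifnot(inherits(state, "evo_state"))
  if (state$phase == 2L) stop("state is already terminal", call. = FALSE)
  out <- cpp_random_playout(state_payload(state), as.integer(seed), trace)
  out$state <- state_from_payload(out$state, attr(state, "history"))
  out
}
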