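#' Scripted opponent specifications
#'
#' Synthetic stand-ins for human participants of graded skill:
#'
#' * `"random"` — uniform over legal actions.
#' * `"greedy"` — slides to the destination with the most coins (ties
#'   uniform); placements uniform.
#' * `"mcts_standard"` — standard-reward MCTS at `budget` iterations,
#'   the strongest ladder rung.
#'
#' @param policy One of `"random"`, `"greedy"`, `"mcts_standard"`.
#' @param budget Iteration budget (only used by `"mcts_standard"`).
#' @param label Optional label for logs; defaults to the policy name
#'   (plus budget for MCTS).
#' @return An object of class `evo_opponent_spec`.
#' @examples
#' opponent_spec("greedy")
#' opponent_spec("mcts_standard", budget = 500)
#' @export
opponent_spec <- function(policy = c("greedy", "random", "mcts_standard"),
                          budget = 1000L, label = NULL) {
  policy <- match.arg(policy)
  budget <- as.integer(budget)
  if (policy == "mcts_standard" && budget < 1L)
    stop("mcts_standard needs budget >= 1", call. = FALSE)
  if (is.null(label))
    label <- if (policy == "mcts_standard") paste0(policy, "_", budget) else policy
  structure(list(policy = policy, budget = budget, label = label),
            class = "evo_opponent_spec")
}

#' @export
print.evo_opponent_spec <- function(x, ...) {
  cat(sprintf("<opponent %s>\n", x$label))
  invisible(x)
}

policy_code <- function(policy) {
  match(policy, c("random", "greedy", "mcts_standard")) - 1L
}

#' Scripted policy moves
#'
#' `policy_move()` draws one move from an opponent specification;
#' `random_policy()`, `greedy_policy()` and `mcts_standard_policy()` are
#' the direct forms.
#'
#' @param state A non-terminal `evo_state` (the policy moves for the
#'   player to move).
#' @param spec An [opponent_spec()].
#' @param seed Integer seed.
#' @param budget Iteration budget for `mcts_standard_policy()`.
#' @param exploration_constant UCB1 constant for the MCTS policy.
#' @return An `evo_move`.
#' @export
policy_move <- function(state, spec, seed = 1L) {
  stopifnot(inherits(state, "evo_state"), inherits(spec, "evo_opponent_spec"))
  if (state$phase == 2L) stop("policy on a terminal state", call. = FALSE)
  m <- cpp_policy_move(state_payload(state), policy_code(spec$policy),
                       spec$budget, sqrt(2), as.integer(seed))
  decode_move(m, state)
}

#' @rdname policy_move
#' @export
random_policy <- function(state, seed = 1L) {
  policy_move(state, opponent_spec("random"), seed)
}

#' @rdname policy_move
#' @export
greedy_policy <- function(state, seed = 1L) {
  policy_move(state, opponent_spec("greedy"), seed)
}

#' @rdname policy_move
#' @export
mcts_standard_policy <- function(state, budget = 1000L, seed = 1L,
                                 exploration_constant = sqrt(2)) {
  stopifnot(inherits(state, "evo_state"))
  if (state$phase == 2L) stop("policy on a terminal state", call. = FALSE)
  m <- cpp_policy_move(state_payload(state), 2L, as.integer(budget),
                       exploration_constant, as.integer(seed))
  decode_move(m, state)
}

#' Play one full match: scripted participant vs difficulty-controlled AI
#'
#' The participant (player 0, moving first in each phase) follows the
#' scripted opponent policy; the AI (player 1) chooses every move with
#' MCTS under the given reward specification.
#'
#' @param state A fresh (or mid-game) `evo_state`; see [standard_game()].
#' @param reward An [reward_spec()] for the AI, e.g. [condition_spec()].
#' @param opponent An [opponent_spec()] for the participant side.
#' @param config An [search_config()] for the AI; its `seed` is ignored in
#'   favour of `seed`.
#' @param seed Integer seed driving both the scripted policy and the
#'   per-move AI searches.
#' @param record_moves Attach the full move list.
#' @return One-row tibble: `participant_score`, `ai_score`, `pwm`,
#'   `result`, `move_count`, plus the terminal state in the `state`
#'   attribute (and `moves` when recorded).
#' @examples
#' \donttest{
#' play_match(tutorial_game(1), condition_spec("tutorial"),
#'            opponent_spec("random"), search_config(iterations = 100),
#'            seed = 7)
#' }
#' @export
play_match <- function(state, reward = condition_spec("balanced"),
                       opponent = opponent_spec("greedy"),
                       config = search_config(), seed = 1L,
                       record_moves = FALSE) {
  stopifnot(inherits(state, "evo_state"), inherits(reward, "evo_reward_spec"),
            inherits(opponent, "evo_opponent_spec"),
            inherits(config, "evo_search_config"))
  out <- cpp_play_match(
    state_payload(state), reward_mode_code(reward), reward$target_pwm,
    reward$max_move_score, reward$span, reward$draw_reward,
    config$iterations, config$exploration_constant,
    match(config$final_selection, c("max_mean_reward", "max_visits")) - 1L,
    policy_code(opponent$policy), opponent$budget, as.integer(seed),
    record_moves)
  res <- tibble::tibble(
    participant_score = out$participant_score, ai_score = out$ai_score,
    pwm = out$pwm,
    result = if (out$pwm > 0) "player_win" else if (out$pwm < 0) "player_loss" else "draw",
    move_count = out$move_count)
  attr(res, "state") <- state_from_payload(out$state)
  if (record_moves) attr(res, "moves") <- tibble::as_tibble(out$moves)
  res
}

#' Sample opponent specifications from a pool
#'
#' Models participant heterogeneity: each session draws its scripted
#' opponent from a configured mixture (e.g. MCTS budgets log-spaced).
#'
#' @param pool List of [opponent_spec()]s (or a single spec).
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return List of `n` opponent specs.
#' @export
sample_opponents <- function(pool, n, seed = 1L) {
  if (inherits(pool, "evo_opponent_spec")) pool <- list(pool)
  stopifnot(length(pool) >= 1,
            all(vapply(pool, inherits, logical(1), "evo_opponent_spec")))
  idx_seed <- split_seed(seed, 1, salt = 101L)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
          add = TRUE)
  set.seed(idx_seed)
  pool[sample.int(length(pool), n, replace = TRUE)]
}

#' Head-to-head match between two scripted policies
#'
#' Pits two scripted opponents against each other (player 0 moves first in
#' each phase), for skill-ladder calibration.
#'
#' @param state A fresh `evo_state`.
#' @param first,second [opponent_spec()]s for player 0 and player 1.
#' @param seed Integer seed.
#' @return One-row tibble as in [play_match()]; `pwm` is first-player score
#'   minus second-player score.
#' @export
play_policy_match <- function(state, first, second, seed = 1L) {
  stopifnot(inherits(state, "evo_state"),
            inherits(first, "evo_opponent_spec"),
            inherits(second, "evo_opponent_spec"))
  out <- cpp_play_match(
    state_payload(state), 0L, 0L, 3L, 162L, 0.5,
    second$budget, sqrt(2), 0L,
    policy_code(first$policy), first$budget, as.integer(seed),
    FALSE, policy_code(second$policy))
  tibble::tibble(
    participant_score = out$participant_score, ai_score = out$ai_score,
    pwm = out$pwm,
    result = if (out$pwm > 0) "player_win" else if (out$pwm < 0) "player_loss" else "draw",
    move_count = out$move_count)
}
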