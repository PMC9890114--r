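#' Terminal reward specifications
#'
#' A reward specification maps terminal game states to `[0, 1]` for the
#' searching AI. Three families are supported:
#'
#' * `"standard"`: 1 for an AI win, 0 for an AI loss, `draw_reward`
#'   (default 0.5) for a draw — the strongest-play setting.
#' * `"osas"`: graded reward peaking (apex) exactly at `target_pwm` and
#'   decaying linearly with the distance of the final PWM from the target,
#'   normalized by `span`.
#' * `"true_posas"`: as `"osas"`, but the maximal-reward plateau covers
#'   `[target_pwm, target_pwm + max_move_score]`. Shifting the apex up by
#'   the maximum score obtainable in a single move (3 points) compensates
#'   the first-mover advantage of the human player, yielding the
#'   "flattened cone" shape.
#'
#' @param mode `"standard"`, `"osas"` or `"true_posas"`.
#' @param target_pwm Target player win margin (easy 15, balanced 0,
#'   hard -15); must lie within `[-span/2, span/2]`.
#' @param max_move_score Maximum coins obtainable in one move (3).
#' @param span Normalization width: the full PWM range (162 on the
#'   standard board, i.e. -81..81).
#' @param draw_reward Reward for a draw under `"standard"` mode.
#' @return An object of class `evo_reward_spec`.
#' @examples
#' spec <- reward_spec("true_posas", target_pwm = 0)
#' reward_true_posas(c(0, 3, -15), spec)
#' @export
reward_spec <- function(mode = c("true_posas", "osas", "standard"),
                        target_pwm = 0L, max_move_score = 3L, span = 162L,
                        draw_reward = 0.5) {
  mode <- match.arg(mode)
  span <- as.integer(span)
  target_pwm <- as.integer(target_pwm)
  if (span <= 0) stop("span must be positive", call. = FALSE)
  if (abs(target_pwm) > span / 2)
    stop("target_pwm must lie within [-span/2, span/2]", call. = FALSE)
  if (max_move_score < 0) stop("max_move_score must be >= 0", call. = FALSE)
  if (draw_reward < 0 || draw_reward > 1)
    stop("draw_reward must lie in [0, 1]", call. = FALSE)
  structure(list(mode = mode, target_pwm = target_pwm,
                 max_move_score = as.integer(max_move_score), span = span,
                 draw_reward = draw_reward),
            class = "evo_reward_spec")
}

#' @export
print.evo_reward_spec <- function(x, ...) {
  if (x$mode == "standard") {
    cat(sprintf("<reward_spec standard | draw %.2f>\n", x$draw_reward))
  } else {
    cat(sprintf("<reward_spec %s | target PWM %+d | plateau width %d | span %d>\n",
                x$mode, x$target_pwm,
                if (x$mode == "true_posas") x$max_move_score else 0L, x$span))
  }
  invisible(x)
}

#' Standard win/draw/loss reward
#'
#' The reward a strongest-play AI maximizes: 1 for an AI win, 0 for an AI
#' loss, `spec$draw_reward` for a draw.
#'
#' @param result Terminal outcome(s): `"player_win"`, `"draw"` or
#'   `"player_loss"` (as reported by [game_outcome()], i.e. from the
#'   participant's side).
#' @param spec An `evo_reward_spec` (only `draw_reward` is used).
#' @return Numeric reward(s) in `[0, 1]`.
#' @export
reward_standard <- function(result, spec = reward_spec("standard")) {
  stopifnot(all(result %in% c("player_win", "draw", "player_loss")))
  unname(c(player_win = 0, draw = spec$draw_reward, player_loss = 1)[result])
}

#' Graded OSAS / True POSAS reward
#'
#' Maps a final PWM to `[0, 1]`: reward 1 on the maximal plateau
#' (`[target, target + max_move_score]` for `true_posas`, the single point
#' `target` for `osas`), decaying linearly as
#' `max(0, 1 - distance_to_plateau / span)` outside it.
#'
#' @param final_pwm Integer final player win margin(s); must satisfy
#'   `|final_pwm| <= span / 2`.
#' @param spec An `evo_reward_spec` with mode `"osas"` or `"true_posas"`.
#' @return Numeric reward(s) in `[0, 1]`.
#' @examples
#' spec <- reward_spec("true_posas", target_pwm = 0, span = 162)
#' reward_true_posas(3, spec)    # on the plateau: 1
#' reward_true_posas(-15, spec)  # 1 - 15/162
#' @export
reward_true_posas <- function(final_pwm, spec) {
  stopifnot(inherits(spec, "evo_reward_spec"))
  if (spec$mode == "standard")
    stop("standard mode has its own reward function, reward_standard()",
         call. = FALSE)
  if (any(abs(final_pwm) > spec$span / 2))
    stop("final_pwm outside the representable range [-span/2, span/2]",
         call. = FALSE)
  lo <- spec$target_pwm
  hi <- spec$target_pwm +
    if (spec$mode == "true_posas") spec$max_move_score else 0L
  d <- pmax(0, pmax(lo - final_pwm, final_pwm - hi))
  pmax(0, 1 - d / spec$span)
}

#' Per-condition reward specifications
#'
#' The three study conditions use True POSAS rewards with target PWMs of
#' 15 (easy), 0 (balanced) and -15 (hard). The tutorial AI always aims for
#' a draw (target 0) regardless of condition.
#'
#' @param name `"easy"`, `"balanced"`, `"hard"` or `"tutorial"`.
#' @return An `evo_reward_spec` with mode `"true_posas"`.
#' @examples
#' condition_spec("easy")$target_pwm  # 15
#' @export
condition_spec <- function(name = c("easy", "balanced", "hard", "tutorial")) {
  name <- match.arg(name)
  target <- switch(name, easy = 15L, balanced = 0L, hard = -15L,
                   tutorial = 0L)
  reward_spec("true_posas", target_pwm = target)
}

#' Condition targets as a tibble
#' @return Tibble with columns `condition`, `target_pwm`.
#' @export
condition_targets <- function() {
  tibble::tibble(condition = c("easy", "balanced", "hard"),
                 target_pwm = c(15L, 0L, -15L))
}

# numeric codes shared with the C++ layer
reward_mode_code <- function(spec) {
  match(spec$mode, c("standard", "osas", "true_posas")) - 1L
}

#' Plot a graded reward function
#'
#' Draws the reward over every integer PWM in `[-span/2, span/2]`,
#' with the nominal target marked.
#'
#' @param object An `evo_reward_spec`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evo_reward_spec <- function(object, ...) {
  if (object$mode == "standard")
    stop("autoplot is defined for graded (osas/true_posas) specs", call. = FALSE)
  half <- object$span %/% 2
  df <- tibble::tibble(pwm = seq(-half, half),
                       reward = reward_true_posas(seq(-half, half), object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pwm, y = .data$reward)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_vline(xintercept = object$target_pwm, linetype = "dashed") +
    ggplot2::labs(x = "final PWM (player score - AI score)",
                  y = "terminal reward",
                  title = sprintf("%s reward, target PWM %+d", object$mode,
                                  object$target_pwm)) +
    ggplot2::theme_minimal()
}
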