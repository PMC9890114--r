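#' Run one participant session
#'
#' A session mirrors the study protocol: the scripted participant plays
#' `games` consecutive matches on freshly shuffled standard boards, the AI
#' aiming for the session's condition target in every match. The tutorial
#' is not part of a session record.
#'
#' @param condition `"easy"`, `"balanced"` or `"hard"`.
#' @param opponent An [opponent_spec()] standing in for the participant.
#' @param games Matches per session (2 in the study design).
#' @param seed Session master seed; per-match board and play seeds are
#'   derived with [split_seed()].
#' @param config [search_config()] for the AI side.
#' @param board_rows,board_cols,coin_counts,figures_per_player Board
#'   configuration; defaults to the standard 7x7 / 81-coin / 3-figure game.
#' @return A tibble of class `evo_session`, one row per match:
#'   `condition`, `game_index`, `opponent`, `budget`, `participant_score`,
#'   `ai_score`, `pwm`, `result`, `move_count`, `board_seed`, `match_seed`.
#'   The session's PWM improvement (last-match PWM minus first-match PWM)
#'   is in the `pwm_improvement` attribute; see [pwm_improvement()].
#' @examples
#' \donttest{
#' s <- run_session("balanced", opponent_spec("random"), games = 2,
#'                  seed = 11, config = search_config(iterations = 50))
#' pwm_improvement(s)
#' }
#' @export
run_session <- function(condition = c("easy", "balanced", "hard"),
                        opponent = opponent_spec("greedy"),
                        games = 2L, seed = 1L,
                        config = search_config(),
                        board_rows = 7L, board_cols = 7L,
                        coin_counts = standard_coin_counts(),
                        figures_per_player = 3L) {
  condition <- match.arg(condition)
  stopifnot(games >= 1)
  reward <- condition_spec(condition)
  board_seeds <- split_seed(seed, games, salt = 1L)
  match_seeds <- split_seed(seed, games, salt = 2L)
  rows <- lapply(seq_len(games), function(g) {
    board <- generate_board(board_rows, board_cols, coin_counts,
                            seed = board_seeds[g],
                            figures_per_player = figures_per_player)
    st <- new_game(board, figures_per_player)
    rec <- play_match(st, reward, opponent, config, seed = match_seeds[g])
    dplyr::mutate(rec, condition = condition, game_index = g,
                  opponent = .env$opponent$label,
                  budget = .env$opponent$budget,
                  board_seed = board_seeds[g], match_seed = match_seeds[g],
                  .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "pwm_improvement") <- out$pwm[games] - out$pwm[1]
  class(out) <- c("evo_session", class(out))
  out
}

#' Session PWM improvement
#'
#' Last-match PWM minus first-match PWM of a session — the study's measure
#' of whether the player (here: the scripted opponent plus AI adaptation)
#' improved between games. 0 for a single-game session.
#'
#' @param session An `evo_session` from [run_session()].
#' @return Integer.
#' @export
pwm_improvement <- function(session) {
  imp <- attr(session, "pwm_improvement")
  if (is.null(imp)) imp <- session$pwm[nrow(session)] - session$pwm[1]
  as.integer(imp)
}

#' Run a full agent-vs-agent study
#'
#' Rebuilds the validation study AI-vs-AI: sessions are assigned to the
#' three conditions round-robin (session 1 easy, 2 balanced, 3 hard, 4
#' easy, ...), each session's scripted opponent is drawn from
#' `opponent_pool`, and every source of randomness derives from `seed`.
#'
#' @param n_per_condition Sessions per condition.
#' @param opponent_pool A single [opponent_spec()] or a list of them;
#'   sessions draw from this pool (participant heterogeneity).
#' @param games Matches per session.
#' @param seed Master seed.
#' @param config [search_config()] for the AI side.
#' @param conditions Character vector of conditions to cycle over.
#' @param ... Board configuration passed to [run_session()].
#' @return An object of class `evo_study`: list with `matches` (tibble,
#'   one row per match, including `session`), `sessions` (tibble, one row
#'   per session with `pwm_first`, `pwm_last`, `pwm_improvement`), and the
#'   run metadata (`seed`, `config`).
#' @examples
#' \donttest{
#' study <- run_study(2, opponent_spec("random"), seed = 5,
#'                    config = search_config(iterations = 50))
#' summarize_study(study)
#' }
#' @export
run_study <- function(n_per_condition, opponent_pool = opponent_spec("greedy"),
                      games = 2L, seed = 1L, config = search_config(),
                      conditions = c("easy", "balanced", "hard"), ...) {
  stopifnot(n_per_condition >= 1)
  n_sessions <- n_per_condition * length(conditions)
  assigned <- conditions[(seq_len(n_sessions) - 1L) %% length(conditions) + 1L]
  opponents <- sample_opponents(opponent_pool, n_sessions, seed = seed)
  session_seeds <- split_seed(seed, n_sessions, salt = 3L)
  matches <- purrr::map_dfr(seq_len(n_sessions), function(i) {
    s <- run_session(assigned[i], opponents[[i]], games = games,
                     seed = session_seeds[i], config = config, ...)
    dplyr::mutate(tibble::as_tibble(s), session = i,
                  session_seed = session_seeds[i], .before = 1)
  })
  sessions <- matches |>
    dplyr::group_by(.data$session, .data$condition, .data$opponent,
                    .data$budget) |>
    dplyr::summarise(
      games = dplyr::n(),
      pwm_first = dplyr::first(.data$pwm),
      pwm_last = dplyr::last(.data$pwm),
      result_last = dplyr::last(.data$result),
      .groups = "drop") |>
    dplyr::mutate(pwm_improvement = .data$pwm_last - .data$pwm_first)
  structure(list(matches = matches, sessions = sessions, seed = seed,
                 config = config,
                 conditions = conditions,
                 n_per_condition = n_per_condition),
            class = "evo_study")
}

#' @export
print.evo_study <- function(x, ...) {
  cat(sprintf("<evo_study %d sessions (%d per condition) x %d games | seed %d>\n",
              nrow(x$sessions), x$n_per_condition,
              max(x$matches$game_index), x$seed))
  print(summarize_study(x))
  invisible(x)
}

#' @export
tidy.evo_study <- function(x, ...) x$matches

#' @export
glance.evo_study <- function(x, ...) {
  tibble::tibble(n_sessions = nrow(x$sessions),
                 n_matches = nrow(x$matches),
                 n_per_condition = x$n_per_condition,
                 games_per_session = max(x$matches$game_index),
                 iterations = x$config$iterations,
                 seed = x$seed)
}

#' Per-condition outcome summaries
#'
#' Aggregates a study into the study report's per-condition rows: sample
#' size, target PWM, mean/sd/median of actual PWM, win/draw/loss
#' percentages, and PWM-improvement statistics. Outcome rates and PWM
#' statistics are computed on the last full match of each session
#' (`pool = "last"`, the default) or over all matches (`pool = "both"`);
#' improvements are always per-session. The sd is the sample sd and is
#' `NA` for single-session conditions.
#'
#' @param study An `evo_study`.
#' @param pool `"last"` or `"both"`.
#' @return A tibble, one row per condition.
#' @export
summarize_study <- function(study, pool = c("last", "both")) {
  stopifnot(inherits(study, "evo_study"))
  pool <- match.arg(pool)
  m <- if (pool == "last") {
    study$matches |>
      dplyr::group_by(.data$session) |>
      dplyr::slice_max(.data$game_index, n = 1) |>
      dplyr::ungroup()
  } else {
    study$matches
  }
  imp <- study$sessions |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(pwm_improvement_mean = mean(.data$pwm_improvement),
                     pwm_improvement_median = median(.data$pwm_improvement),
                     .groups = "drop")
  m |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      pwm_mean = mean(.data$pwm),
      pwm_sd = if (dplyr::n() > 1) sd(.data$pwm) else NA_real_,
      pwm_median = median(.data$pwm),
      win_pct = 100 * mean(.data$result == "player_win"),
      draw_pct = 100 * mean(.data$result == "draw"),
      loss_pct = 100 * mean(.data$result == "player_loss"),
      .groups = "drop") |>
    dplyr::left_join(condition_targets(), by = "condition") |>
    dplyr::left_join(imp, by = "condition") |>
    dplyr::arrange(factor(.data$condition, levels = c("easy", "balanced", "hard"))) |>
    dplyr::relocate("target_pwm", .after = "n")
}

#' Kruskal-Wallis test with epsilon-squared effect size
#'
#' Rank-based between-condition test of PWM differences with tie
#' correction (via [stats::kruskal.test()]) plus the epsilon-squared
#' effect size `H * (n + 1) / (n^2 - 1)`.
#'
#' @param x A list of (>= 2) numeric vectors, one per group, or a numeric
#'   vector of values.
#' @param g Group labels when `x` is a vector.
#' @return Object of class `evo_kw`: list with `H`, `df`, `p`,
#'   `epsilon_sq`, `n_total`.
#' @examples
#' kw <- kruskal_wallis_epsilon2(list(c(1, 2), c(3, 4), c(5, 6)))
#' kw$H
#' @export
kruskal_wallis_epsilon2 <- function(x, g = NULL) {
  if (is.list(x) && is.null(g)) {
    if (length(x) < 2) stop("need at least two groups", call. = FALSE)
    groups <- x
  } else {
    groups <- split(x, g)
    if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  }
  if (any(lengths(groups) == 0)) stop("empty group", call. = FALSE)
  n <- sum(lengths(groups))
  if (n < 3) stop("need total n >= 3", call. = FALSE)
  if (length(unique(unlist(groups))) == 1) {
    # fully degenerate data: no between-group variation at all
    return(structure(list(H = 0, df = length(groups) - 1L, p = 1,
                          epsilon_sq = 0, n_total = n, k = length(groups)),
                     class = "evo_kw"))
  }
  kt <- kruskal.test(groups)
  H <- unname(kt$statistic)
  structure(list(H = H, df = unname(kt$parameter), p = kt$p.value,
                 epsilon_sq = epsilon_squared(H, n), n_total = n,
                 k = length(groups)),
            class = "evo_kw")
}

#' @rdname kruskal_wallis_epsilon2
#' @param H Kruskal-Wallis statistic.
#' @param n Total sample size.
#' @export
epsilon_squared <- function(H, n) H * (n + 1) / (n^2 - 1)

#' @export
print.evo_kw <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H(%d) = %.3f, p = %.3g, epsilon^2 = %.3f (n = %d)\n",
              x$df, x$H, x$p, x$epsilon_sq, x$n_total))
  invisible(x)
}

#' @export
tidy.evo_kw <- function(x, ...) {
  tibble::tibble(statistic = x$H, df = x$df, p.value = x$p,
                 epsilon_sq = x$epsilon_sq, n = x$n_total)
}

#' @export
glance.evo_kw <- function(x, ...) tidy(x)

#' Dunn's pairwise post-hoc comparisons
#'
#' Pairwise z-tests on mean ranks following a Kruskal-Wallis test, with
#' tie correction and Holm-adjusted p-values.
#'
#' @param x Numeric values.
#' @param g Group labels.
#' @param p_adjust Adjustment method for [stats::p.adjust()].
#' @return Tibble with one row per pair: `group1`, `group2`,
#'   `mean_rank_diff`, `z`, `p.value`, `p.adj`.
#' @export
dunn_posthoc <- function(x, g, p_adjust = "holm") {
  g <- factor(g)
  if (nlevels(g) < 2) stop("need at least two groups", call. = FALSE)
  N <- length(x)
  rk <- rank(x)
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  mean_ranks <- tapply(rk, g, mean)
  ns <- tapply(rk, g, length)
  pairs <- utils::combn(levels(g), 2)
  res <- apply(pairs, 2, function(pr) {
    d <- mean_ranks[[pr[1]]] - mean_ranks[[pr[2]]]
    se <- sqrt(sigma2 * (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
    z <- d / se
    c(diff = d, z = z, p = 2 * pnorm(-abs(z)))
  })
  tibble::tibble(group1 = pairs[1, ], group2 = pairs[2, ],
                 mean_rank_diff = res["diff", ], z = res["z", ],
                 p.value = res["p", ],
                 p.adj = p.adjust(res["p", ], method = p_adjust))
}

#' Manipulation-validity analysis of a study
#'
#' The study's validity check: Kruskal-Wallis over per-condition final
#' PWMs plus Dunn pairwise comparisons, computed on the last match per
#' session.
#'
#' @param study An `evo_study`.
#' @return List with `kw` (an `evo_kw`) and `pairwise` (tibble from
#'   [dunn_posthoc()]).
#' @export
validate_manipulation <- function(study) {
  stopifnot(inherits(study, "evo_study"))
  s <- study$sessions
  list(kw = kruskal_wallis_epsilon2(s$pwm_last, s$condition),
       pairwise = dunn_posthoc(s$pwm_last, s$condition))
}

#' Plot study outcomes by condition
#'
#' Final-match PWM per condition with the condition targets marked.
#'
#' @param object An `evo_study`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evo_study <- function(object, ...) {
  s <- object$sessions |>
    dplyr::mutate(condition = factor(.data$condition,
                                     levels = c("easy", "balanced", "hard")))
  tg <- condition_targets() |>
    dplyr::mutate(condition = factor(.data$condition,
                                     levels = levels(s$condition)))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$condition, y = .data$pwm_last)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.5, size = 1) +
    ggplot2::geom_point(data = tg, ggplot2::aes(y = .data$target_pwm),
                        colour = "red", shape = 4, size = 3, stroke = 1.2) +
    ggplot2::labs(x = NULL, y = "final-match PWM",
                  title = "Achieved PWM vs condition targets (x)") +
    ggplot2::theme_minimal()
}
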