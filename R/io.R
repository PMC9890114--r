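#' Serialize a game state to JSON
#'
#' States serialize to a stable, documented JSON schema (grid dimensions,
#' per-tile coins / lava / collected flags, figure owners and positions,
#' scores, phase, player to move, placement counts). Serialization is
#' canonical: `state_to_json(state_from_json(x))` is byte-identical to
#' `x`.
#'
#' @param state An `evo_state`.
#' @param path Optional file to write to.
#' @return The JSON string (invisibly when `path` is given).
#' @examples
#' js <- state_to_json(tutorial_game(1))
#' identical(state_to_json(state_from_json(js)), js)
#' @export
state_to_json <- function(state, path = NULL) {
  stopifnot(inherits(state, "evo_state"))
  js <- jsonlite::toJSON(state_payload(state), auto_unbox = FALSE,
                         digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname state_to_json
#' @param json A JSON string (or a file path to read).
#' @export
state_from_json <- function(json) {
  if (length(json) == 1 && !grepl("^\\s*\\{", json)) json <- readLines(json)
  lst <- jsonlite::fromJSON(paste(json, collapse = "\n"))
  lst <- lapply(lst, as.integer)
  need <- c("rows", "cols", "fpp", "coins", "lava", "scored", "fig_owner",
            "fig_pos", "scores", "phase", "to_move", "placed")
  miss <- setdiff(need, names(lst))
  if (length(miss))
    stop("state JSON missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  lst$rows <- lst$rows[1]; lst$cols <- lst$cols[1]; lst$fpp <- lst$fpp[1]
  lst$phase <- lst$phase[1]; lst$to_move <- lst$to_move[1]
  state_from_payload(lst)
}

#' Read and validate a study run configuration
#'
#' A run is reproducible from its configuration file alone. YAML (or JSON)
#' with keys: `seed`, `n_per_condition`, `games_per_session`, `board`
#' (`rows`, `cols`, `coin_counts`, `figures_per_player`), `search`
#' (`iterations`, `exploration_constant`, `final_selection`), `opponents`
#' (list of `policy` / `budget`). Missing optional keys take the study
#' defaults; a missing or malformed required key raises an error naming
#' it.
#'
#' @param path Path to a YAML/JSON config file.
#' @return A validated config list of class `evo_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A config list (as parsed from YAML).
#' @export
validate_run_config <- function(cfg) {
  need_num <- function(key, value, min = 1) {
    if (is.null(value)) stop("config key missing: ", key, call. = FALSE)
    if (!is.numeric(value) || length(value) != 1 || value < min)
      stop("config key invalid: ", key, call. = FALSE)
    as.integer(value)
  }
  cfg$seed <- need_num("seed", cfg$seed, min = 0)
  cfg$n_per_condition <- need_num("n_per_condition", cfg$n_per_condition)
  cfg$games_per_session <-
    need_num("games_per_session", cfg$games_per_session %||% 2L)
  board <- cfg$board
  if (is.null(board)) stop("config key missing: board", call. = FALSE)
  board$rows <- need_num("board.rows", board$rows)
  board$cols <- need_num("board.cols", board$cols)
  board$figures_per_player <-
    need_num("board.figures_per_player", board$figures_per_player %||% 3L)
  if (is.null(board$coin_counts)) {
    board$coin_counts <- as.list(standard_coin_counts())
  }
  cc <- unlist(board$coin_counts)
  if (sum(cc) != board$rows * board$cols)
    stop("config key invalid: board.coin_counts (must sum to rows*cols)",
         call. = FALSE)
  cfg$board <- board
  search <- cfg$search %||% list()
  search$iterations <- need_num("search.iterations", search$iterations %||% 7500L)
  search$exploration_constant <-
    search$exploration_constant %||% sqrt(2)
  search$final_selection <- search$final_selection %||% "max_mean_reward"
  if (!search$final_selection %in% c("max_mean_reward", "max_visits"))
    stop("config key invalid: search.final_selection", call. = FALSE)
  cfg$search <- search
  opp <- cfg$opponents %||% list(list(policy = "greedy"))
  if (!is.null(opp$policy)) opp <- list(opp)  # single unnested spec
  cfg$opponents <- lapply(seq_along(opp), function(i) {
    o <- opp[[i]]
    if (is.null(o$policy) ||
        !o$policy %in% c("random", "greedy", "mcts_standard"))
      stop("config key invalid: opponents[", i, "].policy", call. = FALSE)
    opponent_spec(o$policy, budget = o$budget %||% 1000L)
  })
  structure(cfg, class = "evo_run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a configured simulation end-to-end
#'
#' Executes the configured study and writes all artifacts to `out_dir`:
#' `matches.jsonl` (one JSON record per match, seeds included),
#' `sessions.csv`, `summary.csv` (per-condition outcomes) and
#' `kruskal_wallis.json` (test + pairwise comparisons). Reruns with the
#' same config produce identical files.
#'
#' @param config Path to a config file, or an `evo_run_config`.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the study object and artifact paths.
#' @export
run_simulation <- function(config, out_dir, quiet = FALSE) {
  cfg <- if (inherits(config, "evo_run_config")) config
         else read_run_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  say("study: ", cfg$n_per_condition, " sessions/condition x ",
      cfg$games_per_session, " games, seed ", cfg$seed)
  study <- run_study(
    n_per_condition = cfg$n_per_condition,
    opponent_pool = cfg$opponents,
    games = cfg$games_per_session,
    seed = cfg$seed,
    config = search_config(iterations = cfg$search$iterations,
                           exploration_constant = cfg$search$exploration_constant,
                           final_selection = cfg$search$final_selection),
    board_rows = cfg$board$rows, board_cols = cfg$board$cols,
    coin_counts = unlist(cfg$board$coin_counts),
    figures_per_player = cfg$board$figures_per_player)
  paths <- list(
    matches = file.path(out_dir, "matches.jsonl"),
    sessions = file.path(out_dir, "sessions.csv"),
    summary = file.path(out_dir, "summary.csv"),
    kw = file.path(out_dir, "kruskal_wallis.json"))
  writeLines(vapply(seq_len(nrow(study$matches)), function(i) {
    jsonlite::toJSON(as.list(study$matches[i, ]), auto_unbox = TRUE,
                     digits = NA)
  }, character(1)), paths$matches)
  write.csv(study$sessions, paths$sessions, row.names = FALSE)
  write.csv(summarize_study(study), paths$summary, row.names = FALSE)
  val <- validate_manipulation(study)
  jsonlite::write_json(
    list(kruskal_wallis = unclass(val$kw),
         pairwise = val$pairwise),
    paths$kw, auto_unbox = TRUE, digits = NA)
  say("Kruskal-Wallis H(", val$kw$df, ") = ", round(val$kw$H, 2),
      ", p = ", signif(val$kw$p, 3))
  invisible(list(study = study, paths = paths))
}

#' Rebuild a per-condition summary from a match log
#'
#' Reads a `matches.jsonl` log (as written by [run_simulation()]) and
#' writes the per-condition summary CSV.
#'
#' @param jsonl_in Path to the JSON-lines match log.
#' @param csv_out Path for the summary CSV.
#' @return The summary tibble, invisibly.
#' @export
report_matches <- function(jsonl_in, csv_out) {
  lines <- readLines(jsonl_in)
  m <- dplyr::bind_rows(lapply(lines, function(l) {
    tibble::as_tibble(jsonlite::fromJSON(l))
  }))
  last <- m |>
    dplyr::group_by(.data$session) |>
    dplyr::slice_max(.data$game_index, n = 1) |>
    dplyr::ungroup()
  imp <- m |>
    dplyr::group_by(.data$session, .data$condition) |>
    dplyr::summarise(imp = dplyr::last(.data$pwm) - dplyr::first(.data$pwm),
                     .groups = "drop") |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(pwm_improvement_mean = mean(.data$imp),
                     pwm_improvement_median = median(.data$imp),
                     .groups = "drop")
  out <- last |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n = dplyr::n(), pwm_mean = mean(.data$pwm),
      pwm_sd = if (dplyr::n() > 1) sd(.data$pwm) else NA_real_,
      pwm_median = median(.data$pwm),
      win_pct = 100 * mean(.data$result == "player_win"),
      draw_pct = 100 * mean(.data$result == "draw"),
      loss_pct = 100 * mean(.data$result == "player_loss"),
      .groups = "drop") |>
    dplyr::left_join(imp, by = "condition")
  write.csv(out, csv_out, row.names = FALSE)
  invisible(out)
}

#' Write the deterministic test fixtures
#'
#' Serializes the small positions used by the test-suite and documentation:
#' a 3x3 endgame with exactly one immediately winning move (verified by
#' exhaustive minimax), a position whose next slide strands and removes an
#' opposing figure, a fresh tutorial game and a terminal example.
#'
#' @param dir Output directory.
#' @param seed Seed for the fresh-board fixture.
#' @return Named list of file paths, invisibly.
#' @export
write_fixtures <- function(dir, seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fx <- list(
    forced_win_3x3 = fixture_forced_win_3x3(),
    stranding = fixture_stranding(),
    tutorial_fresh = tutorial_game(seed),
    terminal = fixture_terminal())
  paths <- lapply(names(fx), function(nm) {
    p <- file.path(dir, paste0(nm, ".json"))
    state_to_json(fx[[nm]], p)
    p
  })
  invisible(stats::setNames(paths, names(fx)))
}

#' Built-in fixture positions
#'
#' `fixture_forced_win_3x3()`: participant to move on a nearly-burnt 3x3
#' board where exactly one slide wins the game outright.
#' `fixture_stranding()`: participant to move; sliding down the open lane
#' seals the AI figure's last exit and removes it in the same transition.
#' `fixture_terminal()`: a finished game (participant 5, AI 3).
#'
#' @return An `evo_state`.
#' @export
fixture_forced_win_3x3 <- function() {
  # scores 2-2; one 3-coin tile reachable: taking it ends 5-2 after the AI
  # figure (boxed in by the resulting lava) is removed
  make_state(3, 3, coins = c(1, 1, 3,
                             1, 1, 1,
                             1, 1, 1),
             lava = c(3, 4, 6, 7, 8),
             participant = c(1, 0), ai = c(2, 1),
             scores = c(2, 2), phase = "movement", to_move = "participant")
}

#' @rdname fixture_forced_win_3x3
#' @export
fixture_stranding <- function() {
  # the AI figure at (0,2) has a single exit, (1,2); the participant slide
  # (1,1) -> (1,2) occupies it and turns (1,1) to lava, so the AI figure is
  # removed in the same transition
  make_state(3, 3, coins = 1,
             lava = 3,
             participant = c(1, 1), ai = c(0, 2),
             scores = c(0, 0), phase = "movement", to_move = "participant")
}

#' @rdname fixture_forced_win_3x3
#' @export
fixture_terminal <- function() {
  st <- make_state(3, 3, coins = 1, lava = 0:8, scores = c(5, 3),
                   phase = "terminal")
  st
}

#' Play against the difficulty-controlled AI in the terminal
#'
#' Renders the board as ASCII and reads moves from `input`
#' (`"place col,row"` during placement, `"col,row col,row"` for slides,
#' `"q"` to quit). Intended for interactive use; `input` and `output` are
#' injectable for scripting.
#'
#' @param condition `"easy"`, `"balanced"`, `"hard"` or `"tutorial"`
#'   (4x4 board, one figure per player, AI aims for a draw).
#' @param budget AI iterations per move.
#' @param seed Integer seed (board + AI).
#' @param input,output Connections for the move loop.
#' @return Invisibly, the final (or last reached) state.
#' @export
play_cli <- function(condition = "tutorial", budget = 2000L, seed = 1L,
                     input = stdin(), output = stdout()) {
  reward <- condition_spec(condition)
  st <- if (condition == "tutorial") tutorial_game(seed) else standard_game(seed)
  say <- function(...) writeLines(paste0(...), output)
  seeds <- split_seed(seed, 500, salt = 9L)
  k <- 0L
  say(sprintf("Explorers vs Owls [%s]: you are E; place on 1-coin tiles, slide in straight lines.", condition))
  while (st$phase != 2L) {
    if (st$to_move == 0L) {
      say(paste(utils::capture.output(print(st)), collapse = "\n"))
      say(if (st$phase == 0L) "your placement ('place col,row' or q): "
          else "your move ('fromcol,fromrow tocol,torow' or q): ")
      line <- readLines(input, n = 1)
      if (!length(line) || trimws(line) == "q") {
        say("quit; partial game logged")
        return(invisible(st))
      }
      mv <- tryCatch(parse_cli_move(line, st), error = function(e) NULL)
      if (is.null(mv)) { say("could not parse that move, try again"); next }
      st2 <- tryCatch(apply_move(st, mv), error = function(e) {
        say(conditionMessage(e)); NULL
      })
      if (is.null(st2)) next
      st <- st2
    } else {
      k <- k + 1L
      res <- mcts_search(st, search_config(iterations = budget,
                                           seed = seeds[k]), reward)
      st <- apply_move(st, res$move)
      say("AI moved.")
    }
  }
  out <- game_outcome(st)
  say(sprintf("final: you %d, AI %d -> PWM %+d (%s)", out$participant_score,
              out$ai_score, pwm(out$participant_score, out$ai_score),
              out$result))
  invisible(st)
}

parse_cli_move <- function(line, state) {
  line <- trimws(line)
  nums <- as.integer(regmatches(line, gregexpr("[0-9]+", line))[[1]])
  if (grepl("^place", line)) {
    stopifnot(length(nums) == 2)
    return(move_place(nums))
  }
  stopifnot(length(nums) == 4)
  move_slide(nums[1:2], nums[3:4])
}
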