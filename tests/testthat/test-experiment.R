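# cheap settings for bookkeeping tests: tutorial-sized board, tiny budget
cheap <- function(it = 40) search_config(iterations = it)
cheap_args <- list(board_rows = 4L, board_cols = 4L,
                   coin_counts = c(`1` = 10L, `2` = 4L, `3` = 2L),
                   figures_per_player = 1L)

run_cheap_session <- function(condition = "balanced", games = 2L, seed = 1L,
                              opponent = opponent_spec("random")) {
  do.call(run_session, c(list(condition = condition, opponent = opponent,
                              games = games, seed = seed, config = cheap()),
                         cheap_args))
}

test_that("sessions record per-match PWMs and the improvement measure", {
  s <- run_cheap_session(games = 2, seed = 11)
  expect_equal(nrow(s), 2)
  expect_equal(s$pwm, s$participant_score - s$ai_score)
  expect_equal(pwm_improvement(s), s$pwm[2] - s$pwm[1])
  expect_true(all(s$result == dplyr::case_when(s$pwm > 0 ~ "player_win",
                                               s$pwm < 0 ~ "player_loss",
                                               TRUE ~ "draw")))

  s1 <- run_cheap_session(games = 1, seed = 11)
  expect_equal(pwm_improvement(s1), 0L)
})

test_that("sessions are reproducible from their seed", {
  a <- run_cheap_session(seed = 21)
  b <- run_cheap_session(seed = 21)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  c <- run_cheap_session(seed = 22)
  expect_false(identical(a$match_seed, c$match_seed))
})

run_cheap_study <- function(n = 2, seed = 5, pool = opponent_spec("random"),
                            games = 2L) {
  do.call(run_study, c(list(n_per_condition = n, opponent_pool = pool,
                            games = games, seed = seed, config = cheap()),
                       cheap_args))
}

test_that("studies assign conditions round-robin and reproduce exactly", {
  study <- run_cheap_study(n = 2, seed = 5)
  expect_equal(nrow(study$sessions), 6)
  expect_equal(unname(table(study$sessions$condition)[c("easy", "balanced", "hard")]),
               rep(2L, 3), ignore_attr = TRUE)
  first6 <- study$matches |>
    dplyr::distinct(.data$session, .data$condition) |>
    dplyr::arrange(.data$session)
  expect_equal(first6$condition, rep(c("easy", "balanced", "hard"), 2))

  again <- run_cheap_study(n = 2, seed = 5)
  expect_identical(study$matches, again$matches)

  one_pool <- run_cheap_study(n = 1, seed = 9)
  expect_true(all(one_pool$matches$opponent == "random"))
})

fake_study <- function(pwms_by_cond, games = 1L) {
  # hand-built evo_study for aggregation semantics
  matches <- purrr::imap_dfr(pwms_by_cond, function(pwms, cond) {
    purrr::map_dfr(seq_along(pwms), function(i) {
      tibble::tibble(session = NA_integer_, condition = cond, game_index = 1L,
                     opponent = "scripted", budget = 0L,
                     participant_score = pmax(pwms[i], 0),
                     ai_score = pmax(-pwms[i], 0), pwm = pwms[i],
                     result = ifelse(pwms[i] > 0, "player_win",
                                     ifelse(pwms[i] < 0, "player_loss", "draw")),
                     move_count = 10L, board_seed = i, match_seed = i)
    })
  })
  matches$session <- seq_len(nrow(matches))
  sessions <- matches |>
    dplyr::group_by(.data$session, .data$condition, .data$opponent, .data$budget) |>
    dplyr::summarise(games = 1L, pwm_first = dplyr::first(.data$pwm),
                     pwm_last = dplyr::last(.data$pwm),
                     result_last = dplyr::last(.data$result),
                     .groups = "drop") |>
    dplyr::mutate(pwm_improvement = 0L)
  structure(list(matches = matches, sessions = sessions, seed = 0L,
                 config = search_config(), conditions = names(pwms_by_cond),
                 n_per_condition = 1L),
            class = "evo_study")
}

test_that("summaries report per-condition medians, rates and improvements", {
  study <- fake_study(list(easy = c(18, 20, 16), balanced = c(-1, 0, 1),
                           hard = c(-15, -10, -20)))
  sm <- summarize_study(study)
  expect_equal(sm$condition, c("easy", "balanced", "hard"))
  expect_equal(sm$pwm_median, c(18, 0, -15))
  expect_equal(sm$target_pwm, c(15, 0, -15))
  expect_equal(sm$win_pct, c(100, 100 / 3, 0))
  expect_equal(sm$win_pct + sm$draw_pct + sm$loss_pct, rep(100, 3))

  draws <- fake_study(list(easy = c(0, 0), balanced = c(0, 0), hard = c(0, 0)))
  smd <- summarize_study(draws)
  expect_equal(smd$draw_pct, rep(100, 3))
  expect_equal(smd$pwm_median, rep(0, 3))

  single <- fake_study(list(easy = 5, balanced = 0, hard = -5))
  expect_true(all(is.na(summarize_study(single)$pwm_sd)))
})

test_that("pooled summaries use all matches, last-match summaries only the final one", {
  s1 <- run_cheap_session(games = 2, seed = 31)
  m <- tibble::as_tibble(s1) |>
    dplyr::mutate(session = 1L, session_seed = 31L, .before = 1)
  study <- structure(list(
    matches = m,
    sessions = tibble::tibble(session = 1L, condition = m$condition[1],
                              opponent = "random", budget = 1000L, games = 2L,
                              pwm_first = m$pwm[1], pwm_last = m$pwm[2],
                              result_last = m$result[2],
                              pwm_improvement = m$pwm[2] - m$pwm[1]),
    seed = 31L, config = cheap(), conditions = "balanced",
    n_per_condition = 1L), class = "evo_study")
  last <- summarize_study(study, pool = "last")
  both <- summarize_study(study, pool = "both")
  expect_equal(last$n, 1L)
  expect_equal(both$n, 2L)
  expect_equal(last$pwm_median, m$pwm[2])
  expect_equal(both$pwm_mean, mean(m$pwm))
})

test_that("Kruskal-Wallis H matches manual rank arithmetic and epsilon^2 its formula", {
  groups <- list(c(1, 2), c(3, 4), c(5, 6))
  kw <- kruskal_wallis_epsilon2(groups)
  # manual: ranks 1..6, mean ranks 1.5/3.5/5.5, no ties
  H_hand <- 12 / (6 * 7) * (2 * 1.5^2 + 2 * 3.5^2 + 2 * 5.5^2) - 3 * 7
  expect_equal(kw$H, H_hand)
  expect_equal(kw$df, 2L)
  expect_equal(kw$epsilon_sq, H_hand * 7 / 35)
  expect_equal(kw$n_total, 6L)

  const <- kruskal_wallis_epsilon2(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(const$H, 0)
  expect_equal(const$epsilon_sq, 0)

  expect_error(kruskal_wallis_epsilon2(list(1:3)), "two groups")
  expect_error(kruskal_wallis_epsilon2(list(numeric(0), 1:3)), "empty")
})

test_that("epsilon^2 applied to the published statistic reproduces its effect size", {
  expect_equal(round(epsilon_squared(244, 311), 3), 0.787)
  expect_lt(abs(epsilon_squared(244, 311) - 0.786), 0.002)
})

test_that("Dunn pairwise z-tests match hand arithmetic and Holm ordering", {
  x <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("a", "b", "c"), each = 2)
  d <- dunn_posthoc(x, g)
  sigma2 <- 6 * 7 / 12  # no ties
  z_ab <- (1.5 - 3.5) / sqrt(sigma2 * (1 / 2 + 1 / 2))
  expect_equal(d$z[d$group1 == "a" & d$group2 == "b"], z_ab)
  expect_equal(d$p.value, 2 * pnorm(-abs(d$z)))
  expect_true(all(d$p.adj >= d$p.value))

  # with ties the variance shrinks by the tie term
  xt <- c(1, 1, 2, 2, 3, 4)
  dt_ <- dunn_posthoc(xt, g)
  rk <- rank(xt)
  ties <- table(rk)
  s2 <- 6 * 7 / 12 - sum(ties^3 - ties) / (12 * 5)
  z_ab_t <- (mean(rk[1:2]) - mean(rk[3:4])) / sqrt(s2 * (1 / 2 + 1 / 2))
  expect_equal(dt_$z[dt_$group1 == "a" & dt_$group2 == "b"], z_ab_t)
})

test_that("validate_manipulation bundles the omnibus and pairwise tests", {
  study <- fake_study(list(easy = c(16, 18, 14, 15), balanced = c(0, 1, -1, 2),
                           hard = c(-14, -16, -15, -13)))
  val <- validate_manipulation(study)
  expect_s3_class(val$kw, "evo_kw")
  expect_equal(nrow(val$pairwise), 3)
  expect_lt(val$kw$p, 0.01)
  td <- tidy(val$kw)
  expect_equal(td$statistic, val$kw$H)
  expect_equal(td$epsilon_sq, val$kw$epsilon_sq)
})

test_that("tidy/glance/autoplot expose study results", {
  study <- run_cheap_study(n = 1, seed = 13)
  expect_identical(tidy(study), study$matches)
  gl <- glance(study)
  expect_equal(gl$n_sessions, 3L)
  expect_equal(gl$n_matches, 6L)
  p <- autoplot(study)
  expect_s3_class(p, "ggplot")
  pr <- autoplot(condition_spec("balanced"))
  expect_s3_class(pr, "ggplot")
})
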