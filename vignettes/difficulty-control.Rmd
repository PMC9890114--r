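---
title: "Outcome-sensitive MCTS and difficulty-target validation in explowl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outcome-sensitive MCTS and difficulty-target validation in explowl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`explowl` packages four things: a deterministic rules engine for the
two-player hex-grid game *Explorers vs Owls*, a Monte Carlo Tree Search
(MCTS) opponent whose terminal reward can be pointed at an arbitrary final
score margin, scripted opponents standing in for human players of varying
skill, and a harness that runs the resulting agent-vs-agent "studies" and
tests whether the targeted difficulty was delivered. This vignette explains
the model choices, the tunable parameters, and what the validation does and
does not establish.

```{r setup}
library(explowl)
```

## The rules engine and its conventions

The game is fully deterministic apart from the initial tile shuffle, so
every property of a match is reproducible from its seeds. A few rule details
are under-determined by an informal description of the game, and the engine
fixes them explicitly:

* **Hex convention.** Tiles live on an "odd-r" horizontal offset grid
  (odd rows shifted right), mapped to axial coordinates; the six slide
  directions are the six axial unit vectors. Any single fixed convention
  yields the same game up to relabelling; this one is documented in
  `hex_neighbours()` and used consistently by engine, tests and fixtures.
* **Coin mix.** The standard 7×7 board uses 26 one-coin, 14 two-coin and
  9 three-coin tiles: 49 tiles, 81 coins, so the PWM range is exactly
  −81…81 (a 162-point span) and at least six one-coin tiles exist for the
  placement phase. The 4×4 tutorial board uses 10/4/2.
* **Placements do not score.** A slide scores the destination tile's
  coins; the origin turns to lava. Since a tile can be entered at most once
  (it is occupied while a figure stands on it and lava afterwards), no coin
  is ever scored twice, which gives the conservation law checked by the
  property tests: scores + coins on open unclaimed tiles + coins forfeited
  to lava = 81.
* **Stranding.** After every applied move, a row-major sweep (run to a
  fixed point, both players) removes every figure with no legal slide; the
  figure's tile becomes lava and its uncollected coins are forfeited. The
  alternative reading — a stranded figure scores the coins it stands on —
  would be equally playable; forfeiting is the more conservative choice and
  keeps "score only on arrival by slide" as the single scoring rule.
* **Turn order.** The participant places first and opens the movement
  phase; afterwards turns alternate, skipping a player with no figures
  left. A player whose figures are all removed simply waits while the
  other finishes.

These choices make termination provable: every slide creates at least one
lava tile and lava never reverts, so a game on `r*c` tiles ends within
`r*c + 2*figures` actions. The property suite exercises all of these
invariants over ten thousand seeded random playouts.

## The search and its reward functions

The AI chooses every move with a plain UCT-style MCTS: selection by the
UCB1 *urgency* `mean + c*sqrt(log(N_parent)/N_child)` with unvisited
children first, expansion of one random untried move, one uniform-random
playout to a terminal state, and backpropagation along the path. Defaults:

| parameter | default | meaning |
|---|---|---|
| `iterations` | 7500 | playouts per move decision; 7500 gives a strong opponent on the standard board, the validation study uses 2000 to trade a little tracking accuracy for speed |
| `exploration_constant` | √2 | canonical UCB1 balance between exploitation and exploration |
| `final_selection` | max mean reward | root move choice after the budget; max visits available as an alternative; ties go to higher visits, then seeded random |
| `max_move_score` | 3 coins | the most a single slide can score; also the True POSAS plateau width |
| `span` | 162 | PWM normalization width (−81…81 on the standard board) |

**Rewards.** Standard mode returns 1/0 for an AI win/loss and 0.5 for a
draw — strongest play. The outcome-sensitive (OSAS) mode replaces this with
a graded cone: reward 1 at the target PWM, decaying linearly at `1/span`
per point of distance, floored at 0 so all backed-up values stay in [0, 1].
The *True POSAS* variant widens the maximum to a plateau
`[target, target + 3]`: because the participant moves first, the AI tends
to undershoot a point target, and allowing the player up to one
maximum-value move of extra margin compensates that first-mover advantage.
The cone's exact decay width is a free parameter of the family; decaying
over the full 162-point span is the default because it gives a nonzero
gradient everywhere, so even hopeless playout outcomes still rank.

**Two-player semantics.** Terminal evaluation produces a reward *pair*: the
searching AI's side uses the configured (e.g. True POSAS) reward, the
opponent's side a standard win/draw/loss reward from that player's
perspective. During descent each node is scored with the reward of the
player to move at its parent. The AI therefore models its opponent as
trying to *win*, not as cooperating with the AI's outcome target — the
realistic assumption for human play, and the reason the balanced condition
is a genuine control problem rather than a scripted draw.

**Numerical details.** Mean-reward ties at the root are resolved within
1e-12, then by visit count, then by a seeded draw; the search RNG is an
internal mt19937, so results are independent of (and do not perturb) R's
global RNG state. A terminal root is rejected; a forced move is still
returned through the normal machinery.

## Synthetic players: what they emulate, what they do not

The scripted opponents (`random`, `greedy`, `mcts_standard(budget)`) form a
skill ladder standing in for participants of graded ability: the test suite
verifies that win rate against a random opponent is non-decreasing along
that ladder (200 seeded games per rung on the standard board) and that
greedy beats random in at least 60% of head-to-head games. Participant
heterogeneity can be modelled by sampling each session's opponent from a
configured pool (`sample_opponents()`), e.g. log-spaced MCTS budgets.

These policies emulate *skill variation*, not human play: they have no
learning between games, no fatigue or attention effects, no human error
structure, and no response to perceived difficulty. Consequently the
validation shows that the AI tracks its targets against opponents of a
given stable strength — the engineering claim — and cannot show anything
about human experience, enjoyment or engagement. Human-only measures
(enjoyment questionnaires, perceived agency, play-again rates) are outside
the package's scope and are never simulated.

## The validation study

`run_study()` mirrors the human-study protocol agent-vs-agent: sessions are
assigned round-robin to easy/balanced/hard (target PWM 15/0/−15), each
session plays two matches on freshly shuffled boards, and
`summarize_study()` reports per-condition outcome rows (PWM mean/sd/median,
win/draw/loss rates, PWM improvement = last-match minus first-match PWM).
Outcome statistics use the last full match of each session by default, with
`pool = "both"` to pool both matches — both readings of a per-condition
summary are defensible, so both are provided.

`kruskal_wallis_epsilon2()` runs the omnibus rank test with tie correction
and reports ε² = H(n+1)/(n²−1); this ε² form is used because it is the
standard rank-based effect size for the Kruskal–Wallis statistic and is
self-consistent with the published analyses this harness mirrors. Pairwise
follow-ups use Dunn's z-tests on mean ranks with Holm correction,
implemented in the package (with a manual rank-arithmetic oracle in the
tests) since no Dunn implementation ships with the imported stack. Fully
degenerate data (all values identical) are reported as H = 0, ε² = 0 rather
than the 0/0 of the tie-corrected formula.

**Problem sizes.** The acceptance-level validation runs True POSAS at 2000
iterations per move against the greedy opponent, 30 sessions × 2 games per
condition (180 matches), and requires: per-condition median final PWM
within ±6 of its target, strict easy > balanced > hard ordering,
Kruskal–Wallis p < 0.001, median PWM improvement within ±3 of 0, and a
player win rate of at least 90% in the easy condition. Exact-oracle checks
compare the search's chosen move against brute-force minimax on boards with
at most 10 open tiles and one figure per player at 20 000 iterations, with
an agreement tolerance of 0.05 on the game-theoretic value. The engine
property suite uses 10 000 fully traced random playouts across 50 boards.

## Reproducibility

One master seed fans out to per-session, per-match and per-search sub-seeds
via `split_seed()` (an isolated `set.seed` + `sample.int` scope, restoring
the caller's RNG state), and every seed is logged in the match records, so
any single match can be replayed in isolation. `run_simulation()` writes
the full artifact set (JSONL match log, CSV summaries, JSON test report)
deterministically: rerunning a config reproduces the files byte-for-byte.

## Known limitations

* The cone's decay width and the opponent model are configuration points;
  other choices (narrower decay windows, adaptive opponent models) may
  track targets differently, especially against much stronger or much
  weaker opponents than the scripted pool.
* In a zero-sum game the controller has hard limits: against a player who
  always blunders, an AI aiming to lose can do no worse than a draw, and
  vice versa. Near those boundaries target tracking degrades by necessity.
* The interactive mode (`play_cli()`) is a debugging aid, not an
  experiment-delivery platform; latency-based exclusion rules and
  web deployment are out of scope.
* MCTS strength — and with it tracking accuracy — scales with the
  iteration budget; budgets far below ~1000 on the standard board leave
  the root statistics too noisy for reliable steering.
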