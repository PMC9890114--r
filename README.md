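# explowl

**A difficulty-controlled game AI test suite for *Explorers vs Owls*.**

Experiments on difficulty–skill balance need a way to set the *objective*
difficulty of a task relative to each individual's skill. `explowl`
implements a complete test bench for that problem: a deterministic
two-player hex-grid game, an MCTS opponent whose reward function steers the
final score margin toward an arbitrary target, scripted synthetic players of
graded skill, and an experiment harness that verifies — with Kruskal–Wallis
tests and ε² effect sizes — that the AI actually delivers the targeted
difficulty. It is aimed at researchers in computational behavioural science
and game-AI who want a reproducible dynamic-difficulty-adjustment (DDA)
paradigm, without human participants in the loop.

## The game

*Explorers vs Owls* is played on a 7×7 grid of hexagonal tiles, each holding
1–3 coins (81 coins in total). Players alternately place three figures each
on one-coin tiles (the human/participant side always moves first), then take
turns sliding a figure any distance in a straight unblocked line. The tile a
figure leaves turns to lava forever; the mover scores the destination tile's
coins. A figure with no legal slide is removed (its tile's uncollected coins
are forfeited), and the game ends when all figures are gone. The winner is
the player with more coins.

The central quantity is the **player win margin (PWM)** — participant score
minus AI score — which can range from −81 to +81 (a 162-point span).

## The difficulty-controlled AI

A standard MCTS opponent plays as strongly as possible: its terminal reward
is 1 for an AI win and 0 for a loss. The outcome-sensitive variant (OSAS)
replaces this with a graded reward peaking at a chosen target PWM `t`:

```
reward(pwm) = 1                      if pwm ∈ [t, t + m]   (m = 3, max coins per move)
            = max(0, 1 − d/162)      d = distance to the plateau
```

The plateau shift by `m` (the **True POSAS** variant, a "flattened cone")
compensates the first-mover advantage of the participant. The three study
conditions are `easy` (t = 15), `balanced` (t = 0) and `hard` (t = −15);
the tutorial AI always aims for a draw.

## Worked example

```r
library(explowl)

spec <- condition_spec("balanced")
spec
#> <reward_spec true_posas | target PWM +0 | plateau width 3 | span 162>
reward_true_posas(c(0, 3, -15, 20), spec)
#> [1] 1.0000000 1.0000000 0.9074074 0.8950617
```

A reward of 1 on the plateau `[0, 3]`; 15 points below the target the reward
has decayed to 1 − 15/162 ≈ 0.907.

```r
st <- tutorial_game(seed = 1)   # 4x4 board, one figure per player
st
#> <evo_state 4x4 | placement | to move: participant | score 0-0>
#>  1 1 1 1
#>   2 1 1 2
#>  3 2 2 1
#>   1 1 3 1
mcts_search(st, search_config(iterations = 2000, seed = 1),
            condition_spec("tutorial"))$move
#> <place -> (3,0)>
```

A small end-to-end study — 10 sessions per condition, two games each, a
greedy scripted participant, True POSAS at 2000 iterations per move:

```r
study <- run_study(10, opponent_spec("greedy"), games = 2, seed = 1,
                   config = search_config(iterations = 2000))
summarize_study(study)
#>   condition     n target_pwm pwm_mean pwm_sd pwm_median win_pct draw_pct loss_pct
#> 1 easy         10         15     19    5.21        17.5     100        0        0
#> 2 balanced     10          0      2.1  0.994        2        90       10        0
#> 3 hard         10        -15    -12.8  2.70       -13.5       0        0      100
validate_manipulation(study)$kw
#> Kruskal-Wallis: H(2) = 25.991, p = 2.27e-06, epsilon^2 = 0.896 (n = 30)
```

The achieved median PWMs (17.5 / 2 / −13.5) track the targets (15 / 0 / −15),
every easy game is a player win, every hard game a loss, and the
between-condition difference is significant with a very large ε². `autoplot(study)`
draws the per-condition margins against their targets; `tidy(study)` returns
the per-match records.

A YAML-configured run with JSONL/CSV artifacts, an ASCII interactive mode
and fixture generation are available through `run_simulation()`, `play_cli()`
and `write_fixtures()`, or the CLI front end in `inst/cli/evo.R`:

```sh
Rscript inst/cli/evo.R play --condition tutorial --budget 2000 --seed 1
```

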