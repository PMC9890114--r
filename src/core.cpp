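// Core engine for Explorers vs Owls: hex-grid rules, random playouts,
// MCTS with pluggable terminal rewards (standard / OSAS / True POSAS),
// exact minimax oracle, scripted policies and a full match runner.
//
// Players are indexed 0 (participant / explorers) and 1 (AI / owls).
// Tiles are indexed row-major: idx = row * cols + col, with "odd-r"
// horizontal offset coordinates mapped to axial coordinates for the six
// slide directions. Figure positions: >=0 tile index, -1 unplaced,
// -2 removed.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
#include <limits>
#include <random>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: self-contained mt19937 so results do not depend on R's RNG state.
// ---------------------------------------------------------------------------
struct Rng {
  std::mt19937 gen;
  explicit Rng(uint32_t seed) : gen(seed) {}
  // uniform integer in [0, n)
  int uniform_int(int n) {
    if (n <= 1) return 0;
    uint32_t un = (uint32_t)n;
    uint32_t lim = UINT32_MAX - (UINT32_MAX % un);
    uint32_t x;
    do { x = gen(); } while (x >= lim);
    return (int)(x % un);
  }
  uint32_t next_u32() { return gen(); }
};

// ---------------------------------------------------------------------------
// Game state
// ---------------------------------------------------------------------------
static const int AXIAL_DIR[6][2] = {
  {+1, 0}, {-1, 0}, {0, +1}, {0, -1}, {+1, -1}, {-1, +1}
};

struct Move {
  int kind;  // 0 = place, 1 = slide
  int fig;   // figure id (0-based)
  int from;  // tile index (-1 for placements)
  int to;    // tile index
};

struct GameState {
  int rows, cols, fpp;          // fpp = figures per player
  std::vector<int> coins;       // per tile, immutable
  std::vector<uint8_t> lava;    // per tile
  std::vector<uint8_t> scored;  // per tile: coins already collected
  std::vector<int> fig_owner;   // size 2*fpp; 0 or 1
  std::vector<int> fig_pos;     // size 2*fpp
  std::vector<int> occupant;    // per tile: figure id or -1
  int scores[2];
  int phase;                    // 0 placement, 1 movement, 2 terminal
  int to_move;                  // 0 or 1
  int placed[2];                // placements made so far

  int n_tiles() const { return rows * cols; }

  // odd-r offset neighbour in axial direction d; returns -1 if off-board
  int neighbour(int idx, int d) const {
    int col = idx % cols, row = idx / cols;
    int q = col - (row - (row & 1)) / 2;
    int r = row;
    q += AXIAL_DIR[d][0];
    r += AXIAL_DIR[d][1];
    if (r < 0 || r >= rows) return -1;
    int ncol = q + (r - (r & 1)) / 2;
    if (ncol < 0 || ncol >= cols) return -1;
    return r * cols + ncol;
  }

  bool tile_open_free(int idx) const {
    return idx >= 0 && !lava[idx] && occupant[idx] < 0;
  }

  // a figure on tile idx can slide somewhere
  bool mobile(int idx) const {
    for (int d = 0; d < 6; ++d)
      if (tile_open_free(neighbour(idx, d))) return true;
    return false;
  }

  int alive_count(int player) const {
    int k = 0;
    for (size_t f = 0; f < fig_pos.size(); ++f)
      if (fig_owner[f] == player && fig_pos[f] >= 0) ++k;
    return k;
  }

  int first_unplaced(int player) const {
    for (size_t f = 0; f < fig_pos.size(); ++f)
      if (fig_owner[f] == player && fig_pos[f] == -1) return (int)f;
    return -1;
  }

  void placements(std::vector<int> &out) const {
    out.clear();
    int n = n_tiles();
    for (int t = 0; t < n; ++t)
      if (!lava[t] && occupant[t] < 0 && coins[t] == 1) out.push_back(t);
  }

  void slides_for_figure(int f, std::vector<Move> &out) const {
    int from = fig_pos[f];
    if (from < 0) return;
    for (int d = 0; d < 6; ++d) {
      int cur = neighbour(from, d);
      while (cur >= 0 && !lava[cur] && occupant[cur] < 0) {
        out.push_back(Move{1, f, from, cur});
        cur = neighbour(cur, d);
      }
    }
  }

  void slides(int player, std::vector<Move> &out) const {
    out.clear();
    for (size_t f = 0; f < fig_pos.size(); ++f)
      if (fig_owner[f] == player && fig_pos[f] >= 0)
        slides_for_figure((int)f, out);
  }

  // all actions available to to_move (placements in phase 0, slides in 1);
  // placements use the player's first unplaced figure (figures are fungible)
  void actions(std::vector<Move> &out) const {
    out.clear();
    if (phase == 0) {
      int f = first_unplaced(to_move);
      std::vector<int> pl;
      placements(pl);
      for (int t : pl) out.push_back(Move{0, f, -1, t});
    } else if (phase == 1) {
      slides(to_move, out);
    }
  }

  // stranding sweep: remove (both players, row-major scan, to fixed point)
  // every alive figure with no legal slide; its tile turns to lava and any
  // uncollected coins on it are forfeited.
  void sweep() {
    bool changed = true;
    int n = n_tiles();
    while (changed) {
      changed = false;
      for (int t = 0; t < n; ++t) {
        int f = occupant[t];
        if (f >= 0 && !mobile(t)) {
          occupant[t] = -1;
          lava[t] = 1;
          fig_pos[f] = -2;
          changed = true;
        }
      }
    }
  }

  // turn hand-over after a move; the placement->movement flip (participant
  // opens the movement phase) is handled in apply()
  void advance_turn(int mover) {
    if (phase == 1 && alive_count(0) + alive_count(1) == 0) {
      phase = 2;
      return;
    }
    if (phase == 0) {
      int other = 1 - mover;
      to_move = (placed[other] < fpp) ? other : mover;
    } else {
      // alternate, skipping a player with no alive figures
      int other = 1 - mover;
      to_move = (alive_count(other) > 0) ? other : mover;
    }
  }

  int lava_count() const {
    int k = 0;
    for (uint8_t v : lava) k += v;
    return k;
  }
  int count_removed() const {
    int k = 0;
    for (int p : fig_pos) k += (p == -2);
    return k;
  }

  // apply a move assumed legal; legality is checked by callers
  void apply(const Move &m) {
    if (m.kind == 0) {
      occupant[m.to] = m.fig;
      fig_pos[m.fig] = m.to;
      placed[fig_owner[m.fig]] += 1;
      int mover = to_move;
      sweep();
      // phase flip to movement happens inside advance_turn; participant
      // opens the movement phase
      if (placed[0] + placed[1] >= 2 * fpp) {
        phase = 1;
        if (alive_count(0) + alive_count(1) == 0) { phase = 2; return; }
        to_move = alive_count(0) > 0 ? 0 : 1;
        return;
      }
      advance_turn(mover);
    } else {
      int owner = fig_owner[m.fig];
      occupant[m.from] = -1;
      lava[m.from] = 1;
      occupant[m.to] = m.fig;
      fig_pos[m.fig] = m.to;
      if (!scored[m.to]) { scores[owner] += coins[m.to]; scored[m.to] = 1; }
      int mover = to_move;
      sweep();
      advance_turn(mover);
    }
  }

  bool legal(const Move &m, std::string &why) const {
    if (phase == 2) { why = "game is over (terminal state)"; return false; }
    if (m.fig < 0 || m.fig >= (int)fig_pos.size()) { why = "unknown figure"; return false; }
    if (fig_owner[m.fig] != to_move) { why = "figure does not belong to the player to move"; return false; }
    if (m.kind == 0) {
      if (phase != 0) { why = "placements are only legal in the placement phase"; return false; }
      if (fig_pos[m.fig] != -1) { why = "figure already placed"; return false; }
      if (m.to < 0 || m.to >= n_tiles()) { why = "placement target off the board"; return false; }
      if (lava[m.to]) { why = "placement target is lava"; return false; }
      if (occupant[m.to] >= 0) { why = "placement target is occupied"; return false; }
      if (coins[m.to] != 1) { why = "placements are only legal on one-coin tiles"; return false; }
      return true;
    }
    if (phase != 1) { why = "slides are only legal in the movement phase"; return false; }
    if (fig_pos[m.fig] < 0) { why = "figure is not on the board"; return false; }
    if (fig_pos[m.fig] != m.from) { why = "slide origin does not match the figure's position"; return false; }
    std::vector<Move> sl;
    slides_for_figure(m.fig, sl);
    for (const Move &s : sl)
      if (s.to == m.to) return true;
    why = "destination is not reachable in a straight unblocked line of open tiles";
    return false;
  }
};

// ---------------------------------------------------------------------------
// R <-> C++ state conversion
// ---------------------------------------------------------------------------
static GameState state_from_list(const List &st) {
  GameState s;
  s.rows = as<int>(st["rows"]);
  s.cols = as<int>(st["cols"]);
  s.fpp = as<int>(st["fpp"]);
  s.coins = as<std::vector<int>>(st["coins"]);
  IntegerVector lv = st["lava"], sc = st["scored"];
  s.lava.assign(lv.begin(), lv.end());
  s.scored.assign(sc.begin(), sc.end());
  s.fig_owner = as<std::vector<int>>(st["fig_owner"]);
  s.fig_pos = as<std::vector<int>>(st["fig_pos"]);
  IntegerVector scv = st["scores"];
  s.scores[0] = scv[0];
  s.scores[1] = scv[1];
  s.phase = as<int>(st["phase"]);
  s.to_move = as<int>(st["to_move"]);
  IntegerVector pl = st["placed"];
  s.placed[0] = pl[0];
  s.placed[1] = pl[1];
  int n = s.rows * s.cols;
  if ((int)s.coins.size() != n) stop("state: coins length != rows*cols");
  s.occupant.assign(n, -1);
  for (size_t f = 0; f < s.fig_pos.size(); ++f)
    if (s.fig_pos[f] >= 0) {
      if (s.fig_pos[f] >= n) stop("state: figure position off the board");
      if (s.occupant[s.fig_pos[f]] >= 0) stop("state: two figures on one tile");
      s.occupant[s.fig_pos[f]] = (int)f;
    }
  return s;
}

static List state_to_list(const GameState &s) {
  return List::create(
    _["rows"] = s.rows, _["cols"] = s.cols, _["fpp"] = s.fpp,
    _["coins"] = IntegerVector(s.coins.begin(), s.coins.end()),
    _["lava"] = IntegerVector(s.lava.begin(), s.lava.end()),
    _["scored"] = IntegerVector(s.scored.begin(), s.scored.end()),
    _["fig_owner"] = IntegerVector(s.fig_owner.begin(), s.fig_owner.end()),
    _["fig_pos"] = IntegerVector(s.fig_pos.begin(), s.fig_pos.end()),
    _["scores"] = IntegerVector::create(s.scores[0], s.scores[1]),
    _["phase"] = s.phase, _["to_move"] = s.to_move,
    _["placed"] = IntegerVector::create(s.placed[0], s.placed[1]));
}

static List move_to_list(const Move &m) {
  return List::create(_["kind"] = m.kind, _["fig"] = m.fig,
                      _["from"] = m.from, _["to"] = m.to);
}

// ---------------------------------------------------------------------------
// Terminal rewards
// ---------------------------------------------------------------------------
// standard win/draw/loss reward from player p's perspective
static double reward_std(const GameState &s, int p, double draw_reward) {
  int d = s.scores[p] - s.scores[1 - p];
  if (d > 0) return 1.0;
  if (d < 0) return 0.0;
  return draw_reward;
}

// graded OSAS / True POSAS reward on pwm = participant - AI score.
// mode 1 = osas (apex at target), mode 2 = true_posas (plateau
// [target, target + max_move_score]).
static double reward_cone(int pwm, int mode, int target, int max_move_score,
                          int span) {
  int lo = target;
  int hi = target + (mode == 2 ? max_move_score : 0);
  int d = 0;
  if (pwm < lo) d = lo - pwm;
  else if (pwm > hi) d = pwm - hi;
  double r = 1.0 - (double)d / (double)span;
  return r < 0.0 ? 0.0 : r;
}

// per-player terminal reward pair; `searcher` uses the configured spec,
// the other player a standard win/draw/loss opponent model
static void reward_pair(const GameState &s, int searcher, int mode, int target,
                        int max_move_score, int span, double draw_reward,
                        double out[2]) {
  int other = 1 - searcher;
  if (mode == 0) out[searcher] = reward_std(s, searcher, draw_reward);
  else out[searcher] = reward_cone(s.scores[0] - s.scores[1], mode, target,
                                   max_move_score, span);
  out[other] = reward_std(s, other, 0.5);
}

// ---------------------------------------------------------------------------
// Exported engine primitives
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_shuffled_coins(int rows, int cols, IntegerVector values,
                                 IntegerVector counts, int seed) {
  int n = rows * cols;
  std::vector<int> coins;
  coins.reserve(n);
  for (int i = 0; i < values.size(); ++i)
    for (int k = 0; k < counts[i]; ++k) coins.push_back(values[i]);
  if ((int)coins.size() != n) stop("coin counts must sum to rows*cols");
  Rng rng((uint32_t)seed);
  for (int i = n - 1; i > 0; --i) {
    int j = rng.uniform_int(i + 1);
    std::swap(coins[i], coins[j]);
  }
  return IntegerVector(coins.begin(), coins.end());
}

// [[Rcpp::export]]
IntegerVector cpp_legal_placements(List state) {
  GameState s = state_from_list(state);
  if (s.phase != 0) stop("legal_placements: state is not in the placement phase");
  std::vector<int> pl;
  s.placements(pl);
  return IntegerVector(pl.begin(), pl.end());
}

// [[Rcpp::export]]
IntegerMatrix cpp_legal_slides(List state, int player) {
  GameState s = state_from_list(state);
  if (s.phase != 1) stop("legal_moves: state is not in the movement phase");
  std::vector<Move> mv;
  s.slides(player, mv);
  IntegerMatrix out(mv.size(), 3);
  for (size_t i = 0; i < mv.size(); ++i) {
    out(i, 0) = mv[i].fig;
    out(i, 1) = mv[i].from;
    out(i, 2) = mv[i].to;
  }
  colnames(out) = CharacterVector::create("fig", "from", "to");
  return out;
}

// [[Rcpp::export]]
List cpp_apply_move(List state, int kind, int fig, int from, int to) {
  GameState s = state_from_list(state);
  if (s.phase == 2) stop("apply_move: game is over (terminal state)");
  Move m{kind, fig, from, to};
  std::string why;
  if (!s.legal(m, why)) stop("illegal move: " + why);
  s.apply(m);
  return state_to_list(s);
}

// [[Rcpp::export]]
int cpp_neighbour(List state, int idx, int dir) {
  GameState s = state_from_list(state);
  return s.neighbour(idx, dir);
}

// Random playout to a terminal state, recording per-action traces used by
// the engine-invariant property tests.
// [[Rcpp::export]]
List cpp_random_playout(List state, int seed, bool trace = false) {
  GameState s = state_from_list(state);
  Rng rng((uint32_t)seed);
  std::vector<Move> acts;
  std::vector<int> lava_trace, p_trace, a_trace, open_coins_trace;
  int total = 0;
  for (int c : s.coins) total += c;
  auto record = [&]() {
    if (!trace) return;
    lava_trace.push_back(s.lava_count());
    p_trace.push_back(s.scores[0]);
    a_trace.push_back(s.scores[1]);
    int oc = 0;
    for (int t = 0; t < s.n_tiles(); ++t)
      if (!s.scored[t] && !s.lava[t]) oc += s.coins[t];
    open_coins_trace.push_back(oc);
  };
  record();
  int moves = 0, bound = s.n_tiles() + 2 * s.fpp + 1;
  bool conserved = true;
  while (s.phase != 2) {
    if (moves > bound) stop("playout exceeded the termination bound");
    s.actions(acts);
    if (acts.empty()) stop("non-terminal state with no legal actions");
    s.apply(acts[rng.uniform_int((int)acts.size())]);
    ++moves;
    if (trace) {
      int forf = 0;
      for (int t = 0; t < s.n_tiles(); ++t)
        if (s.lava[t] && !s.scored[t]) forf += s.coins[t];
      int oc = 0;
      for (int t = 0; t < s.n_tiles(); ++t)
        if (!s.lava[t] && !s.scored[t]) oc += s.coins[t];
      if (s.scores[0] + s.scores[1] + oc + forf != total) conserved = false;
      record();
    }
  }
  List out = List::create(
    _["state"] = state_to_list(s), _["moves"] = moves,
    _["pwm"] = s.scores[0] - s.scores[1], _["conserved"] = conserved);
  if (trace) {
    out["lava_trace"] = IntegerVector(lava_trace.begin(), lava_trace.end());
    out["p_trace"] = IntegerVector(p_trace.begin(), p_trace.end());
    out["a_trace"] = IntegerVector(a_trace.begin(), a_trace.end());
  }
  return out;
}

// ---------------------------------------------------------------------------
// MCTS
// ---------------------------------------------------------------------------
struct Node {
  GameState state;
  Move move;           // incoming move
  int parent;
  std::vector<int> children;
  std::vector<Move> untried;
  int visits;
  double reward[2];
};

struct Mcts {
  std::vector<Node> nodes;
  int searcher, mode, target, max_move_score, span;
  double cexp, draw_reward;
  Rng rng;

  Mcts(const GameState &root_state, int mode_, int target_, int mms, int span_,
       double draw_reward_, double cexp_, uint32_t seed)
      : searcher(root_state.to_move), mode(mode_), target(target_),
        max_move_score(mms), span(span_), cexp(cexp_),
        draw_reward(draw_reward_), rng(seed) {
    Node root;
    root.state = root_state;
    root.move = Move{-1, -1, -1, -1};
    root.parent = -1;
    root.visits = 0;
    root.reward[0] = root.reward[1] = 0.0;
    root.state.actions(root.untried);
    nodes.push_back(std::move(root));
  }

  double urgency(const Node &child, const Node &parent) const {
    if (child.visits == 0) return std::numeric_limits<double>::infinity();
    int pl = parent.state.to_move;
    double mean = child.reward[pl] / child.visits;
    return mean + cexp * std::sqrt(std::log((double)parent.visits) /
                                   (double)child.visits);
  }

  void iterate() {
    int ni = 0;
    // selection
    while (nodes[ni].untried.empty() && !nodes[ni].children.empty()) {
      const Node &nd = nodes[ni];
      double best = -1.0;
      int pick = -1;
      for (int ci : nd.children) {
        double u = urgency(nodes[ci], nd);
        if (u > best) { best = u; pick = ci; }
      }
      ni = pick;
    }
    // expansion
    if (nodes[ni].state.phase != 2 && !nodes[ni].untried.empty()) {
      int k = rng.uniform_int((int)nodes[ni].untried.size());
      Move m = nodes[ni].untried[k];
      nodes[ni].untried.erase(nodes[ni].untried.begin() + k);
      Node child;
      child.state = nodes[ni].state;
      child.state.apply(m);
      child.move = m;
      child.parent = ni;
      child.visits = 0;
      child.reward[0] = child.reward[1] = 0.0;
      child.state.actions(child.untried);
      nodes.push_back(std::move(child));
      int ci = (int)nodes.size() - 1;
      nodes[ni].children.push_back(ci);
      ni = ci;
    }
    // simulation
    GameState sim = nodes[ni].state;
    std::vector<Move> acts;
    while (sim.phase != 2) {
      sim.actions(acts);
      sim.apply(acts[rng.uniform_int((int)acts.size())]);
    }
    double r[2];
    reward_pair(sim, searcher, mode, target, max_move_score, span, draw_reward, r);
    // backpropagation
    while (ni >= 0) {
      nodes[ni].visits += 1;
      nodes[ni].reward[0] += r[0];
      nodes[ni].reward[1] += r[1];
      ni = nodes[ni].parent;
    }
  }

  // best root child under the configured final-selection criterion
  int best_child(int final_sel) {
    const Node &root = nodes[0];
    std::vector<int> cand;
    double best = -1.0;
    const double eps = 1e-12;
    for (int ci : root.children) {
      const Node &c = nodes[ci];
      double crit = (final_sel == 1)
                        ? (double)c.visits
                        : (c.visits > 0 ? c.reward[searcher] / c.visits : -1.0);
      if (crit > best + eps) { best = crit; cand.clear(); cand.push_back(ci); }
      else if (crit >= best - eps) cand.push_back(ci);
    }
    if (cand.size() > 1) {  // ties: higher visits, then seeded random
      int bv = -1;
      std::vector<int> cand2;
      for (int ci : cand) {
        if (nodes[ci].visits > bv) { bv = nodes[ci].visits; cand2.clear(); }
        if (nodes[ci].visits == bv) cand2.push_back(ci);
      }
      cand = cand2;
    }
    return cand[rng.uniform_int((int)cand.size())];
  }
};

static Move run_mcts(const GameState &s, int iterations, double cexp,
                     uint32_t seed, int mode, int target, int max_move_score,
                     int span, double draw_reward, int final_sel) {
  Mcts m(s, mode, target, max_move_score, span, draw_reward, cexp, seed);
  std::vector<Move> acts;
  s.actions(acts);
  if (acts.empty()) stop("search: no legal moves");
  for (int i = 0; i < iterations; ++i) m.iterate();
  return m.nodes[m.best_child(final_sel)].move;
}

// [[Rcpp::export]]
List cpp_mcts_search(List state, int iterations, double cexp, int seed,
                     int mode, int target, int max_move_score, int span,
                     double draw_reward, int final_sel,
                     bool return_children = false, bool return_tree = false) {
  GameState s = state_from_list(state);
  if (s.phase == 2) stop("search: terminal state");
  std::vector<Move> acts;
  s.actions(acts);
  if (acts.empty()) stop("search: no legal moves");
  Mcts m(s, mode, target, max_move_score, span, draw_reward, cexp,
         (uint32_t)seed);
  for (int i = 0; i < iterations; ++i) m.iterate();
  int bi = m.best_child(final_sel);
  List out = List::create(
    _["move"] = move_to_list(m.nodes[bi].move),
    _["iterations"] = iterations,
    _["root_visits"] = m.nodes[0].visits,
    _["n_nodes"] = (int)m.nodes.size(),
    _["searcher"] = m.searcher);
  if (return_children) {
    const Node &root = m.nodes[0];
    int k = (int)root.children.size();
    IntegerVector kind(k), fig(k), from(k), to(k), visits(k);
    NumericVector mean_searcher(k), mean_opponent(k);
    for (int i = 0; i < k; ++i) {
      const Node &c = m.nodes[root.children[i]];
      kind[i] = c.move.kind; fig[i] = c.move.fig;
      from[i] = c.move.from; to[i] = c.move.to;
      visits[i] = c.visits;
      mean_searcher[i] = c.visits ? c.reward[m.searcher] / c.visits : NA_REAL;
      mean_opponent[i] = c.visits ? c.reward[1 - m.searcher] / c.visits : NA_REAL;
    }
    out["children"] = DataFrame::create(
      _["kind"] = kind, _["fig"] = fig, _["from"] = from, _["to"] = to,
      _["visits"] = visits, _["mean_searcher"] = mean_searcher,
      _["mean_opponent"] = mean_opponent);
  }
  if (return_tree) {
    int k = (int)m.nodes.size();
    IntegerVector parent(k), kind(k), fig(k), from(k), to(k), visits(k),
        player(k);
    NumericVector r0(k), r1(k);
    for (int i = 0; i < k; ++i) {
      const Node &c = m.nodes[i];
      parent[i] = c.parent; kind[i] = c.move.kind; fig[i] = c.move.fig;
      from[i] = c.move.from; to[i] = c.move.to; visits[i] = c.visits;
      player[i] = c.state.to_move;
      r0[i] = c.reward[0]; r1[i] = c.reward[1];
    }
    out["tree"] = DataFrame::create(
      _["parent"] = parent, _["kind"] = kind, _["fig"] = fig,
      _["from"] = from, _["to"] = to, _["visits"] = visits,
      _["player_to_move"] = player, _["reward_participant"] = r0,
      _["reward_ai"] = r1);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Exact minimax oracle (standard win/draw/loss reward for `searcher`;
// the opponent minimizes it). Only tractable on tiny boards.
// ---------------------------------------------------------------------------
static double minimax_value(const GameState &s, int searcher, long &visited) {
  if (++visited > 50000000L) stop("minimax: game tree too large");
  if (s.phase == 2) return reward_std(s, searcher, 0.5);
  std::vector<Move> acts;
  s.actions(acts);
  bool maxing = (s.to_move == searcher);
  double best = maxing ? -1.0 : 2.0;
  for (const Move &m : acts) {
    GameState child = s;
    child.apply(m);
    double v = minimax_value(child, searcher, visited);
    if (maxing ? (v > best) : (v < best)) best = v;
  }
  return best;
}

// [[Rcpp::export]]
List cpp_minimax(List state, int searcher = -1) {
  GameState s = state_from_list(state);
  if (searcher < 0) searcher = s.to_move;
  if (s.phase == 2)
    return List::create(_["value"] = reward_std(s, searcher, 0.5),
                        _["move"] = R_NilValue);
  std::vector<Move> acts;
  s.actions(acts);
  long visited = 0;
  double best = -2.0;
  Move bm{-1, -1, -1, -1};
  bool maxing = (s.to_move == searcher);
  best = maxing ? -1.0 : 2.0;
  for (const Move &m : acts) {
    GameState child = s;
    child.apply(m);
    double v = minimax_value(child, searcher, visited);
    if (maxing ? (v > best) : (v < best)) { best = v; bm = m; }
  }
  return List::create(_["value"] = best, _["move"] = move_to_list(bm),
                      _["nodes_visited"] = (double)visited);
}

// [[Rcpp::export]]
double cpp_minimax_value(List state, int searcher) {
  GameState s = state_from_list(state);
  long visited = 0;
  return minimax_value(s, searcher, visited);
}

// ---------------------------------------------------------------------------
// Scripted policies and full-match runner
// ---------------------------------------------------------------------------
// policy: 0 random, 1 greedy (max destination coins; placements uniform),
// 2 mcts_standard (standard reward at `budget` iterations)
static Move policy_move(const GameState &s, int policy, int budget,
                        double cexp, Rng &rng) {
  std::vector<Move> acts;
  s.actions(acts);
  if (acts.empty()) stop("policy: no legal actions");
  if (policy == 0 || s.phase == 0) {
    if (policy == 2 && s.phase == 0) {
      // mcts_standard also searches its placements
      return run_mcts(s, budget, cexp, rng.next_u32(), 0, 0, 3, 162, 0.5, 0);
    }
    return acts[rng.uniform_int((int)acts.size())];
  }
  if (policy == 1) {
    int best = -1;
    std::vector<Move> cand;
    for (const Move &m : acts) {
      int c = s.coins[m.to];
      if (c > best) { best = c; cand.clear(); }
      if (c == best) cand.push_back(m);
    }
    return cand[rng.uniform_int((int)cand.size())];
  }
  return run_mcts(s, budget, cexp, rng.next_u32(), 0, 0, 3, 162, 0.5, 0);
}

// [[Rcpp::export]]
List cpp_policy_move(List state, int policy, int budget, double cexp,
                     int seed) {
  GameState s = state_from_list(state);
  if (s.phase == 2) stop("policy: terminal state");
  Rng rng((uint32_t)seed);
  return move_to_list(policy_move(s, policy, budget, cexp, rng));
}

// Play one full match from a fresh (or given) state: participant (player 0)
// follows the scripted policy, the AI (player 1) runs MCTS with the given
// reward spec — or, when ai_policy >= 0, a scripted policy too (head-to-head
// ladder games). Returns final scores, PWM and the move list.
// [[Rcpp::export]]
List cpp_play_match(List state, int mode, int target, int max_move_score,
                    int span, double draw_reward, int ai_iterations,
                    double cexp, int final_sel, int opp_policy, int opp_budget,
                    int seed, bool record_moves = false, int ai_policy = -1) {
  GameState s = state_from_list(state);
  Rng rng((uint32_t)seed);
  int bound = s.n_tiles() + 2 * s.fpp + 1, moves = 0;
  std::vector<Move> hist;
  while (s.phase != 2) {
    if (moves > bound) stop("match exceeded the termination bound");
    Move m;
    if (s.to_move == 0) {
      m = policy_move(s, opp_policy, opp_budget, cexp, rng);
    } else if (ai_policy >= 0) {
      m = policy_move(s, ai_policy, ai_iterations, cexp, rng);
    } else {
      m = run_mcts(s, ai_iterations, cexp, rng.next_u32(), mode, target,
                   max_move_score, span, draw_reward, final_sel);
    }
    s.apply(m);
    if (record_moves) hist.push_back(m);
    ++moves;
  }
  List out = List::create(
    _["participant_score"] = s.scores[0], _["ai_score"] = s.scores[1],
    _["pwm"] = s.scores[0] - s.scores[1], _["move_count"] = moves,
    _["state"] = state_to_list(s));
  if (record_moves) {
    int k = (int)hist.size();
    IntegerVector kind(k), fig(k), from(k), to(k);
    for (int i = 0; i < k; ++i) {
      kind[i] = hist[i].kind; fig[i] = hist[i].fig;
      from[i] = hist[i].from; to[i] = hist[i].to;
    }
    out["moves"] = DataFrame::create(_["kind"] = kind, _["fig"] = fig,
                                     _["from"] = from, _["to"] = to);
  }
  return out;
}
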