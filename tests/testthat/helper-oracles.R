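# Independent oracles, implemented from first principles so they share no
# code with the engine's move generator or search.

# Cube-coordinate hex stepping ("odd-r" offset -> cube), independent of the
# package's axial helpers.
oracle_cube <- function(col, row) {
  x <- col - (row - row %% 2) / 2
  z <- row
  c(x = x, y = -x - z, z = z)
}
oracle_offset <- function(x, z) c(col = x + (z - z %% 2) / 2, row = z)
ORACLE_CUBE_DIRS <- list(c(1, -1, 0), c(-1, 1, 0), c(0, -1, 1),
                         c(0, 1, -1), c(1, 0, -1), c(-1, 0, 1))

# every destination reachable from (col,row) by a straight unblocked slide,
# by brute-force stepping over all 6 directions and all distances
oracle_slide_destinations <- function(state, col, row) {
  occ <- state$fig_pos[state$fig_pos >= 0]
  blocked <- function(idx) state$lava[idx + 1] == 1 || idx %in% occ
  start <- oracle_cube(col, row)
  out <- list()
  for (d in ORACLE_CUBE_DIRS) {
    cur <- start
    repeat {
      cur <- cur + c(d[1], d[2], d[3])
      off <- oracle_offset(cur[["x"]], cur[["z"]])
      if (off[["row"]] < 0 || off[["row"]] >= state$rows ||
          off[["col"]] < 0 || off[["col"]] >= state$cols) break
      idx <- off[["row"]] * state$cols + off[["col"]]
      if (blocked(idx)) break
      out[[length(out) + 1]] <- off
    }
  }
  if (!length(out)) return(tibble::tibble(col = integer(0), row = integer(0)))
  df <- do.call(rbind, out)
  tibble::tibble(col = as.integer(df[, "col"]), row = as.integer(df[, "row"]))
}

# exhaustive game-tree value of the standard win/draw/loss reward for
# `searcher`, built purely on the package's public rules API (independent of
# the C++ search and of cpp_minimax)
oracle_minimax <- function(state, searcher = state$to_move) {
  if (state$phase == 2L) {
    out <- game_outcome(state)
    d <- if (searcher == 0L) out$participant_score - out$ai_score
         else out$ai_score - out$participant_score
    return(if (d > 0) 1 else if (d < 0) 0 else 0.5)
  }
  moves <- if (state$phase == 0L) legal_placements(state) else legal_moves(state)
  vals <- vapply(seq_len(nrow(moves)), function(i) {
    oracle_minimax(apply_move(state, moves[i, ]), searcher)
  }, numeric(1))
  if (state$to_move == searcher) max(vals) else min(vals)
}

sorted_coords <- function(df) dplyr::arrange(df, col, row)
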