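#' Default coin distributions
#'
#' The standard 7x7 board holds 81 coins (26 one-coin, 14 two-coin and 9
#' three-coin tiles), so the theoretical PWM range spans 162 points, from
#' -81 to 81. The 4x4 tutorial board holds 20 coins (10/4/2).
#'
#' @return A named integer vector mapping coin value to tile count.
#' @examples
#' sum(as.integer(names(standard_coin_counts())) * standard_coin_counts())
#' @export
standard_coin_counts <- function() c(`1` = 26L, `2` = 14L, `3` = 9L)

#' @rdname standard_coin_counts
#' @export
tutorial_coin_counts <- function() c(`1` = 10L, `2` = 4L, `3` = 2L)

#' Generate a random game board
#'
#' Builds a `rows` x `cols` hexagonal board whose multiset of per-tile coin
#' values matches `coin_counts`, shuffled by a seeded generator. The same
#' seed always yields the identical board. Tiles use the "odd-r" horizontal
#' offset layout (odd rows shifted right); see [hex_neighbours()].
#'
#' @param rows,cols Grid dimensions.
#' @param coin_counts Named integer vector mapping coin value (subset of
#'   1,2,3) to tile count; counts must sum to `rows * cols`.
#' @param seed Integer seed for the tile shuffle.
#' @param figures_per_player Number of figures each player will place;
#'   the board must offer at least `2 * figures_per_player` one-coin tiles.
#' @return An object of class `evo_board`: a list with `rows`, `cols`,
#'   `coins` (row-major integer vector), `total_coins` and `seed`.
#' @examples
#' b <- generate_board(7, 7, standard_coin_counts(), seed = 42)
#' b$total_coins  # 81
#' @export
generate_board <- function(rows, cols, coin_counts = standard_coin_counts(),
                           seed = 1L, figures_per_player = 3L) {
  stopifnot(rows >= 1, cols >= 1)
  values <- as.integer(names(coin_counts))
  counts <- as.integer(coin_counts)
  if (anyNA(values) || !all(values %in% 1:3))
    stop("coin values must be a subset of {1, 2, 3}", call. = FALSE)
  if (sum(counts) != rows * cols)
    stop("coin_counts must sum to rows * cols (", rows * cols, " tiles, got ",
         sum(counts), ")", call. = FALSE)
  ones <- sum(counts[values == 1L])
  if (ones < 2L * figures_per_player)
    stop("board needs at least ", 2L * figures_per_player,
         " one-coin tiles for placement, got ", ones, call. = FALSE)
  coins <- cpp_shuffled_coins(rows, cols, values, counts, as.integer(seed))
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols), coins = coins,
         coin_counts = stats::setNames(counts, values),
         total_coins = sum(coins), seed = as.integer(seed)),
    class = "evo_board")
}

#' @export
print.evo_board <- function(x, ...) {
  cat(sprintf("<evo_board %dx%d, %d coins, seed %d>\n",
              x$rows, x$cols, x$total_coins, x$seed))
  invisible(x)
}

#' Hexagonal coordinate helpers
#'
#' Tiles live on an "odd-r" horizontal offset grid: `(col, row)` with both
#' indices 0-based and odd rows displaced half a tile to the right. The six
#' slide directions are the six axial unit vectors. `offset_to_axial()` and
#' `axial_to_offset()` convert between the two conventions;
#' `hex_neighbours()` lists the on-board neighbours of a tile.
#'
#' @param col,row 0-based offset coordinates.
#' @param q,r Axial coordinates.
#' @param rows,cols Board dimensions (for bounds checking).
#' @return `offset_to_axial()` / `axial_to_offset()`: named integer vectors.
#'   `hex_neighbours()`: a tibble with columns `col`, `row`.
#' @examples
#' offset_to_axial(3, 2)
#' hex_neighbours(0, 0, rows = 4, cols = 4)
#' @export
offset_to_axial <- function(col, row) {
  c(q = as.integer(col - (row - row %% 2) %/% 2), r = as.integer(row))
}

#' @rdname offset_to_axial
#' @export
axial_to_offset <- function(q, r) {
  c(col = as.integer(q + (r - r %% 2) %/% 2), row = as.integer(r))
}

# the six axial unit vectors (dq, dr)
AXIAL_DIRECTIONS <- matrix(
  c(1L, 0L, -1L, 0L, 0L, 1L, 0L, -1L, 1L, -1L, -1L, 1L),
  ncol = 2, byrow = TRUE, dimnames = list(NULL, c("dq", "dr")))

#' @rdname offset_to_axial
#' @export
hex_neighbours <- function(col, row, rows, cols) {
  ax <- offset_to_axial(col, row)
  out <- lapply(seq_len(6), function(d) {
    q <- ax[["q"]] + AXIAL_DIRECTIONS[d, "dq"]
    r <- ax[["r"]] + AXIAL_DIRECTIONS[d, "dr"]
    if (r < 0 || r >= rows) return(NULL)
    off <- axial_to_offset(q, r)
    if (off[["col"]] < 0 || off[["col"]] >= cols) return(NULL)
    tibble::tibble(col = off[["col"]], row = off[["row"]])
  })
  dplyr::bind_rows(out)
}

# tile index <-> (col,row), 0-based, row-major
tile_index <- function(col, row, cols) as.integer(row) * as.integer(cols) + as.integer(col)
tile_coord <- function(idx, cols) {
  idx <- as.integer(idx)
  cbind(col = idx %% cols, row = idx %/% cols)
}
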