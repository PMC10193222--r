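#' Sliding-tile board (15-puzzle family)
#'
#' An `rows x cols` grid holding the tiles `1..(rows*cols - 1)` plus one
#' blank (encoded 0), stored row-major. The goal configuration has the tiles
#' in increasing order with the blank last.
#'
#' @param tiles integer vector of length `rows*cols`, a permutation of
#'   `0..(rows*cols - 1)` with 0 the blank, in row-major order.
#' @param rows,cols board dimensions (default the classic 4x4).
#' @return list of class `fifteen_board`.
#' @export
fifteen_board <- function(tiles, rows = 4L, cols = 4L) {
  tiles <- as.integer(tiles)
  n <- rows * cols
  if (length(tiles) != n || !setequal(tiles, 0:(n - 1L))) {
    stop("tiles must be a permutation of 0..", n - 1L, " (0 = blank)",
         call. = FALSE)
  }
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 tiles = tiles), class = "fifteen_board")
}

#' The solved board
#' @param rows,cols dimensions.
#' @return A [fifteen_board()] with tiles in order, blank last.
#' @export
fifteen_solved <- function(rows = 4L, cols = 4L) {
  fifteen_board(c(seq_len(rows * cols - 1L), 0L), rows, cols)
}

#' Parity test for sliding-puzzle solvability
#'
#' Counts inversions among the numbered tiles (blank excluded). For boards
#' of odd width the configuration is solvable iff the inversion count is
#' even; for even width it is solvable iff inversions plus the blank's row
#' counted from the bottom (1-based) is odd. Both branches are exhaustively
#' cross-checked against breadth-first reachability on small boards in the
#' test suite. Legal slides preserve the criterion.
#'
#' @param board a [fifteen_board()].
#' @return logical.
#' @examples
#' fifteen_is_solvable(fifteen_solved())           # TRUE
#' b <- fifteen_solved(); b$tiles[14:15] <- b$tiles[15:14]
#' fifteen_is_solvable(b)                          # FALSE (14/15 swapped)
#' @export
fifteen_is_solvable <- function(board) {
  stopifnot(inherits(board, "fifteen_board"))
  tiles <- board$tiles[board$tiles != 0L]
  inv <- 0L
  n <- length(tiles)
  for (i in seq_len(n - 1L)) {
    inv <- inv + sum(tiles[(i + 1L):n] < tiles[i])
  }
  blank_pos <- which(board$tiles == 0L)
  blank_row_top <- ((blank_pos - 1L) %/% board$cols) + 1L
  blank_row_bottom <- board$rows - blank_row_top + 1L
  if (board$cols %% 2L == 1L) {
    inv %% 2L == 0L
  } else {
    (inv + blank_row_bottom) %% 2L == 1L
  }
}

# Row-major index helpers
fifteen_neighbors <- function(pos, rows, cols) {
  r <- ((pos - 1L) %/% cols) + 1L
  c <- ((pos - 1L) %% cols) + 1L
  nb <- integer(0)
  if (r > 1L) nb <- c(nb, pos - cols)
  if (r < rows) nb <- c(nb, pos + cols)
  if (c > 1L) nb <- c(nb, pos - 1L)
  if (c < cols) nb <- c(nb, pos + 1L)
  nb
}

#' Slide a tile adjacent to the blank
#'
#' @param board a [fifteen_board()].
#' @param tile tile number to slide into the blank.
#' @return The new board.
#' @export
fifteen_slide <- function(board, tile) {
  stopifnot(inherits(board, "fifteen_board"), tile %in% board$tiles, tile != 0L)
  tp <- which(board$tiles == tile)
  bp <- which(board$tiles == 0L)
  if (!(tp %in% fifteen_neighbors(bp, board$rows, board$cols))) {
    stop("tile ", tile, " is not adjacent to the blank", call. = FALSE)
  }
  board$tiles[c(tp, bp)] <- board$tiles[c(bp, tp)]
  board
}

#' Generate a sliding-puzzle level
#'
#' `solvable_easy` boards are produced by at most `easy_moves` random slides
#' from the solved board (so solvable within that many moves by
#' construction). `unsolvable` boards start from a well-shuffled solvable
#' scramble and transpose two non-blank tiles lying in the same row — a move
#' that flips the solvability parity — then verify the result with
#' [fifteen_is_solvable()] and require that it looks like an ordinary
#' scramble (at most `max_tiles_in_place` tiles on their solved squares, so
#' nothing gives the trick away).
#'
#' @param kind `"solvable_easy"` or `"unsolvable"`.
#' @param rng an [rng_stream()].
#' @param rows,cols board size.
#' @param easy_moves scramble depth for the easy board.
#' @param shuffle_moves random slides used before the parity-breaking
#'   transposition.
#' @param max_tiles_in_place normal-appearance bound for unsolvable boards.
#' @return A [fifteen_board()].
#' @export
fifteen_generate <- function(kind = c("solvable_easy", "unsolvable"), rng,
                             rows = 4L, cols = 4L, easy_moves = 5L,
                             shuffle_moves = 80L, max_tiles_in_place = 2L) {
  kind <- match.arg(kind)
  scramble <- function(n_moves) {
    b <- fifteen_solved(rows, cols)
    last <- 0L
    for (i in seq_len(n_moves)) {
      bp <- which(b$tiles == 0L)
      cand <- fifteen_neighbors(bp, rows, cols)
      cand <- cand[b$tiles[cand] != last] # do not undo the previous slide
      tp <- cand[rng_int(rng, 1L, length(cand))]
      last <- b$tiles[tp]
      b <- fifteen_slide(b, last)
    }
    b
  }
  if (kind == "solvable_easy") {
    repeat {
      b <- scramble(easy_moves)
      if (!identical(b$tiles, fifteen_solved(rows, cols)$tiles)) return(b)
    }
  }
  goal <- fifteen_solved(rows, cols)$tiles
  repeat {
    b <- scramble(shuffle_moves)
    rows_ix <- ((seq_along(b$tiles) - 1L) %/% cols) + 1L
    ok_rows <- unique(rows_ix[b$tiles != 0L])
    r <- ok_rows[rng_int(rng, 1L, length(ok_rows))]
    in_row <- which(rows_ix == r & b$tiles != 0L)
    if (length(in_row) < 2L) next
    pick <- rng_sample(rng, in_row, 2L)
    b$tiles[pick] <- b$tiles[rev(pick)]
    if (fifteen_is_solvable(b)) next
    if (sum(b$tiles == goal & b$tiles != 0L) > max_tiles_in_place) next
    return(b)
  }
}
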