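#' Circle-triangle flip puzzle board
#'
#' A grid of squares each showing a circle or a triangle. Clicking a square
#' flips it together with its orthogonal neighbors; the goal is to make
#' every square a circle. Internally the board is a logical matrix with
#' `TRUE` for triangle (still to fix), so the solved board is all-`FALSE` —
#' the classic Lights-Out structure, linear over GF(2).
#'
#' @param cells logical matrix (`TRUE` = triangle) or character matrix of
#'   `"circle"`/`"triangle"`.
#' @param level_index level this board belongs to (metadata).
#' @return list of class `lights_board`.
#' @export
lights_board <- function(cells, level_index = 1L) {
  if (is.character(cells)) {
    stopifnot(all(cells %in% c("circle", "triangle")))
    cells <- matrix(cells == "triangle", nrow(cells), ncol(cells))
  }
  stopifnot(is.logical(cells), is.matrix(cells))
  structure(list(rows = nrow(cells), cols = ncol(cells), cells = cells,
                 level_index = as.integer(level_index)),
            class = "lights_board")
}

#' Is the board solved (all circles)?
#' @param board a [lights_board()].
#' @return logical.
#' @export
lights_is_solved <- function(board) !any(board$cells)

#' Click one square
#'
#' Toggles the clicked square and its in-bounds orthogonal neighbors; every
#' other square is untouched. Clicks are involutions (clicking twice
#' restores the board) and commute, so only the set of clicked cells
#' matters, never the order.
#'
#' @param board a [lights_board()].
#' @param cell `c(row, col)`.
#' @return The new board.
#' @export
lights_click <- function(board, cell) {
  stopifnot(inherits(board, "lights_board"))
  r <- as.integer(cell[1]); c <- as.integer(cell[2])
  if (r < 1L || r > board$rows || c < 1L || c > board$cols) {
    stop("cell out of bounds", call. = FALSE)
  }
  tgt <- rbind(c(r, c), c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))
  keep <- tgt[, 1] >= 1L & tgt[, 1] <= board$rows &
          tgt[, 2] >= 1L & tgt[, 2] <= board$cols
  tgt <- tgt[keep, , drop = FALSE]
  board$cells[tgt] <- !board$cells[tgt]
  board
}

# Influence matrix: column j is the flip pattern of clicking cell j
# (column-major cell order), over GF(2).
lights_influence_matrix <- function(rows, cols) {
  n <- rows * cols
  A <- matrix(0L, n, n)
  for (c0 in seq_len(cols)) for (r0 in seq_len(rows)) {
    j <- (c0 - 1L) * rows + r0
    nb <- rbind(c(r0, c0), c(r0 - 1L, c0), c(r0 + 1L, c0),
                c(r0, c0 - 1L), c(r0, c0 + 1L))
    keep <- nb[, 1] >= 1L & nb[, 1] <= rows & nb[, 2] >= 1L & nb[, 2] <= cols
    nb <- nb[keep, , drop = FALSE]
    A[(nb[, 2] - 1L) * rows + nb[, 1], j] <- 1L
  }
  A
}

# Gaussian elimination over GF(2). Returns a particular solution of
# A x = b (or NULL if inconsistent) plus a null-space basis.
gf2_solve <- function(A, b) {
  n <- ncol(A)
  M <- cbind(A %% 2L, b %% 2L)
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(n)) {
    piv <- which(M[row:nrow(M), col] == 1L)
    if (length(piv) == 0L) next
    piv <- piv[1] + row - 1L
    if (piv != row) M[c(row, piv), ] <- M[c(piv, row), ]
    hit <- which(M[, col] == 1L)
    hit <- setdiff(hit, row)
    if (length(hit) > 0L) {
      M[hit, ] <- (M[hit, , drop = FALSE] +
                   matrix(M[row, ], length(hit), n + 1L, byrow = TRUE)) %% 2L
    }
    pivots <- c(pivots, col)
    row <- row + 1L
    if (row > nrow(M)) break
  }
  # inconsistency: a zero row with nonzero rhs
  if (row <= nrow(M)) {
    tail_rows <- M[row:nrow(M), , drop = FALSE]
    if (any(tail_rows[, n + 1L] == 1L & rowSums(tail_rows[, 1:n, drop = FALSE]) == 0L)) {
      return(NULL)
    }
  }
  free <- setdiff(seq_len(n), pivots)
  x <- integer(n)
  for (i in seq_along(pivots)) x[pivots[i]] <- M[i, n + 1L]
  null_basis <- lapply(free, function(f) {
    v <- integer(n)
    v[f] <- 1L
    for (i in seq_along(pivots)) v[pivots[i]] <- M[i, f]
    v
  })
  list(particular = x, null_basis = null_basis)
}

#' Solve a circle-triangle board with a minimal click set
#'
#' Solves the GF(2) linear system whose unknowns are click indicators, then
#' scans the affine solution space (particular solution plus every null-space
#' combination) for a minimum-weight solution. Because clicks commute, the
#' returned set can be applied in any order.
#'
#' @param board a [lights_board()].
#' @return `NULL` when unsolvable; otherwise an m x 2 matrix of cells to
#'   click (possibly 0 rows for an already-solved board).
#' @export
lights_solve <- function(board) {
  stopifnot(inherits(board, "lights_board"))
  A <- lights_influence_matrix(board$rows, board$cols)
  b <- as.integer(board$cells) # column-major, TRUE = needs flip
  sol <- gf2_solve(A, b)
  if (is.null(sol)) return(NULL)
  best <- sol$particular
  d <- length(sol$null_basis)
  if (d > 0L && d <= 16L) {
    for (mask in seq_len(2^d) - 1L) {
      x <- sol$particular
      for (k in seq_len(d)) {
        if (bitwAnd(mask, bitwShiftL(1L, k - 1L)) != 0L) {
          x <- (x + sol$null_basis[[k]]) %% 2L
        }
      }
      if (sum(x) < sum(best)) best <- x
    }
  }
  ix <- which(best == 1L)
  cbind(row = ((ix - 1L) %% board$rows) + 1L,
        col = ((ix - 1L) %/% board$rows) + 1L)
}

# Level ladder: board size and scramble depth per level.
lights_level_spec <- function(level_index) {
  stopifnot(level_index >= 1L)
  if (level_index <= 3L) {
    list(size = 3L, depth = level_index)
  } else if (level_index <= 6L) {
    list(size = 4L, depth = level_index - 1L)        # depth 3..5
  } else {
    list(size = 5L, depth = min(4L + level_index - 6L, 12L))
  }
}

#' Generate a guaranteed-solvable circle-triangle level
#'
#' Applies `k` distinct random clicks to the solved board, so the board is
#' solvable by construction (clicks are involutions) and the minimal
#' solution needs at most `k` clicks. Board size and scramble depth `k`
#' follow the level ladder: levels 1-3 on 3x3 (depth 1-3), 4-6 on 4x4
#' (depth 3-5), higher levels on 5x5 with growing depth.
#'
#' @param level_index level to generate (>= 1).
#' @param rng an [rng_stream()].
#' @return A scrambled, solvable [lights_board()].
#' @export
lights_generate_level <- function(level_index, rng) {
  spec <- lights_level_spec(level_index)
  n <- spec$size
  repeat {
    board <- lights_board(matrix(FALSE, n, n), level_index = level_index)
    cells <- rng_sample(rng, seq_len(n * n), size = min(spec$depth, n * n))
    for (ix in cells) {
      board <- lights_click(board, c(((ix - 1L) %% n) + 1L,
                                     ((ix - 1L) %/% n) + 1L))
    }
    if (!lights_is_solved(board)) return(board)
  }
}
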