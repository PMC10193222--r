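#' Butterfly-and-flowers board
#'
#' The butterfly starts on its own square and must sit on every flower. It
#' moves one square at a time in the four compass directions and can only
#' land on squares holding an unwithered flower; a visited flower withers
#' away, so no flower can be landed on twice. The level is solvable exactly
#' when a Hamiltonian path over the flowers exists that starts at a flower
#' orthogonally adjacent to the butterfly.
#'
#' @param dims `c(rows, cols)`.
#' @param flowers m x 2 matrix of flower cells.
#' @param butterfly `c(row, col)` start cell (not a flower cell).
#' @return list of class `butterfly_board`.
#' @export
butterfly_board <- function(dims, flowers, butterfly) {
  dims <- as.integer(dims)
  flowers <- matrix(as.integer(flowers), ncol = 2L)
  butterfly <- as.integer(butterfly)
  key <- function(m) paste(m[, 1], m[, 2])
  if (anyDuplicated(key(flowers))) stop("duplicate flower cells", call. = FALSE)
  if (paste(butterfly[1], butterfly[2]) %in% key(flowers)) {
    stop("butterfly start cell must not hold a flower", call. = FALSE)
  }
  inb <- function(m) all(m[, 1] >= 1L & m[, 1] <= dims[1] &
                         m[, 2] >= 1L & m[, 2] <= dims[2])
  if (!inb(flowers) || !inb(matrix(butterfly, ncol = 2L))) {
    stop("cells out of bounds", call. = FALSE)
  }
  structure(list(dims = dims, flowers = flowers, butterfly = butterfly),
            class = "butterfly_board")
}

#' Can the butterfly visit every flower?
#'
#' Exhaustive depth-first search with memoization over (current cell,
#' visited-flower set) states; flowers are adjacent when they share a grid
#' edge. Feasible for the shipped levels (at most ~10 flowers).
#'
#' @param board a [butterfly_board()].
#' @return logical.
#' @export
butterfly_has_path <- function(board) {
  stopifnot(inherits(board, "butterfly_board"))
  m <- nrow(board$flowers)
  if (m == 0L) return(TRUE)
  adjacent <- function(a, b) sum(abs(a - b)) == 1L
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i != j) adj[i, j] <- adjacent(board$flowers[i, ], board$flowers[j, ])
  }
  starts <- which(vapply(seq_len(m), function(i) {
    adjacent(board$butterfly, board$flowers[i, ])
  }, TRUE))
  if (length(starts) == 0L) return(FALSE)
  full <- bitwShiftL(1L, m) - 1L
  memo <- new.env(parent = emptyenv())
  visit <- function(i, mask) {
    if (mask == full) return(TRUE)
    key <- paste0(i, ":", mask)
    hit <- get0(key, envir = memo, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    res <- FALSE
    for (j in which(adj[i, ])) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) == 0L && visit(j, bitwOr(mask, bit))) {
        res <- TRUE
        break
      }
    }
    assign(key, res, envir = memo)
    res
  }
  for (s in starts) {
    if (visit(s, bitwShiftL(1L, s - 1L))) return(TRUE)
  }
  FALSE
}

#' Generate a butterfly level
#'
#' Solvable levels are built from a self-avoiding orthogonal walk (the walk
#' order is a witness path); unsolvable levels are rejection-sampled random
#' flower layouts kept only when [butterfly_has_path()] proves no path
#' exists. Every returned board is re-verified with the oracle.
#'
#' @param kind `"solvable"` or `"unsolvable"`.
#' @param rng an [rng_stream()].
#' @param dims board dimensions.
#' @param n_flowers number of flowers.
#' @param max_tries rejection-sampling bound.
#' @return A [butterfly_board()].
#' @export
butterfly_generate <- function(kind = c("solvable", "unsolvable"), rng,
                               dims = c(4L, 4L), n_flowers = 6L,
                               max_tries = 2000L) {
  kind <- match.arg(kind)
  dims <- as.integer(dims)
  dirs <- rbind(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L))
  inb <- function(p) p[1] >= 1L && p[1] <= dims[1] && p[2] >= 1L && p[2] <= dims[2]
  if (kind == "solvable") {
    for (t in seq_len(max_tries)) {
      start <- c(rng_int(rng, 1L, dims[1]), rng_int(rng, 1L, dims[2]))
      path <- matrix(start, ncol = 2L)
      ok <- TRUE
      for (i in seq_len(n_flowers)) {
        cur <- path[nrow(path), ]
        cand <- lapply(sample_rows(rng, dirs), function(d) cur + d)
        cand <- Filter(function(p) {
          inb(p) && !any(path[, 1] == p[1] & path[, 2] == p[2])
        }, cand)
        if (length(cand) == 0L) { ok <- FALSE; break }
        path <- rbind(path, cand[[1]])
      }
      if (!ok) next
      board <- butterfly_board(dims, path[-1, , drop = FALSE], path[1, ])
      if (butterfly_has_path(board)) return(board)
    }
  } else {
    for (t in seq_len(max_tries)) {
      cells <- rng_sample(rng, seq_len(prod(dims)), n_flowers + 1L)
      pts <- cbind(((cells - 1L) %% dims[1]) + 1L,
                   ((cells - 1L) %/% dims[1]) + 1L)
      board <- butterfly_board(dims, pts[-1, , drop = FALSE], pts[1, ])
      if (!butterfly_has_path(board)) return(board)
    }
  }
  stop("could not generate a ", kind, " butterfly level within the try budget",
       call. = FALSE)
}

# shuffle the rows of a small matrix through the stream
sample_rows <- function(rng, m) {
  ix <- rng_sample(rng, seq_len(nrow(m)))
  lapply(ix, function(i) m[i, ])
}
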