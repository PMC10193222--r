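#' Arc-nesting board
#'
#' A grid holding a solid ball, a small arc and a big arc, each arc with a
#' fixed opening direction. The ball moves one square at a time; it enters
#' an arc only through its opening (i.e. when the arc on the target square
#' opens toward the ball). With the ball inside, an arc moves along with the
#' ball onto empty squares, or into a strictly bigger arc whose opening
#' faces the incoming direction; moving the ball in the direction of the
#' carrying arc's opening makes the ball exit instead. The goal is to nest
#' the small arc inside the big arc.
#'
#' @param dims `c(rows, cols)`.
#' @param ball `c(row, col)` of the ball.
#' @param small_pos,big_pos arc cells (distinct from each other and from the
#'   ball).
#' @param small_open,big_open opening directions, one of `"north"`,
#'   `"south"`, `"east"`, `"west"`.
#' @return list of class `arc_board`.
#' @export
arc_board <- function(dims, ball, small_pos, small_open, big_pos, big_open) {
  dims <- as.integer(dims)
  ok_dir <- c("north", "south", "east", "west")
  stopifnot(small_open %in% ok_dir, big_open %in% ok_dir)
  pos <- rbind(ball, small_pos, big_pos)
  if (anyDuplicated(paste(pos[, 1], pos[, 2]))) {
    stop("ball and arcs must start on distinct squares", call. = FALSE)
  }
  if (any(pos[, 1] < 1L | pos[, 1] > dims[1] | pos[, 2] < 1L | pos[, 2] > dims[2])) {
    stop("positions out of bounds", call. = FALSE)
  }
  structure(list(dims = dims, ball = as.integer(ball),
                 small_pos = as.integer(small_pos), small_open = small_open,
                 big_pos = as.integer(big_pos), big_open = big_open,
                 ball_in = "none", small_in_big = FALSE),
            class = "arc_board")
}

ARC_DELTAS <- list(north = c(-1L, 0L), south = c(1L, 0L),
                   east = c(0L, 1L), west = c(0L, -1L))
ARC_OPPOSITE <- c(north = "south", south = "north", east = "west", west = "east")

arc_in_bounds <- function(board, p) {
  p[1] >= 1L && p[1] <= board$dims[1] && p[2] >= 1L && p[2] <= board$dims[2]
}

#' Apply one cursor move to an arc board
#'
#' @param board an [arc_board()].
#' @param dir `"north"`, `"south"`, `"east"` or `"west"`.
#' @return The new board, or `NULL` when the move is illegal.
#' @export
arc_step <- function(board, dir) {
  stopifnot(inherits(board, "arc_board"), dir %in% names(ARC_DELTAS))
  if (board$small_in_big) return(NULL) # terminal: goal reached
  d <- ARC_DELTAS[[dir]]
  at <- function(p, q) !is.null(q) && all(p == q)
  if (board$ball_in == "none") {
    q <- board$ball + d
    if (!arc_in_bounds(board, q)) return(NULL)
    if (at(q, board$small_pos)) {
      if (board$small_open != ARC_OPPOSITE[[dir]]) return(NULL)
      board$ball <- q; board$ball_in <- "small"
      return(board)
    }
    if (at(q, board$big_pos)) {
      if (board$big_open != ARC_OPPOSITE[[dir]]) return(NULL)
      board$ball <- q; board$ball_in <- "big"
      return(board)
    }
    board$ball <- q
    return(board)
  }
  carrier <- board$ball_in
  cpos <- if (carrier == "small") board$small_pos else board$big_pos
  copen <- if (carrier == "small") board$small_open else board$big_open
  q <- cpos + d
  if (dir == copen) {
    # ball exits through the opening
    if (!arc_in_bounds(board, q)) return(NULL)
    other_pos <- if (carrier == "small") board$big_pos else board$small_pos
    other_open <- if (carrier == "small") board$big_open else board$small_open
    if (at(q, other_pos)) {
      if (other_open != ARC_OPPOSITE[[dir]]) return(NULL)
      board$ball <- q
      board$ball_in <- if (carrier == "small") "big" else "small"
      return(board)
    }
    board$ball <- q; board$ball_in <- "none"
    return(board)
  }
  # arc moves along with the ball
  if (!arc_in_bounds(board, q)) return(NULL)
  if (carrier == "small") {
    if (at(q, board$big_pos)) {
      if (board$big_open != ARC_OPPOSITE[[dir]]) return(NULL)
      board$small_pos <- q; board$ball <- q
      board$small_in_big <- TRUE # goal: small arc nested in big arc
      return(board)
    }
    board$small_pos <- q; board$ball <- q
    return(board)
  }
  if (at(q, board$small_pos)) return(NULL) # a bigger arc cannot enter a smaller one
  board$big_pos <- q; board$ball <- q
  board
}

arc_state_key <- function(board) {
  paste(board$ball[1], board$ball[2], board$small_pos[1], board$small_pos[2],
        board$big_pos[1], board$big_pos[2], board$ball_in, board$small_in_big,
        sep = "|")
}

#' Decide arc-board solvability by breadth-first search
#'
#' Explores the full reachable state space (ball position, arc placements,
#' containment) and reports whether the goal state — small arc nested inside
#' the big arc — is reachable, with a witness move sequence when it is.
#'
#' @param board an [arc_board()].
#' @param cap state-expansion cap; exceeding it returns an `undecided`
#'   signal (never reached on the shipped board sizes).
#' @return list with `solvable` (logical, or `NA` when undecided) and
#'   `witness` (character vector of directions, `NULL` when unsolvable).
#' @export
arc_solve <- function(board, cap = 100000L) {
  stopifnot(inherits(board, "arc_board"))
  if (board$small_in_big) return(list(solvable = TRUE, witness = character()))
  seen <- new.env(parent = emptyenv())
  queue <- list(list(board = board, moves = character()))
  assign(arc_state_key(board), TRUE, envir = seen)
  expanded <- 0L
  while (length(queue) > 0L) {
    cur <- queue[[1]]
    queue <- queue[-1]
    expanded <- expanded + 1L
    if (expanded > cap) return(list(solvable = NA, witness = NULL))
    for (dir in names(ARC_DELTAS)) {
      nxt <- arc_step(cur$board, dir)
      if (is.null(nxt)) next
      if (nxt$small_in_big) {
        return(list(solvable = TRUE, witness = c(cur$moves, dir)))
      }
      key <- arc_state_key(nxt)
      if (is.null(get0(key, envir = seen, inherits = FALSE))) {
        assign(key, TRUE, envir = seen)
        queue[[length(queue) + 1L]] <- list(board = nxt,
                                            moves = c(cur$moves, dir))
      }
    }
  }
  list(solvable = FALSE, witness = NULL)
}

#' Generate an arc level of known solvability
#'
#' Rejection-samples random placements and opening directions and keeps the
#' first board whose [arc_solve()] verdict matches `kind`.
#'
#' @param kind `"solvable"` or `"unsolvable"`.
#' @param rng an [rng_stream()].
#' @param dims board dimensions.
#' @param max_tries sampling bound.
#' @return An [arc_board()].
#' @export
arc_generate <- function(kind = c("solvable", "unsolvable"), rng,
                         dims = c(3L, 3L), max_tries = 2000L) {
  kind <- match.arg(kind)
  dirs <- names(ARC_DELTAS)
  for (t in seq_len(max_tries)) {
    cells <- rng_sample(rng, seq_len(prod(dims)), 3L)
    pts <- cbind(((cells - 1L) %% dims[1]) + 1L, ((cells - 1L) %/% dims[1]) + 1L)
    board <- arc_board(dims, pts[1, ],
                       pts[2, ], dirs[rng_int(rng, 1L, 4L)],
                       pts[3, ], dirs[rng_int(rng, 1L, 4L)])
    verdict <- arc_solve(board)$solvable
    if (identical(verdict, kind == "solvable")) return(board)
  }
  stop("could not generate a ", kind, " arc level within the try budget",
       call. = FALSE)
}
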