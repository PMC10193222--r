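# Independent oracles used to cross-check the package's solvers. These are
# written from first principles (enumeration, brute force, BFS) and share no
# code with the implementation paths they verify.

# --- sliding puzzle: BFS reachability from the solved configuration --------

slide_oracle_neighbors <- function(tiles, rows, cols) {
  bp <- which(tiles == 0L)
  r <- ((bp - 1L) %/% cols) + 1L
  c <- ((bp - 1L) %% cols) + 1L
  out <- list()
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    nr <- r + d[1]; nc <- c + d[2]
    if (nr < 1L || nr > rows || nc < 1L || nc > cols) next
    np <- (nr - 1L) * cols + nc
    nt <- tiles
    nt[c(bp, np)] <- nt[c(np, bp)]
    out[[length(out) + 1L]] <- nt
  }
  out
}

slide_reachable_set <- function(rows, cols) {
  start <- c(seq_len(rows * cols - 1L), 0L)
  key <- function(t) paste(t, collapse = ",")
  seen <- new.env(parent = emptyenv())
  assign(key(start), TRUE, envir = seen)
  queue <- list(start)
  while (length(queue) > 0L) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (nt in slide_oracle_neighbors(cur, rows, cols)) {
      k <- key(nt)
      if (is.null(get0(k, envir = seen, inherits = FALSE))) {
        assign(k, TRUE, envir = seen)
        queue[[length(queue) + 1L]] <- nt
      }
    }
  }
  seen
}

all_tile_permutations <- function(n_cells) {
  perm_rec <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_rec(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  perm_rec(0:(n_cells - 1L))
}

# BFS distance-bounded solve check for easy boards
slide_bfs_distance <- function(tiles, rows, cols, max_depth = 10L) {
  goal <- paste(c(seq_len(rows * cols - 1L), 0L), collapse = ",")
  key <- function(t) paste(t, collapse = ",")
  if (key(tiles) == goal) return(0L)
  seen <- new.env(parent = emptyenv())
  assign(key(tiles), TRUE, envir = seen)
  frontier <- list(tiles)
  for (depth in seq_len(max_depth)) {
    nxt <- list()
    for (cur in frontier) {
      for (nt in slide_oracle_neighbors(cur, rows, cols)) {
        k <- key(nt)
        if (k == goal) return(depth)
        if (is.null(get0(k, envir = seen, inherits = FALSE))) {
          assign(k, TRUE, envir = seen)
          nxt[[length(nxt) + 1L]] <- nt
        }
      }
    }
    frontier <- nxt
    if (length(frontier) == 0L) break
  }
  NA_integer_
}

# --- circle-triangle puzzle: exhaustive subset enumeration on 3x3 ----------

# Flip pattern of clicking cell (r, c) on an nxn board, column-major 0/1.
lights_oracle_pattern <- function(r, c, n) {
  v <- integer(n * n)
  for (d in list(c(0L, 0L), c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    rr <- r + d[1]; cc <- c + d[2]
    if (rr >= 1L && rr <= n && cc >= 1L && cc <= n) {
      v[(cc - 1L) * n + rr] <- 1L
    }
  }
  v
}

# For every one of the 2^(n*n) click subsets: resulting flip pattern and
# subset size. Returns a lookup from pattern key to minimal subset size.
lights_oracle_table <- function(n = 3L) {
  m <- n * n
  subsets <- as.matrix(expand.grid(rep(list(0:1), m)))
  pat_cols <- sapply(seq_len(m), function(j) {
    lights_oracle_pattern(((j - 1L) %% n) + 1L, ((j - 1L) %/% n) + 1L, n)
  })
  patterns <- (subsets %*% t(pat_cols)) %% 2L
  sizes <- rowSums(subsets)
  keys <- apply(patterns, 1L, paste, collapse = "")
  tab <- tapply(sizes, keys, min)
  tab
}

# --- butterfly: factorial enumeration over flower visit orders -------------

butterfly_oracle <- function(board) {
  m <- nrow(board$flowers)
  if (m == 0L) return(TRUE)
  adj <- function(a, b) sum(abs(a - b)) == 1L
  perm_rec <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_rec(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  for (ord in perm_rec(seq_len(m))) {
    if (!adj(board$butterfly, board$flowers[ord[1], ])) next
    ok <- TRUE
    if (m > 1L) {
      for (i in seq_len(m - 1L)) {
        if (!adj(board$flowers[ord[i], ], board$flowers[ord[i + 1L], ])) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

# --- Wilcoxon signed rank: literal enumeration of all sign assignments ----

wilcoxon_brute_p <- function(scores) {
  x <- scores[scores != 0]
  r <- rank(abs(x))
  n <- length(x)
  w_obs <- sum(r[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.numeric(signs %*% r)
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
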