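# -- circle-triangle flip puzzle --------------------------------------------

test_that("clicks toggle the cell and its orthogonal neighbors only", {
  b <- lights_board(matrix(FALSE, 3, 3))
  center <- lights_click(b, c(2, 2))
  expect_identical(sum(center$cells), 5L)
  expect_true(all(center$cells[cbind(c(2, 1, 3, 2, 2), c(2, 2, 2, 1, 3))]))
  corner <- lights_click(b, c(1, 1))
  expect_identical(sum(corner$cells), 3L)
  expect_error(lights_click(b, c(0, 1)), "out of bounds")
})

test_that("clicks are involutive and commute", {
  rng <- rng_stream(41, "lh.invol")
  for (i in 1:20) {
    b <- lights_board(matrix(rng_unif(rng, 9) < 0.5, 3, 3))
    cell <- c(rng_int(rng, 1, 3), rng_int(rng, 1, 3))
    expect_identical(lights_click(lights_click(b, cell), cell)$cells, b$cells)
    c2 <- c(rng_int(rng, 1, 3), rng_int(rng, 1, 3))
    ab <- lights_click(lights_click(b, cell), c2)
    ba <- lights_click(lights_click(b, c2), cell)
    expect_identical(ab$cells, ba$cells)
  }
})

test_that("the GF(2) solver matches exhaustive enumeration on every 3x3 board", {
  oracle <- lights_oracle_table(3L)
  for (code in 0:511) {
    cells <- matrix(bitwAnd(bitwShiftR(code, 0:8), 1L) == 1L, 3, 3)
    b <- lights_board(cells)
    key <- paste(as.integer(cells), collapse = "")
    sol <- lights_solve(b)
    if (key %in% names(oracle)) {
      expect_false(is.null(sol))
      expect_identical(nrow(sol), as.integer(oracle[[key]]))
      # replaying the clicks reaches all-circles
      for (i in seq_len(nrow(sol))) b <- lights_click(b, sol[i, ])
      expect_true(lights_is_solved(b))
    } else {
      expect_null(sol)
    }
  }
})

test_that("generated circle-triangle levels are always solvable and scale up", {
  rng <- rng_stream(8, "lh.gen")
  sizes <- integer(9)
  for (lvl in 1:9) {
    b <- lights_generate_level(lvl, rng)
    sol <- lights_solve(b)
    expect_false(is.null(sol))
    expect_gte(nrow(sol), 1L)
    sizes[lvl] <- b$rows
  }
  expect_identical(sizes, c(3L, 3L, 3L, 4L, 4L, 4L, 5L, 5L, 5L))
})

# -- sliding puzzle ----------------------------------------------------------

test_that("the parity criterion matches BFS reachability on all 2x3 and 3x2 boards", {
  for (dims in list(c(2L, 3L), c(3L, 2L))) {
    reach <- slide_reachable_set(dims[1], dims[2])
    n_reach <- 0L
    for (tiles in all_tile_permutations(6L)) {
      b <- fifteen_board(tiles, dims[1], dims[2])
      reachable <- !is.null(get0(paste(tiles, collapse = ","), envir = reach,
                                 inherits = FALSE))
      n_reach <- n_reach + reachable
      expect_identical(fifteen_is_solvable(b), reachable)
    }
    expect_identical(n_reach, 360L) # half of 720 states
  }
})

test_that("the solved 4x4 board is solvable and a same-row swap breaks it", {
  expect_true(fifteen_is_solvable(fifteen_solved()))
  b <- fifteen_solved()
  b$tiles[14:15] <- b$tiles[15:14]
  expect_false(fifteen_is_solvable(b))
})

test_that("legal slides preserve solvability", {
  rng <- rng_stream(13, "lh.slides")
  b <- fifteen_generate("solvable_easy", rng)
  before <- fifteen_is_solvable(b)
  bp <- which(b$tiles == 0L)
  nb <- cbmgames:::fifteen_neighbors(bp, b$rows, b$cols)
  b2 <- fifteen_slide(b, b$tiles[nb[1]])
  expect_identical(fifteen_is_solvable(b2), before)
})

test_that("easy generated boards are solvable within 5 moves (BFS oracle)", {
  rng <- rng_stream(19, "lh.easy")
  for (i in 1:10) {
    b <- fifteen_generate("solvable_easy", rng)
    expect_true(fifteen_is_solvable(b))
    d <- slide_bfs_distance(b$tiles, b$rows, b$cols, max_depth = 5L)
    expect_false(is.na(d))
  }
})

test_that("generated trick boards are certified unsolvable and look normal", {
  rng <- rng_stream(23, "lh.trick")
  goal <- fifteen_solved()$tiles
  for (i in 1:100) {
    b <- fifteen_generate("unsolvable", rng)
    expect_false(fifteen_is_solvable(b))
    expect_lte(sum(b$tiles == goal & b$tiles != 0L), 2L)
  }
})

# -- butterfly ---------------------------------------------------------------

test_that("simple butterfly layouts decide as expected", {
  row3 <- butterfly_board(c(1, 4), rbind(c(1, 2), c(1, 3), c(1, 4)), c(1, 1))
  expect_true(butterfly_has_path(row3))
  split <- butterfly_board(c(1, 4), rbind(c(1, 2), c(1, 4)), c(1, 1))
  expect_false(butterfly_has_path(split)) # gap at (1,3) cannot be crossed
  none_adjacent <- butterfly_board(c(3, 3), rbind(c(3, 3)), c(1, 1))
  expect_false(butterfly_has_path(none_adjacent))
  no_flowers <- butterfly_board(c(2, 2), matrix(integer(), ncol = 2), c(1, 1))
  expect_true(butterfly_has_path(no_flowers))
})

test_that("the path search agrees with factorial enumeration on random 3x3 boards", {
  rng <- rng_stream(29, "lh.bfly")
  for (i in 1:40) {
    n_fl <- rng_int(rng, 1, 6)
    cells <- rng_sample(rng, 1:9, n_fl + 1L)
    pts <- cbind(((cells - 1L) %% 3L) + 1L, ((cells - 1L) %/% 3L) + 1L)
    b <- butterfly_board(c(3, 3), pts[-1, , drop = FALSE], pts[1, ])
    expect_identical(butterfly_has_path(b), butterfly_oracle(b))
  }
})

test_that("butterfly generation delivers certified solvable and unsolvable levels", {
  rng <- rng_stream(37, "lh.bgen")
  for (i in 1:5) {
    expect_true(butterfly_has_path(butterfly_generate("solvable", rng)))
    expect_false(butterfly_has_path(butterfly_generate("unsolvable", rng)))
  }
})

# -- arc puzzle --------------------------------------------------------------

test_that("aligned openings make the arc board solvable with a replayable witness", {
  b <- arc_board(c(1, 3), ball = c(1, 1), small_pos = c(1, 2),
                 small_open = "west", big_pos = c(1, 3), big_open = "west")
  res <- arc_solve(b)
  expect_true(res$solvable)
  cur <- b
  for (mv in res$witness) cur <- arc_step(cur, mv)
  expect_true(cur$small_in_big)
})

test_that("an opposed big-arc opening makes the one-row board unsolvable", {
  b <- arc_board(c(1, 3), ball = c(1, 1), small_pos = c(1, 2),
                 small_open = "west", big_pos = c(1, 3), big_open = "east")
  expect_false(arc_solve(b)$solvable)
})

test_that("the ball exits an arc only through its opening", {
  b <- arc_board(c(1, 3), ball = c(1, 1), small_pos = c(1, 2),
                 small_open = "west", big_pos = c(1, 3), big_open = "east")
  inside <- arc_step(b, "east")
  expect_identical(inside$ball_in, "small")
  out <- arc_step(inside, "west") # west is the opening: ball exits
  expect_identical(out$ball_in, "none")
  expect_identical(out$ball, c(1L, 1L))
})

test_that("arc generation returns boards matching the requested verdict", {
  rng <- rng_stream(43, "lh.agen")
  for (i in 1:5) {
    expect_true(arc_solve(arc_generate("solvable", rng))$solvable)
    expect_false(arc_solve(arc_generate("unsolvable", rng))$solvable)
  }
})

# -- session state machine ---------------------------------------------------

test_that("the session flow follows the give-up / retry / explanation circuit", {
  st <- lh_session_state()
  expect_identical(st$phase, "ct_play")
  st <- lh_transition(st, "solved")         # level 1 solved
  expect_identical(st$ct_level, 2L)
  st <- lh_transition(st, "gave_up")        # to first trick game
  expect_identical(st$phase, "unsolvable_play")
  expect_identical(st$trick_current, "fifteen")
  expect_identical(st$trick_level, 1L)
  st <- lh_transition(st, "solved")         # easy level solved
  expect_identical(st$trick_level, 2L)
  st <- lh_transition(st, "gave_up")        # first unsolvable level
  expect_identical(st$trick_level, 3L)
  st <- lh_transition(st, "gave_up")        # second unsolvable level
  expect_identical(st$phase, "ct_retry")
  st2 <- lh_transition(st, "gave_up")       # gives up on a solved level
  expect_identical(st2$phase, "ended_explained")
  st3 <- lh_transition(st, "solved")        # or solves it and resumes
  expect_identical(st3$phase, "ct_play")
  expect_identical(st3$ct_level, 2L)
  # next give-up uses a different trick game
  st4 <- lh_transition(st3, "gave_up")
  expect_identical(st4$trick_current, "butterfly")
  expect_error(lh_transition(st2, "solved"), "ended")
})

test_that("completing every circle-triangle level ends with the gold badge", {
  log <- event_log()
  st <- lh_session_state(n_ct_levels = 3L)
  for (i in 1:3) st <- lh_transition(st, "solved", log = log)
  expect_identical(st$phase, "ended_completed")
  ev <- log_events(log, "badge_awarded")
  expect_identical(ev[[1]]$payload$tier, "gold")
})

test_that("reporting an unsolvable trick level as solved is a state-machine error", {
  st <- lh_session_state()
  st <- lh_transition(st, "gave_up")
  st <- lh_transition(st, "solved")   # easy level: fine
  expect_error(lh_transition(st, "solved"), "state-machine")
})

test_that("random agent sessions always terminate in a valid end state", {
  seeds <- 1:200
  rng <- rng_stream(53, "lh.totality")
  outcomes <- character(length(seeds))
  for (i in seq_along(seeds)) {
    p <- agent_profile(skill = rng_unif(rng, 1),
                       persistence = rng_int(rng, 1, 8),
                       resilience = rng_int(rng, 1, 3) - 1L)
    res <- run_lh_session(p, seeds[i])
    outcomes[i] <- res$outcome
    # every trick game used at most once
    trick_ev <- log_events(res$log, "trick_game_started")
    games <- vapply(trick_ev, function(e) e$payload$game, "")
    expect_false(anyDuplicated(games) > 0L)
  }
  expect_true(all(outcomes %in% c("ended_explained", "ended_completed")))
  expect_true(any(outcomes == "ended_explained"))
})
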