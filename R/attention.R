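#' Song levels of the attention-bias game
#'
#' One song is one level; clicking the positive face plays the song's next
#' note. The bundled bank has 20 songs, encoded only by their note counts
#' (the engine never synthesizes audio).
#'
#' @param song_id short identifier.
#' @param n_notes number of musical notes `N` in the song.
#' @return list of class `song_level`.
#' @export
song_level <- function(song_id, n_notes) {
  n_notes <- as.integer(n_notes)
  if (is.na(n_notes) || n_notes < 1L) stop("a song needs at least one note",
                                           call. = FALSE)
  structure(list(song_id = as.character(song_id), n_notes = n_notes),
            class = "song_level")
}

#' Load the bundled 20-song bank
#' @param path JSON file; defaults to the shipped bank.
#' @return list of [song_level()]s.
#' @export
load_song_bank <- function(path = system.file("extdata", "song_bank.json",
                                              package = "cbmgames")) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw$songs, function(s) song_level(s$song_id, s$n_notes))
}

#' Level time limit: notes times per-note time
#'
#' The budget for a level is `TT = N * T` where `N` is the song's note count
#' and `T` the per-note time, initialized at 5000 ms and adapted within
#' `[1000, 5000]` ms.
#'
#' @param level a [song_level()].
#' @param t_ms per-note time in ms, in `[1000, 5000]`.
#' @return `N * T` in ms.
#' @examples
#' time_limit_ms(song_level("s", 20), 5000) # 100000
#' @export
time_limit_ms <- function(level, t_ms) {
  stopifnot(inherits(level, "song_level"))
  if (t_ms < 1000 || t_ms > 5000) {
    stop("per-note time T must lie in [1000, 5000] ms", call. = FALSE)
  }
  as.integer(level$n_notes) * as.integer(t_ms)
}

# Difficulty ladder: grid grows only after T has tightened to its floor,
# then T relaxes back to 5000 ms on the bigger grid.
ATTENTION_GRIDS <- list(c(1L, 2L), c(2L, 2L), c(3L, 2L))
ATTENTION_T_STEPS <- seq(5000L, 1000L, by = -1000L)

attention_ladder <- function() {
  rungs <- list()
  for (g in ATTENTION_GRIDS) for (t in ATTENTION_T_STEPS) {
    rungs[[length(rungs) + 1L]] <- list(dims = g, t_ms = t)
  }
  rungs
}

#' Adaptive state of the attention-bias game
#'
#' @param t_ms per-note time, clamped to `[1000, 5000]`.
#' @param dims grid dimensions, one of 1x2, 2x2, 3x2.
#' @param lives free lives for the level (5 at each level start).
#' @param points accumulated points.
#' @return list of class `attention_adapt_state`.
#' @export
attention_adapt_state <- function(t_ms = 5000L, dims = c(1L, 2L),
                                  lives = 5L, points = 0L) {
  stopifnot(t_ms >= 1000L, t_ms <= 5000L)
  dims <- as.integer(dims)
  if (!any(vapply(ATTENTION_GRIDS, identical, TRUE, y = dims))) {
    stop("grid dims must be one of 1x2, 2x2, 3x2", call. = FALSE)
  }
  structure(list(t_ms = as.integer(t_ms), dims = dims,
                 lives = as.integer(lives), points = as.integer(points),
                 notes_played = 0L, time_remaining_ms = 0L,
                 halted = FALSE),
            class = "attention_adapt_state")
}

#' Compose one face-grid trial
#'
#' Exactly one positive-valence stimulus is placed at a uniformly random
#' cell; the remaining cells are filled with distinct negative stimuli
#' (sampling without replacement within the trial).
#'
#' @param adapt an [attention_adapt_state()] (fixes the grid size).
#' @param pool list with character vectors `positive` and `negative`
#'   (stimulus ids).
#' @param rng an [rng_stream()].
#' @return list of class `grid_trial` with `dims`, `stimuli` (per cell) and
#'   `positive_index`.
#' @export
make_trial <- function(adapt, pool, rng) {
  stopifnot(inherits(adapt, "attention_adapt_state"))
  k <- prod(adapt$dims)
  if (length(pool$positive) < 1L || length(pool$negative) < k - 1L) {
    stop("stimulus pool too small for the requested grid", call. = FALSE)
  }
  pos_ix <- rng_int(rng, 1L, k)
  pos <- rng_sample(rng, pool$positive, 1L)
  negs <- rng_sample(rng, pool$negative, k - 1L)
  stimuli <- character(k)
  stimuli[pos_ix] <- pos
  stimuli[-pos_ix] <- negs
  structure(list(dims = adapt$dims, stimuli = stimuli,
                 positive_index = pos_ix),
            class = "grid_trial")
}

#' Process a click on a grid cell
#'
#' A click on the positive face plays the song's next note and earns points;
#' a click on a negative face plays a beep and costs one life. At zero lives
#' the level halts (the user is offered a replay). Clicks after the clock
#' has expired are no-ops with an expiry signal.
#'
#' @param adapt an [attention_adapt_state()].
#' @param trial the current [make_trial()] trial.
#' @param clicked_cell 1-based cell index.
#' @param points_per_note points for each positive click.
#' @return list with updated `adapt` and `outcome` in
#'   `c("note_played", "beep", "halted", "expired")`.
#' @export
process_click <- function(adapt, trial, clicked_cell, points_per_note = 2L) {
  stopifnot(inherits(adapt, "attention_adapt_state"),
            inherits(trial, "grid_trial"))
  if (adapt$halted) return(list(adapt = adapt, outcome = "halted"))
  if (adapt$time_remaining_ms <= 0L) {
    return(list(adapt = adapt, outcome = "expired"))
  }
  if (clicked_cell == trial$positive_index) {
    adapt$notes_played <- adapt$notes_played + 1L
    adapt$points <- adapt$points + as.integer(points_per_note)
    return(list(adapt = adapt, outcome = "note_played"))
  }
  adapt$lives <- adapt$lives - 1L
  if (adapt$lives <= 0L) {
    adapt$lives <- 0L
    adapt$halted <- TRUE
    return(list(adapt = adapt, outcome = "halted"))
  }
  list(adapt = adapt, outcome = "beep")
}

#' Exchange points for extra level time
#'
#' Offered when the clock expires mid-level: 20 points buy 10 extra seconds.
#'
#' @param adapt an [attention_adapt_state()].
#' @param cost_points,extra_ms exchange rate.
#' @return list with `adapt` and `refused`.
#' @export
buy_extra_time <- function(adapt, cost_points = 20L, extra_ms = 10000L) {
  stopifnot(inherits(adapt, "attention_adapt_state"))
  if (adapt$points < cost_points) return(list(adapt = adapt, refused = TRUE))
  adapt$points <- adapt$points - as.integer(cost_points)
  adapt$time_remaining_ms <- adapt$time_remaining_ms + as.integer(extra_ms)
  list(adapt = adapt, refused = FALSE)
}

#' Staircase adaptation after a level
#'
#' The difficulty ladder orders `(grid, T)` pairs from 1x2 at 5000 ms up to
#' 3x2 at 1000 ms: completing a level with accuracy at or above `up_acc`
#' tightens `T` by 1000 ms, and once `T` sits at its 1000 ms floor the grid
#' grows one step while `T` resets to 5000 ms; failing the level or
#' finishing below `down_acc` takes the reverse step. `T` never leaves
#' `[1000, 5000]` and the grid never leaves {1x2, 2x2, 3x2}.
#'
#' @param adapt an [attention_adapt_state()].
#' @param outcome `"completed"` or `"failed"`.
#' @param accuracy fraction of clicks that hit the positive face.
#' @param up_acc,down_acc staircase thresholds.
#' @return The adapted state (notes/timer reset for the next level).
#' @export
adapt_difficulty <- function(adapt, outcome, accuracy,
                             up_acc = 0.9, down_acc = 0.6) {
  stopifnot(inherits(adapt, "attention_adapt_state"),
            outcome %in% c("completed", "failed"),
            accuracy >= 0, accuracy <= 1)
  ladder <- attention_ladder()
  pos <- which(vapply(ladder, function(r) {
    identical(r$dims, adapt$dims) && r$t_ms == adapt$t_ms
  }, TRUE))
  if (outcome == "completed" && accuracy >= up_acc) {
    pos <- min(pos + 1L, length(ladder))
  } else if (outcome == "failed" || accuracy < down_acc) {
    pos <- max(pos - 1L, 1L)
  }
  adapt$dims <- ladder[[pos]]$dims
  adapt$t_ms <- ladder[[pos]]$t_ms
  adapt$notes_played <- 0L
  adapt$halted <- FALSE
  adapt
}

#' Load the bundled face-stimulus pool
#' @param path JSON file with `positive` and `negative` id vectors.
#' @return list with `positive` and `negative` character vectors.
#' @export
load_stimulus_pool <- function(path = system.file("extdata",
                                                  "stimulus_pool.json",
                                                  package = "cbmgames")) {
  raw <- jsonlite::fromJSON(path)
  list(positive = as.character(raw$positive),
       negative = as.character(raw$negative))
}
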