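#' Fixed stimulus timings of the executive-control training round
#'
#' Flanker arrows stay up to 1000 ms, the valenced image is flashed for
#' 100 ms, a 50 ms blank gap follows, the colored circle stays up to 2000 ms,
#' and the next round begins after a 2000 ms delay.
#' @export
EXEC_TIMINGS <- list(flanker_window_ms = 1000L, image_duration_ms = 100L,
                     gap_duration_ms = 50L, circle_window_ms = 2000L,
                     inter_round_delay_ms = 2000L)

#' Sample one executive-control training round
#'
#' A congruent or incongruent set of five flanker arrows is drawn with 50:50
#' probability; the following image is neutral or negative with 80:20
#' probability after a congruent set and 20:80 after an incongruent set; the
#' circle is green or red with 50:50 probability. The three stages are
#' otherwise independent, so the marginal probability of a negative image is
#' exactly 0.5 by construction.
#'
#' @param rng an [rng_stream()].
#' @param n_arrows flanker set size (center + flankers).
#' @return A list of class `training_round` with the arrows, congruency,
#'   image valence/stimulus id and circle color plus the fixed timings.
#' @export
sample_training_round <- function(rng, n_arrows = 5L) {
  congruent <- rng_bern(rng, 0.5)
  center <- if (rng_bern(rng, 0.5)) "left" else "right"
  flank <- if (congruent) center else setdiff(c("left", "right"), center)
  arrows <- rep(flank, n_arrows)
  arrows[(n_arrows + 1L) %/% 2L] <- center
  p_neutral <- if (congruent) 0.8 else 0.2
  valence <- if (rng_bern(rng, p_neutral)) "neutral" else "negative"
  stim_id <- sprintf("img_%s_%03d", valence, rng_int(rng, 1L, 100L))
  color <- if (rng_bern(rng, 0.5)) "green" else "red"
  structure(list(congruency = if (congruent) "congruent" else "incongruent",
                 arrows = arrows, center_direction = center,
                 image_valence = valence, image_stimulus_id = stim_id,
                 circle_color = color, timings = EXEC_TIMINGS),
            class = "training_round")
}

#' Judge a training-round response
#'
#' A round is correct only when both stages are right: the flanker key equals
#' the center arrow's direction within its 1000 ms window, and the circle key
#' follows the color mapping (green is the up arrow, red the down arrow)
#' within its 2000 ms window. Any timeout makes the round incorrect. Pure
#' function: no state, no randomness.
#'
#' @param round a [sample_training_round()] round.
#' @param response list with `flanker_key` (`"left"`/`"right"`/`NA` for
#'   timeout), `flanker_rt_ms`, `circle_key` (`"up"`/`"down"`/`NA`),
#'   `circle_rt_ms`.
#' @return `"correct"` or `"incorrect"`.
#' @export
evaluate_round <- function(round, response) {
  stopifnot(inherits(round, "training_round"))
  fl_ok <- !is.na(response$flanker_key) &&
    response$flanker_key == round$center_direction &&
    response$flanker_rt_ms <= round$timings$flanker_window_ms
  expected_circle <- if (round$circle_color == "green") "up" else "down"
  ci_ok <- !is.na(response$circle_key) &&
    response$circle_key == expected_circle &&
    response$circle_rt_ms <= round$timings$circle_window_ms
  if (fl_ok && ci_ok) "correct" else "incorrect"
}

#' Run one batch of three training rounds
#'
#' Triggered when the avatar stops in front of the large pit. Instructions
#' are logged before each round; the stimulus timeline within a round follows
#' the fixed windows (flanker up to 1000 ms, image 100 ms, 50 ms gap, circle
#' up to 2000 ms) and rounds are separated by a 2000 ms delay. Each correct
#' round credits a double jump or an extra life (alternating), and the badge
#' rule (6/15/39 cumulative correct responses) is re-evaluated after every
#' round.
#'
#' @param rng an [rng_stream()].
#' @param agent an [agent_profile()] answering the rounds.
#' @param economy an [economy_state()].
#' @param cumulative_correct correct-response count carried across batches.
#' @param log an [event_log()] (mutated).
#' @param t0_ms logical timestamp at batch start.
#' @param rule badge rule for correct responses.
#' @param reward_phase `"double_jump"` or `"life"`: which reward the next
#'   correct round earns (alternates).
#' @return list with `outcomes` (3 results), `economy`,
#'   `cumulative_correct`, `t_ms` (time after the batch), `reward_phase`.
#' @export
run_training_batch <- function(rng, agent, economy,
                               cumulative_correct = 0L,
                               log = event_log(), t0_ms = 0L,
                               rule = badge_rule("correct_responses", 6, 15, 39),
                               reward_phase = "double_jump") {
  t <- as.integer(t0_ms)
  outcomes <- character(3L)
  for (i in 1:3) {
    log_event(log, t, "instructions_shown", list(task = "training_round"))
    round <- sample_training_round(rng)
    resp <- agent_respond_round(agent, round, rng)
    log_event(log, t, "flanker_onset", list(congruency = round$congruency))
    t_fl <- t + as.integer(min(resp$flanker_rt_ms, EXEC_TIMINGS$flanker_window_ms))
    log_event(log, t_fl, "image_onset", list(valence = round$image_valence))
    t_img <- t_fl + EXEC_TIMINGS$image_duration_ms
    log_event(log, t_img, "image_offset", list())
    t_circ <- t_img + EXEC_TIMINGS$gap_duration_ms
    log_event(log, t_circ, "circle_onset", list(color = round$circle_color))
    t_end <- t_circ + as.integer(min(resp$circle_rt_ms, EXEC_TIMINGS$circle_window_ms))
    outcome <- evaluate_round(round, resp)
    outcomes[i] <- outcome
    if (outcome == "correct") {
      cumulative_correct <- cumulative_correct + 1L
      if (reward_phase == "double_jump") {
        economy$free_double_jumps <- economy$free_double_jumps + 1L
        reward_phase <- "life"
      } else {
        economy$lives <- economy$lives + 1L
        reward_phase <- "double_jump"
      }
      before <- economy$badges
      economy <- award_badges(cumulative_correct, rule, economy)
      for (b in setdiff(economy$badges, before)) {
        log_event(log, t_end, "badge_awarded",
                  list(tier = b, metric = rule$metric,
                       count = cumulative_correct))
      }
    }
    log_event(log, t_end, "round_result",
              list(outcome = outcome, congruency = round$congruency,
                   valence = round$image_valence, color = round$circle_color))
    t <- t_end + EXEC_TIMINGS$inter_round_delay_ms
  }
  list(outcomes = outcomes, economy = economy,
       cumulative_correct = cumulative_correct, t_ms = t,
       reward_phase = reward_phase, log = log)
}

#' Start state of the abstract platformer run
#'
#' The run starts with 3 lives and 5 free double jumps; avatar speed ramps
#' up 5% every 10 s of survival (capped at 3x base) and the distance score
#' grows with time while the avatar is alive.
#'
#' @param economy optional starting [economy_state()].
#' @return list of class `platformer_state`.
#' @export
platformer_start <- function(economy = economy_state(lives = 3L,
                                                     free_double_jumps = 5L)) {
  structure(list(speed = 1.0, base_speed = 1.0, distance = 0L,
                 alive = TRUE, t_ms = 0L, economy = economy,
                 obstacle_queue = character()),
            class = "platformer_state")
}

OBSTACLE_KINDS <- c("frog_sitting", "frog_jumping", "pit_single", "pit_double",
                    "pit_platforms_stationary", "pit_platforms_falling",
                    "tunnel")

# What the obstacle demands of the avatar. Tunnels and stationary platforms
# are passable by running; falling platforms and double pits need the double
# jump.
obstacle_required_action <- function(kind) {
  switch(kind,
         frog_sitting = "jump", frog_jumping = "jump", pit_single = "jump",
         pit_double = "double_jump", pit_platforms_stationary = "run",
         pit_platforms_falling = "double_jump", tunnel = "run",
         stop("unknown obstacle kind: ", kind, call. = FALSE))
}

#' Advance the abstract platformer by one time slice
#'
#' Headless abstraction of the side-scroller: the avatar either clears the
#' obstacle at the head of the queue with the required action or loses a
#' life (the run ends at 0 lives). A double jump consumes a free credit
#' first, then 10 coins; with neither, the avatar falls. Coins on the track
#' are collected by jumping. Speed ramps +5% per 10 s, capped at 3x.
#'
#' @param state a [platformer_start()] state.
#' @param action one of `"run"`, `"jump"`, `"double_jump"`.
#' @param dt_ms elapsed logical time for this slice.
#' @param obstacle obstacle kind faced during the slice, or `NA` for open
#'   track.
#' @param coins_on_track coins collectable this slice (by jumping).
#' @return The updated `platformer_state`.
#' @export
step_platformer <- function(state, action = "run", dt_ms = 1000L,
                            obstacle = NA_character_, coins_on_track = 0L) {
  stopifnot(inherits(state, "platformer_state"), state$alive,
            action %in% c("run", "jump", "double_jump"))
  eco <- state$economy
  survived <- TRUE
  if (action == "double_jump") {
    dj <- purchase_double_jump(eco)
    if (dj$refused) {
      survived <- FALSE               # no credit, no coins: the avatar falls
    } else {
      eco <- dj$economy
    }
  }
  if (survived && !is.na(obstacle)) {
    survived <- action == obstacle_required_action(obstacle) ||
      (action == "double_jump" && obstacle_required_action(obstacle) == "jump")
  }
  if (survived) {
    if (action %in% c("jump", "double_jump") && coins_on_track > 0L) {
      eco$coins <- eco$coins + as.integer(coins_on_track)
    }
    state$distance <- state$distance +
      as.integer(round(state$speed * dt_ms / 100))
    eco$points <- eco$points + as.integer(round(dt_ms / 1000))
  } else {
    if (eco$lives > 0L) {
      eco$lives <- eco$lives - 1L
      if (eco$lives == 0L) state$alive <- FALSE
    } else {
      state$alive <- FALSE
    }
  }
  state$t_ms <- state$t_ms + as.integer(dt_ms)
  ramp_steps <- state$t_ms %/% 10000L
  state$speed <- min(state$base_speed * 1.05^ramp_steps, 3 * state$base_speed)
  state$economy <- eco
  state
}
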