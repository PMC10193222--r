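#' Simulated-user agent profile
#'
#' Parameterized response model used to exercise the game engines headlessly.
#' Agents observe the full game state (they exist to drive the logic, not to
#' model human perception).
#'
#' @param skill probability of a correct/optimal action in `[0, 1]`.
#' @param interpretation_bias probability of answering *Yes* to a positive
#'   probe in the word-search game (and *No* to a negative one); `1` is a
#'   fully benign responder.
#' @param rt_median_ms,rt_sigma lognormal response-time model (draws are
#'   truncated to the response window of the task at hand).
#' @param persistence move budget the agent is willing to spend on a puzzle
#'   before giving up.
#' @param resilience number of give-up/trick-game cycles the agent tolerates
#'   before surrendering on a previously solved circle-triangle level.
#' @return list of class `agent_profile`.
#' @export
agent_profile <- function(skill = 1.0, interpretation_bias = 1.0,
                          rt_median_ms = 800, rt_sigma = 0.4,
                          persistence = 100L, resilience = 3L) {
  stopifnot(skill >= 0, skill <= 1,
            interpretation_bias >= 0, interpretation_bias <= 1,
            rt_median_ms > 0, rt_sigma >= 0, persistence >= 0,
            resilience >= 0)
  structure(list(skill = skill, interpretation_bias = interpretation_bias,
                 rt_median_ms = rt_median_ms, rt_sigma = rt_sigma,
                 persistence = as.integer(persistence),
                 resilience = as.integer(resilience)),
            class = "agent_profile")
}

#' Load an agent profile from YAML or JSON
#' @param path profile file with the [agent_profile()] fields.
#' @return An `agent_profile`.
#' @export
load_agent_profile <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path)
  do.call(agent_profile, raw)
}

agent_rt <- function(agent, rng, window_ms) {
  rt <- rng_lognormal_ms(rng, 1L, agent$rt_median_ms, agent$rt_sigma)
  min(as.integer(round(rt)), as.integer(window_ms))
}

#' Agent response to one executive-control training round
#'
#' The flanker and circle keys are each correct with probability `skill`
#' (an incorrect stage presses the wrong key); response times follow the
#' agent's lognormal model truncated to the stage window.
#'
#' @param agent an [agent_profile()].
#' @param round a [sample_training_round()] round.
#' @param rng an [rng_stream()].
#' @return list with `flanker_key`, `flanker_rt_ms`, `circle_key`,
#'   `circle_rt_ms`.
#' @export
agent_respond_round <- function(agent, round, rng) {
  fl_correct <- rng_bern(rng, agent$skill)
  fl_key <- if (fl_correct) round$center_direction
            else setdiff(c("left", "right"), round$center_direction)
  circ_correct <- rng_bern(rng, agent$skill)
  expected <- if (round$circle_color == "green") "up" else "down"
  ci_key <- if (circ_correct) expected else setdiff(c("up", "down"), expected)
  list(flanker_key = fl_key,
       flanker_rt_ms = agent_rt(agent, rng, round$timings$flanker_window_ms),
       circle_key = ci_key,
       circle_rt_ms = agent_rt(agent, rng, round$timings$circle_window_ms))
}

#' Run a full headless session of one game
#'
#' Dispatches to the per-game runner; identical `(profile, seed)` pairs
#' yield byte-identical logs.
#'
#' @param profile an [agent_profile()].
#' @param game one of `"wsap"`, `"executive"`, `"attention"`, `"imagery"`,
#'   `"helplessness"`.
#' @param seed master seed.
#' @param budget per-game budget: levels for wsap/attention/imagery,
#'   training batches for the executive game; ignored by the
#'   learned-helplessness game (it ends on its own).
#' @return list with `log` (an [event_log()]) and game-specific summaries.
#' @export
run_session <- function(profile, game, seed, budget = 10L) {
  stopifnot(inherits(profile, "agent_profile"))
  switch(game,
         wsap = run_wsap_session(profile, seed, n_levels = budget),
         executive = run_exec_session(profile, seed, n_batches = budget),
         attention = run_attention_session(profile, seed, n_levels = budget),
         imagery = run_imagery_session(profile, seed, n_scenarios = budget),
         helplessness = run_lh_session(profile, seed),
         stop("unsupported game id: ", game, call. = FALSE))
}

#' @rdname run_session
#' @param n_levels number of levels to attempt.
#' @param bank optional preloaded content bank.
#' @export
run_wsap_session <- function(profile, seed, n_levels = 10L,
                             bank = load_wsap_bank()) {
  rng <- rng_stream(seed, "wsap.session")
  grid_rng <- rng_stream(seed, "wsap.grid")
  log <- event_log()
  eco <- economy_state()
  rule <- badge_rule("levels_completed", 4, 10, 26)
  completed <- 0L
  level <- 0L
  t <- 0L
  for (i in seq_len(n_levels)) {
    item <- bank[[level + 1L]]
    state <- wsap_level_start(item, level_index = level)
    grid <- build_letter_grid(item, rng = grid_rng)
    log_event(log, t, "level_started", list(level = level))
    found_all <- TRUE
    for (w in item$words) {
      if (rng_bern(rng, profile$skill)) {
        res <- submit_path(state, grid, grid$placements[[w]])
        state <- res$state
        t <- t + agent_rt(profile, rng, state$allotted_ms)
      } else {
        found_all <- FALSE
      }
    }
    if (state$sentence_revealed) {
      t <- t + display_duration_ms(item$sentence)
      log_event(log, t, "sentence_revealed", list(sentence = item$sentence))
      answer <- wsap_agent_answer(profile, item, rng)
      rt <- agent_rt(profile, rng, 5000L)
      pts <- score_probe(item, answer, rt)
      eco$points <- eco$points + pts + state$points
      t <- t + rt
      log_event(log, t, "probe_answered",
                list(answer = answer, correct = answer == item$correct_answer,
                     points = pts))
    }
    if (found_all && state$phase == "probe") {
      completed <- completed + 1L
      before <- eco$badges
      eco <- award_badges(completed, rule, eco)
      for (b in setdiff(eco$badges, before)) {
        log_event(log, t, "badge_awarded",
                  list(tier = b, metric = rule$metric, count = completed))
      }
      log_event(log, t, "level_completed", list(level = level,
                                                completed = completed))
      level <- next_level(level, length(bank))
    } else {
      log_event(log, t, "level_failed", list(level = level))
    }
    t <- t + 1000L
  }
  list(log = log, economy = eco, levels_completed = completed)
}

# Benign-bias responder: yes to positive probes with prob = bias, no to
# negative ones with prob = bias (decoys are still answered by valence,
# which is exactly why the bank needs them).
wsap_agent_answer <- function(profile, item, rng) {
  toward_positive <- rng_bern(rng, profile$interpretation_bias)
  if (item$probe_valence == "positive") {
    if (toward_positive) "yes" else "no"
  } else {
    if (toward_positive) "no" else "yes"
  }
}

#' @rdname run_session
#' @param n_batches number of training batches interleaved with ~30 s of
#'   platformer gameplay.
#' @export
run_exec_session <- function(profile, seed, n_batches = 5L) {
  rng <- rng_stream(seed, "exec.session")
  log <- event_log()
  state <- platformer_start()
  rule <- badge_rule("correct_responses", 6, 15, 39)
  cumulative <- 0L
  reward_phase <- "double_jump"
  round_data <- list()
  t <- 0L
  for (b in seq_len(n_batches)) {
    # ~30 s of platformer gameplay before the batch triggers
    for (s in seq_len(6L)) {
      if (!state$alive) break
      obstacle <- if (rng_bern(rng, 0.5)) OBSTACLE_KINDS[rng_int(rng, 1L, 7L)]
                  else NA_character_
      action <- exec_agent_action(profile, obstacle, rng)
      coins <- if (rng_bern(rng, 0.4)) rng_int(rng, 1L, 3L) else 0L
      state <- step_platformer(state, action, dt_ms = 5000L,
                               obstacle = obstacle, coins_on_track = coins)
      t <- t + 5000L
    }
    if (!state$alive) {
      log_event(log, t, "run_ended", list(distance = state$distance))
      break
    }
    log_event(log, t, "training_triggered", list(batch = b))
    res <- run_training_batch(rng, profile, state$economy,
                              cumulative_correct = cumulative, log = log,
                              t0_ms = t, rule = rule,
                              reward_phase = reward_phase)
    state$economy <- res$economy
    cumulative <- res$cumulative_correct
    reward_phase <- res$reward_phase
    t <- res$t_ms
    round_data[[b]] <- res$outcomes
  }
  list(log = log, economy = state$economy, state = state,
       correct_responses = cumulative,
       batch_outcomes = round_data)
}

exec_agent_action <- function(profile, obstacle, rng) {
  if (is.na(obstacle)) {
    return(if (rng_bern(rng, 0.3)) "jump" else "run")
  }
  required <- obstacle_required_action(obstacle)
  if (rng_bern(rng, profile$skill)) required
  else setdiff(c("run", "jump"), required)[1]
}

#' @rdname run_session
#' @param pool stimulus pool for the attention game.
#' @param song_bank preloaded song bank.
#' @export
run_attention_session <- function(profile, seed, n_levels = 10L,
                                  pool = load_stimulus_pool(),
                                  song_bank = load_song_bank()) {
  rng <- rng_stream(seed, "attention.session")
  log <- event_log()
  adapt <- attention_adapt_state()
  rule <- badge_rule("positive_clicks", 34, 60, 156)
  badges <- character()
  positive_clicks <- 0L
  song_ix <- 1L
  t <- 0L
  for (lvl in seq_len(n_levels)) {
    song <- song_bank[[song_ix]]
    adapt$lives <- 5L # free lives refill at each level start
    adapt$notes_played <- 0L
    adapt$halted <- FALSE
    adapt$time_remaining_ms <- time_limit_ms(song, adapt$t_ms)
    log_event(log, t, "level_started",
              list(song = song$song_id, n_notes = song$n_notes,
                   t_ms = adapt$t_ms, dims = paste(adapt$dims, collapse = "x")))
    clicks <- 0L
    while (adapt$notes_played < song$n_notes && !adapt$halted &&
           adapt$time_remaining_ms > 0L) {
      trial <- make_trial(adapt, pool, rng)
      hit <- rng_bern(rng, profile$skill)
      cell <- if (hit) trial$positive_index else {
        neg <- setdiff(seq_len(prod(trial$dims)), trial$positive_index)
        neg[rng_int(rng, 1L, length(neg))]
      }
      rt <- agent_rt(profile, rng, adapt$t_ms)
      adapt$time_remaining_ms <- adapt$time_remaining_ms - rt
      t <- t + rt
      if (adapt$time_remaining_ms <= 0L) {
        bt <- buy_extra_time(adapt)
        if (bt$refused) break
        adapt <- bt$adapt
        log_event(log, t, "extra_time_bought", list())
      }
      res <- process_click(adapt, trial, cell)
      adapt <- res$adapt
      clicks <- clicks + 1L
      if (res$outcome == "note_played") {
        positive_clicks <- positive_clicks + 1L
        eco <- award_badges(positive_clicks, rule,
                           economy_state(badges = badges))
        for (bd in setdiff(eco$badges, badges)) {
          log_event(log, t, "badge_awarded",
                    list(tier = bd, metric = rule$metric,
                         count = positive_clicks))
        }
        badges <- eco$badges
      }
    }
    completed <- adapt$notes_played >= song$n_notes
    accuracy <- if (clicks > 0L) adapt$notes_played / clicks else 0
    log_event(log, t, if (completed) "level_completed" else "level_failed",
              list(song = song$song_id, accuracy = accuracy))
    adapt <- adapt_difficulty(adapt, if (completed) "completed" else "failed",
                              accuracy)
    song_ix <- (song_ix %% length(song_bank)) + 1L # loop back after song 20
    t <- t + 1000L
  }
  list(log = log, adapt = adapt, positive_clicks = positive_clicks,
       badges = badges)
}

#' @rdname run_session
#' @param n_scenarios number of scenario levels to play.
#' @param scenario_bank preloaded scenario bank.
#' @export
run_imagery_session <- function(profile, seed, n_scenarios = 10L,
                                scenario_bank = load_scenario_bank()) {
  rng <- rng_stream(seed, "imagery.session")
  log <- event_log()
  state <- imagery_state()
  t <- 0L
  for (i in seq_len(n_scenarios)) {
    scen <- scenario_bank[[state$level_index + 1L]]
    log_event(log, t, "instructions_shown",
              list(prompt = "imagine the situation vividly in the first person"))
    repeat {
      part <- state$part
      positive <- rng_bern(rng, profile$skill)
      pool <- if (positive) scen$positive[[part]] else scen$negative[[part]]
      phrase <- pool[rng_int(rng, 1L, length(pool))]
      before <- state$badges
      res <- submit_attempt(state, scen, phrase)
      state <- res$state
      t <- t + agent_rt(profile, rng, 60000L)
      log_event(log, t, "attempt", list(part = part, feedback = res$feedback))
      if (res$feedback == "show_choices") {
        res <- choose_completion(state, scen, 1L)
        state <- res$state
        log_event(log, t, "choice_selected", list(part = part))
      }
      for (b in setdiff(state$badges, before)) {
        log_event(log, t, "badge_awarded",
                  list(tier = b, metric = "positive_resolutions",
                       count = state$positive_resolutions))
      }
      if (res$feedback == "level_concluded") break
      t <- t + 500L
    }
    log_event(log, t, "level_concluded",
              list(positive_resolutions = state$positive_resolutions,
                   badges = paste(state$badges, collapse = ",")))
  }
  list(log = log, state = state)
}

#' @rdname run_session
#' @export
run_lh_session <- function(profile, seed) {
  rng <- rng_stream(seed, "lh.session")
  log <- event_log()
  state <- lh_session_state()
  t <- 0L
  guard <- 0L
  while (!(state$phase %in% c("ended_explained", "ended_completed"))) {
    guard <- guard + 1L
    if (guard > 1000L) stop("runaway learned-helplessness session",
                            call. = FALSE)
    event <- lh_agent_event(profile, state, rng)
    log_event(log, t, "phase_event",
              list(phase = state$phase, ct_level = state$ct_level,
                   trick = state$trick_current,
                   trick_level = state$trick_level, event = event))
    state <- lh_transition(state, event, log = log, t_ms = t)
    t <- t + 1000L
  }
  log_event(log, t, "session_ended", list(outcome = state$phase))
  list(log = log, state = state, outcome = state$phase)
}

# Decide solved/gave_up for the current phase. Circle-triangle levels are
# attempted against the agent's move budget (minimal solution size as the
# effort proxy); trick levels 2-3 are unsolvable so the agent always gives
# up on them; on a retry of a previously solved level the agent surrenders
# once its resilience (tolerated give-up cycles) is exhausted.
lh_agent_event <- function(profile, state, rng) {
  if (state$phase == "ct_play") {
    board <- lights_generate_level(state$ct_level, rng)
    need <- nrow(lights_solve(board))
    return(if (need <= profile$persistence) "solved" else "gave_up")
  }
  if (state$phase == "unsolvable_play") {
    if (state$trick_level == 1L) {
      return(if (profile$persistence >= 1L) "solved" else "gave_up")
    }
    return("gave_up")
  }
  # ct_retry
  if (state$cycles > profile$resilience) "gave_up" else "solved"
}
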