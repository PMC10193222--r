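#' Learned-helplessness session state machine
#'
#' The session alternates between the genuine circle-triangle mini-game and
#' trick mini-games with certified-unsolvable levels. Solving a
#' circle-triangle level advances the ladder ("Great" feedback); giving up
#' routes to the next unused trick mini-game (one easy level, then two
#' unsolvable ones). After giving up on both unsolvable levels the last
#' solved circle-triangle level is shown again: giving up on that
#' previously solved level ends the game with the learned-helplessness
#' explanation, while solving it resumes the ladder. Completing every
#' circle-triangle level ends the game with a gold badge. Each trick
#' mini-game is used at most once per session.
#'
#' @param n_ct_levels number of circle-triangle levels to complete for the
#'   `ended_completed` outcome.
#' @param trick_order order in which the trick mini-games are offered.
#' @return list of class `lh_session_state` in phase `ct_play` at level 1.
#' @export
lh_session_state <- function(n_ct_levels = 9L,
                             trick_order = c("fifteen", "butterfly", "arc")) {
  stopifnot(setequal(trick_order, c("fifteen", "butterfly", "arc")))
  structure(list(phase = "ct_play", ct_level = 1L, last_solved = 0L,
                 n_ct_levels = as.integer(n_ct_levels),
                 trick_order = trick_order, tricks_used = character(),
                 trick_current = NA_character_, trick_level = NA_integer_,
                 cycles = 0L),
            class = "lh_session_state")
}

LH_PHASES <- c("ct_play", "unsolvable_play", "ct_retry",
               "ended_explained", "ended_completed")

#' Transition the learned-helplessness session
#'
#' @param state an [lh_session_state()].
#' @param event `"solved"` or `"gave_up"`.
#' @param log optional [event_log()] for feedback/explanation events.
#' @param t_ms logical timestamp for logged events.
#' @return The next state.
#' @export
lh_transition <- function(state, event, log = NULL, t_ms = 0L) {
  stopifnot(inherits(state, "lh_session_state"),
            event %in% c("solved", "gave_up"))
  emit <- function(kind, payload = list()) {
    if (!is.null(log)) log_event(log, t_ms, kind, payload)
  }
  if (state$phase %in% c("ended_explained", "ended_completed")) {
    stop("session already ended", call. = FALSE)
  }
  if (state$phase == "ct_play") {
    if (event == "solved") {
      emit("feedback", list(message = "Great", sound = "ding"))
      state$last_solved <- state$ct_level
      if (state$ct_level >= state$n_ct_levels) {
        state$phase <- "ended_completed"
        emit("badge_awarded", list(tier = "gold", metric = "game_finished"))
      } else {
        state$ct_level <- state$ct_level + 1L
      }
      return(state)
    }
    remaining <- setdiff(state$trick_order, state$tricks_used)
    if (length(remaining) > 0L) {
      state$phase <- "unsolvable_play"
      state$trick_current <- remaining[1]
      state$tricks_used <- c(state$tricks_used, remaining[1])
      state$trick_level <- 1L # the easy, genuinely solvable level
      emit("trick_game_started", list(game = state$trick_current))
    } else {
      # every trick mini-game already used: show the last solved level again
      state$phase <- "ct_retry"
      state$cycles <- state$cycles + 1L
    }
    return(state)
  }
  if (state$phase == "unsolvable_play") {
    if (event == "solved") {
      if (state$trick_level != 1L) {
        stop("unsolvable level reported as solved: state-machine error",
             call. = FALSE)
      }
      state$trick_level <- 2L
      return(state)
    }
    if (state$trick_level < 3L) {
      state$trick_level <- state$trick_level + 1L
      return(state)
    }
    # gave up on both unsolvable levels: back to the last solved CT level
    state$phase <- "ct_retry"
    state$trick_current <- NA_character_
    state$trick_level <- NA_integer_
    state$cycles <- state$cycles + 1L
    return(state)
  }
  # ct_retry: the previously solved circle-triangle level is shown again
  if (event == "gave_up") {
    state$phase <- "ended_explained"
    emit("explanation_shown",
         list(topic = "learned_helplessness_attribution_bias"))
    return(state)
  }
  state$phase <- "ct_play"
  state$ct_level <- state$last_solved + 1L
  state
}

#' The end-of-game explanation text
#'
#' Shown when the user gives up on a previously solved level: it draws the
#' parallel with learned helplessness and dysfunctional attribution style,
#' with emphasis on personalization and pervasiveness. Ships as an editable
#' text asset.
#'
#' @return A character scalar.
#' @export
lh_explanation_text <- function() {
  path <- system.file("extdata", "lh_explanation.txt", package = "cbmgames")
  paste(readLines(path, warn = FALSE), collapse = "\n")
}
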