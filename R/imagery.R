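#' Normalize a free-text completion phrase
#'
#' Lowercases, strips punctuation, and collapses internal whitespace so that
#' completion matching is invariant to case, punctuation and spacing. The
#' operation is idempotent.
#'
#' @param raw input string.
#' @return Normalized phrase.
#' @examples
#' normalize_phrase("WILL NOT.") # "will not"
#' @export
normalize_phrase <- function(raw) {
  x <- tolower(raw)
  x <- gsub("[^a-z0-9 ]+", " ", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Two-part ambiguous scenario for the imagery game
#'
#' Each level shows a paragraph with a blank, resolvable positively or
#' negatively by comparing the typed phrase against the part's completion
#' lists; part 2 continues the scenario after part 1 is resolved positively.
#'
#' @param part1,part2 scenario texts containing a `______` blank.
#' @param positive1,negative1,positive2,negative2 completion phrase lists
#'   per part (normalized internally; the lists must be disjoint).
#' @param level_index 0-based level index.
#' @return list of class `scenario`.
#' @export
scenario <- function(part1, part2, positive1, negative1, positive2,
                     negative2, level_index = 0L) {
  norm <- function(v) unique(vapply(v, normalize_phrase, ""))
  pos <- list(norm(positive1), norm(positive2))
  neg <- list(norm(negative1), norm(negative2))
  for (p in 1:2) {
    if (length(pos[[p]]) == 0L || length(neg[[p]]) == 0L) {
      stop("both completion lists must be non-empty", call. = FALSE)
    }
    both <- intersect(pos[[p]], neg[[p]])
    if (length(both) > 0L) {
      stop("completion lists overlap after normalization: ",
           paste(both, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(parts = c(part1, part2), positive = pos, negative = neg,
                 level_index = as.integer(level_index)),
            class = "scenario")
}

#' Load the bundled 20-scenario bank
#' @param path JSON file; defaults to the shipped bank.
#' @return list of [scenario()]s in level order.
#' @export
load_scenario_bank <- function(path = system.file("extdata",
                                                  "scenario_bank.json",
                                                  package = "cbmgames")) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(seq_along(raw$scenarios), function(i) {
    s <- raw$scenarios[[i]]
    scenario(s$part1, s$part2,
             unlist(s$positive1), unlist(s$negative1),
             unlist(s$positive2), unlist(s$negative2),
             level_index = i - 1L)
  })
}

#' Classify a completion phrase for one scenario part
#'
#' @param scen a [scenario()].
#' @param part 1 or 2.
#' @param phrase normalized phrase (see [normalize_phrase()]).
#' @return `"positive"`, `"negative"` or `"unrecognized"`.
#' @export
match_completion <- function(scen, part, phrase) {
  stopifnot(inherits(scen, "scenario"), part %in% c(1L, 2L))
  if (phrase %in% scen$positive[[part]]) return("positive")
  if (phrase %in% scen$negative[[part]]) return("negative")
  "unrecognized"
}

#' Session state of the imagery game
#' @param level_index starting 0-based level.
#' @return list of class `imagery_state`.
#' @export
imagery_state <- function(level_index = 0L) {
  structure(list(level_index = as.integer(level_index), part = 1L,
                 attempts = 0L, points = 0L,
                 positive_resolutions = 0L, badges = character()),
            class = "imagery_state")
}

#' Submit a completion attempt
#'
#' A positive resolution advances the scenario (part 1 to part 2, or level
#' conclusion after part 2) and earns 5 points; a negative resolution asks
#' the user to try again; an unrecognized phrase asks for a different one.
#' Both count as failed attempts, and after 3 failed attempts the positive
#' completion list is offered as multiple choice (selection then advances
#' with the same reward). Badges are earned at 4, 10 and 26 positive
#' resolutions. There is no time limit. After level 19 concludes, the game
#' loops to level 0.
#'
#' @param state an [imagery_state()].
#' @param scen the current [scenario()].
#' @param phrase raw free-text completion (normalized internally), or the
#'   phrase picked from the choice list.
#' @param n_levels bank size for the loop.
#' @param points_per_resolution reward per positive resolution.
#' @return list with updated `state` and `feedback` in
#'   `c("advance", "level_concluded", "try_again", "could_not_understand",
#'      "show_choices")`.
#' @export
submit_attempt <- function(state, scen, phrase, n_levels = 20L,
                           points_per_resolution = 5L) {
  stopifnot(inherits(state, "imagery_state"), inherits(scen, "scenario"))
  res <- match_completion(scen, state$part, normalize_phrase(phrase))
  if (res == "positive") {
    state$points <- state$points + as.integer(points_per_resolution)
    state$positive_resolutions <- state$positive_resolutions + 1L
    state$attempts <- 0L
    rule <- badge_rule("positive_resolutions", 4, 10, 26)
    eco <- award_badges(state$positive_resolutions, rule,
                        economy_state(badges = state$badges))
    state$badges <- eco$badges
    if (state$part == 1L) {
      state$part <- 2L
      return(list(state = state, feedback = "advance"))
    }
    state$part <- 1L
    state$level_index <- (state$level_index + 1L) %% as.integer(n_levels)
    return(list(state = state, feedback = "level_concluded"))
  }
  state$attempts <- state$attempts + 1L
  if (state$attempts >= 3L) {
    return(list(state = state, feedback = "show_choices"))
  }
  feedback <- if (res == "negative") "try_again" else "could_not_understand"
  list(state = state, feedback = feedback)
}

#' Resolve a part from the offered choice list
#'
#' Fallback after three failed attempts: the user selects one of the
#' positive completions, which advances the scenario with the usual reward.
#'
#' @param state an [imagery_state()].
#' @param scen the current [scenario()].
#' @param choice_index index into the part's positive completion list.
#' @param ... passed to [submit_attempt()].
#' @return As [submit_attempt()].
#' @export
choose_completion <- function(state, scen, choice_index = 1L, ...) {
  pos <- scen$positive[[state$part]]
  stopifnot(choice_index >= 1L, choice_index <= length(pos))
  submit_attempt(state, scen, pos[[choice_index]], ...)
}
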