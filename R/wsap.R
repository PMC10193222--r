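#' Sentence items for the interpretation-bias word-search game
#'
#' Each level pairs a sentence with a single valenced probe word. For regular
#' items the sentence is ambiguous and the trained response is *Yes* for a
#' positive probe and *No* for a negative one. Decoy items are unambiguous
#' (negative-toned) sentences whose negative word genuinely relates — there
#' the correct answer is *Yes* exactly for a negative probe — which prevents
#' rote yes-to-positive responding.
#'
#' @param sentence sentence text (alphabetic words and spaces).
#' @param probe_word the probe shown after the sentence reveal.
#' @param probe_valence `"positive"` or `"negative"`.
#' @param is_decoy logical; decoys invert the valence-to-answer mapping.
#' @return A list of class `sentence_item` with the derived fields `words`
#'   (unique uppercase hidden words) and `correct_answer` (`"yes"`/`"no"`).
#' @export
sentence_item <- function(sentence, probe_word, probe_valence,
                          is_decoy = FALSE) {
  stopifnot(is.character(sentence), nzchar(sentence),
            probe_valence %in% c("positive", "negative"))
  words <- sentence_words(sentence)
  if (length(words) == 0L) stop("sentence contains no words", call. = FALSE)
  correct <- if (!is_decoy) {
    if (probe_valence == "positive") "yes" else "no"
  } else {
    if (probe_valence == "negative") "yes" else "no"
  }
  structure(list(sentence = sentence, words = words,
                 probe_word = toupper(probe_word),
                 probe_valence = probe_valence,
                 is_decoy = isTRUE(is_decoy),
                 correct_answer = correct),
            class = "sentence_item")
}

sentence_words <- function(sentence) {
  w <- toupper(unlist(strsplit(sentence, "[^A-Za-z]+")))
  unique(w[nzchar(w)])
}

#' Load the bundled 42-item sentence bank
#'
#' Levels are ordered by `(word count, longest-word length)` ascending, so
#' the ladder grows gradually harder; the first four levels additionally show
#' the hidden words jumbled and grant the longest time budgets.
#'
#' @param path JSON bank file; defaults to the bank shipped with the package.
#' @return A list of [sentence_item()]s in level order (level index 0 is the
#'   first element).
#' @export
load_wsap_bank <- function(path = system.file("extdata", "wsap_bank.json",
                                              package = "cbmgames")) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  items <- lapply(raw$items, function(it) {
    sentence_item(it$sentence, it$probe_word, it$probe_valence,
                  isTRUE(it$is_decoy))
  })
  ord <- order(vapply(items, function(it) length(it$words), 1L),
               vapply(items, function(it) max(nchar(it$words)), 1L))
  items[ord]
}

#' Load the bundled bonus-word dictionary
#'
#' Small common-word list used to score valid English words that are not
#' part of the sentence; words shorter than 2 letters never score.
#'
#' @param path one word per line, any case.
#' @return Uppercase character vector.
#' @export
load_bonus_dictionary <- function(path = system.file("extdata", "wordlist.txt",
                                                     package = "cbmgames")) {
  w <- toupper(trimws(readLines(path, warn = FALSE)))
  unique(w[nchar(w) >= 2L])
}

#' Per-level schedule of the word-search game
#'
#' The first two levels allot 150 s, the next two 120 s, and both show the
#' sentence's words jumbled as a tutorial aid; later levels run on the
#' default budget with hidden words.
#'
#' @param level_index 0-based level index.
#' @param default_ms time budget for levels beyond the tutorial block.
#' @return list with `allotted_ms` and `words_jumbled_visible`.
#' @export
wsap_level_schedule <- function(level_index, default_ms = 90000L) {
  stopifnot(level_index >= 0L)
  allotted <- if (level_index < 2L) 150000L
              else if (level_index < 4L) 120000L
              else as.integer(default_ms)
  list(allotted_ms = allotted, words_jumbled_visible = level_index < 4L)
}

#' Advance to the next level of the 42-level loop
#'
#' After the last level the game loops back to the first.
#'
#' @param level_index current 0-based level.
#' @param n_levels number of levels in the bank.
#' @return The next 0-based level index.
#' @export
next_level <- function(level_index, n_levels = 42L) {
  stopifnot(level_index >= 0L, level_index < n_levels)
  (as.integer(level_index) + 1L) %% as.integer(n_levels)
}

#' Sentence display duration scaled to reading speed
#'
#' The sentence reveal is shown for `100 + TC / ARS` milliseconds, where `TC`
#' is the total character count and `ARS` the average reading speed of about
#' 50 characters per 1000 ms — i.e. `100 + 20 * TC` ms.
#'
#' @param sentence non-empty sentence text.
#' @return Duration in milliseconds.
#' @examples
#' display_duration_ms(strrep("x", 50)) # 1100
#' @export
display_duration_ms <- function(sentence) {
  stopifnot(is.character(sentence), length(sentence) == 1L)
  if (!nzchar(sentence)) stop("sentence must be non-empty", call. = FALSE)
  tc <- nchar(sentence)
  as.integer(100 + 20 * tc)
}

# -- letter grid -------------------------------------------------------------

GRID_DIRECTIONS <- rbind(
  c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L),
  c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L)
)

#' Build a word-search letter grid for a sentence item
#'
#' Every hidden word is placed along a straight line of contiguous cells in
#' one of the eight compass directions (words may cross where letters agree);
#' the remaining cells are filled with uniform random letters from the item's
#' stream. Layout is reproducible for a fixed stream.
#'
#' @param item a [sentence_item()].
#' @param dims `c(rows, cols)`; defaults to 8 x 8 grown to fit the longest
#'   word.
#' @param rng an [rng_stream()].
#' @param max_restarts bound on full placement retries before a layout error.
#' @return A list of class `letter_grid` with `cells` (character matrix) and
#'   `placements` (named list of n x 2 cell-path matrices).
#' @export
build_letter_grid <- function(item, dims = NULL, rng = rng_stream(1L, "wsap.grid"),
                              max_restarts = 25L) {
  stopifnot(inherits(item, "sentence_item"))
  longest <- max(nchar(item$words))
  if (is.null(dims)) dims <- rep(max(8L, longest), 2L)
  rows <- as.integer(dims[1]); cols <- as.integer(dims[2])
  if (longest > max(rows, cols)) {
    stop(sprintf("word of length %d cannot fit a %d x %d grid",
                 longest, rows, cols), call. = FALSE)
  }
  words <- item$words[order(-nchar(item$words))] # longest first packs better
  for (restart in seq_len(max_restarts)) {
    cells <- matrix(NA_character_, rows, cols)
    placements <- list()
    ok <- TRUE
    for (w in words) {
      pl <- place_word(cells, w, rng)
      if (is.null(pl)) { ok <- FALSE; break }
      cells <- pl$cells
      placements[[w]] <- pl$path
    }
    if (ok) {
      fill <- is.na(cells)
      cells[fill] <- LETTERS[rng_int(rng, sum(fill), 26L)]
      return(structure(list(rows = rows, cols = cols, cells = cells,
                            placements = placements),
                       class = "letter_grid"))
    }
  }
  stop("could not place all words after bounded retries", call. = FALSE)
}

place_word <- function(cells, word, rng, tries = 200L) {
  rows <- nrow(cells); cols <- ncol(cells)
  letters_w <- strsplit(word, "")[[1]]
  n <- length(letters_w)
  for (t in seq_len(tries)) {
    d <- GRID_DIRECTIONS[rng_int(rng, 1L, 8L), ]
    r0 <- rng_int(rng, 1L, rows); c0 <- rng_int(rng, 1L, cols)
    rr <- r0 + d[1] * (seq_len(n) - 1L)
    cc <- c0 + d[2] * (seq_len(n) - 1L)
    if (any(rr < 1L | rr > rows | cc < 1L | cc > cols)) next
    existing <- cells[cbind(rr, cc)]
    if (any(!is.na(existing) & existing != letters_w)) next
    cells[cbind(rr, cc)] <- letters_w
    return(list(cells = cells, path = cbind(row = rr, col = cc)))
  }
  NULL
}

#' Read the letters along a cell path
#' @param grid a [letter_grid()].
#' @param path n x 2 matrix of (row, col) cells.
#' @return The spelled string.
#' @export
read_path <- function(grid, path) {
  path <- matrix(as.integer(path), ncol = 2L)
  paste(grid$cells[path], collapse = "")
}

path_is_straight <- function(path) {
  n <- nrow(path)
  if (n < 1L) return(FALSE)
  if (n == 1L) return(TRUE)
  dr <- diff(path[, 1]); dc <- diff(path[, 2])
  if (!all(dr == dr[1]) || !all(dc == dc[1])) return(FALSE)
  max(abs(dr[1]), abs(dc[1])) == 1L && (abs(dr[1]) <= 1L && abs(dc[1]) <= 1L)
}

# -- level state -------------------------------------------------------------

#' Start a word-search level
#'
#' @param item a [sentence_item()].
#' @param level_index 0-based level index (drives the time schedule).
#' @param default_ms fallback time budget, see [wsap_level_schedule()].
#' @return A list of class `wsap_level_state`.
#' @export
wsap_level_start <- function(item, level_index = 0L, default_ms = 90000L) {
  sched <- wsap_level_schedule(level_index, default_ms)
  structure(list(item = item, level_index = as.integer(level_index),
                 words_found = character(), bonus_words_found = character(),
                 allotted_ms = sched$allotted_ms,
                 time_remaining_ms = sched$allotted_ms,
                 words_jumbled_visible = sched$words_jumbled_visible,
                 sentence_revealed = FALSE, points = 0L,
                 phase = "searching"),
            class = "wsap_level_state")
}

reveal_threshold <- function(n_words) as.integer(ceiling(n_words / 2))

#' Submit a traced path during the search phase
#'
#' A straight, contiguous path spelling an unfound sentence word scores as a
#' sentence word and fills one progress bar; a straight path spelling a
#' dictionary word (>= 2 letters) that is not part of the sentence scores as
#' a bonus word; anything else is rejected without a state change. When half
#' the words (ceiling for odd counts) have been found the full ambiguous
#' sentence is revealed and the probe phase can begin.
#'
#' @param state a [wsap_level_start()] state.
#' @param grid the level's [build_letter_grid()] grid.
#' @param path n x 2 matrix of (row, col) cells.
#' @param dictionary uppercase word set for bonus scoring.
#' @param word_points,bonus_points points per sentence/bonus word.
#' @return list with updated `state` and `outcome` in
#'   `c("sentence_word", "bonus_word", "rejected")`.
#' @export
submit_path <- function(state, grid, path, dictionary = character(),
                        word_points = 10L, bonus_points = 5L) {
  stopifnot(inherits(state, "wsap_level_state"), inherits(grid, "letter_grid"))
  if (state$phase != "searching" || state$time_remaining_ms <= 0L) {
    return(list(state = state, outcome = "rejected"))
  }
  path <- matrix(as.integer(path), ncol = 2L)
  inb <- path[, 1] >= 1L & path[, 1] <= grid$rows &
         path[, 2] >= 1L & path[, 2] <= grid$cols
  if (!all(inb) || !path_is_straight(path)) {
    return(list(state = state, outcome = "rejected"))
  }
  word <- paste(grid$cells[path], collapse = "")
  if (word %in% state$item$words && !(word %in% state$words_found)) {
    state$words_found <- c(state$words_found, word)
    state$points <- state$points + as.integer(word_points)
    if (length(state$words_found) >= reveal_threshold(length(state$item$words))) {
      state$sentence_revealed <- TRUE
    }
    if (setequal(state$words_found, state$item$words)) state$phase <- "probe"
    return(list(state = state, outcome = "sentence_word"))
  }
  if (nchar(word) >= 2L && word %in% toupper(dictionary) &&
      !(word %in% state$item$words) && !(word %in% state$bonus_words_found)) {
    state$bonus_words_found <- c(state$bonus_words_found, word)
    state$points <- state$points + as.integer(bonus_points)
    return(list(state = state, outcome = "bonus_word"))
  }
  list(state = state, outcome = "rejected")
}

#' Score a timed relatedness probe
#'
#' Incorrect or out-of-window answers earn 0; correct in-window answers earn
#' `ceiling(max_points * (1 - rt/window))` with a floor of one point, so the
#' reward decreases with response time but any correct answer pays.
#'
#' @param item a [sentence_item()]; fixes the correct answer (decoys invert
#'   the valence mapping).
#' @param answer `"yes"` or `"no"`.
#' @param rt_ms response time in ms.
#' @param window_ms response window (default 5000 ms).
#' @param max_points reward for an instantaneous correct answer.
#' @return Integer points.
#' @export
score_probe <- function(item, answer, rt_ms, window_ms = 5000L,
                        max_points = 10L) {
  stopifnot(inherits(item, "sentence_item"), answer %in% c("yes", "no"),
            rt_ms >= 0)
  if (rt_ms > window_ms) return(0L)
  if (answer != item$correct_answer) return(0L)
  max(1L, as.integer(ceiling(max_points * (1 - rt_ms / window_ms))))
}
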